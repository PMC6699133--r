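# Satterthwaite degrees of freedom for linear combinations of fixed effects
# in a random-intercept lmer fit, computed from the dense REML criterion.
#
# For variance parameters phi = (sigma_b^2, sigma^2) the marginal covariance
# is V(phi) = phi2 I + phi1 Z Z'. With f(phi) = L' (X' V^-1 X)^-1 L the
# Satterthwaite df of the t statistic for L'beta is
#   df = 2 f(phi_hat)^2 / (g' A g),
# g the gradient of f at phi_hat and A the asymptotic covariance of phi_hat,
# A = 2 H^-1 with H the hessian of the -2 log REML likelihood. The models in
# scope are small (<= a few hundred rows), so everything is done densely.

.remlCrit <- function(phi, y, X, ZZt) {
  n <- length(y)
  V <- phi[2] * diag(n) + phi[1] * ZZt
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(NA_real_)
  logdetV <- 2 * sum(log(diag(ch)))
  Vi <- chol2inv(ch)
  XtViX <- crossprod(X, Vi %*% X)
  ch2 <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(ch2)) return(NA_real_)
  beta <- chol2inv(ch2) %*% crossprod(X, Vi %*% y)
  r <- y - X %*% beta
  as.numeric(logdetV + 2 * sum(log(diag(ch2))) + crossprod(r, Vi %*% r))
}

.contrastVar <- function(phi, L, X, ZZt) {
  n <- nrow(X)
  V <- phi[2] * diag(n) + phi[1] * ZZt
  Vi <- chol2inv(chol(V))
  Ci <- chol2inv(chol(crossprod(X, Vi %*% X)))
  as.numeric(t(L) %*% Ci %*% L)
}

#' Satterthwaite-corrected tests for a random-intercept mixed model
#'
#' Computes, for each row of `L`, the estimate `L beta`, its standard error,
#' Satterthwaite degrees of freedom, t statistic and two-sided p-value, from a
#' `lme4::lmer` fit with a single random intercept term. When the class
#' variance is estimated at (or numerically indistinguishable from) the
#' boundary, the hessian of the REML criterion is singular; the residual
#' degrees of freedom `n - p` are then used and flagged in the `note` column.
#'
#' @param fit an `lmerMod` with exactly one random intercept grouping factor,
#'   fitted by REML.
#' @param L numeric matrix (rows = linear combinations of the fixed effects)
#'   or a single vector.
#' @return a data.frame: `estimate`, `se`, `df`, `t`, `p`, `note`.
#' @export
satterthwaiteTests <- function(fit, L) {
  if (is.null(dim(L))) L <- matrix(L, nrow = 1)
  y <- lme4::getME(fit, "y")
  X <- as.matrix(lme4::getME(fit, "X"))
  Z <- as.matrix(lme4::getME(fit, "Z"))
  ZZt <- tcrossprod(Z)
  vc <- lme4::VarCorr(fit)
  phi <- c(as.numeric(vc[[1]]), stats::sigma(fit)^2)
  beta <- lme4::fixef(fit)
  n <- length(y); p <- ncol(X)

  est <- as.numeric(L %*% beta)
  out <- data.frame(estimate = est, se = NA_real_, df = NA_real_,
                    t = NA_real_, p = NA_real_, note = "")
  fallback <- function(i) {
    v <- .contrastVar(c(max(phi[1], 0), phi[2]), L[i, ], X, ZZt)
    out$se[i] <<- sqrt(v)
    out$df[i] <<- n - p
    out$note[i] <<- "boundary fit; residual df"
  }
  H <- tryCatch(numDeriv::hessian(.remlCrit, phi, y = y, X = X, ZZt = ZZt),
                error = function(e) NULL)
  A <- if (!is.null(H) && all(is.finite(H)))
    tryCatch(2 * solve(H), error = function(e) NULL) else NULL
  for (i in seq_len(nrow(L))) {
    v <- tryCatch(.contrastVar(phi, L[i, ], X, ZZt), error = function(e) NA)
    if (!is.finite(v) || v <= 0 || is.null(A) || phi[1] < 1e-10 * phi[2]) {
      fallback(i); next
    }
    g <- tryCatch(numDeriv::grad(.contrastVar, phi, L = L[i, ], X = X, ZZt = ZZt),
                  error = function(e) NULL)
    out$se[i] <- sqrt(v)
    denom <- if (is.null(g)) NA else as.numeric(t(g) %*% A %*% g)
    df <- if (is.finite(denom) && denom > 0) 2 * v^2 / denom else NA
    if (!is.finite(df) || df <= 0) {
      out$df[i] <- n - p
      out$note[i] <- "unstable hessian; residual df"
    } else out$df[i] <- min(df, n - p)
  }
  out$t <- out$estimate / out$se
  out$p <- 2 * stats::pt(abs(out$t), out$df, lower.tail = FALSE)
  out
}
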