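#' Condition ordering and the planned-contrast scheme
#'
#' The five conditions are ordered control, random, in_degree, betweenness,
#' closeness, and compared through four orthogonal planned contrasts
#' (Helmert-style nesting):
#' \enumerate{
#'   \item the four interventions vs control (model validity),
#'   \item the three centrality conditions vs random agents,
#'   \item betweenness + closeness vs in-degree,
#'   \item closeness vs betweenness.
#' }
#' Rows are scaled as differences of condition means (each row averages the
#' groups it compares), so a contrast estimate reads directly as "mean of
#' group A minus mean of group B" in success-rate percentage points. Rows sum
#' to zero and are pairwise orthogonal.
#'
#' @return a 4 x 5 matrix; rownames are the contrast labels, colnames the
#'   condition levels.
#' @export
helmertScheme <- function() {
  lev <- conditionLevels()
  m <- rbind(
    interventions_vs_control   = c(-1, 1/4, 1/4, 1/4, 1/4),
    centrality_vs_random       = c(0, -1, 1/3, 1/3, 1/3),
    betw_close_vs_indegree     = c(0, 0, -1, 1/2, 1/2),
    closeness_vs_betweenness   = c(0, 0, 0, -1, 1))
  colnames(m) <- lev
  m
}

#' Condition factor levels in contrast order
#' @return character vector of the five condition names.
#' @export
conditionLevels <- function() {
  c("control", "random", "in_degree", "betweenness", "closeness")
}

# contrast coding whose fitted coefficients EQUAL the mean-difference
# contrasts of helmertScheme(): columns of solve(rbind(intercept, scheme))
.conditionCoding <- function(scheme = helmertScheme()) {
  lev <- colnames(scheme)
  Lfull <- rbind(intercept = rep(1 / length(lev), length(lev)), scheme)
  C <- solve(Lfull)[, -1, drop = FALSE]
  rownames(C) <- lev
  C
}

.conditionFactor <- function(x) {
  lev <- conditionLevels()
  bad <- setdiff(unique(x), lev)
  if (length(bad)) stop("unknown condition name(s): ", paste(bad, collapse = ", "))
  factor(x, levels = lev)
}

#' Mixed-effects model of condition success rates with planned contrasts
#'
#' Fits `success_rate ~ condition + (1 | class_id)` by REML, with the
#' condition factor coded so each fitted coefficient is one of the four
#' planned mean-difference contrasts of [helmertScheme()]. Degrees of freedom
#' are Satterthwaite-corrected via [satterthwaiteTests()]. Singular fits
#' (class variance at the boundary) are reported in the table's `note` column
#' and the `singular` flag, never dropped.
#'
#' @param results a results table from [runExperiment()] (the random condition
#'   must already be its replicate average, one row per class x condition).
#' @param scheme contrast matrix, by default [helmertScheme()].
#' @return a list: `contrasts` (estimate, se, df, t, p per planned contrast),
#'   `means` (per-condition mean success rates), `fit` (the `lmerMod`),
#'   `singular` (logical).
#' @export
fitConditionModel <- function(results, scheme = helmertScheme()) {
  stopifnot(all(c("class_id", "condition", "success_rate") %in% names(results)))
  d <- data.frame(class_id = factor(results$class_id),
                  condition = .conditionFactor(results$condition),
                  success_rate = results$success_rate)
  if (nlevels(d$class_id) < 2L) stop("need at least 2 classes")
  if (any(table(d$class_id, d$condition) != 1L))
    stop("need exactly one row per class x condition")
  C <- .conditionCoding(scheme)
  stats::contrasts(d$condition) <- C
  fit <- lme4::lmer(success_rate ~ condition + (1 | class_id), data = d,
                    REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  # rows of L pick the condition coefficients (intercept first in fixef)
  p <- length(lme4::fixef(fit))
  L <- cbind(0, diag(p - 1))
  tab <- satterthwaiteTests(fit, L)
  tab <- cbind(contrast = rownames(scheme), tab)
  rownames(tab) <- NULL
  means <- tapply(d$success_rate, d$condition, mean)
  singular <- lme4::isSingular(fit)
  if (singular)
    tab$note <- paste0(tab$note, ifelse(nzchar(tab$note), "; ", ""), "singular fit")
  list(contrasts = tab, means = means, fit = fit, singular = singular)
}

#' Repeated-measures ANOVA of conditions with sphericity correction
#'
#' Treats the class x condition success-rate table as a one-way
#' within-subjects design: Mauchly's test of sphericity (via
#' `stats::mauchly.test` on the multivariate fit), Greenhouse-Geisser and
#' Huynh-Feldt epsilons (HF clamped at 1), and the epsilon-corrected F test
#' for the condition effect.
#'
#' @param results a results table from [runExperiment()].
#' @return a list: `mauchly_W`, `mauchly_p`, `gg_epsilon`, `hf_epsilon`,
#'   `F`, `df1`, `df2` (uncorrected), `p_uncorrected`, `p_hf` (Huynh-Feldt
#'   corrected), `n_classes`.
#' @export
rmAnovaSphericity <- function(results) {
  lev <- intersect(conditionLevels(), unique(results$condition))
  if (length(lev) < 3L) stop("sphericity requires at least 3 conditions")
  wide <- stats::reshape(
    results[, c("class_id", "condition", "success_rate")],
    idvar = "class_id", timevar = "condition", direction = "wide")
  Y <- as.matrix(wide[, paste0("success_rate.", lev)])
  colnames(Y) <- lev
  n <- nrow(Y); k <- ncol(Y)
  if (anyNA(Y)) stop("class x condition table must be complete")
  if (n <= k) stop("need more classes than conditions for Mauchly's test")

  mlmfit <- stats::lm(Y ~ 1)
  idata <- data.frame(condition = factor(lev, levels = lev))
  mt <- stats::mauchly.test(mlmfit, X = ~1, M = ~condition, idata = idata)

  # epsilons from the covariance of orthonormal within-subject contrasts
  Ctr <- stats::contr.helmert(k)
  Ctr <- sweep(Ctr, 2, sqrt(colSums(Ctr^2)), "/")
  Sc <- t(Ctr) %*% stats::cov(Y) %*% Ctr
  gg <- sum(diag(Sc))^2 / ((k - 1) * sum(Sc^2))
  hf <- (n * (k - 1) * gg - 2) / ((k - 1) * (n - 1 - (k - 1) * gg))
  hf <- min(max(hf, gg), 1)  # clamp: reported epsilon stays interpretable

  grand <- mean(Y)
  ss_cond <- n * sum((colMeans(Y) - grand)^2)
  resid <- Y - outer(rowMeans(Y), rep(1, k)) -
    outer(rep(1, n), colMeans(Y)) + grand
  ss_err <- sum(resid^2)
  df1 <- k - 1; df2 <- (n - 1) * (k - 1)
  Fval <- (ss_cond / df1) / (ss_err / df2)
  list(mauchly_W = unname(mt$statistic), mauchly_p = mt$p.value,
       gg_epsilon = gg, hf_epsilon = hf,
       F = Fval, df1 = df1, df2 = df2,
       p_uncorrected = stats::pf(Fval, df1, df2, lower.tail = FALSE),
       p_hf = stats::pf(Fval, df1 * hf, df2 * hf, lower.tail = FALSE),
       n_classes = n)
}

#' Moderation of condition effects by a class-structure measure
#'
#' Refits the condition model with a standardized class-level moderator
#' (density or one of the centralizations) and its interactions with the
#' planned contrasts: `success_rate ~ condition * moderator + (1 | class_id)`.
#' Satterthwaite degrees of freedom throughout.
#'
#' @param results a results table from [runExperiment()].
#' @param moderator one of `"density"`, `"centralization_in_degree"`,
#'   `"centralization_betweenness"`, `"centralization_closeness"`.
#' @param structure a class-structure table from [classStructure()].
#' @param scheme contrast matrix, by default [helmertScheme()].
#' @return a list: `table` (main effect of the moderator and its interaction
#'   with each planned contrast, plus the condition contrasts), `fit`,
#'   `moderator`, `singular`.
#' @export
fitModerationModel <- function(results, moderator, structure,
                               scheme = helmertScheme()) {
  stopifnot(moderator %in% c("density", "centralization_in_degree",
                             "centralization_betweenness",
                             "centralization_closeness"))
  mod <- structure[[moderator]][match(results$class_id, structure$class_id)]
  if (anyNA(mod)) stop("moderator missing for some classes")
  if (stats::sd(structure[[moderator]]) == 0)
    stop("moderator has zero variance across classes")
  d <- data.frame(class_id = factor(results$class_id),
                  condition = .conditionFactor(results$condition),
                  success_rate = results$success_rate,
                  mod = as.numeric(scale(mod)))
  stats::contrasts(d$condition) <- .conditionCoding(scheme)
  fit <- lme4::lmer(success_rate ~ condition * mod + (1 | class_id), data = d,
                    REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  fe <- lme4::fixef(fit)
  L <- diag(length(fe))[-1, , drop = FALSE]  # all non-intercept coefficients
  tab <- satterthwaiteTests(fit, L)
  term <- names(fe)[-1]
  label <- sub("^condition", "", term)
  label <- ifelse(label == "mod", paste0(moderator, " (main)"),
                  ifelse(grepl(":mod$", label),
                         paste0(sub(":mod$", "", label), " x ", moderator),
                         label))
  # coefficient names follow the contrast labels of the coding matrix
  tab <- cbind(term = label, tab)
  rownames(tab) <- NULL
  singular <- lme4::isSingular(fit)
  if (singular)
    tab$note <- paste0(tab$note, ifelse(nzchar(tab$note), "; ", ""), "singular fit")
  list(table = tab, fit = fit, moderator = moderator, singular = singular)
}

#' Correlations between intervention success and network structure
#'
#' Pearson correlations of each intervention condition's per-class success
#' rate with each class-structure measure (density and the three
#' centralizations), with two-sided p-values and significance flags at .05 —
#' a 4-structures x 4-interventions matrix.
#'
#' @param results a results table from [runExperiment()].
#' @param structure a class-structure table from [classStructure()].
#' @return a list of 4 x 4 matrices `r`, `p` and logical `sig` (rows =
#'   structures, columns = interventions).
#' @export
structureCorrelations <- function(results, structure) {
  interventions <- c("in_degree", "betweenness", "closeness", "random")
  measures <- c("density", "centralization_in_degree",
                "centralization_betweenness", "centralization_closeness")
  r <- p <- matrix(NA_real_, length(measures), length(interventions),
                   dimnames = list(measures, interventions))
  for (cond in interventions) {
    sub <- results[results$condition == cond, ]
    x <- sub$success_rate[match(structure$class_id, sub$class_id)]
    for (m in measures) {
      y <- structure[[m]]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) next
      ct <- stats::cor.test(x, y)
      r[m, cond] <- unname(ct$estimate)
      p[m, cond] <- ct$p.value
    }
  }
  list(r = r, p = p, sig = p < 0.05)
}

#' Full statistical evaluation of an experiment
#'
#' Planned contrasts, sphericity-corrected RM-ANOVA, moderation by every
#' structure measure, and the structure correlation matrix, in one object.
#'
#' @param results a results table from [runExperiment()].
#' @param structure a class-structure table from [classStructure()].
#' @return a list of the four component results (`condition_model`,
#'   `rm_anova`, `moderation`, `correlations`).
#' @export
evaluateExperiment <- function(results, structure) {
  cm <- fitConditionModel(results)
  rm <- tryCatch(rmAnovaSphericity(results), error = function(e) {
    warning("RM-ANOVA unavailable: ", conditionMessage(e))
    NULL
  })
  mods <- lapply(c("density", "centralization_in_degree",
                   "centralization_betweenness", "centralization_closeness"),
                 function(m) tryCatch(fitModerationModel(results, m, structure),
                                      error = function(e) NULL))
  names(mods) <- c("density", "centralization_in_degree",
                   "centralization_betweenness", "centralization_closeness")
  list(condition_model = cm, rm_anova = rm, moderation = mods,
       correlations = structureCorrelations(results, structure))
}

#' Write the evaluation report
#'
#' Emits `evaluation_report.json` (machine-readable) and `report.txt`
#' (human-readable) into `dir`.
#'
#' @param evaluation output of [evaluateExperiment()].
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
writeEvaluation <- function(evaluation, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cm <- evaluation$condition_model
  rm <- evaluation$rm_anova
  json <- list(
    condition_means = as.list(cm$means),
    contrasts = cm$contrasts,
    singular = cm$singular,
    rm_anova = if (!is.null(rm)) rm[c("mauchly_W", "mauchly_p", "gg_epsilon",
                                      "hf_epsilon", "F", "df1", "df2",
                                      "p_uncorrected", "p_hf")],
    moderation = lapply(evaluation$moderation, function(m)
      if (!is.null(m)) m$table),
    correlations = list(r = evaluation$correlations$r,
                        p = evaluation$correlations$p))
  jpath <- file.path(dir, "evaluation_report.json")
  jsonlite::write_json(json, jpath, auto_unbox = TRUE, digits = 10,
                       dataframe = "rows", matrix = "rowmajor", na = "null")

  tpath <- file.path(dir, "report.txt")
  con <- file(tpath, "w"); on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("Condition mean success rates (%%):")
  for (nm in names(cm$means)) w("  %-12s %8.3f", nm, cm$means[[nm]])
  w("")
  w("Planned contrasts (Satterthwaite df):")
  for (i in seq_len(nrow(cm$contrasts))) {
    r <- cm$contrasts[i, ]
    w("  %-26s est %8.3f  se %7.3f  df %7.2f  t %7.2f  p %.4g %s",
      r$contrast, r$estimate, r$se, r$df, r$t, r$p, r$note)
  }
  if (!is.null(rm)) {
    w("")
    w("RM-ANOVA: Mauchly W = %.4g (p = %.4g); HF epsilon = %.3f",
      rm$mauchly_W, rm$mauchly_p, rm$hf_epsilon)
    w("  F(%.2f, %.2f) = %.3f, p = %.4g (HF-corrected)",
      rm$df1 * rm$hf_epsilon, rm$df2 * rm$hf_epsilon, rm$F, rm$p_hf)
  }
  w("")
  w("Correlations of per-class success rates with class structure:")
  rmat <- evaluation$correlations$r
  w("  %-28s %s", "structure", paste(sprintf("%12s", colnames(rmat)), collapse = ""))
  for (m in rownames(rmat))
    w("  %-28s %s", m, paste(sprintf("%12.3f", rmat[m, ]), collapse = ""))
  invisible(c(jpath, tpath))
}
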