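# simulate a balanced results table: one row per class x condition
sim_results <- function(n_classes = 26, cond_means = rep(0, 5),
                        sd_class = 3, sd_noise = 2) {
  lev <- conditionLevels()
  class_id <- sprintf("C%02d", seq_len(n_classes))
  d <- expand.grid(class_id = class_id, condition = lev,
                   stringsAsFactors = FALSE)
  u <- stats::rnorm(n_classes, 0, sd_class)
  names(u) <- class_id
  d$success_rate <- u[d$class_id] +
    cond_means[match(d$condition, lev)] +
    stats::rnorm(nrow(d), 0, sd_noise)
  d
}

test_that("the planned-contrast scheme is orthogonal and zero-sum", {
  H <- helmertScheme()
  expect_equal(rowSums(H), rep(0, 4), ignore_attr = TRUE)
  G <- H %*% t(H)
  expect_equal(G[lower.tri(G)], rep(0, 6), tolerance = 1e-12)
})

test_that("contrast estimates equal hand-computed cell-mean differences", {
  # noiseless table: class offsets + fixed condition means
  lev <- conditionLevels()
  mu <- c(control = 2, random = 5, in_degree = 7, betweenness = 4, closeness = 9)
  d <- expand.grid(class_id = sprintf("C%d", 1:8), condition = lev,
                   stringsAsFactors = FALSE)
  off <- stats::setNames(seq(-2, 5), sprintf("C%d", 1:8))
  d$success_rate <- mu[d$condition] + off[d$class_id]
  fitted <- suppressWarnings(fitConditionModel(d))  # noiseless fit is singular
  est <- fitted$contrasts$estimate
  expect_equal(est[1], mean(mu[-1]) - mu["control"], ignore_attr = TRUE,
               tolerance = 1e-6)
  expect_equal(est[2], mean(mu[3:5]) - mu["random"], ignore_attr = TRUE,
               tolerance = 1e-6)
  expect_equal(est[3], mean(mu[c("betweenness", "closeness")]) - mu["in_degree"],
               ignore_attr = TRUE, tolerance = 1e-6)
  expect_equal(est[4], mu["closeness"] - mu["betweenness"], ignore_attr = TRUE,
               tolerance = 1e-6)
})

test_that("null tables give near-zero contrasts; planted effects are recovered", {
  set.seed(60)
  # all conditions identical per class (pure class effects): estimates ~ 0
  d0 <- sim_results(n_classes = 12, sd_noise = 0)
  f0 <- suppressWarnings(fitConditionModel(d0))
  expect_true(all(abs(f0$contrasts$estimate) < 1e-8))

  # constant +4 added to every intervention vs control: contrast 1 recovers it
  d1 <- sim_results(n_classes = 26, cond_means = c(0, 4, 4, 4, 4))
  f1 <- fitConditionModel(d1)
  expect_lt(abs(f1$contrasts$estimate[1] - 4), 1.5)
  expect_lt(f1$contrasts$p[1], 0.01)
})

test_that("Satterthwaite df reproduce the classical balanced-design value", {
  set.seed(61)
  d <- sim_results(n_classes = 10, sd_class = 3, sd_noise = 2)
  f <- fitConditionModel(d)
  # balanced one-way within-class design: df = (I-1)(J-1) = 9 * 4 = 36
  expect_equal(f$contrasts$df, rep(36, 4), tolerance = 0.2)
  # and the standard errors agree with lme4's vcov
  se_lme4 <- sqrt(diag(as.matrix(vcov(f$fit))))[-1]
  expect_equal(f$contrasts$se, unname(se_lme4), tolerance = 1e-4)
})

test_that("singular fits are flagged, not dropped", {
  set.seed(62)
  d <- sim_results(n_classes = 8, sd_class = 0, sd_noise = 1)  # no class variance
  f <- suppressWarnings(fitConditionModel(d))
  expect_true(is.finite(f$contrasts$p[1]))
  if (f$singular) expect_true(all(grepl("singular", f$contrasts$note)))
})

test_that("type-I error of the interventions-vs-control contrast is near nominal", {
  set.seed(63)
  reps <- 300
  pvals <- vapply(seq_len(reps), function(i) {
    d <- sim_results(n_classes = 26, sd_class = 3, sd_noise = 2)
    suppressWarnings(fitConditionModel(d))$contrasts$p[1]
  }, numeric(1))
  rate <- mean(pvals < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("RM-ANOVA: epsilons bounded, null calibration, power at a planted effect", {
  set.seed(64)
  # under compound symmetry sphericity holds: Mauchly rejects ~ 5%
  rejects <- vapply(1:500, function(i) {
    d <- sim_results(n_classes = 26)
    r <- rmAnovaSphericity(d)
    c(r$mauchly_p < 0.05, r$hf_epsilon)
  }, numeric(2))
  expect_gte(mean(rejects[1, ]), 0.01)
  expect_lte(mean(rejects[1, ]), 0.10)
  expect_true(all(rejects[2, ] > 0 & rejects[2, ] <= 1))

  # planted condition effect of one residual SD: corrected F has power > 0.8
  hits <- vapply(1:200, function(i) {
    d <- sim_results(n_classes = 26, cond_means = c(0, 0, 0, 0, 2), sd_noise = 2)
    rmAnovaSphericity(d)$p_hf < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.8)

  expect_error(rmAnovaSphericity(sim_results()[
    sim_results()$condition %in% c("control", "random"), ]), "3 conditions")
})

test_that("moderation model: standardization, null interactions, slope recovery", {
  set.seed(65)
  lev <- conditionLevels()
  n_classes <- 26
  class_id <- sprintf("C%02d", seq_len(n_classes))
  structure <- data.frame(class_id = class_id,
                          density = stats::runif(n_classes, 0.4, 0.9),
                          centralization_in_degree = stats::runif(n_classes, 0.1, 0.4),
                          centralization_betweenness = stats::runif(n_classes, 0, 0.1),
                          centralization_closeness = stats::runif(n_classes, 0.1, 0.4))

  # success built as class effect + c * standardized density, c = 2.5
  covered <- vapply(1:200, function(i) {
    modz <- as.numeric(scale(structure$density))
    names(modz) <- class_id
    d <- expand.grid(class_id = class_id, condition = lev,
                     stringsAsFactors = FALSE)
    u <- stats::rnorm(n_classes, 0, 1); names(u) <- class_id
    d$success_rate <- u[d$class_id] + 2.5 * modz[d$class_id] +
      stats::rnorm(nrow(d), 0, 1)
    f <- suppressWarnings(fitModerationModel(d, "density", structure))
    main <- f$table[f$table$term == "density (main)", ]
    abs(main$estimate - 2.5) < 1.96 * main$se * 1.05
  }, logical(1))
  expect_gte(mean(covered), 0.9)

  # moderator uncorrelated with effects: interaction estimates center on zero
  set.seed(66)
  ints <- vapply(1:60, function(i) {
    d <- sim_results(n_classes = 20)
    f <- suppressWarnings(fitModerationModel(d, "density",
                                             structure[1:20, ]))
    mean(f$table$estimate[grepl(" x density$", f$table$term)])
  }, numeric(1))
  expect_lt(abs(mean(ints)), 0.5)

  const <- structure; const$density <- 0.5
  expect_error(fitModerationModel(sim_results(26), "density", const),
               "zero variance")
})

test_that("structure correlation matrix: shape, identity case, null flag rate", {
  set.seed(67)
  n_classes <- 24
  class_id <- sprintf("C%02d", seq_len(n_classes))
  structure <- data.frame(class_id = class_id,
                          density = stats::runif(n_classes, 0.4, 0.9),
                          centralization_in_degree = stats::runif(n_classes),
                          centralization_betweenness = stats::runif(n_classes),
                          centralization_closeness = stats::runif(n_classes))
  lev <- conditionLevels()
  d <- expand.grid(class_id = class_id, condition = lev,
                   stringsAsFactors = FALSE)
  # success identically equal to density: r = 1 in the density row
  d$success_rate <- structure$density[match(d$class_id, structure$class_id)]
  sc <- structureCorrelations(d, structure)
  expect_equal(dim(sc$r), c(4, 4))
  expect_equal(unname(sc$r["density", ]), rep(1, 4), tolerance = 1e-9)

  # independent columns: significance flags fire at about the nominal rate
  flags <- vapply(1:150, function(i) {
    d$success_rate <- stats::rnorm(nrow(d))
    mean(structureCorrelations(d, structure)$sig, na.rm = TRUE)
  }, numeric(1))
  expect_gte(mean(flags), 0.005)
  expect_lte(mean(flags), 0.12)
})
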