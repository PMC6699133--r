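#' Specification of a synthetic cohort
#'
#' Parameters of the synthetic-cohort generator. Defaults emulate the published
#' descriptives of the empirical sample the package stands in for: 26 classes
#' of 10-30 pupils, baseline physical activity level (PAL) 1.50 (SD 0.55) on
#' [0.45, 4.27], pooled daily steps SD 5,730, family-affluence sums 0-13
#' (mean 4.01, SD 1.52), and class network densities spanning 0.46-0.90.
#'
#' @param n_classes number of classes.
#' @param class_size_range integer pair: minimum and maximum class size.
#' @param density_target_range numeric pair: per-class network density targets
#'   are drawn uniformly from this interval.
#' @param sigma_pop_range numeric pair: the per-class dispersion (log-normal
#'   sigma) of the latent popularity weights that drive nomination
#'   probabilities; larger values give more centralized (star-like) classes.
#' @param nomination_rate multiplier on the per-class density target; > 1
#'   makes classes denser, < 1 sparser (targets are clamped to [0.02, 0.98]).
#' @param pal_mean,pal_sd,pal_min,pal_max truncated-normal parameters of the
#'   latent baseline PAL.
#' @param steps_mean,steps_sd daily-step descriptives; `steps_sd` sets the
#'   pooled dispersion of generated daily step counts (day-level noise is
#'   chosen so that between-participant plus within-participant variance
#'   matches it). `steps_mean` is retained for reference; the latent baseline
#'   is anchored on the PAL parameters, because steps and PAL are linked
#'   deterministically by [stepsToPal()] and the two published means are
#'   mutually inconsistent under that link.
#' @param fas_mean,fas_sd normal parameters of the family-affluence sum
#'   (rounded and clamped to 0..13).
#' @param p_wave_missing probability that a participant misses a wave entirely.
#' @param p_partial_wear probability that a day has < 1440 worn minutes.
#' @param p_low_steps probability that a day records < 1000 steps (device
#'   failure); both kinds of day are discarded by the validity filters.
#' @param dup_rate probability that a nomination is repeated in a second wave
#'   (duplicates are collapsed when networks are built).
#' @param seed integer seed; identical specs give byte-identical cohorts.
#'
#' @return a named list of class `cohortSpec`.
#' @seealso [generateCohort()]
#' @export
#' @examples
#' spec <- cohortSpec(n_classes = 4, seed = 7)
#' cohort <- generateCohort(spec)
#' cohort
cohortSpec <- function(n_classes = 26L,
                       class_size_range = c(10L, 30L),
                       density_target_range = c(0.46, 0.90),
                       sigma_pop_range = c(0.2, 1.0),
                       nomination_rate = 1.0,
                       pal_mean = 1.50, pal_sd = 0.55,
                       pal_min = 0.45, pal_max = 4.27,
                       steps_mean = 10505, steps_sd = 5730,
                       fas_mean = 4.01, fas_sd = 1.52,
                       p_wave_missing = 0.05,
                       p_partial_wear = 0.08,
                       p_low_steps = 0.03,
                       dup_rate = 0.3,
                       seed = 1L) {
  spec <- list(n_classes = as.integer(n_classes),
               class_size_range = as.integer(class_size_range),
               density_target_range = density_target_range,
               sigma_pop_range = sigma_pop_range,
               nomination_rate = nomination_rate,
               pal_mean = pal_mean, pal_sd = pal_sd,
               pal_min = pal_min, pal_max = pal_max,
               steps_mean = steps_mean, steps_sd = steps_sd,
               fas_mean = fas_mean, fas_sd = fas_sd,
               p_wave_missing = p_wave_missing,
               p_partial_wear = p_partial_wear,
               p_low_steps = p_low_steps,
               dup_rate = dup_rate,
               seed = as.integer(seed))
  stopifnot(spec$n_classes >= 1L,
            length(spec$class_size_range) == 2L,
            spec$class_size_range[1] >= 2L,
            diff(spec$class_size_range) >= 0L,
            all(spec$density_target_range > 0),
            all(spec$density_target_range < 1),
            spec$nomination_rate > 0,
            spec$pal_min < spec$pal_max,
            spec$pal_sd > 0, spec$steps_sd > 0)
  class(spec) <- "cohortSpec"
  spec
}

#' Keep only valid accelerometer days
#'
#' Applies the published day-validity rules: the first and last day of each
#' wave are discarded as partial (device hand-out and return), as are days
#' with fewer than 1440 worn minutes or fewer than 1000 steps.
#'
#' @param steps data.frame with columns `wave`, `day`, `minutes_worn`, `steps`
#'   (extra columns such as `participant_id` are carried through).
#' @return the filtered data.frame (possibly zero rows).
#' @export
#' @examples
#' d <- data.frame(wave = 1, day = 1:7, minutes_worn = 1440,
#'                 steps = c(9000, 900, 10000, 11000, 12000, 9500, 8000))
#' filterValidDays(d)  # day 1 and 7 partial, day 2 under 1000 steps
filterValidDays <- function(steps) {
  stopifnot(all(c("wave", "day", "minutes_worn", "steps") %in% names(steps)))
  if (!nrow(steps)) return(steps)
  first_last <- logical(nrow(steps))
  for (w in unique(steps$wave)) {
    idx <- which(steps$wave == w)
    d <- steps$day[idx]
    first_last[idx[d == min(d) | d == max(d)]] <- TRUE
  }
  keep <- !first_last & steps$minutes_worn == 1440 & steps$steps >= 1000
  steps[keep, , drop = FALSE]
}

#' Average steps per day within a wave
#'
#' Mean daily steps over the valid days of one wave, provided at least 3 valid
#' days exist; otherwise `NA` (the wave is treated as missing).
#'
#' @param steps a data.frame already filtered by [filterValidDays()].
#' @param wave wave number (1..4).
#' @return a single number, or `NA_real_` when fewer than 3 valid days remain.
#' @export
waveMeanSteps <- function(steps, wave) {
  s <- steps$steps[steps$wave == wave]
  if (length(s) < 3L) NA_real_ else mean(s)
}

#' Rescale daily steps to a physical activity level (PAL)
#'
#' `PAL = steps / 10000 * 1.53`, anchoring 10,000 steps per day at 1.53.
#'
#' @param steps non-negative steps per day (vectorized).
#' @return PAL values.
#' @export
#' @examples
#' stepsToPal(10000)  # 1.53
stepsToPal <- function(steps) {
  if (any(is.na(steps)) || any(steps < 0)) stop("steps must be non-negative")
  steps / 10000 * 1.53
}

#' Convert a family-affluence sum to the socio-environmental score
#'
#' The family-affluence item sum (0..13) is reflected and rescaled to
#' `env = (13 - sum) / 6.5`, clamped to [0, 2]. Higher `env` means lower
#' family affluence.
#'
#' @param fas_sum summed item scores in [0, 13] (vectorized).
#' @return env scores in [0, 2].
#' @export
#' @examples
#' fasToEnv(13)  # 0: maximal affluence
#' fasToEnv(0)   # 2: minimal affluence
fasToEnv <- function(fas_sum) {
  if (any(is.na(fas_sum)) || any(fas_sum < 0 | fas_sum > 13))
    stop("fas_sum must lie in [0, 13]")
  pmin(pmax((13 - fas_sum) / 6.5, 0), 2)
}

# truncated-normal draw by inverse CDF (deterministic under set.seed)
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

# solve the per-question nomination scale so the expected class density hits d
.solveNominationScale <- function(pop, d) {
  f <- function(la) mean(1 - (1 - pmin(1, exp(la) * pop))^6) - d
  if (f(8) < 0)
    stop("infeasible density target ", signif(d, 3), " for this class")
  exp(stats::uniroot(f, c(-14, 8), tol = 1e-10)$root)
}

# baseline PAL from daily records: valid-day filter, per-wave means (>=3 valid
# days), steps -> PAL, mean over observed waves; class-mean fallback for
# participants with no valid wave at all; clamped to the PAL range.
.baselineFromDaily <- function(daily, ids, pal_min, pal_max) {
  pal <- vapply(ids, function(id) {
    d <- filterValidDays(daily[daily$participant_id == id, , drop = FALSE])
    wm <- vapply(1:4, function(w) waveMeanSteps(d, w), numeric(1))
    wm <- wm[!is.na(wm)]
    if (!length(wm)) NA_real_ else mean(stepsToPal(wm))
  }, numeric(1))
  if (anyNA(pal)) pal[is.na(pal)] <- mean(pal, na.rm = TRUE)
  pmin(pmax(pal, pal_min), pal_max)
}

#' Generate a synthetic cohort
#'
#' Draws participant records (class membership, sex, age, family affluence,
#' raw daily accelerometer records) and peer nomination records with the
#' statistical structure described in [cohortSpec()]. Baseline PAL is not
#' drawn directly: latent daily steps are generated from a latent PAL and the
#' published measurement pipeline (day-validity filters, >= 3 valid days per
#' wave, steps-to-PAL rescaling, averaging over observed waves) is applied to
#' recover it, so the measurement operations are exercised end to end.
#'
#' Nominations follow a latent-popularity model: each pupil carries a
#' popularity weight, and the probability of being nominated on any one of the
#' 6 sociometric questions is proportional to it, scaled so the expected class
#' density matches a per-class target drawn from `density_target_range`.
#' Dispersed popularity weights yield centralized (star-like) classes, which
#' is how the generator spans the published in-degree centralization range.
#'
#' @param spec a [cohortSpec()].
#' @return a [Cohort-class] object. Identical specs (including seed) give
#'   byte-identical tables.
#' @export
generateCohort <- function(spec = cohortSpec()) {
  stopifnot(inherits(spec, "cohortSpec"))
  set.seed(spec$seed)
  # day-level step noise: pooled daily SD = between-participant + day variance
  between_sd <- spec$pal_sd * 1e4 / 1.53
  day_sd <- sqrt(max(spec$steps_sd^2 - between_sd^2, (1200)^2))

  part_list <- list(); nom_list <- list(); daily_list <- list()
  for (ci in seq_len(spec$n_classes)) {
    class_id <- sprintf("C%02d", ci)
    n <- sample(seq(spec$class_size_range[1], spec$class_size_range[2]), 1L)
    ids <- sprintf("%sP%02d", class_id, seq_len(n))
    age_center <- stats::runif(1, 9, 13.5)
    age <- round(pmin(pmax(stats::rnorm(n, age_center, 0.5), 8), 15), 1)
    sex <- sample(c("M", "F"), n, replace = TRUE, prob = c(0.515, 0.485))
    fas <- pmin(pmax(round(stats::rnorm(n, spec$fas_mean, spec$fas_sd)), 0), 13)
    env <- fasToEnv(fas)
    latent_pal <- .rtruncnorm(n, spec$pal_mean, spec$pal_sd, spec$pal_min, spec$pal_max)
    latent_steps <- latent_pal / 1.53 * 1e4

    # raw daily records: 4 waves x 7 days, with missing waves, partial wear
    # and low-step failure days
    drows <- list()
    for (i in seq_len(n)) {
      for (w in 1:4) {
        if (stats::runif(1) < spec$p_wave_missing) next
        mw <- ifelse(stats::runif(7) < spec$p_partial_wear,
                     sample(600:1439, 7, replace = TRUE), 1440L)
        st <- pmax(round(stats::rnorm(7, latent_steps[i], day_sd)), 0)
        low <- stats::runif(7) < spec$p_low_steps
        st[low] <- sample(0:999, sum(low), replace = TRUE)
        drows[[length(drows) + 1L]] <- data.frame(
          participant_id = ids[i], wave = w, day = 1:7,
          minutes_worn = as.integer(mw), steps = as.numeric(st))
      }
    }
    daily <- do.call(rbind, drows)
    baseline <- .baselineFromDaily(daily, ids, spec$pal_min, spec$pal_max)

    # nominations via the latent-popularity model
    pop <- stats::rlnorm(n, 0, stats::runif(1, spec$sigma_pop_range[1], spec$sigma_pop_range[2]))
    pop <- pop / mean(pop)
    d_target <- min(max(stats::runif(1, spec$density_target_range[1],
                                     spec$density_target_range[2]) *
                          spec$nomination_rate, 0.02), 0.98)
    a <- .solveNominationScale(pop, d_target)
    pi_v <- pmin(1, a * pop)
    nrows <- list()
    for (u in seq_len(n)) {
      for (v in seq_len(n)) {
        if (u == v) next
        q <- which(stats::runif(6) < pi_v[v])
        if (!length(q)) next
        wv <- sample(1:4, length(q), replace = TRUE)
        dup <- stats::runif(length(q)) < spec$dup_rate
        if (any(dup)) {  # same question repeated in another wave
          q <- c(q, q[dup])
          wv <- c(wv, 1 + (wv[dup] %% 4))
        }
        nrows[[length(nrows) + 1L]] <- data.frame(
          nominator_id = ids[u], nominee_id = ids[v],
          question_id = as.integer(q), wave = as.integer(wv))
      }
    }
    noms <- if (length(nrows)) do.call(rbind, nrows) else
      data.frame(nominator_id = character(), nominee_id = character(),
                 question_id = integer(), wave = integer())
    # every pupil names at least one peer
    silent <- setdiff(ids, unique(noms$nominator_id))
    for (id in silent) {
      noms <- rbind(noms, data.frame(
        nominator_id = id, nominee_id = sample(setdiff(ids, id), 1L),
        question_id = 1L, wave = sample(1:4, 1L)))
    }

    part_list[[ci]] <- data.frame(
      participant_id = ids, class_id = class_id, sex = sex, age = age,
      fas_sum = as.integer(fas), env = env, baseline_pal = baseline)
    nom_list[[ci]] <- noms
    daily_list[[ci]] <- daily
  }
  new("Cohort",
      participants = do.call(rbind, part_list),
      nominations = do.call(rbind, nom_list),
      dailySteps = do.call(rbind, daily_list),
      spec = unclass(spec))
}

#' Write cohort tables to CSV
#'
#' Writes `participants.csv` (participant_id, class_id, sex, age,
#' baseline_pal, env) and `nominations.csv` (nominator_id, nominee_id,
#' question_id, wave), UTF-8, comma-delimited with a header row.
#'
#' @param cohort a [Cohort-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "Cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- participants(cohort)[, c("participant_id", "class_id", "sex", "age",
                                "baseline_pal", "env")]
  paths <- file.path(dir, c("participants.csv", "nominations.csv"))
  utils::write.csv(p, paths[1], row.names = FALSE)
  utils::write.csv(nominations(cohort), paths[2], row.names = FALSE)
  invisible(paths)
}

#' Read cohort tables back from CSV
#'
#' @param dir directory holding `participants.csv` and `nominations.csv`.
#' @return a list with elements `participants` and `nominations`.
#' @export
readCohortTables <- function(dir) {
  list(participants = utils::read.csv(file.path(dir, "participants.csv")),
       nominations = utils::read.csv(file.path(dir, "nominations.csv")))
}
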