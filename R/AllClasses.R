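#' @import methods
NULL

#' ClassNetwork: a weighted directed sociometric graph for one school class
#'
#' One network per class, built from peer nomination records. Nodes are the
#' full class roster (including pupils who never nominated or were never
#' nominated); edges are ordered pairs `(u, v)` meaning "u nominated v", with
#' weight equal to the number of distinct sociometric questions (out of 6) on
#' which u nominated v, divided by 6. Weights are therefore quantized to
#' `{1/6, 2/6, ..., 1}`; pairs with zero nominations carry no edge.
#'
#' @slot classId single character identifier of the class.
#' @slot roster character vector of participant identifiers (the node set).
#' @slot edges data.frame with columns `from`, `to` (character, on the roster)
#'   and `weight` (numeric in `(0, 1]`, a multiple of 1/6).
#'
#' @seealso [buildClassNetwork()], [asIgraph()], [centralities()],
#'   [networkDensity()]
#' @export
setClass("ClassNetwork",
  representation(classId = "character", roster = "character", edges = "data.frame"))

setValidity("ClassNetwork", function(object) {
  msgs <- character()
  if (length(object@classId) != 1L) msgs <- c(msgs, "classId must be a single string")
  if (anyDuplicated(object@roster)) msgs <- c(msgs, "roster ids must be unique")
  e <- object@edges
  if (!all(c("from", "to", "weight") %in% names(e)))
    msgs <- c(msgs, "edges must have columns from, to, weight")
  else if (nrow(e)) {
    if (!all(e$from %in% object@roster) || !all(e$to %in% object@roster))
      msgs <- c(msgs, "edge endpoints must be on the roster")
    if (any(e$from == e$to)) msgs <- c(msgs, "self-loops are not allowed")
    k <- e$weight * 6
    if (any(e$weight <= 0) || any(e$weight > 1) || any(abs(k - round(k)) > 1e-9))
      msgs <- c(msgs, "weights must be k/6 with k in 1..6")
    if (anyDuplicated(e[, c("from", "to")]))
      msgs <- c(msgs, "at most one edge per ordered pair")
  }
  if (length(msgs)) msgs else TRUE
})

#' Cohort: synthetic participant and nomination tables
#'
#' Container for one generated cohort: a participant table (one row per pupil,
#' with sex, age, family-affluence sum, the derived socio-environmental score
#' `env`, and the measured baseline physical activity level `baseline_pal`),
#' the raw daily accelerometer records the baseline was measured from, and the
#' peer nomination table.
#'
#' @slot participants data.frame: `participant_id`, `class_id`, `sex`, `age`,
#'   `fas_sum`, `env`, `baseline_pal`.
#' @slot nominations data.frame: `nominator_id`, `nominee_id`, `question_id`
#'   (1..6), `wave` (1..4).
#' @slot dailySteps data.frame: `participant_id`, `wave`, `day`,
#'   `minutes_worn`, `steps`.
#' @slot spec the [cohortSpec()] list the cohort was generated from.
#'
#' @seealso [generateCohort()], [participants()], [nominations()]
#' @export
setClass("Cohort",
  representation(participants = "data.frame", nominations = "data.frame",
                 dailySteps = "data.frame", spec = "list"))

setValidity("Cohort", function(object) {
  p <- object@participants; nm <- object@nominations
  msgs <- character()
  need <- c("participant_id", "class_id", "sex", "age", "fas_sum", "env", "baseline_pal")
  if (!all(need %in% names(p))) msgs <- c(msgs, "participants table is missing columns")
  if (nrow(nm)) {
    if (any(nm$nominator_id == nm$nominee_id)) msgs <- c(msgs, "self-nominations present")
    if (!all(nm$question_id %in% 1:6)) msgs <- c(msgs, "question_id outside 1..6")
    if (!all(nm$wave %in% 1:4)) msgs <- c(msgs, "wave outside 1..4")
  }
  if (nrow(p)) {
    if (any(p$env < 0 | p$env > 2)) msgs <- c(msgs, "env outside [0, 2]")
  }
  if (length(msgs)) msgs else TRUE
})

#' SimConfig: parameters of the daily diffusion update
#'
#' Configuration of the agent-based model. Each simulated day every agent's
#' physical activity level (PAL) is pulled toward a target that mixes the
#' weighted mean PAL of the peers the agent nominated (weight `1 - lambdaEnv`)
#' with a socio-environmental anchor `palRef * (2 - env) / 2` (weight
#' `lambdaEnv`); the move happens only when the pull exceeds the agent's
#' threshold, and is a fraction `eta` of the remaining gap, clamped to
#' `palBounds`.
#'
#' @slot days integer number of simulated days (day 0 .. days-1).
#' @slot eta numeric in (0, 1]: fraction of the gap closed per day.
#' @slot lambdaEnv numeric in \[0, 1\]: weight of the environmental anchor.
#' @slot threshold numeric >= 0: minimal absolute pull that triggers a change.
#' @slot palBounds numeric length 2: clamp range for PAL.
#' @slot palRef numeric: anchor PAL of a maximally affluent environment (env = 0).
#'
#' @seealso [simConfig()], [runAbm()]
#' @export
setClass("SimConfig",
  representation(days = "integer", eta = "numeric", lambdaEnv = "numeric",
                 threshold = "numeric", palBounds = "numeric", palRef = "numeric"))

setValidity("SimConfig", function(object) {
  msgs <- character()
  if (object@days < 1L) msgs <- c(msgs, "days must be >= 1")
  if (object@eta <= 0 || object@eta > 1) msgs <- c(msgs, "eta must be in (0, 1]")
  if (object@lambdaEnv < 0 || object@lambdaEnv > 1) msgs <- c(msgs, "lambdaEnv must be in [0, 1]")
  if (object@threshold < 0) msgs <- c(msgs, "threshold must be >= 0")
  if (length(object@palBounds) != 2L || diff(object@palBounds) <= 0)
    msgs <- c(msgs, "palBounds must be an increasing pair")
  if (object@palRef < 0) msgs <- c(msgs, "palRef must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Trajectory: daily PAL states of one simulated class
#'
#' Row `d` holds the per-agent PAL on day `d - 1`; row 1 is the
#' post-initialization (for interventions: post-boost) day-0 state, so a run
#' of `days` rows covers days `0 .. days - 1` with `days - 1` updates.
#'
#' @slot pal numeric matrix, days x agents; column names are participant ids.
#' @slot classId single character identifier of the simulated class.
#'
#' @seealso [runAbm()], [meanPal()], [successRate()]
#' @export
setClass("Trajectory", representation(pal = "matrix", classId = "character"))

setValidity("Trajectory", function(object) {
  if (nrow(object@pal) < 1L) return("trajectory must hold at least day 0")
  if (any(!is.finite(object@pal))) return("PAL values must be finite")
  TRUE
})

## ---- accessors ----

#' @describeIn ClassNetwork-class class identifier
#' @param object a `ClassNetwork`
#' @export
setGeneric("classId", function(object) standardGeneric("classId"))
#' @export
setMethod("classId", "ClassNetwork", function(object) object@classId)
#' @export
setMethod("classId", "Trajectory", function(object) object@classId)

#' @describeIn ClassNetwork-class node set (participant ids)
#' @export
setGeneric("roster", function(object) standardGeneric("roster"))
#' @export
setMethod("roster", "ClassNetwork", function(object) object@roster)

#' @describeIn ClassNetwork-class edge table (`from`, `to`, `weight`)
#' @export
setGeneric("edgeTable", function(object) standardGeneric("edgeTable"))
#' @export
setMethod("edgeTable", "ClassNetwork", function(object) object@edges)

#' @describeIn Cohort-class participant table
#' @param object a `Cohort`
#' @export
setGeneric("participants", function(object) standardGeneric("participants"))
#' @export
setMethod("participants", "Cohort", function(object) object@participants)

#' @describeIn Cohort-class nomination table
#' @export
setGeneric("nominations", function(object) standardGeneric("nominations"))
#' @export
setMethod("nominations", "Cohort", function(object) object@nominations)

#' @describeIn Cohort-class raw daily step records
#' @export
setGeneric("dailySteps", function(object) standardGeneric("dailySteps"))
#' @export
setMethod("dailySteps", "Cohort", function(object) object@dailySteps)

#' @describeIn Trajectory-class mean PAL per day (length = days)
#' @export
setGeneric("meanPal", function(object) standardGeneric("meanPal"))
#' @export
setMethod("meanPal", "Trajectory", function(object) rowMeans(object@pal))

#' @describeIn Trajectory-class per-agent PAL matrix (days x agents)
#' @export
setGeneric("palMatrix", function(object) standardGeneric("palMatrix"))
#' @export
setMethod("palMatrix", "Trajectory", function(object) object@pal)

## ---- show methods ----

setMethod("show", "ClassNetwork", function(object) {
  n <- length(object@roster)
  cat("ClassNetwork '", object@classId, "': ", n, " pupils, ",
      nrow(object@edges), " directed edges (density ",
      if (n >= 2) sprintf("%.3f", nrow(object@edges) / (n * (n - 1))) else "NA",
      ")\n", sep = "")
})

setMethod("show", "Cohort", function(object) {
  p <- object@participants
  cat("Cohort: ", length(unique(p$class_id)), " classes, ", nrow(p),
      " participants, ", nrow(object@nominations), " nominations\n", sep = "")
  if (nrow(p))
    cat(sprintf("  baseline PAL %.2f (SD %.2f), env %.2f (SD %.2f)\n",
                mean(p$baseline_pal), stats::sd(p$baseline_pal),
                mean(p$env), stats::sd(p$env)))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %d days, eta = %g, lambdaEnv = %g, threshold = %g, palRef = %g, bounds [%g, %g]\n",
    object@days, object@eta, object@lambdaEnv, object@threshold, object@palRef,
    object@palBounds[1], object@palBounds[2]))
})

setMethod("show", "Trajectory", function(object) {
  m <- meanPal(object)
  cat(sprintf("Trajectory '%s': %d agents, days 0..%d, mean PAL %.3f -> %.3f\n",
              object@classId, ncol(object@pal), nrow(object@pal) - 1L,
              m[1], m[length(m)]))
})
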