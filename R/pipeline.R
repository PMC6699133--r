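#' Default pipeline configuration
#'
#' Nested configuration for the end-to-end pipeline: a `cohort` block
#' (arguments of [cohortSpec()]), an `abm` block (arguments of [simConfig()]),
#' a `conditions` block (shared arguments of [conditionSet()]), and top-level
#' `seed` and `trajectories` switches. The master seed feeds both the cohort
#' generator and the per-class/per-condition child seeds of the experiment.
#'
#' @param seed master seed.
#' @return a nested named list.
#' @export
defaultPipelineConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    trajectories = FALSE,
    cohort = list(n_classes = 26L, class_size_range = c(10L, 30L),
                  density_target_range = c(0.46, 0.90),
                  nomination_rate = 1.0),
    abm = list(days = 365L, eta = 0.05, lambda_env = 0.01, threshold = 0.005,
               pal_bounds = c(0.1, 4.27), pal_ref = 4.8),
    conditions = list(fraction = 0.15, boost = 0.17, random_replicates = 100L)
  )
}

.knownKeys <- list(
  top = c("seed", "trajectories", "cohort", "abm", "conditions"),
  cohort = names(formals(cohortSpec)),
  abm = c("days", "eta", "lambda_env", "threshold", "pal_bounds", "pal_ref"),
  conditions = c("fraction", "boost", "random_replicates"))

#' Validate a pipeline configuration
#'
#' Checks the nesting structure and rejects unknown keys (a typo in a config
#' file should fail loudly, not fall back to a default).
#'
#' @param config a nested list as from [defaultPipelineConfig()].
#' @return the config, with defaults filled in for absent keys.
#' @export
validatePipelineConfig <- function(config) {
  stopifnot(is.list(config))
  chk <- function(keys, known, where) {
    bad <- setdiff(keys, known)
    if (length(bad))
      stop("unknown config key(s) in ", where, ": ", paste(bad, collapse = ", "))
  }
  chk(names(config), .knownKeys$top, "top level")
  for (blk in c("cohort", "abm", "conditions"))
    if (!is.null(config[[blk]])) {
      if (!is.list(config[[blk]])) stop("config block '", blk, "' must be a mapping")
      chk(names(config[[blk]]), .knownKeys[[blk]], blk)
    }
  def <- defaultPipelineConfig(seed = if (is.null(config$seed)) 1L else config$seed)
  out <- utils::modifyList(def, config)
  out$seed <- as.integer(out$seed)
  out
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path file ending in `.yaml`/`.yml` or `.json`.
#' @return a validated config list.
#' @export
readPipelineConfig <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  validatePipelineConfig(cfg)
}

.configSimConfig <- function(config) {
  a <- config$abm
  simConfig(days = a$days, eta = a$eta, lambdaEnv = a$lambda_env,
            threshold = a$threshold, palBounds = a$pal_bounds,
            palRef = a$pal_ref)
}

.configCohortSpec <- function(config) {
  args <- config$cohort
  args$seed <- config$seed
  do.call(cohortSpec, args)
}

#' Run the full pipeline
#'
#' generate -> build networks -> metrics -> simulate -> evaluate, writing
#' `participants.csv`, `nominations.csv`, `class_structure.csv`,
#' `centrality.csv`, `results.csv`, `evaluation_report.json`, `report.txt`
#' and a `manifest.json` (config hash, seed, package version, file list) into
#' `out_dir`. Fully deterministic under a fixed config.
#'
#' @param config a config list (validated on entry), or a path to a YAML/JSON
#'   config file.
#' @param out_dir output directory.
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config = defaultPipelineConfig(), out_dir) {
  if (is.character(config)) config <- readPipelineConfig(config)
  config <- validatePipelineConfig(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- "generate"
  files <- character()
  res <- tryCatch({
    if (config$cohort$n_classes < 5L)
      warning("fewer than 5 classes: the evaluation stage will be unstable",
              call. = FALSE)
    cohort <- generateCohort(.configCohortSpec(config))
    files <- c(files, writeCohort(cohort, out_dir))

    stage <- "metrics"
    networks <- buildNetworks(cohort)
    files <- c(files, writeMetrics(networks, out_dir))
    structure <- classStructure(networks)

    stage <- "simulate"
    results <- runExperiment(cohort, .configSimConfig(config),
                             conditionSet(config$conditions$fraction,
                                          config$conditions$boost,
                                          config$conditions$random_replicates),
                             seed = config$seed,
                             trajectories = isTRUE(config$trajectories))
    files <- c(files, writeResults(results, out_dir))
    if (isTRUE(config$trajectories)) {
      tp <- file.path(out_dir, "trajectories.csv")
      utils::write.csv(attr(results, "trajectories"), tp, row.names = FALSE)
      files <- c(files, tp)
    }

    stage <- "evaluate"
    evaluation <- tryCatch(evaluateExperiment(results, structure),
                           error = function(e) {
                             warning("evaluation incomplete: ",
                                     conditionMessage(e), call. = FALSE)
                             NULL
                           })
    if (!is.null(evaluation))
      files <- c(files, writeEvaluation(evaluation, out_dir))
    list(results = results, evaluation = evaluation)
  }, error = function(e) {
    stop("pipeline failed in stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  cfg_file <- tempfile(fileext = ".json")
  jsonlite::write_json(config, cfg_file, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package_version = as.character(utils::packageVersion("peerspread")),
    seed = config$seed,
    config = config,
    config_md5 = unname(tools::md5sum(cfg_file)),
    files = basename(files))
  unlink(cfg_file)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$files <- c(manifest$files, "manifest.json")
  invisible(manifest)
}
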