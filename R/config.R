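run_config_defaults <- function() {
  list(network = unclass(network_params()),
       task = unclass(task_spec()),
       variant = "feedback",
       n_trials = 1000L,
       seed = 1L,
       snapshots = integer(0),
       eval_trials = 2000L,
       analysis = list(n_shuffles = 200L, cp_shuffles = 0L, min_trials = 3L,
                       pairs = TRUE))
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, rejects unknown keys, fills every omitted key
#' with its documented default, and returns a validated `run_config`. An
#' empty file yields the full default configuration; a run is reproducible
#' from the configuration and its seed alone.
#'
#' @param path YAML file path, or NULL for pure defaults.
#' @return a `run_config` list: `network` ([network_params()]), `task`
#'   ([task_spec()]), `variant`, `n_trials`, `seed`, `snapshots`,
#'   `eval_trials`, `analysis`.
#' @export
load_config <- function(path = NULL) {
  defaults <- run_config_defaults()
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  bad <- setdiff(names(user), names(defaults))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (blk in c("network", "task", "analysis")) {
    if (!is.null(user[[blk]])) {
      badk <- setdiff(names(user[[blk]]),
                      c(names(defaults[[blk]]),
                        if (blk == "task") "directions"))
      if (length(badk))
        stop("unknown config key(s) in '", blk, "': ",
             paste(badk, collapse = ", "))
      defaults[[blk]][names(user[[blk]])] <- user[[blk]]
    }
  }
  for (k in setdiff(names(user), c("network", "task", "analysis")))
    defaults[[k]] <- user[[k]]
  cfg <- defaults
  cfg$network <- do.call(network_params, cfg$network)
  cfg$task <- do.call(task_spec, cfg$task)
  cfg$variant <- match.arg(cfg$variant,
                           c("feedback", "no_feedback", "fixed_tuning"))
  structure(cfg, class = "run_config")
}

#' Save a run configuration to YAML
#' @param config a `run_config`; `path` output file.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  out <- unclass(config)
  out$network <- unclass(out$network)
  out$task <- unclass(out$task)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Run the full pipeline: train, frozen evaluations, analysis, report
#'
#' Trains the configured variant, runs a frozen-weight evaluation at every
#' snapshot (plus the final weights), analyses each evaluation, and writes
#' all artifacts (trial log, snapshots, rate tables, per-neuron statistics,
#' pairwise table, MDS coordinates and a JSON sidecar of settings and the
#' configuration hash) under `out_dir`.
#'
#' @param config a `run_config` (see [load_config()]).
#' @param out_dir output directory (created if missing); NULL skips writing.
#' @return list: the `catcircuit_run`, named list of `evaluations`
#'   (rate datasets), named list of `analyses`, and the psychometric
#'   `summary` per training epoch.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  run <- train(config$variant, config$n_trials, config$network, config$task,
               seed = config$seed, snapshots = config$snapshots)
  snaps <- run$snapshots
  snaps[[as.character(config$n_trials)]] <- run$weights
  evals <- list(); analyses <- list()
  for (nm in names(snaps)) {
    ev <- frozen_evaluation(snaps[[nm]], config$eval_trials, config$network,
                            config$task,
                            seed = config$seed + 1000L + as.integer(nm) %% 1000L)
    an <- analyze_dataset(ev, n_shuffles = config$analysis$n_shuffles,
                          cp_shuffles = config$analysis$cp_shuffles,
                          min_trials = config$analysis$min_trials,
                          pairs = isTRUE(config$analysis$pairs))
    evals[[nm]] <- ev; analyses[[nm]] <- an
  }
  summary <- psychometric(run$trials, boundary = config$task$boundary)
  out <- list(run = run, evaluations = evals, analyses = analyses,
              summary = summary)
  if (!is.null(out_dir)) write_pipeline(out, config, out_dir)
  out
}

write_pipeline <- function(out, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_yaml <- yaml::as.yaml(list(network = unclass(config$network),
                                 task = unclass(config$task),
                                 variant = config$variant,
                                 n_trials = config$n_trials,
                                 seed = config$seed))
  cfg_hash <- sprintf("%08x", sum(utf8ToInt(cfg_yaml) *
                                    seq_along(utf8ToInt(cfg_yaml))) %%
                        .Machine$integer.max)
  utils::write.csv(out$run$trials, file.path(out_dir, "trials.csv"),
                   row.names = FALSE)
  write_snapshots(out$run$snapshots, file.path(out_dir, "snapshots.csv"))
  for (nm in names(out$evaluations)) {
    write_rate_dataset(out$evaluations[[nm]],
                       file.path(out_dir, sprintf("rates_eval_%s.csv", nm)))
    an <- out$analyses[[nm]]
    utils::write.csv(an$neurons,
                     file.path(out_dir, sprintf("neurons_%s.csv", nm)),
                     row.names = FALSE)
    if (!is.null(an$pairs))
      utils::write.csv(an$pairs,
                       file.path(out_dir, sprintf("pairs_%s.csv", nm)),
                       row.names = FALSE)
    utils::write.csv(data.frame(direction = an$mds$directions,
                                x = an$mds$config[, 1], y = an$mds$config[, 2]),
                     file.path(out_dir, sprintf("mds_%s.csv", nm)),
                     row.names = FALSE)
    jsonlite::write_json(c(an$params, list(config_hash = cfg_hash)),
                         file.path(out_dir, sprintf("analysis_%s.json", nm)),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  writeLines(cfg_yaml, file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}
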