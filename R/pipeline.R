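pipeline_defaults <- function() list(
  environment = "ar",
  runs = 10L, blocks_per_run = 9L, trials_per_block = 5L, n_stimuli = 9L,
  soa_ms = 175, flash_ms = 100, prep_ms = 2000, lock_ms = 1500, post_ms = 600,
  sim = list(),          # overrides forwarded to sim_params()
  drop = c("A1", "A2"),
  lo_hz = 0.1, hi_hz = 12, filter = TRUE,
  window_ms = 600, downsample = 3L,
  averages = 1L,
  model = "sepcnn",
  hyper = list(),        # overrides forwarded to train_hyper()
  folds = 5L, itr_T_s = 2.0,
  seed = 1L,
  out_dir = NULL,
  log_level = "info"
)

#' Assemble a validated pipeline configuration
#'
#' Starts from the package defaults (the full 10-run AR protocol, the
#' standard preprocessing chain, SepCNN with 5-fold cross-validation) and
#' applies overrides. Unknown keys are rejected. Every stage derives its own
#' seed deterministically from the single master `seed`.
#'
#' @param ... Named overrides of the default fields (see
#'   `p300sep:::pipeline_defaults()` for the full list).
#' @return List of class `run_config`.
#' @export
run_config <- function(...) {
  over <- list(...)
  if (length(over) == 1 && is.null(names(over)) && is.list(over[[1]]))
    over <- over[[1]]
  cfg <- pipeline_defaults()
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "; valid keys: ", paste(names(cfg), collapse = ", "))
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  for (sub in c("sim", "hyper")) {
    valid <- names(formals(if (sub == "sim") sim_params else train_hyper))
    bad <- setdiff(names(cfg[[sub]]), valid)
    if (length(bad))
      stop("unknown ", sub, " key(s): ", paste(bad, collapse = ", "))
  }
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose top-level keys are [run_config()] fields.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  run_config(yaml::read_yaml(path))
}

log_msg <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(format(Sys.time(), "[%H:%M:%S] "), ...)
}

run_stage <- function(cfg, name, expr) {
  t0 <- Sys.time()
  out <- tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  log_msg(cfg, sprintf("stage %-10s done in %.1fs", name,
                       as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  out
}

#' Run the full pipeline: simulate, preprocess, cross-validate, report
#'
#' Executes every stage with seeds derived from the master seed, optionally
#' writing per-stage artifacts (`session.h5`, `epochs.h5`, `report.json`,
#' `report.csv`) under `out_dir`. One master seed gives a bit-identical
#' report.
#'
#' @param config A [run_config()].
#' @return An `eval_report`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  out_dir <- cfg$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  schedule <- run_stage(cfg, "schedule",
    make_schedule(cfg$runs, cfg$blocks_per_run, cfg$trials_per_block,
                  cfg$n_stimuli, cfg$soa_ms, cfg$flash_ms, cfg$prep_ms,
                  cfg$lock_ms, cfg$post_ms,
                  seed = derive_seed(cfg$seed, "schedule")))

  params <- do.call(sim_params, c(list(environment = cfg$environment), cfg$sim))
  session <- run_stage(cfg, "simulate",
    simulate_session(schedule, params, seed = derive_seed(cfg$seed, "session")))
  if (!is.null(out_dir))
    write_session(session, file.path(out_dir, "session.h5"))

  epochs <- run_stage(cfg, "preprocess",
    preprocess_session(session, drop = cfg$drop, lo_hz = cfg$lo_hz,
                       hi_hz = cfg$hi_hz, window_ms = cfg$window_ms,
                       factor = cfg$downsample, filter = cfg$filter))
  if (cfg$averages > 1)
    epochs <- run_stage(cfg, "average", average_repetitions(epochs, cfg$averages))
  if (!is.null(out_dir))
    write_epochs(epochs, file.path(out_dir, "epochs.h5"))

  hyper <- do.call(train_hyper,
                   c(cfg$hyper[setdiff(names(cfg$hyper), "seed")],
                     list(seed = derive_seed(cfg$seed, "train"))))
  factory <- model_factory(cfg$model, hyper = hyper)
  report <- run_stage(cfg, "evaluate",
    crossval(epochs, factory, folds = cfg$folds,
             seed = derive_seed(cfg$seed, "eval"), itr_T_s = cfg$itr_T_s))

  if (!is.null(out_dir)) {
    write_report_json(report, file.path(out_dir, "report.json"))
    write_report_csv(report, file.path(out_dir, "report.csv"))
  }
  report
}
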