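## HDF5 containers for sessions and epoch sets.
##
## Layout (readable from any HDF5 binding; C-order readers see /eeg as
## channels x samples and /epochs as channels x time x epochs):
##   session: /eeg, /events/{run,block,trial,stimulus,onset_ms},
##            /target_of_block; root attributes: schema_version,
##            sampling_rate_hz, environment, channel_names, timing parameters.
##   epochs:  /epochs, /labels, /meta/{run,block,trial,stimulus,target};
##            root attributes: schema_version, sampling_rate_hz, n_stimuli.

SCHEMA_VERSION <- "1.0"

h5_root_attrs <- function(path, attrs) {
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid))
  gid <- rhdf5::H5Gopen(fid, "/")
  on.exit(rhdf5::H5Gclose(gid), add = TRUE, after = FALSE)
  for (nm in names(attrs)) {
    if (length(attrs[[nm]]) == 0) next
    if (rhdf5::H5Aexists(gid, nm)) rhdf5::H5Adelete(gid, nm)
    rhdf5::h5writeAttribute(attrs[[nm]], gid, nm)
  }
  invisible(path)
}

h5_read_attrs <- function(path) {
  rhdf5::h5readAttributes(path, "/")
}

check_schema <- function(attrs, path) {
  v <- attrs$schema_version
  if (is.null(v))
    stop("'", path, "' carries no schema_version attribute; not a p300sep container")
  major <- as.integer(strsplit(as.character(v), ".", fixed = TRUE)[[1]][1])
  ours <- as.integer(strsplit(SCHEMA_VERSION, ".", fixed = TRUE)[[1]][1])
  if (is.na(major) || major > ours)
    stop("'", path, "' has schema version ", v,
         "; this build reads major version <= ", ours)
}

#' Write a session to an HDF5 container
#'
#' @param session An `eeg_session`.
#' @param path Output path (overwritten if present).
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "eeg_session"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll())
  rhdf5::h5write(session$data, path, "eeg")
  rhdf5::h5createGroup(path, "events")
  ev <- session$schedule$events
  for (col in c("run", "block", "trial", "stimulus"))
    rhdf5::h5write(as.integer(ev[[col]]), path, paste0("events/", col))
  rhdf5::h5write(as.numeric(ev$onset_ms), path, "events/onset_ms")
  rhdf5::h5write(as.integer(session$schedule$target_of_block), path,
                 "target_of_block")
  sch <- session$schedule
  h5_root_attrs(path, list(
    schema_version = SCHEMA_VERSION,
    sampling_rate_hz = session$sampling_rate_hz,
    environment = session$environment,
    channel_names = session$channel_names,
    seed = session$seed,
    n_stimuli = sch$n_stimuli, soa_ms = sch$soa_ms, flash_ms = sch$flash_ms,
    prep_ms = sch$prep_ms, lock_ms = sch$lock_ms, post_ms = sch$post_ms,
    runs = sch$runs, blocks_per_run = sch$blocks_per_run,
    trials_per_block = sch$trials_per_block, schedule_seed = sch$seed))
}

#' Read a session from an HDF5 container
#'
#' @param path Path written by [write_session()].
#' @return An `eeg_session`.
#' @export
read_session <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  on.exit(rhdf5::h5closeAll())
  at <- tryCatch(h5_read_attrs(path), error = function(e)
    stop("cannot parse '", path, "' as an HDF5 session container: ",
         conditionMessage(e)))
  check_schema(at, path)
  data <- rhdf5::h5read(path, "eeg")
  ev <- data.frame(
    run = as.integer(rhdf5::h5read(path, "events/run")),
    block = as.integer(rhdf5::h5read(path, "events/block")),
    trial = as.integer(rhdf5::h5read(path, "events/trial")),
    stimulus = as.integer(rhdf5::h5read(path, "events/stimulus")),
    onset_ms = as.numeric(rhdf5::h5read(path, "events/onset_ms")))
  schedule <- structure(list(
    events = ev,
    target_of_block = as.integer(rhdf5::h5read(path, "target_of_block")),
    n_stimuli = as.integer(at$n_stimuli), soa_ms = as.numeric(at$soa_ms),
    flash_ms = as.numeric(at$flash_ms), prep_ms = as.numeric(at$prep_ms),
    lock_ms = as.numeric(at$lock_ms), post_ms = as.numeric(at$post_ms),
    runs = as.integer(at$runs), blocks_per_run = as.integer(at$blocks_per_run),
    trials_per_block = as.integer(at$trials_per_block),
    seed = as.integer(at$schedule_seed)), class = "stim_schedule")
  ch <- as.character(at$channel_names)
  colnames(data) <- ch
  structure(list(data = data, sampling_rate_hz = as.numeric(at$sampling_rate_hz),
                 channel_names = ch, schedule = schedule,
                 environment = as.character(at$environment),
                 seed = as.integer(at$seed)),
            class = "eeg_session")
}

#' Write an epoch set to an HDF5 container
#'
#' @param epochs An `epoch_set`.
#' @param path Output path (overwritten if present).
#' @return `path`, invisibly.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll())
  tensor <- epochs$tensor
  dimnames(tensor) <- NULL
  rhdf5::h5write(tensor, path, "epochs")
  rhdf5::h5write(as.integer(epochs$labels), path, "labels")
  rhdf5::h5createGroup(path, "meta")
  for (col in names(epochs$meta))
    rhdf5::h5write(as.integer(epochs$meta[[col]]), path, paste0("meta/", col))
  ch <- dimnames(epochs$tensor)[[3]]
  h5_root_attrs(path, list(
    schema_version = SCHEMA_VERSION,
    sampling_rate_hz = epochs$sampling_rate_hz,
    n_stimuli = epochs$n_stimuli,
    channel_names = if (is.null(ch)) character(0) else ch))
}

#' Read an epoch set from an HDF5 container
#'
#' @param path Path written by [write_epochs()].
#' @return An `epoch_set`.
#' @export
read_epochs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  on.exit(rhdf5::h5closeAll())
  at <- tryCatch(h5_read_attrs(path), error = function(e)
    stop("cannot parse '", path, "' as an HDF5 epoch container: ",
         conditionMessage(e)))
  check_schema(at, path)
  tensor <- rhdf5::h5read(path, "epochs")
  ch <- if (is.null(at$channel_names)) character(0) else as.character(at$channel_names)
  if (length(ch) == dim(tensor)[3])
    dimnames(tensor) <- list(NULL, NULL, ch)
  meta_cols <- rhdf5::h5ls(path)
  meta_cols <- meta_cols$name[meta_cols$group == "/meta"]
  meta <- as.data.frame(lapply(stats::setNames(meta_cols, meta_cols),
                               function(col)
                                 as.integer(rhdf5::h5read(path, paste0("meta/", col)))))
  meta <- meta[, intersect(c("run", "block", "trial", "stimulus", "target"),
                           names(meta)), drop = FALSE]
  structure(list(tensor = tensor,
                 labels = as.integer(rhdf5::h5read(path, "labels")),
                 meta = meta,
                 sampling_rate_hz = as.numeric(at$sampling_rate_hz),
                 n_stimuli = as.integer(at$n_stimuli)),
            class = "epoch_set")
}

#' Save / load a fitted scorer checkpoint
#'
#' Single-file checkpoint embedding the model configuration, weights and any
#' feature standardization, so a scorer can move between the `train` and
#' `evaluate` CLI stages.
#'
#' @param scorer A `p300_scorer`.
#' @param path Checkpoint path.
#' @return `path` (save) or the scorer (load).
#' @export
save_scorer <- function(scorer, path) {
  stopifnot(inherits(scorer, "p300_scorer"))
  saveRDS(list(schema_version = SCHEMA_VERSION, scorer = scorer), path)
  invisible(path)
}

#' @rdname save_scorer
#' @export
load_scorer <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$schema_version) || !inherits(obj$scorer, "p300_scorer"))
    stop("'", path, "' is not a p300sep scorer checkpoint")
  check_schema(list(schema_version = obj$schema_version), path)
  obj$scorer
}

#' Export an evaluation report
#'
#' `write_report_json()` serializes the full report; `write_report_csv()`
#' writes the participant x run accuracy matrix (with participant means and
#' grand mean) as a CSV table.
#'
#' @param report An `eval_report` (or `accuracy_table` for the CSV writer).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  out <- list(
    schema_version = SCHEMA_VERSION,
    folds = report$folds, seed = report$seed, itr_T_s = report$itr_T_s,
    accuracy_matrix = report$accuracy$matrix,
    participant_means = report$accuracy$participant_means,
    grand_mean = report$accuracy$grand_mean,
    auc = report$auc, itr_bits_min = report$itr_bits_min,
    per_target_accuracy = report$per_target_accuracy,
    decoded = report$decoded)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_report_json
#' @export
write_report_csv <- function(report, path) {
  acc <- if (inherits(report, "eval_report")) report$accuracy else report
  stopifnot(inherits(acc, "accuracy_table"))
  df <- as.data.frame(acc$matrix)
  df$mean <- acc$participant_means
  df <- rbind(df, Mean = c(colMeans(acc$matrix), acc$grand_mean))
  utils::write.csv(cbind(participant = rownames(df), df), path,
                   row.names = FALSE)
  invisible(path)
}
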