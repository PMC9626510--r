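#' Reference per-run decoding accuracies (15-participant AR benchmark)
#'
#' The published per-run nine-target recognition accuracies (%) of the
#' separable-CNN classifier for 15 participants x 10 runs of the AR speller
#' protocol this package emulates. Used as a fixture for report-layout
#' arithmetic and to calibrate the information-transfer-rate computation.
#'
#' @return data.frame: `participant`, `run1` ... `run10`, and `mean_printed`
#'   (the participant means as published; note the published P7 mean differs
#'   from the mean of its run values by 1.1 points, so recomputed means do
#'   not reproduce it exactly).
#' @export
ref_accuracy_table <- function() {
  utils::read.csv(system.file("extdata", "ref_accuracy_runs.csv",
                              package = "p300sep"))
}

#' Reference mean P300 peak latencies per participant
#'
#' Published mean P300 peak latencies (ms) of 15 participants under
#' computer-screen (CS) and augmented-reality (AR) stimulus presentation;
#' their column means (434.53 / 482.47 ms) are the default latencies of
#' [sim_params()].
#'
#' @return data.frame: `participant`, `cs_ms`, `ar_ms`.
#' @export
ref_latency_table <- function() {
  utils::read.csv(system.file("extdata", "ref_latency_ms.csv",
                              package = "p300sep"))
}

#' Reference accuracies as a trial-free accuracy table
#'
#' Wraps [ref_accuracy_table()] into the same `accuracy_table` structure
#' produced from decoded trials, so downstream summaries (participant means,
#' grand mean, per-participant ITR) run on the published numbers unchanged.
#'
#' @return An `accuracy_table`.
#' @export
ref_accuracy_matrix <- function() {
  df <- ref_accuracy_table()
  mat <- as.matrix(df[, grep("^run", names(df))])
  rownames(mat) <- paste0("P", df$participant)
  pm <- rowMeans(mat)
  structure(list(matrix = mat, participant_means = pm,
                 grand_mean = mean(pm)),
            class = "accuracy_table")
}
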