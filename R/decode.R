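#' Decode one trial from its per-stimulus scores
#'
#' @param scores Numeric vector with exactly one score per stimulus of the
#'   trial (in stimulus order).
#' @param n_stimuli Expected number of stimuli.
#' @return Index (1-based) of the maximum score; ties resolve to the lowest
#'   index.
#' @export
decode_trial <- function(scores, n_stimuli = 9L) {
  if (length(scores) != n_stimuli)
    stop("expected ", n_stimuli, " scores, got ", length(scores))
  which.max(scores)
}

#' Decode every trial of a scored epoch set
#'
#' Groups per-epoch scores by (run, block, trial), reorders each group by
#' stimulus index, and applies [decode_trial()].
#'
#' @param scores Numeric vector, one score per epoch.
#' @param meta Per-epoch metadata (`run`, `block`, `trial`, `stimulus`,
#'   `target`), as in an `epoch_set`.
#' @param n_stimuli Stimuli per trial.
#' @return data.frame with one row per trial: `run`, `block`, `trial`,
#'   `predicted`, `target`, `correct`.
#' @export
decode_trials <- function(scores, meta, n_stimuli = 9L) {
  if (length(scores) != nrow(meta))
    stop("scores and meta are misaligned (", length(scores), " vs ",
         nrow(meta), " rows)")
  key <- paste(meta$run, meta$block, meta$trial, sep = "\r")
  groups <- split(seq_len(nrow(meta)), key)
  rows <- lapply(groups, function(idx) {
    if (length(idx) != n_stimuli)
      stop("trial with ", length(idx), " epochs; expected ", n_stimuli)
    ord <- idx[order(meta$stimulus[idx])]
    data.frame(run = meta$run[idx[1]], block = meta$block[idx[1]],
               trial = meta$trial[idx[1]],
               predicted = decode_trial(scores[ord], n_stimuli),
               target = meta$target[idx[1]])
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$run, out$block, out$trial), ]
  rownames(out) <- NULL
  out$correct <- as.integer(out$predicted == out$target)
  out
}

#' Per-run accuracy table
#'
#' Tabulates trial-level decoding outcomes into the participant x run
#' accuracy matrix (in percent) plus participant means and the grand mean
#' (mean of participant means).
#'
#' @param decoded data.frame with columns `correct` and `run` (and optionally
#'   `participant`; a single participant is assumed when absent), e.g. from
#'   [decode_trials()].
#' @return List of class `accuracy_table`: `matrix` (participant x run, %),
#'   `participant_means`, `grand_mean`.
#' @export
accuracy_table <- function(decoded) {
  if (!all(c("correct", "run") %in% names(decoded)))
    stop("decoded must contain 'correct' and 'run' columns")
  if (is.null(decoded$participant)) decoded$participant <- 1L
  parts <- sort(unique(decoded$participant))
  runs <- sort(unique(decoded$run))
  mat <- matrix(NA_real_, length(parts), length(runs),
                dimnames = list(paste0("P", parts), paste0("run", runs)))
  for (i in seq_along(parts)) for (j in seq_along(runs)) {
    sel <- decoded$participant == parts[i] & decoded$run == runs[j]
    if (any(sel)) mat[i, j] <- 100 * mean(decoded$correct[sel])
  }
  pm <- rowMeans(mat, na.rm = TRUE)
  structure(list(matrix = mat, participant_means = pm,
                 grand_mean = mean(pm)),
            class = "accuracy_table")
}

#' @export
print.accuracy_table <- function(x, ...) {
  cat("<accuracy_table> (%)\n")
  print(round(cbind(x$matrix, mean = x$participant_means), 2))
  cat(sprintf("grand mean: %.2f%%\n", x$grand_mean))
  invisible(x)
}

#' Wolpaw bits per selection
#'
#' `log2(N) + P log2(P) + (1 - P) log2((1 - P) / (N - 1))`, the classical
#' information content of one N-target selection at accuracy P, with the
#' `P = 0` and `P = 1` limits taken continuously.
#'
#' @param P Selection accuracy in `[0, 1]` (vectorized).
#' @param N Number of selectable targets (>= 2).
#' @return Bits per selection.
#' @examples
#' wolpaw_bits(1, 9)      # log2(9)
#' wolpaw_bits(1 / 9, 9)  # 0 (chance)
#' @export
wolpaw_bits <- function(P, N = 9L) {
  if (N < 2) stop("N must be >= 2")
  if (any(P < 0 | P > 1)) stop("P must lie in [0, 1]")
  plog2 <- function(p) ifelse(p > 0, p * log2(p), 0)
  log2(N) + plog2(P) + ifelse(P < 1, (1 - P) * log2((1 - P) / (N - 1)), 0)
}

#' Wolpaw information transfer rate in bits per minute
#'
#' @param P Selection accuracy in `[0, 1]` (vectorized).
#' @param N Number of selectable targets.
#' @param T_s Time per selection in seconds. The default 2.0 s covers the
#'   flash sequence of one trial (9 x 175 ms SOA) plus completion of the
#'   final 600 ms analysis epoch; preparation and target-lock intervals are
#'   excluded.
#' @return Bits per minute.
#' @export
itr_bits_per_min <- function(P, N = 9L, T_s = 2.0) {
  if (T_s <= 0) stop("T_s must be > 0")
  wolpaw_bits(P, N) * 60 / T_s
}

#' Exact binary AUC
#'
#' Probability that a random target epoch outscores a random non-target
#' epoch, ties counting one half (Mann-Whitney rank form).
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (1/TRUE = target).
#' @return AUC in `[0, 1]`.
#' @export
auc_binary <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("scores and labels differ in length")
  pos <- as.numeric(labels) > 0
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present to compute an AUC")
  r <- rank(scores)  # mean ranks handle ties as 1/2
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Paired two-sided t-test
#'
#' @param a,b Paired numeric vectors of equal length (>= 2).
#' @return List with `t`, `p`, `df` (= n - 1).
#' @export
paired_ttest <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  n <- length(a)
  if (n < 2) stop("need at least 2 pairs")
  d <- a - b
  s <- stats::sd(d)
  if (s == 0) {
    if (all(d == 0)) return(list(t = 0, p = 1, df = n - 1))
    stop("zero variance in the paired differences")
  }
  t <- mean(d) / (s / sqrt(n))
  list(t = t, p = 2 * stats::pt(-abs(t), n - 1), df = n - 1)
}

#' One-way analysis of variance
#'
#' @param groups List of numeric vectors (>= 2 groups, each >= 2 values).
#' @return List with `F`, `df_between`, `df_within`, `p`.
#' @export
oneway_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("groups must be a list of at least 2 numeric vectors")
  sizes <- vapply(groups, length, 1L)
  if (any(sizes < 2)) stop("every group needs at least 2 observations")
  all_x <- unlist(groups)
  k <- length(groups); n <- length(all_x)
  gm <- mean(all_x)
  means <- vapply(groups, mean, 1)
  ssb <- sum(sizes * (means - gm)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  if (ssw == 0) stop("zero within-group variance: F is undefined")
  Fst <- (ssb / (k - 1)) / (ssw / (n - k))
  list(F = Fst, df_between = k - 1, df_within = n - k,
       p = stats::pf(Fst, k - 1, n - k, lower.tail = FALSE))
}

#' Grouped k-fold cross-validated decoding
#'
#' Partitions trials -- never single epochs, so the `n_stimuli` epochs of a
#' trial always share a fold -- into `folds` folds, stratified over runs
#' (each fold draws trials from every run). For each fold the model factory
#' is fitted on the remaining trials, held-out epochs are scored, and trials
#' are decoded; results are pooled into an evaluation report.
#'
#' @param epochs An `epoch_set`.
#' @param model_factory Function `epoch_set -> p300_scorer` (see
#'   [model_factory()]).
#' @param folds Number of folds (>= 2).
#' @param seed Seed for the fold assignment.
#' @param itr_T_s Selection time for the ITR (seconds).
#' @return List of class `eval_report`: `accuracy` (an [accuracy_table()]),
#'   `auc` (pooled held-out AUC), `itr_bits_min`, `per_target_accuracy`,
#'   `decoded` (trial table with fold ids), `scores`, `folds`, `seed`.
#' @export
crossval <- function(epochs, model_factory, folds = 5L, seed = 1L,
                     itr_T_s = 2.0) {
  stopifnot(inherits(epochs, "epoch_set"))
  folds <- as.integer(folds)
  if (folds < 2) stop("folds must be >= 2")
  m <- epochs$meta
  key <- paste(m$run, m$block, m$trial, sep = "\r")
  trial_ids <- unique(key)
  if (folds > length(trial_ids))
    stop("fold count (", folds, ") exceeds the number of trials (",
         length(trial_ids), ")")
  trial_run <- m$run[match(trial_ids, key)]

  fold_of <- local_seed(derive_seed(seed, "folds"), {
    f <- integer(length(trial_ids))
    for (r in unique(trial_run)) {
      idx <- which(trial_run == r)
      f[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    f
  })
  epoch_fold <- fold_of[match(key, trial_ids)]

  scores <- numeric(nrow(m))
  for (f in seq_len(folds)) {
    tr <- epoch_fold != f
    if (!any(tr) || !any(!tr)) next
    scorer <- model_factory(subset_epochs(epochs, tr))
    scores[!tr] <- score_epochs(scorer, subset_epochs(epochs, !tr))
  }

  decoded <- decode_trials(scores, m, epochs$n_stimuli)
  decoded$fold <- fold_of[match(paste(decoded$run, decoded$block,
                                      decoded$trial, sep = "\r"), trial_ids)]
  acc <- accuracy_table(decoded)
  per_target <- vapply(sort(unique(decoded$target)), function(tg)
    100 * mean(decoded$correct[decoded$target == tg]), 1)
  names(per_target) <- paste0("target", sort(unique(decoded$target)))
  structure(list(
    accuracy = acc,
    auc = auc_binary(scores, epochs$labels),
    itr_bits_min = itr_bits_per_min(acc$grand_mean / 100, epochs$n_stimuli,
                                    itr_T_s),
    per_target_accuracy = per_target,
    decoded = decoded, scores = scores,
    folds = folds, seed = as.integer(seed), itr_T_s = itr_T_s
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d-fold CV: accuracy %.2f%%, AUC %.3f, ITR %.2f bits/min\n",
              x$folds, x$accuracy$grand_mean, x$auc, x$itr_bits_min))
  invisible(x)
}

#' Subset an epoch set by epoch index
#'
#' @param epochs An `epoch_set`.
#' @param idx Logical or integer epoch selector.
#' @return The reduced `epoch_set`.
#' @export
subset_epochs <- function(epochs, idx) {
  stopifnot(inherits(epochs, "epoch_set"))
  epochs$tensor <- epochs$tensor[idx, , , drop = FALSE]
  epochs$labels <- epochs$labels[idx]
  epochs$meta <- epochs$meta[idx, , drop = FALSE]
  rownames(epochs$meta) <- NULL
  epochs
}

#' Model factory for cross-validation and the pipeline
#'
#' Returns a closure that fits the requested classifier on a training
#' `epoch_set` and returns a `p300_scorer`.
#'
#' @param method `"sepcnn"`, `"cnn"`, or a baseline (`"lda"`, `"blda"`,
#'   `"swlda"`, `"svm"`).
#' @param config A [sepcnn_config()] (CNN variants only).
#' @param hyper A [train_hyper()] (CNN variants only).
#' @param ... Extra arguments for [fit_baseline()].
#' @return Function `epoch_set -> p300_scorer`.
#' @export
model_factory <- function(method = c("sepcnn", "cnn", "lda", "blda", "swlda", "svm"),
                          config = NULL, hyper = train_hyper(), ...) {
  method <- match.arg(method)
  if (method %in% c("sepcnn", "cnn")) {
    force(config); force(hyper)
    function(epochs) {
      cfg <- config
      if (is.null(cfg)) {
        d <- dim(epochs$tensor)
        cfg <- sepcnn_config(input_len = d[2], n_channels = d[3])
      }
      spec <- if (method == "sepcnn") build_sepcnn(cfg) else build_standard_cnn(cfg)
      train_network(spec, epochs, hyper)
    }
  } else {
    function(epochs) fit_baseline(method, epochs, ...)
  }
}
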