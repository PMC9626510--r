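#' Remove channels by name
#'
#' Deletes the named channels (default: the mastoids A1/A2) from a session,
#' preserving the order of the remaining channels.
#'
#' @param session An `eeg_session`.
#' @param names Character vector of channel names to remove; may be empty.
#' @return The session without those channels.
#' @export
drop_channels <- function(session, names = c("A1", "A2")) {
  stopifnot(inherits(session, "eeg_session"))
  if (length(names) == 0) return(session)
  missing <- setdiff(names, session$channel_names)
  if (length(missing))
    stop("unknown channel(s) ", paste(missing, collapse = ", "),
         "; available: ", paste(session$channel_names, collapse = ", "))
  keep <- !(session$channel_names %in% names)
  session$data <- session$data[, keep, drop = FALSE]
  session$channel_names <- session$channel_names[keep]
  session
}

# 2nd-order Butterworth biquad coefficients via the bilinear transform.
# Returns list(b, a) with a[1] == 1.
butter2 <- function(fc, fs, type = c("low", "high")) {
  type <- match.arg(type)
  K <- tan(pi * fc / fs)
  norm <- 1 / (1 + sqrt(2) * K + K^2)
  a <- c(1, 2 * (K^2 - 1) * norm, (1 - sqrt(2) * K + K^2) * norm)
  b <- if (type == "low") c(K^2, 2 * K^2, K^2) * norm
       else c(1, -2, 1) * norm
  list(b = b, a = a)
}

# Causal direct-form IIR filter. Initial conditions correspond to the
# steady state for a constant input x[1] held since t = -Inf, which keeps
# step offsets at the signal edge from exciting slow poles (the same idea
# as scipy's lfilter_zi).
iir_filter <- function(x, b, a) {
  n <- length(x)
  x0 <- x[1]
  v <- b[1] * x
  if (length(b) > 1) for (k in 2:length(b))
    v <- v + b[k] * c(rep(x0, k - 1), x[seq_len(n - k + 1)])
  y0 <- sum(b) / sum(a) * x0
  as.numeric(stats::filter(v, -a[-1], method = "recursive",
                           init = rep(y0, length(a) - 1)))
}

# Zero-phase filtering through a cascade of biquads: even-reflection padding
# (no sign flip, so the pads carry no DC offset that would excite the slow
# high-pass pole), then forward and reverse passes per section.
filtfilt_sos <- function(x, sections, padlen) {
  n <- length(x)
  padlen <- min(n - 1L, as.integer(padlen))
  ext <- if (padlen > 0)
    c(x[seq(padlen + 1, 2)], x, x[seq(n - 1, n - padlen)])
  else x
  for (s in sections) {
    ext <- iir_filter(ext, s$b, s$a)
    ext <- rev(iir_filter(rev(ext), s$b, s$a))
  }
  if (padlen > 0) ext[(padlen + 1):(padlen + n)] else ext
}

#' Zero-phase Butterworth bandpass filter
#'
#' Applies a zero-phase (forward-backward) 4th-order Butterworth bandpass,
#' realized as a cascade of a 2nd-order high-pass at `lo_hz` and a 2nd-order
#' low-pass at `hi_hz`, to every channel independently. Edge transients are
#' suppressed by odd-reflection padding.
#'
#' @param session An `eeg_session`.
#' @param lo_hz,hi_hz Band edges in Hz; `0 < lo_hz < hi_hz < fs/2`.
#' @return The filtered session (same dimensions).
#' @export
bandpass <- function(session, lo_hz = 0.1, hi_hz = 12) {
  stopifnot(inherits(session, "eeg_session"))
  fs <- session$sampling_rate_hz
  if (!(lo_hz > 0 && lo_hz < hi_hz && hi_hz < fs / 2))
    stop("invalid band: need 0 < lo_hz < hi_hz < fs/2 (fs = ", fs, ")")
  sections <- list(butter2(lo_hz, fs, "high"), butter2(hi_hz, fs, "low"))
  padlen <- min(nrow(session$data) - 1L, as.integer(round(3 * fs / lo_hz)))
  for (j in seq_len(ncol(session$data)))
    session$data[, j] <- filtfilt_sos(session$data[, j], sections, padlen)
  session
}

#' Cut stimulus-locked epochs from a continuous session
#'
#' Extracts one fixed-length window `[onset, onset + window_ms)` per flash
#' event and labels it 1 when the flashed stimulus is the cued target of its
#' block, else 0. Windows may overlap (SOA shorter than the window); each is
#' extracted independently.
#'
#' @param session An `eeg_session`.
#' @param window_ms Epoch length in ms (default 600).
#' @return An object of class `epoch_set`: list with `tensor` (epochs x time x
#'   channels, uV), `labels` (0/1 integer), `meta` (data.frame: run, block,
#'   trial, stimulus, target), `sampling_rate_hz`, `n_stimuli`.
#' @export
extract_epochs <- function(session, window_ms = 600) {
  stopifnot(inherits(session, "eeg_session"))
  fs <- session$sampling_rate_hz
  sch <- session$schedule
  n_win <- as.integer(round(window_ms * fs / 1000))
  if (n_win < 1) stop("window_ms too short for the sampling rate")
  i0 <- as.integer(floor(sch$events$onset_ms * fs / 1000)) + 1L
  n_samp <- nrow(session$data)
  if (any(i0 + n_win - 1L > n_samp))
    stop("epoch window extends past the end of the recording (",
         sum(i0 + n_win - 1L > n_samp), " truncated epoch(s)); ",
         "the recording must cover onset + ", window_ms, " ms for every flash")
  n_ep <- length(i0)
  n_ch <- ncol(session$data)
  tensor <- array(0, c(n_ep, n_win, n_ch),
                  dimnames = list(NULL, NULL, session$channel_names))
  for (e in seq_len(n_ep))
    tensor[e, , ] <- session$data[i0[e]:(i0[e] + n_win - 1L), ]
  target <- schedule_targets(sch)
  meta <- data.frame(run = sch$events$run, block = sch$events$block,
                     trial = sch$events$trial, stimulus = sch$events$stimulus,
                     target = target)
  structure(list(
    tensor = tensor,
    labels = as.integer(sch$events$stimulus == target),
    meta = meta, sampling_rate_hz = fs, n_stimuli = sch$n_stimuli
  ), class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$tensor)
  cat(sprintf("<epoch_set> %d epochs x %d samples x %d channels @ %g Hz (%d targets, %d non-targets)\n",
              d[1], d[2], d[3], x$sampling_rate_hz,
              sum(x$labels == 1), sum(x$labels == 0)))
  invisible(x)
}

#' Decimate epochs in time
#'
#' Keeps every `factor`-th sample (starting at the first). The epoch length
#' must be divisible by `factor`. The 12 Hz low-pass applied upstream bounds
#' the spectrum far below the post-decimation Nyquist, so no extra
#' anti-aliasing is performed.
#'
#' @param epochs An `epoch_set`.
#' @param factor Positive integer decimation factor (default 3: 600 -> 200
#'   samples at 1 kHz).
#' @return The decimated `epoch_set`.
#' @export
downsample_epochs <- function(epochs, factor = 3L) {
  stopifnot(inherits(epochs, "epoch_set"))
  factor <- as.integer(factor)
  if (factor < 1) stop("factor must be a positive integer")
  if (factor == 1L) return(epochs)
  n_t <- dim(epochs$tensor)[2]
  if (n_t %% factor != 0)
    stop("epoch length ", n_t, " is not divisible by factor ", factor)
  keep <- seq(1L, n_t, by = factor)
  epochs$tensor <- epochs$tensor[, keep, , drop = FALSE]
  epochs$sampling_rate_hz <- epochs$sampling_rate_hz / factor
  epochs
}

#' Average the first k repetitions of each stimulus
#'
#' Collapses the `k` first trials (repetitions) of every (run, block,
#' stimulus) combination into one sample-wise averaged epoch, the classical
#' multi-averaging step that trades selection speed for SNR. `k = 1` is the
#' identity (single extraction).
#'
#' @param epochs An `epoch_set`.
#' @param k Number of repetitions to average (`1 <= k <=` trials per block).
#' @return An `epoch_set` with one epoch per (run, block, stimulus).
#' @export
average_repetitions <- function(epochs, k) {
  stopifnot(inherits(epochs, "epoch_set"))
  k <- as.integer(k)
  if (k < 1) stop("k must be >= 1")
  if (k == 1L) return(epochs)
  m <- epochs$meta
  key <- paste(m$run, m$block, m$stimulus, sep = "\r")
  groups <- split(seq_len(nrow(m)), key)
  if (any(vapply(groups, length, 1L) < k))
    stop("k = ", k, " exceeds the available repetitions (min ",
         min(vapply(groups, length, 1L)), ") for some (run, block, stimulus)")
  # deterministic output order: by run, block, stimulus
  ord <- order(vapply(groups, function(i) m$run[i[1]], 1),
               vapply(groups, function(i) m$block[i[1]], 1),
               vapply(groups, function(i) m$stimulus[i[1]], 1))
  groups <- groups[ord]
  d <- dim(epochs$tensor)
  out <- array(0, c(length(groups), d[2], d[3]), dimnames = dimnames(epochs$tensor))
  meta_rows <- integer(length(groups))
  for (g in seq_along(groups)) {
    idx <- groups[[g]][order(m$trial[groups[[g]]])][seq_len(k)]
    slab <- epochs$tensor[idx, , , drop = FALSE]
    out[g, , ] <- colMeans(array(slab, c(k, d[2] * d[3])))
    meta_rows[g] <- idx[1]
  }
  meta <- m[meta_rows, , drop = FALSE]
  meta$trial <- 1L
  rownames(meta) <- NULL
  structure(list(
    tensor = out,
    labels = as.integer(meta$stimulus == meta$target),
    meta = meta, sampling_rate_hz = epochs$sampling_rate_hz,
    n_stimuli = epochs$n_stimuli
  ), class = "epoch_set")
}

#' Flatten an epoch tensor to a feature matrix
#'
#' Each epoch becomes one row of length `time x channels` (time fastest
#' within channel), the feature representation the classical linear
#' baselines operate on.
#'
#' @param epochs An `epoch_set`.
#' @return Numeric matrix, epochs x (time * channels).
#' @export
flatten_epochs <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$tensor)
  matrix(epochs$tensor, d[1], d[2] * d[3])
}

#' Run the standard preprocessing chain
#'
#' Convenience wrapper: [drop_channels()] (A1/A2), [bandpass()] (0.1-12 Hz),
#' [extract_epochs()] (600 ms), [downsample_epochs()] (factor 3) -- the chain
#' that turns a raw 32-channel session into 200 x 30 epochs.
#'
#' @param session An `eeg_session`.
#' @param drop Channels to remove first.
#' @param lo_hz,hi_hz Bandpass edges (Hz); set `filter = FALSE` to skip.
#' @param window_ms Epoch window (ms).
#' @param factor Decimation factor.
#' @param filter Apply the bandpass? (Skipping is useful for quick
#'   shape/count checks.)
#' @return An `epoch_set`.
#' @export
preprocess_session <- function(session, drop = c("A1", "A2"),
                               lo_hz = 0.1, hi_hz = 12,
                               window_ms = 600, factor = 3L, filter = TRUE) {
  session <- drop_channels(session, drop)
  if (filter) session <- bandpass(session, lo_hz, hi_hz)
  downsample_epochs(extract_epochs(session, window_ms), factor)
}
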