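#' Default 32-electrode montage
#'
#' Thirty scalp data channels of the 10-20 system plus the two mastoid
#' reference channels A1/A2 that the preprocessing step removes. Approximate
#' schematic head coordinates (x: left-right, y: posterior-anterior, unit
#' head radius) drive the spatial weighting of the simulated ERP.
#'
#' @return data.frame with columns `name`, `x`, `y`.
#' @keywords internal
default_montage <- function() {
  df <- read.table(header = TRUE, text = "
name    x     y
Fp1  -0.31  0.95
Fp2   0.31  0.95
F7   -0.81  0.59
F3   -0.55  0.67
Fz    0.00  0.72
F4    0.55  0.67
F8    0.81  0.59
FT7  -0.92  0.31
FC3  -0.60  0.36
FCz   0.00  0.38
FC4   0.60  0.36
FT8   0.92  0.31
T7   -1.00  0.00
C3   -0.63  0.00
Cz    0.00  0.00
C4    0.63  0.00
T8    1.00  0.00
TP7  -0.92 -0.31
CP3  -0.60 -0.36
CPz   0.00 -0.38
CP4   0.60 -0.36
TP8   0.92 -0.31
P7   -0.81 -0.59
P3   -0.55 -0.67
Pz    0.00 -0.72
P4    0.55 -0.67
P8    0.81 -0.59
O1   -0.31 -0.95
Oz    0.00 -1.00
O2    0.31 -0.95
A1   -1.15  0.00
A2    1.15  0.00
")
  df$name <- as.character(df$name)
  df
}

# Parieto-occipital Gaussian gain bump (max between Pz and Oz); the two
# mastoids get zero ERP gain (noise-only channels).
default_topography <- function(montage = default_montage(), sigma = 0.55) {
  g <- exp(-((montage$x - 0)^2 + (montage$y + 0.85)^2) / (2 * sigma^2))
  g[montage$name %in% c("A1", "A2")] <- 0
  g <- g / max(g)
  names(g) <- montage$name
  g
}

#' Simulation parameters for a synthetic P300 session
#'
#' Bundles the generative model of one recording environment. The P300 of a
#' target flash is a one-cycle raised-cosine positive pulse of `p300_width_ms`
#' width whose peak latency is drawn once per session from
#' `N(p300_latency_mean_ms, p300_latency_sd_ms)` and additionally jittered per
#' flash by `N(0, latency_jitter_ms)`. Its amplitude is `p300_amplitude_uv`
#' scaled by the per-channel topography gain, and further by
#' `ar_amplitude_scale` in the AR environment (AR ERPs are smaller and later
#' than their computer-screen counterparts). The additive background is
#' independent per channel: 1/f pink noise, a 10 Hz alpha sinusoid with random
#' phase, and white noise, each at a stated RMS level in microvolts.
#'
#' @param environment `"ar"` (augmented reality) or `"cs"` (computer screen).
#' @param p300_latency_mean_ms Mean peak latency (ms after flash onset);
#'   defaults: 482.47 (AR), 434.53 (CS).
#' @param p300_latency_sd_ms Between-session SD of the peak latency (ms).
#' @param p300_amplitude_uv Peak amplitude at the topography maximum (uV).
#' @param ar_amplitude_scale Multiplier in (0, 1] applied in the AR
#'   environment only.
#' @param latency_jitter_ms Per-flash latency jitter SD (ms).
#' @param p300_width_ms Full width of the raised-cosine pulse (ms).
#' @param topography Named per-channel gain vector (one entry per channel).
#' @param noise_pink_uv,noise_alpha_uv,noise_white_uv RMS of each noise
#'   component (uV).
#' @param sampling_rate_hz Sampling rate (Hz).
#' @param channel_names Channel names; length defines the channel count.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(environment = c("ar", "cs"),
                       p300_latency_mean_ms = NULL,
                       p300_latency_sd_ms = 3,
                       p300_amplitude_uv = 5,
                       ar_amplitude_scale = 0.7,
                       latency_jitter_ms = 20,
                       p300_width_ms = 300,
                       topography = default_topography(),
                       noise_pink_uv = 6,
                       noise_alpha_uv = 3,
                       noise_white_uv = 2,
                       sampling_rate_hz = 1000,
                       channel_names = default_montage()$name) {
  environment <- match.arg(environment)
  if (is.null(p300_latency_mean_ms))
    p300_latency_mean_ms <- if (environment == "ar") 482.47 else 434.53
  amps <- c(p300_latency_sd_ms, p300_amplitude_uv, latency_jitter_ms,
            p300_width_ms, noise_pink_uv, noise_alpha_uv, noise_white_uv)
  if (any(amps < 0)) stop("amplitude and sd parameters must be >= 0")
  if (ar_amplitude_scale <= 0 || ar_amplitude_scale > 1)
    stop("ar_amplitude_scale must lie in (0, 1]")
  if (anyDuplicated(channel_names)) stop("channel_names must be unique")
  if (length(topography) != length(channel_names))
    stop("topography must have one entry per channel (",
         length(channel_names), " channels, got ", length(topography), ")")
  if (!is.null(names(topography))) topography <- topography[channel_names]
  if (anyNA(topography)) stop("topography is missing entries for some channels")
  structure(list(
    environment = environment,
    p300_latency_mean_ms = p300_latency_mean_ms,
    p300_latency_sd_ms = p300_latency_sd_ms,
    p300_amplitude_uv = p300_amplitude_uv,
    ar_amplitude_scale = ar_amplitude_scale,
    latency_jitter_ms = latency_jitter_ms,
    p300_width_ms = p300_width_ms,
    topography = as.numeric(topography),
    noise_pink_uv = noise_pink_uv,
    noise_alpha_uv = noise_alpha_uv,
    noise_white_uv = noise_white_uv,
    sampling_rate_hz = sampling_rate_hz,
    channel_names = as.character(channel_names)
  ), class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf("<sim_params> %s environment, %d channels @ %g Hz\n",
              toupper(x$environment), length(x$channel_names), x$sampling_rate_hz))
  cat(sprintf("  P300: %g uV (AR scale %g), latency %g +/- %g ms, jitter %g ms\n",
              x$p300_amplitude_uv, x$ar_amplitude_scale,
              x$p300_latency_mean_ms, x$p300_latency_sd_ms, x$latency_jitter_ms))
  cat(sprintf("  noise RMS (uV): pink %g, alpha %g, white %g\n",
              x$noise_pink_uv, x$noise_alpha_uv, x$noise_white_uv))
  invisible(x)
}

# One-cycle raised-cosine positive pulse sampled on `t_ms` (vector of times
# relative to pulse peak); zero outside +/- width/2.
raised_cosine_pulse <- function(t_ms, width_ms) {
  half <- width_ms / 2
  out <- numeric(length(t_ms))
  inside <- abs(t_ms) <= half
  out[inside] <- 0.5 * (1 + cos(pi * t_ms[inside] / half))
  out
}

# 1/f (pink) noise via spectral shaping of white noise, normalized to
# unit RMS per column. The amplitude profile is symmetric in FFT bin
# index, so the inverse transform of shaped real-signal spectra stays real.
pink_noise <- function(n, n_cols = 1) {
  m <- stats::nextn(n)  # FFT-friendly length; excess samples are discarded
  k <- 0:(m - 1)
  amp <- 1 / sqrt(pmax(pmin(k, m - k), 1))  # DC bin treated like bin 1
  out <- matrix(0, n, n_cols)
  for (j in seq_len(n_cols)) {
    x <- Re(stats::fft(stats::fft(stats::rnorm(m)) * amp, inverse = TRUE))[seq_len(n)] / m
    out[, j] <- x / stats::sd(x)
  }
  out
}

#' Simulate a continuous EEG session from a schedule
#'
#' Renders the session as a time x channel matrix in microvolts: a stochastic
#' noise background (pink + 10 Hz alpha + white, per [sim_params()]) plus one
#' ERP pulse per flash of the cued target stimulus. Non-target flashes add
#' nothing. The recording extends `post_ms` beyond the final flash.
#'
#' @param schedule A [make_schedule()] result.
#' @param params A [sim_params()] object.
#' @param seed Integer seed; identical (schedule, params, seed) give
#'   bit-identical sessions.
#' @return An object of class `eeg_session`: list with `data` (samples x
#'   channels matrix, uV), `sampling_rate_hz`, `channel_names`, `schedule`,
#'   `environment`, `seed`.
#' @export
simulate_session <- function(schedule, params = sim_params(), seed = 1L) {
  stopifnot(inherits(schedule, "stim_schedule"), inherits(params, "sim_params"))
  fs <- params$sampling_rate_hz
  n_ch <- length(params$channel_names)
  dur_ms <- max(schedule$events$onset_ms) + schedule$post_ms
  n_samp <- ceiling(dur_ms * fs / 1000)
  if (n_samp < 1) stop("schedule yields an empty recording")

  amp_scale <- params$p300_amplitude_uv *
    if (params$environment == "ar") params$ar_amplitude_scale else 1

  local_seed(seed, {
    data <- matrix(0, n_samp, n_ch)
    if (params$noise_pink_uv > 0)
      data <- data + params$noise_pink_uv * pink_noise(n_samp, n_ch)
    if (params$noise_alpha_uv > 0) {
      tt <- (seq_len(n_samp) - 1) / fs
      phases <- stats::runif(n_ch, 0, 2 * pi)
      alpha <- sqrt(2) * params$noise_alpha_uv *
        sin(outer(2 * pi * 10 * tt, phases, `+`))
      data <- data + alpha
    }
    if (params$noise_white_uv > 0)
      data <- data + matrix(stats::rnorm(n_samp * n_ch, sd = params$noise_white_uv),
                            n_samp, n_ch)

    session_latency <- stats::rnorm(1, params$p300_latency_mean_ms,
                                    params$p300_latency_sd_ms)
    is_target <- schedule$events$stimulus == schedule_targets(schedule)
    onsets <- schedule$events$onset_ms[is_target]
    if (length(onsets) && amp_scale > 0) {
      half <- params$p300_width_ms / 2
      for (onset in onsets) {
        lat <- session_latency + stats::rnorm(1, 0, params$latency_jitter_ms)
        peak_ms <- onset + lat
        i0 <- max(1L, floor((peak_ms - half) * fs / 1000) + 1L)
        i1 <- min(n_samp, ceiling((peak_ms + half) * fs / 1000) + 1L)
        if (i1 < i0) next
        t_rel <- ((i0:i1) - 1) * 1000 / fs - peak_ms
        pulse <- raised_cosine_pulse(t_rel, params$p300_width_ms)
        data[i0:i1, ] <- data[i0:i1, ] +
          (amp_scale * pulse) %o% params$topography
      }
    }
    colnames(data) <- params$channel_names
    structure(list(
      data = data, sampling_rate_hz = fs,
      channel_names = params$channel_names,
      schedule = schedule, environment = params$environment,
      seed = as.integer(seed)
    ), class = "eeg_session")
  })
}

#' @export
print.eeg_session <- function(x, ...) {
  cat(sprintf("<eeg_session> %s, %d channels x %d samples @ %g Hz (%.1f s)\n",
              toupper(x$environment), ncol(x$data), nrow(x$data),
              x$sampling_rate_hz, nrow(x$data) / x$sampling_rate_hz))
  print(x$schedule)
  invisible(x)
}

#' Class-wise grand-average ERP at one channel
#'
#' Averages target and non-target epochs separately at a single channel,
#' e.g. to inspect the simulated P300 at Oz.
#'
#' @param epochs An [extract_epochs()] result.
#' @param channel Channel name or index.
#' @return List with numeric vectors `target`, `nontarget` (epoch length), and
#'   `time_ms` (sample times relative to flash onset).
#' @export
grand_average_erp <- function(epochs, channel) {
  stopifnot(inherits(epochs, "epoch_set"))
  ch_names <- dimnames(epochs$tensor)[[3]]
  if (is.character(channel)) {
    idx <- match(channel, ch_names)
    if (is.na(idx)) stop("unknown channel '", channel, "'; available: ",
                         paste(ch_names, collapse = ", "))
  } else {
    idx <- as.integer(channel)
    if (idx < 1 || idx > dim(epochs$tensor)[3]) stop("channel index out of range")
  }
  for (cls in c(1, 0)) {
    if (!any(epochs$labels == cls))
      stop("no ", if (cls == 1) "target" else "non-target", " epochs present")
  }
  slab <- epochs$tensor[, , idx, drop = FALSE]
  dim(slab) <- dim(epochs$tensor)[1:2]
  list(
    target = colMeans(slab[epochs$labels == 1, , drop = FALSE]),
    nontarget = colMeans(slab[epochs$labels == 0, , drop = FALSE]),
    time_ms = (seq_len(ncol(slab)) - 1) * 1000 / epochs$sampling_rate_hz
  )
}
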