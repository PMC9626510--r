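# Shared fixtures. Expensive objects are built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]]))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# High-SNR simulation world: the noise RMS levels are one quarter of the
# realistic defaults and per-flash latency jitter is halved. Fixed a priori;
# used wherever the contract says "high SNR".
high_snr_params <- function(environment = "ar", ...) {
  sim_params(environment, noise_pink_uv = 1.5, noise_alpha_uv = 0.8,
             noise_white_uv = 0.5, latency_jitter_ms = 10, ...)
}

# Two-run high-SNR AR session and its preprocessed epochs (810 epochs of
# 200 x 30). Preparation/lock intervals are shortened to keep the continuous
# recording small; they carry no epoched signal.
small_schedule <- function(runs = 2)
  make_schedule(runs = runs, prep_ms = 300, lock_ms = 200, seed = 11)

small_session <- function() fixture("small_session", function()
  simulate_session(small_schedule(), high_snr_params(), seed = 12))

small_epochs <- function() fixture("small_epochs", function()
  preprocess_session(small_session()))

# Cross-validated SepCNN report on the small high-SNR session (shared by the
# acceptance suite and the model-comparison test).
sepcnn_cv_report <- function() fixture("sepcnn_cv_report", function()
  crossval(small_epochs(),
           model_factory("sepcnn",
                         hyper = train_hyper(max_epochs = 40, patience = 8,
                                             seed = 5)),
           folds = 5, seed = 9))

# Small separable toy epoch set for fast network tests: targets carry a
# smooth bump template plus noise, non-targets noise only.
toy_epochs <- function(n_trials = 30, len = 60, n_ch = 4, snr = 3,
                       n_stimuli = 3, seed = 42) {
  set.seed(seed)
  n_ep <- n_trials * n_stimuli
  template <- exp(-((seq_len(len) - len / 2)^2) / (2 * (len / 8)^2))
  tensor <- array(rnorm(n_ep * len * n_ch), c(n_ep, len, n_ch))
  meta <- data.frame(
    run = 1L,
    block = rep(seq_len(n_trials), each = n_stimuli),
    trial = 1L,
    stimulus = rep(seq_len(n_stimuli), n_trials),
    target = rep(((seq_len(n_trials) - 1L) %% n_stimuli) + 1L,
                 each = n_stimuli))
  labels <- as.integer(meta$stimulus == meta$target)
  for (e in which(labels == 1))
    tensor[e, , ] <- tensor[e, , ] + snr * template %o% rep(1, n_ch)
  structure(list(tensor = tensor, labels = labels, meta = meta,
                 sampling_rate_hz = 100, n_stimuli = n_stimuli),
            class = "epoch_set")
}

# Minimal epoch_set wrapper around a raw tensor.
wrap_epochs <- function(tensor, labels, n_stimuli = 2L, fs = 100) {
  n <- dim(tensor)[1]
  structure(list(tensor = tensor, labels = as.integer(labels),
                 meta = data.frame(run = 1L, block = seq_len(n), trial = 1L,
                                   stimulus = 1L, target = 1L),
                 sampling_rate_hz = fs, n_stimuli = n_stimuli),
            class = "epoch_set")
}

# Single-channel session wrapper for filter tests.
signal_session <- function(x, fs = 1000) {
  structure(list(data = matrix(x, ncol = 1, dimnames = list(NULL, "X")),
                 sampling_rate_hz = fs, channel_names = "X",
                 schedule = NULL, environment = "cs", seed = 1L),
            class = "eeg_session")
}

rms <- function(x) sqrt(mean(x^2))
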