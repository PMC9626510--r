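test_that("drop_channels removes mastoids and preserves order", {
  ses <- small_session()
  out <- drop_channels(ses)
  expect_equal(ncol(out$data), 30)
  expect_equal(out$channel_names, setdiff(ses$channel_names, c("A1", "A2")))
  expect_identical(drop_channels(ses, character(0)), ses)
  expect_error(drop_channels(ses, "Nope"), "available")
})

test_that("bandpass attenuation matches the filter-design oracles", {
  fs <- 1000; t <- (0:(10 * fs - 1)) / fs
  gain <- function(f) {
    x <- sin(2 * pi * f * t)
    rms(bandpass(signal_session(x))$data[, 1]) / rms(x)
  }
  expect_lt(gain(30), 0.05)   # stopband
  expect_gt(gain(5), 0.90)    # passband
  expect_equal(gain(12), 0.5, tolerance = 0.05)  # -3 dB edge, applied twice
})

test_that("bandpass is loosely idempotent in band and shape-preserving", {
  set.seed(1)
  x <- rnorm(8000)
  s1 <- bandpass(signal_session(x))
  expect_equal(dim(s1$data), c(8000L, 1L))
  s2 <- bandpass(s1)
  expect_lt(abs(rms(s2$data) / rms(s1$data) - 1), 0.25)
  expect_error(bandpass(signal_session(x), 12, 0.1), "invalid band")
  expect_error(bandpass(signal_session(x), 0.1, 600), "invalid band")
})

test_that("epoch extraction yields one labelled 600-sample window per flash", {
  ses <- drop_channels(small_session())
  ep <- extract_epochs(ses)
  sch <- ses$schedule
  expect_equal(dim(ep$tensor), c(nrow(sch$events), 600L, 30L))
  expect_equal(sum(ep$labels), nrow(sch$events) / 9)
  # label invariant: 1 iff stimulus is the block target
  expect_identical(ep$labels,
                   as.integer(ep$meta$stimulus == ep$meta$target))
  # one target per trial
  per_trial <- tapply(ep$labels,
                      interaction(ep$meta$run, ep$meta$block, ep$meta$trial),
                      sum)
  expect_true(all(per_trial == 1))
  # epoch content is the raw window
  i0 <- floor(sch$events$onset_ms[1] * 1000 / 1000) + 1
  expect_equal(ep$tensor[1, , ], ses$data[i0:(i0 + 599), ],
               ignore_attr = TRUE)
})

test_that("truncated final epochs raise an informative error", {
  ses <- drop_channels(small_session())
  ses$data <- ses$data[1:(nrow(ses$data) - 300), , drop = FALSE]
  expect_error(extract_epochs(ses), "past the end")
})

test_that("downsampling decimates time only", {
  ep <- fixture("small_epochs_raw", function()
    extract_epochs(drop_channels(small_session())))
  d3 <- downsample_epochs(ep, 3)
  expect_equal(dim(d3$tensor), c(dim(ep$tensor)[1], 200L, 30L))
  expect_equal(d3$tensor[, 1, ], ep$tensor[, 1, ])
  expect_equal(d3$tensor[, 2, ], ep$tensor[, 4, ])
  expect_identical(d3$labels, ep$labels)
  expect_identical(downsample_epochs(ep, 1), ep)
  expect_error(downsample_epochs(ep, 7), "not divisible")

  const <- wrap_epochs(array(2.5, c(2, 6, 1)), c(1, 0))
  expect_equal(unique(as.numeric(downsample_epochs(const, 3)$tensor)), 2.5)
})

test_that("average_repetitions collapses repetitions with preserved labels", {
  ep <- small_epochs()   # 2 runs x 9 blocks x 5 trials x 9 stimuli
  expect_identical(average_repetitions(ep, 1), ep)
  a5 <- average_repetitions(ep, 5)
  expect_equal(dim(a5$tensor)[1], 2 * 9 * 9)
  expect_equal(sum(a5$labels), 2 * 9)        # label conservation: 90/5 per run
  expect_equal(sum(ep$labels) / 5, sum(a5$labels))
  expect_error(average_repetitions(ep, 6), "exceeds")

  # averaging two identical epochs is the identity
  idx <- which(ep$meta$block == 1 & ep$meta$run == 1 & ep$meta$stimulus == 1)
  dup <- subset_epochs(ep, rep(idx[1], 2))
  dup$meta$trial <- 1:2
  a2 <- average_repetitions(dup, 2)
  expect_equal(a2$tensor[1, , ], ep$tensor[idx[1], , ], ignore_attr = TRUE)

  # averaged epoch equals the sample-wise mean of the first k repetitions
  a3 <- average_repetitions(ep, 3)
  sel <- which(ep$meta$run == 1 & ep$meta$block == 2 & ep$meta$stimulus == 4 &
                 ep$meta$trial <= 3)
  out <- which(a3$meta$run == 1 & a3$meta$block == 2 & a3$meta$stimulus == 4)
  expect_equal(a3$tensor[out, , ],
               apply(ep$tensor[sel, , , drop = FALSE], c(2, 3), mean),
               ignore_attr = TRUE)
})

test_that("averaging raises target-template correlation monotonically in k", {
  # a noisier world than the high-SNR fixture so averaging has work to do;
  # 54 blocks via 6 runs with shortened inter-trial padding
  sch <- make_schedule(runs = 6, prep_ms = 200, lock_ms = 100, seed = 21)
  ep <- preprocess_session(
    simulate_session(sch, sim_params("ar", latency_jitter_ms = 10), seed = 22),
    filter = FALSE)
  template <- p300sep:::raised_cosine_pulse(
    (seq_len(200) - 1) * 3 - 482.47, 300)
  mean_cor <- vapply(c(1, 3, 5), function(k) {
    a <- average_repetitions(ep, k)
    tg <- which(a$labels == 1)
    mean(vapply(tg, function(e) cor(a$tensor[e, , "Oz"], template), 1))
  }, 1)
  expect_true(all(diff(mean_cor) > 0))
})

test_that("the default pipeline emits the 200 x 30 shape contract", {
  ep <- small_epochs()
  expect_equal(dim(ep$tensor)[2:3], c(200L, 30L))
  expect_equal(ep$sampling_rate_hz, 1000 / 3)
})
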