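test_that("conv_output_len matches the architecture table and limits", {
  expect_equal(conv_output_len(200, 10, 6, 4), 34L)
  expect_equal(conv_output_len(10, 10, 1, 0), 1L)
  expect_equal(conv_output_len(200, 1, 1, 0), 200L)
  expect_error(conv_output_len(5, 10, 1, 0), "larger than padded input")
  expect_error(conv_output_len(10, 2, 0, 0), "stride")
})

test_that("default SepCNN reproduces the published shape chain", {
  spec <- build_sepcnn()
  expect_equal(model_shapes(spec),
               list(c(200L, 30L), c(34L, 30L), c(34L, 30L), c(34L, 4L),
                    c(34L, 4L), 136L, 1L, 1L))
  kinds <- vapply(spec$layers, `[[`, "", "kind")
  expect_equal(kinds, c("batchnorm", "depthconv", "batchnorm", "pointconv",
                        "tanh", "flatten", "dense", "sigmoid"))
  # one depthwise kernel per channel; pointwise kernels have size 1
  expect_equal(spec$layers[[2]]$channels, 30L)
  expect_equal(dim(p300sep:::init_params(spec)[[2]]$W), c(10L, 30L))
  expect_equal(build_sepcnn(sepcnn_config(n_pointwise = 1))$config$flatten_dim, 34L)
})

test_that("standard CNN mirrors the separable config with a single conv", {
  spec <- build_standard_cnn()
  kinds <- vapply(spec$layers, `[[`, "", "kind")
  expect_equal(kinds, c("batchnorm", "stdconv", "tanh", "flatten", "dense",
                        "sigmoid"))
  expect_equal(spec$layers[[2]]$out_shape, c(34L, 4L))
  expect_equal(spec$layers[[4]]$out_shape, 136L)
  expect_equal(build_standard_cnn(sepcnn_config(n_pointwise = 1))$layers[[4]]$out_shape, 34L)
  expect_identical(build_standard_cnn(), build_standard_cnn())
})

test_that("SepCNN has strictly fewer trainable parameters than standard CNN", {
  expect_equal(build_sepcnn()$param_count, 711L)
  expect_equal(build_standard_cnn()$param_count, 1401L)
  expect_lt(build_sepcnn()$param_count, build_standard_cnn()$param_count)
  cfg <- sepcnn_config(input_len = 60, n_channels = 8, depth_kernel = 5,
                       stride = 2, padding = 2, n_pointwise = 3)
  expect_lt(build_sepcnn(cfg)$param_count, build_standard_cnn(cfg)$param_count)
})

test_that("vectorized convolutions match the brute-force oracle", {
  set.seed(7)
  cases <- list(
    list(B = 3, T = 20, C = 4, h = 5, s = 2, p = 1, F = 3),
    list(B = 2, T = 17, C = 3, h = 4, s = 3, p = 0, F = 2),
    list(B = 3, T = 200, C = 30, h = 10, s = 6, p = 4, F = 4))
  for (cs in cases) {
    x <- array(rnorm(cs$B * cs$T * cs$C), c(cs$B, cs$T, cs$C))
    Wd <- matrix(rnorm(cs$h * cs$C), cs$h, cs$C); bd <- rnorm(cs$C)
    expect_lt(max(abs(run_layer("depthconv", x, list(W = Wd, b = bd),
                                stride = cs$s, padding = cs$p) -
                        oracle_depthconv(x, Wd, bd, cs$s, cs$p))), 1e-5)
    Wp <- matrix(rnorm(cs$C * cs$F), cs$C, cs$F); bp <- rnorm(cs$F)
    expect_lt(max(abs(run_layer("pointconv", x, list(W = Wp, b = bp)) -
                        oracle_pointconv(x, Wp, bp))), 1e-5)
    Ws <- array(rnorm(cs$h * cs$C * cs$F), c(cs$h, cs$C, cs$F))
    expect_lt(max(abs(run_layer("stdconv", x, list(W = Ws, b = bp),
                                stride = cs$s, padding = cs$p) -
                        oracle_stdconv(x, Ws, bp, cs$s, cs$p))), 1e-5)
  }
})

test_that("cost formulas evaluate exactly and obey the algebraic identity", {
  cp <- separable_cost(200, 10, 4)
  expect_equal(cp$C_sep, 2674)
  expect_equal(cp$C, 7640)
  expect_equal(cp$ratio, 0.35)
  expect_equal(separable_cost(10, 1, 1)$ratio, 2)
  set.seed(1)
  for (i in 1:25) {
    h <- sample(1:50, 1); n <- sample(1:64, 1); H1 <- h + sample(1:500, 1)
    cp <- separable_cost(H1, h, n)
    expect_equal(cp$C_sep / cp$C, 1 / n + 1 / h, tolerance = 1e-15)
    expect_equal(cp$ratio, 1 / n + 1 / h)
  }
  expect_error(separable_cost(10, 10, 2), "smaller than input length")
})

test_that("training is deterministic, shape-checked, and label-checked", {
  ep <- toy_epochs(n_trials = 9, seed = 1)
  cfg <- sepcnn_config(input_len = 60, n_channels = 4, depth_kernel = 6,
                       stride = 3, padding = 2, n_pointwise = 2)
  hy <- train_hyper(max_epochs = 4, patience = 2, batch_size = 8, seed = 99)
  s1 <- train_network(build_sepcnn(cfg), ep, hy)
  s2 <- train_network(build_sepcnn(cfg), ep, hy)
  expect_identical(s1$params, s2$params)
  expect_identical(s1$state, s2$state)

  bad <- ep; bad$labels <- rep(1L, length(ep$labels))
  expect_error(train_network(build_sepcnn(cfg), bad, hy), "both target")
  expect_error(train_network(build_sepcnn(), ep, hy), "expects")
  expect_error(score_epochs(s1, small_epochs()), "expects")
})

test_that("scores are probabilities and duplicated epochs score identically", {
  ep <- toy_epochs(n_trials = 9, seed = 2)
  cfg <- sepcnn_config(input_len = 60, n_channels = 4, depth_kernel = 6,
                       stride = 3, padding = 2, n_pointwise = 2)
  sc <- train_network(build_sepcnn(cfg), ep,
                      train_hyper(max_epochs = 5, batch_size = 8, seed = 3))
  s <- score_epochs(sc, ep)
  expect_true(all(s >= 0 & s <= 1))
  dup <- subset_epochs(ep, c(1, 1, 2))
  sd <- score_epochs(sc, dup)
  expect_identical(sd[1], sd[2])
})

test_that("both variants separate constructed toy data and fail on null labels", {
  cfg <- sepcnn_config(input_len = 60, n_channels = 4, depth_kernel = 6,
                       stride = 3, padding = 2, n_pointwise = 2)
  tr <- toy_epochs(n_trials = 40, seed = 4)
  te <- toy_epochs(n_trials = 25, seed = 5)
  hy <- train_hyper(max_epochs = 40, patience = 8, batch_size = 16, seed = 6)
  for (build in list(build_sepcnn, build_standard_cnn)) {
    sc <- train_network(build(cfg), tr, hy)
    expect_gte(auc_binary(score_epochs(sc, te), te$labels), 0.95)
  }
  # template epoch must outscore a pure-noise epoch
  sc <- train_network(build_sepcnn(cfg), tr, hy)
  s_te <- score_epochs(sc, te)
  expect_gt(mean(s_te[te$labels == 1]), mean(s_te[te$labels == 0]))

  # null-data sanity oracle: no template, random labels -> chance AUC.
  # (Permuting labels while the template stays in the data is not a null
  # world: any chance correlation with the template direction is amplified
  # into a non-chance ranking, in either direction.)
  null_tr <- toy_epochs(n_trials = 40, snr = 0, seed = 8)
  null_te <- toy_epochs(n_trials = 25, snr = 0, seed = 18)
  scp <- train_network(build_sepcnn(cfg), null_tr, hy)
  expect_lt(abs(auc_binary(score_epochs(scp, null_te), null_te$labels) - 0.5),
            0.1)
})

test_that("training loss decreases on a noiseless separable toy set", {
  ep <- toy_epochs(n_trials = 30, snr = 50, seed = 9)  # essentially noiseless
  cfg <- sepcnn_config(input_len = 60, n_channels = 4, depth_kernel = 6,
                       stride = 3, padding = 2, n_pointwise = 2)
  sc <- train_network(build_sepcnn(cfg), ep,
                      train_hyper(max_epochs = 15, patience = 15,
                                  batch_size = 90, val_fraction = 0,
                                  lr = 5e-3, seed = 10))
  h <- sc$train_loss
  expect_lt(h[length(h)], h[1])
  expect_true(all(diff(h) < 0.02))  # non-increasing up to small tolerance
})
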