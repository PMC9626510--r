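test_that("decode_trial takes the argmax with lowest-index ties", {
  expect_equal(decode_trial(c(.1, .2, .3, .4, .5, .9, .4, .3, .2)), 6L)
  expect_equal(decode_trial(rep(0.5, 9)), 1L)
  expect_error(decode_trial(c(.1, .2)), "expected 9")
})

test_that("decode_trials groups epochs and flags correct selections", {
  ep <- small_epochs()
  scores <- as.numeric(ep$labels)           # oracle scores
  dec <- decode_trials(scores, ep$meta, ep$n_stimuli)
  expect_equal(nrow(dec), 90)
  expect_true(all(dec$correct == 1))
  expect_error(decode_trials(scores[-1], ep$meta), "misaligned")
})

test_that("accuracy_table reproduces published fixture arithmetic", {
  ref <- ref_accuracy_matrix()
  expect_equal(dim(ref$matrix), c(15L, 10L))
  expect_equal(round(ref$participant_means[["P1"]], 2), 90.44)
  df <- ref_accuracy_table()
  expect_equal(round(mean(df$mean_printed), 2), 81.10)

  all_right <- data.frame(correct = 1, run = rep(1:3, each = 4))
  at <- accuracy_table(all_right)
  expect_true(all(at$matrix == 100))
  expect_equal(at$grand_mean, 100)
})

test_that("wolpaw_bits matches closed-form values and is monotone", {
  expect_equal(wolpaw_bits(1, 9), log2(9))
  expect_equal(wolpaw_bits(1 / 9, 9), 0)
  expect_equal(wolpaw_bits(0.811, 9), 1.903, tolerance = 5e-4)
  expect_equal(wolpaw_bits(0, 9), log2(9 / 8))
  grid <- seq(1 / 9 + 0.01, 1, length.out = 60)
  expect_true(all(diff(wolpaw_bits(grid, 9)) > 0))
  expect_error(wolpaw_bits(1.2, 9), "\\[0, 1\\]")
})

test_that("itr_bits_per_min scales bits by selections per minute", {
  expect_equal(itr_bits_per_min(1, 9, 2), log2(9) * 30, tolerance = 1e-10)
  expect_equal(itr_bits_per_min(1 / 9, 9, 7.3), 0)
  itrs <- itr_bits_per_min(ref_accuracy_table()$mean_printed / 100, 9, 2.0)
  expect_equal(mean(itrs), 57.90, tolerance = 0.3)
  expect_error(itr_bits_per_min(0.5, 9, 0), "T_s")
})

test_that("auc_binary counts concordant pairs exactly", {
  expect_equal(auc_binary(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_equal(auc_binary(c(5, 6, 1, 2), c(1, 1, 0, 0)), 1)
  expect_equal(auc_binary(c(1, 1), c(1, 0)), 0.5)  # tie counts one half
  set.seed(1)
  s <- rnorm(4000); l <- sample(rep(0:1, 2000))
  expect_lt(abs(auc_binary(s, l) - 0.5), 0.05)
  expect_error(auc_binary(1:3, c(1, 1, 1)), "both classes")
})

test_that("paired_ttest matches the closed form and is antisymmetric", {
  r <- paired_ttest(1:5 + c(1, 2, 3, 4, 5), 1:5)
  expect_equal(r$t, mean(1:5) / (sd(1:5) / sqrt(5)), tolerance = 1e-12)
  expect_equal(r$t, 4.2426, tolerance = 1e-4)
  expect_equal(r$p, 0.0132, tolerance = 1e-2)
  expect_equal(r$p, 2 * pt(-abs(r$t), 4), tolerance = 1e-12)
  expect_equal(r$df, 4)
  same <- paired_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  a <- c(3, 1, 4, 1, 5); b <- c(2, 7, 1, 8, 2)
  expect_equal(paired_ttest(a, b)$t, -paired_ttest(b, a)$t)
  expect_error(paired_ttest(c(1, 2), c(0, 1)), "zero variance")
  # cross-check against stats::t.test
  tt <- t.test(a, b, paired = TRUE)
  expect_equal(paired_ttest(a, b)$p, tt$p.value, tolerance = 1e-12)
})

test_that("oneway_anova returns the published df structure and null behavior", {
  set.seed(2)
  groups <- replicate(9, rnorm(15), simplify = FALSE)
  r <- oneway_anova(groups)
  expect_equal(r$df_between, 8)
  expect_equal(r$df_within, 126)
  av <- anova(lm(y ~ g, data.frame(y = unlist(groups),
                                   g = factor(rep(1:9, each = 15)))))
  expect_equal(r$F, av$`F value`[1], tolerance = 1e-12)
  expect_error(oneway_anova(replicate(3, rep(2, 5), simplify = FALSE)),
               "undefined")
  expect_error(oneway_anova(list(rnorm(5))), "at least 2")
  # null simulation: F averages near 1
  set.seed(3)
  fs <- replicate(300, oneway_anova(replicate(5, rnorm(10),
                                              simplify = FALSE))$F)
  expect_gt(mean(fs), 0.7); expect_lt(mean(fs), 1.4)
})

test_that("crossval keeps trials intact, is seeded, and honors oracle scorers", {
  ep <- small_epochs()
  oracle <- function(train) structure(list(), class = c("oracle_scorer",
                                                        "p300_scorer"))
  registerS3method("score_epochs", "oracle_scorer",
                   function(scorer, epochs) as.numeric(epochs$labels),
                   envir = asNamespace("p300sep"))
  r1 <- crossval(ep, oracle, folds = 5, seed = 4)
  expect_equal(r1$accuracy$grand_mean, 100)
  expect_equal(r1$auc, 1)
  expect_equal(r1$itr_bits_min, log2(9) * 30, tolerance = 1e-10)
  r2 <- crossval(ep, oracle, folds = 5, seed = 4)
  expect_identical(r1$decoded, r2$decoded)
  # epochs of one trial never straddle folds
  key <- paste(ep$meta$run, ep$meta$block, ep$meta$trial)
  dec_key <- paste(r1$decoded$run, r1$decoded$block, r1$decoded$trial)
  fold_per_epoch <- r1$decoded$fold[match(key, dec_key)]
  expect_true(all(tapply(fold_per_epoch, key,
                         function(f) length(unique(f))) == 1))
  # every fold spans both runs (stratification)
  expect_true(all(table(r1$decoded$fold, r1$decoded$run) > 0))
  expect_error(crossval(ep, oracle, folds = 1000, seed = 1), "exceeds")
})
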