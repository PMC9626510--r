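test_that("LDA separates well-separated 2-D clouds with zero training error", {
  set.seed(1)
  X <- rbind(matrix(rnorm(100, mean = 0), 50, 2),
             matrix(rnorm(100, mean = 5), 50, 2))
  y <- rep(c(0, 1), each = 50)
  fit <- fit_lda(X, y)
  s <- as.numeric(X %*% fit$w + fit$b)
  expect_equal(as.integer(s > 0), y)
})

test_that("LDA with equal class means carries almost no signal", {
  set.seed(2)
  n <- 2000
  X <- matrix(rnorm(2 * n), n, 2)
  y <- rep(c(0, 1), n / 2)
  fit <- fit_lda(X, y)
  s <- as.numeric(X %*% fit$w)
  expect_lt(sd(s), 0.2 * sd(X))  # expected ~ sqrt(2 * d / n) ~ 0.045
})

test_that("LDA direction is invariant to dataset duplication", {
  set.seed(3)
  X <- rbind(matrix(rnorm(60), 30, 2), matrix(rnorm(60, 2), 30, 2))
  y <- rep(c(0, 1), each = 30)
  w1 <- fit_lda(X, y)$w
  w2 <- fit_lda(rbind(X, X), c(y, y))$w
  expect_gt(abs(cor(w1, w2)), 0.999)
  expect_error(fit_lda(X, rep(1, 60)), "both classes")
})

test_that("BLDA reduces to OLS when the prior is switched off", {
  set.seed(4)
  X <- matrix(rnorm(100 * 5), 100, 5)
  y <- rbinom(100, 1, 0.5)
  fit <- fit_blda(X, y, alpha = 1e-10)
  ols <- lm.fit(cbind(1, X), ifelse(y > 0, 1, -1))$coefficients
  expect_lt(max(abs(fit$w - ols[-1])), 1e-6)
  expect_lt(abs(fit$b - ols[1]), 1e-6)
})

test_that("BLDA recovers generating weights from noisy regression data", {
  set.seed(5)
  n <- 500; d <- 20
  w_true <- rnorm(d)
  X <- matrix(rnorm(n * d), n, d)
  y <- as.numeric(X %*% w_true + rnorm(n, sd = 0.5))
  fit <- fit_blda(X, y)
  expect_gte(cor(fit$w, w_true), 0.99)
  expect_true(fit$details$converged)
})

test_that("BLDA evidence is non-decreasing across update iterations", {
  set.seed(6)
  X <- matrix(rnorm(200 * 40), 200, 40)
  y <- rbinom(200, 1, 1 / 9)
  fit <- fit_blda(X, y)
  expect_true(all(diff(fit$details$evidence) > -1e-6))
  # non-convergence is flagged loudly, not silently
  expect_warning(fit_blda(X, y, tol = 0, max_iter = 3), "did not converge")
})

test_that("SWLDA finds the single informative feature first", {
  set.seed(7)
  n <- 120
  X <- matrix(rnorm(n * 10), n, 10)
  y <- rbinom(n, 1, 0.5)
  X[, 3] <- ifelse(y > 0, 1, -1) + rnorm(n, sd = 0.3)
  fit <- fit_swlda(X, y)
  expect_equal(fit$details$selected[1], 3L)
  expect_gt(abs(fit$w[3]), 0)
})

test_that("SWLDA honors the entry threshold and the step cap", {
  set.seed(8)
  X <- matrix(rnorm(80 * 30), 80, 30)
  y <- rbinom(80, 1, 0.5)
  empty <- fit_swlda(X, y, p_enter = 0)
  expect_equal(length(empty$details$selected), 0L)
  expect_equal(sd(score_epochs(structure(empty, class = class(empty)),
                               wrap_epochs(array(rnorm(5 * 6 * 5), c(5, 6, 5)),
                                           c(1, 0, 0, 1, 0)))), 0)
  # generous thresholds on pure noise: the step cap still bounds the model
  greedy <- fit_swlda(X, y, p_enter = 0.95, p_remove = 0.99, max_steps = 60)
  expect_lte(length(greedy$details$selected), 60L)
  expect_lte(greedy$details$steps, 60L)
  expect_error(fit_swlda(X, y, max_steps = 0), "max_steps")
})

test_that("linear SVM attains zero hinge loss on large-margin data", {
  set.seed(9)
  X <- rbind(matrix(rnorm(60, -4), 30, 2), matrix(rnorm(60, 4), 30, 2))
  y <- rep(c(0, 1), each = 30)
  fit <- fit_svm_linear(X, y)
  s <- as.numeric(X %*% fit$w + fit$b)
  expect_equal(as.integer(s > 0), y)
  yy <- ifelse(y > 0, 1, -1)
  expect_lt(sum(pmax(0, 1 - yy * s)), 1e-6)
})

test_that("SVM weight norm vanishes as C -> 0", {
  set.seed(10)
  X <- matrix(rnorm(80), 40, 2)
  y <- rep(c(0, 1), 20)
  n1 <- sqrt(sum(fit_svm_linear(X, y, C = 1)$w^2))
  n2 <- sqrt(sum(fit_svm_linear(X, y, C = 1e-4)$w^2))
  expect_lt(n2, 0.01 * max(n1, 1))
})

test_that("SVM decision values agree with a generic QP solution", {
  set.seed(11)
  n <- 20
  X <- cbind(rnorm(n), rnorm(n))
  y <- as.integer(X[, 1] + 0.5 * X[, 2] + rnorm(n, sd = 0.6) > 0)
  fit <- fit_svm_linear(X, y, C = 1, tol = 1e-8, max_passes = 50000)
  # oracle: the identical bias-augmented dual solved by quadprog
  yy <- ifelse(y > 0, 1, -1)
  Xa <- cbind(X, 1)
  Q <- (Xa %*% t(Xa)) * (yy %o% yy)
  sol <- quadprog::solve.QP(Q + diag(1e-9, n), rep(1, n),
                            cbind(diag(n), -diag(n)),
                            c(rep(0, n), rep(-1, n)))
  w_or <- colSums(sol$solution * yy * Xa)
  expect_lt(max(abs((X %*% fit$w + fit$b) - (X %*% w_or[1:2] + w_or[3]))),
            1e-4)
})

test_that("fit_baseline standardizes features and scores epoch sets", {
  ep <- toy_epochs(n_trials = 20, seed = 12)
  for (m in c("lda", "blda", "svm")) {
    sc <- fit_baseline(m, ep)
    expect_s3_class(sc, "p300_scorer")
    s <- score_epochs(sc, ep)
    expect_length(s, dim(ep$tensor)[1])
    expect_gt(auc_binary(s, ep$labels), 0.9)
  }
  sc <- fit_baseline("swlda", ep)
  expect_lte(sum(sc$w != 0), 60)
  expect_error(score_epochs(sc, small_epochs()), "does not match")
})
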