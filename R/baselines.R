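## Classical linear baselines on flattened epoch features.
## All fitters return a `linear_scorer`: score(x) = w . x + b, higher = more
## target-like, with method tag and fitted hyper-parameters attached.

new_linear_scorer <- function(w, b, method, details = list()) {
  structure(list(w = as.numeric(w), b = as.numeric(b), method = method,
                 details = details),
            class = c("linear_scorer", "p300_scorer"))
}

#' @export
print.linear_scorer <- function(x, ...) {
  cat(sprintf("<linear_scorer> %s, %d feature(s), %d active weight(s)\n",
              x$method, length(x$w), sum(x$w != 0)))
  invisible(x)
}

# Code labels as +1 (target) / -1 (non-target); accepts 0/1 or -1/+1.
code_pm1 <- function(y) {
  yy <- ifelse(as.numeric(y) > 0, 1, -1)
  if (length(unique(yy)) < 2)
    stop("both classes (target and non-target) must be present")
  yy
}

check_xy <- function(X, y) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  X
}

#' Fisher linear discriminant with analytic shrinkage
#'
#' Computes the Fisher direction `w = S^-1 (mu1 - mu0)` with the pooled
#' within-class covariance shrunk toward a scaled identity,
#' `S* = (1 - rho) S + rho m I` (Ledoit-Wolf-style intensity estimated from
#' the data). With many more features than samples this is both the
#' regularization and what makes `S*` invertible; the inverse is applied via
#' the Woodbury identity so only an n x n system is ever solved. The score is
#' the projection `w . x + b` with `b` placing the class-mean midpoint at 0.
#'
#' @param X Numeric matrix, samples x features.
#' @param y Binary labels (1/TRUE = target).
#' @param shrinkage `"auto"` for the analytic estimate or a fixed value in
#'   `[0, 1]`.
#' @return A `linear_scorer` (method `"lda"`).
#' @export
fit_lda <- function(X, y, shrinkage = "auto") {
  X <- check_xy(X, y)
  yy <- code_pm1(y)
  n <- nrow(X); d <- ncol(X)
  if (n < 3) stop("need at least 3 samples")
  mu1 <- colMeans(X[yy == 1, , drop = FALSE])
  mu0 <- colMeans(X[yy == -1, , drop = FALSE])
  Xc <- X
  Xc[yy == 1, ] <- sweep(X[yy == 1, , drop = FALSE], 2, mu1)
  Xc[yy == -1, ] <- sweep(X[yy == -1, , drop = FALSE], 2, mu0)
  nu <- n - 2
  G <- tcrossprod(Xc)                       # n x n Gram of centered rows
  trS <- sum(diag(G)) / nu
  m <- trS / d
  S_f2 <- sum(G^2) / nu^2                   # ||S||_F^2
  d2 <- S_f2 / d - m^2
  if (identical(shrinkage, "auto")) {
    if (d2 <= .Machine$double.eps) {
      rho <- 1
    } else {
      xi4 <- diag(G)^2
      xSx <- rowSums(G^2) / nu
      b2 <- sum(xi4 - 2 * xSx + S_f2) / (n^2 * d)
      rho <- min(1, max(0, b2 / d2))
    }
  } else {
    rho <- as.numeric(shrinkage)
    if (rho < 0 || rho > 1) stop("shrinkage must lie in [0, 1]")
  }
  alpha <- max(rho * m, 1e-10 * max(m, 1))  # keep S* invertible
  cc <- (1 - rho) / nu
  delta <- mu1 - mu0
  if (cc > 0) {
    A <- cc * G
    diag(A) <- diag(A) + alpha
    w <- (delta - cc * crossprod(Xc, solve(A, Xc %*% delta))) / alpha
  } else {
    w <- delta / alpha
  }
  b <- -sum(w * (mu1 + mu0)) / 2
  new_linear_scorer(w, b, "lda", list(shrinkage = rho, alpha = alpha))
}

#' Bayesian linear discriminant analysis
#'
#' Bayesian linear regression of the +1/-1 coded labels with a zero-mean
#' isotropic Gaussian prior on the weights (precision `alpha`; the bias is
#' absorbed by centering and carries no prior) and Gaussian noise (precision
#' `beta`). Both precisions are updated by MacKay evidence maximization until
#' the relative change falls below `tol` or `max_iter` is reached; a
#' non-converged fit is returned with `details$converged = FALSE` and a
#' warning. The heavy lifting runs in the sample space via a thin SVD, so the
#' cost is governed by `min(n, d)`.
#'
#' @param X Numeric matrix, samples x features.
#' @param y Binary labels (1/TRUE = target).
#' @param tol Relative-change convergence tolerance for (alpha, beta).
#' @param max_iter Maximum evidence-maximization iterations.
#' @param alpha,beta Optional fixed values; `NULL` (default) = learn.
#' @return A `linear_scorer` (method `"blda"`); `details` holds `alpha`,
#'   `beta`, the log-evidence trace, and `converged`.
#' @export
fit_blda <- function(X, y, tol = 1e-4, max_iter = 100, alpha = NULL, beta = NULL) {
  X <- check_xy(X, y)
  # binary labels are coded +1/-1; any other numeric target is taken as the
  # regression response directly (the model is ridge-style regression either way)
  yy <- if (length(unique(y)) == 2) code_pm1(y) else as.numeric(y)
  n <- nrow(X); d <- ncol(X)
  xbar <- colMeans(X); ybar <- mean(yy)
  Xc <- sweep(X, 2, xbar); yc <- yy - ybar
  sv <- svd(Xc, nu = min(n, d), nv = min(n, d))
  keep <- sv$d > max(sv$d) * 1e-12
  U <- sv$u[, keep, drop = FALSE]; V <- sv$v[, keep, drop = FALSE]
  s <- sv$d[keep]; lam <- s^2
  uty <- as.numeric(crossprod(U, yc))
  y2 <- sum(yc^2)
  out_of_span <- max(y2 - sum(uty^2), 0)

  a <- if (is.null(alpha)) 1 else alpha
  bb <- if (is.null(beta)) 1 / max(stats::var(yc), 1e-12) else beta
  evidence <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    mt <- bb * s * uty / (bb * lam + a)      # coefficients in the V basis
    m2 <- sum(mt^2)
    r2 <- sum((uty - s * mt)^2) + out_of_span
    gamma <- sum(bb * lam / (bb * lam + a))
    logdetA <- sum(log(a + bb * lam)) + (d - length(lam)) * log(a)
    evidence <- c(evidence, 0.5 * (d * log(a) + n * log(bb) - bb * r2 -
                                     a * m2 - logdetA - n * log(2 * pi)))
    a_new <- if (is.null(alpha)) gamma / max(m2, 1e-300) else a
    b_new <- if (is.null(beta)) (n - gamma) / max(r2, 1e-300) else bb
    if (abs(a_new - a) <= tol * abs(a) && abs(b_new - bb) <= tol * abs(bb)) {
      a <- a_new; bb <- b_new
      converged <- TRUE
      break
    }
    a <- a_new; bb <- b_new
  }
  if (!converged && (is.null(alpha) || is.null(beta)))
    warning("BLDA evidence maximization did not converge within ",
            max_iter, " iterations")
  mt <- bb * s * uty / (bb * lam + a)
  w <- as.numeric(V %*% mt)
  b0 <- ybar - sum(w * xbar)
  new_linear_scorer(w, b0, "blda",
                    list(alpha = a, beta = bb, iterations = length(evidence),
                         converged = converged, evidence = evidence))
}

#' Stepwise linear discriminant analysis
#'
#' Forward-backward stepwise ordinary-least-squares regression on the +1/-1
#' coded labels. Each forward step adds the candidate feature with the
#' smallest partial-F p-value if it is below `p_enter` (ties broken by lowest
#' feature index); each backward sweep removes any included feature whose
#' coefficient p-value exceeds `p_remove`. Every addition or removal counts
#' as one step, capped at `max_steps`, so at most `max_steps` features are
#' ever active. The score is the fitted linear predictor on the selected
#' features (a constant when nothing enters).
#'
#' @param X Numeric matrix, samples x features.
#' @param y Binary labels (1/TRUE = target).
#' @param p_enter Largest p-value at which a predictor may enter (default 0.1).
#' @param p_remove Smallest p-value at which a predictor is removed
#'   (default 0.15).
#' @param max_steps Step cap (default 60).
#' @return A `linear_scorer` (method `"swlda"`); `details$selected` lists the
#'   active feature indices in order of entry.
#' @export
fit_swlda <- function(X, y, p_enter = 0.1, p_remove = 0.15, max_steps = 60) {
  X <- check_xy(X, y)
  yy <- code_pm1(y)
  if (max_steps < 1) stop("max_steps must be >= 1")
  n <- nrow(X); d <- ncol(X)
  xbar <- colMeans(X); ybar <- mean(yy)
  Xc <- sweep(X, 2, xbar); yc <- yy - ybar
  xnorm2 <- colSums(Xc^2)

  active <- integer(0)
  Q <- matrix(0, n, 0)
  QtX <- matrix(0, 0, d)
  r <- yc
  steps <- 0L

  rebuild <- function() {
    # re-orthogonalize after a removal
    qrd <- qr(Xc[, active, drop = FALSE])
    Q <<- qr.Q(qrd)[, seq_along(active), drop = FALSE]
    QtX <<- crossprod(Q, Xc)
    r <<- yc - Q %*% crossprod(Q, yc)
  }

  backward_pvals <- function() {
    Xa <- Xc[, active, drop = FALSE]
    qrd <- qr(Xa)
    beta <- qr.coef(qrd, yc)
    res <- yc - Xa %*% beta
    df <- n - length(active) - 1
    if (df < 1) return(rep(0, length(active)))
    s2 <- sum(res^2) / df
    XtXinv_diag <- diag(chol2inv(qr.R(qrd)))
    tt <- beta / sqrt(s2 * XtXinv_diag)
    2 * stats::pt(-abs(tt), df)
  }

  repeat {
    if (steps >= max_steps) break
    p <- length(active)
    nu <- n - p - 2
    if (nu < 1) break
    cand <- setdiff(seq_len(d), active)
    if (length(cand) == 0) break
    perp2 <- xnorm2[cand]
    if (p > 0) perp2 <- perp2 - colSums(QtX[, cand, drop = FALSE]^2)
    rx <- as.numeric(crossprod(Xc[, cand, drop = FALSE], r))
    RSS <- sum(r^2)
    ok <- perp2 > 1e-10 * pmax(xnorm2[cand], 1e-300)
    dRSS <- ifelse(ok, rx^2 / perp2, 0)
    dRSS <- pmin(dRSS, RSS)
    Fstat <- ifelse(ok & (RSS - dRSS) > 0, dRSS / ((RSS - dRSS) / nu), 0)
    Fstat[ok & (RSS - dRSS) <= 0] <- Inf
    pvals <- stats::pf(Fstat, 1, nu, lower.tail = FALSE)
    pvals[!ok] <- 1
    j <- cand[which.min(pvals)]
    if (min(pvals) >= p_enter) break
    q <- Xc[, j]
    if (p > 0) q <- q - Q %*% crossprod(Q, q)
    q <- q / sqrt(sum(q^2))
    Q <- cbind(Q, q)
    QtX <- rbind(QtX, as.numeric(crossprod(q, Xc)))
    r <- r - q * sum(q * r)
    active <- c(active, j)
    steps <- steps + 1L

    # backward sweep
    repeat {
      if (steps >= max_steps || length(active) < 2) break
      pv <- backward_pvals()
      worst <- which.max(pv)
      if (pv[worst] <= p_remove) break
      active <- active[-worst]
      steps <- steps + 1L
      rebuild()
    }
  }

  w <- numeric(d)
  b0 <- ybar
  if (length(active)) {
    Xa <- Xc[, active, drop = FALSE]
    beta <- qr.coef(qr(Xa), yc)
    w[active] <- beta
    b0 <- ybar - sum(xbar[active] * beta)
  }
  new_linear_scorer(w, b0, "swlda",
                    list(selected = active, steps = steps,
                         p_enter = p_enter, p_remove = p_remove,
                         max_steps = max_steps))
}

#' Linear support vector machine (L1 hinge, dual coordinate descent)
#'
#' Soft-margin linear SVM with `C = 1` by default, solved by dual coordinate
#' descent in the liblinear formulation: the bias enters as an augmented
#' constant feature (and is therefore weakly regularized with the weights).
#' The score is the decision value `w . x + b`.
#'
#' @param X Numeric matrix, samples x features.
#' @param y Binary labels (1/TRUE = target).
#' @param C Soft-margin cost (> 0).
#' @param tol Stopping tolerance on the largest projected gradient.
#' @param max_passes Maximum sweeps over the data.
#' @return A `linear_scorer` (method `"svm"`); `details` holds `C`, the dual
#'   variables, and the pass count.
#' @export
fit_svm_linear <- function(X, y, C = 1, tol = 1e-4, max_passes = 500) {
  X <- check_xy(X, y)
  yy <- code_pm1(y)
  if (C <= 0) stop("C must be > 0")
  n <- nrow(X); d <- ncol(X)
  Xa <- cbind(X, 1)
  Qii <- rowSums(Xa^2)
  alpha <- numeric(n)
  w <- numeric(d + 1)
  passes <- 0L
  repeat {
    passes <- passes + 1L
    max_pg <- 0
    for (i in seq_len(n)) {
      G <- yy[i] * sum(w * Xa[i, ]) - 1
      pg <- if (alpha[i] <= 0) min(G, 0)
            else if (alpha[i] >= C) max(G, 0)
            else G
      if (abs(pg) > max_pg) max_pg <- abs(pg)
      if (abs(pg) > 1e-14) {
        a_new <- min(max(alpha[i] - G / Qii[i], 0), C)
        if (a_new != alpha[i]) {
          w <- w + (a_new - alpha[i]) * yy[i] * Xa[i, ]
          alpha[i] <- a_new
        }
      }
    }
    if (max_pg < tol || passes >= max_passes) break
  }
  new_linear_scorer(w[seq_len(d)], w[d + 1], "svm",
                    list(C = C, alpha = alpha, passes = passes,
                         converged = passes < max_passes))
}

#' Fit a classical baseline on an epoch set
#'
#' Flattens the epochs to `time x channels` feature vectors, z-scores every
#' feature on the training data (the standardization is stored in the scorer
#' and re-applied at scoring time), and fits the requested baseline.
#'
#' @param method One of `"lda"`, `"blda"`, `"swlda"`, `"svm"`.
#' @param epochs An `epoch_set`.
#' @param ... Passed to the underlying fitter.
#' @return A `linear_scorer` with embedded feature standardization.
#' @export
fit_baseline <- function(method = c("lda", "blda", "swlda", "svm"), epochs, ...) {
  method <- match.arg(method)
  stopifnot(inherits(epochs, "epoch_set"))
  X <- flatten_epochs(epochs)
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[scale < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale, `/`)
  fit <- switch(method,
    lda = fit_lda(Xs, epochs$labels, ...),
    blda = fit_blda(Xs, epochs$labels, ...),
    swlda = fit_swlda(Xs, epochs$labels, ...),
    svm = fit_svm_linear(Xs, epochs$labels, ...))
  fit$center <- center
  fit$scale <- scale
  fit$input_dim <- dim(epochs$tensor)[2:3]
  fit
}

#' @export
score_epochs.linear_scorer <- function(scorer, epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  X <- flatten_epochs(epochs)
  if (ncol(X) != length(scorer$w))
    stop("epoch feature dimension ", ncol(X),
         " does not match the scorer (", length(scorer$w), ")")
  if (!is.null(scorer$center))
    X <- sweep(sweep(X, 2, scorer$center), 2, scorer$scale, `/`)
  as.numeric(X %*% scorer$w + scorer$b)
}
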