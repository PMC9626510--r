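#' Computational cost of separable vs standard 1D convolution
#'
#' Evaluates the closed-form single-layer cost expressions for an input of
#' length `H1`, kernel size `h` and `n` output feature maps (unit stride, no
#' padding, so the valid output length is `H1 - h + 1`):
#' \deqn{C_{sep} = h (H_1 - h + 1) + n (H_1 - h + 1)}
#' \deqn{C = n h (H_1 - h + 1)}
#' whose ratio is exactly \eqn{C_{sep}/C = 1/n + 1/h}.
#'
#' @param H1 Input length, `H1 > h`.
#' @param h Kernel size, `>= 1`.
#' @param n Number of pointwise kernels / output channels, `>= 1`.
#' @return List of class `cost_params` with `H1`, `h`, `n`, `C_sep`, `C`,
#'   `ratio`.
#' @examples
#' separable_cost(200, 10, 4)  # C_sep 2674, C 7640, ratio 0.35
#' @export
separable_cost <- function(H1, h, n) {
  if (h < 1 || n < 1) stop("h and n must be >= 1")
  if (h >= H1) stop("kernel size h must be smaller than input length H1")
  L <- H1 - h + 1
  structure(list(H1 = H1, h = h, n = n,
                 C_sep = h * L + n * L,
                 C = n * h * L,
                 ratio = 1 / n + 1 / h),
            class = "cost_params")
}

#' @export
print.cost_params <- function(x, ...) {
  cat(sprintf("<cost_params> H1=%g h=%g n=%g: C_sep=%g C=%g ratio=%g\n",
              x$H1, x$h, x$n, x$C_sep, x$C, x$ratio))
  invisible(x)
}
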