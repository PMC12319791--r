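#' Single-gamma hemodynamic response kernel
#'
#' Builds a hemodynamic response function as a single gamma density sampled
#' on the TR grid, without the post-stimulus undershoot of canonical
#' double-gamma models: continuous emotion ratings evolve slowly relative to
#' the BOLD response, so the undershoot adds nothing but ringing. Samples are
#' renormalized to unit sum so that convolution preserves the DC level of the
#' ratings and fitted weights stay in rating units.
#'
#' @param tr Sampling interval in seconds.
#' @param shape Gamma shape parameter (> 1 so the density has an interior
#'   peak at `(shape - 1) * scale` seconds).
#' @param scale Gamma scale parameter in seconds.
#' @param length_s Kernel support in seconds; samples run at
#'   `t = 0, tr, 2 tr, ...` up to and including `length_s`.
#' @return An object of class `hrf_kernel` with elements `samples` (unit-sum,
#'   non-negative), `times`, and the parameters used.
#' @export
#' @examples
#' k <- hrf_kernel(tr = 2.4)
#' sum(k$samples)            # 1
#' (k$shape - 1) * k$scale   # peak latency of the continuous density, 5 s
hrf_kernel <- function(tr, shape = 6, scale = 1, length_s = 30) {
  if (shape <= 1)
    stop("shape must exceed 1 for a gamma HRF with an interior peak",
         call. = FALSE)
  if (scale <= 0 || tr <= 0 || length_s <= 0)
    stop("tr, scale and length_s must be positive", call. = FALSE)
  times <- seq(0, length_s, by = tr)
  samples <- stats::dgamma(times, shape = shape, scale = scale)
  s <- sum(samples)
  if (s <= 0)
    stop("degenerate kernel: all samples zero on this grid", call. = FALSE)
  structure(list(samples = samples / s, times = times, tr = tr,
                 shape = shape, scale = scale, length_s = length_s,
                 normalization = "unit-sum"),
            class = "hrf_kernel")
}

#' @export
print.hrf_kernel <- function(x, ...) {
  cat(sprintf("Gamma HRF: shape %.3g, scale %.3g s, %d taps at TR %.3g s (peak %.3g s)\n",
              x$shape, x$scale, length(x$samples), x$tr,
              (x$shape - 1) * x$scale))
  invisible(x)
}
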