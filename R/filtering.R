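#' Convert ROI time series to percent signal change
#'
#' @param series Time-by-ROI numeric matrix (or vector).
#' @return Matrix of `100 * (y - mean(y)) / mean(y)` per ROI.
#' @export
percent_signal_change <- function(series) {
  m <- as.matrix(series)
  mu <- colMeans(m)
  zero <- which(mu == 0)
  if (length(zero))
    stop("zero temporal mean in ROI(s): ",
         paste(colnames(m)[zero] %||% zero, collapse = ", "), call. = FALSE)
  sweep(sweep(m, 2, mu, "-"), 2, mu, "/") * 100
}

#' Regress nuisance signals out of ROI time series
#'
#' Projects each ROI series onto the orthogonal complement of the confound
#' space spanned by the white-matter and CSF signals, the six motion
#' parameters, the squared motion parameters (second-order effects), a
#' linear trend and an intercept.
#'
#' @param series Time-by-ROI numeric matrix.
#' @param confounds Time-by-confound matrix with columns `wm`, `csf`,
#'   `motion1`..`motion6`.
#' @return Residual time-by-ROI matrix.
#' @export
nuisance_regress <- function(series, confounds) {
  y <- as.matrix(series)
  conf <- as.matrix(confounds)
  needed <- c("wm", "csf", paste0("motion", 1:6))
  missing_cols <- setdiff(needed, colnames(conf))
  if (length(missing_cols))
    stop("confound matrix lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(y) != nrow(conf))
    stop("series and confounds differ in length", call. = FALSE)
  motion <- conf[, paste0("motion", 1:6), drop = FALSE]
  X <- cbind(conf[, c("wm", "csf"), drop = FALSE],
             motion,
             motion^2,
             trend = seq_len(nrow(y)),
             intercept = 1)
  colnames(X)[9:14] <- paste0("motion", 1:6, "_sq")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("confound design is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  resid <- qr.resid(qrX, y)
  dimnames(resid) <- dimnames(y)
  resid
}

#' Design the equiripple FIR bandpass filter for slow BOLD fluctuations
#'
#' Parks-McClellan (Remez exchange) linear-phase FIR bandpass matched to the
#' frequency content of slowly evolving emotion episodes: passband
#' 0.005-0.05 Hz (periods of 200 down to 20 s), with at most 1 dB ripple in
#' the passband and at least 40 dB attenuation in the upper stopband, which
#' begins at 0.0613 Hz. The DC side of a bandpass this close to 0 Hz cannot
#' reach 40 dB at realistic orders, so only >= 20 dB rejection at 0 Hz is
#' required there. The order is increased iteratively until the measured
#' magnitude response on a dense frequency grid satisfies all three bounds.
#'
#' @param sampling_rate_hz Sampling rate (1/TR); default `1/2.4`.
#' @param passband_hz Passband edges in Hz.
#' @param lower_transition_hz Lower stopband edge (start of the lower
#'   transition band) in Hz.
#' @param upper_stopband_hz Upper stopband edge in Hz.
#' @param passband_ripple_db Maximum passband ripple bound in dB.
#' @param stopband_atten_db Minimum upper-stopband attenuation bound in dB.
#' @param dc_atten_db Minimum attenuation bound at and near 0 Hz in dB.
#' @param max_order Hard cap on the filter order.
#' @param n_grid Number of frequency-grid points used to verify the bounds
#'   (at least 4096).
#' @return An object of class `filter_spec` with the coefficients, the
#'   measured single-pass response, and the achieved ripple/attenuation.
#' @export
design_bandpass <- function(sampling_rate_hz = 1 / 2.4,
                            passband_hz = c(0.005, 0.05),
                            lower_transition_hz = 0.001,
                            upper_stopband_hz = 0.0613,
                            passband_ripple_db = 1,
                            stopband_atten_db = 40,
                            dc_atten_db = 20,
                            max_order = 300L,
                            n_grid = 4096L) {
  nyquist <- sampling_rate_hz / 2
  edges <- c(0, lower_transition_hz, passband_hz, upper_stopband_hz, nyquist)
  if (is.unsorted(edges, strictly = TRUE) || upper_stopband_hz >= nyquist)
    stop("band edges must be strictly increasing and below Nyquist",
         call. = FALSE)
  if (n_grid < 4096L) stop("n_grid must be at least 4096", call. = FALSE)
  f_norm <- edges / nyquist
  amps <- c(0, 0, 1, 1, 0, 0)
  # band weights inversely proportional to the allowed ripple per band
  delta_pass <- 1 - 10^(-passband_ripple_db / 20)
  delta_stop <- 10^(-stopband_atten_db / 20)
  delta_dc <- 10^(-dc_atten_db / 20)
  w <- c(delta_pass / delta_dc, 1, delta_pass / delta_stop)

  freqs <- seq(0, nyquist, length.out = n_grid)
  best <- NULL
  for (ord in seq(40L, max_order, by = 10L)) {
    h <- tryCatch(signal::remez(ord, f_norm, amps, w = w, ftype = "bandpass"),
                  error = function(e) NULL)
    if (is.null(h) || any(!is.finite(h))) next
    resp <- fir_response(h, freqs, sampling_rate_hz)
    meas <- measure_response(freqs, resp, passband_hz, upper_stopband_hz,
                             lower_transition_hz)
    best <- meas
    if (meas$passband_ripple_db <= passband_ripple_db &&
        meas$stopband_atten_db >= stopband_atten_db &&
        meas$dc_atten_db >= dc_atten_db) {
      return(structure(list(
        coefficients = as.numeric(h), order = ord,
        sampling_rate_hz = sampling_rate_hz, passband_hz = passband_hz,
        lower_transition_hz = lower_transition_hz,
        upper_stopband_hz = upper_stopband_hz,
        passband_ripple_db = meas$passband_ripple_db,
        stopband_atten_db = meas$stopband_atten_db,
        dc_atten_db = meas$dc_atten_db,
        freqs = freqs, magnitude = resp),
        class = "filter_spec"))
    }
  }
  stop(sprintf(paste0(
    "bandpass specification unattainable up to order %d ",
    "(achieved: ripple %.2f dB, stopband %.1f dB, DC %.1f dB)"),
    max_order, best$passband_ripple_db, best$stopband_atten_db,
    best$dc_atten_db), call. = FALSE)
}

# magnitude of the FIR frequency response at the given frequencies (Hz)
fir_response <- function(h, freqs, fs) {
  k <- seq_along(h) - 1L
  E <- exp(-2i * pi * outer(freqs / fs, k))
  abs(as.vector(E %*% h))
}

measure_response <- function(freqs, mag, passband_hz, upper_stopband_hz,
                             lower_transition_hz) {
  db <- 20 * log10(pmax(mag, .Machine$double.xmin))
  pb <- freqs >= passband_hz[1] & freqs <= passband_hz[2]
  sb <- freqs >= upper_stopband_hz
  dc <- freqs <= lower_transition_hz
  list(passband_ripple_db = max(abs(db[pb])),
       stopband_atten_db = -max(db[sb]),
       dc_atten_db = -max(db[dc]))
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf(paste0(
    "Equiripple FIR bandpass: order %d (%d taps), fs %.4f Hz\n",
    "  passband %.3g-%.3g Hz: ripple %.3f dB\n",
    "  upper stopband >= %.4g Hz: attenuation %.1f dB\n",
    "  DC side: attenuation %.1f dB\n"),
    x$order, length(x$coefficients), x$sampling_rate_hz,
    x$passband_hz[1], x$passband_hz[2], x$passband_ripple_db,
    x$upper_stopband_hz, x$stopband_atten_db, x$dc_atten_db))
  invisible(x)
}

#' Apply the bandpass filter with zero phase
#'
#' Forward-backward application of the linear-phase FIR filter, so the net
#' phase is exactly zero and regressors stay temporally aligned with the
#' filtered BOLD; effective attenuation is twice the single-pass design
#' (bounds are always verified on the single-pass response). Each pass uses
#' the centered ("same") convolution, which for a symmetric kernel already
#' compensates the group delay; output length equals input length. Samples
#' within half a kernel length of either edge mix with zero padding and are
#' flagged in the `edge_samples` attribute.
#'
#' @param series Time-by-ROI matrix or vector.
#' @param spec A `filter_spec` from [design_bandpass()].
#' @param passes Number of filtering passes (2 = forward-backward, default).
#' @return Filtered matrix of the same shape, with attribute `edge_samples`.
#' @export
apply_bandpass <- function(series, spec, passes = 2L) {
  stopifnot(inherits(spec, "filter_spec"))
  y <- as.matrix(series)
  h <- spec$coefficients
  if (nrow(y) <= length(h))
    stop(sprintf("series length (%d) must exceed the filter length (%d)",
                 nrow(y), length(h)), call. = FALSE)
  if (spec$order > nrow(y) / 3)
    stop("filter order exceeds one third of the series length; ",
         "output would be edge-dominated", call. = FALSE)
  out <- y
  for (i in seq_len(passes))
    out <- apply(out, 2, fir_same, h = h)
  dimnames(out) <- dimnames(y)
  half <- (length(h) - 1L) %/% 2L
  n <- nrow(y)
  attr(out, "edge_samples") <- c(seq_len(half), seq(n - half + 1L, n))
  out
}

# centered convolution: zero-phase single pass for a symmetric kernel
fir_same <- function(x, h) {
  n <- length(x)
  full <- stats::convolve(x, rev(h), type = "open")
  delay <- (length(h) - 1L) %/% 2L
  full[delay + seq_len(n)]
}

#' Condition a ROI dataset for model fitting
#'
#' Runs the fixed conditioning chain on every participant and run: percent
#' signal change, nuisance regression, then zero-phase bandpass filtering.
#'
#' @param dataset A `roi_dataset`.
#' @param spec A `filter_spec`; built from defaults when `NULL`.
#' @param psc Convert to percent signal change first (disable for synthetic
#'   series that are already zero-mean fluctuations).
#' @param bandpass Apply the FIR bandpass (requires runs at least three
#'   filter orders long).
#' @return The dataset with conditioned `signals`.
#' @export
condition_dataset <- function(dataset, spec = NULL, psc = TRUE,
                              bandpass = TRUE) {
  stopifnot(inherits(dataset, "roi_dataset"))
  if (bandpass && is.null(spec)) spec <- design_bandpass()
  for (p in seq_along(dataset$signals)) {
    for (r in seq_along(dataset$signals[[p]])) {
      y <- dataset$signals[[p]][[r]]
      if (psc) y <- percent_signal_change(y)
      y <- nuisance_regress(y, dataset$confounds[[p]][[r]])
      if (bandpass) y <- apply_bandpass(y, spec)
      dataset$signals[[p]][[r]] <- y
    }
  }
  dataset$conditioned <- TRUE
  dataset$filter <- spec
  dataset
}

#' Apply the bandpass filter to emotion design matrices
#'
#' Filtering the regressors with the same filter as the BOLD keeps both
#' sides of the model in the same frequency band: clip-scale rating energy
#' below the passband edge would otherwise remain in the design while the
#' filtered BOLD no longer carries it, biasing the fit.
#'
#' @param designs List of `emotion_design`s (one per run).
#' @param spec A `filter_spec`.
#' @return The designs with filtered matrices.
#' @export
filter_designs <- function(designs, spec) {
  lapply(designs, function(d) {
    d$matrix <- apply_bandpass(d$matrix, spec)
    d
  })
}
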