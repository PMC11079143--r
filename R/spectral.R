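#' Welch estimation parameters
#'
#' Defaults follow the benchmark convention used throughout the package:
#' 2-s Hann segments with 50% overlap, spectra reported on 1-50 Hz.
#'
#' @param window_s Segment length in seconds.
#' @param overlap_frac Overlap fraction in `[0, 1)`.
#' @param fmin,fmax Frequency range of the reported grid (Hz).
#' @param window_fn Taper name; `"hann"` (default) or `"rect"`.
#' @return Object of class `welch_params`.
#' @export
welch_params <- function(window_s = 2, overlap_frac = 0.5, fmin = 1,
                         fmax = 50, window_fn = "hann") {
  if (overlap_frac < 0 || overlap_frac >= 1)
    stop("overlap_frac must be in [0, 1)", call. = FALSE)
  if (fmin >= fmax) stop("fmin must be < fmax", call. = FALSE)
  structure(list(window_s = window_s, overlap_frac = overlap_frac,
                 fmin = fmin, fmax = fmax, window_fn = window_fn),
            class = "welch_params")
}

#' Default EEG band scheme
#'
#' delta 1-4, theta 4-8, alpha 8-13, beta 13-30, gamma 30-50 Hz. Bands are
#' half-open `[low, high)` so shared edges are counted once; together they
#' tile `[1, 50)`, matching the analysis bandpass.
#'
#' @param bands Named list of `c(low, high)` pairs (Hz).
#' @return Object of class `band_scheme`.
#' @export
band_scheme <- function(bands = list(delta = c(1, 4), theta = c(4, 8),
                                     alpha = c(8, 13), beta = c(13, 30),
                                     gamma = c(30, 50))) {
  for (b in bands)
    if (length(b) != 2L || b[1] >= b[2])
      stop("each band must be c(low, high) with low < high", call. = FALSE)
  structure(list(bands = bands), class = "band_scheme")
}

taper_window <- function(n, window_fn) {
  switch(window_fn,
         hann = 0.5 * (1 - cos(2 * pi * seq(0, n - 1) / n)),
         rect = rep(1, n),
         stop("unknown window_fn: ", window_fn, call. = FALSE))
}

# Segment matrix of windowed FFTs: returns list(freqs, ffts [nfreq x nseg],
# scale) on the one-sided grid. Shared engine for PSD and cross-spectra.
welch_fft_segments <- function(x, fs, params) {
  x <- as.numeric(x)
  nper <- round(params$window_s * fs)
  if (nper < 2) stop("Welch window shorter than 2 samples", call. = FALSE)
  step <- max(1L, round(nper * (1 - params$overlap_frac)))
  n <- length(x)
  nseg <- if (n >= nper) ((n - nper) %/% step) + 1L else 0L
  if (nseg < 1L)
    stop("signal too short for a single Welch segment", call. = FALSE)
  win <- taper_window(nper, params$window_fn)
  starts <- (seq_len(nseg) - 1L) * step
  segs <- vapply(starts, function(s) x[(s + 1L):(s + nper)] * win,
                 numeric(nper))
  F <- stats::mvfft(segs)
  nfreq <- nper %/% 2L + 1L
  list(freqs = (0:(nfreq - 1L)) * fs / nper,
       ffts = F[seq_len(nfreq), , drop = FALSE],
       scale = 1 / (fs * sum(win^2)),
       nper = nper, nseg = nseg)
}

welch_auto <- function(x, fs, params) {
  w <- welch_fft_segments(x, fs, params)
  p <- rowMeans(Mod(w$ffts)^2) * w$scale
  # one-sided doubling (not DC; not Nyquist when nper even)
  dbl <- rep(2, length(p)); dbl[1] <- 1
  if (w$nper %% 2L == 0L) dbl[length(p)] <- 1
  list(freqs = w$freqs, psd = p * dbl, nseg = w$nseg)
}

restrict_grid <- function(freqs, params) {
  which(freqs >= params$fmin - 1e-12 & freqs <= params$fmax + 1e-12)
}

#' Welch power spectral density
#'
#' Standard Welch periodogram averaging with the taper, segment length and
#' overlap given in `params`; the returned grid is restricted to
#' `[fmin, fmax]`.
#'
#' @param x Numeric vector, or an [recording()] (one PSD per channel).
#' @param fs Sampling rate in Hz (taken from the recording when `x` is one).
#' @param params A [welch_params()] object.
#' @return Object of class `spectral_summary` with fields `freqs`, `values`
#'   (frequencies x channels, uV^2/Hz), `kind = "psd"` and `params`.
#' @export
welch_psd <- function(x, fs = NULL, params = welch_params()) {
  if (inherits(x, "eeg_recording")) {
    fs <- x$fs
    mats <- apply(x$data, 2L, function(col) welch_auto(col, fs, params)$psd)
    freqs <- welch_auto(x$data[, 1L], fs, params)$freqs
    keep <- restrict_grid(freqs, params)
    return(structure(list(freqs = freqs[keep],
                          values = mats[keep, , drop = FALSE],
                          kind = "psd", params = params,
                          channel_names = x$channel_names),
                     class = "spectral_summary"))
  }
  if (is.null(fs)) stop("fs required for vector input", call. = FALSE)
  wa <- welch_auto(x, fs, params)
  keep <- restrict_grid(wa$freqs, params)
  structure(list(freqs = wa$freqs[keep],
                 values = matrix(wa$psd[keep], ncol = 1L),
                 kind = "psd", params = params, channel_names = "x"),
            class = "spectral_summary")
}

#' @export
print.spectral_summary <- function(x, ...) {
  cat(sprintf("<spectral_summary> kind=%s, %d bins (%.2f-%.2f Hz) x %d channels\n",
              x$kind, length(x$freqs), min(x$freqs), max(x$freqs),
              ncol(x$values)))
  invisible(x)
}

#' Temporal relative root-mean-squared error
#'
#' `RMS(filtered - truth) / RMS(truth)`: 0 for perfect recovery, 1 when the
#' residual carries as much power as the ground truth.
#'
#' @param filtered,truth Equal-length numeric vectors (or matrices pooled
#'   over all elements).
#' @return Scalar RRMSE.
#' @export
rrmse_temporal <- function(filtered, truth) {
  filtered <- as.numeric(filtered); truth <- as.numeric(truth)
  if (length(filtered) != length(truth))
    stop("signals must have equal length", call. = FALSE)
  rt <- rms(truth)
  if (rt == 0) stop("ground truth has zero RMS", call. = FALSE)
  rms(filtered - truth) / rt
}

#' Spectral relative root-mean-squared error
#'
#' RMS difference of Welch PSDs over the `[fmin, fmax]` grid, relative to
#' the RMS of the ground-truth PSD.
#'
#' @inheritParams rrmse_temporal
#' @param fs Sampling rate (Hz).
#' @param params A [welch_params()].
#' @return Scalar spectral RRMSE.
#' @export
rrmse_spectral <- function(filtered, truth, fs, params = welch_params()) {
  pf <- welch_psd(as.numeric(filtered), fs, params)$values[, 1L]
  pt_ <- welch_psd(as.numeric(truth), fs, params)$values[, 1L]
  denom <- sqrt(mean(pt_^2))
  if (denom == 0) stop("ground-truth PSD has zero RMS", call. = FALSE)
  sqrt(mean((pf - pt_)^2)) / denom
}

#' Pearson correlation between filtered signal and ground truth
#'
#' @inheritParams rrmse_temporal
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
corr_coef <- function(filtered, truth) {
  filtered <- as.numeric(filtered); truth <- as.numeric(truth)
  if (length(filtered) != length(truth))
    stop("signals must have equal length", call. = FALSE)
  if (var(filtered) == 0 || var(truth) == 0)
    stop("correlation undefined for a constant signal", call. = FALSE)
  cor(filtered, truth)
}

#' Relative band power
#'
#' Integrates the Welch PSD over each band of the scheme (rectangle rule,
#' half-open bands) and divides by the total over all bands of the scheme,
#' so the fractions sum to one.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate (Hz).
#' @param scheme A [band_scheme()].
#' @param params A [welch_params()].
#' @return Named numeric vector of band fractions summing to 1.
#' @export
relative_band_power <- function(x, fs, scheme = band_scheme(),
                                params = welch_params()) {
  wa <- welch_auto(as.numeric(x), fs, params)
  bp <- vapply(scheme$bands, function(b) {
    sel <- wa$freqs >= b[1] - 1e-12 & wa$freqs < b[2] - 1e-12
    sum(wa$psd[sel])
  }, numeric(1))
  tot <- sum(bp)
  if (tot <= 0) stop("total band power is zero", call. = FALSE)
  bp / tot
}

#' Absolute band power
#'
#' Welch PSD integrated over one band (rectangle rule), in uV^2.
#'
#' @inheritParams relative_band_power
#' @param band `c(low, high)` in Hz, half-open.
#' @return Scalar band power.
#' @export
band_power <- function(x, fs, band, params = welch_params()) {
  wa <- welch_auto(as.numeric(x), fs, params)
  df <- wa$freqs[2] - wa$freqs[1]
  sel <- wa$freqs >= band[1] - 1e-12 & wa$freqs < band[2] - 1e-12
  sum(wa$psd[sel]) * df
}

#' Magnitude-squared coherence
#'
#' Welch estimate of `|Sxy|^2 / (Sxx Syy)` on the one-sided grid restricted
#' to `[fmin, fmax]`. At least two segments are required (single-segment
#' coherence is identically 1 and carries no information).
#'
#' @param x,y Equal-length numeric vectors.
#' @param fs Sampling rate (Hz).
#' @param params A [welch_params()].
#' @return `spectral_summary` with `kind = "coherence"`, values in `[0, 1]`.
#' @export
coherence <- function(x, y, fs, params = welch_params()) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    stop("signals must have equal length", call. = FALSE)
  wx <- welch_fft_segments(x, fs, params)
  wy <- welch_fft_segments(y, fs, params)
  if (wx$nseg < 2L)
    stop("coherence needs at least two Welch segments", call. = FALSE)
  sxx <- rowMeans(Mod(wx$ffts)^2)
  syy <- rowMeans(Mod(wy$ffts)^2)
  sxy <- rowMeans(wx$ffts * Conj(wy$ffts))
  g2 <- Mod(sxy)^2 / (sxx * syy)
  g2[!is.finite(g2)] <- 0
  g2 <- pmin(pmax(g2, 0), 1)
  keep <- restrict_grid(wx$freqs, params)
  structure(list(freqs = wx$freqs[keep],
                 values = matrix(g2[keep], ncol = 1L),
                 kind = "coherence", params = params, channel_names = "xy"),
            class = "spectral_summary")
}

#' Per-channel maximum coherence with the acceleration reference
#'
#' For every EEG channel, the maximum of the magnitude-squared coherence
#' with the head-acceleration reference over a frequency band. The movement
#' artifact of a seated body concentrates near its 3-4 Hz resonance, so the
#' conventional inspection band is 3-5 Hz.
#'
#' @param rec An [recording()].
#' @param reference An [accel_trace()] aligned with `rec`.
#' @param band `c(low, high)` Hz over which the maximum is taken; defaults
#'   to the full `params` range.
#' @param params A [welch_params()].
#' @return Named numeric vector, one value in `[0, 1]` per channel.
#' @export
max_coherence_topography <- function(rec, reference, band = NULL,
                                     params = welch_params()) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(reference, "accel_trace"))
  if (nrow(rec$data) != length(reference$data) ||
      !isTRUE(all.equal(rec$fs, reference$fs)))
    stop("recording and reference must be aligned (same fs and length)",
         call. = FALSE)
  if (is.null(band)) band <- c(params$fmin, params$fmax)
  out <- vapply(seq_len(ncol(rec$data)), function(ch) {
    co <- coherence(rec$data[, ch], reference$data, rec$fs, params)
    sel <- co$freqs >= band[1] - 1e-12 & co$freqs <= band[2] + 1e-12
    if (!any(sel)) stop("band outside the coherence grid", call. = FALSE)
    max(co$values[sel, 1L])
  }, numeric(1))
  names(out) <- rec$channel_names
  out
}
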