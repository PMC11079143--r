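#' @useDynLib vibeeg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef cor fft lm mad median nextn pchisq pt quantile rnorm
#'   runif sd var
NULL

#' The 32-channel 10-20 montage channel names
#'
#' Ordered labels of the 32-electrode 10-20 layout used throughout the
#' package (reference electrode FCz, recovered after re-referencing is not
#' part of the data channels).
#'
#' @return Character vector of 32 channel labels.
#' @export
ten20_32_channels <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "FT9", "FC5", "FC1",
    "FCz", "FC2", "FC6", "FT10", "T7", "C3", "C4", "T8", "TP9", "CP5",
    "CP1", "CP2", "CP6", "TP10", "P7", "P3", "Pz", "P4", "P8", "O1",
    "Oz", "O2")
}

#' Construct a multichannel EEG recording
#'
#' A recording is a samples x channels matrix of EEG in microvolts with a
#' sampling rate, ordered channel labels, a reference designation and a
#' start-time offset.
#'
#' @param data Numeric matrix, samples in rows, channels in columns (uV).
#'   A vector is treated as a single channel.
#' @param fs Sampling rate in Hz (> 0).
#' @param channel_names Character vector of unique channel labels, one per
#'   column of `data`.
#' @param reference Reference label, e.g. `"FCz"` or `"common-average"`.
#' @param t0 Start offset in seconds.
#' @param montage Optional montage constraint: `"ten20_32"` requires all
#'   channel names to come from [ten20_32_channels()].
#' @return An object of class `eeg_recording`.
#' @export
recording <- function(data, fs, channel_names, reference = "common-average",
                      t0 = 0, montage = NULL) {
  if (is.vector(data)) data <- matrix(data, ncol = 1L)
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  channel_names <- as.character(channel_names)
  if (length(channel_names) == 0L)
    stop("recording requires at least one channel", call. = FALSE)
  if (anyDuplicated(channel_names))
    stop("channel_names must be unique", call. = FALSE)
  if (ncol(data) != length(channel_names))
    stop(sprintf("data has %d columns but %d channel names were given",
                 ncol(data), length(channel_names)), call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number", call. = FALSE)
  if (nrow(data) < 1L)
    stop("recording must contain at least one sample", call. = FALSE)
  if (!is.null(montage) && identical(montage, "ten20_32")) {
    bad <- setdiff(channel_names, ten20_32_channels())
    if (length(bad))
      stop("channels not in the ten20_32 montage: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  colnames(data) <- channel_names
  structure(
    list(data = data, fs = as.numeric(fs), channel_names = channel_names,
         reference = reference, t0 = as.numeric(t0)),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d samples x %d channels @ %g Hz (%.1f s), ref=%s\n",
              nrow(x$data), ncol(x$data), x$fs, nrow(x$data) / x$fs,
              x$reference))
  cat("channels:", paste(utils::head(x$channel_names, 8), collapse = ", "),
      if (length(x$channel_names) > 8) "...", "\n")
  invisible(x)
}

#' Construct a vertical head-acceleration trace
#'
#' @param data Numeric vector of acceleration samples in m/s^2.
#' @param fs Sampling rate in Hz.
#' @return An object of class `accel_trace` with fixed axis `"vertical"`.
#' @export
accel_trace <- function(data, fs) {
  data <- as.numeric(data)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number", call. = FALSE)
  if (length(data) < 1L) stop("empty acceleration trace", call. = FALSE)
  structure(list(data = data, fs = as.numeric(fs), axis = "vertical"),
            class = "accel_trace")
}

#' @export
print.accel_trace <- function(x, ...) {
  cat(sprintf("<accel_trace> %d samples @ %g Hz (%.1f s), axis=%s, rms=%.3f m/s^2\n",
              length(x$data), x$fs, length(x$data) / x$fs, x$axis,
              rms(x$data)))
  invisible(x)
}

#' Load a scalp montage
#'
#' Montages map channel labels to unit-sphere scalp coordinates. The
#' packaged `"ten20_32"` montage holds idealized spherical 10-20 positions
#' for the 32-channel layout.
#'
#' @param name Montage name (currently `"ten20_32"`) or a path to a montage
#'   JSON file with fields `name` and `positions`.
#' @return An object of class `eeg_montage`: list with `name` and a
#'   channels x 3 `positions` matrix of unit vectors.
#' @export
load_montage <- function(name = "ten20_32") {
  path <- if (file.exists(name)) name else
    system.file("extdata", paste0("montage_", name, ".json"),
                package = "vibeeg")
  if (!nzchar(path) || !file.exists(path))
    stop("unknown montage: ", name, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  pos <- do.call(rbind, raw$positions)
  colnames(pos) <- c("x", "y", "z")
  nrm <- sqrt(rowSums(pos^2))
  if (any(abs(nrm - 1) > 1e-9))
    stop("montage positions must lie on the unit sphere", call. = FALSE)
  structure(list(name = raw$name, positions = pos), class = "eeg_montage")
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat(sprintf("<eeg_montage> '%s', %d channels\n", x$name,
              nrow(x$positions)))
  invisible(x)
}

#' Check that a montage covers a recording's channels
#' @param montage An `eeg_montage`.
#' @param rec An `eeg_recording`.
#' @return Invisibly `TRUE`; errors if any channel lacks a position.
#' @export
montage_covers <- function(montage, rec) {
  missing <- setdiff(rec$channel_names, rownames(montage$positions))
  if (length(missing))
    stop("montage '", montage$name, "' lacks positions for: ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Root mean square
#' @param x Numeric vector or matrix (pooled over all elements).
#' @return Scalar RMS value.
#' @export
rms <- function(x) sqrt(mean(as.numeric(x)^2))

n_samples <- function(rec) nrow(rec$data)

duration_s <- function(rec) nrow(rec$data) / rec$fs

#' Align an EEG recording with an acceleration trace
#'
#' The adaptive noise canceller needs a sample-synchronous reference.
#' Sample index 0 of both streams is taken as a shared trigger; the
#' acceleration is resampled to the EEG rate if the rates differ, and both
#' streams are truncated to the common number of samples.
#'
#' @param rec An `eeg_recording`.
#' @param acc An `accel_trace`.
#' @return List with elements `rec` and `acc`, sharing `fs` and length.
#' @export
align_pair <- function(rec, acc) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(acc, "accel_trace"))
  if (length(acc$data) < 1L || nrow(rec$data) < 1L)
    stop("cannot align empty streams", call. = FALSE)
  x <- acc$data
  if (!isTRUE(all.equal(acc$fs, rec$fs))) {
    x <- resample_vector(x, acc$fs, rec$fs)
  }
  n <- min(nrow(rec$data), length(x))
  if (n < 1L) stop("no temporal overlap between EEG and acceleration",
                   call. = FALSE)
  rec2 <- rec
  rec2$data <- rec$data[seq_len(n), , drop = FALSE]
  acc2 <- accel_trace(x[seq_len(n)], rec$fs)
  list(rec = rec2, acc = acc2)
}

# Polyphase rational resampling: mirror-pad, upsample by p (zero stuffing),
# windowed-sinc anti-alias lowpass, downsample by q, with exact group-delay
# compensation. Written here because the available library resampler shows a
# one-sample lag and visible edge transients on pure tones.
resample_vector <- function(x, fs_from, fs_to) {
  if (isTRUE(all.equal(fs_from, fs_to))) return(x)
  pq <- rational_ratio(fs_to, fs_from)
  p <- pq[1]; q <- pq[2]
  n <- length(x)
  npad <- min(n - 1L, 12L * q + 12L)
  xp <- c(2 * x[1] - x[(npad + 1):2], x, 2 * x[n] - x[(n - 1):(n - npad)])
  nu <- length(xp) * p
  v <- numeric(nu)
  v[seq(1L, nu, by = p)] <- xp * p
  half <- 10L * max(p, q)
  ntaps <- 2L * half + 1L
  h <- signal::fir1(ntaps - 1L, 0.98 * min(1 / p, 1 / q))
  fv <- as.numeric(stats::filter(c(v, numeric(ntaps)), h,
                                 method = "convolution", sides = 1L))
  n_out <- round(n * p / q)
  idx <- npad * p + half + 1L + (seq_len(n_out) - 1L) * q
  fv[idx]
}

rational_ratio <- function(num, den, tol = 1e-9) {
  # continued-fraction rational approximation of num/den
  target <- num / den
  a <- attr(fractions_approx(target, tol), "pq")
  a
}

fractions_approx <- function(x, tol) {
  # simple continued fraction expansion
  p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0; r <- x
  for (i in 1:64) {
    a <- floor(r)
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(p1 / q1 - x) < tol * max(1, abs(x))) break
    frac <- r - a
    if (frac < 1e-15) break
    r <- 1 / frac
  }
  structure(p1 / q1, pq = c(as.integer(p1), as.integer(q1)))
}
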