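# Synthetic ground truth, vibration drive, body response and SNR-calibrated
# contaminated mixtures for benchmarking the adaptive noise cancellers.

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

#' Seated-body vibration response model
#'
#' A unit-peak second-order resonance standing in for the vertical
#' transmissibility of a seated human body (head acceleration over seat
#' acceleration), plus a per-channel coupling gain describing how strongly
#' head acceleration leaks into each EEG electrode.
#'
#' @param resonance_hz Peak frequency of the head response in Hz; seated
#'   bodies resonate near 3-5 Hz, default 3.4.
#' @param damping_ratio Damping ratio in (0, 1); default 0.3.
#' @param coupling_gain Named numeric vector, uV of artifact per m/s^2 of
#'   head acceleration, one entry per channel. Computed from `profile` when
#'   omitted.
#' @param channels Channel labels for which to build the coupling profile.
#' @param profile `"central-topography"` (gain largest at vertex-adjacent
#'   channels, falling toward the periphery, from the montage geometry) or
#'   `"uniform"`.
#' @param base_gain Coupling gain at the vertex in uV per m/s^2.
#' @return Object of class `body_model`.
#' @export
body_model <- function(resonance_hz = 3.4, damping_ratio = 0.3,
                       coupling_gain = NULL, channels = ten20_32_channels(),
                       profile = c("central-topography", "uniform"),
                       base_gain = 30) {
  if (resonance_hz <= 0.5 || resonance_hz >= 25)
    stop("resonance_hz must lie in (0.5, 25) Hz", call. = FALSE)
  if (damping_ratio <= 0 || damping_ratio >= 1)
    stop("damping_ratio must lie in (0, 1)", call. = FALSE)
  profile <- match.arg(profile)
  if (is.null(coupling_gain)) {
    coupling_gain <- coupling_profile(channels, profile, base_gain)
  }
  if (any(coupling_gain < 0)) stop("coupling gains must be >= 0",
                                   call. = FALSE)
  structure(list(resonance_hz = resonance_hz, damping_ratio = damping_ratio,
                 coupling_gain = coupling_gain, profile = profile),
            class = "body_model")
}

coupling_profile <- function(channels, profile, base_gain) {
  if (profile == "uniform")
    return(stats::setNames(rep(base_gain, length(channels)), channels))
  mont <- load_montage("ten20_32")
  missing <- setdiff(channels, rownames(mont$positions))
  if (length(missing))
    stop("no montage position for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  z <- pmax(mont$positions[channels, "z"], 0)
  stats::setNames(base_gain * (0.5 + 0.5 * z), channels)
}

#' Generate synthetic ground-truth EEG
#'
#' Per-channel random EEG with a 1/f-shaped spectrum inside each canonical
#' band, synthesized in the frequency domain so the expected relative band
#' powers equal `band_weights` exactly. An optional frontal alpha asymmetry
#' offset scales the F3/F4 alpha components so that
#' `ln alpha(F3) - ln alpha(F4)` is `faa_offset` in expectation.
#'
#' @param channels Channel labels.
#' @param duration Length in seconds.
#' @param fs Sampling rate in Hz.
#' @param band_weights Named nonnegative weights over a subset of
#'   delta/theta/alpha/beta/gamma; normalized internally. Default: equal.
#' @param faa_offset Target FAA in ln-power units (0 = symmetric).
#' @param seed Integer seed; generation is fully seed-deterministic.
#' @param total_power Total signal power over 1-50 Hz in uV^2 (default 100,
#'   i.e. 10 uV RMS).
#' @param scheme A [band_scheme()] defining the band edges.
#' @return An [recording()] in uV.
#' @export
gen_ground_truth_eeg <- function(channels, duration, fs,
                                 band_weights = NULL, faa_offset = 0,
                                 seed = 1, total_power = 100,
                                 scheme = band_scheme()) {
  bands <- scheme$bands
  if (is.null(band_weights))
    band_weights <- stats::setNames(rep(1, length(bands)), names(bands))
  if (!all(names(band_weights) %in% names(bands)))
    stop("band_weights names must be a subset of the scheme's bands",
         call. = FALSE)
  if (any(band_weights < 0)) stop("band weights must be >= 0", call. = FALSE)
  if (sum(band_weights) <= 0) stop("band weights must sum to > 0",
                                   call. = FALSE)
  if (faa_offset != 0 && !all(c("F3", "F4") %in% channels))
    stop("faa_offset != 0 requires channels F3 and F4", call. = FALSE)
  w <- band_weights / sum(band_weights)
  n <- round(duration * fs)
  if (n < 2) stop("duration too short", call. = FALSE)
  nfreq <- n %/% 2L
  freqs <- seq_len(nfreq) * fs / n          # positive frequencies
  # target one-sided PSD: 1/f within each band, band integral = weight
  S <- numeric(nfreq)
  for (b in names(w)) {
    lo <- bands[[b]][1]; hi <- bands[[b]][2]
    sel <- freqs >= lo & freqs < hi
    S[sel] <- (total_power * w[[b]] / log(hi / lo)) / freqs[sel]
  }
  alpha_sel <- freqs >= bands$alpha[1] & freqs < bands$alpha[2]
  with_seed(seed, {
    data <- matrix(0, nrow = n, ncol = length(channels))
    amp <- sqrt(S * n * fs / 2)
    for (ci in seq_along(channels)) {
      a <- amp
      if (faa_offset != 0 && channels[ci] == "F3")
        a[alpha_sel] <- a[alpha_sel] * exp(faa_offset / 4)
      if (faa_offset != 0 && channels[ci] == "F4")
        a[alpha_sel] <- a[alpha_sel] * exp(-faa_offset / 4)
      X <- complex(real = rnorm(nfreq), imaginary = rnorm(nfreq)) * a / sqrt(2)
      full <- complex(length.out = n)
      full[2:(nfreq + 1L)] <- X
      full[n:(n - nfreq + 1L)] <- Conj(X)
      if (n %% 2L == 0L) full[nfreq + 1L] <- sqrt(2) * Re(X[nfreq])
      data[, ci] <- Re(stats::fft(full, inverse = TRUE)) / n
    }
    recording(data, fs, channels, reference = "common-average")
  })
}

#' Generate a band-limited random vibration drive
#'
#' White noise shaped by a 4th-order Butterworth bandpass (0.5-25 Hz,
#' applied forward-backward for zero phase) and rescaled so the realized
#' r.m.s. equals `magnitude_rms` exactly.
#'
#' @param magnitude_rms Target r.m.s. acceleration in m/s^2 (> 0).
#' @param duration Length in seconds.
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed.
#' @param band Passband in Hz, default `c(0.5, 25)`.
#' @param order Butterworth order (default 4).
#' @return An [accel_trace()].
#' @export
gen_vibration_drive <- function(magnitude_rms, duration, fs, seed = 1,
                                band = c(0.5, 25), order = 4) {
  if (magnitude_rms <= 0) stop("magnitude_rms must be > 0", call. = FALSE)
  n <- round(duration * fs)
  if (n < 10) stop("drive must contain at least 10 samples", call. = FALSE)
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  with_seed(seed, {
    x <- rnorm(n)
    y <- as.numeric(signal::filtfilt(bf, x))
    y <- y * (magnitude_rms / rms(y))
    accel_trace(y, fs)
  })
}

#' Head-acceleration response of the seated body
#'
#' Filters the seat-level drive by the body model's second-order resonance
#' (unit peak gain at `resonance_hz`), applied in the frequency domain so
#' the operation is exactly linear and time-invariant.
#'
#' @param drive An [accel_trace()] of seat acceleration.
#' @param body A [body_model()].
#' @return An [accel_trace()] of vertical head acceleration.
#' @export
head_response <- function(drive, body = body_model()) {
  stopifnot(inherits(drive, "accel_trace"), inherits(body, "body_model"))
  z <- body$damping_ratio
  fp <- body$resonance_hz
  # natural frequency such that |H| peaks at fp (only exists for z < 1/sqrt2)
  fn <- if (z < 1 / sqrt(2)) fp / sqrt(1 - 2 * z^2) else fp
  wn <- 2 * pi * fn
  n <- length(drive$data)
  freqs <- c(0, seq_len(n - 1)) * drive$fs / n
  # unwrap to signed frequencies for the full FFT grid
  fsigned <- ifelse(freqs > drive$fs / 2, freqs - drive$fs, freqs)
  s <- 1i * 2 * pi * fsigned
  H <- wn^2 / (s^2 + 2 * z * wn * s + wn^2)
  peak <- Mod(wn^2 / ((1i * 2 * pi * fp)^2 + 2 * z * wn * (1i * 2 * pi * fp) + wn^2))
  H <- H / peak
  y <- Re(stats::fft(stats::fft(drive$data) * H, inverse = TRUE)) / n
  accel_trace(y, drive$fs)
}

#' Couple head acceleration into EEG channels
#'
#' Builds the per-channel movement-artifact recording: channel `c` is
#' `coupling_gain[c]` times the head acceleration (uV per m/s^2), with an
#' optional per-channel FIR distortion.
#'
#' @param head_acc An [accel_trace()] of head acceleration.
#' @param channels Channel labels to synthesize.
#' @param body A [body_model()] whose `coupling_gain` covers `channels`.
#' @param fir Optional named list of FIR coefficient vectors applied to the
#'   acceleration before scaling (zero-padded causal convolution).
#' @return An [recording()] of the artifact in uV.
#' @export
couple_artifact <- function(head_acc, channels, body = body_model(),
                            fir = NULL) {
  stopifnot(inherits(head_acc, "accel_trace"), inherits(body, "body_model"))
  missing <- setdiff(channels, names(body$coupling_gain))
  if (length(missing))
    stop("coupling_gain missing for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  n <- length(head_acc$data)
  data <- matrix(0, nrow = n, ncol = length(channels))
  for (ci in seq_along(channels)) {
    ch <- channels[ci]
    x <- head_acc$data
    if (!is.null(fir) && !is.null(fir[[ch]])) {
      h <- as.numeric(fir[[ch]])
      x <- as.numeric(stats::filter(x, h, method = "convolution",
                                    sides = 1L))
      x[is.na(x)] <- 0
    }
    data[, ci] <- body$coupling_gain[[ch]] * x
  }
  recording(data, head_acc$fs, channels)
}

#' Signal-to-noise ratio of a contamination
#'
#' `SNR = 10 log10(RMS(s) / RMS(noise))`, the amplitude-ratio convention
#' used by the semi-synthetic benchmark; RMS is pooled over all channels.
#'
#' @param s Clean [recording()].
#' @param noise Scaled artifact [recording()] (i.e. `lambda * N`).
#' @return SNR in dB.
#' @export
snr_db <- function(s, noise) {
  10 * log10(rms(s$data) / rms(noise$data))
}

#' Scaling factor lambda for a target SNR
#'
#' Inverts the benchmark SNR definition: with
#' `SNR = 10 log10(RMS(s)/RMS(lambda N))`,
#' `lambda = (RMS(s)/RMS(N)) * 10^(-snr_db/10)`. RMS is pooled over all
#' channels, so one scalar lambda serves the whole montage.
#'
#' @param s Clean [recording()].
#' @param N Artifact [recording()], same shape.
#' @param snr_db Target SNR in dB.
#' @return Scalar lambda >= 0.
#' @export
lambda_for_snr <- function(s, N, snr_db) {
  rn <- rms(N$data)
  if (rn == 0) stop("artifact has zero RMS; lambda undefined", call. = FALSE)
  (rms(s$data) / rn) * 10^(-snr_db / 10)
}

#' Mix clean EEG with a movement artifact at a target SNR
#'
#' Forms `mixture = s + lambda N` with lambda from [lambda_for_snr()], so
#' the recomputed SNR of the mixture equals the target to numerical
#' precision.
#'
#' @param s Clean [recording()].
#' @param N Artifact [recording()], same fs, length and channel order.
#' @param snr_db Target SNR in dB.
#' @param reference Optional [accel_trace()] stored alongside the set.
#' @return Object of class `contaminated_set` with fields `clean`,
#'   `artifact`, `mixture`, `lam`, `snr_db`, `reference`.
#' @export
mix_at_snr <- function(s, N, snr_db, reference = NULL) {
  stopifnot(inherits(s, "eeg_recording"), inherits(N, "eeg_recording"))
  if (!identical(dim(s$data), dim(N$data)) ||
      !identical(s$channel_names, N$channel_names) ||
      !isTRUE(all.equal(s$fs, N$fs)))
    stop("clean and artifact recordings must share fs, shape and channels",
         call. = FALSE)
  lam <- lambda_for_snr(s, N, snr_db)
  mixture <- s
  mixture$data <- s$data + lam * N$data
  structure(list(clean = s, artifact = N, mixture = mixture, lam = lam,
                 snr_db = snr_db, reference = reference),
            class = "contaminated_set")
}

#' @export
print.contaminated_set <- function(x, ...) {
  cat(sprintf("<contaminated_set> %d samples x %d channels @ %g Hz, lambda=%.4g, target SNR=%g dB\n",
              nrow(x$mixture$data), ncol(x$mixture$data), x$mixture$fs,
              x$lam, x$snr_db))
  invisible(x)
}

#' Build a full synthetic WBV contamination benchmark set
#'
#' Convenience wrapper reproducing the semi-synthetic scheme end to end:
#' ground-truth EEG, band-limited vibration drive, seated-body head
#' response, per-channel coupling, and SNR-calibrated mixing.
#'
#' @param snr_db Target SNR in dB (benchmark levels: -8 and 4).
#' @param channels Channel labels (default: the 32-channel montage).
#' @param duration Seconds (default 60).
#' @param fs Sampling rate (default 250).
#' @param magnitude_rms Drive magnitude in m/s^2 r.m.s. (default 2.0).
#' @param body A [body_model()].
#' @param seed Integer seed (EEG and drive use derived sub-seeds).
#' @param band_weights Passed to [gen_ground_truth_eeg()].
#' @return A `contaminated_set` whose `reference` is the head acceleration.
#' @export
make_benchmark_set <- function(snr_db, channels = ten20_32_channels(),
                               duration = 60, fs = 250, magnitude_rms = 2.0,
                               body = NULL, seed = 1, band_weights = NULL) {
  if (is.null(body)) body <- body_model(channels = channels)
  s <- gen_ground_truth_eeg(channels, duration, fs,
                            band_weights = band_weights, seed = seed)
  drive <- gen_vibration_drive(magnitude_rms, duration, fs,
                               seed = seed + 7919L)
  head_acc <- head_response(drive, body)
  N <- couple_artifact(head_acc, channels, body)
  mix_at_snr(s, N, snr_db, reference = head_acc)
}

#' Generate a synthetic stress-study cohort
#'
#' Builds a complete-block condition set: every subject has one recording
#' per condition, generated by [gen_ground_truth_eeg()] with per-condition
#' FAA offsets and band weights. Emulates the within-subject design of a
#' vibration-stress experiment (static + increasing vibration levels) on
#' frontal channels.
#'
#' @param n_subjects Number of subjects.
#' @param conditions Ordered condition labels.
#' @param faa_offsets Per-condition FAA offsets (recycled if scalar).
#' @param band_weights Single weight vector or list of per-condition weight
#'   vectors.
#' @param channels Channel labels (default: the seven frontal electrodes).
#' @param duration Recording length in seconds (default 120).
#' @param fs Sampling rate (default 250).
#' @param analysis_window_s Trailing analysis window (default 30).
#' @param seed Integer seed; each (subject, condition) uses a derived seed.
#' @return A [condition_set()].
#' @export
gen_stress_cohort <- function(n_subjects, conditions, faa_offsets = 0,
                              band_weights = NULL,
                              channels = frontal_set(), duration = 120,
                              fs = 250, analysis_window_s = 30, seed = 1) {
  k <- length(conditions)
  faa_offsets <- rep_len(faa_offsets, k)
  per_cond_weights <- if (is.list(band_weights)) band_weights
                      else rep(list(band_weights), k)
  recs <- list()
  for (si in seq_len(n_subjects)) {
    for (ci in seq_len(k)) {
      sub_seed <- (as.integer(seed) + si * 131L + ci * 7L) %% 2147483647L
      recs[[paste(si, conditions[ci], sep = "|")]] <-
        gen_ground_truth_eeg(channels, duration, fs,
                             band_weights = per_cond_weights[[ci]],
                             faa_offset = faa_offsets[ci], seed = sub_seed)
    }
  }
  condition_set(conditions, subjects = as.character(seq_len(n_subjects)),
                recordings = recs, analysis_window_s = analysis_window_s)
}
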