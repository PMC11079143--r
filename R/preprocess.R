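# Preprocessing pipeline around the adaptive filter: trim, resample,
# detrend, common-average reference, FIR bandpass, bad-channel handling,
# variance-based epoch rejection, and pluggable hooks for external stages
# (ASR-style reconstruction, ICA) that are prior published methods and not
# re-implemented here.

#' Pipeline configuration
#'
#' @param trim_start Seconds removed from the start of the recording
#'   (vibration onset transient), default 10.
#' @param target_fs Target sampling rate in Hz, default 250.
#' @param band Bandpass `c(low, high)` in Hz, default `c(1, 50)`.
#' @param bad_sd_z Robust-z threshold on channel standard deviations
#'   (median/MAD), default 5.
#' @param bad_corr A channel whose maximum absolute correlation with every
#'   other channel falls below this is flagged, default 0.4.
#' @param epoch_reject_z Variance threshold in calibration standard
#'   deviations for 1-s epoch rejection, default 20.
#' @param epoch_mode `"interpolate"` (replace masked epochs from
#'   neighbours) or `"drop"`.
#' @param hooks Named list of optional external-stage callables
#'   (`asr`, `ica`), each `function(rec) -> rec`; `NULL` disables a hook.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(trim_start = 10, target_fs = 250,
                            band = c(1, 50), bad_sd_z = 5, bad_corr = 0.4,
                            epoch_reject_z = 20,
                            epoch_mode = c("interpolate", "drop"),
                            hooks = list(asr = NULL, ica = NULL)) {
  if (band[1] >= band[2]) stop("band low must be < high", call. = FALSE)
  if (target_fs <= 2 * band[2])
    stop("target_fs must exceed twice the band's upper edge", call. = FALSE)
  structure(list(trim_start = trim_start, target_fs = target_fs,
                 band = band, bad_sd_z = bad_sd_z, bad_corr = bad_corr,
                 epoch_reject_z = epoch_reject_z,
                 epoch_mode = match.arg(epoch_mode), hooks = hooks),
            class = "pipeline_config")
}

#' Trim the initial segment of a recording
#'
#' Removes the vibration-onset transient: the first `round(seconds * fs)`
#' samples are dropped and `t0` advanced.
#'
#' @param rec An [recording()].
#' @param seconds Seconds to remove (>= 0, shorter than the recording).
#' @return Trimmed recording.
#' @export
trim_initial <- function(rec, seconds) {
  stopifnot(inherits(rec, "eeg_recording"))
  ndrop <- round(seconds * rec$fs)
  if (ndrop < 0) stop("seconds must be >= 0", call. = FALSE)
  if (ndrop >= nrow(rec$data))
    stop("trim longer than the recording", call. = FALSE)
  if (ndrop == 0) return(rec)
  out <- rec
  out$data <- rec$data[-seq_len(ndrop), , drop = FALSE]
  out$t0 <- rec$t0 + ndrop / rec$fs
  out
}

#' Anti-aliased downsampling
#'
#' Polyphase resampling to a lower rate (upsampling is out of scope).
#'
#' @param rec An [recording()].
#' @param target_fs Target rate in Hz, `<= rec$fs`.
#' @return Resampled recording.
#' @export
resample_recording <- function(rec, target_fs) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (target_fs > rec$fs)
    stop("upsampling not supported: target_fs exceeds the recording rate",
         call. = FALSE)
  if (isTRUE(all.equal(target_fs, rec$fs))) return(rec)
  cols <- lapply(seq_len(ncol(rec$data)), function(ch)
    resample_vector(rec$data[, ch], rec$fs, target_fs))
  n <- min(lengths(cols))
  out <- rec
  out$data <- vapply(cols, function(col) col[seq_len(n)], numeric(n))
  colnames(out$data) <- rec$channel_names
  out$fs <- target_fs
  out
}

#' Remove per-channel linear trends
#'
#' Least-squares line (intercept + slope) subtracted from every channel.
#'
#' @param rec An [recording()].
#' @return Detrended recording.
#' @export
detrend_linear <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  n <- nrow(rec$data)
  if (n < 2) stop("detrending needs at least 2 samples", call. = FALSE)
  t <- seq_len(n)
  tc <- t - mean(t)
  ss <- sum(tc^2)
  out <- rec
  slopes <- as.numeric(crossprod(tc, rec$data)) / ss
  means <- colMeans(rec$data)
  out$data <- rec$data - outer(rep(1, n), means) - outer(tc, slopes)
  colnames(out$data) <- rec$channel_names
  out
}

#' Re-reference to the common average
#'
#' Subtracts the instantaneous mean across channels from every channel, so
#' each sample's channel mean is zero afterwards.
#'
#' @param rec An [recording()] with at least 2 channels.
#' @return Re-referenced recording with `reference = "common-average"`.
#' @export
rereference_car <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (ncol(rec$data) < 2)
    stop("common-average reference needs at least 2 channels", call. = FALSE)
  out <- rec
  out$data <- rec$data - rowMeans(rec$data)
  colnames(out$data) <- rec$channel_names
  out$reference <- "common-average"
  out
}

#' Zero-phase FIR bandpass
#'
#' Windowed-sinc (Hamming) linear-phase FIR, sized from a 1-Hz transition
#' width at the low edge, applied with reflection padding and group-delay
#' compensation so the net response is zero-phase.
#'
#' @param rec An [recording()].
#' @param low,high Band edges in Hz, `0 < low < high < fs/2`.
#' @return Filtered recording.
#' @export
bandpass_fir <- function(rec, low = 1, high = 50) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (low <= 0 || high <= low || high >= fs / 2)
    stop("band must satisfy 0 < low < high < fs/2", call. = FALSE)
  trans <- 1                                 # Hz transition width at low edge
  ntaps <- ceiling(3.3 * fs / trans)
  if (ntaps %% 2 == 0) ntaps <- ntaps + 1    # odd length -> integer delay
  h <- signal::fir1(ntaps - 1, c(low, high) / (fs / 2), type = "pass")
  delay <- (ntaps - 1) / 2
  n <- nrow(rec$data)
  out <- rec
  out$data <- apply(rec$data, 2L, function(x) fir_zero_phase(x, h, delay))
  colnames(out$data) <- rec$channel_names
  out
}

fir_zero_phase <- function(x, h, delay) {
  n <- length(x)
  p <- length(h)
  pad <- min(p, n - 1)
  # odd (mirror) reflection keeps lines continuous at the edges
  pre <- 2 * x[1] - x[(pad + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - pad)]
  xp <- c(pre, x, post)
  y <- as.numeric(stats::filter(xp, h, method = "convolution", sides = 1L))
  y[(pad + delay + 1):(pad + delay + n)]
}

#' Detect bad channels
#'
#' Flags channels whose standard deviation is a robust-z outlier
#' (median/MAD across channels) or whose maximum absolute correlation with
#' every other channel is below `bad_corr`.
#'
#' @param rec An [recording()] with at least 4 channels.
#' @param bad_sd_z Robust-z threshold, default 5.
#' @param bad_corr Correlation floor, default 0.4.
#' @return Character vector of flagged channel labels (possibly empty).
#' @export
detect_bad_channels <- function(rec, bad_sd_z = 5, bad_corr = 0.4) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (ncol(rec$data) < 4)
    stop("bad-channel detection needs at least 4 channels", call. = FALSE)
  sds <- apply(rec$data, 2L, sd)
  med <- median(sds)
  scale <- mad(sds)
  if (scale == 0) scale <- .Machine$double.eps
  rz <- abs(sds - med) / scale
  cm <- suppressWarnings(cor(rec$data))
  diag(cm) <- NA
  maxcor <- apply(abs(cm), 2L, max, na.rm = TRUE)
  maxcor[!is.finite(maxcor)] <- 0
  bad <- rz > bad_sd_z | maxcor < bad_corr
  rec$channel_names[bad]
}

#' Interpolate bad channels from scalp neighbours
#'
#' Replaces each flagged channel by an inverse-squared-distance weighted
#' combination of the good channels, using chord distances on the montage
#' sphere. Good channels are untouched.
#'
#' @param rec An [recording()].
#' @param bads Labels of channels to rebuild (subset of the recording).
#' @param montage An [load_montage()] covering all channels.
#' @return Recording with bad channels replaced.
#' @export
interpolate_channels <- function(rec, bads, montage) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(montage, "eeg_montage"))
  if (!length(bads)) return(rec)
  unknown <- setdiff(bads, rec$channel_names)
  if (length(unknown))
    stop("bad labels not in the recording: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  montage_covers(montage, rec)
  good <- setdiff(rec$channel_names, bads)
  if (length(good) < 3)
    stop("interpolation needs at least 3 good channels", call. = FALSE)
  pos <- montage$positions
  out <- rec
  for (b in bads) {
    d2 <- colSums((t(pos[good, , drop = FALSE]) - pos[b, ])^2)
    w <- 1 / pmax(d2, 1e-12)
    w <- w / sum(w)
    out$data[, b] <- as.numeric(rec$data[, good, drop = FALSE] %*% w)
  }
  out
}

#' Variance-based epoch rejection
#'
#' A simplified stand-in for ASR-style cleaning: 1-s non-overlapping epochs
#' whose standard deviation in any channel exceeds `z` times that channel's
#' calibration standard deviation are masked and either rebuilt by linear
#' interpolation across the gap or dropped.
#'
#' @param rec An [recording()] to clean.
#' @param reference Calibration [recording()] (resting fixation data), same
#'   channels, at least 10 s long.
#' @param z Threshold in calibration SDs, default 20.
#' @param mode `"interpolate"` or `"drop"`.
#' @return List with `rec` (cleaned recording) and `mask` (logical, one
#'   entry per epoch, `TRUE` = rejected).
#' @export
reject_epochs_variance <- function(rec, reference, z = 20,
                                   mode = c("interpolate", "drop")) {
  stopifnot(inherits(rec, "eeg_recording"),
            inherits(reference, "eeg_recording"))
  mode <- match.arg(mode)
  if (!identical(rec$channel_names, reference$channel_names))
    stop("calibration channels must match the recording", call. = FALSE)
  ep_len <- round(rec$fs)
  if (nrow(reference$data) < 10 * round(reference$fs))
    stop("calibration must cover at least 10 epochs (10 s)", call. = FALSE)
  calib_sd <- apply(reference$data, 2L, sd)
  n_ep <- nrow(rec$data) %/% ep_len
  if (n_ep < 1) stop("recording shorter than one epoch", call. = FALSE)
  mask <- logical(n_ep)
  for (e in seq_len(n_ep)) {
    idx <- ((e - 1L) * ep_len + 1L):(e * ep_len)
    ep_sd <- apply(rec$data[idx, , drop = FALSE], 2L, sd)
    mask[e] <- any(ep_sd > z * calib_sd)
  }
  out <- rec
  if (any(mask)) {
    bad_samples <- unlist(lapply(which(mask), function(e)
      ((e - 1L) * ep_len + 1L):(e * ep_len)))
    if (mode == "drop") {
      keep <- setdiff(seq_len(nrow(rec$data)), bad_samples)
      out$data <- rec$data[keep, , drop = FALSE]
    } else {
      good <- setdiff(seq_len(nrow(rec$data)), bad_samples)
      if (length(good) < 2)
        stop("every epoch was rejected; nothing to interpolate from",
             call. = FALSE)
      for (ch in seq_len(ncol(out$data))) {
        out$data[bad_samples, ch] <-
          stats::approx(good, rec$data[good, ch], xout = bad_samples,
                        rule = 2)$y
      }
    }
  }
  list(rec = out, mask = mask)
}

#' Run the full preprocessing pipeline
#'
#' Canonical stage order: trim, resample, detrend, common-average
#' reference, FIR bandpass, adaptive filter, bad-channel detection,
#' variance-based epoch rejection (or ASR hook), interpolation of bad
#' channels, ICA hook. The acceleration reference is trimmed and resampled
#' alongside the EEG so the adaptive stage sees aligned inputs. A
#' provenance log (one entry per stage, in order) is attached as attribute
#' `"provenance"`.
#'
#' @param rec Raw [recording()].
#' @param acc Synchronized [accel_trace()].
#' @param cfg A [pipeline_config()].
#' @param filter_cfg A [filter_config()]; `NULL` skips the adaptive stage.
#' @param calibration Optional calibration [recording()] for epoch
#'   rejection (skipped when `NULL`).
#' @param montage Optional montage for bad-channel interpolation.
#' @return Cleaned recording with attribute `"provenance"`.
#' @export
run_pipeline <- function(rec, acc, cfg = pipeline_config(),
                         filter_cfg = filter_config(),
                         calibration = NULL, montage = NULL) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(acc, "accel_trace"))
  prov <- list()
  log_stage <- function(stage, params, applied = TRUE) {
    prov[[length(prov) + 1L]] <<- list(stage = stage, params = params,
                                       applied = applied)
  }

  if (cfg$trim_start > 0) {
    rec <- trim_initial(rec, cfg$trim_start)
    ndrop <- round(cfg$trim_start * acc$fs)
    if (ndrop >= length(acc$data))
      stop("trim longer than the acceleration trace", call. = FALSE)
    acc <- accel_trace(acc$data[-seq_len(ndrop)], acc$fs)
  }
  log_stage("trim", list(seconds = cfg$trim_start))

  rec <- resample_recording(rec, cfg$target_fs)
  log_stage("resample", list(target_fs = cfg$target_fs))

  rec <- detrend_linear(rec)
  log_stage("detrend", list())

  rec <- rereference_car(rec)
  log_stage("car", list())

  rec <- bandpass_fir(rec, cfg$band[1], cfg$band[2])
  log_stage("bandpass", list(band = cfg$band))

  if (!is.null(filter_cfg)) {
    pair <- align_pair(rec, acc)
    fr <- run_filter(pair$rec, pair$acc, filter_cfg)
    rec <- fr$cleaned
    log_stage("adaptive_filter",
              list(algorithm = filter_cfg$algorithm,
                   order_L = filter_cfg$order_L))
  } else {
    log_stage("adaptive_filter", list(), applied = FALSE)
  }

  bads <- detect_bad_channels(rec, cfg$bad_sd_z, cfg$bad_corr)
  log_stage("bad_channels", list(flagged = bads))

  if (!is.null(cfg$hooks$asr)) {
    rec <- cfg$hooks$asr(rec)
    log_stage("epoch_rejection", list(hook = "asr"))
  } else if (!is.null(calibration)) {
    er <- reject_epochs_variance(rec, calibration, cfg$epoch_reject_z,
                                 cfg$epoch_mode)
    rec <- er$rec
    log_stage("epoch_rejection",
              list(z = cfg$epoch_reject_z, rejected = sum(er$mask)))
  } else {
    log_stage("epoch_rejection", list(), applied = FALSE)
  }

  if (length(bads) && !is.null(montage)) {
    rec <- interpolate_channels(rec, bads, montage)
    log_stage("interpolation", list(channels = bads))
  } else {
    log_stage("interpolation", list(), applied = length(bads) > 0 &&
                !is.null(montage))
  }

  if (!is.null(cfg$hooks$ica)) {
    rec <- cfg$hooks$ica(rec)
    log_stage("ica_hook", list(hook = "ica"))
  } else {
    log_stage("ica_hook", list(), applied = FALSE)
  }

  attr(rec, "provenance") <- prov
  rec
}
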