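# Acceleration-referenced adaptive noise cancellation (NLMS / RLS).
#
# Architecture: the contaminated EEG channel d[n] is the primary input; the
# vertical head acceleration x[n] is the reference. An FIR filter estimates
# the movement artifact y[n] = sum_k w_k x[n-k]; the canceller output is the
# error e[n] = d[n] - y[n], i.e. the cleaned EEG.

#' Adaptive filter configuration
#'
#' @param algorithm `"rls"` or `"nlms"`.
#' @param order_L Number of FIR taps. The benchmark convention is a 1-s
#'   memory, i.e. `round(fs * 1)` = 250 taps at 250 Hz, long enough to span
#'   the 3-5 Hz artifact period.
#' @param mu NLMS step size in (0, 2); default 0.1. Larger steps adapt
#'   faster but leak more weight noise into the output: the steady-state
#'   misadjustment grows roughly as `mu / (2 - mu)`, and the default keeps
#'   the RMS inflation on an uncorrelated reference under 5 percent.
#' @param eps NLMS regularizer (> 0 guards the zero-energy reference case).
#' @param forget RLS exponential forgetting factor in (0.9, 1]; default
#'   0.9995 (an 8-s memory at 250 Hz). Misadjustment grows as
#'   `order_L (1 - forget) / 2`, so shorter memories trade artifact
#'   tracking speed against noise leakage.
#' @param delta RLS inverse-correlation initialization scale (`P0 =
#'   delta I`); default 100.
#' @param w0 Initial weights, default zeros (vector of length `order_L` or
#'   taps x channels matrix).
#' @param burn_in_s Initial transient (s) to discard from evaluation
#'   metrics; the filter itself always runs from sample one with a
#'   zero-padded reference history.
#' @return Object of class `filter_config`.
#' @export
filter_config <- function(algorithm = c("rls", "nlms"), order_L = 250,
                          mu = 0.1, eps = 1e-8, forget = 0.9995,
                          delta = 100, w0 = NULL, burn_in_s = 2) {
  algorithm <- match.arg(tolower(algorithm[1]), c("rls", "nlms"))
  if (order_L < 1) stop("order_L must be >= 1", call. = FALSE)
  if (mu <= 0 || mu >= 2) stop("mu must lie in (0, 2)", call. = FALSE)
  if (forget <= 0.9 || forget > 1)
    stop("forget must lie in (0.9, 1]", call. = FALSE)
  if (delta <= 0) stop("delta must be > 0", call. = FALSE)
  if (eps < 0) stop("eps must be >= 0", call. = FALSE)
  structure(list(algorithm = algorithm, order_L = as.integer(order_L),
                 mu = mu, eps = eps, forget = forget, delta = delta,
                 w0 = w0, burn_in_s = burn_in_s),
            class = "filter_config")
}

#' FIR prediction of the movement artifact
#'
#' `y = sum_k w_k x[n-k]` over the lagged reference window. The window is
#' ordered most-recent-first: `x_window[1]` is `x[n]`.
#'
#' @param w Weight vector.
#' @param x_window Lagged reference samples, same length as `w`.
#' @return Scalar artifact estimate.
#' @export
fir_predict <- function(w, x_window) {
  if (length(w) != length(x_window))
    stop("weight and window lengths differ", call. = FALSE)
  sum(w * x_window)
}

#' One NLMS update
#'
#' Error `e = d - w . x`; update `w <- w + mu e x / (eps + ||x||^2)`.
#'
#' @param w Current weights.
#' @param x_window Lagged reference window (most-recent-first).
#' @param d Contaminated EEG sample.
#' @param mu Step size.
#' @param eps Regularizer.
#' @return List with `w` (updated weights) and `e` (a-priori error).
#' @export
nlms_step <- function(w, x_window, d, mu = 0.1, eps = 1e-8) {
  e <- d - fir_predict(w, x_window)
  w_next <- w + mu * e * x_window / (eps + sum(x_window^2))
  list(w = w_next, e = e)
}

#' One RLS update
#'
#' Gain `k = P x / (forget + x' P x)`; error `e = d - w . x`;
#' `w <- w + k e`; `P <- (P - k x' P) / forget`.
#'
#' @param w Current weights.
#' @param P Inverse correlation matrix (init `delta * I`).
#' @param x_window Lagged reference window (most-recent-first).
#' @param d Contaminated EEG sample.
#' @param forget Forgetting factor.
#' @return List with `w`, `P`, `e`.
#' @export
rls_step <- function(w, P, x_window, d, forget = 0.9995) {
  x_window <- as.numeric(x_window)
  Px <- as.numeric(P %*% x_window)
  k <- Px / (forget + sum(x_window * Px))
  e <- d - fir_predict(w, x_window)
  w_next <- w + k * e
  P_next <- (P - outer(k, Px)) / forget
  if (!all(is.finite(P_next)))
    stop("RLS diverged: inverse-correlation matrix is not finite",
         call. = FALSE)
  list(w = w_next, P = P_next, e = e)
}

#' Run an adaptive noise canceller over a recording
#'
#' Filters every EEG channel independently against the shared acceleration
#' reference. The first `order_L` samples use a zero-padded reference
#' history; weights start at `cfg$w0` (zeros by default).
#'
#' @param mixture Contaminated [recording()].
#' @param reference Aligned [accel_trace()] (same fs and sample count).
#' @param cfg A [filter_config()].
#' @return Object of class `filter_result`: `cleaned` (the error signal
#'   e[n], one channel per input channel), `estimated_artifact` (y[n]) and
#'   `final_weights` (taps x channels). `cleaned + estimated_artifact`
#'   reconstructs the mixture to float precision.
#' @export
run_filter <- function(mixture, reference, cfg = filter_config()) {
  stopifnot(inherits(mixture, "eeg_recording"),
            inherits(reference, "accel_trace"),
            inherits(cfg, "filter_config"))
  if (!isTRUE(all.equal(mixture$fs, reference$fs)))
    stop("mixture and reference sampling rates differ; align first",
         call. = FALSE)
  if (nrow(mixture$data) != length(reference$data))
    stop("mixture and reference lengths differ; align first", call. = FALSE)
  L <- cfg$order_L
  C <- ncol(mixture$data)
  w0 <- cfg$w0
  if (is.null(w0)) w0 <- matrix(0, nrow = L, ncol = C)
  if (is.vector(w0)) w0 <- matrix(w0, nrow = L, ncol = C)
  if (!identical(dim(w0), c(L, C)))
    stop("w0 must be order_L x n_channels", call. = FALSE)
  res <- if (cfg$algorithm == "rls") {
    .rls_filter_multi(mixture$data, reference$data, L, cfg$forget,
                      cfg$delta, w0)
  } else {
    .nlms_filter_multi(mixture$data, reference$data, L, cfg$mu, cfg$eps, w0)
  }
  cleaned <- mixture
  cleaned$data <- res$e
  colnames(cleaned$data) <- mixture$channel_names
  artifact <- mixture
  artifact$data <- res$y
  colnames(artifact$data) <- mixture$channel_names
  structure(list(cleaned = cleaned, estimated_artifact = artifact,
                 final_weights = res$W, config = cfg),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat(sprintf("<filter_result> %s, %d taps, %d samples x %d channels\n",
              toupper(x$config$algorithm), x$config$order_L,
              nrow(x$cleaned$data), ncol(x$cleaned$data)))
  invisible(x)
}

#' Drop the adaptation transient from a recording
#'
#' @param rec An [recording()].
#' @param seconds Burn-in to discard from the start.
#' @return Shortened recording.
#' @export
discard_burn_in <- function(rec, seconds) trim_initial(rec, seconds)
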