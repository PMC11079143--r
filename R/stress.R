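# Vibration-stress indices and rank statistics: frontal alpha asymmetry,
# frontal relative band powers, Friedman test and Conover pairwise
# comparisons over a complete within-subject condition design.

#' The frontal electrode set
#'
#' The seven frontal 10-20 electrodes used for stress indices.
#'
#' @return Character vector: Fp1, Fp2, F7, F3, Fz, F4, F8.
#' @export
frontal_set <- function() c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8")

#' Construct a condition set
#'
#' A complete block design: every subject has one recording per condition.
#'
#' @param conditions Ordered condition labels (e.g. static, 1.0, 1.5, 2.0
#'   m/s^2 r.m.s.).
#' @param subjects Subject identifiers.
#' @param recordings Named list keyed `"subject|condition"`, each an
#'   [recording()].
#' @param analysis_window_s Trailing analysis window in seconds (default
#'   30).
#' @return Object of class `condition_set`.
#' @export
condition_set <- function(conditions, subjects, recordings,
                          analysis_window_s = 30) {
  conditions <- as.character(conditions)
  subjects <- as.character(subjects)
  if (length(conditions) < 2) stop("need at least 2 conditions",
                                   call. = FALSE)
  for (s in subjects) for (cn in conditions) {
    key <- paste(s, cn, sep = "|")
    if (is.null(recordings[[key]]))
      stop("incomplete design: missing recording for subject ", s,
           ", condition ", cn, call. = FALSE)
    if (!inherits(recordings[[key]], "eeg_recording"))
      stop("entry ", key, " is not an eeg_recording", call. = FALSE)
  }
  structure(list(conditions = conditions, subjects = subjects,
                 recordings = recordings,
                 analysis_window_s = analysis_window_s),
            class = "condition_set")
}

#' @export
print.condition_set <- function(x, ...) {
  cat(sprintf("<condition_set> %d subjects x %d conditions (%s), window=%g s\n",
              length(x$subjects), length(x$conditions),
              paste(x$conditions, collapse = ", "), x$analysis_window_s))
  invisible(x)
}

#' Keep the trailing window of a recording
#'
#' @param rec An [recording()].
#' @param seconds Window length; must not exceed the recording duration.
#' @return Recording holding the last `round(seconds * fs)` samples.
#' @export
trailing_window <- function(rec, seconds) {
  stopifnot(inherits(rec, "eeg_recording"))
  nkeep <- round(seconds * rec$fs)
  if (nkeep < 1) stop("window must be positive", call. = FALSE)
  n <- nrow(rec$data)
  if (nkeep > n) stop("window longer than the recording", call. = FALSE)
  out <- rec
  out$data <- rec$data[(n - nkeep + 1L):n, , drop = FALSE]
  out$t0 <- rec$t0 + (n - nkeep) / rec$fs
  out
}

#' Frontal alpha asymmetry
#'
#' `FAA = ln alpha(F3) - ln alpha(F4)` with absolute alpha band power
#' (8-13 Hz) from the Welch PSD. FAA decreases under stress: right-frontal
#' alpha exceeds left-frontal alpha when avoidance-type affect dominates.
#'
#' @param rec An [recording()] containing channels F3 and F4.
#' @param params A [welch_params()].
#' @param scheme A [band_scheme()] providing the alpha band edges.
#' @return Scalar FAA (ln-power units).
#' @export
frontal_alpha_asymmetry <- function(rec, params = welch_params(),
                                    scheme = band_scheme()) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!all(c("F3", "F4") %in% rec$channel_names))
    stop("FAA requires channels F3 and F4", call. = FALSE)
  alpha <- scheme$bands$alpha
  p3 <- band_power(rec$data[, "F3"], rec$fs, alpha, params)
  p4 <- band_power(rec$data[, "F4"], rec$fs, alpha, params)
  if (p3 <= 0 || p4 <= 0)
    stop("nonpositive alpha band power; FAA undefined", call. = FALSE)
  log(p3) - log(p4)
}

#' Frontal relative band powers
#'
#' Relative band power per frontal channel, averaged across the seven
#' frontal electrodes and renormalized to sum to one.
#'
#' @param rec An [recording()] containing all frontal channels.
#' @param frontal Frontal channel labels, default [frontal_set()].
#' @param scheme A [band_scheme()].
#' @param params A [welch_params()].
#' @return Named fractions over the scheme's bands, summing to 1.
#' @export
frontal_relative_powers <- function(rec, frontal = frontal_set(),
                                    scheme = band_scheme(),
                                    params = welch_params()) {
  stopifnot(inherits(rec, "eeg_recording"))
  missing <- setdiff(frontal, rec$channel_names)
  if (length(missing))
    stop("missing frontal channels: ", paste(missing, collapse = ", "),
         call. = FALSE)
  rp <- vapply(frontal, function(ch)
    relative_band_power(rec$data[, ch], rec$fs, scheme, params),
    numeric(length(scheme$bands)))
  avg <- rowMeans(rp)
  avg / sum(avg)
}

#' Friedman rank test over a complete block design
#'
#' Within-subject ranks (average ranks on ties); the statistic is the
#' classical rank-sum form `chi2 = 12/(n k (k+1)) sum(R_j^2) - 3 n (k+1)`
#' with `df = k - 1` and an upper-tail chi-squared p-value.
#'
#' @param values Numeric matrix, subjects in rows, conditions in columns.
#' @return List with `chi2`, `df`, `p`.
#' @export
friedman_test <- function(values) {
  values <- as.matrix(values)
  n <- nrow(values); k <- ncol(values)
  if (n < 2 || k < 2)
    stop("need at least 2 subjects and 2 conditions", call. = FALSE)
  if (anyNA(values)) stop("incomplete blocks: NA values", call. = FALSE)
  r <- t(apply(values, 1L, rank))
  Rj <- colSums(r)
  chi2 <- 12 * sum(Rj^2) / (n * k * (k + 1)) - 3 * n * (k + 1)
  chi2 <- max(chi2, 0)
  df <- as.integer(k - 1L)
  list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE))
}

#' Conover pairwise comparisons of Friedman rank sums
#'
#' Pairwise follow-up to the Friedman test: the difference of column rank
#' sums divided by its estimated standard error is referred to a
#' t-distribution with `(n-1)(k-1)` degrees of freedom. P-values are
#' reported unadjusted by default; Holm adjustment is available.
#'
#' @param values Subjects x conditions matrix.
#' @param adjust `"none"` (default) or `"holm"`.
#' @return Data frame with columns `cond_i`, `cond_j`, `statistic`, `p`.
#' @export
durbin_conover_posthoc <- function(values, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  values <- as.matrix(values)
  n <- nrow(values); k <- ncol(values)
  if (n < 2 || k < 2)
    stop("need at least 2 subjects and 2 conditions", call. = FALSE)
  if (anyNA(values)) stop("incomplete blocks: NA values", call. = FALSE)
  labels <- colnames(values)
  if (is.null(labels)) labels <- as.character(seq_len(k))
  r <- t(apply(values, 1L, rank))
  Rj <- colSums(r)
  A1 <- sum(r^2)
  C1 <- n * k * (k + 1)^2 / 4
  df <- (n - 1) * (k - 1)
  if (A1 - C1 <= 0) {
    # every observation tied within every block: no information
    T1 <- 0
    se <- 0
  } else {
    T1 <- (k - 1) * (sum(Rj^2) - n^2 * k * (k + 1)^2 / 4) / (A1 - C1)
    fac <- 1 - T1 / (n * (k - 1))
    se <- sqrt(2 * n * (A1 - C1) / df * max(fac, 0))
  }
  pairs <- utils::combn(k, 2)
  out <- data.frame(cond_i = labels[pairs[1, ]], cond_j = labels[pairs[2, ]],
                    statistic = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  for (idx in seq_len(ncol(pairs))) {
    i <- pairs[1, idx]; j <- pairs[2, idx]
    diff <- Rj[i] - Rj[j]
    if (se == 0) {
      stat <- if (diff == 0) 0 else sign(diff) * Inf
    } else {
      stat <- diff / se
    }
    out$statistic[idx] <- stat
    out$p[idx] <- if (is.infinite(stat)) 0 else 2 * pt(-abs(stat), df)
  }
  if (adjust == "holm") out$p <- stats::p.adjust(out$p, method = "holm")
  out
}

#' Assess vibration stress across conditions
#'
#' For every (subject, condition): keep the trailing analysis window,
#' compute FAA and the frontal relative band powers. Each metric (FAA plus
#' one per band) is then tested across conditions with the Friedman test;
#' where Friedman rejects at `alpha`, Conover pairwise comparisons are
#' added.
#'
#' @param set A [condition_set()].
#' @param frontal Frontal channels, default [frontal_set()].
#' @param scheme A [band_scheme()].
#' @param params A [welch_params()].
#' @param alpha Significance level gating the post hoc stage (default
#'   0.05).
#' @param posthoc_adjust Passed to [durbin_conover_posthoc()].
#' @return Object of class `stress_report`: `faa` and per-band `rp`
#'   subject x condition matrices, `friedman` (per metric), `posthoc` (per
#'   metric where run), `alpha`.
#' @export
assess_stress <- function(set, frontal = frontal_set(),
                          scheme = band_scheme(), params = welch_params(),
                          alpha = 0.05, posthoc_adjust = "none") {
  stopifnot(inherits(set, "condition_set"))
  ns <- length(set$subjects); k <- length(set$conditions)
  faa <- matrix(NA_real_, ns, k,
                dimnames = list(set$subjects, set$conditions))
  rp <- lapply(names(scheme$bands), function(b) faa)
  names(rp) <- names(scheme$bands)
  for (si in seq_len(ns)) {
    for (ci in seq_len(k)) {
      key <- paste(set$subjects[si], set$conditions[ci], sep = "|")
      rec <- trailing_window(set$recordings[[key]], set$analysis_window_s)
      faa[si, ci] <- frontal_alpha_asymmetry(rec, params, scheme)
      rps <- frontal_relative_powers(rec, frontal, scheme, params)
      for (b in names(rps)) rp[[b]][si, ci] <- rps[[b]]
    }
  }
  metrics <- c(list(faa = faa), rp)
  fried <- lapply(metrics, friedman_test)
  post <- list()
  for (m in names(metrics)) {
    if (fried[[m]]$p < alpha)
      post[[m]] <- durbin_conover_posthoc(metrics[[m]],
                                          adjust = posthoc_adjust)
  }
  structure(list(faa = faa, rp = rp, friedman = fried, posthoc = post,
                 alpha = alpha, conditions = set$conditions),
            class = "stress_report")
}

#' @export
print.stress_report <- function(x, ...) {
  cat(sprintf("<stress_report> %d subjects x %d conditions\n",
              nrow(x$faa), ncol(x$faa)))
  cat("mean FAA by condition:\n")
  print(round(colMeans(x$faa), 4))
  for (m in names(x$friedman)) {
    f <- x$friedman[[m]]
    cat(sprintf("  %-6s Friedman chi2=%.3f df=%d p=%.4g%s\n", m, f$chi2,
                f$df, f$p, if (f$p < x$alpha) " *" else ""))
  }
  invisible(x)
}
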