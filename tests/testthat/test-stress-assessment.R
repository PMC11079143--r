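alpha_pair_rec <- function(ratio, fs = 250, duration = 60, seed = 81) {
  # F3 alpha power = ratio x F4 alpha power, deterministic construction
  set.seed(seed)
  base <- sine_wave(10, duration, fs) + 0.01 * rnorm(duration * fs)
  recording(cbind(sqrt(ratio) * base, base), fs, c("F3", "F4"))
}

test_that("FAA equals the log alpha-power ratio", {
  expect_equal(frontal_alpha_asymmetry(alpha_pair_rec(1)), 0,
               tolerance = 1e-6)
  expect_equal(frontal_alpha_asymmetry(alpha_pair_rec(exp(1))), 1,
               tolerance = 1e-3)
  rec <- alpha_pair_rec(2.5)
  swapped <- recording(rec$data[, c(2, 1)], rec$fs, c("F3", "F4"))
  expect_equal(frontal_alpha_asymmetry(swapped),
               -frontal_alpha_asymmetry(rec), tolerance = 1e-9)
  bad <- recording(matrix(rnorm(500), ncol = 1), 250, "Fz")
  expect_error(frontal_alpha_asymmetry(bad), "F3")
})

test_that("frontal relative powers average the channel-level fractions", {
  set.seed(82)
  fs <- 250
  x <- rnorm(60 * fs)
  rec <- recording(matrix(rep(x, 7), ncol = 7), fs, frontal_set())
  rp <- frontal_relative_powers(rec)
  expect_equal(rp, relative_band_power(x, fs), tolerance = 1e-12)
  expect_equal(sum(rp), 1, tolerance = 1e-9)

  alpha_rec <- gen_ground_truth_eeg(frontal_set(), 60, fs,
                                    band_weights = c(alpha = 5, delta = 1,
                                                     theta = 1, beta = 1,
                                                     gamma = 1), seed = 83)
  rp2 <- frontal_relative_powers(alpha_rec)
  expect_identical(names(which.max(rp2)), "alpha")
  expect_error(frontal_relative_powers(rand_rec(100, c("F3", "F4"), fs)),
               "missing frontal")
})

test_that("trailing_window keeps exactly the final seconds", {
  rec <- rand_rec(120 * 250, c("F3", "F4"), 250, seed = 84)
  out <- trailing_window(rec, 30)
  expect_equal(nrow(out$data), 7500)
  expect_identical(out$data[7500, ], rec$data[30000, ])
  expect_identical(trailing_window(rec, 120)$data, rec$data)
  expect_error(trailing_window(rec, 0.001), "positive")
  expect_error(trailing_window(rec, 121), "longer")
})

test_that("Friedman statistic matches its closed form and invariances", {
  perfect <- matrix(c(1, 1, 1, 2, 2, 2, 3, 3, 3), nrow = 3)
  res <- friedman_test(perfect)
  expect_equal(res$chi2, 6)
  expect_equal(res$df, 2)
  tied <- matrix(5, nrow = 4, ncol = 3)
  expect_equal(friedman_test(tied)$chi2, 0)
  set.seed(85)
  m <- matrix(rnorm(40), nrow = 10)
  perm <- m[, c(3, 1, 4, 2)]
  expect_equal(friedman_test(m)$chi2, friedman_test(perm)$chi2)
  expect_error(friedman_test(m[1, , drop = FALSE]), "2 subjects")
  m[2, 3] <- NA
  expect_error(friedman_test(m), "NA")
})

test_that("Friedman agrees with stats::friedman.test on tie-free data", {
  set.seed(86)
  m <- matrix(rnorm(22 * 4), nrow = 22)
  ours <- friedman_test(m)
  ref <- stats::friedman.test(m)
  expect_equal(ours$chi2, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
})

test_that("chi-square approximation tracks the exact permutation null", {
  set.seed(87)
  m <- matrix(rnorm(12), nrow = 4, ncol = 3)
  obs <- friedman_test(m)$chi2
  perms <- as.matrix(expand.grid(rep(list(1:6), 4)))
  orders <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  stats_null <- apply(perms, 1L, function(pr) {
    r <- t(vapply(seq_len(4), function(i) orders[[pr[i]]], numeric(3)))
    Rj <- colSums(r)
    12 / (4 * 3 * 4) * sum(Rj^2) - 3 * 4 * 4
  })
  p_exact <- mean(stats_null >= obs - 1e-12)
  p_chi2 <- friedman_test(m)$p
  expect_lt(abs(p_exact - p_chi2), 0.1)
})

test_that("Conover pairwise comparisons behave structurally", {
  set.seed(88)
  # two identical conditions: their pair has statistic 0, p = 1
  a <- rnorm(10)
  m <- cbind(a, a, rnorm(10))
  colnames(m) <- c("c1", "c2", "c3")
  out <- durbin_conover_posthoc(m)
  row12 <- out[out$cond_i == "c1" & out$cond_j == "c2", ]
  expect_equal(row12$statistic, 0)
  expect_equal(row12$p, 1)
  # antisymmetry under swapping the pair's columns
  m2 <- matrix(rnorm(40), nrow = 10,
               dimnames = list(NULL, paste0("c", 1:4)))
  out2 <- durbin_conover_posthoc(m2)
  swapped <- m2[, c(2, 1, 3, 4)]; colnames(swapped) <- colnames(m2)
  out3 <- durbin_conover_posthoc(swapped)
  expect_equal(out3$statistic[1], -out2$statistic[1], tolerance = 1e-12)
})

test_that("Conover statistic matches the rank-residual variance form", {
  set.seed(89)
  m <- matrix(rnorm(22 * 4), nrow = 22)
  colnames(m) <- paste0("c", 1:4)
  n <- nrow(m); k <- ncol(m)
  r <- t(apply(m, 1L, rank))
  Rj <- colSums(r)
  # independent route: variance from column-centered rank residuals
  resid2 <- sum(sweep(r, 2L, colMeans(r))^2)
  df <- (n - 1) * (k - 1)
  se <- sqrt(2 * n * resid2 / df)
  pairs <- utils::combn(k, 2)
  expected_stat <- (Rj[pairs[1, ]] - Rj[pairs[2, ]]) / se
  expected_p <- 2 * pt(-abs(expected_stat), df)
  out <- durbin_conover_posthoc(m)
  expect_equal(out$statistic, unname(expected_stat), tolerance = 1e-10)
  expect_equal(round(out$p, 4), round(unname(expected_p), 4))
  holm <- durbin_conover_posthoc(m, adjust = "holm")
  expect_true(all(holm$p >= out$p - 1e-12))
})

test_that("condition_set enforces the complete block design", {
  recs <- list("1|a" = rand_rec(100, frontal_set(), 250, seed = 90),
               "1|b" = rand_rec(100, frontal_set(), 250, seed = 91),
               "2|a" = rand_rec(100, frontal_set(), 250, seed = 92))
  expect_error(condition_set(c("a", "b"), c("1", "2"), recs), "incomplete")
})

test_that("assess_stress recovers an imposed FAA gradient", {
  set <- gen_stress_cohort(8, c("static", "v1", "v2", "v3"),
                           faa_offsets = c(0.4, 0.15, -0.15, -0.4),
                           duration = 40, seed = 93)
  rep_ <- assess_stress(set)
  means <- colMeans(rep_$faa)
  expect_true(all(diff(means) < 0))
  expect_lt(rep_$friedman$faa$p, 0.05)
  expect_true("faa" %in% names(rep_$posthoc))
  # RP fractions sum to one for every subject x condition
  tot <- Reduce(`+`, rep_$rp)
  expect_true(all(abs(tot - 1) < 1e-9))
})

test_that("alpha suppression across conditions is detected with high power", {
  weights <- lapply(c(0.20, 0.16), function(a)
    c(delta = 0.2, theta = 0.2, alpha = a, beta = 0.2, gamma = 0.2))
  rejections <- vapply(1:10, function(r) {
    set <- gen_stress_cohort(20, c("static", "vib"), band_weights = weights,
                             duration = 40, seed = 200000 + r * 1111)
    rep_ <- assess_stress(set)
    rep_$friedman$alpha$p < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.8)
})
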