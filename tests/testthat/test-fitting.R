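test_that("initial guess finds the rate decade and the decay slope", {
  ser <- simulate_series(sim_spec())
  w <- extract_fit_windows(sort_cycles(ser), 1:8)
  g <- initial_guess(w, model_variant(global_rmax = TRUE))
  expect_equal(log10(g$ka), 5)
  # kd0 from the log-linear tail of the top concentration, within 5%
  expect_lt(abs(g$kd - 1e-4) / 1e-4, 0.05)
  expect_equal(g$rmax, 1.5 * max(vapply(w, function(x)
    max(x$assoc_response), numeric(1))))
})

test_that("pure exponential decay gives kd0 within 5 percent", {
  tt <- seq(0, 30, by = 1)
  dt <- seq(300, 1000, by = 2)
  cyc <- titration_cycle(1, 1e-7, c(tt, 120:300, dt),
                         c(rep(0, 31), rep(50, 181), 50 * exp(-1e-3 * (dt - 300))),
                         phase_schedule(0, 120, 300, 1000))
  ser <- titration_series("d", list(cyc))
  w <- extract_fit_windows(ser, 1)
  g <- initial_guess(w, model_variant())
  expect_lt(abs(g$kd - 1e-3) / 1e-3, 0.05)
})

test_that("an all-zero trace is a no-signal error", {
  tt <- seq(0, 1000, by = 2)
  cyc <- titration_cycle(1, 1e-7, tt, rep(0, length(tt)),
                         phase_schedule(0, 120, 300, 1000))
  ser <- titration_series("z", list(cyc))
  w <- extract_fit_windows(ser, 1)
  expect_error(initial_guess(w, model_variant()), "no signal")
})

test_that("noise-free regenerative and non-regenerative fits recover the truth", {
  for (regen in c(TRUE, FALSE)) {
    ser <- simulate_series(sim_spec(regenerative = regen))
    fit <- fit_series(ser, entry_for(ser, global_rmax = TRUE))
    expect_true(fit$converged)
    expect_lt(abs(fit$params$ka - TRUTH$ka) / TRUTH$ka, 1e-3)
    expect_lt(abs(fit$params$kd - TRUTH$kd) / TRUTH$kd, 1e-3)
    expect_lt(abs(fit$params$rmax[1] - TRUTH$rmax) / TRUTH$rmax, 1e-3)
    expect_equal(fit$kD, fit$params$kd / fit$params$ka, tolerance = 1e-12)
    if (!regen) {
      # fitted extrapolated start times decrease relative to each cycle's t0
      offsets <- fit$params$t0 - vapply(fit$windows, function(w) w$t0,
                                        numeric(1))
      expect_true(all(offsets[-1] < 0))
    }
  }
})

test_that("randomized truths are recovered within 0.1 percent from noise-free data", {
  set.seed(424242)
  for (rep in seq_len(12)) {
    ka <- 10^stats::runif(1, 3, 6)
    kd <- 10^stats::runif(1, -5, -2)
    top <- min(max(50 * kd / ka, 5e-9), 1e-5)
    ser <- simulate_series(sim_spec(ka = ka, kd = kd, top = top))
    fit <- fit_series(ser, entry_for(ser, global_rmax = TRUE))
    expect_lt(abs(fit$params$ka - ka) / ka, 1e-3)
    expect_lt(abs(fit$params$kd - kd) / kd, 1e-3)
  }
})

test_that("local Rmax and drift/shift variants stay faithful when the truth has none", {
  ser <- simulate_series(sim_spec())
  fit_local <- fit_series(ser, entry_for(ser, global_rmax = FALSE))
  expect_lt(abs(fit_local$params$ka - TRUTH$ka) / TRUTH$ka, 1e-3)
  expect_length(fit_local$params$rmax, 5)
  expect_equal(fit_local$params$rmax, rep(100, 5), tolerance = 1e-3)

  # enabling drift on drift-free data leaves the rates unchanged
  fit_plain <- fit_series(ser, entry_for(ser, global_rmax = TRUE))
  fit_drift <- fit_series(ser, entry_for(ser, global_rmax = TRUE, drift = TRUE))
  expect_equal(fit_drift$params$ka, fit_plain$params$ka, tolerance = 1e-6)
  expect_equal(fit_drift$params$kd, fit_plain$params$kd, tolerance = 1e-6)
  expect_equal(max(abs(fit_drift$params$rdrift)), 0, tolerance = 1e-6)
})

test_that("bulk shift amplitudes are recovered when simulated", {
  shifts <- c(2, -1, 3, 1.5, -0.5, 1, 2.5, 0.8)
  ser <- simulate_series(sim_spec(rshift = shifts))
  fit <- fit_series(ser, entry_for(ser, global_rmax = TRUE, bulk_shift = TRUE))
  expect_lt(abs(fit$params$ka - TRUTH$ka) / TRUTH$ka, 1e-3)
  expect_lt(max(abs(fit$params$rshift - shifts[fit$selected])), 0.02)
})

test_that("fitting thinned data changes the rates by less than 0.1 percent", {
  ser5 <- simulate_series(sim_spec(rate_hz = 5, n_conc = 5))
  fit_full <- fit_series(ser5, entry_for(ser5, global_rmax = TRUE))
  ser1 <- thin_to_rate(ser5, 1)
  fit_thin <- fit_series(ser1, entry_for(ser1, global_rmax = TRUE))
  expect_lt(fit_thin$n_points, fit_full$n_points / 4)
  expect_lt(abs(fit_thin$params$ka - fit_full$params$ka) / fit_full$params$ka,
            1e-3)
  expect_lt(abs(fit_thin$params$kd - fit_full$params$kd) / fit_full$params$kd,
            1e-3)
})

test_that("standard errors match the closed form for a single-parameter linear model", {
  # y = a*x + noise: SE(a) = sqrt(rss/dof / sum(x^2))
  x <- seq(0.1, 5, by = 0.1)
  set.seed(5)
  y <- 2 * x + stats::rnorm(length(x), sd = 0.3)
  a_hat <- sum(x * y) / sum(x * x)
  res <- y - a_hat * x
  J <- matrix(-x, ncol = 1)  # d(residual)/da
  se <- compute_standard_errors(J, sum(res^2), length(x) - 1)
  expect_false(se$rank_deficient)
  expect_equal(se$se, sqrt(sum(res^2) / (length(x) - 1) / sum(x^2)),
               tolerance = 1e-12)
})

test_that("zero residuals give zero standard errors", {
  x <- 1:10
  J <- cbind(-x, -x^2)
  se <- compute_standard_errors(J, rss = 0, dof = 8)
  expect_equal(se$se, c(0, 0))
})

test_that("duplicate parameter columns are flagged as rank deficient", {
  x <- as.numeric(1:10)
  se <- compute_standard_errors(cbind(-x, -x), rss = 1, dof = 8)
  expect_true(se$rank_deficient)
  expect_true(all(is.na(se$se)))
})

test_that("KD error propagation reproduces the published worked examples", {
  # rounded printed inputs reproduce KD exactly and Delta-KD to ~1 unit in
  # the 3rd significant digit (the published values were propagated from
  # unrounded estimates)
  r1 <- propagate_kd(1.81e3, 1.19e-4, 8.73, 8.04e-7)
  expect_equal(signif(r1$KD, 3), 6.57e-8)
  expect_equal(r1$SE_KD, 5.45e-10, tolerance = 3e-3)
  r2 <- propagate_kd(3.71e3, 5.99e-5, 9.07e1, 1.14e-6)
  expect_equal(signif(r2$KD, 3), 1.61e-8)
  expect_equal(r2$SE_KD, 4.99e-10, tolerance = 7e-3)
  expect_equal(propagate_kd(1e5, 1e-4, 0, 0)$SE_KD, 0)
  expect_error(propagate_kd(-1, 1e-4, 1, 1), "positive")
})

test_that("replicate summary reproduces the published fold changes", {
  ka <- c(4.07e3, 5.50e3, 2.61e3, 3.71e3)
  kd <- c(5.14e-5, 7.78e-5, 5.53e-5, 5.99e-5)
  kD <- c(1.26e-8, 1.41e-8, 2.12e-8, 1.61e-8)
  df <- data.frame(ka = ka, kd = kd, KD = kD,
                   SE_ka = c(1.18e2, 1.11e2, 9.03e1, 9.07e1),
                   SE_kd = c(1.37e-6, 1.38e-6, 1.13e-6, 1.14e-6),
                   SE_KD = c(4.97e-10, 3.79e-10, 8.52e-10, 4.99e-10))
  s <- summarize_replicates(df)
  expect_equal(round(s$table$fold, 2), c(2.11, 1.51, 1.68))
  expect_equal(s$table$mean[1], mean(ka))
  expect_equal(s$table$cv_pct[1], 100 * sd(ka) / mean(ka))
  expect_equal(unname(s$rel_se[1, "ka"]), 1.18e2 / 4.07e3)
})

test_that("identical replicates give fold 1 and zero CV; fewer than 2 error", {
  fitlike <- data.frame(ka = c(1e5, 1e5), kd = c(1e-4, 1e-4),
                        KD = c(1e-9, 1e-9), SE_ka = c(1, 1), SE_kd = c(1, 1),
                        SE_KD = c(1, 1))
  s <- summarize_replicates(fitlike)
  expect_equal(s$table$fold, c(1, 1, 1))
  expect_equal(s$table$cv_pct, c(0, 0, 0))
  expect_error(summarize_replicates(fitlike[1, ]), "at least 2")
})

test_that("fits are deterministic: identical inputs give identical estimates", {
  ser <- simulate_series(sim_spec(noise_sd = 0.8, seed = 17))
  f1 <- fit_series(ser, entry_for(ser, global_rmax = TRUE))
  f2 <- fit_series(ser, entry_for(ser, global_rmax = TRUE))
  expect_identical(f1$params, f2$params)
  expect_identical(f1$se_ka, f2$se_ka)
})
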