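ref_params <- function(rshift = NULL, rdrift = NULL, t0 = 0) {
  kinetics_params(ka = 1e5, kd = 1e-4, rmax = 100, rshift = rshift,
                  rdrift = rdrift, t0 = t0)
}

test_that("association starts at Rshift and approaches the occupancy plateau", {
  p <- ref_params()
  expect_equal(eval_association(p, 1e-7, 0), 0)
  # plateau: Rmax * ka*C / (ka*C + kd)
  plateau <- 100 * (1e5 * 1e-7) / (1e5 * 1e-7 + 1e-4)
  expect_equal(eval_association(p, 1e-7, 1e7), plateau, tolerance = 1e-12)
  # direct numeric value 100 s into association
  expect_equal(eval_association(p, 1e-7, 100), 62.9461, tolerance = 1e-4)
  p_shift <- ref_params(rshift = 3.5)
  expect_equal(eval_association(p_shift, 1e-7, 0), 3.5)
})

test_that("dissociation is continuous with association at t_asso and halves every ln2/kd", {
  p <- ref_params()
  r_end <- eval_association(p, 1e-7, 300)
  expect_equal(eval_dissociation(p, 1e-7, 300, t_asso = 300), r_end,
               tolerance = 1e-12)
  expect_equal(r_end, 94.2253, tolerance = 1e-4)
  half <- eval_dissociation(p, 1e-7, 300 + log(2) / 1e-4, t_asso = 300)
  expect_equal(half, r_end / 2, tolerance = 1e-12)
})

test_that("continuity at t_asso holds over randomized parameters without shift/drift", {
  set.seed(99)
  for (rep in 1:50) {
    p <- kinetics_params(ka = 10^runif(1, 3, 6), kd = 10^runif(1, -5, -2),
                         rmax = runif(1, 10, 500), t0 = runif(1, 0, 100))
    conc <- 10^runif(1, -9, -6)
    t_asso <- p$t0 + runif(1, 50, 500)
    expect_lt(abs(eval_association(p, conc, t_asso) -
                    eval_dissociation(p, conc, t_asso, t_asso)), 1e-10)
  }
})

test_that("legacy and multiplicative drift forms coincide exactly when drift is zero", {
  p <- ref_params()
  tt <- seq(300, 1000, by = 7)
  expect_equal(eval_dissociation_legacy(p, 1e-7, tt, 300),
               eval_dissociation(p, 1e-7, tt, 300))
})

test_that("drift forms differ by Rdrift*(1 - decayed occupancy rise) and in their limits", {
  p <- ref_params(rdrift = 5)
  # t -> inf: additive form keeps the Rdrift floor, multiplicative decays to 0
  expect_equal(eval_dissociation_legacy(p, 1e-7, 1e9, 300), 5, tolerance = 1e-9)
  expect_equal(eval_dissociation(p, 1e-7, 1e9, 300), 0, tolerance = 1e-9)
  # algebraic difference at t = t_asso: Rdrift * (1 - occupancy rise)
  occ_rise <- (1e5 * 1e-7 / (1e5 * 1e-7 + 1e-4)) *
    (1 - exp(-(1e5 * 1e-7 + 1e-4) * 300))
  expect_equal(eval_dissociation_legacy(p, 1e-7, 300, 300) -
                 eval_dissociation(p, 1e-7, 300, 300),
               5 * (1 - occ_rise), tolerance = 1e-12)
})

test_that("association is monotone in time and concentration; dissociation decays at -kd", {
  p <- ref_params()
  tt <- seq(0, 300, by = 5)
  r <- eval_association(p, 1e-8, tt)
  expect_true(all(diff(r) >= 0))
  concs <- 10^seq(-9, -6, by = 0.25)
  plateaus <- vapply(concs, function(cv) eval_association(p, cv, 1e7),
                     numeric(1))
  expect_true(all(diff(plateaus) > 0))
  td <- seq(300, 900, by = 10)
  rd <- eval_dissociation(p, 1e-7, td, 300)
  expect_true(all(diff(rd) <= 0))
  slope <- diff(log(rd)) / diff(td)
  expect_equal(slope, rep(-1e-4, length(slope)), tolerance = 1e-9)
})

test_that("degenerate zero rate is a model error", {
  p <- ref_params()
  p$kd <- 0   # bypass constructor guard to exercise the evaluator check
  expect_error(eval_association(p, 0, 10), "degenerate rate")
})

test_that("packed parameter counts follow the variant and the mapping is bijective", {
  # regenerative, local Rmax, no shift/drift, n = 5 -> 2 + 5 = 7
  v1 <- model_variant(regenerative = TRUE, global_rmax = FALSE)
  p1 <- kinetics_params(1e5, 1e-4, rmax = c(90, 95, 100, 105, 110),
                        t0 = rep(120, 5))
  vec1 <- pack_parameters(p1, v1, 5)
  expect_length(vec1, 7)
  # non-regenerative, global Rmax, n = 5 -> 2 + 1 + 5 = 8
  v2 <- model_variant(regenerative = FALSE, global_rmax = TRUE)
  p2 <- kinetics_params(1e5, 1e-4, rmax = 100, t0 = c(100, 90, 80, 70, 60))
  vec2 <- pack_parameters(p2, v2, 5)
  expect_length(vec2, 8)
  # round trips
  back1 <- unpack_parameters(vec1, v1, 5, t0_fixed = rep(120, 5))
  expect_equal(back1$ka, p1$ka); expect_equal(back1$rmax, p1$rmax)
  back2 <- unpack_parameters(vec2, v2, 5)
  expect_equal(back2$t0, p2$t0); expect_equal(back2$kd, p2$kd)
  # with shift: 2 + 1 + n
  v3 <- model_variant(global_rmax = TRUE, bulk_shift = TRUE)
  p3 <- kinetics_params(1e4, 1e-3, rmax = 50, rshift = c(1, -2, 3),
                        t0 = rep(0, 3))
  expect_length(pack_parameters(p3, v3, 3), 6)
  expect_equal(unpack_parameters(pack_parameters(p3, v3, 3), v3, 3,
                                 t0_fixed = rep(0, 3))$rshift, p3$rshift)
  expect_error(unpack_parameters(c(1, 2, 3), v2, 5), "length")
})

test_that("bulk shift and drift cannot be combined in a variant", {
  expect_error(model_variant(bulk_shift = TRUE, drift = TRUE),
               "mutually exclusive")
})

test_that("predict_cycle reproduces noise-free simulator output exactly", {
  ser <- simulate_series(sim_spec(n_conc = 3))
  w <- extract_fit_windows(ser, 1:3)
  p <- kinetics_params(TRUTH$ka, TRUTH$kd, TRUTH$rmax, t0 = rep(120, 3))
  for (i in 1:3) {
    pr <- predict_cycle(p, w[[i]]$conc, w[[i]], i)
    expect_equal(pr$assoc, w[[i]]$assoc_response, tolerance = 1e-10)
    expect_equal(pr$dissoc, w[[i]]$dissoc_response, tolerance = 1e-10)
  }
})
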