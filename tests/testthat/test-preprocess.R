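test_that("an already-zeroed regenerative series is unchanged by alignment", {
  ser <- simulate_series(sim_spec(n_conc = 4))
  aligned <- align_baseline(ser)
  for (i in seq_along(ser$cycles)) {
    expect_equal(aligned$cycles[[i]]$response, ser$cycles[[i]]$response,
                 tolerance = 1e-12)
  }
})

test_that("a constant offset is removed: baseline mean becomes zero", {
  ser <- simulate_series(sim_spec(n_conc = 3))
  ser$cycles[[2]]$response <- ser$cycles[[2]]$response + 7.3
  aligned <- align_baseline(ser)
  cyc <- aligned$cycles[[2]]
  base <- cyc$response[cyc$time < cyc$schedule$t0]
  expect_equal(mean(base), 0, tolerance = 1e-12)
})

test_that("alignment is idempotent", {
  ser <- simulate_series(sim_spec(n_conc = 4, noise_sd = 0.7, seed = 3,
                                  regenerative = FALSE))
  once <- align_baseline(ser)
  twice <- align_baseline(once)
  for (i in seq_along(ser$cycles)) {
    expect_equal(twice$cycles[[i]]$response, once$cycles[[i]]$response,
                 tolerance = 1e-12)
  }
})

test_that("non-regenerative stitching removes an injected inter-cycle jump", {
  ser <- simulate_series(sim_spec(n_conc = 5, regenerative = FALSE))
  for (j in 3:5) {  # artificial +5 jump between cycles 2 and 3
    ser$cycles[[j]]$response <- ser$cycles[[j]]$response + 5
  }
  expect_true(max(abs(junction_gaps(ser))) > 1)
  aligned <- align_baseline(ser)
  expect_lt(max(abs(junction_gaps(aligned))), 1e-9)
})

test_that("alignment errors on a cycle without baseline points", {
  ser <- simulate_series(sim_spec(n_conc = 3))
  keep <- ser$cycles[[2]]$time >= ser$cycles[[2]]$schedule$t0
  ser$cycles[[2]]$time <- ser$cycles[[2]]$time[keep]
  ser$cycles[[2]]$response <- ser$cycles[[2]]$response[keep]
  expect_error(align_baseline(ser), "cycle 2.*baseline")
})

test_that("blank identical to a cycle zeroes it; zero blank changes nothing", {
  ser <- simulate_series(sim_spec(n_conc = 3, blank = TRUE))
  ser$blank$response <- ser$cycles[[2]]$response  # same relative clock
  sub <- subtract_blank(ser)
  expect_equal(max(abs(sub$cycles[[2]]$response)), 0)
  expect_null(sub$blank)

  ser2 <- simulate_series(sim_spec(n_conc = 3, blank = TRUE))
  sub2 <- subtract_blank(ser2)   # blank is identically zero (noise-free)
  for (i in 1:3) {
    expect_equal(sub2$cycles[[i]]$response, ser2$cycles[[i]]$response)
  }
})

test_that("blank subtraction with no blank is a no-op with a notice", {
  ser <- simulate_series(sim_spec(n_conc = 3))
  expect_message(sub <- subtract_blank(ser), "no blank")
  expect_equal(sub$cycles[[1]]$response, ser$cycles[[1]]$response)
})

test_that("blank interpolation matches the closed form for a linear ramp", {
  # cycle on a 1.0 s grid, blank ramp 0.5*t_rel on a 0.5 s grid
  tt_c <- seq(0, 30, by = 1)
  tt_b <- seq(0, 30, by = 0.5)
  sched <- phase_schedule(0, 10, 20, 30)
  cyc <- titration_cycle(1, 1e-8, tt_c, rep(2, length(tt_c)), sched)
  blank <- titration_cycle(2, 0, tt_b, 0.5 * (tt_b - 10), sched)
  ser <- titration_series("s", list(cyc), blank = blank)
  sub <- subtract_blank(ser)
  expect_equal(sub$cycles[[1]]$response, 2 - 0.5 * (tt_c - 10),
               tolerance = 1e-12)
})

test_that("a blank shorter than a cycle window is an error naming the cycle", {
  ser <- simulate_series(sim_spec(n_conc = 2, blank = TRUE))
  keep <- seq_len(floor(length(ser$blank$time) / 2))
  ser$blank$time <- ser$blank$time[keep]
  ser$blank$response <- ser$blank$response[keep]
  expect_error(subtract_blank(ser), "cycle 1.*blank trace does not cover")
})

test_that("thinning keeps one point per bin and never upsamples", {
  tt <- seq(0, 99.8, by = 0.2)   # 5 Hz, 100 s
  cyc <- titration_cycle(1, 1e-8, tt, sin(tt), phase_schedule(0, 10, 50, 99.8))
  ser <- titration_series("s", list(cyc))
  thinned <- thin_to_rate(ser, 1)
  expect_true(abs(length(thinned$cycles[[1]]$time) - 100) <= 1)
  expect_equal(thinned$cycles[[1]]$time[1], 0)   # first point preserved
  expect_false(is.unsorted(thinned$cycles[[1]]$time, strictly = TRUE))
  # rate above native sampling: unchanged
  same <- thin_to_rate(ser, 10)
  expect_equal(same$cycles[[1]]$time, tt)
  # degenerate single-point cycle
  one <- titration_series("o", list(titration_cycle(1, 1e-8, 5, 1,
                                                    phase_schedule(0, 1, 2, 5))))
  expect_equal(thin_to_rate(one, 1)$cycles[[1]]$time, 5)
})

test_that("auto selection maximizes the accumulated end-of-association increase", {
  e <- c(2, 5, 11, 22, 40, 65, 85, 95)
  # window scores: 38, 60, 74, 73 -> third window, cycles 3..7
  expect_equal(auto_window(e), 3:7)
  # <= 5 cycles: all selected
  expect_equal(auto_window(c(4, 9, 2)), 1:3)
  # ties go to the lowest-concentration window
  expect_equal(auto_window(c(0, 10, 20, 30, 40, 50, 60)), 1:5)
})

test_that("auto selection equals brute force on randomized response vectors", {
  brute <- function(e) {
    scores <- vapply(seq_len(length(e) - 4L), function(j) e[j + 4L] - e[j],
                     numeric(1))
    j <- which(scores == max(scores))[1]
    seq.int(j, j + 4L)
  }
  set.seed(20240101)
  for (rep in seq_len(300)) {
    e <- round(stats::runif(sample(6:12, 1), 0, 100),
               sample(c(0, 1, 3), 1))    # occasional ties
    expect_identical(auto_window(e), brute(e))
  }
})

test_that("select_concentrations auto mode uses sorted cycles and the E rule", {
  ser <- simulate_series(sim_spec())
  expect_equal(select_concentrations(ser), 1:5)
  expect_error(select_concentrations(toy_series(concs = c(4e-8, 1e-8, 2e-8))),
               "sorted ascending")
})

test_that("manual selection picks the named concentrations and rejects unknown ones", {
  ser <- simulate_series(sim_spec())
  concs <- vapply(ser$cycles, function(cy) cy$conc, numeric(1))
  sel <- select_concentrations(ser, mode = "manual", manual = concs[c(2, 5)])
  expect_equal(sel, c(2L, 5L))
  expect_error(select_concentrations(ser, mode = "manual", manual = 3.14e-7),
               "not found")
})

test_that("fit windows respect skip intervals and the dissociation fit length", {
  ser <- simulate_series(sim_spec(n_conc = 3))
  w0 <- extract_fit_windows(ser, 1:3)
  sch <- ser$cycles[[1]]$schedule
  expect_equal(min(w0[[1]]$assoc_time), sch$t0)
  expect_equal(max(w0[[1]]$assoc_time), sch$t_asso)
  expect_equal(max(w0[[1]]$dissoc_time), sch$dissoc_end)

  w <- extract_fit_windows(ser, 1:3, skip_dissoc = 5, dissoc_fit_len = 300)
  for (k in 1:3) {
    expect_gte(min(w[[k]]$dissoc_time), w[[k]]$t_asso + 5)
    expect_lte(max(w[[k]]$dissoc_time), w[[k]]$t_asso + 300)
  }
  expect_error(extract_fit_windows(ser, 1:3, skip_dissoc = 800,
                                   dissoc_fit_len = 900),
               "cycle 1.*dissociation")
})

test_that("subtracting a zero blank then fitting reproduces the no-blank result", {
  ser <- simulate_series(sim_spec(n_conc = 4, blank = TRUE))
  plain <- simulate_series(sim_spec(n_conc = 4))
  sub <- subtract_blank(ser)
  for (i in 1:4) {
    expect_equal(sub$cycles[[i]]$response, plain$cycles[[i]]$response)
  }
})
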