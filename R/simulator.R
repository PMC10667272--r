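with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Specification for a simulated titration
#'
#' Describes a synthetic titration generated from the 1:1 Langmuir model:
#' truth parameters, the analyte dilution series, the phase schedule, the
#' sampling rate, whether cycles are regenerative, and the pointwise Gaussian
#' noise level. Defaults mirror a typical high-throughput SPRi titration: 8
#' two-fold dilutions topping at 1 uM, 120 s baseline / 300 s association /
#' 750 s dissociation per cycle, sampled at 0.5 Hz.
#'
#' @param ka,kd,rmax Truth values: association rate (M^-1 s^-1), dissociation
#'   rate (s^-1), maximal response (response units).
#' @param concentrations Analyte concentrations (M), ascending. Defaults to
#'   `top / factor^((n_conc-1):0)`.
#' @param top,factor,n_conc Dilution-series shorthand used when
#'   `concentrations` is `NULL`.
#' @param baseline_len,assoc_len,dissoc_len Phase lengths (s).
#' @param rate_hz Sampling rate (points per second).
#' @param regenerative `TRUE` for independent cycles from a zero baseline;
#'   `FALSE` for a single-cycle titration in which response accumulates and
#'   cycles are emitted on one stitched clock.
#' @param noise_sd Standard deviation of i.i.d. Gaussian noise added to every
#'   point (response units); 0 for noise-free data.
#' @param rshift,rdrift Optional per-cycle bulk-shift and dissociation-drift
#'   amplitudes.
#' @param blank Emit an additional zero-concentration blank cycle.
#' @param seed Integer seed for the noise generator.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(ka = 1e5, kd = 1e-4, rmax = 100,
                     concentrations = NULL, top = 1e-6, factor = 2,
                     n_conc = 8, baseline_len = 120, assoc_len = 300,
                     dissoc_len = 750, rate_hz = 0.5, regenerative = TRUE,
                     noise_sd = 0, rshift = NULL, rdrift = NULL,
                     blank = FALSE, seed = 1L) {
  stopifnot(ka > 0, kd > 0, rmax > 0, baseline_len > 0, assoc_len > 0,
            dissoc_len > 0, rate_hz > 0, noise_sd >= 0)
  if (is.null(concentrations)) {
    concentrations <- top / factor^((n_conc - 1):0)
  }
  stopifnot(all(concentrations > 0))
  s <- list(ka = ka, kd = kd, rmax = rmax,
            concentrations = as.numeric(concentrations),
            baseline_len = baseline_len, assoc_len = assoc_len,
            dissoc_len = dissoc_len, rate_hz = rate_hz,
            regenerative = isTRUE(regenerative), noise_sd = noise_sd,
            rshift = rshift, rdrift = rdrift, blank = isTRUE(blank),
            seed = as.integer(seed))
  class(s) <- "sim_spec"
  s
}

#' Simulate a titration series from the 1:1 model
#'
#' Regenerative mode: every cycle is generated independently from a zero
#' baseline, association by [eval_association()] and dissociation by
#' [eval_dissociation()], each cycle on its own clock starting at 0.
#'
#' Non-regenerative mode: cycles are emitted contiguously on one stitched
#' clock and the bound analyte accumulates. Cycle `i`'s baseline continues the
#' previous cycle's dissociation decay, and its association starts from that
#' accumulated response. This is implemented by solving the association
#' equation for the extrapolated zero-response time `t0_i` that reproduces the
#' starting response, so the generated data are exactly representable by the
#' fitted single-cycle model (and the stitched trace is continuous at every
#' junction before noise).
#'
#' Gaussian noise of sd `noise_sd` is then added pointwise under the spec's
#' seed (the global RNG state is left untouched). An optional blank cycle
#' (concentration 0) is emitted as pure noise.
#'
#' @param spec A [sim_spec()].
#' @param series_id Identifier for the generated series.
#' @return A [titration_series()] with schedules attached.
#' @export
simulate_series <- function(spec, series_id = "sim") {
  stopifnot(inherits(spec, "sim_spec"))
  concs <- spec$concentrations
  n <- length(concs)
  dt <- 1 / spec$rate_hz
  d_cycle <- spec$baseline_len + spec$assoc_len + spec$dissoc_len
  n_pts <- floor(d_cycle / dt) + 1L
  rel_t <- seq(0, by = dt, length.out = n_pts)

  per_cycle_amp <- function(x, i) if (is.null(x)) 0 else rep_len(x, n)[i]

  cycles <- vector("list", n)
  if (spec$regenerative) {
    for (i in seq_len(n)) {
      t0 <- spec$baseline_len
      t_asso <- t0 + spec$assoc_len
      p <- kinetics_params(spec$ka, spec$kd, spec$rmax,
                           rshift = per_cycle_amp(spec$rshift, i),
                           rdrift = per_cycle_amp(spec$rdrift, i), t0 = t0)
      resp <- numeric(n_pts)
      a_sel <- rel_t >= t0 & rel_t <= t_asso
      d_sel <- rel_t > t_asso
      resp[a_sel] <- eval_association(p, concs[i], rel_t[a_sel])
      resp[d_sel] <- eval_dissociation(p, concs[i], rel_t[d_sel], t_asso)
      cycles[[i]] <- titration_cycle(
        index = i, conc = concs[i], time = rel_t, response = resp,
        schedule = phase_schedule(0, t0, t_asso, rel_t[n_pts])
      )
    }
  } else {
    if (is.unsorted(concs, strictly = TRUE)) {
      stop("non-regenerative simulation requires strictly ascending concentrations")
    }
    prev_amp <- 0
    prev_t_asso <- -Inf
    for (i in seq_len(n)) {
      offset <- (i - 1) * (rel_t[n_pts] + dt)
      tt <- rel_t + offset
      t0 <- offset + spec$baseline_len
      t_asso <- t0 + spec$assoc_len
      kobs <- spec$ka * concs[i] + spec$kd
      plateau <- spec$rmax * spec$ka * concs[i] / kobs
      carry <- if (i == 1) 0 else prev_amp * exp(-spec$kd * (t0 - prev_t_asso))
      if (carry >= plateau) {
        stop(sprintf("cycle %d: accumulated response %.3g exceeds plateau %.3g; cannot titrate upward",
                     i, carry, plateau))
      }
      # extrapolated zero-response start that reproduces the carried response
      t0i <- t0 + log(1 - carry / plateau) / kobs
      p <- kinetics_params(spec$ka, spec$kd, spec$rmax, t0 = t0i)
      resp <- numeric(n_pts)
      b_sel <- tt < t0
      a_sel <- tt >= t0 & tt <= t_asso
      d_sel <- tt > t_asso
      resp[b_sel] <- if (i == 1) 0 else
        prev_amp * exp(-spec$kd * (tt[b_sel] - prev_t_asso))
      resp[a_sel] <- eval_association(p, concs[i], tt[a_sel])
      resp[d_sel] <- eval_dissociation(p, concs[i], tt[d_sel], t_asso)
      prev_amp <- eval_dissociation(p, concs[i], t_asso, t_asso)
      prev_t_asso <- t_asso
      cycles[[i]] <- titration_cycle(
        index = i, conc = concs[i], time = tt, response = resp,
        schedule = phase_schedule(offset, t0, t_asso, tt[n_pts])
      )
    }
  }

  blank <- NULL
  if (spec$blank) {
    offset <- if (spec$regenerative) 0 else
      n * (rel_t[n_pts] + dt)
    tt <- rel_t + offset
    blank <- titration_cycle(
      index = n + 1L, conc = 0, time = tt, response = numeric(n_pts),
      schedule = phase_schedule(offset, offset + spec$baseline_len,
                                offset + spec$baseline_len + spec$assoc_len,
                                tt[n_pts])
    )
  }

  if (spec$noise_sd > 0) {
    with_seed(spec$seed, {
      cycles <- lapply(cycles, function(cyc) {
        cyc$response <- cyc$response +
          stats::rnorm(length(cyc$response), sd = spec$noise_sd)
        cyc
      })
      if (!is.null(blank)) {
        blank$response <- blank$response +
          stats::rnorm(length(blank$response), sd = spec$noise_sd)
      }
    })
  }

  titration_series(series_id = series_id, cycles = cycles,
                   ligand = "sim-ligand", analyte = "sim-analyte",
                   platform = "generic", regenerative = spec$regenerative,
                   blank = blank)
}

#' Write a ready-to-fit fixture bundle
#'
#' Simulates a series and writes the pair of files the batch driver consumes:
#' a canonical sensorgram table (`data.csv`) and a matching sample sheet
#' (`samples.csv`). The bundle exercises the full pipeline end to end.
#'
#' @param spec A [sim_spec()].
#' @param dir Output directory (created if needed).
#' @param series_id Series identifier used in both files.
#' @param global_rmax Sample-sheet preference: fit a shared Rmax.
#' @return Named list with the `data` and `samples` paths, invisibly.
#' @export
write_fixture_bundle <- function(spec, dir, series_id = "sim",
                                 global_rmax = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ser <- simulate_series(spec, series_id = series_id)
  data_path <- file.path(dir, "data.csv")
  write_canonical_table(list(ser), data_path)
  concs <- spec$concentrations
  blank_idx <- ""
  if (spec$blank) {
    concs <- c(concs, 0)
    blank_idx <- as.character(length(concs))
  }
  sheet_path <- file.path(dir, "samples.csv")
  writeLines(c(
    paste("location", "series_id", "ligand", "analyte", "concentrations",
          "conc_unit", "regenerative", "baseline_len", "assoc_len",
          "dissoc_fit_len", "skip_assoc", "skip_dissoc", "selection_mode",
          "manual_concs", "global_rmax", "bulk_shift", "drift", "blank_cycle",
          "align", sep = ","),
    # simulator output is baseline-aligned by construction: align=false
    paste(series_id, series_id, ser$ligand, ser$analyte,
          paste(sprintf("%.15g", concs), collapse = ";"), "M",
          tolower(spec$regenerative), sprintf("%.15g", spec$baseline_len),
          sprintf("%.15g", spec$assoc_len), sprintf("%.15g", spec$dissoc_len),
          "0", "0", "auto", "", tolower(isTRUE(global_rmax)), "false",
          "false", blank_idx, "false", sep = ",")
  ), sheet_path)
  invisible(list(data = data_path, samples = sheet_path))
}
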