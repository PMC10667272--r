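windows_residual_fn <- function(windows, variant, t0_fixed) {
  n <- length(windows)
  obs <- unlist(lapply(windows, function(w) c(w$assoc_response,
                                              w$dissoc_response)))
  function(vec) {
    p <- unpack_parameters(vec, variant, n, t0_fixed = t0_fixed)
    pred <- unlist(lapply(seq_len(n), function(i) {
      pr <- predict_cycle(p, windows[[i]]$conc, windows[[i]], i)
      c(pr$assoc, pr$dissoc)
    }))
    obs - pred
  }
}

#' Initial parameter guess for the global 1:1 fit
#'
#' Deterministic initialization: `kd0` comes from the slope of a log-linear
#' regression on the last half of the highest-concentration dissociation
#' window (floored at 1e-6 s^-1); `ka0` from a coarse grid over
#' `log10(ka) = 2..7`, scoring the sum of squares with the amplitude(s) solved
#' linearly at each grid point (variable projection); `Rmax0` is 1.5 times the
#' largest observed response; shift/drift terms start at 0. In regenerative
#' fits each `t0_i` is the scheduled association start; in non-regenerative
#' fits it is extrapolated from the response carried into the cycle (the first
#' association response), by inverting the association equation at the
#' initial rates — starting at the scheduled `t0` would begin on a shallow
#' local plateau of the objective for accumulating titrations.
#'
#' @param windows A `fit_windows` list from [extract_fit_windows()], ordered
#'   by ascending concentration.
#' @param variant A [model_variant()].
#' @return A [kinetics_params()] starting point.
#' @export
initial_guess <- function(windows, variant) {
  all_resp <- unlist(lapply(windows, function(w) c(w$assoc_response,
                                                   w$dissoc_response)))
  if (all(all_resp == 0)) stop("no signal: all responses are zero")
  n <- length(windows)

  hi <- windows[[n]]
  mid <- (min(hi$dissoc_time) + max(hi$dissoc_time)) / 2
  sel <- hi$dissoc_time >= mid & hi$dissoc_response > 0
  kd0 <- 1e-3
  if (sum(sel) >= 2) {
    slope <- stats::coef(stats::lm(log(hi$dissoc_response[sel]) ~
                                     hi$dissoc_time[sel]))[2]
    kd0 <- max(-slope, 1e-6)
    if (!is.finite(kd0)) kd0 <- 1e-3
  }

  rmax_guess <- 1.5 * max(all_resp)
  guess_t0 <- function(w, ka, kd) {
    if (variant$regenerative) return(w$t0)
    kobs <- ka * w$conc + kd
    plateau <- rmax_guess * ka * w$conc / kobs
    carry <- w$assoc_response[1]
    if (!is.finite(carry) || carry <= 0 || carry >= 0.999 * plateau) {
      return(w$t0)
    }
    max(w$t0 + log(1 - carry / plateau) / kobs,
        w$t0 - 10 * (w$t_asso - w$t0))
  }

  score_ka <- function(ka) {
    rss <- 0
    amp_basis <- lapply(windows, function(w) {
      kobs <- ka * w$conc + kd0
      occ <- ka * w$conc / kobs
      t0i <- guess_t0(w, ka, kd0)
      b_a <- occ * (1 - exp(-kobs * (w$assoc_time - t0i)))
      b_d <- occ * (1 - exp(-kobs * (w$t_asso - t0i))) *
        exp(-kd0 * (w$dissoc_time - w$t_asso))
      list(b = c(b_a, b_d), y = c(w$assoc_response, w$dissoc_response))
    })
    if (variant$global_rmax) {
      b <- unlist(lapply(amp_basis, `[[`, "b"))
      y <- unlist(lapply(amp_basis, `[[`, "y"))
      a <- sum(b * y) / max(sum(b * b), .Machine$double.eps)
      rss <- sum((y - a * b)^2)
    } else {
      for (ab in amp_basis) {
        a <- sum(ab$b * ab$y) / max(sum(ab$b * ab$b), .Machine$double.eps)
        rss <- rss + sum((ab$y - a * ab$b)^2)
      }
    }
    rss
  }
  grid <- 2:7
  ka0 <- 10^grid[which.min(vapply(10^grid, score_ka, numeric(1)))]

  kinetics_params(
    ka = ka0, kd = kd0,
    rmax = rep(rmax_guess, if (variant$global_rmax) 1L else n),
    rshift = if (variant$bulk_shift) rep(0, n) else NULL,
    rdrift = if (variant$drift) rep(0, n) else NULL,
    t0 = vapply(windows, guess_t0, numeric(1), ka = ka0, kd = kd0)
  )
}

numeric_jacobian <- function(fn, x, eps = 1e-6) {
  f0 <- fn(x)
  J <- matrix(0, nrow = length(f0), ncol = length(x))
  for (j in seq_along(x)) {
    h <- eps * max(1, abs(x[j]))
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    J[, j] <- (fn(xp) - fn(xm)) / (2 * h)
  }
  J
}

#' Standard errors from the Jacobian at the optimum
#'
#' Classical nonlinear least squares errors: the parameter covariance is
#' `(rss/dof) * (J^T J)^{-1}` and standard errors are the square roots of its
#' diagonal. A rank-deficient `J^T J` (over-parameterized model) yields `NA`
#' standard errors and a diagnostics flag rather than an error.
#'
#' @param jacobian Jacobian of the residual vector at the optimum (rows =
#'   residuals, columns = packed parameters).
#' @param rss Residual sum of squares at the optimum.
#' @param dof Degrees of freedom (`n_points - n_parameters`), >= 1.
#' @return List with `se` (per packed parameter, `NA` when unavailable) and
#'   `rank_deficient` flag.
#' @export
compute_standard_errors <- function(jacobian, rss, dof) {
  stopifnot(dof >= 1)
  jtj <- crossprod(jacobian)
  inv <- tryCatch(solve(jtj), error = function(e) NULL)
  if (is.null(inv) || any(!is.finite(diag(inv))) || any(diag(inv) < 0)) {
    return(list(se = rep(NA_real_, ncol(jacobian)), rank_deficient = TRUE))
  }
  list(se = sqrt(pmax(diag(inv), 0) * rss / dof), rank_deficient = FALSE)
}

#' Equilibrium constant with propagated error
#'
#' `KD = kd/ka`, with its standard error propagated from the rate-constant
#' standard errors as
#' `Delta_KD = KD * sqrt((Delta_ka/ka)^2 + (Delta_kd/kd)^2)`.
#'
#' @param ka,kd Rate-constant estimates (> 0).
#' @param se_ka,se_kd Their standard errors (>= 0).
#' @return List with `KD` and `SE_KD` (molar).
#' @export
propagate_kd <- function(ka, kd, se_ka, se_kd) {
  if (!(is.finite(ka) && ka > 0 && is.finite(kd) && kd > 0)) {
    stop("ka and kd must be positive and finite")
  }
  if (is.na(se_ka) || is.na(se_kd)) {
    return(list(KD = kd / ka, SE_KD = NA_real_))
  }
  stopifnot(se_ka >= 0, se_kd >= 0)
  kD <- kd / ka
  list(KD = kD, SE_KD = kD * sqrt((se_ka / ka)^2 + (se_kd / kd)^2))
}

#' Globally fit a titration series to the 1:1 Langmuir model
#'
#' Minimizes the pooled sum of squared residuals over the association and
#' dissociation windows of all selected cycles, by Levenberg-Marquardt least
#' squares on the packed log-scale parameter vector (rates in log10 space;
#' per-cycle `t0_i` bounded to `[t0 - 10*(t_asso - t0), t0]` in
#' non-regenerative fits). Initialization is the deterministic
#' [initial_guess()]; identical inputs and configuration therefore give
#' bit-identical results. Non-convergence is reported through
#' `converged = FALSE` on the result, never as an error.
#'
#' The series is expected to be preprocessed (baseline-aligned, optionally
#' blank-subtracted, optionally thinned); sorting, concentration
#' down-selection and window extraction are performed here according to
#' `config`.
#'
#' @param series A preprocessed [titration_series()] with schedules attached.
#' @param config A [sample_entry()] carrying the fit preferences. Defaults to
#'   an auto-selection entry spanning each cycle's full declared phases.
#' @return An object of class `kin_fit`: kinetics estimates (`params`),
#'   standard errors (`se_ka`, `se_kd`, `se_rmax`, ...), `kD`/`se_kD`,
#'   residuals, `rss`, `dof`, `n_points`, convergence flag, the selected
#'   cycles and a `config` echo.
#' @export
fit_series <- function(series, config = NULL) {
  msgs <- validate_series(series)
  if (length(msgs) > 0) {
    stop(sprintf("invalid series %s: %s", series$series_id,
                 paste(msgs, collapse = "; ")))
  }
  if (is.null(config)) {
    sch1 <- series$cycles[[1]]$schedule
    if (is.null(sch1)) stop("series has no schedules; attach them first")
    config <- sample_entry(
      location = series$series_id, concentrations = cycle_concs(series),
      conc_unit = "M", regenerative = series$regenerative,
      baseline_len = sch1$t0 - sch1$baseline_start,
      assoc_len = sch1$t_asso - sch1$t0,
      dissoc_fit_len = sch1$dissoc_end - sch1$t_asso
    )
  }
  series <- sort_cycles(series)
  selected <- select_concentrations(
    series, mode = config$selection_mode, manual = config$manual_concs,
    skip_assoc = config$skip_assoc
  )
  windows <- extract_fit_windows(
    series, selected, skip_assoc = config$skip_assoc,
    skip_dissoc = config$skip_dissoc, dissoc_fit_len = config$dissoc_fit_len
  )
  variant <- model_variant(
    regenerative = series$regenerative, global_rmax = config$global_rmax,
    bulk_shift = config$bulk_shift, drift = config$drift
  )
  dose_response <- data.frame(
    conc = cycle_concs(series),
    response = end_of_association(series, skip_assoc = config$skip_assoc),
    selected = seq_along(series$cycles) %in% selected
  )
  fit_windows_set(windows, variant, series = series, config = config,
                  selected = selected, dose_response = dose_response)
}

fit_windows_set <- function(windows, variant, series = NULL, config = NULL,
                            selected = integer(0), dose_response = NULL) {
  n <- length(windows)
  t0_fixed <- vapply(windows, function(w) w$t0, numeric(1))
  n_points <- sum(vapply(windows, function(w)
    length(w$assoc_time) + length(w$dissoc_time), numeric(1)))
  p0 <- initial_guess(windows, variant)
  v0 <- pack_parameters(p0, variant, n)
  n_par <- length(v0)
  dof <- n_points - n_par
  if (dof < 1) stop("insufficient degrees of freedom: fewer points than parameters")

  lower <- rep(-Inf, n_par)
  upper <- rep(Inf, n_par)
  lower[1:2] <- c(-3, -12)   # log10 ka, log10 kd
  upper[1:2] <- c(12, 3)
  if (!variant$regenerative) {
    slots <- (n_par - n + 1L):n_par
    t_asso <- vapply(windows, function(w) w$t_asso, numeric(1))
    lower[slots] <- t0_fixed - 10 * (t_asso - t0_fixed)
    upper[slots] <- t0_fixed
  }

  resid_fn <- windows_residual_fn(windows, variant, t0_fixed)
  fit <- minpack.lm::nls.lm(
    par = v0, fn = resid_fn, lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(
      ftol = 1e-10, ptol = 1e-10, gtol = 1e-10,
      maxfev = 2000, maxiter = 1000
    )
  )
  v_hat <- fit$par
  res <- resid_fn(v_hat)
  rss <- sum(res^2)
  converged <- fit$info %in% 1:4

  J <- numeric_jacobian(resid_fn, v_hat)
  se <- compute_standard_errors(J, rss, dof)
  p_hat <- unpack_parameters(v_hat, variant, n, t0_fixed = t0_fixed)

  # delta method: packed rates are log10, se_linear = ln(10) * value * se_log10
  se_ka <- log(10) * p_hat$ka * se$se[1]
  se_kd <- log(10) * p_hat$kd * se$se[2]
  n_rmax <- if (variant$global_rmax) 1L else n
  se_rmax <- se$se[3:(2 + n_rmax)]
  kd_prop <- propagate_kd(p_hat$ka, p_hat$kd, se_ka, se_kd)

  # per-cycle residuals, split back
  residuals <- list()
  pos <- 1L
  for (i in seq_len(n)) {
    na <- length(windows[[i]]$assoc_time)
    nd <- length(windows[[i]]$dissoc_time)
    residuals[[i]] <- list(
      index = windows[[i]]$index,
      assoc = res[pos:(pos + na - 1L)],
      dissoc = res[(pos + na):(pos + na + nd - 1L)]
    )
    pos <- pos + na + nd
  }

  out <- list(
    series_id = if (is.null(series)) "" else series$series_id,
    ligand = if (is.null(series)) "" else series$ligand,
    analyte = if (is.null(series)) "" else series$analyte,
    params = p_hat, variant = variant,
    se_ka = se_ka, se_kd = se_kd, se_rmax = se_rmax,
    kD = kd_prop$KD, se_kD = kd_prop$SE_KD,
    n_points = as.integer(n_points), rss = rss, dof = as.integer(dof),
    residuals = residuals, converged = converged,
    rank_deficient = se$rank_deficient,
    optimizer_info = fit$info, optimizer_message = fit$message,
    selected = selected,
    selected_concs = vapply(windows, function(w) w$conc, numeric(1)),
    windows = windows, config = config, dose_response = dose_response
  )
  class(out) <- "kin_fit"
  out
}

#' @export
print.kin_fit <- function(x, ...) {
  cat(sprintf("<kin_fit> %s (%s vs %s)%s\n", x$series_id, x$ligand, x$analyte,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat(sprintf("  ka = %.3e +/- %.2e M^-1 s^-1\n", x$params$ka, x$se_ka))
  cat(sprintf("  kd = %.3e +/- %.2e s^-1\n", x$params$kd, x$se_kd))
  cat(sprintf("  KD = %.3e +/- %.2e M\n", x$kD, x$se_kD))
  cat(sprintf("  Rmax = %s\n",
              paste(sprintf("%.4g", x$params$rmax), collapse = ", ")))
  cat(sprintf("  n = %d points, rss = %.4g, dof = %d\n",
              x$n_points, x$rss, x$dof))
  invisible(x)
}

#' Summarize replicate fits
#'
#' For each kinetics parameter (`ka`, `kd`, `KD`) across replicate fits of the
#' same interaction: the arithmetic mean, the percent coefficient of variation
#' (100 * sample sd / mean), the fold range (max/min) and each replicate's
#' relative standard error (SE/estimate).
#'
#' @param results A list of `kin_fit` objects (>= 2), or a data frame as
#'   returned by [read_estimates_table()].
#' @return An object of class `replicate_summary` with a `table` data frame
#'   (parameter, mean, cv_pct, fold) and a `rel_se` matrix (replicates x
#'   parameters).
#' @export
summarize_replicates <- function(results) {
  if (is.data.frame(results)) {
    est <- results[, c("ka", "kd", "KD")]
    ses <- results[, c("SE_ka", "SE_kd", "SE_KD")]
  } else {
    est <- data.frame(
      ka = vapply(results, function(r) r$params$ka, numeric(1)),
      kd = vapply(results, function(r) r$params$kd, numeric(1)),
      KD = vapply(results, function(r) r$kD, numeric(1))
    )
    ses <- data.frame(
      SE_ka = vapply(results, function(r) r$se_ka, numeric(1)),
      SE_kd = vapply(results, function(r) r$se_kd, numeric(1)),
      SE_KD = vapply(results, function(r) r$se_kD, numeric(1))
    )
  }
  if (nrow(est) < 2) stop("replicate summary requires at least 2 results")
  tab <- data.frame(
    parameter = c("ka", "kd", "KD"),
    mean = vapply(est, mean, numeric(1)),
    cv_pct = vapply(est, function(x) 100 * stats::sd(x) / mean(x), numeric(1)),
    fold = vapply(est, function(x) max(x) / min(x), numeric(1)),
    row.names = NULL
  )
  rel <- as.matrix(ses) / as.matrix(est)
  colnames(rel) <- c("ka", "kd", "KD")
  out <- list(table = tab, rel_se = rel, n = nrow(est))
  class(out) <- "replicate_summary"
  out
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat(sprintf("<replicate_summary> %d replicates\n", x$n))
  print(transform(x$table, mean = signif(mean, 4), cv_pct = round(cv_pct, 1),
                  fold = round(fold, 2)), row.names = FALSE)
  invisible(x)
}
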