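#' Model variant flags for the 1:1 Langmuir fit
#'
#' The 1:1 interaction model comes in variants controlled by four switches.
#' Bulk shift and dissociation drift are mutually exclusive nuisance terms:
#' fitting both per cycle would over-parameterize the model, so the drift term
#' is dropped whenever the shift term is included.
#'
#' @param regenerative `TRUE`: association start times `t0` are fixed per
#'   cycle from the schedule. `FALSE`: a per-cycle `t0_i` (the extrapolated
#'   time at which the response would be zero) is floated, absorbing the
#'   response accumulated over earlier cycles of a single-cycle titration.
#' @param global_rmax `TRUE`: one shared maximal response `Rmax`; `FALSE`:
#'   one `Rmax_i` per cycle.
#' @param bulk_shift Include a per-cycle bulk-shift offset `Rshift_i`, active
#'   only during association (buffer-mismatch step artifact).
#' @param drift Include a per-cycle dissociation-onset amplitude `Rdrift_i`
#'   (e.g. loss of non-specifically bound analyte).
#'
#' @return An object of class `model_variant`.
#' @export
model_variant <- function(regenerative = TRUE, global_rmax = FALSE,
                          bulk_shift = FALSE, drift = FALSE) {
  if (isTRUE(bulk_shift) && isTRUE(drift)) {
    stop("bulk_shift and drift are mutually exclusive: ",
         "the drift term is dropped when the shift term is included")
  }
  v <- list(
    regenerative = isTRUE(regenerative),
    global_rmax = isTRUE(global_rmax),
    bulk_shift = isTRUE(bulk_shift),
    drift = isTRUE(drift)
  )
  class(v) <- "model_variant"
  v
}

#' Kinetics parameter set
#'
#' The full parameter vector of the 1:1 model: shared rate constants plus
#' per-cycle amplitudes and nuisance terms. Per-cycle vectors must have one
#' entry per selected cycle.
#'
#' @param ka Association rate constant (M^-1 s^-1), > 0.
#' @param kd Dissociation rate constant (s^-1), > 0.
#' @param rmax Maximal response: length 1 when `Rmax` is global, otherwise one
#'   value per cycle.
#' @param rshift Per-cycle bulk-shift offsets (response units); `NULL` or 0
#'   when the bulk-shift term is off.
#' @param rdrift Per-cycle dissociation-onset amplitudes; `NULL` or 0 when the
#'   drift term is off.
#' @param t0 Per-cycle association start times (s): fixed schedule values for
#'   regenerative fits, floated extrapolated zero-response times otherwise.
#'
#' @return An object of class `kinetics_params`.
#' @export
kinetics_params <- function(ka, kd, rmax, rshift = NULL, rdrift = NULL, t0) {
  stopifnot(is.finite(ka), ka > 0, is.finite(kd), kd > 0)
  p <- list(ka = ka, kd = kd, rmax = rmax, rshift = rshift, rdrift = rdrift,
            t0 = t0)
  class(p) <- "kinetics_params"
  p
}

param_for_cycle <- function(x, i) {
  if (is.null(x)) return(0)
  if (length(x) == 1) return(x)
  x[i]
}

#' Evaluate the association phase model
#'
#' Response during association for cycle slot `i`:
#' `R(t) = Rshift_i + Rmax_i * (ka*C / (ka*C + kd)) * (1 - exp(-(ka*C + kd) * (t - t0_i)))`.
#'
#' @param p A [kinetics_params()].
#' @param conc Analyte concentration of the cycle (M).
#' @param t Vector of absolute times (s), `t >= t0_i`.
#' @param i Cycle slot (position among the selected cycles), used to pick the
#'   per-cycle parameters.
#' @return Vector of model responses.
#' @export
eval_association <- function(p, conc, t, i = 1) {
  kobs <- p$ka * conc + p$kd
  if (kobs <= 0) stop("degenerate rate: ka*C + kd must be positive")
  t0i <- param_for_cycle(p$t0, i)
  occ <- p$ka * conc / kobs
  param_for_cycle(p$rshift, i) +
    param_for_cycle(p$rmax, i) * occ * (1 - exp(-kobs * (t - t0i)))
}

#' Evaluate the dissociation phase model (multiplicative-drift form)
#'
#' Response during dissociation for cycle slot `i`:
#' `R(t) = (Rmax_i + Rdrift_i) * (ka*C / (ka*C + kd)) *
#'   (1 - exp(-(ka*C + kd) * (t_asso - t0_i))) * exp(-kd * (t - t_asso))`.
#' This is the form used in fitting; it coincides with the legacy additive
#' form ([eval_dissociation_legacy()]) when `Rdrift_i = 0`, and is numerically
#' better behaved when the drift term is floated.
#'
#' @inheritParams eval_association
#' @param t_asso Absolute association end time of the cycle (s).
#' @return Vector of model responses.
#' @export
eval_dissociation <- function(p, conc, t, t_asso, i = 1) {
  kobs <- p$ka * conc + p$kd
  if (kobs <= 0) stop("degenerate rate: ka*C + kd must be positive")
  t0i <- param_for_cycle(p$t0, i)
  occ <- p$ka * conc / kobs
  (param_for_cycle(p$rmax, i) + param_for_cycle(p$rdrift, i)) * occ *
    (1 - exp(-kobs * (t_asso - t0i))) * exp(-p$kd * (t - t_asso))
}

#' Evaluate the legacy additive-drift dissociation model
#'
#' `R(t) = Rdrift_i + Rmax_i * occ * (1 - exp(-(ka*C + kd)*(t_asso - t0_i))) *
#' exp(-kd*(t - t_asso))`: the drift enters as a constant offset instead of an
#' extra decaying amplitude. Provided for comparison; not used in fitting.
#'
#' @inheritParams eval_dissociation
#' @return Vector of model responses.
#' @export
eval_dissociation_legacy <- function(p, conc, t, t_asso, i = 1) {
  kobs <- p$ka * conc + p$kd
  if (kobs <= 0) stop("degenerate rate: ka*C + kd must be positive")
  t0i <- param_for_cycle(p$t0, i)
  occ <- p$ka * conc / kobs
  param_for_cycle(p$rdrift, i) + param_for_cycle(p$rmax, i) * occ *
    (1 - exp(-kobs * (t_asso - t0i))) * exp(-p$kd * (t - t_asso))
}

n_parameters <- function(variant, n_cycles) {
  2L +
    (if (variant$global_rmax) 1L else n_cycles) +
    (if (variant$bulk_shift) n_cycles else 0L) +
    (if (variant$drift) n_cycles else 0L) +
    (if (variant$regenerative) 0L else n_cycles)
}

#' Pack kinetics parameters into an optimizer vector
#'
#' Maps a [kinetics_params()] onto the flat numeric vector seen by the least
#' squares optimizer. Rate constants are carried as log10 values, which keeps
#' them positive by construction and puts the decades spanned by typical
#' affinities on a comparable scale. The mapping is bijective for a given
#' variant and cycle count.
#'
#' @param p A [kinetics_params()].
#' @param variant A [model_variant()].
#' @param n_cycles Number of selected cycles.
#' @param t0_fixed Per-cycle schedule `t0` values, required to pack/unpack
#'   regenerative parameter sets (where `t0` is fixed, not in the vector).
#' @return Numeric parameter vector.
#' @export
pack_parameters <- function(p, variant, n_cycles, t0_fixed = p$t0) {
  v <- c(log10(p$ka), log10(p$kd))
  v <- c(v, if (variant$global_rmax) p$rmax[1] else rep_len(p$rmax, n_cycles))
  if (variant$bulk_shift) v <- c(v, rep_len(if (is.null(p$rshift)) 0 else p$rshift, n_cycles))
  if (variant$drift) v <- c(v, rep_len(if (is.null(p$rdrift)) 0 else p$rdrift, n_cycles))
  if (!variant$regenerative) v <- c(v, rep_len(p$t0, n_cycles))
  v
}

#' @rdname pack_parameters
#' @param vec Packed numeric vector of the length implied by `variant` and
#'   `n_cycles`.
#' @export
unpack_parameters <- function(vec, variant, n_cycles, t0_fixed = NULL) {
  expected <- n_parameters(variant, n_cycles)
  if (length(vec) != expected) {
    stop(sprintf("internal error: parameter vector length %d, expected %d",
                 length(vec), expected))
  }
  pos <- 3L
  take <- function(k) {
    out <- vec[pos:(pos + k - 1L)]
    pos <<- pos + k
    out
  }
  rmax <- if (variant$global_rmax) take(1L) else take(n_cycles)
  rshift <- if (variant$bulk_shift) take(n_cycles) else NULL
  rdrift <- if (variant$drift) take(n_cycles) else NULL
  t0 <- if (!variant$regenerative) take(n_cycles) else {
    if (is.null(t0_fixed)) stop("t0_fixed required for regenerative unpacking")
    rep_len(t0_fixed, n_cycles)
  }
  kinetics_params(ka = 10^vec[1], kd = 10^vec[2], rmax = rmax,
                  rshift = rshift, rdrift = rdrift, t0 = t0)
}

#' Predict a cycle's responses over its fit windows
#'
#' Association window timestamps are evaluated with [eval_association()],
#' dissociation window timestamps with [eval_dissociation()].
#'
#' @param p A [kinetics_params()].
#' @param conc Analyte concentration (M).
#' @param window One element of the list returned by [extract_fit_windows()]:
#'   a list with `assoc_time`, `dissoc_time` and `t_asso`.
#' @param i Cycle slot among the selected cycles.
#' @return List with numeric vectors `assoc` and `dissoc`.
#' @export
predict_cycle <- function(p, conc, window, i = 1) {
  list(
    assoc = eval_association(p, conc, window$assoc_time, i),
    dissoc = eval_dissociation(p, conc, window$dissoc_time, window$t_asso, i)
  )
}
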