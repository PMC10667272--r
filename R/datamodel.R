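#' Phase schedule of a titration cycle
#'
#' Absolute timestamps (seconds, on the exported clock) delimiting the phases
#' of a single analyte cycle: start of the recorded baseline, start of
#' association (`t0`), end of association (`t_asso`) and end of the recorded
#' dissociation.
#'
#' @param baseline_start Absolute time (s) at which the recorded baseline
#'   begins. Must satisfy `baseline_start <= t0`.
#' @param t0 Absolute time (s) at which association starts.
#' @param t_asso Absolute time (s) at which association ends and dissociation
#'   begins. Must be strictly greater than `t0`.
#' @param dissoc_end Absolute time (s) at which the recorded dissociation
#'   ends. Must be strictly greater than `t_asso`.
#'
#' @return An object of class `phase_schedule`.
#' @export
phase_schedule <- function(baseline_start, t0, t_asso, dissoc_end) {
  s <- list(
    baseline_start = as.numeric(baseline_start),
    t0 = as.numeric(t0),
    t_asso = as.numeric(t_asso),
    dissoc_end = as.numeric(dissoc_end)
  )
  class(s) <- "phase_schedule"
  s
}

schedule_messages <- function(s, where = "schedule") {
  msgs <- character(0)
  vals <- unlist(s[c("baseline_start", "t0", "t_asso", "dissoc_end")])
  if (any(!is.finite(vals))) {
    return(sprintf("%s: non-finite phase timestamp", where))
  }
  if (!(s$baseline_start <= s$t0)) {
    msgs <- c(msgs, sprintf("%s: baseline_start > t0", where))
  }
  if (!(s$t0 < s$t_asso)) {
    msgs <- c(msgs, sprintf("%s: t_asso <= t0", where))
  }
  if (!(s$t_asso < s$dissoc_end)) {
    msgs <- c(msgs, sprintf("%s: dissoc_end <= t_asso", where))
  }
  msgs
}

#' A single titration cycle
#'
#' One analyte injection: the time/response trace recorded for analyte
#' concentration `conc` together with its [phase_schedule()]. Responses are
#' carried in an opaque response unit (RU for SPR, nm for BLI); the model is
#' unit-agnostic.
#'
#' @param index 1-based cycle index, matching instrument exports.
#' @param conc Analyte concentration in molar. Zero is permitted only for
#'   blank cycles.
#' @param time Numeric vector of absolute timestamps (s), strictly increasing.
#' @param response Numeric vector of reference-subtracted responses, same
#'   length as `time`.
#' @param schedule A [phase_schedule()], or `NULL` when the schedule will be
#'   attached later from the sample sheet (see [attach_schedules()]).
#'
#' @return An object of class `titration_cycle`.
#' @export
titration_cycle <- function(index, conc, time, response, schedule = NULL) {
  cyc <- list(
    index = as.integer(index),
    conc = as.numeric(conc),
    time = as.numeric(time),
    response = as.numeric(response),
    schedule = schedule
  )
  class(cyc) <- "titration_cycle"
  cyc
}

cycle_messages <- function(cyc) {
  msgs <- character(0)
  where <- sprintf("cycle %s", cyc$index)
  if (!is.numeric(cyc$index) && !is.integer(cyc$index) || length(cyc$index) != 1 ||
      is.na(cyc$index) || cyc$index < 1) {
    msgs <- c(msgs, sprintf("%s: index must be a positive integer", where))
  }
  if (length(cyc$conc) != 1 || !is.finite(cyc$conc) || cyc$conc < 0) {
    msgs <- c(msgs, sprintf("%s: concentration must be finite and >= 0", where))
  }
  if (length(cyc$time) == 0) {
    msgs <- c(msgs, sprintf("%s: empty trace", where))
  } else {
    if (length(cyc$time) != length(cyc$response)) {
      msgs <- c(msgs, sprintf("%s: time and response lengths differ", where))
    }
    if (any(diff(cyc$time) <= 0)) {
      msgs <- c(msgs, sprintf("%s: times not strictly increasing", where))
    }
  }
  if (!is.null(cyc$schedule)) {
    msgs <- c(msgs, schedule_messages(cyc$schedule, where))
  }
  msgs
}

#' A titration series: the unit of fitting
#'
#' One ligand surface's ordered set of analyte cycles, plus metadata. A blank
#' (zero-concentration) cycle, when present, is kept separately in `blank` and
#' is not part of `cycles`.
#'
#' @param series_id Identifier of the series (one ligand surface).
#' @param cycles List of [titration_cycle()] objects (non-blank).
#' @param ligand,analyte Names of the immobilized ligand and the flowed
#'   analyte.
#' @param platform One of `"generic"`, `"carterra"`, `"biacore"`, `"octet"`.
#' @param regenerative `TRUE` when the surface is regenerated between cycles
#'   (each cycle starts from zero bound analyte); `FALSE` for
#'   non-regenerative (single-cycle) titrations where response accumulates.
#' @param blank Optional blank [titration_cycle()] with concentration 0.
#' @param response_unit Label for the response unit (default `"RU"`).
#'
#' @return An object of class `titration_series`.
#' @export
titration_series <- function(series_id, cycles, ligand = "", analyte = "",
                             platform = c("generic", "carterra", "biacore", "octet"),
                             regenerative = TRUE, blank = NULL,
                             response_unit = "RU") {
  platform <- match.arg(platform)
  ser <- list(
    series_id = as.character(series_id),
    ligand = as.character(ligand),
    analyte = as.character(analyte),
    platform = platform,
    regenerative = isTRUE(regenerative),
    cycles = cycles,
    blank = blank,
    response_unit = response_unit
  )
  class(ser) <- "titration_series"
  ser
}

#' Validate a titration series
#'
#' Checks every type invariant of the series and its cycles. Validation never
#' raises: an empty character vector means the series is well formed, and each
#' message identifies the cycle and the violated rule.
#'
#' @param series A [titration_series()].
#' @return Character vector of validation messages (empty when valid).
#' @export
validate_series <- function(series) {
  msgs <- character(0)
  if (!inherits(series, "titration_series")) {
    return("not a titration_series object")
  }
  if (length(series$cycles) < 1) {
    msgs <- c(msgs, "series must contain at least one non-blank cycle")
  }
  for (cyc in series$cycles) {
    msgs <- c(msgs, cycle_messages(cyc))
    if (length(cyc$conc) == 1 && is.finite(cyc$conc) && cyc$conc == 0) {
      msgs <- c(msgs, sprintf("cycle %s: zero concentration outside the blank slot",
                              cyc$index))
    }
  }
  concs <- vapply(series$cycles, function(cy) cy$conc[1], numeric(1))
  idx <- vapply(series$cycles, function(cy) cy$index[1], numeric(1))
  dup <- unique(concs[duplicated(concs)])
  for (d in dup[is.finite(dup)]) {
    who <- idx[concs == d]
    msgs <- c(msgs, sprintf("duplicated concentration %g M in cycles %s",
                            d, paste(who, collapse = ", ")))
  }
  if (!is.null(series$blank)) {
    msgs <- c(msgs, cycle_messages(series$blank))
    if (is.finite(series$blank$conc) && series$blank$conc != 0) {
      msgs <- c(msgs, "blank cycle concentration must be 0")
    }
  }
  msgs
}

#' Sort cycles by ascending analyte concentration
#'
#' Reorders the non-blank cycles from low to high concentration (the order
#' required before automatic concentration down-selection). The blank cycle is
#' untouched. The sort is stable.
#'
#' @param series A valid [titration_series()].
#' @return The series with `cycles` sorted by ascending concentration.
#' @export
sort_cycles <- function(series) {
  concs <- vapply(series$cycles, function(cy) cy$conc[1], numeric(1))
  series$cycles <- series$cycles[order(concs)]
  series
}

cycle_concs <- function(series) {
  vapply(series$cycles, function(cy) cy$conc[1], numeric(1))
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("<titration_series> %s: %s vs %s [%s, %s]\n",
              x$series_id, x$ligand, x$analyte, x$platform,
              if (x$regenerative) "regenerative" else "non-regenerative"))
  cat(sprintf("  %d cycle(s)%s; concentrations (M): %s\n",
              length(x$cycles),
              if (is.null(x$blank)) "" else " + blank",
              paste(signif(cycle_concs(x), 4), collapse = ", ")))
  invisible(x)
}
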