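#' Baseline-align a titration series
#'
#' Regenerative series: each cycle is shifted so that the mean response over
#' its baseline window (`[t0 - baseline_len, t0)`, or all points before `t0`
#' when `baseline_len` is `NULL`) is zero.
#'
#' Non-regenerative (single-cycle) series: cycle 1 is zeroed on its baseline as
#' above; every subsequent cycle is shifted so that the mean of its baseline
#' window equals the mean response over the final 5 s of the previous cycle's
#' dissociation, stitching the accumulated signal into a continuous trace.
#'
#' @param series A [titration_series()] whose cycles carry schedules.
#' @param baseline_len Length (s) of the baseline window before `t0` used to
#'   compute the baseline mean; `NULL` uses every point before `t0`.
#' @param anchor_len Length (s) of the terminal dissociation window used as the
#'   continuity anchor in non-regenerative mode.
#' @return The aligned series.
#' @export
align_baseline <- function(series, baseline_len = NULL, anchor_len = 5) {
  shift_cycle <- function(cyc, target) {
    sch <- cyc$schedule
    lo <- if (is.null(baseline_len)) sch$baseline_start else sch$t0 - baseline_len
    sel <- cyc$time >= lo & cyc$time < sch$t0
    if (!any(sel)) {
      stop(sprintf("cycle %s: empty baseline window, cannot align", cyc$index))
    }
    cyc$response <- cyc$response - mean(cyc$response[sel]) + target
    cyc
  }
  if (series$regenerative) {
    series$cycles <- lapply(series$cycles, shift_cycle, target = 0)
    if (!is.null(series$blank)) series$blank <- shift_cycle(series$blank, 0)
  } else {
    target <- 0
    for (j in seq_along(series$cycles)) {
      series$cycles[[j]] <- shift_cycle(series$cycles[[j]], target)
      cyc <- series$cycles[[j]]
      tail_sel <- cyc$time > cyc$schedule$dissoc_end - anchor_len &
        cyc$time <= cyc$schedule$dissoc_end
      if (!any(tail_sel)) {
        stop(sprintf("cycle %s: no points in the terminal %g s of dissociation",
                     cyc$index, anchor_len))
      }
      target <- mean(cyc$response[tail_sel])
    }
    if (!is.null(series$blank)) series$blank <- shift_cycle(series$blank, 0)
  }
  series
}

#' Subtract the blank cycle
#'
#' Subtracts the zero-concentration blank trace from every cycle pointwise on
#' the cycle-relative clock (time since the cycle's own `t0`). Blank values at
#' non-matching timestamps are obtained by linear interpolation. After
#' subtraction the blank is removed from the series. When no blank is present
#' the series is returned unchanged with a notice.
#'
#' @param series A [titration_series()] with schedules attached.
#' @return The blank-subtracted series (with `blank = NULL`).
#' @export
subtract_blank <- function(series) {
  if (is.null(series$blank)) {
    message(sprintf("series %s: no blank cycle present, skipping blank subtraction",
                    series$series_id))
    return(series)
  }
  blank <- series$blank
  brel <- blank$time - blank$schedule$t0
  series$cycles <- lapply(series$cycles, function(cyc) {
    rel <- cyc$time - cyc$schedule$t0
    if (min(rel) < min(brel) - 1e-9 || max(rel) > max(brel) + 1e-9) {
      stop(sprintf("cycle %s: blank trace does not cover the cycle window (%.6g..%.6g vs %.6g..%.6g s relative to t0)",
                   cyc$index, min(rel), max(rel), min(brel), max(brel)))
    }
    bl <- stats::approx(brel, blank$response, xout = rel, rule = 2)$y
    cyc$response <- cyc$response - bl
    cyc
  })
  series$blank <- NULL
  series
}

#' Thin a series to a target sampling rate
#'
#' Within each cycle, keeps the first point of each consecutive bin of width
#' `1/rate_hz` seconds, starting at the cycle's first timestamp. Thinning never
#' upsamples, never reorders points and never drops the first point of a
#' cycle. Used to speed up fitting of densely sampled exports (e.g. thinning
#' 10 Hz instrument data to 1 Hz).
#'
#' @param series A [titration_series()].
#' @param rate_hz Target sampling rate (points per second), > 0.
#' @return The thinned series.
#' @export
thin_to_rate <- function(series, rate_hz = 1) {
  stopifnot(is.finite(rate_hz), rate_hz > 0)
  thin <- function(cyc) {
    bins <- floor((cyc$time - cyc$time[1]) * rate_hz + 1e-9)
    keep <- !duplicated(bins)
    cyc$time <- cyc$time[keep]
    cyc$response <- cyc$response[keep]
    cyc
  }
  series$cycles <- lapply(series$cycles, thin)
  if (!is.null(series$blank)) series$blank <- thin(series$blank)
  series
}

end_of_association <- function(series, skip_assoc = 0) {
  vapply(series$cycles, function(cyc) {
    sch <- cyc$schedule
    sel <- cyc$time >= sch$t0 + skip_assoc & cyc$time <= sch$t_asso
    if (!any(sel)) {
      stop(sprintf("cycle %s: empty association window", cyc$index))
    }
    cyc$response[max(which(sel))]
  }, numeric(1))
}

#' Down-select analyte concentrations for fitting
#'
#' At most five analyte concentrations are used per fit. In `auto` mode, if
#' the series has five or fewer cycles all are selected; otherwise, over all
#' windows of 5 consecutive concentrations (sorted ascending), the window with
#' the largest accumulated increase of end-of-association response (last minus
#' first response of the window) is selected — typically the part of the dose
#' response closest to its linear range. Ties go to the lowest-concentration
#' window. In `manual` mode the user's concentrations (at most 5) are selected
#' verbatim.
#'
#' @param series A [titration_series()] with cycles sorted ascending by
#'   concentration (see [sort_cycles()]) and schedules attached.
#' @param mode `"auto"` or `"manual"`.
#' @param manual Numeric vector (length <= 5) of concentrations (M) to select
#'   in manual mode; each must match a cycle concentration.
#' @param skip_assoc Seconds skipped at the start of the association window
#'   when locating the end-of-association response.
#' @return Integer vector of selected positions into `series$cycles`.
#' @export
select_concentrations <- function(series, mode = c("auto", "manual"),
                                  manual = NULL, skip_assoc = 0) {
  mode <- match.arg(mode)
  concs <- cycle_concs(series)
  if (is.unsorted(concs)) {
    stop("cycles must be sorted ascending by concentration before selection")
  }
  n <- length(concs)
  if (mode == "manual") {
    if (is.null(manual) || length(manual) < 1 || length(manual) > 5) {
      stop("manual selection requires between 1 and 5 concentrations")
    }
    sel <- vapply(manual, function(m) {
      hit <- which(abs(concs - m) <= 1e-9 * pmax(abs(concs), abs(m)))
      if (length(hit) != 1) {
        stop(sprintf("manual concentration %g M not found in series", m))
      }
      hit
    }, integer(1))
    return(sort(unique(sel)))
  }
  if (n <= 5) return(seq_len(n))
  auto_window(end_of_association(series, skip_assoc = skip_assoc))
}

#' Auto-selection rule on an end-of-association response vector
#'
#' Core of the `auto` mode of [select_concentrations()]: given the
#' end-of-association responses of cycles sorted ascending by concentration,
#' returns the indices of the window of `width` consecutive concentrations
#' with the largest accumulated response increase (last minus first), ties
#' broken toward the lowest-concentration window.
#'
#' @param e Numeric vector of end-of-association responses, in ascending
#'   concentration order.
#' @param width Window width (default 5).
#' @return Integer vector of `width` consecutive indices (all indices when
#'   `length(e) <= width`).
#' @export
auto_window <- function(e, width = 5L) {
  n <- length(e)
  if (n <= width) return(seq_len(n))
  scores <- vapply(seq_len(n - width + 1L),
                   function(j) e[j + width - 1L] - e[j], numeric(1))
  start <- which.max(scores)  # which.max takes the first (lowest) maximum
  seq.int(start, start + width - 1L)
}

#' Extract association and dissociation fit windows
#'
#' For each selected cycle, collects the association points with
#' `t0 + skip_assoc <= t <= t_asso` and the dissociation points with
#' `t_asso + skip_dissoc <= t <= t_asso + dissoc_fit_len`. Points in the skip
#' intervals and beyond the fitted dissociation length are excluded.
#'
#' @param series An aligned (and optionally blank-subtracted)
#'   [titration_series()].
#' @param selected Integer positions of the selected cycles (from
#'   [select_concentrations()]).
#' @param skip_assoc,skip_dissoc Seconds skipped at the start of the
#'   association and dissociation phases.
#' @param dissoc_fit_len Length (s) of dissociation to fit; `NULL` fits to the
#'   recorded end of dissociation.
#' @return A list of class `fit_windows`, one element per selected cycle, each
#'   holding `conc`, `assoc_time`, `assoc_response`, `dissoc_time`,
#'   `dissoc_response`, `t0`, `t_asso` and the cycle `index`.
#' @export
extract_fit_windows <- function(series, selected, skip_assoc = 0,
                                skip_dissoc = 0, dissoc_fit_len = NULL) {
  windows <- lapply(selected, function(j) {
    cyc <- series$cycles[[j]]
    sch <- cyc$schedule
    if (is.null(sch)) stop(sprintf("cycle %s: no schedule attached", cyc$index))
    d_end <- if (is.null(dissoc_fit_len)) sch$dissoc_end else
      min(sch$dissoc_end, sch$t_asso + dissoc_fit_len)
    a_sel <- cyc$time >= sch$t0 + skip_assoc & cyc$time <= sch$t_asso
    d_sel <- cyc$time >= sch$t_asso + skip_dissoc & cyc$time <= d_end
    if (!any(a_sel)) {
      stop(sprintf("cycle %s: empty association fit window", cyc$index))
    }
    if (!any(d_sel)) {
      stop(sprintf("cycle %s: empty dissociation fit window", cyc$index))
    }
    list(index = cyc$index, conc = cyc$conc,
         assoc_time = cyc$time[a_sel], assoc_response = cyc$response[a_sel],
         dissoc_time = cyc$time[d_sel], dissoc_response = cyc$response[d_sel],
         t0 = sch$t0, t_asso = sch$t_asso)
  })
  class(windows) <- "fit_windows"
  windows
}
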