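# Shared builders for the test suite. Everything is generated in code; the
# canonical truth (ka = 1e5 M^-1 s^-1, kd = 1e-4 s^-1, Rmax = 100 RU over an
# 8-point two-fold titration from 1 uM, 120/300/750 s at 0.5 Hz) is the
# simulator default.

TRUTH <- list(ka = 1e5, kd = 1e-4, rmax = 100)

entry_for <- function(series, ...) {
  sample_entry(location = series$series_id,
               concentrations = vapply(series$cycles, function(cy) cy$conc,
                                       numeric(1)),
               conc_unit = "M", regenerative = series$regenerative, ...)
}

# small hand-built series: 3 cycles, linear toy traces, schedules attached
toy_series <- function(concs = c(1e-8, 2e-8, 4e-8), regenerative = TRUE) {
  cycles <- lapply(seq_along(concs), function(i) {
    tt <- seq(0, 30, by = 1)
    titration_cycle(index = i, conc = concs[i], time = tt,
                    response = tt * 0.1 * i,
                    schedule = phase_schedule(0, 10, 20, 30))
  })
  titration_series("toy", cycles, regenerative = regenerative)
}

# continuity metric used for stitched (non-regenerative) traces: difference
# between the mean over the final anchor_len s of a cycle's dissociation and
# the mean over the next cycle's baseline window
junction_gaps <- function(series, baseline_len = NULL, anchor_len = 5) {
  n <- length(series$cycles)
  vapply(seq_len(n - 1), function(j) {
    prev <- series$cycles[[j]]
    nxt <- series$cycles[[j + 1]]
    tail_sel <- prev$time > prev$schedule$dissoc_end - anchor_len
    lo <- if (is.null(baseline_len)) nxt$schedule$baseline_start else
      nxt$schedule$t0 - baseline_len
    base_sel <- nxt$time >= lo & nxt$time < nxt$schedule$t0
    mean(nxt$response[base_sel]) - mean(prev$response[tail_sel])
  }, numeric(1))
}

pdf_page_count <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  length(grepRaw("/Type /Page", raw, all = TRUE, fixed = TRUE)) -
    length(grepRaw("/Type /Pages", raw, all = TRUE, fixed = TRUE))
}
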