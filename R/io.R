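CONC_UNITS <- c(M = 1, mM = 1e-3, uM = 1e-6, "µM" = 1e-6, nM = 1e-9,
                pM = 1e-12)

conc_to_molar <- function(value, unit) {
  key <- match(trimws(unit), names(CONC_UNITS))
  if (any(is.na(key))) {
    stop(sprintf("unknown concentration unit(s): %s",
                 paste(unique(unit[is.na(key)]), collapse = ", ")))
  }
  value * unname(CONC_UNITS[key])
}

detect_delim <- function(path) {
  first <- readLines(path, n = 1L)
  counts <- c("," = lengths(regmatches(first, gregexpr(",", first, fixed = TRUE))),
              "\t" = lengths(regmatches(first, gregexpr("\t", first, fixed = TRUE))),
              ";" = lengths(regmatches(first, gregexpr(";", first, fixed = TRUE))))
  if (all(counts == 0)) return(",")
  names(counts)[which.max(counts)]
}

read_delim_table <- function(path) {
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("readxl is required to read Excel files")
    }
    df <- as.data.frame(readxl::read_excel(path, sheet = 1,
                                           col_types = "text"),
                        stringsAsFactors = FALSE)
    names(df) <- trimws(names(df))
    return(df)
  }
  utils::read.table(path, header = TRUE, sep = detect_delim(path),
                    colClasses = "character", check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "",
                    quote = "\"", strip.white = TRUE)
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing required column(s): %s", what,
                 paste(missing, collapse = ", ")))
  }
}

numeric_column <- function(df, col, what) {
  raw <- trimws(df[[col]])
  val <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(val) & nzchar(raw))
  if (length(bad) > 0) {
    stop(sprintf("%s: non-numeric %s at line(s) %s", what, col,
                 paste(bad + 1L, collapse = ", ")))  # +1 for the header line
  }
  val
}

#' Read sensorgram data in the canonical long format
#'
#' The canonical interchange format is a delimited text table (comma, tab or
#' semicolon; auto-detected) with a header row and columns `series_id`,
#' `cycle`, `concentration`, `conc_unit`, `time_s`, `response`. Each row is
#' one data point; rows are grouped into cycles by (`series_id`, `cycle`).
#' Phase schedules are not part of the table; attach them from the sample
#' sheet with [attach_schedules()]. Rows with an empty response cell are
#' dropped.
#'
#' @param path Path to the delimited text file.
#' @return A list of [titration_series()] (schedules unset, `platform =
#'   "generic"`, `regenerative = TRUE` until a sample sheet says otherwise).
#' @export
read_canonical_table <- function(path) {
  df <- read_delim_table(path)
  require_columns(df, c("series_id", "cycle", "concentration", "conc_unit",
                        "time_s", "response"), "canonical table")
  if (nrow(df) == 0) return(list())
  cyc_no <- numeric_column(df, "cycle", "canonical table")
  conc <- numeric_column(df, "concentration", "canonical table")
  time_s <- numeric_column(df, "time_s", "canonical table")
  resp <- suppressWarnings(as.numeric(trimws(df$response)))
  bad <- which(is.na(resp) & nzchar(trimws(df$response)))
  if (length(bad) > 0) {
    stop(sprintf("canonical table: non-numeric response at line(s) %s",
                 paste(bad + 1L, collapse = ", ")))
  }
  keep <- !is.na(resp)
  df <- df[keep, , drop = FALSE]
  cyc_no <- cyc_no[keep]; conc <- conc[keep]; time_s <- time_s[keep]
  resp <- resp[keep]
  conc_m <- conc_to_molar(conc, df$conc_unit)

  out <- list()
  for (sid in unique(df$series_id)) {
    rows <- df$series_id == sid
    cycles <- lapply(sort(unique(cyc_no[rows])), function(ci) {
      sel <- rows & cyc_no == ci
      ord <- order(time_s[sel])
      titration_cycle(index = ci, conc = conc_m[sel][1],
                      time = time_s[sel][ord], response = resp[sel][ord])
    })
    out[[length(out) + 1L]] <- titration_series(series_id = sid,
                                                cycles = cycles)
  }
  out
}

#' Write a list of titration series to the canonical long format
#'
#' Inverse of [read_canonical_table()]. Numeric fields are written with 15
#' significant digits, so a write/read round trip preserves them well beyond
#' 12 significant digits.
#'
#' @param series_list List of [titration_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_canonical_table <- function(series_list, path) {
  lines <- "series_id,cycle,concentration,conc_unit,time_s,response"
  for (ser in series_list) {
    cycles <- ser$cycles
    if (!is.null(ser$blank)) cycles <- c(cycles, list(ser$blank))
    for (cyc in cycles) {
      lines <- c(lines, sprintf("%s,%d,%.15g,M,%.15g,%.15g",
                                ser$series_id, cyc$index, cyc$conc,
                                cyc$time, cyc$response))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' A sample-sheet entry: per-series sample information and fit preferences
#'
#' Mirrors one row of the user-provided sample-information sheet: where the
#' series lives in the export (spot/channel/sensor), what was measured, the
#' per-cycle analyte concentrations, the phase lengths and skip times, and the
#' model/selection preferences.
#'
#' @param location Spot/channel/sensor identifier in the instrument export.
#' @param series_id Series identifier (defaults to `location`).
#' @param ligand,analyte Names of the binding partners.
#' @param concentrations Numeric vector of per-cycle analyte concentrations,
#'   in the unit given by `conc_unit`, in cycle-index order (the blank cycle,
#'   if any, listed as 0).
#' @param conc_unit One of `M`, `mM`, `uM`/`µM`, `nM`, `pM`.
#' @param regenerative Logical: regenerative (`TRUE`) or single-cycle
#'   (`FALSE`) titration.
#' @param baseline_len,assoc_len Lengths (s) of the recorded baseline and of
#'   the association phase.
#' @param dissoc_fit_len Length (s) of dissociation to fit.
#' @param skip_assoc,skip_dissoc Seconds skipped at the start of association
#'   and dissociation. `assoc_len > skip_assoc >= 0` and
#'   `dissoc_fit_len > skip_dissoc >= 0` are enforced.
#' @param selection_mode `"auto"` or `"manual"` concentration down-selection.
#' @param manual_concs Concentrations (same unit as `conc_unit`, at most 5)
#'   to fit in manual mode; required iff `selection_mode = "manual"`.
#' @param global_rmax Fit one shared Rmax (`TRUE`) or one per cycle.
#' @param bulk_shift,drift Include the bulk-shift / dissociation-drift term
#'   (mutually exclusive).
#' @param blank_cycle Optional index of a zero-concentration blank cycle.
#' @param align Apply automatic baseline alignment before fitting. Disable for
#'   data that are already baseline-aligned (e.g. simulator output).
#' @return An object of class `sample_entry` (concentrations stored in molar).
#' @export
sample_entry <- function(location, series_id = location, ligand = "",
                         analyte = "", concentrations, conc_unit = "M",
                         regenerative = TRUE, baseline_len = 120,
                         assoc_len = 300, dissoc_fit_len = 750,
                         skip_assoc = 0, skip_dissoc = 0,
                         selection_mode = c("auto", "manual"),
                         manual_concs = NULL, global_rmax = FALSE,
                         bulk_shift = FALSE, drift = FALSE,
                         blank_cycle = NA_integer_, align = TRUE) {
  selection_mode <- match.arg(selection_mode)
  if (!(skip_assoc >= 0 && assoc_len > skip_assoc)) {
    stop("sample sheet: assoc_len must exceed skip_assoc and skip_assoc >= 0")
  }
  if (!(skip_dissoc >= 0 && dissoc_fit_len > skip_dissoc)) {
    stop("sample sheet: dissoc_fit_len must exceed skip_dissoc and skip_dissoc >= 0")
  }
  if (isTRUE(bulk_shift) && isTRUE(drift)) {
    stop("sample sheet: bulk_shift and drift cannot both be enabled ",
         "(the drift term is dropped when the shift term is included)")
  }
  if (selection_mode == "manual") {
    if (is.null(manual_concs) || length(manual_concs) < 1) {
      stop("sample sheet: manual selection_mode requires manual_concs")
    }
    if (length(manual_concs) > 5) {
      stop("sample sheet: at most 5 manual concentrations may be selected")
    }
  } else if (!is.null(manual_concs) && length(manual_concs) > 0) {
    stop("sample sheet: manual_concs given but selection_mode is auto")
  }
  e <- list(
    location = as.character(location), series_id = as.character(series_id),
    ligand = as.character(ligand), analyte = as.character(analyte),
    concentrations = conc_to_molar(as.numeric(concentrations), conc_unit),
    regenerative = isTRUE(regenerative),
    baseline_len = as.numeric(baseline_len),
    assoc_len = as.numeric(assoc_len),
    dissoc_fit_len = as.numeric(dissoc_fit_len),
    skip_assoc = as.numeric(skip_assoc), skip_dissoc = as.numeric(skip_dissoc),
    selection_mode = selection_mode,
    manual_concs = if (is.null(manual_concs)) NULL else
      conc_to_molar(as.numeric(manual_concs), conc_unit),
    global_rmax = isTRUE(global_rmax), bulk_shift = isTRUE(bulk_shift),
    drift = isTRUE(drift),
    blank_cycle = if (is.na(blank_cycle)) NA_integer_ else as.integer(blank_cycle),
    align = isTRUE(align)
  )
  class(e) <- "sample_entry"
  e
}

parse_bool <- function(x) {
  x <- tolower(trimws(x))
  if (x %in% c("true", "t", "yes", "y", "1")) return(TRUE)
  if (x %in% c("false", "f", "no", "n", "0", "")) return(FALSE)
  stop(sprintf("cannot parse '%s' as a logical", x))
}

split_list_field <- function(x) {
  x <- trimws(x)
  if (!nzchar(x)) return(numeric(0))
  as.numeric(strsplit(x, ";", fixed = TRUE)[[1]])
}

#' Read the sample-information sheet
#'
#' The sheet is delimited text (or a single-tab `.xlsx` workbook, first sheet
#' only) with one row per series to fit and the columns documented in
#' [sample_entry()] (`concentrations` and `manual_concs` are
#' semicolon-separated lists). Boolean and enum columns are parsed
#' case-insensitively; concentrations are converted to molar using
#' `conc_unit`. Violated invariants are reported with the offending row.
#'
#' @param path Path to the sheet.
#' @return List of [sample_entry()] objects.
#' @export
read_sample_sheet <- function(path) {
  df <- read_delim_table(path)
  require_columns(df, c("location", "concentrations", "conc_unit"),
                  "sample sheet")
  get <- function(row, col, default) {
    if (!col %in% names(df)) return(default)
    v <- trimws(df[[col]][row])
    if (!nzchar(v) || is.na(v)) default else v
  }
  lapply(seq_len(nrow(df)), function(r) {
    tryCatch(
      sample_entry(
        location = trimws(df$location[r]),
        series_id = get(r, "series_id", trimws(df$location[r])),
        ligand = get(r, "ligand", ""),
        analyte = get(r, "analyte", ""),
        concentrations = split_list_field(df$concentrations[r]),
        conc_unit = trimws(df$conc_unit[r]),
        regenerative = parse_bool(get(r, "regenerative", "true")),
        baseline_len = as.numeric(get(r, "baseline_len", "120")),
        assoc_len = as.numeric(get(r, "assoc_len", "300")),
        dissoc_fit_len = as.numeric(get(r, "dissoc_fit_len", "750")),
        skip_assoc = as.numeric(get(r, "skip_assoc", "0")),
        skip_dissoc = as.numeric(get(r, "skip_dissoc", "0")),
        selection_mode = tolower(get(r, "selection_mode", "auto")),
        manual_concs = {
          m <- split_list_field(get(r, "manual_concs", ""))
          if (length(m) == 0) NULL else m
        },
        global_rmax = parse_bool(get(r, "global_rmax", "false")),
        bulk_shift = parse_bool(get(r, "bulk_shift", "false")),
        drift = parse_bool(get(r, "drift", "false")),
        blank_cycle = {
          b <- get(r, "blank_cycle", "")
          if (!nzchar(b)) NA_integer_ else as.integer(b)
        },
        align = parse_bool(get(r, "align", "true"))
      ),
      error = function(e) {
        stop(sprintf("sample sheet row %d: %s", r, conditionMessage(e)),
             call. = FALSE)
      }
    )
  })
}

#' Attach phase schedules from a sample-sheet entry
#'
#' Builds per-cycle [phase_schedule()]s from the entry's phase lengths: each
#' cycle's baseline starts at its first recorded timestamp, association starts
#' `baseline_len` later and lasts `assoc_len`, and dissociation runs to the
#' last recorded timestamp. Also applies the entry's metadata (ligand,
#' analyte, regenerative flag) and moves the blank cycle, if one is declared,
#' into the series' blank slot.
#'
#' @param series A [titration_series()] (e.g. from [read_canonical_table()]).
#' @param entry A [sample_entry()].
#' @return The series with schedules and metadata attached.
#' @export
attach_schedules <- function(series, entry) {
  series$ligand <- entry$ligand
  series$analyte <- entry$analyte
  series$regenerative <- entry$regenerative
  series$cycles <- lapply(series$cycles, function(cyc) {
    start <- cyc$time[1]
    cyc$schedule <- phase_schedule(
      baseline_start = start,
      t0 = start + entry$baseline_len,
      t_asso = start + entry$baseline_len + entry$assoc_len,
      dissoc_end = cyc$time[length(cyc$time)]
    )
    cyc
  })
  if (!is.na(entry$blank_cycle)) {
    hit <- which(vapply(series$cycles, function(cy) cy$index, integer(1)) ==
                   entry$blank_cycle)
    if (length(hit) != 1) {
      stop(sprintf("blank cycle %d not found in series %s",
                   entry$blank_cycle, series$series_id))
    }
    series$blank <- series$cycles[[hit]]
    series$cycles <- series$cycles[-hit]
  }
  series
}

#' Read a wide-format instrument export
#'
#' Adapters for the export shapes of the supported platforms, all reshaped
#' onto the canonical in-memory representation:
#' \describe{
#'   \item{carterra}{One file for the whole chip: a time column followed by
#'     one response column per spot (column header = spot location). Each
#'     spot's trace is a stitched multi-cycle recording; it is split into as
#'     many equal-duration contiguous blocks as the entry lists
#'     concentrations. Only spots listed in `entries` are materialized.}
#'   \item{biacore}{One file per channel: a time column followed by one
#'     response column per cycle (cycles share the per-cycle clock). Every
#'     entry produces one series from all cycle columns, so the same trace may
#'     be analyzed multiple times under different preferences.}
#'   \item{octet}{One file per sensor, same shape as biacore (one response
#'     column per cycle step).}
#' }
#' Empty cells are dropped per point. Cycle indices are assigned in column
#' (carterra: block) order, matching the order of the entry's concentration
#' list.
#'
#' @param path Path to the export file.
#' @param platform `"carterra"`, `"biacore"` or `"octet"`.
#' @param entries List of [sample_entry()] (the mapping from the sample
#'   sheet).
#' @return List of [titration_series()] with schedules attached.
#' @export
read_platform_export <- function(path, platform = c("carterra", "biacore", "octet"),
                                 entries) {
  platform <- match.arg(platform)
  df <- read_delim_table(path)
  if (ncol(df) < 2) stop("platform export: need a time column plus response columns")
  time_s <- numeric_column(df, names(df)[1], "platform export")
  resp_cols <- names(df)[-1]

  build_cycle <- function(index, conc, tt, rr, entry) {
    ok <- !is.na(rr)
    tt <- tt[ok]; rr <- rr[ok]
    ord <- order(tt)
    tt <- tt[ord]; rr <- rr[ord]
    start <- tt[1]
    titration_cycle(index = index, conc = conc, time = tt, response = rr,
                    schedule = phase_schedule(
                      baseline_start = start,
                      t0 = start + entry$baseline_len,
                      t_asso = start + entry$baseline_len + entry$assoc_len,
                      dissoc_end = tt[length(tt)]
                    ))
  }

  finalize <- function(cycles, entry) {
    ser <- titration_series(series_id = entry$series_id, cycles = cycles,
                            ligand = entry$ligand, analyte = entry$analyte,
                            platform = platform,
                            regenerative = entry$regenerative)
    if (!is.na(entry$blank_cycle)) {
      hit <- which(vapply(ser$cycles, function(cy) cy$index, integer(1)) ==
                     entry$blank_cycle)
      if (length(hit) != 1) {
        stop(sprintf("blank cycle %d not found in series %s",
                     entry$blank_cycle, ser$series_id))
      }
      ser$blank <- ser$cycles[[hit]]
      ser$cycles <- ser$cycles[-hit]
    }
    ser
  }

  if (platform == "carterra") {
    lapply(entries, function(entry) {
      if (!entry$location %in% resp_cols) {
        stop(sprintf("carterra export: spot '%s' not found among %d response columns",
                     entry$location, length(resp_cols)))
      }
      rr <- numeric_column(df, entry$location, "carterra export")
      ok <- !is.na(rr)
      tt <- time_s[ok]; rr <- rr[ok]
      n_cyc <- length(entry$concentrations)
      span <- (max(tt) - min(tt)) / n_cyc
      # split the stitched clock into n equal contiguous blocks
      block <- pmin(floor((tt - min(tt)) / span) + 1L, n_cyc)
      cycles <- lapply(seq_len(n_cyc), function(ci) {
        sel <- block == ci
        if (!any(sel)) {
          stop(sprintf("carterra export: spot '%s' block %d is empty",
                       entry$location, ci))
        }
        build_cycle(ci, entry$concentrations[ci], tt[sel], rr[sel], entry)
      })
      finalize(cycles, entry)
    })
  } else {
    lapply(entries, function(entry) {
      if (length(resp_cols) != length(entry$concentrations)) {
        stop(sprintf("%s export: %d response columns but %d concentrations listed for '%s'",
                     platform, length(resp_cols),
                     length(entry$concentrations), entry$location))
      }
      cycles <- lapply(seq_along(resp_cols), function(ci) {
        rr <- numeric_column(df, resp_cols[ci], paste(platform, "export"))
        build_cycle(ci, entry$concentrations[ci], time_s, rr, entry)
      })
      finalize(cycles, entry)
    })
  }
}

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.12E", x))
}

#' Write the estimates table
#'
#' One row per fitted series with the kinetics estimates and their standard
#' errors: `series_id, ligand, analyte, n_points, ka, SE_ka, kd, SE_kd, KD,
#' SE_KD, Rmax, SE_Rmax, selected_concs, converged`. `Rmax`/`SE_Rmax` and
#' `selected_concs` are semicolon-separated lists when they hold per-cycle
#' values. Numbers are written in scientific notation with 13 significant
#' digits, so a write/read round trip is faithful to at least 12.
#'
#' @param results List of fit results from [fit_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_estimates_table <- function(results, path) {
  header <- paste("series_id", "ligand", "analyte", "n_points", "ka", "SE_ka",
                  "kd", "SE_kd", "KD", "SE_KD", "Rmax", "SE_Rmax",
                  "selected_concs", "converged", sep = ",")
  rows <- vapply(results, function(r) {
    paste(r$series_id, r$ligand, r$analyte, r$n_points,
          fmt_num(r$params$ka), fmt_num(r$se_ka),
          fmt_num(r$params$kd), fmt_num(r$se_kd),
          fmt_num(r$kD), fmt_num(r$se_kD),
          paste(fmt_num(r$params$rmax), collapse = ";"),
          paste(fmt_num(r$se_rmax), collapse = ";"),
          paste(fmt_num(r$selected_concs), collapse = ";"),
          tolower(as.character(isTRUE(r$converged))),
          sep = ",")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read an estimates table back into a data frame
#'
#' Inverse of [write_estimates_table()]; list-valued columns
#' (`Rmax`, `SE_Rmax`, `selected_concs`) come back as list columns of numeric
#' vectors. The result feeds [summarize_replicates()] directly.
#'
#' @param path Path to the estimates CSV.
#' @return A data frame, one row per fitted series.
#' @export
read_estimates_table <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  num <- function(col) as.numeric(df[[col]])
  lst <- function(col) lapply(strsplit(df[[col]], ";", fixed = TRUE), as.numeric)
  data.frame(
    series_id = df$series_id, ligand = df$ligand, analyte = df$analyte,
    n_points = as.integer(df$n_points),
    ka = num("ka"), SE_ka = num("SE_ka"),
    kd = num("kd"), SE_kd = num("SE_kd"),
    KD = num("KD"), SE_KD = num("SE_KD"),
    Rmax = I(lst("Rmax")), SE_Rmax = I(lst("SE_Rmax")),
    selected_concs = I(lst("selected_concs")),
    converged = df$converged == "true",
    stringsAsFactors = FALSE
  )
}
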