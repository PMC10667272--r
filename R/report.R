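cycle_palette <- function(n) {
  grDevices::hcl.colors(max(n, 2), palette = "Dark 3")[seq_len(n)]
}

render_page <- function(r) {
  op <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(op), add = TRUE)
  graphics::layout(matrix(c(1, 1, 2, 3, 4, 4), nrow = 3, byrow = TRUE),
                   heights = c(1.2, 1, 0.8))
  graphics::par(mar = c(4, 4, 3, 1))
  cols <- cycle_palette(length(r$windows))

  # overlay: data points + fitted curves per selected cycle
  all_t <- unlist(lapply(r$windows, function(w) c(w$assoc_time, w$dissoc_time)))
  all_y <- unlist(lapply(r$windows, function(w) c(w$assoc_response,
                                                  w$dissoc_response)))
  title <- sprintf("%s: %s vs %s%s", r$series_id, r$ligand, r$analyte,
                   if (r$converged) "" else "   ** FIT DID NOT CONVERGE **")
  graphics::plot(range(all_t), range(all_y), type = "n", xlab = "time (s)",
                 ylab = "response", main = title,
                 col.main = if (r$converged) "black" else "red")
  for (i in seq_along(r$windows)) {
    w <- r$windows[[i]]
    graphics::points(c(w$assoc_time, w$dissoc_time),
                     c(w$assoc_response, w$dissoc_response),
                     col = grDevices::adjustcolor(cols[i], 0.4), pch = 16,
                     cex = 0.4)
    pr <- predict_cycle(r$params, w$conc, w, i)
    graphics::lines(w$assoc_time, pr$assoc, col = cols[i], lwd = 1.6)
    graphics::lines(w$dissoc_time, pr$dissoc, col = cols[i], lwd = 1.6)
  }
  graphics::legend("topright", bty = "n", lwd = 1.6, col = cols, cex = 0.75,
                   legend = sprintf("%.3g M", r$selected_concs))

  # residuals vs time
  all_res <- unlist(lapply(r$residuals, function(x) c(x$assoc, x$dissoc)))
  graphics::plot(range(all_t), range(all_res), type = "n", xlab = "time (s)",
                 ylab = "residual", main = "Fit residuals")
  graphics::abline(h = 0, col = "grey60")
  for (i in seq_along(r$windows)) {
    w <- r$windows[[i]]
    graphics::points(c(w$assoc_time, w$dissoc_time),
                     c(r$residuals[[i]]$assoc, r$residuals[[i]]$dissoc),
                     col = grDevices::adjustcolor(cols[i], 0.5), pch = 16,
                     cex = 0.35)
  }

  # dose response: end-of-association response vs log10 concentration
  dr <- r$dose_response
  if (!is.null(dr)) {
    graphics::plot(log10(dr$conc), dr$response, pch = 21,
                   bg = ifelse(dr$selected, "red", "grey80"),
                   xlab = "log10 analyte concentration (M)",
                   ylab = "end-of-association response",
                   main = "Dose response (selected in red)")
    graphics::lines(log10(dr$conc), dr$response, col = "grey60")
  } else {
    graphics::plot.new()
  }

  # parameter summary block
  graphics::par(mar = c(0.5, 2, 2, 1))
  graphics::plot.new()
  lines_txt <- c(
    sprintf("ka = %.3E +/- %.3E M-1 s-1", r$params$ka, r$se_ka),
    sprintf("kd = %.3E +/- %.3E s-1", r$params$kd, r$se_kd),
    sprintf("KD = %.3E +/- %.3E M", r$kD, r$se_kD),
    sprintf("Rmax = %s  (SE %s)",
            paste(sprintf("%.4g", r$params$rmax), collapse = ", "),
            paste(sprintf("%.3g", r$se_rmax), collapse = ", ")),
    sprintf("n_points = %d   rss = %.4g   dof = %d   converged = %s",
            r$n_points, r$rss, r$dof, tolower(as.character(r$converged)))
  )
  graphics::text(0, seq(0.95, by = -0.18, length.out = length(lines_txt)),
                 lines_txt, adj = c(0, 1), family = "mono", cex = 0.9)
  graphics::mtext("Parameter estimates", side = 3, adj = 0, cex = 0.8)
}

#' Render a multi-page PDF report
#'
#' One page per fitted series, in input order. Each page carries the four
#' report elements: the fitted sensorgram overlaid on the underlying data,
#' the fit residuals versus time, the dose-response plot (end-of-association
#' response versus log10 analyte concentration, selected concentrations
#' highlighted) and a parameter summary block. Pages for non-converged fits
#' render with a visible flag.
#'
#' @param results List of `kin_fit` objects (>= 1) from [fit_series()].
#' @param path Output PDF path.
#' @return `path`, invisibly.
#' @export
render_report <- function(results, path) {
  if (length(results) < 1) stop("render_report requires at least one result")
  # uncompressed streams keep the report text grep-able and diff-friendly
  grDevices::pdf(path, width = 8.5, height = 11, onefile = TRUE,
                 compress = FALSE)
  on.exit(grDevices::dev.off(), add = TRUE)
  for (r in results) render_page(r)
  invisible(path)
}

find_series <- function(series_list, entry) {
  ids <- vapply(series_list, function(s) s$series_id, character(1))
  hit <- which(ids == entry$series_id | ids == entry$location)
  if (length(hit) < 1) {
    stop(sprintf("no series '%s' in the data file", entry$series_id))
  }
  series_list[[hit[1]]]
}

#' Run the full batch pipeline
#'
#' For every sample-sheet entry: read the sensorgram data, attach schedules,
#' baseline-align (when the entry asks for it), subtract the blank cycle if
#' one is declared, thin to the requested rate, down-select concentrations and
#' fit the 1:1 model. Writes `estimates.csv`, `report.pdf` and `run.log` to
#' `out_dir`. A malformed sample sheet aborts before any fitting; a failure on
#' one series is logged and skipped while the remaining entries are processed,
#' and the exit status reflects any failure.
#'
#' @param data_path Path to the sensorgram data file.
#' @param sheet_path Path to the sample-information sheet.
#' @param out_dir Output directory (created if needed).
#' @param platform `"generic"` (canonical long format) or one of the wide
#'   export adapters `"carterra"`, `"biacore"`, `"octet"`.
#' @param thin_hz Thinning rate in Hz before fitting; `NULL` disables
#'   thinning.
#' @param blank_subtract Subtract declared blank cycles.
#' @return Invisibly, a list with `status` (0 = all entries fitted), the
#'   artifact paths and the list of fit results.
#' @export
run_batch <- function(data_path, sheet_path, out_dir,
                      platform = c("generic", "carterra", "biacore", "octet"),
                      thin_hz = 1, blank_subtract = TRUE) {
  platform <- match.arg(platform)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(
    sprintf("sensorkin %s batch run",
            as.character(utils::packageVersion("sensorkin"))),
    sprintf("data: %s", data_path),
    sprintf("samples: %s", sheet_path),
    sprintf("platform: %s | thin_hz: %s | blank_subtract: %s", platform,
            ifelse(is.null(thin_hz), "off", format(thin_hz)), blank_subtract)
  )
  entries <- read_sample_sheet(sheet_path)   # malformed sheet aborts here
  log_lines <- c(log_lines, sprintf("%d sample sheet entr%s", length(entries),
                                    ifelse(length(entries) == 1, "y", "ies")))
  results <- list()
  status <- 0L
  for (entry in entries) {
    t_start <- proc.time()[["elapsed"]]
    res <- tryCatch({
      ser <- if (platform == "generic") {
        attach_schedules(find_series(read_canonical_table(data_path), entry),
                         entry)
      } else {
        read_platform_export(data_path, platform, list(entry))[[1]]
      }
      msgs <- validate_series(ser)
      if (length(msgs) > 0) stop(paste(msgs, collapse = "; "))
      if (entry$align) ser <- align_baseline(ser, baseline_len = entry$baseline_len)
      if (!is.null(ser$blank)) {
        ser <- if (blank_subtract) subtract_blank(ser) else
          { ser$blank <- NULL; ser }
      }
      if (!is.null(thin_hz)) ser <- thin_to_rate(ser, thin_hz)
      fit_series(ser, entry)
    }, error = function(e) e)
    elapsed <- proc.time()[["elapsed"]] - t_start
    if (inherits(res, "error")) {
      status <- 1L
      log_lines <- c(log_lines,
                     sprintf("FAILED %s (%.2f s): %s", entry$series_id,
                             elapsed, conditionMessage(res)))
    } else {
      results[[length(results) + 1L]] <- res
      log_lines <- c(log_lines,
                     sprintf("ok %s (%.2f s): ka=%.4E kd=%.4E KD=%.4E converged=%s",
                             entry$series_id, elapsed, res$params$ka,
                             res$params$kd, res$kD,
                             tolower(as.character(res$converged))))
      if (!res$converged) {
        log_lines <- c(log_lines,
                       sprintf("warning: %s did not meet convergence tolerance (%s)",
                               entry$series_id, res$optimizer_message))
      }
    }
  }
  estimates_path <- file.path(out_dir, "estimates.csv")
  write_estimates_table(results, estimates_path)
  report_path <- file.path(out_dir, "report.pdf")
  if (length(results) > 0) render_report(results, report_path)
  log_path <- file.path(out_dir, "run.log")
  writeLines(log_lines, log_path)
  invisible(list(status = status, estimates = estimates_path,
                 report = if (length(results) > 0) report_path else NULL,
                 log = log_path, results = results))
}
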