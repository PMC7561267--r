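#' Serialise a trial to plain files
#'
#' Writes three sidecar files for a [run_paced()] or [run_cml()] result:
#' `<prefix>_global_peaks.csv` (columns `beat`, `global_peak`),
#' `<prefix>_field.csv` (rows = beats, columns = sites), and
#' `<prefix>_config.json` (full configuration plus seed).
#'
#' @param trial an `fhn_trial` or `cml_trajectory`.
#' @param prefix path prefix for the output files.
#' @return invisibly, the vector of file paths written.
#' @export
write_trial_result <- function(trial, prefix) {
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  p <- paste0(prefix, "_global_peaks.csv")
  write.csv(data.frame(beat = seq_along(trial$global_peaks),
                       global_peak = trial$global_peaks),
            p, row.names = FALSE)
  paths <- c(paths, p)
  if (!is.null(trial$beat_peak_field)) {
    f <- trial$beat_peak_field
    colnames(f) <- paste0("site_", seq_len(ncol(f)))
    p <- paste0(prefix, "_field.csv")
    write.csv(as.data.frame(f), p, row.names = FALSE)
    paths <- c(paths, p)
  }
  cfg <- trial[intersect(names(trial),
                         c("params", "pacing", "feedback", "seed", "boundary",
                           "c_s"))]
  p <- paste0(prefix, "_config.json")
  jsonlite::write_json(cfg, p, auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(c(paths, p))
}

#' Read a beat-peak field CSV
#'
#' Inverse of the field file written by [write_trial_result()].
#'
#' @param path CSV path (rows = beats, columns = sites).
#' @return numeric matrix.
#' @export
read_beat_peak_field <- function(path) {
  as.matrix(read.csv(path, check.names = FALSE))
}

#' Write ensemble statistics files
#'
#' Writes one row per trial (`seed`, `label`, `max_amp`, `node_count`,
#' `delta_gpeak`), the domain-size and global-amplitude histograms as
#' (`bin_left`, `bin_right`, `count`) CSVs, and a JSON summary.
#'
#' @param stats an [ensemble_stats()] object.
#' @param dir output directory (created if needed).
#' @param config optional [experiment_config()] echoed into the summary.
#' @return invisibly, the paths written.
#' @export
write_ensemble_stats <- function(stats, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, "trials.csv")
  write.csv(stats$trials, paths, row.names = FALSE)
  hist_df <- function(h) data.frame(bin_left = head(h$breaks, -1),
                                    bin_right = tail(h$breaks, -1),
                                    count = h$counts)
  if (!is.null(stats$domain_hist)) {
    p <- file.path(dir, "domain_hist.csv")
    write.csv(hist_df(stats$domain_hist), p, row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "amp_hist.csv")
  write.csv(hist_df(stats$amp_hist), p, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "summary.json")
  jsonlite::write_json(
    list(n_trials = nrow(stats$trials), fraction_dis = stats$fraction_dis,
         eps_p1 = stats$eps_p1, eps_node = stats$eps_node, L = stats$L,
         config = config),
    p, auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
  invisible(c(paths, p))
}

#' Export a boundary curve or spectrum to CSV
#'
#' @param x a `boundary_curve` or `cml_spectrum`.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_stability_csv <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  df <- if (inherits(x, "cml_spectrum"))
    data.frame(k = x$k, lambda = x$lambda)
  else as.data.frame(x)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
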