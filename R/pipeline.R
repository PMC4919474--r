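# End-to-end orchestration of the screen stages: read/normalize ->
# assemble -> fit -> outlier mask -> classify -> cytotoxicity -> triage ->
# summarize, plus report writers. Deterministic for fixed inputs and
# thresholds; all randomness lives in the generators.

#' Run the full screen analysis
#'
#' @param wells Plate-table data frame (see [read_plate_table()]).
#' @param fingerprints Optional fingerprint matrix (compounds x bits) used
#'   to derive structural-series support; compounds without fingerprints
#'   get no series support.
#' @param thresholds A [class_thresholds()] object; validated before any
#'   work.
#' @param z_max Outlier-masking threshold passed to [mask_and_refit()].
#' @param series_threshold Tanimoto threshold for [cluster_series()].
#' @return List of class `screen_result`: `results` (one row per compound:
#'   class, direction, efficacy, EC50, quality, cytotoxicity, series
#'   support), `summary` (a `screen_summary`), `fits` (named list of
#'   `hill_fit`), `series` (the titrations after masking), `thresholds`.
#' @export
run_screen_pipeline <- function(wells, fingerprints = NULL,
                                thresholds = class_thresholds(),
                                z_max = 3, series_threshold = 0.7) {
  stopifnot(inherits(thresholds, "class_thresholds"))
  titrations <- assemble_titrations(wells)

  support <- stats::setNames(rep(FALSE, length(titrations)),
                             names(titrations))
  series_tab <- NULL
  if (!is.null(fingerprints)) {
    series_tab <- cluster_series(fingerprints, threshold = series_threshold)
    hit <- series_tab$compound_id %in% names(support)
    support[series_tab$compound_id[hit]] <- series_tab$support[hit]
  }

  fits <- vector("list", length(titrations))
  names(fits) <- names(titrations)
  rows <- vector("list", length(titrations))
  for (i in seq_along(titrations)) {
    ts <- titrations[[i]]
    fit <- fit_hill(ts)
    mr <- mask_and_refit(ts, fit, z_max = z_max)
    ts <- mr$series; fit <- mr$fit
    titrations[[i]] <- ts
    fits[[i]] <- fit
    res <- assign_curve_class(fit, ts, thresholds)
    tox <- flag_cytotoxicity(ts, fit, thresholds)
    rows[[i]] <- triage_quality(res, tox, support[[ts$compound_id]],
                                thresholds)
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  structure(list(results = results,
                 summary = summarize_screen(results),
                 fits = fits,
                 series = titrations,
                 series_table = series_tab,
                 thresholds = thresholds),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  print(x$summary)
  invisible(x)
}

#' Write screen reports
#'
#' Writes `curve_classes.csv` (per-compound calls, EC50s in nM),
#' `curve_fits.csv` (fit parameters) and `summary.json` (count tree plus
#' the threshold block, so every report carries the cutoffs it was produced
#' under).
#'
#' @param screen A `screen_result` from [run_screen_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_reports <- function(screen, dir) {
  stopifnot(inherits(screen, "screen_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  classes_path <- file.path(dir, "curve_classes.csv")
  out <- screen$results
  out$ec50_nM <- out$ec50 * 1e9
  out$ec50 <- NULL
  utils::write.csv(out, classes_path, row.names = FALSE, quote = FALSE)

  fits_path <- file.path(dir, "curve_fits.csv")
  fit_tab <- do.call(rbind, lapply(names(screen$fits), function(id) {
    f <- screen$fits[[id]]
    data.frame(compound_id = id, bottom = f$bottom, top = f$top,
               ec50_nM = f$ec50 * 1e9, slope = f$slope, r2 = f$r2,
               converged = f$converged, extrapolated = f$extrapolated,
               p_flat = f$p_flat, stringsAsFactors = FALSE)
  }))
  utils::write.csv(fit_tab, fits_path, row.names = FALSE, quote = FALSE)

  summary_path <- file.path(dir, "summary.json")
  s <- screen$summary
  jsonlite::write_json(
    list(n_compounds = s$n_compounds,
         totals = s$totals,
         counts = s$counts,
         thresholds = unclass(screen$thresholds)),
    summary_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(classes_path, fits_path, summary_path))
}
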