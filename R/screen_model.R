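ROLES <- c("sample", "neutral_control", "positive_control")

PLATE_COLUMNS <- c("plate", "well", "compound_id", "role",
                   "concentration_molar", "ld_signal", "cell_signal")

#' Read a plate-level screen table
#'
#' Parses a CSV of per-well raw signals from a lipid-storage screen. Each row
#' is one well, holding the lipid-droplet (LD) channel and the cell-number
#' channel together with compound/role/concentration metadata. Extra columns
#' are ignored.
#'
#' @param path Path to a CSV file with header columns `plate`, `well`,
#'   `compound_id`, `role`, `concentration_molar`, `ld_signal`,
#'   `cell_signal`.
#' @return A data frame of well records, one per data row, in file order.
#'   `role` is one of `sample`, `neutral_control`, `positive_control`.
#' @export
read_plate_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(compound_id = "character"))
  missing <- setdiff(PLATE_COLUMNS, names(df))
  if (length(missing) > 0L) {
    stop("plate table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  df <- df[, c(PLATE_COLUMNS, setdiff(names(df), PLATE_COLUMNS))]
  df$compound_id[is.na(df$compound_id)] <- ""
  validate_wells(df)
  df
}

#' Validate well records
#'
#' Enforces the well-record invariants: known roles, finite non-negative
#' signals, and, for sample wells, a nonempty compound id and a positive
#' molar concentration. Errors name the offending row.
#'
#' @param wells Data frame of well records.
#' @return The validated data frame, invisibly.
#' @export
validate_wells <- function(wells) {
  bad_role <- which(!wells$role %in% ROLES)
  if (length(bad_role) > 0L) {
    stop("row ", bad_role[1L], ": unknown role '", wells$role[bad_role[1L]],
         "'")
  }
  for (col in c("ld_signal", "cell_signal")) {
    bad <- which(!is.finite(wells[[col]]) | wells[[col]] < 0)
    if (length(bad) > 0L) {
      stop("row ", bad[1L], ": ", col, " must be finite and >= 0")
    }
  }
  is_sample <- wells$role == "sample"
  bad <- which(is_sample & (is.na(wells$compound_id) |
                              wells$compound_id == ""))
  if (length(bad) > 0L) {
    stop("row ", bad[1L], ": sample well lacks a compound_id")
  }
  bad <- which(is_sample & (!is.finite(wells$concentration_molar) |
                              wells$concentration_molar <= 0))
  if (length(bad) > 0L) {
    stop("row ", bad[1L], ": sample well needs concentration_molar > 0")
  }
  invisible(wells)
}

#' Write a plate table
#'
#' Inverse of [read_plate_table()]; writes the canonical column set in
#' canonical order so that write -> read -> write round-trips byte-identically.
#'
#' @param wells Data frame of well records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_plate_table <- function(wells, path) {
  validate_wells(wells)
  utils::write.csv(wells[, PLATE_COLUMNS], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Titration concentration grid
#'
#' Geometric dilution series as used in the screen: a top concentration
#' diluted by a fixed ratio. The default campaign grid runs 46 uM down to
#' about 3 nM in 1:5 steps over 7 points.
#'
#' @param top Highest concentration (molar), > 0.
#' @param ratio Dilution factor between neighboring points, > 1.
#' @param n_points Number of concentrations, >= 2.
#' @return Numeric vector of concentrations in increasing order.
#' @examples
#' make_titration_concentrations(46e-6, 5, 7)[1] # ~2.94e-9 M, the "3 nM" floor
#' @export
make_titration_concentrations <- function(top = 46e-6, ratio = 5,
                                          n_points = 7) {
  stopifnot(top > 0, ratio > 1)
  if (n_points < 2) stop("n_points must be >= 2")
  rev(top / ratio^(seq_len(n_points) - 1L))
}

#' Lipid-droplet signal per cell
#'
#' The screen's phenotypic readout: LD signal normalized to the cell-number
#' signal. Wells with no measurable cell signal are not evaluable; they
#' return `NA` (to propagate as a masked point) rather than raising.
#'
#' @param ld_signal LD-channel signal, >= 0.
#' @param cell_signal Cell-channel signal.
#' @return `ld_signal / cell_signal`, or `NA` where `cell_signal <= 0`.
#' @export
ld_per_cell <- function(ld_signal, cell_signal) {
  out <- ifelse(cell_signal > 0, ld_signal / cell_signal, NA_real_)
  out
}

#' Plate control summaries
#'
#' Per-plate medians (and MADs, kept for QC) of the per-cell LD signal for
#' the neutral (solvent) and positive (full-inhibition) control wells, plus
#' the neutral median of the raw cell-channel signal used for the
#' cytotoxicity readout.
#'
#' @param wells Data frame of well records for one or more plates.
#' @return A data frame with one row per plate: `plate`, `neutral_median`,
#'   `positive_median`, `neutral_mad`, `n_neutral`, `n_positive`,
#'   `cell_neutral_median`.
#' @export
plate_controls <- function(wells) {
  validate_wells(wells)
  plates <- unique(wells$plate)
  rows <- lapply(plates, function(p) {
    w <- wells[wells$plate == p, ]
    neu <- w[w$role == "neutral_control", ]
    pos <- w[w$role == "positive_control", ]
    if (nrow(neu) < 1L) stop("plate '", p, "' has no neutral controls")
    if (nrow(pos) < 1L) stop("plate '", p, "' has no positive controls")
    x_neu <- ld_per_cell(neu$ld_signal, neu$cell_signal)
    x_pos <- ld_per_cell(pos$ld_signal, pos$cell_signal)
    data.frame(
      plate = p,
      neutral_median = stats::median(x_neu, na.rm = TRUE),
      positive_median = stats::median(x_pos, na.rm = TRUE),
      neutral_mad = stats::mad(x_neu, na.rm = TRUE),
      n_neutral = nrow(neu),
      n_positive = nrow(pos),
      cell_neutral_median = stats::median(neu$cell_signal),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  bad <- out$neutral_median == out$positive_median
  if (any(bad)) {
    stop("normalization undefined on plate(s) ",
         paste(out$plate[bad], collapse = ", "),
         ": neutral and positive control medians coincide")
  }
  out
}

#' Percent activity relative to plate controls
#'
#' Affine control-based normalization: 0 at the neutral-control median and
#' -100 at the positive-control (full inhibition) median. Activation
#' therefore comes out positive, inhibition negative.
#'
#' @param x Normalized (per-cell) signal value(s).
#' @param neutral_median,positive_median Plate control medians.
#' @return Percent activity, same length as `x`.
#' @export
percent_activity <- function(x, neutral_median, positive_median) {
  if (isTRUE(all.equal(neutral_median, positive_median))) {
    stop("normalization undefined: control medians coincide")
  }
  100 * (x - neutral_median) / (neutral_median - positive_median)
}

#' Build a titration series object
#'
#' @param compound_id Compound identifier.
#' @param concentrations Strictly increasing molar concentrations, all > 0.
#' @param activity Percent activity per concentration.
#' @param cell_activity Percent change in the cell-channel signal per
#'   concentration.
#' @param mask Logical per point; `TRUE` = excluded from fitting. At most
#'   one point may be masked.
#' @return An object of class `titration_series`.
#' @export
titration_series <- function(compound_id, concentrations, activity,
                             cell_activity = rep(0, length(concentrations)),
                             mask = rep(FALSE, length(concentrations))) {
  stopifnot(length(activity) == length(concentrations),
            length(cell_activity) == length(concentrations),
            length(mask) == length(concentrations))
  if (any(concentrations <= 0) || any(diff(concentrations) <= 0)) {
    stop("concentrations must be strictly increasing and > 0")
  }
  if (sum(mask) > 1L) stop("at most one point may be masked")
  structure(
    list(compound_id = compound_id,
         concentrations = as.numeric(concentrations),
         activity = as.numeric(activity),
         cell_activity = as.numeric(cell_activity),
         mask = as.logical(mask)),
    class = "titration_series"
  )
}

#' @export
print.titration_series <- function(x, ...) {
  cat("Titration of", x$compound_id, "-", length(x$concentrations),
      "points,", sum(x$mask), "masked\n")
  print(data.frame(conc_nM = x$concentrations * 1e9,
                   activity = round(x$activity, 2),
                   cell_activity = round(x$cell_activity, 2),
                   mask = x$mask))
  invisible(x)
}

#' Assemble per-compound titrations from well records
#'
#' Normalizes every sample well against its plate's controls, then collects
#' one titration per compound, sorted by concentration. Replicate wells at
#' the same (compound, concentration) are collapsed to their median
#' activity. Wells with no cell signal are dropped as unevaluable.
#'
#' The cell-channel activity is the percent change of the raw cell signal
#' from the plate's neutral-control median (-100 = all cells lost), the
#' cytotoxicity counter-screen readout.
#'
#' @param wells Data frame of well records.
#' @param controls Optional result of [plate_controls()]; computed from
#'   `wells` when omitted.
#' @return Named list of `titration_series`, one per distinct sample
#'   compound.
#' @export
assemble_titrations <- function(wells, controls = NULL) {
  validate_wells(wells)
  if (is.null(controls)) controls <- plate_controls(wells)
  s <- wells[wells$role == "sample", ]
  missing_plates <- setdiff(unique(s$plate), controls$plate)
  if (length(missing_plates) > 0L) {
    stop("no controls for plate(s): ", paste(missing_plates, collapse = ", "))
  }
  idx <- match(s$plate, controls$plate)
  x <- ld_per_cell(s$ld_signal, s$cell_signal)
  act <- percent_activity(x, controls$neutral_median[idx],
                          controls$positive_median[idx])
  cell_act <- 100 * (s$cell_signal - controls$cell_neutral_median[idx]) /
    controls$cell_neutral_median[idx]
  keep <- !is.na(act)
  s <- s[keep, ]; act <- act[keep]; cell_act <- cell_act[keep]
  out <- lapply(split(seq_len(nrow(s)), s$compound_id), function(i) {
    conc <- s$concentration_molar[i]
    a <- tapply(act[i], conc, stats::median)
    ca <- tapply(cell_act[i], conc, stats::median)
    cc <- as.numeric(names(a))
    o <- order(cc)
    titration_series(s$compound_id[i[1L]], cc[o], as.numeric(a)[o],
                     as.numeric(ca)[o])
  })
  out[order(names(out))]
}
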