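# Enzyme activity-assay reduction: percent inhibition of esterification
# counts against the solvent reference, with the no-enzyme (quadruple-
# mutant extract) counts as background, and IC50 estimation through the
# shared Hill machinery.

#' Percent inhibition from scintillation counts
#'
#' `100 * (1 - (counts - bg) / (dmso - bg))`, with the background and
#' solvent levels taken as the means of their replicate counts: 0 at the
#' solvent (uninhibited) level and 100 at the background (no-enzyme) level.
#' Values may fall outside `[0, 100]` with noise.
#'
#' @param counts Counts per concentration (vector or replicate matrix with
#'   one row per concentration).
#' @param dmso_counts Replicate counts for the solvent reference.
#' @param background_counts Replicate counts from the no-enzyme extract.
#' @return Percent inhibition per concentration.
#' @export
percent_inhibition <- function(counts, dmso_counts, background_counts) {
  bg <- mean(background_counts)
  dmso <- mean(dmso_counts)
  if (dmso <= bg) {
    stop("assay uninformative: solvent counts do not exceed background")
  }
  if (is.matrix(counts)) counts <- rowMeans(counts)
  100 * (1 - (counts - bg) / (dmso - bg))
}

#' Build an enzyme-assay titration object
#'
#' @param enzyme `"DGAT1"`, `"DGAT2"`, or `"none"`.
#' @param concentrations Inhibitor concentrations, molar, increasing.
#' @param counts Matrix (concentrations x replicate wells) or vector of
#'   counts, >= 0.
#' @param dmso_counts,background_counts Replicate counts for the solvent
#'   reference and the no-enzyme extract.
#' @return List of class `assay_titration`.
#' @export
assay_titration <- function(enzyme, concentrations, counts, dmso_counts,
                            background_counts) {
  enzyme <- match.arg(enzyme, c("DGAT1", "DGAT2", "none"))
  counts <- if (is.matrix(counts)) counts else matrix(counts, ncol = 1L)
  stopifnot(nrow(counts) == length(concentrations), all(counts >= 0),
            all(dmso_counts >= 0), all(background_counts >= 0))
  if (mean(dmso_counts) <= mean(background_counts)) {
    stop("assay uninformative: solvent counts do not exceed background")
  }
  structure(list(enzyme = enzyme,
                 concentrations = as.numeric(concentrations),
                 counts = counts,
                 dmso_counts = as.numeric(dmso_counts),
                 background_counts = as.numeric(background_counts)),
            class = "assay_titration")
}

#' Fit an IC50 to an enzyme-inhibition titration
#'
#' Converts counts to percent inhibition, then delegates to [fit_hill()]
#' with the low-concentration asymptote constrained near 0 (no inhibition
#' without compound); the high-concentration asymptote is free. A titration
#' with a realized inhibition span below 10 percent, or a non-converged
#' fit, is reported as no inhibition.
#'
#' @param titration An `assay_titration`.
#' @param top_bounds Constraint on the zero-inhibition asymptote,
#'   default `c(-5, 5)` percent.
#' @return List: `ic50` (molar; `NA` when no inhibition), `fit` (the
#'   underlying `hill_fit`), `inhibition` (percent per concentration),
#'   `no_inhibition` flag.
#' @export
fit_ic50 <- function(titration, top_bounds = c(-5, 5)) {
  stopifnot(inherits(titration, "assay_titration"))
  if (length(titration$concentrations) < 4L) {
    stop("need >= 4 concentrations to fit an IC50")
  }
  inh <- percent_inhibition(titration$counts, titration$dmso_counts,
                            titration$background_counts)
  series <- titration_series(
    compound_id = paste0(titration$enzyme, "_inhibition"),
    concentrations = titration$concentrations,
    activity = inh)
  fit <- fit_hill(series, top_bounds = top_bounds)
  eff <- efficacy(fit, series)
  no_inh <- !fit$converged || eff < 10
  list(ic50 = if (no_inh) NA_real_ else fit$ec50,
       fit = fit, inhibition = inh, no_inhibition = no_inh)
}
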