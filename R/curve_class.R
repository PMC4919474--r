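# qHTS curve-class assignment and hit triage. The taxonomy follows the
# quantitative-HTS convention: class 1 = complete sigmoid with both
# asymptotes, class 2 = partial sigmoid missing the saturating asymptote,
# class 3 = activity at a single (highest) concentration, class 4 =
# inactive. Subclasses .1/.2 split full from partial efficacy.

CURVE_CLASSES <- c("CC1_1", "CC1_2", "CC2_1", "CC2_2", "CC3", "CC4")

#' Curve-class decision thresholds
#'
#' All cutoffs used in hit calling and triage, gathered in one declared
#' object so every report can echo them. The numeric defaults are this
#' package's declared reconstruction of standard qHTS practice, not
#' published values.
#'
#' @param r2_min Minimum r-squared for an accepted fit (default 0.9).
#' @param eff_high Efficacy (percent) separating full-response (.1) from
#'   partial-response (.2) subclasses, default 80.
#' @param eff_low Minimum efficacy to count as active at all, default 30.
#' @param plateau_tol Tolerance (percent) for judging that an asymptote is
#'   realized inside the tested range, default 10.
#' @param hq_partial_eff Efficacy a partial-response curve needs (together
#'   with structural-series support) to be promoted to high quality,
#'   default 50.
#' @param tox_cutoff Cell-channel activity (percent change from the neutral
#'   median) below which a well counts as cytotoxic, default -50.
#' @param min_active_points Minimum number of tested concentrations at which
#'   the fitted curve must show |response| >= `plateau_tol` (i.e. a response
#'   distinguishable from baseline) for the fit to be accepted; default 2.
#'   This is what distinguishes a genuine (possibly partial) dose-response
#'   from single-concentration activity (class 3): a steep sigmoid pinned
#'   between the two highest concentrations can reproduce a single active
#'   point essentially perfectly, so fit quality alone cannot.
#' @return A list of class `class_thresholds`.
#' @export
class_thresholds <- function(r2_min = 0.9, eff_high = 80, eff_low = 30,
                             plateau_tol = 10, hq_partial_eff = 50,
                             tox_cutoff = -50, min_active_points = 2L) {
  if (!(eff_low > 0 && eff_low < hq_partial_eff &&
          hq_partial_eff <= eff_high)) {
    stop("need 0 < eff_low < hq_partial_eff <= eff_high")
  }
  if (!(r2_min > 0 && r2_min <= 1)) stop("r2_min must be in (0, 1]")
  structure(list(r2_min = r2_min, eff_high = eff_high, eff_low = eff_low,
                 plateau_tol = plateau_tol, hq_partial_eff = hq_partial_eff,
                 tox_cutoff = tox_cutoff,
                 min_active_points = as.integer(min_active_points)),
            class = "class_thresholds")
}

#' Realized efficacy of a fitted curve
#'
#' The absolute difference between the fitted response at the lowest and the
#' highest tested concentration: the response span the compound actually
#' achieves inside the tested range (not the asymptotic span, which may be
#' extrapolated). 0 for a flat/non-converged fit.
#'
#' @param fit A `hill_fit`.
#' @param series The fitted `titration_series`.
#' @return Efficacy in percent, >= 0.
#' @export
efficacy <- function(fit, series) {
  use <- !series$mask
  conc <- series$concentrations[use]
  if (!fit$converged) return(0)
  abs(predict(fit, max(conc)) - predict(fit, min(conc)))
}

#' Assign a qHTS curve class
#'
#' Applies the decision rules in order:
#' 1. accepted fit: converged, `r2 >= r2_min`, flat-model F test p < 0.05,
#'    and fitted |response| >= `plateau_tol` at >= `min_active_points`
#'    tested concentrations;
#' 2. both asymptotes realized: fitted response within `plateau_tol` of
#'    `top` at the lowest and of `bottom` at the highest concentration;
#' 3. accepted + both asymptotes: CC1_1 if efficacy >= `eff_high`, CC1_2 if
#'    in `[eff_low, eff_high)`;
#' 4. accepted + missing asymptote: CC2_1 / CC2_2 by the same efficacy split;
#' 5. not accepted but |observed activity at the top concentration| >=
#'    `eff_low`: CC3 (single-point activity);
#' 6. otherwise CC4 (inactive).
#'
#' Direction is the sign of the response change from the lowest to the
#' highest concentration: negative = inhibitor, positive = activator; CC4 is
#' inactive.
#'
#' @param fit A `hill_fit`.
#' @param series The fitted `titration_series`.
#' @param thresholds A [class_thresholds()] object.
#' @return A one-row data frame: `compound_id`, `curve_class`, `direction`,
#'   `efficacy`, plus fit diagnostics (`ec50`, `r2`, `p_flat`,
#'   `extrapolated`).
#' @export
assign_curve_class <- function(fit, series, thresholds = class_thresholds()) {
  th <- thresholds
  use <- !series$mask
  conc <- series$concentrations[use]
  act <- series$activity[use]
  c_min <- min(conc); c_max <- max(conc)

  eff <- efficacy(fit, series)
  n_active <- if (fit$converged) {
    sum(abs(predict(fit, conc)) >= th$plateau_tol)
  } else 0L
  accepted <- fit$converged && !is.na(fit$r2) && fit$r2 >= th$r2_min &&
    fit$p_flat < 0.05 && n_active >= th$min_active_points
  both_asym <- fit$converged &&
    abs(predict(fit, c_min) - fit$top) <= th$plateau_tol &&
    abs(predict(fit, c_max) - fit$bottom) <= th$plateau_tol

  act_top <- act[which.max(conc)]
  cls <- if (accepted && eff >= th$eff_low) {
    if (both_asym) {
      if (eff >= th$eff_high) "CC1_1" else "CC1_2"
    } else {
      if (eff >= th$eff_high) "CC2_1" else "CC2_2"
    }
  } else if (!accepted && abs(act_top) >= th$eff_low) {
    "CC3"
  } else {
    "CC4"
  }

  direction <- if (cls == "CC4") {
    "inactive"
  } else {
    delta <- if (fit$converged && cls != "CC3") {
      predict(fit, c_max) - predict(fit, c_min)
    } else {
      act_top - act[which.min(conc)]
    }
    if (delta < 0) "inhibitor" else "activator"
  }

  data.frame(compound_id = series$compound_id,
             curve_class = cls,
             direction = direction,
             efficacy = if (cls == "CC3") abs(act_top) else eff,
             ec50 = fit$ec50,
             r2 = fit$r2,
             p_flat = fit$p_flat,
             extrapolated = isTRUE(fit$extrapolated),
             stringsAsFactors = FALSE)
}

#' Flag cytotoxic compounds from the cell-channel counter-screen
#'
#' A compound is flagged when the cell-channel activity drops below
#' `tox_cutoff` at any concentration inside the active window, defined as
#' concentrations up to 25x the fitted EC50 (all concentrations when no
#' EC50 is available).
#'
#' @param series A `titration_series` (with `cell_activity`).
#' @param fit The compound's `hill_fit` (may be non-converged).
#' @param thresholds A [class_thresholds()] object.
#' @return Logical.
#' @export
flag_cytotoxicity <- function(series, fit, thresholds = class_thresholds()) {
  window <- if (!is.null(fit) && fit$converged && is.finite(fit$ec50) &&
                  !is.na(fit$p_flat) && fit$p_flat < 0.05) {
    series$concentrations <= 25 * fit$ec50
  } else {
    rep(TRUE, length(series$concentrations))
  }
  any(series$cell_activity[window] < thresholds$tox_cutoff)
}

#' Triage a classified compound into a quality tier
#'
#' High quality requires a non-cytotoxic compound with either a complete
#' response (CC1_1, CC2_1) or a partial response (CC1_2, CC2_2) that reaches
#' `hq_partial_eff` efficacy and is backed by a structural series of similar
#' actives. Remaining CC1-CC3 actives are low quality; CC4 has no tier.
#'
#' @param result One-row data frame from [assign_curve_class()].
#' @param cytotoxic Logical, from [flag_cytotoxicity()].
#' @param series_support Logical: does the compound belong to a structural
#'   series with >= 2 members?
#' @param thresholds A [class_thresholds()] object.
#' @return `result` with `quality` and `cytotoxic` columns added.
#' @export
triage_quality <- function(result, cytotoxic, series_support,
                           thresholds = class_thresholds()) {
  th <- thresholds
  cls <- result$curve_class
  quality <- if (cls == "CC4") {
    "none"
  } else if (!cytotoxic &&
               (cls %in% c("CC1_1", "CC2_1") ||
                  (cls %in% c("CC1_2", "CC2_2") &&
                     result$efficacy >= th$hq_partial_eff &&
                     isTRUE(series_support)))) {
    "high"
  } else {
    "low"
  }
  result$quality <- quality
  result$cytotoxic <- cytotoxic
  result$series_support <- isTRUE(series_support)
  result
}

#' Summarize a classified screen
#'
#' Counts compounds by curve class, quality tier and direction, and the
#' four headline totals (high/low quality x inhibitor/activator). Totals are
#' sums of their parts by construction.
#'
#' @param results Data frame with one row per compound (columns
#'   `compound_id`, `curve_class`, `direction`, `quality`).
#' @return A list of class `screen_summary`: `n_compounds`, `counts` (the
#'   class x quality x direction table as a data frame) and `totals`.
#' @export
summarize_screen <- function(results) {
  if (anyDuplicated(results$compound_id)) {
    stop("duplicate compound_id in results: ",
         results$compound_id[anyDuplicated(results$compound_id)])
  }
  counts <- as.data.frame(
    table(curve_class = factor(results$curve_class, levels = CURVE_CLASSES),
          quality = factor(results$quality, levels = c("high", "low", "none")),
          direction = factor(results$direction,
                             levels = c("inhibitor", "activator", "inactive"))),
    stringsAsFactors = FALSE)
  counts <- counts[counts$Freq > 0, , drop = FALSE]
  names(counts)[names(counts) == "Freq"] <- "n"
  tot <- function(q, d) {
    sum(counts$n[counts$quality == q & counts$direction == d])
  }
  totals <- list(
    hq_inhibitors = tot("high", "inhibitor"),
    hq_activators = tot("high", "activator"),
    lq_inhibitors = tot("low", "inhibitor"),
    lq_activators = tot("low", "activator"),
    inactive = sum(counts$n[counts$quality == "none"])
  )
  structure(list(n_compounds = nrow(results), counts = counts,
                 totals = totals),
            class = "screen_summary")
}

#' @export
print.screen_summary <- function(x, ...) {
  cat("qHTS screen summary:", x$n_compounds, "compounds\n")
  cat(sprintf("  high-quality inhibitors: %d\n", x$totals$hq_inhibitors))
  cat(sprintf("  high-quality activators: %d\n", x$totals$hq_activators))
  cat(sprintf("  low-quality inhibitors:  %d\n", x$totals$lq_inhibitors))
  cat(sprintf("  low-quality activators:  %d\n", x$totals$lq_activators))
  cat(sprintf("  inactive:                %d\n", x$totals$inactive))
  invisible(x)
}
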