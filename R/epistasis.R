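# Whole-animal triglyceride statistics and the pharmacogenetic epistasis
# decision: one-way ANOVA, Bonferroni-adjusted post-hoc pairwise tests with
# a pooled within-group variance, and the additive-vs-same-pathway call.

#' One-way ANOVA
#'
#' Classical fixed-effects one-way ANOVA. Degenerate inputs follow explicit
#' conventions: all values identical in every group and across groups gives
#' p = 1; zero within-group variance with differing group means gives
#' F = Inf, p = 0.
#'
#' @param values Numeric vector of measurements (e.g. TAG, ug per animal
#'   pool).
#' @param groups Factor or character vector of group labels, same length.
#' @return List: `F`, `p`, `df_between`, `df_within`, `ms_within`,
#'   `group_means`, `n`.
#' @export
anova_oneway <- function(values, groups) {
  groups <- as.factor(groups)
  k <- nlevels(groups)
  n <- length(values)
  if (k < 2L) stop("need >= 2 groups")
  if (any(table(groups) < 2L)) stop("every group needs n >= 2")
  means <- tapply(values, groups, mean)
  grand <- mean(values)
  ss_between <- sum(table(groups) * (means - grand)^2)
  ss_within <- sum((values - means[groups])^2)
  df_b <- k - 1L
  df_w <- n - k
  if (ss_within == 0 && ss_between == 0) {
    return(list(F = 0, p = 1, df_between = df_b, df_within = df_w,
                ms_within = 0, group_means = means, n = n))
  }
  if (ss_within == 0) {
    return(list(F = Inf, p = 0, df_between = df_b, df_within = df_w,
                ms_within = 0, group_means = means, n = n))
  }
  f <- (ss_between / df_b) / (ss_within / df_w)
  list(F = f, p = stats::pf(f, df_b, df_w, lower.tail = FALSE),
       df_between = df_b, df_within = df_w, ms_within = ss_within / df_w,
       group_means = means, n = n)
}

#' Bonferroni-adjusted post-hoc pairwise tests
#'
#' Pairwise two-sample t tests after a one-way ANOVA, using the pooled
#' within-group mean square from all groups (classical
#' Bonferroni-after-ANOVA); adjusted p = min(1, m * p) for m comparisons.
#' A Welch option (per-pair variances, Welch-Satterthwaite df) is available.
#'
#' @param values,groups As in [anova_oneway()].
#' @param comparisons List of length-2 character vectors naming the group
#'   pairs to test; default all pairs.
#' @param welch Use Welch per-pair t tests instead of the pooled
#'   within-group variance. Default `FALSE`.
#' @return Data frame: `group1`, `group2`, `diff`, `t`, `p_raw`, `p_adj`.
#' @export
bonferroni_posthoc <- function(values, groups, comparisons = NULL,
                               welch = FALSE) {
  groups <- as.factor(groups)
  lv <- levels(groups)
  if (is.null(comparisons)) {
    comparisons <- utils::combn(lv, 2L, simplify = FALSE)
  }
  bad <- !vapply(comparisons, function(p) all(p %in% lv), logical(1))
  if (any(bad)) stop("comparison references unknown group")
  av <- anova_oneway(values, groups)
  m <- length(comparisons)
  rows <- lapply(comparisons, function(pair) {
    x1 <- values[groups == pair[1L]]
    x2 <- values[groups == pair[2L]]
    d <- mean(x1) - mean(x2)
    if (welch) {
      se2 <- stats::var(x1) / length(x1) + stats::var(x2) / length(x2)
      df <- se2^2 / ((stats::var(x1) / length(x1))^2 / (length(x1) - 1) +
                       (stats::var(x2) / length(x2))^2 / (length(x2) - 1))
    } else {
      se2 <- av$ms_within * (1 / length(x1) + 1 / length(x2))
      df <- av$df_within
    }
    if (se2 == 0) {
      p <- if (d == 0) 1 else 0
      t_stat <- if (d == 0) 0 else Inf * sign(d)
    } else {
      t_stat <- d / sqrt(se2)
      p <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
    }
    data.frame(group1 = pair[1L], group2 = pair[2L], diff = d, t = t_stat,
               p_raw = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, m * out$p_raw)
  out
}

#' Epistasis decision from a four-group TAG experiment
#'
#' Given replicate TAG values for the untreated reference, the drug-only,
#' the mutant-only and the combined perturbation, decides whether the two
#' perturbations act in separate pathways ("independent": the combination
#' is lower than either single perturbation and both Bonferroni-adjusted
#' comparisons are significant) or in the same pathway ("no enhancement":
#' both adjusted p-values at or above alpha). Anything else (exactly one
#' significant comparison, or a combination that is not lower) is
#' inconclusive.
#'
#' @param reference,drug_only,mutant_only,combo Numeric replicate vectors,
#'   each n >= 3.
#' @param alpha Significance level for the adjusted comparisons,
#'   default 0.05.
#' @param welch Passed to [bonferroni_posthoc()].
#' @return List of class `epistasis_call`: `verdict` (`independent`,
#'   `same_pathway`, `inconclusive`), `p_combo_vs_drug`,
#'   `p_combo_vs_mutant` (Bonferroni-adjusted), `anova_p`, and
#'   `effect_pct` (group means as percent of the reference mean).
#' @export
epistasis_call <- function(reference, drug_only, mutant_only, combo,
                           alpha = 0.05, welch = FALSE) {
  grp <- list(reference = reference, drug_only = drug_only,
              mutant_only = mutant_only, combo = combo)
  for (nm in names(grp)) {
    if (is.null(grp[[nm]]) || length(grp[[nm]]) < 3L) {
      stop("group '", nm, "' is missing or has n < 3")
    }
  }
  values <- unlist(grp, use.names = FALSE)
  groups <- rep(names(grp), lengths(grp))
  av <- anova_oneway(values, groups)
  ph <- bonferroni_posthoc(values, groups,
                           comparisons = list(c("combo", "drug_only"),
                                              c("combo", "mutant_only")),
                           welch = welch)
  p_drug <- ph$p_adj[ph$group2 == "drug_only"]
  p_mut <- ph$p_adj[ph$group2 == "mutant_only"]
  combo_lower <- mean(combo) < mean(drug_only) &&
    mean(combo) < mean(mutant_only)
  verdict <- if (combo_lower && p_drug < alpha && p_mut < alpha) {
    "independent"
  } else if (p_drug >= alpha && p_mut >= alpha) {
    "same_pathway"
  } else {
    "inconclusive"
  }
  structure(list(verdict = verdict,
                 p_combo_vs_drug = p_drug,
                 p_combo_vs_mutant = p_mut,
                 anova_p = av$p,
                 effect_pct = 100 * vapply(grp, mean, numeric(1)) /
                   mean(reference)),
            class = "epistasis_call")
}

#' @export
print.epistasis_call <- function(x, ...) {
  cat("Epistasis verdict:", x$verdict, "\n")
  cat(sprintf("  combo vs drug-only:   adjusted p = %.4g\n",
              x$p_combo_vs_drug))
  cat(sprintf("  combo vs mutant-only: adjusted p = %.4g\n",
              x$p_combo_vs_mutant))
  cat("  group means (% of reference):\n")
  print(round(x$effect_pct, 1))
  invisible(x)
}
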