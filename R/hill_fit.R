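# Four-parameter logistic (Hill) machinery shared by the screen and the
# enzyme assay. Fits are deterministic: a coarse grid over (log10 EC50,
# slope) with closed-form least squares for the two asymptotes seeds a
# bounded Levenberg-Marquardt refinement; no random restarts.

SLOPE_MIN <- 0.1
SLOPE_MAX <- 5

#' Four-parameter logistic response
#'
#' `top + (bottom - top) / (1 + (ec50/c)^slope)`: approaches `top` as the
#' concentration goes to 0 and `bottom` at saturating concentration; equals
#' the midpoint `(top + bottom)/2` at `c = ec50`. Monotone in `c`.
#'
#' @param conc Concentration(s), molar, > 0.
#' @param top Asymptote at low concentration (percent activity).
#' @param bottom Asymptote at high concentration (percent activity).
#' @param ec50 Midpoint concentration (molar).
#' @param slope Hill coefficient, > 0.
#' @return Percent activity at `conc`.
#' @export
hill_response <- function(conc, top, bottom, ec50, slope) {
  top + (bottom - top) / (1 + (ec50 / conc)^slope)
}

# Closed-form least squares for (top, bottom) given occupancy weights
# w = 1/(1+(ec50/c)^slope): the model is linear, y = top*(1-w) + bottom*w.
.asymptote_ls <- function(w, y) {
  a <- 1 - w
  g11 <- sum(a * a); g12 <- sum(a * w); g22 <- sum(w * w)
  det <- g11 * g22 - g12 * g12
  if (det < 1e-12) {
    m <- mean(y)
    return(c(top = m, bottom = m))
  }
  b1 <- sum(a * y); b2 <- sum(w * y)
  top <- (g22 * b1 - g12 * b2) / det
  bottom <- (g11 * b2 - g12 * b1) / det
  c(top = top, bottom = bottom)
}

.hill_start <- function(conc, act, asym_max) {
  le_lo <- log10(min(conc)) - 2
  le_hi <- log10(max(conc)) + 2
  le_grid <- seq(le_lo, le_hi, length.out = 25L)
  slope_grid <- c(0.5, 1, 2)
  best <- NULL
  for (le in le_grid) {
    for (s in slope_grid) {
      w <- 1 / (1 + (10^le / conc)^s)
      ab <- .asymptote_ls(w, act)
      ab <- pmin(pmax(ab, -asym_max), asym_max)
      pred <- ab[1L] * (1 - w) + ab[2L] * w
      rss <- sum((act - pred)^2)
      if (is.null(best) || rss < best$rss) {
        best <- list(top = ab[[1L]], bottom = ab[[2L]], le = le, s = s,
                     rss = rss)
      }
    }
  }
  best
}

#' Fit a four-parameter logistic to a titration
#'
#' Least squares in log10-concentration space on the unmasked points,
#' optimized over (top, bottom, log10 EC50, log slope) so that the Hill
#' slope stays positive. Initialization is deterministic: a grid over
#' candidate EC50s (two decades beyond the tested range on either side) and
#' slopes with closed-form asymptotes, refined by bounded
#' Levenberg-Marquardt. Optimizer failure is recorded (`converged = FALSE`),
#' not raised.
#'
#' @param series A `titration_series`.
#' @param asym_max Bound on |top| and |bottom| (percent), default 200.
#' @param top_bounds Optional length-2 numeric constraining the low-
#'   concentration asymptote (used e.g. to pin the enzyme-assay baseline
#'   near 0).
#' @return An object of class `hill_fit`: `top`, `bottom`, `ec50`,
#'   `log10_ec50`, `slope`, `rss`, `r2`, `converged`, `n_used`,
#'   `extrapolated` (EC50 outside the tested range), and `p_flat`, the
#'   extra-sum-of-squares F-test p-value against a flat (mean-only) model.
#' @export
fit_hill <- function(series, asym_max = 200, top_bounds = NULL) {
  stopifnot(inherits(series, "titration_series"))
  use <- !series$mask
  conc <- series$concentrations[use]
  act <- series$activity[use]
  n <- length(conc)
  if (n < 4L) stop("insufficient data: need >= 4 unmasked points, have ", n)

  lower <- c(top = -asym_max, bottom = -asym_max,
             le = log10(min(conc)) - 2, ls = log(SLOPE_MIN))
  upper <- c(top = asym_max, bottom = asym_max,
             le = log10(max(conc)) + 2, ls = log(SLOPE_MAX))
  if (!is.null(top_bounds)) {
    lower["top"] <- top_bounds[1L]
    upper["top"] <- top_bounds[2L]
  }
  st <- .hill_start(conc, act, asym_max)
  start <- c(top = min(max(st$top, lower["top"]), upper["top"]),
             bottom = min(max(st$bottom, lower["bottom"]), upper["bottom"]),
             le = st$le, ls = log(min(max(st$s, SLOPE_MIN), SLOPE_MAX)))
  names(start) <- c("top", "bottom", "le", "ls")

  resid_fn <- function(p) {
    act - (p[1L] + (p[2L] - p[1L]) / (1 + (10^p[3L] / conc)^exp(p[4L])))
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = unname(start), fn = resid_fn,
      lower = unname(lower), upper = unname(upper),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)),
    error = function(e) NULL)
  tss <- sum((act - mean(act))^2)
  ok <- !is.null(fit) && all(is.finite(fit$par)) &&
    (fit$info %in% 1:4 ||
       # maxiter with machine-level residuals is success, not failure
       sum(fit$fvec^2) <= 1e-9 * max(tss, 1e-6))
  if (!ok) {
    out <- structure(
      list(top = mean(act), bottom = mean(act), log10_ec50 = NA_real_,
           ec50 = NA_real_, slope = NA_real_,
           rss = tss, r2 = if (tss > 0) 0 else NA_real_,
           converged = FALSE, n_used = n, extrapolated = FALSE,
           p_flat = 1, c_range = range(conc)),
      class = "hill_fit")
    return(out)
  }
  p <- c(top = fit$par[1L], bottom = fit$par[2L], le = fit$par[3L],
         ls = fit$par[4L])
  rss <- sum(fit$fvec^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  ec50 <- 10^p[["le"]]
  out <- structure(
    list(top = p[["top"]], bottom = p[["bottom"]],
         log10_ec50 = p[["le"]], ec50 = ec50, slope = exp(p[["ls"]]),
         rss = rss, r2 = r2, converged = TRUE, n_used = n,
         extrapolated = ec50 < min(conc) || ec50 > max(conc),
         p_flat = NA_real_, c_range = range(conc)),
    class = "hill_fit")
  out$p_flat <- f_test_vs_flat(series, out)
  out
}

#' @export
print.hill_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf(
      "Hill fit: EC50 = %.4g nM%s, slope = %.3g, top = %.3g, bottom = %.3g\n",
      x$ec50 * 1e9, if (x$extrapolated) " (extrapolated)" else "",
      x$slope, x$top, x$bottom))
    cat(sprintf("  r2 = %.4f, p(flat) = %.3g, n = %d\n",
                x$r2, x$p_flat, x$n_used))
  } else {
    cat("Hill fit did not converge (n =", x$n_used, ")\n")
  }
  invisible(x)
}

#' Predicted response from a fitted curve
#'
#' @param object A `hill_fit`.
#' @param conc Concentrations (molar). For a non-converged fit the flat
#'   (mean) model is returned.
#' @param ... Unused.
#' @return Percent activity at `conc`.
#' @export
predict.hill_fit <- function(object, conc, ...) {
  if (!object$converged) return(rep(object$top, length(conc)))
  hill_response(conc, object$top, object$bottom, object$ec50, object$slope)
}

#' Extra-sum-of-squares F test against a flat model
#'
#' Compares the 4-parameter fit with a mean-only model on the same unmasked
#' points: the acceptance gate for concentration dependency. With zero
#' residual variance under both models the p-value is 1 by convention.
#'
#' @param series A `titration_series`.
#' @param fit The corresponding `hill_fit`.
#' @return p-value in `[0, 1]`.
#' @export
f_test_vs_flat <- function(series, fit) {
  use <- !series$mask
  act <- series$activity[use]
  n <- length(act)
  rss0 <- sum((act - mean(act))^2)
  rss1 <- if (fit$converged) fit$rss else rss0
  df1 <- 3L            # extra parameters of the sigmoid over the flat model
  df2 <- n - 4L
  if (df2 <= 0L) return(1)
  eps <- 1e-10 * max(1, mean(act)^2)
  if (rss0 <= eps && rss1 <= eps) return(1)
  if (rss1 <= eps) return(0)
  f <- ((rss0 - rss1) / df1) / (rss1 / df2)
  if (!is.finite(f) || f < 0) return(1)
  stats::pf(f, df1, df2, lower.tail = FALSE)
}

#' Mask a single outlier point and refit
#'
#' Masks at most one point whose standardized residual against the fitted
#' curve exceeds `z_max` (the worst one), then refits. If no point exceeds
#' the threshold, or a point is already masked, inputs are returned
#' unchanged. Residuals are standardized by a robust (MAD-based) scale with
#' a small absolute floor (0.5 percent activity) so that a single displaced
#' point cannot inflate its own yardstick and machine-precision residuals on
#' noiseless curves are never flagged.
#'
#' @param series A `titration_series`.
#' @param fit The initial `hill_fit`.
#' @param z_max Standardized-residual threshold, default 3.
#' @param ... Passed on to [fit_hill()] when refitting.
#' @return List with elements `series` and `fit`.
#' @export
mask_and_refit <- function(series, fit, z_max = 3, ...) {
  if (!fit$converged || any(series$mask)) {
    return(list(series = series, fit = fit))
  }
  use <- !series$mask
  resid <- series$activity[use] -
    predict(fit, series$concentrations[use])
  df <- length(resid) - 4L
  if (df < 1L) return(list(series = series, fit = fit))
  sigma <- max(stats::mad(resid, center = 0), 0.5)
  z <- abs(resid) / sigma
  if (max(z) <= z_max) return(list(series = series, fit = fit))
  worst <- which(use)[which.max(z)]
  series$mask[worst] <- TRUE
  list(series = series, fit = fit_hill(series, ...))
}
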