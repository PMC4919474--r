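# Seeded generators emulating every input the pipeline consumes, with
# ground truth attached. Each generator is a pure function of its arguments
# and seed: the caller's RNG state is saved and restored, and the same seed
# reproduces the same output bit for bit.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Simulate one titration from known Hill parameters
#'
#' Evaluates the four-parameter logistic on a concentration grid and adds
#' iid Gaussian noise. Deterministic per seed.
#'
#' @param top,bottom,ec50,slope Generating Hill parameters.
#' @param grid Concentration grid (molar, increasing); default the
#'   campaign grid, 46 uM down in 1:5 steps over 7 points.
#' @param noise_sd Gaussian noise sd in percent-activity units, >= 0.
#' @param seed RNG seed.
#' @param compound_id Identifier for the series.
#' @return A `titration_series`.
#' @export
simulate_titration <- function(top = 0, bottom = -100, ec50, slope = 1,
                               grid = make_titration_concentrations(),
                               noise_sd = 0, seed = 1,
                               compound_id = "SIM") {
  stopifnot(noise_sd >= 0, ec50 > 0, slope > 0)
  act <- hill_response(grid, top, bottom, ec50, slope)
  if (noise_sd > 0) {
    act <- act + with_seed(seed, stats::rnorm(length(grid), 0, noise_sd))
  }
  titration_series(compound_id, grid, act)
}

# Curve-class generating regions. Parameters are drawn so that every class
# sits inside its decision band with a deliberate margin (realized efficacy
# well away from the 30/80 cutoffs, class-2 midpoints near the top of the
# range so the saturating plateau stays unrealized, class-1 midpoints well
# inside the range so both plateaus are realized).
.draw_class_params <- function(cls, grid) {
  c_min <- min(grid); c_max <- max(grid)
  runifl <- function(a, b) exp(stats::runif(1, log(a), log(b)))
  if (cls %in% c("CC1_1", "CC1_2")) {
    span <- if (cls == "CC1_1") stats::runif(1, 85, 100) else
      stats::runif(1, 45, 70)
    ec50 <- runifl(30 * c_min, c_max / 30)
    slope <- stats::runif(1, 1.8, 3)
    list(span = span, ec50 = ec50, slope = slope)
  } else if (cls %in% c("CC2_1", "CC2_2")) {
    # midpoint near the top tested concentration so the saturating
    # asymptote stays out of range (class definition)
    eff <- if (cls == "CC2_1") stats::runif(1, 90, 100) else
      stats::runif(1, 45, 70)
    ec50 <- if (cls == "CC2_1") runifl(0.65 * c_max, 0.9 * c_max) else
      runifl(0.65 * c_max, c_max)
    slope <- stats::runif(1, 0.9, 1.1)
    w_hi <- 1 / (1 + (ec50 / c_max)^slope)
    w_lo <- 1 / (1 + (ec50 / c_min)^slope)
    list(span = eff / (w_hi - w_lo), ec50 = ec50, slope = slope)
  } else if (cls == "CC3") {
    list(amp = stats::runif(1, 45, 70))
  } else {
    list()
  }
}

#' Simulate a full screen with ground truth
#'
#' Generates `n` compounds with curve classes drawn from `class_mix`,
#' class-consistent Hill parameters, a cytotoxic subpopulation with
#' correlated cell-channel loss, structural series with shared
#' fingerprints, and plate tables laid out one concentration per plate with
#' neutral (solvent) and positive (full inhibition) control wells.
#'
#' @param n Number of compounds.
#' @param class_mix Named numeric vector of class proportions over
#'   `CC1_1, CC1_2, CC2_1, CC2_2, CC3, CC4`, summing to 1. The default
#'   mirrors a primary screen dominated by inactives.
#' @param toxic_frac Fraction of compounds with a cytotoxic cell-channel
#'   response, default 0.05.
#' @param noise_sd Absolute activity noise sd (percent units), default 0.
#' @param noise_frac Additional per-compound noise as a fraction of the
#'   compound's generated response span (|bottom - top|, or the single-point
#'   amplitude for CC3; inactive compounds have zero span), default 0. The
#'   per-well sd is `noise_sd + noise_frac * span`.
#' @param activator_frac Fraction of active compounds that are activators
#'   rather than inhibitors, default 0.25.
#' @param seed RNG seed.
#' @param grid Concentration grid.
#' @param n_controls Neutral and positive control wells per plate,
#'   default 8.
#' @param fp_len Fingerprint length in bits, default 256.
#' @return List: `wells` (plate table data frame), `truth` (per-compound
#'   generating class, direction, parameters, toxicity, series id),
#'   `fingerprints` (compounds x bits logical matrix).
#' @export
simulate_screen <- function(n,
                            class_mix = c(CC1_1 = 0.08, CC1_2 = 0.09,
                                          CC2_1 = 0.08, CC2_2 = 0.10,
                                          CC3 = 0.15, CC4 = 0.50),
                            toxic_frac = 0.05, noise_sd = 0,
                            noise_frac = 0,
                            activator_frac = 0.25, seed = 1,
                            grid = make_titration_concentrations(),
                            n_controls = 8L, fp_len = 256L) {
  stopifnot(abs(sum(class_mix) - 1) < 1e-8,
            all(names(class_mix) %in% CURVE_CLASSES))
  with_seed(seed, {
    ids <- sprintf("CMP%05d", seq_len(n))
    cls <- sample(names(class_mix), n, replace = TRUE, prob = class_mix)
    active <- cls != "CC4"
    direction <- ifelse(active,
                        ifelse(stats::runif(n) < activator_frac,
                               "activator", "inhibitor"),
                        "inactive")
    toxic <- stats::runif(n) < toxic_frac

    # structural series: sizes 1-4, members share a perturbed base print
    series_id <- character(n)
    fp <- matrix(FALSE, n, fp_len, dimnames = list(ids, NULL))
    i <- 1L
    while (i <= n) {
      size <- min(sample(1:4, 1L), n - i + 1L)
      base <- stats::runif(fp_len) < 0.3
      for (j in seq_len(size)) {
        member <- base
        flip <- sample.int(fp_len, 5L)
        member[flip] <- !member[flip]
        fp[i + j - 1L, ] <- member
        series_id[i + j - 1L] <- ids[i]
      }
      i <- i + size
    }

    sgn <- ifelse(direction == "activator", 1, -1)
    truth <- data.frame(compound_id = ids, curve_class = cls,
                        direction = direction,
                        top = 0, bottom = NA_real_, ec50 = NA_real_,
                        slope = NA_real_, amp = NA_real_,
                        toxic = toxic, series_id = series_id,
                        stringsAsFactors = FALSE)
    act <- matrix(0, n, length(grid))
    for (k in seq_len(n)) {
      pars <- .draw_class_params(cls[k], grid)
      if (cls[k] %in% c("CC1_1", "CC1_2", "CC2_1", "CC2_2")) {
        truth$bottom[k] <- sgn[k] * pars$span
        truth$ec50[k] <- pars$ec50
        truth$slope[k] <- pars$slope
        act[k, ] <- hill_response(grid, 0, truth$bottom[k], pars$ec50,
                                  pars$slope)
      } else if (cls[k] == "CC3") {
        truth$amp[k] <- sgn[k] * pars$amp
        act[k, length(grid)] <- truth$amp[k]
      }
    }
    span <- ifelse(is.na(truth$bottom),
                   ifelse(is.na(truth$amp), 0, abs(truth$amp)),
                   abs(truth$bottom - truth$top))
    sd_k <- noise_sd + noise_frac * span
    if (any(sd_k > 0)) {
      act <- act + matrix(stats::rnorm(length(act), 0, rep(sd_k, ncol(act))),
                          n)
    }

    # cytotoxic compounds lose cells along a steep response centered on
    # their own midpoint (or mid-grid when the class has none)
    tox_ec50 <- ifelse(is.na(truth$ec50), grid[ceiling(length(grid) / 2)],
                       truth$ec50)
    cell_act <- matrix(0, n, length(grid))
    for (k in seq_len(n)) {
      if (toxic[k]) {
        cell_act[k, ] <- -85 / (1 + (tox_ec50[k] / grid)^2)
      }
    }
    if (noise_sd > 0) {
      cell_act <- cell_act +
        matrix(stats::rnorm(length(cell_act), 0, noise_sd / 5), n)
    }
    cell_act <- pmax(cell_act, -95)

    # plate layout: one concentration per plate; signals reconstructed from
    # activity so that normalization against controls round-trips exactly
    ld_neutral <- 1.0; ld_positive <- 0.2; cell_neutral <- 500
    plates <- lapply(seq_along(grid), function(p) {
      plate <- sprintf("P%d", p)
      ca <- cell_act[, p]
      cell_sig <- cell_neutral * (1 + ca / 100)
      ldpc <- ld_neutral + act[, p] / 100 * (ld_neutral - ld_positive)
      ldpc <- pmax(ldpc, 0)
      sample_rows <- data.frame(
        plate = plate,
        well = sprintf("S%03d", seq_len(n)),
        compound_id = ids,
        role = "sample",
        concentration_molar = grid[p],
        ld_signal = ldpc * cell_sig,
        cell_signal = cell_sig,
        stringsAsFactors = FALSE)
      ctrl <- data.frame(
        plate = plate,
        well = sprintf("C%03d", seq_len(2L * n_controls)),
        compound_id = "",
        role = rep(c("neutral_control", "positive_control"),
                   each = n_controls),
        concentration_molar = 0,
        ld_signal = rep(c(ld_neutral, ld_positive), each = n_controls) *
          cell_neutral,
        cell_signal = cell_neutral,
        stringsAsFactors = FALSE)
      rbind(sample_rows, ctrl)
    })
    wells <- do.call(rbind, plates)
    rownames(wells) <- NULL
    list(wells = wells, truth = truth, fingerprints = fp)
  })
}

#' Simulate an expression matrix with planted signature clusters
#'
#' Genic values are lognormal around a per-gene baseline; the first
#' `k_clusters * genes_per_cluster` genes carry condition-specific
#' profiles (cluster j upregulated by `effect` log2 units in condition j),
#' the planted ground truth for the signature clustering. Intergenic
#' features come from a low lognormal background rescaled so that the
#' pooled 95th percentile equals `bg_q95` exactly.
#'
#' @param n_genes Number of genic features, default 1000.
#' @param n_intergenic Number of intergenic background features,
#'   default 250.
#' @param conditions Condition labels; need at least `k_clusters`.
#' @param n_reps Replicates per condition, default 3.
#' @param k_clusters Number of planted clusters, default 5.
#' @param genes_per_cluster Genes per planted cluster, default 40.
#' @param effect Planted shift in log2 units, default 2 (a 4-fold change);
#'   0 gives a null matrix.
#' @param noise_sd Per-replicate sd on the log2 scale, default 0.25.
#' @param bg_q95 Target pooled 95th percentile of the intergenic
#'   background, default 1.04 (FPKM units).
#' @param seed RNG seed.
#' @return List: `em` (an `expr_matrix`), `truth` (per-gene planted
#'   cluster, 0 = no signature).
#' @export
simulate_expression <- function(n_genes = 1000, n_intergenic = 250,
                                conditions = c("DMSO_OA", "DMSO_noOA",
                                               "CT1_active", "CT2_active",
                                               "CT3_active", "CT1_inactive",
                                               "CT2_inactive",
                                               "CT3_inactive"),
                                n_reps = 3, k_clusters = 5,
                                genes_per_cluster = 40, effect = 2,
                                noise_sd = 0.25, bg_q95 = 1.04, seed = 1) {
  stopifnot(k_clusters >= 1, length(conditions) >= k_clusters,
            n_genes >= k_clusters * genes_per_cluster)
  with_seed(seed, {
    genes <- sprintf("G%05d", seq_len(n_genes))
    inter <- sprintf("IG%05d", seq_len(n_intergenic))
    samples <- data.frame(
      sample = paste(rep(conditions, each = n_reps),
                     rep(seq_len(n_reps), length(conditions)), sep = "_r"),
      condition = rep(conditions, each = n_reps),
      replicate = rep(seq_len(n_reps), length(conditions)),
      stringsAsFactors = FALSE)
    n_s <- nrow(samples)

    cluster <- integer(n_genes)
    cluster[seq_len(k_clusters * genes_per_cluster)] <-
      rep(seq_len(k_clusters), each = genes_per_cluster)
    base <- stats::rnorm(n_genes, 3, 1.5)
    shift <- matrix(0, n_genes, n_s)
    for (j in seq_len(k_clusters)) {
      rows <- cluster == j
      cols <- samples$condition == conditions[j]
      shift[rows, cols] <- effect
    }
    log2x <- base + shift +
      matrix(stats::rnorm(n_genes * n_s, 0, noise_sd), n_genes)
    genic <- 2^log2x

    bg <- matrix(stats::rlnorm(n_intergenic * n_s, log(0.2), 1),
                 n_intergenic)
    q <- stats::quantile(as.vector(bg), 0.95, type = 7)
    bg <- bg * (bg_q95 / q)

    values <- rbind(genic, bg)
    rownames(values) <- c(genes, inter)
    colnames(values) <- samples$sample
    em <- expression_matrix(values,
                            c(rep("genic", n_genes),
                              rep("intergenic", n_intergenic)),
                            samples)
    list(em = em,
         truth = data.frame(gene = genes, cluster = cluster,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate replicate TAG measurements for named groups
#'
#' Normal deviates truncated at zero (negative draws are redrawn), one row
#' per replicate animal pool.
#'
#' @param groups_spec Data frame with columns `group`, `mean`, `sd`, `n`
#'   (means > 0).
#' @param seed RNG seed.
#' @return Data frame: `group`, `tag_ug`.
#' @export
simulate_tag <- function(groups_spec, seed = 1) {
  stopifnot(all(c("group", "mean", "sd", "n") %in% names(groups_spec)),
            all(groups_spec$mean > 0))
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(groups_spec)), function(i) {
      g <- groups_spec[i, ]
      x <- stats::rnorm(g$n, g$mean, g$sd)
      while (any(x <= 0)) {
        x[x <= 0] <- stats::rnorm(sum(x <= 0), g$mean, g$sd)
      }
      data.frame(group = g$group, tag_ug = x, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Canonical TAG epistasis scenarios
#'
#' Group means for the two canonical outcomes of the four-group epistasis
#' experiment, with sd = 10% of each mean and n = 8 replicate pools.
#' `additive`: the combined perturbation multiplies the single-perturbation
#' effects (separate pathways). `same_pathway`: the combination phenocopies
#' either single perturbation.
#'
#' @param scenario `"additive"` or `"same_pathway"`.
#' @param reference_mean Reference TAG level, default 100.
#' @param n Replicates per group, default 8.
#' @return A `groups_spec` data frame for [simulate_tag()].
#' @export
tag_scenario <- function(scenario = c("additive", "same_pathway"),
                         reference_mean = 100, n = 8) {
  scenario <- match.arg(scenario)
  means <- if (scenario == "additive") {
    c(reference = 1, drug_only = 0.6, mutant_only = 0.5, combo = 0.3)
  } else {
    c(reference = 1, drug_only = 0.55, mutant_only = 0.55, combo = 0.55)
  }
  means <- means * reference_mean
  data.frame(group = names(means), mean = unname(means),
             sd = unname(means) * 0.1, n = n, stringsAsFactors = FALSE)
}

#' Simulate an enzyme-inhibition titration
#'
#' Scintillation counts decline from the solvent level toward the no-enzyme
#' background along a Hill inhibition curve with the given IC50;
#' `enzyme = "DGAT2"` yields no inhibition (counts stay at the solvent
#' level) and `enzyme = "none"` background-only counts. Three replicate
#' wells per concentration by default.
#'
#' @param ic50 Generating IC50 (molar).
#' @param grid Inhibitor concentrations (molar).
#' @param enzyme `"DGAT1"` (inhibited), `"DGAT2"` (not inhibited), or
#'   `"none"`.
#' @param slope Hill slope of the inhibition curve, default 1.
#' @param dmso_level,background_level Mean counts of the solvent reference
#'   and the no-enzyme extract.
#' @param noise_frac Count noise sd as a fraction of the dynamic range,
#'   default 0.
#' @param n_wells Replicate wells per concentration, default 3.
#' @param seed RNG seed.
#' @return An `assay_titration`.
#' @export
simulate_enzyme_assay <- function(ic50 = 27e-9,
                                  grid = make_titration_concentrations(),
                                  enzyme = "DGAT1", slope = 1,
                                  dmso_level = 5000, background_level = 200,
                                  noise_frac = 0, n_wells = 3, seed = 1) {
  stopifnot(ic50 > 0, noise_frac >= 0)
  enzyme <- match.arg(enzyme, c("DGAT1", "DGAT2", "none"))
  with_seed(seed, {
    span <- dmso_level - background_level
    inh_frac <- switch(enzyme,
                       DGAT1 = 1 / (1 + (ic50 / grid)^slope),
                       DGAT2 = rep(0, length(grid)),
                       none = rep(1, length(grid)))
    mu <- background_level + span * (1 - inh_frac)
    noise_sd <- noise_frac * span
    counts <- matrix(rep(mu, n_wells), ncol = n_wells)
    dmso <- rep(dmso_level, n_wells)
    bg <- rep(background_level, n_wells)
    if (noise_sd > 0) {
      counts <- counts + matrix(stats::rnorm(length(counts), 0, noise_sd),
                                nrow = nrow(counts))
      dmso <- dmso + stats::rnorm(n_wells, 0, noise_sd)
      bg <- bg + stats::rnorm(n_wells, 0, noise_sd / 5)
    }
    counts <- pmax(counts, 0)
    assay_titration(enzyme, grid, counts, pmax(dmso, 0), pmax(bg, 0))
  })
}
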