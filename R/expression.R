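# Downstream RNA-Seq computations: expression cutoff from the intergenic
# background, replicate QC by Spearman correlation, differential-expression
# calls, Z-score k-means signatures, paired DE-burden comparison, and
# hypergeometric gene-set enrichment. The DE engine here is a deliberate
# stand-in (Welch t on log2(FPKM+1)); externally computed DE results can be
# supplied to the later stages instead.

#' Construct an expression matrix object
#'
#' Genes x samples FPKM-like values together with the feature kind
#' (genic/intergenic) and the sample sheet (condition, replicate).
#'
#' @param values Numeric matrix, features x samples, non-negative; row names
#'   are feature ids, column names sample ids.
#' @param feature_kind Character vector (`"genic"` / `"intergenic"`) per row.
#' @param samples Data frame with columns `sample`, `condition`,
#'   `replicate`, one row per column of `values`.
#' @return An object of class `expr_matrix`.
#' @export
expression_matrix <- function(values, feature_kind, samples) {
  values <- as.matrix(values)
  stopifnot(length(feature_kind) == nrow(values),
            nrow(samples) == ncol(values),
            all(c("sample", "condition", "replicate") %in% names(samples)))
  if (any(values < 0)) stop("expression values must be non-negative")
  if (!all(feature_kind %in% c("genic", "intergenic"))) {
    stop("feature_kind must be 'genic' or 'intergenic'")
  }
  if (!identical(colnames(values), as.character(samples$sample))) {
    stop("column names of values must match samples$sample in order")
  }
  structure(list(values = values, feature_kind = feature_kind,
                 samples = samples),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("Expression matrix:", nrow(x$values), "features (",
      sum(x$feature_kind == "genic"), "genic /",
      sum(x$feature_kind == "intergenic"), "intergenic ) x",
      ncol(x$values), "samples in",
      length(unique(x$samples$condition)), "conditions\n")
  invisible(x)
}

#' Expression cutoff from the intergenic background
#'
#' The stated percentile (default 95) of all intergenic values pooled across
#' samples, computed with linear interpolation on the empirical
#' distribution. Genes whose maximum value stays below this threshold are
#' treated as unexpressed downstream.
#'
#' @param em An `expr_matrix`.
#' @param percentile Percentile of the intergenic background, default 95.
#' @return The threshold, in the same (FPKM-like) units as the data.
#' @export
expression_cutoff <- function(em, percentile = 95) {
  bg <- em$values[em$feature_kind == "intergenic", , drop = FALSE]
  if (nrow(bg) == 0L) stop("no intergenic features: cutoff undefined")
  if (nrow(bg) < 20L) {
    warning("fewer than 20 intergenic features; cutoff will be unstable")
  }
  unname(stats::quantile(as.vector(bg), percentile / 100, type = 7))
}

#' Flag and drop unexpressed genes
#'
#' @param em An `expr_matrix`.
#' @param threshold Expression cutoff, e.g. from [expression_cutoff()].
#' @return An `expr_matrix` restricted to genic features with at least one
#'   value >= `threshold`.
#' @export
filter_expressed <- function(em, threshold) {
  genic <- em$feature_kind == "genic"
  keep <- genic & apply(em$values, 1L, max) >= threshold
  expression_matrix(em$values[keep, , drop = FALSE],
                    em$feature_kind[keep], em$samples)
}

#' Replicate quality control by Spearman correlation
#'
#' Pairwise Spearman correlations on `log(FPKM + 1)` across all features.
#' Replicates whose median correlation with the other replicates of the
#' same condition falls below `rho_min` are dropped one at a time (worst
#' first) until stable; a condition never drops below 2 replicates (its
#' best-correlated pair is kept, with a warning).
#'
#' @param em An `expr_matrix` (usually already filtered to expressed genes).
#' @param rho_min Retention threshold on the within-condition median
#'   Spearman rho, default 0.95.
#' @return List: `retained` (sample ids), `dropped`, `rho` (the full
#'   correlation matrix on the input samples).
#' @export
replicate_qc <- function(em, rho_min = 0.95) {
  cond <- em$samples$condition
  if (any(table(cond) < 2L)) {
    stop("every condition needs >= 2 replicates on input")
  }
  lx <- log(em$values + 1)
  rho_full <- stats::cor(lx, method = "spearman")
  retained <- em$samples$sample
  repeat {
    worst_s <- NA_character_; worst_r <- Inf
    for (cd in unique(cond)) {
      s_cd <- em$samples$sample[cond == cd]
      s_cd <- s_cd[s_cd %in% retained]
      if (length(s_cd) <= 2L) next   # best-2 floor
      for (s in s_cd) {
        med <- stats::median(rho_full[s, setdiff(s_cd, s)])
        if (med < rho_min && med < worst_r) {
          worst_r <- med; worst_s <- s
        }
      }
    }
    if (is.na(worst_s)) break
    retained <- setdiff(retained, worst_s)
  }
  # conditions reduced to their floor where even the best pair is weak
  for (cd in unique(cond)) {
    s_cd <- intersect(em$samples$sample[cond == cd], retained)
    if (length(s_cd) == 2L && rho_full[s_cd[1L], s_cd[2L]] < rho_min) {
      warning("condition '", cd, "': best replicate pair has rho < ",
              rho_min, "; kept anyway (2-replicate floor)")
    }
  }
  list(retained = retained,
       dropped = setdiff(em$samples$sample, retained),
       rho = rho_full)
}

#' Differential-expression stand-in test
#'
#' Welch two-sample t test per gene on `log2(FPKM + 1)`; the log2 fold
#' change is the difference of condition means on that scale (B minus A).
#' Genes constant in both groups get p = 1. This is a pluggable stand-in
#' for an external DE engine; results from such an engine can be used in
#' the downstream stages instead.
#'
#' @param em An `expr_matrix`.
#' @param cond_a,cond_b Condition labels to compare.
#' @param alpha Significance level for the `significant` flag,
#'   default 0.001.
#' @return Data frame: `gene`, `log2fc`, `p`, `significant`.
#' @export
de_test <- function(em, cond_a, cond_b, alpha = 0.001) {
  sa <- em$samples$condition == cond_a
  sb <- em$samples$condition == cond_b
  if (sum(sa) < 2L || sum(sb) < 2L) {
    stop("both conditions need >= 2 retained replicates")
  }
  la <- log2(em$values[, sa, drop = FALSE] + 1)
  lb <- log2(em$values[, sb, drop = FALSE] + 1)
  ma <- rowMeans(la); mb <- rowMeans(lb)
  va <- apply(la, 1L, stats::var); vb <- apply(lb, 1L, stats::var)
  na <- ncol(la); nb <- ncol(lb)
  se2 <- va / na + vb / nb
  t_stat <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
  degenerate <- se2 == 0
  p[degenerate & (mb - ma) == 0] <- 1
  p[degenerate & (mb - ma) != 0] <- 0
  data.frame(gene = rownames(em$values),
             log2fc = mb - ma,
             p = p,
             significant = p < alpha,
             stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Z-score k-means expression signatures
#'
#' Scales each differentially expressed gene's condition means to Z scores
#' (mean 0, sd 1 across conditions) and partitions the genes with k-means
#' (fixed seed, 50 random restarts, best within-cluster sum of squares
#' kept). Cluster labels are canonicalized by decreasing cluster size so
#' they are reproducible. Genes with zero variance across condition means
#' are excluded with a warning (their Z score is undefined).
#'
#' @param em An `expr_matrix`.
#' @param de_genes Character vector of gene ids to cluster.
#' @param k Number of clusters, default 5.
#' @param seed RNG seed for the k-means restarts.
#' @param nstart Number of restarts, default 50.
#' @return List: `cluster` (named integer vector, labels 1..k by decreasing
#'   size), `centers` (k x conditions matrix of Z-score profiles),
#'   `excluded` (zero-variance genes), `tot_withinss`.
#' @export
signature_clusters <- function(em, de_genes, k = 5, seed = 1, nstart = 50) {
  stopifnot(length(de_genes) > 0)
  de_genes <- intersect(rownames(em$values), de_genes)
  if (k > length(de_genes)) stop("k exceeds the number of DE genes")
  conds <- sort(unique(em$samples$condition))
  cm <- sapply(conds, function(cd) {
    rowMeans(em$values[de_genes, em$samples$condition == cd, drop = FALSE])
  })
  sds <- apply(cm, 1L, stats::sd)
  excluded <- de_genes[sds == 0]
  if (length(excluded) > 0L) {
    warning(length(excluded),
            " gene(s) with zero variance across conditions excluded")
    cm <- cm[sds > 0, , drop = FALSE]
  }
  z <- t(scale(t(cm)))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  km <- stats::kmeans(z, centers = k, nstart = nstart, iter.max = 100L)
  # canonical labels: decreasing size, ties by first occurrence
  ord <- order(-km$size, seq_len(k))
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  cl <- relabel[km$cluster]
  names(cl) <- rownames(z)
  centers <- km$centers[ord, , drop = FALSE]
  rownames(centers) <- seq_len(k)
  list(cluster = cl, centers = centers, excluded = excluded,
       tot_withinss = km$tot.withinss)
}

#' Paired DE-burden comparison
#'
#' Two-sided Wilcoxon signed-rank test on paired per-gene values (e.g.
#' absolute log2 fold changes under an active vs an inactive derivative of
#' the same chemotype, in the same gene order). All-zero differences give
#' p = 1.
#'
#' @param active,inactive Equal-length paired numeric vectors.
#' @return Two-sided p-value.
#' @export
de_burden_compare <- function(active, inactive) {
  stopifnot(length(active) == length(inactive))
  d <- active - inactive
  if (all(d == 0)) return(1)
  stats::wilcox.test(active, inactive, paired = TRUE, exact = NULL,
                     correct = TRUE)$p.value
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test of each gene set's overlap with the DE
#' genes against the expressed-gene universe, with Benjamini-Hochberg
#' adjustment across sets.
#'
#' @param de_genes Character vector of DE gene ids (subset of `universe`).
#' @param universe Character vector: the expressed-gene universe.
#' @param gene_sets Named list of character vectors; each set is
#'   intersected with `universe` before testing.
#' @return Data frame per set: `set`, `n_set`, `n_overlap`, `fold`,
#'   `p`, `q` (BH-adjusted).
#' @export
set_enrichment <- function(de_genes, universe, gene_sets) {
  if (length(universe) == 0L) stop("empty universe")
  universe <- unique(universe)
  de_genes <- intersect(unique(de_genes), universe)
  n_univ <- length(universe)
  n_de <- length(de_genes)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), universe)
    k <- length(intersect(set, de_genes))
    m <- length(set)
    p <- if (m == 0L) 1 else {
      stats::phyper(k - 1L, m, n_univ - m, n_de, lower.tail = FALSE)
    }
    expected <- m * n_de / n_univ
    data.frame(set = nm, n_set = m, n_overlap = k,
               fold = if (expected > 0) k / expected else NA_real_,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}
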