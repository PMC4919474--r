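# Structural-series support for triage ("multiple structurally similar
# compounds") and the cross-species activity-concordance summary over the
# derivative panel. Fingerprints are plain bit vectors of any origin; no
# chemistry I/O is required in core.

#' Tanimoto (Jaccard) similarity between two fingerprints
#'
#' `|a AND b| / |a OR b|` on equal-length bit vectors. Two all-zero vectors
#' are defined as identical (similarity 1).
#'
#' @param a,b Logical or 0/1 integer vectors of equal length.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) {
    stop("fingerprint length mismatch: ", length(a), " vs ", length(b))
  }
  a <- as.logical(a); b <- as.logical(b)
  denom <- sum(a | b)
  if (denom == 0L) return(1)
  sum(a & b) / denom
}

#' Cluster compounds into structural series
#'
#' Single-linkage components of the graph joining fingerprint pairs with
#' Tanimoto similarity at or above `threshold`. Single linkage is
#' deliberate: triage only asks whether a compound has at least one
#' structurally similar neighbor, not for tight clusters. Series labels are
#' deterministic (the lexicographically smallest member id).
#'
#' @param fingerprints A named list of bit vectors, or a logical/0-1 matrix
#'   with one row per compound and row names as compound ids.
#' @param threshold Similarity threshold in `(0, 1]`, default 0.7.
#' @return Data frame: `compound_id`, `series_id`, `series_size`,
#'   `support` (`TRUE` when the series has >= 2 members).
#' @export
cluster_series <- function(fingerprints, threshold = 0.7) {
  stopifnot(threshold > 0, threshold <= 1)
  if (is.list(fingerprints)) {
    fingerprints <- do.call(rbind, lapply(fingerprints, as.logical))
  }
  fp <- matrix(as.logical(fingerprints), nrow = nrow(fingerprints),
               dimnames = dimnames(fingerprints))
  ids <- rownames(fp)
  if (is.null(ids)) stop("fingerprints must carry compound ids as names")
  n <- nrow(fp)
  # pairwise Tanimoto via bit counts: |A&B| = M %*% t(M), |A|B| by inclusion-
  # exclusion; all-zero pairs are defined as similar (handled below)
  m <- fp * 1L
  inter <- tcrossprod(m)
  sizes <- diag(inter)
  union <- outer(sizes, sizes, "+") - inter
  sim <- ifelse(union > 0, inter / union, 1)
  adj <- sim >= threshold
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  series_id <- vapply(seq_len(n), function(i) {
    min(ids[comp == comp[i]])
  }, character(1))
  size <- as.integer(table(comp)[as.character(comp)])
  out <- data.frame(compound_id = ids, series_id = series_id,
                    series_size = size, support = size >= 2L,
                    stringsAsFactors = FALSE)
  out <- out[order(out$compound_id), ]
  rownames(out) <- NULL
  out
}

ACTIVITY_CALLS <- c("no_change", "reduced", "absent", "not_analyzed")

#' Cross-species activity concordance per chemotype
#'
#' Fraction of the derivatives of each chemotype whose lipid-storage call is
#' active (`reduced` or `absent`) in every analyzed cell line.
#' `not_analyzed` entries are excluded from the all-lines requirement, and a
#' derivative with no analyzed mammalian line at all is excluded from the
#' denominator (declared convention).
#'
#' @param calls Data frame or character matrix, one row per derivative
#'   (row names = derivative ids), one column per cell line; entries from
#'   `no_change`, `reduced`, `absent`, `not_analyzed`.
#' @param chemotypes Named character vector mapping derivative id ->
#'   chemotype.
#' @param species Named character vector mapping cell-line (column) name ->
#'   `"fly"` or `"mammal"`.
#' @return Data frame per chemotype: `chemotype`, `n_active`, `n_total`,
#'   `fraction` (`NA` when the denominator is empty).
#' @export
cross_species_concordance <- function(calls, chemotypes, species) {
  calls <- as.matrix(calls)
  if (!all(calls %in% ACTIVITY_CALLS)) {
    bad <- setdiff(unique(as.vector(calls)), ACTIVITY_CALLS)
    stop("unknown activity call(s): ", paste(bad, collapse = ", "))
  }
  if (!all(colnames(calls) %in% names(species))) {
    stop("every cell-line column needs a species label")
  }
  ids <- rownames(calls)
  if (!all(ids %in% names(chemotypes))) {
    stop("every derivative needs a chemotype")
  }
  mam_cols <- colnames(calls)[species[colnames(calls)] == "mammal"]
  analyzed <- calls != "not_analyzed"
  active <- calls %in% c("reduced", "absent")
  dim(active) <- dim(calls)
  has_mam <- rowSums(analyzed[, mam_cols, drop = FALSE]) > 0
  all_active <- rowSums(analyzed & !active) == 0 & rowSums(analyzed) > 0
  eligible <- has_mam
  ct <- chemotypes[ids]
  out <- do.call(rbind, lapply(sort(unique(ct)), function(g) {
    sel <- ct == g & eligible
    n_total <- sum(sel)
    n_active <- sum(sel & all_active)
    data.frame(chemotype = g, n_active = n_active, n_total = n_total,
               fraction = if (n_total > 0) n_active / n_total else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
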