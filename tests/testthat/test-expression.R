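null_em <- function(n_genes = 200, n_intergenic = 30, seed = 1, ...) {
  simulate_expression(n_genes = n_genes, n_intergenic = n_intergenic,
                      effect = 0, seed = seed, ...)$em
}

test_that("expression cutoff is the interpolated intergenic percentile", {
  samples <- data.frame(sample = "s1", condition = "A", replicate = 1)
  vals <- matrix(0.01 * (1:100), ncol = 1,
                 dimnames = list(sprintf("ig%03d", 1:100), "s1"))
  em <- expression_matrix(vals, rep("intergenic", 100), samples)
  cut <- expression_cutoff(em, 95)
  expect_gt(cut, 0.95); expect_lt(cut, 1.00)
  expect_equal(cut, unname(quantile(0.01 * (1:100), 0.95, type = 7)))

  # monotone in the percentile
  expect_lte(expression_cutoff(em, 90), expression_cutoff(em, 95))
  expect_lte(expression_cutoff(em, 95), expression_cutoff(em, 99))

  # all-zero background: threshold 0, nothing filtered
  vals0 <- rbind(matrix(2, 5, 1, dimnames = list(paste0("g", 1:5), NULL)),
                 matrix(0, 30, 1, dimnames = list(paste0("i", 1:30), NULL)))
  colnames(vals0) <- "s1"
  em0 <- expression_matrix(vals0, rep(c("genic", "intergenic"), c(5, 30)),
                           samples)
  expect_equal(expression_cutoff(em0), 0)
  expect_equal(nrow(filter_expressed(em0, 0)$values), 5L)

  # no intergenic features is an error, few a warning
  emg <- expression_matrix(vals0[1:5, , drop = FALSE], rep("genic", 5),
                           samples)
  expect_error(expression_cutoff(emg), "intergenic")
  em_few <- expression_matrix(vals0[1:10, , drop = FALSE],
                              rep(c("genic", "intergenic"), each = 5),
                              samples)
  expect_warning(expression_cutoff(em_few), "fewer than 20")
})

test_that("the generator's background reproduces the 1.04 cutoff", {
  sim <- simulate_expression(n_genes = 300, n_intergenic = 200, seed = 7)
  expect_equal(expression_cutoff(sim$em), 1.04, tolerance = 1e-8)
})

test_that("filtering never removes a gene reaching the threshold", {
  em <- null_em(seed = 3)
  t <- expression_cutoff(em)
  kept <- filter_expressed(em, t)
  dropped <- setdiff(rownames(em$values)[em$feature_kind == "genic"],
                     rownames(kept$values))
  if (length(dropped) > 0) {
    expect_true(all(apply(em$values[dropped, , drop = FALSE], 1, max) < t))
  }
  expect_true(all(apply(kept$values, 1, max) >= t))
})

test_that("replicate QC keeps concordant replicates and drops corrupt ones", {
  em <- null_em(seed = 4)
  # identical up to a monotone transform: Spearman 1, all retained
  v <- em$values
  v[, em$samples$condition == "DMSO_OA"][, 2] <-
    (v[, em$samples$condition == "DMSO_OA"][, 2])^2
  em_m <- expression_matrix(v, em$feature_kind, em$samples)
  qc <- replicate_qc(em_m)
  expect_length(qc$dropped, 0L)

  # a permuted replicate decorrelates and is dropped
  v2 <- em$values
  set.seed(9); v2[, 5] <- sample(v2[, 5])
  qc2 <- replicate_qc(expression_matrix(v2, em$feature_kind, em$samples))
  expect_equal(qc2$dropped, em$samples$sample[5])

  # a fully discordant condition hits the best-2 floor with a warning
  v3 <- em$values
  bad_cols <- which(em$samples$condition == "CT1_active")
  set.seed(10)
  for (j in bad_cols) v3[, j] <- sample(v3[, j])
  expect_warning(qc3 <- replicate_qc(expression_matrix(v3, em$feature_kind,
                                                       em$samples)),
                 "floor")
  expect_equal(sum(qc3$retained %in% em$samples$sample[bad_cols]), 2L)

  # a condition arriving with < 2 replicates is an error
  keep <- !em$samples$sample %in% em$samples$sample[1:2]
  em_s <- expression_matrix(em$values[, keep],
                            em$feature_kind, em$samples[keep, ])
  expect_error(replicate_qc(em_s), ">= 2 replicates")
})

test_that("the DE stand-in recovers planted shifts without false positives", {
  sim <- simulate_expression(n_genes = 2000, genes_per_cluster = 10,
                             effect = 2, noise_sd = 0.1, seed = 11)
  # cluster 1 genes are shifted 4-fold in the first condition; the
  # comparison condition carries no planted cluster of its own
  de <- de_test(sim$em, "CT1_inactive", "DMSO_OA")
  planted <- sim$truth$gene[sim$truth$cluster == 1]
  expect_true(all(de$significant[de$gene %in% planted]))
  n_null <- sum(!de$gene %in% planted)
  fp <- sum(de$significant & !de$gene %in% planted)
  expect_lte(fp, qbinom(0.99, n_null, 0.001))

  # two unplanted conditions: nothing beyond the false-positive rate
  de0 <- de_test(sim$em, "CT2_inactive", "CT3_inactive", alpha = 0.001)
  expect_lte(mean(de0$significant), 0.005)

  # a constant gene takes the p = 1 branch
  em <- sim$em
  em$values["G00999", ] <- 5
  dec <- de_test(em, "DMSO_OA", "CT1_active")
  expect_equal(dec$p[dec$gene == "G00999"], 1)
})

test_that("DE type-I error at alpha is within 3x binomial SE", {
  sim <- simulate_expression(n_genes = 5000, effect = 0, seed = 12)
  de <- de_test(sim$em, "CT1_active", "CT3_active", alpha = 0.001)
  expected <- 5000 * 0.001
  se <- sqrt(5000 * 0.001 * 0.999)
  expect_lte(sum(de$significant), expected + 3 * se)
})

test_that("signature clustering recovers planted structure deterministically", {
  sim <- simulate_expression(seed = 13)
  de_genes <- sim$truth$gene[sim$truth$cluster > 0]
  sc <- signature_clusters(sim$em, de_genes, k = 5, seed = 21)
  truth <- sim$truth$cluster[match(names(sc$cluster), sim$truth$gene)]
  expect_equal(mclust::adjustedRandIndex(sc$cluster, truth), 1)

  # deterministic given the seed
  sc2 <- signature_clusters(sim$em, de_genes, k = 5, seed = 21)
  expect_identical(sc$cluster, sc2$cluster)

  # permuting sample order leaves assignments unchanged
  perm <- sample(ncol(sim$em$values))
  em_p <- expression_matrix(sim$em$values[, perm], sim$em$feature_kind,
                            sim$em$samples[perm, ])
  sc3 <- signature_clusters(em_p, de_genes, k = 5, seed = 21)
  expect_identical(sc$cluster, sc3$cluster)

  # k = 1: inertia equals the total scaled variance around the center
  sc1 <- signature_clusters(sim$em, de_genes, k = 1, seed = 21)
  conds <- sort(unique(sim$em$samples$condition))
  cm <- sapply(conds, function(cd) {
    rowMeans(sim$em$values[de_genes, sim$em$samples$condition == cd])
  })
  z <- t(scale(t(cm)))
  expect_equal(sc1$tot_withinss, sum(scale(z, scale = FALSE)^2),
               tolerance = 1e-8)

  # zero-variance genes are excluded with a warning
  em <- sim$em
  em$values["G00001", ] <- 3
  expect_warning(sc4 <- signature_clusters(em, de_genes, k = 5, seed = 21),
                 "zero variance")
  expect_equal(sc4$excluded, "G00001")
})

test_that("paired DE-burden comparison behaves at its extremes", {
  x <- runif(100)
  expect_equal(de_burden_compare(x, x), 1)
  expect_lt(de_burden_compare(x + 2, x), 1e-10)

  # exact small-sample value vs enumeration of all 2^10 sign patterns
  d <- 1:10 * c(-1, rep(1, 9))
  v_obs <- sum(rank(abs(d))[d > 0])
  all_v <- apply(expand.grid(rep(list(c(0, 1)), 10)), 1,
                 function(s) sum((1:10)[s == 1]))
  p_enum <- mean(all_v >= v_obs | all_v <= sum(1:10) - v_obs)
  expect_equal(de_burden_compare(d, rep(0, 10)), p_enum)
})

test_that("hypergeometric enrichment matches closed forms and BH rules", {
  genes <- paste0("g", 1:20)
  en <- set_enrichment(genes[1:5], genes, list(hit = genes[1:5]))
  expect_equal(en$p, 1 / choose(20, 5))

  en2 <- set_enrichment(genes[1:2], genes, list(miss = genes[15:20]))
  expect_gt(en2$p, 0.45)

  # hand BH computation
  sets <- list(a = genes[1:5], b = genes[6:10], c = genes[11:13])
  en3 <- set_enrichment(genes[1:5], genes, sets)
  expect_equal(en3$q, p.adjust(en3$p, "BH"))
  expect_equal(p.adjust(c(0.001, 0.02, 0.9), "BH"), c(0.003, 0.03, 0.9))

  # q monotone in p and bounded by 1
  expect_true(all(en3$q <= 1))
  expect_true(all(diff(en3$q[order(en3$p)]) >= -1e-12))
  expect_error(set_enrichment(genes[1], character(0), sets), "empty")
})
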