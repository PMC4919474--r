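#!/usr/bin/env Rscript
# Stage 3: the RNA-Seq downstream chain on a synthetic matrix with planted
# signatures: intergenic-background expression cutoff -> replicate QC by
# Spearman correlation -> stand-in DE calls at p < 0.001 -> Z-score k-means
# signatures (k = 5) -> paired DE-burden comparison -> hypergeometric set
# enrichment.

library(ldscreen)

sim <- simulate_expression(n_genes = 1000, n_intergenic = 250,
                           effect = 2, seed = 31)
em <- sim$em

cutoff <- expression_cutoff(em, percentile = 95)
cat(sprintf("Expression cutoff (95th pct of intergenic background): %.3f\n",
            cutoff))
expressed <- filter_expressed(em, cutoff)
cat(sprintf("Expressed genes: %d of %d\n", nrow(expressed$values),
            sum(em$feature_kind == "genic")))

qc <- replicate_qc(expressed, rho_min = 0.95)
cat(sprintf("Replicate QC: %d samples retained, %d dropped\n",
            length(qc$retained), length(qc$dropped)))

# DE per active chemotype condition vs the OA-loaded solvent control
de_by_cond <- lapply(c("CT1_active", "CT2_active", "CT3_active"),
                     function(cd) de_test(expressed, "DMSO_OA", cd,
                                          alpha = 0.001))
names(de_by_cond) <- c("CT1_active", "CT2_active", "CT3_active")
n_de <- vapply(de_by_cond, function(d) sum(d$significant), integer(1))
cat("Significant genes (p < 0.001) vs DMSO_OA:\n"); print(n_de)

de_genes <- unique(unlist(lapply(de_by_cond,
                                 function(d) d$gene[d$significant])))
sc <- signature_clusters(expressed, de_genes, k = 5, seed = 32)
truth <- sim$truth$cluster[match(names(sc$cluster), sim$truth$gene)]
cat(sprintf("Signature clusters: %d genes in 5 clusters (sizes %s)\n",
            length(sc$cluster),
            paste(table(sc$cluster), collapse = "/")))

# active-vs-inactive burden: paired |log2FC| per gene
burden_p <- de_burden_compare(
  abs(de_test(expressed, "DMSO_OA", "CT1_active")$log2fc),
  abs(de_test(expressed, "DMSO_OA", "CT1_inactive")$log2fc))
cat(sprintf("DE burden, active vs inactive CT1 (signed-rank): p = %.3g\n",
            burden_p))

# enrichment of the planted clusters among the DE calls
sets <- split(sim$truth$gene[sim$truth$cluster > 0],
              paste0("cluster", sim$truth$cluster[sim$truth$cluster > 0]))
en <- set_enrichment(de_genes, rownames(expressed$values), sets)
dir.create("results/expression", recursive = TRUE, showWarnings = FALSE)
write.csv(en, "results/expression/enrichment.csv", row.names = FALSE)
write.csv(data.frame(gene = names(sc$cluster), cluster = sc$cluster),
          "results/expression/clusters.csv", row.names = FALSE)
cat("Enrichment of planted clusters among DE genes:\n")
print(en[order(en$p), c("set", "n_overlap", "n_set", "fold", "q")],
      row.names = FALSE)
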