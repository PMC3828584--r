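#!/usr/bin/env Rscript
# Robustness of planted-gene recovery to genotype missingness. For each of
# 20 seeds the same dataset is masked at increasing missingness rates (the
# mask is nested, so per-seed recovery can only decay) and the full cascade
# is re-scored. Writes the recovery curve to results/recovery.tsv.

library(quadrec)

seeds <- 1:20
rates <- c(0, 0.1, 0.3, 0.6, 0.9)
recovered <- matrix(NA, length(seeds), length(rates),
                    dimnames = list(seeds, rates))

for (si in seq_along(seeds)) {
  sim <- simulate_quad(sim_config(seed = seeds[si]))
  ann <- annotate_variants(sim$variants, sim$models)
  novel <- exclude_known(functional_filter(ann), sim$site_dbs)
  idx <- match(variant_key(novel), variant_key(sim$variants))
  for (ri in seq_along(rates)) {
    masked <- apply_missingness(sim$variants, sim$missing_u, rates[ri])
    nv <- novel
    for (s in colnames(sim$missing_u)) {
      nv[[paste0("gt_", s)]] <- masked[[paste0("gt_", s)]][idx]
    }
    final <- intersect_known_genes(recessive_scan(nv, sim$pedigree),
                                   sim$gene_list)
    recovered[si, ri] <- sim$truth$causal_gene %in%
      vapply(final, `[[`, "", "gene_symbol")
  }
}

curve <- data.frame(missingness_rate = rates,
                    recovery = colMeans(recovered),
                    n_seeds = length(seeds))
dir.create("results", showWarnings = FALSE)
write.table(curve, "results/recovery.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("recovery by missingness rate (", length(seeds), "seeds ):\n")
print(curve)
stopifnot(curve$recovery[1] == 1, all(diff(curve$recovery) <= 0))
cat("recovery is 20/20 at zero missingness and monotone non-increasing.\n")
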