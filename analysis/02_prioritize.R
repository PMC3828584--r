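#!/usr/bin/env Rscript
# Run the full prioritization cascade on the simulated dataset from
# 01_simulate.R, exactly as it would run on real files: consequence
# annotation, damaging-class filter, known-site exclusion, recessive
# segregation scan, and intersection with the disease-gene list. Writes the
# per-stage count report and the final candidate table under results/.

library(quadrec)

paths <- list(
  vcf = "results/dataset/quad.vcf", ped = "results/dataset/family.ped",
  bed = "results/dataset/genes.bed", cds = "results/dataset/cds.fa",
  dbs = c("results/dataset/dbsnp_like.tsv", "results/dataset/onekg_like.tsv"),
  genes = "results/dataset/gene_list.txt", msa = "results/dataset/msa.fa")
stopifnot(file.exists(paths$vcf))   # run 01_simulate.R first

res <- run_prioritization(
  vcf = paths$vcf, ped = paths$ped, bed = paths$bed, cds_fasta = paths$cds,
  dbs = paths$dbs, gene_list_path = paths$genes, msa_path = paths$msa,
  out_dir = "results")

cat("stage report:\n")
print(res$stages)
cat("\nfinal candidates:\n")
print(res$report)

truth <- jsonlite::read_json("results/dataset/truth.json",
                             simplifyVector = TRUE)
got <- vapply(res$final, `[[`, "", "gene_symbol")
cat("\nplanted gene", truth$causal_gene,
    if (identical(got, truth$causal_gene)) "recovered exactly."
    else paste("NOT uniquely recovered; got:", paste(got, collapse = ",")),
    "\n")
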