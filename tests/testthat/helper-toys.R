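# Shared fixture builders: deterministic toy genes and in-memory quad
# variant tables. Everything is constructed in code at test time.

QUAD <- pedigree("I1", "I2", c("II1", "II2"), "FAMTEST")

# a CDS of ATG + n internal non-stop codons + TAA, deterministic
toy_cds <- function(n_internal, codons = c("AAA", "CCC", "GGG", "TTT",
                                           "ACA", "CTG", "GAA", "TGC")) {
  paste0("ATG", paste(rep_len(codons, n_internal), collapse = ""), "TAA")
}

# deterministic toy gene; same structure on either strand (same seed =>
# same transcript-orientation flanks and intron interiors)
make_toy <- function(strand = "+", seed = 42, exon_lens = c(9L, 12L, 9L),
                     intron_lens = c(20L, 30L), cds = NULL, flank = 10L,
                     gene = "TOY") {
  if (is.null(cds)) cds <- toy_cds(sum(exon_lens) / 3 - 2)
  set.seed(seed)
  build_toy_gene(gene, cds, exon_lens, intron_lens, strand, flank)
}

# quad variant table written directly: gts is a list of c(father, mother,
# child1, child2) dosage vectors, one element per variant
quad_variants <- function(pos, gts, chrom = "chrT", ref = "A", alt = "G",
                          gene = NULL) {
  n <- length(pos)
  g <- do.call(rbind, gts)
  vt <- variant_table(rep_len(chrom, n), pos, rep_len(ref, n),
                      rep_len(alt, n),
                      genotypes = list(I1 = g[, 1], I2 = g[, 2],
                                       II1 = g[, 3], II2 = g[, 4]))
  if (!is.null(gene)) vt$gene <- rep_len(gene, n)
  vt
}

# candidate summaries for scan/oracle comparison
cand_summary <- function(cands) {
  lapply(cands, function(x) {
    list(gene = x$gene_symbol, mode = x$mode, dual = x$dual_mode,
         keys = sort(paste(x$variants$chrom, x$variants$pos,
                           x$variants$ref, x$variants$alt, sep = ":")),
         origins = sort(x$variants$origin))
  })
}

# Mendelian compatibility of one child dosage given parent dosages
mendel_ok <- function(f, m, ch) {
  if (anyNA(c(f, m, ch))) return(TRUE)   # missing is not auditable
  ft <- switch(f + 1L, 0L, c(0L, 1L), 1L)
  mt <- switch(m + 1L, 0L, c(0L, 1L), 1L)
  any(outer(ft, mt, `+`) == ch)
}
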