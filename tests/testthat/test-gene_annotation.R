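# Coordinate arithmetic, consequence classification, naming.

test_that("CDS position maps to codon and offset by definition", {
  expect_equal(cds_to_codon(8375), list(codon_index = 2792L,
                                        offset_in_codon = 2L))
  expect_equal(cds_to_codon(1), list(codon_index = 1L, offset_in_codon = 1L))
  expect_equal(cds_to_codon(6), list(codon_index = 2L, offset_in_codon = 3L))
  expect_error(cds_to_codon(0), ">= 1")
  # inverse of codon expansion: positions 3k-2..3k -> codon k, offsets 1..3
  for (k in c(1L, 2L, 7L, 50L, 2792L)) {
    cc <- cds_to_codon((3L * k - 2L):(3L * k))
    expect_equal(cc$codon_index, rep(k, 3))
    expect_equal(cc$offset_in_codon, 1:3)
  }
})

test_that("genomic_to_cds matches brute-force enumeration on a toy gene, both strands", {
  tp <- make_toy("+", seed = 42)
  tm <- make_toy("-", seed = 42)
  L <- tp$model$chrom_len
  # hand-laid-out plus-strand structure: flank 10, exons 9/12/9, introns 20/30
  exon1 <- 11:19; exon2 <- 40:51; exon3 <- 82:90
  cds_positions <- c(exon1, exon2, exon3)
  naive <- function(p) {
    if (p %in% cds_positions) {
      return(list(kind = "coding", cds_pos = match(p, cds_positions)))
    }
    if (p >= 20 && p <= 39) {       # intron 1: donor after pos 19, acceptor at 40
      d <- p - 19L; a <- 40L - p
      return(list(kind = "intronic", intron_index = 1L,
                  offset = if (d <= a) d else -a))
    }
    if (p >= 52 && p <= 81) {       # intron 2
      d <- p - 51L; a <- 82L - p
      return(list(kind = "intronic", intron_index = 2L,
                  offset = if (d <= a) d else -a))
    }
    list(kind = "outside")
  }
  for (p in 1:L) {
    expect_equal(genomic_to_cds(p, tp$model), naive(p), info = paste("pos", p))
    # strand symmetry: the mirrored position on the mirrored gene agrees
    expect_equal(genomic_to_cds(L - p + 1L, tm$model), naive(p),
                 info = paste("mirrored pos", p))
  }
  # donor +3 of intron 2 and the first CDS base, explicitly
  expect_equal(genomic_to_cds(54, tp$model),
               list(kind = "intronic", intron_index = 2L, offset = 3L))
  expect_equal(genomic_to_cds(11, tp$model), list(kind = "coding", cds_pos = 1L))
  # inverse mapping round-trips intronic coordinates
  for (j in 1:2) for (off in c(1L, 3L, -2L)) {
    g <- intron_offset_to_genomic(tp$model, j, off)
    expect_equal(genomic_to_cds(g, tp$model),
                 list(kind = "intronic", intron_index = j, offset = off))
    g2 <- intron_offset_to_genomic(tm$model, j, off)
    expect_equal(genomic_to_cds(g2, tm$model),
                 list(kind = "intronic", intron_index = j, offset = off))
  }
})

test_that("coding SNVs classify through codon translation; a middle-base T>C of GTG gives V>A", {
  cds <- paste0("ATG", "GTG", "AAA", "CCC", "GGG", "TTT", "CTG", "GAA",
                "TGC", "TAA")
  tp <- make_toy("+", seed = 7, cds = cds)
  # CDS pos 5 (middle of the valine codon) is genomic 15 on this layout
  res <- classify_consequence("chr_TOY", 15, "T", "C", tp$model)
  expect_equal(res$category, "nonsynonymous")
  expect_equal(res$protein_change,
               list(ref_aa = "V", residue_index = 2L, alt_aa = "A"))
  # same change on the mirrored gene: complemented alleles at mirrored pos
  tm <- make_toy("-", seed = 7, cds = cds)
  res_m <- classify_consequence("chr_TOY", tm$model$chrom_len - 15 + 1,
                                "A", "G", tm$model)
  expect_equal(res_m$category, "nonsynonymous")
  expect_equal(res_m$protein_change, res$protein_change)
  # synonymous third-base change: AAA -> AAG at CDS 9 (genomic 19)
  expect_equal(classify_consequence("chr_TOY", 19, "A", "G", tp$model)$category,
               "synonymous")
  # stop gain: GAA -> TAA at CDS 22 (genomic 82)
  sg <- classify_consequence("chr_TOY", 82, "G", "T", tp$model)
  expect_equal(sg$category, "stop_gain")
  expect_equal(sg$protein_change$alt_aa, "*")
})

test_that("splice window is boundary-inclusive at 10 and indels classify by frame and junctions", {
  tp <- make_toy("+", seed = 9)
  chrom <- tp$chrom_seq
  m <- tp$model
  at <- function(p, len = 1) substring(chrom, p, p + len - 1)
  # intron 2 spans 52..81; donor offsets count from 51
  expect_equal(classify_consequence("chr_TOY", 61, at(61), "N", m)$category,
               "splice_region")              # +10, retained
  expect_equal(classify_consequence("chr_TOY", 62, at(62), "N", m)$category,
               "intronic")                   # +11, dropped
  # 2-base deletion in the CDS shifts frame; 3-base does not
  expect_equal(classify_consequence("chr_TOY", 44, at(44, 3), at(44, 1),
                                    m)$category, "frameshift_indel")
  expect_equal(classify_consequence("chr_TOY", 44, at(44, 4), at(44, 1),
                                    m)$category, "inframe_indel")
  # deletion straddling the exon-1 donor junction
  expect_equal(classify_consequence("chr_TOY", 18, at(18, 4), at(18, 1),
                                    m)$category, "splice_region")
  # intronic deletion near the boundary is splice region; deep one is not
  expect_equal(classify_consequence("chr_TOY", 21, at(21, 3), at(21, 1),
                                    m)$category, "splice_region")
  expect_equal(classify_consequence("chr_TOY", 65, at(65, 3), at(65, 1),
                                    m)$category, "intronic")
})

test_that("exonic positions outside the CDS are UTR and dropped by the filter", {
  tg <- make_toy("+", seed = 13)
  full <- tg$model
  utr_model <- gene_model("TOY", "TOY.t1", "chr_TOY", "+", full$exons,
                          cds_start = 14, cds_end = 87,
                          cds_seq = toy_cds(6), chrom_len = full$chrom_len)
  expect_equal(genomic_to_cds(12, utr_model)$kind, "utr")
  expect_equal(genomic_to_cds(89, utr_model)$kind, "utr")
  expect_equal(genomic_to_cds(14, utr_model), list(kind = "coding", cds_pos = 1L))
  expect_equal(classify_consequence("chr_TOY", 12, "A", "G",
                                    utr_model)$category, "utr")
})

test_that("functional_filter keeps exactly the damaging classes of a constructed 20-record fixture", {
  cds <- paste0("ATG", "GTG", "AAA", "CCC", "GGG", "TTT", "CTG", "GAA",
                "TGC", "TAA")
  tg <- make_toy("+", seed = 21, intron_lens = c(24L, 220L), cds = cds)
  m <- tg$model; chrom <- tg$chrom_seq
  at <- function(p, len = 1) substring(chrom, p, p + len - 1)
  # layout: exon1 11-19, intron1 20-43, exon2 44-55, intron2 56-275, exon3 276-284
  snv <- function(p, alt) list(pos = p, ref = at(p), alt = alt)
  del <- function(p, n) list(pos = p, ref = at(p, n + 1), alt = at(p, 1))
  fixture <- list(
    # 5 synonymous (third-base wobble changes)
    snv(19, "G"), snv(46, "T"), snv(49, "A"), snv(52, "C"), snv(55, "A"),
    # 5 nonsynonymous
    snv(15, "C"), snv(18, "C"), snv(44, "A"), snv(277, "C"), snv(281, "G"),
    # 4 splice-region at offsets +2, +3, +9, -10
    snv(21, "N"), snv(22, "N"), snv(64, "N"), snv(266, "N"),
    # 3 intronic at offsets +11, +30, +100
    snv(66, "N"), snv(85, "N"), snv(155, "N"),
    # 3 frameshift deletions in the CDS
    del(16, 1), del(47, 2), del(278, 1))
  vt <- variant_table(chrom = rep("chr_TOY", 20),
                      pos = vapply(fixture, `[[`, 0, "pos"),
                      ref = vapply(fixture, `[[`, "", "ref"),
                      alt = vapply(fixture, `[[`, "", "alt"))
  ann <- annotate_variants(vt, list(TOY = m))
  expect_equal(nrow(ann), 20)
  expect_equal(sum(ann$category == "synonymous"), 5)
  expect_equal(sum(ann$category == "nonsynonymous"), 5)
  expect_equal(sum(ann$category == "splice_region"), 4)
  expect_equal(sum(ann$category == "intronic"), 3)
  expect_equal(sum(ann$category == "frameshift_indel"), 3)
  kept <- functional_filter(ann)
  expect_equal(nrow(kept), 12)
  # monotone subset, order preserved
  expect_true(all(variant_key(kept) %in% variant_key(ann)))
  expect_equal(variant_key(kept),
               variant_key(ann)[ann$category %in%
                                  c("nonsynonymous", "stop_gain",
                                    "splice_region", "frameshift_indel")])
  # degenerate inputs
  expect_equal(nrow(functional_filter(ann[0, ])), 0)
  expect_equal(nrow(functional_filter(ann[ann$category == "synonymous", ])), 0)
})

test_that("classifier agrees with a full-CDS-rebuild translation oracle on random SNVs", {
  gm <- generate_gene_models(sim_config(seed = 77, n_genes = 25))
  oracle <- function(model, cds_pos, alt_t) {
    mut <- model$cds_seq
    substr(mut, cds_pos, cds_pos) <- alt_t
    p0 <- strsplit(as.character(Biostrings::translate(
      Biostrings::DNAString(model$cds_seq), no.init.codon = TRUE)), "")[[1]]
    p1 <- strsplit(suppressWarnings(as.character(Biostrings::translate(
      Biostrings::DNAString(mut), no.init.codon = TRUE))), "")[[1]]
    d <- which(p0 != p1)
    if (length(d) == 0) return(list(cat = "synonymous", idx = NA))
    list(cat = if (p1[d] == "*") "stop_gain" else "nonsynonymous", idx = d)
  }
  set.seed(78)
  n_checked <- 0
  while (n_checked < 1000) {
    model <- gm$models[[sample(length(gm$models), 1)]]
    cds_pos <- sample(nchar(model$cds_seq) - 3L, 1)   # spare the stop codon
    ref_t <- substr(model$cds_seq, cds_pos, cds_pos)
    alt_t <- sample(setdiff(c("A", "C", "G", "T"), ref_t), 1)
    flip <- model$strand == "-"
    got <- classify_consequence(
      model$chrom, model$cds_map[cds_pos],
      if (flip) comp_base(ref_t) else ref_t,
      if (flip) comp_base(alt_t) else alt_t, model)
    want <- oracle(model, cds_pos, alt_t)
    expect_equal(got$category, want$cat)
    if (!is.na(want$idx)) {
      expect_equal(got$protein_change$residue_index, want$idx)
    }
    n_checked <- n_checked + 1
  }
})

test_that("variant names render in the published notations", {
  expect_equal(hgvs_c_name(list(kind = "coding", cds_pos = 8375), "T", "C"),
               "c.8375T>C")
  expect_equal(hgvs_p_name("V", 2792, "A"), "p.V2792A")
  expect_equal(ivs_name(list(intron_index = 25, offset = 3), "G", "A"),
               "IVS25+3G>A")
  expect_equal(ivs_name(list(intron_index = 2, offset = -5), "C", "T"),
               "IVS2-5C>T")
  expect_error(hgvs_c_name(list(kind = "intronic", intron_index = 1,
                                offset = 3), "G", "A"), "coding")
})
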