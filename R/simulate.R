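# Deterministic synthetic quad-exome datasets with a planted causal
# recessive gene. One seeded RNG stream per dataset: models, planted
# variants, background, decoys, gene list, MSA, then the missingness draw,
# in that documented order. The missingness draw does not depend on the
# rate, so the missing sets are nested as the rate rises.

NON_STOP_CODONS <- setdiff(names(Biostrings::GENETIC_CODE),
                           c("TAA", "TAG", "TGA"))

#' Simulation configuration for a synthetic quad-exome dataset
#'
#' Defaults emulate a desk-scale exome: 200 multi-exon toy genes on one
#' pseudo-chromosome each, a few thousand background variants segregating
#' under Mendelian transmission of which ~90% are catalogued in the site
#' databases (the large known fraction is what makes database exclusion the
#' most powerful single filter, as in real exomes), a planted in-trans
#' compound-het pair in one gene (paternal coding non-synonymous SNV plus
#' maternal intronic donor+3 SNV, the configuration observed in the study
#' family), and near-miss decoys.
#'
#' @param seed integer RNG seed; every draw in the dataset flows from it.
#' @param n_genes number of toy genes (one pseudo-chromosome each).
#' @param exons_per_gene inclusive range of exon counts per gene.
#' @param exon_bp,intron_bp inclusive ranges of exon/intron lengths (bases).
#' @param flank_bp untranscribed flank on each side of a gene.
#' @param n_background_variants background variant count before
#'   deduplication.
#' @param db_membership_rate probability a background variant is catalogued
#'   in at least one site database.
#' @param planted_gene symbol of the causal gene (must be generated).
#' @param planted_mode `"compound_het"` or `"homozygous"`.
#' @param missingness_rate per-genotype missing probability, applied last.
#' @param decoys counts of near-miss decoy genes: `cis_pair` (two variants
#'   from the same parent), `hom_lookalike` (children homozygous but only
#'   one carrier parent), `known_db` (a perfect trans pair catalogued in the
#'   databases).
#' @param indel_rate fraction of background variants that are 1-2 bp
#'   deletions.
#' @param maf_known,maf_novel alternate-allele frequency ranges for
#'   database-catalogued and novel background variants: catalogued sites
#'   are common, novel ones rare, as in real site databases.
#' @param n_gene_list size of the disease-gene list (planted gene plus
#'   distractors).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genes = 200L,
                       exons_per_gene = c(2L, 8L),
                       exon_bp = c(60L, 240L), intron_bp = c(40L, 200L),
                       flank_bp = 100L,
                       n_background_variants = 2000L,
                       db_membership_rate = 0.9,
                       planted_gene = "GENE0001",
                       planted_mode = c("compound_het", "homozygous"),
                       missingness_rate = 0,
                       decoys = c(cis_pair = 2L, hom_lookalike = 2L,
                                  known_db = 2L),
                       indel_rate = 0.05,
                       maf_known = c(0.05, 0.5),
                       maf_novel = c(0.001, 0.02),
                       n_gene_list = 20L) {
  planted_mode <- match.arg(planted_mode)
  stopifnot(db_membership_rate >= 0, db_membership_rate <= 1,
            missingness_rate >= 0, missingness_rate <= 1,
            indel_rate >= 0, indel_rate <= 1,
            n_genes >= 1, exons_per_gene[1] >= 1,
            exon_bp[1] >= 9, intron_bp[1] >= 10)
  gene_id <- as.integer(sub("^GENE", "", planted_gene))
  if (is.na(gene_id) || gene_id < 1 || gene_id > n_genes) {
    stop("planted_gene must be one of the generated GENE%04d symbols")
  }
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 exons_per_gene = as.integer(exons_per_gene),
                 exon_bp = as.integer(exon_bp),
                 intron_bp = as.integer(intron_bp),
                 flank_bp = as.integer(flank_bp),
                 n_background_variants = as.integer(n_background_variants),
                 db_membership_rate = db_membership_rate,
                 planted_gene = planted_gene, planted_mode = planted_mode,
                 missingness_rate = missingness_rate,
                 decoys = decoys, indel_rate = indel_rate,
                 maf_known = maf_known, maf_novel = maf_novel,
                 n_gene_list = as.integer(n_gene_list)),
            class = "sim_config")
}

#' The simulated quad pedigree
#'
#' Father `I1`, mother `I2`, affected children `II1`, `II2`.
#' @param n_children number of affected children.
#' @return a [pedigree()].
#' @export
sim_pedigree <- function(n_children = 2L) {
  pedigree("I1", "I2", paste0("II", seq_len(n_children)), "FAMSIM")
}

#' Generate the toy gene models and pseudo-genome
#'
#' Seeds the RNG from `config$seed` and draws, per gene: exon count, exon
#' lengths (padded so the CDS length is divisible by 3), a CDS of start
#' codon + non-stop codons + stop codon, intron lengths with canonical
#' GT..AG ends, and a strand. Each gene sits on its own pseudo-chromosome.
#'
#' @param config a [sim_config()].
#' @return list with `models` (named list of [gene_model()]s) and `genome`
#'   (named character vector of chromosome sequences).
#' @export
generate_gene_models <- function(config) {
  set.seed(config$seed)
  models <- vector("list", config$n_genes)
  genome <- character(config$n_genes)
  chrom_names <- character(config$n_genes)
  for (i in seq_len(config$n_genes)) {
    sym <- sprintf("GENE%04d", i)
    n_ex <- sample(config$exons_per_gene[1]:config$exons_per_gene[2], 1)
    ex_len <- sample(config$exon_bp[1]:config$exon_bp[2], n_ex, replace = TRUE)
    pad <- (3L - sum(ex_len) %% 3L) %% 3L
    ex_len[n_ex] <- ex_len[n_ex] + pad
    n_codons <- sum(ex_len) %/% 3L
    cds <- paste0("ATG",
                  paste(sample(NON_STOP_CODONS, n_codons - 2L, replace = TRUE),
                        collapse = ""),
                  "TAA")
    in_len <- if (n_ex > 1) {
      sample(config$intron_bp[1]:config$intron_bp[2], n_ex - 1L,
             replace = TRUE)
    } else integer()
    strand <- sample(c("+", "-"), 1)
    tg <- build_toy_gene(sym, cds, ex_len, in_len, strand,
                         flank = config$flank_bp)
    models[[i]] <- tg$model
    genome[i] <- tg$chrom_seq
    chrom_names[i] <- tg$model$chrom
  }
  names(genome) <- chrom_names
  list(models = setNames(models, vapply(models, `[[`, "", "gene_symbol")),
       genome = genome)
}

# a coding SNV guaranteed nonsynonymous (and not stop-gain), avoiding the
# start and stop codons; genomic-strand alleles
pick_coding_snv <- function(model) {
  L <- nchar(model$cds_seq)
  repeat {
    cds_pos <- sample(4:(L - 3L), 1)
    cc <- cds_to_codon(cds_pos)
    codon <- substr(model$cds_seq, 3L * (cc$codon_index - 1L) + 1L,
                    3L * cc$codon_index)
    ref_t <- substr(codon, cc$offset_in_codon, cc$offset_in_codon)
    ref_aa <- unname(Biostrings::GENETIC_CODE[codon])
    alts <- sample(setdiff(c("A", "C", "G", "T"), ref_t))
    for (alt_t in alts) {
      mut <- codon
      substr(mut, cc$offset_in_codon, cc$offset_in_codon) <- alt_t
      alt_aa <- unname(Biostrings::GENETIC_CODE[mut])
      if (alt_aa != ref_aa && alt_aa != "*") {
        flip <- model$strand == "-"
        return(list(chrom = model$chrom, pos = model$cds_map[cds_pos],
                    ref = if (flip) comp_base(ref_t) else ref_t,
                    alt = if (flip) comp_base(alt_t) else alt_t,
                    cds_pos = cds_pos, aa_pos = cc$codon_index))
      }
    }
  }
}

# an intronic SNV at donor offset +3 of a random intron
pick_intron_snv <- function(model, genome) {
  n_introns <- nrow(model$exons) - 1L
  if (n_introns < 1) {
    stop("gene ", model$gene_symbol,
         " has no intron: cannot plant an intronic variant")
  }
  j <- if (n_introns == 1) 1L else sample(n_introns, 1)
  pos <- intron_offset_to_genomic(model, j, 3L)
  ref <- substring(genome[[model$chrom]], pos, pos)
  alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
  list(chrom = model$chrom, pos = pos, ref = ref, alt = alt,
       intron_index = j)
}

# genotype vectors in pedigree member order (father, mother, children)
quad_gt <- function(ped, father, mother, child) {
  gts <- setNames(vector("list", length(pedigree_members(ped))),
                  pedigree_members(ped))
  gts[[ped$father]] <- father
  gts[[ped$mother]] <- mother
  for (k in ped$affected_children) gts[[k]] <- child
  gts
}

#' Plant the causal variants
#'
#' Compound-het mode plants a paternal-origin coding nonsynonymous SNV and a
#' maternal-origin intronic SNV at donor offset +3 — the carrier split
#' observed in the study family — each heterozygous in both children and in
#' exactly one parent. Homozygous mode plants one coding nonsynonymous SNV
#' hom-alt in the children and het in both parents. Planted variants are
#' never entered into the site databases. Draws continue the dataset RNG
#' stream.
#'
#' @param config a [sim_config()].
#' @param models result of [generate_gene_models()]`$models`.
#' @param genome matching pseudo-genome.
#' @param ped the quad [pedigree()].
#' @return list with `records` (a [variant_table()]) and `truth`
#'   (`data.frame` of the planted variants with parental origins).
#' @export
plant_causal <- function(config, models, genome, ped = sim_pedigree()) {
  m <- models[[config$planted_gene]]
  if (is.null(m)) stop("planted gene not among the models")
  if (config$planted_mode == "compound_het") {
    cod <- pick_coding_snv(m)
    intr <- pick_intron_snv(m, genome)
    records <- variant_table(
      chrom = c(cod$chrom, intr$chrom), pos = c(cod$pos, intr$pos),
      ref = c(cod$ref, intr$ref), alt = c(cod$alt, intr$alt),
      genotypes = quad_gt(ped,
                          father = c(1L, 0L), mother = c(0L, 1L),
                          child = c(1L, 1L)))
    truth <- data.frame(
      chrom = c(cod$chrom, intr$chrom), pos = c(cod$pos, intr$pos),
      ref = c(cod$ref, intr$ref), alt = c(cod$alt, intr$alt),
      origin = c("father", "mother"), type = c("coding", "intronic"))
  } else {
    cod <- pick_coding_snv(m)
    records <- variant_table(
      chrom = cod$chrom, pos = cod$pos, ref = cod$ref, alt = cod$alt,
      genotypes = quad_gt(ped, father = 1L, mother = 1L, child = 2L))
    truth <- data.frame(chrom = cod$chrom, pos = cod$pos, ref = cod$ref,
                        alt = cod$alt, origin = "both", type = "coding")
  }
  truth$gene <- config$planted_gene
  list(records = records, truth = truth)
}

#' Generate background variants and decoy genes
#'
#' Background sites are drawn uniformly over transcript spans with
#' genotypes transmitted Mendelianly from random parental genotypes (each
#' child inherits one allele from each parent); a `db_membership_rate`
#' fraction is entered into the site databases. Decoy genes get near-miss
#' patterns: cis-only pairs (both variants from the mother), single-carrier
#' homozygous lookalikes (deliberately non-Mendelian, emulating a
#' genotyping error), and perfect trans pairs that are catalogued in the
#' databases. Draws continue the dataset RNG stream.
#'
#' @param config a [sim_config()].
#' @param models,genome from [generate_gene_models()].
#' @param ped the quad [pedigree()].
#' @param reserved_keys `chrom:pos` keys (e.g. of planted variants) that
#'   background sites must avoid.
#' @return list with `records`, `db_keys` (list `dbsnp_like`, `onekg_like`),
#'   `decoys` (`data.frame` gene/reason), and `background_keys` (variant
#'   keys subject to the Mendelian audit).
#' @export
generate_background <- function(config, models, genome, ped = sim_pedigree(),
                                reserved_keys = character()) {
  n <- config$n_background_variants
  gene_idx <- sample(config$n_genes, n, replace = TRUE)
  spans <- vapply(models, model_span, integer(2))
  chrom_v <- vapply(models, `[[`, "", "chrom")[gene_idx]
  lo <- spans[1, gene_idx]; hi <- spans[2, gene_idx]
  pos <- lo + floor(runif(n) * (hi - lo + 1L))
  is_del <- runif(n) < config$indel_rate
  del_len <- ifelse(is_del, sample(1:2, n, replace = TRUE), 0L)
  ref <- substring(genome[chrom_v], pos, pos + del_len)
  alt_draw <- mapply(function(r, d) {
    if (d > 0) substr(r, 1, 1) else sample(setdiff(c("A", "C", "G", "T"), r), 1)
  }, ref, del_len)
  keep <- !duplicated(paste(chrom_v, pos)) &
    !(paste(chrom_v, pos, sep = ":") %in% reserved_keys) &
    nchar(ref) == del_len + 1L & ref != alt_draw
  chrom_v <- chrom_v[keep]; pos <- pos[keep]
  ref <- ref[keep]; alt <- alt_draw[keep]
  n <- length(pos)

  # database membership is drawn first and the allele frequency conditioned
  # on it: catalogued sites are common, novel sites rare (what "not in
  # dbSNP" means for a segregating site)
  in_db <- runif(n) < config$db_membership_rate
  maf <- ifelse(in_db,
                runif(n, config$maf_known[1], config$maf_known[2]),
                runif(n, config$maf_novel[1], config$maf_novel[2]))
  f_dose <- rbinom(n, 2, maf)
  m_dose <- rbinom(n, 2, maf)
  transmit <- function(dose) ifelse(dose == 1L, rbinom(n, 1, 0.5), dose %/% 2L)
  kids <- ped$affected_children
  child_dose <- lapply(kids, function(k) transmit(f_dose) + transmit(m_dose))
  in_onekg <- in_db & runif(n) < 0.5
  informative <- f_dose + m_dose + Reduce(`+`, child_dose) > 0
  chrom_v <- chrom_v[informative]; pos <- pos[informative]
  ref <- ref[informative]; alt <- alt[informative]
  f_dose <- f_dose[informative]; m_dose <- m_dose[informative]
  child_dose <- lapply(child_dose, `[`, informative)
  in_db <- in_db[informative]; in_onekg <- in_onekg[informative]

  gts <- setNames(c(list(f_dose, m_dose), child_dose),
                  c(ped$father, ped$mother, kids))
  keyed <- paste(chrom_v, pos, ref, alt, sep = ":")
  bg <- variant_table(chrom_v, pos, ref, alt, gts)
  bg_keys <- variant_key(bg)
  db_keys <- list(dbsnp_like = keyed[in_db],
                  onekg_like = keyed[in_onekg])

  # decoys on genes free of other signals
  free_genes <- setdiff(names(models), config$planted_gene)
  n_decoy <- sum(config$decoys)
  decoy_genes <- sample(free_genes, n_decoy)
  decoy_tabs <- list(); decoy_df <- list(); gi <- 0L
  add_decoy <- function(gene, reason, tab) {
    decoy_tabs[[length(decoy_tabs) + 1L]] <<- tab
    decoy_df[[length(decoy_df) + 1L]] <<-
      data.frame(gene = gene, reason = reason)
  }
  for (k in seq_len(config$decoys[["cis_pair"]])) {
    gi <- gi + 1L; g <- decoy_genes[gi]
    v1 <- pick_coding_snv(models[[g]]); v2 <- pick_coding_snv(models[[g]])
    while (v2$pos == v1$pos) v2 <- pick_coding_snv(models[[g]])
    add_decoy(g, "cis_only", variant_table(
      chrom = c(v1$chrom, v2$chrom), pos = c(v1$pos, v2$pos),
      ref = c(v1$ref, v2$ref), alt = c(v1$alt, v2$alt),
      genotypes = quad_gt(ped, father = c(0L, 0L), mother = c(1L, 1L),
                          child = c(1L, 1L))))
  }
  for (k in seq_len(config$decoys[["hom_lookalike"]])) {
    gi <- gi + 1L; g <- decoy_genes[gi]
    v <- pick_coding_snv(models[[g]])
    add_decoy(g, "single_carrier_hom", variant_table(
      chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
      genotypes = quad_gt(ped, father = 1L, mother = 0L, child = 2L)))
  }
  for (k in seq_len(config$decoys[["known_db"]])) {
    gi <- gi + 1L; g <- decoy_genes[gi]
    v1 <- pick_coding_snv(models[[g]]); v2 <- pick_coding_snv(models[[g]])
    while (v2$pos == v1$pos) v2 <- pick_coding_snv(models[[g]])
    tab <- variant_table(
      chrom = c(v1$chrom, v2$chrom), pos = c(v1$pos, v2$pos),
      ref = c(v1$ref, v2$ref), alt = c(v1$alt, v2$alt),
      genotypes = quad_gt(ped, father = c(1L, 0L), mother = c(0L, 1L),
                          child = c(1L, 1L)))
    add_decoy(g, "in_databases", tab)
    db_keys$dbsnp_like <- c(db_keys$dbsnp_like, variant_key(tab))
  }
  records <- bind_variants(bg, do.call(bind_variants, decoy_tabs))
  list(records = records, db_keys = db_keys,
       decoys = do.call(rbind, decoy_df), background_keys = bg_keys)
}

# nine-species MSA around the planted protein; mammals conserved at the
# causal residue, outgroups free to diverge
sim_msa <- function(model, protect_residue = NA_integer_) {
  ref <- model_protein(model)
  L <- nchar(ref)
  rates <- c(human = 0, chimpanzee = 0.02, macaque = 0.03, cow = 0.05,
             dog = 0.05, mouse = 0.08, rat = 0.08, chicken = 0.20,
             zebrafish = 0.30)
  mammals <- c("human", "chimpanzee", "macaque", "cow", "dog", "mouse", "rat")
  aa_alphabet <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], NULL)
  seqs <- vapply(names(rates), function(sp) {
    s <- strsplit(ref, "")[[1]]
    if (rates[[sp]] > 0) {
      mut <- runif(L) < rates[[sp]]
      gap <- runif(L) < 0.02
      if (!is.na(protect_residue) && sp %in% mammals) {
        mut[protect_residue] <- FALSE
        gap[protect_residue] <- FALSE
      }
      s[mut] <- vapply(which(mut), function(i) {
        sample(setdiff(aa_alphabet, s[i]), 1)
      }, character(1))
      s[gap & !mut] <- "-"
    }
    paste(s, collapse = "")
  }, character(1))
  msa(seqs, reference = "human")
}

#' Simulate a complete quad-exome dataset in memory
#'
#' Runs the full generator in the documented draw order (models, planted
#' variants, background + decoys, gene list, MSA, missingness) from a
#' single RNG stream seeded with `config$seed`. Identical configs produce
#' identical datasets.
#'
#' @param config a [sim_config()].
#' @return list with `config`, `pedigree`, `models`, `genome`, `variants`
#'   (a [variant_table()]), `site_dbs` (list of two [site_set()]s),
#'   `gene_list`, `msa`, and `truth` (causal gene/variants, decoys, and the
#'   keys of audit-eligible background records).
#' @export
simulate_quad <- function(config = sim_config()) {
  gm <- generate_gene_models(config)        # seeds the stream
  ped <- sim_pedigree()
  planted <- plant_causal(config, gm$models, gm$genome, ped)
  reserved <- paste(planted$truth$chrom, planted$truth$pos, sep = ":")
  bg <- generate_background(config, gm$models, gm$genome, ped, reserved)

  distractors <- sample(setdiff(names(gm$models), config$planted_gene),
                        config$n_gene_list - 1L)
  gene_list <- structure(toupper(sample(c(config$planted_gene, distractors))),
                         class = "gene_list")

  protect <- if (config$planted_mode == "compound_het" ||
                 config$planted_mode == "homozygous") {
    idx <- which(planted$truth$type == "coding")[1]
    cds_pos <- match(planted$truth$pos[idx],
                     gm$models[[config$planted_gene]]$cds_map)
    if (is.na(cds_pos)) NA_integer_ else cds_to_codon(cds_pos)$codon_index
  } else NA_integer_
  alignment <- sim_msa(gm$models[[config$planted_gene]], protect)

  variants <- bind_variants(planted$records, bg$records)
  members <- pedigree_members(ped)
  u <- matrix(runif(nrow(variants) * length(members)), nrow = nrow(variants),
              dimnames = list(NULL, members))
  variants <- apply_missingness(variants, u, config$missingness_rate)

  site_dbs <- list(site_set(bg$db_keys$dbsnp_like, "dbsnp_like"),
                   site_set(bg$db_keys$onekg_like, "onekg_like"))
  truth <- list(causal_gene = config$planted_gene,
                causal_mode = config$planted_mode,
                causal_variants = planted$truth,
                decoys = bg$decoys,
                background_keys = bg$background_keys)
  list(config = config, pedigree = ped, models = gm$models,
       genome = gm$genome, variants = variants, site_dbs = site_dbs,
       gene_list = gene_list, msa = alignment, truth = truth,
       missing_u = u)
}

#' Mask genotypes as missing by thresholding a uniform draw
#'
#' Sets a genotype to `NA` wherever its mask entry is below `rate`. Because
#' the mask does not depend on the rate, the missing sets produced from one
#' mask are nested as the rate rises — raising the rate can only remove
#' information, never restore it.
#'
#' @param variants a [variant_table()].
#' @param u numeric matrix in `[0, 1]`, rows matching `variants`, columns
#'   named by sample id ([simulate_quad()] returns one as `missing_u`).
#' @param rate per-genotype missing probability.
#' @return the masked variant table.
#' @export
apply_missingness <- function(variants, u, rate) {
  stopifnot(nrow(u) == nrow(variants))
  if (rate > 0) {
    for (s in colnames(u)) {
      col <- paste0("gt_", s)
      variants[[col]][u[, s] < rate] <- NA_integer_
    }
  }
  variants
}

#' Write a simulated dataset to disk
#'
#' Emits the full self-contained bundle in the formats the readers consume:
#' `quad.vcf`, `family.ped`, `genes.bed` + `cds.fa`, `genome.fa`,
#' `dbsnp_like.tsv`, `onekg_like.tsv`, `gene_list.txt`, `msa.fa`,
#' `truth.json`, `config.yaml`.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the in-memory `sim` object and the named
#'   file `paths`.
#' @export
write_dataset <- function(config, dir) {
  sim <- simulate_quad(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- list(
    vcf = file.path(dir, "quad.vcf"), ped = file.path(dir, "family.ped"),
    bed = file.path(dir, "genes.bed"), cds = file.path(dir, "cds.fa"),
    genome = file.path(dir, "genome.fa"),
    dbsnp = file.path(dir, "dbsnp_like.tsv"),
    onekg = file.path(dir, "onekg_like.tsv"),
    gene_list = file.path(dir, "gene_list.txt"),
    msa = file.path(dir, "msa.fa"),
    truth = file.path(dir, "truth.json"),
    config = file.path(dir, "config.yaml"))
  write_vcf(sim$variants, sim$pedigree, p$vcf)
  write_ped(sim$pedigree, p$ped)
  write_gene_models(sim$models, p$bed, p$cds)
  write_genome(sim$genome, p$genome)
  write_sites_db(sim$site_dbs[[1]], p$dbsnp)
  write_sites_db(sim$site_dbs[[2]], p$onekg)
  writeLines(unclass(sim$gene_list), p$gene_list)
  write_msa(sim$msa, p$msa)
  jsonlite::write_json(sim$truth, p$truth, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  cfg <- unclass(sim$config)
  cfg$decoys <- as.list(cfg$decoys)
  yaml::write_yaml(cfg, p$config)
  invisible(list(sim = sim, paths = p))
}
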