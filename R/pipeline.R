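# End-to-end prioritization cascade: annotate -> functional filter ->
# known-site exclusion -> recessive segregation scan -> disease-gene
# intersection, with a per-stage count report.

#' Run the prioritization cascade on in-memory objects
#'
#' Stages run in the order of the published narrative: consequence
#' annotation, damaging-class filter, known-site exclusion, recessive
#' segregation scan, disease-gene-list intersection. The two
#' pre-segregation filters are order-independent (both are pure subset
#' filters on disjoint record properties).
#'
#' @param variants a [variant_table()].
#' @param ped a [pedigree()].
#' @param models named list of [gene_model()]s.
#' @param site_dbs list of [site_set()]s.
#' @param gene_list disease gene list (character / `gene_list`), or `NULL`
#'   to skip the intersection stage.
#' @param splice_window splice-region window in bases (default 10).
#' @return list with `candidates` (all genes surviving the recessive scan),
#'   `final` (after gene-list intersection), and `stages` (a `data.frame`
#'   of per-stage in/out counts).
#' @export
prioritize_variants <- function(variants, ped, models, site_dbs,
                                gene_list = NULL, splice_window = 10L) {
  stage <- function(name, n_in, n_out, note = "") {
    data.frame(stage = name, n_in = n_in, n_out = n_out, note = note)
  }
  ann <- annotate_variants(variants, models, splice_window)
  stages <- stage("annotate", nrow(variants), nrow(ann),
                  "one row per (variant, overlapping gene)")
  fun <- functional_filter(ann)
  stages <- rbind(stages, stage("functional_filter", nrow(ann), nrow(fun),
                                paste(FUNCTIONAL_CATEGORIES, collapse = ",")))
  novel <- exclude_known(fun, site_dbs)
  stages <- rbind(stages, stage("exclude_known", nrow(fun), nrow(novel),
                                paste(length(site_dbs), "database(s)")))
  candidates <- recessive_scan(novel, ped)
  n_var_cand <- sum(vapply(candidates, function(x) nrow(x$variants), 0L))
  modes <- table(factor(vapply(candidates, `[[`, "", "mode"),
                        levels = c("compound_het", "homozygous")))
  stages <- rbind(stages, stage(
    "recessive_scan", nrow(novel), n_var_cand,
    sprintf("%d compound_het + %d homozygous gene(s)",
            modes[["compound_het"]], modes[["homozygous"]])))
  final <- candidates
  if (!is.null(gene_list)) {
    final <- intersect_known_genes(candidates, gene_list)
    stages <- rbind(stages, stage(
      "intersect_known_genes", length(candidates), length(final),
      sprintf("list of %d gene(s)", length(unclass(gene_list)))))
  }
  stages$n_genes_out <- NA_integer_
  stages$n_genes_out[stages$stage == "recessive_scan"] <- length(candidates)
  stages$n_genes_out[stages$stage == "intersect_known_genes"] <- length(final)
  list(candidates = candidates, final = final, stages = stages)
}

#' Flatten candidates into a per-variant report table
#'
#' One row per candidate variant with its segregation mode, parental
#' origin, HGVS / IVS names, and (optionally) protein-domain hits and
#' alignment conservation for coding variants.
#'
#' @param candidates list of [candidate_gene()]s.
#' @param domain_table optional domain table for residue->domain mapping.
#' @param alignment optional [msa()] for conservation at coding residues.
#' @param mammal_ids mammal subset passed to [conservation_at()].
#' @return `data.frame` report (zero rows if no candidates).
#' @export
candidate_report <- function(candidates, domain_table = NULL,
                             alignment = NULL,
                             mammal_ids = c("human", "chimpanzee", "macaque",
                                            "cow", "dog", "mouse", "rat")) {
  rows <- list()
  for (cand in candidates) {
    v <- cand$variants
    for (i in seq_len(nrow(v))) {
      aa_pos <- if ("aa_pos" %in% names(v)) v$aa_pos[i] else NA_integer_
      dom <- NA_character_; cons <- NA_real_; mam <- NA
      if (!is.na(aa_pos) && !is.null(domain_table)) {
        hits <- map_residue_to_domain(aa_pos, domain_table)
        if (nrow(hits) > 0) dom <- paste(hits$domain, collapse = ";")
      }
      if (!is.na(aa_pos) && !is.null(alignment) &&
          aa_pos <= nchar(gsub("-", "", alignment$sequences[[alignment$reference]]))) {
        cv <- conservation_at(alignment, aa_pos, mammal_ids)
        cons <- cv$identity_fraction; mam <- cv$mammal_conserved
      }
      name <- if ("hgvs_c" %in% names(v) && !is.na(v$hgvs_c[i])) {
        v$hgvs_c[i]
      } else if ("ivs" %in% names(v) && !is.na(v$ivs[i])) {
        v$ivs[i]
      } else NA_character_
      rows[[length(rows) + 1L]] <- data.frame(
        gene = cand$gene_symbol, mode = cand$mode,
        dual_mode = cand$dual_mode,
        chrom = v$chrom[i], pos = v$pos[i], ref = v$ref[i], alt = v$alt[i],
        category = if ("category" %in% names(v)) v$category[i] else NA,
        origin = v$origin[i], name = name,
        hgvs_p = if ("hgvs_p" %in% names(v)) v$hgvs_p[i] else NA,
        domain = dom, identity_fraction = cons, mammal_conserved = mam)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(gene = character(), mode = character(),
                      dual_mode = logical(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      category = character(), origin = character(),
                      name = character(), hgvs_p = character(),
                      domain = character(), identity_fraction = double(),
                      mammal_conserved = logical()))
  }
  do.call(rbind, rows)
}

#' Run the full prioritization from files
#'
#' Thin file-level wrapper: reads every input with the package readers,
#' runs [prioritize_variants()], and (optionally) decorates the final
#' candidates with domain and conservation annotation and writes TSV/JSON
#' reports.
#'
#' @param vcf,ped,bed,cds_fasta input files (multi-sample VCF, 6-column
#'   PED, BED12 gene models, per-transcript CDS FASTA).
#' @param dbs character vector of site-database paths (TSV or sites VCF).
#' @param gene_list_path optional disease-gene list file.
#' @param domain_table_path optional domain table (TSV/YAML).
#' @param msa_path optional aligned protein FASTA.
#' @param splice_window splice-region window in bases.
#' @param out_dir if non-`NULL`, writes `candidates.tsv`, `report.json` and
#'   `stage_report.tsv` there.
#' @return list with `candidates`, `final`, `stages`, `report` (the final
#'   [candidate_report()] table).
#' @export
run_prioritization <- function(vcf, ped, bed, cds_fasta, dbs = character(),
                               gene_list_path = NULL,
                               domain_table_path = NULL, msa_path = NULL,
                               splice_window = 10L, out_dir = NULL) {
  pedigree <- read_ped(ped)
  variants <- read_vcf(vcf, pedigree)
  models <- read_gene_models(bed, cds_fasta)
  site_dbs <- lapply(dbs, read_sites_db)
  genes <- if (!is.null(gene_list_path)) read_gene_list(gene_list_path)
  res <- prioritize_variants(variants, pedigree, models, site_dbs, genes,
                             splice_window)
  domain_table <- if (!is.null(domain_table_path))
    read_domain_table(domain_table_path)
  alignment <- if (!is.null(msa_path)) read_msa(msa_path)
  res$report <- candidate_report(res$final, domain_table, alignment)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(res$report, file.path(out_dir, "candidates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(res$stages, file.path(out_dir, "stage_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(stages = res$stages, candidates = res$report),
      file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  res
}
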