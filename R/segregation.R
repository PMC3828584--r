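# The recessive-model core: shared-homozygous and in-trans compound-het
# candidate genes in a quad pedigree under full penetrance. Missing
# genotypes fail closed.

#' Does a variant qualify as a shared-homozygous recessive candidate?
#'
#' True iff every affected child is homozygous for the alternate allele and
#' both parents are heterozygous carriers. Any missing genotype fails
#' closed (returns `FALSE`).
#'
#' @param record one-row [variant_table()] (or a row of one).
#' @param ped a [pedigree()].
#' @return logical.
#' @export
homozygous_qualifies <- function(record, ped) {
  g <- gt_matrix(record, pedigree_members(ped))[1, ]
  if (anyNA(g)) return(FALSE)
  all(g[ped$affected_children] == 2L) &&
    g[ped$father] == 1L && g[ped$mother] == 1L
}

#' Infer the parental origin of a variant heterozygous in the children
#'
#' The variant is maternal iff the mother carries the allele (het or
#' hom-alt) and the father is homozygous reference; paternal symmetric.
#' Both parents carrying gives `ambiguous` (the pair cannot be phased from
#' the quad alone); neither parent carrying gives `inconsistent` (possible
#' de novo or genotyping error). A missing parental genotype gives
#' `ambiguous`.
#'
#' @param record one-row [variant_table()], het in all affected children.
#' @param ped a [pedigree()].
#' @return one of `"mother"`, `"father"`, `"ambiguous"`, `"inconsistent"`.
#' @export
assign_parental_origin <- function(record, ped) {
  g <- gt_matrix(record, c(ped$father, ped$mother))[1, ]
  f <- g[ped$father]; m <- g[ped$mother]
  if (is.na(f) || is.na(m)) return("ambiguous")
  f_carries <- f >= 1L; m_carries <- m >= 1L
  if (m_carries && !f_carries) return("mother")
  if (f_carries && !m_carries) return("father")
  if (f_carries && m_carries) return("ambiguous")
  "inconsistent"
}

# a het-in-all-children record with complete genotypes and no hom-alt parent
# (an unaffected hom-alt parent contradicts the full-penetrance model)
comp_het_listable <- function(gm, ped) {
  kids <- ped$affected_children
  apply(gm, 1, function(g) {
    !anyNA(g) && all(g[kids] == 1L) &&
      g[ped$father] != 2L && g[ped$mother] != 2L
  })
}

#' Test a gene's variants for in-trans compound heterozygosity
#'
#' Considers records heterozygous in all affected children with complete
#' genotypes and no homozygous-alt parent, assigns parental origins, and
#' qualifies the gene iff at least one unambiguously maternal and one
#' unambiguously paternal variant exist (trans configuration). Variants
#' whose origin is ambiguous (both parents carriers) do not count toward the
#' trans requirement but are reported in the candidate's variant list as
#' unphased extras.
#'
#' @param gene_records [variant_table()] rows sharing one gene.
#' @param ped a [pedigree()].
#' @return a `candidate_gene` (mode `compound_het`) or `NULL`.
#' @export
compound_het_qualifies <- function(gene_records, ped) {
  if (nrow(gene_records) == 0) return(NULL)
  gm <- gt_matrix(gene_records, pedigree_members(ped))
  ok <- comp_het_listable(gm, ped)
  listable <- gene_records[ok, , drop = FALSE]
  if (nrow(listable) == 0) return(NULL)
  origin <- vapply(seq_len(nrow(listable)), function(i) {
    assign_parental_origin(listable[i, , drop = FALSE], ped)
  }, character(1))
  keep <- origin != "inconsistent"
  listable <- listable[keep, , drop = FALSE]
  origin <- origin[keep]
  if (!any(origin == "mother") || !any(origin == "father")) return(NULL)
  gene <- if ("gene" %in% names(listable)) listable$gene[1] else NA_character_
  candidate_gene(gene, "compound_het", listable, origin)
}

#' Construct a candidate gene
#'
#' @param gene_symbol gene label.
#' @param mode `"homozygous"` or `"compound_het"`.
#' @param variants the qualifying [variant_table()] rows.
#' @param parental_origin per-variant origin (`mother`/`father`/`ambiguous`);
#'   required for compound-het candidates, which must have at least one
#'   maternal and one paternal variant.
#' @param dual_mode flag set when a gene qualifies under both modes.
#' @return an object of class `candidate_gene`.
#' @export
candidate_gene <- function(gene_symbol, mode, variants,
                           parental_origin = NULL, dual_mode = FALSE) {
  stopifnot(mode %in% c("homozygous", "compound_het"))
  if (mode == "compound_het") {
    stopifnot(length(parental_origin) == nrow(variants),
              any(parental_origin == "mother"),
              any(parental_origin == "father"))
  }
  variants <- as.data.frame(variants)
  variants$origin <- if (is.null(parental_origin))
    rep("biparental", nrow(variants)) else parental_origin
  structure(list(gene_symbol = gene_symbol, mode = mode,
                 variants = variants, dual_mode = dual_mode),
            class = "candidate_gene")
}

#' @export
print.candidate_gene <- function(x, ...) {
  cat(sprintf("<candidate_gene> %s  mode=%s%s  %d variant(s)\n",
              x$gene_symbol, x$mode, if (x$dual_mode) " (dual-mode)" else "",
              nrow(x$variants)))
  invisible(x)
}

# assign a gene symbol to unassigned records by transcript span overlap;
# returns records replicated per overlapping gene, with a `gene` column
assign_genes <- function(records, models) {
  if ("gene" %in% names(records)) return(records)
  by_chrom <- split(models, vapply(models, `[[`, "", "chrom"))
  recs <- as.data.frame(records)
  out <- list()
  for (i in seq_len(nrow(records))) {
    row <- recs[i, , drop = FALSE]
    for (m in by_chrom[[row$chrom]] %||% list()) {
      span <- model_span(m)
      if (identical(row$chrom, m$chrom) && row$pos >= span[1] &&
          row$pos <= span[2]) {
        row2 <- row; row2$gene <- m$gene_symbol
        out[[length(out) + 1L]] <- row2
      }
    }
  }
  if (length(out) == 0) {
    df <- as.data.frame(records)[0, , drop = FALSE]
    df$gene <- character()
    return(df)
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  class(df) <- c("variant_table", "data.frame")
  df
}

#' Scan for recessive candidate genes in a quad pedigree
#'
#' Groups (already consequence- and database-filtered) records by gene and
#' emits candidates: genes with any shared-homozygous variant
#' ([homozygous_qualifies()]) and genes passing the in-trans compound-het
#' test ([compound_het_qualifies()]). A gene qualifying under both modes is
#' reported once with mode `homozygous` and `dual_mode = TRUE`. Records not
#' assignable to any gene are skipped with a message.
#'
#' @param records a [variant_table()]; if it lacks a `gene` column, genes
#'   are assigned by transcript-span overlap against `models`.
#' @param ped a [pedigree()].
#' @param models named list of [gene_model()]s (used only for gene
#'   assignment).
#' @return list of [candidate_gene()]s, sorted by the (chrom, pos) of each
#'   candidate's first variant.
#' @export
recessive_scan <- function(records, ped, models = NULL) {
  if (!"gene" %in% names(records)) {
    if (is.null(models)) stop("records lack a gene column: supply models")
    records <- assign_genes(records, models)
  }
  n_orphan <- sum(is.na(records$gene))
  if (n_orphan > 0) {
    message(n_orphan, " record(s) outside every gene model skipped")
  }
  records <- records[!is.na(records$gene), , drop = FALSE]
  out <- list()
  for (g in unique(records$gene)) {
    rg <- records[records$gene == g, , drop = FALSE]
    class(rg) <- c("variant_table", "data.frame")
    hom_ok <- vapply(seq_len(nrow(rg)), function(i) {
      homozygous_qualifies(rg[i, , drop = FALSE], ped)
    }, logical(1))
    comp <- compound_het_qualifies(rg, ped)
    if (any(hom_ok)) {
      out[[length(out) + 1L]] <-
        candidate_gene(g, "homozygous", rg[hom_ok, , drop = FALSE],
                       dual_mode = !is.null(comp))
    } else if (!is.null(comp)) {
      out[[length(out) + 1L]] <- comp
    }
  }
  if (length(out) > 1) {
    key <- vapply(out, function(cand) {
      sprintf("%s:%012d", cand$variants$chrom[1], cand$variants$pos[1])
    }, character(1))
    out <- out[order(key)]
  }
  out
}

#' Exhaustive reference implementation of the recessive scan
#'
#' A definitional re-implementation kept deliberately independent of
#' [recessive_scan()]: for every gene it enumerates all ordered variant
#' pairs for the trans compound-het rule and all single variants for the
#' shared-homozygous rule, working directly on genotype class strings.
#' Intended for small instances and property tests.
#'
#' @inheritParams recessive_scan
#' @return list of [candidate_gene()]s (same conventions as
#'   [recessive_scan()]).
#' @export
oracle_recessive <- function(records, ped, models = NULL) {
  if (!"gene" %in% names(records)) {
    if (is.null(models)) stop("records lack a gene column: supply models")
    records <- assign_genes(records, models)
  }
  records <- records[!is.na(records$gene), , drop = FALSE]
  kids <- ped$affected_children
  out <- list()
  for (g in unique(records$gene)) {
    rg <- as.data.frame(records[records$gene == g, , drop = FALSE])
    cls <- lapply(seq_len(nrow(rg)), function(i) {
      vapply(pedigree_members(ped), function(s) {
        gt_class(rg[[paste0("gt_", s)]][i])
      }, character(1))
    })
    is_hom <- vapply(cls, function(cl) {
      all(cl[kids] == "hom_alt") && cl[ped$father] == "het" &&
        cl[ped$mother] == "het"
    }, logical(1))
    # definitional per-variant facts for the compound-het rule
    het_all_kids <- vapply(cls, function(cl) all(cl[kids] == "het"), logical(1))
    complete <- vapply(cls, function(cl) !any(cl == "missing"), logical(1))
    no_homalt_parent <- vapply(cls, function(cl) {
      cl[ped$father] != "hom_alt" && cl[ped$mother] != "hom_alt"
    }, logical(1))
    maternal <- vapply(cls, function(cl) {
      cl[ped$mother] %in% c("het", "hom_alt") && cl[ped$father] == "hom_ref"
    }, logical(1))
    paternal <- vapply(cls, function(cl) {
      cl[ped$father] %in% c("het", "hom_alt") && cl[ped$mother] == "hom_ref"
    }, logical(1))
    both_carry <- vapply(cls, function(cl) {
      cl[ped$father] %in% c("het", "hom_alt") &&
        cl[ped$mother] %in% c("het", "hom_alt")
    }, logical(1))
    usable <- het_all_kids & complete & no_homalt_parent
    trans_pair <- FALSE
    for (i in which(usable & maternal)) {
      for (j in which(usable & paternal)) {
        if (i != j) trans_pair <- TRUE
      }
    }
    if (any(is_hom)) {
      comp_too <- trans_pair
      out[[length(out) + 1L]] <-
        candidate_gene(g, "homozygous", rg[is_hom, , drop = FALSE],
                       dual_mode = comp_too)
    } else if (trans_pair) {
      listed <- usable & (maternal | paternal | both_carry)
      origin <- ifelse(maternal[listed], "mother",
                       ifelse(paternal[listed], "father", "ambiguous"))
      out[[length(out) + 1L]] <-
        candidate_gene(g, "compound_het", rg[listed, , drop = FALSE], origin)
    }
  }
  if (length(out) > 1) {
    key <- vapply(out, function(cand) {
      sprintf("%s:%012d", cand$variants$chrom[1], cand$variants$pos[1])
    }, character(1))
    out <- out[order(key)]
  }
  out
}

#' Intersect candidates with a known disease-gene list
#'
#' @param candidates list of [candidate_gene()]s.
#' @param gene_list a [read_gene_list()] result (or character vector;
#'   matching is case-insensitive).
#' @return the candidates whose gene symbol is in the list, order preserved.
#' @export
intersect_known_genes <- function(candidates, gene_list) {
  keep <- vapply(candidates, function(cand) {
    toupper(cand$gene_symbol) %in% toupper(unclass(gene_list))
  }, logical(1))
  candidates[keep]
}
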