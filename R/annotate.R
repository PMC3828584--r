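# Coordinate arithmetic and consequence classification on transcript models.

FUNCTIONAL_CATEGORIES <- c("nonsynonymous", "stop_gain", "splice_region",
                           "frameshift_indel")

#' Map a CDS position to its codon
#'
#' @param cds_pos 1-based position within the coding sequence.
#' @return list with `codon_index` (1-based residue index) and
#'   `offset_in_codon` (1, 2, or 3).
#' @examples
#' cds_to_codon(8375)  # codon 2792, middle base
#' @export
cds_to_codon <- function(cds_pos) {
  if (any(cds_pos < 1)) stop("cds_pos must be >= 1")
  cds_pos <- as.integer(cds_pos)
  list(codon_index = (cds_pos - 1L) %/% 3L + 1L,
       offset_in_codon = (cds_pos - 1L) %% 3L + 1L)
}

#' Map a genomic position onto transcript coordinates
#'
#' Coding positions are mapped through the spliced CDS respecting strand.
#' Intronic positions return the 1-based intron index (introns counted in
#' transcript order) and a signed offset: positive measured from the donor
#' (5') side of the intron, negative from the acceptor (3') side, whichever
#' boundary is nearer (ties resolve to the donor side). Exonic positions
#' outside the CDS are `utr`; positions outside the transcript span are
#' `outside`.
#'
#' @param pos 1-based genomic position.
#' @param model a [gene_model()].
#' @return list with `kind` (`coding`, `intronic`, `utr`, `outside`) and,
#'   as applicable, `cds_pos` or `intron_index` + `offset`.
#' @export
genomic_to_cds <- function(pos, model) {
  span <- model_span(model)
  if (pos < span[1] || pos > span[2]) return(list(kind = "outside"))
  idx <- match(pos, model$cds_map)
  if (!is.na(idx)) return(list(kind = "coding", cds_pos = idx))
  ex <- model$exons
  if (any(pos >= ex$start & pos <= ex$end)) return(list(kind = "utr"))
  # transcript-order exons
  tx <- if (model$strand == "+") ex else ex[rev(seq_len(nrow(ex))), ]
  for (i in seq_len(nrow(tx) - 1)) {
    if (model$strand == "+") {
      lo <- tx$end[i] + 1L; hi <- tx$start[i + 1] - 1L
      if (pos >= lo && pos <= hi) {
        donor_d <- pos - tx$end[i]
        acc_d <- tx$start[i + 1] - pos
        off <- if (donor_d <= acc_d) donor_d else -acc_d
        return(list(kind = "intronic", intron_index = i, offset = off))
      }
    } else {
      lo <- tx$end[i + 1] + 1L; hi <- tx$start[i] - 1L
      if (pos >= lo && pos <= hi) {
        donor_d <- tx$start[i] - pos
        acc_d <- pos - tx$end[i + 1]
        off <- if (donor_d <= acc_d) donor_d else -acc_d
        return(list(kind = "intronic", intron_index = i, offset = off))
      }
    }
  }
  list(kind = "outside")
}

#' Genomic position of an intron-offset coordinate
#'
#' Inverse of the intronic branch of [genomic_to_cds()]: the genomic position
#' at signed `offset` inside transcript-order intron `intron_index`.
#'
#' @param model a [gene_model()].
#' @param intron_index 1-based intron number in transcript order.
#' @param offset signed offset (positive from the donor side, negative from
#'   the acceptor side; never 0).
#' @return 1-based genomic position.
#' @export
intron_offset_to_genomic <- function(model, intron_index, offset) {
  stopifnot(offset != 0)
  ex <- model$exons
  tx <- if (model$strand == "+") ex else ex[rev(seq_len(nrow(ex))), ]
  if (intron_index >= nrow(tx)) stop("no such intron: ", intron_index)
  if (model$strand == "+") {
    if (offset > 0) tx$end[intron_index] + offset
    else tx$start[intron_index + 1] + offset
  } else {
    if (offset > 0) tx$start[intron_index] - offset
    else tx$end[intron_index + 1] - offset
  }
}

#' Classify the consequence of a variant on a transcript
#'
#' Coding SNVs are translated with the standard genetic code (reference and
#' mutated codon compared); intronic SNVs within `splice_window` bases of an
#' exon boundary are `splice_region`; coding indels are `frameshift_indel`
#' when the allele-length difference is not a multiple of 3, else
#' `inframe_indel`; indels straddling an exon/intron junction are
#' `splice_region`. A stop-codon-creating SNV is `stop_gain`.
#' `protein_change` is populated for coding SNVs only.
#'
#' @param chrom,pos,ref,alt the variant (VCF conventions; indels share their
#'   first base).
#' @param model a [gene_model()].
#' @param splice_window intronic distance (bases, boundary-inclusive) that
#'   counts as splice region; default 10.
#' @return list with `category`, the transcript coordinate (`coord`), and
#'   for coding SNVs `protein_change` = list(ref_aa, residue_index, alt_aa).
#' @export
classify_consequence <- function(chrom, pos, ref, alt, model,
                                 splice_window = 10L) {
  if (!identical(chrom, model$chrom)) {
    return(list(category = "intergenic", coord = list(kind = "outside")))
  }
  is_snv <- nchar(ref) == 1 && nchar(alt) == 1
  if (is_snv) {
    coord <- genomic_to_cds(pos, model)
    cat <- switch(coord$kind,
      outside = "intergenic",
      utr = "utr",
      intronic = if (abs(coord$offset) <= splice_window) "splice_region"
                 else "intronic",
      coding = NA_character_)
    if (!is.na(cat) || coord$kind != "coding") {
      return(list(category = cat, coord = coord))
    }
    cc <- cds_to_codon(coord$cds_pos)
    codon <- substr(model$cds_seq, 3L * (cc$codon_index - 1L) + 1L,
                    3L * cc$codon_index)
    alt_t <- if (model$strand == "+") alt else comp_base(alt)
    mut <- codon
    substr(mut, cc$offset_in_codon, cc$offset_in_codon) <- alt_t
    ref_aa <- unname(Biostrings::GENETIC_CODE[codon])
    alt_aa <- unname(Biostrings::GENETIC_CODE[mut])
    cat <- if (ref_aa == alt_aa) "synonymous"
           else if (alt_aa == "*") "stop_gain"
           else "nonsynonymous"
    return(list(category = cat, coord = coord,
                protein_change = list(ref_aa = ref_aa,
                                      residue_index = cc$codon_index,
                                      alt_aa = alt_aa)))
  }
  # indel: examine every reference base it spans (plus the insertion anchor's
  # right neighbour so junction-straddling insertions are caught)
  span <- pos:(pos + max(nchar(ref), 2L) - 1L)
  kinds <- lapply(span, genomic_to_cds, model = model)
  kind_v <- vapply(kinds, `[[`, "", "kind")
  coord <- kinds[[1]]
  if (any(kind_v == "coding") && any(kind_v == "intronic")) {
    return(list(category = "splice_region", coord = coord))
  }
  if (any(kind_v == "coding")) {
    shift <- abs(nchar(ref) - nchar(alt)) %% 3L
    return(list(category = if (shift != 0) "frameshift_indel"
                           else "inframe_indel", coord = coord))
  }
  if (any(kind_v == "intronic")) {
    offs <- vapply(kinds[kind_v == "intronic"], `[[`, 0L, "offset")
    return(list(category = if (min(abs(offs)) <= splice_window)
                  "splice_region" else "intronic", coord = coord))
  }
  if (any(kind_v == "utr")) return(list(category = "utr", coord = coord))
  list(category = "intergenic", coord = coord)
}

#' Annotate a variant table against gene models
#'
#' Produces one output row per (record, overlapping gene) pair; records on
#' chromosomes absent from the models, or outside every transcript span, get
#' a single `intergenic` row with `gene = NA`. Adds transcript coordinates,
#' consequence category, protein change, and the rendered HGVS / IVS names.
#'
#' @param records a [variant_table()].
#' @param models named list of [gene_model()]s.
#' @param splice_window passed to [classify_consequence()].
#' @return the annotated variant table (columns `gene`, `category`,
#'   `cds_pos`, `intron_index`, `intron_offset`, `aa_ref`, `aa_pos`,
#'   `aa_alt`, `hgvs_c`, `hgvs_p`, `ivs` appended).
#' @export
annotate_variants <- function(records, models, splice_window = 10L) {
  ann_cols <- function(df, gene, category, coord = NULL, pc = NULL,
                       ref_t = NA, alt_t = NA) {
    df$gene <- gene
    df$category <- category
    df$cds_pos <- if (!is.null(coord) && coord$kind == "coding")
      coord$cds_pos else NA_integer_
    df$intron_index <- if (!is.null(coord) && coord$kind == "intronic")
      coord$intron_index else NA_integer_
    df$intron_offset <- if (!is.null(coord) && coord$kind == "intronic")
      coord$offset else NA_integer_
    df$aa_ref <- if (!is.null(pc)) pc$ref_aa else NA_character_
    df$aa_pos <- if (!is.null(pc)) pc$residue_index else NA_integer_
    df$aa_alt <- if (!is.null(pc)) pc$alt_aa else NA_character_
    df$hgvs_c <- if (!is.na(df$cds_pos))
      hgvs_c_name(coord, ref_t, alt_t) else NA_character_
    df$hgvs_p <- if (!is.null(pc))
      hgvs_p_name(pc$ref_aa, pc$residue_index, pc$alt_aa) else NA_character_
    df$ivs <- if (!is.na(df$intron_index))
      ivs_name(coord, ref_t, alt_t) else NA_character_
    df
  }
  by_chrom <- split(models, vapply(models, `[[`, "", "chrom"))
  recs <- as.data.frame(records)
  out <- list()
  for (i in seq_len(nrow(records))) {
    row <- recs[i, , drop = FALSE]
    hit <- FALSE
    for (m in by_chrom[[row$chrom]] %||% list()) {
      if (!identical(row$chrom, m$chrom)) next
      span <- model_span(m)
      if (row$pos > span[2] || row$pos + nchar(row$ref) - 1L < span[1]) next
      res <- classify_consequence(row$chrom, row$pos, row$ref, row$alt, m,
                                  splice_window)
      if (res$category == "intergenic") next
      hit <- TRUE
      is_snv <- nchar(row$ref) == 1 && nchar(row$alt) == 1
      ref_t <- if (is_snv && m$strand == "-") comp_base(row$ref) else row$ref
      alt_t <- if (is_snv && m$strand == "-") comp_base(row$alt) else row$alt
      out[[length(out) + 1L]] <-
        ann_cols(row, m$gene_symbol, res$category, res$coord,
                 res$protein_change, ref_t, alt_t)
    }
    if (!hit) {
      out[[length(out) + 1L]] <-
        ann_cols(row, NA_character_, "intergenic")
    }
  }
  if (length(out) == 0) {
    df <- as.data.frame(records)
    for (col in c("gene", "category", "aa_ref", "aa_alt", "hgvs_c",
                  "hgvs_p", "ivs")) df[[col]] <- character()
    for (col in c("cds_pos", "intron_index", "intron_offset", "aa_pos"))
      df[[col]] <- integer()
    class(df) <- c("variant_table", "data.frame")
    return(df)
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  class(df) <- c("variant_table", "data.frame")
  df
}

#' Keep putatively damaging variant classes
#'
#' Retains annotated records whose category is `nonsynonymous`, `stop_gain`,
#' `splice_region`, or `frameshift_indel`; everything else (synonymous,
#' deeper intronic, UTR, in-frame indels, intergenic) is dropped. Input
#' order is preserved; output is always a subset of the input.
#'
#' @param records a variant table; annotated with [annotate_variants()]
#'   first if the `category` column is absent.
#' @param models,splice_window used only if annotation is needed.
#' @return the retained subset.
#' @export
functional_filter <- function(records, models = NULL, splice_window = 10L) {
  if (!"category" %in% names(records)) {
    if (is.null(models)) stop("unannotated records: supply gene models")
    records <- annotate_variants(records, models, splice_window)
  }
  out <- records[records$category %in% FUNCTIONAL_CATEGORIES, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("variant_table", "data.frame")
  out
}
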