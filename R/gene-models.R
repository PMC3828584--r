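# Transcript models: ordered genomic exons plus the spliced, strand-corrected
# CDS sequence. One canonical transcript per gene.

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

comp_base <- function(b) unname(DNA_COMPLEMENT[b])

#' Construct a transcript gene model
#'
#' @param gene_symbol,transcript_id labels.
#' @param chrom chromosome label.
#' @param strand `"+"` or `"-"`.
#' @param exons `data.frame` with 1-based inclusive genomic `start`, `end`
#'   columns; non-overlapping, sorted by genomic start.
#' @param cds_start,cds_end genomic bounds of the coding sequence.
#' @param cds_seq spliced coding nucleotide string, transcript strand,
#'   length divisible by 3, no internal stop codon.
#' @param chrom_len optional chromosome length (used by the simulator).
#' @return an object of class `gene_model`. The model carries `cds_map`, the
#'   genomic position of every CDS base in transcript (5'->3') order.
#' @export
gene_model <- function(gene_symbol, transcript_id, chrom, strand, exons,
                       cds_start, cds_end, cds_seq, chrom_len = NA_integer_) {
  stopifnot(strand %in% c("+", "-"), nrow(exons) >= 1)
  exons <- exons[order(exons$start), c("start", "end"), drop = FALSE]
  rownames(exons) <- NULL
  if (any(exons$start > exons$end)) stop("exon with start > end")
  if (nrow(exons) > 1 && any(exons$start[-1] <= exons$end[-nrow(exons)])) {
    stop("overlapping exons")
  }
  cds_seq <- toupper(cds_seq)
  if (nchar(cds_seq) %% 3 != 0) stop("CDS length not divisible by 3")
  aa <- translate_cds(cds_seq)
  if (any(aa[-length(aa)] == "*")) stop("internal stop codon in CDS")

  m <- structure(list(
    gene_symbol = gene_symbol, transcript_id = transcript_id,
    chrom = chrom, strand = strand, exons = exons,
    cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
    cds_seq = cds_seq, chrom_len = as.integer(chrom_len)),
    class = "gene_model")
  m$cds_map <- cds_genomic_map(m)
  if (length(m$cds_map) != nchar(cds_seq)) {
    stop("CDS sequence length (", nchar(cds_seq),
         ") does not match coding exon span (", length(m$cds_map), ")")
  }
  m
}

# genomic positions of CDS bases in transcript order
cds_genomic_map <- function(m) {
  ex <- m$exons
  coding <- lapply(seq_len(nrow(ex)), function(i) {
    s <- max(ex$start[i], m$cds_start)
    e <- min(ex$end[i], m$cds_end)
    if (s > e) integer() else s:e
  })
  if (m$strand == "+") {
    unlist(coding)
  } else {
    unlist(lapply(rev(coding), rev))
  }
}

# genomic span of the transcript
model_span <- function(m) c(min(m$exons$start), max(m$exons$end))

translate_cds <- function(cds_seq) {
  n <- nchar(cds_seq)
  codons <- substring(cds_seq, seq(1, n, 3), seq(3, n, 3))
  unname(Biostrings::GENETIC_CODE[codons])
}

#' Translated protein of a gene model (terminal stop stripped)
#' @param model a [gene_model()].
#' @return character string of single-letter residues.
#' @export
model_protein <- function(model) {
  aa <- translate_cds(model$cds_seq)
  if (aa[length(aa)] == "*") aa <- aa[-length(aa)]
  paste(aa, collapse = "")
}

#' Assemble a toy gene and its chromosome sequence
#'
#' Lays out `flank + exon1 + intron1 + ... + exonN + flank` in transcript
#' orientation, then mirrors the whole chromosome for minus-strand genes.
#' Exons are fully coding (no UTR); generated introns carry canonical
#' GT..AG ends. Random draws (flanks, intron interiors) come from the
#' current RNG stream.
#'
#' @param gene_symbol gene label; transcript id defaults to `<gene>.t1`.
#' @param cds_seq coding sequence (start codon through stop codon).
#' @param exon_lengths integer vector summing to `nchar(cds_seq)`.
#' @param intron_lengths integer vector, length `length(exon_lengths) - 1`,
#'   all >= 4.
#' @param strand `"+"` or `"-"`.
#' @param flank untranscribed bases added on each side.
#' @param chrom chromosome label (defaults to `chr_<gene>`).
#' @return list with `model` (a [gene_model()]) and `chrom_seq`.
#' @export
build_toy_gene <- function(gene_symbol, cds_seq, exon_lengths,
                           intron_lengths = integer(), strand = "+",
                           flank = 50L, chrom = paste0("chr_", gene_symbol)) {
  stopifnot(sum(exon_lengths) == nchar(cds_seq),
            length(intron_lengths) == length(exon_lengths) - 1)
  if (length(intron_lengths) > 0 && any(intron_lengths < 4)) {
    stop("introns must be at least 4 bases (GT..AG)")
  }
  rand_dna <- function(n) {
    if (n <= 0) "" else paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")
  }
  exon_seqs <- substring(cds_seq,
                         cumsum(c(1, head(exon_lengths, -1))),
                         cumsum(exon_lengths))
  intron_seqs <- vapply(intron_lengths, function(L) {
    paste0("GT", rand_dna(L - 4L), "AG")
  }, character(1))
  pieces <- character(0)
  for (i in seq_along(exon_seqs)) {
    pieces <- c(pieces, exon_seqs[i],
                if (i < length(exon_seqs)) intron_seqs[i])
  }
  layout <- paste0(rand_dna(flank), paste(pieces, collapse = ""),
                   rand_dna(flank))
  L <- nchar(layout)

  # transcript-orientation exon coordinates
  starts <- integer(length(exon_lengths)); ends <- integer(length(exon_lengths))
  at <- flank + 1L
  for (i in seq_along(exon_lengths)) {
    starts[i] <- at
    ends[i] <- at + exon_lengths[i] - 1L
    at <- ends[i] + 1L + if (i < length(exon_lengths)) intron_lengths[i] else 0L
  }
  if (strand == "-") {
    chrom_seq <- revcomp(layout)
    new_starts <- L - ends + 1L
    new_ends <- L - starts + 1L
    starts <- sort(new_starts); ends <- sort(new_ends)
  } else {
    chrom_seq <- layout
  }
  exons <- data.frame(start = starts, end = ends)
  model <- gene_model(gene_symbol, paste0(gene_symbol, ".t1"), chrom, strand,
                      exons, min(starts), max(ends), cds_seq, chrom_len = L)
  list(model = model, chrom_seq = chrom_seq)
}

#' Write gene models as BED12 plus a per-transcript CDS FASTA
#'
#' BED12 blocks are the exons; thickStart/thickEnd delimit the CDS. The name
#' column encodes `gene:transcript`.
#'
#' @param models list of [gene_model()]s.
#' @param bed_path,cds_fasta_path output files.
#' @return invisibly, the two paths.
#' @export
write_gene_models <- function(models, bed_path, cds_fasta_path) {
  lines <- vapply(models, function(m) {
    span <- model_span(m)
    sizes <- m$exons$end - m$exons$start + 1L
    rel <- m$exons$start - span[1]
    paste(m$chrom, span[1] - 1L, span[2],
          paste0(m$gene_symbol, ":", m$transcript_id), 0L, m$strand,
          m$cds_start - 1L, m$cds_end, "0", nrow(m$exons),
          paste0(paste(sizes, collapse = ","), ","),
          paste0(paste(rel, collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, bed_path)
  cds <- Biostrings::DNAStringSet(
    setNames(vapply(models, `[[`, "", "cds_seq"),
             vapply(models, function(m) paste0(m$gene_symbol, ":",
                                               m$transcript_id), "")))
  Biostrings::writeXStringSet(cds, cds_fasta_path, width = 70L)
  invisible(c(bed_path, cds_fasta_path))
}

#' Read gene models from BED12 plus a CDS FASTA
#'
#' @param bed_path BED12 file whose name column is `gene:transcript`.
#' @param cds_fasta_path FASTA of spliced CDS sequences keyed the same way.
#' @return named list of [gene_model()]s keyed by gene symbol.
#' @export
read_gene_models <- function(bed_path, cds_fasta_path) {
  gr <- rtracklayer::import(bed_path, format = "bed")
  cds <- Biostrings::readDNAStringSet(cds_fasta_path)
  cds_by_name <- setNames(as.character(cds), sub("\\s.*$", "", names(cds)))
  models <- lapply(seq_along(gr), function(i) {
    g <- gr[i]
    nm <- strsplit(g$name, ":", fixed = TRUE)[[1]]
    blocks <- g$blocks[[1]]
    exons <- data.frame(
      start = GenomicRanges::start(g) + IRanges::start(blocks) - 1L,
      end = GenomicRanges::start(g) + IRanges::end(blocks) - 1L)
    thick <- g$thick
    if (!g$name %in% names(cds_by_name)) {
      stop("CDS sequence missing for ", g$name)
    }
    gene_model(nm[1], paste(nm[-1], collapse = ":"),
               as.character(GenomicRanges::seqnames(g)),
               as.character(BiocGenerics::strand(g)),
               exons, IRanges::start(thick), IRanges::end(thick),
               cds_by_name[[g$name]])
  })
  setNames(models, vapply(models, `[[`, "", "gene_symbol"))
}

#' Write a toy genome as FASTA
#' @param genome named character vector of chromosome sequences.
#' @param path output FASTA.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path,
                              width = 70L)
  invisible(path)
}
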