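# Site databases, gene lists, aligned FASTA, domain tables.

#' Read a known-variant site database
#'
#' Accepts a 4-column TSV (`chrom pos ref alt`, optional header) or a
#' sites-only VCF (`.vcf` extension). Duplicate rows are deduplicated;
#' membership queries are exact on all four key components.
#'
#' @param path site list file.
#' @param name database label (defaults to the file name).
#' @return an object of class `site_set` with elements `name` and `keys`
#'   (character vector of `chrom:pos:ref:alt` keys).
#' @export
read_sites_db <- function(path, name = basename(path)) {
  if (grepl("\\.vcf$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    if (length(lines) == 0) return(site_set(character(), name))
    f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
    df <- data.frame(chrom = f[, 1], pos = as.integer(f[, 2]),
                     ref = f[, 4], alt = f[, 5], stringsAsFactors = FALSE)
  } else {
    first <- readLines(path, n = 1)
    has_header <- length(first) == 1 &&
      is.na(suppressWarnings(as.integer(strsplit(first, "\t")[[1]][2])))
    df <- tryCatch(
      read.table(path, header = has_header, sep = "\t",
                 stringsAsFactors = FALSE,
                 col.names = c("chrom", "pos", "ref", "alt")),
      error = function(e) data.frame(chrom = character(), pos = integer(),
                                     ref = character(), alt = character()))
  }
  # split multi-allelic alts so membership stays per-allele
  multi <- grepl(",", df$alt, fixed = TRUE)
  if (any(multi)) {
    ext <- df[rep(which(multi), lengths(strsplit(df$alt[multi], ","))), ]
    ext$alt <- unlist(strsplit(df$alt[multi], ","))
    df <- rbind(df[!multi, ], ext)
  }
  site_set(unique(paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")), name)
}

#' Construct a site set from key strings
#' @param keys character vector of `chrom:pos:ref:alt` keys.
#' @param name database label.
#' @return a `site_set`.
#' @export
site_set <- function(keys, name = "sites") {
  structure(list(name = name, keys = unique(as.character(keys))),
            class = "site_set")
}

#' Write a site set as a 4-column TSV
#' @param db a [site_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sites_db <- function(db, path) {
  parts <- strsplit(db$keys, ":", fixed = TRUE)
  df <- data.frame(chrom = vapply(parts, `[`, "", 1),
                   pos = vapply(parts, `[`, "", 2),
                   ref = vapply(parts, `[`, "", 3),
                   alt = vapply(parts, `[`, "", 4))
  df <- df[order(df$chrom, as.integer(df$pos), df$ref, df$alt), ]
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene list (one symbol per line)
#'
#' Symbols are case-normalized to upper case; blank lines and duplicates are
#' dropped. An empty list is fatal.
#'
#' @param path plain-text file.
#' @return character vector of class `gene_list`.
#' @export
read_gene_list <- function(path) {
  g <- toupper(trimws(readLines(path)))
  g <- unique(g[nzchar(g)])
  if (length(g) == 0) stop("gene list is empty: ", path)
  structure(g, class = "gene_list")
}

#' Read an aligned protein FASTA as an MSA
#'
#' All sequences must have equal aligned length (ragged input is fatal).
#' The first sequence is flagged as the reference unless `reference` names
#' another record.
#'
#' @param path aligned FASTA.
#' @param reference id of the reference sequence.
#' @return an object of class `msa`: list with `sequences` (named character
#'   vector of aligned residue strings) and `reference`.
#' @export
read_msa <- function(path, reference = NULL) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(unique(Biostrings::width(aa))) > 1) {
    stop("ragged alignment: sequences differ in aligned length")
  }
  seqs <- setNames(as.character(aa), sub("\\s.*$", "", names(aa)))
  msa(seqs, reference %||% names(seqs)[1])
}

#' Construct an MSA object
#' @param sequences named character vector of equal-length aligned strings.
#' @param reference name of the reference sequence.
#' @return an `msa`.
#' @export
msa <- function(sequences, reference = names(sequences)[1]) {
  stopifnot(length(sequences) >= 1, !is.null(names(sequences)))
  if (length(unique(nchar(sequences))) > 1) {
    stop("ragged alignment: sequences differ in aligned length")
  }
  if (!reference %in% names(sequences)) stop("reference absent from MSA")
  structure(list(sequences = sequences, reference = reference),
            class = "msa")
}

#' Write an MSA as aligned FASTA
#' @param x an [msa()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_msa <- function(x, path) {
  aa <- Biostrings::AAStringSet(x$sequences)
  Biostrings::writeXStringSet(aa, path, width = 70L)
  invisible(path)
}

#' Read a protein domain table
#'
#' A TSV with header columns `domain`, `start`, `end` (1-based inclusive
#' residue bounds), or a YAML list of `{name, start, end}` entries.
#' Intervals may abut or overlap; order is preserved as given.
#'
#' @param path TSV or YAML (`.yml`/`.yaml`) file.
#' @return `data.frame` with columns `domain`, `start`, `end`.
#' @export
read_domain_table <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    entries <- yaml::read_yaml(path)
    df <- data.frame(domain = vapply(entries, function(e) as.character(e$name), ""),
                     start = vapply(entries, function(e) as.integer(e$start), 1L),
                     end = vapply(entries, function(e) as.integer(e$end), 1L))
  } else {
    df <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    names(df) <- tolower(names(df))
    df <- df[, c("domain", "start", "end")]
  }
  stopifnot(all(df$start <= df$end), all(df$start >= 1))
  df
}

#' The myosin XVa protein domain table
#'
#' Residue bounds of the canonical human myosin XVa domains: the N-terminal
#' extension, motor domain, light-chain binding motifs, two MyTH4 domains,
#' two FERM domains, and the putative SH3 domain. Bounds are 1-based
#' inclusive; the SH3 interval overlaps the end of the first FERM domain as
#' published.
#'
#' @return `data.frame` with columns `domain`, `start`, `end`.
#' @export
myo15a_domains <- function() {
  read_domain_table(system.file("extdata", "myo15a_domains.tsv",
                                package = "quadrec", mustWork = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
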