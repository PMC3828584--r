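# Variant tables: one row per biallelic site, genotype columns gt_<sample>
# coded as alt-allele dosage (0 hom_ref, 1 het, 2 hom_alt, NA missing).

#' Construct a variant table
#'
#' The package-wide container for variant calls: a `data.frame` with columns
#' `chrom`, `pos` (1-based position of the first reference base), `ref`,
#' `alt`, and one `gt_<sample>` column per pedigree member holding the
#' alt-allele dosage (0, 1, 2, or `NA` for missing). Every record is
#' biallelic; multi-allelic VCF rows are split on read.
#'
#' @param chrom character vector of chromosome labels.
#' @param pos integer vector of 1-based positions.
#' @param ref,alt character vectors of reference / single alternate alleles.
#' @param genotypes named list or data.frame of dosage vectors, one entry per
#'   sample (names become `gt_<sample>` columns).
#' @return a `data.frame` of class `variant_table`, sorted by `(chrom, pos)`.
#' @export
variant_table <- function(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          genotypes = list()) {
  n <- length(chrom)
  stopifnot(length(pos) == n, length(ref) == n, length(alt) == n)
  if (n > 0) {
    stopifnot(all(pos >= 1), all(nzchar(ref)), all(nzchar(alt)),
              all(ref != alt))
  }
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   ref = as.character(ref), alt = as.character(alt),
                   stringsAsFactors = FALSE)
  for (s in names(genotypes)) {
    g <- as.integer(genotypes[[s]])
    stopifnot(length(g) == n, all(is.na(g) | (g >= 0L & g <= 2L)))
    df[[paste0("gt_", s)]] <- g
  }
  df <- df[order(df$chrom, df$pos, df$ref, df$alt), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("variant_table", "data.frame")
  df
}

#' Sample ids carried by a variant table
#' @param records a variant table.
#' @return character vector of sample ids (the `gt_` columns, unprefixed).
#' @export
vt_samples <- function(records) {
  cols <- grep("^gt_", names(records), value = TRUE)
  sub("^gt_", "", cols)
}

#' Genotype dosage matrix of a variant table
#'
#' @param records a variant table.
#' @param samples sample ids to extract (default: all).
#' @return integer matrix, rows = records, columns = samples.
#' @export
gt_matrix <- function(records, samples = vt_samples(records)) {
  cols <- paste0("gt_", samples)
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols) > 0) {
    stop("samples absent from variant table: ",
         paste(sub("^gt_", "", missing_cols), collapse = ", "))
  }
  m <- as.matrix(as.data.frame(records)[, cols, drop = FALSE])
  colnames(m) <- samples
  storage.mode(m) <- "integer"
  m
}

#' Classify a genotype dosage
#' @param g integer dosage vector (0/1/2/NA).
#' @return character vector in `hom_ref`, `het`, `hom_alt`, `missing`.
#' @export
gt_class <- function(g) {
  out <- rep("missing", length(g))
  out[!is.na(g) & g == 0L] <- "hom_ref"
  out[!is.na(g) & g == 1L] <- "het"
  out[!is.na(g) & g == 2L] <- "hom_alt"
  out
}

#' `chrom:pos:ref:alt` key strings of a variant table
#'
#' The exact-match key used by site databases and joins.
#' @param records a [variant_table()].
#' @return character vector, one key per record.
#' @export
variant_key <- function(records) {
  paste(records$chrom, records$pos, records$ref, records$alt, sep = ":")
}

# rbind variant tables, preserving class and sort order
bind_variants <- function(...) {
  parts <- Filter(function(x) !is.null(x) && nrow(x) > 0, list(...))
  if (length(parts) == 0) return(variant_table())
  df <- do.call(rbind, lapply(parts, as.data.frame))
  df <- df[order(df$chrom, df$pos, df$ref, df$alt), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("variant_table", "data.frame")
  df
}
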