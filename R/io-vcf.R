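# VCF reading/writing. Only CHROM/POS/REF/ALT/GT are retained by the domain
# model; everything else is dropped on read and written back as missing.

#' Read a multi-sample VCF into a variant table
#'
#' Multi-allelic rows are split into one biallelic record per alternate
#' allele, with each sample's dosage recoded against that allele (the count
#' of that allele in the genotype). Phase separators are accepted and
#' ignored; genotypes are treated as unphased throughout. Unparseable
#' genotype fields become missing with a warning.
#'
#' @param path VCF file (4.x, plain text).
#' @param pedigree a [pedigree()]; all members must be declared in the VCF
#'   header (fatal otherwise).
#' @return a [variant_table()] with one `gt_` column per pedigree member,
#'   sorted by `(chrom, pos)`.
#' @export
read_vcf <- function(path, pedigree) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#CHROM\t", lines, value = TRUE)
  if (length(hdr) != 1) stop("malformed VCF: expected one #CHROM header line")
  fields <- strsplit(hdr, "\t", fixed = TRUE)[[1]]
  vcf_samples <- fields[-(1:9)]
  members <- pedigree_members(pedigree)
  absent <- setdiff(members, vcf_samples)
  if (length(absent) > 0) {
    stop("pedigree sample(s) missing from VCF header: ",
         paste(absent, collapse = ", "))
  }
  n_body <- sum(!startsWith(lines, "#"))
  if (n_body == 0) {
    return(variant_table(genotypes = setNames(
      rep(list(integer()), length(members)), members)))
  }

  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix))
  gt_raw <- vcfR::extract.gt(v, element = "GT", convertNA = FALSE)
  if (is.null(dim(gt_raw))) {
    gt_raw <- matrix(gt_raw, nrow = 1,
                     dimnames = list(NULL, names(gt_raw) %||% vcf_samples))
  }

  chrom <- character(); pos <- integer(); ref <- character(); alt <- character()
  gts <- setNames(rep(list(integer()), length(members)), members)
  n_bad <- 0L
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    # parse each member's allele pair once per row
    alleles <- lapply(members, function(s) {
      if (is.na(gt_raw[i, s])) return(NULL)      # missing
      g <- gsub("|", "/", gt_raw[i, s], fixed = TRUE)
      a <- strsplit(g, "/", fixed = TRUE)[[1]]
      if (length(a) != 2 || any(!grepl("^(\\.|[0-9]+)$", a))) {
        if (!identical(g, ".") && !identical(g, "./.")) n_bad <<- n_bad + 1L
        return(NULL)                       # missing
      }
      if (any(a == ".")) return(NULL)
      a_num <- as.integer(a)
      if (any(a_num > length(alts))) { n_bad <<- n_bad + 1L; return(NULL) }
      a_num
    })
    names(alleles) <- members
    for (k in seq_along(alts)) {
      chrom <- c(chrom, fix[i, "CHROM"])
      pos <- c(pos, as.integer(fix[i, "POS"]))
      ref <- c(ref, fix[i, "REF"])
      alt <- c(alt, alts[k])
      for (s in members) {
        d <- if (is.null(alleles[[s]])) NA_integer_ else sum(alleles[[s]] == k)
        gts[[s]] <- c(gts[[s]], d)
      }
    }
  }
  if (n_bad > 0) warning(n_bad, " unparseable genotype field(s) set to missing")
  variant_table(chrom, pos, ref, alt, gts)
}

#' Write a variant table as VCF 4.2
#'
#' Emits a GT-only multi-sample VCF with the pedigree members as sample
#' columns (father, mother, then affected children). Dosages are rendered as
#' unphased genotypes (`0/0`, `0/1`, `1/1`, `./.`).
#'
#' @param records a [variant_table()].
#' @param pedigree a [pedigree()] supplying the sample column order.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(records, pedigree, path) {
  members <- pedigree_members(pedigree)
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", members), collapse = "\t"))
  body <- character(0)
  if (nrow(records) > 0) {
    gm <- gt_matrix(records, members)
    gt_str <- matrix(c("0/0", "0/1", "1/1")[gm + 1L], nrow = nrow(gm))
    gt_str[is.na(gm)] <- "./."
    body <- vapply(seq_len(nrow(records)), function(i) {
      paste(c(records$chrom[i], records$pos[i], ".", records$ref[i],
              records$alt[i], ".", ".", ".", "GT", gt_str[i, ]),
            collapse = "\t")
    }, character(1))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}
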