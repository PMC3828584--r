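# Known-site exclusion against reference databases (dbSNP-like usage:
# presence/absence only, no allele-frequency thresholds).

#' Exclude variants present in any reference site database
#'
#' A record is removed iff its exact `(chrom, pos, ref, alt)` key appears in
#' at least one of the databases. Matching is allele-level: a novel allele
#' at a catalogued position survives. Order is preserved; the output is
#' always a subset of the input, and adding databases can only shrink it.
#'
#' @param records a [variant_table()].
#' @param dbs list of [site_set()]s (an empty list excludes nothing).
#' @return the surviving subset.
#' @export
exclude_known <- function(records, dbs) {
  if (length(dbs) == 0 || nrow(records) == 0) return(records)
  known <- unique(unlist(lapply(dbs, `[[`, "keys")))
  out <- records[!variant_key(records) %in% known, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("variant_table", "data.frame")
  out
}
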