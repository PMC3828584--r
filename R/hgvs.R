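# Variant nomenclature: HGVS coding/protein names and legacy IVS intron names.

#' HGVS coding-DNA name of a substitution
#'
#' Renders `c.<pos><ref>><alt>` for a coding coordinate. `ref`/`alt` are
#' transcript-strand bases. Passing an intronic coordinate is an error; use
#' [ivs_name()] for those.
#'
#' @param coord a coordinate as returned by [genomic_to_cds()] (kind
#'   `coding`), or a bare 1-based CDS position.
#' @param ref,alt transcript-strand alleles.
#' @return e.g. `"c.8375T>C"`.
#' @export
hgvs_c_name <- function(coord, ref, alt) {
  if (is.list(coord)) {
    if (!identical(coord$kind, "coding")) {
      stop("hgvs_c_name requires a coding coordinate; got ", coord$kind)
    }
    coord <- coord$cds_pos
  }
  sprintf("c.%d%s>%s", as.integer(coord), ref, alt)
}

#' HGVS protein name of a substitution
#'
#' @param ref_aa,alt_aa single-letter residues.
#' @param residue_index 1-based residue position.
#' @return e.g. `"p.V2792A"`.
#' @export
hgvs_p_name <- function(ref_aa, residue_index, alt_aa) {
  sprintf("p.%s%d%s", ref_aa, as.integer(residue_index), alt_aa)
}

#' Legacy IVS name of an intronic substitution
#'
#' Renders `IVS<intron><+/-offset><ref>><alt>`, the intervening-sequence
#' notation: intron number in transcript order, signed offset from the
#' nearer splice boundary (positive = donor side).
#'
#' @param coord an intronic coordinate from [genomic_to_cds()], or a list
#'   with `intron_index` and `offset`.
#' @param ref,alt transcript-strand alleles.
#' @return e.g. `"IVS25+3G>A"`.
#' @export
ivs_name <- function(coord, ref, alt) {
  if (!is.list(coord) || is.null(coord$intron_index) || is.null(coord$offset)) {
    stop("ivs_name requires an intronic coordinate")
  }
  sprintf("IVS%d%+d%s>%s", as.integer(coord$intron_index),
          as.integer(coord$offset), ref, alt)
}
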