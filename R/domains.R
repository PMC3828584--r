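# Residue -> protein-domain mapping over closed residue intervals.

#' Map a protein residue to its domain(s)
#'
#' Returns every domain-table entry whose closed interval `[start, end]`
#' contains the residue, in table order; overlapping entries (e.g. the SH3
#' interval overlapping the end of the first FERM domain of myosin XVa)
#' yield multiple hits, and residues in inter-domain linkers yield none.
#'
#' @param residue 1-based residue index.
#' @param table domain table (`data.frame` with `domain`, `start`, `end`),
#'   e.g. [myo15a_domains()].
#' @return the matching rows of `table` (possibly zero rows).
#' @export
map_residue_to_domain <- function(residue, table = myo15a_domains()) {
  stopifnot(residue >= 1)
  hits <- table[table$start <= residue & residue <= table$end, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}
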