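# Alignment-column conservation of a reference residue.

#' Alignment column of an ungapped reference position
#'
#' @param x an [msa()].
#' @param residue_index 1-based position in the ungapped reference sequence.
#' @return the 1-based alignment column whose reference character is the
#'   `residue_index`-th non-gap character; out-of-range is an error.
#' @export
reference_column <- function(x, residue_index) {
  ref <- strsplit(x$sequences[[x$reference]], "")[[1]]
  non_gap <- which(ref != "-")
  if (residue_index < 1 || residue_index > length(non_gap)) {
    stop("residue_index ", residue_index, " outside the reference (",
         length(non_gap), " residues)")
  }
  non_gap[residue_index]
}

#' Conservation of a reference residue across an alignment
#'
#' Maps the reference residue to its alignment column, collects each
#' species' character there, and reports the identity fraction (proportion
#' of non-gap residues equal to the reference residue) and whether the
#' residue is invariant across a declared mammal subset (a gap counts as
#' not conserved).
#'
#' @param x an [msa()].
#' @param residue_index 1-based ungapped reference position.
#' @param mammal_ids species ids forming the mammal subset; all must be in
#'   the alignment. Defaults to the conventional seven-mammal panel used
#'   alongside chicken and zebrafish outgroups.
#' @return list with `residue_index`, `column`, `column_residues` (named
#'   character vector), `identity_fraction`, `mammal_conserved`.
#' @export
conservation_at <- function(x, residue_index,
                            mammal_ids = c("human", "chimpanzee", "macaque",
                                           "cow", "dog", "mouse", "rat")) {
  absent <- setdiff(mammal_ids, names(x$sequences))
  if (length(absent) > 0) {
    stop("species absent from MSA: ", paste(absent, collapse = ", "))
  }
  col <- reference_column(x, residue_index)
  residues <- vapply(x$sequences, substr, "", col, col)
  ref_res <- residues[[x$reference]]
  non_gap <- residues[residues != "-"]
  list(residue_index = as.integer(residue_index),
       column = col,
       column_residues = residues,
       identity_fraction = mean(non_gap == ref_res),
       mammal_conserved = all(residues[mammal_ids] == ref_res))
}
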