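# Pedigree handling: a single nuclear family, recessive design — two
# unaffected parents and >= 1 affected child.

#' Construct a pedigree
#'
#' @param father,mother sample ids of the unaffected parents.
#' @param affected_children character vector (length >= 1) of affected
#'   offspring sample ids.
#' @param family_id family label.
#' @return an object of class `pedigree`.
#' @export
pedigree <- function(father, mother, affected_children, family_id = "FAM1") {
  ids <- c(father, mother, affected_children)
  stopifnot(length(father) == 1, length(mother) == 1,
            length(affected_children) >= 1)
  if (anyDuplicated(ids)) stop("pedigree sample ids must be distinct")
  structure(list(family_id = family_id, father = father, mother = mother,
                 affected_children = affected_children),
            class = "pedigree")
}

#' All member ids of a pedigree (father, mother, affected children)
#' @param ped a [pedigree()].
#' @return character vector of sample ids.
#' @export
pedigree_members <- function(ped) {
  c(ped$father, ped$mother, ped$affected_children)
}

#' @export
print.pedigree <- function(x, ...) {
  cat("Quad-style pedigree", x$family_id, "\n",
      " father:", x$father, " mother:", x$mother, "\n",
      " affected children:", paste(x$affected_children, collapse = ", "), "\n")
  invisible(x)
}

#' Read a 6-column PED file
#'
#' Expects one nuclear family matching the recessive study design: two
#' unaffected parents (phenotype 1) and one or more affected children
#' (phenotype 2) whose father/mother columns name both parents. More than
#' one family, an affected parent, or a child missing a parent is fatal.
#'
#' @param path tab- or whitespace-separated PED file with columns
#'   family, individual, father, mother, sex, phenotype.
#' @return a [pedigree()].
#' @export
read_ped <- function(path) {
  ped <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("fam", "id", "father", "mother",
                                  "sex", "pheno"))
  if (length(unique(ped$fam)) != 1) stop("PED must contain exactly one family")
  founders <- ped[ped$father == "0" & ped$mother == "0", ]
  children <- ped[!(ped$father == "0" & ped$mother == "0"), ]
  if (nrow(children) < 1) stop("PED contains no offspring")
  if (any(children$father == "0" | children$mother == "0")) {
    stop("every child must have both parents in the PED")
  }
  if (length(unique(children$father)) != 1 ||
      length(unique(children$mother)) != 1) {
    stop("all children must share the same two parents")
  }
  father <- unique(children$father)
  mother <- unique(children$mother)
  if (!all(c(father, mother) %in% founders$id)) {
    stop("parent id(s) named by children absent from the PED founders")
  }
  parent_rows <- ped[ped$id %in% c(father, mother), ]
  if (any(parent_rows$pheno == 2)) stop("affected parent violates the recessive quad design")
  if (any(children$pheno != 2)) stop("all offspring must be affected (phenotype 2)")
  pedigree(father = father, mother = mother,
           affected_children = children$id, family_id = unique(ped$fam))
}

#' Write a pedigree as a 6-column PED file
#'
#' @param ped a [pedigree()].
#' @param path output file.
#' @param child_sex integer vector of sex codes for the children (recycled).
#' @return `path`, invisibly.
#' @export
write_ped <- function(ped, path, child_sex = 1L) {
  kids <- ped$affected_children
  rows <- rbind(
    c(ped$family_id, ped$father, "0", "0", 1L, 1L),
    c(ped$family_id, ped$mother, "0", "0", 2L, 1L),
    t(vapply(seq_along(kids), function(i) {
      c(ped$family_id, kids[i], ped$father, ped$mother,
        rep_len(child_sex, length(kids))[i], 2L)
    }, character(6))))
  write.table(rows, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
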