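# Residue and residue-pair descriptor vectors.

#' Descriptor vector of one residue
#'
#' @param residue One-letter residue code.
#' @return Named numeric vector of the 47 scale values.
#' @export
describe_residue <- function(residue) {
  tab <- aa_descriptor_table()
  if (length(residue) != 1 || !residue %in% rownames(tab))
    stop("non-canonical residue code: ", paste(residue, collapse = ""))
  tab[residue, ]
}

#' Descriptor vector of a CDR3/peptide residue pair
#'
#' Concatenates the CDR3-side and peptide-side descriptor vectors with
#' `cdr3.` and `p.` prefixes, yielding the 94-feature vector used by the
#' correlation and feature-elimination analyses.
#'
#' @param cdr3_res,pep_res One-letter residue codes.
#' @return Named numeric vector of length 94.
#' @export
describe_pair <- function(cdr3_res, pep_res) {
  a <- describe_residue(cdr3_res)
  b <- describe_residue(pep_res)
  c(setNames(a, paste0("cdr3.", names(a))),
    setNames(b, paste0("p.", names(b))))
}

# Vectorized pair-descriptor table: one row per (cdr3, peptide) residue pair.
describe_pair_table <- function(cdr3_res, pep_res) {
  tab <- aa_descriptor_table()
  bad <- unique(c(cdr3_res, pep_res))
  bad <- bad[!bad %in% rownames(tab)]
  if (length(bad)) stop("non-canonical residue code(s): ",
                        paste(bad, collapse = ", "))
  out <- cbind(tab[cdr3_res, , drop = FALSE], tab[pep_res, , drop = FALSE])
  colnames(out) <- c(paste0("cdr3.", colnames(tab)),
                     paste0("p.", colnames(tab)))
  rownames(out) <- NULL
  as.data.frame(out)
}
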