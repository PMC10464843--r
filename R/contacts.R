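# CDR3-peptide contact detection and classification.
#
# A contact pair is a (CDR3 residue, peptide residue) pair whose minimum
# heavy-atom distance is below 5 angstroms. Contacting parts (main chain /
# side chain) are attributed from the atom pair achieving the minimum
# distance, and each pair is typed in the residue-interaction-network
# style: IONIC when oppositely charged side-chain group atoms lie within
# 4.0 A, otherwise HBOND when a donor/acceptor heavy-atom pair lies within
# 3.5 A, otherwise VDW. Crystal-style heavy-atom geometry only; hydrogens
# are ignored.

.CONTACT_CUTOFF <- 5.0
.IONIC_CUTOFF <- 4.0
.HBOND_CUTOFF <- 3.5

#' Find CDR3-peptide contact pairs in a model
#'
#' @param model A `tcr_structure`.
#' @param cdr3_range Length-2 vector: first/last CDR3 position within the
#'   TCR chain (substructure numbering).
#' @param cdr3_chain TCR chain identifier carrying the CDR3.
#' @param peptide_chain Peptide chain identifier.
#' @param cutoff Heavy-atom distance cutoff in angstroms (default 5.0).
#' @return data.frame of contact pairs: cdr3_position (1-based from CDR3
#'   start), cdr3_residue, peptide_position, peptide_residue, min_distance,
#'   cdr3_part, peptide_part, interaction_type, closest_flag. Exactly one
#'   pair per contacting CDR3 residue has `closest_flag = TRUE` (ties
#'   broken toward the lower peptide position).
#' @export
find_contacts <- function(model, cdr3_range, cdr3_chain, peptide_chain,
                          cutoff = .CONTACT_CUTOFF) {
  if (is.null(cdr3_range) || length(cdr3_range) != 2 ||
      cdr3_range[2] < cdr3_range[1])
    stop("input error: empty or invalid CDR3 range")
  a <- model$atoms
  cdr3 <- a[a$chain == cdr3_chain & a$subpos >= cdr3_range[1] &
            a$subpos <= cdr3_range[2], ]
  pep <- a[a$chain == peptide_chain, ]
  if (!nrow(cdr3)) stop("input error: CDR3 range selects no atoms")
  rows <- list()
  for (cp in unique(cdr3$subpos)) {
    rc <- cdr3[cdr3$subpos == cp, ]
    for (pp in unique(pep$subpos)) {
      rp <- pep[pep$subpos == pp, ]
      d2 <- outer(rc$x, rp$x, "-")^2 + outer(rc$y, rp$y, "-")^2 +
        outer(rc$z, rp$z, "-")^2
      imin <- which(d2 == min(d2), arr.ind = TRUE)[1, ]
      dmin <- sqrt(d2[imin[1], imin[2]])
      if (dmin >= cutoff) next
      rows[[length(rows) + 1]] <- data.frame(
        cdr3_position = cp - cdr3_range[1] + 1L,
        cdr3_residue = aa_one(rc$resid[1]),
        peptide_position = pp,
        peptide_residue = aa_one(rp$resid[1]),
        min_distance = dmin,
        cdr3_part = ifelse(rc$backbone[imin[1]], "main_chain", "side_chain"),
        peptide_part = ifelse(rp$backbone[imin[2]], "main_chain",
                              "side_chain"),
        interaction_type = .contact_type(rc, rp, sqrt(d2)),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(cdr3_position = integer(), cdr3_residue = character(),
                      peptide_position = integer(),
                      peptide_residue = character(),
                      min_distance = numeric(), cdr3_part = character(),
                      peptide_part = character(),
                      interaction_type = character(),
                      closest_flag = logical(), stringsAsFactors = FALSE))
  pairs <- do.call(rbind, rows)
  pairs$closest_flag <- FALSE
  for (cp in unique(pairs$cdr3_position)) {
    i <- which(pairs$cdr3_position == cp)
    best <- i[order(pairs$min_distance[i], pairs$peptide_position[i])][1]
    pairs$closest_flag[best] <- TRUE
  }
  pairs[order(pairs$cdr3_position, pairs$peptide_position), , drop = FALSE]
}

# Interaction typing from the full atom-pair distance matrix of a residue
# pair. Precedence: IONIC > HBOND > VDW.
.contact_type <- function(rc, rp, dmat) {
  qc <- charged_group(rc$resid, rc$atom)
  qp <- charged_group(rp$resid, rp$atom)
  opp <- (outer(qc == "neg", qp == "pos", "&") |
          outer(qc == "pos", qp == "neg", "&")) &
    outer(!rc$backbone, !rp$backbone, "&")
  if (any(opp & dmat <= .IONIC_CUTOFF)) return("IONIC")
  don_c <- is_donor_atom(rc$resid, rc$atom)
  acc_c <- is_acceptor_atom(rc$resid, rc$atom)
  don_p <- is_donor_atom(rp$resid, rp$atom)
  acc_p <- is_acceptor_atom(rp$resid, rp$atom)
  hb <- outer(don_c, acc_p, "&") | outer(acc_c, don_p, "&")
  if (any(hb & dmat <= .HBOND_CUTOFF)) return("HBOND")
  "VDW"
}

#' Split contact pairs into the four analysis groups
#'
#' Group 1: all contacting residue pairs. Group 2: per CDR3 residue, only
#' the closest peptide residue. Group 3: pairs interacting through at
#' least one side-chain group. Group 4: intersection of groups 2 and 3.
#'
#' @param pairs Contact-pair data.frame from [find_contacts()].
#' @return Named list of four data.frames (group1..group4).
#' @export
contact_groups <- function(pairs) {
  side <- pairs$cdr3_part == "side_chain" | pairs$peptide_part == "side_chain"
  list(group1 = pairs,
       group2 = pairs[pairs$closest_flag, , drop = FALSE],
       group3 = pairs[side, , drop = FALSE],
       group4 = pairs[pairs$closest_flag & side, , drop = FALSE])
}

#' Contact status of a build's substitution
#'
#' @param build A `model_build`.
#' @param pairs Contact pairs of the build's child model.
#' @return `"contacting"` if the substituted CDR3 position appears in any
#'   contact pair, else `"non_contacting"`.
#' @export
substitution_contact_status <- function(build, pairs) {
  if (build$substitution$position %in% pairs$cdr3_position) "contacting"
  else "non_contacting"
}

#' Count amino-acid pair types across contact groups
#'
#' Tallies 20 x 20 (CDR3 residue x peptide residue) contact-pair counts for
#' a modeled set and an original (template/solved) set, per contact group,
#' and lists the pair types novel to the modeled set.
#'
#' @param model_contacts List of contact-pair data.frames from modeled
#'   structures.
#' @param original_contacts List of contact-pair data.frames from original
#'   structures.
#' @return List per group (group1..group4) with elements `modeled`,
#'   `original` (count matrices) and `novel` (data.frame of pair types seen
#'   only in models).
#' @export
count_contact_pair_types <- function(model_contacts, original_contacts) {
  tally <- function(contacts, grp) {
    m <- matrix(0L, 20, 20, dimnames = list(aa_alphabet(), aa_alphabet()))
    for (pairs in contacts) {
      g <- contact_groups(pairs)[[grp]]
      if (nrow(g))
        for (i in seq_len(nrow(g)))
          m[g$cdr3_residue[i], g$peptide_residue[i]] <-
            m[g$cdr3_residue[i], g$peptide_residue[i]] + 1L
    }
    m
  }
  out <- list()
  for (grp in paste0("group", 1:4)) {
    mod <- tally(model_contacts, grp)
    orig <- tally(original_contacts, grp)
    novel <- which(mod > 0 & orig == 0, arr.ind = TRUE)
    out[[grp]] <- list(
      modeled = mod, original = orig,
      novel = data.frame(cdr3_residue = rownames(mod)[novel[, 1]],
                         peptide_residue = colnames(mod)[novel[, 2]],
                         count = mod[novel], stringsAsFactors = FALSE))
  }
  out
}
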