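# CDR3-peptide interface energies under named term presets.
#
# Energies are computed only over CDR3 <-> peptide heavy-atom pairs (face1 =
# CDR3 residues, face2 = peptide residues) and decomposed per CDR3 residue:
# every pairwise term is assigned wholly to the CDR3-side residue, so the
# per-residue contributions sum exactly to the total.
#
# Term presets mirror the scoring-function taxonomy the analyses compare:
#   large_patch = fa_atr, fa_sol, hbond_sr_bb, hbond_lr_bb, hbond_bb_sc,
#                 hbond_sc
#   small_patch = large_patch minus {hbond_sr_bb, hbond_bb_sc}
#   full        = large_patch plus the clash penalty fa_rep
#
# The surrogate term forms are deliberately simple, finite-ranged analogues
# keeping the right taxonomy (attraction, solvation proxy, hydrogen-bond
# classes split by backbone involvement); totals are in arbitrary surrogate
# units and are NOT comparable to any physics-based score. Precomputed
# per-model energy tables (e.g. real scoring-function output) can be loaded
# with read_energy_table() to drive the same downstream analyses.

.ENERGY_CONSTANTS <- list(
  atr_eps = 0.1,        # depth of the attractive well, surrogate units
  atr_range = 6.0,      # A, attraction cutoff
  sol_penalty = 0.2,    # per buried polar-atom pair
  sol_range = 4.5,      # A
  hb_depth = 1.5,       # hydrogen-bond well depth
  hb_lo = 2.6, hb_hi = 3.5,  # A, switch window
  srbb_sep = 4)         # max |cdr3_pos - pep_pos| for "short-range" bb-bb

#' Interface-energy term presets
#'
#' @return Named list of character vectors of term names.
#' @export
energy_presets <- function() {
  large <- c("fa_atr", "fa_sol", "hbond_sr_bb", "hbond_lr_bb",
             "hbond_bb_sc", "hbond_sc")
  list(full = c(large, "fa_rep"),
       large_patch = large,
       small_patch = setdiff(large, c("hbond_sr_bb", "hbond_bb_sc")))
}

.switch_fn <- function(r, lo, hi) {
  w <- rep(0, length(r))
  w[r <= lo] <- 1
  mid <- r > lo & r < hi
  w[mid] <- 0.5 * (1 + cos(pi * (r[mid] - lo) / (hi - lo)))
  w
}

#' CDR3-peptide interface energy
#'
#' @param model A `tcr_structure`.
#' @param cdr3_range First/last CDR3 position within the TCR chain.
#' @param cdr3_chain,peptide_chain Chain identifiers.
#' @param preset `"full"`, `"large_patch"` or `"small_patch"`.
#' @param constants Term constants (see `.ENERGY_CONSTANTS` defaults).
#' @return An `interface_energy` object: `total`, `per_residue` (named by
#'   1-based CDR3 position), `terms` (per-term totals) plus the geometry
#'   context used (model, ranges) for downstream differencing.
#' @export
interface_energy <- function(model, cdr3_range, cdr3_chain, peptide_chain,
                             preset = c("full", "large_patch", "small_patch"),
                             constants = .ENERGY_CONSTANTS) {
  presets <- energy_presets()
  preset <- as.character(preset)[1]
  if (!preset %in% names(presets))
    stop("config error: unknown energy preset: ", preset)
  terms <- presets[[preset]]
  k <- constants
  a <- model$atoms
  A <- a[a$chain == cdr3_chain & a$subpos >= cdr3_range[1] &
         a$subpos <= cdr3_range[2], ]
  B <- a[a$chain == peptide_chain, ]
  cdr3_pos <- A$subpos - cdr3_range[1] + 1L
  positions <- sort(unique(cdr3_pos))
  per_term <- matrix(0, length(positions), 7,
                     dimnames = list(positions,
                                     c("fa_atr", "fa_rep", "fa_sol",
                                       "hbond_sr_bb", "hbond_lr_bb",
                                       "hbond_bb_sc", "hbond_sc")))
  if (nrow(A) && nrow(B)) {
    dx <- outer(A$x, B$x, "-"); dy <- outer(A$y, B$y, "-")
    dz <- outer(A$z, B$z, "-")
    r <- sqrt(dx^2 + dy^2 + dz^2)
    rm <- outer(.ELEMENT_RADII[A$element], .ELEMENT_RADII[B$element], "+")
    # fa_atr: attractive branch, clamped at the minimum and cut at range
    rc <- pmax(r, rm)
    atr <- -k$atr_eps * (rm / rc)^6
    atr[r > k$atr_range] <- 0
    # fa_rep: clash penalty, zero beyond the contact radius
    rep_ <- k$atr_eps * ((rm / r)^12 - 2 * (rm / r)^6 + 1)
    rep_[r >= rm] <- 0
    # fa_sol: burial penalty for polar-polar atom pairs
    polar_a <- A$element %in% c("N", "O")
    polar_b <- B$element %in% c("N", "O")
    sol <- k$sol_penalty * outer(polar_a, polar_b, "&") * (r <= k$sol_range)
    # hydrogen bonds: donor/acceptor heavy-atom pairs in the switch window
    don_a <- is_donor_atom(A$resid, A$atom)
    acc_a <- is_acceptor_atom(A$resid, A$atom)
    don_b <- is_donor_atom(B$resid, B$atom)
    acc_b <- is_acceptor_atom(B$resid, B$atom)
    hb_pair <- outer(don_a, acc_b, "&") | outer(acc_a, don_b, "&")
    hb <- -k$hb_depth * .switch_fn(r, k$hb_lo, k$hb_hi) * hb_pair
    bb <- outer(A$backbone, B$backbone, "&")
    sc <- outer(!A$backbone, !B$backbone, "&")
    mixed <- !(bb | sc)
    sep <- abs(outer(cdr3_pos, B$subpos, "-"))
    srbb <- bb & sep <= k$srbb_sep
    contrib <- list(fa_atr = atr, fa_rep = rep_, fa_sol = sol,
                    hbond_sr_bb = hb * srbb,
                    hbond_lr_bb = hb * (bb & !srbb),
                    hbond_bb_sc = hb * mixed,
                    hbond_sc = hb * sc)
    for (tm in names(contrib)) {
      by_pos <- rowsum(rowSums(contrib[[tm]]), cdr3_pos)
      per_term[rownames(by_pos), tm] <- by_pos[, 1]
    }
  }
  per_residue <- rowSums(per_term[, terms, drop = FALSE])
  names(per_residue) <- positions
  structure(list(preset = preset, total = sum(per_residue),
                 per_residue = per_residue,
                 terms = colSums(per_term),
                 model = model, cdr3_range = cdr3_range,
                 cdr3_chain = cdr3_chain, peptide_chain = peptide_chain),
            class = "interface_energy")
}

#' @export
print.interface_energy <- function(x, ...) {
  cat(sprintf("<interface_energy> preset %s, total %.4f over %d CDR3 positions\n",
              x$preset, x$total, length(x$per_residue)))
  invisible(x)
}

#' Energy change along one substitution step
#'
#' @param parent,child `interface_energy` objects of the parent and child
#'   model under the same preset.
#' @param substitution List with `position` (1-based CDR3 position),
#'   `from`, `to`.
#' @return A `denergy` object: `value` = E(child) - E(parent),
#'   `min_substitution_distance` = minimum heavy-atom distance from the
#'   substituted residue to the peptide in the child model, plus the
#'   substitution and preset.
#' @export
denergy <- function(parent, child, substitution) {
  if (!identical(parent$preset, child$preset))
    stop("preset mismatch: ", parent$preset, " vs ", child$preset)
  val <- child$total - parent$total
  a <- child$model$atoms
  chain_pos <- child$cdr3_range[1] + substitution$position - 1L
  sub_xyz <- as.matrix(a[a$chain == child$cdr3_chain &
                         a$subpos == chain_pos, c("x", "y", "z")])
  pep_xyz <- as.matrix(a[a$chain == child$peptide_chain, c("x", "y", "z")])
  structure(list(value = val, preset = parent$preset,
                 substitution = substitution,
                 min_substitution_distance = .min_dist(sub_xyz, pep_xyz)),
            class = "denergy")
}

#' Energetically valuable CDR3 positions of a template
#'
#' For each preset the position(s) with minimal per-residue energy are
#' selected; when the presets disagree all candidate positions are
#' included (the union across presets).
#'
#' @param energies List of `interface_energy` objects for the same model
#'   under the full, large-patch and small-patch presets.
#' @param tol Tie tolerance on per-residue energies.
#' @return Sorted integer vector of CDR3 positions.
#' @export
valuable_positions <- function(energies, tol = 1e-9) {
  pos <- lapply(energies, function(e) {
    pr <- e$per_residue
    as.integer(names(pr)[pr <= min(pr) + tol])
  })
  sort(unique(unlist(pos)))
}

#' Rate of substitutions landing in valuable positions
#'
#' @param subs data.frame with one row per substitution/build: `valuable`
#'   (logical: position is energetically valuable on its template),
#'   `contacting` (logical: substitution in a contacting position) and
#'   optionally `group` (non-redundancy key; when present the
#'   non-redundant rates average the indicators within groups first).
#' @return List with `redundant` and (if groups given) `nonredundant`
#'   components, each `c(all = ..., contacting = ...)`.
#' @export
valuable_substitution_rate <- function(subs) {
  rate <- function(v, ct) {
    c(all = if (length(v)) mean(v) else 0,
      contacting = if (any(ct)) mean(v[ct]) else 0)
  }
  out <- list(redundant = rate(subs$valuable, subs$contacting))
  if (!is.null(subs$group)) {
    gv <- tapply(subs$valuable, subs$group, mean)
    gc_ <- tapply(subs$contacting, subs$group, mean)
    # a group is "contacting" when any member build contacts the peptide
    out$nonredundant <- c(
      all = mean(gv),
      contacting = if (any(gc_ > 0)) mean(gv[gc_ > 0]) else 0)
  }
  out
}

#' Read a precomputed per-model energy table
#'
#' Accepts tab-separated tables standing in for external scoring output,
#' with columns model_id, preset, total, position, per_residue (one row per
#' CDR3 position).
#'
#' @param path TSV path.
#' @return Named list (by model_id) of lists (by preset) of
#'   `interface_energy`-like objects (no geometry attached).
#' @export
read_energy_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("model_id", "preset", "total", "position", "per_residue")
  if (!all(need %in% names(tab)))
    stop("energy table lacks columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  out <- list()
  for (mid in unique(tab$model_id)) {
    out[[mid]] <- list()
    for (ps in unique(tab$preset[tab$model_id == mid])) {
      rows <- tab[tab$model_id == mid & tab$preset == ps, ]
      pr <- setNames(rows$per_residue, rows$position)
      if (abs(sum(pr) - rows$total[1]) > 1e-6)
        warning("per-residue sum differs from total for ", mid, "/", ps)
      out[[mid]][[ps]] <- structure(
        list(preset = ps, total = rows$total[1], per_residue = pr,
             terms = NULL, model = NULL),
        class = "interface_energy")
    }
  }
  out
}
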