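# Turning build orders into child model structures.
#
# The mutation step follows the template-based protocol: main-chain heavy
# atoms are retained from the parent structure and only the substituted
# residue's side chain changes. The default backend is a deterministic
# geometric surrogate (ideal side-chain geometry on the parent backbone
# frame, parent torsions copied where atom names coincide). An external
# Rosetta-style backend can be plugged in through the same contract
# (mutate/optimize function pair); precomputed energy tables can bypass
# structure building entirely (see the energetics module).

#' Surrogate single-residue mutation
#'
#' Replaces one residue's identity and side chain while copying every
#' backbone heavy atom (and CB, when present and the target is not
#' glycine) from the parent bitwise. Remaining side-chain atoms are placed
#' from the internal ideal-geometry table with torsions copied from the
#' parent wherever the defining atom names coincide. Mutating a residue to
#' its own type returns the parent unchanged.
#'
#' @param parent A `tcr_structure`.
#' @param chain Chain identifier.
#' @param position Residue position (1-based substructure numbering within
#'   the chain).
#' @param to_aa Target one-letter residue code.
#' @return A new `tcr_structure`.
#' @export
surrogate_mutate <- function(parent, chain, position, to_aa) {
  stopifnot(to_aa %in% aa_alphabet())
  a <- parent$atoms
  sel <- a$chain == chain & a$subpos == position
  if (!any(sel)) stop("structural error: residue ", position,
                      " absent from chain ", chain)
  old3 <- a$resid[sel][1]
  new3 <- aa_three(to_aa)
  if (old3 == new3) return(parent)
  old_xyz <- residue_xyz(parent, chain, position)
  need <- c("N", "CA", "C", "O")
  if (!all(need %in% rownames(old_xyz)))
    stop("structural error: backbone atom(s) missing: ",
         paste(setdiff(need, rownames(old_xyz)), collapse = ", "))
  keep <- intersect(rownames(old_xyz), backbone_atom_names())
  if (new3 != "GLY" && "CB" %in% rownames(old_xyz)) keep <- c(keep, "CB")
  xyz <- build_sidechain(new3, old_xyz[keep, , drop = FALSE],
                         parent = old_xyz)
  res <- a[sel, ][1, ]
  new_rows <- data.frame(chain = chain, subpos = position,
                         resno = res$resno, resid = new3,
                         atom = rownames(xyz), x = xyz[, 1], y = xyz[, 2],
                         z = xyz[, 3], stringsAsFactors = FALSE)
  rest <- a[!sel, c("chain", "subpos", "resno", "resid", "atom",
                    "x", "y", "z")]
  tcr_structure(rbind(rest, new_rows))
}

#' Mutation backends
#'
#' A backend is a list with functions `mutate(parent, chain, position,
#' to_aa)` and `optimize(structure, mode, template)`. The surrogate backend
#' implements the mutate contract geometrically; its "minimized" mode is a
#' no-op (the surrogate has no continuous minimizer, and coordinate
#' constraints would bound displacements near zero anyway) and "repacked"
#' runs a greedy chi1 grid search relieving side-chain clashes for CDR3 and
#' peptide residues within 10 angstroms of each other. An external backend
#' wrapping a Rosetta-style tool plugs in through the same contract
#' (input PDB plus a mutation spec, output PDB).
#'
#' @return Backend list.
#' @export
surrogate_backend <- function() {
  list(
    name = "surrogate",
    mutate = surrogate_mutate,
    optimize = function(struct, mode, template) {
      if (mode == "repacked") .surrogate_repack(struct, template)
      else struct
    })
}

# Greedy chi1 sweep over interface residues: for each CDR3 residue whose
# minimum heavy-atom distance to the peptide is under 10 A, try chi1 in
# {-180, -120, -60, 0, 60, 120} and keep the rotamer with the lowest
# surrogate full-preset interface energy. Side-chain atoms only move.
.surrogate_repack <- function(struct, template) {
  chain <- template$.model_chain
  rng <- template_cdr3_range(template, chain)
  tcr_chain <- template_chain_id(template, chain)
  pep_chain <- template$chain_map$peptide
  pep <- as.matrix(struct$atoms[struct$atoms$chain == pep_chain,
                                c("x", "y", "z")])
  for (pos in seq(rng[1], rng[2])) {
    xyz <- residue_xyz(struct, tcr_chain, pos)
    res3 <- struct$atoms$resid[struct$atoms$chain == tcr_chain &
                               struct$atoms$subpos == pos][1]
    topo <- .SIDECHAIN_TOPOLOGY[[res3]]
    if (is.null(topo) || !any(!is.na(topo$chi))) next
    if (.min_dist(xyz, pep) > 10) next
    best <- struct
    e_best <- .model_energy_total(struct, template)
    bb <- xyz[intersect(rownames(xyz), c("N", "CA", "C", "O", "OXT", "CB")),
              , drop = FALSE]
    for (chi1 in seq(-180, 120, by = 60)) {
      cand_xyz <- build_sidechain(res3, bb[intersect(rownames(bb),
                                  c("N", "CA", "C", "O", "OXT")), ,
                                  drop = FALSE],
                                  parent = xyz, chi = list(chi1 = chi1))
      cand <- .replace_residue_atoms(struct, tcr_chain, pos, res3, cand_xyz)
      e <- .model_energy_total(cand, template)
      if (e < e_best - 1e-12) { e_best <- e; best <- cand }
    }
    struct <- best
  }
  struct
}

.min_dist <- function(xyz_a, xyz_b) {
  if (!nrow(xyz_a) || !nrow(xyz_b)) return(Inf)
  d2 <- outer(rowSums(xyz_a^2), rowSums(xyz_b^2), "+") -
    2 * xyz_a %*% t(xyz_b)
  sqrt(max(0, min(d2)))
}

.replace_residue_atoms <- function(struct, chain, pos, res3, xyz) {
  a <- struct$atoms
  sel <- a$chain == chain & a$subpos == pos
  resno <- a$resno[sel][1]
  rest <- a[!sel, c("chain", "subpos", "resno", "resid", "atom",
                    "x", "y", "z")]
  tcr_structure(rbind(rest, data.frame(
    chain = chain, subpos = pos, resno = resno, resid = res3,
    atom = rownames(xyz), x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE)))
}

.model_energy_total <- function(struct, template) {
  chain <- template$.model_chain
  interface_energy(struct,
                   cdr3_range = template_cdr3_range(template, chain),
                   cdr3_chain = template_chain_id(template, chain),
                   peptide_chain = template$chain_map$peptide,
                   preset = "full")$total
}

#' Execute model build orders
#'
#' Runs build orders in prefix order (parents before children), mutating
#' from the template structure along each pathway prefix. Each completed
#' build records its provenance (template, pathway prefix, substitution,
#' backend, optimization arm). A failed build marks its descendants
#' skipped and the run continues (set `fail_fast` to abort instead).
#' Re-running with the same `store` environment reuses completed builds.
#'
#' @param orders Build-order data.frame from [pathway_models()].
#' @param templates Named list of `template_complex` objects keyed by pdb
#'   id.
#' @param backend Backend list; default [surrogate_backend()].
#' @param optimization `"minimized"`, `"repacked"` or `"none"`.
#' @param fail_fast Stop at the first failed build.
#' @param store Optional environment used as a persistent build store.
#' @return List of `model_build` objects (one per order, failed/skipped
#'   builds carry `status` accordingly and no structure).
#' @export
run_builds <- function(orders, templates, backend = surrogate_backend(),
                       optimization = c("minimized", "repacked", "none"),
                       fail_fast = FALSE, store = new.env()) {
  optimization <- match.arg(optimization)
  orders <- orders[order(orders$step_index), , drop = FALSE]
  out <- vector("list", nrow(orders))
  for (i in seq_len(nrow(orders))) {
    o <- orders[i, ]
    tpl <- templates[[o$template]]
    if (is.null(tpl)) stop("unknown template: ", o$template)
    tpl$.model_chain <- o$chain
    key <- paste(o$template, o$chain, o$prefix, optimization)
    if (!is.null(store[[key]])) { out[[i]] <- store[[key]]; next }
    steps <- strsplit(o$prefix, ">", fixed = TRUE)[[1]]
    parent_key <- paste(o$template, o$chain,
                        paste(steps[-length(steps)], collapse = ">"),
                        optimization)
    if (o$step_index == 1) {
      parent_struct <- tpl$structure
    } else {
      pb <- store[[parent_key]]
      if (is.null(pb)) stop("input error: parent prefix not built for ",
                            o$prefix)
      if (pb$status != "ok") {
        out[[i]] <- .model_build(o, NULL, backend$name, optimization,
                                 status = "skipped")
        store[[key]] <- out[[i]]
        next
      }
      parent_struct <- pb$structure
    }
    chain_pos <- template_cdr3_range(tpl, o$chain)[1] + o$position - 1
    build <- tryCatch({
      child <- backend$mutate(parent_struct,
                              template_chain_id(tpl, o$chain),
                              chain_pos, o$to_aa)
      child <- backend$optimize(child, optimization, tpl)
      .model_build(o, child, backend$name, optimization, status = "ok")
    }, error = function(e) {
      if (fail_fast) stop(e)
      .model_build(o, NULL, backend$name, optimization, status = "failed",
                   message = conditionMessage(e))
    })
    out[[i]] <- build
    store[[key]] <- build
  }
  out
}

.model_build <- function(order, structure, backend, optimization,
                         status = "ok", message = NULL) {
  structure(list(
    build_id = order$build_id, template = order$template,
    chain = order$chain, prefix = strsplit(order$prefix, ">")[[1]],
    parent_cdr3 = order$parent_cdr3, child_cdr3 = order$child_cdr3,
    substitution = list(position = order$position, from = order$from_aa,
                        to = order$to_aa),
    structure = structure, backend = backend, optimization = optimization,
    status = status, message = message), class = "model_build")
}

#' @export
print.model_build <- function(x, ...) {
  cat(sprintf("<model_build> %s %s %s->%s (%s%d%s) [%s, %s, %s]\n",
              x$template, x$chain, x$parent_cdr3, x$child_cdr3,
              x$substitution$from, x$substitution$position,
              x$substitution$to, x$backend, x$optimization, x$status))
  invisible(x)
}

#' Group builds into a non-redundant set
#'
#' Builds sharing the template's full set of TCR chain sequences, the final
#' CDR3 and the chain are one group; spatial and energy properties are
#' averaged within groups in downstream non-redundant analyses.
#'
#' @param builds List of `model_build` objects.
#' @param templates Named list of templates (for chain sequences).
#' @return Named list of build lists, keyed by the group key.
#' @export
group_nonredundant <- function(builds, templates) {
  keys <- vapply(builds, function(b) {
    seqs <- template_chain_sequences(templates[[b$template]])
    paste(paste(seqs, collapse = "|"), b$child_cdr3, b$chain, sep = "||")
  }, "")
  split(builds, keys)
}
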