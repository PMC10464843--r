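# CDR3 clustering around template cores and mutation-pathway enumeration.
#
# A cluster is anchored at a "core" CDR3 taken from a solved template
# structure. Database records join the cluster when they share chain, V
# gene, J gene, epitope and CDR3 length with the core, lie within Hamming
# distance 3 of it (no insertions or deletions), and - in the default
# "observed" mode - are reachable from the core through a chain of
# single-substitution (Hamming-1) edges running over observed sequences.
# A mutation pathway is an ordered chain of single substitutions from the
# core whose distance from the core increases by exactly one per step.

#' Hamming distance between equal-length sequences
#'
#' @param a,b Character strings of equal length.
#' @return Integer count of mismatching positions.
#' @export
hamming <- function(a, b) {
  if (nchar(a) != nchar(b))
    stop("length error: sequences differ in length (",
         nchar(a), " vs ", nchar(b), "); insertions/deletions disallowed")
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

.hamming_vec <- function(core, seqs) {
  if (!length(seqs)) return(integer(0))
  cc <- strsplit(core, "")[[1]]
  vapply(strsplit(seqs, ""), function(s) sum(s != cc), 0L)
}

#' Build a CDR3 cluster around a template core
#'
#' @param core Single-row record data.frame: the template's CDR3 annotation
#'   for one chain.
#' @param records Candidate record data.frame.
#' @param template Optional `template_complex` the core belongs to; when
#'   given, the core CDR3 must match the template's annotated CDR3 for the
#'   chain.
#' @param max_distance Maximum Hamming distance from the core (default 3).
#' @param mode `"observed"` (default): members must be connected to the
#'   core through Hamming-1 edges over observed sequences; `"free"`:
#'   arbitrary unobserved intermediates are allowed, so any candidate
#'   within `max_distance` joins.
#' @param gene_level Compare V/J genes after stripping the allele suffix.
#' @return A `cdr3_cluster` object (core, members, template, chain, mode).
#' @export
build_cluster <- function(core, records, template = NULL, max_distance = 3,
                          mode = c("observed", "free"), gene_level = FALSE) {
  mode <- match.arg(mode)
  stopifnot(nrow(core) == 1)
  if (!is.null(template)) {
    tpl_cdr3 <- template_cdr3_sequence(template, core$chain)
    if (!identical(tpl_cdr3, core$cdr3))
      stop("core CDR3 (", core$cdr3, ") does not match template CDR3 (",
           tpl_cdr3, ") for chain ", core$chain)
  }
  vg <- if (gene_level) strip_allele else identity
  cand <- records[records$chain == core$chain &
                  vg(records$v_gene) == vg(core$v_gene) &
                  vg(records$j_gene) == vg(core$j_gene) &
                  records$epitope == core$epitope &
                  nchar(records$cdr3) == nchar(core$cdr3), , drop = FALSE]
  cand <- cand[!duplicated(cand$cdr3), , drop = FALSE]
  d <- .hamming_vec(core$cdr3, cand$cdr3)
  cand <- cand[d > 0 & d <= max_distance, , drop = FALSE]
  if (nrow(cand) && mode == "observed") {
    seqs <- c(core$cdr3, cand$cdr3)
    mat <- do.call(rbind, strsplit(seqs, ""))
    # Hamming-1 adjacency over {core} + candidates
    n <- length(seqs)
    h1 <- matrix(FALSE, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      h1[i, j] <- h1[j, i] <- sum(mat[i, ] != mat[j, ]) == 1L
    g <- igraph::graph_from_adjacency_matrix(h1, mode = "undirected")
    comp <- igraph::components(g)$membership
    keep <- comp[-1] == comp[1]
    cand <- cand[keep, , drop = FALSE]
  }
  cand <- cand[order(cand$cdr3), , drop = FALSE]
  rownames(cand) <- NULL
  structure(list(core = core, members = cand, template = template,
                 chain = core$chain, mode = mode,
                 max_distance = max_distance),
            class = "cdr3_cluster")
}

#' @export
print.cdr3_cluster <- function(x, ...) {
  cat(sprintf("<cdr3_cluster> core %s (%s), %d member(s), mode %s\n",
              x$core$cdr3, x$chain, nrow(x$members), x$mode))
  invisible(x)
}

#' Enumerate stepwise single-substitution mutation pathways
#'
#' Returns every distance-monotone path from the cluster core to every
#' member: each step is a single substitution, the Hamming distance from
#' the core increases by exactly one per step, and (in observed mode) every
#' intermediate is itself a cluster member. In free mode intermediates are
#' unobserved sequences generated by applying the member's substitutions in
#' every possible order.
#'
#' @param cluster A `cdr3_cluster`.
#' @return List of `mutation_pathway` objects, each with elements
#'   `template` (pdb id or NA), `chain`, `steps` (character vector starting
#'   at the core) and `substitutions` (data.frame position/from/to per
#'   step). Pathways are sorted by their step strings.
#' @export
enumerate_pathways <- function(cluster) {
  core <- cluster$core$cdr3
  members <- cluster$members$cdr3
  if (!length(members)) return(list())
  paths <- if (cluster$mode == "free")
    .free_paths(core, members, cluster$max_distance)
  else .observed_paths(core, members, cluster$max_distance)
  paths <- paths[order(vapply(paths, paste, "", collapse = ">"))]
  tpl <- if (is.null(cluster$template)) NA_character_ else
    cluster$template$pdb_id
  lapply(paths, function(p) {
    subs <- do.call(rbind, lapply(seq_len(length(p) - 1), function(i) {
      pos <- which(strsplit(p[i], "")[[1]] != strsplit(p[i + 1], "")[[1]])
      data.frame(step = i, position = pos,
                 from = substr(p[i], pos, pos), to = substr(p[i + 1], pos, pos),
                 stringsAsFactors = FALSE)
    }))
    structure(list(template = tpl, chain = cluster$chain, steps = p,
                   substitutions = subs), class = "mutation_pathway")
  })
}

# Distance-monotone DFS over observed members.
.observed_paths <- function(core, members, max_distance) {
  d <- .hamming_vec(core, members)
  out <- list()
  extend <- function(path, cur, dcur) {
    nxt <- members[d == dcur + 1]
    nxt <- nxt[.hamming_vec(cur, nxt) == 1]
    for (s in sort(nxt)) {
      p <- c(path, s)
      out[[length(out) + 1]] <<- p
      if (dcur + 1 < max_distance) extend(p, s, dcur + 1)
    }
  }
  extend(core, core, 0)
  out
}

# All substitution orders through arbitrary intermediates.
.free_paths <- function(core, members, max_distance) {
  cc <- strsplit(core, "")[[1]]
  out <- list()
  seen <- new.env(parent = emptyenv())
  for (m in sort(members)) {
    mm <- strsplit(m, "")[[1]]
    pos <- which(cc != mm)
    perms <- .permutations(pos)
    for (ord in perms) {
      steps <- core
      cur <- cc
      for (p in ord) {
        cur[p] <- mm[p]
        steps <- c(steps, paste(cur, collapse = ""))
      }
      key <- paste(steps, collapse = ">")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        out[[length(out) + 1]] <- steps
      }
    }
  }
  out
}

.permutations <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in .permutations(x[-i]))
      out[[length(out) + 1]] <- c(x[i], rest)
  out
}

#' Expand pathways into deduplicated model build orders
#'
#' Each pathway step yields one build order (template, parent CDR3, child
#' CDR3); orders sharing the same template and step prefix are built once.
#'
#' @param pathways List of `mutation_pathway` objects (possibly from
#'   several clusters).
#' @return data.frame with columns template, chain, step_index,
#'   parent_cdr3, child_cdr3, position, from_aa, to_aa, prefix and
#'   build_id; attributes `n_pathways`, `n_build_orders` and
#'   `n_final_models` carry the three counters.
#' @export
pathway_models <- function(pathways) {
  rows <- lapply(pathways, function(pw) {
    do.call(rbind, lapply(seq_len(length(pw$steps) - 1), function(i) {
      sub <- pw$substitutions[pw$substitutions$step == i, ]
      data.frame(template = pw$template, chain = pw$chain, step_index = i,
                 parent_cdr3 = pw$steps[i], child_cdr3 = pw$steps[i + 1],
                 position = sub$position, from_aa = sub$from, to_aa = sub$to,
                 prefix = paste(pw$steps[seq_len(i + 1)], collapse = ">"),
                 stringsAsFactors = FALSE)
    }))
  })
  orders <- do.call(rbind, rows)
  if (is.null(orders)) {
    orders <- data.frame(template = character(), chain = character(),
                         step_index = integer(), parent_cdr3 = character(),
                         child_cdr3 = character(), position = integer(),
                         from_aa = character(), to_aa = character(),
                         prefix = character(), build_id = character(),
                         stringsAsFactors = FALSE)
    attr(orders, "n_pathways") <- 0L
    attr(orders, "n_build_orders") <- 0L
    attr(orders, "n_final_models") <- 0L
    return(orders)
  }
  key <- paste(orders$template, orders$chain, orders$prefix)
  orders <- orders[!duplicated(key), , drop = FALSE]
  orders <- orders[order(orders$template, orders$chain, orders$step_index,
                         orders$prefix), , drop = FALSE]
  orders$build_id <- sprintf("b%04d", seq_len(nrow(orders)))
  rownames(orders) <- NULL
  attr(orders, "n_pathways") <- length(pathways)
  attr(orders, "n_build_orders") <- nrow(orders)
  attr(orders, "n_final_models") <-
    nrow(unique(orders[, c("template", "chain", "child_cdr3")]))
  orders
}
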