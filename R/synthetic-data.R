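# Synthetic inputs for every pipeline stage: planted repertoires with known
# cluster/pathway structure, toy complexes with controlled contact
# geometry, and descriptor-energy tables with planted effects.
#
# Ground-truth manifests are produced by brute force inside the generators
# (exhaustive permutation enumeration, all-pairs distance scans) and never
# by calling the analysis modules, so they can serve as independent oracles
# in tests.

#' Generate a planted CDR3 repertoire
#'
#' Builds `n_clusters` clusters around random cores. Members are grown
#' distance-monotonically (each new member attaches one substitution away
#' from an existing member, one step further from the core), so every
#' member has at least one stepwise pathway. Decoys violate exactly one
#' membership rule each: wrong V gene, wrong J gene, wrong length, wrong
#' epitope, Hamming distance above the limit, or Hamming-disconnected.
#'
#' @param spec List: `n_clusters`, `members_per_cluster`, `max_distance`
#'   (<= 3), `cdr3_length`, `alphabet` (character vector), `decoys` (named
#'   counts: wrong_v, wrong_j, wrong_length, wrong_epitope, too_distant,
#'   disconnected), `seed`.
#' @return List: `records` (member + decoy record data.frame), `manifest`
#'   (per cluster: core record, member CDR3s, brute-force pathway list),
#'   `spec`.
#' @export
generate_repertoire <- function(spec) {
  sp <- utils::modifyList(list(
    n_clusters = 1, members_per_cluster = 5, max_distance = 3,
    cdr3_length = 8, alphabet = aa_alphabet(),
    decoys = c(wrong_v = 0, wrong_j = 0, wrong_length = 0,
               wrong_epitope = 0, too_distant = 0, disconnected = 0),
    seed = 1), spec)
  if (sp$max_distance > 3) stop("spec error: max_distance must be <= 3")
  set.seed(sp$seed)
  rand_seq <- function(n) paste(sample(sp$alphabet, n, replace = TRUE),
                                collapse = "")
  records <- list()
  manifest <- list()
  for (ci in seq_len(sp$n_clusters)) {
    chain <- if (!is.null(sp$chains)) sp$chains[ci] else
      if (ci %% 2 == 1) "beta" else "alpha"
    v <- sprintf("TRV%d-%d*01", ci, ci); j <- sprintf("TRJ%d*01", ci)
    epi <- if (!is.null(sp$epitopes)) sp$epitopes[ci] else rand_seq(9)
    core <- if (!is.null(sp$cores)) sp$cores[ci] else
      rand_seq(sp$cdr3_length)
    members <- character(0)
    dist_of <- function(s) hamming_bf(core, s)
    for (mi in seq_len(sp$members_per_cluster)) {
      for (try in 1:200) {
        parent <- sample(c(core, members), 1)
        dp <- dist_of(parent)
        if (dp >= sp$max_distance) next
        # substitute one position currently matching the core
        cc <- strsplit(core, "")[[1]]; pp <- strsplit(parent, "")[[1]]
        free <- which(cc == pp)
        if (!length(free)) next
        pos <- if (length(free) == 1) free else sample(free, 1)
        sub <- sample(setdiff(sp$alphabet, pp[pos]), 1)
        pp[pos] <- sub
        cand <- paste(pp, collapse = "")
        if (!cand %in% c(core, members)) { members <- c(members, cand); break }
      }
    }
    decoy_rows <- .make_decoys(core, members, sp, chain, v, j, epi, ci)
    for (m in members)
      records[[length(records) + 1]] <-
        make_record(m, chain, v, j, epi, record_id = sprintf("c%d:%s", ci, m))
    records <- c(records, decoy_rows)
    manifest[[ci]] <- list(
      core = make_record(core, chain, v, j, epi,
                         record_id = sprintf("core%d", ci)),
      members = sort(members),
      pathways = .bruteforce_paths(core, members))
  }
  list(records = do.call(rbind, records), manifest = manifest, spec = sp)
}

# Independent Hamming (no shared code with the clustering module's loop).
hamming_bf <- function(a, b) {
  length(Filter(identity,
                utf8ToInt(a) != utf8ToInt(b)))
}

# Exhaustive pathway enumeration: all permutations of the differing
# positions, keeping chains whose intermediates are all observed members.
.bruteforce_paths <- function(core, members, observed = TRUE) {
  out <- list()
  for (m in sort(members)) {
    cc <- strsplit(core, "")[[1]]; mm <- strsplit(m, "")[[1]]
    pos <- which(cc != mm)
    for (ord in .permutations(pos)) {
      cur <- cc; steps <- core; ok <- TRUE
      for (p in ord) {
        cur[p] <- mm[p]
        s <- paste(cur, collapse = "")
        if (observed && !s %in% members) { ok <- FALSE; break }
        steps <- c(steps, s)
      }
      if (ok) out[[length(out) + 1]] <- steps
    }
  }
  unique(out)
}

.make_decoys <- function(core, members, sp, chain, v, j, epi, ci) {
  d <- sp$decoys
  d <- vapply(c("wrong_v", "wrong_j", "wrong_length", "wrong_epitope",
                "too_distant", "disconnected"),
              function(nm) if (is.na(d[nm])) 0L else as.integer(d[nm]), 0L)
  mk <- function(cdr3, v2 = v, j2 = j, epi2 = epi, tag) {
    make_record(cdr3, chain, v2, j2, epi2,
                record_id = sprintf("c%d:decoy:%s", ci, tag))
  }
  mutate_core <- function(k) {
    cc <- strsplit(core, "")[[1]]
    pos <- sample(length(cc), k)
    for (p in pos) cc[p] <- sample(setdiff(sp$alphabet, cc[p]), 1)
    paste(cc, collapse = "")
  }
  out <- list()
  rep_n <- function(n, f) for (i in seq_len(n)) out[[length(out) + 1]] <<- f(i)
  rep_n(d["wrong_v"], function(i)
    mk(mutate_core(1), v2 = paste0(v, "-x"), tag = paste0("v", i)))
  rep_n(d["wrong_j"], function(i)
    mk(mutate_core(1), j2 = paste0(j, "-x"), tag = paste0("j", i)))
  rep_n(d["wrong_length"], function(i)
    mk(paste0(core, "A"), tag = paste0("len", i)))
  rep_n(d["wrong_epitope"], function(i)
    mk(mutate_core(1), epi2 = paste0(substr(epi, 2, nchar(epi)), "A"),
       tag = paste0("epi", i)))
  rep_n(d["too_distant"], function(i)
    mk(mutate_core(min(sp$max_distance + 1, nchar(core))),
       tag = paste0("far", i)))
  rep_n(d["disconnected"], function(i) {
    for (try in 1:500) {
      cand <- mutate_core(2)
      near <- vapply(c(core, members), function(s) hamming_bf(cand, s), 0L)
      if (all(near >= 2) && hamming_bf(cand, core) <= sp$max_distance)
        return(mk(cand, tag = paste0("disc", i)))
    }
    stop("spec error: could not place a disconnected decoy")
  })
  out
}

# ---------------------------------------------------------------------------
# Toy complexes
# ---------------------------------------------------------------------------

.PLAN_RESIDUES <- list(IONIC = c(cdr3 = "D", pep = "R"),
                       HBOND = c(cdr3 = "S", pep = "S"),
                       VDW = c(cdr3 = "L", pep = "A"))

#' Generate a toy CDR3-peptide complex with planned contacts
#'
#' Two idealized strands (peptide chain "P", CDR3 chain "C") with residues
#' spaced widely along x; for each planned contact the CDR3 residue is
#' translated toward its peptide partner until the pair's minimum
#' heavy-atom distance equals the target. Residue types default to a
#' donor/acceptor, charged or apolar pair matching the intended
#' interaction type; unplanned residues are alanine kept far from the
#' peptide. The expected contact list is computed by the generator's own
#' all-pairs distance scan.
#'
#' @param spec List: `peptide_length`, `cdr3_length`, `contact_plan`
#'   (data.frame cdr3_pos, pep_pos, distance, type; optional cdr3_res,
#'   pep_res), `seed`, optional `cdr3_seq`/`peptide_seq`.
#' @return List: `structure` (`tcr_structure`), `template`
#'   (`template_complex` wrapping it), `expected_contacts` (data.frame),
#'   `cdr3_seq`, `peptide_seq`, `spec`.
#' @export
generate_toy_complex <- function(spec) {
  plan_default <- data.frame(cdr3_pos = integer(), pep_pos = integer(),
                             distance = numeric(), type = character(),
                             stringsAsFactors = FALSE)
  plan_user <- spec$contact_plan
  spec$contact_plan <- NULL
  sp <- utils::modifyList(list(
    peptide_length = 5, cdr3_length = 7, seed = 1, spacing = 12,
    standoff = 25), spec)
  sp$contact_plan <- if (is.null(plan_user)) plan_default else plan_user
  set.seed(sp$seed)
  plan <- sp$contact_plan
  pep_seq <- strsplit(sp$peptide_seq %||%
                        paste(rep("A", sp$peptide_length), collapse = ""),
                      "")[[1]]
  cdr3_seq <- strsplit(sp$cdr3_seq %||%
                         paste(rep("A", sp$cdr3_length), collapse = ""),
                       "")[[1]]
  if (nrow(plan)) for (i in seq_len(nrow(plan))) {
    ty <- plan$type[i]
    pick <- .PLAN_RESIDUES[[ty]]
    if (is.null(pick)) stop("unknown planned interaction type: ", ty)
    cdr3_seq[plan$cdr3_pos[i]] <-
      if (!is.null(plan$cdr3_res)) plan$cdr3_res[i] else pick[["cdr3"]]
    pep_seq[plan$pep_pos[i]] <-
      if (!is.null(plan$pep_res)) plan$pep_res[i] else pick[["pep"]]
  }
  pep_atoms <- build_toy_strand(paste(pep_seq, collapse = ""), "P",
                                y0 = 0, spacing = sp$spacing, face = +1)
  cdr3_atoms <- build_toy_strand(paste(cdr3_seq, collapse = ""), "C",
                                 y0 = sp$standoff, spacing = sp$spacing,
                                 face = -1)
  if (nrow(plan)) for (i in seq_len(nrow(plan))) {
    ci <- plan$cdr3_pos[i]; pi <- plan$pep_pos[i]
    sel <- cdr3_atoms$subpos == ci
    pa <- pep_atoms[pep_atoms$subpos == pi, c("x", "y", "z")]
    # align over the partner in x, then close the gap along the line of
    # minimum approach until the minimum distance equals the target
    cdr3_atoms$x[sel] <- cdr3_atoms$x[sel] +
      mean(pa$x) - mean(cdr3_atoms$x[sel])
    ca <- cdr3_atoms[sel, c("x", "y", "z")]
    dmat <- .pair_dist(as.matrix(ca), as.matrix(pa))
    amin <- which(dmat == min(dmat), arr.ind = TRUE)[1, ]
    p1 <- as.numeric(ca[amin[1], ]); p2 <- as.numeric(pa[amin[2], ])
    dir <- (p2 - p1) / sqrt(sum((p2 - p1)^2))
    shift <- (min(dmat) - plan$distance[i]) * dir
    cdr3_atoms$x[sel] <- cdr3_atoms$x[sel] + shift[1]
    cdr3_atoms$y[sel] <- cdr3_atoms$y[sel] + shift[2]
    cdr3_atoms$z[sel] <- cdr3_atoms$z[sel] + shift[3]
  }
  struct <- tcr_structure(rbind(pep_atoms, cdr3_atoms))
  expected <- .bruteforce_contacts(struct, "C", "P")
  # verify the plan was realized and nothing else came close
  if (nrow(plan)) for (i in seq_len(nrow(plan))) {
    hit <- expected[expected$cdr3_position == plan$cdr3_pos[i] &
                    expected$peptide_position == plan$pep_pos[i], ]
    if (nrow(hit) != 1 || abs(hit$min_distance - plan$distance[i]) > 0.2)
      stop("generation error: planned contact ", i, " not realized")
  }
  planned_keys <- if (nrow(plan)) paste(plan$cdr3_pos, plan$pep_pos) else
    character(0)
  extra <- expected[!paste(expected$cdr3_position,
                           expected$peptide_position) %in% planned_keys, ]
  if (nrow(extra))
    stop("generation error: unplanned contact under cutoff")
  core <- make_record(paste(cdr3_seq, collapse = ""), "beta",
                      epitope = paste(pep_seq, collapse = ""))
  tpl <- template_complex(struct, list(
    pdb_id = sprintf("toy%04d", sp$seed),
    chain_map = list(tcr_beta = "C", peptide = "P"),
    cdr3_beta_range = c(1L, length(cdr3_seq)),
    core_records = core))
  list(structure = struct, template = tpl, expected_contacts = expected,
       cdr3_seq = paste(cdr3_seq, collapse = ""),
       peptide_seq = paste(pep_seq, collapse = ""), spec = sp)
}

.pair_dist <- function(a, b) {
  sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2 +
         outer(a[, 3], b[, 3], "-")^2)
}

# Independent all-pairs contact scan with its own typing logic.
.bruteforce_contacts <- function(struct, cdr3_chain, pep_chain,
                                 cutoff = 5.0) {
  at <- struct$atoms
  rows <- list()
  for (ci in unique(at$subpos[at$chain == cdr3_chain])) {
    best <- NULL
    for (pi in unique(at$subpos[at$chain == pep_chain])) {
      A <- at[at$chain == cdr3_chain & at$subpos == ci, ]
      B <- at[at$chain == pep_chain & at$subpos == pi, ]
      dmat <- .pair_dist(as.matrix(A[, c("x", "y", "z")]),
                         as.matrix(B[, c("x", "y", "z")]))
      dmin <- min(dmat)
      if (dmin >= cutoff) next
      amin <- which(dmat == dmin, arr.ind = TRUE)[1, ]
      qa <- charged_group(A$resid, A$atom); qb <- charged_group(B$resid, B$atom)
      ionic <- FALSE; hbond <- FALSE
      for (x in seq_len(nrow(A))) for (y in seq_len(nrow(B))) {
        if (dmat[x, y] <= 4.0 && !A$backbone[x] && !B$backbone[y] &&
            ((qa[x] == "neg" && qb[y] == "pos") ||
             (qa[x] == "pos" && qb[y] == "neg"))) ionic <- TRUE
        if (dmat[x, y] <= 3.5 &&
            ((is_donor_atom(A$resid[x], A$atom[x]) &&
              is_acceptor_atom(B$resid[y], B$atom[y])) ||
             (is_acceptor_atom(A$resid[x], A$atom[x]) &&
              is_donor_atom(B$resid[y], B$atom[y])))) hbond <- TRUE
      }
      row <- data.frame(
        cdr3_position = ci, cdr3_residue = aa_one(A$resid[1]),
        peptide_position = pi, peptide_residue = aa_one(B$resid[1]),
        min_distance = dmin,
        cdr3_part = if (A$backbone[amin[1]]) "main_chain" else "side_chain",
        peptide_part = if (B$backbone[amin[2]]) "main_chain" else
          "side_chain",
        interaction_type = if (ionic) "IONIC" else if (hbond) "HBOND" else
          "VDW",
        stringsAsFactors = FALSE)
      rows[[length(rows) + 1]] <- row
      if (is.null(best) || dmin < best$d ||
          (dmin == best$d && pi < best$pi)) best <- list(d = dmin, pi = pi)
    }
    for (k in seq_along(rows))
      if (rows[[k]]$cdr3_position == ci)
        rows[[k]]$closest_flag <- !is.null(best) &&
          rows[[k]]$peptide_position == best$pi
  }
  if (!length(rows))
    return(data.frame(cdr3_position = integer(), cdr3_residue = character(),
                      peptide_position = integer(),
                      peptide_residue = character(),
                      min_distance = numeric(), cdr3_part = character(),
                      peptide_part = character(),
                      interaction_type = character(),
                      closest_flag = logical(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# ---------------------------------------------------------------------------
# Planted descriptor-energy tables
# ---------------------------------------------------------------------------

#' Generate a descriptor-energy table with planted effects
#'
#' Samples random contacting residue pairs, computes their 94 descriptor
#' features, and plants a target energy as a linear combination of the
#' named informative features plus a distance effect and Gaussian noise.
#' Optionally the peptide residue is sampled to mirror the CDR3 residue on
#' a chosen scale, planting cross-side descriptor correlations.
#'
#' @param spec List: `n`, `informative` (feature names, `cdr3.`/`p.`
#'   prefixes; bare scale names mean the CDR3 side), `effects`
#'   (coefficients, recycled), `noise_sd`, `intercept`, `distance_slope`,
#'   `mirror_scale`/`mirror_sd` (optional), `seed`.
#' @return List: `features` (data.frame incl. cdr3_res, pep_res,
#'   min_substitution_distance), `target`, `coefficients`, `spec`.
#' @export
generate_planted_energies <- function(spec) {
  sp <- utils::modifyList(list(
    n = 100, informative = character(0), effects = 1, noise_sd = 0.1,
    distance_slope = 0, intercept = 0, mirror_scale = NULL,
    mirror_sd = 0.5, seed = 1), spec)
  set.seed(sp$seed)
  tab <- aa_descriptor_table()
  cdr3_res <- sample(rownames(tab), sp$n, replace = TRUE)
  if (is.null(sp$mirror_scale)) {
    pep_res <- sample(rownames(tab), sp$n, replace = TRUE)
  } else {
    if (!sp$mirror_scale %in% colnames(tab))
      stop("spec error: unknown mirror scale ", sp$mirror_scale)
    sc <- tab[, sp$mirror_scale]
    pep_res <- vapply(cdr3_res, function(a) {
      w <- exp(-(sc - sc[a])^2 / (2 * sp$mirror_sd^2))
      sample(rownames(tab), 1, prob = w)
    }, "")
  }
  feats <- describe_pair_table(cdr3_res, pep_res)
  dist <- stats::runif(sp$n, 2.5, 10)
  informative <- sp$informative
  if (length(informative)) {
    bare <- !grepl("^(cdr3|p)\\.", informative)
    informative[bare] <- paste0("cdr3.", informative[bare])
    missing <- setdiff(informative, names(feats))
    if (length(missing))
      stop("spec error: unknown scale name(s): ",
           paste(missing, collapse = ", "))
  }
  coef <- rep_len(sp$effects, length(informative))
  names(coef) <- informative
  signal <- if (length(informative))
    as.matrix(feats[, informative, drop = FALSE]) %*% coef else
      numeric(sp$n)
  target <- sp$intercept + as.numeric(signal) + sp$distance_slope * dist +
    stats::rnorm(sp$n, sd = sp$noise_sd)
  feats$cdr3_res <- cdr3_res
  feats$pep_res <- pep_res
  feats$min_substitution_distance <- dist
  list(features = feats, target = target, coefficients = coef, spec = sp)
}
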