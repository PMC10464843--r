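# End-to-end orchestration: from records and templates to the tidy
# dEnergy table consumed by the statistical analyses.

#' Compute the dEnergy analysis table for a set of builds
#'
#' For every completed build and every requested preset, computes the
#' parent and child interface energies, their difference, the substituted
#' residue's minimum distance to the peptide, and the substitution's
#' contact status in the child model.
#'
#' @param builds List of `model_build` objects from [run_builds()].
#' @param templates Named list of `template_complex` objects.
#' @param presets Character vector of preset names.
#' @param arm Label for the optimization arm column.
#' @return data.frame: build_id, template, chain, position, from_aa,
#'   to_aa, preset, arm, value, min_substitution_distance, contact_status,
#'   group (non-redundancy key).
#' @export
build_denergy_table <- function(builds,
                                templates,
                                presets = c("full", "large_patch",
                                            "small_patch"),
                                arm = "minimized") {
  by_key <- list()
  for (b in builds)
    if (b$status == "ok")
      by_key[[paste(b$template, b$chain,
                    paste(b$prefix, collapse = ">"))]] <- b
  rows <- list()
  cache <- new.env()
  energy_of <- function(struct, tpl, chain, preset, key) {
    if (is.null(cache[[paste(key, preset)]]))
      cache[[paste(key, preset)]] <- interface_energy(
        struct, template_cdr3_range(tpl, chain),
        template_chain_id(tpl, chain), tpl$chain_map$peptide, preset)
    cache[[paste(key, preset)]]
  }
  for (b in builds) {
    if (b$status != "ok") next
    tpl <- templates[[b$template]]
    chain <- b$chain
    parent_prefix <- b$prefix[-length(b$prefix)]
    parent_key <- paste(b$template, chain,
                        paste(parent_prefix, collapse = ">"))
    parent_struct <- if (length(parent_prefix) == 1)
      tpl$structure else by_key[[parent_key]]$structure
    if (is.null(parent_struct)) next
    pairs <- find_contacts(b$structure, template_cdr3_range(tpl, chain),
                           template_chain_id(tpl, chain),
                           tpl$chain_map$peptide)
    status <- substitution_contact_status(b, pairs)
    grp <- paste(paste(template_chain_sequences(tpl), collapse = "|"),
                 b$child_cdr3, chain, sep = "||")
    for (ps in presets) {
      pe <- energy_of(parent_struct, tpl, chain, ps, parent_key)
      ce <- energy_of(b$structure, tpl, chain, ps,
                      paste(b$template, chain,
                            paste(b$prefix, collapse = ">")))
      de <- denergy(pe, ce, b$substitution)
      rows[[length(rows) + 1]] <- data.frame(
        build_id = b$build_id, template = b$template, chain = chain,
        parent_cdr3 = b$parent_cdr3, child_cdr3 = b$child_cdr3,
        position = b$substitution$position, from_aa = b$substitution$from,
        to_aa = b$substitution$to, preset = ps, arm = arm,
        value = de$value,
        min_substitution_distance = de$min_substitution_distance,
        contact_status = status, group = grp, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(build_id = character(), template = character(),
                      chain = character(), parent_cdr3 = character(),
                      child_cdr3 = character(), position = integer(),
                      from_aa = character(), to_aa = character(),
                      preset = character(), arm = character(),
                      value = numeric(),
                      min_substitution_distance = numeric(),
                      contact_status = character(), group = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Energetically valuable positions of a template chain
#'
#' @param template A `template_complex`.
#' @param chain `"alpha"` or `"beta"`.
#' @return Integer vector of CDR3 positions (union across the three
#'   presets).
#' @export
template_valuable_positions <- function(template, chain) {
  energies <- lapply(c("full", "large_patch", "small_patch"), function(ps)
    interface_energy(template$structure,
                     template_cdr3_range(template, chain),
                     template_chain_id(template, chain),
                     template$chain_map$peptide, ps))
  valuable_positions(energies)
}

#' Run the full synthetic study
#'
#' Generates toy template complexes with planted contacts, plants CDR3
#' clusters around their cores, enumerates pathways, builds models with
#' the surrogate backend under both optimization arms, and assembles the
#' dEnergy table plus the contact/valuable-position summaries.
#'
#' @param seed Master seed.
#' @param n_templates Number of toy templates (clusters).
#' @param members_per_cluster Planted members per cluster.
#' @param cdr3_length,peptide_length Toy sequence lengths.
#' @param arms Optimization arms to run.
#' @return List: `templates`, `records`, `clusters`, `pathways`, `orders`,
#'   `builds` (per arm), `denergy` (combined table), `contact_summary`,
#'   `valuable_rates`, `counters`.
#' @export
synthetic_study <- function(seed = 1, n_templates = 4,
                            members_per_cluster = 8, cdr3_length = 9,
                            peptide_length = 6,
                            arms = c("minimized", "repacked")) {
  set.seed(seed)
  plan_types <- c("IONIC", "HBOND", "VDW")
  toys <- lapply(seq_len(n_templates), function(i) {
    types <- sample(plan_types, 3, replace = TRUE)
    plan <- data.frame(
      cdr3_pos = sort(sample(2:(cdr3_length - 1), 3)),
      pep_pos = sort(sample(seq_len(peptide_length), 3)),
      distance = vapply(types, function(ty)
        switch(ty, IONIC = stats::runif(1, 2.8, 3.6),
               HBOND = stats::runif(1, 2.8, 3.3),
               VDW = stats::runif(1, 4.0, 4.8)), 0),
      type = types, stringsAsFactors = FALSE)
    generate_toy_complex(list(
      peptide_length = peptide_length, cdr3_length = cdr3_length,
      contact_plan = plan, seed = seed * 1000 + i))
  })
  templates <- setNames(lapply(toys, `[[`, "template"),
                        vapply(toys, function(t) t$template$pdb_id, ""))
  rep_spec <- list(
    n_clusters = n_templates, members_per_cluster = members_per_cluster,
    cores = vapply(toys, `[[`, "", "cdr3_seq"),
    epitopes = vapply(toys, `[[`, "", "peptide_seq"),
    chains = rep("beta", n_templates),
    seed = seed,
    decoys = c(wrong_v = 1, wrong_j = 1, wrong_length = 1,
               wrong_epitope = 1, too_distant = 1, disconnected = 0))
  rep <- generate_repertoire(rep_spec)
  clusters <- lapply(seq_len(n_templates), function(i)
    build_cluster(rep$manifest[[i]]$core, rep$records,
                  template = templates[[i]]))
  pathways <- unlist(lapply(clusters, enumerate_pathways),
                     recursive = FALSE)
  orders <- pathway_models(pathways)
  builds <- list(); de <- list()
  for (arm in arms) {
    builds[[arm]] <- run_builds(orders, templates,
                                optimization = if (arm == "repacked")
                                  "repacked" else "minimized")
    de[[arm]] <- build_denergy_table(builds[[arm]], templates, arm = arm)
  }
  denergy_tab <- do.call(rbind, de)
  rownames(denergy_tab) <- NULL
  # substitution contact/valuable summary on the minimized arm, full preset
  base <- denergy_tab[denergy_tab$arm == arms[1] &
                      denergy_tab$preset == "full", ]
  valuable <- lapply(templates, template_valuable_positions, chain = "beta")
  subs <- data.frame(
    valuable = mapply(function(tp, pos) pos %in% valuable[[tp]],
                      base$template, base$position),
    contacting = base$contact_status == "contacting",
    group = base$group, stringsAsFactors = FALSE)
  list(templates = templates, records = rep$records, manifest = rep$manifest,
       clusters = clusters, pathways = pathways, orders = orders,
       builds = builds, denergy = denergy_tab,
       valuable_positions = valuable,
       valuable_rates = valuable_substitution_rate(subs),
       counters = list(
         n_records = nrow(rep$records),
         n_members = sum(vapply(clusters, function(cl) nrow(cl$members), 0L)),
         n_pathways = attr(orders, "n_pathways"),
         n_build_orders = attr(orders, "n_build_orders"),
         n_final_models = attr(orders, "n_final_models"),
         n_groups = length(unique(base$group)),
         frac_contacting = mean(base$contact_status == "contacting"),
         frac_contacting_nonredundant =
           mean(tapply(base$contact_status == "contacting", base$group,
                       mean) > 0.5)))
}
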