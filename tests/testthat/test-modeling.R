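toy_with_contacts <- function(seed = 2) {
  generate_toy_complex(list(
    peptide_length = 5, cdr3_length = 7, seed = seed,
    contact_plan = data.frame(cdr3_pos = c(2, 4), pep_pos = c(2, 4),
                              distance = c(3.0, 3.2),
                              type = c("IONIC", "HBOND"))))
}

test_that("surrogate mutation keeps the backbone and rebuilds side chains", {
  toy <- toy_with_contacts()
  s <- toy$structure
  mut <- surrogate_mutate(s, "C", 2, "E")     # Asp -> Glu at the contact
  bb <- function(x) {
    a <- x$atoms[x$atoms$chain == "C" & x$atoms$backbone, ]
    a <- a[order(a$subpos, a$atom), c("x", "y", "z")]
    rownames(a) <- NULL
    a
  }
  expect_identical(bb(s), bb(mut))
  # Asp -> Glu adds exactly one side-chain heavy atom
  n_atoms <- function(x, pos) sum(x$atoms$chain == "C" &
                                  x$atoms$subpos == pos)
  expect_equal(n_atoms(mut, 2), n_atoms(s, 2) + 1L)
  # CB is carried over bitwise
  cb <- function(x) unlist(x$atoms[x$atoms$chain == "C" &
                                   x$atoms$subpos == 2 &
                                   x$atoms$atom == "CB", c("x", "y", "z")])
  expect_identical(cb(s), cb(mut))

  # any residue -> Gly drops all side-chain atoms
  g <- surrogate_mutate(s, "C", 2, "G")
  expect_setequal(g$atoms$atom[g$atoms$chain == "C" & g$atoms$subpos == 2],
                  c("N", "CA", "C", "O"))

  # Gly -> Ala places CB at a chemically sane bond length
  a <- surrogate_mutate(g, "C", 2, "A")
  xyz <- residue_xyz(a, "C", 2)
  d <- sqrt(sum((xyz["CB", ] - xyz["CA", ])^2))
  expect_gt(d, 1.5)
  expect_lt(d, 1.6)

  # identity substitution returns the parent unchanged
  expect_identical(surrogate_mutate(s, "C", 2, "D"), s)

  # missing backbone atom -> structural error
  broken <- s
  broken$atoms <- broken$atoms[!(broken$atoms$chain == "C" &
                                 broken$atoms$subpos == 3 &
                                 broken$atoms$atom == "O"), ]
  expect_error(surrogate_mutate(broken, "C", 3, "W"), "structural error")
})

test_that("builds run in prefix order, deterministically, skipping failed branches", {
  toy <- toy_with_contacts(4)
  templates <- setNames(list(toy$template), toy$template$pdb_id)
  core <- toy$cdr3_seq
  m1 <- paste0(substr(core, 1, 1), "W", substr(core, 3, nchar(core)))
  m2 <- paste0(substr(m1, 1, 4), "F", substr(m1, 6, nchar(m1)))
  recs <- records_from(c(m1, m2))
  cl <- build_cluster(make_record(core, "beta"), recs,
                      template = templates[[1]])
  orders <- pathway_models(enumerate_pathways(cl))
  expect_equal(nrow(orders), 2L)

  b1 <- run_builds(orders, templates)
  b2 <- run_builds(orders, templates)
  expect_true(all(vapply(b1, function(b) b$status, "") == "ok"))
  expect_identical(lapply(b1, function(b) b$structure$atoms),
                   lapply(b2, function(b) b$structure$atoms))
  # 2-step pathway: child of step 2 differs from the template by 2 residues
  final <- b1[[which(vapply(b1, function(b) b$child_cdr3, "") == m2)]]
  expect_equal(hamming(chain_sequence(final$structure, "C"), core), 2L)

  # a failing first step marks its descendants skipped
  bad <- orders
  bad$position[bad$step_index == 1] <- 99L
  res <- run_builds(bad, templates)
  expect_equal(vapply(res, function(b) b$status, ""),
               c("failed", "skipped"))
  expect_error(run_builds(bad, templates, fail_fast = TRUE))
})

test_that("non-redundant grouping keys on chain sequences and final CDR3", {
  toy1 <- toy_with_contacts(6)
  # a second template with the same chains under a different pdb id
  toy2 <- toy1
  toy2$template$pdb_id <- "toy9999"
  templates <- list(toy1$template, toy2$template)
  names(templates) <- c(toy1$template$pdb_id, "toy9999")
  core <- toy1$cdr3_seq
  m1 <- paste0(substr(core, 1, 1), "W", substr(core, 3, nchar(core)))
  recs <- records_from(m1)
  orders <- do.call(rbind, lapply(names(templates), function(tp) {
    cl <- build_cluster(make_record(core, "beta"), recs,
                        template = templates[[tp]])
    pathway_models(enumerate_pathways(cl))
  }))
  orders$build_id <- sprintf("b%02d", seq_len(nrow(orders)))
  builds <- run_builds(orders, templates)
  groups <- group_nonredundant(builds, templates)
  expect_length(builds, 2L)
  expect_length(groups, 1L)     # same chains + same final CDR3 -> one group

  # different final CDR3 -> separate groups
  m2 <- paste0(substr(core, 1, 2), "F", substr(core, 4, nchar(core)))
  cl2 <- build_cluster(make_record(core, "beta"),
                       records_from(c(m1, m2)),
                       template = toy1$template)
  orders2 <- pathway_models(enumerate_pathways(cl2))
  builds2 <- run_builds(orders2, setNames(list(toy1$template),
                                          toy1$template$pdb_id))
  expect_length(group_nonredundant(builds2,
                                   setNames(list(toy1$template),
                                            toy1$template$pdb_id)), 2L)
})

test_that("repacking moves only side chains and never raises the energy", {
  toy <- toy_with_contacts(8)
  templates <- setNames(list(toy$template), toy$template$pdb_id)
  core <- toy$cdr3_seq
  # substitute at the ionic contact position to provoke a clash
  m1 <- paste0(substr(core, 1, 1), "W", substr(core, 3, nchar(core)))
  cl <- build_cluster(make_record(core, "beta"), records_from(m1),
                      template = templates[[1]])
  orders <- pathway_models(enumerate_pathways(cl))
  bmin <- run_builds(orders, templates, optimization = "minimized")[[1]]
  brep <- run_builds(orders, templates, optimization = "repacked")[[1]]
  bb <- function(x) x$atoms[x$atoms$backbone,
                            c("chain", "subpos", "atom", "x", "y", "z")]
  expect_equal(bb(bmin$structure), bb(brep$structure))
  e <- function(b) interface_energy(b$structure, c(1, nchar(core)), "C",
                                    "P", "full")$total
  expect_lte(e(brep), e(bmin) + 1e-9)
})
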