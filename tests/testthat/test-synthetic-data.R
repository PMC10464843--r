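test_that("repertoire generation is seed-reproducible with rule-true decoys", {
  spec <- list(n_clusters = 2, members_per_cluster = 4, seed = 17,
               decoys = c(wrong_v = 1, wrong_j = 1, wrong_length = 1,
                          wrong_epitope = 1, too_distant = 1,
                          disconnected = 1))
  r1 <- generate_repertoire(spec)
  r2 <- generate_repertoire(spec)
  expect_identical(r1$records, r2$records)
  expect_identical(r1$manifest, r2$manifest)

  for (ci in 1:2) {
    man <- r1$manifest[[ci]]
    core <- man$core
    recs <- r1$records
    dec <- recs[grepl(sprintf("^c%d:decoy", ci), recs$record_id), ]
    with_tag <- function(tag) dec[grepl(tag, dec$record_id), ]
    expect_false(with_tag("decoy:v")$v_gene == core$v_gene)
    expect_false(with_tag("decoy:j")$j_gene == core$j_gene)
    expect_false(nchar(with_tag("decoy:len")$cdr3) == nchar(core$cdr3))
    expect_false(with_tag("decoy:epi")$epitope == core$epitope)
    expect_gt(hamming(with_tag("decoy:far")$cdr3, core$cdr3), 3)
    disc <- with_tag("decoy:disc")
    near <- vapply(c(core$cdr3, man$members),
                   function(s) hamming(disc$cdr3, s), 0L)
    expect_true(all(near >= 2))
    # decoys never appear in the manifest
    expect_false(any(dec$cdr3 %in% man$members))
    # manifest pathways are monotone chains over members
    for (p in man$pathways) {
      expect_true(all(p[-1] %in% man$members))
      expect_equal(vapply(p, function(s) hamming(core$cdr3, s), 0L),
                   seq_along(p) - 1L, ignore_attr = TRUE)
    }
  }

  # zero members -> core-only manifest
  r0 <- generate_repertoire(list(n_clusters = 1, members_per_cluster = 0,
                                 seed = 2))
  expect_length(r0$manifest[[1]]$members, 0L)
  expect_length(r0$manifest[[1]]$pathways, 0L)
  expect_error(generate_repertoire(list(max_distance = 4)), "spec error")
})

test_that("toy complexes realize their contact plans and nothing else", {
  for (seed in c(41, 42, 43)) {
    spec <- random_toy_spec(seed)
    # keep one planned contact per CDR3 position (the geometric placement
    # translates whole residues)
    spec$contact_plan <-
      spec$contact_plan[!duplicated(spec$contact_plan$cdr3_pos), ,
                        drop = FALSE]
    toy <- generate_toy_complex(spec)
    exp <- toy$expected_contacts
    expect_equal(nrow(exp), nrow(spec$contact_plan))
    if (nrow(exp))
      expect_true(all(abs(exp$min_distance -
                          spec$contact_plan$distance[
                            match(paste(exp$cdr3_position,
                                        exp$peptide_position),
                                  paste(spec$contact_plan$cdr3_pos,
                                        spec$contact_plan$pep_pos))])
                      <= 0.2))
  }
  # seed reproducibility is byte-identical
  t1 <- generate_toy_complex(list(peptide_length = 4, cdr3_length = 6,
                                  seed = 77))
  t2 <- generate_toy_complex(list(peptide_length = 4, cdr3_length = 6,
                                  seed = 77))
  expect_identical(t1$structure$atoms, t2$structure$atoms)

  # charged pair planned within the ionic threshold types as IONIC
  ionic <- generate_toy_complex(list(
    peptide_length = 4, cdr3_length = 5, seed = 9,
    contact_plan = data.frame(cdr3_pos = 2, pep_pos = 2, distance = 2.9,
                              type = "IONIC")))
  expect_equal(ionic$expected_contacts$interaction_type, "IONIC")

  # geometrically unrealizable plans fail loudly
  expect_error(generate_toy_complex(list(
    peptide_length = 4, cdr3_length = 5, seed = 10,
    contact_plan = data.frame(cdr3_pos = 2, pep_pos = 2, distance = 7,
                              type = "VDW"))), "generation error")
})

test_that("planted energy tables honor their specs", {
  # noiseless single-feature plant: the target IS the feature
  pl <- generate_planted_energies(list(n = 150, informative = "cdr3.Z1",
                                       effects = 2, noise_sd = 0,
                                       seed = 31))
  expect_equal(cor(pl$target, pl$features$cdr3.Z1), 1)
  # zero effects -> pure noise, no feature explains it well
  pn <- generate_planted_energies(list(n = 500, effects = 0, noise_sd = 1,
                                       seed = 32))
  cors <- vapply(grep("^(cdr3|p)\\.", names(pn$features), value = TRUE),
                 function(cn) abs(cor(pn$target, pn$features[[cn]])), 0)
  expect_lt(max(cors), 0.2)
  # reproducible and strict about unknown scales
  pl2 <- generate_planted_energies(list(n = 150, informative = "cdr3.Z1",
                                        effects = 2, noise_sd = 0,
                                        seed = 31))
  expect_identical(pl$target, pl2$target)
  expect_error(generate_planted_energies(list(informative = "cdr3.NOPE")),
               "spec error")
})
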