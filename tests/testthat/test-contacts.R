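test_that("contact detection matches distances, parts and typing rules", {
  # hydrogen-bond geometry between Asp and Arg side chains, like the
  # CDR3a Asp-7 / peptide Arg-5 pair of the SARS-CoV-2 templates
  toy <- generate_toy_complex(list(
    peptide_length = 5, cdr3_length = 7, seed = 21,
    contact_plan = data.frame(cdr3_pos = 7, pep_pos = 5, distance = 3.4,
                              type = "IONIC", cdr3_res = "D",
                              pep_res = "R")))
  pairs <- find_contacts(toy$structure, c(1, 7), "C", "P")
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$cdr3_residue, "D")
  expect_equal(pairs$peptide_residue, "R")
  expect_equal(pairs$cdr3_part, "side_chain")
  expect_equal(pairs$peptide_part, "side_chain")
  # oppositely charged groups within 4 A take IONIC precedence over HBOND
  expect_equal(pairs$interaction_type, "IONIC")

  # the same pair pushed beyond the ionic threshold becomes an H-bond
  toy2 <- generate_toy_complex(list(
    peptide_length = 5, cdr3_length = 7, seed = 22,
    contact_plan = data.frame(cdr3_pos = 7, pep_pos = 5, distance = 3.0,
                              type = "HBOND", cdr3_res = "S",
                              pep_res = "S")))
  p2 <- find_contacts(toy2$structure, c(1, 7), "C", "P")
  expect_equal(p2$interaction_type, "HBOND")

  # residues beyond the cutoff yield no pair
  far <- generate_toy_complex(list(peptide_length = 4, cdr3_length = 5,
                                   seed = 23))
  expect_equal(nrow(find_contacts(far$structure, c(1, 5), "C", "P")), 0L)

  expect_error(find_contacts(far$structure, NULL, "C", "P"), "input error")
})

test_that("one CDR3 residue contacting two peptide residues gets one closest flag", {
  # hand-built: one CDR3 alanine 4.0 and 4.5 A from two peptide alanines
  atoms <- rbind(
    stub_residue("P", 1, "ALA", c(0, 0, 0)),
    stub_residue("P", 2, "ALA", c(8, 0, 0)),
    stub_residue("P", 3, "ALA", c(40, 0, 0)),
    stub_residue("C", 1, "ALA", c(4.2, 4.6, 0)))
  s <- tcr_structure(atoms)
  pairs <- find_contacts(s, c(1, 1), "C", "P")
  expect_equal(nrow(pairs), 2L)
  expect_equal(sum(pairs$closest_flag), 1L)
  expect_equal(pairs$peptide_position[pairs$closest_flag],
               pairs$peptide_position[which.min(pairs$min_distance)])
})

test_that("contact groups follow the four-group taxonomy with containment", {
  mixed <- data.frame(
    cdr3_position = c(1, 1, 2, 3, 4),
    cdr3_residue = c("D", "D", "S", "L", "A"),
    peptide_position = c(1, 2, 2, 3, 4),
    peptide_residue = c("R", "T", "S", "A", "A"),
    min_distance = c(3.0, 4.2, 3.1, 4.8, 4.9),
    cdr3_part = c("side_chain", "main_chain", "side_chain", "main_chain",
                  "main_chain"),
    peptide_part = c("side_chain", "side_chain", "side_chain",
                     "main_chain", "main_chain"),
    interaction_type = c("IONIC", "VDW", "HBOND", "VDW", "VDW"),
    closest_flag = c(TRUE, FALSE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  g <- contact_groups(mixed)
  expect_equal(nrow(g$group1), 5L)
  expect_equal(nrow(g$group2), 4L)   # one closest per CDR3 residue
  expect_equal(nrow(g$group3), 3L)   # at least one side-chain part
  expect_equal(nrow(g$group4), 2L)   # closest AND side-chain
  # containment
  key <- function(x) paste(x$cdr3_position, x$peptide_position)
  expect_true(all(key(g$group2) %in% key(g$group1)))
  expect_true(all(key(g$group3) %in% key(g$group1)))
  expect_true(all(key(g$group4) %in% intersect(key(g$group2),
                                               key(g$group3))))
  # all-main-chain input empties groups 3 and 4
  mc <- mixed
  mc$cdr3_part <- mc$peptide_part <- "main_chain"
  gm <- contact_groups(mc)
  expect_equal(nrow(gm$group3), 0L)
  expect_equal(nrow(gm$group4), 0L)
  # empty input -> four empty groups
  ge <- contact_groups(mixed[0, ])
  expect_true(all(vapply(ge, nrow, 0L) == 0L))
})

test_that("substitution contact status and pair-type counting agree with hand tallies", {
  pairs <- data.frame(cdr3_position = c(2, 5), cdr3_residue = c("D", "L"),
                      peptide_position = c(1, 2),
                      peptide_residue = c("R", "A"),
                      min_distance = c(3, 4),
                      cdr3_part = "side_chain", peptide_part = "side_chain",
                      interaction_type = c("IONIC", "VDW"),
                      closest_flag = TRUE, stringsAsFactors = FALSE)
  b <- list(substitution = list(position = 2, from = "N", to = "D"))
  expect_equal(substitution_contact_status(b, pairs), "contacting")
  b2 <- list(substitution = list(position = 3, from = "N", to = "D"))
  expect_equal(substitution_contact_status(b2, pairs), "non_contacting")

  counts <- count_contact_pair_types(list(pairs), list(pairs[1, ]))
  expect_equal(counts$group1$modeled["D", "R"], 1L)
  expect_equal(counts$group1$modeled["L", "A"], 1L)
  expect_equal(counts$group1$original["D", "R"], 1L)
  expect_equal(counts$group1$novel$cdr3_residue, "L")
  # identical modeled and original sets -> nothing novel
  same <- count_contact_pair_types(list(pairs), list(pairs))
  expect_equal(nrow(same$group1$novel), 0L)
})
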