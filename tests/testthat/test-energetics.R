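toy_ionic <- function(seed = 2, d = 3.0) {
  generate_toy_complex(list(
    peptide_length = 5, cdr3_length = 7, seed = seed,
    contact_plan = data.frame(cdr3_pos = c(2, 4), pep_pos = c(2, 4),
                              distance = c(d, 3.2),
                              type = c("IONIC", "HBOND"))))
}

test_that("per-residue decomposition conserves the total and presets nest", {
  toy <- toy_ionic()
  for (ps in c("full", "large_patch", "small_patch")) {
    e <- interface_energy(toy$structure, c(1, 7), "C", "P", ps)
    expect_lt(abs(e$total - sum(e$per_residue)), 1e-9)
  }
  el <- interface_energy(toy$structure, c(1, 7), "C", "P", "large_patch")
  es <- interface_energy(toy$structure, c(1, 7), "C", "P", "small_patch")
  expect_lt(abs(es$total -
                (el$total - el$terms[["hbond_sr_bb"]] -
                 el$terms[["hbond_bb_sc"]])), 1e-12)
  expect_error(interface_energy(toy$structure, c(1, 7), "C", "P",
                                "tiny_patch"), "preset")
})

test_that("term ranges and chemistry behave physically", {
  # everything beyond 8 A contributes nothing
  far <- generate_toy_complex(list(peptide_length = 4, cdr3_length = 5,
                                   seed = 31))
  e0 <- interface_energy(far$structure, c(1, 5), "C", "P", "small_patch")
  expect_equal(e0$total, 0)

  # a salt bridge scores lower (more favorable) than the same pose with
  # the charged partner replaced by alanine
  salt <- generate_toy_complex(list(
    peptide_length = 5, cdr3_length = 7, seed = 32,
    contact_plan = data.frame(cdr3_pos = 2, pep_pos = 2, distance = 3.0,
                              type = "IONIC")))
  ala <- generate_toy_complex(list(
    peptide_length = 5, cdr3_length = 7, seed = 32,
    contact_plan = data.frame(cdr3_pos = 2, pep_pos = 2, distance = 3.0,
                              type = "IONIC", cdr3_res = "D",
                              pep_res = "A")))
  es <- interface_energy(salt$structure, c(1, 7), "C", "P", "large_patch")
  ea <- interface_energy(ala$structure, c(1, 7), "C", "P", "large_patch")
  expect_lt(es$total, 0)
  expect_lt(es$total, ea$total)
  expect_gt(abs(es$total), abs(ea$total))
})

test_that("dEnergy differencing is exact, antisymmetric and local", {
  toy <- toy_ionic(33)
  s <- toy$structure
  e_parent <- interface_energy(s, c(1, 7), "C", "P", "full")

  # identity substitution -> zero
  de0 <- denergy(e_parent, e_parent, list(position = 2, from = "D",
                                          to = "D"))
  expect_equal(de0$value, 0)

  # antisymmetry between the two directions of the same conformer pair
  mut <- surrogate_mutate(s, "C", 2, "E")
  e_child <- interface_energy(mut, c(1, 7), "C", "P", "full")
  d1 <- denergy(e_parent, e_child, list(position = 2, from = "D",
                                        to = "E"))
  d2 <- denergy(e_child, e_parent, list(position = 2, from = "E",
                                        to = "D"))
  expect_equal(d1$value, -d2$value)
  expect_true(is.finite(d1$min_substitution_distance))

  # preset mismatch is rejected
  e_small <- interface_energy(mut, c(1, 7), "C", "P", "small_patch")
  expect_error(denergy(e_parent, e_small, list(position = 2, from = "D",
                                               to = "E")), "preset")

  # substitutions farther than 10 A from the peptide leave the energy
  # untouched (all terms are finite-ranged)
  mut_far <- surrogate_mutate(s, "C", 6, "W")
  e_far <- interface_energy(mut_far, c(1, 7), "C", "P", "full")
  expect_lt(abs(e_far$total - e_parent$total), 1e-9)
})

test_that("valuable positions take the per-preset minima, unioned on disagreement", {
  fake <- function(pr) structure(list(per_residue = pr,
                                      preset = "x"),
                                 class = "interface_energy")
  agree <- list(fake(c("5" = -1, "6" = -3, "7" = -2)),
                fake(c("5" = -1, "6" = -4, "7" = -2)),
                fake(c("5" = 0, "6" = -1, "7" = 0)))
  expect_equal(valuable_positions(agree), 6L)
  split_vote <- list(fake(c("5" = -1, "6" = -3, "7" = -2)),
                     fake(c("5" = -1, "6" = -4, "7" = -2)),
                     fake(c("5" = 0, "6" = -1, "7" = -2)))
  expect_equal(valuable_positions(split_vote), c(6L, 7L))
  flat <- list(fake(c("1" = 0, "2" = 0, "3" = 0)))
  expect_equal(valuable_positions(flat), 1:3)
})

test_that("valuable-substitution rates match hand tallies", {
  none <- data.frame(valuable = rep(FALSE, 4),
                     contacting = c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(valuable_substitution_rate(none)$redundant,
               c(all = 0, contacting = 0))
  subs <- data.frame(
    valuable = c(TRUE, TRUE, rep(FALSE, 8)),
    contacting = c(TRUE, FALSE, TRUE, rep(FALSE, 7)))
  r <- valuable_substitution_rate(subs)$redundant
  expect_equal(r[["all"]], 0.2)
  expect_equal(r[["contacting"]], 0.5)
})

test_that("precomputed energy tables round trip through the TSV dialect", {
  tab <- data.frame(model_id = "m1", preset = "full",
                    total = -2.5, position = 1:5,
                    per_residue = c(-1, -0.5, -0.5, -0.25, -0.25))
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  e <- read_energy_table(f)
  expect_equal(e$m1$full$total, -2.5)
  expect_equal(sum(e$m1$full$per_residue), e$m1$full$total)
})
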