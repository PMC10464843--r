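make_de <- function(value, from_aa = "D", to_aa = "E", chain = "beta",
                    preset = "full", arm = "minimized",
                    contact_status = "contacting", dist = NULL) {
  data.frame(from_aa = from_aa, to_aa = to_aa, preset = preset, arm = arm,
             chain = chain, value = value, contact_status = contact_status,
             min_substitution_distance = if (is.null(dist))
               seq_along(value) else dist,
             stringsAsFactors = FALSE)
}

test_that("correlation machinery matches the textbook formulas", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.0)
  y <- c(2.0, 3.9, 2.5, 6.2, 4.1)
  row <- tcrpmhc:::.cor_row(x, y, "pearson", x = "a", y = "b")
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(row$r, r_hand, tolerance = 1e-12)
  t_hand <- r_hand * sqrt(3 / (1 - r_hand^2))
  expect_equal(row$p_value, 2 * pt(-abs(t_hand), df = 3),
               tolerance = 1e-12)

  srow <- tcrpmhc:::.cor_row(x, y, "spearman", x = "a", y = "b")
  rx <- rank(x); ry <- rank(y)
  rho_hand <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(srow$r, rho_hand, tolerance = 1e-12)
  # rank correlation is invariant under strictly monotone transforms
  srow2 <- tcrpmhc:::.cor_row(exp(3 * x), y^3, "spearman",
                              x = "a", y = "b")
  expect_equal(srow2$r, srow$r)
})

test_that("index-energy correlations recover a planted linear effect", {
  set.seed(11)
  aa <- aa_alphabet()
  from <- sample(aa, 200, replace = TRUE)
  shift <- sample(1:19, 200, replace = TRUE)
  to <- aa[(match(from, aa) + shift - 1) %% 20 + 1]
  idx <- adjusted_blosum(from, to)
  value <- -0.5 * idx + rnorm(200, sd = 0.05)   # |dE| large for dissimilar
  de <- make_de(value, from_aa = from, to_aa = to)
  res <- blosum_energy_correlations(de)
  cell <- res[res$x == "BLA.62.v2" & res$subset == "all_mutations" &
              res$stratum == "all", ]
  expect_lt(cell$r, -0.9)
  expect_lt(cell$p_value, 1e-10)
  expect_true(all(res$adjusted_p >= res$p_value, na.rm = TRUE))

  # y identical to x gives perfect correlation
  de2 <- make_de(abs(idx))
  de2$from_aa <- from; de2$to_aa <- to
  res2 <- blosum_energy_correlations(de2)
  expect_equal(max(abs(res2$r), na.rm = TRUE), 1, tolerance = 1e-12)

  # constant response is flagged not computable
  res3 <- blosum_energy_correlations(make_de(rep(1, 10),
                                             from_aa = sample(aa, 10),
                                             to_aa = sample(aa, 10)))
  expect_false(any(res3$computable))
})

test_that("stratified sample sizes sum to the pooled size", {
  set.seed(5)
  de <- make_de(rnorm(40), from_aa = sample(aa_alphabet(), 40, TRUE),
                to_aa = sample(aa_alphabet(), 40, TRUE),
                chain = sample(c("alpha", "beta"), 40, TRUE))
  res <- distance_energy_correlations(de)
  pooled <- res$n[res$stratum == "all"]
  expect_equal(res$n[res$stratum == "alpha"] + res$n[res$stratum == "beta"],
               pooled)
})

test_that("distance correlations recover a planted remoteness effect", {
  pl <- generate_planted_energies(list(n = 200, intercept = 10,
                                       distance_slope = -0.8,
                                       noise_sd = 0.3, seed = 12))
  de <- make_de(pl$target, dist = pl$features$min_substitution_distance)
  res <- distance_energy_correlations(de)
  cell <- res[res$stratum == "all", ]
  expect_lt(cell$r, -0.5)
  # degenerate: constant distances are not computable
  de2 <- de
  de2$min_substitution_distance <- 4
  expect_false(any(distance_energy_correlations(de2)$computable))
})

test_that("multiplicity adjustment follows Bonferroni and BH by construction", {
  set.seed(9)
  de <- make_de(rnorm(30), from_aa = sample(aa_alphabet(), 30, TRUE),
                to_aa = sample(aa_alphabet(), 30, TRUE))
  bon <- distance_energy_correlations(de, adjust = "bonferroni")
  m <- attr(bon, "m")
  ok <- bon$computable
  expect_equal(bon$adjusted_p[ok], pmin(1, m * bon$p_value[ok]))
  bh <- distance_energy_correlations(de, adjust = "BH")
  o <- order(bh$p_value[bh$computable])
  expect_true(all(diff(bh$adjusted_p[bh$computable][o]) >= -1e-12))
})

test_that("descriptor-pair analysis flags the planted hydrophobicity signal", {
  pl <- generate_planted_energies(list(n = 300, mirror_scale = "VHSE1",
                                       mirror_sd = 0.3, seed = 13))
  dp <- descriptor_pair_correlations(pl$features)
  gt <- dp$group_tests
  hyd <- gt$median_abs_r[gt$group == "hydrophobicity"]
  expect_gt(hyd, max(gt$median_abs_r[gt$group %in%
                                     c("electronic",
                                       "secondary_structure")]))
  # the planted scale pair tops the positive list
  expect_true("p.VHSE1" %in%
              dp$top_positive$y[dp$top_positive$x == "cdr3.VHSE1"])
  expect_equal(dp$m, sum(dp$results$computable))

  # a single observation makes every pair not computable
  dp1 <- descriptor_pair_correlations(pl$features[1, , drop = FALSE])
  expect_false(any(dp1$results$computable))
})
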