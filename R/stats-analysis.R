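# Correlation analyses linking substitution energetics to substitution
# scores, substitution remoteness and descriptor scales.
#
# All energy-side inputs arrive as a tidy "dEnergy table": one row per
# (build x preset x optimization arm) with the substitution, |dEnergy|,
# the substituted residue's minimum distance to the peptide and its
# contact status. Substitution scores are compared against the absolute
# value of dEnergy: substitution matrices score similarity without a
# direction, so the magnitude of the energy change is the comparable
# quantity; signed dEnergy is available behind the `signed` flag for
# exploration.

.cor_row <- function(.xv, .yv, .cor_method, ...) {
  keep <- is.finite(.xv) & is.finite(.yv)
  xv <- .xv[keep]; yv <- .yv[keep]
  meta <- data.frame(..., stringsAsFactors = FALSE)
  if (length(xv) < 3 || stats::sd(xv) == 0 || stats::sd(yv) == 0)
    return(cbind(meta, data.frame(method = .cor_method, r = NA_real_,
                                  p_value = NA_real_, n = length(xv),
                                  computable = FALSE)))
  ct <- suppressWarnings(stats::cor.test(xv, yv, method = .cor_method,
                                         exact = FALSE))
  cbind(meta, data.frame(method = .cor_method, r = unname(ct$estimate),
                         p_value = ct$p.value, n = length(xv),
                         computable = TRUE))
}

.adjust_p <- function(results, method) {
  results$adjusted_p <- NA_real_
  ok <- results$computable
  results$adjusted_p[ok] <- stats::p.adjust(results$p_value[ok],
                                            method = method)
  attr(results, "adjust_method") <- method
  attr(results, "m") <- sum(ok)
  results
}

#' Correlate adjusted substitution indices with |dEnergy|
#'
#' Pearson correlation between the adjusted substitution index (six
#' variants: BLA/SIJ/QIJ x BLOSUM62/BLOSUM100) and |dEnergy|, for every
#' preset x optimization arm cell, for the all-mutations and
#' contacting-mutations subsets, pooled and per chain.
#'
#' @param de dEnergy table with columns from_aa, to_aa, preset, arm,
#'   chain, value, contact_status.
#' @param adjust Multiplicity adjustment over all computed cells
#'   ("bonferroni" default, or "BH").
#' @param signed Correlate signed dEnergy instead of |dEnergy|.
#' @return data.frame of correlation results (x, y, preset, arm, subset,
#'   stratum, method, r, p_value, n, adjusted_p).
#' @export
blosum_energy_correlations <- function(de, adjust = c("bonferroni", "BH"),
                                       signed = FALSE) {
  adjust <- match.arg(adjust)
  idx <- adjusted_blosum_indices(de$from_aa, de$to_aa)
  y_all <- if (signed) de$value else abs(de$value)
  index_cols <- setdiff(names(idx), c("from", "to"))
  out <- list()
  for (col in index_cols)
    for (ps in unique(de$preset))
      for (arm in unique(de$arm))
        for (subset in c("all_mutations", "contacting_mutations"))
          for (stratum in c("all", "alpha", "beta")) {
            sel <- de$preset == ps & de$arm == arm
            if (subset == "contacting_mutations")
              sel <- sel & de$contact_status == "contacting"
            if (stratum != "all") sel <- sel & de$chain == stratum
            out[[length(out) + 1]] <- .cor_row(
              idx[[col]][sel], y_all[sel], "pearson",
              x = col, y = if (signed) "dEnergy" else "abs_dEnergy",
              preset = ps, arm = arm, subset = subset, stratum = stratum)
          }
  .adjust_p(do.call(rbind, out), adjust)
}

#' Correlate substitution remoteness with |dEnergy|
#'
#' Pearson correlation between the substituted residue's minimum distance
#' to the peptide and |dEnergy|, per preset x arm, pooled and per chain.
#'
#' @param de dEnergy table (columns min_substitution_distance, value,
#'   preset, arm, chain).
#' @inheritParams blosum_energy_correlations
#' @return data.frame of correlation results.
#' @export
distance_energy_correlations <- function(de, adjust = c("bonferroni", "BH")) {
  adjust <- match.arg(adjust)
  out <- list()
  for (ps in unique(de$preset))
    for (arm in unique(de$arm))
      for (stratum in c("all", "alpha", "beta")) {
        sel <- de$preset == ps & de$arm == arm
        if (stratum != "all") sel <- sel & de$chain == stratum
        out[[length(out) + 1]] <- .cor_row(
          de$min_substitution_distance[sel], abs(de$value[sel]), "pearson",
          x = "min_substitution_distance", y = "abs_dEnergy",
          preset = ps, arm = arm, subset = "all_mutations",
          stratum = stratum)
      }
  .adjust_p(do.call(rbind, out), adjust)
}

#' Descriptor-pair rank correlations within property groups
#'
#' Spearman correlations between CDR3-side and peptide-side descriptor
#' scales, computed within each property group over contacting residue
#' pairs; each group's correlation-coefficient distribution is tested for
#' normality with Shapiro-Wilk, and the strongest positive/negative pairs
#' are reported.
#'
#' @param features data.frame with the 94 `cdr3.*`/`p.*` descriptor
#'   columns, one row per contact pair (restricted upstream to the
#'   desired contact group, e.g. closest side-chain contacts at mutated
#'   positions).
#' @param groups Group membership lists (default [descriptor_groups()]).
#' @param adjust Multiplicity adjustment over all tested pairs.
#' @param top Number of top positive/negative pairs to report.
#' @return List: `results` (per-pair correlation data.frame),
#'   `group_tests` (per-group Shapiro-Wilk on the r distribution),
#'   `top_positive`/`top_negative`, `m` (number of tests adjusted over).
#' @export
descriptor_pair_correlations <- function(features,
                                         groups = descriptor_groups(),
                                         adjust = c("bonferroni", "BH"),
                                         top = 10) {
  adjust <- match.arg(adjust)
  out <- list()
  for (g in names(groups)) {
    scales <- groups[[g]]
    for (sx in scales) for (sy in scales) {
      cx <- paste0("cdr3.", sx); cy <- paste0("p.", sy)
      if (!cx %in% names(features) || !cy %in% names(features)) next
      out[[length(out) + 1]] <- .cor_row(
        features[[cx]], features[[cy]], "spearman",
        x = cx, y = cy, group = g)
    }
  }
  results <- .adjust_p(do.call(rbind, out), adjust)
  group_tests <- do.call(rbind, lapply(names(groups), function(g) {
    r <- results$r[results$group == g & results$computable]
    p <- if (length(r) >= 3 && stats::sd(r) > 0)
      stats::shapiro.test(r)$p.value else NA_real_
    data.frame(group = g, n_pairs = length(r),
               median_r = if (length(r)) stats::median(r) else NA_real_,
               median_abs_r = if (length(r)) stats::median(abs(r)) else
                 NA_real_,
               shapiro_p = p, stringsAsFactors = FALSE)
  }))
  ok <- results[results$computable, ]
  ok <- ok[order(ok$r), ]
  list(results = results, group_tests = group_tests,
       top_positive = utils::tail(ok, min(top, nrow(ok))),
       top_negative = utils::head(ok, min(top, nrow(ok))),
       m = attr(results, "m"))
}
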