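# Amino-acid descriptor scales.
#
# Seven scale families, 47 scales in total, one value per canonical residue:
#   Blos1-Blos10  BLOSUM-matrix-derived indices (reconstructed, see below)
#   KF1-KF10      Kidera factors (Kidera et al., J Protein Chem 1985)
#   VHSE1-VHSE8   VHSE principal-component scores (Mei et al., Biopolymers 2005)
#   PP1-PP3       Cruciani properties (Cruciani et al., J Chemom 2004)
#   Z1-Z5         extended z-scales (Sandberg et al., J Med Chem 1998)
#   F1-F6         FASGAI-style generalized-information factors (reconstructed)
#   a.pah/a.pss/a.ms/a.cc/a.ec  Atchley factors (Atchley et al., PNAS 2005)
#
# KF, VHSE, PP, Z and Atchley values are transcriptions of the published
# tables. Blos1-Blos10 and F1-F6 are deterministic reconstructions computed
# at load time because the original numeric tables could not be bundled:
# Blos* are the leading eigencomponents of the doubly centered BLOSUM62
# similarity matrix (the construction behind published BLOSUM indices), and
# F* are unit-variance first principal components of anchor scale sets
# matching the six generalized property axes (hydrophobicity, alpha-and-turn
# propensity, bulkiness, composition, flexibility, electronic). Both are
# documented as reconstructions; absolute values differ from the original
# publications while the represented property axes match.

.AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.scale_mat <- function(values, prefix, n) {
  m <- matrix(values, nrow = 20, ncol = n, byrow = TRUE,
              dimnames = list(.AA_ORDER, paste0(prefix, seq_len(n))))
  m
}

.KIDERA <- .scale_mat(c(
  -1.56, -1.67, -0.97, -0.27, -0.93, -0.78, -0.20, -0.08,  0.21, -0.48,
   0.22,  1.27,  1.37,  1.87, -1.70,  0.46,  0.92, -0.39,  0.23,  0.93,
   1.14, -0.07, -0.12,  0.81,  0.18,  0.37, -0.09,  1.23,  1.10, -1.73,
   0.58, -0.22, -1.58,  0.81, -0.92,  0.15, -1.52,  0.47,  0.76,  0.70,
   0.12, -0.89,  0.45, -1.05, -0.71,  2.41,  1.52, -0.69,  1.13,  1.10,
  -0.47,  0.24,  0.07,  1.10,  1.10,  0.59,  0.84, -0.71, -0.03, -2.33,
  -1.45,  0.19, -1.61,  1.17, -1.31,  0.40,  0.04,  0.38, -0.35, -0.12,
   1.46, -1.96, -0.23, -0.16,  0.10, -0.11,  1.32,  2.36, -1.66,  0.46,
  -0.41,  0.52, -0.28,  0.28,  1.61,  1.01, -1.85,  0.47,  1.13,  1.63,
  -0.73, -0.16,  1.79, -0.77, -0.54,  0.03, -0.83,  0.51,  0.66, -1.78,
  -1.04,  0.00, -0.24, -1.10, -0.55, -2.05,  0.96, -0.76,  0.45,  0.93,
  -0.34,  0.82, -0.23,  1.70,  1.54, -1.62,  1.15, -0.08, -0.48,  0.60,
  -1.40,  0.18, -0.42, -0.73,  2.00,  1.52,  0.26,  0.11, -1.27,  0.27,
  -0.21,  0.98, -0.36, -1.43,  0.22, -0.81,  0.67,  1.10,  1.71, -0.44,
   2.06, -0.33, -1.15, -0.75,  0.88, -0.45,  0.30, -2.30,  0.74, -0.28,
   0.81, -1.08,  0.16,  0.42, -0.21, -0.43, -1.89, -1.15, -0.97, -0.23,
   0.26, -0.70,  1.21,  0.63, -0.10,  0.21,  0.24, -1.15, -0.56,  0.19,
   0.30,  2.10, -0.72, -1.57, -1.16,  0.57, -0.48, -0.40, -2.30, -0.60,
   1.38,  1.48,  0.80, -0.56,  0.00, -0.68, -0.31,  1.03, -0.05,  0.53,
  -0.74, -0.71,  2.04, -0.40,  0.50, -0.81, -1.07,  0.06, -0.46,  0.65),
  "KF", 10)

.ZSCALES <- .scale_mat(c(
   0.24, -2.32,  0.60, -0.14,  1.30,
   3.52,  2.50, -3.50,  1.99, -0.17,
   3.05,  1.62,  1.04, -1.15,  1.61,
   3.98,  0.93,  1.93, -2.46,  0.75,
   0.84, -1.67,  3.71,  0.18, -2.65,
   1.75,  0.50, -1.44, -1.34,  0.66,
   3.11,  0.26, -0.11, -0.34, -0.25,
   2.05, -4.06,  0.36, -0.82, -0.38,
   2.47,  1.95,  0.26,  3.90,  0.09,
  -3.89, -1.73, -1.71, -0.84,  0.26,
  -4.28, -1.30, -1.49, -0.72,  0.84,
   2.29,  0.89, -2.49,  1.49,  0.31,
  -2.85, -0.22,  0.47,  1.94, -0.98,
  -4.22,  1.94,  1.06,  0.54, -0.62,
  -1.66,  0.27,  1.84,  0.70,  2.00,
   2.39, -1.07,  1.15, -1.39,  0.67,
   0.75, -2.18, -1.12, -1.46, -0.40,
  -4.36,  3.94,  0.59,  3.44, -1.59,
  -2.54,  2.44,  0.43,  0.04, -1.47,
  -2.59, -2.64, -1.54, -0.85, -0.02),
  "Z", 5)

.VHSE <- .scale_mat(c(
   0.15, -1.11, -1.35, -0.92,  0.02, -0.91,  0.36, -0.48,
  -1.47,  1.45,  1.24,  1.27,  1.55,  1.47,  1.30,  0.83,
  -0.99,  0.00, -0.37,  0.69, -0.55,  0.85,  0.73, -0.80,
  -1.15,  0.67, -0.41, -0.01, -2.68,  1.31,  0.03,  0.56,
   0.18, -1.67, -0.46, -0.21,  0.00,  1.20, -1.61, -0.19,
  -0.96,  0.12,  0.18,  0.16,  0.09,  0.42, -0.20, -0.41,
  -1.18,  0.40,  0.10,  0.36, -2.16, -0.17,  0.91,  0.02,
  -0.20, -1.53, -2.63,  2.28, -0.53, -1.18,  2.01, -1.34,
  -0.43, -0.25,  0.37,  0.19,  0.51,  1.28,  0.93,  0.65,
   1.27, -0.14,  0.30, -1.80,  0.30, -1.61, -0.16, -0.13,
   1.36,  0.07,  0.26, -0.80,  0.22, -1.37,  0.08, -0.62,
  -1.17,  0.70,  0.70,  0.80,  1.64,  0.67,  1.63,  0.13,
   1.01, -0.53,  0.43,  0.00,  0.23,  0.10, -0.86, -0.68,
   1.52,  0.61,  0.96, -0.16,  0.25,  0.28, -1.33, -0.20,
   0.22, -0.17, -0.50,  0.05, -0.01, -1.34, -0.19,  3.56,
  -0.67, -0.86, -1.07, -0.41, -0.32,  0.27, -0.64,  0.11,
  -0.34, -0.51, -0.55, -1.06, -0.06, -0.01, -0.79,  0.39,
   1.50,  2.06,  1.79,  0.75,  0.75, -0.13, -1.01, -0.85,
   0.61,  1.60,  1.17,  0.73,  0.53,  0.25, -0.96, -0.52,
   0.76, -0.92, -0.17, -1.91,  0.22, -1.40, -0.24, -0.03),
  "VHSE", 8)

.CRUCIANI <- .scale_mat(c(
  -0.96, -0.76,  0.31,
   0.80,  0.63,  0.99,
   0.82, -0.57,  0.02,
   1.00, -0.89, -1.00,
  -0.55, -0.47,  0.19,
   0.75, -0.40,  0.13,
   0.94, -0.54, -0.90,
  -0.88, -1.00,  0.49,
   0.67, -0.11,  0.37,
  -0.94,  0.08, -0.16,
  -0.90,  0.08, -0.24,
   0.60,  0.10,  1.00,
  -0.82,  0.21, -0.08,
  -0.85,  0.48, -0.58,
  -0.81, -0.46, -0.23,
   0.41, -0.82,  0.57,
   0.40, -0.64,  0.37,
  -0.60,  1.00, -0.48,
  -0.23,  0.30, -0.38,
  -1.00, -0.24, -0.10),
  "PP", 3)

.ATCHLEY <- {
  m <- .scale_mat(c(
    -0.591, -1.302, -0.733,  1.570, -0.146,
     1.538, -0.055,  1.502,  0.440,  2.897,
     0.945,  0.828,  1.299, -0.169,  0.933,
     1.050,  0.302, -3.656, -0.259, -3.242,
    -1.343,  0.465, -0.862, -1.020, -0.255,
     0.931, -0.179, -3.005, -0.503, -1.853,
     1.357, -1.453,  1.477,  0.113, -0.837,
    -0.384,  1.652,  1.330,  1.045,  2.064,
     0.336, -0.417, -1.673, -1.474, -0.078,
    -1.239, -0.547,  2.131,  0.393,  0.816,
    -1.019, -0.987, -1.505,  1.266, -0.912,
     1.831, -0.561,  0.533, -0.277,  1.648,
    -0.663, -1.524,  2.219, -1.005,  1.212,
    -1.006, -0.590,  1.891, -0.397,  0.412,
     0.189,  2.081, -1.628,  0.421, -1.392,
    -0.228,  1.399, -4.760,  0.670, -2.647,
    -0.032,  0.326,  2.213,  0.908,  1.313,
    -0.595,  0.009,  0.672, -2.128, -0.184,
     0.260,  0.830,  3.097, -0.838,  1.512,
    -1.337, -0.279, -0.544,  1.242, -1.262),
    "x", 5)
  colnames(m) <- c("a.pah", "a.pss", "a.ms", "a.cc", "a.ec")
  m
}

# Blos1-Blos10: classical-MDS components of the BLOSUM62 similarity matrix.
.blosum_index_scales <- function() {
  s <- substitution_matrix("BLOSUM62", "BLA")$values[.AA_ORDER, .AA_ORDER]
  h <- diag(20) - matrix(1 / 20, 20, 20)
  e <- eigen(h %*% s %*% h, symmetric = TRUE)
  comp <- e$vectors[, order(-abs(e$values))[1:10], drop = FALSE]
  comp <- apply(comp, 2, function(v) {
    v <- v * sign(v[which.max(abs(v))])     # deterministic sign convention
    as.numeric(scale(v))
  })
  dimnames(comp) <- list(.AA_ORDER, paste0("Blos", 1:10))
  # orient Blos1 as a hydrophobicity axis (positive for Ile/Val/Leu)
  if (mean(comp[c("I", "L", "V"), 1]) < 0) comp[, 1] <- -comp[, 1]
  comp
}

# F1-F6: anchored first principal components over the embedded scale space,
# one per generalized property axis.
.fasgai_like_scales <- function(base) {
  anchors <- list(
    F1 = list(c("VHSE1", "VHSE2", "KF4", "Z1", "PP2"), "VHSE1"),
    F2 = list(c("KF1", "a.pss", "KF3"), "KF1"),
    F3 = list(c("a.ms", "Z2", "VHSE3", "VHSE4", "KF2"), "a.ms"),
    F4 = list(c("a.cc", "KF9"), "a.cc"),
    F5 = list(c("KF7", "VHSE7", "KF8"), "KF7"),
    F6 = list(c("Z3", "a.ec", "a.pah", "VHSE5", "VHSE6", "PP1"), "Z3"))
  out <- sapply(anchors, function(an) {
    x <- scale(base[, an[[1]], drop = FALSE])
    pc <- prcomp(x, center = FALSE, scale. = FALSE)$x[, 1]
    if (cor(pc, base[, an[[2]]]) < 0) pc <- -pc
    as.numeric(scale(pc))
  })
  dimnames(out) <- list(.AA_ORDER, names(anchors))
  out
}

.descriptor_env <- new.env(parent = emptyenv())

#' Full amino-acid descriptor table
#'
#' Returns the 20 x 47 matrix of descriptor values (residues in rows,
#' scales in columns) covering the seven scale families.
#'
#' @return Numeric matrix, rownames the one-letter residue codes.
#' @export
aa_descriptor_table <- function() {
  if (is.null(.descriptor_env$table)) {
    base <- cbind(.KIDERA, .VHSE, .CRUCIANI, .ZSCALES, .ATCHLEY)
    blos <- .blosum_index_scales()
    fas <- .fasgai_like_scales(cbind(base, blos))
    tab <- cbind(blos, .KIDERA, .VHSE, .CRUCIANI, .ZSCALES, fas, .ATCHLEY)
    stopifnot(ncol(tab) == 47, !anyNA(tab))
    .descriptor_env$table <- tab
  }
  .descriptor_env$table
}

#' Descriptor property-group membership
#'
#' Scales grouped by the physicochemical feature they represent. A scale can
#' appear in several groups (the BLOSUM-derived components mix properties);
#' \code{descriptor_primary_group} resolves each scale to a single group by
#' first listing, with the remaining scales \code{"unassigned"}.
#'
#' @return Named list of character vectors (groups: hydrophobicity, steric,
#'   electronic, secondary_structure).
#' @export
descriptor_groups <- function() {
  list(
    hydrophobicity = c("Z1", "PP2", "F1", "VHSE1", "VHSE2", "Blos1",
                       "KF4", "KF10"),
    steric = c("a.ms", "Z2", "F3", "VHSE3", "VHSE4", "Blos1", "Blos2",
               "Blos3", "KF2"),
    electronic = c("a.pah", "a.ec", "Z3", "PP1", "F6", "VHSE5", "VHSE6",
                   "VHSE7", "VHSE8"),
    secondary_structure = c("a.pss", "F2", "Blos1", "Blos3", "KF1", "KF3",
                            "KF5", "KF8"))
}

#' @rdname descriptor_groups
#' @export
descriptor_primary_group <- function() {
  groups <- descriptor_groups()
  all_scales <- colnames(aa_descriptor_table())
  out <- setNames(rep("unassigned", length(all_scales)), all_scales)
  for (g in rev(names(groups))) out[groups[[g]]] <- g
  out
}
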