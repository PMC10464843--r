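# Amino-acid vocabulary, residue topology and ideal side-chain geometry.
# All geometry is heavy-atom only; hydrogens are never modeled.

#' Canonical amino-acid alphabet
#'
#' The 20 canonical one-letter residue codes, in the conventional
#' ARNDCQEGHILKMFPSTWYV order used by substitution matrices.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

.AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
          Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
          L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
          S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")
.AA1 <- structure(names(.AA3), names = unname(.AA3))

aa_three <- function(one) unname(.AA3[one])
aa_one <- function(three) unname(.AA1[toupper(three)])

is_valid_cdr3 <- function(x) {
  nzchar(x) & !grepl(sprintf("[^%s]", paste(aa_alphabet(), collapse = "")), x)
}

#' @noRd
backbone_atom_names <- function() c("N", "CA", "C", "O", "OXT")

# van der Waals-like radii per element, used by the surrogate energy terms
.ELEMENT_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

atom_element <- function(name) {
  el <- substr(gsub("[0-9]", "", name), 1, 1)
  ifelse(el %in% names(.ELEMENT_RADII), el, "C")
}

# Hydrogen-bond donor/acceptor heavy atoms (backbone N donor, O/OXT acceptor
# handled by name). Side-chain assignments follow common residue chemistry.
.SC_DONORS <- list(
  SER = "OG", THR = "OG1", TYR = "OH", ASN = "ND2", GLN = "NE2",
  LYS = "NZ", ARG = c("NE", "NH1", "NH2"), HIS = c("ND1", "NE2"),
  TRP = "NE1", CYS = "SG"
)
.SC_ACCEPTORS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2")
)

is_donor_atom <- function(resid3, atom) {
  atom == "N" | mapply(function(r, a) a %in% (.SC_DONORS[[r]] %||% character()),
                       resid3, atom)
}
is_acceptor_atom <- function(resid3, atom) {
  atom %in% c("O", "OXT") |
    mapply(function(r, a) a %in% (.SC_ACCEPTORS[[r]] %||% character()),
           resid3, atom)
}

# Formally charged side-chain group atoms for ionic-contact typing:
# carboxylates against Lys NZ / Arg guanidinium / His ring nitrogens.
.NEG_ATOMS <- list(ASP = c("OD1", "OD2", "CG"), GLU = c("OE1", "OE2", "CD"))
.POS_ATOMS <- list(LYS = "NZ", ARG = c("NE", "CZ", "NH1", "NH2"),
                   HIS = c("ND1", "NE2"))

charged_group <- function(resid3, atom) {
  neg <- mapply(function(r, a) a %in% (.NEG_ATOMS[[r]] %||% character()),
                resid3, atom)
  pos <- mapply(function(r, a) a %in% (.POS_ATOMS[[r]] %||% character()),
                resid3, atom)
  ifelse(neg, "neg", ifelse(pos, "pos", "none"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# Ideal side-chain internal coordinates.
#
# Each side-chain atom is placed by the natural-extension-reference-frame
# construction from three previously placed atoms (a, b, c): bond length
# |c-new|, planar angle b-c-new (degrees) and dihedral a-b-c-new (degrees).
# Chi-bearing dihedrals carry the name of the torsion they define so the
# surrogate mutator can copy torsions from a parent residue when the chain
# of defining atoms exists there under the same names.
#
# Ring closures (His, Phe, Tyr, Trp, Pro) are built as dihedral chains; the
# resulting rings are near-ideal but not exactly closed, which is acceptable
# for a distance-based surrogate and documented as such.
# ---------------------------------------------------------------------------

.sc_row <- function(atom, a, b, c, bond, angle, dihedral, chi = NA_character_) {
  data.frame(atom = atom, a = a, b = b, c = c, bond = bond, angle = angle,
             dihedral = dihedral, chi = chi, stringsAsFactors = FALSE)
}

.SIDECHAIN_TOPOLOGY <- local({
  CB <- .sc_row("CB", "C", "N", "CA", 1.53, 110.5, -122.6)
  tp <- list()
  tp$GLY <- CB[0, ]
  tp$ALA <- CB
  tp$SER <- rbind(CB, .sc_row("OG",  "N", "CA", "CB", 1.42, 110.8, -60, "chi1"))
  tp$CYS <- rbind(CB, .sc_row("SG",  "N", "CA", "CB", 1.81, 114.0, -60, "chi1"))
  tp$THR <- rbind(CB,
    .sc_row("OG1", "N", "CA", "CB", 1.43, 109.6, -60, "chi1"),
    .sc_row("CG2", "N", "CA", "CB", 1.52, 110.5,  60))
  tp$VAL <- rbind(CB,
    .sc_row("CG1", "N", "CA", "CB", 1.53, 110.5, 175, "chi1"),
    .sc_row("CG2", "N", "CA", "CB", 1.53, 110.5, -63))
  tp$LEU <- rbind(CB,
    .sc_row("CG",  "N",  "CA", "CB", 1.53, 116.3, -60, "chi1"),
    .sc_row("CD1", "CA", "CB", "CG", 1.53, 110.7, 180, "chi2"),
    .sc_row("CD2", "CA", "CB", "CG", 1.53, 110.7,  60))
  tp$ILE <- rbind(CB,
    .sc_row("CG1", "N",  "CA", "CB",  1.53, 110.4, -60, "chi1"),
    .sc_row("CG2", "N",  "CA", "CB",  1.53, 110.5,  60),
    .sc_row("CD1", "CA", "CB", "CG1", 1.51, 113.9, 180, "chi2"))
  tp$MET <- rbind(CB,
    .sc_row("CG", "N",  "CA", "CB", 1.52, 114.1, -60, "chi1"),
    .sc_row("SD", "CA", "CB", "CG", 1.80, 112.7, 180, "chi2"),
    .sc_row("CE", "CB", "CG", "SD", 1.79, 100.8, 180, "chi3"))
  tp$ASP <- rbind(CB,
    .sc_row("CG",  "N",  "CA", "CB", 1.52, 113.0, -60, "chi1"),
    .sc_row("OD1", "CA", "CB", "CG", 1.25, 119.2, -30, "chi2"),
    .sc_row("OD2", "CA", "CB", "CG", 1.25, 118.2, 150))
  tp$ASN <- rbind(CB,
    .sc_row("CG",  "N",  "CA", "CB", 1.52, 112.6, -60, "chi1"),
    .sc_row("OD1", "CA", "CB", "CG", 1.23, 120.8, -30, "chi2"),
    .sc_row("ND2", "CA", "CB", "CG", 1.33, 116.5, 150))
  tp$GLU <- rbind(CB,
    .sc_row("CG",  "N",  "CA", "CB", 1.52, 114.2, -60, "chi1"),
    .sc_row("CD",  "CA", "CB", "CG", 1.52, 112.6, 180, "chi2"),
    .sc_row("OE1", "CB", "CG", "CD", 1.25, 119.0, -30, "chi3"),
    .sc_row("OE2", "CB", "CG", "CD", 1.25, 118.2, 150))
  tp$GLN <- rbind(CB,
    .sc_row("CG",  "N",  "CA", "CB", 1.52, 114.2, -60, "chi1"),
    .sc_row("CD",  "CA", "CB", "CG", 1.52, 112.6, 180, "chi2"),
    .sc_row("OE1", "CB", "CG", "CD", 1.23, 120.8, -30, "chi3"),
    .sc_row("NE2", "CB", "CG", "CD", 1.33, 116.5, 150))
  tp$LYS <- rbind(CB,
    .sc_row("CG", "N",  "CA", "CB", 1.52, 114.1, -60, "chi1"),
    .sc_row("CD", "CA", "CB", "CG", 1.52, 111.3, 180, "chi2"),
    .sc_row("CE", "CB", "CG", "CD", 1.52, 111.3, 180, "chi3"),
    .sc_row("NZ", "CG", "CD", "CE", 1.49, 111.9, 180, "chi4"))
  tp$ARG <- rbind(CB,
    .sc_row("CG",  "N",  "CA", "CB", 1.52, 114.1, -60, "chi1"),
    .sc_row("CD",  "CA", "CB", "CG", 1.52, 111.3, 180, "chi2"),
    .sc_row("NE",  "CB", "CG", "CD", 1.46, 112.0, 180, "chi3"),
    .sc_row("CZ",  "CG", "CD", "NE", 1.33, 124.2, 180, "chi4"),
    .sc_row("NH1", "CD", "NE", "CZ", 1.33, 120.0,   0),
    .sc_row("NH2", "CD", "NE", "CZ", 1.33, 120.0, 180))
  tp$HIS <- rbind(CB,
    .sc_row("CG",  "N",  "CA", "CB",  1.49, 113.8, -60, "chi1"),
    .sc_row("ND1", "CA", "CB", "CG",  1.38, 122.7, -75, "chi2"),
    .sc_row("CD2", "CA", "CB", "CG",  1.35, 131.1, 105),
    .sc_row("CE1", "CB", "CG", "ND1", 1.32, 109.2, 180),
    .sc_row("NE2", "CG", "ND1", "CE1", 1.32, 108.2, 0))
  phe_ring <- rbind(
    .sc_row("CG",  "N",  "CA", "CB",  1.50, 113.8, -60, "chi1"),
    .sc_row("CD1", "CA", "CB", "CG",  1.39, 120.8,  90, "chi2"),
    .sc_row("CD2", "CA", "CB", "CG",  1.39, 120.8, -90),
    .sc_row("CE1", "CB", "CG", "CD1", 1.39, 120.8, 180),
    .sc_row("CE2", "CB", "CG", "CD2", 1.39, 120.8, 180),
    .sc_row("CZ",  "CG", "CD1", "CE1", 1.39, 120.0, 0))
  tp$PHE <- rbind(CB, phe_ring)
  tp$TYR <- rbind(CB, phe_ring,
    .sc_row("OH", "CD1", "CE1", "CZ", 1.38, 120.0, 180))
  tp$TRP <- rbind(CB,
    .sc_row("CG",  "N",  "CA",  "CB",  1.50, 113.6, -60, "chi1"),
    .sc_row("CD1", "CA", "CB",  "CG",  1.37, 126.9, -90, "chi2"),
    .sc_row("CD2", "CA", "CB",  "CG",  1.43, 126.6,  90),
    .sc_row("NE1", "CB", "CG",  "CD1", 1.38, 110.2, 180),
    .sc_row("CE2", "CB", "CG",  "CD2", 1.41, 107.2, 180),
    .sc_row("CE3", "CB", "CG",  "CD2", 1.40, 133.9,   0),
    .sc_row("CZ2", "CG", "CD2", "CE2", 1.40, 122.4, 180),
    .sc_row("CZ3", "CG", "CD2", "CE3", 1.39, 118.8, 180),
    .sc_row("CH2", "CD2", "CE2", "CZ2", 1.37, 117.5, 0))
  tp$PRO <- rbind(CB,
    .sc_row("CG", "N",  "CA", "CB", 1.50, 104.5,  30, "chi1"),
    .sc_row("CD", "CA", "CB", "CG", 1.51, 105.5, -35, "chi2"))
  tp
})

#' Heavy-atom names of a residue type
#'
#' @param resid3 Three-letter residue code.
#' @param backbone Include backbone atoms N, CA, C, O.
#' @return Character vector of atom names.
#' @export
residue_atom_names <- function(resid3, backbone = TRUE) {
  resid3 <- toupper(resid3)
  if (!resid3 %in% names(.SIDECHAIN_TOPOLOGY))
    stop("unknown residue type: ", resid3)
  sc <- .SIDECHAIN_TOPOLOGY[[resid3]]$atom
  if (backbone) c("N", "CA", "C", "O", sc) else sc
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3], u[1] * v[2] - u[2] * v[1])
}

# Place atom d from reference atoms a, b, c (rows of xyz) using bond length,
# planar angle and dihedral (degrees) -- the standard NeRF construction.
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- -dihedral * pi / 180   # sign matched to dihedral_angle()
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  n <- cross3(b - a, bc)
  n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(dih), sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}
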