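# Light-weight heavy-atom structure container.
#
# A `tcr_structure` holds one atom table. Positions are kept in two
# numbering systems: `resno` (author numbering as read from the PDB file,
# retained internally) and `subpos` (1-based from the start of the
# chain/substructure, the only numbering analysis outputs use).

#' Construct a structure object from an atom table
#'
#' @param atoms data.frame with columns chain, subpos, resno, resid
#'   (three-letter code), atom (PDB atom name), x, y, z.
#' @return An object of class `tcr_structure`.
#' @export
tcr_structure <- function(atoms) {
  required <- c("chain", "subpos", "resid", "atom", "x", "y", "z")
  missing <- setdiff(required, names(atoms))
  if (length(missing))
    stop("atom table lacks columns: ", paste(missing, collapse = ", "))
  if (is.null(atoms$resno)) atoms$resno <- atoms$subpos
  atoms$resid <- toupper(atoms$resid)
  atoms$element <- atom_element(atoms$atom)
  atoms$backbone <- atoms$atom %in% backbone_atom_names()
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite coordinates in atom table")
  atoms <- atoms[order(atoms$chain, atoms$subpos), , drop = FALSE]
  rownames(atoms) <- NULL
  structure(list(atoms = atoms), class = "tcr_structure")
}

#' @export
print.tcr_structure <- function(x, ...) {
  a <- x$atoms
  ch <- split(a, a$chain)
  cat(sprintf("<tcr_structure> %d atoms, %d chains\n", nrow(a), length(ch)))
  for (id in names(ch))
    cat(sprintf("  chain %s: %d residues (%s)\n", id,
                length(unique(ch[[id]]$subpos)),
                chain_sequence(x, id)))
  invisible(x)
}

#' Extract the one-letter sequence of a chain
#'
#' @param struct A `tcr_structure`.
#' @param chain Chain identifier.
#' @return One-letter amino-acid string in substructure order.
#' @export
chain_sequence <- function(struct, chain) {
  a <- struct$atoms[struct$atoms$chain == chain, ]
  if (!nrow(a)) stop("chain not present in structure: ", chain)
  res <- a[!duplicated(a$subpos), ]
  paste(aa_one(res$resid[order(res$subpos)]), collapse = "")
}

residue_xyz <- function(struct, chain, subpos) {
  a <- struct$atoms[struct$atoms$chain == chain & struct$atoms$subpos == subpos, ]
  m <- as.matrix(a[, c("x", "y", "z")])
  rownames(m) <- a$atom
  m
}

#' Read a heavy-atom structure from a PDB file
#'
#' Parses standard ATOM records via bio3d, drops hydrogens and alternate
#' locations, and assigns 1-based substructure numbering per chain in file
#' order of author residue numbers.
#'
#' @param path PDB file path.
#' @param chains Optional chain identifiers to keep.
#' @return A `tcr_structure`.
#' @export
read_structure_pdb <- function(path, chains = NULL) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", ]
  at <- at[!grepl("^[0-9]*H", at$elety), ]            # heavy atoms only
  at <- at[at$alt %in% c("", "A", NA), ]
  if (!is.null(chains)) {
    if (!all(chains %in% at$chain))
      stop("structural error: chain(s) missing from PDB: ",
           paste(setdiff(chains, unique(at$chain)), collapse = ", "))
    at <- at[at$chain %in% chains, ]
  }
  at <- at[toupper(at$resid) %in% names(.AA1), ]
  key <- paste(at$chain, at$resno, at$insert)
  subpos <- integer(nrow(at))
  for (ch in unique(at$chain)) {
    i <- at$chain == ch
    subpos[i] <- match(key[i], unique(key[i]))
  }
  tcr_structure(data.frame(
    chain = at$chain, subpos = subpos, resno = at$resno,
    resid = at$resid, atom = at$elety,
    x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE))
}

#' Write a structure to a PDB file
#'
#' @param struct A `tcr_structure`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(struct, path) {
  a <- struct$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, chain = a$chain, resid = a$resid,
                   elety = a$atom)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Ideal residue construction (shared by the surrogate mutator and the toy
# complex generator).
# ---------------------------------------------------------------------------

# Build side-chain atoms onto existing backbone coordinates.
# `bb` is a named coordinate matrix containing at least N, CA, C.
# Dihedrals are copied from `parent` (named coordinate matrix of the parent
# residue) whenever the parent holds the atom and its three reference atoms
# under the same names; ideal defaults are used elsewhere.
build_sidechain <- function(resid3, bb, parent = NULL, chi = NULL) {
  topo <- .SIDECHAIN_TOPOLOGY[[toupper(resid3)]]
  if (is.null(topo)) stop("unknown residue type: ", resid3)
  coords <- bb
  if (nrow(topo)) for (i in seq_len(nrow(topo))) {
    row <- topo[i, ]
    if (row$atom %in% rownames(coords)) next   # keep pre-placed atoms (CB)
    dih <- row$dihedral
    if (!is.null(parent) &&
        all(c(row$a, row$b, row$c, row$atom) %in% rownames(parent))) {
      dih <- dihedral_angle(parent[row$a, ], parent[row$b, ],
                            parent[row$c, ], parent[row$atom, ])
    }
    if (!is.na(row$chi) && !is.null(chi[[row$chi]])) dih <- chi[[row$chi]]
    pos <- place_atom(coords[row$a, ], coords[row$b, ], coords[row$c, ],
                      row$bond, row$angle, dih)
    coords <- rbind(coords, matrix(pos, 1, 3, dimnames = list(row$atom, NULL)))
  }
  coords
}

# One residue with idealized backbone in a local frame: CA at the origin,
# strand axis = x, side chain extending toward -y. Used for toy strands.
build_ideal_residue <- function(resid3) {
  bb <- rbind(
    N  = c(-1.36, 0.00, 0.53),
    CA = c( 0.00, 0.00, 0.00),
    C  = c( 1.42, 0.00, 0.53),
    O  = c( 1.60, 0.00, 1.75))
  xyz <- build_sidechain(resid3, bb)
  sc <- setdiff(rownames(xyz), rownames(bb))
  if (length(sc)) {
    # orient the side chain along -y so that opposing strands can be
    # brought into contact by pure translation
    tip <- xyz[sc[length(sc)], ] - xyz["CA", ]
    if (tip[2] > 0) xyz[, 2] <- -xyz[, 2]   # mirror: toy geometry only
  }
  xyz
}

# Assemble a toy strand structure: residues spaced `spacing` angstroms along
# x, chain placed at y-offset `y0`, side chains facing `face` (+1/-1 in y).
build_toy_strand <- function(seq1, chain, y0 = 0, z0 = 0, spacing = 12,
                             face = -1) {
  res <- strsplit(seq1, "")[[1]]
  rows <- lapply(seq_along(res), function(i) {
    xyz <- build_ideal_residue(aa_three(res[i]))
    if (face > 0) xyz[, 2] <- -xyz[, 2]
    xyz[, 1] <- xyz[, 1] + (i - 1) * spacing
    xyz[, 2] <- xyz[, 2] + y0
    xyz[, 3] <- xyz[, 3] + z0
    data.frame(chain = chain, subpos = i, resno = i,
               resid = aa_three(res[i]), atom = rownames(xyz),
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
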