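# Substitution matrices and the adjusted substitution statistic.
#
# Three index kinds are supported per matrix:
#   BLA  clustered scoring matrix in half-bit units (the familiar integer
#        BLOSUM scores; taken from the Biostrings copies of the NCBI
#        matrices)
#   SIJ  clustered scoring matrix in bit units
#   QIJ  clustered target (substitution) frequencies
#
# The NCBI sij/qij distribution files are not bundled; when no file is
# supplied, SIJ is derived as BLA/2 and QIJ is reconstructed from the
# half-bit scores by inverting the log-odds relation
#     s_ij = log2( q_ij / (p_i p_j) )
# with the published BLOSUM background residue frequencies, renormalized to
# sum to one. Entries are deterministic functions of the published integer
# scores and background frequencies; they differ from the NCBI file values
# only through the rounding already present in the half-bit scores.
# `read_substitution_matrix` parses authentic NCBI-format files as
# overrides.

.matrix_env <- new.env(parent = emptyenv())

.bla_matrix <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  m <- get(name, envir = e)[.AA_ORDER, .AA_ORDER]
  storage.mode(m) <- "double"
  m
}

# Background amino-acid frequencies of the BLOSUM62 data set (Henikoff &
# Henikoff 1992 marginals), alphabet order ARNDCQEGHILKMFPSTWYV.
.BLOSUM_BACKGROUND <- c(0.074, 0.052, 0.045, 0.054, 0.025, 0.034, 0.054,
                        0.074, 0.026, 0.068, 0.099, 0.058, 0.025, 0.047,
                        0.039, 0.057, 0.051, 0.013, 0.032, 0.073)

.reconstruct_qij <- function(bla) {
  s_bits <- bla / 2
  p <- .BLOSUM_BACKGROUND / sum(.BLOSUM_BACKGROUND)
  q <- outer(p, p) * 2^s_bits
  q <- q / sum(q)
  dimnames(q) <- dimnames(bla)
  q
}

#' Substitution matrix accessor
#'
#' @param name "BLOSUM62" or "BLOSUM100".
#' @param kind Index kind: "BLA" (half-bit scores), "SIJ" (bit-unit scores)
#'   or "QIJ" (target frequencies).
#' @return List with elements `name`, `kind` and `values` (symmetric 20 x 20
#'   matrix over the canonical alphabet).
#' @export
substitution_matrix <- function(name = c("BLOSUM62", "BLOSUM100"),
                                kind = c("BLA", "SIJ", "QIJ")) {
  name <- match.arg(name)
  kind <- match.arg(kind)
  key <- paste(name, kind, sep = ".")
  if (is.null(.matrix_env[[key]])) {
    bla <- .bla_matrix(name)
    values <- switch(kind,
                     BLA = bla,
                     SIJ = bla / 2,
                     QIJ = .reconstruct_qij(bla))
    .matrix_env[[key]] <- list(name = name, kind = kind, values = values)
  }
  .matrix_env[[key]]
}

#' Parse an NCBI-format substitution matrix file
#'
#' Reads the plain-text matrix dialect used by the NCBI BLOSUM distribution
#' (comment lines starting with `#`, a header row of residue codes, one
#' labelled row per residue; works for the iij/sij/qij variants, including
#' lower-triangular files).
#'
#' @param path File path.
#' @param name,kind Labels stored on the returned object.
#' @return Same shape as [substitution_matrix()].
#' @export
read_substitution_matrix <- function(path, name = "custom",
                                     kind = c("BLA", "SIJ", "QIJ")) {
  kind <- match.arg(kind)
  lines <- readLines(path)
  lines <- trimws(lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))])
  header <- strsplit(lines[[1]], "\\s+")[[1]]
  rows <- lapply(lines[-1], function(l) strsplit(l, "\\s+")[[1]])
  n <- length(header)
  m <- matrix(NA_real_, n, n, dimnames = list(header, header))
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    labelled <- suppressWarnings(is.na(as.numeric(r[1])))
    lab <- if (labelled) r[1] else header[i]
    vals <- as.numeric(if (labelled) r[-1] else r)
    m[lab, seq_along(vals)] <- vals
  }
  low <- is.na(m) & !is.na(t(m))
  m[low] <- t(m)[low]
  keep <- intersect(.AA_ORDER, rownames(m))
  if (length(keep) < 20)
    stop("matrix file lacks residues: ",
         paste(setdiff(.AA_ORDER, keep), collapse = ", "))
  m <- m[.AA_ORDER, .AA_ORDER]
  if (anyNA(m)) stop("incomplete matrix in ", path)
  list(name = name, kind = kind, values = m)
}

#' Adjusted substitution index
#'
#' Centers a substitution score so that identity substitutions score zero:
#' `M[from,to] - (M[from,from] + M[to,to]) / 2`. Negative values mark
#' substitutions less conserved than either residue's self-match.
#'
#' @param from,to One-letter residue codes (vectorized).
#' @param matrix A matrix object from [substitution_matrix()] or
#'   [read_substitution_matrix()].
#' @return Numeric vector of adjusted index values.
#' @export
adjusted_blosum <- function(from, to, matrix = substitution_matrix()) {
  m <- matrix$values
  bad <- !(from %in% rownames(m)) | !(to %in% rownames(m))
  if (any(bad))
    stop("unknown residue(s): ",
         paste(unique(c(from[bad], to[bad])), collapse = ", "))
  m[cbind(from, to)] - (m[cbind(from, from)] + m[cbind(to, to)]) / 2
}

#' All six adjusted indices for a set of substitutions
#'
#' Computes the adjusted index under both matrices (BLOSUM62, BLOSUM100)
#' and all three index kinds, using the Table-style column naming
#' `<KIND>.<62|100>.v2`.
#'
#' @param from,to One-letter residue code vectors.
#' @return data.frame with columns from, to and the six index columns.
#' @export
adjusted_blosum_indices <- function(from, to) {
  out <- data.frame(from = from, to = to, stringsAsFactors = FALSE)
  for (nm in c("BLOSUM62", "BLOSUM100")) {
    for (kd in c("BLA", "SIJ", "QIJ")) {
      col <- sprintf("%s.%s.v2", kd, sub("BLOSUM", "", nm))
      out[[col]] <- adjusted_blosum(from, to, substitution_matrix(nm, kd))
    }
  }
  out
}
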