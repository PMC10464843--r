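# Reading and validating specificity records and template annotations.
#
# A specificity record is one row of a VDJdb-style table: a CDR3 amino-acid
# sequence with its chain, allele-resolved V/J genes, cognate epitope and
# MHC allele. Records are held as a plain data.frame with columns
# record_id, chain ("alpha"/"beta"), cdr3, v_gene, j_gene, epitope,
# mhc_allele; duplicate (cdr3, chain, v, j, epitope) rows are collapsed and
# their identifiers merged with ";".

.RECORD_COLS <- c("record_id", "chain", "cdr3", "v_gene", "j_gene",
                  "epitope", "mhc_allele")

.DIALECTS <- list(
  vdjdb_tsv = c(chain = "gene", cdr3 = "cdr3", v_gene = "v.segm",
                j_gene = "j.segm", epitope = "antigen.epitope",
                mhc_allele = "mhc.a"),
  simple_tsv = c(chain = "chain", cdr3 = "cdr3", v_gene = "v_gene",
                 j_gene = "j_gene", epitope = "epitope",
                 mhc_allele = "mhc"))

#' Read specificity records from a TSV file
#'
#' Supports the public VDJdb export column names (`vdjdb_tsv`: gene, cdr3,
#' v.segm, j.segm, antigen.epitope, mhc.a) and a minimal `simple_tsv`
#' dialect (chain, cdr3, v_gene, j_gene, epitope, mhc). Rows failing
#' validation (non-canonical CDR3 characters, unknown chain, empty epitope)
#' are dropped with a warning naming the offending row numbers; duplicate
#' (cdr3, chain, v, j, epitope) tuples are collapsed to a single record with
#' merged record identifiers.
#'
#' @param path TSV file (tab-delimited, header row).
#' @param format Column dialect, `"vdjdb_tsv"` or `"simple_tsv"`.
#' @return data.frame of validated records with an `input_md5` attribute
#'   recording the file checksum.
#' @export
read_records <- function(path, format = c("simple_tsv", "vdjdb_tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("records file not found: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  map <- .DIALECTS[[format]]
  missing <- setdiff(unname(map), names(raw))
  if (length(missing))
    stop("format error: missing required column(s) for dialect ", format,
         ": ", paste(missing, collapse = ", "))
  rec <- data.frame(row = seq_len(nrow(raw)), stringsAsFactors = FALSE)
  for (field in names(map)) rec[[field]] <- as.character(raw[[map[[field]]]])
  rec$chain <- .normalize_chain(rec$chain)
  rec$cdr3 <- toupper(trimws(rec$cdr3))
  rec$record_id <- if ("record_id" %in% names(raw))
    as.character(raw$record_id) else sprintf("%s:%d", basename(path), rec$row)
  bad <- !is_valid_cdr3(rec$cdr3) | is.na(rec$chain) | !nzchar(rec$epitope)
  if (any(bad)) {
    warning(sum(bad), " invalid record row(s) dropped (rows ",
            paste(rec$row[bad], collapse = ", "), ")")
    rec <- rec[!bad, , drop = FALSE]
  }
  key <- do.call(paste, c(rec[c("cdr3", "chain", "v_gene", "j_gene",
                                "epitope")], sep = "\r"))
  ids <- vapply(split(rec$record_id, key), paste, "", collapse = ";")
  rec <- rec[!duplicated(key), , drop = FALSE]
  rec$record_id <- unname(ids[unique(key)])
  rec <- rec[order(rec$chain, rec$cdr3), .RECORD_COLS, drop = FALSE]
  rownames(rec) <- NULL
  attr(rec, "input_md5") <- unname(tools::md5sum(path))
  rec
}

.normalize_chain <- function(x) {
  x <- tolower(trimws(x))
  out <- rep(NA_character_, length(x))
  out[x %in% c("alpha", "a", "tra")] <- "alpha"
  out[x %in% c("beta", "b", "trb")] <- "beta"
  out
}

#' Write specificity records as normalized TSV
#'
#' @param records Record data.frame from [read_records()] or built in code.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  out <- records[, .RECORD_COLS]
  names(out)[names(out) == "mhc_allele"] <- "mhc"   # simple_tsv header
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Build a specificity record in code
#'
#' Convenience constructor for a single record row, used when assembling
#' inputs programmatically rather than reading them from TSV.
#'
#' @param cdr3 CDR3 amino-acid string.
#' @param chain `"alpha"` or `"beta"`.
#' @param v_gene,j_gene,epitope,mhc_allele,record_id Remaining record
#'   fields (defaults are placeholders).
#' @return One-row record data.frame.
#' @export
make_record <- function(cdr3, chain, v_gene = "TRV1*01", j_gene = "TRJ1*01",
                        epitope = "GILGFVFTL", mhc_allele = "HLA-A*02",
                        record_id = NA_character_) {
  data.frame(record_id = ifelse(is.na(record_id), paste0("rec:", cdr3),
                                record_id),
             chain = chain, cdr3 = cdr3, v_gene = v_gene, j_gene = j_gene,
             epitope = epitope, mhc_allele = mhc_allele,
             stringsAsFactors = FALSE)
}

strip_allele <- function(x) sub("\\*[0-9]+$", "", x)

# ---------------------------------------------------------------------------
# Template complexes
# ---------------------------------------------------------------------------

#' Load and verify an annotated template complex
#'
#' Attaches a parsed PDB structure to a template annotation and verifies it:
#' annotated chains must exist, the annotated CDR3 strings must match the
#' residues extracted at the annotated ranges, and the peptide chain length
#' must equal the epitope length.
#'
#' @param pdb_path PDB file of the complex.
#' @param annotation List with elements `pdb_id`, `chain_map` (named list
#'   mapping roles tcr_alpha/tcr_beta/mhc/peptide to chain identifiers;
#'   roles may be absent), `cdr3_alpha_range`/`cdr3_beta_range` (length-2
#'   integer vectors, 1-based inclusive positions within the TCR chain) and
#'   `core_records` (record data.frame annotating the template's CDR3/V/J/
#'   epitope per chain).
#' @return A `template_complex` object.
#' @export
read_template <- function(pdb_path, annotation) {
  struct <- read_structure_pdb(pdb_path,
                               chains = unique(unlist(annotation$chain_map)))
  template_complex(struct, annotation)
}

#' @rdname read_template
#' @param struct A `tcr_structure` (alternative to reading from file).
#' @export
template_complex <- function(struct, annotation) {
  ann <- annotation
  stopifnot(!is.null(ann$pdb_id), !is.null(ann$chain_map))
  cm <- ann$chain_map
  for (role in names(cm))
    if (!cm[[role]] %in% struct$atoms$chain)
      stop("structural error: chain for role ", role,
           " (", cm[[role]], ") missing from structure")
  core <- ann$core_records
  tpl <- structure(list(pdb_id = ann$pdb_id, structure = struct,
                        chain_map = cm,
                        cdr3_alpha_range = ann$cdr3_alpha_range,
                        cdr3_beta_range = ann$cdr3_beta_range,
                        core_records = core),
                   class = "template_complex")
  for (ch in intersect(c("alpha", "beta"), core$chain)) {
    annotated <- core$cdr3[core$chain == ch]
    extracted <- template_cdr3_sequence(tpl, ch)
    if (!identical(annotated, extracted))
      stop("annotation error: CDR3 ", ch, " mismatch; annotated '",
           annotated, "' vs structure '", extracted, "'")
  }
  pep_chain <- cm$peptide
  if (!is.null(pep_chain) && nrow(core)) {
    pep_len <- nchar(chain_sequence(struct, pep_chain))
    if (any(nchar(core$epitope) != pep_len))
      stop("annotation error: peptide chain length (", pep_len,
           ") differs from annotated epitope length")
  }
  tpl
}

#' @export
print.template_complex <- function(x, ...) {
  cat(sprintf("<template_complex> %s\n", x$pdb_id))
  for (ch in intersect(c("alpha", "beta"), x$core_records$chain))
    cat(sprintf("  CDR3%s %s\n", substr(ch, 1, 1),
                template_cdr3_sequence(x, ch)))
  cat(sprintf("  peptide %s\n", x$core_records$epitope[1]))
  invisible(x)
}

template_chain_id <- function(template, chain) {
  template$chain_map[[paste0("tcr_", chain)]]
}

template_cdr3_range <- function(template, chain) {
  template[[paste0("cdr3_", chain, "_range")]]
}

#' Extract the CDR3 sequence of a template chain from the structure
#'
#' @param template A `template_complex`.
#' @param chain `"alpha"` or `"beta"`.
#' @return One-letter CDR3 string.
#' @export
template_cdr3_sequence <- function(template, chain) {
  rng <- template_cdr3_range(template, chain)
  full <- chain_sequence(template$structure, template_chain_id(template, chain))
  substr(full, rng[1], rng[2])
}

# The full set of TCR chain sequences of a template (the non-redundancy key).
template_chain_sequences <- function(template) {
  chains <- unlist(template$chain_map[c("tcr_alpha", "tcr_beta")])
  sort(vapply(chains, function(ch) chain_sequence(template$structure, ch), ""))
}

#' Read template annotations from a YAML config
#'
#' The config is a list of entries, each with `pdb` (path, resolved
#' relative to the config file), `pdb_id`, `chain_map`, CDR3 ranges and
#' `core_records` (list of record-field maps).
#'
#' @param path YAML file.
#' @return List of `template_complex` objects.
#' @export
read_template_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  lapply(cfg, function(entry) {
    pdb <- entry$pdb
    if (!file.exists(pdb))
      pdb <- file.path(dirname(path), entry$pdb)
    core <- do.call(rbind, lapply(entry$core_records, function(r)
      make_record(r$cdr3, r$chain, r$v_gene, r$j_gene, r$epitope,
                  r$mhc %||% "", record_id = paste0(entry$pdb_id, ":", r$chain))))
    ann <- list(pdb_id = entry$pdb_id, chain_map = entry$chain_map,
                cdr3_alpha_range = unlist(entry$cdr3_alpha_range),
                cdr3_beta_range = unlist(entry$cdr3_beta_range),
                core_records = core)
    read_template(pdb, ann)
  })
}
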