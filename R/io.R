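# Readers/writers for the plain-text interchange formats: quant tables and
# abundance matrices as TSV, gene sets as GMT, kinase-substrate tables in
# the PhosphoSitePlus / prediction-score dialects, drug screens as TSV, and
# JSON for provenance, ground truth and signature results.

#' Read a peptide quantification table from TSV
#'
#' @param path file path.
#' @param col_map optional named character vector mapping this export
#'   dialect's column names to the canonical names (`c(canonical = "Export Name")`),
#'   e.g. `c(master_proteins = "Master Protein Accessions")`.
#' @return a validated quant table data.frame.
#' @export
read_quant_tsv <- function(path, col_map = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    for (canonical in names(col_map)) {
      idx <- match(col_map[[canonical]], names(tab))
      if (!is.na(idx)) names(tab)[idx] <- canonical
    }
  }
  if ("localization_ambiguous" %in% names(tab))
    tab$localization_ambiguous <- as.logical(tab$localization_ambiguous)
  if ("phospho_positions" %in% names(tab)) {
    tab$phospho_positions <- as.character(tab$phospho_positions)
    tab$phospho_positions[is.na(tab$phospho_positions)] <- ""
  }
  validate_quant_table(tab, require = intersect(QUANT_META_COLS, names(tab)))
  tab
}

#' Write a peptide quantification table to TSV
#' @param table quant table data.frame.
#' @param path output file path.
#' @export
write_quant_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write an AbundanceMatrix to TSV (matrix + sample metadata sidecar)
#'
#' @param am an `AbundanceMatrix`.
#' @param values_path TSV path for the features x samples matrix
#'   (first column `feature_id`, missing written as `NA`).
#' @param samples_path TSV path for the sample metadata.
#' @export
write_abundance_tsv <- function(am, values_path, samples_path = NULL) {
  df <- data.frame(feature_id = rownames(am$values), am$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, values_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  if (!is.null(samples_path))
    utils::write.table(am$samples, samples_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  invisible(values_path)
}

#' Read an AbundanceMatrix from TSV
#'
#' @param values_path matrix TSV written by [write_abundance_tsv()].
#' @param samples_path sample metadata TSV; if `NULL`, all columns are
#'   treated as non-reference samples of a single plex.
#' @export
read_abundance_tsv <- function(values_path, samples_path = NULL) {
  df <- utils::read.delim(values_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df[[1]]
  if (!is.null(samples_path)) {
    samples <- utils::read.delim(samples_path, check.names = FALSE,
                                 stringsAsFactors = FALSE)
    samples$is_reference <- as.logical(samples$is_reference)
  } else {
    samples <- data.frame(sample_id = colnames(values), plex_id = "plex1",
                          channel_id = colnames(values),
                          is_reference = FALSE, stringsAsFactors = FALSE)
  }
  abundance_matrix(values, samples)
}

#' Read gene sets from a GMT file
#'
#' Standard tab format: set name, description, then member identifiers.
#' Members are uppercased; an optional alias map translates identifiers
#' (e.g. protein accessions to gene symbols) before matching.
#'
#' @param path GMT file path.
#' @param alias_map optional named character vector `c(old = "NEW")`.
#' @return named list of unique uppercase member vectors.
#' @export
read_gmt <- function(path, alias_map = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L)
      stop("malformed GMT line (need name, description, >=1 member): ", parts[1])
    members <- toupper(parts[-(1:2)])
    if (!is.null(alias_map)) {
      hit <- members %in% names(alias_map)
      members[hit] <- toupper(alias_map[members[hit]])
    }
    unique(members[nzchar(members)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  if (anyDuplicated(names(sets))) stop("duplicate gene set names in GMT")
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of member vectors.
#' @param path output path.
#' @param descriptions optional character vector parallel to `sets`.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a curated kinase-substrate table (PhosphoSitePlus dialect)
#'
#' Expected columns: `KINASE`, `SUB_ACC_ID`, `SUB_MOD_RSD` (residue+position,
#' e.g. `S15`).  Rows whose modification token cannot be parsed into a
#' residue in S/T/Y and a positive integer position are skipped, with the
#' skipped count attached as attribute `n_skipped`.
#'
#' @param path TSV path.
#' @return data.frame with columns kinase, accession, residue, position.
#' @export
read_psp_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("KINASE", "SUB_ACC_ID", "SUB_MOD_RSD")
  miss <- setdiff(req, names(tab))
  if (length(miss)) stop("curated table missing column(s): ",
                         paste(miss, collapse = ", "))
  parse_curated_rows(tab$KINASE, tab$SUB_ACC_ID, tab$SUB_MOD_RSD)
}

parse_curated_rows <- function(kinase, accession, mod_rsd) {
  residue <- toupper(substr(mod_rsd, 1, 1))
  position <- suppressWarnings(as.integer(substring(mod_rsd, 2)))
  ok <- residue %in% c("S", "T", "Y") & !is.na(position) & position >= 1
  out <- data.frame(kinase = kinase[ok], accession = accession[ok],
                    residue = residue[ok], position = position[ok],
                    stringsAsFactors = FALSE)
  n_skipped <- sum(!ok)
  if (n_skipped) message(n_skipped, " curated row(s) skipped (malformed position)")
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Read a kinase-substrate prediction score table
#'
#' Expected columns: `kinase`, `accession`, `residue`, `position`, `score`.
#'
#' @param path TSV path.
#' @export
read_predictions_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("kinase", "accession", "residue", "position", "score")
  miss <- setdiff(req, names(tab))
  if (length(miss)) stop("prediction table missing column(s): ",
                         paste(miss, collapse = ", "))
  tab
}

#' Read a drug screen table
#'
#' Columns: `drug_id`, `entry_id`, then one response column per sample
#' (percent viability, or IC50 for external cohorts).  Entries sharing a
#' `drug_id` represent repeated screen entries of the same drug.
#'
#' @param path TSV path.
#' @export
read_drug_screen <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  miss <- setdiff(c("drug_id", "entry_id"), names(tab))
  if (length(miss)) stop("drug screen missing column(s): ",
                         paste(miss, collapse = ", "))
  tab
}

#' Write a drug screen table
#' @param screen drug screen data.frame.
#' @param path output path.
#' @export
write_drug_screen <- function(screen, path) {
  utils::write.table(screen, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write the provenance record of an AbundanceMatrix as JSON
#' @param am an `AbundanceMatrix`.
#' @param path output path.
#' @export
write_provenance <- function(am, path) {
  jsonlite::write_json(am$provenance, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
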