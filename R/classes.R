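# Core containers: AbundanceMatrix (features x samples with plex/channel
# metadata) and helpers.  Quantification tables are plain data.frames with a
# documented column contract (see `validate_quant_table`).

QUANT_META_COLS <- c(
  "peptide_id", "peptide_sequence", "species", "master_proteins",
  "id_score", "plex_id", "phospho_positions", "localization_ambiguous"
)

#' Construct an AbundanceMatrix
#'
#' A features-by-samples numeric matrix with per-sample plex/channel
#' metadata and a provenance list that accumulates every scale factor and
#' filter count applied downstream.
#'
#' @param values numeric matrix; rownames are feature ids (protein
#'   accessions or phosphosite keys), colnames are sample ids.
#' @param samples data.frame with columns `sample_id`, `plex_id`,
#'   `channel_id`, `is_reference` (one row per column of `values`).
#' @param provenance named list of processing records.
#' @return an object of class `AbundanceMatrix`.
#' @export
abundance_matrix <- function(values, samples, provenance = list()) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)))
    stop("`values` must carry feature ids as rownames")
  if (anyDuplicated(rownames(values)))
    stop("feature ids must be unique")
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  req <- c("sample_id", "plex_id", "channel_id", "is_reference")
  miss <- setdiff(req, names(samples))
  if (length(miss))
    stop("samples metadata is missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(colnames(values))) colnames(values) <- samples$sample_id
  if (nrow(samples) != ncol(values) ||
      !identical(colnames(values), as.character(samples$sample_id)))
    stop("samples metadata must match the matrix columns (same ids, same order)")
  ref_per_plex <- tapply(samples$is_reference, samples$plex_id, sum)
  if (any(ref_per_plex > 1))
    stop("at most one reference sample per plex is allowed")
  structure(
    list(values = values, samples = samples, provenance = provenance),
    class = "AbundanceMatrix"
  )
}

#' @export
print.AbundanceMatrix <- function(x, ...) {
  nref <- sum(x$samples$is_reference)
  cat(sprintf(
    "AbundanceMatrix: %d features x %d samples (%d plex(es), %d reference channel(s))\n",
    nrow(x$values), ncol(x$values),
    length(unique(x$samples$plex_id)), nref
  ))
  cat(sprintf("missing: %.1f%%\n", 100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.AbundanceMatrix <- function(x) dim(x$values)

#' Extract the numeric matrix of an AbundanceMatrix
#' @param am an `AbundanceMatrix`.
#' @export
am_values <- function(am) am$values

#' Extract the sample metadata of an AbundanceMatrix
#' @param am an `AbundanceMatrix`.
#' @export
am_samples <- function(am) am$samples

am_is <- function(x) inherits(x, "AbundanceMatrix")

add_provenance <- function(am, name, value) {
  am$provenance[[name]] <- value
  am
}

#' Drop reference channels from an AbundanceMatrix
#'
#' Reference channels carry the pooled internal standard; after IRS they are
#' no longer analytically useful and are removed before statistics.
#'
#' @param am an `AbundanceMatrix`.
#' @export
drop_reference <- function(am) {
  keep <- !am$samples$is_reference
  abundance_matrix(am$values[, keep, drop = FALSE],
                   am$samples[keep, , drop = FALSE],
                   am$provenance)
}

#' Subset an AbundanceMatrix by feature
#' @param am an `AbundanceMatrix`.
#' @param features character vector of feature ids or logical/integer index.
#' @export
subset_features <- function(am, features) {
  abundance_matrix(am$values[features, , drop = FALSE], am$samples,
                   am$provenance)
}

#' log2-transform an AbundanceMatrix
#'
#' Non-positive values (possible after aggressive scaling of near-zero
#' intensities) are set to missing with a recorded count.
#'
#' @param am an `AbundanceMatrix` on the linear intensity scale.
#' @export
log2_transform <- function(am) {
  v <- am$values
  bad <- !is.na(v) & v <= 0
  if (any(bad)) v[bad] <- NA_real_
  am$values <- log2(v)
  add_provenance(am, "log2_nonpositive_masked", sum(bad))
}

#' Combine per-plex AbundanceMatrices into one multi-plex matrix
#'
#' Features are matched by id (union); a feature absent from a plex is
#' missing in that plex's columns.
#'
#' @param mats list of `AbundanceMatrix`, one per plex.
#' @export
combine_plexes <- function(mats) {
  stopifnot(length(mats) >= 1L, all(vapply(mats, am_is, logical(1))))
  if (length(mats) == 1L) return(mats[[1L]])
  feats <- unique(unlist(lapply(mats, function(m) rownames(m$values))))
  blocks <- lapply(mats, function(m) {
    out <- matrix(NA_real_, length(feats), ncol(m$values),
                  dimnames = list(feats, colnames(m$values)))
    out[rownames(m$values), ] <- m$values
    out
  })
  values <- do.call(cbind, blocks)
  samples <- do.call(rbind, lapply(mats, am_samples))
  rownames(samples) <- NULL
  prov <- do.call(c, lapply(mats, function(m) m$provenance))
  abundance_matrix(values, samples, as.list(prov))
}

#' Per-feature missing fraction over analytic (non-reference) samples
#' @param am an `AbundanceMatrix`.
#' @export
feature_missing_frac <- function(am) {
  keep <- !am$samples$is_reference
  rowMeans(is.na(am$values[, keep, drop = FALSE]))
}

#' Validate a peptide quantification table
#'
#' A quantification table is a data.frame with the metadata columns
#' `peptide_id`, `peptide_sequence`, `species` (human/mouse/shared),
#' `master_proteins` (";"-separated accessions), `id_score`, `plex_id`,
#' `phospho_positions` (";"-separated residue+position tokens such as
#' `"S15"`, empty for unmodified peptides), `localization_ambiguous`
#' (logical), plus one numeric abundance column per reporter channel.
#'
#' @param table a data.frame.
#' @param require list of required metadata columns (defaults to all).
#' @return the table, invisibly, or an error describing the violation.
#' @export
validate_quant_table <- function(table, require = QUANT_META_COLS) {
  if (!is.data.frame(table)) stop("quant table must be a data.frame")
  miss <- setdiff(require, names(table))
  if (length(miss))
    stop("quant table is missing column(s): ", paste(miss, collapse = ", "))
  ab <- quant_channel_cols(table)
  if (length(ab)) {
    vals <- as.matrix(table[, ab, drop = FALSE])
    if (any(vals < 0, na.rm = TRUE)) stop("abundances must be nonnegative")
  }
  invisible(table)
}

#' Names of the abundance (reporter channel) columns of a quant table
#' @param table a quant table data.frame.
#' @export
quant_channel_cols <- function(table) {
  cand <- setdiff(names(table), QUANT_META_COLS)
  cand[vapply(table[cand], is.numeric, logical(1))]
}

#' Build an AbundanceMatrix directly from feature rows of a quant table
#'
#' Internal workhorse shared by protein rollup and phosphopeptide matrix
#' construction: aggregates abundance columns over a feature grouping with
#' missing values ignored (all-missing stays missing).
#'
#' @noRd
aggregate_quant <- function(values, groups, fun = c("sum", "mean")) {
  fun <- match.arg(fun)
  obs <- !is.na(values)
  v0 <- values
  v0[!obs] <- 0
  sums <- rowsum(v0, groups)
  counts <- rowsum(obs + 0, groups)
  out <- if (fun == "sum") sums else sums / counts
  out[counts == 0] <- NA_real_
  out
}
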