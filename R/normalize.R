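# Filtering, rollup and the three-stage cross-plex normalization
# (sample loading -> internal reference standard -> trimmed mean of
# M-values) for multi-plex TMT reporter-intensity matrices.

#' Retain only human-unique peptides
#'
#' PDX samples mix human tumor with mouse stroma; only peptides unique to
#' the human proteome are quantitatively interpretable.  Row order is
#' preserved.
#'
#' @param table a quant table with a populated `species` column.
#' @export
filter_human_unique <- function(table) {
  if (!is.data.frame(table) || !("species" %in% names(table)))
    stop("quant table must carry a `species` column")
  table[!is.na(table$species) & table$species == "human", , drop = FALSE]
}

#' Roll peptide abundances up to protein abundances
#'
#' Per protein and channel, the protein abundance is the sum of its
#' peptides' reporter intensities (missing values ignored; all-missing
#' stays missing).  Peptides with more than one master protein are
#' excluded.  The table should already be human-filtered.
#'
#' @param table a single-plex quant table.
#' @param samples sample metadata data.frame covering (at least) this
#'   table's abundance columns.
#' @return an `AbundanceMatrix` keyed by protein accession.
#' @export
rollup_proteins <- function(table, samples) {
  validate_quant_table(table, require = c("master_proteins"))
  multi <- grepl(";", table$master_proteins, fixed = TRUE)
  tab <- table[!multi, , drop = FALSE]
  ab_cols <- quant_channel_cols(tab)
  values <- as.matrix(tab[, ab_cols, drop = FALSE])
  agg <- aggregate_quant(values, tab$master_proteins, "sum")
  smp <- samples[match(ab_cols, samples$sample_id), , drop = FALSE]
  if (anyNA(smp$sample_id))
    stop("sample metadata does not cover all abundance columns")
  rownames(smp) <- NULL
  abundance_matrix(agg, smp,
                   provenance = list(rollup_excluded_multimaster = sum(multi)))
}

#' Remove features with too much missing data
#'
#' Features whose missing fraction over analytic (non-reference) samples is
#' greater than or equal to `max_missing_frac` are removed (a feature
#' missing in exactly half the samples is removed).
#'
#' @param am an `AbundanceMatrix`.
#' @param max_missing_frac removal threshold, in (0, 1].
#' @export
filter_missing <- function(am, max_missing_frac = 0.5) {
  stopifnot(am_is(am), max_missing_frac > 0, max_missing_frac <= 1)
  frac <- feature_missing_frac(am)
  keep <- frac < max_missing_frac
  out <- subset_features(am, keep)
  add_provenance(out, "missing_filter",
                 list(threshold = max_missing_frac, removed = sum(!keep)))
}

#' Sample-loading (SL) normalization
#'
#' Within each plex, every column (including the reference channel) is
#' scaled so that its sum of observed intensities equals the plex's mean
#' column sum, equalizing total reporter signal per channel.
#'
#' @param am an `AbundanceMatrix` on the linear intensity scale.
#' @export
normalize_sl <- function(am) {
  stopifnot(am_is(am))
  v <- am$values
  factors <- stats::setNames(numeric(ncol(v)), colnames(v))
  for (px in unique(am$samples$plex_id)) {
    cols <- which(am$samples$plex_id == px)
    sums <- colSums(v[, cols, drop = FALSE], na.rm = TRUE)
    if (any(sums == 0))
      stop("column(s) with zero total intensity: ",
           paste(colnames(v)[cols][sums == 0], collapse = ", "))
    factors[cols] <- mean(sums) / sums
    v[, cols] <- sweep(v[, cols, drop = FALSE], 2, factors[cols], `*`)
  }
  am$values <- v
  add_provenance(am, "sl_factors", as.list(factors))
}

#' Internal reference standard (IRS) normalization
#'
#' Per feature, the geometric mean of its reference-channel values across
#' plexes defines the cross-plex consensus; each plex's columns are scaled
#' for that feature by consensus / (reference value in that plex).  After
#' the operation every feature's reference values agree across plexes, and
#' applying IRS twice equals applying it once.  Features absent from (or
#' zero in) any plex's reference channel are dropped with a logged count.
#'
#' @param am a combined multi-plex `AbundanceMatrix` with one reference
#'   channel per plex, or a list of per-plex matrices (combined first).
#' @return the combined, IRS-normalized `AbundanceMatrix` (reference
#'   channels retained; see [drop_reference()]).
#' @export
normalize_irs <- function(am) {
  if (is.list(am) && !am_is(am)) am <- combine_plexes(am)
  stopifnot(am_is(am))
  plexes <- unique(am$samples$plex_id)
  ref_cols <- vapply(plexes, function(px) {
    i <- which(am$samples$plex_id == px & am$samples$is_reference)
    if (length(i) != 1L)
      stop("plex ", px, " must have exactly one reference channel for IRS")
    i
  }, integer(1))
  refs <- am$values[, ref_cols, drop = FALSE]     # features x plexes
  bad <- apply(refs, 1, function(r) any(is.na(r) | r <= 0))
  if (any(bad)) {
    am <- subset_features(am, !bad)
    refs <- refs[!bad, , drop = FALSE]
  }
  consensus <- apply(refs, 1, geo_mean)
  v <- am$values
  for (q in seq_along(plexes)) {
    cols <- am$samples$plex_id == plexes[q]
    fac <- consensus / refs[, q]
    v[, cols] <- v[, cols, drop = FALSE] * fac
  }
  am$values <- v
  add_provenance(am, "irs",
                 list(dropped_features = sum(bad), n_plexes = length(plexes)))
}

# Trimmed-mean scale factor of one column against the reference column,
# following the standard TMM recipe: double-trim on M (log2 ratio) and A
# (log2 average), precision weights from the delta-method variance of M.
tmm_column_factor <- function(x, ref, trim_m, trim_a) {
  ok <- !is.na(x) & !is.na(ref) & x > 0 & ref > 0
  x <- x[ok]; ref <- ref[ok]
  if (length(x) == 0L) return(1)
  m <- log2(x / ref)
  a <- 0.5 * log2(x * ref)
  w <- 1 / (1 / x + 1 / ref)
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  rm <- rank(m, ties.method = "first")
  ra <- rank(a, ties.method = "first")
  keep <- rm >= lo_m & rm <= hi_m & ra >= lo_a & ra <= hi_a
  if (!any(keep)) return(1)
  2^(sum(w[keep] * m[keep]) / sum(w[keep]))
}

#' Trimmed mean of M-values (TMM) normalization
#'
#' Computes one scale factor per analytic column as 2^(weighted trimmed
#' mean of the log2 column-to-reference-column ratios), trimming the
#' `trim_m` most extreme M values and `trim_a` most extreme A values on
#' each side, with inverse-variance weights.  The reference column is the
#' one whose upper quartile of observed intensities is closest to the mean
#' upper quartile.  Factors are normalized to geometric mean 1 and columns
#' are divided by their factor.  Reference (IRS) channels are left
#' untouched.
#'
#' @param am an `AbundanceMatrix` (positive intensities where observed).
#' @param trim_m two-sided trim fraction on M (log-ratio) values.
#' @param trim_a two-sided trim fraction on A (log-average) values.
#' @export
normalize_tmm <- function(am, trim_m = 0.30, trim_a = 0.05) {
  stopifnot(am_is(am))
  cols <- which(!am$samples$is_reference)
  if (length(cols) < 2L) {
    warning("fewer than 2 analytic columns: TMM skipped")
    return(am)
  }
  v <- am$values[, cols, drop = FALSE]
  uq <- apply(v, 2, function(x) stats::quantile(x[!is.na(x) & x > 0], 0.75))
  ref_idx <- which.min(abs(uq - mean(uq)))
  factors <- vapply(seq_len(ncol(v)), function(j)
    tmm_column_factor(v[, j], v[, ref_idx], trim_m, trim_a), numeric(1))
  factors <- factors / geo_mean(factors)
  names(factors) <- colnames(v)
  am$values[, cols] <- sweep(v, 2, factors, `/`)
  add_provenance(am, "tmm",
                 list(factors = as.list(factors),
                      reference_column = colnames(v)[ref_idx],
                      trim_m = trim_m, trim_a = trim_a))
}

#' Filter phosphopeptides on score, localization and protein assignment
#'
#' Retains peptides that (i) carry at least one phosphosite, (ii) are
#' localization-unambiguous in every plex, (iii) map to exactly one master
#' protein, and (iv) have an identification score strictly greater than
#' `min_score` in at least one plex (evaluated on the best per-plex score
#' supporting the peptide).
#'
#' @param tables a list of per-plex quant tables (or a single table).
#' @param min_score score threshold (strict inequality).
#' @return the filtered tables in the same shape, row order preserved.
#' @export
filter_phosphopeptides <- function(tables, min_score = 200) {
  single <- is.data.frame(tables)
  if (single) tables <- list(tables)
  for (t in tables)
    validate_quant_table(t, require = c("peptide_sequence", "master_proteins",
                                        "id_score", "phospho_positions",
                                        "localization_ambiguous"))
  key <- function(t) paste(t$peptide_sequence, t$master_proteins,
                           t$phospho_positions, sep = "|")
  long <- do.call(rbind, lapply(tables, function(t)
    data.frame(key = key(t), score = t$id_score,
               ambiguous = t$localization_ambiguous,
               stringsAsFactors = FALSE)))
  best <- tapply(long$score, long$key, max, na.rm = TRUE)
  any_ambiguous <- tapply(long$ambiguous, long$key, any)
  keep_key <- names(best)[best > min_score & !any_ambiguous[names(best)]]
  out <- lapply(tables, function(t) {
    k <- key(t)
    keep <- k %in% keep_key &
      nzchar(t$phospho_positions) &
      !grepl(";", t$master_proteins, fixed = TRUE)
    t[keep, , drop = FALSE]
  })
  if (single) out[[1]] else out
}

#' Phosphopeptide-level AbundanceMatrix and peptide-to-site map
#'
#' Builds a multi-plex peptide matrix (feature = peptide key) from filtered
#' per-plex phosphopeptide tables, plus the expansion of each peptide into
#' the phosphosites it carries (`ACCESSION_RESPOS` keys; a multiply
#' phosphorylated peptide maps to every one of its sites).
#'
#' @param tables list of per-plex phosphopeptide quant tables.
#' @param samples sample metadata data.frame.
#' @return list with `matrix` (an `AbundanceMatrix`) and `site_map`
#'   (data.frame feature_id, site_key).
#' @export
phospho_peptide_matrix <- function(tables, samples) {
  if (is.data.frame(tables)) tables <- list(tables)
  mats <- lapply(tables, function(t) {
    keys <- paste(t$peptide_sequence, t$master_proteins,
                  t$phospho_positions, sep = "|")
    ab_cols <- quant_channel_cols(t)
    values <- aggregate_quant(as.matrix(t[, ab_cols, drop = FALSE]), keys,
                              "mean")
    smp <- samples[match(ab_cols, samples$sample_id), , drop = FALSE]
    rownames(smp) <- NULL
    abundance_matrix(values, smp)
  })
  am <- combine_plexes(mats)
  anno <- unique(do.call(rbind, lapply(tables, function(t)
    data.frame(feature_id = paste(t$peptide_sequence, t$master_proteins,
                                  t$phospho_positions, sep = "|"),
               master = t$master_proteins, positions = t$phospho_positions,
               stringsAsFactors = FALSE))))
  toks <- strsplit(anno$positions, ";", fixed = TRUE)
  site_map <- data.frame(
    feature_id = rep(anno$feature_id, lengths(toks)),
    site_key = paste(rep(anno$master, lengths(toks)),
                     unlist(toks), sep = "_"),
    stringsAsFactors = FALSE
  )
  site_map <- unique(site_map)
  list(matrix = am, site_map = site_map)
}

#' Condense a phosphopeptide matrix to phosphosites
#'
#' Per site and sample, the site abundance is the arithmetic mean over all
#' peptides carrying that site (missing ignored); multiply-phosphorylated
#' peptides contribute to each of their sites.  Run this after
#' normalization: site values are means of normalized peptide abundances.
#'
#' @param am phosphopeptide-level `AbundanceMatrix`.
#' @param site_map data.frame (feature_id, site_key) from
#'   [phospho_peptide_matrix()].
#' @return an `AbundanceMatrix` keyed by phosphosite.
#' @export
condense_phosphosites <- function(am, site_map) {
  stopifnot(am_is(am), all(c("feature_id", "site_key") %in% names(site_map)))
  map <- site_map[site_map$feature_id %in% rownames(am$values), , drop = FALSE]
  expanded <- am$values[map$feature_id, , drop = FALSE]
  values <- aggregate_quant(expanded, map$site_key, "mean")
  abundance_matrix(values, am$samples, am$provenance)
}

#' Flag outlier samples by principal-component distance and missingness
#'
#' Advisory quality-control flags: a sample is flagged if its Euclidean
#' distance from the centroid in the first two principal components (on
#' complete, log2-scale features) exceeds `sd_mult` times the median
#' distance, or if its missing fraction exceeds the `miss_quantile`
#' quantile of all samples' missing fractions by more than `miss_excess`.
#' Exclusion remains a caller decision.
#'
#' @param am an `AbundanceMatrix` of log2 abundances.
#' @param sd_mult multiplier of the median PC distance.
#' @param miss_quantile quantile of per-sample missing fractions.
#' @param miss_excess minimum absolute excess over that quantile.
#' @return data.frame with per-sample distances, missing fractions and
#'   flags.
#' @export
detect_outliers <- function(am, sd_mult = 3, miss_quantile = 0.75,
                            miss_excess = 0.1) {
  stopifnot(am_is(am))
  keep <- !am$samples$is_reference
  v <- am$values[, keep, drop = FALSE]
  if (ncol(v) < 3L) stop("outlier detection needs at least 3 samples")
  complete <- v[stats::complete.cases(v), , drop = FALSE]
  pc_dist <- rep(0, ncol(v))
  if (nrow(complete) >= 2L) {
    pcs <- stats::prcomp(t(complete), center = TRUE, scale. = FALSE)
    k <- min(2L, ncol(pcs$x))
    sc <- pcs$x[, seq_len(k), drop = FALSE]
    ctr <- colMeans(sc)
    pc_dist <- sqrt(rowSums(sweep(sc, 2, ctr)^2))
  }
  miss <- colMeans(is.na(v))
  flagged_pc <- pc_dist > sd_mult * stats::median(pc_dist)
  thr <- stats::quantile(miss, miss_quantile) + miss_excess
  flagged_miss <- miss > thr
  data.frame(
    sample_id = colnames(v),
    pc_distance = pc_dist,
    missing_frac = miss,
    flagged_pc = flagged_pc,
    flagged_missing = flagged_miss,
    flagged = flagged_pc | flagged_miss,
    row.names = NULL, stringsAsFactors = FALSE
  )
}
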