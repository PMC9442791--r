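# Drug-sensitivity correlation signatures: matched-pair Spearman
# correlation of basal abundance with drug response, median over duplicate
# screen entries, top-k signature extraction, per-sample ssGSEA scoring of
# the signature, and extreme-group comparison in external cohorts.

#' Correlate feature abundance with drug response
#'
#' Per screen entry and feature, computes the Spearman correlation on
#' matched (abundance, response) pairs, after removing excluded samples
#' and pairwise-deleting missing values.  Reported values are oriented to
#' sensitivity: `correlation-to-sensitivity = -(rho vs viability)`, so
#' features abundant in sensitive (low-viability) lines score positive.
#' Features with fewer than `min_pairs` matched pairs or zero rank
#' variance are undefined (NA).
#'
#' @param x `AbundanceMatrix` (log2 or linear; Spearman is rank-based) or
#'   numeric features x samples matrix.
#' @param screen drug screen data.frame (`drug_id`, `entry_id`, one
#'   response column per sample).
#' @param excluded_samples sample ids to drop (e.g. flagged outliers).
#' @param min_pairs minimum matched pairs per feature.
#' @return list: `corr` (features x entries matrix of
#'   correlation-to-sensitivity), `entries` (data.frame entry_id, drug_id,
#'   n_matched).
#' @export
correlate_response <- function(x, screen, excluded_samples = character(),
                               min_pairs = 4) {
  if (am_is(x)) x <- x$values[, !x$samples$is_reference, drop = FALSE]
  stopifnot(is.matrix(x), all(c("drug_id", "entry_id") %in% names(screen)))
  resp_cols <- setdiff(names(screen), c("drug_id", "entry_id"))
  common <- setdiff(intersect(colnames(x), resp_cols), excluded_samples)
  if (length(common) == 0L)
    stop("no overlapping samples between abundance matrix and drug screen")
  corr <- matrix(NA_real_, nrow(x), nrow(screen),
                 dimnames = list(rownames(x), screen$entry_id))
  n_matched <- integer(nrow(screen))
  for (e in seq_len(nrow(screen))) {
    y <- as.numeric(screen[e, common])
    names(y) <- common
    ok_y <- !is.na(y)
    n_matched[e] <- sum(ok_y)
    if (sum(ok_y) < min_pairs) next
    sub <- x[, common[ok_y], drop = FALSE]
    rho <- suppressWarnings(
      stats::cor(t(sub), y[ok_y], method = "spearman",
                 use = "pairwise.complete.obs"))[, 1]
    pairs <- rowSums(!is.na(sub))
    rho[pairs < min_pairs] <- NA_real_
    corr[, e] <- -rho
  }
  list(corr = corr,
       entries = data.frame(entry_id = screen$entry_id,
                            drug_id = screen$drug_id,
                            n_matched = n_matched,
                            stringsAsFactors = FALSE))
}

#' Median correlation over a drug's duplicate screen entries
#'
#' @param correlations result of [correlate_response()].
#' @param drug drug id with at least one screen entry.
#' @return named vector of per-feature median correlation-to-sensitivity.
#' @export
median_over_entries <- function(correlations, drug) {
  entries <- correlations$entries
  sel <- entries$drug_id == drug
  if (!any(sel)) stop("no screen entry for drug ", drug)
  sub <- correlations$corr[, entries$entry_id[sel], drop = FALSE]
  apply(sub, 1, stats::median, na.rm = TRUE)
}

#' Extract the top-k sensitivity signature
#'
#' The `k` features with the largest correlation-to-sensitivity; undefined
#' correlations are dropped and boundary ties are broken lexicographically
#' by feature id for determinism.
#'
#' @param correlations named numeric vector (e.g. from
#'   [median_over_entries()]).
#' @param k signature size.
#' @return ordered character vector of signature members (length <= k).
#' @export
extract_signature <- function(correlations, k = 100) {
  correlations <- correlations[!is.na(correlations)]
  if (length(correlations) < k)
    warning("fewer than k = ", k, " features with defined correlation; ",
            "returning all ", length(correlations))
  ord <- order(-correlations, names(correlations))
  names(correlations)[ord][seq_len(min(k, length(correlations)))]
}

#' Score a signature across samples by ssGSEA
#'
#' Per sample, the signature's single-sample enrichment score on that
#' sample's feature profile, with a permutation-normalized NES.
#'
#' @param x `AbundanceMatrix` or numeric features x samples matrix.
#' @param signature character vector of signature members.
#' @param alpha ssGSEA weighting exponent.
#' @param n_perm random same-size sets per sample for NES normalization.
#' @param seed RNG seed.
#' @return data.frame: sample, es, nes.
#' @export
score_signature <- function(x, signature, alpha = 0.75, n_perm = 200,
                            seed = 1L) {
  sets <- list(signature = signature)
  r <- ssgsea_matrix(x, sets, alpha = alpha, nes = "permutation",
                     n_perm = n_perm, seed = seed)
  data.frame(sample = colnames(r$es), es = r$es[1, ], nes = r$nes[1, ],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare drug response between extreme signature-score groups
#'
#' Two-sided t-test (unequal-variance by default) of the response between
#' the top `n_extreme` and bottom `n_extreme` lines ranked by a score
#' (signature NES, or any per-line value such as a single protein's
#' abundance).
#'
#' @param scores named numeric vector of per-line scores.
#' @param response named numeric vector of per-line response (e.g. IC50),
#'   matched to `scores` by name.
#' @param n_extreme group size.
#' @param var_equal use the pooled-variance form.
#' @return list: `t`, `p`, `mean_high`, `mean_low`, `n_extreme`.
#' @export
compare_extremes <- function(scores, response, n_extreme = 50,
                             var_equal = FALSE) {
  common <- intersect(names(scores), names(response))
  common <- common[!is.na(scores[common]) & !is.na(response[common])]
  if (length(common) < 2 * n_extreme)
    stop("cohort too small: need at least 2 x n_extreme = ",
         2 * n_extreme, " lines, have ", length(common))
  ord <- common[order(-scores[common], common)]
  high <- ord[seq_len(n_extreme)]
  low <- rev(ord)[seq_len(n_extreme)]
  ht <- stats::t.test(response[high], response[low], var.equal = var_equal)
  list(t = unname(ht$statistic), p = ht$p.value,
       mean_high = mean(response[high]), mean_low = mean(response[low]),
       n_extreme = n_extreme)
}
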