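# Enrichment scoring: single-sample GSEA (weighted running-sum area),
# ranked-list GSEA with gene-label permutation significance, and the
# hypergeometric over-representation test.

# Deterministic descending sort: ties broken by feature name.
sort_profile <- function(profile) {
  if (is.null(names(profile))) stop("profile must be a named numeric vector")
  profile[order(-profile, names(profile))]
}

#' Single-sample GSEA enrichment score
#'
#' Features are sorted by descending value.  Walking down the list, the
#' running sum increments by `|value|^alpha / sum_set |value|^alpha` at set
#' members and decrements by `1/(N - n_set)` at non-members; the enrichment
#' score is the sum of the running-sum values (the area under the walk).
#' When the set covers all features the decrement pool is empty and only
#' increments contribute.
#'
#' @param profile named numeric vector (one sample's feature values).
#' @param set character vector of member identifiers.
#' @param alpha weighting exponent on the absolute feature values.
#' @param set_name used in error messages.
#' @return list with `es`, `overlap` (members present) and `n` (profile size).
#' @export
ssgsea_score <- function(profile, set, alpha = 0.75, set_name = "gene set") {
  prof <- sort_profile(profile)
  member <- names(prof) %in% set
  n_set <- sum(member)
  if (n_set == 0L)
    stop("no member of ", set_name, " is present in the profile")
  n <- length(prof)
  wts <- abs(prof)^alpha
  inc <- wts * member / sum(wts[member])
  dec <- if (n > n_set) 1 / (n - n_set) else 0
  steps <- ifelse(member, inc, -dec)
  running <- cumsum(steps)
  list(es = sum(running), overlap = n_set, n = n)
}

#' Score a collection of gene sets on one profile (ssGSEA)
#'
#' @param profile named numeric vector.
#' @param sets named list of member vectors.
#' @param alpha weighting exponent.
#' @param nes normalization for the NES column: `"permutation"` divides the
#'   ES by the mean absolute ES of `n_perm` random same-size sets,
#'   `"range"` divides by the range of ES across the evaluated collection,
#'   `"none"` reports NA.
#' @param n_perm number of random sets per distinct set size.
#' @param seed RNG seed for the permutation normalization.
#' @return data.frame: set, es, nes, overlap.
#' @export
ssgsea_collection <- function(profile, sets, alpha = 0.75,
                              nes = c("permutation", "range", "none"),
                              n_perm = 200, seed = 1L) {
  nes <- match.arg(nes)
  res <- lapply(names(sets), function(nm)
    ssgsea_score(profile, sets[[nm]], alpha, set_name = nm))
  es <- vapply(res, `[[`, numeric(1), "es")
  overlap <- vapply(res, `[[`, numeric(1), "overlap")
  nes_val <- rep(NA_real_, length(es))
  if (nes == "permutation") {
    set.seed(seed)
    feats <- names(profile)
    for (size in unique(overlap)) {
      perm <- vapply(seq_len(n_perm), function(b)
        ssgsea_score(profile, sample(feats, size), alpha)$es, numeric(1))
      sel <- overlap == size
      nes_val[sel] <- es[sel] / mean(abs(perm))
    }
  } else if (nes == "range") {
    rg <- diff(range(es))
    if (rg > 0) nes_val <- es / rg
  }
  data.frame(set = names(sets), es = es, nes = nes_val, overlap = overlap,
             stringsAsFactors = FALSE)
}

#' Per-sample ssGSEA scores for a matrix
#'
#' @param x numeric matrix (features x samples) or `AbundanceMatrix`.
#' @param sets named list of gene sets.
#' @inheritParams ssgsea_collection
#' @return list of matrices `es` and `nes` (sets x samples).
#' @export
ssgsea_matrix <- function(x, sets, alpha = 0.75, nes = "permutation",
                          n_perm = 200, seed = 1L) {
  if (am_is(x)) x <- x$values[, !x$samples$is_reference, drop = FALSE]
  es <- nes_m <- matrix(NA_real_, length(sets), ncol(x),
                        dimnames = list(names(sets), colnames(x)))
  for (j in seq_len(ncol(x))) {
    prof <- x[, j]
    prof <- prof[!is.na(prof)]
    r <- ssgsea_collection(prof, sets, alpha, nes = nes, n_perm = n_perm,
                           seed = seed + j)
    es[, j] <- r$es
    nes_m[, j] <- r$nes
  }
  list(es = es, nes = nes_m)
}

# Classical weighted Kolmogorov-Smirnov-style ES on a pre-sorted ranked
# list given member positions.
es_ranked <- function(sorted_values, member_idx, weight = 1) {
  n <- length(sorted_values)
  hit <- numeric(n)
  w <- abs(sorted_values[member_idx])^weight
  if (sum(w) == 0) w <- rep(1, length(member_idx))
  hit[member_idx] <- w / sum(w)
  miss <- rep(1 / (n - length(member_idx)), n)
  miss[member_idx] <- 0
  running <- cumsum(hit - miss)
  running[which.max(abs(running))]
}

#' Ranked-list GSEA with gene-label permutation
#'
#' Computes the classical weighted running-sum enrichment score per set on
#' the list ranked by the signed metric (see [rank_metric()]), estimates
#' significance by permuting gene labels (random same-size sets), and
#' applies Benjamini-Hochberg across sets.
#'
#' @param ranks named numeric vector of ranking-metric values.
#' @param sets named list of gene sets.
#' @param n_perm number of permutations (a value below 100 warns).
#' @param seed RNG seed.
#' @param weight exponent on the absolute ranking values.
#' @return data.frame: set, es, nes, p, q, overlap.
#' @export
gsea_ranked <- function(ranks, sets, n_perm = 1000, seed = 1L, weight = 1) {
  if (n_perm < 100) warning("n_perm < 100 gives unstable permutation p-values")
  sorted <- sort_profile(ranks)
  set.seed(seed)
  out <- lapply(names(sets), function(nm) {
    member_idx <- which(names(sorted) %in% sets[[nm]])
    if (length(member_idx) == 0L)
      return(data.frame(set = nm, es = NA_real_, nes = NA_real_,
                        p = NA_real_, q = NA_real_, overlap = 0L))
    es <- es_ranked(sorted, member_idx, weight)
    perm <- vapply(seq_len(n_perm), function(b)
      es_ranked(sorted, sample(length(sorted), length(member_idx)), weight),
      numeric(1))
    b <- sum(abs(perm) >= abs(es))        # two-sided: |perm ES| >= |ES|
    p <- (b + 1) / (n_perm + 1)
    same <- sign(perm) == sign(es)
    denom <- if (any(same)) mean(abs(perm[same])) else mean(abs(perm))
    nes <- if (denom > 0) es / denom else NA_real_
    data.frame(set = nm, es = es, nes = nes, p = p, q = NA_real_,
               overlap = length(member_idx), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$q <- bh_adjust(res$p)
  res
}

#' Hypergeometric over-representation test
#'
#' Upper-tail hypergeometric probability of observing at least the overlap
#' between a signature and a gene set, within a stated background.
#'
#' @param signature character vector of identifiers (must be a subset of
#'   `background`).
#' @param set character vector, the gene set.
#' @param background character vector, the testable universe.
#' @return the upper-tail p-value (an overlap of zero gives p = 1).
#' @export
hypergeom_ora <- function(signature, set, background) {
  signature <- unique(signature)
  background <- unique(background)
  if (!all(signature %in% background))
    stop("signature must be a subset of the background")
  set_in_bg <- unique(set[set %in% background])
  k <- sum(signature %in% set_in_bg)
  stats::phyper(k - 1, length(set_in_bg),
                length(background) - length(set_in_bg),
                length(signature), lower.tail = FALSE)
}
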