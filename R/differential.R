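# Group-wise differential abundance: one-way fixed-effects ANOVA with
# Tukey-Kramer post-hoc per feature, Benjamini-Hochberg across features,
# and the signed -log10(p) ranking metric feeding enrichment.

#' Benjamini-Hochberg step-up adjustment
#'
#' Hand-rolled step-up procedure (monotonicity enforced); agrees with
#' `p.adjust(method = "BH")`.  Missing values pass through.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return the adjusted q-values.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(pvalues))
  ok <- which(!is.na(pvalues))
  m <- length(ok)
  if (m == 0L) return(q)
  p <- pvalues[ok]
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q[ok] <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
  q
}

#' One-way ANOVA with Tukey post-hoc per feature
#'
#' For each feature (row), fits a one-way fixed-effects ANOVA across the
#' sample groups on log2-scale values, with Tukey-Kramer adjusted pairwise
#' comparisons, and adds Benjamini-Hochberg q-values across features.
#' Features lacking two groups with at least two non-missing values each,
#' or with zero within-group variance and zero between-group variance, are
#' reported as untested rather than erroring the run.  Missing values are
#' dropped per feature (complete-case within feature).
#'
#' @param x numeric matrix (features x samples) of log2 abundances, or an
#'   `AbundanceMatrix` already log2-transformed.
#' @param groups group label per sample (length = number of columns;
#'   for an `AbundanceMatrix`, per analytic column).
#' @return data.frame with one row per feature: `feature`, `n_used`,
#'   `untested`, `F`, `p`, `q`, per-group means `mean_<g>`, and per pair
#'   `log2fc_<a>_vs_<b>` (mean difference) and `tukey_<a>_vs_<b>`
#'   (Tukey-adjusted p).
#' @export
anova_tukey <- function(x, groups) {
  if (am_is(x)) {
    keep <- !x$samples$is_reference
    x <- x$values[, keep, drop = FALSE]
  }
  stopifnot(is.matrix(x))
  if (length(groups) != ncol(x))
    stop("`groups` must supply one label per sample column")
  glev <- unique(as.character(groups))
  if (length(glev) < 2L) stop("at least 2 groups are required")
  groups <- as.character(groups)
  pairs <- utils::combn(glev, 2)
  n_pairs <- ncol(pairs)
  pair_names <- paste0(pairs[1, ], "_vs_", pairs[2, ])

  n_feat <- nrow(x)
  Fv <- p <- rep(NA_real_, n_feat)
  n_used <- integer(n_feat)
  untested <- rep(TRUE, n_feat)
  means <- matrix(NA_real_, n_feat, length(glev),
                  dimnames = list(NULL, glev))
  lfc <- tk <- matrix(NA_real_, n_feat, n_pairs,
                      dimnames = list(NULL, pair_names))

  for (i in seq_len(n_feat)) {
    xi <- x[i, ]
    obs <- !is.na(xi)
    gi <- groups[obs]
    xi <- xi[obs]
    cnt <- table(factor(gi, levels = glev))
    use_groups <- glev[cnt >= 2]
    if (length(use_groups) < 2L) next
    sel <- gi %in% use_groups
    gi <- gi[sel]; xi <- xi[sel]
    ni <- table(factor(gi, levels = use_groups))
    mi <- tapply(xi, factor(gi, levels = use_groups), mean)
    n <- length(xi); k <- length(use_groups)
    grand <- mean(xi)
    ssb <- sum(ni * (mi - grand)^2)
    ssw <- sum((xi - mi[gi])^2)
    means[i, use_groups] <- mi
    n_used[i] <- n
    if (ssw <= 0 && ssb <= 0) next          # zero total variance: untested
    untested[i] <- FALSE
    dfw <- n - k
    msw <- ssw / dfw
    if (ssw <= 0) {
      Fv[i] <- Inf; p[i] <- 0
    } else {
      Fv[i] <- (ssb / (k - 1)) / msw
      p[i] <- stats::pf(Fv[i], k - 1, dfw, lower.tail = FALSE)
    }
    for (j in seq_len(n_pairs)) {
      a <- pairs[1, j]; b <- pairs[2, j]
      if (!(a %in% use_groups && b %in% use_groups)) next
      d <- mi[a] - mi[b]
      lfc[i, j] <- d
      if (ssw > 0) {
        se <- sqrt(msw / 2 * (1 / ni[a] + 1 / ni[b]))
        tk[i, j] <- stats::ptukey(abs(d) / se, nmeans = k, df = dfw,
                                  lower.tail = FALSE)
      } else tk[i, j] <- 0
    }
  }

  out <- data.frame(
    feature = rownames(x) %||% as.character(seq_len(n_feat)),
    n_used = n_used, untested = untested, F = Fv, p = p,
    q = bh_adjust(p), stringsAsFactors = FALSE
  )
  colnames(means) <- paste0("mean_", glev)
  colnames(lfc) <- paste0("log2fc_", pair_names)
  colnames(tk) <- paste0("tukey_", pair_names)
  cbind(out, means, lfc, tk)
}

#' Signed -log10(p) ranking metric
#'
#' The enrichment ranking metric: `-log10(p) * sign(log2fc)`; `sign(0)` is
#' 0.  Zero p-values are clamped to the smallest representable positive
#' double, with a message.
#'
#' @param p p-values in \[0, 1\].
#' @param log2fc finite log2 fold-changes (same length).
#' @return the signed ranking metric, vectorized.
#' @export
rank_metric <- function(p, log2fc) {
  if (length(p) != length(log2fc)) stop("`p` and `log2fc` must align")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  if (any(!is.finite(log2fc) & !is.na(log2fc)))
    stop("log2 fold-changes must be finite")
  zero <- !is.na(p) & p == 0
  if (any(zero)) {
    message(sum(zero), " zero p-value(s) clamped to the smallest positive double")
    p[zero] <- .Machine$double.xmin
  }
  -log10(p) * sign(log2fc)
}
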