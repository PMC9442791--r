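# Independent brute-force oracles.  These deliberately use plain loops and
# elementary arithmetic, separate from the package implementations they
# check.

# Step-by-step ssGSEA running sum.
bf_ssgsea <- function(profile, set, alpha) {
  ord <- order(-profile, names(profile))
  v <- profile[ord]
  ids <- names(profile)[ord]
  in_set <- ids %in% set
  n <- length(v)
  n_set <- sum(in_set)
  denom_in <- sum(abs(v[in_set])^alpha)
  running <- 0
  total <- 0
  for (i in seq_len(n)) {
    if (in_set[i]) {
      running <- running + abs(v[i])^alpha / denom_in
    } else {
      running <- running - 1 / (n - n_set)
    }
    total <- total + running
  }
  unname(total)
}

# Direct trimmed-mean TMM factor (mirrors the documented formula with
# naive loops; no shared code with the package).
bf_tmm_factor <- function(x, ref, trim_m = 0.30, trim_a = 0.05) {
  keep <- !is.na(x) & !is.na(ref) & x > 0 & ref > 0
  x <- x[keep]; ref <- ref[keep]
  m <- log2(x / ref)
  a <- 0.5 * log2(x * ref)
  w <- 1 / (1 / x + 1 / ref)
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  rm_ <- rank(m, ties.method = "first")
  ra_ <- rank(a, ties.method = "first")
  sel <- rm_ >= lo_m & rm_ <= hi_m & ra_ >= lo_a & ra_ <= hi_a
  if (!any(sel)) return(1)
  2^(sum(w[sel] * m[sel]) / sum(w[sel]))
}

# Confusion-matrix recount at one threshold.
bf_confusion <- function(scores, is_curated, t) {
  tp <- fn <- tn <- fp <- 0L
  for (i in seq_along(scores)) {
    if (is_curated[i]) {
      if (scores[i] > t) tp <- tp + 1L else fn <- fn + 1L
    } else {
      if (scores[i] > t) fp <- fp + 1L else tn <- tn + 1L
    }
  }
  c(TP = tp, FN = fn, TN = tn, FP = fp)
}

bf_mcc <- function(cm) {
  cm <- as.double(cm)
  names(cm) <- c("TP", "FN", "TN", "FP")
  tp <- cm["TP"]; fn <- cm["FN"]; tn <- cm["TN"]; fp <- cm["FP"]
  d <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (d == 0) return(0)
  unname((tp * tn - fp * fn) / sqrt(d))
}

# Row-by-row protein accumulation (sum of single-master peptides).
bf_rollup <- function(table) {
  ab_cols <- quant_channel_cols(table)
  acc <- list()
  for (i in seq_len(nrow(table))) {
    if (grepl(";", table$master_proteins[i], fixed = TRUE)) next
    p <- table$master_proteins[i]
    if (is.null(acc[[p]])) acc[[p]] <- rep(NA_real_, length(ab_cols))
    for (j in seq_along(ab_cols)) {
      v <- table[[ab_cols[j]]][i]
      if (!is.na(v))
        acc[[p]][j] <- if (is.na(acc[[p]][j])) v else acc[[p]][j] + v
    }
  }
  out <- do.call(rbind, acc)
  colnames(out) <- ab_cols
  out[sort(rownames(out)), , drop = FALSE]
}

# Spearman rho via explicit average ranks (handles ties by hand).
bf_spearman <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v))
      r[i] <- (sum(v < v[i]) + 1 + sum(v <= v[i])) / 2
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}
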