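# quant_norm module: filtering, rollup, SL/IRS/TMM, phosphopeptide
# handling, outlier QC.

test_that("filter_human_unique keeps exactly the human rows, in order", {
  ab <- matrix(1:6, 3, 2, dimnames = list(NULL, c("S1", "S2")))
  tab <- make_quant_table(ab, species = c("human", "mouse", "shared"))
  out <- filter_human_unique(tab)
  expect_equal(out$peptide_id, "PEP0001")
  all_h <- make_quant_table(ab, species = "human")
  expect_equal(filter_human_unique(all_h), all_h)
  expect_equal(nrow(filter_human_unique(all_h[0, ])), 0L)
  expect_error(filter_human_unique(all_h[, setdiff(names(all_h), "species")]),
               "species")
})

test_that("rollup_proteins sums peptides per protein and channel", {
  ab <- matrix(c(10, 5, 7,
                 2, NA, 3), ncol = 2,
               dimnames = list(NULL, c("S1", "S2")))
  tab <- make_quant_table(ab, master = c("P1", "P1", "P2"))
  samples <- data.frame(sample_id = c("S1", "S2"), plex_id = "plex1",
                        channel_id = c("c1", "c2"), is_reference = FALSE)
  am <- rollup_proteins(tab, samples)
  expect_equal(am$values["P1", "S1"], 15)       # 10 + 5
  expect_equal(am$values["P1", "S2"], 2)        # NA ignored
  expect_equal(am$values["P2", "S1"], 7)        # single peptide passthrough
  # multi-master peptides are excluded
  tab2 <- make_quant_table(ab, master = c("P1", "P1;P2", "P2"))
  am2 <- rollup_proteins(tab2, samples)
  expect_equal(am2$values["P1", "S1"], 10)
  expect_equal(am2$provenance$rollup_excluded_multimaster, 1L)
  # all-missing stays missing
  ab3 <- matrix(c(NA, NA, 1, 2), 2, 2, byrow = TRUE,
                dimnames = list(NULL, c("S1", "S2")))
  am3 <- rollup_proteins(make_quant_table(ab3, master = c("P1", "P1")), samples)
  expect_equal(unname(am3$values["P1", ]), c(1, 2))
})

test_that("rollup matches a brute-force row-by-row accumulation", {
  set.seed(11)
  ab <- matrix(round(runif(15, 1, 100)), 5, 3,
               dimnames = list(NULL, c("S1", "S2", "S3")))
  ab[sample(15, 3)] <- NA
  tab <- make_quant_table(ab, master = c("P1", "P2", "P1", "P2", "P1"))
  samples <- data.frame(sample_id = colnames(ab), plex_id = "plex1",
                        channel_id = colnames(ab), is_reference = FALSE)
  am <- rollup_proteins(tab, samples)
  oracle <- bf_rollup(tab)
  expect_equal(am$values[rownames(oracle), ], oracle)
})

test_that("filter_missing removes features at or above the threshold", {
  v <- matrix(1, 3, 20, dimnames = list(c("half", "nine", "full"), NULL))
  v["half", 1:10] <- NA    # 10/20 -> removed (boundary inclusive)
  v["nine", 1:9] <- NA     # 9/20  -> retained
  am <- make_am(v)
  out <- filter_missing(am, 0.5)
  expect_setequal(rownames(out$values), c("nine", "full"))
  full <- make_am(matrix(1:12, 3, 4))
  expect_equal(rownames(filter_missing(full)$values), rownames(full$values))
})

test_that("normalize_sl equalizes within-plex column sums", {
  v <- matrix(c(50, 50, 100, 100, 150, 150), 2, 3)
  am <- make_am(v)
  out <- normalize_sl(am)
  expect_equal(unname(colSums(out$values)), rep(200, 3), tolerance = 1e-12)
  # hand-computed factors: mean-sum / column-sum = 2, 1, 2/3
  expect_equal(out$values[1, 1], 50 * 2)
  expect_equal(out$values[1, 3], 150 * 2 / 3)
  # equal sums -> identity
  eq <- make_am(matrix(c(1, 3, 2, 2), 2, 2))
  expect_equal(normalize_sl(eq)$values, eq$values)
  # zero column errors with its name
  z <- make_am(matrix(c(1, 1, 0, 0), 2, 2,
                      dimnames = list(NULL, c("ok", "dead"))))
  expect_error(normalize_sl(z), "dead")
})

test_that("SL scales each plex independently and preserves the mask", {
  set.seed(2)
  v <- matrix(rlnorm(40, 10), 5, 8)
  v[sample(40, 6)] <- NA
  am <- make_am(v, plex = rep(c("plex1", "plex2"), each = 4))
  out <- normalize_sl(am)
  for (px in c("plex1", "plex2")) {
    cols <- am$samples$plex_id == px
    s <- colSums(out$values[, cols], na.rm = TRUE)
    expect_lt(diff(range(s)) / mean(s), 1e-9)
  }
  expect_identical(is.na(out$values), is.na(am$values))
})

test_that("normalize_irs equalizes reference values by geometric means", {
  # two plexes, refs 4 and 16 -> geometric mean 8, factors 2 and 0.5
  v <- matrix(c(2, 4, 8, 16), 1, 4,
              dimnames = list("F1", c("a", "ref1", "b", "ref2")))
  am <- abundance_matrix(v, data.frame(
    sample_id = colnames(v), plex_id = c("p1", "p1", "p2", "p2"),
    channel_id = c("c1", "c2", "c1", "c2"),
    is_reference = c(FALSE, TRUE, FALSE, TRUE)))
  out <- normalize_irs(am)
  expect_equal(unname(out$values["F1", ]), c(4, 8, 4, 8))
  # single plex: identity
  one <- make_am(matrix(c(1, 2, 3, 4), 2, 2), ref = c(FALSE, TRUE))
  expect_equal(normalize_irs(one)$values, one$values)
})

test_that("IRS reference equality and idempotence hold on random input", {
  set.seed(5)
  mats <- lapply(1:3, function(q) {
    v <- matrix(rlnorm(40, 8), 10, 4)
    make_am(v, plex = sprintf("plex%d", q), ref = c(FALSE, FALSE, FALSE, TRUE))
  })
  out <- normalize_irs(mats)
  refs <- out$values[, out$samples$is_reference]
  expect_lt(max(apply(refs, 1, function(r) diff(range(r)) / mean(r))), 1e-9)
  twice <- normalize_irs(out)
  expect_equal(twice$values, out$values, tolerance = 1e-12)
  # feature with zero/missing reference is dropped with a logged count
  bad <- mats
  bad[[1]]$values[1, 4] <- 0
  bad[[2]]$values[2, 4] <- NA
  out2 <- normalize_irs(bad)
  expect_equal(nrow(out2$values), 8)
  expect_equal(out2$provenance$irs$dropped_features, 2L)
})

test_that("TMM factors behave on null, scaled and toy data", {
  set.seed(9)
  base <- rlnorm(400, meanlog = 8, sdlog = 1)
  v <- sapply(1:4, function(j) base * rlnorm(400, 0, 0.05))
  am <- make_am(v)
  f_null <- unlist(normalize_tmm(am)$provenance$tmm$factors)
  expect_true(all(abs(f_null - 1) < 0.05))
  # identical columns -> all factors exactly 1
  ident <- make_am(matrix(rep(base[1:50], 3), 50, 3))
  f_ident <- unlist(normalize_tmm(ident)$provenance$tmm$factors)
  expect_equal(unname(f_ident), rep(1, 3))
  # one column multiplied by 2 -> factor ratio ~2 within 5%
  v2 <- v
  v2[, 2] <- v2[, 2] * 2
  am2 <- normalize_tmm(make_am(v2))
  f2 <- unlist(am2$provenance$tmm$factors)
  expect_lt(abs(f2[[2]] / f2[[1]] - 2), 0.1)
  # scaled column is corrected back onto the others
  expect_lt(abs(median(am2$values[, 2] / am2$values[, 1]) - 1), 0.05)
})

test_that("TMM matches the direct trimmed-mean recomputation exactly", {
  set.seed(21)
  v <- matrix(rlnorm(300, 8, 1), 100, 3)
  v[sample(300, 10)] <- NA
  am <- make_am(v)
  out <- normalize_tmm(am)
  vals <- am$values
  j_ref <- match(out$provenance$tmm$reference_column, colnames(vals))
  raw <- vapply(1:3, function(j) bf_tmm_factor(vals[, j], vals[, j_ref]),
                numeric(1))
  oracle <- raw / exp(mean(log(raw)))
  expect_equal(unname(unlist(out$provenance$tmm$factors)), oracle,
               tolerance = 1e-12)
  # fewer than 2 analytic columns: warning, no-op
  one <- make_am(v[, 1, drop = FALSE])
  expect_warning(res <- normalize_tmm(one), "fewer than 2")
  expect_equal(res$values, one$values)
})

test_that("filter_phosphopeptides applies score, ambiguity and master rules", {
  ab <- matrix(1, 4, 2, dimnames = list(NULL, c("S1", "S2")))
  mk <- function(score, plex) make_quant_table(
    ab, score = score, plex = plex,
    positions = c("S15", "S20", "T7", ""),
    master = c("P1", "P2", "P3;P4", "P5"),
    ambiguous = c(FALSE, FALSE, FALSE, FALSE))
  tabs <- list(mk(c(250, 200, 300, 400), "plex1"),
               mk(c(150, 200, 300, 400), "plex2"))
  out <- filter_phosphopeptides(tabs, min_score = 200)
  # row 1: 250 in one plex -> retained; row 2: exactly 200 in both -> removed
  # row 3: two master proteins -> removed; row 4: no phosphosite -> removed
  expect_equal(out[[1]]$peptide_id, "PEP0001")
  expect_equal(out[[2]]$peptide_id, "PEP0001")
  # ambiguity in any plex removes the peptide
  tabs2 <- tabs
  tabs2[[2]]$localization_ambiguous[1] <- TRUE
  expect_equal(nrow(filter_phosphopeptides(tabs2, 200)[[1]]), 0L)
})

test_that("condense_phosphosites averages peptides per site", {
  ab <- matrix(c(8, 12, 20,
                 16, 24, 40), ncol = 2,
               dimnames = list(NULL, c("S1", "S2")))
  tab <- make_quant_table(ab, master = "P1",
                          positions = c("S15", "S15", "S15;T20"))
  samples <- data.frame(sample_id = c("S1", "S2"), plex_id = "plex1",
                        channel_id = c("c1", "c2"), is_reference = FALSE)
  pp <- phospho_peptide_matrix(list(tab), samples)
  sites <- condense_phosphosites(pp$matrix, pp$site_map)
  # S15 covered by all three peptides (incl. the doubly phosphorylated one)
  expect_equal(sites$values["P1_S15", "S1"], mean(c(8, 12, 20)))
  # T20 only by the multi-site peptide
  expect_equal(sites$values["P1_T20", "S1"], 20)
  # enumeration oracle over (peptide, site) pairs
  oracle <- list(P1_S15 = c(8, 12, 20), P1_T20 = 20)
  for (k in names(oracle))
    expect_equal(unname(sites$values[k, "S1"]), mean(oracle[[k]]))
})

test_that("condense_phosphosites commutes with sample reordering", {
  set.seed(3)
  ab <- matrix(rlnorm(12, 5), 3, 4,
               dimnames = list(NULL, sprintf("S%d", 1:4)))
  tab <- make_quant_table(ab, master = "P9",
                          positions = c("S1", "S1;S2", "S2"))
  samples <- data.frame(sample_id = colnames(ab), plex_id = "plex1",
                        channel_id = colnames(ab), is_reference = FALSE)
  pp <- phospho_peptide_matrix(list(tab), samples)
  sites <- condense_phosphosites(pp$matrix, pp$site_map)
  perm <- c(3, 1, 4, 2)
  tab_p <- tab[, c(names(tab)[1:8], colnames(ab)[perm])]
  pp_p <- phospho_peptide_matrix(list(tab_p), samples[perm, ])
  sites_p <- condense_phosphosites(pp_p$matrix, pp_p$site_map)
  expect_equal(sites_p$values[, colnames(sites$values)], sites$values)
})

test_that("detect_outliers flags gross outliers and spares clean data", {
  flagged_runs <- vapply(1:20, function(s) {
    set.seed(s)
    am <- make_am(matrix(rnorm(50 * 12), 50, 12))
    any(detect_outliers(am, sd_mult = 3)$flagged)
  }, logical(1))
  expect_lte(mean(flagged_runs), 0.05 + 2 * sqrt(0.05 * 0.95 / 20))
  set.seed(1)
  v <- matrix(rnorm(50 * 12), 50, 12)
  v[, 5] <- v[, 5] + 10
  out <- detect_outliers(make_am(v), sd_mult = 3)
  expect_true(out$flagged[5])
  # three identical samples: nothing to flag
  same <- make_am(matrix(rep(1:5, 3), 5, 3))
  expect_false(any(detect_outliers(same)$flagged))
  # high-missingness sample is flagged
  v2 <- matrix(rnorm(100 * 10), 100, 10)
  v2[sample(100, 60), 3] <- NA
  out2 <- detect_outliers(make_am(v2))
  expect_true(out2$flagged_missing[3])
})
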