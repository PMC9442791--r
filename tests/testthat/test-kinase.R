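# kinase_activity module: curated matching, MCC cutoff, network assembly,
# bounded activity scoring.

test_that("match_curated links observed sites by exact triplet match", {
  curated <- data.frame(
    kinase = c("AKT1", "AKT1", "CDK1"),
    accession = c("P1", "P2", "P1"),
    residue = c("S", "T", "S"),
    position = c(15L, 7L, 15L))
  links <- match_curated(c("P1_S15", "P9_S9"), curated)
  expect_setequal(links$kinase, c("AKT1", "CDK1"))   # both kinases of P1_S15
  expect_true(all(links$site == "P1_S15"))
  expect_equal(nrow(match_curated("P9_S9", curated)), 0L)
})

test_that("match_curated equals brute-force nested-loop matching", {
  set.seed(23)
  sites <- make_site_key(sample(c("P1", "P2", "P3"), 10, TRUE),
                         sample(c("S", "T"), 10, TRUE),
                         sample(1:20, 10))
  curated <- data.frame(
    kinase = sample(c("K1", "K2"), 6, TRUE),
    accession = sample(c("P1", "P2", "P3"), 6, TRUE),
    residue = sample(c("S", "T"), 6, TRUE),
    position = sample(1:20, 6))
  got <- match_curated(sites, curated)
  oracle <- NULL
  for (i in seq_len(nrow(curated))) {
    ck <- sprintf("%s_%s%d", curated$accession[i], curated$residue[i],
                  curated$position[i])
    for (s in unique(sites))
      if (ck == s) oracle <- rbind(oracle, c(curated$kinase[i], s))
  }
  oracle_pairs <- if (is.null(oracle)) character(0)
                  else unique(paste(oracle[, 1], oracle[, 2]))
  expect_setequal(paste(got$kinase, got$site), oracle_pairs)
})

test_that("malformed curated rows are skipped with a count", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("KINASE\tSUB_ACC_ID\tSUB_MOD_RSD",
               "AKT1\tP1\tS15", "AKT1\tP2\tXbad", "CDK1\tP3\tT0"), path)
  expect_message(cur <- read_psp_tsv(path), "2 curated row")
  expect_equal(nrow(cur), 1L)
  expect_equal(attr(cur, "n_skipped"), 2L)
})

test_that("optimize_cutoff applies the stated confusion rules and tie-break", {
  pred <- data.frame(kinase = rep("K", 6),
                     site = sprintf("P_S%d", 1:6),
                     score = c(10, 10, 10, 1, 1, 1))
  curated <- data.frame(kinase = rep("K", 3), site = sprintf("P_S%d", 1:3))
  res <- optimize_cutoff(pred, curated, grid = c(0.5, 5, 9.5))
  expect_equal(res$grid$mcc, c(0, 1, 1))
  expect_equal(res$chosen, 5)                      # smallest maximizer
  # all predictions curated: MCC 0 everywhere (0/0 convention)
  res2 <- optimize_cutoff(pred[1:3, ], curated, grid = c(0.5, 5))
  expect_equal(res2$grid$mcc, c(0, 0))
  expect_error(optimize_cutoff(pred[4:6, ], curated), "truth set")
})

test_that("confusion matrices equal brute-force recounts at every grid point", {
  set.seed(25)
  n <- 60
  is_cur <- rep(c(TRUE, FALSE), c(20, 40))
  score <- c(rnorm(20, 6, 2), rnorm(40, 2, 2))
  pred <- data.frame(kinase = "K", site = sprintf("S%02d", 1:n), score = score)
  curated <- data.frame(kinase = "K", site = pred$site[is_cur])
  res <- optimize_cutoff(pred, curated)
  for (i in seq_len(nrow(res$grid))) {
    cm <- bf_confusion(score, is_cur, res$grid$threshold[i])
    expect_equal(unlist(res$grid[i, c("TP", "FN", "TN", "FP")]), cm)
    expect_equal(res$grid$mcc[i], bf_mcc(cm), tolerance = 1e-12)
  }
  # chosen threshold agrees with an exhaustive fine sweep
  sweep_grid <- seq(min(score) - 0.1, max(score) + 0.1, by = 0.01)
  mccs <- vapply(sweep_grid, function(t) bf_mcc(bf_confusion(score, is_cur, t)),
                 numeric(1))
  best_fine <- sweep_grid[which.max(mccs)]
  expect_lt(abs(res$chosen - best_fine), 0.5)
})

test_that("build_network applies strict cutoff, dedup and detection filter", {
  curated <- data.frame(kinase = "K1", site = "P1_S1")
  pred <- data.frame(kinase = c("K1", "K2", "K3"),
                     site = c("P1_S1", "P2_S2", "P3_S3"),
                     score = c(9, 5.88, 7))
  net <- build_network(curated, pred, cutoff = 5.88)
  expect_false("P2_S2" %in% net$site)             # exactly at cutoff: excluded
  expect_equal(net$source[net$site == "P1_S1"], "curated")  # curated wins
  expect_equal(nrow(net), 2L)
  net2 <- build_network(curated, pred, 5.88, detected_kinases = c("K1"))
  expect_equal(net2$kinase, "K1")
})

test_that("score_activities solves the hand-checked systems exactly", {
  # one kinase, one site observed at 10
  m1 <- matrix(10, 1, 1, dimnames = list("P_S1", "A1"))
  net1 <- data.frame(kinase = "K1", site = "P_S1")
  pr1 <- score_activities(m1, net1, n_starts = 5, seed = 2)
  expect_equal(unname(pr1$activities["K1", 1]), 10, tolerance = 1e-5)
  expect_lt(pr1$residual[1], 1e-8)
  # kinases A, B with private sites 6 and 14 plus one shared site at 10:
  # unique least-squares solution (6, 14), residual 0 (normal equations by
  # hand: a = 6, b = 14 satisfies all three equations exactly)
  m2 <- matrix(c(6, 14, 10), 3, 1,
               dimnames = list(c("pA", "pB", "pAB"), "A1"))
  net2 <- data.frame(kinase = c("A", "B", "A", "B"),
                     site = c("pA", "pB", "pAB", "pAB"))
  pr2 <- score_activities(m2, net2, n_starts = 20, seed = 3)
  expect_equal(unname(pr2$activities[c("A", "B"), 1]), c(6, 14),
               tolerance = 1e-5)
  expect_lt(pr2$residual[1], 1e-8)
})

test_that("score_activities respects bounds, seeds and exclusions", {
  set.seed(31)
  m <- matrix(rnorm(20, 12, 6), 5, 4,
              dimnames = list(sprintf("s%d", 1:5), sprintf("A%d", 1:4)))
  m[2, 3] <- NA
  net <- data.frame(kinase = rep(c("K1", "K2"), c(3, 3)),
                    site = c("s1", "s2", "s3", "s3", "s4", "s5"))
  p1 <- score_activities(m, net, n_starts = 10, seed = 9)
  p2 <- score_activities(m, net, n_starts = 10, seed = 9)
  expect_identical(p1$activities, p2$activities)
  expect_true(all(p1$activities >= 0 & p1$activities <= 24))
  # kinase with no observed linked site is dropped with a warning
  net_extra <- rbind(net, data.frame(kinase = "K9", site = "unobserved"))
  expect_warning(p3 <- score_activities(m, net_extra, n_starts = 5, seed = 1),
                 "K9")
  expect_false("K9" %in% rownames(p3$activities))
})

test_that("recovery degrades monotonically with noise", {
  cors <- vapply(c(0, 0.25, 1), function(sdn) {
    set.seed(40)
    K <- 6; S <- 4; nsite <- 30
    act <- matrix(runif(K * S, 2, 22), K, S,
                  dimnames = list(sprintf("K%d", 1:K), sprintf("A%d", 1:S)))
    kin_of <- rep_len(seq_len(K), nsite)
    truth_vals <- act[kin_of, ] + matrix(rnorm(nsite * S, 0, sdn), nsite, S)
    rownames(truth_vals) <- sprintf("s%02d", seq_len(nsite))
    net <- data.frame(kinase = rownames(act)[kin_of],
                      site = rownames(truth_vals))
    pr <- score_activities(truth_vals, net, n_starts = 10, seed = 5)
    mean(vapply(seq_len(S), function(j)
      cor(pr$activities[rownames(act), j], act[, j]), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(cors) <= 1e-6))
  expect_gt(cors[1], 0.999999)           # zero noise: exact recovery
})

test_that("differential_activity flags planted shifts and honors nulls", {
  set.seed(44)
  K <- 8; S <- 12
  act <- matrix(rnorm(K * S, 12, 1), K, S,
                dimnames = list(sprintf("K%d", 1:K), sprintf("A%d", 1:S)))
  groups <- rep(c("g1", "g2"), each = 6)
  act[1, groups == "g2"] <- act[1, groups == "g2"] + 4
  prof <- structure(list(activities = act, residual = rep(0, S),
                         lower = 0, upper = 24, n_starts = 1),
                    class = "KinaseActivityProfile")
  res <- differential_activity(prof, groups)
  expect_lt(res$q[res$feature == "K1"], 0.05)
  expect_gt(min(res$p[-1]), 0.001)
})
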