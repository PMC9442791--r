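# Kinase-substrate network construction (curated + score-thresholded
# predicted links, with an MCC-optimized prediction-score cutoff) and
# bounded per-sample kinase activity inference.

#' Build a phosphosite key
#' @param accession protein accession.
#' @param residue one of S, T, Y.
#' @param position 1-based position in the master protein.
#' @return keys of the form `ACCESSION_RESPOS`, e.g. `P04637_S15`.
#' @export
make_site_key <- function(accession, residue, position) {
  if (!all(residue %in% c("S", "T", "Y"))) stop("residue must be S, T or Y")
  if (any(position < 1)) stop("positions are 1-based (>= 1)")
  sprintf("%s_%s%d", accession, residue, as.integer(position))
}

#' Match observed phosphosites against a curated kinase-substrate table
#'
#' One link per exact (accession, residue, position) match; unmatched sites
#' simply yield no link.  Rows of the curated table with malformed
#' positions are skipped with a logged count (see [read_psp_tsv()]).
#'
#' @param sites character vector of observed site keys
#'   (`ACCESSION_RESPOS`).
#' @param curated data.frame with columns kinase, accession, residue,
#'   position.
#' @return data.frame of links: kinase, site, source = "curated",
#'   score = NA.
#' @export
match_curated <- function(sites, curated) {
  req <- c("kinase", "accession", "residue", "position")
  if (!all(req %in% names(curated)))
    stop("curated table needs columns: ", paste(req, collapse = ", "))
  ckey <- make_site_key(curated$accession, curated$residue, curated$position)
  hit <- ckey %in% sites
  out <- data.frame(kinase = curated$kinase[hit], site = ckey[hit],
                    source = rep("curated", sum(hit)),
                    score = rep(NA_real_, sum(hit)),
                    stringsAsFactors = FALSE)
  unique(out)
}

mcc_from_counts <- function(tp, fn, tn, fp) {
  tp <- as.double(tp); fn <- as.double(fn)     # avoid integer overflow
  tn <- as.double(tn); fp <- as.double(fp)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)             # standard 0/0 convention
  (tp * tn - fp * fn) / sqrt(denom)
}

#' Optimize the prediction-score cutoff by Matthews correlation
#'
#' Predictions matching a curated (kinase, site) pair are positives:
#' TP above the threshold (strict), FN at or below.  Predictions without
#' curated support are negatives: FP above, TN at or below.  The chosen
#' cutoff is the smallest grid threshold attaining the maximum MCC
#' (favoring sensitivity on ties).
#'
#' @param predictions data.frame of predicted links with columns kinase,
#'   site, score.
#' @param curated data.frame of curated links with columns kinase, site.
#' @param grid numeric vector of candidate thresholds; by default the
#'   unique observed scores plus midpoints between consecutive scores.
#' @return a `CutoffResult` list: `grid` (threshold, TP, FN, TN, FP, mcc),
#'   `chosen`, `max_mcc`.
#' @export
optimize_cutoff <- function(predictions, curated, grid = NULL) {
  stopifnot(all(c("kinase", "site", "score") %in% names(predictions)),
            all(c("kinase", "site") %in% names(curated)))
  cpairs <- paste(curated$kinase, curated$site)
  is_pos <- paste(predictions$kinase, predictions$site) %in% cpairs
  if (!any(is_pos))
    stop("no curated (kinase, site) pair among the predictions: ",
         "a truth set is required to optimize the cutoff")
  score <- predictions$score
  if (is.null(grid)) {
    s <- sort(unique(score))
    grid <- sort(unique(c(s, (s[-1] + s[-length(s)]) / 2)))
  }
  if (length(grid) == 0L) stop("threshold grid must be non-empty")
  rows <- t(vapply(grid, function(t) {
    tp <- sum(is_pos & score > t); fn <- sum(is_pos & score <= t)
    fp <- sum(!is_pos & score > t); tn <- sum(!is_pos & score <= t)
    c(threshold = t, TP = tp, FN = fn, TN = tn, FP = fp,
      mcc = mcc_from_counts(tp, fn, tn, fp))
  }, numeric(6)))
  rows <- as.data.frame(rows)
  best <- max(rows$mcc)
  chosen <- min(rows$threshold[rows$mcc == best])
  structure(list(grid = rows, chosen = chosen, max_mcc = best),
            class = "CutoffResult")
}

#' @export
print.CutoffResult <- function(x, ...) {
  cat(sprintf("CutoffResult: %d thresholds, chosen = %g (MCC = %.4f)\n",
              nrow(x$grid), x$chosen, x$max_mcc))
  invisible(x)
}

#' Assemble the kinase-substrate network
#'
#' Union of curated links and predicted links with score strictly greater
#' than the cutoff; on duplicate (kinase, site) pairs the curated link
#' wins.  Links whose kinase is absent from `detected_kinases` (kinases
#' seen in the proteomic or phosphoproteomic data) are removed when that
#' list is supplied.
#'
#' @param curated data.frame of curated links (kinase, site).
#' @param predicted data.frame of predicted links (kinase, site, score).
#' @param cutoff score threshold (strict `>`), e.g. from
#'   [optimize_cutoff()].
#' @param detected_kinases optional character vector of detected kinases.
#' @return data.frame of links: kinase, site, source, score.
#' @export
build_network <- function(curated, predicted, cutoff,
                          detected_kinases = NULL) {
  cur <- data.frame(kinase = curated$kinase, site = curated$site,
                    source = "curated", score = NA_real_,
                    stringsAsFactors = FALSE)
  pred <- predicted[predicted$score > cutoff, , drop = FALSE]
  pred <- data.frame(kinase = pred$kinase, site = pred$site,
                     source = "predicted", score = pred$score,
                     stringsAsFactors = FALSE)
  net <- rbind(cur, pred)                       # curated first: wins dedup
  net <- net[!duplicated(paste(net$kinase, net$site)), , drop = FALSE]
  if (!is.null(detected_kinases))
    net <- net[net$kinase %in% detected_kinases, , drop = FALSE]
  rownames(net) <- NULL
  net
}

# Sum-of-squares objective and gradient for one sample: site value is
# modeled as the mean activity of its linked kinases.
activity_objective <- function(a, C, y) sum((as.vector(C %*% a) - y)^2)
activity_gradient <- function(a, C, y) 2 * as.vector(crossprod(C, as.vector(C %*% a) - y))

#' Infer bounded kinase activities from phosphosite abundances
#'
#' Models each phosphosite's log2 abundance as the arithmetic mean of its
#' linked kinases' activities and, per sample, minimizes the sum of squared
#' residuals subject to box constraints, using bounded quasi-Newton
#' optimization restarted from `n_starts` uniform-random initializations in
#' \[lower, upper\] (best objective kept; ties broken by first found).
#' Kinases with no linked observed site are excluded with a warning;
#' missing site values are dropped from that sample's objective.
#'
#' @param x phosphosite `AbundanceMatrix` (log2 scale) or numeric matrix
#'   with site keys as rownames.
#' @param network link data.frame from [build_network()] (kinase, site).
#' @param n_starts number of random restarts.
#' @param lower,upper activity bounds (log2 reporter-intensity range).
#' @param seed RNG seed; identical seeds give identical results.
#' @return a `KinaseActivityProfile` list: `activities` (kinase x sample),
#'   `residual` (best objective per sample), `lower`, `upper`, `n_starts`.
#' @export
score_activities <- function(x, network, n_starts = 100, lower = 0,
                             upper = 24, seed = 1L) {
  if (am_is(x)) x <- x$values[, !x$samples$is_reference, drop = FALSE]
  stopifnot(is.matrix(x), all(c("kinase", "site") %in% names(network)))
  net <- network[network$site %in% rownames(x), , drop = FALSE]
  kin <- sort(unique(net$kinase))
  dropped <- setdiff(unique(network$kinase), kin)
  if (length(dropped))
    warning(length(dropped), " kinase(s) with no linked observed site excluded: ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
  if (length(kin) == 0L) stop("no kinase has a linked observed site")
  sites <- sort(unique(net$site))
  C <- matrix(0, length(sites), length(kin), dimnames = list(sites, kin))
  C[cbind(net$site, net$kinase)] <- 1
  C <- C / rowSums(C)

  S <- ncol(x)
  K <- length(kin)
  act <- matrix(NA_real_, K, S, dimnames = list(kin, colnames(x)))
  resid <- stats::setNames(rep(NA_real_, S), colnames(x))
  set.seed(seed)
  for (j in seq_len(S)) {
    y <- x[sites, j]
    obs <- !is.na(y)
    starts <- matrix(stats::runif(n_starts * K, lower, upper), n_starts, K)
    if (!any(obs)) next
    Cs <- C[obs, , drop = FALSE]
    ys <- y[obs]
    best <- Inf
    best_a <- NULL
    for (s in seq_len(n_starts)) {
      fit <- stats::optim(starts[s, ], fn = activity_objective,
                          gr = activity_gradient, C = Cs, y = ys,
                          method = "L-BFGS-B", lower = lower, upper = upper,
                          control = list(factr = 1e4, maxit = 500))
      if (fit$value < best) {
        best <- fit$value
        best_a <- fit$par
      }
    }
    act[, j] <- pmin(pmax(best_a, lower), upper)
    resid[j] <- best
  }
  structure(list(activities = act, residual = resid, lower = lower,
                 upper = upper, n_starts = n_starts),
            class = "KinaseActivityProfile")
}

#' @export
print.KinaseActivityProfile <- function(x, ...) {
  cat(sprintf(
    "KinaseActivityProfile: %d kinases x %d samples, bounds [%g, %g]\n",
    nrow(x$activities), ncol(x$activities), x$lower, x$upper))
  invisible(x)
}

#' Differential kinase activity between groups
#'
#' Delegates to [anova_tukey()] (one-way ANOVA + Tukey + BH) on the kinase
#' activity matrix.
#'
#' @param profile a `KinaseActivityProfile`.
#' @param groups group label per sample.
#' @export
differential_activity <- function(profile, groups) {
  stopifnot(inherits(profile, "KinaseActivityProfile"))
  anova_tukey(profile$activities, groups)
}
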