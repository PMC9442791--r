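# End-to-end pipeline on a synthetic experiment, plus the command-line
# entry point with one subcommand per module.

#' Run the full analysis pipeline on a synthetic experiment
#'
#' Generates a multi-plex TMT experiment, then runs every downstream stage:
#' human-unique filtering, protein rollup, missingness filtering,
#' SL/IRS/TMM normalization, phosphopeptide filtering and phosphosite
#' condensation, outlier QC, differential abundance (ANOVA/Tukey/BH),
#' kinase activity scoring on the planted curated network, and the
#' drug-sensitivity signature.  Ward/Euclidean clustering of the normalized
#' protein matrix is compared to the planted grouping by adjusted Rand
#' index.
#'
#' @param config a [sim_config()].
#' @param out_dir optional output directory for TSV/JSON artifacts.
#' @param n_starts random restarts for kinase activity scoring.
#' @param k_signature drug signature size.
#' @param q_threshold significance threshold on BH q-values.
#' @return list with the experiment, normalized matrices, differential
#'   tables, kinase activity profile, drug signature results and the
#'   clustering adjusted Rand index.
#' @export
run_pipeline <- function(config, out_dir = NULL, n_starts = 100,
                         k_signature = 100, q_threshold = 0.05) {
  exp <- generate_experiment(config)
  truth <- exp$truth

  # --- protein route -------------------------------------------------
  prot_plex <- lapply(exp$tables, function(tab)
    rollup_proteins(filter_human_unique(tab), exp$samples))
  prot <- combine_plexes(prot_plex)
  prot <- filter_missing(prot, 0.5)
  prot <- normalize_tmm(normalize_irs(normalize_sl(prot)))
  prot_log2 <- log2_transform(drop_reference(prot))

  qc <- detect_outliers(prot_log2)

  # --- phosphosite route ---------------------------------------------
  phos_tabs <- filter_phosphopeptides(
    generate_kinase_sites(config, truth, exp$samples))
  pp <- phospho_peptide_matrix(phos_tabs, exp$samples)
  pep <- filter_missing(pp$matrix, 0.5)
  pep <- normalize_tmm(normalize_irs(normalize_sl(pep)))
  sites <- condense_phosphosites(pep, pp$site_map)
  sites_log2 <- log2_transform(drop_reference(sites))

  # --- differential abundance ----------------------------------------
  grp_of <- stats::setNames(exp$samples$group, exp$samples$sample_id)
  prot_groups <- grp_of[colnames(prot_log2$values)]
  diff_prot <- anova_tukey(prot_log2, prot_groups)
  site_groups <- grp_of[colnames(sites_log2$values)]
  diff_site <- anova_tukey(sites_log2, site_groups)

  # --- kinase activity ------------------------------------------------
  curated <- match_curated(rownames(sites_log2$values),
                           truth_curated_links(truth))
  activity <- score_activities(sites_log2, curated, n_starts = n_starts,
                               seed = config$seed)
  diff_kin <- differential_activity(activity, site_groups)

  # --- drug signature -------------------------------------------------
  screen <- generate_drug_table(config, truth)
  flagged <- qc$sample_id[qc$flagged]
  corr <- correlate_response(prot_log2, screen, excluded_samples = flagged)
  med <- median_over_entries(corr, "drug1")
  signature <- extract_signature(med, k = k_signature)
  sig_scores <- score_signature(prot_log2, signature, seed = config$seed)

  # --- clustering recovery --------------------------------------------
  vals <- prot_log2$values[stats::complete.cases(prot_log2$values), ,
                           drop = FALSE]
  hc <- stats::hclust(stats::dist(t(vals)), method = "ward.D2")
  clusters <- stats::cutree(hc, k = length(unique(prot_groups)))
  ari <- adjusted_rand_index(clusters, prot_groups)

  res <- list(
    experiment = exp,
    protein = prot_log2,
    phosphosite = sites_log2,
    qc = qc,
    diff_protein = diff_prot,
    diff_phosphosite = diff_site,
    kinase_activity = activity,
    diff_kinase = diff_kin,
    drug_screen = screen,
    drug_correlations = med,
    signature = signature,
    signature_scores = sig_scores,
    clusters = clusters,
    cluster_ari = ari,
    q_threshold = q_threshold
  )
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(out_dir, ...)
  write_abundance_tsv(res$protein, fp("protein_matrix.tsv"),
                      fp("protein_samples.tsv"))
  write_abundance_tsv(res$phosphosite, fp("phosphosite_matrix.tsv"))
  utils::write.table(res$qc, fp("sample_qc.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(res$diff_protein, fp("diff_protein.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(res$diff_kinase, fp("diff_kinase.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  act <- data.frame(kinase = rownames(res$kinase_activity$activities),
                    res$kinase_activity$activities, check.names = FALSE)
  utils::write.table(act, fp("kinase_activity.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_drug_screen(res$drug_screen, fp("drug_screen.tsv"))
  sig <- list(
    correlations = as.list(res$drug_correlations),
    signature = res$signature,
    sample_scores = res$signature_scores,
    cluster_ari = res$cluster_ari
  )
  jsonlite::write_json(sig, fp("signature.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  write_provenance(res$protein, fp("provenance.json"))
  invisible(out_dir)
}

# --- command line interface -------------------------------------------

parse_cli_args <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- gsub("-", "_", substring(a, 3))
    if (i < length(args) && !startsWith(args[i + 1L], "--")) {
      out[[key]] <- args[i + 1L]
      i <- i + 2L
    } else {
      out[[key]] <- TRUE
      i <- i + 1L
    }
  }
  out
}

cli_config <- function(opt) {
  cfg <- if (!is.null(opt$config)) sim_config_from_json(opt$config)
         else sim_config()
  if (!is.null(opt$seed)) {
    cfg$seed <- as.integer(opt$seed)
    validate_sim_config(cfg)
  }
  cfg
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic experiment), `normalize`
#' (filter + SL/IRS/TMM a set of quant tables), `diff` (ANOVA/Tukey/BH on a
#' matrix), `enrich` (ssgsea | ranked | ora against a GMT), `kinase`
#' (cutoff | network | score), `drugsig` (correlate | signature | score |
#' compare) and `pipeline` (full synthetic end-to-end run).  See the
#' package README for flag details; an executable wrapper ships in
#' `inst/cli/pdxphos`.
#'
#' @param args character vector of command-line arguments
#'   (e.g. `commandArgs(trailingOnly = TRUE)`).
#' @return 0 invisibly on success.
#' @export
pdxphos_cli <- function(args) {
  if (length(args) == 0L)
    stop("usage: pdxphos <simulate|normalize|diff|enrich|kinase|drugsig|pipeline> [--flags]")
  cmd <- args[1]
  opt <- parse_cli_args(args[-1])
  switch(cmd,
    simulate = cli_simulate(opt),
    normalize = cli_normalize(opt),
    diff = cli_diff(opt),
    enrich = cli_enrich(opt),
    kinase = cli_kinase(opt),
    drugsig = cli_drugsig(opt),
    pipeline = cli_pipeline(opt),
    stop("unknown subcommand: ", cmd)
  )
  invisible(0L)
}

cli_simulate <- function(opt) {
  if (is.null(opt$out)) stop("simulate requires --out DIR")
  cfg <- cli_config(opt)
  exp <- generate_experiment(cfg)
  write_experiment(exp, cfg, opt$out)
  message("synthetic experiment written to ", opt$out)
}

cli_normalize <- function(opt) {
  if (is.null(opt$quant) || is.null(opt$samples) || is.null(opt$out_matrix))
    stop("normalize requires --quant f1,f2,... --samples s.tsv --out-matrix out.tsv")
  mode <- opt$mode %||% "protein"
  tables <- lapply(strsplit(opt$quant, ",")[[1]], read_quant_tsv)
  samples <- utils::read.delim(opt$samples, stringsAsFactors = FALSE)
  samples$is_reference <- as.logical(samples$is_reference)
  max_missing <- as.numeric(opt$max_missing %||% 0.5)
  if (mode == "protein") {
    mats <- lapply(tables, function(t)
      rollup_proteins(filter_human_unique(t), samples))
    am <- filter_missing(combine_plexes(mats), max_missing)
    am <- normalize_tmm(normalize_irs(normalize_sl(am)))
  } else if (mode == "phospho") {
    tabs <- filter_phosphopeptides(lapply(tables, filter_human_unique),
                                   min_score = as.numeric(opt$min_score %||% 200))
    pp <- phospho_peptide_matrix(tabs, samples)
    am <- filter_missing(pp$matrix, max_missing)
    am <- normalize_tmm(normalize_irs(normalize_sl(am)))
    am <- condense_phosphosites(am, pp$site_map)
  } else stop("--mode must be protein or phospho")
  am <- drop_reference(am)
  if (isTRUE(opt$log2) || identical(opt$log2, "true")) am <- log2_transform(am)
  write_abundance_tsv(am, opt$out_matrix, opt$out_samples)
  if (!is.null(opt$provenance)) write_provenance(am, opt$provenance)
  message("normalized matrix written to ", opt$out_matrix)
}

cli_diff <- function(opt) {
  if (is.null(opt$matrix) || is.null(opt$samples) || is.null(opt$out))
    stop("diff requires --matrix m.tsv --samples s.tsv --out out.tsv")
  am <- read_abundance_tsv(opt$matrix, opt$samples)
  groups <- am$samples$group[!am$samples$is_reference]
  res <- anova_tukey(am, groups)
  utils::write.table(res, opt$out, sep = "\t", quote = FALSE, row.names = FALSE)
  qthr <- as.numeric(opt$q_threshold %||% 0.05)
  message(sum(res$q < qthr, na.rm = TRUE), " feature(s) significant at q < ", qthr)
}

cli_enrich <- function(opt) {
  if (is.null(opt$gmt) || is.null(opt$out)) stop("enrich requires --gmt and --out")
  sets <- read_gmt(opt$gmt)
  mode <- opt$mode %||% "ssgsea"
  seed <- as.integer(opt$seed %||% 1)
  if (mode == "ssgsea") {
    am <- read_abundance_tsv(opt$matrix)
    r <- ssgsea_matrix(am, sets, seed = seed)
    out <- data.frame(set = rownames(r$nes), r$nes, check.names = FALSE)
    utils::write.table(out, opt$out, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (mode == "ranked") {
    tab <- utils::read.delim(opt$ranks, stringsAsFactors = FALSE)
    ranks <- stats::setNames(tab[[2]], tab[[1]])
    res <- gsea_ranked(ranks, sets, n_perm = as.integer(opt$n_perm %||% 1000),
                       seed = seed)
    utils::write.table(res, opt$out, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (mode == "ora") {
    sig <- readLines(opt$signature, warn = FALSE)
    bg <- readLines(opt$background, warn = FALSE)
    p <- vapply(sets, function(s) hypergeom_ora(sig, s, bg), numeric(1))
    out <- data.frame(set = names(sets), p = p, q = bh_adjust(p))
    utils::write.table(out, opt$out, sep = "\t", quote = FALSE, row.names = FALSE)
  } else stop("--mode must be ssgsea, ranked or ora")
  message("enrichment written to ", opt$out)
}

cli_kinase <- function(opt) {
  action <- opt$action %||% stop("kinase requires --action cutoff|network|score")
  if (action == "cutoff") {
    pred <- read_predictions_tsv(opt$predictions)
    cur <- read_psp_tsv(opt$curated)
    pred$site <- make_site_key(pred$accession, pred$residue, pred$position)
    curated <- data.frame(kinase = cur$kinase,
                          site = make_site_key(cur$accession, cur$residue,
                                               cur$position))
    res <- optimize_cutoff(pred, curated)
    jsonlite::write_json(list(chosen = res$chosen, max_mcc = res$max_mcc,
                              grid = res$grid),
                         opt$out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    message("chosen cutoff ", res$chosen, " (MCC ", round(res$max_mcc, 4), ")")
  } else if (action == "network") {
    pred <- read_predictions_tsv(opt$predictions)
    cur <- read_psp_tsv(opt$curated)
    pred$site <- make_site_key(pred$accession, pred$residue, pred$position)
    curated <- data.frame(kinase = cur$kinase,
                          site = make_site_key(cur$accession, cur$residue,
                                               cur$position))
    detected <- if (!is.null(opt$detected)) readLines(opt$detected) else NULL
    net <- build_network(curated, pred, as.numeric(opt$cutoff), detected)
    utils::write.table(net, opt$out, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (action == "score") {
    am <- read_abundance_tsv(opt$matrix, opt$samples)
    net <- utils::read.delim(opt$network, stringsAsFactors = FALSE)
    prof <- score_activities(am, net,
                             n_starts = as.integer(opt$n_starts %||% 100),
                             seed = as.integer(opt$seed %||% 1))
    out <- data.frame(kinase = rownames(prof$activities), prof$activities,
                      check.names = FALSE)
    utils::write.table(out, opt$out, sep = "\t", quote = FALSE, row.names = FALSE)
  } else stop("unknown kinase action: ", action)
}

cli_drugsig <- function(opt) {
  action <- opt$action %||% stop("drugsig requires --action correlate|signature|score|compare")
  if (action %in% c("correlate", "signature")) {
    am <- read_abundance_tsv(opt$matrix)
    screen <- read_drug_screen(opt$screen)
    excl <- if (!is.null(opt$exclude)) strsplit(opt$exclude, ",")[[1]] else character()
    corr <- correlate_response(am, screen, excluded_samples = excl)
    if (action == "correlate") {
      out <- data.frame(feature = rownames(corr$corr), corr$corr,
                        check.names = FALSE)
      utils::write.table(out, opt$out, sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
      med <- median_over_entries(corr, opt$drug %||% screen$drug_id[1])
      sig <- extract_signature(med, k = as.integer(opt$k %||% 100))
      writeLines(sig, opt$out)
    }
  } else if (action == "score") {
    am <- read_abundance_tsv(opt$matrix)
    sig <- readLines(opt$signature, warn = FALSE)
    res <- score_signature(am, sig, seed = as.integer(opt$seed %||% 1))
    utils::write.table(res, opt$out, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (action == "compare") {
    sc <- utils::read.delim(opt$scores, stringsAsFactors = FALSE)
    rs <- utils::read.delim(opt$response, stringsAsFactors = FALSE)
    scores <- stats::setNames(sc[[2]], sc[[1]])
    response <- stats::setNames(rs[[2]], rs[[1]])
    res <- compare_extremes(scores, response,
                            n_extreme = as.integer(opt$n_extreme %||% 50))
    jsonlite::write_json(res, opt$out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else stop("unknown drugsig action: ", action)
  message("drugsig ", action, " done")
}

cli_pipeline <- function(opt) {
  if (is.null(opt$out)) stop("pipeline requires --out DIR")
  cfg <- cli_config(opt)
  res <- run_pipeline(cfg, out_dir = opt$out,
                      n_starts = as.integer(opt$n_starts %||% 100),
                      k_signature = as.integer(opt$k %||% 100))
  message(sprintf("pipeline complete: %d proteins, %d phosphosites, ARI %.3f",
                  nrow(res$protein$values), nrow(res$phosphosite$values),
                  res$cluster_ari))
}
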