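# Synthetic TMT experiment generator with planted ground truth.
#
# The generator emulates the design of a two-plex TMT 11-plex PDX study:
# each plex carries a set of sample channels plus one reference channel
# loaded with a pooled internal standard (equal contribution of every
# sample), three sample subgroups, per-plex batch offsets, human/mouse/
# shared peptide contamination, kinase-driven phosphosite abundances and a
# planted drug-response association.  Abundances are simulated and stored
# on the linear reporter-intensity scale; all signal parameters are log2.

TMT11_CHANNELS <- c("126", "127N", "127C", "128N", "128C", "129N", "129C",
                    "130N", "130C", "131N", "131C")

#' Simulation configuration
#'
#' Defaults mirror the cohort design the package targets: 20 PDX samples in
#' two TMT 11-plexes (10 sample channels + 1 pooled reference channel per
#' plex), three molecular subgroups (SHH n=6, G3 n=10, G4 n=4), a plex
#' batch effect of 0.5 log2 SD, peptide-level measurement noise of 0.25
#' log2 SD, and a planted drug association with |Spearman| 0.8.
#'
#' @param n_plexes number of TMT plexes.
#' @param channels_per_plex reporter channels per plex (the last one is the
#'   pooled reference channel).
#' @param n_samples number of biological samples across all plexes.
#' @param groups character vector of group labels, one per sample
#'   (must cover at least 2 groups).
#' @param n_proteins number of human proteins with quantitative ground truth.
#' @param peptides_per_protein mean peptide count per protein
#'   (counts are 1 + Poisson(peptides_per_protein - 1)).
#' @param n_phosphosites number of kinase-driven phosphosites; if `NULL`,
#'   `n_kinases * sites_per_kinase`.
#' @param n_kinases number of simulated kinases.
#' @param sites_per_kinase mean substrate sites per kinase.
#' @param group_effect_size planted group shift, log2 units.
#' @param plex_effect_sd SD of per-plex batch offsets, log2 units.
#' @param noise_sd SD of per-peptide-per-channel measurement noise, log2.
#' @param frac_mouse fraction of emitted peptides labeled mouse (stromal
#'   contamination).
#' @param frac_shared fraction labeled shared (sequence identical between
#'   species; these carry two master proteins).
#' @param missing_rate completely-at-random missingness rate per
#'   peptide-in-sample cell (reference channels are always observed).
#' @param drug_effect magnitude of the planted Spearman correlation between
#'   each drug-associated protein and viability, in \[0,1\].
#' @param seed master RNG seed; one derived stream per simulator component.
#' @param frac_de fraction of non-drug proteins given a group effect.
#' @param n_drug_proteins number of planted drug-associated proteins.
#' @param drug_coef log2 abundance change per SD of the drug latent factor.
#' @param drug_sensitive_group group whose lines are shifted toward
#'   sensitivity on the drug latent factor (drug response tracks a
#'   molecular subgroup, as for MYC-driven lines); default "G3" when
#'   present, otherwise the most frequent group.
#' @param drug_group_shift size of that shift, in SD units of the latent
#'   factor's individual component.
#' @param shared_site_frac fraction of phosphosites assigned to two kinases.
#' @param ambiguous_frac fraction of phosphopeptides flagged as
#'   localization-ambiguous.
#' @param phospho_score_range range of the uniform per-plex identification
#'   score draw for phosphopeptides.
#' @return a validated `SimConfig` list.
#' @export
sim_config <- function(n_plexes = 2,
                       channels_per_plex = 11,
                       n_samples = 20,
                       groups = c(rep("SHH", 6), rep("G3", 10), rep("G4", 4)),
                       n_proteins = 500,
                       peptides_per_protein = 3,
                       n_phosphosites = NULL,
                       n_kinases = 20,
                       sites_per_kinase = 10,
                       group_effect_size = 2,
                       plex_effect_sd = 0.5,
                       noise_sd = 0.25,
                       frac_mouse = 0.15,
                       frac_shared = 0.05,
                       missing_rate = 0.05,
                       drug_effect = 0.8,
                       seed = 1L,
                       frac_de = 0.25,
                       n_drug_proteins = 100,
                       drug_coef = 0.75,
                       drug_sensitive_group = NULL,
                       drug_group_shift = 2,
                       shared_site_frac = 0.2,
                       ambiguous_frac = 0.05,
                       phospho_score_range = c(120, 400)) {
  cfg <- as.list(environment())
  if (is.null(cfg$n_phosphosites))
    cfg$n_phosphosites <- n_kinases * sites_per_kinase
  validate_sim_config(cfg)
  structure(cfg, class = "SimConfig")
}

validate_sim_config <- function(cfg) {
  props <- c("frac_mouse", "frac_shared", "missing_rate", "drug_effect",
             "frac_de", "ambiguous_frac")
  for (p in props)
    if (cfg[[p]] < 0 || cfg[[p]] > 1)
      stop(sprintf("`%s` must lie in [0, 1]", p))
  if (cfg$frac_mouse + cfg$frac_shared >= 1)
    stop("frac_mouse + frac_shared must be < 1 (some peptides must be human)")
  if (cfg$n_samples > cfg$n_plexes * (cfg$channels_per_plex - 1))
    stop("infeasible allocation: n_samples exceeds available sample channels ",
         "(n_plexes x (channels_per_plex - 1))")
  if (length(cfg$groups) != cfg$n_samples)
    stop("`groups` must supply one label per sample")
  if (length(unique(cfg$groups)) < 2)
    stop("group labels must cover at least 2 groups")
  if (cfg$peptides_per_protein < 1)
    stop("peptides_per_protein must be >= 1")
  if (cfg$n_drug_proteins > cfg$n_proteins)
    stop("n_drug_proteins cannot exceed n_proteins")
  invisible(cfg)
}

#' Read a SimConfig from a JSON file
#'
#' Any field of [sim_config()] may be supplied; missing fields take the
#' documented defaults.
#'
#' @param path JSON file path.
#' @export
sim_config_from_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown SimConfig field(s): ", paste(unknown, collapse = ", "))
  do.call(sim_config, raw)
}

# Channel labels for one plex (last = reference).
plex_channels <- function(channels_per_plex) {
  if (channels_per_plex <= length(TMT11_CHANNELS))
    TMT11_CHANNELS[seq_len(channels_per_plex)]
  else
    sprintf("ch%02d", seq_len(channels_per_plex))
}

#' Generate a synthetic multi-plex TMT experiment
#'
#' Produces per-plex peptide quantification tables and the planted ground
#' truth.  Each plex's reference channel is the noise-free pooled mean of
#' all samples (not only that plex's samples) times the plex batch offset,
#' emulating a reference of equal peptide amounts from every line.
#'
#' @param config a [sim_config()].
#' @return list with elements `tables` (named list of quant table
#'   data.frames, one per plex), `samples` (sample metadata incl. group and
#'   reference rows), and `truth` (a `GroundTruth` list: true protein log2
#'   means, kinase activities and site map, drug viability and associated
#'   proteins, plex offsets).
#' @export
generate_experiment <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(derive_seed(config$seed, 1L))
  P <- config$n_plexes
  S <- config$n_samples
  plex_ids <- sprintf("plex%d", seq_len(P))
  sample_ids <- sprintf("PDX%02d", seq_len(S))
  channels <- plex_channels(config$channels_per_plex)
  ref_channel <- channels[length(channels)]

  # balanced random assignment of samples to plexes
  base <- S %/% P
  sizes <- rep(base, P)
  if (S %% P) sizes[seq_len(S %% P)] <- base + 1L
  plex_of <- sample(rep(seq_len(P), times = sizes))
  channel_of <- character(S)
  for (q in seq_len(P))
    channel_of[plex_of == q] <- channels[seq_len(sum(plex_of == q))]

  plex_offsets <- stats::rnorm(P, 0, config$plex_effect_sd)
  names(plex_offsets) <- plex_ids

  # planted structure on the human proteome
  acc <- sprintf("P%05d", seq_len(config$n_proteins))
  drug_idx <- if (config$n_drug_proteins > 0)
    sort(sample(config$n_proteins, config$n_drug_proteins)) else integer(0)
  pool <- setdiff(seq_len(config$n_proteins), drug_idx)
  n_de <- round(config$frac_de * length(pool))
  de_idx <- sort(sample(pool, n_de))
  group_levels <- unique(config$groups)
  up_group <- if (n_de) sample(group_levels, n_de, replace = TRUE) else character(0)

  # sensitivity latent: group-aligned component (drug response tracks one
  # molecular subgroup) plus individual variation, standardized to unit
  # population variance; high latent = sensitive (low viability)
  sens_group <- config$drug_sensitive_group %||%
    (if ("G3" %in% config$groups) "G3"
     else names(which.max(table(config$groups))))
  ind <- as.numeric(config$groups == sens_group)
  p_sens <- mean(ind)
  s_lat <- (config$drug_group_shift * (ind - p_sens) + stats::rnorm(S)) /
    sqrt(1 + config$drug_group_shift^2 * p_sens * (1 - p_sens))
  baseline <- stats::rnorm(config$n_proteins, 17, 1.5)
  M <- matrix(baseline, config$n_proteins, S,
              dimnames = list(acc, sample_ids))
  # planted drug proteins: each mixes the shared sensitivity latent with
  # protein-specific noise so its population Spearman correlation with
  # viability is -drug_effect (Gaussian copula: Pearson = 2*sin(pi*rho/6)),
  # while realized correlations of different planted proteins remain
  # conditionally independent given the latent
  rho_p <- 2 * sin(pi * config$drug_effect / 6)
  if (length(drug_idx)) {
    eta <- matrix(stats::rnorm(length(drug_idx) * S), length(drug_idx), S)
    xdrug <- rho_p * matrix(s_lat, length(drug_idx), S, byrow = TRUE) +
      sqrt(max(0, 1 - rho_p^2)) * eta
    M[drug_idx, ] <- M[drug_idx, ] + config$drug_coef * xdrug
  }
  for (i in seq_along(de_idx))
    M[de_idx[i], config$groups == up_group[i]] <-
      M[de_idx[i], config$groups == up_group[i]] + config$group_effect_size

  viability <- 100 * stats::pnorm(-s_lat)   # strictly monotone in the latent
  names(viability) <- sample_ids

  # human peptides: protein signal split across peptides by fixed weights
  n_pep <- 1L + stats::rpois(config$n_proteins, config$peptides_per_protein - 1)
  pidx <- rep(seq_len(config$n_proteins), times = n_pep)
  H <- length(pidx)
  g <- stats::rgamma(H, shape = 2)
  w <- g / rep(as.vector(rowsum(g, pidx)), times = n_pep)

  lin_human <- w * 2^M[pidx, , drop = FALSE]             # noise-free, H x S

  # contaminant peptides (not part of the quantitative ground truth)
  fm <- config$frac_mouse; fs <- config$frac_shared
  n_extra <- round(H * (fm + fs) / (1 - fm - fs))
  n_mouse <- if (fm + fs > 0) round(n_extra * fm / (fm + fs)) else 0L
  n_shared <- n_extra - n_mouse
  lin_mouse <- lin_shared <- NULL
  mouse_acc <- shared_master <- character(0)
  if (n_mouse > 0) {
    mp <- ceiling(seq_len(n_mouse) / 3)
    mouse_acc <- sprintf("MUSQ%05d", mp)
    bm <- stats::rnorm(max(mp), 16, 1.5)
    Mm <- matrix(bm[mp], n_mouse, S) + matrix(stats::rnorm(n_mouse * S, 0, 0.5),
                                              n_mouse, S)
    gm <- stats::rgamma(n_mouse, shape = 2)
    wm <- gm / rep(as.vector(rowsum(gm, mp)), times = tabulate(mp))
    lin_mouse <- wm * 2^Mm
  }
  if (n_shared > 0) {
    shared_master <- paste(sample(acc, n_shared, replace = TRUE),
                           sprintf("MUSQS%04d", seq_len(n_shared)), sep = ";")
    bs <- stats::rnorm(n_shared, 16, 1.5)
    Ms <- matrix(bs, n_shared, S) + matrix(stats::rnorm(n_shared * S, 0, 0.5),
                                           n_shared, S)
    lin_shared <- 2^Ms
  }

  lin_all <- rbind(lin_human, lin_mouse, lin_shared)
  n_rows <- nrow(lin_all)
  species <- c(rep("human", H), rep("mouse", n_mouse), rep("shared", n_shared))
  masters <- c(acc[pidx], mouse_acc, shared_master)

  # observed sample channels: signal x plex offset x log2-Gaussian noise
  off_s <- plex_offsets[plex_of]
  noise <- matrix(stats::rnorm(n_rows * S, 0, config$noise_sd), n_rows, S)
  observed <- lin_all * 2^(noise + matrix(off_s, n_rows, S, byrow = TRUE))
  colnames(observed) <- sample_ids

  # reference channels: noise-free pooled mean of ALL samples, plus offset
  ref <- rowMeans(lin_all) %o% 2^plex_offsets
  colnames(ref) <- paste0("ref_", plex_ids)

  # per-plex identification scores
  id_scores <- matrix(stats::runif(n_rows * P, 100, 400), n_rows, P)

  # kinase ground truth (activities bounded in [0, 24])
  K <- config$n_kinases
  kinase_ids <- sprintf("KIN%03d", seq_len(K))
  activity <- matrix(stats::runif(K * S, 2, 22), K, S,
                     dimnames = list(kinase_ids, sample_ids))
  n_sites <- config$n_phosphosites
  site_acc <- sample(acc, n_sites, replace = TRUE)
  site_res <- sample(c("S", "T", "Y"), n_sites, replace = TRUE,
                     prob = c(0.882, 0.1175, 0.0005))
  site_pos <- sample(5:4999, n_sites, replace = TRUE)
  key <- sprintf("%s_%s%d", site_acc, site_res, site_pos)
  while (anyDuplicated(key)) {
    dup <- duplicated(key)
    site_pos[dup] <- sample(5:4999, sum(dup), replace = TRUE)
    key <- sprintf("%s_%s%d", site_acc, site_res, site_pos)
  }
  primary <- sample(rep_len(seq_len(K), n_sites))
  site_kinases <- lapply(seq_len(n_sites), function(i) kinase_ids[primary[i]])
  extra <- stats::runif(n_sites) < config$shared_site_frac
  for (i in which(extra & K > 1)) {
    other <- sample(setdiff(seq_len(K), primary[i]), 1)
    site_kinases[[i]] <- c(site_kinases[[i]], kinase_ids[other])
  }
  names(site_kinases) <- key
  sites <- data.frame(site_key = key, accession = site_acc,
                      residue = site_res, position = site_pos,
                      stringsAsFactors = FALSE)

  # MCAR missingness from its own stream (sample channels only)
  set.seed(derive_seed(config$seed, 2L))
  if (config$missing_rate > 0) {
    mask <- matrix(stats::runif(n_rows * S) < config$missing_rate, n_rows, S)
    observed[mask] <- NA_real_
  }

  samples <- data.frame(
    sample_id = c(sample_ids, paste0("ref_", plex_ids)),
    plex_id = c(plex_ids[plex_of], plex_ids),
    channel_id = c(channel_of, rep(ref_channel, P)),
    is_reference = c(rep(FALSE, S), rep(TRUE, P)),
    group = c(config$groups, rep(NA_character_, P)),
    stringsAsFactors = FALSE
  )

  tables <- stats::setNames(lapply(seq_len(P), function(q) {
    in_plex <- plex_of == q
    tab <- data.frame(
      peptide_id = sprintf("PEP%06d", seq_len(n_rows)),
      peptide_sequence = sprintf("SIMPEPTIDE%06dK", seq_len(n_rows)),
      species = species,
      master_proteins = masters,
      id_score = round(id_scores[, q], 2),
      plex_id = plex_ids[q],
      phospho_positions = "",
      localization_ambiguous = FALSE,
      stringsAsFactors = FALSE
    )
    block <- cbind(observed[, in_plex, drop = FALSE],
                   ref[, q, drop = FALSE])
    cbind(tab, as.data.frame(block, optional = TRUE))
  }), plex_ids)

  truth <- structure(list(
    true_protein_means = M,
    true_kinase_activity = activity,
    kinase_site_map = site_kinases,
    sites = sites,
    drug_viability = viability,
    drug_associated_proteins = acc[drug_idx],
    de_proteins = data.frame(accession = acc[de_idx], up_group = up_group,
                             stringsAsFactors = FALSE),
    drug_latent = stats::setNames(s_lat, sample_ids),
    plex_offsets = plex_offsets,
    groups = stats::setNames(config$groups, sample_ids)
  ), class = "GroundTruth")

  list(tables = tables, samples = samples, truth = truth)
}

#' Generate phosphopeptide tables driven by the planted kinase activities
#'
#' Each phosphosite's noise-free log2 abundance in a sample equals the mean
#' activity of its assigned kinases in that sample; Gaussian noise is added
#' on the log2 scale and plex offsets/reference channels follow the same
#' scheme as [generate_experiment()].  One singly-phosphorylated peptide is
#' emitted per site.
#'
#' @param config the [sim_config()] used for the experiment.
#' @param truth the `GroundTruth` returned by [generate_experiment()].
#' @param samples the sample metadata returned by [generate_experiment()].
#' @return named list of per-plex phosphopeptide quant tables.
#' @export
generate_kinase_sites <- function(config, truth, samples) {
  stopifnot(inherits(truth, "GroundTruth"))
  map <- truth$kinase_site_map
  if (any(lengths(map) == 0))
    stop("phosphosite with zero assigned kinases: cannot generate abundances")
  set.seed(derive_seed(config$seed, 3L))
  act <- truth$true_kinase_activity
  smp <- samples[!samples$is_reference, , drop = FALSE]
  S <- nrow(smp)
  n_sites <- length(map)
  site_keys <- names(map)

  L <- t(vapply(map, function(kin)
    colMeans(act[kin, smp$sample_id, drop = FALSE]), numeric(S)))
  rownames(L) <- site_keys
  colnames(L) <- smp$sample_id

  plex_ids <- names(truth$plex_offsets)
  off_s <- truth$plex_offsets[smp$plex_id]
  noise <- matrix(stats::rnorm(n_sites * S, 0, config$noise_sd), n_sites, S)
  observed <- 2^(L + noise + matrix(off_s, n_sites, S, byrow = TRUE))
  ref <- rowMeans(2^L) %o% 2^truth$plex_offsets

  score_lo <- config$phospho_score_range[1]
  score_hi <- config$phospho_score_range[2]
  id_scores <- matrix(stats::runif(n_sites * length(plex_ids), score_lo, score_hi),
                      n_sites, length(plex_ids))
  ambiguous <- stats::runif(n_sites) < config$ambiguous_frac

  set.seed(derive_seed(config$seed, 4L))
  if (config$missing_rate > 0) {
    mask <- matrix(stats::runif(n_sites * S) < config$missing_rate, n_sites, S)
    observed[mask] <- NA_real_
  }

  stats::setNames(lapply(seq_along(plex_ids), function(q) {
    in_plex <- smp$plex_id == plex_ids[q]
    tab <- data.frame(
      peptide_id = sprintf("PPEP%05d", seq_len(n_sites)),
      peptide_sequence = sprintf("SIMPHOSPEP%05dR", seq_len(n_sites)),
      species = "human",
      master_proteins = truth$sites$accession,
      id_score = round(id_scores[, q], 2),
      plex_id = plex_ids[q],
      phospho_positions = sprintf("%s%d", truth$sites$residue,
                                  truth$sites$position),
      localization_ambiguous = ambiguous,
      stringsAsFactors = FALSE
    )
    block <- cbind(observed[, in_plex, drop = FALSE],
                   stats::setNames(as.data.frame(ref[, q, drop = FALSE]),
                                   paste0("ref_", plex_ids[q])))
    cbind(tab, as.data.frame(block, optional = TRUE))
  }), plex_ids)
}

#' Generate a drug screen table with a planted association
#'
#' Emits `n_entries` screen entries for the planted drug (duplicate entries
#' share the drug id, mirroring drugs represented multiple times in a
#' screen) plus optional null drugs with unrelated viability.
#'
#' @param config the [sim_config()].
#' @param truth `GroundTruth` from [generate_experiment()].
#' @param n_entries number of screen entries for the planted drug.
#' @param n_null_drugs number of additional drugs with random viability.
#' @param entry_noise_sd SD (probit scale) of entry-to-entry variation.
#' @return a drug screen data.frame (`drug_id`, `entry_id`, one column per
#'   sample; values are percent viability in \[0, 100\]).
#' @export
generate_drug_table <- function(config, truth, n_entries = 2,
                                n_null_drugs = 0, entry_noise_sd = 0.05) {
  stopifnot(inherits(truth, "GroundTruth"), n_entries >= 1)
  set.seed(derive_seed(config$seed, 5L))
  v <- truth$drug_viability
  S <- length(v)
  zv <- stats::qnorm(pmin(pmax(v / 100, 1e-12), 1 - 1e-12))
  rows <- lapply(seq_len(n_entries), function(e) {
    z <- zv + stats::rnorm(S, 0, entry_noise_sd)
    100 * stats::pnorm(z)
  })
  drug_id <- rep("drug1", n_entries)
  entry_id <- sprintf("drug1_e%d", seq_len(n_entries))
  if (n_null_drugs > 0) {
    for (d in seq_len(n_null_drugs)) {
      for (e in seq_len(n_entries)) {
        rows[[length(rows) + 1L]] <- stats::runif(S, 0, 100)
        drug_id <- c(drug_id, sprintf("null%03d", d))
        entry_id <- c(entry_id, sprintf("null%03d_e%d", d, e))
      }
    }
  }
  resp <- do.call(rbind, rows)
  colnames(resp) <- names(v)
  cbind(data.frame(drug_id = drug_id, entry_id = entry_id,
                   stringsAsFactors = FALSE),
        as.data.frame(resp, optional = TRUE))
}

#' Curated kinase-substrate links implied by the planted ground truth
#'
#' Expands the ground-truth site-to-kinase map into a curated-links table in
#' the same shape as [read_psp_tsv()] output.
#'
#' @param truth `GroundTruth` from [generate_experiment()].
#' @export
truth_curated_links <- function(truth) {
  stopifnot(inherits(truth, "GroundTruth"))
  n <- lengths(truth$kinase_site_map)
  idx <- rep(seq_along(n), times = n)
  data.frame(
    kinase = unlist(truth$kinase_site_map, use.names = FALSE),
    accession = truth$sites$accession[idx],
    residue = truth$sites$residue[idx],
    position = truth$sites$position[idx],
    stringsAsFactors = FALSE
  )
}

#' Write a full synthetic experiment to disk
#'
#' Writes per-plex quant table TSVs, sample metadata, the drug screen, a
#' GMT of planted gene sets (drug signature and per-group shifted sets) and
#' the ground truth as JSON.
#'
#' @param exp result of [generate_experiment()].
#' @param config the [sim_config()] used.
#' @param dir output directory (created if needed).
#' @export
write_experiment <- function(exp, config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (px in names(exp$tables))
    write_quant_tsv(exp$tables[[px]], file.path(dir, paste0("quant_", px, ".tsv")))
  utils::write.table(exp$samples, file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  phospho <- generate_kinase_sites(config, exp$truth, exp$samples)
  for (px in names(phospho))
    write_quant_tsv(phospho[[px]], file.path(dir, paste0("phospho_", px, ".tsv")))
  screen <- generate_drug_table(config, exp$truth)
  write_drug_screen(screen, file.path(dir, "drug_screen.tsv"))
  truth <- exp$truth
  sets <- list(PLANTED_DRUG_SIGNATURE = truth$drug_associated_proteins)
  for (gname in unique(truth$de_proteins$up_group))
    sets[[paste0("PLANTED_UP_", gname)]] <-
      truth$de_proteins$accession[truth$de_proteins$up_group == gname]
  write_gmt(sets, file.path(dir, "planted_sets.gmt"))
  curated <- truth_curated_links(truth)
  utils::write.table(
    data.frame(KINASE = curated$kinase, SUB_ACC_ID = curated$accession,
               SUB_MOD_RSD = paste0(curated$residue, curated$position)),
    file.path(dir, "curated_links.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  tj <- truth
  tj$true_protein_means <- as.data.frame(tj$true_protein_means)
  tj$true_kinase_activity <- as.data.frame(tj$true_kinase_activity)
  jsonlite::write_json(unclass(tj), file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       dataframe = "columns")
  invisible(dir)
}
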