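# Fixture builders shared across tests.  Everything is generated in code;
# no binary fixtures.

# Minimal quant table: one row per peptide, abundance columns named by
# sample id.  `abund` is a matrix (peptides x samples).
make_quant_table <- function(abund, species = "human",
                             master = sprintf("P%05d", seq_len(nrow(abund))),
                             score = 300, plex = "plex1",
                             positions = "", ambiguous = FALSE,
                             sequence = NULL) {
  n <- nrow(abund)
  tab <- data.frame(
    peptide_id = sprintf("PEP%04d", seq_len(n)),
    peptide_sequence = sequence %||% sprintf("SEQ%04dK", seq_len(n)),
    species = rep_len(species, n),
    master_proteins = rep_len(master, n),
    id_score = rep_len(score, n),
    plex_id = rep_len(plex, n),
    phospho_positions = rep_len(positions, n),
    localization_ambiguous = rep_len(ambiguous, n),
    stringsAsFactors = FALSE
  )
  cbind(tab, as.data.frame(abund, optional = TRUE))
}

# AbundanceMatrix with simple metadata; `plex` is a vector per column,
# `ref` a logical vector per column.
make_am <- function(values, plex = "plex1", ref = FALSE) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("F%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("S%02d", seq_len(ncol(values)))
  abundance_matrix(values, data.frame(
    sample_id = colnames(values),
    plex_id = rep_len(plex, ncol(values)),
    channel_id = sprintf("ch%02d", seq_len(ncol(values))),
    is_reference = rep_len(ref, ncol(values)),
    stringsAsFactors = FALSE
  ))
}

tiny_config <- function(...) {
  defaults <- list(
    n_proteins = 30, n_drug_proteins = 5, peptides_per_protein = 2,
    n_kinases = 4, sites_per_kinase = 5, n_samples = 8,
    groups = c(rep("A", 4), rep("B", 4)), missing_rate = 0,
    frac_mouse = 0.1, frac_shared = 0.1, seed = 42
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}
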