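# shared oracles and small utilities used across test files

# unordered pair keys for set comparison of gene pairs
pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b))

# Rand index between two flat partitions (brute-force over pairs)
rand_index <- function(a, b) {
  n <- length(a)
  agree <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      agree <- agree + ((a[i] == a[j]) == (b[i] == b[j]))
    }
  }
  agree / choose(n, 2)
}

# truth label vs pipeline call comparison; background genes must come out
# with family "none"
label_accuracy <- function(truth_genes, calls) {
  cmp <- merge(truth_genes[, c("gene_id", "label")],
               calls[, c("gene_id", "family", "subfamily")],
               by = "gene_id")
  pred <- ifelse(cmp$family == "none", "background", cmp$subfamily)
  mean(cmp$label == pred)
}

# random amino-acid string (test-local, independent of the generator)
random_protein <- function(n, seed = NULL) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (!is.null(seed)) set.seed(seed)
  paste(sample(aa, n, replace = TRUE), collapse = "")
}

classify_accuracy_at <- function(seed, rate, n_genes = 30) {
  cfg <- synthetic_config(seed = seed, noise_mutation_rate = rate,
                          genes_per_species = n_genes, species_count = 1,
                          planted_tandem_pairs = 0,
                          planted_segmental_pairs = 0)
  sim <- generate_genomes(cfg)
  calls <- classify_proteome(sim$proteins$s1, seed = seed)
  label_accuracy(sim$truth$genes, calls)
}
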