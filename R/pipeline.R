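# End-to-end pipeline driver: generates (or loads) inputs, runs domain
# scanning, classification, gene structure, duplication/orthology, phylogeny
# and expression profiling, and writes a run directory with a manifest.

#' Pipeline configuration
#'
#' Thresholds default to the study's stated values: 1e-5 BLASTP mining
#' e-value, 80% identity / 1e-10 e-value / 5 Mb window for duplication
#' classification, 1e-10 for BBH orthology. Bootstrap replicates default to
#' 100 (a scale choice; the support definition does not change with the
#' replicate count).
#'
#' @param out_dir Run directory for stage outputs.
#' @param synthetic A [synthetic_config()] describing the input genomes.
#' @param backend Domain-scan backend (`"internal"`, `"hmmscan"`,
#'   `"blastp"`).
#' @param blastp_evalue Mining e-value for the blastp backend.
#' @param duplication_identity Minimum identity (%) for duplication events.
#' @param duplication_evalue Maximum e-value for duplication events.
#' @param tandem_window_bp Tandem window (bp).
#' @param bbh_evalue Maximum e-value for BBH orthology.
#' @param soloist_identity_cutoff Soloist homology cutoff (%).
#' @param bootstrap_replicates Bootstrap replicates for subgroup assignment.
#' @param log_offset Offset for log10 expression transformation.
#' @param expression_dispersion Dispersion of the simulated count matrix.
#' @param seed Master seed; all stage randomness derives from it.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("ap2erf_run_"),
                            synthetic = synthetic_config(),
                            backend = "internal",
                            blastp_evalue = 1e-5,
                            duplication_identity = 80,
                            duplication_evalue = 1e-10,
                            tandem_window_bp = 5e6,
                            bbh_evalue = 1e-10,
                            soloist_identity_cutoff = 30,
                            bootstrap_replicates = 100,
                            log_offset = 1,
                            expression_dispersion = 0.05,
                            seed = 1) {
  stopifnot(inherits(synthetic, "synthetic_config"))
  if (duplication_identity < 0 || duplication_identity > 100)
    stopf("duplication_identity must be a percentage")
  if (any(c(blastp_evalue, duplication_evalue, bbh_evalue) < 0))
    stopf("e-value thresholds must be >= 0")
  synthetic$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, synthetic = synthetic,
                 backend = backend, blastp_evalue = blastp_evalue,
                 duplication_identity = duplication_identity,
                 duplication_evalue = duplication_evalue,
                 tandem_window_bp = tandem_window_bp,
                 bbh_evalue = bbh_evalue,
                 soloist_identity_cutoff = soloist_identity_cutoff,
                 bootstrap_replicates = bootstrap_replicates,
                 log_offset = log_offset,
                 expression_dispersion = expression_dispersion,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

run_stage <- function(name, log_path, expr) {
  cat(sprintf("[%s] stage %s\n", format(Sys.time(), "%H:%M:%S"), name),
      file = log_path, append = TRUE)
  tryCatch(force(expr), error = function(e) {
    stopf("stage '%s' failed: %s (earlier stage outputs persist)", name,
          conditionMessage(e))
  })
}

#' Run the full gene-family dissection pipeline
#'
#' Generates synthetic genomes, scans domains, classifies every gene,
#' assigns phylogenetic subgroups, computes gene structures, duplication
#' events and orthologs, profiles simulated expression, and writes a
#' per-species summary tally. All outputs are TSV/FASTA/GFF3/Newick files
#' under `config$out_dir`, listed with md5 checksums in `manifest.tsv`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  cat("", file = log_path)

  sim <- run_stage("generate", log_path, {
    sim <- generate_genomes(config$synthetic)
    write_genomes(sim, file.path(config$out_dir, "inputs"))
    sim
  })
  species <- names(sim$proteins)

  hits <- run_stage("scan", log_path, {
    h <- lapply(species, function(sp)
      scan_with_backend(sim$proteins[[sp]], backend = config$backend,
                        blastp_evalue = config$blastp_evalue))
    names(h) <- species
    for (sp in species)
      write_tsv(h[[sp]], file.path(config$out_dir,
                                   sprintf("hits_%s.tsv", sp)))
    h
  })

  calls <- run_stage("classify", log_path, {
    cl <- lapply(species, function(sp)
      classify_proteome(sim$proteins[[sp]],
                        soloist_identity_cutoff =
                          config$soloist_identity_cutoff,
                        bootstrap_replicates = config$bootstrap_replicates,
                        seed = config$seed,
                        hits = if (config$backend == "internal")
                          hits[[sp]] else NULL))
    names(cl) <- species
    cl
  })

  calls <- run_stage("subgroups", log_path, {
    cl <- lapply(species, function(sp)
      assign_subgroups(calls[[sp]],
                       replicates = config$bootstrap_replicates,
                       seed = config$seed))
    names(cl) <- species
    for (sp in species)
      write_tsv(cl[[sp]], file.path(config$out_dir,
                                    sprintf("calls_%s.tsv", sp)))
    cl
  })

  structures <- run_stage("structure", log_path, {
    st <- lapply(species, function(sp) {
      prof <- lapply(sim$models[[sp]], splice_phases)
      data.frame(gene_id = names(prof),
                 intron_count = vapply(prof, `[[`, integer(1),
                                       "intron_count"),
                 phases = vapply(prof, function(p)
                   paste(p$phases, collapse = ","), character(1)),
                 stringsAsFactors = FALSE)
    })
    names(st) <- species
    for (sp in species)
      write_tsv(st[[sp]], file.path(config$out_dir,
                                    sprintf("structure_%s.tsv", sp)))
    st
  })

  duplications <- run_stage("duplication", log_path, {
    dup <- lapply(species, function(sp) {
      fam <- calls[[sp]]$gene_id[calls[[sp]]$family != "none"]
      ev <- find_paralogs(sim$proteins[[sp]][fam],
                          synthetic_locations(sim, sp),
                          min_identity = config$duplication_identity,
                          max_evalue = config$duplication_evalue,
                          tandem_window_bp = config$tandem_window_bp)
      write_tsv(ev, file.path(config$out_dir,
                              sprintf("duplications_%s.tsv", sp)))
      write_link_table(ev, synthetic_locations(sim, sp),
                       file.path(config$out_dir,
                                 sprintf("duplication_links_%s.tsv", sp)))
      ev
    })
    names(dup) <- species
    dup
  })

  orthologs <- run_stage("orthologs", log_path, {
    if (length(species) < 2) list() else {
      ort <- lapply(species[-1], function(sp) {
        fam1 <- calls[[species[1]]]$gene_id[
          calls[[species[1]]]$family != "none"]
        fam2 <- calls[[sp]]$gene_id[calls[[sp]]$family != "none"]
        o <- find_orthologs_bbh(sim$proteins[[species[1]]][fam1],
                                sim$proteins[[sp]][fam2],
                                max_evalue = config$bbh_evalue)
        write_tsv(o, file.path(config$out_dir,
                               sprintf("orthologs_%s_%s.tsv", species[1],
                                       sp)))
        o
      })
      names(ort) <- species[-1]
      ort
    }
  })

  expression <- run_stage("expression", log_path, {
    ex <- generate_expression(sim$truth,
                              dispersion = config$expression_dispersion,
                              seed = config$seed)
    fp <- fpkm(ex$counts, ex$lengths_kb, ex$totals)
    lg <- log_transform(fp, offset = config$log_offset)
    cl <- cluster_expression(lg)
    write_tsv(data.frame(gene_id = rownames(cl$ordered_matrix),
                         cl$ordered_matrix, check.names = FALSE),
              file.path(config$out_dir, "expression_log10_fpkm.tsv"))
    list(counts = ex$counts, fpkm = fp, log10 = lg, clustering = cl,
         blocks = ex$blocks)
  })

  summary_tallies <- run_stage("report", log_path, {
    counts_tab <- legume_family_counts()
    tal <- lapply(species, function(sp) family_tally(calls[[sp]]))
    names(tal) <- species
    rows <- lapply(species, function(sp) {
      t <- tal[[sp]]
      data.frame(species = sp, t(t$subgroup_counts), t(t$other_counts),
                 dreb_total = t$dreb_total, erf_total = t$erf_total,
                 family_total = t$family_total, check.names = FALSE)
    })
    write_tsv(do.call(rbind, rows),
              file.path(config$out_dir, "summary_tally.tsv"))
    tal
  })

  cfg_path <- file.path(config$out_dir, "config.txt")
  write_config(config[setdiff(names(config), c("synthetic", "out_dir"))],
               cfg_path)
  files <- setdiff(list.files(config$out_dir, recursive = TRUE),
                   "run.log")
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(config$out_dir, files))),
    stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(config$out_dir, "manifest.tsv"))

  invisible(structure(list(sim = sim, hits = hits, calls = calls,
                           structures = structures,
                           duplications = duplications,
                           orthologs = orthologs, expression = expression,
                           tallies = summary_tallies, manifest = manifest,
                           config = config),
                      class = "ap2erf_run"))
}

#' @export
print.ap2erf_run <- function(x, ...) {
  cat(sprintf("<ap2erf_run> %s: %d species, %d output files\n",
              x$config$out_dir, length(x$calls), nrow(x$manifest)))
  invisible(x)
}
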