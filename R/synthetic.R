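# Synthetic genome generator: paired proteome/gene-model/expression/Ct
# fixtures with a machine-readable truth table, so every downstream stage is
# testable without external downloads.

#' Configuration for the synthetic-genome generator
#'
#' Defaults emulate a legume-like AP2/ERF + HSP90 complement: the subfamily
#' mix mirrors the relative subfamily sizes observed in the five published
#' legume proteomes (ERF-most, then DREB, AP2, ANT, with few RAV/soloist and
#' a handful of HSP90s), plus unrelated background genes. Species beyond the
#' first are generated as 1:1 orthologous copies of the first species'
#' genes (each retained with probability `planted_ortholog_fraction`,
#' otherwise replaced by a species-specific background gene).
#'
#' @param species_count Number of species (>= 1).
#' @param genes_per_species Genes generated per species.
#' @param chromosome_count Chromosomes per species.
#' @param chromosome_length Chromosome length in bp.
#' @param subfamily_mix Named proportions over `AP2`, `ANT`, `ERF`, `DREB`,
#'   `RAV`, `soloist`, `HSP90`, `background`; must sum to 1.
#' @param planted_tandem_pairs Tandem duplication pairs planted in species 1.
#' @param planted_segmental_pairs Segmental duplication pairs planted in
#'   species 1.
#' @param planted_ortholog_fraction Probability that a species-1 gene has an
#'   orthologous copy in each further species.
#' @param noise_mutation_rate Per-site substitution probability applied to
#'   every emitted protein (0 = noise-free).
#' @param paralog_identity Target whole-protein identity of planted
#'   duplicate copies (divergence confined to inter-domain segments).
#' @param dreb_e19_majority Fraction of DREB genes with the canonical E at
#'   domain position 19 (the rest draw a non-E residue; position 14 stays V).
#' @param crf_fraction Fraction of ERF genes carrying the CRF core motif;
#'   37.5% of those also carry the C-terminal SP[T/V]SVL motif.
#' @param expression_blocks Number of expression blocks genes are assigned
#'   to.
#' @param seed Integer seed; a fixed seed gives byte-identical fixtures.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(species_count = 2,
                             genes_per_species = 60,
                             chromosome_count = 8,
                             chromosome_length = 4e7,
                             subfamily_mix = c(AP2 = 0.06, ANT = 0.04,
                                               ERF = 0.30, DREB = 0.17,
                                               RAV = 0.02, soloist = 0.02,
                                               HSP90 = 0.03,
                                               background = 0.36),
                             planted_tandem_pairs = 2,
                             planted_segmental_pairs = 2,
                             planted_ortholog_fraction = 1,
                             noise_mutation_rate = 0,
                             paralog_identity = 0.92,
                             dreb_e19_majority = 0.9,
                             crf_fraction = 0.1,
                             expression_blocks = 2,
                             seed = 1) {
  mix_names <- c("AP2", "ANT", "ERF", "DREB", "RAV", "soloist", "HSP90",
                 "background")
  missing <- setdiff(mix_names, names(subfamily_mix))
  if (length(missing) > 0)
    stopf("subfamily_mix is missing: %s", paste(missing, collapse = ", "))
  subfamily_mix <- subfamily_mix[mix_names]
  if (abs(sum(subfamily_mix) - 1) > 1e-9)
    stopf("subfamily_mix proportions must sum to 1 (got %.6f)",
          sum(subfamily_mix))
  counts <- c(species_count, genes_per_species, chromosome_count,
              chromosome_length, planted_tandem_pairs,
              planted_segmental_pairs)
  if (any(counts < 0)) stopf("all counts must be >= 0")
  if (species_count < 1 || genes_per_species < 1 || chromosome_count < 1)
    stopf("species, gene and chromosome counts must be >= 1")
  if (planted_ortholog_fraction < 0 || planted_ortholog_fraction > 1)
    stopf("planted_ortholog_fraction must be in [0, 1]")
  if (noise_mutation_rate < 0 || noise_mutation_rate > 1)
    stopf("noise_mutation_rate must be in [0, 1]")
  structure(list(species_count = as.integer(species_count),
                 genes_per_species = as.integer(genes_per_species),
                 chromosome_count = as.integer(chromosome_count),
                 chromosome_length = chromosome_length,
                 subfamily_mix = subfamily_mix,
                 planted_tandem_pairs = as.integer(planted_tandem_pairs),
                 planted_segmental_pairs =
                   as.integer(planted_segmental_pairs),
                 planted_ortholog_fraction = planted_ortholog_fraction,
                 noise_mutation_rate = noise_mutation_rate,
                 paralog_identity = paralog_identity,
                 dreb_e19_majority = dreb_e19_majority,
                 crf_fraction = crf_fraction,
                 expression_blocks = as.integer(expression_blocks),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

rnd_aa <- function(n) {
  bgf <- aa_background()
  sample(names(bgf), n, replace = TRUE, prob = bgf)
}

mutate_chars <- function(chars, rate) {
  if (rate <= 0) return(chars)
  hit <- which(stats::runif(length(chars)) < rate)
  for (p in hit) chars[p] <- sample(setdiff(AA20, chars[p]), 1)
  chars
}

# substitutions restricted to positions outside planted domains
mutate_outside_domains <- function(chars, domains, n_subs) {
  occupied <- unlist(mapply(seq, domains$start, domains$end,
                            SIMPLIFY = FALSE))
  eligible <- setdiff(seq_along(chars), occupied)
  n_subs <- min(n_subs, length(eligible))
  for (p in sample(eligible, n_subs)) {
    chars[p] <- sample(setdiff(AA20, chars[p]), 1)
  }
  chars
}

domain_consensus <- function(domain) {
  cached(paste0("consensus_", domain), {
    f <- c(B3 = "b3_synthetic_seed.afa",
           HATPase_c = "hatpase_c_synthetic_seed.afa",
           HSP90 = "hsp90_synthetic_seed.afa")[[domain]]
    read_fasta_chars(extdata_path("seed_alignments", f))[[1]]
  })
}

# chickpea-like subgroup proportions within DREB (A) and narrow-ERF (B)
A_PROPS <- c(A1 = 6, A2 = 5, A3 = 1, A4 = 14, A5 = 10, A6 = 7) / 43
B_PROPS <- c(B1 = 12, B2 = 5, B3 = 23, B4 = 14, B5 = 8, B6 = 14) / 76

# positions protected from per-gene divergence: the AP2 landmark anchors
# (YRG, RPWG, WLG, F31, RAYD, M50) and the diagnostic residues 14/19; for the
# other domains, the embedded signature motif region
AP2_ANCHOR_POS <- c(1, 2, 3, 7, 8, 9, 10, 27, 28, 29, 31, 41, 42, 43, 44, 50)
DOMAIN_PROTECT <- list(B3 = 18:32, HATPase_c = 25:39, HSP90 = 31:40)
# per-instance substitution counts: every planted domain copy diverges from
# its flavour consensus so that unrelated genes sharing a domain stay well
# below the 80% duplication-identity gate, while planted duplicate/ortholog
# copies (which inherit the instance) stay above it
INDIV_SUBS <- c(AP2 = 14, B3 = 12, HATPase_c = 16, HSP90 = 18)

individuate <- function(chars, protected, n_subs) {
  eligible <- setdiff(seq_along(chars), protected)
  for (p in sample(eligible, min(n_subs, length(eligible)))) {
    chars[p] <- sample(setdiff(AA20, chars[p]), 1)
  }
  chars
}

# construct one clean (pre-noise) protein archetype for a truth label
make_archetype <- function(label, cfg) {
  refs <- ap2_references()
  dom <- function(nm) strsplit(refs[[paste0("REF_", nm)]], "")[[1]]
  # per-gene idiosyncratic divergence of an AP2-domain instance, keeping the
  # anchors, the diagnostics and (for ERF/DREB) the subgroup signature
  indiv_ap2 <- function(chars, base = NULL) {
    protected <- c(AP2_ANCHOR_POS, 14, 19)
    if (!is.null(base)) protected <- c(protected, which(chars != dom(base)))
    individuate(chars, protected, INDIV_SUBS[["AP2"]])
  }
  indiv_other <- function(name) {
    individuate(strsplit(domain_consensus(name), "")[[1]],
                DOMAIN_PROTECT[[name]], INDIV_SUBS[[name]])
  }
  seg <- function(lo, hi) rnd_aa(sample(lo:hi, 1))
  add <- function(parts, domains, name, chars) {
    at <- length(parts$seq) + 1L
    parts$seq <- c(parts$seq, chars)
    parts$domains <- rbind(parts$domains,
                           data.frame(domain = name, start = at,
                                      end = at + length(chars) - 1L))
    parts
  }
  p <- list(seq = character(0),
            domains = data.frame(domain = character(), start = integer(),
                                 end = integer()))
  subgroup <- "none"; crf_core <- FALSE; crf_cterm <- FALSE
  hsp90_group <- NA_integer_
  if (label %in% c("ERF", "DREB")) {
    if (label == "DREB") {
      subgroup <- sample(names(A_PROPS), 1, prob = A_PROPS)
      d <- indiv_ap2(dom(subgroup), base = "DREB_CONS")
      if (stats::runif(1) > cfg$dreb_e19_majority)
        d[19] <- sample(setdiff(AA20, "E"), 1)
    } else {
      subgroup <- sample(names(B_PROPS), 1, prob = B_PROPS)
      d <- indiv_ap2(dom(subgroup), base = "ERF_CONS")
      crf_core <- stats::runif(1) < cfg$crf_fraction
      crf_cterm <- crf_core && stats::runif(1) < 0.375
    }
    nterm <- seg(25, 60)
    if (crf_core) {
      at <- sample(5:(length(nterm) - 6), 1)
      nterm[at:(at + 5)] <- strsplit("ATDQSS", "")[[1]]
    }
    p$seq <- nterm
    p <- add(p, NULL, "AP2", d)
    p$seq <- c(p$seq, seg(30, 80))
    if (crf_cterm) {
      L <- length(p$seq)
      p$seq[(L - 9):(L - 4)] <- strsplit("SPTSVL", "")[[1]]
    }
  } else if (label %in% c("AP2", "ANT")) {
    p$seq <- seg(20, 50)
    p <- add(p, NULL, "AP2", indiv_ap2(dom(paste0(label, "_R1"))))
    p$seq <- c(p$seq, seg(15, 30))
    p <- add(p, NULL, "AP2", indiv_ap2(dom(paste0(label, "_R2"))))
    p$seq <- c(p$seq, seg(30, 60))
  } else if (label == "RAV") {
    p$seq <- seg(10, 30)
    p <- add(p, NULL, "AP2", indiv_ap2(dom("ERF_CONS")))
    p$seq <- c(p$seq, seg(10, 25))
    p <- add(p, NULL, "B3", indiv_other("B3"))
    p$seq <- c(p$seq, seg(20, 50))
  } else if (label == "soloist") {
    p$seq <- seg(20, 50)
    p <- add(p, NULL, "AP2",
             individuate(dom("SOLOIST"),
                         c(1, 2, 3, 9, 10, 27, 28, 29, 14, 19),
                         INDIV_SUBS[["AP2"]]))
    p$seq <- c(p$seq, seg(30, 60))
  } else if (label == "HSP90") {
    hsp90_group <- if (stats::runif(1) < 0.6) 1L else 2L
    p$seq <- seg(20, 40)
    p <- add(p, NULL, "HATPase_c", indiv_other("HATPase_c"))
    p$seq <- c(p$seq, seg(20, 40))
    p <- add(p, NULL, "HSP90", indiv_other("HSP90"))
    p$seq <- c(p$seq, seg(40, 80))
  } else {  # background
    p$seq <- rnd_aa(sample(150:300, 1))
  }
  n_intron <- switch(label,
    ERF = if (stats::runif(1) < 0.67) 0L else 1L,
    DREB = if (stats::runif(1) < 41 / 43) 0L else 1L,
    AP2 = sample(6:11, 1),
    ANT = sample(6:11, 1),
    RAV = 0L,
    soloist = sample(c(3L, 5L), 1),
    HSP90 = if (hsp90_group == 1L) sample(2:4, 1) else sample(14:19, 1),
    sample(0:5, 1))  # background
  list(seq = p$seq, domains = p$domains, label = label, subgroup = subgroup,
       crf_core = crf_core, crf_cterm = crf_cterm,
       hsp90_group = hsp90_group, n_intron = as.integer(n_intron))
}

# split a CDS of `cds_len` nt into n_intron+1 exon lengths (each >= 3 nt)
draw_exon_lengths <- function(cds_len, n_intron) {
  if (n_intron == 0) return(cds_len)
  repeat {
    bp <- sort(sample(seq(3, cds_len - 3), n_intron))
    lens <- diff(c(0, bp, cds_len))
    if (all(lens >= 3)) return(lens)
  }
}

# place a gene on a chromosome without overlapping existing genes
place_gene <- function(occupied, chrom_count, chrom_len, span,
                       chromosome = NULL, near = NULL, window = 5e6) {
  for (try in seq_len(400)) {
    chr <- if (is.null(chromosome)) sample(chrom_count, 1) else chromosome
    if (!is.null(near)) {
      off <- sample(c(-1, 1), 1) * sample(seq(5e4, min(window - span, 3e6)), 1)
      start <- near + off
      if (start < 1 || start + span - 1 > chrom_len) next
    } else {
      start <- sample(seq_len(max(1, chrom_len - span)), 1)
    }
    end <- start + span - 1
    occ <- occupied[[chr]]
    if (is.null(occ) ||
        !any(start <= occ[, 2] & end >= occ[, 1])) {
      occupied[[chr]] <- rbind(occ, c(start, end))
      return(list(occupied = occupied, chromosome = chr, start = start,
                  end = end))
    }
  }
  stopf("capacity error: unable to place a gene of span %d bp without overlap",
        span)
}

# realise a placed gene: exon layout, strand, coordinates, truth phases
realise_gene <- function(arch, species, gene_id, occupied, cfg,
                         chromosome = NULL, near = NULL,
                         force_intron_drop = FALSE) {
  n_intron <- arch$n_intron
  if (force_intron_drop && n_intron > 0) n_intron <- n_intron - 1L
  cds_len <- 3L * length(arch$seq) + 3L
  exon_lens <- draw_exon_lengths(cds_len, n_intron)
  intron_lens <- if (n_intron > 0) sample(80:2000, n_intron, replace = TRUE)
                 else integer(0)
  span <- sum(exon_lens) + sum(intron_lens)
  strand <- sample(c("+", "-"), 1)
  pl <- place_gene(occupied, cfg$chromosome_count, cfg$chromosome_length,
                   span, chromosome = chromosome, near = near)
  lens_g <- if (strand == "+") exon_lens else rev(exon_lens)
  introns_g <- if (strand == "+") intron_lens else rev(intron_lens)
  starts <- integer(length(lens_g)); ends <- integer(length(lens_g))
  pos <- pl$start
  for (i in seq_along(lens_g)) {
    starts[i] <- pos
    ends[i] <- pos + lens_g[i] - 1L
    pos <- ends[i] + 1L + if (i < length(lens_g)) introns_g[i] else 0L
  }
  model <- gene_model(gene_id, paste0("chr", pl$chromosome), strand,
                      data.frame(start = starts, end = ends))
  phases <- if (n_intron > 0)
    as.integer(cumsum(exon_lens)[seq_len(n_intron)] %% 3) else integer(0)
  list(occupied = pl$occupied, model = model, chromosome = pl$chromosome,
       start = pl$start, end = pl$end, strand = strand,
       n_intron = n_intron, phases = phases)
}

#' Generate synthetic genomes with planted truth
#'
#' Produces, for every species, a protein set and gene models plus a truth
#' table recording each gene's planted family/subfamily/subgroup label,
#' domain coordinates, diagnostic residues, intron count and splice phases,
#' expression-block membership, and the planted paralog and ortholog pairs.
#' Species 1 carries the planted tandem (same chromosome, within 5 Mb) and
#' segmental (different chromosome) duplicate pairs; further species are 1:1
#' orthologous copies. All randomness flows from `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return Object of class `ap2erf_synthetic`: list with `proteins` (named
#'   list of named character vectors per species), `models` (lists of
#'   [gene_model()] objects), `truth` (list of data frames `genes`,
#'   `paralogs`, `orthologs`) and `config`.
#' @export
generate_genomes <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  with_seed(cfg$seed, {
    species <- paste0("s", seq_len(cfg$species_count))
    labels <- sample(names(cfg$subfamily_mix), cfg$genes_per_species,
                     replace = TRUE, prob = cfg$subfamily_mix)
    archetypes <- list()      # ancestral (clean) genes, keyed by ancestor id
    anc_meta <- list()
    for (i in seq_along(labels)) {
      arch <- make_archetype(labels[i], cfg)
      arch$ancestor <- sprintf("anc%03d", i)
      arch$block <- sample.int(cfg$expression_blocks, 1)
      archetypes[[arch$ancestor]] <- arch
    }
    # planted duplications: copies of family archetypes with divergence
    # confined to inter-domain segments (the copy keeps the family signature)
    fam_ids <- names(archetypes)[vapply(archetypes, function(a)
      a$label != "background", logical(1))]
    n_pairs <- cfg$planted_tandem_pairs + cfg$planted_segmental_pairs
    if (n_pairs > length(fam_ids))
      stopf("not enough family genes (%d) to plant %d duplicate pairs",
            length(fam_ids), n_pairs)
    donors <- if (n_pairs > 0) sample(fam_ids, n_pairs) else character(0)
    dup_info <- list()
    for (k in seq_len(n_pairs)) {
      donor <- archetypes[[donors[k]]]
      copy <- donor
      copy$ancestor <- sprintf("anc%03dd", match(donors[k], names(archetypes)))
      n_subs <- round((1 - cfg$paralog_identity) * length(donor$seq))
      copy$seq <- mutate_outside_domains(donor$seq, donor$domains, n_subs)
      drop_intron <- donor$n_intron > 0 && stats::runif(1) < 0.25
      copy$force_drop <- drop_intron
      archetypes[[copy$ancestor]] <- copy
      dup_info[[k]] <- list(donor = donors[k], copy = copy$ancestor,
                            tandem = k <= cfg$planted_tandem_pairs)
    }

    proteins <- stats::setNames(vector("list", length(species)), species)
    models <- stats::setNames(vector("list", length(species)), species)
    gene_rows <- list()
    paralog_rows <- list()
    gene_of <- list()  # gene_of[[sp]][[ancestor]] -> gene id
    bg_counter <- 0L

    for (sp_i in seq_along(species)) {
      sp <- species[sp_i]
      occupied <- vector("list", cfg$chromosome_count)
      proteins[[sp]] <- character(0)
      models[[sp]] <- list()
      gene_of[[sp]] <- character(0)
      counter <- 0L
      present <- names(archetypes)
      if (sp_i > 1) {
        keep <- stats::runif(length(present)) <= cfg$planted_ortholog_fraction
        dropped <- present[!keep]
        present <- present[keep]
      } else dropped <- character(0)
      placed <- character(0)  # ancestors placed in this species
      for (anc in present) {
        arch <- archetypes[[anc]]
        counter <- counter + 1L
        gid <- sprintf("%s_g%03d", sp, counter)
        chrom <- NULL; near <- NULL
        if (sp_i == 1) {
          k <- which(vapply(dup_info, function(d) d$copy == anc, logical(1)))
          if (length(k) == 1 && dup_info[[k]]$tandem) {
            donor_gid <- gene_of[[sp]][[dup_info[[k]]$donor]]
            drow <- Filter(function(r) r$gene_id == donor_gid, gene_rows)
            chrom <- drow[[1]]$chromosome_idx
            near <- drow[[1]]$start
          } else if (length(k) == 1) {
            donor_gid <- gene_of[[sp]][[dup_info[[k]]$donor]]
            drow <- Filter(function(r) r$gene_id == donor_gid, gene_rows)
            chrom <- sample(setdiff(seq_len(cfg$chromosome_count),
                                    drow[[1]]$chromosome_idx), 1)
          }
        }
        rg <- realise_gene(arch, sp, gid, occupied, cfg, chromosome = chrom,
                           near = near,
                           force_intron_drop = isTRUE(arch$force_drop))
        occupied <- rg$occupied
        seq_chars <- mutate_chars(arch$seq, cfg$noise_mutation_rate)
        ap2_first <- arch$domains[arch$domains$domain == "AP2", , drop = FALSE]
        r14 <- r19 <- NA_character_
        if (nrow(ap2_first) > 0) {
          st <- min(ap2_first$start)
          r14 <- seq_chars[st + 13L]
          r19 <- seq_chars[st + 18L]
        }
        proteins[[sp]][[gid]] <- paste(seq_chars, collapse = "")
        models[[sp]][[gid]] <- rg$model
        gene_of[[sp]][[anc]] <- gid
        placed <- c(placed, anc)
        gene_rows[[length(gene_rows) + 1]] <- list(
          species = sp, gene_id = gid, ancestor = anc, label = arch$label,
          family = switch(arch$label, background = "none",
                          HSP90 = "HSP90", "AP2/ERF"),
          subgroup = arch$subgroup, residue14 = r14, residue19 = r19,
          crf_core = arch$crf_core, crf_cterm = arch$crf_cterm,
          hsp90_group = arch$hsp90_group,
          protein_length = length(seq_chars),
          intron_count = rg$n_intron,
          phases = paste(rg$phases, collapse = ","),
          chromosome = paste0("chr", rg$chromosome),
          chromosome_idx = rg$chromosome,
          start = rg$start, end = rg$end, strand = rg$strand,
          expression_block = arch$block,
          domains = paste(sprintf("%s:%d-%d", arch$domains$domain,
                                  arch$domains$start, arch$domains$end),
                          collapse = ";"))
      }
      # species-specific background fillers replace dropped orthologs
      if (sp_i > 1) {
        for (d in dropped) {
          counter <- counter + 1L
          bg_counter <- bg_counter + 1L
          gid <- sprintf("%s_g%03d", sp, counter)
          arch <- make_archetype("background", cfg)
          arch$block <- sample.int(cfg$expression_blocks, 1)
          rg <- realise_gene(arch, sp, gid, occupied, cfg)
          occupied <- rg$occupied
          seq_chars <- mutate_chars(arch$seq, cfg$noise_mutation_rate)
          proteins[[sp]][[gid]] <- paste(seq_chars, collapse = "")
          models[[sp]][[gid]] <- rg$model
          gene_rows[[length(gene_rows) + 1]] <- list(
            species = sp, gene_id = gid,
            ancestor = sprintf("%s_private%03d", sp, bg_counter),
            label = "background", family = "none", subgroup = "none",
            residue14 = NA_character_, residue19 = NA_character_,
            crf_core = FALSE, crf_cterm = FALSE, hsp90_group = NA_integer_,
            protein_length = length(seq_chars),
            intron_count = rg$n_intron,
            phases = paste(rg$phases, collapse = ","),
            chromosome = paste0("chr", rg$chromosome),
            chromosome_idx = rg$chromosome,
            start = rg$start, end = rg$end, strand = rg$strand,
            expression_block = arch$block, domains = "")
        }
      }
      # per-species paralog truth from realised coordinates
      for (k in seq_along(dup_info)) {
        d <- dup_info[[k]]
        if (!(d$donor %in% placed && d$copy %in% placed)) next
        ga <- gene_of[[sp]][[d$donor]]; gb <- gene_of[[sp]][[d$copy]]
        ra <- Filter(function(r) r$gene_id == ga, gene_rows)[[1]]
        rb <- Filter(function(r) r$gene_id == gb, gene_rows)[[1]]
        same_chr <- ra$chromosome_idx == rb$chromosome_idx
        dist <- if (same_chr) abs(ra$start - rb$start) else NA_real_
        cls <- if (same_chr && dist <= TANDEM_WINDOW_BP) "tandem"
               else "segmental"
        paralog_rows[[length(paralog_rows) + 1]] <- data.frame(
          species = sp, gene_a = ga, gene_b = gb, class = cls,
          distance = dist, stringsAsFactors = FALSE)
      }
    }
    genes <- do.call(rbind, lapply(gene_rows, function(r)
      as.data.frame(r[setdiff(names(r), "chromosome_idx")],
                    stringsAsFactors = FALSE)))
    paralogs <- if (length(paralog_rows) > 0)
      do.call(rbind, paralog_rows)
    else data.frame(species = character(), gene_a = character(),
                    gene_b = character(), class = character(),
                    distance = numeric(), stringsAsFactors = FALSE)
    # ortholog truth: copies of the same ancestor across species pairs
    orth_rows <- list()
    for (a in seq_len(length(species) - 1)) {
      for (b in seq(a + 1, length(species))) {
        if (length(species) < 2) break
        shared <- intersect(names(gene_of[[species[a]]]),
                            names(gene_of[[species[b]]]))
        shared <- shared[!grepl("_private", shared)]
        if (length(shared) == 0) next
        orth_rows[[length(orth_rows) + 1]] <- data.frame(
          species_a = species[a], gene_a =
            unname(unlist(gene_of[[species[a]]][shared])),
          species_b = species[b], gene_b =
            unname(unlist(gene_of[[species[b]]][shared])),
          ancestor = shared, stringsAsFactors = FALSE)
      }
    }
    orthologs <- if (length(orth_rows) > 0) do.call(rbind, orth_rows)
    else data.frame(species_a = character(), gene_a = character(),
                    species_b = character(), gene_b = character(),
                    ancestor = character(), stringsAsFactors = FALSE)
    structure(list(proteins = proteins, models = models,
                   truth = list(genes = genes, paralogs = paralogs,
                                orthologs = orthologs),
                   config = cfg),
              class = "ap2erf_synthetic")
  })
}

#' @export
print.ap2erf_synthetic <- function(x, ...) {
  cat(sprintf("<ap2erf_synthetic> %d species x %d genes (seed %d)\n",
              length(x$proteins), length(x$proteins[[1]]), x$config$seed))
  print(table(x$truth$genes$label[x$truth$genes$species == "s1"]))
  invisible(x)
}

#' Gene locations of a synthetic genome
#'
#' @param sim An `ap2erf_synthetic` object.
#' @param species Species id (e.g. `"s1"`).
#' @return Data frame with `gene_id`, `chromosome`, `start`, `end`, `strand`.
#' @export
synthetic_locations <- function(sim, species = "s1") {
  g <- sim$truth$genes
  g <- g[g$species == species,
         c("gene_id", "chromosome", "start", "end", "strand")]
  rownames(g) <- NULL
  g
}

#' Generate a block-structured expression count matrix
#'
#' Counts follow a negative-binomial model whose mean is
#' `block_mean * transcript_kb * library_size / 1e6`, so genes of the same
#' truth expression block co-cluster; at `dispersion = 0` counts equal their
#' means exactly.
#'
#' @param truth Truth table list from [generate_genomes()] (or its `genes`
#'   data frame); one species is profiled.
#' @param conditions Condition labels.
#' @param replicates Replicates per condition (>= 2).
#' @param block_means Blocks x conditions matrix of mean FPKM (default two
#'   blocks with 8-fold separation, mirrored across conditions).
#' @param dispersion Negative-binomial dispersion (0 = noise-free).
#' @param species Species to profile.
#' @param seed Integer seed.
#' @return List with `counts`, `lengths_kb`, `totals`, `samples`, `blocks`.
#' @export
generate_expression <- function(truth, conditions = c("control", "stressed"),
                                replicates = 3, block_means = NULL,
                                dispersion = 0.05, species = "s1",
                                seed = 1) {
  genes <- if (is.data.frame(truth)) truth else truth$genes
  genes <- genes[genes$species == species, , drop = FALSE]
  if (nrow(genes) == 0) stopf("truth table has no genes for species %s",
                              species)
  if (replicates < 2) stopf("design error: need >= 2 replicates")
  n_block <- max(genes$expression_block)
  if (is.null(block_means)) {
    base <- 20 * 8^(seq_len(n_block) - 1)
    block_means <- cbind(base, rev(base))[, seq_along(conditions),
                                          drop = FALSE]
  }
  if (nrow(block_means) < n_block)
    stopf("block_means needs a row per expression block")
  with_seed(seed, {
    samples <- expand.grid(replicate = seq_len(replicates),
                           condition = conditions,
                           stringsAsFactors = FALSE)
    samples$sample_id <- sprintf("%s_r%d", samples$condition,
                                 samples$replicate)
    totals <- round(stats::runif(nrow(samples), 1.5e7, 2.5e7))
    names(totals) <- samples$sample_id
    # transcript length = CDS nt of the protein (3 per residue + stop)
    lengths_kb <- (3 * genes$protein_length + 3) / 1000
    names(lengths_kb) <- genes$gene_id
    mu_expr <- block_means[genes$expression_block,
                           match(samples$condition, conditions),
                           drop = FALSE]
    mu <- sweep(sweep(mu_expr, 1, lengths_kb, "*"), 2, totals / 1e6, "*")
    dimnames(mu) <- list(genes$gene_id, samples$sample_id)
    counts <- if (dispersion > 0) {
      matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                            size = 1 / dispersion),
             nrow = nrow(mu), dimnames = dimnames(mu))
    } else mu
    list(counts = counts, lengths_kb = lengths_kb, totals = totals,
         samples = samples,
         blocks = stats::setNames(genes$expression_block, genes$gene_id))
  })
}

#' Generate a qRT-PCR Ct table with planted fold changes
#'
#' Ct values are constructed so that applying the 2^-ddCt formula recovers
#' the planted per-gene fold change exactly when `noise_sd = 0`: the
#' calibrator condition carries a fixed dCt and the stressed condition
#' carries `dCt - log2(fold_change)`.
#'
#' @param fold_changes Named numeric vector of planted fold changes (> 0),
#'   names are gene ids.
#' @param replicates Biological replicates per condition.
#' @param noise_sd Gaussian noise (Ct units) added to each measured Ct.
#' @param conditions Two labels: calibrator first, treated second.
#' @param seed Integer seed.
#' @return Ct table data frame suitable for [ddct_fold_change()].
#' @export
generate_ct_table <- function(fold_changes, replicates = 3, noise_sd = 0,
                              conditions = c("control", "stressed"),
                              seed = 1) {
  if (any(fold_changes <= 0)) stopf("fold changes must be > 0")
  if (is.null(names(fold_changes)))
    names(fold_changes) <- sprintf("gene%02d", seq_along(fold_changes))
  with_seed(seed, {
    out <- list()
    for (g in names(fold_changes)) {
      for (cond_i in 1:2) {
        dct <- if (cond_i == 1) 2 else 2 - log2(fold_changes[[g]])
        for (r in seq_len(replicates)) {
          endo <- 20 + stats::rnorm(1, 0, noise_sd)
          out[[length(out) + 1]] <- data.frame(
            gene_id = g,
            sample_id = sprintf("%s_r%d", conditions[cond_i], r),
            condition = conditions[cond_i],
            is_calibrator = cond_i == 1,
            ct_target = endo + dct + stats::rnorm(1, 0, noise_sd),
            ct_endogenous = endo,
            stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  })
}
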