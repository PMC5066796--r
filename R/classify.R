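# Decision-tree classification of scanned proteins: superfamily membership,
# subfamily (AP2 / ANT / ERF / DREB / RAV / soloist / HSP90), CRF and
# conserved-element flags, physio-chemical properties and summary tallies.

SUBFAMILIES <- c("AP2", "ANT", "ERF", "DREB", "RAV", "soloist", "HSP90",
                 "unresolved")

#' Assign superfamily membership from resolved domain hits
#'
#' At least one AP2 domain puts a protein in the AP2/ERF superfamily; the
#' joint presence of HATPase_c and HSP90 domains defines the HSP90 family. A
#' protein satisfying both (pathological) is called AP2/ERF with a warning.
#'
#' @param hits Hit data frame for a single protein (see [scan_domains()]).
#' @return `"AP2/ERF"`, `"HSP90"` or `"none"`.
#' @export
assign_superfamily <- function(hits) {
  has_ap2 <- any(hits$domain == "AP2")
  has_hsp <- all(c("HATPase_c", "HSP90") %in% hits$domain)
  if (has_ap2 && has_hsp) {
    warning("protein carries both AP2 and HATPase_c+HSP90 domains; ",
            "classifying as AP2/ERF", call. = FALSE)
    return("AP2/ERF")
  }
  if (has_ap2) return("AP2/ERF")
  if (has_hsp) return("HSP90")
  "none"
}

# best identity (%) of a domain sequence against a reference set. Domain
# instances reported by the profile scanner have the profile's fixed length,
# so equal-length pairs are compared column-wise (ungapped); unequal lengths
# fall back to global alignment with gap columns excluded from the
# denominator.
best_reference_identity <- function(domain_sequence, references) {
  best <- 0
  q <- strsplit(domain_sequence, "")[[1]]
  for (r in references) {
    if (nchar(r) == length(q)) {
      ident <- 100 * mean(q == strsplit(r, "")[[1]])
    } else {
      al <- Biostrings::pairwiseAlignment(domain_sequence, r,
                                          type = "global",
                                          substitutionMatrix = blosum62(),
                                          gapOpening = 11, gapExtension = 1)
      ncols <- Biostrings::nmatch(al) + Biostrings::nmismatch(al)
      ident <- if (ncols > 0) 100 * Biostrings::nmatch(al) / ncols else 0
    }
    best <- max(best, ident)
  }
  best
}

# ERF/DREB-flavoured references used for the soloist homology cutoff
erf_reference_set <- function() {
  refs <- ap2_references()
  refs[grepl("^REF_(ERF|DREB|A[1-6]$|B[1-6]$)", names(refs))]
}

#' Subfamily call within the AP2/ERF superfamily
#'
#' AP2 + B3 domains give RAV; two AP2 domains give AP2; a single AP2 domain
#' with best identity to the ERF reference set below the soloist cutoff gives
#' soloist; any other single-AP2 protein belongs to the broad ERF subfamily
#' (split into ERF/DREB by [classify_erf_dreb()]). Phylogenetic refinement may
#' later re-assign single-AP2 genes clustering in the AP2 clade.
#'
#' @param hits Hit data frame for a single AP2/ERF-superfamily protein.
#' @param references Reference AP2 domains for the homology check.
#' @param soloist_identity_cutoff Identity (%) below which a single-AP2
#'   protein is called soloist (default 30).
#' @return List with `subfamily` (`"RAV"`, `"AP2"`, `"soloist"` or
#'   `"ERF-subfamily"`) and `homology_identity`.
#' @export
classify_subfamily <- function(hits, references = erf_reference_set(),
                               soloist_identity_cutoff = 30) {
  ap2 <- hits[hits$domain == "AP2", , drop = FALSE]
  if (nrow(ap2) == 0)
    stopf("classify_subfamily requires at least one AP2 domain hit")
  if (any(hits$domain == "B3"))
    return(list(subfamily = "RAV", homology_identity = NA_real_))
  if (nrow(ap2) >= 2)
    return(list(subfamily = "AP2", homology_identity = NA_real_))
  ident <- best_reference_identity(ap2$domain_sequence[1], references)
  if (ident < soloist_identity_cutoff)
    return(list(subfamily = "soloist", homology_identity = ident))
  list(subfamily = "ERF-subfamily", homology_identity = ident)
}

#' Split the broad ERF subfamily into ERF and DREB by diagnostic residues
#'
#' Valine at canonical AP2-domain position 14 gives DREB irrespective of the
#' residue at position 19 (position-14 primacy); alanine at position 14 gives
#' ERF (classically with aspartate at 19 -- a non-D residue at 19 is still
#' called ERF but flagged for audit); any other residue at 14 is unresolved.
#'
#' @param hit One AP2 hit row (from [scan_domains()]).
#' @param profile The AP2 profile that produced the hit.
#' @return List with `subfamily`, `residue14`, `residue19` and
#'   `flag_noncanonical19`.
#' @export
classify_erf_dreb <- function(hit, profile = bundled_profiles()$AP2) {
  r14 <- canonical_residue(hit, profile, 14)
  r19 <- canonical_residue(hit, profile, 19)
  if (is.na(r14) || is.na(r19))
    return(list(subfamily = "unresolved", residue14 = r14, residue19 = r19,
                flag_noncanonical19 = FALSE, flag_truncated = TRUE))
  sub <- if (r14 == "V") "DREB" else if (r14 == "A") "ERF" else "unresolved"
  list(subfamily = sub, residue14 = r14, residue19 = r19,
       flag_noncanonical19 = (r14 == "A" && r19 != "D"),
       flag_truncated = FALSE)
}

#' Detect cytokinin-response-factor motifs
#'
#' The CRF core is the pattern `A-T-D-x-S-S` N-terminal of the AP2 domain; the
#' putative MAP-kinase phosphorylation site is `S-P-[T/V]-S-V-L` within the
#' C-terminal third of the protein.
#'
#' @param sequence Full protein sequence.
#' @param ap2_start 1-based start of the AP2 domain on the protein.
#' @return List with logicals `crf_core` and `crf_cterm_motif`.
#' @export
detect_crf <- function(sequence, ap2_start) {
  nterm <- substr(sequence, 1, max(0, ap2_start - 1))
  n <- nchar(sequence)
  cterm <- substr(sequence, floor(2 * n / 3) + 1, n)
  list(crf_core = grepl("ATD.SS", nterm),
       crf_cterm_motif = grepl("SP[TV]SVL", cterm))
}

#' Detect conserved WLG / RAYD elements and the EAR repression motif
#'
#' WLG (or its YLG variant) and RAYD (or RAHD) are searched inside the matched
#' AP2 domain; the EAR repression motif is searched over the whole protein in
#' both published forms, `[LD]-x-L-x-L` and `D-L-N-x-x-P`.
#'
#' @param sequence Full protein sequence.
#' @param domain_sequence Matched AP2 domain sequence.
#' @return List with `wlg_state` (`"WLG"`, `"YLG"`, `"absent"`), `rayd_state`
#'   (`"RAYD"`, `"RAHD"`, `"absent"`), `ear_motif` and `ear_form`.
#' @export
detect_elements <- function(sequence, domain_sequence) {
  wlg <- if (grepl("WLG", domain_sequence)) "WLG"
         else if (grepl("YLG", domain_sequence)) "YLG" else "absent"
  rayd <- if (grepl("RAYD", domain_sequence)) "RAYD"
          else if (grepl("RAHD", domain_sequence)) "RAHD" else "absent"
  ear_lxlxl <- grepl("[LD].L.L", sequence)
  ear_dlnp <- grepl("DLN..P", sequence)
  form <- if (ear_lxlxl && ear_dlnp) "both" else if (ear_lxlxl) "LxLxL"
          else if (ear_dlnp) "DLNxxP" else "none"
  list(wlg_state = wlg, rayd_state = rayd,
       ear_motif = ear_lxlxl || ear_dlnp, ear_form = form)
}

#' Classify every protein of a proteome
#'
#' Runs the domain scan and the complete decision tree over a set of protein
#' sequences, with optional phylogenetic refinement: two-AP2-domain genes are
#' split into AP2 versus AINTEGUMENTA by clade assignment against the bundled
#' reference domains (falling back to nearest-reference identity when there
#' are too few taxa for a tree).
#'
#' @param proteins Named character vector of protein sequences.
#' @param profiles Domain profiles (default: bundled set).
#' @param references Labelled reference domains (default: bundled set).
#' @param soloist_identity_cutoff Soloist homology cutoff (%, default 30).
#' @param phylo_refine Resolve AP2 vs ANT through a reference-anchored tree.
#' @param bootstrap_replicates Bootstrap replicates for clade support.
#' @param seed Integer seed for the bootstrap resampling stream.
#' @param hits Optional precomputed hit table (from [scan_proteome()]).
#' @return Data frame with one row per protein (a family-call table).
#' @export
classify_proteome <- function(proteins, profiles = bundled_profiles(),
                              references = ap2_references(),
                              soloist_identity_cutoff = 30,
                              phylo_refine = TRUE,
                              bootstrap_replicates = 100, seed = 1,
                              hits = NULL) {
  if (is.null(hits)) hits <- scan_proteome(proteins, profiles)
  calls <- lapply(names(proteins), function(id) {
    h <- hits[hits$protein_id == id, , drop = FALSE]
    classify_one(proteins[[id]], id, h, profiles, soloist_identity_cutoff)
  })
  calls <- do.call(rbind, c(calls, list(make.row.names = FALSE)))
  if (phylo_refine) {
    calls <- refine_ap2_ant(calls, hits, references,
                            bootstrap_replicates = bootstrap_replicates,
                            seed = seed)
  }
  attr(calls, "hits") <- hits
  calls
}

classify_one <- function(sequence, id, hits, profiles,
                         soloist_identity_cutoff) {
  out <- data.frame(gene_id = id, family = "none", subfamily = "none",
                    subgroup = "none",
                    residue14 = NA_character_, residue19 = NA_character_,
                    crf_core = FALSE, crf_cterm_motif = FALSE,
                    wlg_state = "absent", rayd_state = "absent",
                    ear_motif = FALSE, n_ap2 = 0L,
                    homology_identity = NA_real_,
                    flag_noncanonical19 = FALSE,
                    stringsAsFactors = FALSE)
  fam <- assign_superfamily(hits)
  out$family <- fam
  if (fam == "HSP90") {
    out$subfamily <- "HSP90"
    return(out)
  }
  if (fam == "none") return(out)
  ap2 <- hits[hits$domain == "AP2", , drop = FALSE]
  ap2 <- ap2[order(ap2$start), , drop = FALSE]
  out$n_ap2 <- nrow(ap2)
  sub <- classify_subfamily(hits,
                            soloist_identity_cutoff = soloist_identity_cutoff)
  out$homology_identity <- sub$homology_identity
  first_hit <- ap2[1, , drop = FALSE]
  elems <- detect_elements(sequence, first_hit$domain_sequence)
  out$wlg_state <- elems$wlg_state
  out$rayd_state <- elems$rayd_state
  out$ear_motif <- elems$ear_motif
  if (sub$subfamily != "ERF-subfamily") {
    out$subfamily <- sub$subfamily
    return(out)
  }
  ed <- classify_erf_dreb(first_hit, profiles$AP2)
  out$subfamily <- ed$subfamily
  out$residue14 <- ed$residue14
  out$residue19 <- ed$residue19
  out$flag_noncanonical19 <- ed$flag_noncanonical19
  if (ed$subfamily %in% c("ERF", "DREB")) {
    crf <- detect_crf(sequence, first_hit$start)
    out$crf_core <- crf$crf_core
    out$crf_cterm_motif <- crf$crf_cterm_motif
  }
  out
}

# split two-AP2-domain calls into AP2 vs ANT using the bundled repeat
# references; clade assignment on an NJ tree when enough taxa, otherwise
# nearest reference by identity
refine_ap2_ant <- function(calls, hits, references, bootstrap_replicates = 100,
                           seed = 1) {
  two_dom <- calls$gene_id[calls$subfamily == "AP2"]
  if (length(two_dom) == 0) return(calls)
  refs <- references[grepl("^REF_(AP2|ANT)_R[12]$", names(references))]
  ref_labels <- ifelse(grepl("^REF_AP2", names(refs)), "AP2", "ANT")
  names(ref_labels) <- names(refs)
  doms <- vapply(two_dom, function(id) {
    h <- hits[hits$protein_id == id & hits$domain == "AP2", , drop = FALSE]
    h$domain_sequence[which.min(h$start)]
  }, character(1))
  if (all(nchar(c(doms, refs)) == nchar(refs[[1]])) &&
      length(doms) + length(refs) >= 4) {
    aln <- c(doms, refs)
    tree <- nj_tree(pdistance(aln))
    support <- bootstrap_support(aln, replicates = bootstrap_replicates,
                                 seed = seed, tree = tree)
    grp <- assign_groups(tree, ref_labels, support = support)
    lab <- grp$subgroup[match(two_dom, grp$gene_id)]
  } else {
    lab <- vapply(doms, function(d) {
      id_ap2 <- best_reference_identity(d, refs[ref_labels == "AP2"])
      id_ant <- best_reference_identity(d, refs[ref_labels == "ANT"])
      if (id_ant > id_ap2) "ANT" else "AP2"
    }, character(1))
  }
  lab[is.na(lab) | lab == "none"] <- "AP2"
  calls$subfamily[match(two_dom, calls$gene_id)] <- lab
  calls
}

#' Physio-chemical properties of a protein
#'
#' Molecular weight is the sum of average residue masses plus one water;
#' the isoelectric point is solved by bisection on the net charge (side-chain
#' pKa values from the bundled table, termini at 8.6/3.6) to 0.01 pH units.
#' `X` residues contribute no mass and no charge.
#'
#' @param sequence Amino-acid sequence.
#' @return List with `length`, `molecular_weight` (Da) and
#'   `isoelectric_point`.
#' @export
compute_properties <- function(sequence) {
  letters <- check_aa_sequence(sequence)
  if (length(letters) == 0) stopf("empty sequence")
  tab <- aa_properties()
  mass <- stats::setNames(tab$avg_mass, tab$residue)
  counts <- table(factor(letters[letters != "X"], levels = tab$residue))
  mw <- sum(as.numeric(counts) * mass[names(counts)]) + 18.01524
  pi <- solve_pi(counts)
  list(length = length(letters), molecular_weight = mw,
       isoelectric_point = pi)
}

net_charge <- function(counts, ph) {
  tab <- aa_properties()
  q <- 1 / (1 + 10^(ph - 8.6)) - 1 / (1 + 10^(3.6 - ph))  # termini
  ion <- tab[tab$charge_sign != 0, ]
  for (i in seq_len(nrow(ion))) {
    n <- as.numeric(counts[ion$residue[i]])
    if (is.na(n) || n == 0) next
    if (ion$charge_sign[i] > 0) q <- q + n / (1 + 10^(ph - ion$pka_side[i]))
    else q <- q - n / (1 + 10^(ion$pka_side[i] - ph))
  }
  q
}

solve_pi <- function(counts, tol = 0.01) {
  lo <- 0; hi <- 14
  while (hi - lo > tol / 2) {
    mid <- (lo + hi) / 2
    if (net_charge(counts, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Summary tally of family calls in the style of the five-legume summary table
#'
#' Computes per-subgroup counts (A1-A6, B1-B6), the DREB total (sum of A
#' subgroups), the ERF-subfamily total (DREB total plus B subgroups), the
#' family total (plus AP2, ANT, RAV and soloist members), the percentage of
#' annotated genes and the density per Mb.
#'
#' @param calls Family-call data frame from [classify_proteome()], or `NULL`
#'   when `counts` is given.
#' @param counts Alternatively, a named numeric vector of printed counts with
#'   names `A1..A6`, `B1..B6`, `AP2`, `ANT`, `RAV`, `soloist`.
#' @param genome_gene_total Total annotated genes in the genome.
#' @param genome_size_mb Assembly size in Mb.
#' @return Object of class `ap2erf_tally`.
#' @export
family_tally <- function(calls = NULL, counts = NULL,
                         genome_gene_total = NA, genome_size_mb = NA) {
  if (!is.na(genome_gene_total) && genome_gene_total <= 0)
    stopf("genome_gene_total must be positive")
  if (!is.na(genome_size_mb) && genome_size_mb <= 0)
    stopf("genome_size_mb must be positive")
  grp_names <- c(paste0("A", 1:6), paste0("B", 1:6))
  if (is.null(counts)) {
    stopifnot(is.data.frame(calls))
    sub_counts <- table(factor(calls$subfamily, levels = SUBFAMILIES))
    grp <- table(factor(calls$subgroup, levels = grp_names))
    dreb_total <- sum(calls$subfamily == "DREB")
    b_total <- sum(calls$subfamily == "ERF")
    counts <- c(as.numeric(grp),
                sub_counts[["AP2"]], sub_counts[["ANT"]],
                sub_counts[["RAV"]], sub_counts[["soloist"]])
    names(counts) <- c(grp_names, "AP2", "ANT", "RAV", "soloist")
  } else {
    need <- c(grp_names, "AP2", "ANT", "RAV", "soloist")
    missing <- setdiff(need, names(counts))
    if (length(missing) > 0)
      stopf("counts is missing: %s", paste(missing, collapse = ", "))
    counts <- counts[need]
    dreb_total <- sum(counts[paste0("A", 1:6)])
    b_total <- sum(counts[paste0("B", 1:6)])
  }
  erf_total <- dreb_total + b_total
  family_total <- erf_total + sum(counts[c("AP2", "ANT", "RAV", "soloist")])
  structure(list(
    subgroup_counts = counts[grp_names],
    other_counts = counts[c("AP2", "ANT", "RAV", "soloist")],
    dreb_total = unname(dreb_total),
    erf_total = unname(erf_total),
    family_total = unname(family_total),
    percentage = if (is.na(genome_gene_total)) NA_real_ else
      round(100 * family_total / genome_gene_total, 2),
    density_per_mb = if (is.na(genome_size_mb)) NA_real_ else
      round(family_total / genome_size_mb, 2)),
    class = "ap2erf_tally")
}

#' @export
print.ap2erf_tally <- function(x, ...) {
  cat("AP2/ERF family tally\n")
  cat("  DREB (A1-A6): ", paste(x$subgroup_counts[1:6], collapse = " "),
      " | total ", x$dreb_total, "\n", sep = "")
  cat("  ERF  (B1-B6): ", paste(x$subgroup_counts[7:12], collapse = " "),
      " | total (incl. DREB) ", x$erf_total, "\n", sep = "")
  cat("  AP2 ", x$other_counts[["AP2"]], ", ANT ", x$other_counts[["ANT"]],
      ", RAV ", x$other_counts[["RAV"]], ", soloist ",
      x$other_counts[["soloist"]], "\n", sep = "")
  cat("  family total ", x$family_total, sep = "")
  if (!is.na(x$percentage)) cat(" (", x$percentage, "% of genes)", sep = "")
  if (!is.na(x$density_per_mb)) cat(", ", x$density_per_mb, " per Mb",
                                    sep = "")
  cat("\n")
  invisible(x)
}
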