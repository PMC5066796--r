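refs <- ap2_references()
prof <- bundled_profiles()

hit_for <- function(domain_seq, pad = 12, seed = 5) {
  prot <- paste0(random_protein(pad, seed = seed), domain_seq,
                 random_protein(40, seed = seed + 1))
  list(protein = prot, hits = scan_proteome(setNames(prot, "t1")))
}

test_that("superfamily assignment follows domain content", {
  ap2_hit <- data.frame(protein_id = "x", domain = "AP2", start = 1, end = 60,
                        score = 50, domain_sequence = "")
  hsp_hits <- data.frame(protein_id = "x", domain = c("HATPase_c", "HSP90"),
                         start = c(1, 100), end = c(70, 180), score = 50,
                         domain_sequence = "")
  expect_equal(assign_superfamily(ap2_hit), "AP2/ERF")
  expect_equal(assign_superfamily(hsp_hits), "HSP90")
  expect_equal(assign_superfamily(ap2_hit[0, ]), "none")
  expect_equal(assign_superfamily(hsp_hits[1, , drop = FALSE]), "none")
  expect_warning(out <- assign_superfamily(rbind(ap2_hit, hsp_hits)),
                 "AP2/ERF")
  expect_equal(out, "AP2/ERF")
})

test_that("subfamily decision tree: RAV, AP2, soloist, broad ERF", {
  b3 <- ap2erf:::domain_consensus("B3")
  rav <- hit_for(paste0(refs[["REF_ERF_CONS"]], random_protein(15, seed = 2),
                        b3))
  expect_equal(classify_subfamily(rav$hits)$subfamily, "RAV")
  two <- hit_for(paste0(refs[["REF_AP2_R1"]], random_protein(20, seed = 3),
                        refs[["REF_AP2_R2"]]))
  expect_equal(classify_subfamily(two$hits)$subfamily, "AP2")
  solo <- hit_for(refs[["REF_SOLOIST"]])
  out <- classify_subfamily(solo$hits)
  expect_equal(out$subfamily, "soloist")
  expect_lt(out$homology_identity, 30)
  erf <- hit_for(refs[["REF_B3"]])   # narrow-ERF subgroup flavour
  out2 <- classify_subfamily(erf$hits)
  expect_equal(out2$subfamily, "ERF-subfamily")
  expect_gte(out2$homology_identity, 30)
  expect_error(classify_subfamily(rav$hits[rav$hits$domain == "B3", ]),
               "AP2")
})

test_that("ERF/DREB split honours positions 14 and 19 with 14V primacy", {
  case <- function(r14, r19) {
    d <- strsplit(refs[["REF_ERF_CONS"]], "")[[1]]
    d[14] <- r14; d[19] <- r19
    h <- hit_for(paste(d, collapse = ""))
    classify_erf_dreb(h$hits[h$hits$domain == "AP2", ][1, ], prof$AP2)
  }
  expect_equal(case("V", "E")$subfamily, "DREB")
  expect_equal(case("A", "D")$subfamily, "ERF")
  vq <- case("V", "Q")
  expect_equal(vq$subfamily, "DREB")       # irrespective of position 19
  expect_equal(vq$residue19, "Q")
  an <- case("A", "N")                     # position-14 primacy, flagged
  expect_equal(an$subfamily, "ERF")
  expect_true(an$flag_noncanonical19)
  expect_equal(case("S", "D")$subfamily, "unresolved")
})

test_that("CRF motifs are detected in the documented regions", {
  dom <- refs[["REF_B1"]]
  base <- paste0(random_protein(30, seed = 9), dom,
                 random_protein(60, seed = 10))
  expect_false(detect_crf(base, 31)$crf_core)
  with_core <- paste0(random_protein(10, seed = 9), "ATDQSS",
                      random_protein(14, seed = 11), dom,
                      random_protein(60, seed = 10))
  expect_true(detect_crf(with_core, 31)$crf_core)
  with_tail <- paste0(base, "SPTSVLKK")
  expect_true(detect_crf(with_tail, 31)$crf_cterm_motif)
  expect_true(detect_crf(paste0(base, "SPVSVLKK"), 31)$crf_cterm_motif)
  # core downstream of the domain does not count
  after <- paste0(random_protein(24, seed = 9), dom, "ATDQSS",
                  random_protein(60, seed = 10))
  expect_false(detect_crf(after, 25)$crf_core)
})

test_that("WLG/RAYD element states and EAR motif forms are reported", {
  e1 <- detect_elements("MKKKKKKKKK", refs[["REF_ERF_CONS"]])
  expect_equal(e1$wlg_state, "WLG")
  expect_equal(e1$rayd_state, "RAYD")
  e2 <- detect_elements("MKKKKKKKKK", refs[["REF_AP2_R1"]])
  expect_equal(e2$wlg_state, "YLG")
  e3 <- detect_elements("MKKKKKKKKK", refs[["REF_ANT_R1"]])
  expect_equal(e3$rayd_state, "RAHD")
  e4 <- detect_elements("MKKKKKKKKK", "GGGGGG")
  expect_equal(e4$wlg_state, "absent")
  expect_equal(e4$rayd_state, "absent")
  expect_true(detect_elements("MKKDLNTLPKK", "GGG")$ear_motif)  # DLNxxP
  expect_true(detect_elements("MKKLQLGLKK", "GGG")$ear_motif)   # LxLxL
  expect_false(detect_elements("MKKKKKKKKK", "GGG")$ear_motif)
})

test_that("physio-chemical properties: mass closed form, pI fixed point, D monotonicity", {
  g <- compute_properties("G")
  expect_equal(g$molecular_weight, 75.07, tolerance = 0.01)
  expect_equal(g$length, 1)
  tab <- aa_properties()
  # hand sum for a tripeptide from the bundled mass table
  trip <- compute_properties("GAV")
  expect_equal(trip$molecular_weight,
               sum(tab$avg_mass[match(c("G", "A", "V"), tab$residue)]) +
                 18.01524, tolerance = 1e-6)
  # net charge at the reported pI is ~0
  seqs <- c("MKRHDE", "ACDEFGHIKLMNPQRSTVWY", "KKKKDDDD")
  for (s in seqs) {
    p <- compute_properties(s)
    counts <- table(factor(strsplit(s, "")[[1]], levels = tab$residue))
    expect_lt(abs(ap2erf:::net_charge(counts, p$isoelectric_point)), 0.05)
    expect_gt(p$isoelectric_point, 0)
    expect_lt(p$isoelectric_point, 14)
    # appending an acidic residue never raises the pI
    p2 <- compute_properties(paste0(s, "D"))
    expect_lte(p2$isoelectric_point, p$isoelectric_point + 0.011)
  }
  expect_error(compute_properties("GAZ"), "invalid residue")
  expect_error(compute_properties(""), "empty")
})

test_that("tally identities hold for the published five-legume counts", {
  tab <- legume_family_counts()
  expected <- data.frame(
    species = c("chickpea", "pigeonpea", "common_bean", "medicago", "lotus"),
    dreb = c(43, 50, 54, 41, 48),
    erf = c(119, 148, 149, 107, 122),
    fam = c(147, 176, 179, 131, 140))
  for (i in seq_len(nrow(expected))) {
    row <- tab[tab$species == expected$species[i], ]
    counts <- unlist(row[, c(paste0("A", 1:6), paste0("B", 1:6),
                             "AP2", "ANT", "RAV", "soloist")])
    t <- family_tally(counts = counts,
                      genome_gene_total = row$genome_genes,
                      genome_size_mb = row$genome_mb)
    expect_equal(t$dreb_total, expected$dreb[i])
    expect_equal(t$erf_total, expected$erf[i])
    expect_equal(t$family_total, expected$fam[i])
    # internal sum identity
    expect_equal(t$family_total,
                 t$erf_total + sum(t$other_counts))
  }
})

test_that("tally handles zero calls and validates genome totals", {
  empty <- data.frame(gene_id = character(), family = character(),
                      subfamily = character(), subgroup = character())
  t <- family_tally(empty, genome_gene_total = 1000, genome_size_mb = 100)
  expect_equal(t$family_total, 0)
  expect_equal(t$percentage, 0)
  expect_error(family_tally(empty, genome_gene_total = 0), "positive")
})

test_that("classification is total and deterministic over a mixed proteome", {
  sim <- generate_genomes(synthetic_config(seed = 31, genes_per_species = 25,
                                           species_count = 1))
  c1 <- classify_proteome(sim$proteins$s1, seed = 4)
  c2 <- classify_proteome(sim$proteins$s1, seed = 4)
  expect_identical(c1, c2)
  expect_equal(nrow(c1), length(sim$proteins$s1))
  expect_true(all(c1$subfamily %in% c("AP2", "ANT", "ERF", "DREB", "RAV",
                                      "soloist", "HSP90", "unresolved",
                                      "none")))
  expect_equal(label_accuracy(sim$truth$genes, c1), 1)
})
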