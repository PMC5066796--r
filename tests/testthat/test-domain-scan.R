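test_that("profile columns follow the log-odds closed form", {
  # identical sequences: consensus residue score -> log2(1/background) as
  # pseudocount -> 0
  aln <- rep("ACDE", 6)
  names(aln) <- paste0("s", 1:6)
  prof <- build_profile(aln, "AP2", pseudocount = 1e-9)
  bg <- aa_properties()
  bgf <- setNames(bg$background_freq / sum(bg$background_freq), bg$residue)
  for (j in 1:4) {
    res <- substr("ACDE", j, j)
    expect_equal(unname(prof$log_odds[res, j]), log2(1 / bgf[[res]]),
                 tolerance = 1e-6)
  }
  # uniform residue usage: scores tend to the background log-odds (0 bits)
  aln2 <- setNames(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], paste0("u", 1:20))
  prof2 <- build_profile(aln2, "AP2", pseudocount = 1e-9)
  expect_equal(unname(prof2$log_odds["A", 1]),
               log2((1 / 20) / bgf[["A"]]), tolerance = 1e-6)
})

test_that("gap-heavy columns are dropped, matching a brute-force audit", {
  set.seed(42)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  mat <- matrix(sample(aa, 8 * 30, replace = TRUE), nrow = 8)
  # punch gaps: columns 3 and 17 mostly gapped, column 9 half gapped
  mat[1:5, 3] <- "-"
  mat[1:7, 17] <- "-"
  mat[1:4, 9] <- "-"
  aln <- setNames(apply(mat, 1, paste, collapse = ""), paste0("q", 1:8))
  prof <- build_profile(aln, "B3")
  # independent column-gap counter
  gap_frac <- colMeans(mat == "-")
  expect_equal(prof$length, sum(gap_frac <= 0.5))
  expect_true(all(is.finite(prof$log_odds)))
  expect_gt(prof$score_threshold, 0)
})

test_that("build_profile rejects bad alignments", {
  expect_error(build_profile(character(0), "AP2"), "empty|>= 5")
  expect_error(build_profile(setNames(rep("AAAA", 3), 1:3), "AP2"), ">= 5")
  expect_error(build_profile(setNames(c(rep("AAAA", 5), "AAA"), 1:6), "AP2"),
               "lengths")
})

test_that("scanning finds a planted consensus at the exact offset", {
  prof <- bundled_profiles()$AP2
  cons <- ap2_references()[["REF_ERF_CONS"]]
  bg <- random_protein(120, seed = 7)
  prot <- paste0(substr(bg, 1, 10), cons, substr(bg, 11, 120))
  hits <- scan_domains(prot, prof, "planted")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 11L)
  expect_equal(hits$end, 11L + prof$length - 1L)
  expect_equal(hits$domain_sequence, cons)
  # two non-overlapping planted copies -> exactly 2 hits
  prot2 <- paste0(substr(bg, 1, 10), cons, substr(bg, 11, 40), cons,
                  substr(bg, 41, 120))
  hits2 <- scan_domains(prot2, prof, "double")
  expect_equal(nrow(hits2), 2)
  expect_equal(hits2$start, c(11L, 101L))
})

test_that("short peptides yield an empty result, not an error", {
  prof <- bundled_profiles()$AP2
  expect_equal(nrow(scan_domains("MKVLA", prof)), 0)
})

test_that("window score is invariant to changes outside the window", {
  prof <- bundled_profiles()$AP2
  cons <- ap2_references()[["REF_DREB_CONS"]]
  left_a <- random_protein(30, seed = 1)
  left_b <- random_protein(30, seed = 2)
  h1 <- scan_domains(paste0(left_a, cons), prof)
  h2 <- scan_domains(paste0(left_b, cons), prof)
  expect_equal(h1$score, h2$score)
  expect_equal(h1$start, h2$start)
})

test_that("canonical positions resolve through the reference column map", {
  prof <- bundled_profiles()$AP2
  cons <- ap2_references()[["REF_DREB_CONS"]]
  h <- scan_domains(paste0(random_protein(15, seed = 3), cons), prof)
  expect_equal(canonical_residue(h[1, ], prof, 14), "V")
  expect_equal(canonical_residue(h[1, ], prof, 19), "E")
})

test_that("planted-domain recall is 1 and false discovery 0 on noise-free fixtures", {
  sim <- generate_genomes(synthetic_config(seed = 21, genes_per_species = 30,
                                           species_count = 1))
  hits <- scan_proteome(sim$proteins$s1)
  truth <- sim$truth$genes
  for (i in seq_len(nrow(truth))) {
    planted <- truth$domains[i]
    h <- hits[hits$protein_id == truth$gene_id[i], ]
    if (planted == "") {
      expect_equal(nrow(h), 0)
    } else {
      want <- strsplit(planted, ";")[[1]]
      got <- sprintf("%s:%d-%d", h$domain, h$start, h$end)
      expect_setequal(got, want)
    }
  }
})

test_that("external backends agree with the internal scanner on domain presence", {
  sim <- generate_genomes(synthetic_config(seed = 13, genes_per_species = 12,
                                           species_count = 1))
  prots <- sim$proteins$s1
  internal <- scan_with_backend(prots, "internal")
  key <- function(h) sort(unique(paste(h$protein_id, h$domain)))
  hmm <- scan_with_backend(prots, "hmmscan")
  expect_identical(key(hmm), key(internal))
  # the blastp mining step searches single consensus sequences, so it may
  # miss the most divergent flavours the broad profile still detects; the
  # mining design unions both searches
  bl <- scan_with_backend(prots, "blastp")
  expect_true(all(key(bl) %in% key(internal)))
  expect_identical(sort(union(key(bl), key(hmm))), key(internal))
})

test_that("a missing backend executable raises a typed error", {
  old <- Sys.getenv("PATH")
  on.exit(Sys.setenv(PATH = old))
  Sys.setenv(PATH = tempdir())
  expect_error(scan_with_backend(c(p1 = "MKVLAW"), "hmmscan"),
               class = "ap2erf_backend_unavailable")
  err <- tryCatch(scan_with_backend(c(p1 = "MKVLAW"), "blastp"),
                  error = function(e) e)
  expect_match(conditionMessage(err), "internal")
})

test_that("domtblout and blast6 parsers reject malformed rows", {
  f <- tempfile()
  writeLines(c("# comment", "too few fields"), f)
  expect_error(parse_domtblout(f), "line 1")
  f2 <- tempfile()
  writeLines("a\tb\tc", f2)
  expect_error(parse_blast6(f2), "12")
})
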