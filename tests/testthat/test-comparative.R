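test_that("self-alignment is 100% identical and score is symmetric", {
  s <- random_protein(80, seed = 1)
  t <- random_protein(90, seed = 2)
  self <- align_pair(s, s)
  expect_equal(self$identity, 100)
  expect_equal(align_pair(s, t)$raw_score, align_pair(t, s)$raw_score)
  expect_error(align_pair("", s), "empty")
})

test_that("a gap-free pair with 20/100 substitutions scores 80% identity", {
  set.seed(8)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  a <- sample(aa, 100, replace = TRUE)
  b <- a
  # substitutions confined to the interior so the local alignment spans all
  # 100 columns
  pos <- sample(10:90, 20)
  for (p in pos) b[p] <- sample(setdiff(aa, a[p]), 1)
  al <- align_pair(paste(a, collapse = ""), paste(b, collapse = ""))
  expect_equal(al$aligned_length, 100)
  expect_equal(al$identity, 80)
  expect_lt(al$evalue, 1e-10)
})

test_that("duplication classification applies the 5-Mb / 80% / 1e-10 rule", {
  base <- strsplit(random_protein(150, seed = 4), "")[[1]]
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  mutate_n <- function(x, n, seed) {
    set.seed(seed)
    for (p in sample(15:135, n)) x[p] <- sample(setdiff(aa, x[p]), 1)
    x
  }
  prot <- c(gA = paste(base, collapse = ""),
            gB = paste(mutate_n(base, 15, 1), collapse = ""),   # 90% id
            gC = paste(mutate_n(base, 15, 2), collapse = ""),   # 90% id
            gD = random_protein(150, seed = 5))                 # unrelated
  loc <- data.frame(gene_id = c("gA", "gB", "gC", "gD"),
                    chromosome = c("chr1", "chr1", "chr2", "chr1"),
                    start = c(1e6, 4e6, 2e6, 4.5e6))
  ev <- find_paralogs(prot, loc)
  k <- pair_key(ev$gene_a, ev$gene_b)
  expect_true(pair_key("gA", "gB") %in% k)
  expect_equal(ev$class[k == pair_key("gA", "gB")], "tandem")  # 3 Mb apart
  expect_equal(ev$class[k == pair_key("gA", "gC")], "segmental")  # cross-chr
  expect_false(any(grepl("gD", k)))
  # below the identity threshold: excluded (21/100 interior substitutions)
  base100 <- strsplit(random_protein(100, seed = 6), "")[[1]]
  set.seed(61)
  b79 <- base100
  for (p in sample(10:90, 21)) b79[p] <- sample(setdiff(aa, b79[p]), 1)
  prot79 <- c(gA = paste(base100, collapse = ""),
              gE = paste(b79, collapse = ""))
  loc79 <- data.frame(gene_id = c("gA", "gE"), chromosome = "chr1",
                      start = c(1, 2e6))
  id <- align_pair(prot79[["gA"]], prot79[["gE"]])$identity
  expect_lt(id, 80)
  expect_equal(nrow(find_paralogs(prot79, loc79)), 0)
  # same chromosome, > 5 Mb: segmental
  locfar <- data.frame(gene_id = c("gA", "gB"), chromosome = "chr1",
                       start = c(1, 7e6))
  evfar <- find_paralogs(prot[1:2], locfar)
  expect_equal(evfar$class, "segmental")
  expect_error(find_paralogs(prot[1:2], loc[loc$gene_id == "gA", ]),
               "gB")
})

test_that("BBH orthology: trivial pair, reciprocity and symmetry", {
  p1 <- c(x = random_protein(120, seed = 11))
  expect_equal(nrow(find_orthologs_bbh(p1, c(y = p1[["x"]]))), 1)
  expect_error(find_orthologs_bbh(p1, character(0)), "non-empty")

  sim <- generate_genomes(synthetic_config(seed = 23, genes_per_species = 25))
  b12 <- find_orthologs_bbh(sim$proteins$s1, sim$proteins$s2)
  b21 <- find_orthologs_bbh(sim$proteins$s2, sim$proteins$s1)
  expect_setequal(paste(b12$gene1, b12$gene2), paste(b21$gene2, b21$gene1))
  truth <- sim$truth$orthologs
  expect_setequal(paste(b12$gene1, b12$gene2),
                  paste(truth$gene_a, truth$gene_b))
  expect_true(all(b12$evalue12 <= 1e-10))
})

test_that("planted 1:1 orthologs are recovered exactly under divergence", {
  sim <- generate_genomes(synthetic_config(seed = 29, genes_per_species = 25,
                                           noise_mutation_rate = 0.05))
  b <- find_orthologs_bbh(sim$proteins$s1, sim$proteins$s2)
  truth <- sim$truth$orthologs
  expect_setequal(paste(b$gene1, b$gene2), paste(truth$gene_a, truth$gene_b))
})

test_that("a gene private to one species joins no ortholog pair", {
  sim <- generate_genomes(synthetic_config(seed = 37, genes_per_species = 20))
  extra <- c(private = random_protein(200, seed = 40))
  p1 <- c(sim$proteins$s1, extra)
  b <- find_orthologs_bbh(p1, sim$proteins$s2)
  expect_false("private" %in% b$gene1)
  expect_setequal(paste(b$gene1, b$gene2),
                  paste(sim$truth$orthologs$gene_a,
                        sim$truth$orthologs$gene_b))
})

test_that("tandem and segmental classes partition all surviving pairs", {
  sim <- generate_genomes(synthetic_config(seed = 41, genes_per_species = 30,
                                           species_count = 1,
                                           planted_tandem_pairs = 3,
                                           planted_segmental_pairs = 3))
  ev <- find_paralogs(sim$proteins$s1, synthetic_locations(sim, "s1"))
  expect_true(all(ev$class %in% c("tandem", "segmental")))
  expect_true(all(ev$distance[ev$class == "tandem"] <= 5e6))
  expect_true(all(is.na(ev$distance[ev$class == "segmental"]) |
                    ev$distance[ev$class == "segmental"] > 0))
  expect_equal(anyDuplicated(pair_key(ev$gene_a, ev$gene_b)), 0)
})
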