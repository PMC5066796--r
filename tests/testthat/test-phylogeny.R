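test_that("p-distances implement pairwise deletion", {
  expect_equal(pdistance(c(x = "AAAA", y = "AAAA"))["x", "y"], 0)
  expect_equal(pdistance(c(x = "AAAA", y = "AAAT"))["x", "y"], 0.25)
  # gap column excluded: 3 compared sites, 0 mismatches
  expect_equal(pdistance(c(x = "AA-A", y = "AATA"))["x", "y"], 0)
  d <- pdistance(c(a = "ACGT", b = "AC-T", c = "A--T"))
  expect_equal(d["b", "c"], 0)
  expect_true(isSymmetric(d))
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))
  expect_error(pdistance(c(x = "--AA", y = "TT--")), "no comparable sites")
  expect_error(pdistance(c(x = "AAA", y = "AAAA")), "unequal")
})

test_that("three taxa solve the closed-form three-point lengths", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  expect_s3_class(tr, "phylo")
  lens <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(lens[["a"]], 1)  # (3+4-5)/2
  expect_equal(lens[["b"]], 2)  # (3+5-4)/2
  expect_equal(lens[["c"]], 3)  # (4+5-3)/2
})

test_that("NJ recovers additive trees exactly (topology and lengths)", {
  skip_if_not_installed("phangorn")
  set.seed(12)
  for (n in c(4, 8, 12)) {
    true <- ape::rtree(n)
    d <- ape::cophenetic.phylo(true)
    est <- nj_tree(d)
    expect_equal(phangorn::RF.dist(ape::unroot(est), ape::unroot(true)), 0)
    expect_lt(max(abs(sort(est$edge.length) -
                        sort(ape::unroot(true)$edge.length))), 1e-9)
    # independent implementation agrees on the unrooted topology
    expect_equal(phangorn::RF.dist(ape::unroot(est),
                                   ape::unroot(ape::nj(d))), 0)
  }
})

test_that("permuting taxon order leaves the unrooted topology unchanged", {
  skip_if_not_installed("phangorn")
  set.seed(3)
  true <- ape::rtree(9)
  d <- ape::cophenetic.phylo(true)
  perm <- sample(rownames(d))
  est1 <- nj_tree(d)
  est2 <- nj_tree(d[perm, perm])
  expect_equal(phangorn::RF.dist(ape::unroot(est1), ape::unroot(est2)), 0)
})

test_that("branch lengths are non-negative after adjustment", {
  # a noisy, non-additive matrix that provokes negative NJ estimates
  set.seed(99)
  n <- 7
  m <- matrix(runif(n * n, 0.01, 0.4), n, n)
  d <- (m + t(m)) / 2; diag(d) <- 0
  dimnames(d) <- list(paste0("t", 1:n), paste0("t", 1:n))
  tr <- nj_tree(d)
  expect_true(all(tr$edge.length >= 0))
})

test_that("bootstrap support is 100 for a split present in every column", {
  aln <- c(a = "AAAAAAAA", b = "AAAAAAAA", c = "TTTTTTTT", d = "TTTTTTTT")
  bs <- bootstrap_support(aln, replicates = 100, seed = 2)
  expect_length(bs, 1)           # one internal edge in a 4-taxon tree
  expect_equal(unname(bs), 100)
  expect_error(bootstrap_support(aln, replicates = 0), "replicates")
  expect_true(all(bs >= 0 & bs <= 100))
})

test_that("a well-separated planted split gets >= 95% support over seeds", {
  set.seed(7)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  base <- sample(aa, 60, replace = TRUE)
  make_taxon <- function(group, k) {
    x <- base
    if (group == 2) x[1:20] <- rev(base[1:20])  # strong group signal
    pos <- sample(21:60, 4)                     # taxon-specific noise
    for (p in pos) x[p] <- sample(setdiff(aa, x[p]), 1)
    paste(x, collapse = "")
  }
  taxa <- c(sapply(1:4, function(i) make_taxon(1, i)),
            sapply(1:4, function(i) make_taxon(2, i)))
  names(taxa) <- c(paste0("g1_", 1:4), paste0("g2_", 1:4))
  tree <- nj_tree(pdistance(taxa))
  sets <- ap2erf:::tip_descendants(tree)
  target <- ap2erf:::split_key(paste0("g1_", 1:4), names(taxa))
  supports <- vapply(1:10, function(s) {
    bs <- bootstrap_support(taxa, replicates = 100, seed = s, tree = tree)
    keys <- ap2erf:::internal_splits(tree)
    unname(bs[names(keys)[keys == target]])
  }, numeric(1))
  expect_gte(mean(supports), 95)
})

test_that("clade assignment labels queries by their reference clade", {
  refs <- ap2_references()
  make_gene <- function(ref, seed) {
    set.seed(seed)
    x <- strsplit(refs[[ref]], "")[[1]]
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    for (p in sample(setdiff(5:60, c(14, 19, 27:29, 41:44)), 5))
      x[p] <- sample(setdiff(aa, x[p]), 1)
    paste(x, collapse = "")
  }
  aln <- c(q1 = make_gene("REF_A4", 1), q2 = make_gene("REF_A4", 2),
           q3 = make_gene("REF_B1", 3),
           REF_A4 = refs[["REF_A4"]], REF_B1 = refs[["REF_B1"]],
           REF_A1 = refs[["REF_A1"]])
  tree <- nj_tree(pdistance(aln))
  bs <- bootstrap_support(aln, replicates = 100, seed = 5, tree = tree)
  grp <- assign_groups(tree, c(REF_A4 = "A4", REF_B1 = "B1", REF_A1 = "A1"),
                       support = bs)
  expect_equal(grp$subgroup[grp$gene_id == "q1"], "A4")
  expect_equal(grp$subgroup[grp$gene_id == "q2"], "A4")
  expect_equal(grp$subgroup[grp$gene_id == "q3"], "B1")
  expect_error(assign_groups(tree, c(REF_MISSING = "A1")), "missing")
})

test_that("single-AP2 genes landing in the AP2 reference clade are re-labelled", {
  refs <- ap2_references()
  # a single-domain gene whose domain is the AP2-subfamily repeat flavour
  prot <- c(odd1 = paste0(random_protein(20, seed = 50), refs[["REF_AP2_R1"]],
                          random_protein(40, seed = 51)))
  sim <- generate_genomes(synthetic_config(seed = 43, genes_per_species = 25,
                                           species_count = 1))
  prots <- c(sim$proteins$s1, prot)
  calls <- classify_proteome(prots, seed = 6)
  # one domain only, non-diagnostic residue 14 -> unresolved by the tree rule
  expect_equal(calls$subfamily[calls$gene_id == "odd1"], "unresolved")
  calls2 <- assign_subgroups(calls, seed = 6)
  expect_equal(calls2$subfamily[calls2$gene_id == "odd1"], "AP2")
  expect_true(calls2$phylo_reassigned[calls2$gene_id == "odd1"])
  # the planted single-domain AP2-flavour gene is (re-)assigned AP2, and no
  # true ERF/DREB gene was pulled into the AP2 clade
  tg <- sim$truth$genes
  ed <- calls2[calls2$gene_id %in% tg$gene_id[tg$label %in% c("ERF", "DREB")], ]
  expect_true(all(ed$subfamily %in% c("ERF", "DREB")))
})
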