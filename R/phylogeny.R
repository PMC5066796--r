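# Neighbour-joining phylogenetics on domain alignments: p-distances with
# pairwise deletion, Saitou-Nei NJ, bootstrap support and clade-based
# subgroup assignment against labelled reference taxa.

alignment_matrix <- function(alignment) {
  if (is.matrix(alignment)) return(alignment)
  if (is.null(names(alignment)))
    names(alignment) <- paste0("t", seq_along(alignment))
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1)
    stopf("alignment sequences have unequal lengths")
  m <- do.call(rbind, strsplit(toupper(alignment), ""))
  rownames(m) <- names(alignment)
  m
}

#' Pairwise-deletion p-distances from a gapped alignment
#'
#' For each sequence pair, alignment columns where either sequence has a gap
#' are excluded (pairwise deletion); the distance is the fraction of
#' mismatches over the remaining compared sites.
#'
#' @param alignment Named character vector of equal-length aligned sequences
#'   (or a character matrix, rows = taxa).
#' @return Symmetric numeric matrix of p-distances with zero diagonal.
#' @export
pdistance <- function(alignment) {
  m <- alignment_matrix(alignment)
  n <- nrow(m)
  if (n < 2) stopf("pdistance requires >= 2 sequences")
  gap <- m == "-" | m == "."
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      valid <- !gap[i, ] & !gap[j, ]
      nc <- sum(valid)
      if (nc == 0)
        stopf("no comparable sites for pair %s / %s under pairwise deletion",
              rownames(m)[i], rownames(m)[j])
      d[i, j] <- d[j, i] <- sum(m[i, valid] != m[j, valid]) / nc
    }
  }
  d
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei neighbour joining: iteratively joins the pair minimising the
#' Q-criterion, with branch lengths from the standard NJ formulas. A negative
#' branch length at a join is clamped to zero with the deficit transferred to
#' its sister branch (so the pair's summed length is preserved); the final
#' trifurcation clamps at zero. Ties in the Q-criterion are broken by the
#' order of the input matrix (earlier rows first), making the result
#' deterministic.
#'
#' @param d Symmetric distance matrix (or `dist`), at least 3 taxa.
#' @return An unrooted `phylo` tree (ape).
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  n <- nrow(d)
  if (n < 3) stopf("nj_tree requires >= 3 taxa")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  if (max(abs(d - t(d))) > 1e-8) stopf("distance matrix is not symmetric")

  act <- seq_len(n)            # node ids of active clusters
  D <- unname(d)
  edges <- matrix(integer(0), 0, 2)
  elen <- numeric(0)
  next_id <- n
  while (length(act) > 3) {
    m <- length(act)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    idx <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    pick <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE][1, ]
    i <- pick[[1]]; j <- pick[[2]]
    vi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    vj <- D[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    next_id <- next_id + 1L
    edges <- rbind(edges, c(next_id, act[i]), c(next_id, act[j]))
    elen <- c(elen, vi, vj)
    du <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]),
               c(du[keep], 0))
    act <- c(act[keep], next_id)
  }
  va <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  vb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  vc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  next_id <- next_id + 1L
  edges <- rbind(edges, c(next_id, act[1]), c(next_id, act[2]),
                 c(next_id, act[3]))
  elen <- c(elen, max(va, 0), max(vb, 0), max(vc, 0))

  # renumber: tips 1..n; internals n+1.. in preorder with the final join as
  # root (edges already point parent -> child)
  root_old <- next_id
  new_id <- integer(next_id)
  new_id[seq_len(n)] <- seq_len(n)
  kids <- split(edges[, 2], edges[, 1])
  counter <- n
  stack <- root_old
  while (length(stack) > 0) {
    nd <- stack[length(stack)]
    stack <- stack[-length(stack)]
    counter <- counter + 1L
    new_id[nd] <- counter
    ch <- kids[[as.character(nd)]]
    ch <- ch[ch > n]
    if (length(ch) > 0) stack <- c(stack, rev(ch))
  }
  phy <- list(edge = cbind(new_id[edges[, 1]], new_id[edges[, 2]]),
              edge.length = elen, tip.label = labels, Nnode = n - 2L)
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}

# tips (indices) descending from every node
tip_descendants <- function(phy) {
  n <- length(phy$tip.label)
  sets <- vector("list", n + phy$Nnode)
  for (i in seq_len(n)) sets[[i]] <- i
  po <- ape::reorder.phylo(phy, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

# canonical bipartition key: the side not containing the alphabetically first
# taxon, as a sorted "|"-joined string
split_key <- function(side_labels, all_labels) {
  canon <- sort(all_labels)[1]
  if (canon %in% side_labels)
    side_labels <- setdiff(all_labels, side_labels)
  paste(sort(side_labels), collapse = "|")
}

# keys of all non-trivial splits; named by internal node id where applicable
internal_splits <- function(phy) {
  n <- length(phy$tip.label)
  sets <- tip_descendants(phy)
  nodes <- setdiff(seq_len(n + phy$Nnode), c(seq_len(n), n + 1L))
  keys <- vapply(nodes, function(nd)
    split_key(phy$tip.label[sets[[nd]]], phy$tip.label), character(1))
  stats::setNames(keys, nodes)
}

#' Bootstrap support for the splits of a neighbour-joining tree
#'
#' Alignment columns are resampled with replacement; each replicate alignment
#' is converted to pairwise-deletion p-distances and an NJ tree, and support
#' for each internal edge of the original tree is the percentage of replicate
#' trees containing the same bipartition. A replicate whose resampled columns
#' leave some pair with no comparable sites contributes no support.
#'
#' @param alignment Named character vector of aligned sequences.
#' @param replicates Number of bootstrap replicates (>= 1).
#' @param seed Integer seed for the resampling stream.
#' @param tree Optional precomputed NJ tree of the full alignment.
#' @return Named numeric vector of support percentages, one entry per
#'   internal node (non-root) of the tree.
#' @export
bootstrap_support <- function(alignment, replicates = 100, seed = 1,
                              tree = NULL) {
  if (replicates < 1) stopf("replicates must be >= 1")
  m <- alignment_matrix(alignment)
  if (is.null(tree)) tree <- nj_tree(pdistance(m))
  orig <- internal_splits(tree)
  counts <- stats::setNames(numeric(length(orig)), names(orig))
  with_seed(seed, {
    for (b in seq_len(replicates)) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      keys <- tryCatch(
        internal_splits(nj_tree(pdistance(m[, cols, drop = FALSE]))),
        error = function(e) character(0))
      counts[orig %in% keys] <- counts[orig %in% keys] + 1
    }
  })
  100 * counts / replicates
}

#' Attach bootstrap support to a tree as internal node labels
#'
#' @param tree A `phylo` tree from [nj_tree()].
#' @param support Support vector from [bootstrap_support()].
#' @return The tree with `node.label` set (root label empty).
#' @export
tree_with_support <- function(tree, support) {
  n <- length(tree$tip.label)
  lab <- character(tree$Nnode)
  ids <- as.integer(names(support))
  lab[ids - n] <- sprintf("%g", round(support, 1))
  tree$node.label <- lab
  tree
}

#' Clade-based subgroup assignment against labelled reference taxa
#'
#' Every query leaf receives the label of the smallest supported clade (at
#' `support_threshold`, default 50%) that contains the query and at least one
#' reference taxon, provided all reference taxa inside carry the same label.
#' Queries not resolvable with any reference clade get `"none"`.
#'
#' @param tree A `phylo` tree containing all reference taxa.
#' @param references Named character vector: reference taxon -> label (e.g.
#'   `"A4"`, `"B1"`, `"AP2"`, `"ANT"`).
#' @param support Optional support vector from [bootstrap_support()]; when
#'   absent all edges are treated as resolved.
#' @param support_threshold Minimum support (%) for a clade to be used.
#' @return Data frame with `gene_id` and assigned `subgroup`.
#' @export
assign_groups <- function(tree, references, support = NULL,
                          support_threshold = 50) {
  labels <- tree$tip.label
  refs <- references[names(references) %in% labels]
  if (length(refs) < length(references))
    stopf("tree is missing reference taxa: %s",
          paste(setdiff(names(references), labels), collapse = ", "))
  n <- length(labels)
  sets <- tip_descendants(tree)
  clades <- list()
  for (nd in setdiff(seq_len(n + tree$Nnode), c(seq_len(n), n + 1L))) {
    s <- if (is.null(support)) 100 else support[[as.character(nd)]]
    if (is.null(s) || is.na(s) || s < support_threshold) next
    side <- labels[sets[[nd]]]
    clades[[length(clades) + 1]] <- side
    clades[[length(clades) + 1]] <- setdiff(labels, side)
  }
  queries <- setdiff(labels, names(refs))
  assign_one <- function(q) {
    cand <- Filter(function(cl) q %in% cl && any(names(refs) %in% cl), clades)
    if (length(cand) == 0) return("none")
    cand <- cand[order(vapply(cand, length, integer(1)))]
    for (cl in cand) {
      lab <- unique(refs[names(refs)[names(refs) %in% cl]])
      if (length(lab) == 1) return(unname(lab))
    }
    "none"
  }
  data.frame(gene_id = queries,
             subgroup = vapply(queries, assign_one, character(1)),
             stringsAsFactors = FALSE)
}

#' Phylogenetic subgroup assignment for a family-call table
#'
#' Builds an NJ tree over the AP2-domain sequences of all ERF/DREB calls plus
#' the bundled subgroup references (A1-A6, B1-B6) and the AP2/AINTEGUMENTA
#' repeat references, computes bootstrap support, and assigns each gene the
#' subgroup of its reference clade. Single-AP2-domain genes that land in the
#' AP2 (or ANT) reference clade are re-labelled AP2 (or ANT), overriding the
#' domain-count call.
#'
#' @param calls Family-call data frame from [classify_proteome()] (with its
#'   `hits` attribute, or pass `hits` explicitly).
#' @param hits Domain-hit data frame.
#' @param references Bundled reference domains (see [ap2_references()]).
#' @param replicates Bootstrap replicates (default 100).
#' @param seed Integer seed.
#' @param support_threshold Clade support threshold (%).
#' @return The updated call table (columns `subgroup`, possibly re-labelled
#'   `subfamily`, and logical `phylo_reassigned`).
#' @export
assign_subgroups <- function(calls, hits = attr(calls, "hits"),
                             references = ap2_references(),
                             replicates = 100, seed = 1,
                             support_threshold = 50) {
  sel <- calls$gene_id[calls$subfamily %in% c("ERF", "DREB", "unresolved") &
                         calls$n_ap2 >= 1]
  calls$phylo_reassigned <- FALSE
  if (length(sel) < 2) return(calls)
  doms <- vapply(sel, function(id) {
    h <- hits[hits$protein_id == id & hits$domain == "AP2", , drop = FALSE]
    h$domain_sequence[which.min(h$start)]
  }, character(1))
  refs <- references[grepl("^REF_(A[1-6]|B[1-6])$|^REF_(AP2|ANT)_R[12]$",
                           names(references))]
  ref_labels <- sub("^REF_", "", names(refs))
  ref_labels <- sub("_R[12]$", "", ref_labels)
  names(ref_labels) <- names(refs)
  aln <- c(doms, refs)
  tree <- nj_tree(pdistance(aln))
  support <- bootstrap_support(aln, replicates = replicates, seed = seed,
                               tree = tree)
  grp <- assign_groups(tree, ref_labels, support = support,
                       support_threshold = support_threshold)
  idx <- match(grp$gene_id, calls$gene_id)
  for (k in seq_len(nrow(grp))) {
    g <- grp$subgroup[k]
    i <- idx[k]
    if (g %in% c("AP2", "ANT")) {
      calls$subfamily[i] <- g
      calls$subgroup[i] <- "none"
      calls$phylo_reassigned[i] <- TRUE
    } else if (g != "none") {
      calls$subgroup[i] <- g
      # an unresolved residue-14 call is rescued by its reference clade
      if (calls$subfamily[i] == "unresolved") {
        calls$subfamily[i] <- if (grepl("^A", g)) "DREB" else "ERF"
        calls$phylo_reassigned[i] <- TRUE
      }
    }
  }
  calls
}
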