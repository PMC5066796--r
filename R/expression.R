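# FPKM computation, log transformation, hierarchical clustering for heatmap
# ordering, and the 2^-ddCt qRT-PCR fold-change calculator.

#' FPKM from fragment counts
#'
#' `FPKM[g, s] = counts[g, s] / (length_kb[g] * totals[s] / 1e6)` --
#' fragments per kilobase of transcript per million mapped fragments.
#'
#' @param counts Gene x sample matrix of fragment counts.
#' @param lengths_kb Transcript lengths in kilobases (per gene).
#' @param totals Mapped fragments per sample.
#' @return Matrix of FPKM values with the input dimnames.
#' @export
fpkm <- function(counts, lengths_kb, totals) {
  counts <- as.matrix(counts)
  if (length(lengths_kb) != nrow(counts))
    stopf("lengths_kb must have one entry per gene")
  if (length(totals) != ncol(counts))
    stopf("totals must have one entry per sample")
  if (any(lengths_kb <= 0)) stopf("transcript lengths must be positive")
  if (any(totals <= 0)) stopf("mapped totals must be positive")
  sweep(sweep(counts, 1, lengths_kb, "/"), 2, totals / 1e6, "/")
}

#' Log10 transformation with offset
#'
#' @param m Non-negative expression matrix.
#' @param offset Added before taking log10 (default 1, so FPKM 0 maps to 0).
#' @return `log10(m + offset)`.
#' @export
log_transform <- function(m, offset = 1) {
  m <- as.matrix(m)
  if (any(m < 0, na.rm = TRUE)) stopf("negative expression values")
  if (any(m + offset <= 0)) stopf("offset must make all values positive")
  log10(m + offset)
}

#' Agglomerative clustering of an expression matrix for heatmap display
#'
#' Average-linkage hierarchical clustering of genes (rows) under a Euclidean
#' or correlation metric, returning the dendrogram and the leaf order used to
#' lay out a heatmap. With a single gene a degenerate single-leaf result is
#' returned.
#'
#' @param m Expression matrix (genes x samples), typically log-transformed.
#' @param linkage Agglomeration method (default `"average"`).
#' @param metric `"euclidean"` or `"correlation"` (1 - Pearson).
#' @return List with `hclust` (or `NULL` when degenerate), `order`,
#'   `ordered_matrix`.
#' @export
cluster_expression <- function(m, linkage = "average",
                               metric = c("euclidean", "correlation")) {
  metric <- match.arg(metric)
  m <- as.matrix(m)
  if (any(!is.finite(m))) stopf("expression matrix contains non-finite values")
  if (nrow(m) < 2) {
    return(list(hclust = NULL, order = seq_len(nrow(m)),
                ordered_matrix = m))
  }
  d <- switch(metric,
              euclidean = stats::dist(m),
              correlation = stats::as.dist(1 - stats::cor(t(m))))
  h <- stats::hclust(d, method = linkage)
  list(hclust = h, order = h$order,
       ordered_matrix = m[h$order, , drop = FALSE])
}

#' Cut a gene clustering into k groups
#'
#' @param clustering Result of [cluster_expression()].
#' @param k Number of groups.
#' @return Named integer vector of group memberships.
#' @export
cut_clusters <- function(clustering, k) {
  if (is.null(clustering$hclust)) stopf("degenerate clustering cannot be cut")
  stats::cutree(clustering$hclust, k = k)
}

#' Relative expression by the 2^-ddCt method
#'
#' Per sample, `dCt = Ct_target - Ct_endogenous`; replicate dCt values are
#' averaged on the Ct scale within each (gene, condition); `ddCt` is the
#' mean dCt of a condition minus the mean dCt of the calibrator condition;
#' the fold change is `2^-ddCt`.
#'
#' @param ct Data frame with columns `gene_id`, `sample_id`, `condition`,
#'   `is_calibrator` (logical), `ct_target`, `ct_endogenous`.
#' @return Data frame with `gene_id`, `condition`, `delta_delta_ct`,
#'   `fold_change` for every non-calibrator condition.
#' @export
ddct_fold_change <- function(ct) {
  need <- c("gene_id", "sample_id", "condition", "is_calibrator",
            "ct_target", "ct_endogenous")
  missing <- setdiff(need, names(ct))
  if (length(missing) > 0)
    stopf("Ct table is missing column(s): %s", paste(missing, collapse = ", "))
  bad <- which(!is.finite(ct$ct_endogenous))
  if (length(bad) > 0)
    stopf("missing endogenous-control Ct for sample %s",
          ct$sample_id[bad[1]])
  bad <- which(!is.finite(ct$ct_target))
  if (length(bad) > 0)
    stopf("missing target Ct for sample %s", ct$sample_id[bad[1]])
  ct$dct <- ct$ct_target - ct$ct_endogenous
  out <- list()
  for (g in unique(ct$gene_id)) {
    sub <- ct[ct$gene_id == g, ]
    cal <- sub[sub$is_calibrator, ]
    if (nrow(cal) == 0)
      stopf("gene %s has no calibrator samples", g)
    dct_cal <- mean(cal$dct)
    for (cond in unique(sub$condition[!sub$is_calibrator])) {
      dct <- mean(sub$dct[sub$condition == cond & !sub$is_calibrator])
      ddct <- dct - dct_cal
      out[[length(out) + 1]] <- data.frame(
        gene_id = g, condition = cond, delta_delta_ct = ddct,
        fold_change = 2^(-ddct), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
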