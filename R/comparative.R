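# Tandem / segmental duplication classification and best-bidirectional-hit
# orthology.

TANDEM_WINDOW_BP <- 5e6

#' Find duplicated gene pairs within a proteome and classify them
#'
#' All unordered gene pairs are aligned; pairs with identity at or above
#' `min_identity` and e-value at or below `max_evalue` are duplication events.
#' Pairs on the same chromosome with start-to-start distance within the
#' tandem window (5 Mb) are tandem duplications; same-chromosome pairs beyond
#' the window, and pairs on different chromosomes, are segmental.
#'
#' @param proteins Named character vector of protein sequences.
#' @param locations Data frame with columns `gene_id`, `chromosome`, `start`.
#' @param min_identity Identity threshold (%, default 80).
#' @param max_evalue E-value threshold (default 1e-10).
#' @param tandem_window_bp Tandem distance window (default 5e6).
#' @return Data frame of duplication events: `gene_a`, `gene_b`, `class`
#'   (`"tandem"`/`"segmental"`), `distance` (bp; `NA` across chromosomes),
#'   `identity`, `evalue`.
#' @export
find_paralogs <- function(proteins, locations, min_identity = 80,
                          max_evalue = 1e-10,
                          tandem_window_bp = TANDEM_WINDOW_BP) {
  ids <- names(proteins)
  missing <- setdiff(ids, locations$gene_id)
  if (length(missing) > 0)
    stopf("no location for gene(s): %s", paste(missing, collapse = ", "))
  loc <- locations[match(ids, locations$gene_id), , drop = FALSE]
  n <- length(proteins)
  out <- list()
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      js <- seq(i + 1, n)
      raw <- batch_scores(proteins[js], proteins[[i]])
      ev <- karlin_altschul_evalue(raw, nchar(proteins[js]),
                                   nchar(proteins[[i]]))
      for (k in which(ev <= max_evalue)) {
        j <- js[k]
        al <- align_pair(proteins[[i]], proteins[[j]],
                         query_id = ids[i], subject_id = ids[j])
        if (al$identity < min_identity || al$evalue > max_evalue) next
        same_chr <- loc$chromosome[i] == loc$chromosome[j]
        dist <- if (same_chr) abs(loc$start[i] - loc$start[j]) else NA_real_
        cls <- if (same_chr && dist <= tandem_window_bp) "tandem"
               else "segmental"
        out[[length(out) + 1]] <- data.frame(
          gene_a = ids[i], gene_b = ids[j], class = cls, distance = dist,
          identity = al$identity, evalue = al$evalue,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      class = character(), distance = numeric(),
                      identity = numeric(), evalue = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Best-bidirectional-hit orthologs between two proteomes
#'
#' A pair is emitted iff each sequence is the other's highest-scoring
#' cross-proteome hit at e-value at or below the threshold. Ties are broken
#' by lower e-value, then lexicographically smaller subject identifier, so
#' the result is deterministic and symmetric in the argument order.
#'
#' @param proteome1,proteome2 Named character vectors of protein sequences.
#' @param max_evalue E-value threshold (default 1e-10).
#' @return Data frame with `gene1`, `gene2`, `raw_score`, `evalue12`,
#'   `evalue21`.
#' @export
find_orthologs_bbh <- function(proteome1, proteome2, max_evalue = 1e-10) {
  if (length(proteome1) == 0 || length(proteome2) == 0)
    stopf("both proteomes must be non-empty")
  S <- score_matrix(proteome1, proteome2)
  E <- KA_K * outer(nchar(proteome1), nchar(proteome2)) * exp(-KA_LAMBDA * S)
  S[E > max_evalue] <- -Inf
  best_of <- function(scores, evals, cand_names) {
    ok <- which(is.finite(scores))
    if (length(ok) == 0) return(NA_integer_)
    o <- ok[order(-scores[ok], evals[ok], cand_names[ok])]
    o[1]
  }
  best12 <- vapply(seq_len(nrow(S)), function(i)
    best_of(S[i, ], E[i, ], colnames(S)), integer(1))
  best21 <- vapply(seq_len(ncol(S)), function(j)
    best_of(S[, j], E[, j], rownames(S)), integer(1))
  rows <- which(!is.na(best12))
  rows <- rows[!is.na(best21[best12[rows]]) & best21[best12[rows]] == rows]
  data.frame(gene1 = rownames(S)[rows],
             gene2 = colnames(S)[best12[rows]],
             raw_score = S[cbind(rows, best12[rows])],
             evalue12 = E[cbind(rows, best12[rows])],
             evalue21 = E[cbind(rows, best12[rows])],
             stringsAsFactors = FALSE)
}

#' Write a Circos-compatible link table for paired genes
#'
#' @param pairs Data frame with `gene_a`/`gene_b` (or `gene1`/`gene2`).
#' @param locations Data frame with `gene_id`, `chromosome`, `start`, `end`.
#' @param path Output path (tab-separated: chrom, start, end, chrom, start,
#'   end).
#' @return Invisibly, the written table.
#' @export
write_link_table <- function(pairs, locations, path) {
  a <- if ("gene_a" %in% names(pairs)) pairs$gene_a else pairs$gene1
  b <- if ("gene_b" %in% names(pairs)) pairs$gene_b else pairs$gene2
  la <- locations[match(a, locations$gene_id), ]
  lb <- locations[match(b, locations$gene_id), ]
  out <- data.frame(chrom1 = la$chromosome, start1 = la$start, end1 = la$end,
                    chrom2 = lb$chromosome, start2 = lb$start, end2 = lb$end)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(out)
}
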