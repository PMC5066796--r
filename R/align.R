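# Pairwise protein alignment with Karlin-Altschul e-values. Stands behind the
# duplication and orthology searches.

# gapped BLOSUM62 statistics (gap open 11 / extend 1), documented BLAST values
KA_LAMBDA <- 0.267
KA_K <- 0.041

blosum62 <- function() {
  cached("blosum62", {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    get("BLOSUM62", envir = e)
  })
}

#' Smith-Waterman local alignment of two protein sequences
#'
#' Local alignment under BLOSUM62 with affine gaps (open 11, extend 1 by
#' default). Identity is the percentage of identical columns over aligned
#' non-gap columns. The expectation value follows the Karlin-Altschul form
#' `K * m * n * exp(-lambda * S)` with bundled gapped-BLOSUM62 constants.
#'
#' @param a,b Protein sequences (single strings).
#' @param gap_opening,gap_extension Affine gap penalties.
#' @param query_id,subject_id Identifiers recorded in the result.
#' @return Data frame row with `query_id`, `subject_id`, `identity`, `score`
#'   (bits), `raw_score`, `evalue` and `aligned_length`.
#' @export
align_pair <- function(a, b, gap_opening = 11, gap_extension = 1,
                       query_id = "query", subject_id = "subject") {
  if (nchar(a) == 0 || nchar(b) == 0) stopf("empty sequence in align_pair")
  al <- Biostrings::pairwiseAlignment(a, b, type = "local",
                                      substitutionMatrix = blosum62(),
                                      gapOpening = gap_opening,
                                      gapExtension = gap_extension)
  raw <- Biostrings::score(al)
  nid <- Biostrings::nmatch(al)
  nmis <- Biostrings::nmismatch(al)
  ncols <- Biostrings::nchar(al)  # aligned columns incl. gaps
  data.frame(query_id = query_id, subject_id = subject_id,
             identity = if (nid + nmis > 0) 100 * nid / (nid + nmis) else 0,
             score = (KA_LAMBDA * raw - log(KA_K)) / log(2),
             raw_score = raw,
             evalue = karlin_altschul_evalue(raw, nchar(a), nchar(b)),
             aligned_length = ncols,
             stringsAsFactors = FALSE)
}

karlin_altschul_evalue <- function(raw_score, m, n) {
  KA_K * m * n * exp(-KA_LAMBDA * raw_score)
}

# raw SW scores of all `patterns` against one `subject` (vectorised in C)
batch_scores <- function(patterns, subject, gap_opening = 11,
                         gap_extension = 1) {
  Biostrings::pairwiseAlignment(Biostrings::AAStringSet(patterns), subject,
                                type = "local",
                                substitutionMatrix = blosum62(),
                                gapOpening = gap_opening,
                                gapExtension = gap_extension,
                                scoreOnly = TRUE)
}

# full raw-score matrix between two named sets of sequences
score_matrix <- function(set1, set2) {
  m <- matrix(NA_real_, nrow = length(set1), ncol = length(set2),
              dimnames = list(names(set1), names(set2)))
  for (j in seq_along(set2)) {
    m[, j] <- batch_scores(set1, set2[[j]])
  }
  m
}
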