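# Intron counts, splice phases and paralog exon/intron-structure comparison
# from gene models.

#' Construct a gene model
#'
#' Exons are genomic (start, end) pairs, 1-based inclusive, non-overlapping.
#' They are stored in transcription order (ascending for `+`, descending for
#' `-`). `cds_offset` is the 0-based offset of the reading-frame start within
#' the first exon in transcription order.
#'
#' @param gene_id Gene identifier.
#' @param chromosome Chromosome / scaffold name.
#' @param strand `"+"` or `"-"`.
#' @param exons Data frame or 2-column matrix of exon `start`, `end`.
#' @param cds_offset Coding start offset within the first exon (default 0).
#' @return Object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chromosome, strand, exons, cds_offset = 0) {
  strand <- match.arg(strand, c("+", "-"))
  exons <- as.data.frame(exons)
  if (nrow(exons) == 0 || ncol(exons) < 2)
    stopf("gene %s has zero exons", gene_id)
  names(exons)[1:2] <- c("start", "end")
  if (any(exons$end < exons$start))
    stopf("gene %s has an exon with end < start", gene_id)
  if (any(exons$start < 1)) stopf("gene %s has coordinates < 1", gene_id)
  exons <- exons[order(exons$start), , drop = FALSE]
  if (nrow(exons) > 1 &&
      any(exons$start[-1] <= exons$end[-nrow(exons)]))
    stopf("gene %s has overlapping exons", gene_id)
  if (strand == "-") exons <- exons[rev(seq_len(nrow(exons))), , drop = FALSE]
  rownames(exons) <- NULL
  first_len <- exons$end[1] - exons$start[1] + 1
  if (cds_offset < 0 || cds_offset >= first_len)
    stopf("gene %s: cds_offset %d outside first exon (length %d)",
          gene_id, cds_offset, first_len)
  structure(list(gene_id = gene_id, chromosome = chromosome, strand = strand,
                 exons = exons, cds_offset = as.integer(cds_offset)),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%s strand %s, %d exon(s)\n", x$gene_id,
              x$chromosome, paste(range(unlist(x$exons[, 1:2])),
                                  collapse = "-"),
              x$strand, nrow(x$exons)))
  invisible(x)
}

#' Number of introns of a gene model
#'
#' @param model A `gene_model`.
#' @return Integer: number of exons minus one.
#' @export
intron_count <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  nrow(model$exons) - 1L
}

#' Splice phases of a gene model
#'
#' The phase of an intron is the number of coding nucleotides 5' of the
#' splice junction modulo 3: a boundary after a complete codon is phase 0,
#' after one nucleotide of a codon phase 1, after two phase 2. Exons are
#' traversed in transcription order, so plus- and minus-strand genes with
#' mirrored structures yield identical phases. Only coding nucleotides
#' (from `cds_offset` onwards) are counted.
#'
#' @param model A `gene_model`.
#' @return List with `gene_id`, `intron_count` and integer vector `phases`.
#' @export
splice_phases <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  lens <- model$exons$end - model$exons$start + 1
  coding <- cumsum(lens) - model$cds_offset
  n_intron <- length(lens) - 1L
  phases <- if (n_intron > 0) as.integer(coding[seq_len(n_intron)] %% 3)
            else integer(0)
  structure(list(gene_id = model$gene_id, intron_count = n_intron,
                 phases = phases),
            class = "splice_phase_profile")
}

#' @export
print.splice_phase_profile <- function(x, ...) {
  cat(sprintf("<splice_phases> %s: %d intron(s) [%s]\n", x$gene_id,
              x$intron_count, paste(x$phases, collapse = ",")))
  invisible(x)
}

#' Compare exon/intron structure of a paralogous gene pair
#'
#' A pair is `conserved` when intron counts are equal, otherwise `gain_loss`
#' with `delta` the absolute count difference. Phase strings are reported as
#' auxiliary evidence.
#'
#' @param a,b `splice_phase_profile` objects (from [splice_phases()]).
#' @return List with `status`, `delta`, `phases_a`, `phases_b`,
#'   `phases_equal`.
#' @export
compare_paralog_structure <- function(a, b) {
  stopifnot(inherits(a, "splice_phase_profile"),
            inherits(b, "splice_phase_profile"))
  pa <- paste(a$phases, collapse = ",")
  pb <- paste(b$phases, collapse = ",")
  if (a$intron_count == b$intron_count) {
    list(status = "conserved", delta = 0L, phases_a = pa, phases_b = pb,
         phases_equal = identical(a$phases, b$phases))
  } else {
    list(status = "gain_loss",
         delta = abs(a$intron_count - b$intron_count),
         phases_a = pa, phases_b = pb, phases_equal = FALSE)
  }
}
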