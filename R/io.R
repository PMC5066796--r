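# Readers and writers for the standard formats the pipeline consumes and
# emits: protein FASTA, GFF3 gene models, TSV tables, Newick trees and
# plain-text key-value configuration files.

#' Read a protein FASTA file
#'
#' Identifiers are taken up to the first whitespace of the header line.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of protein sequences.
#' @export
read_protein_fasta <- function(path) {
  seqs <- read_fasta_chars(path)
  if (anyDuplicated(names(seqs)))
    stopf("duplicate sequence id(s) in %s: %s", path,
          paste(unique(names(seqs)[duplicated(names(seqs))]),
                collapse = ", "))
  seqs
}

#' Write protein sequences to FASTA
#'
#' @param proteins Named character vector.
#' @param path Output path.
#' @export
write_protein_fasta <- function(proteins, path) {
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(unlist(proteins)), path)
  invisible(path)
}

validate_gff3_lines <- function(path) {
  lines <- readLines(path)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (ln == "" || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) != 9)
      stopf("malformed GFF3 record at line %d of %s: expected 9 columns",
            i, path)
    st <- suppressWarnings(as.numeric(f[4]))
    en <- suppressWarnings(as.numeric(f[5]))
    if (is.na(st) || is.na(en) || en < st)
      stopf("malformed GFF3 record at line %d of %s: bad coordinates", i,
            path)
  }
  invisible(TRUE)
}

#' Read gene models from a GFF3 file
#'
#' Parses gene/mRNA/CDS features (1-based inclusive coordinates, per the
#' GFF3 standard) into [gene_model()] objects. Coding exons (CDS features)
#' define the model; when a gene has several mRNAs the isoform with the
#' longest summed CDS is used. The reading-frame offset of the first CDS
#' segment (GFF3 phase column) becomes `cds_offset`.
#'
#' @param path Path to a GFF3 file.
#' @return Named list of `gene_model` objects.
#' @export
read_gene_models <- function(path) {
  validate_gff3_lines(path)
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  genes <- gr[typ == "gene"]
  if (anyDuplicated(genes$ID))
    stopf("duplicate gene id(s) in %s: %s", path,
          paste(unique(genes$ID[duplicated(genes$ID)]), collapse = ", "))
  mrnas <- gr[typ == "mRNA"]
  cds <- gr[typ == "CDS"]
  cds_parent <- vapply(cds$Parent, function(p) p[1], character(1))
  out <- list()
  for (gi in seq_along(genes)) {
    gid <- genes$ID[gi]
    tx <- mrnas[vapply(mrnas$Parent, function(p) gid %in% p, logical(1))]
    if (length(tx) == 0) next
    best <- NULL; best_len <- -1
    for (ti in seq_along(tx)) {
      seg <- cds[cds_parent == tx$ID[ti]]
      if (length(seg) == 0) next
      len <- sum(BiocGenerics::width(seg))
      if (len > best_len) { best <- seg; best_len <- len }
    }
    if (is.null(best)) next
    strand <- as.character(BiocGenerics::strand(best)[1])
    exons <- data.frame(start = BiocGenerics::start(best),
                        end = BiocGenerics::end(best))
    phases <- suppressWarnings(as.integer(as.character(best$phase)))
    ord <- order(exons$start, decreasing = (strand == "-"))
    first_phase <- phases[ord[1]]
    offset <- if (length(first_phase) == 1 && !is.na(first_phase))
      first_phase else 0L
    out[[gid]] <- gene_model(gid,
                             as.character(GenomicRanges::seqnames(best)[1]),
                             strand, exons, cds_offset = offset)
  }
  out
}

#' Write gene models to a GFF3 file
#'
#' Emits gene, mRNA, exon and CDS features with Parent links and correct
#' CDS phase columns.
#'
#' @param models List of [gene_model()] objects.
#' @param path Output path.
#' @param source Value for the GFF3 source column.
#' @export
write_gene_models <- function(models, path, source = "ap2erf") {
  rows <- list()
  for (m in models) {
    ex <- m$exons  # transcription order
    span <- c(min(ex$start), max(ex$end))
    tid <- paste0(m$gene_id, ".t1")
    lens <- ex$end - ex$start + 1
    cumbefore <- c(0, cumsum(lens))[seq_len(nrow(ex))]
    phase <- (3 - ((cumbefore - m$cds_offset) %% 3)) %% 3
    rows[[length(rows) + 1]] <- data.frame(
      seqnames = m$chromosome,
      start = c(span[1], span[1], ex$start, ex$start),
      end = c(span[2], span[2], ex$end, ex$end),
      strand = m$strand,
      type = c("gene", "mRNA", rep("exon", nrow(ex)),
               rep("CDS", nrow(ex))),
      ID = c(m$gene_id, tid, rep(NA, 2 * nrow(ex))),
      Parent = c(NA, m$gene_id, rep(tid, 2 * nrow(ex))),
      phase = c(NA, NA, rep(NA, nrow(ex)), phase),
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqnames,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand)
  gr$source <- source
  gr$type <- df$type
  gr$ID <- df$ID
  gr$Parent <- methods::as(lapply(df$Parent, function(p)
    if (is.na(p)) character(0) else p), "CharacterList")
  gr$phase <- df$phase
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write a data frame as TSV
#'
#' @param x Data frame.
#' @param path Output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a tree as Newick, with bootstrap support as internal node labels
#'
#' @param tree `phylo` tree.
#' @param path Output path.
#' @param support Optional support vector from [bootstrap_support()].
#' @export
write_newick <- function(tree, path, support = NULL) {
  if (!is.null(support)) tree <- tree_with_support(tree, support)
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a flat key-value configuration file
#'
#' @param config Named list of atomic values (vectors are comma-joined,
#'   keeping element names as `name=value`).
#' @param path Output path.
#' @export
write_config <- function(config, path) {
  config <- unclass(config)
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    if (length(v) > 1 && !is.null(names(v)))
      v <- paste(sprintf("%s=%s", names(v), v), collapse = ",")
    else v <- paste(v, collapse = ",")
    sprintf("%s\t%s", k, v)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a full synthetic fixture set to a directory
#'
#' Emits, per species, a protein FASTA and a GFF3 of gene models, plus the
#' truth tables (TSV) and the generator configuration (plain-text
#' key-value). Running twice with the same configuration gives
#' byte-identical files.
#'
#' @param sim An `ap2erf_synthetic` object from [generate_genomes()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
write_genomes <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (sp in names(sim$proteins)) {
    fa <- file.path(dir, sprintf("proteins_%s.fasta", sp))
    write_protein_fasta(sim$proteins[[sp]], fa)
    gf <- file.path(dir, sprintf("genes_%s.gff3", sp))
    write_gene_models(sim$models[[sp]], gf)
    paths <- c(paths, fa, gf)
  }
  tg <- file.path(dir, "truth_genes.tsv")
  write_tsv(sim$truth$genes, tg)
  tp <- file.path(dir, "truth_paralogs.tsv")
  write_tsv(sim$truth$paralogs, tp)
  to <- file.path(dir, "truth_orthologs.tsv")
  write_tsv(sim$truth$orthologs, to)
  cf <- file.path(dir, "config.txt")
  write_config(sim$config, cf)
  invisible(c(paths, tg, tp, to, cf))
}
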