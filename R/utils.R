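# internal helpers shared across modules

.ap2erf_cache <- new.env(parent = emptyenv())

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

extdata_path <- function(...) {
  p <- system.file("extdata", ..., package = "ap2erf", mustWork = TRUE)
  p
}

cached <- function(key, expr) {
  if (!exists(key, envir = .ap2erf_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .ap2erf_cache)
  }
  get(key, envir = .ap2erf_cache, inherits = FALSE)
}

#' Residue property table bundled with the package
#'
#' Average residue masses (Da), side-chain pKa values (EMBOSS set), ionizable
#' charge signs and background amino-acid frequencies (Robinson & Robinson).
#'
#' @return A data frame with one row per standard residue.
#' @export
aa_properties <- function() {
  cached("aa_properties", {
    utils::read.delim(extdata_path("aa_properties.tsv"),
                      stringsAsFactors = FALSE)
  })
}

aa_background <- function() {
  tab <- aa_properties()
  stats::setNames(tab$background_freq / sum(tab$background_freq), tab$residue)
}

# run code under a local RNG stream seeded with `seed`, restoring global state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# named character vector of sequences from a (possibly aligned) FASTA
read_fasta_chars <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

check_aa_sequence <- function(seq, allow_gap = FALSE, what = "sequence") {
  letters <- strsplit(seq, "")[[1]]
  ok <- c(AA20, "X", if (allow_gap) c("-", "."))
  bad <- setdiff(unique(letters), ok)
  if (length(bad) > 0)
    stopf("invalid residue letter(s) in %s: %s", what,
          paste(bad, collapse = ", "))
  invisible(letters)
}

#' Published AP2/ERF subgroup counts for five legumes
#'
#' Subgroup counts (A1-A6, B1-B6), AP2, AINTEGUMENTA, RAV and soloist member
#' counts together with annotated gene totals and assembly sizes (Mb) for
#' chickpea, pigeonpea, common bean, Medicago and Lotus, as published for the
#' five reference proteomes.
#'
#' @return A data frame, one row per species.
#' @export
legume_family_counts <- function() {
  cached("legume_counts", {
    utils::read.delim(extdata_path("legume_family_counts.tsv"),
                      check.names = FALSE, stringsAsFactors = FALSE)
  })
}
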