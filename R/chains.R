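#' Exon chains and genomic intervals
#'
#' All coordinates inside the package are 0-based half-open `[start, end)`
#' on a named chromosome with strand `+` or `-`. An *exon chain* is an
#' integer matrix with columns `start` and `end`, rows sorted by `start`,
#' with at least 1 bp between consecutive exons (the introns). Readers
#' convert from the 1-based closed GTF convention at the boundary; writers
#' convert back on output.
#'
#' @name chains
NULL

#' Build and validate an exon chain
#'
#' @param starts,ends Integer vectors of equal length, 0-based half-open.
#' @return An integer matrix with columns `start`, `end`.
#' @examples
#' exon_chain(c(100, 300), c(200, 400))
#' @export
exon_chain <- function(starts, ends) {
  m <- cbind(start = as.integer(starts), end = as.integer(ends))
  validate_chain(m)
  m
}

validate_chain <- function(exons) {
  if (!is.matrix(exons) || ncol(exons) != 2L || nrow(exons) < 1L)
    stop("exon chain must be a matrix with >= 1 row and 2 columns")
  if (any(exons[, 2L] <= exons[, 1L]))
    stop("exon with end <= start")
  if (nrow(exons) > 1L) {
    if (is.unsorted(exons[, 1L], strictly = TRUE))
      stop("exons must be sorted by start")
    gaps <- exons[-1L, 1L] - exons[-nrow(exons), 2L]
    if (any(gaps < 1L))
      stop("consecutive exons must be separated by >= 1 bp (an intron)")
  }
  invisible(exons)
}

#' Introns of an exon chain
#'
#' @param exons An exon chain matrix.
#' @return Integer matrix with columns `start`, `end`, one row per intron
#'   (`nrow(exons) - 1` rows; zero rows for a single-exon chain).
#' @export
chain_introns <- function(exons) {
  n <- nrow(exons)
  if (n < 2L)
    return(matrix(integer(), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  cbind(start = exons[-n, 2L], end = exons[-1L, 1L])
}

# Flat vector of intron boundaries (s1,e1,s2,e2,...); empty for single-exon.
intron_boundaries <- function(exons) {
  as.integer(t(chain_introns(exons)))
}

# String key identifying a chain's intron structure exactly.
chain_key <- function(chrom, strand, exons) {
  paste(chrom, strand, paste(intron_boundaries(exons), collapse = ","), sep = "|")
}

chain_span <- function(exons) c(exons[1L, 1L], exons[nrow(exons), 2L])

chain_len <- function(exons) sum(exons[, 2L] - exons[, 1L])

# Strand-aware 5'/3' genomic ends of a chain.
chain_5p <- function(exons, strand) {
  if (strand == "+") exons[1L, 1L] else exons[nrow(exons), 2L]
}
chain_3p <- function(exons, strand) {
  if (strand == "+") exons[nrow(exons), 2L] else exons[1L, 1L]
}

#' Construct a transcript table
#'
#' The package's container for a set of transcripts (reference annotation,
#' simulated truth, or predicted models): a `data.frame` with one row per
#' transcript and a list column `exons` of exon-chain matrices.
#'
#' @param transcript_id,gene_id,chrom,strand,biotype Character vectors.
#' @param exons List of exon chain matrices (see [exon_chain()]).
#' @return A `data.frame` with class `transcript_set`.
#' @export
transcript_set <- function(transcript_id, gene_id, chrom, strand,
                           exons, biotype = "unknown") {
  stopifnot(length(transcript_id) == length(exons))
  if (anyDuplicated(transcript_id))
    stop("transcript_id values must be unique")
  if (!all(strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  lapply(exons, validate_chain)
  df <- data.frame(
    transcript_id = as.character(transcript_id),
    gene_id = as.character(gene_id),
    chrom = as.character(chrom),
    strand = as.character(strand),
    biotype = rep_len(as.character(biotype), length(transcript_id)),
    stringsAsFactors = FALSE
  )
  df$exons <- exons
  class(df) <- c("transcript_set", "data.frame")
  df
}

#' Construct an aligned-read table
#'
#' @param read_id,sample_id,chrom,strand Character vectors.
#' @param exons List of exon chain matrices.
#' @return A `data.frame` with class `read_set`.
#' @export
read_set <- function(read_id, sample_id, chrom, strand, exons) {
  stopifnot(length(read_id) == length(exons))
  if (anyDuplicated(read_id))
    stop("read_id values must be unique within a dataset")
  if (!all(strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  df <- data.frame(
    read_id = as.character(read_id),
    sample_id = as.character(sample_id),
    chrom = as.character(chrom),
    strand = as.character(strand),
    stringsAsFactors = FALSE
  )
  df$exons <- exons
  class(df) <- c("read_set", "data.frame")
  df
}

# GRanges of transcript spans, in 1-based closed coordinates.
spans_granges <- function(tx) {
  sp <- vapply(tx$exons, chain_span, integer(2L))
  GenomicRanges::GRanges(
    tx$chrom,
    IRanges::IRanges(sp[1L, ] + 1L, sp[2L, ]),
    strand = tx$strand
  )
}

# GRanges of all exons with a transcript index column.
exons_granges <- function(tx) {
  n_ex <- vapply(tx$exons, nrow, integer(1L))
  ex <- do.call(rbind, tx$exons)
  gr <- GenomicRanges::GRanges(
    rep(tx$chrom, n_ex),
    IRanges::IRanges(ex[, 1L] + 1L, ex[, 2L]),
    strand = rep(tx$strand, n_ex)
  )
  S4Vectors::mcols(gr)$tx_idx <- rep(seq_len(nrow(tx)), n_ex)
  gr
}

# Lower median: for even counts, the lower of the two middle values.
median_low <- function(x) sort(x)[ceiling(length(x) / 2)]
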