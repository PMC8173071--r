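#' Read a GTF annotation into a transcript table
#'
#' Exon features are grouped per `transcript_id`, sorted, and converted
#' from the 1-based closed GTF convention to the package's 0-based
#' half-open coordinates. The biotype is taken from the
#' `gene_biotype` or `transcript_biotype` attribute (`"unknown"` when
#' absent).
#'
#' @param path Path to a GTF file with exon features carrying
#'   `transcript_id` and `gene_id` attributes.
#' @return A [transcript_set()] data.frame.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pre_scan_gtf(path)
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[S4Vectors::mcols(gr)$type == "exon"]
  if (length(gr) == 0L) stop("no exon features in ", path)
  mc <- S4Vectors::mcols(gr)
  if (is.null(mc$transcript_id) || anyNA(mc$transcript_id))
    stop("exon feature without transcript_id in ", path)
  bio <- mc$gene_biotype
  if (is.null(bio)) bio <- mc$transcript_biotype
  if (is.null(bio)) bio <- rep(NA_character_, length(gr))
  bio[is.na(bio)] <- "unknown"

  ord <- order(mc$transcript_id, GenomicRanges::start(gr))
  gr <- gr[ord]
  mc <- S4Vectors::mcols(gr)
  bio <- bio[ord]
  tid <- mc$transcript_id
  first <- !duplicated(tid)

  chrom_per_tx <- split(as.character(GenomicRanges::seqnames(gr)), tid)
  if (any(vapply(chrom_per_tx, function(x) length(unique(x)), integer(1L)) > 1L))
    stop("transcript spanning two chromosomes")

  exons <- lapply(
    split(data.frame(s = GenomicRanges::start(gr) - 1L,
                     e = GenomicRanges::end(gr)), tid),
    function(d) exon_chain(d$s, d$e)
  )
  keys <- names(exons)
  idx <- match(keys, tid)
  transcript_set(
    transcript_id = keys,
    gene_id = as.character(mc$gene_id[idx]),
    chrom = as.character(GenomicRanges::seqnames(gr))[idx],
    strand = as.character(GenomicRanges::strand(gr))[idx],
    exons = exons,
    biotype = bio[idx]
  )
}

# Cheap structural scan so malformed lines are reported with their number.
pre_scan_gtf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 9L)
      stop("malformed GTF line ", i, ": expected 9 tab-separated fields")
    s <- suppressWarnings(as.integer(f[[4L]]))
    e <- suppressWarnings(as.integer(f[[5L]]))
    if (is.na(s) || is.na(e))
      stop("malformed GTF line ", i, ": non-numeric coordinates")
    if (e < s)
      stop("malformed GTF line ", i, ": end < start")
  }
  invisible(TRUE)
}

#' Write a transcript table as GTF
#'
#' Exon rows only, Ensembl-dialect attributes; 0-based half-open internal
#' coordinates are converted to 1-based closed on output. Extra
#' per-transcript attributes (e.g. the novelty category) can be supplied.
#'
#' @param tx A [transcript_set()].
#' @param path Output path.
#' @param extra_attrs Optional named list of character vectors (one value
#'   per transcript) written as additional GTF attributes.
#' @export
write_gtf <- function(tx, path, extra_attrs = NULL) {
  n_ex <- vapply(tx$exons, nrow, integer(1L))
  ex <- do.call(rbind, tx$exons)
  gr <- GenomicRanges::GRanges(
    rep(tx$chrom, n_ex),
    IRanges::IRanges(ex[, 1L] + 1L, ex[, 2L]),
    strand = rep(tx$strand, n_ex)
  )
  mc <- S4Vectors::DataFrame(
    source = "isoscribe",
    type = "exon",
    transcript_id = rep(tx$transcript_id, n_ex),
    gene_id = rep(tx$gene_id, n_ex),
    gene_biotype = rep(tx$biotype, n_ex)
  )
  if (!is.null(extra_attrs))
    for (nm in names(extra_attrs))
      mc[[nm]] <- rep(as.character(extra_attrs[[nm]]), n_ex)
  S4Vectors::mcols(gr) <- mc
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read a sample sheet
#'
#' Tab-separated with columns `sample_id`, `tissue`, `individual` and an
#' optional logical `include_flag` (default `TRUE`).
#'
#' @param path Path to the TSV file.
#' @return A data.frame.
#' @export
read_sample_sheet <- function(path) {
  ss <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "tissue", "individual")
  if (!all(need %in% names(ss)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  if (is.null(ss$include_flag)) ss$include_flag <- TRUE
  ss$include_flag <- as.logical(ss$include_flag)
  if (anyDuplicated(ss$sample_id)) stop("duplicate sample_id in sample sheet")
  ss
}

#' Read aligned full-length reads from BED12
#'
#' Block fields are converted to absolute exon coordinates (BED is already
#' 0-based half-open). The sample is resolved by matching a sample-sheet
#' `sample_id` as a prefix of the read name (separated by `.`, `_`, `#`
#' or `|`), unless `sample_id` is given for the whole file. Records with
#' strand `.` are rejected; their count is reported as a warning and in
#' `attr(, "n_strand_dropped")`.
#'
#' @param path Path to a BED12 file.
#' @param samples Sample sheet data.frame (see [read_sample_sheet()]).
#' @param sample_id Optional single sample id applying to every record.
#' @return A [read_set()] data.frame.
#' @export
read_bed12 <- function(path, samples, sample_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pre_scan_bed12(path)
  gr <- rtracklayer::import(path, format = "bed")
  strands <- as.character(GenomicRanges::strand(gr))
  n_drop <- sum(strands == "*")
  if (n_drop > 0L) {
    warning(n_drop, " record(s) with unknown strand dropped")
    gr <- gr[strands != "*"]
  }
  if (length(gr) == 0L) stop("no stranded records in ", path)
  blk <- rtracklayer::blocks(gr)  # absolute 1-based closed exon ranges
  exons <- lapply(seq_along(gr), function(i) {
    r <- blk[[i]]
    exon_chain(GenomicRanges::start(r) - 1L, GenomicRanges::end(r))
  })
  nm <- S4Vectors::mcols(gr)$name
  if (is.null(nm)) nm <- paste0("read", seq_along(gr))
  sid <- if (!is.null(sample_id)) {
    rep(sample_id, length(gr))
  } else {
    resolve_sample_prefix(nm, samples$sample_id)
  }
  rs <- read_set(
    read_id = nm, sample_id = sid,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    exons = exons
  )
  attr(rs, "n_strand_dropped") <- n_drop
  rs
}

pre_scan_bed12 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(ln) || startsWith(ln, "#") || startsWith(ln, "track")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 12L)
      stop("malformed BED12 line ", i, ": expected 12 fields")
    n_blk <- suppressWarnings(as.integer(f[[10L]]))
    sizes <- strsplit(f[[11L]], ",", fixed = TRUE)[[1L]]
    starts <- strsplit(f[[12L]], ",", fixed = TRUE)[[1L]]
    if (is.na(n_blk) || length(sizes) != n_blk || length(starts) != n_blk)
      stop("malformed BED12 line ", i,
           ": blockSizes/blockStarts length does not match blockCount")
  }
  invisible(TRUE)
}

resolve_sample_prefix <- function(read_ids, sample_ids) {
  # Longest sample id first so e.g. "liver_10" wins over "liver_1".
  sids <- sample_ids[order(-nchar(sample_ids))]
  out <- rep(NA_character_, length(read_ids))
  for (s in sids) {
    hit <- is.na(out) & startsWith(read_ids, s) &
      substr(read_ids, nchar(s) + 1L, nchar(s) + 1L) %in% c(".", "_", "#", "|")
    out[hit] <- s
  }
  if (anyNA(out))
    stop("could not resolve sample id for read(s): ",
         paste(utils::head(read_ids[is.na(out)], 3L), collapse = ", "))
  out
}

#' Write aligned reads as BED12
#'
#' @param reads A [read_set()].
#' @param path Output path.
#' @export
write_bed12 <- function(reads, path) {
  lines <- vapply(seq_len(nrow(reads)), function(i) {
    ex <- reads$exons[[i]]
    s <- ex[1L, 1L]; e <- ex[nrow(ex), 2L]
    paste(reads$chrom[i], s, e, reads$read_id[i], 0L, reads$strand[i],
          s, e, "0,0,0", nrow(ex),
          paste0(paste(ex[, 2L] - ex[, 1L], collapse = ","), ","),
          paste0(paste(ex[, 1L] - s, collapse = ","), ","),
          sep = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Write the pipeline's result tables
#'
#' Emits `models.gtf` (predicted transcripts with category attributes),
#' `classification.tsv`, `expression.tsv` (TPM), `counts.tsv`, `tsi.tsv`
#' and `events.tsv` into `out_dir`. All tables are tab-separated with a
#' header row.
#'
#' @param models Predicted transcript models (a [transcript_set()]-like
#'   data.frame with `model_id`, `support`, `locus_id`).
#' @param classifications Classification table from [classify_models()]
#'   (may be `NULL` to skip).
#' @param matrices An [quantify_expression()] result (may be `NULL`).
#' @param tsi TSI record table (may be `NULL`).
#' @param events Splicing event table (may be `NULL`).
#' @param out_dir Output directory (created if absent).
#' @export
write_outputs <- function(models, classifications = NULL, matrices = NULL,
                          tsi = NULL, events = NULL, out_dir) {
  if (is.null(models) || nrow(models) == 0L)
    stop("refusing to write outputs for an empty model set")
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  mt <- if (!is.null(models$model_id)) models_as_transcripts(models) else models
  ids <- if (!is.null(models$model_id)) models$model_id else models$transcript_id
  extra <- list(support = models$support, locus_id = models$locus_id)
  if (!is.null(classifications)) {
    if (nrow(classifications) == 0L)
      stop("refusing to write an empty classification set")
    extra$category <-
      classifications$category[match(ids, classifications$model_id)]
  }
  write_gtf(mt, file.path(out_dir, "models.gtf"), extra_attrs = extra)
  tsv <- function(d, f) utils::write.table(
    d, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(classifications)) tsv(classifications, "classification.tsv")
  if (!is.null(matrices)) {
    tsv(data.frame(transcript_id = rownames(matrices$tpm), matrices$tpm,
                   check.names = FALSE), "expression.tsv")
    tsv(data.frame(transcript_id = rownames(matrices$counts), matrices$counts,
                   check.names = FALSE), "counts.tsv")
  }
  if (!is.null(tsi)) tsv(tsi, "tsi.tsv")
  if (!is.null(events)) tsv(events, "events.tsv")
  invisible(out_dir)
}

# Models (with model_id) as a transcript_set for writing/classifying.
models_as_transcripts <- function(models) {
  transcript_set(
    transcript_id = models$model_id,
    gene_id = models$locus_id,
    chrom = models$chrom,
    strand = models$strand,
    exons = models$exons,
    biotype = "predicted"
  )
}
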