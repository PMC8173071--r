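#' Per-tissue mean expression
#'
#' Averages TPM over the included replicates of each tissue, after
#' removing excluded samples and any tissue left with fewer than two
#' replicates (mirroring the requirement of at least two high-confidence
#' biological replicates per tissue). Transcripts expressed (TPM > 0) in
#' exactly one sample overall are flagged for exclusion from the TSI.
#'
#' @param expr An [quantify_expression()] result.
#' @param exclusions Character vector of sample ids to drop.
#' @return A list: `means` (transcripts x tissues matrix),
#'   `excluded_from_tsi` (logical per transcript), `dropped_tissues`.
#' @export
tissue_means <- function(expr, exclusions = character()) {
  ss <- expr$samples
  ss <- ss[!(ss$sample_id %in% exclusions) & ss$include_flag, , drop = FALSE]
  if (nrow(ss) == 0L) stop("all samples excluded")
  reps <- table(ss$tissue)
  dropped <- names(reps)[reps < 2L]
  ss <- ss[!(ss$tissue %in% dropped), , drop = FALSE]
  if (nrow(ss) == 0L) stop("no tissue retains two replicates")
  tpm <- expr$tpm[, ss$sample_id, drop = FALSE]
  tissues <- sort(unique(ss$tissue))
  means <- sapply(tissues, function(t)
    rowMeans(tpm[, ss$sample_id[ss$tissue == t], drop = FALSE]))
  if (is.null(dim(means)))
    means <- matrix(means, ncol = length(tissues),
                    dimnames = list(rownames(tpm), tissues))
  excluded <- rowSums(expr$tpm > 0) == 1L
  list(means = means, excluded_from_tsi = excluded,
       dropped_tissues = dropped)
}

#' Tissue specificity index
#'
#' `TSI = max(x_i) / sum(x_i)` over per-tissue mean expression `x`:
#' `1/n` for uniform expression over `n` tissues, 1 for single-tissue
#' expression.
#'
#' @param x Numeric vector of per-tissue mean TPM.
#' @return The TSI, or `NA` for an all-zero vector (such transcripts are
#'   skipped by [tsi_records()]).
#' @export
tsi <- function(x) {
  s <- sum(x)
  if (s <= 0) return(NA_real_)
  max(x) / s
}

#' TSI records for an expression matrix
#'
#' @param expr An [quantify_expression()] result.
#' @param exclusions Sample ids to drop before computing tissue means.
#' @return A data.frame with `transcript_id`, per-tissue mean columns,
#'   `mean_tpm`, `tsi`, `top_tissue` and `category`. Transcripts
#'   expressed in at most one sample, or with all-zero tissue means, are
#'   omitted; their counts are in `attr(,"n_excluded")`.
#' @export
tsi_records <- function(expr, exclusions = character()) {
  tm <- tissue_means(expr, exclusions)
  means <- tm$means
  usable <- !tm$excluded_from_tsi & rowSums(means) > 0
  m <- means[usable, , drop = FALSE]
  rec <- data.frame(transcript_id = rownames(m), stringsAsFactors = FALSE)
  rec <- cbind(rec, as.data.frame(m))
  rec$mean_tpm <- rowMeans(m)
  rec$tsi <- apply(m, 1L, tsi)
  rec$top_tissue <- colnames(m)[max.col(m, ties.method = "first")]
  rec <- categorize_tsi(rec)
  attr(rec, "n_excluded") <- sum(!usable)
  attr(rec, "dropped_tissues") <- tm$dropped_tissues
  rec
}

#' Specificity categories and stratified summary
#'
#' `tissue_specific` when TSI >= 0.8, `broad` when TSI < 0.5,
#' `intermediate` for 0.5 <= TSI < 0.8 (interval boundaries taken
#' literally). The summary stratifies category counts by mean expression
#' band (TPM < 1, 1 <= TPM < 10, TPM >= 10).
#'
#' @param records A data.frame with `tsi` (and `mean_tpm` for the
#'   summary).
#' @return `records` with a `category` column; `attr(,"summary")` holds
#'   the count/percentage table.
#' @export
categorize_tsi <- function(records) {
  records$category <- ifelse(records$tsi >= 0.8, "tissue_specific",
                             ifelse(records$tsi < 0.5, "broad", "intermediate"))
  if (!is.null(records$mean_tpm)) {
    band <- cut(records$mean_tpm, c(-Inf, 1, 10, Inf),
                labels = c("tpm_lt_1", "tpm_1_10", "tpm_ge_10"),
                right = FALSE)
    tab <- table(band, factor(records$category,
                              c("tissue_specific", "intermediate", "broad")))
    overall <- colSums(tab)
    attr(records, "summary") <- list(
      by_band = tab,
      overall = overall,
      overall_pct = 100 * overall / sum(overall)
    )
  }
  records
}

#' Unique-TSS fraction per tissue
#'
#' The strand-aware TSS of each tissue-specific transcript, widened by
#' `window` bp on each side, is compared to the widened TSS of every
#' other predicted transcript; it is unique when no same-strand overlap
#' exists.
#'
#' @param specific A data.frame of tissue-specific transcripts with
#'   `transcript_id` and `top_tissue` (e.g. the `tissue_specific` rows of
#'   [tsi_records()]).
#' @param models All predicted models (a table with `model_id`, `chrom`,
#'   `strand`, `exons`).
#' @param window Half-width of the TSS interval in bp.
#' @return Named numeric vector: fraction of unique TSS per tissue.
#' @export
unique_tss <- function(specific, models, window = 50L) {
  idx <- match(specific$transcript_id, models$model_id)
  if (anyNA(idx)) stop("tissue-specific transcript absent from model set")
  tss <- vapply(seq_len(nrow(models)), function(i)
    chain_5p(models$exons[[i]], models$strand[i]), integer(1L))
  gr_all <- GenomicRanges::GRanges(
    models$chrom,
    IRanges::IRanges(pmax(0L, tss - window) + 1L, tss + window + 1L),
    strand = models$strand)
  is_unique <- vapply(idx, function(i) {
    ov <- GenomicRanges::findOverlaps(gr_all[i], gr_all, ignore.strand = FALSE)
    all(S4Vectors::subjectHits(ov) == i)
  }, logical(1L))
  vapply(split(is_unique, specific$top_tissue), mean, numeric(1L))
}
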