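#' Compare predicted 5'/3' ends to reference end sets
#'
#' For each reference set, the fraction of model 5' ends lying within
#' `window` bp of any same-strand reference 5' end. When a
#' classification table with matched reference transcripts is supplied,
#' also reports the fraction of novel isoforms starting within `near`
#' bp of their matched reference TSS and ending within `near` bp of the
#' matched TES, plus the signed TSS distance distribution (positive =
#' model start downstream of the reference start) for degradation-bias
#' checks.
#'
#' @param models Model table.
#' @param reference_sets Named list of [transcript_set()]s (or data
#'   frames with `chrom`, `strand`, `tss` columns).
#' @param window Half-width in bp for the TSS overlap fraction.
#' @param near Distance in bp for the matched-reference comparisons.
#' @param classifications Optional [classify_models()] table; the first
#'   reference set is used to look up matched transcripts.
#' @return A list: `tss_overlap` (named fractions), and when
#'   classifications are given `matched_tss_frac`, `matched_tes_frac`,
#'   `signed_tss_distance`.
#' @export
end_overlap_stats <- function(models, reference_sets, window = 100L,
                              near = 2000L, classifications = NULL) {
  tss <- vapply(seq_len(nrow(models)), function(i)
    chain_5p(models$exons[[i]], models$strand[i]), integer(1L))
  res <- list()
  fr <- vapply(reference_sets, function(ref) {
    if (is.null(ref$tss)) {
      r_tss <- vapply(seq_len(nrow(ref)), function(i)
        chain_5p(ref$exons[[i]], ref$strand[i]), integer(1L))
      rdf <- data.frame(chrom = ref$chrom, strand = ref$strand, tss = r_tss)
    } else rdf <- ref
    if (nrow(rdf) == 0L) return(NA_real_)
    mean(vapply(seq_len(nrow(models)), function(i) {
      any(rdf$chrom == models$chrom[i] & rdf$strand == models$strand[i] &
            abs(rdf$tss - tss[i]) <= window)
    }, logical(1L)))
  }, numeric(1L))
  res$tss_overlap <- fr

  if (!is.null(classifications)) {
    ref <- reference_sets[[1L]]
    ref_col <- grep("^ref_", names(classifications), value = TRUE)[1L]
    novel <- classifications$category == "novel_isoform" &
      !is.na(classifications[[ref_col]])
    if (any(novel)) {
      mi <- match(classifications$model_id[novel],
                  if (!is.null(models$model_id)) models$model_id
                  else models$transcript_id)
      ri <- match(classifications[[ref_col]][novel], ref$transcript_id)
      ok <- !is.na(mi) & !is.na(ri)
      mi <- mi[ok]; ri <- ri[ok]
      m5 <- tss[mi]
      m3 <- vapply(mi, function(i)
        chain_3p(models$exons[[i]], models$strand[i]), integer(1L))
      r5 <- vapply(ri, function(i)
        chain_5p(ref$exons[[i]], ref$strand[i]), integer(1L))
      r3 <- vapply(ri, function(i)
        chain_3p(ref$exons[[i]], ref$strand[i]), integer(1L))
      res$matched_tss_frac <- mean(abs(m5 - r5) <= near)
      res$matched_tes_frac <- mean(abs(m3 - r3) <= near)
      # positive = model start downstream (3'-ward) of reference start
      sgn <- ifelse(models$strand[mi] == "+", 1L, -1L)
      res$signed_tss_distance <- sgn * (m5 - r5)
    } else {
      res$matched_tss_frac <- NA_real_
      res$matched_tes_frac <- NA_real_
      res$signed_tss_distance <- integer(0L)
    }
  }
  res
}

#' Randomize genomic intervals by placement shuffling
#'
#' Re-places each interval uniformly at random on the genome, preserving
#' its length, rejecting placements that would overlap an excluded
#' region (at most `max_tries` rejections per interval). By default the
#' new chromosome is drawn genome-wide with probability proportional to
#' the number of valid start positions; `mode = "same"` keeps each
#' interval on its original chromosome.
#'
#' @param intervals Data.frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param genome Named integer vector of chromosome lengths.
#' @param excluded Optional data.frame of regions (same columns) that
#'   shuffled intervals must not overlap.
#' @param seed Optional integer seed for reproducibility.
#' @param mode `"genome"` (default) or `"same"`.
#' @param max_tries Rejection-sampling cap per interval.
#' @return A data.frame like `intervals` with new placements.
#' @export
shuffle_intervals <- function(intervals, genome, excluded = NULL,
                              seed = NULL, mode = c("genome", "same"),
                              max_tries = 10000L) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  widths <- intervals$end - intervals$start
  if (any(widths > max(genome)))
    stop("interval longer than the longest chromosome")
  out <- intervals
  for (i in seq_len(nrow(intervals))) {
    w <- widths[i]
    chroms <- if (mode == "same") intervals$chrom[i] else names(genome)
    slots <- pmax(0, genome[chroms] - w + 1)
    if (sum(slots) <= 0)
      stop("no valid placement for interval ", i)
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      ch <- if (length(chroms) == 1L) chroms else
        sample(chroms, 1L, prob = slots)
      s <- sample.int(genome[[ch]] - w + 1L, 1L) - 1L
      e <- s + w
      if (!is.null(excluded) && nrow(excluded) > 0L) {
        clash <- excluded$chrom == ch & excluded$start < e & excluded$end > s
        if (any(clash)) next
      }
      out$chrom[i] <- ch; out$start[i] <- s; out$end[i] <- e
      placed <- TRUE
      break
    }
    if (!placed)
      stop("interval ", i, " unplaceable after ", max_tries, " tries")
  }
  out
}

#' Distance from intervals to the nearest gene
#'
#' Minimum gap in bp from each interval to any gene, strand-agnostic;
#' 0 when overlapping or book-ended. Intervals on a chromosome without
#' genes get `NA`.
#'
#' @param intervals,genes Data.frames with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return Numeric distance vector, one per interval.
#' @export
nearest_gene_distance <- function(intervals, genes) {
  if (nrow(genes) == 0L) stop("gene set must be non-empty")
  gi <- GenomicRanges::GRanges(intervals$chrom,
                               IRanges::IRanges(intervals$start + 1L,
                                                intervals$end))
  gg <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start + 1L, genes$end))
  hits <- GenomicRanges::distanceToNearest(gi, gg, ignore.strand = TRUE)
  d <- rep(NA_real_, nrow(intervals))
  d[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  d
}

#' Two-sample rank-sum (Mann-Whitney U) test
#'
#' U is computed from midrank-tied rank sums. The two-sided p-value is
#' exact (full enumeration over all group labelings) when
#' `n1 + n2 <= 12` and there are no ties, and otherwise uses the normal
#' approximation with tie correction and continuity correction.
#'
#' @param x,y Numeric samples.
#' @return A list with `U` (for `x`), `n1`, `n2`, `p_value`, `method`.
#' @export
rank_sum_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop("both groups need at least one value")
  v <- c(x, y)
  r <- rank(v)  # midranks
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(v) > 0L
  if (all(v == v[1L]))
    return(list(U = U, n1 = n1, n2 = n2, p_value = 1, method = "degenerate"))
  if (n1 + n2 <= 12L && !ties) {
    combos <- utils::combn(n1 + n2, n1)
    us <- apply(combos, 2L, function(idx)
      sum(r[idx]) - n1 * (n1 + 1) / 2)
    p <- 2 * min(mean(us <= U), mean(us >= U))
    return(list(U = U, n1 = n1, n2 = n2, p_value = min(1, p),
                method = "exact"))
  }
  mu <- n1 * n2 / 2
  tie_tab <- table(v)
  n <- n1 + n2
  sigma2 <- n1 * n2 / 12 *
    (n + 1 - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  z <- U - mu
  z <- sign(z) * max(0, abs(z) - 0.5) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-abs(z))
  list(U = U, n1 = n1, n2 = n2, p_value = min(1, p),
       method = "normal_approx")
}

#' Positional enrichment of intergenic models near genes
#'
#' Compares the nearest-gene distances of intergenic predicted models to
#' those of the same intervals randomly re-placed on the genome (gene
#' regions excluded from placement), with the rank-sum test.
#'
#' @param intergenic Data.frame of intergenic model spans (`chrom`,
#'   `start`, `end`).
#' @param genes Data.frame of gene spans.
#' @param genome Named chromosome lengths.
#' @param seed Integer seed for the shuffle.
#' @return A list: `observed`, `shuffled` distance vectors and `test`
#'   (a [rank_sum_test()] result).
#' @export
intergenic_proximity_test <- function(intergenic, genes, genome, seed = 1L) {
  obs <- nearest_gene_distance(intergenic, genes)
  shuf <- shuffle_intervals(intergenic, genome, excluded = genes, seed = seed)
  rand <- nearest_gene_distance(shuf, genes)
  keep <- !is.na(obs) & !is.na(rand)
  list(observed = obs, shuffled = rand,
       test = rank_sum_test(obs[keep], rand[keep]))
}
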