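#' Class codes for predicted transcripts
#'
#' One-character structural relation between a predicted model and its
#' best-matching reference transcript, in the style long-read annotation
#' pipelines use to classify novelty:
#'
#' * `=` exact intron-chain match (terminal ends free)
#' * `c` query chain a contiguous sub-chain of the reference (single-exon
#'   query: contained within one reference exon)
#' * `k` reference chain contained within the query chain
#' * `m` every reference intron retained inside query exons
#' * `n` at least one reference intron retained, the others matched
#' * `j` at least one shared splice junction (both multi-exon)
#' * `e` single-exon query overlapping a reference exon and extending at
#'   least 10 bp into the adjacent intron
#' * `o` other same-strand exon overlap
#' * `i` query fully inside a reference intron (same strand)
#' * `y` reference transcript fully inside a query intron
#' * `x` exon overlap on the opposite strand
#' * `p` no overlap, but within 2,000 bp downstream of a same-strand
#'   reference 3' end (possible polymerase run-on)
#' * `s` intron overlap on the opposite strand
#' * `u` none of the above (intergenic)
#'
#' The most specific applicable code wins, in the order listed above.
#'
#' @name class_codes
NULL

CODE_PRECEDENCE <- c("=", "c", "k", "m", "n", "j", "e", "o",
                     "i", "y", "x", "p", "s", "u")
NOVEL_ISOFORM_CODES <- c("c", "k", "j", "m", "n", "o")
NOVEL_LOCUS_CODES <- c("i", "u", "y", "x")
ARTIFACT_CODES <- c("e", "s", "p")

# Is `sub` a contiguous subsequence of intron matrix `full` (exact)?
is_contiguous_subchain <- function(sub, full) {
  ks <- nrow(sub); kf <- nrow(full)
  if (ks == 0L || ks > kf) return(FALSE)
  for (off in 0:(kf - ks)) {
    if (all(sub == full[(off + 1L):(off + ks), , drop = FALSE])) return(TRUE)
  }
  FALSE
}

# Structural code of query q against one same-strand reference r, given
# that their spans overlap. Returns NA_character_ when no same-strand
# code applies (caller falls through to positional codes).
structural_code <- function(q_ex, r_ex) {
  qi <- chain_introns(q_ex)
  ri <- chain_introns(r_ex)
  q_multi <- nrow(qi) > 0L
  r_multi <- nrow(ri) > 0L
  exon_ov <- any_exon_overlap(q_ex, r_ex)

  if (exon_ov) {
    if (q_multi && r_multi && nrow(qi) == nrow(ri) && all(qi == ri))
      return("=")
    if (!q_multi && !r_multi)
      return("=")
    if (!q_multi) {
      # single-exon query vs multi-exon reference
      qs <- q_ex[1L, 1L]; qe <- q_ex[1L, 2L]
      if (any(r_ex[, 1L] <= qs & qe <= r_ex[, 2L])) return("c")
      if (all(ri[, 1L] >= qs & ri[, 2L] <= qe))     return("m")
      ext <- vapply(seq_len(nrow(r_ex)), function(i) {
        if (qs < r_ex[i, 2L] && qe > r_ex[i, 1L]) {
          left <- if (i > 1L) r_ex[i, 1L] - qs else 0L
          right <- if (i < nrow(r_ex)) qe - r_ex[i, 2L] else 0L
          max(left, right)
        } else 0L
      }, numeric(1L))
      if (max(ext) >= 10) return("e")
      return("o")
    }
    if (q_multi && r_multi) {
      retained <- vapply(seq_len(nrow(ri)), function(i)
        any(q_ex[, 1L] <= ri[i, 1L] & ri[i, 2L] <= q_ex[, 2L]), logical(1L))
      matched <- vapply(seq_len(nrow(ri)), function(i)
        any(qi[, 1L] == ri[i, 1L] & qi[, 2L] == ri[i, 2L]), logical(1L))
      # containment ('c') requires intron compatibility: a reference
      # intron retained inside a query exon rules it out
      if (!any(retained) && is_contiguous_subchain(qi, ri)) return("c")
      if (is_contiguous_subchain(ri, qi)) return("k")
      if (all(retained)) return("m")
      if (any(retained) && all(retained | matched)) return("n")
      if (any(matched)) return("j")
      return("o")
    }
    # multi-exon query vs single-exon reference: generic exon overlap
    return("o")
  }

  # Span overlap without exon overlap.
  qs <- q_ex[1L, 1L]; qe <- q_ex[nrow(q_ex), 2L]
  if (r_multi &&
      any(ri[, 1L] <= qs & qe <= ri[, 2L])) return("i")
  rs <- r_ex[1L, 1L]; re <- r_ex[nrow(r_ex), 2L]
  if (nrow(qi) > 0L &&
      any(qi[, 1L] <= rs & re <= qi[, 2L])) return("y")
  NA_character_
}

any_exon_overlap <- function(a_ex, b_ex) {
  for (i in seq_len(nrow(a_ex))) {
    if (any(a_ex[i, 1L] < b_ex[, 2L] & a_ex[i, 2L] > b_ex[, 1L]))
      return(TRUE)
  }
  FALSE
}

n_shared_introns <- function(a_ex, b_ex) {
  ai <- chain_introns(a_ex); bi <- chain_introns(b_ex)
  if (nrow(ai) == 0L || nrow(bi) == 0L) return(0L)
  sum(vapply(seq_len(nrow(ai)), function(i)
    any(bi[, 1L] == ai[i, 1L] & bi[, 2L] == ai[i, 2L]), logical(1L)))
}

overlap_len <- function(a_ex, b_ex) {
  tot <- 0L
  for (i in seq_len(nrow(a_ex))) {
    tot <- tot + sum(pmax(0L, pmin(a_ex[i, 2L], b_ex[, 2L]) -
                            pmax(a_ex[i, 1L], b_ex[, 1L])))
  }
  tot
}

#' Assign the class code of one model against one annotation
#'
#' Evaluates the model against every overlapping reference transcript and
#' returns the most specific applicable code (see [class_codes]); ties
#' between references with the same code are broken by most shared
#' introns, then longest exonic overlap.
#'
#' @param model One-row model data.frame (or list with `chrom`, `strand`,
#'   `exons[[1]]`).
#' @param annotation A [transcript_set()] reference annotation.
#' @return A list with `code` and `ref_id` (NA when no reference is
#'   involved, i.e. code `u`).
#' @export
assign_class_code <- function(model, annotation) {
  q_ex <- model$exons[[1L]]
  same_chr <- annotation$chrom == model$chrom
  if (!any(same_chr)) return(list(code = "u", ref_id = NA_character_))
  qs <- q_ex[1L, 1L]; qe <- q_ex[nrow(q_ex), 2L]
  sp <- vapply(annotation$exons, chain_span, integer(2L))
  ov <- same_chr & sp[1L, ] < qe & sp[2L, ] > qs

  codes <- character(0L); refs <- character(0L)
  shared <- integer(0L); ovlen <- integer(0L)
  for (ri in which(ov)) {
    r_ex <- annotation$exons[[ri]]
    same_strand <- annotation$strand[ri] == model$strand
    code <- if (same_strand) {
      structural_code(q_ex, r_ex)
    } else {
      if (any_exon_overlap(q_ex, r_ex)) "x"
      else "s"  # span overlap on the opposite strand without exon overlap
    }
    if (is.na(code)) next
    codes <- c(codes, code)
    refs <- c(refs, annotation$transcript_id[ri])
    shared <- c(shared, n_shared_introns(q_ex, r_ex))
    ovlen <- c(ovlen, overlap_len(q_ex, r_ex))
  }
  if (length(codes) > 0L) {
    prec <- match(codes, CODE_PRECEDENCE)
    best <- order(prec, -shared, -ovlen)[1L]
    return(list(code = codes[best], ref_id = refs[best]))
  }
  # No overlap at all: possible run-on within 2 kb downstream of a
  # same-strand reference 3' end, else intergenic.
  ss <- which(same_chr & annotation$strand == model$strand)
  for (ri in ss) {
    r_ex <- annotation$exons[[ri]]
    if (model$strand == "+") {
      r3 <- r_ex[nrow(r_ex), 2L]
      if (qs >= r3 && qs - r3 <= 2000L)
        return(list(code = "p", ref_id = annotation$transcript_id[ri]))
    } else {
      r3 <- r_ex[1L, 1L]
      if (qe <= r3 && r3 - qe <= 2000L)
        return(list(code = "p", ref_id = annotation$transcript_id[ri]))
    }
  }
  list(code = "u", ref_id = NA_character_)
}

#' Map per-annotation class codes to a novelty category
#'
#' `known_isoform` if any annotation yields `=`; otherwise
#' `novel_isoform` if any yields `c`, `k`, `j`, `m`, `n` or `o`;
#' otherwise `novel_locus` if any yields `i`, `u`, `y` or `x`; otherwise
#' `artifact` (only `e`, `s` or `p` observed).
#'
#' @param codes Named character vector, one code per annotation.
#' @return A single category string.
#' @export
categorize <- function(codes) {
  codes <- unlist(codes, use.names = FALSE)
  if (length(codes) == 0L) stop("empty code map")
  if (any(codes == "=")) return("known_isoform")
  if (any(codes %in% NOVEL_ISOFORM_CODES)) return("novel_isoform")
  if (any(codes %in% NOVEL_LOCUS_CODES)) return("novel_locus")
  "artifact"
}

#' Classify a model table against one or two annotations
#'
#' @param models A model table (from [build_transcript_models()]).
#' @param annotations A named list of 1 or 2 [transcript_set()]
#'   annotations.
#' @return A data.frame with `model_id`, one code and matched-reference
#'   column per annotation, and `category`.
#' @export
classify_models <- function(models, annotations) {
  if (!is.list(annotations) || length(annotations) < 1L ||
      length(annotations) > 2L)
    stop("annotations must be a named list of 1 or 2 transcript sets")
  if (is.null(names(annotations)))
    names(annotations) <- paste0("ref", seq_along(annotations))
  out <- data.frame(model_id = models$model_id, stringsAsFactors = FALSE)
  code_cols <- list()
  for (nm in names(annotations)) {
    res <- lapply(seq_len(nrow(models)), function(i)
      assign_class_code(models[i, , drop = FALSE], annotations[[nm]]))
    out[[paste0("code_", nm)]] <- vapply(res, `[[`, character(1L), "code")
    out[[paste0("ref_", nm)]] <- vapply(res, `[[`, character(1L), "ref_id")
    code_cols[[nm]] <- out[[paste0("code_", nm)]]
  }
  out$category <- vapply(seq_len(nrow(models)), function(i)
    categorize(vapply(code_cols, `[`, character(1L), i)), character(1L))
  out
}

#' Filter weakly supported single-exon models
#'
#' Multi-exon models are always retained. A single-exon model is retained
#' only when it overlaps (>= 1 bp, same strand) an exon of a
#' protein-coding gene in either annotation, or its support is at least
#' `min_support` alignments.
#'
#' @param models A model table with `support`.
#' @param annotations Named list of [transcript_set()] annotations with
#'   biotypes.
#' @param min_support Support threshold rescuing unannotated single-exon
#'   models.
#' @return The retained models; attribute `removed` logs counts by
#'   reason.
#' @export
filter_single_exon <- function(models, annotations, min_support = 100L) {
  single <- vapply(models$exons, nrow, integer(1L)) == 1L
  if (!any(single)) {
    attr(models, "removed") <- c(no_coding_overlap_low_support = 0L)
    return(models)
  }
  pc_exons <- do.call(c, unname(lapply(annotations, function(ann) {
    pc <- ann[ann$biotype == "protein_coding", , drop = FALSE]
    if (nrow(pc) == 0L)
      GenomicRanges::GRanges()
    else exons_granges(pc)
  })))
  sing_gr <- exons_granges(models[single, , drop = FALSE])
  hit <- rep(FALSE, sum(single))
  if (length(pc_exons) > 0L) {
    ovl <- GenomicRanges::findOverlaps(sing_gr, pc_exons,
                                       minoverlap = 1L, ignore.strand = FALSE)
    hit[unique(S4Vectors::queryHits(ovl))] <- TRUE
  }
  keep_single <- hit | models$support[single] >= min_support
  keep <- !single
  keep[which(single)[keep_single]] <- TRUE
  out <- models[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- c(
    no_coding_overlap_low_support = sum(!keep_single)
  )
  out
}

#' Sensitivity and precision of predicted multi-exon transcripts
#'
#' Computes the base / exon / intron / transcript / locus grid of
#' sensitivity and precision percentages, plus missed/novel exon and
#' intron counts:
#'
#' * base: strand-aware exonic-base overlap.
#' * exon: exact exon coordinate match; boundaries at transcript ends
#'   ("free" ends) only need the internal boundary to match plus overlap.
#' * intron: exact intron match.
#' * transcript: exact intron-chain match (code `=`).
#' * locus: reference gene (or predicted locus) with at least one exact
#'   transcript match or same-strand exon overlap.
#' * missed/novel features: reference (predicted) exons or introns with
#'   no overlapping predicted (reference) feature at all.
#'
#' @param pred Predicted models as a [transcript_set()]-like table (use
#'   multi-exon models for the headline grid). `gene_id`/`locus_id` keys
#'   the predicted loci.
#' @param ref Reference [transcript_set()].
#' @return A list with `levels` (data.frame of percentages) and `counts`.
#' @export
accuracy_metrics <- function(pred, ref) {
  if (nrow(pred) == 0L || nrow(ref) == 0L)
    stop("both transcript sets must be non-empty")
  if (is.null(pred$transcript_id)) pred$transcript_id <- pred$model_id
  if (is.null(pred$gene_id)) pred$gene_id <- pred$locus_id
  pred_ex <- exons_granges(pred)
  ref_ex <- exons_granges(ref)

  # Base level on strand-aware reduced exonic bases.
  pred_u <- GenomicRanges::reduce(pred_ex)
  ref_u <- GenomicRanges::reduce(ref_ex)
  inter <- GenomicRanges::intersect(pred_u, ref_u)
  base_sn <- 100 * sum(GenomicRanges::width(inter)) /
    sum(GenomicRanges::width(ref_u))
  base_sp <- 100 * sum(GenomicRanges::width(inter)) /
    sum(GenomicRanges::width(pred_u))

  # Exon level with free terminal boundaries.
  pe <- exon_feature_table(pred)
  re <- exon_feature_table(ref)
  exon_sn <- 100 * mean(exon_matched(re, pe))
  exon_sp <- 100 * mean(exon_matched(pe, re))

  # Intron level, exact.
  pi_ <- unique_introns(pred)
  ri_ <- unique_introns(ref)
  ikey <- function(m) paste(m$chrom, m$strand, m$start, m$end)
  intron_sn <- 100 * mean(ikey(ri_) %in% ikey(pi_))
  intron_sp <- 100 * mean(ikey(pi_) %in% ikey(ri_))

  # Transcript level: exact intron-chain match among multi-exon entries.
  pk <- chain_keys_multi(pred)
  rk <- chain_keys_multi(ref)
  tx_sn <- 100 * mean(rk$key %in% pk$key)
  tx_sp <- 100 * mean(pk$key %in% rk$key)

  # Locus level: exact transcript match or same-strand exon overlap.
  ref_hit_tx <- rk$id[rk$key %in% pk$key]
  ovl <- GenomicRanges::findOverlaps(ref_ex, pred_ex, ignore.strand = FALSE)
  ref_ov_tx <- unique(ref$transcript_id[
    S4Vectors::mcols(ref_ex)$tx_idx[S4Vectors::queryHits(ovl)]])
  ref_loci_hit <- unique(ref$gene_id[ref$transcript_id %in%
                                       union(ref_hit_tx, ref_ov_tx)])
  locus_sn <- 100 * length(ref_loci_hit) / length(unique(ref$gene_id))
  pred_hit_tx <- pk$id[pk$key %in% rk$key]
  pred_ov_tx <- unique(pred$transcript_id[
    S4Vectors::mcols(pred_ex)$tx_idx[S4Vectors::subjectHits(ovl)]])
  pred_loci_hit <- unique(pred$gene_id[pred$transcript_id %in%
                                         union(pred_hit_tx, pred_ov_tx)])
  locus_sp <- 100 * length(pred_loci_hit) / length(unique(pred$gene_id))

  # Missed/novel features: no overlap with the other set at all.
  re_gr <- GenomicRanges::GRanges(re$chrom, IRanges::IRanges(re$start + 1L, re$end),
                                  strand = re$strand)
  pe_gr <- GenomicRanges::GRanges(pe$chrom, IRanges::IRanges(pe$start + 1L, pe$end),
                                  strand = pe$strand)
  missed_exons <- sum(GenomicRanges::countOverlaps(re_gr, pe_gr) == 0L)
  novel_exons <- sum(GenomicRanges::countOverlaps(pe_gr, re_gr) == 0L)
  ri_gr <- GenomicRanges::GRanges(ri_$chrom, IRanges::IRanges(ri_$start + 1L, ri_$end),
                                  strand = ri_$strand)
  pi_gr <- GenomicRanges::GRanges(pi_$chrom, IRanges::IRanges(pi_$start + 1L, pi_$end),
                                  strand = pi_$strand)
  missed_introns <- sum(GenomicRanges::countOverlaps(ri_gr, pi_gr) == 0L)
  novel_introns <- sum(GenomicRanges::countOverlaps(pi_gr, ri_gr) == 0L)

  list(
    levels = data.frame(
      level = c("base", "exon", "intron", "transcript", "locus"),
      sensitivity = c(base_sn, exon_sn, intron_sn, tx_sn, locus_sn),
      precision = c(base_sp, exon_sp, intron_sp, tx_sp, locus_sp)
    ),
    counts = list(
      missed_exons = c(missed_exons, total = nrow(re)),
      novel_exons = c(novel_exons, total = nrow(pe)),
      missed_introns = c(missed_introns, total = nrow(ri_)),
      novel_introns = c(novel_introns, total = nrow(pi_))
    )
  )
}

# Unique exons with flags marking transcript-terminal ("free") boundaries.
exon_feature_table <- function(tx) {
  rows <- lapply(seq_len(nrow(tx)), function(i) {
    ex <- tx$exons[[i]]
    n <- nrow(ex)
    data.frame(chrom = tx$chrom[i], strand = tx$strand[i],
               start = ex[, 1L], end = ex[, 2L],
               free_start = seq_len(n) == 1L,
               free_end = seq_len(n) == n,
               stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  unique(d)
}

# For each exon in `a`, does some exon in `b` match it? Non-free
# boundaries must be equal; free boundaries only require overlap.
exon_matched <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    cand <- b$chrom == a$chrom[i] & b$strand == a$strand[i] &
      b$start < a$end[i] & b$end > a$start[i]
    if (!any(cand)) return(FALSE)
    ok_start <- a$free_start[i] | b$start[cand] == a$start[i]
    ok_end <- a$free_end[i] | b$end[cand] == a$end[i]
    any(ok_start & ok_end)
  }, logical(1L))
}

unique_introns <- function(tx) {
  rows <- lapply(seq_len(nrow(tx)), function(i) {
    ii <- chain_introns(tx$exons[[i]])
    if (nrow(ii) == 0L) return(NULL)
    data.frame(chrom = tx$chrom[i], strand = tx$strand[i],
               start = ii[, 1L], end = ii[, 2L], stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  if (is.null(d))
    return(data.frame(chrom = character(), strand = character(),
                      start = integer(), end = integer()))
  unique(d)
}

chain_keys_multi <- function(tx) {
  multi <- vapply(tx$exons, nrow, integer(1L)) > 1L
  idx <- which(multi)
  list(
    id = tx$transcript_id[idx],
    key = vapply(idx, function(i)
      chain_key(tx$chrom[i], tx$strand[i], tx$exons[[i]]), character(1L))
  )
}
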