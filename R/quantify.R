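#' Read-to-model compatibility
#'
#' A read is compatible with a model when its intron chain is a
#' contiguous 3'-terminal subsequence of the model's chain (each boundary
#' within `cluster_internal` bp) and the read lies within the model span,
#' allowing `cluster_terminal` bp of slack at the ends; 5' truncation is
#' therefore allowed by construction (3'-anchored matching, since 3' ends
#' of full-length cDNA reads are the more reliable end). A single-exon
#' read is compatible with any model whose 3'-terminal exon contains it
#' within `cluster_terminal` bp.
#'
#' @param reads A [read_set()].
#' @param models A model table.
#' @param tol A [tolerance_set()].
#' @return A list with class `compatibility_matrix`: `read_id`,
#'   `sample_id`, and `compat` (list of compatible model-id character
#'   vectors per read). `attr(,"n_unassigned")` counts reads compatible
#'   with nothing.
#' @export
build_compatibility <- function(reads, models, tol = tolerance_set()) {
  read_gr <- spans_granges(data.frame(chrom = reads$chrom,
                                      strand = reads$strand,
                                      stringsAsFactors = FALSE) |>
                             within_exons(reads$exons))
  model_gr <- spans_granges(data.frame(chrom = models$chrom,
                                       strand = models$strand,
                                       stringsAsFactors = FALSE) |>
                              within_exons(models$exons))
  model_gr <- GenomicRanges::resize(
    model_gr, GenomicRanges::width(model_gr) + 2L * tol$cluster_terminal,
    fix = "center")
  hits <- GenomicRanges::findOverlaps(read_gr, model_gr,
                                      type = "within", ignore.strand = FALSE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ok <- vapply(seq_along(qi), function(h) {
    read_model_compatible(reads$exons[[qi[h]]], models$exons[[si[h]]],
                          reads$strand[qi[h]], tol)
  }, logical(1L))
  compat <- split(models$model_id[si[ok]],
                  factor(qi[ok], levels = seq_len(nrow(reads))))
  compat <- lapply(compat, as.character)
  out <- list(read_id = reads$read_id, sample_id = reads$sample_id,
              compat = unname(compat))
  class(out) <- "compatibility_matrix"
  attr(out, "n_unassigned") <- sum(lengths(compat) == 0L)
  out
}

within_exons <- function(df, exons) { df$exons <- exons; df }

read_model_compatible <- function(r_ex, m_ex, strand, tol) {
  kr <- nrow(r_ex) - 1L
  km <- nrow(m_ex) - 1L
  if (kr > km) return(FALSE)
  if (kr == 0L) {
    term <- if (strand == "+") m_ex[nrow(m_ex), , drop = TRUE] else
      m_ex[1L, , drop = TRUE]
    return(r_ex[1L, 1L] >= term[1L] - tol$cluster_terminal &&
             r_ex[1L, 2L] <= term[2L] + tol$cluster_terminal)
  }
  ri <- chain_introns(r_ex)
  mi <- chain_introns(m_ex)
  sub <- if (strand == "+") {
    mi[(km - kr + 1L):km, , drop = FALSE]
  } else {
    mi[seq_len(kr), , drop = FALSE]
  }
  all(abs(ri - sub) <= tol$cluster_internal)
}

#' EM abundance estimation for one sample
#'
#' Full-length read counting with fractional assignment of ambiguous
#' reads: starting uniform over models with at least one compatible read,
#' the E-step splits each read across its compatible set proportionally
#' to the current abundance estimates, the M-step renormalizes the
#' fractional counts, iterating until the maximum relative change drops
#' below `rel_tol` or `max_iter` is reached.
#'
#' @param compat A [build_compatibility()] result.
#' @param sample Sample id to estimate (reads of other samples ignored).
#' @param max_iter,rel_tol Convergence controls.
#' @return Named numeric vector of proportions summing to 1 over the
#'   models with compatible reads; `attr(,"n_assigned")` gives the read
#'   count used. Zero assigned reads yield an empty vector with a
#'   warning.
#' @export
em_abundance <- function(compat, sample, max_iter = 100L, rel_tol = 1e-6) {
  sel <- compat$sample_id == sample & lengths(compat$compat) > 0L
  if (!any(sel)) {
    warning("no assigned reads in sample ", sample)
    out <- numeric(0L)
    attr(out, "n_assigned") <- 0L
    return(out)
  }
  sets <- compat$compat[sel]
  models <- sort(unique(unlist(sets)))
  read_idx <- rep(seq_along(sets), lengths(sets))
  model_idx <- match(unlist(sets), models)
  n_reads <- length(sets)
  prop <- rep(1 / length(models), length(models))
  for (it in seq_len(max_iter)) {
    w <- prop[model_idx]
    denom <- rowsum(w, read_idx)[, 1L]
    frac <- w / denom[read_idx]
    counts <- rep(0, length(models))
    cs <- rowsum(frac, model_idx)
    counts[as.integer(rownames(cs))] <- cs[, 1L]
    new_prop <- counts / n_reads
    delta <- max(abs(new_prop - prop) / pmax(prop, 1e-12))
    prop <- new_prop
    if (delta < rel_tol) break
  }
  names(prop) <- models
  attr(prop, "n_assigned") <- n_reads
  attr(prop, "iterations") <- it
  prop
}

#' Proportions to transcripts-per-million
#'
#' Full-length counting: `tpm = proportion * 1e6`, with no transcript
#' length term, because each full-length read represents one molecule.
#'
#' @param proportions Named proportions summing to 1.
#' @param assigned_read_count Number of reads behind the proportions
#'   (used by callers for the count layer; not needed for TPM itself).
#' @return Named TPM vector.
#' @export
to_tpm <- function(proportions, assigned_read_count = NULL) {
  proportions * 1e6
}

#' Quantify all samples
#'
#' @param reads A [read_set()].
#' @param models A model table.
#' @param samples Sample sheet data.frame.
#' @param tol A [tolerance_set()].
#' @return A list with class `expression_matrix`: `counts` and `tpm`
#'   (models x samples matrices), `samples` metadata, and `unassigned`
#'   per-sample counts.
#' @export
quantify_expression <- function(reads, models, samples,
                                tol = tolerance_set()) {
  compat <- build_compatibility(reads, models, tol)
  ids <- models$model_id
  tpm <- counts <- matrix(0, nrow = length(ids), ncol = nrow(samples),
                          dimnames = list(ids, samples$sample_id))
  unassigned <- integer(nrow(samples))
  names(unassigned) <- samples$sample_id
  for (s in samples$sample_id) {
    in_sample <- compat$sample_id == s
    unassigned[s] <- sum(in_sample & lengths(compat$compat) == 0L)
    if (!any(in_sample & lengths(compat$compat) > 0L)) next
    prop <- em_abundance(compat, s)
    n <- attr(prop, "n_assigned")
    counts[names(prop), s] <- prop * n
    tpm[names(prop), s] <- to_tpm(prop)
  }
  out <- list(counts = counts, tpm = tpm, samples = samples,
              unassigned = unassigned)
  class(out) <- "expression_matrix"
  out
}
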