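#' Boundary tolerances for clustering and collapse
#'
#' Defaults are the stage parameters of the long-read transcript-model
#' construction procedure: a 20 bp exon-boundary tolerance and 60 bp
#' terminal tolerance during clustering of reads into groups of three or
#' more alignments, and a 5 bp internal / 100 bp 3' / 5,000 bp 5'
#' exon-boundary tolerance during degradation-aware collapse.
#'
#' @param cluster_internal,cluster_terminal,collapse_internal,collapse_3prime,collapse_5prime
#'   Non-negative integer tolerances in bp.
#' @param min_cluster_size Minimum alignments per emitted cluster.
#' @return A named list with class `tolerance_set`.
#' @export
tolerance_set <- function(cluster_internal = 20L, cluster_terminal = 60L,
                          collapse_internal = 5L, collapse_3prime = 100L,
                          collapse_5prime = 5000L, min_cluster_size = 3L) {
  tol <- list(cluster_internal = as.integer(cluster_internal),
              cluster_terminal = as.integer(cluster_terminal),
              collapse_internal = as.integer(collapse_internal),
              collapse_3prime = as.integer(collapse_3prime),
              collapse_5prime = as.integer(collapse_5prime),
              min_cluster_size = as.integer(min_cluster_size))
  if (any(unlist(tol) < 0L)) stop("tolerances must be non-negative")
  class(tol) <- "tolerance_set"
  tol
}

#' Cluster aligned reads by intron-chain similarity
#'
#' Reads are sorted canonically by (chrom, strand, intron count, first
#' boundary) and assigned greedily: a read joins the first existing
#' cluster whose seed read has the same chrom/strand/intron count and
#' every intron boundary within `cluster_internal` bp of the seed's
#' corresponding boundary. For single-exon reads (no introns) both
#' terminal ends must instead lie within `cluster_terminal` bp of the
#' seed's; terminal tolerance is deliberately not enforced for multi-exon
#' reads, whose 5' variability is resolved later by [collapse_models()].
#' Unassignable reads seed new clusters. Only clusters of at least
#' `min_cluster_size` members are emitted.
#'
#' @param reads A [read_set()].
#' @param tol A [tolerance_set()].
#' @return A list of clusters, each a list with `chrom`, `strand`,
#'   `n_introns`, `size`, `member_ids`, `starts`, `ends` and `bounds`
#'   (members x intron-boundary matrix). Attributes `n_emitted`,
#'   `n_discarded_clusters` and `n_discarded_reads` report the
#'   sub-threshold remainder.
#' @export
cluster_alignments <- function(reads, tol = tolerance_set()) {
  if (nrow(reads) == 0L) {
    out <- list()
    attr(out, "n_emitted") <- 0L
    attr(out, "n_discarded_clusters") <- 0L
    attr(out, "n_discarded_reads") <- 0L
    return(out)
  }
  n_int <- vapply(reads$exons, nrow, integer(1L)) - 1L
  firstb <- vapply(seq_len(nrow(reads)), function(i) {
    ex <- reads$exons[[i]]
    if (n_int[i] > 0L) ex[1L, 2L] else ex[1L, 1L]
  }, integer(1L))
  ord <- order(reads$chrom, reads$strand, n_int, firstb, reads$read_id)

  grp <- paste(reads$chrom, reads$strand, n_int, sep = "|")
  clusters <- list()
  for (g in split(ord, grp[ord])) {
    k <- n_int[g[1L]]
    tol_first <- if (k == 0L) tol$cluster_terminal else tol$cluster_internal
    # Boundary matrix used for compatibility: intron boundaries for
    # multi-exon reads, (start, end) for single-exon reads.
    bmat <- t(vapply(g, function(i) {
      ex <- reads$exons[[i]]
      if (k == 0L) c(ex[1L, 1L], ex[1L, 2L]) else intron_boundaries(ex)
    }, integer(if (k == 0L) 2L else 2L * k)))
    tolv <- if (k == 0L) rep(tol$cluster_terminal, 2L) else
      rep(tol$cluster_internal, 2L * k)
    assign <- integer(length(g))
    reps <- list()        # seed boundary vectors
    rep_first <- integer() # their sort key, for retiring stale seeds
    active_from <- 1L
    for (j in seq_along(g)) {
      b <- bmat[j, ]
      # Seeds whose first boundary is out of reach can never match again
      # because reads arrive in ascending first-boundary order.
      while (active_from <= length(reps) &&
             rep_first[active_from] < b[1L] - tol_first) {
        active_from <- active_from + 1L
      }
      hit <- 0L
      if (active_from <= length(reps)) {
        for (ci in active_from:length(reps)) {
          if (all(abs(b - reps[[ci]]) <= tolv)) { hit <- ci; break }
        }
      }
      if (hit == 0L) {
        reps[[length(reps) + 1L]] <- b
        rep_first <- c(rep_first, b[1L])
        hit <- length(reps)
      }
      assign[j] <- hit
    }
    for (ci in seq_along(reps)) {
      members <- g[assign == ci]
      ib <- if (k == 0L) {
        matrix(integer(), nrow = length(members), ncol = 0L)
      } else {
        bmat[assign == ci, , drop = FALSE]
      }
      clusters[[length(clusters) + 1L]] <- list(
        chrom = reads$chrom[members[1L]],
        strand = reads$strand[members[1L]],
        n_introns = k,
        size = length(members),
        member_ids = reads$read_id[members],
        starts = vapply(members, function(i) reads$exons[[i]][1L, 1L], integer(1L)),
        ends = vapply(members, function(i) {
          ex <- reads$exons[[i]]; ex[nrow(ex), 2L]
        }, integer(1L)),
        bounds = ib
      )
    }
  }
  sizes <- vapply(clusters, `[[`, integer(1L), "size")
  keep <- sizes >= tol$min_cluster_size
  out <- clusters[keep]
  attr(out, "n_emitted") <- sum(keep)
  attr(out, "n_discarded_clusters") <- sum(!keep)
  attr(out, "n_discarded_reads") <- sum(sizes[!keep])
  out
}

#' Coordinate consensus of a read cluster
#'
#' Each intron boundary of the model is the member-wise median (lower
#' value on even counts); the model start and end are the medians of the
#' member starts and ends. Exons are reconstructed from the consensus
#' boundaries; a consensus yielding a non-positive exon or intron length
#' rejects the cluster with a warning and returns `NULL`.
#'
#' @param cluster One element of a [cluster_alignments()] result.
#' @return A one-row model data.frame, or `NULL` if rejected.
#' @export
consensus_model <- function(cluster) {
  s <- median_low(cluster$starts)
  e <- median_low(cluster$ends)
  ib <- if (ncol(cluster$bounds) > 0L)
    apply(cluster$bounds, 2L, median_low) else integer()
  bounds <- c(s, ib, e)
  if (is.unsorted(bounds, strictly = TRUE)) {
    warning("consensus produced a zero-length exon or intron; cluster rejected")
    return(NULL)
  }
  n_ex <- cluster$n_introns + 1L
  starts <- bounds[seq(1L, by = 2L, length.out = n_ex)]
  ends <- bounds[seq(2L, by = 2L, length.out = n_ex)]
  m <- data.frame(chrom = cluster$chrom, strand = cluster$strand,
                  support = cluster$size,
                  is_single_exon = cluster$n_introns == 0L,
                  stringsAsFactors = FALSE)
  m$exons <- list(exon_chain(starts, ends))
  m$member_ids <- list(cluster$member_ids)
  m
}

# All clusters -> model table with model ids.
consensus_models <- function(clusters) {
  rows <- Filter(Negate(is.null), lapply(clusters, consensus_model))
  if (length(rows) == 0L)
    stop("no cluster produced a valid consensus model")
  models <- do.call(rbind, rows)
  models$model_id <- sprintf("ISCB.%06d", seq_len(nrow(models)))
  rownames(models) <- NULL
  models
}

#' Group transcript models into loci by 3' end
#'
#' Connected components of the relation "same chrom and strand and
#' strand-aware 3' ends within `collapse_3prime` bp". The locus id is
#' `chrom:leftmost-3'-end:strand`, which is deterministic for a given
#' model set.
#'
#' @param models A model table (from [consensus_models()] internals or
#'   [build_transcript_models()]).
#' @param tol A [tolerance_set()].
#' @return `models` with a `locus_id` column.
#' @export
assign_loci <- function(models, tol = tolerance_set()) {
  p3 <- vapply(seq_len(nrow(models)), function(i)
    chain_3p(models$exons[[i]], models$strand[i]), integer(1L))
  models$locus_id <- NA_character_
  for (g in split(seq_len(nrow(models)),
                  paste(models$chrom, models$strand, sep = "|"))) {
    o <- g[order(p3[g])]
    v <- p3[o]
    # 1-D relation: components are runs of sorted 3' ends with adjacent
    # gaps <= tolerance (transitive closure over the pairwise relation).
    comp <- cumsum(c(1L, as.integer(diff(v) > tol$collapse_3prime)))
    for (cid in unique(comp)) {
      idx <- o[comp == cid]
      models$locus_id[idx] <- paste(models$chrom[idx[1L]], min(p3[idx]),
                                    models$strand[idx[1L]], sep = ":")
    }
  }
  models
}

# Absorption predicate: can model A (a likely 5'-degradation product) be
# absorbed into model B? Requires A's intron chain to be a contiguous
# 3'-terminal subsequence of B's within collapse_internal bp per boundary,
# strand-aware 3' ends within collapse_3prime bp, and A's 5' end within
# collapse_5prime bp of the 5' end of the corresponding B exon.
can_absorb <- function(a_ex, b_ex, strand, tol) {
  ka <- nrow(a_ex) - 1L
  kb <- nrow(b_ex) - 1L
  if (ka > kb) return(FALSE)
  ia <- chain_introns(a_ex)
  ib <- chain_introns(b_ex)
  if (strand == "+") {
    if (ka > 0L) {
      sub <- ib[(kb - ka + 1L):kb, , drop = FALSE]
      if (any(abs(ia - sub) > tol$collapse_internal)) return(FALSE)
    }
    if (abs(a_ex[nrow(a_ex), 2L] - b_ex[nrow(b_ex), 2L]) > tol$collapse_3prime)
      return(FALSE)
    j <- nrow(b_ex) - ka  # B exon aligned with A's 5'-most exon
    abs(a_ex[1L, 1L] - b_ex[j, 1L]) <= tol$collapse_5prime
  } else {
    if (ka > 0L) {
      sub <- ib[seq_len(ka), , drop = FALSE]
      if (any(abs(ia - sub) > tol$collapse_internal)) return(FALSE)
    }
    if (abs(a_ex[1L, 1L] - b_ex[1L, 1L]) > tol$collapse_3prime)
      return(FALSE)
    j <- ka + 1L
    abs(a_ex[nrow(a_ex), 2L] - b_ex[j, 2L]) <= tol$collapse_5prime
  }
}

#' Collapse likely 5'-degradation products
#'
#' Within each locus, a model whose intron chain is a boundary-compatible
#' 3'-terminal subsequence of a longer model's chain (3' ends within
#' `collapse_3prime` bp, 5' end within `collapse_5prime` bp of its
#' projected position) is absorbed into the longer model, adding its
#' support. Candidates are visited fewest-introns-first so fragments meet
#' their longest superset first; when several absorbers qualify the
#' survivor is the one with most introns, then higher support, then
#' longer span, then smaller start. The procedure iterates to a fixed
#' point, so the output contains no absorbable pair.
#'
#' @param models A model table with `locus_id` assigned.
#' @param tol A [tolerance_set()].
#' @return The collapsed model table (absorbed support accumulated).
#' @export
collapse_models <- function(models, tol = tolerance_set()) {
  if (is.null(models$locus_id) || anyNA(models$locus_id))
    stop("assign_loci() must run before collapse_models()")
  keep_rows <- logical(nrow(models))
  support <- models$support
  for (loc in split(seq_len(nrow(models)), models$locus_id)) {
    alive <- rep(TRUE, length(loc))
    n_int <- vapply(loc, function(i) nrow(models$exons[[i]]) - 1L, integer(1L))
    span <- vapply(loc, function(i) {
      ex <- models$exons[[i]]; ex[nrow(ex), 2L] - ex[1L, 1L]
    }, integer(1L))
    starts <- vapply(loc, function(i) models$exons[[i]][1L, 1L], integer(1L))
    strand <- models$strand[loc[1L]]
    repeat {
      changed <- FALSE
      for (ai in order(n_int, support[loc])) {
        if (!alive[ai]) next
        cand <- which(alive & seq_along(loc) != ai)
        cand <- cand[vapply(cand, function(bi)
          can_absorb(models$exons[[loc[ai]]], models$exons[[loc[bi]]],
                     strand, tol), logical(1L))]
        if (length(cand) == 0L) next
        o <- order(-n_int[cand], -support[loc[cand]], -span[cand], starts[cand])
        bi <- cand[o[1L]]
        support[loc[bi]] <- support[loc[bi]] + support[loc[ai]]
        alive[ai] <- FALSE
        changed <- TRUE
      }
      if (!changed) break
    }
    keep_rows[loc[alive]] <- TRUE
  }
  out <- models[keep_rows, , drop = FALSE]
  out$support <- support[keep_rows]
  rownames(out) <- NULL
  out
}

#' Build transcript models from aligned reads
#'
#' Runs the full construction stage: intron-chain clustering of reads,
#' coordinate consensus per cluster, locus assignment by 3' end, and
#' degradation-aware collapse, then re-derives locus ids for the
#' surviving models.
#'
#' @param reads A [read_set()].
#' @param tol A [tolerance_set()].
#' @return A model table with columns `model_id`, `chrom`, `strand`,
#'   `support`, `is_single_exon`, `locus_id` and the `exons` list column.
#'   Attribute `stats` carries cluster/collapse counts.
#' @export
build_transcript_models <- function(reads, tol = tolerance_set()) {
  clusters <- cluster_alignments(reads, tol)
  if (length(clusters) == 0L) stop("no cluster reached the minimum size")
  models <- consensus_models(clusters)
  models <- assign_loci(models, tol)
  n_pre <- nrow(models)
  models <- collapse_models(models, tol)
  models <- assign_loci(models, tol)
  attr(models, "stats") <- list(
    reads_in = nrow(reads),
    clusters_emitted = attr(clusters, "n_emitted"),
    clusters_discarded = attr(clusters, "n_discarded_clusters"),
    reads_discarded = attr(clusters, "n_discarded_reads"),
    models_pre_collapse = n_pre,
    models_post_collapse = nrow(models)
  )
  models
}
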