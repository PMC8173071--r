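#' Enumerate local alternative-splicing events per locus
#'
#' Pairwise comparison of the transcripts of each locus under the
#' standard local-event definitions:
#'
#' * `SE` (skipped exon): an internal exon of one transcript whose two
#'   flanking junctions are joined into a single intron of another.
#' * `RI` (retained intron): an intron of one transcript contained in an
#'   exon of another whose outer boundaries match the flanking exons.
#' * `A5`/`A3` (alternative 5'/3' splice site): two introns sharing one
#'   boundary and differing at the other, with the variable stretch fully
#'   exonic in the transcript carrying the shorter intron; the 5'/3'
#'   label is assigned strand-aware.
#' * `MX` (mutually exclusive exons): two non-overlapping internal exons,
#'   each used by only one transcript, with shared outer flanking
#'   junction boundaries.
#' * `AF`/`AL` (alternative first/last exon): distinct, non-overlapping
#'   first (last) exons with distinct inner junction sites whose inner
#'   junctions join the same downstream (upstream) exon boundary.
#'
#' Events are deduplicated on their coordinate tuple within
#' (locus, type).
#'
#' @param models A model table with `locus_id` (or a [transcript_set()]
#'   with `gene_id` used as the locus key).
#' @return A data.frame: `event_type`, `locus_id`, `chrom`, `strand`,
#'   `coords` (comma-separated defining boundaries), `inclusion_tx`,
#'   `exclusion_tx`. `attr(,"type_counts")` tabulates the seven types.
#' @export
enumerate_events <- function(models) {
  ids <- if (!is.null(models$model_id)) models$model_id else models$transcript_id
  locus <- if (!is.null(models$locus_id)) models$locus_id else models$gene_id
  rows <- list()
  for (loc in split(seq_len(nrow(models)), locus)) {
    if (length(loc) < 2L) next
    strand <- models$strand[loc[1L]]
    chrom <- models$chrom[loc[1L]]
    for (i in loc) for (j in loc) {
      if (i == j) next
      rows <- c(rows, pair_events(models$exons[[i]], models$exons[[j]],
                                  ids[i], ids[j], chrom, strand,
                                  locus[loc[1L]]))
    }
  }
  ev <- if (length(rows) == 0L) {
    data.frame(event_type = character(), locus_id = character(),
               chrom = character(), strand = character(),
               coords = character(), inclusion_tx = character(),
               exclusion_tx = character(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  ev <- ev[!duplicated(ev[, c("event_type", "locus_id", "coords")]), ,
           drop = FALSE]
  rownames(ev) <- NULL
  attr(ev, "type_counts") <- table(
    factor(ev$event_type, c("SE", "MX", "RI", "A5", "A3", "AF", "AL")))
  ev
}

event_row <- function(type, locus, chrom, strand, coords, inc, exc) {
  data.frame(event_type = type, locus_id = locus, chrom = chrom,
             strand = strand, coords = paste(coords, collapse = ","),
             inclusion_tx = inc, exclusion_tx = exc,
             stringsAsFactors = FALSE)
}

# Events where t1 carries the inclusion form and t2 the exclusion form
# (SE, RI, MX) or where the pair is ordered (A5/A3/AF/AL handled with
# i<j ordering by coordinate canonicalization through dedup).
pair_events <- function(ex1, ex2, id1, id2, chrom, strand, locus) {
  out <- list()
  i1 <- chain_introns(ex1)
  i2 <- chain_introns(ex2)
  n1 <- nrow(ex1); n2 <- nrow(ex2)

  # SE: internal exon of t1 skipped in t2.
  if (n1 >= 3L && nrow(i2) > 0L) {
    for (e in 2L:(n1 - 1L)) {
      p <- i1[e - 1L, ]; q <- i1[e, ]
      if (any(i2[, 1L] == p[1L] & i2[, 2L] == q[2L]))
        out <- c(out, list(event_row("SE", locus, chrom, strand,
                                     c(p[1L], p[2L], q[1L], q[2L]),
                                     id1, id2)))
    }
  }

  # RI: intron of t2 retained inside an exon of t1 with shared outer
  # boundaries (t1 carries the inclusion/retention form).
  if (nrow(i2) > 0L) {
    for (k in seq_len(nrow(i2))) {
      a <- ex2[k, 1L]; s <- i2[k, 1L]; e <- i2[k, 2L]; b <- ex2[k + 1L, 2L]
      if (any(ex1[, 1L] == a & ex1[, 2L] == b))
        out <- c(out, list(event_row("RI", locus, chrom, strand,
                                     c(a, s, e, b), id1, id2)))
    }
  }

  # A5/A3: introns sharing exactly one boundary, variable stretch exonic
  # in the shorter-intron transcript.
  if (nrow(i1) > 0L && nrow(i2) > 0L) {
    for (k in seq_len(nrow(i1))) for (l in seq_len(nrow(i2))) {
      a <- i1[k, ]; b <- i2[l, ]
      if (a[1L] == b[1L] && a[2L] != b[2L]) {
        # shared left boundary; ensure [min_end, max_end) exonic in the
        # transcript whose intron ends first
        if (a[2L] < b[2L]) {
          exonic <- ex1[k + 1L, 1L] == a[2L] && ex1[k + 1L, 2L] >= b[2L]
        } else {
          exonic <- ex2[l + 1L, 1L] == b[2L] && ex2[l + 1L, 2L] >= a[2L]
        }
        if (exonic) {
          type <- if (strand == "+") "A3" else "A5"
          out <- c(out, list(event_row(type, locus, chrom, strand,
                                       c(a[1L], min(a[2L], b[2L]),
                                         max(a[2L], b[2L])), id1, id2)))
        }
      } else if (a[2L] == b[2L] && a[1L] != b[1L]) {
        if (a[1L] > b[1L]) {
          exonic <- ex1[k, 2L] == a[1L] && ex1[k, 1L] <= b[1L]
        } else {
          exonic <- ex2[l, 2L] == b[1L] && ex2[l, 1L] <= a[1L]
        }
        if (exonic) {
          type <- if (strand == "+") "A5" else "A3"
          out <- c(out, list(event_row(type, locus, chrom, strand,
                                       c(min(a[1L], b[1L]),
                                         max(a[1L], b[1L]), a[2L]),
                                       id1, id2)))
        }
      }
    }
  }

  # MX: internal exon e1 of t1 and e2 of t2, non-overlapping, shared
  # outer flanking junction boundaries, mutually exclusive.
  if (n1 >= 3L && n2 >= 3L) {
    for (e in 2L:(n1 - 1L)) for (f in 2L:(n2 - 1L)) {
      if (ex1[e, 2L] > ex2[f, 1L]) next  # require e1 strictly left of e2
      if (i1[e - 1L, 1L] == i2[f - 1L, 1L] &&   # shared upstream donor
          i1[e, 2L] == i2[f, 2L] &&             # shared downstream acceptor
          !any(ex2[, 1L] == ex1[e, 1L] & ex2[, 2L] == ex1[e, 2L]) &&
          !any(ex1[, 1L] == ex2[f, 1L] & ex1[, 2L] == ex2[f, 2L])) {
        out <- c(out, list(event_row("MX", locus, chrom, strand,
                                     c(i1[e - 1L, 1L], ex1[e, 1L], ex1[e, 2L],
                                       ex2[f, 1L], ex2[f, 2L], i1[e, 2L]),
                                     id1, id2)))
      }
    }
  }

  # AF/AL on genomic-leftmost first exons: distinct non-overlapping first
  # exons, distinct inner junction sites, same downstream acceptor.
  if (nrow(i1) > 0L && nrow(i2) > 0L) {
    f1 <- ex1[1L, ]; f2 <- ex2[1L, ]
    if (!(f1[1L] == f2[1L] && f1[2L] == f2[2L]) &&
        (f1[2L] <= f2[1L] || f2[2L] <= f1[1L]) &&  # non-overlapping
        f1[2L] != f2[2L] &&                         # distinct inner junctions
        i1[1L, 2L] == i2[1L, 2L]) {                 # same downstream partner
      type <- if (strand == "+") "AF" else "AL"
      lo <- if (f1[1L] < f2[1L]) list(f1, f2) else list(f2, f1)
      out <- c(out, list(event_row(type, locus, chrom, strand,
                                   c(lo[[1L]][1L], lo[[1L]][2L],
                                     lo[[2L]][1L], lo[[2L]][2L], i1[1L, 2L]),
                                   id1, id2)))
    }
    l1 <- ex1[n1, ]; l2 <- ex2[n2, ]
    if (!(l1[1L] == l2[1L] && l1[2L] == l2[2L]) &&
        (l1[2L] <= l2[1L] || l2[2L] <= l1[1L]) &&
        l1[1L] != l2[1L] &&
        i1[nrow(i1), 1L] == i2[nrow(i2), 1L]) {     # same upstream partner
      type <- if (strand == "+") "AL" else "AF"
      lo <- if (l1[1L] < l2[1L]) list(l1, l2) else list(l2, l1)
      out <- c(out, list(event_row(type, locus, chrom, strand,
                                   c(i1[nrow(i1), 1L], lo[[1L]][1L],
                                     lo[[1L]][2L], lo[[2L]][1L],
                                     lo[[2L]][2L]), id1, id2)))
    }
  }
  out
}
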