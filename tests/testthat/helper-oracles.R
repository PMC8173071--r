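# Independent brute-force oracles. These deliberately use different
# representations from the package code (base sets, pairwise counts,
# coordinate flipping) so that agreement is a genuine cross-check.

# --- collapse oracle ---------------------------------------------------

# Orient a chain 5'->3' by negating coordinates on the minus strand.
.orient <- function(ex, strand) {
  if (strand == "+") return(ex)
  m <- cbind(rev(-ex[, 2]), rev(-ex[, 1]))
  colnames(m) <- c("start", "end")
  m
}

.oracle_absorbable <- function(a_ex, b_ex, strand, tol) {
  a <- .orient(a_ex, strand); b <- .orient(b_ex, strand)
  ka <- nrow(a) - 1; kb <- nrow(b) - 1
  if (ka > kb) return(FALSE)
  if (ka > 0) {
    ai <- cbind(a[-nrow(a), 2], a[-1, 1])
    bi <- cbind(b[-nrow(b), 2], b[-1, 1])
    tail_b <- bi[(kb - ka + 1):kb, , drop = FALSE]
    if (max(abs(ai - tail_b)) > tol$collapse_internal) return(FALSE)
  }
  if (abs(a[nrow(a), 2] - b[nrow(b), 2]) > tol$collapse_3prime) return(FALSE)
  j <- nrow(b) - ka
  abs(a[1, 1] - b[j, 1]) <= tol$collapse_5prime
}

# Exhaustive absorption to fixed point with the same survivor preference
# (most introns, higher support, longer span, smaller start).
oracle_collapse <- function(models, tol) {
  alive <- rep(TRUE, nrow(models))
  support <- models$support
  repeat {
    did <- FALSE
    n_int <- vapply(models$exons, nrow, integer(1)) - 1
    for (a in order(n_int, support)) {
      if (!alive[a]) next
      best <- NULL
      for (b in which(alive)) {
        if (a == b) next
        if (models$locus_id[a] != models$locus_id[b]) next
        if (.oracle_absorbable(models$exons[[a]], models$exons[[b]],
                               models$strand[a], tol)) {
          if (is.null(best)) best <- b
          else {
            sp <- function(i) {
              e <- models$exons[[i]]; c(n_int[i], support[i],
                                        e[nrow(e), 2] - e[1, 1], -e[1, 1])
            }
            cb <- sp(b); cbest <- sp(best)
            for (k in 1:4) {
              if (cb[k] > cbest[k]) { best <- b; break }
              if (cb[k] < cbest[k]) break
            }
          }
        }
      }
      if (!is.null(best)) {
        support[best] <- support[best] + support[a]
        alive[a] <- FALSE
        did <- TRUE
      }
    }
    if (!did) break
  }
  out <- models[alive, , drop = FALSE]
  out$support <- support[alive]
  rownames(out) <- NULL
  out
}

# --- class-code oracle (base-set arithmetic) ---------------------------

.bases <- function(ex) unlist(lapply(seq_len(nrow(ex)),
                                     function(i) (ex[i, 1] + 1):ex[i, 2]))
.introns_of <- function(ex) {
  if (nrow(ex) < 2) return(matrix(numeric(), ncol = 2))
  cbind(ex[-nrow(ex), 2], ex[-1, 1])
}

# Code of query against a single reference transcript, or NA.
.oracle_pair_code <- function(q, r) {
  qe <- q$exons[[1]]; re <- r$exons[[1]]
  if (q$chrom != r$chrom) return(NA_character_)
  q_span <- c(qe[1, 1], qe[nrow(qe), 2])
  r_span <- c(re[1, 1], re[nrow(re), 2])
  if (q_span[1] >= r_span[2] || q_span[2] <= r_span[1]) return(NA_character_)
  qb <- .bases(qe); rb <- .bases(re)
  qi <- .introns_of(qe); ri <- .introns_of(re)
  exon_ov <- length(intersect(qb, rb)) > 0
  same <- q$strand == r$strand
  if (!same) return(if (exon_ov) "x" else "s")
  if (exon_ov) {
    if (nrow(qi) > 0 && nrow(ri) > 0 && nrow(qi) == nrow(ri) &&
        all(qi == ri)) return("=")
    if (nrow(qi) == 0 && nrow(ri) == 0) return("=")
    if (nrow(qi) == 0) {
      if (any(re[, 1] <= qe[1, 1] & qe[1, 2] <= re[, 2])) return("c")
      intr_bases <- setdiff((r_span[1] + 1):r_span[2], rb)
      if (all(unlist(lapply(seq_len(nrow(ri)), function(k)
        all((ri[k, 1] + 1):ri[k, 2] %in% qb))))) return("m")
      if (length(intersect(qb, intr_bases)) >= 10) return("e")
      return("o")
    }
    if (nrow(ri) > 0) {
      retained <- vapply(seq_len(nrow(ri)), function(k)
        all((ri[k, 1] + 1):ri[k, 2] %in% qb), logical(1))
      matched <- vapply(seq_len(nrow(ri)), function(k)
        any(qi[, 1] == ri[k, 1] & qi[, 2] == ri[k, 2]), logical(1))
      if (!any(retained) && .is_sub(qi, ri)) return("c")
      if (.is_sub(ri, qi)) return("k")
      if (all(retained)) return("m")
      if (any(retained) && all(retained | matched)) return("n")
      if (any(matched)) return("j")
      return("o")
    }
    return("o")
  }
  if (nrow(ri) > 0 &&
      any(ri[, 1] <= q_span[1] & q_span[2] <= ri[, 2])) return("i")
  if (nrow(qi) > 0 &&
      any(qi[, 1] <= r_span[1] & r_span[2] <= qi[, 2])) return("y")
  NA_character_
}

.is_sub <- function(sub, full) {
  ks <- nrow(sub); kf <- nrow(full)
  if (ks == 0 || ks > kf) return(FALSE)
  any(vapply(0:(kf - ks), function(off)
    all(sub == full[(off + 1):(off + ks), , drop = FALSE]), logical(1)))
}

oracle_class_code <- function(model, annotation) {
  prec <- c("=", "c", "k", "m", "n", "j", "e", "o",
            "i", "y", "x", "p", "s", "u")
  codes <- vapply(seq_len(nrow(annotation)), function(ri)
    .oracle_pair_code(list(chrom = model$chrom, strand = model$strand,
                           exons = model$exons),
                      list(chrom = annotation$chrom[ri],
                           strand = annotation$strand[ri],
                           exons = annotation$exons[ri])), character(1))
  shared <- vapply(seq_len(nrow(annotation)), function(ri) {
    qi <- .introns_of(model$exons[[1]])
    ri_ <- .introns_of(annotation$exons[[ri]])
    if (nrow(qi) == 0 || nrow(ri_) == 0) return(0L)
    sum(vapply(seq_len(nrow(qi)), function(k)
      any(ri_[, 1] == qi[k, 1] & ri_[, 2] == qi[k, 2]), logical(1)))
  }, integer(1))
  ov <- vapply(seq_len(nrow(annotation)), function(ri) {
    if (model$chrom != annotation$chrom[ri]) return(0L)
    length(intersect(.bases(model$exons[[1]]),
                     .bases(annotation$exons[[ri]])))
  }, integer(1))
  hit <- which(!is.na(codes))
  if (length(hit) > 0) {
    best <- hit[order(match(codes[hit], prec), -shared[hit], -ov[hit])][1]
    return(codes[best])
  }
  # run-on: entirely within 2 kb downstream of a same-strand ref 3' end
  qe <- model$exons[[1]]
  qs <- qe[1, 1]; qq <- qe[nrow(qe), 2]
  for (ri in seq_len(nrow(annotation))) {
    if (annotation$chrom[ri] != model$chrom ||
        annotation$strand[ri] != model$strand) next
    re <- annotation$exons[[ri]]
    if (model$strand == "+") {
      if (qs >= re[nrow(re), 2] && qs - re[nrow(re), 2] <= 2000) return("p")
    } else {
      if (qq <= re[1, 1] && re[1, 1] - qq <= 2000) return("p")
    }
  }
  "u"
}

# --- nearest distance oracle -------------------------------------------

oracle_nearest <- function(intervals, genes) {
  vapply(seq_len(nrow(intervals)), function(i) {
    g <- genes[genes$chrom == intervals$chrom[i], , drop = FALSE]
    if (nrow(g) == 0) return(NA_real_)
    min(vapply(seq_len(nrow(g)), function(j) {
      if (intervals$start[i] < g$end[j] && intervals$end[i] > g$start[j])
        return(0)
      max(g$start[j] - intervals$end[i], intervals$start[i] - g$end[j])
    }, numeric(1)))
  }, numeric(1))
}

# --- rank-sum oracles --------------------------------------------------

# U counted from pairwise comparisons instead of rank sums.
oracle_u <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# Exact two-sided p by enumerating all group labelings, with U from
# pairwise counts.
oracle_exact_p <- function(x, y) {
  v <- c(x, y)
  n1 <- length(x)
  obs <- oracle_u(x, y)
  combos <- combn(length(v), n1)
  us <- apply(combos, 2, function(idx) oracle_u(v[idx], v[-idx]))
  min(1, 2 * min(mean(us <= obs), mean(us >= obs)))
}

# --- EM long-run oracle ------------------------------------------------

# Dense-matrix EM run far past convergence.
oracle_em <- function(compat_sets, n_iter = 1000) {
  models <- sort(unique(unlist(compat_sets)))
  A <- t(vapply(compat_sets, function(s) models %in% s,
                logical(length(models))))
  A <- matrix(A, nrow = length(compat_sets))
  p <- rep(1 / length(models), length(models))
  for (it in seq_len(n_iter)) {
    W <- sweep(A * 1, 2, p, "*")
    W <- W / rowSums(W)
    p <- colSums(W) / nrow(W)
  }
  names(p) <- models
  p
}

# --- splicing event oracle ---------------------------------------------

# Exhaustive event detection over all transcript pairs of one locus,
# organized feature-first (every exon/intron pair tested against every
# definition), returning a canonical set of "type:coords" strings.
oracle_events <- function(models) {
  keys <- character(0)
  ids <- seq_len(nrow(models))
  locus <- if (!is.null(models$locus_id)) models$locus_id else models$gene_id
  for (loc in split(ids, locus)) {
    if (length(loc) < 2) next
    strand <- models$strand[loc[1]]
    exsets <- lapply(loc, function(i) models$exons[[i]])
    insets <- lapply(exsets, .introns_of)
    for (p1 in seq_along(loc)) for (p2 in seq_along(loc)) {
      if (p1 == p2) next
      ex1 <- exsets[[p1]]; ex2 <- exsets[[p2]]
      i1 <- insets[[p1]]; i2 <- insets[[p2]]
      # SE
      if (nrow(ex1) >= 3 && nrow(i2) > 0)
        for (e in 2:(nrow(ex1) - 1))
          if (any(i2[, 1] == i1[e - 1, 1] & i2[, 2] == i1[e, 2]))
            keys <- c(keys, paste0("SE:", paste(
              c(i1[e - 1, ], i1[e, ]), collapse = ",")))
      # RI
      if (nrow(i2) > 0)
        for (k in seq_len(nrow(i2)))
          if (any(ex1[, 1] == ex2[k, 1] & ex1[, 2] == ex2[k + 1, 2]))
            keys <- c(keys, paste0("RI:", paste(
              c(ex2[k, 1], i2[k, ], ex2[k + 1, 2]), collapse = ",")))
      # A5/A3
      if (nrow(i1) > 0 && nrow(i2) > 0)
        for (k in seq_len(nrow(i1))) for (l in seq_len(nrow(i2))) {
          a <- i1[k, ]; b <- i2[l, ]
          if (a[1] == b[1] && a[2] != b[2]) {
            short_ex <- if (a[2] < b[2]) ex1[k + 1, ] else ex2[l + 1, ]
            hi <- max(a[2], b[2])
            if (short_ex[2] >= hi)
              keys <- c(keys, paste0(if (strand == "+") "A3:" else "A5:",
                                     paste(c(a[1], min(a[2], b[2]), hi),
                                           collapse = ",")))
          }
          if (a[2] == b[2] && a[1] != b[1]) {
            short_ex <- if (a[1] > b[1]) ex1[k, ] else ex2[l, ]
            lo <- min(a[1], b[1])
            if (short_ex[1] <= lo)
              keys <- c(keys, paste0(if (strand == "+") "A5:" else "A3:",
                                     paste(c(lo, max(a[1], b[1]), a[2]),
                                           collapse = ",")))
          }
        }
      # MX
      if (nrow(ex1) >= 3 && nrow(ex2) >= 3)
        for (e in 2:(nrow(ex1) - 1)) for (f in 2:(nrow(ex2) - 1))
          if (ex1[e, 2] <= ex2[f, 1] &&
              i1[e - 1, 1] == i2[f - 1, 1] && i1[e, 2] == i2[f, 2] &&
              !any(ex2[, 1] == ex1[e, 1] & ex2[, 2] == ex1[e, 2]) &&
              !any(ex1[, 1] == ex2[f, 1] & ex1[, 2] == ex2[f, 2]))
            keys <- c(keys, paste0("MX:", paste(
              c(i1[e - 1, 1], ex1[e, ], ex2[f, ], i1[e, 2]), collapse = ",")))
      # AF/AL (leftmost and rightmost)
      if (nrow(i1) > 0 && nrow(i2) > 0) {
        f1 <- ex1[1, ]; f2 <- ex2[1, ]
        if (!all(f1 == f2) && (f1[2] <= f2[1] || f2[2] <= f1[1]) &&
            f1[2] != f2[2] && i1[1, 2] == i2[1, 2]) {
          pair <- if (f1[1] < f2[1]) c(f1, f2) else c(f2, f1)
          keys <- c(keys, paste0(if (strand == "+") "AF:" else "AL:",
                                 paste(c(pair, i1[1, 2]), collapse = ",")))
        }
        l1 <- ex1[nrow(ex1), ]; l2 <- ex2[nrow(ex2), ]
        if (!all(l1 == l2) && (l1[2] <= l2[1] || l2[2] <= l1[1]) &&
            l1[1] != l2[1] && i1[nrow(i1), 1] == i2[nrow(i2), 1]) {
          pair <- if (l1[1] < l2[1]) c(l1, l2) else c(l2, l1)
          keys <- c(keys, paste0(if (strand == "+") "AL:" else "AF:",
                                 paste(c(i1[nrow(i1), 1], pair),
                                       collapse = ",")))
        }
      }
    }
  }
  sort(unique(keys))
}
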