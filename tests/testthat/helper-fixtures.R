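# Small builders used across test files.

mk_tx <- function(id, starts, ends, chrom = "chr1", strand = "+",
                  gene = "g1", biotype = "protein_coding") {
  transcript_set(id, gene, chrom, strand,
                 list(exon_chain(starts, ends)), biotype)
}

mk_txs <- function(...) {
  parts <- list(...)
  out <- do.call(rbind, parts)
  class(out) <- c("transcript_set", "data.frame")
  out
}

mk_read <- function(id, starts, ends, sample = "s1", chrom = "chr1",
                    strand = "+") {
  read_set(id, sample, chrom, strand, list(exon_chain(starts, ends)))
}

mk_reads <- function(...) {
  out <- do.call(rbind, list(...))
  class(out) <- c("read_set", "data.frame")
  out
}

# n jittered copies of an exon chain as a read_set (integer jitter on
# every boundary, clamped to keep ordering).
jittered_reads <- function(exons, n, sd, clamp = Inf, chrom = "chr1",
                           strand = "+", sample = "s1", prefix = "r") {
  reads <- lapply(seq_len(n), function(i) {
    j <- pmin(pmax(round(rnorm(length(exons), 0, sd)), -clamp), clamp)
    b <- as.vector(t(exons)) + j
    for (k in 2:length(b)) if (b[k] <= b[k - 1]) b[k] <- b[k - 1] + 1
    matrix(as.integer(b), ncol = 2, byrow = TRUE)
  })
  read_set(paste0(prefix, seq_len(n)), sample, chrom, strand, reads)
}

# A random multi-exon chain on [0, span).
random_chain <- function(n_exons, exon_len = c(50, 200),
                         intron_len = c(60, 500), origin = 0L) {
  e <- sample(exon_len[1]:exon_len[2], n_exons, replace = TRUE)
  i <- sample(intron_len[1]:intron_len[2], max(0, n_exons - 1), replace = TRUE)
  starts <- cumsum(c(origin, (e + c(i, 0))[-n_exons]))
  exon_chain(starts, starts + e)
}
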