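#' Simulation configuration
#'
#' Defaults describe a desk-scale multi-tissue full-length cDNA
#' experiment: 20 multi-isoform genes over two synthetic chromosomes,
#' 5 tissues x 2 replicates, roughly 20,000 reads, a mean read length
#' near 759 bases, 30% of reads 5'-truncated by degradation,
#' sub-base-pair splice-boundary jitter (most junctions align exactly,
#' occasional 1-2 bp wobble), and intronic/intergenic single-exon noise
#' reads. A tenth of the transcripts are withheld from the public
#' reference as novel isoforms and a tenth of the genes as novel loci.
#'
#' @param n_genes Number of genes.
#' @param isoform_probs Probability of 1, 2, ... isoforms per gene.
#' @param single_exon_gene_fraction Fraction of genes that are
#'   single-exon.
#' @param exon_count_range Exon counts (uniform) for multi-exon genes.
#' @param exon_len_meanlog,exon_len_sdlog,intron_len_meanlog,intron_len_sdlog
#'   Log-normal length parameters (bp).
#' @param n_tissues,replicates_per_tissue Sample layout.
#' @param tissue_specific_fraction Fraction of transcripts expressed in
#'   exactly one tissue (the rest are expressed in all tissues).
#' @param expr_meanlog,expr_sdlog Log-normal per-transcript mean read
#'   count per expressed sample.
#' @param nb_dispersion Negative-binomial size for per-replicate counts.
#' @param truncation_prob Per-read probability of 5' degradation.
#' @param truncation_mean Mean of the geometric base loss (transcript
#'   coordinates).
#' @param jitter_sd SD (bp) of the discretized Gaussian splice-boundary
#'   jitter.
#' @param end_jitter_sd SD (bp) of terminal-end jitter.
#' @param noise_read_rate Intergenic/intronic single-exon noise reads
#'   per genic read.
#' @param noise_len_meanlog,noise_len_sdlog Noise read lengths.
#' @param novel_isoform_fraction Fraction of transcripts withheld from
#'   the public reference as novel isoforms.
#' @param novel_locus_fraction Fraction of genes withheld entirely.
#' @param protein_coding_fraction Fraction of genes with biotype
#'   `protein_coding` (the rest are `lncRNA`).
#' @param intergenic_gap_range Gap (bp) between consecutive genes.
#' @param n_chroms Number of synthetic chromosomes.
#' @param min_read_length Reads are never truncated below this length.
#' @param seed Integer seed; fully determines all outputs.
#' @return A named list with class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 20L,
                              isoform_probs = c(0.3, 0.4, 0.3),
                              single_exon_gene_fraction = 0.15,
                              exon_count_range = 3:8,
                              exon_len_meanlog = log(120),
                              exon_len_sdlog = 0.35,
                              intron_len_meanlog = log(800),
                              intron_len_sdlog = 0.5,
                              n_tissues = 5L,
                              replicates_per_tissue = 2L,
                              tissue_specific_fraction = 0.3,
                              expr_meanlog = log(60),
                              expr_sdlog = 0.5,
                              nb_dispersion = 20,
                              truncation_prob = 0.3,
                              truncation_mean = 250,
                              jitter_sd = 0.5,
                              end_jitter_sd = 8,
                              noise_read_rate = 0.02,
                              noise_len_meanlog = log(300),
                              noise_len_sdlog = 0.4,
                              novel_isoform_fraction = 0.1,
                              novel_locus_fraction = 0.1,
                              protein_coding_fraction = 0.7,
                              intergenic_gap_range = c(10000L, 20000L),
                              n_chroms = 2L,
                              min_read_length = 60L,
                              seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_tissues >= 2L, abs(sum(cfg$isoform_probs) - 1) < 1e-9,
            cfg$tissue_specific_fraction >= 0, cfg$tissue_specific_fraction <= 1,
            cfg$novel_isoform_fraction >= 0, cfg$novel_isoform_fraction <= 1,
            cfg$novel_locus_fraction >= 0, cfg$novel_locus_fraction <= 1)
  class(cfg) <- "simulation_config"
  cfg
}

# One gene structure at origin 0: master exon chain plus isoform variants
# with distinct intron chains. Variants are chosen so that no isoform's
# chain is a 3'-terminal subsequence of a sibling's: such a pair is, by
# design of the collapse stage, indistinguishable from a degradation
# product and would never be separately recoverable.
simulate_gene_isoforms <- function(cfg, n_iso, single_exon) {
  if (single_exon) {
    len <- max(200L, round(stats::rlnorm(1, log(500), 0.3)))
    return(list(exon_chain(0L, len)))
  }
  n_ex <- sample(cfg$exon_count_range, 1L)
  e_len <- pmax(30L, round(stats::rlnorm(n_ex, cfg$exon_len_meanlog,
                                         cfg$exon_len_sdlog)))
  i_len <- pmax(60L, round(stats::rlnorm(n_ex - 1L, cfg$intron_len_meanlog,
                                         cfg$intron_len_sdlog)))
  starts <- cumsum(c(0L, (e_len + c(i_len, 0L))[-n_ex]))
  master <- exon_chain(starts, starts + e_len)
  isos <- list(master)
  kinds <- c("SE", "A3", "RI", "AF")
  guard <- 0L
  while (length(isos) < n_iso && guard < 50L) {
    guard <- guard + 1L
    kind <- sample(kinds, 1L)
    pick <- function(v) v[sample.int(length(v), 1L)]
    cand <- switch(
      kind,
      SE = if (n_ex >= 4L) master[-pick(2:(n_ex - 1L)), , drop = FALSE],
      A3 = {  # shift an acceptor into the following exon; the shift
        # exceeds the 20 bp clustering tolerance so the variant is
        # separable from its sibling by the method at all
        k <- pick(seq_len(n_ex - 1L))
        d <- pick(25:60)
        m <- master
        if (m[k + 1L, 2L] - (m[k + 1L, 1L] + d) >= 30L) {
          m[k + 1L, 1L] <- m[k + 1L, 1L] + d
          m
        }
      },
      RI = if (n_ex >= 4L) {
        # never retain a terminal intron: on either strand the resulting
        # chain would be a 3'-suffix of the master's and collapse-ambiguous
        k <- pick(2:(n_ex - 2L))
        m <- master
        m[k, 2L] <- m[k + 1L, 2L]
        m[-(k + 1L), , drop = FALSE]
      },
      AF = {  # alternative leftmost exon, non-overlapping, same acceptor
        gap <- pick(200:600)
        len <- max(40L, round(stats::rlnorm(1, cfg$exon_len_meanlog,
                                            cfg$exon_len_sdlog)))
        m <- master
        m[1L, 2L] <- m[1L, 1L] - gap
        m[1L, 1L] <- m[1L, 2L] - len
        m
      }
    )
    if (is.null(cand)) next
    storage.mode(cand) <- "integer"
    if (separable(cand, isos)) isos[[length(isos) + 1L]] <- cand
  }
  isos
}

# A candidate isoform is accepted only if every sibling with the same
# intron count differs by more than 30 bp at some corresponding intron
# boundary: chains closer than that are inside the mutual capture range
# of the 20 bp clustering tolerance (plus jitter) and could never be
# resolved into separate models by the method under study.
separable <- function(cand, isos) {
  cb <- intron_boundaries(cand)
  for (iso in isos) {
    ib <- intron_boundaries(iso)
    if (length(ib) != length(cb)) next
    if (length(cb) == 0L || max(abs(cb - ib)) <= 30L) return(FALSE)
  }
  TRUE
}

#' Simulate the ground-truth annotation and its public reference
#'
#' Generates non-overlapping genes on a small set of synthetic
#' chromosomes, each with one or more isoforms sharing exons, then
#' withholds the planned fraction of transcripts (novel isoforms; their
#' gene keeps at least one isoform) and of whole genes (novel loci) from
#' the public reference. Each transcript is also assigned a designed
#' specificity label (expressed in exactly one tissue, or in all) and a
#' per-tissue mean read count.
#'
#' @param cfg A [simulation_config()].
#' @return A list: `truth` (full [transcript_set()] with a `truth`
#'   data.frame of per-transcript labels), `reference` (public
#'   [transcript_set()]), `genome` (named chromosome lengths), `samples`
#'   (sample sheet), `gene_spans`.
#' @export
simulate_annotation <- function(cfg = simulation_config()) {
  set.seed(cfg$seed)
  n_iso <- sample(seq_along(cfg$isoform_probs), cfg$n_genes,
                  replace = TRUE, prob = cfg$isoform_probs)
  single <- stats::runif(cfg$n_genes) < cfg$single_exon_gene_fraction
  n_iso[single] <- 1L
  structs <- lapply(seq_len(cfg$n_genes), function(g)
    simulate_gene_isoforms(cfg, n_iso[g], single[g]))
  strands <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  biotypes <- ifelse(stats::runif(cfg$n_genes) < cfg$protein_coding_fraction,
                     "protein_coding", "lncRNA")

  # Place genes round-robin over chromosomes with generous gaps so that
  # no gene lies within run-on distance (2 kb) of another.
  chrom_of <- paste0("chrS", 1 + (seq_len(cfg$n_genes) - 1L) %% cfg$n_chroms)
  offsets <- integer(cfg$n_genes)
  cursor <- stats::setNames(rep(0L, cfg$n_chroms),
                            paste0("chrS", seq_len(cfg$n_chroms)))
  for (g in seq_len(cfg$n_genes)) {
    gap <- sample(cfg$intergenic_gap_range[1L]:cfg$intergenic_gap_range[2L], 1L)
    span <- range(unlist(lapply(structs[[g]], range)))
    offsets[g] <- cursor[[chrom_of[g]]] + gap - span[1L]
    cursor[[chrom_of[g]]] <- offsets[g] + span[2L]
  }
  genome <- cursor + 10000L

  tx_rows <- list()
  for (g in seq_len(cfg$n_genes)) {
    for (k in seq_along(structs[[g]])) {
      ex <- structs[[g]][[k]]
      ex[, 1L] <- ex[, 1L] + offsets[g]
      ex[, 2L] <- ex[, 2L] + offsets[g]
      tx_rows[[length(tx_rows) + 1L]] <- list(
        transcript_id = sprintf("SIMT%02d.%d", g, k),
        gene_id = sprintf("SIMG%02d", g),
        chrom = chrom_of[g], strand = strands[g],
        biotype = biotypes[g], exons = ex)
    }
  }
  tx <- transcript_set(
    transcript_id = vapply(tx_rows, `[[`, character(1L), "transcript_id"),
    gene_id = vapply(tx_rows, `[[`, character(1L), "gene_id"),
    chrom = vapply(tx_rows, `[[`, character(1L), "chrom"),
    strand = vapply(tx_rows, `[[`, character(1L), "strand"),
    exons = lapply(tx_rows, `[[`, "exons"),
    biotype = vapply(tx_rows, `[[`, character(1L), "biotype"))

  # Novelty plan: whole genes first (novel loci), then additional
  # transcripts from multi-isoform genes (novel isoforms).
  n_tx <- nrow(tx)
  n_novel_gene <- round(cfg$novel_locus_fraction * cfg$n_genes)
  novel_genes <- if (n_novel_gene > 0L)
    sample(unique(tx$gene_id), n_novel_gene) else character()
  category <- ifelse(tx$gene_id %in% novel_genes, "novel_locus", "known")
  # keep each gene's first isoform in the reference
  first_iso <- !duplicated(tx$gene_id)
  eligible <- which(category == "known" & !first_iso)
  n_novel_iso <- min(length(eligible),
                     round(cfg$novel_isoform_fraction * n_tx))
  if (n_novel_iso > 0L)
    category[sample(eligible, n_novel_iso)] <- "novel_isoform"

  # Designed tissue specificity and expression.
  specific <- stats::runif(n_tx) < cfg$tissue_specific_fraction
  tissue_of <- ifelse(specific,
                      paste0("tissue", sample.int(cfg$n_tissues, n_tx,
                                                  replace = TRUE)),
                      NA_character_)
  mean_count <- stats::rlnorm(n_tx, cfg$expr_meanlog, cfg$expr_sdlog)
  tissues <- paste0("tissue", seq_len(cfg$n_tissues))
  tissue_mean <- matrix(0, n_tx, cfg$n_tissues,
                        dimnames = list(tx$transcript_id, tissues))
  for (i in seq_len(n_tx)) {
    if (specific[i]) tissue_mean[i, tissue_of[i]] <- mean_count[i]
    else tissue_mean[i, ] <- mean_count[i]
  }

  truth <- data.frame(
    transcript_id = tx$transcript_id,
    gene_id = tx$gene_id,
    category = category,
    specificity = ifelse(specific, "tissue_specific", "broad"),
    tissue = tissue_of,
    mean_count = mean_count,
    stringsAsFactors = FALSE)

  samples <- expand.grid(rep = seq_len(cfg$replicates_per_tissue),
                         tissue = tissues, stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = paste0(samples$tissue, "_r", samples$rep),
    tissue = samples$tissue,
    individual = paste0("ind", samples$rep),
    include_flag = TRUE, stringsAsFactors = FALSE)

  reference <- tx[truth$category == "known", , drop = FALSE]
  gene_spans <- do.call(rbind, lapply(split(seq_len(n_tx), tx$gene_id),
    function(ii) {
      sp <- range(unlist(lapply(tx$exons[ii], range)))
      data.frame(gene_id = tx$gene_id[ii[1L]], chrom = tx$chrom[ii[1L]],
                 start = sp[1L], end = sp[2L],
                 strand = tx$strand[ii[1L]], stringsAsFactors = FALSE)
    }))
  rownames(gene_spans) <- NULL

  list(truth = tx, truth_table = truth, tissue_means = tissue_mean,
       reference = reference, genome = genome, samples = samples,
       gene_spans = gene_spans)
}

# Remove `loss` 5' bases (transcript coordinates) from a chain.
truncate_chain_5p <- function(ex, strand, loss) {
  if (loss <= 0L) return(ex)
  lens <- ex[, 2L] - ex[, 1L]
  if (strand == "+") {
    cum <- cumsum(lens)
    drop <- which(cum <= loss)
    if (length(drop) > 0L) ex <- ex[-drop, , drop = FALSE]
    rem <- loss - if (length(drop) > 0L) cum[length(drop)] else 0L
    ex[1L, 1L] <- ex[1L, 1L] + rem
  } else {
    cum <- cumsum(rev(lens))
    drop_r <- which(cum <= loss)
    if (length(drop_r) > 0L)
      ex <- ex[seq_len(nrow(ex) - length(drop_r)), , drop = FALSE]
    rem <- loss - if (length(drop_r) > 0L) cum[length(drop_r)] else 0L
    ex[nrow(ex), 2L] <- ex[nrow(ex), 2L] - rem
  }
  ex
}

# Discretized Gaussian jitter of splice boundaries and terminal ends,
# clamped so every exon and intron keeps >= 1 bp and order is preserved.
jitter_chain <- function(ex, jitter_sd, end_jitter_sd) {
  b <- as.vector(t(ex))  # s1,e1,s2,e2,...
  n <- length(b)
  sd_vec <- c(end_jitter_sd, rep(jitter_sd, n - 2L), end_jitter_sd)
  if (n == 2L) sd_vec <- c(end_jitter_sd, end_jitter_sd)
  j <- round(stats::rnorm(n, 0, sd_vec))
  nb <- b + j
  # clamp left-to-right to preserve strict ordering
  for (i in 2L:n) if (nb[i] <= nb[i - 1L]) nb[i] <- nb[i - 1L] + 1L
  if (nb[1L] < 0L) nb[1L] <- 0L
  storage.mode(nb) <- "integer"
  matrix(nb, ncol = 2L, byrow = TRUE,
         dimnames = list(NULL, c("start", "end")))
}

#' Simulate aligned full-length reads
#'
#' For every transcript and sample, a negative-binomial read count is
#' drawn around the transcript's designed per-tissue mean. Each read
#' copies its transcript's exon chain; with probability
#' `truncation_prob` it loses a geometric number of 5' bases (whole
#' exons and/or part of the 5'-most exon), emulating RNA degradation;
#' every splice boundary is then perturbed by discretized Gaussian
#' jitter and the terminal ends by slightly larger jitter. Single-exon
#' noise reads are added at `noise_read_rate` per genic read, placed
#' uniformly outside gene spans.
#'
#' @param ann A [simulate_annotation()] result.
#' @param cfg The same [simulation_config()].
#' @return A list: `reads` (a [read_set()]) and `read_truth`
#'   (data.frame: `read_id`, `sample_id`, `transcript_id` (`NA` for
#'   noise), `truncated`).
#' @export
simulate_reads <- function(ann, cfg = simulation_config()) {
  set.seed(cfg$seed + 1000L)
  tx <- ann$truth
  tm <- ann$tissue_means
  samples <- ann$samples
  acc <- list()  # one accumulator entry per read, filled by index
  serial <- 0L
  for (i in seq_len(nrow(tx))) {
    ex0 <- tx$exons[[i]]
    tlen <- chain_len(ex0)
    if (tlen < cfg$min_read_length) {
      warning("transcript ", tx$transcript_id[i],
              " shorter than the minimum read length; skipped")
      next
    }
    for (s in seq_len(nrow(samples))) {
      mu <- tm[tx$transcript_id[i], samples$tissue[s]]
      if (mu <= 0) next
      n_reads <- stats::rnbinom(1L, mu = mu, size = cfg$nb_dispersion)
      if (n_reads == 0L) next
      for (r in seq_len(n_reads)) {
        serial <- serial + 1L
        ex <- ex0
        trunc <- stats::runif(1) < cfg$truncation_prob
        if (trunc) {
          loss <- min(stats::rgeom(1L, 1 / cfg$truncation_mean) + 1L,
                      tlen - cfg$min_read_length)
          ex <- truncate_chain_5p(ex, tx$strand[i], loss)
        }
        ex <- jitter_chain(ex, cfg$jitter_sd, cfg$end_jitter_sd)
        acc[[serial]] <- list(
          id = sprintf("%s.%07d", samples$sample_id[s], serial),
          sample = samples$sample_id[s], tx = tx$transcript_id[i],
          trunc = trunc, exons = ex, chrom = tx$chrom[i],
          strand = tx$strand[i])
      }
    }
  }
  n_genic <- length(acc)
  n_noise <- stats::rpois(1L, cfg$noise_read_rate * n_genic)
  if (n_noise > 0L) {
    free <- intergenic_space(ann)
    for (k in seq_len(n_noise)) {
      serial <- serial + 1L
      len <- max(50L, round(stats::rlnorm(1, cfg$noise_len_meanlog,
                                          cfg$noise_len_sdlog)))
      seg <- free[sample.int(nrow(free), 1L, prob = free$width), ]
      len <- min(len, seg$width)
      s0 <- seg$start + sample.int(max(1L, seg$width - len + 1L), 1L) - 1L
      smp <- samples$sample_id[sample.int(nrow(samples), 1L)]
      acc[[serial]] <- list(
        id = sprintf("%s.%07d", smp, serial), sample = smp,
        tx = NA_character_, trunc = FALSE,
        exons = exon_chain(s0, s0 + len), chrom = seg$chrom,
        strand = sample(c("+", "-"), 1L))
    }
  }
  reads <- read_set(
    read_id = vapply(acc, `[[`, character(1L), "id"),
    sample_id = vapply(acc, `[[`, character(1L), "sample"),
    chrom = vapply(acc, `[[`, character(1L), "chrom"),
    strand = vapply(acc, `[[`, character(1L), "strand"),
    exons = lapply(acc, `[[`, "exons"))
  read_truth <- data.frame(
    read_id = reads$read_id, sample_id = reads$sample_id,
    transcript_id = vapply(acc, `[[`, character(1L), "tx"),
    truncated = vapply(acc, `[[`, logical(1L), "trunc"),
    stringsAsFactors = FALSE)
  list(reads = reads, read_truth = read_truth)
}

# Intergenic and intronic space available for noise reads: everything in
# the genome outside gene exon spans, away from chromosome edges.
intergenic_space <- function(ann) {
  segs <- list()
  for (ch in names(ann$genome)) {
    gs <- ann$gene_spans[ann$gene_spans$chrom == ch, , drop = FALSE]
    ir <- IRanges::IRanges(gs$start + 1L, gs$end)
    gaps <- IRanges::gaps(IRanges::reduce(ir), start = 1L,
                          end = ann$genome[[ch]])
    if (length(gaps) == 0L) next
    segs[[ch]] <- data.frame(
      chrom = ch,
      start = IRanges::start(gaps) - 1L,
      end = IRanges::end(gaps),
      stringsAsFactors = FALSE)
  }
  d <- do.call(rbind, segs)
  d$width <- d$end - d$start
  d <- d[d$width >= 100L, , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Write a complete simulated dataset to disk
#'
#' Emits `truth_annotation.gtf`, `public_reference.gtf`, `reads.bed12`,
#' `samples.tsv`, `truth_reads.tsv`, `truth_transcripts.tsv` and the
#' configuration echoed as `config.yaml`.
#'
#' @param cfg A [simulation_config()].
#' @param out_dir Output directory.
#' @return Invisibly, the list of simulated objects.
#' @export
write_simulated_dataset <- function(cfg, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  ann <- simulate_annotation(cfg)
  rd <- simulate_reads(ann, cfg)
  write_gtf(ann$truth, file.path(out_dir, "truth_annotation.gtf"))
  write_gtf(ann$reference, file.path(out_dir, "public_reference.gtf"))
  write_bed12(rd$reads, file.path(out_dir, "reads.bed12"))
  utils::write.table(ann$samples, file.path(out_dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(rd$read_truth, file.path(out_dir, "truth_reads.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ann$truth_table,
                     file.path(out_dir, "truth_transcripts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(unclass(cfg), file.path(out_dir, "config.yaml"))
  invisible(list(annotation = ann, reads = rd))
}
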