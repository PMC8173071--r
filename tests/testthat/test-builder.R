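test_that("identical reads form one cluster; small clusters are discarded", {
  reads <- do.call(mk_reads, lapply(1:3, function(i)
    mk_read(paste0("r", i), c(100, 300), c(200, 400))))
  cl <- cluster_alignments(reads)
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$size, 3L)

  # a read whose intron start deviates by 25 bp (tolerance 20) is
  # excluded, leaving a cluster of 2 -> nothing emitted
  reads2 <- mk_reads(
    mk_read("r1", c(100, 300), c(200, 400)),
    mk_read("r2", c(100, 300), c(200, 400)),
    mk_read("r3", c(100, 325), c(225, 400))
  )
  cl2 <- cluster_alignments(reads2)
  expect_length(cl2, 0L)
  expect_equal(attr(cl2, "n_discarded_reads"), 3L)
})

test_that("jittered reads from one transcript form exactly one cluster", {
  set.seed(11)
  truth <- exon_chain(c(1000, 2000, 3000, 4000),
                      c(1500, 2500, 3500, 4500))
  # sd 5 clamped at +/-8 bp: any two reads differ by at most 16 bp per
  # boundary, inside the 20 bp tolerance, so the pairwise-compatibility
  # oracle predicts a single cluster
  reads <- jittered_reads(truth, 100, sd = 5, clamp = 8)
  cl <- cluster_alignments(reads)
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$size, 100L)
  # brute-force pairwise-compatibility oracle: every pair of reads is
  # mutually within tolerance, so a single cluster is the only outcome
  bmat <- t(vapply(reads$exons, function(e)
    as.integer(t(chain_introns(e))), integer(6)))
  pairwise_ok <- all(apply(bmat, 2, function(col) diff(range(col)) <= 20))
  expect_true(pairwise_ok)
})

test_that("single-exon reads cluster under the terminal tolerance", {
  reads <- mk_reads(
    mk_read("r1", 500, 900), mk_read("r2", 510, 890),
    mk_read("r3", 495, 905),
    mk_read("r4", 700, 1100), mk_read("r5", 705, 1095),
    mk_read("r6", 702, 1090)
  )
  cl <- cluster_alignments(reads)
  expect_length(cl, 2L)
  expect_setequal(vapply(cl, `[[`, integer(1), "size"), c(3L, 3L))
})

test_that("consensus uses the lower median per boundary", {
  cl <- list(chrom = "chr1", strand = "+", n_introns = 1L, size = 3L,
             member_ids = paste0("r", 1:3),
             starts = c(100L, 102L, 104L), ends = c(400L, 398L, 402L),
             bounds = matrix(c(200L, 202L, 204L, 300L, 302L, 304L), 3))
  m <- consensus_model(cl)
  expect_equal(unname(m$exons[[1]]),
               matrix(c(102L, 202L, 302L, 400L), 2, byrow = TRUE))
  # even count: lower of the middle pair
  cl$size <- 2L; cl$member_ids <- paste0("r", 1:2)
  cl$starts <- c(100L, 102L); cl$ends <- c(400L, 402L)
  cl$bounds <- matrix(c(200L, 202L, 300L, 302L), 2)
  m2 <- consensus_model(cl)
  expect_equal(unname(m2$exons[[1]][1, 1]), 100L)
  expect_equal(unname(m2$exons[[1]][1, 2]), 200L)
})

test_that("consensus of jittered reads lands within 1 bp of the truth", {
  set.seed(5)
  truth <- exon_chain(c(100, 500), c(300, 900))
  hits <- replicate(50, {
    reads <- jittered_reads(truth, 101, sd = 3)
    cl <- cluster_alignments(reads)
    m <- consensus_model(cl[[1]])
    abs(m$exons[[1]][1, 2] - 300)
  })
  # median of 101 draws of round(N(0,3)): simulation oracle for the
  # same quantity gives max deviation 1 at this n
  expect_true(all(hits <= 1))
})

test_that("loci group by strand-aware 3' ends with transitive components", {
  mk_model <- function(id, starts, ends, strand = "+") {
    m <- data.frame(model_id = id, chrom = "chr1", strand = strand,
                    support = 3L, stringsAsFactors = FALSE)
    m$exons <- list(exon_chain(starts, ends))
    m
  }
  models <- rbind(mk_model("a", 0, 1000), mk_model("b", 100, 1050),
                  mk_model("c", 100, 1050, strand = "-"))
  out <- assign_loci(models)
  expect_equal(out$locus_id[1], out$locus_id[2])   # 3' ends 1000 vs 1050
  expect_false(out$locus_id[3] == out$locus_id[1]) # opposite strand
  # chain 0,90,180: one locus via transitivity (union-find oracle:
  # pairwise edges 0-90 and 90-180 join all three)
  chain <- rbind(mk_model("x", 0, 400), mk_model("y", 0, 490),
                 mk_model("z", 0, 580))
  chain$exons <- list(exon_chain(0, 400), exon_chain(0, 490),
                      exon_chain(0, 580))
  out2 <- assign_loci(chain)
  expect_length(unique(out2$locus_id), 1L)
})

test_that("collapse absorbs 3'-suffix degradation products and respects limits", {
  mk_model <- function(id, starts, ends, support = 3L, strand = "+") {
    m <- data.frame(model_id = id, chrom = "chr1", strand = strand,
                    support = support, stringsAsFactors = FALSE)
    m$exons <- list(exon_chain(starts, ends))
    m
  }
  # B: 4 exons; A: its last 3 exons with the 5' end 800 bp into B
  b <- mk_model("B", c(0, 1000, 2000, 3000), c(500, 1500, 2500, 3600),
                support = 10L)
  a <- mk_model("A", c(1050, 2000, 3000), c(1500, 2500, 3600), support = 4L)
  models <- assign_loci(rbind(b, a))
  out <- collapse_models(models)
  expect_equal(nrow(out), 1L)
  expect_equal(out$model_id, "B")
  expect_equal(out$support, 14L)

  # same chain shifted so 3' ends differ by 150 bp: not collapsed
  b2 <- mk_model("B2", c(0, 1000), c(500, 1500), support = 10L)
  a2 <- mk_model("A2", c(150, 1150), c(650, 1650), support = 4L)
  models2 <- assign_loci(rbind(b2, a2))
  out2 <- collapse_models(models2)
  expect_equal(nrow(out2), 2L)
})

test_that("collapse reaches an absorption-free fixed point equal to the oracle", {
  set.seed(23)
  tol <- tolerance_set()
  for (rep in 1:40) {
    strand <- sample(c("+", "-"), 1)
    base <- random_chain(sample(3:5, 1), intron_len = c(200, 600))
    n <- sample(4:8, 1)
    rows <- lapply(seq_len(n), function(i) {
      # random 3'-terminal fragments with small boundary wobble
      k <- sample(0:(nrow(base) - 1), 1)
      ex <- if (strand == "+") base[(k + 1):nrow(base), , drop = FALSE]
      else base[seq_len(nrow(base) - k), , drop = FALSE]
      ex <- ex + sample(-2:2, 1)
      m <- data.frame(model_id = paste0("m", i), chrom = "chr1",
                      strand = strand, support = sample(3:50, 1),
                      stringsAsFactors = FALSE)
      m$exons <- list(ex)
      m
    })
    models <- assign_loci(do.call(rbind, rows), tol)
    got <- collapse_models(models, tol)
    want <- oracle_collapse(models, tol)
    expect_setequal(got$model_id, want$model_id)
    expect_equal(got$support[order(got$model_id)],
                 want$support[order(want$model_id)])
    # absorption-free: no surviving pair satisfies the predicate
    for (i in seq_len(nrow(got))) for (j in seq_len(nrow(got))) {
      if (i != j && got$locus_id[i] == got$locus_id[j])
        expect_false(isoscribe:::can_absorb(got$exons[[i]], got$exons[[j]],
                                            got$strand[i], tol))
    }
  }
})

test_that("support is conserved and output is order-invariant", {
  set.seed(31)
  cfg <- simulation_config(n_genes = 6L, seed = 77L)
  ann <- simulate_annotation(cfg)
  rd <- simulate_reads(ann, cfg)
  models <- build_transcript_models(rd$reads)
  st <- attr(models, "stats")
  expect_equal(sum(models$support) + st$reads_discarded, nrow(rd$reads))
  # permuting read order changes nothing
  perm <- rd$reads[sample(nrow(rd$reads)), ]
  class(perm) <- class(rd$reads)
  models2 <- build_transcript_models(perm)
  o1 <- order(models$chrom, models$strand,
              vapply(models$exons, function(e) e[1, 1], integer(1)))
  o2 <- order(models2$chrom, models2$strand,
              vapply(models2$exons, function(e) e[1, 1], integer(1)))
  expect_equal(lapply(models$exons[o1], unname),
               lapply(models2$exons[o2], unname))
  expect_equal(models$support[o1], models2$support[o2])
})

test_that("pipeline recovery: every sufficiently covered transcript is rebuilt exactly", {
  cfg <- simulation_config(n_genes = 10L, seed = 42L)
  ann <- simulate_annotation(cfg)
  rd <- simulate_reads(ann, cfg)
  models <- build_transcript_models(rd$reads)
  rec <- isoform_recovery(models, ann, rd$read_truth)
  expect_equal(rec$recovery_rate, 1)
  expect_gt(rec$n_eligible, 5)
})
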