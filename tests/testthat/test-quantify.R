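mk_model_q <- function(id, starts, ends, strand = "+", chrom = "chr1") {
  m <- data.frame(model_id = id, chrom = chrom, strand = strand,
                  support = 3L, stringsAsFactors = FALSE)
  m$exons <- list(exon_chain(starts, ends))
  m
}

test_that("compatibility is 3'-anchored and truncation-tolerant", {
  models <- rbind(
    mk_model_q("M1", c(0, 1000, 2000), c(500, 1500, 2600)),
    mk_model_q("M2", c(800, 2000), c(1500, 2600))  # shares the 3' suffix
  )
  # undegraded read from M1: compatible with M1 only
  r_full <- mk_read("s1.r1", c(0, 1000, 2000), c(500, 1500, 2600))
  # truncated read keeping the last junction: compatible with both
  r_trunc <- mk_read("s1.r2", c(1100, 2000), c(1500, 2600))
  compat <- build_compatibility(mk_reads(r_full, r_trunc), models)
  expect_equal(compat$compat[[1]], "M1")
  expect_setequal(compat$compat[[2]], c("M1", "M2"))

  # single-exon read inside the 3'-terminal exon: both models
  r_se <- mk_read("s1.r3", 2100, 2550)
  compat2 <- build_compatibility(mk_reads(r_se), models)
  expect_setequal(compat2$compat[[1]], c("M1", "M2"))

  # read with a junction foreign to both models: unassigned
  r_bad <- mk_read("s1.r4", c(1100, 1900), c(1400, 2600))
  compat3 <- build_compatibility(mk_reads(r_bad), models)
  expect_length(compat3$compat[[1]], 0L)
  expect_equal(attr(compat3, "n_unassigned"), 1L)
})

test_that("compatibility contains the true transcript for nearly all reads", {
  cfg <- simulation_config(n_genes = 8L, seed = 3L, noise_read_rate = 0)
  ann <- simulate_annotation(cfg)
  rd <- simulate_reads(ann, cfg)
  models <- build_transcript_models(rd$reads)
  # map models to truth by exact chain
  cls <- classify_models(models, list(truth = ann$truth))
  compat <- build_compatibility(rd$reads, models)
  eq <- cls$code_truth == "="
  model_of_truth <- setNames(cls$model_id[eq], cls$ref_truth[eq])
  tt <- rd$read_truth$transcript_id
  covered <- vapply(seq_along(tt), function(i) {
    mid <- model_of_truth[tt[i]]
    !is.na(mid) && mid %in% compat$compat[[i]]
  }, logical(1))
  expect_gte(mean(covered[tt %in% names(model_of_truth)]), 0.99)
})

test_that("EM fixed points match closed forms and the long-run oracle", {
  # every read uniquely compatible: proportions are count shares
  compat <- structure(list(
    read_id = paste0("r", 1:4), sample_id = rep("s1", 4),
    compat = list("A", "A", "A", "B")), class = "compatibility_matrix")
  p <- em_abundance(compat, "s1")
  expect_equal(unname(p[c("A", "B")]), c(0.75, 0.25))

  # symmetric sharing: 1 unique to A, 1 to B, 2 shared -> (0.5, 0.5)
  compat2 <- structure(list(
    read_id = paste0("r", 1:4), sample_id = rep("s1", 4),
    compat = list("A", "B", c("A", "B"), c("A", "B"))),
    class = "compatibility_matrix")
  p2 <- em_abundance(compat2, "s1")
  expect_equal(unname(p2[c("A", "B")]), c(0.5, 0.5), tolerance = 1e-6)

  # random instances agree with a dense EM run at 10x iterations
  set.seed(19)
  for (rep in 1:20) {
    k <- sample(2:5, 1)
    txs <- LETTERS[seq_len(k)]
    sets <- lapply(seq_len(sample(10:30, 1)), function(i)
      sample(txs, sample(1:k, 1)))
    compat_r <- structure(list(
      read_id = paste0("r", seq_along(sets)),
      sample_id = rep("s1", length(sets)),
      compat = sets), class = "compatibility_matrix")
    got <- em_abundance(compat_r, "s1", max_iter = 1000, rel_tol = 0)
    want <- oracle_em(sets, n_iter = 10000)
    expect_equal(unname(got[names(want)]), unname(want), tolerance = 1e-5)
  }
})

test_that("EM conserves reads and the log-likelihood never decreases", {
  set.seed(29)
  sets <- lapply(1:50, function(i) sample(LETTERS[1:4], sample(1:3, 1)))
  models <- sort(unique(unlist(sets)))
  # manual EM tracking likelihood
  p <- rep(1 / length(models), length(models))
  names(p) <- models
  ll_old <- -Inf
  for (it in 1:50) {
    w <- lapply(sets, function(s) p[s] / sum(p[s]))
    counts <- tapply(unlist(w), unlist(lapply(w, names)), sum)
    counts <- counts[models]
    counts[is.na(counts)] <- 0
    p_new <- counts / length(sets)
    ll <- sum(vapply(sets, function(s) log(sum(p_new[s])), numeric(1)))
    expect_gte(ll, ll_old - 1e-9)
    ll_old <- ll
    p <- p_new
  }
  # package EM: estimated counts sum to assigned reads
  compat_r <- structure(list(
    read_id = paste0("r", seq_along(sets)),
    sample_id = rep("s1", length(sets)), compat = sets),
    class = "compatibility_matrix")
  prop <- em_abundance(compat_r, "s1")
  expect_equal(sum(prop) * attr(prop, "n_assigned"), length(sets),
               tolerance = 1e-9)
})

test_that("TPM scales proportions to a million with no length term", {
  expect_equal(unname(to_tpm(c(0.25, 0.25, 0.5))), c(250000, 250000, 500000))
  expect_equal(unname(to_tpm(1)), 1e6)
  set.seed(3)
  p <- runif(10); p <- p / sum(p)
  expect_equal(sum(to_tpm(p)), 1e6, tolerance = 1e-6)
})

test_that("quantification recovers realized proportions under unique compatibility", {
  cfg <- simulation_config(n_genes = 10L, seed = 8L, noise_read_rate = 0,
                           truncation_prob = 0)
  ann <- simulate_annotation(cfg)
  rd <- simulate_reads(ann, cfg)
  models <- build_transcript_models(rd$reads)
  expr <- quantify_expression(rd$reads, models, ann$samples)
  # per sample, TPM sums to 1e6 whenever reads were assigned
  sums <- colSums(expr$tpm)
  expect_true(all(abs(sums[sums > 0] - 1e6) < 1e-3))
  # counts conserve assigned reads
  per_sample <- table(factor(rd$reads$sample_id,
                             colnames(expr$counts)))
  assigned <- as.integer(per_sample) - as.integer(expr$unassigned)
  expect_equal(unname(colSums(expr$counts)), assigned, tolerance = 1e-6)
})
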