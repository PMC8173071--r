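test_that("shuffle preserves lengths, respects exclusions, and is seeded", {
  genome <- c(chrA = 10000L, chrB = 5000L)
  iv <- data.frame(chrom = c("chrA", "chrA", "chrB"),
                   start = c(100L, 2000L, 300L),
                   end = c(400L, 2500L, 900L))
  excl <- data.frame(chrom = "chrA", start = 0L, end = 6000L)
  s1 <- shuffle_intervals(iv, genome, excl, seed = 5L)
  s2 <- shuffle_intervals(iv, genome, excl, seed = 5L)
  expect_identical(s1, s2)
  expect_equal(s1$end - s1$start, iv$end - iv$start)
  clash <- s1$chrom == "chrA" & s1$start < 6000
  expect_false(any(clash & s1$end > 0 & s1$chrom == "chrA" &
                     pmin(s1$end, 6000) - pmax(s1$start, 0) > 0))
})

test_that("an exclusion leaving one gap forces a deterministic placement", {
  genome <- c(chr1 = 1000L)
  iv <- data.frame(chrom = "chr1", start = 0L, end = 100L)
  excl <- data.frame(chrom = "chr1", start = c(0L, 400L),
                     end = c(300L, 1000L))
  out <- shuffle_intervals(iv, genome, excl, seed = 9L)
  expect_equal(out$start, 300L)
  expect_equal(out$end, 400L)
  # fully excluded genome: unplaceable
  excl_all <- data.frame(chrom = "chr1", start = 0L, end = 1000L)
  expect_error(shuffle_intervals(iv, genome, excl_all, seed = 1L,
                                 max_tries = 50L), "unplaceable")
})

test_that("shuffle placement is length-proportional across chromosomes", {
  genome <- c(chrA = 30000L, chrB = 10000L)
  iv <- data.frame(chrom = "chrA", start = 0L, end = 200L)
  set.seed(100)
  n <- 1000
  chosen <- vapply(seq_len(n), function(i)
    shuffle_intervals(iv, genome, seed = NULL)$chrom, character(1))
  pA <- (30000 - 199) / (30000 - 199 + 10000 - 199)
  ci <- qbinom(c(0.005, 0.995), n, pA)
  expect_gte(sum(chosen == "chrA"), ci[1])
  expect_lte(sum(chosen == "chrA"), ci[2])
})

test_that("nearest gene distance matches the all-pairs oracle", {
  genes <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                      start = c(1000L, 5000L, 100L),
                      end = c(2000L, 6000L, 500L))
  iv <- data.frame(chrom = c("chr1", "chr1", "chr1"),
                   start = c(1500L, 2500L, 4300L),
                   end = c(1600L, 3000L, 4500L))
  d <- nearest_gene_distance(iv, genes)
  expect_equal(d[1], 0)     # overlapping
  expect_equal(d[2], 500)   # 500 left gene, 2000 right gene
  expect_equal(d[3], 500)   # equidistant-ish: min(2300, 500)
  set.seed(44)
  for (rep in 1:20) {
    g <- data.frame(chrom = sample(c("chr1", "chr2"), 8, replace = TRUE),
                    start = sample(0:50000, 8))
    g$end <- g$start + sample(100:2000, 8)
    q <- data.frame(chrom = sample(c("chr1", "chr2"), 15, replace = TRUE),
                    start = sample(0:50000, 15))
    q$end <- q$start + sample(50:500, 15)
    expect_equal(nearest_gene_distance(q, g), oracle_nearest(q, g))
  }
})

test_that("rank-sum statistic and p-values match definitions and oracles", {
  r <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)             # complete separation
  expect_equal(oracle_u(c(1, 2, 3), c(4, 5, 6)), 0)
  r2 <- rank_sum_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r2$p_value, 1)
  r3 <- rank_sum_test(rep(2, 4), rep(2, 5))
  expect_equal(r3$p_value, 1)

  # exact path equals full-enumeration oracle and wilcox.test
  set.seed(8)
  for (rep in 1:30) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    v <- sample(1:1000, n1 + n2)  # distinct values: no ties
    x <- v[seq_len(n1)]; y <- v[-seq_len(n1)]
    got <- rank_sum_test(x, y)
    expect_equal(got$method, "exact")
    expect_equal(got$U, oracle_u(x, y))
    expect_equal(got$p_value, oracle_exact_p(x, y), tolerance = 1e-12)
    expect_equal(got$p_value,
                 wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }

  # approximate path (ties / larger n) equals wilcox.test with
  # continuity and tie correction
  for (rep in 1:20) {
    n1 <- sample(8:20, 1); n2 <- sample(8:20, 1)
    x <- sample(1:10, n1, replace = TRUE)
    y <- sample(2:11, n2, replace = TRUE)
    got <- rank_sum_test(x, y)
    expect_equal(got$method, "normal_approx")
    want <- suppressWarnings(
      wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
    expect_equal(got$p_value, want, tolerance = 1e-10)
  }
})

test_that("U_x + U_y equals n1*n2 with midranks", {
  set.seed(15)
  for (rep in 1:20) {
    x <- sample(1:20, 8, replace = TRUE)
    y <- sample(1:20, 11, replace = TRUE)
    expect_equal(rank_sum_test(x, y)$U + rank_sum_test(y, x)$U, 8 * 11)
  }
})

test_that("intergenic proximity test detects designed enrichment", {
  set.seed(2)
  genome <- c(chr1 = 1000000L)
  genes <- data.frame(chrom = "chr1",
                      start = seq(0L, 900000L, by = 100000L))
  genes$end <- genes$start + 20000L
  # intervals placed just downstream of genes: closer than random
  iv <- data.frame(chrom = "chr1", start = genes$start[1:8] + 22000L)
  iv$end <- iv$start + 500L
  res <- intergenic_proximity_test(iv, genes, genome, seed = 3L)
  expect_lt(res$test$p_value, 0.05)
  expect_equal(max(res$observed), 2000)
})
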