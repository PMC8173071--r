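mk_model <- function(id, starts, ends, chrom = "chr1", strand = "+",
                     support = 5L) {
  m <- data.frame(model_id = id, chrom = chrom, strand = strand,
                  support = support, stringsAsFactors = FALSE)
  m$exons <- list(exon_chain(starts, ends))
  m
}

test_that("hand-built cases get the expected class codes", {
  ref <- mk_txs(
    mk_tx("t1", c(100, 1000, 2000), c(500, 1500, 2600), gene = "g1"),
    mk_tx("t2", c(5000, 7000), c(5500, 7800), gene = "g2", strand = "-")
  )
  code <- function(m) assign_class_code(m, ref)$code
  # same chain, shorter first exon -> '='
  expect_equal(code(mk_model("q", c(300, 1000, 2000), c(500, 1500, 2600))), "=")
  # sub-chain -> 'c'
  expect_equal(code(mk_model("q", c(1050, 2000), c(1500, 2600))), "c")
  # extra flanking introns retaining the reference chain -> 'k'
  expect_equal(code(mk_model("q", c(50, 100, 1000, 2000), c(80, 500, 1500, 2600))), "k")
  # all reference introns retained inside one exon -> 'm'
  expect_equal(code(mk_model("q", 100, 2600)), "m")
  # one intron retained, other matched -> 'n'
  expect_equal(code(mk_model("q", c(100, 2000), c(1500, 2600))), "n")
  # shared junction with novel junction elsewhere -> 'j'
  expect_equal(code(mk_model("q", c(100, 1100, 2000), c(500, 1500, 2600))), "j")
  # single-exon query inside a reference intron, same strand -> 'i'
  expect_equal(code(mk_model("q", 1600, 1900)), "i")
  # single-exon query extending >= 10 bp into the intron -> 'e'
  expect_equal(code(mk_model("q", 400, 550)), "e")
  # exon overlap on the opposite strand -> 'x'
  expect_equal(code(mk_model("q", 5200, 5400, strand = "+")), "x")
  # reverse: same strand as t2 -> '=' (single-exon overlap rule is 'c')
  expect_equal(code(mk_model("q", c(5000, 7000), c(5500, 7800), strand = "-")), "=")
  # downstream run-on within 2 kb, same strand -> 'p'
  expect_equal(code(mk_model("q", 3000, 3400)), "p")
  # beyond 2 kb -> 'u'
  expect_equal(code(mk_model("q", 4700, 4900)), "u")
  # model on a chromosome absent from the annotation -> 'u'
  expect_equal(code(mk_model("q", 100, 400, chrom = "chrZ")), "u")
})

test_that("random queries match the exhaustive class-code oracle", {
  set.seed(97)
  n_checked <- 0
  for (rep in 1:10) {
    # toy annotation: 4 genes on one chromosome
    ref_rows <- lapply(1:4, function(g) {
      strand <- sample(c("+", "-"), 1)
      ch <- random_chain(sample(1:4, 1), origin = (g - 1) * 4000)
      transcript_set(paste0("t", g), paste0("g", g), "chr1", strand,
                     list(ch))
    })
    ref <- do.call(rbind, ref_rows)
    class(ref) <- c("transcript_set", "data.frame")
    for (q in 1:25) {
      strand <- sample(c("+", "-"), 1)
      qch <- random_chain(sample(1:3, 1),
                          origin = sample(0:16000, 1))
      model <- data.frame(model_id = "q", chrom = "chr1", strand = strand,
                          stringsAsFactors = FALSE)
      model$exons <- list(qch)
      got <- assign_class_code(model, ref)$code
      want <- oracle_class_code(model, ref)
      expect_equal(got, want, info = sprintf("rep %d query %d", rep, q))
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 200)
})

test_that("categorize applies the precedence mapping over annotations", {
  expect_equal(categorize(c(ensembl = "=", ncbi = "j")), "known_isoform")
  expect_equal(categorize(c(ensembl = "u", ncbi = "u")), "novel_locus")
  expect_equal(categorize(c(ensembl = "e", ncbi = "p")), "artifact")
  expect_equal(categorize(c(ensembl = "c", ncbi = "u")), "novel_isoform")
  expect_equal(categorize(c(ensembl = "e", ncbi = "i")), "novel_locus")
  expect_error(categorize(character(0)), "empty")
})

test_that("every classified model gets exactly one category and counts partition", {
  cfg <- simulation_config(n_genes = 8L, seed = 13L)
  ann <- simulate_annotation(cfg)
  rd <- simulate_reads(ann, cfg)
  models <- build_transcript_models(rd$reads)
  cls <- classify_models(models, list(ref = ann$reference))
  expect_equal(nrow(cls), nrow(models))
  expect_true(all(cls$category %in% c("known_isoform", "novel_isoform",
                                      "novel_locus", "artifact")))
  expect_equal(sum(table(cls$category)), nrow(models))
})

test_that("single-exon filter retains by coding overlap or strong support", {
  ref <- list(ens = mk_tx("t1", c(100, 1000), c(500, 1600),
                          biotype = "protein_coding"))
  sm <- function(id, s, e, sup, strand = "+")
    mk_model(id, s, e, support = sup, strand = strand)
  models <- rbind(
    sm("overlap_weak", 300, 700, 3L),     # coding overlap, weak -> kept
    sm("intronic_99", 600, 900, 99L),     # no overlap, support 99 -> removed
    sm("intergenic_100", 8000, 8400, 100L),  # support 100 -> kept
    sm("anti_strong", 300, 700, 50L, strand = "-"),  # wrong strand -> removed
    mk_model("multi", c(100, 1000), c(500, 1600), support = 3L)  # multi-exon
  )
  models$locus_id <- paste0("L", seq_len(nrow(models)))
  out <- filter_single_exon(models, ref, min_support = 100L)
  expect_setequal(out$model_id, c("overlap_weak", "intergenic_100", "multi"))
  expect_equal(unname(attr(out, "removed")["no_coding_overlap_low_support"]), 2L)
})

test_that("accuracy metrics are 100 on identity and match hand counts", {
  ref <- mk_txs(
    mk_tx("t1", c(100, 1000, 2000), c(500, 1500, 2600), gene = "g1"),
    mk_tx("t2", c(5000, 7000), c(5500, 7800), gene = "g2", strand = "-")
  )
  acc <- accuracy_metrics(ref, ref)
  expect_true(all(abs(acc$levels$sensitivity - 100) < 1e-9))
  expect_true(all(abs(acc$levels$precision - 100) < 1e-9))
  expect_equal(unname(acc$counts$missed_exons[1]), 0L)
  expect_equal(unname(acc$counts$novel_introns[1]), 0L)

  # reference: one 2-intron transcript; prediction: the same chain plus
  # a spurious 1-intron model elsewhere -> intron sensitivity 100,
  # intron precision 2/3 * 100
  ref1 <- mk_tx("t1", c(100, 1000, 2000), c(500, 1500, 2600), gene = "g1")
  pred <- mk_txs(
    mk_tx("p1", c(100, 1000, 2000), c(500, 1500, 2600), gene = "gp1"),
    mk_tx("p2", c(50000, 52000), c(50500, 52800), gene = "gp2")
  )
  acc2 <- accuracy_metrics(pred, ref1)
  iv <- acc2$levels[acc2$levels$level == "intron", ]
  expect_equal(iv$sensitivity, 100)
  expect_equal(iv$precision, 100 * 2 / 3)
  tv <- acc2$levels[acc2$levels$level == "transcript", ]
  expect_equal(tv$sensitivity, 100)
  expect_equal(tv$precision, 50)
})

test_that("terminal exons match on the internal boundary only", {
  ref <- mk_tx("t1", c(100, 1000, 2000), c(500, 1500, 2600), gene = "g1")
  # same chain, different terminal extents
  pred <- mk_tx("p1", c(300, 1000, 2000), c(500, 1500, 2400), gene = "gp")
  acc <- accuracy_metrics(pred, ref)
  ev <- acc$levels[acc$levels$level == "exon", ]
  expect_equal(ev$sensitivity, 100)
  expect_equal(ev$precision, 100)
  expect_equal(acc$levels$sensitivity[acc$levels$level == "transcript"], 100)
})
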