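#' Pipeline configuration
#'
#' Collects every stage parameter in one place. Defaults equal the
#' procedure's stated constants: clustering 20/60 bp with minimum
#' cluster size 3, collapse 5/100/5,000 bp, single-exon rescue support
#' 100, TSI boundaries 0.5/0.8, TSS window +/-100 bp, unique-TSS window
#' +/-50 bp, matched-end distance 2 kb.
#'
#' @param simulation A [simulation_config()] used when no input paths
#'   are given.
#' @param tolerances A [tolerance_set()].
#' @param min_support Single-exon rescue threshold.
#' @param tsi_broad,tsi_specific TSI category boundaries.
#' @param tss_window,unique_tss_window,near_distance Windows in bp.
#' @param exclude_samples Sample ids excluded from tissue-specificity.
#' @param out_dir Optional output directory for stage files.
#' @param seed Integer seed for the shuffle stage (and simulation).
#' @return A named list with class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            tolerances = tolerance_set(),
                            min_support = 100L,
                            tsi_broad = 0.5, tsi_specific = 0.8,
                            tss_window = 100L, unique_tss_window = 50L,
                            near_distance = 2000L,
                            exclude_samples = character(),
                            out_dir = NULL, seed = 1L) {
  cfg <- as.list(environment())
  cfg$simulation$seed <- seed
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full pipeline on a simulated dataset
#'
#' Executes simulate, build, compare, quantify, tsi, events and
#' structure in dependency order and returns a run summary whose counts
#' partition the model total. When `out_dir` is set, stage outputs are
#' written via [write_outputs()] and the configuration is echoed as
#' YAML.
#'
#' @param config A [pipeline_config()].
#' @return A list with class `pipeline_run`: the stage objects
#'   (`annotation`, `reads`, `models`, `classifications`, `expression`,
#'   `tsi`, `events`, `structure`) and `summary`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  ann <- simulate_annotation(config$simulation)
  rd <- simulate_reads(ann, config$simulation)

  models <- build_transcript_models(rd$reads, config$tolerances)
  build_stats <- attr(models, "stats")

  annotations <- list(reference = ann$reference)
  cls <- classify_models(models, annotations)
  kept <- filter_single_exon(models, annotations,
                             min_support = config$min_support)
  n_removed <- attr(kept, "removed")
  cls_kept <- cls[cls$model_id %in% kept$model_id, , drop = FALSE]

  expr <- quantify_expression(rd$reads, kept, ann$samples,
                              config$tolerances)
  tsi_tab <- tsi_records(expr, exclusions = config$exclude_samples)
  events <- enumerate_events(kept)
  ends <- end_overlap_stats(kept, list(reference = ann$reference),
                            window = config$tss_window,
                            near = config$near_distance,
                            classifications = cls_kept)

  ref_col <- grep("^code_", names(cls_kept), value = TRUE)[1L]
  intergenic_idx <- cls_kept$model_id[cls_kept[[ref_col]] == "u"]
  structure <- NULL
  if (length(intergenic_idx) >= 2L) {
    mi <- match(intergenic_idx, kept$model_id)
    sp <- vapply(kept$exons[mi], chain_span, integer(2L))
    iv <- data.frame(chrom = kept$chrom[mi], start = sp[1L, ], end = sp[2L, ])
    genes <- ann$gene_spans[ann$gene_spans$gene_id %in% ann$reference$gene_id,
                            c("chrom", "start", "end")]
    structure <- intergenic_proximity_test(iv, genes, ann$genome,
                                           seed = config$seed)
  }

  cat_counts <- table(factor(cls_kept$category,
                             c("known_isoform", "novel_isoform",
                               "novel_locus", "artifact")))
  loci <- unique(kept$locus_id)
  tx_per_locus <- nrow(kept) / length(loci)
  multi_tx_loci <- sum(table(kept$locus_id) > 1L)

  summary <- list(
    reads_in = build_stats$reads_in,
    reads_discarded = build_stats$reads_discarded,
    clusters_emitted = build_stats$clusters_emitted,
    clusters_discarded = build_stats$clusters_discarded,
    models_pre_collapse = build_stats$models_pre_collapse,
    models_post_collapse = build_stats$models_post_collapse,
    single_exon_removed = unname(n_removed),
    models_final = nrow(kept),
    loci = length(loci),
    multi_transcript_loci = multi_tx_loci,
    multi_transcript_locus_pct = ratio_pct(multi_tx_loci, length(loci)),
    transcripts_per_locus = tx_per_locus,
    category_counts = as.list(cat_counts),
    category_pct = as.list(partition_pct(cat_counts)),
    unassigned_reads = sum(expr$unassigned),
    tsi_category_counts = as.list(table(factor(
      tsi_tab$category, c("tissue_specific", "intermediate", "broad")))),
    event_counts = as.list(attr(events, "type_counts")),
    tss_overlap = ends$tss_overlap
  )

  run <- list(config = config, annotation = ann, reads = rd,
              models = kept, classifications = cls_kept,
              expression = expr, tsi = tsi_tab, events = events,
              end_stats = ends, structure = structure, summary = summary)
  class(run) <- "pipeline_run"

  if (!is.null(config$out_dir)) {
    write_outputs(kept, cls_kept, expr, tsi_tab, events, config$out_dir)
    yaml::write_yaml(list(simulation = unclass(config$simulation),
                          tolerances = unclass(config$tolerances),
                          min_support = config$min_support,
                          seed = config$seed),
                     file.path(config$out_dir, "config.yaml"))
  }
  run
}

#' Percentage of a ratio
#'
#' @param num,den Counts.
#' @return `100 * num / den`.
#' @export
ratio_pct <- function(num, den) {
  if (den == 0) stop("zero denominator")
  100 * num / den
}

#' Percentages of a partition of counts
#'
#' @param counts Numeric vector (e.g. category counts).
#' @return Percentages summing to 100.
#' @export
partition_pct <- function(counts) {
  100 * counts / sum(counts)
}

#' Recovery metrics against the simulation truth
#'
#' A true transcript is *recovered* when exactly the models matching it
#' exist: same chrom/strand, identical intron chain, and overlapping
#' span (the span condition anchors single-exon transcripts, whose
#' intron chain is empty). Evaluated over true transcripts with at
#' least `min_reads` non-noise reads.
#'
#' @param models Model table.
#' @param ann A [simulate_annotation()] result.
#' @param read_truth The `read_truth` table from [simulate_reads()].
#' @param min_reads Read-support threshold defining recoverable truth.
#' @return A list: `recovery_rate` (fraction), `n_eligible`,
#'   `n_recovered`, and the per-transcript logical `recovered`.
#' @export
isoform_recovery <- function(models, ann, read_truth, min_reads = 3L) {
  reads_per_tx <- table(read_truth$transcript_id)
  eligible <- ann$truth$transcript_id[
    ann$truth$transcript_id %in% names(reads_per_tx)[reads_per_tx >= min_reads]]
  model_keys <- vapply(seq_len(nrow(models)), function(i)
    chain_key(models$chrom[i], models$strand[i], models$exons[[i]]),
    character(1L))
  model_spans <- vapply(models$exons, chain_span, integer(2L))
  recovered <- vapply(eligible, function(tid) {
    i <- match(tid, ann$truth$transcript_id)
    key <- chain_key(ann$truth$chrom[i], ann$truth$strand[i],
                     ann$truth$exons[[i]])
    hit <- model_keys == key
    if (!any(hit)) return(FALSE)
    sp <- chain_span(ann$truth$exons[[i]])
    any(hit & model_spans[1L, ] < sp[2L] & model_spans[2L, ] > sp[1L])
  }, logical(1L))
  list(recovery_rate = mean(recovered), n_eligible = length(eligible),
       n_recovered = sum(recovered), recovered = recovered)
}

#' Category accuracy against the simulation truth
#'
#' Matches each classified model to a true transcript (identical intron
#' chain and overlapping span) and compares its novelty category to the
#' truth label (`known` maps to `known_isoform`).
#'
#' @param models,classifications Builder and classifier outputs.
#' @param ann A [simulate_annotation()] result.
#' @return A list: `accuracy` (fraction over matched models),
#'   `n_matched`, and the comparison data.frame.
#' @export
category_accuracy <- function(models, classifications, ann) {
  truth_keys <- vapply(seq_len(nrow(ann$truth)), function(i)
    chain_key(ann$truth$chrom[i], ann$truth$strand[i], ann$truth$exons[[i]]),
    character(1L))
  truth_spans <- vapply(ann$truth$exons, chain_span, integer(2L))
  rows <- lapply(seq_len(nrow(models)), function(i) {
    key <- chain_key(models$chrom[i], models$strand[i], models$exons[[i]])
    sp <- chain_span(models$exons[[i]])
    hit <- which(truth_keys == key &
                   truth_spans[1L, ] < sp[2L] & truth_spans[2L, ] > sp[1L])
    if (length(hit) == 0L) return(NULL)
    truth_cat <- ann$truth_table$category[hit[1L]]
    expected <- if (truth_cat == "known") "known_isoform" else truth_cat
    got <- classifications$category[classifications$model_id ==
                                      models$model_id[i]]
    data.frame(model_id = models$model_id[i],
               truth = expected, predicted = got,
               stringsAsFactors = FALSE)
  })
  cmp <- do.call(rbind, rows)
  if (is.null(cmp)) return(list(accuracy = NA_real_, n_matched = 0L,
                                comparison = NULL))
  list(accuracy = mean(cmp$truth == cmp$predicted),
       n_matched = nrow(cmp), comparison = cmp)
}

#' Write a run report
#'
#' Markdown tables for the headline structures of a run: category
#' partition, event counts, TSI categories, loci summary; a recovery
#' section is added when the run carries simulation truth. Every number
#' is taken from the run summary or recomputed from the run's own
#' tables.
#'
#' @param run A [run_pipeline()] result.
#' @param path Output file (Markdown).
#' @return The path, invisibly.
#' @export
report_run <- function(run, path) {
  s <- run$summary
  lines <- c(
    "# Pipeline run report", "",
    "## Reads and models", "",
    sprintf("- reads in: %d (discarded in sub-threshold clusters: %d)",
            s$reads_in, s$reads_discarded),
    sprintf("- clusters emitted: %d (discarded: %d)",
            s$clusters_emitted, s$clusters_discarded),
    sprintf("- models: %d pre-collapse, %d post-collapse, %d final",
            s$models_pre_collapse, s$models_post_collapse, s$models_final),
    sprintf("- loci: %d (%.1f%% with multiple transcripts; %.2f transcripts/locus)",
            s$loci, s$multi_transcript_locus_pct, s$transcripts_per_locus),
    "", "## Novelty categories", "",
    "| category | count | % |", "|---|---|---|",
    vapply(names(s$category_counts), function(k)
      sprintf("| %s | %d | %.1f |", k, s$category_counts[[k]],
              s$category_pct[[k]]), character(1L)),
    "", "## Splicing events", "",
    "| type | count |", "|---|---|",
    vapply(names(s$event_counts), function(k)
      sprintf("| %s | %d |", k, s$event_counts[[k]]), character(1L)),
    "", "## Tissue specificity", "",
    "| category | count |", "|---|---|",
    vapply(names(s$tsi_category_counts), function(k)
      sprintf("| %s | %d |", k, s$tsi_category_counts[[k]]), character(1L))
  )
  if (!is.null(run$annotation) && !is.null(run$reads)) {
    rec <- isoform_recovery(run$models, run$annotation,
                            run$reads$read_truth)
    acc <- category_accuracy(run$models, run$classifications,
                             run$annotation)
    lines <- c(lines, "", "## Recovery against simulation truth", "",
               sprintf("- isoform recovery: %d/%d (%.1f%%)",
                       rec$n_recovered, rec$n_eligible,
                       100 * rec$recovery_rate),
               sprintf("- category accuracy: %.1f%% over %d matched models",
                       100 * acc$accuracy, acc$n_matched))
  }
  writeLines(unlist(lines), path)
  invisible(path)
}
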