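#' Run the full analysis pipeline on a simulated experiment
#'
#' Executes, per stage: mapping statistics, RPKM quantification with activity
#' calling, TAR construction, novel-transcript detection, gene-boundary
#' refinement, and alternative-splicing classification; then pairwise
#' differential expression across stages. Thresholds default to the standard
#' rule set (novel length 150 bp / distance 200 bp, IR 90% coverage / 15%
#' depth ratio / 5 bp flanks, DEG FDR 0.001).
#'
#' @param sim a `sim_experiment` from [simulate_experiment()], or an
#'   equivalent list with `models`, `contig_lengths`, `counts` and per-stage
#'   `aln`/`junctions`.
#' @param alpha DEG FDR threshold (default 0.001).
#' @param min_length,min_distance novel-transcript rules (150 bp, 200 bp).
#' @param min_depth,max_gap TAR construction parameters.
#' @param drop_fraction,max_extension boundary-refinement parameters.
#' @param outdir optional directory; when given, per-stage TSV outputs and a
#'   summary are written.
#' @return list of class `pipeline_result`: per-stage results (`stages`),
#'   `as_summary`, `deg` (per stage pair), `report`.
#' @export
run_pipeline <- function(sim, alpha = 0.001, min_length = 150L,
                         min_distance = 200L, min_depth = 2L, max_gap = 0L,
                         drop_fraction = 0.2, max_extension = 2000L,
                         outdir = NULL) {
  models <- sim$models
  exon_len <- tapply(sim$models$exons$end - sim$models$exons$start,
                     sim$models$exons$gene_id, sum)
  stage_res <- list()
  for (st in names(sim$stages)) {
    aln <- sim$stages[[st]]$aln
    jx <- assign_junctions(sim$stages[[st]]$junctions, models)
    cov_u <- compute_coverage(aln, sim$contig_lengths, mode = "unique")
    cov_a <- compute_coverage(aln, sim$contig_lengths, mode = "all")
    mapping <- classify_mappings(aln)
    counts <- sim$counts[, st]
    expr <- expression_table(counts, exon_len[names(counts)],
                             total_mapped = mapping$total_reads, stage = st)
    tars <- build_tars(cov_a, min_depth = min_depth, max_gap = max_gap)
    novel <- detect_novel_transcripts(tars, models, cov_a,
                                      min_length = min_length,
                                      min_distance = min_distance,
                                      min_depth = min_depth)
    refinement <- refine_gene_boundaries(models, cov_a,
                                         drop_fraction = drop_fraction,
                                         max_extension = max_extension)
    events <- detect_as_events(models, jx, cov_u)
    gcov <- gene_coverage(cov_u, models)
    stage_res[[st]] <- list(mapping = mapping, expression = expr,
                            tars = tars, novel = novel,
                            refinement = refinement, as_events = events,
                            gene_coverage = gcov)
  }
  as_summary <- summarize_as(lapply(stage_res, `[[`, "as_events"),
                             genes_tested = nrow(models$genes))
  stages <- names(sim$stages)
  deg <- list()
  if (length(stages) >= 2L) {
    prs <- utils::combn(stages, 2L)
    for (k in seq_len(ncol(prs))) {
      a <- prs[1L, k]; b <- prs[2L, k]
      ta <- stage_res[[a]]$mapping$total_reads
      tb <- stage_res[[b]]$mapping$total_reads
      d <- test_differential_expression(sim$counts[, a], sim$counts[, b],
                                        ta, tb, exon_lengths = exon_len)
      cls <- classify_up_down(d, ta, tb, alpha = alpha)
      deg[[paste0(a, "_vs_", b)]] <- cls
    }
  }
  report <- list(
    mapping = do.call(rbind, lapply(stages, function(st) data.frame(
      stage = st, total = stage_res[[st]]$mapping$total_reads,
      unique = stage_res[[st]]$mapping$unique_matched,
      multi = stage_res[[st]]$mapping$multi_position_matched,
      perfect = stage_res[[st]]$mapping$perfect_matched))),
    novel_candidates = vapply(stage_res,
                              function(s) sum(s$novel$reported), 0L),
    as_summary = as_summary,
    deg_counts = do.call(rbind, lapply(names(deg), function(nm) data.frame(
      pair = nm, n_up = deg[[nm]]$n_up, n_down = deg[[nm]]$n_down))))
  res <- structure(list(stages = stage_res, as_summary = as_summary,
                        deg = deg, report = report),
                   class = "pipeline_result")
  if (!is.null(outdir)) write_pipeline_outputs(res, outdir)
  res
}

write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(d, f) utils::write.table(
    d, file.path(outdir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  for (st in names(res$stages)) {
    s <- res$stages[[st]]
    wt(s$expression, paste0("expression_", st, ".tsv"))
    wt(s$novel, paste0("novel_", st, ".tsv"))
    wt(s$refinement, paste0("refinement_", st, ".tsv"))
    wt(s$as_events, paste0("as_events_", st, ".tsv"))
    wt(s$gene_coverage, paste0("gene_coverage_", st, ".tsv"))
  }
  wt(res$as_summary, "as_summary.tsv")
  for (nm in names(res$deg))
    wt(res$deg[[nm]]$results, paste0("deg_", nm, ".tsv"))
  wt(res$report$mapping, "mapping_summary.tsv")
  invisible(outdir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline result over", length(x$stages), "stage(s)\n")
  print(x$report$as_summary)
  if (!is.null(x$report$deg_counts)) print(x$report$deg_counts)
  invisible(x)
}

match_rows <- function(called, truth, tol) {
  # greedy one-to-one matching on (start, end) within tol
  used <- rep(FALSE, nrow(truth))
  hits <- logical(nrow(called))
  for (i in seq_len(nrow(called))) {
    j <- which(!used &
                 abs(truth$start - called$start[i]) <= tol &
                 abs(truth$end - called$end[i]) <= tol)
    if (length(j)) { used[j[1L]] <- TRUE; hits[i] <- TRUE }
  }
  list(tp = sum(hits), fp = sum(!hits), fn = sum(!used))
}

#' Score pipeline recovery of planted features
#'
#' Compares pipeline outputs against the truth manifest of the simulation
#' that produced them. Junction-anchored splicing events are matched exactly;
#' novel units and boundary extensions within `tol` bp (default 20).
#'
#' @param res a `pipeline_result` from [run_pipeline()].
#' @param sim the `sim_experiment` the pipeline ran on.
#' @param stage stage evaluated for coverage-dependent classes (default the
#'   first).
#' @param tol coordinate tolerance for novel units and extensions, bp.
#' @return data.frame per feature class: n_truth, n_called, tp, fp, fn,
#'   sensitivity, precision (NA when nothing was called).
#' @export
evaluate_recovery <- function(res, sim, stage = NULL, tol = 20L) {
  if (is.null(stage)) stage <- names(sim$stages)[1L]
  man <- sim$manifest
  s <- res$stages[[stage]]
  rows <- list()
  score <- function(class, tp, fp, fn) data.frame(
    class = class, n_truth = tp + fn, n_called = tp + fp, tp = tp, fp = fp,
    fn = fn, sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    stringsAsFactors = FALSE)

  # IR: manifest rows, exact intron coordinates
  truth <- man[man$type == "ir" & man$detectable, c("start", "end")]
  called <- s$as_events[s$as_events$type == "IR", ]
  called <- data.frame(start = called$anchor_start, end = called$anchor_end)
  m <- match_rows(called, truth, 0L)
  rows$ir <- score("IR", m$tp, m$fp, m$fn)

  # junction-anchored classes against the expected-event enumeration
  ee <- sim$expected_events
  for (ty in c("ES", "A5SS", "A3SS")) {
    truth <- ee[ee$type == ty, c("anchor_start", "anchor_end")]
    names(truth) <- c("start", "end")
    called <- s$as_events[s$as_events$type == ty, ]
    called <- data.frame(start = called$anchor_start,
                         end = called$anchor_end)
    m <- match_rows(called, truth, 0L)
    rows[[ty]] <- score(ty, m$tp, m$fp, m$fn)
  }

  # novel transcript units
  truth <- man[man$type == "novel" & man$detectable, c("start", "end")]
  called <- s$novel[s$novel$reported, c("start", "end")]
  m <- match_rows(called, truth, tol)
  rows$novel <- score("novel", m$tp, m$fp, m$fn)

  # UTR extensions (genomic right side), within tol bp
  truth <- man[man$type == "utr_ext", ]
  ref <- s$refinement
  rec <- ref$new_end[match(truth$gene_id, ref$gene_id)] -
    ref$old_end[match(truth$gene_id, ref$gene_id)]
  tp <- sum(abs(rec - truth$value) <= tol, na.rm = TRUE)
  rows$ext <- score("extension", tp, 0L, nrow(truth) - tp)

  # planted overlapping genes must be excluded from refinement
  ov <- man[man$type == "overlap", ]
  if (nrow(ov)) {
    exc <- ref$excluded[match(ov$gene_id, ref$gene_id)]
    rows$overlap <- score("overlap_excluded", sum(exc), 0L, sum(!exc))
  }

  # DEG: planted fold changes. Scored only for stochastic simulations: the
  # exact count test assumes sampling noise, and with deterministic counts
  # the library-size shift induced by the planted genes makes every other
  # gene's rate genuinely differ.
  dg <- man[man$type == "deg" & man$detectable, ]
  if (nrow(dg) && !isTRUE(sim$config$clean)) {
    tp <- 0L; fn <- 0L; fp <- 0L
    for (pairnm in names(res$deg)) {
      parts <- strsplit(pairnm, "_vs_")[[1L]]
      cls <- res$deg[[pairnm]]$results
      truth_here <- dg[dg$stage %in% parts, ]
      expect_dir <- ifelse(truth_here$stage == parts[2L],
                           ifelse(truth_here$value > 1, "up", "down"),
                           ifelse(truth_here$value > 1, "down", "up"))
      got <- cls$call[match(truth_here$gene_id, cls$gene_id)]
      tp <- tp + sum(got == expect_dir)
      fn <- fn + sum(got != expect_dir)
      fp <- fp + sum(cls$call != "ns" &
                       !(cls$gene_id %in% truth_here$gene_id))
    }
    rows$deg <- score("DEG", tp, fp, fn)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
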