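#' Mapping summary: uniqueness and mismatch classes
#'
#' Each read is counted once (by `read_id`): unique-matched when it has a
#' single genomic placement, multi-position-matched otherwise;
#' perfect-matched when it aligns with zero mismatches. Per-mismatch-class
#' counts are reported alongside.
#'
#' @param aln an [alignments()] object.
#' @return list of class `mapping_summary` with `total_reads`,
#'   `unique_matched`, `multi_position_matched`, `perfect_matched` and
#'   `by_mismatch` (named integer vector).
#' @export
classify_mappings <- function(aln) {
  r <- aln$reads
  first <- !duplicated(r$read_id)
  conflict <- stats::ave(r$n_positions, r$read_id,
                         FUN = function(v) length(unique(v))) > 1L
  if (any(conflict))
    stop("read '", r$read_id[which(conflict)[1L]],
         "' has conflicting n_positions across records")
  rr <- r[first, ]
  bym <- table(factor(rr$mismatches, levels = 0:max(rr$mismatches, 0L)))
  structure(list(
    total_reads = nrow(rr),
    unique_matched = sum(rr$n_positions == 1L),
    multi_position_matched = sum(rr$n_positions > 1L),
    perfect_matched = sum(rr$mismatches == 0L),
    by_mismatch = stats::setNames(as.integer(bym), names(bym))
  ), class = "mapping_summary")
}

#' @export
print.mapping_summary <- function(x, ...) {
  cat("mapped reads:", x$total_reads,
      "\n  unique matched:", x$unique_matched,
      "\n  multi-position matched:", x$multi_position_matched,
      "\n  perfect matched:", x$perfect_matched, "\n")
  invisible(x)
}

#' Gene coverage fraction
#'
#' Fraction of a gene's bases covered by at least one unique-mapping read.
#' By default the denominator and the covered-base count are restricted to
#' the exonic bases of the gene model; `span = "full"` uses the whole genomic
#' span including introns.
#'
#' @param coverage a unique-mode [compute_coverage()] track.
#' @param models a [gene_models()] object.
#' @param span `"exonic"` (default) or `"full"`.
#' @return data.frame: gene_id, covered_bases, gene_length, fraction.
#' @export
gene_coverage <- function(coverage, models, span = c("exonic", "full")) {
  span <- match.arg(span)
  if (!identical(attr(coverage, "mode"), "unique"))
    warning("gene coverage is defined on unique-mapping coverage")
  g <- models$genes
  missing_ctg <- setdiff(unique(g$contig), names(coverage))
  if (length(missing_ctg))
    stop("gene(s) on contig(s) absent from coverage: ",
         paste(missing_ctg, collapse = ", "))
  res <- lapply(seq_len(nrow(g)), function(i) {
    depth <- coverage[[g$contig[i]]]
    if (span == "exonic") {
      e <- models$exons[models$exons$gene_id == g$gene_id[i], ]
      idx <- unlist(mapply(function(s, t) seq.int(s + 1L, t),
                           e$start, e$end, SIMPLIFY = FALSE))
    } else {
      idx <- seq.int(g$start[i] + 1L, g$end[i])
    }
    cov_b <- sum(depth[idx] >= 1L)
    data.frame(gene_id = g$gene_id[i], covered_bases = cov_b,
               gene_length = length(idx), fraction = cov_b / length(idx),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Relative-position read distribution along genes
#'
#' Each unique-mapping read whose midpoint falls inside a gene span is
#' assigned a relative position (midpoint - gene start) / gene length,
#' measured from the gene's 5' end (mirrored on minus-strand genes), and
#' binned over [0, 1].
#'
#' @param aln an [alignments()] object.
#' @param models a [gene_models()] object.
#' @param n_bins number of equal-width bins (default 100).
#' @return list with `counts` (integer vector of length `n_bins`),
#'   `breaks`, `n_assigned`, `n_excluded` (unique reads outside all genes).
#' @export
relative_position_histogram <- function(aln, models, n_bins = 100L) {
  stopifnot(n_bins >= 2L)
  r <- aln$reads[aln$reads$n_positions == 1L, ]
  g <- models$genes
  mid <- (r$start + r$end) %/% 2L
  pgr <- GenomicRanges::GRanges(r$contig, IRanges::IRanges(mid + 1L, mid + 1L))
  ggr <- GenomicRanges::GRanges(g$contig, IRanges::IRanges(g$start + 1L, g$end))
  hit <- GenomicRanges::findOverlaps(pgr, ggr, select = "first")
  inside <- !is.na(hit)
  gi <- hit[inside]
  rel <- (mid[inside] - g$start[gi]) / (g$end[gi] - g$start[gi])
  flip <- g$strand[gi] == "-"
  rel[flip] <- 1 - rel[flip]
  bin <- pmin(floor(rel * n_bins) + 1L, n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  list(counts = counts,
       breaks = seq(0, 1, length.out = n_bins + 1L),
       n_assigned = sum(inside),
       n_excluded = sum(!inside))
}
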