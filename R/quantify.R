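#' RPKM: reads per kilobase of exon model per million mapped reads
#'
#' `rpkm = 1e9 * count / (total_mapped * exon_length)`, computed on
#' unique-mapping read counts.
#'
#' @param counts named integer vector (gene -> unique-mapped read count).
#' @param exon_lengths named integer vector (gene -> summed exon length, bp);
#'   names must cover `names(counts)`.
#' @param total_mapped total mapped reads in the library (> 0).
#' @return named numeric vector of RPKM values, same order as `counts`.
#' @export
compute_rpkm <- function(counts, exon_lengths, total_mapped) {
  stopifnot(total_mapped > 0)
  if (any(counts < 0)) stop("negative counts")
  len <- exon_lengths[names(counts)]
  if (anyNA(len)) stop("missing exon length for gene(s): ",
                       paste(names(counts)[is.na(len)], collapse = ", "))
  bad <- len <= 0
  if (any(bad)) stop("zero exon length for gene '", names(counts)[bad][1L], "'")
  1e9 * counts / (total_mapped * as.numeric(len))
}

#' Transcriptional-activity cutoff from the RPKM distribution
#'
#' The cutoff for calling a gene transcriptionally active is taken from a 95%
#' interval over the observed RPKM values. The default is assumption-free:
#' the empirical 2.5th percentile of the positive RPKM values; a normal-theory
#' alternative (mean - 1.96 sd over positive values) is selectable. A gene is
#' active iff its RPKM is at or above the cutoff.
#'
#' @param rpkm named numeric vector of RPKM values (>= 2 values).
#' @param method `"percentile"` (default) or `"normal"`.
#' @param level interval level, default 0.95.
#' @return list with `cutoff` (numeric, >= 0), `active` (named logical) and
#'   `degenerate` (TRUE when all values are zero).
#' @export
activity_cutoff <- function(rpkm, method = c("percentile", "normal"),
                            level = 0.95) {
  method <- match.arg(method)
  stopifnot(length(rpkm) >= 2L, level > 0, level < 1)
  pos <- rpkm[rpkm > 0]
  if (length(pos) == 0L)
    return(list(cutoff = 0, active = stats::setNames(rep(FALSE, length(rpkm)),
                                                     names(rpkm)),
                degenerate = TRUE))
  cutoff <- if (method == "percentile") {
    as.numeric(stats::quantile(pos, probs = (1 - level) / 2, names = FALSE))
  } else {
    max(0, mean(pos) - stats::qnorm(1 - (1 - level) / 2) * stats::sd(pos))
  }
  list(cutoff = cutoff,
       active = stats::setNames(rpkm >= cutoff, names(rpkm)),
       degenerate = FALSE)
}

#' Per-stage expression table
#'
#' Convenience wrapper combining [compute_rpkm()] and [activity_cutoff()]
#' into the per-gene per-stage expression record.
#'
#' @param counts named vector of unique-mapped read counts for one stage.
#' @param exon_lengths named vector of exon-model lengths (bp).
#' @param total_mapped total mapped reads for the stage.
#' @param stage stage label (e.g. `"3d"`).
#' @param ... passed to [activity_cutoff()].
#' @return data.frame: gene_id, stage, count, exon_length, rpkm, active.
#' @export
expression_table <- function(counts, exon_lengths, total_mapped, stage, ...) {
  rpkm <- compute_rpkm(counts, exon_lengths, total_mapped)
  act <- activity_cutoff(rpkm, ...)
  data.frame(gene_id = names(counts), stage = stage,
             count = as.integer(counts),
             exon_length = as.integer(exon_lengths[names(counts)]),
             rpkm = as.numeric(rpkm), active = as.logical(act$active),
             stringsAsFactors = FALSE)
}
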