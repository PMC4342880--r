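#' Build transcription active regions (TARs)
#'
#' A TAR is a maximal run of bases whose read depth reaches `min_depth`;
#' runs separated by at most `max_gap` uncovered bases are merged. TARs are
#' the raw expressed units used for novel-transcript discovery and gene-model
#' linking.
#'
#' @param coverage a [compute_coverage()] track (typically all-reads mode).
#' @param min_depth minimum per-base depth inside a TAR (default 2).
#' @param max_gap largest below-threshold gap to bridge, bp (default 0).
#' @param aln optional [alignments()] object; when given, `n_reads` counts
#'   the reads whose span overlaps each TAR.
#' @return data.frame: contig, start, end (0-based half-open), length,
#'   mean_depth, n_reads (NA unless `aln` supplied).
#' @export
build_tars <- function(coverage, min_depth = 2L, max_gap = 0L, aln = NULL) {
  stopifnot(min_depth >= 1L, max_gap >= 0L)
  out <- lapply(names(coverage), function(cn) {
    depth <- coverage[[cn]]
    hit <- which(depth >= min_depth)
    if (length(hit) == 0L) return(NULL)
    ir <- IRanges::reduce(IRanges::IRanges(hit, hit),
                          min.gapwidth = max_gap + 1L)
    s <- IRanges::start(ir) - 1L
    e <- IRanges::end(ir)
    md <- vapply(seq_along(s),
                 function(i) mean(depth[(s[i] + 1L):e[i]]), numeric(1))
    data.frame(contig = cn, start = s, end = e, length = e - s,
               mean_depth = md, n_reads = NA_integer_,
               stringsAsFactors = FALSE)
  })
  tars <- do.call(rbind, out)
  if (is.null(tars))
    tars <- data.frame(contig = character(0), start = integer(0),
                       end = integer(0), length = integer(0),
                       mean_depth = numeric(0), n_reads = integer(0))
  rownames(tars) <- NULL
  if (!is.null(aln) && nrow(tars)) {
    tgr <- GenomicRanges::GRanges(tars$contig,
                                  IRanges::IRanges(tars$start + 1L, tars$end))
    rgr <- GenomicRanges::GRanges(aln$reads$contig,
                                  IRanges::IRanges(aln$reads$start + 1L,
                                                   aln$reads$end))
    tars$n_reads <- GenomicRanges::countOverlaps(tgr, rgr)
  }
  tars
}

#' Detect candidate novel transcripts among intergenic TARs
#'
#' A TAR that overlaps no annotated gene is a candidate novel transcript when
#' all three rules hold: (1) length strictly greater than `min_length`;
#' (2) the nearest annotated gene boundary is at least `min_distance` bp away
#' on both sides; (3) its mean depth exceeds the local background, defined as
#' the mean all-reads depth over `bg_window` bp flanking windows with genic
#' bases excluded, and also exceeds `min_depth`.
#'
#' @param tars output of [build_tars()].
#' @param models a [gene_models()] object.
#' @param coverage all-reads [compute_coverage()] track (for background).
#' @param min_length length rule threshold, bp (default 150, strict `>`).
#' @param min_distance intergenic distance rule, bp (default 200, `>=`).
#' @param bg_window flanking background window, bp (default 1000).
#' @param min_depth depth floor for the expression rule (default 2).
#' @return data.frame with one row per intergenic TAR: coordinates,
#'   mean_depth, distance_to_nearest_gene, background_depth, pass_length,
#'   pass_distance, pass_expression, reported.
#' @export
detect_novel_transcripts <- function(tars, models, coverage,
                                     min_length = 150L, min_distance = 200L,
                                     bg_window = 1000L, min_depth = 2L) {
  g <- models$genes
  if (nrow(tars) == 0L)
    return(cbind(tars[, c("contig", "start", "end", "length", "mean_depth")],
                 data.frame(distance_to_nearest_gene = numeric(0),
                            background_depth = numeric(0),
                            pass_length = logical(0),
                            pass_distance = logical(0),
                            pass_expression = logical(0),
                            reported = logical(0))))
  tgr <- GenomicRanges::GRanges(tars$contig,
                                IRanges::IRanges(tars$start + 1L, tars$end))
  ggr <- GenomicRanges::GRanges(g$contig, IRanges::IRanges(g$start + 1L, g$end))
  genic <- GenomicRanges::countOverlaps(tgr, ggr) > 0L
  keep <- which(!genic)
  res <- lapply(keep, function(i) {
    depth <- coverage[[tars$contig[i]]]
    clen <- length(depth)
    same <- g$contig == tars$contig[i]
    # boundary-to-boundary distance to the nearest gene on this contig
    dist <- if (any(same)) {
      d_up <- tars$start[i] - g$end[same]    # gene upstream of TAR
      d_dn <- g$start[same] - tars$end[i]    # gene downstream of TAR
      min(pmax(d_up, d_dn))                  # genes never overlap the TAR here
    } else Inf
    # background: mean depth over flanking windows, genic bases excluded
    win <- c(seq.int(max(1L, tars$start[i] - bg_window + 1L), tars$start[i]),
             seq.int(min(clen, tars$end[i] + 1L),
                     min(clen, tars$end[i] + bg_window)))
    win <- unique(win[win >= 1L & win <= clen])
    if (any(same)) {
      genic_pos <- unlist(mapply(function(s, e) seq.int(s + 1L, e),
                                 g$start[same], g$end[same], SIMPLIFY = FALSE))
      win <- setdiff(win, genic_pos)
    }
    bg <- if (length(win)) mean(depth[win]) else 0
    p_len <- tars$length[i] > min_length
    p_dist <- dist >= min_distance
    p_expr <- tars$mean_depth[i] > max(bg, min_depth)
    data.frame(contig = tars$contig[i], start = tars$start[i],
               end = tars$end[i], length = tars$length[i],
               mean_depth = tars$mean_depth[i],
               distance_to_nearest_gene = dist, background_depth = bg,
               pass_length = p_len, pass_distance = p_dist,
               pass_expression = p_expr,
               reported = p_len && p_dist && p_expr,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(contig = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      mean_depth = numeric(0),
                      distance_to_nearest_gene = numeric(0),
                      background_depth = numeric(0),
                      pass_length = logical(0), pass_distance = logical(0),
                      pass_expression = logical(0), reported = logical(0))
  rownames(out) <- NULL
  out
}
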