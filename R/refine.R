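#' Link TARs into potential gene models using mate pairs
#'
#' Builds an undirected graph on TARs where the weight of an edge is the
#' number of read pairs with one mate overlapping each of the two TARs.
#' Edges below `min_pairs` are dropped; the connected components of the
#' remaining graph (including singleton TARs) are the linked gene models.
#'
#' @param tars output of [build_tars()].
#' @param aln an [alignments()] object carrying `mate_id` links.
#' @param min_pairs minimum supporting mate pairs per link (default 2).
#' @return list of class `linked_models`: each element has `tars` (row
#'   indices into `tars`, ordered by start) and `support` (total mate pairs
#'   on the component's edges; 0 for singletons).
#' @export
link_tars <- function(tars, aln, min_pairs = 2L) {
  if (nrow(tars) == 0L) return(structure(list(), class = "linked_models"))
  tgr <- GenomicRanges::GRanges(tars$contig,
                                IRanges::IRanges(tars$start + 1L, tars$end))
  r <- aln$reads
  paired <- which(!is.na(r$mate_id))
  edges <- NULL
  if (length(paired)) {
    rgr <- GenomicRanges::GRanges(r$contig[paired],
                                  IRanges::IRanges(r$start[paired] + 1L,
                                                   r$end[paired]))
    hit <- GenomicRanges::findOverlaps(rgr, tgr, select = "first")
    byp <- split(hit, r$mate_id[paired])
    byp <- byp[vapply(byp, length, 1L) == 2L]
    tt <- vapply(byp, function(v) sort(v), integer(2))
    ok <- !is.na(tt[1L, ]) & !is.na(tt[2L, ]) & tt[1L, ] != tt[2L, ]
    if (any(ok)) {
      key <- paste(tt[1L, ok], tt[2L, ok])
      w <- table(key)
      ij <- do.call(rbind, strsplit(names(w), " "))
      edges <- data.frame(i = as.integer(ij[, 1L]), j = as.integer(ij[, 2L]),
                          weight = as.integer(w))
      edges <- edges[edges$weight >= min_pairs, , drop = FALSE]
    }
  }
  gr <- igraph::make_empty_graph(n = nrow(tars), directed = FALSE)
  if (!is.null(edges) && nrow(edges))
    gr <- igraph::add_edges(gr, rbind(edges$i, edges$j),
                            weight = edges$weight)
  comp <- igraph::components(gr)
  out <- lapply(seq_len(comp$no), function(k) {
    m <- which(comp$membership == k)
    m <- m[order(tars$start[m])]
    supp <- 0L
    if (!is.null(edges) && nrow(edges))
      supp <- sum(edges$weight[edges$i %in% m & edges$j %in% m])
    list(tars = m, support = supp)
  })
  structure(out, class = "linked_models")
}

#' @export
print.linked_models <- function(x, ...) {
  sizes <- vapply(x, function(m) length(m$tars), 1L)
  cat("linked gene models:", length(x), "components;",
      sum(sizes > 1L), "multi-TAR\n")
  invisible(x)
}

scan_extension <- function(depth, positions, threshold, sustain) {
  # positions: 0-based bases walking outward from the boundary.
  # Extension ends at the first sustained (>= sustain bp) drop below
  # threshold; a below-threshold run touching the scan limit also stops it.
  if (length(positions) == 0L) return(0L)
  ok <- depth[positions + 1L] >= threshold
  if (all(ok)) return(length(positions))
  r <- rle(!ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  stop_run <- which(r$values & (r$lengths >= sustain | ends == length(ok)))
  if (length(stop_run) == 0L) return(length(positions))
  starts[stop_run[1L]] - 1L
}

#' Refine annotated gene boundaries from read signal
#'
#' Extends each gene's 5' and 3' boundaries outward while the all-reads depth
#' stays at or above `drop_fraction` times the depth at the annotated
#' boundary; a sharp reduction (depth below that threshold sustained for at
#' least `sustain` bp) ends the extension. Walks are capped at
#' `max_extension` bp and at the nearest neighboring gene. Genes whose
#' annotated span overlaps another gene are excluded.
#'
#' @param models a [gene_models()] object.
#' @param coverage all-reads [compute_coverage()] track.
#' @param drop_fraction fraction of the boundary depth defining a sharp
#'   reduction (default 0.2).
#' @param max_extension longest allowed extension per end, bp (default 2000).
#' @param sustain length of below-threshold run that ends a walk, bp
#'   (default 10).
#' @return data.frame: gene_id, old_start, old_end, new_start, new_end,
#'   extended_5p, extended_3p (by gene strand), excluded, reason.
#' @export
refine_gene_boundaries <- function(models, coverage, drop_fraction = 0.2,
                                   max_extension = 2000L, sustain = 10L) {
  g <- models$genes
  ggr <- GenomicRanges::GRanges(g$contig, IRanges::IRanges(g$start + 1L, g$end))
  n_ov <- GenomicRanges::countOverlaps(ggr, ggr)
  res <- lapply(seq_len(nrow(g)), function(i) {
    base <- data.frame(gene_id = g$gene_id[i], old_start = g$start[i],
                       old_end = g$end[i], new_start = g$start[i],
                       new_end = g$end[i], extended_5p = 0L, extended_3p = 0L,
                       excluded = FALSE, reason = NA_character_,
                       stringsAsFactors = FALSE)
    if (n_ov[i] > 1L) {
      base$excluded <- TRUE
      base$reason <- "boundary overlaps another gene"
      return(base)
    }
    depth <- coverage[[g$contig[i]]]
    clen <- length(depth)
    same <- which(g$contig == g$contig[i])
    same <- same[same != i]
    # walk left from the start boundary
    left_limit <- max(0L, g$start[i] - max_extension)
    if (length(same)) {
      ne <- g$end[same][g$end[same] <= g$start[i]]
      if (length(ne)) left_limit <- max(left_limit, max(ne))
    }
    d_start <- depth[g$start[i] + 1L]
    ext_left <- 0L
    if (d_start > 0 && g$start[i] > left_limit) {
      pos <- seq.int(g$start[i] - 1L, left_limit, by = -1L)
      ext_left <- scan_extension(depth, pos, drop_fraction * d_start, sustain)
    }
    # walk right from the end boundary
    right_limit <- min(clen, g$end[i] + max_extension)
    if (length(same)) {
      ns <- g$start[same][g$start[same] >= g$end[i]]
      if (length(ns)) right_limit <- min(right_limit, min(ns))
    }
    d_end <- depth[g$end[i]]
    ext_right <- 0L
    if (d_end > 0 && g$end[i] < right_limit) {
      pos <- seq.int(g$end[i], right_limit - 1L)
      ext_right <- scan_extension(depth, pos, drop_fraction * d_end, sustain)
    }
    base$new_start <- g$start[i] - ext_left
    base$new_end <- g$end[i] + ext_right
    if (g$strand[i] == "-") {
      base$extended_5p <- ext_right
      base$extended_3p <- ext_left
    } else {
      base$extended_5p <- ext_left
      base$extended_3p <- ext_right
    }
    base
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
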