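#' Detect exon-skipping events
#'
#' An exon-skipping (ES) event is a junction whose donor matches the
#' annotated donor of exon *i* and whose acceptor matches the annotated
#' acceptor of exon *j* with *j >= i + 2* (genomic exon order): the junction
#' splices past at least one annotated internal exon.
#'
#' @param models a [gene_models()] object (one gene or many).
#' @param jx a [junctions()] table with a `gene_id` column (see
#'   [assign_junctions()]).
#' @param tolerance allowed deviation, bp, between junction and annotated
#'   splice-site coordinates (default 0 = exact match).
#' @return data.frame of events: gene_id, type ("ES"), donor, acceptor,
#'   skipped_exons (comma-separated genomic exon ranks), support.
#' @export
detect_exon_skipping <- function(models, jx, tolerance = 0L) {
  out <- lapply(unique(models$genes$gene_id), function(gid) {
    ex <- models$exons[models$exons$gene_id == gid, ]
    ex <- ex[order(ex$start), ]
    if (nrow(ex) < 3L) return(NULL)
    j <- jx[!is.na(jx$gene_id) & jx$gene_id == gid, , drop = FALSE]
    if (nrow(j) == 0L) return(NULL)
    donors <- ex$end - 1L       # last base of each exon
    acceptors <- ex$start       # first base of each exon
    res <- lapply(seq_len(nrow(j)), function(k) {
      di <- which(abs(donors - j$donor[k]) <= tolerance)
      aj <- which(abs(acceptors - j$acceptor[k]) <= tolerance)
      if (length(di) != 1L || length(aj) != 1L || aj < di + 2L) return(NULL)
      data.frame(gene_id = gid, type = "ES", donor = j$donor[k],
                 acceptor = j$acceptor[k],
                 skipped_exons = paste(seq.int(di + 1L, aj - 1L),
                                       collapse = ","),
                 support = j$support[k], stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(gene_id = character(0), type = character(0),
                      donor = integer(0), acceptor = integer(0),
                      skipped_exons = character(0), support = integer(0))
  unique(out)
}

intron_overlaps_other_gene <- function(contig, istart, iend, gid, models) {
  g <- models$genes
  other <- g$gene_id != gid & g$contig == contig
  any(other & g$start < iend & g$end > istart)
}

#' Detect intron-retention events
#'
#' For each annotated intron (between consecutive exons Exon1 and Exon2), an
#' intron-retention (IR) event is called iff all five conditions hold:
#' 1. the intron's own junction is present in the junction set;
#' 2. at least `min_cov_frac` (default 90%) of intron bases are covered by
#'    unique-mapping reads (depth >= 1);
#' 3. the intron's mean depth is at least `min_depth_ratio` (default 15%) of
#'    the larger of the two flanking exons' mean depths;
#' 4. every base of the 5 bp windows immediately inside and outside both
#'    intron boundaries is covered (depth >= 1);
#' 5. the intron interval overlaps no other gene's span.
#'
#' @param models a [gene_models()] object.
#' @param jx junction table with `gene_id` column.
#' @param coverage unique-mode [compute_coverage()] track.
#' @param min_cov_frac condition-2 threshold (default 0.90, inclusive).
#' @param min_depth_ratio condition-3 threshold (default 0.15, inclusive).
#' @param flank condition-4 window size, bp (default 5).
#' @param exon_stat `"mean"` (default) or `"median"` exon depth summary.
#' @param exon_combine `"max"` (default) or `"min"` over the two exons.
#' @return data.frame of events: gene_id, type ("IR"), intron coordinates,
#'   the five condition flags, coverage fraction and depth ratio.
#' @export
detect_intron_retention <- function(models, jx, coverage,
                                    min_cov_frac = 0.90,
                                    min_depth_ratio = 0.15, flank = 5L,
                                    exon_stat = c("mean", "median"),
                                    exon_combine = c("max", "min")) {
  exon_stat <- match.arg(exon_stat)
  exon_combine <- match.arg(exon_combine)
  stat <- if (exon_stat == "mean") mean else stats::median
  comb <- if (exon_combine == "max") max else min
  intr <- introns_of(models)
  if (nrow(intr) == 0L) return(ir_empty())
  res <- lapply(seq_len(nrow(intr)), function(i) {
    gid <- intr$gene_id[i]
    ctg <- intr$contig[i]
    is0 <- intr$start[i]; ie0 <- intr$end[i]
    depth <- coverage[[ctg]]
    j <- jx[!is.na(jx$gene_id) & jx$gene_id == gid, , drop = FALSE]
    jc <- junction_of_intron(is0, ie0)
    c1 <- any(j$donor == jc$donor & j$acceptor == jc$acceptor)
    ibase <- depth[(is0 + 1L):ie0]
    cov_frac <- mean(ibase >= 1L)
    c2 <- cov_frac >= min_cov_frac
    ex <- models$exons[models$exons$gene_id == gid, ]
    ex <- ex[order(ex$start), ]
    k <- intr$intron_rank[i]
    e1 <- depth[(ex$start[k] + 1L):ex$end[k]]
    e2 <- depth[(ex$start[k + 1L] + 1L):ex$end[k + 1L]]
    exd <- comb(stat(e1), stat(e2))
    ratio <- if (exd > 0) mean(ibase) / exd else Inf
    c3 <- mean(ibase) >= min_depth_ratio * exd
    wins <- c(seq.int(is0 - flank + 1L, is0),            # outside, donor side
              seq.int(is0 + 1L, is0 + flank),            # inside, donor side
              seq.int(ie0 - flank + 1L, ie0),            # inside, acceptor side
              seq.int(ie0 + 1L, ie0 + flank))            # outside, acceptor side
    wins <- wins[wins >= 1L & wins <= length(depth)]
    c4 <- all(depth[wins] >= 1L)
    c5 <- !intron_overlaps_other_gene(ctg, is0, ie0, gid, models)
    if (!(c1 && c2 && c3 && c4 && c5)) return(NULL)
    data.frame(gene_id = gid, type = "IR", intron_start = is0,
               intron_end = ie0, junction_present = c1,
               coverage_fraction = cov_frac, depth_ratio = ratio,
               flanks_covered = c4, no_gene_overlap = c5,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) return(ir_empty())
  rownames(out) <- NULL
  out
}

ir_empty <- function() {
  data.frame(gene_id = character(0), type = character(0),
             intron_start = integer(0), intron_end = integer(0),
             junction_present = logical(0), coverage_fraction = numeric(0),
             depth_ratio = numeric(0), flanks_covered = logical(0),
             no_gene_overlap = logical(0))
}

#' Detect alternative 5'/3' splice-site events
#'
#' Junction pairs assigned to one gene that share their acceptor but differ
#' in donor give one alternative-5'-splice-site (A5SS) event per pair; pairs
#' sharing the donor but differing in acceptor give one A3SS event. Labels
#' follow the genomic (plus-strand) donor/acceptor convention, matching an
#' unstranded library; with `use_strand = TRUE` labels are swapped on
#' minus-strand genes.
#'
#' @param models a [gene_models()] object.
#' @param jx junction table with `gene_id` column.
#' @param use_strand swap A5SS/A3SS labels on minus-strand genes
#'   (default FALSE).
#' @return data.frame of events: gene_id, type, donor1, acceptor1, donor2,
#'   acceptor2, support (sum of the two junctions).
#' @export
detect_alt_splice_sites <- function(models, jx, use_strand = FALSE) {
  out <- lapply(unique(models$genes$gene_id), function(gid) {
    j <- jx[!is.na(jx$gene_id) & jx$gene_id == gid, , drop = FALSE]
    j <- unique(j[, c("donor", "acceptor", "support")])
    # duplicated (donor, acceptor) with distinct support: keep max support
    j <- j[order(j$donor, j$acceptor, -j$support), ]
    j <- j[!duplicated(j[, c("donor", "acceptor")]), , drop = FALSE]
    if (nrow(j) < 2L) return(NULL)
    prs <- utils::combn(nrow(j), 2L)
    res <- lapply(seq_len(ncol(prs)), function(k) {
      a <- prs[1L, k]; b <- prs[2L, k]
      type <- if (j$acceptor[a] == j$acceptor[b] && j$donor[a] != j$donor[b])
        "A5SS"
      else if (j$donor[a] == j$donor[b] && j$acceptor[a] != j$acceptor[b])
        "A3SS"
      else return(NULL)
      if (use_strand &&
          models$genes$strand[models$genes$gene_id == gid] == "-")
        type <- if (type == "A5SS") "A3SS" else "A5SS"
      data.frame(gene_id = gid, type = type,
                 donor1 = j$donor[a], acceptor1 = j$acceptor[a],
                 donor2 = j$donor[b], acceptor2 = j$acceptor[b],
                 support = j$support[a] + j$support[b],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(gene_id = character(0), type = character(0),
                      donor1 = integer(0), acceptor1 = integer(0),
                      donor2 = integer(0), acceptor2 = integer(0),
                      support = integer(0))
  rownames(out) <- NULL
  out
}

#' Detect all four alternative-splicing event types for one sample
#'
#' Runs [detect_exon_skipping()], [detect_intron_retention()] and
#' [detect_alt_splice_sites()] and combines the events into one table.
#'
#' @param models a [gene_models()] object.
#' @param jx a [junctions()] table (assigned to genes if not already).
#' @param coverage unique-mode coverage track.
#' @param ... threshold arguments passed to the detectors.
#' @return data.frame: gene_id, type, anchor_start, anchor_end, support.
#' @export
detect_as_events <- function(models, jx, coverage, ...) {
  if (is.null(jx$gene_id)) jx <- assign_junctions(jx, models)
  dots <- list(...)
  pick <- function(f) dots[names(dots) %in% names(formals(f))]
  es <- do.call(detect_exon_skipping,
                c(list(models, jx), pick(detect_exon_skipping)))
  ir <- do.call(detect_intron_retention,
                c(list(models, jx, coverage), pick(detect_intron_retention)))
  ass <- do.call(detect_alt_splice_sites,
                 c(list(models, jx), pick(detect_alt_splice_sites)))
  rows <- list()
  if (nrow(es))
    rows$es <- data.frame(gene_id = es$gene_id, type = es$type,
                          anchor_start = es$donor, anchor_end = es$acceptor,
                          support = es$support, stringsAsFactors = FALSE)
  if (nrow(ir))
    rows$ir <- data.frame(gene_id = ir$gene_id, type = ir$type,
                          anchor_start = ir$intron_start,
                          anchor_end = ir$intron_end, support = NA_integer_,
                          stringsAsFactors = FALSE)
  if (nrow(ass))
    rows$ass <- data.frame(gene_id = ass$gene_id, type = ass$type,
                           anchor_start = pmin(ass$donor1, ass$donor2),
                           anchor_end = pmax(ass$acceptor1, ass$acceptor2),
                           support = ass$support, stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(0), type = character(0),
                      anchor_start = integer(0), anchor_end = integer(0),
                      support = integer(0))
  out <- unique(out)
  rownames(out) <- NULL
  out
}

#' Summarize alternative-splicing events per stage
#'
#' @param events_by_stage named list (stage -> event table from
#'   [detect_as_events()] or a compatible data.frame with `gene_id`, `type`).
#' @param genes_tested number of genes examined (denominator of the AS
#'   fraction).
#' @return data.frame per stage: stage, genes_with_as, n_events, counts per
#'   type, fraction_genes_as, ir_fraction.
#' @export
summarize_as <- function(events_by_stage, genes_tested) {
  types <- c("ES", "IR", "A5SS", "A3SS")
  out <- lapply(names(events_by_stage), function(st) {
    ev <- events_by_stage[[st]]
    cnt <- vapply(types, function(t) sum(ev$type == t), 1L)
    n_ev <- nrow(ev)
    data.frame(stage = st, genes_with_as = length(unique(ev$gene_id)),
               n_events = n_ev, ES = cnt[["ES"]], IR = cnt[["IR"]],
               A5SS = cnt[["A5SS"]], A3SS = cnt[["A3SS"]],
               fraction_genes_as = length(unique(ev$gene_id)) / genes_tested,
               ir_fraction = if (n_ev > 0) cnt[["IR"]] / n_ev else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
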