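#' Construct a splice-junction table
#'
#' A junction records the last base of the upstream (donor-side) exon and the
#' first base of the downstream (acceptor-side) exon, both 0-based. The
#' intron it implies is the half-open interval `[donor + 1, acceptor)`.
#'
#' @param contig,donor,acceptor,support,strand vectors of equal length;
#'   `support` is the spanning-read count (>= 1), strand defaults to `"*"`.
#' @return data.frame of class `junctions`.
#' @export
junctions <- function(contig, donor, acceptor, support = 1L, strand = "*") {
  d <- data.frame(contig = as.character(contig), donor = as.integer(donor),
                  acceptor = as.integer(acceptor),
                  support = as.integer(support),
                  strand = as.character(strand), stringsAsFactors = FALSE)
  if (any(d$donor >= d$acceptor)) stop("junction must have donor < acceptor")
  if (any(d$support < 1L)) stop("junction support must be >= 1")
  class(d) <- c("junctions", "data.frame")
  d
}

#' Junction coordinates of an intron interval
#'
#' @param start,end intron interval, 0-based half-open.
#' @return list with `donor` (= start - 1) and `acceptor` (= end).
#' @export
junction_of_intron <- function(start, end) {
  list(donor = as.integer(start) - 1L, acceptor = as.integer(end))
}

#' Read junctions from BED6+1
#'
#' Columns: contig, donor (0-based last exonic base upstream), acceptor
#' (0-based first exonic base downstream), name, score, strand, support.
#'
#' @param path input file.
#' @return a [junctions()] table.
#' @export
read_junctions <- function(path) {
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 7L) stop("junction BED6+1 needs 7 columns, got ", ncol(d))
  junctions(contig = d[[1L]], donor = d[[2L]], acceptor = d[[3L]],
            support = d[[7L]], strand = d[[6L]])
}

#' Write junctions as BED6+1
#'
#' @param jx a [junctions()] table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_junctions <- function(jx, path) {
  lines <- paste(jx$contig, jx$donor, jx$acceptor,
                 sprintf("JUNC%05d", seq_len(nrow(jx))), 0L,
                 ifelse(jx$strand == "*", ".", jx$strand), jx$support,
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Assign junctions to genes by containment
#'
#' A junction belongs to a gene iff both its donor and acceptor positions fall
#' within the gene's genomic span. Junctions whose donor and acceptor fall in
#' two different genes are assigned to neither.
#'
#' @param jx a [junctions()] table.
#' @param models a [gene_models()] object.
#' @return `jx` with an added `gene_id` column (NA where unassigned).
#' @export
assign_junctions <- function(jx, models) {
  g <- models$genes
  ggr <- GenomicRanges::GRanges(g$contig, IRanges::IRanges(g$start + 1L, g$end))
  pos_gene <- function(pos) {
    pgr <- GenomicRanges::GRanges(jx$contig, IRanges::IRanges(pos + 1L, pos + 1L))
    hit <- GenomicRanges::findOverlaps(pgr, ggr, select = "first")
    hit
  }
  hd <- pos_gene(jx$donor)
  ha <- pos_gene(jx$acceptor)
  gene <- ifelse(!is.na(hd) & !is.na(ha) & hd == ha, hd, NA_integer_)
  spanning <- !is.na(hd) & !is.na(ha) & hd != ha
  if (any(spanning))
    message(sum(spanning), " junction(s) span two genes; assigned to neither")
  jx$gene_id <- ifelse(is.na(gene), NA_character_, g$gene_id[gene])
  jx
}
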