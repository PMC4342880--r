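#' Construct a set of gene models
#'
#' Gene models are held as two data frames: one row per gene and one row per
#' exon. All coordinates are 0-based half-open; conversion to and from the
#' 1-based inclusive convention of GTF happens only at I/O time.
#'
#' @param exons data.frame with columns `gene_id`, `contig`, `start`, `end`
#'   and optionally `strand` (`"+"`, `"-"` or `"*"`). Coordinates 0-based
#'   half-open. Exons of one gene must not overlap.
#' @return An object of class `gene_models`: a list with elements `genes`
#'   (gene_id, contig, start, end, strand, n_exons) and `exons` (gene_id,
#'   contig, start, end, strand, exon_rank), exons sorted by start within
#'   gene.
#' @export
gene_models <- function(exons) {
  stopifnot(is.data.frame(exons),
            all(c("gene_id", "contig", "start", "end") %in% names(exons)))
  if (is.null(exons$strand)) exons$strand <- "*"
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (any(exons$start < 0L) || any(exons$end <= exons$start))
    stop("exon intervals must satisfy 0 <= start < end")

  keep <- split(seq_len(nrow(exons)), exons$gene_id)
  drop_genes <- character(0)
  for (g in names(keep)) {
    idx <- keep[[g]][order(exons$start[keep[[g]]])]
    keep[[g]] <- idx
    if (length(idx) > 1L) {
      s <- exons$start[idx]; e <- exons$end[idx]
      if (any(s[-1L] < e[-length(e)])) {
        warning("gene '", g, "' has overlapping exons; record rejected")
        drop_genes <- c(drop_genes, g)
      }
    }
    if (length(unique(exons$contig[idx])) > 1L)
      stop("gene '", g, "' has exons on multiple contigs")
  }
  keep <- keep[!names(keep) %in% drop_genes]
  ord <- unlist(keep, use.names = FALSE)
  ex <- exons[ord, c("gene_id", "contig", "start", "end", "strand")]
  rownames(ex) <- NULL
  ex$exon_rank <- unlist(lapply(keep, seq_along), use.names = FALSE)

  genes <- do.call(rbind, lapply(keep, function(idx) {
    data.frame(gene_id = exons$gene_id[idx[1L]],
               contig = exons$contig[idx[1L]],
               start = min(exons$start[idx]),
               end = max(exons$end[idx]),
               strand = exons$strand[idx[1L]],
               n_exons = length(idx),
               stringsAsFactors = FALSE)
  }))
  rownames(genes) <- NULL
  structure(list(genes = genes, exons = ex), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$genes), "genes,", nrow(x$exons), "exons on",
      length(unique(x$genes$contig)), "contig(s)\n")
  invisible(x)
}

#' Introns of gene models
#'
#' Introns are the gaps between consecutive exons of each gene, in 0-based
#' half-open coordinates.
#'
#' @param models a `gene_models` object.
#' @return data.frame with `gene_id`, `contig`, `start`, `end`, `strand`,
#'   `intron_rank` (1 = between exon 1 and exon 2 in genomic order).
#' @export
introns_of <- function(models) {
  ex <- models$exons
  out <- lapply(split(ex, ex$gene_id), function(d) {
    if (nrow(d) < 2L) return(NULL)
    d <- d[order(d$start), ]
    data.frame(gene_id = d$gene_id[1L], contig = d$contig[1L],
               start = d$end[-nrow(d)], end = d$start[-1L],
               strand = d$strand[1L],
               intron_rank = seq_len(nrow(d) - 1L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    return(data.frame(gene_id = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), intron_rank = integer(0)))
  rownames(out) <- NULL
  out
}

#' Read gene models from GTF/GFF3 or BED12
#'
#' Exon features are grouped per gene; coordinates are converted from the
#' source convention (1-based inclusive) to the internal 0-based half-open
#' convention. Genes with overlapping exons are rejected with a warning.
#'
#' @param path annotation file; format taken from the extension
#'   (`.gtf`/`.gff`/`.gff3` or `.bed`).
#' @return a [gene_models()] object.
#' @export
read_gene_models <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gtf", "gff", "gff3")) {
    gr <- rtracklayer::import(path)
    gr <- gr[tolower(as.character(gr$type)) == "exon"]
    if (length(gr) == 0L) stop("no exon features in ", path)
    gid <- gr$gene_id
    if (is.null(gid)) gid <- gr$Parent
    gid <- as.character(gid)
    ex <- data.frame(gene_id = gid,
                     contig = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1L,
                     end = GenomicRanges::end(gr),
                     strand = as.character(GenomicRanges::strand(gr)),
                     stringsAsFactors = FALSE)
  } else if (ext == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    bl <- rtracklayer::blocks(gr)
    n <- S4Vectors::elementNROWS(bl)
    flat <- unlist(bl, use.names = FALSE)
    ex <- data.frame(gene_id = rep(gr$name, n),
                     contig = as.character(GenomicRanges::seqnames(flat)),
                     start = GenomicRanges::start(flat) - 1L,
                     end = GenomicRanges::end(flat),
                     strand = rep(as.character(GenomicRanges::strand(gr)), n),
                     stringsAsFactors = FALSE)
  } else stop("unsupported annotation format: ", ext)
  gene_models(ex)
}

#' Write gene models to GTF or BED12
#'
#' @param models a `gene_models` object.
#' @param path output file; `.gtf` or `.bed` extension selects the format.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  ext <- tolower(tools::file_ext(path))
  ex <- models$exons
  if (ext == "gtf") {
    gr <- GenomicRanges::GRanges(
      seqnames = ex$contig,
      ranges = IRanges::IRanges(ex$start + 1L, ex$end),
      strand = ifelse(ex$strand == "*", "*", ex$strand))
    gr$type <- "exon"
    gr$source <- "tarsplice"
    gr$gene_id <- ex$gene_id
    gr$transcript_id <- paste0(ex$gene_id, ".t1")
    rtracklayer::export(gr, path, format = "gtf")
  } else if (ext == "bed") {
    g <- models$genes
    lines <- vapply(seq_len(nrow(g)), function(i) {
      e <- ex[ex$gene_id == g$gene_id[i], ]
      e <- e[order(e$start), ]
      paste(g$contig[i], g$start[i], g$end[i], g$gene_id[i], 0L,
            ifelse(g$strand[i] == "*", ".", g$strand[i]),
            g$start[i], g$end[i], "0", nrow(e),
            paste0(paste(e$end - e$start, collapse = ","), ","),
            paste0(paste(e$start - g$start[i], collapse = ","), ","),
            sep = "\t")
    }, character(1))
    writeLines(lines, path)
  } else stop("unsupported output format: ", ext)
  invisible(path)
}
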