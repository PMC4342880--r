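#' Construct an alignment set
#'
#' Read placements are held as two data frames: one row per read placement and
#' one row per aligned block (spliced reads have >1 block). Coordinates are
#' 0-based half-open.
#'
#' @param reads data.frame with columns `read_id`, `contig`, `start`, `end`,
#'   `strand`, `mismatches`, `n_positions`, `mate_id` (NA when unpaired).
#' @param blocks data.frame with columns `read` (row index into `reads`),
#'   `start`, `end`. Blocks of one read must be sorted, non-overlapping and
#'   within the read's interval.
#' @return object of class `alignments`.
#' @export
alignments <- function(reads, blocks) {
  stopifnot(is.data.frame(reads), is.data.frame(blocks))
  need <- c("read_id", "contig", "start", "end", "strand",
            "mismatches", "n_positions")
  stopifnot(all(need %in% names(reads)), all(c("read", "start", "end") %in% names(blocks)))
  if (is.null(reads$mate_id)) reads$mate_id <- NA_character_
  reads$start <- as.integer(reads$start); reads$end <- as.integer(reads$end)
  blocks$start <- as.integer(blocks$start); blocks$end <- as.integer(blocks$end)
  blocks$read <- as.integer(blocks$read)
  reads$mismatches <- as.integer(reads$mismatches)
  reads$n_positions <- as.integer(reads$n_positions)
  if (any(reads$n_positions < 1L)) stop("n_positions must be >= 1")
  if (any(blocks$end <= blocks$start)) stop("empty or inverted block")
  if (any(blocks$start < reads$start[blocks$read]) ||
      any(blocks$end > reads$end[blocks$read]))
    stop("block outside read interval")
  rownames(reads) <- NULL; rownames(blocks) <- NULL
  structure(list(reads = reads, blocks = blocks), class = "alignments")
}

#' @export
print.alignments <- function(x, ...) {
  cat("alignments:", nrow(x$reads), "read placements,",
      nrow(x$blocks), "blocks;",
      sum(x$reads$n_positions == 1L), "unique-mapping\n")
  invisible(x)
}

n_blocks_per_read <- function(aln) tabulate(aln$blocks$read, nbins = nrow(aln$reads))

#' Read alignments from SAM or the tab-delimited dialect
#'
#' SAM records must carry `NM` (mismatches) and `NH` (number of placements)
#' tags; spliced alignments (`N` CIGAR operations) are decomposed into blocks.
#' The TSV dialect has columns `read_id`, `contig`, `start` (0-based),
#' `cigar`, `nm`, `nh`, `mate_id` (empty when unpaired).
#'
#' @param path `.sam` or `.tsv` file.
#' @param missing_multiplicity what to do when the NH tag / `nh` column is
#'   absent: `"unique"` (default; treat as single placement, with a warning)
#'   or `"error"`.
#' @return an [alignments()] object.
#' @export
read_alignments <- function(path, missing_multiplicity = c("unique", "error")) {
  missing_multiplicity <- match.arg(missing_multiplicity)
  ext <- tolower(tools::file_ext(path))
  if (ext == "sam") {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
    on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
    param <- Rsamtools::ScanBamParam(what = c("qname", "flag"),
                                     tag = c("NM", "NH"))
    ga <- GenomicAlignments::readGAlignments(bam, param = param)
    mc <- S4Vectors::mcols(ga)
    nm <- mc$NM
    if (is.null(nm) || all(is.na(nm))) {
      warning("NM tag absent; mismatches set to 0")
      nm <- rep(0L, length(ga))
    }
    nm[is.na(nm)] <- 0L
    nh <- mc$NH
    if (is.null(nh) || anyNA(nh)) {
      if (missing_multiplicity == "error") stop("NH tag absent")
      warning("NH tag absent for some records; treated as unique-mapping")
      if (is.null(nh)) nh <- rep(1L, length(ga))
      nh[is.na(nh)] <- 1L
    }
    flag <- mc$flag
    paired <- bitwAnd(flag, 1L) > 0L
    first <- bitwAnd(flag, 64L) > 0L
    read_id <- ifelse(paired, paste0(mc$qname, ifelse(first, "/1", "/2")),
                      mc$qname)
    mate_id <- ifelse(paired, mc$qname, NA_character_)
    bl <- GenomicAlignments::grglist(ga)
    nb <- S4Vectors::elementNROWS(bl)
    flat <- unlist(bl, use.names = FALSE)
    reads <- data.frame(
      read_id = read_id,
      contig = as.character(GenomicAlignments::seqnames(ga)),
      start = GenomicAlignments::start(ga) - 1L,
      end = GenomicAlignments::end(ga),
      strand = as.character(GenomicAlignments::strand(ga)),
      mismatches = as.integer(nm),
      n_positions = as.integer(nh),
      mate_id = mate_id,
      stringsAsFactors = FALSE)
    blocks <- data.frame(
      read = rep(seq_along(ga), nb),
      start = GenomicRanges::start(flat) - 1L,
      end = GenomicRanges::end(flat))
    alignments(reads, blocks)
  } else if (ext %in% c("tsv", "txt")) {
    d <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(mate_id = "character"))
    need <- c("read_id", "contig", "start", "cigar", "nm")
    miss <- setdiff(need, names(d))
    if (length(miss))
      stop("malformed alignment TSV, missing column(s): ",
           paste(miss, collapse = ", "))
    if (is.null(d$nh)) {
      if (missing_multiplicity == "error") stop("nh column absent")
      warning("nh column absent; all reads treated as unique-mapping")
      d$nh <- 1L
    }
    if (is.null(d$mate_id)) d$mate_id <- NA_character_
    d$mate_id[!is.na(d$mate_id) & d$mate_id == ""] <- NA_character_
    rl <- GenomicAlignments::cigarRangesAlongReferenceSpace(
      d$cigar, pos = d$start + 1L, ops = c("M", "D", "=", "X"),
      reduce.ranges = TRUE)
    nb <- S4Vectors::elementNROWS(rl)
    flat <- unlist(rl, use.names = FALSE)
    reads <- data.frame(
      read_id = d$read_id, contig = d$contig,
      start = as.integer(d$start),
      end = d$start +
        GenomicAlignments::cigarWidthAlongReferenceSpace(d$cigar),
      strand = if (is.null(d$strand)) "*" else d$strand,
      mismatches = as.integer(d$nm), n_positions = as.integer(d$nh),
      mate_id = d$mate_id, stringsAsFactors = FALSE)
    blocks <- data.frame(read = rep(seq_len(nrow(d)), nb),
                         start = IRanges::start(flat) - 1L,
                         end = IRanges::end(flat))
    alignments(reads, blocks)
  } else stop("unsupported alignment format: ", ext)
}

cigar_from_blocks <- function(starts, ends) {
  n <- length(starts)
  ops <- paste0(ends - starts, "M")
  if (n > 1L) {
    gaps <- paste0(starts[-1L] - ends[-n], "N")
    ops <- c(rbind(ops[-n], gaps), ops[n])
  }
  paste(ops, collapse = "")
}

#' Write alignments as SAM
#'
#' Emits one SAM record per placement with `NM` and `NH` tags; spliced reads
#' get `M`/`N` CIGARs reconstructed from their blocks. Sequences are written
#' as runs of `N` (the analysis is alignment-level; base calls are not
#' retained).
#'
#' @param aln an [alignments()] object.
#' @param path output `.sam` file.
#' @param contig_lengths named integer vector for the `@SQ` header lines.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, path, contig_lengths) {
  r <- aln$reads
  bl <- split(aln$blocks, aln$blocks$read)
  cig <- character(nrow(r))
  rlen <- integer(nrow(r))
  for (i in seq_len(nrow(r))) {
    b <- bl[[as.character(i)]]
    cig[i] <- cigar_from_blocks(b$start, b$end)
    rlen[i] <- sum(b$end - b$start)
  }
  paired <- !is.na(r$mate_id)
  first <- paired & grepl("/1$", r$read_id)
  flag <- ifelse(paired, 1L + 2L, 0L) +
    ifelse(r$strand == "-", 16L, 0L) +
    ifelse(first, 64L, ifelse(paired, 128L, 0L))
  qname <- ifelse(paired, r$mate_id, r$read_id)
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           paste0("@SQ\tSN:", names(contig_lengths),
                  "\tLN:", as.integer(contig_lengths)))
  rec <- paste(qname, flag, r$contig, r$start + 1L, 255L, cig,
               "*", 0L, 0L,
               vapply(rlen, function(k) strrep("N", k), character(1)), "*",
               paste0("NM:i:", r$mismatches), paste0("NH:i:", r$n_positions),
               sep = "\t")
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Write alignments in the tab-delimited dialect
#'
#' @param aln an [alignments()] object.
#' @param path output `.tsv` file.
#' @return `path`, invisibly.
#' @export
write_alignments_tsv <- function(aln, path) {
  r <- aln$reads
  bl <- split(aln$blocks, aln$blocks$read)
  cig <- vapply(seq_len(nrow(r)), function(i) {
    b <- bl[[as.character(i)]]
    cigar_from_blocks(b$start, b$end)
  }, character(1))
  d <- data.frame(read_id = r$read_id, contig = r$contig, start = r$start,
                  cigar = cig, nm = r$mismatches, nh = r$n_positions,
                  strand = r$strand,
                  mate_id = ifelse(is.na(r$mate_id), "", r$mate_id))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-base read coverage
#'
#' @param aln an [alignments()] object.
#' @param contig_lengths named integer vector of contig lengths.
#' @param mode `"unique"` counts only reads with a single genomic placement
#'   (`n_positions == 1`); `"all"` counts every placement.
#' @return object of class `coverage_track`: a named list of integer vectors
#'   (`depth[i]` is the depth at 0-based position `i - 1`), with attribute
#'   `mode`.
#' @export
compute_coverage <- function(aln, contig_lengths, mode = c("unique", "all")) {
  mode <- match.arg(mode)
  keep <- if (mode == "unique") aln$reads$n_positions == 1L
          else rep(TRUE, nrow(aln$reads))
  b <- aln$blocks[keep[aln$blocks$read], , drop = FALSE]
  ctg <- aln$reads$contig[b$read]
  out <- lapply(names(contig_lengths), function(cn) {
    len <- as.integer(contig_lengths[[cn]])
    sel <- ctg == cn
    if (!any(sel)) return(integer(len))
    if (any(b$start[sel] < 0L) || any(b$end[sel] > len)) {
      bad <- which(sel)[which(b$start[sel] < 0L | b$end[sel] > len)[1L]]
      stop("block of read '", aln$reads$read_id[b$read[bad]],
           "' outside contig ", cn)
    }
    ir <- IRanges::IRanges(b$start[sel] + 1L, b$end[sel])
    as.integer(IRanges::coverage(ir, width = len))
  })
  names(out) <- names(contig_lengths)
  # reads on contigs absent from contig_lengths are an error
  unknown <- setdiff(unique(ctg), names(contig_lengths))
  if (length(unknown)) stop("reads on unknown contig(s): ",
                            paste(unknown, collapse = ", "))
  structure(out, class = "coverage_track", mode = mode)
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track (", attr(x, "mode"), "): ", length(x),
     " contig(s), total depth ", sum(vapply(x, function(v) sum(as.numeric(v)), 0)),
     "\n", sep = "")
  invisible(x)
}
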