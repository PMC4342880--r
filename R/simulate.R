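#' Simulation configuration
#'
#' Defines the study conditions the generator emulates: a compact fungal-like
#' genome with multi-exon gene models, three cultivation stages, 90 nt reads
#' in abutting mate pairs, and planted ground-truth features for every
#' pipeline rule (intron retention, exon skipping, alternative splice sites,
#' intergenic novel transcript units, UTR extensions, stage fold changes, an
#' overlapping gene pair).
#'
#' @param seed integer seed; the whole simulate-analyze-evaluate chain is
#'   deterministic given it.
#' @param contig_length contig size, bp.
#' @param n_genes number of annotated genes (excluding the planted
#'   overlapping partner).
#' @param exons_per_gene inclusive range for the exon count of unconstrained
#'   genes (role genes get fixed structures).
#' @param exon_length,intron_length inclusive bp ranges.
#' @param intergenic_gap inclusive bp range between consecutive elements.
#' @param read_length read length, nt (default 90).
#' @param depth per-gene target read depth (clean mode: exact stacked depth;
#'   stochastic mode: Poisson mean coverage).
#' @param stages stage labels.
#' @param clean TRUE (default) places reads on a deterministic lattice giving
#'   exactly rectangular coverage (for exact-recovery tests); FALSE draws
#'   read counts and positions stochastically.
#' @param frac_multi fraction of reads flagged multi-position (stochastic
#'   mode; clean mode emits unique-mapping reads only).
#' @param mismatch_rate fraction of reads carrying one mismatch (stochastic).
#' @param planted list with elements `ir` (data.frame cov_frac, depth_ratio),
#'   `es`, `a5ss`, `a3ss` (integers), `novel` (data.frame length, distance,
#'   depth), `utr_ext` (integer vector of extension lengths, genomic right
#'   side), `deg` (data.frame fold, stage), `overlap_pair` (logical).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       contig_length = 250000L,
                       n_genes = 30L,
                       exons_per_gene = c(2L, 5L),
                       exon_length = c(120L, 300L),
                       intron_length = c(100L, 250L),
                       intergenic_gap = c(900L, 1500L),
                       read_length = 90L,
                       depth = 30L,
                       stages = c("3d", "6d", "9d"),
                       clean = TRUE,
                       frac_multi = 0.02,
                       mismatch_rate = 0.2,
                       planted = NULL) {
  if (is.null(planted)) planted <- list()
  defaults <- list(
    ir = data.frame(cov_frac = c(1.0, 0.6, 1.0),
                    depth_ratio = c(0.5, 0.5, 0.05)),
    es = 2L, a5ss = 2L, a3ss = 2L,
    novel = data.frame(expand.grid(length = c(120L, 151L, 300L),
                                   distance = c(100L, 200L, 250L)),
                       depth = 18L),
    utr_ext = c(0L, 50L, 100L, 500L),
    deg = data.frame(fold = c(2, 2, 2, 0.5, 0.5), stage = "6d"),
    overlap_pair = TRUE)
  for (nm in names(defaults))
    if (is.null(planted[[nm]])) planted[[nm]] <- defaults[[nm]]
  # novel length rule is strict (> 150): lengths must exceed read length to
  # be representable by whole reads
  if (any(planted$novel$length < read_length))
    stop("planted novel units must be at least one read length long")
  cfg <- list(seed = as.integer(seed), contig = "ctg1",
              contig_length = as.integer(contig_length),
              n_genes = as.integer(n_genes),
              exons_per_gene = exons_per_gene, exon_length = exon_length,
              intron_length = intron_length, intergenic_gap = intergenic_gap,
              read_length = as.integer(read_length), depth = as.integer(depth),
              stages = stages, clean = isTRUE(clean),
              frac_multi = frac_multi, mismatch_rate = mismatch_rate,
              planted = planted)
  structure(cfg, class = "sim_config")
}

rint <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(seq.int(range[1], range[2]), n, replace = TRUE)
}

#' Simulate an annotated genome with planted features
#'
#' Lays out non-overlapping genes along the contig (plus one deliberately
#' overlapping partner gene when configured), reserves intergenic space for
#' planted novel-transcript units and UTR extensions, assigns one planted
#' role per gene, and records every planted feature in a truth manifest.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_annotation`: `models` ([gene_models()]),
#'   `manifest` (data.frame: type, gene_id, contig, start, end, value,
#'   value2, stage, detectable), `contig_lengths`, `config`.
#' @export
simulate_annotation <- function(config) {
  set.seed(config$seed)
  pl <- config$planted
  n_novel <- nrow(pl$novel)
  n_utr <- length(pl$utr_ext)
  n_ir <- nrow(pl$ir)
  n_deg <- nrow(pl$deg)
  n_roles <- n_novel + n_utr + n_ir + pl$es + pl$a5ss + pl$a3ss + n_deg
  if (config$n_genes < n_roles + 2L)
    stop("n_genes too small for the planted feature set (need >= ",
         n_roles + 2L, ")")

  roles <- c(rep("novel_gap", n_novel), rep("utr", n_utr), rep("ir", n_ir),
             rep("es", pl$es), rep("a5ss", pl$a5ss), rep("a3ss", pl$a3ss),
             rep("deg", n_deg),
             rep("plain", config$n_genes - n_roles))
  exons <- list(); manifest <- list(); cursor <- 1000L
  utr_i <- 0L; ir_i <- 0L; deg_i <- 0L; novel_i <- 0L
  for (i in seq_len(config$n_genes)) {
    role <- roles[i]
    n_ex <- switch(role, ir = 3L, es = 4L, a5ss = 3L, a3ss = 3L,
                   rint(1L, config$exons_per_gene))
    elens <- rint(n_ex, config$exon_length)
    ilens <- if (n_ex > 1L) rint(n_ex - 1L, config$intron_length) else integer(0)
    if (role == "ir") { ir_i <- ir_i + 1L; ilens[1L] <- 300L }
    gid <- sprintf("gene%03d", i)
    s <- cursor
    starts <- s + cumsum(c(0L, head(elens, -1L) + ilens))
    ends <- starts + elens
    strand <- sample(c("+", "-"), 1L)
    exons[[gid]] <- data.frame(gene_id = gid, contig = config$contig,
                               start = starts, end = ends, strand = strand,
                               stringsAsFactors = FALSE)
    gend <- ends[n_ex]
    cursor_next <- gend + rint(1L, config$intergenic_gap)

    if (role == "novel_gap") {
      novel_i <- novel_i + 1L
      spec <- pl$novel[novel_i, ]
      us <- gend + spec$distance
      ue <- us + spec$length
      manifest[[length(manifest) + 1L]] <- data.frame(
        type = "novel", gene_id = NA_character_, contig = config$contig,
        start = us, end = ue, value = spec$length, value2 = spec$distance,
        stage = NA_character_,
        detectable = spec$length > 150L & spec$distance >= 200L,
        stringsAsFactors = FALSE)
      # next gene far enough that the upstream gene stays nearest
      cursor_next <- ue + spec$distance + 600L
    } else if (role == "utr") {
      utr_i <- utr_i + 1L
      ext <- pl$utr_ext[utr_i]
      manifest[[length(manifest) + 1L]] <- data.frame(
        type = "utr_ext", gene_id = gid, contig = config$contig,
        start = gend, end = gend + ext, value = ext, value2 = NA_real_,
        stage = NA_character_, detectable = TRUE, stringsAsFactors = FALSE)
      cursor_next <- gend + ext + 800L
    } else if (role == "ir") {
      spec <- pl$ir[ir_i, ]
      is0 <- ends[1L]; ie0 <- starts[2L]
      manifest[[length(manifest) + 1L]] <- data.frame(
        type = "ir", gene_id = gid, contig = config$contig,
        start = is0, end = ie0, value = spec$cov_frac,
        value2 = spec$depth_ratio, stage = NA_character_,
        detectable = spec$cov_frac >= 0.90 & spec$depth_ratio >= 0.15,
        stringsAsFactors = FALSE)
    } else if (role == "es") {
      manifest[[length(manifest) + 1L]] <- data.frame(
        type = "es", gene_id = gid, contig = config$contig,
        start = ends[1L] - 1L, end = starts[3L], value = NA_real_,
        value2 = NA_real_, stage = NA_character_, detectable = TRUE,
        stringsAsFactors = FALSE)
    } else if (role %in% c("a5ss", "a3ss")) {
      d1 <- ends[1L] - 1L; a1 <- starts[2L]
      if (role == "a5ss") { d2 <- d1 + 20L; a2 <- a1 }
      else { d2 <- d1; a2 <- a1 - 20L }
      manifest[[length(manifest) + 1L]] <- data.frame(
        type = role, gene_id = gid, contig = config$contig,
        start = d2, end = a2, value = NA_real_, value2 = NA_real_,
        stage = NA_character_, detectable = TRUE, stringsAsFactors = FALSE)
    } else if (role == "deg") {
      deg_i <- deg_i + 1L
      manifest[[length(manifest) + 1L]] <- data.frame(
        type = "deg", gene_id = gid, contig = config$contig,
        start = s, end = gend, value = pl$deg$fold[deg_i],
        value2 = NA_real_, stage = as.character(pl$deg$stage[deg_i]),
        detectable = abs(log2(pl$deg$fold[deg_i])) >= 1,
        stringsAsFactors = FALSE)
    }
    cursor <- as.integer(cursor_next)
  }
  if (isTRUE(pl$overlap_pair)) {
    # partner gene overlapping the last gene's 3' region
    last <- exons[[length(exons)]]
    ogid <- "geneOVL"
    os <- max(last$end) - 60L
    exons[[ogid]] <- data.frame(gene_id = ogid, contig = config$contig,
                                start = os, end = os + 400L, strand = "+",
                                stringsAsFactors = FALSE)
    manifest[[length(manifest) + 1L]] <- data.frame(
      type = "overlap", gene_id = c(last$gene_id[1L], ogid),
      contig = config$contig,
      start = c(min(last$start), os), end = c(max(last$end), os + 400L),
      value = NA_real_, value2 = NA_real_, stage = NA_character_,
      detectable = TRUE, stringsAsFactors = FALSE)
    cursor <- os + 400L + 1000L
  }
  if (cursor > config$contig_length)
    stop("infeasible packing: genes need ", cursor, " bp, contig has ",
         config$contig_length)
  models <- gene_models(do.call(rbind, exons))
  manifest <- do.call(rbind, manifest)
  if (is.null(manifest))
    manifest <- data.frame(type = character(0), gene_id = character(0),
                           contig = character(0), start = integer(0),
                           end = integer(0), value = numeric(0),
                           value2 = numeric(0), stage = character(0),
                           detectable = logical(0))
  rownames(manifest) <- NULL
  structure(list(models = models, manifest = manifest,
                 contig_lengths = stats::setNames(config$contig_length,
                                                  config$contig),
                 config = config),
            class = "sim_annotation")
}

# lattice of interval starts covering [0, span) with pieces of length
# `piece`, `d` stacked copies; final piece pinned at span - piece
tile_starts <- function(span, piece, d) {
  if (span < piece) return(integer(0))
  base <- unique(c(seq.int(0L, span - piece, by = piece),
                   span - piece))
  rep(base, d)
}

# map transcript-space intervals [t, t + len) to genomic blocks through an
# exon chain (data.frame start/end sorted by start)
transcript_to_blocks <- function(chain, tstart, len) {
  w <- chain$end - chain$start
  coff <- cumsum(c(0L, w))
  out <- lapply(seq_along(tstart), function(k) {
    a <- tstart[k]; b <- a + len
    bl <- NULL
    for (e in seq_len(nrow(chain))) {
      lo <- max(a, coff[e]); hi <- min(b, coff[e + 1L])
      if (lo < hi)
        bl <- rbind(bl, c(chain$start[e] + (lo - coff[e]),
                          chain$start[e] + (hi - coff[e])))
    }
    bl
  })
  out
}

# expected splicing events implied by a gene's junction set, enumerated
# directly from exon boundaries (independent of the detector code paths)
expected_junction_events <- function(gid, ex, jset) {
  ev <- list()
  donors <- ex$end - 1L; acceptors <- ex$start
  jset <- unique(jset[, c("donor", "acceptor")])
  nj <- nrow(jset)
  for (k in seq_len(nj)) {
    di <- match(jset$donor[k], donors)
    aj <- match(jset$acceptor[k], acceptors)
    if (!is.na(di) && !is.na(aj) && aj >= di + 2L)
      ev[[length(ev) + 1L]] <- data.frame(
        gene_id = gid, type = "ES", anchor_start = jset$donor[k],
        anchor_end = jset$acceptor[k], stringsAsFactors = FALSE)
  }
  if (nj >= 2L) for (k in seq_len(nj - 1L)) for (l in seq.int(k + 1L, nj)) {
    if (jset$acceptor[k] == jset$acceptor[l] && jset$donor[k] != jset$donor[l])
      ev[[length(ev) + 1L]] <- data.frame(
        gene_id = gid, type = "A5SS",
        anchor_start = min(jset$donor[k], jset$donor[l]),
        anchor_end = max(jset$acceptor[k], jset$acceptor[l]),
        stringsAsFactors = FALSE)
    if (jset$donor[k] == jset$donor[l] && jset$acceptor[k] != jset$acceptor[l])
      ev[[length(ev) + 1L]] <- data.frame(
        gene_id = gid, type = "A3SS",
        anchor_start = min(jset$donor[k], jset$donor[l]),
        anchor_end = max(jset$acceptor[k], jset$acceptor[l]),
        stringsAsFactors = FALSE)
  }
  do.call(rbind, ev)
}

#' Simulate per-stage alignments, junctions and counts
#'
#' Emits read placements for every annotated gene (uniform along the mature
#' transcript; deterministic stacked lattice in clean mode), intronic reads
#' for planted intron-retention events, intergenic reads for planted novel
#' units, UTR-extension read-through, junction records (canonical plus
#' planted alternative junctions), mate-pair linkage, and per-gene per-stage
#' counts scaled by planted fold changes. The manifest gains an
#' `expected_events` attribute: the splicing events implied by the emitted
#' junction set, enumerated directly from exon boundaries.
#'
#' @param ann a [simulate_annotation()] result.
#' @return list of class `sim_experiment`: `models`, `manifest`,
#'   `contig_lengths`, `config`, `counts` (genes x stages matrix), `stages`
#'   (named list with `aln` ([alignments()]) and `junctions` per stage).
#' @export
simulate_alignments <- function(ann) {
  config <- ann$config
  set.seed(config$seed + 1L)
  rl <- config$read_length
  frag <- 2L * rl
  models <- ann$models
  man <- ann$manifest
  pl <- config$planted

  utr_by_gene <- stats::setNames(man$value[man$type == "utr_ext"],
                                 man$gene_id[man$type == "utr_ext"])
  ir_rows <- man[man$type == "ir", , drop = FALSE]
  deg_rows <- man[man$type == "deg", , drop = FALSE]

  gene_ids <- models$genes$gene_id
  counts <- matrix(0L, nrow = length(gene_ids), ncol = length(config$stages),
                   dimnames = list(gene_ids, config$stages))
  stage_out <- list()
  expected_events <- list()

  for (st in config$stages) {
    reads <- list(); blocks <- list(); junc <- list()
    for (gi in seq_along(gene_ids)) {
      gid <- gene_ids[gi]
      ex <- models$exons[models$exons$gene_id == gid, ]
      ex <- ex[order(ex$start), ]
      chain <- ex[, c("start", "end")]
      ext <- if (gid %in% names(utr_by_gene)) utr_by_gene[[gid]] else 0L
      if (!is.na(ext) && ext > 0L)
        chain$end[nrow(chain)] <- chain$end[nrow(chain)] + ext
      tlen <- sum(chain$end - chain$start)
      fold <- 1
      dr <- deg_rows[deg_rows$gene_id == gid & deg_rows$stage == st, ]
      if (nrow(dr)) fold <- dr$value[1L]
      d_st <- max(0L, as.integer(round(config$depth * fold)))

      if (config$clean) {
        fs <- tile_starts(tlen, frag, d_st)
        tstarts <- as.integer(rbind(fs, fs + rl))
        pair <- rep(seq_along(fs), each = 2L)
        mate <- rep(1:2, length(fs))
        n_mism <- integer(length(tstarts))
        npos <- rep(1L, length(tstarts))
      } else {
        nrd <- stats::rpois(1L, d_st * tlen / rl)
        tstarts <- if (tlen > rl) sample.int(tlen - rl, nrd, replace = TRUE) - 1L
                   else integer(0)
        pair <- rep(NA_integer_, length(tstarts))
        mate <- rep(NA_integer_, length(tstarts))
        n_mism <- stats::rbinom(length(tstarts), 1L, config$mismatch_rate)
        npos <- 1L + 2L * stats::rbinom(length(tstarts), 1L, config$frac_multi)
      }
      if (length(tstarts)) {
        bls <- transcript_to_blocks(chain, tstarts, rl)
        rid <- if (config$clean)
          paste0(gid, "_", st, "_f", pair, "/", mate)
        else paste0(gid, "_", st, "_r", seq_along(tstarts))
        mid <- if (config$clean) paste0(gid, "_", st, "_f", pair)
               else rep(NA_character_, length(tstarts))
        reads[[length(reads) + 1L]] <- data.frame(
          read_id = rid, contig = config$contig,
          start = vapply(bls, function(b) b[1L, 1L], 0),
          end = vapply(bls, function(b) b[nrow(b), 2L], 0),
          strand = if (config$clean) ifelse(mate == 1L, "+", "-") else "+",
          mismatches = n_mism, n_positions = npos, mate_id = mid,
          stringsAsFactors = FALSE)
        blocks[[length(blocks) + 1L]] <-
          data.frame(read_local = rep(seq_along(bls),
                                      vapply(bls, nrow, 0L)),
                     start = unlist(lapply(bls, function(b) b[, 1L])),
                     end = unlist(lapply(bls, function(b) b[, 2L])),
                     group = length(reads))
        counts[gid, st] <- counts[gid, st] + length(tstarts)
        # canonical junction support: reads spanning each exon-exon boundary
        if (nrow(ex) > 1L) {
          w <- chain$end - chain$start
          coff <- cumsum(w)[-nrow(chain)]
          for (k in seq_along(coff)) {
            supp <- sum(tstarts < coff[k] & tstarts + rl > coff[k])
            junc[[length(junc) + 1L]] <- data.frame(
              contig = config$contig, donor = ex$end[k] - 1L,
              acceptor = ex$start[k + 1L], support = max(1L, supp),
              strand = ex$strand[1L], stringsAsFactors = FALSE)
          }
        }
      }
      # planted intron-retention coverage: unspliced intronic segments
      irr <- ir_rows[ir_rows$gene_id == gid, ]
      if (nrow(irr)) {
        is0 <- irr$start[1L]; ie0 <- irr$end[1L]
        ilen <- ie0 - is0
        f <- irr$value[1L]; r <- irr$value2[1L]
        # segments carry flags saying whether their outer edge abuts an exon
        # (where unspliced pre-mRNA reads overhang the boundary)
        segs <- if (f >= 1) list(list(c(is0, ie0), c(TRUE, TRUE))) else {
          ktot <- round(f * ilen)
          list(list(c(is0, is0 + (ktot - rl)), c(TRUE, FALSE)),
               list(c(ie0 - rl, ie0), c(FALSE, TRUE)))
        }
        d_i <- max(1L, round(r * d_st))
        for (seg in segs) {
          sg <- seg[[1L]]; overhang <- seg[[2L]]
          ss <- tile_starts(sg[2L] - sg[1L], rl, d_i) + sg[1L]
          if (!config$clean) {
            # read starts over the segment, overhanging into the flanking
            # exon(s) where allowed, as unspliced transcripts produce
            lo <- sg[1L] - if (overhang[1L]) rl - 1L else 0L
            hi <- sg[2L] - if (overhang[2L]) 1L else rl
            nrd <- stats::rpois(1L, d_i * (hi - lo + rl) / rl)
            ss <- if (hi > lo)
              lo + sample.int(hi - lo, nrd, replace = TRUE) - 1L
              else integer(0)
          }
          if (length(ss)) {
            rid <- paste0(gid, "_", st, "_ir", seq_along(ss), "_",
                          sg[1L])
            reads[[length(reads) + 1L]] <- data.frame(
              read_id = rid, contig = config$contig, start = ss,
              end = ss + rl, strand = "+", mismatches = 0L,
              n_positions = 1L, mate_id = NA_character_,
              stringsAsFactors = FALSE)
            blocks[[length(blocks) + 1L]] <- data.frame(
              read_local = seq_along(ss), start = ss, end = ss + rl,
              group = length(reads))
          }
        }
      }
      # planted alternative junctions
      alt <- man[man$gene_id %in% gid & man$type %in% c("es", "a5ss", "a3ss"), ]
      if (nrow(alt))
        junc[[length(junc) + 1L]] <- data.frame(
          contig = config$contig, donor = alt$start, acceptor = alt$end,
          support = 5L, strand = ex$strand[1L], stringsAsFactors = FALSE)
    }
    # planted intergenic novel units
    nov <- man[man$type == "novel", , drop = FALSE]
    for (k in seq_len(nrow(nov))) {
      span <- nov$end[k] - nov$start[k]
      du <- pl$novel$depth[k]
      ss <- if (config$clean) tile_starts(span, rl, du) + nov$start[k]
            else nov$start[k] +
              sample.int(max(1L, span - rl),
                         stats::rpois(1L, du * span / rl),
                         replace = TRUE) - 1L
      if (length(ss)) {
        reads[[length(reads) + 1L]] <- data.frame(
          read_id = paste0("novel", k, "_", st, "_r", seq_along(ss)),
          contig = config$contig, start = ss, end = ss + rl, strand = "+",
          mismatches = 0L, n_positions = 1L, mate_id = NA_character_,
          stringsAsFactors = FALSE)
        blocks[[length(blocks) + 1L]] <- data.frame(
          read_local = seq_along(ss), start = ss, end = ss + rl,
          group = length(reads))
      }
    }
    rdf <- do.call(rbind, reads)
    if (is.null(rdf))
      rdf <- data.frame(read_id = character(0), contig = character(0),
                        start = integer(0), end = integer(0),
                        strand = character(0), mismatches = integer(0),
                        n_positions = integer(0), mate_id = character(0))
    off <- c(0L, cumsum(vapply(reads, nrow, 0L)))
    bdf <- do.call(rbind, blocks)
    if (is.null(bdf))
      bdf <- data.frame(read = integer(0), start = integer(0),
                        end = integer(0))
    else bdf <- data.frame(read = off[bdf$group] + bdf$read_local,
                           start = bdf$start, end = bdf$end)
    aln <- alignments(rdf, bdf)
    jdf <- do.call(rbind, junc)
    if (is.null(jdf)) {
      jdf <- junctions(character(0), integer(0), integer(0), integer(0),
                       character(0))
    } else {
      # collapse duplicate junction records, keeping the largest support
      key <- paste(jdf$contig, jdf$donor, jdf$acceptor)
      agg <- stats::aggregate(jdf$support, by = list(key = key), FUN = max)
      jdf <- jdf[!duplicated(key), ]
      jdf$support <- agg$x[match(paste(jdf$contig, jdf$donor, jdf$acceptor),
                                 agg$key)]
      jdf <- junctions(jdf$contig, jdf$donor, jdf$acceptor, jdf$support,
                       jdf$strand)
    }
    stage_out[[st]] <- list(aln = aln, junctions = jdf)
  }

  # expected junction-anchored events per gene, from the stage-1 junction set
  jx1 <- assign_junctions(stage_out[[1L]]$junctions, models)
  ee <- lapply(gene_ids, function(gid) {
    ex <- models$exons[models$exons$gene_id == gid, ]
    ex <- ex[order(ex$start), ]
    jset <- jx1[!is.na(jx1$gene_id) & jx1$gene_id == gid, , drop = FALSE]
    if (nrow(jset) == 0L) return(NULL)
    expected_junction_events(gid, ex, jset)
  })
  expected_events <- do.call(rbind, ee)

  structure(list(models = models, manifest = man,
                 expected_events = expected_events,
                 contig_lengths = ann$contig_lengths, config = config,
                 counts = counts, stages = stage_out),
            class = "sim_experiment")
}

#' Simulate a complete experiment
#'
#' Convenience wrapper: [simulate_annotation()] then [simulate_alignments()].
#'
#' @param config a [sim_config()] (or arguments forwarded to it).
#' @return a `sim_experiment` (see [simulate_alignments()]).
#' @export
simulate_experiment <- function(config = sim_config()) {
  simulate_alignments(simulate_annotation(config))
}

#' Write a simulated experiment to standard file formats
#'
#' Writes the genome (random bases, deterministic given the seed) as FASTA,
#' gene models as GTF, per-stage alignments as SAM, junctions as BED6+1 and
#' the truth manifest as JSON.
#'
#' @param sim a `sim_experiment`.
#' @param dir output directory (created if needed).
#' @return named list of written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(sim$config$seed + 2L)
  seqs <- Biostrings::DNAStringSet(vapply(sim$contig_lengths, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1)))
  names(seqs) <- names(sim$contig_lengths)
  paths <- list(fasta = file.path(dir, "genome.fa"),
                gtf = file.path(dir, "annotation.gtf"),
                manifest = file.path(dir, "truth_manifest.json"))
  Biostrings::writeXStringSet(seqs, paths$fasta)
  write_gene_models(sim$models, paths$gtf)
  jsonlite::write_json(list(manifest = sim$manifest,
                            expected_events = sim$expected_events,
                            counts = as.data.frame(sim$counts)),
                       paths$manifest, dataframe = "rows", na = "null")
  for (st in names(sim$stages)) {
    sp <- file.path(dir, paste0("reads_", st, ".sam"))
    jp <- file.path(dir, paste0("junctions_", st, ".bed"))
    write_sam(sim$stages[[st]]$aln, sp, sim$contig_lengths)
    write_junctions(sim$stages[[st]]$junctions, jp)
    paths[[paste0("sam_", st)]] <- sp
    paths[[paste0("junc_", st)]] <- jp
  }
  invisible(paths)
}
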