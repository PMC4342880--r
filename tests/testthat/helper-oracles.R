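# Independent oracles and fixture builders used across the suite.
# Oracles are written as literal transcriptions of the definitions, never
# sharing code paths with the implementation they check.

# coverage_track from a plain depth vector
cov_track <- function(depth, mode = "unique", contig = "ctg1") {
  structure(stats::setNames(list(as.integer(depth)), contig),
            class = "coverage_track", mode = mode)
}

# single-block alignment set from a start/end table
aln_from_spans <- function(d) {
  if (is.null(d$read_id)) d$read_id <- paste0("r", seq_len(nrow(d)))
  if (is.null(d$contig)) d$contig <- "ctg1"
  if (is.null(d$strand)) d$strand <- "+"
  if (is.null(d$mismatches)) d$mismatches <- 0L
  if (is.null(d$n_positions)) d$n_positions <- 1L
  if (is.null(d$mate_id)) d$mate_id <- NA_character_
  alignments(d, data.frame(read = seq_len(nrow(d)),
                           start = d$start, end = d$end))
}

# literal series oracle for the conditional count model: probabilities of
# every split (y', s - y') of the observed total s, summed over splits no
# more likely than the observed one (direct log-choose formula)
oracle_ac_two_sided <- function(x, y, n_a, n_b) {
  s <- x + y
  lp <- function(yy) lchoose(s, yy) + yy * log(n_b / (n_a + n_b)) +
    (s - yy) * log(n_a / (n_a + n_b))
  lpy <- lp(0:s)
  sum(exp(lpy[lpy <= lp(y) + log(1 + 1e-7)]))
}

# brute-force five-condition intron-retention check on raw inputs
oracle_ir <- function(intron, exon1, exon2, junc_set, depth, other_genes,
                      min_cov = 0.90, min_ratio = 0.15, flank = 5L) {
  is0 <- intron[1]; ie0 <- intron[2]
  c1 <- any(junc_set$donor == is0 - 1L & junc_set$acceptor == ie0)
  ib <- depth[(is0 + 1):ie0]
  c2 <- mean(ib >= 1) >= min_cov
  m1 <- mean(depth[(exon1[1] + 1):exon1[2]])
  m2 <- mean(depth[(exon2[1] + 1):exon2[2]])
  c3 <- mean(ib) >= min_ratio * max(m1, m2)
  w <- c((is0 - flank + 1):is0, (is0 + 1):(is0 + flank),
         (ie0 - flank + 1):ie0, (ie0 + 1):(ie0 + flank))
  w <- w[w >= 1 & w <= length(depth)]
  c4 <- all(depth[w] >= 1)
  c5 <- TRUE
  if (!is.null(other_genes) && nrow(other_genes))
    c5 <- !any(other_genes$start < ie0 & other_genes$end > is0)
  c(c1, c2, c3, c4, c5)
}

# quadratic brute-force enumeration of junction-pair and skip events
oracle_events <- function(exons, jset) {
  jset <- unique(jset[, c("donor", "acceptor")])
  donors <- exons$end - 1L
  acceptors <- exons$start
  ev <- list()
  for (k in seq_len(nrow(jset))) {
    i <- which(donors == jset$donor[k])
    j <- which(acceptors == jset$acceptor[k])
    if (length(i) == 1 && length(j) == 1 && j >= i + 2)
      ev[[length(ev) + 1]] <- c("ES", jset$donor[k], jset$acceptor[k])
  }
  n <- nrow(jset)
  if (n >= 2) for (a in 1:(n - 1)) for (b in (a + 1):n) {
    if (jset$acceptor[a] == jset$acceptor[b] && jset$donor[a] != jset$donor[b])
      ev[[length(ev) + 1]] <- c("A5SS", min(jset$donor[a], jset$donor[b]),
                                max(jset$acceptor[a], jset$acceptor[b]))
    if (jset$donor[a] == jset$donor[b] && jset$acceptor[a] != jset$acceptor[b])
      ev[[length(ev) + 1]] <- c("A3SS", min(jset$donor[a], jset$donor[b]),
                                max(jset$acceptor[a], jset$acceptor[b]))
  }
  if (!length(ev))
    return(data.frame(type = character(0), anchor_start = integer(0),
                      anchor_end = integer(0)))
  m <- do.call(rbind, ev)
  unique(data.frame(type = m[, 1], anchor_start = as.integer(m[, 2]),
                    anchor_end = as.integer(m[, 3])))
}

# hypergeometric upper tail by direct combinatorial summation
oracle_hyper_tail <- function(k, big_k, n_uni, n_set) {
  kk <- k:min(big_k, n_set)
  sum(exp(lchoose(big_k, kk) + lchoose(n_uni - big_k, n_set - kk) -
            lchoose(n_uni, n_set)))
}

# one shared clean-mode simulation per test run (expensive to build)
.fixtures <- new.env()
sim_clean <- function() {
  if (is.null(.fixtures$sim_clean))
    .fixtures$sim_clean <- simulate_experiment(sim_config(seed = 11L))
  .fixtures$sim_clean
}
pipeline_clean <- function() {
  if (is.null(.fixtures$pipe_clean))
    .fixtures$pipe_clean <- suppressMessages(run_pipeline(sim_clean()))
  .fixtures$pipe_clean
}

# one-gene model: two 100 bp exons around an intron of given length
two_exon_gene <- function(intron_len = 200L, offset = 1000L,
                          gid = "geneT", exon_len = 100L) {
  gene_models(data.frame(
    gene_id = gid, contig = "ctg1",
    start = c(offset, offset + exon_len + intron_len),
    end = c(offset + exon_len, offset + 2L * exon_len + intron_len),
    strand = "+"))
}

# two-exon gene with a planted intron coverage pattern (exact covered-base
# counts split between the two intron ends, gap in the middle)
make_ir_fixture <- function(intron_len = 200L, exon_depth = 40L,
                            cov_frac = 1, ratio = 0.5, junction = TRUE,
                            flanks = TRUE, overlap_gene = FALSE) {
  gm_ex <- data.frame(gene_id = "geneT", contig = "ctg1",
                      start = c(1000L, 1100L + intron_len),
                      end = c(1100L, 1200L + intron_len), strand = "+")
  if (overlap_gene)
    gm_ex <- rbind(gm_ex, data.frame(gene_id = "geneX", contig = "ctg1",
                                     start = 1150L, end = 1250L,
                                     strand = "+"))
  gm <- gene_models(gm_ex)
  d <- integer(3000)
  d[1001:1100] <- exon_depth
  d[(1101 + intron_len):(1200 + intron_len)] <- exon_depth
  is0 <- 1100L; ie0 <- 1100L + intron_len
  ncov <- round(cov_frac * intron_len)
  idep <- max(1L, round(ratio * exon_depth))
  if (ncov > 0) {
    # covered bases split between the two boundary ends (middle gap)
    k1 <- ceiling(ncov / 2); k2 <- ncov - k1
    if (k1 > 0) d[(is0 + 1):(is0 + k1)] <- idep
    if (k2 > 0) d[(ie0 - k2 + 1):ie0] <- idep
  }
  if (!flanks) d[(is0 + 1):(is0 + 5)] <- 0L
  jx <- if (junction) junctions("ctg1", is0 - 1L, ie0, 5L)
        else junctions("ctg1", 1L, 2L, 1L)
  jx$gene_id <- if (junction) "geneT" else NA_character_
  list(gm = gm, jx = jx, cov = cov_track(d), depth = d,
       intron = c(is0, ie0))
}
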