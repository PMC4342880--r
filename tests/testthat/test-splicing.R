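test_that("junction assignment is containment-based", {
  gm <- gene_models(data.frame(gene_id = c("g1", "g2"), contig = "ctg1",
                               start = c(1000L, 3000L), end = c(2000L, 4000L),
                               strand = "+"))
  jx <- junctions("ctg1", donor = c(1200L, 1900L, 1500L),
                  acceptor = c(1400L, 2050L, 3500L), support = 3L)
  aj <- suppressMessages(assign_junctions(jx, gm))
  expect_equal(aj$gene_id, c("g1", NA, NA))  # inside; past end; spans genes
})

test_that("junction assignment agrees with a brute-force containment scan", {
  sim <- sim_clean()
  gm <- sim$models
  set.seed(33)
  n <- 1000L
  don <- sample.int(200000L, n)
  acc <- don + sample(50:500, n, replace = TRUE)
  jx <- junctions("ctg1", don, acc)
  aj <- suppressMessages(assign_junctions(jx, gm))
  g <- gm$genes
  oracle <- vapply(seq_len(n), function(i) {
    ing <- function(p) which(g$start <= p & p < g$end)
    a <- ing(don[i]); b <- ing(acc[i])
    if (length(a) == 1 && length(b) == 1 && a == b) g$gene_id[a]
    else NA_character_
  }, character(1))
  # restrict to positions hitting at most one gene (overlap pair ambiguous)
  amb <- vapply(seq_len(n), function(i)
    sum(g$start <= don[i] & don[i] < g$end) > 1 ||
    sum(g$start <= acc[i] & acc[i] < g$end) > 1, logical(1))
  expect_equal(aj$gene_id[!amb], oracle[!amb])
})

test_that("exon skipping needs a junction bridging non-adjacent exons", {
  gm <- gene_models(data.frame(
    gene_id = "g", contig = "ctg1",
    start = c(1000L, 1300L, 1600L), end = c(1100L, 1400L, 1700L),
    strand = "+"))
  skip <- junctions("ctg1", 1099L, 1600L, 4L)
  skip$gene_id <- "g"
  es <- detect_exon_skipping(gm, skip)
  expect_equal(nrow(es), 1L)
  expect_equal(es$skipped_exons, "2")

  adj <- junctions("ctg1", c(1099L, 1399L), c(1300L, 1600L))
  adj$gene_id <- "g"
  expect_equal(nrow(detect_exon_skipping(gm, adj)), 0L)

  two <- two_exon_gene()
  j2 <- junctions("ctg1", 1099L, 1300L); j2$gene_id <- "geneT"
  expect_equal(nrow(detect_exon_skipping(two, j2)), 0L)
})

test_that("shared-acceptor pairs are A5SS, shared-donor pairs are A3SS", {
  gm <- gene_models(data.frame(gene_id = "g", contig = "ctg1",
                               start = c(50L, 600L), end = c(150L, 700L),
                               strand = "+"))
  j <- junctions("ctg1", c(100L, 120L), c(500L, 500L))
  j$gene_id <- "g"
  a5 <- detect_alt_splice_sites(gm, j)
  expect_equal(a5$type, "A5SS")
  j3 <- junctions("ctg1", c(100L, 100L), c(500L, 480L))
  j3$gene_id <- "g"
  expect_equal(detect_alt_splice_sites(gm, j3)$type, "A3SS")
  # duplicate junction records never create events
  jd <- junctions("ctg1", c(100L, 100L), c(500L, 500L), support = c(2L, 7L))
  jd$gene_id <- "g"
  expect_equal(nrow(detect_alt_splice_sites(gm, jd)), 0L)
})

test_that("event sets equal the quadratic enumeration oracle", {
  set.seed(55)
  for (rep in 1:120) {
    n_ex <- sample(3:6, 1)
    elen <- sample(80:200, n_ex, replace = TRUE)
    ilen <- sample(60:150, n_ex - 1, replace = TRUE)
    starts <- 1000L + cumsum(c(0L, head(elen, -1) + ilen))
    ex <- data.frame(gene_id = "g", contig = "ctg1", start = starts,
                     end = starts + elen, strand = "+")
    gm <- gene_models(ex)
    donors <- ex$end - 1L; acceptors <- ex$start
    # random junction soup: canonical, skipping, shifted variants
    njx <- sample(2:6, 1)
    don <- integer(0); acc <- integer(0)
    for (k in seq_len(njx)) {
      i <- sample(seq_len(n_ex - 1), 1)
      j <- sample(seq.int(i + 1, n_ex), 1)
      d <- donors[i] + sample(c(0L, 0L, sample(-10:10, 1)), 1)
      a <- acceptors[j] + sample(c(0L, 0L, sample(-10:10, 1)), 1)
      if (d < a) { don <- c(don, d); acc <- c(acc, a) }
    }
    if (!length(don)) next
    jx <- junctions("ctg1", don, acc)
    jx$gene_id <- "g"
    es <- detect_exon_skipping(gm, jx)
    ass <- detect_alt_splice_sites(gm, jx)
    got <- rbind(
      if (nrow(es)) data.frame(type = es$type, anchor_start = es$donor,
                               anchor_end = es$acceptor),
      if (nrow(ass)) data.frame(type = ass$type,
                                anchor_start = pmin(ass$donor1, ass$donor2),
                                anchor_end = pmax(ass$acceptor1,
                                                  ass$acceptor2)))
    want <- oracle_events(ex, data.frame(donor = don, acceptor = acc))
    got <- unique(got)   # events deduplicate by (type, anchor coordinates)
    srt <- function(d) {
      if (is.null(d) || nrow(d) == 0)
        return(data.frame(type = character(0), anchor_start = integer(0),
                          anchor_end = integer(0)))
      d <- d[order(d$type, d$anchor_start, d$anchor_end), ]
      rownames(d) <- NULL
      d
    }
    expect_equal(srt(got), srt(want))
  }
})


test_that("intron retention requires all five conditions", {
  f <- make_ir_fixture()
  ir <- detect_intron_retention(f$gm, f$jx, f$cov)
  expect_equal(nrow(ir), 1L)
  expect_equal(c(ir$intron_start, ir$intron_end), f$intron)

  # 80% coverage fails condition 2
  f2 <- make_ir_fixture(cov_frac = 0.8)
  expect_equal(nrow(detect_intron_retention(f2$gm, f2$jx, f2$cov)), 0L)
  # depth 5% of exons fails condition 3
  f3 <- make_ir_fixture(ratio = 0.05)
  expect_equal(nrow(detect_intron_retention(f3$gm, f3$jx, f3$cov)), 0L)
  # missing junction fails condition 1
  f4 <- make_ir_fixture(junction = FALSE)
  expect_equal(nrow(detect_intron_retention(f4$gm, f4$jx, f4$cov)), 0L)
  # uncovered flank window fails condition 4
  f5 <- make_ir_fixture(flanks = FALSE)
  expect_equal(nrow(detect_intron_retention(f5$gm, f5$jx, f5$cov)), 0L)
  # another gene over the intron fails condition 5
  f6 <- make_ir_fixture(overlap_gene = TRUE)
  got <- detect_intron_retention(f6$gm, f6$jx, f6$cov)
  expect_false("geneT" %in% got$gene_id)
})

test_that("IR calls are monotone under added coverage", {
  f <- make_ir_fixture(cov_frac = 1, ratio = 0.5)
  before <- detect_intron_retention(f$gm, f$jx, f$cov)
  d2 <- f$depth + 1L
  after <- detect_intron_retention(f$gm, f$jx, cov_track(d2))
  expect_true(all(paste(before$gene_id, before$intron_start) %in%
                    paste(after$gene_id, after$intron_start)))
})

test_that("AS summary arithmetic", {
  ev <- data.frame(gene_id = c("g1"), type = c("IR"))
  s <- summarize_as(list(`3d` = ev), genes_tested = 2L)
  expect_equal(s$genes_with_as, 1L)
  expect_equal(s$fraction_genes_as, 0.5)
  expect_equal(s$ir_fraction, 1)
  empty <- data.frame(gene_id = character(0), type = character(0))
  s0 <- summarize_as(list(`3d` = empty), genes_tested = 5L)
  expect_equal(s0$n_events, 0L)
  expect_equal(s0$ir_fraction, 0)
})
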