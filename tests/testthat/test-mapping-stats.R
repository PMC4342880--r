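test_that("mapping classes follow uniqueness and mismatch definitions", {
  a <- aln_from_spans(data.frame(start = 0L, end = 50L))
  s <- classify_mappings(a)
  expect_equal(s$unique_matched, 1L)
  expect_equal(s$perfect_matched, 1L)
  m <- aln_from_spans(data.frame(start = 0L, end = 50L, n_positions = 3L))
  sm <- classify_mappings(m)
  expect_equal(sm$multi_position_matched, 1L)
  expect_equal(sm$unique_matched, 0L)
})

test_that("simulated read-class mixture matches a direct tally", {
  sim <- simulate_experiment(sim_config(seed = 5L, clean = FALSE))
  a <- sim$stages[[1]]$aln
  s <- classify_mappings(a)
  r <- a$reads[!duplicated(a$reads$read_id), ]
  expect_equal(s$total_reads, nrow(r))
  expect_equal(s$unique_matched, sum(r$n_positions == 1L))
  expect_equal(s$multi_position_matched, sum(r$n_positions > 1L))
  expect_equal(s$perfect_matched, sum(r$mismatches == 0L))
  expect_equal(s$unique_matched + s$multi_position_matched, s$total_reads)
})

test_that("conflicting multiplicity for one read id is an error", {
  d <- data.frame(read_id = c("r1", "r1"), start = c(0L, 100L),
                  end = c(50L, 150L), n_positions = c(1L, 3L))
  a <- aln_from_spans(d)
  expect_error(classify_mappings(a), "conflicting")
})

test_that("gene coverage fraction equals a per-base brute-force scan", {
  gm <- two_exon_gene(intron_len = 200L)
  depth <- integer(3000)
  depth[1001:1075] <- 2L   # covers 75 of the first exon's 100 bases
  cv <- cov_track(depth)
  gc <- gene_coverage(cv, gm)
  expect_equal(gc$fraction, 75 / 200)
  expect_equal(gene_coverage(cov_track(integer(3000)), gm)$fraction, 0)
  # full-span mode counts intronic bases in the denominator
  gf <- gene_coverage(cv, gm, span = "full")
  expect_equal(gf$fraction, 75 / 400)

  # brute force across the simulated gene set
  sim <- sim_clean()
  cvu <- compute_coverage(sim$stages[[1]]$aln, sim$contig_lengths, "unique")
  gc2 <- gene_coverage(cvu, sim$models)
  for (i in seq_len(nrow(sim$models$genes))) {
    gid <- sim$models$genes$gene_id[i]
    e <- sim$models$exons[sim$models$exons$gene_id == gid, ]
    pos <- unlist(mapply(seq, e$start + 1L, e$end, SIMPLIFY = FALSE))
    expect_equal(gc2$fraction[gc2$gene_id == gid],
                 sum(cvu$ctg1[pos] >= 1) / length(pos))
  }
})

test_that("gene coverage is monotone as reads are added", {
  gm <- two_exon_gene()
  d1 <- integer(3000); d1[1001:1050] <- 1L
  d2 <- d1; d2[1301:1400] <- 1L
  f1 <- gene_coverage(cov_track(d1), gm)$fraction
  f2 <- gene_coverage(cov_track(d2), gm)$fraction
  expect_gte(f2, f1)
})

test_that("relative positions are midpoint-based and strand-mirrored", {
  gm <- gene_models(data.frame(gene_id = "g", contig = "ctg1",
                               start = 0L, end = 1000L, strand = "+"))
  a <- aln_from_spans(data.frame(start = 475L, end = 525L))
  h <- relative_position_histogram(a, gm, n_bins = 10L)
  expect_equal(h$counts[6L], 1L)   # bin containing 0.5
  expect_equal(sum(h$counts), h$n_assigned)
  gm_m <- gene_models(data.frame(gene_id = "g", contig = "ctg1",
                                 start = 0L, end = 1000L, strand = "-"))
  hm <- relative_position_histogram(a, gm_m, n_bins = 10L)
  expect_equal(hm$counts[6L], 1L)  # 0.5 mirrors to 0.5
  # off-center read mirrors to the opposite bin
  b <- aln_from_spans(data.frame(start = 100L, end = 150L))  # rel 0.125
  expect_equal(which(relative_position_histogram(b, gm, 10L)$counts == 1L), 2L)
  expect_equal(which(relative_position_histogram(b, gm_m, 10L)$counts == 1L),
               9L)
})

test_that("histogram mass is conserved and intergenic reads are excluded", {
  sim <- sim_clean()
  a <- sim$stages[[1]]$aln
  h <- relative_position_histogram(a, sim$models, n_bins = 50L)
  expect_equal(sum(h$counts), h$n_assigned)
  expect_equal(h$n_assigned + h$n_excluded,
               sum(a$reads$n_positions == 1L))
  expect_gt(h$n_excluded, 0L)  # planted novel units lie outside genes
})

test_that("uniform reads give a flat histogram within multinomial bounds", {
  set.seed(42)
  gm <- gene_models(data.frame(gene_id = "g", contig = "ctg1",
                               start = 0L, end = 10000L, strand = "+"))
  n <- 20000L
  st <- sample.int(10000L - 100L, n, replace = TRUE) - 1L
  a <- aln_from_spans(data.frame(start = st, end = st + 100L))
  h <- relative_position_histogram(a, gm, n_bins = 10L)
  exp_per_bin <- h$n_assigned / 10
  sigma <- sqrt(h$n_assigned * 0.1 * 0.9)
  expect_true(all(abs(h$counts - exp_per_bin) < 4 * sigma))
})
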