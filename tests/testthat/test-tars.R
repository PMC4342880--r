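test_that("TARs are maximal runs with gap merging", {
  d <- integer(1000)
  d[101:400] <- 3L
  t1 <- build_tars(cov_track(d, "all"), min_depth = 1L, max_gap = 0L)
  expect_equal(nrow(t1), 1L)
  expect_equal(c(t1$start, t1$end), c(100L, 400L))

  d2 <- integer(1000)
  d2[101:200] <- 2L
  d2[211:300] <- 2L     # 10 bp gap
  expect_equal(nrow(build_tars(cov_track(d2, "all"), 1L, max_gap = 0L)), 2L)
  merged <- build_tars(cov_track(d2, "all"), 1L, max_gap = 20L)
  expect_equal(nrow(merged), 1L)
  expect_equal(c(merged$start, merged$end), c(100L, 300L))
})

test_that("TARs equal a brute-force run-length oracle on random tracks", {
  set.seed(21)
  for (rep in 1:20) {
    d <- rpois(500, 1.2)
    md <- sample(1:3, 1)
    gap <- sample(0:5, 1)
    got <- build_tars(cov_track(d, "all"), min_depth = md, max_gap = gap)
    # oracle: linear scan
    ok <- d >= md
    runs <- rle(ok)
    ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
    seg <- cbind(starts[runs$values], ends[runs$values])
    if (nrow(seg) > 1) {
      keep <- list(seg[1, ])
      for (i in 2:nrow(seg)) {
        last <- keep[[length(keep)]]
        if (seg[i, 1] - last[2] - 1L <= gap)
          keep[[length(keep)]] <- c(last[1], seg[i, 2])
        else keep[[length(keep) + 1]] <- seg[i, ]
      }
      seg <- do.call(rbind, keep)
    }
    expect_equal(got$start, as.integer(seg[, 1] - 1L))
    expect_equal(got$end, as.integer(seg[, 2]))
  }
})

test_that("mean depth is averaged over the TAR and reads are counted", {
  d <- integer(300); d[101:200] <- c(rep(2L, 50), rep(4L, 50))
  a <- aln_from_spans(data.frame(start = c(100L, 150L), end = c(150L, 200L)))
  tt <- build_tars(cov_track(d, "all"), 2L, aln = a)
  expect_equal(tt$mean_depth, 3)
  expect_equal(tt$n_reads, 2L)
})

test_that("novel-transcript rules filter by length, distance, expression", {
  # one gene at [1000,2000); TARs planted intergenically
  gm <- gene_models(data.frame(gene_id = "g1", contig = "ctg1",
                               start = 1000L, end = 2000L, strand = "+"))
  d <- integer(10000)
  d[1001:2000] <- 30L
  mk <- function(s, len, depth) d[(s + 1):(s + len)] <<- depth
  mk(2300, 300, 20)   # 300 bp away: qualifies
  mk(2900, 120, 20)   # length fails (120 <= 150)
  mk(3600, 300, 20)   # qualifies
  d[8101:8400] <- 20L # 6.1 kb from the gene: qualifies
  cv <- cov_track(d, "all")
  tars <- build_tars(cv, min_depth = 2L)
  nv <- detect_novel_transcripts(tars, gm, cv)
  expect_equal(sum(nv$reported), 3L)
  bad <- nv[nv$length == 120L, ]
  expect_false(bad$reported)
  expect_false(bad$pass_length)
  expect_true(bad$pass_distance)

  # distance rule: 100 bp from the gene fails, 200 exactly passes
  d2 <- integer(10000); d2[1001:2000] <- 30L
  d2[2101:2400] <- 20L   # starts 100 bp after gene end
  d2[5001:5300] <- 20L   # far away
  cv2 <- cov_track(d2, "all")
  nv2 <- detect_novel_transcripts(build_tars(cv2, 2L), gm, cv2)
  near <- nv2[nv2$start == 2100L, ]
  expect_false(near$reported)
  expect_false(near$pass_distance)
  expect_equal(near$distance_to_nearest_gene, 100)
  d3 <- integer(10000); d3[1001:2000] <- 30L; d3[2201:2500] <- 20L
  cv3 <- cov_track(d3, "all")
  nv3 <- detect_novel_transcripts(build_tars(cv3, 2L), gm, cv3)
  expect_true(nv3$reported[nv3$start == 2200L])
})

test_that("expression rule requires depth above flanking background", {
  gm <- gene_models(data.frame(gene_id = "g1", contig = "ctg1",
                               start = 0L, end = 100L, strand = "+"))
  d <- rep(5L, 10000)          # uniform background depth 5 everywhere
  d[5001:5300] <- 5L           # candidate no higher than background
  cv <- cov_track(d, "all")
  tars <- build_tars(cv, min_depth = 5L)
  nv <- detect_novel_transcripts(tars, gm, cv)
  expect_false(any(nv$pass_expression))
})

test_that("genic TARs are never candidates", {
  gm <- gene_models(data.frame(gene_id = "g1", contig = "ctg1",
                               start = 1000L, end = 2000L, strand = "+"))
  d <- integer(5000); d[1501:1900] <- 10L
  cv <- cov_track(d, "all")
  nv <- detect_novel_transcripts(build_tars(cv, 2L), gm, cv)
  expect_equal(nrow(nv), 0L)
})

test_that("shifting all features shifts candidates by the same offset", {
  base_depth <- integer(20000)
  base_depth[1001:2000] <- 30L
  base_depth[2501:2800] <- 20L
  shift <- 1000L
  mk_res <- function(off) {
    d <- integer(20000)
    d[(1001:2000) + off] <- 30L
    d[(2501:2800) + off] <- 20L
    gm <- gene_models(data.frame(gene_id = "g1", contig = "ctg1",
                                 start = 1000L + off, end = 2000L + off,
                                 strand = "+"))
    cv <- cov_track(d, "all")
    detect_novel_transcripts(build_tars(cv, 2L), gm, cv)
  }
  a <- mk_res(0L); b <- mk_res(shift)
  expect_equal(b$start, a$start + shift)
  expect_equal(b$end, a$end + shift)
  expect_equal(b$reported, a$reported)
})
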