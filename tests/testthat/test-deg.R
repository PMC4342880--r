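test_that("equal counts in equal libraries are a perfect null", {
  expect_gte(ac_test(5, 5, 1e6, 1e6), 0.999)
  expect_gte(ac_test(0, 0, 1e6, 1e6), 0.999)
  d <- test_differential_expression(c(g = 5L), c(g = 5L), 1e6, 1e6)
  expect_equal(d$log2_fold_change, 0)
})

test_that("two-sided p-values match the literal series oracle", {
  cases <- expand.grid(x = c(0, 1, 5, 20, 100), y = c(0, 3, 10, 50, 200),
                       ratio = c(1, 2))
  for (i in seq_len(nrow(cases))) {
    na <- 1e6; nb <- 1e6 * cases$ratio[i]
    got <- ac_test(cases$x[i], cases$y[i], na, nb)
    want <- min(1, oracle_ac_two_sided(cases$x[i], cases$y[i], na, nb))
    expect_equal(got, want, tolerance = 1e-9,
                 label = paste("x", cases$x[i], "y", cases$y[i],
                               "r", cases$ratio[i]))
  }
})

test_that("one-sided tails equal direct summation of the count model", {
  # x = 5, y = 0: the probability of the most extreme low split of s = 5
  na <- nb <- 1e6
  lp <- function(yy, s) lchoose(s, yy) + yy * log(nb / (na + nb)) +
    (s - yy) * log(na / (na + nb))
  expect_equal(ac_test(5, 0, na, nb, alternative = "less"),
               exp(lp(0, 5)), tolerance = 1e-12)
  expect_equal(ac_test(5, 8, na, nb, alternative = "greater"),
               sum(exp(lp(8:13, 13))), tolerance = 1e-10)
  # unequal libraries shift the null split accordingly
  expect_equal(ac_test(5, 8, 1e6, 2e6, alternative = "greater"),
               sum(exp(lchoose(13, 8:13) + (8:13) * log(2 / 3) +
                         (13 - 8:13) * log(1 / 3))), tolerance = 1e-10)
})

test_that("swapping the two stages preserves p and flips every call", {
  set.seed(13)
  x <- rpois(400, 80)
  y <- x
  up <- sample(400, 20); y[up] <- rpois(20, 80 * 6)
  na <- sum(x) * 10; nb <- sum(y) * 10
  d1 <- test_differential_expression(x, y, na, nb)
  d2 <- test_differential_expression(y, x, nb, na)
  expect_equal(d1$p_value, d2$p_value, tolerance = 1e-9)
  c1 <- classify_up_down(d1, na, nb)$results$call
  c2 <- classify_up_down(d2, nb, na)$results$call
  expect_equal(c1 == "up", c2 == "down")
  expect_equal(c1 == "ns", c2 == "ns")
})

test_that("BH adjustment matches hand computation and is rank-monotone", {
  expect_equal(adjust_fdr(0.01), 0.01)
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(2)
  p <- runif(50)
  f <- adjust_fdr(p)
  o <- order(p)
  expect_true(all(diff(f[o]) >= -1e-12))
  expect_error(adjust_fdr(c(0.5, 1.2)))
})

test_that("up/down classification respects threshold, sign and exclusions", {
  d <- data.frame(gene_id = c("a", "b", "c", "d"),
                  count_a = c(10L, 10L, 80L, 0L),
                  count_b = c(80L, 12L, 10L, 0L),
                  rpkm_a = NA_real_, rpkm_b = NA_real_,
                  log2_fold_change = c(3, 0.2, -3, 0),
                  p_value = c(1e-5, 0.01, 5e-4, 1),
                  fdr = c(1e-4, 0.01, 5e-4, 1))
  cls <- suppressMessages(classify_up_down(d, 1e6, 1e6, alpha = 0.001))
  expect_equal(cls$n_up, 1L)
  expect_equal(cls$n_down, 1L)
  expect_true(cls$results$excluded[4])
  expect_equal(cls$results$call, c("up", "ns", "down", "ns"))
  # alpha = 1 calls every non-excluded gene
  all_called <- suppressMessages(classify_up_down(d, 1e6, 1e6, alpha = 1))
  expect_equal(sum(all_called$results$call != "ns"), 3L)
})

test_that("planted strong fold changes are detected with high power", {
  set.seed(17)
  n <- 1000L
  mu <- 100
  planted <- 1:100
  x <- rpois(n, mu)
  lam <- rep(mu, n); lam[planted] <- mu * 8
  y <- rpois(n, lam)
  d <- test_differential_expression(x, y, sum(x) * 20, sum(y) * 20)
  cls <- classify_up_down(d, sum(x) * 20, sum(y) * 20, alpha = 0.001)
  power <- mean(cls$results$call[planted] == "up")
  expect_gte(power, 0.95)
})

test_that("hypergeometric enrichment matches combinatorial summation", {
  ann <- data.frame(gene_id = paste0("g", 1:100),
                    term_id = rep(c("T1", "T2"), each = 50))
  # term annotating every universe gene cannot be enriched
  all_ann <- data.frame(gene_id = paste0("g", 1:100), term_id = "ALL")
  uni <- paste0("g", 1:100)
  res_all <- go_enrichment(paste0("g", 1:10), all_ann, uni)
  expect_equal(res_all$p_value, 1)

  # 8 of 10 set genes carry a term held by 10 of 100 universe genes
  ann2 <- data.frame(gene_id = paste0("g", 1:10), term_id = "T")
  set2 <- c(paste0("g", 1:8), "g50", "g60")
  r <- go_enrichment(set2, ann2, uni)
  expect_equal(r$p_value, oracle_hyper_tail(8, 10, 100, 10),
               tolerance = 1e-12)
  expect_gte(r$adjusted_p, r$p_value - 1e-15)
})

test_that("analytic enrichment p matches a label-permutation null", {
  set.seed(29)
  uni <- paste0("g", 1:200)
  term_genes <- paste0("g", 1:40)
  ann <- data.frame(gene_id = term_genes, term_id = "T")
  dset <- sample(uni, 25)
  k_obs <- sum(dset %in% term_genes)
  p_analytic <- go_enrichment(dset, ann, uni)$p_value
  nperm <- 1000L
  k_perm <- replicate(nperm, sum(sample(uni, 25) %in% term_genes))
  p_emp <- mean(k_perm >= k_obs)
  mc_err <- 3 * sqrt(p_analytic * (1 - p_analytic) / nperm)
  expect_lt(abs(p_emp - p_analytic), mc_err + 0.01)
})
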