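#' Audic-Claverie exact test for two unreplicated counts
#'
#' Given `x` reads for a gene in a library of `n_a` total mapped reads and
#' `y` reads in a library of `n_b`, the Audic-Claverie count model is applied
#' in its symmetrized conditional form: under the null of equal underlying
#' rates, `y` given the sum `s = x + y` is Binomial(`s`,
#' `n_b / (n_a + n_b)`). The two-sided p-value sums the probabilities of all
#' outcomes no more likely than the observed one (the minimum-likelihood
#' convention used by exact tests such as `fisher.test`). This form is
#' exactly invariant under swapping the two libraries, and equal counts in
#' equal-size libraries give p = 1.
#'
#' @param x,y observed counts (vectors recycle against each other).
#' @param n_a,n_b library totals (> 0).
#' @param alternative `"two.sided"` (default), `"greater"` (y larger than
#'   expected) or `"less"`.
#' @return numeric vector of p-values.
#' @export
ac_test <- function(x, y, n_a, n_b,
                    alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (any(x < 0) || any(y < 0)) stop("negative counts")
  stopifnot(all(n_a > 0), all(n_b > 0))
  n <- max(length(x), length(y))
  x <- rep_len(as.numeric(x), n); y <- rep_len(as.numeric(y), n)
  s <- x + y
  pb <- rep_len(n_b / (n_a + n_b), n)
  if (alternative == "greater")
    return(stats::pbinom(y - 1, s, pb, lower.tail = FALSE))
  if (alternative == "less")
    return(stats::pbinom(y, s, pb))

  # canonical orientation (smaller count first) so that swapping the two
  # libraries returns a bitwise-identical two-sided p-value
  pa <- rep_len(n_a / (n_a + n_b), n)
  sw <- y > x | (y == x & pb > pa)
  yy <- ifelse(sw, x, y)
  pb <- ifelse(sw, pa, pb)
  y <- yy

  fy <- stats::dbinom(y, s, pb) * (1 + 1e-7)
  # mode of the unimodal pmf, with local fix-up for floating-point rounding
  m <- pmin(s, pmax(0, floor((s + 1) * pb)))
  for (it in 1:3) {
    m <- m + (m < s & stats::dbinom(pmin(m + 1, s), s, pb) >
                stats::dbinom(m, s, pb))
    m <- m - (m > 0 & stats::dbinom(pmax(m - 1, 0), s, pb) >
                stats::dbinom(m, s, pb))
  }
  p <- numeric(n)

  i <- which(y >= m)   # observed at or right of the mode
  if (length(i)) {
    si <- s[i]; pbi <- pb[i]; fyi <- fy[i]; mi <- m[i]
    pr <- stats::pbinom(y[i] - 1, si, pbi, lower.tail = FALSE)
    # largest a in [0, m) with pmf(a) <= pmf(y) (pmf increasing up to mode)
    a <- rep(-1, length(i))
    at_top <- stats::dbinom(mi, si, pbi) <= fyi
    a[at_top] <- mi[at_top]
    todo <- which(!at_top & stats::dbinom(0, si, pbi) <= fyi)
    if (length(todo)) {
      lo <- rep(0, length(todo)); hi <- mi[todo]
      st <- si[todo]; pbt <- pbi[todo]; fyt <- fyi[todo]
      while (any(hi - lo > 1)) {
        mid <- floor((lo + hi) / 2)
        ok <- stats::dbinom(mid, st, pbt) <= fyt
        adv <- hi - lo > 1
        lo[ok & adv] <- mid[ok & adv]
        hi[!ok & adv] <- mid[!ok & adv]
      }
      a[todo] <- lo
    }
    pl <- ifelse(a >= 0, stats::pbinom(pmax(a, 0), si, pbi), 0)
    p[i] <- pr + pl
  }
  i <- which(y < m)    # observed left of the mode
  if (length(i)) {
    si <- s[i]; pbi <- pb[i]; fyi <- fy[i]
    pl <- stats::pbinom(y[i], si, pbi)
    # smallest b in (mode, s] with pmf(b) <= pmf(y); none if even pmf(s) > fy
    lo <- m[i]; hi <- si
    none <- stats::dbinom(si, si, pbi) > fyi
    at_mode <- stats::dbinom(lo, si, pbi) <= fyi
    hi[at_mode] <- lo[at_mode]
    while (any(hi - lo > 1)) {
      mid <- floor((lo + hi) / 2)
      ok <- stats::dbinom(mid, si, pbi) <= fyi
      adv <- hi - lo > 1
      hi[ok & adv] <- mid[ok & adv]
      lo[!ok & adv] <- mid[!ok & adv]
    }
    pr <- stats::pbinom(hi - 1, si, pbi, lower.tail = FALSE)
    pr[none] <- 0
    p[i] <- pl + pr
  }
  pmin(p, 1)
}

#' Pairwise differential expression without replicates
#'
#' Tests each gene's counts in two libraries with the Audic-Claverie exact
#' count test (default) or a two-proportion test, and reports a
#' Benjamini-Hochberg FDR alongside a display fold change computed on
#' library-size-normalized counts with a pseudocount (the pseudocount never
#' enters the test).
#'
#' @param counts_a,counts_b named count vectors (same genes, same order).
#' @param total_a,total_b library totals (> 0).
#' @param method `"ac"` (default) or `"prop"`.
#' @param pseudocount added to both counts for the fold-change display only
#'   (default 1).
#' @param exon_lengths optional named vector; when given, RPKM columns are
#'   filled.
#' @return data.frame: gene_id, count_a, count_b, rpkm_a, rpkm_b,
#'   log2_fold_change, p_value, fdr.
#' @export
test_differential_expression <- function(counts_a, counts_b, total_a, total_b,
                                         method = c("ac", "prop"),
                                         pseudocount = 1,
                                         exon_lengths = NULL) {
  method <- match.arg(method)
  stopifnot(length(counts_a) == length(counts_b), total_a > 0, total_b > 0)
  if (any(counts_a < 0) || any(counts_b < 0)) stop("negative counts")
  gid <- names(counts_a)
  if (is.null(gid)) gid <- paste0("g", seq_along(counts_a))
  p <- if (method == "ac") {
    ac_test(counts_a, counts_b, total_a, total_b)
  } else {
    vapply(seq_along(counts_a), function(i) {
      if (counts_a[i] + counts_b[i] == 0) return(1)
      suppressWarnings(stats::prop.test(
        c(counts_a[i], counts_b[i]),
        c(total_a, total_b))$p.value)
    }, numeric(1))
  }
  lfc <- log2(((counts_b + pseudocount) / total_b) /
              ((counts_a + pseudocount) / total_a))
  rpkm_a <- rpkm_b <- rep(NA_real_, length(counts_a))
  if (!is.null(exon_lengths)) {
    rpkm_a <- as.numeric(compute_rpkm(stats::setNames(counts_a, gid),
                                      exon_lengths, total_a))
    rpkm_b <- as.numeric(compute_rpkm(stats::setNames(counts_b, gid),
                                      exon_lengths, total_b))
  }
  data.frame(gene_id = gid, count_a = as.integer(counts_a),
             count_b = as.integer(counts_b), rpkm_a = rpkm_a,
             rpkm_b = rpkm_b, log2_fold_change = lfc, p_value = p,
             fdr = adjust_fdr(p), stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg (or Benjamini-Yekutieli) adjusted p-values
#'
#' @param p_values vector in [0, 1].
#' @param method `"BH"` (default) or `"BY"`.
#' @return adjusted values, same length.
#' @export
adjust_fdr <- function(p_values, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values outside [0, 1]")
  stats::p.adjust(p_values, method = method)
}

#' Classify significant genes as up- or down-regulated
#'
#' A gene is called at `fdr <= alpha`; the direction compares library-size
#' normalized rates (B over A). Genes with zero counts in both libraries are
#' excluded from calling.
#'
#' @param deg result of [test_differential_expression()] plus `total_a`,
#'   `total_b` used there.
#' @param total_a,total_b the library totals used in the test.
#' @param alpha FDR threshold (default 0.001).
#' @param annotation optional data.frame (`gene_id`, `term_id`); when given,
#'   a per-term cross-tabulation of up/down calls is returned.
#' @return list: `results` (deg with `call` in {up, down, ns} and `excluded`),
#'   `n_up`, `n_down`, `by_term` (NULL without annotation).
#' @export
classify_up_down <- function(deg, total_a, total_b, alpha = 0.001,
                             annotation = NULL) {
  rate_a <- deg$count_a / total_a
  rate_b <- deg$count_b / total_b
  excluded <- deg$count_a == 0L & deg$count_b == 0L
  if (any(excluded))
    message(sum(excluded), " gene(s) with zero counts in both libraries ",
            "excluded from calling")
  sig <- !excluded & deg$fdr <= alpha
  call <- rep("ns", nrow(deg))
  call[sig & rate_b > rate_a] <- "up"
  call[sig & rate_b < rate_a] <- "down"
  deg$call <- call
  deg$excluded <- excluded
  by_term <- NULL
  if (!is.null(annotation)) {
    ann <- annotation[annotation$gene_id %in% deg$gene_id, ]
    ann$call <- deg$call[match(ann$gene_id, deg$gene_id)]
    by_term <- as.data.frame.matrix(table(ann$term_id, ann$call))
    by_term$term_id <- rownames(by_term)
    rownames(by_term) <- NULL
  }
  list(results = deg, n_up = sum(call == "up"), n_down = sum(call == "down"),
       by_term = by_term)
}

#' GO-term over-representation by the hypergeometric (Fisher) test
#'
#' One-sided hypergeometric tail per term: the probability of seeing at
#' least the observed number of term-annotated genes in the test set, given
#' the term's frequency in the universe. P-values are FDR-adjusted across
#' terms.
#'
#' @param deg_set character vector of test genes (subset of `universe`).
#' @param annotation data.frame with `gene_id` and `term_id`.
#' @param universe character vector of all testable genes.
#' @param adjust `"BH"` (default) or `"BY"`.
#' @return data.frame: term_id, set_with_term, set_size, universe_with_term,
#'   universe_size, p_value, adjusted_p.
#' @export
go_enrichment <- function(deg_set, annotation, universe, adjust = "BH") {
  if (!all(deg_set %in% universe)) stop("deg_set must be a subset of universe")
  ann <- annotation[annotation$gene_id %in% universe, ]
  terms <- split(unique(ann[, c("gene_id", "term_id")])$gene_id,
                 unique(ann[, c("gene_id", "term_id")])$term_id)
  terms <- terms[vapply(terms, length, 1L) > 0L]
  n_set <- length(deg_set)
  n_uni <- length(universe)
  res <- lapply(names(terms), function(tm) {
    genes <- terms[[tm]]
    k <- sum(deg_set %in% genes)
    big_k <- length(genes)
    data.frame(term_id = tm, set_with_term = k, set_size = n_set,
               universe_with_term = big_k, universe_size = n_uni,
               p_value = stats::phyper(k - 1, big_k, n_uni - big_k, n_set,
                                       lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    return(data.frame(term_id = character(0), set_with_term = integer(0),
                      set_size = integer(0), universe_with_term = integer(0),
                      universe_size = integer(0), p_value = numeric(0),
                      adjusted_p = numeric(0)))
  out$adjusted_p <- adjust_fdr(out$p_value, method = adjust)
  out[order(out$p_value), ]
}
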