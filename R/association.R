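#' Chi-squared goodness-of-fit test
#'
#' Pearson's goodness-of-fit statistic `sum((O - E)^2 / E)` with
#' `E = n * p`, no continuity correction, and an upper-tail chi-squared
#' p-value on `length(observed) - 1` degrees of freedom. Used for the
#' segregation-ratio and melanoma-incidence tests.
#'
#' @param observed Non-negative integer counts.
#' @param expected_proportions Proportions summing to 1, same length.
#' @return A list of class `grey_test` with `statistic`, `df`, `p_value`,
#'   `method`.
#' @examples
#' chi2_goodness_of_fit(c(10, 6), c(0.5, 0.5))  # X2 = 1, P = 0.32
#' @export
chi2_goodness_of_fit <- function(observed, expected_proportions) {
  stopifnot(length(observed) == length(expected_proportions),
            all(observed >= 0), sum(observed) > 0)
  if (abs(sum(expected_proportions) - 1) > 1e-8)
    stop("expected proportions must sum to 1")
  if (any(expected_proportions <= 0))
    stop("expected count of zero: all expected proportions must be positive")
  ht <- suppressWarnings(stats::chisq.test(observed, p = expected_proportions))
  structure(list(statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = unname(ht$p.value),
                 method = "chi-squared goodness of fit"),
            class = "grey_test")
}

#' @exportS3Method base::print
print.grey_test <- function(x, ...) {
  cat(x$method, ": ", sep = "")
  if (!is.null(x$statistic) && !is.na(x$statistic))
    cat(sprintf("statistic = %.4g, ", x$statistic))
  if (!is.null(x$df) && !is.na(x$df)) cat(sprintf("df = %d, ", x$df))
  cat(sprintf("P = %.3g\n", x$p_value))
  invisible(x)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric test with fixed margins; the two-sided p-value
#' sums the probabilities of all tables whose point probability does not
#' exceed that of the observed table. Degenerate margins give p = 1.
#'
#' @param table 2x2 matrix of non-negative integer counts, or a length-4
#'   vector `c(a, b, c, d)` filled row-wise.
#' @return A `grey_test` (no statistic; `df` NA).
#' @examples
#' fisher_exact_two_sided(matrix(c(8, 0, 0, 13), 2, byrow = TRUE))
#' @export
fisher_exact_two_sided <- function(table) {
  if (!is.matrix(table)) table <- matrix(table, nrow = 2, byrow = TRUE)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0), sum(table) > 0)
  p <- stats::fisher.test(table, alternative = "two.sided")$p.value
  structure(list(statistic = NA_real_, df = NA_integer_,
                 p_value = min(1, p), method = "Fisher's exact test (two-sided)"),
            class = "grey_test")
}

#' Per-SNP association scan under a dominance model
#'
#' For each site, samples are classified as carriers (genotype >= 1) or
#' non-carriers and cross-tabulated against the two phenotype classes; the
#' two-sided Fisher exact p-value of that 2x2 table is reported. Sites
#' monomorphic in carrier status get p = 1. Samples with missing genotype
#' at a site are dropped from that site's table.
#'
#' @param snps A [snp_matrix()].
#' @param phenotypes Vector with exactly two distinct non-missing classes,
#'   either named by sample or in `rownames(snps$genotypes)` order.
#' @return Data frame `chrom`, `pos`, `p` with one row per site.
#' @export
gwas_dominance_scan <- function(snps, phenotypes) {
  stopifnot(inherits(snps, "snp_matrix"))
  g <- snps$genotypes
  if (!is.null(names(phenotypes))) {
    if (!all(rownames(g) %in% names(phenotypes)))
      stop("phenotypes missing for some samples")
    phenotypes <- phenotypes[rownames(g)]
  }
  if (length(phenotypes) != nrow(g))
    stop("phenotype vector length does not match the number of samples")
  classes <- sort(unique(stats::na.omit(phenotypes)))
  if (length(classes) != 2) stop("exactly two phenotype classes are required")
  is_case <- phenotypes == classes[1]

  # memoize over the (small) set of distinct 2x2 tables
  cache <- new.env(parent = emptyenv())
  p_of <- function(a, b, c, d) {
    key <- paste(a, b, c, d, sep = "_")
    if (is.null(cache[[key]]))
      cache[[key]] <- fisher_exact_two_sided(matrix(c(a, b, c, d), 2,
                                                    byrow = TRUE))$p_value
    cache[[key]]
  }
  n_sites <- ncol(g)
  p <- vapply(seq_len(n_sites), function(j) {
    gt <- g[, j]
    ok <- !is.na(gt) & !is.na(phenotypes)
    carrier <- gt[ok] >= 1
    case <- is_case[ok]
    a <- sum(carrier & case); b <- sum(carrier & !case)
    c_ <- sum(!carrier & case); d <- sum(!carrier & !case)
    if ((a + b == 0) || (c_ + d == 0)) return(1)
    p_of(a, b, c_, d)
  }, numeric(1))
  data.frame(chrom = snps$chrom, pos = snps$positions, p = p,
             stringsAsFactors = FALSE)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate in (0, 1).
#' @param n_tests Number of independent tests (>= 1).
#' @return `alpha / n_tests`.
#' @examples
#' bonferroni_threshold(0.05, 50000)  # 1e-6
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  stopifnot(alpha > 0, alpha < 1, n_tests >= 1)
  alpha / n_tests
}
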