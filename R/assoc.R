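# Non-model statistics: Fisher exact allele-by-dose tests, Wilcoxon
# comparisons, heterozygote ratio t-intervals, homozygote bootstrap ratio
# of means, correlations, and the genotype favourability ranking.

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact hypergeometric two-sided p-value: the sum of the probabilities of
#' all tables (with the observed margins) no more probable than the
#' observed one — the conventional definition, as implemented in
#' [stats::fisher.test()].
#'
#' @param table A 2x2 matrix (or something coercible) of non-negative
#'   integer counts, conventionally allele presence (rows) by dose group
#'   (columns).
#' @return A one-row tibble: `p.value`, `odds.ratio` (conditional MLE).
#' @examples
#' fisher_exact_2x2(matrix(c(13, 5, 5, 13), 2))  # p ~ 0.02
#' @export
fisher_exact_2x2 <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2L, 2L))) abort("`table` must be 2x2.")
  if (any(m < 0) || any(m != round(m))) {
    abort("`table` must contain non-negative integer counts.")
  }
  ft <- stats::fisher.test(m)
  tibble::tibble(p.value = ft$p.value,
                 odds.ratio = unname(ft$estimate))
}

#' Wilcoxon rank-sum test
#'
#' Two-sided Wilcoxon rank-sum comparison of two samples: exact by full
#' enumeration of rank assignments when the combined size is at most 20 and
#' there are no ties, otherwise (or on request) the normal approximation
#' with tie correction.
#'
#' @param x,y Numeric samples.
#' @param exact `NULL` (default: exact when feasible), or a logical
#'   overriding the choice.
#' @return A one-row tibble: `statistic` (rank-sum W), `p.value`, `exact`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(10, 11, 12))$p.value  # 0.1 two-sided
#' @export
wilcoxon_rank_sum <- function(x, y, exact = NULL) {
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- exact %||% (length(x) + length(y) <= 20 && !ties)
  if (use_exact && ties) {
    warn("ties present; falling back to the normal approximation")
    use_exact <- FALSE
  }
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = !use_exact)
  )
  tibble::tibble(statistic = unname(wt$statistic), p.value = wt$p.value,
                 exact = use_exact)
}

#' Mean ratio with t-distribution confidence interval and test against 1
#'
#' For per-participant ratios (e.g. heterozygote *02:*04 usage ratios),
#' reports the mean, the 95% t-distribution confidence interval, and a
#' two-sided one-sample t-test of the null that the mean ratio equals
#' `null`. Degenerate inputs (fewer than two values, or zero variance)
#' return a flagged no-variance result rather than a zero p-value.
#'
#' @param ratios Numeric vector of per-participant ratios.
#' @param null Null value for the test (default 1).
#' @param conf.level Confidence level.
#' @return A one-row tibble: `n`, `estimate`, `se`, `conf.low`,
#'   `conf.high`, `p.value`, `degenerate`.
#' @examples
#' ratio_t_ci(c(2.1, 3.7, 5.2, 4.4))
#' @export
ratio_t_ci <- function(ratios, null = 1, conf.level = 0.95) {
  r <- ratios[!is.na(ratios)]
  n <- length(r)
  if (n == 0) {
    return(tibble::tibble(n = 0L, estimate = NA_real_, se = NA_real_,
                          conf.low = NA_real_, conf.high = NA_real_,
                          p.value = NA_real_, degenerate = TRUE))
  }
  m <- mean(r)
  if (n < 2 || sd(r) == 0) {
    return(tibble::tibble(n = n, estimate = m, se = 0,
                          conf.low = m, conf.high = m,
                          p.value = NA_real_, degenerate = TRUE))
  }
  se <- sd(r) / sqrt(n)
  tq <- qt(1 - (1 - conf.level) / 2, n - 1)
  tstat <- (m - null) / se
  tibble::tibble(n = n, estimate = m, se = se,
                 conf.low = m - tq * se, conf.high = m + tq * se,
                 p.value = 2 * pt(-abs(tstat), n - 1), degenerate = FALSE)
}

#' Bootstrap ratio of group means
#'
#' Percentile bootstrap for the ratio `mean(x_02) / mean(x_04)` between two
#' independent groups (e.g. homozygous *02 vs homozygous *04 participants):
#' participants are resampled with replacement within each group. The
#' p-value inverts the percentile interval via tail proportions,
#' `p = 2 * min(P(ratio* <= null), P(ratio* >= null))`, capped at 1.
#'
#' @param x_02,x_04 Numeric vectors of per-participant values for the two
#'   groups.
#' @param B Number of bootstrap samples (default 10000).
#' @param null Null ratio for the p-value (default 1).
#' @param conf.level Confidence level for the percentile interval.
#' @param seed Optional integer seed for reproducibility.
#' @return A one-row tibble: `estimate` (plug-in ratio), `conf.low`,
#'   `conf.high`, `p.value`, `B`.
#' @examples
#' bootstrap_ratio_of_means(c(3, 4, 5), c(1, 1.5, 2), B = 500, seed = 1)
#' @export
bootstrap_ratio_of_means <- function(x_02, x_04, B = 10000L, null = 1,
                                     conf.level = 0.95, seed = NULL) {
  stopifnot(length(x_02) > 0, length(x_04) > 0, B >= 1)
  if (!is.null(seed)) set.seed(seed)
  n1 <- length(x_02)
  n2 <- length(x_04)
  draws <- vapply(seq_len(B), function(b) {
    mean(x_02[sample.int(n1, n1, replace = TRUE)]) /
      mean(x_04[sample.int(n2, n2, replace = TRUE)])
  }, numeric(1))
  draws <- draws[is.finite(draws)]
  alpha <- 1 - conf.level
  ci <- quantile(draws, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  p <- min(1, 2 * min(mean(draws <= null), mean(draws >= null)))
  tibble::tibble(estimate = mean(x_02) / mean(x_04),
                 conf.low = ci[1], conf.high = ci[2],
                 p.value = p, B = length(draws))
}

#' Correlation with optional exact permutation p-value
#'
#' Rank-based (Spearman, with average ranks) or linear (Pearson)
#' correlation. The p-value uses the t approximation by default; for small
#' samples a permutation p-value is available, computed by full enumeration
#' of all `n!` orderings when `n <= 8` and by seeded random permutations
#' otherwise.
#'
#' @param x,y Numeric vectors.
#' @param method `"spearman"` (rank-based, default) or `"pearson"`
#'   (linear).
#' @param permutation Use a permutation p-value instead of the t
#'   approximation.
#' @param B Random permutations when enumeration is infeasible.
#' @param seed Seed for random permutations.
#' @return A one-row tibble: `estimate` (r), `p.value`, `method`,
#'   `p.method`.
#' @examples
#' correlation(1:6, c(2, 1, 4, 3, 6, 5))
#' @export
correlation <- function(x, y, method = c("spearman", "pearson"),
                        permutation = FALSE, B = 10000L, seed = NULL) {
  method <- match.arg(method)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  stopifnot(n >= 3)
  r <- stats::cor(x, y, method = method)
  if (!permutation) {
    ct <- suppressWarnings(stats::cor.test(x, y, method = method))
    return(tibble::tibble(estimate = r, p.value = ct$p.value,
                          method = method, p.method = "asymptotic"))
  }
  stat <- function(perm) stats::cor(x, y[perm], method = method)
  if (n <= 8) {
    perms <- permutations_of(n)
    stats_all <- apply(perms, 1, stat)
    p <- mean(abs(stats_all) >= abs(r) - 1e-12)
    p.method <- "exact permutation"
  } else {
    if (!is.null(seed)) set.seed(seed)
    stats_all <- vapply(seq_len(B), function(b) stat(sample.int(n)),
                        numeric(1))
    # add-one correction so the observed ordering counts once
    p <- (sum(abs(stats_all) >= abs(r) - 1e-12) + 1) / (B + 1)
    p.method <- "random permutation"
  }
  tibble::tibble(estimate = r, p.value = p, method = method,
                 p.method = p.method)
}

# all permutations of 1..n as a matrix (n! rows); recursion is fine for the
# n <= 8 sizes this is used at
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}

#' Favourability rank of an IGHV1-2 genotype
#'
#' Most-to-least favourable ranking of genotypes for induction of a
#' VRC01-class response, ordered by expected precursor frequency (the
#' *02-family per-allele frequency being roughly four-fold that of *04, and
#' *05/*06 lacking the required binding motif): (1) *02/*02, (2) *02/*04,
#' (3) *02/*05 or *02/*06, (4) *04/*04, (5) *04/*05 or *04/*06. The
#' *05/*06 genotype has no productive allele and is unranked (`NA`).
#'
#' @param allele_1,allele_2 Allele labels (vectors recycle); `*02_S4953`
#'   counts as `*02`.
#' @return Integer rank(s) 1-5, or `NA` for genotypes without a productive
#'   allele.
#' @examples
#' genotype_rank("*02", "*02")  # 1
#' genotype_rank("*04", "*06")  # 5
#' genotype_rank("*05", "*06")  # NA
#' @export
genotype_rank <- function(allele_1, allele_2) {
  z <- zygosity_counts(allele_1, allele_2)
  dplyr::case_when(
    z$n02 == 2L ~ 1L,
    z$n02 == 1L & z$n04 == 1L ~ 2L,
    z$n02 == 1L ~ 3L,
    z$n04 == 2L ~ 4L,
    z$n04 == 1L ~ 5L,
    TRUE ~ NA_integer_
  )
}

#' Allele-by-dose contingency table
#'
#' Builds the 2x2 carrier table (allele present/absent by dose group) for
#' one allele among the vaccine recipients, the input to
#' [fisher_exact_2x2()].
#'
#' @param participants Participant tibble (see [simulate_genotypes()]).
#' @param allele Allele label; `"*02"` includes `*02_S4953`.
#' @param groups The two dose groups to compare.
#' @return A 2x2 integer matrix with dimnames.
#' @export
allele_dose_table <- function(participants, allele,
                              groups = c("low", "high")) {
  pt <- tibble::as_tibble(participants) |>
    dplyr::filter(.data$dose_group %in% groups)
  fam <- if (allele == "*02") alleles_02() else allele
  carrier <- pt$allele_1 %in% fam | pt$allele_2 %in% fam
  m <- vapply(groups, function(g) {
    sel <- pt$dose_group == g
    c(sum(carrier & sel), sum(!carrier & sel))
  }, integer(2))
  dimnames(m) <- list(c("present", "absent"), groups)
  m
}
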