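#' Configuration for a synthetic germline-targeting vaccine trial
#'
#' Bundles every parameter of the synthetic-trial generator: the allele pool
#' and its frequencies, per-allele naive-repertoire mRNA usage rates, the
#' unique-HCDR3 thinning ratio, the additive per-allele response
#' contributions, over-dispersion, library and sampling depths, and the read
#' mutation rate.
#'
#' Defaults are calibrated to the published trial structure: two vaccine dose
#' groups of 18 participants plus 12 placebo recipients; *04 the most common
#' IGHV1-2 allele followed by *02; per-allele mRNA usage of 3.1% for *02 and
#' 0.9% for *04 (with *05 rare at 0.09% and *06 intermediate at 2.4%); a
#' unique-HCDR3-to-mRNA count ratio of 0.23; and a roughly four-fold higher
#' per-allele VRC01-class response contribution for *02 than *04.
#'
#' @param n_per_group Participants per dose group. Either a single integer
#'   (all three groups equal) or a named/ordered length-3 vector for
#'   `low`, `high`, `placebo`. Default `c(18, 18, 12)`.
#' @param allele_freqs Named numeric vector of population frequencies for the
#'   alleles `*02`, `*02_S4953`, `*04`, `*05`, `*06`; must sum to 1.
#' @param expr_rate_per_allele Named numeric vector: expected fraction of all
#'   library mRNA molecules (unique UMIs) contributed by one copy of each
#'   allele.
#' @param hcdr3_ratio Expected ratio of unique-HCDR3 count to UMI count per
#'   allele (binomial thinning probability). Default 0.23.
#' @param beta_02,beta_04 Per-allele VRC01-class response contribution
#'   (expected VRC01-class B cells per sampled IgG B cell per allele copy).
#' @param dose_delta Additive high-dose effect on the response frequency
#'   (same units as the betas). Default 0.
#' @param dispersion Variance inflation factor `phi >= 1` for response
#'   counts; counts have mean `mu` and variance `phi * mu` (NB1). Default 2.
#' @param n_total_umis Unique UMIs per IgM library. Default 30000.
#' @param n_igg_sampled Total IgG B cells sampled per response measurement
#'   (`N`). Default 50000.
#' @param mutation_rate Per-base substitution probability for simulated BCR
#'   reads. Default 0.01.
#' @param seed Integer seed used by [simulate_trial()] when no seed is given
#'   at the call site.
#'
#' @return An object of class `trial_config` (a validated named list).
#' @examples
#' cfg <- trial_config(n_per_group = 6)
#' cfg$allele_freqs
#' @export
trial_config <- function(n_per_group = c(18L, 18L, 12L),
                         allele_freqs = c("*02" = 0.25, "*02_S4953" = 0.02,
                                          "*04" = 0.55, "*05" = 0.03,
                                          "*06" = 0.15),
                         expr_rate_per_allele = c("*02" = 0.031,
                                                  "*02_S4953" = 0.031,
                                                  "*04" = 0.009,
                                                  "*05" = 0.0009,
                                                  "*06" = 0.024),
                         hcdr3_ratio = 0.23,
                         beta_02 = 8e-4,
                         beta_04 = 2e-4,
                         dose_delta = 0,
                         dispersion = 2,
                         n_total_umis = 30000L,
                         n_igg_sampled = 50000L,
                         mutation_rate = 0.01,
                         seed = 1L) {
  if (length(n_per_group) == 1L) n_per_group <- rep(n_per_group, 3L)
  if (length(n_per_group) != 3L) {
    abort("`n_per_group` must have length 1 or 3 (low, high, placebo).")
  }
  n_per_group <- as.integer(n_per_group)
  if (is.null(names(n_per_group)) || !all(nzchar(names(n_per_group)))) {
    names(n_per_group) <- c("low", "high", "placebo")
  }
  if (any(n_per_group < 0L)) abort("`n_per_group` must be non-negative.")

  pool <- ighv12_alleles()
  if (!setequal(names(allele_freqs), pool)) {
    abort(paste0("`allele_freqs` must be named with exactly: ",
                 paste(pool, collapse = ", ")))
  }
  allele_freqs <- allele_freqs[pool]
  if (any(allele_freqs < 0) || abs(sum(allele_freqs) - 1) > 1e-12) {
    abort("`allele_freqs` must be non-negative and sum to 1 (within 1e-12).")
  }

  if (!setequal(names(expr_rate_per_allele), pool)) {
    abort(paste0("`expr_rate_per_allele` must be named with exactly: ",
                 paste(pool, collapse = ", ")))
  }
  expr_rate_per_allele <- expr_rate_per_allele[pool]
  if (any(expr_rate_per_allele < 0) || any(expr_rate_per_allele > 1)) {
    abort("`expr_rate_per_allele` entries must lie in [0, 1].")
  }
  # homozygotes draw at twice the per-allele rate
  if (any(2 * expr_rate_per_allele > 1)) {
    abort("2 * `expr_rate_per_allele` must not exceed 1 for any allele.")
  }

  stopifnot(hcdr3_ratio >= 0, hcdr3_ratio <= 1,
            mutation_rate >= 0, mutation_rate <= 1)
  if (beta_02 < 0 || beta_04 < 0) abort("beta parameters must be >= 0.")
  if (dispersion < 1) abort("`dispersion` must be >= 1.")
  if (2 * max(beta_02, beta_04) + max(dose_delta, 0) > 1) {
    abort("response frequencies imply a per-cell rate > 1.")
  }
  if (dose_delta < 0 && min(beta_02, beta_04) + dose_delta < 0) {
    # the smallest productive genotype is a single *02 or *04 allele;
    # a dose_delta that can push its mean below zero is invalid
    abort("`dose_delta` would produce a negative response mean.")
  }
  n_total_umis <- as.integer(n_total_umis)
  n_igg_sampled <- as.integer(n_igg_sampled)
  stopifnot(n_total_umis > 0L, n_igg_sampled > 0L)

  structure(
    list(n_per_group = n_per_group,
         allele_freqs = allele_freqs,
         expr_rate_per_allele = expr_rate_per_allele,
         hcdr3_ratio = hcdr3_ratio,
         beta_02 = beta_02,
         beta_04 = beta_04,
         dose_delta = dose_delta,
         dispersion = dispersion,
         n_total_umis = n_total_umis,
         n_igg_sampled = n_igg_sampled,
         mutation_rate = mutation_rate,
         seed = as.integer(seed)),
    class = "trial_config"
  )
}

#' @export
print.trial_config <- function(x, ...) {
  cat("<trial_config>\n")
  cat("  groups (low/high/placebo):", paste(x$n_per_group, collapse = "/"), "\n")
  cat("  allele freqs:",
      paste(sprintf("%s=%.3f", names(x$allele_freqs), x$allele_freqs),
            collapse = " "), "\n")
  cat("  expr rates:",
      paste(sprintf("%s=%.4f", names(x$expr_rate_per_allele),
                    x$expr_rate_per_allele), collapse = " "), "\n")
  cat(sprintf("  hcdr3_ratio=%.3g beta_02=%.3g beta_04=%.3g dose_delta=%.3g phi=%.3g\n",
              x$hcdr3_ratio, x$beta_02, x$beta_04, x$dose_delta, x$dispersion))
  cat(sprintf("  n_total_umis=%d n_igg_sampled=%d mutation_rate=%.3g seed=%d\n",
              x$n_total_umis, x$n_igg_sampled, x$mutation_rate, x$seed))
  invisible(x)
}

# zygosity counts from two allele labels: n02 counts *02 and its silent
# variant *02_S4953; n04 counts *04
zygosity_counts <- function(allele_1, allele_2) {
  n02 <- (allele_1 %in% alleles_02()) + (allele_2 %in% alleles_02())
  n04 <- (allele_1 == "*04") + (allele_2 == "*04")
  list(n02 = as.integer(n02), n04 = as.integer(n04))
}
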