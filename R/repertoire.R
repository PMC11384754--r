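# Per-allele naive-repertoire quantification from UMI-tagged IgM
# rearrangement tables.
#
# The measurement model: each unique UMI is one mRNA molecule; only
# germline-identical records (zero V mismatches) count; the per-allele mRNA
# usage frequency is unique UMIs for that allele over all unique UMIs in the
# library, and the unique-HCDR3 frequency is the analogous fraction of
# distinct HCDR3 strings (a proxy for distinct B cell clones).

# rows usable for germline-allele counting: unmutated, with a UMI.
# Records with a missing mismatch annotation are treated as mutated and
# excluded (conservative).
.usable_records <- function(records, require_cdr3 = FALSE) {
  rec <- tibble::as_tibble(records)
  needed <- c("umi", "v_call", "v_mismatches")
  missing_cols <- setdiff(needed, names(rec))
  if (length(missing_cols)) {
    abort(paste("records lack column(s):", paste(missing_cols, collapse = ", ")))
  }
  n_no_umi <- sum(is.na(rec$umi) | rec$umi == "")
  if (n_no_umi > 0) {
    warn(sprintf("%d record(s) without a UMI skipped", n_no_umi))
    rec <- dplyr::filter(rec, !is.na(.data$umi), .data$umi != "")
  }
  if (require_cdr3) {
    n_no_cdr3 <- sum(is.na(rec$cdr3_aa) | rec$cdr3_aa == "")
    if (n_no_cdr3 > 0) {
      warn(sprintf("%d record(s) with empty HCDR3 excluded", n_no_cdr3))
      rec <- dplyr::filter(rec, !is.na(.data$cdr3_aa), .data$cdr3_aa != "")
    }
  }
  dplyr::filter(rec, !is.na(.data$v_mismatches), .data$v_mismatches == 0)
}

#' Count unique UMIs per germline allele
#'
#' Counts, for each V-gene allele call, the unique UMIs among
#' germline-identical records (zero V mismatches). Duplicate (allele, UMI)
#' pairs count once; records with mismatches, a missing mismatch
#' annotation, or no UMI are excluded.
#'
#' @param records Rearrangement table with columns `umi`, `v_call`,
#'   `v_mismatches` (and optionally `participant_id`, `primer_set`).
#' @return A tibble with `v_call`, `umi_count`, and the library total
#'   `total_umis` (unique UMIs over all usable records) repeated on each
#'   row.
#' @examples
#' rec <- tibble::tibble(umi = c("u1", "u1", "u2"),
#'                       v_call = c("*02", "*02", "*04"),
#'                       v_mismatches = c(0, 0, 0))
#' count_umis_per_allele(rec)
#' @export
count_umis_per_allele <- function(records) {
  rec <- .usable_records(records)
  counts <- rec |>
    dplyr::distinct(.data$v_call, .data$umi) |>
    dplyr::count(.data$v_call, name = "umi_count")
  counts$total_umis <- sum(counts$umi_count)
  counts
}

#' Count unique HCDR3s per germline allele
#'
#' Applies the same germline-identical filtering as
#' [count_umis_per_allele()] and counts distinct HCDR3 amino-acid strings
#' per allele (exact string equality; no clustering). Records with an empty
#' HCDR3 are excluded with a warning.
#'
#' @inheritParams count_umis_per_allele
#' @return A tibble with `v_call`, `hcdr3_count`, and the library-wide
#'   total `total_hcdr3s` (distinct HCDR3s over all usable records).
#' @export
count_unique_hcdr3 <- function(records) {
  rec <- .usable_records(records, require_cdr3 = TRUE)
  counts <- rec |>
    dplyr::distinct(.data$v_call, .data$cdr3_aa) |>
    dplyr::count(.data$v_call, name = "hcdr3_count")
  counts$total_hcdr3s <- dplyr::n_distinct(rec$cdr3_aa)
  counts
}

#' Per-allele usage table for one library
#'
#' Combines UMI and unique-HCDR3 counts into one usage table with
#' frequencies relative to the whole library (all IGHV genes).
#'
#' @param records Rearrangement table for a single library (one participant,
#'   one primer set); must carry `participant_id` and `primer_set` columns
#'   or supply them via arguments.
#' @param participant_id,primer_set Overrides when the columns are absent.
#' @return A tibble of class `allele_usage`: `participant_id`, `primer_set`,
#'   `allele` (the `v_call`), `umi_count`, `umi_frequency`, `hcdr3_count`,
#'   `hcdr3_frequency`.
#' @examples
#' cfg <- trial_config(n_total_umis = 500)
#' set.seed(1)
#' p <- simulate_genotypes(cfg)[1, ]
#' allele_usage(simulate_repertoire(p, cfg, "leader"))
#' @export
allele_usage <- function(records, participant_id = NULL, primer_set = NULL) {
  rec <- tibble::as_tibble(records)
  pid <- participant_id %||% unique(rec$participant_id)
  ps <- primer_set %||% unique(rec$primer_set)
  if (length(pid) != 1L || length(ps) != 1L) {
    abort("`records` must come from a single participant and primer set.")
  }
  umis <- count_umis_per_allele(rec)
  hc <- count_unique_hcdr3(rec)
  total_umis <- if (nrow(umis)) umis$total_umis[1] else 0L
  total_hc <- if (nrow(hc)) hc$total_hcdr3s[1] else 0L
  out <- dplyr::full_join(
    dplyr::select(umis, "v_call", "umi_count"),
    dplyr::select(hc, "v_call", "hcdr3_count"),
    by = "v_call"
  ) |>
    tidyr::replace_na(list(umi_count = 0L, hcdr3_count = 0L)) |>
    dplyr::transmute(
      participant_id = pid, primer_set = ps, allele = .data$v_call,
      umi_count = .data$umi_count,
      umi_frequency = if (total_umis > 0) .data$umi_count / total_umis else NA_real_,
      hcdr3_count = .data$hcdr3_count,
      hcdr3_frequency = if (total_hc > 0) .data$hcdr3_count / total_hc else NA_real_
    )
  class(out) <- c("allele_usage", class(out))
  out
}

#' Combine leader and 5'UTR primer-set libraries
#'
#' The relative usage of an allele for a participant is the arithmetic mean
#' of its frequencies in the two independently prepared libraries; counts
#' are summed for reference.
#'
#' @param usage_leader,usage_5utr `allele_usage` tibbles for the two primer
#'   sets of the same participant(s). Alternatively pass a single bound
#'   tibble covering both primer sets as `usage_leader`.
#' @return An `allele_usage` tibble with `primer_set = "combined"`,
#'   per-allele mean frequencies and summed counts.
#' @export
combine_primer_sets <- function(usage_leader, usage_5utr = NULL) {
  both <- dplyr::bind_rows(usage_leader, usage_5utr)
  n_sets <- dplyr::n_distinct(both$primer_set)
  if (n_sets != 2L) {
    abort("expected usage rows from exactly two primer sets.")
  }
  out <- both |>
    dplyr::group_by(.data$participant_id, .data$allele) |>
    dplyr::summarise(
      umi_count = sum(.data$umi_count),
      # an allele absent from one library has frequency 0 there
      umi_frequency = sum(.data$umi_frequency) / 2,
      hcdr3_count = sum(.data$hcdr3_count),
      hcdr3_frequency = sum(.data$hcdr3_frequency) / 2,
      .groups = "drop"
    ) |>
    dplyr::mutate(primer_set = "combined", .after = "participant_id")
  class(out) <- c("allele_usage", class(out))
  out
}

#' Fold the silent *02_S4953 variant into *02
#'
#' `*02_S4953` encodes the same amino-acid sequence as `*02`; reported
#' usage for `*02` is the sum of the two alleles' frequencies (and counts).
#'
#' @param usages An `allele_usage` tibble.
#' @return The same tibble with `*02_S4953` rows merged into `*02`.
#' @examples
#' u <- tibble::tibble(participant_id = "P1", primer_set = "combined",
#'                     allele = c("*02", "*02_S4953"),
#'                     umi_count = c(20L, 10L), umi_frequency = c(0.02, 0.01),
#'                     hcdr3_count = c(5L, 2L), hcdr3_frequency = c(0.01, 0.004))
#' collapse_s4953(u)
#' @export
collapse_s4953 <- function(usages) {
  u <- tibble::as_tibble(usages)
  if (!any(u$allele == "*02_S4953")) return(usages)
  out <- u |>
    dplyr::mutate(allele = ifelse(.data$allele == "*02_S4953", "*02",
                                  .data$allele)) |>
    dplyr::group_by(.data$participant_id, .data$primer_set, .data$allele) |>
    dplyr::summarise(dplyr::across(c("umi_count", "umi_frequency",
                                    "hcdr3_count", "hcdr3_frequency"), sum),
                     .groups = "drop")
  class(out) <- c("allele_usage", class(out))
  out
}

#' HCDR3-to-mRNA ratio diagnostics
#'
#' Per participant and allele, the ratio of unique-HCDR3 count to UMI count
#' (a measure of 1 / BCR cell-surface density) and the ratio of HCDR3
#' frequency to mRNA frequency, with per-allele medians and interquartile
#' ranges.
#'
#' @param usages An `allele_usage` tibble (typically combined + collapsed).
#' @param alleles Alleles to include; defaults to IGHV1-2 alleles (the
#'   background class is dropped).
#' @return A list with `ratios` (per participant x allele tibble with
#'   `count_ratio` and `frequency_ratio`) and `summary` (per-allele median
#'   and IQR of both ratios). Zero-denominator rows are excluded with a
#'   warning.
#' @export
ratio_diagnostics <- function(usages, alleles = c("*02", "*04", "*05", "*06")) {
  u <- tibble::as_tibble(usages) |>
    dplyr::filter(.data$allele %in% alleles)
  n_zero <- sum(u$umi_count == 0)
  if (n_zero > 0) {
    warn(sprintf("%d zero-mRNA row(s) excluded from ratio diagnostics", n_zero))
    u <- dplyr::filter(u, .data$umi_count > 0)
  }
  ratios <- u |>
    dplyr::mutate(
      count_ratio = .data$hcdr3_count / .data$umi_count,
      frequency_ratio = .data$hcdr3_frequency / .data$umi_frequency
    ) |>
    dplyr::select("participant_id", "allele", "count_ratio", "frequency_ratio")
  summary <- ratios |>
    dplyr::group_by(.data$allele) |>
    dplyr::summarise(
      n = dplyr::n(),
      count_ratio_median = median(.data$count_ratio),
      count_ratio_q25 = quantile(.data$count_ratio, 0.25, names = FALSE),
      count_ratio_q75 = quantile(.data$count_ratio, 0.75, names = FALSE),
      frequency_ratio_median = median(.data$frequency_ratio),
      frequency_ratio_q25 = quantile(.data$frequency_ratio, 0.25, names = FALSE),
      frequency_ratio_q75 = quantile(.data$frequency_ratio, 0.75, names = FALSE),
      .groups = "drop"
    )
  list(ratios = ratios, summary = summary)
}

#' Per-allele mean usage stratified by zygosity
#'
#' For each allele, splits participants into homozygotes and heterozygotes,
#' reports group mean usage frequencies with 95% t-distribution confidence
#' intervals, and tests the homozygote-minus-heterozygote difference with a
#' two-sided Welch t-test of zero difference.
#'
#' @param usages An `allele_usage` tibble with one row per participant x
#'   allele (combined primer sets, S4953 collapsed).
#' @param participants Participant tibble from [simulate_genotypes()] (or
#'   any table with `participant_id`, `allele_1`, `allele_2`).
#' @param value Which frequency to analyse: `"umi_frequency"` (default) or
#'   `"hcdr3_frequency"`.
#' @param per_allele If `TRUE`, divide each participant's usage by their
#'   zygosity for that allele before summarising, so homozygotes are
#'   reported per allele copy (under proportional usage the homozygous and
#'   heterozygous per-allele means then coincide). The default `FALSE`
#'   reports total usage, under which homozygotes run at about twice the
#'   heterozygote level.
#' @return A tibble with one row per allele x zygosity group: `n`, `mean`,
#'   `ci_lower`, `ci_upper`, plus the difference estimate and p-value
#'   (`diff_estimate`, `diff_p`) repeated across the allele's rows (NA when
#'   a group is missing or degenerate).
#' @export
zygosity_stratified_means <- function(usages, participants,
                                      value = c("umi_frequency",
                                                "hcdr3_frequency"),
                                      per_allele = FALSE) {
  value <- match.arg(value)
  u <- tibble::as_tibble(usages)
  pt <- tibble::as_tibble(participants) |>
    dplyr::mutate(
      allele_1 = ifelse(.data$allele_1 == "*02_S4953", "*02", .data$allele_1),
      allele_2 = ifelse(.data$allele_2 == "*02_S4953", "*02", .data$allele_2)
    )
  long <- pt |>
    tidyr::pivot_longer(c("allele_1", "allele_2"), values_to = "allele") |>
    dplyr::count(.data$participant_id, .data$allele, name = "zygosity")
  dat <- dplyr::inner_join(u, long, by = c("participant_id", "allele")) |>
    dplyr::mutate(
      group = ifelse(.data$zygosity == 2L, "homozygous", "heterozygous"),
      y = if (per_allele) .data[[value]] / .data$zygosity else .data[[value]]
    )
  dat |>
    dplyr::group_by(.data$allele) |>
    dplyr::group_modify(function(d, key) {
      per_group <- d |>
        dplyr::group_by(.data$group) |>
        dplyr::summarise(n = dplyr::n(), mean = mean(.data$y),
                         sd = sd(.data$y), .groups = "drop") |>
        dplyr::mutate(
          se = .data$sd / sqrt(.data$n),
          ci_lower = .data$mean - qt(0.975, pmax(.data$n - 1, 1)) * .data$se,
          ci_upper = .data$mean + qt(0.975, pmax(.data$n - 1, 1)) * .data$se
        )
      homo <- d$y[d$group == "homozygous"]
      het <- d$y[d$group == "heterozygous"]
      if (length(homo) >= 2 && length(het) >= 2 &&
          (sd(homo) > 0 || sd(het) > 0)) {
        tt <- stats::t.test(homo, het)
        per_group$diff_estimate <- mean(homo) - mean(het)
        per_group$diff_p <- tt$p.value
      } else {
        per_group$diff_estimate <- if (length(homo) && length(het))
          mean(homo) - mean(het) else NA_real_
        per_group$diff_p <- NA_real_
      }
      per_group
    }) |>
    dplyr::ungroup()
}

#' Quantify a whole trial's repertoires
#'
#' Runs the full per-library quantification (UMI and HCDR3 counting, usage
#' frequencies), combines the two primer sets per participant, and folds
#' `*02_S4953` into `*02`.
#'
#' @param repertoire Bound rearrangement tibble over participants and
#'   primer sets (e.g. `simulate_trial(...)$repertoire`).
#' @return An `allele_usage` tibble, one row per participant x allele, with
#'   `primer_set = "combined"`.
#' @export
quantify_repertoires <- function(repertoire) {
  rep <- tibble::as_tibble(repertoire)
  per_lib <- rep |>
    dplyr::group_by(.data$participant_id, .data$primer_set) |>
    dplyr::group_map(function(d, key) {
      allele_usage(d, participant_id = key$participant_id,
                   primer_set = key$primer_set)
    }) |>
    dplyr::bind_rows()
  combined <- combine_primer_sets(per_lib)
  collapse_s4953(combined)
}
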