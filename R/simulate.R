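# Synthetic-trial generators.
#
# These functions generate complete synthetic vaccine trials with the
# statistical structure the downstream analysis assumes: Hardy-Weinberg
# genotypes over the IGHV1-2 allele pool, UMI-tagged IgM repertoires with
# per-allele usage proportional to zygosity, over-dispersed VRC01-class
# response counts with additive per-allele means, and BCR reads copied from
# per-allele germline templates that differ at a single diagnostic
# nucleotide (the *02/*04 distinction).

# Fixed synthetic V-region scaffold (297 nt).  This is NOT a real IGHV1-2
# sequence; it is a synthetic stand-in with the allele-distinguishing
# structure of the real gene: *02 and *04 differ at exactly one position
# (the codon-66 SNP), *02_S4953 is a silent variant of *02, and *05/*06
# carry the codon-50 change plus extra private differences.
.ighv12_scaffold <- paste0(
  "AAAACTCCATGTGTAACTCCGGAAGTAGAATCTTGCACTCGGCCTTTCCATATCTCGTGAACCCCCTGC",
  "ACGCCCTAAAGTACAATTAGGATATTCATCCCTACACTGTATATGCCGAACGTTCTAATAAACGACTTA",
  "GCAACAAGTCGCCTAGAAAGGTACCGCTGGCATATCACGCCTCCCGCTTGCCGTCTTCAACTTCATGAC",
  "CCTCGTGCATCACAAAGCCTCAAGCCGGAGTCTAGGCTTTGAAACAGCTGAATAAATCGTGTGAATACG",
  "TGAGTCGTCGGAAAGCAGTTG"
)

.subst <- function(seq, pos, base) {
  for (i in seq_along(pos)) substr(seq, pos[i], pos[i]) <- base[i]
  seq
}

#' Synthetic germline templates for the IGHV1-2 alleles
#'
#' Returns one synthetic germline V-region sequence per allele. The
#' templates encode the allele structure the assignment step relies on:
#' `*02` and `*04` are identical except at the single diagnostic position
#' (`diagnostic_pos`, the analogue of the codon-66 A/T SNP), `*02_S4953`
#' differs from `*02` only by one silent substitution, and `*05`/`*06`
#' additionally carry the codon-50 change that abolishes precursor binding
#' plus private differences.
#'
#' @return A list with `sequences` (named character vector, one 297-nt
#'   sequence per allele) and `diagnostic_pos` (integer position at which
#'   `*02` and `*04` differ).
#' @examples
#' tpl <- ighv12_synthetic_germlines()
#' substr(tpl$sequences["*02"], tpl$diagnostic_pos, tpl$diagnostic_pos)
#' @export
ighv12_synthetic_germlines <- function() {
  diag_pos <- 196L
  a04 <- .subst(.ighv12_scaffold, diag_pos, "A")  # *04 state at the SNP
  a02 <- .subst(.ighv12_scaffold, diag_pos, "T")  # *02 state
  base <- a04
  a02s <- .subst(a02, 30L, "G")       # silent variant of *02
  a05 <- .subst(base, c(148L, 250L), c("C", "G"))  # codon-50 change + private
  a06 <- .subst(base, c(148L, 60L, 270L), c("C", "T", "C"))
  seqs <- c("*02" = a02, "*02_S4953" = a02s, "*04" = a04,
            "*05" = a05, "*06" = a06)
  list(sequences = seqs, diagnostic_pos = diag_pos)
}

#' Simulate participant genotypes and dose-group assignment
#'
#' Draws each participant's two IGHV1-2 alleles independently from the
#' configured allele frequencies (Hardy-Weinberg sampling) and assigns dose
#' groups in blocks so that group sizes are exactly those configured.
#' Zygosity counts `n02` (copies of `*02` or `*02_S4953`) and `n04` (copies
#' of `*04`) are derived per participant.
#'
#' @param config A [trial_config()].
#' @param genotype_table Optional data frame with columns `dose_group`,
#'   `allele_1`, `allele_2` giving a fixed genotype table to use verbatim
#'   (one row per participant) instead of Hardy-Weinberg sampling; use this
#'   to replicate an observed genotype-by-dose imbalance exactly.
#' @return A tibble with one row per participant: `participant_id`,
#'   `dose_group` (factor low/high/placebo), `allele_1`, `allele_2`, `n02`,
#'   `n04`.
#' @examples
#' cfg <- trial_config(n_per_group = 4, seed = 7)
#' set.seed(cfg$seed)
#' simulate_genotypes(cfg)
#' @export
simulate_genotypes <- function(config, genotype_table = NULL) {
  stopifnot(inherits(config, "trial_config"))
  if (!is.null(genotype_table)) {
    gt <- tibble::as_tibble(genotype_table)
    stopifnot(all(c("dose_group", "allele_1", "allele_2") %in% names(gt)))
    bad <- setdiff(c(gt$allele_1, gt$allele_2), ighv12_alleles())
    if (length(bad)) abort(paste("unknown allele label(s):",
                                 paste(unique(bad), collapse = ", ")))
    z <- zygosity_counts(gt$allele_1, gt$allele_2)
    return(tibble::tibble(
      participant_id = sprintf("P%03d", seq_len(nrow(gt))),
      dose_group = factor(gt$dose_group, levels = c("low", "high", "placebo")),
      allele_1 = gt$allele_1, allele_2 = gt$allele_2,
      n02 = z$n02, n04 = z$n04
    ))
  }
  n <- sum(config$n_per_group)
  pool <- names(config$allele_freqs)
  a1 <- sample(pool, n, replace = TRUE, prob = config$allele_freqs)
  a2 <- sample(pool, n, replace = TRUE, prob = config$allele_freqs)
  z <- zygosity_counts(a1, a2)
  tibble::tibble(
    participant_id = sprintf("P%03d", seq_len(n)),
    dose_group = factor(rep(c("low", "high", "placebo"), config$n_per_group),
                        levels = c("low", "high", "placebo")),
    allele_1 = a1, allele_2 = a2, n02 = z$n02, n04 = z$n04
  )
}

# distinct HCDR3 amino-acid strings; id space is large enough that labels
# never collide within a library
.make_hcdr3 <- function(idx) sprintf("CARH%05dW", idx)

#' Simulate one UMI-tagged IgM repertoire library
#'
#' Generates an AIRR-style rearrangement table for one participant and one
#' primer set. The UMI count for each carried IGHV1-2 allele is drawn as
#' `Binomial(n_total_umis, zygosity * expr_rate)`, remaining UMIs are
#' assigned to a pooled background class of other IGHV genes, and the
#' number of distinct HCDR3s per allele is a binomial thinning of its UMI
#' count at `hcdr3_ratio`. All emitted IGHV1-2 records are unmutated
#' (`v_mismatches = 0`), matching the germline-identical filtering the
#' quantification applies.
#'
#' @param participant One row of the tibble from [simulate_genotypes()]
#'   (or any data frame with `participant_id`, `allele_1`, `allele_2`).
#' @param config A [trial_config()].
#' @param primer_set Library label, conventionally `"leader"` or `"5utr"`.
#' @return A tibble with columns `sequence_id`, `participant_id`, `umi`,
#'   `v_call`, `v_mismatches`, `cdr3_aa`, `primer_set`; one row per unique
#'   UMI. Background records carry `v_call = "IGHVother"`.
#' @examples
#' cfg <- trial_config(n_total_umis = 500, seed = 3)
#' set.seed(cfg$seed)
#' p <- simulate_genotypes(cfg)[1, ]
#' rep <- simulate_repertoire(p, cfg, "leader")
#' dplyr::count(rep, v_call)
#' @export
simulate_repertoire <- function(participant, config, primer_set = "leader") {
  stopifnot(inherits(config, "trial_config"))
  p <- as.list(participant[1, ])
  alleles <- c(p$allele_1, p$allele_2)
  zy <- table(factor(alleles, levels = ighv12_alleles()))
  carried <- names(zy)[zy > 0]
  n_tot <- config$n_total_umis

  rate <- as.numeric(zy[carried]) * config$expr_rate_per_allele[carried]
  if (any(rate > 1)) abort("zygosity x expression rate exceeds 1.")
  umi_counts <- rbinom(length(carried), n_tot, rate)
  names(umi_counts) <- carried
  if (sum(umi_counts) > n_tot) {
    # pathological only when rates are extreme; truncate deterministically
    umi_counts <- pmin(umi_counts, n_tot - cumsum(c(0, head(umi_counts, -1))))
    umi_counts <- pmax(umi_counts, 0L)
  }
  n_bg <- n_tot - sum(umi_counts)

  blocks <- purrr::map(carried, function(al) {
    m <- umi_counts[[al]]
    if (m == 0L) return(NULL)
    u <- rbinom(1L, m, config$hcdr3_ratio)
    u <- max(u, 1L)                      # at least one clone if any mRNA
    cdr3_pool <- .make_hcdr3(sample.int(99999L, u))
    cdr3 <- c(cdr3_pool,
              if (m > u) sample(cdr3_pool, m - u, replace = TRUE))
    tibble::tibble(v_call = al, v_mismatches = 0L, cdr3_aa = cdr3)
  })
  bg <- if (n_bg > 0L) {
    tibble::tibble(v_call = "IGHVother", v_mismatches = 0L,
                   cdr3_aa = .make_hcdr3(sample.int(9e6L, n_bg) + 1e5L))
  }
  out <- dplyr::bind_rows(blocks, bg)
  n <- nrow(out)
  out$umi <- sprintf("UMI%07d", sample.int(n, n))   # unique UMI per molecule
  out$sequence_id <- sprintf("%s_%s_%06d", p$participant_id, primer_set,
                             seq_len(n))
  out$participant_id <- p$participant_id
  out$primer_set <- primer_set
  dplyr::select(out, "sequence_id", "participant_id", "umi", "v_call",
                "v_mismatches", "cdr3_aa", "primer_set")
}

# default seven-point sampling design: compartment x week
response_timepoints <- function() {
  tibble::tibble(
    compartment = c("GC", "MBC", "MBC", "PB", "MBC", "GC", "MBC"),
    week = c(3L, 4L, 8L, 9L, 10L, 11L, 16L)
  )
}

#' Simulate VRC01-class response counts for one participant
#'
#' For each timepoint the expected count is
#' `mu = (beta_02 * n02 + beta_04 * n04 + dose_delta * I(high dose)) * N`
#' with `N = n_igg_sampled`. Counts are drawn with mean `mu` and variance
#' `dispersion * mu` (NB1 parameterisation; exact Poisson when
#' `dispersion = 1`); `V` is identically 0 when `mu = 0`. Placebo
#' participants have `mu = 0` by construction.
#'
#' @param participant One row from [simulate_genotypes()].
#' @param config A [trial_config()].
#' @param timepoints Data frame with columns `compartment` and `week`;
#'   defaults to the seven-point GC/MBC/PB design.
#' @return A tibble with one row per timepoint: `participant_id`,
#'   `dose_group`, `compartment`, `week`, `n02`, `n04`, `high_dose`, `V`,
#'   `N`.
#' @examples
#' cfg <- trial_config(seed = 5)
#' set.seed(cfg$seed)
#' p <- simulate_genotypes(cfg)[1, ]
#' simulate_responses(p, cfg)
#' @export
simulate_responses <- function(participant, config,
                               timepoints = response_timepoints()) {
  stopifnot(inherits(config, "trial_config"))
  p <- as.list(participant[1, ])
  N <- config$n_igg_sampled
  high <- as.integer(p$dose_group == "high")
  vaccinee <- p$dose_group %in% c("low", "high")
  mu <- if (vaccinee) {
    (config$beta_02 * p$n02 + config$beta_04 * p$n04 +
       config$dose_delta * high) * N
  } else 0
  if (mu < 0) abort("negative response mean; check dose_delta.")
  k <- nrow(timepoints)
  V <- rnb1(k, mu, config$dispersion)
  tibble::tibble(
    participant_id = p$participant_id,
    dose_group = p$dose_group,
    compartment = timepoints$compartment,
    week = timepoints$week,
    n02 = p$n02, n04 = p$n04, high_dose = high,
    V = V, N = N
  )
}

# NB1 sampler: mean mu, variance phi * mu.  phi = 1 is exact Poisson;
# otherwise negative binomial with size mu/(phi-1), prob 1/phi.
# `mu` may be a vector (recycled against n); zero means give zero counts
# surely.
rnb1 <- function(n, mu, phi) {
  mu <- rep_len(mu, n)
  out <- integer(n)
  pos <- mu > 0
  if (any(pos)) {
    out[pos] <- if (phi <= 1) {
      rpois(sum(pos), mu[pos])
    } else {
      as.integer(rnbinom(sum(pos), size = mu[pos] / (phi - 1), mu = mu[pos]))
    }
  }
  out
}

#' Simulate responses for a whole participant table
#'
#' Vectorised equivalent of applying [simulate_responses()] to every row of
#' `participants` (draw order differs, so individual counts are not
#' replicate-identical to the per-participant path, but the distribution is
#' the same).
#'
#' @param participants Tibble from [simulate_genotypes()].
#' @param config A [trial_config()].
#' @param timepoints As in [simulate_responses()].
#' @return A tibble with one row per participant x timepoint.
#' @export
simulate_response_table <- function(participants, config,
                                    timepoints = response_timepoints()) {
  stopifnot(inherits(config, "trial_config"))
  pt <- tibble::as_tibble(participants)
  N <- config$n_igg_sampled
  high <- as.integer(pt$dose_group == "high")
  vaccinee <- pt$dose_group %in% c("low", "high")
  mu <- ifelse(vaccinee,
               (config$beta_02 * pt$n02 + config$beta_04 * pt$n04 +
                  config$dose_delta * high) * N,
               0)
  if (any(mu < 0)) abort("negative response mean; check dose_delta.")
  out <- tidyr::crossing(
    dplyr::select(pt, "participant_id"),
    timepoints
  ) |>
    dplyr::inner_join(
      tibble::tibble(participant_id = pt$participant_id,
                     dose_group = pt$dose_group, n02 = pt$n02,
                     n04 = pt$n04, high_dose = high, mu = mu),
      by = "participant_id"
    )
  out$V <- rnb1(nrow(out), out$mu, config$dispersion)
  out$N <- N
  dplyr::select(out, "participant_id", "dose_group", "compartment", "week",
                "n02", "n04", "high_dose", "V", "N")
}

#' Simulate BCR reads from a participant's germline templates
#'
#' Copies reads from the germline templates of the participant's carried
#' `*02`-family and `*04` alleles (origin allele proportional to zygosity by
#' default), substituting each base independently with probability
#' `mutation_rate`. The true origin allele is recorded so assignment
#' accuracy can be scored against it.
#'
#' @param participant One row from [simulate_genotypes()]; must carry at
#'   least one `*02`/`*02_S4953`/`*04` allele.
#' @param config A [trial_config()].
#' @param n_reads Number of reads to simulate.
#' @param origin_probs Optional named numeric vector of origin probabilities
#'   per carried allele; defaults to proportional to zygosity.
#' @param templates Germline template set, defaults to
#'   [ighv12_synthetic_germlines()].
#' @return A tibble: `sequence_id`, `participant_id`, `true_allele`,
#'   `sequence`.
#' @examples
#' cfg <- trial_config(seed = 11)
#' gt <- data.frame(dose_group = "low", allele_1 = "*02", allele_2 = "*04")
#' p <- simulate_genotypes(cfg, genotype_table = gt)
#' set.seed(1)
#' simulate_bcr_reads(p, cfg, n_reads = 3)
#' @export
simulate_bcr_reads <- function(participant, config, n_reads,
                               origin_probs = NULL,
                               templates = ighv12_synthetic_germlines()) {
  stopifnot(inherits(config, "trial_config"))
  n_reads <- as.integer(n_reads)
  if (n_reads < 0L) abort("`n_reads` must be non-negative.")
  p <- as.list(participant[1, ])
  alleles <- c(p$allele_1, p$allele_2)
  productive <- alleles[alleles %in% c(alleles_02(), "*04")]
  if (!length(productive)) {
    abort("participant carries neither a *02-family nor a *04 allele.")
  }
  zy <- table(productive)
  carried <- names(zy)
  probs <- if (is.null(origin_probs)) {
    as.numeric(zy) / sum(zy)
  } else {
    as.numeric(origin_probs[carried]) / sum(origin_probs[carried])
  }
  origin <- sample(carried, n_reads, replace = TRUE, prob = probs)
  tpl <- templates$sequences
  L <- nchar(tpl[[1]])
  seqs <- vapply(origin, function(al) mutate_sequence(tpl[[al]],
                                                      config$mutation_rate),
                 character(1))
  tibble::tibble(
    sequence_id = sprintf("%s_read%05d", p$participant_id, seq_len(n_reads)),
    participant_id = p$participant_id,
    true_allele = origin,
    sequence = unname(seqs)
  )
}

# independent per-base substitution to one of the three other bases
mutate_sequence <- function(seq, rate) {
  if (rate <= 0) return(seq)
  bases <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(bases)) < rate)
  if (length(hit)) {
    alt <- c("A", "C", "G", "T")
    for (i in hit) {
      bases[i] <- sample(setdiff(alt, bases[i]), 1L)
    }
  }
  paste(bases, collapse = "")
}

#' Simulate a complete synthetic trial
#'
#' Convenience wrapper that seeds the RNG from `config$seed` (or the `seed`
#' argument) and generates genotypes, both primer-set repertoire libraries
#' per participant, and the seven-timepoint response table.
#'
#' @param config A [trial_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @param repertoires If `FALSE`, skip the (comparatively large) repertoire
#'   tables.
#' @param genotype_table Passed to [simulate_genotypes()].
#' @return A list with elements `participants`, `repertoire` (bound tibble
#'   over participants and primer sets, or `NULL`), and `responses`.
#' @examples
#' trial <- simulate_trial(trial_config(n_per_group = 2, n_total_umis = 200))
#' trial$participants
#' @export
simulate_trial <- function(config, seed = config$seed, repertoires = TRUE,
                           genotype_table = NULL) {
  stopifnot(inherits(config, "trial_config"))
  set.seed(seed)
  participants <- simulate_genotypes(config, genotype_table = genotype_table)
  reps <- NULL
  if (repertoires) {
    reps <- purrr::map_dfr(seq_len(nrow(participants)), function(i) {
      dplyr::bind_rows(
        simulate_repertoire(participants[i, ], config, "leader"),
        simulate_repertoire(participants[i, ], config, "5utr")
      )
    })
  }
  responses <- simulate_response_table(participants, config)
  list(participants = participants, repertoire = reps, responses = responses)
}
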