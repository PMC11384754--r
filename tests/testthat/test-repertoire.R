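test_that("UMI counting deduplicates and keeps only germline-identical records", {
  rec <- tibble::tibble(
    umi = c("u1", "u1", "u2", "u3", "u4", NA),
    v_call = c("*02", "*02", "*02", "*04", "*04", "*04"),
    v_mismatches = c(0L, 0L, 0L, 0L, 2L, 0L),
    cdr3_aa = "CARW"
  )
  expect_warning(counts <- count_umis_per_allele(rec), "without a UMI")
  expect_identical(counts$umi_count[counts$v_call == "*02"], 2L)
  expect_identical(counts$umi_count[counts$v_call == "*04"], 1L)
  expect_identical(counts$total_umis[1], 3L)

  # a missing mismatch annotation is treated as mutated
  rec2 <- tibble::tibble(umi = c("u1", "u2"), v_call = "*02",
                         v_mismatches = c(0L, NA), cdr3_aa = "CARW")
  expect_identical(count_umis_per_allele(rec2)$umi_count, 1L)
})

test_that("HCDR3 counting is per distinct string, not per molecule", {
  rec <- tibble::tibble(
    umi = sprintf("u%d", 1:7),
    v_call = c(rep("*02", 5), "*04", "*04"),
    v_mismatches = 0L,
    cdr3_aa = c(rep("CARAW", 5), "CARBW", "")
  )
  expect_warning(hc <- count_unique_hcdr3(rec), "empty HCDR3")
  expect_identical(hc$hcdr3_count[hc$v_call == "*02"], 1L)
  expect_identical(hc$hcdr3_count[hc$v_call == "*04"], 1L)
  um <- count_umis_per_allele(rec)
  expect_identical(um$umi_count[um$v_call == "*02"], 5L)
})

test_that("usage frequencies, primer-set combination and S4953 collapse", {
  mk <- function(ps, c02, c04, cS = 0L, total = 100L) {
    n_bg <- total - c02 - c04 - cS
    tibble::tibble(
      participant_id = "P1", primer_set = ps,
      umi = sprintf("%s_u%d", ps, seq_len(total)),
      v_call = c(rep("*02", c02), rep("*02_S4953", cS), rep("*04", c04),
                 rep("IGHVother", n_bg)),
      v_mismatches = 0L,
      cdr3_aa = sprintf("%s_c%d", ps, seq_len(total))
    )
  }
  u_lead <- allele_usage(mk("leader", 2L, 4L, 1L))
  u_utr <- allele_usage(mk("5utr", 4L, 8L, 1L))
  expect_equal(u_lead$umi_frequency[u_lead$allele == "*02"], 0.02)
  expect_equal(u_lead$umi_frequency[u_lead$allele == "*04"], 0.04)

  comb <- combine_primer_sets(u_lead, u_utr)
  expect_equal(comb$umi_frequency[comb$allele == "*02"], 0.03)
  expect_equal(comb$umi_frequency[comb$allele == "*04"], 0.06)
  expect_equal(comb$umi_frequency[comb$allele == "*02_S4953"], 0.01)

  # collapse after combine equals combine after collapse
  a <- collapse_s4953(comb)
  b <- combine_primer_sets(collapse_s4953(u_lead), collapse_s4953(u_utr))
  expect_equal(
    dplyr::arrange(tibble::as_tibble(a), allele)$umi_frequency,
    dplyr::arrange(tibble::as_tibble(b), allele)$umi_frequency
  )
  expect_equal(a$umi_frequency[a$allele == "*02"], 0.04)
  expect_false("*02_S4953" %in% a$allele)
  # totals conserved by the collapse
  expect_equal(sum(a$umi_frequency), sum(comb$umi_frequency))
  # combining identical frequencies is the identity
  same <- combine_primer_sets(u_lead, dplyr::mutate(u_lead, primer_set = "5utr"))
  expect_equal(same$umi_frequency[same$allele == "*02"], 0.02)
})

test_that("quantification recovers the generator's bookkeeping exactly", {
  cfg <- trial_config(n_per_group = 2, n_total_umis = 800L, seed = 17)
  tr <- simulate_trial(cfg)
  u <- quantify_repertoires(tr$repertoire)
  # recompute one participant x allele cell with base R only
  rep1 <- tr$repertoire[tr$repertoire$participant_id == "P001", ]
  for (ps in c("leader", "5utr")) {
    lib <- rep1[rep1$primer_set == ps & rep1$v_mismatches == 0, ]
    al <- tr$participants$allele_1[1]
    truth_umis <- length(unique(lib$umi[lib$v_call == al]))
    got <- allele_usage(lib)
    expect_identical(got$umi_count[got$allele == al], truth_umis)
  }
  expect_true(all(u$hcdr3_count <= u$umi_count))
})

test_that("ratio diagnostics reproduce hand values and drop zero denominators", {
  u <- tibble::tibble(
    participant_id = c("P1", "P1", "P2"),
    primer_set = "combined",
    allele = c("*02", "*04", "*02"),
    umi_count = c(100L, 0L, 50L),
    umi_frequency = c(0.02, 0, 0.01),
    hcdr3_count = c(23L, 0L, 10L),
    hcdr3_frequency = c(0.02, 0, 0.01)
  )
  expect_warning(rd <- ratio_diagnostics(u), "zero-mRNA")
  expect_equal(rd$ratios$count_ratio[1], 0.23)
  expect_equal(rd$ratios$frequency_ratio, c(1, 1))
  expect_identical(nrow(rd$ratios), 2L)
})

test_that("thinning-ratio recovery: median HCDR3/mRNA ratio near its target", {
  cfg <- trial_config(n_per_group = c(12L, 12L, 0L), n_total_umis = 4000L,
                      seed = 23)
  tr <- simulate_trial(cfg)
  u <- quantify_repertoires(tr$repertoire)
  rd <- ratio_diagnostics(u)
  med02 <- rd$summary$count_ratio_median[rd$summary$allele == "*02"]
  expect_lt(abs(med02 - cfg$hcdr3_ratio), 0.03)
})

test_that("zygosity-stratified means use the textbook t interval", {
  u <- tibble::tibble(
    participant_id = c("P1", "P2", "P3", "P4", "P5"),
    primer_set = "combined",
    allele = "*02",
    umi_count = 1L, umi_frequency = c(0.060, 0.064, 0.068, 0.031, 0.033),
    hcdr3_count = 1L, hcdr3_frequency = 0.01
  )
  pt <- tibble::tibble(
    participant_id = sprintf("P%d", 1:5),
    allele_1 = "*02",
    allele_2 = c("*02", "*02", "*02", "*04", "*04")
  )
  z <- zygosity_stratified_means(u, pt)
  homo <- z[z$group == "homozygous", ]
  ci <- t_ci_oracle(c(0.060, 0.064, 0.068))
  expect_equal(homo$mean, 0.064)
  expect_equal(c(homo$ci_lower, homo$ci_upper), ci)
  expect_equal(homo$diff_estimate, 0.064 - 0.032)
  # per-allele reporting halves homozygote totals
  zp <- zygosity_stratified_means(u, pt, per_allele = TRUE)
  expect_equal(zp$mean[zp$group == "homozygous"], 0.064 / 2)
  expect_equal(zp$mean[zp$group == "heterozygous"], 0.032)
  # identical values give a zero-width interval and zero difference
  u2 <- dplyr::mutate(u, umi_frequency = 0.05)
  z2 <- zygosity_stratified_means(u2, pt)
  expect_equal(z2$ci_lower, z2$ci_upper)
  expect_equal(unique(z2$diff_estimate), 0)
})

test_that("simulated homozygotes show twice the heterozygote usage", {
  cfg <- trial_config(n_total_umis = 5000L)
  gt <- data.frame(
    dose_group = "low",
    allele_1 = "*02",
    allele_2 = rep(c("*02", "*04"), each = 10)
  )
  set.seed(29)
  pt <- simulate_genotypes(cfg, genotype_table = gt)
  rep <- purrr::map_dfr(seq_len(nrow(pt)), function(i) {
    dplyr::bind_rows(simulate_repertoire(pt[i, ], cfg, "leader"),
                     simulate_repertoire(pt[i, ], cfg, "5utr"))
  })
  z <- zygosity_stratified_means(quantify_repertoires(rep), pt)
  m <- z[z$allele == "*02", ]
  ratio <- m$mean[m$group == "homozygous"] / m$mean[m$group == "heterozygous"]
  expect_lt(abs(ratio - 2), 0.25)
  expect_lt(m$diff_p[1], 0.01)
})
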