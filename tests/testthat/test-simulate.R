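test_that("degenerate allele distribution gives all-homozygous *02 trials", {
  cfg <- trial_config(n_per_group = 4,
                      allele_freqs = c("*02" = 1, "*02_S4953" = 0,
                                       "*04" = 0, "*05" = 0, "*06" = 0))
  set.seed(1)
  pt <- simulate_genotypes(cfg)
  expect_true(all(pt$allele_1 == "*02" & pt$allele_2 == "*02"))
  expect_true(all(pt$n02 == 2L & pt$n04 == 0L))
  expect_identical(as.integer(table(pt$dose_group)), rep(4L, 3L))
})

test_that("genotype sampling matches Hardy-Weinberg expectations", {
  freqs <- c("*02" = 0.4, "*02_S4953" = 0, "*04" = 0.5, "*05" = 0.05,
             "*06" = 0.05)
  cfg <- trial_config(n_per_group = c(10000L, 0L, 0L), allele_freqs = freqs)
  set.seed(42)
  pt <- simulate_genotypes(cfg)
  # unordered genotype classes and their analytic HWE probabilities
  geno <- apply(cbind(pt$allele_1, pt$allele_2), 1,
                function(a) paste(sort(a), collapse = "/"))
  pool <- names(freqs)[freqs > 0]
  classes <- outer(pool, pool, function(a, b) {
    mapply(function(x, y) paste(sort(c(x, y)), collapse = "/"), a, b)
  })
  probs <- outer(freqs[pool], freqs[pool])
  expected <- tapply(as.vector(probs), as.vector(classes), sum)
  observed <- table(factor(geno, levels = names(expected)))
  gof <- suppressWarnings(stats::chisq.test(observed, p = expected))
  expect_gt(gof$p.value, 0.01)
})

test_that("genotype simulation is reproducible and fixed tables pass through", {
  cfg <- trial_config(n_per_group = 6)
  set.seed(7); a <- simulate_genotypes(cfg)
  set.seed(7); b <- simulate_genotypes(cfg)
  expect_identical(a, b)

  gt <- fixed_participants()
  pt <- simulate_genotypes(cfg, genotype_table = gt)
  expect_identical(pt$allele_1, gt$allele_1)
  expect_identical(pt$n02, c(2L, 1L, 0L, 1L, 0L, 0L, 0L, 1L))
  expect_identical(pt$n04, c(0L, 1L, 2L, 0L, 2L, 0L, 1L, 1L))
})

test_that("repertoire UMI counts track zygosity times expression rate", {
  cfg <- trial_config(n_total_umis = 1500L)
  hom <- simulate_genotypes(cfg, genotype_table = data.frame(
    dose_group = "low", allele_1 = "*02", allele_2 = "*02"))
  het <- simulate_genotypes(cfg, genotype_table = data.frame(
    dose_group = "low", allele_1 = "*02", allele_2 = "*04"))
  n_rep <- 400
  set.seed(11)
  freq_hom <- replicate(n_rep, {
    r <- simulate_repertoire(hom, cfg, "leader")
    sum(r$v_call == "*02") / nrow(r)
  })
  freq_het <- replicate(n_rep, {
    r <- simulate_repertoire(het, cfg, "leader")
    sum(r$v_call == "*02") / nrow(r)
  })
  # binomial mean/variance oracle: 3 Monte-Carlo SEs around zygosity * rate
  rate <- cfg$expr_rate_per_allele[["*02"]]
  for (x in list(list(f = freq_hom, m = 2 * rate),
                 list(f = freq_het, m = rate))) {
    mc_se <- sqrt(x$m * (1 - x$m) / cfg$n_total_umis / n_rep)
    expect_lt(abs(mean(x$f) - x$m), 3 * mc_se)
  }
  # homozygote usage is twice heterozygote usage on average
  expect_lt(abs(mean(freq_hom) / mean(freq_het) - 2), 0.15)
})

test_that("zero expression rate produces no records for that allele", {
  rates <- c("*02" = 0.03, "*02_S4953" = 0, "*04" = 0, "*05" = 0.001,
             "*06" = 0.02)
  cfg <- trial_config(expr_rate_per_allele = rates, n_total_umis = 2000L)
  p <- simulate_genotypes(cfg, genotype_table = data.frame(
    dose_group = "low", allele_1 = "*02", allele_2 = "*04"))
  set.seed(3)
  r <- simulate_repertoire(p, cfg, "leader")
  expect_identical(sum(r$v_call == "*04"), 0L)
  expect_gt(sum(r$v_call == "*02"), 0L)
  # every UMI is unique and the library has the configured size
  expect_identical(nrow(r), 2000L)
  expect_identical(dplyr::n_distinct(r$umi), 2000L)
})

test_that("response counts are Poisson at dispersion 1 and NB1 above it", {
  cfg1 <- trial_config(dispersion = 1)
  many <- simulate_genotypes(cfg1, genotype_table = data.frame(
    dose_group = "low", allele_1 = "*02", allele_2 = "*04")[rep(1, 10000), ])
  tp <- tibble::tibble(compartment = "MBC", week = 4L)
  mu <- (cfg1$beta_02 + cfg1$beta_04) * cfg1$n_igg_sampled
  set.seed(5)
  v1 <- simulate_response_table(many, cfg1, tp)$V
  expect_lt(abs(var(v1) / mean(v1) - 1), 0.06)

  cfg3 <- trial_config(dispersion = 3)
  set.seed(6)
  v3 <- simulate_response_table(many, cfg3, tp)$V
  expect_lt(abs(var(v3) / mean(v3) - 3), 0.2)
  expect_lt(abs(mean(v3) - mu) / mu, 0.05)
})

test_that("participants without productive alleles never respond", {
  cfg <- trial_config()
  p <- simulate_genotypes(cfg, genotype_table = data.frame(
    dose_group = "high", allele_1 = "*05", allele_2 = "*06"))
  set.seed(8)
  resp <- simulate_responses(p, cfg)
  expect_true(all(resp$V == 0L))
  # placebo recipients too, whatever the genotype
  pl <- simulate_genotypes(cfg, genotype_table = data.frame(
    dose_group = "placebo", allele_1 = "*02", allele_2 = "*02"))
  expect_true(all(simulate_responses(pl, cfg)$V == 0L))
})

test_that("BCR reads copy templates exactly at mutation rate zero", {
  cfg <- trial_config(mutation_rate = 0)
  p <- simulate_genotypes(cfg, genotype_table = data.frame(
    dose_group = "low", allele_1 = "*02", allele_2 = "*04"))
  tpl <- ighv12_synthetic_germlines()
  set.seed(2)
  reads <- simulate_bcr_reads(p, cfg, 200)
  expect_true(all(reads$sequence == tpl$sequences[reads$true_allele]))
  # heterozygote origins are close to 50/50 (binomial oracle, 3 SEs)
  n02 <- sum(reads$true_allele == "*02")
  expect_lt(abs(n02 / 200 - 0.5), 3 * sqrt(0.25 / 200))
  expect_error(simulate_bcr_reads(
    simulate_genotypes(cfg, genotype_table = data.frame(
      dose_group = "low", allele_1 = "*05", allele_2 = "*06")), cfg, 10),
    "neither")
})

test_that("the *02 and *04 templates differ at exactly the diagnostic site", {
  tpl <- ighv12_synthetic_germlines()
  d <- hamming_oracle(tpl$sequences[["*02"]], tpl$sequences[["*04"]])
  expect_identical(d, 1L)
  expect_identical(
    hamming_oracle(tpl$sequences[["*02"]], tpl$sequences[["*02_S4953"]]), 1L)
  s02 <- substr(tpl$sequences[["*02"]], tpl$diagnostic_pos, tpl$diagnostic_pos)
  s04 <- substr(tpl$sequences[["*04"]], tpl$diagnostic_pos, tpl$diagnostic_pos)
  expect_identical(c(s02, s04), c("T", "A"))
})

test_that("library frequencies sum to one and trials are bit-reproducible", {
  cfg <- trial_config(n_per_group = 2, n_total_umis = 400L, seed = 13)
  t1 <- simulate_trial(cfg)
  t2 <- simulate_trial(cfg)
  expect_identical(t1, t2)
  u <- quantify_repertoires(t1$repertoire)
  sums <- u |>
    dplyr::group_by(participant_id) |>
    dplyr::summarise(s = sum(umi_frequency))
  expect_true(all(abs(sums$s - 1) < 1e-12))
  expect_true(all(u$hcdr3_count <= u$umi_count))
})
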