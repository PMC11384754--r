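test_that("estimated counts round half-up from the frequency product", {
  expect_identical(estimate_v(0.01, 0.1, 10000), 10L)
  expect_identical(estimate_v(0, 0.5, 1000), 0L)
  expect_identical(estimate_v(0.0106, 1.0, 1000), 11L)
  expect_identical(estimate_v(c(0.001, 0.0015), 1, 1000), c(1L, 2L))
})

test_that("design matrices implement the four mean structures", {
  s <- tibble::tibble(
    dose_group = c("low", "high", "low", "placebo"),
    V = c(3, 5, 0, 0), N = 1000, high_dose = c(0, 1, 0, 0),
    n02 = c(1, 2, 0, 1), n04 = c(1, 0, 0, 0)
  )
  d <- build_response_design("Allele", s)
  expect_identical(nrow(d$X), 3L)  # placebo dropped
  expect_equal(unname(d$X[1, ]), c(1000, 1000))
  expect_equal(unname(d$X[3, ]), c(0, 0))
  full <- build_response_design("Full", s)
  expect_identical(colnames(full$X), c("b_02", "b_04", "b_dose_delta"))
  expect_equal(full$X[, 1:2], d$X)
  null <- build_response_design("Null", s)
  expect_equal(unname(null$X[, 1]), rep(1000, 3))
})

test_that("Null and Dose fits equal pooled count ratios in closed form", {
  set.seed(43)
  for (i in 1:10) {
    n <- 20
    s <- tibble::tibble(
      dose_group = sample(c("low", "high"), n, TRUE),
      N = sample(5000:20000, n, TRUE),
      n02 = sample(0:2, n, TRUE), n04 = sample(0:2, n, TRUE)
    )
    s$high_dose <- as.integer(s$dose_group == "high")
    s$V <- rpois(n, 5e-4 * s$N + 1)
    dn <- build_response_design("Null", s)
    fn <- fit_quasipoisson(dn$X, dn$V)
    expect_equal(unname(coef(fn)), sum(s$V) / sum(s$N), tolerance = 1e-12)

    dd <- build_response_design("Dose", s)
    fd <- fit_quasipoisson(dd$X, dd$V)
    lo <- s$dose_group == "low"
    b_low <- sum(s$V[lo]) / sum(s$N[lo])
    b_hi <- sum(s$V[!lo]) / sum(s$N[!lo])
    expect_equal(unname(coef(fd)), c(b_low, b_hi - b_low), tolerance = 1e-10)
  }
})

test_that("the Allele fit solves the quasi-score equations found by grid search", {
  s <- fixed_responses()
  extra <- dplyr::mutate(s,
    participant_id = paste0(participant_id, "b"),
    V = c(75L, 60L, 25L, 42L, 15L, 0L, 12L, 53L))
  s30 <- dplyr::bind_rows(s, extra, s[1:6, ] |>
    dplyr::mutate(participant_id = paste0(participant_id, "c"),
                  V = c(83L, 51L, 19L, 50L, 21L, 0L)))
  d <- build_response_design("Allele", s30)
  expect_identical(nrow(d$X), 22L)
  f <- fit_quasipoisson(d$X, d$V)
  active <- rowSums(d$X) > 0
  oracle <- qp_grid_root(d$X[active, ], d$V[active],
                         lower = c(1e-5, 1e-5), upper = c(3e-3, 2e-3))
  expect_lt(max(abs(coef(f) - oracle)), 1e-6)
  # the score really is (numerically) zero at the IRLS solution
  expect_lt(max(abs(qp_score(coef(f), d$X[active, ], d$V[active]))), 1e-6)
})

test_that("fits agree with the GLM quasi-Poisson identity-link reference", {
  s <- fixed_responses()
  s <- dplyr::filter(s, n02 + n04 > 0)
  d <- build_response_design("Allele", s)
  f <- fit_quasipoisson(d$X, d$V)
  ref <- stats::glm(d$V ~ 0 + d$X,
                    family = stats::quasipoisson(link = "identity"),
                    start = unname(coef(f)))
  expect_equal(unname(coef(f)), unname(coef(ref)), tolerance = 1e-8)
  expect_equal(f$c_hat, summary(ref)$dispersion, tolerance = 1e-6)
  expect_equal(unname(f$vcov), unname(stats::vcov(ref)), tolerance = 1e-6)
})

test_that("structurally zero rows are retained unless infeasible", {
  s <- fixed_responses()  # row 6 is *05/*06 with V = 0
  d <- build_response_design("Allele", s)
  f <- fit_quasipoisson(d$X, d$V)
  expect_identical(f$n, 8L)
  expect_equal(f$fitted[6], 0)
  bad <- s
  bad$V[6] <- 3L
  db <- build_response_design("Allele", bad)
  expect_error(fit_quasipoisson(db$X, db$V), "zero mean")
})

test_that("QAICc evaluates its formula and reduces to AICc at unit dispersion", {
  expect_equal(qaicc(-5, c_hat = 1, K = 2, n = 10), 10 + 4 + 12 / 7)
  set.seed(47)
  for (i in 1:20) {
    ll <- -runif(1, 1, 200)
    K <- sample(2:5, 1)
    n <- sample((K + 2):40, 1)
    expect_equal(qaicc(ll, c_hat = 1, K = K, n = n), aicc_oracle(ll, K, n))
    # doubling the dispersion halves only the -2 lnL / c term
    q1 <- qaicc(ll, c_hat = 1, K = K, n = n)
    q2 <- qaicc(ll, c_hat = 2, K = K, n = n)
    expect_equal(q1 - q2, -2 * ll - (-2 * ll / 2))
  }
  expect_warning(v <- qaicc(-5, c_hat = 1, K = 4, n = 5), "undefined")
  expect_true(is.na(v))
})

test_that("model ranking sorts by QAICc with a fewer-parameters tie-break", {
  mk <- function(ll, K, ch) {
    structure(list(loglik = ll, K = K, n = 30L, c_hat = ch,
                   coefficients = numeric(K - 1)), class = "qp_fit")
  }
  fits <- list(Null = mk(-40, 2, 1.5), Dose = mk(-35, 3, 1.5),
               Allele = mk(-30, 3, 1.5), Full = mk(-30, 4, 1.5))
  r <- rank_models(fits, c_hat_policy = "per-model")
  expect_identical(r$model[1], "Allele")
  expect_identical(r$model[4], "Null")
  # exact QAICc tie with different K: fewer parameters ranks first
  qof <- function(ll, K, n = 30) -2 * ll + 2 * K + 2 * K * (K + 1) / (n - K - 1)
  ll_B <- -30
  ll_A <- -(qof(ll_B, 2) - 2 * 3 - 2 * 3 * 4 / (30 - 3 - 1)) / 2
  tied <- list(A = mk(ll_A, 3, 1), B = mk(ll_B, 2, 1))
  r2 <- rank_models(tied, c_hat_policy = "per-model")
  expect_equal(r2$QAICc[1], r2$QAICc[2])
  expect_identical(r2$model[1], "B")
  # shared dispersion comes from the most general candidate
  r3 <- rank_models(fits, c_hat_policy = "full")
  expect_true(all(r3$c_hat_used == fits$Full$c_hat))
})

test_that("nested mean structures cannot fit worse than their restrictions", {
  # Poisson deviance at the fitted means; Allele is nested in Full and
  # Null in Dose
  dev <- function(f) {
    mu <- pmax(f$fitted, 1e-12)
    2 * sum(ifelse(f$V > 0, f$V * log(f$V / mu), 0) - (f$V - mu))
  }
  set.seed(53)
  cfg <- trial_config(n_per_group = c(18L, 18L, 0L))
  pt <- simulate_genotypes(cfg)
  s <- simulate_response_table(pt, cfg,
                               tibble::tibble(compartment = "MBC", week = 4L))
  fits <- fit_response_models(s)
  expect_lte(dev(fits$Full), dev(fits$Allele) + 1e-8)
  expect_lte(dev(fits$Dose), dev(fits$Null) + 1e-8)
})

test_that("genotype means are linear combinations with quadratic-form variance", {
  s <- fixed_responses()
  f <- fit_response_models(s)$Allele
  gm <- genotype_mean(f, 1, 1)
  expect_equal(gm$estimate, sum(coef(f)))
  v <- f$vcov
  expect_equal(gm$se^2,
               v["b_02", "b_02"] + v["b_04", "b_04"] + 2 * v["b_02", "b_04"])
  hm <- genotype_mean(f, 2, 0)
  expect_equal(hm$estimate, 2 * coef(f)[["b_02"]])
  expect_equal(hm$se^2, 4 * v["b_02", "b_02"])
})

test_that("the allele difference is the (1, -1) contrast of the genotype machinery", {
  s <- fixed_responses()
  f <- fit_response_models(s)$Allele
  diff <- allele_difference(f)
  # internal consistency: same contrast through the genotype-mean path
  by_hand <- genotype_mean(f, 1, 0)$estimate - genotype_mean(f, 0, 1)$estimate
  expect_equal(diff$estimate, by_hand)
  expect_equal(diff$estimate, coef(f)[["b_02"]] - coef(f)[["b_04"]])
  v <- f$vcov
  expect_equal(diff$se^2,
               v["b_02", "b_02"] + v["b_04", "b_04"] - 2 * v["b_02", "b_04"])
})

test_that("delta-method ratio handles degenerate covariance and truncation", {
  mk_fit <- function(b, vc) {
    structure(list(coefficients = c(b_02 = b[1], b_04 = b[2]),
                   vcov = matrix(vc, 2, 2,
                                 dimnames = list(c("b_02", "b_04"),
                                                 c("b_02", "b_04")))),
              class = "qp_fit")
  }
  exact <- allele_ratio(mk_fit(c(2, 1), rep(0, 4)))
  expect_equal(exact$estimate, 2)
  expect_equal(c(exact$conf.low, exact$conf.high), c(2, 2))
  # huge uncertainty drives the raw lower bound negative -> truncated to 0
  wide <- allele_ratio(mk_fit(c(2, 1), c(4, 0, 0, 0.25)))
  expect_equal(wide$conf.low, 0)
  expect_true(wide$truncated)
  expect_error(allele_ratio(mk_fit(c(2, -0.1), rep(0, 4))), "not positive")
})

test_that("timepoint-wise wrapper ranks every stratum", {
  cfg <- trial_config(n_per_group = c(12L, 12L, 4L), seed = 59)
  tr <- simulate_trial(cfg, repertoires = FALSE)
  out <- model_all_timepoints(tr$responses)
  expect_identical(nrow(out$ranking), 28L)  # 7 timepoints x 4 models
  expect_true(all(out$ranking$delta_QAICc >= 0))
  expect_length(out$fits, 7L)
})
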