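# Shared fixtures and small independent oracles used across test files.

# deterministic participant table covering every genotype class of interest
fixed_participants <- function() {
  tibble::tibble(
    dose_group = c("low", "low", "low", "high", "high", "high", "low",
                   "high"),
    allele_1 = c("*02", "*02", "*04", "*02", "*04", "*05", "*04", "*02"),
    allele_2 = c("*02", "*04", "*04", "*06", "*04", "*06", "*06", "*04")
  )
}

# small deterministic response table with a feasible Allele structure
fixed_responses <- function() {
  tibble::tibble(
    participant_id = sprintf("P%02d", 1:8),
    dose_group = c("low", "low", "low", "high", "high", "high", "low",
                   "high"),
    compartment = "MBC", week = 4L,
    n02 = c(2L, 1L, 0L, 1L, 0L, 0L, 0L, 1L),
    n04 = c(0L, 1L, 2L, 0L, 2L, 0L, 1L, 1L),
    high_dose = c(0L, 0L, 0L, 1L, 1L, 1L, 0L, 1L),
    V = c(80L, 55L, 22L, 47L, 18L, 0L, 9L, 49L),
    N = 50000L
  )
}

# identity-link quasi-Poisson score at beta: sum_i x_i (V_i - mu_i) / mu_i
qp_score <- function(beta, X, V) {
  mu <- drop(X %*% beta)
  drop(crossprod(X, (V - mu) / mu))
}

# independent root of the quasi-score by dense grid + numeric refinement
# (never calls the package's IRLS)
qp_grid_root <- function(X, V, lower, upper, n_grid = 60) {
  p <- ncol(X)
  stopifnot(p == 2)
  g1 <- seq(lower[1], upper[1], length.out = n_grid)
  g2 <- seq(lower[2], upper[2], length.out = n_grid)
  ssq <- function(b) {
    mu <- drop(X %*% b)
    # finite penalty outside the feasible region so gradient-based
    # refinement never sees Inf
    if (any(mu <= 0)) return(1e12 * (1 + sum(pmax(-mu, 0))))
    sum(qp_score(b, X, V)^2)
  }
  best <- c(NA, NA)
  best_val <- Inf
  for (a in g1) for (b in g2) {
    v <- ssq(c(a, b))
    if (v < best_val) {
      best_val <- v
      best <- c(a, b)
    }
  }
  # refine: Nelder-Mead then BFGS on the squared score norm
  o1 <- stats::optim(best, ssq, method = "Nelder-Mead",
                     control = list(reltol = 1e-15, maxit = 5000))
  o2 <- stats::optim(o1$par, ssq, method = "BFGS",
                     control = list(reltol = 1e-15, maxit = 1000,
                                    ndeps = rep(1e-9, p)))
  o2$par
}

# independently coded small-sample AIC (for the QAICc <-> AICc check)
aicc_oracle <- function(loglik, K, n) {
  -2 * loglik + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

# textbook one-sample t interval for a mean
t_ci_oracle <- function(x, conf = 0.95) {
  n <- length(x)
  m <- mean(x)
  se <- stats::sd(x) / sqrt(n)
  tq <- stats::qt(1 - (1 - conf) / 2, n - 1)
  c(m - tq * se, m + tq * se)
}

# brute-force Hamming distance between two equal-length strings
hamming_oracle <- function(a, b) {
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  sum(va != vb)
}

# minimal bcr_calls tibble built by hand (weights only)
manual_calls <- function(n_02, n_04, n_amb) {
  tibble::tibble(
    sequence_id = sprintf("r%d", seq_len(n_02 + n_04 + n_amb)),
    call = c(rep("*02", n_02), rep("*04", n_04), rep("ambiguous", n_amb)),
    `weight_*02` = c(rep(1, n_02), rep(0, n_04), rep(0.5, n_amb)),
    `weight_*04` = c(rep(0, n_02), rep(1, n_04), rep(0.5, n_amb))
  )
}
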