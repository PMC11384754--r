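# Quasi-Poisson models of VRC01-class B cell counts.
#
# Four competing mean structures for the count V of VRC01-class IgG B cells
# among N sampled IgG B cells, all identity-link and intercept-free in the
# usual GLM sense (every column is pre-multiplied by N, so coefficients are
# per-cell response frequencies):
#
#   Null:   E(V) = b_Intercept * N
#   Dose:   E(V) = b_low * N + b_delta * I(high) * N
#   Allele: E(V) = b_02 * n02 * N + b_04 * n04 * N
#   Full:   E(V) = b_02 * n02 * N + b_04 * n04 * N + b_delta * I(high) * N
#
# Var(V) = c_hat * E(V); estimation is by quasi-likelihood (IRLS on the
# quasi-score with weights 1/mu), and models are ranked by QAICc.

qp_model_names <- function() c("Null", "Dose", "Allele", "Full")

#' Estimated VRC01-class count from measured frequencies
#'
#' The count of VRC01-class IgG B cells in a sample is estimated as the
#' product of the frequency of epitope-specific IgG B cells, the frequency
#' of VRC01-class cells among sequenced epitope-specific cells, and the
#' number of IgG B cells sampled, rounded half-up to the nearest integer.
#'
#' @param freq_epitope Fraction of IgG B cells that are epitope-specific.
#' @param freq_vrc01_among_seq Fraction of sequenced epitope-specific cells
#'   that are VRC01-class.
#' @param N Total IgG B cells sampled.
#' @return Integer count(s) `V`.
#' @examples
#' estimate_v(0.01, 0.1, 10000)   # 10
#' estimate_v(0.0106, 1.0, 1000)  # 11 (half-up rounding)
#' @export
estimate_v <- function(freq_epitope, freq_vrc01_among_seq, N) {
  stopifnot(all(freq_epitope >= 0), all(freq_vrc01_among_seq >= 0),
            all(N > 0))
  x <- freq_epitope * freq_vrc01_among_seq * N
  as.integer(floor(x + 0.5))  # round half-up, not banker's rounding
}

#' Build the design matrix for one candidate model
#'
#' Constructs the identity-link, intercept-free design for the requested
#' mean structure. Placebo participants are excluded (their expected
#' vaccine-induced count is structurally zero and they carry no dose or
#' allele information about the response).
#'
#' @param model One of `"Null"`, `"Dose"`, `"Allele"`, `"Full"`.
#' @param samples Data frame of response samples with columns `V`, `N`,
#'   `high_dose` (0/1), `n02`, `n04`, and optionally `dose_group` (rows
#'   with `dose_group == "placebo"` are dropped).
#' @return A list with `X` (design matrix with named columns), `V`
#'   (response vector), and `samples` (the retained rows).
#' @examples
#' s <- tibble::tibble(V = c(3, 0), N = 1000, high_dose = c(0, 1),
#'                     n02 = c(1, 0), n04 = c(1, 2))
#' build_response_design("Allele", s)$X
#' @export
build_response_design <- function(model = qp_model_names(), samples) {
  model <- match.arg(model)
  s <- tibble::as_tibble(samples)
  if ("dose_group" %in% names(s)) {
    s <- dplyr::filter(s, .data$dose_group != "placebo")
  }
  stopifnot(all(c("V", "N") %in% names(s)))
  N <- s$N
  X <- switch(model,
    Null = cbind(b_Intercept = N),
    Dose = cbind(b_low = N, b_dose_delta = s$high_dose * N),
    Allele = cbind(b_02 = s$n02 * N, b_04 = s$n04 * N),
    Full = cbind(b_02 = s$n02 * N, b_04 = s$n04 * N,
                 b_dose_delta = s$high_dose * N)
  )
  list(X = X, V = as.numeric(s$V), samples = s)
}

#' Fit an identity-link quasi-Poisson model
#'
#' Solves the quasi-score equations `sum_i x_i (V_i - mu_i) / mu_i = 0`
#' (identity link, variance `c_hat * mu`) by iteratively reweighted least
#' squares with step-halving to keep every fitted mean of a structurally
#' non-zero row positive. Rows whose design row is all zero have `mu = 0`
#' by construction; they must have `V = 0` (else the model is infeasible)
#' and contribute zero to the likelihood.
#'
#' The dispersion is the Pearson statistic over positive-mean rows divided
#' by (number of such rows minus the number of mean parameters); the
#' coefficient covariance is `c_hat * (X' W X)^-1` with `W = diag(1/mu)` at
#' convergence.
#'
#' @param X Design matrix with named columns (see
#'   [build_response_design()]).
#' @param V Non-negative response counts, one per row of `X`.
#' @param max_iter,tol IRLS controls.
#' @return An object of class `qp_fit`: coefficients, `vcov`, `c_hat`,
#'   Poisson `loglik` at the fitted means, `K` (mean parameters + 1 for the
#'   dispersion), `n`, `fitted`, `converged`, `model` (column names).
#' @examples
#' d <- build_response_design("Null",
#'   tibble::tibble(V = c(2, 5), N = c(100, 200), high_dose = 0,
#'                  n02 = 1, n04 = 1))
#' coef(fit_quasipoisson(d$X, d$V))  # 7/300
#' @export
fit_quasipoisson <- function(X, V, max_iter = 200L, tol = 1e-12) {
  X <- as.matrix(X)
  V <- as.numeric(V)
  stopifnot(nrow(X) == length(V), all(V >= 0))
  p <- ncol(X)
  active <- rowSums(abs(X)) > 0
  if (!any(active)) abort("design matrix has no nonzero rows.")
  infeasible <- !active & V > 0
  if (any(infeasible)) {
    abort(paste("row(s) with structurally zero mean but positive count:",
                paste(head(which(infeasible), 5), collapse = ", ")))
  }
  Xa <- X[active, , drop = FALSE]
  Va <- V[active]
  keep <- colSums(abs(Xa)) > 0
  if (!all(keep)) {
    abort(paste("design column(s) identically zero:",
                paste(colnames(X)[!keep], collapse = ", ")))
  }

  mu_floor <- 1e-8
  # feasible start: equal split of the pooled rate across columns
  beta <- rep(sum(Va) / sum(Xa), p)
  mu <- pmax(drop(Xa %*% beta), mu_floor)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    w <- 1 / pmax(mu, mu_floor)
    XtWX <- crossprod(Xa, Xa * w)
    score <- drop(crossprod(Xa, (Va - mu) * w))
    step <- tryCatch(solve(XtWX, score), error = function(e) NULL)
    if (is.null(step)) {
      step <- drop(MASS_ginv(XtWX) %*% score)
    }
    # step-halve until all active fitted means are positive
    lambda <- 1
    repeat {
      beta_new <- beta + lambda * step
      mu_new <- drop(Xa %*% beta_new)
      if (all(mu_new > 0) || lambda < 1e-10) break
      lambda <- lambda / 2
    }
    if (any(mu_new <= 0)) {
      mu_new <- pmax(mu_new, mu_floor)
    }
    delta <- max(abs(beta_new - beta)) / max(1, max(abs(beta_new)))
    beta <- beta_new
    mu <- mu_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }

  w <- 1 / pmax(mu, mu_floor)
  XtWX <- crossprod(Xa, Xa * w)
  pearson <- sum((Va - mu)^2 / pmax(mu, mu_floor))
  n_pos <- sum(mu > mu_floor / 2)
  c_hat <- pearson / max(n_pos - p, 1)
  vcov <- c_hat * solve(XtWX)
  dimnames(vcov) <- list(colnames(X), colnames(X))
  names(beta) <- colnames(X)

  # Poisson log-likelihood at the fitted means over all rows; zero-mean,
  # zero-count rows contribute 0
  mu_all <- numeric(length(V))
  mu_all[active] <- mu
  ll_rows <- ifelse(mu_all > 0, dpois(V, pmax(mu_all, mu_floor), log = TRUE), 0)
  loglik <- sum(ll_rows)

  structure(
    list(coefficients = beta, vcov = vcov, c_hat = c_hat, loglik = loglik,
         K = p + 1L, n = length(V), fitted = mu_all, V = V,
         pearson = pearson, converged = converged, model = colnames(X)),
    class = "qp_fit"
  )
}

# minimal Moore-Penrose fallback (SVD) for near-singular IRLS steps
MASS_ginv <- function(A, tol = 1e-12) {
  s <- svd(A)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' @export
coef.qp_fit <- function(object, ...) object$coefficients

#' @export
vcov.qp_fit <- function(object, ...) object$vcov

#' @export
print.qp_fit <- function(x, ...) {
  cat("<qp_fit> identity-link quasi-Poisson,", x$n, "samples\n")
  print(round(x$coefficients, 8))
  cat(sprintf("  c_hat = %.4g, logLik = %.4g, converged = %s\n",
              x$c_hat, x$loglik, x$converged))
  invisible(x)
}

#' @export
#' @method tidy qp_fit
tidy.qp_fit <- function(x, conf.level = 0.95, ...) {
  se <- sqrt(diag(x$vcov))
  z <- qnorm(1 - (1 - conf.level) / 2)
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(se),
    statistic = unname(x$coefficients / se),
    p.value = 2 * pnorm(-abs(unname(x$coefficients / se))),
    conf.low = unname(x$coefficients - z * se),
    conf.high = unname(x$coefficients + z * se)
  )
}

#' @export
#' @method glance qp_fit
glance.qp_fit <- function(x, ...) {
  tibble::tibble(
    nobs = x$n, df = length(x$coefficients), c.hat = x$c_hat,
    logLik = x$loglik, QAICc = qaicc(x), converged = x$converged
  )
}

#' Quasi-likelihood second-order information criterion
#'
#' `QAICc = -2 logLik / c_hat + 2 K + 2 K (K + 1) / (n - K - 1)` where `K`
#' counts the mean parameters plus one for the estimated dispersion and
#' `logLik` is the Poisson log-likelihood at the fitted means.
#'
#' @param fit A `qp_fit`, or a numeric Poisson log-likelihood.
#' @param c_hat Dispersion to use; defaults to the fit's own estimate. For
#'   model ranking a dispersion shared across candidates (from the most
#'   general model) is conventional; see [rank_models()].
#' @param K,n Parameter count (including dispersion) and sample count;
#'   taken from the fit when omitted.
#' @return The QAICc value (`NA` with a warning when `n <= K + 1`).
#' @examples
#' qaicc(-5, c_hat = 1, K = 2, n = 10)  # 15.714286
#' @export
qaicc <- function(fit, c_hat = NULL, K = NULL, n = NULL) {
  if (inherits(fit, "qp_fit")) {
    ll <- fit$loglik
    c_hat <- c_hat %||% fit$c_hat
    K <- K %||% fit$K
    n <- n %||% fit$n
  } else {
    ll <- as.numeric(fit)
    if (is.null(c_hat) || is.null(K) || is.null(n)) {
      abort("supply `c_hat`, `K` and `n` when `fit` is a log-likelihood.")
    }
  }
  if (n <= K + 1) {
    warn("QAICc undefined: n <= K + 1")
    return(NA_real_)
  }
  -2 * ll / c_hat + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' Fit all four candidate models at one timepoint
#'
#' @param samples Response samples for a single timepoint (see
#'   [build_response_design()]).
#' @param models Candidate model names.
#' @return A named list of `qp_fit` objects.
#' @export
fit_response_models <- function(samples, models = qp_model_names()) {
  fits <- lapply(models, function(m) {
    d <- build_response_design(m, samples)
    fit_quasipoisson(d$X, d$V)
  })
  names(fits) <- models
  fits
}

#' Rank candidate models by QAICc
#'
#' Computes QAICc for each fitted candidate using a dispersion policy and
#' returns the models in ascending QAICc order, breaking exact ties in
#' favour of fewer parameters.
#'
#' @param fits Named list of `qp_fit` objects (see
#'   [fit_response_models()]).
#' @param c_hat_policy `"full"` (default): the dispersion of the most
#'   general feasible candidate (`Full` when present, else the fit with
#'   most parameters) is shared by all candidates, the standard QAIC
#'   practice; `"per-model"`: each candidate uses its own dispersion.
#' @return A tibble ordered best to worst: `model`, `K`, `c_hat_used`,
#'   `loglik`, `QAICc`, `delta_QAICc`.
#' @export
rank_models <- function(fits, c_hat_policy = c("full", "per-model")) {
  c_hat_policy <- match.arg(c_hat_policy)
  stopifnot(length(fits) > 0, !is.null(names(fits)))
  shared <- if ("Full" %in% names(fits)) {
    fits[["Full"]]$c_hat
  } else {
    fits[[which.max(vapply(fits, function(f) f$K, numeric(1)))]]$c_hat
  }
  rows <- purrr::imap_dfr(fits, function(f, nm) {
    ch <- if (c_hat_policy == "full") shared else f$c_hat
    tibble::tibble(model = nm, K = f$K, c_hat_used = ch, loglik = f$loglik,
                   QAICc = qaicc(f, c_hat = ch))
  })
  rows <- rows[order(rows$QAICc, rows$K), ]
  rows$delta_QAICc <- rows$QAICc - rows$QAICc[1]
  rows
}

#' Model-estimated mean response for a genotype
#'
#' The estimated VRC01-class response frequency for a genotype is the
#' linear combination `n02 * b_02 + n04 * b_04` (plus the dose-delta term
#' under the Full model), with a normal-theory confidence interval from the
#' quadratic form of the coefficient covariance.
#'
#' @param fit A `qp_fit` with `b_02`/`b_04` coefficients.
#' @param n02,n04 Zygosity counts for the genotype.
#' @param high_dose 0/1 dose indicator; only used when the fit has a
#'   `b_dose_delta` term.
#' @param conf.level Confidence level.
#' @return A one-row tibble: `estimate`, `se`, `conf.low`, `conf.high`.
#' @export
genotype_mean <- function(fit, n02, n04, high_dose = 0, conf.level = 0.95) {
  cvec <- setNames(numeric(length(fit$coefficients)),
                   names(fit$coefficients))
  if (!all(c("b_02", "b_04") %in% names(cvec))) {
    abort("`fit` must contain b_02 and b_04 coefficients (Allele or Full).")
  }
  cvec["b_02"] <- n02
  cvec["b_04"] <- n04
  if ("b_dose_delta" %in% names(cvec)) cvec["b_dose_delta"] <- high_dose
  linear_combination(fit, cvec, conf.level = conf.level)
}

# normal-theory inference for a linear combination c'beta
linear_combination <- function(fit, cvec, conf.level = 0.95, null = 0) {
  est <- sum(cvec * fit$coefficients)
  v <- drop(t(cvec) %*% fit$vcov %*% cvec)
  se <- sqrt(max(v, 0))
  z <- qnorm(1 - (1 - conf.level) / 2)
  p <- if (se > 0) 2 * pnorm(-abs((est - null) / se)) else as.numeric(est == null)
  tibble::tibble(estimate = est, se = se,
                 conf.low = est - z * se, conf.high = est + z * se,
                 p.value = p)
}

#' Delta-method ratio of the *02 and *04 coefficients
#'
#' The relative per-allele contribution `b_02 / b_04` with a delta-method
#' variance using gradient `(1/b_04, -b_02/b_04^2)` and a normal-theory
#' confidence interval whose lower bound is truncated at zero.
#'
#' @param fit A `qp_fit` with `b_02`/`b_04` coefficients.
#' @param conf.level Confidence level.
#' @return A one-row tibble: `estimate`, `se`, `conf.low` (>= 0),
#'   `conf.high`, `truncated` (whether the lower bound was raised to 0).
#' @export
allele_ratio <- function(fit, conf.level = 0.95) {
  b <- fit$coefficients
  if (!all(c("b_02", "b_04") %in% names(b))) {
    abort("`fit` must contain b_02 and b_04 coefficients.")
  }
  if (b[["b_04"]] <= 0) {
    abort("b_04 estimate is not positive; the ratio is undefined.")
  }
  g <- setNames(numeric(length(b)), names(b))
  g["b_02"] <- 1 / b[["b_04"]]
  g["b_04"] <- -b[["b_02"]] / (b[["b_04"]]^2)
  est <- b[["b_02"]] / b[["b_04"]]
  se <- sqrt(drop(t(g) %*% fit$vcov %*% g))
  z <- qnorm(1 - (1 - conf.level) / 2)
  lo_raw <- est - z * se
  tibble::tibble(estimate = est, se = se,
                 conf.low = max(0, lo_raw), conf.high = est + z * se,
                 truncated = lo_raw < 0)
}

#' Difference of the *02 and *04 coefficients
#'
#' The contrast `b_02 - b_04` with a normal-theory confidence interval and
#' a two-sided p-value against zero difference.
#'
#' @inheritParams allele_ratio
#' @return A one-row tibble: `estimate`, `se`, `conf.low`, `conf.high`,
#'   `p.value`.
#' @export
allele_difference <- function(fit, conf.level = 0.95) {
  b <- fit$coefficients
  if (!all(c("b_02", "b_04") %in% names(b))) {
    abort("`fit` must contain b_02 and b_04 coefficients.")
  }
  cvec <- setNames(numeric(length(b)), names(b))
  cvec["b_02"] <- 1
  cvec["b_04"] <- -1
  linear_combination(fit, cvec, conf.level = conf.level)
}

#' Fit and rank the candidate models at every timepoint
#'
#' Convenience wrapper over [fit_response_models()] and [rank_models()]
#' applied per compartment x week stratum.
#'
#' @param responses Response tibble covering multiple timepoints (columns
#'   `compartment`, `week`, plus the design columns).
#' @param c_hat_policy Passed to [rank_models()].
#' @return A list with `fits` (nested list per timepoint) and `ranking`
#'   (bound tibble with `compartment`, `week` columns).
#' @export
model_all_timepoints <- function(responses, c_hat_policy = "full") {
  resp <- tibble::as_tibble(responses)
  keys <- dplyr::distinct(resp, .data$compartment, .data$week) |>
    dplyr::arrange(.data$week)
  fits <- list()
  ranking <- purrr::map_dfr(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    s <- dplyr::filter(resp, .data$compartment == k$compartment,
                       .data$week == k$week)
    f <- fit_response_models(s)
    fits[[paste(k$compartment, k$week, sep = "_wk")]] <<- f
    dplyr::mutate(rank_models(f, c_hat_policy = c_hat_policy),
                  compartment = k$compartment, week = k$week,
                  .before = 1)
  })
  list(fits = fits, ranking = ranking)
}
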