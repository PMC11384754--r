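# Affinity summaries and repeated-measures comparisons.
#
# Affinities (equilibrium dissociation constants K_D) for antibodies from
# the same participant are correlated, so group comparisons use a linear
# mixed model with a participant random intercept:
#
#   y_ij = x_ij' beta + b_i + e_ij,  b_i ~ N(0, sb2),  e_ij ~ N(0, se2)
#
# fitted by REML with the variance ratio lambda = sb2/se2 profiled out
# (the random-intercept structure gives closed-form per-participant blocks),
# and fixed-effect tests using Satterthwaite's degrees-of-freedom
# approximation. Analyses are on the log10(K_D) scale by default: K_D spans
# picomolar to micromolar and fold-changes are the natural effect size.

# ---- random-intercept REML core ------------------------------------------

# per-block sufficient statistics for the closed-form V^-1
.block_stats <- function(y, X, group) {
  idx <- split(seq_along(y), group)
  lapply(idx, function(i) {
    Xi <- X[i, , drop = FALSE]
    yi <- y[i]
    list(n = length(i), XtX = crossprod(Xi), Xty = crossprod(Xi, yi),
         yty = sum(yi^2), Xs = colSums(Xi), ys = sum(yi))
  })
}

# -2 * REML log-likelihood (up to the 2*pi constant) for variance ratio
# lambda, plus profiled estimates
.reml_profile <- function(lambda, blocks, p, n) {
  XtVX <- 0
  XtVy <- 0
  yVy <- 0
  logdetV <- 0
  for (b in blocks) {
    ci <- lambda / (1 + lambda * b$n)
    XtVX <- XtVX + b$XtX - ci * tcrossprod(b$Xs)
    XtVy <- XtVy + b$Xty - ci * b$Xs * b$ys
    yVy <- yVy + b$yty - ci * b$ys^2
    logdetV <- logdetV + log1p(lambda * b$n)
  }
  XtVX <- (XtVX + t(XtVX)) / 2
  ch <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(ch)) return(list(crit = Inf))
  beta <- backsolve(ch, forwardsolve(t(ch), XtVy))
  rss <- drop(yVy - 2 * crossprod(beta, XtVy) + crossprod(beta, XtVX %*% beta))
  rss <- max(rss, 1e-300)
  se2 <- rss / (n - p)
  crit <- logdetV + 2 * sum(log(diag(ch))) + (n - p) * log(se2) + (n - p)
  list(crit = crit, beta = drop(beta), se2 = se2, XtVX = XtVX)
}

# -2 REML as a function of theta = (sb2, se2), for the Satterthwaite
# machinery (includes all theta-dependent terms)
.reml_theta <- function(theta, blocks, p, n) {
  sb2 <- theta[1]
  se2 <- theta[2]
  if (se2 <= 0 || sb2 < 0) return(Inf)
  lambda <- sb2 / se2
  pr <- .reml_profile(lambda, blocks, p, n)
  if (!is.finite(pr$crit)) return(Inf)
  # un-profile: logdet terms pick up se2 factors; quadratic form scales
  rss <- pr$se2 * (n - p)
  pr_logdetV <- 0
  XtVX <- 0
  for (b in blocks) {
    ci <- lambda / (1 + lambda * b$n)
    XtVX <- XtVX + b$XtX - ci * tcrossprod(b$Xs)
    pr_logdetV <- pr_logdetV + log1p(lambda * b$n)
  }
  n_log_se2 <- n * log(se2)
  log_XtSigX <- determinant((XtVX + t(XtVX)) / 2 / se2,
                            logarithm = TRUE)$modulus
  n_log_se2 + pr_logdetV + as.numeric(log_XtSigX) + rss / se2
}

# vcov of beta as a function of theta (for the Satterthwaite gradient)
.beta_vcov_theta <- function(theta, blocks) {
  sb2 <- theta[1]
  se2 <- theta[2]
  lambda <- sb2 / se2
  XtVX <- 0
  for (b in blocks) {
    ci <- lambda / (1 + lambda * b$n)
    XtVX <- XtVX + b$XtX - ci * tcrossprod(b$Xs)
  }
  se2 * solve((XtVX + t(XtVX)) / 2)
}

#' Fit a participant random-intercept linear mixed model
#'
#' REML estimation for `y = X beta + b[participant] + e`, profiling the
#' variance ratio `sb2/se2` with a grid-plus-golden-section search over a
#' wide range (including the boundary `sb2 = 0`). Inference for a contrast
#' `c'beta` uses Satterthwaite's degrees-of-freedom approximation computed
#' from numerical derivatives of the REML criterion with respect to the
#' variance components; when the random-intercept variance is estimated at
#' the boundary, or every participant contributes a single observation, the
#' fit reduces to ordinary least squares with residual degrees of freedom.
#'
#' @param y Numeric response.
#' @param X Design matrix for the fixed effects.
#' @param group Participant identifier (coerced to factor).
#' @return An object of class `ri_lme`: `beta`, `vcov`, `sigma_b2`,
#'   `sigma_e2`, `lambda`, `reml_crit`, `n`, `p`, `singleton` (all
#'   participants single-observation), plus the block statistics needed for
#'   contrast tests.
#' @keywords internal
fit_random_intercept <- function(y, X, group) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  group <- factor(group)
  n <- length(y)
  p <- ncol(X)
  stopifnot(nrow(X) == n, n > p)
  blocks <- .block_stats(y, X, group)
  singleton <- all(vapply(blocks, function(b) b$n, numeric(1)) == 1)

  if (singleton || nlevels(group) < 2) {
    # random intercept inestimable: ordinary least squares
    fit <- stats::lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    se2 <- rss / (n - p)
    XtXinv <- solve(crossprod(X))
    return(structure(
      list(beta = setNames(fit$coefficients, colnames(X)),
           vcov = se2 * XtXinv, sigma_b2 = 0, sigma_e2 = se2,
           lambda = 0, reml_crit = NA_real_, n = n, p = p,
           singleton = TRUE, blocks = blocks, converged = TRUE),
      class = "ri_lme"
    ))
  }

  # coarse log-spaced grid, then golden-section refinement in the
  # bracketing interval
  grid <- c(0, 10^seq(-6, 6, length.out = 121))
  crit <- vapply(grid, function(l) .reml_profile(l, blocks, p, n)$crit,
                 numeric(1))
  k <- which.min(crit)
  lo <- grid[max(1, k - 1)]
  hi <- grid[min(length(grid), k + 1)]
  lambda <- if (k == 1 && crit[1] <= crit[2]) 0 else {
    stats::optimize(function(l) .reml_profile(l, blocks, p, n)$crit,
                    interval = c(lo, hi), tol = 1e-10)$minimum
  }
  if (.reml_profile(0, blocks, p, n)$crit <=
      .reml_profile(lambda, blocks, p, n)$crit) {
    lambda <- 0
  }
  pr <- .reml_profile(lambda, blocks, p, n)
  se2 <- pr$se2
  sb2 <- lambda * se2
  vcov <- se2 * solve(pr$XtVX)
  dimnames(vcov) <- list(colnames(X), colnames(X))
  structure(
    list(beta = setNames(pr$beta, colnames(X)), vcov = vcov,
         sigma_b2 = sb2, sigma_e2 = se2, lambda = lambda,
         reml_crit = pr$crit, n = n, p = p, singleton = FALSE,
         blocks = blocks, converged = TRUE),
    class = "ri_lme"
  )
}

# Satterthwaite df for contrast c'beta on an ri_lme fit
satterthwaite_df <- function(fit, cvec) {
  if (fit$singleton || fit$sigma_b2 <= 1e-12 * fit$sigma_e2) {
    return(fit$n - fit$p)
  }
  theta <- c(fit$sigma_b2, fit$sigma_e2)
  blocks <- fit$blocks
  fvar <- function(th) drop(t(cvec) %*% .beta_vcov_theta(th, blocks) %*% cvec)
  h <- pmax(1e-5 * abs(theta), 1e-10)
  g <- vapply(1:2, function(j) {
    tp <- theta; tm <- theta
    tp[j] <- tp[j] + h[j]
    tm[j] <- max(tm[j] - h[j], if (j == 1) 0 else 1e-12)
    (fvar(tp) - fvar(tm)) / (tp[j] - tm[j])
  }, numeric(1))
  m2l <- function(th) .reml_theta(th, blocks, fit$p, fit$n)
  H <- matrix(NA_real_, 2, 2)
  for (j in 1:2) for (k in j:2) {
    hj <- h[j]; hk <- h[k]
    if (j == k) {
      H[j, j] <- (m2l(theta + 2 * hj * (1:2 == j)) -
                    2 * m2l(theta + hj * (1:2 == j)) + m2l(theta)) / hj^2
    } else {
      H[j, k] <- H[k, j] <-
        (m2l(theta + hj * (1:2 == j) + hk * (1:2 == k)) -
           m2l(theta + hj * (1:2 == j)) - m2l(theta + hk * (1:2 == k)) +
           m2l(theta)) / (hj * hk)
    }
  }
  A <- tryCatch(solve(H / 2), error = function(e) NULL)  # asymptotic vcov(theta)
  if (is.null(A) || any(!is.finite(A))) return(fit$n - fit$p)
  f <- fvar(theta)
  denom <- drop(t(g) %*% A %*% g)
  if (denom <= 0) return(fit$n - fit$p)
  df <- 2 * f^2 / denom
  min(max(df, 1), fit$n - fit$p)
}

# contrast test with Satterthwaite df
contrast_test <- function(fit, cvec, conf.level = 0.95) {
  est <- sum(cvec * fit$beta)
  se <- sqrt(drop(t(cvec) %*% fit$vcov %*% cvec))
  df <- satterthwaite_df(fit, cvec)
  tq <- qt(1 - (1 - conf.level) / 2, df)
  p <- if (se > 0) 2 * pt(-abs(est / se), df) else NA_real_
  tibble::tibble(estimate = est, se = se, df = df,
                 conf.low = est - tq * se, conf.high = est + tq * se,
                 statistic = if (se > 0) est / se else NA_real_, p.value = p)
}

# ---- user-facing affinity analyses ---------------------------------------

.affinity_response <- function(records, log10_scale) {
  if (log10_scale) log10(records$kd_molar) else records$kd_molar
}

#' Median and interquartile range of affinities per group
#'
#' Censored records (non-binders at the maximum analyte concentration)
#' have a K_D known only to be at or above the censoring value; they are
#' treated as right-censored: if the median (or an IQR endpoint) order
#' statistic falls on a censored record, the reported value is the
#' censoring limit and flagged as a lower bound.
#'
#' @param records Data frame with `group`, `kd_molar`, and optionally a
#'   logical `censored` column.
#' @return A tibble per group: `n`, `n_censored`, `median`, `q25`, `q75`,
#'   `median_is_lower_bound`.
#' @export
summarize_affinities <- function(records) {
  rec <- tibble::as_tibble(records)
  if (!"censored" %in% names(rec)) rec$censored <- FALSE
  rec$censored[is.na(rec$censored)] <- FALSE
  rec |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(function(d, key) {
      kd <- ifelse(d$censored, Inf, d$kd_molar)
      # order-statistic quantiles when censored values are present (so the
      # Inf placeholders propagate instead of being averaged); the usual
      # interpolated quantiles otherwise
      qs <- quantile(kd, c(0.25, 0.5, 0.75), names = FALSE,
                     type = if (any(d$censored)) 1 else 7)
      lb <- !is.finite(qs[2])
      if (lb) {
        # median sits on a censored record: report the censoring limit
        qs[2] <- max(d$kd_molar[d$censored])
      }
      tibble::tibble(
        n = nrow(d), n_censored = sum(d$censored),
        median = qs[2],
        q25 = if (is.finite(qs[1])) qs[1] else NA_real_,
        q75 = if (is.finite(qs[3])) qs[3] else NA_real_,
        median_is_lower_bound = lb
      )
    }) |>
    dplyr::ungroup()
}

#' Between-group affinity comparison with participant random intercept
#'
#' Fits `log10(K_D) ~ group` (cell means for the two groups) with a
#' participant random intercept by REML and tests the group difference
#' (second level minus first) with Satterthwaite degrees of freedom.
#' Censored records are excluded (with a count). With one observation per
#' participant the fit reduces to ordinary least squares and the test to
#' the pooled two-sample t-test.
#'
#' @param records Data frame with `participant_id`, `group` (two levels),
#'   `kd_molar`, optional logical `censored`.
#' @param log10_scale Analyse `log10(kd_molar)` (default) or the raw scale.
#' @return A list of class `affinity_lme`: `contrast` (tibble with
#'   `estimate`, `se`, `df`, `conf.low`, `conf.high`, `p.value` for the
#'   group difference), `group_means`, `fit` (the `ri_lme`),
#'   `n_censored_excluded`, `log10_scale`, `groups`.
#' @examples
#' rec <- tibble::tibble(
#'   participant_id = rep(c("P1", "P2", "P3", "P4"), each = 2),
#'   group = rep(c("*02", "*04"), each = 4),
#'   kd_molar = c(3e-7, 4e-7, 2e-7, 5e-7, 5e-8, 7e-8, 6e-8, 4e-8))
#' fit_between_group_lme(rec)$contrast
#' @export
fit_between_group_lme <- function(records, log10_scale = TRUE) {
  rec <- tibble::as_tibble(records)
  if (!"censored" %in% names(rec)) rec$censored <- FALSE
  rec$censored[is.na(rec$censored)] <- FALSE
  n_cens <- sum(rec$censored)
  rec <- dplyr::filter(rec, !.data$censored)
  g <- factor(rec$group)
  if (nlevels(g) != 2L) abort("`group` must have exactly two levels.")
  y <- .affinity_response(rec, log10_scale)
  X <- cbind(as.numeric(g == levels(g)[1]), as.numeric(g == levels(g)[2]))
  colnames(X) <- levels(g)
  fit <- fit_random_intercept(y, X, rec$participant_id)
  cvec <- c(-1, 1)  # second level minus first
  contrast <- contrast_test(fit, cvec)
  means <- tibble::tibble(group = levels(g), mean = unname(fit$beta))
  structure(
    list(contrast = contrast, group_means = means, fit = fit,
         n_censored_excluded = n_cens, log10_scale = log10_scale,
         groups = levels(g)),
    class = "affinity_lme"
  )
}

#' Paired original-vs-variant affinity comparison
#'
#' For matched antibody pairs (an original and an engineered variant of the
#' same antibody), models the per-antibody log10 affinity difference
#' `variant - original` with a participant random intercept and tests the
#' mean difference with Satterthwaite degrees of freedom. With one antibody
#' per participant this is exactly the paired t-test.
#'
#' @param records Data frame with `antibody_id`, `participant_id`, `group`
#'   (two levels: original first, variant second, by factor order),
#'   `kd_molar`, optional logical `censored` (censored pairs are dropped).
#' @param log10_scale Analyse differences of `log10(kd_molar)` (default).
#' @return A list of class `affinity_lme` with `contrast` (the mean paired
#'   difference), `fit`, `n_pairs`, `n_censored_excluded`, `log10_scale`.
#' @export
fit_paired_variant_lme <- function(records, log10_scale = TRUE) {
  rec <- tibble::as_tibble(records)
  if (!"censored" %in% names(rec)) rec$censored <- FALSE
  rec$censored[is.na(rec$censored)] <- FALSE
  g <- factor(rec$group)
  if (nlevels(g) != 2L) abort("`group` must have exactly two levels.")
  cens_ab <- unique(rec$antibody_id[rec$censored])
  n_cens <- length(cens_ab)
  rec <- dplyr::filter(rec, !.data$antibody_id %in% cens_ab)
  rec$y <- .affinity_response(rec, log10_scale)
  wide <- rec |>
    dplyr::select("antibody_id", "participant_id", "group", "y") |>
    tidyr::pivot_wider(names_from = "group", values_from = "y")
  lv <- levels(g)
  if (!all(lv %in% names(wide)) || anyNA(wide[lv])) {
    abort("every antibody must have exactly one record per group.")
  }
  d <- wide[[lv[2]]] - wide[[lv[1]]]
  X <- matrix(1, length(d), 1, dimnames = list(NULL, "difference"))
  fit <- fit_random_intercept(d, X, wide$participant_id)
  contrast <- contrast_test(fit, 1)
  structure(
    list(contrast = contrast, fit = fit, n_pairs = length(d),
         n_censored_excluded = n_cens, log10_scale = log10_scale,
         groups = lv),
    class = "affinity_lme"
  )
}

#' @export
print.affinity_lme <- function(x, ...) {
  cat("<affinity_lme>",
      if (x$log10_scale) "log10(K_D) scale" else "raw K_D scale", "\n")
  print(x$contrast)
  cat(sprintf("  sigma_b^2 = %.4g, sigma_e^2 = %.4g, censored excluded = %d\n",
              x$fit$sigma_b2, x$fit$sigma_e2, x$n_censored_excluded))
  invisible(x)
}

#' @export
#' @method tidy affinity_lme
tidy.affinity_lme <- function(x, ...) {
  dplyr::mutate(x$contrast,
                term = if (length(x$groups) == 2)
                  paste(x$groups[2], "-", x$groups[1]) else "difference",
                .before = 1)
}

#' @export
#' @method glance affinity_lme
glance.affinity_lme <- function(x, ...) {
  tibble::tibble(nobs = x$fit$n, sigma.b2 = x$fit$sigma_b2,
                 sigma.e2 = x$fit$sigma_e2, lambda = x$fit$lambda,
                 REML.crit = x$fit$reml_crit, singleton = x$fit$singleton)
}
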