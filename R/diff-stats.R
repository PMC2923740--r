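#' Fit per-protein weighted linear models with a label-swap covariate
#'
#' For each protein group, the observed pool-pair log2 case/control ratios
#' across all diseases are regressed on disease-specific mean parameters
#' plus a covariate `x` equal to +1 when the heavy label was assigned to
#' the case pool and -1 otherwise, by weighted least squares with weights
#' equal to the number of quantified peptides. Fitting jointly across
#' diseases shares the residual degrees of freedom for variance
#' estimation. When the label covariate is aliased with the disease means
#' on the observed rows (e.g. a single disease whose heavy label was
#' always on the case pool), it is dropped and the protein is flagged.
#'
#' @param m A `protein_ratio_matrix` (typically centered and filtered).
#' @param per_disease_lambda If `TRUE`, estimate one labeling coefficient
#'   per disease (disease-by-label interaction) instead of a single shared
#'   coefficient.
#' @return An object of class `model_fits`: list with matrices
#'   `coefficients` (protein x disease effect estimates), `unscaled_se`
#'   (protein x disease multipliers such that SE = unscaled_se * s),
#'   `n_obs` and `total_weight` (per protein per disease), vectors
#'   `lambda`, `s2` (residual variance), `df` (residual df), logical
#'   `aliased`, and `diseases`.
#' @export
fit_weighted_model <- function(m, per_disease_lambda = FALSE) {
  stopifnot(inherits(m, "protein_ratio_matrix"))
  diseases <- unique(m$pairs$disease)
  dis <- factor(m$pairs$disease, levels = diseases)
  x <- m$pairs$x
  nprot <- nrow(m$y)
  prot <- rownames(m$y)

  coefs <- matrix(NA_real_, nprot, length(diseases),
                  dimnames = list(prot, diseases))
  use <- n_obs <- tot_w <- coefs
  lambda <- s2 <- df <- stats::setNames(rep(NA_real_, nprot), prot)
  aliased <- stats::setNames(rep(FALSE, nprot), prot)

  for (g in seq_len(nprot)) {
    obs <- which(!is.na(m$y[g, ]))
    if (length(obs) < 2)
      stop("protein ", prot[g], " has fewer than 2 observed pool pairs; ",
           "apply exclusions first")
    yg <- m$y[g, obs]
    wg <- m$w[g, obs]
    dg <- factor(as.character(dis[obs]), levels = diseases)
    dg <- droplevels(dg)
    Xd <- vapply(levels(dg), function(l) as.numeric(dg == l),
                 numeric(length(obs)))
    if (!is.matrix(Xd)) Xd <- matrix(Xd, nrow = length(obs),
                                     dimnames = list(NULL, levels(dg)))
    Xl <- if (per_disease_lambda) {
      xm <- Xd * x[obs]
      colnames(xm) <- paste0("lambda_", levels(dg))
      xm
    } else {
      matrix(x[obs], ncol = 1, dimnames = list(NULL, "lambda"))
    }
    X <- cbind(Xd, Xl)
    sw <- sqrt(wg)
    qr_full <- qr(X * sw)
    if (qr_full$rank < ncol(X)) {
      # label covariate aliased with the disease means: drop it
      X <- Xd
      aliased[g] <- TRUE
    }
    fit <- stats::lm.wfit(X, yg, wg)
    rank <- fit$rank
    if (rank == 0) stop("rank-0 design for protein ", prot[g])
    cf <- fit$coefficients
    res <- fit$residuals
    df[g] <- length(obs) - rank
    rss <- sum(wg * res^2)
    s2[g] <- if (df[g] > 0) rss / df[g] else 0

    R <- qr.R(fit$qr)
    pivot <- fit$qr$pivot[seq_len(rank)]
    xtwxi <- chol2inv(R[seq_len(rank), seq_len(rank), drop = FALSE])
    u_all <- stats::setNames(rep(NA_real_, ncol(X)), colnames(X))
    u_all[colnames(X)[pivot]] <- sqrt(diag(xtwxi))

    for (d in levels(dg)) {
      coefs[g, d] <- cf[d]
      use[g, d] <- u_all[d]
      rows_d <- obs[as.character(dis[obs]) == d]
      n_obs[g, d] <- length(rows_d)
      tot_w[g, d] <- sum(m$w[g, rows_d])
    }
    if (!aliased[g]) {
      lambda[g] <- if (per_disease_lambda) NA_real_ else cf["lambda"]
    }
  }
  structure(list(coefficients = coefs, unscaled_se = use,
                 n_obs = n_obs, total_weight = tot_w,
                 lambda = lambda, s2 = s2, df = df, aliased = aliased,
                 diseases = diseases),
            class = "model_fits")
}

# Newton solve of trigamma(x) = y, vectorized; the moment-matching step of
# empirical-Bayes variance estimation needs its inverse on (0, Inf).
trigamma_inverse <- function(y) {
  out <- y
  lo <- y < 1e-8
  hi <- y > 1e7
  out[lo] <- 1 / y[lo]
  out[hi] <- 1 / sqrt(y[hi])
  mid <- !(lo | hi)
  if (any(mid)) {
    x <- 0.5 + 1 / y[mid]
    for (i in 1:60) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / y[mid]) / psigamma(x, deriv = 2)
      x <- x + dif
      if (max(abs(dif / x)) < 1e-10) break
    }
    out[mid] <- x
  }
  out
}

#' Estimate empirical-Bayes variance hyperparameters
#'
#' Moment-matching of the log residual variances against a scaled F
#' distribution: with `s_g^2 ~ s0^2 * chisq(d_g)/d_g * F(d0)` under the
#' hierarchical model, `log s_g^2` has known mean and variance offsets in
#' terms of digamma/trigamma functions, giving the prior df `d0` from the
#' excess dispersion of `log s_g^2` (trigamma equation) and the prior
#' variance `s0^2` from the mean equation. When the empirical dispersion
#' does not exceed the dispersion expected under equal true variances,
#' `d0 = Inf` is returned.
#'
#' @param fits A `model_fits` object, or a list with numeric `s2` and `df`.
#' @return A list of class `ebayes_hyperparams` with `d0` (prior df,
#'   possibly `Inf`) and `s02` (prior variance).
#' @export
estimate_hyperparams <- function(fits) {
  s2 <- fits$s2
  d <- fits$df
  keep <- !is.na(s2) & !is.na(d) & d > 0
  s2 <- s2[keep]
  d <- d[keep]
  if (length(s2) < 2) stop("need at least 2 proteins with positive residual df")
  if (all(s2 == s2[1]))
    return(structure(list(d0 = Inf, s02 = s2[1]),
                     class = "ebayes_hyperparams"))
  if (any(s2 <= 0)) {
    # exact-zero variances carry no information about the prior scale
    d <- d[s2 > 0]
    s2 <- s2[s2 > 0]
    if (length(s2) < 2) stop("too few positive residual variances")
  }
  z <- log(s2)
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1) - mean(trigamma(d / 2))
  if (evar <= 0) {
    d0 <- Inf
    s02 <- exp(emean)
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  }
  structure(list(d0 = d0, s02 = s02), class = "ebayes_hyperparams")
}

#' Construct empirical-Bayes hyperparameters directly
#'
#' @param d0 Prior degrees of freedom (> 0, may be `Inf`).
#' @param s02 Prior variance (> 0; 0 tolerated only as a degenerate limit).
#' @return An `ebayes_hyperparams` object.
#' @export
ebayes_hyperparams <- function(d0, s02) {
  if (is.na(d0) || d0 < 0) stop("d0 must be >= 0")
  if (is.na(s02) || s02 < 0) stop("s02 must be >= 0")
  structure(list(d0 = d0, s02 = s02), class = "ebayes_hyperparams")
}

#' Weighted moderated t-tests for disease-specific mean parameters
#'
#' Shrinks each protein's residual variance toward the prior,
#' `s_tilde^2 = (d0*s0^2 + d_g*s_g^2) / (d0 + d_g)`, and tests each
#' disease-specific mean against zero with
#' `t = mu_hat / (u * s_tilde)` on `d0 + d_g` degrees of freedom
#' (standard normal in the `d0 = Inf` limit). With `d0 = 0` this is the
#' ordinary weighted least-squares t-test.
#'
#' @param fits A `model_fits` object.
#' @param hyper An `ebayes_hyperparams` object.
#' @param min_pairs Minimum observed pool pairs for a protein to be
#'   reported for a disease (default 2).
#' @return A data.frame with one row per protein per reported disease:
#'   `protein`, `disease`, `log2_ratio`, `t`, `df_total`, `p`, `n_pairs`,
#'   `total_weight`, plus attribute `hyperparams`.
#' @export
moderated_test <- function(fits, hyper, min_pairs = 2L) {
  stopifnot(inherits(fits, "model_fits"),
            inherits(hyper, "ebayes_hyperparams"))
  d0 <- hyper$d0
  s02 <- hyper$s02
  d <- fits$df
  if (is.infinite(d0)) {
    s2_post <- rep(s02, length(d))
    df_total <- rep(Inf, length(d))
  } else {
    if (any(d0 + d == 0)) stop("zero total degrees of freedom")
    s2_post <- (d0 * s02 + d * fits$s2) / (d0 + d)
    df_total <- d0 + d
  }
  out <- NULL
  for (dd in fits$diseases) {
    ok <- !is.na(fits$coefficients[, dd]) & fits$n_obs[, dd] >= min_pairs
    if (!any(ok)) next
    mu <- fits$coefficients[ok, dd]
    u <- fits$unscaled_se[ok, dd]
    tt <- mu / (u * sqrt(s2_post[ok]))
    p <- 2 * stats::pt(-abs(tt), df = df_total[ok])
    out <- rbind(out, data.frame(
      protein = rownames(fits$coefficients)[ok],
      disease = dd,
      log2_ratio = mu,
      t = tt,
      df_total = df_total[ok],
      p = p,
      n_pairs = fits$n_obs[ok, dd],
      total_weight = fits$total_weight[ok, dd],
      stringsAsFactors = FALSE, row.names = NULL
    ))
  }
  attr(out, "hyperparams") <- hyper
  out
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Step-up adjustment of a (possibly truncated) list of p-values against a
#' stated total number of tests: the adjusted value at rank i is
#' `min over j >= i (within the provided list) of p_(j) * n_total / j`,
#' capped at 1. Supplying only the smallest p-values of `n_total` tests
#' therefore reproduces the adjusted values of a published top-ranked
#' excerpt whenever each entry's step-up minimum is attained inside the
#' excerpt.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param n_total Total number of tests (>= `length(p)`).
#' @return Adjusted values in the input order.
#' @export
bh_adjust <- function(p, n_total = length(p)) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  if (n_total < length(p))
    stop("n_total must be at least length(p)")
  stats::p.adjust(p, method = "BH", n = n_total)
}

#' Per-disease differential results with FDR
#'
#' Convenience wrapper: runs [moderated_test()] and appends a BH-adjusted
#' FDR column computed separately within each disease, with the total test
#' count equal to the number of proteins reported for that disease.
#'
#' @inheritParams moderated_test
#' @return The [moderated_test()] data.frame with an `fdr` column, sorted
#'   by disease then p-value.
#' @export
differential_results <- function(fits, hyper, min_pairs = 2L) {
  res <- moderated_test(fits, hyper, min_pairs = min_pairs)
  res$fdr <- NA_real_
  for (dd in unique(res$disease)) {
    i <- res$disease == dd
    res$fdr[i] <- bh_adjust(res$p[i])
  }
  res <- res[order(res$disease, res$p), ]
  rownames(res) <- NULL
  res
}
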