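#' Paired geometric mean ratio with confidence interval and p-value
#'
#' For matched case/control concentration pairs, computes the geometric
#' mean of the within-pair ratios: with `l_k = ln(case_k / control_k)`,
#' GMR = `exp(mean l)`, the two-sided 95% CI is
#' `exp(mean +/- t_{0.975, n-1} * SE)` and the p-value comes from the
#' one-sample t-test of the `l_k` against zero. Constant ratios (SE = 0)
#' are flagged as degenerate.
#'
#' @param pairs Data.frame with positive `case_conc` and `control_conc`
#'   columns (an ElisaPairTable), >= 3 rows.
#' @param conf_level Confidence level (default 0.95).
#' @return A list with `gmr`, `ci` (length 2), `p`, `n`, `se_log` and
#'   `degenerate`.
#' @export
geometric_mean_ratio <- function(pairs, conf_level = 0.95) {
  if (nrow(pairs) < 3) stop("need at least 3 pairs")
  if (any(pairs$case_conc <= 0) || any(pairs$control_conc <= 0))
    stop("concentrations must be strictly positive")
  l <- log(pairs$case_conc / pairs$control_conc)
  n <- length(l)
  m <- mean(l)
  se <- stats::sd(l) / sqrt(n)
  if (se == 0) {
    return(list(gmr = exp(m), ci = exp(c(m, m)),
                p = if (m == 0) 1 else 0,
                n = n, se_log = 0, degenerate = TRUE))
  }
  tq <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1)
  tstat <- m / se
  list(gmr = exp(m), ci = exp(m + c(-1, 1) * tq * se),
       p = 2 * stats::pt(-abs(tstat), df = n - 1),
       n = n, se_log = se, degenerate = FALSE)
}

#' Covariate-adjusted geometric mean ratio
#'
#' Regresses the within-pair log-ratios on pair-level covariates
#' (differences for continuous covariates taken as given in the table;
#' categorical covariates expanded to indicators) and reports the
#' exponentiated intercept as the adjusted GMR with its Wald-style t CI.
#' With no covariates this reduces exactly to [geometric_mean_ratio()].
#'
#' @param pairs ElisaPairTable data.frame.
#' @param covariates Character vector of column names in `pairs` to adjust
#'   for (may be empty).
#' @param conf_level Confidence level (default 0.95).
#' @return A list with `gmr`, `ci`, `p` (intercept test), `n`,
#'   `dropped` (covariates removed for rank deficiency, with a warning)
#'   and the underlying `fit`.
#' @export
adjusted_ratio_model <- function(pairs, covariates = character(),
                                 conf_level = 0.95) {
  if (nrow(pairs) < 3) stop("need at least 3 pairs")
  if (any(pairs$case_conc <= 0) || any(pairs$control_conc <= 0))
    stop("concentrations must be strictly positive")
  missing_cov <- setdiff(covariates, names(pairs))
  if (length(missing_cov))
    stop("covariates not in table: ", paste(missing_cov, collapse = ", "))
  l <- log(pairs$case_conc / pairs$control_conc)
  df <- data.frame(.l = l, pairs[, covariates, drop = FALSE])
  fml <- if (length(covariates))
    stats::as.formula(paste(".l ~", paste(covariates, collapse = " + ")))
  else stats::as.formula(".l ~ 1")
  fit <- stats::lm(fml, data = df)
  cf <- stats::coef(fit)
  dropped <- names(cf)[is.na(cf)]
  if (length(dropped))
    warning("rank-deficient covariates dropped: ",
            paste(dropped, collapse = ", "))
  sm <- summary(fit)$coefficients
  est <- sm["(Intercept)", "Estimate"]
  se <- sm["(Intercept)", "Std. Error"]
  tq <- stats::qt(1 - (1 - conf_level) / 2, df = fit$df.residual)
  list(gmr = exp(est), ci = exp(est + c(-1, 1) * tq * se),
       p = sm["(Intercept)", "Pr(>|t|)"], n = nrow(pairs),
       dropped = dropped, fit = fit)
}

#' Quartile logistic regression with trend test
#'
#' Expands matched pairs to individual subjects (case = 1, control = 0),
#' cuts the pooled concentration distribution at its quartiles (ties to
#' the lower quartile), and fits an unconditional logistic regression of
#' case status on quartile indicators plus any covariates. Odds ratios
#' for quartiles 2-4 versus the first are exponentiated coefficients with
#' Wald CIs; the trend p-value comes from a companion model with the
#' quartile entered as the ordinal score 1-4.
#'
#' @param subjects Data.frame with columns `outcome` (0/1) and
#'   `concentration` (> 0), plus any covariate columns; alternatively use
#'   [pairs_to_subjects()] on an ElisaPairTable.
#' @param covariates Character vector of covariate column names.
#' @param conf_level Confidence level (default 0.95).
#' @return A list with `or` (named OR2..OR4), `ci` (3 x 2 matrix),
#'   `trend_p`, `trend_beta`, `quartile_breaks`, and the two fitted
#'   models.
#' @export
quartile_logistic <- function(subjects, covariates = character(),
                              conf_level = 0.95) {
  stopifnot(all(c("outcome", "concentration") %in% names(subjects)))
  if (sum(subjects$outcome == 1) < 8 || sum(subjects$outcome == 0) < 8)
    stop("need at least 8 subjects per arm")
  if (any(subjects$concentration <= 0))
    stop("concentrations must be strictly positive")
  br <- stats::quantile(subjects$concentration, probs = seq(0, 1, 0.25))
  q <- cut(subjects$concentration, breaks = unique(br),
           include.lowest = TRUE, labels = FALSE, right = TRUE)
  if (length(unique(q)) < 4)
    stop("fewer than 4 distinct quartile groups (heavily tied data)")
  dat <- data.frame(outcome = subjects$outcome, quartile = factor(q),
                    subjects[, covariates, drop = FALSE])
  rhs <- c("quartile", covariates)
  fml <- stats::as.formula(paste("outcome ~", paste(rhs, collapse = " + ")))
  fit <- stats::glm(fml, data = dat, family = stats::binomial())
  if (!fit$converged || any(abs(stats::coef(fit)) > 15, na.rm = TRUE))
    stop("possible separation in logistic fit; ",
         "consider an exact or penalized method")
  sm <- summary(fit)$coefficients
  qn <- paste0("quartile", 2:4)
  est <- sm[qn, "Estimate"]
  se <- sm[qn, "Std. Error"]
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- cbind(exp(est - zq * se), exp(est + zq * se))
  dimnames(ci) <- list(c("OR2", "OR3", "OR4"), c("lower", "upper"))

  dat$score <- as.numeric(q)
  fml_t <- stats::as.formula(paste("outcome ~",
                                   paste(c("score", covariates),
                                         collapse = " + ")))
  fit_t <- stats::glm(fml_t, data = dat, family = stats::binomial())
  sm_t <- summary(fit_t)$coefficients
  list(or = stats::setNames(exp(est), c("OR2", "OR3", "OR4")), ci = ci,
       trend_p = sm_t["score", "Pr(>|z|)"],
       trend_beta = sm_t["score", "Estimate"],
       quartile_breaks = br, fit = fit, trend_fit = fit_t)
}

#' Logistic slope on log concentration
#'
#' Fits case status on the natural log of concentration (plus covariates)
#' and returns the slope and its standard error, the inputs of
#' [project_or()].
#'
#' @inheritParams quartile_logistic
#' @return A list with `beta`, `se`, `p` and the fitted model.
#' @export
log_concentration_slope <- function(subjects, covariates = character()) {
  stopifnot(all(c("outcome", "concentration") %in% names(subjects)))
  if (any(subjects$concentration <= 0))
    stop("concentrations must be strictly positive")
  dat <- data.frame(outcome = subjects$outcome,
                    log_conc = log(subjects$concentration),
                    subjects[, covariates, drop = FALSE])
  fml <- stats::as.formula(paste("outcome ~",
                                 paste(c("log_conc", covariates),
                                       collapse = " + ")))
  fit <- stats::glm(fml, data = dat, family = stats::binomial())
  sm <- summary(fit)$coefficients
  list(beta = sm["log_conc", "Estimate"], se = sm["log_conc", "Std. Error"],
       p = sm["log_conc", "Pr(>|z|)"], fit = fit)
}

#' Expand an ElisaPairTable to one row per subject
#'
#' @param pairs ElisaPairTable data.frame with `case_conc`, `control_conc`
#'   and optional covariate columns (applied to both members of a pair).
#' @return Data.frame with `pair_id`, `outcome`, `concentration` and the
#'   covariates.
#' @export
pairs_to_subjects <- function(pairs) {
  covs <- setdiff(names(pairs), c("pair_id", "case_conc", "control_conc"))
  out <- data.frame(
    pair_id = rep(pairs$pair_id, 2),
    outcome = rep(c(1L, 0L), each = nrow(pairs)),
    concentration = c(pairs$case_conc, pairs$control_conc),
    stringsAsFactors = FALSE
  )
  for (nm in covs) out[[nm]] <- rep(pairs[[nm]], 2)
  out
}

#' Project a fold-change onto a disease odds ratio
#'
#' Given a logistic slope `beta` on the natural log of a protein's
#' concentration (with standard error `se`), a multiplicative change `g`
#' in concentration projects onto an odds ratio
#' `OR = exp(beta * ln g)` with Wald CI
#' `exp((beta +/- 1.96 se) * ln g)`.
#'
#' @param beta Logistic slope on ln concentration.
#' @param se Standard error of `beta` (default 0 yields a point estimate
#'   with zero-width CI).
#' @param fold Multiplicative concentration change g (> 0), e.g. 1.16 for
#'   a 16% elevation.
#' @return A list with `or` and `ci`.
#' @export
project_or <- function(beta, se = 0, fold) {
  if (!is.finite(fold) || fold <= 0) stop("fold must be > 0")
  lg <- log(fold)
  lims <- sort(c((beta - 1.96 * se) * lg, (beta + 1.96 * se) * lg))
  list(or = exp(beta * lg), ci = exp(lims))
}
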