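test_that("constant response with an aliased label covariate fits cleanly", {
  y <- matrix(0.2, 1, 4, dimnames = list("P1", NULL))
  m <- make_matrix(y)  # single disease, x identically +1
  fits <- fit_weighted_model(m)
  expect_true(fits$aliased["P1"])
  expect_equal(unname(fits$coefficients["P1", "CHD"]), 0.2)
  expect_equal(unname(fits$s2["P1"]), 0)
  expect_equal(unname(fits$df["P1"]), 3)
})

test_that("noise-free two-disease data recover effects and labeling bias exactly", {
  x <- c(1, -1, 1, -1, 1, 1, -1, -1, 1, -1)
  disease <- rep(c("CHD", "stroke"), each = 5)
  delta <- c(CHD = 0.4, stroke = -0.1)
  lambda <- 0.3
  y <- rbind(delta[disease] + lambda * x)
  rownames(y) <- "P1"
  m <- make_matrix(y, disease = disease, x = x)
  fits <- fit_weighted_model(m)
  expect_false(fits$aliased["P1"])
  expect_equal(unname(fits$coefficients["P1", "CHD"]), 0.4, tolerance = 1e-12)
  expect_equal(unname(fits$coefficients["P1", "stroke"]), -0.1,
               tolerance = 1e-12)
  expect_equal(unname(fits$lambda["P1"]), 0.3, tolerance = 1e-12)
  expect_equal(unname(fits$s2["P1"]), 0, tolerance = 1e-12)
})

test_that("weighted fits match the normal-equations oracle on random instances", {
  set.seed(31)
  for (rep in 1:8) {
    n_pairs <- 10
    disease <- rep(c("CHD", "stroke"), each = 5)
    x <- sample(c(-1, 1), n_pairs, replace = TRUE)
    if (length(unique(x)) == 1) x[1] <- -x[1]
    y <- matrix(rnorm(6 * n_pairs), 6, n_pairs)
    w <- matrix(sample(1:9, 6 * n_pairs, replace = TRUE), 6, n_pairs)
    m <- make_matrix(y, w, disease = disease, x = x)
    fits <- fit_weighted_model(m)
    X <- cbind(CHD = as.numeric(disease == "CHD"),
               stroke = as.numeric(disease == "stroke"), lambda = x)
    for (g in 1:6) {
      o <- wls_oracle(X, y[g, ], w[g, ])
      expect_equal(unname(fits$coefficients[g, ]), unname(o$beta[1:2]),
                   tolerance = 1e-10)
      expect_equal(unname(fits$lambda[g]), unname(o$beta[3]),
                   tolerance = 1e-10)
      expect_equal(unname(fits$s2[g]), o$s2, tolerance = 1e-10)
      expect_equal(unname(fits$unscaled_se[g, ]),
                   unname(sqrt(diag(o$cov_unscaled))[1:2]),
                   tolerance = 1e-10)
    }
  }
})

test_that("weights enter only through their relative sizes", {
  set.seed(7)
  y <- matrix(rnorm(20), 2, 10)
  w <- matrix(sample(1:5, 20, replace = TRUE), 2, 10)
  x <- rep(c(1, -1), 5)
  m1 <- fit_weighted_model(make_matrix(y, w, x = x))
  m2 <- fit_weighted_model(make_matrix(y, 10 * w, x = x))
  expect_equal(m1$coefficients, m2$coefficients, tolerance = 1e-12)
  # residual variance rescales with the weights; t statistics do not
  h1 <- moderated_test(m1, ebayes_hyperparams(0, 1))
  h2 <- moderated_test(m2, ebayes_hyperparams(0, 1))
  expect_equal(h1$t, h2$t, tolerance = 1e-10)
})

test_that("joint fitting without a label effect matches per-disease fits", {
  set.seed(13)
  y <- matrix(rnorm(40), 4, 10)
  disease <- rep(c("CHD", "stroke"), each = 5)
  m_joint <- make_matrix(y, disease = disease)          # x all +1: aliased
  f_joint <- fit_weighted_model(m_joint)
  f_chd <- fit_weighted_model(make_matrix(y[, 1:5]))
  expect_true(all(f_joint$aliased))
  expect_equal(unname(f_joint$coefficients[, "CHD"]),
               unname(f_chd$coefficients[, "CHD"]), tolerance = 1e-12)
})

test_that("identical residual variances give an infinite prior df", {
  fits <- list(s2 = rep(0.04, 10), df = rep(5, 10))
  h <- estimate_hyperparams(fits)
  expect_equal(h$d0, Inf)
  expect_equal(h$s02, 0.04)
})

test_that("hyperparameters are recovered from scaled-F simulated variances", {
  set.seed(101)
  d0 <- 4; s02 <- 0.04; dg <- 6; n <- 5000
  true_var <- s02 * d0 / stats::rchisq(n, d0)
  s2 <- true_var * stats::rchisq(n, dg) / dg
  h <- estimate_hyperparams(list(s2 = s2, df = rep(dg, n)))
  expect_equal(h$d0, d0, tolerance = 0.15)
  expect_equal(h$s02, s02, tolerance = 0.05)
})

test_that("the trigamma moment equation matches a root-bracketing oracle", {
  s2 <- c(0.02, 0.09)
  d <- c(4, 6)
  h <- estimate_hyperparams(list(s2 = s2, df = d))
  e <- log(s2) - digamma(d / 2) + log(d / 2)
  evar <- stats::var(e) - mean(trigamma(d / 2))
  skip_if(evar <= 0)
  root <- stats::uniroot(function(x) trigamma(x) - evar,
                         c(1e-6, 1e6), tol = 1e-12)$root
  expect_equal(h$d0, 2 * root, tolerance = 1e-6)
  expect_equal(h$s02, exp(mean(e) + digamma(root) - log(root)),
               tolerance = 1e-8)
})

test_that("moderated t interpolates between ordinary and fully shrunk forms", {
  set.seed(17)
  y <- matrix(rnorm(50, sd = 0.3), 5, 10)
  x <- rep(c(1, -1), 5)
  w <- matrix(sample(1:4, 50, replace = TRUE), 5, 10)
  fits <- fit_weighted_model(make_matrix(y, w, x = x))

  # d0 = 0: ordinary weighted-LS t
  r0 <- moderated_test(fits, ebayes_hyperparams(0, 1))
  t_ord <- fits$coefficients[, "CHD"] /
    (fits$unscaled_se[, "CHD"] * sqrt(fits$s2))
  expect_equal(r0$t, unname(t_ord), tolerance = 1e-12)
  expect_equal(r0$p, 2 * stats::pt(-abs(r0$t), df = fits$df),
               tolerance = 1e-12)

  # d0 = Inf: posterior variance is s0^2 everywhere, normal reference
  rI <- moderated_test(fits, ebayes_hyperparams(Inf, 0.09))
  t_shrunk <- fits$coefficients[, "CHD"] / (fits$unscaled_se[, "CHD"] * 0.3)
  expect_equal(rI$t, unname(t_shrunk), tolerance = 1e-12)
  expect_equal(rI$p, 2 * stats::pnorm(-abs(rI$t)), tolerance = 1e-12)

  # intermediate d0: posterior variance lies between s^2 and s0^2
  rM <- moderated_test(fits, ebayes_hyperparams(4, 0.09))
  s2_post <- (4 * 0.09 + fits$df * fits$s2) / (4 + fits$df)
  expect_true(all(s2_post >= pmin(fits$s2, 0.09) - 1e-12 &
                  s2_post <= pmax(fits$s2, 0.09) + 1e-12))
})

test_that("moderated pipeline agrees with the reference empirical-Bayes implementation", {
  skip_if_not_installed("limma")
  set.seed(23)
  n_prot <- 60; n_pairs <- 12
  disease <- rep(c("CHD", "stroke"), each = 6)
  x <- c(rep(1, 6), rep(c(1, -1), 3))
  y <- matrix(rnorm(n_prot * n_pairs, sd = 0.4), n_prot, n_pairs)
  w <- matrix(sample(1:6, n_prot * n_pairs, replace = TRUE), n_prot, n_pairs)
  m <- make_matrix(y, w, disease = disease, x = x)
  fits <- fit_weighted_model(m)
  hyper <- estimate_hyperparams(fits)
  res <- moderated_test(fits, hyper)

  design <- cbind(CHD = as.numeric(disease == "CHD"),
                  stroke = as.numeric(disease == "stroke"), lambda = x)
  lf <- limma::lmFit(y, design, weights = w)
  expect_equal(unname(fits$coefficients[, "CHD"]),
               unname(lf$coefficients[, "CHD"]), tolerance = 1e-9)
  expect_equal(unname(fits$s2), unname(lf$sigma^2), tolerance = 1e-9)
  eb <- limma::eBayes(lf)
  expect_equal(hyper$d0, eb$df.prior, tolerance = 1e-6)
  expect_equal(hyper$s02, eb$s2.prior, tolerance = 1e-6)
  chd <- res[res$disease == "CHD", ]
  chd <- chd[match(rownames(m$y), chd$protein), ]
  expect_equal(chd$t, unname(eb$t[, "CHD"]), tolerance = 1e-8)
  expect_equal(chd$p, unname(eb$p.value[, "CHD"]), tolerance = 1e-8)
})

test_that("step-up adjustment matches hand computation and stays monotone", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))

  # truncated list against an independent full-list oracle
  set.seed(41)
  for (rep in 1:5) {
    n_total <- 50
    p_full <- sort(stats::runif(n_total))
    k <- 12
    oracle <- stats::setNames(rep(NA_real_, k), seq_len(k))
    for (i in seq_len(k)) {
      oracle[i] <- min(1, min(p_full[i:k] * n_total / (i:k)))
    }
    got <- bh_adjust(p_full[1:k], n_total = n_total)
    expect_equal(got, unname(oracle), tolerance = 1e-12)
    expect_true(all(diff(got) >= -1e-15))
    expect_true(all(got <= 1 & got >= p_full[1:k]))
  }
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.1, 0.2), n_total = 1), "n_total")
})

test_that("confidence intervals from the moderated fit cover the truth", {
  set.seed(59)
  n_prot <- 500
  delta <- stats::rnorm(n_prot, 0, 0.3)
  cfg <- pool_sim_config(n_proteins = n_prot, effect_log2 = delta,
                         label_bias_log2 = 0.2, sigma_protein = 0.2,
                         sigma_peptide = 0.3, missing_rate = 0.1, seed = 59)
  sim <- generate_pool_experiments(cfg)
  m <- center_by_experiment(rollup(sim$peptides))
  fits <- fit_weighted_model(m)
  hyper <- estimate_hyperparams(fits)
  res <- moderated_test(fits, hyper)
  s_post <- sqrt((hyper$d0 * hyper$s02 + fits$df * fits$s2) /
                 (hyper$d0 + fits$df))
  covered <- mapply(function(prot, dd, mu, dftot) {
    half <- stats::qt(0.975, dftot) * fits$unscaled_se[prot, dd] * s_post[prot]
    abs(mu - delta[match(prot, rownames(fits$coefficients))]) <= half
  }, res$protein, res$disease, res$log2_ratio, res$df_total)
  expect_gt(mean(covered), 0.92)
  expect_lt(mean(covered), 0.98)
})
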