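test_that("geometric mean ratio handles identity, constant and generic cases", {
  eq <- data.frame(pair_id = 1:5, case_conc = 2:6, control_conc = 2:6)
  g <- geometric_mean_ratio(eq)
  expect_equal(g$gmr, 1)
  expect_equal(g$p, 1)

  const <- data.frame(pair_id = 1:3, case_conc = c(2, 4, 6),
                      control_conc = c(1, 2, 3))
  g2 <- geometric_mean_ratio(const)
  expect_equal(g2$gmr, 2)
  expect_true(g2$degenerate)
  expect_equal(g2$ci, c(2, 2))

  set.seed(2)
  pairs <- data.frame(pair_id = 1:30,
                      case_conc = exp(rnorm(30, 0.2, 0.3)),
                      control_conc = exp(rnorm(30, 0, 0.3)))
  g3 <- geometric_mean_ratio(pairs)
  l <- log(pairs$case_conc / pairs$control_conc)
  tt <- stats::t.test(l)   # independent oracle
  expect_equal(g3$gmr, exp(unname(tt$estimate)), tolerance = 1e-12)
  expect_equal(g3$ci, exp(unname(tt$conf.int)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(g3$p, tt$p.value, tolerance = 1e-12)

  expect_error(geometric_mean_ratio(eq[1:2, ]), "at least 3")
  bad <- eq; bad$case_conc[1] <- 0
  expect_error(geometric_mean_ratio(bad), "positive")
})

test_that("GMR obeys swap and rescaling invariances", {
  set.seed(4)
  pairs <- data.frame(pair_id = 1:20,
                      case_conc = exp(rnorm(20, 0.1, 0.4)),
                      control_conc = exp(rnorm(20, 0, 0.4)))
  g <- geometric_mean_ratio(pairs)
  swapped <- data.frame(pair_id = pairs$pair_id,
                        case_conc = pairs$control_conc,
                        control_conc = pairs$case_conc)
  gs <- geometric_mean_ratio(swapped)
  expect_equal(gs$gmr, 1 / g$gmr, tolerance = 1e-12)
  expect_equal(gs$p, g$p, tolerance = 1e-12)

  scaled <- pairs
  scaled$case_conc <- scaled$case_conc * 1000
  scaled$control_conc <- scaled$control_conc * 1000
  expect_equal(geometric_mean_ratio(scaled)$gmr, g$gmr, tolerance = 1e-12)
})

test_that("covariate adjustment reduces to the unadjusted GMR when it should", {
  set.seed(6)
  pairs <- data.frame(pair_id = 1:40,
                      case_conc = exp(rnorm(40, 0.15, 0.3)),
                      control_conc = exp(rnorm(40, 0, 0.3)))
  g <- geometric_mean_ratio(pairs)
  a0 <- adjusted_ratio_model(pairs)
  expect_equal(a0$gmr, g$gmr, tolerance = 1e-12)
  expect_equal(a0$ci, g$ci, tolerance = 1e-12)

  # covariate constructed exactly orthogonal to the log-ratios
  l <- log(pairs$case_conc / pairs$control_conc)
  z0 <- rnorm(40)
  pairs$z <- unname(stats::resid(stats::lm(z0 ~ l)))
  a1 <- adjusted_ratio_model(pairs, "z")
  expect_equal(a1$gmr, g$gmr, tolerance = 1e-10)
})

test_that("adjustment removes confounding that biases the crude GMR", {
  cfg <- elisa_sim_config(
    n_pairs = 2000, true_gmr = 1.2, sigma_log = 0.2,
    covariate_effects = list(bmi = list(beta = 0.4, mean = 1,
                                        asymmetric = TRUE)),
    seed = 8)
  pairs <- generate_elisa_pairs(cfg)
  crude <- geometric_mean_ratio(pairs)
  adj <- adjusted_ratio_model(pairs, "bmi")
  expect_gt(crude$gmr, 1.4)                      # biased upward
  expect_equal(adj$gmr, 1.2, tolerance = 0.05)   # recovered
})

test_that("quartile logistic ORs equal contingency cross-product ratios", {
  # 40 subjects per quartile; counts chosen for a Q4 vs Q1 OR of exactly 3:
  # odds(Q1) = 10/30 = 1/3, odds(Q4) = 20/20 = 1
  conc <- rep(c(10, 20, 30, 40), each = 40)
  cases <- c(10, 12, 16, 20)
  outcome <- unlist(lapply(1:4, function(q) {
    rep(c(1L, 0L), c(cases[q], 40 - cases[q]))
  }))
  subjects <- data.frame(outcome = outcome, concentration = conc)
  ql <- quartile_logistic(subjects)
  cross <- function(q) {
    (cases[q] / (40 - cases[q])) / (cases[1] / (40 - cases[1]))
  }
  expect_equal(unname(ql$or["OR4"]), 3.0, tolerance = 1e-6)
  expect_equal(unname(ql$or["OR2"]), cross(2), tolerance = 1e-6)
  expect_equal(unname(ql$or["OR3"]), cross(3), tolerance = 1e-6)
  expect_true(ql$trend_p < 0.05)   # monotone risk gradient present

  # outcome independent of quartile: ORs near 1
  flat <- data.frame(outcome = rep(rep(c(1L, 0L), c(18, 22)), 4),
                     concentration = conc)
  qf <- quartile_logistic(flat)
  expect_equal(unname(qf$or), rep(1, 3), tolerance = 1e-6)
})

test_that("trend p-value decreases with the risk gradient", {
  conc <- rep(c(10, 20, 30, 40), each = 60)
  mk <- function(cases) {
    data.frame(outcome = unlist(lapply(cases, function(k)
      rep(c(1L, 0L), c(k, 60 - k)))), concentration = conc)
  }
  weak <- quartile_logistic(mk(c(25, 27, 29, 31)))
  strong <- quartile_logistic(mk(c(15, 22, 33, 45)))
  expect_lt(strong$trend_p, weak$trend_p)
})

test_that("separation in the logistic fit is reported, not silently fit", {
  conc <- rep(c(10, 20, 30, 40), each = 10)
  outcome <- as.integer(conc > 20)
  expect_error(quartile_logistic(data.frame(outcome = outcome,
                                            concentration = conc)),
               "separation")
})

test_that("fold-change projection follows OR = exp(beta * ln g)", {
  expect_equal(project_or(2.3, 0.4, 1)$or, 1)
  expect_equal(project_or(log(2), 0, 2)$or, exp(log(2)^2), tolerance = 1e-12)
  b <- 1.7; s <- 0.3
  o12 <- project_or(b, s, 1.2)
  o15 <- project_or(b, s, 1.5)
  o18 <- project_or(b, s, 1.2 * 1.5)
  expect_equal(o18$or, o12$or * o15$or, tolerance = 1e-12)
  expect_equal(o12$ci,
               exp((b + c(-1, 1) * 1.96 * s) * log(1.2)), tolerance = 1e-12)
  # a fold below 1 flips the interval ordering; output stays sorted
  dn <- project_or(b, s, 0.8)
  expect_true(dn$ci[1] <= dn$or && dn$or <= dn$ci[2])
  expect_error(project_or(b, s, 0), "fold")
})

test_that("logistic slope on log concentration feeds the projection sensibly", {
  set.seed(10)
  n <- 400
  logc <- rnorm(n, 0, 0.5)
  pr <- stats::plogis(-0.2 + 1.2 * logc)
  subjects <- data.frame(outcome = stats::rbinom(n, 1, pr),
                         concentration = exp(logc))
  sl <- log_concentration_slope(subjects)
  expect_equal(sl$beta, 1.2, tolerance = 0.35)
  proj <- project_or(sl$beta, sl$se, 1.16)
  expect_true(proj$ci[1] < proj$or && proj$or < proj$ci[2])
})

test_that("pair expansion keeps covariates with both members", {
  pairs <- data.frame(pair_id = c("a", "b"), case_conc = c(2, 3),
                      control_conc = c(1, 1), age = c(60, 70))
  s <- pairs_to_subjects(pairs)
  expect_equal(nrow(s), 4)
  expect_equal(sum(s$outcome), 2)
  expect_equal(s$age, c(60, 70, 60, 70))
})
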