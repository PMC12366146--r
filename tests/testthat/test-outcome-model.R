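# Dichotomization, residualization, proportional-odds fitting, effect
# extraction, pseudo-R2, FDR, and the region-model driver.

test_that("dichotomize sends the median and ties to the low group", {
  set.seed(71)
  v33 <- sample(seq(0.01, 0.99, length.out = 33))  # 33 distinct values
  g <- dichotomize(v33)
  expect_equal(attr(g, "group_sizes"), c(low = 17L, high = 16L))
  expect_equal(dichotomize(c(1, 2, 3, 4)), c(0L, 0L, 1L, 1L), ignore_attr = TRUE)
  g2 <- dichotomize(c(0, 0, 0, 5, 9))
  expect_equal(as.integer(g2), c(0L, 0L, 0L, 1L, 1L))
  expect_error(dichotomize(rep(0.3, 5)), "identical")
  expect_error(dichotomize(c(1, NA, 2)), "NA")
})

test_that("residualize is exact OLS with zero residual correlation", {
  # orthogonal case: centered covariate returned
  cov <- c(1, 2, 3, 4)
  against <- c(1, -1, 1, -1)  # orthogonal to the linear trend? check directly
  r <- residualize(cov, against)
  expect_equal(mean(r), 0, tolerance = 1e-14)
  expect_lt(abs(stats::cor(r, against)), 1e-12)
  # collinear case
  expect_equal(residualize(2 * against, against), rep(0, 4), tolerance = 1e-12)
  # 6-point fixture vs hand-solved normal equations
  set.seed(72)
  x <- c(0.1, 0.3, 0.2, 0.8, 0.5, 0.4)
  y <- c(60, 71, 66, 83, 70, 69)
  A <- cbind(1, x)
  beta <- solve(t(A) %*% A, t(A) %*% y)
  expect_equal(residualize(y, x), as.numeric(y - A %*% beta), tolerance = 1e-10)
  expect_error(residualize(y, rep(1, 6)), "zero variance")
  expect_error(residualize(y, x[1:3]), "lengths")
})

test_that("proportional-odds MLE matches MASS::polr", {
  skip_if_not_installed("MASS")
  set.seed(73)
  for (rep in 1:3) {
    n <- 250
    X <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.4), c = runif(n))
    y <- rowSums(outer(X %*% c(0.7, -0.4, 0.3) + rlogis(n),
                       c(-1, 0, 1), ">"))
    f <- fit_proportional_odds(y, X)
    m <- MASS::polr(factor(y, ordered = TRUE) ~ a + b + c,
                    data = data.frame(X, y), Hess = TRUE)
    expect_equal(unname(f$coefficients), unname(coef(m)), tolerance = 1e-4)
    expect_equal(unname(f$zeta), unname(m$zeta), tolerance = 1e-4)
    expect_equal(f$logLik, as.numeric(logLik(m)), tolerance = 1e-7)
    expect_equal(sqrt(diag(f$vcov)), sqrt(diag(vcov(m))[1:3]),
                 tolerance = 1e-4, ignore_attr = TRUE)
  }
})

test_that("binary outcomes reduce the fit to logistic regression", {
  set.seed(74)
  n <- 150
  X <- cbind(x1 = rnorm(n), x2 = runif(n))
  y <- rbinom(n, 1, plogis(0.5 + X %*% c(1, -0.7)))
  f <- fit_proportional_odds(y, X)
  g <- stats::glm(y ~ x1 + x2, family = binomial,
                  data = data.frame(y = y, X))
  expect_equal(unname(f$coefficients), unname(coef(g)[2:3]), tolerance = 1e-6)
  # cutpoint is minus the glm intercept under the cumulative-logit sign
  expect_equal(unname(f$zeta), -unname(coef(g)[1]), tolerance = 1e-6)
})

test_that("the analytic observed information matches numerical Hessians", {
  skip_if_not_installed("numDeriv")
  set.seed(75)
  n <- 120
  X <- cbind(x = rnorm(n))
  y <- rowSums(outer(X[, 1] + rlogis(n), c(-0.5, 0.7), ">"))
  f <- fit_proportional_odds(y, X)
  par <- c(f$zeta, f$coefficients)
  Ha <- wmhnet:::po_hess_zb(par, f$y, f$X, f$K)
  Hn <- numDeriv::hessian(wmhnet:::po_nll_zb, par, y = f$y, X = f$X, K = f$K)
  expect_equal(Ha, Hn, tolerance = 1e-6)
})

test_that("degenerate outcomes and separation raise informative errors", {
  X <- cbind(x = rnorm(30))
  expect_error(fit_proportional_odds(rep(2, 30), X), ">= 2 observed levels")
  # perfect separation
  xs <- c(rep(0, 15), rep(1, 15))
  ys <- c(rep(0, 15), rep(2, 15))
  expect_error(fit_proportional_odds(ys, cbind(x = xs)), "separation")
  # unobserved factor levels collapse with a warning
  yf <- factor(c(rep(0, 10), rep(2, 10), rep(3, 10)), levels = 0:6,
               ordered = TRUE)
  expect_warning(f <- fit_proportional_odds(yf, cbind(x = rnorm(30))),
                 "collapsing")
  expect_equal(f$K, 3)
})

test_that("extract_effect performs closed-form Wald arithmetic", {
  set.seed(76)
  n <- 200
  X <- cbind(g = rbinom(n, 1, 0.5), z = rnorm(n))
  y <- rowSums(outer(0.8 * X[, 1] + rlogis(n), c(-1, 0.5), ">"))
  f <- fit_proportional_odds(y, X)
  eff <- extract_effect(f, "g")
  se <- sqrt(f$vcov["g", "g"])
  expect_equal(eff$or, exp(f$coefficients[["g"]]))
  expect_equal(eff$ci_low, exp(f$coefficients[["g"]] - qnorm(0.975) * se))
  expect_equal(eff$ci_high, exp(f$coefficients[["g"]] + qnorm(0.975) * se))
  expect_equal(eff$p, 2 * pnorm(-abs(f$coefficients[["g"]] / se)))
  # the quoted reference point: coef 0, SE 1 -> OR 1, CI (0.141, 7.10), p 1
  expect_equal(exp(qnorm(0.975)), 7.10, tolerance = 1e-3)
  expect_error(extract_effect(f, "missing_term"), "not in the fit")
})

test_that("profile CIs bracket the Wald interval sensibly", {
  skip_if_not_installed("MASS")
  set.seed(77)
  n <- 150
  X <- cbind(g = rbinom(n, 1, 0.5))
  y <- rowSums(outer(1.2 * X[, 1] + rlogis(n), c(-1, 0, 1), ">"))
  f <- fit_proportional_odds(y, X)
  eff <- extract_effect(f, "g", ci_method = "profile")
  m <- MASS::polr(factor(y, ordered = TRUE) ~ g, data = data.frame(X),
                  Hess = TRUE)
  ci <- suppressWarnings(suppressMessages(exp(confint(m))))
  expect_equal(eff$ci_low, unname(ci[1]), tolerance = 1e-2)
  expect_equal(eff$ci_high, unname(ci[2]), tolerance = 1e-2)
})

test_that("pseudo_r2 follows the Nagelkerke and McFadden formulas", {
  set.seed(78)
  n <- 200
  X <- cbind(x = rnorm(n))
  y <- rowSums(outer(X[, 1] + rlogis(n), c(-1, 1), ">"))
  f1 <- fit_proportional_odds(y, X)
  f0 <- wmhnet:::fit_po_null(y)
  r2 <- pseudo_r2(f1, f0)
  ll1 <- f1$logLik; ll0 <- f0$logLik
  expect_equal(r2, (1 - exp(2 / n * (ll0 - ll1))) / (1 - exp(2 / n * ll0)))
  expect_equal(pseudo_r2(f1, f0, method = "mcfadden"), 1 - ll1 / ll0)
  expect_equal(pseudo_r2(f0, f0), 0)
  expect_gt(r2, 0)
  expect_error(pseudo_r2(f0, f1), "nested")
})

test_that("recovery: estimates land within 3 SE of the truth at n = 500", {
  set.seed(79)
  n <- 500
  X <- cbind(g = rbinom(n, 1, 0.5), z = rnorm(n))
  y <- rowSums(outer(X %*% c(1, 0.3) + rlogis(n),
                     seq(-1.5, 1.5, length.out = 4), ">"))
  f <- fit_proportional_odds(y, X)
  se <- sqrt(f$vcov["g", "g"])
  expect_lt(abs(f$coefficients[["g"]] - 1), 3 * se)
})

test_that("fdr_adjust implements BH step-up exactly", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_adjust(c(0.5, NA, 0.01)), c(0.5, NA, 0.02))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(80)
  for (rep in 1:20) {
    p <- runif(sample(1:40, 1))
    expect_equal(fdr_adjust(p), oracle_bh(p))
    expect_equal(fdr_adjust(p), stats::p.adjust(p, "BH"))
    expect_true(all(fdr_adjust(p) >= p))
  }
})

make_model_cohort <- function(seed = 81, n = 60) {
  cfg <- simulation_config(beta_disconnect = 1.5, seed = seed)
  simulate_outcome_cohort(n, cfg, seed = seed)
}

test_that("run_region_models fits, adjusts and survives bad regions", {
  set.seed(82)
  d <- make_model_cohort()
  n <- nrow(d)
  chaco <- cbind(d$chaco_cont,
                 stats::rbeta(n, 2, 5),
                 rep(0.4, n),                  # constant: dichotomize error
                 stats::rbeta(n, 2, 5))
  res <- run_region_models(chaco, d, 1:4)
  expect_equal(nrow(res), 4)
  expect_equal(res$status[3] == "ok", FALSE)
  expect_true(all(res$status[c(1, 2, 4)] == "ok"))
  ok <- res$status == "ok"
  expect_true(all(res$p_fdr[ok] >= res$p_raw[ok]))
  expect_true(all(res$ci_low[ok] <= res$or[ok] & res$or[ok] <= res$ci_high[ok]))
  expect_true(all(res$r2_gain[ok] >= -1e-8))
  expect_equal(res$r2_gain[ok], res$r2_full[ok] - res$r2_base[ok])
  expect_equal(res$n_low[1] + res$n_high[1], n)
  # the FDR family excludes the failed region
  expect_equal(attr(res, "meta")$n_tested, 3)
  expect_equal(res$p_fdr[ok], fdr_adjust(res$p_raw[ok]))
  # residualized covariates are exactly orthogonal to the region ChaCo
  r_age <- residualize(d$age, d$chaco_cont)
  expect_lt(abs(sum(r_age * (d$chaco_cont - mean(d$chaco_cont)))), 1e-8)
})

test_that("the global-ChaCo base-model variant runs and differs", {
  d <- make_model_cohort(83)
  chaco <- cbind(d$chaco_cont, stats::rbeta(nrow(d), 2, 5))
  r1 <- run_region_models(chaco, d, 1:2, base_adjust = "wmh_volume")
  r2 <- run_region_models(chaco, d, 1:2, base_adjust = "global_chaco")
  expect_true(all(r1$status == "ok") && all(r2$status == "ok"))
  expect_false(isTRUE(all.equal(r1$or, r2$or)))
  expect_equal(attr(r2, "meta")$base_adjust, "global_chaco")
})
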