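test_that("Gauss-Hermite rule reproduces known nodes and exact moments", {
  r2 <- gh_rule(2)
  expect_equal(r2$nodes, c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(r2$weights, rep(sqrt(pi) / 2, 2), tolerance = 1e-12)
  for (n in c(7, 15, 31)) {
    r <- gh_rule(n)
    expect_equal(sum(r$weights), sqrt(pi), tolerance = 1e-10)          # m0
    expect_equal(sum(r$weights * r$nodes^2), sqrt(pi) / 2, tolerance = 1e-10)
    expect_equal(sum(r$weights * r$nodes^4), 3 * sqrt(pi) / 4, tolerance = 1e-9)
  }
})

test_that("marginal log-likelihood matches brute-force integration", {
  cnt <- tiny_counts()
  pts <- list(c(-3.2, 0.4, log(0.3)),
              c(-2.8, -0.5, log(0.8)),
              c(-3.0, 0.0, log(0.05)))
  for (p in pts) {
    expect_equal(mvcl_marginal_loglik(p[1], p[2], p[3], cnt),
                 brute_marginal_loglik(p[1], p[2], p[3], cnt),
                 tolerance = 1e-6)
  }
  expect_error(mvcl_marginal_loglik(NaN, 0, 0, cnt), "finite")
})

test_that("sigma_u -> 0 collapses to the pooled binomial-logistic likelihood", {
  cnt <- tiny_counts()
  a0 <- -3.1; th <- 0.4
  eta_t <- a0 + th; eta_c <- a0
  pooled <- sum(cnt$a) * eta_t - sum(cnt$a + cnt$b) * log1p(exp(eta_t)) +
    sum(cnt$c) * eta_c - sum(cnt$c + cnt$d) * log1p(exp(eta_c))
  expect_equal(mvcl_marginal_loglik(a0, th, log(1e-7), cnt), pooled,
               tolerance = 1e-8)
})

test_that("quadrature refinement converges monotonically", {
  cnt <- tiny_counts()
  p <- c(-3.1, 0.4, log(0.6))
  ll <- vapply(c(7L, 15L, 31L), function(q)
    mvcl_marginal_loglik(p[1], p[2], p[3], cnt, n_quad = q), numeric(1))
  expect_gte(abs(ll[1] - ll[2]), abs(ll[2] - ll[3]) - 1e-12)
  expect_lt(abs(ll[2] - ll[3]), 1e-6)
})

test_that("aggregated and Bernoulli-expanded likelihoods agree exactly", {
  cnt <- tiny_counts()
  for (p in list(c(-3.2, 0.4, log(0.3)), c(-2.9, -0.2, log(0.7)))) {
    expect_equal(mvcl_marginal_loglik(p[1], p[2], p[3], cnt),
                 brute_marginal_loglik_ipd(p[1], p[2], p[3], cnt),
                 tolerance = 1e-8)
  }
})

test_that("MVCL fit recovers closed forms on degenerate designs", {
  # exchangeable arms: theta is exactly zero
  sym <- data.frame(a = c(3, 1, 2), b = c(57, 59, 58),
                    c = c(3, 1, 2), d = c(57, 59, 58))
  f <- fit_mvcl(sym)
  expect_true(f$converged)
  expect_lt(abs(f$theta), 1e-6)

  # single study with sigma_u fixed at zero: ordinary logistic MLE = log(ad/bc)
  f1 <- fit_mvcl(data.frame(a = 10, b = 30, c = 5, d = 35), fix_sigma_u = 0)
  expect_equal(f1$theta, log(10 * 35 / (30 * 5)), tolerance = 1e-5)
  expect_identical(f1$sigma_u2, 0)

  # all-zero events: not estimable
  f0 <- fit_mvcl(data.frame(a = c(0, 0), b = c(50, 50), c = c(0, 0), d = c(50, 50)))
  expect_false(f0$estimable)
})

test_that("fit is a stationary point: nudging any parameter lowers the likelihood", {
  sc <- scenario(pc = 0.05, or_true = 2, tau = 0.3, m = 10, rule_k = 3,
                 scenario_id = 1)
  ms <- simulate_meta_sample(sc, seed = 99)
  f <- fit_mvcl(ms)
  expect_true(f$converged)
  ls <- if (f$sigma_u2 > 0) log(sqrt(f$sigma_u2)) else -6
  ll0 <- mvcl_marginal_loglik(f$alpha0, f$theta, ls, ms$counts)
  expect_equal(ll0, f$loglik, tolerance = 1e-8)
  for (delta in c(-0.01, 0.01)) {
    expect_lt(mvcl_marginal_loglik(f$alpha0 + delta, f$theta, ls, ms$counts), ll0)
    expect_lt(mvcl_marginal_loglik(f$alpha0, f$theta + delta, ls, ms$counts), ll0)
  }
  if (f$sigma_u2 > 0) {
    for (delta in c(-0.01, 0.01)) {
      expect_lt(mvcl_marginal_loglik(f$alpha0, f$theta, ls + delta, ms$counts), ll0)
    }
  }
})

test_that("MVCL fit agrees with the lme4 adaptive-quadrature oracle", {
  library(lme4)
  sc <- scenario(pc = 0.05, or_true = 2, tau = 0.3, m = 10, rule_k = 3,
                 scenario_id = 1)
  for (rep in 1:3) {
    ms <- simulate_meta_sample(sc, replicate_id = rep, seed = 99)
    f <- fit_mvcl(ms)
    d <- ms$counts
    df <- data.frame(study = factor(rep(d$study, 2)),
                     x = rep(c(1, 0), each = nrow(d)),
                     ev = c(d$a, d$c), ne = c(d$b, d$d))
    g <- suppressMessages(suppressWarnings(
      glmer(cbind(ev, ne) ~ x + (1 | study), data = df,
            family = binomial, nAGQ = 25)))
    expect_equal(f$theta, unname(fixef(g)["x"]), tolerance = 1e-3)
    expect_equal(f$se_theta, sqrt(vcov(g)["x", "x"]), tolerance = 1e-3)
    expect_equal(f$sigma_u2, unname(as.numeric(VarCorr(g)$study)),
                 tolerance = 2e-3)
  }
})

test_that("theta is recovered within Monte-Carlo error at large m and n", {
  sc <- scenario(pc = 0.05, or_true = 2, tau = 0.1, m = 200, n_control = 2000,
                 scenario_id = 99)
  ms <- simulate_meta_sample(sc, seed = 17)
  f <- fit_mvcl(ms)
  expect_true(f$converged)
  expect_lt(abs(f$theta - log(2)), 3 * f$se_theta)
})

test_that("latent-scale I2 follows the variance-partition formula", {
  cnt <- data.frame(a = c(6, 2), b = c(54, 58), c = c(3, 4), d = c(57, 56))
  f0 <- fit_mvcl(cnt, fix_sigma_u = 0)
  expect_identical(mvcl_i2(f0), 0)
  f1 <- fit_mvcl(cnt, fix_sigma_u = 1)
  expect_equal(mvcl_i2(f1), 1 / (1 + pi^2 / 3), tolerance = 1e-12)
  expect_equal(mvcl_i2(f1), 0.23310, tolerance = 1e-4)
  fh <- fit_mvcl(cnt, fix_sigma_u = sqrt(pi^2 / 3))
  expect_equal(mvcl_i2(fh), 0.5, tolerance = 1e-12)
})
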