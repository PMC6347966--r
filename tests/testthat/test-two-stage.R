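test_that("study effects reproduce the closed-form log-OR and variances", {
  e <- study_effect(study_counts(10, 10, 10, 10))
  expect_equal(e$theta, 0)
  expect_equal(e$var_iv, 0.4)
  expect_equal(e$var_mh, 0.4)
  expect_false(e$corrected)

  # sparse table, no zero cell: direct scalar arithmetic oracle
  e2 <- study_effect(study_counts(1, 299, 3, 297))
  expect_equal(e2$theta, log((1 * 297) / (299 * 3)), tolerance = 1e-12)
  expect_equal(e2$theta, -1.10526, tolerance = 1e-4)
  expect_equal(e2$var_iv, 1 / 1 + 1 / 299 + 1 / 3 + 1 / 297, tolerance = 1e-12)
  expect_equal(e2$var_iv, 1.34005, tolerance = 1e-4)

  # single-zero table: 0.5 added to every cell before the formulas
  e3 <- study_effect(study_counts(0, 60, 2, 58))
  expect_true(e3$corrected)
  expect_equal(e3$theta, log((0.5 * 58.5) / (60.5 * 2.5)), tolerance = 1e-12)
  expect_equal(e3$theta, -1.64305, tolerance = 1e-4)
  expect_equal(e3$var_mh, (0.5 + 60.5 + 2.5 + 58.5) / (60.5 * 2.5),
               tolerance = 1e-12)

  # double-zero tables are flagged, not corrected
  expect_false(study_effect(study_counts(0, 60, 0, 58))$usable)
  expect_false(study_effect(study_counts(60, 0, 58, 0))$usable)
})

test_that("balanced tables give identical IV and MH variances", {
  set.seed(5)
  for (i in 1:25) {
    k <- rpois(1, 10) + 1L
    e <- study_effect(study_counts(k, k, k, k))
    expect_equal(e$var_iv, e$var_mh, tolerance = 1e-12)
  }
})

test_that("DerSimonian-Laird tau2 matches a hand computation and edge cases", {
  eff <- study_effects(data.frame(a = c(5, 5), b = c(20, 20),
                                  c = c(5, 5), d = c(20, 20)))
  expect_equal(dl_tau2(eff, "iv"), 0)

  one <- study_effects(data.frame(a = 5, b = 20, c = 5, d = 20))
  expect_true(is.na(dl_tau2(one, "iv")))

  # theta = (0, 0.5, 1), sigma2 = 0.1 each:
  # w = 10, Q = 10*(0.25 + 0 + 0.25) = 5, denom = 30 - 300/30 = 20
  # => tau2 = (5 - 2)/20 = 0.15
  eff3 <- structure(
    data.frame(study = 1:3, theta = c(0, 0.5, 1),
               var_iv = 0.1, var_mh = 0.1,
               corrected = FALSE, usable = TRUE),
    class = c("effect_estimates", "data.frame"))
  expect_equal(dl_tau2(eff3, "iv"), 0.15, tolerance = 1e-12)
})

test_that("weighted pooling matches closed forms on degenerate inputs", {
  one <- study_effects(data.frame(a = 10, b = 10, c = 10, d = 10))
  p <- pool_weighted(one, "iv", "fixed")
  expect_equal(p$theta_hat, 0)
  expect_equal(p$se, sqrt(0.4), tolerance = 1e-12)
  expect_equal(p$ci_low_or, exp(-1.96 * sqrt(0.4)), tolerance = 1e-12)
  expect_equal(p$ci_high_or, exp(1.96 * sqrt(0.4)), tolerance = 1e-12)

  two <- study_effects(data.frame(a = c(3, 3), b = c(40, 40),
                                  c = c(5, 5), d = c(38, 38)))
  p2 <- pool_weighted(two, "iv", "fixed")
  expect_equal(p2$theta_hat, two$theta[1], tolerance = 1e-12)
  expect_equal(p2$se, sqrt(two$var_iv[1]) / sqrt(2), tolerance = 1e-12)

  # no usable studies
  none <- study_effects(data.frame(a = 0, b = 10, c = 0, d = 10))
  expect_false(pool_weighted(none, "iv", "fixed")$estimable)
})

test_that("pooling invariants hold over random tables", {
  for (seed in c(101, 202, 303)) {
    cnt <- random_tables(5, seed)
    eff <- study_effects(cnt)
    # independent weighted-mean oracle with W = bc/N on corrected cells
    cc <- ifelse((cnt$a == 0 | cnt$b == 0 | cnt$c == 0 | cnt$d == 0) &
                   !((cnt$a == 0 & cnt$c == 0) | (cnt$b == 0 & cnt$d == 0)),
                 0.5, 0)
    a <- cnt$a + cc; b <- cnt$b + cc; c2 <- cnt$c + cc; d <- cnt$d + cc
    w <- b * c2 / (a + b + c2 + d)
    th <- log(a * d / (b * c2))
    p_mh <- pool_weighted(eff, "mh", "fixed")
    expect_equal(p_mh$theta_hat, sum(w * th) / sum(w), tolerance = 1e-10)

    # convex-combination bound for fixed-effect pooling
    p_iv <- pool_weighted(eff, "iv", "fixed")
    usable <- eff$theta[eff$usable]
    expect_gte(p_iv$theta_hat, min(usable) - 1e-12)
    expect_lte(p_iv$theta_hat, max(usable) + 1e-12)

    # random-effects se is never smaller than fixed-effect se
    for (vk in c("iv", "mh")) {
      expect_gte(pool_weighted(eff, vk, "random")$se,
                 pool_weighted(eff, vk, "fixed")$se - 1e-12)
    }

    # with tau2 = 0 the random model equals the fixed model exactly
    hom <- study_effects(data.frame(a = rep(4, 4), b = rep(40, 4),
                                    c = rep(4, 4), d = rep(40, 4)))
    expect_equal(dl_tau2(hom, "iv"), 0)
    expect_equal(pool_weighted(hom, "iv", "random")$theta_hat,
                 pool_weighted(hom, "iv", "fixed")$theta_hat, tolerance = 1e-12)
    expect_equal(pool_weighted(hom, "iv", "random")$se,
                 pool_weighted(hom, "iv", "fixed")$se, tolerance = 1e-12)
  }
})

test_that("Peto estimator matches the hypergeometric formulas and is invariant to double-zero studies", {
  p <- pool_peto(data.frame(a = 1, b = 99, c = 1, d = 99))
  expect_equal(p$theta_hat, 0)
  expect_equal(p$or_hat, 1)
  # v = (100*100*2*198) / (200^2 * 199)
  v <- (100 * 100 * 2 * 198) / (200^2 * 199)
  expect_equal(p$se, 1 / sqrt(v), tolerance = 1e-12)
  expect_equal(v, 0.49749, tolerance = 1e-4)

  cnt <- random_tables(6, 77)
  base <- pool_peto(cnt)
  with_dz <- rbind(cnt, data.frame(study = 7:8, a = 0, b = 50, c = 0, d = 50))
  aug <- pool_peto(with_dz)
  expect_equal(aug$theta_hat, base$theta_hat, tolerance = 1e-12)
  expect_equal(aug$se, base$se, tolerance = 1e-12)

  all_dz <- data.frame(a = c(0, 0), b = c(50, 50), c = c(0, 0), d = c(50, 50))
  expect_false(pool_peto(all_dz)$estimable)
})

test_that("classical Mantel-Haenszel pooling agrees with mantelhaen.test", {
  for (seed in c(13, 29)) {
    cnt <- random_tables(6, seed, lambda = 6, size = 60L)
    arr <- array(0, dim = c(2, 2, nrow(cnt)))
    for (j in seq_len(nrow(cnt))) {
      arr[, , j] <- matrix(c(cnt$a[j], cnt$c[j], cnt$b[j], cnt$d[j]), 2, 2)
    }
    mh <- stats::mantelhaen.test(arr, correct = FALSE)
    p <- pool_mh(cnt)
    expect_equal(p$or_hat, unname(mh$estimate), tolerance = 1e-10)
  }
  # single study reduces to the raw odds ratio
  expect_equal(pool_mh(data.frame(a = 3, b = 47, c = 6, d = 44))$or_hat,
               (3 * 44) / (47 * 6), tolerance = 1e-12)
})

test_that("meta_pool routes method labels to the right estimators", {
  cnt <- random_tables(6, 41)
  expect_identical(meta_pool(cnt, "peto")$method, "peto")
  expect_equal(meta_pool(cnt, "mh_fixed")$theta_hat, pool_mh(cnt)$theta_hat)
  expect_equal(meta_pool(cnt, "iv_fixed")$theta_hat,
               pool_weighted(study_effects(cnt), "iv", "fixed")$theta_hat)
  # mh_random is the software fallback: DL inverse-variance, relabelled
  mr <- meta_pool(cnt, "mh_random")
  expect_identical(mr$method, "mh_random")
  expect_equal(mr$theta_hat,
               pool_weighted(study_effects(cnt), "iv", "random")$theta_hat)
})
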