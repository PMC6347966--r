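#' Per-study log odds ratio and its variances
#'
#' Computes each study's log odds ratio `theta = log(ad/(bc))` together with
#' the inverse-variance estimate `var_iv = 1/a + 1/b + 1/c + 1/d` and the
#' Mantel-Haenszel-style variance proxy `var_mh = N/(bc)` (whose reciprocal
#' `bc/N` is the classical MH weight). Studies with at least one zero cell
#' have `correction` (default 0.5) added to all four cells first. Double-zero
#' studies -- zero events in both arms, or zero non-events in both arms --
#' carry no information about the odds ratio and are flagged `usable = FALSE`
#' rather than corrected.
#'
#' @param counts A `meta_sample`, a data.frame of per-study cells
#'   (`a`,`b`,`c`,`d`), or a single [study_counts()].
#' @param correction Continuity correction added to every cell of a study
#'   containing a zero cell (>= 0; default 0.5).
#' @return A data.frame of class `"effect_estimates"` with one row per study:
#'   `study`, `theta`, `var_iv`, `var_mh`, `corrected`, `usable`.
#' @examples
#' study_effects(data.frame(a = 10, b = 10, c = 10, d = 10))
#' @export
study_effects <- function(counts, correction = 0.5) {
  cnt <- as_counts(counts)
  if (!is.numeric(correction) || correction < 0) {
    stop("`correction` must be >= 0", call. = FALSE)
  }
  a <- cnt$a; b <- cnt$b; c <- cnt$c; d <- cnt$d
  double_zero <- (a == 0 & c == 0) | (b == 0 & d == 0)
  has_zero <- (a == 0 | b == 0 | c == 0 | d == 0) & !double_zero
  cc <- ifelse(has_zero, correction, 0)
  a <- a + cc; b <- b + cc; c <- c + cc; d <- d + cc
  theta <- log(a * d / (b * c))
  var_iv <- 1 / a + 1 / b + 1 / c + 1 / d
  var_mh <- (a + b + c + d) / (b * c)
  usable <- !double_zero & is.finite(theta) & is.finite(var_iv) &
    var_iv > 0 & is.finite(var_mh) & var_mh > 0
  out <- data.frame(study = cnt$study, theta = theta,
                    var_iv = var_iv, var_mh = var_mh,
                    corrected = has_zero & correction > 0, usable = usable)
  out$theta[!usable] <- NA_real_
  out$var_iv[!usable] <- NA_real_
  out$var_mh[!usable] <- NA_real_
  class(out) <- c("effect_estimates", "data.frame")
  out
}

#' @rdname study_effects
#' @param study A single [study_counts()] (or anything [study_effects()]
#'   accepts with one row).
#' @export
study_effect <- function(study, correction = 0.5) {
  out <- study_effects(study, correction)
  if (nrow(out) != 1L) stop("`study` must describe a single 2x2 table", call. = FALSE)
  out
}

#' DerSimonian-Laird between-study variance
#'
#' Method-of-moments estimator: with fixed weights `w_j = 1/sigma_j^2`,
#' `Q = sum w_j (theta_j - theta_bar)^2` and
#' `tau2 = max(0, (Q - (k - 1)) / (sum w - sum w^2 / sum w))`.
#'
#' @param effects An `"effect_estimates"` data.frame from [study_effects()].
#' @param variance_kind `"iv"` or `"mh"`: which within-study variance to use.
#' @return Nonnegative `tau2`; `NA` when fewer than two usable studies.
#' @export
dl_tau2 <- function(effects, variance_kind = c("iv", "mh")) {
  variance_kind <- match.arg(variance_kind)
  eff <- effects[effects$usable, , drop = FALSE]
  if (nrow(eff) < 2L) return(NA_real_)
  v <- if (variance_kind == "iv") eff$var_iv else eff$var_mh
  w <- 1 / v
  theta_bar <- sum(w * eff$theta) / sum(w)
  q <- sum(w * (eff$theta - theta_bar)^2)
  denom <- sum(w) - sum(w^2) / sum(w)
  if (denom <= 0) return(0)
  max(0, (q - (nrow(eff) - 1)) / denom)
}

pooled_result <- function(method, theta_hat = NA_real_, se = NA_real_,
                          tau2_hat = 0, i2 = NA_real_, k_used = 0L,
                          estimable = FALSE, z = 1.96) {
  structure(
    list(method = method, theta_hat = theta_hat, se = se,
         or_hat = exp(theta_hat),
         ci_low_or = exp(theta_hat - z * se),
         ci_high_or = exp(theta_hat + z * se),
         tau2_hat = tau2_hat, i2 = i2, k_used = as.integer(k_used),
         estimable = estimable),
    class = "pooled_result")
}

#' @export
print.pooled_result <- function(x, ...) {
  if (!x$estimable) {
    cat(sprintf("[%s] not estimable (k_used = %d)\n", x$method, x$k_used))
    return(invisible(x))
  }
  cat(sprintf("[%s] OR = %.4f (95%% CI %.4f-%.4f), log-OR SE = %.4f, k = %d\n",
              x$method, x$or_hat, x$ci_low_or, x$ci_high_or, x$se, x$k_used))
  if (x$method %in% c("iv_random", "mh_random")) {
    cat(sprintf("  tau2 = %.4f, I2 = %.1f%%\n", x$tau2_hat, 100 * x$i2))
  }
  invisible(x)
}

#' Weighted two-stage pooling (inverse-variance or Mantel-Haenszel weights)
#'
#' Pools study log odds ratios with weights `W_j = 1/sigma_j^2` (fixed
#' effect) or `W_j = 1/(sigma_j^2 + tau2)` (random effects, DerSimonian-Laird
#' `tau2`). `sigma_j^2` is the IV variance or the MH proxy `N/(bc)` according
#' to `variance_kind`. The 95% CI is Wald on the log scale. `I2` is reported
#' as `tau2 / (sigma_bar^2 + tau2)` with `sigma_bar^2` the mean usable
#' within-study variance (within-study variance treated as common across
#' studies); it plays no role in the pooling itself.
#'
#' @param effects An `"effect_estimates"` data.frame from [study_effects()],
#'   or anything [study_effects()] accepts (counts are converted with the
#'   default correction).
#' @param variance_kind `"iv"` or `"mh"`.
#' @param model `"fixed"` or `"random"`.
#' @return A `"pooled_result"`: `method`, `theta_hat`, `se`, `or_hat`,
#'   `ci_low_or`, `ci_high_or`, `tau2_hat`, `i2`, `k_used`, `estimable`.
#' @examples
#' ms <- simulate_meta_sample(scenario(pc = 0.05, or_true = 2, tau = 0,
#'                                     m = 10, rule_k = 3), seed = 1)
#' pool_weighted(study_effects(ms), "iv", "random")
#' @export
pool_weighted <- function(effects, variance_kind = c("iv", "mh"),
                          model = c("fixed", "random")) {
  variance_kind <- match.arg(variance_kind)
  model <- match.arg(model)
  if (!inherits(effects, "effect_estimates")) effects <- study_effects(effects)
  method <- paste0(variance_kind, "_", model)
  eff <- effects[effects$usable, , drop = FALSE]
  k <- nrow(eff)
  if (k == 0L || (model == "random" && k < 2L)) {
    return(pooled_result(method, k_used = k, estimable = FALSE))
  }
  v <- if (variance_kind == "iv") eff$var_iv else eff$var_mh
  tau2 <- 0
  if (model == "random") tau2 <- dl_tau2(effects, variance_kind)
  w <- 1 / (v + tau2)
  theta_hat <- sum(w * eff$theta) / sum(w)
  se <- sqrt(1 / sum(w))
  i2 <- if (k >= 2L) {
    t2 <- if (model == "random") tau2 else dl_tau2(effects, variance_kind)
    t2 / (mean(v) + t2)
  } else NA_real_
  pooled_result(method, theta_hat = theta_hat, se = se,
                tau2_hat = tau2, i2 = i2, k_used = k, estimable = TRUE)
}

#' Classical Mantel-Haenszel pooled odds ratio
#'
#' The fixed-effect Mantel-Haenszel estimator as implemented in standard
#' meta-analysis software: `OR_MH = sum(a_j d_j / N_j) / sum(b_j c_j / N_j)`,
#' with the Robins-Breslow-Greenland variance for `log(OR_MH)`. No
#' continuity correction is needed -- single-zero studies contribute to one
#' of the sums and double-zero studies contribute nothing, so the estimate
#' is defined whenever at least one study has a discordant pair.
#'
#' This is the estimator behind the `"mh_fixed"` method label. It is *not*
#' the weighted mean of study log odds ratios with weights `bc/N` that the
#' variance proxy `N/(bc)` would suggest (that mean is available through
#' [pool_weighted()] with `variance_kind = "mh"`); the proxy-weighted mean
#' is severely biased toward the null for rare events because the weight is
#' dominated by the control-arm event count.
#'
#' @param studies A `meta_sample` or data.frame of per-study cells.
#' @return A `"pooled_result"` with `method = "mh_fixed"`.
#' @references Robins J, Breslow N, Greenland S (1986). Estimators of the
#'   Mantel-Haenszel variance consistent in both sparse data and
#'   large-strata limiting models. *Biometrics* 42, 311-323.
#' @export
pool_mh <- function(studies) {
  cnt <- as_counts(studies)
  a <- as.double(cnt$a); b <- as.double(cnt$b)
  c <- as.double(cnt$c); d <- as.double(cnt$d)
  n <- a + b + c + d
  rj <- a * d / n
  sj <- b * c / n
  k_used <- sum(rj > 0 | sj > 0)
  r <- sum(rj); s <- sum(sj)
  if (r == 0 || s == 0) {
    return(pooled_result("mh_fixed", k_used = as.integer(k_used),
                         estimable = FALSE))
  }
  pj <- (a + d) / n
  qj <- (b + c) / n
  var_log <- sum(pj * rj) / (2 * r^2) +
    sum(pj * sj + qj * rj) / (2 * r * s) +
    sum(qj * sj) / (2 * s^2)
  pooled_result("mh_fixed", theta_hat = log(r / s), se = sqrt(var_log),
                tau2_hat = 0, i2 = NA_real_, k_used = as.integer(k_used),
                estimable = TRUE)
}

#' Peto pooled odds ratio
#'
#' One-step estimator `theta_hat = sum(a_j - E[a_j]) / sum(v_j)` where,
#' conditional on the 2x2 margins, `E[a_j] = (a+b)(a+c)/N` and `v_j` is the
#' hypergeometric variance `(a+b)(c+d)(a+c)(b+d) / (N^2 (N-1))`. No
#' continuity correction is used; studies whose event (or non-event) margin
#' is zero have `v_j = 0` and contribute nothing, so the estimate is
#' invariant to adding double-zero studies. Fixed effect only.
#'
#' @param studies A `meta_sample` or data.frame of per-study cells.
#' @return A `"pooled_result"` with `method = "peto"`.
#' @export
pool_peto <- function(studies) {
  cnt <- as_counts(studies)
  # doubles: the hypergeometric variance product overflows integer range
  a <- as.double(cnt$a); b <- as.double(cnt$b)
  c <- as.double(cnt$c); d <- as.double(cnt$d)
  n <- a + b + c + d
  e_a <- (a + b) * (a + c) / n
  v <- (a + b) * (c + d) * (a + c) * (b + d) / (n^2 * (n - 1))
  v[!is.finite(v)] <- 0
  keep <- v > 0
  if (!any(keep)) {
    return(pooled_result("peto", k_used = 0L, estimable = FALSE))
  }
  sv <- sum(v[keep])
  theta_hat <- sum((a - e_a)[keep]) / sv
  pooled_result("peto", theta_hat = theta_hat, se = 1 / sqrt(sv),
                tau2_hat = 0, i2 = NA_real_, k_used = sum(keep),
                estimable = TRUE)
}

#' Pool a meta-analysis sample with any of the six methods
#'
#' Dispatcher over the five two-stage estimators and the one-stage MVCL fit.
#' `"iv_fixed"`/`"iv_random"` are inverse-variance pooling via
#' [pool_weighted()]; `"mh_fixed"` is the classical Mantel-Haenszel
#' ratio-of-sums estimator ([pool_mh()]); `"mh_random"` follows the standard
#' software convention for a random-effects Mantel-Haenszel analysis and
#' falls back to DerSimonian-Laird inverse-variance pooling (relabelled);
#' `"peto"` is [pool_peto()]; `"one_stage"` is [fit_mvcl()].
#'
#' @param counts A `meta_sample` or per-study counts data.frame.
#' @param method One of `"one_stage"`, `"iv_fixed"`, `"iv_random"`,
#'   `"mh_fixed"`, `"mh_random"`, `"peto"`.
#' @param correction Continuity correction for the IV-based paths.
#' @param ... Further arguments passed to [fit_mvcl()] for
#'   `method = "one_stage"`.
#' @return A `"pooled_result"`.
#' @export
meta_pool <- function(counts, method = c("one_stage", "iv_fixed", "iv_random",
                                         "mh_fixed", "mh_random", "peto"),
                      correction = 0.5, ...) {
  method <- match.arg(method)
  if (method == "peto") return(pool_peto(counts))
  if (method == "mh_fixed") return(pool_mh(counts))
  if (method == "one_stage") {
    fit <- fit_mvcl(counts, ...)
    return(as_pooled_result(fit))
  }
  if (method == "mh_random") {
    res <- pool_weighted(study_effects(counts, correction), "iv", "random")
    res$method <- "mh_random"
    return(res)
  }
  parts <- strsplit(method, "_", fixed = TRUE)[[1]]
  pool_weighted(study_effects(counts, correction), parts[1], parts[2])
}

#' All six methods as labels
#' @return Character vector of the six method labels.
#' @export
meta_methods <- function() {
  c("one_stage", "iv_fixed", "iv_random", "mh_fixed", "mh_random", "peto")
}
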