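#' Gauss-Hermite quadrature rule
#'
#' Nodes and weights for the weight function `exp(-z^2)` computed by the
#' Golub-Welsch eigenvalue method on the Jacobi matrix of the Hermite
#' recurrence. Exact for polynomials up to degree `2n - 1`.
#'
#' @param n Number of nodes (>= 1).
#' @return List with `nodes` and `weights`, each length `n`.
#' @export
gh_rule <- function(n) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  if (n == 1L) return(list(nodes = 0, weights = sqrt(pi)))
  i <- seq_len(n - 1L)
  jac <- matrix(0, n, n)
  off <- sqrt(i / 2)
  jac[cbind(i, i + 1L)] <- off
  jac[cbind(i + 1L, i)] <- off
  e <- eigen(jac, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord],
       weights = sqrt(pi) * e$vectors[1, ord]^2)
}

# Per-study posterior modes and curvatures of the integrand
#   log g_j(u) = a log p_t + b log(1-p_t) + c log p_c + d log(1-p_c)
#               + log phi(u; 0, sigma^2)
# with p_t = plogis(alpha0 + theta + u), p_c = plogis(alpha0 + u).
# The log-integrand is strictly concave in u, so Newton from 0 converges.
mvcl_modes <- function(alpha0, theta, sigma2, cnt, iter = 25L, tol = 1e-10) {
  a <- cnt$a; b <- cnt$b; c <- cnt$c; d <- cnt$d
  nt <- a + b; nc <- c + d
  u <- numeric(length(a))
  for (it in seq_len(iter)) {
    pt <- stats::plogis(alpha0 + theta + u)
    pc_ <- stats::plogis(alpha0 + u)
    grad <- (a - nt * pt) + (c - nc * pc_) - u / sigma2
    hess <- -(nt * pt * (1 - pt) + nc * pc_ * (1 - pc_) + 1 / sigma2)
    step <- grad / hess
    u <- u - step
    if (max(abs(step)) < tol) break
  }
  pt <- stats::plogis(alpha0 + theta + u)
  pc_ <- stats::plogis(alpha0 + u)
  list(u = u, curv = nt * pt * (1 - pt) + nc * pc_ * (1 - pc_) + 1 / sigma2)
}

# Binomial kernel on the log scale, without the n-choose-y constants. The
# constants do not involve the parameters, so dropping them leaves the MLE,
# Hessian and likelihood-ratio geometry untouched and makes the aggregated
# and Bernoulli-expanded forms of the likelihood agree exactly.
log_binom_kernel <- function(y, n, eta) {
  y * eta - n * log1p(exp(eta))
}

#' Marginal log-likelihood of the multilevel variance-component logistic model
#'
#' The model places a normal random intercept on each study's log odds:
#' arm-level counts are `Bin(n, plogis(alpha0 + theta * x + u_j))` with
#' `x = 1` for treatment, and `u_j ~ N(0, sigma_u^2)`. The study random
#' effect is integrated out with adaptive Gauss-Hermite quadrature centered
#' at each study's posterior mode and scaled by the curvature there.
#' Binomial normalizing constants are omitted (they do not depend on the
#' parameters), so the value equals the Bernoulli-expanded log-likelihood of
#' the same data exactly.
#'
#' @param alpha0 Fixed intercept on the logit scale.
#' @param theta Treatment log odds ratio.
#' @param log_sigma_u Log of the between-study SD `sigma_u`.
#' @param counts A `meta_sample` or per-study counts data.frame.
#' @param n_quad Number of quadrature nodes (>= 1; default 15).
#' @param gh Optional precomputed [gh_rule()] (saves the eigendecomposition
#'   in tight loops).
#' @return The marginal log-likelihood (a scalar).
#' @export
mvcl_marginal_loglik <- function(alpha0, theta, log_sigma_u, counts,
                                 n_quad = 15L, gh = NULL) {
  if (!all(is.finite(c(alpha0, theta, log_sigma_u)))) {
    stop("parameters must be finite", call. = FALSE)
  }
  cnt <- as_counts(counts)
  if (is.null(gh)) gh <- gh_rule(n_quad)
  sigma <- exp(log_sigma_u)
  sigma2 <- sigma^2
  md <- mvcl_modes(alpha0, theta, sigma2, cnt)
  s <- 1 / sqrt(md$curv)                      # per-study scale
  # nodes: m x q matrix of evaluation points u_jq = u_j + sqrt(2) s_j z_q
  z <- gh$nodes
  lw <- log(gh$weights) + z^2
  uq <- outer(md$u, rep(1, length(z))) + sqrt(2) * outer(s, z)
  eta_t <- alpha0 + theta + uq
  eta_c <- alpha0 + uq
  lg <- log_binom_kernel(cnt$a, cnt$a + cnt$b, eta_t) +
    log_binom_kernel(cnt$c, cnt$c + cnt$d, eta_c) +
    stats::dnorm(uq, 0, sigma, log = TRUE)
  lg <- sweep(lg, 2L, lw, "+")
  mx <- apply(lg, 1L, max)
  sum(mx + log(rowSums(exp(lg - mx))) + log(sqrt(2) * s))
}

# observed-information SE via central finite differences of the marginal
# log-likelihood; returns NA on a non-invertible or non-PD Hessian
fd_hessian <- function(f, par, h = NULL) {
  p <- length(par)
  if (is.null(h)) h <- pmax(1e-4, 1e-4 * abs(par))
  hess <- matrix(NA_real_, p, p)
  f0 <- f(par)
  for (i in seq_len(p)) {
    for (j in i:p) {
      ei <- ej <- numeric(p)
      ei[i] <- h[i]; ej[j] <- h[j]
      if (i == j) {
        hess[i, i] <- (f(par + ei) - 2 * f0 + f(par - ei)) / h[i]^2
      } else {
        hess[i, j] <- hess[j, i] <-
          (f(par + ei + ej) - f(par + ei - ej) -
             f(par - ei + ej) + f(par - ei - ej)) / (4 * h[i] * h[j])
      }
    }
  }
  hess
}

#' Fit the one-stage multilevel variance-component logistic model
#'
#' Maximizes the marginal likelihood of [mvcl_marginal_loglik()] over
#' `(alpha0, theta, log sigma_u)` with `L-BFGS-B`, falling back to a
#' Nelder-Mead multi-start grid over `log sigma_u` when the first attempt
#' fails. Starting values are `alpha0 = qlogis(pooled event rate)`,
#' `theta` = the continuity-corrected pooled log odds ratio, and
#' `sigma_u = 0.1`. The log-OR standard error comes from the inverse
#' observed (finite-difference) Hessian at the optimum; when `sigma_u` is at
#' its lower boundary the Hessian is taken over `(alpha0, theta)` only and
#' the fit reports `sigma_u2 = 0`. Double-zero studies are retained: the
#' marginal likelihood is defined for them and they inform `alpha0` and
#' `sigma_u`.
#'
#' @param counts A `meta_sample` or per-study counts data.frame (>= 1 study
#'   with at least one event and one non-event overall).
#' @param n_quad Quadrature nodes for the adaptive Gauss-Hermite rule.
#' @param fix_sigma_u Optional: fix `sigma_u` at this value (>= 0) instead of
#'   estimating it (0 reduces the model to ordinary pooled logistic
#'   regression with a study-free intercept).
#' @return An object of class `"mvcl_fit"`: `alpha0`, `theta`, `sigma_u2`,
#'   `se_theta`, `or_hat`, `ci_low_or`, `ci_high_or`, `loglik`, `converged`,
#'   `n_quad`, `level1_variance` (`pi^2/3`), `i2`, `estimable`, `message`.
#' @examples
#' ms <- simulate_meta_sample(scenario(pc = 0.05, or_true = 2, tau = 0.1,
#'                                     m = 10, rule_k = 3), seed = 7)
#' fit_mvcl(ms)
#' @export
fit_mvcl <- function(counts, n_quad = 15L, fix_sigma_u = NULL) {
  cnt <- as_counts(counts)
  events <- sum(cnt$a + cnt$c)
  total <- sum(cnt$a + cnt$b + cnt$c + cnt$d)
  if (events == 0L || events == total) {
    return(structure(
      list(alpha0 = NA_real_, theta = NA_real_, sigma_u2 = NA_real_,
           se_theta = NA_real_, or_hat = NA_real_, ci_low_or = NA_real_,
           ci_high_or = NA_real_, loglik = NA_real_, converged = FALSE,
           n_quad = as.integer(n_quad), level1_variance = pi^2 / 3,
           i2 = NA_real_, estimable = FALSE,
           message = "all-zero or all-one outcomes: log odds ratio not estimable"),
      class = "mvcl_fit"))
  }
  gh <- gh_rule(n_quad)
  lb_sigma <- -6  # sigma_u ~ 0.0025: numerically indistinguishable from 0

  # starting values from the corrected two-stage summary
  eff <- study_effects(cnt, 0.5)
  theta0 <- if (any(eff$usable)) {
    w <- 1 / eff$var_iv[eff$usable]
    sum(w * eff$theta[eff$usable]) / sum(w)
  } else 0
  alpha0_start <- stats::qlogis(min(max(events / total, 1e-10), 1 - 1e-10))

  if (!is.null(fix_sigma_u)) {
    stopifnot(is.numeric(fix_sigma_u), fix_sigma_u >= 0)
    ls_fix <- if (fix_sigma_u <= exp(lb_sigma)) lb_sigma else log(fix_sigma_u)
    negll <- function(p) -mvcl_marginal_loglik(p[1], p[2], ls_fix, cnt,
                                               gh = gh)
    opt <- stats::optim(c(alpha0_start, theta0), negll, method = "L-BFGS-B",
                        lower = c(-35, -15), upper = c(15, 15),
                        control = list(maxit = 500L, factr = 1e2, pgtol = 1e-10))
    par <- c(opt$par, ls_fix)
    conv <- opt$convergence == 0L
    at_boundary <- fix_sigma_u <= exp(lb_sigma)
  } else {
    negll3 <- function(p) -mvcl_marginal_loglik(p[1], p[2], p[3], cnt,
                                                gh = gh)
    starts <- list(c(alpha0_start, theta0, log(0.1)),
                   c(alpha0_start, theta0, log(0.01)),
                   c(alpha0_start, theta0, log(0.5)),
                   c(alpha0_start, theta0, log(1)))
    opt <- NULL
    for (st in starts) {
      cand <- tryCatch(
        stats::optim(st, negll3, method = "L-BFGS-B",
                     lower = c(-35, -15, lb_sigma), upper = c(15, 15, 3),
                     control = list(maxit = 500L, factr = 1e2, pgtol = 1e-10)),
        error = function(e) NULL)
      if (!is.null(cand) && (is.null(opt) || cand$value < opt$value - 1e-8)) {
        opt <- cand
        if (opt$convergence == 0L && identical(st, starts[[1]])) break
      }
    }
    if (is.null(opt)) {  # last resort: derivative-free
      opt <- stats::optim(starts[[1]], negll3, method = "Nelder-Mead",
                          control = list(maxit = 2000L))
      opt$par[3] <- min(max(opt$par[3], lb_sigma), 3)
    }
    par <- opt$par
    conv <- opt$convergence == 0L
    at_boundary <- par[3] <= lb_sigma + 1e-6
  }

  sigma_u2 <- if (at_boundary) 0 else exp(2 * par[3])
  loglik <- mvcl_marginal_loglik(par[1], par[2], par[3], cnt, gh = gh)

  # SE from the observed information; on a sigma boundary the 3x3 Hessian is
  # singular in the log-sigma direction, so profile to (alpha0, theta)
  se_theta <- NA_real_
  ll_par <- function(p3) mvcl_marginal_loglik(p3[1], p3[2], p3[3], cnt, gh = gh)
  hs <- tryCatch({
    if (at_boundary || !is.null(fix_sigma_u)) {
      h2 <- fd_hessian(function(p) ll_par(c(p, par[3])), par[1:2])
      solve(-h2)[2, 2]
    } else {
      h3 <- fd_hessian(ll_par, par)
      solve(-h3)[2, 2]
    }
  }, error = function(e) NA_real_)
  if (is.finite(hs) && hs > 0) se_theta <- sqrt(hs)
  conv <- conv && is.finite(se_theta)

  z <- 1.96
  structure(
    list(alpha0 = par[1], theta = par[2], sigma_u2 = sigma_u2,
         se_theta = se_theta, or_hat = exp(par[2]),
         ci_low_or = exp(par[2] - z * se_theta),
         ci_high_or = exp(par[2] + z * se_theta),
         loglik = loglik, converged = conv, n_quad = as.integer(n_quad),
         level1_variance = pi^2 / 3,
         i2 = sigma_u2 / (pi^2 / 3 + sigma_u2),
         estimable = TRUE,
         message = if (conv) "converged" else "optimizer did not converge"),
    class = "mvcl_fit")
}

#' @export
print.mvcl_fit <- function(x, ...) {
  if (!x$estimable) {
    cat("One-stage MVCL fit: not estimable --", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf(
    "One-stage MVCL fit%s\n  OR = %.4f (95%% CI %.4f-%.4f)\n  theta = %.4f (SE %.4f), alpha0 = %.4f\n  sigma_u2 = %.4f, I2 = %.1f%% (latent scale), logLik = %.3f\n",
    if (x$converged) "" else "  [NOT CONVERGED]",
    x$or_hat, x$ci_low_or, x$ci_high_or, x$theta, x$se_theta, x$alpha0,
    x$sigma_u2, 100 * x$i2, x$loglik))
  invisible(x)
}

#' Latent-scale heterogeneity statistic of an MVCL fit
#'
#' Variance partition coefficient `sigma_u^2 / (pi^2/3 + sigma_u^2)`:
#' the share of total latent variance attributable to between-study
#' variation, with the level-1 variance fixed at the logistic residual
#' variance `pi^2/3`.
#'
#' @param fit An `"mvcl_fit"` object.
#' @return A number in `[0, 1)`.
#' @export
mvcl_i2 <- function(fit) {
  stopifnot(inherits(fit, "mvcl_fit"))
  fit$sigma_u2 / (fit$level1_variance + fit$sigma_u2)
}

# view an mvcl_fit through the common pooled-result interface
as_pooled_result <- function(fit) {
  structure(
    list(method = "one_stage", theta_hat = fit$theta, se = fit$se_theta,
         or_hat = fit$or_hat, ci_low_or = fit$ci_low_or,
         ci_high_or = fit$ci_high_or, tau2_hat = fit$sigma_u2, i2 = fit$i2,
         k_used = NA_integer_, estimable = fit$estimable,
         converged = fit$converged),
    class = "pooled_result")
}
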