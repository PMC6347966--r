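# Independent oracles used across test files. These deliberately avoid the
# package's own code paths: plain trapezoid integration, scalar arithmetic
# on the printed formulas, and direct Monte Carlo.

# Brute-force marginal log-likelihood of the random-intercept binomial
# model by trapezoid integration over u in [-10 sigma, 10 sigma], using the
# same coefficient-free binomial kernel as the package.
brute_marginal_loglik <- function(alpha0, theta, log_sigma_u, cnt,
                                  n_grid = 20001L) {
  s <- exp(log_sigma_u)
  total <- 0
  for (j in seq_len(nrow(cnt))) {
    u <- seq(-10 * s, 10 * s, length.out = n_grid)
    eta_t <- alpha0 + theta + u
    eta_c <- alpha0 + u
    lg <- cnt$a[j] * eta_t - (cnt$a[j] + cnt$b[j]) * log1p(exp(eta_t)) +
      cnt$c[j] * eta_c - (cnt$c[j] + cnt$d[j]) * log1p(exp(eta_c)) +
      dnorm(u, 0, s, log = TRUE)
    mx <- max(lg)
    total <- total + mx + log(sum(exp(lg - mx)) * (u[2] - u[1]))
  }
  total
}

# Same integral evaluated on the Bernoulli expansion of the counts: one
# factor per individual record instead of one binomial factor per arm.
brute_marginal_loglik_ipd <- function(alpha0, theta, log_sigma_u, cnt,
                                      n_grid = 20001L) {
  s <- exp(log_sigma_u)
  total <- 0
  for (j in seq_len(nrow(cnt))) {
    rec <- expand_to_ipd(cnt[j, ])
    u <- seq(-10 * s, 10 * s, length.out = n_grid)
    lg <- dnorm(u, 0, s, log = TRUE)
    for (i in seq_len(nrow(rec))) {
      eta <- alpha0 + theta * rec$x[i] + u
      lg <- lg + rec$y[i] * eta - log1p(exp(eta))
    }
    mx <- max(lg)
    total <- total + mx + log(sum(exp(lg - mx)) * (u[2] - u[1]))
  }
  total
}

# small fixed meta-analysis with sparse counts, used by several files
tiny_counts <- function() {
  data.frame(study = 1:3,
             a = c(2L, 0L, 1L), b = c(58L, 60L, 59L),
             c = c(1L, 2L, 0L), d = c(59L, 58L, 60L))
}

random_tables <- function(n, seed, lambda = 4, size = 50L) {
  set.seed(seed)
  data.frame(study = seq_len(n),
             a = rpois(n, lambda), b = size, c = rpois(n, lambda), d = size)
}
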