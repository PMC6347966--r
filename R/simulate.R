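#' A single trial's 2x2 table
#'
#' Cell layout is fixed package-wide as `a` = events in the treatment arm,
#' `b` = non-events in the treatment arm, `c` = events in the control arm,
#' `d` = non-events in the control arm, so that the odds ratio is
#' `ad / (bc)`.
#'
#' @param a,b,c,d Nonnegative integer cell counts; each arm must contain at
#'   least one subject.
#' @return An object of class `"study_counts"`.
#' @examples
#' study_counts(1, 299, 3, 297)
#' @export
study_counts <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("cells must be nonnegative integers", call. = FALSE)
  }
  if (a + b < 1) stop("treatment arm is empty (a + b must be >= 1)", call. = FALSE)
  if (c + d < 1) stop("control arm is empty (c + d must be >= 1)", call. = FALSE)
  structure(list(a = as.integer(a), b = as.integer(b),
                 c = as.integer(c), d = as.integer(d)),
            class = "study_counts")
}

# Deterministic per-replicate seed derived from (seed, scenario_id,
# replicate_id); kept below 2^31 - 1 so it is a valid R integer. Doubles are
# exact here: intermediate products stay below 2^48.
substream_seed <- function(seed, scenario_id, replicate_id) {
  m <- 2147483647
  s <- as.double(seed) %% m
  sid <- ifelse(is.na(scenario_id), 0, as.double(scenario_id))
  s <- (s * 69069 + sid * 1009 + 1) %% m
  s <- (s * 69069 + as.double(replicate_id)) %% m
  as.integer(s)
}

#' Simulate one trial's 2x2 table
#'
#' Draws a study-level random effect `u ~ N(0, tau^2)` and binomial event
#' counts for the two arms. Under the default `heterogeneity = "treatment"`
#' the control arm has event probability `pc` and the treatment arm
#' `plogis(qlogis(pc) + log(or_true) + u)`: the study-specific true log odds
#' ratio is `log(or_true) + u`, i.e. heterogeneity acts on the effect, which
#' is the standard random-effects reading `theta_j ~ N(theta, tau^2)`.
#' `heterogeneity = "shared"` instead places `u` on the intercept of both
#' arms (`plogis(qlogis(pc) + u)` vs `plogis(qlogis(pc) + u + log(or_true))`),
#' so every study shares the same true odds ratio; this is the exact
#' data-generating model assumed by [fit_mvcl()].
#'
#' @param scen A [scenario()].
#' @param heterogeneity `"treatment"` (default) or `"shared"`; see Details.
#' @return A list with elements `study` (a [study_counts()]) and `u` (the
#'   realized study random effect).
#' @export
simulate_study <- function(scen, heterogeneity = c("treatment", "shared")) {
  stopifnot(inherits(scen, "scenario"))
  heterogeneity <- match.arg(heterogeneity)
  u <- stats::rnorm(1L, 0, scen$tau)
  lp <- stats::qlogis(scen$pc)
  if (heterogeneity == "treatment") {
    p_c <- scen$pc
    p_t <- stats::plogis(lp + log(scen$or_true) + u)
  } else {
    p_c <- stats::plogis(lp + u)
    p_t <- stats::plogis(lp + u + log(scen$or_true))
  }
  c_ev <- stats::rbinom(1L, scen$n_control, p_c)
  a_ev <- stats::rbinom(1L, scen$n_treat, p_t)
  list(study = study_counts(a_ev, scen$n_treat - a_ev,
                            c_ev, scen$n_control - c_ev),
       u = u)
}

#' Simulate one meta-analysis data set
#'
#' Generates `scen$m` independent studies from the hierarchical binomial
#' model described in [simulate_study()]. When `seed` is supplied the
#' replicate is drawn from a deterministic substream keyed by
#' `(seed, scenario_id, replicate_id)`, so any replicate of any scenario can
#' be regenerated independently and in parallel.
#'
#' @param scen A [scenario()].
#' @param replicate_id Integer replicate label (>= 1).
#' @param seed Optional master seed; if `NULL`, the current RNG state is used.
#' @param heterogeneity Passed to [simulate_study()].
#' @return An object of class `"meta_sample"`: a list with `scenario`,
#'   `counts` (data.frame with columns `study`, `a`, `b`, `c`, `d`),
#'   `u` (realized study effects), `replicate_id` and `seed_used`.
#' @examples
#' s <- scenario(pc = 0.05, or_true = 1.25, tau = 0.1, m = 10, rule_k = 3,
#'               scenario_id = 1)
#' ms <- simulate_meta_sample(s, replicate_id = 1, seed = 42)
#' ms$counts
#' @export
simulate_meta_sample <- function(scen, replicate_id = 1L, seed = NULL,
                                 heterogeneity = c("treatment", "shared")) {
  stopifnot(inherits(scen, "scenario"))
  heterogeneity <- match.arg(heterogeneity)
  seed_used <- NA_integer_
  if (!is.null(seed)) {
    seed_used <- substream_seed(seed, scen$scenario_id, replicate_id)
    set.seed(seed_used)
  }
  # vectorized draw across the m studies
  u <- stats::rnorm(scen$m, 0, scen$tau)
  lp <- stats::qlogis(scen$pc)
  if (heterogeneity == "treatment") {
    p_c <- rep(scen$pc, scen$m)
    p_t <- stats::plogis(lp + log(scen$or_true) + u)
  } else {
    p_c <- stats::plogis(lp + u)
    p_t <- stats::plogis(lp + u + log(scen$or_true))
  }
  c_ev <- stats::rbinom(scen$m, scen$n_control, p_c)
  a_ev <- stats::rbinom(scen$m, scen$n_treat, p_t)
  counts <- data.frame(study = seq_len(scen$m),
                       a = a_ev, b = scen$n_treat - a_ev,
                       c = c_ev, d = scen$n_control - c_ev)
  structure(list(scenario = scen, counts = counts, u = u,
                 replicate_id = as.integer(replicate_id),
                 seed_used = seed_used),
            class = "meta_sample")
}

#' @export
print.meta_sample <- function(x, ...) {
  cat(sprintf("Meta-analysis sample: %d studies (replicate %d)\n",
              nrow(x$counts), x$replicate_id))
  print(x$counts)
  invisible(x)
}

#' Expand a 2x2 table to individual participant records
#'
#' Bridges the aggregated and individual-level formulations of the binomial
#' likelihood: the returned records, tabulated, recover the table exactly.
#' Order is deterministic: treatment arm first (events before non-events),
#' then control arm.
#'
#' @param study A [study_counts()] object or a list/one-row data.frame with
#'   elements `a`, `b`, `c`, `d`.
#' @return A data.frame with `a+b+c+d` rows and columns `x` (1 = treatment)
#'   and `y` (1 = event).
#' @export
expand_to_ipd <- function(study) {
  s <- study_counts(study$a, study$b, study$c, study$d)
  data.frame(
    x = rep(c(1L, 0L), c(s$a + s$b, s$c + s$d)),
    y = c(rep(c(1L, 0L), c(s$a, s$b)), rep(c(1L, 0L), c(s$c, s$d)))
  )
}

# Normalize the various count containers (meta_sample, a/b/c/d data frame,
# or the external CSV schema) to a data.frame with columns study, a, b, c, d.
as_counts <- function(x) {
  if (inherits(x, "meta_sample")) return(x$counts)
  if (inherits(x, "study_counts")) {
    return(data.frame(study = 1L, a = x$a, b = x$b, c = x$c, d = x$d))
  }
  x <- as.data.frame(x)
  if (all(c("a", "b", "c", "d") %in% names(x))) {
    if (is.null(x$study)) x$study <- seq_len(nrow(x))
    return(x[, c("study", "a", "b", "c", "d")])
  }
  ext <- c("n_treat", "events_treat", "n_control", "events_control")
  if (all(ext %in% names(x))) {
    out <- data.frame(
      study = if (is.null(x$study)) seq_len(nrow(x)) else x$study,
      a = x$events_treat, b = x$n_treat - x$events_treat,
      c = x$events_control, d = x$n_control - x$events_control)
    return(out)
  }
  stop("cannot interpret `x` as per-study 2x2 counts", call. = FALSE)
}

#' Read and write per-study counts as CSV
#'
#' The on-disk schema has one row per study with columns `study`, `n_treat`,
#' `events_treat`, `n_control`, `events_control`.
#'
#' @param x A `meta_sample` or a data.frame of counts (columns `a`,`b`,`c`,`d`
#'   or the CSV schema).
#' @param path File path.
#' @return `read_counts_csv()` returns a data.frame with columns `study`,
#'   `a`, `b`, `c`, `d`; `write_counts_csv()` returns `path` invisibly.
#' @export
write_counts_csv <- function(x, path) {
  cnt <- as_counts(x)
  out <- data.frame(study = cnt$study,
                    n_treat = cnt$a + cnt$b, events_treat = cnt$a,
                    n_control = cnt$c + cnt$d, events_control = cnt$c)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_csv
#' @export
read_counts_csv <- function(path) {
  as_counts(utils::read.csv(path))
}

#' Export a meta-analysis sample as individual participant records
#'
#' One row per subject with columns `study`, `arm` (1 = treatment) and `y`
#' (1 = event), the long format of [expand_to_ipd()] across studies.
#'
#' @inheritParams write_counts_csv
#' @return `path`, invisibly.
#' @export
write_ipd_csv <- function(x, path) {
  cnt <- as_counts(x)
  rows <- lapply(seq_len(nrow(cnt)), function(j) {
    rec <- expand_to_ipd(cnt[j, ])
    data.frame(study = cnt$study[j], arm = rec$x, y = rec$y)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
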