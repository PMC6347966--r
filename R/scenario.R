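#' Control-arm sample size under the rule of k
#'
#' The "rule of three" chooses the per-arm sample size `n = 3/pc` so that a
#' trial has roughly a 95% chance of observing at least one adverse event of
#' probability `pc`; the rules of two and one use `2/pc` and `1/pc` and give
#' weaker guarantees. The expected number of control-arm events equals `rule_k`
#' by construction.
#'
#' @param pc Control-arm event probability, in (0, 1).
#' @param rule_k Integer 1, 2 or 3: the expected number of control-arm events.
#' @return Positive integer control-arm sample size, `round(rule_k / pc)`.
#' @examples
#' sample_size_for_rule(0.01, 3)   # 300
#' sample_size_for_rule(0.05, 1)   # 20
#' @export
sample_size_for_rule <- function(pc, rule_k) {
  if (!is.numeric(pc) || any(pc <= 0) || any(pc >= 1)) {
    stop("`pc` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!is.numeric(rule_k) || any(!rule_k %in% c(1L, 2L, 3L))) {
    stop("`rule_k` must be 1, 2 or 3", call. = FALSE)
  }
  as.integer(round(rule_k / pc))
}

#' Define a simulation scenario
#'
#' A scenario bundles the six parameters that drive the trial simulator:
#' control-arm incidence `pc`, true odds ratio `or_true`, between-study
#' standard deviation `tau` on the log-odds-ratio scale, number of studies `m`
#' per meta-analysis, treatment:control allocation ratio `r`, and the
#' control-arm size -- given either directly as `n_control` or through a
#' rule-of-k sample-size rule (`rule_k`).
#'
#' @param pc Control-arm event probability, in (0, 1).
#' @param or_true True odds ratio (> 0) for the adverse event.
#' @param tau Between-study SD of the true study log odds ratios (>= 0).
#' @param m Number of studies per meta-analysis (>= 1).
#' @param r Treatment:control sample-size ratio (> 0); the treatment arm gets
#'   `round(r * n_control)` subjects.
#' @param rule_k Optional rule-of-k selector in \{1, 2, 3\}; sets
#'   `n_control = round(rule_k / pc)`. Exactly one of `rule_k` and
#'   `n_control` must be supplied.
#' @param n_control Optional explicit control-arm size (>= 1).
#' @param scenario_id Integer label carried through records and summaries.
#' @return An object of class `"scenario"`: a list with elements
#'   `scenario_id`, `pc`, `or_true`, `tau`, `m`, `r`, `rule_k` (or `NA`),
#'   `n_control`, `n_treat`.
#' @seealso [sample_size_for_rule()], [build_scenario_grid()]
#' @examples
#' scenario(pc = 0.05, or_true = 1.25, tau = 0.1, m = 10, rule_k = 3)
#' @export
scenario <- function(pc, or_true = 1, tau = 0, m = 10L, r = 1,
                     rule_k = NULL, n_control = NULL,
                     scenario_id = NA_integer_) {
  stopifnot(is.numeric(pc), length(pc) == 1L)
  if (pc <= 0 || pc >= 1) stop("`pc` must lie strictly between 0 and 1", call. = FALSE)
  if (!is.numeric(or_true) || or_true <= 0) stop("`or_true` must be > 0", call. = FALSE)
  if (!is.numeric(tau) || tau < 0) stop("`tau` must be >= 0", call. = FALSE)
  if (!is.numeric(m) || m < 1 || m != round(m)) stop("`m` must be a positive integer", call. = FALSE)
  if (!is.numeric(r) || r <= 0) stop("`r` must be > 0", call. = FALSE)
  if (is.null(rule_k) == is.null(n_control)) {
    stop("supply exactly one of `rule_k` and `n_control`", call. = FALSE)
  }
  if (!is.null(rule_k)) {
    n_control <- sample_size_for_rule(pc, rule_k)
  } else {
    if (!is.numeric(n_control) || n_control < 1 || n_control != round(n_control)) {
      stop("`n_control` must be a positive integer", call. = FALSE)
    }
    n_control <- as.integer(n_control)
    rule_k <- NA_integer_
  }
  n_treat <- as.integer(round(r * n_control))
  if (n_treat < 1) stop("`r * n_control` rounds to zero subjects", call. = FALSE)
  structure(
    list(scenario_id = as.integer(scenario_id), pc = pc, or_true = or_true,
         tau = tau, m = as.integer(m), r = r, rule_k = as.integer(rule_k),
         n_control = n_control, n_treat = n_treat),
    class = "scenario"
  )
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf(
    "Scenario %s: pc=%g, OR=%g, tau=%g, m=%d, r=%g, n_control=%d, n_treat=%d%s\n",
    ifelse(is.na(x$scenario_id), "<unlabelled>", x$scenario_id),
    x$pc, x$or_true, x$tau, x$m, x$r, x$n_control, x$n_treat,
    ifelse(is.na(x$rule_k), "", sprintf(" (rule of %d)", x$rule_k))
  ))
  invisible(x)
}

#' The 52-scenario evaluation grid
#'
#' Enumerates the full factorial study design used by the package's
#' simulation experiments: scenarios 1-12 vary the sample-size rule
#' (three/two/one) over four incidence rates at OR = 1.25, tau = 0.1, m = 10;
#' 13-28 vary the odds ratio (1, 1.25, 2, 5) under the rule of three;
#' 29-40 vary heterogeneity (tau = 0.1, 0.5, 1); 41-52 vary the number of
#' studies (m = 5, 10, 15). The allocation ratio is 1 throughout.
#'
#' @return A list of 52 [scenario()] objects with `scenario_id` 1 to 52.
#' @examples
#' grid <- build_scenario_grid()
#' length(grid)         # 52
#' grid[[4]]            # pc = 0.01, n = 300, OR = 1.25, tau = 0.1, m = 10
#' @export
build_scenario_grid <- function() {
  pcs <- c(0.05, 0.01, 0.001, 0.0001)
  out <- vector("list", 52L)
  id <- 0L
  add <- function(pc, or_true, tau, m, rule_k) {
    id <<- id + 1L
    out[[id]] <<- scenario(pc = pc, or_true = or_true, tau = tau, m = m,
                           r = 1, rule_k = rule_k, scenario_id = id)
  }
  # 1-12: rules of three/two/one at each incidence
  for (pc in pcs) for (k in c(3L, 2L, 1L)) add(pc, 1.25, 0.1, 10L, k)
  # 13-28: odds ratios 1/1.25/2/5 under the rule of three
  for (pc in pcs) for (or in c(1, 1.25, 2, 5)) add(pc, or, 0.1, 10L, 3L)
  # 29-40: heterogeneity 0.1/0.5/1 under the rule of three
  for (pc in pcs) for (tau in c(0.1, 0.5, 1)) add(pc, 1.25, tau, 10L, 3L)
  # 41-52: m = 5/10/15 under the rule of three
  for (pc in pcs) for (m in c(5L, 10L, 15L)) add(pc, 1.25, 0.1, m, 3L)
  stopifnot(id == 52L)
  out
}

#' Read scenarios and run settings from a JSON configuration file
#'
#' The file holds either a single object or an array of objects, each with
#' keys `pc`, `or_true`, `tau`, `m`, `r` and one of `rule_k` / `n_control`
#' (plus optional `scenario_id`); top-level keys `reps` and `seed`, when
#' present on a single wrapping object alongside `scenarios`, are returned
#' too.
#'
#' @param path Path to a JSON file.
#' @return A list with `scenarios` (list of [scenario()] objects) and, when
#'   present, `reps` and `seed`.
#' @export
read_scenario_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  has_names <- !is.null(names(cfg))
  entries <- if (has_names && !is.null(cfg$scenarios)) cfg$scenarios
             else if (has_names) list(cfg) else cfg
  scens <- lapply(entries, function(e) {
    scenario(pc = e$pc,
             or_true = if (is.null(e$or_true)) 1 else e$or_true,
             tau = if (is.null(e$tau)) 0 else e$tau,
             m = if (is.null(e$m)) 10L else e$m,
             r = if (is.null(e$r)) 1 else e$r,
             rule_k = e$rule_k, n_control = e$n_control,
             scenario_id = if (is.null(e$scenario_id)) NA_integer_
                           else e$scenario_id)
  })
  out <- list(scenarios = scens)
  if (has_names && !is.null(cfg$reps)) out$reps <- as.integer(cfg$reps)
  if (has_names && !is.null(cfg$seed)) out$seed <- as.integer(cfg$seed)
  out
}

#' Retrieve one scenario from the evaluation grid
#'
#' @param scenario_id Integer in 1..52.
#' @return A [scenario()] object.
#' @export
grid_scenario <- function(scenario_id) {
  if (!is.numeric(scenario_id) || scenario_id < 1 || scenario_id > 52) {
    stop("`scenario_id` must be in 1..52", call. = FALSE)
  }
  build_scenario_grid()[[as.integer(scenario_id)]]
}
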