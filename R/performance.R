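#' Monte-Carlo performance statistics
#'
#' The four indicators used to rank estimators across simulation scenarios,
#' all computed on the odds-ratio scale:
#' `percentage_bias()` is `100 * (mean(or_hat) - or_true) / or_true`;
#' `mse()` is the mean of `(or_hat - or_true)^2` (set `scale = "log"` for the
#' log-OR variant); `coverage()` is the fraction of closed intervals
#' `[low, high]` containing `or_true`; `avg_ci_width()` is the mean of
#' `high - low`.
#'
#' @param or_estimates Positive numeric vector of pooled OR estimates, one
#'   per replicate.
#' @param or_true True odds ratio (> 0).
#' @return A scalar; `NA` on empty input.
#' @examples
#' percentage_bias(c(1.2, 1.3), 1.25)   # 0
#' mse(c(1, 2), 1.5)                    # 0.25
#' @export
percentage_bias <- function(or_estimates, or_true) {
  or_estimates <- or_estimates[is.finite(or_estimates)]
  if (length(or_estimates) == 0L) return(NA_real_)
  stopifnot(or_true > 0)
  100 * (mean(or_estimates) - or_true) / or_true
}

#' @rdname percentage_bias
#' @param scale `"or"` (default) or `"log"`: scale on which squared error is
#'   taken.
#' @export
mse <- function(or_estimates, or_true, scale = c("or", "log")) {
  scale <- match.arg(scale)
  or_estimates <- or_estimates[is.finite(or_estimates)]
  if (length(or_estimates) == 0L) return(NA_real_)
  stopifnot(or_true > 0)
  if (scale == "log") {
    mean((log(or_estimates) - log(or_true))^2)
  } else {
    mean((or_estimates - or_true)^2)
  }
}

#' @rdname percentage_bias
#' @param intervals Two-column matrix or data.frame of CI endpoints
#'   `(low, high)` on the OR scale.
#' @export
coverage <- function(intervals, or_true) {
  intervals <- as.matrix(intervals)
  keep <- is.finite(intervals[, 1]) & is.finite(intervals[, 2])
  intervals <- intervals[keep, , drop = FALSE]
  if (nrow(intervals) == 0L) return(NA_real_)
  mean(intervals[, 1] <= or_true & or_true <= intervals[, 2])
}

#' @rdname percentage_bias
#' @export
avg_ci_width <- function(intervals) {
  intervals <- as.matrix(intervals)
  keep <- is.finite(intervals[, 1]) & is.finite(intervals[, 2])
  intervals <- intervals[keep, , drop = FALSE]
  if (nrow(intervals) == 0L) return(NA_real_)
  mean(intervals[, 2] - intervals[, 1])
}

#' Summarize replicate records into per-method performance rows
#'
#' Aggregates one scenario's replicate-level pooled results into one row per
#' method with the four performance statistics. Replicates that are not
#' estimable, or (for the one-stage method) did not converge, are dropped per
#' method and counted in `n_reps_used`; nothing is imputed.
#'
#' @param records Data.frame with columns `scenario_id`, `replicate_id`,
#'   `method`, `or_hat`, `ci_low_or`, `ci_high_or`, `estimable`, `converged`
#'   (as produced by [run_scenario()]).
#' @param scen The [scenario()] the records came from (supplies `or_true`).
#' @param mse_scale Passed to [mse()].
#' @return Data.frame with one row per method: `scenario_id`, `method`,
#'   `n_reps_total`, `n_reps_used`, `mean_or`, `pct_bias`, `mse`, `coverage`,
#'   `avg_ci_width`, `estimable`.
#' @export
summarize_records <- function(records, scen, mse_scale = c("or", "log")) {
  mse_scale <- match.arg(mse_scale)
  stopifnot(inherits(scen, "scenario"))
  if (nrow(records) == 0L) stop("no records to summarize", call. = FALSE)
  sid <- unique(records$scenario_id)
  if (length(sid) > 1L) {
    stop("records span more than one scenario", call. = FALSE)
  }
  methods <- unique(records$method)
  rows <- lapply(methods, function(mth) {
    rec <- records[records$method == mth, , drop = FALSE]
    ok <- rec$estimable & rec$converged & is.finite(rec$or_hat)
    used <- rec[ok, , drop = FALSE]
    if (nrow(used) == 0L) {
      return(data.frame(scenario_id = sid, method = mth,
                        n_reps_total = nrow(rec), n_reps_used = 0L,
                        mean_or = NA_real_, pct_bias = NA_real_,
                        mse = NA_real_, coverage = NA_real_,
                        avg_ci_width = NA_real_, estimable = FALSE))
    }
    ci <- cbind(used$ci_low_or, used$ci_high_or)
    data.frame(scenario_id = sid, method = mth,
               n_reps_total = nrow(rec), n_reps_used = nrow(used),
               mean_or = mean(used$or_hat),
               pct_bias = percentage_bias(used$or_hat, scen$or_true),
               mse = mse(used$or_hat, scen$or_true, mse_scale),
               coverage = coverage(ci, scen$or_true),
               avg_ci_width = avg_ci_width(ci),
               estimable = TRUE)
  })
  do.call(rbind, rows)
}
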