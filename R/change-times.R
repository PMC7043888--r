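# Change-time sampler: offset + exponential truncated at an upper bound,
# with the exponential scale calibrated so the truncated mean matches the
# configured mean (the task states range and mean but no rate parameter).

# cache of calibrated scales keyed by (range, mean)
.scale_cache <- new.env(parent = emptyenv())

#' Calibrate the truncated-exponential scale of the change-time sampler
#'
#' For a change time `min + X` with `X ~ Exp(scale)` truncated to `[0, L]`
#' (`L = max - min`), the truncated mean is
#' `E[X | X <= L] = s - L * exp(-L/s) / (1 - exp(-L/s))`.
#' This solves for the scale `s` such that the truncated mean equals
#' `mean - min`. The mean of the truncated distribution ranges over
#' `(0, L/2)`, so the configured mean must lie strictly between `min` and
#' `(min + max) / 2`.
#'
#' @param params A [task_params()] object.
#' @return The exponential scale in seconds (about 2.80 s at defaults).
#' @examples
#' change_time_scale(task_params())
#' @export
change_time_scale <- function(params = task_params()) {
  L <- params$change_time_max - params$change_time_min
  m <- params$change_time_mean - params$change_time_min
  if (!(m > 0 && m < L / 2)) {
    stop("change-time configuration infeasible: mean must lie in (min, (min+max)/2)",
         call. = FALSE)
  }
  key <- paste(L, m, sep = "|")
  if (!is.null(.scale_cache[[key]])) return(.scale_cache[[key]])
  f <- function(s) s - L * exp(-L / s) / (1 - exp(-L / s)) - m
  s <- stats::uniroot(f, c(1e-4, 1e4), tol = 1e-12)$root
  .scale_cache[[key]] <- s
  s
}

#' Draw change (or sham-change) times
#'
#' Samples trial change times from the task's truncated-exponential
#' distribution: `change_time_min` plus an exponential draw bounded above by
#' `change_time_max`, with the scale calibrated by [change_time_scale()] so
#' the mean equals `change_time_mean`. Catch-trial sham times use the
#' identical sampler so false alarms are measured under the same temporal
#' statistics as changes. Sampling is by inverse CDF of the truncated
#' distribution (one uniform per draw), so hard bounds hold by construction.
#'
#' @param n Number of draws.
#' @param params A [task_params()] object.
#' @param scale Optional pre-computed scale (seconds), to avoid re-solving
#'   inside tight loops.
#' @return Numeric vector of times in seconds from trial start, all within
#'   `[change_time_min, change_time_max]`.
#' @examples
#' set.seed(1)
#' summary(sample_change_time(1000))
#' @export
sample_change_time <- function(n = 1, params = task_params(), scale = NULL) {
  s <- scale %||% change_time_scale(params)
  L <- params$change_time_max - params$change_time_min
  u <- stats::runif(n)
  params$change_time_min - s * log(1 - u * (1 - exp(-L / s)))
}
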