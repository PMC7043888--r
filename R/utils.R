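# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Seeds the global RNG, runs `code`, and restores the previous RNG state so
#' that seeded package functions do not perturb the caller's random stream.
#'
#' @param seed Integer seed (required; simulation functions refuse to run
#'   unseeded to honour the reproducibility contract).
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop("a seed is required for reproducibility", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# scalar validators
check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a probability in [0, 1]", name), call. = FALSE)
  }
  x
}

check_pos <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (strict) x > 0 else x >= 0)
  if (!ok) {
    stop(sprintf("'%s' must be a %s number", name,
                 if (strict) "positive" else "non-negative"), call. = FALSE)
  }
  x
}

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 ||
      x != round(x)) {
    stop(sprintf("'%s' must be a non-negative integer", name), call. = FALSE)
  }
  as.integer(x)
}

# first lick strictly inside (lo, hi], NA if none (licks need not be sorted)
first_lick_in <- function(licks, lo, hi) {
  hit <- licks[licks > lo & licks <= hi]
  if (length(hit)) min(hit) else NA_real_
}
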