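#' Remove neuropil contamination from a measured fluorescence trace
#'
#' The measured somatic trace is modeled as `FM = FC + r * FN`, where `FC`
#' is the true cell fluorescence, `FN` the surrounding neuropil trace and
#' `r` the contamination ratio. Given `r`, the true trace is recovered
#' exactly as `FC = FM - r * FN`.
#'
#' @param FM Measured trace.
#' @param FN Neuropil trace, same length.
#' @param r Contamination ratio, `>= 0`.
#' @return The corrected trace `FM - r * FN`.
#' @examples
#' subtract_neuropil(c(10, 12), c(2, 2), r = 0.7)
#' @export
subtract_neuropil <- function(FM, FN, r) {
  if (length(FM) != length(FN)) {
    stop("'FM' and 'FN' must have the same length", call. = FALSE)
  }
  check_pos(r, "r", strict = FALSE)
  FM - r * FN
}

#' Compute dF/F with a rolling-mode baseline
#'
#' The baseline `F0` at each frame is the mode of the fluorescence values in
#' the trailing `baseline_window` seconds (window clipped at the trace
#' start, so the baseline never looks forward). The mode of the continuous
#' trace is estimated by histogram binning at `mode_bin_width` (default
#' 0.1% of the trace range) and taking the center of the fullest bin;
#' counts are updated incrementally as the window slides. The output is
#' `(F - F0) / F0`.
#'
#' @param F Raw fluorescence trace (predominantly positive).
#' @param frame_rate Sampling rate in Hz.
#' @param baseline_window Rolling window length in seconds.
#' @param mode_bin_width Histogram bin width in trace units; default
#'   `diff(range(F)) / 1000`.
#' @return The dF/F trace, same length as `F`.
#' @examples
#' compute_dff(rep(100, 200), frame_rate = 30, baseline_window = 2)
#' @export
compute_dff <- function(F, frame_rate = 30, baseline_window = 180,
                        mode_bin_width = NULL) {
  n <- length(F)
  w <- as.integer(round(baseline_window * frame_rate))
  if (n <= 1L) stop("trace too short", call. = FALSE)
  rng <- range(F)
  if (rng[2] == rng[1]) {
    F0 <- F
  } else {
    bw <- mode_bin_width %||% (diff(rng) / 1000)
    bins <- pmin(as.integer(floor((F - rng[1]) / bw)) + 1L,
                 as.integer(floor(diff(rng) / bw)) + 1L)
    nb <- max(bins)
    counts <- integer(nb)
    mode_bin <- bins[1L]
    F0 <- numeric(n)
    for (i in seq_len(n)) {
      b <- bins[i]
      counts[b] <- counts[b] + 1L
      if (counts[b] > counts[mode_bin]) mode_bin <- b
      if (i > w) {
        bo <- bins[i - w]
        counts[bo] <- counts[bo] - 1L
        if (bo == mode_bin) mode_bin <- which.max(counts)
      }
      F0[i] <- rng[1] + (mode_bin - 0.5) * bw
    }
  }
  bad <- which(F0 <= 0)
  if (length(bad)) {
    stop(sprintf("non-positive baseline F0 at frame %d", bad[1]),
         call. = FALSE)
  }
  (F - F0) / F0
}

#' Smooth an event trace with a causal half-Gaussian filter
#'
#' Convolves the trace with the non-negative-lag half of a Gaussian of
#' standard deviation `sd` seconds (default 65 ms), sampled at the frame
#' rate, truncated at `support` standard deviations and normalized to unit
#' sum. The kernel is zero for negative lags, so the output at a frame
#' depends only on that frame and earlier ones, and total event mass is
#' conserved.
#'
#' @param events Non-negative event-magnitude trace.
#' @param frame_rate Sampling rate in Hz.
#' @param sd Kernel standard deviation in seconds.
#' @param support Truncation point in multiples of `sd`.
#' @return The smoothed trace, same length as `events`.
#' @examples
#' x <- c(0, 0, 1, 0, 0, 0)
#' sum(smooth_events(x, frame_rate = 30))
#' @export
smooth_events <- function(events, frame_rate = 30, sd = 0.065, support = 4) {
  check_pos(sd, "sd")
  k_len <- as.integer(ceiling(support * sd * frame_rate)) + 1L
  lags <- (seq_len(k_len) - 1) / frame_rate
  kern <- exp(-lags^2 / (2 * sd^2))
  kern <- kern / sum(kern)
  padded <- c(numeric(k_len), events)
  out <- stats::filter(padded, kern, method = "convolution", sides = 1)
  as.numeric(out)[k_len + seq_along(events)]
}

#' Map imaging frames to the preceding stimulus clock time
#'
#' Associates each two-photon frame with the latest stimulus clock time
#' strictly before it, so responses are never attributed to stimulus or
#' behavior events occurring after the imaging sample. Frames at or before
#' the first stimulus time map to none.
#'
#' @param frame_times Imaging frame times, sorted ascending.
#' @param stimulus_times Stimulus clock times, sorted ascending.
#' @return Integer vector: for each frame, the index into `stimulus_times`
#'   of the nearest strictly-preceding time, or `NA` if none.
#' @examples
#' align_frames(c(0.01, 0.02, 0.03), c(0, 0.0167, 0.0333))
#' @export
align_frames <- function(frame_times, stimulus_times) {
  if (is.unsorted(frame_times) || is.unsorted(stimulus_times)) {
    stop("'frame_times' and 'stimulus_times' must be sorted ascending",
         call. = FALSE)
  }
  idx <- findInterval(frame_times, stimulus_times, left.open = TRUE)
  idx[idx == 0L] <- NA_integer_
  idx
}

#' Fit an ellipse to tracked pupil (or eyelid) points
#'
#' Least-squares algebraic conic fit to the tracked points whose confidence
#' is at least `min_confidence`; no fit is attempted (returns `NULL`) when
#' fewer than `min_points` such points are available, as happens during
#' blinks. Degenerate geometry (e.g. collinear points, non-elliptical
#' conic) also yields `NULL`. Pupil area is reported as the area of a
#' circle whose radius is the fitted semi-major axis.
#'
#' @param x,y Tracked point coordinates.
#' @param confidence Per-point tracker confidence in `[0, 1]`.
#' @param min_confidence Minimum confidence for a point to be used.
#' @param min_points Minimum number of usable points for a fit.
#' @return `NULL`, or a list with `center` (x, y), `axes` (semi-major,
#'   semi-minor), `angle` (radians, orientation of the major axis),
#'   `area` (`pi * semi_major^2`) and `ellipse_area` (`pi * a * b`).
#' @examples
#' th <- seq(0, 2 * pi, length.out = 13)[-13]
#' fit_pupil_ellipse(3 * cos(th), 3 * sin(th), rep(1, 12))$axes
#' @export
fit_pupil_ellipse <- function(x, y, confidence = rep(1, length(x)),
                              min_confidence = 0.8, min_points = 6) {
  keep <- !is.na(x) & !is.na(y) & confidence >= min_confidence
  x <- x[keep]; y <- y[keep]
  if (length(x) < min_points) return(NULL)
  # conic a x^2 + b xy + c y^2 + d x + e y = 1 (centered for conditioning)
  mx <- mean(x); my <- mean(y)
  xc <- x - mx; yc <- y - my
  D <- cbind(xc^2, xc * yc, yc^2, xc, yc)
  beta <- tryCatch(qr.solve(D, rep(1, length(x))), error = function(e) NULL)
  if (is.null(beta) || any(!is.finite(beta))) return(NULL)
  A <- beta[1]; B <- beta[2]; C <- beta[3]; Dd <- beta[4]; E <- beta[5]
  M <- matrix(c(A, B / 2, B / 2, C), 2)
  if (det(M) <= 0) return(NULL)              # not an ellipse
  ctr <- tryCatch(solve(2 * M, -c(Dd, E)), error = function(e) NULL)
  if (is.null(ctr)) return(NULL)
  # value of the quadratic form at the center; conic is Q(x) = 1
  k <- 1 - (A * ctr[1]^2 + B * ctr[1] * ctr[2] + C * ctr[2]^2 +
              Dd * ctr[1] + E * ctr[2])
  ev <- eigen(M, symmetric = TRUE)
  # Q(center + u) = Q(center) + u' M u, so u' M u = k on the ellipse
  if (any(ev$values <= 0) || k <= 0) return(NULL)
  axes <- sqrt(k / ev$values)                # descending eigenvalues -> minor first
  ord <- order(axes, decreasing = TRUE)
  axes <- axes[ord]
  vec <- ev$vectors[, ord[1]]
  list(center = c(x = ctr[1] + mx, y = ctr[2] + my),
       axes = c(major = axes[1], minor = axes[2]),
       angle = atan2(vec[2], vec[1]),
       area = pi * axes[1]^2,
       ellipse_area = pi * axes[1] * axes[2])
}

#' Clean a pupil-area trace
#'
#' Removes frames more than three standard deviations from the trace mean,
#' widens every run of missing frames by two frames on each side (tracking
#' is unreliable just before and after a lost fit), and linearly
#' interpolates across all removed or missing frames, extrapolating flat at
#' the edges.
#'
#' @param area Pupil-area trace; may contain `NA` for frames without a fit.
#' @param n_sd Outlier threshold in standard deviations.
#' @param pad Frames removed on each side of a missing run.
#' @return The cleaned trace with no missing values.
#' @examples
#' clean_pupil_trace(c(10, 10, NA, 10, 10, 10, 10, 10))
#' @export
clean_pupil_trace <- function(area, n_sd = 3, pad = 2) {
  n <- length(area)
  if (all(is.na(area))) stop("pupil trace is entirely missing",
                             call. = FALSE)
  mu <- mean(area, na.rm = TRUE)
  sdv <- stats::sd(area, na.rm = TRUE)
  bad <- is.na(area)
  if (is.finite(sdv) && sdv > 0) bad <- bad | abs(area - mu) > n_sd * sdv
  miss <- which(is.na(area))
  if (length(miss) && pad > 0) {
    expand <- unique(unlist(lapply(miss, function(i) (i - pad):(i + pad))))
    expand <- expand[expand >= 1 & expand <= n]
    bad[expand] <- TRUE
  }
  if (all(bad)) stop("pupil trace is entirely missing after cleaning",
                     call. = FALSE)
  good <- which(!bad)
  out <- area
  out[bad] <- stats::approx(good, area[good], xout = which(bad),
                            rule = 2)$y
  out
}
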