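# Neural response statistics on event traces: windowed flash/omission
# responses, preferred image, resampling responsiveness classification,
# lifetime sparseness, population tuning curves, event-triggered averages,
# time-to-peak and ramp indices.

#' Per-presentation windowed responses
#'
#' For every cell and every presentation, the mean of the event trace over
#' frames whose times fall in `[onset, onset + window)`: a 500 ms window
#' after stimulus onset for displayed flashes (covering the 250 ms flash
#' plus 250 ms after, to capture delayed and off responses), and a 750 ms
#' window anchored at the scheduled-but-not-shown onset for omissions.
#' Presentations whose window extends past the end of the traces are
#' dropped.
#'
#' @param traces An [generate_event_traces()] object (or any list with
#'   `frame_times` and a cells-by-frames `magnitudes` matrix).
#' @param stimuli Stimulus table.
#' @param stimulus_window,omission_window Window lengths in seconds.
#' @return An object of class `flash_response_matrix`: list with `response`
#'   (cells x presentations matrix), `presentations` (the retained stimulus
#'   rows) and `cells`.
#' @export
flash_responses <- function(traces, stimuli, stimulus_window = 0.5,
                            omission_window = 0.75) {
  ft <- traces$frame_times
  win <- ifelse(stimuli$is_omitted, omission_window, stimulus_window)
  lo <- findInterval(stimuli$onset, ft, left.open = TRUE) + 1L
  hi <- findInterval(stimuli$onset + win, ft, left.open = TRUE)
  keep <- stimuli$onset + win <= max(ft) + 1e-9 & hi >= lo
  if (!all(keep)) {
    message(sprintf("flash_responses: dropped %d presentation(s) extending past trace end",
                    sum(!keep)))
  }
  pres <- stimuli[keep, , drop = FALSE]
  lo <- lo[keep]; hi <- hi[keep]
  n_cells <- nrow(traces$magnitudes)
  cum <- cbind(0, t(apply(traces$magnitudes, 1, cumsum)))
  nfr <- hi - lo + 1L
  resp <- (cum[, hi + 1L, drop = FALSE] - cum[, lo, drop = FALSE]) /
    rep(nfr, each = n_cells)
  structure(list(response = resp, presentations = pres,
                 cells = traces$cells),
            class = "flash_response_matrix")
}

#' Preferred image per cell
#'
#' The image evoking the largest mean windowed response for each cell, over
#' displayed (non-omitted) presentations; ties break to the lowest image
#' id.
#'
#' @param frm A [flash_responses()] result.
#' @return Integer vector of image ids, one per cell.
#' @export
preferred_image <- function(frm) {
  shown <- !frm$presentations$is_omitted
  imgs <- sort(unique(frm$presentations$image_id[shown]))
  means <- vapply(imgs, function(im) {
    sel <- shown & frm$presentations$image_id == im
    rowMeans(frm$response[, sel, drop = FALSE])
  }, numeric(nrow(frm$response)))
  if (is.null(dim(means))) means <- matrix(means, nrow = 1)
  imgs[max.col(means, ties.method = "first")]
}

#' Resampling-based responsiveness classification
#'
#' Classifies a cell as responsive by comparing each target-presentation
#' response to a null distribution resampled (with replacement,
#' `n_resamples` draws) from the complementary response pool: omission
#' responses when testing image responsiveness, displayed-flash responses
#' when testing omission responsiveness. Each presentation's p-value is the
#' proportion of null draws greater than or equal to its response (ties
#' count against significance, so an all-zero cell is never responsive),
#' and the cell is flagged responsive when at least `presentation_frac` of
#' presentations have `p < alpha` (0.25 for image responsiveness, 0.10 for
#' omission responsiveness).
#'
#' Uses the current RNG state; seed the caller for reproducibility.
#'
#' @param target_responses Per-presentation responses being tested.
#' @param null_responses The complementary response pool.
#' @param n_resamples Number of null draws.
#' @param presentation_frac Fraction of significant presentations required.
#' @param alpha Per-presentation significance level.
#' @return List with `responsive` (flag), `p_values` (per presentation) and
#'   `frac_significant`.
#' @examples
#' set.seed(1)
#' classify_responsiveness(rnorm(20, 5), rnorm(100), n_resamples = 1000)$responsive
#' @export
classify_responsiveness <- function(target_responses, null_responses,
                                    n_resamples = 10000,
                                    presentation_frac = 0.25,
                                    alpha = 0.05) {
  if (!length(null_responses)) {
    stop("empty null response pool", call. = FALSE)
  }
  if (!length(target_responses)) {
    return(list(responsive = FALSE, p_values = numeric(0),
                frac_significant = NA_real_))
  }
  draws <- sort(sample(null_responses, n_resamples, replace = TRUE))
  # p_i = #{draws >= t_i} / n  (#{draws < t} via left-open findInterval)
  p <- (n_resamples -
          findInterval(target_responses, draws, left.open = TRUE)) /
    n_resamples
  frac <- mean(p < alpha)
  list(responsive = frac >= presentation_frac, p_values = p,
       frac_significant = frac)
}

#' Lifetime sparseness
#'
#' Tuning-curve concentration in `[0, 1]`:
#' `S = (1 - (sum(r)/N)^2 / (sum(r^2)/N)) / (1 - 1/N)`
#' with `r_i` the mean response to image `i` and `N` the number of images.
#' `S = 1` for a cell responding to a single image, `S = 0` for uniform
#' tuning. In the pipeline it is only computed for image-responsive cells.
#'
#' @param r Non-negative mean responses per image (length `N >= 2`).
#' @return Sparseness `S`, or `NA` for an all-zero tuning vector.
#' @examples
#' lifetime_sparseness(c(1, 0, 0, 0, 0, 0, 0, 0))  # 1
#' @export
lifetime_sparseness <- function(r) {
  N <- length(r)
  if (N < 2) stop("need at least two images", call. = FALSE)
  if (any(r < 0)) stop("responses must be non-negative", call. = FALSE)
  if (all(r == 0)) return(NA_real_)
  (1 - (sum(r) / N)^2 / (sum(r^2) / N)) / (1 - 1 / N)
}

#' Population tuning curve
#'
#' Rank-sorts each responsive cell's mean response to the images
#' (descending) and averages the sorted curves position-wise across cells,
#' yielding a non-increasing population curve from preferred to least
#' preferred image.
#'
#' @param frm A [flash_responses()] result.
#' @param responsive_cells Indices (rows of the response matrix) of the
#'   cells to include.
#' @param min_cells Curves are suppressed (`NULL`) below this cell count.
#' @return Numeric vector of length `n_images` (rank positions), or `NULL`.
#' @export
population_tuning_curve <- function(frm, responsive_cells,
                                    min_cells = 10) {
  if (length(responsive_cells) < 1) return(NULL)
  if (length(responsive_cells) < min_cells) return(NULL)
  shown <- !frm$presentations$is_omitted
  imgs <- sort(unique(frm$presentations$image_id[shown]))
  curves <- vapply(responsive_cells, function(ci) {
    m <- vapply(imgs, function(im) {
      sel <- shown & frm$presentations$image_id == im
      mean(frm$response[ci, sel])
    }, numeric(1))
    sort(m, decreasing = TRUE)
  }, numeric(length(imgs)))
  rowMeans(curves)
}

#' Event-triggered average trace
#'
#' Averages the event traces around a set of anchor times (flash onsets or
#' scheduled omission onsets) on a relative time grid with frame-width
#' (1/frame-rate) bins. Because frames are evenly spaced, each bin holds
#' exactly one frame per anchor; anchors whose window extends beyond the
#' trace are dropped.
#'
#' @param traces An [generate_event_traces()]-like object.
#' @param anchors Anchor times, seconds.
#' @param window Two-element window relative to the anchors, seconds.
#' @return List with `time` (bin start times relative to the anchor) and
#'   `mean` (cells x bins matrix), class `triggered_average`.
#' @export
triggered_average <- function(traces, anchors, window = c(-0.75, 0.75)) {
  fr <- traces$frame_rate
  ft <- traces$frame_times
  n_bins <- as.integer(round((window[2] - window[1]) * fr))
  rel <- window[1] + (seq_len(n_bins) - 1) / fr
  anchors <- anchors[anchors + window[1] >= ft[1] - 1e-9 &
                       anchors + window[2] <= ft[length(ft)] + 1e-9]
  if (!length(anchors)) {
    stop("no anchors with a fully covered window", call. = FALSE)
  }
  # first frame at or after each bin start (frames start at ft[1], step 1/fr)
  starts <- outer(anchors, rel, `+`)
  idx <- ceiling((starts - ft[1]) * fr - 1e-6) + 1L
  idx[idx < 1L] <- 1L
  idx[idx > length(ft)] <- length(ft)
  nc <- nrow(traces$magnitudes)
  avg <- matrix(0, nc, n_bins)
  for (ci in seq_len(nc)) {
    v <- traces$magnitudes[ci, ][idx]
    avg[ci, ] <- colMeans(matrix(v, nrow = length(anchors)))
  }
  structure(list(time = rel, mean = avg, n_anchors = length(anchors),
                 frame_rate = fr),
            class = "triggered_average")
}

#' Time to peak of the stimulus-triggered response
#'
#' The time, within a 500 ms window after stimulus onset, at which each
#' cell's average stimulus-triggered trace reaches its maximum.
#'
#' @param avg A [triggered_average()] whose grid covers `[0, window)`.
#' @param window Search window length after the anchor, seconds.
#' @return Numeric vector of peak times (seconds after onset), one per
#'   cell.
#' @export
time_to_peak <- function(avg, window = 0.5) {
  sel <- which(avg$time >= -1e-9 & avg$time < window - 1e-9)
  if (!length(sel)) stop("triggered average does not cover the window",
                         call. = FALSE)
  avg$time[sel][apply(avg$mean[, sel, drop = FALSE], 1, which.max)]
}

#' Ramp index of a windowed trace
#'
#' Quantifies the direction and magnitude of activity change across a
#' window as `log2((R_late + eps) / (R_early + eps))`, where `R_early` and
#' `R_late` are the mean responses over the early and late sub-windows. The
#' index is positive when the trace increases across the window and
#' negative when it decreases; `eps` guards all-zero windows (which map to
#' index 0).
#'
#' @param values Trace values across the window, in time order.
#' @param n_sub Number of samples in each sub-window (early = first
#'   `n_sub`, late = last `n_sub`; sub-windows may overlap mid-window).
#' @param eps Small positive constant.
#' @return The ramp index (unitless).
#' @examples
#' ramp_index(c(1, 1, 2, 2), n_sub = 2)  # 1
#' @export
ramp_index <- function(values, n_sub, eps = 1e-6) {
  n <- length(values)
  if (n_sub < 1 || n_sub > n) stop("invalid sub-window length",
                                   call. = FALSE)
  r_early <- mean(values[seq_len(n_sub)])
  r_late <- mean(values[(n - n_sub + 1L):n])
  log2((r_late + eps) / (r_early + eps))
}

#' Pre-stimulus, stimulus and omission ramp indices for all cells
#'
#' Computes the three conventional ramp indices from triggered averages:
#' \describe{
#'   \item{pre_stimulus}{over the 400 ms before stimulus onset, comparing
#'     the first and last 120 ms;}
#'   \item{stimulus}{over the 125 ms after the anchor (stimulus onset by
#'     default; `anchor = "offset"` reproduces the offset-anchored
#'     variant), comparing the first and last 65 ms;}
#'   \item{omission}{over the 750 ms omission window, comparing its two
#'     375 ms halves.}
#' }
#' Sub-window lengths are rounded to the nearest whole frame; the 65 ms
#' sub-windows of the 125 ms stimulus window overlap in the middle.
#' Cells with a positive stimulus ramp index are classed stimulus-driven,
#' otherwise stimulus-suppressed.
#'
#' @param stim_avg A [triggered_average()] around flash onsets covering at
#'   least `[-0.4, 0.2]` s.
#' @param omission_avg Optional [triggered_average()] around omission
#'   onsets covering `[0, 0.75]` s.
#' @param eps Passed to [ramp_index()].
#' @param anchor Anchor of the stimulus window: `"onset"` (default) or
#'   `"offset"` (125 ms window starting at stimulus offset, 250 ms after
#'   onset).
#' @param flash_duration Flash duration, seconds (used for
#'   `anchor = "offset"`).
#' @return data.frame with `pre_stimulus_ramp_index`,
#'   `stimulus_ramp_index`, `omission_ramp_index` (`NA` without
#'   `omission_avg`) and `dynamics_class`.
#' @export
ramp_indices <- function(stim_avg, omission_avg = NULL, eps = 1e-6,
                         anchor = c("onset", "offset"),
                         flash_duration = 0.25) {
  anchor <- match.arg(anchor)
  fr <- stim_avg$frame_rate
  t <- stim_avg$time
  n_cells <- nrow(stim_avg$mean)

  pre_n <- as.integer(round(0.4 * fr))
  pre_sub <- as.integer(round(0.12 * fr))
  pre_sel <- which(t >= -0.4 - 1e-9 & t < -1e-9)
  if (length(pre_sel) != pre_n) pre_sel <- utils::tail(which(t < -1e-9),
                                                       pre_n)

  stim_start <- if (anchor == "onset") 0 else flash_duration
  stim_n <- as.integer(round(0.125 * fr))
  stim_sub <- as.integer(round(0.065 * fr))
  stim_sel <- which(t >= stim_start - 1e-9)[seq_len(stim_n)]

  if (length(pre_sel) < pre_sub || any(is.na(stim_sel))) {
    stop("triggered average does not cover the ramp windows", call. = FALSE)
  }

  pre <- apply(stim_avg$mean[, pre_sel, drop = FALSE], 1, ramp_index,
               n_sub = pre_sub, eps = eps)
  stim <- apply(stim_avg$mean[, stim_sel, drop = FALSE], 1, ramp_index,
                n_sub = stim_sub, eps = eps)

  om <- rep(NA_real_, n_cells)
  if (!is.null(omission_avg)) {
    to <- omission_avg$time
    om_n <- as.integer(round(0.75 * omission_avg$frame_rate))
    om_sub <- as.integer(round(0.375 * omission_avg$frame_rate))
    om_sel <- which(to >= -1e-9)[seq_len(om_n)]
    om <- apply(omission_avg$mean[, om_sel, drop = FALSE], 1, ramp_index,
                n_sub = om_sub, eps = eps)
  }

  data.frame(
    pre_stimulus_ramp_index = pre,
    stimulus_ramp_index = stim,
    omission_ramp_index = om,
    dynamics_class = ifelse(stim > 0, "stimulus_driven",
                            "stimulus_suppressed")
  )
}

#' Least-squares association between two per-cell indices
#'
#' Linear least-squares fit of `y` on `x` with the Pearson correlation and
#' its p-value (via [stats::cor.test()]).
#'
#' @param x,y Per-cell values; pairs with missing values are dropped.
#' @return List with `r`, `p`, `slope`, `intercept`, `n`.
#' @export
index_correlation <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 finite pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, slope = NA_real_,
                intercept = NA_real_, n = length(x),
                degenerate = TRUE))
  }
  ct <- stats::cor.test(x, y)
  fit <- stats::lm.fit(cbind(1, x), y)
  list(r = unname(ct$estimate), p = ct$p.value,
       slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]), n = length(x),
       degenerate = FALSE)
}

#' Per-cell summary of neural response metrics
#'
#' Runs the full per-cell analysis for one session's traces: windowed
#' responses, preferred image, image/omission responsiveness (resampling
#' classifier), lifetime sparseness (image-responsive cells only),
#' time-to-peak and the three ramp indices with the dynamics class.
#'
#' @param traces An [generate_event_traces()] object.
#' @param stimuli Matching stimulus table.
#' @param n_resamples Resamples for [classify_responsiveness()].
#' @param seed Integer seed for the resampling draws; required.
#' @param anchor Stimulus ramp-window anchor, see [ramp_indices()].
#' @return data.frame, one row per cell (class `cell_summary`), with the
#'   cell metadata and metric columns.
#' @export
summarize_cells <- function(traces, stimuli, n_resamples = 10000, seed,
                            anchor = "onset") {
  if (missing(seed)) stop("a seed is required for reproducibility",
                          call. = FALSE)
  frm <- flash_responses(traces, stimuli)
  pres <- frm$presentations
  shown <- !pres$is_omitted
  omitted <- pres$is_omitted
  pref <- preferred_image(frm)
  n_cells <- nrow(frm$response)

  stim_on <- pres$onset[shown]
  stim_avg <- triggered_average(traces, stim_on, window = c(-0.4, 0.5))
  om_avg <- if (any(omitted)) {
    triggered_average(traces, pres$onset[omitted], window = c(-0.4, 0.75))
  } else NULL
  ri <- ramp_indices(stim_avg, om_avg,
                     anchor = anchor,
                     flash_duration = min(pres$offset - pres$onset,
                                          na.rm = TRUE))
  ttp <- time_to_peak(stim_avg)

  img_resp <- logical(n_cells)
  om_resp <- logical(n_cells)
  sparseness <- rep(NA_real_, n_cells)
  imgs <- sort(unique(pres$image_id[shown]))
  with_seed(seed, {
    for (ci in seq_len(n_cells)) {
      tgt <- frm$response[ci, shown & pres$image_id == pref[ci]]
      null_om <- frm$response[ci, omitted]
      null_img <- frm$response[ci, shown]
      if (length(null_om)) {
        img_resp[ci] <- classify_responsiveness(
          tgt, null_om, n_resamples, presentation_frac = 0.25)$responsive
        om_resp[ci] <- classify_responsiveness(
          frm$response[ci, omitted], null_img, n_resamples,
          presentation_frac = 0.10)$responsive
      }
      if (img_resp[ci]) {
        r <- vapply(imgs, function(im) {
          mean(frm$response[ci, shown & pres$image_id == im])
        }, numeric(1))
        sparseness[ci] <- lifetime_sparseness(r)
      }
    }
  })

  out <- cbind(
    traces$cells,
    data.frame(
      estimated_preferred_image = pref,
      image_responsive = img_resp,
      omission_responsive = om_resp,
      sparseness = sparseness,
      time_to_peak = ttp
    ),
    ri
  )
  class(out) <- c("cell_summary", "data.frame")
  out
}
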