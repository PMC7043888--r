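# Synthetic calcium event traces with the phenomenology the analysis
# expects: image-tuned transient excitatory responses, and VIP cells that
# are either stimulus-driven (novel condition) or pre-stimulus
# ramping / stimulus-suppressed / omission-ramping (familiar condition).

#' Build a per-cycle event-rate profile for a cell
#'
#' Returns the rate model for one cell as a function of the time elapsed
#' since the most recent *displayed* flash onset:
#' \describe{
#'   \item{transient}{(excitatory cells and driven-mode VIP): a Gaussian
#'     rate bump peaking ~150 ms after onset of the preferred image, scaled
#'     by the cell's per-image tuning weights; silent during omission gaps
#'     (`omission_rule = "silent"`).}
#'   \item{suppressed_ramping}{(familiar-mode VIP): rate decays from its
#'     peak right after stimulus onset, then ramps linearly back up across
#'     the inter-stimulus interval to peak at the next onset; when a flash
#'     is omitted the ramp continues to grow through the gap until the next
#'     displayed stimulus (`omission_rule = "continue_ramp"`).}
#' }
#' Excitatory amplitudes under the familiar condition are scaled by
#' `familiar_amplitude_factor` and tuning is sharpened, reflecting the
#' reduced but more selective responses seen with familiar images.
#'
#' @param cell_class `"excitatory"` or `"vip"`.
#' @param condition `"familiar"` or `"novel"`.
#' @param params A [population_params()] object.
#' @param preferred_image Planted preferred image id in
#'   `0:(n_images - 1)`; drawn uniformly if `NULL`.
#' @param mode For VIP cells, `"driven"` or `"suppressed_ramping"`;
#'   defaults to the condition's majority mode.
#' @param n_images Number of images in the set.
#' @return An object of class `rate_profile`: list with `type`, `amp`
#'   (peak events/s), `weights` (per-image), `omission_rule` and shape
#'   constants. Uses the current RNG state for tuning draws.
#' @examples
#' set.seed(1)
#' make_rate_profile("vip", "familiar", population_params(condition = "familiar"))
#' @export
make_rate_profile <- function(cell_class = c("excitatory", "vip"),
                              condition = c("novel", "familiar"),
                              params = population_params(),
                              preferred_image = NULL,
                              mode = NULL,
                              n_images = 8) {
  cell_class <- match.arg(cell_class)
  condition <- match.arg(condition)
  pref <- preferred_image %||% (sample.int(n_images, 1L) - 1L)
  familiar <- condition == "familiar"

  if (cell_class == "vip" && is.null(mode)) {
    mode <- if (familiar) "suppressed_ramping" else "driven"
  }
  type <- if (cell_class == "vip" && mode == "suppressed_ramping") {
    "suppressed_ramping"
  } else {
    "transient"
  }

  w_max <- exp(-params$tuning_sharpness)
  weights <- stats::runif(n_images, 0, w_max)
  weights[pref + 1L] <- 1

  if (cell_class == "excitatory") {
    amp <- params$exc_amplitude_scale *
      (if (familiar) params$familiar_amplitude_factor else 1)
  } else {
    amp <- params$vip_amplitude_scale
    if (type == "transient") {
      # VIP cells are weakly image selective
      weights <- pmax(weights, 0.5)
    } else {
      weights[] <- 1                    # ramping is not image specific
    }
  }

  structure(list(
    cell_class = cell_class,
    condition = condition,
    type = type,
    mode = if (cell_class == "vip") mode else "driven",
    amp = amp,
    weights = weights,
    preferred_image = as.integer(pref),
    omission_rule = if (type == "suppressed_ramping") "continue_ramp"
                    else "silent",
    bump_center = 0.15,               # s after onset, transient profiles
    bump_sd = 0.05,
    suppress_time = 0.15,             # s of post-onset decay, ramping mode
    ramp_floor = 0.1,                 # fraction of peak at the trough
    omission_gain = 1.5               # extra ramp growth per omitted cycle
  ), class = "rate_profile")
}

#' Evaluate a rate profile
#'
#' Computes the instantaneous event rate (events/s) at times `t_gap`
#' seconds after the most recent displayed flash onset, for the image shown
#' at that flash. Values of `t_gap >= period` lie inside an omission gap
#' and follow the profile's omission rule.
#'
#' @param profile A [make_rate_profile()] object.
#' @param t_gap Seconds since the last displayed flash onset.
#' @param image_id Image shown at that flash (same length as `t_gap` or
#'   scalar).
#' @param period Flash period in seconds.
#' @return Event rate in events/s, `>= 0`.
#' @export
rate_profile_eval <- function(profile, t_gap, image_id, period = 0.75) {
  w <- profile$weights[image_id + 1L]
  in_gap <- t_gap >= period
  if (profile$type == "transient") {
    r <- profile$amp * w *
      exp(-(t_gap - profile$bump_center)^2 / (2 * profile$bump_sd^2))
    r[in_gap] <- 0
  } else {
    ts <- profile$suppress_time
    lo <- profile$ramp_floor
    tc <- pmin(t_gap, period)
    r <- ifelse(tc < ts,
                1 - (1 - lo) * tc / ts,
                lo + (1 - lo) * (tc - ts) / (period - ts))
    # omission: the ramp keeps growing past the expected onset
    r <- ifelse(in_gap,
                1 + profile$omission_gain * (t_gap - period) / period,
                r)
    r <- profile$amp * r
  }
  pmax(r, 0)
}

#' Generate synthetic event traces for a cell population
#'
#' Draws per-cell event traces on the imaging frame grid as an
#' inhomogeneous point process: for each frame, an event count is Poisson
#' with the cell's instantaneous rate (its [make_rate_profile()] driven by
#' the stimulus table, plus a background `noise_event_rate`), and the frame
#' magnitude is the sum of that many exponential marks with mean
#' `event_magnitude_mean`. VIP mode composition is deterministic:
#' `round(n_vip * fraction)` cells per mode. The planted ground truth
#' (preferred image, mode) is recorded for recovery tests.
#'
#' @param stimuli Stimulus table from [simulate_session()] (with omissions
#'   scheduled).
#' @param pop A [population_params()] object.
#' @param seed Integer seed; required.
#' @return An object of class `event_traces`: list with `frame_times`,
#'   `magnitudes` (cells x frames matrix, non-negative), `cells`
#'   (data.frame of `cell_id`, `cell_class`, `condition`, `mode`,
#'   `preferred_image`), `profiles` (list of rate profiles) and
#'   `frame_rate`.
#' @examples
#' s <- simulate_session(task_params(session_duration = 60),
#'                       agent_params(), seed = 1)
#' tr <- generate_event_traces(s$stimuli,
#'                             population_params(n_excitatory = 3, n_vip = 2),
#'                             seed = 2)
#' dim(tr$magnitudes)
#' @export
generate_event_traces <- function(stimuli, pop = population_params(), seed) {
  if (missing(seed)) stop("a seed is required for reproducibility",
                          call. = FALSE)
  with_seed(seed, {
    fr <- pop$frame_rate
    period <- if (nrow(stimuli) > 1) diff(stimuli$onset[1:2]) else 0.75
    t_end <- max(stimuli$onset) + period
    frame_times <- seq(0, t_end, by = 1 / fr)
    nf <- length(frame_times)

    shown <- stimuli[!stimuli$is_omitted, , drop = FALSE]
    if (nrow(shown) == 0L) {
      stop("stimulus table contains no displayed flashes", call. = FALSE)
    }
    last <- findInterval(frame_times, shown$onset)
    valid <- last >= 1L
    t_gap <- ifelse(valid, frame_times - shown$onset[pmax(last, 1L)], Inf)
    img <- ifelse(valid, shown$image_id[pmax(last, 1L)], 0L)

    n_cells <- pop$n_excitatory + pop$n_vip
    n_supp <- round(pop$n_vip * pop$vip_mode_fractions[["suppressed_ramping"]])
    vip_modes <- rep(c("driven", "suppressed_ramping"),
                     c(pop$n_vip - n_supp, n_supp))

    cells <- data.frame(
      cell_id = seq_len(n_cells),
      cell_class = rep(c("excitatory", "vip"),
                       c(pop$n_excitatory, pop$n_vip)),
      condition = pop$condition,
      mode = c(rep("driven", pop$n_excitatory), vip_modes),
      preferred_image = NA_integer_,
      stringsAsFactors = FALSE
    )

    mags <- matrix(0, n_cells, nf)
    profiles <- vector("list", n_cells)
    n_images <- max(stimuli$image_id) + 1L
    for (i in seq_len(n_cells)) {
      prof <- make_rate_profile(cells$cell_class[i], pop$condition, pop,
                                mode = if (cells$cell_class[i] == "vip")
                                         cells$mode[i] else NULL,
                                n_images = n_images)
      profiles[[i]] <- prof
      cells$preferred_image[i] <- prof$preferred_image
      rate <- rate_profile_eval(prof, t_gap, img, period) +
        pop$noise_event_rate
      rate[!valid] <- pop$noise_event_rate
      counts <- stats::rpois(nf, rate / fr)
      pos <- counts > 0L
      if (any(pos)) {
        mags[i, pos] <- stats::rgamma(sum(pos), shape = counts[pos],
                                      scale = pop$event_magnitude_mean)
      }
    }

    structure(list(frame_times = frame_times, magnitudes = mags,
                   cells = cells, profiles = profiles, frame_rate = fr,
                   condition = pop$condition, seed = seed),
              class = "event_traces")
  })
}

#' @export
print.event_traces <- function(x, ...) {
  cat(sprintf("Synthetic event traces: %d cells x %d frames (%g Hz, %s)\n",
              nrow(x$magnitudes), ncol(x$magnitudes), x$frame_rate,
              x$condition))
  print(table(x$cells$cell_class, x$cells$mode))
  invisible(x)
}

#' Render a raw-fluorescence forward model from event traces
#'
#' Builds measured/neuropil fluorescence pairs from event traces: the true
#' somatic trace is `FC_true = F0 + events` convolved with a causal
#' single-exponential calcium kernel (decay `kernel_tau`, unit peak, so a
#' lone event of magnitude m peaks at m above baseline); the neuropil trace
#' `FN` is an independent smooth noise process; and the measured trace is
#' composed exactly as `FM = FC_true + r * FN` plus optional white
#' measurement noise. This provides ground truth for testing
#' [subtract_neuropil()] and [compute_dff()].
#'
#' @param traces An [generate_event_traces()] object.
#' @param kernel_tau Calcium decay time constant, seconds.
#' @param r Neuropil contamination ratio.
#' @param F0 Baseline fluorescence, arbitrary units.
#' @param noise_sd Standard deviation of white measurement noise added to
#'   `FM` (0 disables it).
#' @param event_gain Fluorescence units per unit event magnitude.
#' @param seed Integer seed; required.
#' @return An object of class `fluorescence_pair`: list with matrices `FM`,
#'   `FN`, `FC_true` (cells x frames), plus `r`, `F0`, `kernel_tau` and
#'   `frame_times`.
#' @export
render_fluorescence <- function(traces, kernel_tau = 0.7, r = 0.7,
                                F0 = 100, noise_sd = 0, event_gain = 100,
                                seed) {
  if (missing(seed)) stop("a seed is required for reproducibility",
                          call. = FALSE)
  with_seed(seed, {
    fr <- traces$frame_rate
    a <- exp(-1 / (kernel_tau * fr))
    nf <- ncol(traces$magnitudes)
    nc <- nrow(traces$magnitudes)
    FC <- t(apply(traces$magnitudes * event_gain, 1, function(x) {
      F0 + as.numeric(stats::filter(x, a, method = "recursive"))
    }))
    if (nc == 1L) FC <- matrix(FC, 1L, nf)
    FN <- t(replicate(nc, {
      base <- 0.3 * F0
      ar <- as.numeric(stats::filter(stats::rnorm(nf, 0, 0.005 * F0),
                                     0.95, method = "recursive"))
      base + ar
    }))
    if (nc == 1L) FN <- matrix(FN, 1L, nf)
    FM <- FC + r * FN
    if (noise_sd > 0) FM <- FM + matrix(stats::rnorm(nc * nf, 0, noise_sd),
                                        nc, nf)
    structure(list(FM = FM, FN = FN, FC_true = FC, r = r, F0 = F0,
                   kernel_tau = kernel_tau,
                   frame_times = traces$frame_times),
              class = "fluorescence_pair")
  })
}

#' Write event traces to CSV with a ground-truth sidecar
#'
#' Writes the traces in long format (`cell_id`, `frame_time`, `magnitude`,
#' zero frames skipped) plus a JSON sidecar of the planted ground truth.
#'
#' @param traces An [generate_event_traces()] object.
#' @param dir Output directory.
#' @return Invisibly, the files written.
#' @export
write_event_traces <- function(traces, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nz <- which(traces$magnitudes > 0, arr.ind = TRUE)
  long <- data.frame(
    cell_id = traces$cells$cell_id[nz[, 1]],
    frame_time = traces$frame_times[nz[, 2]],
    magnitude = traces$magnitudes[nz]
  )
  long <- long[order(long$cell_id, long$frame_time), ]
  f1 <- file.path(dir, "event_traces.csv")
  f2 <- file.path(dir, "ground_truth.json")
  utils::write.csv(long, f1, row.names = FALSE)
  jsonlite::write_json(traces$cells, f2, dataframe = "rows")
  invisible(c(f1, f2))
}
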