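# Group-level statistics across image-set conditions and the end-to-end
# pipeline orchestration (simulate -> synthesize -> process -> analyze ->
# report).

#' Compare a per-cell metric across image sets
#'
#' One-way ANOVA (equal-variance F test) for an overall effect of image
#' set, followed by pairwise Welch two-sample t-tests with a
#' Bonferroni-corrected significance level `0.05 / n_pairs` (0.0083 for
#' four image sets). Pairwise tests are always computed; the ANOVA gates
#' nothing and is reported alongside.
#'
#' @param values Numeric vector of the per-cell metric.
#' @param group Image-set label per value (factor or character).
#' @param alpha Family significance level before correction.
#' @return An object of class `image_set_comparison`: list with `anova_F`,
#'   `anova_p`, `pairs` (data.frame: group_1, group_2, welch_t, welch_p,
#'   significant) and `corrected_alpha`.
#' @examples
#' set.seed(1)
#' compare_image_sets(rnorm(40), rep(c("A", "B", "C", "D"), each = 10))
#' @export
compare_image_sets <- function(values, group, alpha = 0.05) {
  ok <- is.finite(values) & !is.na(group)
  values <- values[ok]
  group <- as.character(group)[ok]
  gs <- sort(unique(group))
  if (length(gs) < 2) stop("need at least two groups", call. = FALSE)
  sizes <- table(group)
  if (any(sizes < 2)) stop("each group needs at least two values",
                           call. = FALSE)
  av <- stats::oneway.test(values ~ factor(group), var.equal = TRUE)
  prs <- utils::combn(gs, 2)
  n_pairs <- ncol(prs)
  corrected <- alpha / n_pairs
  pair_rows <- lapply(seq_len(n_pairs), function(i) {
    a <- values[group == prs[1, i]]
    b <- values[group == prs[2, i]]
    degen <- stats::sd(a) == 0 && stats::sd(b) == 0
    if (degen) {
      data.frame(group_1 = prs[1, i], group_2 = prs[2, i],
                 welch_t = NA_real_, welch_p = NA_real_,
                 significant = FALSE, degenerate = TRUE)
    } else {
      tt <- stats::t.test(a, b, var.equal = FALSE)
      data.frame(group_1 = prs[1, i], group_2 = prs[2, i],
                 welch_t = unname(tt$statistic), welch_p = tt$p.value,
                 significant = tt$p.value < corrected, degenerate = FALSE)
    }
  })
  structure(list(
    anova_F = unname(av$statistic),
    anova_p = av$p.value,
    pairs = do.call(rbind, pair_rows),
    corrected_alpha = corrected
  ), class = "image_set_comparison")
}

#' @export
print.image_set_comparison <- function(x, ...) {
  cat(sprintf("ANOVA F = %.3f, p = %.3g; pairwise Welch at alpha = %.4f\n",
              x$anova_F, x$anova_p, x$corrected_alpha))
  print(x$pairs, row.names = FALSE)
  invisible(x)
}

#' Percentile bootstrap confidence interval for the mean
#'
#' @param values Numeric vector (`n >= 2`).
#' @param level Confidence level.
#' @param n_boot Bootstrap replicates.
#' @return Named numeric vector `c(lower, mean, upper)`.
#' @examples
#' set.seed(1)
#' bootstrap_ci(rnorm(50))
#' @export
bootstrap_ci <- function(values, level = 0.95, n_boot = 1000) {
  if (length(values) < 2) stop("need at least two values", call. = FALSE)
  boots <- vapply(seq_len(n_boot), function(i) {
    mean(sample(values, length(values), replace = TRUE))
  }, numeric(1))
  q <- stats::quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2),
                       names = FALSE)
  c(lower = q[1], mean = mean(values), upper = q[2])
}

#' Default pipeline configuration
#'
#' Desk-scale defaults for [run_pipeline()]: a shortened session, a modest
#' population and a reduced resample count, so a full four-condition run
#' completes in well under a minute. All blocks can be overridden via a
#' YAML config file or an R list.
#'
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return A nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1) {
  list(
    task = list(session_duration = 600),
    agent = list(),
    population = list(n_excitatory = 40, n_vip = 12),
    analysis = list(n_resamples = 1000, anchor = "onset"),
    stats = list(ci_level = 0.95, n_boot = 1000,
                 ci_method = "bootstrap"),
    conditions = list(A = "familiar", B = "novel", C = "novel",
                      D = "novel"),
    seeds = list(simulate = seed, synthesize = seed + 100,
                 classify = seed + 200, bootstrap = seed + 300)
  )
}

read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  base <- default_pipeline_config()
  base[names(config)] <- config
  base
}

#' Run the full simulation-and-analysis pipeline
#'
#' For each configured image-set condition (by default A familiar and B, C,
#' D novel) this simulates a behavior session, synthesizes excitatory and
#' VIP event traces, computes behavior metrics and per-cell neural
#' summaries, and then compares the preferred-image response magnitude and
#' omission response across image sets (ANOVA + pairwise Welch with
#' Bonferroni correction). Tables, a JSON summary and a run log (seeds and
#' parameter echo) are written to `out_dir` when given.
#'
#' @param config A configuration list (see [default_pipeline_config()]) or
#'   the path to a YAML file with the same structure.
#' @param out_dir Optional output directory.
#' @return An object of class `pipeline_result`: list with `conditions`
#'   (per-condition session, traces, behavior and cell summaries),
#'   `cell_table` (all cells pooled), `fractions` (per condition:
#'   stimulus-driven/suppressed and responsiveness fractions with bootstrap
#'   CIs), `comparisons` and `config`.
#' @examples
#' \donttest{
#' res <- run_pipeline(list(task = list(session_duration = 300)))
#' res$fractions
#' }
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = NULL) {
  cfg <- read_pipeline_config(config)
  task <- do.call(task_params, cfg$task)
  agent <- do.call(agent_params, cfg$agent)
  if (task$session_duration < task$flash_period) {
    stop("configured session too short for a single flash", call. = FALSE)
  }

  conds <- cfg$conditions
  results <- list()
  cell_rows <- list()
  for (i in seq_along(conds)) {
    set_name <- names(conds)[i]
    condition <- conds[[i]]
    pop <- do.call(population_params,
                   c(cfg$population, list(condition = condition)))
    sess <- simulate_session(task, agent,
                             seed = cfg$seeds$simulate + i - 1)
    traces <- generate_event_traces(sess$stimuli, pop,
                                    seed = cfg$seeds$synthesize + i - 1)
    beh <- behavior_summary(sess)
    cells <- summarize_cells(traces, sess$stimuli,
                             n_resamples = cfg$analysis$n_resamples,
                             seed = cfg$seeds$classify + i - 1,
                             anchor = cfg$analysis$anchor)
    frm <- flash_responses(traces, sess$stimuli)
    shown <- !frm$presentations$is_omitted
    pref_resp <- vapply(seq_len(nrow(cells)), function(ci) {
      sel <- shown &
        frm$presentations$image_id == cells$estimated_preferred_image[ci]
      mean(frm$response[ci, sel])
    }, numeric(1))
    om_resp_mag <- if (any(!shown)) {
      rowMeans(frm$response[, !shown, drop = FALSE])
    } else rep(NA_real_, nrow(cells))
    cells$preferred_response <- pref_resp
    cells$omission_response <- om_resp_mag
    cells$image_set <- set_name
    results[[set_name]] <- list(session = sess, traces = traces,
                                behavior = beh, cells = cells)
    cell_rows[[set_name]] <- cells
  }
  cell_table <- do.call(rbind, cell_rows)

  with_seed(cfg$seeds$bootstrap, {
    fractions <- do.call(rbind, lapply(names(results), function(nm) {
      cc <- results[[nm]]$cells
      vip <- cc[cc$cell_class == "vip", ]
      ci <- if (sum(is.finite(cc$preferred_response)) >= 2) {
        bootstrap_ci(cc$preferred_response[is.finite(cc$preferred_response)],
                     level = cfg$stats$ci_level,
                     n_boot = cfg$stats$n_boot)
      } else {
        c(lower = NA_real_, mean = mean(cc$preferred_response),
          upper = NA_real_)
      }
      data.frame(
        image_set = nm,
        condition = conds[[nm]],
        frac_vip_stimulus_suppressed =
          mean(vip$dynamics_class == "stimulus_suppressed"),
        frac_vip_omission_responsive = mean(vip$omission_responsive),
        frac_exc_image_responsive =
          mean(cc$image_responsive[cc$cell_class == "excitatory"]),
        mean_preferred_response = ci[["mean"]],
        preferred_response_ci_lower = ci[["lower"]],
        preferred_response_ci_upper = ci[["upper"]]
      )
    }))
  })

  comparisons <- list()
  for (metric in c("preferred_response", "omission_response")) {
    v <- cell_table[[metric]]
    if (sum(is.finite(v)) >= 8) {
      comparisons[[metric]] <- compare_image_sets(v, cell_table$image_set)
    }
  }

  out <- structure(list(conditions = results, cell_table = cell_table,
                        fractions = fractions, comparisons = comparisons,
                        config = cfg),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ct <- res$cell_table
  utils::write.csv(ct, file.path(out_dir, "cell_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(res$fractions, file.path(out_dir, "fractions.csv"),
                   row.names = FALSE)
  beh <- do.call(rbind, lapply(names(res$conditions), function(nm) {
    cbind(image_set = nm, res$conditions[[nm]]$behavior)
  }))
  utils::write.csv(beh, file.path(out_dir, "behavior_summary.csv"),
                   row.names = FALSE)
  for (nm in names(res$conditions)) {
    write_session_tables(res$conditions[[nm]]$session,
                         file.path(out_dir, paste0("session_", nm)))
  }
  summary <- list(
    fractions = res$fractions,
    comparisons = lapply(res$comparisons, function(cmp) {
      list(anova_F = cmp$anova_F, anova_p = cmp$anova_p,
           corrected_alpha = cmp$corrected_alpha, pairs = cmp$pairs)
    })
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  log_lines <- c(
    sprintf("vipramp pipeline run: %s", format(Sys.time())),
    sprintf("package version: %s",
            as.character(utils::packageVersion("vipramp"))),
    sprintf("seeds: %s",
            paste(names(res$config$seeds), unlist(res$config$seeds),
                  sep = "=", collapse = ", ")),
    "config:",
    utils::capture.output(utils::str(res$config))
  )
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("vipramp pipeline result\n")
  print(x$fractions, row.names = FALSE)
  invisible(x)
}
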