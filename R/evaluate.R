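## Replicated simulation studies: bias, SD, RMSE and coverage of the
## weighted and unweighted estimators over the scenario grid.

msm_variants <- c("weighted_interaction", "weighted_no_interaction",
                  "unweighted_interaction")

#' Separation filter for a simulated dataset
#'
#' A replicate is usable only if each of the four joint-exposure categories
#' `(a1, a2) = (0,0), (1,0), (0,1), (1,1)` -- evaluated at the interval in
#' which the event occurs -- contains at least one event; otherwise the
#' treatment effects are not identifiable and the replicate is discarded.
#'
#' @param panel a `long_panel`.
#' @return `TRUE` iff all four exposure categories contain an event.
#' @export
passes_event_category_filter <- function(panel) {
  ev <- panel[panel$event == 1, , drop = FALSE]
  if (!nrow(ev)) return(FALSE)
  length(unique(paste(ev$a1, ev$a2))) == 4
}

variant_fitter <- function(variant, weight_spec) {
  switch(variant,
    weighted_interaction = function(panel, weights)
      fit_weighted_cox(panel, weights, include_interaction = TRUE),
    weighted_no_interaction = function(panel, weights)
      fit_weighted_cox(panel, weights, include_interaction = FALSE),
    unweighted_interaction = function(panel, weights)
      fit_unweighted_td_cox(panel, include_interaction = TRUE),
    stop_validation("unknown model variant '%s'", variant))
}

## msm_fit coefficient names -> evaluation parameter names
extract_params <- function(fit) {
  map <- c(a1 = "beta1", a2 = "beta2", a1.a2 = "beta3")
  est <- se <- setNames(rep(NA_real_, 3), map)
  keep <- intersect(names(fit$coefficients), names(map))
  est[map[keep]] <- fit$coefficients[keep]
  se[map[keep]] <- fit$robust_se[keep]
  list(est = est, se = se)
}

#' Run a replicated simulation study for one scenario
#'
#' For each replicate: simulate a cohort, apply the event-category
#' separation filter, estimate stabilized weights (when any weighted
#' variant is requested) and fit every requested model variant. Discarded
#' or failed replicates are replaced from fresh derived seeds up to
#' `max_attempt_factor * n_reps` attempts, and the discard count is
#' reported. Metrics are computed against the configured true `beta`.
#'
#' @param config a [sim_config()] (typically from [scenario_config()]).
#' @param n_reps number of kept replicates requested.
#' @param variants subset of
#'   `c("weighted_interaction", "weighted_no_interaction",
#'   "unweighted_interaction")`, or a named list of custom fitter functions
#'   `function(panel, weights)` returning an `msm_fit`-like list with named
#'   `coefficients` and `robust_se`.
#' @param seed master seed for the study; per-replicate seeds are derived
#'   deterministically from it (default: the config's seed).
#' @param weight_spec a [weight_model_spec()] for the weighted variants.
#' @param max_attempt_factor cap on simulation attempts, as a multiple of
#'   `n_reps`.
#' @return A `scenario_run`: per variant, the estimate and SE matrices and
#'   a metrics table (mean estimate, bias, SD, RMSE, coverage of 95% CIs),
#'   plus counts of kept, discarded and estimation-failed replicates and
#'   the per-replicate event counts.
#' @examples
#' \donttest{
#' run <- run_replicates(scenario_config("1A", n_subjects = 300), n_reps = 5)
#' run$variants$weighted_interaction$metrics
#' }
#' @export
run_replicates <- function(config, n_reps,
                           variants = msm_variants,
                           seed = config$seed,
                           weight_spec = weight_model_spec(),
                           max_attempt_factor = 3) {
  if (n_reps < 1) stop_validation("n_reps must be >= 1")
  if (is.list(variants)) {
    fitters <- variants
    if (is.null(names(fitters)) || any(names(fitters) == ""))
      stop_validation("custom variant fitters must be named")
  } else {
    fitters <- setNames(lapply(variants, variant_fitter, weight_spec), variants)
  }
  needs_weights <- is.list(variants) || any(grepl("^weighted", names(fitters)))

  est <- lapply(fitters, function(f) matrix(NA_real_, n_reps, 3,
                                            dimnames = list(NULL, paste0("beta", 1:3))))
  ses <- est
  events <- integer(n_reps)
  kept <- 0L; discarded <- 0L; failed <- 0L; attempt <- 0L
  max_attempts <- ceiling(max_attempt_factor * n_reps)

  while (kept < n_reps && attempt < max_attempts) {
    attempt <- attempt + 1L
    cfg <- config
    cfg$seed <- derive_seed(seed, attempt, salt = 7L)
    panel <- simulate_dataset(cfg)
    if (!passes_event_category_filter(panel)) {
      discarded <- discarded + 1L
      next
    }
    res <- tryCatch({
      w <- if (needs_weights) estimate_weights(panel, weight_spec) else NULL
      lapply(fitters, function(f) extract_params(f(panel, w)))
    }, jointmsm_estimation_error = function(e) NULL)
    if (is.null(res)) {
      failed <- failed + 1L
      next
    }
    kept <- kept + 1L
    events[kept] <- sum(panel$event)
    for (v in names(fitters)) {
      est[[v]][kept, ] <- res[[v]]$est
      ses[[v]][kept, ] <- res[[v]]$se
    }
  }
  if (!kept)
    stop_estimation("all %d attempted replicates were discarded or failed", attempt)
  if (kept < n_reps) {
    est <- lapply(est, function(m) m[seq_len(kept), , drop = FALSE])
    ses <- lapply(ses, function(m) m[seq_len(kept), , drop = FALSE])
    events <- events[seq_len(kept)]
  }

  out_variants <- setNames(lapply(names(fitters), function(v) {
    list(estimates = est[[v]], ses = ses[[v]],
         metrics = summarize_estimates(est[[v]], ses[[v]], config$beta))
  }), names(fitters))
  structure(list(config = config, seed = seed, variants = out_variants,
                 n_requested = n_reps, n_kept = kept, n_discarded = discarded,
                 n_estimation_failures = failed, events = events,
                 mean_events = mean(events)),
            class = "scenario_run")
}

#' Monte-Carlo performance metrics for a matrix of estimates
#'
#' @param estimates,ses replicate-by-parameter matrices (NA columns allowed
#'   for parameters absent from a variant).
#' @param truth vector of generating parameter values.
#' @param level confidence level for the coverage metric.
#' @return Data frame with one row per estimated parameter: mean estimate,
#'   mean bias, SD over replicates, RMSE, coverage (%), Monte-Carlo SE of
#'   the mean.
#' @export
summarize_estimates <- function(estimates, ses, truth, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  rows <- lapply(seq_along(truth), function(j) {
    e <- estimates[, j]
    if (all(is.na(e))) return(NULL)
    s <- ses[, j]
    r <- sum(!is.na(e))
    data.frame(parameter = colnames(estimates)[j], truth = truth[j],
               mean_est = mean(e, na.rm = TRUE),
               bias = mean(e, na.rm = TRUE) - truth[j],
               sd = stats::sd(e, na.rm = TRUE),
               rmse = sqrt(mean((e - truth[j])^2, na.rm = TRUE)),
               coverage = 100 * mean(abs(e - truth[j]) <= z * s, na.rm = TRUE),
               mc_se = stats::sd(e, na.rm = TRUE) / sqrt(r),
               n = r)
  })
  do.call(rbind, rows)
}

#' @export
print.scenario_run <- function(x, ...) {
  cat(sprintf("<scenario_run> %d kept / %d requested replicates (%d discarded by event filter, %d estimation failures)\n",
              x$n_kept, x$n_requested, x$n_discarded, x$n_estimation_failures))
  cat(sprintf("mean events per replicate: %.1f; true beta = (%g, %g, %g)\n",
              x$mean_events, x$config$beta[1], x$config$beta[2], x$config$beta[3]))
  for (v in names(x$variants)) {
    cat(sprintf("-- %s\n", v))
    print(x$variants[[v]]$metrics, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Tidy results table over scenarios
#'
#' One row per (scenario, model variant, parameter) with the full metric
#' set and replicate bookkeeping.
#'
#' @param runs named list of `scenario_run` objects (names are scenario
#'   ids).
#' @param path optional CSV destination.
#' @return A data frame.
#' @export
grid_report <- function(runs, path = NULL) {
  if (!length(runs)) stop_validation("no scenario runs supplied")
  rows <- lapply(names(runs), function(sc) {
    run <- runs[[sc]]
    do.call(rbind, lapply(names(run$variants), function(v) {
      m <- run$variants[[v]]$metrics
      cbind(data.frame(scenario = sc, variant = v), m,
            data.frame(n_kept = run$n_kept, n_discarded = run$n_discarded,
                       mean_events = run$mean_events))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}

#' Bias and coverage stratified by realized event count
#'
#' Splits the kept replicates of one variant into `n_bins` groups at the
#' empirical quantiles of the per-replicate event count and recomputes bias
#' and coverage within each, mirroring performance-versus-events summaries.
#'
#' @param run a `scenario_run`.
#' @param variant variant name within the run.
#' @param n_bins number of event-count strata.
#' @return Data frame with one row per (stratum, parameter).
#' @export
event_strata_summary <- function(run, variant = names(run$variants)[1],
                                 n_bins = 3) {
  v <- run$variants[[variant]]
  if (is.null(v)) stop_validation("variant '%s' not present in run", variant)
  breaks <- unique(quantile(run$events, seq(0, 1, length.out = n_bins + 1),
                            type = 7))
  bins <- cut(run$events, breaks, include.lowest = TRUE)
  do.call(rbind, lapply(levels(bins), function(b) {
    i <- bins == b
    m <- summarize_estimates(v$estimates[i, , drop = FALSE],
                             v$ses[i, , drop = FALSE], run$config$beta)
    cbind(data.frame(events = b), m)
  }))
}
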