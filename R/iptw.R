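## Stabilized inverse-probability-of-treatment weights.
##
## For each treatment, pooled logistic models are fitted on the person-visits
## still untreated at the previous visit (after initiation the conditional
## probability of the observed value is 1 by monotonicity, contributing a
## factor of 1). The stabilized weight at visit m is the cumulative product
## over visits <= m of numerator/denominator probabilities of the observed
## treatment value; the numerator conditions on treatment history and
## baseline confounder only, the denominator additionally on the current
## confounder. With administrative end-of-follow-up censoring only, the
## censoring factor is identically 1.

weight_covariates <- c("lag_other", "L0", "L", "m")

#' Specification of the stabilized-weight models
#'
#' @param numerator covariates of the numerator pooled logistic model;
#'   subset of `c("lag_other", "L0", "L", "m")` where `lag_other` is the
#'   other treatment's lagged indicator and `m` the visit index (linear).
#' @param denominator covariates of the denominator model; must contain the
#'   numerator set. The default adds the current confounder `L`, which is
#'   what makes the weights correct for time-dependent confounding.
#' @param truncation `NULL` for no truncation, or `c(lower, upper)`
#'   percentiles (e.g. `c(1, 99)`) applied to the total weight across all
#'   person-months.
#' @return A `weight_model_spec` object.
#' @export
weight_model_spec <- function(numerator = c("lag_other", "L0", "m"),
                              denominator = c("lag_other", "L0", "L", "m"),
                              truncation = NULL) {
  bad <- setdiff(c(numerator, denominator), weight_covariates)
  if (length(bad))
    stop_validation("unknown weight-model covariate(s): %s (allowed: %s)",
                    paste(bad, collapse = ", "),
                    paste(weight_covariates, collapse = ", "))
  if (!all(numerator %in% denominator))
    stop_validation("numerator covariates must be a subset of denominator covariates")
  if (!is.null(truncation)) {
    if (length(truncation) != 2 || !all(is.finite(truncation)) ||
        truncation[1] < 0 || truncation[2] > 100 ||
        truncation[1] >= truncation[2])
      stop_validation("truncation must be percentiles 0 <= lower < upper <= 100")
  }
  structure(list(numerator = numerator, denominator = denominator,
                 truncation = truncation), class = "weight_model_spec")
}

## lagged treatment indicators and visit index, computed row-wise on the
## sorted panel (lag is 0 at each subject's first visit)
add_history_columns <- function(panel) {
  first <- !duplicated(panel$id)
  lag1 <- c(0, panel$a1[-nrow(panel)])
  lag2 <- c(0, panel$a2[-nrow(panel)])
  panel$lag_a1 <- ifelse(first, 0, lag1)
  panel$lag_a2 <- ifelse(first, 0, lag2)
  panel$m <- panel$start
  panel
}

pooled_logistic <- function(data, response, covs, label) {
  rhs <- if (length(covs)) paste(covs, collapse = " + ") else "1"
  f <- stats::as.formula(paste(response, "~", rhs))
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(f, family = binomial(), data = data, model = FALSE, y = TRUE),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (!fit$converged)
    stop_estimation("pooled logistic model '%s' did not converge", label)
  if (sep || any(abs(coef(fit)) > 20, na.rm = TRUE))
    stop_estimation("perfect or quasi-perfect separation in model '%s'", label)
  fit
}

#' Fit pooled logistic treatment models for stabilized weights
#'
#' For each treatment, numerator and denominator logistic models for
#' initiation are fitted on the person-visits still untreated at the
#' previous visit.
#'
#' @param panel a `long_panel`.
#' @param spec a [weight_model_spec()].
#' @return A `treatment_weight_models` object: per treatment, the fitted
#'   numerator and denominator `glm`s plus risk-set bookkeeping.
#' @export
fit_treatment_models <- function(panel, spec = weight_model_spec()) {
  panel <- add_history_columns(as_long_panel(panel))
  out <- list(spec = spec)
  for (trt in c("a1", "a2")) {
    own_lag <- if (trt == "a1") "lag_a1" else "lag_a2"
    other_lag <- if (trt == "a1") "lag_a2" else "lag_a1"
    rs <- panel[panel[[own_lag]] == 0, , drop = FALSE]
    rs$lag_other <- rs[[other_lag]]
    n_init <- sum(rs[[trt]] == 1)
    if (n_init == 0)
      stop_estimation("no initiation events for treatment %s: model not estimable", trt)
    if (n_init == nrow(rs))
      stop_estimation("every at-risk person-visit initiates treatment %s", trt)
    out[[trt]] <- list(
      numerator = pooled_logistic(rs, trt, spec$numerator,
                                  paste0(trt, " numerator")),
      denominator = pooled_logistic(rs, trt, spec$denominator,
                                    paste0(trt, " denominator")),
      n_risk = nrow(rs), n_init = n_init)
  }
  structure(out, class = "treatment_weight_models")
}

#' @export
print.treatment_weight_models <- function(x, ...) {
  cat("<treatment_weight_models>\n")
  for (trt in c("a1", "a2"))
    cat(sprintf("  %s: %d initiations / %d at-risk person-visits; denominator L coef = %s\n",
                trt, x[[trt]]$n_init, x[[trt]]$n_risk,
                if ("L" %in% names(coef(x[[trt]]$denominator)))
                  format(coef(x[[trt]]$denominator)[["L"]], digits = 4)
                else "(absent)"))
  invisible(x)
}

#' Compute stabilized weights from fitted treatment models
#'
#' Per person-visit, the treatment-specific factor is the ratio of
#' numerator to denominator probability of the observed treatment value
#' while still untreated, and exactly 1 after initiation; stabilized
#' weights are the within-subject cumulative products, and the total weight
#' is the row-wise product `sw = sw_a1 * sw_a2 * sw_c`. The censoring
#' component `sw_c` is identically 1 (censoring occurs only at the
#' administrative end of follow-up).
#'
#' @param panel the `long_panel` the models were fitted on (same schema).
#' @param models a `treatment_weight_models` object.
#' @return A `weight_set` data frame: `id, start, sw_a1, sw_a2, sw_c, sw`,
#'   row-aligned with the sorted panel.
#' @export
compute_stabilized_weights <- function(panel, models) {
  panel <- add_history_columns(as_long_panel(panel))
  sw <- data.frame(id = panel$id, start = panel$start)
  for (trt in c("a1", "a2")) {
    own_lag <- if (trt == "a1") "lag_a1" else "lag_a2"
    other_lag <- if (trt == "a1") "lag_a2" else "lag_a1"
    untreated <- panel[[own_lag]] == 0
    rs <- panel[untreated, , drop = FALSE]
    rs$lag_other <- rs[[other_lag]]
    p_num <- predict(models[[trt]]$numerator, newdata = rs, type = "response")
    p_den <- predict(models[[trt]]$denominator, newdata = rs, type = "response")
    a <- rs[[trt]]
    obs_num <- a * p_num + (1 - a) * (1 - p_num)
    obs_den <- a * p_den + (1 - a) * (1 - p_den)
    if (any(obs_den == 0)) {
      i <- which(obs_den == 0)[1]
      stop_estimation("positivity violation: subject %s, visit %d has denominator probability 0 for %s",
                      format(rs$id[i]), rs$start[i], trt)
    }
    factor <- rep(1, nrow(panel))
    factor[untreated] <- obs_num / obs_den
    sw[[paste0("sw_", trt)]] <- ave(factor, panel$id, FUN = cumprod)
  }
  sw$sw_c <- 1
  sw$sw <- sw$sw_a1 * sw$sw_a2 * sw$sw_c
  structure(sw, class = c("weight_set", "data.frame"))
}

#' One-call stabilized-weight estimation
#'
#' Fits the treatment models and computes the weights; applies percentile
#' truncation to the total weight `sw` when the spec requests it (the
#' per-treatment factors are left untruncated so the factorization of the
#' untruncated weight remains visible).
#'
#' @inheritParams fit_treatment_models
#' @return A `weight_set`, with the fitted models in attribute `models`.
#' @examples
#' p <- simulate_dataset(sim_config(n_subjects = 300, seed = 11))
#' w <- estimate_weights(p)
#' summary(w$sw)
#' @export
estimate_weights <- function(panel, spec = weight_model_spec()) {
  models <- fit_treatment_models(panel, spec)
  ws <- compute_stabilized_weights(panel, models)
  if (!is.null(spec$truncation))
    ws$sw <- truncate_weights(ws$sw, spec$truncation[1], spec$truncation[2])
  attr(ws, "models") <- models
  ws
}

#' Percentile truncation of weights
#'
#' Clips weights to the empirical `lower_pct` / `upper_pct` percentiles of
#' their distribution across all person-months, the standard mitigation for
#' extreme weights. Percentiles use linear interpolation between order
#' statistics (`stats::quantile()` type 7), so results are reproducible
#' bit for bit.
#'
#' @param weights positive weight vector.
#' @param lower_pct,upper_pct percentiles in `[0, 100]`, `lower < upper`.
#' @return The clipped vector.
#' @examples
#' truncate_weights(1:100, 1, 99)
#' @export
truncate_weights <- function(weights, lower_pct = 1, upper_pct = 99) {
  if (lower_pct >= upper_pct)
    stop_validation("lower percentile (%g) must be below upper percentile (%g)",
                    lower_pct, upper_pct)
  bounds <- quantile(weights, c(lower_pct, upper_pct) / 100,
                     names = FALSE, type = 7)
  pmin(pmax(weights, bounds[1]), bounds[2])
}

#' Time-dependent-confounding diagnostics
#'
#' Reproduces the two exploratory checks used to justify weighting:
#' (a) a pooled logistic model of each treatment's initiation on the
#' current confounder in three categories (tertiles of the observed
#' person-month distribution; top tertile = reference), adjusted for the
#' other treatment's lagged indicator, reporting odds
#' ratios; and (b) a linear model of the current
#' confounder on both lagged treatments and the baseline confounder. A
#' treatment is flagged as subject to time-dependent confounding affected
#' by past treatment when both associations are significant at the 5%
#' level.
#'
#' @param panel a `long_panel`.
#' @return A `confounding_diagnostics` object with components
#'   `treatment_prediction` (per treatment: OR table or `"not estimable"`),
#'   `confounder_model` (coefficient table or `"not estimable"`) and
#'   `flagged` (named logical).
#' @export
confounding_diagnostics <- function(panel) {
  panel <- add_history_columns(as_long_panel(panel))
  cuts <- unique(quantile(panel$L, c(0, 1 / 3, 2 / 3, 1)))
  panel$Lcat <- if (length(cuts) < 4) factor(rep("high", nrow(panel))) else
    cut(panel$L, cuts, labels = c("low", "moderate", "high"),
        include.lowest = TRUE)
  panel$Lcat <- stats::relevel(factor(panel$Lcat), ref = "high")

  predict_trt <- function(trt) {
    own_lag <- if (trt == "a1") "lag_a1" else "lag_a2"
    other_lag <- if (trt == "a1") "lag_a2" else "lag_a1"
    rs <- panel[panel[[own_lag]] == 0, , drop = FALSE]
    rs$Lcat <- droplevels(rs$Lcat)
    rs$lag_other <- rs[[other_lag]]
    if (length(unique(rs[[trt]])) < 2 || nlevels(rs$Lcat) < 2)
      return("not estimable")
    fit <- tryCatch(
      stats::glm(stats::as.formula(paste(trt, "~ Lcat + lag_other")),
                 family = binomial(), data = rs),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit) || !fit$converged) return("not estimable")
    s <- summary(fit)$coefficients
    rows <- grep("^Lcat", rownames(s), value = TRUE)
    data.frame(term = sub("^Lcat", "L ", rows),
               odds_ratio = exp(s[rows, "Estimate"]),
               se_log_or = s[rows, "Std. Error"],
               p_value = s[rows, "Pr(>|z|)"], row.names = NULL)
  }

  confounder_model <- local({
    d <- panel[panel$start >= 1, , drop = FALSE]
    if (!nrow(d) || (all(d$lag_a1 == d$lag_a1[1]) && all(d$lag_a2 == d$lag_a2[1])))
      return("not estimable")
    fit <- stats::lm(L ~ lag_a1 + lag_a2 + L0, data = d)
    s <- summary(fit)$coefficients
    rows <- intersect(c("lag_a1", "lag_a2"), rownames(s))
    data.frame(term = rows, estimate = s[rows, "Estimate"],
               se = s[rows, "Std. Error"], p_value = s[rows, "Pr(>|t|)"],
               row.names = NULL)
  })

  tp <- list(a1 = predict_trt("a1"), a2 = predict_trt("a2"))
  flagged <- vapply(c("a1", "a2"), function(trt) {
    a <- tp[[trt]]
    b <- confounder_model
    is.data.frame(a) && any(a$p_value < 0.05) &&
      is.data.frame(b) && paste0("lag_", trt) %in% b$term &&
      b$p_value[b$term == paste0("lag_", trt)] < 0.05
  }, logical(1))
  structure(list(treatment_prediction = tp, confounder_model = confounder_model,
                 flagged = flagged), class = "confounding_diagnostics")
}

#' @export
print.confounding_diagnostics <- function(x, ...) {
  cat("<confounding_diagnostics>\n")
  for (trt in c("a1", "a2")) {
    cat(sprintf("treatment %s: confounder predicts initiation?\n", trt))
    print(x$treatment_prediction[[trt]])
  }
  cat("confounder response to lagged treatment:\n")
  print(x$confounder_model)
  cat(sprintf("time-dependent confounder affected by past treatment: a1=%s, a2=%s\n",
              x$flagged[["a1"]], x$flagged[["a2"]]))
  invisible(x)
}
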