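#' Simulation configuration for a two-treatment longitudinal cohort
#'
#' Bundles every parameter of the data-generating process. Subjects are
#' followed over `n_visits` monthly intervals `[m, m+1)`. A counterfactual
#' (never-treated) survival time `T0` is exponential with rate `lambda0`;
#' the CD4-like confounder tracks the remaining counterfactual survival
#' budget, `L(m) = b + c * log(T0 - H(m)) + k1*A1(m-1) + k2*A2(m-1) + e_m`,
#' where `b ~ N(mu_b, sigma_b^2)` is a subject set-point, `H(m)` is the
#' counterfactual time consumed by visit `m`, and `e_m ~ N(0, sigma_e^2)`.
#' Treatments initiate via logistic models on the current confounder and
#' treatment lags, continue forever once initiated, and act on the hazard
#' through the marginal structural model
#' `lambda(t) = lambda0 * exp(beta1*a1 + beta2*a2 + beta3*a1*a2)`.
#'
#' @param n_subjects number of subjects (cohort size).
#' @param n_visits number of monthly visits `M`; follow-up is
#'   administratively censored at `M` months.
#' @param lambda0 exponential rate (per month) of the counterfactual
#'   survival time; also the untreated hazard.
#' @param c association between the confounder and the log remaining
#'   counterfactual time (CD4 cells per log-month).
#' @param mu_b,sigma_b mean and SD of the subject set-point `b` (cells).
#' @param sigma_e SD of the visit-level confounder noise (cells).
#' @param alpha1,omega1 coefficients of the current confounder `L(m)` in the
#'   initiation models of treatments 1 and 2 (per cell).
#' @param alpha,omega optional full 5-vectors
#'   `(intercept, L, lag A1, lag A2, lag A1 x lag A2)` for the two
#'   initiation models. When `NULL`, the intercept is calibrated so that an
#'   untreated subject at `L = ref_L` initiates with monthly probability
#'   `init_prob`, and both lag coefficients and the product default to 0.5.
#'   A treatment's own lag never reaches its model: once initiated the
#'   treatment continues with probability 1.
#' @param confounder_update length-2 vector: additive effect of each lagged
#'   treatment on the current confounder (cells).
#' @param beta length-3 vector `(beta1, beta2, beta3)` of true marginal log
#'   hazard ratios: treatment 1, treatment 2, interaction.
#' @param ref_L,init_prob reference confounder value and target monthly
#'   initiation probability used to calibrate missing intercepts.
#' @param seed master RNG seed (integer below 2^31).
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(n_subjects = 200, seed = 7)
#' cfg
#' @seealso [scenario_config()], [scenario_grid()], [simulate_dataset()]
#' @export
sim_config <- function(n_subjects = 1000, n_visits = 12, lambda0 = 0.006,
                       c = 6, mu_b = 600, sigma_b = 200, sigma_e = 3,
                       alpha1 = 0.004, omega1 = 0.004,
                       alpha = NULL, omega = NULL,
                       confounder_update = c(a1 = 30, a2 = 30),
                       beta = c(0.5, 0.5, 0.5),
                       ref_L = 600, init_prob = 0.1,
                       seed = 1L) {
  if (length(beta) != 3 || !is.numeric(beta))
    stop_validation("beta must be 3 finite log hazard ratios")
  if (length(confounder_update) != 2 || !is.numeric(confounder_update))
    stop_validation("confounder_update must be 2 finite coefficients")
  if (is.null(alpha)) alpha <- default_initiation_coefs(alpha1, ref_L, init_prob)
  if (is.null(omega)) omega <- default_initiation_coefs(omega1, ref_L, init_prob)
  cfg <- structure(list(
    n_subjects = n_subjects, n_visits = n_visits, lambda0 = lambda0,
    c = c, mu_b = mu_b, sigma_b = sigma_b, sigma_e = sigma_e,
    alpha = alpha, omega = omega,
    confounder_update = setNames(as.numeric(confounder_update), c("a1", "a2")),
    beta = setNames(as.numeric(beta), c("beta1", "beta2", "beta3")),
    seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
}

default_initiation_coefs <- function(coef_L, ref_L, init_prob) {
  c(intercept = qlogis(init_prob) - coef_L * ref_L, L = coef_L,
    lag_a1 = 0.5, lag_a2 = 0.5, lag_prod = 0.5)
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, msg, ...) if (!ok) stop_validation(msg, ...)
  chk(is.numeric(cfg$n_subjects) && length(cfg$n_subjects) == 1 &&
        cfg$n_subjects >= 1 && cfg$n_subjects == floor(cfg$n_subjects),
      "n_subjects must be a positive integer")
  chk(is.numeric(cfg$n_visits) && length(cfg$n_visits) == 1 &&
        cfg$n_visits >= 1 && cfg$n_visits == floor(cfg$n_visits),
      "n_visits must be a positive integer")
  chk(is.numeric(cfg$lambda0) && length(cfg$lambda0) == 1 && cfg$lambda0 > 0,
      "lambda0 must be a positive rate, got %s", format(cfg$lambda0))
  chk(cfg$sigma_b >= 0 && cfg$sigma_e >= 0, "sigma_b and sigma_e must be >= 0")
  chk(length(cfg$beta) == 3 && all(is.finite(cfg$beta)),
      "beta must be 3 finite log hazard ratios")
  chk(length(cfg$alpha) == 5 && length(cfg$omega) == 5,
      "alpha and omega must have 5 components (intercept, L, lags, product)")
  chk(length(cfg$confounder_update) == 2 &&
        all(is.finite(cfg$confounder_update)),
      "confounder_update must be 2 finite coefficients")
  chk(is.finite(cfg$seed) && abs(cfg$seed) < 2^31, "seed must fit in 32 bits")
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  cohort: %d subjects x %d monthly visits\n",
              x$n_subjects, x$n_visits))
  cat(sprintf("  counterfactual hazard lambda0 = %g /month\n", x$lambda0))
  cat(sprintf("  confounder: b ~ N(%g, %g^2), c = %g, sigma_e = %g, ",
              x$mu_b, x$sigma_b, x$c, x$sigma_e))
  cat(sprintf("treatment lifts = (%g, %g)\n",
              x$confounder_update[1], x$confounder_update[2]))
  cat(sprintf("  initiation: alpha1 = %g, omega1 = %g\n",
              x$alpha[["L"]], x$omega[["L"]]))
  cat(sprintf("  true effects: beta1 = %g, beta2 = %g, beta3 = %g\n",
              x$beta[1], x$beta[2], x$beta[3]))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

## Table of the 15 evaluation sub-cases: three confounding cases for
## treatment 2 crossed with five true-effect sets. alpha1 is 0.004
## throughout; case 3 removes both arrows touching A2 (L -> A2 and A2 -> L).
scenario_table <- function() {
  cases <- data.frame(
    case = c("1", "2", "3"),
    omega1 = c(0.004, 0.001, 0),
    k2 = c(30, 30, 0),
    label = c("strong confounding for A2", "weak confounding for A2",
              "no confounding for A2")
  )
  effects <- data.frame(
    set = c("A", "B", "C", "D", "E"),
    beta1 = c(0.5, 0.5, 0, 0, 0),
    beta2 = c(0.5, 0.5, 0.5, 0, 0),
    beta3 = c(0, 0.5, 0, 0.5, 0)
  )
  out <- merge(cases, effects)
  out$id <- paste0(out$case, out$set)
  out[order(out$case, out$set),
      c("id", "case", "set", "omega1", "k2", "beta1", "beta2", "beta3", "label")]
}

#' Configuration for one of the 15 evaluation sub-cases
#'
#' Sub-cases are labelled `"1A"` to `"3E"`: the digit selects the degree of
#' time-dependent confounding for treatment 2 (1 strong, `omega1 = 0.004`;
#' 2 weak, `omega1 = 0.001`; 3 none, `omega1 = 0` and no effect of treatment
#' 2 on the confounder), the letter selects the true-effect set
#' (A `(0.5, 0.5, 0)`, B `(0.5, 0.5, 0.5)`, C `(0, 0.5, 0)`,
#' D `(0, 0, 0.5)`, E `(0, 0, 0)`). Treatment 1 keeps `alpha1 = 0.004`
#' throughout.
#'
#' @param id sub-case label, e.g. `"1B"`.
#' @param ... overrides passed on to [sim_config()] (commonly `n_subjects`,
#'   `seed`, `lambda0`).
#' @return A [sim_config()] object.
#' @examples
#' scenario_config("2B", n_subjects = 100)$beta
#' @export
scenario_config <- function(id, ...) {
  tab <- scenario_table()
  row <- tab[tab$id == id, ]
  if (nrow(row) != 1)
    stop_validation("unknown scenario id '%s' (expected one of %s)",
                    id, paste(tab$id, collapse = ", "))
  args <- list(...)
  fixed <- list(omega1 = row$omega1,
                confounder_update = c(a1 = 30, a2 = row$k2),
                beta = c(row$beta1, row$beta2, row$beta3))
  clash <- intersect(names(args), c(names(fixed), "alpha1", "omega"))
  if (length(clash))
    stop_validation("cannot override scenario-defining parameter(s): %s",
                    paste(clash, collapse = ", "))
  do.call(sim_config, utils::modifyList(fixed, args))
}

#' All 15 scenario configurations
#'
#' The cross of confounding cases 1-3 with effect sets A-E, every other
#' parameter at its default. See [scenario_config()] for the labelling.
#'
#' @param ... overrides applied to every sub-case (e.g. `n_subjects`, `seed`).
#' @return Named list of 15 [sim_config()] objects, `"1A"` ... `"3E"`.
#' @examples
#' length(scenario_grid())
#' scenario_grid(n_subjects = 50)[["3E"]]$beta
#' @export
scenario_grid <- function(...) {
  ids <- scenario_table()$id
  setNames(lapply(ids, scenario_config, ...), ids)
}
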