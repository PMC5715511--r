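## Data generation
##
## The generator follows the classical counterfactual-budget construction:
## a never-treated survival time T0 ~ Exp(lambda0) is "spent" at rate
## exp(beta' a(u)) while treated, so the observed hazard at every instant is
## exactly lambda0 * exp(beta1 a1 + beta2 a2 + beta3 a1 a2) -- the marginal
## structural model the estimators target. The confounder is anchored to the
## remaining budget, which is what makes it a genuine time-dependent
## confounder: it predicts the event, responds to past treatment, and
## predicts future treatment.

#' Draw counterfactual (never-treated) survival times
#'
#' @param n number of draws.
#' @param lambda0 exponential rate per month; must be positive.
#' @param seed optional seed applied before drawing.
#' @return Vector of `n` positive times in months.
#' @examples
#' mean(draw_counterfactual_times(1000, 0.01, seed = 1)) # ~ 100
#' @export
draw_counterfactual_times <- function(n, lambda0, seed = NULL) {
  if (!is.numeric(lambda0) || length(lambda0) != 1 || !is.finite(lambda0) ||
      lambda0 <= 0)
    stop_validation("lambda0 must be a positive rate, got %s", format(lambda0))
  if (!is.null(seed)) set.seed(seed)
  stats::rexp(n, rate = lambda0)
}

#' Baseline confounder values
#'
#' `L(0) = b + c * log(T0) + e0` with `b ~ N(mu_b, sigma_b^2)` and
#' `e0 ~ N(0, sigma_e^2)`. Subjects with longer counterfactual survival
#' start with higher confounder values, which is the seed of all
#' confounding in the generator.
#'
#' @param T0 vector of positive counterfactual times.
#' @param config a [sim_config()].
#' @param b,noise optional pre-drawn subject set-points and noise (same
#'   length as `T0`); drawn internally when `NULL`.
#' @return Vector of baseline confounder values.
#' @export
init_baseline_confounder <- function(T0, config, b = NULL, noise = NULL) {
  if (any(T0 <= 0)) stop_validation("T0 must be positive elementwise")
  n <- length(T0)
  if (is.null(b)) b <- rnorm(n, config$mu_b, config$sigma_b)
  if (is.null(noise)) noise <- rnorm(n, 0, config$sigma_e)
  update_confounder(b, T0, 0, 0, config, noise)
}

#' Confounder value at a follow-up visit
#'
#' `L(m) = b + c * log(remaining) + k1 * A1(m-1) + k2 * A2(m-1) + e_m`,
#' where `remaining = T0 - H(m)` is the counterfactual survival budget not
#' yet consumed at visit `m` (equal to `T0` at baseline, so the baseline
#' formula is the special case with zero treatment lags). Past treatment
#' lifts the confounder by the `confounder_update` coefficients; the
#' remaining-budget term keeps the confounder prognostic at every visit.
#'
#' @param b subject set-point(s).
#' @param remaining remaining counterfactual budget(s), must be positive
#'   (subjects still at risk).
#' @param A1_prev,A2_prev lagged treatment indicators.
#' @param config a [sim_config()] (uses `c` and `confounder_update`).
#' @param noise visit-level noise draw(s), `N(0, sigma_e^2)` in generation.
#' @return Confounder value(s).
#' @export
update_confounder <- function(b, remaining, A1_prev, A2_prev, config, noise) {
  if (any(remaining <= 0))
    stop_validation("remaining budget must be positive for at-risk subjects")
  k <- config$confounder_update
  b + config$c * log(remaining) + k[["a1"]] * A1_prev + k[["a2"]] * A2_prev +
    noise
}

#' Monthly treatment-initiation probability
#'
#' Inverse-logit of `intercept + coef_L * L(m) + c3 * A1(m-1) +
#' c4 * A2(m-1) + c5 * A1(m-1) * A2(m-1)`, except that a treatment already
#' initiated continues with probability exactly 1 (monotone treatment).
#'
#' @param L_m current confounder value(s).
#' @param A1_prev,A2_prev lagged treatment indicators.
#' @param coeffs 5-vector as in `sim_config()$alpha` / `$omega`.
#' @param treatment which treatment the probability is for (1 or 2); decides
#'   which lag is the "own" lag that forces continuation.
#' @return Probability vector.
#' @examples
#' cf <- sim_config(n_subjects = 1)$alpha
#' treatment_initiation_probability(600, 1, 0, cf, treatment = 1) # 1
#' @export
treatment_initiation_probability <- function(L_m, A1_prev, A2_prev, coeffs,
                                             treatment = 1L) {
  lp <- coeffs[[1]] + coeffs[[2]] * L_m + coeffs[[3]] * A1_prev +
    coeffs[[4]] * A2_prev + coeffs[[5]] * A1_prev * A2_prev
  own <- if (treatment == 1L) A1_prev else A2_prev
  ifelse(own == 1, 1, plogis(lp))
}

#' Observed survival time under piecewise-constant treatment paths
#'
#' Inverts the cumulative-hazard budget equation: the observed time `T`
#' solves `integral_0^T exp(beta1 a1(u) + beta2 a2(u) + beta3 a1(u) a2(u))
#' du = T0`, with `a(u)` constant on each interval `[m, m+1)`. The event is
#' attributed to the visit interval containing `T`; subjects whose budget
#' outlasts `M` intervals are administratively censored at `M`.
#'
#' @param T0 counterfactual survival time.
#' @param a1_path,a2_path binary treatment values at visits `0 .. M-1`.
#' @param beta length-3 vector of true marginal log hazard ratios.
#' @return List with `time` (observed, equals `M` when censored), `event`
#'   (0/1) and `event_visit` (`NA` when censored).
#' @examples
#' derive_observed_outcome(5, rep(0, 12), rep(0, 12), c(0.5, 0.5, 0.5))$time
#' @export
derive_observed_outcome <- function(T0, a1_path, a2_path, beta) {
  M <- length(a1_path)
  stopifnot(length(a2_path) == M, T0 > 0)
  u <- exp(beta[1] * a1_path + beta[2] * a2_path + beta[3] * a1_path * a2_path)
  H <- cumsum(u)                       # budget consumed by end of each interval
  if (T0 > H[M])
    return(list(time = M, event = 0L, event_visit = NA_integer_))
  m <- which(H >= T0)[1] - 1L          # event interval [m, m+1)
  consumed <- if (m == 0L) 0 else H[m]
  list(time = m + (T0 - consumed) / u[m + 1L], event = 1L, event_visit = m)
}

## Fixed-position uniform blocks: subject i always reads block i of the
## stream, so its draws do not depend on the cohort size and a cohort is a
## prefix of any larger cohort with the same seed.
subject_draws <- function(config) {
  n <- config$n_subjects
  M <- config$n_visits
  set.seed(config$seed)
  U <- matrix(runif(n * (2 + 3 * M)), nrow = n, byrow = TRUE)
  list(T0 = qexp(U[, 1], rate = config$lambda0),
       b = qnorm(U[, 2], config$mu_b, config$sigma_b),
       E = qnorm(U[, 3:(2 + M), drop = FALSE], 0, config$sigma_e),
       U1 = U[, (3 + M):(2 + 2 * M), drop = FALSE],
       U2 = U[, (3 + 2 * M):(2 + 3 * M), drop = FALSE])
}

#' Simulate a longitudinal two-treatment cohort
#'
#' Sequential per-subject generation: counterfactual time, baseline
#' confounder, then visit by visit treatment draws, budget consumption and
#' confounder updates, producing a counting-process panel with one row per
#' person-visit up to and including the event interval.
#'
#' The result is a `long_panel` data frame with columns `id`, `start`,
#' `stop`, `event`, `a1`, `a2`, `L`, `L0` and two attributes: `subjects`
#' (per-subject summary with exact event times `T0`, `time`, `event_visit`)
#' and `config`.
#'
#' @param config a [sim_config()].
#' @return A `long_panel` data frame.
#' @examples
#' p <- simulate_dataset(sim_config(n_subjects = 50, seed = 3))
#' head(p)
#' monthly_event_rate(p)
#' @export
simulate_dataset <- function(config) {
  config <- validate_sim_config(config)
  n <- config$n_subjects
  M <- config$n_visits
  d <- subject_draws(config)
  beta <- config$beta

  H <- numeric(n)                          # consumed budget at current visit
  A1 <- A2 <- integer(n)
  at_risk <- rep(TRUE, n)
  time <- rep(as.numeric(M), n)
  event_visit <- rep(NA_integer_, n)

  cols <- c("id", "start", "event", "a1", "a2", "L")
  acc <- setNames(vector("list", length(cols)), cols)
  for (m in 0:(M - 1)) {
    idx <- which(at_risk)
    if (!length(idx)) break
    L <- update_confounder(d$b[idx], d$T0[idx] - H[idx],
                           A1[idx], A2[idx], config, d$E[idx, m + 1])
    p1 <- treatment_initiation_probability(L, A1[idx], A2[idx],
                                           config$alpha, treatment = 1L)
    p2 <- treatment_initiation_probability(L, A1[idx], A2[idx],
                                           config$omega, treatment = 2L)
    A1[idx] <- as.integer(d$U1[idx, m + 1] < p1)
    A2[idx] <- as.integer(d$U2[idx, m + 1] < p2)
    u <- exp(beta[1] * A1[idx] + beta[2] * A2[idx] +
               beta[3] * A1[idx] * A2[idx])
    rem <- d$T0[idx] - H[idx]
    ev <- rem <= u                         # event inside [m, m+1)
    acc$id[[m + 1]] <- idx
    acc$start[[m + 1]] <- rep.int(m, length(idx))
    acc$event[[m + 1]] <- as.integer(ev)
    acc$a1[[m + 1]] <- A1[idx]
    acc$a2[[m + 1]] <- A2[idx]
    acc$L[[m + 1]] <- L
    time[idx[ev]] <- m + rem[ev] / u[ev]
    event_visit[idx[ev]] <- m
    H[idx] <- H[idx] + u
    at_risk[idx[ev]] <- FALSE
  }

  panel <- data.frame(id = unlist(acc$id), start = unlist(acc$start),
                      event = unlist(acc$event), a1 = unlist(acc$a1),
                      a2 = unlist(acc$a2), L = unlist(acc$L))
  panel <- panel[order(panel$id, panel$start), ]
  panel$stop <- panel$start + 1L
  first <- !duplicated(panel$id)
  panel$L0 <- panel$L[first][match(panel$id, panel$id[first])]
  panel <- panel[, c("id", "start", "stop", "event", "a1", "a2", "L", "L0")]
  rownames(panel) <- NULL
  class(panel) <- c("long_panel", "data.frame")
  attr(panel, "subjects") <- data.frame(
    id = seq_len(n), T0 = d$T0, b = d$b, time = time,
    event = as.integer(!is.na(event_visit)), event_visit = event_visit)
  attr(panel, "config") <- config
  panel
}

#' Realized per-interval event proportion
#'
#' Events divided by person-intervals; the quantity the generator's
#' `lambda0` is calibrated against (target band roughly 0.1--2% per month).
#'
#' @param panel a `long_panel`.
#' @return A single proportion.
#' @export
monthly_event_rate <- function(panel) sum(panel$event) / nrow(panel)

#' Calibrate `lambda0` to a target monthly event proportion
#'
#' Sweeps a log-spaced grid of candidate rates, simulates a moderate cohort
#' at each, and returns the candidate whose realized per-interval event
#' proportion is closest to `target`.
#'
#' @param config a [sim_config()] whose other parameters are kept.
#' @param target desired monthly event proportion.
#' @param lambdas candidate rates; default 25 points in `[1e-4, 0.05]`.
#' @param n_subjects cohort size used for each probe.
#' @return The selected rate, with the probed grid and realized rates
#'   attached as attributes.
#' @export
calibrate_lambda0 <- function(config, target = 0.01,
                              lambdas = exp(seq(log(1e-4), log(0.05),
                                                length.out = 25)),
                              n_subjects = 4000) {
  rates <- vapply(lambdas, function(l) {
    cfg <- config
    cfg$lambda0 <- l
    cfg$n_subjects <- n_subjects
    monthly_event_rate(simulate_dataset(cfg))
  }, numeric(1))
  best <- which.min(abs(rates - target))
  structure(lambdas[best], grid = lambdas, realized = rates)
}
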