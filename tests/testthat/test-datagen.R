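test_that("counterfactual times are exponential and reproducible", {
  t0 <- draw_counterfactual_times(1e5, 0.01, seed = 42)
  se_mean <- 100 / sqrt(1e5)
  expect_lt(abs(mean(t0) - 100), 3 * se_mean)
  p12 <- mean(t0 > 12)
  se_p <- sqrt(p12 * (1 - p12) / 1e5)
  expect_lt(abs(p12 - exp(-0.12)), 3 * se_p)
  expect_identical(t0, draw_counterfactual_times(1e5, 0.01, seed = 42))
  expect_error(draw_counterfactual_times(10, 0), "positive rate",
               class = "jointmsm_validation_error")
})

test_that("baseline confounder follows b + c log T0 + e", {
  cfg0 <- sim_config(c = 0, sigma_b = 0, sigma_e = 0, n_subjects = 10)
  expect_equal(init_baseline_confounder(rexp(10, 1) + 0.5, cfg0),
               rep(600, 10))
  cfg <- sim_config(n_subjects = 1)
  expect_equal(
    init_baseline_confounder(exp(1), cfg, b = 600, noise = 0), 606)
  expect_error(init_baseline_confounder(c(1, -2), cfg),
               class = "jointmsm_validation_error")

  # empirical cov(L0, log T0) = c * Var(log T0), Monte-Carlo check
  set.seed(7)
  T0 <- draw_counterfactual_times(1e5, 0.006)
  L0 <- init_baseline_confounder(T0, sim_config(n_subjects = 1e5))
  x <- log(T0)
  prod_dev <- (L0 - mean(L0)) * (x - mean(x))
  se_cov <- sd(prod_dev) / sqrt(1e5)
  expect_lt(abs(cov(L0, x) - 6 * pi^2 / 6), 3 * se_cov)
})

test_that("initiation probability is logistic with monotone continuation", {
  cf <- c(0, 0, 0, 0, 0)
  expect_equal(treatment_initiation_probability(550, 1, 0, cf, 1), 1)
  expect_equal(treatment_initiation_probability(550, 0, 1, cf, 2), 1)
  expect_equal(treatment_initiation_probability(550, 0, 0, cf, 1), 0.5)
  # intercept -> -Inf: nobody initiates, cohort stays in category (0,0)
  expect_equal(
    treatment_initiation_probability(550, 0, 0, c(-Inf, 0.004, 0, 0, 0), 1), 0)
  # vectorized over the confounder
  p <- treatment_initiation_probability(c(400, 600), c(0, 0), c(0, 0),
                                        sim_config(n_subjects = 1)$alpha, 1)
  expect_true(p[2] > p[1])
})

test_that("confounder update reads off its coefficients", {
  cfg <- sim_config(n_subjects = 1)
  expect_equal(update_confounder(600, exp(1), 0, 0, cfg, 0), 606)
  # treatment lifts enter additively with the configured coefficients
  expect_equal(update_confounder(600, exp(1), 1, 1, cfg, 0) -
                 update_confounder(600, exp(1), 0, 0, cfg, 0), 60)
  expect_error(update_confounder(600, -1, 0, 0, cfg, 0),
               class = "jointmsm_validation_error")
})

test_that("never-treated at-risk confounder mean matches the memoryless oracle", {
  # with no treatment, remaining budget at visit m is Exp(lambda0) by
  # memorylessness, so E[L(m)] = mu_b + c * (-gamma - log lambda0) at all m
  none <- c(-Inf, 0, 0, 0, 0)
  cfg <- sim_config(n_subjects = 8000, alpha = none, omega = none,
                    beta = c(0, 0, 0), seed = 31)
  p <- simulate_dataset(cfg)
  expected <- 600 + 6 * (digamma(1) - log(0.006))
  for (m in c(0, 6, 11)) {
    Lm <- p$L[p$start == m]
    expect_lt(abs(mean(Lm) - expected), 3 * sd(Lm) / sqrt(length(Lm)))
  }
})

test_that("observed outcome inverts the cumulative-hazard budget", {
  beta <- c(0.5, 0.5, 0.5)
  none <- rep(0, 12)
  expect_equal(derive_observed_outcome(7.3, none, none, beta)$time, 7.3)
  both <- rep(1, 12)
  out <- derive_observed_outcome(2, both, both, beta)
  expect_equal(out$time, 2 * exp(-1.5))
  expect_identical(out$event_visit, 0L)
  # A1 from month 2, beta = (0.5, 0, 0), T0 = 5: two months at rate 1 then
  # the remaining 3 budget units at rate exp(0.5)
  a1 <- c(0, 0, rep(1, 10))
  out <- derive_observed_outcome(5, a1, none, c(0.5, 0, 0))
  expect_equal(out$time, 2 + 3 * exp(-0.5))
  expect_equal(oracle_invert_budget(5, a1, none, c(0.5, 0, 0))$time,
               out$time, tolerance = 1e-10)
  # censoring past the follow-up horizon
  out <- derive_observed_outcome(40, none, none, beta)
  expect_identical(out$event, 0L)
  expect_equal(out$time, 12)
})

test_that("simulated panels satisfy the structural invariants", {
  cfg <- scenario_config("1B", n_subjects = 1000, seed = 17)
  p <- simulate_dataset(cfg)
  expect_s3_class(p, "long_panel")
  expect_lte(nrow(p), 12000)
  expect_identical(p, as_long_panel(as.data.frame(p))) # invariants green

  # rows stop at the event interval; event is terminal
  s <- attr(p, "subjects")
  last <- p[!duplicated(p$id, fromLast = TRUE), ]
  dead <- s$id[s$event == 1]
  expect_setequal(last$id[last$event == 1], dead)
  expect_equal(last$start[match(dead, last$id)], s$event_visit[s$event == 1])

  # budget consistency: re-deriving the outcome from the realized paths
  # recovers the generator's exact event times and the numeric oracle
  ids <- sample(s$id[s$event == 1], 40)
  for (i in ids) {
    rows <- p[p$id == i, ]
    M <- cfg$n_visits
    pad <- function(a) c(a, rep(a[length(a)], M - length(a)))
    out <- derive_observed_outcome(s$T0[i], pad(rows$a1), pad(rows$a2),
                                   cfg$beta)
    expect_equal(out$time, s$time[i], tolerance = 1e-10)
    orc <- oracle_invert_budget(s$T0[i], pad(rows$a1), pad(rows$a2), cfg$beta)
    expect_equal(orc$time, s$time[i], tolerance = 1e-9)
  }
})

test_that("generation is deterministic and subject draws are invariant to n", {
  cfg <- scenario_config("1A", n_subjects = 120, seed = 5)
  p1 <- simulate_dataset(cfg)
  p2 <- simulate_dataset(cfg)
  expect_identical(p1, p2)
  small <- simulate_dataset(scenario_config("1A", n_subjects = 60, seed = 5))
  strip <- function(d) {
    d <- as.data.frame(d)
    attributes(d)[c("subjects", "config")] <- NULL
    rownames(d) <- NULL
    d
  }
  expect_equal(strip(small), strip(p1[p1$id <= 60, ]))
  expect_equal(attr(small, "subjects"), attr(p1, "subjects")[1:60, ])
})

test_that("null generation reduces to the counterfactual law", {
  none <- c(-Inf, 0, 0, 0, 0)
  cfg <- sim_config(n_subjects = 1e4, alpha = none, omega = none,
                    beta = c(0, 0, 0), seed = 23)
  p <- simulate_dataset(cfg)
  expect_equal(sum(p$a1) + sum(p$a2), 0)
  s <- attr(p, "subjects")
  tev <- s$time[s$event == 1]
  ks <- suppressWarnings(
    stats::ks.test(tev, function(q) pexp(q, 0.006) / pexp(12, 0.006)))
  expect_gt(ks$p.value, 0.001)
})

test_that("treatment-independent confounder under null coefficients", {
  cfg <- sim_config(n_subjects = 3000, alpha1 = 0, omega1 = 0,
                    confounder_update = c(0, 0), beta = c(0, 0, 0), seed = 13)
  p <- jointmsm:::add_history_columns(simulate_dataset(cfg))
  d <- p[p$start >= 1, ]
  fit <- lm(L ~ lag_a1 + lag_a2 + L0, data = d)
  # errors are clustered within subject (shared set-point), so use a
  # cluster-robust sandwich for the null check
  X <- model.matrix(fit)
  e <- residuals(fit)
  bread <- solve(crossprod(X))
  scores <- rowsum(X * e, d$id)
  vc <- bread %*% crossprod(as.matrix(scores)) %*% bread
  se <- sqrt(diag(vc))[c("lag_a1", "lag_a2")]
  expect_lt(abs(coef(fit)[["lag_a1"]]), 3 * se[["lag_a1"]])
  expect_lt(abs(coef(fit)[["lag_a2"]]), 3 * se[["lag_a2"]])
})

test_that("higher confounder values mean more initiation (confounding direction)", {
  p <- jointmsm:::add_history_columns(quick_sim(4000, seed = 3))
  rs <- p[p$lag_a1 == 0, ]
  tert <- cut(rs$L, quantile(rs$L, c(0, 1 / 3, 2 / 3, 1)),
              include.lowest = TRUE)
  rates <- tapply(rs$a1, tert, mean)
  expect_gt(rates[3], rates[1])
})

test_that("scenario grid reproduces the 15 sub-cases", {
  grid <- scenario_grid(n_subjects = 10)
  expect_length(grid, 15)
  expect_named(grid, paste0(rep(1:3, each = 5), rep(LETTERS[1:5], 3)))
  expect_equal(grid[["2B"]]$omega[["L"]], 0.001)
  expect_equal(unname(grid[["2B"]]$beta), c(0.5, 0.5, 0.5))
  expect_equal(grid[["3E"]]$omega[["L"]], 0)
  expect_equal(unname(grid[["3E"]]$beta), c(0, 0, 0))
  # case 3 removes both arrows touching A2
  expect_equal(grid[["3A"]]$confounder_update[["a2"]], 0)
  expect_equal(grid[["1A"]]$confounder_update[["a2"]], 30)
  expect_error(scenario_config("4A"), "unknown scenario",
               class = "jointmsm_validation_error")
  expect_error(scenario_config("1A", beta = c(1, 1, 1)),
               "scenario-defining", class = "jointmsm_validation_error")
})

test_that("config validation rejects bad parameters before generation", {
  expect_error(sim_config(lambda0 = -1), class = "jointmsm_validation_error")
  expect_error(sim_config(n_subjects = 0), class = "jointmsm_validation_error")
  expect_error(sim_config(beta = c(1, 2)), class = "jointmsm_validation_error")
  expect_error(sim_config(sigma_b = -5), class = "jointmsm_validation_error")
})

test_that("realized monthly event rate sits in the intended band", {
  expect_gt(monthly_event_rate(quick_sim(4000, seed = 9, "1A")), 0.001)
  expect_lt(monthly_event_rate(quick_sim(4000, seed = 9, "1B")), 0.02)
})
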