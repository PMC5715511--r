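# Independent oracles used against the implementation paths.

# Numeric inversion of the cumulative-hazard budget equation by root
# finding: H(t) accumulated with a naive per-interval loop, inverted with
# uniroot. Independent of the closed-form division in
# derive_observed_outcome().
oracle_invert_budget <- function(T0, a1_path, a2_path, beta) {
  M <- length(a1_path)
  rate <- function(k) exp(beta[1] * a1_path[k] + beta[2] * a2_path[k] +
                            beta[3] * a1_path[k] * a2_path[k])
  H <- function(t) {
    s <- 0
    full <- floor(t)
    for (k in seq_len(min(full, M))) s <- s + rate(k)
    if (t > full && full < M) s <- s + (t - full) * rate(full + 1)
    s
  }
  if (H(M) < T0) return(list(time = M, event = 0L))
  root <- uniroot(function(t) H(t) - T0, c(0, M), tol = 1e-13)
  list(time = root$root, event = 1L)
}

# Hand-written weighted Breslow partial log-likelihood on counting-process
# rows, maximized by optim. The design matrix is built explicitly; risk
# sets are recomputed per event time. Used to cross-check coxph-based fits.
oracle_breslow_loglik <- function(beta, X, d, w) {
  eta <- drop(X %*% beta)
  r <- exp(eta)
  ll <- 0
  for (t in sort(unique(d$stop[d$event == 1]))) {
    dead <- d$event == 1 & d$stop == t
    risk <- d$start < t & t <= d$stop
    ll <- ll + sum(w[dead] * eta[dead]) -
      sum(w[dead]) * log(sum(w[risk] * r[risk]))
  }
  ll
}

oracle_breslow_fit <- function(panel, covariate_cols, w = rep(1, nrow(panel))) {
  d <- as.data.frame(panel)
  X <- as.matrix(d[covariate_cols])
  if ("a1:a2" %in% covariate_cols) stop("build the product column explicitly")
  opt <- optim(rep(0, ncol(X)), function(b) -oracle_breslow_loglik(b, X, d, w),
               method = "BFGS", control = list(reltol = 1e-15, maxit = 2000))
  setNames(opt$par, covariate_cols)
}

# Sort-based percentile oracle (type-7 linear interpolation written out).
oracle_percentile <- function(x, p) {
  xs <- sort(x)
  h <- (length(xs) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}
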