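# Shared fixtures for the suite. Fits are cached so several test files can
# reuse the same small posterior without refitting.

.fixture_env <- new.env(parent = emptyenv())

# Generating parameters used throughout: a trial whose baseline marginal
# daily loss is around 1000 SEK/day with roughly 40% abstinent weeks, a
# sharp drop at treatment start and a small arm gap.
default_truth <- function() {
  twopart_params(
    beta_occ = c(0.4, -0.8, -0.05, 0.02, -0.3, -0.02, 0.01),
    beta_amt = c(7.2, -0.9, -0.04, 0.02, -0.2, -0.02, 0.01),
    shape = 1.2, sd_occ = 1, sd_amt = 0.8, rho = 0.5
  )
}

# Reduced MCMC settings for tests: short chains, relaxed gate.
test_mcmc <- function(chains = 2, adapt = 250, burn = 250, iter = 500,
                      rhat_gate = 1.1) {
  mcmc_config(chains = chains, adapt = adapt, burn = burn, iter = iter,
              rhat_gate = rhat_gate)
}

# One cached fit of model-generated data (60 subjects x 14 weeks).
shared_twopart_fit <- function() {
  if (is.null(.fixture_env$fit)) {
    sim <- generate_from_model(default_truth(), list(n_subjects = 60),
                               seed = 424242)
    .fixture_env$sim <- sim
    .fixture_env$fit <- suppressWarnings(
      fit_twopart(sim$weekly, sim$design, mcmc = test_mcmc(), seed = 99)
    )
  }
  list(sim = .fixture_env$sim, fit = .fixture_env$fit)
}

# Independent restricted-cubic-spline transcription: direct truncated-power
# formula, written without reference to the package implementation.
rcs_oracle <- function(x, k) {
  stopifnot(length(k) == 3)
  tp3 <- function(u) ifelse(u > 0, u^3, 0)
  nl <- (tp3(x - k[1]) -
           tp3(x - k[2]) * (k[3] - k[1]) / (k[3] - k[2]) +
           tp3(x - k[3]) * (k[2] - k[1]) / (k[3] - k[2])) / (k[3] - k[1])^2
  cbind(x, nl)
}

# Independent linear-interpolation percentile oracle: h = (n-1)p + 1
# between order statistics.
percentile_oracle <- function(v, p) {
  v <- sort(v)
  n <- length(v)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  v[lo] + (h - lo) * (v[hi] - v[lo])
}

# Independent two-part log-density transcription (written from the density
# formula, not via dgamma).
twopart_loglik_oracle <- function(y, eta_occ, eta_amt, shape) {
  p <- 1 / (1 + exp(-eta_occ))
  ll <- 0
  for (i in seq_along(y)) {
    if (y[i] == 0) {
      ll <- ll + log(1 - p[i])
    } else {
      mu <- exp(eta_amt[i])
      rate <- shape / mu
      ll <- ll + log(p[i]) +
        shape * log(rate) + (shape - 1) * log(y[i]) - rate * y[i] -
        lgamma(shape)
    }
  }
  ll
}

# Items summing to a target total for a sum-scored instrument.
items_for_total <- function(total, n_items, item_max) {
  items <- integer(n_items)
  full <- total %/% item_max
  items[seq_len(full)] <- item_max
  if (total %% item_max > 0) items[full + 1] <- total %% item_max
  items
}

# NODS probe items endorsing exactly `total` criteria (deterministic: uses
# the first items of each criterion in the standard layout order).
nods_items_for_total <- function(total) {
  # criterion -> (items, all-required?) in standard layout order
  crit <- list(
    list(1:2, FALSE), list(3, FALSE), list(4:5, TRUE), list(6:7, TRUE),
    list(8, FALSE), list(9, FALSE), list(10:11, TRUE), list(12, FALSE),
    list(13:15, FALSE), list(16:17, FALSE)
  )
  items <- integer(17)
  for (ci in seq_len(total)) {
    idx <- crit[[ci]][[1]]
    if (crit[[ci]][[2]]) items[idx] <- 1L else items[idx[1]] <- 1L
  }
  items
}
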