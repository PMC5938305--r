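test_that("the log-likelihood matches closed forms", {
  X <- matrix(1, 1, 1)
  # y = 0 with p = 0.5 contributes log(1 - p)
  p5 <- twopart_params(beta_occ = 0, beta_amt = 0, shape = 1,
                       sd_occ = 1, sd_amt = 1, rho = 0)
  expect_equal(twopart_loglik(0, X, p5), log(0.5), tolerance = 1e-12)
  # y = 100, p = 0.5, shape = 1, mean = 100: the gamma part is exponential
  pe <- twopart_params(beta_occ = 0, beta_amt = log(100), shape = 1,
                       sd_occ = 1, sd_amt = 1, rho = 0)
  expect_equal(twopart_loglik(100, X, pe), log(0.5) - log(100) - 1,
               tolerance = 1e-10)
  # empty observation set
  expect_identical(twopart_loglik(numeric(0), X[0, , drop = FALSE], p5), 0)
  expect_error(twopart_loglik(-1, X, p5), "non-negative")
})

test_that("the log-likelihood agrees with an independent density transcription", {
  set.seed(3)
  for (rep in 1:5) {
    n <- 40
    X <- cbind(1, rnorm(n), rnorm(n))
    pars <- twopart_params(beta_occ = rnorm(3, 0, 0.5),
                           beta_amt = c(5, rnorm(2, 0, 0.3)),
                           shape = runif(1, 0.5, 3),
                           sd_occ = 1, sd_amt = 1, rho = 0.3)
    b <- cbind(rnorm(4), rnorm(4))
    subject <- sample(1:4, n, replace = TRUE)
    eta_o <- as.numeric(X %*% pars$beta_occ) + b[subject, 1]
    eta_a <- as.numeric(X %*% pars$beta_amt) + b[subject, 2]
    y <- ifelse(runif(n) < plogis(eta_o),
                rgamma(n, pars$shape, rate = pars$shape / exp(eta_a)), 0)
    expect_equal(twopart_loglik(y, X, pars, b = b, subject = subject),
                 twopart_loglik_oracle(y, eta_o, eta_a, pars$shape),
                 tolerance = 1e-10)
  }
})

test_that("the two-part density is proper", {
  for (pars in list(c(p = 0.3, mu = 50, shape = 0.7),
                    c(p = 0.9, mu = 2000, shape = 2.5))) {
    gamma_mass <- integrate(function(y) {
      dgamma(y, shape = pars["shape"], rate = pars["shape"] / pars["mu"])
    }, 0, Inf, rel.tol = 1e-9)$value
    total <- (1 - pars["p"]) + pars["p"] * gamma_mass
    expect_equal(unname(total), 1, tolerance = 1e-6)
  }
})

test_that("marginal p x mu equals the Monte Carlo mean of simulated outcomes", {
  set.seed(10)
  p <- 0.6; mu <- 800; shape <- 1.3
  n <- 1e6
  z <- rbinom(n, 1, p)
  y <- ifelse(z == 1, rgamma(n, shape, rate = shape / mu), 0)
  expect_equal(mean(y), p * mu, tolerance = 0.01)
})

# Minimal hand-built fit object: known draws, no MCMC.
fake_fit <- function(draw_p, draw_mu) {
  weekly <- data.frame(participant_id = rep(c("a", "b"), each = 3),
                       week = rep(c(0, 1, 2), 2))
  des <- build_design(weekly, arms = c(a = "BCT", b = "CBT"),
                      knots = c(0.2, 1, 1.8))
  nd <- length(draw_p)
  draws <- as.data.frame(matrix(0, nd, 2 * ncol(des$X)))
  names(draws) <- c(paste0("occ:", colnames(des$X)),
                    paste0("amt:", colnames(des$X)))
  draws[["occ:(Intercept)"]] <- qlogis(draw_p)
  draws[["amt:(Intercept)"]] <- log(draw_mu)
  draws$shape <- 1; draws$sd_occ <- 1; draws$sd_amt <- 1; draws$rho <- 0
  structure(list(draws = draws, design = des, subjects = c("a", "b")),
            class = "twopart_fit")
}

test_that("marginal daily loss averages the two parts at median random effects", {
  f <- fake_fit(0.5, 200)
  out <- marginal_daily_loss(f, 0, "BCT")
  expect_equal(out$estimate, 100)
  # p = 0 forces the marginal to 0 regardless of the mean
  f0 <- fake_fit(1e-12, 5000)
  expect_lt(marginal_daily_loss(f0, 0, "BCT")$estimate, 1e-6)
  # draws {(0.5, 200), (0.25, 400)} both give 100; the median is 100
  f2 <- fake_fit(c(0.5, 0.25), c(200, 400))
  out2 <- marginal_daily_loss(f2, 0, "BCT")
  expect_equal(out2$estimate, 100)
  expect_equal(out2$ci_low, 100)
  expect_equal(out2$ci_high, 100)
  expect_error(marginal_daily_loss(f, row = c(1, 2)), "conform")
})

test_that("fits are reproducible: same seed and config give identical draws", {
  sim <- generate_from_model(default_truth(), list(n_subjects = 8),
                             seed = 21)
  mc <- test_mcmc(chains = 2, adapt = 100, burn = 100, iter = 100,
                  rhat_gate = 2)
  f1 <- suppressWarnings(fit_twopart(sim$weekly, sim$design, mcmc = mc,
                                     seed = 5))
  f2 <- suppressWarnings(fit_twopart(sim$weekly, sim$design, mcmc = mc,
                                     seed = 5))
  expect_identical(f1$draws, f2$draws)
  f3 <- suppressWarnings(fit_twopart(sim$weekly, sim$design, mcmc = mc,
                                     seed = 6))
  expect_false(identical(f1$draws, f2$draws) && identical(f1$draws, f3$draws))
})

test_that("an all-zero outcome vector leaves the gamma part unidentified", {
  weekly <- data.frame(participant_id = rep("a", 4), week = 0:3,
                       avg_daily_loss = 0)
  des <- build_design(weekly, arms = c(a = "BCT"), knots = c(0.5, 1.5, 2.5))
  expect_error(fit_twopart(weekly, des, seed = 1), "unidentified")
})

test_that("posterior medians recover the generating fixed effects", {
  sf <- shared_twopart_fit()
  s <- summary(sf$fit)
  truth <- c(default_truth()$beta_occ, default_truth()$beta_amt)
  est <- s$estimate[1:14]
  err <- abs(est - truth)
  rel <- err / pmax(abs(truth), 1e-9)
  # most coefficients land close to truth; the rest stay within their
  # posterior uncertainty on this single dataset
  expect_gte(sum(rel < 0.2 | err < 0.25), 11)
  z99 <- stats::qnorm(0.995)
  half_width <- (s$ci_high[1:14] - s$ci_low[1:14]) / 2 * z99 / stats::qnorm(0.975)
  expect_true(all(err < pmax(half_width, 0.25)))
  # CIs behave like intervals
  expect_true(all(s$ci_low <= s$estimate & s$estimate <= s$ci_high))
})

test_that("the fitted arm contrast is exactly zero at baseline for every draw", {
  sf <- shared_twopart_fit()
  rb <- design_row(sf$fit$design, 0, "BCT")
  rc <- design_row(sf$fit$design, 0, "CBT")
  expect_identical(rb, setNames(rc, names(rb)))
  ct <- arm_contrast(sf$fit, 0)
  expect_identical(ct$estimate[1], 0)
  expect_identical(ct$ci_low[1], 0)
  expect_identical(ct$ci_high[1], 0)
  expect_warning(arm_contrast(sf$fit, 99), "extrapolat")
})

test_that("the likelihood peaks at the generating parameters", {
  set.seed(77)
  truth <- default_truth()
  sim <- generate_from_model(truth, list(n_subjects = 150), seed = 31)
  X <- sim$design$X
  subj <- match(sim$weekly$participant_id, unique(sim$weekly$participant_id))
  ll0 <- twopart_loglik(sim$weekly$avg_daily_loss, X, truth,
                        b = unname(sim$b), subject = subj)
  for (part in c("beta_occ", "beta_amt")) {
    for (j in seq_along(truth[[part]])) {
      for (delta in c(-0.5, 0.5)) {
        pert <- truth
        pert[[part]][j] <- pert[[part]][j] + delta
        llp <- twopart_loglik(sim$weekly$avg_daily_loss, X, pert,
                              b = unname(sim$b), subject = subj)
        expect_lt(llp, ll0)
      }
    }
  }
})
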