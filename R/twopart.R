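#' Parameters of the two-part semicontinuous model
#'
#' Container and validator for the model's parameters: fixed effects of the
#' occurrence part (logit scale) and the amount part (log scale), the gamma
#' shape, the two random-intercept SDs and their correlation. The gamma part
#' is parameterized by (mean, shape), so the amount linear predictor is the
#' log of the conditional mean loss on gambling weeks.
#'
#' @param beta_occ,beta_amt Numeric coefficient vectors on the time-design
#'   columns (occurrence: logit scale; amount: log scale).
#' @param shape Gamma shape, > 0.
#' @param sd_occ,sd_amt Random-intercept SDs, > 0.
#' @param rho Correlation of the two subject intercepts, in [-1, 1].
#' @return A `twopart_params` list.
#' @export
twopart_params <- function(beta_occ, beta_amt, shape, sd_occ, sd_amt, rho) {
  if (length(beta_occ) != length(beta_amt)) {
    stop("beta_occ and beta_amt must conform to the same design",
         call. = FALSE)
  }
  if (!is.finite(shape) || shape <= 0) stop("shape must be > 0", call. = FALSE)
  if (sd_occ <= 0 || sd_amt <= 0) stop("random-intercept SDs must be > 0",
                                       call. = FALSE)
  if (abs(rho) > 1) stop("rho must lie in [-1, 1]", call. = FALSE)
  structure(list(beta_occ = beta_occ, beta_amt = beta_amt, shape = shape,
                 sd_occ = sd_occ, sd_amt = sd_amt, rho = rho),
            class = "twopart_params")
}

#' Log-likelihood of the two-part model
#'
#' Each zero week contributes `log(1 - p)`; each positive week contributes
#' `log(p)` plus the gamma log-density with mean `exp(amount linear
#' predictor)` and the given shape, where `p` is the inverse logit of the
#' occurrence linear predictor. Subject intercepts, when supplied, are added
#' to the respective linear predictors.
#'
#' This function is a direct density transcription kept independent of the
#' MCMC machinery; it backs oracle tests and likelihood sanity checks.
#'
#' @param y Non-negative weekly average daily losses.
#' @param X Design matrix with one row per element of `y`.
#' @param params A [twopart_params].
#' @param b Optional matrix of subject intercepts (columns: occurrence,
#'   amount), one row per subject.
#' @param subject Optional integer vector mapping each row of `X` to a row
#'   of `b`.
#' @return Total log-likelihood (scalar); 0 for an empty observation set.
#' @export
twopart_loglik <- function(y, X, params, b = NULL, subject = NULL) {
  if (length(y) == 0) return(0)
  if (any(y < 0)) stop("losses must be non-negative", call. = FALSE)
  X <- rbind(X)
  if (is.null(b)) {
    b_occ <- b_amt <- rep(0, length(y))
  } else {
    b_occ <- b[subject, 1]
    b_amt <- b[subject, 2]
  }
  eta_occ <- as.numeric(X %*% params$beta_occ) + b_occ
  eta_amt <- as.numeric(X %*% params$beta_amt) + b_amt
  if (any(!is.finite(eta_occ)) || any(!is.finite(eta_amt))) {
    stop("non-finite linear predictor", call. = FALSE)
  }
  pos <- y > 0
  ll <- sum(stats::plogis(eta_occ[!pos], lower.tail = FALSE, log.p = TRUE)) +
    sum(stats::plogis(eta_occ[pos], log.p = TRUE))
  if (any(pos)) {
    mu <- exp(eta_amt[pos])
    ll <- ll + sum(stats::dgamma(y[pos], shape = params$shape,
                                 rate = params$shape / mu, log = TRUE))
  }
  ll
}

#' Priors for the two-part model
#'
#' Defaults follow common weakly informative practice for hierarchical
#' hurdle models: effectively flat normal priors (SD 10) for fixed effects
#' on the link scale, half-Student-t(3, 0, 2.5) for the random-intercept
#' SDs, uniform correlation on [-1, 1], and half-Normal(0, 5) for the gamma
#' shape. All are configurable.
#'
#' @param beta_sd Prior SD of fixed effects (applied on the orthogonalized
#'   coefficient scale used for sampling; see the methods vignette).
#' @param sd_scale,sd_df Scale and df of the half-Student-t prior on the
#'   random-intercept SDs.
#' @param shape_sd Scale of the half-normal prior on the gamma shape.
#' @return A `twopart_priors` list.
#' @export
twopart_priors <- function(beta_sd = 10, sd_scale = 2.5, sd_df = 3,
                           shape_sd = 5) {
  stopifnot(beta_sd > 0, sd_scale > 0, sd_df > 0, shape_sd > 0)
  structure(list(beta_sd = beta_sd, sd_scale = sd_scale, sd_df = sd_df,
                 shape_sd = shape_sd), class = "twopart_priors")
}

#' MCMC configuration
#'
#' @param chains Number of chains (default 4).
#' @param adapt Adaptation iterations per chain.
#' @param burn Burn-in iterations per chain.
#' @param iter Retained iterations per chain (default 1000, so the default
#'   posterior has at least 4000 draws).
#' @param thin Thinning interval.
#' @param rhat_gate Convergence gate: largest acceptable split R-hat at the
#'   default (full-length) settings.
#' @return An `mcmc_config` list.
#' @export
mcmc_config <- function(chains = 4, adapt = 500, burn = 500, iter = 1000,
                        thin = 1, rhat_gate = 1.01) {
  stopifnot(chains >= 1, iter >= 1, thin >= 1)
  structure(list(chains = chains, adapt = adapt, burn = burn, iter = iter,
                 thin = thin, rhat_gate = rhat_gate), class = "mcmc_config")
}

# Signed QR of the design, scaled so Q columns have norm sqrt(N). Sampling
# runs on the rotated coefficients (near-orthogonal -> good slice-sampler
# mixing); draws are rotated back to the design scale afterwards. A
# rank-deficient design (e.g. an empty arm x timepoint cell) cannot be
# rotated; those fits fall back to the identity basis, where the
# unidentified coefficient simply follows its prior.
.qr_rotate <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    return(list(Q = X, R = diag(ncol(X)), Rinv = diag(ncol(X))))
  }
  Q <- qr.Q(qrX); R <- qr.R(qrX)
  s <- sign(diag(R)); s[s == 0] <- 1
  Q <- sweep(Q, 2, s, `*`); R <- sweep(R, 1, s, `*`)
  n <- nrow(X)
  list(Q = Q * sqrt(n), R = R / sqrt(n), Rinv = solve(R / sqrt(n)))
}

.twopart_model_code <- function(priors) {
  sprintf("
model {
  eta_occ <- Q %%*%% th_occ
  eta_amt <- Q %%*%% th_amt
  for (i in 1:N) {
    z[i] ~ dbern(p[i])
    logit(p[i]) <- eta_occ[i] + b1[subj[i]]
  }
  for (j in 1:Npos) {
    y[j] ~ dgamma(shape, shape / mu[j])
    log(mu[j]) <- eta_amt[pos[j]] + b2[subj[pos[j]]]
  }
  for (s in 1:S) {
    b1[s] ~ dnorm(0, 1 / (sd_occ * sd_occ))
    b2[s] ~ dnorm(rho * (sd_amt / sd_occ) * b1[s],
                  1 / (sd_amt * sd_amt * (1 - rho * rho)))
  }
  for (k in 1:P) {
    th_occ[k] ~ dnorm(0, %.8g)
    th_amt[k] ~ dnorm(0, %.8g)
  }
  sd_occ ~ dt(0, %.8g, %d) T(0,)
  sd_amt ~ dt(0, %.8g, %d) T(0,)
  rho ~ dunif(-1, 1)
  shape ~ dnorm(0, %.8g) T(0,)
}", priors$beta_sd^-2, priors$beta_sd^-2,
    priors$sd_scale^-2, priors$sd_df,
    priors$sd_scale^-2, priors$sd_df,
    priors$shape_sd^-2)
}

# Deterministic per-chain RNG seeds derived from one user seed.
.chain_seeds <- function(seed, chains) {
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed %% .Machine$integer.max)
  sample.int(2^31 - 2, chains)
}

.run_jags <- function(code, data, inits_base, monitors, mcmc, seed) {
  inits <- lapply(seq_len(mcmc$chains), function(ch) {
    c(inits_base,
      list(.RNG.name = "base::Mersenne-Twister",
           .RNG.seed = .chain_seeds(seed, mcmc$chains)[ch]))
  })
  jm <- rjags::jags.model(textConnection(code), data = data, inits = inits,
                          n.chains = mcmc$chains, n.adapt = mcmc$adapt,
                          quiet = TRUE)
  if (mcmc$burn > 0) stats::update(jm, mcmc$burn, progress.bar = "none")
  rjags::coda.samples(jm, monitors, n.iter = mcmc$iter, thin = mcmc$thin,
                      progress.bar = "none")
}

# Rename/rotate raw theta-scale chains back to design-scale coefficients.
.rotate_chain <- function(M, Rinv, cols, subjects) {
  P <- length(cols)
  th_occ <- M[, paste0("th_occ[", seq_len(P), "]"), drop = FALSE]
  th_amt <- M[, paste0("th_amt[", seq_len(P), "]"), drop = FALSE]
  bocc <- th_occ %*% t(Rinv)
  bamt <- th_amt %*% t(Rinv)
  colnames(bocc) <- paste0("occ:", cols)
  colnames(bamt) <- paste0("amt:", cols)
  b1 <- M[, paste0("b1[", seq_along(subjects), "]"), drop = FALSE]
  b2 <- M[, paste0("b2[", seq_along(subjects), "]"), drop = FALSE]
  colnames(b1) <- paste0("b_occ:", subjects)
  colnames(b2) <- paste0("b_amt:", subjects)
  cbind(bocc, bamt,
        shape = M[, "shape"], sd_occ = M[, "sd_occ"],
        sd_amt = M[, "sd_amt"], rho = M[, "rho"], b1, b2)
}

.diagnose <- function(chains_mat, param_cols, gate) {
  ml <- coda::mcmc.list(lapply(chains_mat, function(m) {
    coda::mcmc(m[, param_cols, drop = FALSE])
  }))
  rhat <- if (length(chains_mat) >= 2) {
    coda::gelman.diag(ml, multivariate = FALSE, autoburnin = FALSE)$psrf[, 1]
  } else {
    stats::setNames(rep(NA_real_, length(param_cols)), param_cols)
  }
  ess <- coda::effectiveSize(ml)
  converged <- !any(is.finite(rhat) & rhat > gate)
  list(rhat = rhat, ess = ess, rhat_gate = gate, converged = converged)
}

#' Fit the Bayesian two-part semicontinuous mixed model
#'
#' Fits the hurdle model for weekly average daily gambling losses: a
#' Bernoulli part for whether the participant gambled that week (logit
#' link) and a gamma part for the average daily amount lost on gambling
#' weeks (log link, mean-shape parameterization), with correlated subject
#' random intercepts in both parts. Sampling is MCMC via JAGS; for mixing,
#' fixed effects are sampled in a QR-orthogonalized basis and rotated back,
#' so reported coefficients are on the original design columns. Weeks that
#' are absent from `weekly` are simply not part of the likelihood, which is
#' the correct treatment under the missing-at-random assumption.
#'
#' @param weekly Data frame with `participant_id` and `avg_daily_loss`
#'   aligned row-for-row with `design`.
#' @param design A [build_design] `time_design` whose rows align with
#'   `weekly`.
#' @param priors A [twopart_priors].
#' @param mcmc An [mcmc_config].
#' @param seed Integer seed; identical seed and config reproduce the draws
#'   exactly.
#' @return A `twopart_fit`: `draws` (data frame, one row per retained draw,
#'   with `chain`, `draw`, fixed effects `occ:*`/`amt:*`, `shape`,
#'   `sd_occ`, `sd_amt`, `rho` and per-subject intercepts `b_occ:*`,
#'   `b_amt:*`), `diagnostics` (split R-hat, effective sample size,
#'   convergence gate), the `design`, `subjects`, `priors`, `mcmc`, `seed`.
#' @export
fit_twopart <- function(weekly, design, priors = twopart_priors(),
                        mcmc = mcmc_config(), seed) {
  stopifnot(inherits(design, "time_design"))
  if (missing(seed)) stop("a seed is required for a reproducible fit",
                          call. = FALSE)
  y <- weekly$avg_daily_loss
  if (length(y) != nrow(design$X)) {
    stop("design rows do not align with observations", call. = FALSE)
  }
  if (any(y < 0)) stop("losses must be non-negative", call. = FALSE)
  subjects <- unique(as.character(weekly$participant_id))
  subj <- match(as.character(weekly$participant_id), subjects)
  pos <- which(y > 0)
  if (length(pos) == 0) {
    stop("all observations are zero: the gamma (amount) part is unidentified",
         call. = FALSE)
  }
  rot <- .qr_rotate(design$X)
  P <- ncol(design$X)
  data <- list(N = length(y), Npos = length(pos), z = as.numeric(y > 0),
               y = y[pos], pos = pos, Q = rot$Q, subj = subj,
               S = length(subjects), P = P)
  inits_base <- list(
    th_occ = rep(0, P),
    th_amt = c(log(mean(y[pos])), rep(0, P - 1)),
    sd_occ = 1, sd_amt = 1, rho = 0, shape = 1,
    b1 = rep(0, length(subjects)), b2 = rep(0, length(subjects))
  )
  sm <- .run_jags(.twopart_model_code(priors), data, inits_base,
                  c("th_occ", "th_amt", "shape", "sd_occ", "sd_amt", "rho",
                    "b1", "b2"),
                  mcmc, seed)
  cols <- colnames(design$X)
  chains_mat <- lapply(sm, function(ch) {
    .rotate_chain(as.matrix(ch), rot$Rinv, cols, subjects)
  })
  param_cols <- c(paste0("occ:", cols), paste0("amt:", cols),
                  "shape", "sd_occ", "sd_amt", "rho")
  diag <- .diagnose(chains_mat, param_cols, mcmc$rhat_gate)
  if (!diag$converged) {
    warning(sprintf("convergence gate failed: max R-hat %.3f > %.3f",
                    max(diag$rhat, na.rm = TRUE), mcmc$rhat_gate),
            call. = FALSE)
  }
  draws <- do.call(rbind, lapply(seq_along(chains_mat), function(ci) {
    data.frame(chain = ci, draw = seq_len(nrow(chains_mat[[ci]])),
               chains_mat[[ci]], check.names = FALSE)
  }))
  rownames(draws) <- NULL
  structure(
    list(draws = draws, diagnostics = diag, design = design,
         subjects = subjects, priors = priors, mcmc = mcmc, seed = seed,
         n_obs = length(y), n_pos = length(pos)),
    class = "twopart_fit"
  )
}

#' @export
print.twopart_fit <- function(x, ...) {
  cat(sprintf(paste0(
    "Two-part gamma hurdle mixed model fit\n",
    "  %d observations (%d positive) on %d subjects\n",
    "  %d draws (%d chains); max R-hat %.3f (gate %.2f, %s)\n"),
    x$n_obs, x$n_pos, length(x$subjects), nrow(x$draws), x$mcmc$chains,
    max(x$diagnostics$rhat, na.rm = TRUE), x$diagnostics$rhat_gate,
    if (x$diagnostics$converged) "passed" else "FAILED"))
  invisible(x)
}

#' Posterior summary of the fixed effects
#'
#' @param object A `twopart_fit`.
#' @param ... Unused.
#' @return Data frame of posterior medians and equal-tailed 95% credible
#'   intervals for the fixed effects, shape, SDs and correlation.
#' @export
summary.twopart_fit <- function(object, ...) {
  cols <- c(paste0("occ:", colnames(object$design$X)),
            paste0("amt:", colnames(object$design$X)),
            "shape", "sd_occ", "sd_amt", "rho")
  qs <- t(vapply(cols, function(cn) {
    stats::quantile(object$draws[[cn]], c(0.025, 0.5, 0.975))
  }, numeric(3)))
  data.frame(parameter = cols, estimate = qs[, 2],
             ci_low = qs[, 1], ci_high = qs[, 3], row.names = NULL)
}

# Per-draw fixed-effect matrices (draws x P) for one part.
.fixef_draws <- function(fit, part = c("occ", "amt")) {
  part <- match.arg(part)
  cols <- paste0(part, ":", colnames(fit$design$X))
  as.matrix(fit$draws[, cols, drop = FALSE])
}

# Drawwise marginal daily loss p * mu at a covariate row, subject
# intercepts set to zero (median-subject interpretation).
.marginal_drawwise <- function(fit, row) {
  cols <- colnames(fit$design$X)
  if (length(row) != length(cols)) {
    stop("covariate row does not conform to the design", call. = FALSE)
  }
  if (!is.null(names(row)) && !identical(names(row), cols)) {
    if (!all(cols %in% names(row))) {
      stop("covariate row does not conform to the design", call. = FALSE)
    }
    row <- row[cols]
  }
  p <- stats::plogis(.fixef_draws(fit, "occ") %*% row)
  mu <- exp(.fixef_draws(fit, "amt") %*% row)
  as.numeric(p * mu)
}

.effect_summary <- function(label, drawwise, scale = "SEK/day") {
  q <- stats::quantile(drawwise, c(0.025, 0.5, 0.975))
  data.frame(label = label, estimate = q[2], ci_low = q[1], ci_high = q[3],
             scale = scale, row.names = NULL)
}

#' Marginal average daily loss at a given week and arm
#'
#' Averages over the two parts of the model: per posterior draw the
#' occurrence probability times the conditional mean loss, `p * mu`, with
#' the subject random intercepts set to zero rather than integrated out —
#' the result reads as the average daily loss per week for an individual
#' with a median amount of losses. Draws are summarized as the posterior
#' median with an equal-tailed 95% credible interval.
#'
#' @param fit A `twopart_fit`.
#' @param week Week at which to predict (ignored when `row` is given).
#' @param arm `"BCT"` or `"CBT"`.
#' @param row Optional explicit covariate row conforming to the design.
#' @param label Label for the output row.
#' @return One-row data frame: `label`, `estimate`, `ci_low`, `ci_high`,
#'   `scale`.
#' @export
marginal_daily_loss <- function(fit, week = NULL, arm = "BCT", row = NULL,
                                label = NULL) {
  stopifnot(inherits(fit, "twopart_fit"))
  if (is.null(row)) {
    if (is.null(week)) stop("supply `week` (and `arm`) or a covariate row",
                            call. = FALSE)
    row <- design_row(fit$design, week, arm)
    if (is.null(label)) label <- sprintf("%s @ week %g", arm, week)
  } else if (is.null(label)) {
    label <- "custom row"
  }
  .effect_summary(label, .marginal_drawwise(fit, row))
}

#' Between-arm contrasts and within-arm changes in marginal daily loss
#'
#' For each requested week, computes per posterior draw the difference
#' (CBT - BCT) of the marginal daily losses and each arm's change from
#' baseline (week `w` minus week 0), then summarizes draws as posterior
#' medians with equal-tailed 95% credible intervals. Because arm enters the
#' design only through post-baseline interactions, the contrast at week 0
#' is exactly zero for every draw.
#'
#' @param fit A `twopart_fit`.
#' @param weeks Weeks at which to evaluate the contrasts.
#' @return Data frame of effect summaries: per week the `CBT - BCT`
#'   contrast and both within-arm changes from baseline. If any requested
#'   week lies outside the fitted week range, an `"extrapolation"`
#'   attribute lists the offending weeks and a warning is raised.
#' @export
arm_contrast <- function(fit, weeks) {
  stopifnot(inherits(fit, "twopart_fit"))
  rng <- range(fit$design$week)
  extrap <- weeks[weeks < rng[1] | weeks > rng[2]]
  if (length(extrap)) {
    warning("extrapolating beyond observed weeks: ",
            paste(extrap, collapse = ", "), call. = FALSE)
  }
  base <- lapply(c(BCT = "BCT", CBT = "CBT"), function(a) {
    .marginal_drawwise(fit, design_row(fit$design, 0, a))
  })
  out <- do.call(rbind, lapply(weeks, function(w) {
    mw <- lapply(c(BCT = "BCT", CBT = "CBT"), function(a) {
      .marginal_drawwise(fit, design_row(fit$design, w, a))
    })
    rbind(
      .effect_summary(sprintf("CBT - BCT @ week %g", w),
                      mw$CBT - mw$BCT),
      .effect_summary(sprintf("BCT change from baseline @ week %g", w),
                      mw$BCT - base$BCT),
      .effect_summary(sprintf("CBT change from baseline @ week %g", w),
                      mw$CBT - base$CBT)
    )
  }))
  attr(out, "extrapolation") <- extrap
  out
}
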