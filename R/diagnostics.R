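#' Posterior-predictive summary statistics of a loss collection
#'
#' The four data features the model is checked against: the proportion of
#' exact zeros (abstinent weeks), the median and the maximum weekly average
#' daily loss, and the sample variance (denominator n - 1).
#'
#' @param losses Non-empty numeric vector of weekly average daily losses.
#' @return Named numeric vector: `prop_zero`, `median_loss`, `max_loss`,
#'   `variance`.
#' @export
ppc_stats <- function(losses) {
  if (length(losses) == 0) stop("empty loss collection", call. = FALSE)
  if (length(losses) < 2) {
    stop("sample variance is undefined for a single observation",
         call. = FALSE)
  }
  c(prop_zero = mean(losses == 0),
    median_loss = stats::median(losses),
    max_loss = max(losses),
    variance = stats::var(losses))
}

#' Simulate replicate datasets from a fitted two-part model's posterior
#'
#' Each replicate uses one retained posterior draw — fixed effects, shape
#' and that draw's per-subject random intercepts — to simulate a new
#' dataset with exactly the design shape of the observed data (same
#' subjects, same weeks). Draws are taken evenly across the retained
#' posterior.
#'
#' @param fit A `twopart_fit`.
#' @param n_rep Number of replicate datasets (>= 1).
#' @param seed Integer seed.
#' @param draw_idx Optional explicit draw indices (length `n_rep`)
#'   overriding the default even spacing across the retained posterior.
#' @return Matrix of simulated losses, one column per replicate, rows
#'   aligned with the fitted observations.
#' @export
simulate_replicates <- function(fit, n_rep, seed, draw_idx = NULL) {
  stopifnot(inherits(fit, "twopart_fit"))
  if (n_rep < 1) stop("n_rep must be >= 1", call. = FALSE)
  set.seed(seed)
  idx <- if (is.null(draw_idx)) {
    round(seq(1, nrow(fit$draws), length.out = n_rep))
  } else {
    stopifnot(length(draw_idx) == n_rep)
    draw_idx
  }
  X <- fit$design$X
  subj <- match(fit$design$participant_id, fit$subjects)
  bo_cols <- paste0("b_occ:", fit$subjects)
  ba_cols <- paste0("b_amt:", fit$subjects)
  occ <- .fixef_draws(fit, "occ")
  amt <- .fixef_draws(fit, "amt")
  out <- matrix(0, nrow(X), n_rep)
  for (r in seq_len(n_rep)) {
    d <- idx[r]
    eta_o <- as.numeric(X %*% occ[d, ]) +
      as.numeric(fit$draws[d, bo_cols])[subj]
    eta_a <- as.numeric(X %*% amt[d, ]) +
      as.numeric(fit$draws[d, ba_cols])[subj]
    shape <- fit$draws$shape[d]
    z <- stats::rbinom(nrow(X), 1, stats::plogis(eta_o))
    mu <- exp(eta_a)
    out[, r] <- ifelse(z == 1,
                       stats::rgamma(nrow(X), shape, rate = shape / mu), 0)
  }
  out
}

#' Compare observed statistics with posterior-predictive replicates
#'
#' For each named statistic, the two-sided tail probability is
#' `min(1, 2 * min(P(rep >= obs), P(rep <= obs)))`, with ties counted half
#' and the add-one convention `(count + 1) / (n_rep + 1)`, so an observed
#' value beyond every replicate yields `2 / (n_rep + 1)` rather than zero.
#'
#' @param observed Named numeric vector of observed statistics
#'   (e.g. [ppc_stats]).
#' @param replicates Matrix or data frame of replicate statistics, one row
#'   per replicate, columns matching `names(observed)`.
#' @return A `ppc_result` data frame: statistic, observed value, replicate
#'   median, central 95% replicate interval, two-sided tail probability.
#' @export
ppc_compare <- function(observed, replicates) {
  replicates <- as.matrix(replicates)
  if (!setequal(names(observed), colnames(replicates))) {
    stop("statistic names do not match between observed and replicates",
         call. = FALSE)
  }
  n <- nrow(replicates)
  if (n < 1) stop("no replicates", call. = FALSE)
  out <- do.call(rbind, lapply(names(observed), function(s) {
    rep_s <- replicates[, s]
    obs <- observed[[s]]
    p_ge <- (sum(rep_s > obs) + 0.5 * sum(rep_s == obs) + 1) / (n + 1)
    p_le <- (sum(rep_s < obs) + 0.5 * sum(rep_s == obs) + 1) / (n + 1)
    q <- stats::quantile(rep_s, c(0.025, 0.5, 0.975))
    data.frame(statistic = s, observed = obs, rep_median = q[2],
               rep_low = q[1], rep_high = q[3],
               tail_prob = min(1, 2 * min(p_ge, p_le)), row.names = NULL)
  }))
  class(out) <- c("ppc_result", class(out))
  out
}

#' Monte Carlo coverage study for the two-part model's credible intervals
#'
#' Repeatedly simulates data from the model at known parameters
#' ([generate_from_model]), refits with [fit_twopart], and records whether
#' each fixed effect's equal-tailed 95% credible interval contains the
#' truth. Replicates that fail the convergence gate are excluded (never
#' silently imputed) and counted. The Monte Carlo standard error of a
#' coverage proportion c over n kept replicates is `sqrt(c (1 - c) / n)`.
#'
#' @param true_params Generating [twopart_params].
#' @param trial_shape Trial shape passed to [generate_from_model].
#' @param n_rep Number of replicates (>= 1).
#' @param priors,mcmc Passed to [fit_twopart]; use reduced MCMC settings
#'   for large studies.
#' @param seed Integer seed; replicate seeds are derived from it.
#' @param level Credible level (default 0.95).
#' @param gate_params Which parameters the per-replicate convergence gate
#'   inspects: `"fixed"` (default) applies the R-hat gate to the fixed
#'   effects — the parameters whose intervals the study assesses — so that
#'   replicates are only discarded for relevant non-convergence; `"all"`
#'   additionally gates on the shape, SD and correlation parameters.
#' @return A `coverage_result` data frame: `parameter`, `truth`,
#'   `n_replicates` (kept), `coverage`, `mcse`, `n_excluded`.
#' @export
run_coverage <- function(true_params, trial_shape, n_rep,
                         priors = twopart_priors(), mcmc = mcmc_config(),
                         seed, level = 0.95,
                         gate_params = c("fixed", "all")) {
  if (n_rep < 1) stop("n_rep must be >= 1", call. = FALSE)
  gate_params <- match.arg(gate_params)
  rep_seeds <- .chain_seeds(seed, 2 * n_rep)
  alpha <- (1 - level) / 2
  hits <- NULL
  n_excluded <- 0
  for (r in seq_len(n_rep)) {
    sim <- generate_from_model(true_params, trial_shape, rep_seeds[r])
    fit <- suppressWarnings(
      fit_twopart(sim$weekly, sim$design, priors = priors, mcmc = mcmc,
                  seed = rep_seeds[n_rep + r])
    )
    rh <- fit$diagnostics$rhat
    if (gate_params == "fixed") {
      rh <- rh[grep("^(occ|amt):", names(rh))]
    }
    failed <- any(is.finite(rh) & rh > mcmc$rhat_gate)
    if (failed) {
      n_excluded <- n_excluded + 1
      next
    }
    cols <- colnames(sim$design$X)
    truth <- c(stats::setNames(true_params$beta_occ, paste0("occ:", cols)),
               stats::setNames(true_params$beta_amt, paste0("amt:", cols)))
    hit <- vapply(names(truth), function(par) {
      ci <- stats::quantile(fit$draws[[par]], c(alpha, 1 - alpha))
      ci[1] <= truth[[par]] && truth[[par]] <= ci[2]
    }, logical(1))
    hits <- rbind(hits, hit)
  }
  if (is.null(hits)) {
    stop("all replicates failed the convergence gate", call. = FALSE)
  }
  cov <- colMeans(hits)
  n_kept <- nrow(hits)
  cols <- colnames(generate_from_model(true_params, trial_shape, 1)$design$X)
  truth <- c(stats::setNames(true_params$beta_occ, paste0("occ:", cols)),
             stats::setNames(true_params$beta_amt, paste0("amt:", cols)))
  out <- data.frame(parameter = names(cov), truth = unname(truth[names(cov)]),
                    n_replicates = n_kept, coverage = unname(cov),
                    mcse = sqrt(unname(cov) * (1 - unname(cov)) / n_kept),
                    n_excluded = n_excluded, row.names = NULL)
  class(out) <- c("coverage_result", class(out))
  out
}

#' Independent-samples t-test from summary statistics
#'
#' Two-sample t-test computed from printed group means, SDs and sizes, as
#' used to compare randomized participants with the no-contact group at
#' baseline. Default is the pooled-variance test with
#' `df = n1 + n2 - 2`; `welch = TRUE` switches to the Welch
#' unequal-variance form.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1.
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @param welch Use the Welch-Satterthwaite form instead of pooled
#'   variance.
#' @return List: `t`, `df`, `p` (two-sided).
#' @export
baseline_ttest <- function(mean1, sd1, n1, mean2, sd2, n2, welch = FALSE) {
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2", call. = FALSE)
  if (sd1 <= 0 || sd2 <= 0) stop("SDs must be positive", call. = FALSE)
  if (welch) {
    se2 <- sd1^2 / n1 + sd2^2 / n2
    t <- (mean1 - mean2) / sqrt(se2)
    df <- se2^2 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}
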