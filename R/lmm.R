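.timepoints <- c("pre", "post", "m3", "m6")

.lmm_model_code <- function(priors) {
  sprintf("
model {
  eta <- Q %%*%% th
  for (i in 1:N) {
    y[i] ~ dnorm(eta[i] + b[subj[i]], 1 / (sd_resid * sd_resid))
  }
  for (s in 1:S) {
    b[s] ~ dnorm(0, 1 / (sd_subj * sd_subj))
  }
  for (k in 1:P) {
    th[k] ~ dnorm(0, %.8g)
  }
  sd_subj ~ dt(0, %.8g, %d) T(0,)
  sd_resid ~ dt(0, %.8g, %d) T(0,)
}", priors$beta_sd^-2,
    priors$sd_scale^-2, priors$sd_df,
    priors$sd_scale^-2, priors$sd_df)
}

# Cell-means design: intercept, timepoint dummies (pre = reference), arm
# main effect (baseline arm differences are freely estimated, unlike the
# TLFB model) and arm x timepoint interactions.
.lmm_design <- function(timepoint, arm) {
  tp <- factor(timepoint, levels = .timepoints)
  if (anyNA(tp)) {
    stop("unknown timepoint: ",
         paste(unique(timepoint[is.na(tp)]), collapse = ", "), call. = FALSE)
  }
  cbt <- as.numeric(arm == "CBT")
  tpd <- matrix(vapply(.timepoints[-1], function(t) as.numeric(tp == t),
                       numeric(length(tp))),
                nrow = length(tp))
  X <- cbind("(Intercept)" = 1, tpd, armCBT = cbt, tpd * cbt)
  colnames(X) <- c("(Intercept)", paste0("tp_", .timepoints[-1]), "armCBT",
                   paste0("tp_", .timepoints[-1], ":armCBT"))
  X
}

#' Fit a Bayesian linear mixed model for a questionnaire outcome
#'
#' Gaussian mixed model for instrument totals (NODS, PHQ-9, GAD-7) with
#' time as a categorical variable (pre/post/m3/m6, pre = reference),
#' arm, arm-by-time interactions and subject-specific random intercepts.
#' Unlike the TLFB two-part model, the arm difference at baseline is freely
#' estimated — the output mirrors the pre-treatment "Diff. from BCT" row of
#' the trial's outcome tables. Missing timepoints are simply absent from
#' the likelihood (valid under MAR). Priors are shared with the two-part
#' module's fixed-effect and SD priors.
#'
#' @param outcomes Data frame with `participant_id`, `timepoint`
#'   (`"pre"`, `"post"`, `"m3"`, `"m6"`), `arm` (`"BCT"`/`"CBT"`) and
#'   `total` (instrument total score).
#' @param priors A [twopart_priors] (the fixed-effect and SD components are
#'   used).
#' @param mcmc An [mcmc_config].
#' @param seed Integer seed.
#' @return An `lmm_fit`: `draws` (one row per retained draw: `chain`,
#'   `draw`, coefficients, `sd_subj`, `sd_resid`, per-subject intercepts),
#'   `diagnostics`, `subjects`, `coef_names`, `empty_cells`.
#' @export
fit_lmm <- function(outcomes, priors = twopart_priors(), mcmc = mcmc_config(),
                    seed) {
  if (missing(seed)) stop("a seed is required for a reproducible fit",
                          call. = FALSE)
  need <- c("participant_id", "timepoint", "arm", "total")
  miss <- setdiff(need, names(outcomes))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (length(unique(outcomes$timepoint)) < 2) {
    stop("need at least 2 timepoints to fit a longitudinal model",
         call. = FALSE)
  }
  X <- .lmm_design(outcomes$timepoint, outcomes$arm)
  tab <- table(factor(outcomes$timepoint, levels = .timepoints), outcomes$arm)
  empty <- which(tab == 0, arr.ind = TRUE)
  empty_cells <- if (nrow(empty)) {
    paste(rownames(tab)[empty[, 1]], colnames(tab)[empty[, 2]], sep = ":")
  } else character(0)
  if (length(empty_cells)) {
    warning("empty design cells: ", paste(empty_cells, collapse = ", "),
            call. = FALSE)
  }
  subjects <- unique(as.character(outcomes$participant_id))
  subj <- match(as.character(outcomes$participant_id), subjects)
  rot <- .qr_rotate(X)
  data <- list(N = nrow(X), Q = rot$Q, y = as.numeric(outcomes$total),
               subj = subj, S = length(subjects), P = ncol(X))
  inits_base <- list(th = c(mean(data$y), rep(0, ncol(X) - 1)),
                     sd_subj = 1, sd_resid = stats::sd(data$y) + 0.5,
                     b = rep(0, length(subjects)))
  sm <- .run_jags(.lmm_model_code(priors), data, inits_base,
                  c("th", "sd_subj", "sd_resid", "b"), mcmc, seed)
  cols <- colnames(X)
  chains_mat <- lapply(sm, function(ch) {
    M <- as.matrix(ch)
    beta <- M[, paste0("th[", seq_along(cols), "]"), drop = FALSE] %*%
      t(rot$Rinv)
    colnames(beta) <- cols
    b <- M[, paste0("b[", seq_along(subjects), "]"), drop = FALSE]
    colnames(b) <- paste0("b:", subjects)
    cbind(beta, sd_subj = M[, "sd_subj"], sd_resid = M[, "sd_resid"], b)
  })
  diag <- .diagnose(chains_mat, c(cols, "sd_subj", "sd_resid"),
                    mcmc$rhat_gate)
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
    list(draws = draws, diagnostics = diag, subjects = subjects,
         coef_names = cols, empty_cells = empty_cells, priors = priors,
         mcmc = mcmc, seed = seed),
    class = "lmm_fit"
  )
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf(paste0(
    "Bayesian linear mixed model fit (categorical time)\n",
    "  %d subjects; %d draws; max R-hat %.3f (%s)\n"),
    length(x$subjects), nrow(x$draws),
    max(x$diagnostics$rhat, na.rm = TRUE),
    if (x$diagnostics$converged) "passed" else "FAILED"))
  invisible(x)
}

# Drawwise cell mean for an arm x timepoint combination.
.lmm_cell <- function(fit, arm, timepoint) {
  row <- .lmm_design(timepoint, arm)[1, ]
  as.numeric(as.matrix(fit$draws[, fit$coef_names]) %*% row)
}

#' Change from baseline and between-arm difference for an LMM fit
#'
#' For the requested timepoint: the within-arm change from the
#' pre-treatment cell mean, and the between-arm (CBT - BCT) difference at
#' that timepoint, each as a posterior median with an equal-tailed 95%
#' credible interval — the two columns of the trial-style outcome tables.
#'
#' @param fit An `lmm_fit`.
#' @param arm Arm for the within-arm change (`"BCT"` or `"CBT"`).
#' @param timepoint One of `"pre"`, `"post"`, `"m3"`, `"m6"`. The change at
#'   `"pre"` is exactly 0.
#' @return Two-row data frame of effect summaries (change, diff from BCT).
#' @export
lmm_change <- function(fit, arm = "BCT", timepoint = "post") {
  stopifnot(inherits(fit, "lmm_fit"))
  if (!timepoint %in% .timepoints) {
    stop("unknown timepoint: ", timepoint, call. = FALSE)
  }
  change <- .lmm_cell(fit, arm, timepoint) - .lmm_cell(fit, arm, "pre")
  diff <- .lmm_cell(fit, "CBT", timepoint) - .lmm_cell(fit, "BCT", timepoint)
  rbind(
    .effect_summary(sprintf("%s change from pre @ %s", arm, timepoint),
                    change, scale = "score points"),
    .effect_summary(sprintf("CBT - BCT @ %s", timepoint),
                    diff, scale = "score points")
  )
}

#' Trial-style outcome table for an LMM fit
#'
#' Mirrors the published layout: the pre-treatment score in the reference
#' arm (BCT) with its baseline difference from BCT for CBT, then the
#' post-treatment, 3-month and 6-month changes from baseline per arm with
#' the between-arm difference at each timepoint.
#'
#' @param fit An `lmm_fit`.
#' @return Data frame of effect summaries.
#' @export
lmm_table <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  pre_bct <- .lmm_cell(fit, "BCT", "pre")
  pre_diff <- .lmm_cell(fit, "CBT", "pre") - pre_bct
  out <- rbind(
    .effect_summary("BCT pre-treatment score", pre_bct, "score points"),
    .effect_summary("CBT - BCT @ pre", pre_diff, "score points")
  )
  for (tp in c("post", "m3", "m6")) {
    out <- rbind(out,
                 lmm_change(fit, "BCT", tp)[1, ],
                 lmm_change(fit, "CBT", tp))
  }
  rownames(out) <- NULL
  out
}
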