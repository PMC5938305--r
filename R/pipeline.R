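#' Validate a pipeline run configuration
#'
#' A run configuration holds exactly one data source — `input` (paths to
#' `tlfb_daily.csv`, `questionnaires.csv`, `participants.csv`) or
#' `simulate` (arguments for [trial_config]) — plus an `analysis` block
#' (rater choice, knot override, arm-interaction switch, prior and MCMC
#' overrides, contrast weeks, PPC replicate count), an output directory
#' and a seed. A seed is required: every stochastic stage derives its seed
#' from it.
#'
#' @param config List, or path to a YAML/JSON file holding one.
#' @return The validated config (class `run_config`).
#' @export
run_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  has_input <- !is.null(config$input)
  has_sim <- !is.null(config$simulate)
  if (has_input == has_sim) {
    stop("config must contain exactly one of `input` or `simulate`",
         call. = FALSE)
  }
  if (is.null(config$seed)) stop("config requires a seed", call. = FALSE)
  if (is.null(config$out_dir)) stop("config requires out_dir", call. = FALSE)
  if (is.null(config$analysis)) config$analysis <- list()
  a <- config$analysis
  config$analysis$rater <- if (is.null(a$rater)) "gambler" else a$rater
  config$analysis$contrast_weeks <-
    if (is.null(a$contrast_weeks)) c(12, 25, 38) else a$contrast_weeks
  config$analysis$ppc_n_rep <- if (is.null(a$ppc_n_rep)) 200 else a$ppc_n_rep
  structure(config, class = c("run_config", "list"))
}

.mcmc_from_config <- function(a) {
  args <- a$mcmc
  if (is.null(args)) args <- list()
  do.call(mcmc_config, args)
}

.priors_from_config <- function(a) {
  args <- a$priors
  if (is.null(args)) args <- list()
  do.call(twopart_priors, args)
}

#' Run the full trial analysis pipeline
#'
#' Executes the stages end to end: obtain data (simulate a synthetic trial
#' or read the CSV interfaces), ingest and aggregate the TLFB-G series for
#' the chosen rater, build the spline + discontinuity design, fit the
#' two-part model, compute marginal losses and arm contrasts, score the
#' questionnaires and fit a linear mixed model per instrument and role,
#' and run posterior predictive checks. All exports plus a manifest
#' (config echo, seeds consumed, package version, diagnostics, collected
#' warnings) are written under `config$out_dir`.
#'
#' @param config A [run_config] (or anything it accepts).
#' @return Invisibly, a list with all stage results and `ok` — `TRUE` when
#'   every fit passed its convergence gate (drives the CLI exit status).
#' @export
run_full_analysis <- function(config) {
  config <- run_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  warnings_log <- character(0)
  note <- function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  seeds <- list(master = config$seed)
  set.seed(config$seed)
  stage_seeds <- sample.int(2^31 - 2, 5)
  seeds$simulate <- stage_seeds[1]; seeds$fit_tlfb <- stage_seeds[2]
  seeds$fit_lmm <- stage_seeds[3]; seeds$ppc <- stage_seeds[4]
  seeds$dropout <- stage_seeds[5]

  # --- data -----------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    apply_do <- isTRUE(sim_args$apply_dropout)
    sim_args$apply_dropout <- NULL
    sim_args$seed <- seeds$simulate
    trial <- generate_trial(do.call(trial_config, sim_args))
    if (apply_do) trial <- apply_dropout(trial, seed = seeds$dropout)
    roster <- trial$roster
    daily <- trial$tlfb_daily
    quest <- trial$questionnaires
  } else {
    roster <- utils::read.csv(config$input$participants)
    daily <- utils::read.csv(config$input$tlfb_daily)
    names(daily)[names(daily) == "net_loss_sek"] <- "net_loss"
    quest <- utils::read.csv(config$input$questionnaires)
    trial <- NULL
  }

  # --- TLFB: ingest -> aggregate -> design -> fit ---------------------
  ing <- withCallingHandlers(ingest_daily(daily), warning = note)
  weekly_all <- aggregate_weekly(ing)
  rater <- config$analysis$rater
  weekly <- weekly_all[weekly_all$rater == rater, , drop = FALSE]
  arms <- stats::setNames(roster$arm, roster$participant_id)
  knots <- config$analysis$knots
  ai <- config$analysis$arm_interactions
  design <- build_design(weekly, arms = arms,
                         knots = if (is.null(knots)) NULL else knots,
                         arm_interactions = if (is.null(ai)) {
                           c("post", "lin", "nonlin")
                         } else ai)
  mcmc <- .mcmc_from_config(config$analysis)
  priors <- .priors_from_config(config$analysis)
  fit <- withCallingHandlers(
    fit_twopart(weekly, design, priors = priors, mcmc = mcmc,
                seed = seeds$fit_tlfb),
    warning = note
  )
  cw <- config$analysis$contrast_weeks
  contrasts <- withCallingHandlers(arm_contrast(fit, cw), warning = note)
  marginals <- do.call(rbind, lapply(c(0, cw), function(w) {
    rbind(marginal_daily_loss(fit, w, "BCT"),
          marginal_daily_loss(fit, w, "CBT"))
  }))

  # --- questionnaires: score + LMM per instrument/role ----------------
  scored <- score_questionnaires(quest)
  role_of <- stats::setNames(roster$role, roster$participant_id)
  scored$role <- role_of[scored$participant_id]
  scored$arm <- arms[scored$participant_id]
  lmm_fits <- list()
  lmm_tables <- list()
  li <- 0
  for (inst in c("NODS", "PHQ9", "GAD7")) {
    roles <- if (inst == "NODS") "gambler" else c("gambler", "cso")
    for (rl in roles) {
      sub <- scored[scored$instrument == inst & scored$role == rl &
                      scored$timepoint %in% .timepoints, ]
      if (nrow(sub) == 0 || length(unique(sub$timepoint)) < 2) next
      li <- li + 1
      key <- paste(inst, rl, sep = "_")
      lmm_fits[[key]] <- withCallingHandlers(
        fit_lmm(sub, priors = priors, mcmc = mcmc,
                seed = (seeds$fit_lmm + li) %% (2^31 - 1)),
        warning = note
      )
      lmm_tables[[key]] <- lmm_table(lmm_fits[[key]])
    }
  }

  # --- posterior predictive checks ------------------------------------
  n_rep <- config$analysis$ppc_n_rep
  reps <- simulate_replicates(fit, n_rep, seed = seeds$ppc)
  rep_stats <- t(apply(reps, 2, ppc_stats))
  ppc <- ppc_compare(ppc_stats(weekly$avg_daily_loss), rep_stats)

  # --- exports --------------------------------------------------------
  utils::write.csv(weekly_all, file.path(out_dir, "tlfb_weekly.csv"),
                   row.names = FALSE)
  utils::write.csv(scored, file.path(out_dir, "questionnaires_scored.csv"),
                   row.names = FALSE)
  utils::write.csv(fit$draws, file.path(out_dir, "twopart_draws.csv"),
                   row.names = FALSE)
  utils::write.csv(rbind(marginals, contrasts),
                   file.path(out_dir, "twopart_summary.csv"),
                   row.names = FALSE)
  for (key in names(lmm_tables)) {
    utils::write.csv(lmm_tables[[key]],
                     file.path(out_dir, paste0("lmm_", key, ".csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    lapply(seq_len(nrow(ppc)), function(i) as.list(ppc[i, ])),
    file.path(out_dir, "ppc_report.json"), auto_unbox = TRUE, digits = NA)
  ok <- fit$diagnostics$converged &&
    all(vapply(lmm_fits, function(f) f$diagnostics$converged, logical(1)))
  manifest <- list(
    package_version = as.character(utils::packageVersion("gamblehurdle")),
    config = unclass(config),
    seeds = seeds,
    ingest_report = ing$report,
    twopart_diagnostics = list(
      max_rhat = max(fit$diagnostics$rhat, na.rm = TRUE),
      min_ess = min(fit$diagnostics$ess),
      converged = fit$diagnostics$converged),
    lmm_converged = lapply(lmm_fits, function(f) f$diagnostics$converged),
    warnings = warnings_log,
    ok = ok
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(trial = trial, weekly = weekly, design = design, fit = fit,
                 marginals = marginals, contrasts = contrasts,
                 scored = scored, lmm_fits = lmm_fits,
                 lmm_tables = lmm_tables, ppc = ppc, manifest = manifest,
                 ok = ok))
}
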