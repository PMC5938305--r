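# Timepoint -> week anchors shared by the questionnaire schedule and the
# dropout mechanism.
.tp_weeks <- c(pre = 0, post = 12, m3 = 25, m6 = 38)

# Draw correlated subject intercepts from the 2x2 covariance.
.draw_intercepts <- function(n, sd_occ, sd_amt, rho) {
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  cbind(occ = sd_occ * z1,
        amt = sd_amt * (rho * z1 + sqrt(1 - rho^2) * z2))
}

#' Simulate weekly losses exactly from the two-part model
#'
#' Inverts the inference model: draws correlated subject intercepts from
#' the 2x2 covariance, then for every subject-week a Bernoulli gambling
#' indicator with probability `p` (inverse-logit occurrence predictor) and,
#' when gambling occurred, a gamma average daily loss with mean
#' `exp(amount predictor)` and the given shape. Produces exact model data
#' for parameter-recovery and coverage studies.
#'
#' @param params A [twopart_params] whose coefficient vectors conform to
#'   the design implied by `trial_shape`.
#' @param trial_shape List: `n_subjects`, `weeks` (default `0:13`),
#'   optional `arms` (default alternating BCT/CBT), optional `knots`
#'   (default placed from the week values), optional `arm_interactions`.
#' @param seed Integer seed; identical seed yields identical tables.
#' @return List: `weekly` (data frame `participant_id`, `rater`, `week`,
#'   `avg_daily_loss`, `n_days_observed`), `design` (the `time_design`
#'   used), `truth` (the generating `params`), `b` (true subject
#'   intercepts).
#' @export
generate_from_model <- function(params, trial_shape, seed) {
  if (!inherits(params, "twopart_params")) {
    params <- do.call(twopart_params, params)
  }
  n <- trial_shape$n_subjects
  stopifnot(n >= 1)
  weeks <- if (is.null(trial_shape$weeks)) 0:13 else trial_shape$weeks
  arms <- if (is.null(trial_shape$arms)) {
    rep(c("BCT", "CBT"), length.out = n)
  } else trial_shape$arms
  stopifnot(length(arms) == n)
  ids <- sprintf("S%03d", seq_len(n))
  skel <- data.frame(
    participant_id = rep(ids, each = length(weeks)),
    week = rep(weeks, n)
  )
  knots <- if (is.null(trial_shape$knots)) place_knots(skel$week) else trial_shape$knots
  ai <- if (is.null(trial_shape$arm_interactions)) {
    c("post", "lin", "nonlin")
  } else trial_shape$arm_interactions
  design <- build_design(skel, arms = stats::setNames(arms, ids),
                         knots = knots, arm_interactions = ai)
  if (length(params$beta_occ) != ncol(design$X)) {
    stop(sprintf("params have %d coefficients but the design has %d columns",
                 length(params$beta_occ), ncol(design$X)), call. = FALSE)
  }
  set.seed(seed)
  b <- .draw_intercepts(n, params$sd_occ, params$sd_amt, params$rho)
  subj <- match(skel$participant_id, ids)
  p <- stats::plogis(as.numeric(design$X %*% params$beta_occ) + b[subj, "occ"])
  mu <- exp(as.numeric(design$X %*% params$beta_amt) + b[subj, "amt"])
  z <- stats::rbinom(nrow(skel), 1, p)
  y <- ifelse(z == 1,
              stats::rgamma(nrow(skel), shape = params$shape,
                            rate = params$shape / mu),
              0)
  weekly <- data.frame(
    participant_id = skel$participant_id, rater = "gambler",
    week = skel$week, avg_daily_loss = y, n_days_observed = 7L
  )
  list(weekly = weekly, design = design, truth = params, b = b,
       arms = stats::setNames(arms, ids))
}

#' Configuration of a synthetic gambling trial
#'
#' Describes the full generative process of a behaviorally structured
#' synthetic trial: pair count and 1:1 pair-level randomization, the daily
#' gambling process (abstinence runs broken by binge episodes), the
#' treatment effect applied after treatment start, questionnaire cell
#' means, and the monotone MAR dropout hazard. Defaults emulate an
#' 18-pair internet-delivered trial: heavily zero-inflated daily losses
#' with right-skewed binge amounts around 1500 SEK/day, an abrupt
#' reduction in gambling at treatment start that is similar in both arms,
#' and questionnaire trajectories that improve from the clinical range
#' toward recovery over pre/post/3-month/6-month assessments.
#'
#' @param n_pairs Number of gambler/CSO pairs (default 18).
#' @param seed Integer seed.
#' @param binge List: `abstinence_mean_days` (mean abstinence-run length,
#'   geometric), `binge_mean_days` (mean binge-episode length, geometric),
#'   `loss_meanlog`, `loss_sdlog` (lognormal daily loss during a binge).
#' @param effect List: `post_occ_multiplier` and `post_loss_multiplier`,
#'   named per arm — multipliers applied to the daily gambling hazard and
#'   to binge losses after treatment start.
#' @param dropout List: `base_hazard` (per-week), `per_1000_sek`
#'   (log-hazard increment per 1000 SEK of the last observed weekly loss —
#'   MAR, depends on observed history only), `arm_multiplier` named per
#'   arm.
#' @param questionnaires Nested list of cell means and SDs per instrument
#'   and role; see the package default for the layout.
#' @param cso_rating List: `sdlog` of the lognormal multiplicative noise on
#'   the CSO's rating of the gambler's losses.
#' @return A `trial_config` list.
#' @export
trial_config <- function(n_pairs = 18, seed = 1,
                         binge = list(abstinence_mean_days = 6,
                                      binge_mean_days = 2,
                                      loss_meanlog = log(1500),
                                      loss_sdlog = 0.8),
                         effect = list(
                           post_occ_multiplier = c(BCT = 0.3, CBT = 0.3),
                           post_loss_multiplier = c(BCT = 0.6, CBT = 0.6)),
                         dropout = list(base_hazard = 0.015,
                                        per_1000_sek = 0.1,
                                        arm_multiplier = c(BCT = 1, CBT = 1)),
                         questionnaires = NULL,
                         cso_rating = list(sdlog = 0.3)) {
  if (n_pairs < 1) stop("n_pairs must be >= 1", call. = FALSE)
  if (binge$abstinence_mean_days <= 0 || binge$binge_mean_days <= 0) {
    stop("abstinence and binge run lengths must be positive", call. = FALSE)
  }
  if (dropout$base_hazard < 0 || dropout$base_hazard > 1) {
    stop("dropout hazard must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(questionnaires)) questionnaires <- .default_questionnaire_truth()
  structure(list(n_pairs = n_pairs, seed = seed, binge = binge,
                 effect = effect, dropout = dropout,
                 questionnaires = questionnaires, cso_rating = cso_rating),
            class = "trial_config")
}

# Cell-mean trajectories (pre, post, m3, m6) per instrument, role and arm.
# Chosen to emulate a trial where both arms' gamblers improve markedly and
# the BCT CSOs improve more than the CBT CSOs.
.default_questionnaire_truth <- function() {
  list(
    NODS = list(sd = 2, gambler = list(BCT = c(6.9, 3.1, 2.6, 2.2),
                                       CBT = c(6.4, 2.8, 2.0, 1.5))),
    PHQ9 = list(sd = 4, gambler = list(BCT = c(11.7, 5.2, 6.5, 6.6),
                                       CBT = c(12.3, 4.5, 6.8, 3.6)),
                cso = list(BCT = c(10.2, 4.7, 3.2, 4.1),
                           CBT = c(6.8, 7.0, 10.0, 5.4))),
    GAD7 = list(sd = 3, gambler = list(BCT = c(8.2, 3.9, 2.9, 5.6),
                                       CBT = c(8.8, 2.2, 3.7, 2.7)),
                cso = list(BCT = c(10.3, 4.7, 4.1, 3.7),
                           CBT = c(6.4, 5.4, 8.5, 5.8)))
  )
}

# Distribute an integer total across items respecting per-item maxima.
.items_from_total <- function(total, n_items, item_max) {
  items <- integer(n_items)
  for (i in seq_len(total)) {
    open <- which(items < item_max)
    pick <- open[sample.int(length(open), 1)]
    items[pick] <- items[pick] + 1L
  }
  items
}

# NODS items endorsing exactly `total` criteria under the gated layout.
.nods_items_from_total <- function(total) {
  items <- integer(17)
  chosen <- sample(seq_along(.nods_criteria), total)
  for (ci in chosen) {
    cr <- .nods_criteria[[ci]]
    if (cr$rule == "all") {
      items[cr$items] <- 1L
    } else {
      items[cr$items[sample.int(length(cr$items), 1)]] <- 1L
    }
  }
  items
}

.draw_total <- function(mean, sd, max_total, min_total = 0) {
  t <- round(stats::rnorm(1, mean, sd))
  min(max(t, min_total), max_total)
}

# Daily loss series for one gambler over a day grid: alternating geometric
# abstinence runs and binge episodes with lognormal daily losses; after
# day 0 the arm's multipliers shrink the gambling hazard and the losses.
.daily_series <- function(days, binge, occ_mult, loss_mult) {
  p_gamble_base <- binge$binge_mean_days /
    (binge$binge_mean_days + binge$abstinence_mean_days)
  out <- numeric(length(days))
  state <- "abstinent"
  remaining <- stats::rgeom(1, 1 / binge$abstinence_mean_days) + 1
  for (i in seq_along(days)) {
    post <- days[i] >= 0
    if (remaining == 0) {
      if (state == "abstinent") {
        # chance to start a binge; treatment lowers it after day 0
        start <- stats::runif(1) < p_gamble_base * (if (post) occ_mult else 1)
        if (start) {
          state <- "binge"
          remaining <- stats::rgeom(1, 1 / binge$binge_mean_days) + 1
        } else {
          remaining <- stats::rgeom(1, 1 / binge$abstinence_mean_days) + 1
        }
      } else {
        state <- "abstinent"
        remaining <- stats::rgeom(1, 1 / binge$abstinence_mean_days) + 1
      }
    }
    if (state == "binge") {
      out[i] <- stats::rlnorm(1, binge$loss_meanlog, binge$loss_sdlog) *
        (if (post) loss_mult else 1)
    }
    remaining <- remaining - 1
  }
  out
}

#' Generate a behaviorally structured synthetic trial
#'
#' Builds a full synthetic trial from a [trial_config]: an
#' eligible-by-construction roster (every gambler screens PGSI >= 8, every
#' CSO below the problem threshold, adults, relationship of at least
#' 3 months), pair-level 1:1 randomization, daily TLFB-G losses built from
#' alternating abstinence runs and binge episodes (zero-heavy with skewed
#' positive losses, dropping abruptly at treatment start), a CSO-rated
#' parallel series with multiplicative noise, and questionnaire item tables
#' whose totals follow the configured cell-mean trajectories.
#'
#' The day grid covers the baseline month (days -30..-1), the treatment and
#' post-treatment window (days 0..83, weeks 1-12) and one recalled month
#' before each of the 3- and 6-month assessments.
#'
#' @param config A [trial_config].
#' @return A `synthetic_trial`: `roster`, `tlfb_daily`, `tlfb_weekly`
#'   (gambler-rated), `questionnaires`, `truth` (config echo).
#' @export
generate_trial <- function(config = trial_config()) {
  stopifnot(inherits(config, "trial_config"))
  set.seed(config$seed)
  n <- config$n_pairs
  pair_ids <- sprintf("P%02d", seq_len(n))
  arms <- sample(rep(c("BCT", "CBT"), length.out = n))
  roster <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(
      pair_id = pair_ids[i],
      participant_id = paste0(pair_ids[i], c("G", "C")),
      role = c("gambler", "cso"),
      arm = arms[i],
      age = sample(18:70, 2, replace = TRUE),
      sex = sample(c("male", "female"), 2, replace = TRUE),
      relationship_months = sample(3:300, 1),
      screening_pgsi = c(.draw_total(19, 4, 27, min_total = 8),
                         .draw_total(1.5, 1.5, 7)),
      severe_psychiatric = FALSE
    )
  }))
  rownames(roster) <- NULL
  days <- c(-30:-1, 0:83, 147:174, 238:265)
  tlfb_daily <- do.call(rbind, lapply(seq_len(n), function(i) {
    arm <- arms[i]
    g <- .daily_series(days, config$binge,
                       config$effect$post_occ_multiplier[[arm]],
                       config$effect$post_loss_multiplier[[arm]])
    cso <- g * ifelse(g > 0,
                      stats::rlnorm(length(g), 0, config$cso_rating$sdlog), 1)
    rbind(
      data.frame(participant_id = paste0(pair_ids[i], "G"), rater = "gambler",
                 study_day = days, net_loss = g),
      data.frame(participant_id = paste0(pair_ids[i], "G"), rater = "cso",
                 study_day = days, net_loss = cso)
    )
  }))
  rownames(tlfb_daily) <- NULL
  tlfb_weekly <- aggregate_weekly(ingest_daily(tlfb_daily))
  q_truth <- config$questionnaires
  quest <- list()
  for (i in seq_len(n)) {
    for (role in c("gambler", "cso")) {
      pid <- paste0(pair_ids[i], if (role == "gambler") "G" else "C")
      arm <- arms[i]
      # PGSI at screening: items consistent with the roster total
      pg <- roster$screening_pgsi[roster$participant_id == pid]
      quest[[length(quest) + 1]] <- .quest_row(pid, "PGSI", "pre",
                                               .items_from_total(pg, 9, 3))
      if (role == "gambler") {
        # AUDIT administered before treatment only
        quest[[length(quest) + 1]] <- .quest_row(
          pid, "AUDIT", "pre", .items_from_total(.draw_total(4.2, 3, 40), 10, 4))
      }
      for (inst in names(q_truth)) {
        tr <- q_truth[[inst]][[role]]
        if (is.null(tr)) next
        for (ti in seq_along(.tp_weeks)) {
          tp <- names(.tp_weeks)[ti]
          tot <- .draw_total(tr[[arm]][ti], q_truth[[inst]]$sd,
                             .instrument_spec[[inst]]$total_max)
          items <- if (inst == "NODS") .nods_items_from_total(tot)
                   else .items_from_total(tot, .instrument_spec[[inst]]$n_items,
                                          .instrument_spec[[inst]]$item_max)
          quest[[length(quest) + 1]] <- .quest_row(pid, inst, tp, items)
        }
      }
    }
  }
  questionnaires <- do.call(rbind, quest)
  rownames(questionnaires) <- NULL
  structure(
    list(roster = roster, tlfb_daily = tlfb_daily, tlfb_weekly = tlfb_weekly,
         questionnaires = questionnaires, truth = config),
    class = "synthetic_trial"
  )
}

.quest_row <- function(pid, inst, tp, items) {
  row <- data.frame(participant_id = pid, instrument = inst, timepoint = tp)
  it <- rep(NA_integer_, 17)
  it[seq_along(items)] <- items
  row[paste0("item_", 1:17)] <- as.list(it)
  row
}

#' @export
print.synthetic_trial <- function(x, ...) {
  cat(sprintf(paste0(
    "synthetic_trial: %d pairs (%d participants), %d daily TLFB rows, ",
    "%d weekly rows, %d questionnaire rows\n"),
    x$truth$n_pairs, nrow(x$roster), nrow(x$tlfb_daily),
    nrow(x$tlfb_weekly), nrow(x$questionnaires)))
  invisible(x)
}

#' Apply monotone MAR dropout to a synthetic trial
#'
#' Simulates per-participant dropout with a weekly hazard that depends only
#' on arm, week and the last observed weekly loss (missing at random:
#' missingness never depends on unobserved data). Dropout is monotone: once
#' a participant drops at week `w`, all TLFB records after week `w` and all
#' questionnaires scheduled after week `w` are removed. Both members of a
#' pair drop independently; the gambler's dropout removes both raters'
#' TLFB series (the CSO rates the gambler's gambling).
#'
#' @param trial A `synthetic_trial`.
#' @param dropout Dropout config (default the trial's own
#'   `truth$dropout`): `base_hazard`, `per_1000_sek`, `arm_multiplier`.
#' @param seed Integer seed.
#' @return The trial with missingness applied and a `missingness` data
#'   frame attached (`participant_id`, `dropout_week`, `NA` = completed).
#' @export
apply_dropout <- function(trial, dropout = NULL, seed) {
  stopifnot(inherits(trial, "synthetic_trial"))
  if (is.null(dropout)) dropout <- trial$truth$dropout
  if (dropout$base_hazard < 0 || dropout$base_hazard > 1) {
    stop("dropout hazard must lie in [0, 1]", call. = FALSE)
  }
  set.seed(seed)
  weekly <- trial$tlfb_weekly
  roster <- trial$roster
  max_week <- max(weekly$week)
  drop_week <- stats::setNames(rep(NA_real_, nrow(roster)),
                               roster$participant_id)
  for (i in seq_len(nrow(roster))) {
    pid <- roster$participant_id[i]
    arm <- roster$arm[i]
    gid <- paste0(roster$pair_id[i], "G")  # losses observed on the gambler
    ws <- weekly[weekly$participant_id == gid & weekly$rater == "gambler", ]
    last_loss <- 0
    for (w in 1:max_week) {
      row <- ws[ws$week == max(ws$week[ws$week < w], 0), ]
      if (nrow(row)) last_loss <- row$avg_daily_loss[1]
      hz <- min(1, dropout$base_hazard *
                  exp(dropout$per_1000_sek * last_loss / 1000) *
                  dropout$arm_multiplier[[arm]])
      if (stats::runif(1) < hz) {
        drop_week[pid] <- w
        break
      }
    }
  }
  # gambler dropout removes both raters' TLFB (the series is the gambler's)
  keep_tlfb <- function(df, week_col) {
    gambler_of <- stats::setNames(paste0(roster$pair_id, "G"),
                                  roster$participant_id)
    dw <- drop_week[gambler_of[df$participant_id]]
    df[is.na(dw) | df[[week_col]] <= dw, , drop = FALSE]
  }
  weekly_wk <- weekly$week
  trial$tlfb_weekly <- keep_tlfb(weekly, "week")
  daily <- trial$tlfb_daily
  daily$week <- default_week_map(daily$study_day)
  trial$tlfb_daily <- keep_tlfb(daily, "week")
  trial$tlfb_daily$week <- NULL
  q <- trial$questionnaires
  qw <- .tp_weeks[q$timepoint]
  dwq <- drop_week[q$participant_id]
  trial$questionnaires <- q[is.na(dwq) | qw <= dwq, , drop = FALSE]
  trial$missingness <- data.frame(participant_id = names(drop_week),
                                  dropout_week = unname(drop_week))
  trial
}
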