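#' Default study-day to week mapping
#'
#' Maps TLFB-G study days onto the weekly modeling grid: the baseline month
#' (negative study days, day 0 = treatment start) collapses to week 0, and
#' post-baseline days fall into calendar weeks from treatment start
#' (`floor(day / 7) + 1`). Under this rule the 10 treatment weeks are weeks
#' 1-10, the post-treatment assessment month ends at week 12, and TLFB
#' windows recalled at the 3- and 6-month follow-ups land in weeks around
#' 25 and 38.
#'
#' @param study_day Integer vector of study days (0 = treatment start,
#'   negative = baseline month).
#' @return Integer vector of week indices (>= 0).
#' @export
default_week_map <- function(study_day) {
  ifelse(study_day < 0, 0L, as.integer(study_day %/% 7L) + 1L)
}

#' Ingest raw daily TLFB-G loss records
#'
#' Validates and cleans raw daily net-loss rows. Days with a net win
#' (negative net loss) are clamped to zero when `clamp_negative` is `TRUE`;
#' every clamp is counted and reported, never silent. Duplicate
#' (participant, rater, day) keys are rejected.
#'
#' @param records Data frame with columns `participant_id`, `rater`
#'   (`"gambler"` or `"cso"`), `study_day`, `net_loss` (SEK per day).
#' @param clamp_negative Clamp negative net losses to 0 (default `TRUE`).
#' @return A list of class `tlfb_ingest`: `records` (clean data frame) and
#'   `report` (`n_clamped`, `clamped_rows`, `n_records`).
#' @export
ingest_daily <- function(records, clamp_negative = TRUE) {
  need <- c("participant_id", "rater", "study_day", "net_loss")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (!is.numeric(records$net_loss)) {
    bad <- which(is.na(suppressWarnings(as.numeric(records$net_loss))))
    stop("non-numeric net_loss at row ",
         if (length(bad)) bad[1] else "(unknown)", call. = FALSE)
  }
  if (anyNA(records$net_loss)) {
    stop("non-numeric net_loss at row ", which(is.na(records$net_loss))[1],
         call. = FALSE)
  }
  key <- paste(records$participant_id, records$rater, records$study_day,
               sep = "\r")
  if (anyDuplicated(key)) {
    d <- records[duplicated(key), , drop = FALSE][1, ]
    stop(sprintf("duplicate daily record for (%s, %s, day %s)",
                 d$participant_id, d$rater, d$study_day), call. = FALSE)
  }
  clamped_rows <- integer(0)
  out <- records[, need]
  if (any(out$net_loss < 0)) {
    clamped_rows <- which(out$net_loss < 0)
    if (clamp_negative) {
      out$net_loss[clamped_rows] <- 0
    } else {
      stop("negative net_loss present and clamp_negative = FALSE; first at row ",
           clamped_rows[1], call. = FALSE)
    }
  }
  structure(
    list(records = out,
         report = list(n_records = nrow(out),
                       n_clamped = length(clamped_rows),
                       clamped_rows = clamped_rows)),
    class = "tlfb_ingest"
  )
}

#' @export
print.tlfb_ingest <- function(x, ...) {
  cat(sprintf("TLFB-G ingest: %d daily records, %d negative losses clamped to 0\n",
              x$report$n_records, x$report$n_clamped))
  invisible(x)
}

#' Aggregate daily TLFB-G losses to average daily loss per week
#'
#' The modeling unit is the participant-week average daily loss, which keeps
#' the meaning of a zero ("no gambling that week") identical across the
#' baseline month, treatment weeks and follow-up windows. The average is
#' taken over observed days only; a week with no observed days is simply
#' absent (missing, handled downstream under MAR).
#'
#' @param daily A `tlfb_ingest` object or a clean daily data frame.
#' @param week_map Function mapping `study_day` to week index;
#'   default [default_week_map].
#' @return Data frame with `participant_id`, `rater`, `week`,
#'   `avg_daily_loss`, `n_days_observed`, sorted by participant, rater, week.
#' @export
aggregate_weekly <- function(daily, week_map = default_week_map) {
  if (inherits(daily, "tlfb_ingest")) daily <- daily$records
  wk <- week_map(daily$study_day)
  key <- interaction(daily$participant_id, daily$rater, wk, drop = TRUE)
  agg <- data.frame(
    participant_id = tapply(daily$participant_id, key, `[`, 1),
    rater = tapply(daily$rater, key, `[`, 1),
    week = as.integer(tapply(wk, key, `[`, 1)),
    avg_daily_loss = as.numeric(tapply(daily$net_loss, key, mean)),
    n_days_observed = as.integer(tapply(daily$net_loss, key, length)),
    row.names = NULL
  )
  agg <- agg[order(agg$participant_id, agg$rater, agg$week), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Place restricted-cubic-spline knots at the 10th/50th/90th percentiles
#'
#' Knots are placed at the 10th, 50th and 90th percentiles of the
#' observation-level week variable, using linear interpolation between order
#' statistics. Three knots keep the spline parsimonious for a small trial.
#'
#' @param weeks Numeric vector of week values, one per observation.
#' @return Numeric vector of three increasing knots.
#' @export
place_knots <- function(weeks) {
  if (length(unique(weeks)) < 3) {
    stop("need at least 3 distinct week values to place spline knots",
         call. = FALSE)
  }
  k <- unname(stats::quantile(weeks, probs = c(0.1, 0.5, 0.9), type = 7))
  if (any(diff(k) <= 0)) {
    stop("degenerate knots (percentiles coincide): ",
         paste(signif(k, 4), collapse = ", "), call. = FALSE)
  }
  k
}

#' Restricted cubic spline basis with three knots
#'
#' Builds the two-column truncated-power basis of a restricted cubic spline
#' with knots `k1 < k2 < k3`: a linear column `x` and one nonlinear column
#' built from truncated cubes constrained so the function is linear beyond
#' both boundary knots, scaled by `(k3 - k1)^2` so both columns share the
#' scale of `x`.
#'
#' @param x Numeric vector of time values.
#' @param knots Numeric vector of three increasing knots.
#' @return Matrix with columns `lin` and `nonlin`, `length(x)` rows.
#' @export
rcs_basis <- function(x, knots) {
  if (length(knots) != 3 || any(diff(knots) <= 0)) {
    stop("knots must be three increasing values", call. = FALSE)
  }
  k1 <- knots[1]; k2 <- knots[2]; k3 <- knots[3]
  cube <- function(u) pmax(u, 0)^3
  nonlin <- (cube(x - k1) -
               cube(x - k2) * (k3 - k1) / (k3 - k2) +
               cube(x - k3) * (k2 - k1) / (k3 - k2)) / (k3 - k1)^2
  cbind(lin = x, nonlin = nonlin)
}

#' Build the two-part model's time design matrix
#'
#' Columns: intercept; `post`, a 0/1 dummy separating the baseline week from
#' all post-baseline weeks (the discontinuous treatment-start jump); the two
#' restricted-cubic-spline columns centered so both are 0 at week 0; and the
#' arm interactions. BCT is the reference arm and arm effects enter only
#' through post-baseline interaction columns, so the baseline (week 0) mean
#' is constrained to be identical across arms: every column that differs by
#' arm is identically 0 at week 0.
#'
#' @param weekly Data frame with `participant_id` and `week` columns
#'   (e.g. from [aggregate_weekly]).
#' @param arms Either a named character vector mapping participant id to
#'   `"BCT"`/`"CBT"`, or `NULL` if `weekly` carries an `arm` column.
#' @param knots Three spline knots; default `place_knots(weekly$week)`.
#' @param arm_interactions Which time columns interact with arm; default all
#'   of `post`, `lin`, `nonlin`.
#' @return A `time_design`: design matrix `X` plus metadata (`knots`,
#'   `arm_levels`, `arm_interactions`, aligned `week`, `arm`,
#'   `participant_id`).
#' @export
build_design <- function(weekly, arms = NULL, knots = NULL,
                         arm_interactions = c("post", "lin", "nonlin")) {
  if (is.null(arms)) {
    if (!"arm" %in% names(weekly)) {
      stop("no arm labels: supply `arms` or an `arm` column", call. = FALSE)
    }
    arm <- as.character(weekly$arm)
  } else {
    arm <- as.character(arms[as.character(weekly$participant_id)])
  }
  bad <- !arm %in% c("BCT", "CBT") | is.na(arm)
  if (any(bad)) {
    stop("unknown arm label: ",
         paste(unique(arm[bad]), collapse = ", "), call. = FALSE)
  }
  arm_interactions <- match.arg(arm_interactions,
                                c("post", "lin", "nonlin"), several.ok = TRUE)
  week <- as.numeric(weekly$week)
  if (is.null(knots)) knots <- place_knots(week)
  B <- rcs_basis(week, knots)
  B0 <- rcs_basis(0, knots)
  B <- sweep(B, 2, as.numeric(B0))  # center: both spline columns 0 at week 0
  post <- as.numeric(week > 0)
  cbt <- as.numeric(arm == "CBT")
  timecols <- cbind(post = post, week_lin = B[, "lin"],
                    week_nonlin = B[, "nonlin"])
  inter_names <- c(post = "post", lin = "week_lin", nonlin = "week_nonlin")
  icols <- timecols[, inter_names[arm_interactions], drop = FALSE] * cbt
  colnames(icols) <- paste0(inter_names[arm_interactions], ":armCBT")
  X <- cbind("(Intercept)" = 1, timecols, icols)
  structure(
    list(X = X, knots = knots, arm_levels = c("BCT", "CBT"),
         arm_interactions = arm_interactions, week = week, arm = arm,
         participant_id = as.character(weekly$participant_id)),
    class = "time_design"
  )
}

#' @export
print.time_design <- function(x, ...) {
  cat(sprintf("time_design: %d rows x %d columns, knots at (%s)\n",
              nrow(x$X), ncol(x$X),
              paste(signif(x$knots, 4), collapse = ", ")))
  invisible(x)
}

#' Covariate row for a given week and arm
#'
#' Rebuilds one design row (same columns as [build_design]) for prediction,
#' marginal summaries and contrasts.
#'
#' @param design A `time_design` (source of knots and column layout).
#' @param week Week value.
#' @param arm `"BCT"` or `"CBT"`.
#' @return Named numeric vector conforming to `design$X` columns.
#' @export
design_row <- function(design, week, arm) {
  stopifnot(inherits(design, "time_design"))
  if (!arm %in% c("BCT", "CBT")) stop("unknown arm label: ", arm, call. = FALSE)
  B <- as.numeric(rcs_basis(week, design$knots) - rcs_basis(0, design$knots))
  post <- as.numeric(week > 0)
  cbt <- as.numeric(arm == "CBT")
  timecols <- c(post = post, week_lin = B[1], week_nonlin = B[2])
  inter_names <- c(post = "post", lin = "week_lin", nonlin = "week_nonlin")
  sel <- inter_names[design$arm_interactions]
  row <- c("(Intercept)" = 1, timecols,
           stats::setNames(timecols[sel] * cbt, paste0(sel, ":armCBT")))
  row[colnames(design$X)]
}
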