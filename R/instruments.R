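# Instrument metadata: item counts and per-item score ranges.
.instrument_spec <- list(
  NODS  = list(n_items = 17, item_max = 1,  total_max = 10),
  PGSI  = list(n_items = 9,  item_max = 3,  total_max = 27),
  PHQ9  = list(n_items = 9,  item_max = 3,  total_max = 27),
  GAD7  = list(n_items = 7,  item_max = 3,  total_max = 21),
  AUDIT = list(n_items = 10, item_max = 4,  total_max = 40)
)

.check_items <- function(items, instrument) {
  spec <- .instrument_spec[[instrument]]
  if (length(items) != spec$n_items) {
    stop(sprintf("%s requires %d items, got %d",
                 instrument, spec$n_items, length(items)), call. = FALSE)
  }
  if (anyNA(items) || !is.numeric(items)) {
    stop(sprintf("%s items must be numeric and non-missing", instrument),
         call. = FALSE)
  }
  bad <- which(items < 0 | items > spec$item_max | items != round(items))
  if (length(bad)) {
    stop(sprintf("%s item %d out of range [0, %d]: %s",
                 instrument, bad[1], spec$item_max, items[bad[1]]),
         call. = FALSE)
  }
  as.integer(items)
}

.scored <- function(instrument, total, category, flag = NA) {
  structure(
    list(instrument = instrument, total = as.integer(total),
         category = category, flag = flag),
    class = "scored_instrument"
  )
}

#' @export
print.scored_instrument <- function(x, ...) {
  cat(sprintf("%s total %d: %s", x$instrument, x$total, x$category))
  if (!is.na(x$flag)) cat(sprintf(" [flag: %s]", x$flag))
  cat("\n")
  invisible(x)
}

# Map a total to a category given band lower edges (descending) and labels.
.band <- function(total, edges, labels) {
  labels[[which(total >= edges)[1]]]
}

#' Score the PHQ-9 depression questionnaire
#'
#' Sums the nine items (each 0-3) and maps the total to the standard severity
#' bands: 0-4 no depression, 5-9 minimal symptoms, 10-14 minor depression,
#' 15-19 moderately severe major depression, 20-27 severe major depression.
#'
#' @param items Integer vector of 9 item scores, each in 0-3.
#' @return A `scored_instrument` with `total` and `category`.
#' @examples
#' score_phq9(c(2, 1, 2, 1, 2, 1, 1, 1, 1))
#' @export
score_phq9 <- function(items) {
  items <- .check_items(items, "PHQ9")
  total <- sum(items)
  cat_ <- .band(total, c(20, 15, 10, 5, 0),
                c("severe major depression", "moderately severe major depression",
                  "minor depression", "minimal symptoms", "no depression"))
  .scored("PHQ9", total, cat_)
}

#' Score the GAD-7 anxiety questionnaire
#'
#' Sums the seven items (each 0-3); bands: 0-4 no anxiety, 5-9 mild,
#' 10-14 moderate, 15-21 severe anxiety.
#'
#' @param items Integer vector of 7 item scores, each in 0-3.
#' @return A `scored_instrument`.
#' @export
score_gad7 <- function(items) {
  items <- .check_items(items, "GAD7")
  total <- sum(items)
  cat_ <- .band(total, c(15, 10, 5, 0),
                c("severe anxiety", "moderate anxiety", "mild anxiety",
                  "no anxiety"))
  .scored("GAD7", total, cat_)
}

#' Score the AUDIT alcohol-use questionnaire
#'
#' Sums the ten items (each 0-4). The hazardous/harmful-use flag uses the
#' sex-specific strict thresholds: total above 7 for men, above 5 for women.
#' With `sex = "unspecified"` the flag cannot be determined and is returned
#' as `NA` rather than silently `FALSE`.
#'
#' @param items Integer vector of 10 item scores, each in 0-4.
#' @param sex One of `"male"`, `"female"`, `"unspecified"`.
#' @return A `scored_instrument`; `flag` is `TRUE` for hazardous or harmful
#'   use, `NA` if sex is unspecified.
#' @export
score_audit <- function(items, sex = c("male", "female", "unspecified")) {
  items <- .check_items(items, "AUDIT")
  sex <- match.arg(sex)
  total <- sum(items)
  flag <- switch(sex,
                 male = total > 7,
                 female = total > 5,
                 unspecified = NA)
  cat_ <- if (is.na(flag)) "undetermined (sex unspecified)"
          else if (flag) "hazardous or harmful use" else "low-risk use"
  .scored("AUDIT", total, cat_, flag = flag)
}

# NODS 17-item layout: probe items map onto 10 DSM-IV criteria. Gated pairs
# (withdrawal, loss of control, lying) need both probes; alternatives
# (preoccupation, bailout, relationship problems) need any one.
.nods_criteria <- list(
  preoccupation = list(items = 1:2,   rule = "any"),
  tolerance     = list(items = 3,     rule = "any"),
  withdrawal    = list(items = 4:5,   rule = "all"),
  loss_control  = list(items = 6:7,   rule = "all"),
  escape        = list(items = 8,     rule = "any"),
  chasing       = list(items = 9,     rule = "any"),
  lying         = list(items = 10:11, rule = "all"),
  illegal_acts  = list(items = 12,    rule = "any"),
  risked_ties   = list(items = 13:15, rule = "any"),
  bailout       = list(items = 16:17, rule = "any")
)

#' Score the NODS gambling screen
#'
#' The NODS has 17 yes/no probe items that map onto the 10 DSM-IV
#' pathological-gambling criteria; each criterion contributes at most one
#' point, so the total is 0-10. Criteria probed by a gated pair (withdrawal,
#' loss of control, lying) count only when both probes are endorsed;
#' criteria with alternative probes count when any is endorsed.
#' Bands: 0 no problematic gambling, 1-2 mild subclinical risk,
#' 3-4 moderate subclinical problems, 5-10 likely pathological gambling.
#'
#' @param items Integer vector of 17 binary item responses in the standard
#'   NODS layout.
#' @return A `scored_instrument` with criterion-count total in 0-10.
#' @export
score_nods <- function(items) {
  items <- .check_items(items, "NODS")
  total <- sum(vapply(.nods_criteria, function(cr) {
    v <- items[cr$items] == 1L
    if (cr$rule == "all") all(v) else any(v)
  }, logical(1)))
  cat_ <- .band(total, c(5, 3, 1, 0),
                c("likely pathological gambling",
                  "moderate subclinical gambling problems",
                  "mild subclinical gambling risk",
                  "no problematic gambling"))
  .scored("NODS", total, cat_)
}

#' Score the PGSI problem-gambling screen
#'
#' Sums the nine items (each 0-3). The `flag` marks the problem-gambling
#' threshold total >= 8 used for trial eligibility. The attached category
#' uses the standard PGSI bands (0 non-problem, 1-2 low risk, 3-7 moderate
#' risk, 8-27 problem gambling).
#'
#' @param items Integer vector of 9 item scores, each in 0-3.
#' @return A `scored_instrument`; `flag` is `TRUE` iff total >= 8.
#' @export
score_pgsi <- function(items) {
  items <- .check_items(items, "PGSI")
  total <- sum(items)
  cat_ <- .band(total, c(8, 3, 1, 0),
                c("problem gambling", "moderate-risk gambling",
                  "low-risk gambling", "non-problem gambling"))
  .scored("PGSI", total, cat_, flag = total >= 8)
}

#' Score one instrument by name
#'
#' Dispatch helper used by the CSV interface and the pipeline.
#'
#' @param instrument One of `"NODS"`, `"PGSI"`, `"PHQ9"`, `"GAD7"`, `"AUDIT"`.
#' @param items Item vector for that instrument.
#' @param sex Sex, used by AUDIT only.
#' @return A `scored_instrument`.
#' @export
score_instrument <- function(instrument, items, sex = "unspecified") {
  switch(instrument,
         NODS = score_nods(items),
         PGSI = score_pgsi(items),
         PHQ9 = score_phq9(items),
         GAD7 = score_gad7(items),
         AUDIT = score_audit(items, sex),
         stop("unknown instrument: ", instrument, call. = FALSE))
}

#' Apply the trial eligibility rules to a gambler/CSO pair
#'
#' A pair is eligible when the gambler screens as a problem gambler
#' (PGSI total >= 8), the concerned significant other (CSO) is below the
#' problem-gambling threshold, the two have known each other for at least
#' 3 months, both are adults, and neither carries a severe-psychiatric
#' exclusion flag (screened upstream; represented here as a boolean).
#'
#' @param gambler,cso Lists with fields `pgsi_total`, `age`,
#'   `severe_psychiatric` (logical).
#' @param relationship_months Months the pair have known each other.
#' @return An `eligibility_decision`: `eligible` (logical) and `reasons`
#'   (character vector of failed-criterion codes, empty when eligible).
#' @export
check_eligibility <- function(gambler, cso, relationship_months) {
  need <- c("pgsi_total", "age", "severe_psychiatric")
  missing_fields <- c(
    paste0("gambler$", setdiff(need, names(gambler))),
    paste0("cso$", setdiff(need, names(cso)))
  )
  missing_fields <- missing_fields[!endsWith(missing_fields, "$")]
  if (missing(relationship_months) || is.null(relationship_months)) {
    missing_fields <- c(missing_fields, "relationship_months")
  }
  if (length(missing_fields)) {
    stop("missing eligibility fields: ", paste(missing_fields, collapse = ", "),
         call. = FALSE)
  }
  reasons <- character(0)
  if (gambler$pgsi_total < 8) reasons <- c(reasons, "gambler_pgsi_below_8")
  if (cso$pgsi_total >= 8) reasons <- c(reasons, "cso_pgsi_problem")
  if (relationship_months < 3) reasons <- c(reasons, "relationship_under_3_months")
  if (gambler$age < 18 || cso$age < 18) reasons <- c(reasons, "under_18")
  if (isTRUE(gambler$severe_psychiatric) || isTRUE(cso$severe_psychiatric)) {
    reasons <- c(reasons, "severe_psychiatric_flag")
  }
  structure(list(eligible = length(reasons) == 0L, reasons = reasons),
            class = "eligibility_decision")
}

#' @export
print.eligibility_decision <- function(x, ...) {
  if (x$eligible) cat("eligible\n")
  else cat("ineligible:", paste(x$reasons, collapse = ", "), "\n")
  invisible(x)
}

#' Score a long-format questionnaire table
#'
#' Reads rows shaped like the `questionnaires.csv` interface
#' (`participant_id`, `instrument`, `timepoint`, `item_1..item_17`, unused
#' trailing item columns empty) and appends `total`, `category`, `flag`.
#'
#' @param df Data frame in the long questionnaire layout. An optional `sex`
#'   column feeds the AUDIT flag.
#' @return The input with `total`, `category` and `flag` columns appended.
#' @export
score_questionnaires <- function(df) {
  item_cols <- grep("^item_", names(df), value = TRUE)
  item_cols <- item_cols[order(as.integer(sub("item_", "", item_cols)))]
  out <- df
  out$total <- NA_integer_
  out$category <- NA_character_
  out$flag <- NA
  for (i in seq_len(nrow(df))) {
    inst <- df$instrument[i]
    n <- .instrument_spec[[inst]]$n_items
    items <- as.numeric(df[i, item_cols[seq_len(n)]])
    sex <- if ("sex" %in% names(df)) df$sex[i] else "unspecified"
    s <- score_instrument(inst, items, sex)
    out$total[i] <- s$total
    out$category[i] <- s$category
    out$flag[i] <- s$flag
  }
  out
}
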