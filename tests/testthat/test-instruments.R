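# Frozen band tables (lower edge, label) for the sum-scored instruments.
.bands <- list(
  PHQ9 = list(max = 27, edges = c(0, 5, 10, 15, 20),
              labels = c("no depression", "minimal symptoms",
                         "minor depression",
                         "moderately severe major depression",
                         "severe major depression")),
  GAD7 = list(max = 21, edges = c(0, 5, 10, 15),
              labels = c("no anxiety", "mild anxiety", "moderate anxiety",
                         "severe anxiety")),
  PGSI = list(max = 27, edges = c(0, 1, 3, 8),
              labels = c("non-problem gambling", "low-risk gambling",
                         "moderate-risk gambling", "problem gambling"))
)

.expected_band <- function(total, inst) {
  b <- .bands[[inst]]
  b$labels[findInterval(total, b$edges)]
}

scorer_of <- list(PHQ9 = score_phq9, GAD7 = score_gad7, PGSI = score_pgsi)
n_items_of <- c(PHQ9 = 9, GAD7 = 7, PGSI = 9)

test_that("every total of each sum-scored instrument maps to exactly one printed band", {
  for (inst in names(.bands)) {
    for (total in 0:.bands[[inst]]$max) {
      s <- scorer_of[[inst]](items_for_total(total, n_items_of[inst], 3))
      expect_identical(s$total, as.integer(total))
      expect_identical(s$category, .expected_band(total, inst),
                       label = sprintf("%s total %d", inst, total))
    }
  }
})

test_that("PHQ-9 and GAD-7 reproduce the published severity examples", {
  expect_identical(score_phq9(rep(3, 9))$total, 27L)
  expect_identical(score_phq9(rep(3, 9))$category, "severe major depression")
  expect_identical(score_phq9(items_for_total(12, 9, 3))$category,
                   "minor depression")
  expect_identical(score_phq9(items_for_total(4, 9, 3))$category,
                   "no depression")
  expect_identical(score_gad7(rep(0, 7))$total, 0L)
  expect_identical(score_gad7(rep(0, 7))$category, "no anxiety")
  expect_identical(score_gad7(items_for_total(8, 7, 3))$category,
                   "mild anxiety")
  expect_identical(score_gad7(items_for_total(15, 7, 3))$category,
                   "severe anxiety")
})

test_that("AUDIT hazardous-use flag uses strict sex-specific thresholds", {
  expect_true(score_audit(items_for_total(8, 10, 4), "male")$flag)
  expect_false(score_audit(items_for_total(7, 10, 4), "male")$flag)
  expect_true(score_audit(items_for_total(6, 10, 4), "female")$flag)
  expect_false(score_audit(items_for_total(5, 10, 4), "female")$flag)
  # boundary sweep: flag flips exactly at the threshold
  for (t in 0:40) {
    expect_identical(score_audit(items_for_total(t, 10, 4), "male")$flag,
                     t > 7)
    expect_identical(score_audit(items_for_total(t, 10, 4), "female")$flag,
                     t > 5)
  }
  s <- score_audit(items_for_total(9, 10, 4), "unspecified")
  expect_true(is.na(s$flag))
})

test_that("NODS criterion counting respects the gated item layout", {
  expect_identical(score_nods(rep(0L, 17))$total, 0L)
  expect_identical(score_nods(rep(0L, 17))$category, "no problematic gambling")
  expect_identical(score_nods(rep(1L, 17))$total, 10L)
  # every boundary total maps to its band
  band <- c(`0` = "no problematic gambling",
            `1` = "mild subclinical gambling risk",
            `2` = "mild subclinical gambling risk",
            `3` = "moderate subclinical gambling problems",
            `4` = "moderate subclinical gambling problems",
            `5` = "likely pathological gambling",
            `10` = "likely pathological gambling")
  for (t in as.integer(names(band))) {
    s <- score_nods(nods_items_for_total(t))
    expect_identical(s$total, t)
    expect_identical(s$category, band[[as.character(t)]])
  }
  # gated pairs: a lone probe of an all-rule criterion scores nothing
  lone <- integer(17); lone[5] <- 1L   # withdrawal probe without its gate
  expect_identical(score_nods(lone)$total, 0L)
  both <- integer(17); both[4:5] <- 1L
  expect_identical(score_nods(both)$total, 1L)
  # alternative probes: either preoccupation item scores the criterion once
  either <- integer(17); either[1] <- 1L
  expect_identical(score_nods(either)$total, 1L)
  both_pre <- integer(17); both_pre[1:2] <- 1L
  expect_identical(score_nods(both_pre)$total, 1L)
})

test_that("PGSI problem-gambling flag triggers at the trial threshold of 8", {
  expect_true(score_pgsi(items_for_total(8, 9, 3))$flag)
  expect_false(score_pgsi(items_for_total(7, 9, 3))$flag)
  s <- score_pgsi(rep(3, 9))
  expect_identical(s$total, 27L)
  expect_true(s$flag)
})

test_that("item validation names the offending item and rejects bad counts", {
  expect_error(score_phq9(rep(1, 8)), "9 items")
  expect_error(score_phq9(c(rep(1, 8), 4)), "item 9")
  expect_error(score_nods(rep(1, 16)), "17 items")
  expect_error(score_audit(c(rep(1, 9), 5), "male"), "item 10")
  expect_error(score_gad7(c(1, 2, -1, 0, 0, 0, 0)), "item 3")
})

test_that("eligibility applies the recruitment rules and lists failure reasons", {
  ok_g <- list(pgsi_total = 19, age = 33, severe_psychiatric = FALSE)
  ok_c <- list(pgsi_total = 0, age = 44, severe_psychiatric = FALSE)
  d <- check_eligibility(ok_g, ok_c, 24)
  expect_true(d$eligible)
  expect_length(d$reasons, 0)

  d <- check_eligibility(modifyList(ok_g, list(pgsi_total = 7)), ok_c, 24)
  expect_false(d$eligible)
  expect_identical(d$reasons, "gambler_pgsi_below_8")

  d <- check_eligibility(ok_g, modifyList(ok_c, list(pgsi_total = 9)), 24)
  expect_false(d$eligible)
  expect_identical(d$reasons, "cso_pgsi_problem")

  d <- check_eligibility(ok_g, ok_c, 2)
  expect_identical(d$reasons, "relationship_under_3_months")
  d <- check_eligibility(modifyList(ok_g, list(age = 17)), ok_c, 24)
  expect_identical(d$reasons, "under_18")
  d <- check_eligibility(ok_g,
                         modifyList(ok_c, list(severe_psychiatric = TRUE)), 24)
  expect_identical(d$reasons, "severe_psychiatric_flag")

  expect_error(check_eligibility(list(pgsi_total = 10), ok_c, 24),
               "gambler\\$age")
})

test_that("eligibility is monotone: adding a failed criterion never helps", {
  set.seed(1)
  breakers <- list(
    function(g, c, m) list(modifyList(g, list(pgsi_total = 3)), c, m),
    function(g, c, m) list(g, modifyList(c, list(pgsi_total = 12)), m),
    function(g, c, m) list(g, c, 1),
    function(g, c, m) list(modifyList(g, list(age = 16)), c, m),
    function(g, c, m) list(g, modifyList(c, list(severe_psychiatric = TRUE)), m)
  )
  for (rep in 1:25) {
    g <- list(pgsi_total = sample(0:27, 1), age = sample(15:70, 1),
              severe_psychiatric = sample(c(TRUE, FALSE), 1))
    cso <- list(pgsi_total = sample(0:27, 1), age = sample(15:70, 1),
                severe_psychiatric = sample(c(TRUE, FALSE), 1))
    m <- sample(0:48, 1)
    before <- check_eligibility(g, cso, m)
    br <- breakers[[sample(length(breakers), 1)]](g, cso, m)
    after <- check_eligibility(br[[1]], br[[2]], br[[3]])
    if (!before$eligible) expect_false(after$eligible)
    expect_true(all(setdiff(before$reasons, after$reasons) %in%
                      c("gambler_pgsi_below_8", "cso_pgsi_problem",
                        "relationship_under_3_months", "under_18",
                        "severe_psychiatric_flag")))
  }
})

test_that("long-format questionnaire tables are scored row by row", {
  df <- rbind(
    data.frame(participant_id = "a", instrument = "PHQ9", timepoint = "pre",
               t(setNames(c(items_for_total(12, 9, 3), rep(NA, 8)),
                          paste0("item_", 1:17)))),
    data.frame(participant_id = "a", instrument = "GAD7", timepoint = "pre",
               t(setNames(c(items_for_total(15, 7, 3), rep(NA, 10)),
                          paste0("item_", 1:17))))
  )
  out <- score_questionnaires(df)
  expect_identical(out$total, c(12L, 15L))
  expect_identical(out$category, c("minor depression", "severe anxiety"))
})
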