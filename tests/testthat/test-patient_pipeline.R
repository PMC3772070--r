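make_patients <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(patient_id = r[[1]], age_at_referral = as.numeric(r[[2]]),
               referral_date = r[[3]], care_end_date = r[[4]],
               stringsAsFactors = FALSE)
  }))
}

test_that("cohort filters apply age, window and care-duration rules", {
  # hand-enumerated register: expected membership worked out per row
  pats <- make_patients(
    list("a01", 15, "2009-05-01", "2011-05-01"),  # age 15: excluded (>15 strict)
    list("a02", 16, "2009-05-01", "2011-05-01"),  # in
    list("a03", 40, "2007-12-31", "2010-01-01"),  # referral before window
    list("a04", 40, "2012-01-01", "2013-01-01"),  # referral after window
    list("a05", 40, "2008-01-01", "2008-12-01"),  # 11 months care: excluded
    list("a06", 40, "2008-01-01", "2009-01-01"),  # exactly 12 months: in
    list("a07", 40, "2008-01-15", "2009-01-14"),  # 11 months (day rule)
    list("a08", 40, "2008-01-15", "2009-01-15"),  # 12 months: in
    list("a09", 40, "2011-12-31", NA),            # open episode: in
    list("a10", 80, "2010-06-01", "2010-07-01"))  # 1 month: excluded
  spec <- cohort_spec()
  coh <- build_cohort(pats, spec)
  expect_setequal(coh$patient_id, c("a02", "a06", "a08", "a09"))

  # threshold boundary: 11-month patient included when duration rule off
  no_dur <- cohort_spec(min_care_months = NULL)
  expect_true("a05" %in% build_cohort(pats, no_dur)$patient_id)
  expect_false("a01" %in% build_cohort(pats, no_dur)$patient_id)

  # idempotence
  expect_identical(build_cohort(coh, spec)$patient_id, coh$patient_id)

  # malformed dates: row dropped with a diagnostic, not a crash
  bad <- make_patients(list("b1", 30, "not-a-date", "2011-01-01"),
                       list("b2", 30, "2009-01-01", "2011-01-01"))
  expect_warning(res <- build_cohort(bad, spec), "malformed")
  expect_identical(res$patient_id, "b2")
})

test_that("patient status resolves to the first record after referral", {
  pat <- data.frame(patient_id = "p1", referral_date = as.Date("2009-01-01"))
  day <- function(d) as.Date("2009-01-01") + d
  txt <- data.frame(patient_id = "p1", date = day(3), status = "never")
  str <- data.frame(patient_id = "p1", date = day(10), status = "current")

  r <- resolve_patient_status(txt, str, pat)
  expect_identical(r$status, "never")
  expect_identical(r$source, "text")

  # only records dated before referral -> no resolved status
  early <- data.frame(patient_id = "p1", date = day(-5), status = "current")
  expect_identical(nrow(resolve_patient_status(early, NULL, pat)), 0L)

  # same-date conflict: structured wins by default, text when configured
  fx <- make_fixture_suite()$same_date_conflict
  r2 <- resolve_patient_status(fx$text_records, fx$structured, fx$patient)
  expect_identical(r2$status, fx$expected$status)
  expect_identical(r2$source, fx$expected$source)
  r3 <- resolve_patient_status(fx$text_records, fx$structured, fx$patient,
                               tie_break = "text")
  expect_identical(r3$source, "text")

  # same-date conflict within text: current > past > never
  txt2 <- data.frame(patient_id = "p1", date = day(2),
                     status = c("never", "current", "past"))
  expect_identical(resolve_patient_status(txt2, NULL, pat)$status, "current")
})

test_that("resolution is order-invariant with one status per patient", {
  reg <- default_register()
  ann <- annotations_with_dates(default_annotations(), reg$corpus)
  r1 <- resolve_patient_status(ann, reg$structured, reg$patients)
  expect_lte(nrow(r1), nrow(reg$patients))
  expect_identical(anyDuplicated(r1$patient_id), 0L)

  set.seed(2)
  shuf <- function(df) df[sample(nrow(df)), , drop = FALSE]
  r2 <- resolve_patient_status(shuf(ann), shuf(reg$structured),
                               shuf(reg$patients))
  r2 <- r2[order(r2$patient_id), ]
  rownames(r2) <- NULL
  expect_identical(r1[order(r1$patient_id), ]$status, r2$status)
  expect_identical(r1[order(r1$patient_id), ]$date, r2$date)
})

test_that("coverage by source counts structured-only vs combined regimes", {
  reg <- default_register()
  ann <- annotations_with_dates(default_annotations(), reg$corpus)
  cov <- coverage_by_source(reg$patients, ann, reg$structured)
  expect_identical(cov$source, c("structured_only", "structured_plus_text"))
  expect_lte(cov$n_with_status[1], cov$n_with_status[2])
  expect_equal(cov$percent,
               round(100 * cov$n_with_status / nrow(reg$patients), 1))

  # every patient structured -> 100% in both rows
  pats <- data.frame(patient_id = c("x1", "x2"), age_at_referral = 30,
                     referral_date = as.Date("2009-01-01"),
                     care_end_date = as.Date("2011-01-01"))
  str <- data.frame(patient_id = c("x1", "x2"),
                    date = as.Date("2009-02-01"), status = "current")
  cov2 <- coverage_by_source(pats, NULL, str)
  expect_equal(cov2$percent, c(100, 100))

  expect_error(coverage_by_source(pats[0, ], NULL, str), "empty cohort")
})

test_that("coverage by year tabulates trends across referral years", {
  # constant coverage: 3 years x 40 patients, 16 covered each -> trend p = 1
  pats <- data.frame(
    patient_id = sprintf("y%03d", 1:120), age_at_referral = 30,
    referral_date = as.Date(rep(c("2008-06-01", "2009-06-01", "2010-06-01"),
                                each = 40)),
    care_end_date = as.Date("2012-01-01"))
  covered <- pats$patient_id[as.vector(outer(1:16, c(0, 40, 80), "+"))]
  str <- data.frame(patient_id = covered,
                    date = as.Date("2011-01-01"), status = "never")
  cy <- coverage_by_year(pats, NULL, str)
  expect_equal(cy$table$pct_structured, rep(40, 3))
  expect_equal(unname(cy$trend["structured"]), 1)

  # rising coverage 0.4/0.5/0.6 at n=200/year: significant positive trend,
  # p equal to the independent trend-test oracle
  n <- 200
  pats2 <- data.frame(
    patient_id = sprintf("z%03d", 1:(3 * n)), age_at_referral = 30,
    referral_date = as.Date(rep(c("2008-06-01", "2009-06-01", "2010-06-01"),
                                each = n)),
    care_end_date = as.Date("2012-01-01"))
  k <- c(80, 100, 120)
  covered2 <- pats2$patient_id[as.vector(unlist(
    Map(function(kk, off) off + seq_len(kk), k, c(0, n, 2 * n))))]
  str2 <- data.frame(patient_id = covered2,
                     date = as.Date("2011-01-01"), status = "current")
  cy2 <- coverage_by_year(pats2, NULL, str2)
  # the oracle's internal anova warns on this exactly-linear fixture
  oracle <- suppressWarnings(stats::prop.trend.test(k, rep(n, 3), 0:2))
  expect_equal(unname(cy2$trend["structured"]), oracle$p.value,
               tolerance = 1e-10)
  expect_lt(cy2$trend[["structured"]], 0.01)

  # a requested year with no patients is omitted with a warning
  expect_warning(cy3 <- coverage_by_year(pats, NULL, str, years = 2008:2011),
                 "2011")
  expect_identical(cy3$table$year, 2008:2010)
})

test_that("with missingness off the pipeline recovers ground truth exactly", {
  cfg <- simulation_config(
    n_patients = 60, seed = 99,
    missing_coefs = c(intercept = -30, female = 0, age_35_64 = 0,
                      age_65plus = 0, dep_least = 0, dep_middle = 0,
                      bipolar = 0),
    mention_prob = 1, out_of_lexicon_prob = 0, bare_mention_prob = 0,
    distractor_prob = 0.3)
  reg <- generate_register(cfg)
  expect_true(all(reg$patients$ascertainable))
  ann <- annotations_with_dates(annotate_corpus(reg$corpus), reg$corpus)
  res <- resolve_patient_status(ann, reg$structured, reg$patients)
  expect_identical(nrow(res), nrow(reg$patients))  # 100% coverage
  m <- merge(res, reg$patients[, c("patient_id", "true_status")])
  expect_identical(m$status, m$true_status)
})
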