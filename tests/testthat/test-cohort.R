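test_that("write_cohort / read_cohort round-trips field for field", {
  co <- make_cohort(list(
    make_record("a", mln_count = 12, lns_examined = 30),
    make_record("b", sex = "female", tumor_size_mm = NA_real_,
                followup_months = 3.5, event = 0),
    make_record("c", mln_count = 40, lns_examined = 41,
                ethnicity = "asian")))
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, f)
  back <- read_cohort(f)
  expect_s3_class(back, "cohort")
  expect_equal(nrow(back), 3L)
  expect_equal(as.data.frame(back), as.data.frame(co), ignore_attr = TRUE)
  expect_equal(back$mln_count[1], 12)
  expect_equal(back$lns_examined[1], 30)
  expect_true(is.na(back$tumor_size_mm[2]))
})

test_that("read_cohort rejects broken files with informative errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  co <- make_cohort(list(make_record("a")))
  write_cohort(co, f)
  # drop the mln_count column
  tab <- read.csv(f)
  tab$mln_count <- NULL
  write.csv(tab, f, row.names = FALSE, na = "")
  expect_error(read_cohort(f), "mln_count")

  write_cohort(co, f)
  lines <- readLines(f)
  lines[2] <- sub("30,12", "30,twelve", lines[2])
  writeLines(lines, f)
  expect_error(read_cohort(f), "mln_count.*row 1")
})

test_that("cohort container enforces its structural invariants", {
  expect_error(make_cohort(list(make_record("a"), make_record("a"))),
               "unique")
  expect_error(make_cohort(list(make_record("a", mln_count = 31,
                                            lns_examined = 30))),
               "exceeds")
  expect_error(make_cohort(list(make_record("a", event = 2))), "event")
  expect_error(make_cohort(list(make_record("a", sex = "unknown"))), "sex")
})

test_that("screening excludes by first failing criterion and reconciles", {
  # 10 records: 6 eligible, 4 failing one distinct criterion each
  co <- make_cohort(c(
    lapply(1:6, function(i) make_record(paste0("ok", i))),
    list(make_record("x1", lns_examined = 15, mln_count = 10),
         make_record("x2", followup_months = 0.5),
         make_record("x3", age_years = 16),
         make_record("x4", m_category = "M1"))))
  res <- screen_cohort(co)
  expect_equal(res$report$n_input, 10L)
  expect_equal(res$report$n_eligible, 6L)
  excl <- res$report$exclusions
  expect_equal(unname(excl[["lns_examined_le_15"]]), 1L)
  expect_equal(unname(excl[["survival_lt_1_month"]]), 1L)
  expect_equal(unname(excl[["age_under_18"]]), 1L)
  expect_equal(unname(excl[["not_m0"]]), 1L)
  expect_equal(res$report$n_input,
               res$report$n_eligible + sum(excl))
  expect_setequal(res$cohort$id, paste0("ok", 1:6))
})

test_that("boundary cases: exactly 15 nodes examined and 1-month survival", {
  co <- make_cohort(list(
    make_record("b15", lns_examined = 15, mln_count = 10),
    make_record("b16", lns_examined = 16, mln_count = 10),
    make_record("fu1", followup_months = 1),
    make_record("fu05", followup_months = 0.5)))
  res <- screen_cohort(co)
  expect_setequal(res$cohort$id, c("b16", "fu1"))
  expect_equal(unname(res$report$exclusions[["lns_examined_le_15"]]), 1L)
  expect_equal(unname(res$report$exclusions[["survival_lt_1_month"]]), 1L)
})

test_that("a record failing several criteria is charged to the first", {
  co <- make_cohort(list(
    make_record("multi", primary_site_stomach = 0, age_years = 15,
                followup_months = 0.2)))
  res <- screen_cohort(co)
  expect_equal(unname(res$report$exclusions[["non_gastric_primary"]]), 1L)
  expect_equal(sum(res$report$exclusions), 1L)
})

test_that("missing required fields are excluded as incomplete records", {
  co <- make_cohort(list(make_record("m", tumor_size_mm = NA_real_),
                         make_record("ok")))
  res <- screen_cohort(co)
  expect_equal(unname(res$report$exclusions[["incomplete_record"]]), 1L)
  expect_equal(res$cohort$id, "ok")
})

test_that("summary reproduces the two-source male percentage arithmetic", {
  # registry-style counts: 1024 of 1833 male in one source, 674 of 920 in
  # the other -> overall 1698/2753 = 61.7%
  recs <- c(
    lapply(seq_len(1833), function(i)
      make_record(paste0("s", i), source = "SEER",
                  sex = if (i <= 1024) "male" else "female")),
    lapply(seq_len(920), function(i)
      make_record(paste0("f", i), source = "FMUUH",
                  sex = if (i <= 674) "male" else "female")))
  co <- make_cohort(recs)
  s <- summarize_cohort(co, by_source = TRUE)
  male <- s$categorical[s$categorical$variable == "sex" &
                          s$categorical$level == "male", ]
  expect_equal(male$n_overall, 1698L)
  expect_equal(male$pct_overall, 61.7)
  expect_equal(male$pct_SEER, 55.9)
  expect_equal(male$pct_FMUUH, 73.3)
  expect_lt(male$p_value, 0.001)
})

test_that("degenerate summaries behave per contract", {
  one <- make_cohort(list(make_record("solo")))
  s <- summarize_cohort(one, by_source = FALSE)
  expect_true(all(s$categorical$pct_overall == 100.0))
  expect_error(summarize_cohort(one[0, ], by_source = FALSE))

  # identical proportions in both sources -> chi2 p = 1 (statistic 0)
  recs <- c(
    lapply(1:20, function(i) make_record(paste0("a", i), source = "SEER",
                                         sex = if (i <= 10) "male" else "female")),
    lapply(1:20, function(i) make_record(paste0("b", i), source = "FMUUH",
                                         sex = if (i <= 10) "male" else "female")))
  s2 <- summarize_cohort(make_cohort(recs), by_source = TRUE)
  male <- s2$categorical[s2$categorical$variable == "sex" &
                           s2$categorical$level == "male", ]
  expect_equal(male$p_value, 1)
})

test_that("percentages within each variable sum to 100 within rounding", {
  co <- generate_cohort(default_paperlike_config(n = 400, seed = 11))
  s <- summarize_cohort(co, by_source = FALSE)
  for (v in unique(s$categorical$variable)) {
    tot <- sum(s$categorical$pct_overall[s$categorical$variable == v])
    expect_lt(abs(tot - 100), 0.1 * sum(s$categorical$variable == v))
  }
})
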