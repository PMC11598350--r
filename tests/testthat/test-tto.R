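test_that("age-unit conversion matches the FAERS code table and flags implausibles", {
  expect_equal(normalize_age(65, "YR"), 65)
  expect_equal(normalize_age(6.5, "DEC"), 65)
  expect_equal(normalize_age(780, "MON"), 65)
  expect_equal(normalize_age(52.1786, "WK"), 1)
  expect_equal(normalize_age(365.25, "DY"), 1)
  expect_equal(normalize_age(8766, "HR"), 1)
  expect_true(is.na(normalize_age(130, "YR")))     # implausible
  expect_true(is.na(normalize_age(-1, "YR")))
  expect_true(is.na(normalize_age(60, "XX")))      # unknown code
  expect_true(is.na(normalize_age(NA, "YR")))
})

onset_cohort <- function() {
  th <- data.table::data.table(
    caseid = c("c1", "c2", "c3", "c3", "c4", "c5"),
    drug_seq = c(1L, 1L, 1L, 2L, 1L, 1L),
    start_dt = c(20200101L, 20210601L, 20190101L, 20210101L, NA, 202001L),
    end_dt = NA_integer_)
  coh <- toy_cohort(5,
                    exposed = list(methotrexate = 1:5),
                    reactions = list(`Skin cancer` = 1:5),
                    event_dt = c(20200701L, 20210101L, 20210601L, 20200701L,
                                 20200701L),
                    therapies = th)
  # case 3 has two therapy episodes for the same PS drug
  coh$exposures <- rbind(coh$exposures,
                         data.table::data.table(caseid = "c3", drug_seq = 2L,
                                                ingredient = "methotrexate",
                                                class = "csDMARD"))
  coh
}

test_that("onset uses the earliest start, excludes negatives and partial/missing dates", {
  r <- compute_onset(onset_cohort())
  r <- r[match(paste0("c", 1:5), r$caseid), ]
  expect_equal(r$onset_years[1], 182 / 365.25, tolerance = 1e-12)
  expect_equal(r$status[2], "negative")            # event before start
  expect_equal(r$onset_years[3],
               as.numeric(as.Date("2021-06-01") - as.Date("2019-01-01")) / 365.25,
               tolerance = 1e-12)                  # earliest-start rule
  expect_equal(r$status[4], "missing_date")
  expect_equal(r$status[5], "partial_date")
  # conservation: every exposed case accounted for
  expect_equal(nrow(r), 5L)
  expect_equal(sum(r$status == "ok") + sum(r$status != "ok"), 5L)
})

test_that("partial-date midpoint imputation is available but off by default", {
  r <- compute_onset(onset_cohort(), impute_partial = TRUE)
  r5 <- r[r$caseid == "c5", ]
  expect_equal(r5$status, "ok")
  expect_equal(r5$onset_years,
               as.numeric(as.Date("2020-07-01") - as.Date("2020-01-15")) / 365.25)
})

test_that("onset summaries use interpolated quartiles and flag small groups", {
  rec <- data.frame(caseid = as.character(1:8),
                    drug = c(rep("a", 3), rep("b", 4), "c"),
                    onset_years = c(0.5, 1, 2, 1, 2, 3, 4, 3),
                    status = "ok")
  s <- summarize_onset(rec, min_n = 3)
  expect_equal(s$median[s$drug == "a"], 1)
  expect_equal(s$median[s$drug == "b"], 2.5)       # even-n interpolation
  expect_equal(s$median[s$drug == "c"], 3)         # single value, degenerate IQR
  expect_equal(s$q1[s$drug == "c"], 3)
  expect_true(s$below_min_n[s$drug == "c"])

  set.seed(4)
  x <- rlnorm(101, 0, 1)
  s1 <- summarize_onset(data.frame(caseid = as.character(1:101), drug = "z",
                                   onset_years = x, status = "ok"))
  expect_equal(s1$median, oracle_quantile(x, 0.5))
  expect_equal(s1$q1, oracle_quantile(x, 0.25))
  expect_equal(s1$q3, oracle_quantile(x, 0.75))
})

test_that("percentage shares round half-up to two decimals", {
  expect_equal(percent_share(3447, 17412), 19.80)
  expect_equal(percent_share(10274, 17412), 59.01)
  expect_equal(percent_share(0, 17412), 0.00)
  expect_equal(percent_share(1, 800), 0.13)        # 0.125 rounds up, not to even
  expect_error(percent_share(1, 0), "positive")
  expect_error(percent_share(5, 4), "count")
})

test_that("descriptive shares over the exposed partition sum to 100 within rounding", {
  set.seed(3)
  n <- 500
  drugs <- c("methotrexate", "adalimumab", "tofacitinib", "abatacept")
  assign <- split(1:n, sample(drugs, n, replace = TRUE))
  coh <- toy_cohort(n, exposed = assign,
                    reactions = list(Rash = 1:n),
                    sex = sample(c("F", "M", "UNK"), n, replace = TRUE),
                    age_years = rnorm(n, 62, 10),
                    outcomes = data.frame(caseid = paste0("c", 1:n),
                                          outc_cod = sample(c("HO", "OT", "DE"),
                                                            n, replace = TRUE)))
  d <- summarize_descriptives(coh)
  expect_equal(d$n_reports, n)
  expect_lt(abs(sum(d$by_drug$share) - 100), 0.05)
  expect_lt(abs(sum(d$by_class$share) - 100), 0.05)
  expect_equal(sum(d$outcomes$n), n)
  expect_equal(sum(d$sex), n)
})

test_that("outcome tabulation counts entries, not cases", {
  coh <- toy_cohort(3, exposed = list(methotrexate = 1:3),
                    reactions = list(Rash = 1:3),
                    outcomes = data.frame(caseid = c("c1", "c1", "c2"),
                                          outc_cod = c("HO", "DE", "HO")))
  d <- summarize_descriptives(coh)
  expect_equal(d$outcomes$n[d$outcomes$code == "HO"], 2L)
  expect_equal(d$outcomes$n[d$outcomes$code == "DE"], 1L)
  expect_equal(d$outcomes$pct_of_entries[d$outcomes$code == "HO"],
               percent_share(2, 3))
  expect_equal(d$outcomes$pct_of_reports[d$outcomes$code == "HO"],
               percent_share(2, 3))
})
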