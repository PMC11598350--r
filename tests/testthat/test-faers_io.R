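test_that("quarter reader parses rows, flags bad dates, rejects missing columns", {
  demo <- data.frame(primaryid = c("11", "21", "31"), caseid = c("1", "2", "3"),
                     fda_dt = c("20200101", "", "20200301"),
                     sex = c("F", "M", ""), age = c("65", "", "70"),
                     age_cod = c("YR", "", "YR"))
  drug <- data.frame(primaryid = "11", caseid = "1", drug_seq = "1",
                     role_cod = "PS", drugname = "HUMIRA")
  reac <- data.frame(primaryid = "11", caseid = "1", pt = "Skin cancer")
  paths <- write_quarter(demo = demo, drug = drug, reac = reac)

  q <- read_faers_quarter(paths, quarter = "2020Q1")
  expect_equal(nrow(q$demo), 3L)
  expect_equal(sum(is.na(q$demo$fda_dt)), 1L)
  expect_equal(q$log$n_skipped, c(0L, 0L, 0L))

  # empty body with a valid header
  paths2 <- paths
  writeLines("primaryid$caseid$fda_dt", file.path(dirname(paths$demo), "empty.txt"))
  paths2$demo <- file.path(dirname(paths$demo), "empty.txt")
  q2 <- read_faers_quarter(paths2)
  expect_equal(nrow(q2$demo), 0L)

  # a missing mandatory column is a hard error naming it
  bad <- data.frame(primaryid = "11", fda_dt = "20200101")
  pbad <- write_quarter(demo = bad, drug = drug, reac = reac)
  expect_error(read_faers_quarter(pbad), "CASEID")
})

test_that("date parser accepts only valid calendar dates at full precision", {
  expect_equal(parse_faers_date(c("20200229", "20210229", "2020", "202013", "x")),
               c(20200229L, NA, NA, NA, NA))
  expect_equal(parse_faers_date(c("2020", "202006"), precision = "any"),
               c(2020L, 202006L))
  expect_true(is.na(parse_faers_date("202013", precision = "any")))
})

test_that("deduplication keeps latest FDA_DT, breaks ties by higher PRIMARYID, honours deletions", {
  demo <- data.frame(
    caseid = c("123", "123", "9", "9", "7"),
    primaryid = c("1234567", "2234567", "91", "92", "71"),
    fda_dt = c(20220101L, 20230301L, 20210601L, 20210601L, 20200101L))
  dd <- deduplicate_reports(demo, deleted_caseids = "7")
  surv <- setNames(dd$survivors$primaryid, dd$survivors$caseid)
  expect_equal(unname(surv["123"]), "2234567")
  expect_equal(unname(surv["9"]), "92")
  expect_false("7" %in% names(surv))
  expect_equal(dd$n_versions, 5L)
  expect_equal(dd$n_deleted, 1L)
  expect_equal(dd$n_versions, dd$n_survivors + dd$n_superseded + dd$n_deleted)
})

test_that("deduplication is idempotent and order independent; missing FDA_DT sorts lowest", {
  set.seed(31)
  demo <- data.frame(
    caseid = as.character(rep(1:40, times = sample(1:4, 40, replace = TRUE))))
  demo$primaryid <- as.character(seq_len(nrow(demo)) + 1000L)
  demo$fda_dt <- sample(c(NA, 20200101L, 20210101L, 20220101L),
                        nrow(demo), replace = TRUE)
  d1 <- deduplicate_reports(demo)
  # idempotence: running on the survivor set changes nothing
  d2 <- deduplicate_reports(d1$survivors)
  expect_equal(data.frame(d2$survivors[order(caseid)]),
               data.frame(d1$survivors[order(caseid)]))
  # order independence
  perm <- demo[sample(nrow(demo)), ]
  d3 <- deduplicate_reports(perm)
  expect_equal(data.frame(d3$survivors[order(caseid)]),
               data.frame(d1$survivors[order(caseid)]))
  # a dated version always beats an undated one
  demo2 <- data.frame(caseid = c("x", "x"), primaryid = c("99", "1"),
                      fda_dt = c(NA, 20190101L))
  expect_equal(deduplicate_reports(demo2)$survivors$primaryid, "1")
})

test_that("case assembly joins surviving versions, drops superseded children, dedups PTs", {
  demo <- data.frame(primaryid = c("11", "12"), caseid = c("1", "1"),
                     fda_dt = c("20200101", "20210101"),
                     sex = "F", age = "60", age_cod = "YR")
  drug <- data.frame(primaryid = c("12", "12", "11"), caseid = "1",
                     drug_seq = c("1", "2", "1"),
                     role_cod = c("PS", "C", "PS"),
                     drugname = c("HUMIRA", "METHOTREXATE", "OLD DRUG ROW"))
  reac <- data.frame(primaryid = c("12", "12", "12", "11"), caseid = "1",
                     pt = c("Skin cancer", "Nausea", "Skin cancer", "Old PT"))
  paths <- write_quarter(demo = demo, drug = drug, reac = reac)
  cs <- assemble_cases(read_faers_quarter(paths))
  expect_equal(nrow(cs$cases), 1L)
  expect_equal(cs$cases$primaryid, "12")
  expect_equal(nrow(cs$drugs), 2L)                       # superseded row gone
  expect_setequal(cs$reactions$pt, c("Skin cancer", "Nausea"))
  expect_equal(nrow(cs$reactions), 2L)                   # repeated PT collapsed
  expect_true(cs$cases$analyzable)
})

test_that("a case with no reactions is kept but flagged non-analyzable", {
  demo <- data.frame(primaryid = c("11", "21"), caseid = c("1", "2"),
                     fda_dt = "20200101", sex = "F", age = "60", age_cod = "YR")
  drug <- data.frame(primaryid = c("11", "21"), caseid = c("1", "2"),
                     drug_seq = "1", role_cod = "PS", drugname = "ENBREL")
  reac <- data.frame(primaryid = "11", caseid = "1", pt = "Rash")
  cs <- assemble_cases(read_faers_quarter(write_quarter(demo = demo, drug = drug,
                                                        reac = reac)))
  expect_equal(nrow(cs$cases), 2L)
  expect_equal(sort(cs$cases$analyzable), c(FALSE, TRUE))
})
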