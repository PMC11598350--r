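test_that("generator output is byte-identical under the same seed", {
  cfg <- synth_config(seed = 12, n_cases = 800)
  g1 <- generate_faers(cfg, tempfile("s1"))
  g2 <- generate_faers(cfg, tempfile("s2"))
  for (nm in names(g1$paths)) {
    expect_identical(unname(tools::md5sum(g1$paths[[nm]])),
                     unname(tools::md5sum(g2$paths[[nm]])), label = nm)
  }
  g3 <- generate_faers(synth_config(seed = 13, n_cases = 800), tempfile("s3"))
  expect_false(identical(unname(tools::md5sum(g1$paths$demo)),
                         unname(tools::md5sum(g3$paths$demo))))
})

test_that("invalid configurations fail before any file is written", {
  expect_error(synth_config(duplicate_rate = 1.5), "probabilities")
  expect_error(synth_config(associations = data.frame(drug = "methotrexate",
                                                      event = "Skin cancer",
                                                      rr = -1)), "rates")
  expect_error(synth_config(associations = data.frame(drug = "notadrug",
                                                      event = "Skin cancer",
                                                      rr = 2)), "absent")
})

test_that("duplicate_rate zero yields unique caseids; positive rate yields clusters", {
  g0 <- generate_faers(synth_config(seed = 4, n_cases = 600,
                                    duplicate_rate = 0), tempfile())
  demo0 <- data.table::fread(g0$paths$demo, sep = "$", colClasses = "character")
  expect_equal(anyDuplicated(demo0$caseid), 0L)

  g1 <- generate_faers(synth_config(seed = 4, n_cases = 600,
                                    duplicate_rate = 0.5), tempfile())
  demo1 <- data.table::fread(g1$paths$demo, sep = "$", colClasses = "character")
  expect_gt(sum(duplicated(demo1$caseid)), 0L)
})

test_that("empirical marginals track the configured probabilities", {
  n <- 40000
  cfg <- synth_config(seed = 8, n_cases = n, duplicate_rate = 0,
                      deleted_rate = 0)
  gen <- generate_faers(cfg, tempfile())
  tr <- gen$truth$cases
  for (ing in c("methotrexate", "adalimumab", "tofacitinib")) {
    p <- cfg$drugs$p_ps[cfg$drugs$ingredient == ing]
    phat <- mean(tr$ps_ingredient == ing)
    expect_lt(abs(phat - p), 3 * sqrt(p * (1 - p) / n))
  }
  expect_lt(abs(mean(tr$ra) - cfg$ra_fraction),
            3 * sqrt(cfg$ra_fraction * (1 - cfg$ra_fraction) / n))
  # zero-probability drugs never appear
  expect_false(any(tr$ps_ingredient %in% c("iguratimod", "filgotinib",
                                           "peficitinib")))
})

test_that("with all relative rates at 1 the screen sees odds ratios near 1", {
  cfg <- synth_config(seed = 15, n_cases = 60000,
                      associations = data.frame(drug = character(),
                                                event = character(),
                                                rr = numeric()),
                      duplicate_rate = 0, deleted_rate = 0)
  gen <- generate_faers(cfg, tempfile())
  q <- read_faers_quarter(gen$paths)
  coh <- build_cohort(assemble_cases(q))
  scr <- screen_signals(coh, events = cfg$events$pt[cfg$events$malignancy])
  # condition on the (association-free) margins, not on the observed cell a,
  # which would select upward-fluctuating pairs
  expected <- (scr$a + scr$b) * (scr$a + scr$c) / (scr$a + scr$b + scr$c + scr$d)
  lr <- log(scr$ror[!is.na(scr$ror) & expected >= 10])
  expect_gt(length(lr), 100)
  expect_lt(abs(mean(lr)), 0.1)
  expect_lt(mean(scr$signal), 0.02)
})

test_that("the estimated ROR approaches the injected RR as n grows", {
  assoc <- data.frame(drug = "methotrexate",
                      event = "Lymphoproliferative disorder", rr = 5)
  est <- vapply(c(small = 5000, large = 80000), function(n) {
    cfg <- synth_config(seed = 33, n_cases = n, associations = assoc,
                        duplicate_rate = 0, deleted_rate = 0)
    gen <- generate_faers(cfg, tempfile())
    coh <- build_cohort(assemble_cases(read_faers_quarter(gen$paths)))
    scr <- screen_signals(coh, drugs = "methotrexate",
                          events = "Lymphoproliferative disorder")
    scr$ror[1]
  }, 0)
  expect_lt(abs(log(est["large"] / 5)), 0.15)
  expect_lt(abs(log(est["large"] / 5)), abs(log(est["small"] / 5)) + 0.15)
})

test_that("roundtrip recovery finds injected pairs without false alarms", {
  rt <- roundtrip_check(synth_config(seed = 5, n_cases = 20000))
  expect_equal(rt$sensitivity, 1)
  expect_gte(rt$n_null_pairs, 300)
  expect_lte(rt$false_signal_rate, 0.02)
  expect_true(rt$dedup_recovered)
  expect_lt(abs(rt$ror_log_bias), 0.5)
})

test_that("the confounded simulator induces crude bias with the stated conditional OR", {
  ds <- simulate_confounded(n = 30000, true_or = 2.0, seed = 3)
  fit <- fit_adjusted(ds)
  expect_lt(abs(fit$adjusted_ror / 2.0 - 1), 0.10)
})
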