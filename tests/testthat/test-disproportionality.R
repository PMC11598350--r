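# 10 cases: 3 exposed to drug X (2 with event e), 4 unexposed with e
ten_case_cohort <- function() {
  toy_cohort(10,
             exposed = list(methotrexate = 1:3),
             reactions = list(`Skin cancer` = c(1, 2, 4, 5, 6, 7),
                              Rash = c(3, 8, 9, 10)))
}

test_that("2x2 cells enumerate the toy cohort correctly and sum to N", {
  t <- build_table(ten_case_cohort(), "methotrexate", "Skin cancer")
  expect_equal(c(t$a, t$b, t$c, t$d), c(2L, 1L, 4L, 3L))
  expect_equal(t$a + t$b + t$c + t$d, 10L)

  # absent event
  t0 <- build_table(ten_case_cohort(), "methotrexate", "No such PT")
  expect_equal(c(t0$a, t0$c), c(0L, 0L))

  # everyone exposed and affected
  coh <- toy_cohort(4, exposed = list(methotrexate = 1:4),
                    reactions = list(`Skin cancer` = 1:4))
  t1 <- build_table(coh, "methotrexate", "Skin cancer")
  expect_equal(c(t1$a, t1$b, t1$c, t1$d), c(4L, 0L, 0L, 0L))
})

test_that("a case with a repeated PT counts once at report level", {
  coh <- toy_cohort(5, exposed = list(methotrexate = 1:2),
                    reactions = list(`Skin cancer` = c(1, 3)))
  coh$reactions <- rbind(coh$reactions, coh$reactions[1, ])  # duplicate PT row
  t <- build_table(coh, "methotrexate", "Skin cancer")
  expect_equal(t$a, 1L)
})

test_that("ROR point estimate and Wald bounds match hand-derived values", {
  r <- compute_ror(5, 10, 20, 100)
  expect_equal(r$ror, 2.5)
  # se = sqrt(1/5+1/10+1/20+1/100) = sqrt(0.36) = 0.6
  expect_equal(r$ror025, exp(log(2.5) - 1.96 * 0.6), tolerance = 1e-12)
  expect_equal(r$ror025, 0.771, tolerance = 1e-3)
  expect_equal(r$ror975, 8.103, tolerance = 1e-3)

  expect_equal(compute_ror(25, 25, 25, 25)$ror, 1.0)

  z <- compute_ror(0, 10, 20, 100)
  expect_true(is.na(z$ror) && is.na(z$ror025))
  expect_false(classify_signal(0, z$ror025, 1))
})

test_that("IC and IC025 match hand-derived shrinkage values", {
  # a=5, a+b=100, a+c=50, N=10000 -> E=0.5
  r <- compute_ic(5, 95, 45, 9855)
  expect_equal(r$ic, log2(5.5 / 1.0), tolerance = 1e-12)
  expect_equal(r$ic, 2.4594, tolerance = 1e-4)
  expect_equal(r$ic025, 2.4594 - 3.3 / sqrt(5.5) - 2 * 5.5^-1.5,
               tolerance = 1e-4)
  expect_equal(r$ic025, 0.8972, tolerance = 1e-4)

  # a equal to its expectation gives IC = 0
  r0 <- compute_ic(5, 45, 95, 855)   # E = 50*100/1000 = 5
  expect_equal(r0$ic, 0)

  # empty top-left cell: shrinkage keeps everything defined, IC025 < 0
  re <- compute_ic(0, 0, 0, 100)
  expect_equal(re$ic, 0)
  expect_equal(re$ic025, -3.3 / sqrt(0.5) - 2 / 0.5^1.5)
  expect_lt(re$ic025, 0)
})

test_that("ROR and IC agree with an independent brute-force oracle on 1000 random tables", {
  set.seed(99)
  a <- sample(1:500, 1000, replace = TRUE)
  b <- sample(1:500, 1000, replace = TRUE)
  c_ <- sample(1:500, 1000, replace = TRUE)
  d <- sample(1:500, 1000, replace = TRUE)
  r <- compute_ror(a, b, c_, d)
  ic <- compute_ic(a, b, c_, d)
  o_r <- oracle_ror(a, b, c_, d)
  o_i <- oracle_ic(a, b, c_, d)
  expect_lt(max(abs(r$ror / o_r$ror - 1)), 1e-10)
  expect_lt(max(abs(r$ror025 / o_r$lo - 1)), 1e-10)
  expect_lt(max(abs(r$ror975 / o_r$hi - 1)), 1e-10)
  expect_lt(max(abs(ic$ic - o_i$ic)), 1e-10)
  expect_lt(max(abs(ic$ic025 - o_i$ic025)), 1e-10)
  # the credibility correction is strictly positive
  expect_true(all(ic$ic025 < ic$ic))
})

test_that("IC rises with a at fixed margins; ROR rises with a at fixed b,c,d", {
  # margins a+b = 60, a+c = 80, N = 1000 fixed -> E constant
  a <- 1:50
  ic <- compute_ic(a, 60 - a, 80 - a, 1000 - 60 - 80 + a)$ic
  expect_true(all(diff(ic) > 0))
  ror <- compute_ror(a, 30, 40, 500)$ror
  expect_true(all(diff(ror) > 0))
})

test_that("ROR is scale invariant, IC is not (shrinkage)", {
  base <- c(a = 12, b = 40, c = 25, d = 300)
  r1 <- compute_ror(base["a"], base["b"], base["c"], base["d"])
  r7 <- compute_ror(7 * base["a"], 7 * base["b"], 7 * base["c"], 7 * base["d"])
  expect_equal(r1$ror, r7$ror, tolerance = 1e-12)
  i1 <- compute_ic(base["a"], base["b"], base["c"], base["d"])
  i7 <- compute_ic(7 * base["a"], 7 * base["b"], 7 * base["c"], 7 * base["d"])
  expect_false(isTRUE(all.equal(i1$ic, i7$ic)))
})

test_that("the three-condition signal rule uses strict thresholds", {
  expect_true(classify_signal(3, 1.01, 0.01))
  expect_false(classify_signal(2, 5.0, 2.0))       # too few reports
  expect_false(classify_signal(100, 0.99, 0.5))    # ROR bound not above 1
  expect_false(classify_signal(10, 1.5, NA))
})

test_that("screening returns deterministic sorted output and flags the injected pair", {
  coh <- toy_cohort(60,
                    exposed = list(methotrexate = 1:15, adalimumab = 16:30),
                    reactions = list(`Skin cancer` = c(1:9, 31:33),
                                     Rash = c(10:15, 16:30, 34:60)))
  s <- screen_signals(coh)
  expect_s3_class(s, "signal_screen")
  expect_true(all(s$a >= 1))
  expect_equal(s[order(s$drug, s$event), ], s, ignore_attr = TRUE)
  sig <- s[s$signal, ]
  expect_equal(nrow(sig), 1L)
  expect_equal(sig$drug, "methotrexate")
  expect_equal(sig$event, "skin cancer")
  # determinism on re-run
  expect_identical(as.data.frame(screen_signals(coh)), as.data.frame(s))
  # empty drug list
  expect_equal(nrow(screen_signals(coh, drugs = character(0))), 0L)
})
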