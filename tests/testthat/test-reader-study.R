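test_that("ledger cell counts multiply out and exclusions propagate", {
  led <- build_ledger(40, 30, 4)
  ct <- ledger_counts(led)
  expect_identical(ct$total, 4800L)
  expect_identical(ct$excluded, 0L)

  excl <- data.frame(segment = rep(1:17, 2), patient = rep(1:2, each = 17))
  led2 <- build_ledger(40, 30, 4, exclusions = excl)
  ct2 <- ledger_counts(led2)
  expect_identical(ct2$total, 4800L)
  expect_identical(ct2$scored, 4664L)
  expect_identical(ct2$excluded, 136L)
  # exclusion identical across dose levels for each (segment, patient)
  by_pair <- tapply(led2$excluded, paste(led2$segment, led2$patient),
                    function(z) length(unique(z)))
  expect_true(all(by_pair == 1))

  expect_identical(ledger_counts(build_ledger(1, 1, 1))$total, 1L)
})

test_that("ledger conservation holds across random exclusion sets", {
  set.seed(42)
  for (i in 1:20) {
    ns <- sample(2:12, 1); np <- sample(2:8, 1); nd <- sample(1:4, 1)
    k <- sample(0:(ns * np), 1)
    pairs <- expand.grid(segment = 1:ns, patient = 1:np)
    excl <- pairs[sample(nrow(pairs), k), ]
    ct <- ledger_counts(build_ledger(ns, np, nd, exclusions = excl))
    expect_identical(ct$scored + ct$excluded, ct$total)
    expect_identical(ct$excluded, as.integer(k * nd))
  }
})

test_that("invalid exclusion sets are rejected", {
  expect_error(
    build_ledger(4, 4, 2, exclusions = data.frame(segment = c(1, 1),
                                                  patient = c(2, 2))),
    "duplicate"
  )
  expect_error(
    build_ledger(4, 4, 2, exclusions = data.frame(segment = 9, patient = 1)),
    "out of range"
  )
})

test_that("dichotomization splits the score scale at 2/3", {
  expect_identical(dichotomize(1L), "nondiagnostic")
  expect_identical(dichotomize(2L), "nondiagnostic")
  expect_identical(dichotomize(3L), "diagnostic")
  expect_identical(dichotomize(5L), "diagnostic")
  expect_identical(dichotomize(c(NA_integer_, 4L)), c(NA, "diagnostic"))
  expect_error(dichotomize(0L), "1..5")
  expect_error(dichotomize(6L), "1..5")
})

test_that("dichotomized categories partition the scored cells", {
  led <- synth_scores(
    build_ledger(10, 6, 4,
                 exclusions = data.frame(segment = 1:3, patient = c(1, 1, 2))),
    snr_by_dose = c(dose_1 = 30, dose_2 = 22, dose_3 = 15, dose_4 = 8),
    seed = 7
  )
  di <- dichotomize(led$score)
  ct <- ledger_counts(led)
  expect_identical(sum(di == "diagnostic", na.rm = TRUE) +
                     sum(di == "nondiagnostic", na.rm = TRUE),
                   ct$scored)
  expect_true(all(is.na(led$score[led$excluded])))
})

test_that("synthetic scores: deterministic at zero reader noise, seeded otherwise", {
  led <- build_ledger(8, 4, 2)
  snr <- c(dose_1 = 25, dose_2 = 10)
  a <- synth_scores(led, snr, seed = 3)
  b <- synth_scores(led, snr, seed = 3)
  expect_identical(a$score, b$score)
  z <- synth_scores(led, snr, seed = 3, reader_sd = 0)
  # zero reader noise: score is a pure function of the dose level
  expect_identical(length(unique(z$score[z$dose_level == "dose_1"])), 1L)
  expect_identical(length(unique(z$score[z$dose_level == "dose_2"])), 1L)
  expect_gt(z$score[z$dose_level == "dose_1"][1],
            z$score[z$dose_level == "dose_2"][1])
})

test_that("higher SNR yields a stochastically dominant score distribution", {
  led <- build_ledger(25, 40, 2)  # 1000 cells per dose level
  filled <- synth_scores(led, c(dose_1 = 28, dose_2 = 9), seed = 11)
  hi <- filled$score[filled$dose_level == "dose_1"]
  lo <- filled$score[filled$dose_level == "dose_2"]
  cdf_hi <- ecdf(hi); cdf_lo <- ecdf(lo)
  expect_true(all(cdf_hi(1:5) <= cdf_lo(1:5)))
  expect_gt(mean(hi), mean(lo))
})

test_that("score synthesis requires an SNR for every dose level", {
  led <- build_ledger(4, 2, 3)
  expect_error(synth_scores(led, c(dose_1 = 20, dose_2 = 10), seed = 1),
               "missing dose level")
  expect_error(synth_scores(led, c(dose_1 = 20, dose_2 = 10, dose_3 = -2),
                            seed = 1),
               "positive")
})

test_that("score summaries count diagnostic fractions per dose level", {
  led <- synth_scores(build_ledger(20, 10, 4),
                      c(dose_1 = 30, dose_2 = 20, dose_3 = 12, dose_4 = 5),
                      seed = 2)
  sm <- summarize_scores(led)
  expect_identical(nrow(sm), 4L)
  expect_true(all(sm$diagnostic + sm$nondiagnostic == sm$n))
  # diagnostic fraction falls with dose level SNR
  frac <- sm$diagnostic / sm$n
  expect_true(frac[1] >= frac[4])
})
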