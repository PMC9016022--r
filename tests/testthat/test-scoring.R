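test_that("hospitalization term scales at 0.1/day and caps at 4 from day 40", {
  expect_equal(idda_hosp_term(c(0, 20, 40, 60, 100)), c(0, 2, 4, 4, 4))
  # continuity at the branch point: both branches give 4
  expect_equal(idda_hosp_term(40 - 1e-9), 4, tolerance = 1e-7)
  expect_error(idda_hosp_term(101), "line 16")
})

test_that("ICU term scales at 0.8/day and caps at 8 from day 10", {
  expect_equal(idda_icu_term(c(0, 5, 10, 25, 100)), c(0, 4, 8, 8, 8))
  expect_equal(idda_icu_term(10 - 1e-9), 8, tolerance = 1e-7)
  expect_error(idda_icu_term(-1), "line 17")
})

test_that("performance multiplier is 150/kps above 29% and 6 at or below", {
  expect_equal(idda_multiplier(c(100, 75, 30, 29, 20, 10)),
               c(1.5, 2, 5, 6, 6, 6))
  # the floor introduces a jump of exactly 1.0 between 30% and 29%
  expect_equal(idda_multiplier(29) - idda_multiplier(30), 1)
  expect_error(idda_multiplier(105), "line 15")
})

test_that("scores match the published formula on constructed records", {
  zero <- idda_visit("P1", "2024-01-01", performance = 100)
  s <- idda_score(zero)
  expect_identical(s$total, 0)
  expect_equal(unlist(s[, c("organ_sum", "hosp_term", "icu_term",
                            "supportive_sum")]), rep(0, 4),
               ignore_attr = TRUE)
  expect_equal(s$multiplier, 1.5)

  worked <- idda_visit("P2", "2024-01-01",
                       organ_grades = c(2, 0, 3, 2, 0, 1, 0, 0, 0, 2, 0, 0, 1, 2),
                       performance = 70, hosp_days = 20, igg = "iv",
                       infestation = 2, other_organ = 1, nutrition = 2)
  s <- idda_score(worked)
  expect_equal(s$organ_sum, 13L)
  expect_equal(s$hosp_term, 2)
  expect_equal(s$supportive_sum, 8L)
  expect_equal(s$total, (13 + 2 + 0 + 8) * 150 / 70, tolerance = 1e-12)

  worst <- idda_visit("P3", "2024-01-01", organ_grades = rep(4, 14),
                      performance = 20, hosp_days = 50, icu_days = 12,
                      igg = "iv", infestation = 4, other_organ = 4,
                      nutrition = 4)
  expect_equal(idda_score(worst)$total, 498)
})

test_that("malignancy is carried along but never scored", {
  v <- idda_visit("P1", "2024-01-01", performance = 100, malignancy = TRUE)
  s <- idda_score(v)
  expect_identical(s$total, 0)
  expect_true(s$malignancy)
})

test_that("compute agrees with an independent formula transcription", {
  r <- random_visits(2000, seed = 21)
  expect_equal(idda_score(r)$total, excel_total(r), tolerance = 1e-9)
})

test_that("breakdown components recompose into the total", {
  r <- random_visits(500, seed = 31)
  s <- idda_score(r)
  expect_equal(s$total,
               (s$organ_sum + s$hosp_term + s$icu_term + s$supportive_sum) *
                 s$multiplier,
               tolerance = 1e-12)
  expect_true(all(s$total >= 0 & s$total <= 498))
  expect_true(all(s$multiplier >= 1.5 & s$multiplier <= 6))
})

test_that("missing items refuse by default and impute as zero on request", {
  v <- idda_visit("P1", "2024-01-01", organ_grades = c(NA, rep(2, 13)),
                  performance = 50)
  expect_error(idda_score(v), "line\\(s\\) 1")
  s <- idda_score(v, missing_policy = "zero")
  expect_equal(s$organ_sum, 26L)  # NA imputed as absent: a lower bound
  full <- v; full$p01 <- 2
  expect_true(idda_score(full)$total > s$total)
})

test_that("invalid records are refused with the first finding", {
  v <- idda_visit("P1", "2024-01-01", performance = 105)
  expect_error(idda_score(v), "line 15")
})

test_that("trajectories sort chronologically and label score changes", {
  g <- function(total13) c(total13, rep(0, 13))
  v <- rbind(
    idda_visit("P1", "2024-09-01", therapy_phase = "post-HSCT",
               organ_grades = g(0), performance = 100),
    idda_visit("P1", "2024-01-01", therapy_phase = "pre-HSCT",
               organ_grades = g(4), performance = 60, hosp_days = 30),
    idda_visit("P1", "2024-05-01", therapy_phase = "post-HSCT",
               organ_grades = g(2), performance = 80)
  )
  tr <- score_trajectory(v)
  expect_identical(tr$visit_date,
                   as.Date(c("2024-01-01", "2024-05-01", "2024-09-01")))
  expect_true(all(diff(tr$total) < 0))
  expect_identical(tr$change, c(NA, "improving", "improving"))
  expect_identical(attr(tr, "summary"), "improving")
  # stable under input permutation
  tr2 <- score_trajectory(v[c(2, 3, 1), ])
  expect_identical(tr$total, tr2$total)

  single <- score_trajectory(v[1, , drop = FALSE])
  expect_identical(nrow(single), 1L)
  expect_identical(attr(single, "summary"), "single-visit")

  v_dup <- v; v_dup$visit_date[2] <- v_dup$visit_date[1]
  expect_error(score_trajectory(v_dup), "duplicate")
  v_mix <- v; v_mix$patient_id[1] <- "P2"
  expect_error(score_trajectory(v_mix), "multiple patients")
})

test_that("phase deltas compare per-item means between therapy phases", {
  pre <- idda_visit(c("P1", "P1"), c("2024-01-01", "2024-02-01"),
                    therapy_phase = "pre",
                    organ_grades = rbind(c(3, rep(0, 12), 2),
                                         c(3, rep(0, 12), 0)),
                    performance = c(60, 70), hosp_days = c(20, 10))
  post <- idda_visit(c("P1", "P1"), c("2024-05-01", "2024-06-01"),
                     therapy_phase = "post",
                     organ_grades = rbind(c(1, rep(0, 13)),
                                          c(1, rep(0, 13))),
                     performance = c(90, 90))
  d <- phase_delta(rbind(pre, post), "pre", "post")
  expect_equal(d$delta[d$line %in% 3], 0)
  expect_equal(d$delta[d$line %in% 1], 1 - 3)     # grade 3 -> 1
  expect_equal(d$delta[d$line %in% 14], 0 - 1)    # mean 1 -> 0
  expect_equal(d$delta[d$line %in% 15], 90 - 65)
  expect_equal(d$delta[d$line %in% 16], -15)
  tot <- d[is.na(d$line), ]
  expect_identical(tot$item, "total")
  expect_equal(tot$mean_a,
               mean(c((5 + 2) * 150 / 60, (3 + 1) * 150 / 70)))
  expect_equal(tot$mean_b, 1 * 150 / 90)
  # identical phases have all-zero deltas
  same <- phase_delta(rbind(pre, pre2 <- transform(pre, therapy_phase = "post")),
                      "pre", "post")
  expect_true(all(abs(same$delta) < 1e-12))
  expect_error(phase_delta(rbind(pre, post), "pre", "during"), "during")
})
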