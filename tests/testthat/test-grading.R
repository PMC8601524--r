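rules <- ctcae_rules()

test_that("grading reproduces the printed nadir-value groupings", {
  # severe column: individually printed values
  expect_equal(grade_value("haemoglobin", c(4.3, 4.6), "mmol/L", rules),
               c(3L, 3L))
  expect_true(all(grade_value("leucocytes", c(1.0, 1.9, 1.9), "10^9/L",
                              rules) >= 3))
  expect_true(all(grade_value("neutrophils", c(0.7, 0.9), "10^9/L",
                              rules) >= 3))
  expect_gte(grade_value("platelets", 40, "10^9/L", rules), 3)
  expect_equal(grade_value("platelets", 24.9, "10^9/L", rules), 4L)
  # grade-2 column medians
  expect_equal(grade_value("haemoglobin", 6.0, "mmol/L", rules), 2L)
  expect_equal(grade_value("leucocytes", 2.5, "10^9/L", rules), 2L)
  expect_equal(grade_value("neutrophils", 1.3, "10^9/L", rules), 2L)
  expect_equal(grade_value("platelets", 62, "10^9/L", rules), 2L)
  # mild column medians
  expect_lte(grade_value("haemoglobin", 7.2, "mmol/L", rules), 1)
  expect_lte(grade_value("leucocytes", 3.8, "10^9/L", rules), 1)
  expect_lte(grade_value("neutrophils", 2.5, "10^9/L", rules), 1)
  expect_lte(grade_value("platelets", 144, "10^9/L", rules), 1)
})

test_that("grading is monotone and unit-consistent", {
  for (p in c("haemoglobin", "leucocytes", "neutrophils", "platelets")) {
    unit <- if (p == "haemoglobin") "mmol/L" else "10^9/L"
    vals <- seq(0.5, 300, length.out = 400)
    g <- grade_value(p, vals, unit, rules)
    expect_true(all(diff(g) <= 0))      # lower value => grade at least as high
  }
  # converting haemoglobin to g/dL first cannot change the grade
  v <- seq(0.5, 12, by = 0.01)
  g_mmol <- grade_value("haemoglobin", v, "mmol/L", rules)
  g_gdl <- grade_value("haemoglobin", v * 1.6113, "g/dL", rules)
  expect_identical(g_mmol, g_gdl)
  expect_error(grade_value("haemoglobin", 5, "mol/L", rules), "unit")
  expect_error(grade_value("basophils", 5, "10^9/L", rules), "parameter")
})

test_that("anaemia caps at grade 3 on values alone", {
  expect_equal(grade_value("haemoglobin", 1.2, "mmol/L", rules), 3L)
  expect_equal(grade_value("leucocytes", 0.4, "10^9/L", rules), 4L)
})

test_that("rules survive a JSON round trip", {
  path <- withr::local_tempfile(fileext = ".json")
  write_ctcae_rules(rules, path)
  back <- ctcae_rules(path = path)
  v <- c(0.6, 1.2, 2.4, 3.5, 5)
  expect_identical(grade_value("leucocytes", v, "10^9/L", back),
                   grade_value("leucocytes", v, "10^9/L", rules))
  expect_identical(grade_value("haemoglobin", v, "mmol/L", back),
                   grade_value("haemoglobin", v, "mmol/L", rules))
})

test_that("nadir finds the minimum, excludes baseline, breaks ties early", {
  labs <- make_labs(1, "platelets", c(-7, 0, 21, 42, 60),
                    c(260, 250, 180, 62, 110))
  nd <- nadir(labs)
  expect_equal(nd$nadir_value, 62)
  expect_equal(nd$nadir_day, 42)
  # baseline lower than any follow-up must not win
  labs2 <- make_labs(1, "platelets", c(-7, 21, 42), c(50, 180, 120))
  expect_equal(nadir(labs2)$nadir_value, 120)
  # ties resolve to the earliest day
  labs3 <- make_labs(1, "platelets", c(-7, 21, 42), c(250, 99, 99))
  expect_equal(nadir(labs3)$nadir_day, 21)
  expect_error(nadir(make_labs(1, "platelets", c(-7), c(250))), "window")
})

test_that("overall grade is the max across parameters with group labels", {
  labs <- four_param_labs(c(haemoglobin = 7.2, leucocytes = 3.8,
                            neutrophils = 2.5, platelets = 144))
  pr <- overall_patient_grade(labs)
  expect_lte(pr$overall_grade, 1)
  expect_equal(as.character(pr$grade_group), "0-1")

  labs2 <- four_param_labs(c(haemoglobin = 7.2, leucocytes = 4.5,
                             neutrophils = 2.5, platelets = 62))
  pr2 <- overall_patient_grade(labs2)
  expect_equal(pr2$overall_grade, 2L)
  expect_equal(as.character(pr2$grade_group), "2")
  expect_equal(pr2$platelets_grade, 2L)

  labs3 <- four_param_labs(c(haemoglobin = 8.2, leucocytes = 6,
                             neutrophils = 3.5, platelets = 260))
  expect_equal(overall_patient_grade(labs3)$overall_grade, 0L)

  expect_error(overall_patient_grade(labs[labs$parameter != "platelets", ]),
               "platelets")
})

test_that("per-cycle windows are half-open and translation-equivariant", {
  course <- tibble::tibble(patient_id = 1, cycle = 1:4,
                           day = c(0, 70, 140, 210), activity_gbq = 7.4)
  mk <- function(shift) {
    dplyr::bind_rows(
      four_param_labs(c(haemoglobin = 8.5, leucocytes = 7,
                        neutrophils = 4, platelets = 250))[1:4 * 3 - 2, ],
      make_labs(1, "haemoglobin", 21 + shift, 8.4),
      make_labs(1, "leucocytes", 21 + shift, 6.5),
      make_labs(1, "neutrophils", 21 + shift, 3.5),
      make_labs(1, "platelets", 21 + shift, 62)
    )
  }
  g1 <- per_cycle_grades(mk(0), course)
  expect_equal(g1$overall[g1$cycle == 1], 2L)
  expect_true(all(is.na(g1$overall[g1$cycle > 1])))
  expect_equal(first_occurrence_cycle(g1, 2)$first_cycle, 1L)
  # shifting the toxic sample by one whole cycle moves the occurrence
  g2 <- per_cycle_grades(mk(70), course)
  expect_equal(first_occurrence_cycle(g2, 2)$first_cycle, 2L)
  # a value exactly on the next cycle's day belongs to the earlier window
  g3 <- per_cycle_grades(mk(49), course)   # day 70 = cycle 2 start
  expect_equal(first_occurrence_cycle(g3, 2)$first_cycle, 1L)
})

test_that("observations outside all windows are reported, not graded", {
  course <- tibble::tibble(patient_id = 1, cycle = 1, day = 0,
                           activity_gbq = 7.4)
  labs <- dplyr::bind_rows(
    four_param_labs(c(haemoglobin = 8.5, leucocytes = 7, neutrophils = 4,
                      platelets = 250)),
    make_labs(1, "platelets", 200, 40)    # far beyond day 70 tail
  )
  expect_message(g <- per_cycle_grades(labs, course), "outside")
  expect_lt(max(g$overall), 3)
})

test_that("eligibility uses strict limits and lists every failure", {
  ok <- tibble::tibble(haemoglobin = 8, leucocytes = 6, neutrophils = 3,
                       platelets = 250, gfr = 80, albumin = 40)
  res <- eligibility_check(ok)
  expect_true(res$eligible)
  expect_equal(res$failing, "")

  one <- ok; one$leucocytes <- 2.9
  res1 <- eligibility_check(one)
  expect_false(res1$eligible)
  expect_equal(res1$failing, "leucocytes")

  # boundary values fail the strict inequalities
  bd <- ok; bd$haemoglobin <- 5.5
  expect_false(eligibility_check(bd)$eligible)

  two <- ok; two$leucocytes <- 2.4; two$neutrophils <- 0.9
  expect_equal(eligibility_check(two)$failing, "leucocytes,neutrophils")

  expect_error(eligibility_check(ok[, -6]), "albumin")
})

test_that("the printed discontinuation values fail their count criteria", {
  for (wbc in c(2.9, 2.2, 2.4)) {
    d <- tibble::tibble(haemoglobin = 8, leucocytes = wbc, neutrophils = 3,
                        platelets = 250, gfr = 80, albumin = 40)
    expect_match(eligibility_check(d)$failing, "leucocytes")
  }
  d <- tibble::tibble(haemoglobin = 8, leucocytes = 6, neutrophils = 0.99,
                      platelets = 250, gfr = 80, albumin = 40)
  expect_match(eligibility_check(d)$failing, "neutrophils")
})

test_that("course classification flags postponement and reduction", {
  mk_course <- function(days, acts) {
    tibble::tibble(patient_id = 1, cycle = seq_along(days), day = days,
                   activity_gbq = acts)
  }
  # intervals (70, 84, 70): the 84-day gap exceeds 70 + 7
  c1 <- classify_course(mk_course(cumsum(c(0, 70, 84, 70)), rep(7.4, 4)))
  expect_true(c1$postponed)
  expect_false(c1$reduced)
  expect_true(c1$completed)
  # reduced activities as printed in the swimmers-plot caption
  c2 <- classify_course(mk_course(cumsum(c(0, 70, 70, 70)),
                                  c(7.4, 7.4, 5.5, 3.7)))
  expect_true(c2$reduced)
  expect_false(c2$postponed)
  expect_equal(c2$min_activity_gbq, 3.7)
  # exactly planned schedule: no flags
  c3 <- classify_course(mk_course(cumsum(c(0, 70, 70, 70)), rep(7.4, 4)))
  expect_false(c3$postponed)
  expect_false(c3$reduced)
  # discontinuation reason passes through
  c4 <- classify_course(
    dplyr::mutate(mk_course(c(0, 70), c(7.4, 7.4))[1:2, ],
                  discontinuation_reason = "haematotoxicity"))
  expect_true(c4$discontinued_haematotoxicity)
  expect_false(c4$completed)
})

test_that("synthetic grade frequencies match the analytic bin probabilities", {
  dec <- default_decline_model()
  for (p in names(dec)) dec[[p]]$cv <- 0
  spec <- cohort_spec(n = 400, decline = dec, seed = 19)
  co <- generate_cohort(spec)
  pr <- overall_patient_grade(co$labs)
  emp <- table(factor(pr$grade_group, levels = c("0-1", "2", "3-4"))) / 400
  ana <- analytic_grade_group_probs(spec, rules)
  for (g in names(ana)) {
    se <- sqrt(ana[[g]] * (1 - ana[[g]]) / 400)
    expect_lt(abs(emp[[g]] - ana[[g]]), 3 * se + 1e-6)
  }
})
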