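test_that("clinically-high-risk arms fire exactly as printed", {
  expect_true(clinically_high_risk(simple_profile(sbp = 160, dbp = 89,
                                                  tc = 176)))
  expect_false(clinically_high_risk(simple_profile(sbp = 120, dbp = 80,
                                                   tc = 180, ldl = 100,
                                                   hdl = 50)))
  # TC >= 320 and TC/HDL = 8.2 > 8
  expect_true(clinically_high_risk(simple_profile(tc = 328, hdl = 40)))
  expect_true(clinically_high_risk(simple_profile(sbp = 150, dbp = 100)))
  expect_true(clinically_high_risk(simple_profile(ldl = 240)))
  # ratio arm alone: 8 exactly does not fire, above 8 does
  expect_false(clinically_high_risk(simple_profile(tc = 240, hdl = 30)))
  expect_true(clinically_high_risk(simple_profile(tc = 242, hdl = 30)))
  # missing lipids never trigger
  expect_false(clinically_high_risk(simple_profile(sbp = 159, dbp = 99)))
})

test_that("IFG is the half-open fasting band or diabetes history", {
  fasting <- function(g, hist = FALSE) {
    simple_profile(glucose_value = g, glucose_type = "fasting",
                   history = medical_history(past_diabetes = hist))
  }
  expect_true(impaired_fasting_glucose(fasting(118)))
  expect_false(impaired_fasting_glucose(
    simple_profile(glucose_value = 118, glucose_type = "random")))
  expect_equal(vapply(c(109, 110, 125, 126), function(g) {
    impaired_fasting_glucose(fasting(g))
  }, logical(1)), c(FALSE, TRUE, TRUE, FALSE))
  # history arm (literal rule) fires regardless of glucose
  expect_true(impaired_fasting_glucose(fasting(95, hist = TRUE)))
})

test_that("weight status thresholds are 25 and 30 with half-open bands", {
  expect_identical(weight_status(30), "obese")
  expect_identical(weight_status(25), "overweight")
  expect_identical(weight_status(24.99), "normal")
  expect_identical(weight_status(29.99), "overweight")
  expect_identical(weight_status(45), "obese")
  expect_error(weight_status(0), "positive")
})

test_that("hypertension and diabetes status follow their cut-offs", {
  expect_true(hypertension(simple_profile(sbp = 140, dbp = 80)))
  expect_false(hypertension(simple_profile(sbp = 139, dbp = 89)))
  expect_true(hypertension(simple_profile(sbp = 120, dbp = 90)))
  expect_true(hypertension(simple_profile(
    history = medical_history(past_hypertension = TRUE))))

  expect_true(diabetes_status(simple_profile(
    history = medical_history(past_diabetes = TRUE))))
  expect_true(diabetes_status(simple_profile(glucose_value = 126,
                                             glucose_type = "fasting")))
  expect_false(diabetes_status(simple_profile(glucose_value = 118,
                                              glucose_type = "fasting")))
  expect_false(diabetes_status(simple_profile(glucose_value = 199,
                                              glucose_type = "random")))
  expect_true(diabetes_status(simple_profile(glucose_value = 200,
                                             glucose_type = "random")))
  # unknown history treated as no
  expect_false(diabetes_status(simple_profile()))
})

test_that("management plans match the printed tier rows", {
  charts <- fixture_charts()
  p_low <- simple_profile(sbp = 118, dbp = 76)
  plan_high <- management_plan("R40_PLUS", sub_conditions(p_low), p_low)
  expect_true(plan_high$referral)
  expect_identical(plan_high$cvd_screening_interval, 3)
  expect_setequal(plan_high$medications,
                  c("bp_lowering", "lipid_lowering", "antiplatelet"))

  plan_low <- management_plan("R0_10", sub_conditions(p_low), p_low)
  expect_false(plan_low$referral)
  expect_identical(plan_low$cvd_screening_interval, 60)
  expect_length(plan_low$medications, 0)

  p_ifg <- simple_profile(sbp = 118, dbp = 76, glucose_value = 115,
                          glucose_type = "fasting")
  plan_ifg <- management_plan("R10_20", sub_conditions(p_ifg), p_ifg)
  expect_true(plan_ifg$referral)
  expect_true("ifg" %in% plan_ifg$referral_reasons)
  expect_identical(plan_ifg$cvd_screening_interval, 24)
  expect_true(plan_ifg$diabetes_screening_flag)
})

test_that("plans equal the hand-coded decision table on a dense grid", {
  grid <- expand.grid(
    band = c("R0_10", "R10_20", "R20_30", "R30_40", "R40_PLUS"),
    sbp = c(120, 145, 165), dbp = c(80, 95),
    glucose = c(95, 118, 130), past_diabetes = c(FALSE, TRUE),
    past_cvd = c(FALSE, TRUE), tc = c(180, 210, 330),
    smoker = c(FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  rules <- load_rules()
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    p <- risk_profile(
      age = 50, gender = "male", smoker = g$smoker,
      sbp = g$sbp, dbp = g$dbp,
      glucose_value = g$glucose, glucose_type = "fasting",
      tc = g$tc, hdl = 40, ldl = 130,
      history = medical_history(past_diabetes = g$past_diabetes,
                                past_stroke = g$past_cvd))
    sub <- sub_conditions(p)

    chr <- oracle_chr(g$sbp, g$dbp, g$tc, ldl = 130, hdl = 40)
    ifg <- oracle_ifg(g$glucose, "fasting", g$past_diabetes)
    dia <- oracle_diabetes(g$glucose, "fasting", g$past_diabetes)
    expect_identical(sub$clinically_high_risk, chr)
    expect_identical(sub$ifg, ifg)
    expect_identical(sub$diabetes, dia)
    expect_identical(sub$hypertension,
                     oracle_hypertension(g$sbp, g$dbp))

    want <- oracle_plan(g$band, dia, ifg, chr, g$past_cvd, g$past_diabetes,
                        g$sbp, g$dbp, g$tc, ldl = 130, smoker = g$smoker)
    got <- management_plan(g$band, sub, p, rules)
    expect_identical(got$tier, want$tier)
    expect_identical(got$referral, want$referral, info = paste("row", i))
    expect_identical(got$cvd_screening_interval, want$interval)
    expect_setequal(got$medications,
                    if (is.null(want$meds)) character(0) else want$meds)
    expect_setequal(got$general_advice, want$advice)
  }
})

test_that("plan invariants hold across a random profile sweep", {
  charts <- fixture_charts()
  set.seed(21)
  for (i in 1:150) {
    p <- risk_profile(
      age = sample(40:80, 1), gender = sample(c("male", "female"), 1),
      smoker = sample(c(TRUE, FALSE), 1),
      sbp = sample(100:200, 1), dbp = sample(60:95, 1),
      glucose_value = sample(80:250, 1),
      glucose_type = sample(c("fasting", "random"), 1),
      tc = sample(120:340, 1), hdl = sample(25:70, 1),
      history = medical_history(
        past_diabetes = sample(c(TRUE, FALSE), 1),
        past_mi_angina = sample(c(TRUE, FALSE, NA), 1)))
    risk <- assess_risk(p, charts$li, charts$hi)
    sub <- sub_conditions(p)
    plan <- management_plan(risk, sub, p)

    if (plan$tier == "high") {
      expect_true(plan$referral)
      expect_setequal(plan$medications,
                      c("bp_lowering", "lipid_lowering", "antiplatelet"))
    }
    if (sub$ifg) {
      expect_true(plan$referral)
      expect_true("ifg" %in% plan$referral_reasons)
    }
    if (length(plan$referral_reasons) > 0) expect_true(plan$referral)
    expect_identical("smoking_cessation" %in% plan$general_advice,
                     isTRUE(p$smoker))
    expect_true(all(c("nutrition", "lifestyle") %in% plan$general_advice))

    # identical inputs give identical plans
    expect_identical(plan, management_plan(risk, sub, p))
  }
})

test_that("screening interval decreases with the effective tier", {
  p <- simple_profile(sbp = 118, dbp = 76)
  sub <- sub_conditions(p)
  intervals <- vapply(c("R0_10", "R10_20", "R20_30", "R30_40", "R40_PLUS"),
                      function(b) management_plan(b, sub, p)$cvd_screening_interval,
                      numeric(1))
  expect_true(all(diff(intervals) <= 0))
  expect_equal(unname(intervals), c(60, 24, 12, 3, 3))
})

test_that("rules files are completeness-checked at load", {
  rules <- load_rules()
  expect_s3_class(rules, "cds_rules")
  bad <- unclass(rules)
  bad$tiers$low <- NULL
  tmp <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(bad, tmp)
  expect_error(load_rules(tmp), "missing tier",
               class = "cvdscreen_input_error")

  bad2 <- unclass(rules)
  bad2$tiers$high$medications$antiplatelet <- list("sometimes")
  yaml::write_yaml(bad2, tmp)
  expect_error(load_rules(tmp), "unknown condition",
               class = "cvdscreen_input_error")
})
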