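# Independent brute-force oracles the test suite checks the package
# against. These are deliberately naive transcriptions of the published
# rules and never call the implementation paths they verify.

# direct evaluation of each clinically-high-risk arm
oracle_chr <- function(sbp, dbp, tc = NULL, ldl = NULL, hdl = NULL) {
  isTRUE(sbp >= 160) || isTRUE(dbp >= 100) ||
    (!is.null(tc) && tc >= 320) || (!is.null(ldl) && ldl >= 240) ||
    (!is.null(tc) && !is.null(hdl) && tc / hdl > 8)
}

oracle_ifg <- function(glucose = NULL, type = NULL, past_diabetes = FALSE) {
  (!is.null(glucose) && identical(type, "fasting") &&
     glucose >= 110 && glucose < 126) || isTRUE(past_diabetes)
}

oracle_diabetes <- function(glucose = NULL, type = NULL,
                            past_diabetes = FALSE) {
  isTRUE(past_diabetes) ||
    (!is.null(glucose) && identical(type, "fasting") && glucose >= 126) ||
    (!is.null(glucose) && identical(type, "random") && glucose >= 200)
}

oracle_hypertension <- function(sbp, dbp, past_htn = FALSE) {
  isTRUE(sbp >= 140) || isTRUE(dbp >= 90) || isTRUE(past_htn)
}

# hand-coded decision table: referral / interval / medications per tier
oracle_plan <- function(band, diabetes, ifg, chr, past_cvd, past_diabetes,
                        sbp, dbp, tc = NULL, ldl = NULL, smoker = FALSE) {
  bp_140_90 <- sbp >= 140 || dbp >= 90
  high <- band %in% c("R30_40", "R40_PLUS") || past_cvd || chr
  if (high) {
    out <- list(tier = "high", referral = TRUE, interval = 3,
                meds = c("bp_lowering", "lipid_lowering", "antiplatelet"))
  } else if (band == "R20_30") {
    out <- list(
      tier = "intermediate", referral = TRUE, interval = 12,
      meds = c(if (bp_140_90) "bp_lowering",
               if (diabetes || sbp >= 160 ||
                   (!is.null(tc) && tc > 200) ||
                   (!is.null(ldl) && ldl > 120)) "lipid_lowering"))
  } else {
    out <- list(
      tier = if (band == "R10_20") "elevated" else "low",
      referral = diabetes || ifg || (past_diabetes && sbp >= 160),
      interval = if (band == "R10_20") 24 else 60,
      meds = c(if ((diabetes && bp_140_90) || sbp >= 160) "bp_lowering",
               if (diabetes || sbp >= 160) "lipid_lowering"))
  }
  out$advice <- c(if (smoker) "smoking_cessation", "nutrition", "lifestyle")
  out
}

# fixture-building shortcuts -----------------------------------------------

fixture_charts <- function() {
  list(li = synthetic_chart("LI"), hi = synthetic_chart("HI"))
}

# the counterfactual-demo participant: young male smoker with diabetes,
# BP 160/89 mmHg, TC 176 mg/dL
demo_profile <- function() {
  risk_profile(age = 33, gender = "male", smoker = TRUE,
               sbp = 160, dbp = 89, tc = 176,
               history = medical_history(past_diabetes = TRUE))
}

simple_profile <- function(age = 55, gender = "female", smoker = FALSE,
                           sbp = 120, dbp = 80, ...) {
  risk_profile(age = age, gender = gender, smoker = smoker,
               sbp = sbp, dbp = dbp, ...)
}

# small deterministic event log: two workers, configurable encounters
make_log_row <- function(t, user, enc, step, element, value = NA_character_) {
  data.frame(timestamp = t, user_id = user, encounter_id = enc,
             step = step, element_id = element, value = value,
             stringsAsFactors = FALSE)
}

# one minimal complete encounter spanning [t0, t0 + total_s]
minimal_encounter_events <- function(user, enc, t0, total_s = 1200,
                                     bluetooth = FALSE, sections = c(TRUE,
                                       TRUE, TRUE), likert = 4) {
  q <- total_s / 12
  rows <- list(
    make_log_row(t0, user, enc, 1L, "step_open"),
    make_log_row(t0 + 2 * q, user, enc, 1L, "step_complete"),
    make_log_row(t0 + 2 * q + 5, user, enc, 2L, "step_open"),
    make_log_row(t0 + 3 * q, user, enc, 2L, "step_complete"),
    make_log_row(t0 + 3 * q + 5, user, enc, 3L, "step_open"),
    make_log_row(t0 + 3 * q + 10, user, enc, 3L, "bp_start"),
    if (bluetooth) {
      make_log_row(t0 + 5 * q, user, enc, 3L, "bp_bluetooth_receive")
    } else {
      make_log_row(t0 + 5 * q, user, enc, 3L, "bp_manual_entry")
    },
    make_log_row(t0 + 6 * q, user, enc, 3L, "bp_done"),
    make_log_row(t0 + 7 * q, user, enc, 3L, "glucose_entry", "100"),
    make_log_row(t0 + 9 * q, user, enc, 3L, "step_complete"),
    make_log_row(t0 + 9 * q + 5, user, enc, 4L, "step_open"),
    if (sections[1]) make_log_row(t0 + 10 * q, user, enc, 4L,
                                  "riskmeter_open"),
    if (sections[2]) make_log_row(t0 + 10 * q + 5, user, enc, 4L,
                                  "recs_open"),
    if (sections[3]) make_log_row(t0 + 10 * q + 10, user, enc, 4L,
                                  "nextvisit_open"),
    make_log_row(t0 + 11 * q, user, enc, 4L, "likert_rating",
                 as.character(likert)),
    make_log_row(t0 + total_s, user, enc, 4L, "step_complete")
  )
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}
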