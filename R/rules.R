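# Sub-condition detection and the referral / medication / next-visit logic.
# The decision table (tiers, intervals, referral and medication conditionals)
# is data-driven: it ships as a YAML rules file and is validated at load.

#' Clinically-high-risk sub-condition
#'
#' A participant is clinically high risk (CHR), independent of the chart
#' band, when SBP >= 160 mmHg or DBP >= 100 mmHg or TC >= 320 mg/dL or
#' LDL >= 240 mg/dL or TC/HDL > 8. Missing lipids never trigger.
#'
#' @param profile A [risk_profile()].
#' @return Logical.
#' @export
#' @examples
#' clinically_high_risk(risk_profile(age = 33, gender = "male", smoker = TRUE,
#'                                   sbp = 160, dbp = 89, tc = 176))
clinically_high_risk <- function(profile) {
  stopifnot(inherits(profile, "risk_profile"))
  bp <- effective_bp(profile)
  tc <- profile$tc
  ldl <- profile$ldl
  hdl <- profile$hdl
  isTRUE(bp[["sbp"]] >= 160) ||
    isTRUE(bp[["dbp"]] >= 100) ||
    isTRUE(!is.null(tc) && tc >= 320) ||
    isTRUE(!is.null(ldl) && ldl >= 240) ||
    isTRUE(!is.null(tc) && !is.null(hdl) && tc / hdl > 8)
}

#' Impaired-fasting-glucose sub-condition
#'
#' True when fasting glucose lies in the half-open band
#' \[110, 126) mg/dL, or when the participant reports a history of diabetes.
#' The history arm is a literal transcription of the deployed rule even
#' though it conflates IFG with established diabetes; see the methods
#' vignette. Random (non-fasting) glucose never triggers.
#'
#' @inheritParams clinically_high_risk
#' @return Logical.
#' @export
impaired_fasting_glucose <- function(profile) {
  stopifnot(inherits(profile, "risk_profile"))
  fasting_in_band <- !is.null(profile$glucose_value) &&
    identical(profile$glucose_type, "fasting") &&
    profile$glucose_value >= 110 && profile$glucose_value < 126
  fasting_in_band || hist_flag(profile, "past_diabetes")
}

#' Weight status from BMI
#'
#' Obese when BMI >= 30, overweight when 25 <= BMI < 30, else normal.
#' Apply to the unrounded BMI.
#'
#' @param bmi Body-mass index, kg/m^2 (> 0).
#' @return `"normal"`, `"overweight"` or `"obese"`.
#' @export
#' @examples
#' weight_status(30)     # obese
#' weight_status(24.99)  # normal
weight_status <- function(bmi) {
  if (!is_scalar_number(bmi) || bmi <= 0) {
    stop("bmi must be a positive number", call. = FALSE)
  }
  if (bmi >= 30) "obese" else if (bmi >= 25) "overweight" else "normal"
}

#' Hypertension sub-condition
#'
#' SBP >= 140 mmHg or DBP >= 90 mmHg or a history of hypertension.
#'
#' @inheritParams clinically_high_risk
#' @return Logical.
#' @export
hypertension <- function(profile) {
  stopifnot(inherits(profile, "risk_profile"))
  bp <- effective_bp(profile)
  isTRUE(bp[["sbp"]] >= 140) || isTRUE(bp[["dbp"]] >= 90) ||
    hist_flag(profile, "past_hypertension")
}

#' Diabetes status fed to the risk chart and rules
#'
#' True on a history of diabetes, fasting glucose >= 126 mg/dL, or random
#' glucose >= 200 mg/dL (standard diagnostic cut-offs). A logical
#' `diabetes_override` field on the profile (set by counterfactual
#' projection) takes precedence.
#'
#' @inheritParams clinically_high_risk
#' @return Logical.
#' @export
diabetes_status <- function(profile) {
  stopifnot(inherits(profile, "risk_profile"))
  if (!is.null(profile$diabetes_override)) {
    return(isTRUE(profile$diabetes_override))
  }
  if (hist_flag(profile, "past_diabetes")) return(TRUE)
  g <- profile$glucose_value
  if (is.null(g)) return(FALSE)
  (identical(profile$glucose_type, "fasting") && g >= 126) ||
    (identical(profile$glucose_type, "random") && g >= 200)
}

#' Compute all management sub-conditions for a profile
#'
#' Bundles [clinically_high_risk()], [impaired_fasting_glucose()],
#' [weight_status()] (on [compute_bmi()]; `NA` when height or weight is
#' missing), [hypertension()] and [diabetes_status()].
#'
#' @inheritParams clinically_high_risk
#' @return A list of class `sub_conditions` with elements
#'   `clinically_high_risk`, `ifg`, `weight_status`, `hypertension`,
#'   `diabetes`.
#' @export
sub_conditions <- function(profile) {
  stopifnot(inherits(profile, "risk_profile"))
  ws <- if (!is.null(profile$height) && !is.null(profile$weight)) {
    weight_status(compute_bmi_raw(profile$height, profile$weight))
  } else {
    NA_character_
  }
  structure(list(
    clinically_high_risk = clinically_high_risk(profile),
    ifg = impaired_fasting_glucose(profile),
    weight_status = ws,
    hypertension = hypertension(profile),
    diabetes = diabetes_status(profile)
  ), class = "sub_conditions")
}

#' @export
print.sub_conditions <- function(x, ...) {
  cat("<sub_conditions> CHR:", x$clinically_high_risk,
      "| IFG:", x$ifg, "| weight:", x$weight_status,
      "| hypertension:", x$hypertension, "| diabetes:", x$diabetes, "\n")
  invisible(x)
}

# ---- rules file -----------------------------------------------------------

RULE_TIERS <- c("high", "intermediate", "elevated", "low")
RULE_CONDITIONS <- c("always", "never", "diabetes", "ifg", "bp_140_90",
                     "sbp_160", "tc_gt_200", "ldl_gt_120",
                     "diabetes_and_bp_140_90", "diabetes_history_and_sbp_160")
MEDICATIONS <- c("bp_lowering", "lipid_lowering", "antiplatelet")

#' Load and validate a management rules file
#'
#' The decision table behind [management_plan()] is externalized as YAML:
#' one block per risk tier (`high`, `intermediate` for 20-<30%, `elevated`
#' for 10-<20%, `low` for <10%), each with `interval_months` (next CVD
#' screening), a `referral` conditional and per-medication conditionals.
#' Conditionals are lists of named primitive conditions combined as "any
#' of"; the vocabulary is `always`, `never`, `diabetes`, `ifg`,
#' `bp_140_90` (SBP >= 140 or DBP >= 90), `sbp_160`, `tc_gt_200`,
#' `ldl_gt_120`, `diabetes_and_bp_140_90`,
#' `diabetes_history_and_sbp_160`. Completeness (all four tiers, all
#' medication entries, known condition names, positive intervals) is
#' checked at load; failures name the offending entry.
#'
#' @param path YAML file; defaults to the shipped rules reproducing the
#'   published decision table.
#' @return A list of class `cds_rules`.
#' @export
load_rules <- function(path = default_rules_path()) {
  if (!file.exists(path)) input_error(paste0("rules file not found: ", path))
  rules <- yaml::read_yaml(path)
  validate_rules(rules)
  structure(rules, class = "cds_rules")
}

default_rules_path <- function() {
  system.file("extdata", "rules_default.yaml", package = "cvdscreen",
              mustWork = TRUE)
}

validate_rules <- function(rules) {
  if (!is.list(rules) || !identical(sort(names(rules)),
                                    sort(c("tiers", "thresholds")))) {
    input_error("rules file must have top-level 'tiers' and 'thresholds'")
  }
  missing_tier <- setdiff(RULE_TIERS, names(rules$tiers))
  if (length(missing_tier) > 0L) {
    input_error(paste0("rules file missing tier(s): ",
                       paste(missing_tier, collapse = ", ")))
  }
  for (tier in RULE_TIERS) {
    t <- rules$tiers[[tier]]
    if (!is_scalar_number(t$interval_months) || t$interval_months <= 0) {
      input_error(paste0("tier '", tier, "': interval_months must be > 0"))
    }
    conds <- c(list(referral = t$referral), t$medications)
    med_missing <- setdiff(MEDICATIONS, names(t$medications))
    if (length(med_missing) > 0L) {
      input_error(paste0("tier '", tier, "': missing medication entry ",
                         paste(med_missing, collapse = ", ")))
    }
    for (nm in names(conds)) {
      bad <- setdiff(unlist(conds[[nm]]), RULE_CONDITIONS)
      if (length(bad) > 0L) {
        input_error(paste0("tier '", tier, "', '", nm,
                           "': unknown condition ", paste(bad, collapse = ", ")))
      }
    }
  }
  for (th in c("sbp_high", "bp_sbp", "bp_dbp", "tc_gt", "ldl_gt")) {
    if (!is_scalar_number(rules$thresholds[[th]])) {
      input_error(paste0("rules thresholds missing '", th, "'"))
    }
  }
  invisible(TRUE)
}

# default rules object, parsed once per session
rules_cache <- new.env(parent = emptyenv())
default_rules <- function() {
  if (is.null(rules_cache$rules)) rules_cache$rules <- load_rules()
  rules_cache$rules
}

eval_condition <- function(cond, ctx, th) {
  switch(cond,
    always = TRUE,
    never = FALSE,
    diabetes = ctx$diabetes,
    ifg = ctx$ifg,
    bp_140_90 = isTRUE(ctx$sbp >= th$bp_sbp) || isTRUE(ctx$dbp >= th$bp_dbp),
    sbp_160 = isTRUE(ctx$sbp >= th$sbp_high),
    tc_gt_200 = isTRUE(!is.null(ctx$tc) && ctx$tc > th$tc_gt),
    ldl_gt_120 = isTRUE(!is.null(ctx$ldl) && ctx$ldl > th$ldl_gt),
    diabetes_and_bp_140_90 = ctx$diabetes &&
      (isTRUE(ctx$sbp >= th$bp_sbp) || isTRUE(ctx$dbp >= th$bp_dbp)),
    diabetes_history_and_sbp_160 = ctx$past_diabetes &&
      isTRUE(ctx$sbp >= th$sbp_high),
    stop("unknown rule condition: ", cond, call. = FALSE)
  )
}

eval_any <- function(conds, ctx, th) {
  any(vapply(unlist(conds), eval_condition, logical(1), ctx = ctx, th = th))
}

#' Management tier for a chart band and sub-conditions
#'
#' The effective tier is `high` when the chart band is >= 30%, the
#' participant has a past CVD event (myocardial infarction/angina, stroke
#' or peripheral vascular disease), or the clinically-high-risk
#' sub-condition holds; otherwise the band maps directly
#' (20-<30% `intermediate`, 10-<20% `elevated`, <10% `low`).
#'
#' @param band One of the five chart bands (string or factor).
#' @param sub A [sub_conditions()] list.
#' @param profile The source [risk_profile()].
#' @return Tier label.
#' @export
management_tier <- function(band, sub, profile) {
  band <- as.character(band)
  past_cvd <- hist_flag(profile, "past_mi_angina") ||
    hist_flag(profile, "past_stroke") || hist_flag(profile, "past_pvd")
  if (band %in% c("R30_40", "R40_PLUS") || past_cvd ||
      isTRUE(sub$clinically_high_risk)) {
    "high"
  } else {
    switch(band, R20_30 = "intermediate", R10_20 = "elevated", R0_10 = "low",
           stop("unknown band: ", band, call. = FALSE))
  }
}

#' Referral, medication and next-visit plan
#'
#' Applies the data-driven decision table to a chart band and the
#' sub-conditions computed from the same profile. High tier (>= 30% band,
#' past CVD, or clinically high risk): refer, re-screen in 3 months
#' (configurable 3-6), all three medication classes. Intermediate
#' (20-<30%): refer, yearly screening, BP-lowering if BP >= 140/90,
#' lipid-lowering if diabetes or SBP >= 160 or TC > 200 or LDL > 120 mg/dL.
#' 10-<20% and <10%: screening every 2 / 5 years, referral only when
#' diabetes or IFG is present (or diabetic history with SBP >= 160),
#' BP-lowering if (diabetes and BP >= 140/90) or SBP >= 160, lipid-lowering
#' if diabetes or SBP >= 160. Smoking-cessation advice is attached only for
#' smokers; nutrition and lifestyle advice always.
#'
#' Referral reasons use the two-label vocabulary `high_cvd_risk`
#' (band/tier-driven) and `ifg` (attached whenever the IFG flag holds);
#' diabetes-driven referrals without the IFG flag carry no reason label.
#' The next-visit diabetes screening flag is set when IFG holds.
#'
#' @param risk A `risk_assessment` from [assess_risk()] (or a band label).
#' @param sub [sub_conditions()] for the same profile.
#' @param profile The source [risk_profile()].
#' @param rules A `cds_rules` object; defaults to the shipped table.
#' @return A list of class `management_plan`: `tier`, `referral`,
#'   `referral_reasons`, `cvd_screening_interval` (months),
#'   `cvd_screening_interval_range`, `diabetes_screening_flag`,
#'   `medications`, `general_advice`.
#' @export
#' @examples
#' p <- risk_profile(age = 55, gender = "female", smoker = FALSE,
#'                   sbp = 120, dbp = 80)
#' management_plan("R0_10", sub_conditions(p), p)
management_plan <- function(risk, sub, profile, rules = default_rules()) {
  stopifnot(inherits(sub, "sub_conditions"), inherits(profile, "risk_profile"))
  band <- if (inherits(risk, "risk_assessment")) risk$band else risk_band(risk)
  if (!inherits(rules, "cds_rules")) {
    validate_rules(rules)
    class(rules) <- "cds_rules"
  }
  tier <- management_tier(band, sub, profile)
  t <- rules$tiers[[tier]]
  th <- rules$thresholds

  bp <- effective_bp(profile)
  ctx <- list(
    diabetes = isTRUE(sub$diabetes), ifg = isTRUE(sub$ifg),
    past_diabetes = hist_flag(profile, "past_diabetes"),
    sbp = if (is.null(bp)) NULL else bp[["sbp"]],
    dbp = if (is.null(bp)) NULL else bp[["dbp"]],
    tc = profile$tc, ldl = profile$ldl
  )

  reasons <- character(0)
  if (tier %in% c("high", "intermediate")) reasons <- c(reasons, "high_cvd_risk")
  if (isTRUE(sub$ifg)) reasons <- c(reasons, "ifg")
  referral <- eval_any(t$referral, ctx, th) || length(reasons) > 0L

  meds <- MEDICATIONS[vapply(MEDICATIONS, function(m) {
    eval_any(t$medications[[m]], ctx, th)
  }, logical(1))]

  advice <- c(if (isTRUE(profile$smoker)) "smoking_cessation",
              "nutrition", "lifestyle")

  structure(list(
    tier = tier, band = band,
    referral = referral, referral_reasons = reasons,
    cvd_screening_interval = as.numeric(t$interval_months),
    cvd_screening_interval_range = as.numeric(unlist(t$interval_range %||%
                                                       t$interval_months)),
    diabetes_screening_flag = isTRUE(sub$ifg),
    medications = meds, general_advice = advice
  ), class = "management_plan")
}

#' @export
print.management_plan <- function(x, ...) {
  cat("<management_plan> tier ", x$tier, " (band ", as.character(x$band),
      ")\n", sep = "")
  cat("  referral:", if (x$referral) "YES" else "no",
      if (length(x$referral_reasons))
        paste0("(", paste(x$referral_reasons, collapse = ", "), ")") else "",
      "\n")
  cat("  next CVD screening in", x$cvd_screening_interval, "months\n")
  if (x$diabetes_screening_flag) cat("  diabetes screening advised\n")
  cat("  medications:",
      if (length(x$medications)) paste(x$medications, collapse = ", ")
      else "none", "\n")
  cat("  advice:", paste(x$general_advice, collapse = ", "), "\n")
  invisible(x)
}
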