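# Participant record: the four-step screening encounter (demographics,
# medical history, risk-factor acquisition, decision support) flattened into
# a single risk-factor profile consumed by the chart lookup and the rules.

#' Default clinical validation ranges
#'
#' Plausibility bounds applied by [validate_step()] to every measured
#' quantity. The screening charts and rules never see a value outside these
#' ranges. All bounds are configurable: pass a modified copy of this list to
#' [validate_step()].
#'
#' @return Named list; each element is `c(lower, upper)` in the unit of the
#'   field (years, mmHg, mg/dL, cm, kg).
#' @export
#' @examples
#' validation_ranges()$sbp
validation_ranges <- function() {
  list(
    age     = c(18, 120),   # years
    sbp     = c(60, 300),   # mmHg
    dbp     = c(30, 200),   # mmHg
    glucose = c(20, 600),   # mg/dL
    tc      = c(50, 500),   # mg/dL
    hdl     = c(10, 150),   # mg/dL
    ldl     = c(20, 400),   # mg/dL
    tg      = c(20, 1000),  # mg/dL
    height  = c(100, 250),  # cm
    weight  = c(20, 250)    # kg
  )
}

#' Medical-history record (screening step 2)
#'
#' Past and family history flags plus current medication and BP targets.
#' Every flag is tri-state: `TRUE`, `FALSE` or `NA` (unknown). Downstream
#' rules treat `NA` as `FALSE` (conservative for medication triggers) while
#' the stored value is preserved for audit.
#'
#' @param past_mi_angina,past_stroke,past_pvd Past history of myocardial
#'   infarction/angina, stroke, peripheral vascular disease.
#' @param past_diabetes,past_hypertension Past history of diabetes /
#'   hypertension.
#' @param family_mi_angina,family_stroke,family_diabetes Family history
#'   flags.
#' @param on_bp_lowering,on_lipid_lowering,on_antiplatelet Current
#'   medication flags.
#' @param target_sbp,target_dbp Optional treatment targets, mmHg.
#' @return A list of class `medical_history`.
#' @export
medical_history <- function(past_mi_angina = NA, past_stroke = NA,
                            past_pvd = NA, past_diabetes = NA,
                            past_hypertension = NA,
                            family_mi_angina = NA, family_stroke = NA,
                            family_diabetes = NA,
                            on_bp_lowering = NA, on_lipid_lowering = NA,
                            on_antiplatelet = NA,
                            target_sbp = NULL, target_dbp = NULL) {
  flags <- list(
    past_mi_angina = past_mi_angina, past_stroke = past_stroke,
    past_pvd = past_pvd, past_diabetes = past_diabetes,
    past_hypertension = past_hypertension,
    family_mi_angina = family_mi_angina, family_stroke = family_stroke,
    family_diabetes = family_diabetes,
    on_bp_lowering = on_bp_lowering, on_lipid_lowering = on_lipid_lowering,
    on_antiplatelet = on_antiplatelet
  )
  for (nm in names(flags)) {
    if (!is.logical(flags[[nm]]) || length(flags[[nm]]) != 1L) {
      stop("history flag '", nm, "' must be TRUE, FALSE or NA", call. = FALSE)
    }
  }
  structure(c(flags, list(target_sbp = target_sbp, target_dbp = target_dbp)),
            class = "medical_history")
}

#' Risk-factor profile for one screening participant
#'
#' The flat container consumed by the chart lookup ([assess_risk()]) and the
#' decision rules ([sub_conditions()], [management_plan()]). It merges the
#' four acquisition steps: demographics, medical history, and measured risk
#' factors. Blood pressure may be supplied either as a single `sbp`/`dbp`
#' pair or as up to three readings in `bp_readings` (the representative pair
#' is then derived by [summarize_bp()]).
#'
#' @param age Age in completed years.
#' @param gender `"male"` or `"female"`.
#' @param smoker Current smoking status (`TRUE`/`FALSE`).
#' @param sbp,dbp Systolic/diastolic blood pressure, mmHg (optional when
#'   `bp_readings` given).
#' @param bp_readings Optional list of up to three `c(sbp, dbp)` pairs.
#' @param glucose_value Blood glucose, mg/dL (optional).
#' @param glucose_type `"fasting"` or `"random"`; required when
#'   `glucose_value` is given.
#' @param tc,hdl,ldl,tg Lipids, mg/dL (each optional; total cholesterol
#'   `tc` selects the high-information chart when present).
#' @param height,weight Height in cm, weight in kg (optional).
#' @param history A [medical_history()] record.
#' @param patient_id Opaque non-empty identifier.
#' @param name,location Free-text demographics (optional).
#' @return A list of class `risk_profile`.
#' @export
#' @examples
#' p <- risk_profile(age = 33, gender = "male", smoker = TRUE,
#'                   sbp = 160, dbp = 89, tc = 176,
#'                   history = medical_history(past_diabetes = TRUE))
risk_profile <- function(age, gender, smoker,
                         sbp = NULL, dbp = NULL, bp_readings = NULL,
                         glucose_value = NULL, glucose_type = NULL,
                         tc = NULL, hdl = NULL, ldl = NULL, tg = NULL,
                         height = NULL, weight = NULL,
                         history = medical_history(),
                         patient_id = "anon", name = NULL, location = NULL) {
  if (!is_scalar_number(age)) stop("age must be a single number")
  gender <- match.arg(gender, c("male", "female"))
  if (!is.logical(smoker) || length(smoker) != 1L || is.na(smoker)) {
    stop("smoker must be TRUE or FALSE")
  }
  if (!is.null(glucose_value) && is.null(glucose_type)) {
    stop("glucose_type (fasting/random) is required when glucose_value is given")
  }
  if (!is.null(glucose_type)) {
    glucose_type <- match.arg(glucose_type, c("fasting", "random"))
  }
  if (!is.null(bp_readings)) {
    if (!is.list(bp_readings) || length(bp_readings) < 1L ||
        length(bp_readings) > 3L) {
      stop("bp_readings must be a list of 1-3 c(sbp, dbp) pairs")
    }
    bp_readings <- lapply(bp_readings, function(r) {
      r <- as.numeric(r)
      if (length(r) != 2L || any(!is.finite(r))) {
        stop("each BP reading must be a finite c(sbp, dbp) pair")
      }
      r
    })
  }
  if (!inherits(history, "medical_history")) {
    stop("history must be a medical_history() record")
  }
  if (!is.character(patient_id) || length(patient_id) != 1L ||
      !nzchar(patient_id)) {
    stop("patient_id must be a non-empty string")
  }
  structure(list(
    patient_id = patient_id, name = name, location = location,
    age = age, gender = gender, smoker = smoker,
    sbp = sbp, dbp = dbp, bp_readings = bp_readings,
    glucose_value = glucose_value, glucose_type = glucose_type,
    tc = tc, hdl = hdl, ldl = ldl, tg = tg,
    height = height, weight = weight,
    history = history
  ), class = "risk_profile")
}

#' @export
print.risk_profile <- function(x, ...) {
  cat("<risk_profile> ", x$patient_id, ": ", x$age, "y ", x$gender,
      if (isTRUE(x$smoker)) ", smoker" else ", non-smoker", "\n", sep = "")
  bp <- effective_bp(x)
  if (!is.null(bp)) cat("  BP ", bp[1], "/", bp[2], " mmHg\n", sep = "")
  if (!is.null(x$glucose_value)) {
    cat("  glucose ", x$glucose_value, " mg/dL (", x$glucose_type, ")\n",
        sep = "")
  }
  if (!is.null(x$tc)) cat("  TC ", x$tc, " mg/dL\n", sep = "")
  invisible(x)
}

# representative (sbp, dbp) pair: summarized readings when present,
# otherwise the single stored pair; NULL when no BP at all
effective_bp <- function(profile) {
  if (!is.null(profile$bp_readings)) {
    return(summarize_bp(profile$bp_readings))
  }
  if (!is.null(profile$sbp) && !is.null(profile$dbp)) {
    return(c(sbp = profile$sbp, dbp = profile$dbp))
  }
  NULL
}

hist_flag <- function(profile, flag) isTRUE(profile$history[[flag]])

new_validation_result <- function(violations) {
  stopifnot(is.data.frame(violations))
  structure(list(valid = nrow(violations) == 0L, violations = violations),
            class = "validation_result")
}

violation_row <- function(field, value, rule) {
  data.frame(field = field,
             value = if (is.null(value)) NA_character_ else
               paste(format(value), collapse = "/"),
             rule = rule, stringsAsFactors = FALSE)
}

#' @export
print.validation_result <- function(x, ...) {
  if (x$valid) {
    cat("<validation_result> valid\n")
  } else {
    cat("<validation_result> INVALID:", nrow(x$violations), "violation(s)\n")
    print(x$violations, row.names = FALSE)
  }
  invisible(x)
}

#' Validate one acquisition step of an encounter record
#'
#' Re-creates the on-screen plausibility checks performed at the end of each
#' acquisition step: range checks on every measured value, the systolic >
#' diastolic ordering rule, and basic completeness of the step's fields.
#' Step 4 (decision support) carries no user-entered measurements and always
#' validates. The input record is never modified and validation is
#' idempotent.
#'
#' @param record A [risk_profile()].
#' @param step_id Acquisition step, integer 1-4 (1 demographics, 2 medical
#'   history, 3 risk factors, 4 decision support).
#' @param ranges Validation bounds, defaults to [validation_ranges()].
#' @return A `validation_result`: list with `valid` (logical) and
#'   `violations` (data frame with columns `field`, `value`, `rule`);
#'   `valid` is `TRUE` iff `violations` has no rows.
#' @export
#' @examples
#' p <- risk_profile(age = 50, gender = "female", smoker = FALSE,
#'                   sbp = 89, dbp = 160)
#' validate_step(p, 3)   # flags the sbp > dbp ordering rule
validate_step <- function(record, step_id, ranges = validation_ranges()) {
  if (!inherits(record, "risk_profile")) {
    stop("record must be a risk_profile", call. = FALSE)
  }
  if (!is_scalar_number(step_id) || !(step_id %in% 1:4)) {
    stop("step_id must be 1, 2, 3 or 4", call. = FALSE)
  }
  v <- data.frame(field = character(0), value = character(0),
                  rule = character(0), stringsAsFactors = FALSE)

  in_range <- function(field, value, range_name) {
    r <- ranges[[range_name]]
    if (!is_scalar_number(value)) {
      violation_row(field, value, "not a finite number")
    } else if (value < r[1] || value > r[2]) {
      violation_row(field, value,
                    sprintf("outside range [%g, %g]", r[1], r[2]))
    } else {
      NULL
    }
  }
  add <- function(x) if (!is.null(x)) v <<- rbind(v, x)

  if (step_id == 1) {
    add(in_range("age", record$age, "age"))
    if (!nzchar(record$patient_id %||% "")) {
      add(violation_row("patient_id", record$patient_id, "must be non-empty"))
    }
    if (!record$gender %in% c("male", "female")) {
      add(violation_row("gender", record$gender, "must be male or female"))
    }
  } else if (step_id == 2) {
    h <- record$history
    if (!is.null(h$target_sbp)) add(in_range("target_sbp", h$target_sbp, "sbp"))
    if (!is.null(h$target_dbp)) add(in_range("target_dbp", h$target_dbp, "dbp"))
    if (!is.null(h$target_sbp) && !is.null(h$target_dbp) &&
        is_scalar_number(h$target_sbp) && is_scalar_number(h$target_dbp) &&
        h$target_sbp <= h$target_dbp) {
      add(violation_row("target_sbp/target_dbp",
                        c(h$target_sbp, h$target_dbp), "sbp>dbp"))
    }
  } else if (step_id == 3) {
    pairs <- record$bp_readings %||%
      (if (!is.null(record$sbp) || !is.null(record$dbp)) {
        list(c(record$sbp %||% NA_real_, record$dbp %||% NA_real_))
      } else list())
    for (i in seq_along(pairs)) {
      pr <- pairs[[i]]
      lab <- if (length(pairs) > 1L) paste0("bp_reading_", i) else "bp"
      add(in_range(paste0(lab, ".sbp"), pr[1], "sbp"))
      add(in_range(paste0(lab, ".dbp"), pr[2], "dbp"))
      if (is_scalar_number(pr[1]) && is_scalar_number(pr[2]) &&
          pr[1] <= pr[2]) {
        add(violation_row(lab, pr, "sbp>dbp"))
      }
    }
    if (!is.null(record$glucose_value)) {
      add(in_range("glucose_value", record$glucose_value, "glucose"))
      if (is.null(record$glucose_type)) {
        add(violation_row("glucose_type", NULL,
                          "required when glucose_value present"))
      }
    }
    for (f in c("tc", "hdl", "ldl", "tg", "height", "weight")) {
      if (!is.null(record[[f]])) add(in_range(f, record[[f]], f))
    }
  }
  # step 4 holds tool outputs only; nothing user-entered to check
  new_validation_result(v)
}

#' Body-mass index
#'
#' BMI = weight / (height in metres)^2, reported to one decimal place.
#' Weight categorisation ([weight_status()]) is applied to the unrounded
#' value to avoid boundary artefacts.
#'
#' @param height Height in cm (> 0).
#' @param weight Weight in kg (> 0).
#' @return BMI in kg/m^2, rounded to 1 decimal.
#' @export
#' @examples
#' compute_bmi(160, 76.8)   # 30.0
compute_bmi <- function(height, weight) {
  if (!is_scalar_number(height) || height <= 0) {
    stop("height must be a positive number (cm)", call. = FALSE)
  }
  if (!is_scalar_number(weight) || weight <= 0) {
    stop("weight must be a positive number (kg)", call. = FALSE)
  }
  round(compute_bmi_raw(height, weight), 1)
}

compute_bmi_raw <- function(height, weight) weight / (height / 100)^2

#' Summarize repeated blood-pressure readings
#'
#' Reduces up to three automated readings to the single representative pair
#' fed to the risk chart: with three readings the first is discarded and the
#' last two averaged (standard screening practice, since the first reading
#' runs high); with fewer, all readings are averaged. Results are rounded to
#' the nearest integer mmHg.
#'
#' @param bp_readings List of 1-3 numeric `c(sbp, dbp)` pairs.
#' @return Named numeric `c(sbp, dbp)` in mmHg.
#' @export
#' @examples
#' summarize_bp(list(c(170, 100), c(160, 90), c(150, 80)))  # c(155, 85)
summarize_bp <- function(bp_readings) {
  if (!is.list(bp_readings) || length(bp_readings) == 0L) {
    stop("bp_readings must be a non-empty list of c(sbp, dbp) pairs",
         call. = FALSE)
  }
  if (length(bp_readings) > 3L) stop("at most three BP readings", call. = FALSE)
  m <- do.call(rbind, lapply(bp_readings, function(r) {
    r <- as.numeric(r)
    if (length(r) != 2L || any(!is.finite(r))) {
      stop("each BP reading must be a finite c(sbp, dbp) pair", call. = FALSE)
    }
    r
  }))
  use <- if (nrow(m) == 3L) m[2:3, , drop = FALSE] else m
  out <- round(colMeans(use))
  c(sbp = out[1], dbp = out[2])
}

#' Estimate age from a remembered historical event
#'
#' Participants who do not know their year of birth anchor their age to a
#' well-known event ("how old were you at Indian independence, 1947?").
#' The inferred age is `current_year - (event_year - age_at_event)`.
#'
#' @param event_year Calendar year of the event.
#' @param age_at_event Participant's age (years) at that event, >= 0.
#' @param current_year Current calendar year, >= `event_year`.
#' @return Estimated current age in years.
#' @export
#' @examples
#' estimate_age_from_event(1947, 0, 2013)   # 66
estimate_age_from_event <- function(event_year, age_at_event, current_year) {
  for (x in list(event_year, age_at_event, current_year)) {
    if (!is_scalar_number(x)) stop("all arguments must be single numbers",
                                   call. = FALSE)
  }
  if (age_at_event < 0) stop("age_at_event must be >= 0", call. = FALSE)
  if (event_year > current_year) {
    stop("event_year must not be after current_year", call. = FALSE)
  }
  birth_year <- event_year - age_at_event
  if (birth_year < 0) stop("inferred birth year is negative", call. = FALSE)
  age <- current_year - birth_year
  if (age < 0) stop("inferred age is negative", call. = FALSE)
  age
}
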