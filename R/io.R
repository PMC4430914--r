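# Serialization: nested JSON for single encounters (human-auditable),
# flat CSV for cohorts (tabular bulk).

#' Read and write encounter records as JSON
#'
#' One JSON object per participant with nested blocks mirroring the four
#' acquisition steps: `demographics` (patient_id, name, location, age,
#' gender), `medical_history` (tri-state flags, medication flags, BP
#' targets), `risk_factors` (BP readings or a single pair, glucose,
#' lipids, anthropometry, smoking status).
#'
#' @param path JSON file path.
#' @return `read_encounter()` returns a [risk_profile()];
#'   `write_encounter()` invisibly returns `path`.
#' @export
read_encounter <- function(path) {
  if (!file.exists(path)) input_error(paste0("encounter file not found: ",
                                             path))
  x <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                error = function(e) {
                  input_error(paste0("cannot parse encounter JSON: ",
                                     conditionMessage(e)))
                })
  d <- x$demographics
  h <- x$medical_history %||% list()
  r <- x$risk_factors
  if (is.null(d) || is.null(r)) {
    input_error("encounter JSON needs 'demographics' and 'risk_factors' blocks")
  }
  need <- function(block, field, where) {
    if (is.null(block[[field]])) {
      input_error(paste0("encounter field missing: ", where, ".", field))
    }
    block[[field]]
  }
  flag <- function(v) if (is.null(v)) NA else as.logical(v)
  num <- function(v) if (is.null(v)) NULL else as.numeric(v)
  readings <- if (!is.null(r$bp_readings)) {
    lapply(r$bp_readings, function(p) as.numeric(unlist(p)))
  } else NULL
  risk_profile(
    age = as.numeric(need(d, "age", "demographics")),
    gender = as.character(need(d, "gender", "demographics")),
    smoker = isTRUE(as.logical(need(r, "smoker", "risk_factors"))),
    sbp = num(r$sbp), dbp = num(r$dbp), bp_readings = readings,
    glucose_value = num(r$glucose_value),
    glucose_type = if (is.null(r$glucose_type)) NULL
                   else as.character(r$glucose_type),
    tc = num(r$tc), hdl = num(r$hdl), ldl = num(r$ldl), tg = num(r$tg),
    height = num(r$height), weight = num(r$weight),
    history = medical_history(
      past_mi_angina = flag(h$past_mi_angina),
      past_stroke = flag(h$past_stroke),
      past_pvd = flag(h$past_pvd),
      past_diabetes = flag(h$past_diabetes),
      past_hypertension = flag(h$past_hypertension),
      family_mi_angina = flag(h$family_mi_angina),
      family_stroke = flag(h$family_stroke),
      family_diabetes = flag(h$family_diabetes),
      on_bp_lowering = flag(h$on_bp_lowering),
      on_lipid_lowering = flag(h$on_lipid_lowering),
      on_antiplatelet = flag(h$on_antiplatelet),
      target_sbp = num(h$target_sbp), target_dbp = num(h$target_dbp)
    ),
    patient_id = as.character(need(d, "patient_id", "demographics")),
    name = if (is.null(d$name)) NULL else as.character(d$name),
    location = if (is.null(d$location)) NULL else as.character(d$location)
  )
}

#' @rdname read_encounter
#' @param profile A [risk_profile()].
#' @export
write_encounter <- function(profile, path) {
  stopifnot(inherits(profile, "risk_profile"))
  h <- profile$history
  drop_null <- function(x) x[!vapply(x, is.null, logical(1))]
  obj <- list(
    demographics = drop_null(list(
      patient_id = profile$patient_id, name = profile$name,
      location = profile$location, age = profile$age,
      gender = profile$gender)),
    medical_history = drop_null(list(
      past_mi_angina = h$past_mi_angina, past_stroke = h$past_stroke,
      past_pvd = h$past_pvd, past_diabetes = h$past_diabetes,
      past_hypertension = h$past_hypertension,
      family_mi_angina = h$family_mi_angina,
      family_stroke = h$family_stroke,
      family_diabetes = h$family_diabetes,
      on_bp_lowering = h$on_bp_lowering,
      on_lipid_lowering = h$on_lipid_lowering,
      on_antiplatelet = h$on_antiplatelet,
      target_sbp = h$target_sbp, target_dbp = h$target_dbp)),
    risk_factors = drop_null(list(
      smoker = profile$smoker, sbp = profile$sbp, dbp = profile$dbp,
      bp_readings = profile$bp_readings,
      glucose_value = profile$glucose_value,
      glucose_type = profile$glucose_type,
      tc = profile$tc, hdl = profile$hdl, ldl = profile$ldl,
      tg = profile$tg, height = profile$height, weight = profile$weight))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

COHORT_COLUMNS <- c("patient_id", "age", "gender", "smoker", "sbp", "dbp",
                    "glucose_value", "glucose_type", "tc", "hdl", "ldl",
                    "tg", "height", "weight", "past_mi_angina",
                    "past_stroke", "past_pvd", "past_diabetes",
                    "past_hypertension")

#' Read and write cohort tables as flat CSV
#'
#' One row per participant; columns are the flattened profile fields
#' (`patient_id`, `age`, `gender`, `smoker`, `sbp`, `dbp`,
#' `glucose_value`, `glucose_type`, lipids, `height`, `weight`, history
#' flags). Extra columns (e.g. the generator's `stratum`) round-trip
#' unchanged.
#'
#' @param path CSV file path.
#' @return `read_cohort()` returns a data frame; rows convert to profiles
#'   with [as_risk_profile()].
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) input_error(paste0("cohort file not found: ", path))
  x <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(COHORT_COLUMNS, names(x))
  if (length(missing_cols) > 0L) {
    input_error(paste0("cohort CSV missing column(s): ",
                       paste(missing_cols, collapse = ", ")))
  }
  if (nrow(x) == 0L) input_error("cohort CSV has no rows")
  x
}

#' @rdname read_cohort
#' @param cohort Cohort data frame.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}
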