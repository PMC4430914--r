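# Chart-based 10-year absolute CVD risk: five ordered bands looked up from
# categorical cells keyed by (diabetes, gender, smoker, age band, SBP band,
# and - on the high-information variant - total-cholesterol band).

AGE_BANDS <- c("40-49", "50-59", "60-69", "70+")
SBP_BANDS <- c("lt140", "140-159", "160-179", "180+")
TC_BANDS  <- c("lt5", "5-6", "6-7", "7-8", "8+")

CHART_HEADER <- c("region", "variant", "diabetes", "gender", "smoker",
                  "age_band", "sbp_band", "tc_band", "category")

#' Band a continuous input onto the chart grid
#'
#' Half-open banding, lower edge inclusive: SBP 159 falls in `140-159`,
#' 160 in `160-179`; age 49 in `40-49`, 50 in `50-59`. The topmost band is
#' closed above. Ages below 40 are the caller's concern ([assess_risk()]
#' clamps them to the lowest band with a warning flag).
#'
#' @param age Age in years (>= 40 for an in-range band).
#' @param sbp Systolic blood pressure, mmHg.
#' @param tc_mgdl Total cholesterol, mg/dL (converted internally to mmol/L
#'   with the standard divisor 38.67 before banding).
#' @return The band label used in the chart CSV dialect.
#' @export
#' @examples
#' age_band(49); age_band(50)
#' sbp_band(159); sbp_band(160)
#' tc_band(176)   # 4.55 mmol/L -> "lt5"
age_band <- function(age) {
  stopifnot(is_scalar_number(age))
  if (age < 40) stop("age below the chart range; clamp before banding",
                     call. = FALSE)
  AGE_BANDS[findInterval(age, c(40, 50, 60, 70))]
}

#' @rdname age_band
#' @export
sbp_band <- function(sbp) {
  stopifnot(is_scalar_number(sbp))
  SBP_BANDS[findInterval(sbp, c(-Inf, 140, 160, 180))]
}

#' @rdname age_band
#' @export
tc_band <- function(tc_mgdl) {
  stopifnot(is_scalar_number(tc_mgdl))
  mmol <- tc_mgdl / MGDL_PER_MMOL_TC
  TC_BANDS[findInterval(mmol, c(-Inf, 5, 6, 7, 8))]
}

# the full cell grid a chart of the given variant must cover
chart_grid <- function(variant) {
  g <- expand.grid(
    diabetes = c(FALSE, TRUE), gender = c("female", "male"),
    smoker = c(FALSE, TRUE), age_band = AGE_BANDS, sbp_band = SBP_BANDS,
    tc_band = if (variant == "HI") TC_BANDS else "NA",
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  g[order(g$diabetes, g$gender, g$smoker,
          match(g$age_band, AGE_BANDS), match(g$sbp_band, SBP_BANDS),
          match(g$tc_band, TC_BANDS)), , drop = FALSE]
}

cell_key <- function(diabetes, gender, smoker, age_band, sbp_band, tc_band) {
  paste(as.logical(diabetes), gender, as.logical(smoker),
        age_band, sbp_band, tc_band, sep = "|")
}

new_chart <- function(region, variant, cells) {
  lookup <- setNames(
    as.character(cells$category),
    cell_key(cells$diabetes, cells$gender, cells$smoker,
             cells$age_band, cells$sbp_band, cells$tc_band)
  )
  structure(list(region = region, variant = variant, cells = cells,
                 lookup = lookup),
            class = "cvd_chart")
}

#' @export
print.cvd_chart <- function(x, ...) {
  cat("<cvd_chart> region '", x$region, "', variant ", x$variant, ", ",
      nrow(x$cells), " cells\n", sep = "")
  print(table(band = x$cells$category))
  invisible(x)
}

#' Load a risk chart from CSV
#'
#' Reads a chart in the documented dialect (header
#' `region,variant,diabetes,gender,smoker,age_band,sbp_band,tc_band,category`)
#' and checks it is a total mapping over its band grid: every combination of
#' diabetes status, gender, smoking status, age band, SBP band (and TC band
#' on HI charts) must appear exactly once. Low-information (LI) charts must
#' carry the literal `tc_band` value `NA` in every row. Missing cells,
#' duplicate cells and unknown labels are load failures naming the offending
#' cell or row.
#'
#' @param path CSV file path.
#' @return A `cvd_chart` object.
#' @seealso [synthetic_chart()] for the fixture charts shipped with the
#'   package, [write_chart()] for the writer.
#' @export
load_chart <- function(path) {
  if (!file.exists(path)) input_error(paste0("chart file not found: ", path))
  raw <- read.csv(path, colClasses = "character", na.strings = "",
                  check.names = FALSE)
  if (!identical(names(raw), CHART_HEADER)) {
    input_error(paste0("chart header must be exactly: ",
                       paste(CHART_HEADER, collapse = ",")))
  }
  if (nrow(raw) == 0L) input_error("chart file has no rows")

  check_labels <- function(col, allowed) {
    bad <- which(!raw[[col]] %in% allowed)
    if (length(bad) > 0L) {
      input_error(sprintf(
        "chart row %d: unknown %s label '%s'", bad[1] + 1L, col,
        raw[[col]][bad[1]]))
    }
  }
  check_labels("variant", c("LI", "HI"))
  check_labels("diabetes", c("TRUE", "FALSE"))
  check_labels("smoker", c("TRUE", "FALSE"))
  check_labels("gender", c("male", "female"))
  check_labels("age_band", AGE_BANDS)
  check_labels("sbp_band", SBP_BANDS)
  check_labels("tc_band", c(TC_BANDS, "NA"))
  check_labels("category", RISK_BANDS)

  variant <- unique(raw$variant)
  if (length(variant) != 1L) input_error("chart mixes LI and HI rows")
  region <- unique(raw$region)
  if (length(region) != 1L) input_error("chart mixes region labels")
  if (variant == "LI" && any(raw$tc_band != "NA")) {
    input_error("LI chart rows must all have tc_band = NA")
  }
  if (variant == "HI" && any(raw$tc_band == "NA")) {
    input_error("HI chart rows must all carry a TC band")
  }

  cells <- data.frame(
    diabetes = raw$diabetes == "TRUE", gender = raw$gender,
    smoker = raw$smoker == "TRUE", age_band = raw$age_band,
    sbp_band = raw$sbp_band, tc_band = raw$tc_band,
    category = raw$category, stringsAsFactors = FALSE
  )
  keys <- cell_key(cells$diabetes, cells$gender, cells$smoker,
                   cells$age_band, cells$sbp_band, cells$tc_band)
  dup <- which(duplicated(keys))
  if (length(dup) > 0L) {
    input_error(paste0("duplicate chart cell: ", keys[dup[1]],
                       " (row ", dup[1] + 1L, ")"))
  }
  grid <- chart_grid(variant)
  grid_keys <- cell_key(grid$diabetes, grid$gender, grid$smoker,
                        grid$age_band, grid$sbp_band, grid$tc_band)
  missing <- setdiff(grid_keys, keys)
  if (length(missing) > 0L) {
    input_error(paste0("chart is not total: missing cell ", missing[1],
                       if (length(missing) > 1L)
                         paste0(" (and ", length(missing) - 1L, " more)")))
  }
  new_chart(region, variant, cells)
}

#' @rdname load_chart
#' @param chart A `cvd_chart` object.
#' @export
write_chart <- function(chart, path) {
  stopifnot(inherits(chart, "cvd_chart"))
  out <- cbind(region = chart$region, variant = chart$variant,
               chart$cells)
  out$diabetes <- ifelse(out$diabetes, "TRUE", "FALSE")
  out$smoker <- ifelse(out$smoker, "TRUE", "FALSE")
  write.csv(out[, CHART_HEADER], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Synthetic fixture risk chart
#'
#' Builds a complete, clearly synthetic chart for tests, examples and the
#' shipped default configuration. The cell values are NOT transcribed from
#' any published chart: each cell's band is derived from an additive score
#' over the cell's factors (monotone in SBP band, age band, TC band,
#' diabetes, smoking and male gender), so risk is monotone non-decreasing in
#' every input. The HI scoring is arranged so that a diabetic male smoker in
#' the lowest age band with SBP 160-179 and TC < 5 mmol/L sits in the top
#' (>= 40%) band while the same cell one SBP band lower sits in 20-<30% --
#' the transition the counterfactual risk meter illustrates. Users with
#' access to a published chart can transcribe it into the CSV dialect and
#' load it with [load_chart()] instead.
#'
#' @param variant `"LI"` (no cholesterol dimension) or `"HI"`.
#' @param region Region label stored in the chart metadata.
#' @return A `cvd_chart`.
#' @export
#' @examples
#' synthetic_chart("HI")
synthetic_chart <- function(variant = c("HI", "LI"),
                            region = "synthetic") {
  variant <- match.arg(variant)
  cells <- chart_grid(variant)
  score <- 2L * (match(cells$sbp_band, SBP_BANDS) - 1L) +
    (match(cells$age_band, AGE_BANDS) - 1L) +
    2L * cells$diabetes + cells$smoker + (cells$gender == "male")
  if (variant == "HI") {
    score <- score + (match(cells$tc_band, TC_BANDS) - 1L)
    cuts <- c(5, 6, 7, 8)
  } else {
    cuts <- c(4, 5, 6, 7)
  }
  cells$category <- RISK_BANDS[findInterval(score, cuts) + 1L]
  new_chart(region, variant, cells)
}

#' Assess 10-year absolute CVD risk from the charts
#'
#' Looks the profile up on the high-information (HI) chart when total
#' cholesterol is present, otherwise on the low-information (LI) chart.
#' Continuous inputs are banded half-open ([age_band()], [sbp_band()],
#' [tc_band()]); the SBP fed to the chart is the [summarize_bp()] output
#' when repeated readings are stored. Diabetes status is resolved by
#' [diabetes_status()]. Ages below the lowest chart band are clamped to it
#' and the result carries the warning flag `"age_below_chart_range"`.
#'
#' @param profile A validated [risk_profile()].
#' @param chart_li,chart_hi `cvd_chart` objects of the matching variant.
#' @return A `risk_assessment`: list with `band` (ordered factor over the
#'   five chart bands), `variant` (`"LI"`/`"HI"`), `warnings` (character),
#'   and `inputs` (the banded values used).
#' @export
#' @examples
#' p <- risk_profile(age = 33, gender = "male", smoker = TRUE,
#'                   sbp = 160, dbp = 89, tc = 176,
#'                   history = medical_history(past_diabetes = TRUE))
#' assess_risk(p, synthetic_chart("LI"), synthetic_chart("HI"))
assess_risk <- function(profile, chart_li, chart_hi) {
  stopifnot(inherits(profile, "risk_profile"),
            inherits(chart_li, "cvd_chart"),
            inherits(chart_hi, "cvd_chart"))
  if (chart_li$variant != "LI" || chart_hi$variant != "HI") {
    stop("chart_li/chart_hi must have variants LI and HI", call. = FALSE)
  }
  warnings <- character(0)

  bp <- effective_bp(profile)
  if (is.null(bp)) stop("profile has no blood pressure", call. = FALSE)

  age <- profile$age
  if (age < 40) {
    age <- 40
    warnings <- c(warnings, "age_below_chart_range")
  }

  tc_present <- !is.null(profile$tc) && !is.na(profile$tc)
  chart <- if (tc_present) chart_hi else chart_li
  tcb <- if (tc_present) tc_band(profile$tc) else "NA"

  key <- cell_key(diabetes_status(profile), profile$gender,
                  isTRUE(profile$smoker), age_band(age), sbp_band(bp[["sbp"]]),
                  tcb)
  band <- unname(chart$lookup[key])
  if (is.na(band)) stop("chart has no cell for key ", key, call. = FALSE)

  structure(list(
    band = risk_band(band), variant = chart$variant, warnings = warnings,
    inputs = list(diabetes = diabetes_status(profile),
                  gender = profile$gender, smoker = isTRUE(profile$smoker),
                  age_band = age_band(age), sbp_band = sbp_band(bp[["sbp"]]),
                  tc_band = tcb, sbp = unname(bp[["sbp"]]))
  ), class = "risk_assessment")
}

#' @export
print.risk_assessment <- function(x, ...) {
  labels <- c(R0_10 = "<10%", R10_20 = "10 to <20%", R20_30 = "20 to <30%",
              R30_40 = "30 to <40%", R40_PLUS = ">=40%")
  cat("<risk_assessment> 10-year CVD risk ", labels[[as.character(x$band)]],
      " [", as.character(x$band), "], ", x$variant, " chart\n", sep = "")
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = ", "),
                              "\n")
  invisible(x)
}

#' Counterfactual risk projection
#'
#' Re-assesses a profile after hypothetical risk-factor changes, the
#' computation behind a "what if" risk projection display (e.g. the band
#' reached if the participant lowered systolic pressure by 10 mmHg). The
#' input profile is never modified.
#'
#' Modifications are a named list over `sbp`, `tc` (numeric values are
#' additive deltas in the profile's units), `sbp_to`, `tc_to` (absolute
#' replacements), and `smoker`, `diabetes` (logical replacements; `diabetes`
#' overrides the resolved [diabetes_status()]).
#'
#' @param profile A [risk_profile()].
#' @param modifications Named list of deltas/replacements (may be empty).
#' @param chart_li,chart_hi Charts as in [assess_risk()].
#' @return List with elements `before` and `after`, both `risk_assessment`s.
#' @export
#' @examples
#' p <- risk_profile(age = 33, gender = "male", smoker = TRUE,
#'                   sbp = 160, dbp = 89, tc = 176,
#'                   history = medical_history(past_diabetes = TRUE))
#' project_risk(p, list(sbp = -10), synthetic_chart("LI"), synthetic_chart("HI"))
project_risk <- function(profile, modifications, chart_li, chart_hi) {
  stopifnot(inherits(profile, "risk_profile"))
  if (length(modifications) > 0 &&
      (is.null(names(modifications)) || any(!nzchar(names(modifications))))) {
    stop("modifications must be a named list", call. = FALSE)
  }
  allowed <- c("sbp", "tc", "sbp_to", "tc_to", "smoker", "diabetes")
  bad <- setdiff(names(modifications), allowed)
  if (length(bad) > 0L) {
    stop("unknown modification(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  before <- assess_risk(profile, chart_li, chart_hi)

  mod <- profile
  apply_sbp <- function(new_sbp) {
    if (!is_scalar_number(new_sbp) || new_sbp <= 0) {
      stop("modification produces invalid SBP: ", new_sbp, call. = FALSE)
    }
    # shift readings by the same amount so the summarized value moves too
    if (!is.null(mod$bp_readings)) {
      shift <- new_sbp - effective_bp(profile)[["sbp"]]
      mod$bp_readings <<- lapply(mod$bp_readings,
                                 function(r) c(r[1] + shift, r[2]))
    } else {
      mod$sbp <<- new_sbp
    }
  }
  for (nm in names(modifications)) {
    val <- modifications[[nm]]
    switch(nm,
      sbp = apply_sbp(effective_bp(profile)[["sbp"]] + val),
      sbp_to = apply_sbp(val),
      tc = {
        if (is.null(mod$tc)) stop("cannot apply a TC delta: profile has no TC",
                                  call. = FALSE)
        mod$tc <- mod$tc + val
      },
      tc_to = mod$tc <- val,
      smoker = {
        if (!is.logical(val) || is.na(val)) stop("smoker must be TRUE/FALSE",
                                                 call. = FALSE)
        mod$smoker <- val
      },
      diabetes = {
        if (!is.logical(val) || is.na(val)) stop("diabetes must be TRUE/FALSE",
                                                 call. = FALSE)
        mod$diabetes_override <- val
      }
    )
  }
  if (!is.null(mod$tc) && (!is_scalar_number(mod$tc) || mod$tc <= 0)) {
    stop("modification produces invalid TC: ", mod$tc, call. = FALSE)
  }
  after <- assess_risk(mod, chart_li, chart_hi)
  list(before = before, after = after)
}
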