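# Seeded generators for screening cohorts, per-worker click-event streams
# and glucometer memories. These emulate the statistical structure the
# analytics assume: a bimodal (low/high) risk distribution, right-skewed
# lognormal step times with a learning-curve decay, logistic Bluetooth
# adoption, partial dissemination of the management sections, and
# occasional digit transcription/transposition errors in glucose entry.

#' Parameters for a synthetic screening cohort
#'
#' Defaults emulate a rural door-to-door screening population: adults aged
#' 40+ (mean 51.4, SD 13.1 years), and a two-component mixture in which a
#' `high_fraction` stratum carries elevated blood pressure, cholesterol,
#' diabetes and prior CVD so that about a third of participants end up in
#' the high-risk management tier (>= 30% band, clinically high risk, or
#' past CVD) under the shipped synthetic charts, and the remainder are
#' low-risk with a sizeable impaired-fasting-glucose subgroup (so just
#' over half of all participants meet a referral condition).
#'
#' @param n Number of participants (>= 1).
#' @param seed Mandatory integer seed.
#' @param high_fraction Target fraction assigned to the high-risk stratum.
#' @param age_mean,age_sd,age_min Age distribution (years); draws are
#'   truncated at `age_min`.
#' @param smoking_prev,diabetes_hist_prev,htn_hist_prev,cvd_hist_prev,
#'   ifg_prev Named `c(low = , high = )` per-stratum prevalences.
#' @return List of class `cohort_params`.
#' @export
cohort_params <- function(n, seed, high_fraction = 0.34,
                          age_mean = 51.4, age_sd = 13.1, age_min = 40,
                          smoking_prev = c(low = 0.15, high = 0.50),
                          diabetes_hist_prev = c(low = 0.04, high = 0.35),
                          htn_hist_prev = c(low = 0.08, high = 0.50),
                          cvd_hist_prev = c(low = 0.00, high = 0.15),
                          ifg_prev = c(low = 0.30, high = 0.20)) {
  if (!is_scalar_number(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  if (missing(seed) || !is_scalar_number(seed)) {
    input_error("cohort_params requires an explicit integer seed")
  }
  for (p in list(high_fraction, smoking_prev, diabetes_hist_prev,
                 htn_hist_prev, cvd_hist_prev, ifg_prev)) {
    if (any(p < 0 | p > 1)) stop("prevalences must lie in [0, 1]",
                                 call. = FALSE)
  }
  structure(list(
    n = as.integer(n), seed = as.integer(seed),
    high_fraction = high_fraction,
    age_mean = age_mean, age_sd = age_sd, age_min = age_min,
    smoking_prev = smoking_prev, diabetes_hist_prev = diabetes_hist_prev,
    htn_hist_prev = htn_hist_prev, cvd_hist_prev = cvd_hist_prev,
    ifg_prev = ifg_prev
  ), class = "cohort_params")
}

rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  tries <- 0L
  while (length(bad) > 0L && tries < 100L) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x < lower | x > upper)
    tries <- tries + 1L
  }
  pmin(pmax(x, lower), upper)
}

#' Generate a synthetic screening cohort
#'
#' Draws `params$n` participants from the two-stratum mixture described in
#' [cohort_params()]. When charts are supplied (the shipped synthetic
#' fixtures by default) the achieved fraction of participants who are
#' high-band, clinically high risk or have prior CVD is checked against
#' `params$high_fraction`; if it is off by more than 5 percentage points
#' the cohort is redrawn (bounded retries), and a warning reporting the
#' achieved fraction is issued if the target remains unreachable.
#' Fully reproducible: the same params (including seed) give the same
#' cohort.
#'
#' @param params A [cohort_params()] object.
#' @param chart_li,chart_hi Charts used for the target-fraction check;
#'   `NULL` skips the check.
#' @return Data frame, one row per participant, with every
#'   [risk_profile()] field plus the true stratum; attribute
#'   `achieved_high_fraction`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_params(n = 50, seed = 1))
generate_cohort <- function(params,
                            chart_li = synthetic_chart("LI"),
                            chart_hi = synthetic_chart("HI")) {
  stopifnot(inherits(params, "cohort_params"))
  max_tries <- 5L
  for (attempt in seq_len(max_tries)) {
    cohort <- withr::with_seed(params$seed + (attempt - 1L) * 1000L,
                               draw_cohort(params))
    if (is.null(chart_li) || is.null(chart_hi)) {
      attr(cohort, "achieved_high_fraction") <- NA_real_
      return(cohort)
    }
    achieved <- mean(vapply(seq_len(nrow(cohort)), function(i) {
      p <- as_risk_profile(cohort[i, ])
      band <- assess_risk(p, chart_li, chart_hi)$band
      band >= "R30_40" || clinically_high_risk(p) ||
        hist_flag(p, "past_mi_angina") || hist_flag(p, "past_stroke") ||
        hist_flag(p, "past_pvd")
    }, logical(1)))
    if (abs(achieved - params$high_fraction) <= 0.05) {
      attr(cohort, "achieved_high_fraction") <- achieved
      return(cohort)
    }
  }
  warning(sprintf(
    "target high-risk fraction %.2f not reached after %d draws; achieved %.2f",
    params$high_fraction, max_tries, achieved))
  attr(cohort, "achieved_high_fraction") <- achieved
  cohort
}

draw_cohort <- function(params) {
  n <- params$n
  stratum <- ifelse(rbinom(n, 1, params$high_fraction) == 1, "high", "low")
  s <- function(prev) ifelse(stratum == "high", prev[["high"]], prev[["low"]])
  hi <- stratum == "high"

  age <- round(rtrunc_norm(n, params$age_mean, params$age_sd,
                           params$age_min, 95))
  gender <- ifelse(runif(n) < 0.55, "female", "male")
  smoker <- runif(n) < s(params$smoking_prev)
  past_diabetes <- runif(n) < s(params$diabetes_hist_prev)
  past_htn <- runif(n) < s(params$htn_hist_prev)
  past_cvd <- runif(n) < s(params$cvd_hist_prev)
  # split a prior-CVD participant's event type
  cvd_kind <- sample(c("mi", "stroke", "pvd"), n, replace = TRUE)

  sbp <- ifelse(hi, rtrunc_norm(n, 172, 12, 150, 230),
                rtrunc_norm(n, 122, 9, 95, 150))
  dbp <- pmin(pmax(round(0.6 * sbp + rnorm(n, 0, 5)), 50), sbp - 15)
  dbp <- ifelse(hi, pmin(dbp, 130), pmin(dbp, 92))

  tc <- ifelse(hi, rtrunc_norm(n, 235, 35, 150, 345),
               rtrunc_norm(n, 180, 25, 120, 260))
  hdl <- rtrunc_norm(n, 46, 8, 25, 90)
  ldl <- pmax(tc - hdl - rtrunc_norm(n, 60, 15, 30, 120), 30)
  tg <- rtrunc_norm(n, 140, 45, 50, 400)

  ifg_draw <- runif(n) < s(params$ifg_prev)
  glucose <- ifelse(
    past_diabetes, rtrunc_norm(n, 160, 35, 90, 400),
    ifelse(ifg_draw, runif(n, 110, 125.9),
           ifelse(hi, rtrunc_norm(n, 100, 10, 70, 124),
                  rtrunc_norm(n, 95, 8, 70, 109))))

  height <- ifelse(gender == "male", rtrunc_norm(n, 165, 7, 145, 190),
                   rtrunc_norm(n, 152, 6, 135, 180))
  bmi <- ifelse(hi, rtrunc_norm(n, 26, 4, 16, 42),
                rtrunc_norm(n, 23.5, 3.5, 16, 38))
  weight <- round(bmi * (height / 100)^2, 1)

  data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    age = age, gender = gender, smoker = smoker,
    sbp = round(sbp), dbp = dbp,
    glucose_value = round(glucose), glucose_type = "fasting",
    tc = round(tc), hdl = round(hdl), ldl = round(ldl), tg = round(tg),
    height = round(height), weight = weight,
    past_mi_angina = past_cvd & cvd_kind == "mi",
    past_stroke = past_cvd & cvd_kind == "stroke",
    past_pvd = past_cvd & cvd_kind == "pvd",
    past_diabetes = past_diabetes, past_hypertension = past_htn,
    stratum = stratum,
    stringsAsFactors = FALSE
  )
}

#' Build a risk profile from a cohort row
#'
#' @param row One-row data frame (or list) with the cohort column layout.
#' @return A [risk_profile()].
#' @export
as_risk_profile <- function(row) {
  row <- as.list(row)
  num_or_null <- function(x) {
    if (is.null(x) || length(x) == 0L || is.na(x)) NULL else as.numeric(x)
  }
  chr_or_null <- function(x) {
    if (is.null(x) || length(x) == 0L || is.na(x) || !nzchar(x)) NULL
    else as.character(x)
  }
  flag <- function(x) if (is.null(x)) NA else as.logical(x)
  risk_profile(
    age = as.numeric(row$age), gender = as.character(row$gender),
    smoker = isTRUE(as.logical(row$smoker)),
    sbp = num_or_null(row$sbp), dbp = num_or_null(row$dbp),
    glucose_value = num_or_null(row$glucose_value),
    glucose_type = chr_or_null(row$glucose_type),
    tc = num_or_null(row$tc), hdl = num_or_null(row$hdl),
    ldl = num_or_null(row$ldl), tg = num_or_null(row$tg),
    height = num_or_null(row$height), weight = num_or_null(row$weight),
    history = medical_history(
      past_mi_angina = flag(row$past_mi_angina),
      past_stroke = flag(row$past_stroke),
      past_pvd = flag(row$past_pvd),
      past_diabetes = flag(row$past_diabetes),
      past_hypertension = flag(row$past_hypertension)
    ),
    patient_id = as.character(row$patient_id %||% "anon")
  )
}

#' Behavioural profile of a synthetic field worker
#'
#' Drives [generate_event_stream()]. Baseline per-step time medians are
#' start-of-study values; the defaults are the observed study-wide field
#' medians (157/68/633/90 s for demographics, medical history, risk-factor
#' acquisition, decision support) inflated by the mid-study learning factor
#' `1 / 0.97^10`, so that with the default decay a ~20-procedure study has
#' study-wide medians near the observed ones. Per-step lognormal spreads
#' are chosen to reproduce the wide observed IQRs. Learning is a geometric
#' decay of every duration median per procedure performed.
#' Bluetooth adoption follows a logistic curve in the procedure index;
#' management-section visits are independent Bernoulli draws; manual
#' glucose entry is corrupted (digit transposition or single-digit slip)
#' with probability `glucose_error_prob`.
#'
#' @param worker_id Worker label.
#' @param n_procedures Number of procedures to generate (>= 1).
#' @param seed Mandatory integer seed.
#' @param step_median_s Baseline step-time medians, seconds (length 4).
#' @param step_sdlog Lognormal sdlog per step (length 4).
#' @param learning_decay Multiplicative decay of duration medians per
#'   procedure, in (0, 1].
#' @param bt_intercept,bt_slope Logit-scale intercept/slope of the
#'   Bluetooth adoption probability at procedure index k:
#'   `plogis(bt_intercept + bt_slope * k)`.
#' @param section_probs Named probabilities for `risk_meter`,
#'   `recommendations`, `next_visit` visits.
#' @param glucose_error_prob Probability a manual glucose entry is
#'   corrupted.
#' @param likert_probs Probabilities of ratings 1-4 (sums to 1).
#' @param bp_bt_median_s,bp_manual_median_s Median BP acquisition span via
#'   Bluetooth / manual entry, seconds.
#' @param start_time POSIXct of the first procedure; one procedure per day.
#' @return List of class `worker_profile`.
#' @export
worker_profile <- function(worker_id, n_procedures, seed,
                           step_median_s = c(213, 92, 859, 122),
                           step_sdlog = c(0.63, 0.95, 0.77, 0.87),
                           learning_decay = 0.97,
                           bt_intercept = -1.5, bt_slope = 0.15,
                           section_probs = c(risk_meter = 0.79,
                                             recommendations = 0.90,
                                             next_visit = 0.90),
                           glucose_error_prob = 0.06,
                           likert_probs = c(0, 0, 0.28, 0.72),
                           bp_bt_median_s = 434, bp_manual_median_s = 638,
                           start_time = as.POSIXct("2013-05-01 09:00:00",
                                                   tz = "UTC")) {
  if (missing(seed) || !is_scalar_number(seed)) {
    input_error("worker_profile requires an explicit integer seed")
  }
  if (!is_scalar_number(n_procedures) || n_procedures < 1) {
    stop("n_procedures must be >= 1", call. = FALSE)
  }
  if (learning_decay <= 0 || learning_decay > 1) {
    stop("learning_decay must be in (0, 1]", call. = FALSE)
  }
  stopifnot(length(step_median_s) == 4L, length(step_sdlog) == 4L,
            all(step_median_s > 0), all(step_sdlog >= 0))
  if (any(section_probs < 0 | section_probs > 1) ||
      !all(c("risk_meter", "recommendations", "next_visit") %in%
             names(section_probs))) {
    stop("section_probs must name risk_meter/recommendations/next_visit in [0,1]",
         call. = FALSE)
  }
  if (glucose_error_prob < 0 || glucose_error_prob > 1) {
    stop("glucose_error_prob must be in [0, 1]", call. = FALSE)
  }
  if (length(likert_probs) != 4L || abs(sum(likert_probs) - 1) > 1e-8) {
    stop("likert_probs must be 4 probabilities summing to 1", call. = FALSE)
  }
  structure(list(
    worker_id = as.character(worker_id),
    n_procedures = as.integer(n_procedures), seed = as.integer(seed),
    step_median_s = step_median_s, step_sdlog = step_sdlog,
    learning_decay = learning_decay,
    bt_intercept = bt_intercept, bt_slope = bt_slope,
    section_probs = section_probs,
    glucose_error_prob = glucose_error_prob, likert_probs = likert_probs,
    bp_bt_median_s = bp_bt_median_s, bp_manual_median_s = bp_manual_median_s,
    start_time = start_time
  ), class = "worker_profile")
}

# corrupt an integer glucose value: transpose two adjacent digits or slip
# one digit by +/- 1..5; always returns a different positive value
corrupt_glucose <- function(value) {
  digits <- strsplit(as.character(round(value)), "")[[1]]
  for (try in 1:20) {
    d <- digits
    transposable <- length(d) >= 2L
    if (transposable && runif(1) < 0.5) {
      pos <- sample.int(length(d) - 1L, 1L)
      d[c(pos, pos + 1L)] <- d[c(pos + 1L, pos)]
    } else {
      pos <- sample.int(length(d), 1L)
      slip <- sample(1:5, 1L) * sample(c(-1L, 1L), 1L)
      d[pos] <- as.character(max(0L, min(9L, as.integer(d[pos]) + slip)))
    }
    out <- as.integer(paste(d, collapse = ""))
    if (!is.na(out) && out != round(value) && out > 0 && d[1] != "0") {
      return(out)
    }
  }
  round(value) + 10L
}

#' Generate a per-worker click-event stream
#'
#' Emits a well-formed event log for `worker$n_procedures` sequential
#' procedures (one per day), screening successive participants of the
#' cohort slice: step 1-4 open/complete event pairs with lognormal
#' durations whose medians decay geometrically with the procedure index,
#' a BP sub-step using Bluetooth with the adoption-curve probability
#' (shorter acquisition) or manual entry (three readings, longer), one
#' manual glucose entry per procedure (corrupted with the configured
#' probability; the true value is the participant's cohort glucose),
#' management-section visit events per the section probabilities, and one
#' Likert rating. Ground-truth parameters and per-procedure outcomes are
#' returned alongside the events. Byte-identical across runs for the same
#' worker profile (seed included).
#'
#' @param worker A [worker_profile()].
#' @param cohort Cohort data frame with at least `worker$n_procedures` rows
#'   ([generate_cohort()]).
#' @return List of class `event_stream`: `events` (event-log data frame),
#'   `truth` (per-procedure data frame: durations, bluetooth, sections,
#'   `glucose_true`, `glucose_entered`, `corrupted`, `likert`), `worker`.
#' @export
generate_event_stream <- function(worker, cohort) {
  stopifnot(inherits(worker, "worker_profile"), is.data.frame(cohort))
  if (nrow(cohort) < worker$n_procedures) {
    stop("cohort slice smaller than n_procedures", call. = FALSE)
  }
  withr::with_seed(worker$seed, {
    # flat accumulators (one data.frame build at the end keeps this fast
    # for long streams)
    acc <- new.env(parent = emptyenv())
    acc$t <- numeric(0)
    acc$enc <- character(0)
    acc$step <- integer(0)
    acc$element <- character(0)
    acc$value <- character(0)
    truth <- list()
    enc_id <- NULL
    emit <- function(t, step, element, value = NA_character_) {
      n <- length(acc$t) + 1L
      acc$t[n] <- as.numeric(t)
      acc$enc[n] <- enc_id
      acc$step[n] <- step
      acc$element[n] <- element
      acc$value[n] <- value
      t
    }
    rl <- function(median_s, sdlog) {
      max(round(rlnorm(1, meanlog = log(median_s), sdlog = sdlog)), 2)
    }
    for (k in seq_len(worker$n_procedures)) {
      lk <- worker$learning_decay^(k - 1)
      enc_id <- sprintf("%s-E%03d", worker$worker_id, k)
      participant <- cohort[k, ]
      t <- worker$start_time + (k - 1) * 86400

      # steps 1 and 2: open -> complete
      d1 <- rl(worker$step_median_s[1] * lk, worker$step_sdlog[1])
      emit(t, 1L, "step_open")
      t <- emit(t + d1, 1L, "step_complete")
      t <- t + rl(20 * lk, 0.4)
      d2 <- rl(worker$step_median_s[2] * lk, worker$step_sdlog[2])
      emit(t, 2L, "step_open")
      t <- emit(t + d2, 2L, "step_complete")
      t <- t + rl(20 * lk, 0.4)

      # step 3: BP sub-step, glucose entry, remaining risk factors
      t3_open <- emit(t, 3L, "step_open")
      p_bt <- plogis(worker$bt_intercept + worker$bt_slope * k)
      bluetooth <- runif(1) < p_bt
      bp_start <- emit(t3_open + rl(10 * lk, 0.3), 3L, "bp_start")
      if (bluetooth) {
        bp_dur <- rl(worker$bp_bt_median_s * lk, 0.5)
        emit(bp_start + bp_dur - 1, 3L, "bp_bluetooth_receive")
      } else {
        bp_dur <- rl(worker$bp_manual_median_s * lk, 0.5)
        for (m in 1:3) emit(bp_start + round(m * bp_dur / 3) - 1, 3L,
                            "bp_manual_entry")
      }
      bp_done <- emit(bp_start + bp_dur, 3L, "bp_done")
      g_true <- as.numeric(participant$glucose_value)
      corrupted <- runif(1) < worker$glucose_error_prob
      g_entered <- if (corrupted) corrupt_glucose(g_true) else round(g_true)
      t_gluc <- emit(bp_done + rl(90 * lk, 0.5), 3L, "glucose_entry",
                     value = as.character(g_entered))
      t <- emit(t_gluc + rl(150 * lk, 0.6), 3L, "step_complete")
      t <- t + rl(20 * lk, 0.4)

      # step 4: management sections, Likert, completion
      t4_open <- emit(t, 4L, "step_open")
      t <- t4_open
      visited <- c(risk_meter = FALSE, recommendations = FALSE,
                   next_visit = FALSE)
      section_elements <- c(risk_meter = "riskmeter_open",
                            recommendations = "recs_open",
                            next_visit = "nextvisit_open")
      for (s in names(section_elements)) {
        if (runif(1) < worker$section_probs[[s]]) {
          visited[[s]] <- TRUE
          t <- emit(t + rl(25 * lk, 0.5), 4L, section_elements[[s]])
        }
      }
      likert <- sample(1:4, 1L, prob = worker$likert_probs)
      t <- emit(t + rl(15 * lk, 0.4), 4L, "likert_rating",
                value = as.character(likert))
      t_end <- emit(t + rl(10 * lk, 0.4), 4L, "step_complete")

      truth[[k]] <- data.frame(
        k = k, encounter_id = enc_id, user_id = worker$worker_id,
        total_s = as.numeric(t_end) -
          as.numeric(worker$start_time + (k - 1) * 86400),
        bluetooth = bluetooth, bp_s = as.numeric(bp_done) -
          as.numeric(bp_start),
        risk_meter = visited[["risk_meter"]],
        recommendations = visited[["recommendations"]],
        next_visit = visited[["next_visit"]],
        glucose_true = round(g_true), glucose_entered = g_entered,
        glucose_time = t_gluc, corrupted = corrupted, likert = likert,
        stringsAsFactors = FALSE
      )
    }
    events <- data.frame(
      timestamp = as.POSIXct(acc$t, origin = "1970-01-01", tz = "UTC"),
      user_id = worker$worker_id, encounter_id = acc$enc,
      step = acc$step, element_id = acc$element, value = acc$value,
      stringsAsFactors = FALSE
    )
    events <- events[order(events$timestamp), , drop = FALSE]
    rownames(events) <- NULL
    truth <- do.call(rbind, truth)
    rownames(truth) <- NULL
    structure(list(events = events, truth = truth, worker = worker),
              class = "event_stream")
  })
}

#' Generate the glucometer memory for an event stream
#'
#' One meter record per glucose measurement, at the true (uncorrupted)
#' value, timestamped shortly before the corresponding manual entry (the
#' measurement precedes the transcription), hence inside the procedure
#' window. Deterministic given the stream.
#'
#' @param stream An `event_stream` from [generate_event_stream()].
#' @return Data frame with `timestamp` (POSIXct) and `glucose_mgdl`.
#' @export
generate_glucometer_memory <- function(stream) {
  stopifnot(inherits(stream, "event_stream"))
  truth <- stream$truth
  if (is.null(truth) || nrow(truth) == 0L) {
    return(data.frame(timestamp = as.POSIXct(character(0), tz = "UTC"),
                      glucose_mgdl = numeric(0)))
  }
  data.frame(timestamp = truth$glucose_time - 90,
             glucose_mgdl = truth$glucose_true)
}

#' @rdname generate_glucometer_memory
#' @param meter Data frame with `timestamp`, `glucose_mgdl`.
#' @param path CSV path.
#' @export
write_glucometer_csv <- function(meter, path) {
  out <- data.frame(timestamp = format_ts(meter$timestamp),
                    glucose_mgdl = meter$glucose_mgdl)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname generate_glucometer_memory
#' @export
read_glucometer_csv <- function(path) {
  if (!file.exists(path)) input_error(paste0("glucometer file not found: ",
                                             path))
  raw <- read.csv(path, colClasses = "character", na.strings = "")
  if (!identical(names(raw), c("timestamp", "glucose_mgdl"))) {
    input_error("glucometer CSV must have header timestamp,glucose_mgdl")
  }
  ts <- parse_ts(raw$timestamp)
  if (any(is.na(ts))) input_error("glucometer CSV has unparseable timestamps")
  data.frame(timestamp = ts, glucose_mgdl = as.numeric(raw$glucose_mgdl))
}

#' Deterministic demonstration field log
#'
#' Builds an event log for three archetypal workers with fixed
#' per-procedure outcomes chosen to reproduce a published-style usage
#' table: worker `npB1` performs 28 procedures (Bluetooth in 17; risk
#' meter / recommendations / next visit opened in 22 / 27 / 26), `npM1`
#' 20 procedures (10; 15 / 17 / 18), `npL1` 16 procedures (6;
#' 13 / 13 / 13). Durations are fixed (no randomness), so every derived
#' statistic is exactly reproducible. Likert ratings are 4 for the first
#' 72% of each worker's procedures and 3 thereafter.
#'
#' @return An event-log data frame accepted by [build_procedures()].
#' @export
#' @examples
#' dissemination_rates(build_procedures(field_demo_log()))
field_demo_log <- function() {
  spec <- list(
    npB1 = list(n = 28, bt = 17, sections = c(22, 27, 26)),
    npM1 = list(n = 20, bt = 10, sections = c(15, 17, 18)),
    npL1 = list(n = 16, bt = 6, sections = c(13, 13, 13))
  )
  base <- as.POSIXct("2013-05-01 09:00:00", tz = "UTC")
  rows <- list()
  for (w in names(spec)) {
    cfg <- spec[[w]]
    for (k in seq_len(cfg$n)) {
      enc <- sprintf("%s-E%03d", w, k)
      t <- base + (k - 1) * 86400 + (match(w, names(spec)) - 1) * 10800
      add <- function(offset_s, step, element, value = NA_character_) {
        rows[[length(rows) + 1L]] <<- data.frame(
          timestamp = t + offset_s, user_id = w, encounter_id = enc,
          step = step, element_id = element, value = value,
          stringsAsFactors = FALSE)
      }
      add(0, 1L, "step_open"); add(150, 1L, "step_complete")
      add(170, 2L, "step_open"); add(240, 2L, "step_complete")
      add(260, 3L, "step_open"); add(270, 3L, "bp_start")
      if (k <= cfg$bt) {
        add(590, 3L, "bp_bluetooth_receive"); add(591, 3L, "bp_done")
      } else {
        add(430, 3L, "bp_manual_entry"); add(600, 3L, "bp_manual_entry")
        add(770, 3L, "bp_manual_entry"); add(774, 3L, "bp_done")
      }
      add(860, 3L, "glucose_entry", "100"); add(980, 3L, "step_complete")
      add(1000, 4L, "step_open")
      off <- 1010
      sections <- c("riskmeter_open", "recs_open", "nextvisit_open")
      for (si in seq_along(sections)) {
        if (k <= cfg$sections[si]) {
          add(off, 4L, sections[si])
          off <- off + 20
        }
      }
      add(off + 10, 4L, "likert_rating",
          if (k <= ceiling(0.72 * cfg$n)) "4" else "3")
      add(off + 30, 4L, "step_complete")
    }
  }
  events <- do.call(rbind, rows)
  events <- events[order(events$timestamp, events$encounter_id), ,
                   drop = FALSE]
  rownames(events) <- NULL
  structure(events, class = c("event_log", "data.frame"),
            bad_rows = data.frame(line = integer(0),
                                  reason = character(0)))
}
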