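# Field-evaluation analytics: click-stream parsing, procedure/step timing,
# sequential bootstrap CIs, Bluetooth-adoption and dissemination rates,
# manual-entry error reconciliation, Likert summaries, unit conversion.

EVENT_ELEMENTS <- c("step_open", "step_complete", "bp_start",
                    "bp_bluetooth_receive", "bp_manual_entry", "bp_done",
                    "glucose_entry", "riskmeter_open", "recs_open",
                    "nextvisit_open", "likert_rating")

LOG_HEADER <- c("timestamp", "user_id", "encounter_id", "step", "element_id",
                "value")

TS_FORMAT <- "%Y-%m-%dT%H:%M:%S"

parse_ts <- function(x) as.POSIXct(x, format = TS_FORMAT, tz = "UTC")
format_ts <- function(t) format(t, TS_FORMAT, tz = "UTC")

#' Read a click-event log
#'
#' Parses the event-log CSV dialect
#' (`timestamp,user_id,encounter_id,step,element_id,value`; ISO-8601
#' timestamps, UTC). Rows with an unparseable timestamp, a step outside
#' 1-4, an element outside the documented vocabulary, or a Likert value
#' outside 1-4 are collected (with their line numbers) rather than aborting
#' the load; well-formed events are returned sorted chronologically.
#'
#' @param path CSV file path.
#' @return A data frame of class `event_log` (columns as in the dialect,
#'   `timestamp` as POSIXct, `step` integer) with attribute `bad_rows`,
#'   a data frame of `line` / `reason` for every rejected row.
#' @export
parse_event_log <- function(path) {
  if (!file.exists(path)) input_error(paste0("event log not found: ", path))
  raw <- read.csv(path, colClasses = "character", na.strings = "",
                  check.names = FALSE)
  if (!identical(names(raw), LOG_HEADER)) {
    input_error(paste0("event log header must be exactly: ",
                       paste(LOG_HEADER, collapse = ",")))
  }
  ts <- parse_ts(raw$timestamp)
  step <- suppressWarnings(as.integer(raw$step))
  reason <- rep(NA_character_, nrow(raw))
  reason[is.na(ts)] <- "unparseable timestamp"
  reason[is.na(reason) & (is.na(step) | !(step %in% 1:4))] <-
    "step outside 1-4"
  reason[is.na(reason) & !(raw$element_id %in% EVENT_ELEMENTS)] <-
    "unknown element_id"
  likert_bad <- raw$element_id == "likert_rating" &
    !(suppressWarnings(as.numeric(raw$value)) %in% 1:4)
  reason[is.na(reason) & likert_bad] <- "likert rating outside 1-4"

  bad <- data.frame(line = which(!is.na(reason)) + 1L,
                    reason = reason[!is.na(reason)],
                    stringsAsFactors = FALSE)
  keep <- is.na(reason)
  events <- data.frame(
    timestamp = ts[keep], user_id = raw$user_id[keep],
    encounter_id = raw$encounter_id[keep], step = step[keep],
    element_id = raw$element_id[keep], value = raw$value[keep],
    stringsAsFactors = FALSE
  )
  events <- events[order(events$timestamp, events$encounter_id), ,
                   drop = FALSE]
  rownames(events) <- NULL
  structure(events, class = c("event_log", "data.frame"), bad_rows = bad)
}

#' @rdname parse_event_log
#' @param events An event-log data frame.
#' @export
write_event_log <- function(events, path) {
  out <- as.data.frame(events)[, LOG_HEADER]
  out$timestamp <- format_ts(out$timestamp)
  out$value[is.na(out$value)] <- ""
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Reconstruct screening procedures from click events
#'
#' Groups events by encounter and derives one procedure record each: start
#' (first event), end (step-4 completion), completeness, per-step and BP
#' sub-step durations, Bluetooth use, which management sections were
#' visited, and the Likert rating. An encounter with no step-4 completion is
#' flagged incomplete and excluded from timing summaries. A procedure is
#' flagged non-sequential when its time span overlaps another encounter of
#' the same user (the worker interleaved two assessments); both overlapping
#' procedures are excluded from timing analyses.
#'
#' @param events A chronologically sorted event log ([parse_event_log()]).
#' @return Data frame of class `procedures`: one row per encounter with
#'   columns `encounter_id`, `user_id`, `start`, `end`, `complete`,
#'   `sequential`, `total_s`, `step1_s` ... `step4_s`, `bp_s`,
#'   `bluetooth_used`, `risk_meter`, `recommendations`, `next_visit`,
#'   `likert`.
#' @export
build_procedures <- function(events) {
  stopifnot(is.data.frame(events))
  if (nrow(events) == 0L) input_error("event log has no events")
  recs <- lapply(split(seq_len(nrow(events)), events$encounter_id), function(i) {
    e <- events[i, , drop = FALSE]
    e <- e[order(e$timestamp), , drop = FALSE]
    at <- function(el, s = NULL) {
      sel <- e$element_id == el
      if (!is.null(s)) sel <- sel & e$step == s
      if (any(sel)) e$timestamp[which(sel)[1]] else as.POSIXct(NA)
    }
    span_s <- function(a, b) {
      if (is.na(a) || is.na(b)) NA_real_ else as.numeric(b) - as.numeric(a)
    }
    end4 <- at("step_complete", 4L)
    step_s <- vapply(1:4, function(s) {
      span_s(at("step_open", s), at("step_complete", s))
    }, numeric(1))
    lik <- e$value[e$element_id == "likert_rating"]
    data.frame(
      encounter_id = e$encounter_id[1], user_id = e$user_id[1],
      start = min(e$timestamp), end = if (is.na(end4)) max(e$timestamp) else end4,
      complete = !is.na(end4),
      total_s = span_s(min(e$timestamp), end4),
      step1_s = step_s[1], step2_s = step_s[2], step3_s = step_s[3],
      step4_s = step_s[4],
      bp_s = span_s(at("bp_start"), at("bp_done")),
      bluetooth_used = any(e$element_id == "bp_bluetooth_receive"),
      risk_meter = any(e$element_id == "riskmeter_open"),
      recommendations = any(e$element_id == "recs_open"),
      next_visit = any(e$element_id == "nextvisit_open"),
      likert = if (length(lik)) as.integer(lik[length(lik)]) else NA_integer_,
      stringsAsFactors = FALSE
    )
  })
  procs <- do.call(rbind, recs)
  rownames(procs) <- NULL
  procs <- procs[order(procs$start, procs$encounter_id), , drop = FALSE]

  # interleaving detector: overlap with any other encounter of the same user
  procs$sequential <- TRUE
  for (u in unique(procs$user_id)) {
    idx <- which(procs$user_id == u)
    if (length(idx) < 2L) next
    for (a in idx) for (b in idx) {
      if (a >= b) next
      if (procs$start[a] < procs$end[b] && procs$end[a] > procs$start[b]) {
        procs$sequential[c(a, b)] <- FALSE
      }
    }
  }
  class(procs) <- c("procedures", "data.frame")
  procs
}

# procedures usable for timing and rate denominators
timing_subset <- function(procedures) {
  procedures[procedures$complete & procedures$sequential, , drop = FALSE]
}

iqr_stats <- function(x) {
  q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  c(median = q[2], q1 = q[1], q3 = q[3], iqr = q[3] - q[1])
}

#' Median and IQR of procedure durations
#'
#' Summarizes total (or per-step) durations over complete, sequential
#' procedures. Quartiles use linear interpolation between order statistics
#' (R quantile type 7); IQR is Q3 - Q1.
#'
#' @param procedures A [build_procedures()] result.
#' @param by_step Summarize each of the four steps instead of the total.
#' @return Data frame with `metric`, `n`, `median_s`, `q1_s`, `q3_s`,
#'   `iqr_s` (seconds).
#' @export
duration_summary <- function(procedures, by_step = FALSE) {
  use <- timing_subset(procedures)
  if (nrow(use) == 0L) {
    stop("no complete sequential procedures to summarize", call. = FALSE)
  }
  metrics <- if (by_step) paste0("step", 1:4, "_s") else "total_s"
  out <- do.call(rbind, lapply(metrics, function(m) {
    x <- use[[m]]
    x <- x[!is.na(x)]
    s <- iqr_stats(x)
    data.frame(metric = sub("_s$", "", m), n = length(x),
               median_s = s[["median"]], q1_s = s[["q1"]], q3_s = s[["q3"]],
               iqr_s = s[["iqr"]], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Sequential bootstrap confidence intervals for the mean procedure time
#'
#' For every procedure index k, resamples with replacement from the
#' durations of procedures 1..k (`n_boot` times), giving the bootstrap
#' estimate of the mean completion time and a percentile interval at the
#' requested level, considering all samples available up until and
#' including that procedure. The series shows how a worker's estimated
#' mean time and its uncertainty evolve over the study. Fully reproducible
#' given `seed`.
#'
#' By default the percentile levels are expanded for small samples
#' (Hesterberg's adjustment: quantiles at
#' `pnorm(sqrt(k/(k-1)) * qt(alpha/2, k-1))` instead of `alpha/2`), which
#' corrects the well-known narrowness bias of the plain percentile
#' interval so that a nominal 95% interval covers the mean at close to
#' 95% for the sample sizes a field worker accrues; `expand = FALSE`
#' gives the unadjusted percentile interval.
#'
#' @param durations Numeric vector of procedure durations (seconds),
#'   ordered by procedure index.
#' @param n_boot Bootstrap replicates per index (default 2000).
#' @param level Interval level in (0, 1), default 0.95.
#' @param seed Mandatory integer seed.
#' @param expand Use expanded percentile levels (default `TRUE`).
#' @return Data frame of class `ci_series`: `k`, `n` (= k), `mean`,
#'   `ci_low`, `ci_high`.
#' @export
#' @examples
#' sequential_bootstrap_ci(c(1800, 1500, 1350, 1300), n_boot = 200, seed = 1)
sequential_bootstrap_ci <- function(durations, n_boot = 2000, level = 0.95,
                                    seed, expand = TRUE) {
  if (missing(seed) || !is_scalar_number(seed)) {
    input_error("sequential_bootstrap_ci requires an explicit integer seed")
  }
  durations <- as.numeric(durations)
  if (length(durations) == 0L || any(!is.finite(durations))) {
    stop("durations must be a non-empty finite numeric vector", call. = FALSE)
  }
  if (!is_scalar_number(n_boot) || n_boot < 1) stop("n_boot must be >= 1")
  if (!is_scalar_number(level) || level <= 0 || level >= 1) {
    stop("level must be in (0, 1)")
  }
  out <- withr::with_seed(as.integer(seed), {
    do.call(rbind, lapply(seq_along(durations), function(k) {
      means <- bootstrap_means(durations[seq_len(k)], n_boot)
      a <- percentile_alpha(level, k, expand)
      ci <- quantile(means, c(a, 1 - a), type = 7, names = FALSE)
      data.frame(k = k, n = k, mean = mean(means),
                 ci_low = ci[1], ci_high = ci[2])
    }))
  })
  rownames(out) <- NULL
  structure(out, class = c("ci_series", "data.frame"),
            level = level, n_boot = n_boot)
}

# lower tail level for the percentile interval; expanded levels follow
# Hesterberg (2015), correcting small-sample narrowness of the bootstrap
# distribution of the mean
percentile_alpha <- function(level, k, expand) {
  alpha <- (1 - level) / 2
  if (!expand || k < 2L) return(alpha)
  stats::pnorm(sqrt(k / (k - 1)) * stats::qt(alpha, df = k - 1))
}

bootstrap_means <- function(x, n_boot) {
  k <- length(x)
  if (k == 1L) return(rep(x, n_boot))
  m <- matrix(sample(x, k * n_boot, replace = TRUE), nrow = n_boot)
  rowMeans(m)
}

#' Percentile bootstrap CI for a single sample mean
#'
#' The single-index building block of [sequential_bootstrap_ci()], exposed
#' for coverage checks and one-off estimates.
#'
#' @inheritParams sequential_bootstrap_ci
#' @param x Numeric sample.
#' @return Named numeric: `mean`, `ci_low`, `ci_high`.
#' @export
bootstrap_mean_ci <- function(x, n_boot = 2000, level = 0.95, seed,
                              expand = TRUE) {
  if (missing(seed) || !is_scalar_number(seed)) {
    input_error("bootstrap_mean_ci requires an explicit integer seed")
  }
  a <- percentile_alpha(level, length(x), expand)
  withr::with_seed(as.integer(seed), {
    means <- bootstrap_means(as.numeric(x), n_boot)
    ci <- quantile(means, c(a, 1 - a), type = 7, names = FALSE)
    c(mean = mean(means), ci_low = ci[1], ci_high = ci[2])
  })
}

#' Bluetooth adoption rate and BP acquisition time
#'
#' Per worker: the fraction of complete sequential procedures in which the
#' automated Bluetooth BP transfer was used, the mean and SD of the BP
#' acquisition time over Bluetooth procedures, and (optionally) the rate
#' before and after a given procedure index, to show adoption over the
#' study. Rates are reported both as raw fractions (authoritative) and
#' nearest-integer percent (display).
#'
#' @param procedures A [build_procedures()] result.
#' @param split_at Optional procedure index; rates are additionally reported
#'   for procedures 1..`split_at` and `split_at`+1.. per worker.
#' @return Data frame per worker: `user_id`, `n`, `n_bluetooth`, `rate`
#'   (fraction), `rate_pct`, `bp_mean_s`, `bp_sd_s`, and when `split_at`
#'   is given `rate_before`/`rate_after` (+ `_pct`).
#' @export
bluetooth_usage <- function(procedures, split_at = NULL) {
  use <- timing_subset(procedures)
  if (nrow(use) == 0L) stop("no procedures to analyse", call. = FALSE)
  out <- do.call(rbind, lapply(split(use, use$user_id), function(p) {
    p <- p[order(p$start), , drop = FALSE]
    bt <- p$bluetooth_used
    times <- p$bp_s[bt & !is.na(p$bp_s)]
    row <- data.frame(
      user_id = p$user_id[1], n = nrow(p), n_bluetooth = sum(bt),
      rate = sum(bt) / nrow(p), rate_pct = round(100 * sum(bt) / nrow(p)),
      bp_mean_s = if (length(times)) mean(times) else NA_real_,
      bp_sd_s = if (length(times) > 1L) sd(times) else NA_real_,
      stringsAsFactors = FALSE
    )
    if (!is.null(split_at)) {
      idx <- seq_len(nrow(p))
      pre <- bt[idx <= split_at]
      post <- bt[idx > split_at]
      row$rate_before <- if (length(pre)) mean(pre) else NA_real_
      row$rate_after <- if (length(post)) mean(post) else NA_real_
      row$rate_before_pct <- round(100 * row$rate_before)
      row$rate_after_pct <- round(100 * row$rate_after)
    }
    row
  }))
  rownames(out) <- NULL
  out
}

#' Dissemination rates of the management sections
#'
#' For each worker and management section (risk projection meter,
#' recommendations, next visit): the fraction of that worker's complete
#' sequential procedures in which the section was opened at least once.
#' Raw fractions are authoritative; nearest-integer percentages reproduce
#' the usual report format.
#'
#' @param procedures A [build_procedures()] result.
#' @return Data frame: `user_id`, `section`, `n_visited`, `n`, `rate`
#'   (fraction), `rate_pct`.
#' @export
dissemination_rates <- function(procedures) {
  use <- timing_subset(procedures)
  if (nrow(use) == 0L) stop("no procedures to analyse", call. = FALSE)
  sections <- c("risk_meter", "recommendations", "next_visit")
  out <- do.call(rbind, lapply(split(use, use$user_id), function(p) {
    do.call(rbind, lapply(sections, function(s) {
      visited <- sum(p[[s]])
      data.frame(user_id = p$user_id[1], section = s, n_visited = visited,
                 n = nrow(p), rate = visited / nrow(p),
                 rate_pct = round(100 * visited / nrow(p)),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Reconcile manually entered glucose values against glucometer memory
#'
#' Matches each manually entered value to the nearest meter reading in time
#' (greedy one-to-one on the smallest absolute time gap) within the
#' tolerance window, then reports the absolute discrepancies. `n_errors`
#' counts matched pairs with a non-zero discrepancy; the median and IQR are
#' computed over the non-zero discrepancies. Entered values with no meter
#' reading inside the window are reported separately, not counted as
#' errors.
#'
#' @param entered Data frame with `timestamp` (POSIXct) and `value` (mg/dL)
#'   for the manual entries.
#' @param meter Data frame with `timestamp` and `value` for the glucometer
#'   memory dump.
#' @param tolerance_minutes Matching window, minutes (> 0; default 10).
#' @return List of class `glucose_error_report`: `n_matched`, `n_errors`,
#'   `errors` (data frame of matched pairs with `entered`, `meter`,
#'   `error_mgdl`, `gap_s`), `median_error`, `iqr_error` (mg/dL, over
#'   non-zero errors; `NA` when none), `unmatched` (data frame).
#' @export
glucose_entry_errors <- function(entered, meter, tolerance_minutes = 10) {
  for (d in list(entered, meter)) {
    if (!is.data.frame(d) || !all(c("timestamp", "value") %in% names(d))) {
      stop("entered/meter must be data frames with timestamp and value",
           call. = FALSE)
    }
  }
  if (!is_scalar_number(tolerance_minutes) || tolerance_minutes <= 0) {
    stop("tolerance_minutes must be > 0", call. = FALSE)
  }
  tol_s <- tolerance_minutes * 60

  if (nrow(entered) == 0L || nrow(meter) == 0L) {
    pairs <- data.frame(entered_time = as.POSIXct(character(0), tz = "UTC"),
                        entered = numeric(0), meter = numeric(0),
                        error_mgdl = numeric(0), gap_s = numeric(0))
  } else {
    cand <- expand.grid(i = seq_len(nrow(entered)), j = seq_len(nrow(meter)),
                        KEEP.OUT.ATTRS = FALSE)
    cand$gap <- abs(as.numeric(entered$timestamp[cand$i]) -
                      as.numeric(meter$timestamp[cand$j]))
    cand <- cand[cand$gap <= tol_s, , drop = FALSE]
    cand <- cand[order(cand$gap, cand$i, cand$j), , drop = FALSE]
    used_i <- logical(nrow(entered))
    used_j <- logical(nrow(meter))
    keep <- integer(0)
    for (r in seq_len(nrow(cand))) {
      i <- cand$i[r]; j <- cand$j[r]
      if (!used_i[i] && !used_j[j]) {
        used_i[i] <- TRUE
        used_j[j] <- TRUE
        keep <- c(keep, r)
      }
    }
    m <- cand[keep, , drop = FALSE]
    pairs <- data.frame(
      entered_time = entered$timestamp[m$i],
      entered = as.numeric(entered$value[m$i]),
      meter = as.numeric(meter$value[m$j]),
      gap_s = m$gap
    )
    pairs$error_mgdl <- abs(pairs$entered - pairs$meter)
    pairs <- pairs[order(pairs$entered_time), , drop = FALSE]
    rownames(pairs) <- NULL
  }
  unmatched <- if (nrow(entered) > 0L) {
    entered[!entered$timestamp %in% pairs$entered_time, , drop = FALSE]
  } else entered

  nz <- pairs$error_mgdl[pairs$error_mgdl > 0]
  s <- if (length(nz)) iqr_stats(nz) else c(median = NA_real_, q1 = NA_real_,
                                            q3 = NA_real_, iqr = NA_real_)
  structure(list(
    n_matched = nrow(pairs), n_errors = length(nz),
    errors = pairs, median_error = unname(s[["median"]]),
    iqr_error = unname(s[["iqr"]]), unmatched = unmatched
  ), class = "glucose_error_report")
}

#' @export
print.glucose_error_report <- function(x, ...) {
  cat("<glucose_error_report>", x$n_matched, "matched,", x$n_errors,
      "erroneous entries\n")
  if (x$n_errors > 0) {
    mmol <- convert_glucose(c(x$median_error, x$iqr_error), "mgdl_to_mmol")
    cat(sprintf("  median error %.2f mg/dL (%.2f mmol/L), IQR %.2f mg/dL (%.2f mmol/L)\n",
                x$median_error, mmol$rounded[1], x$iqr_error, mmol$rounded[2]))
  }
  if (nrow(x$unmatched) > 0) cat(" ", nrow(x$unmatched), "entries unmatched\n")
  invisible(x)
}

#' Likert usability summary
#'
#' Counts per rating on the four-point scale, the fraction of procedures
#' rated at or above a threshold (default 3, "easy to use"), and the
#' minimum rating given.
#'
#' @param x A [build_procedures()] result (uses its `likert` column) or a
#'   numeric vector of ratings in 1-4.
#' @param threshold Rating threshold for the "at or above" fraction.
#' @return List: `counts` (named, ratings 1-4), `n`, `fraction_at_or_above`,
#'   `pct_at_or_above`, `min_rating`, `threshold`.
#' @export
likert_summary <- function(x, threshold = 3) {
  ratings <- if (is.data.frame(x)) x$likert else x
  ratings <- ratings[!is.na(ratings)]
  if (length(ratings) == 0L) stop("no Likert ratings", call. = FALSE)
  if (any(!(ratings %in% 1:4))) {
    stop("Likert ratings must be integers 1-4", call. = FALSE)
  }
  counts <- table(factor(ratings, levels = 1:4))
  frac <- mean(ratings >= threshold)
  list(counts = setNames(as.integer(counts), names(counts)),
       n = length(ratings), fraction_at_or_above = frac,
       pct_at_or_above = round(100 * frac), min_rating = min(ratings),
       threshold = threshold)
}

#' Convert glucose between mg/dL and mmol/L
#'
#' Standard molar conversion (18.016 mg/dL per mmol/L). The raw converted
#' value is returned alongside a 2-decimal rounding for reporting.
#'
#' @param value Non-negative numeric (vectorized).
#' @param direction `"mgdl_to_mmol"` or `"mmol_to_mgdl"`.
#' @return List with `raw` and `rounded` numeric vectors.
#' @export
#' @examples
#' convert_glucose(9.55, "mgdl_to_mmol")$rounded   # 0.53
convert_glucose <- function(value, direction = c("mgdl_to_mmol",
                                                 "mmol_to_mgdl")) {
  direction <- match.arg(direction)
  if (!is.numeric(value) || any(!is.finite(value)) || any(value < 0)) {
    stop("value must be non-negative and finite", call. = FALSE)
  }
  raw <- if (direction == "mgdl_to_mmol") value / MGDL_PER_MMOL_GLUCOSE
         else value * MGDL_PER_MMOL_GLUCOSE
  list(raw = raw, rounded = round(raw, 2))
}
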