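base_t <- as.POSIXct("2013-05-01 09:00:00", tz = "UTC")

test_that("event logs parse, report bad rows, and round-trip", {
  ev <- rbind(minimal_encounter_events("W1", "W1-E001", base_t),
              minimal_encounter_events("W1", "W1-E002", base_t + 86400))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_event_log(ev, tmp)
  parsed <- parse_event_log(tmp)
  expect_identical(nrow(attr(parsed, "bad_rows")), 0L)
  expect_equal(as.data.frame(parsed),
               ev[order(ev$timestamp), , drop = FALSE],
               ignore_attr = TRUE)
  expect_true(!is.unsorted(parsed$timestamp))

  # inject malformed rows: bad timestamp, bad step, bad element
  lines <- readLines(tmp)
  lines <- c(lines,
             "not-a-time,W1,W1-E003,1,step_open,",
             "2013-05-03T09:00:00,W1,W1-E003,9,step_open,",
             "2013-05-03T09:00:05,W1,W1-E003,1,teleport,")
  writeLines(lines, tmp)
  parsed2 <- parse_event_log(tmp)
  bad <- attr(parsed2, "bad_rows")
  expect_identical(nrow(bad), 3L)
  expect_setequal(bad$reason, c("unparseable timestamp", "step outside 1-4",
                                "unknown element_id"))
  expect_identical(nrow(parsed2), nrow(parsed))
})

test_that("a large generated log round-trips identically", {
  wp <- worker_profile("W9", n_procedures = 40, seed = 5)
  cohort <- generate_cohort(cohort_params(n = 40, seed = 6),
                            chart_li = NULL, chart_hi = NULL)
  stream <- generate_event_stream(wp, cohort)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_event_log(stream$events, tmp)
  parsed <- parse_event_log(tmp)
  expect_identical(nrow(attr(parsed, "bad_rows")), 0L)
  expect_equal(as.data.frame(parsed), stream$events, ignore_attr = TRUE)
})

test_that("procedures partition events and detect interleaving", {
  ev <- rbind(
    minimal_encounter_events("W1", "A", base_t),
    minimal_encounter_events("W1", "B", base_t + 7200),
    minimal_encounter_events("W2", "C", base_t + 600)  # other user, overlaps A
  )
  procs <- build_procedures(ev)
  expect_identical(nrow(procs), 3L)
  # every event's encounter appears exactly once
  expect_setequal(procs$encounter_id, c("A", "B", "C"))
  expect_true(all(procs$sequential))   # overlap across users is fine
  expect_true(all(procs$complete))

  # same-user interleaving: B2 strictly inside A2's span
  ev2 <- rbind(
    minimal_encounter_events("W1", "A2", base_t, total_s = 3600),
    minimal_encounter_events("W1", "B2", base_t + 600, total_s = 1200)
  )
  procs2 <- build_procedures(ev2)
  expect_false(any(procs2$sequential))

  # encounter without step-4 completion is incomplete and excluded
  ev3 <- minimal_encounter_events("W1", "D", base_t)
  ev3 <- ev3[!(ev3$element_id == "step_complete" & ev3$step == 4L), ]
  procs3 <- build_procedures(rbind(ev3,
    minimal_encounter_events("W1", "E", base_t + 86400)))
  expect_false(procs3$complete[procs3$encounter_id == "D"])
  expect_identical(duration_summary(procs3)$n, 1L)
})

test_that("per-step durations are consistent with the total", {
  ev <- minimal_encounter_events("W1", "A", base_t, total_s = 2400)
  p <- build_procedures(ev)
  expect_true(sum(p[, paste0("step", 1:4, "_s")]) <= p$total_s)
  expect_equal(p$total_s, 2400)
  expect_true(p$bp_s > 0)
})

test_that("duration summaries use interpolated quartiles", {
  mk <- function(durs) {
    do.call(rbind, lapply(seq_along(durs), function(i) {
      minimal_encounter_events("W1", paste0("E", i),
                               base_t + (i - 1) * 86400,
                               total_s = durs[i])
    }))
  }
  s <- duration_summary(build_procedures(mk(c(600, 1200, 1800))))
  expect_equal(s$median_s, 1200)
  expect_equal(s$iqr_s, 600)

  s1 <- duration_summary(build_procedures(mk(1500)))
  expect_equal(s1$median_s, 1500)
  expect_equal(s1$iqr_s, 0)

  by_step <- duration_summary(build_procedures(mk(c(600, 1200, 1800))),
                              by_step = TRUE)
  expect_identical(by_step$metric, paste0("step", 1:4))
  expect_error(duration_summary(build_procedures(mk(1500))[0, ]), "no complete")
})

test_that("sequential bootstrap collapses on degenerate input and reproduces", {
  const <- rep(600, 8)
  ci <- sequential_bootstrap_ci(const, n_boot = 500, seed = 1)
  expect_equal(ci$mean, rep(600, 8))
  expect_equal(ci$ci_low, rep(600, 8))
  expect_equal(ci$ci_high, rep(600, 8))

  x <- c(1800, 2400, 1200, 3000, 900)
  a <- sequential_bootstrap_ci(x, n_boot = 300, seed = 42)
  b <- sequential_bootstrap_ci(x, n_boot = 300, seed = 42)
  expect_identical(a, b)
  c_ <- sequential_bootstrap_ci(x, n_boot = 300, seed = 43)
  expect_false(identical(a$mean, c_$mean))

  # k = 1 collapses to the single value
  expect_equal(unlist(a[1, c("mean", "ci_low", "ci_high")]),
               c(mean = 1800, ci_low = 1800, ci_high = 1800))
  # interval sanity at every k
  expect_true(all(a$ci_low <= a$mean & a$mean <= a$ci_high))
  expect_error(sequential_bootstrap_ci(x, n_boot = 300),
               class = "cvdscreen_input_error")
})

test_that("widening the level widens every interval", {
  x <- c(1800, 2400, 1200, 3000, 900, 2100, 1500)
  lo <- sequential_bootstrap_ci(x, n_boot = 400, level = 0.80, seed = 9)
  hi <- sequential_bootstrap_ci(x, n_boot = 400, level = 0.99, seed = 9)
  expect_true(all(hi$ci_low <= lo$ci_low))
  expect_true(all(hi$ci_high >= lo$ci_high))
})

test_that("CI width shrinks in expectation as procedures accrue", {
  set.seed(31)
  widths <- replicate(30, {
    x <- rlnorm(20, log(1500), 0.4)
    ci <- sequential_bootstrap_ci(x, n_boot = 200,
                                  seed = sample.int(1e6, 1))
    w <- ci$ci_high - ci$ci_low
    c(early = mean(w[3:6]), late = mean(w[15:20]))
  })
  expect_lt(mean(widths["late", ]), mean(widths["early", ]))
})

test_that("bluetooth usage rates and split reproduce hand counts", {
  mk_worker <- function(user, n, bt_idx, t0) {
    do.call(rbind, lapply(seq_len(n), function(i) {
      minimal_encounter_events(user, paste0(user, "-E", i),
                               t0 + (i - 1) * 86400,
                               bluetooth = i %in% bt_idx)
    }))
  }
  ev <- rbind(mk_worker("npB1", 28, 1:17, base_t),
              mk_worker("npL1", 16, 1:6, base_t + 3600))
  bu <- bluetooth_usage(build_procedures(ev), split_at = 10)
  b1 <- bu[bu$user_id == "npB1", ]
  l1 <- bu[bu$user_id == "npL1", ]
  expect_identical(b1$rate_pct, 61)        # 17/28
  expect_equal(l1$rate, 6 / 16)            # raw fraction is authoritative
  expect_identical(l1$rate_pct, 38)
  expect_equal(b1$rate_before, 1)          # first 10 all bluetooth here
  expect_equal(b1$rate_after, 7 / 18)
  # zero usage
  ev0 <- mk_worker("W0", 5, integer(0), base_t)
  expect_identical(bluetooth_usage(build_procedures(ev0))$rate_pct, 0)
})

test_that("dissemination rates reproduce the demo-log table exactly", {
  rates <- dissemination_rates(build_procedures(field_demo_log()))
  get <- function(u, s) rates$rate_pct[rates$user_id == u &
                                         rates$section == s]
  expect_identical(get("npB1", "risk_meter"), 79)
  expect_identical(get("npB1", "recommendations"), 96)
  expect_identical(get("npB1", "next_visit"), 93)
  expect_identical(get("npM1", "risk_meter"), 75)
  expect_identical(get("npM1", "recommendations"), 85)
  expect_identical(get("npM1", "next_visit"), 90)
  expect_true(all(rates$rate_pct[rates$user_id == "npL1"] == 81))
  expect_true(all(rates$rate >= 0 & rates$rate <= 1))
  # same denominator as bluetooth rates: that user's completed procedures
  bu <- bluetooth_usage(build_procedures(field_demo_log()))
  expect_identical(sort(unique(rates$n[rates$user_id == "npB1"])),
                   bu$n[bu$user_id == "npB1"])
})

test_that("glucose reconciliation matches greedily and symmetrically", {
  t0 <- base_t
  entered <- data.frame(timestamp = t0 + c(0, 600, 1200),
                        value = c(118, 181, 95))
  meter <- data.frame(timestamp = t0 + c(30, 590, 1190),
                      value = c(118, 118, 95))
  rep_ <- glucose_entry_errors(entered, meter, tolerance_minutes = 10)
  expect_identical(rep_$n_matched, 3L)
  expect_identical(rep_$n_errors, 1L)
  expect_equal(rep_$errors$error_mgdl, c(0, 63, 0))  # transposition 181/118
  expect_equal(rep_$median_error, 63)

  # identical lists: no errors
  same <- glucose_entry_errors(entered, setNames(entered, c("timestamp",
                                                            "value")))
  expect_identical(same$n_errors, 0L)
  expect_true(is.na(same$median_error))

  # unmatched entries are reported separately
  far <- glucose_entry_errors(entered,
                              data.frame(timestamp = t0 + 50000, value = 100))
  expect_identical(far$n_matched, 0L)
  expect_identical(nrow(far$unmatched), 3L)

  # symmetry of matched error magnitudes under role swap
  swap <- glucose_entry_errors(
    data.frame(timestamp = meter$timestamp, value = meter$value),
    data.frame(timestamp = entered$timestamp, value = entered$value))
  expect_equal(sort(swap$errors$error_mgdl), sort(rep_$errors$error_mgdl))
})

test_that("likert summaries count thresholds and reject bad ratings", {
  expect_equal(likert_summary(rep(4, 10))$pct_at_or_above, 100)
  expect_identical(likert_summary(rep(4, 10))$min_rating, 4)
  s <- likert_summary(c(3, 3, 4, 4), threshold = 4)
  expect_equal(s$fraction_at_or_above, 0.5)
  expect_identical(unname(s$counts), c(0L, 0L, 2L, 2L))
  expect_error(likert_summary(numeric(0)), "no Likert")
  expect_error(likert_summary(c(3, 5)), "1-4")
})

test_that("glucose unit conversion is exact and invertible", {
  expect_identical(convert_glucose(9.55, "mgdl_to_mmol")$rounded, 0.53)
  expect_identical(convert_glucose(35.75, "mgdl_to_mmol")$rounded, 1.98)
  expect_identical(convert_glucose(0, "mgdl_to_mmol")$rounded, 0)
  x <- c(0.3, 9.55, 100, 180)
  back <- convert_glucose(convert_glucose(x, "mgdl_to_mmol")$raw,
                          "mmol_to_mgdl")$raw
  expect_equal(back, x, tolerance = 1e-12)
  expect_error(convert_glucose(-1, "mgdl_to_mmol"), "non-negative")
})
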