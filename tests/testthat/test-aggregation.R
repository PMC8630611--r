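test_that("development scheme picks the index arm at visit 1 and pools all visits", {
  r <- rbind(
    office_rows(1, 1, "right", rep(142, 3), rep(88, 3)),
    office_rows(1, 1, "left", rep(138, 3), rep(90, 3)),
    office_rows(1, 2, "right", rep(140, 3), rep(90, 3)),
    office_rows(1, 2, "left", rep(170, 3), rep(110, 3)),  # ignored: not index
    office_rows(1, 3, "right", rep(138, 3), rep(92, 3)),
    office_rows(1, 3, "left", rep(170, 3), rep(110, 3)))
  a <- aggregate_office(r, "development")
  expect_equal(a$index_arm, "right")       # visit-1 SBP decides
  expect_equal(a$sbp, 140)
  expect_equal(a$dbp, 90)
})

test_that("index-arm ties break on DBP, then to the right arm", {
  r <- rbind(office_rows(1, 1, "right", rep(140, 3), rep(88, 3)),
             office_rows(1, 1, "left", rep(140, 3), rep(90, 3)))
  expect_equal(aggregate_office(r, "development")$index_arm, "left")
  r2 <- rbind(office_rows(1, 1, "right", rep(140, 3), rep(90, 3)),
              office_rows(1, 1, "left", rep(140, 3), rep(90, 3)))
  expect_equal(aggregate_office(r2, "development")$index_arm, "right")
})

test_that("validation scheme compares whole-study per-arm means", {
  r <- rbind(
    office_rows(1, 1, "right", rep(150, 3), rep(95, 3)),
    office_rows(1, 1, "left", rep(140, 3), rep(85, 3)),
    office_rows(1, 2, "right", rep(130, 3), rep(80, 3)),
    office_rows(1, 2, "left", rep(148, 3), rep(93, 3)))
  a <- aggregate_office(r, "validation")
  # right mean 140, left mean 144 -> left is index despite visit 1
  expect_equal(a$index_arm, "left")
  expect_equal(a$sbp, 144)
  expect_error(aggregate_office(office_rows(1, 1, "right", 150, 95),
                                "validation"), "both arms")
})

test_that("a missing arm at the index visit is an explicit error", {
  expect_error(aggregate_office(office_rows(7, 1, "right", rep(150, 3),
                                            rep(95, 3)), "development"),
               "subject 7: visit 1")
})

test_that("home validity needs 5 qualifying days per session after the discards", {
  expect_true(validate_home(home_grid()))
  expect_false(validate_home(home_grid()[0, ]))
  # 4 complete days only
  g4 <- do.call(rbind, lapply(1:4, function(d) rbind(
    home_rows(1, d, "morning", rep(130, 3), rep(80, 3)),
    home_rows(1, d, "evening", rep(130, 3), rep(80, 3)))))
  expect_false(validate_home(g4))
  # 7 days but single-reading evening sessions never qualify
  g1e <- do.call(rbind, lapply(1:7, function(d) rbind(
    home_rows(1, d, "morning", rep(130, 3), rep(80, 3)),
    home_rows(1, d, "evening", 130, 80))))
  expect_false(validate_home(g1e))
  # exactly 5 qualifying days for each session, counting the discards:
  # day-1 evening and day-2 morning must not contribute
  g5 <- rbind(
    do.call(rbind, lapply(c(1, 3, 4, 5, 6), function(d)
      home_rows(1, d, "morning", rep(130, 2), rep(80, 2)))),
    do.call(rbind, lapply(c(2, 3, 4, 5, 6), function(d)
      home_rows(1, d, "evening", rep(130, 2), rep(80, 2)))))
  expect_true(validate_home(g5))
  # the same sessions shifted onto the discarded slots fail
  g_disc <- rbind(
    do.call(rbind, lapply(c(2, 3, 4, 5, 6), function(d)
      home_rows(1, d, "morning", rep(130, 2), rep(80, 2)))),
    do.call(rbind, lapply(c(1, 3, 4, 5, 6), function(d)
      home_rows(1, d, "evening", rep(130, 2), rep(80, 2)))))
  expect_false(validate_home(g_disc))
})

test_that("home aggregation discards day-1 evening, day-2 morning and third readings", {
  g <- home_grid(sbp = 130, dbp = 80)
  expect_equal(aggregate_home(g), list(sbp = 130, dbp = 80))
  # contaminate only the discarded sessions: aggregate unchanged
  g2 <- g
  disc <- (g2$day == 1 & g2$session == "evening") |
    (g2$day == 2 & g2$session == "morning")
  g2$sbp[disc] <- 200; g2$dbp[disc] <- 120
  expect_equal(aggregate_home(g2), list(sbp = 130, dbp = 80))
  # third readings are ignored within each session
  g3 <- g
  g3$sbp[g3$reading_index == 3] <- 190
  expect_equal(aggregate_home(g3), list(sbp = 130, dbp = 80))
  # removing a discarded session entirely never changes the aggregate
  expect_equal(aggregate_home(g[!disc, ]), aggregate_home(g))
})

test_that("sessions pool equally: half at 120/80 and half at 140/90 average to 130/85", {
  rows <- list()
  for (d in 1:7) {
    for (s in c("morning", "evening")) {
      v <- if (xor(d %% 2 == 0, s == "evening")) c(120, 80) else c(140, 90)
      rows[[length(rows) + 1L]] <- home_rows(1, d, s, rep(v[1], 3), rep(v[2], 3))
    }
  }
  g <- do.call(rbind, rows)
  kept <- g[!((g$day == 1 & g$session == "evening") |
                (g$day == 2 & g$session == "morning")), ]
  sess <- unique(kept[, c("day", "session")])
  v <- ifelse(xor(sess$day %% 2 == 0, sess$session == "evening"), 120, 140)
  expect_equal(aggregate_home(g)$sbp, mean(v))  # session-level pooling
})

test_that("home aggregation on an invalid series is an explicit error", {
  expect_error(aggregate_home(home_rows(5, 1, "morning", rep(130, 3), rep(80, 3))),
               "invalid home series")
})

test_that("ambulatory validity uses a strict 70% ratio and window minima", {
  sch <- schedule_spec()
  ts_day <- sprintf("%02d:%02d", 10 + (0:19) %/% 2, 30 * ((0:19) %% 2))
  ts_night <- sprintf("%02d:%02d", (0:9) %/% 2, 30 * ((0:9) %% 2))
  ok <- amb_rows(1, c(ts_day, ts_night), 135, 85)
  expect_true(validate_ambulatory(ok, sch))
  # 35/50 valid is exactly 0.70, which is not > 0.70
  half <- amb_rows(1, c(ts_day, ts_night, rep("22:00", 20)), 135, 85,
                   valid = rep(c(TRUE, FALSE), c(35, 15)))
  expect_equal(nrow(half), 50)
  expect_false(validate_ambulatory(half, sch))
  # 13 valid daytime readings fail the daytime minimum
  few_day <- amb_rows(1, c(ts_day[1:13], ts_night), 135, 85)
  expect_false(validate_ambulatory(few_day, sch))
  # 6 nighttime readings fail the nighttime minimum
  few_night <- amb_rows(1, c(ts_day, ts_night[1:6]), 135, 85)
  expect_false(validate_ambulatory(few_night, sch))
})

test_that("window means use the half-open [start, end) convention", {
  r <- amb_rows(1, c("09:59", "10:00", "19:59", "20:00"),
                c(100, 130, 140, 200), c(60, 80, 90, 120))
  m <- aggregate_window(r, c("10:00", "20:00"))
  expect_equal(m, list(sbp = 135, dbp = 85))  # 09:59 and 20:00 excluded
  expect_equal(aggregate_window(r, c("00:00", "24:00"))$sbp, mean(c(100, 130, 140, 200)))
  expect_error(aggregate_window(r, c("02:00", "03:00")), "no valid")
  # invalid readings never contribute
  r2 <- rbind(r, amb_rows(1, "12:00", 250, 150, valid = FALSE))
  expect_equal(aggregate_window(r2, c("10:00", "20:00")), m)
})

test_that("aggregation is invariant to reading order", {
  p <- cohort_params(n_subjects = 3, seed = 55)
  g <- generate_cohort(p)
  coh1 <- aggregate_subjects(g$readings, "development", p$schedule)
  set.seed(1)
  shuf <- g$readings[sample(nrow(g$readings)), ]
  coh2 <- aggregate_subjects(shuf, "development", p$schedule)
  coh2 <- coh2[order(coh2$subject_id), ]
  rownames(coh2) <- NULL
  expect_equal(coh1, coh2)
})
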