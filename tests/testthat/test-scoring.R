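geom <- screen_geometry()

test_that("TMT label sequences are correct for both versions", {
  expect_equal(tmt_labels("A", 25), as.character(1:25))
  b <- tmt_labels("B", 25)
  expect_equal(b[1:5], c("1", "A", "2", "B", "3"))
  expect_equal(b[24:25], c("L", "13"))
  expect_equal(length(unique(b)), 25)
  expect_equal(tmt_labels("B", 8), c("1", "A", "2", "B", "3", "C", "4", "D"))
})

test_that("fixations classify as guiding, searching or unassigned by AOI distance", {
  lay <- toy_layout(c(-6, 0, 6))
  # at the current target's center: zero distance, guiding
  expect_equal(classify_fixation(c(0, 0), lay, 2)$role, "guiding")
  # at the previous target's center: past target, searching
  prev <- classify_fixation(c(-6, 0), lay, 2)
  expect_equal(prev$role, "searching")
  expect_equal(prev$target, 1L)
  # 1.70 deg from the current target, > 1.625 from all others: outside
  # every 3.25/2 = 1.625 deg AOI radius
  un <- classify_fixation(c(1.70, 0), lay, 2)
  expect_equal(un$role, "unassigned")
  expect_true(is.na(un$target))
  # just inside the AOI radius
  expect_equal(classify_fixation(c(1.60, 0), lay, 2)$role, "guiding")
  # within two AOIs: nearest center wins
  lay2 <- toy_layout(c(0, 2.5))
  expect_equal(classify_fixation(c(1.0, 0), lay2, 1)$role, "guiding")
  expect_equal(classify_fixation(c(1.5, 0), lay2, 1)$role, "searching")
  # exact tie goes to the current target
  expect_equal(classify_fixation(c(1.25, 0), lay2, 1)$role, "guiding")
  expect_equal(classify_fixation(c(1.25, 0), lay2, 2)$role, "guiding")
})

make_toy_trial <- function(fix, clicks, lay = toy_layout(c(-6, 0, 6)),
                           end_t = max(clicks$t_ms)) {
  trial_record("s01", "A", "accuracy", 0, end_t,
               fix, data.frame(onset = numeric(0), offset = numeric(0),
                               duration = numeric(0), amplitude = numeric(0),
                               peak_velocity = numeric(0)),
               clicks, lay)
}

fix_row <- function(onset, dur, x) {
  data.frame(onset = onset, offset = onset + dur, duration = dur,
             x_deg = x, y_deg = 0)
}

click_row <- function(t, target, lay) {
  px <- lay$targets[target, c("x_px", "y_px")]
  data.frame(t_ms = t, x_px = px$x_px, y_px = px$y_px, hit = TRUE,
             target_index = target)
}

test_that("a hand-built trial scores exactly as enumerated", {
  lay <- toy_layout(c(-6, 0, 6))
  # search T2, guide T1, guide T2, guide T3
  fix <- rbind(fix_row(200, 200, 0),     # current 1, lands on 2: searching
               fix_row(500, 200, -6),    # guiding T1
               fix_row(1600, 200, 0),    # guiding T2 (after T1 hit)
               fix_row(2600, 200, 6))    # guiding T3
  clicks <- rbind(click_row(1500, 1, lay), click_row(2500, 2, lay),
                  click_row(3500, 3, lay))
  tr <- make_toy_trial(fix, clicks, lay)
  sc <- score_trial(tr)
  expect_equal(sc$n_fixations, 4)
  expect_equal(sc$n_guiding, 3)
  expect_equal(sc$n_searching, 1)
  expect_equal(sc$trial_duration, 3.5)
  expect_equal(sc$mean_fixation_duration, 200)
  # scanpath over centroids 0, -6, 0, 6: 6 + 6 + 6
  expect_equal(sc$scanpath_length, 18)
  # spans: T1 1500-500, T2 2500-1600, T3 3500-2600
  expect_equal(unname(eye_hand_span(tr)), c(1.0, 0.9, 0.9))
  expect_equal(sc$mean_eye_hand_span, mean(c(1.0, 0.9, 0.9)))
  # determinism: identical input, identical output
  expect_identical(sc, score_trial(tr))
})

test_that("the eye-hand span uses the first qualifying guiding fixation", {
  lay <- toy_layout(c(-6, 0))
  fix <- rbind(fix_row(100, 200, -6),    # guide T1
               fix_row(800, 200, 0),     # guide T2, first
               fix_row(1400, 200, 0))    # guide T2, second
  clicks <- rbind(click_row(600, 1, lay), click_row(2000, 2, lay))
  tr <- make_toy_trial(fix, clicks, lay)
  sp <- eye_hand_span(tr)
  expect_equal(unname(sp), c(0.5, 1.2))
  # a guiding fixation before the target became current does not count:
  # move the first T2 fixation before the T1 hit
  fix2 <- fix
  fix2$onset[2] <- 300
  fix2$offset[2] <- 500
  tr2 <- make_toy_trial(fix2, clicks, lay)
  expect_equal(unname(eye_hand_span(tr2)), c(0.5, 0.6))
})

test_that("targets clicked without a guiding fixation contribute no span", {
  lay <- toy_layout(c(-6, 0))
  fix <- fix_row(100, 200, -6)           # only T1 fixated
  clicks <- rbind(click_row(600, 1, lay), click_row(2000, 2, lay))
  tr <- make_toy_trial(fix, clicks, lay)
  expect_equal(length(eye_hand_span(tr)), 1)
  # all fixations unassigned: no subtypes, span missing (NA, not zero)
  fix3 <- fix_row(100, 200, 20)
  tr3 <- make_toy_trial(fix3, clicks, lay)
  sc3 <- score_trial(tr3)
  expect_equal(sc3$n_guiding, 0)
  expect_equal(sc3$n_searching, 0)
  expect_equal(sc3$n_fixations, 1)
  expect_true(is.na(sc3$mean_eye_hand_span))
  expect_equal(score_trial(tr3, include_unassigned = FALSE)$n_fixations, 0)
})

test_that("scanpath length is the sum of consecutive centroid distances", {
  fx <- data.frame(x_deg = c(0, 3), y_deg = c(0, 4))
  expect_equal(scanpath_length(fx), 5)
  expect_equal(scanpath_length(fx[1, , drop = FALSE]), 0)
  expect_equal(scanpath_length(data.frame(x_deg = c(0, 1, 2),
                                          y_deg = c(0, 0, 0))), 2)
})

test_that("trial duration converts the trial window to seconds", {
  lay <- target_layout("A", matrix(c(512, 384), 1), labels = "1")
  clicks <- data.frame(t_ms = 72550, x_px = 512, y_px = 384, hit = TRUE,
                       target_index = 1L)
  tr <- trial_record("s01", "A", "speed", 0, 72550,
                     fix_row(100, 200, 0)[0, ],
                     data.frame(onset = numeric(0), offset = numeric(0),
                                duration = numeric(0),
                                amplitude = numeric(0),
                                peak_velocity = numeric(0)),
                     clicks, lay)
  expect_equal(score_trial(tr)$trial_duration, 72.55)
})

test_that("trial integrity violations are rejected", {
  lay <- toy_layout(c(-6, 0))
  clicks <- rbind(click_row(600, 1, lay), click_row(2000, 2, lay))
  fix <- fix_row(100, 200, -6)
  expect_error(make_toy_trial(fix, clicks, lay, end_t = 1800),
               "final hit")
  expect_error(trial_record("s", "A", "speed", 100, 50, fix, fix[0, ],
                            clicks, lay), "start_t")
  # missing hit on target 2
  expect_error(make_toy_trial(fix, clicks[1, ], lay), "advance")
  # event outside the trial window
  fix_out <- fix_row(2100, 200, -6)
  expect_error(make_toy_trial(fix_out, clicks, lay), "outside")
})

test_that("simulated trials satisfy the scoring invariants", {
  lay <- generate_layout("A", layout_config(n_targets = 8), seed = 11)
  for (s in 1:4) {
    tr <- simulate_trial(lay, list(test_type = "A",
                                   instruction = c("accuracy", "speed")[1 + s %% 2]),
                         seed = 100 + s)
    sc <- score_trial(tr)
    fx <- classify_fixations(tr)
    # partition: every fixation has exactly one role
    expect_true(all(fx$role %in% c("guiding", "searching", "unassigned")))
    expect_lte(sc$n_guiding + sc$n_searching, sc$n_fixations)
    sp <- eye_hand_span(tr)
    expect_true(all(sp > 0))
    expect_true(all(sp <= sc$trial_duration))
    expect_gte(sc$scanpath_length, 0)
  }
})

test_that("aggregation averages repeated trials per design cell", {
  sc <- rbind(
    data.frame(subject = "s1", test_type = "A", instruction = "speed",
               trial_duration = c(10, 14), mean_fixation_duration = c(150, 170),
               mean_saccade_amplitude = 5, n_fixations = c(30, 40),
               n_guiding = 10, n_searching = 12,
               mean_eye_hand_span = c(1, NA), scanpath_length = 100))
  ag <- aggregate_scores(sc)
  expect_equal(nrow(ag), 1)
  expect_equal(ag$trial_duration, 12)
  expect_equal(ag$mean_eye_hand_span, 1)  # NA ignored
})
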