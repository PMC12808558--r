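test_that("confidence threshold is inclusive at 0.989", {
  preds <- rbind(pred_row(confidence = 0.989, segment_start = 1),
                 pred_row(confidence = 0.9889, segment_start = 4),
                 pred_row(confidence = 0.9891, segment_start = 7))
  got <- filter_predictions(preds, threshold = 0.989)
  expect_equal(sort(got$confidence), c(0.989, 0.9891))
})

test_that("only the best call per 3-s segment is kept, ties by precedence", {
  preds <- rbind(
    pred_row(call_type = "four-note", confidence = 0.990),
    pred_row(call_type = "contact", confidence = 0.995),
    pred_row(call_type = "crow bark", confidence = 0.991, segment_start = 200),
    pred_row(call_type = "monkey hoot", confidence = 0.991, segment_start = 200))
  got <- filter_predictions(preds, threshold = 0.989)
  expect_equal(nrow(got), 2)
  expect_equal(got$call_type[got$segment_start == 100], "contact")
  # equal confidence: crow bark precedes monkey hoot
  expect_equal(got$call_type[got$segment_start == 200], "crow bark")
})

test_that("call-back exclusion drops events within 1.5 km on the same night", {
  aru <- data.frame(aru_id = c("A1", "A2", "A3"), x = c(0, 1600, 0),
                    y = c(1200, 0, 500))
  cb <- data.frame(x = 0, y = 0, night = as.Date("2021-04-05"))
  preds <- rbind(
    pred_row(aru_id = "A1", segment_start = 1),   # 1.2 km away -> dropped
    pred_row(aru_id = "A2", segment_start = 2),   # 1.6 km away -> kept
    pred_row(aru_id = "A3", segment_start = 3,
             night = as.Date("2021-04-06")))      # different night -> kept
  got <- filter_predictions(preds, threshold = 0.9, callback_surveys = cb,
                            aru_locations = aru)
  expect_setequal(got$aru_id, c("A2", "A3"))
  # boundary inclusive at exactly 1500 m
  aru2 <- data.frame(aru_id = "A1", x = 1500, y = 0)
  got2 <- filter_predictions(pred_row(aru_id = "A1"), threshold = 0.9,
                             callback_surveys = cb, aru_locations = aru2)
  expect_equal(nrow(got2), 0)
  expect_error(filter_predictions(pred_row(), threshold = 0.9,
                                  callback_surveys = cb),
               "aru_locations")
})

test_that("validated false positives are removed and filtering is idempotent", {
  preds <- rbind(pred_row(segment_start = 1, validated = "true-positive"),
                 pred_row(segment_start = 2, validated = "false-positive"),
                 pred_row(segment_start = 3, validated = "unreviewed"))
  got <- filter_predictions(preds, threshold = 0.9)
  expect_equal(nrow(got), 2)
  again <- filter_predictions(got, threshold = 0.9)
  expect_equal(as.data.frame(again), as.data.frame(got),
               ignore_attr = TRUE)
  expect_error(filter_predictions(pred_row(confidence = 1.2)), "malformed")
})

test_that("the >=2-nights rule governs weekly coding", {
  dep <- one_cell_deployment(nights = 126)
  # one detection night only: all surveyed weeks coded 0
  ev1 <- data.frame(cell_id = "C0001", aru_id = "A1",
                    night = as.Date("2021-04-05"))
  h1 <- build_encounter_history(ev1, dep)
  expect_true(all(h1$Y == 0, na.rm = TRUE))
  # two nights in week 5 (Apr 29 .. May 5): week 5 is 1, others 0
  ev2 <- data.frame(cell_id = "C0001", aru_id = "A1",
                    night = as.Date(c("2021-04-30", "2021-05-02")))
  h2 <- build_encounter_history(ev2, dep)
  expect_equal(unname(h2$Y[1, 1, 5]), 1)
  expect_equal(sum(h2$Y, na.rm = TRUE), 1)
  # nights in weeks 3 and 9: both weeks 1
  ev3 <- data.frame(cell_id = "C0001", aru_id = "A1",
                    night = as.Date(c("2021-04-16", "2021-05-28")))
  h3 <- build_encounter_history(ev3, dep)
  expect_equal(unname(h3$Y[1, 1, 3]), 1)
  expect_equal(unname(h3$Y[1, 1, 9]), 1)
  expect_equal(sum(h3$Y, na.rm = TRUE), 2)
})

test_that("unsurveyed weeks are missing and effort is summed across ARUs", {
  dep <- rbind(one_cell_deployment(nights = 14),
               one_cell_deployment(nights = 7, aru_id = "A2"))
  h <- build_encounter_history(NULL, dep)
  expect_equal(unname(h$effort[1, 1, 1]), 7 * 10 + 7 * 10)
  expect_equal(unname(h$effort[1, 1, 2]), 7 * 10)
  expect_true(all(is.na(h$Y[1, 1, 3:18])))
  expect_true(all(h$effort[1, 1, 3:18] == 0))
  # the two nights need not fall in different weeks but may span ARUs
  ev <- data.frame(cell_id = "C0001", aru_id = c("A1", "A2"),
                   night = as.Date(c("2021-04-02", "2021-04-03")))
  h2 <- build_encounter_history(ev, dep)
  expect_equal(unname(h2$Y[1, 1, 1]), 1)
})

test_that("events in zero-effort weeks are a hard error", {
  dep <- one_cell_deployment(nights = 7)
  ev <- data.frame(cell_id = "C0001", aru_id = "A1",
                   night = as.Date(c("2021-04-02", "2021-05-20")))
  expect_error(build_encounter_history(ev, dep), "zero recorded effort")
})

test_that("out-of-season events are dropped with a warning", {
  dep <- one_cell_deployment(nights = 126)
  ev <- data.frame(cell_id = "C0001", aru_id = "A1",
                   night = as.Date(c("2021-04-02", "2021-04-03",
                                     "2021-09-20")))
  expect_warning(h <- build_encounter_history(ev, dep), "outside")
  expect_equal(sum(h$Y, na.rm = TRUE), 1)
})

test_that("encounter histories satisfy their invariants on random fixtures", {
  for (s in 1:5) {
    pip <- small_pipeline(n_cells = 15, seed = 100 + s)
    h <- pip$det$truth
    expect_equal(dim(h$Y)[3], 18)
    expect_true(all(is.na(h$Y) == (h$effort == 0)))
    expect_true(all(h$Y %in% c(0, 1, NA)))
    expect_true(all(h$effort >= 0))
    # constructor enforces the same invariants
    expect_error(encounter_history(h$Y, h$effort * 0, h$site_ids, h$years),
                 "NA where effort")
  }
})

test_that("validation summaries count thresholded records consistently", {
  preds <- rbind(
    do.call(rbind, lapply(1:10, function(i)
      pred_row(segment_start = i, confidence = 0.99,
               validated = "true-positive"))),
    do.call(rbind, lapply(11:13, function(i)
      pred_row(segment_start = i, confidence = 0.995,
               validated = "false-positive"))),
    pred_row(segment_start = 99, confidence = 0.5,
             validated = "false-positive"))
  v <- validation_summary(preds, threshold = 0.989)
  expect_equal(v$reviewed, 13)
  expect_equal(v$true_positive, 10)
  expect_equal(v$false_positive, 3)
  expect_equal(v$reviewed, v$true_positive + v$false_positive + v$unreviewed)
  all_tp <- validation_summary(preds[preds$validated == "true-positive", ])
  expect_equal(all_tp$false_positive, 0)
  none <- validation_summary(transform(preds, confidence = 0.5), 0.989)
  expect_equal(none$reviewed, 0)
})
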