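test_that("landscape generation respects sizes, determinism and forest blocks", {
  one <- gen_landscape(1, 1, seed = 1)
  expect_equal(nrow(one), 1)
  expect_true(all(is.finite(unlist(one[, c("northing", "elevation",
                                           "canopy_height")]))))
  a <- gen_landscape(200, 5, seed = 7)
  b <- gen_landscape(200, 5, seed = 7)
  expect_identical(a, b)
  big <- gen_landscape(800, 7, seed = 2)
  expect_equal(sum(table(big$forest_id)), 800)
  expect_equal(length(unique(big$forest_id)), 7)
  # forests are contiguous along northing
  expect_true(all(diff(big$forest_id[order(big$northing)]) >= 0))
  expect_false(anyDuplicated(big$cell_id) > 0)
  expect_true(all(big$elevation >= 0 & big$canopy_height >= 0))
  expect_error(gen_landscape(0, 1, seed = 1), "must be >= 1")
})

test_that("fire histories have the configured rate, bounds and footprints", {
  cells <- gen_landscape(50, 2, seed = 1)
  expect_equal(nrow(gen_fire_history(cells, 2000:2009, fire_rate = 0,
                                     seed = 1)), 0)
  expect_error(gen_fire_history(cells[0, ], 2000:2009, seed = 1), "empty")
  expect_error(gen_fire_history(cells, c(2000, 2002), seed = 1),
               "contiguous")
  b <- gen_fire_history(cells, 2000:2009, fire_rate = 2, seed = 3)
  expect_true(all(b$fraction >= 0 & b$fraction <= 1))
  expect_true(all(b$fire_year %in% 2000:2009))
  # Monte-Carlo: expected fires per run = fire_rate * n_years
  n_fires <- vapply(1:200, function(s) {
    nrow(gen_fire_history(cells, 2000:2009, fire_rate = 2, seed = s,
                          footprint_size_dist = function(n) rep(3L, n))) / 3
  }, numeric(1))
  expect_lt(abs(mean(n_fires) - 20), 1)
})

test_that("a full-cell fire yields cumulative proportion 1 thereafter", {
  burns <- data.frame(cell_id = "C0001", fire_year = 2010, fraction = 1.0)
  expect_equal(cumulative_high_severity(burns, "C0001", 2015), 1.0)
  expect_equal(cumulative_high_severity(burns, "C0001", 2011), 1.0)
  expect_equal(cumulative_high_severity(burns, "C0001", 2010), 0.0)
})

test_that("occupancy simulation obeys absorbing limits and baseline rates", {
  cells <- gen_landscape(40, 2, seed = 1)
  yrs <- 2021:2024
  all_on <- flat_params(psi = 1 - 1e-12, eps = 1e-12, n_forests = 2)
  # psi = 1, eps = 0: occupancy is absorbing
  z1 <- simulate_occupancy(cells, NULL, all_on, yrs, seed = 2)$z
  expect_true(all(z1 == 1))
  all_off <- flat_params(psi = 1e-12, gamma = 1e-12, n_forests = 2)
  z0 <- simulate_occupancy(cells, NULL, all_off, yrs, seed = 2)$z
  expect_true(all(z0 == 0))
  # baseline gamma = 0.12, eps = 0.39 recovered from 5,000 transitions
  big <- gen_landscape(1000, 1, seed = 1)
  params <- flat_params(n_years = 6)
  z <- simulate_occupancy(big, NULL, params, 2021:2026, seed = 42)$z
  from <- as.vector(z[, -6]); to <- as.vector(z[, -1])
  expect_equal(length(from), 5000)
  expect_lt(abs(mean(to[from == 0]) - 0.12), 0.02)
  expect_lt(abs(mean(1 - to[from == 1]) - 0.39), 0.02)
  # determinism
  z2 <- simulate_occupancy(big, NULL, params, 2021:2026, seed = 42)$z
  expect_identical(z, z2)
})

test_that("detection simulation matches the weekly detection model", {
  cells <- gen_landscape(30, 1, seed = 1)
  yrs <- 2021:2022
  params <- flat_params(psi = 1 - 1e-12, eps = 1e-12, p = 0.55,
                        n_years = 2)
  st <- simulate_occupancy(cells, NULL, params, yrs, seed = 2)
  dep <- gen_deployments(cells, yrs, p_skip = 0, seed = 3)
  det <- simulate_detections(st, dep, params, seed = 4)
  # all sites occupied: weekly detection frequency ~ mean weekly p
  surveyed <- !is.na(det$truth$Y)
  expect_gt(sum(surveyed), 300)
  emp <- mean(det$truth$Y[surveyed])
  expected <- mean(det$p_weekly[surveyed])
  expect_lt(abs(emp - expected), 3 * sqrt(expected * (1 - expected) /
                                            sum(surveyed)))
  # z = 0 everywhere: no events at all
  off <- flat_params(psi = 1e-12, gamma = 1e-12, n_years = 2)
  st0 <- simulate_occupancy(cells, NULL, off, yrs, seed = 2)
  det0 <- simulate_detections(st0, dep, off, seed = 4)
  expect_equal(nrow(det0$events), 0)
  expect_true(all(det0$truth$Y == 0, na.rm = TRUE))
  # weeks without effort are missing in the truth history
  expect_true(all(is.na(det$truth$Y[det$truth$effort == 0])))
})

test_that("deployments outside the season are rejected", {
  cells <- gen_landscape(3, 1, seed = 1)
  params <- flat_params(n_years = 1)
  st <- simulate_occupancy(cells, NULL, params, 2021, seed = 1)
  dep <- one_cell_deployment(start = "-03-15", nights = 10)
  expect_error(simulate_detections(st, dep, params, seed = 1),
               "outside the.*season")
})

test_that("prediction tables round-trip through filtering when clean", {
  pip <- small_pipeline(n_cells = 25, seed = 11,
                        params = flat_params(psi = 0.9, p = 0.7,
                                             n_forests = 3))
  ev <- pip$det$events
  preds <- gen_prediction_table(ev, pip$dep, fp_rate = 0,
                                tp_confidence_dist = function(n) rep(1, n),
                                seed = 5)
  got <- filter_predictions(preds, threshold = 1.0)
  expect_equal(nrow(got), nrow(ev))
  expect_setequal(paste(got$cell_id, got$night),
                  paste(ev$cell_id, ev$night))
  # all confidences 0.5 against threshold 0.989: nothing survives
  preds2 <- gen_prediction_table(ev, pip$dep, fp_rate = 0,
                                 tp_confidence_dist = function(n)
                                   rep(0.5, n), seed = 5)
  expect_equal(nrow(filter_predictions(preds2, threshold = 0.989)), 0)
})

test_that("injected false positives survive thresholding but not validation", {
  dep <- one_cell_deployment(nights = 100)
  ev <- data.frame(cell_id = character(), aru_id = character(),
                   night = as.Date(character()), stringsAsFactors = FALSE)
  preds <- gen_prediction_table(ev, dep, fp_rate = 1,
                                fp_confidence_dist = function(n)
                                  rep(0.999, n), seed = 8)
  expect_gt(nrow(preds), 0)
  expect_true(all(preds$validated == "false-positive"))
  thresholded <- preds[preds$confidence >= 0.989, ]
  expect_equal(nrow(thresholded), nrow(preds))
  expect_equal(nrow(filter_predictions(preds, threshold = 0.989)), 0)
})

test_that("simulated bundle survives the round-trip through the history builder", {
  # high p and a clean prediction table: built history == truth history
  params <- flat_params(psi = 0.7, gamma = 0.3, eps = 0.2, p = 0.995,
                        n_forests = 2)
  pip <- small_pipeline(n_cells = 20, n_forests = 2, params = params,
                        seed = 21, p_skip = 0)
  preds <- gen_prediction_table(pip$det$events, pip$dep, fp_rate = 0,
                                tp_confidence_dist = function(n) rep(1, n),
                                seed = 6)
  ev <- filter_predictions(preds, threshold = 0)
  built <- build_encounter_history(ev, pip$dep)
  expect_equal(built$Y, pip$det$truth$Y)
  expect_equal(built$effort, pip$det$truth$effort)
})
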