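test_that("elevation residualization matches closed-form least squares", {
  # exact linear relation leaves zero residuals
  cells <- data.frame(cell_id = paste0("C", 1:5), northing = 1:5,
                      elevation = 100 + 3 * (1:5))
  expect_equal(residualize_elevation(cells), rep(0, 5), tolerance = 1e-12)
  # three-point fixture solved by hand: slope 2.5, intercept -0.5
  cells3 <- data.frame(cell_id = paste0("C", 1:3), northing = c(0, 1, 2),
                       elevation = c(0, 1, 5))
  r <- residualize_elevation(cells3)
  expect_equal(r, c(0.5, -1, 0.5), tolerance = 1e-12)
  expect_lt(abs(mean(r)), 1e-8 * sd(cells3$elevation))
  # orthogonality to the predictor (defining property of OLS residuals)
  expect_lt(abs(sum(r * cells3$northing)), 1e-10)
  flat <- data.frame(cell_id = paste0("C", 1:4), northing = rep(1, 4),
                     elevation = c(5, 7, 9, 11))
  expect_error(residualize_elevation(flat), "singular")
})

test_that("CBI high-severity classification is inclusive at 2.25", {
  expect_true(classify_high_severity(2.25))
  expect_false(classify_high_severity(2.24))
  expect_true(classify_high_severity(3.0))
  expect_warning(out <- classify_high_severity(c(-0.5, 3.5)), "clamped")
  expect_equal(out, c(FALSE, TRUE))
})

test_that("cumulative burned proportion excludes the monitoring year", {
  burns <- data.frame(cell_id = "C1", fire_year = 2014, fraction = 0.30)
  expect_equal(cumulative_high_severity(burns, "C1", 2021), 0.30)
  this_year <- data.frame(cell_id = "C1", fire_year = 2021, fraction = 0.4)
  expect_equal(cumulative_high_severity(this_year, "C1", 2021), 0)
  expect_error(cumulative_high_severity(
    data.frame(cell_id = "C1", fire_year = 2000, fraction = -0.1),
    "C1", 2021), "negative")
})

test_that("pixel-mask unions agree with a brute-force oracle and with the
           scalar path on disjoint fires", {
  set.seed(4)
  m1 <- matrix(runif(100) < 0.4, 10, 10)
  m2 <- matrix(FALSE, 10, 10)
  # overlap half of the first fire's footprint
  m2[which(m1)[seq_len(sum(m1) / 2)]] <- TRUE
  m2[which(!m1)[1:10]] <- TRUE
  layers <- list(`2010` = m1, `2015` = m2)
  got <- cumulative_high_severity(layers, "C1", 2020)
  # brute force over pixels
  expect_equal(got, mean(m1 | m2))
  # union is strictly smaller than the fraction sum when fires overlap
  expect_lt(got, mean(m1) + mean(m2))
  # a single fire: pixel and scalar paths agree exactly
  d1 <- matrix(FALSE, 10, 10); d1[1:20] <- TRUE
  pix1 <- cumulative_high_severity(list(`2010` = d1), "C1", 2020)
  sca1 <- cumulative_high_severity(
    data.frame(cell_id = "C1", fire_year = 2010, fraction = mean(d1)),
    "C1", 2020)
  expect_equal(pix1, sca1, tolerance = 1e-12)
  # several disjoint fires: the complement-product union is conservative,
  # bounded by the exact pixel union and the fraction sum
  d2 <- matrix(FALSE, 10, 10); d2[51:70] <- TRUE
  pix2 <- cumulative_high_severity(list(`2010` = d1, `2015` = d2),
                                   "C1", 2020)
  sca2 <- cumulative_high_severity(
    data.frame(cell_id = "C1", fire_year = c(2010, 2015),
               fraction = c(mean(d1), mean(d2))), "C1", 2020)
  expect_lte(sca2, pix2)
  expect_lte(sca2, mean(d1) + mean(d2))
  expect_gt(sca2, mean(d1))
})

test_that("cumulative burned proportion is non-decreasing in monitoring year", {
  cells <- gen_landscape(30, 2, seed = 5)
  burns <- gen_fire_history(cells, 1990:2020, fire_rate = 2, seed = 6)
  for (cell in cells$cell_id[c(1, 10, 25)]) {
    ph <- vapply(1995:2024, function(yr)
      cumulative_high_severity(burns, cell, yr), numeric(1))
    expect_true(all(diff(ph) >= 0))
    expect_true(all(ph >= 0 & ph <= 1))
  }
})

test_that("design matrices are standardized with recoverable scaling", {
  pip <- small_pipeline(n_cells = 50, seed = 31)
  des <- pip$det$design
  for (col in c("canopy", "elev", "lat")) {
    x <- des$X_psi[, col]
    expect_lt(abs(mean(x)), 1e-10)
    expect_lt(abs(sd(x) - 1), 1e-10)
  }
  # quadratics are squares of the standardized linear columns
  expect_equal(des$X_psi[, "elev2"], des$X_psi[, "elev"]^2)
  expect_equal(des$X_psi[, "lat2"], des$X_psi[, "lat"]^2)
  # scaling round-trip
  raw <- unstandardize(des, "canopy", des$X_psi[, "canopy"])
  expect_equal(unname(raw), pip$cells$canopy_height, tolerance = 1e-10)
  # detection covariates standardized over surveyed weeks only
  obs <- !is.na(des$X_p[, , , 1])
  expect_lt(abs(mean(des$X_p[, , , 1][obs])), 1e-10)
  expect_lt(abs(sd(des$X_p[, , , 2][obs]) - 1), 1e-6)
})

test_that("transition covariates carry the pre-fire burned proportion", {
  cells <- gen_landscape(10, 1, seed = 1)
  # a single fire in 2022 on cell 1
  burns <- data.frame(cell_id = "C0001", fire_year = 2022, fraction = 0.6)
  des <- build_design(cells, burns, years = 2021:2024)
  # initial-occupancy column sees no fire (before 2021)
  expect_equal(unname(des$prop_hs[, 1]), rep(0, 10))
  # transition 2021 -> 2022 uses fires through 2021: still none
  ph_t1 <- unstandardize(des, "propHS", des$X_gamma[1, 1, "propHS"])
  expect_equal(unname(ph_t1), 0)
  # transition 2022 -> 2023 sees the 2022 fire
  ph_t2 <- unstandardize(des, "propHS", des$X_gamma[1, 2, "propHS"])
  expect_equal(unname(ph_t2), 0.6)
  # year dummies: reference is the first transition year
  expect_equal(unname(des$X_gamma[1, , "yr2022"]), c(0, 1, 0))
  expect_equal(unname(des$X_gamma[1, , "yr2023"]), c(0, 0, 1))
})
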