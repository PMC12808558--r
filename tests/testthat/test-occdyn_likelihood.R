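test_that("inverse-link probabilities behave at zero and at saturation", {
  cells <- gen_landscape(12, 2, seed = 1)
  params <- flat_params(psi = 0.5, gamma = 0.5, eps = 0.5, p = 0.5,
                        n_forests = 2)
  st <- simulate_occupancy(cells, NULL, params, 2021:2024, seed = 2)
  dep <- gen_deployments(cells, 2021:2024, p_skip = 0, seed = 3)
  det <- simulate_detections(st, dep, params, seed = 4)
  pr <- link_probs(params, det$design)
  # all coefficients and intercepts zero on the logit scale: everything 0.5
  expect_true(all(abs(pr$psi - 0.5) < 1e-12))
  expect_true(all(abs(pr$gamma - 0.5) < 1e-12))
  obs <- !is.na(pr$p)
  expect_true(all(abs(pr$p[obs] - 0.5) < 1e-12))
  # detection undefined where effort missing
  expect_true(all(is.na(pr$p[det$design$effort == 0])))
  # extreme linear predictors saturate smoothly instead of overflowing
  sat <- params
  sat$alpha_psi <- rep(1e6, 2)
  pr2 <- link_probs(sat, det$design)
  expect_true(all(pr2$psi > 1 - 1e-12))
  expect_true(all(is.finite(pr2$psi)))
  # more survey effort raises detection monotonically
  eff <- flat_params(p = 0.55, n_forests = 2)
  eff$beta_p[1] <- 0.58
  pr3 <- link_probs(eff, det$design)
  lh <- det$design$X_p[, , , 1]
  o <- !is.na(lh)
  ord <- order(lh[o])
  expect_true(all(diff(pr3$p[o][ord]) >= -1e-12))
  expect_gt(max(pr3$p[o]) - min(pr3$p[o]), 0.05)
})

test_that("single-season single-week likelihood has its closed form", {
  Y <- matrix(1, 1, 1)
  p <- matrix(0.7, 1, 1)
  expect_equal(site_loglik(Y, 0.4, numeric(0), numeric(0), p),
               log(0.4 * 0.7), tolerance = 1e-12)
  Y0 <- matrix(0, 1, 1)
  expect_equal(site_loglik(Y0, 0.4, numeric(0), numeric(0), p),
               log(0.4 * 0.3 + 0.6), tolerance = 1e-12)
  # all-missing history carries no information
  Yna <- matrix(NA_real_, 2, 3)
  pna <- matrix(NA_real_, 2, 3)
  expect_equal(site_loglik(Yna, 0.4, 0.2, 0.3, pna), 0)
  expect_error(site_loglik(matrix(1, 1, 1), 0.4, numeric(0), numeric(0),
                           matrix(NA_real_, 1, 1)), "no effort")
})

test_that("forward recursion equals exhaustive enumeration on random instances", {
  set.seed(99)
  for (i in 1:300) {
    inst <- random_lik_instance()
    got <- site_loglik(inst$Y, inst$psi, inst$gamma, inst$eps, inst$p)
    want <- enum_site_loglik(inst$Y, inst$psi, inst$gamma, inst$eps,
                             inst$p)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("compiled batch likelihood agrees with the per-site recursion", {
  pip <- small_pipeline(n_cells = 30, seed = 51, p_skip = 0)
  h <- pip$det$truth
  des <- pip$det$design
  n <- dim(h$Y)[1]
  pr <- link_probs(pip$params, des)
  per_site <- vapply(seq_len(n), function(i)
    site_loglik(h$Y[i, , ], pr$psi[i], pr$gamma[i, ], pr$eps[i, ],
                pr$p[i, , ]), numeric(1))
  batch <- occ_loglik(pip$params, history = h, design = des,
                      by_site = TRUE)
  expect_equal(batch, per_site, tolerance = 1e-10)
  # permuting site order leaves the total unchanged
  expect_equal(sum(batch), sum(per_site[sample(n)]))
  # an extra all-missing week contributes nothing
  Y2 <- array(NA_real_, dim(h$Y) + c(0, 0, 1))
  E2 <- array(0, dim(Y2))
  Y2[, , 1:18] <- h$Y
  E2[, , 1:18] <- h$effort
  h2 <- encounter_history(Y2, E2, h$site_ids, h$years, 1:19)
  pr2 <- array(NA_real_, dim(Y2))
  per_site2 <- vapply(seq_len(n), function(i) {
    pp <- rbind(cbind(pr$p[i, , ], NA))
    site_loglik(Y2[i, , ], pr$psi[i], pr$gamma[i, ], pr$eps[i, ], pp)
  }, numeric(1))
  expect_equal(per_site2, per_site, tolerance = 1e-12)
})

test_that("with no transitions the model factorizes over independent seasons", {
  # gamma = eps = 0 freezes z: likelihood equals the single-season
  # likelihood of the pooled detection record with shared psi
  set.seed(7)
  psi <- 0.45
  p <- matrix(runif(12, 0.2, 0.8), 3, 4)
  Y <- matrix(rbinom(12, 1, 0.5), 3, 4)
  got <- site_loglik(Y, psi, c(0, 0), c(0, 0), p)
  d1 <- apply(Y * log(p) + (1 - Y) * log(1 - p), 1, sum)
  manual <- log(psi * exp(sum(d1)) +
                  (1 - psi) * as.numeric(all(Y == 0)))
  expect_equal(got, manual, tolerance = 1e-12)
})

test_that("analytic likelihood gradient matches central differences", {
  pip <- small_pipeline(n_cells = 20, seed = 61)
  dat <- prep_occ_data(pip$det$truth, pip$det$design)
  p <- pip$params
  g <- pamdyn:::.occ_loglik_grad_cpp(dat, p$beta_psi, p$beta_gamma,
                                     p$beta_eps, p$beta_p, p$alpha_psi,
                                     p$alpha_gamma, p$alpha_eps, p$alpha_p)
  ana <- c(g$gbpsi, g$gbgam, g$gbeps, g$gbp, g$gapsi, g$gagam, g$gaeps,
           g$gap)
  th <- pamdyn:::flatten_params(p)
  dims <- attr(th, "dims")
  nlik <- length(ana)
  f <- function(theta) occ_loglik(pamdyn:::unflatten_params(theta, dims),
                                  dat)
  num <- vapply(seq_len(nlik), function(k) {
    e <- rep(0, length(th)); e[k] <- 1e-5
    (f(unname(th) + e) - f(unname(th) - e)) / 2e-5
  }, numeric(1))
  expect_equal(ana, num, tolerance = 1e-6)
  expect_equal(g$loglik, f(unname(th)), tolerance = 1e-10)
})

test_that("priors have the documented shape", {
  params <- flat_params()
  base <- log_prior(params)
  expect_true(is.finite(base))
  # moving one coefficient from 0 to x costs x^2 / (2 * 2.5^2)
  p2 <- params
  p2$beta_psi[1] <- 2
  expect_equal(base - log_prior(p2), 2^2 / (2 * 2.5^2), tolerance = 1e-12)
  # half-Cauchy keeps density finite as sigma -> 0+
  p3 <- params
  p3$sigma_psi <- 1e-10
  expect_true(is.finite(log_prior(p3)))
  expect_error(occ_params(beta_psi = rep(0, 6), beta_gamma = 0,
                          beta_eps = 0, beta_p = rep(0, 3),
                          alpha_psi = 0, alpha_gamma = 0, alpha_eps = 0,
                          alpha_p = 0, sigma_psi = -1),
               "strictly positive")
})
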