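#' Parameter vector for the dynamic occupancy model
#'
#' Collects every coefficient of the four submodels (initial occupancy,
#' colonization, extinction, detection), the forest-level random intercepts
#' and their hierarchical means and standard deviations.
#'
#' All coefficients act on *standardized* covariates (see
#' [build_design()]), so their scale matches how field studies report
#' logit-scale effect sizes.
#'
#' @param beta_psi numeric(6): canopy, elev, elev2, lat, lat2, propHS.
#' @param beta_gamma,beta_eps numeric(1 + n_trans_years): propHS followed by
#'   year dummies for the second and later transition start years.
#' @param beta_p numeric(3 + n_det_years): log_hours, date, date2 followed
#'   by year dummies for the second and later survey years.
#' @param alpha_psi,alpha_gamma,alpha_eps,alpha_p numeric(F) forest-level
#'   intercepts on the logit scale (one per forest, submodel-specific).
#' @param mu_psi,mu_gamma,mu_eps,mu_p hierarchical means of the forest
#'   intercepts.
#' @param sigma_psi,sigma_gamma,sigma_eps,sigma_p hierarchical SDs of the
#'   forest intercepts; must be strictly positive.
#' @return an object of class `occ_params`.
#' @export
occ_params <- function(beta_psi, beta_gamma, beta_eps, beta_p,
                       alpha_psi, alpha_gamma, alpha_eps, alpha_p,
                       mu_psi = 0, mu_gamma = 0, mu_eps = 0, mu_p = 0,
                       sigma_psi = 1, sigma_gamma = 1, sigma_eps = 1,
                       sigma_p = 1) {
  p <- list(
    beta_psi = as.numeric(beta_psi),
    beta_gamma = as.numeric(beta_gamma),
    beta_eps = as.numeric(beta_eps),
    beta_p = as.numeric(beta_p),
    alpha_psi = as.numeric(alpha_psi),
    alpha_gamma = as.numeric(alpha_gamma),
    alpha_eps = as.numeric(alpha_eps),
    alpha_p = as.numeric(alpha_p),
    mu_psi = as.numeric(mu_psi), mu_gamma = as.numeric(mu_gamma),
    mu_eps = as.numeric(mu_eps), mu_p = as.numeric(mu_p),
    sigma_psi = as.numeric(sigma_psi), sigma_gamma = as.numeric(sigma_gamma),
    sigma_eps = as.numeric(sigma_eps), sigma_p = as.numeric(sigma_p)
  )
  sds <- unlist(p[grep("^sigma_", names(p))])
  if (any(!is.finite(sds)) || any(sds <= 0)) {
    stop("random-intercept SDs must be strictly positive")
  }
  nf <- vapply(p[c("alpha_psi", "alpha_gamma", "alpha_eps", "alpha_p")],
               length, integer(1))
  if (length(unique(nf)) != 1L) {
    stop("all four alpha vectors must have the same length (one per forest)")
  }
  structure(p, class = "occ_params")
}

#' Study-calibrated simulation preset
#'
#' Parameter values matching the study system this package was built around:
#' a ~30% initially occupied landscape with baseline annual colonization
#' 0.12, baseline annual extinction 0.39, weekly detection probability
#' around 0.6 at mean covariates, strong positive canopy-height and negative
#' high-severity-fire effects. Fire effects are beta_propHS = -0.19 (initial
#' occupancy), -0.77 (colonization), +0.73 (extinction) on the standardized
#' logit scale.
#'
#' @param n_forests number of forest units (random-intercept groups).
#' @param n_years number of monitored years (primary occasions).
#' @param sigma_forest common SD of the forest-level intercepts used to
#'   draw the alphas around their submodel means.
#' @param seed optional seed for drawing the forest intercepts; when `NULL`
#'   the alphas are set exactly to their submodel means.
#' @return an `occ_params` object.
#' @export
owl_preset <- function(n_forests = 7, n_years = 4, sigma_forest = 0.3,
                       seed = NULL) {
  mu <- c(psi = stats::qlogis(0.30), gamma = stats::qlogis(0.12),
          eps = stats::qlogis(0.39), p = stats::qlogis(0.60))
  if (is.null(seed)) {
    a <- lapply(mu, function(m) rep(m, n_forests))
  } else {
    set.seed(seed)
    a <- lapply(mu, function(m) stats::rnorm(n_forests, m, sigma_forest))
  }
  n_ty_trans <- max(n_years - 2L, 0L)  # year dummies for transitions
  n_ty_det <- max(n_years - 1L, 0L)    # year dummies for detection
  yr_gamma <- c(0.28, -0.36)           # start years 2 and 3
  yr_eps <- c(-0.13, -0.15)
  yr_p <- c(0, 0, -0.17)               # survey years 2..4
  occ_params(
    beta_psi = c(canopy = 1.14, elev = -0.24, elev2 = -0.43,
                 lat = -0.89, lat2 = -0.21, propHS = -0.19),
    beta_gamma = c(propHS = -0.77, rep_len(yr_gamma, n_ty_trans)),
    beta_eps = c(propHS = 0.73, rep_len(yr_eps, n_ty_trans)),
    beta_p = c(log_hours = 0.58, date = 0.01, date2 = -0.17,
               rep_len(yr_p, n_ty_det)),
    alpha_psi = a$psi, alpha_gamma = a$gamma,
    alpha_eps = a$eps, alpha_p = a$p,
    mu_psi = mu[["psi"]], mu_gamma = mu[["gamma"]],
    mu_eps = mu[["eps"]], mu_p = mu[["p"]],
    sigma_psi = sigma_forest, sigma_gamma = sigma_forest,
    sigma_eps = sigma_forest, sigma_p = sigma_forest
  )
}

# Flatten params to an unconstrained vector (SDs on log scale) and back.
# Used by the MAP optimizer; order is stable and recorded in names.
flatten_params <- function(params) {
  stopifnot(inherits(params, "occ_params"))
  th <- c(
    bpsi = params$beta_psi, bgam = params$beta_gamma,
    beps = params$beta_eps, bp = params$beta_p,
    apsi = params$alpha_psi, agam = params$alpha_gamma,
    aeps = params$alpha_eps, ap = params$alpha_p,
    mu = c(params$mu_psi, params$mu_gamma, params$mu_eps, params$mu_p),
    lsig = log(c(params$sigma_psi, params$sigma_gamma,
                 params$sigma_eps, params$sigma_p))
  )
  attr(th, "dims") <- list(
    k_psi = length(params$beta_psi), k_gamma = length(params$beta_gamma),
    k_eps = length(params$beta_eps), k_p = length(params$beta_p),
    n_forests = length(params$alpha_psi)
  )
  th
}

unflatten_params <- function(theta, dims) {
  i <- 0L
  take <- function(k) {
    out <- theta[(i + 1L):(i + k)]
    i <<- i + k
    unname(out)
  }
  f <- dims$n_forests
  occ_params(
    beta_psi = take(dims$k_psi), beta_gamma = take(dims$k_gamma),
    beta_eps = take(dims$k_eps), beta_p = take(dims$k_p),
    alpha_psi = take(f), alpha_gamma = take(f),
    alpha_eps = take(f), alpha_p = take(f),
    mu_psi = take(1), mu_gamma = take(1), mu_eps = take(1), mu_p = take(1),
    sigma_psi = exp(take(1)), sigma_gamma = exp(take(1)),
    sigma_eps = exp(take(1)), sigma_p = exp(take(1))
  )
}
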