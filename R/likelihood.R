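clip_eta <- function(eta) pmin(pmax(eta, -35), 35)

#' Link-scale probabilities for all four submodels
#'
#' Applies the inverse-logit to the four linear predictors of the model:
#' initial occupancy psi_i, colonization gamma_(i,t), extinction
#' eps_(i,t) and weekly detection p_(i,t,j). Linear predictors are clipped
#' at +/-35 before exponentiation so the returned probabilities are always
#' inside (0, 1). Detection probabilities are `NA` for unsurveyed
#' cell-weeks.
#'
#' @param params an [occ_params()].
#' @param design an `occ_design` from [build_design()].
#' @return list with psi (n), gamma and eps (n x T-1), p (n x T x J or
#'   `NULL` when the design has no detection component).
#' @export
link_probs <- function(params, design) {
  f <- design$forest
  if (length(params$alpha_psi) < design$n_forests) {
    stop("params have fewer forest intercepts than the design has forests")
  }
  eta_psi <- params$alpha_psi[f] +
    drop(design$X_psi %*% params$beta_psi)
  check_eta <- function(e, what) {
    if (any(!is.finite(e[!is.na(e)]))) {
      stop("non-finite linear predictor in ", what, " submodel")
    }
    e
  }
  psi <- stats::plogis(clip_eta(check_eta(eta_psi, "initial occupancy")))
  gamma <- eps <- NULL
  T <- length(design$years)
  if (!is.null(design$X_gamma)) {
    n <- nrow(design$X_psi)
    gamma <- eps <- matrix(NA_real_, n, T - 1)
    for (t in seq_len(T - 1)) {
      eg <- params$alpha_gamma[f] +
        drop(matrix(design$X_gamma[, t, ], nrow = n) %*% params$beta_gamma)
      ee <- params$alpha_eps[f] +
        drop(matrix(design$X_eps[, t, ], nrow = n) %*% params$beta_eps)
      gamma[, t] <- stats::plogis(clip_eta(check_eta(eg, "colonization")))
      eps[, t] <- stats::plogis(clip_eta(check_eta(ee, "extinction")))
    }
  }
  p <- NULL
  if (!is.null(design$X_p)) {
    dm <- dim(design$X_p)
    Xp <- matrix(design$X_p, prod(dm[1:3]), dm[4])
    eta_p <- params$alpha_p[f] + drop(Xp %*% params$beta_p)  # f recycles
    obs <- !is.na(eta_p)
    if (any(!is.finite(eta_p[obs]))) {
      stop("non-finite linear predictor in detection submodel")
    }
    p <- array(NA_real_, dm[1:3])
    p[obs] <- stats::plogis(clip_eta(eta_p[obs]))
    dimnames(p) <- dimnames(design$effort)
  }
  list(psi = psi, gamma = gamma, eps = eps, p = p)
}

#' Marginal log-likelihood of one site's encounter history
#'
#' Forward recursion over the latent occupancy state z in {0, 1}: the
#' per-year detection likelihood is `prod_j p^y (1-p)^(1-y)` given z = 1
#' (missing weeks contribute a factor of 1) and the indicator that no
#' detection occurred given z = 0; years are chained through the transition
#' matrix `[1-gamma, gamma; eps, 1-eps]`. Computed in log space with
#' per-year scaling so long histories do not underflow.
#'
#' This is the plain-R reference implementation; the batch likelihood used
#' in fitting ([occ_loglik()]) is compiled code tested against it.
#'
#' @param Y_i years x weeks matrix in {0, 1, NA}.
#' @param psi_i scalar initial occupancy probability.
#' @param gamma_i,eps_i transition probabilities, length T-1.
#' @param p_i years x weeks matrix of detection probabilities (NA where the
#'   week is unsurveyed).
#' @return log-likelihood scalar.
#' @export
site_loglik <- function(Y_i, psi_i, gamma_i, eps_i, p_i) {
  Y_i <- rbind(Y_i); p_i <- rbind(p_i)
  T <- nrow(Y_i)
  if (any(Y_i == 1 & is.na(p_i), na.rm = TRUE)) {
    stop("detection recorded in a week with no effort")
  }
  p_i <- pmin(pmax(p_i, 1e-12), 1 - 1e-12)
  a <- c(1 - psi_i, psi_i)
  acc <- 0
  for (t in seq_len(T)) {
    if (t > 1) {
      a <- c(a[1] * (1 - gamma_i[t - 1]) + a[2] * eps_i[t - 1],
             a[1] * gamma_i[t - 1] + a[2] * (1 - eps_i[t - 1]))
    }
    obs <- !is.na(Y_i[t, ]) & !is.na(p_i[t, ])
    y <- Y_i[t, obs]; p <- p_i[t, obs]
    logd1 <- sum(y * log(p) + (1 - y) * log1p(-p))
    logd0 <- if (any(y == 1)) -Inf else 0
    m <- max(logd1, logd0)
    a <- a * exp(c(logd0, logd1) - m)
    s <- sum(a)
    acc <- acc + m + log(s)
    a <- a / s
  }
  acc
}

#' Prepare the likelihood data block
#'
#' Packs an encounter history and design into the flat structure the
#' compiled likelihood consumes. Build it once and reuse it across
#' likelihood evaluations (the optimizer does this internally).
#'
#' @param history an [encounter_history()].
#' @param design matching `occ_design`.
#' @return opaque list for [occ_loglik()].
#' @export
prep_occ_data <- function(history, design) {
  n <- dim(history$Y)[1]; T <- dim(history$Y)[2]; J <- dim(history$Y)[3]
  stopifnot(nrow(design$X_psi) == n, length(design$years) == T)
  obs <- which(!is.na(history$Y))
  idx <- arrayInd(obs, dim(history$Y))
  dm <- dim(design$X_p)
  Xp_full <- matrix(design$X_p, prod(dm[1:3]), dm[4])
  Xp <- Xp_full[obs, , drop = FALSE]
  if (any(is.na(Xp))) stop("design has NA detection covariates where Y is ",
                           "observed")
  if (T > 1) {
    Xg <- matrix(design$X_gamma, n * (T - 1), dim(design$X_gamma)[3])
    Xe <- matrix(design$X_eps, n * (T - 1), dim(design$X_eps)[3])
  } else {
    Xg <- Xe <- matrix(0, 0, 1)  # single season: no transitions
  }
  list(n = n, T = T, forest = as.integer(design$forest),
       Xpsi = design$X_psi, Xgam = Xg, Xeps = Xe,
       det_site = as.integer(idx[, 1]), det_year = as.integer(idx[, 2]),
       det_y = as.integer(history$Y[obs]),
       Xp_t = t(Xp),  # transposed for contiguous per-row access
       Xp = Xp,
       k = list(k_psi = ncol(design$X_psi), k_gamma = ncol(Xg),
                k_eps = ncol(Xe), k_p = ncol(Xp),
                n_forests = design$n_forests))
}

#' Batch marginal log-likelihood
#'
#' Total (or per-site) marginalized log-likelihood of an encounter history,
#' computed by the compiled forward recursion.
#'
#' @param params an [occ_params()].
#' @param data likelihood block from [prep_occ_data()] (or pass `history`
#'   and `design` and it is built on the fly).
#' @param history,design alternative inputs when `data` is `NULL`.
#' @param by_site return the per-site vector instead of the sum.
#' @return numeric scalar (or vector when `by_site = TRUE`).
#' @export
occ_loglik <- function(params, data = NULL, history = NULL, design = NULL,
                       by_site = FALSE) {
  if (is.null(data)) data <- prep_occ_data(history, design)
  ll <- .occ_loglik_cpp(data, params$beta_psi, params$beta_gamma,
                        params$beta_eps, params$beta_p,
                        params$alpha_psi, params$alpha_gamma,
                        params$alpha_eps, params$alpha_p)
  if (by_site) ll else sum(ll)
}

#' Default weakly informative prior configuration
#'
#' Coefficients get Normal(0, 2.5) priors; forest-level intercepts are
#' Normal(mu, sigma) with hierarchical mean mu ~ Normal(0, 5) and SD
#' sigma ~ half-Cauchy(0, 2.5), per submodel. All scales are configurable.
#'
#' @param beta_sd SD of the coefficient priors.
#' @param mu_sd SD of the prior on the hierarchical intercept means.
#' @param sigma_scale scale of the half-Cauchy prior on random-intercept
#'   SDs.
#' @return list used by [log_prior()], [fit_map()], [sample_posterior()].
#' @export
prior_config <- function(beta_sd = 2.5, mu_sd = 5, sigma_scale = 2.5) {
  list(beta_sd = beta_sd, mu_sd = mu_sd, sigma_scale = sigma_scale)
}

#' Log prior density of a parameter vector
#'
#' @param params an [occ_params()].
#' @param config a [prior_config()].
#' @return log prior density (`-Inf` for non-positive SDs).
#' @export
log_prior <- function(params, config = prior_config()) {
  betas <- c(params$beta_psi, params$beta_gamma, params$beta_eps,
             params$beta_p)
  lp <- sum(stats::dnorm(betas, 0, config$beta_sd, log = TRUE))
  for (s in c("psi", "gamma", "eps", "p")) {
    sig <- params[[paste0("sigma_", s)]]
    if (!is.finite(sig) || sig <= 0) return(-Inf)
    mu <- params[[paste0("mu_", s)]]
    a <- params[[paste0("alpha_", s)]]
    lp <- lp + sum(stats::dnorm(a, mu, sig, log = TRUE)) +
      stats::dnorm(mu, 0, config$mu_sd, log = TRUE) +
      log(2) + stats::dcauchy(sig, 0, config$sigma_scale, log = TRUE)
  }
  lp
}

#' Log posterior (unnormalized)
#'
#' @inheritParams occ_loglik
#' @param config a [prior_config()].
#' @return scalar log posterior.
#' @export
log_posterior <- function(params, data = NULL, history = NULL,
                          design = NULL, config = prior_config()) {
  lp <- log_prior(params, config)
  if (!is.finite(lp)) return(lp)
  lp + occ_loglik(params, data, history, design)
}
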