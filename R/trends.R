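#' Project per-cell occupancy trajectories from posterior draws
#'
#' For each draw, computes the *projected* (unconditional on the observed
#' detections) occupancy trajectory:
#' `psi[i,1]` from the initial submodel, then
#' `psi[i,t+1] = psi[i,t](1 - eps[i,t]) + (1 - psi[i,t]) gamma[i,t]`.
#'
#' @param draws an `occ_draws`, or a list of [occ_params()] (one per draw).
#' @param design an `occ_design` covering all cells and years.
#' @param draw_ids optional subset of draw indices.
#' @return array draws x sites x years.
#' @export
project_occupancy <- function(draws, design, draw_ids = NULL) {
  plist <- if (inherits(draws, "occ_draws")) {
    if (is.null(draw_ids)) draw_ids <- seq_len(nrow(draws$draws))
    lapply(draw_ids, function(i) draw_params(draws, i))
  } else {
    if (!is.null(draw_ids)) draws[draw_ids] else draws
  }
  n <- nrow(design$X_psi); T <- length(design$years)
  out <- array(NA_real_, c(length(plist), n, T),
               dimnames = list(NULL, design$site_ids, design$years))
  for (d in seq_along(plist)) {
    pr <- link_probs(plist[[d]], design)
    psi <- pr$psi
    out[d, , 1] <- psi
    if (T > 1) for (t in 2:T) {
      psi <- psi * (1 - pr$eps[, t - 1]) + (1 - psi) * pr$gamma[, t - 1]
      out[d, , t] <- psi
    }
  }
  out
}

#' Single-trajectory projection from fixed probabilities
#'
#' Deterministic helper: chains an initial occupancy through constant (or
#' per-interval) colonization/extinction probabilities.
#'
#' @param psi1 initial occupancy.
#' @param gamma,eps colonization/extinction, scalars or length T-1.
#' @param n_years trajectory length.
#' @return numeric vector of length `n_years`.
#' @export
project_trajectory <- function(psi1, gamma, eps, n_years) {
  gamma <- rep_len(gamma, n_years - 1)
  eps <- rep_len(eps, n_years - 1)
  out <- numeric(n_years)
  out[1] <- psi1
  for (t in seq_len(n_years - 1)) {
    out[t + 1] <- out[t] * (1 - eps[t]) + (1 - out[t]) * gamma[t]
  }
  out
}

#' Group-level occupancy trajectories
#'
#' Averages projected per-cell occupancy over cell groups, per posterior
#' draw, then summarizes (posterior mean and central 95% interval per
#' year).
#'
#' @param psi_draws array draws x sites x years from [project_occupancy()].
#' @param cell_groups named list of cell index vectors (or a factor /
#'   character vector of group labels, one per cell).
#' @return named list, one element per group: `draws` (draws x years
#'   matrix of group-mean occupancy) and `summary` (data.frame year, mean,
#'   lo95, hi95).
#' @export
group_trajectory <- function(psi_draws, cell_groups) {
  n <- dim(psi_draws)[2]
  if (!is.list(cell_groups)) {
    f <- as.factor(cell_groups)
    stopifnot(length(f) == n)
    cell_groups <- split(seq_len(n), f)
  }
  years <- dimnames(psi_draws)[[3]]
  lapply(cell_groups, function(idx) {
    if (!length(idx)) stop("empty cell group")
    m <- apply(psi_draws[, idx, , drop = FALSE], c(1, 3), mean)
    s <- data.frame(
      year = if (is.null(years)) seq_len(ncol(m)) else as.integer(years),
      mean = colMeans(m),
      lo95 = apply(m, 2, stats::quantile, 0.025),
      hi95 = apply(m, 2, stats::quantile, 0.975), row.names = NULL)
    list(draws = m, summary = s)
  })
}

#' Fire-severity strata for grouping cells
#'
#' Assigns each cell to one of three strata by the cumulative proportion
#' burned at high severity evaluated at a reference year: `unburned`
#' (exactly 0), `lt_0.5` (positive but below one half) and `ge_0.5` (one
#' half or more). Membership is evaluated at a single reference year
#' because the burned proportion is time-varying; the default is the final
#' monitoring year.
#'
#' @param design an `occ_design` (carries the raw burned-proportion
#'   matrix).
#' @param reference_year year at which to evaluate membership.
#' @return factor of length n with levels unburned, lt_0.5, ge_0.5.
#' @export
fire_strata <- function(design, reference_year = NULL) {
  if (is.null(design$prop_hs)) stop("design carries no burned-proportion ",
                                    "matrix")
  if (is.null(reference_year)) {
    reference_year <- design$years[length(design$years)]
  }
  k <- match(reference_year, design$years)
  if (is.na(k)) stop("reference_year outside the design years")
  ph <- design$prop_hs[, k]
  factor(ifelse(ph == 0, "unburned", ifelse(ph < 0.5, "lt_0.5", "ge_0.5")),
         levels = c("unburned", "lt_0.5", "ge_0.5"))
}

#' Mean annual rate of change in occupancy (lambda-bar)
#'
#' Per posterior draw, the annual rate `lambda_t = psibar[t+1] / psibar[t]`
#' over the group-mean occupancy trajectory, and their arithmetic mean
#' `lambda_bar = mean(lambda_t)` across the T-1 intervals. Values below one
#' indicate a declining number of occupied sites. The probability of a
#' declining trend is the fraction of draws with `lambda_bar < 1`.
#'
#' @param group_psi_draws draws x years matrix of group-mean occupancy.
#' @return list: lambda_t (draws x T-1), lambda_bar (draws), summary
#'   (mean, lo95, hi95), pd_decline, pd (probability of direction relative
#'   to 1, with sign attribute).
#' @export
lambda_bar <- function(group_psi_draws) {
  m <- as.matrix(group_psi_draws)
  T <- ncol(m)
  if (T < 2) stop("need >= 2 years for a trend")
  if (any(m == 0)) stop("zero mean occupancy in a draw: lambda undefined")
  lt <- m[, -1, drop = FALSE] / m[, -T, drop = FALSE]
  lb <- rowMeans(lt)
  pdd <- mean(lb < 1) + 0.5 * mean(lb == 1)
  list(lambda_t = lt, lambda_bar = lb,
       summary = c(mean = mean(lb),
                   lo95 = unname(stats::quantile(lb, 0.025)),
                   hi95 = unname(stats::quantile(lb, 0.975))),
       pd_decline = pdd,
       pd = prob_direction(lb, reference = 1))
}

#' Probability of direction
#'
#' The fraction of a posterior sample on the dominant side of a reference
#' value - an index of effect existence and direction in [0.5, 1]. Draws
#' exactly at the reference are split evenly.
#'
#' @param draws_of_scalar numeric posterior draws.
#' @param reference reference value (0 for effects, 1 for rates).
#' @return numeric in [0.5, 1] with attribute `sign` ("positive" or
#'   "negative" for the dominant side).
#' @export
prob_direction <- function(draws_of_scalar, reference = 0) {
  x <- draws_of_scalar
  if (!length(x)) stop("need at least one draw")
  p_gt <- mean(x > reference) + 0.5 * mean(x == reference)
  pd <- max(p_gt, 1 - p_gt)
  attr(pd, "sign") <- if (p_gt >= 0.5) "positive" else "negative"
  pd
}

#' Cumulative detection probability over repeated occasions
#'
#' Probability of at least one detection over `n_weeks` independent weekly
#' occasions, `p* = 1 - (1 - p)^n`. Vectorized over `p`, so it can be
#' applied per posterior draw and then summarized.
#'
#' @param p_weekly weekly detection probability in [0, 1].
#' @param n_weeks number of occasions (>= 0).
#' @return cumulative detection probability.
#' @export
cumulative_detection <- function(p_weekly, n_weeks) {
  if (any(p_weekly < 0 | p_weekly > 1)) stop("p must be in [0, 1]")
  if (any(n_weeks < 0)) stop("n_weeks must be >= 0")
  1 - (1 - p_weekly)^n_weeks
}

#' Mean posterior coefficient of variation of group occupancy
#'
#' CV = posterior SD / posterior mean of group-mean occupancy, per
#' group-year; returns the mean over all group-years (a precision summary
#' for the estimated trajectories).
#'
#' @param group_trajectories result of [group_trajectory()], or a single
#'   draws x years matrix.
#' @return mean CV (scalar).
#' @export
cv_summary <- function(group_trajectories) {
  if (is.matrix(group_trajectories)) {
    group_trajectories <- list(list(draws = group_trajectories))
  }
  cvs <- unlist(lapply(group_trajectories, function(g) {
    mu <- colMeans(g$draws)
    if (any(mu == 0)) stop("zero posterior mean occupancy: CV undefined")
    apply(g$draws, 2, stats::sd) / mu
  }))
  mean(cvs)
}
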