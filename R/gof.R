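# chi-square over detection-history cohorts for one dataset, given the
# projected occupancy and detection probabilities of one parameter draw.
# Cohorts are formed per year and per missingness pattern; the expected
# count of a history h within a pattern group is the sum over the group's
# sites of P(h | site). Cohorts with expected count <= eps, and the
# never-observed remainder of each pattern group, are pooled.
mb_chisq <- function(Y, proj, p, eps = 1e-6) {
  n <- dim(Y)[1]; T <- dim(Y)[2]
  chi2 <- 0
  for (t in seq_len(T)) {
    yt <- Y[, t, , drop = TRUE]
    if (is.null(dim(yt))) yt <- matrix(yt, n)
    pt <- p[, t, , drop = TRUE]
    if (is.null(dim(pt))) pt <- matrix(pt, n)
    miss <- is.na(yt)
    surveyed <- rowSums(!miss) > 0
    if (!any(surveyed)) next
    pattern <- apply(miss, 1, paste, collapse = "")
    hist_str <- apply(yt, 1, function(r)
      paste(ifelse(is.na(r), ".", r), collapse = ""))
    for (pat in unique(pattern[surveyed])) {
      grp <- which(pattern == pat & surveyed)
      obs_w <- !miss[grp[1], ]
      hs <- unique(hist_str[grp])
      O <- as.numeric(table(factor(hist_str[grp], levels = hs)))
      # P(h | site i): marginal over the latent state at year t
      E <- vapply(hs, function(h) {
        yv <- as.integer(strsplit(h, "")[[1]][obs_w])
        sum(vapply(grp, function(i) {
          pw <- pt[i, obs_w]
          d1 <- prod(ifelse(yv == 1, pw, 1 - pw))
          d0 <- as.numeric(all(yv == 0))
          proj[i, t] * d1 + (1 - proj[i, t]) * d0
        }, numeric(1)))
      }, numeric(1))
      pool_O <- 0
      pool_E <- length(grp) - sum(E)  # mass of never-observed histories
      keep <- E > eps
      chi2 <- chi2 + sum((O[keep] - E[keep])^2 / E[keep])
      pool_O <- pool_O + sum(O[!keep])
      pool_E <- pool_E + sum(E[!keep])
      if (pool_E > eps) chi2 <- chi2 + (pool_O - pool_E)^2 / pool_E
    }
  }
  chi2
}

# simulate a replicate encounter history from one parameter draw, keeping
# the observed missingness pattern
sim_replicate_Y <- function(Y, pr) {
  n <- dim(Y)[1]; T <- dim(Y)[2]; J <- dim(Y)[3]
  z <- matrix(0L, n, T)
  z[, 1] <- stats::rbinom(n, 1, pr$psi)
  if (T > 1) for (t in 2:T) {
    z[, t] <- stats::rbinom(n, 1, z[, t - 1] * (1 - pr$eps[, t - 1]) +
                              (1 - z[, t - 1]) * pr$gamma[, t - 1])
  }
  Yr <- array(NA_real_, dim(Y))
  obs <- !is.na(Y)
  zexp <- array(rep(z, J), dim(Y))
  Yr[obs] <- stats::rbinom(sum(obs), 1, (zexp * pr$p)[obs])
  Yr
}

#' MacKenzie-Bailey posterior predictive check
#'
#' For each sampled posterior draw, computes the chi-square fit statistic
#' over observed detection-history cohorts (grouped per year and
#' missingness pattern, expected counts from the draw's projected occupancy
#' and detection probabilities, small cohorts pooled), simulates a
#' replicate dataset from the same draw, and computes the statistic on the
#' replicate. The Bayesian p-value is the fraction of replicates whose
#' statistic is at least the observed one; values far from 0.5 (outside
#' roughly 0.05-0.95) indicate lack of fit.
#'
#' @param draws an `occ_draws`.
#' @param history the fitted [encounter_history()].
#' @param design matching `occ_design`.
#' @param n_reps number of posterior draws to use (< 50 triggers a
#'   warning: the p-value becomes unstable).
#' @param seed RNG seed for draw selection and replicate simulation.
#' @return list of class `occ_gof`: p_value, chi2_obs, chi2_rep, draw_ids.
#' @export
mb_chisq_ppc <- function(draws, history, design, n_reps = 100, seed = 1) {
  if (n_reps < 50) warning("n_reps < 50: Bayesian p-value will be unstable")
  set.seed(seed)
  n_avail <- nrow(draws$draws)
  ids <- if (n_reps >= n_avail) seq_len(n_avail) else
    sort(sample.int(n_avail, n_reps))
  Y <- history$Y
  chi_obs <- chi_rep <- numeric(length(ids))
  for (k in seq_along(ids)) {
    params <- draw_params(draws, ids[k])
    pr <- link_probs(params, design)
    # projected (unconditional) occupancy per site-year
    proj <- matrix(NA_real_, dim(Y)[1], dim(Y)[2])
    proj[, 1] <- pr$psi
    if (dim(Y)[2] > 1) for (t in 2:dim(Y)[2]) {
      proj[, t] <- proj[, t - 1] * (1 - pr$eps[, t - 1]) +
        (1 - proj[, t - 1]) * pr$gamma[, t - 1]
    }
    chi_obs[k] <- mb_chisq(Y, proj, pr$p)
    Yr <- sim_replicate_Y(Y, pr)
    chi_rep[k] <- mb_chisq(Yr, proj, pr$p)
  }
  structure(list(p_value = mean(chi_rep >= chi_obs),
                 chi2_obs = chi_obs, chi2_rep = chi_rep, draw_ids = ids),
            class = "occ_gof")
}

#' @export
print.occ_gof <- function(x, ...) {
  cat(sprintf(
    "MacKenzie-Bailey posterior predictive check: Bayesian p = %.3f (%d draws)\n",
    x$p_value, length(x$draw_ids)))
  invisible(x)
}
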