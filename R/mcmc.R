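occ_jags_model <- function() {
  paste(
    "model {",
    "  for (k in 1:Kpsi) { bpsi[k] ~ dnorm(0, prec_b) }",
    "  for (k in 1:Kgam) { bgam[k] ~ dnorm(0, prec_b) }",
    "  for (k in 1:Keps) { beps[k] ~ dnorm(0, prec_b) }",
    "  for (k in 1:Kp)   { bp[k]   ~ dnorm(0, prec_b) }",
    "  for (s in 1:4) {",
    "    mu[s] ~ dnorm(0, prec_mu)",
    "    sig[s] ~ dt(0, prec_sig, 1) T(0,)",
    "    tau[s] <- pow(sig[s], -2)",
    "  }",
    "  for (f in 1:F) { for (s in 1:4) { a[f, s] ~ dnorm(mu[s], tau[s]) } }",
    "  for (i in 1:n) {",
    "    logit(psi[i]) <- a[forest[i], 1] + inprod(Xpsi[i, ], bpsi)",
    "    z[i, 1] ~ dbern(psi[i])",
    "    for (t in 1:(T - 1)) {",
    "      logit(g[i, t]) <- a[forest[i], 2] + inprod(Xgam[i + n*(t-1), ], bgam)",
    "      logit(e[i, t]) <- a[forest[i], 3] + inprod(Xeps[i + n*(t-1), ], beps)",
    "      z[i, t + 1] ~ dbern(z[i, t] * (1 - e[i, t]) + (1 - z[i, t]) * g[i, t])",
    "    }",
    "  }",
    "  for (r in 1:R) {",
    "    logit(p[r]) <- a[forest[det_site[r]], 4] + inprod(Xp[r, ], bp)",
    "    y[r] ~ dbern(z[det_site[r], det_year[r]] * p[r])",
    "  }",
    "}", sep = "\n")
}

#' Sample the posterior of the dynamic occupancy model
#'
#' Runs MCMC over the hierarchical posterior (the same model whose
#' marginalized log posterior [log_posterior()] evaluates) using a
#' discrete-latent-state Gibbs sampler (JAGS). The engine is an
#' implementation detail: correctness is defined by the log-posterior
#' and the convergence diagnostics, and draws are returned in a plain
#' matrix any sampler could fill. `warmup` iterations per chain are used
#' for adaptation and discarded; `iter - warmup` draws per chain are kept.
#'
#' @param history an [encounter_history()].
#' @param design matching `occ_design`.
#' @param config a [prior_config()].
#' @param chains number of chains (>= 2 for diagnostics).
#' @param iter total iterations per chain.
#' @param warmup warmup (adaptation) iterations per chain.
#' @param seed integer seed; chain c uses seed + c, so identical seeds give
#'   identical draws.
#' @param quiet suppress sampler progress output.
#' @return object of class `occ_draws`: draws matrix (rows = post-warmup
#'   draws from all chains), chain id per row, dims, run metadata, and a
#'   `diagnostics` table from [convergence_report()] (with a recorded
#'   warning status when any parameter has Rhat > 1.01).
#' @export
sample_posterior <- function(history, design, config = prior_config(),
                             chains = 3, iter = 1500, warmup = 750,
                             seed = 1, quiet = TRUE) {
  if (length(design$years) < 2) stop("need >= 2 primary occasions")
  if (warmup >= iter) stop("warmup must be < iter")
  data <- prep_occ_data(history, design)
  jd <- list(
    n = data$n, T = data$T, F = data$k$n_forests, forest = data$forest,
    Xpsi = data$Xpsi, Xgam = data$Xgam, Xeps = data$Xeps, Xp = data$Xp,
    det_site = data$det_site, det_year = data$det_year, y = data$det_y,
    R = length(data$det_y),
    Kpsi = data$k$k_psi, Kgam = data$k$k_gamma, Keps = data$k$k_eps,
    Kp = data$k$k_p,
    prec_b = 1 / config$beta_sd^2, prec_mu = 1 / config$mu_sd^2,
    prec_sig = 1 / config$sigma_scale^2
  )
  inits <- lapply(seq_len(chains), function(c) list(
    z = matrix(1L, data$n, data$T),
    .RNG.name = "base::Wichmann-Hill",
    .RNG.seed = as.integer(seed + c)
  ))
  jm <- rjags::jags.model(textConnection(occ_jags_model()), data = jd,
                          inits = inits, n.chains = chains,
                          n.adapt = warmup, quiet = quiet)
  monitors <- c("bpsi", "bgam", "beps", "bp", "a", "mu", "sig")
  samp <- rjags::coda.samples(jm, monitors, n.iter = iter - warmup,
                              progress.bar = if (quiet) "none" else "text")
  draws <- do.call(rbind, lapply(samp, as.matrix))
  chain_id <- rep(seq_len(chains), each = iter - warmup)
  out <- structure(list(
    draws = draws, chain = chain_id, n_chains = chains, iter = iter,
    warmup = warmup, seed = seed, dims = data$k, engine = "jags",
    prior = config
  ), class = "occ_draws")
  out$diagnostics <- convergence_report(out)
  if (any(out$diagnostics$rhat > 1.01, na.rm = TRUE)) {
    out$status <- "warning: Rhat > 1.01 for some parameters"
    warning(out$status)
  } else out$status <- "ok"
  out
}

#' @export
print.occ_draws <- function(x, ...) {
  cat(sprintf("Posterior draws: %d draws x %d parameters (%d chains)\n",
              nrow(x$draws), ncol(x$draws), x$n_chains))
  cat(sprintf("  max Rhat %.3f, min bulk ESS %.0f [%s]\n",
              max(x$diagnostics$rhat, na.rm = TRUE),
              min(x$diagnostics$ess, na.rm = TRUE), x$status))
  invisible(x)
}

#' Rebuild an [occ_params()] from one posterior draw
#'
#' @param draws an `occ_draws`.
#' @param i draw (row) index.
#' @return an `occ_params`.
#' @export
draw_params <- function(draws, i) {
  d <- draws$draws[i, ]
  k <- draws$dims
  Fn <- k$n_forests
  get <- function(name, len) {
    nm <- paste0(name, "[", seq_len(len), "]")
    # a length-1 monitored vector is reported without the index
    if (len == 1 && !(nm %in% names(d)) && name %in% names(d)) nm <- name
    unname(d[nm])
  }
  amat <- matrix(NA_real_, Fn, 4)
  for (f in seq_len(Fn)) for (s in 1:4) {
    amat[f, s] <- d[paste0("a[", f, ",", s, "]")]
  }
  occ_params(
    beta_psi = get("bpsi", k$k_psi), beta_gamma = get("bgam", k$k_gamma),
    beta_eps = get("beps", k$k_eps), beta_p = get("bp", k$k_p),
    alpha_psi = amat[, 1], alpha_gamma = amat[, 2],
    alpha_eps = amat[, 3], alpha_p = amat[, 4],
    mu_psi = d["mu[1]"], mu_gamma = d["mu[2]"], mu_eps = d["mu[3]"],
    mu_p = d["mu[4]"],
    sigma_psi = d["sig[1]"], sigma_gamma = d["sig[2]"],
    sigma_eps = d["sig[3]"], sigma_p = d["sig[4]"]
  )
}

rank_normalize <- function(x) {
  r <- rank(x, ties.method = "average")
  stats::qnorm((r - 3 / 8) / (length(x) + 1 / 4))
}

# split-Rhat and bulk ESS on one parameter, given a draws x ... matrix of
# split chains (columns = split half-chains)
.rhat_ess_one <- function(mat) {
  n2 <- nrow(mat); m <- ncol(mat)
  if (stats::sd(as.vector(mat)) == 0) return(c(rhat = NA_real_,
                                               ess = NA_real_))
  z <- matrix(rank_normalize(as.vector(mat)), n2, m)
  W <- mean(apply(z, 2, stats::var))
  B <- n2 * stats::var(colMeans(z))
  var_plus <- (n2 - 1) / n2 * W + B / n2
  rhat <- sqrt(var_plus / W)
  # bulk ESS: Geyer initial monotone sequence on the combined autocovariance
  max_lag <- min(n2 - 1, 500)
  acov <- sapply(seq_len(m), function(j)
    stats::acf(z[, j], lag.max = max_lag, type = "covariance",
               plot = FALSE, demean = TRUE)$acf[, 1, 1])
  s_t <- rowMeans(acov)  # lag 0 .. max_lag
  rho <- 1 - (W - s_t) / var_plus
  # pair sums P_k = rho_{2k} + rho_{2k+1}
  n_pairs <- floor((length(rho) - 1) / 2)
  tau <- rho[1]
  prev <- Inf
  k <- 1
  while (k <= n_pairs) {
    P <- rho[2 * k] + rho[2 * k + 1]
    if (P <= 0) break
    P <- min(P, prev)
    tau <- tau + 2 * P
    prev <- P
    k <- k + 1
  }
  ess <- m * n2 / max(tau, 1e-12)
  c(rhat = rhat, ess = min(ess, m * n2))
}

#' Convergence diagnostics: rank-normalized split-Rhat and bulk ESS
#'
#' Computes the rank-normalized split-Rhat statistic and bulk effective
#' sample size for every monitored parameter, with a pass flag at the
#' thresholds the study used (Rhat <= 1.01 and ESS > 300). Degenerate
#' (constant) parameters get `NA` diagnostics and a fail flag.
#'
#' @param draws an `occ_draws` (or a list with `draws` matrix and `chain`
#'   vector); needs >= 2 chains.
#' @param rhat_max,ess_min pass thresholds.
#' @return data.frame: param, rhat, ess, pass.
#' @export
convergence_report <- function(draws, rhat_max = 1.01, ess_min = 300) {
  mat <- draws$draws
  chain <- draws$chain
  if (length(unique(chain)) < 2) {
    stop("split-Rhat requires at least 2 chains")
  }
  per_chain <- split(seq_len(nrow(mat)), chain)
  n_iter <- min(lengths(per_chain))
  half <- floor(n_iter / 2)
  cols <- lapply(per_chain, function(idx) {
    idx <- idx[seq_len(2 * half)]
    list(idx[seq_len(half)], idx[half + seq_len(half)])
  })
  split_idx <- do.call(c, cols)
  res <- t(apply(mat, 2, function(x) {
    .rhat_ess_one(vapply(split_idx, function(idx) x[idx],
                         numeric(half)))
  }))
  out <- data.frame(param = colnames(mat), rhat = res[, "rhat"],
                    ess = res[, "ess"], row.names = NULL,
                    stringsAsFactors = FALSE)
  out$pass <- !is.na(out$rhat) & out$rhat <= rhat_max &
    !is.na(out$ess) & out$ess > ess_min
  out
}
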