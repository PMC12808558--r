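# independent oracles kept free of the implementations they check

# exhaustive latent-state enumeration of the dynamic occupancy likelihood
enum_site_loglik <- function(Y, psi, gamma, eps, p) {
  Y <- rbind(Y); p <- rbind(p)
  T <- nrow(Y)
  total <- 0
  for (mask in 0:(2^T - 1)) {
    zs <- as.integer(intToBits(mask))[seq_len(T)]
    pr <- if (zs[1] == 1) psi else 1 - psi
    if (T > 1) for (t in 2:T) {
      pr <- pr * if (zs[t - 1] == 1) {
        if (zs[t] == 1) 1 - eps[t - 1] else eps[t - 1]
      } else {
        if (zs[t] == 1) gamma[t - 1] else 1 - gamma[t - 1]
      }
    }
    for (t in seq_len(T)) {
      obs <- !is.na(Y[t, ])
      y <- Y[t, obs]; pw <- p[t, obs]
      pr <- pr * if (zs[t] == 1) {
        prod(pw^y * (1 - pw)^(1 - y))
      } else {
        as.numeric(all(y == 0))
      }
    }
    total <- total + pr
  }
  log(total)
}

# random small likelihood instance (T <= 4, J <= 5) with moderate p so the
# probability floor in the implementation is inactive
random_lik_instance <- function() {
  T <- sample(1:4, 1); J <- sample(1:5, 1)
  psi <- runif(1, 0.05, 0.95)
  gamma <- runif(max(T - 1, 0), 0.05, 0.95)
  eps <- runif(max(T - 1, 0), 0.05, 0.95)
  p <- matrix(runif(T * J, 0.05, 0.95), T, J)
  Y <- matrix(rbinom(T * J, 1, 0.4), T, J)
  miss <- matrix(runif(T * J) < 0.3, T, J)
  Y[miss] <- NA
  p[miss] <- NA
  list(Y = Y, psi = psi, gamma = gamma, eps = eps, p = p)
}
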