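# Shared helpers: random strategy pairs and independent oracles.

rand_transmitter <- function() sample_viable_strategy(with_feedback = TRUE)

rand_receiver <- function(a0 = runif(1, 0, 0.9), a1 = runif(1)) {
  receiver_strategy(a0 = a0, a1 = a1, p0 = runif(1), p_ct = runif(1),
                    p_cf = runif(1), p_nt = runif(1), p_nf = runif(1))
}

quick_opt <- function(...) {
  optimize_config(burn_in = 1500L, measure = 1500L, ...)
}

# Power-iteration oracle for the stationary distribution of a 4x4
# row-stochastic matrix (irreducible, aperiodic; start from uniform).
power_iter_stationary <- function(M, iters = 1000000L, tol = 1e-15) {
  x <- rep(0.25, 4)
  for (i in seq_len(iters)) {
    nxt <- as.numeric(x %*% M)
    if (max(abs(nxt - x)) < tol) { x <- nxt; break }
    x <- nxt
  }
  x / sum(x)
}

# Brute-force single-step simulation oracle: draws one round of the game
# from joint state (i, j) by simulating each described coin flip in turn,
# independent of the closed-form transition matrix construction.
single_step_oracle <- function(transmitter, receiver, config, state,
                               n = 200000L) {
  i <- substr(state, 1, 1)  # "c" or "n"
  j <- substr(state, 2, 2)  # "t" or "f"
  k <- as.integer(i == "c")
  out <- character(n)
  for (s in seq_len(n)) {
    jp <- if (runif(1) < config$eta) setdiff(c("t", "f"), j) else j
    p <- transmit_prob(transmitter, jp, k, 1L)
    m <- if (runif(1) < p) "t" else "f"
    if (runif(1) < config$epsilon) m <- setdiff(c("t", "f"), m)
    q <- engage_prob(receiver, i, j, m)
    e <- if (runif(1) < q) "c" else "n"
    if (runif(1) < config$epsilon) e <- setdiff(c("c", "n"), e)
    out[s] <- paste0(e, m)
  }
  tab <- table(factor(out, levels = c("ct", "cf", "nt", "nf")))
  as.numeric(tab) / n
}

# Hand-computed DerSimonian-Laird estimator, independent of metafor.
dl_meta_oracle <- function(slope, se) {
  w <- 1 / se^2
  mu_fe <- sum(w * slope) / sum(w)
  Q <- sum(w * (slope - mu_fe)^2)
  k <- length(slope)
  tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (se^2 + tau2)
  mu <- sum(ws * slope) / sum(ws)
  se_mu <- sqrt(1 / sum(ws))
  list(mu = mu, se_mu = se_mu, tau2 = tau2,
       p = 2 * pnorm(-abs(mu / se_mu)))
}
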