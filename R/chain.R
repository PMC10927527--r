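#' One-round transition matrix of the single-receiver game
#'
#' The joint state of the repeated game with one receiver is (previous
#' engagement, previous veracity) over the ordered states
#' `(c,t), (c,f), (n,t), (n,f)`. From state `(i,j)` the transmitter recalls
#' `j` (mislabelled with probability `eta`), applies its rule at
#' `k = 1{i = c}` engaged receivers, and its chosen action is flipped with
#' probability `epsilon`; the receiver's engagement draw from
#' \eqn{q_{ij}^m} is likewise `epsilon`-flipped.
#'
#' @param transmitter A [transmitter_strategy()].
#' @param receiver A [receiver_strategy()].
#' @param config A [game_config()]; must have `N = 1` (use
#'   [simulate_rounds()] for receiver populations).
#' @return A 4x4 row-stochastic matrix with dimnames
#'   `c("ct","cf","nt","nf")`.
#' @export
transition_matrix <- function(transmitter, receiver, config = game_config()) {
  if (config$N != 1L) {
    stop("transition_matrix supports N = 1 only; use simulate_rounds() for N > 1",
         call. = FALSE)
  }
  M <- cpp_transition(transmitter_vec(transmitter), receiver_vec(receiver),
                      config$epsilon, config$eta)
  dimnames(M) <- list(c("ct", "cf", "nt", "nf"), c("ct", "cf", "nt", "nf"))
  M
}

# The four action probabilities (r0t, r1t, r0f, r1f) at k = 0, 1 (N = 1).
transmitter_vec <- function(transmitter) {
  c(transmit_prob(transmitter, "t", 0, 1), transmit_prob(transmitter, "t", 1, 1),
    transmit_prob(transmitter, "f", 0, 1), transmit_prob(transmitter, "f", 1, 1))
}

#' Stationary distribution of the repeated game
#'
#' Long-run frequencies \eqn{v = (v_{tc}, v_{fc}, v_{tn}, v_{fn})} of the
#' four (veracity, engagement) outcomes. The distribution is obtained by a
#' direct linear solve; for reducible chains (possible only at
#' `epsilon = 0`) the Cesaro limit of power iteration started from the
#' uniform distribution is used, so degenerate strategies such as
#' never-engaging receivers are handled deterministically.
#'
#' @param x Either a 4x4 row-stochastic matrix (states ordered
#'   `ct, cf, nt, nf`) or a `transmitter_strategy` (in which case
#'   `receiver` and `config` are used to build the matrix first).
#' @param receiver,config Used only when `x` is a strategy.
#' @return An object of class `stationary_distribution`: a named numeric
#'   vector `(v_tc, v_fc, v_tn, v_fn)` summing to one.
#' @examples
#' v <- stationary_distribution(canned_strategies()$no_feedback,
#'                              receiver_strategy(p0 = 0.5))
#' v_false(v)
#' @export
stationary_distribution <- function(x, receiver = NULL,
                                    config = game_config()) {
  if (inherits(x, "transmitter_strategy")) {
    x <- transition_matrix(x, receiver, config)
  }
  stopifnot(is.matrix(x), all(dim(x) == c(4L, 4L)))
  if (max(abs(rowSums(x) - 1)) > 1e-9) {
    stop("matrix is not row-stochastic", call. = FALSE)
  }
  v <- cpp_stationary(x)
  structure(setNames(v, c("v_tc", "v_fc", "v_tn", "v_fn")),
            class = "stationary_distribution")
}

#' @exportS3Method base::print
print.stationary_distribution <- function(x, ...) {
  cat("<stationary_distribution>\n")
  print(round(unclass(x), 6))
  invisible(x)
}

#' Summaries of a stationary distribution
#'
#' `v_true()`/`v_false()` return the long-run share of true/false stories;
#' `engage_per_true()`/`engage_per_false()` return the per-story engagement
#' rates \eqn{v_{tc}/v_t} and \eqn{v_{fc}/v_f}, which are `NaN` when fewer
#' than `1e-9` of the stories are of that type.
#'
#' @param v A `stationary_distribution` (or any named vector with the four
#'   outcome components).
#' @return A scalar.
#' @export
v_true <- function(v) unname(v[["v_tc"]] + v[["v_tn"]])

#' @rdname v_true
#' @export
v_false <- function(v) unname(v[["v_fc"]] + v[["v_fn"]])

#' @rdname v_true
#' @export
engage_per_true <- function(v) {
  vt <- v_true(v)
  if (vt < 1e-9) return(NaN)
  unname(v[["v_tc"]]) / vt
}

#' @rdname v_true
#' @export
engage_per_false <- function(v) {
  vf <- v_false(v)
  if (vf < 1e-9) return(NaN)
  unname(v[["v_fc"]]) / vf
}

#' Expected per-round payoffs
#'
#' Receiver payoff \eqn{\pi_t v_{tc} + \pi_f v_{fc}} and transmitter payoff
#' \eqn{b_t v_{tc} + b_f v_{fc}}; non-engagement contributes nothing.
#'
#' @param v A [stationary_distribution()].
#' @param config A [game_config()].
#' @return Named numeric vector `c(receiver = , transmitter = )`.
#' @export
payoffs <- function(v, config = game_config()) {
  c(receiver = config$pi_t * v[["v_tc"]] + config$pi_f * v[["v_fc"]],
    transmitter = config$b_t * v[["v_tc"]] + config$b_f * v[["v_fc"]])
}

#' Residual of the enforced outcome constraint
#'
#' A fixed polynomial transmitter strategy enforces, at stationarity of the
#' noise-free game and regardless of the receiver's strategy, the linear
#' relation
#' \deqn{v_f = \frac{1-\alpha}{1-\alpha+\beta}
#'   - \frac{\theta}{1-\alpha+\beta} v_{fc}
#'   - \frac{\gamma}{1-\alpha+\beta} v_{tc},}
#' with \eqn{\gamma = \sum_l \gamma_l}, \eqn{\theta = \sum_l \theta_l}.
#' This function returns the residual `v_f - rhs`; it vanishes (to within
#' numerical precision) at the exact stationary distribution when
#' `epsilon = eta = 0` and is of order `epsilon + eta` otherwise.
#'
#' @param transmitter A polynomial [transmitter_strategy()].
#' @param v A [stationary_distribution()].
#' @return The residual (a scalar).
#' @export
enforced_constraint_residual <- function(transmitter, v) {
  if (transmitter$form != "polynomial") {
    stop("the enforced constraint applies to polynomial strategies", call. = FALSE)
  }
  al <- transmitter$alpha; be <- transmitter$beta
  ga <- sum(transmitter$gamma); th <- sum(transmitter$theta)
  s <- 1 - al + be
  if (abs(s) < 1e-12) {
    stop("degenerate strategy: 1 - alpha + beta = 0", call. = FALSE)
  }
  rhs <- (1 - al) / s - th / s * v[["v_fc"]] - ga / s * v[["v_tc"]]
  v_false(v) - rhs
}

#' Simulate rounds of the repeated game
#'
#' Direct simulation with `N` receivers holding fixed strategies. Each
#' round the transmitter observes the engagement count `k` of the previous
#' story and its (`eta`-mislabelled) veracity, draws the next story's
#' veracity (`epsilon`-flipped), and every receiver independently draws an
#' (`epsilon`-flipped) engagement decision from its own memory state. The
#' first round starts from state `(n, t)`: previous story true, nobody
#' engaged.
#'
#' @param transmitter A [transmitter_strategy()].
#' @param receivers A single [receiver_strategy()] (shared by all `N`
#'   receivers of `config`) or a list of length `config$N`.
#' @param config A [game_config()].
#' @param rounds Number of rounds to simulate.
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `game_simulation`: a list with `trace` (a
#'   tibble with `round`, `veracity`, `k_engaged`) and `receivers` (a
#'   tibble of per-receiver empirical outcome frequencies
#'   `v_tc, v_fc, v_tn, v_fn`).
#' @export
simulate_rounds <- function(transmitter, receivers, config = game_config(),
                            rounds = 10000L, seed = NULL) {
  stopifnot(rounds >= 1)
  if (inherits(receivers, "receiver_strategy")) {
    receivers <- rep(list(receivers), config$N)
  }
  if (length(receivers) == 0L) stop("empty receiver list", call. = FALSE)
  if (length(receivers) != config$N) {
    stop("length(receivers) must equal config$N", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  N <- config$N
  rt <- transmit_prob(transmitter, "t", 0:N, N)
  rf <- transmit_prob(transmitter, "f", 0:N, N)
  rcv <- do.call(rbind, lapply(receivers, receiver_vec))
  out <- cpp_simulate_rounds(rt, rf, rcv, config$epsilon, config$eta,
                             as.integer(rounds))
  counts <- out$counts
  freq <- counts / rounds
  structure(list(
    trace = tibble::tibble(
      round = seq_len(rounds),
      veracity = ifelse(out$veracity == 0L, "t", "f"),
      k_engaged = out$k),
    receivers = tibble::tibble(
      receiver = seq_len(N),
      v_tc = freq[, 1], v_fc = freq[, 2], v_tn = freq[, 3], v_fn = freq[, 4])
  ), class = "game_simulation")
}

#' @exportS3Method base::print
print.game_simulation <- function(x, ...) {
  cat(sprintf("<game_simulation: %d rounds, %d receiver(s)>\n",
              nrow(x$trace), nrow(x$receivers)))
  cat(sprintf("  share false: %.3f  mean engagement: %.3f\n",
              mean(x$trace$veracity == "f"),
              mean(x$trace$k_engaged) / nrow(x$receivers)))
  invisible(x)
}

#' Write a simulation trace to CSV
#'
#' @param sim A `game_simulation`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(sim, path) {
  write.csv(sim$trace, path, row.names = FALSE)
  invisible(path)
}
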