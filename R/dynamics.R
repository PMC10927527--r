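#' Fermi acceptance rule
#'
#' Under myopic noisy optimization a player switches from its current
#' strategy (payoff `w_current`) to a candidate (payoff `w_candidate`) with
#' probability
#' \deqn{\pi = \frac{1}{1 + \exp[\sigma (w_i - w_j)]},}
#' where \eqn{\sigma \ge 0} is the attention the player pays to payoffs:
#' \eqn{\sigma = 0} gives random drift (probability 1/2 regardless of
#' payoffs) and large \eqn{\sigma} approaches greedy hill climbing.
#'
#' `fermi_prob()` returns the switching probability; `fermi_accept()` draws
#' the decision.
#'
#' @param w_current,w_candidate Payoffs of the incumbent and candidate
#'   strategies (vectorised).
#' @param sigma Attention to payoffs, `>= 0`.
#' @return `fermi_prob()`: probabilities; `fermi_accept()`: logicals.
#' @export
fermi_prob <- function(w_current, w_candidate, sigma) {
  stopifnot(sigma >= 0)
  x <- pmin(pmax(sigma * (w_current - w_candidate), -700), 700)
  1 / (1 + exp(x))
}

#' @rdname fermi_prob
#' @export
fermi_accept <- function(w_current, w_candidate, sigma) {
  runif(length(w_current)) < fermi_prob(w_current, w_candidate, sigma)
}

#' Optimization settings
#'
#' @param sigma Attention to payoffs in the Fermi rule.
#' @param proposal_scale Half-width of the local proposal step: one
#'   behavioural component is perturbed by a uniform draw on
#'   `[-proposal_scale, proposal_scale]` and reflected into `[0, 1]`.
#' @param proposal_kind `"local"` (reflected perturbation) or `"global"`
#'   (the chosen component is redrawn uniformly on `[0, 1]`).
#' @param burn_in,measure Number of update events discarded and then
#'   averaged over.
#' @param seed Optional integer seed.
#' @return An object of class `optimize_config`.
#' @export
optimize_config <- function(sigma = 1, proposal_scale = 0.1,
                            proposal_kind = c("local", "global"),
                            burn_in = 10000L, measure = 10000L, seed = NULL) {
  proposal_kind <- match.arg(proposal_kind)
  stopifnot(burn_in >= 1, measure >= 1, proposal_scale > 0, sigma >= 0)
  structure(list(sigma = sigma, proposal_scale = proposal_scale,
                 proposal_kind = proposal_kind,
                 burn_in = as.integer(burn_in), measure = as.integer(measure),
                 seed = seed),
            class = "optimize_config")
}

#' Propose a perturbed receiver strategy
#'
#' One uniformly chosen free behavioural component among
#' `p0, p_ct, p_cf, p_nt, p_nf` is perturbed (local kind: symmetric uniform
#' step of half-width `proposal_scale`, reflected into `[0, 1]`; global
#' kind: redrawn uniformly). The attention parameters `a0`, `a1` are
#' exogenous and held fixed.
#'
#' @param current A [receiver_strategy()].
#' @param opt An [optimize_config()].
#' @return A new `receiver_strategy`.
#' @export
propose_receiver <- function(current, opt = optimize_config()) {
  comps <- c("p0", "p_ct", "p_cf", "p_nt", "p_nf")
  comp <- sample(comps, 1L)
  x <- current[[comp]]
  if (opt$proposal_kind == "global") {
    x <- runif(1)
  } else {
    x <- x + runif(1, -opt$proposal_scale, opt$proposal_scale)
    x <- abs(x)
    if (x > 1) x <- 2 - x
  }
  out <- current
  out[[comp]] <- x
  out
}

summarise_mean_v <- function(mean_v, mean_payoff) {
  v_f <- mean_v[2] + mean_v[4]
  v_t <- mean_v[1] + mean_v[3]
  tibble::tibble(
    v_tc = mean_v[1], v_fc = mean_v[2], v_tn = mean_v[3], v_fn = mean_v[4],
    v_t = v_t, v_f = v_f,
    engage_per_true = ifelse(v_t < 1e-9, NaN, mean_v[1] / v_t),
    engage_per_false = ifelse(v_f < 1e-9, NaN, mean_v[2] / v_f),
    mean_payoff = mean_payoff)
}

#' Myopic receiver optimization against a fixed transmitter
#'
#' Starting from a receiver that never engages (all behavioural components
#' zero), each update event proposes an alternate strategy, evaluates both
#' incumbent and candidate at the exact stationary distribution of the
#' single-receiver chain, and switches by the Fermi rule. After `burn_in`
#' events the outcome frequencies and receiver payoff are averaged over
#' `measure` further events; per-story engagement rates are ratios of these
#' time averages.
#'
#' @param transmitter A [transmitter_strategy()].
#' @param config A [game_config()] (must have `N = 1`).
#' @param opt An [optimize_config()].
#' @param a0,a1 Receiver attention parameters (held fixed during
#'   optimization). The default `a0 = 0, a1 = 1` is the inattentive,
#'   memory-using receiver of the strategy-search ensembles.
#' @param init Numeric vector of the five initial behavioural components
#'   `(p0, p_ct, p_cf, p_nt, p_nf)`.
#' @param trajectory_thin If positive, record the outcome state every this
#'   many events in `$trajectory`.
#' @return An object of class `receiver_optimization`: list with `summary`
#'   (one-row tibble of time-averaged outcomes), `mean_p`, `final_p`, and
#'   optionally `trajectory`.
#' @export
optimize_receiver <- function(transmitter, config = game_config(),
                              opt = optimize_config(), a0 = 0, a1 = 1,
                              init = rep(0, 5), trajectory_thin = 0L) {
  if (config$N != 1L) stop("optimize_receiver requires N = 1", call. = FALSE)
  if (!is.null(opt$seed)) set.seed(opt$seed)
  out <- cpp_optimize_receiver(
    transmitter_vec(transmitter), a0, a1, init, config$pi_t, config$pi_f,
    config$epsilon, config$eta, opt$sigma, opt$proposal_scale,
    opt$proposal_kind == "global", opt$burn_in, opt$measure,
    as.integer(trajectory_thin))
  traj <- NULL
  if (trajectory_thin > 0L) {
    traj <- tibble::as_tibble(as.data.frame(out$trajectory))
    names(traj) <- c("event", "v_tc", "v_fc", "v_tn", "v_fn", "payoff", "p0")
  }
  structure(list(
    summary = summarise_mean_v(out$mean_v, out$mean_payoff),
    mean_p = setNames(out$mean_p, c("p0", "p_ct", "p_cf", "p_nt", "p_nf")),
    final_p = setNames(out$final_p, c("p0", "p_ct", "p_cf", "p_nt", "p_nf")),
    trajectory = traj), class = "receiver_optimization")
}

#' @exportS3Method base::print
print.receiver_optimization <- function(x, ...) {
  cat("<receiver_optimization>\n")
  print(as.data.frame(round(x$summary, 4)), row.names = FALSE)
  invisible(x)
}

#' Co-optimization of transmitter and receiver strategies
#'
#' Both players update by the myopic noisy process: each time-step performs
#' one receiver update event followed by one transmitter update event.
#' Transmitter proposals perturb the four action probabilities
#' `(r_0^t, r_1^t, r_0^f, r_1^f)` directly (each reflected into `[0, 1]`),
#' which spans exactly the viable linear-feedback strategies.
#'
#' @param transmitter_init,receiver_init Initial strategies.
#' @param config A [game_config()] (`N = 1`); `b_t`, `b_f` define the
#'   transmitter's payoff.
#' @param opt_T,opt_R [optimize_config()]s for the transmitter and
#'   receiver; `opt_T$sigma` defaults to 100 (an attentive producer).
#' @param steps Total number of time-steps.
#' @param burn_in Time-steps discarded before measuring; defaults to half
#'   of `steps`.
#' @return List with `summary` (time-averaged outcomes and payoffs),
#'   `final_transmitter`, `final_p` (receiver components).
#' @export
co_optimize <- function(transmitter_init, receiver_init,
                        config = game_config(),
                        opt_T = optimize_config(sigma = 100),
                        opt_R = optimize_config(), steps = 10000L,
                        burn_in = NULL) {
  stopifnot(steps >= 2)
  if (is.null(burn_in)) burn_in <- steps %/% 2L
  if (burn_in >= steps) stop("burn_in must leave a measurement window", call. = FALSE)
  if (!is.null(opt_R$seed)) set.seed(opt_R$seed)
  rv <- receiver_vec(receiver_init)
  out <- cpp_co_optimize(
    transmitter_vec(transmitter_init), rv[1], rv[2], rv[3:7],
    config$pi_t, config$pi_f, config$b_t, config$b_f, config$epsilon,
    config$eta, opt_R$sigma, opt_R$proposal_scale, opt_T$sigma,
    opt_T$proposal_scale, as.integer(steps), as.integer(burn_in))
  summ <- summarise_mean_v(out$mean_v, out$mean_payoff_receiver)
  summ$mean_payoff_transmitter <- out$mean_payoff_transmitter
  ft <- out$final_transmitter
  list(summary = summ,
       final_transmitter = transmitter_strategy(
         alpha = ft[1], beta = ft[3], gamma = ft[2] - ft[1],
         theta = ft[4] - ft[3]),
       final_p = setNames(out$final_p, c("p0", "p_ct", "p_cf", "p_nt", "p_nf")))
}

#' Grid specification for engagement-region scans
#'
#' @param pi_f_values Receiver utilities for false stories; the true-story
#'   utility is set to `-pi_f` throughout.
#' @param sigma_values Receiver attention values (log-spaced grids are
#'   conventional).
#' @param replicates Co-optimization replicates per cell.
#' @param steps Time-steps per replicate.
#' @return An object of class `region_grid`.
#' @export
region_grid <- function(pi_f_values = seq(-1, 1, length.out = 5),
                        sigma_values = 10^seq(-2, 2, length.out = 5),
                        replicates = 10L, steps = 2000L) {
  stopifnot(length(pi_f_values) >= 1, length(sigma_values) >= 1,
            replicates >= 1, steps >= 2)
  structure(list(pi_f_values = pi_f_values, sigma_values = sigma_values,
                 replicates = as.integer(replicates),
                 steps = as.integer(steps)),
            class = "region_grid")
}

#' Scan engagement regions over receiver preference and attention
#'
#' For each cell \eqn{(\pi_f, \sigma)} of the grid (with
#' \eqn{\pi_t = -\pi_f}), receivers and a transmitter of the given type
#' co-optimize; the cell records the mean per-story engagement difference
#' \eqn{v_{fc}/v_f - v_{tc}/v_t} over replicates. Its sign classifies the
#' engagement regions: against a misinformation transmitter, attentive
#' truth-seeking receivers engage more with true stories (negative),
#' inattentive truth-seekers are driven to engage more with false stories
#' (positive), and fake-news-preferring receivers engage more with false
#' stories regardless of attention (positive). Receivers here use
#' `a0 = a1 = 0` (engagement baseline only) with local exploration.
#'
#' @param grid A [region_grid()].
#' @param transmitter_type `"misinformation"` (`b_f = 1, b_t = 0`) or
#'   `"accurate"` (`b_t = 1, b_f = 0`).
#' @param config Base [game_config()]; payoffs are overridden per cell.
#' @param opt_T,opt_R Optimization settings (transmitter attention defaults
#'   to `sigma = 100`).
#' @param seed Optional integer seed.
#' @return A tibble of class `region_scan` with columns `pi_f`, `sigma`,
#'   `mean_diff`, `n_replicates`.
#' @export
region_scan <- function(grid = region_grid(),
                        transmitter_type = c("misinformation", "accurate"),
                        config = game_config(),
                        opt_T = optimize_config(sigma = 100),
                        opt_R = optimize_config(), seed = NULL) {
  transmitter_type <- match.arg(transmitter_type)
  if (!is.null(seed)) set.seed(seed)
  if (transmitter_type == "misinformation") {
    config$b_f <- 1; config$b_t <- 0
  } else {
    config$b_f <- 0; config$b_t <- 1
  }
  cells <- tidyr::expand_grid(pi_f = grid$pi_f_values,
                              sigma = grid$sigma_values)
  res <- purrr::pmap_dfr(cells, function(pi_f, sigma) {
    cfg <- config
    cfg$pi_f <- pi_f; cfg$pi_t <- -pi_f
    oR <- opt_R; oR$sigma <- sigma; oR$seed <- NULL
    diffs <- purrr::map_dbl(seq_len(grid$replicates), function(r) {
      tr0 <- sample_viable_strategy(with_feedback = TRUE)
      out <- co_optimize(tr0, receiver_strategy(), cfg, opt_T, oR,
                         steps = grid$steps)
      out$summary$engage_per_false - out$summary$engage_per_true
    })
    tibble::tibble(pi_f = pi_f, sigma = sigma,
                   mean_diff = mean(diffs, na.rm = TRUE),
                   n_replicates = grid$replicates)
  })
  class(res) <- c("region_scan", class(res))
  res
}

#' Heatmap of a region scan
#'
#' @param object A [region_scan()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.region_scan <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = factor(signif(.data$pi_f, 3)), y = factor(signif(.data$sigma, 3)),
    fill = .data$mean_diff)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  midpoint = 0) +
    ggplot2::labs(x = expression(pi[f]), y = expression(sigma),
                  fill = "engagement\ndifference") +
    ggplot2::theme_minimal()
}
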