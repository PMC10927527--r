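#' Construct a transmitter strategy
#'
#' A transmitter strategy maps the veracity of the previous story and the
#' engagement it generated to the probability that the next story is true.
#' In the polynomial form the probability of transmitting a true story is
#' \deqn{r_k^t = \alpha + \sum_l \gamma_l (k/N)^l, \qquad
#'       r_k^f = \beta + \sum_l \theta_l (k/N)^l,}
#' where \eqn{k} of \eqn{N} targeted receivers engaged with the previous
#' story, \eqn{\alpha} and \eqn{\beta} are baseline accuracies after a true
#' (resp. false) story and \eqn{\gamma_l}, \eqn{\theta_l} shape the
#' engagement feedback. A strategy is *viable* when both rules stay inside
#' \eqn{[0,1]} for every attainable engagement level.
#'
#' @param alpha Baseline probability of a true story after a true story.
#' @param beta Baseline probability of a true story after a false story.
#' @param gamma Numeric vector of feedback coefficients \eqn{\gamma_l}
#'   applied to \eqn{(k/N)^l} after a true story (default no feedback).
#' @param theta Feedback coefficients \eqn{\theta_l} after a false story.
#' @param N Receiver count used to verify viability on the grid
#'   \eqn{k = 0, \dots, N}. For linear feedback viability does not depend
#'   on `N`.
#' @return An object of class `transmitter_strategy`.
#' @seealso [sigmoid_strategy()] for the nonlinear sigmoidal form,
#'   [transmit_prob()] to evaluate the rule.
#' @examples
#' tr <- transmitter_strategy(alpha = 0.9, beta = 0.4, gamma = -0.5, theta = -0.2)
#' transmit_prob(tr, "t", k = 1, N = 1)
#' @export
transmitter_strategy <- function(alpha, beta, gamma = 0, theta = 0, N = 1L) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0, alpha <= 1,
            is.numeric(beta), length(beta) == 1L, beta >= 0, beta <= 1,
            is.numeric(gamma), is.numeric(theta))
  s <- structure(
    list(alpha = alpha, beta = beta, gamma = as.numeric(gamma),
         theta = as.numeric(theta), form = "polynomial",
         sigmoid_params = NULL),
    class = "transmitter_strategy")
  if (!is_viable(s, N = N)) {
    stop("non-viable transmitter strategy: r_k must lie in [0,1] for all k = 0..N",
         call. = FALSE)
  }
  s
}

#' Construct a sigmoidal transmitter strategy
#'
#' The sigmoidal form
#' \deqn{r_k^t = 1/(1+\exp[\lambda(k/N - m_t)]), \qquad
#'       r_k^f = 1/(1+\exp[\lambda(k/N - m_f)])}
#' produces (for large \eqn{\lambda}) a sharp switch from mostly-true output
#' at low engagement to mostly-false output at high engagement. The
#' steepness \eqn{\lambda = 100} with midpoints \eqn{m_t = 0.5},
#' \eqn{m_f = 0.25} is the canonical demonstration strategy.
#'
#' @param lambda Steepness of the switch.
#' @param m_t Midpoint (as a fraction of receivers engaged) of the rule
#'   applied after a true story.
#' @param m_f Midpoint of the rule applied after a false story.
#' @return An object of class `transmitter_strategy` with `form = "sigmoid"`.
#' @export
sigmoid_strategy <- function(lambda = 100, m_t = 0.5, m_f = 0.25) {
  structure(
    list(alpha = NA_real_, beta = NA_real_, gamma = NA_real_, theta = NA_real_,
         form = "sigmoid",
         sigmoid_params = list(lambda = lambda, m_t = m_t, m_f = m_f)),
    class = "transmitter_strategy")
}

#' @exportS3Method base::print
print.transmitter_strategy <- function(x, ...) {
  if (x$form == "sigmoid") {
    p <- x$sigmoid_params
    cat(sprintf("<transmitter_strategy: sigmoid lambda=%g m_t=%g m_f=%g>\n",
                p$lambda, p$m_t, p$m_f))
  } else {
    cat(sprintf("<transmitter_strategy: alpha=%.3f beta=%.3f gamma=(%s) theta=(%s)>\n",
                x$alpha, x$beta, paste(signif(x$gamma, 3), collapse = ","),
                paste(signif(x$theta, 3), collapse = ",")))
  }
  invisible(x)
}

#' Check viability of a polynomial transmitter strategy
#'
#' @param strategy A `transmitter_strategy`.
#' @param N Receiver count defining the engagement grid `0:N`.
#' @return `TRUE` when both transmission rules lie in `[0,1]` on the grid.
#' @export
is_viable <- function(strategy, N = 1L) {
  if (strategy$form == "sigmoid") return(TRUE)
  k <- 0:N
  rt <- transmit_prob_raw(strategy, "t", k, N)
  rf <- transmit_prob_raw(strategy, "f", k, N)
  all(rt >= -1e-12 & rt <= 1 + 1e-12 & rf >= -1e-12 & rf <= 1 + 1e-12)
}

# Rule evaluation without the domain checks, used by the validator.
transmit_prob_raw <- function(strategy, prev_veracity, k, N) {
  x <- k / N
  if (strategy$form == "sigmoid") {
    p <- strategy$sigmoid_params
    m <- if (prev_veracity == "t") p$m_t else p$m_f
    return(1 / (1 + exp(pmin(pmax(p$lambda * (x - m), -700), 700))))
  }
  base <- if (prev_veracity == "t") strategy$alpha else strategy$beta
  cf <- if (prev_veracity == "t") strategy$gamma else strategy$theta
  fb <- 0
  for (l in seq_along(cf)) fb <- fb + cf[l] * x^l
  base + fb
}

#' Probability that the next story is true
#'
#' Evaluates the transmitter's rule \eqn{r_k^i} given the veracity of the
#' previous story and the number of receivers that engaged with it.
#'
#' @param strategy A [transmitter_strategy()] or [sigmoid_strategy()].
#' @param prev_veracity `"t"` or `"f"`, the previous story's (perceived)
#'   veracity.
#' @param k Number of receivers that engaged with the previous story
#'   (vectorised).
#' @param N Total number of targeted receivers.
#' @return Probability (or vector of probabilities) in `[0, 1]`.
#' @export
transmit_prob <- function(strategy, prev_veracity = c("t", "f"), k, N = 1L) {
  prev_veracity <- match.arg(prev_veracity)
  if (any(k < 0 | k > N)) stop("k must satisfy 0 <= k <= N", call. = FALSE)
  p <- transmit_prob_raw(strategy, prev_veracity, k, N)
  pmin(pmax(p, 0), 1)
}

#' Construct a receiver strategy
#'
#' A receiver engages with the current story with probability
#' \deqn{q_{ij}^m = a_0 \delta_{mt} + (1-a_0)(1-a_1) p_0 + (1-a_0) a_1 p_{ij},}
#' where with probability \eqn{a_0} the receiver directly assesses the
#' current story's veracity \eqn{m} (engaging iff it is true), otherwise
#' with probability \eqn{a_1} they consult their memory of the source --
#' the behavioural vector \eqn{p = \{p_{ct}, p_{cf}, p_{nt}, p_{nf}\}}
#' indexed by whether they engaged with (c) or ignored (n) the previous
#' story and whether it was true (t) or false (f) -- and otherwise they
#' engage at the baseline rate \eqn{p_0}.
#'
#' @param a0 Attention to the current story's veracity.
#' @param a1 Attention to memory of the source, used when the current story
#'   is not assessed directly.
#' @param p0 Baseline engagement probability.
#' @param p_ct,p_cf,p_nt,p_nf Memory-conditioned engagement probabilities.
#' @return An object of class `receiver_strategy`.
#' @export
receiver_strategy <- function(a0 = 0, a1 = 0, p0 = 0,
                              p_ct = 0, p_cf = 0, p_nt = 0, p_nf = 0) {
  vals <- c(a0 = a0, a1 = a1, p0 = p0, p_ct = p_ct, p_cf = p_cf,
            p_nt = p_nt, p_nf = p_nf)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1)) {
    stop("all receiver strategy components must lie in [0, 1]", call. = FALSE)
  }
  structure(as.list(vals), class = "receiver_strategy")
}

#' @exportS3Method base::print
print.receiver_strategy <- function(x, ...) {
  cat(sprintf(
    "<receiver_strategy: a0=%.2f a1=%.2f p0=%.2f p=(%.2f,%.2f,%.2f,%.2f)>\n",
    x$a0, x$a1, x$p0, x$p_ct, x$p_cf, x$p_nt, x$p_nf))
  invisible(x)
}

# Seven-vector used by the compiled core.
receiver_vec <- function(receiver) {
  c(receiver$a0, receiver$a1, receiver$p0, receiver$p_ct, receiver$p_cf,
    receiver$p_nt, receiver$p_nf)
}

#' Probability of engaging with the current story
#'
#' @param receiver A [receiver_strategy()].
#' @param prev_engaged `"c"` (engaged) or `"n"` (did not engage) in the
#'   previous round.
#' @param prev_veracity Veracity of the previous story, `"t"` or `"f"`.
#' @param cur_veracity Veracity of the current story, `"t"` or `"f"`.
#' @return Engagement probability \eqn{q_{ij}^m} in `[0, 1]`.
#' @export
engage_prob <- function(receiver, prev_engaged = c("c", "n"),
                        prev_veracity = c("t", "f"),
                        cur_veracity = c("t", "f")) {
  prev_engaged <- match.arg(prev_engaged)
  prev_veracity <- match.arg(prev_veracity)
  cur_veracity <- match.arg(cur_veracity)
  pij <- receiver[[paste0("p_", prev_engaged, prev_veracity)]]
  delta <- as.numeric(cur_veracity == "t")
  receiver$a0 * delta + (1 - receiver$a0) * (1 - receiver$a1) * receiver$p0 +
    (1 - receiver$a0) * receiver$a1 * pij
}

#' Game configuration
#'
#' Payoffs, noise rates and receiver count for the repeated game. Receivers
#' derive utility `pi_t` from engaging with a true story and `pi_f` from a
#' false one (and nothing from non-engagement); transmitters derive benefit
#' `b_t` or `b_f` from each engaged true/false story. `epsilon` is the
#' execution error (each intended action -- the transmitter's veracity
#' choice and each receiver's engagement decision -- is flipped
#' independently with this probability) and `eta` the transmitter's
#' perception error (the memory of the previous story's veracity is
#' mislabelled with this probability before the rule is applied).
#'
#' @param pi_t,pi_f Receiver utilities per engaged true/false story.
#' @param b_t,b_f Transmitter benefits per engaged true/false story. The
#'   defaults describe a misinformation transmitter (`b_f = 1`, `b_t = 0`);
#'   use `b_t = 1, b_f = 0` for an accurate (mainstream) transmitter.
#' @param epsilon Execution error probability in `[0, 0.5]`.
#' @param eta Perception error probability in `[0, 0.5]`.
#' @param N Number of targeted receivers.
#' @return An object of class `game_config`.
#' @export
game_config <- function(pi_t = 1, pi_f = -1, b_t = 0, b_f = 1,
                        epsilon = 1e-3, eta = 0.3, N = 1L) {
  stopifnot(epsilon >= 0, epsilon <= 0.5, eta >= 0, eta <= 0.5, N >= 1)
  structure(list(pi_t = pi_t, pi_f = pi_f, b_t = b_t, b_f = b_f,
                 epsilon = epsilon, eta = eta, N = as.integer(N)),
            class = "game_config")
}

#' @exportS3Method base::print
print.game_config <- function(x, ...) {
  cat(sprintf(
    "<game_config: pi=(%g,%g) b=(%g,%g) eps=%g eta=%g N=%d>\n",
    x$pi_t, x$pi_f, x$b_t, x$b_f, x$epsilon, x$eta, x$N))
  invisible(x)
}

#' Serialize or restore strategies as JSON
#'
#' Round-trip exact JSON representation of transmitter and receiver
#' strategies.
#'
#' @param strategy A `transmitter_strategy` or `receiver_strategy`.
#' @return `strategy_to_json()` returns a JSON string; `strategy_from_json()`
#'   returns the strategy object.
#' @export
strategy_to_json <- function(strategy) {
  if (inherits(strategy, "transmitter_strategy")) {
    obj <- list(kind = "transmitter", alpha = strategy$alpha,
                beta = strategy$beta, gamma_coeffs = strategy$gamma,
                theta_coeffs = strategy$theta, form = strategy$form,
                sigmoid_params = strategy$sigmoid_params)
  } else if (inherits(strategy, "receiver_strategy")) {
    obj <- c(list(kind = "receiver"), unclass(strategy))
  } else {
    stop("not a strategy object", call. = FALSE)
  }
  jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
}

#' @param json A JSON string produced by `strategy_to_json()`.
#' @rdname strategy_to_json
#' @export
strategy_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  if (identical(obj$kind, "transmitter")) {
    if (identical(obj$form, "sigmoid")) {
      sp <- obj$sigmoid_params
      return(sigmoid_strategy(lambda = sp$lambda, m_t = sp$m_t, m_f = sp$m_f))
    }
    return(transmitter_strategy(alpha = obj$alpha, beta = obj$beta,
                                gamma = obj$gamma_coeffs,
                                theta = obj$theta_coeffs))
  }
  if (identical(obj$kind, "receiver")) {
    return(receiver_strategy(a0 = obj$a0, a1 = obj$a1, p0 = obj$p0,
                             p_ct = obj$p_ct, p_cf = obj$p_cf,
                             p_nt = obj$p_nt, p_nf = obj$p_nf))
  }
  stop("unrecognised strategy JSON", call. = FALSE)
}

#' Canned strategy fixtures
#'
#' A named set of transmitter strategies with documented qualitative
#' behaviour, useful for examples and tests:
#' \describe{
#'   \item{`sigmoid_switch`}{the steep sigmoidal feedback strategy
#'     (`lambda = 100`, midpoints 0.5 after true and 0.25 after false):
#'     mostly true output at low engagement, mostly false at high
#'     engagement.}
#'   \item{`always_true`}{`alpha = beta = 1`, no feedback.}
#'   \item{`always_false`}{`alpha = beta = 0`, no feedback.}
#'   \item{`no_feedback`}{a fixed interior baseline strategy with
#'     `gamma = theta = 0`; its misinformation share is independent of
#'     engagement.}
#'   \item{`responsive_misinfo`}{a linear-feedback exemplar whose enforced
#'     outcome constraint guarantees a majority of false stories even
#'     against a perfectly discriminating truth-seeking receiver.}
#' }
#'
#' @return A named list of `transmitter_strategy` objects.
#' @export
canned_strategies <- function() {
  list(
    sigmoid_switch = sigmoid_strategy(lambda = 100, m_t = 0.5, m_f = 0.25),
    always_true = transmitter_strategy(1, 1),
    always_false = transmitter_strategy(0, 0),
    no_feedback = transmitter_strategy(0.7, 0.4),
    responsive_misinfo = transmitter_strategy(0.9, 0.5, gamma = -0.9,
                                              theta = -0.5)
  )
}
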