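#' Sample a viable linear-feedback transmitter strategy
#'
#' Baselines are drawn uniformly, `alpha, beta ~ U[0, 1]`; with feedback,
#' the linear coefficients are drawn uniformly on the interval required for
#' viability, `gamma ~ U[-alpha, 1-alpha]` and `theta ~ U[-beta, 1-beta]`
#' (equivalently, the action probabilities at zero and full engagement are
#' independent uniforms). Without feedback `gamma = theta = 0`.
#'
#' @param with_feedback Draw feedback coefficients (`TRUE`) or set them to
#'   zero (`FALSE`).
#' @return A viable [transmitter_strategy()].
#' @export
sample_viable_strategy <- function(with_feedback = TRUE) {
  al <- runif(1); be <- runif(1)
  if (with_feedback) {
    ga <- runif(1, -al, 1 - al)
    th <- runif(1, -be, 1 - be)
  } else {
    ga <- 0; th <- 0
  }
  transmitter_strategy(alpha = al, beta = be, gamma = ga, theta = th)
}

#' Classify the enforcement structure of a transmitter strategy
#'
#' The enforced outcome constraint writes the misinformation share as an
#' affine function of engagement,
#' \eqn{v_f = v_0 + c_t v_{tc} + c_f v_{fc}} with
#' \eqn{v_0 = (1-\alpha)/(1-\alpha+\beta)},
#' \eqn{c_t = -\gamma/(1-\alpha+\beta)},
#' \eqn{c_f = -\theta/(1-\alpha+\beta)}. The classification reports:
#'
#' \describe{
#'   \item{`enforcement_sign`}{`"positive"` if both slopes are
#'     non-negative with at least one positive (misinformation output rises
#'     with engagement), `"negative"` for the mirror case, `"none"`
#'     otherwise (including no feedback).}
#'   \item{`responsive_misinfo`}{`TRUE` when the constraint guarantees
#'     \eqn{v_f \ge v_{fc} + v_{tc}} at every vertex of the feasible
#'     outcome polytope \eqn{\{v_{tc}, v_{fc} \ge 0,\; v_{fc} \le v_f,\;
#'     v_{tc} \le 1 - v_f\}} at which the inequality is attainable. Three
#'     of the four vertices hold automatically (two with equality); the
#'     all-engage corner would force \eqn{v_f = 1}, which only the boundary
#'     family `alpha = 1, gamma = theta = -beta` can deliver, so it is
#'     excluded. The test reduces to \eqn{\gamma \le 1 - \alpha - \beta}:
#'     even against a perfectly discriminating truth-seeking receiver the
#'     strategy still delivers a majority of false stories.}
#'   \item{`responsive_accurate`}{mirror condition for
#'     \eqn{1 - v_f \ge v_{fc} + v_{tc}}, reducing to
#'     \eqn{\theta \ge 1 - \alpha - \beta}.}
#'   \item{`responsive_misinfo_strict`, `responsive_accurate_strict`}{the
#'     literal unit-simplex vertex test over
#'     \eqn{(v_{tc}, v_{fc}) \in \{(0,0), (1,0), (0,1)\}} ignoring outcome
#'     feasibility; satisfiable only on the boundary of the viable set.}
#'   \item{`extortion_neighbor`}{`TRUE` when the strategy lies within
#'     max-norm distance `delta` (in \eqn{(\alpha,\beta,\gamma,\theta)}) of
#'     one of the equality-enforcing families: `alpha = 1,
#'     gamma = theta = -b` (enforcing \eqn{v_f = v_{fc}+v_{tc}}) or
#'     `beta = 0, gamma = theta = 1-a` (enforcing
#'     \eqn{1-v_f = v_{fc}+v_{tc}}).}
#' }
#'
#' @param strategy A polynomial [transmitter_strategy()] (linear feedback).
#' @param delta Neighbourhood radius for the extortion classification.
#' @return A one-row tibble with the fields described above plus the
#'   distances `extortion_dist_pos`, `extortion_dist_neg`.
#' @export
classify_enforcement <- function(strategy, delta = 0.05) {
  if (strategy$form != "polynomial") {
    stop("classification applies to polynomial strategies", call. = FALSE)
  }
  al <- strategy$alpha; be <- strategy$beta
  ga <- sum(strategy$gamma); th <- sum(strategy$theta)
  s <- 1 - al + be
  if (abs(s) < 1e-12) {
    stop("degenerate strategy: 1 - alpha + beta = 0", call. = FALSE)
  }
  v0 <- (1 - al) / s
  ct <- -ga / s
  cf <- -th / s
  sign_lab <- if (ct >= 0 && cf >= 0 && (ct > 0 || cf > 0)) {
    "positive"
  } else if (ct <= 0 && cf <= 0 && (ct < 0 || cf < 0)) {
    "negative"
  } else {
    "none"
  }
  tol <- 1e-12
  # max-norm distance to the equality-enforcing families (the free family
  # parameter is the midrange of its three targets, clipped to [0, 1])
  dist_family <- function(fixed_dev, targets) {
    b <- (min(targets) + max(targets)) / 2
    b <- min(max(b, 0), 1)
    max(abs(fixed_dev), max(abs(targets - b)))
  }
  d_pos <- dist_family(al - 1, c(be, -ga, -th))
  d_neg <- dist_family(be, c(al, 1 - ga, 1 - th))
  tibble::tibble(
    enforcement_sign = sign_lab,
    responsive_misinfo = ga <= 1 - al - be + tol,
    responsive_accurate = th >= 1 - al - be - tol,
    responsive_misinfo_strict = (v0 + ct >= 1 - tol) && (v0 + cf >= 1 - tol),
    responsive_accurate_strict = (ct <= -v0 + tol) && (cf <= -v0 + tol),
    extortion_dist_pos = d_pos,
    extortion_dist_neg = d_neg,
    extortion_neighbor = min(d_pos, d_neg) <= delta)
}

#' Evaluate a transmitter strategy against an optimizing receiver
#'
#' Runs [optimize_receiver()] (inattentive receiver, `a0 = 0`, memory
#' attention `a1 = 1`, starting from the never-engage strategy) against the
#' given transmitter and combines the measured outcome frequencies with the
#' enforcement classification of the strategy.
#'
#' @param strategy A [transmitter_strategy()].
#' @param config A [game_config()].
#' @param opt An [optimize_config()] (`sigma = 1` by default).
#' @param a0,a1 Receiver attention parameters.
#' @param delta Extortion neighbourhood radius.
#' @return A one-row tibble (an ensemble record): strategy parameters,
#'   measured `v_f`, `v_t`, per-story engagement rates, the receiver's
#'   final behavioural components, and classification flags.
#' @export
evaluate_strategy <- function(strategy, config = game_config(),
                              opt = optimize_config(), a0 = 0, a1 = 1,
                              delta = 0.05) {
  res <- optimize_receiver(strategy, config, opt, a0 = a0, a1 = a1)
  cls <- classify_enforcement(strategy, delta = delta)
  ga <- sum(strategy$gamma); th <- sum(strategy$theta)
  dplyr::bind_cols(
    tibble::tibble(alpha = strategy$alpha, beta = strategy$beta,
                   gamma = ga, theta = th,
                   has_feedback = (ga != 0 || th != 0)),
    res$summary,
    tibble::as_tibble(as.list(setNames(
      res$final_p, paste0("receiver_", names(res$final_p))))),
    cls)
}

#' Random-search ensemble over viable transmitter strategies
#'
#' Samples `n` viable strategies (with or without linear feedback),
#' evaluates each against a myopically optimizing inattentive receiver
#' ([evaluate_strategy()]), and returns one record per strategy.
#'
#' @param n Number of strategies.
#' @param with_feedback Sample feedback coefficients or fix them at zero.
#' @param config A [game_config()]. The defaults (`pi_t = 1, pi_f = -1`,
#'   `epsilon = 1e-3`, `eta = 0.3`, `N = 1`) are the canonical ensemble
#'   conditions.
#' @param opt An [optimize_config()].
#' @param seed Optional integer seed.
#' @param progress Print a dot every 500 strategies.
#' @return A tibble of class `misinfo_ensemble`, one row per strategy.
#' @export
run_ensemble <- function(n = 1000L, with_feedback = TRUE,
                         config = game_config(), opt = optimize_config(),
                         seed = NULL, progress = FALSE) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    s <- sample_viable_strategy(with_feedback)
    rows[[i]] <- evaluate_strategy(s, config, opt)
    if (progress && i %% 500L == 0L) cat(".")
  }
  if (progress) cat("\n")
  out <- dplyr::bind_rows(rows)
  class(out) <- c("misinfo_ensemble", class(out))
  out
}

# Top-fraction cutoff using the "higher" order-statistic convention: at
# most ceiling(frac * n) records at or above the cutoff (up to ties).
top_cutoff <- function(x, frac) {
  n <- length(x)
  sort(x)[n - ceiling(frac * n) + 1L]
}

#' Select successful transmitter strategies
#'
#' Successful misinformation strategies share misinformation more often
#' than not (`v_f > share_threshold`) and produce a per-false-story
#' engagement rate within the top `top_fraction` of all records; successful
#' accurate strategies are the mirror image (majority true output, top
#' per-true-story engagement).
#'
#' @param records An ensemble tibble from [run_ensemble()].
#' @param type `"misinformation"` or `"accurate"`.
#' @param top_fraction Engagement quantile defining success (default top
#'   10%), computed over all records supplied.
#' @param share_threshold Minimum share of the favoured story type.
#' @return The selected subset of `records` (possibly empty).
#' @export
select_successful <- function(records,
                              type = c("misinformation", "accurate"),
                              top_fraction = 0.1, share_threshold = 0.5) {
  type <- match.arg(type)
  if (nrow(records) == 0L) stop("empty ensemble", call. = FALSE)
  if (type == "misinformation") {
    cut <- top_cutoff(records$engage_per_false, top_fraction)
    dplyr::filter(records, .data$v_f > share_threshold,
                  .data$engage_per_false >= cut)
  } else {
    cut <- top_cutoff(records$engage_per_true, top_fraction)
    dplyr::filter(records, .data$v_t > share_threshold,
                  .data$engage_per_true >= cut)
  }
}

#' Proportion of successful strategies that are responsive
#'
#' @param successful Records returned by [select_successful()].
#' @param type `"misinformation"` (fraction enforcing
#'   \eqn{v_f \ge v_{fc} + v_{tc}}) or `"accurate"` (fraction enforcing
#'   \eqn{1 - v_f \ge v_{fc} + v_{tc}}).
#' @return A percentage.
#' @export
responsive_proportion <- function(successful,
                                  type = c("misinformation", "accurate")) {
  type <- match.arg(type)
  if (nrow(successful) == 0L) stop("no successful strategies", call. = FALSE)
  flag <- if (type == "misinformation") successful$responsive_misinfo
          else successful$responsive_accurate
  100 * mean(flag)
}

#' Enrichment of extortion-neighbourhood strategies among the successful
#'
#' One-sided exact binomial test of the prevalence of
#' `extortion_neighbor` among successful strategies against its prevalence
#' in the full ensemble (the null draw probability).
#'
#' @param records Full ensemble.
#' @param successful Selected subset.
#' @return A one-row tibble with `prevalence_successful`,
#'   `prevalence_null`, and `p_value`.
#' @export
extortion_enrichment <- function(records, successful) {
  stopifnot(nrow(records) > 0L, nrow(successful) > 0L)
  p0 <- mean(records$extortion_neighbor)
  k <- sum(successful$extortion_neighbor)
  n <- nrow(successful)
  p <- if (p0 <= 0) {
    if (k > 0) 0 else 1
  } else if (p0 >= 1) {
    1
  } else {
    binom.test(k, n, p = p0, alternative = "greater")$p.value
  }
  tibble::tibble(prevalence_successful = k / n, prevalence_null = p0,
                 p_value = p)
}

#' Summarise an ensemble run
#'
#' Applies success selection and responsive classification for both
#' transmitter types.
#'
#' @param records A `misinfo_ensemble` tibble.
#' @param top_fraction,share_threshold Passed to [select_successful()].
#' @return A tibble with one row per transmitter type: number successful,
#'   responsive percentage, mean engagement rates.
#' @export
summarise_ensemble <- function(records, top_fraction = 0.1,
                               share_threshold = 0.5) {
  purrr::map_dfr(c("misinformation", "accurate"), function(ty) {
    suc <- select_successful(records, ty, top_fraction, share_threshold)
    tibble::tibble(
      type = ty,
      n_successful = nrow(suc),
      responsive_pct = if (nrow(suc)) responsive_proportion(suc, ty) else NA_real_,
      mean_engage_per_false = mean(suc$engage_per_false),
      mean_engage_per_true = mean(suc$engage_per_true),
      mean_v_f = mean(suc$v_f))
  })
}
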