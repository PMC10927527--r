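#' Simulate a sequence of news stories with population engagement
#'
#' Iterates the game for a transmitter strategy against a population of
#' receivers sharing a behavioural strategy -- typically a successful
#' strategy and its associated receiver from an ensemble run. For each
#' story the population engagement probability (engaged and non-engaged
#' receivers apply their respective memory components) is computed, the
#' realized engagement count is drawn binomially, and that realized
#' fraction both updates the population's memory state and drives the
#' transmitter's feedback for the next story. Between stories the shared
#' receiver strategy continues its myopic noisy optimization
#' (`updates_per_story` Fermi update events at attention `sigma`),
#' reflecting the game's two-timescale structure. The story's perceived
#' accuracy is its binary veracity flipped with the perception error
#' `eta`.
#'
#' @param transmitter A polynomial [transmitter_strategy()] (linear
#'   feedback; the rule is evaluated at the realized engaged fraction).
#' @param receiver A [receiver_strategy()].
#' @param n_stories Number of stories (at least 2).
#' @param population Number of receivers for the binomial engagement draw.
#' @param epsilon,eta Execution and perception error rates.
#' @param realized Report the realized engaged fraction (`TRUE`, default)
#'   or the expected engagement probability.
#' @param updates_per_story Receiver optimization events between
#'   consecutive stories (0 freezes the receiver).
#' @param pi_t,pi_f Receiver utilities used during those updates.
#' @param sigma,proposal_scale Fermi attention and local kernel width for
#'   the updates.
#' @param seed Optional integer seed.
#' @return A tibble with one row per story: `index`, `veracity`,
#'   `perceived_accuracy`, `engagement_rate`, `expected_engagement`.
#' @export
simulate_story_sequence <- function(transmitter, receiver, n_stories = 20L,
                                    population = 100000L, epsilon = 1e-3,
                                    eta = 0.3, realized = TRUE,
                                    updates_per_story = 50L, pi_t = 1,
                                    pi_f = -1, sigma = 1,
                                    proposal_scale = 0.1, seed = NULL) {
  if (n_stories < 2L) stop("need at least 2 stories for a regression", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  out <- cpp_story_sequence(transmitter_vec(transmitter),
                            receiver_vec(receiver), epsilon, eta,
                            as.integer(n_stories), as.integer(population),
                            realized, as.integer(updates_per_story),
                            pi_t, pi_f, sigma, proposal_scale)
  tibble::tibble(
    index = seq_len(n_stories),
    veracity = ifelse(out$veracity == 0L, "t", "f"),
    perceived_accuracy = out$perceived_accuracy,
    engagement_rate = out$engagement_rate,
    expected_engagement = out$expected_q)
}

#' Standardized engagement-accuracy regression slope
#'
#' OLS slope of z-scored engagement rate on z-scored perceived accuracy --
#' equal to the sample correlation coefficient. When either variable has
#' zero variance (e.g. an always-true transmitter under `eta = 0`) the
#' slope is 0 by convention, with a warning.
#'
#' @param stories A tibble from [simulate_story_sequence()] (columns
#'   `engagement_rate` and `perceived_accuracy`).
#' @return The standardized slope (a scalar in `[-1, 1]`).
#' @export
engagement_accuracy_slope <- function(stories) {
  stopifnot(nrow(stories) >= 2L)
  x <- stories$perceived_accuracy
  y <- stories$engagement_rate
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero variance in accuracy or engagement; slope set to 0")
    return(0)
  }
  unname(stats::cov(x, y) / (sd(x) * sd(y)))
}

#' Rank-ordering experiment for engagement-accuracy slopes
#'
#' Per replicate, `n_each` (transmitter, receiver) pairs are drawn from the
#' successful-accurate and successful-misinformation pools, a story
#' sequence is simulated for each and its standardized engagement-accuracy
#' slope computed, and the `2 * n_each` slopes are ranked from lowest to
#' highest. Averaging over replicates gives the mean slope at each rank and
#' the fraction of misinformation-type transmitters occupying it. With
#' feedback, the lowest ranks are negative and dominated by misinformation
#' transmitters and the highest positive and dominated by accurate ones;
#' without feedback the composition is exchangeable (about 50/50).
#'
#' @param accurate_pool,misinfo_pool Ensemble record tibbles (rows carrying
#'   `alpha`, `beta`, `gamma`, `theta` and `receiver_*` columns), e.g. the
#'   outputs of [select_successful()].
#' @param replicates Number of replicates.
#' @param n_each Transmitters drawn per type per replicate (with
#'   replacement).
#' @param n_stories,population,epsilon,eta Passed to
#'   [simulate_story_sequence()].
#' @param a0,a1 Receiver attention parameters for the paired receivers.
#' @param seed Optional integer seed.
#' @return A tibble of class `rank_experiment`: `rank`, `mean_slope`,
#'   `frac_misinformation`.
#' @export
rank_experiment <- function(accurate_pool, misinfo_pool, replicates = 100L,
                            n_each = 20L, n_stories = 20L,
                            population = 100000L, epsilon = 1e-3, eta = 0.3,
                            a0 = 0, a1 = 1, seed = NULL) {
  stopifnot(nrow(accurate_pool) >= 1L, nrow(misinfo_pool) >= 1L,
            replicates >= 1L)
  if (!is.null(seed)) set.seed(seed)
  n_ranks <- 2L * n_each
  slope_sum <- numeric(n_ranks)
  misinfo_sum <- numeric(n_ranks)
  pools <- list(accurate = accurate_pool, misinformation = misinfo_pool)
  for (rep in seq_len(replicates)) {
    slopes <- numeric(n_ranks)
    is_mis <- logical(n_ranks)
    idx <- 1L
    for (ty in names(pools)) {
      pool <- pools[[ty]]
      take <- sample.int(nrow(pool), n_each, replace = TRUE)
      for (i in take) {
        row <- pool[i, ]
        tr <- transmitter_strategy(row$alpha, row$beta, row$gamma, row$theta)
        rc <- receiver_strategy(a0 = a0, a1 = a1, p0 = row$receiver_p0,
                                p_ct = row$receiver_p_ct,
                                p_cf = row$receiver_p_cf,
                                p_nt = row$receiver_p_nt,
                                p_nf = row$receiver_p_nf)
        st <- simulate_story_sequence(tr, rc, n_stories, population,
                                      epsilon, eta)
        slopes[idx] <- suppressWarnings(engagement_accuracy_slope(st))
        is_mis[idx] <- ty == "misinformation"
        idx <- idx + 1L
      }
    }
    ord <- order(slopes)
    slope_sum <- slope_sum + slopes[ord]
    misinfo_sum <- misinfo_sum + as.numeric(is_mis[ord])
  }
  out <- tibble::tibble(rank = seq_len(n_ranks),
                        mean_slope = slope_sum / replicates,
                        frac_misinformation = misinfo_sum / replicates)
  class(out) <- c("rank_experiment", class(out))
  out
}

#' @export
autoplot.rank_experiment <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$rank, y = .data$mean_slope,
    fill = .data$frac_misinformation)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_gradient(low = "steelblue", high = "firebrick",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "rank (lowest to highest slope)",
                  y = "mean standardized slope",
                  fill = "fraction\nmisinformation") +
    ggplot2::theme_minimal()
}

#' Demonstration of engagement-driven misinformation switching
#'
#' Runs the steep sigmoidal feedback transmitter (`lambda = 100`, midpoints
#' 0.5 after true stories and 0.25 after false ones) against a population
#' of `N = 100` receivers who share a behavioural strategy updated by
#' population-level myopic optimization with low attention to accuracy
#' (`a0 = 0`), experience (`a1 = 0`) and payoff (`sigma = 1`). The
#' transmitter produces mostly true stories while engagement is low and
#' switches to mostly false stories when engagement is high, so that the
#' average engagement probability per false story ends up higher than per
#' true story even though receivers seek true stories.
#'
#' @param transmitter Transmitter strategy (defaults to the sigmoid
#'   switch).
#' @param N Number of receivers.
#' @param config A [game_config()]; `N` is taken from the argument above.
#' @param sigma,proposal_scale Receiver optimization settings.
#' @param epochs Number of receiver update events.
#' @param rounds_per_epoch Game rounds played (and recorded) between update
#'   events; candidate strategies are scored on as many unrecorded rounds.
#' @param a0,a1 Receiver attention parameters.
#' @param seed Optional integer seed.
#' @return An object of class `sigmoid_demo`: list with `trace` (round,
#'   veracity, k_engaged, p0 of the current strategy), `engage_per_true`,
#'   `engage_per_false`, and `misinfo_by_engagement` (mean share of false
#'   stories in rounds with above- vs below-median engagement).
#' @export
sigmoid_demo <- function(transmitter = sigmoid_strategy(), N = 100L,
                         config = game_config(), sigma = 1,
                         proposal_scale = 0.1, epochs = 2000L,
                         rounds_per_epoch = 50L, a0 = 0, a1 = 0,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rt <- transmit_prob(transmitter, "t", 0:N, N)
  rf <- transmit_prob(transmitter, "f", 0:N, N)
  out <- cpp_population_optimize(rt, rf, as.integer(N), a0, a1, rep(0, 5),
                                 config$pi_t, config$pi_f, config$epsilon,
                                 config$eta, sigma, proposal_scale,
                                 as.integer(epochs),
                                 as.integer(rounds_per_epoch))
  trace <- tibble::tibble(
    round = seq_along(out$veracity),
    veracity = ifelse(out$veracity == 0L, "t", "f"),
    k_engaged = out$k)
  med <- stats::median(trace$k_engaged)
  hi <- trace$k_engaged > med
  lo <- trace$k_engaged < med
  structure(list(
    trace = trace,
    p0_series = out$p0_series,
    engage_per_true = out$engage_per_true,
    engage_per_false = out$engage_per_false,
    misinfo_by_engagement = c(
      high = mean(trace$veracity[hi] == "f"),
      low = mean(trace$veracity[lo] == "f"))
  ), class = "sigmoid_demo")
}

#' @exportS3Method base::print
print.sigmoid_demo <- function(x, ...) {
  cat("<sigmoid_demo>\n")
  cat(sprintf("  engagement per true story : %.3f\n", x$engage_per_true))
  cat(sprintf("  engagement per false story: %.3f\n", x$engage_per_false))
  cat(sprintf("  share false | high engagement: %.3f, low engagement: %.3f\n",
              x$misinfo_by_engagement[["high"]],
              x$misinfo_by_engagement[["low"]]))
  invisible(x)
}

#' @export
autoplot.sigmoid_demo <- function(object, window = 200L, ...) {
  tr <- object$trace
  n <- nrow(tr)
  grp <- ceiling(seq_len(n) / window)
  df <- tibble::tibble(
    block = tapply(tr$round, grp, mean),
    engagement = tapply(tr$k_engaged, grp, mean) / max(tr$k_engaged, 1),
    share_true = tapply(tr$veracity == "t", grp, mean))
  df <- tidyr::pivot_longer(df, c("engagement", "share_true"),
                            names_to = "series")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$block, y = .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "round", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
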