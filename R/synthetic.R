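#' Generate a synthetic site table with known ground truth
#'
#' Emulates the structure of a site-level engagement study: per site,
#' headline accuracies are drawn from the site type's normal distribution
#' (clipped to the 1-7 rating scale) and
#' \deqn{\log_{10}(\mathrm{engagement}) = \mu_e + \sigma_e\,
#'   [\rho\, z(\mathrm{accuracy}) + \sqrt{1 - \rho^2}\, \varepsilon],}
#' so the population correlation between accuracy and log-engagement
#' within a site equals the type's `true_slope` \eqn{\rho} exactly (the
#' standardized slope recovered by [site_slope()]). Engagement counts are
#' `round(10^x)`.
#'
#' @param n_sites_per_type Sites per type.
#' @param headlines_per_site Headlines per site (at least 3).
#' @param true_slope_mainstream,true_slope_misinfo Standardized
#'   accuracy-engagement slopes (defaults mirror typical empirical
#'   magnitudes, 0.13 and -0.11).
#' @param accuracy_mean Named vector of mean accuracy ratings per type
#'   (mainstream sites share more plausible headlines).
#' @param accuracy_sd Accuracy rating standard deviation.
#' @param engagement_log_mean,engagement_log_sd Location and scale of
#'   log10 engagement.
#' @param seed Optional integer seed.
#' @return A tibble: `site_id`, `site_type`, `headline_id`,
#'   `mean_accuracy`, `engagement`.
#' @export
generate_site_table <- function(n_sites_per_type = 20L,
                                headlines_per_site = 25L,
                                true_slope_mainstream = 0.13,
                                true_slope_misinfo = -0.11,
                                accuracy_mean = c(mainstream = 4.8,
                                                  misinformation = 3.4),
                                accuracy_sd = 1,
                                engagement_log_mean = 3,
                                engagement_log_sd = 0.5,
                                seed = NULL) {
  stopifnot(headlines_per_site >= 3L, accuracy_sd > 0, engagement_log_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  slopes <- c(mainstream = true_slope_mainstream,
              misinformation = true_slope_misinfo)
  purrr::map_dfr(c("mainstream", "misinformation"), function(ty) {
    purrr::map_dfr(seq_len(n_sites_per_type), function(s) {
      acc <- pmin(pmax(rnorm(headlines_per_site, accuracy_mean[[ty]],
                             accuracy_sd), 1), 7)
      z <- as.numeric(scale(acc))
      rho <- slopes[[ty]]
      x <- engagement_log_mean + engagement_log_sd *
        (rho * z + sqrt(1 - rho^2) * rnorm(headlines_per_site))
      tibble::tibble(
        site_id = sprintf("%s_%02d", substr(ty, 1, 4), s),
        site_type = ty,
        headline_id = sprintf("%s_%02d_h%02d", substr(ty, 1, 4), s,
                              seq_len(headlines_per_site)),
        mean_accuracy = acc,
        engagement = round(10^x))
    })
  })
}

#' Generate a synthetic rating table with crossed random effects
#'
#' Emulates a rating-level survey: every subject rates every headline.
#' A latent accuracy perception `a ~ veracity_shift + N(0, 1)` drives the
#' outcome
#' \deqn{y = \beta a + u_{subject} + w_{headline} + e,}
#' with independent normal random intercepts and noise. With the default
#' variance components (`0.5^2` each and `beta = 0.5`) the total outcome
#' variance is 1, so the standardized rating-level effect recovered by
#' [clustered_rating_regression()] equals `true_effect` exactly. Ratings
#' are mapped to the 1-7 scale by an affine rescale and clipping.
#'
#' @param n_subjects,n_headlines Design size (at least 2 each).
#' @param true_effect Standardized effect of accuracy on the outcomes.
#' @param subject_sd,headline_sd,noise_sd Random-intercept and residual
#'   standard deviations.
#' @param veracity_shift Shift of the latent accuracy mean for truly true
#'   headlines (half the headlines are true).
#' @param seed Optional integer seed.
#' @return A tibble: `subject_id`, `headline_id`, `accuracy`, `click`,
#'   `share`, `headline_veracity`.
#' @export
generate_rating_table <- function(n_subjects = 200L, n_headlines = 40L,
                                  true_effect = 0.5, subject_sd = 0.5,
                                  headline_sd = 0.5, noise_sd = 0.5,
                                  veracity_shift = 0.3, seed = NULL) {
  stopifnot(n_subjects >= 2L, n_headlines >= 2L, subject_sd >= 0,
            headline_sd >= 0, noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  veracity <- rep(c(TRUE, FALSE), length.out = n_headlines)
  u <- rnorm(n_subjects, 0, subject_sd)
  w <- rnorm(n_headlines, 0, headline_sd)
  grid <- tidyr::expand_grid(subject = seq_len(n_subjects),
                             headline = seq_len(n_headlines))
  a <- veracity_shift * ifelse(veracity[grid$headline], 1, -1) +
    rnorm(nrow(grid))
  to_scale <- function(x) pmin(pmax(4 + x, 1), 7)
  mk_outcome <- function() {
    true_effect * a + u[grid$subject] + w[grid$headline] +
      rnorm(nrow(grid), 0, noise_sd)
  }
  tibble::tibble(
    subject_id = sprintf("s%03d", grid$subject),
    headline_id = sprintf("h%03d", grid$headline),
    accuracy = to_scale(a),
    click = to_scale(mk_outcome()),
    share = to_scale(mk_outcome()),
    headline_veracity = ifelse(veracity[grid$headline], "true", "false"))
}
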