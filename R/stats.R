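#' Within-site accuracy-engagement regression
#'
#' OLS slope of z-scored `log10(engagement)` on z-scored mean headline
#' accuracy within one site. Because both variables are standardized the
#' slope equals the sample correlation coefficient; the conventional
#' standard error and two-sided t-test p-value (df = n - 2) are returned.
#' If any engagement count in the site is zero, `log10(engagement + 1)` is
#' used for all rows of that site (recorded in the `offset` column).
#'
#' @param site_rows Rows of a site table for a single site (columns
#'   `mean_accuracy`, `engagement`).
#' @return A one-row tibble: `slope`, `se`, `p`, `n`, `offset`.
#' @export
site_slope <- function(site_rows) {
  n <- nrow(site_rows)
  if (n < 3L) stop("need at least 3 headlines per site", call. = FALSE)
  if (any(site_rows$engagement < 0)) stop("negative engagement", call. = FALSE)
  offset <- as.numeric(any(site_rows$engagement == 0))
  y <- log10(site_rows$engagement + offset)
  x <- site_rows$mean_accuracy
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero variance within site; slope set to 0")
    return(tibble::tibble(slope = 0, se = NA_real_, p = 1, n = n,
                          offset = offset))
  }
  r <- stats::cov(x, y) / (sd(x) * sd(y))
  r <- min(max(r, -1), 1)
  se <- sqrt((1 - r^2) / (n - 2))
  tstat <- if (se == 0) sign(r) * Inf else r / se
  p <- 2 * pt(-abs(tstat), df = n - 2)
  tibble::tibble(slope = r, se = se, p = p, n = n, offset = offset)
}

#' Fisher's combined probability test
#'
#' Combines independent p-values via \eqn{X^2 = -2 \sum_i \log p_i}, which
#' is chi-square distributed with `2k` degrees of freedom under the global
#' null.
#'
#' @param p_values Numeric vector of p-values in `(0, 1]`.
#' @return A one-row tibble: `statistic`, `df`, `p`.
#' @export
fishers_combined <- function(p_values) {
  if (length(p_values) == 0L) stop("no p-values", call. = FALSE)
  if (any(p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stat <- -2 * sum(log(p_values))
  df <- 2L * length(p_values)
  tibble::tibble(statistic = stat, df = df,
                 p = pchisq(stat, df = df, lower.tail = FALSE))
}

#' Random-effects meta-analysis of site slopes
#'
#' DerSimonian-Laird random-effects pooling of per-site standardized
#' slopes: the between-site variance \eqn{\tau^2} is the moment estimator
#' truncated at zero, the pooled mean is inverse-variance weighted, and the
#' two-sided p-value comes from the normal approximation. Implemented via
#' `metafor::rma(method = "DL")`.
#'
#' @param effects A data frame with columns `slope` and `se` (one row per
#'   site), or a numeric vector of slopes with `se` given separately.
#' @param se Standard errors when `effects` is a numeric vector.
#' @return A one-row tibble: `mu`, `se_mu`, `tau2`, `p`, `k`.
#' @export
random_effects_meta <- function(effects, se = NULL) {
  if (is.numeric(effects)) {
    effects <- tibble::tibble(slope = effects, se = se)
  }
  if (nrow(effects) < 2L) stop("need at least 2 effects", call. = FALSE)
  if (any(effects$se <= 0 | !is.finite(effects$se))) {
    stop("all standard errors must be positive and finite", call. = FALSE)
  }
  fit <- metafor::rma(yi = effects$slope, sei = effects$se, method = "DL")
  tibble::tibble(mu = as.numeric(fit$beta), se_mu = fit$se,
                 tau2 = fit$tau2, p = fit$pval, k = fit$k)
}

#' Rating-level regression with two-way cluster-robust standard errors
#'
#' OLS of the z-scored outcome (`click` or `share`) on the z-scored
#' accuracy rating at the rating level. The covariance matrix is the
#' two-way clustered sandwich estimator
#' \eqn{V = V_{subject} + V_{headline} - V_{subject \times headline}}
#' (inclusion-exclusion over the two clustering dimensions, via
#' `sandwich::vcovCL`), without small-sample adjustment unless requested.
#'
#' @param table A rating table (columns `subject_id`, `headline_id`,
#'   `accuracy`, and the outcome).
#' @param outcome `"click"` or `"share"`.
#' @param cadjust Apply the G/(G-1) cluster adjustment (default `FALSE`).
#' @return An object of class `rating_regression` with [tidy()] and
#'   [glance()] methods; a list with `beta`, `se`, `z`, `p`, the fitted
#'   `lm`, and bookkeeping counts.
#' @export
clustered_rating_regression <- function(table, outcome = c("click", "share"),
                                        cadjust = FALSE) {
  outcome <- match.arg(outcome)
  if (length(unique(table$subject_id)) < 2L ||
      length(unique(table$headline_id)) < 1L) {
    stop("need at least 2 subjects and 1 headline", call. = FALSE)
  }
  df <- data.frame(
    y = as.numeric(scale(table[[outcome]])),
    x = as.numeric(scale(table$accuracy)),
    subject_id = factor(table$subject_id),
    headline_id = factor(table$headline_id))
  if (!all(is.finite(df$x)) || !all(is.finite(df$y))) {
    stop("zero variance in outcome or predictor", call. = FALSE)
  }
  fit <- lm(y ~ x, data = df)
  V <- sandwich::vcovCL(fit, cluster = ~ subject_id + headline_id,
                        type = "HC0", cadjust = cadjust)
  beta <- unname(coef(fit)["x"])
  se <- sqrt(V["x", "x"])
  z <- beta / se
  structure(list(beta = beta, se = se, z = z, p = 2 * pnorm(-abs(z)),
                 outcome = outcome, fit = fit,
                 n = nrow(df),
                 n_subjects = nlevels(df$subject_id),
                 n_headlines = nlevels(df$headline_id)),
            class = "rating_regression")
}

#' @exportS3Method base::print
print.rating_regression <- function(x, ...) {
  cat(sprintf(
    "<rating_regression: z(%s) ~ z(accuracy)>\n  beta = %.4f  se = %.4f  z = %.2f  p = %.3g\n",
    x$outcome, x$beta, x$se, x$z, x$p))
  cat(sprintf("  %d ratings, %d subjects, %d headlines\n",
              x$n, x$n_subjects, x$n_headlines))
  invisible(x)
}

#' @export
tidy.rating_regression <- function(x, ...) {
  tibble::tibble(term = "accuracy", estimate = x$beta, std.error = x$se,
                 statistic = x$z, p.value = x$p)
}

#' @export
glance.rating_regression <- function(x, ...) {
  tibble::tibble(nobs = x$n, n_subjects = x$n_subjects,
                 n_headlines = x$n_headlines, outcome = x$outcome)
}

#' Full site-table analysis
#'
#' Applies [site_slope()] to every site, then [fishers_combined()] and
#' [random_effects_meta()] separately to the mainstream and misinformation
#' site groups.
#'
#' @param table A site table (columns `site_id`, `site_type`,
#'   `headline_id`, `mean_accuracy`, `engagement`).
#' @return An object of class `site_analysis` with [tidy()] (per-site
#'   slopes) and [glance()] (per-type combined statistics) methods.
#' @export
analyze_site_table <- function(table) {
  stopifnot(all(c("site_id", "site_type", "mean_accuracy", "engagement")
                %in% names(table)))
  types <- unique(table$site_type)
  for (ty in c("mainstream", "misinformation")) {
    ids <- unique(table$site_id[table$site_type == ty])
    if (length(ids) < 2L) {
      stop(sprintf("need at least 2 sites of type '%s'", ty), call. = FALSE)
    }
  }
  slopes <- table |>
    dplyr::group_by(.data$site_id, .data$site_type) |>
    dplyr::group_modify(~ site_slope(.x)) |>
    dplyr::ungroup()
  groups <- purrr::map_dfr(unique(slopes$site_type), function(ty) {
    sl <- dplyr::filter(slopes, .data$site_type == ty)
    fc <- fishers_combined(sl$p)
    re <- random_effects_meta(sl[, c("slope", "se")])
    tibble::tibble(site_type = ty, n_sites = nrow(sl),
                   mean_slope = mean(sl$slope),
                   fisher_statistic = fc$statistic, fisher_df = fc$df,
                   fisher_p = fc$p, mu = re$mu, se_mu = re$se_mu,
                   tau2 = re$tau2, meta_p = re$p)
  })
  structure(list(slopes = slopes, groups = groups,
                 log_offset_note = "sites containing zero engagement use log10(engagement + 1)"),
            class = "site_analysis")
}

#' @exportS3Method base::print
print.site_analysis <- function(x, ...) {
  cat("<site_analysis>\n")
  print(as.data.frame(dplyr::mutate(
    x$groups, dplyr::across(dplyr::where(is.numeric), ~ signif(.x, 3)))),
    row.names = FALSE)
  invisible(x)
}

#' @export
tidy.site_analysis <- function(x, ...) x$slopes

#' @export
glance.site_analysis <- function(x, ...) x$groups

#' @export
autoplot.site_analysis <- function(object, ...) {
  mu <- object$groups
  ggplot2::ggplot(object$slopes,
                  ggplot2::aes(x = .data$site_type, y = .data$slope,
                               colour = .data$site_type)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_point(data = mu,
                        ggplot2::aes(y = .data$mu), size = 4, shape = 18) +
    ggplot2::scale_colour_manual(values = c(mainstream = "steelblue",
                                            misinformation = "firebrick")) +
    ggplot2::labs(x = NULL, y = "standardized accuracy-engagement slope") +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}
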