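test_that("site slopes equal within-site correlations, with lm as oracle", {
  set.seed(601)
  site <- tibble::tibble(mean_accuracy = runif(25, 1, 7))
  site$engagement <- round(10^site$mean_accuracy)
  s <- site_slope(site)
  expect_equal(s$slope, 1, tolerance = 1e-3)
  expect_lt(s$p, 1e-12)

  site2 <- tibble::tibble(mean_accuracy = rnorm(25, 4),
                          engagement = round(10^rnorm(25, 3, 0.5)))
  s2 <- site_slope(site2)
  fit <- lm(scale(log10(site2$engagement)) ~ scale(site2$mean_accuracy))
  sm <- summary(fit)$coefficients[2, ]
  expect_equal(s2$slope, unname(sm["Estimate"]), tolerance = 1e-10)
  expect_equal(s2$se, unname(sm["Std. Error"]), tolerance = 1e-10)
  expect_equal(s2$p, unname(sm["Pr(>|t|)"]), tolerance = 1e-10)

  # scale invariance of engagement units
  site3 <- dplyr::mutate(site2, engagement = engagement * 100)
  expect_equal(site_slope(site3)$slope, s2$slope, tolerance = 1e-12)

  # permutation null is centred at zero
  null_slopes <- replicate(300, {
    site_slope(dplyr::mutate(site2, mean_accuracy = sample(mean_accuracy)))$slope
  })
  expect_lt(abs(mean(null_slopes)), 0.05)

  expect_error(site_slope(site2[1:2, ]), "at least 3")
})

test_that("Fisher's combined test matches its closed form and is additive", {
  expect_equal(fishers_combined(rep(1, 4))$statistic, 0)
  expect_equal(fishers_combined(rep(1, 4))$p, 1)
  expect_equal(fishers_combined(0.05)$p, 0.05, tolerance = 1e-12)

  fc <- fishers_combined(c(0.01, 0.04))
  expect_equal(fc$statistic, -2 * (log(0.01) + log(0.04)), tolerance = 1e-12)
  expect_equal(fc$statistic, 15.648, tolerance = 1e-3)
  expect_equal(fc$df, 4L)
  expect_equal(fc$p, 0.0035, tolerance = 1e-2)

  set.seed(602)
  p1 <- runif(5); p2 <- runif(3)
  expect_equal(fishers_combined(c(p1, p2))$statistic,
               fishers_combined(p1)$statistic + fishers_combined(p2)$statistic)
  expect_equal(fishers_combined(c(p1, p2))$df,
               fishers_combined(p1)$df + fishers_combined(p2)$df)
  expect_error(fishers_combined(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("random-effects pooling matches the DerSimonian-Laird closed form", {
  eq <- random_effects_meta(rep(0.3, 6), se = rep(0.1, 6))
  expect_equal(eq$mu, 0.3, tolerance = 1e-10)
  expect_equal(eq$tau2, 0)

  set.seed(603)
  for (i in 1:20) {
    k <- sample(3:15, 1)
    slope <- rnorm(k, 0.2, 0.3)
    se <- runif(k, 0.05, 0.4)
    got <- random_effects_meta(slope, se = se)
    want <- dl_meta_oracle(slope, se)
    expect_equal(got$mu, want$mu, tolerance = 1e-8)
    expect_equal(got$se_mu, want$se_mu, tolerance = 1e-8)
    expect_equal(got$tau2, want$tau2, tolerance = 1e-8)
    expect_equal(got$p, want$p, tolerance = 1e-8)
    expect_gte(got$mu, min(slope))
    expect_lte(got$mu, max(slope))
  }
  expect_error(random_effects_meta(0.2, se = 0.1), "at least 2")
})

test_that("meta-analysis recovers a known mean slope from synthetic sites", {
  tab <- generate_site_table(n_sites_per_type = 20, headlines_per_site = 25,
                             true_slope_mainstream = 0.13, seed = 3)
  an <- analyze_site_table(tab)
  g <- glance(an)
  main <- g[g$site_type == "mainstream", ]
  expect_lt(abs(main$mu - 0.13), 2 * main$se_mu)
})

test_that("two-way clustered regression is exact, reduces, and recovers", {
  set.seed(605)
  # outcome identical to predictor: unit slope, vanishing uncertainty
  tab <- generate_rating_table(n_subjects = 30, n_headlines = 10,
                               true_effect = 1, subject_sd = 0,
                               headline_sd = 0, noise_sd = 0, seed = 606)
  fit <- suppressWarnings(clustered_rating_regression(tab, "click"))
  expect_equal(fit$beta, 1, tolerance = 1e-8)
  expect_lt(fit$se, 1e-8)

  # singleton headline clusters: two-way clustering collapses to one-way
  # clustering on subject
  tab2 <- generate_rating_table(n_subjects = 25, n_headlines = 8, seed = 607)
  tab2$headline_id <- sprintf("r%04d", seq_len(nrow(tab2)))
  fit2 <- clustered_rating_regression(tab2, "share")
  m <- lm(scale(share) ~ scale(accuracy), data = tab2)
  V1 <- sandwich::vcovCL(m, cluster = tab2$subject_id, type = "HC0",
                         cadjust = FALSE)
  expect_equal(fit2$se, sqrt(V1[2, 2]), tolerance = 1e-8)

  # parameter recovery with crossed random effects; clustering widens SEs
  tab3 <- generate_rating_table(n_subjects = 150, n_headlines = 40,
                                true_effect = 0.5, seed = 608)
  fit3 <- clustered_rating_regression(tab3, "click")
  expect_lt(abs(fit3$beta - 0.5), 2 * fit3$se)
  naive_se <- summary(fit3$fit)$coefficients[2, 2]
  expect_gt(fit3$se, naive_se)

  td <- tidy(fit3)
  expect_equal(td$estimate, fit3$beta)
  expect_equal(glance(fit3)$n_subjects, 150L)
})

test_that("site-table analysis recovers generator ground truth", {
  tab <- generate_site_table(seed = 609)
  an <- analyze_site_table(tab)
  g <- glance(an)
  expect_gt(g$mu[g$site_type == "mainstream"], 0)
  expect_lt(g$mu[g$site_type == "misinformation"], 0)
  # a stronger true slope makes the combined test decisively significant
  strong <- generate_site_table(true_slope_mainstream = 0.4,
                                true_slope_misinfo = -0.4, seed = 610)
  gs <- glance(analyze_site_table(strong))
  expect_lt(max(gs$fisher_p), 1e-3)
  expect_equal(nrow(tidy(an)), 40L)
  expect_s3_class(autoplot(an), "ggplot")

  solo <- dplyr::filter(tab, site_type == "mainstream" |
                          site_id == "misi_01")
  expect_error(analyze_site_table(solo), "at least 2 sites")
})
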