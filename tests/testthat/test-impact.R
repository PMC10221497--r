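test_that("fixed-variance filtering matches brute-force joint-Gaussian evaluation", {
  withr::with_seed(1, y <- rnorm(5, 10, 1))
  for (pars in list(c(0.8, 0.3), c(2.0, 0.01))) {
    kf <- kalman_filter(y, pars[1], pars[2], m0 = 9.5, P0 = 4)
    bf <- brute_force_local_level(y, pars[1], pars[2], m0 = 9.5, P0 = 4)
    expect_lt(abs(kf$loglik - bf$loglik), 1e-6)
    expect_lt(max(abs(kf$filtered_mean - bf$filtered_mean)), 1e-6)
  }
})

test_that("posterior medians recover the generating variances within a factor of two", {
  s <- sim_local_level(500, 0, sigma2_obs = 1.0, sigma2_level = 0.01,
                       level0 = 10, seed = 11)
  fit <- fit_local_level(s$value, seed = 2)
  med_obs <- median(fit$draws$s2_obs)
  med_lvl <- median(fit$draws$s2_level)
  expect_gt(med_obs, 0.5); expect_lt(med_obs, 2.0)
  expect_gt(med_lvl, 0.005); expect_lt(med_lvl, 0.02)
  expect_lt(max(fit$rhat), 1.1)
})

test_that("a constant series triggers a degenerate fit with a flat counterfactual", {
  expect_warning(fit <- fit_local_level(rep(3, 40), seed = 1), "degenerate")
  cf <- predict_counterfactual(fit, horizon = 10)
  expect_true(all(abs(cf$quantiles$mean - 3) < 1e-3))
  expect_true(all(abs(cf$quantiles$q975 - 3) < 1e-2))
})

test_that("predictive uncertainty accumulates with horizon and vanishes without innovation", {
  fit <- structure(list(
    draws = tibble::tibble(chain = 1L, s2_obs = rep(1, 2000),
                           s2_level = 0.5, level_T = 5),
    seed = 1L
  ), class = "local_level_fit")
  cf <- predict_counterfactual(fit, horizon = 30, seed = 4)
  width <- cf$quantiles$q975 - cf$quantiles$q025
  fitw <- lm(width ~ seq_along(width))
  expect_gt(coef(fitw)[2], 0)           # variance accumulates with horizon
  expect_gt(width[30], width[1])

  # zero level innovation: predictive mean flat at the last filtered level
  fit0 <- structure(list(
    draws = tibble::tibble(chain = 1L, s2_obs = rep(1e-8, 500),
                           s2_level = 0, level_T = 7),
    seed = 1L
  ), class = "local_level_fit")
  cf0 <- predict_counterfactual(fit0, horizon = 20, seed = 5)
  expect_true(all(abs(cf0$quantiles$mean - 7) < 1e-3))
  expect_error(predict_counterfactual(fit0, horizon = 0),
               class = "eventpulse_validation_error")
})

test_that("effect summaries degenerate correctly when nothing changed", {
  obs <- c(2, 3, 4)
  paths <- matrix(rep(obs, each = 50), nrow = 50)
  res <- summarize_effect(obs, paths)
  expect_identical(res$summary$abs_effect, 0)
  expect_identical(res$summary$rel_effect, 0)
  expect_identical(res$summary$p, 1)
  expect_identical(res$series$point_effect, c(0, 0, 0))
  # tail-area probability is floored at 1/(draws + 1)
  paths2 <- matrix(rnorm(50 * 3, 0, 0.001), 50, 3)
  res2 <- summarize_effect(obs, paths2)
  expect_gte(res2$summary$p, 1 / 51)
  # draws with nonpositive totals are rejected with a message
  paths3 <- rbind(paths, matrix(-10, 5, 3))
  expect_message(res3 <- summarize_effect(obs, paths3), "rejected 5")
  expect_identical(res3$summary$n_rejected, 5L)
})

test_that("median absolute and relative effects share a sign", {
  withr::with_seed(6, {
    for (i in 1:5) {
      obs <- rnorm(20, 10, 1) * sample(c(0.5, 2), 1)
      paths <- matrix(rnorm(200 * 20, 10, 1), 200, 20)
      s <- summarize_effect(obs, paths)$summary
      expect_identical(sign(median(s$abs_effect)), sign(median(s$rel_effect)))
    }
  })
})

test_that("a planted threefold step is recovered with calibrated intervals", {
  hits <- 0L
  for (i in 1:10) {
    s <- sim_local_level(300, 150, sigma2_obs = 1, sigma2_level = 0.01,
                         level0 = 10, multiplier = 3, seed = 400 + i)
    imp <- estimate_impact(s, "identity", n_chains = 2, n_iter = 1000,
                           burn_in = 300, seed = 500 + i)
    ci <- imp$summary$rel_ci
    hits <- hits + (ci[1] <= 200 && 200 <= ci[2])
    expect_lt(imp$summary$p, 0.05)
  }
  expect_gte(hits, 9L)
})

test_that("count series modeled on log1p report effects on the original scale", {
  withr::with_seed(8, {
    lam <- c(rep(20, 60), rep(60, 20))
    y <- rpois(80, lam)
  })
  series <- tibble::tibble(
    date = seq(as.Date("2022-01-01"), by = "day", length.out = 80),
    value = as.numeric(y),
    period = factor(rep(c("pre", "post"), c(60, 20)), c("pre", "post"))
  )
  imp <- estimate_impact(series, "log1p", n_chains = 2, n_iter = 1000,
                         burn_in = 300, seed = 3)
  expect_gt(imp$summary$rel_effect, 100)
  expect_lt(imp$summary$rel_effect, 350)
  expect_gt(imp$summary$predicted_mean, 10)
  td <- tidy(imp)
  expect_identical(nrow(td), 80L)
  expect_true(all(is.na(td$predicted[td$period == "pre"])))
  g <- glance(imp)
  expect_identical(nrow(g), 1L)
  expect_true(g$rel_lower <= g$rel_effect && g$rel_effect <= g$rel_upper)
})

test_that("impact results serialize to the documented CSV + JSON pair", {
  s <- sim_local_level(60, 20, 1, 0.01, 10, multiplier = 2, seed = 9)
  imp <- estimate_impact(s, "identity", n_chains = 2, n_iter = 600,
                         burn_in = 200, seed = 10)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_impact_result(imp, csv, js)
  back <- read.csv(csv)
  expect_identical(nrow(back), 80L)
  sm <- jsonlite::read_json(js)
  expect_equal(sm$rel_effect, imp$summary$rel_effect, tolerance = 1e-12)
})
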