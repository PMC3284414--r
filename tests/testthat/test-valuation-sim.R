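test_that("simulation config validates and datasets are reproducible", {
  expect_error(sim_config(n_respondents = 0), "at least 1")
  expect_error(sim_config(noise_sd = -1), ">= 0")
  expect_error(sim_config(states = character(0)), "non-empty")
  expect_error(sim_config(clip = c(1, 0)), "lo <= hi")

  cfg <- sim_config(n_respondents = 3, noise_sd = 0.2, seed = 11)
  d1 <- simulate_tto(cfg)
  d2 <- simulate_tto(cfg)
  expect_identical(d1, d2)
  expect_equal(nrow(d1), 242 * 3)
  # different seed, different noise
  cfg2 <- cfg; cfg2$seed <- 12L
  expect_false(identical(simulate_tto(cfg2)$disutility, d1$disutility))
})

test_that("noiseless observations equal the true disutilities", {
  cfg <- sim_config(n_respondents = 1, noise_sd = 0)
  d <- simulate_tto(cfg)
  expect_equal(setNames(d$disutility, d$state),
               1 - predict_value(us_d1o_tariff(), d$state),
               tolerance = 1e-14)
  expect_equal(d$disutility[d$state == "22222"], 0.406, tolerance = 1e-10)
})

test_that("clipping bounds the observed disutilities", {
  cfg <- sim_config(n_respondents = 5, noise_sd = 1, seed = 3, clip = c(0, 1))
  d <- simulate_tto(cfg)
  expect_true(all(d$disutility >= 0 & d$disutility <= 1))
})

test_that("noiseless OLS recovers each specification's generating coefficients", {
  cfg <- sim_config(n_respondents = 1, noise_sd = 0)
  d <- simulate_tto(cfg)
  fit_o <- fit_ols(d, "D1O")
  expect_equal(fit_o$coefficients, us_d1o_tariff()$coefficients,
               tolerance = 1e-10)
  fit_c <- fit_ols(d, "D1C")
  expect_equal(fit_c$coefficients, reparameterize(us_d1o_tariff())$coefficients,
               tolerance = 1e-10)
  expect_equal(unname(fit_o$fitted_utility[c("22222", "33333")]),
               c(0.594, -0.102), tolerance = 1e-10)
})

test_that("the two specifications are equivalent on every simulated dataset", {
  set.seed(99)
  for (i in 1:5) {
    cfg <- sim_config(n_respondents = 2, noise_sd = 0.3, seed = 100 + i)
    d <- simulate_tto(cfg)
    fo <- fit_ols(d, "D1O")
    fc <- fit_ols(d, "D1C")
    expect_equal(fo$fitted_utility, fc$fitted_utility[names(fo$fitted_utility)],
                 tolerance = 1e-10)
    expect_equal(fo$rss, fc$rss, tolerance = 1e-10)
    expect_equal(fo$r_squared, fc$r_squared, tolerance = 1e-10)
    # exact coefficient mapping between the fits
    expect_equal(fc$coefficients[["(Intercept)"]], -fo$coefficients[["D1"]],
                 tolerance = 1e-10)
    dummies <- c("M2", "S2", "U2", "P2", "A2", "M3", "S3", "U3", "P3", "A3")
    expect_equal(fc$coefficients[dummies],
                 fo$coefficients[dummies] + fo$coefficients[["D1"]],
                 tolerance = 1e-10)
  }
})

test_that("fit_ols guards rank deficiency and out-of-scope observations", {
  # too few distinct states to identify 14 coefficients
  cfg <- sim_config(states = c("21111", "12111"), n_respondents = 3,
                    noise_sd = 0.1)
  expect_error(fit_ols(simulate_tto(cfg), "D1O"), "rank deficient")

  # state 11111 is dropped before fitting, with a message
  d <- simulate_tto(sim_config(states = enumerate_states(), n_respondents = 1,
                               noise_sd = 0))
  expect_message(fit <- fit_ols(d, "D1C"), "11111")
  expect_false("11111" %in% fit$states)
  expect_equal(fit$n_obs, 242)
})

test_that("fits convert to tariffs that score states", {
  d <- simulate_tto(sim_config(n_respondents = 1, noise_sd = 0))
  t <- as_tariff(fit_ols(d, "D1O"))
  expect_s3_class(t, "eq_tariff")
  expect_equal(unname(predict_value(t, "22222")), 0.594, tolerance = 1e-10)
})

test_that("prediction SEs propagate the coefficient covariance", {
  d <- simulate_tto(sim_config(n_respondents = 4, noise_sd = 0.2, seed = 21))
  fo <- fit_ols(d, "D1O")
  fc <- fit_ols(d, "D1C")
  states <- c("11111", "11211", "22222", "33333")

  # equivalent models give identical full-covariance prediction SEs
  se_o <- prediction_se(fo, enumerate_states())
  se_c <- prediction_se(fc, enumerate_states())
  expect_equal(se_o, se_c, tolerance = 1e-8)

  # the axiomatic state has no prediction uncertainty
  expect_equal(unname(prediction_se(fo, "11111")), 0)
  expect_equal(unname(prediction_se(fc, "11111", mode = "diagonal_only")), 0)

  # diagonal-only accounting: for 33333 the D1 variance enters with
  # multiplier 16, the constant's with multiplier 1 -- so the naive SE
  # differs between the parameterizations even though the fits agree
  dg_o <- prediction_se(fo, "33333", mode = "diagonal_only")
  dg_c <- prediction_se(fc, "33333", mode = "diagonal_only")
  x <- build_design("D1O", "33333")
  manual <- sqrt(sum(x[1, ]^2 * diag(fo$vcov)))
  expect_equal(unname(dg_o), manual, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(dg_o, dg_c, tolerance = 1e-4,
                                check.attributes = FALSE)))
})

test_that("the recovery experiment is unbiased with calibrated SEs", {
  cfg <- sim_config(n_respondents = 10, noise_sd = 0.2, seed = 500)
  rec <- recovery_experiment(cfg, replicates = 60)
  for (s in c("D1O", "D1C")) {
    tab <- rec$summaries[[s]]
    # bias indistinguishable from zero at 3 Monte-Carlo SEs
    expect_true(all(abs(tab$bias) <= 3 * tab$mc_se))
    # reported OLS SEs track the empirical spread of the estimates
    expect_true(all(abs(tab$mean_reported_se / tab$empirical_sd - 1) < 0.25))
  }
  # determinism: same config, same summaries
  rec2 <- recovery_experiment(cfg, replicates = 60)
  expect_equal(rec$summaries, rec2$summaries)
})
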