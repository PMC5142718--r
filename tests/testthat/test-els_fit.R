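make_pairs <- function(observed, predicted) {
  tibble::tibble(series = "x", cycle = seq_along(observed),
                 observed = observed, predicted = predicted)
}

test_that("the extended-least-squares objective matches closed forms and a brute-force sum", {
  # residuals {+1, -1}, sigma = 1, gamma = 0: (1 + 1) + (0 + 0)
  p <- parameter_set(logit_fec_hcg = 0, logit_pi_clin = 0,
                     log_sigma = 0, gamma = 0)
  expect_equal(els_objective(p, make_pairs(c(11, 9), c(10, 10))), 2)

  # single zero residual, sigma = 2, gamma = 0: ln 4
  p2 <- parameter_set(logit_fec_hcg = 0, logit_pi_clin = 0,
                      log_sigma = log(2), gamma = 0)
  expect_equal(els_objective(p2, make_pairs(5, 5)), log(4))

  # gamma = 2 against an independently coded sum with g = sigma^2 f^2
  set.seed(4)
  f <- runif(25, 1, 60)
  y <- f + rnorm(25, sd = 3)
  sigma <- 0.7
  p3 <- parameter_set(logit_fec_hcg = 0, logit_pi_clin = 0,
                      log_sigma = log(sigma), gamma = 2)
  brute <- 0
  for (i in seq_along(y)) {
    g <- sigma^2 * f[i]^2
    brute <- brute + (y[i] - f[i])^2 / g + log(g)
  }
  expect_equal(els_objective(p3, make_pairs(y, f)), brute, tolerance = 1e-12)
})

test_that("scaling every variance term shifts the objective by n log c only", {
  set.seed(5)
  f <- runif(20, 5, 50); y <- f + rnorm(20)
  pairs <- make_pairs(y, f)
  for (gamma in c(0, 1, 2)) {
    base <- parameter_set(logit_fec_hcg = 0, logit_pi_clin = 0,
                          log_sigma = log(0.9), gamma = gamma)
    c_ <- 3.7
    scaled <- parameter_set(logit_fec_hcg = 0, logit_pi_clin = 0,
                            log_sigma = log(0.9 * sqrt(c_)), gamma = gamma)
    shift <- els_objective(scaled, pairs) - els_objective(base, pairs)
    resid_part <- sum((y - f)^2 / (0.9^2 * f^gamma)) * (1 / c_ - 1)
    expect_equal(shift, 20 * log(c_) + resid_part, tolerance = 1e-9)
  }
})

test_that("a noise-free expected-count dataset is a fixed point of the fit", {
  truth <- parameter_set(logit_fert1 = 0.408,
                         logit_fec_hcg = c(-0.118, -1.087),
                         logit_pi_clin = 0.558)
  d <- study_design(n_initial = 221, n_cycles = 9,
                    observed_fin = rep(0, 9), observed_drop = rep(3, 9),
                    horizon = 24)
  ds <- expected_counts(truth, d, rounding = "none")
  spec <- model_spec(n_subcohorts = 2, shared_pi_clin = TRUE,
                     gamma_fixed_zero = TRUE)
  fit <- suppressWarnings(fit_model(ds, spec, options = list(fixed_sigma = 1)))
  expect_equal(unname(fit$theta[c("logit_mix1", "logit_fec_hcg1",
                                  "logit_fec_hcg2", "logit_pi_clin")]),
               c(0.408, -0.118, -1.087, 0.558), tolerance = 1e-4)
  expect_lt(fit$objective_value, 1e-6)
})

test_that("fits converge with a small gradient and ordered nested objectives", {
  sim <- simulate_study(wilcox_truth_config(n_initial = 1000), seed = 21)
  f0 <- fit_model(sim$dataset, model_spec("0"))
  expect_identical(f0$convergence$status, 0L)
  # stationarity relative to the objective scale
  expect_lt(f0$convergence$gradient_norm, 1e-3 * (1 + abs(f0$objective_value)))
  expect_true(f0$convergence$hessian_ok)
  expect_identical(f0$n_parameters, 6L)
  expect_identical(f0$degrees_of_freedom, f0$n_observations - 6L)

  # nesting: 1 sub-cohort >= 2 sub-cohorts >= 3 sub-cohorts
  f1 <- fit_model(sim$dataset, model_spec("1"),
                  options = list(extra_starts = list(parameter_set(
                    logit_fec_hcg = f0$estimates$logit_fec_hcg[1],
                    logit_pi_clin = f0$estimates$logit_pi_clin,
                    log_sigma = f0$estimates$log_sigma,
                    gamma = f0$estimates$gamma))))
  p0 <- f0$estimates
  f2 <- fit_model(sim$dataset, model_spec("2"),
                  options = list(extra_starts = list(parameter_set(
                    logit_fert1 = c(p0$logit_fert1, 0),
                    logit_fec_hcg = c(p0$logit_fec_hcg, p0$logit_fec_hcg[2]),
                    logit_pi_clin = p0$logit_pi_clin,
                    log_sigma = p0$log_sigma, gamma = p0$gamma))))
  expect_gte(f1$objective_value, f0$objective_value - 1e-6)
  expect_gte(f0$objective_value, f2$objective_value - 1e-6)
})

test_that("the two parameterisations of the clinical stage are statistically identical", {
  sim <- simulate_study(wilcox_truth_config(n_initial = 800), seed = 31)
  f0 <- fit_model(sim$dataset, model_spec("0"))
  f00 <- fit_model(sim$dataset, model_spec("00"))
  expect_equal(f00$objective_value, f0$objective_value, tolerance = 1e-6)
  # the clinical fecundability estimated by one equals FEC_HCG * pi_CLIN of the other
  fec_clin_00 <- logit10_to_prob(f00$theta[["logit_fec_clin1"]])
  fec_clin_0 <- logit10_to_prob(f0$theta[["logit_fec_hcg1"]]) *
    logit10_to_prob(f0$theta[["logit_pi_clin"]])
  expect_equal(fec_clin_00, fec_clin_0, tolerance = 1e-4)
})

test_that("Wald intervals map correctly to the probability scale", {
  fake <- structure(list(
    theta = c(logit_a = 0.408, logit_b = 0, log_sigma = log(2), gamma = 1.1),
    standard_errors = c(logit_a = 0.085, logit_b = 0.2, log_sigma = 0.1,
                        gamma = 0.2)), class = "fit_result")
  ci <- parameter_intervals(fake, level = 0.95)

  a <- ci[ci$parameter == "a", ]
  expect_equal(a$estimate, logit10_to_prob(0.408), tolerance = 1e-6)
  expect_equal(c(a$lower, a$upper), c(0.636, 0.790), tolerance = 2e-3)

  # logit 0: interval symmetric about one half on the probability scale
  b <- ci[ci$parameter == "b", ]
  expect_equal(b$estimate, 0.5)
  expect_equal(b$upper - 0.5, 0.5 - b$lower, tolerance = 1e-12)

  # sigma mapped through exp, gamma untouched
  expect_equal(ci$estimate[ci$scale == "sigma"], 2)
  expect_equal(ci$estimate[ci$scale == "gamma"], 1.1)

  # zero standard error collapses the interval onto the point
  fake0 <- structure(list(theta = c(logit_a = 0.3),
                          standard_errors = c(logit_a = 0)),
                     class = "fit_result")
  ci0 <- parameter_intervals(fake0)
  expect_equal(ci0$lower, ci0$estimate)
  expect_equal(ci0$upper, ci0$estimate)

  # absent standard errors yield an unavailable marker
  fakeNA <- structure(list(theta = c(logit_a = 0.3), standard_errors = NULL),
                      class = "fit_result")
  expect_false(any(parameter_intervals(fakeNA)$available))
})
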