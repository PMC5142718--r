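test_that("base-10 logit maps reproduce known probabilities and invert exactly", {
  # published logit estimates and their probability-scale counterparts
  expect_equal(round(logit10_to_prob(-0.118), 3), 0.432)
  expect_equal(round(logit10_to_prob(0.845), 3), 0.875)
  expect_equal(logit10_to_prob(0), 0.5)
  expect_equal(round(prob_to_logit10(0.719), 3), 0.408)
  expect_equal(prob_to_logit10(0.5), 0)

  x <- seq(-3, 3, by = 0.5)
  expect_equal(prob_to_logit10(logit10_to_prob(x)), x, tolerance = 1e-12)
  expect_equal(logit10_to_prob(-x), 1 - logit10_to_prob(x), tolerance = 1e-12)
  expect_true(all(diff(logit10_to_prob(x)) > 0))

  expect_error(logit10_to_prob(Inf), "finite")
  expect_error(prob_to_logit10(1), "strictly")
  expect_error(prob_to_logit10(0), "strictly")
})

test_that("degenerate fecundabilities produce the forced trajectories", {
  d <- study_design(n_initial = 50, n_cycles = 5,
                    observed_fin = rep(0, 5), observed_drop = rep(0, 5))
  # impossible conception: the cohort never depletes
  p0 <- parameter_set(logit_fec_hcg = -12, logit_pi_clin = 0)
  s0 <- predict_series(p0, d)
  expect_equal(s0$n_pred, rep(50, 5), tolerance = 1e-6)
  expect_equal(s0$preg_clin_pred, rep(0, 5), tolerance = 1e-6)

  # near-certain conception and progression: everyone pregnant in cycle 1
  p1 <- parameter_set(logit_fec_hcg = 12, logit_pi_clin = 12)
  s1 <- predict_series(p1, d)
  expect_equal(s1$preg_clin_pred[1], 50, tolerance = 1e-6)
  expect_equal(s1$n_pred[2], 0, tolerance = 1e-6)
})

test_that("predicted trajectories conserve women and deplete the fertile fraction", {
  set.seed(11)
  for (rep in 1:20) {
    p <- parameter_set(
      logit_fert1 = runif(1, -0.5, 1),
      logit_fec_hcg = sort(runif(2, -1.5, 0.2), decreasing = TRUE),
      logit_pi_clin = runif(1, 0, 1))
    K <- sample(5:12, 1)
    d <- study_design(n_initial = sample(100:500, 1), n_cycles = K,
                      observed_fin = c(rep(0, K - 1), 10),
                      observed_drop = runif(K, 0, 4))
    s <- predict_series(p, d)
    lhs <- s$n_pred[-K]
    rhs <- s$n_pred[-1] + s$preg_clin_pred[-K] +
      d$observed_fin[-K] + d$observed_drop[-K]
    expect_equal(lhs, rhs, tolerance = 1e-9)
    expect_true(all(s$preg_clin_pred <= s$preg_hcg_pred + 1e-12))
    expect_true(all(s$preg_hcg_pred <= s$n_pred + 1e-12))
    # the fertile sub-cohort conceives faster, so its share must shrink
    expect_true(all(diff(s$pct_fert) < 0))
  }
})

test_that("a two-sub-cohort model with equal fecundabilities collapses to one", {
  d <- study_design(n_initial = 300, n_cycles = 8,
                    observed_fin = c(rep(0, 7), 20), observed_drop = rep(3, 8),
                    horizon = 24)
  p2 <- parameter_set(logit_fert1 = 0.3, logit_fec_hcg = c(-0.4, -0.4),
                      logit_pi_clin = 0.5)
  p1 <- parameter_set(logit_fec_hcg = -0.4, logit_pi_clin = 0.5)
  s2 <- predict_series(p2, d)
  s1 <- predict_series(p1, d)
  expect_equal(s2$n_pred, s1$n_pred, tolerance = 1e-10)
  expect_equal(s2$preg_hcg_pred, s1$preg_hcg_pred, tolerance = 1e-10)
  expect_equal(s2$preg_clin_pred, s1$preg_clin_pred, tolerance = 1e-10)
  expect_equal(attr(s2, "nonpreg_pred"), attr(s1, "nonpreg_pred"),
               tolerance = 1e-10)
})

test_that("the long-horizon expectation matches the 14-of-221 never-pregnant count", {
  p <- table1_wilcox_params()
  d <- study_design(n_initial = 221, n_cycles = 9,
                    observed_fin = rep(0, 9), observed_drop = rep(0, 9),
                    horizon = 24)
  s <- predict_series(p, d)
  expect_equal(attr(s, "nonpreg_pred"), 14, tolerance = 1 / 14)  # within 1 woman
})

test_that("observation vectors have the documented composition for the three study shapes", {
  p <- table1_wilcox_params()

  shape <- function(K, hcg_cycles, horizon) {
    n <- round(seq(221, 40, length.out = K))
    clin <- pmax(round(0.6 * (-diff(c(n, n[K])))), 0)
    drop <- pmax(-diff(c(n, n[K])) - clin, 0)
    fin <- rep(0, K); fin[K] <- n[K] - clin[K] - drop[K]
    hcg <- ifelse(seq_len(K) %in% hcg_cycles, clin + 2, NA)
    study_dataset(
      cycles = tibble::tibble(cycle = 1:K, n_start = n, preg_hcg = hcg,
                              preg_clin = clin, finished = fin, dropped = drop),
      nonpreg_horizon = if (is.null(horizon)) NULL else
        list(horizon_cycles = horizon, nonpreg_count = 14))
  }

  # 9 cycles, hCG throughout, long-horizon record: 8 + 9 + 9 + 1
  pairs_w <- observation_pairs(shape(9, 1:9, 24), p)
  expect_identical(nrow(pairs_w), 27L)
  # 12 cycles, hCG in the first three only, no horizon: 11 + 3 + 12
  pairs_z <- observation_pairs(shape(12, 1:3, NULL), p)
  expect_identical(nrow(pairs_z), 26L)
  # 14 cycles, hCG throughout, no horizon: 13 + 14 + 14
  pairs_g <- observation_pairs(shape(14, 1:14, NULL), p)
  expect_identical(nrow(pairs_g), 41L)

  # the documented ordering: cohort sizes, then hCG, then clinical, then horizon
  expect_identical(unique(pairs_w$series),
                   c("n_start", "preg_hcg", "preg_clin", "nonpreg"))
  expect_equal(pairs_w$cycle[pairs_w$series == "n_start"], 2:9)
  expect_true(all(is.finite(pairs_z$observed)))
})

test_that("mixture fractions use a stick-breaking construction that sums to one", {
  p3 <- parameter_set(logit_fert1 = c(0.2, -0.3),
                      logit_fec_hcg = c(-0.1, -0.8, -1.5),
                      logit_pi_clin = 0.5)
  fr <- mixture_fractions(p3)
  expect_length(fr, 3)
  expect_equal(sum(fr), 1, tolerance = 1e-12)
  expect_true(all(fr > 0))
  # two-sub-cohort case reduces to the plain fertile fraction
  p2 <- parameter_set(logit_fert1 = 0.408, logit_fec_hcg = c(-0.1, -1),
                      logit_pi_clin = 0.5)
  expect_equal(mixture_fractions(p2)[1], logit10_to_prob(0.408))
})
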