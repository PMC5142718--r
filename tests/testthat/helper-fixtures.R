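# Shared fixtures: the published two-sub-cohort estimates for the 221-woman
# cohort serve as the canonical generating truth for synthetic studies.

table1_wilcox_params <- function() {
  parameter_set(logit_fert1 = 0.408,
                logit_fec_hcg = c(-0.118, -1.087),
                logit_pi_clin = 0.558,
                log_sigma = log(0.437), gamma = 1.26)
}

# the same truth on the probability scale, as a simulator configuration;
# dropout 0.02/cycle is the generator's nominal withdrawal rate
wilcox_truth_config <- function(n_initial = 221, n_cycles = 9,
                                dropout_prob = 0.02, long_horizon = 24) {
  p <- table1_wilcox_params()
  sim_config(n_initial = n_initial,
             fractions = mixture_fractions(p),
             fec_hcg = logit10_to_prob(p$logit_fec_hcg),
             pi_clin = logit10_to_prob(p$logit_pi_clin[1]),
             dropout_prob = dropout_prob, n_cycles = n_cycles,
             long_horizon = long_horizon)
}

one_cohort_config <- function(n_initial = 1000, n_cycles = 9,
                              fec_hcg = 0.30, pi_clin = 0.80,
                              dropout_prob = 0.02) {
  sim_config(n_initial = n_initial, fractions = 1, fec_hcg = fec_hcg,
             pi_clin = pi_clin, dropout_prob = dropout_prob,
             n_cycles = n_cycles)
}

# a small hand-built conserving dataset used by the I/O and validation tests
toy_dataset <- function() {
  study_dataset(
    cycles = tibble::tibble(
      cycle = 1:4,
      n_start = c(100, 78, 62, 50),
      preg_hcg = c(25, 18, NA, 10),
      preg_clin = c(20, 14, 10, 8),
      finished = c(0, 0, 0, 41),
      dropped = c(2, 2, 2, 1)
    ),
    study_name = "toy",
    nonpreg_horizon = list(horizon_cycles = 24, nonpreg_count = 6)
  )
}
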