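#' Configuration of a simulated prospective conception study
#'
#' Describes the generating process of an individual-level simulation: a
#' starting cohort that is a finite mixture of fertility classes, per-cycle
#' Bernoulli hCG conception with class-specific probability, progression of
#' an hCG pregnancy to clinical recognition with probability `pi_clin`
#' (clinical pregnancy removes the woman from the risk set; an hCG-only
#' pregnancy does not), independent Bernoulli dropout at cycle end among
#' women not clinically pregnant, completion at cycle `n_cycles`, and an
#' optional silent long-horizon follow-up yielding a never-clinically-
#' pregnant count.
#'
#' @param n_initial starting cohort size.
#' @param fractions mixture fractions of the fertility classes (sum to 1).
#' @param fec_hcg per-class per-cycle hCG-conception probabilities, same
#'   length as `fractions`.
#' @param pi_clin probability an hCG pregnancy becomes clinical; a single
#'   shared value or one per class.
#' @param dropout_prob per-woman per-cycle withdrawal probability at cycle
#'   end.
#' @param n_cycles number of reported cycles K.
#' @param long_horizon optional number of cycles (`>= n_cycles`) to follow
#'   the cohort silently for the never-pregnant count.
#' @param hcg_observed_cycles cycles whose hCG counts are reported (others
#'   are emitted as unobserved).
#' @param study_name label for the emitted dataset.
#' @return An object of class `sim_config`.
#' @export
#' @examples
#' sim_config(n_initial = 221, fractions = c(0.719, 0.281),
#'            fec_hcg = c(0.432, 0.076), pi_clin = 0.783,
#'            dropout_prob = 0.05, n_cycles = 9, long_horizon = 24)
sim_config <- function(n_initial, fractions, fec_hcg, pi_clin,
                       dropout_prob = 0, n_cycles, long_horizon = NULL,
                       hcg_observed_cycles = seq_len(n_cycles),
                       study_name = "simulated") {
  stopifnot(n_initial >= 1, n_cycles >= 1)
  if (length(fractions) != length(fec_hcg)) {
    stop("fractions and fec_hcg must have the same length", call. = FALSE)
  }
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1", call. = FALSE)
  if (!length(pi_clin) %in% c(1L, length(fractions))) {
    stop("pi_clin must be shared or per-class", call. = FALSE)
  }
  probs <- c(fractions, fec_hcg, pi_clin, dropout_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(long_horizon) && long_horizon < n_cycles) {
    stop("long_horizon must be >= n_cycles", call. = FALSE)
  }
  structure(
    list(n_initial = as.integer(n_initial),
         fractions = as.numeric(fractions),
         fec_hcg = as.numeric(fec_hcg),
         pi_clin = if (length(pi_clin) == 1L) rep(as.numeric(pi_clin), length(fractions))
                   else as.numeric(pi_clin),
         dropout_prob = as.numeric(dropout_prob),
         n_cycles = as.integer(n_cycles),
         long_horizon = if (is.null(long_horizon)) NULL else as.integer(long_horizon),
         hcg_observed_cycles = as.integer(hcg_observed_cycles),
         study_name = as.character(study_name)),
    class = "sim_config"
  )
}

#' Parameter set corresponding to a simulation configuration
#'
#' Maps a [sim_config()]'s probability-scale truth onto the logit-scale
#' [parameter_set()] the deterministic model and the fit work with (the
#' residual parameters, which the generator does not use, are set to
#' `sigma = 1`, `gamma = 0`). Boundary probabilities (0 or 1), which the
#' simulator allows but the logit scale cannot represent, are clamped to
#' within 1e-12 of the boundary.
#'
#' @param config a [sim_config()].
#' @return A [parameter_set()].
#' @export
config_to_params <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  clamp <- function(p) pmin(pmax(p, 1e-12), 1 - 1e-12)
  n <- length(config$fractions)
  mix <- numeric(0)
  if (n >= 2L) {
    # invert the stick-breaking construction
    rem <- 1
    mix <- numeric(n - 1L)
    for (j in seq_len(n - 1L)) {
      mix[j] <- prob_to_logit10(clamp(config$fractions[j] / rem))
      rem <- rem - config$fractions[j]
    }
  }
  pic <- if (length(unique(config$pi_clin)) == 1L) config$pi_clin[1L] else config$pi_clin
  parameter_set(logit_fert1 = mix,
                logit_fec_hcg = prob_to_logit10(clamp(config$fec_hcg)),
                logit_pi_clin = prob_to_logit10(clamp(pic)),
                log_sigma = 0, gamma = 0)
}

#' Simulate a prospective conception study at the individual level
#'
#' Draws one study: each woman is assigned a latent fertility class by the
#' mixture fractions; each cycle she conceives an hCG pregnancy with her
#' class's probability; a conception becomes clinical with `pi_clin` and
#' removes her from the risk set, while an hCG-only pregnancy leaves her in;
#' women still at risk withdraw at cycle end with `dropout_prob`; survivors
#' of cycle K are recorded as finished. When `long_horizon` is set, every
#' woman not clinically pregnant by then (including those who finished at K
#' or dropped out — the horizon count summarises the whole starting cohort,
#' matching the deterministic model's never-pregnant expectation) is followed
#' silently and the never-pregnant count at the horizon is recorded.
#'
#' The same seed always reproduces the same study; the RNG state of the
#' session is restored afterwards.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return A list with `dataset` (a [study_dataset()] that passes
#'   [validate_dataset()]) and `truth`: the generating [parameter_set()]
#'   (`params`), per-woman classes and exits (`women`: tibble with `id`,
#'   `class`, `exit_cycle`, `exit_type`, `clin_by_horizon`), and all hCG
#'   conceptions (`hcg_events`: tibble with `id`, `cycle`, `clinical`).
#' @export
#' @examples
#' cfg <- sim_config(n_initial = 200, fractions = c(0.7, 0.3),
#'                   fec_hcg = c(0.4, 0.05), pi_clin = 0.8,
#'                   dropout_prob = 0.03, n_cycles = 6)
#' sim <- simulate_study(cfg, seed = 42)
#' sim$dataset
simulate_study <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(seed, {
    n <- config$n_initial
    K <- config$n_cycles
    n_class <- length(config$fractions)
    class <- sample.int(n_class, n, replace = TRUE, prob = config$fractions)
    fec <- config$fec_hcg[class]
    pic <- config$pi_clin[class]

    at_risk <- rep(TRUE, n)           # in the reported study
    exit_cycle <- rep(NA_integer_, n)
    exit_type <- rep(NA_character_, n)
    hcg_id <- integer(0); hcg_cycle <- integer(0); hcg_clin <- logical(0)
    n_start <- preg_hcg <- preg_clin <- finished <- dropped <- numeric(K)

    for (k in seq_len(K)) {
      idx <- which(at_risk)
      n_start[k] <- length(idx)
      conceive <- idx[stats::runif(length(idx)) < fec[idx]]
      clinical <- conceive[stats::runif(length(conceive)) < pic[conceive]]
      preg_hcg[k] <- length(conceive)
      preg_clin[k] <- length(clinical)
      hcg_id <- c(hcg_id, conceive)
      hcg_cycle <- c(hcg_cycle, rep.int(k, length(conceive)))
      hcg_clin <- c(hcg_clin, conceive %in% clinical)
      at_risk[clinical] <- FALSE
      exit_cycle[clinical] <- k
      exit_type[clinical] <- "clinical"
      remaining <- which(at_risk)
      if (k < K) {
        drop_idx <- remaining[stats::runif(length(remaining)) < config$dropout_prob]
        dropped[k] <- length(drop_idx)
        at_risk[drop_idx] <- FALSE
        exit_cycle[drop_idx] <- k
        exit_type[drop_idx] <- "dropout"
      } else {
        finished[k] <- length(remaining)
        exit_cycle[remaining] <- k
        exit_type[remaining] <- "completed"
      }
    }

    nonpreg_horizon <- NULL
    clin_by_horizon <- exit_type == "clinical"
    if (!is.null(config$long_horizon)) {
      # silent follow-up of every woman not clinically pregnant during the
      # reported phase: from the cycle after her exit (dropout or completion)
      # to the horizon she conceives clinically with per-cycle probability
      # fec * pi_clin; one aggregate draw per woman is distributionally
      # equivalent to cycle-by-cycle Bernoulli draws
      open <- which(exit_type != "clinical")
      if (length(open) > 0L) {
        silent_cycles <- config$long_horizon - exit_cycle[open]
        p_clin_by_h <- 1 - (1 - fec[open] * pic[open])^silent_cycles
        hit <- stats::runif(length(open)) < p_clin_by_h
        clin_by_horizon[open[hit]] <- TRUE
      }
      nonpreg_horizon <- list(horizon_cycles = config$long_horizon,
                              nonpreg_count = sum(!clin_by_horizon))
    }

    hcg_rep <- preg_hcg
    hcg_rep[setdiff(seq_len(K), config$hcg_observed_cycles)] <- NA

    dataset <- study_dataset(
      cycles = tibble::tibble(cycle = seq_len(K), n_start = n_start,
                              preg_hcg = hcg_rep, preg_clin = preg_clin,
                              finished = finished, dropped = dropped),
      study_name = config$study_name,
      nonpreg_horizon = nonpreg_horizon)

    truth <- list(
      params = config_to_params(config),
      women = tibble::tibble(id = seq_len(n), class = class,
                             exit_cycle = exit_cycle, exit_type = exit_type,
                             clin_by_horizon = clin_by_horizon),
      hcg_events = tibble::tibble(id = hcg_id, cycle = hcg_cycle,
                                  clinical = hcg_clin),
      preg_hcg_full = preg_hcg)
    list(dataset = dataset, truth = truth)
  })
}

#' Deterministic expected-count dataset
#'
#' Wraps [predict_series()] as a dataset factory: the expected per-cycle
#' aggregates at given parameters and design, either real-valued (`rounding =
#' "none"`, flagged so validation skips integrality — test use only) or
#' rounded to whole women (`rounding = "nearest"`, with the finished count of
#' each cycle adjusted so conservation still holds exactly; a warning is
#' issued when an adjustment was needed).
#'
#' The finished count of the last cycle is set to the surviving cohort (all
#' women still at risk complete the study at cycle K), so the dataset is
#' internally complete.
#'
#' @param params a [parameter_set()].
#' @param design a [study_design()]; its `observed_fin`/`observed_drop` give
#'   the exits for cycles before K.
#' @param rounding `"none"` or `"nearest"`.
#' @param study_name label for the dataset.
#' @return A [study_dataset()]; when the design has a horizon, the expected
#'   never-pregnant count is attached as the dataset's horizon metadata.
#' @export
expected_counts <- function(params, design, rounding = c("none", "nearest"),
                            study_name = "expected") {
  rounding <- match.arg(rounding)
  core <- .predict_core(params, design)
  K <- design$n_cycles
  fin <- design$observed_fin
  drop <- design$observed_drop
  clin <- core$preg_clin
  n_start <- core$n_pred
  # close the study: survivors of cycle K finish
  fin[K] <- max(n_start[K] - clin[K] - drop[K], 0)

  hcg <- core$preg_hcg
  hcg_rep <- hcg
  hcg_rep[setdiff(seq_len(K), design$hcg_observed_cycles)] <- NA

  nonpreg <- if (is.null(design$horizon)) NULL else
    list(horizon_cycles = design$horizon, nonpreg_count = core$nonpreg)

  if (rounding == "nearest") {
    clin_r <- round(clin); drop_r <- round(drop); fin_r <- round(fin)
    hcg_r <- round(hcg_rep)
    n_r <- numeric(K)
    n_r[1L] <- round(design$n_initial)
    adjusted <- FALSE
    for (k in seq_len(K - 1L)) {
      nxt <- round(n_start[k + 1L])
      # conservation must hold on the rounded counts; absorb the rounding
      # residue into the finished count
      resid <- n_r[k] - clin_r[k] - fin_r[k] - drop_r[k] - nxt
      if (resid != 0) {
        fin_r[k] <- fin_r[k] + resid
        adjusted <- TRUE
        if (fin_r[k] < 0) { drop_r[k] <- drop_r[k] + fin_r[k]; fin_r[k] <- 0 }
      }
      n_r[k + 1L] <- nxt
    }
    fin_r[K] <- max(n_r[K] - clin_r[K] - drop_r[K], 0)
    if (adjusted) {
      warning("rounded counts broke conservation; finished counts adjusted",
              call. = FALSE)
    }
    if (!is.null(nonpreg)) nonpreg$nonpreg_count <- round(nonpreg$nonpreg_count)
    study_dataset(
      cycles = tibble::tibble(cycle = seq_len(K), n_start = n_r,
                              preg_hcg = hcg_r, preg_clin = clin_r,
                              finished = fin_r, dropped = drop_r),
      study_name = study_name, nonpreg_horizon = nonpreg)
  } else {
    study_dataset(
      cycles = tibble::tibble(cycle = seq_len(K), n_start = n_start,
                              preg_hcg = hcg_rep, preg_clin = clin,
                              finished = fin, dropped = drop),
      study_name = study_name, nonpreg_horizon = nonpreg,
      real_valued = TRUE)
  }
}
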