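#' Base-10 logit transforms
#'
#' All probabilities in the cohort-depletion model are estimated on the
#' base-10 logit scale, theta = log10(p / (1 - p)); the inverse map is
#' p = 10^theta / (1 + 10^theta). `logit10_to_prob` is strictly increasing
#' and satisfies `logit10_to_prob(-x) == 1 - logit10_to_prob(x)`.
#'
#' @param theta finite base-10 logit(s).
#' @param p probability(ies) strictly inside (0, 1).
#' @return `logit10_to_prob`: probabilities in (0, 1); `prob_to_logit10`:
#'   base-10 logits.
#' @export
#' @examples
#' logit10_to_prob(0)        # 0.5
#' logit10_to_prob(0.408)    # ~0.719, the fertile fraction behind "28.1% sub-fertile"
#' prob_to_logit10(0.875)
logit10_to_prob <- function(theta) {
  if (any(!is.finite(theta))) stop("theta must be finite", call. = FALSE)
  # plogis on the natural scale keeps large |theta| overflow-safe
  stats::plogis(theta * log(10))
}

#' @rdname logit10_to_prob
#' @export
prob_to_logit10 <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("p must lie strictly in (0, 1)", call. = FALSE)
  }
  log10(p / (1 - p))
}

#' Structural and residual parameters of the mixture cohort model
#'
#' Bundles the parameters of the cohort-depletion model on their estimation
#' scales: base-10 logits for all probabilities, natural log for the residual
#' scale sigma. With `n` sub-cohorts the mixture fractions of the starting
#' cohort are described by `n - 1` logits via a stick-breaking construction
#' (for two sub-cohorts this is just the logit of the fertile fraction
#' `%fert(1)`; sub-cohort 1 is conventionally the most fertile).
#'
#' @param logit_fert1 numeric vector of length `n_subcohorts - 1`: stick-
#'   breaking logits of the starting mixture fractions. Ignored (may be
#'   `NULL`) for a single sub-cohort.
#' @param logit_fec_hcg numeric vector, one base-10 logit of the per-cycle
#'   hCG-conception probability (`FEC_HCG`) per sub-cohort.
#' @param logit_pi_clin base-10 logit(s) of the probability that an hCG
#'   pregnancy progresses to clinical recognition: either a single shared
#'   value or one per sub-cohort.
#' @param log_sigma natural log of the residual scale sigma.
#' @param gamma residual variance exponent (0 = homoscedastic residuals,
#'   2 = constant coefficient of variation).
#' @return An object of class `parameter_set`.
#' @export
#' @examples
#' # the fitted two-sub-cohort values for the 221-woman cohort
#' parameter_set(logit_fert1 = 0.408, logit_fec_hcg = c(-0.118, -1.087),
#'               logit_pi_clin = 0.558, log_sigma = log(0.437), gamma = 1.26)
parameter_set <- function(logit_fert1 = NULL, logit_fec_hcg,
                          logit_pi_clin, log_sigma = 0, gamma = 0) {
  n_sub <- length(logit_fec_hcg)
  if (!n_sub %in% 1:3) stop("1 to 3 sub-cohorts are supported", call. = FALSE)
  if (n_sub == 1L) {
    logit_fert1 <- numeric(0)
  } else {
    if (length(logit_fert1) != n_sub - 1L) {
      stop(sprintf("logit_fert1 must have length %d for %d sub-cohorts",
                   n_sub - 1L, n_sub), call. = FALSE)
    }
  }
  if (!length(logit_pi_clin) %in% c(1L, n_sub)) {
    stop("logit_pi_clin must be shared (length 1) or per-sub-cohort",
         call. = FALSE)
  }
  vals <- c(logit_fert1, logit_fec_hcg, logit_pi_clin, log_sigma, gamma)
  if (any(!is.finite(vals))) stop("all parameters must be finite", call. = FALSE)
  structure(
    list(logit_fert1 = as.numeric(logit_fert1),
         logit_fec_hcg = as.numeric(logit_fec_hcg),
         logit_pi_clin = as.numeric(logit_pi_clin),
         log_sigma = as.numeric(log_sigma),
         gamma = as.numeric(gamma),
         n_subcohorts = n_sub),
    class = "parameter_set"
  )
}

#' @export
print.parameter_set <- function(x, ...) {
  cat(sprintf("<parameter_set> %d sub-cohort(s)\n", x$n_subcohorts))
  fr <- mixture_fractions(x)
  cat("  fractions:", paste(sprintf("%.4f", fr), collapse = " "), "\n")
  cat("  FEC_HCG:  ", paste(sprintf("%.4f", logit10_to_prob(x$logit_fec_hcg)),
                            collapse = " "), "\n")
  cat("  pi_CLIN:  ", paste(sprintf("%.4f", logit10_to_prob(x$logit_pi_clin)),
                            collapse = " "), "\n")
  cat(sprintf("  sigma: %.4f  gamma: %.3f\n", exp(x$log_sigma), x$gamma))
  invisible(x)
}

#' Starting mixture fractions implied by a parameter set
#'
#' Maps the stick-breaking logits to sub-cohort fractions that sum to one.
#' With one sub-cohort the result is `1`; with two it is
#' `c(%fert(1), 1 - %fert(1))`.
#'
#' @param params a [parameter_set()].
#' @return Numeric vector of length `n_subcohorts`, summing to 1.
#' @export
mixture_fractions <- function(params) {
  n_sub <- params$n_subcohorts
  if (n_sub == 1L) return(1)
  p <- logit10_to_prob(params$logit_fert1)
  frac <- numeric(n_sub)
  rem <- 1
  for (j in seq_len(n_sub - 1L)) {
    frac[j] <- rem * p[j]
    rem <- rem - frac[j]
  }
  frac[n_sub] <- rem
  frac
}

#' Study design for the deterministic forward model
#'
#' Everything the cohort recursion needs besides the parameters: the fixed
#' starting cohort size, the number of reported cycles, the observed per-cycle
#' exits (women finishing non-pregnant and dropouts, which deplete the cohort
#' as data, not as model predictions), which cycles contribute hCG and
#' cohort-size observations, and an optional long horizon for the
#' never-clinically-pregnant expectation.
#'
#' @param n_initial fixed starting cohort size `N(1)`.
#' @param n_cycles number of reported cycles `K`.
#' @param observed_fin,observed_drop numeric vectors of length `n_cycles`:
#'   women finishing the study non-pregnant / withdrawing at the end of each
#'   cycle.
#' @param hcg_observed_cycles cycle indices whose hCG pregnancy counts were
#'   reported (default: all).
#' @param n_start_observed_cycles cycle indices whose starting counts are fit
#'   observations (default `2:K`; `N(1)` is fixed by design, not fitted).
#' @param horizon optional number of cycles (`>= n_cycles`) at which the
#'   expected never-clinically-pregnant count is evaluated.
#' @return An object of class `study_design`.
#' @export
study_design <- function(n_initial, n_cycles, observed_fin, observed_drop,
                         hcg_observed_cycles = seq_len(n_cycles),
                         n_start_observed_cycles = if (n_cycles >= 2) 2:n_cycles else integer(0),
                         horizon = NULL) {
  n_cycles <- as.integer(n_cycles)
  stopifnot(n_cycles >= 1L, n_initial > 0,
            length(observed_fin) == n_cycles,
            length(observed_drop) == n_cycles)
  if (!is.null(horizon) && horizon < n_cycles) {
    stop("horizon must be >= n_cycles", call. = FALSE)
  }
  structure(
    list(n_initial = as.numeric(n_initial), n_cycles = n_cycles,
         observed_fin = as.numeric(observed_fin),
         observed_drop = as.numeric(observed_drop),
         hcg_observed_cycles = as.integer(hcg_observed_cycles),
         n_start_observed_cycles = as.integer(n_start_observed_cycles),
         horizon = if (is.null(horizon)) NULL else as.numeric(horizon)),
    class = "study_design"
  )
}

#' Derive a study design from a dataset
#'
#' Extracts the [study_design()] implied by a [study_dataset()]: `FIN` and
#' `DROP` come from the recorded counts, hCG-observed cycles from the
#' non-missing `preg_hcg` cells, and the horizon from the dataset's
#' `nonpreg_horizon` metadata.
#'
#' @param dataset a [study_dataset()].
#' @return A [study_design()].
#' @export
design_from_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "study_dataset"))
  cy <- dataset$cycles
  study_design(
    n_initial = dataset$n_initial,
    n_cycles = nrow(cy),
    observed_fin = cy$finished,
    observed_drop = cy$dropped,
    hcg_observed_cycles = dataset$hcg_observed_cycles,
    horizon = if (is.null(dataset$nonpreg_horizon)) NULL
              else dataset$nonpreg_horizon$horizon_cycles
  )
}

# Fast core of the forward recursion; returns plain vectors/matrices.
# n_c: per-sub-cohort expected counts starting each cycle (K x n_sub).
.predict_core <- function(params, design) {
  n_sub <- params$n_subcohorts
  fec_hcg <- logit10_to_prob(params$logit_fec_hcg)
  pi_clin <- logit10_to_prob(params$logit_pi_clin)
  if (length(pi_clin) == 1L) pi_clin <- rep(pi_clin, n_sub)
  fec_clin <- fec_hcg * pi_clin

  K <- design$n_cycles
  frac <- mixture_fractions(params)
  n_c <- matrix(0, K, n_sub)
  n_pred <- numeric(K)
  preg_hcg_c <- matrix(0, K, n_sub)
  preg_clin_c <- matrix(0, K, n_sub)

  n_pred[1L] <- design$n_initial
  n_c[1L, ] <- design$n_initial * frac
  for (k in seq_len(K)) {
    preg_hcg_c[k, ] <- n_c[k, ] * fec_hcg
    preg_clin_c[k, ] <- n_c[k, ] * fec_clin
    clin_tot <- sum(preg_clin_c[k, ])
    if (k < K) {
      n_next <- n_pred[k] - clin_tot - design$observed_fin[k] - design$observed_drop[k]
      # fractions update: finishers and dropouts exit proportionally across
      # sub-cohorts, so only clinical pregnancies reshape the mixture
      denom <- n_pred[k] - clin_tot
      frac_next <- if (denom > 0) (n_c[k, ] - preg_clin_c[k, ]) / denom else frac
      n_pred[k + 1L] <- n_next
      n_c[k + 1L, ] <- n_next * frac_next
    }
  }

  nonpreg <- NULL
  if (!is.null(design$horizon)) {
    nonpreg <- sum(design$n_initial * frac * (1 - fec_clin)^design$horizon)
  }
  list(n_pred = n_pred, n_c = n_c,
       preg_hcg = rowSums(preg_hcg_c), preg_clin = rowSums(preg_clin_c),
       preg_hcg_c = preg_hcg_c, preg_clin_c = preg_clin_c,
       pct_fert = n_c[, 1L] / pmax(n_pred, .Machine$double.eps),
       nonpreg = nonpreg, fec_hcg = fec_hcg, fec_clin = fec_clin,
       pi_clin = pi_clin)
}

#' Deterministic forward prediction of a cohort trajectory
#'
#' Runs the cycle-by-cycle mixture cohort-depletion recursion. Each cycle the
#' cohort is split into sub-cohorts by the current mixture fractions; each
#' sub-cohort contributes expected hCG pregnancies (`N_c * FEC_HCG_c`) and
#' expected clinical pregnancies (`N_c * FEC_HCG_c * pi_CLIN_c`); the cohort
#' is then depleted by the predicted clinical pregnancies together with the
#' observed finishers and dropouts from the design, and the mixture fractions
#' are updated (clinical pregnancies remove proportionally more fertile
#' women, so the fertile fraction declines cycle on cycle). When the design
#' has a long horizon, the expected number of women never clinically pregnant
#' after `horizon` cycles is `sum_c N_c(1) * (1 - FEC_CLIN_c)^horizon`.
#'
#' All quantities are real-valued expectations in units of women.
#'
#' @param params a [parameter_set()].
#' @param design a [study_design()].
#' @return An object of class `prediction_series`: a tibble with one row per
#'   cycle and columns `cycle`, `n_pred`, `pct_fert`, per-sub-cohort counts
#'   `n_sub1..`, `preg_hcg_pred`, `preg_clin_pred`; the expected
#'   never-pregnant count (if a horizon is set) is in attribute
#'   `nonpreg_pred`, the per-cycle sub-cohort matrices in attribute `cohorts`.
#' @export
#' @examples
#' p <- parameter_set(logit_fert1 = 0.408, logit_fec_hcg = c(-0.118, -1.087),
#'                    logit_pi_clin = 0.558)
#' d <- study_design(n_initial = 221, n_cycles = 9,
#'                   observed_fin = c(rep(0, 8), 100), observed_drop = rep(2, 9),
#'                   horizon = 24)
#' ps <- predict_series(p, d)
#' attr(ps, "nonpreg_pred")  # ~14 women never pregnant by cycle 24
predict_series <- function(params, design) {
  stopifnot(inherits(params, "parameter_set"), inherits(design, "study_design"))
  core <- .predict_core(params, design)
  out <- tibble::tibble(
    cycle = seq_len(design$n_cycles),
    n_pred = core$n_pred,
    pct_fert = core$pct_fert,
    preg_hcg_pred = core$preg_hcg,
    preg_clin_pred = core$preg_clin
  )
  for (j in seq_len(params$n_subcohorts)) {
    out[[paste0("n_sub", j)]] <- core$n_c[, j]
  }
  structure(out,
            nonpreg_pred = core$nonpreg,
            cohorts = list(preg_hcg = core$preg_hcg_c,
                           preg_clin = core$preg_clin_c),
            fec_clin = core$fec_clin,
            class = c("prediction_series", class(out)))
}

#' Observed/predicted pairs entering the fit objective
#'
#' Assembles the observation vector the extended-least-squares fit consumes,
#' paired with the model predictions at the supplied parameters. The order is
#' fixed and documented: (1) cohort sizes `n_start` for cycles `2..K` (`N(1)`
#' is fixed by design and not an observation); (2) hCG pregnancy counts for
#' the cycles where they were reported, in cycle order; (3) clinical
#' pregnancy counts for cycles `1..K`; (4) the never-clinically-pregnant
#' count at the horizon, when present. For the three study shapes this yields
#' 8+9+9+1 = 27, 11+3+12 = 26 and 13+14+14 = 41 pairs respectively.
#'
#' @param dataset a [study_dataset()].
#' @param params a [parameter_set()].
#' @return A tibble with columns `series` (`"n_start"`, `"preg_hcg"`,
#'   `"preg_clin"`, `"nonpreg"`), `cycle`, `observed`, `predicted`.
#' @export
observation_pairs <- function(dataset, params) {
  design <- design_from_dataset(dataset)
  core <- .predict_core(params, design)
  cy <- dataset$cycles
  K <- design$n_cycles

  idx_n <- design$n_start_observed_cycles
  idx_h <- design$hcg_observed_cycles
  series <- c(rep("n_start", length(idx_n)), rep("preg_hcg", length(idx_h)),
              rep("preg_clin", K))
  cycle <- c(idx_n, idx_h, seq_len(K))
  observed <- c(cy$n_start[idx_n], cy$preg_hcg[idx_h], cy$preg_clin)
  predicted <- c(core$n_pred[idx_n], core$preg_hcg[idx_h], core$preg_clin)
  if (!is.null(dataset$nonpreg_horizon)) {
    series <- c(series, "nonpreg")
    cycle <- c(cycle, dataset$nonpreg_horizon$horizon_cycles)
    observed <- c(observed, dataset$nonpreg_horizon$nonpreg_count)
    predicted <- c(predicted, core$nonpreg)
  }
  tibble::tibble(series = series, cycle = cycle,
                 observed = observed, predicted = predicted)
}
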