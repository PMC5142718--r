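#' Specify a model variant
#'
#' The model variants differ in the number of fecundability sub-cohorts,
#' whether the hCG-to-clinical progression probability is shared across
#' sub-cohorts, whether the residual variance exponent gamma is fixed at zero
#' (homoscedastic residuals), and the parameterisation of the clinical stage.
#' Under `"hcg+piclin"` the model estimates `pi_CLIN` directly; under
#' `"hcg+clin"` it estimates the fertile sub-cohort's clinical fecundability
#' `FEC_CLIN` instead, with `pi_CLIN = FEC_CLIN / FEC_HCG` derived — the two
#' parameterisations describe the same model and reach the same objective,
#' but give standard errors for different quantities.
#'
#' Named variants: `"0"` two sub-cohorts, shared `pi_CLIN`; `"00"` the same
#' model with the clinical-fecundability parameterisation; `"1"` a single
#' sub-cohort; `"2"` three sub-cohorts, shared `pi_CLIN`; `"3"` three
#' sub-cohorts with per-sub-cohort `pi_CLIN`; `"4"` two sub-cohorts with
#' `gamma` fixed at 0.
#'
#' @param model optional variant name (`"0"`, `"00"`, `"1"`, `"2"`, `"3"`,
#'   `"4"`); when given, the remaining arguments are filled in.
#' @param n_subcohorts 1, 2 or 3.
#' @param shared_pi_clin logical; one `pi_CLIN` for all sub-cohorts?
#' @param gamma_fixed_zero logical; fix the variance exponent at 0?
#' @param parameterization `"hcg+piclin"` or `"hcg+clin"`.
#' @return An object of class `model_spec`.
#' @export
#' @examples
#' model_spec("0")
#' model_spec(n_subcohorts = 3, shared_pi_clin = FALSE)
model_spec <- function(model = NULL, n_subcohorts = 2, shared_pi_clin = TRUE,
                       gamma_fixed_zero = FALSE,
                       parameterization = c("hcg+piclin", "hcg+clin")) {
  if (!is.null(model)) {
    model <- as.character(model)
    defs <- list(
      "0"  = list(2, TRUE,  FALSE, "hcg+piclin"),
      "00" = list(2, TRUE,  FALSE, "hcg+clin"),
      "1"  = list(1, TRUE,  FALSE, "hcg+piclin"),
      "2"  = list(3, TRUE,  FALSE, "hcg+piclin"),
      "3"  = list(3, FALSE, FALSE, "hcg+piclin"),
      "4"  = list(2, TRUE,  TRUE,  "hcg+piclin")
    )
    if (!model %in% names(defs)) {
      stop("unknown model variant: ", model, call. = FALSE)
    }
    d <- defs[[model]]
    n_subcohorts <- d[[1]]; shared_pi_clin <- d[[2]]
    gamma_fixed_zero <- d[[3]]; parameterization <- d[[4]]
  }
  parameterization <- match.arg(parameterization)
  if (!n_subcohorts %in% 1:3) stop("n_subcohorts must be 1, 2 or 3", call. = FALSE)
  if (parameterization == "hcg+clin" && !shared_pi_clin) {
    stop("the clinical-fecundability parameterisation requires a shared pi_CLIN",
         call. = FALSE)
  }
  structure(
    list(name = if (is.null(model)) NA_character_ else model,
         n_subcohorts = as.integer(n_subcohorts),
         shared_pi_clin = isTRUE(shared_pi_clin),
         gamma_fixed_zero = isTRUE(gamma_fixed_zero),
         parameterization = parameterization),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec%s> %d sub-cohort(s), pi_CLIN %s, gamma %s, %s\n",
              if (is.na(x$name)) "" else paste0(" ", x$name),
              x$n_subcohorts,
              if (x$shared_pi_clin) "shared" else "per-sub-cohort",
              if (x$gamma_fixed_zero) "fixed at 0" else "free",
              x$parameterization))
  invisible(x)
}

#' Extended-least-squares objective
#'
#' The fit minimises `sum_i [ (y_i - f_i)^2 / g_i + ln g_i ]` over the model
#' parameters, where `y_i` are the observed counts, `f_i` the model
#' predictions, and the residual variance follows a power-of-the-mean model
#' `g_i = sigma^2 * max(f_i, floor)^gamma`. The objective plays the role of
#' -2 log-likelihood under normal residuals (the additive `n log 2*pi`
#' constant is omitted, so only differences between objectives are
#' convention-free). With `gamma = 0` residuals are homoscedastic; with
#' `gamma = 2` the residual coefficient of variation is constant.
#'
#' @param params a [parameter_set()] supplying `sigma = exp(log_sigma)` and
#'   `gamma`.
#' @param pairs observation/prediction pairs as returned by
#'   [observation_pairs()] (columns `observed`, `predicted`).
#' @param floor lower bound applied to predictions inside the variance model,
#'   preventing variance collapse when predicted counts approach zero in late
#'   cycles (in units of women).
#' @return The objective value (scalar).
#' @export
els_objective <- function(params, pairs, floor = 1e-6) {
  stopifnot(inherits(params, "parameter_set"))
  y <- pairs$observed
  f <- pairs$predicted
  if (length(y) == 0L) stop("pairs must be non-empty", call. = FALSE)
  sigma <- exp(params$log_sigma)
  g <- sigma^2 * pmax(f, floor)^params$gamma
  if (any(!is.finite(g)) || any(g <= 0)) {
    stop("residual variance g underflowed to a non-positive value", call. = FALSE)
  }
  sum((y - f)^2 / g + log(g))
}

# ---- internal: packing between the unconstrained theta vector and a
# parameter_set, per model_spec ------------------------------------------

.theta_layout <- function(spec, fixed_sigma = NULL) {
  n <- spec$n_subcohorts
  nm <- character(0)
  if (n >= 2L) nm <- c(nm, paste0("logit_mix", seq_len(n - 1L)))
  nm <- c(nm, paste0("logit_fec_hcg", seq_len(n)))
  if (spec$parameterization == "hcg+clin") {
    nm <- c(nm, "logit_fec_clin1")
  } else if (spec$shared_pi_clin) {
    nm <- c(nm, "logit_pi_clin")
  } else {
    nm <- c(nm, paste0("logit_pi_clin", seq_len(n)))
  }
  if (is.null(fixed_sigma)) nm <- c(nm, "log_sigma")
  if (!spec$gamma_fixed_zero) nm <- c(nm, "gamma")
  nm
}

# returns a parameter_set, or NULL if theta is infeasible (hcg+clin with
# implied pi_CLIN outside (0,1))
.theta_to_params <- function(theta, spec, fixed_sigma = NULL) {
  n <- spec$n_subcohorts
  i <- 0L
  take <- function(k) { v <- theta[i + seq_len(k)]; i <<- i + k; v }
  mix <- if (n >= 2L) take(n - 1L) else numeric(0)
  hcg <- take(n)
  if (spec$parameterization == "hcg+clin") {
    clin1 <- take(1L)
    p_hcg1 <- logit10_to_prob(hcg[1L])
    p_clin1 <- logit10_to_prob(clin1)
    pi_clin_p <- p_clin1 / p_hcg1
    if (!is.finite(pi_clin_p) || pi_clin_p <= 0 || pi_clin_p >= 1) return(NULL)
    pic <- prob_to_logit10(pi_clin_p)
  } else {
    pic <- take(if (spec$shared_pi_clin) 1L else n)
  }
  log_sigma <- if (is.null(fixed_sigma)) take(1L) else log(fixed_sigma)
  gamma <- if (spec$gamma_fixed_zero) 0 else take(1L)
  parameter_set(logit_fert1 = mix, logit_fec_hcg = hcg, logit_pi_clin = pic,
                log_sigma = log_sigma, gamma = gamma)
}

.params_to_theta <- function(params, spec, fixed_sigma = NULL) {
  th <- c(params$logit_fert1, params$logit_fec_hcg)
  if (spec$parameterization == "hcg+clin") {
    fec_clin1 <- logit10_to_prob(params$logit_fec_hcg[1L]) *
      logit10_to_prob(params$logit_pi_clin[1L])
    th <- c(th, prob_to_logit10(fec_clin1))
  } else {
    th <- c(th, params$logit_pi_clin)
  }
  if (is.null(fixed_sigma)) th <- c(th, params$log_sigma)
  if (!spec$gamma_fixed_zero) th <- c(th, params$gamma)
  stats::setNames(th, .theta_layout(spec, fixed_sigma))
}

# Relabel sub-cohorts so FEC_HCG is decreasing (sub-cohort 1 most fertile).
# The objective is invariant under relabelling, so the canonical point is the
# same optimum; without this, label switching across seeds or starts makes
# estimates incomparable.
.canonicalize_params <- function(params) {
  n <- params$n_subcohorts
  if (n == 1L) return(params)
  ord <- order(params$logit_fec_hcg, decreasing = TRUE)
  if (identical(ord, seq_len(n))) return(params)
  frac <- mixture_fractions(params)[ord]
  # re-derive the stick-breaking logits of the permuted fractions
  mix <- numeric(n - 1L)
  rem <- 1
  for (j in seq_len(n - 1L)) {
    mix[j] <- prob_to_logit10(min(max(frac[j] / rem, 1e-15), 1 - 1e-15))
    rem <- rem - frac[j]
  }
  pic <- params$logit_pi_clin
  if (length(pic) == n) pic <- pic[ord]
  parameter_set(logit_fert1 = mix,
                logit_fec_hcg = params$logit_fec_hcg[ord],
                logit_pi_clin = pic,
                log_sigma = params$log_sigma, gamma = params$gamma)
}

# evaluate code with a temporary RNG state
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Fit a cohort-depletion model by extended least squares
#'
#' Minimises the [els_objective()] over the unconstrained parameter vector
#' (base-10 logits for probabilities, log sigma, gamma) with a seeded
#' multi-start quasi-Newton (BFGS) search: one start at neutral values and
#' the rest jittered by up to one logit. Standard errors come from the
#' inverse Hessian of half the objective at the best optimum (the objective
#' plays -2 log-likelihood), computed by finite differences.
#'
#' @param dataset a [study_dataset()].
#' @param spec a [model_spec()] (or a variant name accepted by it).
#' @param options list of fitting options: `starts` (number of starts,
#'   default 8), `seed` (for the start jitter, default 1), `extra_starts`
#'   (list of [parameter_set()]s added as additional starting points, used
#'   e.g. to seed a three-sub-cohort fit from a two-sub-cohort optimum),
#'   `fixed_sigma` (fix sigma at this value instead of estimating it; used by
#'   noise-free recovery tests where a free sigma would diverge), `maxit`,
#'   `reltol` (passed to [stats::optim()]).
#' @return An object of class `fit_result`: estimates (as a
#'   [parameter_set()] and as the named unconstrained vector `theta`),
#'   standard errors on the estimation scale (`NULL` if the Hessian is
#'   singular), covariance matrix, objective value, observation and parameter
#'   counts, degrees of freedom, residuals, the observation pairs at the
#'   optimum, and a convergence block (per-start objectives, best start,
#'   gradient norm).
#' @export
fit_model <- function(dataset, spec = model_spec("0"), options = list()) {
  if (!inherits(spec, "model_spec")) spec <- model_spec(spec)
  stopifnot(inherits(dataset, "study_dataset"))
  opts <- utils::modifyList(
    list(starts = 8L, seed = 1L, extra_starts = NULL, fixed_sigma = NULL,
         maxit = 2000L, reltol = 1e-12),
    options)

  design <- design_from_dataset(dataset)
  cy <- dataset$cycles
  idx_n <- design$n_start_observed_cycles
  idx_h <- design$hcg_observed_cycles
  K <- design$n_cycles
  has_horizon <- !is.null(dataset$nonpreg_horizon)
  observed <- c(cy$n_start[idx_n], cy$preg_hcg[idx_h], cy$preg_clin,
                if (has_horizon) dataset$nonpreg_horizon$nonpreg_count)
  n_obs <- length(observed)

  nm <- .theta_layout(spec, opts$fixed_sigma)
  n_par <- length(nm)
  if (n_obs <= n_par) {
    stop("observation count must exceed parameter count", call. = FALSE)
  }

  floor_ <- 1e-6
  predict_vec <- function(params) {
    core <- .predict_core(params, design)
    c(core$n_pred[idx_n], core$preg_hcg[idx_h], core$preg_clin,
      if (has_horizon) core$nonpreg)
  }
  obj <- function(theta) {
    params <- tryCatch(.theta_to_params(theta, spec, opts$fixed_sigma),
                       error = function(e) NULL)
    if (is.null(params)) return(1e10)
    f <- predict_vec(params)
    g <- exp(2 * params$log_sigma) * pmax(f, floor_)^params$gamma
    v <- sum((observed - f)^2 / g + log(g))
    if (!is.finite(v)) 1e10 else v
  }

  # starting points: neutral, seeded jitters, plus any caller-supplied ones
  neutral <- stats::setNames(rep(0, n_par), nm)
  if ("gamma" %in% nm) neutral[["gamma"]] <- 1
  if (spec$n_subcohorts >= 2L) {
    # spread the fecundability logits so sub-cohorts start distinct
    hcg_idx <- grep("^logit_fec_hcg", nm)
    neutral[hcg_idx] <- seq(0, -1 * (spec$n_subcohorts - 1L),
                            length.out = spec$n_subcohorts)
  }
  if (spec$parameterization == "hcg+clin") {
    # keep FEC_CLIN below FEC_HCG at the start so pi_CLIN is feasible
    neutral[["logit_fec_clin1"]] <- neutral[[grep("^logit_fec_hcg1", nm, value = TRUE)]] - 0.3
  }
  starts <- list(neutral)
  n_jitter <- max(opts$starts - 1L, 0L)
  if (n_jitter > 0L) {
    jit <- .with_seed(opts$seed,
                      matrix(stats::runif(n_jitter * n_par, -1, 1), n_jitter, n_par))
    for (j in seq_len(n_jitter)) starts[[length(starts) + 1L]] <- neutral + jit[j, ]
  }
  if (!is.null(opts$extra_starts)) {
    for (ps in opts$extra_starts) {
      starts[[length(starts) + 1L]] <- .params_to_theta(ps, spec, opts$fixed_sigma)
    }
  }

  fits <- vector("list", length(starts))
  for (s in seq_along(starts)) {
    fits[[s]] <- tryCatch(
      stats::optim(starts[[s]], obj, method = "BFGS",
                   control = list(maxit = opts$maxit, reltol = opts$reltol)),
      error = function(e) list(value = Inf, convergence = 99L,
                               message = conditionMessage(e)))
  }
  vals <- vapply(fits, function(f) f$value, numeric(1))
  if (all(!is.finite(vals) | vals >= 1e10)) {
    stop("no start converged to a feasible optimum; per-start objectives: ",
         paste(signif(vals, 6), collapse = ", "), call. = FALSE)
  }
  best_idx <- which.min(vals)  # which.min takes the first of ties
  best <- fits[[best_idx]]
  theta_hat <- stats::setNames(best$par, nm)
  params_hat <- .theta_to_params(theta_hat, spec, opts$fixed_sigma)
  # report in canonical sub-cohort order (decreasing FEC_HCG); the relabelled
  # point is the same optimum, so SEs are computed there
  canon <- .canonicalize_params(params_hat)
  if (!isTRUE(all.equal(canon$logit_fec_hcg, params_hat$logit_fec_hcg))) {
    params_hat <- canon
    theta_hat <- .params_to_theta(params_hat, spec, opts$fixed_sigma)
  }

  # numerical gradient norm at the optimum, for the convergence record
  eps <- 1e-6
  grad <- vapply(seq_len(n_par), function(j) {
    tp <- theta_hat; tm <- theta_hat
    tp[j] <- tp[j] + eps; tm[j] <- tm[j] - eps
    (obj(tp) - obj(tm)) / (2 * eps)
  }, numeric(1))

  # covariance = inverse Hessian of half the objective (ELS ~ -2 log L)
  se <- NULL; vcov <- NULL; hessian_ok <- FALSE
  H <- tryCatch(stats::optimHess(theta_hat, function(t) 0.5 * obj(t)),
                error = function(e) NULL)
  if (!is.null(H)) {
    vcov <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(vcov) && all(diag(vcov) > 0)) {
      se <- stats::setNames(sqrt(diag(vcov)), nm)
      hessian_ok <- TRUE
    }
  }
  if (!hessian_ok) {
    warning("Hessian singular or not positive definite; standard errors unavailable",
            call. = FALSE)
    vcov <- NULL
  }

  f_hat <- predict_vec(params_hat)
  pairs <- observation_pairs(dataset, params_hat)

  structure(
    list(model_spec = spec,
         theta = theta_hat,
         estimates = params_hat,
         standard_errors = se,
         vcov = vcov,
         objective_value = best$value,
         n_observations = n_obs,
         n_parameters = n_par,
         degrees_of_freedom = n_obs - n_par,
         residuals = observed - f_hat,
         pairs = pairs,
         fixed_sigma = opts$fixed_sigma,
         convergence = list(
           status = best$convergence,
           optimizer = "BFGS (stats::optim), multi-start",
           iterations = unname(best$counts["function"]),
           gradient_norm = sqrt(sum(grad^2)),
           best_start = best_idx,
           start_objectives = vals,
           hessian_ok = hessian_ok)),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> model %s: ELS = %.4f, N = %d, parameters = %d, dof = %d\n",
              if (is.na(x$model_spec$name)) "(custom)" else x$model_spec$name,
              x$objective_value, x$n_observations, x$n_parameters,
              x$degrees_of_freedom))
  est <- x$theta
  se <- if (is.null(x$standard_errors)) rep(NA_real_, length(est)) else x$standard_errors
  for (j in seq_along(est)) {
    cat(sprintf("  %-16s %8.4f  (SE %s)\n", names(est)[j], est[j],
                ifelse(is.na(se[j]), "n/a", sprintf("%.4f", se[j]))))
  }
  invisible(x)
}

#' Wald confidence intervals on the natural scales
#'
#' Builds Wald intervals `estimate +/- z * SE` on the estimation scale and
#' maps them to the natural scale of each parameter: base-10 logits through
#' the inverse logit (so probability intervals respect (0, 1) by
#' construction), `log_sigma` through `exp`, `gamma` unchanged.
#'
#' @param fit a [fit_result][fit_model()] with standard errors.
#' @param level confidence level (default 0.95).
#' @return A tibble with columns `parameter`, `scale` (`"probability"`,
#'   `"sigma"`, or `"gamma"`), `estimate`, `lower`, `upper`. When the fit has
#'   no standard errors the bounds are `NA` and a column `available` is
#'   `FALSE`.
#' @export
parameter_intervals <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "fit_result"))
  z <- stats::qnorm(1 - (1 - level) / 2)
  nm <- names(fit$theta)
  est <- fit$theta
  if (is.null(fit$standard_errors)) {
    return(tibble::tibble(parameter = nm, scale = NA_character_,
                          estimate = NA_real_, lower = NA_real_,
                          upper = NA_real_, available = FALSE))
  }
  se <- fit$standard_errors
  lo <- est - z * se
  hi <- est + z * se
  scale <- ifelse(grepl("^logit_", nm), "probability",
                  ifelse(nm == "log_sigma", "sigma", "gamma"))
  transf <- function(v, s) {
    ifelse(s == "probability", logit10_to_prob(v),
           ifelse(s == "sigma", exp(v), v))
  }
  tibble::tibble(
    parameter = sub("^log_sigma$", "sigma", sub("^logit_", "", nm)),
    scale = scale,
    estimate = transf(est, scale),
    lower = transf(lo, scale),
    upper = transf(hi, scale),
    available = TRUE
  )
}
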