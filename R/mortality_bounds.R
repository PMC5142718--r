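#' Stage probabilities of the reproductive-success chain
#'
#' A menstrual cycle ends in a live birth only if five stages succeed in
#' turn: sperm-ovum co-localisation (`pi_soc`), fertilisation (`pi_fert`),
#' implantation, signalled by detectable hCG (`pi_hcg`), clinical recognition
#' (`pi_clin`) and survival to live birth (`pi_lb`). The cumulative products
#' define four fecundabilities: total (`pi_soc * pi_fert`), hCG-detectable,
#' clinical and live-birth. Unknown stages may be left `NA`.
#'
#' @param pi_soc,pi_fert,pi_hcg,pi_clin,pi_lb probabilities in (0, 1], or
#'   `NA` when unknown.
#' @return An object of class `stage_probabilities` with the five stages and
#'   the four cumulative fecundabilities (`fec_tot`, `fec_hcg`, `fec_clin`,
#'   `fec_lb`; `NA` where an upstream stage is unknown).
#' @export
#' @examples
#' stage_probabilities(pi_soc = 0.8, pi_fert = 0.735, pi_hcg = 0.735,
#'                     pi_clin = 0.783, pi_lb = 136 / 155)
stage_probabilities <- function(pi_soc = NA, pi_fert = NA, pi_hcg = NA,
                                pi_clin = NA, pi_lb = NA) {
  st <- c(pi_soc = pi_soc, pi_fert = pi_fert, pi_hcg = pi_hcg,
          pi_clin = pi_clin, pi_lb = pi_lb)
  known <- !is.na(st)
  if (any(st[known] <= 0 | st[known] > 1)) {
    stop("known stage probabilities must lie in (0, 1]", call. = FALSE)
  }
  structure(
    c(as.list(st),
      list(fec_tot = unname(st["pi_soc"] * st["pi_fert"]),
           fec_hcg = unname(st["pi_soc"] * st["pi_fert"] * st["pi_hcg"]),
           fec_clin = unname(st["pi_soc"] * st["pi_fert"] * st["pi_hcg"] * st["pi_clin"]),
           fec_lb = unname(st["pi_soc"] * st["pi_fert"] * st["pi_hcg"] *
                             st["pi_clin"] * st["pi_lb"]))),
    class = "stage_probabilities"
  )
}

#' @export
print.stage_probabilities <- function(x, ...) {
  cat("<stage_probabilities>\n")
  fmt <- function(v) ifelse(is.na(v), "  ?  ", sprintf("%.3f", v))
  cat(sprintf("  pi_SOC %s  pi_FERT %s  pi_HCG %s  pi_CLIN %s  pi_LB %s\n",
              fmt(x$pi_soc), fmt(x$pi_fert), fmt(x$pi_hcg), fmt(x$pi_clin),
              fmt(x$pi_lb)))
  cat(sprintf("  FEC_TOT %s  FEC_HCG %s  FEC_CLIN %s  FEC_LB %s\n",
              fmt(x$fec_tot), fmt(x$fec_hcg), fmt(x$fec_clin), fmt(x$fec_lb)))
  invisible(x)
}

#' Probability that a clinical pregnancy ends in a live birth
#'
#' Simple proportion of live births among clinical pregnancies with a known
#' eligible outcome (pregnancies lost to follow-up and induced abortions are
#' excluded from the denominator before calling this).
#'
#' @param live_births number of live births.
#' @param eligible_clinical_pregnancies number of clinical pregnancies with a
#'   known eligible outcome; must be positive.
#' @return `live_births / eligible_clinical_pregnancies`.
#' @export
#' @examples
#' live_birth_probability(136, 155)  # 0.877
live_birth_probability <- function(live_births, eligible_clinical_pregnancies) {
  if (eligible_clinical_pregnancies <= 0) {
    stop("eligible_clinical_pregnancies must be positive", call. = FALSE)
  }
  if (live_births < 0 || live_births > eligible_clinical_pregnancies) {
    stop("live_births must lie in [0, eligible_clinical_pregnancies]",
         call. = FALSE)
  }
  live_births / eligible_clinical_pregnancies
}

#' Crude per-cycle success probability
#'
#' Successes divided by cycles observed — the crude fecundability one reads
#' off a prospective study without any adjustment for cohort heterogeneity.
#' It is a lower bound for the fecundability of normally fertile couples.
#'
#' @param successes number of successes (e.g. live births).
#' @param cycles number of observed cycles; must be positive.
#' @return `successes / cycles`.
#' @export
#' @examples
#' crude_fecundability(136, 707)  # 0.192
crude_fecundability <- function(successes, cycles) {
  if (cycles <= 0) stop("cycles must be positive", call. = FALSE)
  if (successes < 0 || successes > cycles) {
    stop("successes must lie in [0, cycles]", call. = FALSE)
  }
  successes / cycles
}

#' Stage-wise losses of fertilised eggs
#'
#' Given the implantation, clinical-recognition and live-birth stage
#' probabilities, returns the cumulative percentage of fertilised eggs lost
#' before implantation, `100 * (1 - pi_hcg)`; before clinical recognition,
#' `100 * (1 - pi_hcg * pi_clin)`; and before live birth,
#' `100 * (1 - pi_hcg * pi_clin * pi_lb)`; plus the loss from implantation to
#' live birth, `100 * (1 - pi_clin * pi_lb)`. All chaining is done at full
#' precision — rounding the stage probabilities first visibly distorts the
#' results.
#'
#' @param pi_hcg,pi_clin,pi_lb stage probabilities in (0, 1].
#' @return Named numeric vector with elements `before_implantation`,
#'   `before_clinical`, `before_live_birth`, `implantation_to_birth`
#'   (percentages).
#' @export
#' @examples
#' stage_losses(pi_hcg = 0.9, pi_clin = logit10_to_prob(0.558),
#'              pi_lb = 136 / 155)
stage_losses <- function(pi_hcg, pi_clin, pi_lb) {
  pi_hcg <- unname(pi_hcg); pi_clin <- unname(pi_clin); pi_lb <- unname(pi_lb)
  v <- c(pi_hcg, pi_clin, pi_lb)
  if (any(!is.finite(v)) || any(v <= 0 | v > 1)) {
    stop("stage probabilities must lie in (0, 1]", call. = FALSE)
  }
  c(before_implantation = 100 * (1 - pi_hcg),
    before_clinical = 100 * (1 - pi_hcg * pi_clin),
    before_live_birth = 100 * (1 - pi_hcg * pi_clin * pi_lb),
    implantation_to_birth = 100 * (1 - pi_clin * pi_lb))
}

#' Decompose an hCG fecundability into stage probabilities under a scenario
#'
#' `FEC_HCG = pi_soc * pi_fert * pi_hcg`, so given an assumed `pi_soc` the
#' product `pi_fert * pi_hcg = fec_hcg / pi_soc` is fixed, but its split is
#' not identifiable from hCG data. The split is resolved by scenario:
#' \describe{
#'   \item{`"equal_fert_hcg"`}{`pi_fert = pi_hcg = sqrt(product)`.}
#'   \item{`"pi_fert_fixed"`}{`pi_fert` fixed at `fixed_value`,
#'     `pi_hcg = product / fixed_value`.}
#'   \item{`"pi_hcg_fixed"`}{`pi_hcg` fixed at `fixed_value`,
#'     `pi_fert = product / fixed_value`.}
#' }
#' A derived probability above 1 makes the scenario infeasible and raises an
#' error naming the binding constraint.
#'
#' @param fec_hcg per-cycle hCG-conception probability, in (0, 1).
#' @param pi_soc assumed probability of sperm-ovum co-localisation. This is an
#'   explicit assumption knob and has no default.
#' @param scenario one of `"equal_fert_hcg"`, `"pi_fert_fixed"`,
#'   `"pi_hcg_fixed"`.
#' @param fixed_value the fixed stage probability for the `*_fixed` scenarios.
#' @param pi_clin,pi_lb optional downstream probabilities; when supplied the
#'   loss percentages are attached.
#' @return An object of class `scenario_result`: the scenario label, the
#'   completed [stage_probabilities()], and (when `pi_clin` and `pi_lb` are
#'   given) the `losses` vector of [stage_losses()].
#' @export
#' @examples
#' decompose_under_scenario(logit10_to_prob(-0.118), pi_soc = 0.80,
#'                          scenario = "equal_fert_hcg")
decompose_under_scenario <- function(fec_hcg, pi_soc,
                                     scenario = c("equal_fert_hcg",
                                                  "pi_fert_fixed",
                                                  "pi_hcg_fixed"),
                                     fixed_value = NULL,
                                     pi_clin = NA, pi_lb = NA) {
  scenario <- match.arg(scenario)
  if (fec_hcg <= 0 || fec_hcg >= 1) stop("fec_hcg must lie in (0, 1)", call. = FALSE)
  if (pi_soc <= 0 || pi_soc > 1) stop("pi_soc must lie in (0, 1]", call. = FALSE)
  product <- fec_hcg / pi_soc
  if (product > 1) {
    stop(sprintf(paste0("infeasible: fec_hcg / pi_soc = %.4f > 1; ",
                        "pi_soc must be at least fec_hcg"), product),
         call. = FALSE)
  }
  if (scenario == "equal_fert_hcg") {
    pi_fert <- pi_hcg <- sqrt(product)
  } else {
    if (is.null(fixed_value) || fixed_value <= 0 || fixed_value > 1) {
      stop("fixed_value in (0, 1] is required for this scenario", call. = FALSE)
    }
    other <- product / fixed_value
    if (other > 1) {
      stop(sprintf(paste0("infeasible: (fec_hcg / pi_soc) / fixed_value = %.4f > 1; ",
                          "the fixed stage is the binding constraint"), other),
           call. = FALSE)
    }
    if (scenario == "pi_fert_fixed") { pi_fert <- fixed_value; pi_hcg <- other }
    else { pi_hcg <- fixed_value; pi_fert <- other }
  }
  stages <- stage_probabilities(pi_soc = pi_soc, pi_fert = pi_fert,
                                pi_hcg = pi_hcg, pi_clin = pi_clin,
                                pi_lb = pi_lb)
  losses <- if (!is.na(pi_clin) && !is.na(pi_lb)) {
    stage_losses(pi_hcg, pi_clin, pi_lb)
  } else NULL
  structure(list(scenario = scenario, stages = stages, losses = losses),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> %s\n", x$scenario))
  print(x$stages)
  if (!is.null(x$losses)) {
    cat(sprintf(paste0("  %% loss: before implantation %.1f, before clinical %.1f,",
                       " before live birth %.1f\n"),
                x$losses["before_implantation"], x$losses["before_clinical"],
                x$losses["before_live_birth"]))
  }
  invisible(x)
}

#' Full stage-probability / scenario grid across studies
#'
#' For each study, takes the fertile sub-cohort's hCG fecundability and the
#' hCG-to-clinical probability (as base-10 logits, i.e. on the scale the
#' model estimates them — chaining from rounded probabilities distorts the
#' loss percentages), together with the live-birth outcome counts, and
#' tabulates: `FEC_HCG`, `FEC_CLIN`, `pi_CLIN`, `pi_LB`, the
#' implantation-to-birth loss, and for each of the three scenarios the
#' completed stage split and the three cumulative loss percentages. A
#' scenario that is infeasible for a study yields `NA` cells for that block.
#'
#' @param studies a data frame (or tibble) with one row per study and columns
#'   `study`, `logit_fec_hcg_fert`, `logit_pi_clin`, `live_births`,
#'   `eligible_clinical_pregnancies`.
#' @param pi_soc assumed sperm-ovum co-localisation probability (no default;
#'   an explicit modelling assumption).
#' @param fixed_value the fixed probability used by the `pi_fert_fixed` and
#'   `pi_hcg_fixed` scenarios (e.g. 0.90).
#' @return A tibble with one row per study x scenario and columns `study`,
#'   `scenario`, `fec_hcg`, `fec_clin`, `pi_clin`, `pi_lb`,
#'   `implantation_to_birth`, `pi_fert`, `pi_hcg`, `loss_before_implantation`,
#'   `loss_before_clinical`, `loss_before_live_birth`. Values are full
#'   precision; round only for presentation.
#' @export
scenario_table <- function(studies, pi_soc, fixed_value = 0.90) {
  required <- c("study", "logit_fec_hcg_fert", "logit_pi_clin", "live_births",
                "eligible_clinical_pregnancies")
  missing_cols <- setdiff(required, names(studies))
  if (length(missing_cols) > 0L) {
    stop("studies is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  scenarios <- c("pi_hcg_fixed", "equal_fert_hcg", "pi_fert_fixed")
  rows <- list()
  for (i in seq_len(nrow(studies))) {
    fec_hcg <- logit10_to_prob(studies$logit_fec_hcg_fert[i])
    pi_clin <- logit10_to_prob(studies$logit_pi_clin[i])
    pi_lb <- live_birth_probability(studies$live_births[i],
                                    studies$eligible_clinical_pregnancies[i])
    for (sc in scenarios) {
      res <- tryCatch(
        decompose_under_scenario(fec_hcg, pi_soc, scenario = sc,
                                 fixed_value = fixed_value,
                                 pi_clin = pi_clin, pi_lb = pi_lb),
        error = function(e) NULL)
      if (is.null(res)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          study = studies$study[i], scenario = sc, fec_hcg = fec_hcg,
          fec_clin = fec_hcg * pi_clin, pi_clin = pi_clin, pi_lb = pi_lb,
          implantation_to_birth = 100 * (1 - pi_clin * pi_lb),
          pi_fert = NA_real_, pi_hcg = NA_real_,
          loss_before_implantation = NA_real_,
          loss_before_clinical = NA_real_,
          loss_before_live_birth = NA_real_)
      } else {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          study = studies$study[i], scenario = sc, fec_hcg = fec_hcg,
          fec_clin = fec_hcg * pi_clin, pi_clin = pi_clin, pi_lb = pi_lb,
          implantation_to_birth = res$losses["implantation_to_birth"],
          pi_fert = res$stages$pi_fert, pi_hcg = res$stages$pi_hcg,
          loss_before_implantation = res$losses["before_implantation"],
          loss_before_clinical = res$losses["before_clinical"],
          loss_before_live_birth = res$losses["before_live_birth"])
      }
    }
  }
  do.call(rbind, rows)
}

#' Range of live-birth losses over the scenario grid
#'
#' Summarises a [scenario_table()] into the minimum and maximum percentage
#' loss of fertilised eggs before live birth across all feasible study x
#' scenario cells — the plausibility band for total embryo and fetal
#' mortality implied by the grid. A derived summary of the grid, not a
#' fitted quantity.
#'
#' @param grid output of [scenario_table()].
#' @return Named numeric vector `c(min = ..., max = ...)` in percent.
#' @export
loss_bounds <- function(grid) {
  v <- grid$loss_before_live_birth
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("no feasible scenario cells in grid", call. = FALSE)
  c(min = min(v), max = max(v))
}
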