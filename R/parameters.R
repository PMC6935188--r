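#' Cost pairs printed on both the pre-inflation and 2017-CAD scales
#'
#' Three annual health-service costs are reported twice in the source
#' literature: once on their original price basis and once inflated to 2017
#' Canadian dollars (first year of life 15976/20265, diagnosed FASD
#' 3426/4346, undiagnosed FASD 2713/3441). The implied inflation factor is
#' recovered from these pairs rather than from an external CPI series.
#'
#' @return A two-column matrix with columns `pre` and `post`.
#' @export
printed_cost_pairs <- function() {
  cbind(pre = c(3426, 15976, 2713), post = c(4346, 20265, 3441))
}

#' Derive the inflation factor from pre/post cost pairs
#'
#' Least-squares ratio `sum(pre * post) / sum(pre^2)` across the pairs. If
#' the per-pair ratios disagree by more than 1% a warning is emitted (the
#' pairs are then not all on the same price basis) but the pooled ratio is
#' still returned.
#'
#' @param pairs Two-column matrix or data frame, first column pre-inflation
#'   cost, second column the same cost in 2017 CAD. All entries positive.
#' @return The scalar inflation factor.
#' @examples
#' derive_inflation_factor(printed_cost_pairs()) # about 1.2685
#' @export
derive_inflation_factor <- function(pairs = printed_cost_pairs()) {
  pairs <- as.matrix(pairs)
  if (nrow(pairs) < 1 || any(pairs <= 0)) {
    stop("'pairs' must contain at least one pair of positive costs")
  }
  ratios <- pairs[, 2] / pairs[, 1]
  if (max(ratios) / min(ratios) > 1.01) {
    warning("per-pair inflation ratios differ by more than 1%")
  }
  sum(pairs[, 1] * pairs[, 2]) / sum(pairs[, 1]^2)
}

#' Inflate a cost to 2017 Canadian dollars
#'
#' @param cost_pre Non-negative cost on the pre-inflation basis.
#' @param factor Positive inflation factor (see [derive_inflation_factor()]).
#' @return `cost_pre * factor`, unrounded; rounding is left to reporting.
#' @examples
#' round(inflate(3426, derive_inflation_factor())) # 4346
#' @export
inflate <- function(cost_pre, factor) {
  if (any(cost_pre < 0)) stop("'cost_pre' must be non-negative")
  if (any(factor <= 0)) stop("'factor' must be positive")
  cost_pre * factor
}

#' Screening-tool profile
#'
#' Describes one screening tool: its pooled accuracy, unit cost, the age at
#' which it is administered and the lag (in years) between a positive screen
#' and diagnostic testing. Meconium testing is administered at birth with a
#' five-year lag to testing; the NST is administered at age 5 with no lag.
#'
#' @param name `"meconium"` or `"nst"`.
#' @param sensitivity,specificity Proportions in \[0, 1\].
#' @param unit_cost Cost per screen, 2017 CAD.
#' @param screen_age Integer age (years) at screening.
#' @param lag_to_testing Integer years between positive screen and
#'   diagnostic testing.
#' @return An object of class `tool_profile`.
#' @export
tool_profile <- function(name, sensitivity, specificity, unit_cost,
                         screen_age, lag_to_testing) {
  stop_unless_prob(sensitivity, "sensitivity")
  stop_unless_prob(specificity, "specificity")
  if (unit_cost < 0) stop("'unit_cost' must be >= 0")
  if (screen_age < 0 || screen_age != round(screen_age)) {
    stop("'screen_age' must be a non-negative integer")
  }
  if (lag_to_testing < 0 || lag_to_testing != round(lag_to_testing)) {
    stop("'lag_to_testing' must be a non-negative integer")
  }
  structure(list(name = name, sensitivity = sensitivity,
                 specificity = specificity, unit_cost = unit_cost,
                 screen_age = screen_age, lag_to_testing = lag_to_testing),
            class = "tool_profile")
}

#' Annual and one-off cost set
#'
#' Annual health-service costs by model state plus the one-off diagnostic
#' testing cost. Annual costs may be supplied on either the pre-inflation
#' basis (as tabulated in the source literature) or already in 2017 CAD; the
#' model normalizes to 2017 CAD internally. The diagnostic-testing cost is
#' already a 2017 value and is never inflated.
#'
#' @param first_year Annual cost applied to every living cohort member in
#'   the first year of life (newborn comparison only).
#' @param diagnosed_annual,undiagnosed_annual,no_fasd_annual Annual
#'   health-service cost for the diagnosed-FASD, undiagnosed-FASD and
#'   no-FASD states.
#' @param diagnostic_testing One-off cost of the diagnostic assessment.
#' @param basis `"pre_inflation"` or `"inflated_2017"`.
#' @return An object of class `cost_set`.
#' @export
cost_set <- function(first_year = 15976, diagnosed_annual = 3426,
                     undiagnosed_annual = 2713, no_fasd_annual = 3101,
                     diagnostic_testing = 3870,
                     basis = c("pre_inflation", "inflated_2017")) {
  basis <- match.arg(basis)
  vals <- c(first_year, diagnosed_annual, undiagnosed_annual, no_fasd_annual,
            diagnostic_testing)
  if (any(vals < 0)) stop("all costs must be >= 0")
  if (basis == "inflated_2017" &&
      !(first_year >= diagnosed_annual && diagnosed_annual >= undiagnosed_annual)) {
    stop("on the inflated basis, first_year >= diagnosed_annual >= undiagnosed_annual must hold")
  }
  structure(list(first_year = first_year, diagnosed_annual = diagnosed_annual,
                 undiagnosed_annual = undiagnosed_annual,
                 no_fasd_annual = no_fasd_annual,
                 diagnostic_testing = diagnostic_testing, basis = basis),
            class = "cost_set")
}

#' Mortality parameters
#'
#' Standardized mortality ratios applied multiplicatively to background
#' (life-table) death probabilities. Diagnosed FASD carries an SMR of 3.15;
#' undiagnosed FASD is assumed 10% higher than diagnosed; children without
#' FASD (but suspected of it) share the diagnosed SMR.
#'
#' @param smr_diagnosed SMR for diagnosed FASD, >= 0.
#' @param undiagnosed_multiplier Ratio (>= 1) applied on top of
#'   `smr_diagnosed` for undiagnosed FASD.
#' @param smr_no_fasd SMR for the no-FASD state.
#' @return An object of class `mortality_params`.
#' @export
mortality_params <- function(smr_diagnosed = 3.15,
                             undiagnosed_multiplier = 1.10,
                             smr_no_fasd = 3.15) {
  if (smr_diagnosed < 0 || smr_no_fasd < 0) stop("SMRs must be >= 0")
  if (undiagnosed_multiplier < 1) stop("'undiagnosed_multiplier' must be >= 1")
  structure(list(smr_diagnosed = smr_diagnosed,
                 undiagnosed_multiplier = undiagnosed_multiplier,
                 smr_no_fasd = smr_no_fasd),
            class = "mortality_params")
}

#' Full model parameter set
#'
#' Bundles every input of the decision model: cohort, screening tool,
#' costs, mortality, discounting, time horizon and the future-diagnosis
#' process, together with the modelling conventions that the published
#' analysis leaves open (half-cycle variant, conversion timing, cost state
#' of children awaiting testing, cost basis).
#'
#' @param cohort_size Number of children entering the model (default 100;
#'   results are therefore "per 100 screened").
#' @param prevalence Proportion of the suspected-FASD cohort that truly
#'   meets FASD criteria (base case 0.663).
#' @param tool A [tool_profile()]; defaults to the named base-case tool.
#' @param costs A [cost_set()].
#' @param mortality A [mortality_params()].
#' @param discount_rate Annual discount rate (base case 0.015).
#' @param end_age Age at which accrual stops (18).
#' @param future_diagnosis_rate Annual rate at which children missed by
#'   screening are nevertheless diagnosed later (base case 0.05).
#' @param diagnostic_sensitivity Sensitivity of the diagnostic assessment
#'   itself (1 in the base case: testing is assumed perfectly accurate).
#' @param inflation_factor Factor converting pre-inflation annual costs to
#'   2017 CAD.
#' @param options A [model_options()] list of convention switches.
#' @return An object of class `model_parameters`.
#' @examples
#' p <- base_case("meconium")
#' p$tool$sensitivity
#' @export
model_parameters <- function(cohort_size = 100, prevalence = 0.663,
                             tool = default_tool("meconium"),
                             costs = cost_set(),
                             mortality = mortality_params(),
                             discount_rate = 0.015, end_age = 18,
                             future_diagnosis_rate = 0.05,
                             diagnostic_sensitivity = 1,
                             inflation_factor = derive_inflation_factor(),
                             options = model_options()) {
  if (cohort_size <= 0) stop("'cohort_size' must be > 0")
  if (prevalence <= 0 || prevalence >= 1) stop("'prevalence' must be in (0, 1)")
  if (discount_rate < 0) stop("'discount_rate' must be >= 0")
  if (end_age <= 0 || end_age != round(end_age)) {
    stop("'end_age' must be a positive integer")
  }
  stop_unless_prob(future_diagnosis_rate, "future_diagnosis_rate")
  stop_unless_prob(diagnostic_sensitivity, "diagnostic_sensitivity")
  if (inflation_factor <= 0) stop("'inflation_factor' must be > 0")
  stopifnot(inherits(tool, "tool_profile"), inherits(costs, "cost_set"),
            inherits(mortality, "mortality_params"))
  structure(list(cohort_size = cohort_size, prevalence = prevalence,
                 tool = tool, costs = costs, mortality = mortality,
                 discount_rate = discount_rate, end_age = end_age,
                 future_diagnosis_rate = future_diagnosis_rate,
                 diagnostic_sensitivity = diagnostic_sensitivity,
                 inflation_factor = inflation_factor, options = options),
            class = "model_parameters")
}

#' Modelling convention switches
#'
#' The published analysis leaves several mechanical conventions open. Each
#' is exposed here; defaults are the combination that best reproduces the
#' published incremental results (see the methods vignette).
#'
#' @param half_cycle `"trapezoid"` (accrue on the average of start- and
#'   end-of-cycle occupancy; default) or `"midcycle"` (accrue on the
#'   end-of-cycle occupancy). Discounting is mid-cycle in both variants.
#' @param conversion_start `"at_testing"` (future-diagnosis conversions can
#'   occur from the cycle containing the testing age; default) or
#'   `"after_testing"`.
#' @param future_diagnosis_model `"hazard"` (each cycle a fraction
#'   `future_diagnosis_rate` of the remaining undiagnosed pool converts;
#'   default) or `"uniform"` (the same fraction of the original
#'   false-negative pool converts each cycle, i.e. a uniform conversion
#'   time).
#' @param pending_fasd_cost Annual-cost state used for FASD children
#'   awaiting diagnostic testing: `"undiagnosed"` (default), `"no_fasd"` or
#'   `"diagnosed"`.
#' @param use_inflated_costs Normalize annual costs to 2017 CAD before
#'   modelling (default `TRUE`).
#' @param inflate_no_fasd Treat the no-FASD annual cost as pre-inflation and
#'   inflate it with the others (default `TRUE`).
#' @return A list of class `model_options`.
#' @export
model_options <- function(half_cycle = c("trapezoid", "midcycle"),
                          conversion_start = c("at_testing", "after_testing"),
                          future_diagnosis_model = c("hazard", "uniform"),
                          pending_fasd_cost = c("undiagnosed", "no_fasd",
                                                "diagnosed"),
                          use_inflated_costs = TRUE,
                          inflate_no_fasd = TRUE) {
  structure(list(half_cycle = match.arg(half_cycle),
                 conversion_start = match.arg(conversion_start),
                 future_diagnosis_model = match.arg(future_diagnosis_model),
                 pending_fasd_cost = match.arg(pending_fasd_cost),
                 use_inflated_costs = isTRUE(use_inflated_costs),
                 inflate_no_fasd = isTRUE(inflate_no_fasd)),
            class = "model_options")
}

#' Base-case screening tool profiles
#'
#' @param name `"meconium"` or `"nst"`.
#' @return A [tool_profile()] with the base-case pooled accuracy, unit cost
#'   and timing for the named tool.
#' @export
default_tool <- function(name = c("meconium", "nst")) {
  name <- match.arg(name)
  if (name == "meconium") {
    tool_profile("meconium", sensitivity = 0.924, specificity = 0.515,
                 unit_cost = 175, screen_age = 0, lag_to_testing = 5)
  } else {
    tool_profile("nst", sensitivity = 0.859, specificity = 0.729,
                 unit_cost = 20, screen_age = 5, lag_to_testing = 0)
  }
}

#' Base-case parameter set for a comparison
#'
#' @param comparison `"meconium"` or `"nst"`.
#' @param ... Overrides passed on to [model_parameters()].
#' @return A `model_parameters` object.
#' @export
base_case <- function(comparison = c("meconium", "nst"), ...) {
  comparison <- match.arg(comparison)
  model_parameters(tool = default_tool(comparison), ...)
}

#' Annual and one-off costs on the modelling basis
#'
#' Resolves a parameter set's [cost_set()] to the values actually used in a
#' model run: annual health-service costs are inflated to 2017 CAD when the
#' set is on the pre-inflation basis (and `use_inflated_costs` is on);
#' screening and diagnostic-testing costs are already 2017 values and pass
#' through unchanged.
#'
#' @param params A `model_parameters` object.
#' @return A list with elements `first_year`, `diagnosed_annual`,
#'   `undiagnosed_annual`, `no_fasd_annual`, `diagnostic_testing`,
#'   `screening`.
#' @export
modelling_costs <- function(params) {
  cs <- params$costs
  f <- if (cs$basis == "pre_inflation" && params$options$use_inflated_costs) {
    params$inflation_factor
  } else {
    1
  }
  list(first_year = cs$first_year * f,
       diagnosed_annual = cs$diagnosed_annual * f,
       undiagnosed_annual = cs$undiagnosed_annual * f,
       no_fasd_annual = cs$no_fasd_annual *
         (if (params$options$inflate_no_fasd) f else 1),
       diagnostic_testing = cs$diagnostic_testing,
       screening = params$tool$unit_cost)
}

stop_unless_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("'%s' must lie in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("FASD screening model parameters\n")
  cat(sprintf("  cohort: %d children, prevalence %.3f\n",
              x$cohort_size, x$prevalence))
  cat(sprintf("  tool: %s (Se %.3f, Sp %.3f, $%.2f at age %d, lag %d y)\n",
              x$tool$name, x$tool$sensitivity, x$tool$specificity,
              x$tool$unit_cost, x$tool$screen_age, x$tool$lag_to_testing))
  cm <- modelling_costs(x)
  cat(sprintf("  annual costs (2017 CAD): y1 %.0f, diagnosed %.0f, undiagnosed %.0f, no-FASD %.0f\n",
              cm$first_year, cm$diagnosed_annual, cm$undiagnosed_annual,
              cm$no_fasd_annual))
  cat(sprintf("  diagnostic testing $%.0f; discount %.1f%%; horizon to age %d\n",
              cm$diagnostic_testing, 100 * x$discount_rate, x$end_age))
  invisible(x)
}
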