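MODEL_STATES <- c("pending_fasd", "undiagnosed", "diagnosed",
                  "pending_no_fasd", "no_fasd", "dead")

#' Strategy definition
#'
#' A strategy is either screening with a tool or no screening (diagnostic
#' testing for everyone). In both arms of a comparison the model starts at
#' the tool's screening age and diagnostic testing happens at the same
#' testing age, so that the two arms differ only in who reaches testing:
#' newborn (meconium) comparisons start at birth with testing at age 5; NST
#' comparisons start at age 5 with immediate testing.
#'
#' @param kind `"screen"` or `"no_screen"`.
#' @param tool A [tool_profile()] (required for `"screen"`).
#' @param model_start_age Age at model entry.
#' @param testing_age Age at which scheduled diagnostic testing occurs.
#' @return An object of class `strategy_definition`.
#' @export
strategy_definition <- function(kind = c("screen", "no_screen"), tool = NULL,
                                model_start_age, testing_age) {
  kind <- match.arg(kind)
  if (kind == "screen" && !inherits(tool, "tool_profile")) {
    stop("a screen strategy requires a tool_profile")
  }
  if (testing_age < model_start_age) {
    stop("'testing_age' must not precede 'model_start_age'")
  }
  structure(list(kind = kind, tool = tool,
                 model_start_age = model_start_age,
                 testing_age = testing_age),
            class = "strategy_definition")
}

#' Both arms of a published comparison
#'
#' @param comparison `"meconium"` (model from birth, testing at age 5 in
#'   both arms) or `"nst"` (model from age 5, immediate testing).
#' @param params A `model_parameters` object; its tool is used for the
#'   screen arm.
#' @return List with elements `no_screen` and `screen`.
#' @export
comparison_strategies <- function(comparison = c("meconium", "nst"),
                                  params = base_case(comparison)) {
  comparison <- match.arg(comparison)
  tool <- params$tool
  start <- tool$screen_age
  testing <- tool$screen_age + tool$lag_to_testing
  list(no_screen = strategy_definition("no_screen", NULL, start, testing),
       screen = strategy_definition("screen", tool, start, testing))
}

#' Initial cohort distribution from the decision tree
#'
#' Screening splits the cohort by true status and screen result: true
#' positives are scheduled for diagnostic testing (`pending_fasd`), false
#' negatives become `undiagnosed`, false positives are scheduled for
#' rule-out testing (`pending_no_fasd`), true negatives are never tested
#' (`no_fasd`). Without screening every child is scheduled for testing.
#'
#' @param params A `model_parameters` object.
#' @param strategy A [strategy_definition()].
#' @return Named numeric vector over the model states, summing to
#'   `cohort_size`.
#' @export
initial_distribution <- function(params, strategy) {
  n_fasd <- params$cohort_size * params$prevalence
  n_no <- params$cohort_size - n_fasd
  sv <- stats::setNames(numeric(length(MODEL_STATES)), MODEL_STATES)
  if (strategy$kind == "screen") {
    se <- strategy$tool$sensitivity
    sp <- strategy$tool$specificity
    sv["pending_fasd"] <- n_fasd * se
    sv["undiagnosed"] <- n_fasd * (1 - se)
    sv["pending_no_fasd"] <- n_no * (1 - sp)
    sv["no_fasd"] <- n_no * sp
  } else {
    sv["pending_fasd"] <- n_fasd
    sv["pending_no_fasd"] <- n_no
  }
  check_conservation(sv, params$cohort_size)
  sv
}

#' State-specific annual death probability
#'
#' Multiplies a background life-table probability by the state's
#' standardized mortality ratio, capping at 1. FASD states awaiting or
#' holding a diagnosis use the diagnosed SMR; undiagnosed FASD is elevated
#' by the undiagnosed multiplier; non-FASD states use the no-FASD SMR.
#'
#' @param q_background Background annual death probability in \[0, 1).
#' @param state One of the model states.
#' @param mortality A [mortality_params()].
#' @return The adjusted annual death probability.
#' @export
state_mortality <- function(q_background, state, mortality) {
  if (any(q_background < 0 | q_background >= 1)) {
    stop("'q_background' must lie in [0, 1)")
  }
  state <- match.arg(state, MODEL_STATES)
  ratio <- switch(state,
                  pending_fasd = ,
                  diagnosed = mortality$smr_diagnosed,
                  undiagnosed = mortality$smr_diagnosed *
                    mortality$undiagnosed_multiplier,
                  pending_no_fasd = ,
                  no_fasd = mortality$smr_no_fasd,
                  dead = 0)
  pmin(1, q_background * ratio)
}

#' Mid-cycle discount weight
#'
#' Events in cycle `cycle` (the cycle spanning one model year) are
#' discounted to its midpoint, `(1 + rate)^-(cycle + 0.5)`, implementing
#' the half-cycle correction on the discounting side.
#'
#' @param cycle Zero-based cycle index.
#' @param rate Annual discount rate, >= 0.
#' @return Discount weight(s) in (0, 1\].
#' @export
discount_factor <- function(cycle, rate) {
  if (any(rate < 0)) stop("'rate' must be >= 0")
  (1 + rate)^-(cycle + 0.5)
}

#' Advance the cohort by one cycle
#'
#' Applies, in order: state-specific mortality; scheduled diagnostic
#' testing in the cycle containing the testing age (perfectly accurate by
#' default, `diagnostic_sensitivity` otherwise; every tested child incurs
#' the testing cost once); future-diagnosis conversion of undiagnosed
#' children (re-screen plus testing cost at conversion); annual state
#' costs (the first-year-of-life cost replaces state costs in cycle 0 of a
#' from-birth model); and diagnosed-year accrual. Occupancy accrual uses
#' the cycle average (trapezoid) or end-of-cycle state per
#' `params$options$half_cycle`; all accruals are discounted mid-cycle.
#'
#' @param sv Named state vector at cycle start.
#' @param cycle Zero-based cycle index.
#' @param params,strategy,life_table Model inputs.
#' @param undiagnosed_reference Reference mass for the `"uniform"`
#'   future-diagnosis model (ignored under `"hazard"`).
#' @return List with the end-of-cycle `state`, the updated
#'   `undiagnosed_reference`, and the cycle's `cost`, `cost_discounted`,
#'   `effect`, `effect_discounted`.
#' @export
advance_cycle <- function(sv, cycle, params, strategy,
                          life_table = make_life_table(end_age = params$end_age),
                          undiagnosed_reference = sv[["undiagnosed"]]) {
  check_conservation(sv, params$cohort_size)
  opts <- params$options
  costs <- modelling_costs(params)
  age <- strategy$model_start_age + cycle
  d <- discount_factor(cycle, params$discount_rate)
  sv0 <- sv
  one_off <- 0

  if (strategy$kind == "screen" && cycle == 0) {
    one_off <- one_off + costs$screening * params$cohort_size
  }

  q <- lookup_qx(life_table, age)
  m <- params$mortality
  qd <- min(1, q * m$smr_diagnosed)
  qu <- min(1, q * m$smr_diagnosed * m$undiagnosed_multiplier)
  qn <- min(1, q * m$smr_no_fasd)
  qs <- c(pending_fasd = qd, undiagnosed = qu, diagnosed = qd,
          pending_no_fasd = qn, no_fasd = qn, dead = 0)[MODEL_STATES]
  sv["dead"] <- sv[["dead"]] + sum(sv * qs)
  sv <- sv * (1 - qs)
  undiagnosed_reference <- undiagnosed_reference * (1 - qu)

  if (age == strategy$testing_age) {
    tested <- sv[["pending_fasd"]] + sv[["pending_no_fasd"]]
    one_off <- one_off + costs$diagnostic_testing * tested
    ds <- params$diagnostic_sensitivity
    sv["diagnosed"] <- sv["diagnosed"] + sv[["pending_fasd"]] * ds
    missed <- sv[["pending_fasd"]] * (1 - ds)
    sv["undiagnosed"] <- sv["undiagnosed"] + missed
    undiagnosed_reference <- undiagnosed_reference + missed
    sv["pending_fasd"] <- 0
    sv["no_fasd"] <- sv["no_fasd"] + sv[["pending_no_fasd"]]
    sv["pending_no_fasd"] <- 0
  }

  conv_from <- strategy$testing_age +
    (opts$conversion_start == "after_testing")
  if (sv[["undiagnosed"]] > 0 && age >= conv_from) {
    rho <- params$future_diagnosis_rate
    converting <- if (opts$future_diagnosis_model == "hazard") {
      rho * sv[["undiagnosed"]]
    } else {
      min(sv[["undiagnosed"]], rho * undiagnosed_reference)
    }
    sv["undiagnosed"] <- sv["undiagnosed"] - converting
    sv["diagnosed"] <- sv["diagnosed"] + converting
    rescreen <- if (is.null(strategy$tool)) 0 else strategy$tool$unit_cost
    one_off <- one_off + converting * (rescreen + costs$diagnostic_testing)
  }

  acc <- if (opts$half_cycle == "trapezoid") (sv0 + sv) / 2 else sv
  alive <- sum(acc) - acc[["dead"]]
  annual <- if (strategy$model_start_age == 0 && cycle == 0) {
    costs$first_year * alive
  } else {
    pending_cost <- switch(opts$pending_fasd_cost,
                           undiagnosed = costs$undiagnosed_annual,
                           no_fasd = costs$no_fasd_annual,
                           diagnosed = costs$diagnosed_annual)
    acc[["diagnosed"]] * costs$diagnosed_annual +
      acc[["undiagnosed"]] * costs$undiagnosed_annual +
      acc[["pending_fasd"]] * pending_cost +
      (acc[["no_fasd"]] + acc[["pending_no_fasd"]]) * costs$no_fasd_annual
  }
  effect <- acc[["diagnosed"]]

  check_conservation(sv, params$cohort_size)
  list(state = sv, undiagnosed_reference = undiagnosed_reference,
       cost = one_off + annual, cost_discounted = d * (one_off + annual),
       effect = effect, effect_discounted = d * effect)
}

#' Run one strategy through the Markov cohort model
#'
#' Distributes the cohort with [initial_distribution()] and advances it in
#' one-year cycles to `end_age`, accumulating discounted cost and
#' discounted years lived in the diagnosed state.
#'
#' @param params A `model_parameters` object.
#' @param strategy A [strategy_definition()].
#' @param life_table A `life_table`; defaults to the synthetic table.
#' @param trace Keep the per-cycle trace? Disable inside tight loops
#'   (e.g. probabilistic analysis) where only the totals matter.
#' @return An object of class `strategy_result`: totals (per cohort, i.e.
#'   per `cohort_size` children screened) plus a per-cycle `trace` data
#'   frame (`NULL` when `trace = FALSE`).
#' @examples
#' arms <- comparison_strategies("nst")
#' run_strategy(base_case("nst"), arms$no_screen)
#' @export
run_strategy <- function(params, strategy,
                         life_table = make_life_table(end_age = params$end_age),
                         trace = TRUE) {
  horizon <- params$end_age - strategy$model_start_age
  if (horizon <= 0) stop("'end_age' must exceed the model start age")
  sv <- initial_distribution(params, strategy)
  uref <- sv[["undiagnosed"]]
  rows <- if (trace) matrix(0, horizon, length(MODEL_STATES) + 6)
  total_cost <- total_effect <- total_cost_undisc <- total_effect_undisc <- 0
  for (cycle in 0:(horizon - 1)) {
    step <- advance_cycle(sv, cycle, params, strategy, life_table, uref)
    sv <- step$state
    uref <- step$undiagnosed_reference
    total_cost <- total_cost + step$cost_discounted
    total_effect <- total_effect + step$effect_discounted
    total_cost_undisc <- total_cost_undisc + step$cost
    total_effect_undisc <- total_effect_undisc + step$effect
    if (trace) {
      rows[cycle + 1, ] <- c(cycle, strategy$model_start_age + cycle, sv,
                             step$cost, step$cost_discounted, step$effect,
                             step$effect_discounted)
    }
  }
  if (trace) {
    rows <- as.data.frame(rows)
    names(rows) <- c("cycle", "age", MODEL_STATES, "cost", "cost_discounted",
                     "effect", "effect_discounted")
  }
  structure(list(strategy = strategy,
                 total_cost = unname(total_cost),
                 total_effect = unname(total_effect),
                 total_cost_undiscounted = unname(total_cost_undisc),
                 total_effect_undiscounted = unname(total_effect_undisc),
                 cohort_size = params$cohort_size,
                 trace = if (trace) rows),
            class = "strategy_result")
}

#' @export
print.strategy_result <- function(x, ...) {
  label <- if (x$strategy$kind == "screen") {
    sprintf("screen (%s)", x$strategy$tool$name)
  } else {
    "no screening"
  }
  cat(sprintf("Strategy: %s, per %g children\n", label, x$cohort_size))
  cat(sprintf("  discounted cost:            $%.2f\n", x$total_cost))
  cat(sprintf("  discounted diagnosed years: %.2f\n", x$total_effect))
  invisible(x)
}

check_conservation <- function(sv, cohort_size) {
  if (any(sv < -1e-9)) stop("internal error: negative state occupancy")
  if (abs(sum(sv) - cohort_size) > 1e-6 * max(1, cohort_size)) {
    stop("internal error: state occupancies do not sum to the cohort size")
  }
  invisible(sv)
}

#' Write a cycle trace to CSV
#'
#' @param result A `strategy_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(result, path) {
  utils::write.csv(result$trace, path, row.names = FALSE)
  invisible(path)
}
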