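#' Per-individual microsimulation of a strategy
#'
#' Simulates individuals one at a time through the same rules as the
#' cohort engine — true-status and screen-result draws, scheduled testing,
#' stochastic death and future-diagnosis conversion, half-cycle-corrected
#' cost and diagnosed-year accrual — and reports totals normalized to the
#' cohort size. Because every transition in the cohort model is linear in
#' occupancy, the microsimulation's expectation equals the cohort model's
#' output; it serves as an independent Monte-Carlo check of the engine.
#'
#' @param params A `model_parameters` object.
#' @param strategy A [strategy_definition()].
#' @param life_table A `life_table`.
#' @param n_individuals Number of simulated individuals.
#' @param seed Integer seed.
#' @param stratify_prevalence Assign exactly `round(n_individuals *
#'   prevalence)` individuals FASD status instead of drawing it, removing
#'   prevalence sampling noise (useful for degenerate exact-match checks).
#' @return An object of class `microsim_result`: `total_cost` and
#'   `total_effect` (normalized per `cohort_size`), their Monte-Carlo
#'   standard errors `se_cost` and `se_effect`, and `n_individuals`.
#' @export
microsimulate <- function(params, strategy,
                          life_table = make_life_table(end_age = params$end_age),
                          n_individuals = 10000, seed = 20190101,
                          stratify_prevalence = FALSE) {
  if (n_individuals < 1) stop("'n_individuals' must be >= 1")
  set.seed(seed)
  opts <- params$options
  costs <- modelling_costs(params)
  horizon <- params$end_age - strategy$model_start_age
  if (horizon <= 0) stop("'end_age' must exceed the model start age")
  n <- n_individuals

  PF <- 1L; UD <- 2L; DG <- 3L; PN <- 4L; NF <- 5L; DE <- 6L
  fasd <- if (stratify_prevalence) {
    k <- round(n * params$prevalence)
    sample(rep(c(TRUE, FALSE), c(k, n - k)))
  } else {
    stats::runif(n) < params$prevalence
  }
  state <- integer(n)
  if (strategy$kind == "screen") {
    pos <- ifelse(fasd, stats::runif(n) < strategy$tool$sensitivity,
                  stats::runif(n) >= strategy$tool$specificity)
    state[fasd & pos] <- PF
    state[fasd & !pos] <- UD
    state[!fasd & pos] <- PN
    state[!fasd & !pos] <- NF
  } else {
    state[fasd] <- PF
    state[!fasd] <- PN
  }

  # For the uniform conversion-time variant: cycle offset (from the first
  # conversion-eligible cycle) at which each person would convert, drawn so
  # that a fraction rho of the original pool converts per cycle.
  rho <- params$future_diagnosis_rate
  conv_from <- strategy$testing_age +
    (opts$conversion_start == "after_testing")
  if (opts$future_diagnosis_model == "uniform" && rho > 0) {
    conv_offset <- floor(stats::runif(n) / rho)
  }

  annual_cost <- c(switch(opts$pending_fasd_cost,
                          undiagnosed = costs$undiagnosed_annual,
                          no_fasd = costs$no_fasd_annual,
                          diagnosed = costs$diagnosed_annual),
                   costs$undiagnosed_annual, costs$diagnosed_annual,
                   costs$no_fasd_annual, costs$no_fasd_annual, 0)
  rescreen <- if (strategy$kind == "screen") strategy$tool$unit_cost else 0

  cost <- numeric(n)
  effect <- numeric(n)
  for (cycle in 0:(horizon - 1)) {
    age <- strategy$model_start_age + cycle
    d <- discount_factor(cycle, params$discount_rate)
    s0 <- state
    if (strategy$kind == "screen" && cycle == 0) {
      cost <- cost + d * costs$screening
    }
    q <- lookup_qx(life_table, age)
    qs <- c(state_mortality(q, "pending_fasd", params$mortality),
            state_mortality(q, "undiagnosed", params$mortality),
            state_mortality(q, "diagnosed", params$mortality),
            state_mortality(q, "pending_no_fasd", params$mortality),
            state_mortality(q, "no_fasd", params$mortality), 0)
    dies <- stats::runif(n) < qs[state]
    state[dies] <- DE
    if (age == strategy$testing_age) {
      tested <- state == PF | state == PN
      cost[tested] <- cost[tested] + d * costs$diagnostic_testing
      pf <- state == PF
      found <- pf & (stats::runif(n) < params$diagnostic_sensitivity)
      state[found] <- DG
      state[pf & !found] <- UD
      state[state == PN] <- NF
    }
    if (age >= conv_from && rho > 0) {
      ud <- state == UD
      converts <- if (opts$future_diagnosis_model == "hazard") {
        ud & (stats::runif(n) < rho)
      } else {
        ud & (conv_offset == age - conv_from)
      }
      state[converts] <- DG
      cost[converts] <- cost[converts] +
        d * (rescreen + costs$diagnostic_testing)
    }
    w1 <- if (opts$half_cycle == "trapezoid") 0.5 else 1
    w0 <- 1 - w1
    if (strategy$model_start_age == 0 && cycle == 0) {
      alive_frac <- w0 * (s0 != DE) + w1 * (state != DE)
      cost <- cost + d * costs$first_year * alive_frac
    } else {
      cost <- cost + d * (w0 * annual_cost[s0] + w1 * annual_cost[state])
    }
    effect <- effect + d * (w0 * (s0 == DG) + w1 * (state == DG))
  }

  scale <- params$cohort_size
  structure(list(total_cost = mean(cost) * scale,
                 total_effect = mean(effect) * scale,
                 se_cost = stats::sd(cost) / sqrt(n) * scale,
                 se_effect = stats::sd(effect) / sqrt(n) * scale,
                 n_individuals = n, cohort_size = scale),
            class = "microsim_result")
}

#' @export
print.microsim_result <- function(x, ...) {
  cat(sprintf("Microsimulation (%d individuals, per %g children)\n",
              x$n_individuals, x$cohort_size))
  cat(sprintf("  discounted cost:            $%.2f (MC SE %.2f)\n",
              x$total_cost, x$se_cost))
  cat(sprintf("  discounted diagnosed years: %.3f (MC SE %.3f)\n",
              x$total_effect, x$se_effect))
  invisible(x)
}
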