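test_that("the decision tree reproduces hand-computed initial occupancies", {
  p <- base_case("meconium")
  arms <- comparison_strategies("meconium", p)
  sv <- initial_distribution(p, arms$screen)
  expect_equal(sv[["pending_fasd"]], 66.3 * 0.924)
  expect_equal(sv[["undiagnosed"]], 66.3 * 0.076)
  expect_equal(sv[["pending_no_fasd"]], 33.7 * 0.485)
  expect_equal(sv[["no_fasd"]], 33.7 * 0.515)
  expect_equal(sum(sv), 100)

  ns <- initial_distribution(p, arms$no_screen)
  expect_equal(ns[["pending_fasd"]], 66.3)
  expect_equal(ns[["pending_no_fasd"]], 33.7)

  p$tool$sensitivity <- 1
  p$tool$specificity <- 1
  perfect <- initial_distribution(p, comparison_strategies("meconium", p)$screen)
  expect_equal(perfect[["undiagnosed"]], 0)
  expect_equal(perfect[["pending_no_fasd"]], 0)
})

test_that("state-specific mortality scales the background rate by the SMR", {
  m <- mortality_params()
  expect_equal(state_mortality(3e-4, "diagnosed", m), 3e-4 * 3.15)
  expect_equal(state_mortality(3e-4, "pending_fasd", m), 3e-4 * 3.15)
  expect_equal(state_mortality(3e-4, "undiagnosed", m), 3e-4 * 3.15 * 1.10)
  expect_equal(state_mortality(0, "no_fasd", m), 0)
  expect_equal(state_mortality(0.5, "diagnosed", m), 1) # capped
  expect_equal(state_mortality(0.1, "dead", m), 0)
})

test_that("the discount weight is evaluated mid-cycle", {
  expect_equal(discount_factor(0, 0.015), 1.015^-0.5)
  expect_equal(round(discount_factor(0, 0.015), 5), 0.99258)
  expect_equal(round(discount_factor(12, 0.015), 4), 0.8302)
  expect_equal(discount_factor(7, 0), 1)
})

test_that("future-diagnosis conversion carries the expected one-off cost", {
  p <- base_case("meconium")
  strat <- comparison_strategies("meconium", p)$screen
  lt0 <- make_life_table(0, 0)
  sv <- setNames(numeric(6), c("pending_fasd", "undiagnosed", "diagnosed",
                               "pending_no_fasd", "no_fasd", "dead"))
  sv["undiagnosed"] <- 10
  sv["no_fasd"] <- 90
  cycle <- 8 # age 8, past the testing age, zero mortality
  step <- advance_cycle(sv, cycle, p, strat, lt0)
  expect_equal(step$state[["undiagnosed"]], 9.5)
  expect_equal(step$state[["diagnosed"]], 0.5)
  cm <- modelling_costs(p)
  one_off <- 0.5 * (cm$screening + cm$diagnostic_testing)
  annual <- 9.75 * cm$undiagnosed_annual + 0.25 * cm$diagnosed_annual +
    90 * cm$no_fasd_annual
  expect_equal(step$cost, one_off + annual)
  expect_equal(step$cost_discounted, step$cost * discount_factor(cycle, 0.015))
  expect_equal(step$effect, 0.25) # cycle-average of 0 and 0.5
})

test_that("an all-dead cohort accrues nothing and stays dead", {
  p <- base_case("meconium")
  strat <- comparison_strategies("meconium", p)$no_screen
  sv <- setNames(c(0, 0, 0, 0, 0, 100),
                 c("pending_fasd", "undiagnosed", "diagnosed",
                   "pending_no_fasd", "no_fasd", "dead"))
  step <- advance_cycle(sv, 3, p, strat)
  expect_equal(step$state, sv)
  expect_equal(step$cost, 0)
  expect_equal(step$effect, 0)
})

test_that("occupancies are conserved every cycle in both arms", {
  for (seed in 1:4) {
    for (comparison in c("meconium", "nst")) {
      p <- random_params(seed, comparison)
      res <- run_both_arms(p, comparison)
      for (r in res) {
        sums <- rowSums(r$trace[, c("pending_fasd", "undiagnosed",
                                    "diagnosed", "pending_no_fasd",
                                    "no_fasd", "dead")])
        expect_equal(sums, rep(100, nrow(r$trace)), tolerance = 1e-9)
      }
    }
  }
})

test_that("diagnostic testing is charged once per tested person", {
  # Zero out everything except the testing cost; the undiscounted total is
  # then exactly (persons ever tested) x unit test cost.
  p <- base_case("meconium")
  p$costs <- cost_set(0, 0, 0, 0, diagnostic_testing = 3870)
  p$tool$unit_cost <- 0
  p$future_diagnosis_rate <- 0
  lt0 <- make_life_table(0, 0)
  res <- run_both_arms(p, "meconium", lt0)
  tested_screen <- 66.3 * 0.924 + 33.7 * 0.485
  expect_equal(res$screen$total_cost_undiscounted, 3870 * tested_screen)
  expect_equal(res$no_screen$total_cost_undiscounted, 3870 * 100)
})

test_that("no-screen diagnosed years match the closed form without mortality or discounting", {
  lt0 <- make_life_table(0, 0)
  for (comparison in c("meconium", "nst")) {
    p <- base_case(comparison)
    p$discount_rate <- 0
    years <- p$end_age - (p$tool$screen_age + p$tool$lag_to_testing)
    ns <- comparison_strategies(comparison, p)$no_screen

    p$options$half_cycle <- "midcycle"
    expect_equal(run_strategy(p, ns, lt0)$total_effect, 66.3 * years)

    # under cycle-average accrual the diagnosis cycle contributes half
    p$options$half_cycle <- "trapezoid"
    expect_equal(run_strategy(p, ns, lt0)$total_effect, 66.3 * (years - 0.5))
  }
})

test_that("a perfect free screen makes the arms equivalent", {
  for (comparison in c("meconium", "nst")) {
    p <- base_case(comparison)
    p$tool$sensitivity <- 1
    p$tool$specificity <- 1
    p$tool$unit_cost <- 0
    res <- run_both_arms(p, comparison)
    # identical diagnosed-year streams regardless of costs
    expect_equal(res$screen$total_effect, res$no_screen$total_effect,
                 tolerance = 1e-12)
    # the only cost difference is the rule-out testing the screen arm
    # avoids for true negatives
    testing_cycle <- p$tool$screen_age + p$tool$lag_to_testing -
      p$tool$screen_age
    survival <- res$no_screen$trace$pending_no_fasd[testing_cycle + 1] +
      res$no_screen$trace$no_fasd[testing_cycle + 1]
    avoided <- survival * modelling_costs(p)$diagnostic_testing *
      discount_factor(testing_cycle, p$discount_rate)
    expect_equal(res$no_screen$total_cost - res$screen$total_cost, avoided,
                 tolerance = 1e-9)
    # with free testing as well, the arms are exactly identical
    p$costs$diagnostic_testing <- 0
    res <- run_both_arms(p, comparison)
    expect_equal(res$screen$total_cost, res$no_screen$total_cost,
                 tolerance = 1e-12)
  }
})

test_that("totals respond monotonically to rates and accuracy", {
  base <- base_case("meconium")
  arms <- comparison_strategies("meconium", base)
  run_at <- function(mod) {
    p <- base
    p <- mod(p)
    run_strategy(p, comparison_strategies("meconium", p)$screen)
  }
  r_lo <- run_at(function(p) { p$discount_rate <- 0.01; p })
  r_hi <- run_at(function(p) { p$discount_rate <- 0.05; p })
  expect_lt(r_hi$total_cost, r_lo$total_cost)
  expect_lt(r_hi$total_effect, r_lo$total_effect)

  se_lo <- run_at(function(p) { p$tool$sensitivity <- 0.7; p })
  se_hi <- run_at(function(p) { p$tool$sensitivity <- 0.99; p })
  expect_gt(se_hi$total_effect, se_lo$total_effect)

  sp_lo <- run_at(function(p) { p$tool$specificity <- 0.4; p })
  sp_hi <- run_at(function(p) { p$tool$specificity <- 0.9; p })
  expect_lt(sp_hi$total_cost, sp_lo$total_cost)
})

test_that("imperfect diagnostic testing diverts cases to the undiagnosed state", {
  p <- base_case("nst")
  p$diagnostic_sensitivity <- 0.8
  lt0 <- make_life_table(0, 0)
  res <- run_both_arms(p, "nst", lt0)
  tr <- res$no_screen$trace
  # end of the testing cycle: 80% found by testing, plus the cycle's
  # future-diagnosis conversion of the 20% it missed
  expect_equal(tr$undiagnosed[1] + tr$diagnosed[1], 66.3)
  expect_equal(tr$diagnosed[1], 66.3 * 0.8 + 0.05 * 66.3 * 0.2)
  expect_lt(res$no_screen$total_effect, 66.3 * 13)
})

test_that("strategy results print their totals", {
  res <- run_strategy(base_case("nst"),
                      comparison_strategies("nst")$no_screen)
  expect_output(print(res), "no screening")
  expect_output(print(res), "diagnosed years")
})
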