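# Shared fixtures for the test suite. Everything is generated in code; the
# only data files are the published accuracy tables in inst/extdata.

# Published Table 4-scale anchors used by the acceptance tests.
published <- list(
  meconium = list(delta_cost = -89186.04, delta_effect = -37.80,
                  icer = 2359.15),
  nst = list(delta_cost = -183894.98, delta_effect = -76.95,
             icer = 2389.86),
  pooled = c(meconium_se = 0.924, meconium_sp = 0.515,
             nst_se = 0.859, nst_sp = 0.729),
  icer_r0 = c(meconium = 2256, nst = 2253),
  icer_r3 = c(meconium = 2459, nst = 2531))

# A randomized but valid parameter set for property-style tests.
random_params <- function(seed, comparison = "meconium") {
  set.seed(seed)
  tool <- default_tool(comparison)
  tool$sensitivity <- runif(1, 0.6, 0.99)
  tool$specificity <- runif(1, 0.3, 0.99)
  tool$unit_cost <- runif(1, 10, 400)
  model_parameters(
    prevalence = runif(1, 0.3, 0.9),
    tool = tool,
    costs = cost_set(first_year = runif(1, 8000, 25000),
                     diagnosed_annual = runif(1, 3000, 6000),
                     undiagnosed_annual = runif(1, 1500, 3000),
                     no_fasd_annual = runif(1, 1000, 3000),
                     diagnostic_testing = runif(1, 2000, 6000)),
    mortality = mortality_params(runif(1, 1, 5), runif(1, 1, 1.2),
                                 runif(1, 1, 5)),
    discount_rate = runif(1, 0, 0.05),
    future_diagnosis_rate = runif(1, 0.01, 0.1))
}

run_both_arms <- function(params, comparison,
                          life_table = make_life_table(end_age = params$end_age)) {
  arms <- comparison_strategies(comparison, params)
  list(no_screen = run_strategy(params, arms$no_screen, life_table),
       screen = run_strategy(params, arms$screen, life_table))
}
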