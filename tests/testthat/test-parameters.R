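test_that("the inflation factor is recovered from the printed cost pairs", {
  f <- derive_inflation_factor()
  expect_lt(abs(f - 1.2685), 5e-4)
  expect_equal(derive_inflation_factor(cbind(100, 100)), 1.0)
  expect_lt(abs(derive_inflation_factor(cbind(2713, 3441)) - 3441 / 2713),
            1e-12)
  # per-pair ratios of the printed pairs agree within 0.1%
  pairs <- printed_cost_pairs()
  ratios <- pairs[, 2] / pairs[, 1]
  expect_lt(max(ratios) / min(ratios) - 1, 0.001)
  expect_warning(derive_inflation_factor(cbind(c(1, 1), c(1, 1.5))),
                 "differ")
})

test_that("inflation reproduces the published 2017-CAD costs", {
  f <- derive_inflation_factor()
  expect_equal(round(inflate(3426, f)), 4346)
  expect_equal(round(inflate(15976, f)), 20265)
  expect_equal(round(inflate(2713, f)), 3441)
  expect_equal(inflate(123.45, 1), 123.45)
  expect_error(inflate(-1, 1.2), "non-negative")
  expect_error(inflate(100, 0), "positive")
})

test_that("constructors enforce their invariants", {
  expect_error(tool_profile("meconium", 1.2, 0.5, 175, 0, 5), "\\[0, 1\\]")
  expect_error(tool_profile("meconium", 0.9, 0.5, -1, 0, 5), ">= 0")
  expect_error(cost_set(diagnosed_annual = -5), ">= 0")
  expect_error(cost_set(first_year = 1000, diagnosed_annual = 3426,
                        basis = "inflated_2017"), "first_year")
  expect_error(mortality_params(undiagnosed_multiplier = 0.9), ">= 1")
  expect_error(model_parameters(prevalence = 0), "prevalence")
  expect_error(model_parameters(discount_rate = -0.01), "discount_rate")
})

test_that("base-case parameters carry the published values", {
  p <- base_case("meconium")
  expect_equal(p$prevalence, 0.663)
  expect_equal(p$discount_rate, 0.015)
  expect_equal(p$future_diagnosis_rate, 0.05)
  expect_equal(p$end_age, 18)
  expect_equal(p$tool$sensitivity, 0.924)
  expect_equal(p$tool$screen_age, 0)
  expect_equal(p$tool$lag_to_testing, 5)
  n <- base_case("nst")
  expect_equal(n$tool$screen_age, 5)
  expect_equal(n$tool$lag_to_testing, 0)
  expect_equal(n$tool$unit_cost, 20)
})

test_that("modelling costs are normalized to inflated 2017 CAD", {
  p <- base_case("meconium")
  cm <- modelling_costs(p)
  expect_equal(round(cm$diagnosed_annual), 4346)
  expect_equal(round(cm$first_year), 20265)
  expect_equal(round(cm$undiagnosed_annual), 3441)
  expect_equal(cm$diagnostic_testing, 3870) # already a 2017 value
  expect_equal(cm$screening, 175)
  # switching off no-FASD inflation leaves it at its printed value
  p$options$inflate_no_fasd <- FALSE
  expect_equal(modelling_costs(p)$no_fasd_annual, 3101)
  # pre-inflation modelling basis
  p$options$use_inflated_costs <- FALSE
  expect_equal(modelling_costs(p)$diagnosed_annual, 3426)
})

test_that("configuration files round-trip and validate", {
  path <- withr::local_tempfile(fileext = ".yaml")
  p <- base_case("nst")
  p$discount_rate <- 0.03
  p$tool$sensitivity <- 0.9
  write_parameters(p, path)
  q <- load_parameters(path)
  expect_equal(unclass(q)[names(unclass(q))], unclass(p)[names(unclass(p))],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(attr(q, "comparison"), "nst")
})

test_that("empty and partial configurations fall back to the base case", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines("", path)
  p <- load_parameters(path, "meconium")
  expect_equal(p$prevalence, 0.663)
  expect_equal(p$discount_rate, 0.015)

  writeLines("cohort:\n  prevalence: 0.5\n", path)
  p <- load_parameters(path, "meconium")
  expect_equal(p$prevalence, 0.5)
  expect_equal(p$future_diagnosis_rate, 0.05) # omitted key -> base case
})

test_that("bad configurations fail with named errors", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines("tool:\n  sensitivity: 1.2\n", path)
  expect_error(load_parameters(path), "sensitivity")

  writeLines("cohort:\n  prevalnce: 0.5\n", path)
  expect_error(load_parameters(path), "prevalnce")

  writeLines("nonsense_section:\n  a: 1\n", path)
  expect_error(load_parameters(path), "nonsense_section")

  writeLines("cohort: [1, 2", path)
  expect_error(load_parameters(path), "parse")
})
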