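test_that("sampled values respect their family's support and moments", {
  set.seed(99)
  n <- 1e5

  b <- sample_parameter(dist_spec("beta", 0.663, 0.014), n)
  expect_lt(abs(mean(b) - 0.663), 0.001)
  expect_lt(abs(sd(b) - 0.014), 0.001)
  expect_true(all(b > 0 & b < 1))

  u <- sample_parameter(dist_spec("uniform", 0.05, lower = 0.03,
                                  upper = 0.07), n)
  expect_true(all(u >= 0.03 & u <= 0.07))
  expect_lt(abs(mean(u) - 0.05), 0.001)

  nb <- sample_parameter(dist_spec("normal_bounded", 175, 17.5,
                                   131.25, 218.75), n)
  expect_true(all(nb >= 131.25 & nb <= 218.75))
  expect_lt(abs(mean(nb) - 175), 1)

  ln <- sample_parameter(dist_spec("log_normal", 3426, 342.6), n)
  expect_true(all(ln > 0))
  expect_lt(abs(mean(ln) - 3426), 5)
  expect_lt(abs(sd(ln) - 342.6), 5)

  tn <- sample_parameter(dist_spec("truncated_normal", 3.15, 1.6, lower = 1), n)
  expect_true(all(tn >= 1))

  expect_equal(sample_parameter(dist_spec("fixed", 0.42), 3), rep(0.42, 3))
})

test_that("infeasible distribution specifications are rejected by name", {
  expect_error(dist_spec("beta", 0.5, 0.6), "infeasible beta")
  expect_error(dist_spec("uniform", 1, lower = 2, upper = 1), "lower < upper")
})

test_that("PSA runs are reproducible and collapse to the base case when fixed", {
  p <- base_case("nst")
  a <- run_psa(p, "nst", n_draws = 20, seed = 123)
  b <- run_psa(p, "nst", n_draws = 20, seed = 123)
  expect_identical(a$delta_cost, b$delta_cost)
  c <- run_psa(p, "nst", n_draws = 20, seed = 124)
  expect_false(identical(a$delta_cost, c$delta_cost))
})

test_that("PSA deltas are centred near the deterministic deltas", {
  p <- base_case("nst")
  psa <- run_psa(p, "nst", n_draws = 400, seed = 42)
  res <- run_both_arms(p, "nst")
  det <- compare_strategies(res$no_screen, res$screen)
  se <- sd(psa$delta_cost) / sqrt(nrow(psa))
  expect_lt(abs(mean(psa$delta_cost) - det$delta_cost), 4 * se)
  # quadrant counts cover all draws
  expect_equal(sum(cep(psa)$quadrant_counts), nrow(psa))
})

test_that("the acceptability curve steps at the draws' savings ratios", {
  sw <- data.frame(delta_cost = rep(-89186.04, 5),
                   delta_effect = rep(-37.80, 5))
  curve <- ceac(sw, c(1000, 2359, 3000))
  expect_equal(curve$probability, c(1, 1, 0))

  dominant <- data.frame(delta_cost = -100, delta_effect = 5)
  expect_equal(ceac(dominant, c(0, 1e6))$probability, c(1, 1))

  dominated <- data.frame(delta_cost = 100, delta_effect = -5)
  expect_equal(ceac(dominated, c(0, 1e6))$probability, c(0, 0))
})

test_that("the curve is monotone non-increasing for a south-west draw cloud", {
  set.seed(7)
  cloud <- data.frame(delta_cost = -runif(500, 5e4, 2e5),
                      delta_effect = -runif(500, 20, 90))
  curve <- ceac(cloud, seq(0, 6000, by = 250))
  expect_true(all(diff(curve$probability) <= 0))
  expect_true(all(curve$probability >= 0 & curve$probability <= 1))
})

test_that("one-way analysis ranks parameters and ignores inert ones", {
  tw <- one_way(comparison = "nst")
  expect_true(all(diff(tw$range) <= 0))
  expect_equal(tw$parameter[1], "sensitivity")
  # the first-year-of-life cost plays no role in a model starting at age 5
  expect_equal(tw$range[tw$parameter == "first_year"], 0)
  expect_error(one_way(comparison = "nst", parameters = "no_such_knob"),
               "unknown one-way parameter")
})

test_that("tornado output is deterministic", {
  a <- one_way(comparison = "meconium",
               parameters = c("specificity", "screening_cost"))
  b <- one_way(comparison = "meconium",
               parameters = c("specificity", "screening_cost"))
  expect_identical(a, b)
})

test_that("discount scenarios bracket the base case consistently", {
  sc <- discount_scenarios(comparison = "meconium", rates = c(0, 0.015, 0.03))
  res <- run_both_arms(base_case("meconium"), "meconium")
  base <- compare_strategies(res$no_screen, res$screen)
  expect_equal(sc$icer[sc$rate == 0.015], base$icer, tolerance = 1e-12)
  # a higher discount rate shrinks both deltas but raises this ICER
  expect_true(all(diff(sc$icer) > 0))
  expect_true(all(diff(abs(sc$delta_cost)) < 0))
})

test_that("PSA draws sampled on the pre-inflation basis are inflated in the model", {
  p <- base_case("meconium")
  psa <- run_psa(p, "meconium", n_draws = 50, seed = 9)
  # sampled diagnosed cost is pre-inflation scale (mean 3426, not 4346)
  expect_lt(abs(mean(psa$diagnosed_annual) - 3426), 200)
  expect_true(all(psa$undiagnosed_psych_rate <= psa$diagnosed_psych_rate))
})
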