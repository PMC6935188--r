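#' Distribution specification for probabilistic analysis
#'
#' @param family One of `"beta"` (moment-matched to mean/sd),
#'   `"normal_bounded"` (normal resampled until inside `[lower, upper]`),
#'   `"log_normal"` (moment-matched), `"uniform"`, `"truncated_normal"`
#'   (normal resampled until at least `lower`) or `"fixed"`.
#' @param mean,sd Location and scale (as applicable).
#' @param lower,upper Bounds (as applicable).
#' @return An object of class `dist_spec`.
#' @export
dist_spec <- function(family = c("beta", "normal_bounded", "log_normal",
                                 "uniform", "truncated_normal", "fixed"),
                      mean = NA_real_, sd = NA_real_,
                      lower = NA_real_, upper = NA_real_) {
  family <- match.arg(family)
  if (family == "beta") {
    if (sd^2 >= mean * (1 - mean)) {
      stop(sprintf("infeasible beta: sd^2 = %.4g >= mean*(1-mean) = %.4g",
                   sd^2, mean * (1 - mean)))
    }
  }
  if (family %in% c("uniform", "normal_bounded") && !(lower < upper)) {
    stop("bounded families require lower < upper")
  }
  structure(list(family = family, mean = mean, sd = sd,
                 lower = lower, upper = upper),
            class = "dist_spec")
}

#' Sample from a distribution specification
#'
#' Beta draws are moment-matched (`nu = m(1-m)/s^2 - 1`, `alpha = m nu`,
#' `beta = (1-m) nu`); log-normal draws are moment-matched on the natural
#' scale; bounded and truncated normals use rejection sampling (never
#' clipping, which would pile mass on the bounds and shift the mean).
#' Draws come from R's global RNG stream, so a single `set.seed()` before a
#' sampling run makes the whole draw sequence reproducible.
#'
#' @param spec A [dist_spec()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_parameter <- function(spec, n = 1) {
  stopifnot(inherits(spec, "dist_spec"))
  m <- spec$mean
  s <- spec$sd
  switch(spec$family,
    fixed = rep(m, n),
    beta = {
      nu <- m * (1 - m) / s^2 - 1
      stats::rbeta(n, m * nu, (1 - m) * nu)
    },
    log_normal = {
      sigma2 <- log(1 + (s / m)^2)
      stats::rlnorm(n, log(m) - sigma2 / 2, sqrt(sigma2))
    },
    uniform = stats::runif(n, spec$lower, spec$upper),
    normal_bounded = resample(n, function(k) stats::rnorm(k, m, s),
                              function(x) x >= spec$lower & x <= spec$upper),
    truncated_normal = resample(n, function(k) stats::rnorm(k, m, s),
                                function(x) x >= spec$lower))
}

resample <- function(n, draw, keep) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- draw(n)
    out <- c(out, x[keep(x)])
  }
  out[seq_len(n)]
}

#' Probabilistic distributions for one comparison
#'
#' The full set of sampled parameters: beta for proportions (prevalence,
#' tool accuracy, psychiatric-recommendation rates), bounded normals
#' (+/-25% of the mean, SD 10% of the mean) for screening and
#' diagnostic-testing costs, log-normals (SD 10% of the mean) for the
#' experimental annual costs on their pre-inflation basis, uniform 3-7% for
#' the future-diagnosis rate and 1.0-1.2 for the undiagnosed mortality
#' multiplier, and SMR normals truncated below at 1 (mortality cannot be
#' better than the general population; the no-FASD SMR's SD is the
#' diagnosed SD inflated by 1.25). The undiagnosed annual cost is not
#' sampled directly: each draw recomputes it from the sampled
#' recommendation rates via [undiagnosed_annual_cost()]. The no-FASD annual
#' cost is not varied.
#'
#' @param params A `model_parameters` object supplying the means.
#' @return Named list of [dist_spec()] objects.
#' @export
psa_distributions <- function(params) {
  tool <- params$tool
  cs <- params$costs
  list(
    prevalence = dist_spec("beta", 0.663, 0.014),
    sensitivity = dist_spec("beta", tool$sensitivity,
                            if (tool$name == "meconium") 0.081 else 0.055),
    specificity = dist_spec("beta", tool$specificity,
                            if (tool$name == "meconium") 0.197 else 0.107),
    screening_cost = dist_spec("normal_bounded", tool$unit_cost,
                               0.1 * tool$unit_cost,
                               0.75 * tool$unit_cost, 1.25 * tool$unit_cost),
    diagnostic_testing = dist_spec("normal_bounded", cs$diagnostic_testing,
                                   0.1 * cs$diagnostic_testing,
                                   0.75 * cs$diagnostic_testing,
                                   1.25 * cs$diagnostic_testing),
    first_year = dist_spec("log_normal", cs$first_year, 0.1 * cs$first_year),
    diagnosed_annual = dist_spec("log_normal", cs$diagnosed_annual,
                                 0.1 * cs$diagnosed_annual),
    diagnosed_psych_rate = dist_spec("beta", 0.556, 0.073),
    undiagnosed_psych_rate = dist_spec("beta", 0.330, 0.147),
    future_diagnosis_rate = dist_spec("uniform", 0.05, lower = 0.03,
                                      upper = 0.07),
    undiagnosed_multiplier = dist_spec("uniform", 1.10, lower = 1.0,
                                       upper = 1.2),
    smr_diagnosed = dist_spec("truncated_normal", 3.15, 1.6, lower = 1),
    smr_no_fasd = dist_spec("truncated_normal", 3.15, 1.6 * 1.25, lower = 1))
}

# Build a full parameter set from one row of sampled values. Annual costs
# are sampled on the pre-inflation basis and inflated afterwards, matching
# how the published analysis varied them.
params_from_draw <- function(params, draw) {
  undiag <- undiagnosed_annual_cost(draw$diagnosed_annual,
                                    draw$diagnosed_psych_rate,
                                    draw$undiagnosed_psych_rate)
  tool <- params$tool
  tool$sensitivity <- draw$sensitivity
  tool$specificity <- draw$specificity
  tool$unit_cost <- draw$screening_cost
  model_parameters(
    cohort_size = params$cohort_size,
    prevalence = draw$prevalence,
    tool = tool,
    costs = cost_set(first_year = draw$first_year,
                     diagnosed_annual = draw$diagnosed_annual,
                     undiagnosed_annual = undiag,
                     no_fasd_annual = params$costs$no_fasd_annual,
                     diagnostic_testing = draw$diagnostic_testing,
                     basis = "pre_inflation"),
    mortality = mortality_params(draw$smr_diagnosed,
                                 draw$undiagnosed_multiplier,
                                 draw$smr_no_fasd),
    discount_rate = params$discount_rate,
    end_age = params$end_age,
    future_diagnosis_rate = draw$future_diagnosis_rate,
    diagnostic_sensitivity = params$diagnostic_sensitivity,
    inflation_factor = params$inflation_factor,
    options = params$options)
}

#' Probabilistic sensitivity analysis
#'
#' Samples every varied parameter independently from its
#' [psa_distributions()] entry, rebuilds the model, runs both arms and
#' records the incremental cost and effectiveness of screening. Draws whose
#' sampled undiagnosed annual cost exceeds the diagnosed annual cost (the
#' recommendation-rate betas can cross) fail validation and are resampled;
#' the count is recorded in attribute `n_resampled`.
#'
#' @param params Base-case `model_parameters`.
#' @param comparison `"meconium"` or `"nst"`.
#' @param n_draws Number of retained draws (published analysis: 5000).
#' @param seed Integer seed for the single RNG stream.
#' @param life_table Optional `life_table`.
#' @return Data frame of class `psa_result` with the sampled parameters and
#'   columns `delta_cost`, `delta_effect`, `icer`, `quadrant`.
#' @export
run_psa <- function(params = base_case(comparison),
                    comparison = c("meconium", "nst"), n_draws = 5000,
                    seed = 20190101,
                    life_table = make_life_table(end_age = params$end_age)) {
  comparison <- match.arg(comparison)
  if (n_draws < 1) stop("'n_draws' must be >= 1")
  specs <- psa_distributions(params)
  set.seed(seed)
  rows <- vector("list", n_draws)
  n_resampled <- 0L
  for (i in seq_len(n_draws)) {
    repeat {
      draw <- lapply(specs, sample_parameter)
      if (draw$undiagnosed_psych_rate <= draw$diagnosed_psych_rate) break
      n_resampled <- n_resampled + 1L
    }
    draw_params <- params_from_draw(params, draw)
    arms_i <- comparison_strategies(comparison, draw_params)
    ns <- run_strategy(draw_params, arms_i$no_screen, life_table,
                       trace = FALSE)
    sc <- run_strategy(draw_params, arms_i$screen, life_table, trace = FALSE)
    res <- icer_point(sc$total_cost - ns$total_cost,
                      sc$total_effect - ns$total_effect)
    rows[[i]] <- data.frame(draw, delta_cost = res$delta_cost,
                            delta_effect = res$delta_effect,
                            icer = res$icer, quadrant = res$quadrant)
  }
  out <- do.call(rbind, rows)
  attr(out, "comparison") <- comparison
  attr(out, "seed") <- seed
  attr(out, "n_resampled") <- n_resampled
  class(out) <- c("psa_result", "data.frame")
  out
}

# Is a (delta_cost, delta_effect) draw acceptable at willingness-to-accept
# lambda? Screening here forgoes diagnosed years in exchange for savings,
# so a south-west draw is acceptable when its savings per diagnosed year
# forgone are at least lambda; a dominant (south-east) draw always is; a
# dominated (north-west) draw never is; a north-east draw is judged as a
# conventional willingness-to-pay ratio.
acceptable_at <- function(dc, de, lambda) {
  ifelse(de < 0 & dc < 0, dc / de >= lambda,
    ifelse(de >= 0 & dc <= 0, TRUE,
      ifelse(de <= 0, FALSE, dc / de <= lambda)))
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-accept (WTA) threshold, the fraction of PSA
#' draws in which screening is acceptable. Because screening saves money
#' and forgoes diagnosed years (south-west quadrant), acceptability means
#' the draw's savings per diagnosed year forgone meet the threshold, and
#' the curve is non-increasing in WTA — higher compensation demanded per
#' forgone diagnosed year makes screening harder to justify. This is the
#' mirror image of a textbook willingness-to-pay CEAC and matches the
#' published curve's direction.
#'
#' @param psa A `psa_result`.
#' @param wta_grid Thresholds (currency per diagnosed year).
#' @return Data frame of class `ceac_curve` with columns `wta` and
#'   `probability`.
#' @export
ceac <- function(psa, wta_grid = seq(0, 5000, by = 100)) {
  if (nrow(psa) < 1) stop("no PSA draws supplied")
  probability <- vapply(wta_grid, function(l) {
    mean(acceptable_at(psa$delta_cost, psa$delta_effect, l))
  }, numeric(1))
  structure(data.frame(wta = wta_grid, probability = probability),
            class = c("ceac_curve", "data.frame"))
}

#' Cost-effectiveness plane summary
#'
#' @param psa A `psa_result`.
#' @return List with the per-draw `points` (delta effect, delta cost,
#'   quadrant) and a `quadrant_counts` table summing to the number of
#'   draws.
#' @export
cep <- function(psa) {
  counts <- table(factor(psa$quadrant,
                         levels = c("NE", "NW", "SE", "SW", "on-axis")))
  list(points = psa[, c("delta_effect", "delta_cost", "quadrant")],
       quadrant_counts = counts)
}

ONE_WAY_PARAMETERS <- c("sensitivity", "specificity",
                        "diagnostic_sensitivity", "prevalence",
                        "diagnosed_annual", "undiagnosed_annual",
                        "first_year", "diagnostic_testing", "screening_cost",
                        "future_diagnosis_rate", "smr_diagnosed")

set_scalar_parameter <- function(params, name, value) {
  switch(name,
    sensitivity = {
      params$tool$sensitivity <- min(1, value)
      params
    },
    specificity = {
      params$tool$specificity <- min(1, value)
      params
    },
    diagnostic_sensitivity = {
      params$diagnostic_sensitivity <- min(1, value)
      params
    },
    prevalence = {
      params$prevalence <- min(1 - 1e-9, value)
      params
    },
    diagnosed_annual = {
      params$costs$diagnosed_annual <- value
      params
    },
    undiagnosed_annual = {
      params$costs$undiagnosed_annual <- value
      params
    },
    first_year = {
      params$costs$first_year <- value
      params
    },
    diagnostic_testing = {
      params$costs$diagnostic_testing <- value
      params
    },
    screening_cost = {
      params$tool$unit_cost <- value
      params
    },
    future_diagnosis_rate = {
      params$future_diagnosis_rate <- min(1, value)
      params
    },
    smr_diagnosed = {
      params$mortality$smr_diagnosed <- value
      params
    },
    stop(sprintf("unknown one-way parameter '%s'", name)))
}

get_scalar_parameter <- function(params, name) {
  switch(name,
    sensitivity = params$tool$sensitivity,
    specificity = params$tool$specificity,
    diagnostic_sensitivity = params$diagnostic_sensitivity,
    prevalence = params$prevalence,
    diagnosed_annual = params$costs$diagnosed_annual,
    undiagnosed_annual = params$costs$undiagnosed_annual,
    first_year = params$costs$first_year,
    diagnostic_testing = params$costs$diagnostic_testing,
    screening_cost = params$tool$unit_cost,
    future_diagnosis_rate = params$future_diagnosis_rate,
    smr_diagnosed = params$mortality$smr_diagnosed,
    stop(sprintf("unknown one-way parameter '%s'", name)))
}

# One-way endpoints can push the effectiveness difference to exactly zero
# (e.g. a sensitivity capped at 1 makes the screen arm forgo nothing while
# still saving testing costs); the ICER then grows without bound and the
# endpoint is recorded as a signed infinity rather than NA so that the
# tornado ranking reflects the unbounded range.
deterministic_icer <- function(params, comparison, life_table) {
  arms <- comparison_strategies(comparison, params)
  ns <- run_strategy(params, arms$no_screen, life_table, trace = FALSE)
  sc <- run_strategy(params, arms$screen, life_table, trace = FALSE)
  res <- compare_strategies(ns, sc)
  if (res$delta_effect == 0) {
    if (res$delta_cost == 0) 0 else sign(res$delta_cost) * Inf
  } else {
    res$icer
  }
}

#' One-way (tornado) sensitivity analysis
#'
#' Re-runs the deterministic comparison with each named parameter at 0.75x
#' and 1.25x its base value (proportions capped at 1), holding everything
#' else fixed, and ranks parameters by the width of the resulting ICER
#' range. Costs are varied on the basis stored in the parameter set
#' (pre-inflation in the base case) and inflated as usual.
#'
#' @param params Base-case `model_parameters`.
#' @param comparison `"meconium"` or `"nst"`.
#' @param parameters Character vector of parameter names (default: the
#'   published one-way set).
#' @param life_table Optional `life_table`.
#' @return Data frame of class `tornado`, sorted by `range` descending,
#'   with columns `parameter`, `low`, `high`, `icer_low`, `icer_high`,
#'   `range`.
#' @export
one_way <- function(params = base_case(comparison),
                    comparison = c("meconium", "nst"),
                    parameters = ONE_WAY_PARAMETERS,
                    life_table = make_life_table(end_age = params$end_age)) {
  comparison <- match.arg(comparison)
  rows <- lapply(parameters, function(name) {
    base <- get_scalar_parameter(params, name)
    lo <- 0.75 * base
    hi <- 1.25 * base
    icer_lo <- deterministic_icer(set_scalar_parameter(params, name, lo),
                                  comparison, life_table)
    icer_hi <- deterministic_icer(set_scalar_parameter(params, name, hi),
                                  comparison, life_table)
    data.frame(parameter = name, low = lo, high = hi,
               icer_low = icer_lo, icer_high = icer_hi,
               range = abs(icer_hi - icer_lo))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$range), ]
  rownames(out) <- NULL
  class(out) <- c("tornado", "data.frame")
  out
}

#' Deterministic ICERs under alternative discount rates
#'
#' @param params Base-case `model_parameters`.
#' @param comparison `"meconium"` or `"nst"`.
#' @param rates Annual discount rates (default: the scenario set 0, 1.5%,
#'   3%).
#' @param life_table Optional `life_table`.
#' @return Data frame with one row per rate: `rate`, `delta_cost`,
#'   `delta_effect`, `icer`, `quadrant`.
#' @export
discount_scenarios <- function(params = base_case(comparison),
                               comparison = c("meconium", "nst"),
                               rates = c(0, 0.015, 0.03),
                               life_table = make_life_table(end_age = params$end_age)) {
  comparison <- match.arg(comparison)
  if (any(rates < 0)) stop("'rates' must be >= 0")
  rows <- lapply(rates, function(r) {
    p <- params
    p$discount_rate <- r
    arms <- comparison_strategies(comparison, p)
    ns <- run_strategy(p, arms$no_screen, life_table)
    sc <- run_strategy(p, arms$screen, life_table)
    res <- compare_strategies(ns, sc)
    data.frame(rate = r, delta_cost = res$delta_cost,
               delta_effect = res$delta_effect, icer = res$icer,
               quadrant = res$quadrant)
  })
  do.call(rbind, rows)
}
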