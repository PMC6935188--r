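#' Read a model configuration file
#'
#' Configuration is a YAML (or JSON, which YAML subsumes) file with sections
#' `cohort`, `tool`, `costs`, `mortality`, `time`, `future_diagnosis`,
#' `inflation` and `model`. Every key is optional; omitted keys take the
#' base-case value for the requested comparison. Unknown keys are rejected
#' by name so that typos cannot silently revert a parameter to its default.
#'
#' @param path Path to the configuration file.
#' @param comparison Base case supplying defaults, `"meconium"` or `"nst"`.
#'   Ignored when the file itself carries a `comparison` key.
#' @return A validated [model_parameters()] object with attribute
#'   `comparison`.
#' @seealso [write_parameters()] for the inverse; a fixture reproducing the
#'   full base case ships in `inst/extdata/base_case_meconium.yaml`.
#' @export
load_parameters <- function(path, comparison = c("meconium", "nst")) {
  comparison <- match.arg(comparison)
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e) {
                    stop(sprintf("failed to parse '%s': %s", path,
                                 conditionMessage(e)), call. = FALSE)
                  })
  if (is.null(cfg)) cfg <- list()
  params_from_config(cfg, comparison)
}

params_from_config <- function(cfg, comparison) {
  if (!is.null(cfg$comparison)) {
    comparison <- match.arg(cfg$comparison, c("meconium", "nst"))
  }
  known <- c("comparison", "cohort", "tool", "costs", "mortality", "time",
             "future_diagnosis", "inflation", "model")
  check_keys(cfg, known, "top level")

  co <- section(cfg, "cohort", c("size", "prevalence"))
  tl <- section(cfg, "tool", c("name", "sensitivity", "specificity",
                               "unit_cost", "screen_age", "lag_to_testing"))
  cs <- section(cfg, "costs", c("first_year", "diagnosed_annual",
                                "undiagnosed_annual", "no_fasd_annual",
                                "diagnostic_testing", "basis"))
  mo <- section(cfg, "mortality", c("smr_diagnosed", "undiagnosed_multiplier",
                                    "smr_no_fasd"))
  tm <- section(cfg, "time", c("discount_rate", "end_age"))
  fd <- section(cfg, "future_diagnosis", c("rate", "model", "start"))
  infl <- section(cfg, "inflation", c("factor", "inflate_no_fasd"))
  md <- section(cfg, "model", c("half_cycle", "pending_fasd_cost",
                                "use_inflated_costs", "diagnostic_sensitivity"))

  dt <- default_tool(comparison)
  tool <- tool_profile(
    name = tl$name %||% dt$name,
    sensitivity = tl$sensitivity %||% dt$sensitivity,
    specificity = tl$specificity %||% dt$specificity,
    unit_cost = tl$unit_cost %||% dt$unit_cost,
    screen_age = tl$screen_age %||% dt$screen_age,
    lag_to_testing = tl$lag_to_testing %||% dt$lag_to_testing)
  dc <- cost_set()
  costs <- cost_set(
    first_year = cs$first_year %||% dc$first_year,
    diagnosed_annual = cs$diagnosed_annual %||% dc$diagnosed_annual,
    undiagnosed_annual = cs$undiagnosed_annual %||% dc$undiagnosed_annual,
    no_fasd_annual = cs$no_fasd_annual %||% dc$no_fasd_annual,
    diagnostic_testing = cs$diagnostic_testing %||% dc$diagnostic_testing,
    basis = cs$basis %||% dc$basis)
  mortality <- mortality_params(
    smr_diagnosed = mo$smr_diagnosed %||% 3.15,
    undiagnosed_multiplier = mo$undiagnosed_multiplier %||% 1.10,
    smr_no_fasd = mo$smr_no_fasd %||% 3.15)
  opts <- model_options(
    half_cycle = md$half_cycle %||% "trapezoid",
    conversion_start = fd$start %||% "at_testing",
    future_diagnosis_model = fd$model %||% "hazard",
    pending_fasd_cost = md$pending_fasd_cost %||% "undiagnosed",
    use_inflated_costs = md$use_inflated_costs %||% TRUE,
    inflate_no_fasd = infl$inflate_no_fasd %||% TRUE)
  params <- model_parameters(
    cohort_size = co$size %||% 100,
    prevalence = co$prevalence %||% 0.663,
    tool = tool, costs = costs, mortality = mortality,
    discount_rate = tm$discount_rate %||% 0.015,
    end_age = tm$end_age %||% 18,
    future_diagnosis_rate = fd$rate %||% 0.05,
    diagnostic_sensitivity = md$diagnostic_sensitivity %||% 1,
    inflation_factor = infl$factor %||% derive_inflation_factor(),
    options = opts)
  attr(params, "comparison") <- comparison
  params
}

#' Write a model configuration file
#'
#' Serializes a [model_parameters()] object to YAML such that
#' [load_parameters()] reproduces it field for field.
#'
#' @param params A `model_parameters` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "model_parameters"))
  cfg <- list(
    comparison = attr(params, "comparison") %||% params$tool$name,
    cohort = list(size = params$cohort_size, prevalence = params$prevalence),
    tool = unclass(params$tool),
    costs = unclass(params$costs),
    mortality = unclass(params$mortality),
    time = list(discount_rate = params$discount_rate,
                end_age = params$end_age),
    future_diagnosis = list(rate = params$future_diagnosis_rate,
                            model = params$options$future_diagnosis_model,
                            start = params$options$conversion_start),
    inflation = list(factor = params$inflation_factor,
                     inflate_no_fasd = params$options$inflate_no_fasd),
    model = list(half_cycle = params$options$half_cycle,
                 pending_fasd_cost = params$options$pending_fasd_cost,
                 use_inflated_costs = params$options$use_inflated_costs,
                 diagnostic_sensitivity = params$diagnostic_sensitivity))
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

section <- function(cfg, name, known) {
  s <- cfg[[name]]
  if (is.null(s)) return(list())
  if (!is.list(s)) stop(sprintf("config section '%s' must be a mapping", name))
  check_keys(s, known, sprintf("section '%s'", name))
  s
}

check_keys <- function(x, known, where) {
  extra <- setdiff(names(x), known)
  if (length(extra)) {
    stop(sprintf("unknown key(s) in %s: %s", where,
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
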