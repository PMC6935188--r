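#' Incremental cost-effectiveness comparison of two strategies
#'
#' Deltas are comparator minus reference (reference: no screening). The
#' ICER is the ratio of the deltas, reported with its cost-effectiveness
#' plane quadrant: screening typically lands in the south-west quadrant
#' (cost saving, diagnosed years forgone), where the positive ICER is read
#' as savings per diagnosed year forgone and judged against a
#' willingness-to-accept threshold.
#'
#' @param reference,comparator `strategy_result` objects from the same
#'   comparison (same start age and horizon).
#' @return An object of class `icer_result` with `delta_cost`,
#'   `delta_effect`, `icer` (NA when `delta_effect` is 0), `quadrant`
#'   (`"NE"`, `"NW"`, `"SE"`, `"SW"` or `"on-axis"`) and a `dominance`
#'   label (`"comparator dominates"`, `"reference dominates"` or `"trade-off"`).
#' @examples
#' p <- base_case("nst")
#' arms <- comparison_strategies("nst", p)
#' compare_strategies(run_strategy(p, arms$no_screen),
#'                    run_strategy(p, arms$screen))
#' @export
compare_strategies <- function(reference, comparator) {
  stopifnot(inherits(reference, "strategy_result"),
            inherits(comparator, "strategy_result"))
  if (reference$strategy$model_start_age !=
      comparator$strategy$model_start_age) {
    stop("strategies come from models with different start ages")
  }
  dc <- comparator$total_cost - reference$total_cost
  de <- comparator$total_effect - reference$total_effect
  icer_point(dc, de, reference = reference, comparator = comparator)
}

# Shared constructor so PSA draws classify identically.
icer_point <- function(dc, de, reference = NULL, comparator = NULL) {
  quadrant <- if (dc == 0 || de == 0) {
    "on-axis"
  } else if (de > 0 && dc > 0) {
    "NE"
  } else if (de < 0 && dc > 0) {
    "NW"
  } else if (de > 0 && dc < 0) {
    "SE"
  } else {
    "SW"
  }
  dominance <- if (de >= 0 && dc <= 0 && (de > 0 || dc < 0)) {
    "comparator dominates"
  } else if (de <= 0 && dc >= 0 && (de < 0 || dc > 0)) {
    "reference dominates"
  } else {
    "trade-off"
  }
  structure(list(delta_cost = dc, delta_effect = de,
                 icer = if (de == 0) NA_real_ else dc / de,
                 quadrant = quadrant, dominance = dominance,
                 reference = reference, comparator = comparator),
            class = "icer_result")
}

#' @export
print.icer_result <- function(x, ...) {
  cat("Incremental cost-effectiveness\n")
  cat(sprintf("  delta cost:   $%.2f\n", x$delta_cost))
  cat(sprintf("  delta effect: %.2f diagnosed years\n", x$delta_effect))
  if (is.na(x$icer)) {
    cat(sprintf("  ICER: undefined (no effectiveness difference; %s)\n",
                x$dominance))
  } else {
    cat(sprintf("  ICER: $%.2f per diagnosed year (%s, %s)\n",
                x$icer, x$quadrant, x$dominance))
  }
  invisible(x)
}

#' Results table for one comparison
#'
#' Runs both arms and assembles the standard two-row incremental table
#' (cost, effectiveness, deltas, ICER per 100 screened).
#'
#' @param comparison `"meconium"` or `"nst"`.
#' @param params Model parameters (defaults to the comparison base case).
#' @param life_table Optional `life_table`.
#' @return A data frame with one row per strategy.
#' @export
cea_table <- function(comparison = c("meconium", "nst"),
                      params = base_case(comparison),
                      life_table = make_life_table(end_age = params$end_age)) {
  comparison <- match.arg(comparison)
  arms <- comparison_strategies(comparison, params)
  ns <- run_strategy(params, arms$no_screen, life_table)
  sc <- run_strategy(params, arms$screen, life_table)
  res <- compare_strategies(ns, sc)
  data.frame(
    strategy = c("No screening", if (comparison == "meconium") {
      "Meconium testing"
    } else {
      "The NST"
    }),
    cost = c(ns$total_cost, sc$total_cost),
    effectiveness = c(ns$total_effect, sc$total_effect),
    delta_cost = c(NA, res$delta_cost),
    delta_effectiveness = c(NA, res$delta_effect),
    icer = c(NA, res$icer),
    quadrant = c(NA, res$quadrant))
}
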