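#' Run a full comparison and write its outputs
#'
#' Runs both arms of a comparison deterministically, writes the two-row
#' incremental table and per-cycle traces as CSV, optionally runs the
#' probabilistic and one-way analyses, and records a manifest of every
#' file written.
#'
#' @param comparison `"meconium"` or `"nst"`.
#' @param params Model parameters (default: the comparison's base case); a
#'   file path is also accepted and read with [load_parameters()].
#' @param outdir Output directory, created if needed.
#' @param seed Integer seed driving all randomness in the run.
#' @param psa_draws Number of PSA draws (0 skips the probabilistic
#'   analysis).
#' @param tornado Run the one-way analysis as well.
#' @param life_table Optional `life_table`.
#' @return The manifest (named list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_comparison <- function(comparison = c("meconium", "nst"),
                           params = base_case(comparison),
                           outdir = ".", seed = 20190101, psa_draws = 0,
                           tornado = FALSE,
                           life_table = NULL) {
  comparison <- match.arg(comparison)
  if (is.character(params)) params <- load_parameters(params, comparison)
  stopifnot(inherits(params, "model_parameters"))
  if (is.null(life_table)) life_table <- make_life_table(end_age = params$end_age)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(outdir, sprintf(...))

  arms <- comparison_strategies(comparison, params)
  ns <- run_strategy(params, arms$no_screen, life_table)
  sc <- run_strategy(params, arms$screen, life_table)
  tab <- cea_table(comparison, params, life_table)
  files <- list(icer_table = out("icer_%s.csv", comparison),
                trace_no_screen = out("trace_%s_no_screen.csv", comparison),
                trace_screen = out("trace_%s_screen.csv", comparison))
  utils::write.csv(tab, files$icer_table, row.names = FALSE)
  write_trace(ns, files$trace_no_screen)
  write_trace(sc, files$trace_screen)

  if (psa_draws > 0) {
    psa <- run_psa(params, comparison, n_draws = psa_draws, seed = seed,
                   life_table = life_table)
    curve <- ceac(psa)
    files$psa_draws <- out("psa_%s.csv", comparison)
    files$ceac <- out("ceac_%s.csv", comparison)
    utils::write.csv(as.data.frame(psa), files$psa_draws, row.names = FALSE)
    utils::write.csv(as.data.frame(curve), files$ceac, row.names = FALSE)
  }
  if (tornado) {
    tw <- one_way(params, comparison, life_table = life_table)
    files$tornado <- out("tornado_%s.csv", comparison)
    utils::write.csv(as.data.frame(tw), files$tornado, row.names = FALSE)
  }

  manifest <- list(comparison = comparison, seed = seed,
                   package_version = as.character(utils::packageVersion("fasdcea")),
                   timestamp = format(Sys.time(), tz = "UTC"),
                   outputs = files)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
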