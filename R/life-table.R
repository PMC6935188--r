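#' Synthetic pediatric life table
#'
#' Generates age-specific annual background death probabilities for ages 0
#' to `end_age - 1`: an elevated infant rate at age 0 and a low flat rate
#' thereafter. This emulates the shape of a national pediatric life table
#' (infant mortality dominates; child mortality is roughly constant and an
#' order of magnitude lower) without requiring external data. The defaults
#' (q0 = 0.005, flat = 0.0002) are plausible Canadian magnitudes; a real
#' life table read with [read_life_table()] can be substituted anywhere one
#' is accepted.
#'
#' @param infant_q0 Annual death probability at age 0, in \[0, 0.05\].
#' @param child_q_flat Annual death probability at ages 1+, in \[0, 0.05\]
#'   and not exceeding `infant_q0`.
#' @param end_age One past the last age covered (default 18).
#' @return A data frame of class `life_table` with columns `age` and `qx`.
#' @examples
#' lt <- make_life_table()
#' lt$qx[lt$age == 0]
#' make_life_table(0, 0) # immortal cohort, for closed-form checks
#' @export
make_life_table <- function(infant_q0 = 0.005, child_q_flat = 0.0002,
                            end_age = 18) {
  if (infant_q0 < 0 || infant_q0 > 0.05 || child_q_flat < 0 ||
      child_q_flat > 0.05) {
    stop("death probabilities must lie in [0, 0.05]")
  }
  if (infant_q0 < child_q_flat) {
    stop("'infant_q0' must be at least 'child_q_flat'")
  }
  if (end_age < 1) stop("'end_age' must be >= 1")
  lt <- data.frame(age = 0:(end_age - 1),
                   qx = c(infant_q0, rep(child_q_flat, end_age - 1)))
  class(lt) <- c("life_table", "data.frame")
  lt
}

#' Read a life table from CSV
#'
#' @param path CSV with columns `age` (consecutive integers from 0) and
#'   `qx` (annual death probabilities in \[0, 1)).
#' @return A `life_table` data frame.
#' @export
read_life_table <- function(path) {
  lt <- utils::read.csv(path)
  stopifnot(all(c("age", "qx") %in% names(lt)))
  if (any(lt$qx < 0 | lt$qx >= 1)) stop("'qx' must lie in [0, 1)")
  if (!identical(as.integer(lt$age), seq(0L, length.out = nrow(lt)))) {
    stop("'age' must run 0, 1, 2, ... without gaps")
  }
  lt <- lt[, c("age", "qx")]
  class(lt) <- c("life_table", "data.frame")
  lt
}

#' Write a life table to CSV
#'
#' @param life_table A `life_table` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_life_table <- function(life_table, path) {
  utils::write.csv(as.data.frame(life_table), path, row.names = FALSE)
  invisible(path)
}

# Background death probability at an integer age; ages beyond the table
# reuse its last entry.
lookup_qx <- function(life_table, age) {
  qx <- life_table$qx[match(pmin(age, max(life_table$age)), life_table$age)]
  if (anyNA(qx)) stop(sprintf("life table does not cover age %s", age))
  qx
}

#' Generate synthetic accuracy studies for pooling checks
#'
#' Draws `k` studies around a common true proportion: group sizes uniform
#' on `n_range`, successes binomial, SDs imputed the same way as for the
#' published tables. Used for parameter-recovery tests of
#' [pool_random_effects()].
#'
#' @param true_p True proportion in (0, 1).
#' @param k Number of studies.
#' @param n_range Length-2 integer range of group sizes.
#' @param seed Integer seed; the same seed reproduces the same study set.
#' @return Data frame with columns `label`, `proportion`, `group_n`, `sd`.
#' @export
make_accuracy_studies <- function(true_p, k, n_range = c(30, 200),
                                  seed = 20190101) {
  if (true_p <= 0 || true_p >= 1) stop("'true_p' must be in (0, 1)")
  if (k < 1) stop("'k' must be >= 1")
  set.seed(seed)
  n <- sample(n_range[1]:n_range[2], k, replace = TRUE)
  x <- stats::rbinom(k, n, true_p)
  data.frame(label = sprintf("synthetic %02d", seq_len(k)),
             proportion = x / n, group_n = n, sd = NA_real_)
}
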