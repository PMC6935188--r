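#' Cap boundary proportions
#'
#' A proportion of exactly 1 (or 0) has zero beta-distribution variance, so
#' study accuracies reported as 100% are taken as 99% before dispersion is
#' imputed; 0% is handled symmetrically as 1%.
#'
#' @param p Proportion(s) in \[0, 1\].
#' @return `p` with exact 0/1 values moved to 0.01/0.99.
#' @export
cap_extreme <- function(p) {
  stop_unless_prob(p, "p")
  p[p == 1] <- 0.99
  p[p == 0] <- 0.01
  p
}

#' Impute a study-level SD with the beta-distribution variance formula
#'
#' For a proportion `p` observed in a group of `n` subjects the implied
#' beta distribution (shape parameters `n * p` and `n * (1 - p)`) has
#' variance `p * (1 - p) / (n + 1)`; its square root stands in for an
#' unreported study SD.
#'
#' @param p Proportion in (0, 1); cap boundary values with [cap_extreme()]
#'   first.
#' @param n Number of subjects contributing to the proportion (positive
#'   cases for a sensitivity, controls for a specificity).
#' @return The imputed standard deviation.
#' @examples
#' beta_sd(0.68, 93) # 0.048, the imputed SD for a 68% sensitivity among 93 cases
#' @export
beta_sd <- function(p, n) {
  if (any(p <= 0) || any(p >= 1)) {
    stop("'p' must lie strictly in (0, 1); apply cap_extreme() first")
  }
  if (any(n < 1)) stop("'n' must be >= 1")
  sqrt(p * (1 - p) / (n + 1))
}

#' Prepare accuracy studies for pooling
#'
#' Caps boundary proportions and imputes missing SDs via [beta_sd()].
#'
#' @param studies Data frame with columns `label`, `proportion`, `group_n`
#'   and optionally `sd` (NA where unreported).
#' @return The data frame with `proportion` capped and `sd` complete.
#' @export
impute_study_sd <- function(studies) {
  stopifnot(all(c("label", "proportion", "group_n") %in% names(studies)))
  studies$proportion <- cap_extreme(studies$proportion)
  if (is.null(studies$sd)) studies$sd <- NA_real_
  miss <- is.na(studies$sd)
  studies$sd[miss] <- beta_sd(studies$proportion[miss], studies$group_n[miss])
  if (any(studies$sd <= 0 | studies$sd >= 1)) {
    stop("study SDs must lie in (0, 1)")
  }
  studies
}

#' Pool study proportions with DerSimonian-Laird random effects
#'
#' Moment-based random-effects pooling on the raw proportion scale:
#' fixed-effect weights `w = 1/sd^2` give the heterogeneity statistic
#' `Q = sum(w * (p - mu_FE)^2)`; the between-study variance is
#' `tau2 = max(0, (Q - (k - 1)) / (sum(w) - sum(w^2)/sum(w)))`; the pooled
#' mean reweights by `1/(sd^2 + tau2)`. A logit-scale variant (delta-method
#' SEs, back-transformed mean) is available but the raw scale is the
#' default: it is the scale on which the published pooled accuracies are
#' reproduced.
#'
#' @param studies Data frame as accepted by [impute_study_sd()] (SDs may be
#'   missing; they are imputed).
#' @param scale `"proportion"` (default) or `"logit"`.
#' @return An object of class `pooled_accuracy`: list with `mean`,
#'   `between_study_variance`, `pooled_sd` (`sqrt(tau2)`), `k`, `Q`, and the
#'   prepared `studies`.
#' @examples
#' pool_random_effects(meconium_accuracy_studies("sensitivity"))$mean
#' @export
pool_random_effects <- function(studies, scale = c("proportion", "logit")) {
  scale <- match.arg(scale)
  studies <- impute_study_sd(studies)
  p <- studies$proportion
  s <- studies$sd
  k <- length(p)
  if (k < 1) stop("at least one study is required")
  if (scale == "logit") {
    y <- stats::qlogis(p)
    sy <- s / (p * (1 - p))
  } else {
    y <- p
    sy <- s
  }
  if (k == 1) {
    est <- list(mean = p, between_study_variance = 0, pooled_sd = 0, k = 1L,
                Q = 0, studies = studies, scale = scale)
    class(est) <- "pooled_accuracy"
    return(est)
  }
  w <- 1 / sy^2
  mu_fe <- sum(w * y) / sum(w)
  Q <- sum(w * (y - mu_fe)^2)
  tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (sy^2 + tau2)
  mu <- sum(ws * y) / sum(ws)
  mean_p <- if (scale == "logit") stats::plogis(mu) else mu
  structure(list(mean = mean_p, between_study_variance = tau2,
                 pooled_sd = sqrt(tau2), k = as.integer(k), Q = Q,
                 studies = studies, scale = scale),
            class = "pooled_accuracy")
}

#' @export
print.pooled_accuracy <- function(x, ...) {
  cat(sprintf("Pooled accuracy (%s scale, DerSimonian-Laird, k = %d)\n",
              x$scale, x$k))
  cat(sprintf("  mean %.4f, tau^2 %.5f (between-study SD %.4f)\n",
              x$mean, x$between_study_variance, x$pooled_sd))
  invisible(x)
}

#' Published accuracy studies of meconium FAEE testing
#'
#' The four studies of meconium fatty acid ethyl ester testing against
#' confirmed prenatal alcohol exposure, as used in the pooled base case.
#' `group_n` is the number of positive cases (sensitivity rows) or controls
#' (specificity rows); `sd` is NA throughout (all dispersions are imputed).
#' `sd_printed` carries the tabulated SDs for reference.
#'
#' @param measure `"sensitivity"` or `"specificity"`.
#' @return Data frame with columns `label`, `measure`, `proportion`,
#'   `group_n`, `sd`, `sd_printed`.
#' @export
meconium_accuracy_studies <- function(measure = c("sensitivity", "specificity")) {
  measure <- match.arg(measure)
  read_accuracy_fixture("meconium_accuracy.csv", measure)
}

#' Published accuracy studies of the Neurobehavioral Screening Tool
#'
#' Six comparison rows from four studies (two studies each contribute two
#' control-group comparisons, tabulated separately).
#'
#' @inheritParams meconium_accuracy_studies
#' @return Data frame as in [meconium_accuracy_studies()].
#' @export
nst_accuracy_studies <- function(measure = c("sensitivity", "specificity")) {
  measure <- match.arg(measure)
  read_accuracy_fixture("nst_accuracy.csv", measure)
}

read_accuracy_fixture <- function(file, measure) {
  path <- system.file("extdata", file, package = "fasdcea", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- df[df$measure == measure, , drop = FALSE]
  df$sd <- as.numeric(df$sd)
  rownames(df) <- NULL
  df
}

#' Read accuracy studies from CSV
#'
#' @param path CSV with columns `label`, `proportion`, `group_n` and
#'   optionally `sd`.
#' @return Data frame suitable for [pool_random_effects()].
#' @export
read_accuracy_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("label", "proportion", "group_n") %in% names(df)))
  df
}
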