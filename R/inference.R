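#' Settings for simultaneous inference
#'
#' Controls the quasi-Monte-Carlo evaluation of multivariate t/normal
#' probabilities (Genz-Bretz algorithm) behind the equicoordinate quantile,
#' the adjusted p-values and the simultaneous confidence intervals.
#'
#' @param alpha Familywise error level in (0, 1); two-sided throughout.
#' @param quantile_tolerance Absolute tolerance on the equicoordinate
#'   quantile (root finding stops when the bracketing interval is smaller).
#' @param prob_tolerance Absolute error requested from the integration
#'   algorithm for each probability.
#' @param integration_seed Integer seed fixing the quasi-Monte-Carlo draws so
#'   that p-values and quantiles are reproducible run to run.
#' @param maxpts Maximum number of integrand evaluations per probability.
#'
#' @return A list of class `"gm_settings"`.
#' @export
gm_settings <- function(alpha = 0.05,
                        quantile_tolerance = 1e-3,
                        prob_tolerance = 1e-4,
                        integration_seed = 20230714L,
                        maxpts = 25000L) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1,
            quantile_tolerance > 0, prob_tolerance > 0)
  structure(list(alpha = alpha,
                 quantile_tolerance = quantile_tolerance,
                 prob_tolerance = prob_tolerance,
                 integration_seed = as.integer(integration_seed),
                 maxpts = as.integer(maxpts)),
            class = "gm_settings")
}

# evaluate code under a fixed seed without disturbing the caller's RNG stream
with_preserved_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Validate a correlation matrix; attempt a small ridge repair before failing.
# Degenerate (NA) rows/columns must be removed by the caller.
check_correlation <- function(R, ridge = 1e-10) {
  R <- as.matrix(R)
  if (anyNA(R)) stop("Correlation matrix contains NA.", call. = FALSE)
  if (max(abs(R - t(R))) > 1e-8) stop("Correlation matrix must be symmetric.",
                                      call. = FALSE)
  if (max(abs(diag(R) - 1)) > 1e-8 || max(abs(R)) > 1 + 1e-8) {
    stop("Not a correlation matrix: unit diagonal and entries in [-1, 1] ",
         "required.", call. = FALSE)
  }
  ev <- eigen((R + t(R)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    message("Correlation matrix is not positive semidefinite; ",
            "applying ridge repair of ", format(ridge), ".")
    K <- nrow(R)
    R <- (R + diag(ridge, K)) / (1 + ridge)
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) {
      stop("Correlation matrix is not positive semidefinite ",
           "(ridge repair failed).", call. = FALSE)
    }
  }
  R
}

.gb_algorithm <- function(settings, maxpts = NULL) {
  mvtnorm::GenzBretz(maxpts = maxpts %||% settings$maxpts,
                     abseps = settings$prob_tolerance, releps = 0)
}

# P(max_k |T_k| <= q) for central multivariate t(df, R); normal when df = Inf.
# The quasi-Monte-Carlo integrator supports integer df only, so fractional
# (Satterthwaite) df are rounded to the nearest integer (floor 1) here; the
# univariate marginals elsewhere keep the fractional value.
central_box_prob <- function(q, R, df, settings) {
  K <- nrow(R)
  if (K == 1L) {
    return(if (is.infinite(df)) stats::pnorm(q) - stats::pnorm(-q)
           else stats::pt(q, df) - stats::pt(-q, df))
  }
  if (is.finite(df)) df <- max(1L, as.integer(round(df)))
  alg <- .gb_algorithm(settings)
  with_preserved_seed(settings$integration_seed, {
    if (is.infinite(df)) {
      as.numeric(mvtnorm::pmvnorm(lower = rep(-q, K), upper = rep(q, K),
                                  corr = R, algorithm = alg))
    } else {
      as.numeric(mvtnorm::pmvt(lower = rep(-q, K), upper = rep(q, K),
                               corr = R, df = df, algorithm = alg))
    }
  })
}

#' Two-sided equicoordinate quantile of a multivariate t or normal
#'
#' Finds q with \eqn{P(\max_k |T_k| \le q) = 1 - \alpha} for a central
#' multivariate t with correlation matrix `R` and `df` degrees of freedom
#' (multivariate normal when `df` is infinite). This is the critical value
#' of the single-step simultaneous test and the half-width multiplier of the
#' simultaneous confidence intervals.
#'
#' @param R Correlation matrix of the contrast statistics.
#' @param alpha Two-sided familywise level; defaults to `settings$alpha`.
#' @param df Degrees of freedom (`Inf` for the normal case).
#' @param settings A [gm_settings()] object.
#'
#' @return The quantile q (a single number).
#' @export
equicoordinate_quantile <- function(R, alpha = NULL, df = Inf,
                                    settings = gm_settings()) {
  if (is.null(alpha)) alpha <- settings$alpha
  stopifnot(alpha > 0, alpha < 1)
  R <- check_correlation(R)
  K <- nrow(R)
  if (K == 1L) {
    return(if (is.infinite(df)) stats::qnorm(1 - alpha / 2)
           else stats::qt(1 - alpha / 2, df))
  }
  # bracket between the unadjusted and the Bonferroni two-sided quantiles
  lo <- if (is.infinite(df)) stats::qnorm(1 - alpha / 2) else
    stats::qt(1 - alpha / 2, df)
  hi <- if (is.infinite(df)) stats::qnorm(1 - alpha / (2 * K)) else
    stats::qt(1 - alpha / (2 * K), df)
  lo <- lo - 1e-6
  hi <- hi + 1e-6
  f <- function(q) central_box_prob(q, R, df, settings) - (1 - alpha)
  stats::uniroot(f, lower = lo, upper = hi, extendInt = "upX",
                 tol = settings$quantile_tolerance)$root
}

#' Single-step adjusted p-values
#'
#' For each statistic \eqn{t_k}, the adjusted p-value is
#' \eqn{p_k = 1 - P(\max_j |T_j| \le |t_k|)} under the central multivariate
#' t (or normal) with the estimated correlation matrix, so that
#' \eqn{p_k < \alpha} exactly when \eqn{|t_k|} exceeds the equicoordinate
#' quantile. `NA` statistics (degenerate contrasts) give `NA` p-values with
#' a warning.
#'
#' @param t_stats Vector of observed t statistics.
#' @param R Correlation matrix (rows/columns of degenerate statistics may be
#'   `NA`; they are dropped from the maximum).
#' @param df Degrees of freedom (`Inf` for the normal reference).
#' @param settings A [gm_settings()] object.
#'
#' @return Numeric vector of adjusted p-values in [0, 1].
#' @export
adjusted_pvalues <- function(t_stats, R, df = Inf, settings = gm_settings()) {
  K <- length(t_stats)
  ok <- !is.na(t_stats)
  if (!all(ok)) {
    warning("Undefined t statistics (zero standard error); the corresponding ",
            "adjusted p-values are reported as NA.", call. = FALSE)
  }
  p <- rep(NA_real_, K)
  if (!any(ok)) return(p)
  Rok <- check_correlation(as.matrix(R)[ok, ok, drop = FALSE])
  tok <- t_stats[ok]
  p[ok] <- vapply(tok, function(tk) {
    pr <- central_box_prob(abs(tk), Rok, df, settings)
    min(max(1 - pr, 0), 1)
  }, numeric(1))
  p
}

#' Simultaneous confidence intervals for the deviations
#'
#' Intervals \eqn{\hat d_k \pm q \, se(\hat d_k)} with joint coverage
#' \eqn{1 - \alpha} when q is the equicoordinate quantile for the estimated
#' correlation matrix.
#'
#' @param dev A [apply_contrasts()] result.
#' @param q Positive critical value.
#'
#' @return A tibble with columns `center`, `lower`, `upper`.
#' @export
simultaneous_ci <- function(dev, q) {
  stopifnot(inherits(dev, "gm_deviations"), is.numeric(q), length(q) == 1L,
            q >= 0)
  tibble::tibble(center = dev$labels,
                 lower = unname(dev$deviations - q * dev$std_errors),
                 upper = unname(dev$deviations + q * dev$std_errors))
}

#' Equivalence margins
#'
#' A symmetric (by default) range \eqn{[-\delta, \delta]} of practically
#' irrelevant deviation from the Grand Mean, on the scale of the analysis.
#'
#' @param delta Positive half-width; or supply `lower`/`upper` directly.
#' @param lower,upper Optional asymmetric limits (`lower < 0 < upper`).
#' @return A list of class `"gm_margins"`.
#' @export
gm_margins <- function(delta = NULL, lower = NULL, upper = NULL) {
  if (!is.null(delta)) {
    stopifnot(is.numeric(delta), length(delta) == 1L, delta > 0)
    lower <- -delta
    upper <- delta
  }
  stopifnot(is.numeric(lower), is.numeric(upper), lower < 0, upper > 0)
  structure(list(lower = lower, upper = upper), class = "gm_margins")
}

#' Classify centers from their simultaneous confidence intervals
#'
#' A center is a `significant_deviation` when its interval excludes 0;
#' `equivalent` when margins are supplied and the interval lies inside
#' \eqn{[-\delta, \delta]} (while covering 0); `inconclusive` when the
#' interval covers 0 but is not contained in the margins; and
#' `not_assessed` when no margins are given and the interval covers 0.
#' Centers with undefined intervals are `not_assessed`.
#'
#' @param lower,upper Numeric vectors of interval limits.
#' @param margins Optional [gm_margins()].
#'
#' @return A list with `flag` (factor) and `within_margins` (logical, `NA`
#'   when margins are absent).
#' @export
classify_centers <- function(lower, upper, margins = NULL) {
  stopifnot(length(lower) == length(upper))
  levs <- c("significant_deviation", "equivalent", "inconclusive",
            "not_assessed")
  flag <- character(length(lower))
  excludes0 <- !is.na(lower) & !is.na(upper) & (lower > 0 | upper < 0)
  if (is.null(margins)) {
    within <- rep(NA, length(lower))
    flag[] <- ifelse(excludes0, "significant_deviation", "not_assessed")
  } else {
    stopifnot(inherits(margins, "gm_margins"))
    within <- !is.na(lower) & !is.na(upper) &
      lower > margins$lower & upper < margins$upper
    flag[] <- dplyr::case_when(
      is.na(lower) | is.na(upper) ~ "not_assessed",
      excludes0 ~ "significant_deviation",
      within ~ "equivalent",
      TRUE ~ "inconclusive")
  }
  flag[is.na(lower) | is.na(upper)] <- "not_assessed"
  list(flag = factor(flag, levels = levs), within_margins = within)
}
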