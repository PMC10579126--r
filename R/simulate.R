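#' Monte Carlo error helpers
#'
#' Standard error of an estimated rejection rate, and the range in which 95%
#' of simulated rates are expected when a method holds the nominal level
#' exactly: `rate +/- 1.96 sqrt(rate (1 - rate) / reps)`.
#'
#' @param rate Rejection probability.
#' @param reps Number of Monte Carlo replicates.
#' @return `mc_std_error()` a number; `mc_interval()` a length-2 vector.
#' @export
mc_std_error <- function(rate, reps) {
  stopifnot(rate >= 0, rate <= 1, reps >= 1)
  sqrt(rate * (1 - rate) / reps)
}

#' @rdname mc_std_error
#' @export
mc_interval <- function(rate = 0.05, reps = 1000) {
  se <- mc_std_error(rate, reps)
  c(lower = rate - stats::qnorm(0.975) * se,
    upper = rate + stats::qnorm(0.975) * se)
}

#' Calibrate a mean shift to 80% two-sample t-test power
#'
#' Returns the true difference delta (sigma = 1) at which a two-sided
#' two-sample t-test with `n` subjects per group attains the target power,
#' by noncentral-t inversion.
#'
#' @param n Subjects per group (>= 2).
#' @param power Target power.
#' @param alpha Two-sided significance level.
#' @return The calibrated delta.
#' @export
calibrate_delta_ttest <- function(n, power = 0.8, alpha = 0.05) {
  stopifnot(n >= 2, power > alpha, power < 1)
  out <- stats::power.t.test(n = n, power = power, sig.level = alpha,
                             type = "two.sample",
                             alternative = "two.sided", strict = TRUE,
                             tol = 1e-10)
  out$delta
}

# two-sided power of the pooled-variance normal-approximation two-sample
# proportion test (the classical formula, as in stats::power.prop.test)
prop_test_power <- function(p1, p2, n, alpha = 0.05) {
  z <- stats::qnorm(1 - alpha / 2)
  pbar <- (p1 + p2) / 2
  d <- abs(p1 - p2)
  s0 <- sqrt(2 * pbar * (1 - pbar))
  s1 <- sqrt(p1 * (1 - p1) + p2 * (1 - p2))
  stats::pnorm((sqrt(n) * d - z * s0) / s1) +
    stats::pnorm((-sqrt(n) * d - z * s0) / s1)
}

#' Calibrate a deviating success probability to 80% proportion-test power
#'
#' Returns the upper root pi1 > pi0 at which the two-sided two-sample
#' proportion test (pooled normal approximation) with `n` subjects per
#' group attains the target power against baseline `pi0`.
#'
#' @param pi0 Baseline success probability in (0, 1).
#' @param n Subjects per group.
#' @param power Target power.
#' @param alpha Two-sided significance level.
#' @return The calibrated pi1 (upper root).
#' @export
calibrate_prop_test <- function(pi0, n, power = 0.8, alpha = 0.05) {
  stopifnot(pi0 > 0, pi0 < 1, n >= 2, power > alpha, power < 1)
  f <- function(p1) prop_test_power(pi0, p1, n, alpha) - power
  upper <- 1 - 1e-9
  if (f(upper) < 0) {
    stop("Power ", power, " is unattainable for pi0 = ", pi0,
         " with n = ", n, " per group.", call. = FALSE)
  }
  stats::uniroot(f, lower = pi0 + 1e-9, upper = upper, tol = 1e-9)$root
}

#' Define one simulation scenario
#'
#' One cell of the Monte Carlo grid: outcome type, analysis method, number
#' of centers, per-center size profile, baseline parameters and the effect
#' carried by a single deviating center (0 under the null).
#'
#' Size profiles: balanced designs give every center `n` subjects. Under
#' the null, `unbalanced = TRUE` alternates `n` and `n/2` across centers;
#' under the alternative the deviating center gets half the observations of
#' the others.
#'
#' @param outcome `"continuous"`, `"binomial"` or `"ordinal"`.
#' @param method Analysis backend (see [gm_analyze()]).
#' @param I Number of centers.
#' @param n Subjects per center (scalar) or an explicit size vector.
#' @param pi0 Baseline success probability (binomial outcomes).
#' @param delta Effect of the deviating center: a mean shift (continuous /
#'   ordinal) or the deviating success probability pi1 (binomial). 0 (or
#'   `NULL` for binomial) encodes the null.
#' @param deviating_center Index of the deviating center.
#' @param unbalanced Use the unbalanced size profile.
#' @param rounding Rounding rule for ordinal generation:
#'   `"half_even"` (IEC 60559, the default) or `"half_up"`.
#' @return A list of class `"gm_scenario"`.
#' @export
gm_scenario <- function(outcome = c("continuous", "binomial", "ordinal"),
                        method = c("lm", "glm", "bayesglm", "brglm",
                                   "nparcomp"),
                        I = 5, n = 10, pi0 = NULL, delta = 0,
                        deviating_center = 1L, unbalanced = FALSE,
                        rounding = c("half_even", "half_up")) {
  outcome <- match.arg(outcome)
  method <- match.arg(method)
  rounding <- match.arg(rounding)
  stopifnot(I >= 2, deviating_center >= 1, deviating_center <= I)
  null_scenario <- if (outcome == "binomial") {
    is.null(delta) || (!is.null(pi0) && isTRUE(all.equal(delta, pi0)))
  } else {
    isTRUE(all.equal(delta, 0))
  }
  if (length(n) == 1L) {
    sizes <- rep(as.integer(n), I)
    if (unbalanced) {
      if (null_scenario) {
        half <- pmax(1L, as.integer(floor(n / 2)))
        sizes[seq(2, I, by = 2)] <- half
      } else {
        sizes[deviating_center] <- pmax(1L, as.integer(floor(n / 2)))
      }
    }
  } else {
    stopifnot(length(n) == I)
    sizes <- as.integer(n)
  }
  if (outcome == "binomial" && is.null(pi0)) {
    stop("Binomial scenarios need `pi0`.", call. = FALSE)
  }
  structure(list(outcome = outcome, method = method, I = as.integer(I),
                 n = n, sizes = sizes, pi0 = pi0, delta = delta,
                 deviating_center = as.integer(deviating_center),
                 unbalanced = unbalanced, rounding = rounding,
                 null_scenario = null_scenario),
            class = "gm_scenario")
}

#' Generate one dataset from a scenario
#'
#' Continuous outcomes are N(m_i, 1); ordinal outcomes are the same normal
#' draws rounded to 0 digits (round-half-even by default); binomial
#' outcomes are per-center event counts Binomial(n_i, pi_i). Exactly one
#' center carries the effect under the alternative.
#'
#' @param scenario A [gm_scenario()].
#' @return A tibble: long format (`center`, `value`) for continuous and
#'   ordinal outcomes, aggregated (`center`, `events`, `total`) for
#'   binomial ones. Uses the current RNG stream.
#' @export
gm_simulate_data <- function(scenario) {
  stopifnot(inherits(scenario, "gm_scenario"))
  sizes <- scenario$sizes
  I <- scenario$I
  labels <- sprintf("C%02d", seq_len(I))
  if (scenario$outcome == "binomial") {
    pi_i <- rep(scenario$pi0, I)
    if (!scenario$null_scenario) {
      pi_i[scenario$deviating_center] <- scenario$delta
    }
    return(tibble::tibble(center = labels,
                          events = stats::rbinom(I, sizes, pi_i),
                          total = sizes))
  }
  m <- rep(0, I)
  if (!scenario$null_scenario) m[scenario$deviating_center] <- scenario$delta
  v <- stats::rnorm(sum(sizes), mean = rep(m, sizes), sd = 1)
  if (scenario$outcome == "ordinal") {
    v <- if (scenario$rounding == "half_even") round(v) else
      sign(v) * floor(abs(v) + 0.5)
  }
  tibble::tibble(center = rep(labels, sizes), value = v)
}

# Fast familywise rejection indicator: is any single-step adjusted p < alpha?
# Uses the bracket raw p <= adjusted p <= K * raw p to avoid the multivariate
# integral except when the decision is genuinely close.
gm_reject <- function(data, scenario, settings = gm_settings()) {
  fit <- switch(scenario$method,
    lm = fit_center_lm(data),
    nparcomp = fit_relative_effects(data),
    glm = fit_center_glm(data),
    brglm = fit_center_brglm(data),
    bayesglm = fit_center_bayesglm(data))
  dev <- apply_contrasts(fit)
  ok <- !is.na(dev$t_stats)
  if (!any(ok)) return(FALSE)
  tmax <- max(abs(dev$t_stats[ok]))
  K <- sum(ok)
  praw <- if (is.infinite(dev$df)) 2 * stats::pnorm(-tmax) else
    2 * stats::pt(-tmax, dev$df)
  if (K * praw < settings$alpha) return(TRUE)   # Bonferroni already rejects
  if (praw >= settings$alpha) return(FALSE)     # even unadjusted fails
  R <- dev$correlation[ok, ok, drop = FALSE]
  pr <- central_box_prob(tmax, R, dev$df, settings)
  (1 - pr) < settings$alpha
}

#' Run a Monte Carlo study over a list of scenarios
#'
#' For each scenario, generates `reps` datasets, applies the scenario's
#' backend with the single-step Grand-Mean test, and records the
#' probability of rejecting the global null for at least one center.
#' Per-scenario RNG substreams are derived deterministically from the
#' master seed, so identical seeds reproduce identical tables. Replicates
#' whose fit fails (e.g. plain-GLM separation) are counted and, by default,
#' treated as non-rejections; `failed_fits = "drop"` removes them from the
#' denominator instead.
#'
#' @param scenarios A list of [gm_scenario()] objects (or a single one).
#' @param reps Replicates per scenario.
#' @param seed Master integer seed.
#' @param settings A [gm_settings()]; its `alpha` is the test level. For
#'   speed the simulation integrates probabilities at a looser tolerance
#'   than reporting runs; override via `settings`.
#' @param failed_fits `"nonrejection"` (default) or `"drop"`.
#' @return A tibble with one row per scenario: the grid coordinates, the
#'   estimated `rejection_rate`, its `mc_std_error`, `reps_used` and
#'   `n_failed_fits`.
#' @export
run_gm_study <- function(scenarios, reps = 1000, seed = 1,
                         settings = gm_settings(prob_tolerance = 2.5e-3,
                                                maxpts = 10000L),
                         failed_fits = c("nonrejection", "drop")) {
  if (inherits(scenarios, "gm_scenario")) scenarios <- list(scenarios)
  failed_fits <- match.arg(failed_fits)
  rows <- vector("list", length(scenarios))
  for (s in seq_along(scenarios)) {
    sc <- scenarios[[s]]
    set.seed((as.integer(seed) + 7919L * s) %% 2147483647L)
    rejected <- 0L
    failed <- 0L
    for (r in seq_len(reps)) {
      data <- gm_simulate_data(sc)
      res <- tryCatch(gm_reject(data, sc, settings),
                      error = function(e) NA)
      if (is.na(res)) failed <- failed + 1L
      else if (res) rejected <- rejected + 1L
    }
    denom <- if (failed_fits == "drop") reps - failed else reps
    rate <- if (denom > 0) rejected / denom else NA_real_
    rows[[s]] <- tibble::tibble(
      outcome = sc$outcome, method = sc$method, I = sc$I,
      n = if (length(sc$n) == 1L) sc$n else NA_integer_,
      unbalanced = sc$unbalanced,
      pi0 = if (is.null(sc$pi0)) NA_real_ else sc$pi0,
      delta = if (is.null(sc$delta)) NA_real_ else sc$delta,
      null_scenario = sc$null_scenario,
      rejection_rate = rate,
      mc_std_error = if (is.na(rate)) NA_real_ else
        mc_std_error(rate, denom),
      reps_used = denom,
      n_failed_fits = failed)
  }
  dplyr::bind_rows(rows)
}

#' Plot a simulation results table
#'
#' Rejection rate against per-center sample size, one line per method, with
#' the nominal level (type I error studies) or target power drawn as a
#' horizontal reference and a Monte Carlo error band around it.
#'
#' @param results A tibble from [run_gm_study()].
#' @param reference Nominal rate: 0.05 for null studies, 0.8 for power.
#' @return A ggplot object.
#' @export
plot_gm_study <- function(results, reference = 0.05) {
  stopifnot(nrow(results) > 0)
  band <- mc_interval(reference, max(results$reps_used))
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data$n, y = .data$rejection_rate,
                               colour = .data$method)) +
    ggplot2::geom_hline(yintercept = reference, colour = "grey30") +
    ggplot2::geom_hline(yintercept = band, colour = "steelblue",
                        linetype = 3) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$I),
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "subjects per center", y = "rejection rate") +
    ggplot2::theme_minimal()
}
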