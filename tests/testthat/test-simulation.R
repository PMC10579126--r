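test_that("Monte Carlo error analytics match the closed form", {
  expect_equal(mc_std_error(0.05, 1000), sqrt(0.05 * 0.95 / 1000))
  expect_equal(mc_std_error(0.05, 1000), 0.007, tolerance = 0.02)
  ival <- mc_interval(0.05, 1000)
  expect_equal(unname(ival[1]), 0.036, tolerance = 0.02)
  expect_equal(unname(ival[2]), 0.063, tolerance = 0.02)
})

test_that("t-test shift calibration inverts noncentral-t power", {
  # independent oracle: direct noncentral-t power at the calibrated delta
  ncp_power <- function(delta, n, alpha = 0.05) {
    df <- 2 * n - 2
    crit <- qt(1 - alpha / 2, df)
    ncp <- delta * sqrt(n / 2)
    pt(crit, df, ncp = ncp, lower.tail = FALSE) + pt(-crit, df, ncp = ncp)
  }
  for (n in c(2, 5, 50, 200)) {
    delta <- calibrate_delta_ttest(n)
    expect_equal(ncp_power(delta, n), 0.8, tolerance = 1e-6)
  }
  expect_equal(calibrate_delta_ttest(50), 0.566, tolerance = 1e-3)
  # monotone: larger delta -> more power, so calibrated delta shrinks in n
  expect_true(all(diff(vapply(c(2, 5, 20, 100), calibrate_delta_ttest,
                              numeric(1))) < 0))
  # normal limit
  n <- 5000
  expect_equal(calibrate_delta_ttest(n),
               (qnorm(0.975) + qnorm(0.8)) * sqrt(2 / n), tolerance = 1e-3)
})

test_that("proportion calibration inverts the pooled-approximation power", {
  # independent oracle: recompute the pooled two-sample proportion power
  pooled_power <- function(p1, p2, n, alpha = 0.05) {
    z <- qnorm(1 - alpha / 2)
    pbar <- (p1 + p2) / 2
    s0 <- sqrt(2 * pbar * (1 - pbar))
    s1 <- sqrt(p1 * (1 - p1) + p2 * (1 - p2))
    pnorm((sqrt(n) * abs(p1 - p2) - z * s0) / s1) +
      pnorm((-sqrt(n) * abs(p1 - p2) - z * s0) / s1)
  }
  for (pi0 in c(0.1, 0.3, 0.5)) {
    pi1 <- calibrate_prop_test(pi0, 100)
    expect_gt(pi1, pi0)
    expect_equal(pooled_power(pi0, pi1, 100), 0.8, tolerance = 1e-6)
  }
  # the classical pooled formula is the one behind stats::power.prop.test
  # (both roots found numerically, hence the root-finder-level tolerance)
  expect_equal(calibrate_prop_test(0.5, 100),
               power.prop.test(n = 100, p1 = 0.5, power = 0.8)$p2,
               tolerance = 1e-4)
  expect_equal(calibrate_prop_test(0.5, 100), 0.6932, tolerance = 1e-3)
  # pi1 approaches pi0 as n grows
  expect_lt(calibrate_prop_test(0.3, 10000) - 0.3,
            calibrate_prop_test(0.3, 100) - 0.3)
  # symmetry at pi0 = 1/2: lower root mirrors the upper root
  f <- function(p1) pooled_power(0.5, p1, 100) - 0.8
  lower_root <- uniroot(f, c(1e-9, 0.5 - 1e-9), tol = 1e-9)$root
  expect_equal(lower_root, 1 - calibrate_prop_test(0.5, 100),
               tolerance = 1e-6)
  expect_error(calibrate_prop_test(0.5, 2, power = 0.999), "unattainable")
})

test_that("scenario size profiles follow the design rules", {
  sc <- gm_scenario("continuous", "lm", I = 5, n = 10)
  expect_equal(sc$sizes, rep(10L, 5))
  # unbalanced null alternates n and n/2
  sc2 <- gm_scenario("continuous", "lm", I = 5, n = 10, unbalanced = TRUE)
  expect_equal(sc2$sizes, c(10L, 5L, 10L, 5L, 10L))
  # unbalanced power halves the deviating center
  sc3 <- gm_scenario("continuous", "lm", I = 5, n = 10, delta = 1,
                     deviating_center = 3, unbalanced = TRUE)
  expect_equal(sc3$sizes, c(10L, 10L, 5L, 10L, 10L))
})

test_that("simulated datasets honor the scenario", {
  set.seed(31)
  sc <- gm_scenario("ordinal", "nparcomp", I = 4, n = 6)
  d <- gm_simulate_data(sc)
  expect_equal(nrow(d), 24)
  expect_true(all(d$value == round(d$value)))
  # round-half-even at 0 digits
  expect_equal(round(c(0.4, -1.6, 2.2)), c(0, -2, 2))
  expect_equal(round(c(0.5, 1.5, 2.5)), c(0, 2, 2))
  # binomial counts bounded by totals
  scb <- gm_scenario("binomial", "glm", I = 5, n = 20, pi0 = 0.3,
                     delta = 0.6)
  db <- gm_simulate_data(scb)
  expect_true(all(db$events >= 0 & db$events <= db$total))
  # exactly one deviating center under the alternative
  scc <- gm_scenario("continuous", "lm", I = 3, n = 5000, delta = 1,
                     deviating_center = 2)
  dc <- gm_simulate_data(scc)
  mns <- tapply(dc$value, dc$center, mean)
  expect_equal(as.numeric(round(mns)), c(0, 1, 0))
})

test_that("a single replicate yields a degenerate rate", {
  res <- run_gm_study(gm_scenario("continuous", "lm", I = 3, n = 10),
                      reps = 1, seed = 4)
  expect_true(res$rejection_rate %in% c(0, 1))
})

test_that("studies are reproducible for identical master seeds", {
  scs <- list(gm_scenario("continuous", "lm", I = 5, n = 4),
              gm_scenario("ordinal", "nparcomp", I = 5, n = 4))
  r1 <- run_gm_study(scs, reps = 30, seed = 7)
  r2 <- run_gm_study(scs, reps = 30, seed = 7)
  expect_identical(r1, r2)
  r3 <- run_gm_study(scs, reps = 30, seed = 8)
  expect_false(identical(r1$rejection_rate, r3$rejection_rate))
})

test_that("failed fits are counted and handled by the chosen rule", {
  # tiny n * pi: plain GLM separation is near-certain
  sc <- gm_scenario("binomial", "glm", I = 5, n = 5, pi0 = 0.05)
  res <- run_gm_study(sc, reps = 20, seed = 2)
  expect_gt(res$n_failed_fits, 0)
  expect_equal(res$reps_used, 20)
  res2 <- run_gm_study(sc, reps = 20, seed = 2, failed_fits = "drop")
  expect_equal(res2$reps_used, 20 - res2$n_failed_fits)
})

test_that("power grows with sample size at a fixed effect", {
  scs <- lapply(c(4, 10, 30), function(n)
    gm_scenario("continuous", "lm", I = 5, n = n, delta = 1))
  res <- run_gm_study(scs, reps = 150, seed = 12)
  expect_true(all(diff(res$rejection_rate) > -2 * max(res$mc_std_error)))
})

test_that("plots and result tables stay consistent", {
  res <- run_gm_study(gm_scenario("continuous", "lm", I = 3, n = 10),
                      reps = 20, seed = 5)
  p <- plot_gm_study(res)
  expect_s3_class(p, "ggplot")
  expect_true(all(c("rejection_rate", "mc_std_error", "n_failed_fits")
                  %in% names(res)))
  expect_equal(res$mc_std_error,
               sqrt(res$rejection_rate * (1 - res$rejection_rate) /
                      res$reps_used))
})
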