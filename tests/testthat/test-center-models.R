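test_that("linear backend recovers means, pooled variance and df", {
  d <- data.frame(center = c("A", "A", "B", "B"), value = c(0, 2, 4, 6))
  fit <- fit_center_lm(d)
  expect_equal(unname(fit$estimates), c(1, 5))
  expect_equal(fit$extra$sigma2, 2)
  expect_equal(fit$df, 2)
  expect_equal(unname(diag(fit$vcov)), c(1, 1))
  expect_equal(fit$scale, "identity")
})

test_that("linear backend agrees with stats::lm cell-means fit", {
  set.seed(5)
  d <- make_long(c(0, 1, -0.5), n = c(8, 12, 5))
  fit <- fit_center_lm(d)
  ref <- lm(value ~ 0 + center, data = d)
  expect_equal(unname(fit$estimates), unname(coef(ref)), tolerance = 1e-10)
  expect_equal(unname(fit$vcov), unname(vcov(ref)), tolerance = 1e-10)
  expect_equal(fit$df, ref$df.residual)
})

test_that("linear backend handles missing data and degenerate inputs", {
  d <- data.frame(center = c("A", "A", "A", "B", "B", "C"),
                  value = c(1, 2, NA, 3, 4, NA))
  expect_warning(fit <- fit_center_lm(d), "excluded")
  expect_equal(fit$labels, c("A", "B"))
  expect_equal(fit$extra$n_missing_dropped, 2)
  # all observations equal: zero pooled variance, degenerate path downstream
  d2 <- data.frame(center = rep(c("A", "B"), each = 3), value = rep(7, 6))
  fit2 <- fit_center_lm(d2)
  expect_equal(fit2$extra$sigma2, 0)
  dev <- apply_contrasts(fit2)
  expect_true(all(is.na(dev$t_stats)))
  # no residual df
  d3 <- data.frame(center = c("A", "B"), value = c(1, 2))
  expect_error(fit_center_lm(d3), "residual degrees of freedom")
})

test_that("plain GLM matches saturated logits and refuses separation", {
  b <- make_binomial(c(3, 5), c(10, 10))
  fit <- fit_center_glm(b)
  expect_equal(unname(fit$estimates), c(log(3 / 7), 0))
  expect_equal(unname(diag(fit$vcov)), c(1 / 3 + 1 / 7, 1 / 5 + 1 / 5))
  expect_identical(fit$df, Inf)
  # y = n/2 gives logit 0 and variance 4/n
  fit2 <- fit_center_glm(make_binomial(c(10, 20), c(20, 40)))
  expect_equal(unname(fit2$estimates), c(0, 0))
  expect_equal(unname(diag(fit2$vcov)), c(4 / 20, 4 / 40))
  expect_error(fit_center_glm(make_binomial(c(0, 5), c(10, 10))),
               "Separation.*A.*brglm")
  expect_error(fit_center_glm(make_binomial(c(3, 10), c(10, 10))),
               "Separation")
})

test_that("plain GLM agrees with stats::glm cell-means fit", {
  b <- make_binomial(c(3, 5, 12), c(10, 11, 40))
  fit <- fit_center_glm(b)
  ref <- glm(cbind(events, total - events) ~ 0 + center, data = b,
             family = binomial())
  expect_equal(unname(fit$estimates), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(diag(fit$vcov)), unname(diag(vcov(ref))),
               tolerance = 1e-6)
})

test_that("Firth fit equals the add-half closed form in the one-way layout", {
  set.seed(8)
  for (rep in 1:10) {
    I <- sample(2:8, 1)
    total <- sample(3:60, I, replace = TRUE)
    events <- vapply(total, function(n) sample(0:n, 1), integer(1))
    fit <- fit_center_brglm(make_binomial(events, total))
    closed <- log((events + 0.5) / (total - events + 0.5))
    expect_equal(unname(fit$estimates), closed, tolerance = 1e-6)
    expect_true(all(is.finite(fit$estimates)))
    expect_true(all(is.finite(diag(fit$vcov))))
  }
  # y = 0, n = 10 oracle
  f <- fit_center_brglm(make_binomial(c(0, 5), c(10, 10)))
  expect_equal(unname(f$estimates)[1], log(0.5 / 10.5), tolerance = 1e-6)
})

test_that("Firth correction vanishes for large symmetric counts", {
  f_firth <- fit_center_brglm(make_binomial(c(500, 400), c(1000, 800)))
  f_glm <- fit_center_glm(make_binomial(c(500, 400), c(1000, 800)))
  expect_equal(unname(f_firth$estimates), unname(f_glm$estimates),
               tolerance = 2e-3)
})

test_that("all-zero-event centers get finite equal Firth estimates", {
  f <- fit_center_brglm(make_binomial(c(0, 0, 0), c(12, 12, 12)))
  expect_true(all(is.finite(f$estimates)))
  expect_equal(max(f$estimates) - min(f$estimates), 0, tolerance = 1e-8)
})

test_that("Cauchy-prior fit is finite under separation and tracks the GLM
           for moderate counts", {
  f <- fit_center_bayesglm(make_binomial(c(0, 4, 8), c(25, 30, 40)))
  expect_true(all(is.finite(f$estimates)))
  expect_true(all(is.finite(diag(f$vcov))))
  # identical centers with moderate counts: prior influence negligible
  b <- make_binomial(rep(20, 4), rep(100, 4))
  f2 <- fit_center_bayesglm(b)
  expect_true(all(abs(f2$estimates - log(20 / 80)) < 0.05))
})

test_that("stronger priors shrink estimates monotonically", {
  b <- make_binomial(c(2, 30), c(40, 40))
  scales <- c(10, 2.5, 1, 0.25)
  # effect of the second center relative to the first shrinks with the prior
  eff <- vapply(scales, function(s) {
    f <- fit_center_bayesglm(b, prior_scale = s)
    unname(diff(f$estimates))
  }, numeric(1))
  expect_true(all(diff(eff) < 0))
})

test_that("binomial backends are equivariant under success/failure swap", {
  b <- make_binomial(c(0, 7, 19), c(20, 25, 30))
  swapped <- make_binomial(b$total - b$events, b$total)
  for (f in list(fit_center_brglm, fit_center_bayesglm)) {
    expect_equal(unname(f(b)$estimates), -unname(f(swapped)$estimates),
                 tolerance = 1e-6)
  }
  b2 <- make_binomial(c(4, 7, 19), c(20, 25, 30))
  swapped2 <- make_binomial(b2$total - b2$events, b2$total)
  expect_equal(unname(fit_center_glm(b2)$estimates),
               -unname(fit_center_glm(swapped2)$estimates), tolerance = 1e-10)
})

test_that("bias-reduced and Bayesian fits match plain GLM for large counts", {
  # the add-half shift is about 0.5 (1/y - 1/(n-y)) on the logit scale, so
  # agreement to 3 decimals needs counts in the hundreds
  b <- make_binomial(c(500, 600, 750), c(1500, 1800, 2250))
  m_glm <- fit_center_glm(b)$estimates
  expect_equal(unname(fit_center_brglm(b)$estimates), unname(m_glm),
               tolerance = 1e-3)
  expect_equal(unname(fit_center_bayesglm(b)$estimates), unname(m_glm),
               tolerance = 1e-3)
})

test_that("center relabeling permutes linear estimates", {
  set.seed(9)
  d <- make_long(c(0, 1, 2), n = 6)
  fit <- fit_center_lm(d)
  d2 <- d
  d2$center <- chartr("ABC", "CAB", d2$center)  # relabel
  fit2 <- fit_center_lm(d2)
  expect_equal(sort(unname(fit$estimates)), sort(unname(fit2$estimates)))
})
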