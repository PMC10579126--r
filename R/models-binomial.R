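#' Aggregated binomial center data
#'
#' Validates per-center event counts: `events` successes out of `total`
#' subjects, \eqn{Y_i \sim Binomial(n_i, \pi_i)}. All binomial backends
#' model the center logits \eqn{m_i = \log(\pi_i / (1 - \pi_i))}.
#'
#' @param data Data frame with one row per center.
#' @param center,events,total Column names (tidy-eval).
#' @return A tibble with columns `center`, `events`, `total`, sorted by
#'   center label.
#' @export
as_binomial_data <- function(data, center = center, events = events,
                             total = total) {
  d <- dplyr::transmute(as.data.frame(data),
                        center = as.character({{ center }}),
                        events = as.numeric({{ events }}),
                        total = as.numeric({{ total }}))
  if (!nrow(d)) stop("No rows in `data`.", call. = FALSE)
  if (any(is.na(d$center) | d$center == "")) {
    stop("Empty or missing center labels are not allowed.", call. = FALSE)
  }
  if (anyDuplicated(d$center)) {
    stop("Duplicated center labels in aggregated binomial data.",
         call. = FALSE)
  }
  if (anyNA(d$events) || anyNA(d$total) ||
      any(d$events != round(d$events)) || any(d$total != round(d$total)) ||
      any(d$total < 1) || any(d$events < 0) || any(d$events > d$total)) {
    stop("Need integer counts with 0 <= events <= total and total >= 1.",
         call. = FALSE)
  }
  tibble::as_tibble(d[order(d$center), , drop = FALSE])
}

#' Binomial logit GLM fit (maximum likelihood)
#'
#' Saturated one-way logistic model: \eqn{\hat m_i = \log(y_i/(n_i - y_i))}
#' with covariance \eqn{diag(1/y_i + 1/(n_i - y_i))} and an asymptotic
#' (multivariate normal) reference. Centers with zero events or zero
#' non-events have infinite logits, so the fit refuses such data and points
#' to the bias-reduced or Bayesian backends.
#'
#' @inheritParams as_binomial_data
#' @return A [new_center_fit()] with `scale = "logit"`, `df = Inf`.
#' @export
fit_center_glm <- function(data, center = center, events = events,
                           total = total) {
  d <- as_binomial_data(data, {{ center }}, {{ events }}, {{ total }})
  bad <- d$events == 0 | d$events == d$total
  if (any(bad)) {
    stop("Separation: center(s) ", paste(d$center[bad], collapse = ", "),
         " have 0 events or 0 non-events, so the ML logit and its standard ",
         "error are infinite. Use method 'brglm' or 'bayesglm' instead.",
         call. = FALSE)
  }
  m <- log(d$events / (d$total - d$events))
  v <- 1 / d$events + 1 / (d$total - d$events)
  new_center_fit(estimates = m,
                 vcov = diag(v, nrow = nrow(d)),
                 scale = "logit",
                 df = Inf,
                 center_sizes = d$total,
                 labels = d$center,
                 method = "glm")
}

# Firth-penalized logistic IRLS for grouped binomial data with an arbitrary
# design matrix: solves the adjusted score X'(y - n*mu + h*(1/2 - mu)) = 0,
# h the hat diagonals of W^{1/2} X (X'WX)^{-1} X' W^{1/2}.
firth_logit_irls <- function(X, y, n, max_iter = 100L, tol = 1e-8) {
  p <- ncol(X)
  beta <- rep(0, p)
  trace <- numeric(max_iter)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- n * mu * (1 - mu)
    XtWX <- crossprod(X, X * w)
    XtWX_inv <- solve(XtWX)
    h <- rowSums((X %*% XtWX_inv) * X) * w
    score <- crossprod(X, y - n * mu + h * (0.5 - mu))
    delta <- drop(XtWX_inv %*% score)
    # dampen overly large steps to keep the iteration stable at tiny counts
    step <- max(abs(delta))
    if (step > 5) delta <- delta * 5 / step
    beta <- beta + delta
    trace[it] <- max(abs(score))
    if (max(abs(score)) < tol && max(abs(delta)) < sqrt(tol)) {
      eta <- drop(X %*% beta)
      mu <- stats::plogis(eta)
      w <- n * mu * (1 - mu)
      return(list(beta = beta, vcov = solve(crossprod(X, X * w)),
                  iterations = it))
    }
  }
  stop("Firth-penalized IRLS did not converge after ", max_iter,
       " iterations; score trace: ",
       paste(signif(trace[seq_len(min(10L, max_iter))], 3), collapse = ", "),
       call. = FALSE)
}

#' Firth bias-reduced logistic fit of center logits
#'
#' Iteratively reweighted least squares with Firth's hat-value score
#' adjustment, which penalizes the likelihood by Jeffreys' prior and always
#' yields finite logits and standard errors, including for centers with 0
#' events or all events. In the saturated one-way layout the solution
#' coincides with adding 1/2 to both successes and failures:
#' \eqn{\hat m_i = \log((y_i + 1/2)/(n_i - y_i + 1/2))}.
#'
#' @inheritParams as_binomial_data
#' @param max_iter,tol Iteration cap and score-convergence tolerance.
#' @return A [new_center_fit()] with `scale = "logit"`, `df = Inf`.
#' @export
fit_center_brglm <- function(data, center = center, events = events,
                             total = total, max_iter = 100L, tol = 1e-8) {
  d <- as_binomial_data(data, {{ center }}, {{ events }}, {{ total }})
  I <- nrow(d)
  if (I < 2L) stop("At least 2 centers are required.", call. = FALSE)
  X <- diag(1, I)
  res <- firth_logit_irls(X, d$events, d$total, max_iter = max_iter,
                          tol = tol)
  new_center_fit(estimates = res$beta,
                 vcov = res$vcov,
                 scale = "logit",
                 df = Inf,
                 center_sizes = d$total,
                 labels = d$center,
                 method = "brglm",
                 extra = list(iterations = res$iterations))
}

#' Bayesian logistic fit with Cauchy priors (posterior mode)
#'
#' Weakly informative independent Cauchy priors on the coefficients of an
#' intercept + center-effect parameterization: a wide prior (scale 10) on
#' the intercept, which plays the role of a baseline logit, and scale 2.5
#' priors on the center effects, so extreme center logits are shrunk and
#' their standard errors stay finite even with 0 events. The posterior mode
#' is found by penalized IRLS with the Cauchy priors handled as scale
#' mixtures of normals via EM updates of the prior precisions. The fitted
#' coefficients and their penalized-information covariance are mapped
#' linearly back to the center logits.
#'
#' @inheritParams as_binomial_data
#' @param prior_scale Cauchy scale of the center-effect priors.
#' @param prior_scale_intercept Cauchy scale of the intercept prior.
#' @param prior_df Prior degrees of freedom (1 = Cauchy).
#' @param max_iter,tol Iteration cap and coefficient-change tolerance.
#' @return A [new_center_fit()] with `scale = "logit"`, `df = Inf`.
#' @export
fit_center_bayesglm <- function(data, center = center, events = events,
                                total = total,
                                prior_scale = 2.5,
                                prior_scale_intercept = 10,
                                prior_df = 1,
                                max_iter = 200L, tol = 1e-8) {
  d <- as_binomial_data(data, {{ center }}, {{ events }}, {{ total }})
  I <- nrow(d)
  if (I < 2L) stop("At least 2 centers are required.", call. = FALSE)
  stopifnot(prior_scale > 0, prior_scale_intercept > 0, prior_df > 0)
  # intercept + treatment-coded center effects (first center is baseline)
  X <- cbind(1, rbind(0, diag(1, I - 1L)))
  s <- c(prior_scale_intercept, rep(prior_scale, I - 1L))
  nu <- prior_df
  y <- d$events
  n <- d$total
  beta <- rep(0, ncol(X))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- n * mu * (1 - mu)
    # EM step for the t-prior scale mixture: conditional prior precisions
    lambda <- (nu + 1) / (nu * s^2 + beta^2)
    XtWX <- crossprod(X, X * w)
    rhs <- XtWX %*% beta + crossprod(X, y - n * mu)
    beta_new <- drop(solve(XtWX + diag(lambda, ncol(X)), rhs))
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop("Penalized IRLS/EM for the Cauchy-prior fit did not converge ",
         "after ", max_iter, " iterations.", call. = FALSE)
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- n * mu * (1 - mu)
  lambda <- (nu + 1) / (nu * s^2 + beta^2)
  Sigma <- solve(crossprod(X, X * w) + diag(lambda, ncol(X)))
  # map coefficients to center logits with full covariance propagation
  A <- X
  m <- drop(A %*% beta)
  V <- A %*% Sigma %*% t(A)
  new_center_fit(estimates = m,
                 vcov = V,
                 scale = "logit",
                 df = Inf,
                 center_sizes = d$total,
                 labels = d$center,
                 method = "bayesglm",
                 extra = list(iterations = it,
                              prior_scale = prior_scale,
                              prior_scale_intercept = prior_scale_intercept,
                              prior_df = prior_df))
}
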