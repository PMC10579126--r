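#' Grand-Mean contrast matrix
#'
#' Builds the K x I matrix of contrast coefficients that compares every
#' center parameter \eqn{m_k} with the sample-size-weighted Grand Mean
#' \eqn{m_. = \sum_i (n_i/N) m_i}. Row \eqn{k} carries \eqn{1 - n_k/N} in
#' column \eqn{k} and \eqn{-n_i/N} elsewhere, so each row sums to zero and
#' \eqn{d_k = c_k' m = m_k - m_.}. One contrast is produced per center
#' (\eqn{K = I}).
#'
#' @param center_sizes Integer vector of per-center sample sizes \eqn{n_i}
#'   (all at least 1, length at least 2).
#' @param labels Optional character vector of center labels; defaults to the
#'   names of `center_sizes` or `"C1", "C2", ...`.
#'
#' @return A numeric matrix of class `"gm_contrast_matrix"` with attributes
#'   `center_sizes`, `total_n` and dimnames naming the centers.
#'
#' @examples
#' gm_contrast_matrix(c(50, 100, 50))
#' @export
gm_contrast_matrix <- function(center_sizes, labels = NULL) {
  if (length(center_sizes) < 2L) {
    stop("Grand-Mean contrasts need at least 2 centers, got ",
         length(center_sizes), ".", call. = FALSE)
  }
  if (anyNA(center_sizes) || any(center_sizes < 1) ||
      any(center_sizes != round(center_sizes))) {
    stop("`center_sizes` must be positive integers.", call. = FALSE)
  }
  n <- as.numeric(center_sizes)
  I <- length(n)
  N <- sum(n)
  if (is.null(labels)) {
    labels <- names(center_sizes)
    if (is.null(labels)) labels <- paste0("C", seq_len(I))
  }
  C <- matrix(rep(-n / N, each = I), nrow = I, ncol = I)
  diag(C) <- 1 - n / N
  dimnames(C) <- list(labels, labels)
  structure(C,
            center_sizes = as.integer(center_sizes),
            total_n = as.integer(N),
            class = c("gm_contrast_matrix", "matrix", "array"))
}

#' Center-level model fit container
#'
#' Uniform container produced by every estimation backend: center parameter
#' estimates \eqn{\hat m} on a stated scale, their covariance \eqn{\hat V},
#' and the degrees of freedom that drive the reference distribution of the
#' simultaneous tests (finite df: multivariate t; infinite: multivariate
#' normal).
#'
#' @param estimates Numeric vector of center-level estimates \eqn{\hat m_i}.
#' @param vcov Symmetric positive semidefinite covariance matrix \eqn{\hat V}.
#' @param scale One of `"identity"`, `"logit"`, `"relative_effect"`.
#' @param df Positive degrees of freedom, or `Inf` for asymptotic normality.
#' @param center_sizes Integer vector of per-center sample sizes.
#' @param labels Character vector of center labels.
#' @param method Character label of the backend that produced the fit.
#' @param extra Optional named list of backend-specific diagnostics.
#'
#' @return An object of class `"center_fit"`.
#' @export
new_center_fit <- function(estimates, vcov, scale, df, center_sizes,
                           labels = NULL, method = "unknown", extra = list()) {
  I <- length(estimates)
  vcov <- as.matrix(vcov)
  if (!all(dim(vcov) == I)) {
    stop("`vcov` must be ", I, " x ", I, " to match `estimates`.",
         call. = FALSE)
  }
  if (length(center_sizes) != I) {
    stop("`center_sizes` length must match `estimates`.", call. = FALSE)
  }
  if (max(abs(vcov - t(vcov))) > 1e-8 * (1 + max(abs(vcov)))) {
    stop("`vcov` must be symmetric.", call. = FALSE)
  }
  vcov <- (vcov + t(vcov)) / 2
  ev <- eigen(vcov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop("`vcov` must be positive semidefinite.", call. = FALSE)
  }
  scale <- match.arg(scale, c("identity", "logit", "relative_effect"))
  if (!(is.numeric(df) && length(df) == 1L && (df > 0 || is.infinite(df)))) {
    stop("`df` must be a positive number or Inf.", call. = FALSE)
  }
  if (is.null(labels)) labels <- paste0("C", seq_len(I))
  structure(
    list(estimates = stats::setNames(as.numeric(estimates), labels),
         vcov = vcov,
         scale = scale,
         df = df,
         center_sizes = stats::setNames(as.integer(center_sizes), labels),
         labels = as.character(labels),
         method = method,
         extra = extra),
    class = "center_fit")
}

#' @export
print.center_fit <- function(x, ...) {
  cat("Center-level fit (", x$method, "), scale: ", x$scale,
      ", df: ", format(x$df), "\n", sep = "")
  print(tibble::tibble(center = x$labels,
                       n = as.integer(x$center_sizes),
                       estimate = unname(x$estimates),
                       std_error = sqrt(pmax(diag(x$vcov), 0))))
  invisible(x)
}

#' Tidy a center-level fit
#'
#' @param x A `center_fit`.
#' @param ... Unused.
#' @return A tibble with one row per center: label, size, estimate and its
#'   standard error on the fit's scale.
#' @exportS3Method generics::tidy
tidy.center_fit <- function(x, ...) {
  tibble::tibble(center = x$labels,
                 n = as.integer(x$center_sizes),
                 estimate = unname(x$estimates),
                 std_error = sqrt(pmax(diag(x$vcov), 0)),
                 scale = x$scale)
}

# diagonal of U below this is treated as a degenerate (zero-variance) contrast
.gm_zero_var_tol <- 1e-12

#' Propagate a center fit through the Grand-Mean contrasts
#'
#' Computes the deviations \eqn{\hat d = C \hat m}, their covariance
#' \eqn{\hat U = C \hat V C'}, standard errors, the correlation matrix
#' \eqn{\hat R} used by the simultaneous tests, and the t statistics
#' \eqn{t_k = \hat d_k / se(\hat d_k)}.
#'
#' Contrasts whose variance falls below `1e-12` are reported with `NA`
#' t statistics rather than infinite values.
#'
#' @param fit A [new_center_fit()] object.
#' @param C A [gm_contrast_matrix()]; defaults to the matrix implied by the
#'   fit's center sizes.
#'
#' @return An object of class `"gm_deviations"`: a list with elements
#'   `deviations`, `vcov`, `std_errors`, `correlation`, `t_stats`, `df`,
#'   `center_sizes`, `labels`, `scale`, `method`.
#' @export
apply_contrasts <- function(fit, C = NULL) {
  stopifnot(inherits(fit, "center_fit"))
  if (is.null(C)) C <- gm_contrast_matrix(fit$center_sizes, fit$labels)
  I <- length(fit$estimates)
  if (ncol(C) != I) {
    stop("Contrast matrix has ", ncol(C), " columns but the fit has ",
         I, " centers.", call. = FALSE)
  }
  if (!identical(as.integer(attr(C, "center_sizes")),
                 as.integer(unname(fit$center_sizes)))) {
    stop("Center sizes of the contrast matrix and the fit disagree; ",
         "build the matrix from the same data (same center order).",
         call. = FALSE)
  }
  Cm <- unclass(C)
  d <- drop(Cm %*% fit$estimates)
  U <- Cm %*% fit$vcov %*% t(Cm)
  U <- (U + t(U)) / 2
  u <- diag(U)
  degenerate <- u < .gm_zero_var_tol
  se <- sqrt(pmax(u, 0))
  if (any(degenerate & abs(d) > 1e-8)) {
    stop("Degenerate variance: contrast(s) ",
         paste(fit$labels[degenerate & abs(d) > 1e-8], collapse = ", "),
         " have zero standard error but nonzero deviation.", call. = FALSE)
  }
  # correlation only over non-degenerate contrasts; degenerate rows kept as NA
  R <- matrix(NA_real_, I, I, dimnames = dimnames(U))
  ok <- !degenerate
  if (any(ok)) {
    s <- se[ok]
    R[ok, ok] <- U[ok, ok, drop = FALSE] / tcrossprod(s)
    diag(R)[ok] <- 1
  }
  t_stats <- ifelse(degenerate, NA_real_, d / ifelse(se > 0, se, NA_real_))
  structure(
    list(deviations = stats::setNames(d, fit$labels),
         vcov = U,
         std_errors = stats::setNames(ifelse(degenerate, 0, se), fit$labels),
         correlation = R,
         t_stats = stats::setNames(t_stats, fit$labels),
         df = fit$df,
         center_sizes = fit$center_sizes,
         labels = fit$labels,
         scale = fit$scale,
         method = fit$method,
         degenerate = stats::setNames(degenerate, fit$labels)),
    class = "gm_deviations")
}

#' @export
print.gm_deviations <- function(x, ...) {
  cat("Deviations from the Grand Mean (", x$method, ", scale ", x$scale,
      ", df ", format(x$df), ")\n", sep = "")
  print(tibble::tibble(center = x$labels,
                       deviation = unname(x$deviations),
                       std_error = unname(x$std_errors),
                       t_stat = unname(x$t_stats)))
  invisible(x)
}
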