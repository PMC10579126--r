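#' One-way linear model fit of center means
#'
#' Cell-means one-way layout \eqn{Y_{ij} = m_i + e_{ij}},
#' \eqn{e_{ij} \sim N(0, \sigma^2)}: estimates are the center sample means,
#' the covariance is \eqn{s^2 \, diag(1/n_i)} with the pooled residual
#' variance \eqn{s^2}, and the residual degrees of freedom \eqn{N - I} feed
#' the multivariate t reference of the simultaneous tests. With normal
#' errors this backend makes the Grand-Mean comparison procedure exact.
#'
#' Missing outcome values are dropped per subject; centers left with no
#' observation are excluded with a warning.
#'
#' @param data A data frame in long format, one row per subject.
#' @param center,value Column names (tidy-eval) of the center label and the
#'   outcome.
#'
#' @return A [new_center_fit()] with `scale = "identity"`.
#' @export
fit_center_lm <- function(data, center = center, value = value) {
  d <- collect_long(data, {{ center }}, {{ value }})
  dropped <- attr(d, "n_missing")
  empty <- setdiff(attr(d, "all_centers"), unique(d$center))
  if (length(empty)) {
    warning("Center(s) with no non-missing outcome excluded: ",
            paste(empty, collapse = ", "), call. = FALSE)
  }
  split_vals <- split(d$value, d$center)
  labels <- names(split_vals)
  I <- length(labels)
  if (I < 2L) stop("At least 2 centers with data are required.", call. = FALSE)
  n <- lengths(split_vals)
  N <- sum(n)
  if (N <= I) {
    stop("No residual degrees of freedom: N = ", N, " observations for ",
         I, " centers.", call. = FALSE)
  }
  m <- vapply(split_vals, mean, numeric(1))
  rss <- sum(vapply(split_vals, function(v) sum((v - mean(v))^2), numeric(1)))
  s2 <- rss / (N - I)
  new_center_fit(estimates = m,
                 vcov = diag(s2 / n, nrow = I),
                 scale = "identity",
                 df = N - I,
                 center_sizes = n,
                 labels = labels,
                 method = "lm",
                 extra = list(sigma2 = s2, n_missing_dropped = dropped))
}

# shared long-format collection: validates, drops NA with bookkeeping,
# orders centers by sorted label so runs are reproducible
collect_long <- function(data, center, value) {
  d <- dplyr::transmute(as.data.frame(data),
                        center = as.character({{ center }}),
                        value = as.numeric({{ value }}))
  if (!nrow(d)) stop("No rows in `data`.", call. = FALSE)
  if (any(is.na(d$center) | d$center == "")) {
    stop("Empty or missing center labels are not allowed.", call. = FALSE)
  }
  all_centers <- sort(unique(d$center))
  keep <- !is.na(d$value)
  out <- d[keep, , drop = FALSE]
  out <- out[order(out$center), , drop = FALSE]
  attr(out, "n_missing") <- sum(!keep)
  attr(out, "all_centers") <- all_centers
  out
}
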