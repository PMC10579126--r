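#' Nonparametric relative effects of centers (pseudo-ranks)
#'
#' Estimates, for every center i, the relative effect
#' \eqn{p_i = P(X_G \le X_i)} - the probability that an observation from the
#' unweighted average distribution \eqn{G = (1/I) \sum_r F_r} of all centers
#' is smaller than (or, with ties, equal in the mid-distribution sense to)
#' an observation from center i. Mid-distribution functions (midranks /
#' pseudo-ranks) are used throughout, so heavily tied and ordinal data are
#' admissible. Effects are accompanied by the asymptotic covariance of
#' \eqn{\hat p} estimated from the empirical influence functions, and a
#' Satterthwaite-type degree of freedom for the multivariate-t reference.
#'
#' @param data Long-format data frame, one row per subject.
#' @param center,value Column names (tidy-eval).
#' @param df_method How the multivariate-t approximation df is formed from
#'   the per-center rank variance components: `"contrast_min"` (default)
#'   computes a Satterthwaite df for every Grand-Mean contrast and takes the
#'   smallest, which acknowledges that each contrast's variance is dominated
#'   by its own center's component; `"total"` pools all components into one
#'   global Satterthwaite df (more liberal for small centers).
#' @param df_floor Lower bound on the approximation degrees of freedom.
#'
#' @return A [new_center_fit()] with `scale = "relative_effect"`; the
#'   estimates are the \eqn{\hat p_i}, whose unweighted mean is always 1/2.
#' @export
fit_relative_effects <- function(data, center = center, value = value,
                                 df_method = c("contrast_min", "total"),
                                 df_floor = 2) {
  df_method <- match.arg(df_method)
  d <- collect_long(data, {{ center }}, {{ value }})
  split_vals <- split(d$value, d$center)
  labels <- names(split_vals)
  I <- length(labels)
  if (I < 2L) stop("At least 2 centers with data are required.", call. = FALSE)
  n <- lengths(split_vals)
  if (any(n < 2L)) {
    stop("Relative-effect variance estimation needs at least 2 observations ",
         "per center; offending center(s): ",
         paste(labels[n < 2L], collapse = ", "), call. = FALSE)
  }
  x <- unlist(split_vals, use.names = FALSE)
  g <- rep(seq_len(I), n)
  N <- length(x)

  # mid-distribution function of every center evaluated at every observation:
  # F[s, t] = (#(X_s < x_t) + 0.5 #(X_s = x_t)) / n_s
  Fmat <- matrix(0, I, N)
  for (s in seq_len(I)) {
    xs <- sort(split_vals[[s]])
    below <- findInterval(x, xs, left.open = TRUE)      # strict <= shifted
    upto <- findInterval(x, xs)                          # #(X_s <= x_t)
    # findInterval(x, xs, left.open=TRUE) counts xs < x (strict) when ties
    # are present at x itself
    Fmat[s, ] <- (below + 0.5 * (upto - below)) / n[s]
  }
  G <- colMeans(Fmat)
  p <- as.numeric(tapply(G, g, mean))

  # W[s, r] = int F_s dF_r, estimated by the mean of F_s over center r
  W <- matrix(0, I, I)
  for (r in seq_len(I)) {
    W[, r] <- rowMeans(Fmat[, g == r, drop = FALSE])
  }

  # empirical influence of each observation on each effect:
  # obs t in center r contributes (W[i, r] - F_i(x_t)) / I to p-hat_i (i != r)
  # and -(sum over s != r of that same term) to its own effect
  D <- matrix(0, N, I)
  for (t in seq_len(N)) {
    r <- g[t]
    gen <- (W[, r] - Fmat[, t]) / I
    gen[r] <- 0
    D[t, ] <- gen
    D[t, r] <- -sum(gen)
  }
  V <- matrix(0, I, I)
  var_comp <- numeric(I)
  S_list <- vector("list", I)
  for (r in seq_len(I)) {
    Sr <- stats::cov(D[g == r, , drop = FALSE])
    S_list[[r]] <- Sr
    V <- V + Sr / n[r]
    var_comp[r] <- sum(diag(Sr)) / n[r]
  }
  V <- (V + t(V)) / 2

  # Satterthwaite-type df from the per-center rank variance components
  df <- if (df_method == "total") {
    denom <- sum(var_comp^2 / (n - 1))
    if (denom > 0) sum(var_comp)^2 / denom else Inf
  } else {
    # per Grand-Mean contrast: Var(d_k) = sum_r c_k' S_r c_k / n_r; take the
    # smallest Satterthwaite df across the K contrasts
    C <- unclass(gm_contrast_matrix(n))
    df_k <- apply(C, 1, function(ck) {
      a <- vapply(seq_len(I), function(r)
        drop(crossprod(ck, S_list[[r]] %*% ck)) / n[r], numeric(1))
      den <- sum(a^2 / (n - 1))
      if (den > 0) sum(a)^2 / den else Inf
    })
    min(df_k)
  }
  df <- max(df, df_floor)

  new_center_fit(estimates = p,
                 vcov = V,
                 scale = "relative_effect",
                 df = df,
                 center_sizes = n,
                 labels = labels,
                 method = "nparcomp",
                 extra = list(n_missing_dropped = attr(d, "n_missing"),
                              variance_components = var_comp))
}
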