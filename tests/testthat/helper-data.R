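# shared fixture builders; everything is generated in code

make_long <- function(means, n, sd = 1, labels = NULL) {
  I <- length(means)
  if (length(n) == 1L) n <- rep(n, I)
  if (is.null(labels)) labels <- LETTERS[seq_len(I)]
  data.frame(center = rep(labels, n),
             value = stats::rnorm(sum(n), rep(means, n), sd))
}

make_binomial <- function(events, total, labels = NULL) {
  if (is.null(labels)) labels <- LETTERS[seq_along(events)]
  data.frame(center = labels, events = events, total = total)
}

# brute-force pairwise counting oracle for the unweighted relative effects:
# p_i = (1/I) sum_r P(X_r < X_i) + 0.5 P(X_r = X_i), including r = i
relative_effects_oracle <- function(values, groups) {
  groups <- as.character(groups)
  labs <- sort(unique(groups))
  I <- length(labs)
  vapply(labs, function(li) {
    xi <- values[groups == li]
    mean(vapply(labs, function(lr) {
      xr <- values[groups == lr]
      tot <- 0
      for (a in xr) for (b in xi) tot <- tot + (a < b) + 0.5 * (a == b)
      tot / (length(xr) * length(xi))
    }, numeric(1)))
  }, numeric(1))
}

# independence closed form for the equicoordinate two-sided normal quantile
indep_quantile_oracle <- function(alpha, K) {
  stats::qnorm((1 + (1 - alpha)^(1 / K)) / 2)
}

fast_settings <- gm_settings(prob_tolerance = 2.5e-3, maxpts = 10000L)
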