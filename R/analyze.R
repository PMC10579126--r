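#' Compare every center with the Grand Mean
#'
#' End-to-end pipeline: fit the requested backend, build the
#' sample-size-weighted Grand-Mean contrast matrix, propagate estimates and
#' covariance, compute the equicoordinate critical value, single-step
#' adjusted p-values and simultaneous confidence intervals, and classify
#' each center (optionally against equivalence margins).
#'
#' Valid method/outcome pairs: `lm` and `nparcomp` for `continuous`,
#' `nparcomp` for `ordinal`, and `glm`, `bayesglm`, `brglm` for `binary`
#' (aggregated events/total data).
#'
#' @param data Long-format subject-level data (`continuous`/`ordinal`) or
#'   per-center aggregated counts (`binary`).
#' @param outcome One of `"continuous"`, `"binary"`, `"ordinal"`.
#' @param method One of `"lm"`, `"glm"`, `"bayesglm"`, `"brglm"`,
#'   `"nparcomp"`.
#' @param center,value Columns for long-format data (tidy-eval).
#' @param events,total Columns for aggregated binomial data (tidy-eval).
#' @param margins Optional [gm_margins()] for equivalence classification.
#' @param settings A [gm_settings()]; set `alpha` and the integration seed
#'   here.
#' @param ... Passed to the backend fit function.
#'
#' @return A `gm_report`: a tibble with one row per center (columns
#'   `center`, `n`, `estimate`, `deviation`, `std_error`, `t_stat`,
#'   `adj_p`, `ci_lower`, `ci_upper`, `flag`, `within_margins`) carrying the
#'   critical value, degrees of freedom, scale, method and settings as
#'   attributes.
#'
#' @examples
#' set.seed(1)
#' d <- data.frame(center = rep(c("A", "B", "C"), each = 20),
#'                 value = rnorm(60) + rep(c(0, 0, 1), each = 20))
#' gm_analyze(d, outcome = "continuous", method = "lm")
#' @export
gm_analyze <- function(data,
                       outcome = c("continuous", "binary", "ordinal"),
                       method = c("lm", "glm", "bayesglm", "brglm",
                                  "nparcomp"),
                       center = center, value = value,
                       events = events, total = total,
                       margins = NULL,
                       settings = gm_settings(),
                       ...) {
  outcome <- match.arg(outcome)
  method <- match.arg(method)
  valid <- list(continuous = c("lm", "nparcomp"),
                binary = c("glm", "bayesglm", "brglm"),
                ordinal = "nparcomp")
  if (!method %in% valid[[outcome]]) {
    stop("Method '", method, "' is not available for ", outcome,
         " outcomes. Valid pairs: continuous - lm, nparcomp; binary - glm, ",
         "bayesglm, brglm; ordinal - nparcomp.", call. = FALSE)
  }
  fit <- switch(method,
    lm = fit_center_lm(data, {{ center }}, {{ value }}),
    nparcomp = fit_relative_effects(data, {{ center }}, {{ value }}, ...),
    glm = fit_center_glm(data, {{ center }}, {{ events }}, {{ total }}),
    brglm = fit_center_brglm(data, {{ center }}, {{ events }}, {{ total }},
                             ...),
    bayesglm = fit_center_bayesglm(data, {{ center }}, {{ events }},
                                   {{ total }}, ...))
  gm_report(fit, margins = margins, settings = settings)
}

#' Build a deviation report from a fitted backend
#'
#' Lower-level entry for users who already have a [new_center_fit()].
#'
#' @param fit A `center_fit`.
#' @param margins Optional [gm_margins()].
#' @param settings A [gm_settings()].
#' @return A `gm_report` tibble; see [gm_analyze()].
#' @export
gm_report <- function(fit, margins = NULL, settings = gm_settings()) {
  stopifnot(inherits(fit, "center_fit"))
  C <- gm_contrast_matrix(fit$center_sizes, fit$labels)
  dev <- apply_contrasts(fit, C)
  ok <- !dev$degenerate
  if (any(ok)) {
    Rok <- dev$correlation[ok, ok, drop = FALSE]
    q <- equicoordinate_quantile(Rok, alpha = settings$alpha, df = dev$df,
                                 settings = settings)
    p <- adjusted_pvalues(dev$t_stats, dev$correlation, df = dev$df,
                          settings = settings)
  } else {
    q <- NA_real_
    p <- rep(NA_real_, length(dev$t_stats))
  }
  ci <- if (is.na(q)) {
    tibble::tibble(center = dev$labels, lower = NA_real_, upper = NA_real_)
  } else {
    simultaneous_ci(dev, q)
  }
  ci$lower[dev$degenerate] <- NA_real_
  ci$upper[dev$degenerate] <- NA_real_
  cls <- classify_centers(ci$lower, ci$upper, margins)
  weights <- fit$center_sizes / sum(fit$center_sizes)
  out <- tibble::tibble(
    center = dev$labels,
    n = as.integer(fit$center_sizes),
    estimate = unname(fit$estimates),
    deviation = unname(dev$deviations),
    std_error = unname(dev$std_errors),
    t_stat = unname(dev$t_stats),
    adj_p = p,
    ci_lower = ci$lower,
    ci_upper = ci$upper,
    flag = cls$flag,
    within_margins = cls$within_margins)
  structure(out,
            class = c("gm_report", class(out)),
            method = fit$method,
            scale = fit$scale,
            alpha = settings$alpha,
            critical_value = q,
            df = dev$df,
            grand_mean = sum(weights * fit$estimates),
            margins = margins,
            settings = settings)
}

#' @export
print.gm_report <- function(x, ...) {
  cat("Grand-Mean deviation report -- method: ", attr(x, "method"),
      ", scale: ", attr(x, "scale"), "\n", sep = "")
  cat("alpha = ", attr(x, "alpha"),
      ", critical value q = ", signif(attr(x, "critical_value"), 5),
      ", df = ", format(round(attr(x, "df"), 2)),
      ", Grand Mean = ", signif(attr(x, "grand_mean"), 5), "\n", sep = "")
  m <- attr(x, "margins")
  if (!is.null(m)) {
    cat("equivalence margins: [", m$lower, ", ", m$upper, "]\n", sep = "")
  }
  NextMethod()
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.gm_report <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @exportS3Method generics::glance
glance.gm_report <- function(x, ...) {
  tibble::tibble(method = attr(x, "method"),
                 scale = attr(x, "scale"),
                 n_centers = nrow(x),
                 n_total = sum(x$n),
                 alpha = attr(x, "alpha"),
                 critical_value = attr(x, "critical_value"),
                 df = attr(x, "df"),
                 grand_mean = attr(x, "grand_mean"),
                 n_significant = sum(x$flag == "significant_deviation"),
                 n_equivalent = sum(x$flag == "equivalent"))
}

#' Forest plot of center deviations from the Grand Mean
#'
#' One simultaneous confidence interval per center around the zero line;
#' significant centers are highlighted, equivalence margins (when present)
#' are drawn as dashed lines.
#'
#' @param object A `gm_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.gm_report <- function(object, ...) {
  if (!nrow(object)) stop("Empty report: nothing to plot.", call. = FALSE)
  df <- tibble::as_tibble(object)
  df$center <- factor(df$center, levels = rev(df$center))
  df$significant <- df$flag == "significant_deviation"
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$deviation,
                                        y = .data$center,
                                        colour = .data$significant)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 1, colour = "grey40") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_lower,
                                         xmax = .data$ci_upper),
                            height = 0.25) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(
      x = paste0("Deviation from Grand Mean (", attr(object, "scale"),
                 " scale)"),
      y = NULL,
      title = "Simultaneous confidence intervals for center deviations",
      subtitle = paste0("method: ", attr(object, "method"),
                        ", 1 - alpha = ", 1 - attr(object, "alpha"))) +
    ggplot2::theme_minimal()
  m <- attr(object, "margins")
  if (!is.null(m)) {
    p <- p + ggplot2::geom_vline(xintercept = c(m$lower, m$upper),
                                 linetype = 2, colour = "steelblue")
  }
  p
}

#' @rdname autoplot.gm_report
#' @param report A `gm_report`.
#' @param path Output file (`.png`, `.svg` or `.pdf`).
#' @param width,height,dpi Device size passed to [ggplot2::ggsave()].
#' @return `path`, invisibly.
#' @export
plot_deviation_report <- function(report, path, width = 7, height = NULL,
                                  dpi = 150) {
  p <- autoplot.gm_report(report)
  if (is.null(height)) height <- max(2, 0.6 + 0.3 * nrow(report))
  ggplot2::ggsave(path, plot = p, width = width, height = height, dpi = dpi)
  invisible(path)
}
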