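#' Bland-Altman agreement analysis
#'
#' Treats the per-location means of the two measuring modalities as
#' paired measurements and summarises their agreement: the mean
#' difference `d_bar`, the sample standard deviation `s` of the
#' differences (n - 1 denominator), and the limits of agreement
#' `d_bar +/- 1.96 s`, between which ~95% of differences are expected
#' when the differences are approximately normal. The t-based confidence
#' interval of `d_bar` itself (`d_bar +/- t * s / sqrt(n)`) is reported
#' separately.
#'
#' @param physical_means,virtual_means Equal-length numeric vectors
#'   (mm), length >= 2; differences are virtual minus physical.
#' @return An object of class `"bland_altman"`: `d_bar`, `s`, `loa_low`,
#'   `loa_high`, `ci_dbar_low`, `ci_dbar_high`, `n`, and `pairs` (tibble
#'   of pair means and differences for plotting). [tidy()] returns the
#'   pairs, [glance()] the one-row statistics, [autoplot()] the plot.
#' @export
#' @examples
#' t1 <- table1_fixture()
#' glance(bland_altman(t1$mean_physical_mm, t1$mean_virtual_mm))
bland_altman <- function(physical_means, virtual_means) {
  if (length(physical_means) != length(virtual_means))
    abort("paired vectors must have equal length.",
          class = "orbitometry_validation_error")
  n <- length(physical_means)
  if (n < 2L) abort("need at least 2 pairs.",
                    class = "orbitometry_validation_error")
  d <- virtual_means - physical_means
  d_bar <- mean(d)
  s <- sd(d)
  tq <- qt(0.975, n - 1)
  structure(
    list(d_bar = d_bar, s = s,
         loa_low = d_bar - 1.96 * s, loa_high = d_bar + 1.96 * s,
         ci_dbar_low = d_bar - tq * s / sqrt(n),
         ci_dbar_high = d_bar + tq * s / sqrt(n),
         n = n,
         pairs = tibble::tibble(
           pair_mean = (physical_means + virtual_means) / 2,
           difference = d)),
    class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman: d_bar = %.3f mm, s = %.3f mm, LoA [%.3f, %.3f] (n = %d)\n",
    x$d_bar, x$s, x$loa_low, x$loa_high, x$n))
  invisible(x)
}

#' @describeIn bland_altman Pairs tibble (`pair_mean`, `difference`).
#' @param x A `"bland_altman"` object.
#' @param ... Unused.
#' @export
tidy.bland_altman <- function(x, ...) x$pairs

#' @describeIn bland_altman One-row tibble of the agreement statistics.
#' @export
glance.bland_altman <- function(x, ...) {
  tibble::tibble(d_bar = x$d_bar, s = x$s,
                 loa_low = x$loa_low, loa_high = x$loa_high,
                 ci_dbar_low = x$ci_dbar_low, ci_dbar_high = x$ci_dbar_high,
                 n = x$n)
}

#' @describeIn bland_altman Bland-Altman plot: differences against pair
#'   means, solid mean-difference line, dashed limits of agreement.
#' @param object A `"bland_altman"` object.
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$pair_mean, y = .data$difference)) +
    ggplot2::geom_hline(yintercept = object$d_bar, linewidth = 0.6) +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Pair mean (mm)",
                  y = "Difference, virtual - physical (mm)",
                  title = "Bland-Altman agreement") +
    ggplot2::theme_minimal()
}
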