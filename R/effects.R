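cohen_category <- function(d) {
  ad <- abs(d)
  dplyr::case_when(ad > 1.2 ~ "large",
                   ad > 0.5 ~ "medium",
                   ad > 0.01 ~ "small",
                   TRUE ~ "negligible")
}

effect_row <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- var(x); v2 <- var(y)
  if (v1 == 0 && v2 == 0)
    abort("Cohen's d undefined: zero variance in both groups.",
          class = "orbitometry_undefined_error")
  tt <- stats::t.test(y, x, var.equal = FALSE)
  vt <- stats::var.test(y, x)
  # report the variance ratio with the larger variance in the numerator
  if (vt$estimate < 1) {
    f <- 1 / vt$estimate
    df1 <- vt$parameter[["denom df"]]; df2 <- vt$parameter[["num df"]]
  } else {
    f <- vt$estimate
    df1 <- vt$parameter[["num df"]]; df2 <- vt$parameter[["denom df"]]
  }
  sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
  d <- if (sp == 0) 0 else (mean(y) - mean(x)) / sp
  tibble::tibble(
    n_physical = n1, n_virtual = n2,
    mean_physical_mm = mean(x), mean_virtual_mm = mean(y),
    t_welch = unname(tt$statistic), df_welch = unname(tt$parameter),
    p_value = tt$p.value,
    variance_ratio_F = unname(f),
    variance_df1 = unname(df1), variance_df2 = unname(df2),
    variance_p = vt$p.value,
    cohen_d = d, category = cohen_category(d)
  )
}

#' Compare physical and virtual measurements
#'
#' For every location, and pooled over all locations, tests whether the
#' virtual readings differ from the physical ones: Welch's t-test
#' (unequal variances, Welch-Satterthwaite degrees of freedom), a
#' two-sided variance-ratio F-test (larger variance reported in the
#' numerator), and Cohen's d with the pooled standard deviation.
#' Statistical significance is judged at the 1% level. Effect-size
#' categories: large for |d| > 1.2, medium > 0.5, small > 0.01, else
#' negligible.
#'
#' @param table A measurement tibble with both worlds, at least 2
#'   observations per world in every group compared.
#' @param alpha Significance level, default 0.01.
#' @return A tibble with one row per location plus a pooled row
#'   (`scope = "pooled"`, `location_id = NA`): sample sizes, means,
#'   Welch t/df/p, variance F/dfs/p, `cohen_d`, `category`, and logical
#'   `significant` / `variances_differ` at `alpha`.
#' @export
compare_worlds <- function(table, alpha = 0.01) {
  validate_measurements(table)
  split_xy <- function(df) {
    x <- df$diameter_mm[df$world == "physical"]
    y <- df$diameter_mm[df$world == "virtual"]
    if (length(x) < 2L || length(y) < 2L)
      abort("need >= 2 observations per world in every comparison.",
            class = "orbitometry_design_error")
    list(x = x, y = y)
  }
  per_loc <- table |>
    dplyr::group_by(.data$location_id) |>
    dplyr::group_modify(function(df, key) {
      xy <- split_xy(df)
      effect_row(xy$x, xy$y)
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(scope = "location", .before = 1)
  xy <- split_xy(table)
  pooled <- effect_row(xy$x, xy$y) |>
    dplyr::mutate(scope = "pooled", location_id = NA_integer_, .before = 1)
  dplyr::bind_rows(per_loc, pooled) |>
    dplyr::mutate(significant = .data$p_value < alpha,
                  variances_differ = .data$variance_p < alpha)
}

#' Refinement summary of the virtual-world measurements
#'
#' The VR caliper logs how often each measurement was corrected before it
#' was saved; the refinement count is a confidence/skill proxy with no
#' physical-world counterpart. This summarises the grand mean and the
#' per-grader means (the bar-plot data).
#'
#' @param table A measurement tibble containing virtual records.
#' @return An object of class `"refinement_summary"`: `grand_mean`,
#'   `n`, and `per_grader` (tibble `grader_id`, `n`,
#'   `mean_refinements`). [tidy()] returns the per-grader tibble,
#'   [glance()] the grand mean.
#' @export
refinement_summary <- function(table) {
  validate_measurements(table)
  virt <- table[table$world == "virtual", ]
  if (nrow(virt) == 0L)
    abort("no virtual records: refinements are only logged in VR.",
          class = "orbitometry_design_error")
  per <- virt |>
    dplyr::group_by(.data$grader_id) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_refinements = mean(.data$refinements),
                     .groups = "drop")
  structure(list(grand_mean = mean(virt$refinements), n = nrow(virt),
                 per_grader = per),
            class = "refinement_summary")
}

#' @export
print.refinement_summary <- function(x, ...) {
  cat(sprintf("Mean refinements before save: %.2f over %d VR measurements\n",
              x$grand_mean, x$n))
  invisible(x)
}

#' @describeIn refinement_summary Per-grader tibble.
#' @param x A `"refinement_summary"`.
#' @param ... Unused.
#' @export
tidy.refinement_summary <- function(x, ...) x$per_grader

#' @describeIn refinement_summary One-row tibble with the grand mean.
#' @export
glance.refinement_summary <- function(x, ...) {
  tibble::tibble(grand_mean = x$grand_mean, n = x$n)
}

#' @describeIn refinement_summary Bar plot of per-grader mean refinement
#'   counts with the grand mean as a reference line.
#' @param object A `"refinement_summary"`.
#' @export
autoplot.refinement_summary <- function(object, ...) {
  ggplot2::ggplot(object$per_grader,
                  ggplot2::aes(x = .data$grader_id, y = .data$mean_refinements)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_hline(yintercept = object$grand_mean, linetype = "dashed") +
    ggplot2::labs(x = "VR grader", y = "Mean refinements before save",
                  title = "Caliper refinements in virtual reality") +
    ggplot2::theme_minimal()
}

#' Measurement spread by location and world
#'
#' Box plot of the raw diameters per location, split by world — the
#' at-a-glance view of where physical measurements scatter (worst at the
#' oblique intra-orbital location) while VR measurements stay tight.
#'
#' @param table A measurement tibble.
#' @return A ggplot object.
#' @export
plot_measurements <- function(table) {
  validate_measurements(table)
  ggplot2::ggplot(table,
                  ggplot2::aes(x = factor(.data$location_id),
                               y = .data$diameter_mm,
                               fill = .data$world)) +
    ggplot2::geom_boxplot(outlier.size = 0.8, position = "dodge") +
    ggplot2::labs(x = "Location", y = "Diameter (mm)", fill = "World",
                  title = "Repeated diameter measurements by location") +
    ggplot2::theme_minimal()
}
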