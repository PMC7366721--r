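#' Two-way intraclass correlation coefficient
#'
#' ICC from the complete two-way subjects x raters layout with one
#' observation per cell, in the four variants used for inter-rater
#' reliability of a fixed rater panel:
#'
#' * consistency, single: `(MSR - MSE) / (MSR + (k-1) MSE)` — ICC(C,1)
#' * consistency, average: `(MSR - MSE) / MSR` — ICC(C,k)
#' * agreement, single:
#'   `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))` — ICC(A,1)
#' * agreement, average: `(MSR - MSE) / (MSR + (MSC - MSE)/n)` — ICC(A,k)
#'
#' where `MSR`, `MSC`, `MSE` are the subject, rater and residual mean
#' squares of the two-way ANOVA decomposition, `n` the number of subjects
#' and `k` the number of raters. "Agreement" counts rater systematic
#' offsets (the `MSC` term) as error; "consistency" cancels them.
#' "Single" is the reliability of one rater's reading, "average" that of
#' the k-rater mean. Confidence intervals use the exact F construction
#' for the consistency forms and the Satterthwaite-approximated F
#' construction for the agreement forms.
#'
#' @param ratings Numeric matrix or data frame, subjects in rows, raters
#'   in columns, no missing cells (see [ratings_matrix()]).
#' @param type `"agreement"` or `"consistency"`.
#' @param unit `"single"` or `"average"`.
#' @param conf_level Confidence level, default 0.95.
#' @return An object of class `"icc_result"`: list with `icc`, `ci_low`,
#'   `ci_high`, the mean squares (`msr`, `msc`, `mse`), `n`, `k`, `type`,
#'   `unit`, `label` (e.g. `"ICC(A,1)"`). Use [tidy()] for a one-row
#'   tibble.
#' @export
#' @examples
#' m <- cbind(r1 = c(10, 20, 30), r2 = c(11, 21, 31), r3 = c(9, 19, 29))
#' icc_twoway(m, "agreement", "single")$icc
icc_twoway <- function(ratings, type = c("agreement", "consistency"),
                       unit = c("single", "average"), conf_level = 0.95) {
  type <- match.arg(type); unit <- match.arg(unit)
  m <- as.matrix(ratings)
  if (!is.numeric(m) || anyNA(m))
    abort("`ratings` must be a complete numeric matrix.",
          class = "orbitometry_validation_error")
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L)
    abort("need at least 2 subjects and 2 raters.",
          class = "orbitometry_design_error")
  ms <- icc_mean_squares(m)
  msr <- ms$msr; msc <- ms$msc; mse <- ms$mse
  if (ms$ssr + ms$sse <= 1e-12 * max(ms$sst, 1))
    abort("ICC undefined: no subject or residual variance (MSR = MSE = 0).",
          class = "orbitometry_undefined_error")
  alpha <- 1 - conf_level
  icc <- switch(paste(type, unit),
    "consistency single" = (msr - mse) / (msr + (k - 1) * mse),
    "consistency average" = (msr - mse) / msr,
    "agreement single" = (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse)),
    "agreement average" = (msr - mse) / (msr + (msc - mse) / n)
  )
  if (mse <= 1e-300 && (type == "consistency" || msc <= 1e-300)) {
    # degenerate perfect agreement: F quantities blow up, CI collapses
    ci <- c(icc, icc)
  } else if (type == "consistency") {
    fobs <- msr / mse
    df1 <- n - 1; df2 <- (n - 1) * (k - 1)
    fl <- fobs / qf(1 - alpha / 2, df1, df2)
    fu <- fobs * qf(1 - alpha / 2, df2, df1)
    ci <- if (unit == "single")
      c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
    else c(1 - 1 / fl, 1 - 1 / fu)
  } else {
    r1 <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
    a <- k * r1 / (n * (1 - r1))
    b <- 1 + k * r1 * (n - 1) / (n * (1 - r1))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f1 <- qf(1 - alpha / 2, n - 1, v)
    f2 <- qf(1 - alpha / 2, v, n - 1)
    low1 <- n * (msr - f1 * mse) /
      (f1 * (k * msc + (k * n - k - n) * mse) + n * msr)
    up1 <- n * (f2 * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f2 * msr)
    ci <- if (unit == "single") c(low1, up1)
    else {
      sb <- function(r) r * k / (1 + (k - 1) * r)   # Spearman-Brown step-up
      c(sb(low1), sb(up1))
    }
  }
  ci <- sort(pmin(ci, 1))
  structure(
    list(model = "twoway", type = type, unit = unit,
         icc = icc, ci_low = min(ci[1], icc), ci_high = max(ci[2], icc),
         conf_level = conf_level, n = n, k = k,
         msr = msr, msc = msc, mse = mse,
         label = sprintf("ICC(%s,%s)", if (type == "agreement") "A" else "C",
                         if (unit == "single") "1" else as.character(k))),
    class = "icc_result")
}

# Two-way ANOVA mean squares, one observation per cell.
icc_mean_squares <- function(m) {
  n <- nrow(m); k <- ncol(m)
  gm <- mean(m)
  rm <- rowMeans(m); cm <- colMeans(m)
  ssr <- k * sum((rm - gm)^2)
  ssc <- n * sum((cm - gm)^2)
  sst <- sum((m - gm)^2)
  sse <- sst - ssr - ssc
  list(msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)),
       ssr = ssr, ssc = ssc, sse = sse, sst = sst)
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("Two-way %s %s %s = %.4f  %d%% CI [%.4f, %.4f]  (n=%d, k=%d)\n",
              x$type, x$unit, x$label, x$icc, round(100 * x$conf_level),
              x$ci_low, x$ci_high, x$n, x$k))
  invisible(x)
}

#' @describeIn icc_twoway One-row tibble: label, type, unit, icc, CI.
#' @param x An `"icc_result"`.
#' @param ... Unused.
#' @export
tidy.icc_result <- function(x, ...) {
  tibble::tibble(label = x$label, model = x$model, type = x$type,
                 unit = x$unit, icc = x$icc,
                 ci_low = x$ci_low, ci_high = x$ci_high)
}

#' @describeIn icc_twoway One-row tibble with the mean squares and layout
#'   size alongside the estimate.
#' @export
glance.icc_result <- function(x, ...) {
  tibble::tibble(icc = x$icc, ci_low = x$ci_low, ci_high = x$ci_high,
                 msr = x$msr, msc = x$msc, mse = x$mse,
                 n_subjects = x$n, k_raters = x$k,
                 conf_level = x$conf_level)
}

#' All four two-way ICC variants of one ratings matrix
#'
#' Convenience wrapper producing the reliability-table shape: agreement
#' and consistency, single and average, one row each.
#'
#' @inheritParams icc_twoway
#' @return A four-row tibble as from [tidy()] on each variant.
#' @export
icc_all <- function(ratings, conf_level = 0.95) {
  grid <- expand.grid(type = c("agreement", "consistency"),
                      unit = c("average", "single"),
                      stringsAsFactors = FALSE)
  purrr::pmap_dfr(grid, function(type, unit)
    tidy(icc_twoway(ratings, type, unit, conf_level)))
}
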