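test_that("identical group means give d = 0 labelled negligible", {
  t1 <- table1_fixture()
  set.seed(2)
  tab <- constant_table(t1$mean_physical_mm, t1$mean_physical_mm)
  tab$diameter_mm <- tab$diameter_mm + rnorm(nrow(tab), 0, 1e-3)
  eff <- compare_worlds(tab)
  pooled <- eff[eff$scope == "pooled", ]
  expect_lt(abs(pooled$cohen_d), 0.2)
  expect_identical(orbitometry:::cohen_category(0), "negligible")
  expect_identical(orbitometry:::cohen_category(0.3), "small")
  expect_identical(orbitometry:::cohen_category(0.8), "medium")
  expect_identical(orbitometry:::cohen_category(1.3), "large")
})

test_that("a 4-sigma mean shift is recovered as d ~ 4, category large", {
  set.seed(55)
  ds <- replicate(1000, {
    x <- rnorm(9, 40, 1); y <- rnorm(12, 44, 1)
    sp <- sqrt(((9 - 1) * var(x) + (12 - 1) * var(y)) / (9 + 12 - 2))
    (mean(y) - mean(x)) / sp
  })
  # closed form: d = delta/sigma = 4; simulation mean within its own SE
  expect_lt(abs(mean(ds) - 4), 4 * sd(ds) / sqrt(length(ds)) + 0.2)

  set.seed(56)
  tab <- constant_table(rep(40, 9), rep(44, 9))
  tab$diameter_mm <- tab$diameter_mm + rnorm(nrow(tab))
  pooled <- compare_worlds(tab) |> dplyr::filter(.data$scope == "pooled")
  expect_identical(pooled$category, "large")
  expect_true(pooled$significant)
})

test_that("Welch statistics equal the textbook formulas", {
  set.seed(31)
  x <- rnorm(9, 40, 1.1); y <- rnorm(12, 41, 2.3)
  # single-location table: physical gets x, virtual gets y
  tab <- tibble::tibble(
    grader_id = c(paste0("P", seq_along(x)), paste0("V", seq_along(y))),
    world = rep(c("physical", "virtual"), c(length(x), length(y))),
    location_id = 1L, landmark_kind = "bead",
    repetition = 1L, diameter_mm = c(x, y),
    refinements = rep(c(NA_integer_, 1L), c(length(x), length(y)))
  )
  eff <- compare_worlds(tab)
  row <- eff[eff$scope == "location", ]
  # independent textbook-formula oracle
  se2 <- var(x) / 9 + var(y) / 12
  t_oracle <- (mean(y) - mean(x)) / sqrt(se2)
  df_oracle <- se2^2 / ((var(x) / 9)^2 / 8 + (var(y) / 12)^2 / 11)
  p_oracle <- 2 * pt(-abs(t_oracle), df_oracle)
  expect_equal(row$t_welch, t_oracle, tolerance = 1e-10)
  expect_equal(row$df_welch, df_oracle, tolerance = 1e-10)
  expect_equal(row$p_value, p_oracle, tolerance = 1e-10)
  # variance ratio carries the larger variance in the numerator
  expect_gte(row$variance_ratio_F, 1)
  expect_equal(row$variance_ratio_F, max(var(x), var(y)) / min(var(x), var(y)),
               tolerance = 1e-12)
})

test_that("per-location effect rows cover all locations plus a pooled row", {
  tab <- test_study(seed = 61L)
  eff <- compare_worlds(tab)
  expect_identical(nrow(eff), 10L)
  expect_identical(sum(eff$scope == "pooled"), 1L)
  expect_setequal(eff$location_id[eff$scope == "location"], 1:9)
  # VR reads high by design, so the shift is positive everywhere; the
  # per-location tests see it clearly (the pooled contrast is diluted by
  # the 25-42 mm spread between locations)
  pooled <- eff[eff$scope == "pooled", ]
  expect_gt(pooled$mean_virtual_mm, pooled$mean_physical_mm)
  loc <- eff[eff$scope == "location", ]
  expect_true(all(loc$cohen_d > 0))
  expect_gte(sum(loc$significant), 7L)
})

test_that("zero variance in both groups is rejected", {
  tab <- constant_table(rep(40, 9), rep(44, 9))
  expect_error(compare_worlds(tab), class = "orbitometry_undefined_error")
})

test_that("refinement summaries average the logged counts", {
  tab <- test_study(seed = 71L)
  tab$refinements[tab$world == "virtual"] <- 0L
  expect_equal(refinement_summary(tab)$grand_mean, 0)
  tab$refinements[tab$world == "virtual"] <- rep(c(1L, 2L), 54)
  rs <- refinement_summary(tab)
  expect_equal(rs$grand_mean, 1.5)
  expect_identical(nrow(tidy(rs)), 4L)
  expect_equal(glance(rs)$grand_mean, 1.5)
  expect_error(refinement_summary(tab[tab$world == "physical", ]),
               class = "orbitometry_design_error")
  expect_s3_class(autoplot(rs), "ggplot")
  expect_s3_class(plot_measurements(tab), "ggplot")
})

test_that("the simulated refinement rate is recovered at scale", {
  fx <- default_study_fixture()
  design <- study_design(n_repetitions = 2500L, seed = 83L)
  tab <- simulate_measurements(fx$truths, fx$graders, design)
  rs <- refinement_summary(tab)
  se <- sqrt(1.5 / rs$n)
  expect_lt(abs(rs$grand_mean - 1.5), 3 * se)
})
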