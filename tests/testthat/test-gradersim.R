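test_that("the default design yields 189 records, 81 physical and 108 virtual", {
  tab <- test_study()
  expect_identical(nrow(tab), 189L)
  expect_identical(sum(tab$world == "physical"), 81L)
  expect_identical(sum(tab$world == "virtual"), 108L)
  expect_identical(anyDuplicated(paste(tab$grader_id, tab$location_id, tab$repetition)), 0L)
  expect_true(all(is.na(tab$refinements[tab$world == "physical"])))
  expect_true(all(!is.na(tab$refinements[tab$world == "virtual"])))
  expect_identical(unique(tab$landmark_kind[tab$location_id <= 6]), "bead")
  expect_identical(unique(tab$landmark_kind[tab$location_id > 6]), "pin")
})

test_that("zero noise and zero bias reproduce the truths exactly", {
  truths <- fixture_truths()
  graders <- c(purrr::map(1:3, ~ grader_model(paste0("P", .x), "physical")),
               purrr::map(1:4, ~ grader_model(paste0("V", .x), "virtual")))
  tab <- simulate_measurements(truths, graders, study_design(seed = 2))
  tv <- setNames(truths$true_diameter_mm, truths$location_id)
  expect_equal(tab$diameter_mm, unname(tv[as.character(tab$location_id)]),
               tolerance = 1e-12)
})

test_that("a deterministic multiplicative bias scales readings", {
  truths <- setNames(rep(40, 9), 1:9)
  graders <- c(purrr::map(1:3, ~ grader_model(paste0("P", .x), "physical")),
               purrr::map(1:4, ~ grader_model(paste0("V", .x), "virtual",
                                              bias_fraction = 0.05)))
  tab <- simulate_measurements(truths, graders, study_design(seed = 2))
  expect_true(all(tab$diameter_mm[tab$world == "virtual"] == 42.0))
  expect_true(all(tab$diameter_mm[tab$world == "physical"] == 40.0))
})

test_that("simulation is bit-reproducible under a fixed seed", {
  expect_identical(test_study(seed = 123L), test_study(seed = 123L))
  expect_false(identical(test_study(seed = 123L)$diameter_mm,
                         test_study(seed = 124L)$diameter_mm))
})

test_that("per-location means converge to truth * (1 + bias)", {
  fx <- default_study_fixture()
  design <- study_design(n_physical_graders = 1L, n_virtual_graders = 1L,
                         n_repetitions = 10000L, seed = 31L)
  graders <- fx$graders[c(1, 4)]
  tab <- simulate_measurements(fx$truths, graders, design)
  tv <- setNames(fx$truths$true_diameter_mm, fx$truths$location_id)
  vr <- fx$graders[[4]]
  for (loc in 1:9) {
    pm <- mean(tab$diameter_mm[tab$world == "physical" & tab$location_id == loc])
    sd_p <- fx$graders[[1]]$noise_sd_mm[[as.character(loc)]]
    expect_lt(abs(pm - tv[[as.character(loc)]]),
              3 * sd_p / sqrt(design$n_repetitions))
    vm <- mean(tab$diameter_mm[tab$world == "virtual" & tab$location_id == loc])
    expected <- tv[[as.character(loc)]] * (1 + vr$bias_fraction[[as.character(loc)]])
    expect_lt(abs(vm - expected), 3 * 0.08 / sqrt(design$n_repetitions))
  }
  # refinement grand mean converges to the Poisson rate
  rmean <- mean(tab$refinements[tab$world == "virtual"])
  expect_lt(abs(rmean - 1.5), 3 * sqrt(1.5 / (9 * design$n_repetitions)))
})

test_that("fixture calibration matches the reference group means", {
  fx <- default_study_fixture()
  tr <- fx$truths$true_diameter_mm
  expect_equal(mean(tr[1:6]), 37.38, tolerance = 1e-12)
  expect_equal(mean(tr[7:9]), 25.01, tolerance = 1e-12)
  vr <- fx$graders[[4]]
  bead_bias <- vr$bias_fraction[["1"]]
  expect_equal(mean(tr[1:6]) * (1 + bead_bias), 39.90, tolerance = 1e-9)
  # physical noise is worst at the oblique intra-orbital location 3
  p_noise <- fx$graders[[1]]$noise_sd_mm
  expect_identical(names(which.max(p_noise)), "3")
  expect_equal(fx$graders[[4]]$refinement_rate, 1.5)
})

test_that("expected VR bead-group mean under the fixture is ~39.90 mm", {
  fx <- default_study_fixture()
  design <- study_design(n_physical_graders = 1L, n_virtual_graders = 1L,
                         n_repetitions = 5000L, seed = 17L)
  tab <- simulate_measurements(fx$truths, fx$graders[c(1, 4)], design)
  bead_means <- vapply(1:6, function(l)
    mean(tab$diameter_mm[tab$world == "virtual" & tab$location_id == l]),
    numeric(1))
  expect_equal(mean(bead_means), 39.90, tolerance = 0.01)
})

test_that("missing truths and mismatched grader lists are configuration errors", {
  fx <- default_study_fixture()
  expect_error(
    simulate_measurements(setNames(rep(30, 8), 1:8), fx$graders, fx$design),
    class = "orbitometry_config_error")
  expect_error(
    simulate_measurements(fx$truths, fx$graders[1:5], fx$design),
    class = "orbitometry_config_error")
  expect_error(grader_model("P9", "physical", refinement_rate = 1),
               class = "orbitometry_config_error")
  expect_error(study_design(n_repetitions = 0), class = "orbitometry_config_error")
})

test_that("measurement CSV round-trips losslessly", {
  tab <- test_study()
  path <- withr::local_tempfile(fileext = ".csv")
  write_measurements(tab, path)
  back <- read_measurements(path)
  expect_equal(as.data.frame(back), as.data.frame(tab))
})

test_that("malformed measurement tables are rejected with clear messages", {
  tab <- test_study()
  bad <- tab
  bad$refinements[bad$world == "physical"][1] <- 2L
  expect_error(validate <- write_measurements(bad, tempfile()),
               class = "orbitometry_validation_error")
  dup <- dplyr::bind_rows(tab, tab[1, ])
  expect_error(write_measurements(dup, tempfile()),
               class = "orbitometry_validation_error")
  neg <- tab; neg$diameter_mm[5] <- -1
  expect_error(write_measurements(neg, tempfile()),
               class = "orbitometry_validation_error")

  p <- withr::local_tempfile(fileext = ".csv")
  file.create(p)
  expect_error(read_measurements(p), "empty")
  extra <- dplyr::mutate(tab, comment = "x")
  p2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(extra, p2, na = "")
  expect_error(read_measurements(p2), "unknown measurement column")
})
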