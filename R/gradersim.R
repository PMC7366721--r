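#' Describe a grader's measurement behaviour
#'
#' A grader is modelled by a multiplicative bias (VR readings run a few
#' percent high, physical readings are taken as unbiased), per-location
#' additive Gaussian noise, an optional constant offset (a grader-level
#' systematic error, useful for making agreement and consistency ICC
#' differ), and — for virtual graders only — a Poisson refinement rate
#' giving how often a marker is repositioned before saving.
#'
#' @param grader_id Character label, unique within a study.
#' @param world `"physical"` or `"virtual"`.
#' @param bias_fraction Multiplicative bias: a single number, or a named
#'   numeric vector keyed by location id when the bias differs between
#'   landmark groups (e.g. bead vs pin locations).
#' @param noise_sd_mm Reading noise SD in mm: a single number or a named
#'   per-location vector; must cover every measured location.
#' @param refinement_rate Mean of the Poisson refinement count; virtual
#'   graders only (`NULL` for physical graders).
#' @param offset_mm Constant additive offset (mm), default 0.
#' @return An object of class `"grader_model"`.
#' @export
grader_model <- function(grader_id, world = c("physical", "virtual"),
                         bias_fraction = 0, noise_sd_mm = 0,
                         refinement_rate = NULL, offset_mm = 0) {
  world <- match.arg(world)
  if (world == "physical" && !is.null(refinement_rate))
    abort("physical graders have no refinement_rate.",
          class = "orbitometry_config_error")
  if (world == "virtual") {
    refinement_rate <- refinement_rate %||% 0
    if (!is.finite(refinement_rate) || refinement_rate < 0)
      abort("`refinement_rate` must be >= 0.", class = "orbitometry_config_error")
  }
  if (any(!is.finite(noise_sd_mm)) || any(noise_sd_mm < 0))
    abort("`noise_sd_mm` must be non-negative.", class = "orbitometry_config_error")
  structure(
    list(grader_id = as.character(grader_id), world = world,
         bias_fraction = bias_fraction, noise_sd_mm = noise_sd_mm,
         refinement_rate = refinement_rate, offset_mm = offset_mm),
    class = "grader_model")
}

#' Study design of the measurement experiment
#'
#' Defaults mirror the validation study: three physical-world graders,
#' four virtual-reality graders, nine diameter locations, each measured
#' three times by every grader — 189 measurements in total.
#'
#' @param n_physical_graders,n_virtual_graders,n_repetitions Positive
#'   integers.
#' @param location_ids Measured locations (default 1:9; 1--6 bead-delimited,
#'   7--9 pin-delimited).
#' @param seed Integer seed used by [simulate_measurements()].
#' @return An object of class `"study_design"`.
#' @export
study_design <- function(n_physical_graders = 3L, n_virtual_graders = 4L,
                         n_repetitions = 3L, location_ids = 1:9,
                         seed = 1L) {
  counts <- c(n_physical_graders, n_virtual_graders, n_repetitions)
  if (any(counts < 1L)) abort("all design counts must be >= 1.",
                              class = "orbitometry_config_error")
  structure(
    list(n_physical_graders = as.integer(n_physical_graders),
         n_virtual_graders = as.integer(n_virtual_graders),
         n_repetitions = as.integer(n_repetitions),
         location_ids = as.integer(location_ids),
         seed = as.integer(seed)),
    class = "study_design")
}

per_location <- function(x, location_ids, what) {
  if (length(x) == 1L && is.null(names(x)))
    return(setNames(rep(as.numeric(x), length(location_ids)),
                    as.character(location_ids)))
  miss <- setdiff(as.character(location_ids), names(x))
  if (length(miss))
    abort(paste0(what, " missing for location(s) ", paste(miss, collapse = ", ")),
          class = "orbitometry_config_error")
  as.numeric(x[as.character(location_ids)]) |>
    setNames(as.character(location_ids))
}

truths_vector <- function(truths, location_ids) {
  if (is.data.frame(truths)) {
    v <- setNames(truths$true_diameter_mm, as.character(truths$location_id))
  } else {
    v <- truths
    if (is.null(names(v))) names(v) <- as.character(seq_along(v))
  }
  per_location(v, location_ids, "truth")
}

#' Simulate blinded repeated grader measurements
#'
#' Draws every grader x location x repetition diameter reading as
#' `truth * (1 + bias) + offset + Normal(0, noise_sd)` mm, with
#' independent noise across readings (the two grader groups worked
#' concurrently and independently, and graders within a group were
#' blinded to each other and to the displayed value). Virtual graders
#' additionally log a Poisson-distributed refinement count per
#' measurement. Reproducible for a fixed design seed.
#'
#' @param truths True diameters: the tibble from [true_diameters()] /
#'   [fixture_truths()], or a named numeric vector keyed by location id.
#' @param graders List of [grader_model()]s; its physical/virtual counts
#'   must match the design.
#' @param design A [study_design()].
#' @return A measurement table: a tibble with one row per reading and
#'   columns `grader_id`, `world`, `location_id`, `landmark_kind`,
#'   `repetition`, `diameter_mm` and `refinements` (`NA` on physical
#'   rows).
#' @export
#' @examples
#' fx <- default_study_fixture()
#' tab <- simulate_measurements(fx$truths, fx$graders, fx$design)
#' nrow(tab)  # 189
simulate_measurements <- function(truths, graders, design = study_design()) {
  stopifnot(inherits(design, "study_design"))
  worlds <- vapply(graders, function(g) g$world, character(1))
  if (sum(worlds == "physical") != design$n_physical_graders ||
      sum(worlds == "virtual") != design$n_virtual_graders)
    abort("grader list does not match the design's physical/virtual counts.",
          class = "orbitometry_config_error")
  loc <- design$location_ids
  tv <- truths_vector(truths, loc)
  kind <- if (is.data.frame(truths) && "landmark_kind" %in% names(truths)) {
    setNames(truths$landmark_kind, as.character(truths$location_id))[as.character(loc)]
  } else {
    ifelse(loc <= 6L, "bead", "pin")
  }
  set.seed(design$seed)
  rows <- purrr::map_dfr(graders, function(g) {
    bias <- per_location(g$bias_fraction, loc, "bias_fraction")
    nsd <- per_location(g$noise_sd_mm, loc, "noise_sd_mm")
    purrr::map_dfr(seq_along(loc), function(i) {
      n <- design$n_repetitions
      d <- tv[i] * (1 + bias[i]) + g$offset_mm + rnorm(n, 0, nsd[i])
      tibble::tibble(
        grader_id = g$grader_id, world = g$world,
        location_id = loc[i], landmark_kind = unname(kind[i]),
        repetition = seq_len(n), diameter_mm = as.numeric(d),
        refinements = if (g$world == "virtual")
          rpois(n, g$refinement_rate) else NA_integer_
      )
    })
  })
  rows
}

#' Default study fixture: truths, graders and design
#'
#' The calibrated study conditions: per-location true diameters anchored
#' to the reference table ([fixture_truths()]); three unbiased physical
#' graders whose noise is location-dependent and worst at location 3 (the
#' oblique diameter inside the orbit, the hardest to reach with a
#' physical caliper); four virtual graders with small location-independent
#' noise, a positive multiplicative bias of +6.74% at bead locations and
#' +4.25% at pin locations (the VR renderings of the metal landmarks
#' appear slightly enlarged), and a Poisson refinement rate of 1.5.
#'
#' @param seed Design seed.
#' @param vr_noise_sd_mm Virtual-world reading noise SD (mm).
#' @return A list with elements `truths` (tibble), `graders` (list of
#'   [grader_model()]) and `design` ([study_design()]).
#' @export
default_study_fixture <- function(seed = 1L, vr_noise_sd_mm = 0.08) {
  truths <- fixture_truths()
  grp <- table1_group_rows()
  mrow <- function(g, col) grp[[col]][grp$group == g & grp$statistic == "mean"]
  bead_bias <- mrow("beads", "mean_virtual_mm") / mrow("beads", "mean_physical_mm") - 1
  pin_phys <- truths$true_diameter_mm[truths$landmark_kind == "pin"]
  pin_virt <- table1_fixture()$mean_virtual_mm[7:9]
  pin_bias <- mean(pin_virt) / mean(pin_phys) - 1
  vr_bias <- setNames(c(rep(bead_bias, 6L), rep(pin_bias, 3L)), as.character(1:9))
  phys_noise <- setNames(c(0.55, 0.60, 1.40, 0.55, 0.50, 0.60,
                           0.18, 0.18, 0.22), as.character(1:9))
  graders <- c(
    purrr::map(1:3, ~ grader_model(paste0("P", .x), "physical",
                                   bias_fraction = 0,
                                   noise_sd_mm = phys_noise)),
    purrr::map(1:4, ~ grader_model(paste0("V", .x), "virtual",
                                   bias_fraction = vr_bias,
                                   noise_sd_mm = vr_noise_sd_mm,
                                   refinement_rate = 1.5))
  )
  list(truths = truths, graders = graders, design = study_design(seed = seed))
}

measurement_columns <- c("grader_id", "world", "location_id", "landmark_kind",
                         "repetition", "diameter_mm", "refinements")

validate_measurements <- function(table) {
  extra <- setdiff(names(table), measurement_columns)
  miss <- setdiff(measurement_columns, names(table))
  if (length(extra))
    abort(paste0("unknown measurement column(s): ", paste(extra, collapse = ", ")),
          class = "orbitometry_validation_error")
  if (length(miss))
    abort(paste0("missing measurement column(s): ", paste(miss, collapse = ", ")),
          class = "orbitometry_validation_error")
  if (nrow(table) == 0L)
    abort("measurement table is empty.", class = "orbitometry_validation_error")
  if (!all(table$world %in% c("physical", "virtual")))
    abort("`world` must be 'physical' or 'virtual'.",
          class = "orbitometry_validation_error")
  if (any(!is.finite(table$diameter_mm)) || any(table$diameter_mm <= 0))
    abort("`diameter_mm` must be positive and finite.",
          class = "orbitometry_validation_error")
  key <- paste(table$grader_id, table$location_id, table$repetition)
  if (anyDuplicated(key))
    abort("duplicate (grader, location, repetition) rows.",
          class = "orbitometry_validation_error")
  phys <- table$world == "physical"
  if (any(!is.na(table$refinements[phys])))
    abort("physical records must not carry refinement counts.",
          class = "orbitometry_validation_error")
  if (any(is.na(table$refinements[!phys])) ||
      any(table$refinements[!phys] < 0))
    abort("virtual records need a non-negative refinement count.",
          class = "orbitometry_validation_error")
  invisible(table)
}

#' Write / read a measurement table as CSV
#'
#' Lossless round-trip of the long-format measurement table; the header
#' is mandatory and the column set fixed (`grader_id, world, location_id,
#' landmark_kind, repetition, diameter_mm, refinements`, the last empty
#' on physical rows). Unknown columns, duplicate
#' (grader, location, repetition) keys, non-positive diameters and
#' refinement counts on physical rows are rejected with a clear message.
#'
#' @param table A measurement tibble as from [simulate_measurements()].
#' @param path CSV path.
#' @return `write_measurements()` returns `path` invisibly;
#'   `read_measurements()` returns the validated tibble.
#' @export
write_measurements <- function(table, path) {
  validate_measurements(table)
  readr::write_csv(table, path, na = "")
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: '", path, "'"))
  if (file.size(path) == 0L)
    abort("empty measurement file.", class = "orbitometry_validation_error")
  tab <- suppressWarnings(readr::read_csv(
    path, na = "", show_col_types = FALSE,
    col_types = readr::cols(
      grader_id = readr::col_character(), world = readr::col_character(),
      location_id = readr::col_integer(), landmark_kind = readr::col_character(),
      repetition = readr::col_integer(), diameter_mm = readr::col_double(),
      refinements = readr::col_integer(), .default = readr::col_character()
    )))
  if (nrow(tab) == 0L)
    abort("empty measurement table.", class = "orbitometry_validation_error")
  validate_measurements(tibble::as_tibble(tab))
  tibble::as_tibble(tab)
}
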