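#' Per-location summary of a measurement table
#'
#' Pools, for each diameter location, all graders and repetitions within
#' each world into a single mean, and reports the virtual-minus-physical
#' difference — the per-location rows of the study's summary table.
#'
#' @param table A measurement tibble (see [simulate_measurements()]).
#' @return A tibble with one row per location: `location_id`,
#'   `landmark_kind`, `mean_physical_mm`, `mean_virtual_mm`,
#'   `difference_mm`.
#' @export
summarize_locations <- function(table) {
  validate_measurements(table)
  by_loc <- table |>
    dplyr::group_by(.data$location_id, .data$landmark_kind, .data$world) |>
    dplyr::summarise(mean_mm = mean(.data$diameter_mm), .groups = "drop")
  wide <- by_loc |>
    tidyr::pivot_wider(names_from = "world", values_from = "mean_mm")
  if (!all(c("physical", "virtual") %in% names(wide)) ||
      anyNA(wide$physical) || anyNA(wide$virtual))
    abort("incomplete design: every location needs both worlds.",
          class = "orbitometry_design_error")
  wide |>
    dplyr::transmute(
      location_id = .data$location_id,
      landmark_kind = .data$landmark_kind,
      mean_physical_mm = .data$physical,
      mean_virtual_mm = .data$virtual,
      difference_mm = .data$virtual - .data$physical
    ) |>
    dplyr::arrange(.data$location_id)
}

group_stats <- function(df) {
  mp <- mean(df$mean_physical_mm); mv <- mean(df$mean_virtual_mm)
  tibble::tibble(
    mean_physical_mm = mp, mean_virtual_mm = mv,
    mean_difference_mm = mean(df$difference_mm),
    min_physical_mm = min(df$mean_physical_mm),
    max_physical_mm = max(df$mean_physical_mm),
    min_virtual_mm = min(df$mean_virtual_mm),
    max_virtual_mm = max(df$mean_virtual_mm),
    min_difference_mm = min(df$difference_mm),
    max_difference_mm = max(df$difference_mm),
    percent_increase = 100 * (mv - mp) / mp
  )
}

#' Group summary: beads, pins and overall
#'
#' Aggregates per-location summaries into the bead group (locations with
#' `landmark_kind == "bead"`), the pin group, and an overall row. Group
#' means and extremes are computed from the per-location rows. The percent
#' increase of each landmark group is
#' `100 * (mean_virtual - mean_physical) / mean_physical`; the overall
#' percent increase is the arithmetic mean of the two group percentages,
#' the convention under which the study's headline "VR reads ~5.5% high"
#' figure arises from the bead (6.74%) and pin (4.25%) groups.
#'
#' @param summaries The tibble from [summarize_locations()] (or
#'   [table1_fixture()]); needs 6 bead rows and 3 pin rows.
#' @return A tibble with rows `beads`, `pins`, `overall` and columns
#'   `group`, `mean_physical_mm`, `mean_virtual_mm`, `mean_difference_mm`,
#'   min/max of each, and `percent_increase`.
#' @export
summarize_groups <- function(summaries) {
  need <- c("location_id", "landmark_kind", "mean_physical_mm",
            "mean_virtual_mm", "difference_mm")
  if (!all(need %in% names(summaries)))
    abort("`summaries` must carry the per-location summary columns.",
          class = "orbitometry_validation_error")
  beads <- summaries[summaries$landmark_kind == "bead", ]
  pins <- summaries[summaries$landmark_kind == "pin", ]
  if (nrow(beads) != 6L || nrow(pins) != 3L)
    abort("expected 6 bead and 3 pin locations.",
          class = "orbitometry_design_error")
  gb <- group_stats(beads); gp <- group_stats(pins); go <- group_stats(summaries)
  go$percent_increase <- (gb$percent_increase + gp$percent_increase) / 2
  dplyr::bind_rows(
    dplyr::mutate(gb, group = "beads", .before = 1),
    dplyr::mutate(gp, group = "pins", .before = 1),
    dplyr::mutate(go, group = "overall", .before = 1)
  )
}

#' Ratings matrix for reliability analysis
#'
#' Reshapes one world's measurements into the complete two-way layout the
#' reliability statistics operate on: subjects (rows) are the measurement
#' locations, raters (columns) are the graders, and each cell is that
#' grader's mean over the repetitions.
#'
#' @param table A measurement tibble.
#' @param world `"physical"` or `"virtual"`.
#' @return A numeric matrix (locations x graders) with the world recorded
#'   in attribute `"world"`; errors if any cell would be empty.
#' @export
ratings_matrix <- function(table, world = c("physical", "virtual")) {
  world <- match.arg(world)
  sub <- table[table$world == world, ]
  if (nrow(sub) == 0L)
    abort(paste0("no ", world, " records in the table."),
          class = "orbitometry_design_error")
  wide <- sub |>
    dplyr::group_by(.data$location_id, .data$grader_id) |>
    dplyr::summarise(mean_mm = mean(.data$diameter_mm), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "grader_id", values_from = "mean_mm") |>
    dplyr::arrange(.data$location_id)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$location_id
  if (anyNA(m))
    abort("incomplete two-way layout: a grader is missing a location.",
          class = "orbitometry_design_error")
  attr(m, "world") <- world
  m
}
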