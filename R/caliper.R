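#' Detect metal fiducials in a volume
#'
#' Automated stand-in for the human landmark identification step: the
#' volume is thresholded, 26-connected components are extracted, small
#' components are dropped, and each remaining component is summarised by
#' its intensity-weighted centroid. On an unblurred phantom this recovers
#' every bead and pin centroid to within half a voxel.
#'
#' @param volume 3-D numeric array (HU).
#' @param spacing_mm Voxel spacing triple (mm).
#' @param hu_threshold Detection threshold; voxels with value >= threshold
#'   are foreground. Choose it above bone and below metal.
#' @param min_voxels Drop components with fewer voxels than this.
#' @return A tibble sorted by component size (descending), ties broken by
#'   lexicographic centroid, with columns `centroid_x_mm`, `centroid_y_mm`,
#'   `centroid_z_mm`, `voxel_count` and `mean_hu`. Zero rows when nothing
#'   exceeds the threshold.
#' @export
detect_fiducials <- function(volume, spacing_mm, hu_threshold, min_voxels = 1L) {
  if (min_voxels < 1L) abort("`min_voxels` must be >= 1.")
  dims <- dim(volume)
  lin <- which(volume >= hu_threshold)
  empty <- tibble::tibble(centroid_x_mm = double(), centroid_y_mm = double(),
                          centroid_z_mm = double(), voxel_count = integer(),
                          mean_hu = double())
  if (length(lin) == 0L) return(empty)
  ai <- arrayInd(lin, dims)
  n <- length(lin)
  key <- (ai[, 1] - 1) + dims[1] * ((ai[, 2] - 1) + dims[2] * (ai[, 3] - 1))
  # 13 half-neighbourhood offsets give full 26-connectivity on an
  # undirected graph.
  offsets <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offsets <- offsets[(offsets[, 3] > 0) |
                     (offsets[, 3] == 0 & offsets[, 2] > 0) |
                     (offsets[, 3] == 0 & offsets[, 2] == 0 & offsets[, 1] > 0), ,
                     drop = FALSE]
  edges <- vector("list", nrow(offsets))
  for (o in seq_len(nrow(offsets))) {
    d <- offsets[o, ]
    ni <- ai[, 1] + d[1]; nj <- ai[, 2] + d[2]; nk <- ai[, 3] + d[3]
    ok <- ni >= 1 & ni <= dims[1] & nj >= 1 & nj <= dims[2] &
          nk >= 1 & nk <= dims[3]
    nkey <- (ni - 1) + dims[1] * ((nj - 1) + dims[2] * (nk - 1))
    m <- match(nkey[ok], key)
    src <- which(ok)[!is.na(m)]
    dst <- m[!is.na(m)]
    edges[[o]] <- rbind(src, dst)
  }
  em <- do.call(cbind, edges)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(em)) g <- igraph::add_edges(g, as.vector(em))
  memb <- igraph::components(g)$membership
  hu <- volume[lin]
  wx <- rowsum(hu * (ai[, 1] - 1) * spacing_mm[1], memb)
  wy <- rowsum(hu * (ai[, 2] - 1) * spacing_mm[2], memb)
  wz <- rowsum(hu * (ai[, 3] - 1) * spacing_mm[3], memb)
  wsum <- rowsum(hu, memb)
  cnt <- as.integer(rowsum(rep(1L, n), memb))
  out <- tibble::tibble(
    centroid_x_mm = as.numeric(wx / wsum),
    centroid_y_mm = as.numeric(wy / wsum),
    centroid_z_mm = as.numeric(wz / wsum),
    voxel_count = cnt,
    mean_hu = as.numeric(wsum) / cnt
  )
  out <- out[out$voxel_count >= min_voxels, , drop = FALSE]
  out[order(-out$voxel_count, out$centroid_x_mm, out$centroid_y_mm,
            out$centroid_z_mm), ]
}

#' Place a digital caliper marker pair
#'
#' Starts a fresh caliper measurement: two markers in world coordinates,
#' distance computed immediately, no refinements yet, not saved. Mirrors
#' the physical caliper being reset to zero before each measurement — no
#' state carries over between measurements.
#'
#' @param marker_a_mm,marker_b_mm Finite numeric length-3 world positions
#'   (mm).
#' @return An object of class `"caliper_measurement"` with fields
#'   `marker_a_mm`, `marker_b_mm`, `distance_mm`, `refinement_count`,
#'   `history` (ordered list of every marker position set) and `saved`.
#' @export
#' @examples
#' m <- caliper_place(c(0, 0, 0), c(3, 4, 0))
#' m$distance_mm  # 5
caliper_place <- function(marker_a_mm, marker_b_mm) {
  check_marker(marker_a_mm); check_marker(marker_b_mm)
  structure(
    list(marker_a_mm = as.numeric(marker_a_mm),
         marker_b_mm = as.numeric(marker_b_mm),
         distance_mm = euclid(marker_a_mm, marker_b_mm),
         refinement_count = 0L,
         history = list(as.numeric(marker_a_mm), as.numeric(marker_b_mm)),
         saved = FALSE),
    class = "caliper_measurement")
}

check_marker <- function(p) {
  if (!is.numeric(p) || length(p) != 3L || any(!is.finite(p)))
    abort("markers must be finite numeric length-3 positions (mm).",
          class = "orbitometry_validation_error")
  invisible(p)
}

euclid <- function(a, b) sqrt(sum((as.numeric(a) - as.numeric(b))^2))

#' Reposition one caliper marker
#'
#' A refinement moves one marker of an unsaved measurement; the distance
#' is recomputed, the refinement counter incremented and the new position
#' appended to the history. Refining a saved measurement is an error —
#' once saved, the record is immutable.
#'
#' @param measurement A [caliper_place()] result.
#' @param which_marker `"a"` or `"b"`.
#' @param new_position_mm Finite numeric length-3 position (mm).
#' @return The updated `"caliper_measurement"`.
#' @export
caliper_refine <- function(measurement, which_marker, new_position_mm) {
  stopifnot(inherits(measurement, "caliper_measurement"))
  if (isTRUE(measurement$saved))
    abort("measurement already saved; repositioning is not accepted.",
          class = "orbitometry_state_error")
  which_marker <- match.arg(which_marker, c("a", "b"))
  check_marker(new_position_mm)
  slot <- paste0("marker_", which_marker, "_mm")
  measurement[[slot]] <- as.numeric(new_position_mm)
  measurement$distance_mm <- euclid(measurement$marker_a_mm, measurement$marker_b_mm)
  measurement$refinement_count <- measurement$refinement_count + 1L
  measurement$history <- c(measurement$history, list(as.numeric(new_position_mm)))
  measurement
}

#' Save a caliper measurement
#'
#' Freezes the measurement: the final positions, distance and number of
#' adjustments are logged and no further repositioning is accepted. Saving
#' twice is an idempotent no-op.
#'
#' @param measurement A `"caliper_measurement"`.
#' @return The measurement with `saved = TRUE`.
#' @export
caliper_save <- function(measurement) {
  stopifnot(inherits(measurement, "caliper_measurement"))
  measurement$saved <- TRUE
  measurement
}

#' @export
print.caliper_measurement <- function(x, ...) {
  cat(sprintf("<caliper> %.4f mm, %d refinement(s), %s\n", x$distance_mm,
              x$refinement_count, if (x$saved) "saved" else "open"))
  invisible(x)
}

#' @describeIn caliper_save One-row tibble form of a saved measurement
#'   (marker coordinates, distance, refinement count) — the shape of one
#'   measurement-log row.
#' @param x A `"caliper_measurement"`.
#' @param ... Unused.
#' @export
tidy.caliper_measurement <- function(x, ...) {
  tibble::tibble(
    ax_mm = x$marker_a_mm[1], ay_mm = x$marker_a_mm[2], az_mm = x$marker_a_mm[3],
    bx_mm = x$marker_b_mm[1], by_mm = x$marker_b_mm[2], bz_mm = x$marker_b_mm[3],
    distance_mm = x$distance_mm,
    refinement_count = x$refinement_count,
    saved = x$saved
  )
}

#' Write a caliper measurement log
#'
#' One CSV row per saved measurement: marker coordinates, distance and
#' refinement count.
#'
#' @param measurements A list of `"caliper_measurement"` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_caliper_log <- function(measurements, path) {
  log <- purrr::map_dfr(measurements, tidy)
  readr::write_csv(log, path)
  invisible(path)
}
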