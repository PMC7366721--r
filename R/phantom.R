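#' Configuration of the synthetic CT skull phantom
#'
#' Defines the voxel grid, fiducial geometry and attenuation values of the
#' synthetic phantom that stands in for the CT scan of the dried skull.
#' Defaults follow the study hardware: isotropic 0.625 mm voxels (the CT
#' layer thickness), 2 mm metal beads and 25 mm metal pins. Hounsfield
#' values must be strictly ordered air < soft < bone < metal so that
#' threshold-based fiducial detection is unambiguous.
#'
#' @param grid_shape Integer triple, voxels per axis.
#' @param voxel_spacing_mm Positive real triple, mm per voxel.
#' @param bead_diameter_mm Diameter of the metal beads (mm).
#' @param pin_length_mm Length of the metal pins (mm); must exceed
#'   `bead_diameter_mm`.
#' @param hu_air,hu_soft,hu_bone,hu_metal Attenuation values (HU) of the
#'   four tissue/material classes.
#' @param blooming_sigma_mm Standard deviation (mm) of an optional Gaussian
#'   blur applied to the rasterized volume, mimicking the CT blooming
#'   artefact around dense metal. `0` (default) keeps the rasterization
#'   crisp.
#' @param seed Integer seed recorded with the phantom; generation is fully
#'   deterministic.
#' @return A validated list of class `"phantom_config"`.
#' @export
phantom_config <- function(grid_shape = c(112L, 112L, 112L),
                           voxel_spacing_mm = c(0.625, 0.625, 0.625),
                           bead_diameter_mm = 2,
                           pin_length_mm = 25,
                           hu_air = -1000, hu_soft = 40,
                           hu_bone = 1200, hu_metal = 3000,
                           blooming_sigma_mm = 0,
                           seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(is.na(grid_shape)) || any(grid_shape < 2L))
    abort("`grid_shape` must be three integers >= 2.", class = "orbitometry_config_error")
  if (length(voxel_spacing_mm) != 3L || any(!is.finite(voxel_spacing_mm)) ||
      any(voxel_spacing_mm <= 0))
    abort("`voxel_spacing_mm` must be three positive reals.", class = "orbitometry_config_error")
  if (!is.finite(bead_diameter_mm) || bead_diameter_mm <= 0 ||
      !is.finite(pin_length_mm) || pin_length_mm <= 0 ||
      bead_diameter_mm >= pin_length_mm)
    abort("need 0 < bead_diameter_mm < pin_length_mm.", class = "orbitometry_config_error")
  hu <- c(hu_air, hu_soft, hu_bone, hu_metal)
  if (any(!is.finite(hu)) || any(diff(hu) <= 0))
    abort("HU values must satisfy hu_air < hu_soft < hu_bone < hu_metal.",
          class = "orbitometry_config_error")
  if (!is.finite(blooming_sigma_mm) || blooming_sigma_mm < 0)
    abort("`blooming_sigma_mm` must be >= 0.", class = "orbitometry_config_error")
  extent <- (grid_shape - 1L) * voxel_spacing_mm
  if (max(extent) < pin_length_mm)
    abort("grid too small: no axis can contain `pin_length_mm`.",
          class = "orbitometry_config_error")
  structure(
    list(grid_shape = grid_shape, voxel_spacing_mm = as.numeric(voxel_spacing_mm),
         bead_diameter_mm = bead_diameter_mm, pin_length_mm = pin_length_mm,
         hu_air = hu_air, hu_soft = hu_soft, hu_bone = hu_bone,
         hu_metal = hu_metal, blooming_sigma_mm = blooming_sigma_mm,
         seed = as.integer(seed)),
    class = "phantom_config")
}

#' Fiducial specification table
#'
#' Builds and validates the table of fiducial landmarks. Locations 1--6 are
#' bead pairs, 7--9 pins. For a bead pair the true diameter is the
#' caliper-relevant outer-surface distance (endpoint distance plus one bead
#' diameter, mirroring jaw contact on the outer borders); for a pin it is
#' the endpoint distance itself.
#'
#' @param location_id Integer 1--9.
#' @param kind `"bead_pair"` or `"pin"`.
#' @param endpoint_a_mm,endpoint_b_mm Lists of length-3 numeric world
#'   coordinates (mm). World coordinates are 0-based voxel index times
#'   spacing; no orientation matrix.
#' @param bead_diameter_mm Bead diameter used for the outer-surface rule.
#' @return A tibble with columns `location_id`, `kind`, `endpoint_a_mm`,
#'   `endpoint_b_mm` (list-columns) and `true_diameter_mm`.
#' @export
fiducial_spec <- function(location_id, kind, endpoint_a_mm, endpoint_b_mm,
                          bead_diameter_mm = 2) {
  stopifnot(length(location_id) == length(kind),
            length(endpoint_a_mm) == length(location_id),
            length(endpoint_b_mm) == length(location_id))
  if (!all(kind %in% c("bead_pair", "pin")))
    abort("`kind` must be 'bead_pair' or 'pin'.", class = "orbitometry_config_error")
  dist <- purrr::map2_dbl(endpoint_a_mm, endpoint_b_mm,
                          ~ sqrt(sum((.x - .y)^2)))
  tibble::tibble(
    location_id = as.integer(location_id),
    kind = kind,
    endpoint_a_mm = endpoint_a_mm,
    endpoint_b_mm = endpoint_b_mm,
    true_diameter_mm = ifelse(kind == "bead_pair", dist + bead_diameter_mm, dist)
  )
}

# Default placement of the nine fiducials inside the grid: bead pairs along
# the frontal/longitudinal/oblique axes around the skull centre, pins along
# the three main axes near the periphery. Directions and lateral offsets are
# chosen so that no two metal components touch.
default_fiducial_layout <- function(config, truths = fixture_truths()) {
  centre <- (config$grid_shape - 1L) * config$voxel_spacing_mm / 2
  tt <- truths$true_diameter_mm
  names(tt) <- truths$location_id
  unit <- function(v) v / sqrt(sum(v^2))
  dirs <- list(`1` = c(1, 0, 0), `2` = c(0, 1, 0), `3` = unit(c(1, 1, 1)),
               `4` = c(0, 0, 1), `5` = c(1, 0, 0), `6` = c(0, 1, 0))
  offs <- list(`1` = c(0, -10, 0), `2` = c(10, 0, 0), `3` = c(0, 0, 0),
               `4` = c(-10, 0, 0), `5` = c(0, 10, 8), `6` = c(-10, 0, -8))
  bead_a <- bead_b <- vector("list", 6L)
  for (i in 1:6) {
    half <- (tt[[as.character(i)]] - config$bead_diameter_mm) / 2
    bead_a[[i]] <- centre + offs[[i]] - half * dirs[[i]]
    bead_b[[i]] <- centre + offs[[i]] + half * dirs[[i]]
  }
  extent <- (config$grid_shape - 1L) * config$voxel_spacing_mm
  pin_a <- list(c(0.14, 0.79, 0.14) * extent,
                c(0.79, 0.14, 0.79) * extent,
                c(0.17, 0.17, 0.50) * extent)
  pin_dir <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  pin_b <- purrr::map(1:3, ~ pin_a[[.x]] + tt[[as.character(.x + 6L)]] * pin_dir[[.x]])
  spec <- fiducial_spec(
    location_id = 1:9,
    kind = rep(c("bead_pair", "pin"), c(6L, 3L)),
    endpoint_a_mm = c(bead_a, pin_a),
    endpoint_b_mm = c(bead_b, pin_b),
    bead_diameter_mm = config$bead_diameter_mm
  )
  spec
}

rasterize_sphere <- function(volume, spacing, centre_mm, radius_mm, value) {
  dims <- dim(volume)
  rng <- lapply(1:3, function(a) {
    lo <- max(0L, floor((centre_mm[a] - radius_mm) / spacing[a]))
    hi <- min(dims[a] - 1L, ceiling((centre_mm[a] + radius_mm) / spacing[a]))
    lo:hi
  })
  g <- expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]])
  d2 <- (g$i * spacing[1] - centre_mm[1])^2 +
        (g$j * spacing[2] - centre_mm[2])^2 +
        (g$k * spacing[3] - centre_mm[3])^2
  sel <- d2 <= radius_mm^2
  volume[cbind(g$i[sel] + 1L, g$j[sel] + 1L, g$k[sel] + 1L)] <- value
  volume
}

rasterize_capsule <- function(volume, spacing, a_mm, b_mm, radius_mm, value) {
  dims <- dim(volume)
  lo_mm <- pmin(a_mm, b_mm) - radius_mm
  hi_mm <- pmax(a_mm, b_mm) + radius_mm
  rng <- lapply(1:3, function(ax) {
    lo <- max(0L, floor(lo_mm[ax] / spacing[ax]))
    hi <- min(dims[ax] - 1L, ceiling(hi_mm[ax] / spacing[ax]))
    lo:hi
  })
  g <- expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]])
  p <- cbind(g$i * spacing[1], g$j * spacing[2], g$k * spacing[3])
  ab <- b_mm - a_mm
  t <- pmin(1, pmax(0, ((p[, 1] - a_mm[1]) * ab[1] + (p[, 2] - a_mm[2]) * ab[2] +
                        (p[, 3] - a_mm[3]) * ab[3]) / sum(ab^2)))
  d2 <- (p[, 1] - (a_mm[1] + t * ab[1]))^2 +
        (p[, 2] - (a_mm[2] + t * ab[2]))^2 +
        (p[, 3] - (a_mm[3] + t * ab[3]))^2
  sel <- d2 <= radius_mm^2
  volume[cbind(g$i[sel] + 1L, g$j[sel] + 1L, g$k[sel] + 1L)] <- value
  volume
}

# Separable Gaussian smoothing along the first array axis; callers permute.
smooth_axis1 <- function(arr, sigma_vox) {
  r <- max(1L, ceiling(3 * sigma_vox))
  w <- exp(-(( -r:r)^2) / (2 * sigma_vox^2))
  w <- w / sum(w)
  d <- dim(arr)
  m <- matrix(arr, nrow = d[1])
  out <- matrix(0, nrow = d[1], ncol = ncol(m))
  for (s in -r:r) {
    rows <- pmin(pmax(seq_len(d[1]) + s, 1L), d[1])  # replicate edges
    out <- out + w[s + r + 1L] * m[rows, , drop = FALSE]
  }
  array(out, dim = d)
}

gaussian_blur3 <- function(volume, sigma_mm, spacing) {
  for (ax in 1:3) {
    sigma_vox <- sigma_mm / spacing[ax]
    if (sigma_vox > 0) {
      perm <- c(ax, setdiff(1:3, ax))
      v <- aperm(volume, perm)
      v <- smooth_axis1(v, sigma_vox)
      volume <- aperm(v, order(perm))
    }
  }
  volume
}

#' Build the synthetic CT skull phantom
#'
#' Rasterizes, on the configured voxel grid, an ellipsoidal bone shell with
#' two spherical orbital cavities, six metal bead pairs and three metal
#' pins at known world positions, and optionally applies a Gaussian
#' blooming blur. The returned object carries the exact fiducial geometry
#' as ground truth, so every downstream measurement can be scored against
#' known diameters. Generation is deterministic for a given configuration.
#'
#' World coordinates are 0-based voxel index times spacing (mm), axis order
#' as stored; there is no orientation matrix.
#'
#' @param config A [phantom_config()].
#' @param fiducials Optional fiducial table from [fiducial_spec()];
#'   defaults to the built-in layout whose true diameters follow
#'   [fixture_truths()].
#' @return An object of class `"phantom"`: a list with `volume` (3-D HU
#'   array), `spacing_mm`, `fiducials` (tibble) and `config`.
#' @export
#' @examples
#' ph <- build_phantom(phantom_config(grid_shape = c(96, 96, 96)))
#' dim(ph$volume)
build_phantom <- function(config = phantom_config(), fiducials = NULL) {
  if (!inherits(config, "phantom_config"))
    abort("`config` must come from phantom_config().", class = "orbitometry_config_error")
  if (is.null(fiducials)) fiducials <- default_fiducial_layout(config)
  extent <- (config$grid_shape - 1L) * config$voxel_spacing_mm
  pts <- c(fiducials$endpoint_a_mm, fiducials$endpoint_b_mm)
  inside <- vapply(pts, function(p) all(p >= 0) && all(p <= extent), logical(1))
  if (!all(inside))
    abort("fiducial endpoints fall outside the grid extent; enlarge `grid_shape`.",
          class = "orbitometry_config_error")
  if (anyDuplicated(fiducials$location_id))
    abort("duplicate location_id in fiducials.", class = "orbitometry_integrity_error")

  sp <- config$voxel_spacing_mm
  dims <- config$grid_shape
  centre <- extent / 2
  x <- (seq_len(dims[1]) - 1L) * sp[1]
  y <- (seq_len(dims[2]) - 1L) * sp[2]
  z <- (seq_len(dims[3]) - 1L) * sp[3]
  semi <- extent * c(0.46, 0.42, 0.42)
  nrm <- outer(outer((x - centre[1])^2 / semi[1]^2,
                     (y - centre[2])^2 / semi[2]^2, "+"),
               (z - centre[3])^2 / semi[3]^2, "+")
  volume <- array(config$hu_air, dim = dims)
  volume[nrm <= 1] <- config$hu_bone            # shell ...
  volume[nrm <= 0.82] <- config$hu_soft         # ... with soft interior
  # two spherical orbital cavities
  orb_r <- 0.16 * max(extent)
  for (sgn in c(-1, 1)) {
    oc <- centre + c(sgn * 0.22, 0.12, 0.12) * extent
    volume <- rasterize_sphere(volume, sp, oc, orb_r, config$hu_air)
  }
  bead_r <- config$bead_diameter_mm / 2
  pin_r <- 0.75
  for (i in seq_len(nrow(fiducials))) {
    a <- fiducials$endpoint_a_mm[[i]]
    b <- fiducials$endpoint_b_mm[[i]]
    if (fiducials$kind[i] == "bead_pair") {
      volume <- rasterize_sphere(volume, sp, a, bead_r, config$hu_metal)
      volume <- rasterize_sphere(volume, sp, b, bead_r, config$hu_metal)
    } else {
      volume <- rasterize_capsule(volume, sp, a, b, pin_r, config$hu_metal)
    }
  }
  if (config$blooming_sigma_mm > 0) {
    volume <- gaussian_blur3(volume, config$blooming_sigma_mm, sp)
    volume <- pmin(pmax(volume, config$hu_air), config$hu_metal)
  }
  structure(list(volume = volume, spacing_mm = sp,
                 fiducials = fiducials, config = config),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat("<phantom> ", paste(dim(x$volume), collapse = " x "),
      " voxels @ ", paste(signif(x$spacing_mm, 4), collapse = "/"),
      " mm, ", nrow(x$fiducials), " fiducials\n", sep = "")
  invisible(x)
}

#' Ground-truth diameters of a phantom
#'
#' Reads the true diameter of each measurement location off the phantom's
#' fiducial geometry: outer-surface distance for bead pairs, endpoint
#' distance for pins.
#'
#' @param phantom A [build_phantom()] result.
#' @return A tibble with columns `location_id`, `landmark_kind` (`"bead"` /
#'   `"pin"`) and `true_diameter_mm`, one row per location.
#' @export
true_diameters <- function(phantom) {
  if (!inherits(phantom, "phantom"))
    abort("`phantom` must come from build_phantom().")
  f <- phantom$fiducials
  if (anyDuplicated(f$location_id))
    abort("duplicate location_id in fiducials.", class = "orbitometry_integrity_error")
  if (any(f$true_diameter_mm <= 0))
    abort("non-positive true diameter.", class = "orbitometry_integrity_error")
  tibble::tibble(
    location_id = f$location_id,
    landmark_kind = ifelse(f$kind == "bead_pair", "bead", "pin"),
    true_diameter_mm = f$true_diameter_mm
  ) |> dplyr::arrange(.data$location_id)
}
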