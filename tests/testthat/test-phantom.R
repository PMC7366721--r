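test_that("phantom construction honours the fiducial contract", {
  ph <- test_phantom()
  f <- ph$fiducials
  expect_identical(sort(f$location_id), 1:9)
  expect_identical(as.vector(table(f$kind)[c("bead_pair", "pin")]),
                   c(6L, 3L))
  td <- true_diameters(ph)
  expect_true(all(td$true_diameter_mm > 0))
  # pin length: endpoints placed pin_length apart measure exactly that
  pin7 <- f[f$location_id == 7L, ]
  expect_equal(pin7$true_diameter_mm,
               sqrt(sum((pin7$endpoint_a_mm[[1]] - pin7$endpoint_b_mm[[1]])^2)))
  # a pin built to be exactly 25 mm long
  spec <- fiducial_spec(7L, "pin", list(c(5, 5, 5)), list(c(30, 5, 5)))
  expect_equal(spec$true_diameter_mm, 25.0)
})

test_that("bead voxels are rasterized at hu_metal when unblurred", {
  ph <- test_phantom()
  expect_identical(ph$config$blooming_sigma_mm, 0)
  a <- ph$fiducials$endpoint_a_mm[[1]]
  idx <- round(a / ph$spacing_mm) + 1L
  expect_equal(ph$volume[idx[1], idx[2], idx[3]], ph$config$hu_metal)
  expect_true(all(ph$volume >= ph$config$hu_air))
  expect_true(all(ph$volume <= ph$config$hu_metal))
})

test_that("bead-pair diameters follow the outer-surface rule", {
  cfg <- phantom_config()
  f <- test_phantom()$fiducials
  beads <- f[f$kind == "bead_pair", ]
  centre_dist <- purrr::map2_dbl(beads$endpoint_a_mm, beads$endpoint_b_mm,
                                 ~ sqrt(sum((.x - .y)^2)))
  expect_equal(beads$true_diameter_mm, centre_dist + cfg$bead_diameter_mm,
               tolerance = 1e-12)
})

test_that("true diameters agree with endpoints and a brute-force oracle", {
  ph <- test_phantom()
  td <- true_diameters(ph)
  f <- ph$fiducials
  brute <- vapply(seq_len(nrow(f)), function(i) {
    a <- f$endpoint_a_mm[[i]]; b <- f$endpoint_b_mm[[i]]
    acc <- 0
    for (ax in 1:3) acc <- acc + (a[ax] - b[ax])^2   # explicit loop oracle
    d <- sqrt(acc)
    if (f$kind[i] == "bead_pair") d + ph$config$bead_diameter_mm else d
  }, numeric(1))
  expect_lt(max(abs(td$true_diameter_mm[order(f$location_id)] - brute[order(f$location_id)])),
            1e-9)

  # randomized endpoints
  set.seed(99)
  for (rep in 1:25) {
    a <- runif(3, 0, 50); b <- runif(3, 0, 50)
    spec <- fiducial_spec(9L, "pin", list(a), list(b))
    expect_equal(spec$true_diameter_mm, sqrt(sum((a - b)^2)), tolerance = 1e-12)
  }
})

test_that("default fixture truths anchor location 5 near 28.2 mm", {
  td <- true_diameters(test_phantom())
  expect_equal(td$true_diameter_mm[td$location_id == 5L], 28.2,
               tolerance = 0.005)
})

test_that("rasterization conserves bead centroids to half a voxel", {
  ph <- test_phantom()
  thr <- (ph$config$hu_bone + ph$config$hu_metal) / 2
  det <- detect_fiducials(ph$volume, ph$spacing_mm, thr, min_voxels = 2)
  truth_pts <- do.call(rbind, c(ph$fiducials$endpoint_a_mm[ph$fiducials$kind == "bead_pair"],
                                ph$fiducials$endpoint_b_mm[ph$fiducials$kind == "bead_pair"]))
  cent <- as.matrix(det[, c("centroid_x_mm", "centroid_y_mm", "centroid_z_mm")])
  half_vox <- max(ph$spacing_mm) / 2
  for (i in seq_len(nrow(truth_pts))) {
    d <- sqrt(rowSums((cent - matrix(truth_pts[i, ], nrow(cent), 3, byrow = TRUE))^2))
    expect_lt(min(d), half_vox)
  }
})

test_that("blooming blur barely moves fiducial centroids", {
  sigma <- 0.4
  cfg <- phantom_config(grid_shape = c(96, 96, 96), blooming_sigma_mm = sigma)
  ph <- build_phantom(cfg)
  # blooming pulls peak HU of the small beads down, so threshold just above
  # bone rather than midway to metal
  thr <- cfg$hu_bone + 400
  det <- detect_fiducials(ph$volume, ph$spacing_mm, thr, min_voxels = 2)
  sharp <- detect_fiducials(test_phantom()$volume, ph$spacing_mm, thr, min_voxels = 2)
  expect_equal(nrow(det), nrow(sharp))
  # bead components are the 12 smallest; pin centroids are not landmark
  # points (their blur halo widens where the pin crosses the bone shell)
  bead_rows <- function(x) utils::tail(x[order(-x$voxel_count), ], 12L)
  cent_b <- as.matrix(bead_rows(det)[, 1:3])
  cent_s <- as.matrix(bead_rows(sharp)[, 1:3])
  for (i in seq_len(nrow(cent_s))) {
    d <- sqrt(rowSums((cent_b - matrix(cent_s[i, ], nrow(cent_b), 3, byrow = TRUE))^2))
    expect_lt(min(d), sigma)
  }
})

test_that("phantom generation is bit-reproducible", {
  cfg <- phantom_config(grid_shape = c(96, 96, 96))
  expect_identical(build_phantom(cfg)$volume, build_phantom(cfg)$volume)
})

test_that("invalid configurations are rejected", {
  expect_error(phantom_config(grid_shape = c(20, 20, 20)),
               class = "orbitometry_config_error")  # cannot hold a 25 mm pin
  expect_error(phantom_config(voxel_spacing_mm = c(0.625, 0, 0.625)),
               class = "orbitometry_config_error")
  expect_error(phantom_config(hu_bone = 5000),
               class = "orbitometry_config_error")
  expect_error(phantom_config(bead_diameter_mm = 30),
               class = "orbitometry_config_error")
  bad <- test_phantom()
  bad$fiducials$location_id[2] <- 1L
  expect_error(true_diameters(bad), class = "orbitometry_integrity_error")
})
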