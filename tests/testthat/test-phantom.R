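small_spec <- function(diameter = 6, spacing = 0.3, blur = 0, speckle = FALSE,
                       seed = 1L, margin = 4) {
  half <- diameter / 2 + margin
  phantom_spec(
    size_mm = c(2 * half, 2 * half, 12),
    spacing_mm = spacing,
    inserts = tibble::tibble(cx = half, cy = half, cz = 6,
                             ax = 0, ay = 0, az = 1,
                             diameter_mm = diameter, length_mm = 8),
    blur_sigma_mm = blur, speckle = speckle, seed = seed
  )
}

test_that("noise-free phantoms take exact plateau intensities", {
  spec <- small_spec(diameter = 6, spacing = 0.3)
  img <- generate_phantom(spec)
  centre_idx <- round(physical_to_index(img, c(7, 7, 6))) + 1
  expect_identical(img$voxels[centre_idx[1], centre_idx[2], centre_idx[3]],
                   spec$insert_intensity)
  expect_identical(img$voxels[1, 1, 1], spec$background)

  # default three-insert spec: every insert interior darker than background
  spec3 <- phantom_spec(spacing_mm = 0.4, blur_sigma_mm = 0.4, speckle = TRUE)
  img3 <- generate_phantom(spec3)
  for (i in seq_len(nrow(spec3$inserts))) {
    ins <- spec3$inserts[i, ]
    ctr <- physical_to_index(img3, c(ins$cx, ins$cy, ins$cz))
    r_vox <- floor(ins$diameter_mm / 2 / 0.4) - 1
    block <- img3$voxels[round(ctr[1]) + seq(-r_vox, r_vox) + 1,
                         round(ctr[2]) + seq(-r_vox, r_vox) + 1,
                         round(ctr[3]) + 1]
    expect_lt(mean(block), mean(img3$voxels))
  }
})

test_that("phantom generation is deterministic given the seed", {
  spec <- small_spec(spacing = 0.4, blur = 0.4, speckle = TRUE, seed = 99L)
  expect_identical(generate_phantom(spec)$voxels, generate_phantom(spec)$voxels)
  spec2 <- small_spec(spacing = 0.4, blur = 0.4, speckle = TRUE, seed = 100L)
  expect_false(identical(generate_phantom(spec)$voxels,
                         generate_phantom(spec2)$voxels))
})

test_that("overlapping or ill-posed inserts are rejected", {
  overlapping <- tibble::tibble(
    cx = c(10, 12), cy = 10, cz = 6, ax = 0, ay = 0, az = 1,
    diameter_mm = c(6, 6), length_mm = 8
  )
  expect_error(
    phantom_spec(size_mm = c(20, 20, 12), inserts = overlapping),
    class = "caliper3d_phantom_error"
  )
  expect_error(
    phantom_spec(insert_intensity = 0.7, background = 0.6),
    class = "caliper3d_phantom_error"
  )
  too_big <- tibble::tibble(cx = 5, cy = 5, cz = 6, ax = 0, ay = 0, az = 1,
                            diameter_mm = 30, length_mm = 8)
  expect_error(phantom_spec(size_mm = c(10, 10, 12), inserts = too_big),
               class = "caliper3d_phantom_error")
})

test_that("edge localisation is exact on an analytic profile", {
  # symmetric profile with linear edges crossing half-contrast at 2.5 mm
  dist <- seq(0, 8, by = 0.05)
  ramp <- function(d) pmin(pmax((d - 2.4) / 0.2, 0), 1)
  prof <- list(dist = dist, val = 0.1 + 0.8 * ramp(dist))
  edge <- profile_edge(prof, plateau_halfwidth_mm = 1)
  expect_equal(edge$distance, 2.5, tolerance = 1e-9)
  expect_equal(edge$threshold, 0.5, tolerance = 1e-9)
  # diameter = sum of the two (symmetric) edge distances
  expect_equal(edge$distance * 2, 5.0, tolerance = 1e-9)
})

test_that("the caliper recovers known insert diameters", {
  spec <- small_spec(diameter = 6, spacing = 0.2, blur = 0.3)
  img <- generate_phantom(spec)
  for (u in list(c(1, 0, 0), c(0, 1, 0))) {
    res <- measure_insert_diameter(img, c(7, 7, 6), u)
    expect_equal(res$diameter_mm, 6, tolerance = 0.2)
    expect_equal(sqrt(sum((res$edge_mm[, 1] - res$edge_mm[, 2])^2)),
                 res$diameter_mm, tolerance = 1e-9)
  }
  expect_identical(measure_insert_diameter(img, c(7, 7, 6), c(1, 0, 0))$axis_label, "H")
  expect_identical(measure_insert_diameter(img, c(7, 7, 6), c(0, 1, 0))$axis_label, "V")
})

test_that("caliper error is non-increasing as voxels shrink (blur-free limit)", {
  errs <- vapply(c(0.4, 0.2, 0.1), function(sp) {
    spec <- small_spec(diameter = 4, spacing = sp, blur = 0)
    img <- generate_phantom(spec)
    abs(measure_insert_diameter(img, c(6, 6, 6), c(1, 0, 0))$diameter_mm - 4)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-9))
  expect_lt(errs[3], 0.1)
})

test_that("the caliper is invariant to affine intensity rescaling", {
  spec <- small_spec(diameter = 6, spacing = 0.3, blur = 0.4, speckle = TRUE)
  img <- generate_phantom(spec)
  d1 <- measure_insert_diameter(img, c(7, 7, 6), c(1, 0, 0))$diameter_mm
  img2 <- img
  img2$voxels <- 37.5 * img$voxels + 12
  d2 <- measure_insert_diameter(img2, c(7, 7, 6), c(1, 0, 0))$diameter_mm
  expect_equal(d1, d2, tolerance = 1e-9)
})

test_that("speckled measurements are unbiased within two voxel spacings", {
  ds <- vapply(1:50, function(seed) {
    spec <- small_spec(diameter = 6, spacing = 0.4, blur = 0.8,
                       speckle = TRUE, seed = seed)
    img <- generate_phantom(spec)
    measure_insert_diameter(img, c(7, 7, 6), c(1, 0, 0))$diameter_mm
  }, numeric(1))
  expect_lt(abs(mean(ds) - 6), 2 * 0.4)
})

test_that("profiles with no contrast or no room report an edge error", {
  flat <- volume_image(array(0.5, c(30, 30, 30)), spacing = c(0.5, 0.5, 0.5))
  expect_error(measure_insert_diameter(flat, c(7, 7, 7), c(1, 0, 0)),
               class = "caliper3d_edge_error")
  expect_error(profile_edge(list(dist = c(0, 0.1), val = c(0, 1))),
               class = "caliper3d_edge_error")
})

test_that("phantom specs round-trip through YAML configs", {
  spec <- phantom_spec(spacing_mm = 0.25, blur_sigma_mm = 0.5, speckle = FALSE,
                       seed = 42L)
  path <- withr::local_tempfile(fileext = ".yaml")
  phantom_spec_write(spec, path)
  back <- phantom_spec_read(path)
  expect_equal(back$size_mm, spec$size_mm)
  expect_equal(back$spacing_mm, spec$spacing_mm)
  expect_identical(back$seed, spec$seed)
  expect_equal(as.data.frame(back$inserts), as.data.frame(spec$inserts))
  expect_identical(back$speckle, FALSE)
})
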