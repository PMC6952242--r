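test_that("measurements anchor endpoints at the requested world positions", {
  fix <- measurement_fixture(c(0, 0, 0), c(10, 0, 0))
  expect_equal(to_local(fix$m$node, to_world(fix$m$start, c(0, 0, 0))),
               fix$m$start$local$translation, tolerance = 1e-12)
  expect_equal(to_world(fix$m$start, c(0, 0, 0)), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(to_world(fix$m$end, c(0, 0, 0)), c(0.01, 0, 0), tolerance = 1e-12)

  # translated volume: same world inputs land at shifted local positions
  root <- scene_node("root")
  vol <- attach_volume(root, volume_image(array(0, c(4, 4, 4))))
  set_local_transform(vol, transform3d(c(1, 0, 0)))
  m <- create_measurement(vol, c(0, 0, 0), c(0.01, 0, 0), "m")
  expect_equal(m$start$local$translation, c(-1, 0, 0), tolerance = 1e-12)
  expect_equal(to_world(m$start, c(0, 0, 0)), c(0, 0, 0), tolerance = 1e-12)

  # random volume pose: world positions reproduced through the scene graph
  set.seed(41)
  for (rep in 1:5) {
    root <- scene_node("root")
    vol <- attach_volume(root, volume_image(array(0, c(4, 4, 4))))
    set_local_transform(vol, random_pose()$transform)
    sw <- rnorm(3); ew <- rnorm(3)
    m <- create_measurement(vol, sw, ew, "m")
    expect_equal(to_world(m$start, c(0, 0, 0)), sw, tolerance = 1e-9)
    expect_equal(to_world(m$end, c(0, 0, 0)), ew, tolerance = 1e-9)
  }
})

test_that("measured distance is rigid- and zoom-invariant and matches the mm oracle", {
  fix <- measurement_fixture(c(0, 0, 0), c(30, 0, 0))
  expect_equal(measured_distance(fix$m), 30, tolerance = 1e-12)
  set_uniform_scale(fix$vol, 2)
  expect_equal(measured_distance(fix$m), 30, tolerance = 1e-9)

  set.seed(42)
  for (rep in 1:20) {
    p1 <- runif(3, 0, 50); p2 <- runif(3, 0, 50)
    fix <- measurement_fixture(p1, p2)
    truth <- sqrt(sum((p1 - p2)^2)) # mm-space Euclidean oracle
    expect_equal(measured_distance(fix$m), truth, tolerance = 1e-9)
    # random rigid motion + uniform zoom of the volume node
    pose <- random_pose()
    set_local_transform(fix$vol, pose$transform)
    expect_equal(measured_distance(fix$m), truth, tolerance = 1e-9)
    # cross-check: volume-space distance agrees while nothing is grabbed
    expect_equal(measured_distance_volume_space(fix$m), truth, tolerance = 1e-9)
  }
})

test_that("a zero-length measurement is allowed and reads 0", {
  fix <- measurement_fixture(c(5, 5, 5), c(5, 5, 5))
  expect_equal(measured_distance(fix$m), 0)
})

test_that("missing reference node is a configuration error", {
  root <- scene_node("root")
  vol <- attach_volume(root, volume_image(array(0, c(4, 4, 4))))
  m <- create_measurement(vol, c(0, 0, 0), c(0.01, 0, 0), "m")
  vol$is_reference_scale <- FALSE
  expect_error(measured_distance(m), class = "caliper3d_configuration_error")
})

test_that("grab/move/release edits the measurement through re-parenting", {
  fix <- measurement_fixture(c(0, 0, 0), c(30, 0, 0))
  controller <- scene_node("controller", parent = fix$root)

  grab(fix$m$end, controller)
  expect_identical(fix$m$end$parent, controller)
  set_local_transform(controller,
                      transform3d(controller$local$translation + c(0.01, 0, 0)))
  release(fix$m$end)
  expect_identical(fix$m$end$parent, fix$m$node)
  # oracle: endpoint moved +10 mm along x in anatomy space
  expect_equal(measured_distance(fix$m), 40, tolerance = 1e-9)

  # grab/release without motion leaves the measurement unchanged
  d0 <- measured_distance(fix$m)
  s0 <- fix$m$start$local$translation
  grab(fix$m$start, controller); release(fix$m$start)
  expect_equal(measured_distance(fix$m), d0, tolerance = 1e-9)
  expect_equal(fix$m$start$local$translation, s0, tolerance = 1e-9)
})

test_that("grabbing the connector moves the whole measurement rigidly", {
  fix <- measurement_fixture(c(0, 0, 0), c(30, 0, 0))
  controller <- scene_node("controller", parent = fix$root)
  s_before <- to_world(fix$m$start, c(0, 0, 0))
  e_before <- to_world(fix$m$end, c(0, 0, 0))

  moved <- grab(fix$m$connector, controller)
  expect_identical(moved, fix$m$node) # redirected to the parent measurement
  set_local_transform(controller, transform3d(c(0.005, -0.002, 0.001)))
  expect_equal(to_world(fix$m$start, c(0, 0, 0)) - s_before,
               c(0.005, -0.002, 0.001), tolerance = 1e-9)
  expect_equal(to_world(fix$m$end, c(0, 0, 0)) - e_before,
               c(0.005, -0.002, 0.001), tolerance = 1e-9)
  expect_equal(measured_distance(fix$m), 30, tolerance = 1e-9)
  release(fix$m$connector)
  expect_identical(fix$m$node$parent, fix$vol)
})

test_that("grab state errors are reported and editing preserves structure", {
  fix <- measurement_fixture(c(0, 0, 0), c(30, 0, 0))
  controller <- scene_node("controller", parent = fix$root)
  grab(fix$m$end, controller)
  expect_error(grab(fix$m$end, controller), class = "caliper3d_state_error")
  # volume-space distance is undefined while an endpoint is grabbed
  expect_error(measured_distance_volume_space(fix$m),
               class = "caliper3d_state_error")
  release(fix$m$end)
  expect_warning(release(fix$m$end), "without grab")

  # editing closure: random grab/move/release sequences keep the
  # five-child structure intact and the graph a forest
  set.seed(43)
  for (rep in 1:10) {
    el <- list(fix$m$start, fix$m$end, fix$m$label, fix$m$connector)[[sample(4, 1)]]
    grab(el, controller)
    set_local_transform(controller, transform3d(rnorm(3, sd = 0.01)))
    release(el)
  }
  kids <- vapply(fix$m$node$children, function(n) n$role, character(1))
  expect_setequal(kids, c("start", "end", "connector", "label", "label_connector"))
  expect_identical(node_root(fix$m$start)$name, "root")
})

test_that("connector layout keeps regular symmetric spacing", {
  lay <- connector_layout(c(0, 0, 0), c(10, 0, 0), segment_length = 1, gap = 1)
  expect_identical(nrow(lay$segments), 5L)
  expect_equal(lay$segments$centre_x, c(0.5, 2.5, 4.5, 6.5, 8.5) + 0.5)
  expect_identical(nrow(connector_layout(c(1, 1, 1), c(1, 1, 1), 1, 1)$segments), 0L)

  set.seed(44)
  last_n <- 0L
  for (d in sort(runif(20, 0.1, 50))) {
    u <- random_axis()
    lay <- connector_layout(c(0, 0, 0), d * u, segment_length = 2, gap = 2)
    n <- nrow(lay$segments)
    expect_gte(n, last_n) # count non-decreasing with distance
    last_n <- n
    expect_equal(unique(lay$segments$length), 2)
    expect_equal(c(lay$segments$dir_x[1], lay$segments$dir_y[1], lay$segments$dir_z[1]),
                 u, tolerance = 1e-12)
    if (n >= 2L) {
      centres <- as.matrix(lay$segments[, c("centre_x", "centre_y", "centre_z")])
      gaps <- sqrt(rowSums(diff(centres)^2))
      expect_lt(max(gaps) - min(gaps), 1e-9) # equal spacing
      # symmetric placement about the chord midpoint
      mid <- (centres[1, ] + centres[n, ]) / 2
      expect_equal(as.numeric(mid), as.numeric(d * u / 2), tolerance = 1e-9)
    }
  }
})

test_that("marker render scale exactly cancels the reference zoom", {
  expect_equal(marker_render_scale(1), 1)
  expect_equal(marker_render_scale(2), 0.5)
  expect_equal(marker_render_scale(0.25), 4.0)
  for (s in c(0.1, 0.5, 1, 3, 17)) {
    expect_identical(marker_render_scale(s) * s, 1)
  }
})

test_that("labels quantize with ties away from zero and match the precision's decimals", {
  expect_identical(format_label(30.04, 0.1), "30.0 mm")
  expect_identical(format_label(10.4, 1.0), "10 mm")
  expect_identical(format_label(3.45, 0.1), "3.5 mm")
  expect_identical(format_label(0, 0.1), "0.0 mm")
  expect_identical(format_label(10.125, 0.25), "10.25 mm")
})

test_that("measurement sidecar files round-trip stored decimals exactly", {
  fix <- measurement_fixture(c(1.25, 2.5, 3.75), c(31.25, 2.5, 3.75))
  path <- withr::local_tempfile(fileext = ".json")
  measurements_write(list(fix$m), path, volume_node = fix$vol)
  tab <- measurements_read(path)
  expect_identical(nrow(tab), 1L)
  expect_identical(tab$id, "m1")
  expect_identical(tab$label, "30.0 mm")
  expect_equal(tab$start_mm[[1]], c(1.25, 2.5, 3.75), tolerance = 1e-12)
  expect_equal(tab$distance_mm, 30, tolerance = 1e-12)

  # write the tibble back out: byte-identical JSON
  path2 <- withr::local_tempfile(fileext = ".json")
  measurements_write(tab, path2)
  expect_identical(readLines(path2), readLines(path))
})
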