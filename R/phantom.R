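#' Synthetic ultrasound calibration-phantom specification
#'
#' Describes a speckle-background volume containing cylindrical low-scatter
#' ("cyst") inserts of known diameter, emulating the appearance of an
#' ultrasound calibration phantom used to assess measurement accuracy. The
#' default specification carries three parallel cylinders of 4, 6 and 10 mm
#' diameter, which measured both horizontally and vertically yields the six
#' phantom sizing tasks of the study protocol.
#'
#' The inserts tibble has one row per cylinder: centre (mm), axis (unit
#' vector), diameter (mm) and length (mm). Inserts must fit inside the
#' volume, must not overlap, and must be darker than the background.
#'
#' @param size_mm Physical extent of the volume, mm (length 3).
#' @param spacing_mm Isotropic voxel spacing, mm (scalar or length 3).
#' @param background Mean background (speckle) intensity.
#' @param insert_intensity Mean intensity inside the low-scatter inserts;
#'   must be below `background`.
#' @param inserts Tibble with columns `cx, cy, cz, ax, ay, az, diameter_mm,
#'   length_mm`; default three cylinders of 4, 6, 10 mm diameter with axes
#'   along z, separated both laterally (x) and in depth (y).
#' @param blur_sigma_mm Isotropic Gaussian blur applied after noise, mm
#'   (0 disables).
#' @param speckle Apply multiplicative unit-mean Rayleigh speckle before
#'   the blur.
#' @param seed RNG seed for the speckle field.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(size_mm = c(40, 30, 20),
                         spacing_mm = 0.2,
                         background = 0.6,
                         insert_intensity = 0.1,
                         inserts = default_inserts(),
                         blur_sigma_mm = 0.3,
                         speckle = TRUE,
                         seed = 1L) {
  size_mm <- as.numeric(size_mm)
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  stopifnot(length(size_mm) == 3L, all(size_mm > 0), all(spacing_mm > 0),
            blur_sigma_mm >= 0)
  if (insert_intensity >= background) {
    rlang::abort("insert intensity must be below the background (low scatter)",
                 class = "caliper3d_phantom_error")
  }
  inserts <- tibble::as_tibble(inserts)
  req <- c("cx", "cy", "cz", "ax", "ay", "az", "diameter_mm", "length_mm")
  stopifnot(all(req %in% names(inserts)))
  if (any(inserts$diameter_mm <= 0) || any(inserts$length_mm <= 0)) {
    rlang::abort("insert diameters and lengths must be positive",
                 class = "caliper3d_phantom_error")
  }
  spec <- structure(
    list(size_mm = size_mm, spacing_mm = spacing_mm, background = background,
         insert_intensity = insert_intensity, inserts = inserts,
         blur_sigma_mm = blur_sigma_mm, speckle = isTRUE(speckle),
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
  check_inserts(spec)
  spec
}

#' @rdname phantom_spec
#' @export
default_inserts <- function() {
  tibble::tibble(
    cx = c(8, 20, 31),
    cy = c(8, 15, 22), # staggered depths so H profiles clear the neighbours
    cz = 10,
    ax = 0, ay = 0, az = 1,
    diameter_mm = c(4, 6, 10),
    length_mm = 14
  )
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %s mm at %s mm/voxel, %d insert(s): %s mm diameter\n",
              paste(x$size_mm, collapse = "x"),
              paste(format(x$spacing_mm, digits = 3), collapse = "x"),
              nrow(x$inserts),
              paste(x$inserts$diameter_mm, collapse = ", ")))
  invisible(x)
}

check_inserts <- function(spec) {
  ins <- spec$inserts
  for (i in seq_len(nrow(ins))) {
    r <- ins$diameter_mm[i] / 2
    u <- c(ins$ax[i], ins$ay[i], ins$az[i]); u <- u / sqrt(sum(u^2))
    # exact axis-aligned extent of a finite cylinder
    reach <- (ins$length_mm[i] / 2) * abs(u) + r * sqrt(pmax(1 - u^2, 0))
    centre <- c(ins$cx[i], ins$cy[i], ins$cz[i])
    if (any(centre - reach < 0) || any(centre + reach > spec$size_mm)) {
      rlang::abort(sprintf("insert %d does not fit inside the volume", i),
                   class = "caliper3d_phantom_error")
    }
  }
  if (nrow(ins) > 1L) {
    for (i in seq_len(nrow(ins) - 1L)) {
      for (j in seq(i + 1L, nrow(ins))) {
        cij <- sqrt((ins$cx[i] - ins$cx[j])^2 + (ins$cy[i] - ins$cy[j])^2 +
                      (ins$cz[i] - ins$cz[j])^2)
        reach_i <- sqrt((ins$diameter_mm[i] / 2)^2 + (ins$length_mm[i] / 2)^2)
        reach_j <- sqrt((ins$diameter_mm[j] / 2)^2 + (ins$length_mm[j] / 2)^2)
        if (cij < reach_i + reach_j &&
            cylinders_overlap(ins[i, ], ins[j, ])) {
          rlang::abort(sprintf("inserts %d and %d overlap", i, j),
                       class = "caliper3d_phantom_error")
        }
      }
    }
  }
  invisible(spec)
}

# conservative overlap test for parallel-ish cylinders: bounding spheres of
# the cross-sections along the common axis direction
cylinders_overlap <- function(a, b) {
  ca <- c(a$cx, a$cy, a$cz); cb <- c(b$cx, b$cy, b$cz)
  ua <- c(a$ax, a$ay, a$az); ua <- ua / sqrt(sum(ua^2))
  d <- cb - ca
  axial <- abs(sum(d * ua))
  radial <- sqrt(max(sum(d^2) - sum(d * ua)^2, 0))
  axial < (a$length_mm + b$length_mm) / 2 &&
    radial < (a$diameter_mm + b$diameter_mm) / 2
}

#' Generate a synthetic phantom volume
#'
#' Renders the specification into a [volume_image()]: voxels whose centres
#' fall inside any cylinder take the insert intensity and all others the
#' background intensity; optional multiplicative unit-mean Rayleigh
#' speckle (seeded, drawn before the blur) emulates ultrasound texture;
#' finally an isotropic Gaussian blur of the stated sigma softens the
#' edges as the imaging system's point-spread function would. The output
#' is deterministic given the spec's seed.
#'
#' This is an appearance emulation for exercising calipers and observer
#' models — not an acoustic simulation (no beamforming, attenuation or
#' shadowing).
#'
#' @param spec A [phantom_spec()].
#' @return A [volume_image()] with the spec's spacing and origin at
#'   (0, 0, 0) (first voxel centre at half a spacing).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  check_inserts(spec)
  dims <- pmax(1L, as.integer(round(spec$size_mm / spec$spacing_mm)))
  vox <- array(spec$background, dim = dims)
  origin <- spec$spacing_mm / 2 # voxel (0,0,0) centred half a voxel in
  xs <- origin[1] + spec$spacing_mm[1] * (seq_len(dims[1]) - 1L)
  ys <- origin[2] + spec$spacing_mm[2] * (seq_len(dims[2]) - 1L)
  zs <- origin[3] + spec$spacing_mm[3] * (seq_len(dims[3]) - 1L)
  for (i in seq_len(nrow(spec$inserts))) {
    ins <- spec$inserts[i, ]
    u <- c(ins$ax, ins$ay, ins$az); u <- u / sqrt(sum(u^2))
    r <- ins$diameter_mm / 2
    half_len <- ins$length_mm / 2
    centre <- c(ins$cx, ins$cy, ins$cz)
    reach <- sqrt(r^2 + half_len^2)
    sub <- lapply(1:3, function(a) {
      coords <- list(xs, ys, zs)[[a]]
      which(coords >= centre[a] - reach & coords <= centre[a] + reach)
    })
    if (any(lengths(sub) == 0L)) next
    gx <- xs[sub[[1]]] - centre[1]
    gy <- ys[sub[[2]]] - centre[2]
    gz <- zs[sub[[3]]] - centre[3]
    nx <- length(gx); ny <- length(gy); nz <- length(gz)
    X <- array(gx, dim = c(nx, ny, nz))
    Y <- array(rep(gy, each = nx), dim = c(nx, ny, nz))
    Z <- array(rep(gz, each = nx * ny), dim = c(nx, ny, nz))
    axial <- X * u[1] + Y * u[2] + Z * u[3]
    rad2 <- X^2 + Y^2 + Z^2 - axial^2
    inside <- rad2 <= r^2 & abs(axial) <= half_len
    block <- vox[sub[[1]], sub[[2]], sub[[3]]]
    block[inside] <- spec$insert_intensity
    vox[sub[[1]], sub[[2]], sub[[3]]] <- block
  }
  if (spec$speckle) {
    vox <- withr::with_seed(spec$seed, {
      # unit-mean Rayleigh: sigma = sqrt(2/pi); inverse-CDF draw
      sigma <- sqrt(2 / pi)
      n <- length(vox)
      vox * array(sigma * sqrt(-2 * log(stats::runif(n))), dim = dim(vox))
    })
  }
  if (spec$blur_sigma_mm > 0) {
    vox <- gaussian_blur3d(vox, spec$blur_sigma_mm / spec$spacing_mm)
  }
  volume_image(vox, spacing = spec$spacing_mm, origin = origin)
}

#' Separable 3-D Gaussian blur
#'
#' Convolves an array with an isotropic Gaussian, one axis at a time, with
#' replicated edges. Sigma is given per axis in voxel units; a kernel of
#' radius `ceiling(3 * sigma)` is used and renormalised to unit sum.
#'
#' @param a 3-D numeric array.
#' @param sigma_vox Per-axis sigma in voxels (scalar or length 3).
#' @return Blurred array, same dimensions.
#' @export
gaussian_blur3d <- function(a, sigma_vox) {
  stopifnot(is.array(a), length(dim(a)) == 3L)
  sigma_vox <- as.numeric(sigma_vox)
  if (length(sigma_vox) == 1L) sigma_vox <- rep(sigma_vox, 3L)
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    r <- ceiling(3 * s)
    w <- stats::dnorm(seq(-r, r), sd = s)
    w <- w / sum(w)
    a <- convolve_axis(a, w, axis)
  }
  a
}

# shifted-sum convolution along one axis with replicated (clamped) edges
convolve_axis <- function(a, w, axis) {
  d <- dim(a)
  n <- d[axis]
  r <- (length(w) - 1L) / 2
  out <- array(0, dim = d)
  base <- seq_len(n)
  for (k in seq_along(w)) {
    shift <- k - 1L - r
    idx <- pmin(pmax(base + shift, 1L), n)
    shifted <- switch(axis,
                      a[idx, , , drop = FALSE],
                      a[, idx, , drop = FALSE],
                      a[, , idx, drop = FALSE])
    out <- out + w[k] * shifted
  }
  out
}

# ---- automated caliper --------------------------------------------------

#' Automated full-width-at-half-contrast caliper
#'
#' Measures an insert's diameter the way a human places calipers on a cyst
#' edge, but automatically: the intensity profile is sampled by trilinear
#' interpolation along `+/- direction` from the given centre; the insert
#' plateau level is estimated near the centre and the background plateau
#' from the far field of each side; then, walking outward on each side,
#' the first crossing of the half-way threshold
#' `(insert_plateau + background_plateau) / 2` is localised by linear
#' interpolation between samples. The diameter is the distance between the
#' two crossings (full width at half contrast). The estimate is invariant
#' to any global affine rescaling of the image intensities.
#'
#' @param image A [volume_image()].
#' @param centre_mm Length-3 physical point inside the insert, mm.
#' @param direction Length-3 profile direction (normalised internally).
#' @param step_mm Profile sampling step, mm; default half the smallest
#'   voxel spacing.
#' @param threshold_fraction Position of the edge threshold between the
#'   insert and background plateaus; default 0.5 (half contrast).
#' @param plateau_halfwidth_mm Half-width of the central window used to
#'   estimate the insert plateau, mm.
#' @return A `caliper_result`: list with `diameter_mm`, `edge_mm` (3x2
#'   matrix of the two edge points), `axis_label` ("H", "V" or "P"),
#'   `threshold`, `profile` (tibble with `distance_mm`, `side`,
#'   `intensity`).
#' @export
measure_insert_diameter <- function(image, centre_mm, direction,
                                    step_mm = NULL,
                                    threshold_fraction = 0.5,
                                    plateau_halfwidth_mm = 1) {
  stopifnot(is_volume_image(image))
  direction <- as.numeric(direction)
  u <- direction / sqrt(sum(direction^2))
  if (is.null(step_mm)) step_mm <- min(image$spacing) / 2
  stopifnot(step_mm > 0)
  centre_mm <- as.numeric(centre_mm)

  side_profile <- function(sgn) {
    # march to the volume face along sgn*u
    reach <- profile_reach(image, centre_mm, sgn * u)
    dist <- seq(0, reach, by = step_mm)
    pts <- centre_mm + t(outer(sgn * dist, u))
    val <- sample_trilinear(image, physical_to_index(image, pts))
    keep <- !is.na(val)
    list(dist = dist[keep], val = val[keep])
  }
  pos <- side_profile(+1)
  neg <- side_profile(-1)
  edge1 <- profile_edge(pos, plateau_halfwidth_mm, threshold_fraction)
  edge2 <- profile_edge(neg, plateau_halfwidth_mm, threshold_fraction)
  diameter <- edge1$distance + edge2$distance
  axis_label <- profile_axis_label(u)
  profile <- dplyr::bind_rows(
    tibble::tibble(distance_mm = pos$dist, side = "+", intensity = pos$val),
    tibble::tibble(distance_mm = -neg$dist, side = "-", intensity = neg$val)
  )
  structure(
    list(
      diameter_mm = diameter,
      edge_mm = cbind(centre_mm + edge1$distance * u,
                      centre_mm - edge2$distance * u),
      axis_label = axis_label,
      threshold = (edge1$threshold + edge2$threshold) / 2,
      profile = profile
    ),
    class = "caliper_result"
  )
}

#' @export
print.caliper_result <- function(x, ...) {
  cat(sprintf("<caliper_result> %s diameter %.3f mm\n", x$axis_label, x$diameter_mm))
  invisible(x)
}

profile_axis_label <- function(u) {
  ax <- which.max(abs(u))
  if (abs(u[ax]) < 0.9) return("P") # oblique profile
  c("H", "V", "P")[ax]
}

profile_reach <- function(image, centre_mm, u) {
  # largest t with centre + t*u still inside the voxel-centre hull
  d <- dim(image$voxels)
  ijk0 <- physical_to_index(image, centre_mm)
  du <- as.numeric(physical_to_index(image, centre_mm + u)) - as.numeric(ijk0)
  tmax <- Inf
  for (a in 1:3) {
    if (abs(du[a]) < 1e-12) next
    lim <- if (du[a] > 0) (d[a] - 1 - ijk0[a]) / du[a] else (0 - ijk0[a]) / du[a]
    tmax <- min(tmax, lim)
  }
  max(tmax, 0)
}

#' Locate the half-contrast edge on a one-sided intensity profile
#'
#' Shared edge-localisation core of the caliper, usable directly on any
#' sampled profile (distances from the insert centre and intensities).
#' Estimates the insert plateau as the mean within
#' `plateau_halfwidth_mm` of the centre and the background plateau as the
#' mean over the outer 70–95% of the side's reach, then finds the first
#' outward crossing of
#' `insert + threshold_fraction * (background - insert)` and localises it
#' by linear interpolation between the straddling samples.
#'
#' @param profile List with `dist` (increasing distances from the centre,
#'   mm) and `val` (intensities).
#' @param plateau_halfwidth_mm Central plateau window half-width, mm.
#' @param threshold_fraction Fractional contrast level of the edge.
#' @return List with `distance` (mm from centre), `threshold`.
#' @export
profile_edge <- function(profile, plateau_halfwidth_mm = 1,
                         threshold_fraction = 0.5) {
  dist <- profile$dist; val <- profile$val
  stopifnot(length(dist) == length(val))
  if (length(dist) <= 2L) {
    rlang::abort("edge not found: profile too short", class = "caliper3d_edge_error")
  }
  reach <- max(dist)
  inner <- dist <= plateau_halfwidth_mm
  outer <- dist >= 0.7 * reach & dist <= 0.95 * reach
  if (!any(inner) || !any(outer)) {
    rlang::abort("edge not found: profile too short for plateau estimation",
                 class = "caliper3d_edge_error")
  }
  insert_level <- mean(val[inner])
  background_level <- mean(val[outer])
  if (abs(background_level - insert_level) <=
      1e-6 * max(abs(c(background_level, insert_level)), .Machine$double.eps)) {
    rlang::abort("edge not found: no contrast between plateaus",
                 class = "caliper3d_edge_error")
  }
  thr <- insert_level + threshold_fraction * (background_level - insert_level)
  rising <- background_level > insert_level
  crossed <- if (rising) val >= thr else val <= thr
  crossed[inner] <- FALSE # ignore the central plateau itself
  k <- which(crossed)[1]
  if (is.na(k) || k <= 1L) {
    rlang::abort("edge not found within the volume",
                 class = "caliper3d_edge_error")
  }
  # linear interpolation between samples k-1 and k
  v0 <- val[k - 1L]; v1 <- val[k]
  f <- if (abs(v1 - v0) < .Machine$double.eps) 0 else (thr - v0) / (v1 - v0)
  list(distance = dist[k - 1L] + f * (dist[k] - dist[k - 1L]), threshold = thr)
}

#' Measure all inserts of a phantom spec
#'
#' Runs the automated caliper through every insert centre of a spec, both
#' horizontally (x) and vertically (y), returning a tidy table — the
#' phantom sizing tasks of the evaluation protocol.
#'
#' @param image Phantom [volume_image()] (typically from
#'   [generate_phantom()]).
#' @param spec The [phantom_spec()] that generated it.
#' @param ... Passed to [measure_insert_diameter()].
#' @return Tibble with columns `size_mm` (true diameter), `axis` ("H"/"V"),
#'   `measured_mm`.
#' @export
measure_phantom <- function(image, spec, ...) {
  stopifnot(inherits(spec, "phantom_spec"))
  grid <- tidyr::expand_grid(i = seq_len(nrow(spec$inserts)),
                             axis = c("H", "V"))
  purrr::pmap_dfr(grid, function(i, axis) {
    ins <- spec$inserts[i, ]
    u <- if (axis == "H") c(1, 0, 0) else c(0, 1, 0)
    res <- measure_insert_diameter(image, c(ins$cx, ins$cy, ins$cz), u, ...)
    tibble::tibble(size_mm = ins$diameter_mm, axis = axis,
                   measured_mm = res$diameter_mm)
  })
}

# ---- plain-text spec config --------------------------------------------

#' Read and write phantom specs as YAML
#'
#' @param spec A [phantom_spec()].
#' @param path YAML file path.
#' @return `phantom_spec_read()` returns a [phantom_spec()];
#'   `phantom_spec_write()` returns `path`, invisibly.
#' @export
phantom_spec_write <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  x <- unclass(spec)
  x$inserts <- as.data.frame(x$inserts)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname phantom_spec_write
#' @export
phantom_spec_read <- function(path) {
  x <- yaml::read_yaml(path)
  phantom_spec(
    size_mm = unlist(x$size_mm),
    spacing_mm = unlist(x$spacing_mm),
    background = x$background,
    insert_intensity = x$insert_intensity,
    inserts = tibble::as_tibble(as.data.frame(x$inserts)),
    blur_sigma_mm = x$blur_sigma_mm,
    speckle = x$speckle,
    seed = x$seed
  )
}
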