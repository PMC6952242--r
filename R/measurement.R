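#' Linear measurements anchored to a volume
#'
#' A measurement is a small sub-hierarchy parented under the volume node so
#' that it translates, rotates and zooms with the image and stays at the
#' same anatomical position. It has five children: the start point, the end
#' point, a dashed connector between them, a distance label, and a thin
#' connector linking the label to the end point. The start and end points
#' are ordinary scene nodes, so editing them is plain re-parenting.
#'
#' `create_measurement()` places the endpoints at the given world
#' positions; their local positions are derived so the world positions are
#' reproduced exactly whatever the volume's current pose.
#'
#' @param volume_node A volume node from [attach_volume()].
#' @param start_world,end_world Length-3 world-space endpoint positions.
#' @param id Measurement identifier.
#' @param display_precision_mm Display rounding granularity of the
#'   distance label, mm (default 0.1).
#' @return A `measurement3d` object (an environment; fields `id`, `node`,
#'   `start`, `end`, `connector`, `label`, `label_connector`,
#'   `display_precision_mm`).
#' @examples
#' root <- scene_node("root")
#' vol <- attach_volume(root, volume_image(array(0, c(4, 4, 4))))
#' m <- create_measurement(vol, c(0, 0, 0), c(0.03, 0, 0), "d1")
#' measured_distance(m) # 30 mm
#' @export
create_measurement <- function(volume_node, start_world, end_world, id,
                               display_precision_mm = 0.1) {
  stopifnot(is_scene_node(volume_node), is.character(id), length(id) == 1L,
            display_precision_mm > 0)
  if (is.null(node_root(volume_node))) {
    rlang::abort("volume node must be attached to a scene")
  }
  mnode <- scene_node(paste0("measurement:", id), parent = volume_node)
  mnode$role <- "measurement"
  child <- function(role, world_pos = NULL) {
    n <- scene_node(paste0(role, ":", id), parent = mnode)
    n$role <- role
    if (!is.null(world_pos)) {
      n$local <- transform3d(translation = to_local(mnode, world_pos))
    }
    n
  }
  m <- new.env(parent = emptyenv())
  m$id <- id
  m$node <- mnode
  m$start <- child("start", start_world)
  m$end <- child("end", end_world)
  m$connector <- child("connector")
  m$label <- child("label")
  m$label_connector <- child("label_connector")
  m$display_precision_mm <- display_precision_mm
  # marker/connector render geometry, mm at reference scale (not rendered
  # here; carried so sidecar files fully describe the display)
  m$marker <- list(sphere_radius_mm = 1, spoke_length_mm = 4,
                   spoke_thickness_mm = 0.3)
  m$connector_style <- list(segment_length_mm = 2, gap_mm = 2)
  class(m) <- "measurement3d"
  m
}

is_measurement3d <- function(x) inherits(x, "measurement3d")

#' @export
print.measurement3d <- function(x, ...) {
  d <- tryCatch(measured_distance(x), error = function(e) NA_real_)
  cat(sprintf("<measurement3d '%s'> %s\n", x$id,
              if (is.na(d)) "(no reference scale)" else format_label(d, x$display_precision_mm)))
  invisible(x)
}

measurement_volume_node <- function(m) {
  n <- m$node$parent
  while (!is.null(n) && !is_volume_node(n)) n <- n$parent
  n
}

#' Scale-invariant measured distance
#'
#' The distance between the start and end points is computed in world
#' space and inversely scaled by the accumulated zoom of the scene's
#' reference-scale node, then converted to millimetres:
#' `mm_per_world_unit * ||world(end) - world(start)|| / reference_zoom`.
#' The result is therefore invariant to any rigid motion or uniform zoom
#' of the volume — the measurement reads true anatomical millimetres even
#' while an endpoint is grabbed (parented elsewhere), which is why world
#' space rather than volume-local space is used.
#'
#' @param m A `measurement3d`.
#' @param mm_per_world_unit Millimetres per world unit at reference zoom 1;
#'   defaults to the volume node's setting (1000: a world of metres).
#' @return Distance in mm.
#' @export
measured_distance <- function(m, mm_per_world_unit = NULL) {
  stopifnot(is_measurement3d(m))
  ref <- find_reference_node(m$node)
  if (is.null(ref)) {
    rlang::abort("no reference-scale node in the scene",
                 class = "caliper3d_configuration_error")
  }
  if (is.null(mm_per_world_unit)) {
    mm_per_world_unit <- ref$mm_per_world_unit %||% 1000
  }
  w0 <- to_world(m$start, c(0, 0, 0))
  w1 <- to_world(m$end, c(0, 0, 0))
  mm_per_world_unit * sqrt(sum((w1 - w0)^2)) / accumulated_uniform_scale(ref)
}

#' Volume-space distance (cross-check)
#'
#' Computes the same distance from the endpoints' positions in the
#' volume's local space instead of world space. Valid only while both
#' endpoints are parented under the measurement (nothing grabbed); used as
#' an independent cross-check of [measured_distance()], which remains
#' correct during editing.
#'
#' @inheritParams measured_distance
#' @return Distance in mm.
#' @export
measured_distance_volume_space <- function(m, mm_per_world_unit = NULL) {
  stopifnot(is_measurement3d(m))
  if (!identical(m$start$parent, m$node) || !identical(m$end$parent, m$node)) {
    rlang::abort("volume-space distance is undefined while an endpoint is grabbed",
                 class = "caliper3d_state_error")
  }
  vol <- measurement_volume_node(m)
  if (is.null(vol)) {
    rlang::abort("measurement is not under a volume node",
                 class = "caliper3d_configuration_error")
  }
  if (is.null(mm_per_world_unit)) mm_per_world_unit <- vol$mm_per_world_unit %||% 1000
  p0 <- to_local(vol, to_world(m$start, c(0, 0, 0)))
  p1 <- to_local(vol, to_world(m$end, c(0, 0, 0)))
  mm_per_world_unit * sqrt(sum((p1 - p0)^2))
}

#' Grab and release measurement elements
#'
#' `grab()` picks an element up with a controller node: the element is
#' re-parented under the controller (world pose preserved) so it tracks
#' the controller's motion, and its original parent is remembered.
#' `release()` restores the original parent, again preserving world pose.
#' Grabbing the connector redirects to the whole measurement node, so all
#' five children move together.
#'
#' @param element A start/end/label/connector node of a measurement.
#' @param controller Any `scene_node` acting as the controller.
#' @return The node actually moved, invisibly.
#' @export
grab <- function(element, controller) {
  stopifnot(is_scene_node(element), is_scene_node(controller))
  target <- if (identical(element$role, "connector")) element$parent else element
  if (!is.null(target$grab_original_parent)) {
    rlang::abort(sprintf("'%s' is already grabbed", target$name),
                 class = "caliper3d_state_error")
  }
  target$grab_original_parent <- target$parent
  reparent_keep_world(target, controller)
  invisible(target)
}

#' @rdname grab
#' @export
release <- function(element) {
  stopifnot(is_scene_node(element))
  target <- if (identical(element$role, "connector")) element$parent else element
  orig <- target$grab_original_parent
  if (is.null(orig)) {
    rlang::warn(sprintf("release of '%s' without grab; ignored", target$name))
    return(invisible(target))
  }
  target$grab_original_parent <- NULL
  reparent_keep_world(target, orig)
  invisible(target)
}

#' Dashed-connector layout
#'
#' Lays out the dashed line between two points as equal cylinder segments
#' with equal gaps: `n = max(1, floor((d + gap) / (segment_length + gap)))`
#' segments for separation `d > 0`, centred symmetrically on the chord and
#' all oriented along the unit chord vector. A zero separation yields an
#' empty layout.
#'
#' @param start_world,end_world Length-3 endpoint positions.
#' @param segment_length Cylinder length (> 0), same units as the points.
#' @param gap Gap between consecutive cylinders (>= 0).
#' @return A `connector_layout`: list with `segments` (tibble with columns
#'   `centre_x/y/z`, `dir_x/y/z`, `length`), `gap`, `segment_length`.
#' @export
connector_layout <- function(start_world, end_world, segment_length, gap) {
  stopifnot(segment_length > 0, gap >= 0)
  start_world <- as.numeric(start_world); end_world <- as.numeric(end_world)
  delta <- end_world - start_world
  d <- sqrt(sum(delta^2))
  if (d == 0) {
    segs <- tibble::tibble(centre_x = numeric(), centre_y = numeric(),
                           centre_z = numeric(), dir_x = numeric(),
                           dir_y = numeric(), dir_z = numeric(),
                           length = numeric())
  } else {
    u <- delta / d
    n <- max(1L, floor((d + gap) / (segment_length + gap)))
    span <- n * segment_length + (n - 1) * gap
    offset <- (d - span) / 2
    pos <- offset + segment_length / 2 + (seq_len(n) - 1) * (segment_length + gap)
    centres <- t(outer(pos, u)) + start_world
    segs <- tibble::tibble(
      centre_x = centres[1, ], centre_y = centres[2, ], centre_z = centres[3, ],
      dir_x = u[1], dir_y = u[2], dir_z = u[3],
      length = segment_length
    )
  }
  structure(list(segments = segs, gap = gap, segment_length = segment_length),
            class = "connector_layout")
}

#' Marker render scale under zoom
#'
#' Inverse of the reference zoom: multiplying a marker's render mesh by
#' this keeps its world size constant as the user zooms the volume, so end
#' points and labels neither swell to obscure the anatomy when zooming in
#' nor vanish when zooming out. `marker_render_scale(s) * s == 1` exactly.
#'
#' @param reference_scale Accumulated uniform zoom of the reference node
#'   (> 0).
#' @return Positive scalar.
#' @export
marker_render_scale <- function(reference_scale) {
  stopifnot(is.numeric(reference_scale), all(reference_scale > 0))
  1 / reference_scale
}

#' Format a distance label
#'
#' Rounds to the nearest multiple of the display precision (ties away from
#' zero, the common clinical convention) and renders with matching decimal
#' places and an "mm" suffix, e.g. `format_label(30.04, 0.1)` is
#' `"30.0 mm"` and `format_label(10.4, 1)` is `"10 mm"`.
#'
#' @param distance_mm Distance in mm.
#' @param display_precision_mm Rounding granularity in mm (e.g. 0.1 or 1).
#' @return Character label.
#' @export
format_label <- function(distance_mm, display_precision_mm = 0.1) {
  q <- quantize(distance_mm, display_precision_mm)
  dec <- precision_decimals(display_precision_mm)
  paste0(formatC(q, format = "f", digits = dec), " mm")
}

precision_decimals <- function(precision) {
  s <- format(precision, scientific = FALSE, trim = TRUE)
  if (!grepl("\\.", s)) return(0L)
  nchar(sub("0+$", "", sub("^[^.]*\\.", "", s)))
}

#' Quantize a value to a display precision
#'
#' Nearest multiple of `precision`, ties rounded away from zero: this is
#' the display quantization of clinical tools whose read-outs have a fixed
#' granularity (0.1 mm or 1 mm in the tools studied here).
#'
#' @param value Numeric vector, mm.
#' @param precision Positive granularity, mm (scalar or vectorised over
#'   `value`).
#' @return Quantized values.
#' @export
quantize <- function(value, precision) {
  stopifnot(is.numeric(precision), all(precision > 0))
  # epsilon absorbs binary representation error so decimal ties (e.g. 3.45
  # at precision 0.1) round away from zero as intended
  sign(value) * floor(abs(value) / precision + 0.5 + 1e-9) * precision
}

# ---- sidecar JSON -------------------------------------------------------

#' Read and write measurement sidecar files
#'
#' Measurements are stored as a JSON array of records with endpoint
#' coordinates in the volume's physical mm space (so files are portable
#' across viewers): `id`, `label`, `start_mm`, `end_mm`, `distance_mm`,
#' `display_precision_mm`, `frame_index`. Numbers are written at full
#' precision, so stored decimals round-trip exactly.
#'
#' `measurements_write()` accepts either a list of `measurement3d` objects
#' (anchored to `volume_node`) or a tibble as returned by
#' `measurements_read()`.
#'
#' @param x List of `measurement3d` objects, or a tibble with columns
#'   `id`, `label`, `start_mm` (list of length-3), `end_mm`, `distance_mm`,
#'   `display_precision_mm`, `frame_index`.
#' @param path JSON file path.
#' @param volume_node Volume node used to express endpoints in physical mm
#'   (required when `x` is a list of measurements).
#' @param frame_index Frame tag for 4-D acquisitions; default 0.
#' @return `measurements_read()` returns a tibble;
#'   `measurements_write()` returns `path`, invisibly.
#' @export
measurements_write <- function(x, path, volume_node = NULL, frame_index = 0L) {
  if (is.data.frame(x)) {
    recs <- purrr::pmap(x, function(id, label, start_mm, end_mm, distance_mm,
                                    display_precision_mm, frame_index, ...) {
      list(id = id, label = label, start_mm = as.numeric(start_mm),
           end_mm = as.numeric(end_mm), distance_mm = distance_mm,
           display_precision_mm = display_precision_mm,
           frame_index = frame_index)
    })
  } else {
    stopifnot(is.list(x), !is.null(volume_node))
    recs <- lapply(x, function(m) {
      stopifnot(is_measurement3d(m))
      d <- measured_distance(m)
      list(
        id = m$id,
        label = format_label(d, m$display_precision_mm),
        start_mm = as.numeric(world_to_volume(volume_node, to_world(m$start, c(0, 0, 0)))),
        end_mm = as.numeric(world_to_volume(volume_node, to_world(m$end, c(0, 0, 0)))),
        distance_mm = d,
        display_precision_mm = m$display_precision_mm,
        frame_index = frame_index
      )
    })
  }
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname measurements_write
#' @export
measurements_read <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  tibble::tibble(
    id = purrr::map_chr(recs, "id"),
    label = purrr::map_chr(recs, "label"),
    start_mm = purrr::map(recs, ~ as.numeric(unlist(.x$start_mm))),
    end_mm = purrr::map(recs, ~ as.numeric(unlist(.x$end_mm))),
    distance_mm = purrr::map_dbl(recs, "distance_mm"),
    display_precision_mm = purrr::map_dbl(recs, "display_precision_mm"),
    frame_index = purrr::map_int(recs, ~ as.integer(.x$frame_index))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
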