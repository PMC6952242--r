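#' Scene-graph nodes
#'
#' A `scene_node` is a mutable node in a parent-child transform hierarchy
#' (a forest): each node carries a local pose ([transform3d()]) relative to
#' its parent, and the world pose of a node is the fold of local poses from
#' its root down. Nodes are environments, so edits (re-parenting, pose
#' updates) have reference semantics, as in any scene graph.
#'
#' At most one node in a scene may be flagged `is_reference_scale`: the
#' node whose accumulated zoom is divided out of measured distances so that
#' they stay in anatomical millimetres (see [measured_distance()]).
#'
#' @param name Node name (free text, used in serialisation and messages).
#' @param local Local pose, a [transform3d()].
#' @param parent Optional parent `scene_node`; the new node is appended to
#'   its children.
#' @param is_reference_scale Flag this node as the reference-scale node.
#' @return A `scene_node` environment.
#' @examples
#' root <- scene_node("root")
#' child <- scene_node("child", transform3d(translation = c(1, 0, 0)), parent = root)
#' to_world(child, c(0, 0, 0))
#' @export
scene_node <- function(name, local = transform3d(), parent = NULL,
                       is_reference_scale = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, is_transform3d(local))
  node <- new.env(parent = emptyenv())
  node$name <- name
  node$local <- local
  node$parent <- NULL
  node$children <- list()
  node$is_reference_scale <- isTRUE(is_reference_scale)
  node$role <- "node"
  class(node) <- "scene_node"
  if (!is.null(parent)) add_child(parent, node)
  node
}

is_scene_node <- function(x) inherits(x, "scene_node")

#' @export
print.scene_node <- function(x, ...) {
  cat(sprintf("<scene_node '%s'> (%d children%s)\n", x$name, length(x$children),
              if (x$is_reference_scale) ", reference scale" else ""))
  invisible(x)
}

#' Attach a node to a parent
#'
#' The node must currently be a root (no parent); attaching a node that
#' would create a cycle (a node under itself or one of its descendants) is
#' a structural error, preserving the forest invariant.
#'
#' @param parent,node `scene_node`s.
#' @return `node`, invisibly.
#' @export
add_child <- function(parent, node) {
  stopifnot(is_scene_node(parent), is_scene_node(node))
  if (!is.null(node$parent)) {
    rlang::abort(sprintf("node '%s' already has a parent", node$name),
                 class = "caliper3d_structure_error")
  }
  if (is_same_or_descendant(parent, node)) {
    rlang::abort("attaching here would create a cycle",
                 class = "caliper3d_structure_error")
  }
  node$parent <- parent
  parent$children <- c(parent$children, list(node))
  invisible(node)
}

is_same_or_descendant <- function(candidate, ancestor) {
  # TRUE if candidate == ancestor or candidate lies in ancestor's subtree
  n <- candidate
  steps <- 0L
  while (!is.null(n)) {
    if (identical(n, ancestor)) return(TRUE)
    n <- n$parent
    steps <- steps + 1L
    if (steps > 1e6L) {
      rlang::abort("cycle detected in scene graph", class = "caliper3d_structure_error")
    }
  }
  FALSE
}

node_path <- function(node) {
  # root-first list of nodes from the root down to `node`, with cycle guard
  path <- list()
  n <- node
  while (!is.null(n)) {
    for (seen in path) {
      if (identical(seen, n)) {
        rlang::abort("cycle detected in scene graph", class = "caliper3d_structure_error")
      }
    }
    path <- c(list(n), path)
    n <- n$parent
  }
  path
}

node_root <- function(node) node_path(node)[[1L]]

#' World transform of a node
#'
#' Folds [compose_transforms()] over the local poses from the node's root
#' down to the node; a root's world transform is its local transform.
#'
#' @param node A `scene_node`.
#' @return A [transform3d()].
#' @export
world_transform <- function(node) {
  transform_from_matrix(world_matrix(node))
}

world_matrix <- function(node) {
  stopifnot(is_scene_node(node))
  M <- diag(4)
  for (n in node_path(node)) M <- M %*% transform_matrix(n$local)
  M
}

#' Local/world point conversion
#'
#' `to_world()` maps points in a node's local frame to world coordinates;
#' `to_local()` is its exact inverse.
#'
#' @param node A `scene_node`.
#' @param p A length-3 point or 3-row matrix of points.
#' @return Mapped points, same shape as `p`.
#' @export
to_world <- function(node, p) {
  apply_homogeneous(world_matrix(node), p)
}

#' @rdname to_world
#' @export
to_local <- function(node, p) {
  apply_homogeneous(solve(world_matrix(node)), p)
}

#' Re-parent a node, preserving its world pose
#'
#' Detaches `node` from its current parent (if any) and attaches it under
#' `new_parent`, recomputing the node's local pose so that its world
#' transform — and hence the world position of every point in its subtree —
#' is unchanged. This is the editing primitive: picking up a scene object
#' re-parents it under the controller, and releasing it re-parents it back.
#'
#' @param node Node to move.
#' @param new_parent Target parent; must not be `node` or one of its
#'   descendants.
#' @return `node`, invisibly.
#' @export
reparent_keep_world <- function(node, new_parent) {
  stopifnot(is_scene_node(node), is_scene_node(new_parent))
  if (is_same_or_descendant(new_parent, node)) {
    rlang::abort("cannot re-parent a node under itself or its descendant",
                 class = "caliper3d_structure_error")
  }
  W <- world_matrix(node)
  detach_node(node)
  new_local <- solve(world_matrix(new_parent)) %*% W
  node$local <- transform_from_matrix(new_local)
  node$parent <- new_parent
  new_parent$children <- c(new_parent$children, list(node))
  invisible(node)
}

detach_node <- function(node) {
  p <- node$parent
  if (is.null(p)) return(invisible(node))
  keep <- !vapply(p$children, identical, logical(1), y = node)
  p$children <- p$children[keep]
  node$parent <- NULL
  invisible(node)
}

#' Accumulated uniform scale along a node's root path
#'
#' Product of the (isotropic) scales from the root down to `node`. This is
#' the zoom factor of the reference-scale node that measured distances are
#' divided by. Every scale on the path must be isotropic within `tol`
#' relative spread (the correction is defined only for uniform zoom);
#' near-isotropic scales are collapsed to their geometric mean.
#'
#' @param node A `scene_node`.
#' @param tol Relative anisotropy tolerance, default `1e-6`.
#' @return Positive scalar zoom factor.
#' @export
accumulated_uniform_scale <- function(node, tol = 1e-6) {
  acc <- 1
  for (n in node_path(node)) {
    s <- n$local$scale
    m <- exp(mean(log(s)))
    if (max(abs(s - m)) > tol * m) {
      rlang::abort(
        sprintf("anisotropic reference scale on node '%s': (%s)",
                n$name, paste(format(s), collapse = ", ")),
        class = "caliper3d_anisotropic_scale_error"
      )
    }
    acc <- acc * m
  }
  acc
}

#' Find the reference-scale node of a scene
#'
#' Searches the tree containing `node` (from its root) for the unique node
#' flagged `is_reference_scale`.
#'
#' @param node Any node of the scene.
#' @return The reference `scene_node`, or `NULL` if none is flagged.
#' @export
find_reference_node <- function(node) {
  found <- NULL
  walk <- function(n) {
    if (n$is_reference_scale) {
      if (!is.null(found)) {
        rlang::abort("scene has more than one reference-scale node",
                     class = "caliper3d_configuration_error")
      }
      found <<- n
    }
    for (ch in n$children) walk(ch)
  }
  walk(node_root(node))
  found
}

#' Set a node's uniform scale (zoom)
#'
#' Convenience for user zoom on a node: replaces the node's local scale
#' with an isotropic scale `s`.
#'
#' @param node A `scene_node`.
#' @param s Positive scalar.
#' @return `node`, invisibly.
#' @export
set_uniform_scale <- function(node, s) {
  stopifnot(is.numeric(s), length(s) == 1L, s > 0)
  node$local <- transform3d(node$local$translation, node$local$rotation, rep(s, 3L))
  invisible(node)
}

#' Set a node's local pose
#'
#' @param node A `scene_node`.
#' @param local A [transform3d()].
#' @return `node`, invisibly.
#' @export
set_local_transform <- function(node, local) {
  stopifnot(is_transform3d(local))
  node$local <- local
  invisible(node)
}

# ---- scene (de)serialisation -------------------------------------------

node_to_list <- function(node) {
  out <- list(
    name = node$name,
    translation = node$local$translation,
    rotation = node$local$rotation,
    scale = node$local$scale,
    is_reference_scale = node$is_reference_scale,
    role = node$role
  )
  if (!is.null(node$mm_per_world_unit)) out$mm_per_world_unit <- node$mm_per_world_unit
  out$children <- lapply(node$children, node_to_list)
  out
}

node_from_list <- function(x, parent = NULL) {
  node <- scene_node(
    x$name,
    transform3d(unlist(x$translation), unlist(x$rotation), unlist(x$scale)),
    parent = parent,
    is_reference_scale = isTRUE(x$is_reference_scale)
  )
  if (!is.null(x$role)) node$role <- x$role
  if (!is.null(x$mm_per_world_unit)) node$mm_per_world_unit <- x$mm_per_world_unit
  for (ch in x$children) node_from_list(ch, parent = node)
  node
}

#' Read and write scenes as JSON
#'
#' Serialises a scene (the tree under a root node) to a JSON document and
#' back, at full numeric precision so that a write/read round trip
#' reproduces every pose exactly.
#'
#' @param root Root `scene_node` of the scene.
#' @param path File path.
#' @return `scene_read()` returns the root `scene_node`;
#'   `scene_write()` returns `path`, invisibly.
#' @export
scene_write <- function(root, path) {
  stopifnot(is_scene_node(root), is.null(root$parent))
  jsonlite::write_json(node_to_list(root), path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname scene_write
#' @export
scene_read <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  node_from_list(x)
}

#' Tabulate a scene
#'
#' Flattens a scene into a tibble with one row per node: name, role,
#' depth, local pose components and world position. Handy for inspection
#' and for tidyverse-style assertions on a whole hierarchy.
#'
#' @param root Root `scene_node`.
#' @return A tibble with columns `name`, `role`, `depth`, `parent`,
#'   `is_reference_scale`, `world_x`, `world_y`, `world_z`.
#' @export
scene_tibble <- function(root) {
  rows <- list()
  walk <- function(n, depth) {
    w <- to_world(n, c(0, 0, 0))
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      name = n$name, role = n$role, depth = depth,
      parent = if (is.null(n$parent)) NA_character_ else n$parent$name,
      is_reference_scale = n$is_reference_scale,
      world_x = w[1], world_y = w[2], world_z = w[3]
    )
    for (ch in n$children) walk(ch, depth + 1L)
  }
  walk(root, 0L)
  dplyr::bind_rows(rows)
}
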