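#' Volumetric images with physical geometry
#'
#' A `volume_image` is a 3-D intensity array plus the geometry that places
#' it in physical space: voxel `spacing` (mm/voxel), `origin` (mm, position
#' of voxel (0,0,0)'s centre) and a 3x3 orthonormal `direction` matrix
#' whose columns are the physical directions of the i, j, k axes. Physical
#' space is LPS millimetres (the DICOM convention); NIfTI's RAS affine is
#' converted on read and write.
#'
#' @param voxels 3-D numeric array of intensities.
#' @param spacing Length-3 positive spacing, mm per voxel.
#' @param origin Length-3 origin, mm.
#' @param direction 3x3 orthonormal direction-cosine matrix.
#' @return A `volume_image` object.
#' @export
volume_image <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         direction = diag(3)) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L)
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  direction <- matrix(as.numeric(direction), 3L, 3L)
  stopifnot(length(spacing) == 3L, length(origin) == 3L)
  if (any(spacing <= 0)) {
    rlang::abort("voxel spacing must be positive", class = "caliper3d_geometry_error")
  }
  if (max(abs(crossprod(direction) - diag(3))) > 1e-6) {
    rlang::abort("direction matrix must be orthonormal (within 1e-6)",
                 class = "caliper3d_geometry_error")
  }
  structure(
    list(voxels = voxels, spacing = spacing, origin = origin,
         direction = direction),
    class = "volume_image"
  )
}

is_volume_image <- function(x) inherits(x, "volume_image")

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("<volume_image> %s voxels, spacing (%s) mm, origin (%s) mm\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(format(x$spacing, digits = 4), collapse = ", "),
              paste(format(x$origin, digits = 4), collapse = ", ")))
  invisible(x)
}

#' Voxel index to physical coordinates and back
#'
#' Continuous 0-based voxel-centre indices: `physical = origin +
#' direction %*% (spacing * ijk)`. `physical_to_index()` is the exact
#' inverse. Out-of-grid indices are allowed (the maps are affine); use the
#' `in_grid` attribute of the result to detect them.
#'
#' @param image A [volume_image()].
#' @param ijk,p Length-3 point or 3-row matrix of points (continuous
#'   indices / physical mm).
#' @return Mapped points, same shape as the input, with attribute
#'   `in_grid` (logical, per point).
#' @export
index_to_physical <- function(image, ijk) {
  stopifnot(is_volume_image(image))
  vec <- !is.matrix(ijk)
  if (vec) ijk <- matrix(as.numeric(ijk), nrow = 3L)
  out <- image$direction %*% (image$spacing * ijk) + image$origin
  ok <- index_in_grid(image, ijk)
  if (vec) out <- as.numeric(out)
  attr(out, "in_grid") <- ok
  out
}

#' @rdname index_to_physical
#' @export
physical_to_index <- function(image, p) {
  stopifnot(is_volume_image(image))
  vec <- !is.matrix(p)
  if (vec) p <- matrix(as.numeric(p), nrow = 3L)
  ijk <- (t(image$direction) %*% (p - image$origin)) / image$spacing
  ok <- index_in_grid(image, ijk)
  if (vec) ijk <- as.numeric(ijk)
  attr(ijk, "in_grid") <- ok
  ijk
}

index_in_grid <- function(image, ijk) {
  d <- dim(image$voxels)
  ijk[1, ] >= 0 & ijk[1, ] <= d[1] - 1 &
    ijk[2, ] >= 0 & ijk[2, ] <= d[2] - 1 &
    ijk[3, ] >= 0 & ijk[3, ] <= d[3] - 1
}

#' Trilinear intensity sampling
#'
#' Samples the image at continuous 0-based voxel indices by trilinear
#' interpolation. Points outside the grid return `NA`.
#'
#' @param image A [volume_image()].
#' @param ijk 3-row matrix of continuous indices (or a length-3 vector).
#' @return Numeric vector of sampled intensities.
#' @export
sample_trilinear <- function(image, ijk) {
  if (!is.matrix(ijk)) ijk <- matrix(as.numeric(ijk), nrow = 3L)
  d <- dim(image$voxels)
  n <- ncol(ijk)
  out <- rep(NA_real_, n)
  ok <- index_in_grid(image, ijk)
  if (!any(ok)) return(out)
  q <- ijk[, ok, drop = FALSE]
  i0 <- pmin(floor(q[1, ]), d[1] - 2); i0 <- pmax(i0, 0)
  j0 <- pmin(floor(q[2, ]), d[2] - 2); j0 <- pmax(j0, 0)
  k0 <- pmin(floor(q[3, ]), d[3] - 2); k0 <- pmax(k0, 0)
  fx <- q[1, ] - i0; fy <- q[2, ] - j0; fz <- q[3, ] - k0
  v <- image$voxels
  at <- function(di, dj, dk) v[cbind(i0 + di + 1, j0 + dj + 1, k0 + dk + 1)]
  val <-
    at(0, 0, 0) * (1 - fx) * (1 - fy) * (1 - fz) +
    at(1, 0, 0) * fx       * (1 - fy) * (1 - fz) +
    at(0, 1, 0) * (1 - fx) * fy       * (1 - fz) +
    at(1, 1, 0) * fx       * fy       * (1 - fz) +
    at(0, 0, 1) * (1 - fx) * (1 - fy) * fz +
    at(1, 0, 1) * fx       * (1 - fy) * fz +
    at(0, 1, 1) * (1 - fx) * fy       * fz +
    at(1, 1, 1) * fx       * fy       * fz
  out[ok] <- val
  out
}

# ---- file I/O -----------------------------------------------------------

#' Read and write volumes (NIfTI / MetaImage)
#'
#' Format is inferred from the extension: `.nii` / `.nii.gz` (NIfTI-1, via
#' RNifti) or `.mha` / `.mhd` (MetaImage; `.mhd` writes a separate `.raw`
#' data file). Geometry metadata is preserved; a write/read round trip is
#' lossless for double, float and integer voxel data (NIfTI affines are
#' stored as 32-bit floats, so geometry round-trips to single precision
#' through NIfTI and exactly through MetaImage).
#'
#' @param path File path ending in `.nii`, `.nii.gz`, `.mha` or `.mhd`.
#' @param image A [volume_image()].
#' @param dtype Element type for MetaImage output: `"double"`, `"float"`,
#'   `"short"`, or `"uchar"`.
#' @return `read_volume()` returns a [volume_image()]; `write_volume()`
#'   returns `path`, invisibly.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("volume file not found: %s", path),
                 class = "caliper3d_format_error")
  }
  low <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", low)) {
    read_nifti_volume(path)
  } else if (grepl("\\.mha$|\\.mhd$", low)) {
    read_metaimage(path)
  } else {
    rlang::abort(sprintf("unknown volume format for '%s' (expected .nii, .nii.gz, .mha, .mhd)", path),
                 class = "caliper3d_format_error")
  }
}

#' @rdname read_volume
#' @export
write_volume <- function(image, path, dtype = "double") {
  stopifnot(is_volume_image(image))
  low <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", low)) {
    write_nifti_volume(image, path)
  } else if (grepl("\\.mha$|\\.mhd$", low)) {
    write_metaimage(image, path, dtype = dtype)
  } else {
    rlang::abort(sprintf("unknown volume format for '%s'", path),
                 class = "caliper3d_format_error")
  }
  invisible(path)
}

# NIfTI stores an index->RAS affine; internal physical space is LPS, so the
# first two affine rows change sign on the way in and out.
read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  aff_lps <- aff
  aff_lps[1:2, ] <- -aff_lps[1:2, ]
  sp <- RNifti::pixdim(img)[1:3]
  dir <- aff_lps[1:3, 1:3] %*% diag(1 / sp, 3L)
  vox <- as.array(img)
  d <- dim(vox)
  if (length(d) == 4L && d[4] == 1L) d <- d[1:3]
  vox <- array(as.numeric(vox), dim = d) # drop RNifti's attributes/class
  volume_image(vox, spacing = sp, origin = aff_lps[1:3, 4], direction = dir)
}

write_nifti_volume <- function(image, path) {
  img <- RNifti::asNifti(image$voxels)
  RNifti::pixdim(img) <- image$spacing
  aff <- diag(4)
  aff[1:3, 1:3] <- image$direction %*% diag(image$spacing, 3L)
  aff[1:3, 4] <- image$origin
  aff[1:2, ] <- -aff[1:2, ] # LPS -> RAS
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
}

meta_types <- c(double = "MET_DOUBLE", float = "MET_FLOAT",
                short = "MET_SHORT", uchar = "MET_UCHAR")
meta_sizes <- c(MET_DOUBLE = 8L, MET_FLOAT = 4L, MET_SHORT = 2L, MET_UCHAR = 1L)

# MetaImage: plain-text "Key = Value" header; TransformMatrix lists the
# direction cosines of the i, j, k axes in that order (column-by-column).
read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) {
      rlang::abort(sprintf("corrupt MetaImage header in '%s': no ElementDataFile", path),
                   class = "caliper3d_format_error")
    }
    kv <- regmatches(line, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*?)\\s*$", line))[[1]]
    if (length(kv) != 3L) {
      rlang::abort(sprintf("corrupt MetaImage header line in '%s': %s", path, line),
                   class = "caliper3d_format_error")
    }
    hdr[[kv[2]]] <- kv[3]
    if (kv[2] == "ElementDataFile") break
  }
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  if (length(dims) != 3L || anyNA(dims)) {
    rlang::abort(sprintf("unsupported MetaImage DimSize in '%s'", path),
                 class = "caliper3d_format_error")
  }
  etype <- hdr$ElementType
  if (!etype %in% names(meta_sizes)) {
    rlang::abort(sprintf("unsupported MetaImage ElementType '%s'", etype),
                 class = "caliper3d_format_error")
  }
  sp <- if (!is.null(hdr$ElementSpacing)) as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]]) else c(1, 1, 1)
  org <- if (!is.null(hdr$Offset)) as.numeric(strsplit(hdr$Offset, "\\s+")[[1]]) else c(0, 0, 0)
  dir <- if (!is.null(hdr$TransformMatrix)) {
    matrix(as.numeric(strsplit(hdr$TransformMatrix, "\\s+")[[1]]), 3L, 3L)
  } else diag(3)
  n <- prod(dims)
  what <- switch(etype, MET_DOUBLE = , MET_FLOAT = "double", "integer")
  size <- meta_sizes[[etype]]
  signed <- etype != "MET_UCHAR"
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    raw <- readBin(con, what, n = n, size = size, signed = signed, endian = "little")
  } else {
    data_path <- file.path(dirname(path), hdr$ElementDataFile)
    if (!file.exists(data_path)) {
      rlang::abort(sprintf("MetaImage data file not found: %s", data_path),
                   class = "caliper3d_format_error")
    }
    dcon <- file(data_path, "rb")
    on.exit(close(dcon), add = TRUE)
    raw <- readBin(dcon, what, n = n, size = size, signed = signed, endian = "little")
  }
  if (length(raw) != n) {
    rlang::abort(sprintf("MetaImage data in '%s' is truncated", path),
                 class = "caliper3d_format_error")
  }
  volume_image(array(as.numeric(raw), dim = dims), spacing = sp, origin = org,
               direction = dir)
}

write_metaimage <- function(image, path, dtype = "double") {
  if (!dtype %in% names(meta_types)) {
    rlang::abort(sprintf("unsupported MetaImage dtype '%s'", dtype),
                 class = "caliper3d_format_error")
  }
  etype <- meta_types[[dtype]]
  local_data <- grepl("\\.mha$", tolower(path))
  data_file <- if (local_data) "LOCAL" else paste0(sub("\\.mhd$", "", basename(path), ignore.case = TRUE), ".raw")
  num <- function(x) paste(formatC(x, format = "g", digits = 17), collapse = " ")
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    paste("TransformMatrix =", num(as.numeric(image$direction))),
    paste("Offset =", num(image$origin)),
    "CenterOfRotation = 0 0 0",
    paste("ElementSpacing =", num(image$spacing)),
    paste("DimSize =", paste(dim(image$voxels), collapse = " ")),
    paste("ElementType =", etype),
    paste("ElementDataFile =", data_file)
  )
  vox <- as.numeric(image$voxels)
  if (dtype %in% c("short", "uchar")) vox <- as.integer(round(vox))
  size <- meta_sizes[[etype]]
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con)
  if (local_data) {
    writeBin(vox, con, size = size, endian = "little")
  } else {
    dcon <- file(file.path(dirname(path), data_file), "wb")
    on.exit(close(dcon), add = TRUE)
    writeBin(vox, dcon, size = size, endian = "little")
  }
  invisible(path)
}

# ---- scene attachment ---------------------------------------------------

#' Attach a volume to a scene at metre scale
#'
#' Creates a volume node under `root` that carries the image and the
#' millimetre-to-world conversion: with the default
#' `mm_per_world_unit = 1000`, a physical point 30 mm from the volume
#' origin sits 0.03 world units from the node origin, matching a world
#' defined in metres. The node is flagged as the scene's reference-scale
#' node (its transform scale carries only user zoom, initially 1), so
#' measured distances can divide the zoom back out.
#'
#' @param root Scene root `scene_node`.
#' @param image A [volume_image()].
#' @param mm_per_world_unit Millimetres of anatomy per world unit at zoom
#'   1; default 1000 (world units are metres).
#' @param name Node name.
#' @return The volume `scene_node` (fields `image`, `mm_per_world_unit`).
#' @export
attach_volume <- function(root, image, mm_per_world_unit = 1000,
                          name = "volume") {
  stopifnot(is_scene_node(root), is_volume_image(image),
            is.numeric(mm_per_world_unit), mm_per_world_unit > 0)
  if (!is.null(find_reference_node(root))) {
    rlang::abort("scene already has a reference-scale node",
                 class = "caliper3d_configuration_error")
  }
  node <- scene_node(name, parent = root, is_reference_scale = TRUE)
  node$role <- "volume"
  node$image <- image
  node$mm_per_world_unit <- mm_per_world_unit
  node
}

is_volume_node <- function(x) is_scene_node(x) && identical(x$role, "volume")

#' Physical-mm to world conversion through a volume node
#'
#' Maps points in the volume's physical mm space to world coordinates (and
#' back) through the volume node's pose: the node's local frame is the
#' physical frame divided by `mm_per_world_unit`.
#'
#' @param volume_node A node created by [attach_volume()].
#' @param p Length-3 point or 3-row matrix (mm for `volume_to_world`,
#'   world units for `world_to_volume`).
#' @return Mapped points, same shape as `p`.
#' @export
volume_to_world <- function(volume_node, p) {
  stopifnot(is_volume_node(volume_node))
  to_world(volume_node, p / volume_node$mm_per_world_unit)
}

#' @rdname volume_to_world
#' @export
world_to_volume <- function(volume_node, p) {
  stopifnot(is_volume_node(volume_node))
  to_local(volume_node, p) * volume_node$mm_per_world_unit
}
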