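#' Construct an image volume
#'
#' An `image_volume` is the basic scalar grid used throughout the package:
#' a 2D or 3D array of intensities plus the physical geometry needed to map
#' voxel indices to millimetre coordinates. Axis order is `(x, y)` for 2D and
#' `(x, y, z)` for 3D; indexing is voxel-centre based, so the physical
#' coordinate of (1-based) voxel index `i` along an axis is
#' `origin + (i - 1) * spacing`.
#'
#' @param data numeric array with 2 or 3 dimensions; intensities in arbitrary
#'   units.
#' @param spacing positive numeric vector, physical voxel size per axis (mm).
#'   A scalar is recycled.
#' @param origin numeric vector, physical coordinate of voxel index 1 (mm).
#'   Defaults to the zero vector.
#' @return An object of class `image_volume` with fields `data`, `spacing`,
#'   `origin`.
#' @examples
#' v <- image_volume(array(0, c(8, 8, 4)), spacing = c(1, 1, 3))
#' dim(v$data)
#' @export
image_volume <- function(data, spacing = 1, origin = 0) {
  if (is.null(dim(data))) stop("'data' must be a 2D or 3D array", call. = FALSE)
  nd <- length(dim(data))
  if (!nd %in% c(2L, 3L)) stop("'data' must have 2 or 3 axes, got ", nd, call. = FALSE)
  if (any(dim(data) < 1L)) stop("all axis lengths must be >= 1", call. = FALSE)
  spacing <- rep_len(as.numeric(spacing), nd)
  origin <- rep_len(as.numeric(origin), nd)
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("'spacing' must be strictly positive and finite on every axis", call. = FALSE)
  }
  if (any(!is.finite(origin))) stop("'origin' must be finite", call. = FALSE)
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing (", paste(format(x$spacing), collapse = ", "),
      ") mm, origin (", paste(format(x$origin), collapse = ", "), ") mm\n",
      sep = "")
  invisible(x)
}

#' Construct a label mask
#'
#' Integer-labelled grid aligned with a companion [image_volume()]. Label 0 is
#' background by convention; positive labels identify structures (vertebral
#' bodies, disc, vessel in the phantom).
#'
#' @param labels integer array (2D or 3D), values >= 0.
#' @param spacing,origin geometry as in [image_volume()].
#' @return An object of class `label_mask` with fields `labels`, `spacing`,
#'   `origin`.
#' @export
label_mask <- function(labels, spacing = 1, origin = 0) {
  if (is.null(dim(labels))) stop("'labels' must be a 2D or 3D array", call. = FALSE)
  nd <- length(dim(labels))
  if (!nd %in% c(2L, 3L)) stop("'labels' must have 2 or 3 axes", call. = FALSE)
  if (any(labels < 0) || any(labels != round(labels))) {
    stop("labels must be nonnegative integers", call. = FALSE)
  }
  spacing <- rep_len(as.numeric(spacing), nd)
  origin <- rep_len(as.numeric(origin), nd)
  if (any(spacing <= 0)) stop("'spacing' must be strictly positive", call. = FALSE)
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, spacing = spacing, origin = origin),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  labs <- sort(unique(as.vector(x$labels)))
  cat("<label_mask> ", paste(dim(x$labels), collapse = " x "),
      " voxels, labels {", paste(labs, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' Construct a landmark set
#'
#' Physical-coordinate point sets used for target-registration-error
#' evaluation. When `paired_points` is given, row i of `points` corresponds to
#' row i of `paired_points` (a known anatomical correspondence).
#'
#' @param points numeric matrix, one point per row, 2 or 3 columns (mm).
#' @param paired_points optional numeric matrix of identical shape (mm).
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(points, paired_points = NULL) {
  points <- as.matrix(points)
  if (!ncol(points) %in% c(2L, 3L)) stop("points must have 2 or 3 columns", call. = FALSE)
  if (any(!is.finite(points))) stop("all coordinates must be finite", call. = FALSE)
  if (!is.null(paired_points)) {
    paired_points <- as.matrix(paired_points)
    if (!all(dim(paired_points) == dim(points))) {
      stop("'paired_points' must match 'points' in shape", call. = FALSE)
    }
    if (any(!is.finite(paired_points))) stop("all coordinates must be finite", call. = FALSE)
  }
  structure(list(points = points, paired_points = paired_points),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("<landmark_set> ", nrow(x$points), " points (", ncol(x$points), "D)",
      if (!is.null(x$paired_points)) ", paired" else "", "\n", sep = "")
  invisible(x)
}

# Extract (spacing-scaled) axis-aligned voxel dimensions from an RNifti xform.
# Returns NULL when the rotation part is not a (signed) axis-aligned scaling.
.axis_aligned_scales <- function(xf, nd) {
  rot <- xf[seq_len(nd), seq_len(nd), drop = FALSE]
  scales <- sqrt(colSums(rot^2))
  ok <- abs(abs(rot) - diag(scales, nd)) < 1e-4 * pmax(scales, 1)
  if (!all(ok)) return(NULL)
  list(scales = scales, sign = sign(diag(rot)), shift = xf[seq_len(nd), nd + 1L])
}

#' Read a NIfTI volume
#'
#' Reads a `.nii` / `.nii.gz` file into an [image_volume()]. Spacing and origin
#' are taken from the file header. Any intensity slope/intercept stored in the
#' header is applied by the NIfTI backend exactly once; files whose orientation
#' matrix is not an axis-aligned scaling are rejected rather than silently
#' reoriented.
#'
#' @param path path to a NIfTI file.
#' @param as_mask logical; if `TRUE` return a [label_mask()] (values rounded to
#'   integer) instead of an [image_volume()].
#' @return An [image_volume()] (or [label_mask()]).
#' @export
read_volume <- function(path, as_mask = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("not a readable NIfTI file: ", path,
                                           " (", conditionMessage(e), ")", call. = FALSE))
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))   # drop RNifti header attributes
  nd <- length(dim(arr))
  if (!nd %in% c(2L, 3L)) stop("expected a 2D or 3D image, got ", nd, " axes", call. = FALSE)
  pix <- RNifti::pixdim(img)[seq_len(nd)]
  xf <- try(RNifti::xform(img), silent = TRUE)
  origin <- rep(0, nd)
  if (!inherits(xf, "try-error") && is.matrix(xf)) {
    aa <- .axis_aligned_scales(xf, nd)
    if (is.null(aa)) {
      stop("NIfTI orientation is not an axis-aligned scaling; ",
           "refusing to guess a reorientation", call. = FALSE)
    }
    origin <- aa$shift * aa$sign  # fold sign flips into the origin sign convention
  }
  if (as_mask) {
    label_mask(array(as.integer(round(arr)), dim(arr)), spacing = pix, origin = origin)
  } else {
    image_volume(arr, spacing = pix, origin = origin)
  }
}

#' Write a NIfTI volume
#'
#' Writes an [image_volume()] or [label_mask()] to `.nii` / `.nii.gz`.
#' Intensities are stored as 64-bit floats for volumes (bit-exact round-trip)
#' and as 32-bit integers for masks.
#'
#' @param volume an [image_volume()] or [label_mask()].
#' @param path destination path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  is_mask <- inherits(volume, "label_mask")
  if (!is_mask && !inherits(volume, "image_volume")) {
    stop("'volume' must be an image_volume or label_mask", call. = FALSE)
  }
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir, call. = FALSE)
  if (file.access(dir, 2L) != 0L) stop("directory not writable: ", dir, call. = FALSE)
  arr <- if (is_mask) volume$labels else volume$data
  nd <- length(dim(arr))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- volume$spacing
  # RNifti xforms are 4x4; embed 2D as a unit z axis
  full <- diag(4)
  full[seq_len(nd), seq_len(nd)] <- diag(volume$spacing, nd)
  full[seq_len(nd), 4L] <- volume$origin
  RNifti::qform(img) <- structure(full, code = 2L)
  RNifti::sform(img) <- structure(full, code = 2L)
  datatype <- if (is_mask) "int32" else "float64"
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a landmark table
#'
#' Parses a whitespace- or comma-delimited text file with one point per row.
#' Lines starting with `#` are comments. 2 or 3 numeric columns give unpaired
#' 2D/3D points; 4 or 6 columns give paired points (`x y [z] x' y' [z']`).
#'
#' @param path path to the text file.
#' @return A [landmark_set()].
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("no landmark rows in ", path, call. = FALSE)
  rows <- lapply(lines, function(l) {
    toks <- strsplit(l, "[,[:space:]]+")[[1]]
    toks <- toks[nzchar(toks)]
    vals <- suppressWarnings(as.numeric(toks))
    if (any(is.na(vals))) stop("non-numeric field in landmark row: '", l, "'", call. = FALSE)
    vals
  })
  ncols <- unique(vapply(rows, length, 1L))
  if (length(ncols) != 1L) stop("ragged rows in landmark file (columns: ",
                                paste(ncols, collapse = ", "), ")", call. = FALSE)
  if (!ncols %in% c(2L, 3L, 4L, 6L)) {
    stop("landmark rows must have 2, 3, 4 or 6 columns, got ", ncols, call. = FALSE)
  }
  m <- do.call(rbind, rows)
  if (ncols %in% c(2L, 3L)) {
    landmark_set(m)
  } else {
    d <- ncols %/% 2L
    landmark_set(m[, seq_len(d), drop = FALSE], m[, d + seq_len(d), drop = FALSE])
  }
}

#' Write a landmark table
#'
#' Inverse of [read_landmarks()]: whitespace-delimited, one point per row,
#' paired coordinates appended as extra columns when present.
#'
#' @param landmarks a [landmark_set()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  stopifnot(inherits(landmarks, "landmark_set"))
  m <- landmarks$points
  if (!is.null(landmarks$paired_points)) m <- cbind(m, landmarks$paired_points)
  utils::write.table(m, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# shared: physical coordinates of all voxel centres, as an n x nd matrix
# (column-major voxel order, matching as.vector on the data array)
.voxel_centres <- function(shape, spacing, origin) {
  nd <- length(shape)
  idx <- arrayInd(seq_len(prod(shape)), shape)
  sweep(sweep(idx - 1, 2L, spacing, "*"), 2L, origin, "+")
}
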