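#' Cubic B-spline basis functions
#'
#' The four cubic basis polynomials that interpolate control-point
#' displacements in a free-form deformation:
#' \deqn{R_0(n) = (1-n)^3/6,\quad R_1(n) = (3n^3 - 6n^2 + 4)/6,}
#' \deqn{R_2(n) = (-3n^3 + 3n^2 + 3n + 1)/6,\quad R_3(n) = n^3/6,}
#' for a fractional cell offset \eqn{n \in [0, 1)}. They form a partition of
#' unity: \eqn{\sum_l R_l(n) = 1} for every \eqn{n}.
#'
#' @param l basis index, integer in 0..3.
#' @param n fractional offset(s) in `[0, 1)` (the closed value 1 is accepted at
#'   the upper domain boundary).
#' @return Numeric vector of weights, same length as `n`.
#' @examples
#' bspline_basis(0, 0)  # 1/6
#' sum(sapply(0:3, bspline_basis, n = 0.3))  # 1
#' @export
bspline_basis <- function(l, n) {
  if (length(l) != 1L || !l %in% 0:3) stop("'l' must be a single integer in 0..3", call. = FALSE)
  if (any(n < 0 | n > 1)) stop("'n' must lie in [0, 1]", call. = FALSE)
  switch(as.character(l),
         "0" = (1 - n)^3 / 6,
         "1" = (3 * n^3 - 6 * n^2 + 4) / 6,
         "2" = (-3 * n^3 + 3 * n^2 + 3 * n + 1) / 6,
         "3" = n^3 / 6)
}

# first and second derivatives of the basis polynomials w.r.t. n
.bspline_basis_d1 <- function(l, n) {
  switch(as.character(l),
         "0" = -(1 - n)^2 / 2,
         "1" = (3 * n^2 - 4 * n) / 2,
         "2" = (-3 * n^2 + 2 * n + 1) / 2,
         "3" = n^2 / 2)
}

.bspline_basis_d2 <- function(l, n) {
  switch(as.character(l),
         "0" = 1 - n,
         "1" = 3 * n - 2,
         "2" = 1 - 3 * n,
         "3" = n)
}

#' Construct a cubic B-spline free-form deformation transform
#'
#' The transform is parameterized by a regular lattice of control-point
#' displacement vectors \eqn{\phi} with physical spacing `grid_spacing`. The
#' displacement at a physical point is the tensor-product sum of the 4 (per
#' axis) surrounding control points weighted by [bspline_basis()]; the mapped
#' point is `point + displacement`. All-zero \eqn{\phi} is the identity.
#'
#' The lattice is sized to cover the given physical domain with one ring of
#' control points before the domain and two after it on every axis, so the
#' cubic support always exists.
#'
#' @param domain_min,domain_max physical corners of the covered image domain
#'   (mm), numeric vectors of length 2 or 3.
#' @param grid_spacing control-point spacing per axis (mm); scalar recycled.
#' @param phi optional displacement lattice, array of dim `c(ncp, ndim)` where
#'   `ncp` is the control-grid shape; defaults to all zeros (identity).
#' @return An object of class `bspline_transform` with fields `phi`
#'   (array, last dimension indexes the displacement component),
#'   `grid_spacing`, `grid_origin`, `domain_min`, `domain_max`.
#' @examples
#' tr <- bspline_transform(c(0, 0), c(63, 63), grid_spacing = 16)
#' dim(tr$phi)
#' @export
bspline_transform <- function(domain_min, domain_max, grid_spacing, phi = NULL) {
  nd <- length(domain_min)
  if (!nd %in% c(2L, 3L) || length(domain_max) != nd) {
    stop("domain corners must both have 2 or 3 components", call. = FALSE)
  }
  grid_spacing <- rep_len(as.numeric(grid_spacing), nd)
  if (any(grid_spacing <= 0)) stop("'grid_spacing' must be strictly positive", call. = FALSE)
  if (any(domain_max <= domain_min)) stop("domain_max must exceed domain_min", call. = FALSE)
  ncells <- pmax(1L, as.integer(ceiling((domain_max - domain_min) / grid_spacing - 1e-9)))
  ncp <- ncells + 4L                      # indices 0..ncells+3, one ring before, two after
  grid_origin <- domain_min - grid_spacing
  if (is.null(phi)) {
    phi <- array(0, dim = c(ncp, nd))
  } else {
    phi <- as.array(phi)
    if (!all(dim(phi) == c(ncp, nd))) {
      stop("phi must have dim (", paste(c(ncp, nd), collapse = ", "), ")", call. = FALSE)
    }
  }
  structure(list(phi = phi, grid_spacing = grid_spacing, grid_origin = grid_origin,
                 domain_min = as.numeric(domain_min), domain_max = as.numeric(domain_max)),
            class = "bspline_transform")
}

#' @export
print.bspline_transform <- function(x, ...) {
  nd <- length(x$grid_spacing)
  cat("<bspline_transform> ", nd, "D, control grid ",
      paste(utils::head(dim(x$phi), -1L), collapse = " x "),
      ", spacing (", paste(format(x$grid_spacing), collapse = ", "), ") mm, ",
      "max |phi| = ", format(max(abs(x$phi))), " mm\n", sep = "")
  invisible(x)
}

#' Transform covering an image volume's grid
#'
#' Convenience constructor: a [bspline_transform()] whose domain is the
#' bounding box of the volume's voxel centres.
#'
#' @param volume an [image_volume()] or [label_mask()].
#' @param grid_spacing control-point spacing (mm).
#' @param phi optional lattice, as in [bspline_transform()].
#' @return A `bspline_transform`.
#' @export
bspline_transform_for <- function(volume, grid_spacing, phi = NULL) {
  arr <- if (inherits(volume, "label_mask")) volume$labels else volume$data
  shape <- dim(arr)
  dmin <- volume$origin
  dmax <- volume$origin + (shape - 1) * volume$spacing
  bspline_transform(dmin, dmax, grid_spacing, phi)
}

#' Map physical points to local lattice coordinates
#'
#' Decomposes each point into an integer control-cell index and a fractional
#' offset per axis, such that
#' `grid_origin + (cell + frac) * grid_spacing == point`. The cell index is the
#' (0-based) index of the first of the four supporting control points along
#' each axis. `frac` lies in `[0, 1)` except exactly at the upper domain
#' boundary, where the last interior cell is used with `frac = 1` (the cubic
#' basis is continuous there, so the decomposition remains exact).
#'
#' @param transform a [bspline_transform()].
#' @param points numeric matrix of physical coordinates, one point per row
#'   (a single point may be given as a vector).
#' @return List with integer matrix `cell` and numeric matrix `frac`.
#' @export
to_local <- function(transform, points) {
  points <- rbind(points)
  nd <- length(transform$grid_spacing)
  if (ncol(points) != nd) stop("points must have ", nd, " columns", call. = FALSE)
  eps <- 1e-9 * max(transform$grid_spacing)
  inside <- sweep(points, 2L, transform$domain_min - eps, ">=") &
            sweep(points, 2L, transform$domain_max + eps, "<=")
  if (!all(inside)) stop("point outside transform domain", call. = FALSE)
  s <- sweep(sweep(points, 2L, transform$grid_origin, "-"), 2L,
             transform$grid_spacing, "/")
  cell <- floor(s)
  ncp <- utils::head(dim(transform$phi), -1L)
  for (k in seq_len(nd)) {                # clamp so cell+3 stays on the lattice
    top <- ncp[k] - 4L
    cell[, k] <- pmin(pmax(cell[, k], 0), top)
  }
  frac <- s - cell
  list(cell = matrix(as.integer(cell), nrow(points), nd),
       frac = frac)
}

# tensor-product weights and lattice indices for a point set.
# deriv: per-axis derivative order (0, 1 or 2); derivatives w.r.t. physical mm.
# Returns list(W, idx): n x 4^nd weight matrix and matching matrix of linear
# indices into the flattened (per-component) control lattice. Reused by the
# registration optimizer to cache the fixed geometry across cost evaluations.
.ffd_weights <- function(transform, points, deriv = NULL) {
  nd <- length(transform$grid_spacing)
  loc <- to_local(transform, points)
  n <- nrow(loc$cell)
  if (is.null(deriv)) deriv <- rep(0L, nd)
  ncp <- utils::head(dim(transform$phi), -1L)
  wfun <- list(bspline_basis, .bspline_basis_d1, .bspline_basis_d2)
  wt <- vector("list", nd)
  for (k in seq_len(nd)) {
    f <- wfun[[deriv[k] + 1L]]
    wt[[k]] <- lapply(0:3, function(l) f(l, loc$frac[, k]) / transform$grid_spacing[k]^deriv[k])
  }
  offsets <- as.matrix(expand.grid(rep(list(0:3), nd)))
  stride <- cumprod(c(1L, ncp[-nd]))
  base_idx <- 1 + as.vector((loc$cell %*% stride))
  K <- nrow(offsets)
  W <- matrix(0, n, K)
  idx <- matrix(0L, n, K)
  for (r in seq_len(K)) {
    off <- offsets[r, ]
    w <- wt[[1L]][[off[1L] + 1L]]
    for (k in seq_len(nd)[-1L]) w <- w * wt[[k]][[off[k] + 1L]]
    W[, r] <- w
    idx[, r] <- base_idx + sum(off * stride)
  }
  list(W = W, idx = idx)
}

# displacement (or derivative) field from cached weights and a lattice
.ffd_apply <- function(wi, phi_flat) {
  nd <- ncol(phi_flat)
  n <- nrow(wi$W)
  out <- matrix(0, n, nd)
  iv <- as.vector(wi$idx)
  for (c in seq_len(nd)) {
    out[, c] <- rowSums(wi$W * matrix(phi_flat[iv, c], n))
  }
  out
}

# tensor-product evaluation shared by transform_point / second_derivatives
.ffd_eval <- function(transform, points, deriv = NULL) {
  nd <- length(transform$grid_spacing)
  wi <- .ffd_weights(transform, points, deriv)
  .ffd_apply(wi, matrix(transform$phi, ncol = nd))
}

#' Apply a B-spline transform to physical points
#'
#' Returns `point + displacement(point)`, where the displacement is the
#' tensor-product B-spline sum over the surrounding 4x4 (2D) or 4x4x4 (3D)
#' control points.
#'
#' @param transform a [bspline_transform()].
#' @param points matrix of physical coordinates (one per row) or a single
#'   point as a vector.
#' @return Matrix of mapped physical coordinates, same shape as `points`.
#' @export
transform_point <- function(transform, points) {
  vec_in <- is.null(dim(points))
  points <- rbind(points)
  out <- points + .ffd_eval(transform, points)
  if (vec_in && nrow(out) == 1L) out <- drop(out)
  out
}

#' Displacement field of a transform at given points
#'
#' @inheritParams transform_point
#' @return Matrix of displacement vectors (mm), one row per point.
#' @export
displacement <- function(transform, points) {
  .ffd_eval(transform, rbind(points))
}

#' Analytic second spatial derivatives of the displacement field
#'
#' Evaluates, for each displacement component, the unique second partial
#' derivatives of the B-spline displacement field: `(xx, yy, xy)` in 2D and
#' `(xx, yy, zz, xy, xz, yz)` in 3D. These feed the bending-energy penalty.
#' Units are mm^-1 (displacement in mm per mm^2).
#'
#' @param transform a [bspline_transform()].
#' @param points matrix of physical points, one per row.
#' @return A 3D array `n_points x n_terms x n_components`, with the terms in
#'   the order listed above and dimnames on the term axis.
#' @export
second_derivatives <- function(transform, points) {
  points <- rbind(points)
  nd <- length(transform$grid_spacing)
  pairs <- if (nd == 2L) list(c(1, 1), c(2, 2), c(1, 2))
           else list(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(1, 3), c(2, 3))
  nm <- if (nd == 2L) c("xx", "yy", "xy") else c("xx", "yy", "zz", "xy", "xz", "yz")
  out <- array(0, dim = c(nrow(points), length(pairs), nd),
               dimnames = list(NULL, nm, NULL))
  for (i in seq_along(pairs)) {
    dv <- rep(0L, nd)
    p <- pairs[[i]]
    dv[p[1]] <- dv[p[1]] + 1L
    dv[p[2]] <- dv[p[2]] + 1L
    out[, i, ] <- .ffd_eval(transform, points, deriv = dv)
  }
  out
}

# linear / nearest interpolation of an array at continuous 0-based voxel
# coordinates (n x nd matrix); outside samples -> NA
.interp_array <- function(arr, coords, method = c("linear", "nearest")) {
  method <- match.arg(method)
  shape <- dim(arr)
  nd <- length(shape)
  n <- nrow(coords)
  inside <- rep(TRUE, n)
  for (k in seq_len(nd)) inside <- inside & coords[, k] >= 0 & coords[, k] <= shape[k] - 1
  vals <- rep(NA_real_, n)
  if (!any(inside)) return(vals)
  co <- coords[inside, , drop = FALSE]
  if (method == "nearest") {
    idx0 <- round(co)
    stride <- cumprod(c(1, shape[-nd]))
    lin <- 1 + as.vector(idx0 %*% stride)
    vals[inside] <- arr[lin]
    return(vals)
  }
  i0 <- pmin(floor(co), matrix(shape - 2, nrow(co), nd, byrow = TRUE))
  i0 <- pmax(i0, 0)
  fr <- co - i0
  stride <- cumprod(c(1, shape[-nd]))
  base <- 1 + as.vector(i0 %*% stride)
  acc <- numeric(nrow(co))
  corners <- as.matrix(expand.grid(rep(list(0:1), nd)))
  for (r in seq_len(nrow(corners))) {
    cr <- corners[r, ]
    w <- rep(1, nrow(co))
    for (k in seq_len(nd)) w <- w * (if (cr[k] == 1) fr[, k] else 1 - fr[, k])
    acc <- acc + w * arr[base + sum(cr * stride)]
  }
  vals[inside] <- acc
  vals
}

# backward-warp: sample `arr` (on in_spacing/in_origin geometry) at the
# transform-mapped centres of the output grid; returns list(values, valid)
.warp_core <- function(transform, arr, in_spacing, in_origin, method,
                       out_shape = dim(arr), out_spacing = in_spacing,
                       out_origin = in_origin) {
  pts <- .voxel_centres(out_shape, out_spacing, out_origin)
  mapped <- transform_point(transform, pts)
  vox <- sweep(sweep(rbind(mapped), 2L, in_origin, "-"), 2L, in_spacing, "/")
  vals <- .interp_array(arr, vox, method)
  list(values = vals, valid = !is.na(vals))
}

#' Warp an image through a B-spline transform
#'
#' Backward warping: the output voxel at physical position `p` holds the input
#' image sampled at `transform(p)`. Samples falling outside the input grid are
#' filled with 0 (the background convention).
#'
#' @param transform a [bspline_transform()] whose domain covers the volume.
#' @param volume an [image_volume()] or [label_mask()] (masks are warped with
#'   nearest-neighbour interpolation regardless of `interpolation`).
#' @param interpolation `"linear"` (default) or `"nearest"`.
#' @return A warped object of the same class as `volume`.
#' @export
warp_image <- function(transform, volume, interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  is_mask <- inherits(volume, "label_mask")
  arr <- if (is_mask) volume$labels else volume$data
  if (is_mask) interpolation <- "nearest"
  w <- .warp_core(transform, arr, volume$spacing, volume$origin, interpolation)
  vals <- w$values
  vals[!w$valid] <- 0
  out <- array(vals, dim(arr))
  if (is_mask) label_mask(out, volume$spacing, volume$origin)
  else image_volume(out, volume$spacing, volume$origin)
}

#' Serialize a B-spline transform to JSON
#'
#' Writes grid origin, spacing, domain, lattice shape and the flattened
#' displacement lattice at full floating-point precision, so that
#' [read_transform()] round-trips exactly.
#'
#' @param transform a [bspline_transform()].
#' @param path destination path (`.json`).
#' @return `path`, invisibly.
#' @export
write_transform <- function(transform, path) {
  stopifnot(inherits(transform, "bspline_transform"))
  obj <- list(format = "spinereg-bspline-transform", version = 1L,
              grid_origin = transform$grid_origin,
              grid_spacing = transform$grid_spacing,
              domain_min = transform$domain_min,
              domain_max = transform$domain_max,
              phi_shape = dim(transform$phi),
              phi = as.vector(transform$phi))
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = FALSE)
  invisible(path)
}

#' Read a serialized B-spline transform
#'
#' @param path path written by [write_transform()].
#' @return A [bspline_transform()].
#' @export
read_transform <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "spinereg-bspline-transform") {
    stop("not a spinereg transform file: ", path, call. = FALSE)
  }
  tr <- bspline_transform(obj$domain_min, obj$domain_max, obj$grid_spacing,
                          phi = array(obj$phi, dim = obj$phi_shape))
  stopifnot(all(abs(tr$grid_origin - obj$grid_origin) < 1e-9))
  tr
}
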