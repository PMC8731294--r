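#' Registration cost configuration
#'
#' Weights and sampling options for the composite registration objective
#' `alpha1 * F + alpha2 * V`, where `F = -MI(A, warp(B))` is the (negated)
#' mutual-information similarity and `V` is the bending-energy penalty. The
#' single-weight form `F + lambda * V` is sugar for `alpha1 = 1,
#' alpha2 = lambda`.
#'
#' @param alpha1 weight on the similarity term, > 0 (default 1).
#' @param alpha2 weight on the bending-energy penalty, >= 0 (default 0.01).
#' @param lambda if given, overrides the pair as `alpha1 = 1, alpha2 = lambda`.
#' @param bins MI histogram bins (default 32).
#' @param sample_stride voxel subsampling stride (>= 1) used for both the MI
#'   histogram and the bending-energy point set; 1 uses every voxel.
#' @return An object of class `cost_config`.
#' @export
cost_config <- function(alpha1 = 1, alpha2 = 0.01, lambda = NULL,
                        bins = 32L, sample_stride = 1L) {
  if (!is.null(lambda)) { alpha1 <- 1; alpha2 <- lambda }
  if (alpha1 <= 0) stop("'alpha1' must be > 0", call. = FALSE)
  if (alpha2 < 0) stop("'alpha2' must be >= 0", call. = FALSE)
  if (sample_stride < 1L) stop("'sample_stride' must be >= 1", call. = FALSE)
  structure(list(alpha1 = alpha1, alpha2 = alpha2, bins = as.integer(bins),
                 sample_stride = as.integer(sample_stride)),
            class = "cost_config")
}

# indices of every stride-th voxel centre (column-major linear indices)
.stride_index <- function(shape, stride) {
  if (stride <= 1L) return(seq_len(prod(shape)))
  axes <- lapply(shape, function(s) seq(1L, s, by = stride))
  idx <- as.matrix(expand.grid(axes))
  stridev <- cumprod(c(1L, shape[-length(shape)]))
  as.vector(1 + (idx - 1) %*% stridev)
}

#' Bending (distortion) energy of a transform
#'
#' The mean, over sampled voxel centres of the domain, of the summed squared
#' second spatial derivatives of the displacement field:
#' \deqn{\Phi = G_{xx}^2 + G_{yy}^2 + G_{zz}^2 + 2G_{xy}^2 + 2G_{xz}^2 +
#'   2G_{yz}^2,}
#' summed over displacement components and averaged over the M sampled points
#' (2D drops the z terms). Zero for the identity and for any pure translation;
#' strictly positive for any deformation with spatial curvature.
#'
#' @param transform a [bspline_transform()] covering the domain.
#' @param domain an [image_volume()] (or [label_mask()]) defining the sampled
#'   voxel grid.
#' @param stride sampling stride (>= 1); every stride-th voxel centre is used.
#' @return Bending energy (mm^-2 scale; nonnegative scalar).
#' @export
bending_energy <- function(transform, domain, stride = 1L) {
  if (stride < 1L) stop("'stride' must be >= 1", call. = FALSE)
  arr <- if (inherits(domain, "label_mask")) domain$labels else domain$data
  shape <- dim(arr)
  pts <- .voxel_centres(shape, domain$spacing, domain$origin)
  pts <- pts[.stride_index(shape, as.integer(stride)), , drop = FALSE]
  d2 <- second_derivatives(transform, pts)     # n x terms x components
  nd <- length(shape)
  w <- if (nd == 2L) c(1, 1, 2) else c(1, 1, 1, 2, 2, 2)  # cross terms doubled
  phi_per_point <- apply(d2^2, 1L, function(m) sum(m * w))
  mean(phi_per_point)
}

#' Composite registration cost
#'
#' Evaluates `alpha1 * (-MI(A, warp(B))) + alpha2 * V(transform)`, lower is
#' better. The floating image `B` is backward-warped into `A`'s grid; voxels
#' whose warped sample falls outside `B` are excluded from the MI histogram
#' (overlap-region convention).
#'
#' @param transform a [bspline_transform()] covering `A`'s domain.
#' @param A reference [image_volume()].
#' @param B floating [image_volume()].
#' @param config a [cost_config()].
#' @return Total cost (scalar) with attribute `terms`, a named vector holding
#'   `mi`, `bending`, `similarity_term`, `penalty_term`.
#' @export
total_cost <- function(transform, A, B, config = cost_config()) {
  stopifnot(inherits(A, "image_volume"), inherits(B, "image_volume"))
  w <- .warp_core(transform, B$data, B$spacing, B$origin, "linear",
                  out_shape = dim(A$data), out_spacing = A$spacing,
                  out_origin = A$origin)
  sel <- .stride_index(dim(A$data), config$sample_stride)
  a <- as.vector(A$data)[sel]
  bvals <- w$values[sel]
  valid <- w$valid[sel]
  if (!any(valid)) stop("warped image has empty overlap with the reference", call. = FALSE)
  mi <- as.numeric(mutual_information(a[valid], bvals[valid], bins = config$bins))
  V <- if (config$alpha2 > 0) bending_energy(transform, A, stride = config$sample_stride) else 0
  total <- config$alpha1 * (-mi) + config$alpha2 * V
  structure(total, terms = c(mi = mi, bending = V,
                             similarity_term = config$alpha1 * (-mi),
                             penalty_term = config$alpha2 * V))
}
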