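# region extraction shared by the overlap metrics: logical vector of voxels
# carrying `label` (or any nonzero label when label is NULL)
.region <- function(mask, label) {
  arr <- if (inherits(mask, "label_mask")) mask$labels else mask
  v <- as.vector(arr)
  if (is.null(label)) v != 0 else v == label
}

#' Overlap report between two mask regions
#'
#' Computes the Dice coefficient `D = 2|Q n W| / (|Q| + |W|)` and the
#' voxelwise Jaccard index `J = |Q n W| / |Q u W|` between the regions
#' carrying `label` in a reference and a test mask, together with the raw
#' voxel counts. The two metrics satisfy `D = 2J / (1 + J)` exactly.
#'
#' Convention for degenerate regions: if both regions are empty, D = J = 1
#' (perfect agreement of empty sets); if exactly one is empty, D = J = 0.
#'
#' @param ref,test [label_mask()] objects (or logical/integer arrays) of
#'   identical shape.
#' @param label label value selecting the region; `NULL` selects all nonzero
#'   voxels.
#' @return List of class `overlap_report` with fields `dice`, `jaccard`,
#'   `n_ref`, `n_test`, `n_intersect`.
#' @examples
#' q <- matrix(0L, 4, 4); q[1:2, 1:2] <- 1L
#' w <- matrix(0L, 4, 4); w[2:3, 1:2] <- 1L
#' overlap_report(label_mask(q), label_mask(w), label = 1)
#' @export
overlap_report <- function(ref, test, label = NULL) {
  q <- .region(ref, label)
  w <- .region(test, label)
  if (length(q) != length(w)) stop("masks must have the same shape", call. = FALSE)
  n_q <- sum(q); n_w <- sum(w); n_i <- sum(q & w)
  if (n_q == 0L && n_w == 0L) {
    d <- 1; j <- 1
  } else {
    d <- 2 * n_i / (n_q + n_w)
    j <- n_i / (n_q + n_w - n_i)
  }
  structure(list(dice = d, jaccard = j, n_ref = n_q, n_test = n_w,
                 n_intersect = n_i),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("<overlap_report> Dice = %.4f, Jaccard = %.4f (|Q| = %d, |W| = %d, |QnW| = %d)\n",
              x$dice, x$jaccard, x$n_ref, x$n_test, x$n_intersect))
  invisible(x)
}

#' Dice coefficient
#'
#' @inheritParams overlap_report
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(ref, test, label = NULL) overlap_report(ref, test, label)$dice

#' Jaccard index
#'
#' @inheritParams overlap_report
#' @return Jaccard index in `[0, 1]`.
#' @export
jaccard <- function(ref, test, label = NULL) overlap_report(ref, test, label)$jaccard

#' Mean target registration error
#'
#' For paired landmarks `(x_i, x_i')`, the arithmetic mean of the Euclidean
#' distances between the transformed points `G(x_i)` and their known
#' correspondents `x_i'` (mm). With `transform = NULL` the identity map is
#' used, giving the pre-registration error.
#'
#' @param transform a [bspline_transform()] or `NULL` (identity).
#' @param landmarks a paired [landmark_set()].
#' @return Mean TRE (mm).
#' @export
mean_tre <- function(transform, landmarks) {
  stopifnot(inherits(landmarks, "landmark_set"))
  if (is.null(landmarks$paired_points)) {
    stop("mean TRE requires paired landmarks", call. = FALSE)
  }
  mapped <- if (is.null(transform)) landmarks$points
            else rbind(transform_point(transform, landmarks$points))
  mean(sqrt(rowSums((mapped - landmarks$paired_points)^2)))
}

#' Relative noise level inside a region of interest
#'
#' The sample standard deviation of the intensities inside the ROI, divided by
#' the volume's dynamic range (max - min). Dimensionless; 0 for a constant
#' volume. Intended for single-tissue ROIs, where intensity variation is noise.
#'
#' @param volume an [image_volume()].
#' @param roi a [label_mask()] (or logical array) selecting the region.
#' @param label label value selecting the region in `roi`; `NULL` = nonzero.
#' @return Noise level (dimensionless scalar).
#' @export
noise_level <- function(volume, roi, label = NULL) {
  stopifnot(inherits(volume, "image_volume"))
  sel <- .region(roi, label)
  if (length(sel) != length(volume$data)) {
    stop("'roi' must match the volume's shape", call. = FALSE)
  }
  if (!any(sel)) stop("empty ROI", call. = FALSE)
  vals <- as.vector(volume$data)[sel]
  rng <- diff(range(volume$data))
  if (rng == 0) return(0)
  s <- stats::sd(vals)
  if (is.na(s)) s <- 0   # single-voxel ROI
  s / rng
}
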