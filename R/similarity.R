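#' Joint intensity histogram of two images
#'
#' Bins the paired voxel intensities of two same-shape images into a
#' `bins x bins` table with uniform bin edges spanning each image's
#' `[min, max]` range (the maximum falls in the top bin). Returns the raw
#' counts, the normalized joint probabilities `p(a, b)` and both marginals.
#' A constant image occupies a single bin; that is valid input.
#'
#' @param A,B [image_volume()] objects (or plain numeric arrays/vectors) of
#'   identical shape.
#' @param bins number of intensity bins per image, >= 2 (default 32).
#' @param mask optional logical vector/array selecting the voxel pairs to
#'   count (the overlap region); default all.
#' @return An object of class `joint_histogram` with fields `counts`, `p_ab`,
#'   `p_a`, `p_b`, `bin_edges_a`, `bin_edges_b`, `n_samples`.
#' @export
joint_histogram <- function(A, B, bins = 32L, mask = NULL) {
  a <- if (inherits(A, "image_volume")) as.vector(A$data) else as.vector(A)
  b <- if (inherits(B, "image_volume")) as.vector(B$data) else as.vector(B)
  if (length(a) != length(b)) stop("'A' and 'B' must have the same shape", call. = FALSE)
  if (bins < 2L) stop("'bins' must be >= 2", call. = FALSE)
  if (!is.null(mask)) {
    mask <- as.vector(mask)
    a <- a[mask]; b <- b[mask]
  }
  if (length(a) == 0L) stop("no voxel pairs to histogram (empty overlap)", call. = FALSE)
  ia <- .bin_index(a, bins)
  ib <- .bin_index(b, bins)
  counts <- matrix(tabulate(ia$idx + (ib$idx - 1L) * bins, nbins = bins * bins),
                   bins, bins)
  n <- length(a)
  p_ab <- counts / n
  structure(list(counts = counts, p_ab = p_ab,
                 p_a = rowSums(p_ab), p_b = colSums(p_ab),
                 bin_edges_a = ia$edges, bin_edges_b = ib$edges,
                 n_samples = n),
            class = "joint_histogram")
}

# hard assignment to uniform bins over [min, max]; max goes to the top bin
.bin_index <- function(x, bins) {
  lo <- min(x); hi <- max(x)
  if (hi == lo) {
    return(list(idx = rep(1L, length(x)), edges = seq(lo, lo + 1, length.out = bins + 1L)))
  }
  w <- (hi - lo) / bins
  idx <- pmin(bins, floor((x - lo) / w) + 1L)
  list(idx = as.integer(idx), edges = seq(lo, hi, length.out = bins + 1L))
}

#' @export
print.joint_histogram <- function(x, ...) {
  cat("<joint_histogram> ", nrow(x$counts), " x ", ncol(x$counts),
      " bins, ", x$n_samples, " samples\n", sep = "")
  invisible(x)
}

#' Write a joint histogram as TSV
#'
#' Debug dump: columns `bin_a`, `bin_b`, `count`, one occupied bin per row.
#'
#' @param h a [joint_histogram()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_histogram_tsv <- function(h, path) {
  stopifnot(inherits(h, "joint_histogram"))
  occ <- which(h$counts > 0, arr.ind = TRUE)
  df <- data.frame(bin_a = occ[, 1], bin_b = occ[, 2], count = h$counts[occ])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Shannon entropy of a probability distribution
#'
#' Computes \eqn{-\sum_i p_i \log p_i} with \eqn{0 \log 0 = 0}. Log base 2 by
#' default (entropy in bits).
#'
#' @param p nonnegative numeric vector/matrix summing to 1 (tolerance 1e-6).
#' @param base logarithm base (default 2).
#' @return Entropy (scalar).
#' @examples
#' shannon_entropy(rep(1/4, 4))  # 2 bits
#' @export
shannon_entropy <- function(p, base = 2) {
  p <- as.vector(p)
  if (any(p < 0)) stop("probabilities must be nonnegative", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-6) stop("probabilities must sum to 1 (got ",
                                   format(sum(p)), ")", call. = FALSE)
  nz <- p > 0
  -sum(p[nz] * log(p[nz], base = base))
}

#' Mutual information between two images
#'
#' Estimates MI from the hard-binned joint histogram, in bits by default. Two
#' algebraically equivalent forms are computed and cross-checked:
#' the entropy combination \eqn{MI = K(A) + K(B) - K(A,B)} (marginal entropies
#' minus joint entropy) and the double sum
#' \eqn{\sum_{a,b} p(a,b) \log\left(p(a,b) / (p(a)p(b))\right)}. They must
#' agree to 1e-9; the entropy-combination value is returned.
#'
#' @inheritParams joint_histogram
#' @param base logarithm base (default 2: bits).
#' @return MI value with attribute `entropies` carrying `K_A`, `K_B`, `K_AB`.
#' @export
mutual_information <- function(A, B, bins = 32L, mask = NULL, base = 2) {
  h <- joint_histogram(A, B, bins = bins, mask = mask)
  mutual_information_from_histogram(h, base = base)
}

#' Mutual information from a precomputed joint histogram
#'
#' @param h a [joint_histogram()].
#' @param base logarithm base.
#' @return MI value, as in [mutual_information()].
#' @export
mutual_information_from_histogram <- function(h, base = 2) {
  stopifnot(inherits(h, "joint_histogram"))
  K_A <- shannon_entropy(h$p_a, base = base)
  K_B <- shannon_entropy(h$p_b, base = base)
  K_AB <- shannon_entropy(h$p_ab, base = base)
  mi_entropy <- K_A + K_B - K_AB
  # double-sum form over occupied cells
  nz <- which(h$p_ab > 0, arr.ind = TRUE)
  pj <- h$p_ab[nz]
  mi_sum <- sum(pj * log(pj / (h$p_a[nz[, 1]] * h$p_b[nz[, 2]]), base = base))
  if (abs(mi_entropy - mi_sum) > 1e-9) {
    stop("internal inconsistency: entropy-form and sum-form MI differ by ",
         format(abs(mi_entropy - mi_sum)), call. = FALSE)
  }
  structure(mi_entropy, entropies = c(K_A = K_A, K_B = K_B, K_AB = K_AB))
}
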