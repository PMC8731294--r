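#' Registration configuration
#'
#' Controls the multiresolution optimization that fits a B-spline free-form
#' deformation minimizing the composite cost (negated mutual information plus
#' weighted bending energy). Levels run coarse to fine: each level pairs an
#' image-pyramid factor with a control-grid spacing, a histogram resolution
#' and a step ladder, and each finer level starts from the coarse solution
#' resampled onto its lattice.
#'
#' The defaults implement a three-stage strategy that proved necessary for
#' sub-voxel recovery: (1) global alignment on a half-resolution image with a
#' 16 mm lattice and a coarse 32-bin histogram; (2) the same lattice at full
#' resolution; (3) an 8 mm lattice with a 64-bin histogram, followed by
#' residual-targeted escape moves (see below) and a final descent with a
#' sharper `refine_bins`-bin histogram. Coarse histograms give a wide, smooth
#' similarity basin; sharp histograms resolve fine intensity structure and
#' deepen the optimum, so bins are annealed rather than fixed.
#'
#' Greedy coordinate descent can leave an isolated image region locked in a
#' local optimum while its surroundings are well aligned; single control-point
#' moves then cannot escape because any one move degrades the aligned border
#' of the region. The escape ("hop") stage therefore ranks control points by
#' the mean absolute intensity residual around them, and for the worst few
#' tries shifting the whole 3x3 neighbourhood jointly by `hop_step` in each
#' direction, locally re-relaxes, and keeps the move only if the total cost
#' improves. All stages are deterministic.
#'
#' @param grid_spacing_schedule control-point spacings (mm), coarse to fine
#'   (non-increasing).
#' @param pyramid_factors per-level image downsampling factors (powers of 2,
#'   non-increasing; 1 = full resolution). Recycled to the schedule length.
#' @param bins_schedule per-level MI histogram bins (non-decreasing).
#' @param step_init per-level initial coordinate step (mm); each level works
#'   down a halving ladder from this value to `min_step`.
#' @param min_step step size (mm) below which a level's ladder stops.
#' @param max_sweeps_per_step sweeps allowed at one step size before halving.
#' @param max_iters overall sweep cap per level.
#' @param tol relative total-cost improvement per sweep below which the step
#'   is halved early.
#' @param hop_rounds rounds of residual-targeted escape moves at the finest
#'   level (0 disables).
#' @param hop_candidates control points re-examined per hop round.
#' @param hop_step magnitude (mm) of the joint neighbourhood shift.
#' @param refine_bins histogram bins for the final sharpened descent at the
#'   finest level (0 disables).
#' @param seed integer seed (kept for API symmetry; the optimizer is
#'   deterministic).
#' @param cost a [cost_config()]; its `bins` field is superseded by
#'   `bins_schedule` inside [register()].
#' @return An object of class `registration_config`.
#' @export
registration_config <- function(grid_spacing_schedule = c(16, 16, 8),
                                pyramid_factors = c(2, 1, 1),
                                bins_schedule = c(32, 32, 64),
                                step_init = c(2, 2, 0.5),
                                min_step = 0.05,
                                max_sweeps_per_step = 4L, max_iters = 60L,
                                tol = 1e-4,
                                hop_rounds = 8L, hop_candidates = 4L,
                                hop_step = 1,
                                refine_bins = 128L,
                                seed = 1L,
                                cost = cost_config(sample_stride = 1L)) {
  L <- length(grid_spacing_schedule)
  if (L == 0L) stop("schedule must be nonempty", call. = FALSE)
  if (is.unsorted(rev(grid_spacing_schedule))) {
    stop("'grid_spacing_schedule' must be non-increasing (coarse to fine)", call. = FALSE)
  }
  pyramid_factors <- rep_len(pyramid_factors, L)
  bins_schedule <- rep_len(as.integer(bins_schedule), L)
  step_init <- rep_len(step_init, L)
  if (any(pyramid_factors < 1) || any(pyramid_factors != 2^round(log2(pyramid_factors)))) {
    stop("'pyramid_factors' must be powers of 2 (>= 1)", call. = FALSE)
  }
  if (is.unsorted(rev(pyramid_factors))) {
    stop("'pyramid_factors' must be non-increasing", call. = FALSE)
  }
  if (max_iters < 1L) stop("'max_iters' must be >= 1", call. = FALSE)
  if (tol <= 0) stop("'tol' must be > 0", call. = FALSE)
  if (min_step <= 0 || any(step_init < min_step)) {
    stop("need step_init >= min_step > 0", call. = FALSE)
  }
  structure(list(grid_spacing_schedule = grid_spacing_schedule,
                 pyramid_factors = as.integer(pyramid_factors),
                 bins_schedule = bins_schedule,
                 step_init = step_init, min_step = min_step,
                 max_sweeps_per_step = as.integer(max_sweeps_per_step),
                 max_iters = as.integer(max_iters), tol = tol,
                 hop_rounds = as.integer(hop_rounds),
                 hop_candidates = as.integer(hop_candidates),
                 hop_step = hop_step,
                 refine_bins = as.integer(refine_bins),
                 seed = as.integer(seed), cost = cost),
            class = "registration_config")
}

# separable binomial [1,4,6,4,1]/16 smoothing along one axis, edge-replicated
.smooth_axis <- function(arr, axis) {
  k <- c(1, 4, 6, 4, 1) / 16
  n <- dim(arr)[axis]
  if (n < 2L) return(arr)
  out <- array(0, dim(arr))
  for (t in -2:2) {
    sl <- pmin(pmax(seq_len(n) + t, 1L), n)
    idx <- lapply(dim(arr), seq_len)
    idx[[axis]] <- sl
    out <- out + k[t + 3] * do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
  }
  out
}

# one pyramid step: binomial smoothing then factor-2 decimation
.downsample <- function(volume) {
  arr <- volume$data
  nd <- length(dim(arr))
  for (ax in seq_len(nd)) arr <- .smooth_axis(arr, ax)
  idx <- lapply(dim(arr), function(n) seq(1L, n, by = 2L))
  arr <- do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
  image_volume(arr, spacing = volume$spacing * 2, origin = volume$origin)
}

# lean bilinear sampling of a 2D array at continuous 0-based coordinates;
# outside -> NA (hot path of the registration cost)
.interp2 <- function(arr, x, y) {
  nx <- nrow(arr); ny <- ncol(arr)
  inside <- x >= 0 & x <= nx - 1 & y >= 0 & y <= ny - 1
  out <- rep(NA_real_, length(x))
  if (!any(inside)) return(out)
  xi <- x[inside]; yi <- y[inside]
  i0 <- pmax(pmin(floor(xi), nx - 2), 0)
  j0 <- pmax(pmin(floor(yi), ny - 2), 0)
  fx <- xi - i0; fy <- yi - j0
  base <- i0 + j0 * nx + 1
  v00 <- arr[base];          v10 <- arr[base + 1]
  v01 <- arr[base + nx];     v11 <- arr[base + nx + 1]
  out[inside] <- (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
                 (1 - fx) * fy * v01 + fx * fy * v11
  out
}

# entropy (bits) of a count vector, via log2(n) - sum(c log2 c)/n
.count_entropy <- function(counts, n) {
  nz <- counts[counts > 0L]
  log2(n) - sum(nz * log2(nz)) / n
}

# build the compiled incremental cost evaluator for a fixed image pair and
# lattice geometry. Returns a handle with the external pointer plus the
# helpers the optimizer needs. Floating-image bin edges are fixed from the
# full floating image so that incremental histogram updates stay exact.
.make_cost_evaluator <- function(template, A, B, config, bins = config$bins) {
  nd <- length(template$grid_spacing)
  shape <- dim(A$data)
  sel <- .stride_index(shape, config$sample_stride)
  pts <- .voxel_centres(shape, A$spacing, A$origin)[sel, , drop = FALSE]
  a_vals <- as.vector(A$data)[sel]
  ia <- .bin_index(a_vals, bins)$idx
  wi <- .ffd_weights(template, pts)
  pairs <- if (nd == 2L) list(c(1, 1), c(2, 2), c(1, 2))
           else list(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(1, 3), c(2, 3))
  wterm <- if (nd == 2L) c(1, 1, 2) else c(1, 1, 1, 2, 2, 2)
  W2 <- lapply(pairs, function(p) {
    dv <- rep(0L, nd); dv[p[1]] <- dv[p[1]] + 1L; dv[p[2]] <- dv[p[2]] + 1L
    .ffd_weights(template, pts, deriv = dv)$W
  })
  blo <- min(B$data); bhi <- max(B$data)
  bwidth <- if (bhi > blo) (bhi - blo) / bins else 1
  ncp <- prod(utils::head(dim(template$phi), -1L))
  ptr <- .ev_new(nd, pts, wi$W, wi$idx, W2, wterm, as.integer(ia), as.integer(bins),
                 as.vector(B$data), as.integer(dim(B$data)), B$origin, B$spacing,
                 blo, bwidth, as.integer(ncp),
                 config$alpha1, config$alpha2)
  list(ptr = ptr, n_par = nd * ncp,
       eval = function(phi) .ev_set_phi(ptr, as.vector(phi)))
}

# initialize a lattice from a coarser solution: sample its displacement field
# at the new control-point positions (clamped into the coarse domain)
.transfer_phi <- function(coarse, fine_template) {
  nd <- length(fine_template$grid_spacing)
  ncp <- utils::head(dim(fine_template$phi), -1L)
  # kernel centres: with the cell = floor(s) support convention, node j
  # (1-based) carries the cubic kernel centred at origin + (j - 2) * spacing
  nodes <- .voxel_centres(ncp, fine_template$grid_spacing,
                          fine_template$grid_origin - fine_template$grid_spacing)
  for (k in seq_len(nd)) {
    nodes[, k] <- pmin(pmax(nodes[, k], coarse$domain_min[k]), coarse$domain_max[k])
  }
  array(displacement(coarse, nodes), dim = dim(fine_template$phi))
}

# greedy first-improvement coordinate descent over `idx` (default: all
# parameters) down a halving step ladder, executed sweep-by-sweep in compiled
# code; returns list(phi, cost, trace rows, converged)
.coord_descent <- function(ev, phi, step0, min_step, max_sweeps_per_step,
                           max_iters, tol, idx = NULL, trace_label = "descent") {
  sel <- as.integer(if (is.null(idx)) seq_len(ev$n_par) else idx)
  cur <- .ev_set_phi(ev$ptr, as.vector(phi))
  step <- step0
  sweeps_at_step <- 0L
  rows <- list()
  exhausted <- FALSE
  sweeps <- 0L
  while (sweeps < max_iters) {
    sweeps <- sweeps + 1L
    sweep_start <- cur["total"]
    .ev_sweep(ev$ptr, sel, step)
    cur <- .ev_parts(ev$ptr)
    rows[[length(rows) + 1L]] <- data.frame(stage = trace_label, sweep = sweeps,
                                            step = step, mi = unname(cur["mi"]),
                                            bending = unname(cur["bending"]),
                                            total = unname(cur["total"]))
    rel <- (sweep_start - cur["total"]) / max(abs(sweep_start), 1e-12)
    sweeps_at_step <- sweeps_at_step + 1L
    if (rel < tol || sweeps_at_step >= max_sweeps_per_step) {
      step <- step / 2
      sweeps_at_step <- 0L
      if (step < min_step) { exhausted <- TRUE; break }
    }
  }
  list(phi = .ev_get_phi(ev$ptr), cost = cur, rows = rows,
       converged = exhausted, sweeps = sweeps)
}

# residual-targeted escape moves: jointly shift the 3^nd neighbourhood of the
# highest-residual control points, locally relax, keep only improvements
.hop_escape <- function(ev, phi, template, A, B, config) {
  nd <- length(template$grid_spacing)
  ncp <- utils::head(dim(template$phi), -1L)
  npt <- prod(ncp)
  shape <- dim(A$data)
  pts <- .voxel_centres(shape, A$spacing, A$origin)
  node_idx <- arrayInd(seq_len(npt), ncp)
  # kernel centres (see .transfer_phi): one spacing below the raw node index
  node_pos <- sweep(sweep(node_idx - 2, 2L, template$grid_spacing, "*"),
                    2L, template$grid_origin, "+")
  # voxels within 1.5 spacings of each node, for residual scoring
  node_vox <- lapply(seq_len(npt), function(j) {
    selv <- rep(TRUE, nrow(pts))
    for (k in seq_len(nd)) {
      selv <- selv & abs(pts[, k] - node_pos[j, k]) <= 1.5 * template$grid_spacing[k]
    }
    which(selv)
  })
  # 3^nd neighbourhood (linear indices) of each node
  stridev <- cumprod(c(1L, ncp[-nd]))
  neigh <- function(j) {
    offs <- as.matrix(expand.grid(rep(list(-1:1), nd)))
    cand <- sweep(offs, 2L, node_idx[j, ], "+")
    ok <- rep(TRUE, nrow(cand))
    for (k in seq_len(nd)) ok <- ok & cand[, k] >= 1 & cand[, k] <= ncp[k]
    as.vector(1 + (cand[ok, , drop = FALSE] - 1) %*% stridev)
  }
  dirs <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), nd)))
  dirs <- dirs[rowSums(abs(dirs)) > 0, , drop = FALSE]
  rows <- list()
  tmpl_phi_dim <- dim(template$phi)
  cur <- .ev_set_phi(ev$ptr, phi)
  # nodes whose escape attempts failed at the current state; retried only
  # after some other move is accepted (which changes the landscape)
  tried <- rep(FALSE, npt)
  for (round in seq_len(config$hop_rounds)) {
    trc <- bspline_transform(template$domain_min, template$domain_max,
                             template$grid_spacing,
                             phi = array(phi, tmpl_phi_dim))
    w <- .warp_core(trc, B$data, B$spacing, B$origin, "linear",
                    out_shape = shape, out_spacing = A$spacing,
                    out_origin = A$origin)
    resid <- abs(as.vector(A$data) - w$values)
    resid[!w$valid] <- 0
    score <- vapply(node_vox, function(v) if (length(v)) mean(resid[v]) else 0, 0)
    ranked <- order(score, decreasing = TRUE)
    ranked <- ranked[!tried[ranked]]
    if (length(ranked) == 0L) break
    cand_nodes <- ranked[seq_len(min(config$hop_candidates, length(ranked)))]
    improved <- FALSE
    for (j in cand_nodes) {
      nb <- neigh(j)
      block <- as.vector(outer(nb, (seq_len(nd) - 1L) * npt, "+"))
      best_phi <- NULL; best_cost <- cur
      for (r in seq_len(nrow(dirs))) {
        trial <- phi
        for (k in seq_len(nd)) {
          trial[nb + (k - 1L) * npt] <- trial[nb + (k - 1L) * npt] +
            dirs[r, k] * config$hop_step
        }
        rel <- .coord_descent(ev, trial, step0 = config$hop_step / 2,
                              min_step = config$hop_step / 4,
                              max_sweeps_per_step = 1L, max_iters = 2L,
                              tol = config$tol, idx = block,
                              trace_label = "hop-relax")
        if (rel$cost["total"] < best_cost["total"] - 1e-12) {
          best_phi <- rel$phi; best_cost <- rel$cost
        }
      }
      if (!is.null(best_phi)) {
        phi <- best_phi; cur <- best_cost; improved <- TRUE
        tried[] <- FALSE
        rows[[length(rows) + 1L]] <- data.frame(stage = "hop", sweep = round,
                                                step = config$hop_step,
                                                mi = unname(cur["mi"]),
                                                bending = unname(cur["bending"]),
                                                total = unname(cur["total"]))
        # settle the block border after the jump
        pol <- .coord_descent(ev, phi, step0 = config$hop_step / 4,
                              min_step = config$hop_step / 8,
                              max_sweeps_per_step = 1L, max_iters = 2L,
                              tol = config$tol, idx = block,
                              trace_label = "hop-relax")
        phi <- pol$phi; cur <- pol$cost
      } else {
        tried[j] <- TRUE
      }
    }
  }
  list(phi = phi, cost = cur, rows = rows)
}

#' Nonrigid registration of two images
#'
#' Finds the B-spline free-form deformation minimizing the composite cost
#' `alpha1 * (-MI) + alpha2 * V` between the reference image `A` and the
#' backward-warped floating image `B`. The optimizer is greedy
#' first-improvement coordinate descent over control-point displacements on a
#' halving step ladder, inside a coarse-to-fine schedule over image pyramid,
#' control-grid spacing and histogram resolution, with residual-targeted
#' escape moves at the finest level (see [registration_config()]). Fully
#' deterministic: fixed scan order, first improving move accepted.
#'
#' @param A reference [image_volume()] (nonconstant).
#' @param B floating [image_volume()] (nonconstant).
#' @param config a [registration_config()].
#' @return An object of class `registration_result` with fields `transform`
#'   (the fitted [bspline_transform()] on `A`'s full-resolution domain),
#'   `cost_trace` (data frame: level, stage, sweep, step, bins, mi, bending,
#'   total — accepted states only; the total is comparable within a level and
#'   bin count, not across them), `converged`, and `levels` (per-level
#'   summaries).
#' @export
register <- function(A, B, config = registration_config()) {
  stopifnot(inherits(A, "image_volume"), inherits(B, "image_volume"))
  if (diff(range(A$data)) == 0 || diff(range(B$data)) == 0) {
    stop("constant image: mutual information is degenerate", call. = FALSE)
  }
  schedule <- config$grid_spacing_schedule
  n_levels <- length(schedule)
  # image pyramid keyed by downsampling factor
  pyr <- list(`1` = list(A = A, B = B))
  maxf <- max(config$pyramid_factors)
  f <- 1L
  while (f < maxf) {
    prev <- pyr[[as.character(f)]]
    f <- f * 2L
    pyr[[as.character(f)]] <- list(A = .downsample(prev$A), B = .downsample(prev$B))
  }
  trace <- list()
  level_summaries <- list()
  converged <- FALSE
  tr <- NULL
  for (lv in seq_len(n_levels)) {
    pl <- pyr[[as.character(config$pyramid_factors[lv])]]
    Al <- pl$A; Bl <- pl$B
    bins <- config$bins_schedule[lv]
    template <- bspline_transform_for(Al, schedule[lv])
    phi <- if (is.null(tr)) array(0, dim(template$phi)) else .transfer_phi(tr, template)
    phi <- as.vector(phi)
    evalc <- .make_cost_evaluator(template, Al, Bl, config$cost, bins = bins)
    cur <- evalc$eval(phi)
    init_total <- cur["total"]
    add_rows <- function(rows, lv, bins) {
      for (r in rows) {
        r$level <- lv; r$bins <- bins
        trace[[length(trace) + 1L]] <<- r
      }
    }
    trace[[length(trace) + 1L]] <- data.frame(stage = "init", sweep = 0L, step = 0,
                                              mi = unname(cur["mi"]),
                                              bending = unname(cur["bending"]),
                                              total = unname(cur["total"]),
                                              level = lv, bins = bins)
    des <- .coord_descent(evalc, phi, step0 = config$step_init[lv],
                          min_step = config$min_step,
                          max_sweeps_per_step = config$max_sweeps_per_step,
                          max_iters = config$max_iters, tol = config$tol)
    phi <- des$phi; cur <- des$cost
    add_rows(des$rows, lv, bins)
    lv_converged <- des$converged
    if (lv == n_levels) {
      # first escape pass under the level objective: gross stuck regions are
      # easiest to move while the histogram is still forgiving
      if (config$hop_rounds > 0L) {
        hop <- .hop_escape(evalc, phi, template, Al, Bl, config)
        phi <- hop$phi; cur <- hop$cost
        add_rows(hop$rows, lv, bins)
      }
      # sharpen the histogram before the second escape pass: under the sharp
      # objective the aligned optimum is deepest, so escape moves are judged
      # most reliably there
      evr <- evalc; rbins <- bins
      if (config$refine_bins > 0L && config$refine_bins != bins) {
        rbins <- config$refine_bins
        evr <- .make_cost_evaluator(template, Al, Bl, config$cost, bins = rbins)
        ref <- .coord_descent(evr, phi, step0 = max(4 * config$min_step, config$min_step),
                              min_step = config$min_step,
                              max_sweeps_per_step = config$max_sweeps_per_step,
                              max_iters = config$max_iters, tol = config$tol,
                              trace_label = "refine")
        phi <- ref$phi; cur <- ref$cost
        add_rows(ref$rows, lv, rbins)
        lv_converged <- ref$converged
      }
      if (config$hop_rounds > 0L) {
        hop <- .hop_escape(evr, phi, template, Al, Bl, config)
        phi <- hop$phi; cur <- hop$cost
        add_rows(hop$rows, lv, rbins)
        pol <- .coord_descent(evr, phi, step0 = max(4 * config$min_step, config$min_step),
                              min_step = config$min_step,
                              max_sweeps_per_step = config$max_sweeps_per_step,
                              max_iters = config$max_iters, tol = config$tol,
                              trace_label = "polish")
        phi <- pol$phi; cur <- pol$cost
        add_rows(pol$rows, lv, rbins)
        lv_converged <- pol$converged
      }
    }
    tr <- bspline_transform(template$domain_min, template$domain_max,
                            template$grid_spacing,
                            phi = array(phi, dim(template$phi)))
    level_summaries[[lv]] <- list(level = lv, grid_spacing = schedule[lv],
                                  pyramid_factor = config$pyramid_factors[lv],
                                  bins = bins,
                                  image_shape = dim(Al$data),
                                  initial_cost = unname(init_total),
                                  final_cost = unname(cur["total"]),
                                  converged = lv_converged)
    if (lv == n_levels) converged <- lv_converged
  }
  trace <- do.call(rbind, trace)
  rownames(trace) <- NULL
  trace <- trace[, c("level", "stage", "sweep", "step", "bins", "mi", "bending", "total")]
  structure(list(transform = tr, cost_trace = trace, converged = converged,
                 levels = level_summaries),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  n <- nrow(x$cost_trace)
  cat("<registration_result> ", length(x$levels), " level(s), final cost ",
      format(x$cost_trace$total[n]), " (MI = ", format(x$cost_trace$mi[n]),
      " bits), converged: ", x$converged, "\n", sep = "")
  invisible(x)
}

#' Write a registration cost trace as TSV
#'
#' @param result a [register()] result.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_cost_trace <- function(result, path) {
  stopifnot(inherits(result, "registration_result"))
  utils::write.table(result$cost_trace, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
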