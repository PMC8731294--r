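#' Softmax over per-class scores
#'
#' Converts raw per-class scores at one or more pixels into class
#' probabilities: `h_a = exp(s_a) / sum_a' exp(s_a')`. Numerically stabilized
#' by subtracting the row maximum, so adding any constant to all scores of a
#' pixel leaves the output unchanged up to floating-point rounding of the
#' shifted scores.
#'
#' @param scores numeric vector (one pixel) or matrix (pixels in rows, classes
#'   in columns); at least 2 classes, all finite.
#' @return Probabilities of the same shape; each pixel's probabilities sum
#'   to 1.
#' @examples
#' softmax_energy(c(0, 0, 0, 0))  # 1/4 each
#' @export
softmax_energy <- function(scores) {
  vec_in <- is.null(dim(scores))
  s <- rbind(scores)
  if (ncol(s) < 2L) stop("need at least 2 classes", call. = FALSE)
  if (any(!is.finite(s))) stop("scores must be finite", call. = FALSE)
  e <- exp(s - apply(s, 1L, max))
  p <- e / rowSums(e)
  if (vec_in) drop(p) else p
}

#' Soft-Dice training loss
#'
#' `1 - mean` over foreground classes of the soft Dice coefficient
#' `(2 * sum(p*t) + eps) / (sum(p) + sum(t) + eps)`, where `p` are the
#' predicted class probabilities and `t` the one-hot target. Background
#' (label 0) is excluded from the mean, so the loss drives foreground overlap.
#' Bounded in `[0, 1]`; 0 when predictions are exactly one-hot on the target
#' (up to the `eps` smoothing).
#'
#' @param probs numeric matrix, pixels in rows and classes in columns (or an
#'   `(H, W, C)` array), rows on the probability simplex.
#' @param target integer vector/array of labels in `0..n_classes-1`, one per
#'   pixel.
#' @param eps smoothing constant (default 1).
#' @return Scalar loss.
#' @export
dice_loss <- function(probs, target, eps = 1) {
  if (length(dim(probs)) == 3L) {
    probs <- matrix(probs, ncol = dim(probs)[3L])
  }
  target <- as.vector(target)
  C <- ncol(probs)
  if (length(target) != nrow(probs)) stop("shape mismatch", call. = FALSE)
  if (any(target < 0) || any(target >= C)) {
    stop("target labels must lie in 0..", C - 1L, call. = FALSE)
  }
  Tm <- .one_hot(target, C)
  fg <- 2:C
  d <- vapply(fg, function(c) {
    (2 * sum(probs[, c] * Tm[, c]) + eps) / (sum(probs[, c]) + sum(Tm[, c]) + eps)
  }, numeric(1))
  1 - mean(d)
}

.one_hot <- function(labels, C) {
  Tm <- matrix(0, length(labels), C)
  Tm[cbind(seq_along(labels), labels + 1L)] <- 1
  Tm
}

#' U-net segmenter configuration
#'
#' Hyperparameters of the compact encoder-decoder segmentation network: two
#' 3x3 same-padded convolutions with ReLU per level, 2x2 max pooling on the
#' contraction path, nearest-neighbour upsampling plus convolution on the
#' expansion path, skip concatenation between matching levels, a 1x1
#' convolution head and a per-pixel softmax. Trained with the soft-Dice
#' objective ([dice_loss()]) and Adam. The default is deliberately small
#' (depth 3, 8 base channels, 64x64 inputs) so that training runs in minutes
#' on one CPU.
#'
#' @param n_classes number of segmentation classes (>= 2, incl. background).
#' @param depth number of contraction (pooling) levels, >= 1.
#' @param base_channels feature maps at the first level; doubled per level.
#' @param epochs,batch_size,learning_rate training hyperparameters.
#' @param seed integer seed for weight initialization and shuffling.
#' @return An object of class `segnet_config`.
#' @export
segnet_config <- function(n_classes = 2L, depth = 3L, base_channels = 8L,
                          epochs = 20L, batch_size = 8L, learning_rate = 3e-3,
                          seed = 1L) {
  if (n_classes < 2L) stop("'n_classes' must be >= 2", call. = FALSE)
  if (depth < 1L) stop("'depth' must be >= 1", call. = FALSE)
  if (base_channels < 1L || epochs < 1L || batch_size < 1L || learning_rate <= 0) {
    stop("hyperparameters must be positive", call. = FALSE)
  }
  structure(list(n_classes = as.integer(n_classes), depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "segnet_config")
}

# ---- tensor plumbing -------------------------------------------------------
# Feature maps are (N*H*W) x C matrices; pixel rows are column-major over
# (H, W) per image, images stacked. Shift maps implement zero-padded 3x3
# convolution support.

# index vector (length N*H*W, NA = outside) for offset (dh, dw)
.shift_map <- function(N, H, W, dh, dw) {
  h <- rep(seq_len(H), W) + dh
  w <- rep(seq_len(W), each = H) + dw
  idx <- ifelse(h >= 1 & h <= H & w >= 1 & w <= W, (w - 1L) * H + h, NA_integer_)
  if (N > 1L) {
    idx <- rep(idx, N) + rep((seq_len(N) - 1L) * (H * W), each = H * W)
  }
  as.integer(idx)
}

# all 9 shift maps for a (N, H, W) resolution, keyed cache
.shift_cache <- function(cache, N, H, W) {
  key <- paste(N, H, W, sep = "x")
  if (is.null(cache[[key]])) {
    maps <- list()
    for (dh in -1:1) for (dw in -1:1) {
      maps[[paste(dh, dw)]] <- .shift_map(N, H, W, dh, dw)
    }
    cache[[key]] <- maps
  }
  cache[[key]]
}

.shifted <- function(X, idx) {
  out <- X[idx, , drop = FALSE]
  out[is.na(idx), ] <- 0
  out
}

# 3x3 same-padded convolution. W: array (3, 3, Cin, Cout) indexed by
# (dh+2, dw+2); b: length Cout
.conv3_fwd <- function(X, W, b, maps) {
  Cout <- dim(W)[4L]
  Cin <- dim(W)[3L]
  Y <- matrix(rep(b, each = nrow(X)), nrow(X), Cout)
  for (dh in -1:1) for (dw in -1:1) {
    Wk <- matrix(W[dh + 2L, dw + 2L, , ], Cin, Cout)
    Y <- Y + .shifted(X, maps[[paste(dh, dw)]]) %*% Wk
  }
  Y
}

.conv3_bwd <- function(dY, X, W, maps) {
  dW <- array(0, dim(W))
  dX <- matrix(0, nrow(X), dim(W)[3L])
  for (dh in -1:1) for (dw in -1:1) {
    Xs <- .shifted(X, maps[[paste(dh, dw)]])
    dW[dh + 2L, dw + 2L, , ] <- crossprod(Xs, dY)
    dX <- dX + .shifted(dY, maps[[paste(-dh, -dw)]]) %*% t(matrix(W[dh + 2L, dw + 2L, , ],
                                                                  dim(W)[3L]))
  }
  list(dX = dX, dW = dW, db = colSums(dY))
}

# 2x2 max pooling, stride 2
.pool_fwd <- function(X, N, H, W) {
  Ho <- H %/% 2L; Wo <- W %/% 2L
  idx <- vector("list", 4L)
  k <- 0L
  for (dw in 0:1) for (dh in 0:1) {
    k <- k + 1L
    h <- rep(seq_len(Ho) * 2L - 1L + dh, Wo)
    w <- rep(seq_len(Wo) * 2L - 1L + dw, each = Ho)
    base <- (w - 1L) * H + h
    idx[[k]] <- if (N > 1L) rep(base, N) + rep((seq_len(N) - 1L) * (H * W), each = Ho * Wo)
                else base
  }
  cur <- X[idx[[1L]], , drop = FALSE]
  am <- matrix(1L, nrow(cur), ncol(cur))
  for (k in 2:4) {
    cand <- X[idx[[k]], , drop = FALSE]
    upd <- cand > cur
    am[upd] <- k
    cur[upd] <- cand[upd]
  }
  list(out = cur, argmax = am, idx = idx)
}

.pool_bwd <- function(dY, cache, n_in_rows) {
  dX <- matrix(0, n_in_rows, ncol(dY))
  for (k in 1:4) {
    sel <- cache$argmax == k
    tmp <- dY
    tmp[!sel] <- 0
    dX[cache$idx[[k]], ] <- dX[cache$idx[[k]], ] + tmp
  }
  dX
}

# nearest-neighbour 2x upsampling
.up_map <- function(N, H, W) {
  Ho <- H * 2L; Wo <- W * 2L
  h <- (rep(seq_len(Ho), Wo) + 1L) %/% 2L
  w <- (rep(seq_len(Wo), each = Ho) + 1L) %/% 2L
  base <- (w - 1L) * H + h
  if (N > 1L) rep(base, N) + rep((seq_len(N) - 1L) * (H * W), each = Ho * Wo)
  else base
}

# ---- model -----------------------------------------------------------------

.unet_channels <- function(config) config$base_channels * 2L^(0:config$depth)

#' Initialize an untrained U-net
#'
#' He-normal weight initialization, seeded from the config.
#'
#' @param config a [segnet_config()].
#' @return An object of class `unet_model` (weights, config, normalization
#'   slots, training history).
#' @export
unet_init <- function(config) {
  stopifnot(inherits(config, "segnet_config"))
  old <- .Random.seed_save()
  set.seed(config$seed)
  ch <- .unet_channels(config)
  D <- config$depth
  w <- list()
  mk3 <- function(cin, cout) {
    list(W = array(stats::rnorm(9 * cin * cout, 0, sqrt(2 / (9 * cin))),
                   dim = c(3, 3, cin, cout)),
         b = rep(0, cout))
  }
  cin <- 1L
  for (i in seq_len(D)) {
    w[[paste0("enc", i, "a")]] <- mk3(cin, ch[i])
    w[[paste0("enc", i, "b")]] <- mk3(ch[i], ch[i])
    cin <- ch[i]
  }
  w[["bota"]] <- mk3(ch[D], ch[D + 1L])
  w[["botb"]] <- mk3(ch[D + 1L], ch[D + 1L])
  for (i in rev(seq_len(D))) {
    w[[paste0("up", i)]] <- mk3(ch[i + 1L], ch[i])
    w[[paste0("dec", i, "a")]] <- mk3(2L * ch[i], ch[i])
    w[[paste0("dec", i, "b")]] <- mk3(ch[i], ch[i])
  }
  w[["head"]] <- list(W = matrix(stats::rnorm(ch[1L] * config$n_classes, 0,
                                              sqrt(2 / ch[1L])), ch[1L]),
                      b = rep(0, config$n_classes))
  .Random.seed_restore(old)
  structure(list(config = config, weights = w,
                 norm = list(center = 0, scale = 1),
                 history = NULL),
            class = "unet_model")
}

# forward pass; X: (N*H*W) x 1. Returns probs (+ caches when training)
.unet_fwd <- function(model, X, N, H, W, caches_env = NULL, train = FALSE) {
  wts <- model$weights
  D <- model$config$depth
  maps_for <- function(h, w) .shift_cache(caches_env, N, h, w)
  cache <- list()
  cur <- X; h <- H; wd <- W
  skips <- vector("list", D)
  conv_relu <- function(name, x, maps) {
    y <- .conv3_fwd(x, wts[[name]]$W, wts[[name]]$b, maps)
    m <- y > 0
    y[!m] <- 0
    if (train) cache[[name]] <<- list(x = x, mask = m, maps = maps)
    y
  }
  for (i in seq_len(D)) {
    maps <- maps_for(h, wd)
    cur <- conv_relu(paste0("enc", i, "a"), cur, maps)
    cur <- conv_relu(paste0("enc", i, "b"), cur, maps)
    skips[[i]] <- cur
    pl <- .pool_fwd(cur, N, h, wd)
    if (train) cache[[paste0("pool", i)]] <- c(pl["argmax"], pl["idx"],
                                               list(n_in = nrow(cur), h = h, w = wd))
    cur <- pl$out
    h <- h %/% 2L; wd <- wd %/% 2L
  }
  maps <- maps_for(h, wd)
  cur <- conv_relu("bota", cur, maps)
  cur <- conv_relu("botb", cur, maps)
  for (i in rev(seq_len(D))) {
    um <- .up_map(N, h, wd)
    cur <- cur[um, , drop = FALSE]
    if (train) cache[[paste0("upmap", i)]] <- list(map = um, n_in = h * wd * N)
    h <- h * 2L; wd <- wd * 2L
    maps <- maps_for(h, wd)
    cur <- conv_relu(paste0("up", i), cur, maps)
    nskip <- ncol(skips[[i]])
    cur <- cbind(skips[[i]], cur)
    if (train) cache[[paste0("cat", i)]] <- nskip
    cur <- conv_relu(paste0("dec", i, "a"), cur, maps)
    cur <- conv_relu(paste0("dec", i, "b"), cur, maps)
  }
  scores <- cur %*% wts$head$W + matrix(rep(wts$head$b, each = nrow(cur)),
                                        nrow(cur))
  if (train) cache[["head_in"]] <- cur
  probs <- softmax_energy(scores)
  list(probs = probs, cache = cache)
}

# backward pass from dL/dprobs; returns gradient list parallel to weights
.unet_bwd <- function(model, fwd, dProbs) {
  wts <- model$weights
  D <- model$config$depth
  cache <- fwd$cache
  P <- fwd$probs
  grads <- list()
  # softmax jacobian-vector product
  dS <- P * (dProbs - rowSums(dProbs * P))
  grads$head <- list(W = crossprod(cache$head_in, dS), b = colSums(dS))
  cur <- dS %*% t(wts$head$W)
  conv_bwd <- function(name, d) {
    cc <- cache[[name]]
    d[!cc$mask] <- 0
    g <- .conv3_bwd(d, cc$x, wts[[name]]$W, cc$maps)
    grads[[name]] <<- list(W = g$dW, b = g$db)
    g$dX
  }
  for (i in seq_len(D)) {
    cur <- conv_bwd(paste0("dec", i, "b"), cur)
    cur <- conv_bwd(paste0("dec", i, "a"), cur)
    nskip <- cache[[paste0("cat", i)]]
    dskip <- cur[, seq_len(nskip), drop = FALSE]
    cur <- cur[, -seq_len(nskip), drop = FALSE]
    cur <- conv_bwd(paste0("up", i), cur)
    um <- cache[[paste0("upmap", i)]]
    cur <- rowsum(cur, group = um$map)
    # skip-path gradient flows into the encoder below
    cache[[paste0("skipgrad", i)]] <- dskip
  }
  cur <- conv_bwd("botb", cur)
  cur <- conv_bwd("bota", cur)
  for (i in rev(seq_len(D))) {
    pc <- cache[[paste0("pool", i)]]
    cur <- .pool_bwd(cur, pc, pc$n_in)
    cur <- cur + cache[[paste0("skipgrad", i)]]
    cur <- conv_bwd(paste0("enc", i, "b"), cur)
    cur <- conv_bwd(paste0("enc", i, "a"), cur)
  }
  grads
}

# soft-Dice loss + gradient w.r.t. probs (batch-global per-class sums)
.dice_loss_grad <- function(P, target, eps = 1) {
  C <- ncol(P)
  Tm <- .one_hot(target, C)
  fg <- 2:C
  K <- length(fg)
  loss_terms <- numeric(K)
  dP <- matrix(0, nrow(P), C)
  for (j in seq_along(fg)) {
    c <- fg[j]
    S_pt <- sum(P[, c] * Tm[, c]); S_p <- sum(P[, c]); S_t <- sum(Tm[, c])
    den <- S_p + S_t + eps
    loss_terms[j] <- (2 * S_pt + eps) / den
    dP[, c] <- -(2 * Tm[, c] * den - (2 * S_pt + eps)) / den^2 / K
  }
  list(loss = 1 - mean(loss_terms), dP = dP)
}

.adam_step <- function(state, grads, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(grads)) {
    for (slot in c("W", "b")) {
      g <- grads[[nm]][[slot]]
      state$m[[nm]][[slot]] <- beta1 * state$m[[nm]][[slot]] + (1 - beta1) * g
      state$v[[nm]][[slot]] <- beta2 * state$v[[nm]][[slot]] + (1 - beta2) * g^2
      mhat <- state$m[[nm]][[slot]] / (1 - beta1^t)
      vhat <- state$v[[nm]][[slot]] / (1 - beta2^t)
      state$weights[[nm]][[slot]] <- state$weights[[nm]][[slot]] -
        lr * mhat / (sqrt(vhat) + eps)
    }
  }
  state
}

# stack a list of 2D arrays into the (N*H*W) x 1 batch layout
.stack_images <- function(arrs) {
  matrix(unlist(lapply(arrs, as.vector)), ncol = 1L)
}

#' Train the U-net segmenter
#'
#' Trains on pairs of 2D images and label masks with the soft-Dice objective
#' and Adam. Images are standardized with the training set's global mean and
#' standard deviation (stored in the model and re-applied at inference).
#' Deterministic for a fixed config seed: weight initialization and epoch
#' shuffling share the seeded stream and the optimizer is deterministic.
#'
#' @param dataset list of training pairs; each element a list with fields
#'   `volume` (an [image_volume()], 2D) and `mask` (a [label_mask()], labels
#'   in `0..n_classes-1`).
#' @param config a [segnet_config()].
#' @return A trained `unet_model`; `model$history` is a data frame with one
#'   row per epoch (`epoch`, `mean_loss`).
#' @export
train_unet <- function(dataset, config = segnet_config()) {
  stopifnot(inherits(config, "segnet_config"))
  if (length(dataset) < 1L) stop("need at least one training pair", call. = FALSE)
  imgs <- lapply(dataset, function(d) {
    arr <- if (inherits(d$volume, "image_volume")) d$volume$data else d$volume
    if (length(dim(arr)) != 2L) stop("training images must be 2D", call. = FALSE)
    arr
  })
  msks <- lapply(dataset, function(d) {
    m <- if (inherits(d$mask, "label_mask")) d$mask$labels else d$mask
    if (max(m) >= config$n_classes) {
      stop("mask label ", max(m), " out of range for ", config$n_classes,
           " classes", call. = FALSE)
    }
    m
  })
  H <- nrow(imgs[[1L]]); W <- ncol(imgs[[1L]])
  if (H != W) stop("training images must be square", call. = FALSE)
  if (H %% 2L^config$depth != 0L) {
    stop("image side ", H, " not divisible by 2^depth = ", 2L^config$depth,
         call. = FALSE)
  }
  all_px <- unlist(imgs)
  center <- mean(all_px); scale <- stats::sd(all_px)
  if (!is.finite(scale) || scale == 0) scale <- 1
  imgs <- lapply(imgs, function(a) (a - center) / scale)

  model <- unet_init(config)
  model$norm <- list(center = center, scale = scale)
  zero_like <- lapply(model$weights, function(l) list(W = l$W * 0, b = l$b * 0))
  state <- list(weights = model$weights, m = zero_like, v = zero_like)
  caches_env <- new.env(parent = emptyenv())

  old <- .Random.seed_save()
  set.seed(config$seed + 1L)
  t <- 0L
  history <- data.frame(epoch = integer(), mean_loss = numeric())
  n <- length(dataset)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    losses <- c()
    for (start in seq(1L, n, by = config$batch_size)) {
      sel <- ord[start:min(start + config$batch_size - 1L, n)]
      N <- length(sel)
      X <- .stack_images(imgs[sel])
      target <- unlist(lapply(msks[sel], as.vector))
      model$weights <- state$weights
      fwd <- .unet_fwd(model, X, N, H, W, caches_env, train = TRUE)
      lg <- .dice_loss_grad(fwd$probs, target)
      grads <- .unet_bwd(model, fwd, lg$dP)
      t <- t + 1L
      state <- .adam_step(state, grads, config$learning_rate, t)
      losses <- c(losses, lg$loss)
    }
    history <- rbind(history, data.frame(epoch = ep, mean_loss = mean(losses)))
  }
  .Random.seed_restore(old)
  model$weights <- state$weights
  model$history <- history
  model
}

#' @export
print.unet_model <- function(x, ...) {
  np <- sum(vapply(x$weights, function(l) length(l$W) + length(l$b), numeric(1)))
  cat("<unet_model> depth ", x$config$depth, ", ", x$config$n_classes,
      " classes, ", format(np, big.mark = ","), " parameters",
      if (!is.null(x$history)) paste0(", final loss ",
                                      format(utils::tail(x$history$mean_loss, 1))),
      "\n", sep = "")
  invisible(x)
}

#' Segment an image with a trained U-net
#'
#' Applies the network and takes the per-pixel argmax of the softmax
#' probabilities.
#'
#' @param model a trained `unet_model` from [train_unet()].
#' @param volume an [image_volume()] (2D, side divisible by `2^depth`).
#' @return A [label_mask()] with labels in `0..n_classes-1`.
#' @export
segment <- function(model, volume) {
  stopifnot(inherits(model, "unet_model"))
  arr <- if (inherits(volume, "image_volume")) volume$data else volume
  if (length(dim(arr)) != 2L) stop("'volume' must be 2D", call. = FALSE)
  H <- nrow(arr); W <- ncol(arr)
  if (H %% 2L^model$config$depth != 0L || W %% 2L^model$config$depth != 0L) {
    stop("image sides must be divisible by 2^depth", call. = FALSE)
  }
  X <- matrix((as.vector(arr) - model$norm$center) / model$norm$scale, ncol = 1L)
  caches_env <- new.env(parent = emptyenv())
  fwd <- .unet_fwd(model, X, 1L, H, W, caches_env, train = FALSE)
  labels <- max.col(fwd$probs, ties.method = "first") - 1L
  sp <- if (inherits(volume, "image_volume")) volume$spacing else 1
  or <- if (inherits(volume, "image_volume")) volume$origin else 0
  label_mask(array(labels, c(H, W)), spacing = sp, origin = or)
}

#' Per-pixel class probabilities from a trained U-net
#'
#' @param model a trained `unet_model`.
#' @param volume an [image_volume()] (2D).
#' @return `(H, W, n_classes)` array of softmax probabilities.
#' @export
segment_probs <- function(model, volume) {
  stopifnot(inherits(model, "unet_model"))
  arr <- if (inherits(volume, "image_volume")) volume$data else volume
  H <- nrow(arr); W <- ncol(arr)
  X <- matrix((as.vector(arr) - model$norm$center) / model$norm$scale, ncol = 1L)
  caches_env <- new.env(parent = emptyenv())
  fwd <- .unet_fwd(model, X, 1L, H, W, caches_env, train = FALSE)
  array(fwd$probs, c(H, W, ncol(fwd$probs)))
}

#' Save a trained U-net to a self-describing JSON container
#'
#' @param model a `unet_model`.
#' @param path destination path (`.json`).
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "unet_model"))
  obj <- list(format = "spinereg-unet", version = 1L,
              config = unclass(model$config),
              norm = model$norm,
              weights = lapply(model$weights, function(l) {
                list(W = as.vector(l$W), W_dim = dim(l$W) %||% c(nrow(l$W), ncol(l$W)),
                     b = l$b)
              }))
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a U-net saved by [write_model()]
#'
#' @param path path to the JSON container.
#' @return A `unet_model`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "spinereg-unet") {
    stop("not a spinereg model file: ", path, call. = FALSE)
  }
  cfg <- do.call(segnet_config, obj$config)
  model <- unet_init(cfg)
  model$norm <- obj$norm
  for (nm in names(model$weights)) {
    wrec <- obj$weights[[nm]]
    Wd <- wrec$W_dim
    model$weights[[nm]]$W <- if (length(Wd) == 2L) matrix(wrec$W, Wd[1], Wd[2])
                             else array(wrec$W, Wd)
    model$weights[[nm]]$b <- wrec$b
  }
  model
}
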