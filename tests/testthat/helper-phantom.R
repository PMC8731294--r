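# shared fixtures, all generated in code

# a small noise-free 2D phantom (3 vertebrae) for geometric tests
small_phantom <- function(seed = 1L, noise_sd = 0, shape = c(48, 48), nv = 3L) {
  generate_phantom(phantom_config(shape = shape, n_vertebrae = nv,
                                  noise_sd = noise_sd, seed = seed))
}

# binary vertebra-vs-background training pair at 64x64
binary_pair <- function(seed, noise_sd = 5) {
  cfg <- phantom_config(shape = c(64, 64), noise_sd = noise_sd, seed = seed)
  ph <- generate_phantom(cfg)
  lab <- ph$mask$labels
  bin <- array(as.integer(lab >= 1L & lab <= cfg$n_vertebrae), dim(lab))
  list(volume = ph$volume, mask = label_mask(bin, ph$mask$spacing),
       full_mask = ph$mask, landmarks = ph$landmarks, config = cfg)
}

# random small label mask (for metric property tests)
random_mask <- function(shape = c(8, 8), p = 0.4) {
  label_mask(array(as.integer(stats::runif(prod(shape)) < p), shape))
}

# brute-force second derivative of a transform's displacement by central
# differences of transform_point (independent of the analytic path)
fd_second_derivative <- function(tr, pt, ax1, ax2, h) {
  nd <- length(pt)
  e1 <- rep(0, nd); e1[ax1] <- h
  e2 <- rep(0, nd); e2[ax2] <- h
  d <- function(p) rbind(transform_point(tr, rbind(p)))[1, ] - p
  if (ax1 == ax2) {
    (d(pt + e1) - 2 * d(pt) + d(pt - e1)) / h^2
  } else {
    (d(pt + e1 + e2) - d(pt + e1 - e2) - d(pt - e1 + e2) + d(pt - e1 - e2)) / (4 * h^2)
  }
}

# training pair with the anatomy displaced by a random ground-truth warp:
# deformation augmentation, so the network must follow image content instead
# of memorizing the phantom's fixed geometry
binary_pair_deformed <- function(seed, noise_sd = 5, max_displacement = 2.5) {
  p <- binary_pair(seed, noise_sd)
  gt <- random_deformation(p$config, max_displacement)
  list(volume = warp_image(gt, p$volume), mask = warp_image(gt, p$mask))
}

# standard training set: half canonical, half deformation-augmented
binary_training_set <- function(n = 60, noise_sd = 5, seed_base = 0) {
  c(lapply(seed_base + seq_len(n / 2), binary_pair, noise_sd = noise_sd),
    lapply(seed_base + n / 2 + seq_len(n / 2), binary_pair_deformed,
           noise_sd = noise_sd))
}

# cache for expensive shared fixtures (trained segmenter)
.fixture_env <- new.env(parent = emptyenv())

trained_segmenter <- function() {
  if (is.null(.fixture_env$model)) {
    .fixture_env$model <- train_unet(binary_training_set(60),
                                     segnet_config(seed = 1L))
  }
  .fixture_env$model
}
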