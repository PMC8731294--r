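test_that("softmax is a shift-invariant probability simplex", {
  expect_equal(softmax_energy(rep(1.3, 5)), rep(1 / 5, 5))
  s <- c(0.2, -1.5, 3.1, 0.4)
  expect_equal(softmax_energy(s + 7.5), softmax_energy(s), tolerance = 1e-12)
  # direct exp/normalize oracle
  set.seed(51)
  m <- matrix(rnorm(40), 10, 4)
  want <- t(apply(m, 1, function(r) exp(r) / sum(exp(r))))
  expect_equal(softmax_energy(m), want, tolerance = 1e-12)
  expect_equal(rowSums(softmax_energy(m)), rep(1, 10))
  expect_equal(apply(softmax_energy(m), 1, which.max), apply(m, 1, which.max))
  expect_error(softmax_energy(c(1, NA)), "finite")
  expect_error(softmax_energy(5), "2 classes")
})

test_that("soft-Dice loss hits its extremes and a closed-form midpoint", {
  n <- 100
  target <- rep(c(0L, 1L), each = n / 2)
  onehot <- cbind(1 - target, target)
  expect_lt(dice_loss(onehot, target), 0.01)              # perfect prediction
  expect_gt(dice_loss(cbind(target, 1 - target), target), 0.98)  # fully wrong
  # uniform prediction: soft Dice = (2*S/2 + 1)/(n/2 + S + 1) with S = |fg|
  unif <- matrix(0.5, n, 2)
  S <- n / 2
  want <- 1 - (2 * 0.5 * S + 1) / (0.5 * n + S + 1)
  expect_equal(dice_loss(unif, target), want, tolerance = 1e-12)
  expect_error(dice_loss(onehot, rep(2L, n)), "labels")
})

test_that("dice loss decreases toward the target along a straight line", {
  set.seed(52)
  target <- sample(0:1, 64, replace = TRUE)
  onehot <- cbind(1 - target, target)
  rand <- matrix(runif(128), 64, 2); rand <- rand / rowSums(rand)
  lam <- seq(0, 1, by = 0.25)
  losses <- sapply(lam, function(l) dice_loss((1 - l) * rand + l * onehot, target))
  expect_true(all(diff(losses) < 0))
})

test_that("training is seed-deterministic and validates shapes", {
  train <- lapply(1:6, binary_pair)
  sc <- segnet_config(epochs = 2L, seed = 7L)
  m1 <- train_unet(train, sc)
  m2 <- train_unet(train, sc)
  expect_identical(m1$weights, m2$weights)
  expect_true(all(is.finite(m1$history$mean_loss)))
  # shape contract: side must be divisible by 2^depth
  bad <- list(list(volume = image_volume(matrix(rnorm(60^2), 60)),
                   mask = label_mask(matrix(0L, 60, 60))))
  expect_error(train_unet(bad, segnet_config(depth = 3)), "divisible")
  # labels must fit the class count
  bad2 <- lapply(1:2, function(s) {
    p <- binary_pair(s)
    p$mask$labels[1] <- 5L
    list(volume = p$volume, mask = p$mask)
  })
  expect_error(train_unet(bad2, segnet_config(n_classes = 2)), "out of range")
})

test_that("segmentation output is a valid label mask of the input shape", {
  train <- lapply(1:6, binary_pair)
  model <- train_unet(train, segnet_config(epochs = 2L, seed = 1L))
  p <- binary_pair(50)
  seg <- segment(model, p$volume)
  expect_s3_class(seg, "label_mask")
  expect_identical(dim(seg$labels), dim(p$volume$data))
  expect_true(all(seg$labels %in% 0:1))
  pr <- segment_probs(model, p$volume)
  expect_equal(dim(pr), c(64, 64, 2))
  expect_equal(apply(pr, c(1, 2), sum), matrix(1, 64, 64), tolerance = 1e-12)
  expect_error(segment(model, image_volume(matrix(0, 60, 60))), "divisible")
})

test_that("a constant image yields a spatially constant interior prediction", {
  sc <- segnet_config(depth = 1L, epochs = 1L, seed = 2L)
  train <- list(list(volume = image_volume(matrix(rnorm(32^2), 32)),
                     mask = label_mask(matrix(sample(0:1, 32^2, TRUE), 32))))
  model <- train_unet(train, sc)
  seg <- segment(model, image_volume(matrix(3.7, 32, 32)))
  interior <- seg$labels[13:20, 13:20]
  expect_equal(length(unique(as.vector(interior))), 1L)
})

test_that("model serialization preserves predictions", {
  train <- lapply(1:4, binary_pair)
  model <- train_unet(train, segnet_config(epochs = 2L, seed = 3L))
  p <- tempfile(fileext = ".json")
  write_model(model, p)
  m2 <- read_model(p)
  img <- binary_pair(60)$volume
  expect_equal(segment_probs(m2, img), segment_probs(model, img), tolerance = 1e-12)
  expect_identical(segment(m2, img)$labels, segment(model, img)$labels)
  unlink(p)
})
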