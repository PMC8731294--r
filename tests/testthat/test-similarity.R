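test_that("joint histogram satisfies its normalization invariants", {
  set.seed(21)
  A <- image_volume(matrix(runif(64^2, 0, 10), 64))
  B <- image_volume(matrix(runif(64^2, 0, 10), 64))
  h <- joint_histogram(A, B, bins = 16)
  expect_equal(sum(h$counts), h$n_samples)
  expect_equal(sum(h$p_ab), 1)
  expect_equal(rowSums(h$p_ab), h$p_a)
  expect_equal(colSums(h$p_ab), h$p_b)
  expect_error(joint_histogram(A, image_volume(matrix(0, 8, 8))), "same shape")
  expect_error(joint_histogram(A, B, bins = 1), "bins")
})

test_that("identical images concentrate the joint histogram on the diagonal", {
  set.seed(22)
  A <- image_volume(matrix(rnorm(32^2), 32))
  h <- joint_histogram(A, A, bins = 8)
  expect_equal(sum(diag(h$counts)), h$n_samples)
  expect_true(all(h$counts[upper.tri(h$counts)] == 0))
  expect_true(all(h$counts[lower.tri(h$counts)] == 0))
})

test_that("constant images occupy a single bin", {
  A <- image_volume(matrix(3, 16, 16))
  B <- image_volume(matrix(7, 16, 16))
  h <- joint_histogram(A, B, bins = 8)
  expect_equal(sum(h$counts > 0), 1)
  expect_equal(max(h$p_ab), 1)
})

test_that("checkerboard pair matches a brute-force voxel tally", {
  n <- 32
  xy <- expand.grid(x = 0:(n - 1), y = 0:(n - 1))
  A <- image_volume(matrix((xy$x + xy$y) %% 2, n))
  B <- image_volume(matrix(xy$x %% 2, n))
  h <- joint_histogram(A, B, bins = 2)
  # independent tally: loop over voxels, count the four intensity pairs
  tally <- matrix(0, 2, 2)
  for (i in seq_len(n * n)) {
    a <- A$data[i] + 1; b <- B$data[i] + 1
    tally[a, b] <- tally[a, b] + 1
  }
  expect_equal(h$counts, tally)
  expect_equal(as.vector(h$p_ab), rep(1 / 4, 4))
})

test_that("entropy matches closed forms and validates input", {
  expect_equal(shannon_entropy(c(1, 0, 0)), 0)
  expect_equal(shannon_entropy(rep(1 / 4, 4)), 2)
  expect_equal(shannon_entropy(rep(1 / 4, 4), base = exp(1)), log(4))
  set.seed(23)
  p <- runif(8); p <- p / sum(p)
  expect_equal(shannon_entropy(p), -sum(p * log2(p)), tolerance = 1e-12)
  expect_error(shannon_entropy(c(-0.1, 1.1)), "nonnegative")
  expect_error(shannon_entropy(c(0.5, 0.4)), "sum to 1")
})

test_that("MI identities: self-information, symmetry, bounds", {
  set.seed(24)
  for (rep in 1:5) {
    A <- image_volume(matrix(rnorm(32^2), 32))
    B <- image_volume(matrix(rnorm(32^2) + 0.5 * A$data, 32))
    miAB <- mutual_information(A, B, bins = 16)
    miBA <- mutual_information(B, A, bins = 16)
    expect_equal(as.numeric(miAB), as.numeric(miBA), tolerance = 1e-12)
    ent <- attr(miAB, "entropies")
    expect_gte(as.numeric(miAB), -1e-12)
    expect_lte(as.numeric(miAB), min(ent["K_A"], ent["K_B"]) + 1e-12)
    miAA <- mutual_information(A, A, bins = 16)
    expect_equal(as.numeric(miAA), unname(attr(miAA, "entropies")["K_A"]),
                 tolerance = 1e-12)
  }
})

test_that("MI of independent noise is within the small-sample bias bound", {
  set.seed(25)
  bins <- 32
  A <- image_volume(array(rnorm(64 * 64 * 16), c(64, 64, 16)))
  B <- image_volume(array(rnorm(64 * 64 * 16), c(64, 64, 16)))
  n <- length(A$data)
  bias_bound <- 2 * (bins - 1)^2 / (2 * n * log(2))
  expect_lt(as.numeric(mutual_information(A, B, bins = bins)), bias_bound)
})

test_that("MI is invariant to permuting histogram bins", {
  set.seed(26)
  A <- image_volume(matrix(runif(32^2), 32))
  B <- image_volume(matrix(runif(32^2), 32))
  h <- joint_histogram(A, B, bins = 8)
  mi0 <- as.numeric(mutual_information_from_histogram(h))
  perm_a <- sample(8); perm_b <- sample(8)
  hp <- h
  hp$counts <- h$counts[perm_a, perm_b]
  hp$p_ab <- h$p_ab[perm_a, perm_b]
  hp$p_a <- h$p_a[perm_a]
  hp$p_b <- h$p_b[perm_b]
  expect_equal(as.numeric(mutual_information_from_histogram(hp)), mi0,
               tolerance = 1e-12)
})

test_that("histogram TSV dump lists every occupied bin", {
  A <- image_volume(matrix(1:16, 4))
  h <- joint_histogram(A, A, bins = 4)
  p <- tempfile(fileext = ".tsv")
  write_histogram_tsv(h, p)
  df <- read.delim(p)
  expect_equal(sum(df$count), h$n_samples)
  expect_equal(nrow(df), sum(h$counts > 0))
  unlink(p)
})
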