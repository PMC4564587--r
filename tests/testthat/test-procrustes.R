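test_that("centroid size matches its defining formula", {
  sq <- landmark_config("sq", rbind(c(.5, .5, 0), c(.5, -.5, 0),
                                    c(-.5, .5, 0), c(-.5, -.5, 0)))
  expect_equal(centroid_size(sq), sqrt(2))
  expect_equal(centroid_size(matrix(1, 4, 3)), 0)
  set.seed(10)
  xyz <- matrix(rnorm(44 * 3), 44, 3)
  ctr <- colMeans(xyz)
  oracle <- sqrt(sum(apply(xyz, 1, function(p) sum((p - ctr)^2))))
  expect_equal(centroid_size(xyz), oracle, tolerance = 1e-12)
  cf <- landmark_config("m", xyz, present = c(FALSE, rep(TRUE, 43)))
  expect_equal(centroid_size(cf), centroid_size(xyz[-1, ]))
})

test_that("ordinary Procrustes alignment is similarity-invariant and chiral", {
  set.seed(11)
  x <- matrix(rnorm(30), 10, 3)
  copy <- rand_similarity(x)
  expect_lt(opa_align(copy, x)$distance, 1e-9)
  mirror <- x %*% diag(c(-1, 1, 1))
  expect_gt(opa_align(mirror, x)$distance, 0.1)  # reflections disallowed
  expect_error(opa_align(matrix(rnorm(6), 2, 3), matrix(rnorm(6), 2, 3)),
               "3 landmarks")
  collinear <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(opa_align(collinear, matrix(rnorm(15), 5, 3)), "collinear")
})

test_that("alignment distance matches a brute-force rotation-grid oracle on planar shapes", {
  set.seed(12)
  for (rep in 1:3) {
    x <- cbind(matrix(rnorm(10), 5, 2), 0)
    y <- cbind(matrix(rnorm(10), 5, 2), 0)
    expect_equal(opa_align(y, x)$distance, planar_opa_oracle(x, y),
                 tolerance = 1e-4)
  }
})

test_that("procrustes distance is a metric and agrees with vegan's symmetric fit", {
  set.seed(13)
  shapes <- replicate(6, matrix(rnorm(24), 8, 3), simplify = FALSE)
  for (i in 1:5) {
    a <- shapes[[i]]; b <- shapes[[i + 1]]
    expect_equal(procrustes_distance(a, b), procrustes_distance(b, a),
                 tolerance = 1e-12)
  }
  expect_equal(procrustes_distance(shapes[[1]], shapes[[1]]), 0, tolerance = 1e-12)
  for (i in 1:4) {
    d_ab <- procrustes_distance(shapes[[i]], shapes[[i + 1]])
    d_bc <- procrustes_distance(shapes[[i + 1]], shapes[[i + 2]])
    d_ac <- procrustes_distance(shapes[[i]], shapes[[i + 2]])
    expect_lte(d_ac, d_ab + d_bc + 1e-9)
  }
  # independent implementation check (vegan allows reflection, so compare
  # only when its solution is a proper rotation)
  cs <- function(m) { m <- sweep(m, 2, colMeans(m)); m / sqrt(sum(m^2)) }
  for (i in 1:3) {
    a <- cs(shapes[[i]]); b <- cs(shapes[[i + 1]])
    v <- vegan::procrustes(a, b, scale = FALSE)
    if (abs(det(v$rotation) - 1) < 1e-8)
      expect_equal(procrustes_distance(a, b),
                   sqrt(sum((v$X - v$Yrot)^2)), tolerance = 1e-6)
  }
})

test_that("GPA recovers exact fits and is invariant to input order and similarity transforms", {
  set.seed(14)
  base <- matrix(rnorm(36), 12, 3)
  copies <- lapply(1:5, function(i)
    landmark_config(paste0("c", i), rand_similarity(base)))
  fit <- gpa(copies)
  expect_true(fit$converged)
  resid <- apply(fit$coords, 3, function(m) sqrt(sum((m - fit$mean_shape)^2)))
  expect_lt(max(resid), 1e-8)

  # two distinct shapes: consensus is equidistant from both
  two <- list(landmark_config("a", matrix(rnorm(36), 12, 3)),
              landmark_config("b", matrix(rnorm(36), 12, 3)))
  f2 <- gpa(two)
  d <- apply(f2$coords, 3, function(m) procrustes_distance(f2$mean_shape, m))
  expect_equal(d[1], d[2], tolerance = 1e-9, ignore_attr = TRUE)

  # order invariance: means agree up to rotation (a coherent sample —
  # with unrelated shapes the consensus itself is weakly determined)
  core <- matrix(rnorm(27), 9, 3)
  sample6 <- lapply(1:6, function(i)
    landmark_config(paste0("s", i),
                    rand_similarity(core + matrix(rnorm(27, sd = .1), 9, 3))))
  m1 <- gpa(sample6)$mean_shape
  m2 <- gpa(rev(sample6))$mean_shape
  expect_lt(procrustes_distance(m1, m2), 1e-8)

  # similarity transform of any input leaves aligned inter-specimen
  # distances unchanged
  f_ref <- gpa(sample6)
  perturbed <- sample6
  perturbed[[3]]$coords <- rand_similarity(perturbed[[3]]$coords)
  f_pert <- gpa(perturbed)
  expect_lt(max(abs(aligned_pairwise(f_ref) - aligned_pairwise(f_pert))), 1e-8)
})

test_that("GPA output satisfies centering, scaling and consensus identities", {
  set.seed(15)
  sample8 <- lapply(1:8, function(i) rand_config(paste0("s", i), K = 11))
  fit <- gpa(sample8)
  cs <- apply(fit$coords, 3, function(m) sqrt(sum(m^2)))
  expect_lt(max(abs(cs - 1)), 1e-9)
  ctr <- apply(fit$coords, 3, colMeans)
  expect_lt(max(abs(ctr)), 1e-9)
  # sum of aligned coordinates = n * mean (mean recomputed pre-normalization)
  avg <- apply(fit$coords, c(1, 2), mean)
  expect_lt(procrustes_distance(avg / sqrt(sum(avg^2)), fit$mean_shape), 1e-8)
  expect_equal(sqrt(sum(fit$mean_shape^2)), 1, tolerance = 1e-9)
})

test_that("repeatability test behaves at both extremes", {
  set.seed(16)
  base <- matrix(rnorm(27), 9, 3)
  trials <- lapply(1:5, function(i)
    landmark_config(paste0("t", i),
                    rand_similarity(base + matrix(rnorm(27, sd = 0.01), 9, 3))))
  same <- repeatability_test(trials, trials)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  noisy <- lapply(1:5, function(i)
    landmark_config(paste0("n", i),
                    rand_similarity(base + matrix(rnorm(27, sd = 0.4), 9, 3))))
  off <- repeatability_test(trials, noisy)
  expect_lt(off$p, 0.05)
  expect_gte(off$p, 0)
  expect_lte(off$p, 1)
  expect_error(repeatability_test(trials[1], noisy[1]), "2 trial pairs")
})
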