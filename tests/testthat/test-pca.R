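make_fit <- function(n = 12, K = 9, seed = 20) {
  set.seed(seed)
  base <- matrix(rnorm(K * 3), K, 3)
  gpa(lapply(seq_len(n), function(i)
    landmark_config(paste0("s", i),
                    rand_similarity(base + matrix(rnorm(K * 3, sd = .05), K, 3)),
                    population = c("A", "B")[1 + i %% 2], age_category = "AC2")))
}

test_that("score space is an isometric image of aligned shape space", {
  fit <- make_fit()
  pca <- fit_pca(fit)
  d_scores <- as.matrix(dist(pca$scores))
  expect_lt(max(abs(d_scores - aligned_pairwise(fit))), 1e-8)
  expect_equal(sum(pca$variance_fractions), 1, tolerance = 1e-9)
  expect_true(all(diff(pca$variance_fractions) <= 1e-12))
  expect_lt(max(abs(colMeans(pca$scores))), 1e-9)
  expect_lt(max(abs(crossprod(pca$rotation) - diag(ncol(pca$rotation)))), 1e-9)
})

test_that("full-rank reconstruction reproduces every aligned specimen", {
  fit <- make_fit(n = 8)
  pca <- fit_pca(fit)
  X <- pca$scores %*% t(pca$rotation)
  for (i in 1:8) {
    rec <- sweep(matrix(X[i, ], ncol = 3, byrow = TRUE), 2, 0)
    obs <- fit$coords[, , i]
    grand <- apply(fit$coords, c(1, 2), mean)
    expect_lt(max(abs((grand + rec) - obs)), 1e-8)
  }
})

test_that("a planted dominant direction is recovered as PC1", {
  set.seed(21)
  K <- 10
  base <- matrix(rnorm(K * 3), K, 3)
  # construct a genuine shape-space direction: the aligned difference
  # between two superimposed shapes has no translation/rotation component
  ali <- opa_align(base + matrix(rnorm(K * 3, sd = .3), K, 3), base)
  dir <- ali$aligned - ali$reference
  dir <- dir / sqrt(sum(dir^2))
  configs <- lapply(1:20, function(i)
    landmark_config(paste0("s", i),
                    rand_similarity(ali$reference + rnorm(1, sd = 0.05) * dir +
                                      matrix(rnorm(K * 3, sd = 1e-4), K, 3))))
  fit <- gpa(configs)
  pca <- fit_pca(fit)
  # transport the planted direction into the consensus frame of the fit
  a0 <- opa_align(ali$reference, fit$mean_shape)$aligned
  a1 <- opa_align(ali$reference + 1e-3 * dir, fit$mean_shape)$aligned
  v <- as.numeric(t(a1 - a0))
  cos_sim <- abs(sum(pca$rotation[, 1] * v)) / sqrt(sum(v^2))
  expect_gt(cos_sim, 0.99)
  expect_gt(pca$variance_fractions[1], 0.9)
  expect_equal(major_pcs(pca), 1L)
})

test_that("PC-score regressions recover planted linear structure", {
  fit <- make_fit(n = 30, seed = 22)
  pca <- fit_pca(fit)
  ages <- pca$scores[, 1] / 0.3  # scores exactly linear in covariate
  res <- regress_pc(pca, ages, 1)
  expect_equal(res$r, 1, tolerance = 1e-9)
  expect_lt(res$p, 1e-20)
  expect_equal(res$slope, 0.3, tolerance = 1e-9)

  set.seed(23)
  age2 <- runif(30, 2, 20)
  noisy <- 0.3 * age2 + rnorm(30, sd = 0.5)
  pca2 <- pca
  pca2$scores[, 2] <- noisy - mean(noisy)
  res2 <- regress_pc(pca2, age2, 2)
  se <- sqrt(sum(residuals(lm(noisy ~ age2))^2) / 28 / sum((age2 - mean(age2))^2))
  expect_lt(abs(res2$slope - 0.3), 2 * se)
  expect_error(regress_pc(pca, rep(1, 30), 1), "constant")
  expect_error(regress_pc(pca, ages, 99), "out of range")
})

test_that("null regressions reject at the nominal rate", {
  fit <- make_fit(n = 25, seed = 24)
  pca <- fit_pca(fit)
  set.seed(24)
  p_vals <- replicate(600, regress_pc(pca, rnorm(25), 1)$p)
  fp <- mean(p_vals < 0.05)
  expect_gt(fp, 0.025)
  expect_lt(fp, 0.08)
})

test_that("per-population significance tables flag only meaningful components", {
  fit <- make_fit(n = 40, seed = 25)
  pca <- fit_pca(fit)
  ages <- age_years(sample(c("AC1", "AC2", "AC3"), 40, TRUE))
  tab <- significant_pc_table(pca, ages, log(fit$centroid_sizes), max_pc = 3)
  expect_setequal(unique(tab$scope), c("ALL", "A", "B"))
  expect_setequal(unique(tab$covariate), c("numeric_age", "log_centroid_size"))
  expect_equal(nrow(tab), 6)
})

test_that("morphing along a component is linear and round-trips through scores", {
  fit <- make_fit(seed = 26)
  pca <- fit_pca(fit)
  expect_equal(morph_along_pc(pca, 1, 0), pca$mean_shape, ignore_attr = TRUE)
  plus <- morph_along_pc(pca, 2, 0.1)
  minus <- morph_along_pc(pca, 2, -0.1)
  expect_equal(plus + minus, 2 * pca$mean_shape, tolerance = 1e-12,
               ignore_attr = TRUE)
  # project the morph back: score s on the morphed axis, 0 elsewhere
  grand <- apply(fit$coords, c(1, 2), mean)
  resid <- as.numeric(t(morph_along_pc(pca, 2, 0.1))) -
    as.numeric(t(grand)) - (as.numeric(t(pca$mean_shape - grand)))
  back <- crossprod(pca$rotation, resid)
  expect_equal(back[2], 0.1, tolerance = 1e-8)
  expect_lt(max(abs(back[-2])), 1e-8)
})

test_that("wireframes round-trip through OBJ-style text", {
  set.seed(27)
  shape <- matrix(rnorm(9), 3, 3)
  path <- withr::local_tempfile(fileext = ".obj")
  export_wireframe(shape, rbind(c(1, 2), c(2, 3)), path)
  lines <- readLines(path)
  expect_equal(sum(startsWith(lines, "v ")), 3)
  expect_equal(sum(startsWith(lines, "l ")), 2)
  back <- read_wireframe(path)
  expect_equal(back$vertices, shape, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back$edges, rbind(c(1L, 2L), c(2L, 3L)), ignore_attr = TRUE)
  export_wireframe(shape, NULL, path)
  expect_equal(nrow(read_wireframe(path)$edges), 0)
  expect_error(export_wireframe(shape, rbind(c(1, 9)), path), "out of range")
})
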