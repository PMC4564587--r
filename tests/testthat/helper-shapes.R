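# Shared generators and independent oracles for the suite.

# random non-degenerate configuration
rand_config <- function(id = "s1", K = 10, pop = NA_character_, age = "AC2",
                        sd = 1) {
  landmark_config(id, matrix(rnorm(K * 3, sd = sd), K, 3),
                  population = pop, age_category = age)
}

# random similarity transform of a coordinate matrix
rand_similarity <- function(xyz) {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  s <- exp(rnorm(1))
  sweep(s * xyz %*% q, 2, runif(3, -50, 50), `+`)
}

# small two-population sample of configs around a template
two_group_sample <- function(n_per = 8, K = 8, offset = 0, noise = 0.02,
                             template = NULL) {
  if (is.null(template)) template <- matrix(rnorm(K * 3), K, 3)
  template <- template / centroid_size(template)
  delta <- matrix(rnorm(K * 3), K, 3)
  delta <- delta - rep(colMeans(delta), each = K)
  delta <- delta / sqrt(sum(delta^2))
  lapply(seq_len(2 * n_per), function(i) {
    grp <- if (i <= n_per) "A" else "B"
    shift <- if (grp == "B") offset * delta else 0
    landmark_config(paste0("s", i),
                    rand_similarity(template + shift +
                                      matrix(rnorm(K * 3, sd = noise), K, 3)),
                    population = grp, age_category = "AC2")
  })
}

# Euclidean distances between aligned specimens (rows of flattened coords)
aligned_pairwise <- function(fit) {
  n <- dim(fit$coords)[3]
  X <- t(vapply(seq_len(n), function(i) as.numeric(fit$coords[, , i]),
                numeric(prod(dim(fit$coords)[1:2]))))
  as.matrix(dist(X))
}

# Brute-force OPA oracle for planar (z = 0) configurations: minimize over a
# fine grid of in-plane rotations, with and without an in-plane reflection
# (realizable as a proper 3D rotation for planar shapes).
planar_opa_oracle <- function(x, y, n_grid = 20000) {
  cs <- function(m) { m <- sweep(m, 2, colMeans(m)); m / sqrt(sum(m^2)) }
  x <- cs(x); y <- cs(y)
  best <- Inf
  for (flip in c(FALSE, TRUE)) {
    yy <- y
    if (flip) yy[, 2] <- -yy[, 2]
    for (th in seq(0, 2 * pi, length.out = n_grid)) {
      R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
      best <- min(best, sqrt(sum((x - yy %*% R)^2)))
    }
  }
  best
}

# random symmetric nonnegative zero-diagonal matrix (for Mantel nulls)
rand_dist_matrix <- function(n, labels = paste0("P", seq_len(n))) {
  p <- matrix(runif(n * 3), n)
  dist_matrix(as.matrix(dist(p)), labels = labels)
}
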