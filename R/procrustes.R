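#' Centroid size of a configuration
#'
#' The standard geometric-morphometric size measure: the square root of the
#' summed squared distances of the (present) landmarks from their centroid.
#'
#' @param config a [landmark_config], or a bare K x 3 coordinate matrix.
#' @return positive scalar (0 for fully coincident landmarks).
#' @export
centroid_size <- function(config) {
  xyz <- if (inherits(config, "landmark_config")) {
    if (!any(config$present)) stop("all landmarks missing: ", config$specimen_id)
    config$coords[config$present, , drop = FALSE]
  } else as.matrix(config)
  ctr <- colMeans(xyz)
  sqrt(sum(sweep(xyz, 2, ctr)^2))
}

center_scale <- function(xyz, tol = 1e-12) {
  xyz <- sweep(xyz, 2, colMeans(xyz))
  cs <- sqrt(sum(xyz^2))
  if (cs < tol) stop("degenerate configuration: zero centroid size")
  if (qr(xyz)$rank < 2L)
    stop("degenerate configuration: landmarks are collinear")
  xyz / cs
}

# Optimal rotation of (centered, scaled) y onto x, reflection disallowed.
optimal_rotation <- function(x, y) {
  s <- svd(crossprod(x, y))
  d <- sign(det(s$v %*% t(s$u)))
  s$v %*% diag(c(1, 1, d)) %*% t(s$u)
}

#' Ordinary Procrustes alignment of one configuration onto another
#'
#' Both configurations are centered and scaled to unit centroid size; the
#' moving one is then rotated onto the reference by the singular-value
#' solution with the determinant forced to +1 (reflections are never
#' allowed: left/right anatomy must not flip).
#'
#' @param moving,reference `landmark_config` objects or K x 3 matrices with
#'   the same landmarks in the same order, both complete.
#' @return list with `aligned` (the moving configuration after alignment),
#'   `reference` (centered/scaled), and `distance` (root summed squared
#'   landmark differences of the aligned pair).
#' @export
opa_align <- function(moving, reference) {
  get_xyz <- function(cf) {
    if (inherits(cf, "landmark_config")) {
      if (!all(cf$present)) stop("opa_align requires complete configurations")
      cf$coords
    } else as.matrix(cf)
  }
  x <- get_xyz(reference); y <- get_xyz(moving)
  if (!all(dim(x) == dim(y))) stop("configurations differ in landmark count")
  if (nrow(x) < 3L) stop("at least 3 landmarks are required")
  x <- center_scale(x); y <- center_scale(y)
  yr <- y %*% optimal_rotation(x, y)
  list(aligned = yr, reference = x, distance = sqrt(sum((x - yr)^2)))
}

#' Procrustes distance between two shapes
#'
#' Full optimal superimposition (translation, unit-size scaling, rotation
#' without reflection) of `shape_b` onto `shape_a`, then the root summed
#' squared landmark differences. Symmetric in its arguments.
#'
#' @param shape_a,shape_b K x 3 matrices or `landmark_config` objects.
#' @return nonnegative scalar.
#' @export
procrustes_distance <- function(shape_a, shape_b) {
  opa_align(shape_b, shape_a)$distance
}

#' Generalized Procrustes Analysis
#'
#' Iteratively superimposes a sample of configurations on their developing
#' consensus: all are centered and scaled to unit centroid size, rotated onto
#' the current mean, and the mean is recomputed and rescaled to unit size,
#' until the root summed squared change in the mean drops below `tol`.
#' This is the partial-Procrustes convention: specimens stay at unit centroid
#' size throughout (no secondary cosine rescaling).
#'
#' @param configs list of complete [landmark_config]s (or a K x 3 x n array).
#' @param tol convergence tolerance on the mean-shape change.
#' @param max_iter iteration cap.
#' @return an object of class `gpa_fit`: list with `coords` (K x 3 x n
#'   aligned, unit-centroid-size), `centroid_sizes` (original scale),
#'   `mean_shape` (unit centroid size), `info` (specimen metadata),
#'   `iterations`, `converged`.
#' @export
gpa <- function(configs, tol = 1e-10, max_iter = 100L) {
  if (is.array(configs) && length(dim(configs)) == 3L) {
    arr <- configs
    info <- data.frame(specimen_id = dimnames(arr)[[3]] %||%
                         paste0("S", seq_len(dim(arr)[3])),
                       population = NA_character_, age_category = NA_character_,
                       stringsAsFactors = FALSE)
  } else {
    arr <- config_array(configs)
    info <- config_metadata(configs)
  }
  n <- dim(arr)[3]
  if (n < 2L) stop("GPA needs at least 2 configurations")
  cs <- apply(arr, 3, centroid_size)
  for (i in seq_len(n)) arr[, , i] <- center_scale(arr[, , i])
  mean_shape <- arr[, , 1]
  iter <- 0L; converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    for (i in seq_len(n))
      arr[, , i] <- arr[, , i] %*% optimal_rotation(mean_shape, arr[, , i])
    new_mean <- apply(arr, c(1, 2), mean)
    new_mean <- new_mean / sqrt(sum(new_mean^2))
    delta <- sqrt(sum((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    if (delta < tol) { converged <- TRUE; break }
  }
  structure(list(coords = arr, centroid_sizes = cs, mean_shape = mean_shape,
                 info = info, iterations = iter, converged = converged),
            class = "gpa_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.gpa_fit <- function(x, ...) {
  cat(sprintf("<gpa_fit> %d specimens, %d landmarks; %d iterations (%s)\n",
              dim(x$coords)[3], dim(x$coords)[1], x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

# flatten aligned array to n x 3K (landmark-major: x1 y1 z1 x2 ...)
flatten_coords <- function(arr) {
  n <- dim(arr)[3]
  t(vapply(seq_len(n), function(i) as.numeric(t(arr[, , i])),
           numeric(prod(dim(arr)[1:2]))))
}

unflatten_coords <- function(v) matrix(v, ncol = 3, byrow = TRUE,
                                       dimnames = list(NULL, c("x", "y", "z")))

#' Digitizing repeatability check
#'
#' The same specimen digitized repeatedly in two trial sets is superimposed
#' jointly; each trial's root-mean-square Procrustes residual from the joint
#' consensus is computed, and the two sets of residuals are compared with a
#' paired t-test. A nonsignificant result indicates digitizing error is
#' negligible relative to the consensus.
#'
#' @param trials_a,trials_b equal-length lists of `landmark_config`s of the
#'   same specimen (pairing by position).
#' @return list with `t`, `p` (two-sided), `df`, and per-trial `rms_a`,
#'   `rms_b`.
#' @export
repeatability_test <- function(trials_a, trials_b) {
  if (length(trials_a) != length(trials_b)) stop("trial sets must pair up")
  if (length(trials_a) < 2L) stop("at least 2 trial pairs are required")
  fit <- gpa(c(trials_a, trials_b))
  K <- dim(fit$coords)[1]
  rms <- apply(fit$coords, 3, function(m) sqrt(sum((m - fit$mean_shape)^2) / K))
  na <- length(trials_a)
  rms_a <- rms[seq_len(na)]; rms_b <- rms[na + seq_len(na)]
  d <- rms_a - rms_b
  if (all(abs(d) < 1e-15)) {
    t_stat <- 0; p <- 1
  } else {
    ht <- stats::t.test(rms_a, rms_b, paired = TRUE)
    t_stat <- unname(ht$statistic); p <- ht$p.value
  }
  list(t = t_stat, p = p, df = na - 1L, rms_a = rms_a, rms_b = rms_b)
}
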