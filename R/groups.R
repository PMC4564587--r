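group_mean_shapes <- function(arr, labels) {
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  means <- lapply(groups, function(g) {
    idx <- which(labels == g)
    if (!length(idx)) stop("empty group: ", g)
    m <- apply(arr[, , idx, drop = FALSE], c(1, 2), mean)
    m <- sweep(m, 2, colMeans(m))
    m / sqrt(sum(m^2))  # back to unit centroid size, stays in shape space
  })
  names(means) <- groups
  means
}

#' Pairwise Procrustes distances among population mean shapes
#'
#' Per-population means of the aligned coordinates, re-normalized to unit
#' centroid size, then full-superimposition Procrustes distance between each
#' pair of means.
#'
#' @param fit a [gpa] result.
#' @param labels group labels per specimen (default: populations from the
#'   fit's metadata).
#' @return a [dist_matrix] over the group labels.
#' @export
population_distance_matrix <- function(fit, labels = fit$info$population) {
  if (length(unique(labels)) < 2L) stop("need at least 2 groups")
  means <- group_mean_shapes(fit$coords, labels)
  g <- length(means)
  vals <- matrix(0, g, g)
  for (i in seq_len(g - 1)) for (j in (i + 1):g)
    vals[i, j] <- vals[j, i] <- procrustes_distance(means[[i]], means[[j]])
  dist_matrix(vals, labels = names(means))
}

#' Permutation significance of pairwise population distances
#'
#' For each pair of groups the specimens are pooled, group labels are
#' shuffled preserving group sizes, and the between-mean Procrustes distance
#' is recomputed; the one-sided p-value is
#' `(1 + #(permuted >= observed)) / (1 + n_perm)`.
#'
#' @param fit a [gpa] result.
#' @param labels group labels per specimen.
#' @param n_perm number of permutation replicates.
#' @param seed RNG seed (required for reproducibility).
#' @return list with `matrix` (observed [dist_matrix]), `p_values`
#'   (labeled matrix, `NA` diagonal), `n_perm`, `seed`.
#' @export
pairwise_permutation_test <- function(fit, labels = fit$info$population,
                                      n_perm = 1000L, seed) {
  if (n_perm < 1L) stop("n_perm must be at least 1")
  labels <- as.character(labels)
  sizes <- table(labels)
  if (any(sizes < 2L))
    stop("each group needs at least 2 specimens: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  obs <- population_distance_matrix(fit, labels)
  groups <- dm_labels(obs)
  g <- length(groups)
  pv <- matrix(NA_real_, g, g, dimnames = list(groups, groups))
  set.seed(seed)
  flat <- flatten_coords(fit$coords)  # n x 3K; group means by colMeans
  mean_dist <- function(X, rows_a, rows_b) {
    ma <- unflatten_coords(colMeans(X[rows_a, , drop = FALSE]))
    mb <- unflatten_coords(colMeans(X[rows_b, , drop = FALSE]))
    ma <- sweep(ma, 2, colMeans(ma)); ma <- ma / sqrt(sum(ma^2))
    mb <- sweep(mb, 2, colMeans(mb)); mb <- mb / sqrt(sum(mb^2))
    sqrt(sum((ma - mb %*% optimal_rotation(ma, mb))^2))
  }
  for (i in seq_len(g - 1)) for (j in (i + 1):g) {
    idx <- which(labels %in% c(groups[i], groups[j]))
    ni <- sum(labels == groups[i])
    X <- flat[idx, , drop = FALSE]
    d_obs <- obs[groups[i], groups[j]]
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      perm <- sample(length(idx))
      d_perm <- mean_dist(X, perm[seq_len(ni)], perm[-seq_len(ni)])
      if (d_perm >= d_obs) exceed <- exceed + 1L
    }
    pv[i, j] <- pv[j, i] <- (1 + exceed) / (1 + n_perm)
  }
  list(matrix = obs, p_values = pv, n_perm = as.integer(n_perm), seed = seed)
}

#' Leave-one-out cross-validated discriminant classification
#'
#' Linear discriminant analysis (pooled within-group covariance) on PC
#' scores, evaluated by leave-one-out cross-validation: each specimen is
#' classified by a discriminant fit to all others. The component basis is
#' computed once on the full sample (scores are taken as given, as when a
#' discriminant analysis consumes precomputed PC scores), which is a known
#' mild leakage documented in the methods vignette. Groups with a single
#' specimen are excluded with a warning. Score columns with (near) zero
#' pooled variance are dropped before fitting.
#'
#' @param scores n x m numeric matrix of PC scores (or a `shape_pca`).
#' @param labels group labels per row.
#' @param n_components number of leading score columns to use; if `NULL`,
#'   the smallest number reaching `variance_threshold` cumulative variance
#'   (requires a `shape_pca`), capped at `n - g - 1`.
#' @param variance_threshold cumulative variance target used when
#'   `n_components` is `NULL` and a `shape_pca` is supplied.
#' @return an object of class `confusion_matrix`: `labels`, `counts` (g x g,
#'   rows = true), `per_group_pct`, `overall_pct`, `n_components`.
#' @export
lda_loocv <- function(scores, labels, n_components = NULL,
                      variance_threshold = 0.95) {
  pca <- NULL
  if (inherits(scores, "shape_pca")) {
    pca <- scores
    if (missing(labels)) labels <- pca$info$population
    scores <- pca$scores
  }
  labels <- as.character(labels)
  sizes <- table(labels)
  if (any(sizes < 2L)) {
    warning("excluding singleton group(s): ",
            paste(names(sizes)[sizes < 2], collapse = ", "))
    keep <- labels %in% names(sizes)[sizes >= 2L]
    scores <- scores[keep, , drop = FALSE]
    labels <- labels[keep]
  }
  g <- length(unique(labels))
  if (g < 2L) stop("need at least 2 groups with 2+ specimens")
  n <- nrow(scores)
  if (is.null(n_components)) {
    n_components <- if (!is.null(pca))
      which(cumsum(pca$variance_fractions) >= variance_threshold)[1]
    else ncol(scores)
    if (is.na(n_components)) n_components <- ncol(scores)
  }
  n_components <- min(n_components, ncol(scores), n - g - 1L)
  if (n_components < 1L) stop("sample too small for any discriminant axis")
  X <- scores[, seq_len(n_components), drop = FALSE]
  keep_col <- apply(X, 2, stats::sd) > 1e-12
  X <- X[, keep_col, drop = FALSE]
  fit <- MASS::lda(X, grouping = factor(labels), CV = TRUE)
  pred <- as.character(fit$class)
  groups <- sort(unique(labels))
  counts <- table(factor(labels, groups), factor(pred, groups))
  counts <- matrix(as.integer(counts), g, g, dimnames = list(groups, groups))
  per_group <- 100 * diag(counts) / rowSums(counts)
  structure(list(labels = groups, counts = counts,
                 per_group_pct = per_group,
                 overall_pct = 100 * sum(diag(counts)) / n,
                 n_components = ncol(X)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  df <- data.frame(`% Correct` = round(x$per_group_pct, 1), x$counts,
                   Total = rowSums(x$counts), check.names = FALSE)
  print(df)
  cat(sprintf("%.1f%% of cross-validated grouped cases correctly classified.\n",
              x$overall_pct))
  invisible(x)
}

#' Write a confusion matrix as tabular text
#'
#' Layout: per-group % correct first, then counts by predicted group, then
#' row totals.
#'
#' @param cm a `confusion_matrix`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_confusion <- function(cm, path) {
  df <- data.frame(group = cm$labels,
                   pct_correct = round(cm$per_group_pct, 1),
                   cm$counts, Total = rowSums(cm$counts),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
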