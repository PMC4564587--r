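#' Principal components of aligned shape
#'
#' PCA of the flattened aligned coordinates about the consensus. The default
#' `projection = "procrustes_residuals"` takes the covariance of the aligned
#' coordinates directly (the usual practice after a Procrustes fit);
#' `"orthogonal_tangent"` first projects the residuals orthogonally to the
#' consensus direction, a strict tangent-space linearization. After a
#' similarity superimposition at most `min(n - 1, 3K - 7)` dimensions carry
#' variance (7 degrees of freedom are consumed by translation, scale and
#' rotation).
#'
#' @param fit a [gpa] result.
#' @param projection `"procrustes_residuals"` (default) or
#'   `"orthogonal_tangent"`.
#' @return an object of class `shape_pca`: `mean_shape`, `rotation`
#'   (3K x m orthonormal columns), `scores` (n x m, zero column means),
#'   `variance_fractions` (over retained components), `sdev`, `projection`,
#'   `info`.
#' @export
fit_pca <- function(fit, projection = c("procrustes_residuals", "orthogonal_tangent")) {
  projection <- match.arg(projection)
  n <- dim(fit$coords)[3]
  if (n < 3L) stop("PCA needs at least 3 specimens")
  K <- dim(fit$coords)[1]
  X <- flatten_coords(fit$coords)
  mu <- as.numeric(t(fit$mean_shape))
  R <- sweep(X, 2, colMeans(X))
  if (projection == "orthogonal_tangent") {
    u <- mu / sqrt(sum(mu^2))
    R <- R - tcrossprod(R %*% u, u)
  }
  pc <- stats::prcomp(R, center = TRUE, scale. = FALSE)
  m <- min(n - 1L, 3L * K - 7L)
  keep <- which(pc$sdev[seq_len(min(m, length(pc$sdev)))] > 1e-12 * pc$sdev[1])
  ev <- pc$sdev[keep]^2
  structure(list(mean_shape = fit$mean_shape,
                 rotation = pc$rotation[, keep, drop = FALSE],
                 scores = pc$x[, keep, drop = FALSE],
                 variance_fractions = ev / sum(pc$sdev^2),
                 sdev = pc$sdev[keep],
                 projection = projection,
                 info = fit$info),
            class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  vf <- round(100 * x$variance_fractions[seq_len(min(5, length(x$variance_fractions)))], 2)
  cat(sprintf("<shape_pca> %d specimens, %d components (%s); top var%%: %s\n",
              nrow(x$scores), ncol(x$scores), x$projection,
              paste(vf, collapse = ", ")))
  invisible(x)
}

#' Flag components above a variance threshold
#'
#' @param pca a `shape_pca`.
#' @param threshold fraction of total variance (default 0.05, the usual cut
#'   for wireframe visualization).
#' @return integer indices of components explaining more than `threshold`.
#' @export
major_pcs <- function(pca, threshold = 0.05) {
  which(pca$variance_fractions > threshold)
}

#' Regress a PC score on age or size
#'
#' Ordinary least squares of one component's scores on a specimen-level
#' covariate (numeric age for ontogeny, log centroid size for allometry),
#' optionally within a single population.
#'
#' @param pca a `shape_pca`.
#' @param covariate numeric vector, one value per specimen in `pca`.
#' @param pc_index which component.
#' @param scope `"ALL"` or one population label.
#' @param covariate_name label stored in the result.
#' @return list with `pc_index`, `covariate`, `scope`, `n`, `r` (Pearson),
#'   `p` (two-sided), `slope`, `intercept`; for scopes with fewer than 3
#'   specimens `r`/`p` are `NA` and `flag = "insufficient_n"`.
#' @export
regress_pc <- function(pca, covariate, pc_index, scope = "ALL",
                       covariate_name = deparse(substitute(covariate))) {
  if (pc_index < 1L || pc_index > ncol(pca$scores))
    stop("pc_index out of range")
  if (length(covariate) != nrow(pca$scores))
    stop("covariate length must match specimen count")
  sel <- if (identical(scope, "ALL")) rep(TRUE, nrow(pca$scores))
         else pca$info$population == scope
  y <- pca$scores[sel, pc_index]; x <- covariate[sel]
  out <- list(pc_index = pc_index, covariate = covariate_name, scope = scope,
              n = sum(sel), r = NA_real_, p = NA_real_,
              slope = NA_real_, intercept = NA_real_, flag = NA_character_)
  if (sum(sel) < 3L) { out$flag <- "insufficient_n"; return(out) }
  if (stats::sd(x) == 0) stop("covariate is constant within scope ", scope)
  fit <- stats::lm(y ~ x)
  ct <- stats::cor.test(x, y)
  out$r <- unname(ct$estimate)
  out$p <- ct$p.value
  out$slope <- unname(stats::coef(fit)[2])
  out$intercept <- unname(stats::coef(fit)[1])
  out
}

#' Table of PCs significantly associated with age and size
#'
#' For each population (and pooled) and each retained component, tests the
#' association of scores with numeric age and with log centroid size and
#' reports those with p below `alpha` — the summary layout used to describe
#' ontogenetic and allometric signal per cranial region.
#'
#' @param pca a `shape_pca`.
#' @param ages numeric ages per specimen.
#' @param log_cs log centroid sizes per specimen.
#' @param alpha significance threshold.
#' @param max_pc number of leading components to test.
#' @return data.frame with columns `scope`, `covariate`, `significant_pcs`.
#' @export
significant_pc_table <- function(pca, ages, log_cs, alpha = 0.05,
                                 max_pc = length(major_pcs(pca))) {
  max_pc <- max(1L, min(max_pc, ncol(pca$scores)))
  scopes <- c("ALL", sort(unique(pca$info$population)))
  scopes <- scopes[!is.na(scopes)]
  rows <- list()
  for (scope in scopes) for (cov_name in c("numeric_age", "log_centroid_size")) {
    cov <- if (cov_name == "numeric_age") ages else log_cs
    sig <- integer(0)
    for (j in seq_len(max_pc)) {
      res <- regress_pc(pca, cov, j, scope, covariate_name = cov_name)
      if (!is.na(res$p) && res$p < alpha) sig <- c(sig, j)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      scope = scope, covariate = cov_name,
      significant_pcs = paste(sig, collapse = ","),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Deform the consensus along one component
#'
#' Visualization primitive behind wireframe morphs: the consensus shape plus
#' `score` times the component's loading vector, folded back to K x 3.
#'
#' @param pca a `shape_pca`.
#' @param pc_index retained component index.
#' @param score displacement along the component, in score units.
#' @return K x 3 matrix.
#' @export
morph_along_pc <- function(pca, pc_index, score) {
  if (pc_index < 1L || pc_index > ncol(pca$rotation))
    stop("pc_index out of range")
  v <- as.numeric(t(pca$mean_shape)) + score * pca$rotation[, pc_index]
  out <- unflatten_coords(v)
  rownames(out) <- rownames(pca$mean_shape)
  out
}

#' Write / read a wireframe
#'
#' OBJ-style plain text: `v x y z` vertex records and `l i j` edge records.
#'
#' @param shape K x 3 matrix.
#' @param edges two-column integer matrix (or list of pairs) of 1-based
#'   landmark indices; may be empty.
#' @param path file path.
#' @return `export_wireframe`: `path` invisibly; `read_wireframe`: list with
#'   `vertices` and `edges`.
#' @export
export_wireframe <- function(shape, edges, path) {
  shape <- as.matrix(shape)
  if (is.list(edges)) edges <- do.call(rbind, edges)
  if (is.null(edges)) edges <- matrix(integer(0), 0, 2)
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) && (any(edges < 1) || any(edges > nrow(shape))))
    stop("edge index out of range")
  lines <- c(apply(shape, 1, function(r)
    paste("v", paste(format(r, digits = 15, scientific = FALSE, trim = TRUE),
                     collapse = " "))),
    if (nrow(edges)) paste("l", edges[, 1], edges[, 2]))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname export_wireframe
#' @export
read_wireframe <- function(path) {
  lines <- readLines(path)
  vs <- grep("^v ", lines, value = TRUE)
  ls <- grep("^l ", lines, value = TRUE)
  vertices <- t(vapply(strsplit(vs, "\\s+"),
                       function(f) as.numeric(f[2:4]), numeric(3)))
  colnames(vertices) <- c("x", "y", "z")
  edges <- if (length(ls))
    t(vapply(strsplit(ls, "\\s+"), function(f) as.integer(f[2:3]), integer(2)))
  else matrix(integer(0), 0, 2)
  list(vertices = vertices, edges = edges)
}
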