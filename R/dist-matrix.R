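#' Labeled symmetric distance matrix
#'
#' The common currency of the pipeline: population-level morphological
#' (Procrustes) and molecular (F_ST / Slatkin) distances are both square,
#' symmetric, zero-diagonal, nonnegative labeled matrices. The constructor
#' enforces those invariants on every construction path.
#'
#' @param values numeric n x n matrix.
#' @param labels character vector of n labels; defaults to the dimnames of
#'   `values`.
#' @param tol asymmetry tolerance.
#' @return an object of class `dist_matrix` (a labeled numeric matrix).
#' @export
dist_matrix <- function(values, labels = NULL, tol = 1e-9) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != ncol(values)) stop("distance matrix must be square")
  if (is.null(labels)) labels <- rownames(values)
  if (is.null(labels)) stop("labels are required")
  labels <- as.character(labels)
  if (length(labels) != nrow(values)) stop("label count does not match matrix")
  if (anyDuplicated(labels)) stop("duplicate labels: ",
                                  paste(labels[duplicated(labels)], collapse = ", "))
  if (any(!is.finite(values))) stop("distance matrix entries must be finite")
  if (max(abs(values - t(values))) > tol)
    stop("distance matrix is asymmetric beyond tolerance")
  values <- (values + t(values)) / 2
  if (any(values < 0)) stop("distance matrix entries must be nonnegative")
  diag(values) <- 0
  dimnames(values) <- list(labels, labels)
  structure(values, class = c("dist_matrix", "matrix", "array"))
}

#' @export
print.dist_matrix <- function(x, digits = 4, ...) {
  cat(sprintf("<dist_matrix> %d labels\n", nrow(x)))
  print(round(unclass(x), digits), ...)
  invisible(x)
}

dm_labels <- function(m) rownames(m)

# off-diagonal unordered pairs, in a fixed (column-major lower-triangle) order
dm_lower <- function(m) unclass(m)[lower.tri(m)]

#' Drop one population from a distance matrix
#'
#' Used by the exclusion sensitivity scan: removes a label's row and column.
#'
#' @param m a `dist_matrix`.
#' @param label label to remove.
#' @return a `dist_matrix` of size n-1.
#' @export
exclude_population <- function(m, label) {
  labs <- dm_labels(m)
  if (!label %in% labs)
    stop("label not present in matrix: ", label)
  keep <- labs != label
  dist_matrix(unclass(m)[keep, keep, drop = FALSE])
}

#' Read / write labeled distance matrices
#'
#' Plain-text format: a header line of n tab-separated labels (leading empty
#' field optional), then n rows of `label <tab> n values`. Row labels must
#' match the header order. `read_dist_matrix` enforces all `dist_matrix`
#' invariants (squareness, symmetry to 1e-9, nonnegativity).
#'
#' @param path file path.
#' @param m a `dist_matrix`.
#' @return `read_dist_matrix`: a `dist_matrix`; `write_dist_matrix`:
#'   `path`, invisibly.
#' @export
read_dist_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  head <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (!nzchar(head[1])) head <- head[-1]
  n <- length(head)
  if (length(lines) != n + 1L)
    stop(sprintf("expected %d data rows, found %d", n, length(lines) - 1L))
  vals <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    f <- strsplit(lines[[i + 1L]], "\t", fixed = TRUE)[[1]]
    if (length(f) != n + 1L || f[1] != head[i])
      stop("malformed or misordered matrix row: ", lines[[i + 1L]])
    vals[i, ] <- as.numeric(f[-1])
  }
  if (anyNA(vals)) stop("non-numeric entries in matrix body")
  dist_matrix(vals, labels = head)
}

#' @rdname read_dist_matrix
#' @export
write_dist_matrix <- function(m, path) {
  labs <- dm_labels(m)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("", labs), collapse = "\t"), con)
  body <- apply(unclass(m), 1, function(r)
    paste(format(r, digits = 15, scientific = FALSE, trim = TRUE), collapse = "\t"))
  writeLines(paste(labs, body, sep = "\t"), con)
  invisible(path)
}
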