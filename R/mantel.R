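all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 0L
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    idx <- row + seq_len(nrow(sub))
    out[idx, 1] <- k
    out[idx, -1] <- matrix(rest[sub], nrow(sub), n - 1L)
    row <- row + nrow(sub)
  }
  out
}

align_by_labels <- function(a, b) {
  la <- dm_labels(a); lb <- dm_labels(b)
  if (!setequal(la, lb))
    stop("label sets differ: only in first [",
         paste(setdiff(la, lb), collapse = ", "), "]; only in second [",
         paste(setdiff(lb, la), collapse = ", "), "]")
  ord <- match(la, lb)
  list(a = unclass(a), b = unclass(b)[ord, ord, drop = FALSE])
}

#' Mantel test between two labeled distance matrices
#'
#' Pearson correlation over the n(n-1)/2 unordered off-diagonal pairs, with
#' a permutation null obtained by relabeling one matrix (simultaneous row
#' and column shuffle). Matrices are reconciled by label, never by position.
#' For n <= 8 the null is the exact enumeration of all n! relabelings
#' (fully deterministic: 5040 statistics at n = 7, 720 at n = 6); otherwise
#' a Monte-Carlo null with the add-one correction is used. Both tail
#' p-values are always recorded; `tail` selects which is reported as `p`.
#'
#' @param morph,mol two [dist_matrix] objects with identical label sets.
#' @param tail `"upper"` (default; large positive correlation is evidence of
#'   concordance), `"lower"`, or `"two_sided"`.
#' @param n_perm Monte-Carlo replicates (ignored when the exact null is used).
#' @param seed RNG seed for the Monte-Carlo null.
#' @param exact force (`TRUE`) or forbid (`FALSE`) exact enumeration;
#'   default: exact whenever n <= 8.
#' @return an object of class `mantel_result`: `r`, `p`, `p_upper`,
#'   `p_lower`, `p_two_sided`, `method`, `n_perm`, `seed`, `n_labels`,
#'   `tail`.
#' @export
mantel_test <- function(morph, mol, tail = c("upper", "lower", "two_sided"),
                        n_perm = 9999L, seed = NULL, exact = NULL) {
  tail <- match.arg(tail)
  al <- align_by_labels(morph, mol)
  n <- nrow(al$a)
  if (n < 4L) stop("Mantel test needs at least 4 labels")
  lt <- lower.tri(al$a)
  x <- al$a[lt]; y <- al$b[lt]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant off-diagonal distances: correlation undefined")
  r_obs <- stats::cor(x, y)
  if (is.null(exact)) exact <- factorial(n) <= 50000
  if (exact && factorial(n) > 50000)
    stop("exact enumeration limited to n <= 8 labels")
  perm_r <- if (exact) {
    perms <- all_permutations(n)
    vapply(seq_len(nrow(perms)), function(i) {
      p <- perms[i, ]
      stats::cor(al$a[p, p][lt], y)
    }, numeric(1))
  } else {
    if (n_perm < 1L) stop("n_perm must be positive")
    if (!is.null(seed)) set.seed(seed)
    vapply(seq_len(n_perm), function(i) {
      p <- sample(n)
      stats::cor(al$a[p, p][lt], y)
    }, numeric(1))
  }
  if (exact) {
    m <- length(perm_r)
    p_up <- sum(perm_r >= r_obs - 1e-12) / m
    p_lo <- sum(perm_r <= r_obs + 1e-12) / m
    p_two <- sum(abs(perm_r) >= abs(r_obs) - 1e-12) / m
  } else {
    p_up <- (1 + sum(perm_r >= r_obs - 1e-12)) / (1 + n_perm)
    p_lo <- (1 + sum(perm_r <= r_obs + 1e-12)) / (1 + n_perm)
    p_two <- (1 + sum(abs(perm_r) >= abs(r_obs) - 1e-12)) / (1 + n_perm)
  }
  p <- switch(tail, upper = p_up, lower = p_lo, two_sided = p_two)
  structure(list(r = r_obs, p = p, p_upper = p_up, p_lower = p_lo,
                 p_two_sided = p_two,
                 method = if (exact) "exact_enumeration" else "monte_carlo",
                 n_perm = if (exact) length(perm_r) else as.integer(n_perm),
                 seed = seed, n_labels = n, tail = tail),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("<mantel_result> r = %.4f, p(%s) = %.4g  [%s, %d permutations, n = %d]\n",
              x$r, x$tail, x$p, x$method, x$n_perm, x$n_labels))
  invisible(x)
}

#' Population-exclusion sensitivity scan
#'
#' Repeats the Mantel test after dropping each population in turn (plus the
#' all-populations baseline), to reveal whether concordance is driven or
#' masked by a single population.
#'
#' @param morph,mol two [dist_matrix] objects with identical label sets,
#'   n >= 5.
#' @param tail,n_perm,seed passed to [mantel_test].
#' @return data.frame with columns `excluded` (`"none"` first), `n`, `r`,
#'   `p`, `p_upper`, `p_lower`, `method`.
#' @export
exclusion_scan <- function(morph, mol, tail = "upper", n_perm = 9999L,
                           seed = NULL) {
  labs <- dm_labels(morph)
  if (length(labs) < 5L) stop("exclusion scan needs at least 5 labels")
  one <- function(excl) {
    m1 <- if (is.na(excl)) morph else exclude_population(morph, excl)
    m2 <- if (is.na(excl)) mol else exclude_population(mol, excl)
    res <- mantel_test(m1, m2, tail = tail, n_perm = n_perm, seed = seed)
    data.frame(excluded = ifelse(is.na(excl), "none", excl),
               n = res$n_labels, r = res$r, p = res$p,
               p_upper = res$p_upper, p_lower = res$p_lower,
               method = res$method, stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(c(NA_character_, labs), one))
}

#' Concordance report across conventions
#'
#' Runs the Mantel test of each morphological matrix against the molecular
#' matrix under both the raw and the Slatkin-linearized molecular distances,
#' reporting the statistic with both tail p-values. This is the diagnostic
#' layout used when checking published correlation values whose exact
#' computational convention is uncertain.
#'
#' @param morph_list named list of morphological [dist_matrix] objects.
#' @param mol molecular [dist_matrix].
#' @param exclude optional label excluded from every matrix first.
#' @return data.frame with one row per (dataset x molecular variant).
#' @export
mantel_report <- function(morph_list, mol, exclude = NULL) {
  if (!is.null(exclude)) {
    mol <- exclude_population(mol, exclude)
    morph_list <- lapply(morph_list, exclude_population, label = exclude)
  }
  variants <- list(fst = mol, slatkin = slatkin_linearize(mol))
  rows <- list()
  for (nm in names(morph_list)) for (v in names(variants)) {
    res <- mantel_test(morph_list[[nm]], variants[[v]])
    rows[[length(rows) + 1L]] <- data.frame(
      dataset = nm, molecular = v, n = res$n_labels,
      r = res$r, p_upper = res$p_upper, p_lower = res$p_lower,
      method = res$method, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
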