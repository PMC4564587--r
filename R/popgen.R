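# Weir-Cockerham variance components for one locus, two-or-more populations.
# a1/a2: allele-size vectors for the individuals typed at this locus;
# pop: integer population index per individual.
wc_components_locus <- function(a1, a2, pop) {
  r <- length(unique(pop))
  ni <- as.numeric(table(factor(pop, sort(unique(pop)))))
  nbar <- mean(ni)
  nsum <- sum(ni)
  nc <- (nsum - sum(ni^2) / nsum) / (r - 1)
  alleles <- sort(unique(c(a1, a2)))
  pops <- sort(unique(pop))
  A <- 0; B <- 0; C <- 0
  for (al in alleles) {
    # per-population frequency and heterozygote proportion for this allele
    p_i <- h_i <- numeric(r)
    for (k in seq_len(r)) {
      sel <- pop == pops[k]
      p_i[k] <- (sum(a1[sel] == al) + sum(a2[sel] == al)) / (2 * ni[k])
      h_i[k] <- sum((a1[sel] == al) != (a2[sel] == al)) / ni[k]
    }
    pbar <- sum(ni * p_i) / nsum
    hbar <- sum(ni * h_i) / nsum
    s2 <- sum(ni * (p_i - pbar)^2) / ((r - 1) * nbar)
    a <- (nbar / nc) *
      (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc <- hbar / 2
    A <- A + a; B <- B + b; C <- C + cc
  }
  c(a = A, b = B, c = C)
}

# Allele-size analogue: nested ANOVA variance components on repeat sizes
# (among populations / among individuals within / within individuals).
rst_components_locus <- function(a1, a2, pop) {
  pops <- sort(unique(pop))
  r <- length(pops)
  ni <- as.numeric(table(factor(pop, pops)))
  N <- sum(ni)
  nc <- (N - sum(ni^2) / N) / (r - 1)
  ind_mean <- (a1 + a2) / 2
  pop_mean <- tapply((a1 + a2), factor(pop, pops), sum) / (2 * ni)
  grand <- sum(a1 + a2) / (2 * N)
  ssd_within <- sum((a1 - a2)^2) / 2
  ssd_ind <- sum(2 * (ind_mean - pop_mean[match(pop, pops)])^2)
  ssd_pop <- sum(2 * ni * (pop_mean - grand)^2)
  msg <- ssd_within / N
  msi <- if (N - r > 0) ssd_ind / (N - r) else 0
  msp <- ssd_pop / (r - 1)
  sw <- msg
  sb <- (msi - msg) / 2
  sa <- (msp - msi) / (2 * nc)
  c(a = sa, b = sb, c = sw)
}

fst_pair <- function(g, pop_a, pop_b, estimator, min_individuals) {
  comp_fun <- switch(estimator, weir_cockerham = wc_components_locus,
                     rst_allele_size = rst_components_locus)
  sel <- g$populations %in% c(pop_a, pop_b)
  a1 <- g$a1[sel, , drop = FALSE]; a2 <- g$a2[sel, , drop = FALSE]
  pop <- match(g$populations[sel], c(pop_a, pop_b))
  A <- B <- C <- 0
  shared <- 0L
  for (l in seq_len(ncol(a1))) {
    typed <- !is.na(a1[, l])
    np <- table(factor(pop[typed], 1:2))
    if (any(np < min_individuals)) next
    shared <- shared + 1L
    comp <- comp_fun(a1[typed, l], a2[typed, l], pop[typed])
    A <- A + comp["a"]; B <- B + comp["b"]; C <- C + comp["c"]
  }
  if (shared == 0L)
    stop(sprintf("populations %s and %s share no adequately typed locus",
                 pop_a, pop_b))
  denom <- A + B + C
  unname(if (denom <= 0) 0 else A / denom)
}

#' Pairwise F-statistics from a genotype table
#'
#' Multilocus pairwise differentiation between populations, as the ratio of
#' summed among-population variance components to summed total components
#' over loci (and, for the allele-frequency estimator, over alleles).
#' `estimator = "weir_cockerham"` is the classic theta on allele frequencies;
#' `"rst_allele_size"` computes the same nested analysis of variance on
#' allele repeat sizes (the microsatellite R_ST convention, which weights
#' alleles by their mutational distance under stepwise mutation). Negative
#' per-locus components are retained in the sums; only the final multilocus
#' ratio is floored at zero (the unfloored value is kept in the `"raw"`
#' attribute). Missing genotypes are dropped per locus per individual.
#'
#' @param g an [str_genotypes] table.
#' @param estimator `"weir_cockerham"` (default) or `"rst_allele_size"`.
#' @param linearize apply the Slatkin transform F/(1-F) to the floored
#'   estimates.
#' @param min_individuals minimum typed individuals per population per locus
#'   for the locus to enter a pair's estimate (>= 2).
#' @return a [dist_matrix] over population labels, with attribute `"raw"`
#'   holding the unfloored estimates.
#' @export
pairwise_fst <- function(g, estimator = c("weir_cockerham", "rst_allele_size"),
                         linearize = FALSE, min_individuals = 2L) {
  estimator <- match.arg(estimator)
  if (min_individuals < 2L) stop("min_individuals must be >= 2")
  pops <- sort(unique(g$populations))
  if (length(pops) < 2L) stop("need at least 2 populations")
  np <- length(pops)
  raw <- matrix(0, np, np, dimnames = list(pops, pops))
  for (i in seq_len(np - 1)) for (j in (i + 1):np)
    raw[i, j] <- raw[j, i] <- fst_pair(g, pops[i], pops[j], estimator,
                                       min_individuals)
  vals <- pmax(raw, 0)
  if (linearize) {
    if (any(vals >= 1))
      stop("F = 1 cannot be Slatkin-linearized (infinite distance)")
    vals <- vals / (1 - vals)
  }
  out <- dist_matrix(vals, labels = pops)
  attr(out, "raw") <- raw
  attr(out, "estimator") <- estimator
  out
}

#' Slatkin linearization of a fixation-index matrix
#'
#' Entrywise F/(1-F), turning fixation indices into distances proportional
#' to divergence time under pure drift. Requires entries in [0, 1).
#'
#' @param m a [dist_matrix] of F values.
#' @return a [dist_matrix].
#' @export
slatkin_linearize <- function(m) {
  v <- unclass(m)
  if (any(v >= 1)) stop("entries must be < 1 for Slatkin linearization")
  if (any(v < 0)) stop("entries must be nonnegative")
  dist_matrix(v / (1 - v), labels = dm_labels(m))
}
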