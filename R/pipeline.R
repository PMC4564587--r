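#' End-to-end morphology-genetics concordance pipeline
#'
#' For each cranial region and each age grouping (combined subadults, AC1,
#' AC2, AC3): keeps the specimens complete for the region, superimposes them
#' (GPA), fits the shape PCA, computes the pairwise population Procrustes
#' distance matrix with permutation significance, the leave-one-out
#' cross-validated discriminant classification, and the age/size regression
#' summary. Genotypes (if given) yield the pairwise F_ST matrix, and every
#' regional morphological matrix is tested against it with a Mantel test
#' plus a population-exclusion scan. Adults enter superimposition and PCA
#' but not the group comparisons, which follow the subadult groupings.
#'
#' @param configs list of [landmark_config] specimens.
#' @param genotypes optional [str_genotypes]; alternatively supply
#'   `molecular` directly.
#' @param molecular optional molecular [dist_matrix] (overrides
#'   `genotypes`).
#' @param regions named list of [region_def]; default [cranial_regions()].
#' @param n_perm permutation replicates for distance significance.
#' @param seed seed for all stochastic stages.
#' @param out_dir optional directory; when given, every table is written as
#'   plain text and a JSON-ish manifest records seed and settings.
#' @param min_group minimum specimens per population for a population to
#'   enter a grouping's distance/classification analyses.
#' @return nested list: `$regions[[region]][[grouping]]` with elements
#'   `gpa`, `pca`, `distances`, `perm`, `confusion`, `regressions`,
#'   `mantel`, `exclusion`; plus `$molecular` and `$log`.
#' @export
run_pipeline <- function(configs, genotypes = NULL, molecular = NULL,
                         regions = cranial_regions(), n_perm = 1000L,
                         seed = 1L, out_dir = NULL, min_group = 2L) {
  if (is.null(molecular) && !is.null(genotypes))
    molecular <- pairwise_fst(genotypes)
  groupings <- list(subadults = c("AC1", "AC2", "AC3"),
                    AC1 = "AC1", AC2 = "AC2", AC3 = "AC3")
  log_lines <- character()
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  res <- list()
  for (rn in names(regions)) {
    keep <- filter_complete(lapply(configs, subset_region, region = regions[[rn]]),
                            quiet = TRUE)
    note("region %s: %d of %d specimens complete", rn, length(keep),
         length(configs))
    if (length(keep) < 4L) { note("region %s skipped (too few specimens)", rn); next }
    fit_all <- gpa(keep)
    pca_all <- fit_pca(fit_all)
    ages <- age_years(fit_all$info$age_category)
    reg_tab <- significant_pc_table(pca_all, ages, log(fit_all$centroid_sizes))
    region_out <- list(all = list(gpa = fit_all, pca = pca_all,
                                  regressions = reg_tab))
    for (gn in names(groupings)) {
      sel <- vapply(keep, function(cf) cf$age_category %in% groupings[[gn]],
                    logical(1))
      sub <- keep[sel]
      sizes <- table(vapply(sub, `[[`, "", "population"))
      ok_pops <- names(sizes)[sizes >= min_group]
      sub <- sub[vapply(sub, function(cf) cf$population %in% ok_pops, logical(1))]
      if (length(ok_pops) < 2L || length(sub) < 4L) {
        note("region %s / %s skipped (insufficient groups)", rn, gn); next
      }
      fit <- gpa(sub)
      perm <- pairwise_permutation_test(fit, n_perm = n_perm, seed = seed)
      pca <- fit_pca(fit)
      conf <- tryCatch(lda_loocv(pca), error = function(e) {
        note("region %s / %s: classification skipped (%s)", rn, gn,
             conditionMessage(e)); NULL })
      entry <- list(gpa = fit, pca = pca, distances = perm$matrix,
                    perm = perm, confusion = conf)
      if (!is.null(molecular) &&
          all(dm_labels(perm$matrix) %in% dm_labels(molecular))) {
        mol_sub <- dist_matrix(unclass(molecular)[dm_labels(perm$matrix),
                                                  dm_labels(perm$matrix)])
        entry$mantel <- mantel_test(perm$matrix, mol_sub, seed = seed)
        if (nrow(mol_sub) >= 5L)
          entry$exclusion <- exclusion_scan(perm$matrix, mol_sub, seed = seed)
      }
      region_out[[gn]] <- entry
      if (!is.null(out_dir)) {
        base <- file.path(out_dir, paste0(rn, "_", gn))
        write_dist_matrix(perm$matrix, paste0(base, "_distances.txt"))
        utils::write.csv(data.frame(perm$p_values),
                         paste0(base, "_perm_p.csv"), row.names = TRUE)
        if (!is.null(conf)) write_confusion(conf, paste0(base, "_confusion.csv"))
        if (!is.null(entry$exclusion))
          utils::write.csv(entry$exclusion, paste0(base, "_mantel_scan.csv"),
                           row.names = FALSE)
      }
    }
    res[[rn]] <- region_out
  }
  out <- list(regions = res, molecular = molecular, log = log_lines,
              seed = seed, n_perm = n_perm)
  if (!is.null(out_dir)) {
    if (!is.null(molecular))
      write_dist_matrix(molecular, file.path(out_dir, "molecular_fst.txt"))
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
    writeLines(c(sprintf("seed: %d", seed), sprintf("n_perm: %d", n_perm),
                 sprintf("regions: %s", paste(names(regions), collapse = ", ")),
                 sprintf("generated: %s", format(Sys.time(), "%Y-%m-%d"))),
               file.path(out_dir, "manifest.txt"))
  }
  out
}

#' Mantel summary table across regions and age groupings
#'
#' Flattens a [run_pipeline] result into the region x age-grouping
#' correlation report layout (R and p per cell).
#'
#' @param pipeline a [run_pipeline] result.
#' @return data.frame with columns `region`, `grouping`, `n`, `r`, `p`.
#' @export
mantel_summary <- function(pipeline) {
  rows <- list()
  for (rn in names(pipeline$regions)) for (gn in names(pipeline$regions[[rn]])) {
    m <- pipeline$regions[[rn]][[gn]]$mantel
    if (is.null(m)) next
    rows[[length(rows) + 1L]] <- data.frame(
      region = rn, grouping = gn, n = m$n_labels, r = m$r, p = m$p,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(data.frame(region = character(),
                                       grouping = character(), n = integer(),
                                       r = numeric(), p = numeric()))
  do.call(rbind, rows)
}
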