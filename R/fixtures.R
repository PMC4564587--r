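#' Published population distance matrices bundled with the package
#'
#' The seven-population molecular F_ST matrix (from published STR data) and
#' the four basicranial Procrustes matrices (combined subadults and age
#' categories AC1-AC3), transcribed from the printed study tables. They are
#' the deterministic concordance fixtures: Mantel tests on them need no
#' specimen data.
#'
#' @return named list of [dist_matrix] objects: `fst`, `subadults`, `ac1`,
#'   `ac2`, `ac3`.
#' @export
printed_distance_fixtures <- function() {
  files <- c(fst = "fst_str_populations.txt",
             subadults = "procrustes_basicranium_subadults.txt",
             ac1 = "procrustes_basicranium_ac1.txt",
             ac2 = "procrustes_basicranium_ac2.txt",
             ac3 = "procrustes_basicranium_ac3.txt")
  paths <- vapply(files, function(f)
    system.file("extdata", f, package = "ontocrania", mustWork = TRUE), "")
  lapply(paths, read_dist_matrix)
}

#' Write the bundled distance matrices to a directory
#'
#' Emits the five fixture matrices as labeled square text files, for use as
#' pipeline inputs or external checks.
#'
#' @param dir output directory (created if needed).
#' @return named character vector of paths, invisibly.
#' @export
make_fixture_tables <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fx <- printed_distance_fixtures()
  out <- vapply(names(fx), function(nm) {
    p <- file.path(dir, paste0(nm, ".txt"))
    write_dist_matrix(fx[[nm]], p)
    p
  }, "")
  invisible(out)
}

#' Study sample sizes per population and subadult age category
#'
#' The subadult sampling design of the study (48 AC1 + 51 AC2 + 85 AC3 =
#' 184 subadults over seven populations); the synthetic generator defaults
#' to this design.
#'
#' @return data.frame with columns `population`, `AC1`, `AC2`, `AC3`.
#' @export
study_sample_sizes <- function() {
  data.frame(
    population = c("Alaska", "Austria", "Egypt", "Mexico", "Peru",
                   "Polynesia", "Utah"),
    AC1 = c(10L, 5L, 9L, 8L, 3L, 2L, 11L),
    AC2 = c(6L, 10L, 7L, 7L, 8L, 6L, 7L),
    AC3 = c(14L, 13L, 11L, 15L, 19L, 9L, 4L),
    stringsAsFactors = FALSE)
}
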