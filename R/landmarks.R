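#' Landmark configuration for one specimen
#'
#' Bundles one specimen's ordered 3D landmark coordinates with its identity,
#' population and ontogenetic age-category labels. Landmarks that could not
#' be digitized (damaged or missing anatomy) are kept in place with
#' `present = FALSE` so that landmark order and numbering stay aligned with
#' the digitizing protocol; absent landmarks are excluded from every
#' downstream computation that touches them.
#'
#' @param specimen_id character scalar, unique specimen identifier.
#' @param coords numeric K x 3 matrix of landmark coordinates (mm).
#' @param population character scalar, population label.
#' @param age_category one of `"AC1"`, `"AC2"`, `"AC3"`, `"ADULT"`.
#' @param landmark_names optional character vector of length K; defaults to
#'   `L1..LK`.
#' @param present optional logical vector of length K; `FALSE` marks a
#'   landmark as not digitized. Rows of `coords` with any `NA` are marked
#'   absent automatically.
#' @return an object of class `landmark_config`.
#' @export
landmark_config <- function(specimen_id, coords, population = NA_character_,
                            age_category = c("AC1", "AC2", "AC3", "ADULT"),
                            landmark_names = NULL, present = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L) stop("coords must be a K x 3 matrix")
  K <- nrow(coords)
  if (K < 3L) stop("at least 3 landmarks are required")
  age_category <- match.arg(age_category)
  if (is.null(landmark_names)) landmark_names <- paste0("L", seq_len(K))
  if (length(landmark_names) != K) stop("landmark_names must have length K")
  if (is.null(present)) present <- rep(TRUE, K)
  present <- as.logical(present) & stats::complete.cases(coords)
  if (any(!is.finite(coords[present, , drop = FALSE])))
    stop("present landmark coordinates must be finite: ", specimen_id)
  rownames(coords) <- landmark_names
  colnames(coords) <- c("x", "y", "z")
  structure(
    list(specimen_id = as.character(specimen_id),
         population = as.character(population),
         age_category = age_category,
         coords = coords,
         present = present),
    class = "landmark_config")
}

#' @export
print.landmark_config <- function(x, ...) {
  cat(sprintf("<landmark_config> %s  pop=%s  age=%s  K=%d (%d present)\n",
              x$specimen_id, x$population, x$age_category,
              nrow(x$coords), sum(x$present)))
  invisible(x)
}

n_landmarks <- function(config) nrow(config$coords)

#' Cranial region definitions
#'
#' A region is a named, ordered subset of the landmark numbering. The bundled
#' basicranial scheme has 44 landmarks partitioned (with overlap at sutural
#' points shared by adjacent bones) into occipital (13), temporal (24) and
#' sphenoid (12) regions; `basicranium` is the full set.
#'
#' @param name region name.
#' @param indices 1-based landmark positions, unique, in region order.
#' @return an object of class `region_def`.
#' @export
region_def <- function(name, indices) {
  indices <- as.integer(indices)
  if (anyDuplicated(indices)) stop("region indices must be unique")
  if (any(indices < 1L)) stop("region indices are 1-based")
  structure(list(name = name, indices = indices), class = "region_def")
}

#' @rdname region_def
#' @return `cranial_regions()`: named list of the four bundled regions.
#' @export
cranial_regions <- function() {
  list(
    basicranium = region_def("basicranium", 1:44),
    temporal    = region_def("temporal", c(13:34, 36, 37)),
    occipital   = region_def("occipital", 1:13),
    sphenoid    = region_def("sphenoid", c(1, 2, 33, 35, 36, 38:44)))
}

#' Restrict a configuration to one cranial region
#'
#' @param config a `landmark_config`.
#' @param region a `region_def`.
#' @return a `landmark_config` holding exactly the region's landmarks, in
#'   region order, with specimen metadata preserved.
#' @export
subset_region <- function(config, region) {
  K <- n_landmarks(config)
  if (any(region$indices > K))
    stop(sprintf("region '%s' indexes landmark %d but configuration has %d",
                 region$name, max(region$indices), K))
  idx <- region$indices
  landmark_config(config$specimen_id,
                  config$coords[idx, , drop = FALSE],
                  population = config$population,
                  age_category = config$age_category,
                  landmark_names = rownames(config$coords)[idx],
                  present = config$present[idx])
}

#' Keep only specimens complete for a region
#'
#' Specimens missing any landmark of the region are dropped (the analysis
#' excludes incomplete specimens rather than imputing). A summary of removals
#' per population x age category is attached and reported via `message()`.
#'
#' @param configs list of `landmark_config`.
#' @param region a `region_def`; default keeps specimens complete for all
#'   their landmarks.
#' @param quiet suppress the removal message.
#' @return the retained sublist, with a `"removed"` attribute (data.frame of
#'   counts removed per population x age category).
#' @export
filter_complete <- function(configs, region = NULL, quiet = FALSE) {
  ok <- vapply(configs, function(cf) {
    idx <- if (is.null(region)) seq_len(n_landmarks(cf)) else region$indices
    if (any(idx > n_landmarks(cf))) return(FALSE)
    all(cf$present[idx])
  }, logical(1))
  removed <- configs[!ok]
  tab <- if (length(removed)) {
    as.data.frame(table(
      population = vapply(removed, `[[`, "", "population"),
      age_category = vapply(removed, `[[`, "", "age_category")),
      responseName = "n_removed")
  } else {
    data.frame(population = character(), age_category = character(),
               n_removed = integer())
  }
  tab <- tab[tab$n_removed > 0, , drop = FALSE]
  if (!quiet && nrow(tab))
    message(sprintf("filter_complete: removed %d incomplete specimen(s)",
                    sum(tab$n_removed)))
  if (!quiet && !any(ok)) warning("no complete specimens remain")
  structure(configs[ok], removed = tab)
}

#' Numeric encoding of ontogenetic age categories
#'
#' The three subadult categories are defined by molar eruption and correspond
#' roughly to <5, 5-12 and 13-18 years; regressions need a numeric age, so
#' categories are coded at interval midpoints by default (adults, whose ages
#' cannot be estimated from eruption, at a nominal 21). The mapping is
#' configurable and must be strictly increasing with category.
#'
#' @param categories character vector of `"AC1"/"AC2"/"AC3"/"ADULT"`.
#' @param mapping named numeric vector giving years per category.
#' @return numeric vector of ages in years.
#' @export
age_years <- function(categories,
                      mapping = c(AC1 = 2.5, AC2 = 8.5, AC3 = 15.5, ADULT = 21)) {
  if (!all(c("AC1", "AC2", "AC3", "ADULT") %in% names(mapping)))
    stop("mapping must name AC1, AC2, AC3, ADULT")
  if (any(diff(mapping[c("AC1", "AC2", "AC3", "ADULT")]) <= 0))
    stop("age mapping must be strictly increasing with category")
  unname(mapping[as.character(categories)])
}

config_metadata <- function(configs) {
  data.frame(
    specimen_id = vapply(configs, `[[`, "", "specimen_id"),
    population = vapply(configs, `[[`, "", "population"),
    age_category = vapply(configs, `[[`, "", "age_category"),
    stringsAsFactors = FALSE)
}

# Stack complete, equally-sized configurations into a K x 3 x n array.
config_array <- function(configs) {
  Ks <- vapply(configs, n_landmarks, integer(1))
  if (length(unique(Ks)) != 1L) stop("configurations differ in landmark count")
  if (!all(vapply(configs, function(cf) all(cf$present), logical(1))))
    stop("all configurations must be complete (use filter_complete first)")
  arr <- array(NA_real_, c(Ks[1], 3L, length(configs)),
               dimnames = list(rownames(configs[[1]]$coords), c("x", "y", "z"),
                               vapply(configs, `[[`, "", "specimen_id")))
  for (i in seq_along(configs)) arr[, , i] <- configs[[i]]$coords
  arr
}
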