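#' Read landmark configurations from TPS or tabular text
#'
#' Two dialects are supported. `format = "tps"` reads 3D TPS blocks:
#' an `LM3=K` header, K whitespace-separated `x y z` lines (a literal `NA`
#' marks a coordinate of an undigitized landmark), a mandatory `ID=` line,
#' and optional `POP=` / `AGE=` metadata lines (`SCALE=` lines are ignored;
#' scale is irrelevant after superimposition). `format = "table"` reads a
#' comma-separated file with columns
#' `specimen_id, population, age_category, landmark, x, y, z`, one row per
#' (specimen, landmark); blank or `NA` coordinate cells mark the landmark
#' absent.
#'
#' @param path file path.
#' @param format `"tps"` or `"table"`.
#' @return list of [landmark_config] objects, one per specimen, landmark
#'   order preserved.
#' @export
read_landmarks <- function(path, format = c("tps", "table")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  configs <- switch(format,
                    tps = read_landmarks_tps(path),
                    table = read_landmarks_table(path))
  ids <- vapply(configs, `[[`, "", "specimen_id")
  if (anyDuplicated(ids))
    stop("duplicate specimen_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  configs
}

read_landmarks_tps <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  starts <- grep("^LM3\\s*=", lines)
  if (!length(starts)) stop("no LM3= blocks found in ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  lapply(seq_along(starts), function(b) {
    block <- lines[starts[b]:ends[b]]
    K <- as.integer(sub("^LM3\\s*=\\s*", "", block[1]))
    if (length(block) < K + 1L ||
        any(grepl("=", block[seq_len(K) + 1L])))
      stop(sprintf("TPS block %d: header says %d landmarks but block is short", b, K))
    coord_lines <- block[seq_len(K) + 1L]
    coords <- t(vapply(coord_lines, function(l) {
      f <- strsplit(l, "\\s+")[[1]]
      if (length(f) != 3L)
        stop("TPS coordinate line does not have 3 fields: ", l)
      suppressWarnings(as.numeric(f))
    }, numeric(3)))
    meta <- block[-seq_len(K + 1L)]
    get1 <- function(key) {
      hit <- grep(paste0("^", key, "\\s*="), meta, value = TRUE)
      if (length(hit)) sub(paste0("^", key, "\\s*=\\s*"), "", hit[1]) else NA_character_
    }
    id <- get1("ID")
    if (is.na(id)) stop(sprintf("TPS block %d lacks the mandatory ID= line", b))
    age <- get1("AGE")
    landmark_config(id, coords,
                    population = get1("POP"),
                    age_category = if (is.na(age)) "ADULT" else age)
  })
}

read_landmarks_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "population", "age_category", "landmark", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("landmark table must have columns: ", paste(need, collapse = ", "))
  for (v in c("x", "y", "z")) df[[v]] <- suppressWarnings(as.numeric(df[[v]]))
  lapply(split(df, factor(df$specimen_id, levels = unique(df$specimen_id))),
         function(d) {
           landmark_config(d$specimen_id[1],
                           cbind(d$x, d$y, d$z),
                           population = d$population[1],
                           age_category = d$age_category[1],
                           landmark_names = as.character(d$landmark))
         })
}

#' Write landmark configurations
#'
#' Inverse of [read_landmarks]; absent landmarks are written as `NA`.
#'
#' @param configs list of `landmark_config`.
#' @param path output path.
#' @param format `"tps"` or `"table"`.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(configs, path, format = c("tps", "table")) {
  format <- match.arg(format)
  fmt <- function(v) ifelse(is.na(v), "NA",
                            format(v, digits = 15, scientific = FALSE, trim = TRUE))
  if (format == "tps") {
    out <- unlist(lapply(configs, function(cf) {
      xyz <- cf$coords
      xyz[!cf$present, ] <- NA_real_
      c(sprintf("LM3=%d", nrow(xyz)),
        apply(xyz, 1, function(r) paste(fmt(r), collapse = " ")),
        sprintf("ID=%s", cf$specimen_id),
        sprintf("POP=%s", cf$population),
        sprintf("AGE=%s", cf$age_category),
        "")
    }))
    writeLines(out, path)
  } else {
    df <- do.call(rbind, lapply(configs, function(cf) {
      xyz <- cf$coords
      xyz[!cf$present, ] <- NA_real_
      data.frame(specimen_id = cf$specimen_id, population = cf$population,
                 age_category = cf$age_category,
                 landmark = rownames(xyz),
                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Microsatellite genotype table
#'
#' Diploid allele repeat sizes for individuals x loci. Missing genotypes are
#' `NA` pairs (never zero-coded). Stored as two parallel integer matrices so
#' per-locus frequency computations stay vectorized; the pair is unordered
#' (a1 <= a2 after construction).
#'
#' @param individual_ids character vector, unique.
#' @param populations character vector, one per individual.
#' @param a1,a2 integer matrices (individuals x loci) of allele repeat sizes;
#'   `NA` in either marks the genotype missing.
#' @param loci locus names; default from `a1` colnames.
#' @return an object of class `str_genotypes`.
#' @export
str_genotypes <- function(individual_ids, populations, a1, a2, loci = NULL) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  if (!all(dim(a1) == dim(a2))) stop("allele matrices differ in shape")
  if (anyDuplicated(individual_ids)) stop("duplicate individual ids")
  if (length(individual_ids) != nrow(a1) || length(populations) != nrow(a1))
    stop("metadata length does not match genotype rows")
  if (is.null(loci)) loci <- colnames(a1)
  if (is.null(loci)) loci <- paste0("locus", seq_len(ncol(a1)))
  miss <- is.na(a1) | is.na(a2)
  a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
  if (any(c(a1, a2) <= 0, na.rm = TRUE))
    stop("allele repeat sizes must be positive integers")
  lo <- pmin(a1, a2); hi <- pmax(a1, a2)
  storage.mode(lo) <- "integer"; storage.mode(hi) <- "integer"
  dimnames(lo) <- dimnames(hi) <- list(individual_ids, loci)
  structure(list(individual_ids = as.character(individual_ids),
                 populations = as.character(populations),
                 loci = as.character(loci),
                 a1 = lo, a2 = hi),
            class = "str_genotypes")
}

#' @export
print.str_genotypes <- function(x, ...) {
  cat(sprintf("<str_genotypes> %d individuals x %d loci, %d populations, %.1f%% missing\n",
              nrow(x$a1), ncol(x$a1), length(unique(x$populations)),
              100 * mean(is.na(x$a1))))
  invisible(x)
}

#' Read / write genotype tables
#'
#' Comma-separated text with columns `individual_id, population`, then one
#' column per locus holding `a1/a2` allele repeat sizes, `.` for missing.
#'
#' @param path file path.
#' @param g an `str_genotypes` object.
#' @return `read_genotypes`: an `str_genotypes`; `write_genotypes`: `path`,
#'   invisibly.
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  if (!all(c("individual_id", "population") %in% names(df)))
    stop("genotype table must have individual_id and population columns")
  loci <- setdiff(names(df), c("individual_id", "population"))
  if (!length(loci)) stop("genotype table has no locus columns")
  parse_allele <- function(cells, which) {
    out <- rep(NA_integer_, length(cells))
    ok <- !is.na(cells) & cells != "." & nzchar(cells)
    parts <- strsplit(cells[ok], "/", fixed = TRUE)
    if (any(lengths(parts) != 2L)) stop("genotype cells must be 'a1/a2' or '.'")
    out[ok] <- as.integer(vapply(parts, `[[`, "", which))
    out
  }
  a1 <- sapply(loci, function(l) parse_allele(df[[l]], 1L))
  a2 <- sapply(loci, function(l) parse_allele(df[[l]], 2L))
  if (nrow(df) == 1L) { a1 <- t(a1); a2 <- t(a2) }
  str_genotypes(df$individual_id, df$population, a1, a2, loci = loci)
}

#' @rdname read_genotypes
#' @export
write_genotypes <- function(g, path) {
  cells <- matrix(".", nrow(g$a1), ncol(g$a1))
  ok <- !is.na(g$a1)
  cells[ok] <- paste0(g$a1[ok], "/", g$a2[ok])
  df <- data.frame(individual_id = g$individual_ids, population = g$populations,
                   cells, stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- c("individual_id", "population", g$loci)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
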