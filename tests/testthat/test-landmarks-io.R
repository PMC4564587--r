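test_that("bundled cranial regions partition the 44 landmarks as documented", {
  reg <- cranial_regions()
  expect_length(reg$occipital$indices, 13)
  expect_length(reg$temporal$indices, 24)
  expect_length(reg$sphenoid$indices, 12)
  expect_setequal(
    sort(unique(c(reg$occipital$indices, reg$temporal$indices,
                  reg$sphenoid$indices))), 1:44)
  all_idx <- c(reg$occipital$indices, reg$temporal$indices,
               reg$sphenoid$indices)
  shared <- sort(unique(all_idx[duplicated(all_idx)]))
  expect_identical(shared, c(1L, 2L, 13L, 33L, 36L))
})

test_that("subset_region extracts the region's landmarks and keeps metadata", {
  set.seed(1)
  cf <- rand_config("sp1", K = 44, pop = "Egypt", age = "AC3")
  reg <- cranial_regions()
  occ <- subset_region(cf, reg$occipital)
  expect_equal(nrow(occ$coords), 13)
  expect_equal(occ$population, "Egypt")
  expect_equal(occ$age_category, "AC3")
  expect_equal(occ$coords, cf$coords[1:13, ])
  expect_equal(nrow(subset_region(cf, reg$temporal)$coords), 24)
  full <- subset_region(cf, reg$basicranium)
  expect_equal(full$coords, cf$coords)
  small <- rand_config("sp2", K = 10)
  expect_error(subset_region(small, reg$temporal), "indexes landmark")
})

test_that("filter_complete keeps exactly the specimens complete for a region", {
  set.seed(2)
  reg <- region_def("front", 1:5)
  configs <- lapply(1:12, function(i) {
    cf <- rand_config(paste0("s", i), K = 8, pop = "A")
    if (i > 10) cf$present[3] <- FALSE
    cf
  })
  kept <- filter_complete(configs, reg, quiet = TRUE)
  expect_length(kept, 10)
  expect_equal(attr(kept, "removed")$n_removed, 2L)
  expect_length(filter_complete(configs[1:10], reg, quiet = TRUE), 10)
  # randomized missingness agrees with brute-force mask conjunction
  configs2 <- lapply(1:30, function(i) {
    cf <- rand_config(paste0("r", i), K = 8)
    cf$present <- runif(8) > 0.2
    cf
  })
  kept2 <- filter_complete(configs2, reg, quiet = TRUE)
  brute <- Filter(function(cf) all(cf$present[1:5]), configs2)
  expect_equal(vapply(kept2, `[[`, "", "specimen_id"),
               vapply(brute, `[[`, "", "specimen_id"))
})

test_that("age encoding is strictly increasing and configurable", {
  expect_equal(age_years(c("AC1", "AC2", "AC3", "ADULT")),
               c(2.5, 8.5, 15.5, 21))
  expect_equal(age_years("AC2", mapping = c(AC1 = 1, AC2 = 6, AC3 = 14,
                                            ADULT = 25)), 6)
  expect_error(age_years("AC1", mapping = c(AC1 = 5, AC2 = 3, AC3 = 14,
                                            ADULT = 25)), "increasing")
})

test_that("landmark files round-trip through TPS and table formats", {
  set.seed(3)
  configs <- lapply(1:4, function(i)
    rand_config(paste0("sp", i), K = 6, pop = c("A", "B")[1 + i %% 2],
                age = c("AC1", "ADULT")[1 + (i > 2)]))
  configs[[2]]$present[4] <- FALSE
  for (fmt in c("tps", "table")) {
    path <- withr::local_tempfile(fileext = ".txt")
    write_landmarks(configs, path, format = fmt)
    back <- read_landmarks(path, format = fmt)
    expect_length(back, 4)
    for (i in 1:4) {
      expect_equal(back[[i]]$specimen_id, configs[[i]]$specimen_id)
      expect_equal(back[[i]]$population, configs[[i]]$population)
      expect_equal(back[[i]]$age_category, configs[[i]]$age_category)
      expect_equal(back[[i]]$present, configs[[i]]$present)
      ok <- configs[[i]]$present
      expect_equal(back[[i]]$coords[ok, ], configs[[i]]$coords[ok, ],
                   tolerance = 1e-6)
    }
  }
})

test_that("TPS parser enforces block structure and unique specimen ids", {
  path <- withr::local_tempfile(fileext = ".tps")
  writeLines(c("LM3=4", "0 0 0", "1 0 0", "0 1 0", "0 0 1", "ID=one"), path)
  one <- read_landmarks(path, format = "tps")
  expect_length(one, 1)
  expect_equal(nrow(one[[1]]$coords), 4)
  expect_true(all(one[[1]]$present))
  writeLines(c("LM3=4", "0 0 0", "1 0 0", "0 1 0", "ID=short"), path)
  expect_error(read_landmarks(path, format = "tps"), "header says")
  writeLines(c("LM3=3", "0 0 0", "1 0 0", "0 1 0"), path)
  expect_error(read_landmarks(path, format = "tps"), "ID=")
  writeLines(rep(c("LM3=3", "0 0 0", "1 0 0", "0 1 0", "ID=dup"), 2), path)
  expect_error(read_landmarks(path, format = "tps"), "duplicate")
})

test_that("blank coordinates in tabular landmarks mark the landmark absent", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("specimen_id,population,age_category,landmark,x,y,z",
               "s1,A,AC1,L1,0,0,0", "s1,A,AC1,L2,1,0,0",
               "s1,A,AC1,L3,0,1,0", "s1,A,AC1,L4,0,0,"), path)
  cf <- read_landmarks(path, format = "table")[[1]]
  expect_equal(cf$present, c(TRUE, TRUE, TRUE, FALSE))
})

test_that("distance matrices enforce their invariants on every path", {
  m <- dist_matrix(matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3),
                   labels = c("a", "b", "c"))
  expect_equal(m["b", "c"], 3)
  bad <- matrix(c(0, 1, 2, 4, 0, 3, 2, 3, 0), 3)
  expect_error(dist_matrix(bad, labels = letters[1:3]), "asymmetric")
  expect_error(dist_matrix(-m, labels = letters[1:3]), "nonnegative")
  expect_error(dist_matrix(matrix(0, 2, 3)), "square")
  path <- withr::local_tempfile(fileext = ".txt")
  set.seed(4)
  r <- rand_dist_matrix(5)
  write_dist_matrix(r, path)
  expect_equal(unclass(read_dist_matrix(path)), unclass(r), tolerance = 1e-6)
  # asymmetric file rejected
  lines <- readLines(path)
  f <- strsplit(lines[3], "\t")[[1]]; f[2] <- "9.9"
  lines[3] <- paste(f, collapse = "\t")
  writeLines(lines, path)
  expect_error(read_dist_matrix(path), "asymmetric")
})

test_that("bundled fixture matrices match the published values", {
  fx <- printed_distance_fixtures()
  expect_equal(fx$fst["Alaska", "Austria"], 0.0455)
  expect_equal(fx$fst["Alaska", "Utah"], 0.0984)
  expect_equal(fx$subadults["Egypt", "Utah"], 0.0998)
  expect_equal(fx$ac1["Austria", "Peru"], 0.1867)
  expect_equal(fx$ac3["Egypt", "Utah"], 0.1382)
  for (m in fx) {
    expect_s3_class(m, "dist_matrix")
    expect_equal(diag(unclass(m)), setNames(rep(0, 7), dm_labels(m)))
  }
  out <- withr::local_tempdir()
  paths <- make_fixture_tables(out)
  expect_equal(unclass(read_dist_matrix(paths[["fst"]])), unclass(fx$fst))
})

test_that("genotype tables round-trip with missing genotypes preserved", {
  set.seed(5)
  a1 <- matrix(sample(8:20, 40, TRUE), 10, 4)
  a2 <- matrix(sample(8:20, 40, TRUE), 10, 4)
  a1[2, 3] <- NA
  g <- str_genotypes(paste0("i", 1:10), rep(c("P1", "P2"), 5), a1, a2)
  expect_true(is.na(g$a2[2, 3]))          # NA in either allele voids the pair
  expect_true(all(g$a1 <= g$a2, na.rm = TRUE))  # unordered pair, stored sorted
  path <- withr::local_tempfile(fileext = ".csv")
  write_genotypes(g, path)
  back <- read_genotypes(path)
  expect_equal(back$a1, g$a1)
  expect_equal(back$a2, g$a2)
  expect_equal(back$populations, g$populations)
  expect_error(str_genotypes("i1", "P1", matrix(0L), matrix(5L)), "positive")
})
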