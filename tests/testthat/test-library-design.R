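test_that("library enumeration covers the full cross-product in canonical order", {
  d <- tiny_design()
  lib <- enumerate_library(d)
  expect_equal(nrow(lib), 2 * 3 * 1)
  expect_equal(lib$variant_name[1], "WT")
  expect_equal(anyDuplicated(lib$variant_name), 0L)
  # library size identity holds for arbitrary random designs
  for (s in 1:5) {
    rd <- random_design(n_positions = sample(2:5, 1), seed = s)
    expected <- prod(vapply(rd$positions$alternatives, length, 1L) + 1L)
    expect_equal(nrow(enumerate_library(rd)), expected)
  }
  # a WED x PI split of 12 x 108 option combinations gives 1296 variants
  kkh <- benchmark_design(1)
  by_domain <- tapply(
    vapply(kkh$positions$alternatives, length, 1L) + 1L,
    kkh$positions$domain, prod
  )
  expect_equal(as.numeric(by_domain[c("WED", "PI")]), c(12, 108))
  expect_equal(n_library_variants(kkh), 1296)
  expect_equal(nrow(enumerate_library(kkh)), 1296)
  # 8 positions x 2 alternatives each = 3^8
  d38 <- library_design(data.frame(
    position = 1:8, wildtype = "A", alternatives = "C;D"
  ))
  expect_equal(n_library_variants(d38), 3^8)
})

test_that("single-position, no-alternative design enumerates to WT only", {
  d1 <- library_design(data.frame(position = 4L, wildtype = "M", alternatives = ""))
  lib <- enumerate_library(d1)
  expect_equal(lib$variant_name, "WT")
})

test_that("design validation rejects malformed inputs", {
  expect_error(library_design(data.frame(
    position = c(3L, 3L), wildtype = c("A", "A"), alternatives = c("C", "D")
  )), "duplicate|increasing")
  expect_error(library_design(data.frame(
    position = 1L, wildtype = "A", alternatives = "A;C"
  )), "wild-type")
  expect_error(library_design(data.frame(
    position = 1L, wildtype = "B", alternatives = "C"
  )), "canonical")
  expect_error(library_design(data.frame(
    position = 2L, wildtype = "C", alternatives = "D"
  ), reference = "AA"), "reference|disagrees")
})

test_that("variant names parse and render as inverses over the full library", {
  d <- benchmark_design(2)
  lib <- enumerate_library(d)
  m <- residue_matrix(lib, d)
  reparsed <- t(vapply(
    lib$variant_name, parse_variant_name, character(8), design = d
  ))
  expect_equal(unname(reparsed), unname(m))
  # and names re-rendered from parsed residues match (bijection)
  renames <- make_variant_names(reparsed, d)
  expect_equal(unname(renames), lib$variant_name)
})

test_that("parsing resolves substitutions and rejects illegal tokens", {
  d <- library_design(data.frame(
    position = c(888L, 889L), wildtype = c("N", "A"), alternatives = c("R", "Q")
  ))
  v <- parse_variant_name("N888R/A889Q", d)
  expect_equal(unname(v), c("R", "Q"))
  expect_equal(unname(parse_variant_name("WT", d)), c("N", "A"))
  expect_error(parse_variant_name("Q888R", d), "wild type")
  expect_error(parse_variant_name("N887R", d), "not mutable")
  expect_error(parse_variant_name("N888W", d), "not an allowed")
})

test_that("mismatch distance is a metric on the library", {
  d <- benchmark_design(3)
  lib <- enumerate_library(d)
  expect_equal(mismatch_distance(lib$variant_name[5], lib$variant_name[5], d), 0)
  dm <- withr::with_seed(42, {
    idx <- sample(nrow(lib), 30)
    pairwise_mismatch(lib$variant_name[idx], d)
  })
  expect_true(isSymmetric(dm))
  expect_true(all(diag(dm) == 0))
  expect_true(all(dm[upper.tri(dm)] >= 1)) # distinct variants differ
  expect_true(all(dm <= 8))
  # triangle inequality on random triples
  withr::with_seed(1, for (r in 1:50) {
    ijk <- sample(nrow(dm), 3)
    expect_lte(dm[ijk[1], ijk[3]], dm[ijk[1], ijk[2]] + dm[ijk[2], ijk[3]])
  })
  # maximum distance over the full library attains the number of positions
  full <- pairwise_mismatch(lib, d)
  expect_equal(max(full), 8L)
})

test_that("double mutants sit two mismatches from wild type", {
  d <- library_design(data.frame(
    position = c(888L, 889L, 985L), wildtype = c("N", "A", "T"),
    alternatives = c("R", "Q", "S")
  ))
  expect_equal(mismatch_distance("N888R/A889Q", "WT", d), 2)
})

test_that("protein sequences are rebuilt with exactly the designated substitutions", {
  ref <- paste(rep("ACDEFGHIKL", 3), collapse = "") # 30 residues
  d <- library_design(
    data.frame(
      position = c(3L, 14L), wildtype = c("D", "E"), alternatives = c("N", "Q")
    ),
    reference = ref
  )
  expect_equal(build_protein_sequence(ref, "WT", d), ref)
  s1 <- build_protein_sequence(ref, "D3N", d)
  expect_equal(nchar(s1), nchar(ref))
  diffs <- which(strsplit(s1, "")[[1]] != strsplit(ref, "")[[1]])
  expect_equal(diffs, 3L)
  s2 <- build_protein_sequence(ref, "D3N/E14Q", d)
  expect_equal(sum(strsplit(s2, "")[[1]] != strsplit(ref, "")[[1]]), 2L)
  expect_error(build_protein_sequence("ACD", "D3N", d), "shorter")
})

test_that("designs and libraries round-trip through their delimited formats", {
  d <- tiny_design()
  path <- withr::local_tempfile(fileext = ".csv")
  write_design(d, path)
  d2 <- read_design(path, name = "tiny")
  expect_equal(d2$positions$position, d$positions$position)
  expect_equal(d2$positions$alternatives, d$positions$alternatives)
  lib <- enumerate_library(d)
  lpath <- withr::local_tempfile(fileext = ".csv")
  write_library(lib, lpath)
  lib2 <- utils::read.csv(lpath, stringsAsFactors = FALSE)
  expect_equal(lib2$variant_name, lib$variant_name)
})
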