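# minimal hand-written PDB records for parser tests
pdb_line <- function(serial, name, alt, resn, chain, resno, x, y, z,
                     occ = 1, elem) {
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, paste0(" ", name), alt, resn, chain, resno, x, y, z,
          occ, 20, elem)
}

write_toy_pdb <- function(lines) {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(lines, "END"), f)
  f
}

test_that("structures parse with residue classification and altloc resolution", {
  f <- write_toy_pdb(c(
    pdb_line(1, "N", " ", "ALA", "A", 1, 0, 0, 0, 1, "N"),
    pdb_line(2, "CA", " ", "ALA", "A", 1, 1.5, 0, 0, 1, "C"),
    pdb_line(3, "O", " ", "ALA", "A", 1, 2.4, 1, 0, 1, "O")))
  m <- read_structure(f)
  expect_identical(nrow(m), 3L)
  expect_identical(unique(m$polymer), "protein")

  # altloc: highest occupancy wins; ties break by label
  f2 <- write_toy_pdb(c(
    pdb_line(1, "N", "A", "ALA", "A", 1, 0, 0, 0, 0.6, "N"),
    pdb_line(2, "N", "B", "ALA", "A", 1, 9, 0, 0, 0.4, "N"),
    pdb_line(3, "CA", "A", "ALA", "A", 1, 1, 0, 0, 0.5, "C"),
    pdb_line(4, "CA", "B", "ALA", "A", 1, 8, 0, 0, 0.5, "C")))
  m2 <- read_structure(f2)
  expect_identical(nrow(m2), 2L)
  expect_identical(m2$x[m2$atom == "N"], 0)
  expect_identical(m2$altloc[m2$atom == "CA"], "A")

  f3 <- write_toy_pdb(c(
    pdb_line(1, "CA", " ", "ALA", "A", 1, 0, 0, 0, 1, "C"),
    pdb_line(2, "P", " ", "DT", "B", 1, 5, 0, 0, 1, "P"),
    pdb_line(3, "O", " ", "HOH", "S", 1, 9, 0, 0, 1, "O"),
    pdb_line(4, "C1", " ", "XYZ", "C", 1, 12, 0, 0, 1, "C")))
  expect_warning(m3 <- read_structure(f3), "other")
  expect_identical(m3$polymer[order(m3$chain)],
                   c("protein", "DNA", "other", "water"))
})

test_that("atom counts are per class, heavy atoms only, order-invariant", {
  lines <- c(
    pdb_line(1, "N", " ", "GLY", "A", 1, 0, 0, 0, 1, "N"),
    pdb_line(2, "CA", " ", "GLY", "A", 1, 1.5, 0, 0, 1, "C"),
    pdb_line(3, "H", " ", "GLY", "A", 1, 0.5, 1, 0, 1, "H"),
    pdb_line(4, "P", " ", "DA", "B", 1, 8, 0, 0, 1, "P"),
    pdb_line(5, "O", " ", "HOH", "S", 1, 12, 0, 0, 1, "O"))
  m <- read_structure(write_toy_pdb(lines))
  expect_identical(count_atoms(m, "protein"), 2L)  # H excluded
  expect_identical(count_atoms(m, "DNA"), 1L)
  expect_identical(count_atoms(m, "water"), 1L)
  expect_error(count_atoms(m, "lipid"), "unknown")

  m_rev <- read_structure(write_toy_pdb(rev(lines)))
  for (cl in c("protein", "DNA", "water"))
    expect_identical(count_atoms(m_rev, cl), count_atoms(m, cl))
})

test_that("hydrogen bonds follow the distance window", {
  two <- function(d) write_toy_pdb(c(
    pdb_line(1, "N", " ", "ALA", "A", 1, 0, 0, 0, 1, "N"),
    pdb_line(2, "O", " ", "GLY", "A", 2, d, 0, 0, 1, "O")))
  expect_identical(nrow(find_hbonds(read_structure(two(2.9)))), 1L)
  expect_identical(find_hbonds(read_structure(two(2.9)))$distance, 2.9)
  expect_identical(nrow(find_hbonds(read_structure(two(3.6)))), 0L)
  # the long threonine-adenine class of contacts appears at 4.0
  expect_identical(nrow(find_hbonds(read_structure(two(3.6)),
                                    cutoff = 4.0)), 1L)
  # same residue and covalent-range pairs are excluded
  same <- write_toy_pdb(c(
    pdb_line(1, "N", " ", "ALA", "A", 1, 0, 0, 0, 1, "N"),
    pdb_line(2, "O", " ", "ALA", "A", 1, 2.9, 0, 0, 1, "O")))
  expect_identical(nrow(find_hbonds(read_structure(same))), 0L)
  expect_identical(nrow(find_hbonds(read_structure(two(1.4)))), 0L)
})

test_that("hbond detection equals a brute-force all-pairs scan", {
  set.seed(41)
  resns <- c("ALA", "GLY", "SER")
  lines <- character(0)
  for (i in 1:60) {
    elem <- sample(c("N", "O", "C"), 1)
    lines <- c(lines, pdb_line(i, elem, " ", sample(resns, 1), "A",
                               i %/% 3 + 1, runif(1, 0, 12),
                               runif(1, 0, 12), runif(1, 0, 12), 1,
                               elem))
  }
  m <- read_structure(write_toy_pdb(lines))
  expect_identical(nrow(find_hbonds(m)), brute_hbonds(m))
  expect_identical(nrow(find_hbonds(m, cutoff = 5)),
                   brute_hbonds(m, cutoff = 5))
})

test_that("junction networks read the solenoid geometry", {
  f <- withr::local_tempfile(fileext = ".pdb")
  synthetic_solenoid(f, n_repeats = 4, length_A = 40,
                     arg16_glu19 = c(TRUE, FALSE, TRUE),
                     lys28_glu26 = c(FALSE, TRUE, TRUE))
  jn <- junction_networks(read_structure(f), n_repeats = 4)
  expect_identical(nrow(jn), 3L)
  expect_identical(jn$arg16_glu19, c(TRUE, FALSE, TRUE))
  expect_identical(jn$lys28_glu26, c(FALSE, TRUE, TRUE))

  # displaced glutamates lose every junction
  f2 <- withr::local_tempfile(fileext = ".pdb")
  synthetic_solenoid(f2, n_repeats = 4, length_A = 40,
                     arg16_glu19 = rep(FALSE, 3),
                     lys28_glu26 = rep(FALSE, 3))
  jn2 <- junction_networks(read_structure(f2), n_repeats = 4)
  expect_true(all(!jn2$arg16_glu19))

  # missing residues are indeterminate, not absent
  m <- read_structure(f)
  m_missing <- m[!(m$resno %in% global_residue_index(2, c(16L, 19L))), ]
  class(m_missing) <- class(m)
  jn3 <- junction_networks(m_missing, n_repeats = 4)
  expect_true(is.na(jn3$arg16_glu19[1]))
})

test_that("network comparison counts apo-present, bound-absent junctions", {
  dir <- withr::local_tempdir()
  p <- synthetic_solenoid_pair(dir, n_repeats = 10,
                               rearranged = c(3L, 5L, 8L))
  apo <- read_structure(p$apo)
  bound <- read_structure(p$bound)
  ja <- junction_networks(apo, 10)
  jb <- junction_networks(bound, 10)
  n <- compare_networks(ja, jb)
  expect_identical(as.integer(n), 3L)
  expect_identical(attr(n, "junctions"), c(3L, 5L, 8L))
  expect_identical(as.integer(compare_networks(ja, ja)), 0L)
  expect_error(compare_networks(ja, jb[-1, ]), "differ")

  # indeterminate junctions are excluded and reported
  jb_na <- jb
  jb_na$arg16_glu19[3] <- NA
  expect_message(n2 <- compare_networks(ja, jb_na), "indeterminate")
  expect_identical(as.integer(n2), 2L)
  expect_identical(attr(n2, "indeterminate"), 3L)
})

test_that("superhelix length is the maximal CA extent and shrinks on binding", {
  # 65 collinear CA atoms spaced 1 apart span 64
  lines <- vapply(1:65, function(i)
    pdb_line(i, "CA", " ", "GLY", "A", i, i - 1, 0, 0, 1, "C"), "")
  m <- read_structure(write_toy_pdb(lines))
  expect_equal(as.numeric(superhelix_length(m)), 64)

  two <- read_structure(write_toy_pdb(c(
    pdb_line(1, "CA", " ", "GLY", "A", 1, 0, 0, 0, 1, "C"),
    pdb_line(2, "CA", " ", "GLY", "A", 2, 6, 8, 0, 1, "C"))))
  expect_equal(as.numeric(superhelix_length(two)), 10)

  one <- read_structure(write_toy_pdb(
    pdb_line(1, "CA", " ", "GLY", "A", 1, 0, 0, 0, 1, "C")))
  expect_error(superhelix_length(one), "C-alpha")

  dir <- withr::local_tempdir()
  p <- synthetic_solenoid_pair(dir)
  apo_len <- superhelix_length(read_structure(p$apo))
  bound_len <- superhelix_length(read_structure(p$bound))
  expect_lt(bound_len, apo_len)
  expect_identical(attr(apo_len, "convention"),
                   "max pairwise CA-CA distance")
})
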