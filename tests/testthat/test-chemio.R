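test_that("mol2 files parse with atoms, bonds and charges preserved", {
  f <- withr::local_tempfile(fileext = ".mol2")
  ch <- c(-0.4123, 0.1031, 0.1031, 0.1030, 0.1031)
  writeLines(methane_mol2_text(ch), f)
  m <- read_molecule(f)
  expect_s3_class(m, "fragsig_molecule")
  expect_equal(nrow(m$atoms), 5)
  expect_equal(nrow(m$bonds), 4)
  expect_identical(m$atoms$element, c("C", "H", "H", "H", "H"))
  # charges equal the file's text fields bit-for-bit
  expect_identical(m$atoms$charge, ch)
})

test_that("multi-record mol2 files yield a sequence of molecules", {
  f <- withr::local_tempfile(fileext = ".mol2")
  writeLines(c(methane_mol2_text(), methane_mol2_text()), f)
  ms <- read_molecule(f)
  expect_length(ms, 2)
  expect_true(all(vapply(ms, inherits, logical(1), "fragsig_molecule")))
})

test_that("SDF records parse and 2D-only coordinates are rejected", {
  f <- withr::local_tempfile(fileext = ".sdf")
  writeLines(methane_sdf_text(), f)
  m <- read_molecule(f)
  expect_equal(nrow(m$atoms), 5)
  expect_equal(nrow(m$bonds), 4)
  f2 <- withr::local_tempfile(fileext = ".sdf")
  writeLines(gsub("0\\.6300", "0.0000", methane_sdf_text()), f2)
  expect_error(read_molecule(f2), "3D|coordinates|identical")
})

test_that("benzene fixture has the C6H6 formula and mol2 round trip is faithful", {
  b <- make_toy_molecule("benzene")
  expect_equal(sum(!b$atoms$is_h), 6)
  expect_equal(nrow(b$atoms), 12)
  hb <- b$bonds[!b$atoms$is_h[b$bonds$i] & !b$atoms$is_h[b$bonds$j], ]
  expect_equal(nrow(hb), 6)
  f <- withr::local_tempfile(fileext = ".mol2")
  write_molecule(b, f)
  b2 <- read_molecule(f)
  expect_equal(nrow(b2$atoms), nrow(b$atoms))
  expect_equal(as.matrix(b2$atoms[, c("x", "y", "z")]),
               as.matrix(b$atoms[, c("x", "y", "z")]), tolerance = 1e-4)
  key <- function(m) sort(paste(pmin(m$bonds$i, m$bonds$j), pmax(m$bonds$i, m$bonds$j)))
  expect_identical(key(b2), key(b))
  expect_true(all(abs(b2$atoms$charge - b$atoms$charge) <= 5e-5 + 1e-12))
})

test_that("radii assignment follows the named table and rejects unknown elements", {
  m <- single_atom_molecule("C")
  expect_equal(m$atoms$radius, 1.70)
  h <- single_atom_molecule("H")
  expect_equal(h$atoms$radius, 1.20)
  bad <- molecule("bad", tibble::tibble(element = "Xx", x = 0, y = 0, z = 0),
                  tibble::tibble(i = integer(), j = integer()))
  expect_error(assign_radii(bad), "Xx")
  # idempotence
  expect_identical(assign_radii(m)$atoms$radius, m$atoms$radius)
})

test_that("charge handling: keep-imported, gasteiger-type conservation, zero", {
  f <- withr::local_tempfile(fileext = ".mol2")
  writeLines(methane_mol2_text(), f)
  m <- read_molecule(f)
  kept <- ensure_charges(m, "keep-imported")
  expect_identical(kept$atoms$charge, m$atoms$charge)
  m$atoms$charge <- NA_real_
  expect_error(ensure_charges(m, "keep-imported"), "gasteiger|zero")
  g <- ensure_charges(m, "gasteiger")
  expect_lt(abs(sum(g$atoms$charge)), 1e-3)   # neutral molecule stays neutral
  expect_lt(g$atoms$charge[1], 0)             # C more electronegative than H
  z <- ensure_charges(m, "zero")
  expect_identical(z$atoms$charge, rep(0, 5))
})

test_that("gasteiger-type charges conserve neutrality on aromatic systems", {
  for (nm in c("benzene", "toluene", "naphthalene")) {
    m <- ensure_charges(make_toy_molecule(nm), "gasteiger")
    expect_lt(abs(sum(m$atoms$charge)), 1e-3)
  }
})
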