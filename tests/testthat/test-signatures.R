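# small hand-built traces with known segment lengths
two_segment_trace <- function(l1 = 4, l2 = 5, mep = -0.5) {
  new_raytrace(
    reflections = tibble::tibble(mep = c(0, mep, 0), fragment = c(1L, 1L, 1L),
                                 run = 1L),
    segments = tibble::tibble(length = c(l1, l2), from = 1L, to = 1L))
}

test_that("1D accumulation bins segments per fragment with conservation", {
  tr <- two_segment_trace()
  h <- accumulate_1d(tr, bin_width = 1)
  expect_length(h$intra, 1)
  hh <- h$intra[["1"]]
  expect_equal(hh$counts[5], 1)   # [4,5)
  expect_equal(hh$counts[6], 1)   # [5,6)
  expect_equal(hh$heights[5:6], c(0.5, 0.5))
  expect_equal(sum(hh$counts), 2)

  # identical lengths collapse into one full bin
  tr2 <- new_raytrace(
    reflections = tibble::tibble(mep = 0, fragment = 1L, run = 1L)[rep(1, 5), ],
    segments = tibble::tibble(length = rep(3.2, 4), from = 1L, to = 1L))
  h2 <- accumulate_1d(tr2, 0.5)$intra[["1"]]
  expect_equal(sum(h2$heights != 0), 1)
  expect_equal(max(h2$heights), 1)

  # intra + inter raw counts partition the segment list
  tr3 <- new_raytrace(
    reflections = tibble::tibble(mep = 0, fragment = c(1L, 1L, 2L, 2L, 1L), run = 1L),
    segments = tibble::tibble(length = c(2, 3, 4, 5),
                              from = c(1L, 1L, 2L, 2L), to = c(1L, 2L, 2L, 1L)))
  h3 <- accumulate_1d(tr3, 0.5)
  tot <- sum(vapply(c(h3$intra, h3$inter), function(x) sum(x$counts), numeric(1)))
  expect_equal(tot, 4)
  expect_named(h3$inter, "1|2")
})

test_that("the worked 2D example lands in the right shape and sign bins", {
  tr <- two_segment_trace(4, 5, mep = -0.5)
  red <- accumulate_2d(tr, bin_width = 0.5, mep_axis = "reduced")$intra[["1"]]
  # one interior reflection: shape value 4 + 5 = 9 A, negative potential
  expect_equal(sum(red$counts), 1)
  expect_equal(red$counts[floor(9 / 0.5) + 1, 1], 1)   # column 1 = negative
  inv <- accumulate_2d(tr, 0.5, "reduced_inverted")$intra[["1"]]
  expect_equal(inv$counts[floor(9 / 0.5) + 1, 2], 1)   # sign flipped
  full <- accumulate_2d(tr, 0.5, "full")$intra[["1"]]
  expect_equal(sum(full$counts), 1)
  K <- ceiling(0.5 / 0.025)
  expect_equal(full$counts[19, floor(-0.5 / 0.025) + K + 2], 1)
  # zero potential goes to the positive bin by convention
  tr0 <- two_segment_trace(4, 5, mep = 0)
  red0 <- accumulate_2d(tr0, 0.5, "reduced")$intra[["1"]]
  expect_equal(red0$counts[19, 2], 1)
})

test_that("2D attribution follows the principal-atom fragment and spans pairs", {
  tr <- new_raytrace(
    reflections = tibble::tibble(mep = c(0.1, -0.2, 0.3, 0.1),
                                 fragment = c(1L, 1L, 2L, 2L), run = 1L),
    segments = tibble::tibble(length = c(2, 3, 4),
                              from = c(1L, 1L, 2L), to = c(1L, 2L, 2L)))
  h <- accumulate_2d(tr, 0.5, "reduced")
  # reflection 2 (frag 1, neighbors 1 and 2) -> pair; reflection 3 (frag 2,
  # neighbors 1 and 2) -> pair
  expect_named(h$inter, "1|2")
  expect_equal(sum(h$inter[["1|2"]]$counts), 2)
  expect_length(h$intra, 0)
})

test_that("normalization is exact, idempotent, and guards empty histograms", {
  h <- new_hist1d(c(2, 2), 0.5)
  hn <- normalize(h)
  expect_equal(hn$heights, c(0.5, 0.5))
  expect_equal(sum(normalize(new_hist1d(c(1), 1))$heights), 1)
  expect_identical(normalize(hn)$heights, hn$heights)
  expect_identical(hn$counts, h$counts)          # raw counts preserved
  expect_error(normalize(new_hist1d(numeric(0), 1)), "empty")
})

test_that("global histogram reconstruction is exact on raw counts", {
  m <- make_toy_molecule("hexylbenzene")
  sig <- molecule_signature(m, n_segments = 2e4, seed = 3)
  g <- global_histogram(sig)
  # oracle: re-accumulate all segments directly, ignoring fragments
  fr <- assign_fragments(m)
  surf <- compute_vertex_mep(triangulate_surface(m), m)
  tr <- fragsig::trace(surf, fr, n_segments = 2e4, seed = 3)
  direct <- tabulate(floor(tr$segments$length / 0.5) + 1L)
  expect_equal(as.numeric(g$counts), as.numeric(direct))
  expect_equal(sum(g$heights), 1, tolerance = 1e-12)
  # single-fragment molecule: global equals the one intra histogram
  sigb <- molecule_signature(make_toy_molecule("benzene"), n_segments = 5e3, seed = 1)
  expect_equal(global_histogram(sigb)$counts, sigb$frag_sigs[["1"]]$h1$counts)
})

test_that("signatures survive a lossless serialization round trip", {
  sig <- molecule_signature(make_toy_molecule("biphenyl"), n_segments = 5e3, seed = 2)
  f <- withr::local_tempfile(fileext = ".fsig")
  write_signature(sig, f)
  sig2 <- read_signature(f)
  expect_identical(sig2$id, sig$id)
  expect_equal(sig2$params, sig$params)
  expect_equal(sig2$total_segments, sig$total_segments)
  for (k in names(sig$frag_sigs)) {
    expect_equal(sig2$frag_sigs[[k]]$count, sig$frag_sigs[[k]]$count)
    expect_equal(sig2$frag_sigs[[k]]$h1$counts, sig$frag_sigs[[k]]$h1$counts)
    expect_equal(sig2$frag_sigs[[k]]$h2_full$counts, sig$frag_sigs[[k]]$h2_full$counts)
  }
  for (k in names(sig$inter))
    expect_equal(sig2$inter[[k]]$h1$counts, sig$inter[[k]]$h1$counts)
  # corruption is detected
  raw <- readBin(f, "raw", file.info(f)$size)
  f2 <- withr::local_tempfile(fileext = ".fsig")
  writeBin(raw[1:floor(length(raw) * 0.7)], f2)
  expect_error(read_signature(f2), "checksum|read|corrupt")
  # XML export writes a parseable document
  fx <- withr::local_tempfile(fileext = ".xml")
  write_signature_xml(sig, fx)
  doc <- xml2::read_xml(fx)
  expect_equal(xml2::xml_name(doc), "shape-signature")
})

test_that("signatures with different binning are refused at comparison time", {
  a <- make_synthetic_signature(2, "path", seed = 1, bin_width = 0.5)
  b <- make_synthetic_signature(2, "path", seed = 2, bin_width = 0.25)
  expect_error(compare_molecules(a, b), "bin width")
  expect_error(l1_distance(a$frag_sigs[["1"]]$h1, b$frag_sigs[["1"]]$h1), "bin width")
})

test_that("doubling coordinates doubles the segment-length scale", {
  s1 <- make_sphere_mesh(1, 2)
  s2 <- make_sphere_mesh(2, 2)
  t1 <- fragsig::trace(s1, NULL, n_segments = 1e4, seed = 5)
  t2 <- fragsig::trace(s2, NULL, n_segments = 1e4, seed = 5)
  expect_equal(mean(t2$segments$length) / mean(t1$segments$length), 2,
               tolerance = 0.03)
})
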