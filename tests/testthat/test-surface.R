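test_that("a single atom gives a closed all-contact sphere with the right area", {
  m <- single_atom_molecule("C")          # r = 1.70
  s <- triangulate_surface(m, probe_radius = 1.4, spacing = 0.4)
  expect_equal(length(unique(s$component)), 1)
  expect_equal(surface_euler(s), 2)
  expect_true(all(surface_edge_counts(s) == 2))        # watertight
  expect_equal(sum(s$area), 4 * pi * 1.7^2, tolerance = 0.02)
  expect_true(all(s$class == "contact"))
  expect_true(all(s$atoms[, 1] == 1))
  expect_true(all(s$primary_atom == 1))
  # closed surface: area-weighted normals sum to ~0
  expect_lt(sqrt(sum(colSums(s$normal * s$area)^2)), 1e-6 * sum(s$area))
  # outward orientation
  expect_true(all(rowSums(s$normal * s$center) > 0))
})

test_that("mesh area converges to the analytic sphere area with density", {
  m <- single_atom_molecule("C")
  errs <- vapply(c(0.5, 0.25), function(h) {
    abs(sum(triangulate_surface(m, 1.4, h, classify = FALSE)$area) / (4 * pi * 1.7^2) - 1)
  }, numeric(1))
  expect_lt(errs[2], errs[1])             # finer grid, smaller error
  expect_lt(errs[2], 0.01)
})

test_that("surface components follow atom separation", {
  far <- molecule("far", tibble::tibble(element = c("C", "C"),
                                        x = c(0, 12), y = 0, z = 0),
                  tibble::tibble(i = integer(), j = integer()))
  far <- assign_radii(far)
  s <- triangulate_surface(far, 1.4, 0.4, classify = FALSE)
  expect_equal(length(unique(s$component)), 2)

  near <- diatomic_molecule(1.5)
  s2 <- triangulate_surface(near, 1.4, 0.4)
  expect_equal(length(unique(s2$component)), 1)
  expect_equal(surface_euler(s2), 2)
})

test_that("classification matches probe contact counts", {
  # diatomic: contact and saddle present, reentrant impossible with 2 atoms
  s <- triangulate_surface(diatomic_molecule(1.5), 1.4, 0.35)
  expect_true(all(c("contact", "saddle") %in% s$class))
  expect_false("reentrant" %in% s$class)
  expect_true(all(rowSums(!is.na(s$atoms)) == ifelse(s$class == "contact", 1, 2)))
  # tight triangle of atoms: probe bridges three atoms somewhere
  tri <- molecule("tri", tibble::tibble(
    element = "C", x = c(0, 2.9, 1.45), y = c(0, 0, 2.51), z = 0),
    tibble::tibble(i = c(1L, 2L, 1L), j = c(2L, 3L, 3L), order = "1"))
  tri <- assign_radii(tri)
  s3 <- triangulate_surface(tri, 1.4, 0.35)
  expect_gt(sum(s3$area[s3$class == "reentrant"]), 0)
})

test_that("classification is invariant under rigid-body motion", {
  m <- diatomic_molecule(1.5)
  s1 <- triangulate_surface(m, 1.4, 0.4)
  th <- 0.7
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  xyz <- as.matrix(m$atoms[, c("x", "y", "z")]) %*% t(Rz)
  m2 <- m
  m2$atoms$x <- xyz[, 1] + 3.1
  m2$atoms$y <- xyz[, 2] - 1.2
  m2$atoms$z <- xyz[, 3] + 0.4
  s2 <- triangulate_surface(m2, 1.4, 0.4)
  f1 <- table(s1$class) / length(s1$class)
  f2 <- table(s2$class) / length(s2$class)
  # class fractions are stable to a few percent (absolute), limited by the
  # grid discretization of the rotated surface
  expect_lt(max(abs(as.numeric(f2[names(f1)]) - as.numeric(f1))), 0.05)
})

test_that("primary atoms are the assigned atom nearest the element center", {
  s <- triangulate_surface(diatomic_molecule(1.5), 1.4, 0.4)
  m <- diatomic_molecule(1.5)
  xyz <- as.matrix(m$atoms[, c("x", "y", "z")])
  # saddle elements: primary is whichever of the two is closer
  sad <- which(s$class == "saddle")
  for (t in head(sad, 25)) {
    cand <- s$atoms[t, !is.na(s$atoms[t, ])]
    d <- sqrt(rowSums((xyz[cand, , drop = FALSE] -
                       matrix(s$center[t, ], length(cand), 3, byrow = TRUE))^2))
    expect_equal(s$primary_atom[t], cand[which.min(d)])
  }
  # contact elements: primary is their single atom
  expect_true(all(s$primary_atom[s$class == "contact"] ==
                  s$atoms[s$class == "contact", 1]))
})

test_that("vertex MEP is the Coulomb sum with the documented conventions", {
  m <- single_atom_molecule("C", charge = 1)
  s <- triangulate_surface(m, 1.4, 0.4)
  s <- compute_vertex_mep(s, m)
  expect_equal(mean(s$mep), 1 / 1.7, tolerance = 0.01)  # q / (eps * r)
  # zero charges give exactly zero potential
  m0 <- m
  m0$atoms$charge <- 0
  expect_true(all(compute_vertex_mep(s, m0)$mep == 0))
  # linearity: negating the charge negates the potential
  mneg <- m
  mneg$atoms$charge <- -1
  expect_equal(compute_vertex_mep(s, mneg)$mep, -s$mep)
  # dielectric scales inversely
  expect_equal(compute_vertex_mep(s, m, dielectric = 2)$mep, s$mep / 2)
})

test_that("degenerate inputs are rejected", {
  dup <- molecule("dup", tibble::tibble(element = c("C", "C"), x = 0, y = 0, z = 0),
                  tibble::tibble(i = integer(), j = integer()))
  dup <- assign_radii(dup)
  expect_error(triangulate_surface(dup, 1.4, 0.5), "overlapping")
  m <- single_atom_molecule("C")
  m$atoms$radius <- NA_real_
  expect_error(triangulate_surface(m, 1.4, 0.5), "radii")
})
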