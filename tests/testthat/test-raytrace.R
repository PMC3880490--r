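test_that("grid assignment is by corner membership, 1 to 3 cubes per element", {
  box <- make_box_mesh(2, 4)
  g <- build_grid(box, spacing = 1.0)
  ncubes <- vapply(g$element_cubes, nrow, integer(1))
  expect_true(all(ncubes >= 1 & ncubes <= 3))
  expect_length(g$element_cubes, nrow(box$triangles))    # completeness
  # a small triangle straddling no grid plane sits in exactly one cube;
  # corners split across cube boundaries give more cubes
  surf1 <- fragsig:::new_surface(
    rbind(c(0.1, 0.1, 0.1), c(0.3, 0.1, 0.1), c(0.2, 0.3, 0.1)),
    matrix(c(1L, 2L, 3L), 1, 3))
  g1 <- fragsig:::.cpp_grid_assign(surf1$vertices, surf1$triangles, 1.0)
  expect_equal(nrow(g1$element_cubes[[1]]), 1)
  surf3 <- fragsig:::new_surface(
    rbind(c(0.5, 0.5, 0.5), c(1.5, 0.5, 0.5), c(0.5, 1.5, 0.5)),
    matrix(c(1L, 2L, 3L), 1, 3))
  g3 <- fragsig:::.cpp_grid_assign(surf3$vertices, surf3$triangles, 1.0)
  expect_equal(nrow(g3$element_cubes[[1]]), 3)
})

test_that("rays start on contact elements, antiparallel to the outward normal", {
  sph <- make_sphere_mesh(1, 2)
  for (seed in c(0, 1, 99)) {
    st <- start_ray(sph, seed = seed)
    expect_identical(sph$class[st$element], "contact")
    expect_equal(sum(st$direction * sph$normal[st$element, ]), -1, tolerance = 1e-12)
  }
  expect_identical(start_ray(sph, seed = 5), start_ray(sph, seed = 5))
})

test_that("reflection follows the mirror law and cone sampling stays in the cap", {
  expect_equal(reflect(c(0, 0, -1), c(0, 0, 1), 0), c(0, 0, 1))
  r <- reflect(c(sqrt(2) / 2, 0, -sqrt(2) / 2), c(0, 0, 1), 0)
  expect_equal(r, c(sqrt(2) / 2, 0, sqrt(2) / 2), tolerance = 1e-12)
  # cone 5 degrees: deviation bounded, azimuth empirically uniform
  ideal <- c(0, 0, 1)
  outs <- t(vapply(seq_len(10000), function(s) reflect(c(0, 0, -1), c(0, 0, 1), 5, seed = s),
                   numeric(3)))
  dev <- acos(pmin(1, outs %*% ideal)) * 180 / pi
  expect_lt(max(dev), 5 + 1e-6)
  az <- atan2(outs[, 2], outs[, 1])
  counts <- table(cut(az, breaks = seq(-pi, pi, length.out = 13)))
  expect_gt(stats::chisq.test(counts)$p.value, 1e-4)
  # polar angle matches uniform-cap sampling: cos(dev) uniform on [cos 5deg, 1]
  u <- (cos(dev * pi / 180) - cos(5 * pi / 180)) / (1 - cos(5 * pi / 180))
  expect_gt(stats::ks.test(u, "punif")$p.value, 1e-4)
})

test_that("next_reflection finds the diameter chord and matches brute force", {
  sph <- make_sphere_mesh(1, 3)
  st <- start_ray(sph, seed = 3)
  hit <- next_reflection(sph, st$point, st$direction, exclude = st$element)
  edge <- fragsig:::max_edge_length(sph)
  expect_lt(abs(hit$t - 2), 2 * edge)          # analytic chord 2R
  expect_true(all(hit$bary >= -1e-6 & hit$bary <= 1 + 1e-6))
  expect_equal(sum(hit$bary), 1, tolerance = 1e-9)

  # grid-accelerated result equals the all-element scan on random states
  box <- make_box_mesh(2, 5)
  u <- fragsig:::splitmix_runif(17, 1200)
  p <- c(0.1, -0.3, 0.2)
  d <- c(0.4, 0.45, -0.8); d <- d / sqrt(sum(d^2))
  excl <- 0L
  for (i in 1:200) {
    hg <- next_reflection(box, p, d, exclude = excl, brute = FALSE)
    hb <- next_reflection(box, p, d, exclude = excl, brute = TRUE)
    if (is.null(hb)) {               # exact edge exit: both must agree
      expect_null(hg)
      break
    }
    expect_identical(hg$element, hb$element)
    expect_equal(hg$t, hb$t, tolerance = 1e-12)
    p <- hg$position
    d <- reflect(d, box$normal[hg$element, ], 0)
    excl <- hg$element
  }
})

test_that("rays escaping through an artificial hole signal failure", {
  box <- make_box_mesh(2, 4)
  top <- box$center[, 3] > 0.99
  holed <- fragsig:::new_surface(box$vertices, box$triangles[!top, , drop = FALSE])
  hit <- next_reflection(holed, c(0, 0, 0), c(0, 0, 1), exclude = 0L)
  expect_null(hit)
})

test_that("trace records consistent runs, fragments and reproducible output", {
  sph <- make_sphere_mesh(1, 2)
  tr <- fragsig::trace(sph, NULL, n_segments = 2000, cone_angle = 3, seed = 4)
  expect_gte(nrow(tr$segments), 2000)
  expect_true(all(tr$segments$kind == "intra"))   # single implicit fragment
  # segments = reflections - runs
  expect_equal(nrow(tr$segments),
               nrow(tr$reflections) - length(unique(tr$reflections$run)))
  tr2 <- fragsig::trace(sph, NULL, n_segments = 2000, cone_angle = 3, seed = 4)
  expect_identical(tr$reflections, tr2$reflections)
  expect_identical(tr$segments, tr2$segments)
  # reflection points lie on their element's plane
  idx <- seq(1, nrow(tr$reflections), length.out = 50)
  for (i in idx) {
    el <- tr$reflections$element[i]
    v1 <- sph$vertices[sph$triangles[el, 1], ]
    p <- c(tr$reflections$x[i], tr$reflections$y[i], tr$reflections$z[i])
    expect_lt(abs(sum((p - v1) * sph$normal[el, ])), 1e-6)
  }
})

test_that("mean segment length matches the 4V/S chord oracle on the box", {
  box <- make_box_mesh(2, 6)
  tr <- fragsig::trace(box, NULL, n_segments = 3e4, cone_angle = 3, seed = 9)
  expect_equal(mean(tr$segments$length), 2 * 2 / 3, tolerance = 0.02)
})
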