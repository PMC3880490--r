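test_that("the L1 score has the documented bounds and metric behavior", {
  a <- normalize(new_hist1d(c(1, 1), 1))
  expect_equal(l1_distance(a, a), 0)
  d1 <- normalize(new_hist1d(c(1, 0), 1))
  d2 <- normalize(new_hist1d(c(0, 1), 1))
  expect_equal(l1_distance(d1, d2), 2)                 # disjoint support
  expect_equal(l1_distance(a, d1), 1)                  # [.5,.5] vs [1,0]
  # shorter histogram is padded with zeros
  expect_equal(l1_distance(normalize(new_hist1d(1, 1)),
                           normalize(new_hist1d(c(0.5, 0.5), 1))), 1)
  # metric properties on random triples
  for (i in 1:25) {
    u <- fragsig:::splitmix_runif(400 + i, 30)
    h <- lapply(0:2, function(k) normalize(new_hist1d(u[k * 10 + 1:10], 1)))
    expect_equal(l1_distance(h[[1]], h[[2]]), l1_distance(h[[2]], h[[1]]))
    expect_lte(l1_distance(h[[1]], h[[3]]),
               l1_distance(h[[1]], h[[2]]) + l1_distance(h[[2]], h[[3]]) + 1e-12)
  }
})

test_that("mapping enumeration matches the brute-force maximal oracle", {
  expect_length(enumerate_mappings(path_adj(1), path_adj(1)), 1)
  expect_length(enumerate_mappings(path_adj(2), path_adj(2)), 2)
  for (m in 1:4) for (n in 1:4) {
    got <- canon_set(enumerate_mappings(path_adj(m), path_adj(n)))
    want <- canon_set(brute_maximal_mappings(path_adj(m), path_adj(n)))
    expect_identical(got, want, label = sprintf("paths %d vs %d", m, n))
  }
  graphs <- list(star_adj(3), star_adj(4), tri_adj(), path_adj(4))
  for (a in graphs) for (b in graphs) {
    got <- canon_set(enumerate_mappings(a, b))
    want <- canon_set(brute_maximal_mappings(a, b))
    expect_identical(got, want)
  }
})

test_that("every enumerated mapping is consistent, injective and maximal", {
  Aq <- star_adj(4)
  At <- path_adj(3)
  for (L in enumerate_mappings(Aq, At)) {
    expect_equal(anyDuplicated(L[, 1]), 0)
    expect_equal(anyDuplicated(L[, 2]), 0)
    if (nrow(L) >= 2) {
      for (a in 1:(nrow(L) - 1)) for (b in (a + 1):nrow(L)) {
        if (Aq[L[a, 1], L[b, 1]] == 1) expect_equal(At[L[a, 2], L[b, 2]], 1)
      }
    }
  }
})

test_that("the closed-form linear mapping count matches direct enumeration", {
  expect_identical(linear_mapping_count(5, 5), 85L)
  expect_identical(linear_mapping_count(1, 1), 1L)
  expect_identical(linear_mapping_count(2, 3), 10L)
  for (m in 1:6) for (n in 1:6)
    expect_identical(linear_mapping_count(m, n), as.integer(count_contiguous_mappings(m, n)),
                     label = sprintf("m=%d n=%d", m, n))
})

test_that("the score transform has its fixed points and domain guard", {
  expect_equal(transform_score(2), 0)
  expect_equal(transform_score(1), 1)
  expect_equal(transform_score(0.25), 3)
  expect_error(transform_score(0), "s > 0")
  expect_error(transform_score(-1), "s > 0")
})

test_that("mapped scores apply count weighting exactly", {
  # distances are controlled through prescribed histograms:
  # frag pair (q1,t1): L1 = 0.2; (q2,t2): L1 = 1.0
  hq1 <- c(0.9, 0.1); ht1 <- c(1.0, 0.0)          # L1 = 0.2
  hq2 <- c(0.5, 0.5); ht2 <- c(1.0, 0.0)          # L1 = 1.0
  adj2 <- tibble::tibble(a = 1L, b = 2L)
  qs <- prescribed_signature("q", list(hq1, hq2), c(100, 300), adj2)
  ts <- prescribed_signature("t", list(ht1, ht2), c(200, 200), adj2)
  M <- cbind(query = 1:2, target = 1:2)
  sc <- mapped_score(qs, ts, M)
  expect_equal(sc$score, ((100 + 200) * 0.2 + (300 + 200) * 1.0) / 800)
  expect_equal(sc$unused_query, 0)
  expect_equal(sc$unused_target, 0)
  # single link: weights cancel, score is the plain distance
  sc1 <- mapped_score(qs, ts, cbind(1L, 1L))
  expect_equal(sc1$score, 0.2)
  expect_equal(sc1$unused_query, 100 * 300 / 400)  # 75% of query unused
  # equal counts: unweighted mean
  qe <- prescribed_signature("qe", list(hq1, hq2), c(100, 100), adj2)
  te <- prescribed_signature("te", list(ht1, ht2), c(100, 100), adj2)
  expect_equal(mapped_score(qe, te, M)$score, (0.2 + 1.0) / 2)
  expect_error(mapped_score(qs, ts, M[0, , drop = FALSE]), "empty")
})

test_that("mapped scoring is symmetric under swapping query and target", {
  qs <- make_synthetic_signature(3, "path", seed = 11)
  ts <- make_synthetic_signature(4, "path", seed = 12)
  for (L in enumerate_mappings(qs, ts)) {
    Linv <- cbind(query = L[, 2], target = L[, 1])
    Linv <- Linv[order(Linv[, 1]), , drop = FALSE]
    expect_equal(mapped_score(qs, ts, L)$score, mapped_score(ts, qs, Linv)$score)
  }
})

test_that("compare_molecules ranks mappings and applies the unused filter", {
  s <- make_synthetic_signature(3, "path", seed = 21)
  cmp <- compare_molecules(s, s)
  expect_equal(cmp$best$score, 0)
  expect_equal(nrow(cmp$best$mapping), 3)        # identity among the best
  expect_true(all(diff(cmp$results$score) >= 0))
  expect_true(is.infinite(cmp$best$transformed))
  # a 2-fragment query against a single-fragment target always leaves about
  # half the query unused: a strict filter removes every mapping
  q2 <- make_synthetic_signature(2, "path", seed = 22)
  t1 <- make_synthetic_signature(1, "path", seed = 23)
  strict <- compare_molecules(q2, t1, max_unused = 5)
  expect_null(strict$best)
  expect_equal(nrow(strict$results), 0)
  open <- compare_molecules(q2, t1, max_unused = NULL)
  expect_gt(nrow(open$results), 0)
})
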