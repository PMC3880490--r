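synthetic_db <- function(n = 10, seed0 = 100) {
  sigs <- lapply(seq_len(n), function(k) {
    u <- fragsig:::splitmix_runif(seed0 + k, 2)
    make_synthetic_signature(1 + (k %% 4), if (u[1] < 0.5) "path" else "star",
                             seed = seed0 + k)
  })
  build_db(sigs)
}

test_that("databases hold one signature per unique id and guard parameters", {
  db <- synthetic_db(10)
  expect_length(db$signatures, 10)
  expect_length(db$reduced, 10)
  # ingesting the same signatures again skips them as duplicates
  db2 <- suppressMessages(build_db(c(unname(db$signatures), unname(db$signatures))))
  expect_length(db2$signatures, 10)
  expect_equal(db2$duplicates, 10)
  # mixed bin widths are refused
  odd <- make_synthetic_signature(2, "path", seed = 999, bin_width = 0.25)
  expect_error(build_db(c(unname(db$signatures)[1], list(odd))), "different")
})

test_that("databases round trip through their container file", {
  db <- synthetic_db(5)
  f <- withr::local_tempfile(fileext = ".fsigdb")
  write_db(db, f)
  db2 <- read_db(f)
  expect_identical(names(db2$signatures), names(db$signatures))
  expect_equal(db2$params$bin_width, db$params$bin_width)
  k <- names(db$signatures)[3]
  expect_equal(db2$signatures[[k]]$frag_sigs[["1"]]$h1$counts,
               db$signatures[[k]]$frag_sigs[["1"]]$h1$counts)
  # wrong kind is refused
  sig <- db$signatures[[1]]
  f2 <- withr::local_tempfile(fileext = ".fsig")
  write_signature(sig, f2)
  expect_error(read_db(f2), "kind|holds")
})

test_that("prefilter returns its query with a near-zero bound and respects K", {
  db <- synthetic_db(12)
  q <- db$signatures[[4]]
  pf <- prefilter_search(q, db, K = 12)
  expect_equal(nrow(pf), 12)
  expect_lt(pf$bound[pf$id == q$id], 1e-9)
  expect_true(all(diff(pf$bound) >= 0))
  expect_equal(nrow(prefilter_search(q, db, K = 1e6)), 12)  # clamped to DB size
  expect_error(prefilter_search(q, db, K = 0), "positive")
})

test_that("the prefilter bound never exceeds the best full mapped score", {
  db <- synthetic_db(8, seed0 = 300)
  viol <- 0
  for (k in 1:6) {
    q <- make_synthetic_signature(1 + (k %% 4), "path", seed = 500 + k)
    pf <- prefilter_search(q, db, K = 8)
    for (id in pf$id) {
      full <- compare_molecules(q, db$signatures[[id]])$best$score
      if (pf$bound[pf$id == id] > full + 1e-9) viol <- viol + 1
    }
  }
  expect_equal(viol, 0)
})

test_that("full search ranks self first with deterministic ordered output", {
  db <- synthetic_db(10)
  q <- db$signatures[[7]]
  hits <- full_search(q, db, max_unused = NULL)
  expect_s3_class(hits, "fragsig_hitlist")
  expect_identical(hits$id[1], q$id)
  expect_true(all(diff(hits$score) >= 0))
  expect_identical(hits$rank, seq_len(nrow(hits)))
  hits2 <- full_search(q, db, max_unused = NULL)
  expect_identical(hits, hits2)
  # unused-fraction filter removes candidates with no acceptable mapping
  hits3 <- full_search(q, db, max_unused = 0.5)
  expect_true(all(hits3$unused_query <= 0.5 & hits3$unused_target <= 0.5))
  expect_error(full_search(q, db, candidates = "no_such_id"), "not in the database")
})

test_that("hit-list merging is a non-redundant best-score union", {
  db <- synthetic_db(10)
  h1 <- full_search(db$signatures[[1]], db, max_unused = NULL, max_hits = 5)
  h2 <- full_search(db$signatures[[9]], db, max_unused = NULL, max_hits = 5)
  mg <- merge_hitlists(h1, h2)
  expect_equal(anyDuplicated(mg$id), 0)
  expect_setequal(mg$id, union(h1$id, h2$id))
  for (id in intersect(h1$id, h2$id))
    expect_equal(mg$score[mg$id == id], min(h1$score[h1$id == id], h2$score[h2$id == id]))
  expect_true(all(diff(mg$score) >= 0))
  # merging a single list is the identity up to re-ranking
  expect_identical(merge_hitlists(h1)$id, h1$id)
})

test_that("ROC construction is monotone and matches an independent AUC", {
  # perfect separation
  sc <- tibble::tibble(id = paste0("m", 1:10), score = c(1:5 / 10, 6:10 / 5))
  lab <- setNames(rep(c(TRUE, FALSE), each = 5), sc$id)
  roc <- roc_points(sc, lab)
  expect_true(any(roc$fpr == 0 & roc$tpr == 1))
  expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
  expect_error(roc_points(sc, setNames(rep(TRUE, 10), sc$id)), "both")
  # random scores: AUC agrees with pROC and is near 1/2
  u <- fragsig:::splitmix_runif(77, 400)
  sc2 <- tibble::tibble(id = paste0("r", 1:200), score = u[1:200])
  lab2 <- setNames(u[201:400] < 0.5, sc2$id)
  roc2 <- roc_points(sc2, lab2)
  auc_trap <- sum(diff(c(0, roc2$fpr, 1)) * (c(0, roc2$tpr) + c(roc2$tpr, 1)) / 2)
  p <- pROC::roc(response = lab2[sc2$id], predictor = -sc2$score,
                 levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  expect_equal(auc_trap, as.numeric(pROC::auc(p)), tolerance = 0.01)
  expect_lt(abs(auc_trap - 0.5), 0.12)   # ~3 sd at 100/100 labels
})
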