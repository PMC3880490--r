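#' L1 distance between two normalized histograms
#'
#' The discretized L1 metric `S(q,t) = sum_mu |h_mu^q - h_mu^t|` over
#' corresponding bins, in units of probability: 0 for identical histograms,
#' 2 for distributions with no common support.  The shorter histogram is
#' padded with zero bins; histograms with different bin widths or different
#' MEP axes are incomparable and raise an error.
#'
#' @param hq,ht two `fragsig_hist1d` or two `fragsig_hist2d` objects.
#' @return the score, in `[0, 2]`.
#' @export
l1_distance <- function(hq, ht) {
  if (!identical(class(hq), class(ht)))
    stop("histograms of different dimensionality are incomparable")
  if (abs(hq$bin_width - ht$bin_width) > 1e-12)
    stop("histograms with different bin widths are incomparable ",
         "(database and query must be generated with the same bin width)")
  if (inherits(hq, "fragsig_hist2d")) {
    if (hq$mep_axis != ht$mep_axis)
      stop("histograms with different MEP axes are incomparable")
    if (hq$mep_axis == "full" &&
        (abs(hq$mep_bin_width - ht$mep_bin_width) > 1e-12 || hq$mep_max != ht$mep_max))
      stop("histograms with different MEP binning are incomparable")
    a <- if (hq$normalized) hq$heights else normalize(hq)$heights
    b <- if (ht$normalized) ht$heights else normalize(ht)$heights
    nr <- max(nrow(a), nrow(b))
    pa <- matrix(0, nr, ncol(a)); pa[seq_len(nrow(a)), ] <- a
    pb <- matrix(0, nr, ncol(b)); pb[seq_len(nrow(b)), ] <- b
    return(sum(abs(pa - pb)))
  }
  a <- if (hq$normalized) hq$heights else normalize(hq)$heights
  b <- if (ht$normalized) ht$heights else normalize(ht)$heights
  n <- max(length(a), length(b))
  sum(abs(c(a, rep(0, n - length(a))) - c(b, rep(0, n - length(b)))))
}

#' Closed-form mapping count for linear fragment topologies
#'
#' For query and target whose fragment adjacency graphs are paths of `m`
#' and `n` fragments, the number of contiguous-interval mappings is
#' `m*n + 2 * sum_{k=2}^{min(m,n)} (m-k+1)(n-k+1)`: the first term counts
#' single-link mappings and the factor 2 accounts for the two possible
#' orientations of mappings with two or more links.
#'
#' @param m,n fragment counts of query and target.
#' @return integer mapping count.
#' @export
linear_mapping_count <- function(m, n) {
  stopifnot(m >= 1, n >= 1)
  kmax <- min(m, n)
  extra <- if (kmax >= 2) {
    k <- 2:kmax
    2 * sum((m - k + 1) * (n - k + 1))
  } else 0
  as.integer(m * n + extra)
}

# adjacency matrix from an igraph / matrix / fragsig_signature
as_adjacency <- function(g) {
  if (inherits(g, "fragsig_signature")) {
    ids <- g$fragments$fragment
    A <- matrix(0L, length(ids), length(ids))
    if (nrow(g$adjacency) > 0) {
      ia <- match(g$adjacency$a, ids); ib <- match(g$adjacency$b, ids)
      A[cbind(ia, ib)] <- 1L
      A[cbind(ib, ia)] <- 1L
    }
    return(A)
  }
  if (inherits(g, "igraph"))
    return(as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE)) > 0)
  as.matrix(g) > 0
}

#' Enumerate maximal connectivity-consistent fragment mappings
#'
#' A mapping is a set of links (query fragment, target fragment), injective
#' in both directions, and consistent with chemistry: whenever two mapped
#' query fragments are bonded, their images must be bonded in the target.
#' Enumeration starts from all single-fragment links and expands each
#' recursively in every consistent way, deduplicating as it goes; expansion
#' is greedy, so a mapping is retained only when no further link can be
#' added (single links survive only when nothing extends them).  Not every
#' fragment need be covered: substructure matches are first-class results.
#'
#' @param qgraph,tgraph fragment adjacency: an \pkg{igraph} graph, a 0/1
#'   matrix, or a `fragsig_signature`.
#' @return list of mappings, each an integer matrix with columns `query`,
#'   `target`, rows sorted by query fragment.
#' @export
enumerate_mappings <- function(qgraph, tgraph) {
  Aq <- as_adjacency(qgraph)
  At <- as_adjacency(tgraph)
  m <- nrow(Aq); n <- nrow(At)
  if (m == 0 || n == 0) stop("empty fragment graph")
  results <- new.env(parent = emptyenv())
  seen <- new.env(parent = emptyenv())
  key_of <- function(links) paste(links[, 1], links[, 2], sep = "-", collapse = ",")

  extension_ok <- function(links, x, mu) {
    # consistency of the candidate link against every existing link
    for (r in seq_len(nrow(links))) {
      y <- links[r, 1]; nu <- links[r, 2]
      if (Aq[x, y] && !At[mu, nu]) return(FALSE)
      if (Aq[y, x] && !At[nu, mu]) return(FALSE)
    }
    TRUE
  }
  expand <- function(links) {
    k <- key_of(links)
    if (!is.null(seen[[k]])) return(invisible())
    seen[[k]] <- TRUE
    free_q <- setdiff(seq_len(m), links[, 1])
    free_t <- setdiff(seq_len(n), links[, 2])
    extended <- FALSE
    for (x in free_q) for (mu in free_t) {
      if (extension_ok(links, x, mu)) {
        extended <- TRUE
        nl <- rbind(links, c(x, mu))
        nl <- nl[order(nl[, 1]), , drop = FALSE]
        expand(nl)
      }
    }
    if (!extended) results[[k]] <- links
  }
  for (x in seq_len(m)) for (mu in seq_len(n))
    expand(matrix(c(x, mu), 1, 2))
  out <- as.list(results)
  out <- lapply(out, function(L) {
    colnames(L) <- c("query", "target")
    L
  })
  # deterministic order: more links first, then lexicographic link list
  keys <- vapply(out, function(L) sprintf("%04d|%s", 9999 - nrow(L),
                                          paste(t(L), collapse = ",")), character(1))
  unname(out[order(keys)])
}

#' Transform a raw distance score to the similarity scale
#'
#' `T(s) = 1 - log2(s)`: zero at the maximal inter-descriptor distance of
#' 2, increasing without bound as the raw distance approaches zero.
#'
#' @param s raw L1-based score, `s > 0`.
#' @return transformed score.
#' @export
transform_score <- function(s) {
  if (any(s <= 0)) stop("transform_score requires s > 0 (stochastic signatures ",
                        "essentially never produce an exact 0)")
  1 - log2(s)
}

pick_hist <- function(fs, variant) {
  switch(variant, "1d" = fs$h1, "2d_full" = fs$h2_full, "2d_reduced" = fs$h2_reduced,
         "2d_reduced_inverted" = fs$h2_reduced_inverted,
         stop("unknown descriptor variant '", variant, "'"))
}

check_compatible <- function(qsig, tsig) {
  p <- qsig$params; q <- tsig$params
  if (abs(p$bin_width - q$bin_width) > 1e-12)
    stop("signatures generated with different bin widths are incomparable")
  if (!isTRUE(all.equal(p$mep_bin_width, q$mep_bin_width)) ||
      !isTRUE(all.equal(p$mep_max, q$mep_max)))
    stop("signatures generated with different MEP binning are incomparable")
  invisible(TRUE)
}

#' Score two signatures under a fragment mapping
#'
#' Count-weighted average of per-link L1 distances:
#' `S(q,t/M) = sum_m (c_x + c_mu) S(f_x, f_mu) / sum_m (c_x + c_mu)` where
#' `c` are the intra-fragment segment counts of the linked fragments.  The
#' unused fractions report, per molecule, the percentage of ray-trace
#' segments lying in fragments not covered by the mapping.
#'
#' @param qsig,tsig `fragsig_signature` objects with identical generation
#'   parameters.
#' @param mapping a link matrix as returned by [enumerate_mappings()]
#'   (columns `query`, `target`, 1-based fragment positions).
#' @param variant `"1d"` (the default used for screening), `"2d_full"`,
#'   `"2d_reduced"`, or `"2d_reduced_inverted"`.
#' @return a `fragsig_mapped_score`: list with `score`, `transformed`,
#'   `unused_query`, `unused_target` (percent), `mapping`, `variant`.
#' @export
mapped_score <- function(qsig, tsig, mapping, variant = "1d") {
  check_compatible(qsig, tsig)
  if (is.null(mapping) || nrow(mapping) == 0) stop("empty mapping")
  qf <- qsig$frag_sigs
  tf <- tsig$frag_sigs
  w <- numeric(nrow(mapping))
  s <- numeric(nrow(mapping))
  for (r in seq_len(nrow(mapping))) {
    a <- qf[[mapping[r, 1]]]
    b <- tf[[mapping[r, 2]]]
    if (is.null(a) || is.null(b)) stop("mapping refers to a missing fragment")
    w[r] <- a$count + b$count
    s[r] <- l1_distance(pick_hist(a, variant), pick_hist(b, variant))
  }
  score <- sum(w * s) / sum(w)
  unused_q <- 100 * sum(vapply(qf[-mapping[, 1]], function(f) f$count, numeric(1))) /
    qsig$total_segments
  unused_t <- 100 * sum(vapply(tf[-mapping[, 2]], function(f) f$count, numeric(1))) /
    tsig$total_segments
  structure(list(score = score,
                 transformed = if (score > 0) transform_score(score) else Inf,
                 unused_query = unused_q, unused_target = unused_t,
                 mapping = mapping, variant = variant),
            class = "fragsig_mapped_score")
}

#' @export
print.fragsig_mapped_score <- function(x, ...) {
  cat(sprintf("<fragsig_mapped_score> s = %.4f (T = %.2f), %d link(s), unused q/t = %.1f%% / %.1f%% [%s]\n",
              x$score, x$transformed, nrow(x$mapping), x$unused_query,
              x$unused_target, x$variant))
  invisible(x)
}

mapping_label <- function(mapping) {
  paste(sprintf("%d-%d", mapping[, 1], mapping[, 2]), collapse = ",")
}

#' Compare two molecules over all maximal fragment mappings
#'
#' Enumerates every greedy-maximal connectivity-consistent mapping between
#' the fragment graphs, scores each with [mapped_score()], and returns the
#' results ordered by ascending raw score (ties: more links first, then
#' lexicographic link list).  Optionally drops mappings whose unused
#' fraction exceeds a threshold in either molecule, the filter used for
#' library screening.
#'
#' @param qsig,tsig signatures to compare.
#' @param variant descriptor variant, see [mapped_score()].
#' @param max_unused optional percentage threshold; mappings leaving more
#'   than this fraction of query or target segments unused are dropped
#'   (`NULL` = keep everything).
#' @return list with `best` (a `fragsig_mapped_score`, or `NULL` if all
#'   mappings were filtered) and `results`, a tibble with one row per
#'   retained mapping (score, transformed, links, unused percentages,
#'   mapping label).
#' @export
compare_molecules <- function(qsig, tsig, variant = "1d", max_unused = NULL) {
  check_compatible(qsig, tsig)
  maps <- enumerate_mappings(qsig, tsig)
  scored <- lapply(maps, function(L) mapped_score(qsig, tsig, L, variant))
  keep <- if (is.null(max_unused)) rep(TRUE, length(scored)) else
    vapply(scored, function(x) x$unused_query <= max_unused &&
             x$unused_target <= max_unused, logical(1))
  scored <- scored[keep]
  if (length(scored) == 0)
    return(list(best = NULL, results = tibble(
      score = numeric(), transformed = numeric(), n_links = integer(),
      unused_query = numeric(), unused_target = numeric(), mapping = character())))
  res <- tibble(
    score = vapply(scored, function(x) x$score, numeric(1)),
    transformed = vapply(scored, function(x) x$transformed, numeric(1)),
    n_links = vapply(scored, function(x) nrow(x$mapping), integer(1)),
    unused_query = vapply(scored, function(x) x$unused_query, numeric(1)),
    unused_target = vapply(scored, function(x) x$unused_target, numeric(1)),
    mapping = vapply(scored, function(x) mapping_label(x$mapping), character(1)))
  ord <- order(res$score, -res$n_links, res$mapping)
  res <- res[ord, ]
  res$rank <- seq_len(nrow(res))
  list(best = scored[[ord[1]]], results = res)
}
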