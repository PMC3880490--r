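#' Build a signature database for a molecule library
#'
#' Generates one signature per unique molecule id and stores them under a
#' single generation-parameter header; a database mixes exactly one
#' parameter set, because signatures generated with different bin widths or
#' trace settings are incomparable.  Duplicate ids are skipped and counted.
#' A reduced companion (per-fragment shape-only histograms plus segment
#' counts, connectivity ignored) is assembled in the same pass for the
#' prefilter.
#'
#' @param inputs molecule files (mol2/sdf paths, or a directory of them), a
#'   list of `fragsig_molecule`, or a list of precomputed
#'   `fragsig_signature` objects (which must share generation parameters).
#' @param params named list of [molecule_signature()] arguments applied to
#'   every molecule.
#' @param seed base ray-trace seed; molecule `k` of the library uses
#'   `seed + k - 1`.
#' @return a `fragsig_db`: `params`, `signatures` (named list),
#'   `reduced`, `duplicates` (count of skipped duplicate ids).
#' @export
build_db <- function(inputs, params = list(), seed = 0) {
  sigs <- list()
  dup <- 0L
  push <- function(sig) {
    if (!is.null(sigs[[sig$id]])) {
      dup <<- dup + 1L
      return(invisible())
    }
    if (length(sigs) > 0) {
      ok <- tryCatch({
        check_compatible(sigs[[1]], sig)
        TRUE
      }, error = function(e) FALSE)
      if (!ok) stop("signature for '", sig$id, "' was generated with different ",
                    "parameters than the database header")
    }
    sigs[[sig$id]] <<- sig
  }
  if (is.character(inputs)) {
    files <- unlist(lapply(inputs, function(p) {
      if (dir.exists(p)) list.files(p, pattern = "\\.(mol2|sdf|sd|mol)$",
                                    full.names = TRUE)
      else p
    }))
    mols <- list()
    for (f in files) {
      m <- read_molecule(f)
      mols <- c(mols, if (inherits(m, "fragsig_molecule")) list(m) else m)
    }
    inputs <- mols
  }
  k <- 0L
  for (x in inputs) {
    k <- k + 1L
    if (inherits(x, "fragsig_signature")) {
      push(x)
    } else if (inherits(x, "fragsig_molecule")) {
      args <- c(list(mol = x, seed = seed + k - 1L), params)
      push(do.call(molecule_signature, args))
    } else {
      stop("build_db inputs must be files, molecules, or signatures")
    }
  }
  if (length(sigs) == 0) stop("no molecules to index")
  if (dup > 0) message(dup, " duplicate id(s) skipped")
  new_db(sigs, dup)
}

new_db <- function(sigs, duplicates = 0L) {
  structure(list(params = sigs[[1]]$params, signatures = sigs,
                 reduced = lapply(sigs, reduced_record), duplicates = duplicates),
            class = "fragsig_db")
}

# reduced descriptor: 1D shape-only per-fragment histograms + counts,
# fragment connectivity deliberately dropped
reduced_record <- function(sig) {
  list(id = sig$id,
       counts = vapply(sig$frag_sigs, function(f) f$count, numeric(1)),
       h1 = lapply(sig$frag_sigs, function(f) f$h1),
       m = length(sig$frag_sigs),
       adjacency_info = list(n_edges = nrow(sig$adjacency),
                             degree = fragment_degrees(sig)))
}

fragment_degrees <- function(sig) {
  ids <- sig$fragments$fragment
  deg <- setNames(rep(0L, length(ids)), as.character(ids))
  if (nrow(sig$adjacency) > 0) {
    t1 <- table(as.character(sig$adjacency$a))
    t2 <- table(as.character(sig$adjacency$b))
    deg[names(t1)] <- deg[names(t1)] + as.integer(t1)
    deg[names(t2)] <- deg[names(t2)] + as.integer(t2)
  }
  unname(deg)
}

#' @export
print.fragsig_db <- function(x, ...) {
  cat("<fragsig_db> ", length(x$signatures), " signature(s), bin ",
      x$params$bin_width, " A, ", x$params$n_segments, " segments each\n", sep = "")
  invisible(x)
}

#' Save / load a signature database
#'
#' Same container format as [write_signature()] (gzip JSON, versioned,
#' checksummed), holding the parameter header and every signature.
#'
#' @param db a `fragsig_db`.
#' @param path file path (conventionally `.fsigdb`).
#' @return `path` invisibly, or the loaded `fragsig_db`.
#' @export
write_db <- function(db, path) {
  payload <- list(params = db$params, duplicates = db$duplicates,
                  signatures = lapply(unname(db$signatures), signature_payload))
  write_container(payload, "db", path)
}

#' @rdname write_db
#' @export
read_db <- function(path) {
  p <- read_container(path, "db")
  sigs <- lapply(p$signatures, signature_unpayload)
  names(sigs) <- vapply(sigs, function(s) s$id, character(1))
  new_db(sigs, as.integer(p$duplicates))
}

# Admissible lower bound on the best mapped score between a query signature
# and a reduced target record.  Per query fragment, the optimal (minimum)
# shape-only L1 distance over all target fragments is found, connectivity
# ignored and target fragments reusable.  These optima are combined with the
# count weighting used in mapped scoring, made pessimistic so the result
# never exceeds the score of any maximal mapping:
#   - every maximal mapping carries at least two links whenever both
#     fragment graphs are connected with >= 2 nodes, so the bound is the
#     minimum over query-fragment pairs of the weighted average of their two
#     optima, with each weight pushed to the end of its feasible range
#     [c_q + min c_t, c_q + max c_t] that minimizes the average;
#   - single-link mappings can be maximal only when query or target has one
#     fragment (or a dominating query fragment meets an isolated target
#     fragment); exactly in those cases the bound also admits the best
#     single optimum.
prefilter_bound <- function(qsig, red) {
  qf <- qsig$frag_sigs
  m <- length(qf)
  n <- red$m
  cq <- vapply(qf, function(f) f$count, numeric(1))
  ct <- red$counts
  sstar <- numeric(m)
  for (x in seq_len(m)) {
    dmin <- Inf
    for (mu in seq_len(n)) {
      d <- l1_distance(qf[[x]]$h1, red$h1[[mu]])
      if (d < dmin) dmin <- d
    }
    sstar[x] <- dmin
  }
  ctmin <- min(ct)
  ctmax <- max(ct)
  cand <- Inf
  qdeg <- fragment_degrees(qsig)
  tdeg <- red$adjacency_info$degree
  singleton_possible <- (m == 1) || (n == 1) ||
    (any(qdeg == m - 1) && any(tdeg == 0))
  if (singleton_possible) {
    xs <- if (n == 1) seq_len(m) else which(qdeg == m - 1)
    cand <- min(cand, min(sstar[xs]))
  }
  if (m >= 2 && n >= 2) {
    for (x in seq_len(m - 1)) for (y in (x + 1):m) {
      if (sstar[x] <= sstar[y]) {
        lo <- x; hi <- y
      } else {
        lo <- y; hi <- x
      }
      w_lo <- cq[lo] + ctmax   # maximal weight on the smaller optimum
      w_hi <- cq[hi] + ctmin
      cand <- min(cand, (w_lo * sstar[lo] + w_hi * sstar[hi]) / (w_lo + w_hi))
    }
  } else {
    cand <- min(cand, min(sstar))
  }
  cand
}

#' Prefilter a library with the lower-bound score
#'
#' Fast shortlist: for every target the reduced records yield a provable
#' lower bound on the best full mapped score (see the package vignette),
#' so retrieving the `K` lowest bounds can never lose the true best hit
#' when `K` is large enough to include it.
#'
#' @param qsig query signature.
#' @param db a `fragsig_db` (its reduced companion is used).
#' @param K number of candidates to keep (clamped to the database size).
#' @return tibble with `id` and `bound`, ascending by bound.
#' @export
prefilter_search <- function(qsig, db, K = 20000) {
  if (K <= 0) stop("K must be positive")
  check_compatible(qsig, db$signatures[[1]])
  bounds <- vapply(db$reduced, function(red) prefilter_bound(qsig, red), numeric(1))
  out <- tibble(id = names(db$reduced), bound = unname(bounds))
  out <- out[order(out$bound, out$id), ]
  head(out, min(K, nrow(out)))
}

#' Full mapped search over a candidate list
#'
#' Runs [compare_molecules()] against each candidate, drops candidates
#' whose every mapping leaves more than `max_unused` percent of query or
#' target segments unused, ranks the survivors by ascending best raw score
#' (ties broken by id), and truncates to `max_hits`.
#'
#' @param qsig query signature.
#' @param db a `fragsig_db`.
#' @param candidates character vector of target ids (e.g. from
#'   [prefilter_search()]); default the whole database.
#' @param max_hits hit-list length cap.
#' @param max_unused unused-fraction threshold in percent (`NULL` disables
#'   the filter).
#' @param variant descriptor variant for scoring.
#' @return a `fragsig_hitlist`: tibble with `rank`, `id`, `score`,
#'   `transformed`, `unused_query`, `unused_target`, `mapping`.
#' @export
full_search <- function(qsig, db, candidates = NULL, max_hits = 5000,
                        max_unused = 25, variant = "1d") {
  if (is.null(candidates)) candidates <- names(db$signatures)
  missing <- setdiff(candidates, names(db$signatures))
  if (length(missing) > 0)
    stop("candidate id(s) not in the database: ", paste(head(missing, 5), collapse = ", "))
  rows <- list()
  for (id in candidates) {
    cmp <- compare_molecules(qsig, db$signatures[[id]], variant = variant,
                             max_unused = max_unused)
    if (is.null(cmp$best)) next
    rows[[id]] <- tibble(id = id, score = cmp$best$score,
                         transformed = cmp$best$transformed,
                         unused_query = cmp$best$unused_query,
                         unused_target = cmp$best$unused_target,
                         mapping = mapping_label(cmp$best$mapping))
  }
  hits <- if (length(rows) == 0) {
    tibble(id = character(), score = numeric(), transformed = numeric(),
           unused_query = numeric(), unused_target = numeric(), mapping = character())
  } else do.call(rbind, rows)
  hits <- hits[order(hits$score, hits$id), ]
  hits <- head(hits, max_hits)
  hits <- cbind(tibble(rank = seq_len(nrow(hits))), hits)
  structure(as_tibble(hits), class = c("fragsig_hitlist", class(as_tibble(hits))))
}

#' Merge hit lists into a non-redundant ranking
#'
#' The union of several hit lists (e.g. from multiple queries against the
#' same library): each molecule is kept once at its best (lowest) score,
#' and the merged list is re-ranked.
#'
#' @param ... hit lists from [full_search()] (or a single list of them).
#' @return a merged `fragsig_hitlist`.
#' @export
merge_hitlists <- function(...) {
  lists <- list(...)
  if (length(lists) == 1 && !inherits(lists[[1]], "fragsig_hitlist")) lists <- lists[[1]]
  all <- do.call(rbind, lapply(lists, function(h) h[setdiff(names(h), "rank")]))
  all <- all[order(all$score, all$id), ]
  all <- all[!duplicated(all$id), ]
  out <- cbind(tibble(rank = seq_len(nrow(all))), all)
  structure(as_tibble(out), class = c("fragsig_hitlist", class(as_tibble(out))))
}

#' Write a hit list as delimited text
#'
#' @param hits a `fragsig_hitlist`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_hitlist <- function(hits, path) {
  utils::write.table(as.data.frame(hits), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' ROC points for a scored, labeled hit list
#'
#' Standard ROC construction using the raw score as the variable decision
#' threshold: at threshold `s`, molecules scoring `<= s` (more similar) are
#' called positive.  Both coordinates are monotone non-decreasing along the
#' sweep.
#'
#' @param scores tibble/data frame with columns `id` and `score`, or a
#'   `fragsig_hitlist`.
#' @param labels named logical/character vector id -> positive status
#'   (`TRUE`/`"positive"` = active).
#' @param thresholds score grid; default all observed scores.
#' @return tibble with `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels, thresholds = NULL) {
  df <- as.data.frame(scores)
  lab <- labels[df$id]
  if (any(is.na(lab))) stop("every scored id must be labeled")
  pos <- lab == TRUE | lab == "positive"
  if (all(pos) || all(!pos)) stop("need both positive and negative labels")
  if (is.null(thresholds)) thresholds <- sort(unique(df$score))
  tp <- vapply(thresholds, function(s) sum(df$score <= s & pos), numeric(1))
  fp <- vapply(thresholds, function(s) sum(df$score <= s & !pos), numeric(1))
  tibble(threshold = thresholds, fpr = fp / sum(!pos), tpr = tp / sum(pos))
}
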