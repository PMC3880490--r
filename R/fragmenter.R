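#' Heavy-atom molecular graph
#'
#' Builds the graph with heavy atoms as vertices and heavy-heavy bonds as
#' edges, the structure on which ring perception and fragmentation operate.
#'
#' @param mol a `fragsig_molecule`.
#' @return an \pkg{igraph} graph whose vertex attribute `atom` holds the
#'   1-based atom index in `mol`.
#' @export
mol_graph <- function(mol) {
  heavy <- heavy_atoms(mol)
  idx <- match(seq_len(n_atoms(mol)), heavy)  # atom -> heavy position
  b <- mol$bonds
  hb <- b[!mol$atoms$is_h[b$i] & !mol$atoms$is_h[b$j], , drop = FALSE]
  g <- igraph::make_empty_graph(n = length(heavy), directed = FALSE)
  if (nrow(hb) > 0)
    g <- igraph::add_edges(g, rbind(idx[hb$i], idx[hb$j]))
  igraph::V(g)$atom <- heavy
  g
}

#' Locate ring-closure bonds
#'
#' Grows a maximal spanning subtree of the heavy-atom graph by depth-first
#' extension and returns the bonds left out of the tree: the ring closures,
#' always equal in number to the cyclomatic number E - V + C.  The specific
#' closure bonds depend on the traversal, so the traversal here is
#' deterministic: the seed defaults to the lowest-index edge and neighbors
#' are visited in increasing vertex order.
#'
#' @param graph heavy-atom graph from [mol_graph()].
#' @param seed optional length-2 vector, an edge (graph vertex ids) to seed
#'   the subtree.
#' @return integer matrix with columns `from`, `to` (graph vertex ids), one
#'   row per ring closure; zero rows for an acyclic graph.
#' @export
find_ring_closures <- function(graph, seed = NULL) {
  nv <- igraph::vcount(graph)
  if (nv == 0) return(cbind(from = integer(), to = integer()))
  el <- igraph::as_edgelist(graph, names = FALSE)
  if (nrow(el) > 0) el <- t(apply(el, 1, sort)) else el <- matrix(integer(), 0, 2)
  adj <- lapply(seq_len(nv), function(v) sort(unique(c(
    el[el[, 1] == v, 2], el[el[, 2] == v, 1]))))
  visited <- rep(FALSE, nv)
  in_tree <- rep(FALSE, nrow(el))
  edge_id <- function(u, v) which((el[, 1] == min(u, v)) & (el[, 2] == max(u, v)))[1]
  grow <- function(stack) {  # stack vertices must already be marked visited
    while (length(stack) > 0) {
      v <- stack[length(stack)]
      nxt <- adj[[v]][!visited[adj[[v]]]]
      if (length(nxt) == 0) {
        stack <- stack[-length(stack)]
      } else {
        u <- nxt[1]
        visited[u] <<- TRUE
        in_tree[edge_id(v, u)] <<- TRUE
        stack <- c(stack, u)
      }
    }
  }
  if (!is.null(seed)) {
    seed <- sort(as.integer(seed))
    eid <- if (nrow(el) > 0) edge_id(seed[1], seed[2]) else NA_integer_
    if (is.na(eid)) stop("seed is not an edge of the graph")
    visited[seed] <- TRUE      # the seed bond enters the tree first
    in_tree[eid] <- TRUE
    grow(seed)
  } else if (nrow(el) > 0) {   # lowest-index bond seeds the subtree
    visited[el[1, 1]] <- TRUE
    grow(el[1, 1])
  }
  for (v in seq_len(nv)) if (!visited[v]) {
    visited[v] <- TRUE
    grow(v)
  }
  cl <- el[!in_tree, , drop = FALSE]
  colnames(cl) <- c("from", "to")
  cl
}

#' Grow ring systems from ring closures
#'
#' Each closure, together with the union of all non-self-intersecting paths
#' joining its two ends, spans a set of ring atoms; closures whose paths
#' merge (fused rings) collapse into one system, and systems sharing any
#' atom (including spiro junctions) are merged so that every ring atom
#' belongs to exactly one ring system.
#'
#' @param graph heavy-atom graph from [mol_graph()].
#' @param closures closure edge matrix from [find_ring_closures()].
#' @return list of integer vectors of graph vertex ids, one per ring system.
#' @export
grow_ring_systems <- function(graph, closures) {
  if (is.null(closures) || nrow(closures) == 0) return(list())
  # atoms on some simple path between the ends of a closure = the vertices of
  # the biconnected component containing that closure edge
  bc <- igraph::biconnected_components(graph)
  comp_vertices <- lapply(bc$components, as.integer)
  comp_edges <- lapply(bc$component_edges, function(es)
    igraph::as_edgelist(igraph::subgraph_from_edges(graph, es, delete.vertices = FALSE),
                        names = FALSE))
  systems <- list()
  for (r in seq_len(nrow(closures))) {
    u <- closures[r, 1]; v <- closures[r, 2]
    hit <- which(vapply(comp_edges, function(e)
      any((e[, 1] == u & e[, 2] == v) | (e[, 1] == v & e[, 2] == u)), logical(1)))
    systems[[length(systems) + 1]] <- comp_vertices[[hit[1]]]
  }
  # merge systems sharing atoms (fused already identical; spiro overlap)
  merged <- list()
  for (s in systems) {
    joined <- FALSE
    for (k in seq_along(merged)) {
      if (length(intersect(merged[[k]], s)) > 0) {
        merged[[k]] <- sort(union(merged[[k]], s))
        joined <- TRUE
        break
      }
    }
    if (!joined) merged[[length(merged) + 1]] <- sort(s)
  }
  # repeat until stable (chained spiro)
  repeat {
    n0 <- length(merged)
    out <- list()
    for (s in merged) {
      joined <- FALSE
      for (k in seq_along(out)) {
        if (length(intersect(out[[k]], s)) > 0) {
          out[[k]] <- sort(union(out[[k]], s))
          joined <- TRUE
          break
        }
      }
      if (!joined) out[[length(out) + 1]] <- s
    }
    merged <- out
    if (length(merged) == n0) break
  }
  merged[order(vapply(merged, min, numeric(1)))]
}

#' Partition a molecule into ring-system-based fragments
#'
#' Ring systems become fragments.  Each remaining non-ring connected
#' component is classified by the number of distinct ring systems it borders:
#' two or more, it is always its own fragment; exactly one, it is its own
#' fragment only if it has more than `max_subsumed` heavy atoms and is
#' otherwise subsumed into that ring system; zero (an acyclic molecule or
#' acyclic disconnected piece), it is a single fragment of its own.
#' Hydrogens join the fragment of the heavy atom they are bonded to.
#'
#' @param mol a `fragsig_molecule`.
#' @param max_subsumed largest heavy-atom count of a single-ring-system
#'   substituent that is still merged into the ring system (default 5:
#'   "more than five heavy atoms" makes a separate fragment).
#' @return a `fragsig_fragmentation`: list with `assignment` (tibble
#'   `atom`, `fragment`), `fragments` (tibble `fragment`, `n_heavy`,
#'   `n_atoms`), and `adjacency` (tibble `a`, `b`).
#' @export
assign_fragments <- function(mol, max_subsumed = 5L) {
  if (n_atoms(mol) == 0) stop("molecule has no atoms")
  g <- mol_graph(mol)
  heavy <- igraph::V(g)$atom
  nh <- length(heavy)
  closures <- find_ring_closures(g)
  systems <- grow_ring_systems(g, closures)   # graph vertex ids
  in_ring <- rep(FALSE, nh)
  for (s in systems) in_ring[s] <- TRUE

  piece_of <- rep(NA_integer_, nh)            # preliminary grouping
  np <- 0L
  group_atoms <- list()
  group_is_ring <- logical()
  for (s in systems) {
    np <- np + 1L
    piece_of[s] <- np
    group_atoms[[np]] <- s
    group_is_ring[np] <- TRUE
  }
  # non-ring components
  if (any(!in_ring)) {
    sub <- igraph::induced_subgraph(g, which(!in_ring))
    cmp <- igraph::components(sub)
    orig <- which(!in_ring)
    for (cidx in seq_len(cmp$no)) {
      verts <- orig[cmp$membership == cidx]
      # distinct neighboring ring systems
      nbr_sys <- integer()
      for (v in verts) {
        for (w in as.integer(igraph::neighbors(g, v))) {
          if (in_ring[w]) nbr_sys <- union(nbr_sys, piece_of[w])
        }
      }
      nheavy_comp <- length(verts)
      if (length(nbr_sys) == 1 && nheavy_comp <= max_subsumed) {
        k <- nbr_sys[1]
        piece_of[verts] <- k
        group_atoms[[k]] <- sort(c(group_atoms[[k]], verts))
      } else {
        np <- np + 1L
        piece_of[verts] <- np
        group_atoms[[np]] <- sort(verts)
        group_is_ring[np] <- FALSE
      }
    }
  }
  # order fragments by their lowest member atom index
  lowest <- vapply(group_atoms, function(vs) min(heavy[vs]), numeric(1))
  ord <- order(lowest)
  frag_of_group <- match(seq_len(np), ord)

  frag_atom <- rep(NA_integer_, n_atoms(mol))
  frag_atom[heavy] <- frag_of_group[piece_of]
  # hydrogens inherit from their heavy neighbor
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    i <- b$i[k]; j <- b$j[k]
    if (mol$atoms$is_h[i] && !mol$atoms$is_h[j]) frag_atom[i] <- frag_atom[j]
    if (mol$atoms$is_h[j] && !mol$atoms$is_h[i]) frag_atom[j] <- frag_atom[i]
  }
  if (any(is.na(frag_atom[mol$atoms$is_h]))) {
    # isolated hydrogens (e.g. H2): their own acyclic fragment per component
    for (i in which(is.na(frag_atom))) {
      frag_atom[i] <- max(frag_atom, na.rm = TRUE) + 1L
    }
  }
  new_fragmentation(mol, frag_atom)
}

new_fragmentation <- function(mol, frag_atom) {
  stopifnot(!anyNA(frag_atom))
  ids <- sort(unique(frag_atom))
  summ <- tibble(
    fragment = ids,
    n_heavy = vapply(ids, function(f) sum(frag_atom == f & !mol$atoms$is_h), integer(1)),
    n_atoms = vapply(ids, function(f) sum(frag_atom == f), integer(1)))
  b <- mol$bonds
  fa <- frag_atom[b$i]
  fb <- frag_atom[b$j]
  cross <- fa != fb
  adj <- unique(tibble(a = pmin(fa[cross], fb[cross]), b = pmax(fa[cross], fb[cross])))
  adj <- adj[order(adj$a, adj$b), ]
  structure(list(molecule_id = mol$id,
                 assignment = tibble(atom = seq_along(frag_atom),
                                     fragment = as.integer(frag_atom)),
                 fragments = summ, adjacency = adj),
            class = "fragsig_fragmentation")
}

#' @export
print.fragsig_fragmentation <- function(x, ...) {
  cat("<fragsig_fragmentation> ", x$molecule_id, ": ", nrow(x$fragments),
      " fragment(s); heavy atoms per fragment: ",
      paste(x$fragments$n_heavy, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Load a custom per-atom fragment assignment
#'
#' File format: whitespace-separated `atom_index fragment_id` pairs, 1-based
#' atom indices, `#` comments.  Every heavy atom must be assigned; hydrogens
#' left unlisted inherit the fragment of the heavy atom they are bonded to.
#'
#' @param path assignment file.
#' @param mol the molecule the assignment refers to.
#' @return a `fragsig_fragmentation`.
#' @export
load_fragment_assignment <- function(path, mol) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty fragment assignment file: ", path)
  parts <- strsplit(lines, "[[:space:]]+")
  bad <- vapply(parts, length, integer(1)) != 2
  if (any(bad)) stop("malformed line(s) in ", path, ": ",
                     paste(lines[bad], collapse = "; "))
  atom <- as.integer(vapply(parts, `[`, character(1), 1))
  frag <- as.integer(vapply(parts, `[`, character(1), 2))
  n <- n_atoms(mol)
  if (any(is.na(atom)) || any(atom < 1 | atom > n))
    stop("atom index out of range (molecule has ", n, " atoms)")
  frag_atom <- rep(NA_integer_, n)
  frag_atom[atom] <- frag
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    i <- b$i[k]; j <- b$j[k]
    if (mol$atoms$is_h[i] && is.na(frag_atom[i]) && !mol$atoms$is_h[j])
      frag_atom[i] <- frag_atom[j]
    if (mol$atoms$is_h[j] && is.na(frag_atom[j]) && !mol$atoms$is_h[i])
      frag_atom[j] <- frag_atom[i]
  }
  un <- which(is.na(frag_atom) & !mol$atoms$is_h)
  if (length(un) > 0)
    stop("heavy atom(s) not assigned to any fragment: ", paste(un, collapse = ", "))
  if (anyNA(frag_atom))
    stop("hydrogen(s) with no assigned heavy neighbor: ",
         paste(which(is.na(frag_atom)), collapse = ", "))
  new_fragmentation(mol, frag_atom)
}

#' Fragment adjacency graph
#'
#' Two fragments are adjacent iff at least one bond joins an atom of one to
#' an atom of the other.  This is the graph on which mapping consistency is
#' checked during scoring.
#'
#' @param frag a `fragsig_fragmentation`.
#' @return an \pkg{igraph} graph with one vertex per fragment (vertex
#'   attribute `fragment` holds the fragment id).
#' @export
fragment_adjacency <- function(frag) {
  ids <- frag$fragments$fragment
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  igraph::V(g)$fragment <- ids
  if (nrow(frag$adjacency) > 0) {
    ia <- match(frag$adjacency$a, ids)
    ib <- match(frag$adjacency$b, ids)
    g <- igraph::add_edges(g, rbind(ia, ib))
  }
  g
}
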