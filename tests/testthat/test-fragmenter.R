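test_that("ring closures equal the cyclomatic number, independent of the seed", {
  cases <- list(benzene = 1L, naphthalene = 2L, decalin = 2L, biphenyl = 2L,
                tetracycle = 4L, toluene = 1L)
  for (nm in names(cases)) {
    g <- mol_graph(make_toy_molecule(nm))
    cl <- find_ring_closures(g)
    expect_equal(nrow(cl), cases[[nm]], label = nm)
    # every edge as seed gives the same closure count
    el <- igraph::as_edgelist(g, names = FALSE)
    counts <- apply(el, 1, function(e) nrow(find_ring_closures(g, seed = e)))
    expect_true(all(counts == cases[[nm]]), label = paste(nm, "seed independence"))
  }
  # acyclic chain: no closures
  hex <- make_alkane(6)
  expect_equal(nrow(find_ring_closures(mol_graph(hex))), 0)
})

test_that("ring systems grow correctly for fused, linked and spiro rings", {
  naph <- make_toy_molecule("naphthalene")
  g <- mol_graph(naph)
  sys <- grow_ring_systems(g, find_ring_closures(g))
  expect_length(sys, 1)
  expect_length(sys[[1]], 10)

  bip <- make_toy_molecule("biphenyl")
  g2 <- mol_graph(bip)
  sys2 <- grow_ring_systems(g2, find_ring_closures(g2))
  expect_length(sys2, 2)
  expect_identical(sort(lengths(sys2)), c(6L, 6L))
  expect_length(intersect(sys2[[1]], sys2[[2]]), 0)

  dec <- make_toy_molecule("decalin")
  g3 <- mol_graph(dec)
  sys3 <- grow_ring_systems(g3, find_ring_closures(g3))
  expect_length(sys3, 1)
  expect_length(sys3[[1]], 10)
})

test_that("ring systems match the union of simple closure paths (oracle)", {
  # independent oracle: atoms on any simple path joining the closure ends in
  # the graph without that closure edge, accumulated over all closures
  for (nm in c("naphthalene", "biphenyl", "toluene")) {
    g <- mol_graph(make_toy_molecule(nm))
    cl <- find_ring_closures(g)
    sys <- grow_ring_systems(g, cl)
    got <- sort(unique(unlist(sys)))
    want <- integer()
    for (r in seq_len(nrow(cl))) {
      gm <- igraph::delete_edges(g, igraph::get_edge_ids(g, cl[r, ]))
      paths <- igraph::all_simple_paths(gm, from = cl[r, 1], to = cl[r, 2])
      want <- union(want, unlist(lapply(paths, as.integer)))
    }
    expect_identical(got, sort(as.integer(want)), label = nm)
  }
})

test_that("fragment assignment follows the substituent size rules", {
  cases <- list(methane = 1L, benzene = 1L, toluene = 1L, naphthalene = 1L,
                decalin = 1L, tetracycle = 1L,
                hexylbenzene = 2L,       # 6 heavy atoms > 5: separate fragment
                biphenyl = 2L,
                diphenylethane = 3L)     # bridge borders two ring systems
  for (nm in names(cases)) {
    fr <- assign_fragments(make_toy_molecule(nm))
    expect_equal(nrow(fr$fragments), cases[[nm]], label = nm)
    expect_false(anyNA(fr$assignment$fragment), label = nm)
  }
  # a 5-carbon substituent is subsumed, a 6-carbon one is not
  expect_equal(nrow(assign_fragments(make_alkylbenzene(5))$fragments), 1)
  expect_equal(nrow(assign_fragments(make_alkylbenzene(6))$fragments), 2)
  # acyclic molecules collapse to a single fragment
  expect_equal(nrow(assign_fragments(make_alkane(8))$fragments), 1)
})

test_that("fragmentation partitions all atoms and is stable under atom reordering", {
  m <- make_toy_molecule("diphenylethane")
  fr <- assign_fragments(m)
  expect_setequal(fr$assignment$atom, seq_len(nrow(m$atoms)))
  sizes1 <- sort(fr$fragments$n_heavy)
  # reverse the atom order
  n <- nrow(m$atoms)
  perm <- rev(seq_len(n))
  inv <- order(perm)
  m2 <- molecule("reordered", m$atoms[perm, ],
                 tibble::tibble(i = inv[m$bonds$i], j = inv[m$bonds$j],
                                order = m$bonds$order))
  fr2 <- assign_fragments(m2)
  expect_equal(nrow(fr2$fragments), nrow(fr$fragments))
  expect_identical(sort(fr2$fragments$n_heavy), sizes1)
})

test_that("custom fragment files are honored verbatim with hydrogen inheritance", {
  bip <- make_toy_molecule("biphenyl")
  f <- withr::local_tempfile()
  writeLines(c("# split by ring", paste(1:6, 1), paste(7:12, 2)), f)
  fr <- load_fragment_assignment(f, bip)
  expect_equal(nrow(fr$fragments), 2)
  expect_equal(nrow(fr$adjacency), 1)
  # hydrogens inherited their heavy neighbor's fragment
  expect_false(anyNA(fr$assignment$fragment))

  f2 <- withr::local_tempfile()
  writeLines(paste(seq_len(nrow(bip$atoms)), 0), f2)
  expect_equal(nrow(load_fragment_assignment(f2, bip)$fragments), 1)

  f3 <- withr::local_tempfile()
  writeLines("999 1", f3)
  expect_error(load_fragment_assignment(f3, bip), "out of range")

  f4 <- withr::local_tempfile()
  writeLines("1 1", f4)  # heavy atoms 2..12 unassigned
  expect_error(load_fragment_assignment(f4, bip), "not assigned")
})

test_that("fragment adjacency reflects bonds between fragments", {
  dpe <- make_toy_molecule("diphenylethane")
  fr <- assign_fragments(dpe)
  g <- fragment_adjacency(fr)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 2)
  degs <- sort(igraph::degree(g))
  expect_identical(as.integer(degs), c(1L, 1L, 2L))  # path topology
  # single fragment: no edges
  g1 <- fragment_adjacency(assign_fragments(make_toy_molecule("benzene")))
  expect_equal(igraph::ecount(g1), 0)
})
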