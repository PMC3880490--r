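# Shared independent oracles and small fixture builders.  Everything here is
# deliberately naive (exhaustive enumeration, all-element scans) so package
# results can be checked against implementations that share no code paths.

path_adj <- function(m) {
  A <- matrix(0, m, m)
  if (m > 1) for (i in 1:(m - 1)) A[i, i + 1] <- A[i + 1, i] <- 1
  A
}
star_adj <- function(m) {
  A <- matrix(0, m, m)
  if (m > 1) for (i in 2:m) A[1, i] <- A[i, 1] <- 1
  A
}
tri_adj <- function() matrix(1, 3, 3) - diag(3)

canon_mapping <- function(L) {
  paste(sort(paste(L[, 1], L[, 2], sep = "-")), collapse = ",")
}

canon_set <- function(maps) {
  sort(unname(vapply(maps, canon_mapping, character(1))))
}

# exhaustive enumeration of all injective consistent maps, filtered to the
# maximal ones: the oracle for enumerate_mappings()
brute_maximal_mappings <- function(Aq, At) {
  m <- nrow(Aq)
  n <- nrow(At)
  consistent <- function(L) {
    if (nrow(L) < 2) return(TRUE)
    for (a in 1:(nrow(L) - 1)) for (b in (a + 1):nrow(L)) {
      if (Aq[L[a, 1], L[b, 1]] == 1 && At[L[a, 2], L[b, 2]] != 1) return(FALSE)
    }
    TRUE
  }
  maps <- list()
  gen <- function(L, xs) {
    if (nrow(L) > 0) maps[[canon_mapping(L)]] <<- L
    for (x in xs) for (mu in setdiff(seq_len(n), L[, 2])) {
      L2 <- rbind(L, c(x, mu))
      if (consistent(L2)) gen(L2, setdiff(xs, x))
    }
  }
  gen(matrix(numeric(0), 0, 2), seq_len(m))
  is_max <- function(L) {
    for (x in setdiff(seq_len(m), L[, 1])) for (mu in setdiff(seq_len(n), L[, 2]))
      if (consistent(rbind(L, c(x, mu)))) return(FALSE)
    TRUE
  }
  Filter(is_max, maps)
}

# direct enumeration of contiguous-interval mappings between two path graphs
# (single links plus oriented multi-link interval matches): the oracle for
# the closed-form linear mapping count
count_contiguous_mappings <- function(m, n) {
  keys <- character()
  for (i in 1:m) for (j in 1:n)
    keys <- c(keys, canon_mapping(matrix(c(i, j), 1, 2)))
  kmax <- min(m, n)
  if (kmax >= 2) for (k in 2:kmax) {
    for (i in 1:(m - k + 1)) for (j in 1:(n - k + 1)) {
      fwd <- cbind(i:(i + k - 1), j:(j + k - 1))
      rev <- cbind(i:(i + k - 1), (j + k - 1):j)
      keys <- c(keys, canon_mapping(fwd), canon_mapping(rev))
    }
  }
  length(unique(keys))  # distinct link sets only
}

# brute-force nearest ray-triangle intersection over every element
brute_nearest_reflection <- function(surf, p, d, exclude = 0L) {
  next_reflection(surf, p, d, exclude = exclude, brute = TRUE)
}

# a synthetic signature with fully prescribed per-fragment histograms and
# counts, for hand-computable scoring tests
prescribed_signature <- function(id, hists, counts, adjacency, bin_width = 0.5) {
  m <- length(hists)
  frag_sigs <- lapply(seq_len(m), function(f) {
    list(fragment = f, count = counts[f],
         h1 = normalize(new_hist1d(hists[[f]], bin_width)),
         h2_full = NULL, h2_reduced = NULL, h2_reduced_inverted = NULL)
  })
  names(frag_sigs) <- as.character(seq_len(m))
  structure(list(
    id = id,
    params = list(bin_width = bin_width, n_segments = NA, cone_angle = NA,
                  probe_radius = NA, surface_spacing = NA, grid_spacing = NA,
                  mep_bin_width = 0.025, mep_max = 0.5, dielectric = 1, seed = 0),
    fragments = tibble::tibble(fragment = seq_len(m), n_heavy = NA_integer_,
                               n_atoms = NA_integer_),
    adjacency = adjacency,
    frag_sigs = frag_sigs, inter = list(),
    total_segments = sum(counts), restarts = 0L), class = "fragsig_signature")
}

# minimal hand-written mol2 fixture text (methane with explicit charges)
methane_mol2_text <- function(charges = c(-0.4, 0.1, 0.1, 0.1, 0.1)) {
  c("@<TRIPOS>MOLECULE", "methane", "5 4 1", "SMALL", "USER_CHARGES", "",
    "@<TRIPOS>ATOM",
    sprintf("1 C1 0.0000 0.0000 0.0000 C.3 1 MOL %.4f", charges[1]),
    sprintf("2 H1 0.6300 0.6300 0.6300 H 1 MOL %.4f", charges[2]),
    sprintf("3 H2 -0.6300 -0.6300 0.6300 H 1 MOL %.4f", charges[3]),
    sprintf("4 H3 -0.6300 0.6300 -0.6300 H 1 MOL %.4f", charges[4]),
    sprintf("5 H4 0.6300 -0.6300 -0.6300 H 1 MOL %.4f", charges[5]),
    "@<TRIPOS>BOND", "1 1 2 1", "2 1 3 1", "3 1 4 1", "4 1 5 1")
}

methane_sdf_text <- function() {
  c("methane", "  fragsig", "", "  5  4  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0",
    "    0.6300    0.6300    0.6300 H   0  0",
    "   -0.6300   -0.6300    0.6300 H   0  0",
    "   -0.6300    0.6300   -0.6300 H   0  0",
    "    0.6300   -0.6300   -0.6300 H   0  0",
    "  1  2  1  0", "  1  3  1  0", "  1  4  1  0", "  1  5  1  0",
    "M  END", "$$$$")
}

single_atom_molecule <- function(element = "C", charge = NA_real_) {
  m <- molecule(paste0("atom_", element),
                tibble::tibble(element = element, x = 0, y = 0, z = 0,
                               charge = charge),
                tibble::tibble(i = integer(), j = integer()))
  assign_radii(m)
}

diatomic_molecule <- function(dist = 1.5) {
  m <- molecule("diatomic",
                tibble::tibble(element = c("C", "C"), x = c(0, dist), y = 0, z = 0),
                tibble::tibble(i = 1L, j = 2L, order = "1"))
  assign_radii(m)
}
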