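# Deterministic test fixtures: analytic meshes with known geometry (sphere,
# box), idealized toy hydrocarbons covering the fragmentation cases (single
# rings, fused and linked ring systems, long and short substituents), and
# synthetic random signatures for scoring/prefilter tests.  Everything is
# generated in code; nothing is downloaded.

#' Icosphere mesh fixture
#'
#' Closed icosahedral sphere mesh of radius `R`, all elements contact class
#' assigned to a single pseudo-atom at the origin, outward-oriented.  The
#' analytic chord statistics of the sphere (mean chord `4R/3`) make it the
#' main geometric oracle for the ray tracer.
#'
#' @param R radius in Angstrom.
#' @param subdivisions icosahedron subdivision level (4 gives 5120 faces).
#' @return a `fragsig_surface`.
#' @export
make_sphere_mesh <- function(R = 1, subdivisions = 4) {
  stopifnot(R > 0)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    mid_cache <- new.env(parent = emptyenv())
    nv <- nrow(v)
    newv <- list()
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      hit <- mid_cache[[key]]
      if (!is.null(hit)) return(hit)
      p <- (v[a, ] + v[b, ]) / 2
      p <- p / sqrt(sum(p^2))
      newv[[length(newv) + 1]] <<- p
      id <- nv + length(newv)
      mid_cache[[key]] <- id
      id
    }
    newf <- matrix(0L, nrow(f) * 4, 3)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; cc <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newf[4 * t - 3, ] <- c(a, ab, ca)
      newf[4 * t - 2, ] <- c(b, bc, ab)
      newf[4 * t - 1, ] <- c(cc, ca, bc)
      newf[4 * t, ] <- c(ab, bc, ca)
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- newf
  }
  surf <- new_surface(R * v, f, molecule_id = sprintf("sphere_R%g", R))
  fixture_contact_surface(surf)
}

fixture_contact_surface <- function(surf) {
  nt <- nrow(surf$triangles)
  # fix outward orientation if needed (fixture meshes are star-shaped)
  flip <- rowSums(surf$normal * surf$center) < 0
  if (any(flip)) {
    tr <- surf$triangles
    tr[flip, c(2, 3)] <- tr[flip, c(3, 2)]
    surf <- new_surface(surf$vertices, tr, molecule_id = surf$molecule_id)
  }
  surf$class <- rep("contact", nt)
  surf$atoms <- matrix(c(rep(1L, nt), rep(NA_integer_, 2 * nt)), nt, 3)
  surf$primary_atom <- rep(1L, nt)
  surf$mep <- numeric(nrow(surf$vertices))
  surf
}

#' Axis-aligned cube mesh fixture
#'
#' Closed cube of side `L` centered at the origin; mean interior chord
#' `4V/S = 2L/3`.
#'
#' @param L side length, Angstrom.
#' @param resolution quads per edge per face.
#' @return a `fragsig_surface`.
#' @export
make_box_mesh <- function(L = 1, resolution = 8) {
  stopifnot(L > 0, resolution >= 1)
  h <- L / resolution
  key_env <- new.env(parent = emptyenv())
  verts <- list()
  vid <- function(p) {
    key <- paste(round(p / (h / 2)), collapse = ",")
    hit <- key_env[[key]]
    if (!is.null(hit)) return(hit)
    verts[[length(verts) + 1]] <<- p
    key_env[[key]] <- length(verts)
    length(verts)
  }
  faces <- list()
  axes <- list(c(2, 3, 1), c(3, 1, 2), c(1, 2, 3))
  for (ax in 1:3) for (sgn in c(-1, 1)) {
    for (i in seq_len(resolution)) for (j in seq_len(resolution)) {
      u0 <- -L / 2 + (i - 1) * h; u1 <- u0 + h
      w0 <- -L / 2 + (j - 1) * h; w1 <- w0 + h
      corner <- function(u, w) {
        p <- numeric(3)
        p[axes[[ax]][1]] <- u
        p[axes[[ax]][2]] <- w
        p[axes[[ax]][3]] <- sgn * L / 2
        p
      }
      a <- vid(corner(u0, w0)); b <- vid(corner(u1, w0))
      cc <- vid(corner(u1, w1)); d <- vid(corner(u0, w1))
      if (sgn > 0) {
        faces[[length(faces) + 1]] <- c(a, b, cc)
        faces[[length(faces) + 1]] <- c(a, cc, d)
      } else {
        faces[[length(faces) + 1]] <- c(a, cc, b)
        faces[[length(faces) + 1]] <- c(a, d, cc)
      }
    }
  }
  surf <- new_surface(do.call(rbind, verts), do.call(rbind, faces),
                      molecule_id = sprintf("box_L%g", L))
  fixture_contact_surface(surf)
}

# ---- toy molecule geometry -------------------------------------------------

CC_AROMATIC <- 1.39
CC_SINGLE <- 1.54
CC_LINK <- 1.48   # sp2-sp2 single bond (ring-ring)
CC_SP3_RING <- 1.51  # sp2-sp3 (ring-substituent)
CH_BOND <- 1.09

# zigzag step directions for sp3 chains (tetrahedral angle, xz-plane)
ZIG_A <- c(sin(acos(-1 / 3) / 2), 0, cos(acos(-1 / 3) / 2))
ZIG_B <- c(ZIG_A[1], 0, -ZIG_A[3])

ring_coords <- function(n, d, center = c(0, 0, 0), phase = 0) {
  r <- d / (2 * sin(pi / n))
  th <- phase + 2 * pi * (seq_len(n) - 1) / n
  cbind(center[1] + r * cos(th), center[2] + r * sin(th), center[3] + 0 * th)
}

rot_x <- function(deg) {
  a <- deg * pi / 180
  rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
}

# heavy-atom skeleton -> molecule with geometrically placed hydrogens
# sp2[i] TRUE means trigonal carbon (3 neighbors total), else tetrahedral
hydrocarbon <- function(id, coords, bonds, sp2, bond_order = NULL) {
  nh <- nrow(coords)
  if (is.null(bond_order)) bond_order <- rep("1", nrow(bonds))
  deg <- tabulate(c(bonds[, 1], bonds[, 2]), nbins = nh)
  nbrs <- lapply(seq_len(nh), function(i)
    c(bonds[bonds[, 1] == i, 2], bonds[bonds[, 2] == i, 1]))
  atoms <- list()
  hbonds <- list()
  hcoords <- list()
  for (i in seq_len(nh)) {
    val <- if (sp2[i]) 3L else 4L
    n_h <- val - deg[i]
    if (n_h <= 0) next
    us <- lapply(nbrs[[i]], function(j) {
      u <- coords[j, ] - coords[i, ]
      u / sqrt(sum(u^2))
    })
    dirs <- h_directions(us, n_h)
    for (d in dirs) {
      hcoords[[length(hcoords) + 1]] <- coords[i, ] + CH_BOND * d
      hbonds[[length(hbonds) + 1]] <- c(i, nh + length(hcoords))
    }
  }
  all_coords <- rbind(coords, do.call(rbind, hcoords))
  el <- c(rep("C", nh), rep("H", length(hcoords)))
  bnd <- rbind(cbind(bonds, order = bond_order),
               if (length(hbonds) > 0)
                 cbind(do.call(rbind, hbonds), order = "1"))
  molecule(id,
           atoms = tibble(element = el, x = all_coords[, 1], y = all_coords[, 2],
                          z = all_coords[, 3]),
           bonds = tibble(i = as.integer(bnd[, 1]), j = as.integer(bnd[, 2]),
                          order = bnd[, 3]),
           source = "fixture")
}

h_directions <- function(us, n_h) {
  k <- length(us)
  unitize <- function(v) v / sqrt(sum(v^2))
  if (k == 0) {  # methane-like
    t <- 1 / sqrt(3)
    return(list(c(t, t, t), c(-t, -t, t), c(-t, t, -t), c(t, -t, -t))[seq_len(n_h)])
  }
  if (k == 1) {  # terminal CH3 (or CH2= not needed for these fixtures)
    a <- -us[[1]]
    ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- unitize(ref - sum(ref * a) * a)
    e2 <- c(a[2] * e1[3] - a[3] * e1[2], a[3] * e1[1] - a[1] * e1[3],
            a[1] * e1[2] - a[2] * e1[1])
    ct <- cos(pi - acos(-1 / 3))   # tetrahedral tilt from the axis
    st <- sqrt(1 - ct^2)
    lapply(2 * pi * (seq_len(n_h) - 1) / 3, function(ph)
      unitize(ct * a + st * (cos(ph) * e1 + sin(ph) * e2)))
  } else if (k == 2) {
    b <- unitize(-(us[[1]] + us[[2]]))
    if (n_h == 1) return(list(b))  # aromatic CH
    p <- c(us[[1]][2] * us[[2]][3] - us[[1]][3] * us[[2]][2],
           us[[1]][3] * us[[2]][1] - us[[1]][1] * us[[2]][3],
           us[[1]][1] * us[[2]][2] - us[[1]][2] * us[[2]][1])
    p <- unitize(p)
    half <- acos(-1 / 3) / 2
    list(unitize(cos(half) * b + sin(half) * p),
         unitize(cos(half) * b - sin(half) * p))
  } else {
    s <- us[[1]] + us[[2]] + us[[3]]
    if (sqrt(sum(s * s)) < 0.35) {
      # near-coplanar neighbors (planar fused-ring junctions): point the
      # hydrogen along the plane normal instead of the vanishing bisector
      p <- c(us[[1]][2] * us[[2]][3] - us[[1]][3] * us[[2]][2],
             us[[1]][3] * us[[2]][1] - us[[1]][1] * us[[2]][3],
             us[[1]][1] * us[[2]][2] - us[[1]][2] * us[[2]][1])
      if (p[3] < 0) p <- -p
      list(unitize(p))[seq_len(n_h)]
    } else {
      list(unitize(-s))[seq_len(n_h)]
    }
  }
}

ring_bonds <- function(n, offset = 0L) {
  cbind(offset + seq_len(n), offset + c(seq_len(n - 1) + 1, 1))
}

# linearly fused hexagon chain (naphthalene k=2, tetracene-like k=4, decalin
# with d = 1.54); returns heavy coords + bonds
fused_hex_chain <- function(k, d) {
  pts <- list()
  for (i in seq_len(k)) {
    center <- c((i - 1) * sqrt(3) * d, 0, 0)
    th <- pi / 6 + 2 * pi * (0:5) / 6
    for (t in th) pts[[length(pts) + 1]] <- center + d * c(cos(t), sin(t), 0)
  }
  m <- do.call(rbind, pts)
  key <- apply(round(m / 1e-3), 1, paste, collapse = ",")
  keep <- !duplicated(key)
  m <- m[keep, , drop = FALSE]
  dd <- as.matrix(stats::dist(m))
  bonds <- which(dd > d - 0.05 & dd < d + 0.05, arr.ind = TRUE)
  bonds <- bonds[bonds[, 1] < bonds[, 2], , drop = FALSE]
  list(coords = m, bonds = bonds)
}

chain_coords <- function(anchor, n, first_len = CC_SINGLE) {
  out <- matrix(0, n, 3)
  p <- anchor
  for (j in seq_len(n)) {
    step <- if (j %% 2 == 1) ZIG_A else ZIG_B
    len <- if (j == 1) first_len else CC_SINGLE
    p <- p + len * step
    out[j, ] <- p
  }
  out
}

#' Toy molecule fixtures
#'
#' Small idealized hydrocarbons with documented fragmentation behavior,
#' generated from standard bond lengths and angles (no conformer search;
#' fused ring systems are laid out planar).  Gasteiger-type charges are
#' assigned at construction.
#'
#' Expected automatic fragment counts: methane, benzene, toluene,
#' naphthalene, decalin and tetracycle give 1; hexylbenzene and biphenyl
#' give 2; diphenylethane gives 3 (two rings plus the bridge).
#'
#' @param name one of `"methane"`, `"benzene"`, `"toluene"`, `"biphenyl"`,
#'   `"naphthalene"`, `"decalin"`, `"hexylbenzene"`, `"diphenylethane"`,
#'   `"tetracycle"`.
#' @return a `fragsig_molecule` with radii and charges assigned.
#' @export
make_toy_molecule <- function(name) {
  mol <- switch(
    name,
    methane = hydrocarbon("methane", matrix(0, 1, 3), matrix(0L, 0, 2), sp2 = FALSE),
    benzene = {
      co <- ring_coords(6, CC_AROMATIC)
      hydrocarbon("benzene", co, ring_bonds(6), sp2 = rep(TRUE, 6),
                  bond_order = rep("ar", 6))
    },
    toluene = make_alkylbenzene(1, id = "toluene"),
    hexylbenzene = make_alkylbenzene(6, id = "hexylbenzene"),
    biphenyl = make_polyphenyl(2, id = "biphenyl"),
    naphthalene = {
      g <- fused_hex_chain(2, CC_AROMATIC)
      hydrocarbon("naphthalene", g$coords, g$bonds, sp2 = rep(TRUE, nrow(g$coords)),
                  bond_order = rep("ar", nrow(g$bonds)))
    },
    decalin = {
      g <- fused_hex_chain(2, CC_SINGLE)
      hydrocarbon("decalin", g$coords, g$bonds, sp2 = rep(FALSE, nrow(g$coords)))
    },
    tetracycle = {
      g <- fused_hex_chain(4, CC_AROMATIC)
      hydrocarbon("tetracycle", g$coords, g$bonds, sp2 = rep(TRUE, nrow(g$coords)),
                  bond_order = rep("ar", nrow(g$bonds)))
    },
    diphenylethane = make_diphenyl_bridge(2, id = "diphenylethane"),
    stop("unknown toy molecule '", name, "'"))
  mol <- assign_radii(mol)
  ensure_charges(mol, "gasteiger")
}

#' @rdname make_toy_molecule
#' @param n_chain,n_rings,n_bridge,n sizes of the parametric variants.
#' @param id molecule id override.
#' @export
make_alkane <- function(n, id = sprintf("alkane_C%d", n)) {
  stopifnot(n >= 1)
  if (n == 1) return(assign_radii(make_toy_molecule("methane")))
  co <- chain_coords(c(0, 0, 0), n, first_len = CC_SINGLE)
  bonds <- cbind(seq_len(n - 1), seq_len(n - 1) + 1)
  mol <- hydrocarbon(id, co, bonds, sp2 = rep(FALSE, n))
  ensure_charges(assign_radii(mol), "gasteiger")
}

#' @rdname make_toy_molecule
#' @export
make_cycloalkane <- function(n, id = sprintf("cycloalkane_C%d", n)) {
  stopifnot(n >= 3)
  co <- ring_coords(n, CC_SINGLE)
  mol <- hydrocarbon(id, co, ring_bonds(n), sp2 = rep(FALSE, n))
  ensure_charges(assign_radii(mol), "gasteiger")
}

#' @rdname make_toy_molecule
#' @export
make_alkylbenzene <- function(n_chain, id = sprintf("alkylbenzene_C%d", n_chain)) {
  co_ring <- ring_coords(6, CC_AROMATIC)
  anchor <- co_ring[1, ]
  co_chain <- chain_coords(anchor, n_chain, first_len = CC_SP3_RING)
  coords <- rbind(co_ring, co_chain)
  bonds <- rbind(ring_bonds(6), c(1, 7),
                 if (n_chain > 1) cbind(6 + seq_len(n_chain - 1), 7 + seq_len(n_chain - 1)))
  orders <- c(rep("ar", 6), rep("1", 1 + max(n_chain - 1, 0)))
  mol <- hydrocarbon(id, coords, bonds, sp2 = c(rep(TRUE, 6), rep(FALSE, n_chain)),
                     bond_order = orders)
  ensure_charges(assign_radii(mol), "gasteiger")
}

#' @rdname make_toy_molecule
#' @export
make_polyphenyl <- function(n_rings, id = sprintf("polyphenyl_%d", n_rings)) {
  stopifnot(n_rings >= 2)
  spacing <- 2 * CC_AROMATIC + CC_LINK
  coords <- NULL
  bonds <- NULL
  orders <- character()
  for (r in seq_len(n_rings)) {
    center <- c((r - 1) * spacing, 0, 0)
    co <- ring_coords(6, CC_AROMATIC, center = c(0, 0, 0))
    twist <- if (r %% 2 == 0) 40 else 0     # stagger rings to avoid H clashes
    co <- co %*% t(rot_x(twist))
    co <- sweep(co, 2, center, `+`)
    off <- nrow(coords %||% matrix(0, 0, 3))
    coords <- rbind(coords, co)
    bonds <- rbind(bonds, ring_bonds(6, offset = off))
    orders <- c(orders, rep("ar", 6))
    if (r > 1) {
      # para link: vertex 4 (angle 180) of ring r to vertex 1 of ring r-1
      bonds <- rbind(bonds, c(off - 6 + 1, off + 4))
      orders <- c(orders, "1")
    }
  }
  mol <- hydrocarbon(id, coords, bonds, sp2 = rep(TRUE, nrow(coords)),
                     bond_order = orders)
  ensure_charges(assign_radii(mol), "gasteiger")
}

#' @rdname make_toy_molecule
#' @export
make_diphenyl_bridge <- function(n_bridge, id = sprintf("diphenyl_C%d_bridge", n_bridge)) {
  stopifnot(n_bridge >= 1)
  co_a <- ring_coords(6, CC_AROMATIC)
  br <- chain_coords(co_a[1, ], n_bridge, first_len = CC_SP3_RING)
  # ring B: its vertex 4 bonds the last bridge atom
  last <- br[n_bridge, ]
  step <- if ((n_bridge + 1) %% 2 == 1) ZIG_A else ZIG_B
  link <- last + CC_SP3_RING * step
  center_b <- link + c(CC_AROMATIC, 0, 0)
  co_b <- ring_coords(6, CC_AROMATIC, center = center_b, phase = pi)
  coords <- rbind(co_a, br, co_b)
  nb <- nrow(co_a) + n_bridge
  bonds <- rbind(ring_bonds(6),
                 c(1, 7),
                 if (n_bridge > 1) cbind(6 + seq_len(n_bridge - 1), 7 + seq_len(n_bridge - 1)),
                 c(6 + n_bridge, nb + 1),
                 ring_bonds(6, offset = nb))
  orders <- c(rep("ar", 6), rep("1", n_bridge + 1), rep("ar", 6))
  mol <- hydrocarbon(id, coords, bonds,
                     sp2 = c(rep(TRUE, 6), rep(FALSE, n_bridge), rep(TRUE, 6)),
                     bond_order = orders)
  ensure_charges(assign_radii(mol), "gasteiger")
}

#' @rdname make_toy_molecule
#' @export
make_bicyclohexyl <- function(id = "bicyclohexyl") {
  co_a <- ring_coords(6, CC_SINGLE)
  link <- co_a[1, ] + c(CC_SINGLE, 0, 0)     # vertex 1 of the second ring
  co_b <- ring_coords(6, CC_SINGLE, center = link + c(ring_radius(6, CC_SINGLE), 0, 0),
                      phase = pi)
  co_b <- sweep(sweep(co_b, 2, link, `-`) %*% t(rot_x(40)), 2, link, `+`)
  coords <- rbind(co_a, co_b)
  bonds <- rbind(ring_bonds(6), c(1, 7), ring_bonds(6, offset = 6))
  mol <- hydrocarbon(id, coords, bonds, sp2 = rep(FALSE, 12),
                     bond_order = rep("1", nrow(bonds)))
  ensure_charges(assign_radii(mol), "gasteiger")
}

#' @rdname make_toy_molecule
#' @export
make_tbutylbenzene <- function(id = "tbutylbenzene") {
  co <- ring_coords(6, CC_AROMATIC)
  u <- co[1, ] / sqrt(sum(co[1, ]^2))
  qc <- co[1, ] + CC_SP3_RING * u            # quaternary carbon
  # three methyls tetrahedrally arranged around the axis pointing away
  # from the ring
  ct <- 1 / 3
  st <- sqrt(1 - ct^2)
  e1 <- c(0, 0, 1)
  e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  methyls <- t(vapply(2 * pi * (0:2) / 3, function(ph) {
    qc + CC_SINGLE * (ct * u + st * (cos(ph) * e1 + sin(ph) * e2))
  }, numeric(3)))
  coords <- rbind(co, qc, methyls)
  bonds <- rbind(ring_bonds(6), c(1, 7), c(7, 8), c(7, 9), c(7, 10))
  mol <- hydrocarbon(id, coords, bonds, sp2 = c(rep(TRUE, 6), rep(FALSE, 4)),
                     bond_order = c(rep("ar", 6), rep("1", 4)))
  ensure_charges(assign_radii(mol), "gasteiger")
}

ring_radius <- function(n, d) d / (2 * sin(pi / n))

#' @rdname make_toy_molecule
#' @export
make_mesitylene <- function(id = "mesitylene") {
  co <- ring_coords(6, CC_AROMATIC)
  methyls <- t(vapply(c(1, 3, 5), function(v) {
    u <- co[v, ] / sqrt(sum(co[v, ]^2))
    co[v, ] + CC_SP3_RING * u
  }, numeric(3)))
  coords <- rbind(co, methyls)
  bonds <- rbind(ring_bonds(6), c(1, 7), c(3, 8), c(5, 9))
  mol <- hydrocarbon(id, coords, bonds, sp2 = c(rep(TRUE, 6), rep(FALSE, 3)),
                     bond_order = c(rep("ar", 6), rep("1", 3)))
  ensure_charges(assign_radii(mol), "gasteiger")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Thirty-molecule toy screening library
#'
#' A fixed, deterministic library spanning the fixture chemotypes: the nine
#' named toys, n-alkanes C3-C8, alkylbenzenes with 2-5 carbon chains,
#' cycloalkanes C5-C8, terphenyl, bicyclohexyl, tert-butylbenzene, two
#' extra diphenyl bridges, mesitylene and anthracene.  Molecules are
#' pairwise distinct in size or topology, and the library deliberately
#' avoids quasi-exact fragment-level homolog pairs (such as oligophenyls
#' differing by a single ring): mapped scoring rewards substructure
#' matches by design, so such pairs can legitimately outscore a
#' stochastic self-match and would make self-retrieval an ill-posed test.
#'
#' @return named list of 30 `fragsig_molecule` objects.
#' @export
make_toy_library <- function() {
  mols <- c(
    lapply(c("methane", "benzene", "toluene", "biphenyl", "naphthalene",
             "decalin", "hexylbenzene", "diphenylethane", "tetracycle"),
           make_toy_molecule),
    lapply(3:8, make_alkane),
    lapply(2:5, make_alkylbenzene),
    lapply(5:8, make_cycloalkane),
    list(make_polyphenyl(3), make_bicyclohexyl(), make_tbutylbenzene(),
         make_diphenyl_bridge(1), make_diphenyl_bridge(3),
         make_mesitylene(),
         {
           g <- fused_hex_chain(3, CC_AROMATIC)
           m <- hydrocarbon("anthracene", g$coords, g$bonds,
                            sp2 = rep(TRUE, nrow(g$coords)),
                            bond_order = rep("ar", nrow(g$bonds)))
           ensure_charges(assign_radii(m), "gasteiger")
         }))
  names(mols) <- vapply(mols, function(m) m$id, character(1))
  mols
}

#' Synthetic random signature fixture
#'
#' A `fragsig_signature` with random normalized per-fragment shape
#' histograms and random positive segment counts, on a declared path or
#' star fragment topology.  Deterministic under `seed`; used to exercise
#' mapping enumeration, scoring and the prefilter without any geometry.
#'
#' @param m fragment count.
#' @param topology `"path"` or `"star"` (fragment 1 is the hub).
#' @param bins number of shape bins carrying mass.
#' @param seed integer seed.
#' @param bin_width shape bin width recorded in the parameters.
#' @return a `fragsig_signature` (1D descriptors only).
#' @export
make_synthetic_signature <- function(m, topology = c("path", "star"), bins = 20,
                                     seed = 0, bin_width = 0.5) {
  topology <- match.arg(topology)
  stopifnot(m >= 1, bins >= 1)
  u <- splitmix_runif(seed, m * bins + m)
  frag_sigs <- lapply(seq_len(m), function(f) {
    raw <- -log(pmax(u[(f - 1) * bins + seq_len(bins)], 1e-12))  # gamma(1) draws
    cnt <- round(1000 + u[m * bins + f] * 49000)
    counts <- round(raw / sum(raw) * cnt)
    counts[1] <- counts[1] + cnt - sum(counts)   # preserve the total exactly
    list(fragment = f, count = sum(counts),
         h1 = normalize(new_hist1d(counts, bin_width)),
         h2_full = NULL, h2_reduced = NULL, h2_reduced_inverted = NULL)
  })
  names(frag_sigs) <- as.character(seq_len(m))
  adjacency <- if (m < 2) {
    tibble(a = integer(), b = integer())
  } else if (topology == "path") {
    tibble(a = 1:(m - 1), b = 2:m)
  } else {
    tibble(a = rep(1L, m - 1), b = 2:m)
  }
  structure(list(
    id = sprintf("synthetic_%s_m%d_seed%d", topology, m, seed),
    params = list(bin_width = bin_width, n_segments = NA, cone_angle = NA,
                  probe_radius = NA, surface_spacing = NA, grid_spacing = NA,
                  mep_bin_width = 0.025, mep_max = 0.5, dielectric = 1,
                  seed = seed),
    fragments = tibble(fragment = seq_len(m), n_heavy = NA_integer_,
                       n_atoms = NA_integer_),
    adjacency = adjacency,
    frag_sigs = frag_sigs, inter = list(),
    total_segments = sum(vapply(frag_sigs, function(f) f$count, numeric(1))),
    restarts = 0L), class = "fragsig_signature")
}
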