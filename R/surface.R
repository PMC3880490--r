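#' Triangulate the solvent-excluded molecular surface
#'
#' Extracts a closed, outward-oriented triangle mesh of the surface traced
#' by the inward face of a probe sphere rolling over the van der Waals
#' spheres.  The mesh is the zero level set of a probe-erosion distance
#' field sampled on a regular grid and polygonized by marching tetrahedra,
#' which guarantees a watertight mesh.  Interior cavity shells (closed
#' components with negative enclosed volume, unreachable by exterior
#' solvent) are discarded.
#'
#' @param mol a `fragsig_molecule` with radii assigned.
#' @param probe_radius probe sphere radius in Angstrom (1.4 = water).
#' @param spacing grid spacing in Angstrom; the median mesh edge comes out
#'   at roughly `0.6 * spacing`.
#' @param classify also run [classify_elements()] and
#'   [assign_primary_atoms()] (default `TRUE`).
#' @return a `fragsig_surface`: vertices (n x 3), triangles (m x 3,
#'   1-based, outward winding), per-element `center`, `normal`, `area`,
#'   `component`, and after classification `class`, `atoms`,
#'   `primary_atom`.
#' @export
triangulate_surface <- function(mol, probe_radius = 1.4, spacing = 0.6,
                                classify = TRUE) {
  if (n_atoms(mol) == 0) stop("empty molecule")
  if (any(is.na(mol$atoms$radius))) stop("assign radii before surface generation")
  if (probe_radius <= 0) stop("probe_radius must be positive")
  xyz <- coords(mol)
  d <- as.matrix(stats::dist(xyz))
  diag(d) <- Inf
  if (any(d < 1e-6)) stop("overlapping identical atoms in '", mol$id, "'")
  mesh <- .cpp_ses_mesh(xyz, mol$atoms$radius, probe_radius, spacing, TRUE)
  surf <- new_surface(mesh$vertices, mesh$triangles, component = mesh$component,
                      probe_radius = probe_radius, spacing = spacing,
                      molecule_id = mol$id)
  if (classify) {
    surf <- classify_elements(surf, mol, probe_radius)
    surf <- assign_primary_atoms(surf, mol)
  }
  surf
}

new_surface <- function(vertices, triangles, component = NULL, probe_radius = NA,
                        spacing = NA, molecule_id = NA_character_) {
  v1 <- vertices[triangles[, 1], , drop = FALSE]
  v2 <- vertices[triangles[, 2], , drop = FALSE]
  v3 <- vertices[triangles[, 3], , drop = FALSE]
  e1 <- v2 - v1
  e2 <- v3 - v1
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nrm <- sqrt(rowSums(cr^2))
  area <- nrm / 2
  unitn <- cr / pmax(nrm, 1e-300)
  structure(list(
    vertices = vertices, triangles = triangles,
    center = (v1 + v2 + v3) / 3, normal = unitn, area = area,
    component = if (is.null(component)) rep(1L, nrow(triangles)) else component,
    class = NULL, atoms = NULL, primary_atom = NULL, mep = NULL,
    probe_radius = probe_radius, spacing = spacing, molecule_id = molecule_id),
    class = "fragsig_surface")
}

#' @export
print.fragsig_surface <- function(x, ...) {
  cat("<fragsig_surface> ", x$molecule_id, ": ", nrow(x$vertices), " vertices, ",
      nrow(x$triangles), " elements, ", length(unique(x$component)),
      " component(s), area ", sprintf("%.1f", sum(x$area)), " A^2\n", sep = "")
  if (!is.null(x$class)) {
    tb <- table(x$class)
    cat("  classes: ", paste(names(tb), tb, sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Classify surface elements as contact, saddle or reentrant
#'
#' An element's class is decided by how many atoms the rolling probe touches
#' at the probe position behind the element: the probe center is placed one
#' probe radius along the element's outward normal, and the atoms whose
#' inflated spheres (radius + probe) pass within `tol` of that point are the
#' touched set.  One touched atom is contact surface, two saddle, three or
#' more reentrant (capped at three assigned atoms).  Elements with no atom
#' within tolerance fall back to nearest-atom contact assignment.
#'
#' @param surf a `fragsig_surface`.
#' @param mol the molecule the surface was built from.
#' @param probe_radius probe radius used to build the surface.
#' @param tol contact tolerance in Angstrom (defaults to a value matched to
#'   the grid spacing).
#' @return the surface with `class` and `atoms` filled.
#' @export
classify_elements <- function(surf, mol, probe_radius = surf$probe_radius, tol = NULL) {
  if (is.null(tol)) tol <- max(0.35, 0.8 * if (is.na(surf$spacing)) 0.5 else surf$spacing)
  xyz <- coords(mol)
  nat <- nrow(xyz)
  nt <- nrow(surf$triangles)
  pc <- surf$center + probe_radius * surf$normal   # probe positions
  # squared distances probe position -> atom centers, minus inflated radius
  slack <- matrix(0, nt, nat)
  infl <- mol$atoms$radius + probe_radius
  for (a in seq_len(nat)) {
    dd <- sqrt((pc[, 1] - xyz[a, 1])^2 + (pc[, 2] - xyz[a, 2])^2 +
               (pc[, 3] - xyz[a, 3])^2)
    slack[, a] <- dd - infl[a]
  }
  ntouch <- rowSums(abs(slack) <= tol)
  cls <- ifelse(ntouch <= 1, "contact", ifelse(ntouch == 2, "saddle", "reentrant"))
  # three best-matching atoms per element, vectorized partial sort
  aslack <- abs(slack)
  a1 <- max.col(-aslack, ties.method = "first")
  atoms <- matrix(NA_integer_, nt, 3)
  atoms[, 1] <- a1
  k <- pmin(pmax(ntouch, 1L), 3L)
  if (nat >= 2) {
    aslack[cbind(seq_len(nt), a1)] <- Inf
    a2 <- max.col(-aslack, ties.method = "first")
    atoms[k >= 2, 2] <- a2[k >= 2]
    if (nat >= 3) {
      aslack[cbind(seq_len(nt), a2)] <- Inf
      a3 <- max.col(-aslack, ties.method = "first")
      atoms[k >= 3, 3] <- a3[k >= 3]
    }
  }
  if (any(ntouch == 0)) {
    # numerically ambiguous: nearest-atom fallback (slot 1 already holds it)
    warning(sum(ntouch == 0), " element(s) had no atom within tolerance; ",
            "assigned to the nearest atom as contact surface")
  }
  surf$class <- cls
  surf$atoms <- atoms
  surf
}

#' Assign each element to its principal atom
#'
#' The principal atom is the assigned atom whose center is closest to the
#' geometric center of the element; exact ties go to the lowest atom index.
#'
#' @param surf classified `fragsig_surface`.
#' @param mol the molecule.
#' @return the surface with `primary_atom` filled.
#' @export
assign_primary_atoms <- function(surf, mol) {
  if (is.null(surf$atoms)) stop("classify elements before assigning primary atoms")
  xyz <- coords(mol)
  nt <- nrow(surf$triangles)
  dist_to <- function(a) {  # distance center -> assigned atom in column slot
    out <- rep(Inf, nt)
    ok <- !is.na(a)
    out[ok] <- sqrt(rowSums((surf$center[ok, , drop = FALSE] -
                             xyz[a[ok], , drop = FALSE])^2))
    out
  }
  d <- cbind(dist_to(surf$atoms[, 1]), dist_to(surf$atoms[, 2]), dist_to(surf$atoms[, 3]))
  dmin <- pmin(d[, 1], d[, 2], d[, 3])
  cand <- surf$atoms
  cand[d > dmin + 1e-12] <- NA_integer_  # keep distance ties only
  surf$primary_atom <- as.integer(pmin(cand[, 1], cand[, 2], cand[, 3], na.rm = TRUE))
  surf
}

#' Compute the electrostatic potential at surface vertices
#'
#' Coulomb sum `MEP(v) = sum_i q_i / (dielectric * |v - r_i|)` in units of
#' elementary charge per Angstrom, from the molecule's partial charges.
#'
#' @param surf a `fragsig_surface`.
#' @param mol molecule with charges assigned (see [ensure_charges()]).
#' @param dielectric unitless dielectric constant (default 1).
#' @return the surface with per-vertex `mep` filled.
#' @export
compute_vertex_mep <- function(surf, mol, dielectric = 1.0) {
  if (any(is.na(mol$atoms$charge))) stop("assign charges before computing the MEP")
  xyz <- coords(mol)
  q <- mol$atoms$charge
  v <- surf$vertices
  mep <- numeric(nrow(v))
  for (a in seq_len(nrow(xyz))) {
    dd <- sqrt((v[, 1] - xyz[a, 1])^2 + (v[, 2] - xyz[a, 2])^2 +
               (v[, 3] - xyz[a, 3])^2)
    if (any(dd < 1e-9)) stop("surface vertex coincides with an atom center")
    mep <- mep + q[a] / (dielectric * dd)
  }
  surf$mep <- mep
  surf
}

#' Export a surface mesh as OFF
#'
#' Plain-text Object File Format, for quick visualization in external mesh
#' viewers.
#'
#' @param surf a `fragsig_surface`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_surface_off <- function(surf, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(surf$vertices), nrow(surf$triangles)), con)
  writeLines(sprintf("%.6f %.6f %.6f", surf$vertices[, 1], surf$vertices[, 2],
                     surf$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d", surf$triangles[, 1] - 1L,
                     surf$triangles[, 2] - 1L, surf$triangles[, 3] - 1L), con)
  invisible(path)
}

# watertightness / orientation diagnostics used by tests and sanity checks
surface_edge_counts <- function(surf) {
  tr <- surf$triangles
  ed <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  table(key)
}

surface_euler <- function(surf, component = NULL) {
  tr <- surf$triangles
  if (!is.null(component)) tr <- tr[surf$component == component, , drop = FALSE]
  vids <- unique(as.vector(tr))
  ed <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  ne <- length(unique(paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))))
  length(vids) - ne + nrow(tr)
}
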