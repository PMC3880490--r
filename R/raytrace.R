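#' Build the uniform acceleration grid for a surface
#'
#' Surface elements are registered in the grid cube(s) that contain their
#' corners: an element lands in one cube when all three corners share it,
#' and in at most three.  The grid only accelerates the search; the
#' intersection found is identical to a brute-force scan over all elements
#' (the traversal inspects the full neighbourhood of each cube it crosses,
#' and the spacing is clamped to the longest mesh edge so corner
#' registration cannot miss a candidate).
#'
#' @param surf a `fragsig_surface`.
#' @param spacing cube edge length in Angstrom (default 1.0; clamped up to
#'   the longest mesh edge).
#' @return a list with `element_cubes` (per element, an integer matrix of
#'   cube coordinates), `origin`, `spacing`, `dims`.
#' @export
build_grid <- function(surf, spacing = 1.0) {
  if (spacing <= 0) stop("spacing must be positive")
  spacing <- max(spacing, max_edge_length(surf))
  g <- .cpp_grid_assign(surf$vertices, surf$triangles, spacing)
  g
}

max_edge_length <- function(surf) {
  tr <- surf$triangles
  v <- surf$vertices
  e <- rbind(v[tr[, 1], ] - v[tr[, 2], ], v[tr[, 2], ] - v[tr[, 3], ],
             v[tr[, 3], ] - v[tr[, 1], ])
  sqrt(max(rowSums(e^2)))
}

#' Choose a ray-trace starting point and direction
#'
#' The trace starts at the center of a randomly chosen contact-class
#' element, directed antiparallel to the outward surface normal (into the
#' molecular interior).
#'
#' @param surf classified `fragsig_surface`.
#' @param seed integer seed for the draw.
#' @return list with `point`, `direction` (unit), `element`.
#' @export
start_ray <- function(surf, seed = 0) {
  if (is.null(surf$class)) stop("surface is not classified")
  contact <- which(surf$class == "contact")
  if (length(contact) == 0) stop("surface has no contact elements")
  u <- splitmix_runif(seed, 1)
  el <- contact[floor(u * length(contact)) + 1]
  list(point = surf$center[el, ], direction = -surf$normal[el, ], element = el)
}

# R port of the C++ splitmix64 generator so R-level draws are reproducible
# and independent of the session RNG
splitmix_runif <- function(seed, n) {
  s <- as.numeric(seed)
  out <- numeric(n)
  # 64-bit arithmetic emulated via two 32-bit halves would be overkill here:
  # delegate to the compiled generator
  .cpp_splitmix_runif(s, as.integer(n))
}

#' Specular reflection with cone perturbation
#'
#' Ideal mirror reflection of `d_in` about the plane with unit normal `n`,
#' optionally followed by a random perturbation uniform over the spherical
#' cap of half-angle `cone_angle` centered on the ideal direction.  The
#' perturbation prevents a ray from shuttling forever between parallel
#' faces.
#'
#' @param d_in incident unit direction.
#' @param n unit surface normal.
#' @param cone_angle cone half-angle in degrees (0 = ideal reflection).
#' @param seed integer seed for the perturbation draw.
#' @return unit direction of the reflected ray.
#' @export
reflect <- function(d_in, n, cone_angle = 0, seed = 0) {
  if (cone_angle < 0) stop("cone_angle must be >= 0")
  .cpp_reflect(d_in, n, cone_angle, seed)
}

#' Find the next reflection of a ray
#'
#' Returns the nearest valid ray-triangle intersection strictly ahead of
#' `point`, excluding the element the ray just left.  With `brute = TRUE`
#' the search scans every element; the default grid-accelerated search
#' returns the identical intersection.
#'
#' @param surf a `fragsig_surface`.
#' @param point ray origin.
#' @param direction ray direction (normalized internally).
#' @param exclude element index to exclude (the launching element), or 0.
#' @param spacing acceleration grid spacing.
#' @param brute use the brute-force all-element scan.
#' @return list with `element`, `t`, `position`, `bary`, or `NULL` if the
#'   ray escapes (propagation failure).
#' @export
next_reflection <- function(surf, point, direction, exclude = 0L, spacing = 1.0,
                            brute = FALSE) {
  spacing <- max(spacing, max_edge_length(surf))
  hit <- .cpp_next_reflection(surf$vertices, surf$triangles, as.numeric(point),
                              as.numeric(direction), spacing, as.integer(exclude),
                              brute)
  if (is.na(hit$element[1])) return(NULL)
  hit
}

#' Interior ray-trace of a molecular surface
#'
#' Runs the billiard ray-trace until at least `n_segments` segments are
#' recorded: rays start on random contact elements, propagate by specular
#' reflection with cone perturbation, and are restarted from a fresh random
#' element whenever propagation fails (the segments up to the failure are
#' kept).  Every reflection records the interpolated surface electrostatic
#' potential and the fragment of the element's principal atom; every
#' segment is tagged intra- or inter-fragment by the fragments at its two
#' ends.
#'
#' @param surf classified `fragsig_surface` with MEP computed (or zero MEP
#'   if absent).
#' @param frag a `fragsig_fragmentation` of the same molecule, or `NULL`
#'   for a single implicit fragment.
#' @param n_segments number of segments to record (default 1e5).
#' @param cone_angle perturbation cone half-angle, degrees.
#' @param grid_spacing acceleration grid spacing, Angstrom.
#' @param seed integer RNG seed; the same seed reproduces the trace
#'   bit-for-bit.
#' @param max_failures consecutive fresh-start failures tolerated before
#'   aborting with a mesh-quality error.
#' @return a `fragsig_raytrace`: `reflections` (tibble: position, element,
#'   mep, fragment, run), `segments` (tibble: length, from, to, kind),
#'   `restarts`, and the generation parameters.
#' @export
trace <- function(surf, frag = NULL, n_segments = 1e5, cone_angle = 3,
                  grid_spacing = 1.0, seed = 0, max_failures = 50) {
  if (is.null(surf$class) || is.null(surf$primary_atom))
    stop("surface must be classified with primary atoms assigned")
  if (n_segments < 1) stop("n_segments must be >= 1")
  elem_frag <- if (is.null(frag)) {
    rep(1L, nrow(surf$triangles))
  } else {
    frag$assignment$fragment[surf$primary_atom]
  }
  mep <- if (is.null(surf$mep)) numeric(nrow(surf$vertices)) else surf$mep
  spacing <- max(grid_spacing, max_edge_length(surf))
  contact <- which(surf$class == "contact")
  if (length(contact) == 0) stop("surface has no contact elements")
  res <- .cpp_trace(surf$vertices, surf$triangles, mep, as.integer(elem_frag),
                    as.integer(contact), as.integer(n_segments), cone_angle,
                    spacing, as.numeric(seed), as.integer(max_failures))
  refl <- tibble(x = res$position[, 1], y = res$position[, 2], z = res$position[, 3],
                 element = res$element, mep = res$mep,
                 fragment = elem_frag[res$element], run = res$run)
  seg <- tibble(length = res$seg_length, from = res$seg_from, to = res$seg_to,
                kind = ifelse(res$seg_from == res$seg_to, "intra", "inter"))
  new_raytrace(refl, seg, restarts = res$restarts, cone_angle = cone_angle,
               seed = seed, grid_spacing = spacing, molecule_id = surf$molecule_id)
}

#' Assemble a ray-trace record from its tables
#'
#' Constructor for `fragsig_raytrace` objects, used by the tracer itself
#' and handy for building small hand-specified traces (e.g. to feed
#' [accumulate_1d()] / [accumulate_2d()] with known segment lengths).
#' `reflections` needs columns `mep`, `fragment` and `run`; `segments`
#' needs `length`, `from`, `to` (fragment ids at the segment ends) and
#' optionally `kind`.  Segment `i` of a run joins reflections `i` and
#' `i + 1` of that run.
#'
#' @param reflections reflections tibble.
#' @param segments segments tibble.
#' @param restarts number of propagation restarts.
#' @param cone_angle,seed,grid_spacing generation parameters.
#' @param molecule_id molecule identifier.
#' @return a `fragsig_raytrace`.
#' @export
new_raytrace <- function(reflections, segments, restarts = 0L, cone_angle = NA,
                         seed = NA, grid_spacing = NA, molecule_id = NA_character_) {
  reflections <- as_tibble(reflections)
  segments <- as_tibble(segments)
  if (!"kind" %in% names(segments))
    segments$kind <- ifelse(segments$from == segments$to, "intra", "inter")
  if (nrow(segments) > 0 && any(segments$length <= 0))
    stop("segment lengths must be positive")
  if (!"run" %in% names(reflections)) reflections$run <- 1L
  structure(list(reflections = reflections, segments = segments,
                 restarts = restarts, cone_angle = cone_angle, seed = seed,
                 grid_spacing = grid_spacing, molecule_id = molecule_id),
            class = "fragsig_raytrace")
}

#' @export
print.fragsig_raytrace <- function(x, ...) {
  cat("<fragsig_raytrace> ", x$molecule_id, ": ", nrow(x$segments), " segments (",
      sum(x$segments$kind == "inter"), " inter-fragment), ",
      x$restarts, " restart(s), cone ", x$cone_angle, " deg, seed ", x$seed,
      "\n", sep = "")
  invisible(x)
}

#' Dump a ray-trace as tabular text
#'
#' @param trace a `fragsig_raytrace`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_trace_tsv <- function(trace, path) {
  utils::write.table(trace$reflections, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
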