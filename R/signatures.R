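#' Shape histograms
#'
#' 1D histograms bin ray-trace segment lengths on a fixed grid starting at
#' zero; 2D histograms bin, per interior reflection, the sum of the two
#' incident segment lengths against the electrostatic potential at the
#' reflection point.  The MEP axis is either `full` (fixed-width bins,
#' symmetric range with overflow bins), `reduced` (two bins: negative /
#' non-negative potential), or `reduced_inverted` (the reduced bins with
#' the sign of the potential flipped, for electrostatic complementarity
#' matching).  Raw counts are always retained alongside normalized heights,
#' because scoring weights descriptors by their segment counts.
#'
#' @param counts numeric vector (1D) of per-bin counts, bin k covering
#'   `[(k-1) * bin_width, k * bin_width)`.
#' @param bin_width shape-axis bin width in Angstrom.
#' @return a `fragsig_hist1d`.
#' @export
new_hist1d <- function(counts, bin_width) {
  stopifnot(bin_width > 0, all(counts >= 0))
  counts <- trim_trailing(as.numeric(counts))
  structure(list(bin_width = bin_width, counts = counts, heights = NULL,
                 normalized = FALSE), class = "fragsig_hist1d")
}

trim_trailing <- function(x) {
  nz <- which(x != 0)
  if (length(nz) == 0) x[0] else x[seq_len(max(nz))]
}

#' @rdname new_hist1d
#' @param counts2 matrix of counts, rows = shape bins, columns = MEP bins.
#' @param mep_axis `"full"`, `"reduced"`, or `"reduced_inverted"`.
#' @param mep_bin_width MEP bin width (e/Angstrom) for the full axis.
#' @param mep_max symmetric MEP range for the full axis; values beyond fall
#'   into overflow bins.
#' @export
new_hist2d <- function(counts2, bin_width, mep_axis, mep_bin_width = 0.025,
                       mep_max = 0.5) {
  stopifnot(bin_width > 0, all(counts2 >= 0))
  if (mep_axis %in% c("reduced", "reduced_inverted")) stopifnot(ncol(counts2) == 2)
  structure(list(bin_width = bin_width, mep_axis = mep_axis,
                 mep_bin_width = mep_bin_width, mep_max = mep_max,
                 counts = counts2, heights = NULL, normalized = FALSE),
            class = "fragsig_hist2d")
}

#' Normalize a histogram to unit mass
#'
#' Heights sum to one; raw counts are preserved for count-weighted scoring.
#' Idempotent.
#'
#' @param h a `fragsig_hist1d` or `fragsig_hist2d`.
#' @return the histogram with `heights` filled and `normalized = TRUE`.
#' @export
normalize <- function(h) UseMethod("normalize")

#' @export
normalize.fragsig_hist1d <- function(h) {
  tot <- sum(h$counts)
  if (tot <= 0) stop("cannot normalize an empty histogram")
  h$heights <- h$counts / tot
  h$normalized <- TRUE
  h
}

#' @export
normalize.fragsig_hist2d <- function(h) {
  tot <- sum(h$counts)
  if (tot <= 0) stop("cannot normalize an empty histogram")
  h$heights <- h$counts / tot
  h$normalized <- TRUE
  h
}

hist_total <- function(h) sum(h$counts)

# MEP value -> column index for a 2D histogram axis with K regular bins per
# sign and one overflow bin per side; reduced axes have columns (neg, pos)
# and potential exactly 0 lands in the positive bin by convention
mep_bin_index <- function(mep, mep_axis, mep_bin_width, mep_max) {
  if (mep_axis == "reduced") return(ifelse(mep < 0, 1L, 2L))
  if (mep_axis == "reduced_inverted") return(ifelse(-mep < 0, 1L, 2L))
  K <- ceiling(mep_max / mep_bin_width)
  raw <- floor(mep / mep_bin_width)           # ...,-1 -> negative, 0 -> first positive
  idx <- raw + K + 1L                         # 1..2K for in-range
  pmin(pmax(idx, 0L), 2L * K + 1L) + 1L       # clamp into overflow bins 1 and 2K+2
}

mep_axis_ncol <- function(mep_axis, mep_bin_width, mep_max) {
  if (mep_axis != "full") return(2L)
  2L * ceiling(mep_max / mep_bin_width) + 2L
}

#' Accumulate per-fragment 1D segment-length histograms
#'
#' Every ray-trace segment contributes one count to exactly one histogram:
#' the intra-fragment histogram of its fragment when both end points lie in
#' the same fragment, otherwise the inter-fragment histogram of the
#' unordered fragment pair.
#'
#' @param trace a `fragsig_raytrace`.
#' @param bin_width shape bin width in Angstrom.
#' @return list with `intra` (named by fragment id) and `inter` (named
#'   `"a|b"`, a < b) lists of normalized `fragsig_hist1d`.
#' @export
accumulate_1d <- function(trace, bin_width = 0.5) {
  seg <- trace$segments
  if (nrow(seg) == 0) stop("empty trace")
  if (bin_width <= 0) stop("bin_width must be positive")
  bins <- floor(seg$length / bin_width)
  key <- ifelse(seg$from == seg$to, as.character(seg$from),
                paste(pmin(seg$from, seg$to), pmax(seg$from, seg$to), sep = "|"))
  out_i <- list()
  out_x <- list()
  for (k in unique(key)) {
    sel <- key == k
    counts <- tabulate(bins[sel] + 1L, nbins = max(bins[sel]) + 1L)
    h <- normalize(new_hist1d(counts, bin_width))
    if (grepl("|", k, fixed = TRUE)) out_x[[k]] <- h else out_i[[k]] <- h
  }
  list(intra = out_i[order(as.integer(names(out_i)))], inter = out_x)
}

#' Accumulate 2D (shape by MEP) histograms per fragment
#'
#' Each interior reflection (one with both an incoming and an outgoing
#' segment in the same run) contributes one count at (sum of the two
#' incident segment lengths, MEP bin).  The reflection belongs to the
#' fragment of its element's principal atom; when its two incident
#' segments connect it to a different fragment, the count goes to that
#' unordered pair's inter-fragment histogram instead.
#'
#' @param trace a `fragsig_raytrace`.
#' @param bin_width shape bin width (Angstrom).
#' @param mep_axis `"full"`, `"reduced"`, or `"reduced_inverted"`.
#' @param mep_bin_width,mep_max full-axis parameters, see [new_hist2d()].
#' @return list with `intra` and `inter` named lists of normalized
#'   `fragsig_hist2d`.
#' @export
accumulate_2d <- function(trace, bin_width = 0.5, mep_axis = c("reduced", "full",
                          "reduced_inverted"), mep_bin_width = 0.025, mep_max = 0.5) {
  mep_axis <- match.arg(mep_axis)
  if (nrow(trace$segments) < 2) stop("trace has fewer than 2 segments")
  refl <- trace$reflections
  seg <- trace$segments
  # within each run, reflection i (2 <= i <= n_run - 1) is interior, its
  # incident segments are the (i-1)-th and i-th segments of that run
  runs <- rle(refl$run)
  idx_end <- cumsum(runs$lengths)
  idx_start <- idx_end - runs$lengths + 1L
  seg_off <- c(0L, cumsum(pmax(runs$lengths - 1L, 0L)))[seq_along(runs$lengths)]
  rows <- list()
  for (r in seq_along(runs$lengths)) {
    n <- runs$lengths[r]
    if (n < 3) next
    i <- (idx_start[r] + 1L):(idx_end[r] - 1L)      # interior reflections
    s_in <- seg_off[r] + seq_len(n - 2L)            # incoming segment rows
    rows[[r]] <- tibble(
      shape = seg$length[s_in] + seg$length[s_in + 1L],
      mep = refl$mep[i],
      f = refl$fragment[i],
      prev = refl$fragment[i - 1L],
      nxt = refl$fragment[i + 1L])
  }
  if (length(rows) == 0) stop("trace has no interior reflections")
  d <- do.call(rbind, rows)
  other <- ifelse(d$prev != d$f, d$prev, ifelse(d$nxt != d$f, d$nxt, d$f))
  key <- ifelse(other == d$f, as.character(d$f),
                paste(pmin(d$f, other), pmax(d$f, other), sep = "|"))
  sb <- floor(d$shape / bin_width)
  mb <- mep_bin_index(d$mep, mep_axis, mep_bin_width, mep_max)
  ncol2 <- mep_axis_ncol(mep_axis, mep_bin_width, mep_max)
  out_i <- list()
  out_x <- list()
  for (k in unique(key)) {
    sel <- key == k
    nr <- max(sb[sel]) + 1L
    m <- matrix(0, nr, ncol2)
    for (q in which(sel)) m[sb[q] + 1L, mb[q]] <- m[sb[q] + 1L, mb[q]] + 1
    h <- normalize(new_hist2d(m, bin_width, mep_axis, mep_bin_width, mep_max))
    if (grepl("|", k, fixed = TRUE)) out_x[[k]] <- h else out_i[[k]] <- h
  }
  list(intra = out_i[order(as.integer(names(out_i)))], inter = out_x)
}

#' Full shape-signature descriptor of a molecule
#'
#' One-call pipeline: radii, charges, fragmentation, surface, electrostatic
#' potential, ray-trace, and histogram accumulation.  The result bundles the
#' per-fragment intra histograms (1D and the three 2D variants), the
#' per-pair inter histograms, segment counts, the fragment adjacency needed
#' for mapping, and every generation parameter (bin widths must match
#' between signatures for them to be comparable).
#'
#' @param mol a `fragsig_molecule`.
#' @param frag optional `fragsig_fragmentation`; default automatic
#'   ring-system fragmentation.
#' @param n_segments ray-trace segments to record.
#' @param bin_width shape histogram bin width, Angstrom.
#' @param cone_angle reflection perturbation cone, degrees.
#' @param probe_radius rolling probe radius, Angstrom.
#' @param surface_spacing surface grid spacing, Angstrom.
#' @param grid_spacing ray-trace acceleration grid spacing, Angstrom.
#' @param mep_bin_width,mep_max full MEP axis parameters.
#' @param dielectric dielectric constant for the Coulomb potential.
#' @param charge_method `"auto"` keeps imported charges when present and
#'   falls back to the Gasteiger-type calculation; otherwise as
#'   [ensure_charges()].
#' @param seed ray-trace seed.
#' @return a `fragsig_signature`.
#' @export
molecule_signature <- function(mol, frag = NULL, n_segments = 1e5, bin_width = 0.5,
                               cone_angle = 3, probe_radius = 1.4,
                               surface_spacing = 0.6, grid_spacing = 1.0,
                               mep_bin_width = 0.025, mep_max = 0.5,
                               dielectric = 1.0, charge_method = "auto", seed = 0) {
  if (any(is.na(mol$atoms$radius))) mol <- assign_radii(mol)
  if (charge_method == "auto") {
    mol <- if (!any(is.na(mol$atoms$charge))) mol else
      tryCatch(ensure_charges(mol, "gasteiger"),
               error = function(e) ensure_charges(mol, "zero"))
  } else {
    mol <- ensure_charges(mol, charge_method)
  }
  if (is.null(frag)) frag <- assign_fragments(mol)
  surf <- triangulate_surface(mol, probe_radius, surface_spacing)
  surf <- compute_vertex_mep(surf, mol, dielectric)
  tr <- trace(surf, frag, n_segments = n_segments, cone_angle = cone_angle,
              grid_spacing = grid_spacing, seed = seed)
  signature_from_trace(tr, frag, id = mol$id,
                       params = list(bin_width = bin_width, n_segments = n_segments,
                                     cone_angle = cone_angle, probe_radius = probe_radius,
                                     surface_spacing = surface_spacing,
                                     grid_spacing = grid_spacing,
                                     mep_bin_width = mep_bin_width, mep_max = mep_max,
                                     dielectric = dielectric, seed = seed))
}

#' Build a signature from an existing ray-trace
#'
#' @param tr a `fragsig_raytrace`.
#' @param frag the fragmentation used for the trace.
#' @param id molecule id.
#' @param params generation parameter list (see [molecule_signature()]).
#' @return a `fragsig_signature`.
#' @export
signature_from_trace <- function(tr, frag, id, params) {
  bw <- params$bin_width
  h1 <- accumulate_1d(tr, bw)
  h2f <- accumulate_2d(tr, bw, "full", params$mep_bin_width, params$mep_max)
  h2r <- accumulate_2d(tr, bw, "reduced", params$mep_bin_width, params$mep_max)
  h2v <- accumulate_2d(tr, bw, "reduced_inverted", params$mep_bin_width, params$mep_max)
  frag_ids <- frag$fragments$fragment
  frag_sigs <- lapply(frag_ids, function(f) {
    k <- as.character(f)
    list(fragment = f,
         count = if (!is.null(h1$intra[[k]])) hist_total(h1$intra[[k]]) else 0,
         h1 = h1$intra[[k]], h2_full = h2f$intra[[k]], h2_reduced = h2r$intra[[k]],
         h2_reduced_inverted = h2v$intra[[k]])
  })
  names(frag_sigs) <- as.character(frag_ids)
  pair_keys <- unique(c(names(h1$inter), names(h2f$inter), names(h2r$inter),
                        names(h2v$inter)))
  inter <- lapply(pair_keys, function(k) {
    list(pair = as.integer(strsplit(k, "|", fixed = TRUE)[[1]]),
         count = if (!is.null(h1$inter[[k]])) hist_total(h1$inter[[k]]) else 0,
         h1 = h1$inter[[k]], h2_full = h2f$inter[[k]], h2_reduced = h2r$inter[[k]],
         h2_reduced_inverted = h2v$inter[[k]])
  })
  names(inter) <- pair_keys
  structure(list(id = id, params = params,
                 fragments = frag$fragments, adjacency = frag$adjacency,
                 frag_sigs = frag_sigs, inter = inter,
                 total_segments = nrow(tr$segments), restarts = tr$restarts),
            class = "fragsig_signature")
}

#' @export
print.fragsig_signature <- function(x, ...) {
  cat("<fragsig_signature> ", x$id, ": ", nrow(x$fragments), " fragment(s), ",
      x$total_segments, " segments (",
      sprintf("%.1f%%", 100 * sum(vapply(x$inter, function(p) p$count, numeric(1))) /
                max(x$total_segments, 1)),
      " inter-fragment), bin ", x$params$bin_width, " A\n", sep = "")
  invisible(x)
}

#' Recover the unfragmented global histogram
#'
#' Count-weighted sum of corresponding bins over every intra- and
#' inter-fragment 1D histogram; on raw counts this equals a histogram
#' accumulated directly from all segments, and scoring with it reproduces
#' the original non-fragment method.
#'
#' @param sig a `fragsig_signature`.
#' @return normalized `fragsig_hist1d`.
#' @export
global_histogram <- function(sig) {
  hs <- c(lapply(sig$frag_sigs, function(f) f$h1), lapply(sig$inter, function(p) p$h1))
  hs <- Filter(Negate(is.null), hs)
  bw <- hs[[1]]$bin_width
  n <- max(vapply(hs, function(h) length(h$counts), numeric(1)))
  total <- numeric(n)
  for (h in hs) {
    stopifnot(h$bin_width == bw)
    total[seq_along(h$counts)] <- total[seq_along(h$counts)] + h$counts
  }
  normalize(new_hist1d(total, bw))
}

# fraction of segments on inter-fragment histograms
inter_fraction <- function(sig) {
  sum(vapply(sig$inter, function(p) p$count, numeric(1))) / sig$total_segments
}
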