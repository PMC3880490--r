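#' Construct a molecule object
#'
#' The internal chemical model: an ordered atom table with coordinates,
#' van der Waals radii and partial charges, plus a bond list.  Radii and
#' charges may be `NA` until assigned by [assign_radii()] / [ensure_charges()].
#'
#' @param id molecule identifier string.
#' @param atoms data frame with columns `element`, `x`, `y`, `z` and
#'   optionally `radius`, `charge`.
#' @param bonds data frame with columns `i`, `j` (1-based atom indices) and
#'   optionally `order` (character: `"1"`, `"2"`, `"3"`, `"ar"`, `"am"`).
#' @param source format tag, e.g. `"mol2"`, `"sdf"`, `"fixture"`.
#' @return an object of class `fragsig_molecule`.
#' @export
molecule <- function(id, atoms, bonds, source = "r") {
  atoms <- as_tibble(atoms)
  stopifnot(all(c("element", "x", "y", "z") %in% names(atoms)))
  if (!"radius" %in% names(atoms)) atoms$radius <- NA_real_
  if (!"charge" %in% names(atoms)) atoms$charge <- NA_real_
  atoms$element <- normalize_element(atoms$element)
  atoms$is_h <- atoms$element == "H"
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("molecule '", id, "': non-finite atomic coordinates")
  bonds <- as_tibble(bonds)
  if (nrow(bonds) > 0) {
    stopifnot(all(c("i", "j") %in% names(bonds)))
    if (is.null(bonds$order)) bonds$order <- "1"
    bonds$order <- as.character(bonds$order)
    n <- nrow(atoms)
    if (any(bonds$i < 1 | bonds$i > n | bonds$j < 1 | bonds$j > n))
      stop("molecule '", id, "': bond references an atom index out of range")
    if (any(bonds$i == bonds$j))
      stop("molecule '", id, "': self-bond")
  } else {
    bonds <- tibble(i = integer(), j = integer(), order = character())
  }
  structure(list(id = id, atoms = atoms, bonds = bonds, source = source),
            class = "fragsig_molecule")
}

#' @export
print.fragsig_molecule <- function(x, ...) {
  nh <- sum(!x$atoms$is_h)
  cat("<fragsig_molecule> ", x$id, ": ", nrow(x$atoms), " atoms (", nh,
      " heavy), ", nrow(x$bonds), " bonds [", x$source, "]\n", sep = "")
  invisible(x)
}

n_atoms <- function(mol) nrow(mol$atoms)
heavy_atoms <- function(mol) which(!mol$atoms$is_h)
coords <- function(mol) as.matrix(mol$atoms[, c("x", "y", "z")])

normalize_element <- function(e) {
  # mol2 atom types look like "C.3", "N.ar"; strip the hybridization suffix
  e <- sub("\\..*$", "", e)
  paste0(toupper(substr(e, 1, 1)), tolower(substr(e, 2, nchar(e))))
}

#' Read molecules from a MOL2 or SDF file
#'
#' Tripos MOL2 files (including multi-record files) are parsed with
#' \pkg{bio3d}; SDF/MOL V2000 files with \pkg{ChemmineR}.  3D coordinates
#' must be present; there is no embedding step.  Per-atom partial charges
#' found in a MOL2 file are preserved.
#'
#' @param path file path.
#' @param format `"mol2"`, `"sdf"`, or `"auto"` (from the file extension).
#' @return a single `fragsig_molecule`, or a list of them for multi-record
#'   files.
#' @export
read_molecule <- function(path, format = c("auto", "mol2", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mol2 = "mol2", sdf = "sdf", sd = "sdf", mol = "sdf",
                     stop("cannot infer format from extension '", ext, "'"))
  }
  mols <- switch(format, mol2 = read_mol2_multi(path), sdf = read_sdf_multi(path))
  if (length(mols) == 1) mols[[1]] else mols
}

read_mol2_multi <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^@<TRIPOS>MOLECULE", lines)
  if (length(starts) == 0) stop("malformed mol2 file (no @<TRIPOS>MOLECULE record): ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  lapply(seq_along(starts), function(r) {
    chunk <- lines[starts[r]:ends[r]]
    tf <- tempfile(fileext = ".mol2")
    on.exit(unlink(tf))
    writeLines(chunk, tf)
    m <- tryCatch(bio3d::read.mol2(tf),
                  error = function(e) stop("malformed mol2 record ", r, " in ", path,
                                           ": ", conditionMessage(e)),
                  warning = function(w) stop("malformed mol2 record ", r, " in ", path,
                                             ": ", conditionMessage(w)))
    at <- m$atom
    if (any(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z)))
      stop("mol2 record ", r, " in ", path, ": missing 3D coordinates")
    charges <- if ("charge" %in% names(at)) as.numeric(at$charge) else rep(NA_real_, nrow(at))
    atoms <- tibble(element = normalize_element(at$elety), x = at$x, y = at$y, z = at$z,
                    charge = charges)
    bonds <- if (is.null(m$bond) || nrow(m$bond) == 0) {
      tibble(i = integer(), j = integer(), order = character())
    } else {
      tibble(i = as.integer(m$bond$origin), j = as.integer(m$bond$target),
             order = as.character(m$bond$type))
    }
    id <- if (!is.null(m$name) && nzchar(m$name[1])) m$name[1] else
      sprintf("%s#%d", basename(path), r)
    molecule(id = id, atoms = atoms, bonds = bonds, source = "mol2")
  })
}

read_sdf_multi <- function(path) {
  if (!requireNamespace("ChemmineR", quietly = TRUE))
    stop("reading SDF requires the ChemmineR package")
  set <- tryCatch(ChemmineR::read.SDFset(path),
                  error = function(e) stop("malformed SDF file ", path, ": ",
                                           conditionMessage(e)))
  lapply(seq_along(set), function(r) {
    sdf <- set[[r]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    if (all(ab[, "C3"] == 0) && nrow(ab) > 1)
      stop("SDF record ", r, " in ", path, ": coordinates look 2D (all z = 0); ",
           "3D coordinates are required")
    el <- sub("_[0-9]+$", "", rownames(ab))
    atoms <- tibble(element = normalize_element(el),
                    x = ab[, 1], y = ab[, 2], z = ab[, 3], charge = NA_real_)
    bonds <- tibble(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                    order = as.character(bb[, 3]))
    id <- ChemmineR::sdfid(sdf)
    if (is.null(id) || !nzchar(id)) id <- sprintf("%s#%d", basename(path), r)
    molecule(id = id, atoms = atoms, bonds = bonds, source = "sdf")
  })
}

#' Write a molecule to a Tripos MOL2 file
#'
#' @param mol a `fragsig_molecule` (or list of them for a multi-record file).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_molecule <- function(mol, path) {
  mols <- if (inherits(mol, "fragsig_molecule")) list(mol) else mol
  con <- file(path, "w")
  on.exit(close(con))
  for (m in mols) {
    at <- m$atoms
    ch <- at$charge
    has_charges <- !all(is.na(ch))
    writeLines(c("@<TRIPOS>MOLECULE", m$id,
                 sprintf("%d %d 1", nrow(at), nrow(m$bonds)),
                 "SMALL",
                 if (has_charges) "USER_CHARGES" else "NO_CHARGES", ""), con)
    writeLines("@<TRIPOS>ATOM", con)
    for (i in seq_len(nrow(at))) {
      ln <- sprintf("%6d %-6s %10.4f %10.4f %10.4f %-6s %3d %-6s",
                    i, paste0(at$element[i], i), at$x[i], at$y[i], at$z[i],
                    at$element[i], 1L, "MOL")
      if (has_charges) ln <- sprintf("%s %10.4f", ln, ch[i])
      writeLines(ln, con)
    }
    writeLines("@<TRIPOS>BOND", con)
    b <- m$bonds
    for (k in seq_len(nrow(b)))
      writeLines(sprintf("%6d %5d %5d %4s", k, b$i[k], b$j[k], b$order[k]), con)
  }
  invisible(path)
}

#' Van der Waals radii table
#'
#' Named radii sets shipped as editable text resources under
#' `inst/extdata/`.  The default is the Bondi set.
#'
#' @param set radii set name (currently `"bondi"`).
#' @return named numeric vector, element symbol to radius in Angstrom.
#' @export
vdw_radii <- function(set = "bondi") {
  path <- system.file("extdata", paste0("radii_", set, ".tsv"), package = "fragsig")
  if (!nzchar(path)) stop("unknown radii set '", set, "'")
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
  setNames(tab$radius, tab$element)
}

#' Assign van der Waals radii to every atom
#'
#' @param mol a `fragsig_molecule`.
#' @param table either a radii set name (see [vdw_radii()]) or a named
#'   numeric vector element -> radius (Angstrom).
#' @return the molecule with `atoms$radius` filled; idempotent.
#' @export
assign_radii <- function(mol, table = "bondi") {
  radii <- if (is.character(table) && length(table) == 1) vdw_radii(table) else table
  el <- mol$atoms$element
  unknown <- setdiff(unique(el), names(radii))
  if (length(unknown) > 0)
    stop("no van der Waals radius for element(s): ", paste(unknown, collapse = ", "))
  r <- unname(radii[el])
  if (any(!is.finite(r) | r <= 0)) stop("radii table contains non-positive radii")
  mol$atoms$radius <- r
  mol
}

#' Ensure every atom carries a finite partial charge
#'
#' `"keep-imported"` requires charges to be present from the input file and
#' never overwrites them; `"gasteiger"` runs an in-package
#' electronegativity-equalization (PEOE) calculation; `"zero"` sets all
#' charges to zero, which makes all downstream electrostatic potentials zero
#' (pure-shape descriptors).
#'
#' @param mol a `fragsig_molecule`.
#' @param method `"keep-imported"`, `"gasteiger"`, or `"zero"`.
#' @return the molecule with `atoms$charge` finite everywhere.
#' @export
ensure_charges <- function(mol, method = c("keep-imported", "gasteiger", "zero")) {
  method <- match.arg(method)
  if (method == "keep-imported") {
    if (any(is.na(mol$atoms$charge)))
      stop("molecule '", mol$id, "' has no imported charges; use method = ",
           "\"gasteiger\" or \"zero\"")
    return(mol)
  }
  if (method == "zero") {
    mol$atoms$charge <- 0
    return(mol)
  }
  mol$atoms$charge <- gasteiger_charges(mol)
  mol
}
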