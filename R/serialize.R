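# Signature container format: gzip-compressed JSON with an embedded MD5
# checksum and a format version.  The payload is held as a canonical JSON
# string inside the envelope so the checksum is computed over exactly the
# bytes that are parsed back.

FRAGSIG_FORMAT_VERSION <- 1L

json_encode <- function(x) {
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null"))
}

md5_of_string <- function(s) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeChar(s, tf, eos = NULL)
  unname(tools::md5sum(tf))
}

write_container <- function(payload, kind, path) {
  ptxt <- json_encode(payload)
  env <- list(format = "fragsig", version = FRAGSIG_FORMAT_VERSION, kind = kind,
              checksum = md5_of_string(ptxt), payload = ptxt)
  con <- gzfile(path, "wb")
  on.exit(close(con))
  writeLines(json_encode(env), con)
  invisible(path)
}

read_container <- function(path, kind) {
  con <- gzfile(path, "rb")
  on.exit(close(con))
  txt <- tryCatch(paste(readLines(con, warn = FALSE), collapse = "\n"),
                  error = function(e) stop("cannot read container ", path, ": ",
                                           conditionMessage(e)))
  env <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = TRUE),
                  error = function(e) stop("container ", path,
                                           " is corrupt or truncated: ",
                                           conditionMessage(e)))
  if (!identical(env$format, "fragsig"))
    stop("not a fragsig container: ", path)
  if (!identical(as.integer(env$version), FRAGSIG_FORMAT_VERSION))
    stop("container version ", env$version, " is not supported (expected ",
         FRAGSIG_FORMAT_VERSION, ")")
  if (!identical(env$kind, kind))
    stop("container holds a '", env$kind, "', expected a '", kind, "'")
  if (!identical(md5_of_string(env$payload), env$checksum))
    stop("checksum mismatch: container ", path, " is corrupt or truncated")
  # no simplification: payload structure is reconstructed field by field
  jsonlite::fromJSON(env$payload, simplifyVector = FALSE)
}

# scalars serialized from NA arrive as "NA" strings or nulls; empty arrays as
# empty lists
from_json_vec <- function(x, as = as.numeric) {
  if (is.null(x)) return(as(NULL))
  if (!is.list(x)) x <- list(x)
  vals <- lapply(x, function(v)
    if (is.null(v) || identical(v, "NA")) NA else v)
  as(unlist(vals, use.names = FALSE))
}

hist1d_payload <- function(h) {
  if (is.null(h)) return(NULL)
  list(bin_width = h$bin_width, counts = as.numeric(h$counts))
}

hist1d_unpayload <- function(p) {
  if (is.null(p)) return(NULL)
  normalize(new_hist1d(from_json_vec(p$counts), p$bin_width))
}

hist2d_payload <- function(h) {
  if (is.null(h)) return(NULL)
  list(bin_width = h$bin_width, mep_axis = h$mep_axis,
       mep_bin_width = h$mep_bin_width, mep_max = h$mep_max,
       nrow = nrow(h$counts), ncol = ncol(h$counts),
       counts = as.numeric(h$counts))
}

hist2d_unpayload <- function(p) {
  if (is.null(p)) return(NULL)
  m <- matrix(from_json_vec(p$counts), p$nrow, p$ncol)
  normalize(new_hist2d(m, p$bin_width, p$mep_axis, p$mep_bin_width, p$mep_max))
}

fragsig_payload <- function(fs) {
  list(fragment = fs$fragment, count = fs$count,
       h1 = hist1d_payload(fs$h1), h2_full = hist2d_payload(fs$h2_full),
       h2_reduced = hist2d_payload(fs$h2_reduced),
       h2_reduced_inverted = hist2d_payload(fs$h2_reduced_inverted))
}

fragsig_unpayload <- function(p) {
  list(fragment = from_json_vec(p$fragment, as.integer),
       count = from_json_vec(p$count),
       h1 = hist1d_unpayload(p$h1), h2_full = hist2d_unpayload(p$h2_full),
       h2_reduced = hist2d_unpayload(p$h2_reduced),
       h2_reduced_inverted = hist2d_unpayload(p$h2_reduced_inverted))
}

signature_payload <- function(sig) {
  list(id = sig$id, params = sig$params,
       fragments = list(fragment = sig$fragments$fragment,
                        n_heavy = sig$fragments$n_heavy,
                        n_atoms = sig$fragments$n_atoms),
       adjacency = list(a = sig$adjacency$a, b = sig$adjacency$b),
       frag_sigs = lapply(unname(sig$frag_sigs), fragsig_payload),
       inter = lapply(unname(sig$inter), function(p)
         c(list(pair = p$pair), fragsig_payload(p))),
       total_segments = sig$total_segments, restarts = sig$restarts)
}

signature_unpayload <- function(p) {
  frag_sigs <- lapply(p$frag_sigs, fragsig_unpayload)
  names(frag_sigs) <- vapply(frag_sigs, function(f) as.character(f$fragment), character(1))
  inter <- lapply(p$inter, function(q) {
    out <- fragsig_unpayload(q)
    out$pair <- from_json_vec(q$pair, as.integer)
    out
  })
  names(inter) <- vapply(inter, function(q) paste(q$pair, collapse = "|"), character(1))
  params <- lapply(p$params, function(v)
    if (is.null(v) || identical(v, "NA")) NA else v)
  structure(list(
    id = p$id, params = params,
    fragments = tibble(fragment = from_json_vec(p$fragments$fragment, as.integer),
                       n_heavy = from_json_vec(p$fragments$n_heavy, as.integer),
                       n_atoms = from_json_vec(p$fragments$n_atoms, as.integer)),
    adjacency = tibble(a = from_json_vec(p$adjacency$a, as.integer),
                       b = from_json_vec(p$adjacency$b, as.integer)),
    frag_sigs = frag_sigs, inter = inter,
    total_segments = from_json_vec(p$total_segments),
    restarts = from_json_vec(p$restarts, as.integer)), class = "fragsig_signature")
}

#' Serialize a signature to a container file
#'
#' Lossless round trip of the full descriptor: raw counts, generation
#' parameters, fragmentation summary.  The container is gzip-compressed
#' JSON carrying a format version and an MD5 checksum; corruption and
#' version mismatches are detected on read.
#'
#' @param sig a `fragsig_signature`.
#' @param path output path (conventionally `.fsig`).
#' @return `path`, invisibly.
#' @export
write_signature <- function(sig, path) {
  write_container(signature_payload(sig), "signature", path)
}

#' @rdname write_signature
#' @return for `read_signature`, the deserialized `fragsig_signature`.
#' @export
read_signature <- function(path) {
  signature_unpayload(read_container(path, "signature"))
}

#' Export a signature as XML
#'
#' Human-readable export for interoperability and debugging; the container
#' format of [write_signature()] is the lossless native serialization.
#'
#' @param sig a `fragsig_signature`.
#' @param path output XML path.
#' @return `path`, invisibly.
#' @export
write_signature_xml <- function(sig, path) {
  doc <- xml2::xml_new_root("shape-signature", id = sig$id,
                            version = as.character(FRAGSIG_FORMAT_VERSION))
  pn <- xml2::xml_add_child(doc, "parameters")
  for (k in names(sig$params))
    xml2::xml_add_child(pn, "param", name = k, value = as.character(sig$params[[k]]))
  fn <- xml2::xml_add_child(doc, "fragments", count = as.character(nrow(sig$fragments)))
  for (r in seq_len(nrow(sig$fragments)))
    xml2::xml_add_child(fn, "fragment", id = as.character(sig$fragments$fragment[r]),
                        heavy = as.character(sig$fragments$n_heavy[r]))
  an <- xml2::xml_add_child(doc, "adjacency")
  for (r in seq_len(nrow(sig$adjacency)))
    xml2::xml_add_child(an, "edge", a = as.character(sig$adjacency$a[r]),
                        b = as.character(sig$adjacency$b[r]))
  hn <- xml2::xml_add_child(doc, "histograms")
  for (fs in sig$frag_sigs) {
    node <- xml2::xml_add_child(hn, "intra", fragment = as.character(fs$fragment),
                                segments = as.character(fs$count))
    h1n <- xml2::xml_add_child(node, "h1", bin_width = as.character(fs$h1$bin_width))
    xml2::xml_set_text(h1n, paste(fs$h1$counts, collapse = " "))
  }
  for (p in sig$inter) {
    node <- xml2::xml_add_child(hn, "inter", pair = paste(p$pair, collapse = "-"),
                                segments = as.character(p$count))
    if (!is.null(p$h1)) {
      h1n <- xml2::xml_add_child(node, "h1", bin_width = as.character(p$h1$bin_width))
      xml2::xml_set_text(h1n, paste(p$h1$counts, collapse = " "))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
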