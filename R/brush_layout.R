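#' Parse a 6HB brush-layout string
#'
#' Layouts describe which axial domains of a six-helix-bundle (6HB) DNA
#' origami carry grafted DNA brushes, using a run-length notation: the bundle
#' is divided into `n_domains` equal axial domains, the name lists contiguous
#' runs separated by `/`, and an asterisk marks a modified (brush-carrying)
#' run.  A suffix names the brush kind, e.g. `"6HB-5*/17/5*-DS"` is a
#' 27-domain bundle with 5 modified domains at each end, 17 bare domains in
#' the middle, and double-stranded brushes.  A bare `"6HB"` has no brushes.
#'
#' @param name layout string matching `6HB[-SEG(/SEG)*][-SS|-DS]` where
#'   `SEG` is a positive integer with optional `*`.
#' @param n_domains total number of axial domains (default 27).
#' @param density_factor integer k in 1..4; at k the nearest same-helix
#'   neighbour initiators sit k*42 bp apart, i.e. each helix carries a graft
#'   in every k-th modified domain (staggered across helices).
#' @return an object of class `brush_layout` with fields `n_domains`,
#'   `segments` (data.frame of `domain_count`, `modified`), `brush_kind`
#'   (`"NONE"`, `"SS"` or `"DS"`) and `density_factor`.
#' @examples
#' parse_layout("6HB-27*-SS")
#' parse_layout("6HB-5*/17/5*-DS")
#' parse_layout("6HB")
#' @export
parse_layout <- function(name, n_domains = 27, density_factor = 1L) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!(n_domains >= 1 && n_domains == as.integer(n_domains)))
    stop("parse error: n_domains must be a positive integer")
  if (!(density_factor %in% 1:4))
    stop("parse error: density_factor must be in 1..4")

  m <- regmatches(name, regexec(
    "^6HB(?:-((?:[0-9]+\\*?)(?:/[0-9]+\\*?)*))?(?:-(SS|DS))?$", name))[[1]]
  if (length(m) == 0L) stop("parse error: malformed layout name '", name, "'")
  seg_txt <- m[2]
  kind <- m[3]

  if (seg_txt == "") {
    segments <- data.frame(domain_count = as.integer(n_domains), modified = FALSE)
  } else {
    toks <- strsplit(seg_txt, "/", fixed = TRUE)[[1]]
    modified <- grepl("\\*$", toks)
    counts <- as.integer(sub("\\*$", "", toks))
    if (any(counts <= 0)) stop("parse error: zero-length segment")
    segments <- data.frame(domain_count = counts, modified = modified)
  }
  if (sum(segments$domain_count) != n_domains)
    stop("layout error: segment domain counts sum to ",
         sum(segments$domain_count), ", expected n_domains = ", n_domains)
  any_mod <- any(segments$modified)
  if (any_mod && kind == "")
    stop("layout error: modified domains (*) require an -SS or -DS suffix")
  if (!any_mod && kind != "")
    stop("layout error: brush kind ", kind, " given but no modified domain")

  structure(list(
    n_domains = as.integer(n_domains),
    segments = segments,
    brush_kind = if (any_mod) kind else "NONE",
    density_factor = as.integer(density_factor)
  ), class = "brush_layout")
}

#' Format a brush layout back to its canonical name
#'
#' Inverse of [parse_layout()] for canonical names (`parse -> format ->
#' parse` is the identity).
#'
#' @param spec a `brush_layout`.
#' @return the canonical layout string.
#' @export
format_layout <- function(spec) {
  stopifnot(inherits(spec, "brush_layout"))
  seg <- spec$segments
  one_bare <- nrow(seg) == 1L && !seg$modified[1]
  body <- if (one_bare && spec$brush_kind == "NONE") {
    ""
  } else {
    paste0("-", paste0(seg$domain_count, ifelse(seg$modified, "*", ""),
                       collapse = "/"))
  }
  suffix <- if (spec$brush_kind == "NONE") "" else paste0("-", spec$brush_kind)
  paste0("6HB", body, suffix)
}

#' @export
print.brush_layout <- function(x, ...) {
  cat(sprintf("<brush_layout> %s  (%d domains, kind %s, density factor %d)\n",
              format_layout(x), x$n_domains, x$brush_kind, x$density_factor))
  invisible(x)
}

# 1-based indices of modified domains, in axial order
modified_domains <- function(spec) {
  idx <- rep(seq_len(nrow(spec$segments)), spec$segments$domain_count)
  which(spec$segments$modified[idx])
}

#' Enumerate brush graft sites on the bundle
#'
#' Each modified domain offers one graft position on each of the six helices,
#' at the domain's axial centre.  At density factor k only every k-th
#' modified domain per helix carries a graft, staggered across helices
#' (helix h keeps the modified domains whose ordinal position among all
#' modified domains is congruent to h mod k), so the full-coverage 27-domain
#' layout yields 162 sites at k = 1 and 81 at k = 2.
#'
#' @param spec a `brush_layout`.
#' @param bundle_length bundle length in nm.
#' @return data.frame with columns `site_id`, `domain_index` (1-based),
#'   `helix_index` (0..5), `axial_position_nm`, ordered by (domain, helix).
#' @examples
#' nrow(enumerate_graft_sites(parse_layout("6HB-27*-SS"), 400))  # 162
#' @export
enumerate_graft_sites <- function(spec, bundle_length) {
  stopifnot(inherits(spec, "brush_layout"))
  if (!(is.numeric(bundle_length) && bundle_length > 0))
    stop("bundle_length must be > 0")
  mods <- modified_domains(spec)
  k <- spec$density_factor
  if (length(mods) == 0L) {
    return(data.frame(site_id = integer(), domain_index = integer(),
                      helix_index = integer(), axial_position_nm = numeric()))
  }
  domain_len <- bundle_length / spec$n_domains
  rows <- do.call(rbind, lapply(seq_along(mods), function(ord) {
    helices <- which((0:5) %% k == (ord - 1) %% k) - 1L
    if (length(helices) == 0L) return(NULL)
    data.frame(domain_index = mods[ord], helix_index = helices)
  }))
  rows <- rows[order(rows$domain_index, rows$helix_index), , drop = FALSE]
  rows$axial_position_nm <- (rows$domain_index - 0.5) * domain_len
  data.frame(site_id = seq_len(nrow(rows)),
             domain_index = rows$domain_index,
             helix_index = rows$helix_index,
             axial_position_nm = rows$axial_position_nm,
             row.names = NULL)
}

#' Axial BRUSH/BARE region map of a layout
#'
#' Converts the layout's segments into contiguous half-open axial intervals
#' labelled `BRUSH` (modified) or `BARE`, partitioning `[0, bundle_length)`.
#'
#' @param spec a `brush_layout`.
#' @param bundle_length bundle length in nm.
#' @return data.frame with columns `start_nm`, `end_nm`, `label`.
#' @export
assign_regions <- function(spec, bundle_length) {
  stopifnot(inherits(spec, "brush_layout"), bundle_length > 0)
  seg <- spec$segments
  domain_len <- bundle_length / spec$n_domains
  ends <- cumsum(seg$domain_count) * domain_len
  starts <- c(0, ends[-length(ends)])
  data.frame(start_nm = starts, end_nm = ends,
             label = ifelse(seg$modified, "BRUSH", "BARE"))
}

#' Write graft sites to CSV
#'
#' @param sites data.frame from [enumerate_graft_sites()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_graft_sites <- function(sites, path) {
  utils::write.csv(sites, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
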