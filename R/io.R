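#' Configuration files, trajectory/topology export and provenance
#'
#' Run configurations are YAML documents mirroring [default_config()].
#' Validation is strict: unknown keys are rejected so that every
#' under-specified model constant stays visible and versioned.
#'
#' @name io
NULL

config_schema <- function() {
  list(layout = "character", n_domains = "integer",
       domain_length_nm = "numeric", density_factor = "integer",
       brush = list(contour_nm = "numeric"),
       precursors = list(count = "integer", min_separation_nm = "numeric"),
       salt = list(mono_mM = "numeric", di_mM = "numeric", mode = "character"),
       forcefield = list(wca_epsilon = "numeric",
                         attraction_epsilon = "numeric",
                         attraction_range = "numeric", pair_cutoff = "numeric",
                         bjerrum_length = "numeric"),
       integrator = list(dt = "numeric", n_steps = "integer",
                         frame_stride = "integer"),
       analysis = list(r_condense = "numeric", r_near = "numeric",
                       grace = "integer",
                       residence_min_radial_nm = "numeric",
                       window_fraction = "numeric"))
}

validate_against <- function(value, schema, path) {
  if (is.list(schema)) {
    if (!is.list(value))
      stop("config error at ", path, ": expected a section")
    unknown <- setdiff(names(value), names(schema))
    if (length(unknown))
      stop("config error at ", path, ": unknown key(s) ",
           paste(unknown, collapse = ", "))
    for (k in names(value))
      validate_against(value[[k]], schema[[k]], paste0(path, "/", k))
  } else {
    ok <- switch(schema,
                 character = is.character(value),
                 integer = is.numeric(value) && all(value == round(value)),
                 numeric = is.numeric(value))
    if (!ok) stop("config error at ", path, ": expected ", schema)
  }
  invisible(TRUE)
}

#' Read and validate a run configuration
#'
#' Missing keys fall back to [default_config()]; unknown keys are errors.
#'
#' @param path YAML file path.
#' @return a validated configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  validate_against(user, config_schema(), "")
  modifyList(default_config(), user)
}

#' Write a configuration to YAML
#'
#' @param config configuration list.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_config <- function(config, path) {
  validate_against(config, config_schema(), "")
  yaml::write_yaml(config, path)
  invisible(path)
}

# element symbols used for the species in XYZ/PDB exports
species_element <- c(CORE = "C", SS_BEAD = "S", DS_BEAD = "P",
                     PRECURSOR = "O", ION_MONO = "N", ION_DI = "M")

#' Write a trajectory (or single frame) as multi-frame XYZ
#'
#' Species are encoded in the element column (CORE C, SS_BEAD S, DS_BEAD P,
#' PRECURSOR O, ION_MONO N, ION_DI M); coordinates in nm.
#'
#' @param traj a `cg_trajectory`.
#' @param path output path.
#' @param frames frame indices (default all).
#' @return the path, invisibly.
#' @export
write_xyz <- function(traj, path, frames = NULL) {
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  el <- species_element[traj$topology$beads$species]
  con <- file(path, "w")
  on.exit(close(con))
  for (f in frames) {
    pos <- frame_positions(traj, f)
    writeLines(c(as.character(length(el)),
                 sprintf("frame %d time %.4f tau", f, traj$times[f])), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", el, pos[, 1], pos[, 2], pos[, 3]),
               con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ file
#'
#' @param path XYZ path.
#' @return list with `frames` (N x 3 x F array), `elements`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1
  el <- NULL
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    block <- lines[(i + 2):(i + 1 + n)]
    parts <- do.call(rbind, strsplit(trimws(block), "\\s+"))
    el <- parts[, 1]
    frames[[length(frames) + 1]] <- matrix(as.numeric(parts[, 2:4]), ncol = 3)
    i <- i + 2 + n
  }
  arr <- array(unlist(frames), dim = c(length(el), 3, length(frames)))
  list(frames = arr, elements = el)
}

#' Export a topology as PDB plus JSON sidecar
#'
#' Beads become HETATM pseudo-atoms (species in the residue name,
#' coordinates in Angstrom as PDB requires); bonds, angles, charges, radii
#' and the box go into a JSON sidecar next to the PDB.
#'
#' @param topo a `cg_topology`.
#' @param path PDB output path; the sidecar is `<path>.json`.
#' @return paths, invisibly.
#' @export
write_topology_pdb <- function(topo, path) {
  b <- topo$beads
  el <- species_element[b$species]
  res <- substr(b$species, 1, 3)
  lines <- sprintf(
    "HETATM%5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    b$bead_id %% 100000, el, res, (b$bead_id - 1) %% 10000 + 1,
    b$x * 10, b$y * 10, b$z * 10, el)
  writeLines(c(lines, "END"), path)
  side <- paste0(path, ".json")
  jsonlite::write_json(list(
    beads = b[, c("bead_id", "species", "charge", "radius", "chain_id", "fixed")],
    bonds = topo$bonds, angles = topo$angles,
    box = list(lx = topo$box$lx, ly = topo$box$ly, lz = topo$box$lz,
               boundary = as.list(topo$box$boundary)),
    geometry = unclass(topo$geometry)),
    side, auto_unbox = TRUE, digits = NA)
  invisible(c(pdb = path, json = side))
}

#' Reload a topology from its PDB + JSON export
#'
#' @param path the PDB path written by [write_topology_pdb()].
#' @return a `cg_topology`.
#' @export
read_topology_pdb <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  lines <- grep("^HETATM", readLines(path), value = TRUE)
  xyz <- cbind(as.numeric(substr(lines, 31, 38)),
               as.numeric(substr(lines, 39, 46)),
               as.numeric(substr(lines, 47, 54))) / 10
  beads <- side$beads
  beads$x <- xyz[, 1]; beads$y <- xyz[, 2]; beads$z <- xyz[, 3]
  beads <- beads[, c("bead_id", "species", "charge", "radius",
                     "x", "y", "z", "chain_id", "fixed")]
  bonds <- if (length(side$bonds)) side$bonds else
    data.frame(i = integer(), j = integer(), r0 = numeric(), k = numeric())
  angles <- if (length(side$angles)) side$angles else
    data.frame(i = integer(), j = integer(), k_idx = integer(),
               theta0 = numeric(), kappa = numeric())
  geom <- do.call(geometry_params, side$geometry)
  box <- box_spec(side$box$lx, side$box$ly, side$box$lz,
                  unlist(side$box$boundary))
  topo <- new_topology(beads, bonds, angles, box, geom)
  topo$core_beads_per_helix <- sum(beads$species == "CORE") / 6
  topo
}

#' Provenance record for a run
#'
#' @param config configuration list.
#' @param seed integer seed.
#' @return list with the config, its hash, seed, package version, date.
#' @export
provenance <- function(config, seed) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  list(config = config,
       config_hash = sprintf("%08x", sum(utf8ToInt(cfg_json) *
                                           (seq_along(utf8ToInt(cfg_json)) %% 257))),
       seed = seed,
       package_version = as.character(utils::packageVersion("silicabrush")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
}

#' Write tidy condensation results and a JSON summary
#'
#' @param studies list of results from [condensation_study()].
#' @param dir output directory (created if needed).
#' @param config configuration list for provenance.
#' @return paths of the files written, invisibly.
#' @export
write_results <- function(studies, dir, config = default_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (st in studies) {
    for (r in st$runs) {
      s <- r$condensation$series
      rows[[length(rows) + 1]] <- data.frame(
        kind = st$kind, seed = r$seed, time = s$time,
        count_brush = s$count_brush, count_bare = s$count_bare)
    }
  }
  csv <- file.path(dir, "condensation_timeseries.csv")
  utils::write.csv(do.call(rbind, rows), csv, row.names = FALSE)
  summ <- lapply(studies, function(st) list(
    kind = st$kind,
    enhancement_percent = st$enhancement$mean_percent,
    enhancement_se = st$enhancement$se_percent,
    mean_residence_tau = st$mean_residence))
  js <- file.path(dir, "summary.json")
  jsonlite::write_json(list(results = summ,
                            provenance = provenance(config, NA)),
                       js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv, json = js))
}
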