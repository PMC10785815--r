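#' Geometry of the six-helix bundle
#'
#' The 6HB is modelled as six straight, parallel strings of fixed beads whose
#' centres sit on a ring of radius `helix_ring_radius`; with 1-nm-radius
#' helices this gives the theoretical 6-nm envelope diameter.  The bundle
#' axis is the z axis, spanning `[0, bundle_length)`.
#'
#' @param bundle_length bundle length in nm.
#' @param helix_ring_radius radius of the ring of helix centres (nm).
#' @param helix_radius radius of one duplex (nm).
#' @param core_bead_spacing axial spacing of core beads (nm); 0.68 nm = 2 bp.
#' @param rise_per_bp helical rise (nm/bp).
#' @return a `geometry_params` list.
#' @export
geometry_params <- function(bundle_length,
                            helix_ring_radius = 2.0,
                            helix_radius = 1.0,
                            core_bead_spacing = 0.68,
                            rise_per_bp = 0.34) {
  if (!(bundle_length > 0)) stop("geometry error: bundle_length must be > 0")
  structure(list(bundle_length = bundle_length,
                 helix_ring_radius = helix_ring_radius,
                 helix_radius = helix_radius,
                 core_bead_spacing = core_bead_spacing,
                 rise_per_bp = rise_per_bp),
            class = "geometry_params")
}

#' Envelope diameter of the bundle cross-section
#'
#' Maximal cross-section extent: bead centre-to-centre distance across the
#' ring plus two helix radii (6.0 nm at defaults).
#'
#' @param geometry a `geometry_params`.
#' @return diameter in nm.
#' @export
envelope_diameter <- function(geometry) {
  2 * (geometry$helix_ring_radius + geometry$helix_radius)
}

# Per-species defaults: effective (Manning-renormalised) charges in e,
# excluded-volume radii in nm, and Stokes-like friction per bead in
# kBT*tau/nm^2 (gamma proportional to radius; 1 for the 0.5-nm precursor).
species_defaults <- function() {
  data.frame(
    species = SPECIES_LEVELS,
    charge = c(-1.0, -0.75, -1.5, +1.0, +1.0, +2.0),
    radius = c(1.0, 0.4, 0.5, 0.5, 0.2, 0.3),
    gamma  = c(2.0, 0.8, 1.0, 1.0, 0.4, 0.6),
    stringsAsFactors = FALSE
  )
}

# Brush chain defaults: coarse mapping, bond length and rest bending.
# SS: 3 nt/bead, freely jointed; DS: 3 bp/bead, kappa chosen so the chain
# persistence length ~ kappa * bond = 50 nm.
brush_defaults <- function(kind) {
  switch(kind,
    SS = list(species = "SS_BEAD", bond = 1.5, k_bond = 100, kappa = 0,
              units_per_bead = 3),
    DS = list(species = "DS_BEAD", bond = 1.0, k_bond = 100, kappa = 50,
              units_per_bead = 3),
    stop("brush kind must be SS or DS"))
}

#' Number of brush beads for a nucleotide count
#'
#' @param n_units nucleotides (SS) or base pairs (DS).
#' @param kind `"SS"` or `"DS"`.
#' @return bead count (3 nt or bp per bead, rounded up).
#' @export
beads_for_units <- function(n_units, kind) {
  as.integer(ceiling(n_units / brush_defaults(kind)$units_per_bead))
}

#' Simulation box specification
#'
#' Reflecting walls radially (x, y) and a periodic axial (z) boundary
#' approximate an infinite bundle segment while conserving precursor count.
#' The box is centred on the bundle axis in x and y.
#'
#' @param lx,ly,lz box edge lengths (nm); z should equal the bundle length
#'   when the axial boundary is periodic.
#' @param boundary named character vector, per-axis `"REFLECTING"` or
#'   `"PERIODIC"`.
#' @return a `box_spec` list.
#' @export
box_spec <- function(lx, ly, lz,
                     boundary = c(x = "REFLECTING", y = "REFLECTING",
                                  z = "PERIODIC")) {
  stopifnot(lx > 0, ly > 0, lz > 0,
            all(boundary %in% c("REFLECTING", "PERIODIC")),
            all(c("x", "y", "z") %in% names(boundary)))
  structure(list(lx = lx, ly = ly, lz = lz,
                 boundary = boundary[c("x", "y", "z")]),
            class = "box_spec")
}

#' Default box for a bundle with brushes
#'
#' Radial half-width is the bundle envelope radius plus twice the brush
#' contour length (clearance so brushes never interact with the walls);
#' the axial extent equals the bundle length (periodic image).
#'
#' @param geometry a `geometry_params`.
#' @param brush_contour brush contour length in nm (0 for bare bundles).
#' @return a `box_spec`.
#' @export
default_box <- function(geometry, brush_contour = 0) {
  half <- geometry$helix_ring_radius + geometry$helix_radius +
    max(2 * brush_contour, 10)
  box_spec(2 * half, 2 * half, geometry$bundle_length)
}

empty_beads <- function() {
  data.frame(bead_id = integer(), species = character(), charge = numeric(),
             radius = numeric(), x = numeric(), y = numeric(), z = numeric(),
             chain_id = integer(), fixed = logical(),
             stringsAsFactors = FALSE)
}

new_topology <- function(beads, bonds, angles, box, geometry) {
  structure(list(beads = beads, bonds = bonds, angles = angles,
                 box = box, geometry = geometry,
                 grafts = NULL),
            class = "cg_topology")
}

#' @export
print.cg_topology <- function(x, ...) {
  tab <- table(factor(x$beads$species, levels = SPECIES_LEVELS))
  cat("<cg_topology>", nrow(x$beads), "beads |",
      nrow(x$bonds), "bonds |", nrow(x$angles), "angles\n")
  cat("  ", paste(sprintf("%s:%d", names(tab)[tab > 0], tab[tab > 0]),
                  collapse = "  "), "\n")
  cat(sprintf("   box %.1f x %.1f x %.1f nm (%s/%s/%s)\n",
              x$box$lx, x$box$ly, x$box$lz,
              x$box$boundary[1], x$box$boundary[2], x$box$boundary[3]))
  invisible(x)
}

#' Build the rigid 6HB core
#'
#' Six straight strings of fixed beads on the helix ring, one bead every
#' `core_bead_spacing` nm (2 bp), each with the CORE default charge.  Fixed
#' beads feel forces in analyses but are never integrated.
#'
#' @param geometry a `geometry_params`.
#' @param box optional `box_spec`; default [default_box()] with no brushes.
#' @return a `cg_topology`.
#' @examples
#' topo <- build_core(geometry_params(100))
#' nrow(topo$beads)  # 888
#' @export
build_core <- function(geometry, box = NULL) {
  stopifnot(inherits(geometry, "geometry_params"))
  if (geometry$bundle_length < geometry$core_bead_spacing)
    stop("geometry error: bundle_length < core_bead_spacing")
  if (is.null(box)) box <- default_box(geometry)
  sd <- species_defaults()
  core <- sd[sd$species == "CORE", ]

  n_per <- floor(geometry$bundle_length / geometry$core_bead_spacing) + 1
  zs <- (seq_len(n_per) - 1) * geometry$core_bead_spacing
  phis <- (0:5) * pi / 3
  beads <- do.call(rbind, lapply(0:5, function(h) {
    data.frame(bead_id = NA_integer_, species = "CORE",
               charge = core$charge, radius = core$radius,
               x = geometry$helix_ring_radius * cos(phis[h + 1]),
               y = geometry$helix_ring_radius * sin(phis[h + 1]),
               z = zs, chain_id = 0L, fixed = TRUE,
               stringsAsFactors = FALSE)
  }))
  beads$bead_id <- seq_len(nrow(beads))
  topo <- new_topology(beads,
                       data.frame(i = integer(), j = integer(),
                                  r0 = numeric(), k = numeric()),
                       data.frame(i = integer(), j = integer(), k_idx = integer(),
                                  theta0 = numeric(), kappa = numeric()),
                       box, geometry)
  topo$core_beads_per_helix <- n_per
  topo
}

# Index of the core bead on helix h nearest to axial position z
core_anchor_index <- function(topo, helix_index, axial_position) {
  n_per <- topo$core_beads_per_helix
  slot <- round(axial_position / topo$geometry$core_bead_spacing)
  slot <- max(0, min(n_per - 1, slot))
  helix_index * n_per + slot + 1L
}

#' Graft brush chains at the given sites
#'
#' Each graft site gains a linear bead-spring chain bonded to the nearest
#' core bead of its helix.  Single-stranded (SS) chains are freely jointed
#' with low per-bead charge; double-stranded (DS) chains carry a harmonic
#' bending potential tuned to a ~50-nm persistence length and higher charge.
#' Initial conformations are straight radial rays with a small seeded
#' Gaussian perturbation (0.05 nm per coordinate).
#'
#' @param topo a `cg_topology` containing a core.
#' @param sites data.frame from [enumerate_graft_sites()].
#' @param n_beads beads per chain.
#' @param kind `"SS"` or `"DS"`.
#' @param seed integer seed for the conformational jitter.
#' @return the augmented `cg_topology`; `topo$grafts` records site, anchor
#'   bead and chain id.
#' @export
attach_brushes <- function(topo, sites, n_beads, kind, seed = 1L) {
  stopifnot(inherits(topo, "cg_topology"))
  if (nrow(sites) == 0L) return(topo)
  if (n_beads < 1) stop("n_beads must be >= 1")
  bp <- brush_defaults(kind)
  sd <- species_defaults()
  brow <- sd[sd$species == bp$species, ]
  geom <- topo$geometry
  contour <- bp$bond * n_beads
  half_x <- topo$box$lx / 2
  if (geom$helix_ring_radius + geom$helix_radius + contour + brow$radius > half_x)
    stop("box error: brush chains would exit the box radially")

  old_n <- nrow(topo$beads)
  next_chain <- max(topo$beads$chain_id, 0L)
  withr_seed <- seed    # all build randomness flows through set.seed
  set.seed(withr_seed)

  bead_rows <- vector("list", nrow(sites))
  bond_rows <- vector("list", nrow(sites))
  angle_rows <- vector("list", nrow(sites))
  grafts <- sites
  grafts$anchor_bead <- NA_integer_
  grafts$chain_id <- NA_integer_
  grafts$first_bead <- NA_integer_

  for (s in seq_len(nrow(sites))) {
    h <- sites$helix_index[s]
    anchor <- core_anchor_index(topo, h, sites$axial_position_nm[s])
    a <- topo$beads[anchor, ]
    dir <- c(cos(h * pi / 3), sin(h * pi / 3), 0)  # outward radial ray
    d0 <- a$radius + brow$radius                   # anchor bond rest length
    dist <- d0 + bp$bond * (seq_len(n_beads) - 1)
    px <- a$x + dir[1] * dist + stats::rnorm(n_beads, 0, 0.05)
    py <- a$y + dir[2] * dist + stats::rnorm(n_beads, 0, 0.05)
    pz <- a$z + dir[3] * dist + stats::rnorm(n_beads, 0, 0.05)
    ids <- old_n + (s - 1) * n_beads + seq_len(n_beads)
    chain <- next_chain + s
    bead_rows[[s]] <- data.frame(
      bead_id = ids, species = bp$species, charge = brow$charge,
      radius = brow$radius, x = px, y = py, z = pz,
      chain_id = chain, fixed = FALSE, stringsAsFactors = FALSE)
    bi <- c(anchor, ids[-n_beads])
    bj <- ids
    bond_rows[[s]] <- data.frame(i = bi, j = bj,
                                 r0 = c(d0, rep(bp$bond, n_beads - 1)),
                                 k = bp$k_bond)
    if (bp$kappa > 0 && n_beads >= 3) {
      trip <- seq_len(n_beads - 2)
      angle_rows[[s]] <- data.frame(i = ids[trip], j = ids[trip + 1],
                                    k_idx = ids[trip + 2],
                                    theta0 = pi, kappa = bp$kappa)
    }
    grafts$anchor_bead[s] <- anchor
    grafts$chain_id[s] <- chain
    grafts$first_bead[s] <- ids[1]
  }

  topo$beads <- rbind(topo$beads, do.call(rbind, bead_rows))
  topo$bonds <- rbind(topo$bonds, do.call(rbind, bond_rows))
  ang <- do.call(rbind, angle_rows)
  if (!is.null(ang)) topo$angles <- rbind(topo$angles, ang)
  topo$grafts <- rbind(topo$grafts, grafts)
  topo$brush_kind <- kind
  topo$brush_contour_nm <- contour
  topo
}

# Uniform random point in the box (box centred in x/y, z in [0, lz))
runif_in_box <- function(n, box) {
  cbind(stats::runif(n, -box$lx / 2, box$lx / 2),
        stats::runif(n, -box$ly / 2, box$ly / 2),
        stats::runif(n, 0, box$lz))
}

min_image_dz <- function(dz, lz) dz - lz * round(dz / lz)

# TRUE when point p clears every row of mat by the row-wise required
# distance (centre-to-centre), under the box's z image
clears_all <- function(p, mat, required, box) {
  if (nrow(mat) == 0L) return(TRUE)
  dx <- mat[, 1] - p[1]
  dy <- mat[, 2] - p[2]
  dz <- mat[, 3] - p[3]
  if (box$boundary["z"] == "PERIODIC") dz <- min_image_dz(dz, box$lz)
  all(dx * dx + dy * dy + dz * dz >= required^2)
}

place_random_beads <- function(topo, count, species, charge, radius,
                               min_separation, seed, max_tries = 2000L) {
  if (count == 0L) return(topo)
  set.seed(seed)
  box <- topo$box
  existing <- as.matrix(topo$beads[, c("x", "y", "z")])
  # clear both the stated separation and hard-sphere contact
  req_exist <- pmax(min_separation, topo$beads$radius + radius)
  req_same <- max(min_separation, 2 * radius)
  placed <- matrix(numeric(0), ncol = 3)
  for (i in seq_len(count)) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      p <- runif_in_box(1, box)[1, ]
      if (clears_all(p, existing, req_exist, box) &&
          clears_all(p, placed, req_same, box)) {
        placed <- rbind(placed, p)
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("packing error: could not place bead ", i, " of ", count,
                  " at min_separation ", min_separation)
  }
  old_n <- nrow(topo$beads)
  sd <- species_defaults()
  topo$beads <- rbind(topo$beads, data.frame(
    bead_id = old_n + seq_len(count), species = species, charge = charge,
    radius = radius, x = placed[, 1], y = placed[, 2], z = placed[, 3],
    chain_id = 0L, fixed = FALSE, stringsAsFactors = FALSE))
  topo
}

#' Build a gas of unconnected particles
#'
#' A minimal topology with no bundle: `count` beads of one species placed
#' uniformly at random.  Used for free-diffusion and equilibrium-sampling
#' validation of the integrator.
#'
#' @param count number of particles.
#' @param box a `box_spec`.
#' @param species species name (default PRECURSOR).
#' @param charge per-bead charge override (default: species default).
#' @param seed integer seed.
#' @param min_separation packing distance (nm).
#' @return a `cg_topology` with no bonds or angles.
#' @export
particle_gas <- function(count, box, species = "PRECURSOR", charge = NULL,
                         seed = 1L, min_separation = NULL) {
  sd <- species_defaults()
  row <- sd[sd$species == species, ]
  if (nrow(row) == 0) stop("unknown species: ", species)
  if (is.null(charge)) charge <- row$charge
  if (is.null(min_separation)) min_separation <- 2 * row$radius
  topo <- new_topology(empty_beads(),
                       data.frame(i = integer(), j = integer(),
                                  r0 = numeric(), k = numeric()),
                       data.frame(i = integer(), j = integer(),
                                  k_idx = integer(), theta0 = numeric(),
                                  kappa = numeric()),
                       box, geometry_params(box$lz))
  place_random_beads(topo, as.integer(count), species, charge, row$radius,
                     min_separation, seed)
}

#' Place cationic silica precursors
#'
#' TMAPS/TEOS precursors are modelled jointly as small +1 beads placed
#' uniformly at random in the box, at least `min_separation` from every
#' existing bead.  Identical seeds give identical placements.
#'
#' @param topo a `cg_topology`.
#' @param count number of precursors.
#' @param min_separation minimum centre-to-centre distance (nm).
#' @param seed integer seed.
#' @return the augmented `cg_topology`.
#' @export
place_precursors <- function(topo, count, min_separation = 1.0, seed = 1L) {
  stopifnot(count >= 0)
  sd <- species_defaults()
  p <- sd[sd$species == "PRECURSOR", ]
  place_random_beads(topo, as.integer(count), "PRECURSOR", p$charge, p$radius,
                     min_separation, seed)
}

#' Ion counts for a molar concentration and box volume
#'
#' @param conc_mM concentration in mmol/L.
#' @param box a `box_spec`.
#' @return rounded particle count (c * V * N_A).
#' @export
ion_count <- function(conc_mM, box) {
  v_nm3 <- box$lx * box$ly * box$lz
  round(conc_mM * 6.02214076e-4 * v_nm3)
}

#' Add explicit salt ions
#'
#' Adds +1 and +2 cations at the counts implied by the concentrations and
#' box volume, then monovalent counter-ions for exact electroneutrality.
#'
#' @param topo a `cg_topology`.
#' @param mono_mM monovalent cation concentration (mM).
#' @param di_mM divalent cation concentration (mM).
#' @param seed integer seed.
#' @param min_separation packing distance (nm).
#' @return the augmented, net-neutral `cg_topology`.
#' @export
add_salt <- function(topo, mono_mM, di_mM, seed = 1L, min_separation = 0.5) {
  stopifnot(mono_mM >= 0, di_mM >= 0)
  n_di <- ion_count(di_mM, topo$box)
  n_mono <- ion_count(mono_mM, topo$box)
  if (n_di == 0 && n_mono == 0) return(topo)
  sd <- species_defaults()
  di <- sd[sd$species == "ION_DI", ]
  mo <- sd[sd$species == "ION_MONO", ]
  topo <- place_random_beads(topo, n_di, "ION_DI", di$charge, di$radius,
                             min_separation, seed)
  topo <- place_random_beads(topo, n_mono, "ION_MONO", mo$charge, mo$radius,
                             min_separation, seed + 1L)
  q <- sum(topo$beads$charge)
  if (q > 0) {
    topo <- place_random_beads(topo, as.integer(round(q)), "ION_MONO",
                               -1.0, mo$radius, min_separation, seed + 2L)
  } else if (q < 0) {
    topo <- place_random_beads(topo, as.integer(round(-q)), "ION_MONO",
                               +1.0, mo$radius, min_separation, seed + 2L)
  }
  topo
}
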