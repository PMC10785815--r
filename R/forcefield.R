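#' Debye screening length
#'
#' lambda_D = 0.304 nm / sqrt(I) at 298 K, with ionic strength
#' I = 1/2 sum c_i z_i^2 in mol/L.  Monovalent salt contributes its own
#' concentration; a divalent chloride salt contributes three times its
#' concentration (the cation at z = 2 plus two monovalent counter-ions).
#' The 0.304 prefactor absorbs the sqrt(eps(T) k_B T) temperature scaling
#' at the reference 298 K.
#'
#' @param mono_mM monovalent salt concentration (mM).
#' @param di_mM divalent (e.g. MgCl2) concentration (mM).
#' @param temperature_K temperature; only 298 K is parameterised.
#' @return screening length in nm.
#' @examples
#' debye_length(100, 0)  # 0.96 nm
#' debye_length(0, 5)    # 2.48 nm
#' @export
debye_length <- function(mono_mM, di_mM = 0, temperature_K = 298) {
  stopifnot(mono_mM >= 0, di_mM >= 0)
  if (mono_mM == 0 && di_mM == 0)
    stop("undefined-screening error: at least one salt concentration must be > 0")
  I <- mono_mM / 1000 + 3 * di_mM / 1000
  0.304 / sqrt(I)
}

#' Force-field parameters
#'
#' Non-bonded interactions are the sum of (i) WCA excluded volume between
#' all pairs, (ii) Debye-Hueckel screened Coulomb between charged pairs,
#' energy-shifted to vanish at `pair_cutoff`, and (iii) a short-range
#' attractive well (the attractive branch of a Lennard-Jones potential, flat
#' at depth `attraction_epsilon` inside its minimum, energy-shifted to zero
#' at `attraction_range`) between precursors and DNA beads only.  The
#' attraction is the effective stand-in for TMAPS/TEOS-DNA condensation
#' chemistry; one scalar applies to every DNA species so that any
#' brush-region selectivity must come from charge and geometry.
#'
#' `attraction_epsilon`'s default is the package calibration: it was fixed
#' once so that the double-stranded-brush system reproduces the ~54%
#' condensation enhancement, and is then frozen for every other analysis.
#'
#' @param debye_length screening length in nm.
#' @param bjerrum_length Bjerrum length in nm (0.71 in water at 298 K).
#' @param wca_epsilon WCA repulsion strength (kBT).
#' @param attraction_epsilon precursor-DNA well depth (kBT).
#' @param attraction_range cutoff of the attractive well (nm).
#' @param pair_cutoff global non-bonded cutoff (nm).
#' @param mono_mM,di_mM implicit-salt concentrations used to derive
#'   `debye_length` when it is not given directly.
#' @return a `forcefield_params` list.
#' @export
forcefield_params <- function(debye_length = NULL,
                              bjerrum_length = 0.71,
                              wca_epsilon = 1.0,
                              attraction_epsilon = 0.45,
                              attraction_range = 3.5,
                              pair_cutoff = 6.0,
                              mono_mM = 0, di_mM = 5) {
  if (is.null(debye_length))
    debye_length <- debye_length(mono_mM, di_mM)
  stopifnot(debye_length > 0, bjerrum_length > 0, wca_epsilon >= 0,
            attraction_range > 0, pair_cutoff > 0)
  if (attraction_range > pair_cutoff)
    stop("attraction_range must not exceed pair_cutoff")
  structure(list(debye_length = debye_length,
                 bjerrum_length = bjerrum_length,
                 wca_epsilon = wca_epsilon,
                 attraction_epsilon = attraction_epsilon,
                 attraction_range = attraction_range,
                 pair_cutoff = pair_cutoff,
                 mono_mM = mono_mM, di_mM = di_mM),
            class = "forcefield_params")
}

# Is (i, j) a precursor-DNA pair (the only pairs feeling the attraction)?
is_attraction_pair <- function(species_i, species_j) {
  dna <- c("CORE", "SS_BEAD", "DS_BEAD")
  (species_i == "PRECURSOR" & species_j %in% dna) |
    (species_j == "PRECURSOR" & species_i %in% dna)
}

#' Non-bonded pair energy (reference implementation)
#'
#' Pure-R scalar/vector evaluation of the non-bonded pair potential, in kBT.
#' The compiled simulation core implements the identical functional form;
#' this function is the documentation-grade reference used in analyses and
#' tests.
#'
#' @param species_i,species_j species names (see `SPECIES_LEVELS`).
#' @param q_i,q_j charges in elementary charges.
#' @param r centre-to-centre distance(s) in nm.
#' @param params a `forcefield_params`.
#' @param sigma optional contact distance override (nm); defaults to the sum
#'   of the species' radii.
#' @return energy in kBT (0 beyond `pair_cutoff`).
#' @examples
#' p <- forcefield_params(debye_length = 1.0)
#' pair_energy("ION_MONO", "ION_MONO", -1, -1, 1.0, p, sigma = 0.2)  # ~ +0.261
#' @export
pair_energy <- function(species_i, species_j, q_i, q_j, r, params,
                        sigma = NULL) {
  if (any(r <= 0)) stop("domain error: r must be > 0")
  sd <- species_defaults()
  if (is.null(sigma))
    sigma <- sd$radius[match(species_i, sd$species)] +
      sd$radius[match(species_j, sd$species)]
  u <- numeric(length(r))
  rc <- params$pair_cutoff
  inside <- r < rc
  rmin <- 2^(1 / 6) * sigma
  # WCA
  wca <- inside & r < rmin
  if (any(wca)) {
    sr6 <- (sigma / r[wca])^6
    u[wca] <- u[wca] + 4 * params$wca_epsilon * (sr6^2 - sr6) + params$wca_epsilon
  }
  # screened Coulomb, energy-shifted at the cutoff
  qq <- q_i * q_j
  if (qq != 0) {
    shift <- exp(-rc / params$debye_length) / rc
    u[inside] <- u[inside] + params$bjerrum_length * qq *
      (exp(-r[inside] / params$debye_length) / r[inside] - shift)
  }
  # precursor-DNA attractive well
  if (is_attraction_pair(species_i, species_j) && params$attraction_epsilon != 0) {
    eps <- params$attraction_epsilon
    rca <- params$attraction_range
    sr6c <- (sigma / rca)^6
    shift <- 4 * eps * (sr6c^2 - sr6c)
    flat <- inside & r < rmin
    tail <- inside & r >= rmin & r < rca
    u[flat] <- u[flat] - eps - shift
    if (any(tail)) {
      sr6 <- (sigma / r[tail])^6
      u[tail] <- u[tail] + 4 * eps * (sr6^2 - sr6) - shift
    }
  }
  u
}

ff_to_cpp <- function(params) {
  params[c("bjerrum_length", "debye_length", "wca_epsilon",
           "attraction_epsilon", "attraction_range", "pair_cutoff")]
}

box_to_cpp <- function(box) {
  list(lx = box$lx, ly = box$ly, lz = box$lz,
       boundary = unname(box$boundary[c("x", "y", "z")]))
}

topo_arrays <- function(topo) {
  b <- topo$beads
  sd <- species_defaults()
  list(pos = cbind(b$x, b$y, b$z),
       species = species_code(b$species),
       charge = b$charge,
       radius = b$radius,
       fixed = b$fixed,
       gamma = sd$gamma[match(b$species, sd$species)],
       bonds = if (nrow(topo$bonds)) as.matrix(topo$bonds[, c("i", "j")]) else
         matrix(integer(), ncol = 2),
       bond_r0 = topo$bonds$r0, bond_k = topo$bonds$k,
       angles = if (nrow(topo$angles)) as.matrix(topo$angles[, c("i", "j", "k_idx")]) else
         matrix(integer(), ncol = 3),
       ang_t0 = topo$angles$theta0, ang_kap = topo$angles$kappa)
}

#' Neighbor pairs within a cutoff
#'
#' Cell-list enumeration of all bead pairs within `cutoff + skin`
#' (fixed-fixed pairs optionally skipped), with the box's periodic images.
#'
#' @param topo a `cg_topology`.
#' @param positions optional N x 3 matrix overriding the topology positions.
#' @param cutoff interaction cutoff (nm).
#' @param skin Verlet skin (nm).
#' @param skip_fixed_fixed drop pairs where both beads are fixed.
#' @return two-column integer matrix of 1-based pair indices (i < j).
#' @export
build_neighbor_list <- function(topo, positions = NULL, cutoff, skin = 0,
                                skip_fixed_fixed = FALSE) {
  if (is.null(positions)) positions <- as.matrix(topo$beads[, c("x", "y", "z")])
  box <- box_to_cpp(topo$box)
  for (ax in 1:3) {
    L <- c(topo$box$lx, topo$box$ly, topo$box$lz)[ax]
    if (box$boundary[ax] == "PERIODIC" && cutoff + skin > L / 2)
      stop("neighbor error: cutoff+skin exceeds half the periodic box")
  }
  cpp_neighbor_pairs(positions, box, cutoff + skin,
                     topo$beads$fixed, skip_fixed_fixed)
}

#' Total forces and potential energy
#'
#' Exact negative gradient of the total (bonded + non-bonded) energy under
#' the cutoff scheme, evaluated through the compiled cell-list path.  Fixed
#' beads receive forces but are never integrated.
#'
#' @param topo a `cg_topology`.
#' @param positions optional N x 3 position matrix (defaults to topology).
#' @param params a `forcefield_params`.
#' @param skip_fixed_fixed omit fixed-fixed pair interactions (the dynamics
#'   convention; set `FALSE` for full-system energies).
#' @return list with `forces` (N x 3, kBT/nm), `energy` (kBT), `n_pairs`.
#' @export
total_forces <- function(topo, positions = NULL, params,
                         skip_fixed_fixed = FALSE) {
  a <- topo_arrays(topo)
  if (!is.null(positions)) a$pos <- positions
  cpp_forces(a$pos, a$species, a$charge, a$radius, a$fixed, a$gamma,
             a$bonds, a$bond_r0, a$bond_k, a$angles, a$ang_t0, a$ang_kap,
             ff_to_cpp(params), box_to_cpp(topo$box), skip_fixed_fixed)
}
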