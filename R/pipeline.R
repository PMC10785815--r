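#' Desk-scale study system and replicate experiments
#'
#' The reference simulated object is a scaled-down analogue of the
#' end-modified 5*/17/5* bundle: a 9-domain bundle (2 modified domains at
#' each end, 5 bare in the middle, 10-nm domains), brushes of 12-nm contour
#' length grafted at every modified domain on all six helices, and ~50
#' cationic precursors in a box with reflecting radial walls and a periodic
#' axis.  SS and DS systems share graft sites and brush contour length and
#' differ only in bead species (charge, stiffness, size).
#'
#' @name pipeline
NULL

#' Default study configuration
#'
#' All tunable quantities of the scaled-down study in one list; see the
#' methods vignette for the rationale behind each value.
#'
#' @return nested list of geometry/layout/brush/precursor/forcefield/
#'   integrator settings.
#' @export
default_config <- function() {
  list(
    layout = "6HB-2*/5/2*",
    n_domains = 9L,
    domain_length_nm = 10,
    density_factor = 1L,
    brush = list(contour_nm = 12),      # SS: 8 beads x 1.5 nm; DS: 12 x 1.0 nm
    precursors = list(count = 50L, min_separation_nm = 1.0),
    salt = list(mono_mM = 0, di_mM = 5, mode = "implicit"),
    forcefield = list(wca_epsilon = 1.0, attraction_epsilon = 0.45,
                      attraction_range = 3.5, pair_cutoff = 6.0,
                      bjerrum_length = 0.71),
    integrator = list(dt = 0.002, n_steps = 150000L, frame_stride = 750L),
    analysis = list(r_condense = 1.5, r_near = 1.2, grace = 2L,
                    residence_min_radial_nm = 6.5,   # canopy: beyond the
                    # core envelope (3 nm) + attraction range (3.5 nm)
                    window_fraction = 0.5)
  )
}

#' Force-field parameters implied by a configuration
#'
#' @param config configuration list from [default_config()].
#' @return a `forcefield_params` with the Debye length derived from the
#'   configured salt.
#' @export
config_forcefield <- function(config) {
  ffc <- config$forcefield
  forcefield_params(
    debye_length = debye_length(config$salt$mono_mM, config$salt$di_mM),
    bjerrum_length = ffc$bjerrum_length,
    wca_epsilon = ffc$wca_epsilon,
    attraction_epsilon = ffc$attraction_epsilon,
    attraction_range = ffc$attraction_range,
    pair_cutoff = ffc$pair_cutoff,
    mono_mM = config$salt$mono_mM, di_mM = config$salt$di_mM)
}

#' Build the full study system for one brush kind
#'
#' @param kind `"SS"`, `"DS"` or `"NONE"` (bare bundle).
#' @param seed integer seed (placement jitter and precursor packing).
#' @param config configuration list from [default_config()].
#' @param zero_interactions if TRUE, all charges are set to zero and the
#'   builder tags the system as a control (used with a zero-attraction
#'   force field for null-enhancement checks).
#' @return list with `topo` (`cg_topology`) and `spec` (`brush_layout`).
#' @export
build_study_system <- function(kind = "DS", seed = 1L,
                               config = default_config(),
                               zero_interactions = FALSE) {
  L <- config$n_domains * config$domain_length_nm
  geom <- geometry_params(L)
  layout_name <- if (kind == "NONE") "6HB" else
    paste0(config$layout, "-", kind)
  spec <- parse_layout(layout_name, n_domains = config$n_domains,
                       density_factor = config$density_factor)
  box <- default_box(geom, if (kind == "NONE") 0 else config$brush$contour_nm)
  topo <- build_core(geom, box)
  if (kind != "NONE") {
    sites <- enumerate_graft_sites(spec, L)
    n_beads <- as.integer(round(config$brush$contour_nm /
                                  brush_defaults(kind)$bond))
    topo <- attach_brushes(topo, sites, n_beads, kind, seed = seed)
  }
  topo <- place_precursors(topo, config$precursors$count,
                           config$precursors$min_separation_nm, seed = seed)
  if (identical(config$salt$mode, "explicit")) {
    topo <- add_salt(topo, 0, config$salt$di_mM, seed = seed + 7L)
  }
  if (zero_interactions) topo$beads$charge <- 0
  list(topo = topo, spec = spec)
}

#' Run one seeded condensation trajectory and its analyses
#'
#' @param kind brush kind (`"SS"`, `"DS"`, `"NONE"`).
#' @param seed integer seed (build jitter, packing and thermal noise).
#' @param config configuration list.
#' @param control zero-interaction control: charges and precursor-DNA
#'   attraction both zeroed.
#' @param keep_trajectory retain the full trajectory in the result.
#' @return list: `condensation` (`regional_condensation`), `residence`
#'   (events + mean duration), `seed`, and optionally `trajectory`.
#' @export
run_condensation_experiment <- function(kind, seed, config = default_config(),
                                        control = FALSE,
                                        keep_trajectory = FALSE) {
  sys <- build_study_system(kind, seed, config, zero_interactions = control)
  ff <- config_forcefield(config)
  if (control) ff$attraction_epsilon <- 0
  ip <- integrator_params(dt = config$integrator$dt,
                          n_steps = config$integrator$n_steps,
                          frame_stride = config$integrator$frame_stride,
                          seed = seed)
  traj <- run_bd(sys$topo, ff, ip)
  cond <- regional_condensation(traj, sys$spec,
                                r_condense = config$analysis$r_condense,
                                window_fraction = config$analysis$window_fraction)
  res <- if (kind %in% c("SS", "DS"))
    residence_times(traj, r_near = config$analysis$r_near,
                    grace = config$analysis$grace,
                    min_radial_nm = config$analysis$residence_min_radial_nm)
  else list(events = NULL, mean_duration = NA_real_)
  out <- list(kind = kind, seed = seed, condensation = cond, residence = res,
              spec = sys$spec)
  if (keep_trajectory) out$trajectory <- traj
  out
}

#' Multi-seed condensation study for one brush kind
#'
#' @param kind brush kind.
#' @param seeds integer vector of seeds (>= 3 recommended).
#' @param config configuration list.
#' @param control zero-interaction control.
#' @param keep_trajectories keep per-seed trajectories.
#' @return list with `runs` (per-seed results), `enhancement` (mean, SE,
#'   per-seed) and `mean_residence` (tau, averaged over seeds).
#' @export
condensation_study <- function(kind, seeds, config = default_config(),
                               control = FALSE, keep_trajectories = FALSE) {
  runs <- lapply(seeds, function(s)
    run_condensation_experiment(kind, s, config, control = control,
                                keep_trajectory = keep_trajectories))
  enh <- enhancement(lapply(runs, `[[`, "condensation"))
  res_means <- vapply(runs, function(r) r$residence$mean_duration, numeric(1))
  list(kind = kind, seeds = seeds, runs = runs, enhancement = enh,
       mean_residence = mean(res_means, na.rm = TRUE),
       residence_per_seed = res_means)
}

#' Divalent-salt sweep of condensation
#'
#' Re-runs the condensation experiment across Mg2+ levels.  In implicit
#' mode each level only changes the Debye length (stronger screening at
#' higher ionic strength); in explicit mode the divalent ions are placed as
#' particles and the Debye length reflects the remaining implicit
#' (monovalent) background.
#'
#' @param kind brush kind.
#' @param mg_levels_mM divalent concentrations (mM).
#' @param seeds seeds per level.
#' @param config configuration list.
#' @param mode `"implicit"` or `"explicit"`.
#' @return data.frame: one row per (level, seed) with the Debye length and
#'   the window-averaged total condensed count.
#' @export
mg_sweep <- function(kind = "DS", mg_levels_mM = c(5, 16), seeds = 1:5,
                     config = default_config(), mode = "implicit") {
  rows <- list()
  for (mg in mg_levels_mM) {
    cfg <- config
    cfg$salt$di_mM <- mg
    cfg$salt$mode <- mode
    lam <- if (mode == "implicit") debye_length(cfg$salt$mono_mM, mg)
    else debye_length(cfg$salt$mono_mM, 0)
    for (s in seeds) {
      r <- run_condensation_experiment(kind, s, cfg)
      w <- r$condensation$window_frames
      tot <- mean(r$condensation$series$count_brush[w] +
                    r$condensation$series$count_bare[w])
      rows[[length(rows) + 1]] <- data.frame(
        mg_mM = mg, lambda_D_nm = lam, seed = s, condensed_mean = tot)
    }
  }
  do.call(rbind, rows)
}
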