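#' Regional condensation, retention and charge-profile analyses
#'
#' "Condensed" is a geometric definition: a precursor counts as condensed
#' when its surface-to-surface separation from the nearest core bead is at
#' most `r_condense` (the model has no reactive chemistry).  Proximity
#' thresholds throughout are surface separations, i.e. centre distance minus
#' the two bead radii, so one threshold is meaningful across bead sizes.
#'
#' @name condensation
NULL

# min over rows of `ref` of (centre distance - contact) from each row of `pts`
surface_dist_min <- function(pts, ref, ref_radius, pt_radius, box) {
  t(vapply(seq_len(nrow(pts)), function(i) {
    dx <- ref[, 1] - pts[i, 1]
    dy <- ref[, 2] - pts[i, 2]
    dz <- ref[, 3] - pts[i, 3]
    if (box$boundary["z"] == "PERIODIC") dz <- min_image_dz(dz, box$lz)
    d <- sqrt(dx * dx + dy * dy + dz * dz) - (ref_radius + pt_radius)
    j <- which.min(d)
    c(d[j], j)
  }, numeric(2)))
}

#' Condensed-precursor counts per region for one frame
#'
#' A precursor is condensed iff its surface separation from any core bead is
#' at most `r_condense`; it is assigned to the region (half-open axial
#' interval) of its nearest core bead.
#'
#' @param positions N x 3 position matrix of the frame.
#' @param topo a `cg_topology`.
#' @param region_map data.frame from [assign_regions()].
#' @param r_condense surface-separation threshold (nm).
#' @return named integer vector `c(count_brush =, count_bare =)`.
#' @export
condensed_counts <- function(positions, topo, region_map, r_condense = 1.5) {
  stopifnot(r_condense > 0)
  is_core <- topo$beads$species == "CORE"
  is_prec <- topo$beads$species == "PRECURSOR"
  out <- c(count_brush = 0L, count_bare = 0L)
  if (!any(is_prec)) return(out)
  core <- positions[is_core, , drop = FALSE]
  prec <- positions[is_prec, , drop = FALSE]
  r_core <- topo$beads$radius[is_core][1]
  r_prec <- topo$beads$radius[is_prec][1]
  dm <- surface_dist_min(prec, core, r_core, r_prec, topo$box)
  cond <- dm[, 1] <= r_condense
  if (!any(cond)) return(out)
  zc <- core[dm[cond, 2], 3]
  lab <- region_map$label[findInterval(zc, region_map$start_nm)]
  out["count_brush"] <- sum(lab == "BRUSH")
  out["count_bare"] <- sum(lab == "BARE")
  out
}

#' Regional condensation time series and enhancement for one trajectory
#'
#' Counts condensed precursors per region in every stored frame, converts
#' the analysis-window averages to per-length densities (precursors/nm) so
#' unequal region lengths cancel, and reports the brush-over-bare percent
#' enhancement.
#'
#' @param traj a `cg_trajectory` of a brush-layout system.
#' @param spec the `brush_layout` used to build the system.
#' @param r_condense surface-separation threshold (nm).
#' @param window_fraction analysis window (fraction of frames, from the end).
#' @return a `regional_condensation` list: `series` (data.frame time/counts),
#'   `rho_brush`, `rho_bare` (per nm), `enhancement_percent`, region lengths
#'   and the window used.
#' @export
regional_condensation <- function(traj, spec, r_condense = 1.5,
                                  window_fraction = 0.5) {
  topo <- traj$topology
  L <- topo$geometry$bundle_length
  rmap <- assign_regions(spec, L)
  len_brush <- sum(rmap$end_nm[rmap$label == "BRUSH"] -
                     rmap$start_nm[rmap$label == "BRUSH"])
  len_bare <- L - len_brush
  nf <- n_frames(traj)
  counts <- t(vapply(seq_len(nf), function(f) {
    condensed_counts(frame_positions(traj, f), topo, rmap, r_condense)
  }, c(count_brush = 0L, count_bare = 0L)))
  series <- data.frame(time = traj$times,
                       count_brush = counts[, 1], count_bare = counts[, 2])
  win <- analysis_window(traj, window_fraction)
  rho_brush <- mean(counts[win, 1]) / len_brush
  rho_bare <- if (len_bare > 0) mean(counts[win, 2]) / len_bare else NA_real_
  enh <- if (!is.na(rho_bare) && rho_bare > 0)
    100 * (rho_brush - rho_bare) / rho_bare else NA_real_
  structure(list(series = series, rho_brush = rho_brush, rho_bare = rho_bare,
                 enhancement_percent = enh,
                 len_brush_nm = len_brush, len_bare_nm = len_bare,
                 window_frames = win, r_condense = r_condense),
            class = "regional_condensation")
}

#' @export
print.regional_condensation <- function(x, ...) {
  cat(sprintf(paste0("<regional_condensation> rho_brush %.4f /nm, rho_bare ",
                     "%.4f /nm, enhancement %.1f%%\n"),
              x$rho_brush, x$rho_bare, x$enhancement_percent))
  invisible(x)
}

#' Enhancement across seeds
#'
#' The headline estimate is the ratio of seed-pooled per-length densities
#' (more stable than averaging per-seed ratios, whose small bare-region
#' denominators are noisy); the seed-to-seed standard error is a jackknife
#' over seeds of the pooled estimator, and the per-seed ratios are
#' reported alongside.
#'
#' @param results list of `regional_condensation` (one per seed).
#' @return list with `mean_percent` (pooled), `se_percent` (jackknife over
#'   seeds), and the `per_seed` ratio values.
#' @export
enhancement <- function(results) {
  stopifnot(length(results) >= 1)
  rb <- vapply(results, function(r) r$rho_brush, numeric(1))
  rc <- vapply(results, function(r) r$rho_bare, numeric(1))
  pooled <- function(idx) 100 * (mean(rb[idx]) - mean(rc[idx])) / mean(rc[idx])
  n <- length(results)
  est <- pooled(seq_len(n))
  se <- if (n > 1) {
    jk <- vapply(seq_len(n), function(i) pooled(setdiff(seq_len(n), i)),
                 numeric(1))
    sqrt((n - 1) / n * sum((jk - mean(jk))^2))
  } else NA_real_
  list(mean_percent = est, se_percent = se,
       per_seed = vapply(results, function(r) r$enhancement_percent,
                         numeric(1)))
}

# merge FALSE runs of length <= grace that are flanked by TRUE runs
merge_excursions <- function(near, grace) {
  if (grace <= 0 || !any(near)) return(near)
  r <- rle(near)
  n <- length(r$lengths)
  for (i in seq_len(n)) {
    if (!r$values[i] && r$lengths[i] <= grace && i > 1 && i < n)
      r$values[i] <- TRUE
  }
  inverse.rle(r)
}

#' Brush residence events of precursors
#'
#' An event spans contiguous frames in which a precursor sits within
#' `r_near` (surface separation) of any brush bead; excursions of at most
#' `grace` frames do not terminate an event.  Durations are in tau
#' (frames times the frame spacing).
#'
#' @param traj a `cg_trajectory` with brush beads.
#' @param r_near surface-separation threshold (nm).
#' @param grace tolerated excursion length in frames.
#' @param min_radial_nm only brush beads at least this far from the bundle
#'   axis define proximity (0 = every brush bead).  Restricting events to
#'   the canopy (beyond the core's own binding shell) isolates retention
#'   *by the brushes* from adsorption at the bundle surface, which is the
#'   retention statistic the brush-kind comparison uses.
#' @return list with `events` (data.frame: precursor_id, start_frame,
#'   end_frame, start_time, end_time, duration) and `mean_duration` (tau).
#' @export
residence_times <- function(traj, r_near = 1.2, grace = 2L,
                            min_radial_nm = 0) {
  stopifnot(r_near > 0, grace >= 0)
  topo <- traj$topology
  is_brush <- topo$beads$species %in% c("SS_BEAD", "DS_BEAD")
  is_prec <- topo$beads$species == "PRECURSOR"
  nf <- n_frames(traj)
  if (!any(is_brush) || !any(is_prec) || nf == 0) {
    return(list(events = data.frame(precursor_id = integer(),
                                    start_frame = integer(), end_frame = integer(),
                                    start_time = numeric(), end_time = numeric(),
                                    duration = numeric()),
                mean_duration = NA_real_))
  }
  r_b <- topo$beads$radius[is_brush][1]
  r_p <- topo$beads$radius[is_prec][1]
  prec_ids <- which(is_prec)
  near <- matrix(FALSE, nrow = nf, ncol = length(prec_ids))
  for (f in seq_len(nf)) {
    pos <- frame_positions(traj, f)
    bp <- pos[is_brush, , drop = FALSE]
    if (min_radial_nm > 0) {
      keep <- sqrt(bp[, 1]^2 + bp[, 2]^2) >= min_radial_nm
      if (!any(keep)) next
      bp <- bp[keep, , drop = FALSE]
    }
    dm <- surface_dist_min(pos[is_prec, , drop = FALSE], bp, r_b, r_p,
                           topo$box)
    near[f, ] <- dm[, 1] <= r_near
  }
  dt_frame <- if (nf > 1) traj$times[2] - traj$times[1] else 1
  ev <- list()
  for (p in seq_along(prec_ids)) {
    v <- merge_excursions(near[, p], grace)
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    if (length(keep)) {
      ev[[length(ev) + 1]] <- data.frame(
        precursor_id = prec_ids[p],
        start_frame = starts[keep], end_frame = ends[keep],
        start_time = traj$times[starts[keep]],
        end_time = traj$times[ends[keep]],
        duration = r$lengths[keep] * dt_frame)
    }
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(precursor_id = integer(), start_frame = integer(),
               end_frame = integer(), start_time = numeric(),
               end_time = numeric(), duration = numeric())
  list(events = events,
       mean_duration = if (nrow(events)) mean(events$duration) else NA_real_)
}

#' Time-averaged radial brush charge profile
#'
#' Bins the brush-bead charge by radial distance from the bundle axis,
#' averaged over the analysis window.  Unnormalised: the bin sum equals the
#' total brush charge.
#'
#' @param traj a `cg_trajectory`.
#' @param breaks radial bin edges (nm); default 0.5-nm bins out to the box
#'   radius so no charge falls outside.
#' @param window_fraction analysis window.
#' @return data.frame `r_lo`, `r_mid`, `r_hi`, `charge_e` (mean charge per
#'   bin, e).
#' @export
radial_charge_profile <- function(traj, breaks = NULL, window_fraction = 0.5) {
  topo <- traj$topology
  is_brush <- topo$beads$species %in% c("SS_BEAD", "DS_BEAD")
  if (!any(is_brush)) stop("no brush beads in topology")
  if (is.null(breaks)) {
    rmax <- sqrt((topo$box$lx / 2)^2 + (topo$box$ly / 2)^2) + 1
    breaks <- seq(0, ceiling(rmax * 2) / 2, by = 0.5)
  }
  q <- topo$beads$charge[is_brush]
  win <- analysis_window(traj, window_fraction)
  acc <- numeric(length(breaks) - 1)
  for (f in win) {
    pos <- frame_positions(traj, f)[is_brush, , drop = FALSE]
    r <- sqrt(pos[, 1]^2 + pos[, 2]^2)
    bin <- findInterval(r, breaks, rightmost.closed = TRUE)
    bin[bin < 1] <- 1
    bin[bin > length(acc)] <- length(acc)
    acc <- acc + vapply(seq_along(acc),
                        function(b) sum(q[bin == b]), numeric(1))
  }
  data.frame(r_lo = breaks[-length(breaks)], r_hi = breaks[-1],
             r_mid = (breaks[-length(breaks)] + breaks[-1]) / 2,
             charge_e = acc / length(win))[, c("r_lo", "r_mid", "r_hi",
                                               "charge_e")]
}

#' Mean radial extent of the brush charge
#'
#' Charge-weighted mean radial distance of brush beads from the bundle
#' axis, averaged over the analysis window (the stiffness/extension
#' summary statistic: DS > SS at equal contour length).
#'
#' @inheritParams radial_charge_profile
#' @return mean radial distance (nm).
#' @export
mean_brush_radial_extent <- function(traj, window_fraction = 0.5) {
  prof <- radial_charge_profile(traj, window_fraction = window_fraction)
  sum(prof$r_mid * prof$charge_e) / sum(prof$charge_e)
}

#' Probe electrostatic-energy scan along the bundle
#'
#' Places a probe charge at a fixed offset from the core envelope surface
#' at a grid of axial positions (averaged over azimuths), and evaluates the
#' exact (uncut) screened-Coulomb energy against all core and brush charges
#' for a set of decorrelated frames.  Mobile precursors and ions are
#' excluded: the scan measures the DNA-generated field.
#'
#' @param traj a `cg_trajectory`.
#' @param spec the `brush_layout` of the system.
#' @param ff a `forcefield_params` (Bjerrum and Debye lengths).
#' @param probe_charge probe charge (e).
#' @param offset radial offset of the probe from the envelope surface (nm).
#' @param n_axial number of axial grid positions.
#' @param n_azimuth number of azimuthal positions averaged per grid point.
#' @param frames frame indices to average over; default 10 evenly spaced
#'   frames in the last half.
#' @param azimuth_average how the azimuthal ring of probe positions is
#'   collapsed per axial position.  `"boltzmann"` (default) reports the
#'   Boltzmann-weighted mean electrostatic energy, with weights from the
#'   full probe potential (screened Coulomb plus WCA overlap with DNA
#'   beads): the mean energy a bound precursor, free to equilibrate around
#'   the ring, actually experiences.  `"mean"` is the plain arithmetic
#'   average over accessible positions.
#' @return an `energy_scan` list: `profile` (axial position, mean energy
#'   kBT, region label), `region_means`, and `excess_vs_bare` (bare-region
#'   mean minus each region mean; positive = more attractive than bare).
#' @export
electrostatic_scan <- function(traj, spec, ff, probe_charge = 1.0,
                               offset = 0.5, n_axial = 36, n_azimuth = 36,
                               frames = NULL,
                               azimuth_average = c("boltzmann", "mean")) {
  azimuth_average <- match.arg(azimuth_average)
  topo <- traj$topology
  geom <- topo$geometry
  L <- geom$bundle_length
  rmap <- assign_regions(spec, L)
  if (is.null(frames)) {
    win <- analysis_window(traj, 0.5)
    frames <- unique(round(seq(min(win), max(win), length.out = 10)))
  }
  sel <- topo$beads$species %in% c("CORE", "SS_BEAD", "DS_BEAD") &
    topo$beads$charge != 0
  q <- topo$beads$charge[sel]
  sig <- topo$beads$radius[sel] + 0.5   # probe excluded-volume contact
  r_probe <- geom$helix_ring_radius + geom$helix_radius + offset
  zs <- (seq_len(n_axial) - 0.5) * L / n_axial
  phis <- (seq_len(n_azimuth) - 1) * 2 * pi / n_azimuth
  lB <- ff$bjerrum_length
  lam <- ff$debye_length
  energy <- matrix(0, nrow = n_axial, ncol = length(frames))
  if (probe_charge != 0) {
    for (fi in seq_along(frames)) {
      pos <- frame_positions(traj, frames[fi])[sel, , drop = FALSE]
      for (a in seq_len(n_axial)) {
        e_az <- t(vapply(phis, function(phi) {
          px <- r_probe * cos(phi); py <- r_probe * sin(phi); pz <- zs[a]
          dx <- pos[, 1] - px; dy <- pos[, 2] - py; dz <- pos[, 3] - pz
          if (topo$box$boundary["z"] == "PERIODIC")
            dz <- min_image_dz(dz, topo$box$lz)
          d <- sqrt(dx * dx + dy * dy + dz * dz)
          u_dh <- sum(lB * probe_charge * q * exp(-d / lam) / d)
          ov <- d < 2^(1 / 6) * sig
          u_wca <- if (any(ov)) {
            sr6 <- (sig[ov] / d[ov])^6
            sum(4 * (sr6^2 - sr6) + 1)
          } else 0
          c(u_dh, u_wca)
        }, numeric(2)))
        energy[a, fi] <- if (azimuth_average == "boltzmann") {
          w <- exp(-(e_az[, 1] + e_az[, 2]))
          sum(w * e_az[, 1]) / sum(w)
        } else mean(e_az[, 1])
      }
    }
  }
  mean_e <- rowMeans(energy)
  lab <- rmap$label[findInterval(zs, rmap$start_nm)]
  profile <- data.frame(axial_nm = zs, energy_kBT = mean_e, region = lab)
  region_means <- tapply(mean_e, lab, mean)
  bare <- if ("BARE" %in% names(region_means)) region_means[["BARE"]] else NA_real_
  structure(list(profile = profile,
                 region_means = region_means,
                 excess_vs_bare = bare - region_means,
                 probe_charge = probe_charge, offset = offset,
                 frames = frames),
            class = "energy_scan")
}

#' @export
print.energy_scan <- function(x, ...) {
  cat("<energy_scan> region means (kBT):\n")
  print(round(x$region_means, 3))
  invisible(x)
}
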