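# hand-built single-frame "trajectory" around a small bundle
make_static_traj <- function(kind = "DS", seed = 1, config = NULL,
                             n_frames = 1) {
  if (is.null(config)) {
    config <- default_config()
    config$precursors$count <- 5L
  }
  sys <- build_study_system(kind, seed, config)
  ff <- config_forcefield(config)
  ip <- integrator_params(dt = 0.002, n_steps = 0, frame_stride = 1,
                          seed = seed)
  traj <- run_bd(sys$topo, ff, ip)
  list(traj = traj, sys = sys, config = config)
}

test_that("condensed counts match a brute-force distance check", {
  st <- make_static_traj("DS", seed = 21)
  topo <- st$traj$topology
  rmap <- assign_regions(st$sys$spec, topo$geometry$bundle_length)
  pos <- frame_positions(st$traj, 1)
  # place the 5 precursors by hand: two touching brush-region core, one
  # touching bare-region core, two far away
  prec <- which(topo$beads$species == "PRECURSOR")
  r_contact <- 1.5   # core radius 1.0 + precursor radius 0.5
  put <- function(i, z, gap) {
    pos[prec[i], ] <<- c(2 + r_contact + gap, 0, z)  # next to helix 0
  }
  put(1, 5, 0.5)    # brush domain (z in [0,20))
  put(2, 15, 1.4)   # brush domain, just inside the 1.5 threshold
  put(3, 45, 0.1)   # bare domain (z in [20,70))
  put(4, 45, 3.0)   # bare domain but beyond threshold
  pos[prec[5], ] <- c(-25, 25, 80)  # far away
  counts <- condensed_counts(pos, topo, rmap, r_condense = 1.5)
  expect_equal(counts, c(count_brush = 2L, count_bare = 1L))

  # brute-force recomputation over every precursor
  core <- which(topo$beads$species == "CORE")
  brute <- c(0L, 0L)
  for (p in prec) {
    dz <- pos[core, 3] - pos[p, 3]
    dz <- dz - topo$box$lz * round(dz / topo$box$lz)
    d <- sqrt((pos[core, 1] - pos[p, 1])^2 + (pos[core, 2] - pos[p, 2])^2 +
                dz^2) - 1.5
    if (min(d) <= 1.5) {
      zc <- pos[core[which.min(d)], 3]
      lab <- rmap$label[findInterval(zc, rmap$start_nm)]
      brute <- brute + c(lab == "BRUSH", lab == "BARE")
    }
  }
  expect_equal(unname(counts), brute)

  # all precursors far from the core -> (0, 0)
  pos[prec, 1] <- -30; pos[prec, 2] <- 30
  expect_equal(condensed_counts(pos, topo, rmap, 1.5),
               c(count_brush = 0L, count_bare = 0L))
})

test_that("boundary precursors follow the half-open interval convention", {
  # 0.5-nm core spacing puts a bead exactly on the 20-nm BRUSH/BARE
  # boundary of the 9-domain layout
  geom <- geometry_params(90, core_bead_spacing = 0.5)
  topo <- build_core(geom, box_spec(54, 54, 90))
  spec <- parse_layout("6HB-2*/5/2*-DS", n_domains = 9)
  rmap <- assign_regions(spec, 90)
  sdp <- silicabrush:::species_defaults()
  p <- sdp[sdp$species == "PRECURSOR", ]
  exact <- which(topo$beads$z == 20)[1]
  b <- topo$beads[exact, ]
  topo$beads <- rbind(topo$beads, data.frame(
    bead_id = nrow(topo$beads) + 1L, species = "PRECURSOR",
    charge = p$charge, radius = p$radius,
    x = b$x * (1 + 1.6 / 2), y = b$y * (1 + 1.6 / 2), z = b$z,
    chain_id = 0L, fixed = FALSE, stringsAsFactors = FALSE))
  pos <- as.matrix(topo$beads[, c("x", "y", "z")])
  # the bead at z = 20 starts the BARE interval [20, 70)
  counts <- condensed_counts(pos, topo, rmap, 1.5)
  expect_equal(unname(counts), c(0L, 1L))
})

test_that("per-length densities cancel the unequal region lengths", {
  st <- make_static_traj("DS", seed = 23)
  topo <- st$traj$topology
  L <- topo$geometry$bundle_length
  rmap <- assign_regions(st$sys$spec, L)
  len_brush <- sum(rmap$end_nm[rmap$label == "BRUSH"] -
                     rmap$start_nm[rmap$label == "BRUSH"])
  expect_equal(len_brush, L * 4 / 9)
  rc <- regional_condensation(st$traj, st$sys$spec)
  expect_equal(rc$len_brush_nm, len_brush)
  expect_equal(rc$len_bare_nm, L - len_brush)
  s <- rc$series
  expect_true(all(s$count_brush >= 0 & s$count_bare >= 0))
})

test_that("residence events merge short excursions under the grace rule", {
  near <- c(FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE)
  # grace 3 bridges the 2-frame excursion into one merged event
  merged <- silicabrush:::merge_excursions(near, grace = 3)
  expect_equal(which(merged), 2:8)
  # grace 1 leaves two separate events
  kept <- silicabrush:::merge_excursions(near, grace = 1)
  expect_equal(rle(kept)$lengths[rle(kept)$values], c(2, 3))
  # leading/trailing absences are never bridged
  expect_false(any(silicabrush:::merge_excursions(
    c(FALSE, FALSE, TRUE), grace = 5)[1:2]))
})

test_that("residence bookkeeping yields non-overlapping per-precursor events", {
  cfg <- default_config()
  cfg$precursors$count <- 10L
  cfg$integrator$dt <- 0.002
  cfg$integrator$n_steps <- 4000L
  cfg$integrator$frame_stride <- 200L
  r <- run_condensation_experiment("DS", seed = 31, config = cfg,
                                   keep_trajectory = TRUE)
  ev <- residence_times(r$trajectory, r_near = 1.2, grace = 2)
  if (nrow(ev$events)) {
    expect_true(all(ev$events$end_frame >= ev$events$start_frame))
    for (p in unique(ev$events$precursor_id)) {
      e <- ev$events[ev$events$precursor_id == p, ]
      if (nrow(e) > 1) {
        e <- e[order(e$start_frame), ]
        expect_true(all(e$start_frame[-1] > e$end_frame[-nrow(e)]))
      }
    }
    expect_equal(ev$mean_duration, mean(ev$events$duration))
  }
  # no brushes -> no events
  bare <- run_condensation_experiment("NONE", seed = 31, config = cfg,
                                      keep_trajectory = TRUE)
  expect_equal(nrow(residence_times(bare$trajectory)$events), 0)
})

test_that("radial charge profile conserves charge and shows a step for
          straight chains", {
  # static straight DS brushes: all charge sits between graft radius and
  # graft radius + contour, in a predictable slab
  cfg <- default_config()
  cfg$precursors$count <- 0L
  sys <- build_study_system("DS", seed = 41, config = cfg)
  ff <- config_forcefield(cfg)
  traj <- run_bd(sys$topo, ff, integrator_params(dt = 0.002, n_steps = 0,
                                                 frame_stride = 1, seed = 1))
  prof <- radial_charge_profile(traj, breaks = seq(0, 28, 0.5))
  total <- sum(sys$topo$beads$charge[sys$topo$beads$species == "DS_BEAD"])
  expect_equal(sum(prof$charge_e), total, tolerance = 1e-9)
  # straight rays: first bead at radius 3.5 nm, last at 14.5 nm
  expect_equal(sum(prof$charge_e[prof$r_hi <= 2.5]), 0)
  expect_equal(sum(prof$charge_e[prof$r_lo >= 16]), 0)
  # analytic step: one -1.5 e bead per 1-nm of ray on each of 24 chains,
  # so every 1-nm window in the occupied band holds exactly -36 e
  # (0.5-nm bins alternate with the commensurate bead spacing)
  band <- prof[prof$r_lo >= 4 & prof$r_hi <= 14, "charge_e"]
  windows <- band[seq(1, length(band) - 1, by = 2)] +
    band[seq(2, length(band), by = 2)]
  expect_equal(windows, rep(-1.5 * 24, length(windows)), tolerance = 1e-9)
})

test_that("DS brushes carry their charge farther out than SS at equal
          contour", {
  cfg <- default_config()
  cfg$precursors$count <- 0L
  cfg$integrator$n_steps <- 20000L
  cfg$integrator$frame_stride <- 2000L
  cfg$integrator$dt <- 0.002
  ext <- sapply(c("SS", "DS"), function(k) {
    r <- run_condensation_experiment(k, seed = 51, config = cfg,
                                     keep_trajectory = TRUE)
    mean_brush_radial_extent(r$trajectory)
  })
  expect_gt(ext["DS"], ext["SS"])
})

test_that("electrostatic scan matches the screened-Coulomb closed form for
          a single fixed charge", {
  # bundle-free analogue: a single unit charge on the axis
  cfg <- default_config()
  cfg$precursors$count <- 0L
  sys <- build_study_system("NONE", seed = 61, config = cfg)
  topo <- sys$topo
  keep <- 1L   # one core bead only
  topo$beads <- topo$beads[keep, , drop = FALSE]
  topo$beads$charge <- -1
  topo$beads$x <- 0; topo$beads$y <- 0; topo$beads$z <- 45
  ff <- config_forcefield(cfg)
  traj <- run_bd(topo, ff, integrator_params(dt = 0.002, n_steps = 0,
                                             frame_stride = 1, seed = 1))
  scan <- electrostatic_scan(traj, sys$spec, ff, probe_charge = 1,
                             offset = 0.5, n_axial = 9, n_azimuth = 4,
                             frames = 1)
  r_probe <- 3.5
  zs <- scan$profile$axial_nm
  expected <- sapply(zs, function(z) {
    dz <- z - 45
    dz <- dz - 90 * round(dz / 90)
    d <- sqrt(r_probe^2 + dz^2)
    -ff$bjerrum_length * exp(-d / ff$debye_length) / d
  })
  expect_equal(scan$profile$energy_kBT, expected, tolerance = 1e-9)

  # zero probe charge -> identically zero
  scan0 <- electrostatic_scan(traj, sys$spec, ff, probe_charge = 0,
                              frames = 1)
  expect_true(all(scan0$profile$energy_kBT == 0))
})

test_that("Mg sweep reports the closed-form Debye length per level", {
  cfg <- default_config()
  cfg$precursors$count <- 8L
  cfg$integrator$n_steps <- 1000L
  cfg$integrator$frame_stride <- 250L
  tab <- mg_sweep("DS", mg_levels_mM = c(5, 16), seeds = 1, config = cfg)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$lambda_D_nm,
               c(debye_length(0, 5), debye_length(0, 16)))
  # single level -> degenerate one-row table
  tab1 <- mg_sweep("DS", mg_levels_mM = 5, seeds = 1, config = cfg)
  expect_equal(nrow(tab1), 1)
})
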