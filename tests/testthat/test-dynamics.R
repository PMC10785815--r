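test_that("zero steps leave the state unchanged and strides bound frames", {
  topo <- particle_gas(20, box_spec(30, 30, 30), seed = 1)
  ff <- forcefield_params(debye_length = 1.0)
  traj0 <- run_bd(topo, ff, integrator_params(n_steps = 0, frame_stride = 10))
  expect_equal(n_frames(traj0), 1)
  expect_equal(frame_positions(traj0, 1),
               unname(as.matrix(topo$beads[, c("x", "y", "z")])),
               ignore_attr = TRUE)

  # stride = n_steps -> exactly initial and final frames
  traj <- run_bd(topo, ff, integrator_params(n_steps = 100,
                                             frame_stride = 100, seed = 2))
  expect_equal(n_frames(traj), 2)
  expect_equal(traj$times, c(0, 100 * 0.005))
})

test_that("identical seeds give bit-identical trajectories", {
  sys <- build_study_system("SS", seed = 5)
  ff <- config_forcefield(default_config())
  ip <- integrator_params(dt = 0.002, n_steps = 500, frame_stride = 100,
                          seed = 9)
  t1 <- run_bd(sys$topo, ff, ip)
  t2 <- run_bd(sys$topo, ff, ip)
  expect_identical(t1$frames, t2$frames)
  # different seed -> different thermal history
  ip2 <- integrator_params(dt = 0.002, n_steps = 500, frame_stride = 100,
                           seed = 10)
  expect_false(identical(run_bd(sys$topo, ff, ip2)$frames, t1$frames))
})

test_that("fixed core beads never move and precursor count is conserved", {
  sys <- build_study_system("DS", seed = 2)
  ff <- config_forcefield(default_config())
  traj <- run_bd(sys$topo, ff,
                 integrator_params(dt = 0.002, n_steps = 2000,
                                   frame_stride = 200, seed = 4))
  fixed <- which(sys$topo$beads$fixed)
  first <- frame_positions(traj, 1)[fixed, ]
  for (f in seq_len(n_frames(traj))) {
    expect_identical(frame_positions(traj, f)[fixed, ], first)
    pos <- frame_positions(traj, f)
    inside <- abs(pos[, 1]) <= sys$topo$box$lx / 2 + 1e-9 &
      abs(pos[, 2]) <= sys$topo$box$ly / 2 + 1e-9 &
      pos[, 3] >= -1e-9 & pos[, 3] <= sys$topo$box$lz + 1e-9
    expect_true(all(inside))
  }
})

test_that("free diffusion satisfies the Einstein relation within 5%", {
  # 1000 non-interacting particles; periodic box with min-image unwrapping
  # between frames (per-frame moves are far below the box length)
  L <- 2000
  box <- box_spec(L, L, L, boundary = c(x = "PERIODIC", y = "PERIODIC",
                                        z = "PERIODIC"))
  topo <- particle_gas(1000, box, charge = 0, seed = 11, min_separation = 0)
  ff <- forcefield_params(debye_length = 1.0, attraction_epsilon = 0,
                          wca_epsilon = 0, attraction_range = 1.5,
                          pair_cutoff = 1.5)
  ip <- integrator_params(dt = 0.005, n_steps = 10000, frame_stride = 1000,
                          seed = 12)
  traj <- run_bd(topo, ff, ip)
  disp <- frame_positions(traj, 1) * 0
  msd <- numeric(n_frames(traj) - 1)
  prev <- frame_positions(traj, 1)
  for (f in 2:n_frames(traj)) {
    cur <- frame_positions(traj, f)
    d <- cur - prev
    d <- d - L * round(d / L)
    disp <- disp + d
    msd[f - 1] <- mean(rowSums(disp^2))
    prev <- cur
  }
  # MSD(t) = 6 D t with D = kBT/gamma = 1 for the 0.5-nm precursor
  t_vals <- traj$times[-1]
  slope <- sum(msd * t_vals) / sum(t_vals^2)
  expect_equal(slope, 6, tolerance = 0.05)
})

test_that("a single precursor samples the Boltzmann radial distribution", {
  # one mobile +1 precursor around one fixed -1 charge: p(r) ~ r^2 exp(-U(r))
  box <- box_spec(12, 12, 12, boundary = c(x = "REFLECTING", y = "REFLECTING",
                                           z = "REFLECTING"))
  topo <- particle_gas(2, box, species = "PRECURSOR", seed = 1)
  topo$beads$x <- c(0, 2); topo$beads$y <- c(0, 0); topo$beads$z <- c(6, 6)
  topo$beads$fixed[1] <- TRUE
  topo$beads$charge <- c(-1, 1)
  ff <- forcefield_params(debye_length = 1.0, attraction_epsilon = 0,
                          pair_cutoff = 5.5)
  ip <- integrator_params(dt = 0.004, n_steps = 2e6, frame_stride = 40,
                          seed = 77)
  traj <- run_bd(topo, ff, ip)
  ctr <- c(0, 0, 6)
  r <- sqrt(colSums((traj$frames[2, , ] - ctr)^2))
  r <- r[-seq_len(2000)]                        # discard equilibration
  # expected density within the largest fully-enclosed sphere
  breaks <- seq(0.9, 5.5, by = 0.35)
  keep <- r >= min(breaks) & r < max(breaks)
  obs <- table(cut(r[keep], breaks))
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  u <- pair_energy("PRECURSOR", "PRECURSOR", -1, 1, mids, ff)
  pexp <- mids^2 * exp(-u)
  pexp <- pexp / sum(pexp)
  # merge sparse bins then chi-square against the Boltzmann prediction,
  # with the effective sample size deflated for autocorrelation
  n_eff <- length(r[keep]) / 20
  chisq <- sum((as.numeric(obs) / sum(obs) - pexp)^2 / pexp) * n_eff
  pval <- stats::pchisq(chisq, df = length(pexp) - 1, lower.tail = FALSE)
  expect_gt(pval, 0.01)
})

test_that("mobile beads do not penetrate core excluded volume", {
  sys <- build_study_system("DS", seed = 6)
  ff <- config_forcefield(default_config())
  traj <- run_bd(sys$topo, ff,
                 integrator_params(dt = 0.002, n_steps = 10000,
                                   frame_stride = 1000, seed = 8))
  topo <- sys$topo
  core <- which(topo$beads$species == "CORE")
  mob <- which(!topo$beads$fixed)
  lz <- topo$box$lz
  for (f in seq_len(n_frames(traj))) {
    pos <- frame_positions(traj, f)
    for (m in mob) {
      dz <- pos[core, 3] - pos[m, 3]
      dz <- dz - lz * round(dz / lz)
      d <- sqrt((pos[core, 1] - pos[m, 1])^2 +
                  (pos[core, 2] - pos[m, 2])^2 + dz^2)
      sigma <- topo$beads$radius[core[1]] + topo$beads$radius[m]
      expect_gt(min(d), 0.8 * sigma)
    }
  }
})

test_that("equilibrated DS brushes reach the configured persistence length", {
  # brush-only system: free-standing check of the bending parameterisation
  cfg <- default_config()
  cfg$precursors$count <- 0L
  sys <- build_study_system("DS", seed = 3, config = cfg)
  ff <- config_forcefield(cfg)
  traj <- run_bd(sys$topo, ff,
                 integrator_params(dt = 0.002, n_steps = 40000,
                                   frame_stride = 2000, seed = 13))
  contours <- brush_contours(traj, frames = analysis_window(traj),
                             resample_step = 1.0)
  # drop the anchor segment: the graft bond is not part of the chain
  contours <- lapply(contours, function(m) {
    structure(m[-1, , drop = FALSE], step = attr(m, "step"),
              convention = "3D", class = "wlc_contour")
  })
  fit <- estimate_lp(contours, convention = "3D", max_fraction = 0.8)
  expect_equal(fit$persistence_length_nm, 50, tolerance = 0.35)

  # stiffness ordering at equal contour: DS chains are more extended
  sys_ss <- build_study_system("SS", seed = 3, config = cfg)
  traj_ss <- run_bd(sys_ss$topo, ff,
                    integrator_params(dt = 0.002, n_steps = 40000,
                                      frame_stride = 2000, seed = 13))
  ee <- function(tr) {
    topo <- tr$topology
    lz <- topo$box$lz
    vals <- c()
    for (f in analysis_window(tr)) {
      pos <- frame_positions(tr, f)
      for (ch in unique(topo$beads$chain_id[topo$beads$chain_id > 0])) {
        ids <- which(topo$beads$chain_id == ch)
        d <- pos[ids[length(ids)], ] - pos[ids[1], ]
        d[3] <- d[3] - lz * round(d[3] / lz)
        vals <- c(vals, sqrt(sum(d^2)))
      }
    }
    mean(vals)
  }
  expect_gt(ee(traj), ee(traj_ss))
})
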