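test_that("Debye length follows the ionic-strength closed form", {
  expect_equal(debye_length(100, 0), 0.304 / sqrt(0.1))   # 0.96 nm
  expect_equal(round(debye_length(100, 0), 2), 0.96)
  # 5 mM divalent chloride: I = 15 mM
  expect_equal(debye_length(0, 5), 0.304 / sqrt(0.015))
  expect_equal(round(debye_length(0, 5), 2), 2.48)
  # high-salt limit
  expect_lt(debye_length(1e9, 0), 1e-3)
  expect_error(debye_length(0, 0), "undefined-screening")
})

test_that("thermal energy at 298 K is 0.6 kcal/mol to one decimal", {
  expect_equal(round(kBT_kcal_mol(298), 1), 0.6)
  expect_equal(kBT_kcal_mol(298), 0.5922, tolerance = 1e-3)
})

test_that("screened-Coulomb pair energy matches the closed form", {
  p <- forcefield_params(debye_length = 1.0)
  # like charges one Debye length apart, no overlap, no attraction term:
  # lB * exp(-1) / 1  (up to the cutoff energy shift)
  u <- pair_energy("ION_MONO", "ION_MONO", -1, -1, 1.0, p, sigma = 0.4)
  expect_equal(u, 0.71 * exp(-1), tolerance = 2e-3)
  expect_equal(round(u, 2), 0.26)
  # zero beyond the cutoff
  expect_identical(pair_energy("ION_MONO", "ION_MONO", -1, -1,
                               p$pair_cutoff * 1.01, p), 0)
  # opposite charges attract
  expect_lt(pair_energy("PRECURSOR", "ION_MONO", 1, -1, 2.0, p, sigma = 0.7), 0)
  expect_error(pair_energy("CORE", "CORE", -1, -1, 0, p), "domain error")
})

test_that("pair energy is symmetric, continuous at cutoffs, and attractive
          only for precursor-DNA pairs", {
  p <- forcefield_params(debye_length = 1.5, attraction_epsilon = 1.2)
  expect_equal(pair_energy("PRECURSOR", "DS_BEAD", 1, -1.5, 1.7, p),
               pair_energy("DS_BEAD", "PRECURSOR", -1.5, 1, 1.7, p))
  # continuity at pair_cutoff to 1e-9
  eps <- 1e-7
  for (sp in list(c("PRECURSOR", "CORE"), c("ION_MONO", "ION_MONO"))) {
    below <- pair_energy(sp[1], sp[2], 1, -1, p$pair_cutoff - eps, p)
    expect_lt(abs(below), 1e-9)
  }
  # continuity at the attraction range
  u_in <- pair_energy("PRECURSOR", "CORE", 0, 0, p$attraction_range - 1e-8, p)
  u_out <- pair_energy("PRECURSOR", "CORE", 0, 0, p$attraction_range + 1e-8, p)
  expect_lt(abs(u_in - u_out), 1e-9)
  # continuity at the WCA/flat-well junction
  sigma <- 1.5
  rmin <- 2^(1 / 6) * sigma
  u_a <- pair_energy("PRECURSOR", "CORE", 0, 0, rmin - eps, p)
  u_b <- pair_energy("PRECURSOR", "CORE", 0, 0, rmin + eps, p)
  expect_lt(abs(u_a - u_b), 1e-6)
  # neutral non-DNA pairs feel no attraction: pure WCA is zero past rmin
  expect_identical(pair_energy("PRECURSOR", "PRECURSOR", 0, 0, 1.2, p), 0)
  # precursor-DNA well is attractive past rmin
  expect_lt(pair_energy("PRECURSOR", "CORE", 0, 0, 2.0, p), 0)
})

test_that("compiled pair energies agree with the R reference", {
  p <- forcefield_params(debye_length = 1.3, attraction_epsilon = 0.9)
  rs <- seq(0.4, 6.5, by = 0.037)
  for (case in list(
    list(si = "PRECURSOR", sj = "CORE", qi = 1, qj = -1),
    list(si = "PRECURSOR", sj = "DS_BEAD", qi = 1, qj = -1.5),
    list(si = "SS_BEAD", sj = "SS_BEAD", qi = -0.75, qj = -0.75))) {
    sdf <- silicabrush:::species_defaults()
    sigma <- sum(sdf$radius[match(c(case$si, case$sj), sdf$species)])
    r_ref <- pair_energy(case$si, case$sj, case$qi, case$qj, rs, p)
    r_cpp <- silicabrush:::cpp_pair_energy(
      rs, case$qi * case$qj, sigma,
      silicabrush:::is_attraction_pair(case$si, case$sj),
      silicabrush:::ff_to_cpp(p))
    expect_equal(r_cpp, r_ref, tolerance = 1e-12)
  }
})

test_that("neighbor list equals the brute-force pair set", {
  topo <- make_random_system(n_free = 40, n_chains = 2, seed = 11)
  pos <- as.matrix(topo$beads[, c("x", "y", "z")])
  nl <- build_neighbor_list(topo, cutoff = 4, skin = 0.5)
  got <- paste(nl[, 1], nl[, 2])
  want <- oracle_pairs(topo, pos, 4.5)
  expect_setequal(got, want)

  # single bead -> empty list
  solo <- particle_gas(1, box_spec(30, 30, 30))
  expect_equal(nrow(build_neighbor_list(solo, cutoff = 5, skin = 0)), 0)

  # cutoff+skin beyond the half periodic box is rejected
  expect_error(build_neighbor_list(topo, cutoff = 11, skin = 0),
               "neighbor error")
})

test_that("cell-list forces match the brute-force oracle to 1e-10", {
  for (seed in c(5, 23)) {
    topo <- make_random_system(n_free = 35, n_chains = 3, chain_len = 5,
                               seed = seed)
    ff <- forcefield_params(debye_length = 1.4, attraction_epsilon = 1.1,
                            pair_cutoff = 5)
    got <- total_forces(topo, params = ff)
    want <- oracle_forces(topo, ff)
    scale <- max(abs(want$forces))
    expect_lt(max(abs(got$forces - want$forces)) / scale, 1e-10)
    expect_equal(got$energy, want$energy, tolerance = 1e-8)
  }
})

test_that("isolated pairs obey Newton's third law and bond rest lengths", {
  box <- box_spec(30, 30, 30)
  topo <- particle_gas(2, box, species = "PRECURSOR", seed = 3)
  topo$beads$x <- c(-1, 1); topo$beads$y <- c(0, 0); topo$beads$z <- c(15, 15)
  ff <- forcefield_params(debye_length = 1.0)
  f <- total_forces(topo, params = ff)
  expect_equal(f$forces[1, ], -f$forces[2, ], tolerance = 1e-14)

  # bonded pair at rest length: zero net force
  topo$beads$charge <- 0
  topo$bonds <- data.frame(i = 1, j = 2, r0 = 2.0, k = 50)
  f2 <- total_forces(topo, params = ff)
  expect_equal(max(abs(f2$forces)), 0, tolerance = 1e-12)
})

test_that("forces are the exact negative gradient of the energy", {
  topo <- make_random_system(n_free = 10, n_chains = 1, chain_len = 4,
                             seed = 9)
  ff <- forcefield_params(debye_length = 1.2, attraction_epsilon = 0.8)
  pos <- as.matrix(topo$beads[, c("x", "y", "z")])
  f <- total_forces(topo, pos, ff)
  h <- 1e-6
  set.seed(1)
  for (i in sample(nrow(pos), 4)) {
    for (ax in 1:3) {
      pp <- pos; pp[i, ax] <- pp[i, ax] + h
      pm <- pos; pm[i, ax] <- pm[i, ax] - h
      num <- -(total_forces(topo, pp, ff)$energy -
                 total_forces(topo, pm, ff)$energy) / (2 * h)
      expect_equal(f$forces[i, ax], num, tolerance = 1e-5)
    }
  }
})
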