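# Independent O(N^2) brute-force oracle for energies and forces, written in
# plain R against the documented functional forms.  Used to validate the
# compiled cell-list path.

oracle_min_image <- function(d, box) {
  if (box$boundary["x"] == "PERIODIC") d[1] <- d[1] - box$lx * round(d[1] / box$lx)
  if (box$boundary["y"] == "PERIODIC") d[2] <- d[2] - box$ly * round(d[2] / box$ly)
  if (box$boundary["z"] == "PERIODIC") d[3] <- d[3] - box$lz * round(d[3] / box$lz)
  d
}

# energy and dU/dr of one non-bonded pair at distance r
oracle_pair <- function(r, qq, sigma, att, ff) {
  e <- 0; dudr <- 0
  if (r >= ff$pair_cutoff) return(c(e = 0, dudr = 0))
  rmin <- 2^(1 / 6) * sigma
  if (r < rmin) {
    sr6 <- (sigma / r)^6
    e <- e + 4 * ff$wca_epsilon * (sr6^2 - sr6) + ff$wca_epsilon
    dudr <- dudr - 24 * ff$wca_epsilon * (2 * sr6^2 - sr6) / r
  }
  if (qq != 0) {
    sh <- exp(-ff$pair_cutoff / ff$debye_length) / ff$pair_cutoff
    e <- e + ff$bjerrum_length * qq * (exp(-r / ff$debye_length) / r - sh)
    dudr <- dudr - ff$bjerrum_length * qq * exp(-r / ff$debye_length) *
      (1 / (ff$debye_length * r) + 1 / r^2)
  }
  if (att && ff$attraction_epsilon != 0 && r < ff$attraction_range) {
    eps <- ff$attraction_epsilon
    sr6c <- (sigma / ff$attraction_range)^6
    sh <- 4 * eps * (sr6c^2 - sr6c)
    if (r < rmin) {
      e <- e - eps - sh
    } else {
      sr6 <- (sigma / r)^6
      e <- e + 4 * eps * (sr6^2 - sr6) - sh
      dudr <- dudr - 24 * eps * (2 * sr6^2 - sr6) / r
    }
  }
  c(e = e, dudr = dudr)
}

oracle_forces <- function(topo, ff, positions = NULL,
                          skip_fixed_fixed = FALSE) {
  b <- topo$beads
  pos <- if (is.null(positions)) as.matrix(b[, c("x", "y", "z")]) else positions
  n <- nrow(pos)
  F <- matrix(0, n, 3)
  E <- 0
  box <- topo$box
  dna <- c("CORE", "SS_BEAD", "DS_BEAD")
  excl <- oracle_exclusions(topo)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (skip_fixed_fixed && b$fixed[i] && b$fixed[j]) next
      if (paste(i, j) %in% excl) next
      d <- oracle_min_image(pos[i, ] - pos[j, ], box)
      r <- sqrt(sum(d^2))
      att <- (b$species[i] == "PRECURSOR" && b$species[j] %in% dna) ||
        (b$species[j] == "PRECURSOR" && b$species[i] %in% dna)
      pe <- oracle_pair(r, b$charge[i] * b$charge[j],
                        b$radius[i] + b$radius[j], att, ff)
      E <- E + pe["e"]
      f <- -pe["dudr"] / r * d
      F[i, ] <- F[i, ] + f
      F[j, ] <- F[j, ] - f
    }
  }
  # bonds
  for (k in seq_len(nrow(topo$bonds))) {
    i <- topo$bonds$i[k]; j <- topo$bonds$j[k]
    d <- oracle_min_image(pos[i, ] - pos[j, ], box)
    r <- sqrt(sum(d^2))
    E <- E + 0.5 * topo$bonds$k[k] * (r - topo$bonds$r0[k])^2
    f <- -topo$bonds$k[k] * (r - topo$bonds$r0[k]) / r * d
    F[i, ] <- F[i, ] + f
    F[j, ] <- F[j, ] - f
  }
  # angles: analytic gradient of U = kappa/2 (theta - theta0)^2 at vertex j
  for (k in seq_len(nrow(topo$angles))) {
    i <- topo$angles$i[k]; j <- topo$angles$j[k]; l <- topo$angles$k_idx[k]
    u <- oracle_min_image(pos[i, ] - pos[j, ], box)
    v <- oracle_min_image(pos[l, ] - pos[j, ], box)
    nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
    ct <- max(-1, min(1, sum(u * v) / (nu * nv)))
    th <- acos(ct)
    st <- sqrt(max(1 - ct^2, 1e-12))
    E <- E + 0.5 * topo$angles$kappa[k] * (th - topo$angles$theta0[k])^2
    coef <- topo$angles$kappa[k] * (th - topo$angles$theta0[k]) / st
    gi <- (v / nv - ct * u / nu) / nu
    gl <- (u / nu - ct * v / nv) / nv
    F[i, ] <- F[i, ] + coef * gi
    F[l, ] <- F[l, ] + coef * gl
    F[j, ] <- F[j, ] - coef * (gi + gl)
  }
  list(forces = F, energy = unname(E))
}

oracle_exclusions <- function(topo) {
  keys <- character(0)
  bonds <- topo$bonds
  if (nrow(bonds) == 0) return(keys)
  add <- function(i, j) paste(min(i, j), max(i, j))
  for (k in seq_len(nrow(bonds))) keys <- c(keys, add(bonds$i[k], bonds$j[k]))
  adj <- split(c(bonds$j, bonds$i), c(bonds$i, bonds$j))
  for (nb in adj) {
    if (length(nb) >= 2) {
      pr <- utils::combn(nb, 2)
      for (c1 in seq_len(ncol(pr))) keys <- c(keys, add(pr[1, c1], pr[2, c1]))
    }
  }
  if (nrow(topo$angles))
    for (k in seq_len(nrow(topo$angles)))
      keys <- c(keys, add(topo$angles$i[k], topo$angles$k_idx[k]))
  unique(keys)
}

# brute-force neighbour pair set for list validation
oracle_pairs <- function(topo, positions, rlist, skip_fixed_fixed = FALSE) {
  n <- nrow(positions)
  out <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (skip_fixed_fixed && topo$beads$fixed[i] && topo$beads$fixed[j]) next
      d <- oracle_min_image(positions[i, ] - positions[j, ], topo$box)
      if (sum(d^2) <= rlist^2) out <- c(out, paste(i, j))
    }
  }
  out
}

# small random test system: a few bonded chains plus loose charged beads
make_random_system <- function(n_free = 30, n_chains = 3, chain_len = 5,
                               seed = 42, lz = 20) {
  set.seed(seed)
  box <- box_spec(20, 20, lz)
  topo <- particle_gas(n_free, box, species = "PRECURSOR", seed = seed)
  sdf <- silicabrush:::species_defaults()
  for (c1 in seq_len(n_chains)) {
    start <- stats::runif(3, -5, 5) + c(0, 0, 10)
    dirv <- stats::rnorm(3); dirv <- dirv / sqrt(sum(dirv^2))
    ids <- nrow(topo$beads) + seq_len(chain_len)
    pts <- t(sapply(seq_len(chain_len) - 1, function(m) start + m * 1.2 * dirv))
    topo$beads <- rbind(topo$beads, data.frame(
      bead_id = ids, species = "DS_BEAD",
      charge = sdf$charge[sdf$species == "DS_BEAD"],
      radius = sdf$radius[sdf$species == "DS_BEAD"],
      x = pts[, 1], y = pts[, 2], z = pts[, 3] %% lz,
      chain_id = c1, fixed = FALSE, stringsAsFactors = FALSE))
    topo$bonds <- rbind(topo$bonds, data.frame(
      i = ids[-chain_len], j = ids[-1], r0 = 1.2, k = 100))
    trip <- seq_len(chain_len - 2)
    topo$angles <- rbind(topo$angles, data.frame(
      i = ids[trip], j = ids[trip + 1], k_idx = ids[trip + 2],
      theta0 = pi, kappa = 20))
  }
  topo
}
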