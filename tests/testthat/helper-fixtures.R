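# Shared fixtures, all generated in code.

two_basin_specs <- function(populations = c(0.5, 0.5)) {
  list(
    basin_spec(1, populations[1], c(180, 60, -60, 180), 60,
               hbond_distance_mean = 2.9),
    basin_spec(2, populations[2], c(-60, 180, 60, -60), 60,
               hbond_distance_mean = 3.6, energy_offset = 1)
  )
}

tiny_ensemble <- function(n = 40, seed = 42, basins = two_basin_specs()) {
  generate_ensemble(basins, n, seed = seed)
}

# A single-frame ensemble holding explicit coordinates.
frame_ensemble <- function(xyz, species, energy = 0) {
  conformer_ensemble(list(xyz), species, energy)
}

# Ideal collinear N-H...O geometry builder: donor at origin, H on +x at
# d_dh, acceptor on +x at d_da.
ideal_hbond_frame <- function(d_dh = 1.0, d_da = 2.9) {
  xyz <- rbind(c(0, 0, 0), c(d_dh, 0, 0), c(d_da, 0, 0))
  list(xyz = xyz, species = c("N", "H", "O"))
}

gaussian_peak_spectrum <- function(center, fwhm = 10, grid = seq(500, 3700, 1)) {
  broaden(tibble::tibble(wavenumber = center, intensity = 1),
          fwhm = fwhm, grid = grid)
}

# Brute-force quick-shift oracle: independent steepest-ascent transcription.
quickshift_oracle <- function(G, dens, lambda, alpha) {
  ng <- nrow(G)
  parent <- integer(ng)
  for (i in seq_len(ng)) {
    best <- 0L; best_d <- Inf
    for (j in seq_len(ng)) {
      if (dens[j] <= dens[i]) next
      dij <- sqrt(sum((G[i, ] - G[j, ])^2))
      if (dij <= alpha * lambda[i] && dij < best_d) { best_d <- dij; best <- j }
    }
    parent[i] <- best
  }
  root <- vapply(seq_len(ng), function(i) {
    while (parent[i] != 0) i <- parent[i]
    i
  }, integer(1))
  match(root, sort(unique(root)))
}

# Independent Pendry R implementation used as an oracle: literal
# transcription of the defining formula with its own derivative code.
pendry_oracle <- function(grid, ia, ib, v_oi) {
  lder <- function(I) {
    n <- length(I)
    d <- numeric(n)
    for (k in 2:(n - 1)) d[k] <- (I[k + 1] - I[k - 1]) / (grid[k + 1] - grid[k - 1])
    d[1] <- (I[2] - I[1]) / (grid[2] - grid[1])
    d[n] <- (I[n] - I[n - 1]) / (grid[n] - grid[n - 1])
    d
  }
  yfun <- function(I) {
    eps <- 1e-8 * max(abs(I))
    L <- ifelse(abs(I) > eps, lder(I) / I, 0)
    ifelse(abs(I) > eps, L / (1 + v_oi^2 * L^2), 0)
  }
  ya <- yfun(ia); yb <- yfun(ib)
  sum((ya - yb)^2) / sum(ya^2 + yb^2)
}
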