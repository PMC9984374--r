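#' Specification of one conformational basin
#'
#' A basin is one metastable free-energy well of the synthetic peptide-like
#' chain: a set of mean torsion angles with a von-Mises-like spread, a
#' characteristic donor--acceptor hydrogen-bond distance, a baseline energy
#' offset, and a stick spectrum whose line positions shift linearly with the
#' instantaneous H-bond distance.
#'
#' @param id integer basin identifier.
#' @param population equilibrium fraction of frames drawn from this basin.
#' @param torsion_means mean values (degrees) of the chain's 4 free torsions.
#' @param torsion_concentrations positive concentration parameters; the
#'   angular spread is approximately `1/sqrt(concentration)` radians
#'   (large-concentration von Mises limit). Recycled to length 4.
#' @param hbond_distance_mean characteristic N...O donor-acceptor distance
#'   (Angstrom) of the basin's intramolecular hydrogen bond.
#' @param hbond_distance_sd per-frame spread of that distance (Angstrom).
#' @param stick_peaks data frame with columns `wavenumber` (cm^-1),
#'   `intensity` (>= 0) and `shift_slope` (cm^-1 per Angstrom of H-bond
#'   distance deviation from the basin mean).
#' @param energy_offset baseline potential energy of the basin (kcal/mol).
#' @return an object of class `basin_spec`.
#' @export
basin_spec <- function(id, population, torsion_means, torsion_concentrations = 50,
                       hbond_distance_mean = 2.9, hbond_distance_sd = 0.05,
                       stick_peaks = default_stick_peaks(id),
                       energy_offset = 0) {
  if (population < 0 || population > 1) abort("`population` must lie in [0, 1]")
  if (any(torsion_concentrations <= 0)) abort("torsion concentrations must be > 0")
  if (any(stick_peaks$intensity < 0)) abort("stick intensities must be >= 0")
  if (length(torsion_means) != 4) abort("the chain template has exactly 4 free torsions")
  structure(
    list(id = as.integer(id), population = population,
         torsion_means = as.numeric(torsion_means),
         torsion_concentrations = rep_len(as.numeric(torsion_concentrations), 4),
         hbond_distance_mean = hbond_distance_mean,
         hbond_distance_sd = hbond_distance_sd,
         stick_peaks = tibble::as_tibble(stick_peaks),
         energy_offset = energy_offset),
    class = "basin_spec"
  )
}

#' Default synthetic stick spectra, one flavour per basin id
#'
#' Peaks sit in the amide I/II (1500-1700 cm^-1), amide III (1250 cm^-1) and
#' N-H stretch (3300 cm^-1) regions typical of peptide IR spectra; positions
#' are staggered across basins so distinct basins have distinct spectra, and
#' H-bond-sensitive lines carry a negative shift slope (red shift for a
#' shorter, stronger H bond means positive slope in distance).
#'
#' @param id basin id used to stagger the peak positions.
#' @return a tibble with columns wavenumber, intensity, shift_slope.
#' @export
default_stick_peaks <- function(id) {
  k <- (as.integer(id) - 1L) %% 5L
  tibble::tibble(
    wavenumber  = c(1240 + 18 * k, 1545 + 14 * k, 1660 - 12 * k, 3290 + 25 * k),
    intensity   = c(0.6, 0.8, 1.0, 0.5),
    shift_slope = c(0, 40, 60, 120)
  )
}

# ---- chain template ---------------------------------------------------------

# Fixed internal-coordinate template of the synthetic peptide-like chain:
# a 7-atom heavy backbone N-C-C-N-C-C-O with amide-like substituents, two
# N-H donor groups and three backbone O acceptors, plus a pendant carbonyl
# acceptor placed along the first N-H axis at the basin's H-bond distance.
# Columns: species, a (bond ref), b (angle ref), c (dihedral ref), r (A),
# theta (deg), phi0 (deg), tor (free-torsion index, 0 = rigid).
chain_template <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cache <<- chain_template_build()
    cache
  }
})

chain_template_build <- function() {
  tpl <- rbind(
    data.frame(species = "N", a = 0, b = 0, c = 0, r = 0,    theta = 0,     phi0 = 0,   tor = 0),
    data.frame(species = "C", a = 1, b = 0, c = 0, r = 1.47, theta = 0,     phi0 = 0,   tor = 0),
    data.frame(species = "C", a = 2, b = 1, c = 0, r = 1.52, theta = 115,   phi0 = 0,   tor = 0),
    data.frame(species = "N", a = 3, b = 2, c = 1, r = 1.35, theta = 115,   phi0 = 0,   tor = 1),
    data.frame(species = "C", a = 4, b = 3, c = 2, r = 1.45, theta = 118,   phi0 = 0,   tor = 2),
    data.frame(species = "C", a = 5, b = 4, c = 3, r = 1.52, theta = 112,   phi0 = 0,   tor = 3),
    data.frame(species = "O", a = 6, b = 5, c = 4, r = 1.41, theta = 110,   phi0 = 0,   tor = 4),
    data.frame(species = "H", a = 1, b = 2, c = 3, r = 1.01, theta = 109.5, phi0 = 60,  tor = 0),
    data.frame(species = "H", a = 1, b = 2, c = 3, r = 1.01, theta = 109.5, phi0 = 300, tor = 0),
    data.frame(species = "O", a = 3, b = 2, c = 1, r = 1.23, theta = 121,   phi0 = 180, tor = 1),
    data.frame(species = "H", a = 4, b = 3, c = 2, r = 1.01, theta = 119,   phi0 = 180, tor = 2),
    data.frame(species = "H", a = 2, b = 3, c = 4, r = 1.09, theta = 109.5, phi0 = 120, tor = 0),
    data.frame(species = "H", a = 2, b = 3, c = 4, r = 1.09, theta = 109.5, phi0 = 240, tor = 0),
    data.frame(species = "H", a = 5, b = 4, c = 3, r = 1.09, theta = 109.5, phi0 = 120, tor = 3),
    data.frame(species = "H", a = 5, b = 4, c = 3, r = 1.09, theta = 109.5, phi0 = 240, tor = 3),
    data.frame(species = "H", a = 7, b = 6, c = 5, r = 0.97, theta = 108,   phi0 = 180, tor = 0),
    data.frame(species = "O", a = 6, b = 5, c = 4, r = 1.23, theta = 121,   phi0 = 180, tor = 4)
  )
  tpl
}

# Place atom D given three reference positions and internals (NeRF step).
nerf_place <- function(A, B, C, r, theta, phi) {
  th <- deg2rad(theta); ph <- deg2rad(phi)
  b1 <- B - A; b2 <- C - B
  u2 <- b2 / sqrt(sum(b2^2))
  n <- c(b1[2] * b2[3] - b1[3] * b2[2],
         b1[3] * b2[1] - b1[1] * b2[3],
         b1[1] * b2[2] - b1[2] * b2[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * u2[3] - n[3] * u2[2],
         n[3] * u2[1] - n[1] * u2[3],
         n[1] * u2[2] - n[2] * u2[1])
  d <- r * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  C + cbind(u2, m, n) %*% d
}

# Build Cartesian coordinates (Angstrom) from the template, 4 torsions
# (degrees) and a pendant-acceptor distance d_DA (Angstrom).
build_chain <- function(torsions, d_da) {
  tpl <- chain_template()
  nt <- nrow(tpl)
  xyz <- matrix(0, nt + 3L, 3L)
  # first three atoms define the frame
  xyz[1, ] <- c(0, 0, 0)
  xyz[2, ] <- c(tpl$r[2], 0, 0)
  th3 <- deg2rad(tpl$theta[3])
  xyz[3, ] <- xyz[2, ] + tpl$r[3] * c(-cos(th3), sin(th3), 0)
  for (i in 4:nt) {
    phi <- tpl$phi0[i] + if (tpl$tor[i] > 0) torsions[tpl$tor[i]] else 0
    xyz[i, ] <- nerf_place(xyz[tpl$c[i], ], xyz[tpl$b[i], ], xyz[tpl$a[i], ],
                           tpl$r[i], tpl$theta[i], phi)
  }
  # pendant acceptor: carbonyl O on the N1-H axis at distance d_DA, plus its
  # carbon and a capping hydrogen
  u <- xyz[8, ] - xyz[1, ]; u <- u / sqrt(sum(u^2))
  v <- xyz[2, ] - xyz[1, ]; v <- v - sum(v * u) * u; v <- v / sqrt(sum(v^2))
  o_acc <- xyz[1, ] + d_da * u
  c_p <- o_acc + 1.23 * (0.5 * u + sqrt(0.75) * v)
  h_p <- c_p + 1.09 * u
  xyz[nt + 1L, ] <- o_acc
  xyz[nt + 2L, ] <- c_p
  xyz[nt + 3L, ] <- h_p
  list(coords = xyz, species = c(tpl$species, "O", "C", "H"))
}

min_pair_distance <- function(xyz) {
  d <- as.matrix(stats::dist(xyz))
  min(d[upper.tri(d)])
}

# ---- ensemble generation ----------------------------------------------------

#' Generate a synthetic conformer ensemble with known ground truth
#'
#' Frames are drawn from a mixture of conformational basins: a basin is
#' chosen with probability equal to its population, torsions are sampled
#' around the basin means, and Cartesian coordinates are rebuilt from a fixed
#' internal-coordinate chain template. Per-frame energies follow
#' `offset + harmonic torsion penalty + |N(0, sigma_E)|`; one exact
#' torsion-mean frame per basin is appended with zero penalty and zero noise,
#' so each basin's ground-truth lowest-energy representative exists exactly.
#'
#' @param basins list of [basin_spec] objects; populations must sum to 1.
#' @param n_frames number of sampled frames (the appended basin-mean frames
#'   come on top of these).
#' @param temperature sampling temperature (K), stored on the ensemble.
#' @param seed integer master seed; all randomness derives from it.
#' @param sigma_e standard deviation of the folded-normal energy noise
#'   (kcal/mol).
#' @param torsion_stiffness harmonic energy penalty per squared degree of
#'   torsion deviation (kcal/mol/deg^2).
#' @param max_retries clash-regeneration attempts per frame before failing.
#' @return a list with elements `ensemble` (a [conformer_ensemble]) and
#'   `truth` (class `synthetic_truth`: per-frame basin labels, per-frame
#'   H-bond distances, basin specs, appended representative indices, seed).
#' @export
generate_ensemble <- function(basins, n_frames, temperature = 300, seed = 1,
                              sigma_e = 0.1, torsion_stiffness = 0.002,
                              max_retries = 25) {
  if (length(basins) == 0) abort("need at least one basin")
  pops <- vapply(basins, function(b) b$population, numeric(1))
  if (abs(sum(pops) - 1) > 1e-12) {
    abort(sprintf("basin populations must sum to 1 (got %.12f)", sum(pops)))
  }
  if (n_frames < 1) abort("`n_frames` must be >= 1")
  set.seed(split_seed(seed, 0L))
  k <- length(basins)
  labels <- sample.int(k, n_frames, replace = TRUE, prob = pops)
  n_tot <- n_frames + k
  coords <- vector("list", n_tot)
  d_da <- numeric(n_tot)
  energy <- numeric(n_tot)
  species <- NULL
  for (i in seq_len(n_frames)) {
    b <- basins[[labels[i]]]
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      sd_deg <- rad2deg(1 / sqrt(b$torsion_concentrations))
      tors <- b$torsion_means + rnorm(4, 0, sd_deg)
      dd <- abs(rnorm(1, b$hbond_distance_mean, b$hbond_distance_sd))
      geom <- build_chain(tors, dd)
      if (min_pair_distance(geom$coords) >= 0.5) { ok <- TRUE; break }
    }
    if (!ok) {
      abort(sprintf("frame %d: could not generate clash-free geometry in %d tries",
                    i, max_retries))
    }
    if (try > 1) warn(sprintf("frame %d: regenerated %d time(s) after atom clash", i, try - 1L))
    coords[[i]] <- geom$coords
    species <- geom$species
    d_da[i] <- dd
    dev <- ang_diff(tors, b$torsion_means)
    energy[i] <- b$energy_offset + torsion_stiffness * sum(dev^2) +
      abs(rnorm(1, 0, sigma_e))
  }
  # exact basin-mean frames: ground-truth representatives
  rep_idx <- integer(k)
  for (j in seq_len(k)) {
    b <- basins[[j]]
    geom <- build_chain(b$torsion_means, b$hbond_distance_mean)
    idx <- n_frames + j
    coords[[idx]] <- geom$coords
    species <- geom$species
    d_da[idx] <- b$hbond_distance_mean
    energy[idx] <- b$energy_offset
    labels <- c(labels, j)
    rep_idx[j] <- idx
  }
  ens <- conformer_ensemble(coords, species, energy, temperature)
  truth <- structure(
    list(frame_labels = labels, basin_specs = basins, d_da = d_da,
         representative_frames = rep_idx, reference_spectrum = NULL,
         seed = seed),
    class = "synthetic_truth"
  )
  list(ensemble = ens, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %d frames, %d basins, seed %d\n",
              length(x$frame_labels), length(x$basin_specs), x$seed))
  invisible(x)
}

#' Ground-truth stick spectrum of one frame
#'
#' The frame's basin stick spectrum with each H-bond-sensitive line shifted
#' by `shift_slope * (d_DA - basin mean distance)`: a shorter (stronger)
#' hydrogen bond red-shifts the line.
#'
#' @param truth a `synthetic_truth` object.
#' @param frame frame index.
#' @return a stick spectrum tibble (wavenumber, intensity).
#' @export
frame_stick_spectrum <- function(truth, frame) {
  b <- truth$basin_specs[[truth$frame_labels[frame]]]
  shift <- truth$d_da[frame] - b$hbond_distance_mean
  tibble::tibble(
    wavenumber = b$stick_peaks$wavenumber + b$stick_peaks$shift_slope * shift,
    intensity = b$stick_peaks$intensity
  )
}

#' Noise-free or noisy ground-truth reference spectrum
#'
#' The population-weighted sum of each basin's broadened stick spectrum plus
#' optional i.i.d. Gaussian noise: the synthetic stand-in for a measured
#' action spectrum.
#'
#' @param truth a `synthetic_truth` object.
#' @param fwhm Gaussian broadening full width at half maximum (cm^-1).
#' @param noise_sd standard deviation of additive intensity noise.
#' @param seed integer seed for the noise stream.
#' @param grid wavenumber grid (cm^-1) on which to evaluate.
#' @return a grid spectrum tibble (wavenumber, intensity).
#' @export
generate_reference_spectrum <- function(truth, fwhm = 10, noise_sd = 0,
                                        seed = truth$seed,
                                        grid = seq(500, 3700, by = 1)) {
  if (fwhm <= 0) abort("`fwhm` must be > 0")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0")
  specs <- lapply(truth$basin_specs, function(b) {
    if (nrow(b$stick_peaks) == 0) abort(sprintf("basin %d has an empty stick list", b$id))
    broaden(b$stick_peaks[, c("wavenumber", "intensity")], fwhm = fwhm, grid = grid)
  })
  pops <- vapply(truth$basin_specs, function(b) b$population, numeric(1))
  ref <- ensemble_average(specs, pops / sum(pops))
  if (noise_sd > 0) {
    set.seed(split_seed(seed, 3L))
    ref$intensity <- ref$intensity + rnorm(length(grid), 0, noise_sd)
  }
  ref
}

#' Default three-basin study conditions
#'
#' Three well-separated basins with populations (0.6, 0.3, 0.1), torsion
#' means ~120 degrees apart, and H-bond distances 2.9 / 3.3 / 3.7 Angstrom
#' (strong, intermediate, broken), used throughout validation.
#'
#' @param populations basin populations (must sum to 1).
#' @return a list of three [basin_spec] objects.
#' @export
default_basins <- function(populations = c(0.6, 0.3, 0.1)) {
  stopifnot(length(populations) == 3)
  list(
    basin_spec(1, populations[1], c(180, 60, -60, 180), 60,
               hbond_distance_mean = 2.9, energy_offset = 0),
    basin_spec(2, populations[2], c(-60, 180, 60, -60), 60,
               hbond_distance_mean = 3.3, energy_offset = 1),
    basin_spec(3, populations[3], c(60, -60, 180, 60), 60,
               hbond_distance_mean = 3.7, energy_offset = 2)
  )
}

#' Serialize ground truth to JSON
#'
#' @param truth a `synthetic_truth` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  x <- list(
    seed = truth$seed,
    frame_labels = truth$frame_labels,
    d_da = truth$d_da,
    representative_frames = truth$representative_frames,
    basins = lapply(truth$basin_specs, function(b) {
      list(id = b$id, population = b$population,
           torsion_means = b$torsion_means,
           torsion_concentrations = b$torsion_concentrations,
           hbond_distance_mean = b$hbond_distance_mean,
           hbond_distance_sd = b$hbond_distance_sd,
           energy_offset = b$energy_offset,
           stick_peaks = b$stick_peaks)
    })
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
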