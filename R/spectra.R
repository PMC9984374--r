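#' Read / write two-column spectrum text files
#'
#' Plain whitespace-delimited text: wavenumber (cm^-1) then intensity.
#' Comment lines starting with `#` are ignored on read.
#'
#' @param path file path.
#' @return `read_spectrum()` returns a tibble with columns `wavenumber` and
#'   `intensity`.
#' @export
read_spectrum <- function(path) {
  x <- utils::read.table(path, col.names = c("wavenumber", "intensity"),
                         comment.char = "#")
  tibble::as_tibble(x)
}

#' @rdname read_spectrum
#' @param s spectrum data frame (wavenumber, intensity).
#' @export
write_spectrum <- function(s, path) {
  stopifnot(all(c("wavenumber", "intensity") %in% names(s)))
  writeLines(sprintf("%.10g %.12g", s$wavenumber, s$intensity), path)
  invisible(path)
}

#' Broaden a stick spectrum with Gaussians
#'
#' Each line becomes a unit-area Gaussian of the given full width at half
#' maximum, scaled by the line intensity; contributions are summed on the
#' wavenumber grid. Line positions are first multiplied by `scale_factor`
#' (harmonic-frequency scaling; 1 for synthetic data).
#'
#' @param sticks data frame of lines with columns `wavenumber` (> 0, cm^-1)
#'   and `intensity` (>= 0).
#' @param fwhm full width at half maximum of the Gaussians (cm^-1).
#' @param grid strictly increasing wavenumber grid (cm^-1).
#' @param scale_factor multiplicative frequency scaling applied to line
#'   positions before broadening.
#' @return a grid spectrum tibble (wavenumber, intensity).
#' @export
broaden <- function(sticks, fwhm = 10, grid = seq(500, 3700, by = 1),
                    scale_factor = 1) {
  if (fwhm <= 0) abort("`fwhm` must be > 0")
  if (scale_factor <= 0) abort("`scale_factor` must be > 0")
  if (is.unsorted(grid, strictly = TRUE)) abort("`grid` must be strictly increasing")
  if (nrow(sticks) == 0) {
    warn("empty stick list: returning a zero spectrum")
    return(tibble::tibble(wavenumber = grid, intensity = rep(0, length(grid))))
  }
  if (any(sticks$wavenumber <= 0)) abort("stick wavenumbers must be > 0")
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  pos <- sticks$wavenumber * scale_factor
  intensity <- rep(0, length(grid))
  for (i in seq_along(pos)) {
    intensity <- intensity + sticks$intensity[i] * dnorm(grid, pos[i], sigma)
  }
  tibble::tibble(wavenumber = grid, intensity = intensity)
}

#' Population-weighted average of grid spectra
#'
#' Pointwise convex combination of spectra that share one wavenumber grid.
#' No implicit resampling: mismatched grids are an error.
#'
#' @param spectra list of grid spectrum tibbles on a common grid.
#' @param weights non-negative weights summing to 1.
#' @return a grid spectrum tibble.
#' @export
ensemble_average <- function(spectra, weights) {
  if (length(spectra) != length(weights)) abort("one weight per spectrum required")
  if (abs(sum(weights) - 1) > 1e-9) {
    abort(sprintf("weights must sum to 1 (got %.12f)", sum(weights)))
  }
  g <- spectra[[1]]$wavenumber
  for (s in spectra) {
    if (length(s$wavenumber) != length(g) || any(s$wavenumber != g)) {
      abort("spectra are not on a common wavenumber grid (no implicit resampling)")
    }
  }
  intensity <- rep(0, length(g))
  for (i in seq_along(spectra)) {
    intensity <- intensity + weights[i] * spectra[[i]]$intensity
  }
  tibble::tibble(wavenumber = g, intensity = intensity)
}

#' Moving-average smoothing of a grid spectrum
#'
#' Boxcar convolution with reflective boundaries; the window is given in
#' wavenumber units and rounded to an odd number of grid points. Total
#' intensity mass is preserved.
#'
#' @param s grid spectrum tibble.
#' @param window smoothing window (cm^-1); must be at least the grid spacing.
#' @return a smoothed grid spectrum tibble.
#' @export
smooth_spectrum <- function(s, window) {
  stopif_not_spectrum(s)
  dg <- min(diff(s$wavenumber))
  if (window < dg) {
    warn("smoothing window below grid spacing: returning spectrum unchanged")
    return(s)
  }
  half <- max(1L, floor(window / (2 * dg)))
  n <- length(s$intensity)
  padded <- c(rev(s$intensity[seq_len(half) + 1L]), s$intensity,
              rev(s$intensity[n - seq_len(half)]))
  k <- 2L * half + 1L
  sm <- stats::filter(padded, rep(1 / k, k), sides = 2)
  tibble::tibble(wavenumber = s$wavenumber,
                 intensity = as.numeric(sm[(half + 1L):(half + n)]))
}

# Linear interpolation of a spectrum onto a grid restricted to `region`;
# refuses extrapolation.
resample_region <- function(s, grid) {
  if (min(grid) < min(s$wavenumber) || max(grid) > max(s$wavenumber)) {
    abort("requested region extends beyond the spectrum grid (no extrapolation)")
  }
  stats::approx(s$wavenumber, s$intensity, xout = grid)$y
}

#' Pendry reliability factor between two spectra
#'
#' Compares two spectra through the Y-function of their logarithmic
#' derivatives: `Y = L / (1 + v_oi^2 L^2)` with `L = I'/I`, which makes the
#' comparison sensitive to peak positions and widths but invariant to the
#' absolute intensity scale. `R_P = sum((Y_a - Y_b)^2) / sum(Y_a^2 + Y_b^2)`:
#' 0 for identical spectra, 1 for uncorrelated (disjoint-support) spectra.
#'
#' @param a,b grid spectrum tibbles covering `region`.
#' @param v_oi Y-function width parameter (cm^-1), conventionally the
#'   approximate half-width of the peaks.
#' @param region numeric length-2 evaluation window (cm^-1).
#' @param dg evaluation grid spacing (cm^-1).
#' @return an object of class `pendry_result`: list with `r_p`, `region`,
#'   `v_oi`.
#' @export
pendry_r <- function(a, b, v_oi = 5, region = c(600, 1800), dg = 1) {
  stopif_not_spectrum(a); stopif_not_spectrum(b)
  if (v_oi <= 0) abort("`v_oi` must be > 0")
  grid <- seq(region[1], region[2], by = dg)
  ia <- resample_region(a, grid)
  ib <- resample_region(b, grid)
  if (all(ia == 0) && all(ib == 0)) {
    abort("both spectra are identically zero on the region: R_P undefined")
  }
  ya <- y_function(grid, ia, v_oi)
  yb <- y_function(grid, ib, v_oi)
  denom <- sum(ya^2 + yb^2)
  structure(list(r_p = sum((ya - yb)^2) / denom,
                 region = region, v_oi = v_oi),
            class = "pendry_result")
}

# Pendry Y-function on a uniform grid: central-difference logarithmic
# derivative with an epsilon guard in near-zero regions (Y set to 0 there).
y_function <- function(grid, intensity, v_oi, eps_rel = 1e-8) {
  n <- length(grid)
  h <- grid[2] - grid[1]
  deriv <- numeric(n)
  deriv[2:(n - 1)] <- (intensity[3:n] - intensity[1:(n - 2)]) / (2 * h)
  deriv[1] <- (intensity[2] - intensity[1]) / h
  deriv[n] <- (intensity[n] - intensity[n - 1]) / h
  eps <- eps_rel * max(abs(intensity))
  y <- numeric(n)
  ok <- abs(intensity) > eps
  l <- deriv[ok] / intensity[ok]
  y[ok] <- l / (1 + v_oi^2 * l^2)
  y
}

#' @export
print.pendry_result <- function(x, ...) {
  cat(sprintf("Pendry R_P = %.4f on [%g, %g] cm^-1 (v_oi = %g cm^-1)\n",
              x$r_p, x$region[1], x$region[2], x$v_oi))
  invisible(x)
}

#' Pendry factors for the standard amide regions
#'
#' Evaluates [pendry_r()] separately on the amide I/II/III/V window
#' (600-1800 cm^-1) and the amide A/B window (2700-3600 cm^-1).
#'
#' @inheritParams pendry_r
#' @param regions named list of length-2 windows (cm^-1).
#' @return a tibble with columns region, lo, hi, r_p, v_oi.
#' @export
region_report <- function(a, b, v_oi = 5,
                          regions = list(`amide I/II/III/V` = c(600, 1800),
                                         `amide A/B` = c(2700, 3600))) {
  purrr::imap_dfr(regions, function(reg, nm) {
    p <- pendry_r(a, b, v_oi = v_oi, region = reg)
    tibble::tibble(region = nm, lo = reg[1], hi = reg[2],
                   r_p = p$r_p, v_oi = v_oi)
  })
}

#' Spectrum series along a cluster merge hierarchy
#'
#' For every level of the merge tree, from all leaf clusters down to the
#' single root, forms the weighted average of the representative spectra of
#' that level's clusters using the merged weights. Merged nodes take the
#' lower-energy child's representative.
#'
#' @param tree a `merge_tree` from [merge_hierarchy()].
#' @param spectra named list: one grid spectrum per leaf cluster id (names
#'   are cluster ids as character).
#' @return a list with one element per level, named by the number of
#'   clusters (`"K"`, ..., `"1"`); each element is a grid spectrum tibble.
#' @export
hierarchical_series <- function(tree, spectra) {
  lv <- tree$levels
  out <- list()
  for (level in lv) {
    specs <- lapply(level$clusters, function(cl) {
      s <- spectra[[as.character(cl$representative_leaf)]]
      if (is.null(s)) {
        abort(sprintf("no spectrum provided for leaf cluster %s", cl$representative_leaf))
      }
      s
    })
    w <- vapply(level$clusters, function(cl) cl$weight, numeric(1))
    out[[as.character(length(specs))]] <- ensemble_average(specs, w / sum(w))
  }
  out
}
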