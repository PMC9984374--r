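#' Enumerate candidate N-H...O hydrogen-bond triplets in one frame
#'
#' Covalent donor-hydrogen pairs are identified by a distance below
#' `covalent_max`; every such pair is combined with every acceptor atom
#' whose donor-acceptor distance is within `cutoff`. Ordering is
#' deterministic: by donor, then hydrogen, then acceptor index.
#'
#' @param xyz n_atoms x 3 coordinate matrix (Angstrom).
#' @param species element symbols per atom.
#' @param donor_species,acceptor_species element symbols acting as donors /
#'   acceptors (N-H...O by default; O-H...O is excluded).
#' @param cutoff maximum donor-acceptor distance (Angstrom).
#' @param covalent_max maximum covalent D-H bond length (Angstrom).
#' @return a tibble with columns donor, hydrogen, acceptor (atom indices)
#'   and d_dh, d_ah, d_da (Angstrom); zero rows when no donors or acceptors.
#' @export
enumerate_triplets <- function(xyz, species, donor_species = "N",
                               acceptor_species = "O", cutoff = 4.5,
                               covalent_max = 1.3) {
  donors <- which(species %in% donor_species)
  hydros <- which(species == "H")
  accept <- which(species %in% acceptor_species)
  empty <- tibble::tibble(donor = integer(), hydrogen = integer(),
                          acceptor = integer(), d_dh = numeric(),
                          d_ah = numeric(), d_da = numeric())
  if (length(donors) == 0 || length(accept) == 0 || length(hydros) == 0) {
    return(empty)
  }
  d <- as.matrix(stats::dist(xyz))
  rows <- list()
  for (dn in donors) {
    bound_h <- hydros[d[dn, hydros] < covalent_max]
    for (h in bound_h) {
      ok_a <- accept[d[dn, accept] <= cutoff]
      for (a in ok_a) {
        rows[[length(rows) + 1L]] <- c(dn, h, a, d[dn, h], d[a, h], d[dn, a])
      }
    }
  }
  if (length(rows) == 0) return(empty)
  m <- do.call(rbind, rows)
  tibble::tibble(donor = as.integer(m[, 1]), hydrogen = as.integer(m[, 2]),
                 acceptor = as.integer(m[, 3]), d_dh = m[, 4],
                 d_ah = m[, 5], d_da = m[, 6])
}

#' Two-component hydrogen-bond membership model
#'
#' Defines the continuous 0-1 hydrogen-bond counting function as the
#' posterior probability of the bonded component in a two-component mixture
#' over the proton-transfer coordinates `nu = d_DH - d_AH`,
#' `mu = d_DH + d_AH` and the donor-acceptor distance `d_DA`. The bonded
#' component is a narrow Gaussian at the reference H-bond geometry; the
#' background is a broad Gaussian representing unbonded triplets. A perfect
#' reference geometry scores ~1; a dissociated triplet scores ~0.
#'
#' @param bonded_mean,bonded_sd mean and sd of (nu, mu, d_DA) for the bonded
#'   component (Angstrom).
#' @param background_mean,background_sd same for the broad background.
#' @param mix prior weight of the bonded component.
#' @return an object of class `hbond_model`.
#' @export
hbond_model <- function(bonded_mean = c(-0.9, 2.9, 2.9),
                        bonded_sd = c(0.25, 0.25, 0.25),
                        background_mean = c(0, 4, 3),
                        background_sd = c(3, 4, 3),
                        mix = 0.5) {
  stopifnot(length(bonded_mean) == 3, length(bonded_sd) == 3,
            all(bonded_sd > 0), all(background_sd > 0), mix > 0, mix < 1)
  structure(list(bonded_mean = bonded_mean, bonded_sd = bonded_sd,
                 background_mean = background_mean, background_sd = background_sd,
                 mix = mix),
            class = "hbond_model")
}

#' Hydrogen-bond membership of triplets
#'
#' @param model an [hbond_model()].
#' @param triplets tibble with columns d_dh, d_ah, d_da (as from
#'   [enumerate_triplets()]).
#' @return numeric vector of memberships in `[0, 1]`, one per triplet.
#' @export
membership <- function(model, triplets) {
  if (nrow(triplets) == 0) return(numeric(0))
  x <- cbind(triplets$d_dh - triplets$d_ah,
             triplets$d_dh + triplets$d_ah,
             triplets$d_da)
  log_comp <- function(mean, sd) {
    dnorm(x[, 1], mean[1], sd[1], log = TRUE) +
      dnorm(x[, 2], mean[2], sd[2], log = TRUE) +
      dnorm(x[, 3], mean[3], sd[3], log = TRUE)
  }
  lb <- log(model$mix) + log_comp(model$bonded_mean, model$bonded_sd)
  lg <- log(1 - model$mix) + log_comp(model$background_mean, model$background_sd)
  m <- pmax(lb, lg)
  exp(lb - m) / (exp(lb - m) + exp(lg - m))
}

#' Continuous hydrogen-bond counts for ensemble frames
#'
#' For every frame, sums triplet memberships per tagged atom: `s_D` over all
#' triplets donating from a given N, `s_A` over all triplets accepted by a
#' given O, `s_H` over all triplets mediated by a given H. Atoms whose total
#' count falls below `participation_threshold` are excluded, the continuous
#' analog of ignoring atoms that do not participate in hydrogen bonding.
#'
#' @param ensemble a [conformer_ensemble].
#' @param model an [hbond_model()].
#' @param frames frame indices to process (default all).
#' @param cutoff donor-acceptor enumeration cutoff (Angstrom).
#' @param participation_threshold counts below this are treated as
#'   non-participating and dropped.
#' @return a tibble with columns frame, atom, role (`donor`, `acceptor`,
#'   `hydrogen`), value.
#' @export
count_hbonds <- function(ensemble, model = hbond_model(),
                         frames = seq_along(ensemble$coords), cutoff = 4.5,
                         participation_threshold = 0.01) {
  purrr::map_dfr(frames, function(f) {
    tr <- enumerate_triplets(ensemble$coords[[f]], ensemble$species,
                             cutoff = cutoff)
    if (nrow(tr) == 0) return(NULL)
    tr$m <- membership(model, tr)
    long <- dplyr::bind_rows(
      dplyr::summarise(dplyr::group_by(tr, atom = .data$donor),
                       value = sum(.data$m), .groups = "drop") |>
        dplyr::mutate(role = "donor"),
      dplyr::summarise(dplyr::group_by(tr, atom = .data$acceptor),
                       value = sum(.data$m), .groups = "drop") |>
        dplyr::mutate(role = "acceptor"),
      dplyr::summarise(dplyr::group_by(tr, atom = .data$hydrogen),
                       value = sum(.data$m), .groups = "drop") |>
        dplyr::mutate(role = "hydrogen")
    )
    long <- long[long$value >= participation_threshold, ]
    if (nrow(long) == 0) return(NULL)
    tibble::tibble(frame = f, atom = long$atom, role = long$role,
                   value = long$value)
  })
}

# Triangular-kernel mass of samples into histogram bins: each sample is
# smeared as a triangle of half-width `width` and integrated over the bins.
triangular_bin <- function(x, edges, width) {
  tri_cdf <- function(u) {
    u <- pmax(-width, pmin(width, u))
    ifelse(u < 0, 0.5 * (1 + u / width)^2, 1 - 0.5 * (1 - u / width)^2)
  }
  p <- numeric(length(edges) - 1)
  lo_bin <- findInterval(x - width, edges, all.inside = TRUE)
  hi_bin <- findInterval(x + width, edges, all.inside = TRUE)
  for (i in seq_along(x)) {
    for (b in lo_bin[i]:hi_bin[i]) {
      p[b] <- p[b] + tri_cdf(edges[b + 1] - x[i]) - tri_cdf(edges[b] - x[i])
    }
  }
  p / length(x)
}

#' Smoothed probability and free-energy surface of H-bond counts
#'
#' Histograms samples of one count variable (or joint samples of two) on
#' fixed bins, smears each sample with a triangular kernel, normalizes, and
#' converts to free energies `F = -k_B T ln(P)` (kcal/mol) where `P > 0`.
#'
#' @param samples numeric vector (1D) or two-column matrix/data frame of
#'   `(s_A, s_D)` joint samples.
#' @param temperature temperature in K.
#' @param width triangular-kernel half-width in count units.
#' @param bin_width histogram bin width.
#' @param range length-2 count range; extended automatically to cover the
#'   samples.
#' @return an object of class `prob_surface`: bin `edges` (list per axis),
#'   `P` (vector or matrix), `F`, `temperature`, `width`.
#' @export
hbond_surface <- function(samples, temperature = 300, width = 0.025,
                          bin_width = 0.05, range = c(0, 3)) {
  if (temperature <= 0) abort("`temperature` must be > 0")
  sm <- as.matrix(samples)
  if (nrow(sm) < 1) abort("need at least one sample")
  ndim <- ncol(sm)
  make_edges <- function(v) {
    lo <- min(range[1], floor((min(v) - width) / bin_width) * bin_width)
    hi <- max(range[2], ceiling((max(v) + width) / bin_width) * bin_width)
    seq(lo, hi, by = bin_width)
  }
  if (ndim == 1) {
    edges <- make_edges(sm[, 1])
    P <- triangular_bin(sm[, 1], edges, width)
    P <- P / sum(P)
    edges_list <- list(s = edges)
  } else if (ndim == 2) {
    e1 <- make_edges(sm[, 1]); e2 <- make_edges(sm[, 2])
    P <- matrix(0, length(e1) - 1, length(e2) - 1)
    for (i in seq_len(nrow(sm))) {
      p1 <- triangular_bin(sm[i, 1], e1, width)
      p2 <- triangular_bin(sm[i, 2], e2, width)
      P <- P + outer(p1, p2)
    }
    P <- P / sum(P)
    edges_list <- list(s_A = e1, s_D = e2)
  } else {
    abort("`samples` must be 1- or 2-dimensional")
  }
  F <- ifelse(P > 0, -KB_KCAL * temperature * log(P), NA_real_)
  structure(list(edges = edges_list, P = P, F = F,
                 temperature = temperature, width = width,
                 k_b = KB_KCAL, ndim = ndim),
            class = "prob_surface")
}

#' @export
print.prob_surface <- function(x, ...) {
  cat(sprintf("<prob_surface> %dD, %s bins, T = %g K, sum(P) = %.9f\n",
              x$ndim, paste(vapply(x$edges, function(e) length(e) - 1, numeric(1)),
                            collapse = " x "),
              x$temperature, sum(x$P)))
  invisible(x)
}

#' Integrated probabilities per integer cell
#'
#' Sums the smoothed probability mass over cells
#' `[i - 0.5, i + 0.5)` (per axis) and reports each cell's percentage plus
#' the most probable cell.
#'
#' @param surface a `prob_surface` (1D or 2D).
#' @return a list with `cells` (tibble of cell coordinates and `pct`) and
#'   `most_probable` (tibble row with the argmax cell and its percentage).
#' @export
integrate_cells <- function(surface) {
  centers <- lapply(surface$edges, function(e) (head(e, -1) + tail(e, -1)) / 2)
  cell_of <- lapply(centers, function(cc) as.integer(floor(cc + 0.5)))
  if (surface$ndim == 1) {
    agg <- rowsum(matrix(surface$P, ncol = 1), cell_of[[1]])
    cells <- tibble::tibble(s = as.integer(rownames(agg)),
                            pct = 100 * as.numeric(agg[, 1]))
  } else {
    df <- expand.grid(i = seq_along(centers[[1]]), j = seq_along(centers[[2]]))
    df$ca <- cell_of[[1]][df$i]; df$cd <- cell_of[[2]][df$j]
    df$p <- surface$P[cbind(df$i, df$j)]
    cells <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(df),
                                              s_A = .data$ca, s_D = .data$cd),
                              pct = 100 * sum(.data$p), .groups = "drop")
  }
  mp <- cells[which.max(cells$pct), ]
  list(cells = cells, most_probable = mp)
}

#' Per-cluster hydrogen-bonding summary table
#'
#' Mirrors the canonical cluster summary: weighted-average accepted and
#' donated H-bond counts with population standard deviations, the most
#' probable integer `(s_A, s_D)` tuple with its joint percentage, and the
#' cluster weight. Counts are averaged frame-first (mean over participating
#' atoms within a frame, then over frames). Joint `(s_A, s_D)` samples are
#' the cross pairs of participating acceptor and donor values within a
#' frame.
#'
#' @param counts tibble from [count_hbonds()].
#' @param clusters a `cluster_set`.
#' @param temperature temperature (K) for the underlying surfaces.
#' @param width triangular-kernel half-width.
#' @return a tibble with columns cluster, mean_sA, sd_sA, mean_sD, sd_sD,
#'   mp_tuple, mp_pct, weight_pct.
#' @export
per_cluster_summary <- function(counts, clusters, temperature = 300,
                                width = 0.025) {
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  purrr::map_dfr(seq_len(clusters$n_clusters), function(cl) {
    frames <- which(clusters$labels == cl)
    cc <- counts[counts$frame %in% frames, ]
    base <- tibble::tibble(cluster = cl, mean_sA = NA_real_, sd_sA = NA_real_,
                           mean_sD = NA_real_, sd_sD = NA_real_,
                           mp_tuple = NA_character_, mp_pct = NA_real_,
                           weight_pct = 100 * clusters$weights[cl])
    if (nrow(cc) == 0) return(base)
    frame_means <- function(role) {
      x <- cc[cc$role == role, ]
      if (nrow(x) == 0) return(numeric(0))
      tapply(x$value, x$frame, mean)
    }
    fa <- frame_means("acceptor"); fd <- frame_means("donor")
    if (length(fa) > 0) { base$mean_sA <- mean(fa); base$sd_sA <- pop_sd(fa) }
    if (length(fd) > 0) { base$mean_sD <- mean(fd); base$sd_sD <- pop_sd(fd) }
    # joint samples: cross pairs of acceptor and donor values within a frame
    joint <- purrr::map_dfr(frames, function(f) {
      a <- cc$value[cc$frame == f & cc$role == "acceptor"]
      d <- cc$value[cc$frame == f & cc$role == "donor"]
      if (length(a) == 0 || length(d) == 0) return(NULL)
      tidyr::expand_grid(s_A = a, s_D = d)
    })
    if (nrow(joint) > 0) {
      surf <- hbond_surface(as.matrix(joint), temperature, width)
      mp <- integrate_cells(surf)$most_probable
      base$mp_tuple <- sprintf("(%d,%d)", mp$s_A, mp$s_D)
      base$mp_pct <- mp$pct
    }
    base
  })
}

#' Tabulate a probability surface
#'
#' @param x a `prob_surface`.
#' @param ... unused.
#' @return a tibble with one row per bin: bin centers per axis, `P` and `F`.
#' @export
tidy.prob_surface <- function(x, ...) {
  centers <- lapply(x$edges, function(e) (head(e, -1) + tail(e, -1)) / 2)
  if (x$ndim == 1) {
    tibble::tibble(s = centers[[1]], P = as.numeric(x$P), F = as.numeric(x$F))
  } else {
    df <- expand.grid(s_A = centers[[1]], s_D = centers[[2]])
    tibble::tibble(s_A = df$s_A, s_D = df$s_D,
                   P = as.vector(x$P), F = as.vector(x$F))
  }
}
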