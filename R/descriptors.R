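#' SOAP descriptor parameters
#'
#' @param cutoff radial cutoff (Angstrom); must exceed `2 * atom_sigma`.
#' @param n_max number of radial basis functions.
#' @param l_max maximum angular momentum channel.
#' @param atom_sigma Gaussian smearing width of the neighbor density
#'   (Angstrom).
#' @param species element symbols the descriptor resolves; must cover every
#'   atom in the ensemble.
#' @param normalize L2-normalize each frame's descriptor row.
#' @return a list of validated SOAP parameters.
#' @export
soap_params <- function(cutoff = 5, n_max = 6, l_max = 4, atom_sigma = 0.4,
                        species = c("C", "H", "N", "O"), normalize = TRUE) {
  if (cutoff <= 2 * atom_sigma) abort("`cutoff` must exceed 2 * atom_sigma")
  if (n_max < 1 || l_max < 0) abort("need n_max >= 1 and l_max >= 0")
  list(cutoff = cutoff, n_max = n_max, l_max = l_max, atom_sigma = atom_sigma,
       species = sort(unique(species)), normalize = normalize)
}

# Orthonormalized Gaussian radial basis evaluated at quadrature nodes.
# Returns list(nodes, weights, G) with G an n_max x Q matrix such that
# sum_q w_q s_q^2 G[i,q] G[j,q] = delta_ij.
radial_basis <- function(cutoff, n_max, n_quad = 24) {
  gl <- pracma::gaussLegendre(n_quad, 0, cutoff)
  s <- gl$x; w <- gl$w
  centers <- cutoff * seq_len(n_max) / n_max
  width <- cutoff / n_max
  raw <- t(vapply(centers, function(c0) exp(-((s - c0)^2) / (2 * width^2)),
                  numeric(n_quad)))
  S <- matrix(0, n_max, n_max)
  for (i in seq_len(n_max)) for (j in seq_len(n_max)) {
    S[i, j] <- sum(w * s^2 * raw[i, ] * raw[j, ])
  }
  e <- eigen(S, symmetric = TRUE)
  s_inv_half <- e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-14)), n_max) %*% t(e$vectors)
  list(nodes = s, weights = w, G = s_inv_half %*% raw)
}

# Exponentially scaled modified spherical Bessel functions
# i_l(t) * exp(-t) for l = 0..l_max, stable for both small and large t.
scaled_bessel_i <- function(t, l_max) {
  out <- vector("list", l_max + 1)
  small <- which(t < 0.05)
  ts <- t
  ts[small] <- 1  # avoid 0/0; small entries overwritten by the series below
  E <- exp(-2 * ts)
  sh <- (1 - E) / 2
  ch <- (1 + E) / 2
  i0 <- sh / ts
  i1 <- (ts * ch - sh) / ts^2
  dfact <- function(l) prod(seq(1, 2 * l + 1, by = 2))
  tsm <- t[small]
  series <- function(l) tsm^l / dfact(l) * (1 + tsm^2 / (2 * (2 * l + 3))) * exp(-tsm)
  i0[small] <- series(0)
  out[[1]] <- i0
  if (l_max >= 1) {
    prev2 <- i0
    prev1 <- i1
    prev1[small] <- series(1)
    out[[2]] <- prev1
    if (l_max >= 2) {
      for (l in 2:l_max) {
        cur <- prev2 - (2 * l - 1) / ts * prev1
        cur[small] <- series(l)
        out[[l + 1]] <- cur
        prev2 <- prev1; prev1 <- cur
      }
    }
  }
  out
}

# Real spherical harmonics Y_lm for unit vectors (rows of u), returned as a
# list over l of (2l+1) x P matrices, rows ordered m = -l..l.
real_sph_harm <- function(u, l_max) {
  z <- pmin(pmax(u[, 3], -1), 1)
  phi <- atan2(u[, 2], u[, 1])
  out <- vector("list", l_max + 1)
  for (l in 0:l_max) {
    P <- if (l == 0) matrix(1, 1, length(z)) else pracma::legendre(l, z)
    Y <- matrix(0, 2 * l + 1, length(z))
    # m = 0
    Y[l + 1, ] <- sqrt((2 * l + 1) / (4 * pi)) * P[1, ]
    if (l > 0) {
      for (m in 1:l) {
        nlm <- sqrt((2 * l + 1) / (4 * pi) *
                      exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
        Y[l + 1 + m, ] <- sqrt(2) * nlm * P[m + 1, ] * cos(m * phi)
        Y[l + 1 - m, ] <- sqrt(2) * nlm * P[m + 1, ] * sin(m * phi)
      }
    }
    out[[l + 1]] <- Y
  }
  out
}

#' Compute average SOAP descriptors for every frame of an ensemble
#'
#' Expands the Gaussian-smeared neighbor density around each atom in an
#' orthonormal radial basis times real spherical harmonics, contracts the
#' expansion coefficients into the rotationally invariant power spectrum per
#' species pair, and averages over the atoms of the frame (the "average"
#' global descriptor). Invariant to rigid motions and to permutations of
#' atoms within a species.
#'
#' @param ensemble a [conformer_ensemble].
#' @param params a [soap_params()] list.
#' @param chunk number of frames processed per vectorized block.
#' @return a list of class `descriptor_matrix`: `values` (n_frames x D),
#'   `feature_meta` (tibble of species pair / n / n' / l channels),
#'   `normalized` flag.
#' @export
compute_soap <- function(ensemble, params = soap_params(), chunk = 250) {
  sp_all <- unique(ensemble$species)
  unknown <- setdiff(sp_all, params$species)
  if (length(unknown) > 0) {
    abort(paste0("species not covered by descriptor parameters: ",
                 paste(unknown, collapse = ", ")))
  }
  S <- length(params$species)
  nmax <- params$n_max; lmax <- params$l_max
  rb <- radial_basis(params$cutoff, nmax)
  sp_idx <- match(ensemble$species, params$species)
  n_at <- length(ensemble$species)
  n_frames <- length(ensemble$coords)
  nsn <- S * nmax  # combined (species, n) coefficient channels
  n_pairs_ab <- nsn * (nsn + 1) / 2
  ab <- which(upper.tri(matrix(0, nsn, nsn), diag = TRUE), arr.ind = TRUE)
  D <- n_pairs_ab * (lmax + 1)
  values <- matrix(0, n_frames, D)
  sigma2 <- params$atom_sigma^2

  for (f0 in seq(1, n_frames, by = chunk)) {
    f1 <- min(f0 + chunk - 1L, n_frames)
    frames <- f0:f1
    nf <- length(frames)
    # pair list across the chunk
    pc <- pair_list(ensemble$coords[frames], params$cutoff)
    if (nrow(pc$pairs) == 0) next
    r <- pc$pairs$r
    u <- cbind(pc$pairs$ux, pc$pairs$uy, pc$pairs$uz)
    t_mat <- outer(rb$nodes, r) / sigma2                      # Q x P
    gauss <- exp(-(outer(rb$nodes, r, `-`)^2) / (2 * sigma2)) # exp(-(s-r)^2/2sig^2)
    bessel <- scaled_bessel_i(t_mat, lmax)
    Ylist <- real_sph_harm(u, lmax)
    # center-species groups: one coefficient block per (center atom, species)
    centers_global <- (pc$pairs$frame_local - 1L) * n_at + pc$pairs$center
    grp <- (centers_global - 1L) * S + sp_idx[pc$pairs$neighbor]
    n_centers <- nf * n_at
    n_groups <- n_centers * S
    # coefficients per l, laid out (centers, nsn) per m
    pow <- matrix(0, n_centers, D)
    col0 <- 0L
    Gw <- rb$G * rep(rb$weights * rb$nodes^2, each = nmax)  # fold quadrature into basis
    for (l in 0:lmax) {
      I_l <- Gw %*% (gauss * bessel[[l + 1]])                    # nmax x P
      Y <- Ylist[[l + 1]]                                        # (2l+1) x P
      acc <- matrix(0, n_centers, n_pairs_ab)
      for (mi in seq_len(2 * l + 1)) {
        contrib <- t(I_l) * Y[mi, ]                              # P x nmax
        # sum contributions into the (center, species, n) coefficient table;
        # rowsum drops empty groups, so scatter back into the full table
        R0 <- rowsum(contrib, grp)
        Cfull <- matrix(0, n_groups, nmax)
        Cfull[as.integer(rownames(R0)), ] <- R0
        Cm <- t(matrix(t(Cfull), nsn, n_centers))  # centers x (S*nmax), species-major
        acc <- acc + Cm[, ab[, 1], drop = FALSE] * Cm[, ab[, 2], drop = FALSE]
      }
      pow[, col0 + seq_len(n_pairs_ab)] <- acc
      col0 <- col0 + n_pairs_ab
    }
    # average over atoms of each frame
    frame_of_center <- rep(seq_len(nf), each = n_at)
    values[frames, ] <- rowsum(pow, frame_of_center) / n_at
  }
  if (params$normalize) {
    nrm <- sqrt(rowSums(values^2))
    nrm[nrm == 0] <- 1
    values <- values / nrm
  }
  meta <- tidyr::expand_grid(
    l = 0:lmax,
    idx = seq_len(n_pairs_ab)
  )
  ch <- tibble::tibble(
    a_species = params$species[(ab[, 1] - 1L) %/% nmax + 1L],
    a_n = (ab[, 1] - 1L) %% nmax + 1L,
    b_species = params$species[(ab[, 2] - 1L) %/% nmax + 1L],
    b_n = (ab[, 2] - 1L) %% nmax + 1L
  )
  feature_meta <- dplyr::bind_cols(meta["l"], ch[meta$idx, ])
  structure(list(values = values, feature_meta = feature_meta,
                 normalized = params$normalize, params = params),
            class = "descriptor_matrix")
}

# Neighbor pair list for a list of coordinate frames (all ordered pairs
# center != neighbor with distance <= cutoff), with unit vectors.
pair_list <- function(coords, cutoff) {
  res <- purrr::map_dfr(seq_along(coords), function(fl) {
    xyz <- coords[[fl]]
    n <- nrow(xyz)
    d <- as.matrix(stats::dist(xyz))
    idx <- which(d <= cutoff & d > 0, arr.ind = TRUE)
    if (nrow(idx) == 0) return(NULL)
    dr <- xyz[idx[, 2], , drop = FALSE] - xyz[idx[, 1], , drop = FALSE]
    r <- d[idx]
    tibble::tibble(frame_local = fl, center = idx[, 1], neighbor = idx[, 2],
                   r = r, ux = dr[, 1] / r, uy = dr[, 2] / r, uz = dr[, 3] / r)
  })
  list(pairs = res)
}

#' @export
print.descriptor_matrix <- function(x, ...) {
  cat(sprintf("<descriptor_matrix> %d frames x %d features (normalized: %s)\n",
              nrow(x$values), ncol(x$values), x$normalized))
  invisible(x)
}

#' Principal component analysis of a descriptor matrix
#'
#' Thin wrapper over the standard singular-value decomposition PCA of the
#' column-centered descriptor matrix.
#'
#' @param X a `descriptor_matrix` or plain numeric matrix.
#' @param n_components number of components to keep.
#' @return a list of class `pca_projection`: `components` (D x d),
#'   `projected` (n x d), `explained_variance_ratio`, `mean`.
#' @export
pca_project <- function(X, n_components = 2) {
  M <- if (inherits(X, "descriptor_matrix")) X$values else as.matrix(X)
  if (n_components < 1 || n_components > min(dim(M))) {
    abort("`n_components` must lie in [1, min(n_frames, D)]")
  }
  total_var <- sum(apply(M, 2, var))
  if (total_var < .Machine$double.eps) {
    abort("descriptor matrix has zero variance: PCA undefined")
  }
  p <- prcomp(M, center = TRUE, scale. = FALSE, rank. = n_components)
  evr <- p$sdev[seq_len(n_components)]^2 / sum(p$sdev^2)
  structure(list(components = unname(p$rotation),
                 projected = unname(p$x),
                 explained_variance_ratio = evr,
                 mean = unname(p$center)),
            class = "pca_projection")
}

#' Farthest point sampling
#'
#' Greedy max-min landmark selection: starting from `start_index`, each
#' successive pick maximizes the minimum Euclidean distance to everything
#' already selected. Deterministic; distance ties break to the lowest index.
#'
#' @param X numeric matrix (rows are points).
#' @param n_select number of landmarks, at most `nrow(X)`.
#' @param start_index row index of the first landmark.
#' @return integer vector of selected row indices, in selection order.
#' @export
farthest_point_sampling <- function(X, n_select, start_index = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n_select < 1 || n_select > n) abort("`n_select` must lie in [1, nrow(X)]")
  sel <- integer(n_select)
  sel[1] <- as.integer(start_index)
  mind <- sqrt(rowSums(sweep(X, 2, X[start_index, ])^2))
  if (n_select > 1) {
    for (i in 2:n_select) {
      nxt <- which.max(mind)  # first max = lowest index on ties
      sel[i] <- nxt
      d <- sqrt(rowSums(sweep(X, 2, X[nxt, ])^2))
      mind <- pmin(mind, d)
    }
  }
  sel
}

#' Persist / load a descriptor matrix as CSV with a JSON metadata sidecar
#'
#' The dense matrix goes to `<path>` as headerless CSV (one frame per row);
#' channel metadata and the normalization flag go to `<path>.meta.json`.
#'
#' @param X a `descriptor_matrix`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_descriptors <- function(X, path) {
  stopifnot(inherits(X, "descriptor_matrix"))
  utils::write.table(X$values, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(
    list(normalized = X$normalized, feature_meta = X$feature_meta),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_descriptors
#' @export
read_descriptors <- function(path) {
  values <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(values) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  structure(list(values = values,
                 feature_meta = tibble::as_tibble(meta$feature_meta),
                 normalized = meta$normalized),
            class = "descriptor_matrix")
}
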