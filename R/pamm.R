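#' Build a farthest-point-sampled density grid
#'
#' Selects `n_grid` landmark frames by farthest point sampling in the
#' projected descriptor space and assigns every frame to its nearest
#' landmark (Voronoi cells). Voronoi weights are the fraction of frames in
#' each cell.
#'
#' @param X numeric matrix of projected descriptors (frames x d).
#' @param n_grid number of grid points (default `min(1000, n)`).
#' @param start_index first FPS landmark.
#' @return an object of class `pamm_model` (grid only; densities added by
#'   [estimate_density()]).
#' @export
build_grid <- function(X, n_grid = min(1000L, nrow(X)), start_index = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n_grid > n) abort("`n_grid` cannot exceed the number of frames")
  gi <- farthest_point_sampling(X, n_grid, start_index)
  G <- X[gi, , drop = FALSE]
  voronoi <- nearest_rows(X, G)
  w <- tabulate(voronoi$nearest, nbins = n_grid) / n
  structure(list(X = X, grid_indices = gi, grid_points = G,
                 voronoi = voronoi$nearest, voronoi_second = voronoi$second,
                 voronoi_weights = w, n_frames = n, d = ncol(X)),
            class = "pamm_model")
}

# Nearest and second-nearest rows of G for every row of X.
nearest_rows <- function(X, G) {
  d2 <- outer(rowSums(X^2), rep(1, nrow(G))) - 2 * X %*% t(G) +
    outer(rep(1, nrow(X)), rowSums(G^2))
  nearest <- max.col(-d2, ties.method = "first")
  if (nrow(G) > 1) {
    d2[cbind(seq_len(nrow(X)), nearest)] <- Inf
    second <- max.col(-d2, ties.method = "first")
  } else {
    second <- nearest
  }
  list(nearest = nearest, second = second)
}

#' Estimate the kernel density on the grid
#'
#' Per-grid-point Gaussian kernel density over all frames. The bandwidth at
#' grid point i follows a localized Silverman rule: the spread of the
#' nearest fraction `f_points` of frames (never fewer than d + 1), scaled by
#' `(4 / ((d + 2) n_loc))^(1 / (d + 4))`. Each frame contributes with the
#' bandwidth of its own Voronoi grid point. Two fields are stored:
#' `density`, the continuous KDE estimate, and `prob`, the Voronoi-mass
#' normalized discrete probability (sums to 1).
#'
#' @param model a `pamm_model` from [build_grid()].
#' @param f_points fraction of frames defining each local neighborhood.
#' @param bandwidth `"silverman"` (localized Silverman rule, the fine-probe
#'   default) or `"localization"` (kernel width equal to the localization
#'   spread itself, a smoother estimate suited to mode counting at moderate
#'   sample sizes).
#' @return the model with `bandwidths`, `density`, `prob` and `f_points`
#'   fields added.
#' @export
estimate_density <- function(model, f_points = 0.008,
                             bandwidth = c("silverman", "localization")) {
  bandwidth <- match.arg(bandwidth)
  stopifnot(inherits(model, "pamm_model"))
  X <- model$X; G <- model$grid_points
  n <- model$n_frames; d <- model$d
  n_loc <- ceiling(f_points * n)
  if (n_loc < d + 1) {
    warn(sprintf("f_points = %g gives %d local samples < d + 1 = %d: floor applied",
                 f_points, n_loc, d + 1))
    n_loc <- d + 1L
  }
  d2 <- outer(rowSums(G^2), rep(1, n)) - 2 * G %*% t(X) +
    outer(rep(1, nrow(G)), rowSums(X^2))
  d2[d2 < 0] <- 0
  bw <- numeric(nrow(G))
  loc_scale <- numeric(nrow(G))
  for (i in seq_len(nrow(G))) {
    loc <- order(d2[i, ])[seq_len(n_loc)]
    sigma2 <- mean(apply(X[loc, , drop = FALSE], 2, var))
    sigma2 <- max(sigma2, 1e-12)
    loc_scale[i] <- sqrt(sigma2)
    bw[i] <- if (bandwidth == "silverman") {
      sqrt(sigma2) * (4 / ((d + 2) * n_loc))^(1 / (d + 4))
    } else {
      sqrt(sigma2)
    }
  }
  # KDE at grid points: each frame smeared with its Voronoi point's bandwidth
  lam <- bw[model$voronoi]
  dens <- numeric(nrow(G))
  log_norm <- -0.5 * d * log(2 * pi)
  for (i in seq_len(nrow(G))) {
    dens[i] <- sum(exp(log_norm - d * log(lam) - 0.5 * d2[i, ] / lam^2)) / n
  }
  model$bandwidths <- bw
  model$loc_scale <- loc_scale
  model$density <- dens
  mass <- dens * model$voronoi_weights
  model$prob <- mass / sum(mass)
  model$f_points <- f_points
  model
}

#' Quick-shift mode seeking on the density grid
#'
#' Links every grid point to its nearest grid point of strictly higher
#' density within distance `alpha * bandwidth_i`; unlinked points are modes.
#' Clusters are the trees rooted at modes. Deterministic; ties break to the
#' lowest grid index.
#'
#' @param model a `pamm_model` with densities estimated.
#' @param alpha quick-shift cutoff scaling (> 0).
#' @return the model with `mode_of` (parent pointers, 0 for modes) and
#'   `cluster_of_grid` (1-based labels in order of mode grid index) added.
#' @export
quickshift <- function(model, alpha = 0.9) {
  stopifnot(inherits(model, "pamm_model"), !is.null(model$density))
  if (alpha <= 0) abort("`alpha` must be > 0")
  G <- model$grid_points
  ng <- nrow(G)
  dg <- as.matrix(stats::dist(G))
  parent <- integer(ng)
  # cutoff scale: the localization spread of the density estimate (the
  # pre-Silverman local bandwidth scale), which tracks the size of the
  # neighborhood the density at i was estimated from
  lambda <- model$loc_scale
  for (i in seq_len(ng)) {
    higher <- which(model$density > model$density[i] & dg[i, ] <= alpha * lambda[i])
    if (length(higher) > 0) {
      parent[i] <- higher[which.min(dg[i, higher])]
    }
  }
  # resolve roots (forest guaranteed: links strictly increase density)
  root <- seq_len(ng)
  for (i in seq_len(ng)) {
    r <- i
    while (parent[r] != 0L) r <- parent[r]
    root[i] <- r
  }
  modes <- sort(unique(root))
  model$mode_of <- parent
  model$alpha <- alpha
  model$cluster_of_grid <- match(root, modes)
  model$modes <- modes
  model
}

#' Assign frames to clusters, compute canonical weights and representatives
#'
#' Each frame takes the cluster of its nearest grid point. The canonical
#' weight of a cluster is its share of all frames; the representative is the
#' lowest-energy frame of the cluster (ties to the lowest frame index).
#'
#' @param model a `pamm_model` after [quickshift()].
#' @param ensemble the [conformer_ensemble] the model was built from.
#' @return an object of class `cluster_set`: `labels`, `weights`,
#'   `representative`, `n_clusters`.
#' @export
assign_and_weigh <- function(model, ensemble) {
  stopifnot(inherits(model, "pamm_model"), !is.null(model$cluster_of_grid))
  labels <- model$cluster_of_grid[model$voronoi]
  k <- max(model$cluster_of_grid)
  counts <- tabulate(labels, nbins = k)
  if (any(counts == 0)) {
    warn(sprintf("%d empty cluster(s) dropped after frame assignment", sum(counts == 0)))
    keep <- which(counts > 0)
    labels <- match(labels, keep)
    counts <- counts[keep]
    k <- length(keep)
  }
  weights <- counts / sum(counts)
  representative <- vapply(seq_len(k), function(c) {
    members <- which(labels == c)
    members[which.min(ensemble$energy[members])]
  }, integer(1))
  structure(list(labels = labels, weights = weights,
                 representative = representative, n_clusters = k),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d clusters over %d frames\n",
              x$n_clusters, length(x$labels)))
  print(tidy.cluster_set(x))
  invisible(x)
}

#' Tabulate a cluster set
#'
#' @param x a `cluster_set`.
#' @param ... unused.
#' @return a tibble with columns cluster, weight, n_frames, representative.
#' @export
tidy.cluster_set <- function(x, ...) {
  tibble::tibble(cluster = seq_len(x$n_clusters),
                 weight = x$weights,
                 n_frames = as.integer(round(x$weights * length(x$labels))),
                 representative = x$representative)
}

#' One-line cluster-set summary
#'
#' @param x a `cluster_set`.
#' @param ... unused.
#' @export
glance.cluster_set <- function(x, ...) {
  tibble::tibble(n_clusters = x$n_clusters,
                 n_frames = length(x$labels),
                 max_weight = max(x$weights),
                 min_weight = min(x$weights))
}

#' Run the full PAMM clustering on a projected descriptor matrix
#'
#' Convenience wrapper: [build_grid()], [estimate_density()], [quickshift()],
#' [assign_and_weigh()].
#'
#' @param X projected descriptor matrix (frames x d).
#' @param ensemble the matching [conformer_ensemble].
#' @param n_grid,start_index grid construction parameters.
#' @param f_points localized-Silverman density fraction.
#' @param alpha quick-shift cutoff scaling.
#' @param bandwidth bandwidth rule, see [estimate_density()].
#' @return list with elements `model` (`pamm_model`) and `clusters`
#'   (`cluster_set`).
#' @export
pamm <- function(X, ensemble, n_grid = min(1000L, nrow(X)), start_index = 1,
                 f_points = 0.008, alpha = 0.9,
                 bandwidth = c("silverman", "localization")) {
  model <- build_grid(X, n_grid, start_index)
  model <- estimate_density(model, f_points, bandwidth)
  model <- quickshift(model, alpha)
  clusters <- assign_and_weigh(model, ensemble)
  list(model = model, clusters = clusters)
}

# Cluster adjacency from the grid: two clusters are adjacent if some frame's
# nearest and second-nearest grid points fall in the two clusters (a shared
# Voronoi boundary).
cluster_adjacency <- function(clusters, model) {
  # cluster label of each grid point after any empty-cluster drops: grid
  # point g is frame model$grid_indices[g]
  grid_label <- clusters$labels[model$grid_indices]
  a <- grid_label[model$voronoi]
  b <- grid_label[model$voronoi_second]
  keep <- !is.na(a) & !is.na(b) & a != b
  adj <- matrix(FALSE, clusters$n_clusters, clusters$n_clusters)
  if (any(keep)) {
    idx <- unique(cbind(pmin(a[keep], b[keep]), pmax(a[keep], b[keep])))
    adj[idx] <- TRUE
    adj[idx[, c(2, 1), drop = FALSE]] <- TRUE
  }
  adj
}

#' Hierarchical merging of clusters by adjacency-restricted Ward linkage
#'
#' Agglomerates cluster centroids in the projected descriptor space under
#' Ward's criterion, allowing only merges of clusters that share a Voronoi
#' boundary on the density grid. Merged weights are the sums of the
#' children's; the merged representative is the lowest-energy representative
#' over the union. If the adjacency graph is disconnected the merge falls
#' back to unrestricted Ward with a warning.
#'
#' @param clusters a `cluster_set`.
#' @param model the `pamm_model` behind it.
#' @param ensemble the matching [conformer_ensemble] (for representative
#'   energies).
#' @return an object of class `merge_tree`: tibble `merges` (step, a, b,
#'   height; node ids K+step for merged nodes) and `levels`, a list from K
#'   clusters down to 1, each a list of clusters with members, weight,
#'   representative frame and leaf.
#' @export
merge_hierarchy <- function(clusters, model, ensemble) {
  k <- clusters$n_clusters
  if (k < 2) abort("need at least 2 clusters to merge")
  X <- model$X
  adj <- cluster_adjacency(clusters, model)
  # active node bookkeeping
  nodes <- lapply(seq_len(k), function(c) {
    members <- which(clusters$labels == c)
    list(id = c, leaves = c, size = length(members),
         centroid = colMeans(X[members, , drop = FALSE]),
         weight = clusters$weights[c],
         rep_frame = clusters$representative[c],
         rep_leaf = c)
  })
  active <- seq_len(k)
  adj_ids <- lapply(seq_len(k), function(c) which(adj[c, ]))
  restricted <- TRUE
  if (!graph_connected(adj)) {
    warn("cluster adjacency graph is disconnected: falling back to unrestricted Ward")
    restricted <- FALSE
  }
  merges <- tibble::tibble(step = integer(), a = integer(), b = integer(),
                           height = numeric())
  levels <- list()
  levels[[1]] <- nodes
  next_id <- k
  last_h <- 0
  node_by_id <- nodes
  names(node_by_id) <- as.character(seq_len(k))
  for (step in seq_len(k - 1)) {
    best <- NULL; best_d <- Inf
    act <- sort(active)
    for (ii in seq_along(act)) {
      for (jj in seq_along(act)) {
        if (jj <= ii) next
        na <- node_by_id[[as.character(act[ii])]]
        nb <- node_by_id[[as.character(act[jj])]]
        if (restricted && !nodes_adjacent(na, nb, adj)) next
        dd <- ward_distance(na, nb)
        if (dd < best_d - 1e-15) { best_d <- dd; best <- c(act[ii], act[jj]) }
      }
    }
    if (is.null(best)) {
      warn("no adjacent pair available: completing merge without adjacency restriction")
      restricted <- FALSE
      for (ii in seq_along(act)) for (jj in seq_along(act)) {
        if (jj <= ii) next
        na <- node_by_id[[as.character(act[ii])]]
        nb <- node_by_id[[as.character(act[jj])]]
        dd <- ward_distance(na, nb)
        if (dd < best_d - 1e-15) { best_d <- dd; best <- c(act[ii], act[jj]) }
      }
    }
    na <- node_by_id[[as.character(best[1])]]
    nb <- node_by_id[[as.character(best[2])]]
    next_id <- next_id + 1L
    h <- max(best_d, last_h); last_h <- h
    merged <- list(
      id = next_id,
      leaves = sort(c(na$leaves, nb$leaves)),
      size = na$size + nb$size,
      centroid = (na$size * na$centroid + nb$size * nb$centroid) / (na$size + nb$size),
      weight = na$weight + nb$weight,
      rep_frame = if (ensemble$energy[na$rep_frame] <= ensemble$energy[nb$rep_frame])
        na$rep_frame else nb$rep_frame,
      rep_leaf = if (ensemble$energy[na$rep_frame] <= ensemble$energy[nb$rep_frame])
        na$rep_leaf else nb$rep_leaf
    )
    node_by_id[[as.character(next_id)]] <- merged
    active <- c(setdiff(active, best), next_id)
    merges <- dplyr::bind_rows(merges, tibble::tibble(
      step = step, a = best[1], b = best[2], height = h))
    levels[[step + 1]] <- lapply(sort(active), function(id) node_by_id[[as.character(id)]])
  }
  lv <- lapply(levels, function(level) {
    list(clusters = lapply(level, function(nd) {
      list(members = nd$leaves, weight = nd$weight,
           representative_frame = nd$rep_frame,
           representative_leaf = nd$rep_leaf)
    }))
  })
  structure(list(merges = merges, levels = lv, n_leaves = k),
            class = "merge_tree")
}

ward_distance <- function(a, b) {
  a$size * b$size / (a$size + b$size) * sum((a$centroid - b$centroid)^2)
}

nodes_adjacent <- function(a, b, adj) {
  any(adj[a$leaves, b$leaves, drop = FALSE])
}

graph_connected <- function(adj) {
  k <- nrow(adj)
  if (k <= 1) return(TRUE)
  seen <- logical(k); queue <- 1L; seen[1] <- TRUE
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    nb <- which(adj[v, ] & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

#' @export
print.merge_tree <- function(x, ...) {
  cat(sprintf("<merge_tree> %d leaf clusters, %d merges\n",
              x$n_leaves, nrow(x$merges)))
  print(x$merges)
  invisible(x)
}

#' Export a merge tree in Newick format
#'
#' @param tree a `merge_tree`.
#' @param path optional file path; if `NULL` the string is returned.
#' @return the Newick string, invisibly if written to file.
#' @export
write_newick <- function(tree, path = NULL) {
  k <- tree$n_leaves
  lab <- as.list(as.character(seq_len(k)))
  h <- c(rep(0, k), tree$merges$height)
  for (i in seq_len(nrow(tree$merges))) {
    a <- tree$merges$a[i]; b <- tree$merges$b[i]
    id <- k + i
    bl_a <- tree$merges$height[i] - h[a]
    bl_b <- tree$merges$height[i] - h[b]
    lab[[id]] <- sprintf("(%s:%.6g,%s:%.6g)", lab[[a]], bl_a, lab[[b]], bl_b)
  }
  nwk <- paste0(lab[[k + nrow(tree$merges)]], ";")
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(nwk)
}
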