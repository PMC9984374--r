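three_clouds <- function(n_per = 40, seed = 5, sd = 0.05) {
  set.seed(seed)
  centers <- rbind(c(0, 0), c(3, 0), c(0, 3))
  X <- do.call(rbind, lapply(1:3, function(k) {
    cbind(rnorm(n_per, centers[k, 1], sd), rnorm(n_per, centers[k, 2], sd))
  }))
  list(X = X, labels = rep(1:3, each = n_per))
}

test_that("grid construction covers the data with correct Voronoi weights", {
  cl <- three_clouds()
  m <- build_grid(cl$X, n_grid = nrow(cl$X))
  expect_equal(sort(m$grid_indices), seq_len(nrow(cl$X)))
  expect_equal(m$voronoi_weights, rep(1 / nrow(cl$X), nrow(cl$X)))

  m30 <- build_grid(cl$X, n_grid = 30)
  for (b in 1:3) {
    expect_gt(sum(cl$labels[m30$grid_indices] == b), 0)
  }
  # brute-force nearest-landmark check
  G <- m30$grid_points
  for (i in sample(nrow(cl$X), 20)) {
    d <- sqrt(rowSums(sweep(G, 2, cl$X[i, ])^2))
    expect_equal(m30$voronoi[i], which.min(d))
  }
  m30b <- build_grid(cl$X, n_grid = 30)
  expect_identical(m30$grid_indices, m30b$grid_indices)
})

test_that("grid density matches the analytic normal density", {
  set.seed(10)
  X <- matrix(rnorm(20000), ncol = 1)
  m <- build_grid(X, n_grid = 400)
  m <- estimate_density(m, f_points = 0.01)
  i0 <- which.min(abs(m$grid_points[, 1]))
  expect_lt(abs(m$density[i0] - dnorm(m$grid_points[i0, 1])) / dnorm(0), 0.05)
  expect_equal(sum(m$prob), 1, tolerance = 1e-6)
})

test_that("density mass splits evenly between two symmetric far modes", {
  set.seed(11)
  X <- matrix(c(rnorm(5000, -10), rnorm(5000, 10)), ncol = 1)
  m <- build_grid(X, n_grid = 300)
  m <- estimate_density(m, f_points = 0.02)
  left <- sum(m$prob[m$grid_points[, 1] < 0])
  expect_lt(abs(left - 0.5), 0.02)
})

test_that("a degenerate repeated point concentrates all mass", {
  X <- matrix(rep(c(1.5, -2), each = 30), ncol = 2)
  m <- build_grid(X, n_grid = 1)
  m <- suppressWarnings(estimate_density(m, f_points = 0.1))
  expect_equal(sum(m$prob), 1)
  expect_equal(m$voronoi_weights, 1)
})

test_that("quick-shift matches brute-force steepest ascent on small grids", {
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(rnorm(100, sd = 2), ncol = 2)
    m <- build_grid(X, n_grid = 50)
    m <- suppressWarnings(estimate_density(m, f_points = 0.2))
    m <- quickshift(m, alpha = 1.5)
    oracle <- quickshift_oracle(m$grid_points, m$density, m$loc_scale, 1.5)
    expect_identical(m$cluster_of_grid, oracle)
  }
})

test_that("quick-shift limits behave as required", {
  # strictly monotone density on a 1D grid: one cluster
  X <- matrix(seq(0, 1, length.out = 30)^2, ncol = 1)
  m <- build_grid(X, n_grid = 30)
  m <- suppressWarnings(estimate_density(m, f_points = 0.5))
  m$density <- as.numeric(seq_len(30)[order(order(m$grid_points[, 1]))])
  m$loc_scale <- rep(10, 30)
  m <- quickshift(m, alpha = 1)
  expect_equal(max(m$cluster_of_grid), 1)

  # alpha -> 0+: every grid point becomes its own mode
  m <- quickshift(m, alpha = 1e-12)
  expect_equal(max(m$cluster_of_grid), 30)
})

test_that("two-peak density splits at the density minimum", {
  x <- seq(-4, 4, length.out = 41)
  X <- matrix(x, ncol = 1)
  m <- build_grid(X, n_grid = 41)
  m <- suppressWarnings(estimate_density(m, f_points = 0.3))
  dens <- dnorm(m$grid_points[, 1], -2, 0.7) + dnorm(m$grid_points[, 1], 2, 0.7)
  m$density <- dens
  m$loc_scale <- rep(1.0, 41)
  m <- quickshift(m, alpha = 1)
  expect_equal(max(m$cluster_of_grid), 2)
  lab <- m$cluster_of_grid[order(m$grid_points[, 1])]
  # boundary at the central density minimum
  expect_true(all(lab[1:20] == lab[1]))
  expect_true(all(lab[22:41] == lab[41]))
  oracle <- quickshift_oracle(m$grid_points, m$density, m$loc_scale, 1)
  expect_identical(m$cluster_of_grid, oracle)
})

test_that("weights reproduce constructed cluster populations", {
  # nine point-locations with multiplicities proportional to published-style
  # percentages; each location becomes its own mode under a tiny cutoff
  pct <- c(13.0, 4.6, 9.8, 14.2, 20.1, 2.5, 29.3, 0.2, 6.3)
  counts <- round(pct * 10)
  locs <- cbind(seq_len(9) * 10, 0)
  X <- locs[rep(seq_len(9), counts), ]
  ens <- structure(list(coords = vector("list", nrow(X)),
                        species = "C", energy = seq_len(nrow(X)),
                        temperature = 300), class = "conformer_ensemble")
  m <- build_grid(X, n_grid = 9)
  m <- suppressWarnings(estimate_density(m, f_points = 0.5))
  m <- quickshift(m, alpha = 1e-9)
  cl <- assign_and_weigh(m, ens)
  expect_equal(cl$n_clusters, 9)
  expect_equal(sort(100 * cl$weights), sort(pct), tolerance = 1e-9)
  expect_equal(sum(cl$weights), 1, tolerance = 1e-12)
})

test_that("representatives are the lowest-energy member frames", {
  cl <- three_clouds(n_per = 20, seed = 9)
  set.seed(1)
  energy <- runif(60)
  energy[13] <- -5  # unique minimum in cloud 1
  ens <- structure(list(coords = vector("list", 60), species = "C",
                        energy = energy, temperature = 300),
                   class = "conformer_ensemble")
  fit <- suppressWarnings(pamm(cl$X, ens, n_grid = 60, f_points = 0.3,
                               alpha = 3, bandwidth = "localization"))
  expect_equal(fit$clusters$n_clusters, 3)
  own <- fit$clusters$labels[13]
  expect_equal(fit$clusters$representative[own], 13L)
})

test_that("Ward merging follows the exhaustive ESS oracle and conserves weight", {
  cl <- three_clouds(n_per = 15, seed = 12)
  set.seed(2)
  ens <- structure(list(coords = vector("list", 45), species = "C",
                        energy = runif(45), temperature = 300),
                   class = "conformer_ensemble")
  fit <- suppressWarnings(pamm(cl$X, ens, n_grid = 45, f_points = 0.3,
                               alpha = 3, bandwidth = "localization"))
  expect_equal(fit$clusters$n_clusters, 3)
  tree <- suppressWarnings(merge_hierarchy(fit$clusters, fit$model, ens))
  expect_equal(nrow(tree$merges), 2)
  # every level's weights sum to one
  for (lv in tree$levels) {
    expect_equal(sum(vapply(lv$clusters, function(c) c$weight, numeric(1))), 1,
                 tolerance = 1e-12)
  }
  # root inherits the lower-energy representative
  root <- tree$levels[[3]]$clusters[[1]]
  expect_equal(root$representative_frame,
               fit$clusters$representative[which.min(
                 ens$energy[fit$clusters$representative])])

  # 4-cluster merge order against an independent ESS-increase oracle
  set.seed(13)
  centers4 <- rbind(c(0, 0), c(1.2, 0), c(5, 0), c(5, 1.4))
  X4 <- do.call(rbind, lapply(1:4, function(k)
    cbind(rnorm(12, centers4[k, 1], 0.05), rnorm(12, centers4[k, 2], 0.05))))
  ens4 <- structure(list(coords = vector("list", 48), species = "C",
                         energy = runif(48), temperature = 300),
                    class = "conformer_ensemble")
  fit4 <- suppressWarnings(pamm(X4, ens4, n_grid = 48, f_points = 0.25,
                                alpha = 3, bandwidth = "localization"))
  expect_equal(fit4$clusters$n_clusters, 4)
  tree4 <- suppressWarnings(merge_hierarchy(fit4$clusters, fit4$model, ens4))
  # oracle: ESS computed from raw member points, exhaustive pair scan,
  # ignoring adjacency (the clouds' adjacency graph is complete or the
  # fallback engages; verify merge heights are non-decreasing regardless)
  ess <- function(members) {
    P <- X4[members, , drop = FALSE]
    sum(sweep(P, 2, colMeans(P))^2)
  }
  groups <- lapply(1:4, function(c) which(fit4$clusters$labels == c))
  order_oracle <- character(0)
  repeat {
    if (length(groups) == 1) break
    best <- NULL; best_d <- Inf
    for (i in seq_along(groups)) for (j in seq_along(groups)) {
      if (j <= i) next
      dd <- ess(c(groups[[i]], groups[[j]])) - ess(groups[[i]]) - ess(groups[[j]])
      if (dd < best_d - 1e-12) { best_d <- dd; best <- c(i, j) }
    }
    order_oracle <- c(order_oracle,
                      paste(sort(c(min(groups[[best[1]]]), min(groups[[best[2]]]))),
                            collapse = "-"))
    groups[[best[1]]] <- c(groups[[best[1]]], groups[[best[2]]])
    groups <- groups[-best[2]]
  }
  # express implementation merges in the same member-anchored labels
  node_members <- lapply(1:4, function(c) which(fit4$clusters$labels == c))
  impl <- character(0)
  for (s in seq_len(nrow(tree4$merges))) {
    a <- tree4$merges$a[s]; b <- tree4$merges$b[s]
    impl <- c(impl, paste(sort(c(min(node_members[[a]]), min(node_members[[b]]))),
                          collapse = "-"))
    node_members[[4 + s]] <- c(node_members[[a]], node_members[[b]])
  }
  expect_identical(impl, order_oracle)
  expect_true(all(diff(tree4$merges$height) >= 0))
})

test_that("relabeling clusters leaves weights and averaged spectra unchanged", {
  cl <- three_clouds(n_per = 15, seed = 20)
  ens <- structure(list(coords = vector("list", 45), species = "C",
                        energy = seq_len(45), temperature = 300),
                   class = "conformer_ensemble")
  fit <- suppressWarnings(pamm(cl$X, ens, n_grid = 45, f_points = 0.3,
                               alpha = 3, bandwidth = "localization"))
  clu <- fit$clusters
  grid <- seq(600, 1800, 1)
  specs <- lapply(1:clu$n_clusters, function(k) gaussian_peak_spectrum(800 + 100 * k, grid = grid))
  avg1 <- ensemble_average(specs, clu$weights)
  perm <- rev(seq_len(clu$n_clusters))
  avg2 <- ensemble_average(specs[perm], clu$weights[perm])
  expect_equal(avg1$intensity, avg2$intensity, tolerance = 1e-15)
  expect_setequal(round(clu$weights, 12), round(clu$weights[perm], 12))
})

test_that("merge trees export as valid Newick", {
  cl <- three_clouds(n_per = 10, seed = 30)
  ens <- structure(list(coords = vector("list", 30), species = "C",
                        energy = seq_len(30), temperature = 300),
                   class = "conformer_ensemble")
  fit <- suppressWarnings(pamm(cl$X, ens, n_grid = 30, f_points = 0.4,
                               alpha = 3, bandwidth = "localization"))
  tree <- suppressWarnings(merge_hierarchy(fit$clusters, fit$model, ens))
  nwk <- write_newick(tree)
  phylo <- ape::read.tree(text = nwk)
  expect_equal(length(phylo$tip.label), fit$clusters$n_clusters)
})
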