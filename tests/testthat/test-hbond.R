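test_that("triplet enumeration finds exactly the N-H...O patterns", {
  # alkane-like fragment: no donors or acceptors
  alkane <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(0, 1.1, 0), c(1.5, 1.1, 0))
  expect_equal(nrow(enumerate_triplets(alkane, c("C", "C", "H", "H"))), 0)

  f <- ideal_hbond_frame()
  tr <- enumerate_triplets(f$xyz, f$species)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$d_da, 2.9)
  expect_equal(tr$d_dh, 1.0)
  expect_equal(tr$d_ah, 1.9)
})

test_that("triplet enumeration agrees with a cubic brute-force oracle", {
  gen <- tiny_ensemble(1, seed = 33)
  xyz <- gen$ensemble$coords[[1]]
  species <- gen$ensemble$species
  tr <- enumerate_triplets(xyz, species)
  # O(n^3) oracle: loop every (donor, hydrogen, acceptor) triple
  oracle <- list()
  for (dn in seq_along(species)) for (h in seq_along(species)) for (a in seq_along(species)) {
    if (species[dn] != "N" || species[h] != "H" || species[a] != "O") next
    d_dh <- sqrt(sum((xyz[dn, ] - xyz[h, ])^2))
    d_da <- sqrt(sum((xyz[dn, ] - xyz[a, ])^2))
    if (d_dh < 1.3 && d_da <= 4.5) {
      oracle[[length(oracle) + 1]] <- c(dn, h, a)
    }
  }
  om <- do.call(rbind, oracle)
  expect_equal(nrow(tr), nrow(om))
  expect_setequal(paste(tr$donor, tr$hydrogen, tr$acceptor),
                  paste(om[, 1], om[, 2], om[, 3]))
})

test_that("membership honors its limits and the mixture-posterior formula", {
  m <- hbond_model()
  ref <- tibble::tibble(d_dh = 1.0, d_ah = 1.9, d_da = 2.9)
  expect_gte(membership(m, ref), 0.99)

  far <- tibble::tibble(d_dh = 1.0, d_ah = 9.0, d_da = 10)
  expect_lte(membership(m, far), 1e-6)

  mid <- tibble::tibble(d_dh = 1.0, d_ah = 2.4, d_da = 3.3)
  # direct posterior evaluation
  x <- c(1.0 - 2.4, 1.0 + 2.4, 3.3)
  fb <- prod(dnorm(x, m$bonded_mean, m$bonded_sd))
  fg <- prod(dnorm(x, m$background_mean, m$background_sd))
  expect_equal(membership(m, mid), 0.5 * fb / (0.5 * fb + 0.5 * fg),
               tolerance = 1e-12)
})

test_that("membership decays monotonically with donor-acceptor distance", {
  m <- hbond_model()
  dda <- seq(2.9, 8, 0.1)
  vals <- membership(m, tibble::tibble(d_dh = 1.0, d_ah = dda - 1.0, d_da = dda))
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("counting sums memberships per tagged atom", {
  # ammonium-like donor with two ideal acceptors on opposite sides
  xyz <- rbind(c(0, 0, 0),          # N
               c(1, 0, 0), c(-1, 0, 0),  # two H
               c(2.9, 0, 0), c(-2.9, 0, 0))  # two O
  ens <- frame_ensemble(xyz, c("N", "H", "H", "O", "O"))
  counts <- count_hbonds(ens)
  sd_n <- counts$value[counts$role == "donor" & counts$atom == 1]
  expect_equal(sd_n, 2.0, tolerance = 0.02)

  # no triplets -> empty result
  ens0 <- frame_ensemble(rbind(c(0, 0, 0), c(1.5, 0, 0)), c("C", "C"))
  expect_equal(nrow(count_hbonds(ens0)), 0)

  # random frame matches a brute-force membership sum
  gen <- tiny_ensemble(1, seed = 44)
  counts <- count_hbonds(gen$ensemble, frames = 1)
  tr <- enumerate_triplets(gen$ensemble$coords[[1]], gen$ensemble$species)
  tr$m <- membership(hbond_model(), tr)
  for (dn in unique(tr$donor)) {
    expected <- sum(tr$m[tr$donor == dn])
    got <- counts$value[counts$role == "donor" & counts$atom == dn]
    if (expected >= 0.01) expect_equal(got, expected, tolerance = 1e-12)
  }
})

test_that("probability surfaces are normalized and give exact free-energy ratios", {
  # uniform two-state distribution: no free-energy difference
  s <- hbond_surface(c(rep(1.0, 50), rep(2.0, 50)), temperature = 300)
  expect_equal(sum(s$P), 1, tolerance = 1e-9)
  cells <- integrate_cells(s)$cells
  p1 <- cells$pct[cells$s == 1] / 100
  p2 <- cells$pct[cells$s == 2] / 100
  expect_equal(p1, p2, tolerance = 1e-12)

  # 2:1 ratio at 300 K: Delta F = k_B T ln 2
  s <- hbond_surface(c(rep(1.0, 200), rep(2.0, 100)), temperature = 300)
  cells <- integrate_cells(s)$cells
  p1 <- cells$pct[cells$s == 1] / 100
  p2 <- cells$pct[cells$s == 2] / 100
  dF <- -0.0019872 * 300 * log(p2 / p1)
  expect_equal(dF, 0.413, tolerance = 0.005)

  expect_error(hbond_surface(c(1, 2), temperature = -5), "temperature")
})

test_that("smoothing conserves probability mass and scale invariance of F", {
  set.seed(2)
  x <- runif(500, 0, 3)
  s <- hbond_surface(x)
  expect_equal(sum(s$P), 1, tolerance = 1e-9)
  # replicating every sample (count scaling) leaves P and F unchanged
  s3 <- hbond_surface(rep(x, 3))
  expect_equal(s3$P, s$P, tolerance = 1e-12)
  expect_equal(s3$F, s$F, tolerance = 1e-9)
})

test_that("integer-cell integration reports the most probable tuple", {
  pts <- matrix(rep(c(1.0, 2.0), 40), ncol = 2, byrow = TRUE)
  s <- hbond_surface(pts)
  ic <- integrate_cells(s)
  expect_equal(ic$most_probable$s_A, 1)
  expect_equal(ic$most_probable$s_D, 2)
  expect_equal(ic$most_probable$pct, 100, tolerance = 1e-9)
  expect_equal(sum(ic$cells$pct), 100, tolerance = 1e-6)

  # constructed mixture with 42% of mass in the (1,2) cell
  set.seed(6)
  n <- 5000
  n12 <- round(0.42 * n)
  in12 <- cbind(runif(n12, 0.8, 1.2), runif(n12, 1.8, 2.2))
  # remaining mass split over three other cells, each below 42%
  n_r <- n - n12
  third <- n_r %/% 3
  rest <- rbind(
    cbind(runif(third, 2.6, 2.9), runif(third, 0.1, 0.4)),
    cbind(runif(third, 0.1, 0.4), runif(third, 0.6, 0.9)),
    cbind(runif(n_r - 2 * third, 1.6, 1.9), runif(n_r - 2 * third, 2.6, 2.9)))
  s <- hbond_surface(rbind(in12, rest))
  ic <- integrate_cells(s)
  expect_equal(ic$most_probable$s_A, 1)
  expect_equal(ic$most_probable$s_D, 2)
  expect_equal(ic$most_probable$pct, 42, tolerance = 0.5)
})

test_that("per-cluster summaries average frame-first with population sd", {
  counts <- tibble::tibble(frame = c(1, 2), atom = c(1, 1),
                           role = "donor", value = c(1.0, 2.0))
  cl <- structure(list(labels = c(1L, 1L), weights = 1, representative = 1L,
                       n_clusters = 1L), class = "cluster_set")
  out <- per_cluster_summary(counts, cl)
  expect_equal(out$mean_sD, 1.5)
  expect_equal(out$sd_sD, 0.5)
  expect_equal(names(out), c("cluster", "mean_sA", "sd_sA", "mean_sD", "sd_sD",
                             "mp_tuple", "mp_pct", "weight_pct"))

  one <- per_cluster_summary(
    tibble::tibble(frame = 1, atom = 1, role = "donor", value = 1.0),
    structure(list(labels = 1L, weights = 1, representative = 1L,
                   n_clusters = 1L), class = "cluster_set"))
  expect_equal(one$mean_sD, 1.0)
  expect_equal(one$sd_sD, 0)
  # no acceptor records: fields absent, not zero
  expect_true(is.na(one$mean_sA))
})

test_that("prescribed basin occupancies are recovered by per-cluster means", {
  # basin A: one ideal H bond; basin B: two ideal H bonds
  one_hb <- rbind(c(0, 0, 0), c(1, 0, 0), c(2.9, 0, 0), c(0, 8, 0))
  sp1 <- c("N", "H", "O", "O")
  # basin B has a second covalent H so two ideal bonds can donate
  two_hb <- rbind(c(0, 0, 0), c(1, 0, 0), c(2.9, 0, 0), c(-2.9, 0, 0), c(-1, 0, 0))
  sp2 <- c("N", "H", "O", "O", "H")
  ens1 <- conformer_ensemble(replicate(5, one_hb, simplify = FALSE), sp1, rep(0, 5))
  ens2 <- conformer_ensemble(replicate(5, two_hb, simplify = FALSE), sp2, rep(0, 5))
  c1 <- count_hbonds(ens1)
  c2 <- count_hbonds(ens2)
  m1 <- mean(c1$value[c1$role == "donor"])
  m2 <- mean(c2$value[c2$role == "donor"])
  expect_lt(abs(m1 - 1), 0.1)
  expect_lt(abs(m2 - 2), 0.1)
})

test_that("probability surfaces tabulate tidily in 1D and 2D", {
  s1 <- hbond_surface(c(1, 1, 2))
  td1 <- tidy(s1)
  expect_equal(sum(td1$P), 1, tolerance = 1e-12)
  expect_true(all(is.na(td1$F) | td1$F >= min(td1$F, na.rm = TRUE)))
  s2 <- hbond_surface(cbind(c(1, 2), c(2, 1)))
  td2 <- tidy(s2)
  expect_equal(names(td2), c("s_A", "s_D", "P", "F"))
  expect_equal(sum(td2$P), 1, tolerance = 1e-12)
})
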