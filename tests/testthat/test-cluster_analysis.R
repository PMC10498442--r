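test_that("alignment recovers rigid motion exactly", {
  tb <- two_basin_trajectory(2, seed = 5)
  base <- tb$trajectory$frames[1, , ]
  n <- nrow(base)
  R <- random_rotation_matrix(3)
  moved <- base %*% t(R) + matrix(c(3, -2, 7), n, 3, byrow = TRUE)
  fr <- array(0, c(2, n, 3))
  fr[1, , ] <- base; fr[2, , ] <- moved
  t2 <- trajectory(tb$trajectory$topology, fr)
  al <- align_trajectory(t2, 1, seq_len(n))
  # frame aligned to itself is untouched
  expect_equal(al$frames[1, , ], base, tolerance = 1e-10)
  rms <- sqrt(mean(rowSums((al$frames[2, , ] - base)^2)))
  expect_lt(rms, 1e-8)
})

test_that("single displaced atom yields the closed-form RMSD d/sqrt(n)", {
  coords <- matrix(rnorm(30), 10, 3)
  s <- xyz_structure(rep("C", 10), coords)
  fr <- array(0, c(2, 10, 3))
  fr[1, , ] <- coords
  coords2 <- coords
  coords2[10, ] <- coords2[10, ] + c(1, 0, 0)
  fr[2, , ] <- coords2
  t <- trajectory(s, fr)
  d <- rmsd_matrix(t, mask = 1:10)  # no alignment: direct displacement
  expect_equal(d[1, 2], 1 / sqrt(10), tolerance = 1e-10)
})

test_that("rmsd_matrix equals the brute-force double loop and is invariant
           under consistent atom relabeling", {
  tb <- two_basin_trajectory(3, seed = 9)
  t <- tb$trajectory
  d <- rmsd_matrix(t)
  heavy <- which(t$topology$elements != "H")
  f <- n_frames(t)
  oracle <- matrix(0, f, f)
  for (a in seq_len(f)) for (b in seq_len(f)) {
    diff <- t$frames[a, heavy, ] - t$frames[b, heavy, ]
    oracle[a, b] <- sqrt(mean(rowSums(diff^2)))
  }
  expect_equal(d, oracle, tolerance = 1e-12)
  expect_true(all(d == t(d)))
  expect_true(all(diag(d) == 0))

  set.seed(11)
  perm <- sample(n_atoms(t$topology))
  t2 <- trajectory(xyz_structure(t$topology$elements[perm],
                                 matrix(t$frames[1, perm, ], ncol = 3)),
                   t$frames[, perm, , drop = FALSE])
  expect_equal(rmsd_matrix(t2), d, tolerance = 1e-12)

  expect_error(rmsd_matrix(t, mask = integer(0)), "empty")
})

test_that("identical frames give a zero RMSD matrix", {
  tb <- two_basin_trajectory(2, noise_sigma = 0, seed = 1)
  t <- tb$trajectory
  t$frames[2, , ] <- t$frames[1, , ]
  expect_true(all(rmsd_matrix(t)[1:2, 1:2] == 0))
})

test_that("Kabsch superposition beats random rigid perturbations", {
  tb <- two_basin_trajectory(2, seed = 21)
  t <- tb$trajectory
  al <- align_trajectory(t, 1, 1:8)
  sel <- 1:8
  ref <- t$frames[1, sel, ]
  rmsd_of <- function(x) sqrt(mean(rowSums((x - ref)^2)))
  best <- rmsd_of(al$frames[3, sel, ])
  set.seed(2)
  for (rep in 1:100) {
    R <- random_rotation_matrix(sample.int(1e6, 1))
    shift <- rnorm(3, 0, 0.5)
    cand <- sweep(t$frames[3, sel, ] %*% t(R), 2, shift, "+")
    expect_gte(rmsd_of(cand), best - 1e-10)
  }
})

test_that("collinear or tiny alignment selections error", {
  tb <- two_basin_trajectory(2, seed = 5)
  expect_error(align_trajectory(tb$trajectory, 1, c(1, 2)), "at least 3")
  lin <- xyz_structure(rep("C", 3),
                       rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)))
  fr <- array(rep(lin$coords, each = 2), c(2, 3, 3))
  fr[1, , ] <- lin$coords; fr[2, , ] <- lin$coords
  expect_error(align_trajectory(trajectory(lin, fr), 1, 1:3), "collinear")
})

test_that("all four methods resolve the two-basin fixture", {
  tb <- two_basin_trajectory(50, displacement = 3, noise_sigma = 0.1,
                             seed = 2023)
  t <- align_trajectory(tb$trajectory, 1, 1:8)
  d <- rmsd_matrix(t)
  for (m in c("kmeans", "hierarchical", "dpeaks")) {
    cl <- cluster_frames(d, m, k = 2, seed = 2023)
    expect_equal(adjusted_rand(cl$labels, tb$labels), 1.0, tolerance = 1e-12)
  }
  intra <- max(d[tb$labels == 1, tb$labels == 1])
  inter <- min(d[tb$labels == 1, tb$labels == 2])
  cl <- cluster_frames(d, "dbscan", eps = (intra + inter) / 2)
  expect_length(cl$representatives, 2)
  expect_equal(adjusted_rand(cl$labels, tb$labels), 1.0, tolerance = 1e-12)

  skip_if_not_installed("mclust")
  cl2 <- cluster_frames(d, "kmeans", k = 2, seed = 2023)
  expect_equal(mclust::adjustedRandIndex(cl2$labels, tb$labels), 1.0)
})

test_that("clustering edge cases behave", {
  tb <- two_basin_trajectory(3, seed = 13)
  d <- rmsd_matrix(tb$trajectory)
  f <- nrow(d)
  cl <- cluster_frames(d, "kmeans", k = f, seed = 1)
  expect_equal(sort(cl$labels), seq_len(f))  # every frame its own cluster
  expect_error(cluster_frames(d, "kmeans", k = f + 1), "exceeds")
  expect_error(cluster_frames(d, "dbscan", eps = 1e-9), "larger eps")
})

test_that("representatives are medoids and the k-medoids objective descends", {
  tb <- two_basin_trajectory(8, seed = 31)
  d <- rmsd_matrix(tb$trajectory)
  cl <- cluster_frames(d, "kmeans", k = 3, seed = 7)
  for (c_ in seq_along(cl$representatives)) {
    mem <- which(cl$labels == c_)
    sums <- rowSums(d[mem, mem, drop = FALSE])
    expect_equal(cl$representatives[c_], mem[which.min(sums)])
    expect_equal(cl$labels[cl$representatives[c_]], c_)
  }
  tr <- cl$objective_trace
  expect_true(all(diff(tr) <= 1e-12))

  skip_if_not_installed("cluster")
  # PAM as independent oracle on a clearly separated instance
  tb2 <- two_basin_trajectory(10, seed = 41)
  d2 <- rmsd_matrix(align_trajectory(tb2$trajectory, 1, 1:8))
  cl2 <- cluster_frames(d2, "kmeans", k = 2, seed = 7)
  pam <- cluster::pam(stats::as.dist(d2), k = 2)
  expect_equal(adjusted_rand(cl2$labels, pam$clustering), 1.0)
})

test_that("ranking sorts by energy with population tie-breaks", {
  tb <- two_basin_trajectory(10, seed = 3)
  d <- rmsd_matrix(tb$trajectory)
  cl <- cluster_frames(d, "kmeans", k = 3, seed = 1)
  r <- rank_clusters(cl, c(3.0, 1.0, 2.0))
  expect_equal(r$ranking, c(2L, 3L, 1L))
  expect_equal(r$rel_energies, c(2.0, 0.0, 1.0))
  expect_equal(min(r$rel_energies), 0)

  # tie on energy: larger population first
  sizes <- cl$sizes
  e <- c(1, 1, 5)
  r2 <- rank_clusters(cl, e)
  first_two <- r2$ranking[1:2]
  expect_equal(first_two[1], first_two[order(-sizes[first_two])][1])

  cl1 <- cluster_frames(d, "kmeans", k = 1, seed = 1)
  expect_equal(rank_clusters(cl1, 5)$ranking, 1L)
  expect_error(rank_clusters(cl, c(1, 2)), "one energy per cluster")
})

test_that("trajectory xyz round trip and report writing work", {
  tb <- two_basin_trajectory(3, seed = 17)
  t2 <- read_xyz_traj(write_xyz_traj(tb$trajectory))
  expect_identical(t2$topology$elements, tb$trajectory$topology$elements)
  expect_equal(t2$frames, tb$trajectory$frames, tolerance = 1e-6)

  d <- rmsd_matrix(tb$trajectory)
  cl <- rank_clusters(cluster_frames(d, "kmeans", k = 2, seed = 1),
                      c(2.5, 0.5))
  dir <- withr::local_tempdir()
  path <- write_cluster_report(tb$trajectory, cl, dir)
  expect_true(file.exists(path))
  tab <- utils::read.delim(path)
  expect_equal(tab$cluster, cl$ranking)
  expect_equal(tab$rel_energy[1], 0)
  expect_true(all(file.exists(file.path(dir, c("cluster_01.xyz",
                                               "cluster_02.xyz")))))

  en <- read_energy_table("# cluster energy\n1 -12.5\n2 -14.0")
  expect_equal(en$energy, c(-12.5, -14.0))
})
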