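#' Harmonic bonded model
#'
#' A synthetic bonded energy model E = sum k_r (r - r_eq)^2 +
#' sum k_theta (theta - theta_eq)^2 (Amber convention), used to build
#' analytic Hessian fixtures with known generating constants.
#'
#' @param bonds Data frame or list with columns/fields `i`, `j`, `k_r`
#'   (kcal mol^-1 A^-2), `r_eq` (A); may be empty.
#' @param angles Data frame with columns `i`, `j`, `k`, `k_theta`
#'   (kcal mol^-1 rad^-2), `theta_eq` (degrees); `j` is the apex.
#' @return Object of class `harmonic_model`.
#' @export
harmonic_model <- function(bonds = NULL, angles = NULL) {
  empty_b <- data.frame(i = integer(0), j = integer(0), k_r = numeric(0),
                        r_eq = numeric(0))
  empty_a <- data.frame(i = integer(0), j = integer(0), k = integer(0),
                        k_theta = numeric(0), theta_eq = numeric(0))
  bonds <- if (is.null(bonds)) empty_b else as.data.frame(bonds)
  angles <- if (is.null(angles)) empty_a else as.data.frame(angles)
  if (nrow(bonds) && any(bonds$k_r < 0)) stop("k_r must be >= 0")
  if (nrow(angles) && any(angles$k_theta < 0)) stop("k_theta must be >= 0")
  structure(list(bonds = bonds, angles = angles), class = "harmonic_model")
}

#' Energy of a harmonic model at given coordinates
#'
#' @param m A [harmonic_model()].
#' @param coords N x 3 coordinate matrix, Angstrom.
#' @return Energy in kcal/mol.
#' @export
harmonic_energy <- function(m, coords) {
  e <- 0
  b <- m$bonds
  for (r in seq_len(nrow(b))) {
    d <- sqrt(sum((coords[b$j[r], ] - coords[b$i[r], ])^2))
    e <- e + b$k_r[r] * (d - b$r_eq[r])^2
  }
  a <- m$angles
  for (r in seq_len(nrow(a))) {
    th <- .angle_rad(coords, a$i[r], a$j[r], a$k[r])
    e <- e + a$k_theta[r] * (th - a$theta_eq[r] * pi / 180)^2
  }
  e
}

.angle_rad <- function(coords, i, j, k) {
  v1 <- coords[i, ] - coords[j, ]
  v2 <- coords[k, ] - coords[j, ]
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(max(-1, min(1, cosang)))
}

#' Analytic Hessian of a harmonic model at its equilibrium geometry
#'
#' Assembles the exact second derivatives of the model energy.  At the
#' equilibrium geometry every term reduces to an outer product
#' 2 k grad(q) grad(q)^T of the internal-coordinate gradient, so the
#' result is exact (cross-validated against central finite differences in
#' the test suite).  The geometry must sit at the model's equilibrium
#' (|r - r_eq| and |theta - theta_eq| below 1e-8); anything else is an
#' error, which keeps Seminario recovery fixtures well defined.
#'
#' @param m A [harmonic_model()].
#' @param geom An `xyzmol` structure at the model's equilibrium.
#' @return A [cart_hessian()].
#' @export
analytic_hessian <- function(m, geom) {
  coords <- geom$coords
  n3 <- 3L * nrow(coords)
  H <- matrix(0, n3, n3)
  sl <- function(a) (3L * (a - 1L) + 1L):(3L * a)
  add_outer <- function(idx, grads, k2) {
    # grads: list of 3-vectors per atom in idx; adds k2 * g g^T
    for (p in seq_along(idx)) for (q in seq_along(idx)) {
      H[sl(idx[p]), sl(idx[q])] <<- H[sl(idx[p]), sl(idx[q])] +
        k2 * outer(grads[[p]], grads[[q]])
    }
  }
  b <- m$bonds
  for (r in seq_len(nrow(b))) {
    i <- b$i[r]; j <- b$j[r]
    d <- coords[j, ] - coords[i, ]
    rr <- sqrt(sum(d^2))
    if (abs(rr - b$r_eq[r]) > 1e-8)
      stop("bond ", i, "-", j, " is off equilibrium (r = ",
           sprintf("%.10f", rr), ", r_eq = ", b$r_eq[r], ")")
    u <- d / rr
    add_outer(c(i, j), list(-u, u), 2 * b$k_r[r])
  }
  a <- m$angles
  for (r in seq_len(nrow(a))) {
    i <- a$i[r]; j <- a$j[r]; k <- a$k[r]
    vji <- coords[i, ] - coords[j, ]; vjk <- coords[k, ] - coords[j, ]
    Rji <- sqrt(sum(vji^2)); Rjk <- sqrt(sum(vjk^2))
    uji <- vji / Rji; ujk <- vjk / Rjk
    th <- .angle_rad(coords, i, j, k)
    if (abs(th - a$theta_eq[r] * pi / 180) > 1e-8)
      stop("angle ", i, "-", j, "-", k, " is off equilibrium")
    s <- sin(th); cth <- cos(th)
    gi <- (cth * uji - ujk) / (Rji * s)
    gk <- (cth * ujk - uji) / (Rjk * s)
    gj <- -(gi + gk)
    add_outer(c(i, j, k), list(gi, gj, gk), 2 * a$k_theta[r])
  }
  cart_hessian(H, geom)
}

#' Central finite-difference Hessian of an arbitrary energy function
#'
#' Independent numerical oracle for [analytic_hessian()].
#'
#' @param energy Function taking an N x 3 coordinate matrix, returning a
#'   scalar energy.
#' @param coords N x 3 coordinate matrix.
#' @param step Displacement step in Angstrom (default 1e-5).
#' @return A plain 3N x 3N matrix.
#' @export
fd_hessian <- function(energy, coords, step = 1e-5) {
  x0 <- as.vector(t(coords))
  n <- length(x0)
  ev <- function(x) energy(matrix(x, ncol = 3L, byrow = TRUE))
  H <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in i:n) {
    pert <- function(si, sj) {
      x <- x0; x[i] <- x[i] + si * step; x[j] <- x[j] + sj * step
      ev(x)
    }
    v <- (pert(1, 1) - pert(1, -1) - pert(-1, 1) + pert(-1, -1)) /
      (4 * step^2)
    H[i, j] <- v; H[j, i] <- v
  }
  H
}

#' Random harmonic fixtures with known generating constants
#'
#' Generates (geometry, model) pairs in the two regimes where the Seminario
#' estimators are the exact inverse of the harmonic generator: random bond
#' networks (arbitrary geometry; interatomic Hessian blocks of distinct
#' bonds never overlap) and isolated orthogonal-arm angle triatomics.
#'
#' @param type `"bonds"` for a random bonded network (spanning tree over
#'   4-8 atoms plus extra edges), `"angle"` for a single 90-degree angle
#'   with random arm lengths.
#' @param seed Integer RNG seed.
#' @return List with `geom` (an `xyzmol`), `model` (a [harmonic_model()]).
#' @export
random_harmonic_fixture <- function(type = c("bonds", "angle"), seed = 1L) {
  type <- match.arg(type)
  rs <- .seeded_rng(seed)
  if (type == "angle") {
    r1 <- rs$unif(1, 0.9, 2.4); r2 <- rs$unif(1, 0.9, 2.4)
    k <- rs$unif(1, 20, 300)
    coords <- rbind(c(r1, 0, 0), c(0, 0, 0), c(0, r2, 0))
    rot <- .random_rotation(rs)
    coords <- coords %*% t(rot) +
      matrix(rs$unif(3, -5, 5), 3, 3, byrow = TRUE)
    geom <- xyz_structure(c("O", "C", "O"), coords)
    model <- harmonic_model(angles = data.frame(
      i = 1L, j = 2L, k = 3L, k_theta = k, theta_eq = 90))
    return(list(geom = geom, model = model))
  }
  n <- 4L + rs$int(1, 5L)
  repeat {
    coords <- matrix(rs$unif(3L * n, -3, 3), n, 3L)
    if (min(stats::dist(coords)) > 1.0) break
  }
  edges <- cbind(2:n, vapply(2:n, function(i) rs$int(1, i - 1L), 1L))
  extra <- 1L + rs$int(1, 2L)
  for (e in seq_len(extra)) {
    cand <- c(rs$int(1, n), rs$int(1, n))
    if (cand[1L] != cand[2L]) edges <- rbind(edges, sort(cand))
  }
  edges <- unique(t(apply(edges, 1L, sort)))
  d <- apply(edges, 1L, function(p)
    sqrt(sum((coords[p[1L], ] - coords[p[2L], ])^2)))
  model <- harmonic_model(bonds = data.frame(
    i = edges[, 1L], j = edges[, 2L],
    k_r = rs$unif(nrow(edges), 100, 1000), r_eq = d))
  geom <- xyz_structure(rep("C", n), coords)
  list(geom = geom, model = model)
}

# Self-contained RNG helper: isolates fixture generation from the global
# RNG stream while remaining deterministic under `seed`.
.seeded_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    st <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
    st
  })
  draw <- function(fn) function(n, ...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    out <- fn(n, ...)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
    out
  }
  list(unif = draw(stats::runif),
       norm = draw(stats::rnorm),
       int = draw(function(n, k) sample.int(k, n, replace = TRUE)),
       perm = draw(function(n, k = n) sample.int(k, n)))
}

.random_rotation <- function(rs) {
  q <- rs$norm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  rbind(c(1 - 2 * (y^2 + z^2), 2 * (x * y - z * w), 2 * (x * z + y * w)),
        c(2 * (x * y + z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z - x * w)),
        c(2 * (x * z - y * w), 2 * (y * z + x * w), 1 - 2 * (x^2 + y^2)))
}

#' Two-basin synthetic trajectory with known labels
#'
#' Frames are Gaussian perturbations of one of two reference geometries:
#' the base structure, or a copy in which one peripheral ("side-chain")
#' atom is displaced by `displacement` Angstrom.  With
#' `displacement >> noise_sigma` the basins are separable by heavy-atom
#' RMSD, providing ground-truth labels for clustering tests.
#'
#' @param n_per_basin Frames per basin.
#' @param displacement Side-chain displacement, Angstrom (default 3).
#' @param noise_sigma Per-coordinate Gaussian noise, Angstrom (default 0.1).
#' @param seed Integer RNG seed (default 2023).
#' @param base Optional base `xyzmol`; defaults to a built-in 10-atom
#'   molecule (8 heavy atoms + 2 hydrogens).
#' @return List with `trajectory` (a [trajectory()]) and `labels`
#'   (integer vector, 1 or 2 per frame).
#' @export
two_basin_trajectory <- function(n_per_basin = 50L, displacement = 3,
                                 noise_sigma = 0.1, seed = 2023L,
                                 base = NULL) {
  if (is.null(base)) {
    coords <- rbind(
      c(0, 0, 0), c(1.5, 0, 0), c(2.3, 1.3, 0), c(3.8, 1.3, 0),
      c(4.6, 2.6, 0), c(4.6, 0, 1.0), c(-0.8, 1.3, 0), c(-0.8, -1.3, 0),
      c(1.9, -0.9, 0.4), c(3.4, 2.2, -0.4))
    base <- xyz_structure(c(rep("C", 6), "N", "O", "H", "H"), coords)
  }
  rs <- .seeded_rng(seed)
  n <- n_atoms(base)
  centerA <- base$coords
  centerB <- centerA
  # displace the last heavy atom perpendicular to the molecular plane
  heavy <- which(base$elements != "H")
  mv <- heavy[length(heavy)]
  centerB[mv, ] <- centerB[mv, ] + c(0, 0, displacement)
  f_total <- 2L * n_per_basin
  frames <- array(0, c(f_total, n, 3L))
  labels <- rep(c(1L, 2L), each = n_per_basin)
  for (f in seq_len(f_total)) {
    center <- if (labels[f] == 1L) centerA else centerB
    frames[f, , ] <- center +
      matrix(rs$norm(3L * n, 0, noise_sigma), n, 3L)
  }
  list(trajectory = trajectory(base, frames), labels = labels)
}
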