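# Directional Seminario sum: eigendecompose a 3x3 interatomic sub-block
# (generally non-symmetric; complex parts are discarded as in standard
# implementations) and accumulate lambda_m * |u . v_m|.
.seminario_sum <- function(block, u) {
  e <- eigen(block)
  val <- Re(e$values)
  vec <- Re(e$vectors)
  s <- 0
  for (m in 1:3) {
    v <- vec[, m]
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) next
    s <- s + val[m] * abs(sum(u * v)) / nv
  }
  s
}

.block <- function(h, i, j) {
  ri <- (3L * (i - 1L) + 1L):(3L * i)
  rj <- (3L * (j - 1L) + 1L):(3L * j)
  -h$matrix[ri, rj, drop = FALSE]
}

#' Seminario bond parameters from a Cartesian Hessian
#'
#' Eigendecomposes the negated 3x3 interatomic Hessian block between atoms
#' `i` and `j`, projects the eigenvalues onto the unit bond vector in both
#' block directions, averages the two directional spring constants, and
#' halves the result so the returned force constant is in the Amber
#' convention E = k_r (r - r_eq)^2.  Negative accumulated constants
#' (possible at non-stationary geometries) are clamped to zero with a
#' warning.  The equilibrium length is taken from the reference geometry.
#'
#' @param h A [cart_hessian()] in internal units.
#' @param i,j Atom indices (1-based), distinct.
#' @return List with `i`, `j`, `k_r` (kcal mol^-1 A^-2) and `r_eq` (A).
#' @export
seminario_bond <- function(h, i, j) {
  if (i == j) stop("i and j must differ")
  g <- h$geometry
  d <- g$coords[j, ] - g$coords[i, ]
  r <- sqrt(sum(d^2))
  if (r < 1e-8) stop("atoms ", i, " and ", j, " are coincident")
  u <- d / r
  k_spring <- (.seminario_sum(.block(h, i, j), u) +
               .seminario_sum(.block(h, j, i), u)) / 2
  k_r <- k_spring / 2
  if (k_r < 0) {
    warning("negative bond force constant for ", i, "-", j,
            " clamped to zero")
    k_r <- 0
  }
  list(i = i, j = j, k_r = k_r, r_eq = r)
}

#' Seminario angle parameters from a Cartesian Hessian
#'
#' For the angle i-j-k with apex `j`, projects the eigen-systems of the two
#' arm blocks onto the in-plane unit vectors perpendicular to each arm and
#' combines the two arm measurements in series:
#' 1/k_theta = 1/(R_ji^2 kPA) + 1/(R_jk^2 kPC).  The series combination of
#' the two full spring measurements yields the Amber-convention constant
#' for E = k_theta (theta - theta_eq)^2 directly (exact when the arms are
#' orthogonal).  The equilibrium angle comes from the reference geometry.
#'
#' @param h A [cart_hessian()].
#' @param i,j,k Atom indices, `j` the apex; must be non-collinear.
#' @return List with `i`, `j`, `k`, `k_theta` (kcal mol^-1 rad^-2) and
#'   `theta_eq` (degrees).
#' @export
seminario_angle <- function(h, i, j, k) {
  if (anyDuplicated(c(i, j, k))) stop("indices must be distinct")
  g <- h$geometry
  vji <- g$coords[i, ] - g$coords[j, ]
  vjk <- g$coords[k, ] - g$coords[j, ]
  Rji <- sqrt(sum(vji^2)); Rjk <- sqrt(sum(vjk^2))
  if (Rji < 1e-8 || Rjk < 1e-8) stop("coincident atoms in angle")
  uji <- vji / Rji; ujk <- vjk / Rjk
  cosang <- max(-1, min(1, sum(uji * ujk)))
  theta <- acos(cosang)
  if (theta < 1e-3 || theta > pi - 1e-3)
    stop("angle ", i, "-", j, "-", k, " is collinear (",
         sprintf("%.2f", theta * 180 / pi), " deg)")
  un <- .cross3(uji, ujk); un <- un / sqrt(sum(un^2))
  u_pa <- .cross3(un, uji); u_pa <- u_pa / sqrt(sum(u_pa^2))
  u_pc <- .cross3(ujk, un); u_pc <- u_pc / sqrt(sum(u_pc^2))
  k_pa <- .seminario_sum(.block(h, i, j), u_pa)
  k_pc <- .seminario_sum(.block(h, k, j), u_pc)
  if (k_pa <= 0 || k_pc <= 0) {
    warning("non-positive angle projection for ", i, "-", j, "-", k,
            "; force constant clamped to zero")
    k_theta <- 0
  } else {
    k_theta <- 1 / (1 / (Rji^2 * k_pa) + 1 / (Rjk^2 * k_pc))
  }
  list(i = i, j = j, k = k, k_theta = k_theta, theta_eq = theta * 180 / pi)
}

.cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Derive all metal-involving bonded parameters
#'
#' One bond parameter per metal contact; one angle parameter per pair of
#' contacts sharing the same metal apex and per
#' (ligand-neighbor, ligand-atom, metal) triple where the ligand atom is a
#' metal contact partner and the neighbor comes from the non-metal
#' adjacency.  Carbon-metal contacts are treated like all others.
#' Collinear angle triples (e.g. trans pairs in square-planar complexes)
#' are skipped with a warning since the Seminario angle projection is
#' undefined there.
#'
#' @param h A [cart_hessian()].
#' @param g A `bondgraph` for the same structure.
#' @return List with data frames `bonds` (i, j, k_r, r_eq) and `angles`
#'   (i, j, k, k_theta, theta_eq).
#' @export
derive_metal_params <- function(h, g) {
  mc <- g$metal_contacts
  bonds <- data.frame(i = integer(0), j = integer(0),
                      k_r = numeric(0), r_eq = numeric(0))
  angles <- data.frame(i = integer(0), j = integer(0), k = integer(0),
                       k_theta = numeric(0), theta_eq = numeric(0))
  if (!nrow(mc)) return(list(bonds = bonds, angles = angles))
  for (r in seq_len(nrow(mc))) {
    b <- seminario_bond(h, mc[r, 1L], mc[r, 2L])
    bonds[nrow(bonds) + 1L, ] <- b[c("i", "j", "k_r", "r_eq")]
  }
  add_angle <- function(i, j, k) {
    a <- tryCatch(seminario_angle(h, i, j, k), error = function(e) {
      warning("skipping angle ", i, "-", j, "-", k, ": ",
              conditionMessage(e))
      NULL
    })
    if (!is.null(a))
      angles[nrow(angles) + 1L, ] <<- a[c("i", "j", "k", "k_theta",
                                          "theta_eq")]
  }
  # ligand-metal-ligand angles, metal apex
  for (m in unique(mc[, 1L])) {
    part <- mc[mc[, 1L] == m, 2L]
    if (length(part) > 1L) {
      cmb <- utils::combn(sort(part), 2L)
      for (c_ in seq_len(ncol(cmb))) add_angle(cmb[1L, c_], m, cmb[2L, c_])
    }
  }
  # neighbor-ligand-metal angles, ligand-atom apex
  for (r in seq_len(nrow(mc))) {
    m <- mc[r, 1L]; lig <- mc[r, 2L]
    nbrs <- c(g$adjacency[g$adjacency[, 1L] == lig, 2L],
              g$adjacency[g$adjacency[, 2L] == lig, 1L])
    for (nb in sort(unique(nbrs))) add_angle(nb, lig, m)
  }
  list(bonds = bonds, angles = angles)
}
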