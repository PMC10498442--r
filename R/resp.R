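#' Build Merz-Kollman ESP shell points
#'
#' Places near-uniform points on spheres of radius scale * vdW around every
#' atom, one layer per shell scale, using a deterministic Fibonacci lattice
#' (reproducible without a seed).  Points falling inside any other atom's
#' sphere at the same scale are discarded, leaving the outer molecular
#' surface at each shell.
#'
#' @param s An `xyzmol` structure.
#' @param scales Shell multipliers on the vdW radii
#'   (default `c(1.4, 1.6, 1.8, 2.0)`, the standard Merz-Kollman set).
#' @param density Surface point density, points per square Angstrom
#'   (default 1).
#' @param table Element table for vdW radii.
#' @return M x 3 matrix of point coordinates (Angstrom); zero rows when
#'   `scales` is empty.
#' @export
build_mk_grid <- function(s, scales = c(1.4, 1.6, 1.8, 2.0), density = 1.0,
                          table = element_table()) {
  if (n_atoms(s) < 1L) stop("structure is empty")
  radii <- element_vdw(s$elements, table)
  pts <- list()
  for (sc in scales) {
    rs <- sc * radii
    for (a in seq_len(n_atoms(s))) {
      np <- max(1L, round(4 * pi * rs[a]^2 * density))
      sph <- .fibonacci_sphere(np) * rs[a]
      sph <- sweep(sph, 2L, s$coords[a, ], "+")
      keep <- rep(TRUE, np)
      for (b in seq_len(n_atoms(s))) {
        if (b == a) next
        d2 <- rowSums(sweep(sph, 2L, s$coords[b, ], "-")^2)
        keep <- keep & d2 >= (rs[b] - 1e-9)^2
      }
      if (any(keep)) pts[[length(pts) + 1L]] <- sph[keep, , drop = FALSE]
    }
  }
  if (!length(pts)) return(matrix(numeric(0), 0L, 3L))
  do.call(rbind, pts)
}

.fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Electrostatic potential of point charges
#'
#' v(p) = sum_a q_a / |p - r_a| with distances converted to bohr, so the
#' returned values are in atomic units (e/bohr).  Serves as the grid
#' generator for self-consistency fixtures and as the design model of the
#' RESP fit.
#'
#' @param charges Per-atom charges, e.
#' @param atom_coords N x 3 matrix, Angstrom.
#' @param points M x 3 matrix, Angstrom.
#' @return Numeric vector of M potentials, atomic units.
#' @export
point_charge_esp <- function(charges, atom_coords, points) {
  atom_coords <- as.matrix(atom_coords); points <- as.matrix(points)
  if (length(charges) != nrow(atom_coords))
    stop("charges and atom_coords disagree in length")
  A <- .esp_design(atom_coords, points)
  as.vector(A %*% charges)
}

# Design matrix A[p, a] = 1 / d_bohr(p, a); errors on coincident points.
.esp_design <- function(atom_coords, points) {
  M <- nrow(points); n <- nrow(atom_coords)
  A <- matrix(0, M, n)
  for (a in seq_len(n)) {
    d <- sqrt(rowSums(sweep(points, 2L, atom_coords[a, ], "-")^2))
    if (any(d < 1e-8))
      stop("grid point coincides with atom ", a)
    A[, a] <- 1 / (d / BOHR_ANGSTROM)
  }
  A
}

#' ESP grid container
#'
#' @param points M x 3 matrix, Angstrom.
#' @param values M potentials, atomic units (e/bohr).
#' @return Object of class `espgrid`.
#' @export
esp_grid <- function(points, values) {
  points <- as.matrix(points)
  if (nrow(points) != length(values))
    stop("points and values disagree in length")
  structure(list(points = points, values = as.numeric(values)),
            class = "espgrid")
}

#' Read/write the plain-text grid dialect: one `x y z value` line per point
#' (coordinates in Angstrom, potentials in atomic units).
#'
#' @param x Path or text.
#' @return An [esp_grid()].
#' @export
read_esp_grid <- function(x) {
  lines <- .as_lines(x)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", trimws(lines))]
  m <- do.call(rbind, lapply(strsplit(trimws(lines), "[[:space:]]+"),
                             as.numeric))
  if (ncol(m) != 4L) stop("expected 4 columns: x y z value")
  esp_grid(m[, 1:3, drop = FALSE], m[, 4L])
}

#' @rdname read_esp_grid
#' @param grid An [esp_grid()].
#' @param file Optional output path.
#' @export
write_esp_grid <- function(grid, file = NULL) {
  txt <- paste(sprintf("%14.8f %14.8f %14.8f %16.10e",
                       grid$points[, 1L], grid$points[, 2L],
                       grid$points[, 3L], grid$values), collapse = "\n")
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' RESP charge fit
#'
#' Fits per-atom point charges to an ESP grid by minimizing
#' sum_p (v_p - sum_a q_a/|p - r_a|)^2 + a * sum_a (sqrt(q_a^2 + b^2) - b)
#' subject to sum q_a = total, with the hyperbolic restraint handled by the
#' standard iterated linearization (weights a / sqrt(q_prev^2 + b^2)) and
#' convergence declared when the maximum absolute charge change drops below
#' 1e-8.  When equivalence groups are supplied, the standard two-stage
#' protocol runs: stage 1 fits all atoms freely at restraint `a1`; stage 2
#' refits only the grouped atoms (members share one charge) at `a2` with
#' every other atom frozen.  Without groups the fit degenerates to the
#' single stage at `a1`.
#'
#' @param grid An [esp_grid()] with at least one point.
#' @param s The `xyzmol` structure the grid belongs to.
#' @param total Integer total charge constraint, e.
#' @param equiv_groups List of disjoint atom-index vectors whose members
#'   must share one charge (default none).
#' @param a1 Stage-1 restraint strength (default 0.0005).
#' @param a2 Stage-2 restraint strength (default 0.001).
#' @param b Restraint width, e (default 0.1).
#' @param max_iter Restraint iteration cap (default 200).
#' @return Object of class `chargeset`: fields `charges`, `total`,
#'   `restraint_a`, `restraint_b`, `rrms` (relative RMS fit residual).
#' @export
resp_fit <- function(grid, s, total, equiv_groups = list(),
                     a1 = 0.0005, a2 = 0.001, b = 0.1, max_iter = 200L) {
  if (!inherits(grid, "espgrid")) stop("grid must be an espgrid")
  if (nrow(grid$points) < 1L) stop("empty ESP grid")
  if (length(equiv_groups)) {
    flat <- unlist(equiv_groups)
    if (anyDuplicated(flat)) stop("equivalence groups must be disjoint")
    if (any(flat < 1L) || any(flat > n_atoms(s)))
      stop("equivalence group index out of range")
  }
  A <- .esp_design(s$coords, grid$points)
  v <- grid$values
  q1 <- .resp_stage(A, v, n_atoms(s), total, a = a1, b = b,
                    groups = list(), frozen = numeric(0),
                    free = seq_len(n_atoms(s)), max_iter = max_iter)
  q <- q1
  a_used <- a1
  if (length(equiv_groups)) {
    free <- sort(unlist(equiv_groups))
    frozen_idx <- setdiff(seq_len(n_atoms(s)), free)
    q <- .resp_stage(A, v, n_atoms(s), total, a = a2, b = b,
                     groups = equiv_groups, frozen = q1[frozen_idx],
                     free = free, max_iter = max_iter)
    a_used <- a2
  }
  resid <- v - as.vector(A %*% q)
  rrms <- sqrt(sum(resid^2) / max(sum(v^2), .Machine$double.eps))
  structure(list(charges = q, total = total, restraint_a = a_used,
                 restraint_b = b, rrms = rrms),
            class = "chargeset")
}

#' @export
print.chargeset <- function(x, ...) {
  cat(sprintf("<chargeset> %d charges, sum %+.6f, rrms %.4g\n",
              length(x$charges), sum(x$charges), x$rrms))
  invisible(x)
}

# One restrained stage.  `free` are the atom indices being fit; `frozen`
# holds the fixed charges of the remaining atoms (in setdiff order).
# `groups` (subsets of `free`) share a single fitted charge.
.resp_stage <- function(A, v, n, total, a, b, groups, frozen, free,
                        max_iter) {
  frozen_idx <- setdiff(seq_len(n), free)
  v_eff <- v
  if (length(frozen_idx))
    v_eff <- v - as.vector(A[, frozen_idx, drop = FALSE] %*% frozen)
  # reduction matrix G: q_free = G z
  in_group <- unlist(groups)
  singles <- setdiff(free, in_group)
  cols <- c(lapply(singles, identity), groups)
  nz <- length(cols)
  G <- matrix(0, length(free), nz)
  for (c_ in seq_len(nz))
    G[match(cols[[c_]], free), c_] <- 1
  Af <- A[, free, drop = FALSE] %*% G
  AtA <- crossprod(Af)
  Atv <- crossprod(Af, v_eff)
  ones <- colSums(G)  # constraint row: sum over atoms of G z
  target <- total - sum(frozen)
  q_free <- rep(0, length(free))
  prev_obj <- Inf
  for (it in seq_len(max_iter)) {
    w_atom <- if (a > 0) a / sqrt(q_free^2 + b^2) else rep(0, length(free))
    W <- crossprod(G, w_atom * G)
    K <- rbind(cbind(2 * (AtA + W), ones), c(ones, 0))
    rhs <- c(2 * Atv, target)
    sol <- tryCatch(solve(K, rhs), error = function(e)
      stop("singular RESP normal equations: ", conditionMessage(e)))
    z <- sol[seq_len(nz)]
    q_new <- as.vector(G %*% z)
    delta <- max(abs(q_new - q_free))
    q_free <- q_new
    if (a == 0 || delta < 1e-8) break
    if (it == max_iter) {
      resid <- v_eff - as.vector(Af %*% z)
      stop("RESP restraint iteration did not converge in ", max_iter,
           " steps (last charge change ", sprintf("%.3g", delta),
           ", residual RMS ", sprintf("%.6g", sqrt(mean(resid^2))), ")")
    }
  }
  q <- numeric(n)
  q[free] <- q_free
  q[frozen_idx] <- frozen
  q
}
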