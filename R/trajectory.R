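#' Trajectory container
#'
#' @param topology An `xyzmol` giving elements and a reference frame.
#' @param frames F x N x 3 numeric array of coordinates, Angstrom.
#' @return Object of class `mdtraj`.
#' @export
trajectory <- function(topology, frames) {
  frames <- as.array(frames)
  if (length(dim(frames)) != 3L || dim(frames)[2L] != n_atoms(topology) ||
      dim(frames)[3L] != 3L)
    stop("frames must be an F x N x 3 array matching the topology")
  if (dim(frames)[1L] < 1L) stop("trajectory needs at least one frame")
  structure(list(topology = topology, frames = frames), class = "mdtraj")
}

#' @export
print.mdtraj <- function(x, ...) {
  cat(sprintf("<mdtraj> %d frames x %d atoms\n", n_frames(x),
              n_atoms(x$topology)))
  invisible(x)
}

#' Number of frames
#' @param t An `mdtraj`.
#' @export
n_frames <- function(t) dim(t$frames)[1L]

#' Read a multi-frame XMOL xyz trajectory
#'
#' Concatenated xyz blocks with a constant atom count.
#'
#' @param x Path or text.
#' @return An [trajectory()] whose topology is the first frame.
#' @export
read_xyz_traj <- function(x) {
  lines <- .as_lines(x)
  while (length(lines) && !nzchar(trimws(lines[length(lines)])))
    lines <- lines[-length(lines)]
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || n < 1L) stop("bad atom count on line 1")
  block <- n + 2L
  if (length(lines) %% block != 0L)
    stop("trajectory length ", length(lines),
         " is not a multiple of the frame block (", block, " lines)")
  f <- length(lines) %/% block
  frames <- array(0, c(f, n, 3L))
  topo <- NULL
  for (k in seq_len(f)) {
    blk <- lines[((k - 1L) * block + 1L):(k * block)]
    s <- read_xyz(paste(blk, collapse = "\n"))
    if (is.null(topo)) topo <- s
    else if (!identical(s$elements, topo$elements))
      stop("frame ", k, " has different atoms than frame 1")
    frames[k, , ] <- s$coords
  }
  trajectory(topo, frames)
}

#' Write a trajectory as multi-frame xyz
#'
#' @param t An `mdtraj`.
#' @param file Optional output path.
#' @param digits Coordinate decimals.
#' @export
write_xyz_traj <- function(t, file = NULL, digits = 6L) {
  txts <- vapply(seq_len(n_frames(t)), function(k) {
    s <- t$topology
    s$coords <- matrix(t$frames[k, , ], ncol = 3L)
    s$comment <- sprintf("frame %d", k)
    write_xyz(s, digits = digits)
  }, "")
  txt <- paste(txts, collapse = "\n")
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

# Kabsch superposition: optimal rotation (and translation) mapping the
# selected atoms of `mobile` onto `ref`; returns the transform.
.kabsch <- function(mobile, ref) {
  cm <- colMeans(mobile); cr <- colMeans(ref)
  P <- sweep(mobile, 2L, cm, "-")
  Q <- sweep(ref, 2L, cr, "-")
  s <- svd(crossprod(P, Q))
  d <- sign(det(tcrossprod(s$v, s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  list(R = R, center_mobile = cm, center_ref = cr)
}

#' Align trajectory frames on a user-supplied atom selection
#'
#' Each frame is rigidly transformed by the least-squares (Kabsch)
#' superposition of the selected atoms onto the reference frame; the
#' transform is then applied to all atoms of the frame.
#'
#' @param t An [trajectory()].
#' @param ref_frame Reference frame index (default 1).
#' @param align_indices Atom indices (1-based) used for the superposition;
#'   at least 3 non-collinear atoms.
#' @return The aligned trajectory.
#' @export
align_trajectory <- function(t, ref_frame = 1L, align_indices) {
  align_indices <- as.integer(align_indices)
  n <- n_atoms(t$topology)
  if (any(align_indices < 1L | align_indices > n))
    stop("align index out of range 1..", n)
  if (length(unique(align_indices)) < 3L)
    stop("need at least 3 distinct alignment atoms")
  ref <- matrix(t$frames[ref_frame, align_indices, ], ncol = 3L)
  sv <- svd(sweep(ref, 2L, colMeans(ref), "-"))$d
  if (sv[2L] < 1e-8 * max(sv[1L], 1))
    stop("alignment selection is collinear")
  out <- t$frames
  for (k in seq_len(n_frames(t))) {
    fr <- matrix(t$frames[k, , ], ncol = 3L)
    tr <- .kabsch(fr[align_indices, , drop = FALSE], ref)
    out[k, , ] <- sweep(sweep(fr, 2L, tr$center_mobile, "-") %*% t(tr$R),
                        2L, tr$center_ref, "+")
  }
  trajectory(t$topology, out)
}

#' Pairwise RMSD matrix over masked atoms
#'
#' Entry (a, b) is the root-mean-square deviation of the masked atom
#' positions between frames a and b of an already aligned trajectory.  The
#' default mask selects heavy atoms (everything but hydrogen), the
#' standard conformer-clustering criterion.
#'
#' @param t An aligned [trajectory()].
#' @param mask Atom indices to include; default all non-hydrogen atoms.
#' @return Symmetric F x F matrix with zero diagonal.
#' @export
rmsd_matrix <- function(t, mask = NULL) {
  if (is.null(mask)) mask <- which(t$topology$elements != "H")
  if (!length(mask)) stop("empty atom mask")
  f <- n_frames(t)
  X <- matrix(0, f, 3L * length(mask))
  for (k in seq_len(f))
    X[k, ] <- as.vector(t$frames[k, mask, ])
  sq <- rowSums(X^2)
  d2 <- (outer(sq, sq, "+") - 2 * tcrossprod(X)) / length(mask)
  d2[d2 < 0] <- 0
  m <- sqrt(d2)
  diag(m) <- 0
  (m + t(m)) / 2
}
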