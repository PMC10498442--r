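# Unit constants (CODATA 2018)
HARTREE_KCALMOL <- 627.509474
BOHR_ANGSTROM <- 0.529177210903
HARTREE_BOHR2_TO_KCAL_A2 <- HARTREE_KCALMOL / BOHR_ANGSTROM^2

#' Cartesian Hessian container
#'
#' @param matrix 3N x 3N numeric matrix of second derivatives in
#'   kcal mol^-1 A^-2 (internal units).
#' @param geometry Reference `xyzmol` structure (N atoms).
#' @return Object of class `carthessian`.
#' @export
cart_hessian <- function(matrix, geometry) {
  matrix <- as.matrix(matrix)
  n3 <- 3L * n_atoms(geometry)
  if (nrow(matrix) != n3 || ncol(matrix) != n3)
    stop("Hessian is ", nrow(matrix), "x", ncol(matrix),
         " but the geometry implies ", n3, "x", n3)
  structure(list(matrix = matrix, geometry = geometry,
                 units = "kcal_mol_A2"),
            class = "carthessian")
}

#' @export
print.carthessian <- function(x, ...) {
  cat(sprintf("<carthessian> %d atoms (%dx%d), kcal/mol/A^2\n",
              n_atoms(x$geometry), nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Load a Cartesian Hessian
#'
#' Reads either the ORCA `.hess` text dialect (only the `$hessian` block is
#' consumed; values in hartree/bohr^2) or a plain whitespace-delimited
#' square matrix.  The matrix is converted to internal units
#' (kcal mol^-1 A^-2), symmetrized, and its dimension checked against the
#' reference geometry.
#'
#' @param x Path or text (see [read_xyz()] conventions).
#' @param geometry Reference `xyzmol` structure.
#' @param units Units of the input values: `"auto"` (ORCA dialect implies
#'   `"hartree_bohr2"`, a plain matrix implies `"kcal_mol_A2"`), or one of
#'   those two tags explicitly.
#' @return A [cart_hessian()] in internal units.
#' @export
load_hessian <- function(x, geometry,
                         units = c("auto", "hartree_bohr2", "kcal_mol_A2")) {
  units <- match.arg(units)
  lines <- .as_lines(x)
  is_orca <- any(grepl("^\\$hessian", trimws(lines)))
  m <- if (is_orca) .parse_orca_hess(lines) else .parse_plain_matrix(lines)
  if (units == "auto") units <- if (is_orca) "hartree_bohr2" else "kcal_mol_A2"
  if (units == "hartree_bohr2") m <- m * HARTREE_BOHR2_TO_KCAL_A2
  n3 <- 3L * n_atoms(geometry)
  if (nrow(m) != n3)
    stop("Hessian dimension ", nrow(m), " does not match 3*N = ", n3,
         " for the supplied geometry")
  scale <- max(abs(m))
  if (scale > 0 && max(abs(m - t(m))) / scale > 1e-3)
    stop("Hessian asymmetry exceeds 1e-3 relative; refusing to symmetrize")
  cart_hessian((m + t(m)) / 2, geometry)
}

.parse_plain_matrix <- function(lines) {
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", trimws(lines))]
  vals <- lapply(strsplit(trimws(lines), "[[:space:]]+"), as.numeric)
  nc <- unique(lengths(vals))
  if (length(nc) != 1L)
    stop("ragged matrix: rows have ", paste(nc, collapse = "/"), " columns")
  m <- do.call(rbind, vals)
  if (nrow(m) != ncol(m))
    stop("matrix is ", nrow(m), "x", ncol(m), ", expected square")
  m
}

.parse_orca_hess <- function(lines) {
  start <- which(grepl("^\\$hessian", trimws(lines)))[1L]
  dim_ <- as.integer(trimws(lines[start + 1L]))
  if (is.na(dim_) || dim_ < 1L) stop("bad $hessian dimension line")
  m <- matrix(NA_real_, dim_, dim_)
  i <- start + 2L
  while (anyNA(m) && i <= length(lines)) {
    ln <- trimws(lines[i])
    if (grepl("^\\$", ln)) break
    if (!nzchar(ln)) { i <- i + 1L; next }
    cols <- as.integer(strsplit(ln, "[[:space:]]+")[[1L]]) + 1L
    for (r in seq_len(dim_)) {
      toks <- strsplit(trimws(lines[i + r]), "[[:space:]]+")[[1L]]
      row <- as.integer(toks[1L]) + 1L
      m[row, cols] <- as.numeric(toks[-1L])
    }
    i <- i + dim_ + 1L
  }
  if (anyNA(m)) stop("incomplete $hessian block")
  m
}

#' Write a Hessian in the ORCA `.hess` text dialect
#'
#' Emits `$hessian` (values converted to hartree/bohr^2) and `$atoms`
#' blocks, column-chunked five at a time, suitable for [load_hessian()].
#'
#' @param h A [cart_hessian()].
#' @param file Optional output path.
#' @return The text, invisibly when written to a file.
#' @export
write_orca_hess <- function(h, file = NULL) {
  m <- h$matrix / HARTREE_BOHR2_TO_KCAL_A2
  d <- nrow(m)
  out <- c("$orca_hessian_file", "", "$hessian", as.character(d))
  for (c0 in seq(1L, d, by = 5L)) {
    cols <- c0:min(c0 + 4L, d)
    out <- c(out, paste0("    ", paste(sprintf("%10d", cols - 1L),
                                       collapse = " ")))
    for (r in seq_len(d))
      out <- c(out, paste0(sprintf("%6d", r - 1L), " ",
                           paste(sprintf("%14.8e", m[r, cols]),
                                 collapse = " ")))
  }
  g <- h$geometry
  out <- c(out, "", "$atoms", as.character(n_atoms(g)))
  mass <- element_mass(g$elements)
  out <- c(out, sprintf("%-3s %10.5f %14.8f %14.8f %14.8f", g$elements, mass,
                        g$coords[, 1L] / BOHR_ANGSTROM,
                        g$coords[, 2L] / BOHR_ANGSTROM,
                        g$coords[, 3L] / BOHR_ANGSTROM))
  out <- c(out, "", "$end")
  txt <- paste(out, collapse = "\n")
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}
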