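#' Molecular structure container
#'
#' A lightweight container for a molecular system: ordered element symbols,
#' Cartesian coordinates in Angstrom, integer total charge (e) and spin
#' multiplicity.
#'
#' @param elements Character vector of element symbols.
#' @param coords Numeric N x 3 matrix of Cartesian coordinates, Angstrom.
#' @param total_charge Integer total charge in e (default 0).
#' @param multiplicity Positive integer spin multiplicity (default 1).
#' @param comment Free-text comment carried through xyz round trips.
#' @param table Element table used to validate symbols.
#' @return An object of class `xyzmol`.
#' @export
xyz_structure <- function(elements, coords, total_charge = 0L,
                          multiplicity = 1L, comment = "",
                          table = element_table()) {
  coords <- as.matrix(coords)
  if (length(elements) == 0L || nrow(coords) != length(elements) ||
      ncol(coords) != 3L)
    stop("coords must be an N x 3 matrix matching length(elements)")
  if (multiplicity < 1L) stop("multiplicity must be >= 1")
  element_info(elements, table)  # errors on unknown symbols
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  structure(list(elements = as.character(elements), coords = coords,
                 total_charge = as.integer(total_charge),
                 multiplicity = as.integer(multiplicity),
                 comment = as.character(comment)),
            class = "xyzmol")
}

#' @export
print.xyzmol <- function(x, ...) {
  cat(sprintf("<xyzmol> %d atoms, charge %+d, multiplicity %d\n",
              n_atoms(x), x$total_charge, x$multiplicity))
  f <- table(x$elements)
  cat("  formula:", paste0(names(f), ifelse(f > 1, f, ""), collapse = ""), "\n")
  invisible(x)
}

#' Number of atoms in a structure
#' @param s An `xyzmol` object.
#' @export
n_atoms <- function(s) length(s$elements)

#' Read an XMOL xyz file
#'
#' Parses the XMOL dialect: first line the atom count, second line a free
#' comment, then one `symbol x y z` line per atom.  Total charge and
#' multiplicity default to 0 and 1; set them afterwards from configuration.
#'
#' @param x Path to a file, or a character scalar containing xyz text.
#' @param table Element table for symbol validation.
#' @return An [xyz_structure()] object.
#' @export
read_xyz <- function(x, table = element_table()) {
  lines <- .as_lines(x)
  if (length(lines) < 1L) stop("empty xyz input")
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || n < 1L)
    stop("line 1: expected a positive atom count, got '", lines[1L], "'")
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < n)
    stop("atom count mismatch: header declares ", n, " atoms but only ",
         length(body), " atom lines follow (first missing: line ",
         length(body) + 3L, ")")
  body <- body[seq_len(n)]
  toks <- strsplit(trimws(body), "[[:space:]]+")
  bad <- which(vapply(toks, length, 1L) < 4L)
  if (length(bad))
    stop("line ", bad[1L] + 2L, ": expected 'symbol x y z'")
  elements <- vapply(toks, `[[`, "", 1L)
  coords <- t(vapply(toks, function(tk)
    suppressWarnings(as.numeric(tk[2:4])), numeric(3)))
  if (anyNA(coords))
    stop("non-numeric coordinate on line ",
         which(apply(is.na(coords), 1L, any))[1L] + 2L)
  comment <- if (length(lines) >= 2L) lines[2L] else ""
  xyz_structure(elements, coords, comment = comment, table = table)
}

#' Write a structure as XMOL xyz text
#'
#' @param s An `xyzmol` object.
#' @param file Optional path; if `NULL` the text is returned invisibly.
#' @param digits Coordinate decimals (default 6).
#' @return The xyz text, invisibly when written to a file.
#' @export
write_xyz <- function(s, file = NULL, digits = 6L) {
  fmt <- sprintf("%%-3s %%%d.%df %%%d.%df %%%d.%df",
                 digits + 6L, digits, digits + 6L, digits, digits + 6L, digits)
  body <- sprintf(fmt, s$elements, s$coords[, 1L], s$coords[, 2L],
                  s$coords[, 3L])
  txt <- paste(c(as.character(n_atoms(s)), s$comment, body), collapse = "\n")
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

.as_lines <- function(x) {
  if (length(x) == 1L && !grepl("\n", x, fixed = TRUE) && file.exists(x))
    return(readLines(x, warn = FALSE))
  if (length(x) == 1L) return(strsplit(x, "\n", fixed = TRUE)[[1L]])
  as.character(x)
}

#' Write per-fragment PDB files
#'
#' Emits one PDB v3.3 text per fragment, HETATM records only.  Atom names
#' are made unique within each fragment as element symbol plus a running
#' counter (C1, C2, H1, ...); serial numbers restart at 1 in every file;
#' the residue name is the fragment label.  Connectivity is not written
#' (it lives in the bond graph), so no CONECT records are emitted.
#'
#' @param s An `xyzmol` object.
#' @param frags A [fragment_set()] whose fragments partition the atoms of `s`.
#' @return Named list of PDB-format strings, one per fragment.
#' @export
write_fragment_pdbs <- function(s, frags) {
  idxs <- frags$fragments
  all_idx <- unlist(idxs)
  if (anyDuplicated(all_idx))
    stop("fragments overlap: atom(s) ",
         paste(unique(all_idx[duplicated(all_idx)]), collapse = ", "),
         " appear in more than one fragment")
  if (!setequal(all_idx, seq_len(n_atoms(s))))
    stop("fragments must partition all ", n_atoms(s), " atoms")
  out <- vector("list", length(idxs))
  labels <- frags$labels
  if (is.null(labels)) labels <- sprintf("F%02d", seq_along(idxs))
  for (f in seq_along(idxs)) {
    ai <- idxs[[f]]
    el <- s$elements[ai]
    cnt <- stats::ave(seq_along(el), el, FUN = seq_along)
    names_ <- paste0(el, cnt)
    rec <- sprintf(
      "HETATM%5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_along(ai), substr(names_, 1L, 4L), substr(labels[f], 1L, 3L), f,
      s$coords[ai, 1L], s$coords[ai, 2L], s$coords[ai, 3L],
      toupper(substr(el, 1L, 2L)))
    out[[f]] <- paste(c(rec, "END"), collapse = "\n")
  }
  names(out) <- labels
  out
}
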