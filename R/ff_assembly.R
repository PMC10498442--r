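# Default Lennard-Jones parameters (r_min/2 in Angstrom, epsilon in
# kcal/mol) for metal atom types; overridable via assign_atom_types().
# Values are generic starting points for a bonded metal model, not fitted.
.default_metal_vdw <- list(
  Cu = c(1.218, 0.0427), Zn = c(1.395, 0.0125), Fe = c(1.409, 0.0135),
  Ni = c(1.373, 0.0149), Co = c(1.404, 0.0132), Mn = c(1.467, 0.0105),
  Mo = c(1.526, 0.0560), Ru = c(1.483, 0.0560), Pd = c(1.573, 0.0320),
  Pt = c(1.607, 0.0400), Mg = c(1.185, 0.0150), Ca = c(1.463, 0.0600))
.metal_vdw_default <- c(1.500, 0.0500)

#' Assign atom types, with fresh types for the metal coordination shell
#'
#' Every metal atom and every partner in a metal contact receives a fresh
#' type code (M1, M2, ... for metals; Y1, Y2, ... for shell atoms), one
#' type per atom, avoiding collisions with the supplied base types.  All
#' remaining atoms keep their base types.
#'
#' @param s An `xyzmol` structure.
#' @param g A `bondgraph` for `s`.
#' @param base_types Character vector, one existing type code per atom
#'   (from ligand inputs or element defaults; defaults to lowercase element
#'   symbols).
#' @param metal_vdw Optional named list overriding the packaged metal
#'   Lennard-Jones defaults; entries are `c(rmin_half, epsilon)`.
#' @return Data frame of class `atomtypes` with columns `atom`, `element`,
#'   `type`, `origin` (`"existing"` or `"new-metal-shell"`), `vdw_radius`,
#'   `vdw_eps`, `mass`.
#' @export
assign_atom_types <- function(s, g, base_types = NULL, metal_vdw = list()) {
  n <- n_atoms(s)
  if (is.null(base_types)) base_types <- tolower(s$elements)
  if (length(base_types) != n)
    stop("base_types must supply one type per atom")
  metal_idx <- which(g$is_metal)
  shell_idx <- setdiff(sort(unique(as.vector(g$metal_contacts))), metal_idx)
  fresh <- function(prefix, count, taken) {
    out <- character(0); k <- 0L
    while (length(out) < count) {
      k <- k + 1L
      if (k > 99L) stop("more than 99 fresh '", prefix, "' types needed")
      cand <- paste0(prefix, k)
      if (!(cand %in% taken)) out <- c(out, cand)
    }
    out
  }
  types <- base_types
  origin <- rep("existing", n)
  taken <- unique(base_types)
  if (length(metal_idx)) {
    mt <- fresh("M", length(metal_idx), taken)
    types[metal_idx] <- mt
    origin[metal_idx] <- "new-metal-shell"
    taken <- c(taken, mt)
  }
  if (length(shell_idx)) {
    yt <- fresh("Y", length(shell_idx), taken)
    types[shell_idx] <- yt
    origin[shell_idx] <- "new-metal-shell"
  }
  vdw <- t(vapply(seq_len(n), function(a) {
    el <- s$elements[a]
    if (g$is_metal[a]) {
      p <- metal_vdw[[el]]
      if (is.null(p)) p <- .default_metal_vdw[[el]]
      if (is.null(p)) p <- .metal_vdw_default
      p
    } else {
      r <- element_vdw(el)
      c(r, 0.06)
    }
  }, numeric(2)))
  out <- data.frame(atom = seq_len(n), element = s$elements, type = types,
                    origin = origin, vdw_radius = vdw[, 1L],
                    vdw_eps = vdw[, 2L], mass = element_mass(s$elements),
                    stringsAsFactors = FALSE)
  class(out) <- c("atomtypes", "data.frame")
  out
}

#' Force-field parameter set
#'
#' Container merging typed bonded parameters, nonbonded terms and charges
#' ahead of file emission.  Bond/angle/dihedral entries are keyed by type
#' codes; duplicate keys are rejected.
#'
#' @param types An `atomtypes` data frame (unique rows per type are used
#'   for MASS/NONBON sections).
#' @param bonds Data frame `ti`, `tj`, `k_r`, `r_eq`.
#' @param angles Data frame `ti`, `tj`, `tk`, `k_theta`, `theta_eq`.
#' @param dihedrals Data frame `ti`, `tj`, `tk`, `tl`, `idivf`, `pk`,
#'   `phase`, `pn`.
#' @param charges Optional `chargeset`.
#' @return Object of class `paramset`.
#' @export
param_set <- function(types, bonds = NULL, angles = NULL, dihedrals = NULL,
                      charges = NULL) {
  empty <- function(...) {
    df <- data.frame(...)
    df[0L, , drop = FALSE]
  }
  if (is.null(bonds))
    bonds <- empty(ti = "", tj = "", k_r = 0, r_eq = 0)
  if (is.null(angles))
    angles <- empty(ti = "", tj = "", tk = "", k_theta = 0, theta_eq = 0)
  if (is.null(dihedrals))
    dihedrals <- empty(ti = "", tj = "", tk = "", tl = "", idivf = 1,
                       pk = 0, phase = 0, pn = 1)
  bkey <- apply(bonds[, c("ti", "tj"), drop = FALSE], 1L,
                function(r) paste(sort(r), collapse = "-"))
  if (anyDuplicated(bkey)) stop("duplicate bond type keys")
  akey <- apply(angles[, c("ti", "tj", "tk"), drop = FALSE], 1L,
                function(r) paste(r[2L], paste(sort(r[c(1L, 3L)]),
                                               collapse = "-"), sep = ":"))
  if (anyDuplicated(akey)) stop("duplicate angle type keys")
  structure(list(types = types, bonds = bonds, angles = angles,
                 dihedrals = dihedrals, charges = charges),
            class = "paramset")
}

#' Write an Amber frcmod file
#'
#' Emits MASS, BOND, ANGLE, DIHE and NONBON sections with fixed-width
#' 4-decimal numeric formatting.  Force constants are written exactly as
#' stored: `k_r` multiplies (r - r_eq)^2 and `k_theta` multiplies
#' (theta - theta_eq)^2, the Amber harmonic convention, so no halving is
#' applied at write time.
#'
#' @param p A [param_set()].
#' @param file Optional output path.
#' @param title Header line.
#' @return The frcmod text, invisibly when written to a file.
#' @export
write_frcmod <- function(p, file = NULL,
                         title = "metalff generated parameters") {
  ty <- unique(p$types[, c("type", "element", "mass", "vdw_radius",
                           "vdw_eps")])
  need <- unique(c(p$bonds$ti, p$bonds$tj, p$angles$ti, p$angles$tj,
                   p$angles$tk))
  missing <- setdiff(need, ty$type)
  if (length(missing))
    stop("no mass/type entry for type(s): ", paste(missing, collapse = ", "))
  out <- c(title, "MASS")
  out <- c(out, sprintf("%-2s %10.4f", ty$type, ty$mass))
  out <- c(out, "", "BOND")
  b <- p$bonds
  if (nrow(b))
    out <- c(out, sprintf("%-2s-%-2s %12.4f %10.4f", b$ti, b$tj, b$k_r,
                          b$r_eq))
  out <- c(out, "", "ANGLE")
  a <- p$angles
  if (nrow(a))
    out <- c(out, sprintf("%-2s-%-2s-%-2s %12.4f %10.4f", a$ti, a$tj, a$tk,
                          a$k_theta, a$theta_eq))
  out <- c(out, "", "DIHE")
  d <- p$dihedrals
  if (nrow(d))
    out <- c(out, sprintf("%-2s-%-2s-%-2s-%-2s %4d %10.4f %10.4f %6.1f",
                          d$ti, d$tj, d$tk, d$tl, as.integer(d$idivf),
                          d$pk, d$phase, d$pn))
  out <- c(out, "", "NONBON")
  out <- c(out, sprintf("  %-2s %12.4f %12.4f", ty$type, ty$vdw_radius,
                        ty$vdw_eps))
  out <- c(out, "")
  txt <- paste(out, collapse = "\n")
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Read an Amber frcmod file written by [write_frcmod()]
#'
#' @param x Path or text.
#' @return List with data frames `mass`, `bonds`, `angles`, `dihedrals`,
#'   `nonbon`.
#' @export
read_frcmod <- function(x) {
  lines <- .as_lines(x)
  sec <- ""
  mass <- list(); bonds <- list(); angles <- list(); dihe <- list()
  nonbon <- list()
  for (ln in lines[-1L]) {
    t_ <- trimws(ln)
    if (!nzchar(t_)) next
    if (t_ %in% c("MASS", "BOND", "ANGLE", "DIHE", "NONBON")) {
      sec <- t_; next
    }
    toks <- strsplit(t_, "[[:space:]]+")[[1L]]
    if (sec == "MASS") {
      mass[[length(mass) + 1L]] <- data.frame(
        type = toks[1L], mass = as.numeric(toks[2L]))
    } else if (sec == "BOND") {
      ty <- trimws(strsplit(substr(ln, 1L, 5L), "-")[[1L]])
      rest <- as.numeric(strsplit(trimws(substr(ln, 6L, nchar(ln))),
                                  "[[:space:]]+")[[1L]])
      bonds[[length(bonds) + 1L]] <- data.frame(
        ti = ty[1L], tj = ty[2L], k_r = rest[1L], r_eq = rest[2L])
    } else if (sec == "ANGLE") {
      ty <- trimws(strsplit(substr(ln, 1L, 8L), "-")[[1L]])
      rest <- as.numeric(strsplit(trimws(substr(ln, 9L, nchar(ln))),
                                  "[[:space:]]+")[[1L]])
      angles[[length(angles) + 1L]] <- data.frame(
        ti = ty[1L], tj = ty[2L], tk = ty[3L], k_theta = rest[1L],
        theta_eq = rest[2L])
    } else if (sec == "DIHE") {
      ty <- trimws(strsplit(substr(ln, 1L, 11L), "-")[[1L]])
      rest <- as.numeric(strsplit(trimws(substr(ln, 12L, nchar(ln))),
                                  "[[:space:]]+")[[1L]])
      dihe[[length(dihe) + 1L]] <- data.frame(
        ti = ty[1L], tj = ty[2L], tk = ty[3L], tl = ty[4L],
        idivf = rest[1L], pk = rest[2L], phase = rest[3L], pn = rest[4L])
    } else if (sec == "NONBON") {
      nonbon[[length(nonbon) + 1L]] <- data.frame(
        type = toks[1L], vdw_radius = as.numeric(toks[2L]),
        vdw_eps = as.numeric(toks[3L]))
    }
  }
  bind <- function(l, proto) if (length(l)) do.call(rbind, l) else proto
  list(
    mass = bind(mass, data.frame(type = character(0), mass = numeric(0))),
    bonds = bind(bonds, data.frame(ti = character(0), tj = character(0),
                                   k_r = numeric(0), r_eq = numeric(0))),
    angles = bind(angles, data.frame(ti = character(0), tj = character(0),
                                     tk = character(0), k_theta = numeric(0),
                                     theta_eq = numeric(0))),
    dihedrals = bind(dihe, data.frame(ti = character(0), tj = character(0),
                                      tk = character(0), tl = character(0),
                                      idivf = numeric(0), pk = numeric(0),
                                      phase = numeric(0), pn = numeric(0))),
    nonbon = bind(nonbon, data.frame(type = character(0),
                                     vdw_radius = numeric(0),
                                     vdw_eps = numeric(0))))
}

#' Write a TRIPOS mol2 file
#'
#' ATOM records carry the fitted charges and assigned types; BOND records
#' are the non-metal adjacency plus the metal contacts, so metal-ligand
#' bonds of the bonded model are explicit.
#'
#' @param s An `xyzmol` structure.
#' @param charges Numeric per-atom charges (or a `chargeset`).
#' @param types Character per-atom types (or an `atomtypes` frame).
#' @param g A `bondgraph`.
#' @param name Molecule name.
#' @param file Optional output path.
#' @return mol2 text, invisibly when written to a file.
#' @export
write_mol2 <- function(s, charges, types, g, name = "MOL", file = NULL) {
  if (inherits(charges, "chargeset")) charges <- charges$charges
  if (inherits(types, "data.frame")) types <- types$type
  n <- n_atoms(s)
  if (length(charges) != n || length(types) != n)
    stop("charges/types must have one entry per atom")
  bonds <- rbind(g$adjacency, g$metal_contacts)
  el <- s$elements
  cnt <- stats::ave(seq_len(n), el, FUN = seq_along)
  out <- c("@<TRIPOS>MOLECULE", name,
           sprintf(" %d %d 1 0 0", n, nrow(bonds)),
           "SMALL", "USER_CHARGES", "", "@<TRIPOS>ATOM")
  out <- c(out, sprintf(
    "%7d %-8s %10.4f %10.4f %10.4f %-6s 1 %-4s %10.6f",
    seq_len(n), paste0(el, cnt), s$coords[, 1L], s$coords[, 2L],
    s$coords[, 3L], types, name, charges))
  out <- c(out, "@<TRIPOS>BOND")
  if (nrow(bonds))
    out <- c(out, sprintf("%6d %5d %5d 1", seq_len(nrow(bonds)),
                          bonds[, 1L], bonds[, 2L]))
  txt <- paste(out, collapse = "\n")
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Read a TRIPOS mol2 file
#'
#' @param x Path or text.
#' @return List with `structure` (an `xyzmol`; element symbols are inferred
#'   from atom names), `charges`, `types`, `bonds` (two-column matrix).
#' @export
read_mol2 <- function(x) {
  lines <- .as_lines(x)
  sec <- ""
  atoms <- list(); bonds <- list()
  for (ln in lines) {
    t_ <- trimws(ln)
    if (startsWith(t_, "@<TRIPOS>")) { sec <- t_; next }
    if (!nzchar(t_)) next
    toks <- strsplit(t_, "[[:space:]]+")[[1L]]
    if (sec == "@<TRIPOS>ATOM") {
      atoms[[length(atoms) + 1L]] <- toks
    } else if (sec == "@<TRIPOS>BOND" && length(toks) >= 3L) {
      bonds[[length(bonds) + 1L]] <- as.integer(toks[2:3])
    }
  }
  if (!length(atoms)) stop("no ATOM records in mol2 input")
  name <- vapply(atoms, `[[`, "", 2L)
  el <- sub("[0-9]+$", "", name)
  el <- paste0(toupper(substr(el, 1L, 1L)),
               tolower(substr(el, 2L, nchar(el))))
  coords <- t(vapply(atoms, function(a) as.numeric(a[3:5]), numeric(3)))
  types <- vapply(atoms, `[[`, "", 6L)
  charges <- vapply(atoms, function(a)
    if (length(a) >= 9L) as.numeric(a[9L]) else NA_real_, 0)
  bm <- if (length(bonds)) do.call(rbind, bonds) else
    matrix(integer(0), 0L, 2L)
  list(structure = xyz_structure(el, coords), charges = charges,
       types = types, bonds = bm)
}
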