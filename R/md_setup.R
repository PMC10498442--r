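# Experimental liquid densities (g/cm^3, 298 K) for the packaged solvents.
.solvent_densities <- c(water = 0.997, chloroform = 1.489,
                        dichloromethane = 1.327)

#' Load a solvent template
#'
#' Packaged templates (`"water"`, `"chloroform"`, `"dichloromethane"`) ship
#' as mol2 + frcmod pairs under `inst/extdata/solvents`; user-defined
#' solvents are loaded from file pairs.  A template is a single connected
#' molecule with per-atom charges and a target liquid density used by
#' [build_box()].
#'
#' @param name Packaged template name, or a label for user files.
#' @param mol2 Optional path to a user mol2 file.
#' @param frcmod Optional path to a user frcmod file.
#' @param density Target density in g/cm^3 (required for user templates).
#' @return Object of class `solvent_template`.
#' @export
solvent_template <- function(name, mol2 = NULL, frcmod = NULL,
                             density = NULL) {
  if (is.null(mol2)) {
    dir <- system.file("extdata", "solvents", package = "metalff",
                       mustWork = TRUE)
    mol2 <- file.path(dir, paste0(name, ".mol2"))
    frcmod <- file.path(dir, paste0(name, ".frcmod"))
    if (!file.exists(mol2))
      stop("no packaged solvent '", name, "'; available: ",
           paste(names(.solvent_densities), collapse = ", "))
    if (is.null(density)) density <- .solvent_densities[[name]]
  }
  if (is.null(density) || density <= 0)
    stop("a positive target density (g/cm^3) is required")
  m <- read_mol2(mol2)
  ft <- if (!is.null(frcmod) && file.exists(frcmod))
    paste(readLines(frcmod, warn = FALSE), collapse = "\n") else NULL
  g <- detect_bonds(m$structure)
  fr <- find_fragments(g)
  if (length(fr$fragments) != 1L)
    stop("solvent template must be a single connected fragment")
  structure(list(name = name, structure = m$structure, charges = m$charges,
                 types = m$types, density = density, frcmod = ft),
            class = "solvent_template")
}

#' Counterion template
#'
#' @param element Element symbol (e.g. `"Cl"`).
#' @param charge Integer formal charge in e.
#' @param type Atom type code (defaults to the symbol).
#' @return Object of class `ion_template`.
#' @export
ion_template <- function(element, charge, type = element) {
  structure(list(element = element, charge = as.integer(charge),
                 type = type), class = "ion_template")
}

#' Pack a solvent box around a solute
#'
#' Builds a cubic box with edge length equal to the solute extent plus
#' twice `margin` and fills it with solvent copies at the template's target
#' density.  Copies sit on a jittered simple-cubic lattice with two
#' alternating (checkerboard) orientations; the orientation pair is chosen
#' by a seeded search that maximizes the minimum interatomic clearance
#' between lattice neighbors, which lets common solvents reach their
#' experimental density without violating `min_dist`.  Copies with any atom
#' closer than `min_dist` to the solute (or, after a safety sweep, to a
#' previously placed copy) are removed.  Counterions are placed at the box
#' faces farthest from the solute, one per charge unit needed to
#' neutralize the solute charge.
#'
#' @param solute An `xyzmol`, or `NULL` for a pure-solvent box.
#' @param solvent A [solvent_template()].
#' @param margin Padding in Angstrom (> 0) between solute extent and wall.
#' @param ions List of [ion_template()] objects (the first is used).
#' @param min_dist Minimum allowed interatomic distance, Angstrom
#'   (default 2).
#' @param seed Integer seed controlling orientation search, site choice
#'   and jitter (default 2023).
#' @return Object of class `simbox`: fields `structure` (combined
#'   `xyzmol`), `box_length`, `n_solvent`, `n_ions`, `solute_atoms`,
#'   `solvent_atoms`, `ion_atoms`.
#' @export
build_box <- function(solute, solvent, margin, ions = list(),
                      min_dist = 2.0, seed = 2023L) {
  if (margin <= 0) stop("margin must be positive")
  tcoords <- solvent$structure$coords
  tcoords <- sweep(tcoords, 2L, colMeans(tcoords), "-")
  has_solute <- !is.null(solute) && n_atoms(solute) > 0L
  extent <- if (has_solute) max(apply(solute$coords, 2L,
                                      function(v) diff(range(v)))) else 0
  L <- extent + 2 * margin
  mass <- sum(element_mass(solvent$structure$elements))
  n_target <- round(solvent$density * L^3 * 1e-24 * 6.02214076e23 / mass)
  if (n_target < 1L)
    stop("box of edge ", sprintf("%.1f", L),
         " A is too small for any '", solvent$name, "' molecule")
  rs <- .seeded_rng(seed)
  # shrink the lattice until the checkerboard orientation search finds a
  # clearance >= min_dist; each shrink costs density
  n_side <- as.integer(ceiling(n_target^(1 / 3)))
  repeat {
    if (n_side < 1L) stop("box too small: no clash-free packing found")
    cell <- L / n_side
    ori <- .orient_pair_search(tcoords, cell, rs, n_trials = 250L)
    if (ori$clearance >= min_dist || n_side == 1L) break
    n_side <- n_side - 1L
  }
  if (ori$clearance < min_dist && n_side == 1L && n_target > 1L)
    stop("box too small: no clash-free packing found")
  sites <- as.matrix(expand.grid(i = seq_len(n_side), j = seq_len(n_side),
                                 k = seq_len(n_side)))
  if (nrow(sites) > n_target)
    sites <- sites[sort(rs$perm(n_target, nrow(sites))), , drop = FALSE]
  origin <- if (has_solute)
    colMeans(apply(solute$coords, 2L, range)) - L / 2 else c(0, 0, 0)
  jit <- min(0.1, max(0, (ori$clearance - min_dist) / 4))
  centers <- (sites - 0.5) * cell
  centers <- sweep(centers, 2L, origin, "+") +
    matrix(rs$unif(3L * nrow(sites), -jit, jit), ncol = 3L)
  parity <- (rowSums(sites) %% 2L) == 0L
  copies <- lapply(seq_len(nrow(sites)), function(s_) {
    R <- if (parity[s_]) ori$RA else ori$RB
    sweep(tcoords %*% t(R), 2L, centers[s_, ], "+")
  })
  # remove copies clashing with the solute
  if (has_solute) {
    keep <- vapply(copies, function(cc)
      min(.cross_dist2(cc, solute$coords)) >= min_dist^2, TRUE)
    copies <- copies[keep]
  }
  # safety sweep: greedy removal of any copy clashing with an earlier one
  kept <- list()
  for (cc in copies) {
    ok <- all(vapply(kept, function(kk)
      min(.cross_dist2(cc, kk)) >= min_dist^2, TRUE))
    if (ok) kept[[length(kept) + 1L]] <- cc
  }
  copies <- kept
  # counterions for neutrality
  ion_pos <- matrix(numeric(0), 0L, 3L)
  ion_el <- character(0)
  q_solute <- if (has_solute) solute$total_charge else 0L
  if (length(ions) && q_solute != 0L) {
    ion <- ions[[1L]]
    if (sign(ion$charge) == sign(q_solute)) {
      warning("ion charge has the same sign as the solute; cannot neutralize")
    } else {
      n_ion <- abs(q_solute) %/% abs(ion$charge)
      if (n_ion * abs(ion$charge) != abs(q_solute))
        warning("ion charge ", ion$charge, " cannot exactly neutralize ",
                "solute charge ", q_solute)
      faces <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                     c(0, 0, 1), c(0, 0, -1))
      ctr <- origin + L / 2
      fpos <- sweep(faces * (L / 2 - min_dist), 2L, ctr, "+")
      if (has_solute) {
        sc <- colMeans(solute$coords)
        fpos <- fpos[order(-sqrt(rowSums(sweep(fpos, 2L, sc, "-")^2))), ,
                     drop = FALSE]
      }
      idx <- ((seq_len(n_ion) - 1L) %% 6L) + 1L
      ion_pos <- fpos[idx, , drop = FALSE]
      ion_el <- rep(ion$element, n_ion)
      # clear solvent around each ion
      for (r in seq_len(nrow(ion_pos))) {
        copies <- Filter(function(cc)
          min(.cross_dist2(cc, ion_pos[r, , drop = FALSE])) >= min_dist^2,
          copies)
      }
    }
  }
  n_solv <- length(copies)
  el <- c(if (has_solute) solute$elements,
          rep(solvent$structure$elements, n_solv), ion_el)
  coords <- do.call(rbind, c(if (has_solute) list(solute$coords), copies,
                             if (nrow(ion_pos)) list(ion_pos)))
  n_su <- if (has_solute) n_atoms(solute) else 0L
  n_per <- n_atoms(solvent$structure)
  q_total <- q_solute + (if (length(ion_el))
    length(ion_el) * ions[[1L]]$charge else 0L)
  all_s <- xyz_structure(el, coords, total_charge = q_total)
  structure(list(structure = all_s, box_length = L, n_solvent = n_solv,
                 n_ions = length(ion_el),
                 solute_atoms = seq_len(n_su),
                 solvent_atoms = n_su + seq_len(n_solv * n_per),
                 ion_atoms = n_su + n_solv * n_per + seq_along(ion_el),
                 density_target = solvent$density,
                 density_achieved = n_solv * mass /
                   (L^3 * 1e-24 * 6.02214076e23)),
            class = "simbox")
}

.cross_dist2 <- function(a, b) {
  # min-ready squared distances between row sets a (n x 3) and b (m x 3)
  outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
}

# Seeded search for a checkerboard orientation pair maximizing the minimum
# interatomic clearance between lattice-neighbor molecules.
.orient_pair_search <- function(tcoords, cell, rs, n_trials = 250L) {
  ax <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
              c(0, 0, 1), c(0, 0, -1)) * cell
  fd <- rbind(c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
              c(0, 1, 1), c(0, 1, -1)) * cell
  clearance <- function(RA, RB) {
    A <- tcoords %*% t(RA); B <- tcoords %*% t(RB)
    m <- Inf
    for (r in seq_len(nrow(ax)))
      m <- min(m, .cross_dist2(sweep(A, 2L, ax[r, ], "+"), B))
    for (X in list(A, B)) for (r in seq_len(nrow(fd)))
      m <- min(m, .cross_dist2(sweep(X, 2L, fd[r, ], "+"), X))
    sqrt(max(m, 0))
  }
  best <- list(clearance = -Inf)
  for (t_ in seq_len(n_trials)) {
    RA <- .random_rotation(rs); RB <- .random_rotation(rs)
    cl <- clearance(RA, RB)
    if (cl > best$clearance) best <- list(RA = RA, RB = RB, clearance = cl)
  }
  best
}

#' Simulation protocol
#'
#' An ordered list of equilibration stages followed by one production run.
#' The default protocol is a configurable stand-in: restrained
#' minimization, stepwise NVT heating 10 -> 300 K, one cool/reheat cycle,
#' a short unrestrained NPT stage, then 100 ns NVT production at 300 K.
#'
#' @param stages Data frame with columns `name`, `ensemble` (`"min"`,
#'   `"NVT"`, `"NPT"`), `temp` (K), `length_ps`, `restraint_wt`
#'   (kcal/mol/A^2; 0 = unrestrained).
#' @param production List with `ensemble`, `temp` (K), `length_ns`.
#' @param dt_fs Timestep in femtoseconds (default 2).
#' @return Object of class `sim_protocol`.
#' @export
sim_protocol <- function(stages = NULL,
                         production = list(ensemble = "NVT", temp = 300,
                                           length_ns = 100),
                         dt_fs = 2) {
  if (is.null(stages)) stages <- default_equilibration_stages()
  stopifnot(all(stages$temp >= 0), all(stages$length_ps > 0),
            production$temp >= 0, production$length_ns > 0, dt_fs > 0)
  structure(list(stages = stages, production = production, dt_fs = dt_fs),
            class = "sim_protocol")
}

#' @rdname sim_protocol
#' @export
default_equilibration_stages <- function() {
  data.frame(
    name = c("min_restrained", "heat_010", "heat_100", "heat_200",
             "heat_300", "cool_100", "reheat_300", "npt_relax"),
    ensemble = c("min", "NVT", "NVT", "NVT", "NVT", "NVT", "NVT", "NPT"),
    temp = c(0, 10, 100, 200, 300, 100, 300, 300),
    length_ps = c(1, 20, 20, 20, 50, 20, 50, 100),
    restraint_wt = c(10, 5, 5, 2, 2, 2, 0, 0),
    stringsAsFactors = FALSE)
}

#' Emit Amber mdin input decks
#'
#' One mdin text per equilibration stage plus one production deck.  The
#' production deck encodes the target ensemble and temperature and a step
#' count equal to the production length at the configured timestep
#' (100 ns at 2 fs = 50,000,000 steps by default).
#'
#' @param p A [sim_protocol()].
#' @return Named list of mdin texts; the production deck is named
#'   `"production"`.
#' @export
emit_inputs <- function(p) {
  decks <- list()
  for (r in seq_len(nrow(p$stages))) {
    st <- p$stages[r, ]
    decks[[st$name]] <- .mdin_deck(
      title = st$name, ensemble = st$ensemble, temp = st$temp,
      nstlim = if (st$ensemble == "min") 2000L else
        as.integer(round(st$length_ps * 1000 / p$dt_fs)),
      dt_fs = p$dt_fs, restraint_wt = st$restraint_wt)
  }
  pr <- p$production
  decks[["production"]] <- .mdin_deck(
    title = sprintf("production %g ns %s", pr$length_ns, pr$ensemble),
    ensemble = pr$ensemble, temp = pr$temp,
    nstlim = as.integer(round(pr$length_ns * 1e6 / p$dt_fs)),
    dt_fs = p$dt_fs, restraint_wt = 0)
  decks
}

.mdin_deck <- function(title, ensemble, temp, nstlim, dt_fs, restraint_wt) {
  lines <- c(title, " &cntrl")
  if (ensemble == "min") {
    lines <- c(lines, "  imin = 1,", sprintf("  maxcyc = %d,", nstlim),
               "  ncyc = 500,")
  } else {
    ntb <- if (ensemble == "NPT") 2L else 1L
    ntp <- if (ensemble == "NPT") 1L else 0L
    lines <- c(lines,
               "  imin = 0,",
               sprintf("  nstlim = %d,", nstlim),
               sprintf("  dt = %.4f,", dt_fs / 1000),
               sprintf("  ntb = %d, ntp = %d,", ntb, ntp),
               sprintf("  ntt = 3, gamma_ln = 2.0, temp0 = %.1f,", temp),
               "  cut = 10.0,")
  }
  if (restraint_wt > 0)
    lines <- c(lines, sprintf("  ntr = 1, restraint_wt = %.1f,",
                              restraint_wt),
               "  restraintmask = '!:WAT & !@H=',")
  c_ <- c(lines, " /", "")
  paste(c_, collapse = "\n")
}
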