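#' Synthetic tetraammine metal complex fixture
#'
#' A Cu(2+) center with four ammonia ligands on tetrahedral vertices
#' (Cu-N 2.05 A, N-H 1.01 A), the smallest system exercising every stage
#' of the parametrization workflow: metal contacts, multi-fragment
#' perception, Seminario parameters at the metal, RESP charges and box
#' setup.  A matching harmonic model (bonds plus metal-apex angles at the
#' tetrahedral angle) is returned so an analytic Hessian can stand in for
#' a quantum one.
#'
#' @param k_metal_bond Harmonic constant for Cu-N bonds
#'   (kcal mol^-1 A^-2, default 120).
#' @param k_ligand_bond Constant for N-H bonds (default 600).
#' @param k_angle Constant for N-Cu-N angles (kcal mol^-1 rad^-2,
#'   default 50).
#' @return List with `structure` (charge +2), `model`
#'   (a [harmonic_model()]), and `fragment_charges` in fragment order
#'   (+2 for the metal singleton, which holds atom 1 and therefore sorts
#'   first, then four zeros for the ammonia ligands).
#' @export
demo_complex <- function(k_metal_bond = 120, k_ligand_bond = 600,
                         k_angle = 50) {
  dirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) /
    sqrt(3)
  r_cun <- 2.05; r_nh <- 1.01
  coords <- matrix(0, 1L, 3L)  # Cu at origin
  elements <- "Cu"
  for (d in seq_len(4L)) {
    npos <- dirs[d, ] * r_cun
    coords <- rbind(coords, npos)
    elements <- c(elements, "N")
    # three H on a cone pointing away from the metal
    axis <- dirs[d, ]
    perp1 <- .cross3(axis, c(0, 0, 1))
    if (sqrt(sum(perp1^2)) < 1e-6) perp1 <- .cross3(axis, c(0, 1, 0))
    perp1 <- perp1 / sqrt(sum(perp1^2))
    perp2 <- .cross3(axis, perp1)
    for (hh in 0:2) {
      ang <- 2 * pi * hh / 3
      dir_h <- 0.47 * axis + 0.88 * (cos(ang) * perp1 + sin(ang) * perp2)
      dir_h <- dir_h / sqrt(sum(dir_h^2))
      coords <- rbind(coords, npos + dir_h * r_nh)
      elements <- c(elements, "H")
    }
  }
  s <- xyz_structure(elements, coords, total_charge = 2L)
  n_idx <- which(elements == "N")
  bonds <- data.frame(i = integer(0), j = integer(0), k_r = numeric(0),
                      r_eq = numeric(0))
  for (nn in n_idx) {
    bonds <- rbind(bonds, data.frame(
      i = 1L, j = nn, k_r = k_metal_bond,
      r_eq = sqrt(sum(coords[nn, ]^2))))
    for (hh in which(elements == "H")) {
      d <- sqrt(sum((coords[hh, ] - coords[nn, ])^2))
      if (d < 1.2)
        bonds <- rbind(bonds, data.frame(i = nn, j = hh, k_r = k_ligand_bond,
                                         r_eq = d))
    }
  }
  cmb <- utils::combn(n_idx, 2L)
  angles <- data.frame(
    i = cmb[1L, ], j = 1L, k = cmb[2L, ], k_theta = k_angle,
    theta_eq = vapply(seq_len(ncol(cmb)), function(c_)
      .angle_rad(coords, cmb[1L, c_], 1L, cmb[2L, c_]) * 180 / pi, 0))
  list(structure = s, model = harmonic_model(bonds, angles),
       fragment_charges = c(2L, rep(0L, 4L)))
}

#' Run the full parametrization workflow on one system
#'
#' Bond perception, fragmentation, metal-parameter derivation from the
#' Hessian, RESP charge fitting on the supplied ESP grid, atom typing and
#' parameter-file assembly, in one call.
#'
#' @param s An `xyzmol` with its total charge set.
#' @param h A [cart_hessian()] for `s`.
#' @param esp An [esp_grid()] sampled around `s`.
#' @param fragment_charges Integer charges, one per perceived fragment.
#' @param bond_factor Scale for [detect_bonds()] (default 0.6).
#' @param equiv_groups RESP equivalence groups (default none).
#' @param base_types Base atom types (default lowercase element symbols).
#' @return List with fields `graph`, `fragments`, `types`, `charges`,
#'   `metal_params`, `paramset`, `frcmod` (text), `mol2` (text).
#' @export
parametrize_complex <- function(s, h, esp, fragment_charges,
                                bond_factor = 0.6, equiv_groups = list(),
                                base_types = NULL) {
  g <- detect_bonds(s, factor = bond_factor)
  frags <- find_fragments(g)
  frags <- assign_fragment_charges(frags, fragment_charges, s$total_charge)
  mp <- derive_metal_params(h, g)
  charges <- resp_fit(esp, s, total = s$total_charge,
                      equiv_groups = equiv_groups)
  types <- assign_atom_types(s, g, base_types = base_types)
  # atoms sharing one type triple/pair (e.g. three equivalent H-N-M
  # angles) collapse to a single entry with averaged parameters
  tb <- mp$bonds
  bonds <- NULL
  if (nrow(tb)) {
    bonds <- data.frame(ti = types$type[tb$i], tj = types$type[tb$j],
                        k_r = tb$k_r, r_eq = tb$r_eq)
    key <- apply(bonds[, 1:2], 1L, function(r)
      paste(sort(r), collapse = "-"))
    bonds <- do.call(rbind, lapply(split(bonds, key), function(gr)
      data.frame(ti = gr$ti[1L], tj = gr$tj[1L], k_r = mean(gr$k_r),
                 r_eq = mean(gr$r_eq))))
    rownames(bonds) <- NULL
  }
  ta <- mp$angles
  angles <- NULL
  if (nrow(ta)) {
    angles <- data.frame(ti = types$type[ta$i], tj = types$type[ta$j],
                         tk = types$type[ta$k], k_theta = ta$k_theta,
                         theta_eq = ta$theta_eq)
    key <- apply(angles[, 1:3], 1L, function(r)
      paste(r[2L], paste(sort(r[c(1L, 3L)]), collapse = "-"), sep = ":"))
    angles <- do.call(rbind, lapply(split(angles, key), function(gr)
      data.frame(ti = gr$ti[1L], tj = gr$tj[1L], tk = gr$tk[1L],
                 k_theta = mean(gr$k_theta),
                 theta_eq = mean(gr$theta_eq))))
    rownames(angles) <- NULL
  }
  ps <- param_set(types, bonds = bonds, angles = angles, charges = charges)
  list(graph = g, fragments = frags, types = types, charges = charges,
       metal_params = mp, paramset = ps, frcmod = write_frcmod(ps),
       mol2 = write_mol2(s, charges, types, g))
}
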