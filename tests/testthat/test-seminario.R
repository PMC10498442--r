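diatomic <- function(k = 500, r = 1.5, rot_seed = NULL, shift = c(0, 0, 0)) {
  coords <- rbind(c(0, 0, 0), c(0, 0, r))
  if (!is.null(rot_seed))
    coords <- coords %*% t(random_rotation_matrix(rot_seed))
  coords <- sweep(coords, 2, shift, "+")
  geom <- xyz_structure(c("C", "C"), coords)
  model <- harmonic_model(bonds = data.frame(i = 1L, j = 2L, k_r = k,
                                             r_eq = r))
  list(geom = geom, h = analytic_hessian(model, geom))
}

test_that("plain and ORCA Hessian dialects load, convert and validate", {
  geom <- xyz_structure(c("N", "N"), rbind(c(0, 0, 0), c(0, 0, 1.1)))
  m6 <- paste(apply(matrix(0, 6, 6), 1, paste, collapse = " "),
              collapse = "\n")
  h0 <- load_hessian(m6, geom)
  expect_equal(dim(h0$matrix), c(6, 6))
  expect_true(all(h0$matrix == 0))
  # zero matrix is unit invariant
  expect_true(all(load_hessian(m6, geom, units = "hartree_bohr2")$matrix
                  == 0))
  # identity in hartree/bohr^2 converts by the CODATA factor
  id6 <- paste(apply(diag(6), 1, paste, collapse = " "), collapse = "\n")
  hid <- load_hessian(id6, geom, units = "hartree_bohr2")
  factor <- 627.509474 / 0.529177210903^2
  expect_equal(diag(hid$matrix), rep(factor, 6), tolerance = 1e-12)
  expect_equal(factor, 2240.88, tolerance = 1e-5)

  expect_error(load_hessian(m6, xyz_structure("C", matrix(0, 1, 3))),
               "does not match")
  asym <- matrix(0, 6, 6); asym[1, 2] <- 1
  expect_error(load_hessian(paste(apply(asym, 1, paste, collapse = " "),
                                  collapse = "\n"), geom), "asymmetry")
})

test_that("ORCA hess write/read round trips the matrix", {
  fx <- random_harmonic_fixture("bonds", seed = 3)
  h <- analytic_hessian(fx$model, fx$geom)
  h2 <- load_hessian(write_orca_hess(h), fx$geom)
  expect_equal(h2$matrix, h$matrix,
               tolerance = 1e-8)
})

test_that("seminario_bond recovers a diatomic harmonic constant exactly", {
  d <- diatomic(k = 500, r = 1.5)
  b <- seminario_bond(d$h, 1, 2)
  expect_equal(b$k_r, 500, tolerance = 1e-9)
  expect_equal(b$r_eq, 1.5, tolerance = 1e-12)
  # zero Hessian
  z <- cart_hessian(matrix(0, 6, 6), d$geom)
  expect_equal(seminario_bond(z, 1, 2)$k_r, 0)
  # direction symmetry
  expect_equal(seminario_bond(d$h, 2, 1)$k_r, b$k_r)
})

test_that("bond constants are invariant under rigid motion", {
  for (seed in 1:6) {
    d <- diatomic(k = 500, r = 1.5, rot_seed = seed,
                  shift = c(seed, -seed, 2))
    expect_equal(seminario_bond(d$h, 1, 2)$k_r, 500, tolerance = 1e-9)
  }
})

test_that("seminario_angle is exact for orthogonal-arm angle fixtures", {
  for (seed in 1:10) {
    fx <- random_harmonic_fixture("angle", seed = 300 + seed)
    h <- analytic_hessian(fx$model, fx$geom)
    a <- fx$model$angles
    got <- seminario_angle(h, a$i, a$j, a$k)
    expect_equal(got$k_theta, a$k_theta, tolerance = 1e-9)
    expect_equal(got$theta_eq, 90, tolerance = 1e-8)
  }
})

test_that("general-angle estimates follow the closed-form geometric factor", {
  # at non-orthogonal arms the reciprocal-sum estimator carries a known
  # cos(theta)-dependent factor; the closed form is the oracle
  for (case in list(c(104.5, 1.0, 1.3, 100), c(120, 1.2, 1.2, 75),
                    c(95, 0.96, 1.8, 140))) {
    th <- case[1]; r1 <- case[2]; r2 <- case[3]; k <- case[4]
    coords <- rbind(c(r1, 0, 0), c(0, 0, 0),
                    c(r2 * cos(th * pi / 180), r2 * sin(th * pi / 180), 0))
    geom <- xyz_structure(c("O", "C", "O"), coords)
    model <- harmonic_model(angles = data.frame(i = 1L, j = 2L, k = 3L,
                                                k_theta = k, theta_eq = th))
    got <- seminario_angle(analytic_hessian(model, geom), 1, 2, 3)
    expect_equal(got$k_theta, seminario_angle_closed_form(k, th, r1, r2),
                 tolerance = 1e-9)
    expect_equal(got$theta_eq, th, tolerance = 1e-8)
  }
})

test_that("zero and collinear angle inputs behave", {
  coords <- rbind(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0))
  geom <- xyz_structure(c("O", "C", "O"), coords)
  z <- cart_hessian(matrix(0, 9, 9), geom)
  expect_warning(a0 <- seminario_angle(z, 1, 2, 3), "clamped")
  expect_equal(a0$k_theta, 0)
  lin <- xyz_structure(c("O", "C", "O"),
                       rbind(c(-1, 0, 0), c(0, 0, 0), c(1, 0, 0)))
  expect_error(seminario_angle(cart_hessian(matrix(0, 9, 9), lin), 1, 2, 3),
               "collinear")
})

test_that("mixed bond+angle models recover within the method's tolerance", {
  # coupled terms contaminate the interatomic blocks; the estimator is an
  # approximation there.  Document the magnitude: bonds within ~1%, and the
  # estimate never goes negative.
  th <- 104.5 * pi / 180
  coords <- rbind(c(0.9572, 0, 0), c(0, 0, 0),
                  c(0.9572 * cos(th), 0.9572 * sin(th), 0))
  geom <- xyz_structure(c("H", "O", "H"), coords)
  model <- harmonic_model(
    bonds = data.frame(i = c(2L, 2L), j = c(1L, 3L), k_r = 800,
                       r_eq = 0.9572),
    angles = data.frame(i = 1L, j = 2L, k = 3L, k_theta = 75,
                        theta_eq = 104.5))
  h <- analytic_hessian(model, geom)
  b <- seminario_bond(h, 2, 1)
  expect_equal(b$k_r, 800, tolerance = 0.01)
  a <- seminario_angle(h, 1, 2, 3)
  expect_gt(a$k_theta, 0)
  expect_equal(a$theta_eq, 104.5, tolerance = 1e-6)
})

test_that("derive_metal_params enumerates contacts and angle triples", {
  dc <- demo_complex()
  h <- analytic_hessian(dc$model, dc$structure)
  g <- detect_bonds(dc$structure)
  mp <- derive_metal_params(h, g)
  expect_equal(nrow(mp$bonds), 4)          # one per Cu-N contact
  expect_equal(nrow(mp$angles), 6 + 12)    # C(4,2) N-Cu-N + 3 H-N-Cu per N
  expect_equal(mp$bonds$k_r, rep(120, 4), tolerance = 1e-9)
  expect_equal(mp$bonds$r_eq, rep(2.05, 4), tolerance = 1e-9)
  expect_true(all(mp$angles$k_theta >= 0))

  # no metal: empty result
  g0 <- detect_bonds(water_structure())
  h0 <- cart_hessian(matrix(0, 9, 9), water_structure())
  mp0 <- derive_metal_params(h0, g0)
  expect_equal(nrow(mp0$bonds), 0)
  expect_equal(nrow(mp0$angles), 0)
})

test_that("square-planar bond-only fixture recovers every k_r exactly", {
  coords <- rbind(c(0, 0, 0), c(2, 0, 0), c(-2, 0, 0), c(0, 2, 0),
                  c(0, -2, 0))
  geom <- xyz_structure(c("Cu", "N", "N", "N", "N"), coords)
  model <- harmonic_model(bonds = data.frame(
    i = 1L, j = 2:5, k_r = 120, r_eq = 2))
  h <- analytic_hessian(model, geom)
  g <- detect_bonds(geom)
  # trans pairs are collinear (skipped with a warning) and the bond-only
  # model leaves zero perpendicular curvature for the cis angles (clamped)
  warns <- character(0)
  mp <- withCallingHandlers(derive_metal_params(h, g),
                            warning = function(w) {
                              warns <<- c(warns, conditionMessage(w))
                              invokeRestart("muffleWarning")
                            })
  expect_true(any(grepl("collinear", warns)))
  expect_equal(mp$bonds$k_r, rep(120, 4), tolerance = 1e-9)
  expect_equal(nrow(mp$angles), 4)
  expect_equal(mp$angles$k_theta, rep(0, 4))
})
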