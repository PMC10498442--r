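test_that("metal and shell atoms get fresh unique types", {
  dc <- demo_complex()
  g <- detect_bonds(dc$structure)
  ty <- assign_atom_types(dc$structure, g)
  fresh <- ty[ty$origin == "new-metal-shell", ]
  expect_equal(nrow(fresh), 5)  # Cu + 4 N
  expect_equal(fresh$type[fresh$element == "Cu"], "M1")
  expect_setequal(fresh$type[fresh$element == "N"],
                  paste0("Y", 1:4))
  expect_equal(anyDuplicated(fresh$type), 0)
  # every atom has exactly one type
  expect_equal(nrow(ty), n_atoms(dc$structure))
  # hydrogens keep their base types
  expect_true(all(ty$type[ty$element == "H"] == "h"))
})

test_that("metal-free systems keep base types; collisions are avoided", {
  w <- water_structure()
  g <- detect_bonds(w)
  ty <- assign_atom_types(w, g, base_types = c("ow", "hw", "hw"))
  expect_equal(ty$type, c("ow", "hw", "hw"))
  expect_true(all(ty$origin == "existing"))

  # base types already using M1: fresh naming skips it
  cun <- xyz_structure(c("Cu", "N"), rbind(c(0, 0, 0), c(2, 0, 0)))
  ty2 <- assign_atom_types(cun, detect_bonds(cun),
                           base_types = c("M1", "n"))
  expect_equal(ty2$type[1], "M2")
})

test_that("a ligand atom bridging two metals gets exactly one fresh type", {
  s <- xyz_structure(c("Cu", "O", "Cu"),
                     rbind(c(-1.9, 0, 0), c(0, 0, 0), c(1.9, 0, 0)))
  g <- detect_bonds(s)
  expect_equal(nrow(g$metal_contacts), 2)
  ty <- assign_atom_types(s, g)
  expect_equal(sum(ty$element == "O" & grepl("^Y", ty$type)), 1)
  expect_equal(anyDuplicated(ty$type), 0)
})

test_that("frcmod formatting writes 4-decimal fixed-width parameters", {
  ty <- data.frame(atom = 1:2, element = c("Cu", "N"),
                   type = c("M1", "Y1"), origin = "new-metal-shell",
                   vdw_radius = c(1.218, 1.824), vdw_eps = c(0.043, 0.17),
                   mass = c(63.546, 14.007))
  ps <- param_set(ty, bonds = data.frame(ti = "M1", tj = "Y1", k_r = 500,
                                         r_eq = 1.5))
  txt <- write_frcmod(ps)
  expect_match(txt, "500\\.0000")
  expect_match(txt, "1\\.5000")
  for (sec in c("MASS", "BOND", "ANGLE", "DIHE", "NONBON"))
    expect_match(txt, paste0("(^|\n)", sec, "(\n|$)"))

  # empty set still carries every section header
  txt0 <- write_frcmod(param_set(ty[0, ]))
  for (sec in c("MASS", "BOND", "ANGLE", "DIHE", "NONBON"))
    expect_match(txt0, sec)

  # a bond referencing an unknown type has no mass entry
  bad <- param_set(ty, bonds = data.frame(ti = "M1", tj = "ZZ", k_r = 1,
                                          r_eq = 1))
  expect_error(write_frcmod(bad), "ZZ")
})

test_that("frcmod write/read round trips randomized parameter sets", {
  set.seed(7)
  for (rep in 1:5) {
    nt <- sample(2:5, 1)
    ty <- data.frame(atom = seq_len(nt), element = rep("C", nt),
                     type = paste0("T", seq_len(nt)), origin = "existing",
                     vdw_radius = round(runif(nt, 1, 2), 4),
                     vdw_eps = round(runif(nt, 0.01, 0.3), 4),
                     mass = round(runif(nt, 1, 200), 4))
    nb <- sample(1:4, 1)
    bonds <- data.frame(ti = paste0("T", sample(nt, nb, replace = TRUE)),
                        tj = paste0("T", sample(nt, nb, replace = TRUE)),
                        k_r = round(runif(nb, 0, 900), 4),
                        r_eq = round(runif(nb, 0.8, 2.5), 4))
    key <- apply(bonds[, 1:2], 1, function(r) paste(sort(r), collapse = "-"))
    bonds <- bonds[!duplicated(key), ]
    angles <- data.frame(ti = "T1", tj = "T2", tk = "T1",
                         k_theta = round(runif(1, 0, 200), 4),
                         theta_eq = round(runif(1, 60, 170), 4))
    ps <- param_set(ty, bonds = bonds, angles = angles)
    rt <- read_frcmod(write_frcmod(ps))
    expect_equal(rt$bonds$k_r, bonds$k_r, tolerance = 1e-4)
    expect_equal(rt$bonds$r_eq, bonds$r_eq, tolerance = 1e-4)
    expect_equal(rt$angles$k_theta, angles$k_theta, tolerance = 1e-4)
    expect_equal(rt$angles$theta_eq, angles$theta_eq, tolerance = 1e-4)
    expect_equal(rt$mass$mass, ty$mass, tolerance = 1e-4)
    expect_equal(rt$nonbon$vdw_radius, ty$vdw_radius, tolerance = 1e-4)
  }
})

test_that("mol2 output counts ATOM and BOND records correctly", {
  w <- water_structure()
  g <- detect_bonds(w)
  txt <- write_mol2(w, c(-0.8, 0.4, 0.4), c("ow", "hw", "hw"), g)
  lines <- strsplit(txt, "\n")[[1]]
  atom_at <- which(lines == "@<TRIPOS>ATOM")
  bond_at <- which(lines == "@<TRIPOS>BOND")
  expect_equal(bond_at - atom_at - 1, 3)
  expect_equal(length(lines) - bond_at, 2)

  one <- xyz_structure("He", matrix(0, 1, 3))
  t1 <- write_mol2(one, 0, "He", detect_bonds(one))
  expect_equal(length(strsplit(t1, "\n")[[1]]) -
                 which(strsplit(t1, "\n")[[1]] == "@<TRIPOS>BOND"), 0)

  # metal contacts appear as explicit bonds
  dc <- demo_complex()
  gg <- detect_bonds(dc$structure)
  tm <- write_mol2(dc$structure, rep(0, 17), rep("du", 17), gg)
  nb <- length(grep("^\\s*\\d+\\s+\\d+\\s+\\d+ 1$",
                    strsplit(tm, "\n")[[1]]))
  expect_equal(nb, nrow(gg$adjacency) + nrow(gg$metal_contacts))
})

test_that("mol2 write/read round trips structure and charges", {
  w <- water_structure()
  g <- detect_bonds(w)
  m <- read_mol2(write_mol2(w, c(-0.834, 0.417, 0.417),
                            c("ow", "hw", "hw"), g))
  expect_identical(m$structure$elements, w$elements)
  expect_equal(m$structure$coords, w$coords, tolerance = 1e-4)
  expect_equal(m$charges, c(-0.834, 0.417, 0.417), tolerance = 1e-6)
  expect_equal(nrow(m$bonds), 2)
})
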