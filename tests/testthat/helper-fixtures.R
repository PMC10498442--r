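# Shared fixtures built in code.

water_xyz <- "3\nwater\nO 0 0 0\nH 0.9572 0 0\nH -0.2399 0.9266 0"

water_structure <- function() read_xyz(water_xyz)

# random geometry with a minimum interatomic separation, for bond-perception
# property tests
random_geometry <- function(n, seed, spread = 4, min_sep = 0.7,
                            elements = NULL) {
  set.seed(seed)
  repeat {
    coords <- matrix(stats::runif(3 * n, -spread, spread), n, 3)
    if (n == 1 || min(stats::dist(coords)) > min_sep) break
  }
  if (is.null(elements))
    elements <- sample(c("C", "N", "O", "H", "S"), n, replace = TRUE)
  xyz_structure(elements, coords)
}

# independent union-find connected components over an explicit edge list
union_find_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  if (nrow(edges)) for (r in seq_len(nrow(edges))) {
    a <- find(edges[r, 1]); b <- find(edges[r, 2])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_len(n), find, 1L)
  split(seq_len(n), match(roots, unique(roots[order(seq_len(n))])))
}

# random rotation matrix from a seeded quaternion
random_rotation_matrix <- function(seed) {
  set.seed(seed)
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(c(1 - 2 * (y^2 + z^2), 2 * (x * y - z * w), 2 * (x * z + y * w)),
        c(2 * (x * y + z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z - x * w)),
        c(2 * (x * z - y * w), 2 * (y * z + x * w), 1 - 2 * (x^2 + y^2)))
}

# closed-form value the reciprocal-sum Seminario estimator returns for a
# pure harmonic angle term E = k (theta - theta0)^2 with arm lengths R1, R2:
# each arm measures k_s (1 - c R_arm/R_other) with k_s = 2k and c = cos(theta);
# the series combination gives the value below (equal to k at c = 0).
seminario_angle_closed_form <- function(k, theta_deg, R1, R2) {
  ks <- 2 * k
  c_ <- cos(theta_deg * pi / 180)
  a <- ks * (1 - c_ * R1 / R2)
  b <- ks * (1 - c_ * R2 / R1)
  a * b / (a + b)
}

# adjusted Rand index (small self-contained implementation; mclust serves
# as the independent cross-check where available)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

water_solvent_template <- function() solvent_template("water")
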