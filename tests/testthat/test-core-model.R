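# Domain types, torsion measurement, cosine terms, MM energy, Kabsch RMSD.

test_that("measure_dihedral follows the IUPAC convention and its contracts", {
  trans <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0))
  cis <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  expect_equal(measure_dihedral(trans, 1:4), 180)
  expect_equal(measure_dihedral(cis, 1:4), 0)
  expect_equal(measure_dihedral(trans, 4:1), measure_dihedral(trans, 1:4))

  # rigid-motion invariance against the recomputed oracle, several torsions
  set.seed(5)
  for (rep in 1:20) {
    g <- rbind(c(0, 1.2, 0.3), c(0, 0, 0), c(1.4, 0, 0),
               c(1.4, 0, 0) + stats::rnorm(3))
    phi <- tryCatch(measure_dihedral(g, 1:4), error = function(e) NULL)
    if (is.null(phi)) next
    g2 <- rigid_transform(g, angles = stats::runif(3, -pi, pi),
                          shift = stats::rnorm(3, 0, 5))
    expect_lt(abs(wrap_angle(measure_dihedral(g2, 1:4) - phi)), 1e-9)
    expect_equal(measure_dihedral(g2, 4:1), measure_dihedral(g2, 1:4))
  }

  collinear <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0))
  expect_error(measure_dihedral(collinear, 1:4),
               class = "phasefit_degenerate_geometry")
  expect_error(measure_dihedral(trans, c(1, 1, 2, 3)), "distinct")
})

test_that("dihedral_term_energy matches Eq-style scalar evaluation", {
  expect_equal(dihedral_term_energy(dihedral_term(1, 2, 180), 90), 2.0)
  expect_equal(dihedral_term_energy(dihedral_term(1, 2, 180), 0), 0.0)

  terms <- list(dihedral_term(0.5, 1, 0), dihedral_term(1.2, 3, 180))
  phi <- 37.3
  oracle <- 0.5 * (1 + cos(pi / 180 * (1 * phi - 0))) +
    1.2 * (1 + cos(pi / 180 * (3 * phi - 180)))
  expect_equal(dihedral_term_energy(terms, phi), oracle, tolerance = 1e-12)

  # periodicity, bounds and the delta = 180 trigonometric identity on a grid
  grid <- seq(-180, 180, by = 7.5)
  for (n in c(1, 2, 3, 4, 6)) {
    t180 <- dihedral_term(0.8, n, 180)
    expect_equal(dihedral_term_energy(t180, grid),
                 dihedral_term_energy(t180, grid + 360))
    expect_equal(dihedral_term_energy(t180, grid),
                 0.8 * (1 - cos(pi / 180 * n * grid)))
    expect_true(all(dihedral_term_energy(t180, grid) >= 0))
    expect_true(all(dihedral_term_energy(t180, grid) <= 2 * 0.8 + 1e-12))
  }
})

test_that("dihedral_term canonicalises negative force constants", {
  t <- dihedral_term(-0.5, 3, 0)
  expect_equal(t$k_phi, 0.5)
  expect_equal(t$delta, 180)
  expect_error(dihedral_term(1, 5, 0), "multiplicity")
  expect_error(dihedral_term(1, 3, 90), "phase")
})

test_that("mm_energy handles the harmonic examples and breakdown contract", {
  sys <- two_atom_system(b = 1.5)
  expect_equal(mm_energy(sys, two_atom_params(100, 1.5), sys$reference_geometry)$total, 0)
  g <- rbind(c(0, 0, 0), c(1.6, 0, 0))
  e <- mm_energy(sys, two_atom_params(100, 1.5), g)
  expect_equal(e$total, 1.0, tolerance = 1e-10)
  expect_equal(unname(e$breakdown["bond"]), 1.0, tolerance = 1e-10)
  expect_equal(sum(e$breakdown), e$total)

  opts_off <- mm_options(bond = FALSE, angle = FALSE, dihedral = FALSE,
                         improper = FALSE, lj = FALSE, coulomb = FALSE)
  expect_identical(mm_energy(sys, two_atom_params(), g, opts_off)$total, 0)
})

test_that("mm_energy equals the brute-force instance enumeration oracle", {
  fx <- get_fixture("fused45-carboxylate", seed = 6)
  sys <- fx$system
  sys$atoms$charge <- round(seq(-0.3, 0.3, length.out = nrow(sys$atoms)), 3)
  p <- fx$truth
  for (t in unique(sys$atoms$type)) p <- ps_set_nonbonded(p, t, 0.06, 1.85)
  set.seed(11)
  for (rep in 1:3) {
    g <- sys$reference_geometry + matrix(stats::rnorm(3 * nrow(sys$atoms), 0, 0.05),
                                         ncol = 3)
    expect_equal(mm_energy(sys, p, g)$total, brute_force_energy(sys, p, g),
                 tolerance = 1e-10)
  }
})

test_that("mm_energy is invariant under rigid motion of the frame", {
  fx <- get_fixture("fused46", seed = 2)
  set.seed(3)
  g <- fx$system$reference_geometry + matrix(stats::rnorm(24, 0, 0.05), ncol = 3)
  e1 <- mm_energy(fx$system, fx$truth, g)$total
  g2 <- rigid_transform(g, angles = c(0.4, -1.1, 2.2), shift = c(3, -8, 0.5))
  expect_equal(mm_energy(fx$system, fx$truth, g2)$total, e1, tolerance = 1e-8)
})

test_that("nonbonded terms exclude 1-2/1-3 pairs and include 1-4", {
  sys <- butane_system(60)
  p <- butane_params()
  # only the (1,4) pair is beyond a 1-3 path in a 4-atom chain
  e <- mm_energy(sys, p, sys$reference_geometry,
                 mm_options(bond = FALSE, angle = FALSE, dihedral = FALSE,
                            improper = FALSE))
  r14 <- measure_bond(sys$reference_geometry, 1, 4)
  eps <- 0.05; rmin <- 2 * 1.9
  lj <- eps * ((rmin / r14)^12 - 2 * (rmin / r14)^6)
  coul <- 332.0716 * 0.1 * 0.1 / r14
  expect_equal(unname(e$breakdown["lj"]), lj, tolerance = 1e-10)
  expect_equal(unname(e$breakdown["coulomb"]), coul, tolerance = 1e-10)
})

test_that("mm_energy names the missing parameter", {
  sys <- butane_system()
  p <- butane_params()
  p$angles[["Q1 Q2 Q3"]] <- NULL
  expect_error(mm_energy(sys, p, sys$reference_geometry),
               class = "phasefit_unparametrised")
  expect_error(mm_energy(sys, p, sys$reference_geometry), "Q1 Q2 Q3")
})

test_that("analytic gradient matches finite differences", {
  fx <- get_fixture("fused45-carboxylate", seed = 6)
  sys <- fx$system
  sys$atoms$charge <- round(seq(-0.2, 0.2, length.out = nrow(sys$atoms)), 3)
  p <- fx$truth
  for (t in unique(sys$atoms$type)) p <- ps_set_nonbonded(p, t, 0.04, 1.9)
  set.seed(2)
  g <- sys$reference_geometry + matrix(stats::rnorm(30, 0, 0.05), ncol = 3)
  grad <- mm_gradient(sys, p, g)
  h <- 1e-6
  fd <- matrix(0, nrow(g), 3)
  for (a in seq_len(nrow(g))) {
    for (c in 1:3) {
      gp <- g; gp[a, c] <- gp[a, c] + h
      gm <- g; gm[a, c] <- gm[a, c] - h
      fd[a, c] <- (mm_energy(sys, p, gp)$total - mm_energy(sys, p, gm)$total) / (2 * h)
    }
  }
  expect_lt(max(abs(grad - fd)) / max(abs(fd)), 1e-4)
})

test_that("kabsch_rmsd satisfies its contracts", {
  set.seed(9)
  a <- matrix(stats::rnorm(15, 0, 2), 5, 3)
  expect_equal(kabsch_rmsd(a, a), 0)
  b <- rigid_transform(a, angles = c(1.2, -0.7, 0.3), shift = c(5, -2, 1))
  expect_lt(kabsch_rmsd(a, b), 1e-9)
  expect_equal(kabsch_rmsd(a, b), kabsch_rmsd(b, a), tolerance = 1e-9)
  expect_error(kabsch_rmsd(a, b, selection = 1:2),
               class = "phasefit_underdetermined")

  # displaced point: brute-force Euler-angle grid search (coarse-to-fine)
  ref <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))
  mob <- ref
  mob[1, ] <- mob[1, ] + c(0, 0, 0.4)
  refc <- sweep(ref, 2, colMeans(ref))
  mobc <- sweep(mob, 2, colMeans(mob))
  euler_rmsd <- function(a, b, c) {
    ra <- rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
    rb <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
    rc <- rbind(c(1, 0, 0), c(0, cos(c), -sin(c)), c(0, sin(c), cos(c)))
    sqrt(sum((mobc %*% t(ra %*% rb %*% rc) - refc)^2) / 4)
  }
  centre <- c(0, 0, 0); width <- pi
  best <- Inf
  for (level in 1:6) {
    grid <- seq(-width, width, length.out = 9)
    vals <- expand.grid(a = centre[1] + grid, b = centre[2] + grid,
                        c = centre[3] + grid)
    r <- mapply(euler_rmsd, vals$a, vals$b, vals$c)
    best <- min(r)
    centre <- as.numeric(vals[which.min(r), ])
    width <- width / 4
  }
  expect_equal(kabsch_rmsd(ref, mob), best, tolerance = 1e-4)
})

test_that("molecule_system enforces its invariants", {
  atoms <- data.frame(element = c("C", "C", "C"), type = c("A", "B", "C"),
                      charge = 0, mass = 12)
  g <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(3, 0, 0))
  expect_error(molecule_system(atoms, rbind(c(1, 2)), g), "connected")
  expect_error(molecule_system(atoms, rbind(c(1, 2), c(2, 4)), g), "range")
  expect_error(molecule_system(atoms, rbind(c(1, 2), c(2, 3)), g[1:2, ]),
               "one coordinate triple")
  sys <- molecule_system(atoms, rbind(c(1, 2), c(2, 3)), g)
  expect_equal(nrow(sys$angles), 1)      # exactly the length-2 simple paths
  expect_equal(nrow(sys$dihedrals), 0)

  # a 4-ring: 4 angles, 4 torsions (length-3 simple paths), no 1-4 pairs
  fx <- get_fixture("ring4", seed = 1)
  expect_equal(nrow(fx$system$angles), 4)
  expect_equal(nrow(fx$system$dihedrals), 4)
  expect_equal(nrow(fx$system$exclusions), 0)
})

test_that("frame validates energies", {
  expect_error(frame(matrix(0, 2, 3), energy = NaN), "finite")
  fr <- frame(matrix(0, 2, 3), energy = 1.5)
  expect_s3_class(fr, "frame")
})
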