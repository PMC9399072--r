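# MM profiles, grid minima, conformer search, GROMOS clustering and the
# validation verdict.

test_that("mm_profile is self-consistent on generator scans", {
  fx <- get_fixture("chain", seed = 1)
  scans <- get_plan_scans("chain", seed = 1)
  prof <- mm_profile(fx$system, fx$truth, scans[[1]])
  expect_lt(attr(prof, "rmse"), 1e-8)
  expect_equal(prof$mm_rel, prof$target_rel, tolerance = 1e-7)

  # all-zero dihedral k -> profile equals the baseline
  zeroed <- zero_k_start(fx$truth)
  prof0 <- mm_profile(fx$system, zeroed, scans[[1]])
  base <- scan_baseline(fx$system, zeroed,
                        scans[[1]], dihedral_group("none", character(), 1L))
  expect_equal(prof0$mm_rel, base, tolerance = 1e-10)
})

test_that("locate_minima handles 1D grids with and without wrap", {
  phi <- seq(-90, 90, by = 10)
  e <- dihedral_term_energy(dihedral_term(1, 2, 180), phi)
  lm <- locate_minima(e, phi)
  expect_equal(lm$minima$phi1, 0)          # grid does not span +-180
  expect_true(is.na(lm$flip_barrier))

  # periodic wrap: minima of an n=2 term over the full circle
  phi2 <- seq(-180, 170, by = 10)
  e2 <- dihedral_term_energy(dihedral_term(1, 2, 180), phi2)
  lm2 <- locate_minima(e2, phi2)
  expect_setequal(lm2$minima$phi1, c(-180, 0))

  expect_error(locate_minima(c(1, 2), c(0, 10)), class = "phasefit_grid_error")
})

test_that("2D minima match brute-force enumeration on separable surfaces", {
  p1 <- seq(-80, 80, by = 10); p2 <- seq(-80, 80, by = 10)
  f <- function(x) cos(3 * pi / 180 * x)   # interior minima at +-60
  E <- outer(f(p1), f(p2), `+`)
  lm <- locate_minima(E, list(p1, p2))
  # brute-force 8-neighbour enumeration
  brute <- list()
  for (i in 2:(length(p1) - 1)) {
    for (j in 2:(length(p2) - 1)) {
      nb <- E[(i - 1):(i + 1), (j - 1):(j + 1)]
      if (E[i, j] < min(nb[-5])) brute[[length(brute) + 1L]] <- c(p1[i], p2[j])
    }
  }
  expect_equal(nrow(lm$minima), length(brute))
  got <- paste(lm$minima$phi1, lm$minima$phi2)
  expect_setequal(got, vapply(brute, function(x) paste(x[1], x[2]),
                              character(1)))
  # separable two-by-two minima form the Cartesian product
  expect_equal(nrow(lm$minima), 4)
})

test_that("the coupled-flip surface has two low minima joined by a low valley", {
  # the reference pucker sits near (-30, +30); +-84 brackets both the
  # reference and the mirror minimum away from the grid boundary
  ff <- get_fixture("fused45", seed = 4, flip_mode = TRUE)
  scan2 <- cached("scan2d-flip-fine",
                  generate_scan(ff, ff$flip_dihedrals, range = 84, step = 14))
  u1 <- sort(unique(scan2$rows$phi1)); u2 <- sort(unique(scan2$rows$phi2))
  E <- matrix(scan2$rows$energy, nrow = length(u1), byrow = TRUE)
  E <- E - min(E)
  lm <- locate_minima(E, list(u1, u2))
  expect_gte(nrow(lm$minima), 2)
  two <- lm$minima[1:2, ]
  # opposite quadrants (phi1 and phi2 swap signs between the two minima)
  expect_lt(two$phi1[1] * two$phi1[2], 0)
  expect_lt(two$phi2[1] * two$phi2[2], 0)
  expect_lt(abs(two$energy[2] - two$energy[1]), 0.25)   # near-degenerate
  expect_lt(lm$flip_barrier, 1)                          # almost no barrier
})

test_that("conformer_search is deterministic and converges", {
  fx <- get_fixture("chain", seed = 1)
  quads <- list(fx$system$dihedrals[1, ])
  # amplitude 0: every start reaches the same minimum
  c0 <- conformer_search(fx$system, fx$truth, list(dihedrals = quads,
                                                   amplitude = 0),
                         n_starts = 4, seed = 3)
  coords <- lapply(c0$frames, `[[`, "coordinates")
  for (i in 2:length(coords)) {
    expect_lt(kabsch_rmsd(coords[[1]], coords[[i]]), 1e-3)
  }
  # same seed -> identical frames; different seed -> different starts
  c1 <- conformer_search(fx$system, fx$truth, list(dihedrals = quads,
                                                   amplitude = 45),
                         n_starts = 6, seed = 42)
  c2 <- conformer_search(fx$system, fx$truth, list(dihedrals = quads,
                                                   amplitude = 45),
                         n_starts = 6, seed = 42)
  expect_equal(lapply(c1$frames, `[[`, "coordinates"),
               lapply(c2$frames, `[[`, "coordinates"))
  # minimised energies are at or below the (already minimal) reference energy
  eref <- mm_energy(fx$system, fx$truth, fx$system$reference_geometry)$total
  for (f in c1$frames) expect_lte(f$energy, eref + 1e-6)
})

test_that("gromos_cluster reproduces brute-force neighbour counting", {
  set.seed(8)
  base1 <- matrix(stats::rnorm(15, 0, 1.5), 5, 3)
  base2 <- base1
  base2[1, ] <- base2[1, ] + c(1.2, 0, 0)   # internal deformation ~1 A
  frames <- c(lapply(1:4, function(i) base1 + stats::rnorm(15, 0, 0.01)),
              lapply(1:3, function(i) base2 + stats::rnorm(15, 0, 0.01)))
  cl <- gromos_cluster(frames, cutoff = 0.2)
  expect_length(cl$clusters, 2)
  expect_setequal(cl$clusters[[1]]$members, 1:4)
  expect_setequal(cl$clusters[[2]]$members, 5:7)
  expect_equal(sum(vapply(cl$clusters, `[[`, numeric(1), "fraction")), 1)
  # every member within the cutoff of its centroid (exact assertion)
  for (c_ in cl$clusters) {
    for (m in c_$members) expect_lte(cl$rmsd[c_$centroid, m], cl$cutoff)
  }
  # singleton
  cl1 <- gromos_cluster(frames[1], cutoff = 0.2)
  expect_length(cl1$clusters, 1)
  expect_equal(cl1$clusters[[1]]$fraction, 1.0)
  # all identical
  clid <- gromos_cluster(rep(list(base1), 5), cutoff = 0.2)
  expect_length(clid$clusters, 1)
  expect_equal(length(clid$clusters[[1]]$members), 5)

  # partition invariance under frame reordering
  perm <- c(3, 7, 1, 5, 2, 6, 4)
  clp <- gromos_cluster(frames[perm], cutoff = 0.2)
  part1 <- lapply(cl$clusters, function(c_) sort(c_$members))
  part2 <- lapply(clp$clusters, function(c_) sort(perm[c_$members]))
  expect_setequal(vapply(part1, paste, character(1), collapse = ","),
                  vapply(part2, paste, character(1), collapse = ","))
})

test_that("validate_parameters passes ground truth and fails a flipped set", {
  fx <- get_fixture("chain", seed = 7)
  scans <- get_plan_scans("chain", seed = 7)
  cfg <- run_config(seed = 11)
  rep_ok <- validate_parameters(fx$system, fx$truth, scans, config = cfg,
                                n_starts = 12)
  expect_true(rep_ok$verdict)
  expect_lt(rep_ok$top_cluster_rmsd, 0.05)

  # deliberately phase-flipped parameters: barrier at the reference torsion,
  # displaced MM minimum, failing verdict
  p_flip <- flip_all_phases(fx$truth)
  prof <- mm_profile(fx$system, p_flip, scans[[1]])
  ref_phi <- measure_dihedral(fx$system$reference_geometry,
                              scans[[1]]$driven[[1]])
  i0 <- which.min(abs(prof$phi1 - ref_phi))
  expect_gt(prof$mm_rel[i0], prof$mm_rel[i0 - 1])
  expect_gt(prof$mm_rel[i0], prof$mm_rel[i0 + 1])
  rep_bad <- validate_parameters(fx$system, p_flip, scans, config = cfg,
                                 n_starts = 12)
  expect_false(rep_bad$verdict)
  expect_false(all(stats::na.omit(rep_bad$scan_report$min_ok)))
})

test_that("flip fixtures produce two dominant clusters and a flip annotation", {
  ff <- get_fixture("fused45", seed = 4, flip_mode = TRUE)
  scans <- cached("flip-scan-1d", list(
    generate_scan(ff, ff$flip_dihedrals[[1]], range = 60, step = 15)))
  cfg <- run_config(seed = 5)
  rep <- validate_parameters(ff$system, ff$truth, scans, config = cfg,
                             perturb = list(dihedrals = ff$flip_dihedrals,
                                            amplitude = 60),
                             n_starts = 50)
  expect_equal(rep$n_dominant_clusters, 2L)
  expect_true(rep$flip)
  expect_true(rep$verdict)
  expect_lt(rep$top_cluster_rmsd, 0.05)
})

test_that("rank_assignments orders by top-cluster RMSD then scan RMSE", {
  fx <- get_fixture("chain", seed = 7)
  scans <- get_plan_scans("chain", seed = 7)
  cfg <- run_config(seed = 11)
  reports <- list(
    default = validate_parameters(fx$system, fx$truth, scans, config = cfg,
                                  n_starts = 8),
    flipped = validate_parameters(fx$system, flip_all_phases(fx$truth), scans,
                                  config = cfg, n_starts = 8))
  rk <- rank_assignments(reports)
  expect_equal(rk$assignment[1], "default")
  expect_true(rk$verdict[1])
  expect_false(rk$verdict[2])
})
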