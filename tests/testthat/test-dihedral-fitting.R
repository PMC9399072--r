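# Torsion-scan fitting: baselines, NNLS with fixed phases, exclusion rule,
# augmentation, group-sequential workflow and the two-fold symmetry rule.

test_that("scan_baseline matches the generator's recorded decomposition", {
  fx <- get_fixture("ring5", seed = 1)
  scans <- get_plan_scans("ring5", seed = 1)
  scan <- scans[[1]]
  grp <- fx$groups[[1]]
  base <- scan_baseline(fx$system, fx$truth, scan, grp)
  br <- attr(scan, "true_breakdown")
  te <- attr(scan, "true_term_energy")
  in_group <- grepl(paste0("^(", paste(gsub("([()])", "\\\\\\1", grp$members),
                                       collapse = "|"), ") \\| "),
                    colnames(te))
  oracle <- rowSums(br) - rowSums(te[, in_group, drop = FALSE])
  oracle <- oracle - min(oracle)
  expect_equal(base, oracle[scan$rows$frame], tolerance = 1e-8)

  # empty group -> full MM profile (min-subtracted)
  empty <- dihedral_group("none", character(), 1L)
  b2 <- scan_baseline(fx$system, fx$truth, scan, empty)
  full <- rowSums(br)[scan$rows$frame]
  expect_equal(b2, full - min(full), tolerance = 1e-10)

  # all dihedral types zeroed, all other classes disabled -> identically 0
  allg <- dihedral_group("all", names(fx$truth$dihedrals), 1L)
  b3 <- scan_baseline(fx$system, fx$truth, scan, allg,
                      mm_options(bond = FALSE, angle = FALSE, improper = FALSE,
                                 lj = FALSE, coulomb = FALSE))
  expect_equal(b3, rep(0, nrow(scan$rows)))
})

test_that("fit_group recovers known constants and matches a grid search", {
  fx <- get_fixture("chain", seed = 1)
  scans <- get_plan_scans("chain", seed = 1)
  grp <- dihedral_group("all", names(fx$truth$dihedrals), 1L)
  start <- zero_k_start(fx$truth)
  fit <- fit_group(fx$system, start, scans, grp)
  tt <- truth_term_table(fx$truth)
  expect_lt(max(abs(fit$fitted[tt$id] - tt$k_phi)), 1e-6)
  expect_lt(fit$rmse_after, 1e-8)
  expect_lte(fit$rmse_after, fit$rmse_before + 1e-9)
  expect_equal(fit$points_used + fit$points_excluded,
               sum(vapply(scans, function(s) nrow(s$rows), numeric(1))))

  # linear objective: brute-force grid search over k agrees to grid resolution
  kgrid <- seq(0, 10, by = 0.01)
  scan <- scans[[1]]
  e_rel <- scan$rows$energy - min(scan$rows$energy)
  base <- scan_baseline(fx$system, start, scan, grp)
  basis <- phasefit:::term_basis(fx$system, scan, tt$type_key[1], tt$n[1],
                                 tt$delta[1])
  sse <- vapply(kgrid, function(k) {
    r <- e_rel - base - k * basis
    sum((r - mean(r))^2)
  }, numeric(1))
  expect_lt(abs(kgrid[which.min(sse)] - fit$fitted[[tt$id[1]]]), 0.01)
})

test_that("target equal to baseline fits all k to zero", {
  fx <- get_fixture("ring4", seed = 2)
  scans <- get_plan_scans("ring4", seed = 2)
  grp <- dihedral_group("all", names(fx$truth$dihedrals), 1L)
  zeroed <- zero_k_start(fx$truth)
  # replace scan energies by the zero-k model's own energies
  scans0 <- lapply(scans, function(s) {
    model <- phasefit:::compile_model(fx$system, zeroed, mm_options())
    s$rows$energy <- vapply(s$frames[s$rows$frame], function(g) {
      sum(phasefit:::energy_breakdown_fast(model, g))
    }, numeric(1))
    s
  })
  fit <- fit_group(fx$system, zeroed, scans0, grp)
  expect_lt(max(fit$fitted), 1e-8)
  expect_lt(fit$rmse_after, 1e-9)
})

test_that("the 10 kcal/mol cutoff equals deleting rows up front", {
  fx <- get_fixture("ring4", seed = 1)
  scans <- get_plan_scans("ring4", seed = 1)
  grp <- dihedral_group("all", names(fx$truth$dihedrals), 1L)
  start <- zero_k_start(fx$truth)
  scan <- scans[[1]]
  e_rel <- scan$rows$energy - min(scan$rows$energy)
  expect_gt(sum(e_rel > 10), 0)        # the +-45 ring scan does exceed 10

  fit_all <- fit_group(fx$system, start, list(scan), grp, cutoff = 10)
  pre <- scan
  keep <- which(e_rel <= 10)
  pre$rows <- pre$rows[keep, , drop = FALSE]
  fit_pre <- fit_group(fx$system, start, list(pre), grp, cutoff = Inf)
  expect_identical(fit_all$fitted, fit_pre$fitted)
  expect_identical(fit_all$rmse_after, fit_pre$rmse_after)
  expect_equal(fit_all$points_used, nrow(pre$rows))

  # cutoff excluding everything is an error
  high <- scan
  high$rows$energy <- high$rows$energy + c(0, rep(100, nrow(high$rows) - 1))
  expect_error(fit_group(fx$system, start, list(high), grp, cutoff = -1),
               class = "phasefit_empty_fit")
})

test_that("unidentifiable terms keep their incoming constants", {
  # a carboxylate scan does not move the distant 4-ring torsions: fitting the
  # whole parameter set against it leaves those terms untouched
  fx <- get_fixture("fused45-carboxylate", seed = 1)
  piv <- fx$scan_plan[[which(vapply(fx$scan_plan, function(p) p$range == 180,
                                    logical(1)))]]
  scan <- cached("carbox-pivot-scan",
                 generate_scan(fx, piv$driven, range = 180, step = 10))
  grp <- dihedral_group("all", names(fx$truth$dihedrals), 1L)
  fit <- fit_group(fx$system, fx$truth, list(scan), grp)
  expect_gt(length(fit$unidentifiable), 0)
  tt <- truth_term_table(fx$truth)
  for (id in fit$unidentifiable) {
    expect_equal(fit$fitted[[id]], tt$k_phi[tt$id == id],
                 info = id)
  }
})

test_that("noisy fits stay within the statistical envelope", {
  fx <- get_fixture("ring5", seed = 2)
  scans <- get_plan_scans("ring5", seed = 2)
  grp <- dihedral_group("all", names(fx$truth$dihedrals), 1L)
  start <- zero_k_start(fx$truth)
  tt <- truth_term_table(fx$truth)
  errs <- c()
  for (rep in 1:5) {
    noisy <- lapply(seq_along(scans), function(s) {
      scan_with_noise(scans[[s]], 0.1, 31 * rep + s)
    })
    fit <- fit_group(fx$system, start, noisy, grp)
    errs <- c(errs, abs(fit$fitted[tt$id] - tt$k_phi))
    expect_lte(fit$rmse_after, fit$rmse_before + 1e-9)
  }
  expect_lt(stats::median(errs), 0.1)
})

test_that("augmentation recovers a missing term and respects the threshold", {
  fx <- get_fixture("chain", seed = 9)
  key <- names(fx$truth$dihedrals)[1]
  target <- ps_set_dihedral_term(fx$truth, phasefit:::key_types(key),
                                 dihedral_term(0.3, 4L, 0))
  scans <- cached("chain9-augment-scans",
                  generate_plan_scans(fx, params = target))
  grp <- dihedral_group("all", names(fx$truth$dihedrals), 1L)

  res <- augment_multiplicities(fx$system, fx$truth, scans, grp,
                                accept_threshold = 0.10)
  acc <- res$report[res$report$accepted, ]
  expect_equal(nrow(acc), 1)
  expect_equal(acc$n, 4)
  expect_equal(acc$delta, 0)
  got <- Filter(function(t) t$n == 4, res$params$dihedrals[[key]])[[1]]
  expect_lt(abs(got$k_phi - 0.3), 1e-4)
  # every trial carries its RMSE; both phases of each candidate were tried
  expect_true(all(table(res$report$n[!res$report$accepted |
                                       res$report$accepted]) >= 1))
  expect_true(all(c(0, 180) %in% res$report$delta))

  # base fit already exact -> nothing accepted
  scans0 <- get_plan_scans("chain", seed = 9)
  res0 <- augment_multiplicities(fx$system, fx$truth, scans0, grp,
                                 accept_threshold = 0.10)
  expect_false(any(res0$report$accepted))
  # augmentation never increases the RMSE
  base0 <- fit_group(fx$system, fx$truth, scans0, grp)
  expect_lte(res0$fit$rmse_after, base0$rmse_after + 1e-12)
})

test_that("fit_workflow is stable at a fixed point and monotone", {
  fx <- get_fixture("chain", seed = 1)
  scans <- get_plan_scans("chain", seed = 1)
  grp <- dihedral_group("all", names(fx$truth$dihedrals), 1L)
  start <- zero_k_start(fx$truth)
  wf1 <- fit_workflow(fx$system, start, scans, list(grp), iterations = 1)
  wf2 <- fit_workflow(fx$system, start, scans, list(grp), iterations = 2)
  t1 <- truth_term_table(wf1$params); t2 <- truth_term_table(wf2$params)
  expect_lt(max(abs(t1$k_phi - t2$k_phi)), 1e-8)
  expect_true(all(wf2$scan_rmse_by_iteration[, 2] <=
                    wf2$scan_rmse_by_iteration[, 1] + 1e-9))
  expect_error(fit_workflow(fx$system, start, scans,
                            list(grp, dihedral_group("dup", grp$members, 2L))),
               "disjoint")
})

test_that("double-bond-first ordering puts the largest 6-ring k on the double bond", {
  # realistic starting point: the corrupted database-like set (phases wrong,
  # constants plausible), as in the actual protocol
  fx <- get_fixture("fused46", seed = 1, perturb_params = TRUE)
  scans <- get_plan_scans("fused46", seed = 1)
  start <- fx$corrupted
  decs <- apply_double_bond_rule(predict_phases(fx$system, fx$truth), fx$system)
  assign <- enumerate_alternatives(decs)[[1]]
  wf <- fit_workflow(fx$system, start, scans, fx$groups, assignment = assign,
                     iterations = 2)
  # group order honoured: double-bond stage first
  expect_equal(wf$stages[[1]]$group, "double-bond")
  tt <- truth_term_table(wf$params)
  keys <- instance_keys(fx$system, "dihedral")
  dbl_key <- unique(keys[fx$system$dihedrals[, 2] %in% c(6, 7) &
                           fx$system$dihedrals[, 3] %in% c(6, 7)])
  six_ring <- unique(keys[!(fx$system$dihedrals[, 2] %in% 1:4 &
                              fx$system$dihedrals[, 3] %in% 1:4)])
  sub <- tt[tt$type_key %in% six_ring, ]
  expect_equal(sub$type_key[which.max(sub$k_phi)], dbl_key)
  # coupled-group convergence: iteration 2 never worse than iteration 1
  expect_true(all(wf$scan_rmse_by_iteration[, 2] <=
                    wf$scan_rmse_by_iteration[, 1] + 1e-9))
})

test_that("the two-fold symmetry rule assigns n = 2 to carboxylate torsions", {
  fx <- get_fixture("fused45-carboxylate", seed = 1, perturb_params = TRUE)
  # the CGenFF-like corrupted set suggests n = 3 on the carboxylate rotation
  carbox_keys <- fx$groups[[which(vapply(fx$groups, `[[`, character(1),
                                         "name") == "carboxylate")]]$members
  for (key in carbox_keys) {
    ns <- vapply(fx$corrupted$dihedrals[[key]], `[[`, integer(1), "n")
    expect_true(3L %in% ns)
  }
  res <- apply_twofold_symmetry_rule(fx$system, fx$corrupted)
  expect_true(all(carbox_keys %in% res$report$type_key))
  expect_true(all(res$report$n_assigned == 2L))
  for (key in carbox_keys) {
    ns <- vapply(res$params$dihedrals[[key]], `[[`, integer(1), "n")
    expect_equal(ns, 2L)
  }
  # idempotent
  res2 <- apply_twofold_symmetry_rule(fx$system, res$params)
  expect_equal(phasefit:::dihedral_term_df(res2$params),
               phasefit:::dihedral_term_df(res$params))
})
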