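# Synthetic fused-ring fixtures with known ground-truth parameters.
#
# Fixtures are MM-native: the "QM" reference data (geometries, scan energies,
# Hessians) are generated from a ground-truth MM parameter set, so parameter
# recovery is exact in the noiseless limit and protocol correctness is
# separated from QM/MM model error.  Non-flip templates are built strain-free:
# planar (or all-trans) reference geometries whose torsions sit exactly at the
# minima of their cosine terms, with b0/theta0/omega0 equal to the measured
# values and no nonbonded forces (zero charges, zero epsilon) - the built
# geometry is then an exact stationary point of the ground-truth energy.
# flip_mode fixtures instead carry n=4, delta=0 terms on two coupled 5-ring
# torsions and are relaxed into a puckered reference with an exactly
# degenerate mirror conformer (the ring-flip pair).

.ELEMENT_MASS <- c(C = 12.011, N = 14.007, O = 15.999)

#' Specify a synthetic fixture
#'
#' @param template one of `"chain"`, `"ring4"`, `"ring5"`, `"fused45"`,
#'   `"fused46"`, `"fused45-carboxylate"`.
#' @param seed integer; fully determines all stochastic output.
#' @param noise_sigma Gaussian noise (kcal/mol) added to generated scan
#'   energies by default.
#' @param flip_mode build a puckered 5-ring with a near-degenerate flipped
#'   second minimum (supported on the fused45 templates).
#' @param perturb_params also return a "CGenFF-like" corrupted starting set:
#'   about half the angle equilibria biased by 5-20 degrees, every dihedral
#'   phase randomised (and carboxylate multiplicities set to 3), with
#'   penalties > 10 on the corrupted entries.
#' @export
fixture_spec <- function(template = c("chain", "ring4", "ring5", "fused45",
                                      "fused46", "fused45-carboxylate"),
                         seed = 1L, noise_sigma = 0, flip_mode = FALSE,
                         perturb_params = FALSE) {
  template <- match.arg(template)
  if (flip_mode && !template %in% c("fused45", "fused45-carboxylate"))
    stop("flip_mode is supported on the fused45 templates only")
  structure(list(template = template, seed = as.integer(seed),
                 noise_sigma = noise_sigma, flip_mode = flip_mode,
                 perturb_params = perturb_params), class = "fixture_spec")
}

rot2d <- function(v, deg) {
  th <- deg2rad(deg)
  c(cos(th) * v[1] - sin(th) * v[2], sin(th) * v[1] + cos(th) * v[2], 0)
}

# Two regular polygons sharing the edge P1=(0,-L/2) -> P2=(0,+L/2).
fused_ring_coords <- function(m1, m2, L) {
  a1 <- L / (2 * tan(pi / m1)); R1 <- L / (2 * sin(pi / m1))
  a2 <- L / (2 * tan(pi / m2)); R2 <- L / (2 * sin(pi / m2))
  left <- t(vapply(0:(m1 - 1), function(k) {
    ps <- pi / m1 + k * 2 * pi / m1
    c(-a1 + R1 * cos(ps), R1 * sin(ps), 0)
  }, numeric(3)))
  right <- t(vapply(0:(m2 - 1), function(k) {
    ps <- pi - pi / m2 - k * 2 * pi / m2
    c(a2 + R2 * cos(ps), R2 * sin(ps), 0)
  }, numeric(3)))
  # ring1 atoms ordered P1, unique left vertices from P1 side, P2
  ring1 <- left[c(m1, (m1 - 1):2, 1), , drop = FALSE]
  ring2_extra <- right[2:(m2 - 1), , drop = FALSE]   # P2 side -> P1 side
  list(ring1 = ring1, ring2_extra = ring2_extra)
}

template_topology <- function(template) {
  L <- 1.53
  if (template == "chain") {
    n <- 5
    xyz <- matrix(0, n, 3)
    heading <- 0
    turn <- 180 - 112
    for (i in 2:n) {
      xyz[i, ] <- xyz[i - 1, ] + L * c(cos(deg2rad(heading)),
                                       sin(deg2rad(heading)), 0)
      heading <- heading + if (i %% 2 == 0) turn else -turn
    }
    return(list(
      coords = xyz,
      elements = rep("C", n),
      types = c("CM", "CT", "CC0", "CT", "CM"),
      bonds = cbind(1:4, 2:5),
      orders = NULL, impropers = NULL,
      ring4_bonds = NULL, ring5_bonds = NULL, double_bonds = NULL,
      pivot_bond = NULL, heavy = 1:n))
  }
  if (template %in% c("ring4", "ring5")) {
    m <- if (template == "ring4") 4 else 5
    R <- L / (2 * sin(pi / m))
    xyz <- t(vapply(0:(m - 1), function(k) {
      c(R * cos(2 * pi * k / m), R * sin(2 * pi * k / m), 0)
    }, numeric(3)))
    bonds <- cbind(1:m, c(2:m, 1))
    # one carbon type, as in cyclobutane/cyclopentane: the ring torsion is a
    # single multi-instance dihedral type
    types <- rep(paste0("R", m), m)
    return(list(coords = xyz, elements = rep("C", m), types = types,
                bonds = bonds, orders = NULL, impropers = NULL,
                ring4_bonds = if (m == 4) bonds else NULL,
                ring5_bonds = if (m == 5) bonds else NULL,
                double_bonds = NULL, pivot_bond = NULL, heavy = 1:m))
  }
  if (template %in% c("fused45", "fused46", "fused45-carboxylate")) {
    m2 <- if (template == "fused46") 6 else 5
    fr <- fused_ring_coords(4, m2, L)
    xyz <- rbind(fr$ring1, fr$ring2_extra)
    n_ring <- nrow(xyz)                       # 7 (fused45) or 8 (fused46)
    bonds <- rbind(cbind(1:3, 2:4), c(1, 4),
                   cbind(c(4, 4 + seq_len(m2 - 3)), c(5, 5 + seq_len(m2 - 3))),
                   c(n_ring, 1))
    elements <- rep("C", n_ring)
    # types respect the molecule's mirror symmetry (bridgeheads 1/4 swap,
    # 2<->3 and the partner-ring flanks swap), as a chemical type assignment
    # would; symmetric instances then share one parameter
    types <- if (template == "fused46") {
      c("GB", "GR4", "GR4", "GB", "GR6", "GR6A", "GR6A", "GR6")
    } else {
      c("FB", "FR4", "FR4", "FB", "FR5", "FR5A", "FR5")
    }
    orders <- NULL; impropers <- NULL; pivot <- NULL
    ring4_bonds <- rbind(cbind(1:3, 2:4), c(1, 4))
    ring5_bonds <- rbind(cbind(c(4, 4 + seq_len(m2 - 3)),
                               c(5, 5 + seq_len(m2 - 3))), c(n_ring, 1))
    if (template == "fused46") {
      orders <- setNames(rep(1, nrow(bonds)),
                         paste0(pmin(bonds[, 1], bonds[, 2]), "-",
                                pmax(bonds[, 1], bonds[, 2])))
      orders["6-7"] <- 2
    }
    if (template == "fused45-carboxylate") {
      apex <- 6
      ctr2 <- c(L / (2 * tan(pi / 5)), 0, 0)
      u <- xyz[apex, ] - ctr2
      u <- u / sqrt(sum(u^2))
      c8 <- xyz[apex, ] + 1.52 * u
      o9 <- c8 + 1.25 * rot2d(-u, 118)
      o10 <- c8 + 1.25 * rot2d(-u, -118)
      xyz <- rbind(xyz, c8, o9, o10)
      elements <- c(elements, "C", "O", "O")
      types <- c(types, "CC", "OC", "OC")
      bonds <- rbind(bonds, c(apex, 8), c(8, 9), c(8, 10))
      impropers <- matrix(c(8, 9, 10, apex), nrow = 1)
      pivot <- c(apex, 8)
    }
    return(list(coords = xyz, elements = elements, types = types,
                bonds = bonds, orders = orders, impropers = impropers,
                ring4_bonds = ring4_bonds, ring5_bonds = ring5_bonds,
                double_bonds = if (template == "fused46") matrix(c(6, 7), 1) else NULL,
                pivot_bond = pivot, heavy = seq_len(n_ring)))
  }
  stop("unknown template")
}

bond_id <- function(i, j) paste0(min(i, j), "-", max(i, j))

bond_in_set <- function(i, j, set) {
  if (is.null(set)) return(FALSE)
  any(pmin(set[, 1], set[, 2]) == min(i, j) &
        pmax(set[, 1], set[, 2]) == max(i, j))
}

#' Build a synthetic fixture
#'
#' @param spec a [fixture_spec()].
#' @return A `fixture`: list with the `system`, ground-truth `truth` and
#'   `corrupted` parameter sets, dihedral `groups`, a `scan_plan`, and for
#'   flip fixtures the two coupled `flip_dihedrals`.
#' @export
make_fixture <- function(spec) {
  if (is.character(spec)) spec <- fixture_spec(spec)
  topo <- template_topology(spec$template)
  atoms <- data.frame(element = topo$elements, type = topo$types,
                      charge = 0, mass = unname(.ELEMENT_MASS[topo$elements]),
                      stringsAsFactors = FALSE)
  sys <- molecule_system(atoms, topo$bonds, topo$coords,
                         bond_orders = topo$orders, impropers = topo$impropers,
                         selections = list("ring-heavy" = topo$heavy))

  truth <- parameter_set()
  with_seed(spec$seed, {
    # bonds / angles / impropers: harmonic at the measured (exact) values
    for (key in unique(instance_keys(sys, "bond"))) {
      inst <- instances_by_key(sys, "bond")[[key]]
      b0 <- measure_bond(topo$coords, inst[1, 1], inst[1, 2])
      truth <- ps_set_bond(truth, key_types(key),
                            round(stats::runif(1, 250, 350), 2), b0)
    }
    ring5_atoms <- unique(as.integer(topo$ring5_bonds))
    for (key in unique(instance_keys(sys, "angle"))) {
      inst <- as.matrix(instances_by_key(sys, "angle")[[key]])
      th0 <- measure_angle(topo$coords, inst[1, 1], inst[1, 2], inst[1, 3])
      soft <- spec$flip_mode && all(inst[1, ] %in% ring5_atoms)
      kth <- if (soft) round(stats::runif(1, 35, 45), 2)
             else round(stats::runif(1, 50, 90), 2)
      truth <- ps_set_angle(truth, key_types(key), kth, th0)
    }
    if (!is.null(sys$impropers)) {
      for (key in unique(instance_keys(sys, "improper"))) {
        inst <- as.matrix(instances_by_key(sys, "improper")[[key]])
        w0 <- measure_dihedral(topo$coords, inst[1, ])
        truth <- ps_set_improper(truth, key_types(key), 60, w0)
      }
    }

    # dihedral terms: multiplicities cycle 2,3,4,1 over the sorted type keys
    # so that co-varying ring torsions carry functionally distinct cosine
    # columns; phases are predicted from the geometry (exact minima by
    # construction on the planar/trans templates)
    dkeys <- instance_keys(sys, "dihedral")
    rep_bond <- vapply(sort(unique(dkeys)), function(key) {
      r <- which(dkeys == key)[1]
      bond_id(sys$dihedrals[r, 2], sys$dihedrals[r, 3])
    }, character(1))
    n_cycle <- c(2L, 3L, 4L, 1L)
    flip_bonds <- character(); zero_bonds <- character()
    if (spec$flip_mode) {
      rb <- topo$ring5_bonds
      # flip pair: the two 5-ring bonds not touching the fused edge atoms 1/4
      touch_fuse <- (rb[, 1] %in% c(1, 4)) | (rb[, 2] %in% c(1, 4))
      flip_bonds <- apply(rb[!touch_fuse, , drop = FALSE], 1,
                          function(b) bond_id(b[1], b[2]))
      zero_bonds <- apply(rb[touch_fuse, , drop = FALSE], 1,
                          function(b) bond_id(b[1], b[2]))
    }
    cycle_pos <- 0L
    for (key in names(rep_bond)) {
      bid <- rep_bond[[key]]
      ij <- as.integer(strsplit(bid, "-")[[1]])
      dbl <- bond_in_set(ij[1], ij[2], topo$double_bonds)
      pivot <- !is.null(topo$pivot_bond) &&
        bond_id(topo$pivot_bond[1], topo$pivot_bond[2]) == bid
      quads <- dihedral_instances_of(sys, key)
      phis <- measure_dihedrals(topo$coords, quads)
      if (bid %in% flip_bonds) {
        truth <- ps_set_dihedral_term(truth, key_types(key),
                                      dihedral_term(0.35, 4L, 0))
        next
      }
      if (bid %in% zero_bonds) {
        truth <- ps_set_dihedral_term(truth, key_types(key),
                                      dihedral_term(0, 3L, 180))
        next
      }
      n <- if (dbl || pivot) 2L else n_cycle[cycle_pos %% 4L + 1L]
      cycle_pos <- cycle_pos + 1L
      k <- if (dbl) 8.5 else if (pivot) round(stats::runif(1, 0.3, 0.8), 4)
           else round(stats::runif(1, 0.3, 2.2), 4)
      if (spec$flip_mode && n %% 2L == 1L) n <- 2L  # keep ring terms even-n
      delta <- predict_phase_summed(n, phis)$delta
      truth <- ps_set_dihedral_term(truth, key_types(key),
                                    dihedral_term(k, n, delta))
    }
    if (spec$template == "fused46") {
      # one type carries two terms, exercising term-list accumulation
      key56 <- names(rep_bond)[rep_bond == bond_id(5, 6)][1]
      have_n <- vapply(truth$dihedrals[[key56]], `[[`, integer(1), "n")
      n_extra <- setdiff(c(4L, 6L, 1L), have_n)[1]
      truth <- ps_set_dihedral_term(truth, key_types(key56),
                                    dihedral_term(0.4, n_extra, 180))
    }
    for (t in unique(atoms$type)) truth <- ps_set_nonbonded(truth, t, 0, 1.8)
  })

  flip_dihedrals <- NULL
  if (spec$flip_mode) {
    rb <- topo$ring5_bonds
    touch_fuse <- (rb[, 1] %in% c(1, 4)) | (rb[, 2] %in% c(1, 4))
    fb <- rb[!touch_fuse, , drop = FALSE]
    flip_dihedrals <- lapply(seq_len(nrow(fb)), function(r) {
      quads <- sys$dihedrals[sys$dihedrals[, 2] == fb[r, 1] &
                               sys$dihedrals[, 3] == fb[r, 2] |
                               sys$dihedrals[, 2] == fb[r, 2] &
                               sys$dihedrals[, 3] == fb[r, 1], , drop = FALSE]
      quads[1, ]
    })
    # pucker the 5-ring apex out of plane and relax into one flip basin
    start <- topo$coords
    apex <- setdiff(unique(as.integer(rb)), c(1, 4))
    mid <- apex[ceiling(length(apex) / 2)]
    start[mid, 3] <- start[mid, 3] + 0.55
    start[setdiff(apex, mid), 3] <- start[setdiff(apex, mid), 3] + 0.15
    res <- minimise_frame(sys, truth, start, tol = 1e-6, maxit = 8000)
    if (!res$converged)
      stop("flip fixture construction failed to reach a minimum (max grad ",
           format(res$max_grad), ")")
    sys$reference_geometry <- res$coordinates
    # phases of zero-k terms follow the final geometry; nonzero-k phases must
    # already be the geometric optimum (construction invariant)
    dkeys <- instance_keys(sys, "dihedral")
    for (key in names(truth$dihedrals)) {
      quads <- sys$dihedrals[dkeys == key, , drop = FALSE]
      if (!nrow(quads)) next
      phis <- measure_dihedrals(sys$reference_geometry, quads)
      for (t in truth$dihedrals[[key]]) {
        d_geo <- predict_phase_summed(t$n, phis)$delta
        if (t$k_phi == 0) {
          truth <- ps_set_dihedral_term(truth, key_types(key),
                                        dihedral_term(0, t$n, d_geo))
        } else if (d_geo != t$delta) {
          stop("flip fixture construction violated the phase invariant for '",
               key, "' (n=", t$n, ")")
        }
      }
    }
  } else {
    g <- mm_gradient(sys, truth, sys$reference_geometry)
    if (max(abs(g)) > 1e-6)
      stop("fixture reference geometry is not a stationary point (max grad ",
           format(max(abs(g))), ")")
  }

  corrupted <- truth
  if (spec$perturb_params) {
    corrupted <- with_seed(spec$seed + 1000L, {
      p <- truth
      akeys <- names(p$angles)
      biased <- sort(sample(akeys, ceiling(length(akeys) / 2)))
      for (key in biased) {
        shift <- stats::runif(1, 5, 20) * sample(c(-1, 1), 1)
        th <- min(170, max(20, p$angles[[key]]$theta0 + shift))
        p <- ps_set_angle(p, key_types(key), p$angles[[key]]$k, th,
                          penalty = round(stats::runif(1, 15, 60), 3))
      }
      for (key in names(p$dihedrals)) {
        terms <- p$dihedrals[[key]]
        pivot_key <- !is.null(topo$pivot_bond) && length(terms) == 1 &&
          terms[[1]]$n == 2L && grepl("OC", key)
        new_terms <- lapply(terms, function(t) {
          n <- if (pivot_key) 3L else t$n    # CGenFF-like n=3 on carboxylate
          dihedral_term(t$k_phi, n, sample(c(0, 180), 1))
        })
        p$dihedrals[[key]] <- new_terms[order(vapply(new_terms, `[[`,
                                                     integer(1), "n"))]
        p <- set_penalty(p, "dihedral", key, round(stats::runif(1, 15, 60), 3))
      }
      p
    })
  }

  groups <- fixture_groups(sys, topo, spec$template)
  scan_plan <- fixture_scan_plan(sys, topo)

  structure(list(spec = spec, system = sys, truth = truth,
                 corrupted = corrupted, groups = groups,
                 scan_plan = scan_plan, flip_dihedrals = flip_dihedrals),
            class = "fixture")
}

fixture_groups <- function(sys, topo, template) {
  dkeys <- instance_keys(sys, "dihedral")
  bond_of_key <- vapply(seq_len(nrow(sys$dihedrals)), function(r) {
    bond_id(sys$dihedrals[r, 2], sys$dihedrals[r, 3])
  }, character(1))
  key_bond <- tapply(bond_of_key, dkeys, `[`, 1)
  in_set <- function(set) {
    if (is.null(set)) return(character())
    ids <- apply(set, 1, function(b) bond_id(b[1], b[2]))
    sort(names(key_bond)[key_bond %in% ids])
  }
  ring4 <- in_set(topo$ring4_bonds)
  dbl <- in_set(topo$double_bonds)
  ring4 <- setdiff(ring4, dbl)
  pivot <- if (!is.null(topo$pivot_bond)) {
    sort(names(key_bond)[key_bond == bond_id(topo$pivot_bond[1],
                                             topo$pivot_bond[2])])
  } else character()
  rest <- setdiff(names(key_bond), c(ring4, dbl, pivot))
  groups <- list()
  rank <- 1L
  if (length(dbl)) {
    groups[[length(groups) + 1L]] <- dihedral_group("double-bond", dbl, rank)
    rank <- rank + 1L
  }
  if (length(ring4)) {
    groups[[length(groups) + 1L]] <- dihedral_group("ring4", ring4, rank)
    rank <- rank + 1L
  }
  if (length(rest)) {
    name <- if (template == "chain") "chain" else "fused-ring"
    groups[[length(groups) + 1L]] <- dihedral_group(name, sort(rest), rank)
    rank <- rank + 1L
  }
  if (length(pivot)) {
    groups[[length(groups) + 1L]] <- dihedral_group("carboxylate", pivot, rank)
  }
  groups
}

fixture_scan_plan <- function(sys, topo) {
  plan <- list()
  seen <- character()
  for (r in seq_len(nrow(sys$dihedrals))) {
    q <- sys$dihedrals[r, ]
    bid <- bond_id(q[2], q[3])
    if (bid %in% seen) next
    seen <- c(seen, bid)
    ij <- as.integer(strsplit(bid, "-")[[1]])
    if (!is.null(topo$pivot_bond) &&
        bid == bond_id(topo$pivot_bond[1], topo$pivot_bond[2])) {
      plan[[length(plan) + 1L]] <- list(driven = q, range = 180, step = 10)
    } else if (bond_in_set(ij[1], ij[2], topo$ring4_bonds)) {
      plan[[length(plan) + 1L]] <- list(driven = q, range = 45, step = 5)
    } else {
      plan[[length(plan) + 1L]] <- list(driven = q, range = 90, step = 10)
    }
  }
  plan
}

# Is bond (j,k) part of a ring (still connected after removing the edge)?
bond_in_ring <- function(sys, j, k) {
  seen <- logical(nrow(sys$atoms))
  seen[k] <- TRUE
  queue <- k
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- sys$adjacency[[v]]
    if (v == k) nb <- setdiff(nb, j)
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  seen[j]
}

#' Generate a torsion scan from a fixture
#'
#' Rigid mode rotates the downstream fragment about the central bond (ring
#' bonds refuse and direct to relaxed mode); relaxed mode minimises all other
#' degrees of freedom with the driven torsion(s) restrained (harmonic,
#' 1000 kcal/mol/rad^2).  Energies are ground-truth MM plus optional Gaussian
#' noise; the exact per-row decomposition is recorded in attributes
#' `true_breakdown` and `true_term_energy` for oracle use.
#'
#' @param fixture a `fixture` from [make_fixture()].
#' @param driven one quadruple (1D) or a list of two (2D).
#' @param range scan half-width in degrees around the reference torsion.
#' @param step step size in degrees.
#' @param mode `"relaxed"` or `"rigid"`.
#' @param noise_sigma Gaussian noise sd (kcal/mol); default from the fixture spec.
#' @param seed noise seed; default derived from the fixture seed.
#' @param params parameter set used as ground truth (default `fixture$truth`).
#' @return A `scan_table`.
#' @export
generate_scan <- function(fixture, driven, range = 90, step = 10,
                          mode = c("relaxed", "rigid"), noise_sigma = NULL,
                          seed = NULL, params = NULL) {
  mode <- match.arg(mode)
  sys <- fixture$system
  params <- params %||% fixture$truth
  noise_sigma <- noise_sigma %||% fixture$spec$noise_sigma
  seed <- seed %||% (fixture$spec$seed + 77L)
  two_d <- is.list(driven) && length(driven) == 2
  quads <- if (two_d) driven else list(driven)
  if (length(range) == 1) range <- rep(range, length(quads))
  if (length(step) == 1) step <- rep(step, length(quads))

  for (q in quads) {
    if (mode == "rigid" && bond_in_ring(sys, q[2], q[3]))
      stop_pf("rigid scan of a ring-internal torsion cannot preserve ring ",
              "closure; use mode = 'relaxed'", class = "phasefit_rigid_ring")
  }

  phi0 <- vapply(quads, function(q) {
    measure_dihedral(sys$reference_geometry, q)
  }, numeric(1))
  offsets <- lapply(seq_along(quads), function(d) {
    if (range[d] >= 180) seq(-180, 180 - step[d], by = step[d])
    else seq(-range[d], range[d], by = step[d])
  })

  model <- compile_model(sys, params, mm_options())
  run_point <- function(g_start, targets) {
    if (mode == "rigid") {
      g <- sys$reference_geometry
      for (d in seq_along(quads)) {
        q <- quads[[d]]
        moving <- downstream_atoms(sys, q[2], q[3])
        cur <- measure_dihedral(g, q)
        g <- rotate_about_bond(g, q[2], q[3], moving, targets[d] - cur)
      }
      return(g)
    }
    restraints <- lapply(seq_along(quads), function(d) {
      list(quadruple = quads[[d]], target = targets[d], k = 1000)
    })
    # the recorded energy is evaluated on the returned frame, so fitting is
    # exact regardless of how tightly the restrained relaxation converged;
    # a moderate tolerance keeps scan generation fast.  On strongly strained
    # cells the nominal 1000 kcal/mol/rad^2 restraint can let the driven
    # torsion sag by more than the 1-degree declared-angle contract, so the
    # restraint is stiffened adaptively until the frame honours it.
    for (kr in c(1000, 1e4, 1e5)) {
      for (d in seq_along(restraints)) restraints[[d]]$k <- kr
      res <- minimise_frame(sys, params, g_start, restraints = restraints,
                            tol = 1e-4, maxit = 2000)
      dev <- max(vapply(seq_along(quads), function(d) {
        abs(wrap_angle(measure_dihedral(res$coordinates, quads[[d]]) -
                         targets[d]))
      }, numeric(1)))
      g_start <- res$coordinates
      if (dev <= 0.5) break
    }
    res$coordinates
  }

  if (!two_d) {
    offs <- offsets[[1]]
    ord <- order(abs(offs))           # walk outward from the reference
    frames <- vector("list", length(offs))
    g_prev_pos <- sys$reference_geometry
    g_prev_neg <- sys$reference_geometry
    for (i in ord) {
      start <- if (offs[i] >= 0) g_prev_pos else g_prev_neg
      g <- run_point(start, phi0 + offs[i])
      frames[[i]] <- g
      if (offs[i] >= 0) g_prev_pos <- g else g_prev_neg <- g
    }
    angles <- phi0 + offs
    rows <- data.frame(phi1 = angles, energy = NA_real_,
                       frame = seq_along(offs))
    md <- list(step = step[1], range = c(phi0 + min(offs), phi0 + max(offs)),
               origin = "absolute")
    scan <- new_scan_table(list(quads[[1]]), rows, frames, md)
  } else {
    o1 <- offsets[[1]]; o2 <- offsets[[2]]
    frames <- vector("list", length(o1) * length(o2))
    idx <- function(i, j) (i - 1L) * length(o2) + j
    # walk outward from the centre cell; every cell is warm-started from an
    # adjacent already-relaxed cell so the restrained targets never jump by
    # more than one grid step (a serpentine row restart would jump the full
    # grid width and derail the relaxation on strained surfaces)
    row_order <- order(abs(o1))
    col_order <- order(abs(o2))
    done_rows <- integer()
    for (i in row_order) {
      prev_row <- if (length(done_rows)) {
        done_rows[which.min(abs(done_rows - i))]
      } else NA_integer_
      for (pos in seq_along(col_order)) {
        j <- col_order[pos]
        start <- if (!is.na(prev_row)) {
          frames[[idx(prev_row, j)]]
        } else if (pos > 1) {
          jn <- col_order[which.min(abs(col_order[seq_len(pos - 1)] - j))]
          frames[[idx(i, jn)]]
        } else {
          sys$reference_geometry
        }
        frames[[idx(i, j)]] <- run_point(start,
                                         c(phi0[1] + o1[i], phi0[2] + o2[j]))
      }
      done_rows <- c(done_rows, i)
    }
    rows <- data.frame(phi1 = phi0[1] + rep(o1, each = length(o2)),
                       phi2 = phi0[2] + rep(o2, times = length(o1)),
                       energy = NA_real_,
                       frame = seq_len(length(o1) * length(o2)))
    md <- list(step = step, range = c(phi0[1] - range[1], phi0[1] + range[1],
                                      phi0[2] - range[2], phi0[2] + range[2]),
               origin = "absolute")
    scan <- new_scan_table(quads, rows, frames, md)
  }

  # energies + exact decomposition bookkeeping
  br <- t(vapply(scan$frames, function(g) energy_breakdown_fast(model, g),
                 numeric(6)))
  colnames(br) <- c("bond", "angle", "dihedral", "improper", "lj", "coulomb")
  term_df <- dihedral_term_df(params)
  te <- matrix(0, nrow(scan$rows), nrow(term_df))
  if (nrow(term_df)) {
    colnames(te) <- paste0(term_df$type_key, " | n=", term_df$n)
    for (tr in seq_len(nrow(term_df))) {
      quads_t <- dihedral_instances_of(sys, term_df$type_key[tr])
      if (!nrow(quads_t)) next
      te[, tr] <- vapply(scan$frames, function(g) {
        phis <- measure_dihedrals(g, quads_t)
        sum(term_df$k_phi[tr] *
              (1 + cos(deg2rad(term_df$n[tr] * phis - term_df$delta[tr]))))
      }, numeric(1))
    }
  }
  energy <- rowSums(br)
  if (noise_sigma > 0) {
    energy <- energy + with_seed(seed, stats::rnorm(length(energy), 0,
                                                    noise_sigma))
  }
  scan$rows$energy <- energy[scan$rows$frame]
  attr(scan, "true_breakdown") <- br
  attr(scan, "true_term_energy") <- te
  scan
}

#' Run a fixture's scan plan
#'
#' @inheritParams generate_scan
#' @export
generate_plan_scans <- function(fixture, noise_sigma = NULL, seed = NULL,
                                params = NULL) {
  lapply(seq_along(fixture$scan_plan), function(i) {
    p <- fixture$scan_plan[[i]]
    generate_scan(fixture, p$driven, range = p$range, step = p$step,
                  mode = "relaxed", noise_sigma = noise_sigma,
                  seed = (seed %||% (fixture$spec$seed + 77L)) + i,
                  params = params)
  })
}

#' Generate a finite-difference Hessian of the ground-truth energy
#'
#' Central differences of the analytic gradient (displacement 1e-4 A),
#' symmetrised.
#'
#' @param fixture a `fixture`.
#' @param params parameter set (default ground truth).
#' @param h displacement (Angstrom).
#' @export
generate_hessian <- function(fixture, params = NULL, h = 1e-4) {
  sys <- fixture$system
  params <- params %||% fixture$truth
  model <- compile_model(sys, params, mm_options())
  g0 <- sys$reference_geometry
  n3 <- 3 * nrow(g0)
  H <- matrix(0, n3, n3)
  for (c_ in seq_len(n3)) {
    at <- (c_ - 1) %/% 3 + 1; xyz <- (c_ - 1) %% 3 + 1
    gp <- g0; gp[at, xyz] <- gp[at, xyz] + h
    gm <- g0; gm[at, xyz] <- gm[at, xyz] - h
    dgrad <- (gradient_fast(model, gp) - gradient_fast(model, gm)) / (2 * h)
    H[, c_] <- as.numeric(t(dgrad))
  }
  hessian_matrix((H + t(H)) / 2, g0)
}

#' Add Gaussian noise to a scan's energies
#'
#' Returns a copy of the scan with `rnorm(n, 0, sigma)` added to the energy
#' column (the frames are untouched), reproducing what [generate_scan()]
#' does with a nonzero `noise_sigma` without re-relaxing the frames.
#'
#' @param scan a `scan_table`.
#' @param sigma noise standard deviation (kcal/mol).
#' @param seed RNG seed.
#' @export
scan_with_noise <- function(scan, sigma, seed) {
  noisy <- scan
  noisy$rows$energy <- scan$rows$energy +
    with_seed(seed, stats::rnorm(nrow(scan$rows), 0, sigma))
  noisy
}
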