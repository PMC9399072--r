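# Shared test helpers: tiny hand-built systems and memoised synthetic
# fixtures (scan generation is the expensive step, so fixtures and plan
# scans are cached across test files).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

get_fixture <- function(template, seed = 1, flip_mode = FALSE,
                        perturb_params = FALSE) {
  key <- paste("fx", template, seed, flip_mode, perturb_params)
  cached(key, make_fixture(fixture_spec(template, seed = seed,
                                        flip_mode = flip_mode,
                                        perturb_params = perturb_params)))
}

get_plan_scans <- function(template, seed = 1, flip_mode = FALSE) {
  key <- paste("scans", template, seed, flip_mode)
  cached(key, generate_plan_scans(get_fixture(template, seed,
                                              flip_mode = flip_mode)))
}

# Two bonded atoms with one bond parameter.
two_atom_system <- function(b = 1.5) {
  atoms <- data.frame(element = c("C", "C"), type = c("XA", "XB"),
                      charge = 0, mass = 12.011)
  molecule_system(atoms, rbind(c(1, 2)), rbind(c(0, 0, 0), c(b, 0, 0)))
}

two_atom_params <- function(k = 100, b0 = 1.5) {
  p <- parameter_set()
  p <- ps_set_bond(p, c("XA", "XB"), k, b0)
  p <- ps_set_nonbonded(p, "XA", 0, 1.8)
  ps_set_nonbonded(p, "XB", 0, 1.8)
}

# Butane-like 4-atom chain with one dihedral, full nonbonded (the single 1-4
# pair interacts).
butane_system <- function(phi = 60) {
  atoms <- data.frame(element = "C", type = c("Q1", "Q2", "Q3", "Q4"),
                      charge = c(0.1, -0.1, -0.1, 0.1), mass = 12.011)
  g <- rbind(c(0, 1.4, 0), c(0, 0, 0), c(1.5, 0, 0), c(1.5, 1.4, 0))
  sys <- molecule_system(atoms, rbind(c(1, 2), c(2, 3), c(3, 4)), g)
  sys$reference_geometry <- rotate_about_bond(g, 2, 3, 4, phi)
  sys
}

butane_params <- function(k_phi = 1.2, n = 3, delta = 0) {
  p <- parameter_set()
  p <- ps_set_bond(p, c("Q1", "Q2"), 220, 1.4)
  p <- ps_set_bond(p, c("Q2", "Q3"), 200, 1.5)
  p <- ps_set_bond(p, c("Q3", "Q4"), 220, 1.4)
  p <- ps_set_angle(p, c("Q1", "Q2", "Q3"), 60, 90)
  p <- ps_set_angle(p, c("Q2", "Q3", "Q4"), 60, 90)
  p <- ps_set_dihedral_term(p, c("Q1", "Q2", "Q3", "Q4"),
                            dihedral_term(k_phi, n, delta))
  for (t in c("Q1", "Q2", "Q3", "Q4")) p <- ps_set_nonbonded(p, t, 0.05, 1.9)
  p
}

# Naive brute-force MM energy: explicit instance enumeration with scalar
# arithmetic, independent of the vectorised production path.
brute_force_energy <- function(sys, params, coords) {
  e <- 0
  for (r in seq_len(nrow(sys$bonds))) {
    ij <- sys$bonds[r, ]
    p <- phasefit:::ps_get(params, "bond", sys$atoms$type[ij])
    e <- e + p$k * (measure_bond(coords, ij[1], ij[2]) - p$b0)^2
  }
  for (r in seq_len(nrow(sys$angles))) {
    ijk <- sys$angles[r, ]
    p <- phasefit:::ps_get(params, "angle", sys$atoms$type[ijk])
    th <- measure_angle(coords, ijk[1], ijk[2], ijk[3]) * pi / 180
    e <- e + p$k * (th - p$theta0 * pi / 180)^2
  }
  for (r in seq_len(nrow(sys$dihedrals))) {
    q <- sys$dihedrals[r, ]
    terms <- phasefit:::ps_get(params, "dihedral", sys$atoms$type[q])
    phi <- measure_dihedral(coords, q)
    for (t in terms) {
      e <- e + t$k_phi * (1 + cos((t$n * phi - t$delta) * pi / 180))
    }
  }
  if (!is.null(sys$impropers)) {
    for (r in seq_len(nrow(sys$impropers))) {
      q <- sys$impropers[r, ]
      p <- phasefit:::ps_get(params, "improper", sys$atoms$type[q])
      dw <- measure_dihedral(coords, q) - p$omega0
      dw <- ((dw + 180) %% 360) - 180
      e <- e + p$k * (dw * pi / 180)^2
    }
  }
  n <- nrow(sys$atoms)
  # 1-2 / 1-3 exclusions by bond-path distance
  dist <- matrix(Inf, n, n); diag(dist) <- 0
  for (r in seq_len(nrow(sys$bonds))) {
    dist[sys$bonds[r, 1], sys$bonds[r, 2]] <- 1
    dist[sys$bonds[r, 2], sys$bonds[r, 1]] <- 1
  }
  for (k in 1:n) for (i in 1:n) for (j in 1:n) {
    dist[i, j] <- min(dist[i, j], dist[i, k] + dist[k, j])
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (dist[i, j] <= 2) next
      ti <- sys$atoms$type[i]; tj <- sys$atoms$type[j]
      pi_ <- params$nonbonded[[ti]]; pj <- params$nonbonded[[tj]]
      r <- measure_bond(coords, i, j)
      eps <- sqrt(pi_$epsilon * pj$epsilon)
      rmin <- pi_$rmin_half + pj$rmin_half
      if (eps > 0) e <- e + eps * ((rmin / r)^12 - 2 * (rmin / r)^6)
      e <- e + 332.0716 * sys$atoms$charge[i] * sys$atoms$charge[j] / r
    }
  }
  e
}

# Zero out all dihedral force constants (fit starting point).
zero_k_start <- function(params) {
  for (key in names(params$dihedrals)) {
    for (t in params$dihedrals[[key]]) {
      params <- ps_set_dihedral_term(params, phasefit:::key_types(key),
                                     dihedral_term(0, t$n, t$delta))
    }
  }
  params
}

truth_term_table <- function(params) {
  df <- phasefit:::dihedral_term_df(params)
  df$id <- paste0(df$type_key, " | n=", df$n)
  df
}

# Parameters with every dihedral phase flipped, force constants kept.
flip_all_phases <- function(params) {
  for (key in names(params$dihedrals)) {
    for (t in params$dihedrals[[key]]) {
      params <- ps_set_dihedral_term(
        params, phasefit:::key_types(key),
        dihedral_term(t$k_phi, t$n, if (t$delta == 0) 180 else 0))
    }
  }
  params
}

random_parameter_set <- function(seed) {
  # values at the stream writer's printed precision so a single write/read
  # round-trip is exact
  set.seed(seed)
  p <- parameter_set()
  p <- ps_set_bond(p, c("T1", "T2"), round(runif(1, 100, 400), 2),
                   round(runif(1, 1, 2), 4), penalty = round(runif(1, 0, 50), 3))
  p <- ps_set_bond(p, c("T2", "T3"), round(runif(1, 100, 400), 2),
                   round(runif(1, 1, 2), 4))
  p <- ps_set_bond(p, c("T3", "T4"), round(runif(1, 100, 400), 2),
                   round(runif(1, 1, 2), 4))
  p <- ps_set_angle(p, c("T1", "T2", "T3"), round(runif(1, 30, 100), 2),
                    round(runif(1, 90, 130), 4),
                    penalty = round(runif(1, 0, 50), 3))
  p <- ps_set_angle(p, c("T2", "T3", "T4"), round(runif(1, 30, 100), 2),
                    round(runif(1, 90, 130), 4))
  ns <- sample(c(1, 2, 3, 4, 6), sample(2:3, 1))
  for (n in ns) {
    p <- ps_set_dihedral_term(p, c("T1", "T2", "T3", "T4"),
                              dihedral_term(round(runif(1, 0, 3), 4), n,
                                            sample(c(0, 180), 1)),
                              penalty = round(runif(1, 0, 50), 3))
  }
  p <- ps_set_improper(p, c("T2", "T1", "T3", "T4"), round(runif(1, 20, 80), 4),
                       round(runif(1, -10, 10), 4))
  for (t in paste0("T", 1:4)) {
    p <- ps_set_nonbonded(p, t, round(runif(1, 0, 0.2), 4),
                          round(runif(1, 1.5, 2.2), 4))
  }
  p
}

withr_local_tempdir <- function(env = parent.frame()) {
  td <- tempfile("phasefit-test-")
  dir.create(td)
  withr::defer(unlink(td, recursive = TRUE), envir = env)
  td
}
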