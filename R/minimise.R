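# Cartesian energy minimisation with analytic gradients (L-BFGS-B), with
# optional harmonic torsion restraints for relaxed scans.

# The tolerant vectorised torsion measure is used here: a line-search step
# may pass through a near-collinear configuration, which must not abort the
# minimisation.
restraint_energy <- function(coords, restraints) {
  e <- 0
  for (rs in restraints) {
    phi <- measure_dihedrals(coords, matrix(as.integer(rs$quadruple), ncol = 4))
    dphi <- deg2rad(wrap_angle(phi - rs$target))
    e <- e + rs$k * dphi^2
  }
  e
}

restraint_gradient <- function(coords, restraints, n) {
  grad <- matrix(0, n, 3)
  for (rs in restraints) {
    ix <- matrix(as.integer(rs$quadruple), ncol = 4)
    phi <- measure_dihedrals(coords, ix)
    dphi <- deg2rad(wrap_angle(phi - rs$target))
    grad <- dihedral_grad_acc(grad, coords, ix, 2 * rs$k * dphi)
  }
  grad
}

#' Minimise the MM energy of a frame
#'
#' Gradient-based local minimisation in Cartesian coordinates.  Convergence is
#' declared when the largest gradient component falls below `tol`
#' (kcal/mol/Angstrom) or after `maxit` function evaluations.
#'
#' @inheritParams mm_energy
#' @param coords starting N x 3 coordinates.
#' @param restraints optional list of harmonic torsion restraints, each a list
#'   `(quadruple, target, k)` with `target` in degrees and `k` in
#'   kcal/mol/rad^2.
#' @param tol gradient convergence threshold (kcal/mol/Angstrom).
#' @param maxit maximum number of evaluations across restarts.
#' @return List with `coordinates`, `energy` (restraint excluded), `converged`,
#'   `max_grad`.
#' @export
minimise_frame <- function(system, params, coords,
                           options = mm_options(), restraints = NULL,
                           tol = 1e-6, maxit = 5000) {
  model <- compile_model(system, params, options)
  n <- model$n
  x0 <- as.numeric(t(as_coords(coords)))

  fn <- function(x) {
    g <- matrix(x, ncol = 3, byrow = TRUE)
    e <- sum(energy_breakdown_fast(model, g))
    if (!is.null(restraints)) e <- e + restraint_energy(g, restraints)
    e
  }
  gr <- function(x) {
    g <- matrix(x, ncol = 3, byrow = TRUE)
    gg <- gradient_fast(model, g)
    if (!is.null(restraints)) gg <- gg + restraint_gradient(g, restraints, n)
    as.numeric(t(gg))
  }

  x <- x0
  used <- 0
  max_grad <- Inf
  for (attempt in 1:6) {
    res <- stats::optim(x, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = max(50, maxit - used),
                                       factr = 10, pgtol = 0.5 * tol))
    x <- res$par
    used <- used + res$counts[1]
    max_grad <- max(abs(gr(x)))
    if (max_grad < tol || used >= maxit) break
  }

  g <- matrix(x, ncol = 3, byrow = TRUE)
  list(coordinates = g,
       energy = sum(energy_breakdown_fast(model, g)),
       converged = max_grad < tol,
       max_grad = max_grad)
}
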