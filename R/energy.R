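# Molecular-mechanics bonded + nonbonded energy and analytic gradient.
# Bond/angle/improper terms are harmonic k (x - x0)^2 (CHARMM convention,
# no leading 1/2); dihedral terms are cosine series; nonbonded is 12-6
# Lennard-Jones (Lorentz-Berthelot-style combination from epsilon/rmin_half)
# plus plain Coulomb, excluding 1-2 and 1-3 pairs, no cutoff.

#' Term-class toggles for the MM energy
#'
#' @param bond,angle,dihedral,improper,lj,coulomb logical, enable the class.
#' @param zero_dihedral_types character vector of canonical dihedral type keys
#'   whose cosine terms are zeroed (used to build fitting baselines).
#' @export
mm_options <- function(bond = TRUE, angle = TRUE, dihedral = TRUE,
                       improper = TRUE, lj = TRUE, coulomb = TRUE,
                       zero_dihedral_types = character()) {
  list(bond = bond, angle = angle, dihedral = dihedral, improper = improper,
       lj = lj, coulomb = coulomb, zero_dihedral_types = zero_dihedral_types)
}

# Resolve every instance to its parameters once; returns flat numeric tables.
compile_model <- function(system, params, options = mm_options()) {
  types <- system$atoms$type
  need <- function(kind, inst_idx) {
    key <- canonical_key(types[inst_idx])
    p <- switch(kind, bond = params$bonds, angle = params$angles,
                dihedral = params$dihedrals, improper = params$impropers)[[key]]
    if (is.null(p))
      stop_pf("unparametrised ", kind, " instance: no parameter for type key '",
              key, "'", class = "phasefit_unparametrised")
    list(key = key, p = p)
  }

  model <- list(n = nrow(system$atoms))

  if (options$bond && nrow(system$bonds)) {
    m <- nrow(system$bonds)
    k <- numeric(m); b0 <- numeric(m)
    for (r in seq_len(m)) {
      p <- need("bond", system$bonds[r, ])$p
      k[r] <- p$k; b0[r] <- p$b0
    }
    model$bonds <- list(idx = system$bonds, k = k, b0 = b0)
  }

  if (options$angle && nrow(system$angles)) {
    m <- nrow(system$angles)
    k <- numeric(m); th0 <- numeric(m)
    for (r in seq_len(m)) {
      p <- need("angle", system$angles[r, ])$p
      k[r] <- p$k; th0[r] <- deg2rad(p$theta0)
    }
    model$angles <- list(idx = system$angles, k = k, theta0 = th0)
  }

  if (options$dihedral && nrow(system$dihedrals)) {
    quads <- list(); k <- numeric(); nn <- numeric(); dl <- numeric()
    for (r in seq_len(nrow(system$dihedrals))) {
      q <- system$dihedrals[r, ]
      res <- need("dihedral", q)
      if (res$key %in% options$zero_dihedral_types) next
      for (t in res$p) {
        if (t$k_phi == 0) next
        quads[[length(quads) + 1L]] <- q
        k <- c(k, t$k_phi); nn <- c(nn, t$n); dl <- c(dl, deg2rad(t$delta))
      }
    }
    if (length(quads)) {
      model$dihedrals <- list(idx = do.call(rbind, quads), k = k, n = nn,
                              delta = dl)
    }
  }

  if (options$improper && !is.null(system$impropers) && nrow(system$impropers)) {
    m <- nrow(system$impropers)
    k <- numeric(m); w0 <- numeric(m)
    for (r in seq_len(m)) {
      p <- need("improper", system$impropers[r, ])$p
      k[r] <- p$k; w0[r] <- p$omega0
    }
    model$impropers <- list(idx = system$impropers, k = k, omega0 = w0)
  }

  if ((options$lj || options$coulomb) && nrow(system$exclusions)) {
    prs <- system$exclusions
    ti <- types[prs[, 1]]; tj <- types[prs[, 2]]
    nb <- params$nonbonded
    getnb <- function(tt) {
      p <- nb[[tt]]
      if (is.null(p)) {
        if (options$lj)
          stop_pf("unparametrised nonbonded atom type '", tt, "'",
                  class = "phasefit_unparametrised")
        p <- list(epsilon = 0, rmin_half = 0)
      }
      p
    }
    eps <- numeric(nrow(prs)); rmin <- numeric(nrow(prs))
    if (options$lj) {
      for (r in seq_len(nrow(prs))) {
        pi_ <- getnb(ti[r]); pj <- getnb(tj[r])
        eps[r] <- sqrt(pi_$epsilon * pj$epsilon)
        rmin[r] <- pi_$rmin_half + pj$rmin_half
      }
    }
    qq <- if (options$coulomb) {
      .COULOMB_K * system$atoms$charge[prs[, 1]] * system$atoms$charge[prs[, 2]]
    } else numeric(nrow(prs))
    keep <- (options$lj & eps > 0) | (options$coulomb & qq != 0)
    if (any(keep)) {
      model$nb <- list(idx = prs[keep, , drop = FALSE], eps = eps[keep],
                       rmin = rmin[keep], qq = qq[keep],
                       lj = options$lj, coulomb = options$coulomb)
    }
  }

  model
}

energy_breakdown_fast <- function(model, coords) {
  br <- c(bond = 0, angle = 0, dihedral = 0, improper = 0, lj = 0, coulomb = 0)
  g <- coords

  if (!is.null(model$bonds)) {
    d <- g[model$bonds$idx[, 1], , drop = FALSE] - g[model$bonds$idx[, 2], , drop = FALSE]
    b <- sqrt(rowSums(d^2))
    br["bond"] <- sum(model$bonds$k * (b - model$bonds$b0)^2)
  }
  if (!is.null(model$angles)) {
    ix <- model$angles$idx
    u <- g[ix[, 1], , drop = FALSE] - g[ix[, 2], , drop = FALSE]
    v <- g[ix[, 3], , drop = FALSE] - g[ix[, 2], , drop = FALSE]
    cosx <- rowSums(u * v) / sqrt(rowSums(u^2) * rowSums(v^2))
    th <- acos(pmin(1, pmax(-1, cosx)))
    br["angle"] <- sum(model$angles$k * (th - model$angles$theta0)^2)
  }
  if (!is.null(model$dihedrals)) {
    phi <- deg2rad(measure_dihedrals(g, model$dihedrals$idx))
    br["dihedral"] <- sum(model$dihedrals$k *
                            (1 + cos(model$dihedrals$n * phi - model$dihedrals$delta)))
  }
  if (!is.null(model$impropers)) {
    w <- measure_dihedrals(g, model$impropers$idx)
    dw <- deg2rad(wrap_angle(w - model$impropers$omega0))
    br["improper"] <- sum(model$impropers$k * dw^2)
  }
  if (!is.null(model$nb)) {
    d <- g[model$nb$idx[, 1], , drop = FALSE] - g[model$nb$idx[, 2], , drop = FALSE]
    r <- sqrt(rowSums(d^2))
    if (model$nb$lj) {
      sr6 <- (model$nb$rmin / r)^6
      br["lj"] <- sum(model$nb$eps * (sr6^2 - 2 * sr6))
    }
    if (model$nb$coulomb) br["coulomb"] <- sum(model$nb$qq / r)
  }
  br
}

# Accumulate per-instance gradient contributions into the atom gradient.
acc_grad <- function(grad, idx, contrib) {
  s <- rowsum(contrib, group = idx)
  at <- as.integer(rownames(s))
  grad[at, ] <- grad[at, , drop = FALSE] + s
  grad
}

gradient_fast <- function(model, coords) {
  g <- coords
  grad <- matrix(0, model$n, 3)

  if (!is.null(model$bonds)) {
    ix <- model$bonds$idx
    d <- g[ix[, 1], , drop = FALSE] - g[ix[, 2], , drop = FALSE]
    b <- sqrt(rowSums(d^2))
    f <- 2 * model$bonds$k * (b - model$bonds$b0) / b
    grad <- acc_grad(grad, ix[, 1], d * f)
    grad <- acc_grad(grad, ix[, 2], -d * f)
  }

  if (!is.null(model$angles)) {
    ix <- model$angles$idx
    u <- g[ix[, 1], , drop = FALSE] - g[ix[, 2], , drop = FALSE]
    v <- g[ix[, 3], , drop = FALSE] - g[ix[, 2], , drop = FALSE]
    un <- sqrt(rowSums(u^2)); vn <- sqrt(rowSums(v^2))
    uh <- u / un; vh <- v / vn
    cosx <- pmin(1, pmax(-1, rowSums(uh * vh)))
    sinx <- sqrt(pmax(1e-12, 1 - cosx^2))
    th <- acos(cosx)
    pref <- 2 * model$angles$k * (th - model$angles$theta0)
    dthi <- (cosx * uh - vh) / (un * sinx)
    dthk <- (cosx * vh - uh) / (vn * sinx)
    grad <- acc_grad(grad, ix[, 1], pref * dthi)
    grad <- acc_grad(grad, ix[, 3], pref * dthk)
    grad <- acc_grad(grad, ix[, 2], -pref * (dthi + dthk))
  }

  if (!is.null(model$dihedrals)) {
    ix <- model$dihedrals$idx
    phi <- deg2rad(measure_dihedrals(g, ix))
    dV <- -model$dihedrals$k * model$dihedrals$n *
      sin(model$dihedrals$n * phi - model$dihedrals$delta)
    grad <- dihedral_grad_acc(grad, g, ix, dV)
  }

  if (!is.null(model$impropers)) {
    ix <- model$impropers$idx
    w <- measure_dihedrals(g, ix)
    dw <- deg2rad(wrap_angle(w - model$impropers$omega0))
    dV <- 2 * model$impropers$k * dw
    grad <- dihedral_grad_acc(grad, g, ix, dV)
  }

  if (!is.null(model$nb)) {
    ix <- model$nb$idx
    d <- g[ix[, 1], , drop = FALSE] - g[ix[, 2], , drop = FALSE]
    r <- sqrt(rowSums(d^2))
    dVdr <- numeric(length(r))
    if (model$nb$lj) {
      sr6 <- (model$nb$rmin / r)^6
      dVdr <- dVdr - 12 * model$nb$eps * (sr6^2 - sr6) / r
    }
    if (model$nb$coulomb) dVdr <- dVdr - model$nb$qq / r^2
    f <- dVdr / r
    grad <- acc_grad(grad, ix[, 1], d * f)
    grad <- acc_grad(grad, ix[, 2], -d * f)
  }

  grad
}

# d(phi)/d(cartesians) for torsion quadruples (Blondel-Karplus form), times
# dV/dphi (in kcal/mol/rad), accumulated into grad.
dihedral_grad_acc <- function(grad, g, ix, dV) {
  F <- g[ix[, 1], , drop = FALSE] - g[ix[, 2], , drop = FALSE]
  G <- g[ix[, 2], , drop = FALSE] - g[ix[, 3], , drop = FALSE]
  H <- g[ix[, 4], , drop = FALSE] - g[ix[, 3], , drop = FALSE]
  A <- cross3m(F, G)
  B <- cross3m(H, G)
  Gn <- sqrt(rowSums(G^2))
  # clamp against collinear configurations visited during line searches
  A2 <- pmax(rowSums(A^2), 1e-12); B2 <- pmax(rowSums(B^2), 1e-12)
  # signs fixed against the atan2-based measure_dihedral convention
  dpi <- (Gn / A2) * A
  dpl <- -(Gn / B2) * B
  fg <- rowSums(F * G); hg <- rowSums(H * G)
  tA <- -(fg / (A2 * Gn)) * A
  tB <- -(hg / (B2 * Gn)) * B
  dpj <- -dpi + tA - tB
  dpk <- -tA + tB - dpl
  grad <- acc_grad(grad, ix[, 1], dV * dpi)
  grad <- acc_grad(grad, ix[, 2], dV * dpj)
  grad <- acc_grad(grad, ix[, 3], dV * dpk)
  grad <- acc_grad(grad, ix[, 4], dV * dpl)
  grad
}

#' Molecular-mechanics energy with per-class breakdown
#'
#' @param system a [molecule_system()].
#' @param params a [parameter_set()]; every instance in the system must
#'   resolve to a parameter after canonical key orientation.
#' @param frame a [frame()] or an N x 3 coordinate matrix.
#' @param options term toggles from [mm_options()].
#' @return List with `total` (kcal/mol) and `breakdown`, a named vector over
#'   term classes (bond, angle, dihedral, improper, lj, coulomb) whose sum
#'   equals `total`.
#' @export
mm_energy <- function(system, params, frame, options = mm_options()) {
  model <- compile_model(system, params, options)
  br <- energy_breakdown_fast(model, as_coords(frame))
  list(total = sum(br), breakdown = br)
}

#' Analytic gradient of the MM energy
#'
#' @inheritParams mm_energy
#' @return N x 3 matrix of dE/dx in kcal/mol/Angstrom.
#' @export
mm_gradient <- function(system, params, frame, options = mm_options()) {
  model <- compile_model(system, params, options)
  gradient_fast(model, as_coords(frame))
}
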