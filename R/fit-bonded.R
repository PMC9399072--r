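# Hessian-based fitting of harmonic bond/angle/improper parameters, penalty
# based parameter selection, and the equilibrium-geometry tolerance check.
#
# Equilibrium values are taken directly from the reference geometry (which
# guarantees the 0.03 A / 3 degree envelope by construction).  Force
# constants come from the Cartesian Hessian: the default method decomposes H
# over the rank-1 curvature matrices B_q' B_q of all internal coordinates by
# (non-negative) least squares, which is exact for a Hessian generated by a
# harmonic-consistent model; the "uncoupled" method is the simpler
# per-internal projection k = d' H d / (2 |B|^2), whose error is bounded by
# the coupling between internals.

#' Select parameters to optimise by penalty policy
#'
#' Under `"penalty-threshold"` a key is selected iff its penalty is strictly
#' larger than `threshold` (the "larger than 10" rule); under `"all-bonded"`
#' every bond/angle/dihedral/improper key is selected regardless of penalty.
#' Charges are recorded separately (non-hydrogen atoms above the threshold)
#' but charge fitting is out of scope.
#'
#' @param params a [parameter_set()] (absent penalty annotations count as 0).
#' @param policy `"penalty-threshold"` or `"all-bonded"`.
#' @param threshold penalty threshold (default 10).
#' @param charge_penalties optional named per-atom penalty vector.
#' @param elements optional element symbols parallel to `charge_penalties`.
#' @return A `penalty_selection` with `selected` (prefixed keys like
#'   `"angle:A B C"`), `policy`, `threshold` and `charges`.
#' @export
select_parameters <- function(params,
                              policy = c("penalty-threshold", "all-bonded"),
                              threshold = 10, charge_penalties = NULL,
                              elements = NULL) {
  policy <- match.arg(policy)
  nm <- function(x) names(x) %||% character()
  all_keys <- c(paste0("bond:", nm(params$bonds), recycle0 = TRUE),
                paste0("angle:", nm(params$angles), recycle0 = TRUE),
                paste0("dihedral:", nm(params$dihedrals), recycle0 = TRUE),
                paste0("improper:", nm(params$impropers), recycle0 = TRUE))
  selected <- if (policy == "all-bonded") {
    all_keys
  } else {
    Filter(function(k) {
      p <- params$penalties[k]
      !is.na(p) && p > threshold
    }, all_keys)
  }
  charges <- character()
  if (!is.null(charge_penalties)) {
    sel <- charge_penalties > threshold
    if (!is.null(elements)) sel <- sel & toupper(elements) != "H"
    charges <- names(charge_penalties)[sel]
  }
  structure(list(selected = sort(unlist(selected)), policy = policy,
                 threshold = threshold, charges = charges),
            class = "penalty_selection")
}

# Wilson B row (first derivative of an internal coordinate with respect to
# the Cartesians) by central finite differences.  Bonds in A/A, angles and
# impropers in rad/A.
wilson_b_row <- function(geometry, kind, idx, h = 1e-5) {
  g <- as_coords(geometry)
  n <- nrow(g)
  measure <- switch(kind,
    bond = function(gg) measure_bond(gg, idx[1], idx[2]),
    angle = function(gg) deg2rad(measure_angle(gg, idx[1], idx[2], idx[3])),
    improper = ,
    dihedral = function(gg) deg2rad(measure_dihedral(gg, idx)))
  B <- numeric(3 * n)
  ref <- measure(g)
  for (a in idx) {
    for (c in 1:3) {
      gp <- g; gp[a, c] <- gp[a, c] + h
      gm <- g; gm[a, c] <- gm[a, c] - h
      vp <- measure(gp); vm <- measure(gm)
      d <- vp - vm
      if (kind %in% c("improper", "dihedral")) {
        d <- deg2rad(wrap_angle(rad2deg(vp) - rad2deg(vm)))
      }
      B[3 * (a - 1) + c] <- d / (2 * h)
    }
  }
  B
}

# Instances grouped by canonical type key for one kind.
instances_by_key <- function(system, kind) {
  inst <- switch(kind, bond = system$bonds, angle = system$angles,
                 improper = system$impropers, dihedral = system$dihedrals)
  if (is.null(inst) || nrow(inst) == 0) return(list())
  keys <- apply(inst, 1, function(ix) canonical_key(system$atoms$type[ix]))
  split.data.frame(as.data.frame(inst), keys)
}

measure_internal <- function(geometry, kind, idx) {
  switch(kind,
    bond = measure_bond(geometry, idx[1], idx[2]),
    angle = measure_angle(geometry, idx[1], idx[2], idx[3]),
    improper = measure_dihedral(geometry, idx))
}

#' Fit harmonic bonded parameters from a Cartesian Hessian
#'
#' @inheritParams mm_energy
#' @param hessian a `hessian_matrix` evaluated at the reference geometry
#'   (checked to 1e-4 A per coordinate when the geometry is attached).
#' @param initial incoming [parameter_set()].
#' @param selection a `penalty_selection`; only selected bond/angle/improper
#'   keys are updated (dihedral keys are handled by the torsion-scan fit).
#' @param method `"coupled"` (default, least-squares decomposition over all
#'   internals with dihedral curvatures as free nuisance terms) or
#'   `"uncoupled"` (per-internal projection, coupling neglected).
#' @return The updated parameter set.
#' @export
fit_bonds_angles <- function(system, hessian, initial, selection,
                             method = c("coupled", "uncoupled")) {
  method <- match.arg(method)
  geom <- system$reference_geometry
  if (!is.null(hessian$geometry)) {
    if (max(abs(hessian$geometry - geom)) > 1e-4)
      stop("Hessian geometry does not match the reference geometry (1e-4 A)")
  }
  H <- hessian$matrix
  if (nrow(H) != 3 * nrow(geom)) stop("Hessian dimension does not match system")

  sel_keys <- function(kind) {
    pref <- paste0(kind, ":")
    sub(pref, "", grep(paste0("^", pref), selection$selected, value = TRUE),
        fixed = FALSE)
  }
  wanted <- list(bond = sel_keys("bond"), angle = sel_keys("angle"),
                 improper = sel_keys("improper"))
  if (!length(unlist(wanted))) return(initial)

  kinds <- c("bond", "angle", "improper")
  by_key <- lapply(kinds, function(k) instances_by_key(system, k))
  names(by_key) <- kinds

  k_est <- list()
  if (method == "uncoupled") {
    # distortion direction of each internal with all other internals held
    # fixed to first order: x_q = pseudo-inverse(B_full) e_q; the harmonic
    # constant follows from E(h) = k (B_q x_q h)^2 = 1/2 h^2 x_q' H x_q.
    # Internal-internal coupling (off-diagonal curvature) is neglected.
    rows <- list(); row_kind <- character(); row_key <- character()
    for (kind in c(kinds, "dihedral")) {
      bk <- instances_by_key(system, kind)
      for (key in names(bk)) {
        inst <- as.matrix(bk[[key]])
        for (r in seq_len(nrow(inst))) {
          B <- wilson_b_row(geom, kind, inst[r, ])
          if (sum(B^2) < 1e-12) next
          rows[[length(rows) + 1L]] <- B
          row_kind <- c(row_kind, kind)
          row_key <- c(row_key, key)
        }
      }
    }
    Bfull <- do.call(rbind, rows)
    sv <- svd(Bfull)
    keep <- sv$d > 1e-8 * max(sv$d)
    pinv <- sv$v[, keep, drop = FALSE] %*%
      (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
    for (kind in kinds) {
      for (key in intersect(wanted[[kind]], names(by_key[[kind]]))) {
        sel_rows <- which(row_kind == kind & row_key == key)
        ks <- numeric(0)
        for (r in sel_rows) {
          x <- pinv[, r]
          dq <- sum(rows[[r]] * x)
          if (abs(dq) < 1e-8) {
            warning("degenerate internal for ", kind, " '", key, "'; skipped")
            next
          }
          ks <- c(ks, max(0, as.numeric(x %*% H %*% x) / (2 * dq^2)))
        }
        if (length(ks)) k_est[[paste0(kind, ":", key)]] <- mean(ks)
        else warning("degenerate internal (near-zero Wilson row) for ", kind,
                     " '", key, "'; skipped")
      }
    }
  } else {
    # one constrained column per bond/angle/improper type key (sum of the
    # rank-1 curvature matrices of its instances), dihedral curvatures free
    cols <- list(); col_kind <- character()
    for (kind in kinds) {
      for (key in names(by_key[[kind]])) {
        inst <- as.matrix(by_key[[kind]][[key]])
        M <- 0
        ok <- FALSE
        for (r in seq_len(nrow(inst))) {
          B <- wilson_b_row(geom, kind, inst[r, ])
          if (sum(B^2) < 1e-12) next
          M <- M + 2 * tcrossprod(B)
          ok <- TRUE
        }
        if (!ok) {
          warning("degenerate internal (near-zero Wilson row) for ", kind,
                  " '", key, "'; skipped")
          next
        }
        cols[[paste0(kind, ":", key)]] <- as.numeric(M)
        col_kind <- c(col_kind, kind)
      }
    }
    free <- list()
    dih <- instances_by_key(system, "dihedral")
    for (key in names(dih)) {
      inst <- as.matrix(dih[[key]])
      M <- 0
      for (r in seq_len(nrow(inst))) {
        B <- wilson_b_row(geom, "dihedral", inst[r, ])
        M <- M + tcrossprod(B)
      }
      free[[paste0("dihedral:", key)]] <- as.numeric(M)
    }
    C <- do.call(cbind, cols)
    h_vec <- as.numeric(H)
    if (length(free)) {
      F <- do.call(cbind, free)
      qf <- qr(F)
      h_res <- h_vec - qr.fitted(qf, h_vec)
      C_res <- C - qr.fitted(qf, C)
    } else {
      h_res <- h_vec
      C_res <- C
    }
    k_all <- nnls_fit(C_res, h_res)
    names(k_all) <- colnames(C)
    for (nm in names(k_all)) k_est[[nm]] <- unname(k_all[[nm]])
  }

  params <- initial
  for (kind in kinds) {
    for (key in intersect(wanted[[kind]], names(by_key[[kind]]))) {
      kn <- paste0(kind, ":", key)
      if (is.null(k_est[[kn]])) next
      inst <- as.matrix(by_key[[kind]][[key]])
      x0 <- mean(vapply(seq_len(nrow(inst)), function(r) {
        measure_internal(geom, kind, inst[r, ])
      }, numeric(1)))
      params <- switch(kind,
        bond = ps_set_bond(params, key_types(key), k_est[[kn]], x0,
                           penalty = ps_penalty(params, "bond", key)),
        angle = ps_set_angle(params, key_types(key), k_est[[kn]], x0,
                             penalty = ps_penalty(params, "angle", key)),
        improper = ps_set_improper(params, key_types(key), k_est[[kn]], x0,
                                   penalty = ps_penalty(params, "improper", key)))
    }
  }
  params
}

#' Check bonded equilibrium values against the reference geometry
#'
#' Compares every bond/angle instance's parameter equilibrium value with the
#' value measured on the reference geometry; the stated envelope is 0.03 A
#' for bonds and 3 degrees for angles.
#'
#' @inheritParams mm_energy
#' @param tol_bond,tol_angle tolerances (A, degrees).
#' @return data.frame (kind, type_key, instance, value, measured, deviation,
#'   pass) with attribute `overall_pass`.
#' @export
check_equilibria <- function(system, params, tol_bond = 0.03, tol_angle = 3) {
  geom <- system$reference_geometry
  rows <- list()
  add_rows <- function(kind, inst_mat, get_value, tol) {
    for (r in seq_len(nrow(inst_mat))) {
      ix <- inst_mat[r, ]
      key <- canonical_key(system$atoms$type[ix])
      p <- switch(kind, bond = params$bonds, angle = params$angles)[[key]]
      if (is.null(p))
        stop_pf("unparametrised ", kind, " instance: '", key, "'",
                class = "phasefit_unparametrised")
      value <- get_value(p)
      measured <- measure_internal(geom, kind, ix)
      dev <- abs(value - measured)
      rows[[length(rows) + 1L]] <<- data.frame(
        kind = kind, type_key = key, instance = paste(ix, collapse = "-"),
        value = value, measured = measured, deviation = dev,
        pass = dev <= tol, stringsAsFactors = FALSE)
    }
  }
  add_rows("bond", system$bonds, function(p) p$b0, tol_bond)
  if (nrow(system$angles))
    add_rows("angle", system$angles, function(p) p$theta0, tol_angle)
  out <- do.call(rbind, rows)
  attr(out, "overall_pass") <- all(out$pass)
  out
}
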