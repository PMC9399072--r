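# ParameterSet: typed bonded parameters with penalty annotations, stored under
# canonical (lexicographically oriented) type keys.  A dihedral type key maps
# to a list of cosine terms, at most one per multiplicity n.

.VALID_N <- c(1L, 2L, 3L, 4L, 6L)

#' One cosine dihedral term k * (1 + cos(n * phi - delta))
#'
#' Canonical form has `k_phi >= 0`; a negative force constant is normalised by
#' flipping the phase by 180 degrees (which shifts only the constant offset).
#'
#' @param k_phi force constant (kcal/mol).
#' @param n multiplicity, one of 1, 2, 3, 4, 6.
#' @param delta phase shift in degrees, 0 or 180.
#' @export
dihedral_term <- function(k_phi, n, delta) {
  n <- as.integer(n)
  if (!n %in% .VALID_N) stop("multiplicity n must be one of 1, 2, 3, 4, 6")
  if (!delta %in% c(0, 180)) stop("phase shift delta must be 0 or 180 degrees")
  if (k_phi < 0) {
    k_phi <- -k_phi
    delta <- if (delta == 0) 180 else 0
  }
  structure(list(k_phi = as.numeric(k_phi), n = n, delta = as.numeric(delta)),
            class = "dihedral_term")
}

#' Evaluate a list of cosine dihedral terms
#'
#' @param terms list of [dihedral_term()] objects.
#' @param phi torsion angle(s) in degrees.
#' @return Energy in kcal/mol, `sum_t k_t * (1 + cos(n_t * phi - delta_t))`.
#' @export
dihedral_term_energy <- function(terms, phi) {
  if (inherits(terms, "dihedral_term")) terms <- list(terms)
  e <- numeric(length(phi))
  for (t in terms) {
    e <- e + t$k_phi * (1 + cos(deg2rad(t$n * phi - t$delta)))
  }
  e
}

#' Create an empty parameter set
#'
#' Containers: `bonds` (k_b kcal/mol/A^2, b0 A), `angles` (k_theta
#' kcal/mol/rad^2, theta0 deg), `dihedrals` (term lists), `impropers`
#' (k_omega kcal/mol/rad^2, omega0 deg), `nonbonded` (epsilon kcal/mol,
#' rmin_half A per atom type), `penalties` (named, keyed `"kind:types"`).
#'
#' @export
parameter_set <- function() {
  structure(list(bonds = list(), angles = list(), dihedrals = list(),
                 impropers = list(), nonbonded = list(),
                 penalties = numeric()), class = "parameter_set")
}

penalty_key <- function(kind, key) paste0(kind, ":", key)

set_penalty <- function(params, kind, key, penalty) {
  params$penalties[penalty_key(kind, key)] <- as.numeric(penalty)
  params
}

#' @rdname parameter_set
#' @param params a parameter set.
#' @param types character vector of atom types naming the parameter.
#' @param k,x0 force constant and equilibrium value (b0 in Angstrom for bonds,
#'   theta0/omega0 in degrees for angles/impropers).
#' @param penalty CGenFF-style penalty annotation (0 = no optimisation demanded).
#' @export
ps_set_bond <- function(params, types, k, x0, penalty = 0) {
  if (k < 0 || x0 <= 0) stop("bond parameters require k >= 0 and b0 > 0")
  key <- canonical_key(types)
  params$bonds[[key]] <- list(k = as.numeric(k), b0 = as.numeric(x0))
  set_penalty(params, "bond", key, penalty)
}

#' @rdname parameter_set
#' @export
ps_set_angle <- function(params, types, k, x0, penalty = 0) {
  if (k < 0 || x0 <= 0 || x0 >= 180)
    stop("angle parameters require k >= 0 and 0 < theta0 < 180")
  key <- canonical_key(types)
  params$angles[[key]] <- list(k = as.numeric(k), theta0 = as.numeric(x0))
  set_penalty(params, "angle", key, penalty)
}

#' @rdname parameter_set
#' @export
ps_set_improper <- function(params, types, k, x0, penalty = 0) {
  if (k < 0) stop("improper force constant must be >= 0")
  key <- canonical_key(types)
  params$impropers[[key]] <- list(k = as.numeric(k), omega0 = as.numeric(x0))
  set_penalty(params, "improper", key, penalty)
}

#' @rdname parameter_set
#' @param term a [dihedral_term()]; replaces any existing term with the same n.
#' @export
ps_set_dihedral_term <- function(params, types, term, penalty = NULL) {
  key <- canonical_key(types)
  terms <- params$dihedrals[[key]] %||% list()
  terms <- Filter(function(t) t$n != term$n, terms)
  terms[[length(terms) + 1L]] <- term
  ord <- order(vapply(terms, function(t) t$n, integer(1)))
  params$dihedrals[[key]] <- terms[ord]
  if (!is.null(penalty)) params <- set_penalty(params, "dihedral", key, penalty)
  if (is.na(params$penalties[penalty_key("dihedral", key)] %||% NA))
    params <- set_penalty(params, "dihedral", key, 0)
  params
}

#' @rdname parameter_set
#' @export
ps_drop_dihedral_term <- function(params, types, n) {
  key <- canonical_key(types)
  terms <- Filter(function(t) t$n != n, params$dihedrals[[key]] %||% list())
  params$dihedrals[[key]] <- terms
  params
}

#' @rdname parameter_set
#' @param type single atom type.
#' @param epsilon,rmin_half Lennard-Jones well depth (kcal/mol) and half
#'   minimum distance (Angstrom).
#' @export
ps_set_nonbonded <- function(params, type, epsilon, rmin_half) {
  if (epsilon < 0) stop("epsilon is stored positive")
  params$nonbonded[[type]] <- list(epsilon = as.numeric(epsilon),
                                   rmin_half = as.numeric(rmin_half))
  params
}

ps_get <- function(params, kind, types) {
  key <- canonical_key(types)
  slot <- switch(kind, bond = "bonds", angle = "angles",
                 dihedral = "dihedrals", improper = "impropers")
  params[[slot]][[key]]
}

ps_penalty <- function(params, kind, key) {
  p <- params$penalties[penalty_key(kind, key)]
  if (is.na(p)) 0 else unname(p)
}

dihedral_term_df <- function(params) {
  keys <- names(params$dihedrals)
  rows <- list()
  for (key in keys) {
    for (t in params$dihedrals[[key]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        type_key = key, n = t$n, k_phi = t$k_phi, delta = t$delta,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(type_key = character(), n = integer(),
                      k_phi = numeric(), delta = numeric()))
  }
  do.call(rbind, rows)
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set> ", length(x$bonds), " bond, ", length(x$angles),
      " angle, ", length(x$dihedrals), " dihedral, ", length(x$impropers),
      " improper type keys; ", length(x$nonbonded), " nonbonded types\n", sep = "")
  invisible(x)
}

# Approximate equality of two parameter sets (used by round-trip tests).
params_equal <- function(a, b, tol = 1e-8) {
  same_names <- function(x, y) setequal(names(x), names(y))
  if (!same_names(a$bonds, b$bonds) || !same_names(a$angles, b$angles) ||
      !same_names(a$dihedrals, b$dihedrals) ||
      !same_names(a$impropers, b$impropers) ||
      !same_names(a$nonbonded, b$nonbonded)) return(FALSE)
  near <- function(x, y) abs(x - y) <= tol
  for (k in names(a$bonds)) {
    if (!near(a$bonds[[k]]$k, b$bonds[[k]]$k) ||
        !near(a$bonds[[k]]$b0, b$bonds[[k]]$b0)) return(FALSE)
  }
  for (k in names(a$angles)) {
    if (!near(a$angles[[k]]$k, b$angles[[k]]$k) ||
        !near(a$angles[[k]]$theta0, b$angles[[k]]$theta0)) return(FALSE)
  }
  for (k in names(a$impropers)) {
    if (!near(a$impropers[[k]]$k, b$impropers[[k]]$k) ||
        !near(a$impropers[[k]]$omega0, b$impropers[[k]]$omega0)) return(FALSE)
  }
  for (k in names(a$nonbonded)) {
    if (!near(a$nonbonded[[k]]$epsilon, b$nonbonded[[k]]$epsilon) ||
        !near(a$nonbonded[[k]]$rmin_half, b$nonbonded[[k]]$rmin_half)) return(FALSE)
  }
  for (k in names(a$dihedrals)) {
    ta <- a$dihedrals[[k]]; tb <- b$dihedrals[[k]]
    if (length(ta) != length(tb)) return(FALSE)
    for (i in seq_along(ta)) {
      if (ta[[i]]$n != tb[[i]]$n || !near(ta[[i]]$k_phi, tb[[i]]$k_phi) ||
          ta[[i]]$delta != tb[[i]]$delta) return(FALSE)
    }
  }
  pk <- union(names(a$penalties), names(b$penalties))
  for (k in pk) {
    pa <- if (k %in% names(a$penalties)) a$penalties[[k]] else 0
    pb <- if (k %in% names(b$penalties)) b$penalties[[k]] else 0
    if (!near(pa, pb)) return(FALSE)
  }
  TRUE
}
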