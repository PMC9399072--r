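# Phase-shift prediction from the equilibrium geometry.
#
# Because the force field is additive and the reference geometry is a global
# minimum, each cosine term's phase is chosen so that the term has a local
# minimum at the equilibrium torsion: evaluate cos(n*phi0 - delta) for
# delta in {0, 180} and keep whichever is lower.  Near-ties are flagged as
# ambiguous and both candidates are reported.

phase_decision <- function(type_key, n, delta, score_gap, ambiguous, source,
                           alternatives = NULL, phi0 = NA_real_) {
  structure(list(type_key = type_key, n = as.integer(n), delta = delta,
                 score_gap = score_gap, ambiguous = ambiguous, source = source,
                 alternatives = alternatives, phi0 = phi0),
            class = "phase_decision")
}

#' Predict a dihedral phase shift from the equilibrium torsion
#'
#' Evaluates `c(delta) = cos(n * phi0 - delta)` for `delta` in \{0, 180\} and
#' returns the phase with the smaller value, so the term is minimal at the
#' equilibrium geometry.  `score_gap` is the dimensionless (per unit force
#' constant) difference between the rejected and chosen values; the decision
#' is ambiguous when the gap falls below `tie_tol`, in which case both
#' candidates are reported (geometry-derived first).
#'
#' @param n multiplicity, one of 1, 2, 3, 4, 6.
#' @param phi0 equilibrium torsion in degrees, in (-180, 180].
#' @param tie_tol tie tolerance on the cosine scale (default 0.05).
#' @param type_key optional dihedral type key carried through to the decision.
#' @return A `phase_decision`.
#' @export
predict_phase <- function(n, phi0, tie_tol = 0.05, type_key = NA_character_) {
  n <- as.integer(n)
  if (!n %in% .VALID_N)
    stop_pf("invalid multiplicity n = ", n, " (must be 1, 2, 3, 4 or 6)",
            class = "phasefit_domain_error")
  c0 <- cos(deg2rad(n * phi0))
  c180 <- cos(deg2rad(n * phi0 - 180))
  delta <- if (c0 <= c180) 0 else 180
  gap <- abs(c0 - c180)
  ambiguous <- gap < tie_tol
  alternatives <- if (ambiguous) c(delta, setdiff(c(0, 180), delta)) else NULL
  phase_decision(type_key, n, delta, gap, ambiguous, "geometry",
                 alternatives, phi0 = phi0)
}

# Summed criterion over several geometric instances of one type.
predict_phase_summed <- function(n, phis, tie_tol = 0.05,
                                 type_key = NA_character_) {
  n <- as.integer(n)
  if (!n %in% .VALID_N)
    stop_pf("invalid multiplicity n = ", n, class = "phasefit_domain_error")
  s0 <- sum(cos(deg2rad(n * phis)))
  s180 <- sum(cos(deg2rad(n * phis - 180)))
  delta <- if (s0 <= s180) 0 else 180
  gap <- abs(s0 - s180)
  ambiguous <- gap < tie_tol
  alternatives <- if (ambiguous) c(delta, setdiff(c(0, 180), delta)) else NULL
  phase_decision(type_key, n, delta, gap, ambiguous, "geometry", alternatives,
                 phi0 = phis[1])
}

#' Predict phase shifts for every dihedral term of a parameter set
#'
#' For a type with multiple geometric instances the phase minimises the sum
#' of the cosine term over instances (what enters the additive energy).  A
#' parameter type with no instance in the system raises an orphan-parameter
#' warning and yields no decision.
#'
#' @inheritParams mm_energy
#' @param tie_tol tie tolerance on the cosine scale.
#' @return List of `phase_decision` objects, one per (type key, n) pair.
#' @export
predict_phases <- function(system, params, tie_tol = 0.05) {
  keys <- instance_keys(system, "dihedral")
  decisions <- list()
  for (key in sort(names(params$dihedrals))) {
    quads <- system$dihedrals[keys == key, , drop = FALSE]
    if (nrow(quads) == 0) {
      warning("orphan parameter: dihedral type '", key,
              "' has no instance in the system")
      next
    }
    phis <- measure_dihedrals(system$reference_geometry, quads)
    for (t in params$dihedrals[[key]]) {
      decisions[[length(decisions) + 1L]] <-
        predict_phase_summed(t$n, phis, tie_tol, type_key = key)
    }
  }
  decisions
}

#' Force delta = 180 for n = 2 terms across double bonds
#'
#' The one well-established literature rule: an n = 2 term whose central bond
#' has bond order 2 gets phase 180 unconditionally, overriding the geometric
#' decision.  Idempotent; decisions for other terms are untouched.
#'
#' @param decisions list of `phase_decision`s from [predict_phases()].
#' @param system the molecule system; `bond_orders` must be available.
#' @export
apply_double_bond_rule <- function(decisions, system) {
  if (is.null(system$bond_orders))
    stop_pf("double-bond rule requested but the system has no bond orders",
            class = "phasefit_config_error")
  keys <- instance_keys(system, "dihedral")
  for (i in seq_along(decisions)) {
    d <- decisions[[i]]
    if (d$n != 2L) next
    quads <- system$dihedrals[keys == d$type_key, , drop = FALSE]
    if (nrow(quads) == 0) next
    orders <- vapply(seq_len(nrow(quads)), function(r) {
      bond_order_of(system, quads[r, 2], quads[r, 3])
    }, numeric(1))
    if (any(is.na(orders)))
      stop_pf("missing bond order for the central bond of '", d$type_key, "'",
              class = "phasefit_config_error")
    if (any(orders == 2)) {
      d$delta <- 180
      d$source <- "double-bond-rule"
      d$ambiguous <- FALSE
      d$alternatives <- NULL
      decisions[[i]] <- d
    }
  }
  decisions
}

decision_id <- function(d) paste0(d$type_key, " | n=", d$n)

#' Enumerate alternative phase assignments
#'
#' Returns the default assignment first, then assignments flipping each
#' subset of the ambiguous (and manually named) decisions, in increasing
#' subset size, truncated at `cap`.  Each assignment is a complete
#' `(type key, n) -> delta` mapping, named `"<type key> | n=<n>"`.
#'
#' @param decisions list of `phase_decision`s.
#' @param overrides optional character vector of decision ids
#'   (`"<type key> | n=<n>"`) that may be flipped in addition to the
#'   ambiguous ones.
#' @param cap maximum number of assignments returned.
#' @export
enumerate_alternatives <- function(decisions, overrides = NULL, cap = 16L) {
  stopifnot(cap >= 1)
  ids <- vapply(decisions, decision_id, character(1))
  base <- setNames(vapply(decisions, function(d) d$delta, numeric(1)), ids)
  if (!is.null(overrides)) {
    unknown <- setdiff(overrides, ids)
    if (length(unknown))
      stop_pf("override names unknown (type, n) targets: ",
              paste(unknown, collapse = "; "),
              class = "phasefit_unknown_target")
  }
  flippable <- unique(c(ids[vapply(decisions, `[[`, logical(1), "ambiguous")],
                        overrides))
  assignments <- list(base)
  if (length(flippable)) {
    for (size in seq_along(flippable)) {
      combos <- utils::combn(flippable, size, simplify = FALSE)
      for (cset in combos) {
        a <- base
        a[cset] <- ifelse(a[cset] == 0, 180, 0)
        assignments[[length(assignments) + 1L]] <- a
        if (length(assignments) >= cap) return(assignments)
      }
    }
  }
  assignments
}

#' @export
print.phase_decision <- function(x, ...) {
  cat(sprintf("<phase_decision> %s n=%d -> delta=%g (gap %.4f%s, %s)\n",
              x$type_key, x$n, x$delta, x$score_gap,
              if (x$ambiguous) ", AMBIGUOUS" else "", x$source))
  invisible(x)
}

# Tabular view used by reports and the CLI.
phase_decision_df <- function(decisions) {
  if (!length(decisions)) {
    return(data.frame(type_key = character(), n = integer(), delta = numeric(),
                      score_gap = numeric(), ambiguous = logical(),
                      source = character()))
  }
  data.frame(
    type_key = vapply(decisions, `[[`, character(1), "type_key"),
    n = vapply(decisions, `[[`, integer(1), "n"),
    delta = vapply(decisions, `[[`, numeric(1), "delta"),
    score_gap = vapply(decisions, `[[`, numeric(1), "score_gap"),
    ambiguous = vapply(decisions, `[[`, logical(1), "ambiguous"),
    source = vapply(decisions, `[[`, character(1), "source"),
    stringsAsFactors = FALSE)
}
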