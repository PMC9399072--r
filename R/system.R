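# MoleculeSystem: atoms, connectivity, atom types, charges, reference geometry.
# Angle instances are exactly the length-2 simple paths of the bond graph and
# dihedral instances exactly the length-3 simple paths; both are enumerated
# once at construction together with their canonical type keys.

#' Construct a molecule system
#'
#' @param atoms data.frame with columns `element`, `type`, `charge`, `mass`
#'   and optionally `name` (atom names default to element + index).
#' @param bonds two-column integer matrix of bonded atom index pairs.
#' @param reference_geometry N x 3 coordinate matrix (Angstrom), the target
#'   equilibrium geometry.
#' @param bond_orders optional named numeric vector keyed `"i-j"` (i < j) or a
#'   vector parallel to the rows of `bonds`; unlisted bonds default to order 1.
#'   `NULL` means bond orders are unknown.
#' @param impropers optional matrix (rows of 4 atom indices) of improper
#'   dihedral instances in CHARMM quadruple order.
#' @param selections named list of atom-index vectors (e.g. `"ring-heavy"`).
#' @return An object of class `molecule_system`.
#' @export
molecule_system <- function(atoms, bonds, reference_geometry,
                            bond_orders = NULL, impropers = NULL,
                            selections = list()) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  stopifnot(all(c("element", "type", "charge", "mass") %in% names(atoms)))
  n <- nrow(atoms)
  if (n < 1) stop("empty molecule")
  if (any(!nzchar(atoms$element))) stop("every atom needs a non-empty element")
  if (any(!is.finite(atoms$charge))) stop("charges must be finite")
  if (is.null(atoms$name)) atoms$name <- paste0(atoms$element, seq_len(n))
  if (anyDuplicated(atoms$name) > 0) stop("atom names must be unique")

  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (any(bonds < 1L) || any(bonds > n)) stop("bond index out of range")
  if (any(bonds[, 1] == bonds[, 2])) stop("bond indices must be distinct")
  bonds <- t(apply(bonds, 1, sort))
  bonds <- bonds[!duplicated(paste(bonds[, 1], bonds[, 2])), , drop = FALSE]

  geom <- as_coords(reference_geometry)
  if (nrow(geom) != n)
    stop("reference_geometry must have one coordinate triple per atom")

  adj <- vector("list", n)
  for (r in seq_len(nrow(bonds))) {
    i <- bonds[r, 1]; j <- bonds[r, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj <- lapply(adj, function(x) sort(unique(x)))
  if (!graph_connected(adj, n)) stop("bond graph must be connected")

  if (!is.null(bond_orders)) {
    if (is.null(names(bond_orders))) {
      if (length(bond_orders) != nrow(bonds))
        stop("unnamed bond_orders must parallel the bond list")
      names(bond_orders) <- paste0(bonds[, 1], "-", bonds[, 2])
    }
    full <- setNames(rep(1, nrow(bonds)), paste0(bonds[, 1], "-", bonds[, 2]))
    unknown <- setdiff(names(bond_orders), names(full))
    if (length(unknown))
      stop("bond_orders given for non-bonded pairs: ", paste(unknown, collapse = ", "))
    full[names(bond_orders)] <- bond_orders
    bond_orders <- full
  }

  if (!is.null(impropers)) {
    impropers <- matrix(as.integer(impropers), ncol = 4)
    if (any(impropers < 1L) || any(impropers > n)) stop("improper index out of range")
  }

  sys <- structure(list(
    atoms = atoms, bonds = bonds, bond_orders = bond_orders,
    impropers = impropers, reference_geometry = geom,
    selections = selections, adjacency = adj), class = "molecule_system")
  sys$angles <- enumerate_angles(sys)
  sys$dihedrals <- enumerate_dihedrals(sys)
  sys$exclusions <- topo_exclusions(sys)
  sys
}

graph_connected <- function(adj, n) {
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- adj[[v]]
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  all(seen)
}

# Length-2 simple paths (i, j, k), i < k to avoid double counting.
enumerate_angles <- function(sys) {
  out <- list()
  for (j in seq_len(nrow(sys$atoms))) {
    nb <- sys$adjacency[[j]]
    if (length(nb) < 2) next
    for (a in seq_len(length(nb) - 1)) {
      for (b in (a + 1):length(nb)) {
        out[[length(out) + 1L]] <- c(nb[a], j, nb[b])
      }
    }
  }
  if (!length(out)) return(matrix(integer(), ncol = 3))
  do.call(rbind, out)
}

# Length-3 simple paths (i, j, k, l) enumerated once per central bond.
enumerate_dihedrals <- function(sys) {
  out <- list()
  for (r in seq_len(nrow(sys$bonds))) {
    j <- sys$bonds[r, 1]; k <- sys$bonds[r, 2]
    for (i in setdiff(sys$adjacency[[j]], k)) {
      for (l in setdiff(sys$adjacency[[k]], j)) {
        if (i == l) next   # 3-ring: not a simple path
        out[[length(out) + 1L]] <- c(i, j, k, l)
      }
    }
  }
  if (!length(out)) return(matrix(integer(), ncol = 4))
  quads <- do.call(rbind, out)
  # One instance per unordered quadruple
  keys <- apply(quads, 1, function(q) {
    fwd <- paste(q, collapse = "-"); bwd <- paste(rev(q), collapse = "-")
    if (bwd < fwd) bwd else fwd
  })
  quads[!duplicated(keys), , drop = FALSE]
}

# 1-2 and 1-3 excluded pairs; everything else (1-4 and beyond) interacts.
topo_exclusions <- function(sys) {
  n <- nrow(sys$atoms)
  excl <- new.env(hash = TRUE)
  mark <- function(i, j) assign(paste(min(i, j), max(i, j)), TRUE, envir = excl)
  for (r in seq_len(nrow(sys$bonds))) mark(sys$bonds[r, 1], sys$bonds[r, 2])
  if (nrow(sys$angles)) {
    for (r in seq_len(nrow(sys$angles))) mark(sys$angles[r, 1], sys$angles[r, 3])
  }
  pairs <- list()
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (!exists(paste(i, j), envir = excl)) pairs[[length(pairs) + 1L]] <- c(i, j)
      }
    }
  }
  if (!length(pairs)) matrix(integer(), ncol = 2) else do.call(rbind, pairs)
}

atom_types <- function(sys) sys$atoms$type

instance_type_key <- function(sys, idx) canonical_key(sys$atoms$type[idx])

# Canonical type keys for all instances of one class.
instance_keys <- function(sys, kind = c("bond", "angle", "dihedral", "improper")) {
  kind <- match.arg(kind)
  inst <- switch(kind,
    bond = sys$bonds, angle = sys$angles,
    dihedral = sys$dihedrals, improper = sys$impropers)
  if (is.null(inst) || nrow(inst) == 0) return(character())
  apply(inst, 1, function(ix) canonical_key(sys$atoms$type[ix]))
}

# Instances (rows) of a given canonical dihedral type key.
dihedral_instances_of <- function(sys, type_key) {
  keys <- instance_keys(sys, "dihedral")
  sys$dihedrals[keys == type_key, , drop = FALSE]
}

# Atoms on the k-side of bond (j, k), for torsion perturbation.  BFS from k
# without crossing the j-k edge; for ring bonds the walk additionally never
# enters atom `block` (usually the first atom of the driven quadruple), which
# splits the ring there.
downstream_atoms <- function(sys, j, k, block = integer()) {
  seen <- logical(nrow(sys$atoms))
  seen[c(j, block)] <- TRUE
  queue <- k
  seen[k] <- TRUE
  out <- integer()
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    out <- c(out, v)
    nb <- sys$adjacency[[v]]
    if (v == k) nb <- setdiff(nb, j)
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  setdiff(out, k)
}

bond_order_of <- function(sys, i, j) {
  if (is.null(sys$bond_orders)) return(NA_real_)
  key <- paste0(min(i, j), "-", max(i, j))
  unname(sys$bond_orders[key])
}

#' @export
print.molecule_system <- function(x, ...) {
  cat("<molecule_system> ", nrow(x$atoms), " atoms, ", nrow(x$bonds), " bonds, ",
      nrow(x$angles), " angles, ", nrow(x$dihedrals), " dihedrals, ",
      if (is.null(x$impropers)) 0 else nrow(x$impropers), " impropers\n", sep = "")
  invisible(x)
}

#' Construct a frame (one geometry with optional energy)
#'
#' @param coordinates N x 3 coordinate matrix (Angstrom).
#' @param energy optional energy in kcal/mol.
#' @param driven_angles optional named numeric vector of driven torsions.
#' @export
frame <- function(coordinates, energy = NULL, driven_angles = NULL) {
  coordinates <- as_coords(coordinates)
  if (!is.null(energy) && !is.finite(energy)) stop("frame energy must be finite")
  structure(list(coordinates = coordinates, energy = energy,
                 driven_angles = driven_angles), class = "frame")
}
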