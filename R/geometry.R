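# Internal-coordinate geometry: bonds, angles, torsions, Kabsch superposition.
# All angles are in degrees at every interface; coordinates in Angstrom as
# an N x 3 numeric matrix.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Row-wise cross product for m x 3 matrices.
cross3m <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

as_coords <- function(geometry) {
  if (is.list(geometry) && !is.null(geometry$coordinates)) {
    geometry <- geometry$coordinates
  }
  geometry <- as.matrix(geometry)
  if (ncol(geometry) != 3) stop("geometry must be an N x 3 matrix")
  storage.mode(geometry) <- "double"
  geometry
}

#' Measure a bond length
#'
#' @param geometry N x 3 coordinate matrix (Angstrom) or a [frame()].
#' @param i,j atom indices (1-based).
#' @return Distance in Angstrom.
#' @export
measure_bond <- function(geometry, i, j) {
  g <- as_coords(geometry)
  sqrt(sum((g[i, ] - g[j, ])^2))
}

#' Measure a valence angle
#'
#' @inheritParams measure_bond
#' @param k third atom index; the angle is at atom `j`.
#' @return Angle in degrees in \[0, 180\].
#' @export
measure_angle <- function(geometry, i, j, k) {
  g <- as_coords(geometry)
  u <- g[i, ] - g[j, ]
  v <- g[k, ] - g[j, ]
  cosx <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  rad2deg(acos(pmin(1, pmax(-1, cosx))))
}

#' Measure a dihedral (torsion) angle
#'
#' Signed torsion in the IUPAC convention (cis = 0), value in (-180, 180].
#' Reversing the quadruple returns the same value.
#'
#' @param geometry N x 3 coordinate matrix (Angstrom) or a [frame()].
#' @param quadruple four distinct atom indices (i, j, k, l).
#' @return Torsion angle in degrees.
#' @export
measure_dihedral <- function(geometry, quadruple) {
  g <- as_coords(geometry)
  q <- as.integer(quadruple)
  if (length(q) != 4 || anyDuplicated(q) > 0 || any(q < 1L) || any(q > nrow(g)))
    stop("quadruple must be four distinct in-range atom indices")
  b1 <- g[q[2], ] - g[q[1], ]
  b2 <- g[q[3], ] - g[q[2], ]
  b3 <- g[q[4], ] - g[q[3], ]
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  n1n <- sqrt(sum(n1^2)); n2n <- sqrt(sum(n2^2))
  scale <- sqrt(sum(b1^2)) * sum(abs(b2)) + sqrt(sum(b3^2))
  if (n1n < 1e-10 * max(1, scale) || n2n < 1e-10 * max(1, scale))
    stop_pf("degenerate geometry: collinear triple in quadruple (",
            paste(q, collapse = ", "), ")", class = "phasefit_degenerate_geometry")
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  wrap_angle(rad2deg(atan2(sum(m1 * n2), sum(n1 * n2))))
}

# Vectorised torsions for a set of quadruples (matrix with 4 columns).
measure_dihedrals <- function(geometry, quads) {
  g <- as_coords(geometry)
  if (is.null(dim(quads))) quads <- matrix(quads, ncol = 4)
  b1 <- g[quads[, 2], , drop = FALSE] - g[quads[, 1], , drop = FALSE]
  b2 <- g[quads[, 3], , drop = FALSE] - g[quads[, 2], , drop = FALSE]
  b3 <- g[quads[, 4], , drop = FALSE] - g[quads[, 3], , drop = FALSE]
  n1 <- cross3m(b1, b2)
  n2 <- cross3m(b2, b3)
  b2n <- sqrt(rowSums(b2^2))
  m1 <- cross3m(n1, b2 / b2n)
  wrap_angle(rad2deg(atan2(rowSums(m1 * n2), rowSums(n1 * n2))))
}

#' Optimal rigid-body superposition (Kabsch) RMSD
#'
#' Minimum root-mean-square deviation over all proper rotations and
#' translations (no reflection), restricted to `selection`.
#'
#' @param reference,mobile N x 3 coordinate matrices.
#' @param selection atom indices used for the superposition (default: all).
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(reference, mobile, selection = NULL) {
  ref <- as_coords(reference)
  mob <- as_coords(mobile)
  if (is.null(selection)) selection <- seq_len(nrow(ref))
  selection <- as.integer(selection)
  if (length(selection) < 3)
    stop_pf("underdetermined superposition: selection has fewer than 3 atoms",
            class = "phasefit_underdetermined")
  a <- ref[selection, , drop = FALSE]
  b <- mob[selection, , drop = FALSE]
  a <- sweep(a, 2, colMeans(a))
  b <- sweep(b, 2, colMeans(b))
  s <- svd(crossprod(b, a))            # 3x3
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  diff <- b %*% rot - a
  sqrt(sum(diff^2) / length(selection))
}

# Apply a random rigid rotation + translation (used by tests and fixtures).
rigid_transform <- function(coords, angles = c(0, 0, 0), shift = c(0, 0, 0)) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  sweep(as_coords(coords) %*% t(rz %*% ry %*% rx), 2, -shift)
}

# Rotate `moving` atom set about the axis r[j] -> r[k] by `angle_deg`.
rotate_about_bond <- function(coords, j, k, moving, angle_deg) {
  g <- as_coords(coords)
  axis <- g[k, ] - g[j, ]
  axis <- axis / sqrt(sum(axis^2))
  th <- deg2rad(angle_deg)
  ct <- cos(th); st <- sin(th)
  ux <- axis[1]; uy <- axis[2]; uz <- axis[3]
  rot <- rbind(
    c(ct + ux^2 * (1 - ct), ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st),
    c(uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct), uy * uz * (1 - ct) - ux * st),
    c(uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)))
  origin <- g[k, ]
  g[moving, ] <- sweep(sweep(g[moving, , drop = FALSE], 2, origin) %*% t(rot), 2, -origin)
  g
}
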