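# Desk-scale validation surrogate: MM vs target torsion profiles, grid
# minima (with a staircase flip barrier on 2D surfaces), multi-start
# conformer search on the full MM model, GROMOS conformational clustering,
# and an overall verdict per parameter set.

#' MM torsion profile on the stored scan geometries
#'
#' @inheritParams scan_baseline
#' @return data.frame with the scan angles, the relative target energy
#'   (`target_rel`) and the min-subtracted MM energy (`mm_rel`); attribute
#'   `rmse` holds the offset-free RMSE between the two.
#' @export
mm_profile <- function(system, params, scan) {
  model <- compile_model(system, params, mm_options())
  mm <- vapply(scan$frames[scan$rows$frame], function(g) {
    sum(energy_breakdown_fast(model, g))
  }, numeric(1))
  out <- scan$rows
  out$target_rel <- out$energy - min(out$energy)
  out$mm_rel <- mm - min(mm)
  r <- out$target_rel - out$mm_rel
  r <- r - mean(r)
  attr(out, "rmse") <- sqrt(mean(r^2))
  out
}

#' Locate grid minima of a 1D or 2D torsion profile
#'
#' 1D: interior points lower than both neighbours, with periodic wrap only if
#' the grid spans 360 degrees.  2D: points lower than all 8 neighbours.  For
#' a 2D grid the minimum-energy monotone staircase path between the two
#' lowest minima is reported as the flip barrier (relative to the higher of
#' the two minima).
#'
#' @param energies numeric vector (1D) or matrix (2D, rows = first angle).
#' @param angles numeric vector (1D) or list of two vectors (2D).
#' @return List with `minima` (data.frame sorted by energy) and
#'   `flip_barrier` (2D only, else NA).
#' @export
locate_minima <- function(energies, angles) {
  if (is.matrix(energies)) return(locate_minima_2d(energies, angles))
  e <- as.numeric(energies)
  phi <- as.numeric(angles)
  m <- length(e)
  if (m < 3) stop_pf("grid too small: need at least 3 points",
                     class = "phasefit_grid_error")
  step <- phi[2] - phi[1]
  periodic <- isTRUE(all.equal(max(phi) - min(phi) + step, 360))
  idx <- integer()
  for (i in seq_len(m)) {
    # interior points only: a non-periodic boundary cell is never a minimum
    lo <- if (i > 1) e[i - 1] else if (periodic) e[m] else NA
    hi <- if (i < m) e[i + 1] else if (periodic) e[1] else NA
    if (!is.na(lo) && !is.na(hi) && e[i] < lo && e[i] < hi) idx <- c(idx, i)
  }
  minima <- data.frame(phi1 = phi[idx], energy = e[idx])
  minima <- minima[order(minima$energy), , drop = FALSE]
  rownames(minima) <- NULL
  list(minima = minima, flip_barrier = NA_real_)
}

locate_minima_2d <- function(E, angles) {
  p1 <- as.numeric(angles[[1]]); p2 <- as.numeric(angles[[2]])
  n1 <- length(p1); n2 <- length(p2)
  if (n1 < 3 || n2 < 3) stop_pf("grid too small: need at least 3 points per dimension",
                                class = "phasefit_grid_error")
  stopifnot(nrow(E) == n1, ncol(E) == n2)
  step1 <- p1[2] - p1[1]; step2 <- p2[2] - p2[1]
  per1 <- isTRUE(all.equal(max(p1) - min(p1) + step1, 360))
  per2 <- isTRUE(all.equal(max(p2) - min(p2) + step2, 360))
  wrapi <- function(i, n, per) {
    if (i < 1) { if (per) n else NA } else if (i > n) { if (per) 1 else NA } else i
  }
  mins <- list()
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) {
      ok <- TRUE
      for (di in -1:1) {
        for (dj in -1:1) {
          if (di == 0 && dj == 0) next
          ii <- wrapi(i + di, n1, per1); jj <- wrapi(j + dj, n2, per2)
          if (is.na(ii) || is.na(jj)) { ok <- FALSE; break }  # boundary cell
          if (E[ii, jj] <= E[i, j]) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (ok) mins[[length(mins) + 1L]] <- c(i, j)
    }
  }
  if (!length(mins)) {
    return(list(minima = data.frame(phi1 = numeric(), phi2 = numeric(),
                                    energy = numeric()),
                flip_barrier = NA_real_))
  }
  md <- do.call(rbind, mins)
  minima <- data.frame(phi1 = p1[md[, 1]], phi2 = p2[md[, 2]],
                       energy = E[cbind(md[, 1], md[, 2])])
  ord <- order(minima$energy)
  minima <- minima[ord, , drop = FALSE]
  rownames(minima) <- NULL
  md <- md[ord, , drop = FALSE]

  barrier <- NA_real_
  if (nrow(minima) >= 2) {
    a <- md[1, ]; b <- md[2, ]
    path_max <- staircase_minimax(E, a, b)
    barrier <- path_max - max(E[a[1], a[2]], E[b[1], b[2]])
  }
  list(minima = minima, flip_barrier = barrier)
}

# Minimax energy over monotone staircase paths from cell a to cell b.
# Moves are row, column or diagonal steps towards the target (a diagonal
# valley is then followed exactly rather than through off-valley corners).
staircase_minimax <- function(E, a, b) {
  is_ <- seq(a[1], b[1], by = if (b[1] >= a[1]) 1 else -1)
  js <- seq(a[2], b[2], by = if (b[2] >= a[2]) 1 else -1)
  ni <- length(is_); nj <- length(js)
  cost <- matrix(Inf, ni, nj)
  cost[1, 1] <- E[a[1], a[2]]
  for (i in seq_len(ni)) {
    for (j in seq_len(nj)) {
      if (i == 1 && j == 1) next
      prev <- Inf
      if (i > 1) prev <- min(prev, cost[i - 1, j])
      if (j > 1) prev <- min(prev, cost[i, j - 1])
      if (i > 1 && j > 1) prev <- min(prev, cost[i - 1, j - 1])
      cost[i, j] <- max(E[is_[i], js[j]], prev)
    }
  }
  cost[ni, nj]
}

#' Multi-start conformer search
#'
#' Generates starting frames by applying random torsion perturbations to the
#' reference geometry (for ring bonds the downstream walk splits the ring at
#' the first quadruple atom, so the kick distorts the ring and minimisation
#' settles it into a basin), then minimises the full MM energy.  Deterministic
#' given `seed`; non-converged starts are dropped with a warning.
#'
#' @inheritParams mm_energy
#' @param perturb list with `dihedrals` (list of quadruples) and `amplitude`
#'   (degrees, uniform in +-amplitude).
#' @param n_starts number of random starts.
#' @param seed RNG seed.
#' @param tol,maxit minimiser controls (see [minimise_frame()]).
#' @return A `conformer_set`: list of minimised frames with energies.
#' @export
conformer_search <- function(system, params, perturb, n_starts = 50, seed = 1,
                             tol = 1e-6, maxit = 3000) {
  stopifnot(n_starts >= 1)
  amp <- perturb$amplitude %||% 45
  quads <- perturb$dihedrals
  kicks <- with_seed(seed, {
    matrix(stats::runif(n_starts * length(quads), -amp, amp),
           nrow = n_starts)
  })
  frames <- list()
  dropped <- 0L
  for (s in seq_len(n_starts)) {
    g <- system$reference_geometry
    for (qi in seq_along(quads)) {
      q <- quads[[qi]]
      moving <- downstream_atoms(system, q[2], q[3], block = q[1])
      if (!length(moving)) next
      g <- rotate_about_bond(g, q[2], q[3], moving, kicks[s, qi])
    }
    res <- minimise_frame(system, params, g, tol = tol, maxit = maxit)
    if (!res$converged && res$max_grad > 1e-3) {
      dropped <- dropped + 1L
      next
    }
    frames[[length(frames) + 1L]] <- frame(res$coordinates, res$energy)
  }
  if (dropped > 0)
    warning(dropped, " of ", n_starts, " starts failed to converge and were dropped")
  structure(list(frames = frames, seed = seed, n_starts = n_starts,
                 dropped = dropped), class = "conformer_set")
}

frame_coords_list <- function(frames) {
  if (inherits(frames, "conformer_set")) frames <- frames$frames
  lapply(frames, as_coords)
}

#' GROMOS conformational clustering
#'
#' Iteratively: compute pairwise superposition RMSDs on `selection`; the
#' frame with the most neighbours within `cutoff` becomes a centroid, it and
#' its neighbours form a cluster and are removed; repeat.  Ties are broken by
#' the lowest frame index.
#'
#' @param frames a `conformer_set`, or list of frames / coordinate matrices.
#' @param selection atom indices used for the RMSD.
#' @param cutoff RMSD cutoff in Angstrom (default 0.2).
#' @return A `cluster_set`: clusters ordered by descending size, each with
#'   `members`, `centroid` (frame index) and `fraction`.
#' @export
gromos_cluster <- function(frames, selection = NULL, cutoff = 0.2) {
  coords <- frame_coords_list(frames)
  n <- length(coords)
  if (n < 1) stop("need at least one frame")
  D <- matrix(0, n, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        D[i, j] <- D[j, i] <- kabsch_rmsd(coords[[i]], coords[[j]], selection)
      }
    }
  }
  remaining <- seq_len(n)
  clusters <- list()
  while (length(remaining)) {
    counts <- vapply(remaining, function(i) {
      sum(D[i, remaining] <= cutoff)   # includes self
    }, numeric(1))
    centroid <- remaining[which.max(counts)]   # which.max: lowest index wins ties
    members <- remaining[D[centroid, remaining] <= cutoff]
    clusters[[length(clusters) + 1L]] <- list(
      members = members, centroid = centroid,
      fraction = length(members) / n)
    remaining <- setdiff(remaining, members)
  }
  structure(list(clusters = clusters, n_frames = n, cutoff = cutoff,
                 rmsd = D), class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("<cluster_set> ", length(x$clusters), " clusters over ", x$n_frames,
      " frames (cutoff ", x$cutoff, " A)\n", sep = "")
  for (i in seq_along(x$clusters)) {
    cl <- x$clusters[[i]]
    cat(sprintf("  #%d: %d frames (%.1f%%), centroid frame %d\n", i,
                length(cl$members), 100 * cl$fraction, cl$centroid))
  }
  invisible(x)
}

#' Validate a parameter set against scans and the reference geometry
#'
#' Reports (a) per-scan MM-vs-target RMSE, (b) whether the MM global minimum
#' of each 1D profile lies within 15 degrees of the reference torsion,
#' (c) the conformer-search cluster structure with per-cluster RMSD to the
#' reference on the `ring-heavy` selection, and (d) a verdict: pass iff all
#' 1D minima agree and the top cluster's RMSD is at most `verdict_rmsd`.
#' Two dominant clusters (fraction >= `dominant_fraction`) are annotated as a
#' conformational flip.
#'
#' @inheritParams conformer_search
#' @param scans list of `scan_table`s.
#' @param config a [run_config()] (cluster cutoff, verdict RMSD, seed, ...).
#' @param perturb torsion-perturbation spec; defaults to all scanned torsions
#'   at 45 degrees amplitude.
#' @param selection RMSD selection; defaults to the system's `"ring-heavy"`
#'   selection, else all atoms.
#' @return A `validation_report`.
#' @export
validate_parameters <- function(system, params, scans, config = run_config(),
                                perturb = NULL, selection = NULL,
                                n_starts = 50) {
  if (inherits(scans, "scan_table")) scans <- list(scans)
  selection <- selection %||% system$selections[["ring-heavy"]] %||%
    seq_len(nrow(system$atoms))

  scan_rows <- list()
  for (s in seq_along(scans)) {
    scan <- scans[[s]]
    prof <- mm_profile(system, params, scan)
    if (!scan_is_2d(scan)) {
      lm <- locate_minima(prof$mm_rel, prof$phi1)
      ref_phi <- measure_dihedral(system$reference_geometry, scan$driven[[1]])
      mm_min <- if (nrow(lm$minima)) lm$minima$phi1[1] else NA_real_
      ok <- !is.na(mm_min) && abs(wrap_angle(mm_min - ref_phi)) <= 15
      scan_rows[[s]] <- data.frame(scan = s, dims = 1,
                                   rmse = attr(prof, "rmse"),
                                   mm_min_phi = mm_min, ref_phi = ref_phi,
                                   min_ok = ok)
    } else {
      scan_rows[[s]] <- data.frame(scan = s, dims = 2,
                                   rmse = attr(prof, "rmse"),
                                   mm_min_phi = NA_real_, ref_phi = NA_real_,
                                   min_ok = NA)
    }
  }
  scan_report <- do.call(rbind, scan_rows)

  if (is.null(perturb)) {
    quads <- lapply(Filter(function(s) !scan_is_2d(s), scans),
                    function(s) s$driven[[1]])
    if (!length(quads)) quads <- lapply(scans, function(s) s$driven[[1]])
    perturb <- list(dihedrals = quads, amplitude = 45)
  }
  conf <- conformer_search(system, params, perturb, n_starts = n_starts,
                           seed = config$seed)
  clusters <- gromos_cluster(conf, selection = selection,
                             cutoff = config$cluster_cutoff)
  coords <- frame_coords_list(conf)
  rmsd_ref <- vapply(clusters$clusters, function(cl) {
    kabsch_rmsd(system$reference_geometry, coords[[cl$centroid]], selection)
  }, numeric(1))

  fractions <- vapply(clusters$clusters, `[[`, numeric(1), "fraction")
  n_dominant <- sum(fractions >= config$dominant_fraction)
  top_rmsd <- rmsd_ref[1]
  min_checks <- scan_report$min_ok[!is.na(scan_report$min_ok)]
  verdict <- all(min_checks) && top_rmsd <= config$verdict_rmsd

  structure(list(scan_report = scan_report, clusters = clusters,
                 cluster_rmsd_to_reference = rmsd_ref,
                 n_dominant_clusters = n_dominant,
                 flip = n_dominant == 2L,
                 top_cluster_rmsd = top_rmsd,
                 verdict = verdict,
                 selection = selection,
                 conformers = conf,
                 config = config), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> verdict:", if (x$verdict) "PASS" else "FAIL", "\n")
  cat("  top cluster RMSD to reference:", round(x$top_cluster_rmsd, 4), "A\n")
  cat("  dominant clusters:", x$n_dominant_clusters,
      if (x$flip) "(conformational flip)" else "", "\n")
  cat("  mean scan RMSE:", round(mean(x$scan_report$rmse), 4), "kcal/mol\n")
  invisible(x)
}

#' Rank validated phase assignments
#'
#' Assignments are ranked by top-cluster RMSD to the reference, ties broken
#' by mean scan RMSE.
#'
#' @param reports named list of `validation_report`s.
#' @return data.frame, best assignment first.
#' @export
rank_assignments <- function(reports) {
  df <- data.frame(
    assignment = names(reports) %||% as.character(seq_along(reports)),
    top_cluster_rmsd = vapply(reports, `[[`, numeric(1), "top_cluster_rmsd"),
    mean_scan_rmse = vapply(reports, function(r) mean(r$scan_report$rmse),
                            numeric(1)),
    verdict = vapply(reports, `[[`, logical(1), "verdict"),
    stringsAsFactors = FALSE)
  df <- df[order(df$top_cluster_rmsd, df$mean_scan_rmse), , drop = FALSE]
  rownames(df) <- NULL
  df
}
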