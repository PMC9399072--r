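# Dihedral force-constant fitting: with multiplicities and phases fixed the
# objective is linear in k, so the fit is a non-negative least-squares
# problem with one free additive offset per scan (QM and MM energy zeros are
# unrelated).  Rows whose min-subtracted target energy exceeds the cutoff
# (default 10 kcal/mol) are excluded before fitting.

#' A named group of dihedral type keys with a fitting priority
#'
#' @param name group label (e.g. `"ring4"`, `"double-bond"`, `"carboxylate"`).
#' @param members character vector of canonical dihedral type keys.
#' @param order_rank integer fitting priority (smaller fits first).
#' @export
dihedral_group <- function(name, members, order_rank = 1L) {
  structure(list(name = name, members = unique(members),
                 order_rank = as.integer(order_rank)),
            class = "dihedral_group")
}

# Lawson-Hanson non-negative least squares: min ||Ax - b||, x >= 0.
nnls_fit <- function(A, b) {
  n <- ncol(A)
  if (n == 0) return(numeric(0))
  x <- numeric(n)
  P <- logical(n)
  tol <- 1e-10 * max(1, max(abs(crossprod(A, b))))
  outer_iter <- 0L
  repeat {
    outer_iter <- outer_iter + 1L
    w <- as.numeric(crossprod(A, b - A %*% x))
    if (all(P) || max(w[!P]) <= tol || outer_iter > 30L * n) break
    j <- which(!P)[which.max(w[!P])]
    P[j] <- TRUE
    inner_iter <- 0L
    repeat {
      inner_iter <- inner_iter + 1L
      z <- numeric(n)
      zp <- qr.coef(qr(A[, P, drop = FALSE]), b)
      zp[is.na(zp)] <- 0
      z[P] <- zp
      if (all(z[P] > tol) || inner_iter > 30L * n) { x <- z; break }
      neg <- P & (z <= tol)
      if (!any(neg)) { x <- z; break }
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      P[P & (x <= tol)] <- FALSE
      x[!P] <- 0
    }
  }
  pmax(x, 0)
}

#' Per-row MM baseline of a scan with a dihedral group zeroed
#'
#' The MM energy of each scan frame with every cosine term of the group's
#' member types removed, min-subtracted across the scan's rows.
#'
#' @inheritParams mm_energy
#' @param scan a `scan_table`.
#' @param group a [dihedral_group()]; an empty group gives the full MM profile.
#' @param options base term toggles (the group zeroing is added on top).
#' @export
scan_baseline <- function(system, params, scan, group,
                          options = mm_options()) {
  options$zero_dihedral_types <- unique(c(options$zero_dihedral_types,
                                          group$members))
  model <- compile_model(system, params, options)
  e <- vapply(scan$frames[scan$rows$frame], function(g) {
    sum(energy_breakdown_fast(model, g))
  }, numeric(1))
  e - min(e)
}

# Column of the fitting design: sum over instances of a type of
# (1 + cos(n phi - delta)) per scan row.
term_basis <- function(system, scan, type_key, n, delta) {
  quads <- dihedral_instances_of(system, type_key)
  if (nrow(quads) == 0) return(rep(0, nrow(scan$rows)))
  vapply(scan$frames[scan$rows$frame], function(g) {
    phis <- measure_dihedrals(g, quads)
    sum(1 + cos(deg2rad(n * phis - delta)))
  }, numeric(1))
}

term_id <- function(key, n) paste0(key, " | n=", n)

# Terms of a group resolved against params + assignment.
group_terms <- function(params, group, assignment = NULL) {
  out <- list()
  for (key in intersect(sort(names(params$dihedrals)), sort(group$members))) {
    for (t in params$dihedrals[[key]]) {
      id <- term_id(key, t$n)
      delta <- if (!is.null(assignment) && id %in% names(assignment)) {
        unname(assignment[id])
      } else t$delta
      out[[id]] <- list(key = key, n = t$n, delta = delta, k_in = t$k_phi)
    }
  }
  out
}

#' Fit dihedral force constants of one group to torsion scans
#'
#' Solves `min over {k >= 0, per-scan offsets}` of the squared residual
#' between the relative target energies and baseline + cosine terms, with
#' phases fixed by `assignment` (or the incoming parameter phases).  Rows
#' whose min-subtracted target energy exceeds `cutoff` are excluded.  Terms
#' whose basis column has no variance across the included rows are reported
#' as unidentifiable and keep their incoming force constant.
#'
#' @inheritParams scan_baseline
#' @param scans list of `scan_table`s.
#' @param assignment named numeric vector `"<type key> | n=<n>" -> delta`.
#' @param cutoff energy cutoff in kcal/mol (default 10).
#' @return A `fit_result` with fitted constants, per-scan offsets, RMSE
#'   before/after, row counts, the assignment used, the design conditioning
#'   (`kappa`) and the updated `params`.
#' @export
fit_group <- function(system, params, scans, group, assignment = NULL,
                      cutoff = 10) {
  if (inherits(scans, "scan_table")) scans <- list(scans)
  terms <- group_terms(params, group, assignment)
  ids <- names(terms)

  y <- numeric(); scan_of <- integer(); basis <- NULL
  used <- 0L; excluded <- 0L
  for (s in seq_along(scans)) {
    scan <- scans[[s]]
    e_rel <- scan$rows$energy - min(scan$rows$energy)
    keep <- e_rel <= cutoff
    if (!any(keep))
      stop_pf("all rows of scan ", s, " excluded by the ", cutoff,
              " kcal/mol cutoff", class = "phasefit_empty_fit")
    used <- used + sum(keep)
    excluded <- excluded + sum(!keep)
    base <- scan_baseline(system, params, scan, group)
    cols <- vapply(ids, function(id) {
      term_basis(system, scan, terms[[id]]$key, terms[[id]]$n,
                 terms[[id]]$delta)
    }, numeric(nrow(scan$rows)))
    cols <- matrix(cols, nrow = nrow(scan$rows))
    y <- c(y, (e_rel - base)[keep])
    basis <- rbind(basis, cols[keep, , drop = FALSE])
    scan_of <- c(scan_of, rep(s, sum(keep)))
  }
  if (length(ids) == 0)
    stop_pf("group '", group$name, "' has no fittable terms",
            class = "phasefit_empty_fit")
  colnames(basis) <- ids

  center <- function(v) v - stats::ave(v, scan_of)
  yc <- center(y)
  Xc <- apply(basis, 2, center)
  Xc <- matrix(Xc, nrow = length(y), dimnames = list(NULL, ids))

  identifiable <- apply(Xc, 2, function(col) diff(range(col)) > 1e-8)
  k_in <- vapply(ids, function(id) terms[[id]]$k_in, numeric(1))

  # unidentifiable terms keep incoming k; their contribution moves into y
  if (any(!identifiable)) {
    y <- y - basis[, !identifiable, drop = FALSE] %*% k_in[!identifiable]
    y <- as.numeric(y)
    yc <- center(y)
  }
  Xi <- Xc[, identifiable, drop = FALSE]

  rmse <- function(k_id) {
    r <- yc - Xi %*% k_id
    sqrt(mean(r^2))
  }
  rmse_before <- rmse(k_in[identifiable])

  k_fit <- k_in
  kappa <- NA_real_
  if (ncol(Xi) > 0) {
    k_fit[identifiable] <- nnls_fit(Xi, yc)
    sv <- svd(Xi)$d
    kappa <- if (min(sv) > 0) max(sv) / min(sv) else Inf
  }
  rmse_after <- rmse(k_fit[identifiable])

  # free per-scan offsets recovered on the uncentered system
  resid_raw <- y - basis %*% k_fit
  offsets <- tapply(as.numeric(resid_raw), scan_of, mean)

  new_params <- params
  for (id in ids) {
    tt <- terms[[id]]
    new_params <- ps_set_dihedral_term(new_params, key_types(tt$key),
                                       dihedral_term(k_fit[[id]], tt$n,
                                                     tt$delta))
  }

  structure(list(
    group = group$name,
    fitted = setNames(k_fit, ids),
    offsets = as.numeric(offsets),
    rmse_before = rmse_before,
    rmse_after = rmse_after,
    points_used = used,
    points_excluded = excluded,
    assignment = setNames(vapply(ids, function(id) terms[[id]]$delta,
                                 numeric(1)), ids),
    unidentifiable = ids[!identifiable],
    kappa = kappa,
    params = new_params), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> group '%s': rmse %.4f -> %.4f kcal/mol (%d rows, %d excluded)\n",
              x$group, x$rmse_before, x$rmse_after, x$points_used,
              x$points_excluded))
  for (id in names(x$fitted)) {
    cat(sprintf("  %s: k = %.4f, delta = %g%s\n", id, x$fitted[[id]],
                x$assignment[[id]],
                if (id %in% x$unidentifiable) " (unidentifiable)" else ""))
  }
  invisible(x)
}

#' Greedy multiplicity augmentation
#'
#' Starting from a completed base fit, tries every candidate multiplicity not
#' already present on each member type, with both the geometry-predicted
#' phase and its alternate; accepts the single best candidate whenever it
#' reduces the group RMSE by at least `accept_threshold` (relative), then
#' repeats until no candidate qualifies.  Every trial is reported.
#'
#' @inheritParams fit_group
#' @param candidates multiplicities to try (default 1, 2, 3, 4, 6).
#' @param accept_threshold relative RMSE reduction required (default 0.10).
#' @param tie_tol tie tolerance passed to the phase prediction.
#' @return List with updated `params`, the trial `report`, the final `fit`
#'   and the final `assignment`.
#' @export
augment_multiplicities <- function(system, params, scans, group,
                                   assignment = NULL,
                                   candidates = c(1, 2, 3, 4, 6),
                                   accept_threshold = 0.10, cutoff = 10,
                                   tie_tol = 0.05) {
  if (inherits(scans, "scan_table")) scans <- list(scans)
  base <- fit_group(system, params, scans, group, assignment, cutoff)
  params <- base$params
  if (is.null(assignment)) assignment <- base$assignment
  report <- list()
  dihedral_keys <- instance_keys(system, "dihedral")

  repeat {
    if (base$rmse_after < 1e-9) break
    best <- NULL
    for (key in intersect(sort(names(params$dihedrals)), sort(group$members))) {
      have_n <- vapply(params$dihedrals[[key]], `[[`, integer(1), "n")
      quads <- system$dihedrals[dihedral_keys == key, , drop = FALSE]
      phis <- measure_dihedrals(system$reference_geometry, quads)
      for (n in setdiff(as.integer(candidates), have_n)) {
        d_geo <- predict_phase_summed(n, phis, tie_tol)$delta
        for (delta in c(d_geo, setdiff(c(0, 180), d_geo))) {
          p_try <- ps_set_dihedral_term(params, key_types(key),
                                        dihedral_term(0, n, delta))
          a_try <- assignment
          a_try[term_id(key, n)] <- delta
          fit <- fit_group(system, p_try, scans, group, a_try, cutoff)
          reduction <- (base$rmse_after - fit$rmse_after) / base$rmse_after
          report[[length(report) + 1L]] <- data.frame(
            type_key = key, n = n, delta = delta, rmse = fit$rmse_after,
            reduction = reduction, accepted = FALSE, stringsAsFactors = FALSE)
          if (reduction >= accept_threshold &&
              (is.null(best) || fit$rmse_after < best$fit$rmse_after)) {
            best <- list(fit = fit, assignment = a_try,
                         row = length(report))
          }
        }
      }
    }
    if (is.null(best)) break
    report[[best$row]]$accepted <- TRUE
    params <- best$fit$params
    assignment <- best$assignment
    base <- best$fit
  }

  report <- if (length(report)) do.call(rbind, report) else
    data.frame(type_key = character(), n = integer(), delta = numeric(),
               rmse = numeric(), reduction = numeric(), accepted = logical())
  list(params = params, report = report, fit = base, assignment = assignment)
}

# Full-model RMSE of one scan (free offset, included rows only).
scan_rmse <- function(system, params, scan, cutoff = Inf) {
  e_rel <- scan$rows$energy - min(scan$rows$energy)
  keep <- e_rel <= cutoff
  model <- compile_model(system, params, mm_options())
  mm <- vapply(scan$frames[scan$rows$frame], function(g) {
    sum(energy_breakdown_fast(model, g))
  }, numeric(1))
  r <- (e_rel - (mm - min(mm)))[keep]
  r <- r - mean(r)
  sqrt(mean(r^2))
}

# A scan belongs to a group when its driven dihedral is an instance of a
# member, or when it couples to one (some member torsion varies by more than
# `coupling_tol` degrees across the scan frames - ring scans couple to every
# ring group, a rigid exocyclic rotation does not).
scans_for_group <- function(system, scans, group, coupling_tol = 5) {
  keep <- vapply(scans, function(scan) {
    if (any(vapply(scan$driven, function(q) {
      instance_type_key(system, q) %in% group$members
    }, logical(1)))) return(TRUE)
    for (key in group$members) {
      quads <- dihedral_instances_of(system, key)
      if (!nrow(quads)) next
      phis <- vapply(scan$frames[scan$rows$frame], function(g) {
        measure_dihedrals(g, quads)
      }, numeric(nrow(quads)))
      phis <- matrix(phis, nrow = nrow(quads))
      spread <- max(apply(phis, 1, function(v) {
        diff(range(wrap_angle(v - v[1])))
      }))
      if (spread > coupling_tol) return(TRUE)
    }
    FALSE
  }, logical(1))
  scans[keep]
}

#' Group-sequential dihedral fitting workflow
#'
#' Fits groups in `order_rank` order, each stage seeing the parameters left by
#' the previous one, and repeats the whole sequence `iterations` times (the
#' second pass ensures convergence of coupled groups).  Each group is fitted
#' against the scans whose driven dihedral is an instance of one of its
#' members; scans matching no group are used by every group.
#'
#' @inheritParams fit_group
#' @param groups list of [dihedral_group()]s; disjoint membership required.
#' @param iterations number of passes over the group sequence (default 2).
#' @return List with final `params`, per-stage `stages`, and
#'   `scan_rmse_by_iteration` (scans x iterations matrix, non-increasing
#'   column-wise).
#' @export
fit_workflow <- function(system, params, scans, groups, assignment = NULL,
                         iterations = 2, cutoff = 10) {
  if (inherits(scans, "scan_table")) scans <- list(scans)
  all_members <- unlist(lapply(groups, `[[`, "members"))
  if (anyDuplicated(all_members) > 0)
    stop("dihedral groups must be disjoint")
  groups <- groups[order(vapply(groups, `[[`, integer(1), "order_rank"))]

  # the predicted phases are fixed on every term up front, before any
  # fitting: baselines must never see stale phases from the starting set
  if (!is.null(assignment)) {
    for (id in names(assignment)) {
      parts <- strsplit(id, " | n=", fixed = TRUE)[[1]]
      key <- parts[1]; n <- as.integer(parts[2])
      for (t in params$dihedrals[[key]] %||% list()) {
        if (t$n == n && t$delta != assignment[[id]]) {
          params <- ps_set_dihedral_term(params, key_types(key),
                                         dihedral_term(t$k_phi, n,
                                                       assignment[[id]]))
        }
      }
    }
  }

  matched_idx <- lapply(groups, function(g) {
    which(vapply(seq_along(scans), function(s) {
      length(scans_for_group(system, scans[s], g)) == 1L
    }, logical(1)))
  })
  orphan <- setdiff(seq_along(scans), unlist(matched_idx))
  if (length(orphan)) {
    warning(length(orphan),
            " scan(s) drive or couple to no group member; used by every group")
    matched_idx <- lapply(matched_idx, function(ix) sort(union(ix, orphan)))
  }
  matched <- lapply(matched_idx, function(ix) scans[ix])

  stages <- list()
  rmse_mat <- matrix(NA_real_, nrow = length(scans), ncol = iterations)
  for (iter in seq_len(iterations)) {
    for (gi in seq_along(groups)) {
      g_scans <- matched[[gi]]
      if (!length(g_scans)) next
      fit <- fit_group(system, params, g_scans, groups[[gi]], assignment,
                       cutoff)
      params <- fit$params
      stages[[length(stages) + 1L]] <- fit
    }
    rmse_mat[, iter] <- vapply(scans, function(s) scan_rmse(system, params, s,
                                                            cutoff),
                               numeric(1))
  }
  if (iterations > 1) {
    worsened <- rmse_mat[, iterations] > rmse_mat[, 1] + 1e-9
    if (any(worsened))
      warning("scan RMSE increased across iterations for scan(s) ",
              paste(which(worsened), collapse = ", "))
  }
  list(params = params, stages = stages, scan_rmse_by_iteration = rmse_mat,
       assignment = assignment)
}

#' Two-fold terminal-group symmetry rule
#'
#' A terminal group with two-fold rotational symmetry (e.g. a carboxylate:
#' a pivot atom bearing two terminal atoms of identical element and type)
#' makes the rotation profile 180-degree periodic, so the dihedral terms that
#' drive it get multiplicity n = 2 regardless of the database suggestion.
#' Existing terms on the affected type keys are replaced by a single n = 2
#' term (largest incoming force constant, phase re-predicted from the
#' reference geometry over all instances).
#'
#' @inheritParams mm_energy
#' @param tie_tol tie tolerance for the phase re-prediction.
#' @return List with updated `params` and a `report` data.frame
#'   (`type_key`, `n_assigned`, `delta`).
#' @export
apply_twofold_symmetry_rule <- function(system, params, tie_tol = 0.05) {
  deg <- vapply(system$adjacency, length, integer(1))
  affected <- character()
  for (pivot in seq_len(nrow(system$atoms))) {
    nb <- system$adjacency[[pivot]]
    terminal <- nb[deg[nb] == 1]
    anchor <- setdiff(nb, terminal)
    if (length(anchor) != 1 || length(terminal) < 2) next
    sig <- paste(system$atoms$element[terminal], system$atoms$type[terminal])
    tab <- table(sig)
    if (!any(tab == 2)) next
    twins <- terminal[sig %in% names(tab)[tab == 2]]
    keys <- instance_keys(system, "dihedral")
    sel <- apply(system$dihedrals, 1, function(q) {
      central <- sort(q[2:3])
      identical(central, sort(c(anchor, pivot))) && (q[1] %in% twins || q[4] %in% twins)
    })
    affected <- union(affected, keys[sel])
  }
  report <- list()
  dihedral_keys <- instance_keys(system, "dihedral")
  for (key in sort(affected)) {
    terms <- params$dihedrals[[key]]
    if (is.null(terms)) next
    k_keep <- max(vapply(terms, `[[`, numeric(1), "k_phi"))
    quads <- system$dihedrals[dihedral_keys == key, , drop = FALSE]
    phis <- measure_dihedrals(system$reference_geometry, quads)
    delta <- predict_phase_summed(2L, phis, tie_tol)$delta
    params$dihedrals[[key]] <- list(dihedral_term(k_keep, 2L, delta))
    report[[length(report) + 1L]] <- data.frame(
      type_key = key, n_assigned = 2L, delta = delta, stringsAsFactors = FALSE)
  }
  report <- if (length(report)) do.call(rbind, report) else
    data.frame(type_key = character(), n_assigned = integer(), delta = numeric())
  list(params = params, report = report)
}
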