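# Readers/writers: CHARMM stream-file dialect (RTF + PRM with CGenFF-style
# penalty comments), XYZ (single/multi-frame), PDB (read-only), torsion-scan
# tables (plain delimited text defined by this package) and plain-text
# Hessian matrices.  Parsers never silently drop lines: every non-comment,
# non-blank line is either consumed or reported.

read_lines_any <- function(source) {
  if (length(source) == 1 && !grepl("\n", source) && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else {
    unlist(strsplit(paste(source, collapse = "\n"), "\n"))
  }
}

num_or_stop <- function(tok, lineno, what) {
  x <- suppressWarnings(as.numeric(tok))
  if (any(is.na(x)))
    stop_pf("malformed numeric field (", what, ") at line ", lineno,
            class = "phasefit_parse_error")
  x
}

# -- CHARMM stream ----------------------------------------------------------

#' Read a CHARMM stream file (CGenFF-style dialect)
#'
#' Parses a residue topology block (MASS, RESI, ATOM, BOND, IMPR) and
#' parameter blocks (BONDS, ANGLES, DIHEDRALS, IMPROPERS, NONBONDED).
#' Trailing comments of the form `! ... penalty= X` (or `penalty: X`,
#' case-insensitive) become penalty annotations; a missing annotation is
#' treated as penalty 0.  Dihedral lines sharing a type key with distinct
#' multiplicities accumulate into one term list; a duplicate (key, n) pair is
#' an error.
#'
#' @param source path to a `.str` file, or the file contents as a character
#'   vector.
#' @return List with `topology` (resname, atoms data.frame, bonds by name,
#'   impropers by name) and `params`, a [parameter_set()].
#' @export
read_stream <- function(source) {
  lines <- read_lines_any(source)
  params <- parameter_set()
  masses <- list()      # type -> list(mass, element)
  atoms <- list()       # name -> list(type, charge)
  atom_order <- character()
  bonds <- list()       # character pairs
  imprs <- list()       # character quadruples
  resname <- NA_character_
  mode <- "none"        # none / rtf / param
  section <- ""
  unconsumed <- integer()

  for (ln in seq_along(lines)) {
    raw <- lines[ln]
    penalty <- NA_real_
    m <- regmatches(raw, regexec("penalty[=:][ \t]*([-+0-9.eE]+)", raw,
                                 ignore.case = TRUE))[[1]]
    if (length(m) == 2) penalty <- as.numeric(m[2])
    code <- sub("!.*$", "", raw)
    code <- trimws(code)
    if (!nzchar(code)) next
    if (startsWith(code, "*")) next
    tok <- strsplit(code, "[ \t]+")[[1]]
    kw <- toupper(tok[1])

    if (kw == "READ") {
      mode <- if (any(toupper(tok) == "RTF")) "rtf" else "param"
      section <- ""
      next
    }
    if (kw == "END") { section <- ""; mode <- "none"; next }
    if (kw == "RETURN") next
    if (kw %in% c("BONDS", "ANGLES", "DIHEDRALS", "IMPROPERS", "NONBONDED")) {
      mode <- "param"; section <- kw; next
    }
    if (kw == "MASS") {
      if (length(tok) < 5) stop_pf("malformed MASS line at ", ln,
                                   class = "phasefit_parse_error")
      masses[[tok[3]]] <- list(mass = num_or_stop(tok[4], ln, "mass"),
                               element = tok[5])
      next
    }
    if (kw == "RESI") { resname <- tok[2]; mode <- "rtf"; section <- ""; next }
    if (kw == "ATOM") {
      atoms[[tok[2]]] <- list(type = tok[3],
                              charge = num_or_stop(tok[4], ln, "charge"))
      atom_order <- c(atom_order, tok[2])
      next
    }
    if (kw == "BOND") {
      names_ <- tok[-1]
      if (length(names_) %% 2 != 0)
        stop_pf("BOND line at ", ln, " must list atom-name pairs",
                class = "phasefit_parse_error")
      for (p in seq(1, length(names_), by = 2)) {
        bonds[[length(bonds) + 1L]] <- names_[p:(p + 1)]
      }
      next
    }
    if (kw == "IMPR") {
      names_ <- tok[-1]
      if (length(names_) %% 4 != 0)
        stop_pf("IMPR line at ", ln, " must list atom-name quadruples",
                class = "phasefit_parse_error")
      for (p in seq(1, length(names_), by = 4)) {
        imprs[[length(imprs) + 1L]] <- names_[p:(p + 3)]
      }
      next
    }
    if (mode == "rtf" && grepl("^[0-9 \t]+$", code)) next  # rtf version line

    if (mode == "param" && section == "BONDS" && length(tok) >= 4) {
      v <- num_or_stop(tok[3:4], ln, "bond parameter")
      params <- ps_set_bond(params, tok[1:2], v[1], v[2],
                            penalty = ifelse(is.na(penalty), 0, penalty))
      next
    }
    if (mode == "param" && section == "ANGLES" && length(tok) >= 5) {
      v <- num_or_stop(tok[4:5], ln, "angle parameter")
      params <- ps_set_angle(params, tok[1:3], v[1], v[2],
                             penalty = ifelse(is.na(penalty), 0, penalty))
      next
    }
    if (mode == "param" && section == "DIHEDRALS" && length(tok) >= 7) {
      v <- num_or_stop(tok[5:7], ln, "dihedral parameter")
      key <- canonical_key(tok[1:4])
      existing <- params$dihedrals[[key]] %||% list()
      if (any(vapply(existing, function(t) t$n, integer(1)) == as.integer(v[2])))
        stop_pf("duplicate dihedral term (", key, ", n=", v[2], ") at line ", ln,
                class = "phasefit_duplicate_term")
      params <- ps_set_dihedral_term(params, tok[1:4],
                                     dihedral_term(v[1], v[2], v[3]),
                                     penalty = ifelse(is.na(penalty), 0, penalty))
      next
    }
    if (mode == "param" && section == "IMPROPERS" && length(tok) >= 7) {
      v <- num_or_stop(tok[5:7], ln, "improper parameter")
      params <- ps_set_improper(params, tok[1:4], v[1], v[3],
                                penalty = ifelse(is.na(penalty), 0, penalty))
      next
    }
    if (mode == "param" && section == "NONBONDED" && length(tok) >= 4) {
      v <- num_or_stop(tok[2:4], ln, "nonbonded parameter")
      params <- ps_set_nonbonded(params, tok[1], abs(v[2]), v[3])
      next
    }
    unconsumed <- c(unconsumed, ln)
  }

  if (length(unconsumed))
    warning("unrecognised stream lines (not consumed): ",
            paste(unconsumed, collapse = ", "))

  if (length(atoms)) {
    adf <- data.frame(
      name = atom_order,
      type = vapply(atom_order, function(n) atoms[[n]]$type, character(1)),
      charge = vapply(atom_order, function(n) atoms[[n]]$charge, numeric(1)),
      stringsAsFactors = FALSE)
    adf$element <- vapply(adf$type, function(t) {
      if (!is.null(masses[[t]])) masses[[t]]$element else NA_character_
    }, character(1))
    adf$mass <- vapply(adf$type, function(t) {
      if (!is.null(masses[[t]])) masses[[t]]$mass else NA_real_
    }, numeric(1))
    rownames(adf) <- NULL
  } else {
    adf <- NULL
  }

  list(topology = list(resname = resname, atoms = adf, bonds = bonds,
                       impropers = imprs),
       params = params)
}

#' Build a molecule system from parsed stream topology plus a geometry
#'
#' @param stream result of [read_stream()].
#' @param geometry N x 3 coordinates in the ATOM-line order.
#' @param bond_orders,selections passed to [molecule_system()].
#' @export
stream_system <- function(stream, geometry, bond_orders = NULL,
                          selections = list()) {
  topo <- stream$topology
  if (is.null(topo$atoms)) stop("stream has no topology block")
  if (any(is.na(topo$atoms$element)))
    stop("missing MASS line (element) for some atom types; elements must be explicit")
  name_idx <- setNames(seq_len(nrow(topo$atoms)), topo$atoms$name)
  to_idx <- function(nm) {
    ix <- name_idx[nm]
    if (any(is.na(ix))) stop("unknown atom name in topology: ",
                             paste(nm[is.na(ix)], collapse = ", "))
    unname(ix)
  }
  bonds <- do.call(rbind, lapply(topo$bonds, to_idx))
  imprs <- if (length(topo$impropers)) {
    do.call(rbind, lapply(topo$impropers, to_idx))
  } else NULL
  molecule_system(topo$atoms, bonds, geometry, bond_orders = bond_orders,
                  impropers = imprs, selections = selections)
}

#' Write a CHARMM stream file
#'
#' Deterministic output: sorted type keys, ascending multiplicity, fixed
#' numeric formatting (bond/angle force constants 2 decimals, lengths 4
#' decimals, dihedral k 4 decimals, delta printed as 0.00 or 180.00).
#'
#' @inheritParams mm_energy
#' @param path optional output path.
#' @param title title comment line.
#' @return The file contents, invisibly if `path` is given.
#' @export
write_stream <- function(system, params, path = NULL, title = "phasefit stream") {
  if (is.null(system) || nrow(system$atoms) == 0) stop("empty molecule")
  # refuse to write an incomplete parameter set
  tryCatch(invisible(compile_model(system, params, mm_options())),
           phasefit_unparametrised = function(e) {
             stop_pf("refusing to write stream: ", conditionMessage(e),
                     class = "phasefit_unparametrised")
           })
  for (t in unique(system$atoms$type)) {
    if (is.null(params$nonbonded[[t]]))
      stop_pf("refusing to write stream: no nonbonded parameter for type '",
              t, "'", class = "phasefit_unparametrised")
  }

  out <- c(paste0("* ", title), "*", "", "read rtf card append",
           "* topology", "*", "36 1", "")
  type_first <- !duplicated(system$atoms$type)
  for (r in which(type_first)) {
    out <- c(out, sprintf("MASS -1 %s %s %s", system$atoms$type[r],
                          fmt_num(system$atoms$mass[r], 4),
                          system$atoms$element[r]))
  }
  out <- c(out, "",
           sprintf("RESI LIG %s", fmt_num(sum(system$atoms$charge), 4)))
  for (r in seq_len(nrow(system$atoms))) {
    out <- c(out, sprintf("ATOM %s %s %s", system$atoms$name[r],
                          system$atoms$type[r], fmt_num(system$atoms$charge[r], 4)))
  }
  for (r in seq_len(nrow(system$bonds))) {
    out <- c(out, sprintf("BOND %s %s",
                          system$atoms$name[system$bonds[r, 1]],
                          system$atoms$name[system$bonds[r, 2]]))
  }
  if (!is.null(system$impropers)) {
    for (r in seq_len(nrow(system$impropers))) {
      out <- c(out, paste("IMPR",
                          paste(system$atoms$name[system$impropers[r, ]],
                                collapse = " ")))
    }
  }
  out <- c(out, "END", "", "read param card flex append", "* parameters", "*", "")

  pen <- function(kind, key) {
    sprintf(" ! penalty= %s", fmt_num(ps_penalty(params, kind, key), 3))
  }
  out <- c(out, "BONDS")
  for (key in sort(names(params$bonds))) {
    p <- params$bonds[[key]]
    out <- c(out, paste0(key, " ", fmt_num(p$k, 2), " ", fmt_num(p$b0, 4),
                         pen("bond", key)))
  }
  out <- c(out, "", "ANGLES")
  for (key in sort(names(params$angles))) {
    p <- params$angles[[key]]
    out <- c(out, paste0(key, " ", fmt_num(p$k, 2), " ", fmt_num(p$theta0, 4),
                         pen("angle", key)))
  }
  out <- c(out, "", "DIHEDRALS")
  for (key in sort(names(params$dihedrals))) {
    for (t in params$dihedrals[[key]]) {   # already ascending n
      out <- c(out, paste0(key, " ", fmt_num(t$k_phi, 4), " ", t$n, " ",
                           fmt_num(t$delta, 2), pen("dihedral", key)))
    }
  }
  out <- c(out, "", "IMPROPERS")
  for (key in sort(names(params$impropers))) {
    p <- params$impropers[[key]]
    out <- c(out, paste0(key, " ", fmt_num(p$k, 4), " 0 ", fmt_num(p$omega0, 4),
                         pen("improper", key)))
  }
  out <- c(out, "", "NONBONDED")
  for (key in sort(names(params$nonbonded))) {
    p <- params$nonbonded[[key]]
    out <- c(out, paste0(key, " 0.00 ", fmt_num(-p$epsilon, 4), " ",
                         fmt_num(p$rmin_half, 4)))
  }
  out <- c(out, "", "END", "RETURN", "")

  text <- paste(out, collapse = "\n")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(text))
  }
  text
}

# -- XYZ / PDB --------------------------------------------------------------

#' Read an XYZ file (single or multi-frame)
#'
#' @param source path or file contents.
#' @return List of frames, each `list(elements, coordinates, comment)`.
#' @export
read_xyz <- function(source) {
  lines <- read_lines_any(source)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat)) stop_pf("malformed XYZ atom count at line ", i,
                            class = "phasefit_parse_error")
    if (i + 1L + nat > length(lines))
      stop_pf("truncated XYZ frame starting at line ", i,
              class = "phasefit_parse_error")
    comment <- lines[i + 1L]
    el <- character(nat); xyz <- matrix(NA_real_, nat, 3)
    for (a in seq_len(nat)) {
      tok <- strsplit(trimws(lines[i + 1L + a]), "[ \t]+")[[1]]
      if (length(tok) < 4) stop_pf("malformed XYZ atom line ", i + 1L + a,
                                   class = "phasefit_parse_error")
      el[a] <- tok[1]
      xyz[a, ] <- num_or_stop(tok[2:4], i + 1L + a, "coordinate")
    }
    frames[[length(frames) + 1L]] <- list(elements = el, coordinates = xyz,
                                          comment = comment)
    i <- i + 2L + nat
  }
  frames
}

#' Write an XYZ file (single or multi-frame)
#'
#' @param coords one N x 3 matrix or a list of them.
#' @param elements character vector of element symbols.
#' @param path optional output path.
#' @param comments per-frame comment lines.
#' @export
write_xyz <- function(coords, elements, path = NULL, comments = NULL) {
  if (!is.list(coords)) coords <- list(coords)
  if (is.null(comments)) comments <- paste("frame", seq_along(coords))
  out <- character()
  for (f in seq_along(coords)) {
    g <- as_coords(coords[[f]])
    out <- c(out, as.character(nrow(g)), comments[f],
             sprintf("%s %s %s %s", elements, fmt_num(g[, 1], 8),
                     fmt_num(g[, 2], 8), fmt_num(g[, 3], 8)))
  }
  text <- paste(out, collapse = "\n")
  if (!is.null(path)) { writeLines(out, path); return(invisible(text)) }
  text
}

#' Read coordinates and elements from a PDB file (read-only)
#'
#' @param source path or file contents.
#' @return `list(elements, coordinates)`.
#' @export
read_pdb <- function(source) {
  lines <- read_lines_any(source)
  rec <- substr(lines, 1, 6)
  keep <- trimws(rec) %in% c("ATOM", "HETATM")
  lines <- lines[keep]
  if (!length(lines)) stop_pf("no ATOM/HETATM records",
                              class = "phasefit_parse_error")
  x <- as.numeric(substr(lines, 31, 38))
  y <- as.numeric(substr(lines, 39, 46))
  z <- as.numeric(substr(lines, 47, 54))
  if (any(is.na(c(x, y, z))))
    stop_pf("malformed PDB coordinates", class = "phasefit_parse_error")
  el <- trimws(substr(lines, 77, 78))
  fallback <- trimws(substr(lines, 13, 14))
  el[!nzchar(el)] <- gsub("[0-9]", "", fallback[!nzchar(el)])
  list(elements = el, coordinates = cbind(x, y, z))
}

# -- Torsion scans ----------------------------------------------------------

new_scan_table <- function(driven, rows, frames, metadata) {
  structure(list(driven = driven, rows = rows, frames = frames,
                 metadata = metadata), class = "scan_table")
}

scan_is_2d <- function(scan) length(scan$driven) == 2

#' Write a torsion-scan table and its frames
#'
#' @param scan a `scan_table`.
#' @param elements element symbols for the frames file.
#' @param table_path,frames_path output paths (NULL returns text).
#' @export
write_scan <- function(scan, elements, table_path = NULL, frames_path = NULL) {
  md <- scan$metadata
  out <- c("# phasefit torsion scan",
           paste("# driven:", paste(scan$driven[[1]], collapse = " ")))
  if (scan_is_2d(scan))
    out <- c(out, paste("# driven2:", paste(scan$driven[[2]], collapse = " ")))
  out <- c(out, paste("# step:", paste(md$step, collapse = " ")),
           paste("# range:", paste(md$range, collapse = " ")),
           paste("# origin:", md$origin))
  r <- scan$rows
  if (scan_is_2d(scan)) {
    out <- c(out, sprintf("%s %s %s %d", fmt_num(r$phi1, 4), fmt_num(r$phi2, 4),
                          fmt_num(r$energy, 8), r$frame))
  } else {
    out <- c(out, sprintf("%s %s %d", fmt_num(r$phi1, 4),
                          fmt_num(r$energy, 8), r$frame))
  }
  tab <- paste(out, collapse = "\n")
  if (!is.null(table_path)) writeLines(out, table_path)
  frames_text <- write_xyz(scan$frames, elements, path = frames_path,
                           comments = paste("scan frame", seq_along(scan$frames)))
  invisible(list(table = tab, frames = frames_text))
}

#' Read a torsion-scan table with its geometry frames
#'
#' Validates grid completeness/monotonicity and re-measures the driven
#' dihedral(s) on every frame; a deviation beyond `tol` degrees from the
#' declared angle is an error.
#'
#' @param table_source,frames_source paths or file contents.
#' @param tol re-measurement tolerance in degrees.
#' @return A `scan_table`.
#' @export
read_scan <- function(table_source, frames_source, tol = 1.0) {
  lines <- read_lines_any(table_source)
  driven <- list()
  md <- list(step = NA_real_, range = NA_real_, origin = "absolute")
  data_rows <- list()
  for (ln in seq_along(lines)) {
    raw <- trimws(lines[ln])
    if (!nzchar(raw)) next
    if (startsWith(raw, "#")) {
      body <- trimws(sub("^#", "", raw))
      if (grepl("^driven2:", body)) {
        driven[[2]] <- as.integer(strsplit(trimws(sub("^driven2:", "", body)),
                                           "[ \t]+")[[1]])
      } else if (grepl("^driven:", body)) {
        driven[[1]] <- as.integer(strsplit(trimws(sub("^driven:", "", body)),
                                           "[ \t]+")[[1]])
      } else if (grepl("^step:", body)) {
        md$step <- as.numeric(strsplit(trimws(sub("^step:", "", body)),
                                       "[ \t]+")[[1]])
      } else if (grepl("^range:", body)) {
        md$range <- as.numeric(strsplit(trimws(sub("^range:", "", body)),
                                        "[ \t]+")[[1]])
      } else if (grepl("^origin:", body)) {
        md$origin <- trimws(sub("^origin:", "", body))
      }
      next
    }
    tok <- strsplit(raw, "[ \t]+")[[1]]
    data_rows[[length(data_rows) + 1L]] <- num_or_stop(tok, ln, "scan row")
  }
  if (!length(driven)) stop_pf("scan table has no '# driven:' header",
                               class = "phasefit_parse_error")
  ncol_expect <- length(driven) + 2L
  if (any(vapply(data_rows, length, integer(1)) != ncol_expect))
    stop_pf("scan rows must have ", ncol_expect, " columns",
            class = "phasefit_parse_error")
  tab <- do.call(rbind, data_rows)
  if (length(driven) == 1) {
    rows <- data.frame(phi1 = tab[, 1], energy = tab[, 2],
                       frame = as.integer(tab[, 3]))
  } else {
    rows <- data.frame(phi1 = tab[, 1], phi2 = tab[, 2], energy = tab[, 3],
                       frame = as.integer(tab[, 4]))
  }

  if (anyDuplicated(rows$frame) > 0)
    stop_pf("frame indices must be unique", class = "phasefit_parse_error")

  if (length(driven) == 1) {
    if (any(diff(rows$phi1) <= 0))
      stop_pf("1D scan angles must be strictly increasing",
              class = "phasefit_incomplete_grid")
    if (!is.na(md$step[1])) {
      expect <- seq(min(rows$phi1), max(rows$phi1), by = md$step[1])
      missing <- setdiff(round(expect, 6), round(rows$phi1, 6))
      if (length(missing))
        stop_pf("incomplete 1D grid, missing angles: ",
                paste(missing, collapse = ", "),
                class = "phasefit_incomplete_grid")
    }
  } else {
    u1 <- sort(unique(rows$phi1)); u2 <- sort(unique(rows$phi2))
    want <- paste(rep(round(u1, 6), each = length(u2)), round(u2, 6))
    have <- paste(round(rows$phi1, 6), round(rows$phi2, 6))
    absent <- setdiff(want, have)
    if (length(absent) || nrow(rows) != length(u1) * length(u2))
      stop_pf("incomplete 2D grid, absent cells: ",
              paste(utils::head(absent, 20), collapse = "; "),
              class = "phasefit_incomplete_grid")
  }

  xyz <- read_xyz(frames_source)
  if (max(rows$frame) > length(xyz) || min(rows$frame) < 1)
    stop_pf("scan frame index out of range of frames file",
            class = "phasefit_parse_error")
  frames <- lapply(xyz, `[[`, "coordinates")

  for (r in seq_len(nrow(rows))) {
    for (d in seq_along(driven)) {
      declared <- rows[[paste0("phi", d)]][r]
      meas <- measure_dihedral(frames[[rows$frame[r]]], driven[[d]])
      if (abs(wrap_angle(meas - declared)) > tol)
        stop_pf("frame/angle mismatch at row ", r, ": declared ", declared,
                " but measured ", round(meas, 3), " (tolerance ", tol, ")",
                class = "phasefit_scan_mismatch")
    }
  }

  if (all(is.na(md$step))) {
    md$step <- if (length(driven) == 1) {
      round(stats::median(diff(rows$phi1)), 6)
    } else {
      c(round(stats::median(diff(sort(unique(rows$phi1)))), 6),
        round(stats::median(diff(sort(unique(rows$phi2)))), 6))
    }
  }
  if (all(is.na(md$range))) {
    md$range <- if (length(driven) == 1) {
      c(min(rows$phi1), max(rows$phi1))
    } else {
      c(min(rows$phi1), max(rows$phi1), min(rows$phi2), max(rows$phi2))
    }
  }

  new_scan_table(driven, rows, frames, md)
}

#' @export
print.scan_table <- function(x, ...) {
  cat("<scan_table> ", if (scan_is_2d(x)) "2D" else "1D", ", ",
      nrow(x$rows), " rows, step ", paste(x$metadata$step, collapse = "/"),
      "\n", sep = "")
  invisible(x)
}

# -- Hessians ---------------------------------------------------------------

#' Read a plain-text Cartesian Hessian
#'
#' Accepts a full or lower-triangular whitespace-separated matrix.  The
#' result is symmetrised as (H + t(H))/2 after checking symmetry to 1e-6
#' relative tolerance.
#'
#' @param source path or file contents.
#' @param units `"kcal"` for kcal/mol/A^2 (native) or `"hartree"` for
#'   Hartree/Bohr^2 (converted on read).
#' @param geometry optional N x 3 geometry the Hessian was evaluated at; the
#'   dimension is checked against it.
#' @return `list(matrix, geometry)` of class `hessian_matrix`.
#' @export
read_hessian <- function(source, units = c("kcal", "hartree"), geometry = NULL) {
  units <- match.arg(units)
  lines <- read_lines_any(source)
  lines <- lines[!grepl("^[ \t]*[#!]", lines)]
  vals <- suppressWarnings(as.numeric(unlist(strsplit(trimws(paste(lines, collapse = " ")),
                                                      "[ \t]+"))))
  vals <- vals[!is.na(vals)]
  m <- length(vals)
  dim_full <- sqrt(m)
  dim_tri <- (sqrt(8 * m + 1) - 1) / 2
  if (abs(dim_full - round(dim_full)) < 1e-9) {
    d <- as.integer(round(dim_full))
    H <- matrix(vals, d, d, byrow = TRUE)
  } else if (abs(dim_tri - round(dim_tri)) < 1e-9) {
    d <- as.integer(round(dim_tri))
    H <- matrix(0, d, d)
    pos <- 1L
    for (i in seq_len(d)) {
      H[i, 1:i] <- vals[pos:(pos + i - 1L)]
      pos <- pos + i
    }
    H <- H + t(H) - diag(diag(H))
  } else {
    stop_pf("Hessian is neither a square matrix nor a lower triangle (",
            m, " values)", class = "phasefit_shape_error")
  }
  if (d %% 3 != 0)
    stop_pf("Hessian dimension ", d, " is not 3N", class = "phasefit_shape_error")
  if (units == "hartree") H <- H * (.HARTREE_KCAL / .BOHR_ANG^2)
  hessian_matrix(H, geometry)
}

#' @rdname read_hessian
#' @param H square numeric matrix (kcal/mol/A^2).
#' @export
hessian_matrix <- function(H, geometry = NULL) {
  H <- as.matrix(H)
  if (nrow(H) != ncol(H))
    stop_pf("Hessian must be square", class = "phasefit_shape_error")
  scale <- max(abs(H), 1e-12)
  if (max(abs(H - t(H))) / scale > 1e-6)
    stop_pf("Hessian is not symmetric to 1e-6 relative tolerance",
            class = "phasefit_shape_error")
  if (!is.null(geometry)) {
    geometry <- as_coords(geometry)
    if (nrow(H) != 3 * nrow(geometry))
      stop_pf("Hessian dimension ", nrow(H), " does not match geometry (3N = ",
              3 * nrow(geometry), ")", class = "phasefit_shape_error")
  }
  structure(list(matrix = (H + t(H)) / 2, geometry = geometry),
            class = "hessian_matrix")
}

#' @rdname read_hessian
#' @param hessian a `hessian_matrix`.
#' @param path optional output path.
#' @export
write_hessian <- function(hessian, path = NULL) {
  H <- hessian$matrix
  out <- apply(H, 1, function(row) paste(formatC(row, format = "e", digits = 10),
                                         collapse = " "))
  text <- paste(out, collapse = "\n")
  if (!is.null(path)) { writeLines(out, path); return(invisible(text)) }
  text
}
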