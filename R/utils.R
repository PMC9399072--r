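# Internal constants and small helpers shared across modules.

# kcal mol^-1 Angstrom e^-2 (CHARMM electrostatic constant)
.COULOMB_K <- 332.0716
.HARTREE_KCAL <- 627.509474
.BOHR_ANG <- 0.529177210903

deg2rad <- function(x) x * (pi / 180)
rad2deg <- function(x) x * (180 / pi)

# Wrap angles (degrees) into (-180, 180].
wrap_angle <- function(x) {
  y <- x - 360 * round(x / 360)
  y[y <= -180] <- y[y <= -180] + 360
  y
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `code` with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Type-key helpers ----------------------------------------------------------

key_str <- function(types) paste(types, collapse = " ")
key_types <- function(key) strsplit(key, " ", fixed = TRUE)[[1]]

# Canonical orientation: lexicographically smaller of forward/reversed tuple.
canonical_types <- function(types) {
  fwd <- key_str(types)
  bwd <- key_str(rev(types))
  if (bwd < fwd) rev(types) else types
}

canonical_key <- function(types) key_str(canonical_types(types))

fmt_num <- function(x, digits) formatC(x, format = "f", digits = digits)

stop_pf <- function(..., class) {
  stop(structure(class = c(class, "phasefit_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
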