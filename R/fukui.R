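# Conceptual-DFT reactivity indicators: condensed Fukui functions from charge
# populations of the N / N+1 / N-1 electron states, point-charge dipoles, and
# orbital-energy bookkeeping.

DEBYE_PER_E_ANGSTROM <- 4.80320

#' Per-atom partial charges at a labeled electron-count state
#'
#' @param charges Numeric vector of partial charges (elementary charge units),
#'   aligned to the molecule's atom order.
#' @param state One of `"neutral"`, `"anion"`, `"cation"`.
#' @param charge_model Free-text tag naming the population analysis (e.g.
#'   `"hirshfeld"`).
#' @param tol Tolerance on the total-charge invariant (sum must equal 0, -1 or
#'   +1 for neutral/anion/cation).
#' @return An object of class `"charge_set"`.
#' @examples
#' charge_set(c(-0.1, 0.1), "neutral")
#' @export
charge_set <- function(charges, state = c("neutral", "anion", "cation"),
                       charge_model = "hirshfeld", tol = 1e-3) {
  state <- match.arg(state)
  charges <- as.numeric(charges)
  if (length(charges) < 1L || !all(is.finite(charges)))
    stop("charges must be a non-empty finite numeric vector")
  expected <- c(neutral = 0, anion = -1, cation = 1)[[state]]
  if (abs(sum(charges) - expected) > tol)
    stop(sprintf("%s charge set sums to %.6f, expected %g (tol %g)",
                 state, sum(charges), expected, tol))
  structure(list(state = state, charge_model = charge_model, charges = charges),
            class = "charge_set")
}

#' @export
print.charge_set <- function(x, ...) {
  cat("<charge_set> ", x$state, " (", x$charge_model, "), ",
      length(x$charges), " atoms, sum ", sprintf("%.4f", sum(x$charges)),
      "\n", sep = "")
  invisible(x)
}

#' Atom-condensed Fukui function from three charge states
#'
#' Finite-difference condensed Fukui indices in the charge convention:
#' f+ = q(N) - q(N+1) (nucleophilic-attack sites, electron gain),
#' f- = q(N-1) - q(N) (electrophilic-attack sites, electron loss),
#' f0 = (f+ + f-)/2. Each vector sums to 1 by charge conservation. Negative
#' entries (orbital relaxation artifacts) are allowed and propagate as-is
#' with a warning.
#'
#' @param neutral,anion,cation `charge_set` objects for the N, N+1, N-1
#'   electron states, aligned to one molecule.
#' @param mode One of `"f_plus"`, `"f_minus"`, `"f_zero"`.
#' @return An object of class `"fukui_vector"`: list with `mode`, `values`
#'   (named by atom index), and `condensed` (FALSE here; see
#'   [hydrogen_condense()]).
#' @examples
#' n <- charge_set(c(0.1, -0.1, 0), "neutral")
#' a <- charge_set(c(-0.3, -0.4, -0.3), "anion")
#' k <- charge_set(c(0.5, 0.3, 0.2), "cation")
#' condensed_fukui(n, a, k, "f_plus")$values
#' @export
condensed_fukui <- function(neutral, anion, cation,
                            mode = c("f_plus", "f_minus", "f_zero")) {
  mode <- match.arg(mode)
  for (cs in list(neutral, anion, cation))
    if (!inherits(cs, "charge_set")) stop("inputs must be charge_set objects")
  if (neutral$state != "neutral" || anion$state != "anion" || cation$state != "cation")
    stop("state labels do not match argument positions (neutral, anion, cation)")
  n <- length(neutral$charges)
  if (length(anion$charges) != n || length(cation$charges) != n)
    stop("charge sets have mismatched lengths")
  f_plus <- neutral$charges - anion$charges
  f_minus <- cation$charges - neutral$charges
  values <- switch(mode,
    f_plus = f_plus,
    f_minus = f_minus,
    f_zero = (f_plus + f_minus) / 2
  )
  if (any(values < 0))
    warning("negative Fukui entries (orbital relaxation artifacts) propagated as-is")
  names(values) <- seq_len(n)
  structure(list(mode = mode, values = values, condensed = FALSE),
            class = "fukui_vector")
}

#' @export
print.fukui_vector <- function(x, ...) {
  cat("<fukui_vector> ", x$mode, if (x$condensed) " (hydrogen-condensed)",
      ", ", length(x$values), " sites, sum ", sprintf("%.4f", sum(x$values)),
      "\n", sep = "")
  invisible(x)
}

#' Fold hydrogen Fukui weight into the bonded heavy atoms
#'
#' Adds each hydrogen's value to its unique bonded heavy atom and drops the
#' hydrogens, so the result is comparable to per-carbon tabulations. The
#' total is preserved.
#'
#' @param fv An atom-resolved `fukui_vector`.
#' @param mol The `molecule` the vector is aligned to.
#' @param bonds Its `bond_graph`.
#' @return A `fukui_vector` with `condensed = TRUE`, values named by heavy-atom
#'   index.
#' @export
hydrogen_condense <- function(fv, mol, bonds) {
  stopifnot(inherits(fv, "fukui_vector"), inherits(mol, "molecule"),
            inherits(bonds, "bond_graph"))
  if (fv$condensed) stop("fukui_vector is already condensed")
  if (length(fv$values) != n_atoms(mol))
    stop("fukui_vector length does not match atom count")
  vals <- fv$values
  is_h <- mol$elements == "H"
  for (h in which(is_h)) {
    nb <- bond_neighbors(bonds, h)
    heavy_nb <- nb[!is_h[nb]]
    if (length(heavy_nb) != 1L)
      stop("hydrogen atom ", h, " has ", length(heavy_nb),
           " heavy neighbors (need exactly 1)")
    vals[heavy_nb] <- vals[heavy_nb] + vals[h]
  }
  out <- vals[!is_h]
  structure(list(mode = fv$mode, values = out, condensed = TRUE),
            class = "fukui_vector")
}

#' Dipole vector container
#'
#' @param vector Numeric 3-vector in Debye.
#' @return Object of class `"dipole_vector"` with `vector` and `magnitude`.
#' @examples
#' dipole_vector(c(5, 0, 0))
#' @export
dipole_vector <- function(vector) {
  vector <- as.numeric(vector)
  if (length(vector) != 3L || !all(is.finite(vector)))
    stop("dipole vector must be a finite 3-vector (Debye)")
  structure(list(vector = vector, magnitude = sqrt(sum(vector^2))),
            class = "dipole_vector")
}

#' @export
print.dipole_vector <- function(x, ...) {
  cat(sprintf("<dipole_vector> (%.4f, %.4f, %.4f) D, |D| = %.4f D\n",
              x$vector[1], x$vector[2], x$vector[3], x$magnitude))
  invisible(x)
}

#' Molecular dipole moment from point charges
#'
#' D = k * sum_i q_i (r_i - origin), with k = 4.80320 Debye per e*Angstrom.
#' The default origin is the center of nuclear charge; for a neutral charge
#' set the result is origin-independent.
#'
#' @param mol A `molecule`.
#' @param cs A `charge_set` (normally the neutral state).
#' @param origin Optional explicit 3-vector origin (Angstrom). Required when
#'   the charges do not sum to zero, since the dipole of a charged system is
#'   origin-dependent.
#' @return A `dipole_vector` (Debye).
#' @export
dipole_from_point_charges <- function(mol, cs, origin = NULL) {
  stopifnot(inherits(mol, "molecule"), inherits(cs, "charge_set"))
  q <- cs$charges
  if (length(q) != n_atoms(mol)) stop("charge set length does not match atom count")
  if (is.null(origin)) {
    if (abs(sum(q)) > 1e-3)
      stop("net charge ", sprintf("%.4f", sum(q)),
           ": dipole is origin-dependent; supply an explicit origin")
    z <- atomic_number(mol$elements)
    origin <- colSums(mol$coords * z) / sum(z)
  }
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stop("origin must be a 3-vector")
  rel <- sweep(mol$coords, 2L, origin)
  dipole_vector(DEBYE_PER_E_ANGSTROM * colSums(rel * q))
}

#' Sites with the largest Fukui value
#'
#' Returns all indices whose value lies within `tol` of the maximum, so exact
#' and near ties are reported rather than broken.
#'
#' @param fv A (normally hydrogen-condensed) `fukui_vector`.
#' @param tol Tie tolerance; default 1e-3.
#' @return Integer atom indices in increasing order.
#' @examples
#' fv <- structure(list(mode = "f_plus",
#'                      values = c(`1` = 0.068, `2` = 0.068, `3` = 0.05),
#'                      condensed = TRUE), class = "fukui_vector")
#' largest_fukui_sites(fv)
#' @export
largest_fukui_sites <- function(fv, tol = 1e-3) {
  stopifnot(inherits(fv, "fukui_vector"))
  if (length(fv$values) == 0L) stop("empty fukui_vector")
  mx <- max(fv$values)
  idx <- as.integer(names(fv$values)[fv$values >= mx - tol])
  sort(idx)
}

#' Frontier orbital energies
#'
#' @param homo,lumo HOMO and LUMO energies in eV; requires `lumo >= homo`.
#' @return List of class `"orbital_energies"` with `homo`, `lumo`, `gap`
#'   (`lumo - homo`, eV).
#' @export
orbital_energies <- function(homo, lumo) {
  if (!is.finite(homo) || !is.finite(lumo)) stop("orbital energies must be finite")
  if (lumo < homo) stop("LUMO below HOMO: gap would be negative")
  structure(list(homo = homo, lumo = lumo, gap = lumo - homo),
            class = "orbital_energies")
}
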