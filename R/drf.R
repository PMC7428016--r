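# The directional reactive (DR) model. The score of a ligand against a
# charged receptor is
#
#   DRF = C_LR * Q_R,net * sum_n F_n^{+/-} |D| cos(phi_n)
#
# where the sum runs over the ligand's terminal sites (heavy atoms bearing an
# exocyclic H or functional group), F_n is the condensed Fukui weight of the
# site's heavy atom, D the molecular dipole vector and phi_n the angle
# between the dipole line of action and the site's bond direction n_hat.
# Sites "behind" the molecule (cos phi < 0) reduce the score. The Fukui mode
# (f+ vs f-) follows the receptor charge state: cytosolic ions screen the
# receptor so the ligand faces an effective potential of opposite sign, hence
# f+ for a net-positive receptor.

#' Control parameters for the directional reactivity score
#'
#' @param c_lr Coupling coefficient (dimensionless normalization of
#'   1/(4 pi eps0 epsR r)); default 1, making DRF scores relative model
#'   units (Fukui x Debye x e). It is constant across ligands at equal
#'   ligand-receptor distance for one receptor.
#' @param epsilon_r Relative permittivity of the receptor cytosol (metadata
#'   only; absorbed into `c_lr`).
#' @param r Ligand-receptor distance (metadata only; absorbed into `c_lr`).
#' @param tau Orientation-class threshold on cos(phi); default cos(75 deg).
#'   The most-reactive site is classed forward (F) when mean cos(phi) > tau,
#'   backward (B) when < -tau, else perpendicular (P).
#' @param fukui_mode_override Optional `"f_plus"` or `"f_minus"` overriding
#'   the receptor-charge-based selection.
#' @param condense Logical; fold hydrogen Fukui weight into heavy atoms
#'   before scoring (default TRUE).
#' @return List of class `"drf_control"`.
#' @export
drf_control <- function(c_lr = 1, epsilon_r = NA_real_, r = NA_real_,
                        tau = cos(75 * pi / 180), fukui_mode_override = NULL,
                        condense = TRUE) {
  if (!is.finite(c_lr) || c_lr <= 0) stop("c_lr must be positive")
  if (!is.finite(tau) || tau < 0 || tau >= 1) stop("tau must be in [0, 1)")
  if (!is.null(fukui_mode_override) &&
      !fukui_mode_override %in% c("f_plus", "f_minus"))
    stop("fukui_mode_override must be 'f_plus' or 'f_minus'")
  structure(list(c_lr = c_lr, epsilon_r = epsilon_r, r = r, tau = tau,
                 fukui_mode_override = fukui_mode_override,
                 condense = isTRUE(condense)),
            class = "drf_control")
}

#' Select the Fukui mode from the receptor charge state
#'
#' Dissolved cytosolic ions (Na+, K+, Cl-) trapped around the charged
#' residues screen the receptor, so an incoming ligand sees an effective
#' potential of sign opposite to the receptor's net charge. A net-positive
#' receptor therefore engages the ligand's nucleophilic (electron-accepting)
#' sites: f+ for `q_net > 0`, f- for `q_net < 0`.
#'
#' @param q_net Receptor net charge (elementary charges).
#' @param override Optional explicit mode; wins when supplied.
#' @return `"f_plus"` or `"f_minus"`.
#' @examples
#' select_fukui_mode(4.1)   # "f_plus"
#' select_fukui_mode(-4.1)  # "f_minus"
#' @export
select_fukui_mode <- function(q_net, override = NULL) {
  if (!is.null(override)) {
    if (!override %in% c("f_plus", "f_minus"))
      stop("override must be 'f_plus' or 'f_minus'")
    return(override)
  }
  if (!is.finite(q_net)) stop("q_net must be finite")
  if (q_net == 0) stop("q_net = 0: Fukui mode is undetermined without an override")
  if (q_net > 0) "f_plus" else "f_minus"
}

#' Per-site contributions to the directional reactivity score
#'
#' For each terminal site n, computes cos(phi_n) = n_hat . D_hat and the
#' term F_n |D| cos(phi_n). A zero dipole yields all-zero terms with
#' cos(phi) set to 0.
#'
#' @param sites A `terminal_sites` data frame (from [find_terminal_sites()]).
#' @param fukui A `fukui_vector` whose names cover every site's heavy atom.
#' @param dipole A `dipole_vector` (Debye).
#' @return Data frame with columns `heavy`, `substituent`, `fukui`,
#'   `cos_phi`, `term`.
#' @export
site_contributions <- function(sites, fukui, dipole) {
  stopifnot(inherits(sites, "terminal_sites"), inherits(fukui, "fukui_vector"),
            inherits(dipole, "dipole_vector"))
  key <- as.character(sites$heavy)
  missing <- setdiff(unique(key), names(fukui$values))
  if (length(missing))
    stop("no Fukui value for site heavy atom(s): ", paste(missing, collapse = ", "))
  f <- unname(fukui$values[key])
  dirs <- as.matrix(sites[, c("dx", "dy", "dz")])
  if (dipole$magnitude > 0) {
    dhat <- dipole$vector / dipole$magnitude
    cos_phi <- as.numeric(dirs %*% dhat)
  } else {
    cos_phi <- rep(0, nrow(sites))
  }
  data.frame(heavy = sites$heavy, substituent = sites$substituent,
             fukui = f, cos_phi = cos_phi,
             term = f * dipole$magnitude * cos_phi)
}

#' Assemble the directional reactivity score from site contributions
#'
#' @param contribs Data frame from [site_contributions()].
#' @param q_net Receptor net charge (elementary charges).
#' @param params A [drf_control()].
#' @return The scalar score `c_lr * q_net * sum(term)` (model units).
#' @export
compute_drf <- function(contribs, q_net, params = drf_control()) {
  if (!is.data.frame(contribs) || nrow(contribs) == 0L)
    stop("contribs must be a non-empty data frame")
  if (!all(is.finite(contribs$term)) || !is.finite(q_net))
    stop("non-finite input to compute_drf")
  params$c_lr * q_net * sum(contribs$term)
}

#' Classify the orientation of the most reactive site(s)
#'
#' Uses the mean cos(phi) over the maximum-Fukui site(s): forward (`"F"`)
#' when above `tau`, backward (`"B"`) when below `-tau`, perpendicular
#' (`"P"`) otherwise (including the zero-dipole case). Ties among
#' maximum-Fukui atoms are averaged, not broken.
#'
#' @param max_fukui_atoms Integer heavy-atom indices with the largest Fukui
#'   value (see [largest_fukui_sites()]).
#' @param contribs Data frame from [site_contributions()].
#' @param tau Threshold on cos(phi); default cos(75 deg).
#' @return `"F"`, `"P"` or `"B"`.
#' @export
classify_orientation <- function(max_fukui_atoms, contribs,
                                 tau = cos(75 * pi / 180)) {
  if (length(max_fukui_atoms) < 1L) stop("need at least one max-Fukui site")
  sel <- contribs$heavy %in% max_fukui_atoms
  if (!any(sel)) stop("max-Fukui atoms have no terminal-site contributions")
  m <- mean(contribs$cos_phi[sel])
  if (m > tau) "F" else if (m < -tau) "B" else "P"
}

#' Directional reactivity score of a ligand against a charged receptor
#'
#' End-to-end scoring: perceives bonds and terminal sites, forms the
#' condensed Fukui vector from the three charge states (mode chosen from the
#' receptor charge sign), takes the supplied dipole or derives one from the
#' neutral point charges, and evaluates
#' `DRF = c_lr * q_net * sum_n F_n |D| cos(phi_n)` together with the
#' orientation class of the most reactive carbon(s).
#'
#' @param mol A `molecule`.
#' @param neutral,anion,cation `charge_set`s for the N, N+1, N-1 states.
#' @param q_net Receptor net charge (elementary charges), e.g. from
#'   [net_charge()].
#' @param dipole Optional `dipole_vector` (Debye); when `NULL`, computed from
#'   the neutral point charges.
#' @param params A [drf_control()].
#' @param compound Compound name (defaults to the molecule's name).
#' @return Object of class `"drf"`: list with `compound`, `drf`,
#'   `contributions`, `fukui_mode`, `q_net`, `dipole`, `orientation_class`,
#'   `max_fukui_atoms`, `params`.
#' @examples
#' mol <- make_ring_molecule(2)
#' heavy <- which(mol$elements != "H")
#' cs <- plant_charge_states(mol, rep(1 / length(heavy), length(heavy)),
#'                           planted_dipole = c(3, 1, 0))
#' drf(mol, cs$neutral, cs$anion, cs$cation, q_net = 4.1)
#' @export
drf <- function(mol, neutral, anion, cation, q_net, dipole = NULL,
                params = drf_control(), compound = mol$name) {
  stopifnot(inherits(mol, "molecule"), inherits(params, "drf_control"))
  mode <- select_fukui_mode(q_net, params$fukui_mode_override)
  bonds <- perceive_bonds(mol)
  sites <- find_terminal_sites(mol, bonds)
  if (nrow(sites) == 0L) stop("molecule has no terminal sites")
  fv <- condensed_fukui(neutral, anion, cation, mode)
  if (params$condense) fv <- hydrogen_condense(fv, mol, bonds)
  if (is.null(dipole)) dipole <- dipole_from_point_charges(mol, neutral)
  stopifnot(inherits(dipole, "dipole_vector"))
  contribs <- site_contributions(sites, fv, dipole)
  score <- compute_drf(contribs, q_net, params)
  # the tabulated maximum is over terminal carbons, so restrict the argmax
  # to atoms that actually bear a site
  fv_sites <- fv
  fv_sites$values <- fv$values[names(fv$values) %in% as.character(sites$heavy)]
  max_atoms <- largest_fukui_sites(fv_sites)
  cls <- if (dipole$magnitude == 0) "P" else
    classify_orientation(max_atoms, contribs, params$tau)
  structure(list(compound = compound, drf = score, contributions = contribs,
                 fukui_mode = mode, q_net = q_net, dipole = dipole,
                 orientation_class = cls, max_fukui_atoms = max_atoms,
                 params = params),
            class = "drf")
}

#' @export
print.drf <- function(x, ...) {
  cat(sprintf("<drf> %s: DRF = %.4f (%s, Q_net = %+.2f e, |D| = %.3f D, orientation %s)\n",
              x$compound, x$drf, x$fukui_mode, x$q_net, x$dipole$magnitude,
              x$orientation_class))
  invisible(x)
}

#' @export
summary.drf <- function(object, ...) {
  structure(object, class = c("summary.drf", class(object)))
}

#' @export
print.summary.drf <- function(x, ...) {
  print.drf(x)
  cat("  max-Fukui atom(s): ", paste(x$max_fukui_atoms, collapse = ", "),
      "\n  per-site contributions:\n", sep = "")
  print(format(x$contributions, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Rank compounds by directional reactivity score
#'
#' @param results A list of `"drf"` objects, or a data frame with columns
#'   `compound` and `drf`.
#' @return Data frame ordered by decreasing `drf` (ties broken by compound
#'   name, stable and documented), with a `rank` column.
#' @export
rank_by_drf <- function(results) {
  if (is.data.frame(results)) {
    df <- results[, c("compound", "drf")]
  } else {
    if (length(results) < 1L) stop("need at least one result")
    df <- data.frame(
      compound = vapply(results, function(r) r$compound, character(1)),
      drf = vapply(results, function(r) r$drf, numeric(1)),
      stringsAsFactors = FALSE
    )
  }
  if (anyDuplicated(df$compound))
    stop("duplicate compound names: ",
         paste(unique(df$compound[duplicated(df$compound)]), collapse = ", "))
  df <- df[order(-df$drf, df$compound), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}
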