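# Molecular geometry, covalent-radius bond perception, ring detection and
# terminal reactive sites.
#
# A molecule is a light S3 object: element vector plus an n x 3 Cartesian
# coordinate matrix in Angstrom. Atom indices are 1-based in memory (R
# convention); all on-disk formats use 0-based indices (see read_charge_csv).

#' Construct a molecule
#'
#' @param elements Character vector of element symbols, one per atom.
#' @param coords Numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @param name Compound name.
#' @param formal_charge Integer net formal charge (elementary charges).
#' @return An object of class `"molecule"`: a list with `name`, `elements`,
#'   `coords` (n x 3 matrix) and `formal_charge`.
#' @examples
#' h2 <- molecule(c("H", "H"), rbind(c(0, 0, 0), c(0.74, 0, 0)), name = "H2")
#' n_atoms(h2)
#' @export
molecule <- function(elements, coords, name = "molecule", formal_charge = 0L) {
  elements <- as.character(elements)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  if (length(elements) < 1L) stop("a molecule needs at least one atom")
  if (nrow(coords) != length(elements) || ncol(coords) != 3L)
    stop("coords must be a length(elements) x 3 matrix")
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  covalent_radius(elements)  # errors on unknown symbols
  structure(
    list(name = as.character(name), elements = elements, coords = coords,
         formal_charge = as.integer(formal_charge)),
    class = "molecule"
  )
}

#' @export
print.molecule <- function(x, ...) {
  comp <- table(x$elements)
  formula <- paste0(names(comp), ifelse(comp > 1L, comp, ""), collapse = "")
  cat("<molecule> ", x$name, ": ", formula, ", ", n_atoms(x), " atoms",
      if (x$formal_charge != 0L) paste0(", charge ", sprintf("%+d", x$formal_charge)),
      "\n", sep = "")
  invisible(x)
}

#' Number of atoms in a molecule
#' @param mol A `molecule`.
#' @return Integer atom count.
#' @export
n_atoms <- function(mol) length(mol$elements)

#' Perceive covalent bonds from interatomic distances
#'
#' Two atoms are bonded when their distance does not exceed
#' `scale` times the sum of their covalent radii. This is the standard
#' distance heuristic for idealized or optimized geometries.
#'
#' @param mol A `molecule`.
#' @param scale Dimensionless cutoff factor in (1, 1.5]; default 1.2.
#' @return An object of class `"bond_graph"`: a list with `edges` (m x 2
#'   integer matrix, each row i < j) and `n` (atom count).
#' @examples
#' m <- molecule(c("C", "C"), rbind(c(0, 0, 0), c(1.4, 0, 0)))
#' perceive_bonds(m)$edges
#' @export
perceive_bonds <- function(mol, scale = 1.2) {
  stopifnot(inherits(mol, "molecule"))
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 1.0 || scale > 1.5)
    stop("scale must be a single number in (1.0, 1.5]")
  n <- n_atoms(mol)
  radii <- covalent_radius(mol$elements)
  d <- as.matrix(stats::dist(mol$coords))
  too_close <- d < 0.5
  diag(too_close) <- FALSE
  if (any(too_close)) {
    ij <- which(too_close, arr.ind = TRUE)[1L, ]
    stop(sprintf("atoms %d and %d are closer than 0.5 Angstrom (overlapping input)",
                 ij[1L], ij[2L]))
  }
  cutoff <- outer(radii, radii, "+") * scale
  adj <- d <= cutoff
  adj[lower.tri(adj, diag = TRUE)] <- FALSE
  edges <- which(adj, arr.ind = TRUE)
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  dimnames(edges) <- NULL
  structure(list(edges = edges, n = n), class = "bond_graph")
}

#' @export
print.bond_graph <- function(x, ...) {
  cat("<bond_graph> ", x$n, " atoms, ", nrow(x$edges), " bonds\n", sep = "")
  invisible(x)
}

# neighbor list: integer vector of partners for atom i
bond_neighbors <- function(bonds, i) {
  e <- bonds$edges
  sort(c(e[e[, 1L] == i, 2L], e[e[, 2L] == i, 1L]))
}

# Atoms belonging to at least one cycle: endpoints of non-bridge edges.
ring_atoms <- function(bonds) {
  if (nrow(bonds$edges) == 0L) return(integer(0))
  g <- igraph::graph_from_edgelist(bonds$edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, bonds$n - igraph::vcount(g)))
  br <- igraph::bridges(g)
  cyc_edges <- setdiff(seq_len(igraph::ecount(g)), as.integer(br))
  if (length(cyc_edges) == 0L) return(integer(0))
  ends <- igraph::ends(g, cyc_edges, names = FALSE)
  sort(unique(as.integer(ends)))
}

#' Unit vector along a bond
#'
#' @param mol A `molecule`.
#' @param i,j Atom indices (1-based); the vector points from `i` to `j`.
#' @return Unit 3-vector.
#' @examples
#' m <- molecule(c("C", "H"), rbind(c(0, 0, 0), c(2, 0, 0)))
#' bond_unit_vector(m, 1, 2)
#' @export
bond_unit_vector <- function(mol, i, j) {
  stopifnot(inherits(mol, "molecule"))
  if (i == j) stop("i and j must differ")
  v <- mol$coords[j, ] - mol$coords[i, ]
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("atoms ", i, " and ", j, " have coincident positions")
  v / nv
}

#' Terminal reactive sites of a ligand
#'
#' Identifies the heavy atoms that carry an exocyclic substituent -- the
#' "terminal atoms bonded with hydrogen or other functional groups" whose
#' bond directions enter the directional reactivity score. For every carbon
#' with at least one neighbor that is not a ring ("backbone") carbon, one
#' site is emitted per such neighbor: H, O, N, or an acyclic carbon (e.g. a
#' methyl carbon). For multi-atom substituents the direction uses the first
#' atom of the group (C->C for methyl, C->O for hydroxyl). Ring membership is
#' decided by cycle detection on the bond graph.
#'
#' @param mol A `molecule`.
#' @param bonds Its `bond_graph` (from [perceive_bonds()]).
#' @return A data frame of class `"terminal_sites"` with columns
#'   `heavy` (carbon index), `substituent` (neighbor index), `element`
#'   (neighbor element) and `dx`, `dy`, `dz` (unit bond direction from the
#'   carbon toward the substituent), ordered by (heavy, substituent).
#' @examples
#' benz <- make_ring_molecule(1)
#' sites <- find_terminal_sites(benz, perceive_bonds(benz))
#' nrow(sites)  # one C-H site per ring carbon
#' @export
find_terminal_sites <- function(mol, bonds) {
  stopifnot(inherits(mol, "molecule"), inherits(bonds, "bond_graph"))
  if (n_atoms(mol) < 1L) stop("empty molecule")
  in_ring <- rep(FALSE, n_atoms(mol))
  in_ring[ring_atoms(bonds)] <- TRUE
  is_c <- mol$elements == "C"

  heavy <- integer(0); sub <- integer(0)
  for (i in which(is_c)) {
    for (j in bond_neighbors(bonds, i)) {
      el <- mol$elements[j]
      exocyclic <- el %in% c("H", "O", "N") || (el == "C" && !in_ring[j])
      if (exocyclic) { heavy <- c(heavy, i); sub <- c(sub, j) }
    }
  }
  o <- order(heavy, sub)
  heavy <- heavy[o]; sub <- sub[o]
  dirs <- matrix(0, length(heavy), 3L)
  for (k in seq_along(heavy)) dirs[k, ] <- bond_unit_vector(mol, heavy[k], sub[k])
  out <- data.frame(heavy = heavy, substituent = sub,
                    element = mol$elements[sub],
                    dx = dirs[, 1L], dy = dirs[, 2L], dz = dirs[, 3L],
                    stringsAsFactors = FALSE)
  class(out) <- c("terminal_sites", "data.frame")
  out
}
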