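# Deterministic, seeded generators standing in for the DFT and bioassay
# inputs: idealized planar fused-ring geometries, charge-state triples with
# planted Fukui vectors and dipoles, noisy sigmoidal dose-response curves
# with planted EC50s -- plus a deliberately naive brute-force re-derivation
# of the directional reactivity score used only as an independent test
# oracle.

CC_AROMATIC <- 1.40  # ring C-C, Angstrom
CH_BOND <- 1.09
CO_BOND <- 1.36
OH_BOND <- 0.96
C_METHYL <- 1.50

#' Specification of one synthetic fixture
#'
#' Collects the planted quantities a fixture is generated from. Unset slots
#' are drawn reproducibly from the seed: ring count 1-6, 0-2 random methyl /
#' hydroxyl substituents, a random in-plane dipole of 1-10 Debye, a random
#' non-negative Fukui vector over the heavy atoms summing to 1.
#'
#' @param seed Integer seed fixing all randomness.
#' @param n_rings Number of fused hexagons (>= 1); `NULL` to draw.
#' @param substituents Named map position -> `"methyl"`/`"hydroxyl"`, where
#'   position indexes the peripheral C-H carbons in atom order; `NULL` to
#'   draw.
#' @param planted_dipole In-plane 3-vector in Debye (z component 0 for the
#'   planar geometries); `NULL` to draw.
#' @param planted_fukui Per-heavy-atom weights summing to 1, or `NULL` to
#'   draw after the geometry is known.
#' @param planted_ec50 Planted EC50 in micromolar (default 5).
#' @param noise_sd Gaussian response noise, %BaP_max (default 5).
#' @return List of class `"fixture_spec"`.
#' @export
fixture_spec <- function(seed = 1L, n_rings = NULL, substituents = NULL,
                         planted_dipole = NULL, planted_fukui = NULL,
                         planted_ec50 = 5, noise_sd = 5) {
  seed <- as.integer(seed)
  rng <- local({ set.seed(seed); list(
    n_rings = sample(1:6, 1L),
    n_sub = sample(0:2, 1L),
    dipole = c(stats::runif(2, -1, 1), 0) * stats::runif(1, 1, 10)
  )})
  if (is.null(n_rings)) n_rings <- rng$n_rings
  if (n_rings < 1L) stop("n_rings must be >= 1")
  if (is.null(planted_dipole)) planted_dipole <- rng$dipole
  if (!is.null(planted_fukui)) {
    if (abs(sum(planted_fukui) - 1) > 1e-9)
      stop("planted_fukui must sum to 1")
    if (any(planted_fukui < 0)) stop("planted_fukui must be non-negative")
  }
  if (planted_ec50 <= 0) stop("planted_ec50 must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(seed = seed, n_rings = n_rings,
                 substituents = substituents, draw_substituents = is.null(substituents),
                 n_random_sub = rng$n_sub,
                 planted_dipole = as.numeric(planted_dipole),
                 planted_fukui = planted_fukui,
                 planted_ec50 = planted_ec50, noise_sd = noise_sd),
            class = "fixture_spec")
}

# Hexagon vertices (flat-top) around a center; ring centers of edge-fused
# neighbors sit at distance 2*apothem along multiples of 60 degrees.
.hex_vertices <- function(center) {
  th <- (30 + 60 * 0:5) * pi / 180
  cbind(center[1] + CC_AROMATIC * cos(th), center[2] + CC_AROMATIC * sin(th))
}

#' Idealized planar fused-ring molecule
#'
#' Builds a cata-condensed polycyclic scaffold of `n_rings` fused hexagons
#' in the z = 0 plane with standard bond lengths (C-C 1.40, C-H 1.09,
#' C-O 1.36, O-H 0.96, C-CH3 1.50 Angstrom). Rings are fused in a zigzag
#' (angular, chrysene-like) pattern by default. Peripheral C-H positions can
#' carry methyl or hydroxyl substituents. Deterministic: the same arguments
#' always give bit-identical coordinates.
#'
#' @param n_rings Number of fused hexagons (>= 1); 1 gives benzene, 4 the
#'   chrysene-like C18H12 scaffold.
#' @param substituents Optional named list/vector, e.g. `c("2" = "methyl")`:
#'   names index the peripheral C-H carbons (in atom order, 1-based),
#'   values are `"methyl"` or `"hydroxyl"`.
#' @param fusion `"angular"` (zigzag) or `"linear"` (acene-like).
#' @param name Molecule name.
#' @return A `molecule`: ring carbons first (in ring order), then for each
#'   peripheral position its H or substituent-group atoms.
#' @examples
#' make_ring_molecule(1)            # benzene, 12 atoms
#' make_ring_molecule(4)            # C18H12, 30 atoms
#' @export
make_ring_molecule <- function(n_rings, substituents = NULL,
                               fusion = c("angular", "linear"),
                               name = sprintf("ring%d", n_rings)) {
  fusion <- match.arg(fusion)
  if (n_rings < 1L) stop("n_rings must be >= 1")
  step <- 2 * CC_AROMATIC * cos(pi / 6)
  centers <- matrix(0, n_rings, 2L)
  ang <- 0
  for (k in seq_len(n_rings)[-1]) {
    if (fusion == "angular") ang <- if (k %% 2L == 0L) 0 else pi / 3
    centers[k, ] <- centers[k - 1L, ] + step * c(cos(ang), sin(ang))
  }
  verts <- do.call(rbind, lapply(seq_len(n_rings), function(k) .hex_vertices(centers[k, ])))
  key <- paste(round(verts[, 1], 6), round(verts[, 2], 6))
  carbons <- verts[!duplicated(key), , drop = FALSE]
  nC <- nrow(carbons)

  # ring-carbon adjacency at the aromatic bond length
  d <- as.matrix(stats::dist(carbons))
  adj <- d < CC_AROMATIC * 1.1 & d > 0

  elements <- rep("C", nC)
  coords <- cbind(carbons, 0)
  peripheral <- which(rowSums(adj) == 2L)  # carbons needing an H or group

  subs <- rep("H", length(peripheral))
  if (!is.null(substituents)) {
    pos <- as.integer(names(substituents))
    if (any(is.na(pos)) || any(pos < 1L) || any(pos > length(peripheral)))
      stop("substituent position out of range (1..", length(peripheral), ")")
    subs[pos] <- unlist(substituents)
    if (!all(subs %in% c("H", "methyl", "hydroxyl")))
      stop("substituents must be 'methyl' or 'hydroxyl'")
  }

  for (k in seq_along(peripheral)) {
    i <- peripheral[k]
    nb <- which(adj[i, ])
    u <- carbons[i, ] - colMeans(carbons[nb, , drop = FALSE])
    u <- u / sqrt(sum(u^2))            # outward, in-plane
    v <- c(-u[2], u[1])                # in-plane perpendicular
    base <- c(carbons[i, ], 0)
    u3 <- c(u, 0); v3 <- c(v, 0); w3 <- c(0, 0, 1)
    if (subs[k] == "H") {
      elements <- c(elements, "H")
      coords <- rbind(coords, base + CH_BOND * u3)
    } else if (subs[k] == "hydroxyl") {
      o_pos <- base + CO_BOND * u3
      # C-O-H angle ~104.5 deg, H kept in-plane, pointing away from the ring
      a <- 104.5 * pi / 180
      hdir <- -cos(a) * u3 + sin(a) * v3
      elements <- c(elements, "O", "H")
      coords <- rbind(coords, o_pos, o_pos + OH_BOND * hdir)
    } else {  # methyl
      c_pos <- base + C_METHYL * u3
      th <- (180 - 109.5) * pi / 180   # H-C-C angle 109.5 deg
      phis <- c(90, 210, 330) * pi / 180
      hs <- t(vapply(phis, function(phi)
        c_pos + CH_BOND * (cos(th) * u3 + sin(th) * (cos(phi) * v3 + sin(phi) * w3)),
        numeric(3)))
      elements <- c(elements, "C", "H", "H", "H")
      coords <- rbind(coords, c_pos, hs)
    }
  }
  molecule(elements, coords, name = name)
}

#' Number of peripheral substitutable positions of a fused-ring scaffold
#' @param n_rings Ring count.
#' @param fusion Fusion pattern, as in [make_ring_molecule()].
#' @return Integer count of peripheral C-H positions.
#' @export
n_peripheral_positions <- function(n_rings, fusion = "angular") {
  mol <- make_ring_molecule(n_rings, fusion = fusion)
  sum(mol$elements == "H")
}

#' Plant charge-state triples with a prescribed Fukui vector and dipole
#'
#' Constructs neutral/anion/cation charge sets such that (i) the neutral set
#' sums to zero and reproduces the planted dipole under the point-charge
#' dipole formula, via a minimum-norm linear solve, and (ii) the condensed
#' Fukui functions recover the planted weights exactly: the anion is
#' `neutral - f_plus`, the cation `neutral + f_minus`, with the planted
#' weights on heavy atoms and zero on hydrogens.
#'
#' @param mol A `molecule` (typically from [make_ring_molecule()]).
#' @param planted_fukui Non-negative weights over the heavy atoms (in heavy
#'   atom order), summing to 1; used for f+ (and, by default, f-).
#' @param planted_dipole 3-vector in Debye; must lie in the span reachable
#'   from the geometry (in-plane for planar molecules), else an error is
#'   raised.
#' @param planted_fukui_minus Optional distinct weights for f-.
#' @return List with `charge_set`s `neutral`, `anion`, `cation` and the
#'   `heavy` atom indices.
#' @export
plant_charge_states <- function(mol, planted_fukui, planted_dipole,
                                planted_fukui_minus = planted_fukui) {
  stopifnot(inherits(mol, "molecule"))
  heavy <- which(mol$elements != "H")
  if (length(planted_fukui) != length(heavy) ||
      abs(sum(planted_fukui) - 1) > 1e-9)
    stop("planted_fukui must cover the heavy atoms and sum to 1")
  if (abs(sum(planted_fukui_minus) - 1) > 1e-9)
    stop("planted_fukui_minus must sum to 1")
  n <- n_atoms(mol)
  ctr <- colMeans(mol$coords)
  A <- rbind(rep(1, n), DEBYE_PER_E_ANGSTROM * t(sweep(mol$coords, 2L, ctr)))
  b <- c(0, as.numeric(planted_dipole))
  # minimum-norm solution via SVD pseudo-inverse
  sv <- svd(A)
  keep <- sv$d > max(sv$d) * 1e-10
  q <- sv$v[, keep, drop = FALSE] %*%
    ((t(sv$u[, keep, drop = FALSE]) %*% b) / sv$d[keep])
  q <- as.numeric(q)
  if (sqrt(sum((A %*% q - b)^2)) > 1e-8)
    stop("planted dipole is infeasible for this geometry ",
         "(out-of-plane component on a planar molecule?)")
  fp <- numeric(n); fp[heavy] <- planted_fukui
  fm <- numeric(n); fm[heavy] <- planted_fukui_minus
  list(neutral = charge_set(q, "neutral", charge_model = "planted"),
       anion = charge_set(q - fp, "anion", charge_model = "planted"),
       cation = charge_set(q + fm, "cation", charge_model = "planted"),
       heavy = heavy)
}

#' Simulate a noisy dose-response curve with a planted EC50
#'
#' Emulates the assay design: 10 fivefold serial dilutions from a top dose,
#' a logistic mean response (bottom 0, top 100 %BaP_max by default) and
#' Gaussian noise, with replicates. Seed-deterministic.
#'
#' @param spec A [fixture_spec()] supplying `seed`, `planted_ec50`,
#'   `noise_sd`.
#' @param top_dose Highest dose (uM); 10 fivefold dilutions descend from it.
#' @param replicates Replicates per dose (default 3).
#' @param hill Hill slope of the generating curve (default 1.2).
#' @param bottom,top Asymptotes in %BaP_max.
#' @return A [dose_response()] with attributes `planted_ec50`, `hill`.
#' @export
simulate_dose_response <- function(spec, top_dose = 100, replicates = 3L,
                                   hill = 1.2, bottom = 0, top = 100) {
  stopifnot(inherits(spec, "fixture_spec"))
  doses <- rep(top_dose / 5^(0:9), each = replicates)
  mu <- ll4_mean(doses, bottom, top, hill, log10(spec$planted_ec50))
  set.seed(spec$seed + 1000003L)
  resp <- mu + stats::rnorm(length(mu), 0, spec$noise_sd)
  out <- dose_response(doses, resp,
                       compound = sprintf("fixture-seed%d", spec$seed))
  attr(out, "planted_ec50") <- spec$planted_ec50
  attr(out, "hill") <- hill
  out
}

# Idealized substituent placements can clash at bay or ortho positions;
# a sane geometry has every H bonded to exactly one atom, every O to two,
# every C to three or four.
.geometry_sane <- function(mol) {
  bonds <- tryCatch(perceive_bonds(mol), error = function(e) NULL)
  if (is.null(bonds)) return(FALSE)
  deg <- tabulate(c(bonds$edges), nbins = n_atoms(mol))
  all(deg[mol$elements == "H"] == 1L) &&
    all(deg[mol$elements == "O"] == 2L) &&
    all(deg[mol$elements == "C"] %in% c(3L, 4L))
}

#' Generate a complete random DRF fixture from a seed
#'
#' Draws the geometry (1-6 rings, random substituents), a random planted
#' Fukui vector and in-plane dipole, plants the charge states, and draws a
#' random nonzero receptor charge. Used by the oracle-equivalence and
#' symmetry test suites.
#'
#' @param seed Integer seed.
#' @return List with `spec`, `mol`, `charges` (neutral/anion/cation),
#'   `dipole` (`dipole_vector`), `q_net`.
#' @export
random_drf_fixture <- function(seed) {
  spec <- fixture_spec(seed = seed)
  set.seed(spec$seed + 2000003L)
  subs <- spec$substituents
  mol <- NULL
  for (attempt in seq_len(25L)) {
    if (spec$draw_substituents && spec$n_random_sub > 0L) {
      npos <- n_peripheral_positions(spec$n_rings)
      pos <- sample(npos, min(spec$n_random_sub, npos))
      subs <- stats::setNames(sample(c("methyl", "hydroxyl"), length(pos),
                                     replace = TRUE), pos)
    }
    cand <- make_ring_molecule(spec$n_rings, subs,
                               name = sprintf("fixture-seed%d", seed))
    if (.geometry_sane(cand)) { mol <- cand; break }
    if (!spec$draw_substituents) break  # user-fixed substituents: no retry
    subs <- spec$substituents
  }
  if (is.null(mol)) {  # idealized substituents clash at drawn positions
    subs <- NULL
    mol <- make_ring_molecule(spec$n_rings,
                              name = sprintf("fixture-seed%d", seed))
  }
  heavy <- which(mol$elements != "H")
  w <- stats::runif(length(heavy))
  fuk <- w / sum(w)
  charges <- plant_charge_states(mol, fuk, spec$planted_dipole)
  q_net <- sample(c(-1, 1), 1L) * stats::runif(1, 0.5, 10)
  list(spec = spec, mol = mol, substituents = subs, planted_fukui = fuk,
       charges = charges, dipole = dipole_vector(spec$planted_dipole),
       q_net = q_net)
}

#' Brute-force directional reactivity oracle
#'
#' A deliberately naive, self-contained re-derivation of the directional
#' reactivity score -- explicit loops, its own distance-based bond
#' perception, cycle detection by edge-removal reachability, its own Fukui
#' differences and hydrogen condensation -- sharing no helpers with the
#' engine. Used only in tests and validation.
#'
#' @param mol A `molecule`.
#' @param neutral,anion,cation The three `charge_set`s.
#' @param dipole A `dipole_vector`.
#' @param q_net Receptor net charge.
#' @param params A [drf_control()].
#' @return The scalar score.
#' @export
drf_bruteforce_oracle <- function(mol, neutral, anion, cation, dipole, q_net,
                                  params = drf_control()) {
  rad <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66)
  el <- mol$elements
  xyz <- mol$coords
  n <- length(el)
  # bonds, naively
  bonded <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    dd <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (dd <= 1.2 * (rad[[el[i]]] + rad[[el[j]]])) {
      bonded[i, j] <- TRUE; bonded[j, i] <- TRUE
    }
  }
  # an atom is in a ring iff some incident edge lies on a cycle, i.e. its
  # endpoints stay connected after removing that edge
  reachable <- function(adj, from, to) {
    seen <- rep(FALSE, n); queue <- from; seen[from] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in which(adj[v, ])) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
    seen[to]
  }
  in_ring <- rep(FALSE, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j || !bonded[i, j]) next
    adj2 <- bonded; adj2[i, j] <- FALSE; adj2[j, i] <- FALSE
    if (reachable(adj2, i, j)) { in_ring[i] <- TRUE; in_ring[j] <- TRUE }
  }
  # fukui by explicit differences, mode by receptor sign
  mode <- if (!is.null(params$fukui_mode_override)) params$fukui_mode_override
          else if (q_net > 0) "f_plus" else "f_minus"
  f <- numeric(n)
  for (k in seq_len(n)) {
    f[k] <- if (mode == "f_plus") neutral$charges[k] - anion$charges[k]
            else cation$charges[k] - neutral$charges[k]
  }
  if (params$condense) {
    for (h in seq_len(n)) {
      if (el[h] != "H") next
      hv <- 0L
      for (j in seq_len(n)) if (bonded[h, j] && el[j] != "H") hv <- j
      f[hv] <- f[hv] + f[h]
      f[h] <- 0
    }
  }
  dmag <- sqrt(sum(dipole$vector^2))
  total <- 0
  for (i in seq_len(n)) {
    if (el[i] != "C") next
    for (j in seq_len(n)) {
      if (!bonded[i, j]) next
      ok <- el[j] %in% c("H", "O", "N") || (el[j] == "C" && !in_ring[j])
      if (!ok) next
      v <- xyz[j, ] - xyz[i, ]
      v <- v / sqrt(sum(v^2))
      cosphi <- if (dmag > 0) sum(v * dipole$vector) / dmag else 0
      total <- total + f[i] * dmag * cosphi
    }
  }
  params$c_lr * q_net * total
}
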