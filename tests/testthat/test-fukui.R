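test_that("condensed Fukui functions are the finite-difference charge gaps", {
  # whole added electron on a single atom
  n1 <- charge_set(0, "neutral"); a1 <- charge_set(-1, "anion")
  k1 <- charge_set(1, "cation")
  expect_equal(unname(condensed_fukui(n1, a1, k1, "f_plus")$values), 1)

  # three-atom toy, element-wise subtraction oracle
  n3 <- charge_set(c(0.1, -0.1, 0.0), "neutral")
  a3 <- charge_set(c(-0.3, -0.4, -0.3), "anion")
  k3 <- charge_set(c(0.5, 0.3, 0.2), "cation")
  expect_equal(unname(condensed_fukui(n3, a3, k3, "f_plus")$values),
               c(0.4, 0.3, 0.3))
  expect_equal(unname(condensed_fukui(n3, a3, k3, "f_minus")$values),
               c(0.4, 0.4, 0.2))
  f0 <- condensed_fukui(n3, a3, k3, "f_zero")$values
  expect_equal(unname(f0), c(0.4, 0.35, 0.25))

  # conservation: all three modes sum to 1
  for (mode in c("f_plus", "f_minus", "f_zero"))
    expect_equal(sum(condensed_fukui(n3, a3, k3, mode)$values), 1,
                 tolerance = 1e-12)
})

test_that("charge-set and Fukui input validation catches misuse", {
  expect_error(charge_set(c(0.3, 0.3), "neutral"), "sums to")
  expect_error(charge_set(c(0.5, 0.4), "anion"), "sums to")
  n <- charge_set(c(0, 0), "neutral")
  a <- charge_set(c(-0.5, -0.5), "anion")
  k <- charge_set(c(0.5, 0.5), "cation")
  expect_error(condensed_fukui(a, n, k), "state labels")
  a3 <- charge_set(c(-0.4, -0.3, -0.3), "anion")
  expect_error(condensed_fukui(n, a3, k), "mismatched lengths")
  neg <- charge_set(c(1.2, -1.2), "neutral")
  expect_warning(condensed_fukui(neg, a, k, "f_plus"), "negative Fukui")
})

test_that("hydrogen condensation folds H weight into heavy atoms and conserves totals", {
  benz <- make_ring_molecule(1)
  bonds <- perceive_bonds(benz)
  uniform <- charge_set(rep(0, 12), "neutral")
  an <- charge_set(rep(-1 / 12, 12), "anion")
  ka <- charge_set(rep(1 / 12, 12), "cation")
  fv <- condensed_fukui(uniform, an, ka, "f_plus")
  cond <- hydrogen_condense(fv, benz, bonds)
  expect_equal(length(cond$values), 6L)
  expect_equal(unname(cond$values), rep(1 / 6, 6))

  # planted per-atom values match a hand-summed oracle
  fx <- random_drf_fixture(21)
  fv2 <- condensed_fukui(fx$charges$neutral, fx$charges$anion,
                         fx$charges$cation, "f_plus")
  bonds2 <- perceive_bonds(fx$mol)
  cond2 <- hydrogen_condense(fv2, fx$mol, bonds2)
  hand <- fv2$values
  for (h in which(fx$mol$elements == "H")) {
    nb <- setdiff(which(apply(bonds2$edges, 1L, function(e) h %in% e)), integer(0))
    partners <- setdiff(as.integer(bonds2$edges[nb, ]), h)
    heavy <- partners[fx$mol$elements[partners] != "H"]
    hand[heavy] <- hand[heavy] + hand[as.character(h)]
  }
  expect_equal(unname(cond2$values),
               unname(hand[fx$mol$elements != "H"]), tolerance = 1e-12)
  expect_equal(sum(cond2$values), sum(fv2$values), tolerance = 1e-12)

  # H2: a hydrogen with no heavy neighbor is rejected
  h2 <- molecule(c("H", "H"), rbind(c(0, 0, 0), c(0.74, 0, 0)))
  fvh <- condensed_fukui(charge_set(c(0, 0), "neutral"),
                         charge_set(c(-0.5, -0.5), "anion"),
                         charge_set(c(0.5, 0.5), "cation"))
  expect_error(hydrogen_condense(fvh, h2, perceive_bonds(h2)), "heavy neighbors")
})

test_that("point-charge dipoles follow the Debye conversion and symmetry", {
  m <- molecule(c("C", "C"), rbind(c(0.5, 0, 0), c(-0.5, 0, 0)))
  cs <- charge_set(c(0.1, -0.1), "neutral")
  d <- dipole_from_point_charges(m, cs)
  expect_equal(d$vector, c(0.48032, 0, 0), tolerance = 1e-12)
  expect_equal(d$magnitude, 0.48032, tolerance = 1e-12)

  # centro-symmetric distribution: zero vector
  sq <- molecule(rep("C", 4),
                 rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0)))
  cs4 <- charge_set(c(0.2, 0.2, -0.2, -0.2), "neutral")
  expect_equal(dipole_from_point_charges(sq, cs4)$vector, c(0, 0, 0),
               tolerance = 1e-12)

  # translation invariance for a neutral system; independent summation oracle
  fx <- random_drf_fixture(31)
  d1 <- dipole_from_point_charges(fx$mol, fx$charges$neutral)
  shifted <- molecule(fx$mol$elements, sweep(fx$mol$coords, 2L, c(-3, 7, 2), "+"))
  d2 <- dipole_from_point_charges(shifted, fx$charges$neutral)
  expect_equal(d1$vector, d2$vector, tolerance = 1e-10)
  oracle <- c(0, 0, 0)
  for (i in seq_len(n_atoms(fx$mol)))
    oracle <- oracle + fx$charges$neutral$charges[i] * fx$mol$coords[i, ]
  expect_equal(d1$vector, 4.80320 * oracle, tolerance = 1e-10)

  # charged set needs an explicit origin
  expect_error(dipole_from_point_charges(m, charge_set(c(1.05, -0.05), "cation")),
               "origin")
})

test_that("largest-Fukui selection reports ties and matches a brute-force scan", {
  mk <- function(v) structure(list(mode = "f_plus",
                                   values = stats::setNames(v, seq_along(v)),
                                   condensed = TRUE), class = "fukui_vector")
  expect_equal(largest_fukui_sites(mk(c(0.068, 0.068, 0.050))), c(1L, 2L))
  expect_equal(largest_fukui_sites(mk(c(0.3, 0.2, 0.1))), 1L)
  set.seed(8)
  v <- runif(20)
  planted <- sample(20, 1); v[planted] <- max(v) + 0.1
  expect_equal(largest_fukui_sites(mk(v)), planted)
  expect_error(largest_fukui_sites(mk(numeric(0))), "empty")
})

test_that("orbital-energy bookkeeping enforces a non-negative gap", {
  oe <- orbital_energies(-5.75, -1.51)
  expect_equal(oe$gap, 4.24)
  expect_error(orbital_energies(-1.0, -2.0), "gap")
})
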