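test_that("fused-ring generator produces cata-condensed formulas deterministically", {
  benz <- make_ring_molecule(1)
  expect_equal(n_atoms(benz), 12L)
  expect_equal(sum(benz$elements == "C"), 6L)

  # cata-condensed PAH bookkeeping: C(4n+2) H(2n+4)
  for (n in 1:6) for (fusion in c("angular", "linear")) {
    m <- make_ring_molecule(n, fusion = fusion)
    expect_equal(sum(m$elements == "C"), 4L * n + 2L)
    expect_equal(sum(m$elements == "H"), 2L * n + 4L)
  }
  chry <- make_ring_molecule(4)
  expect_equal(n_atoms(chry), 30L)  # C18H12

  expect_identical(make_ring_molecule(3, c("2" = "methyl"))$coords,
                   make_ring_molecule(3, c("2" = "methyl"))$coords)
  expect_error(make_ring_molecule(2, c("99" = "methyl")), "out of range")
  expect_error(make_ring_molecule(2, c("1" = "bromo")), "substituents")
})

test_that("planted charge states round-trip Fukui, dipole and argmax", {
  mol <- make_ring_molecule(2)
  heavy <- which(mol$elements != "H")
  uniform <- rep(1 / length(heavy), length(heavy))
  cs <- plant_charge_states(mol, uniform, c(3, -1, 0))
  expect_equal(sum(cs$neutral$charges), 0, tolerance = 1e-9)
  expect_equal(sum(cs$anion$charges), -1, tolerance = 1e-9)
  expect_equal(sum(cs$cation$charges), 1, tolerance = 1e-9)

  fv <- condensed_fukui(cs$neutral, cs$anion, cs$cation, "f_plus")
  expect_equal(unname(fv$values[heavy]), uniform, tolerance = 1e-9)
  d <- dipole_from_point_charges(mol, cs$neutral)
  expect_equal(d$vector, c(3, -1, 0), tolerance = 1e-6)

  # asymmetric plant: known argmax is recovered after condensation
  w <- uniform; w[4] <- w[4] + 0.5; w <- w / sum(w)
  cs2 <- plant_charge_states(mol, w, c(2, 1, 0))
  fv2 <- hydrogen_condense(
    condensed_fukui(cs2$neutral, cs2$anion, cs2$cation), mol,
    perceive_bonds(mol))
  expect_equal(largest_fukui_sites(fv2), heavy[4])

  # out-of-plane dipole is infeasible for in-plane point charges
  expect_error(plant_charge_states(mol, uniform, c(0, 0, 5)), "infeasible")
})

test_that("simulated dose-response curves sit on the planted logistic", {
  spec <- fixture_spec(seed = 5, planted_ec50 = 4, noise_sd = 0)
  cv <- simulate_dose_response(spec)
  expect_equal(nrow(cv), 30L)  # 10 doses x 3 replicates
  # dose = planted EC50 (4 uM is on the fivefold grid) -> response 50
  expect_equal(unique(cv$response[cv$dose == 4]), 50, tolerance = 1e-9)
  # monotone non-decreasing mean response with dose
  mu <- tapply(cv$response, cv$dose, mean)
  expect_true(all(diff(mu) > 0))
  # determinism with noise
  spec2 <- fixture_spec(seed = 5, planted_ec50 = 4, noise_sd = 5)
  expect_identical(simulate_dose_response(spec2)$response,
                   simulate_dose_response(spec2)$response)
})

test_that("fixture specs validate planted quantities", {
  expect_error(fixture_spec(seed = 1, planted_ec50 = -1), "positive")
  expect_error(fixture_spec(seed = 1, noise_sd = -2), "non-negative")
  expect_error(fixture_spec(seed = 1, planted_fukui = c(0.5, 0.4)), "sum to 1")
  expect_identical(fixture_spec(seed = 9)$planted_dipole,
                   fixture_spec(seed = 9)$planted_dipole)
})

test_that("the brute-force oracle reproduces hand arithmetic and degenerate cases", {
  mol <- toy_ch(c(1, 0, 0))
  cs <- list(neutral = charge_set(c(0, 0), "neutral"),
             anion = charge_set(c(-0.95, -0.05), "anion"),
             cation = charge_set(c(0.95, 0.05), "cation"))
  # f+ on C condenses to 1; single parallel site: 4.1 * 1 * 10 * 1 = 41
  expect_equal(drf_bruteforce_oracle(mol, cs$neutral, cs$anion, cs$cation,
                                     dipole_vector(c(10, 0, 0)), 4.1), 41,
               tolerance = 1e-12)
  expect_equal(drf_bruteforce_oracle(mol, cs$neutral, cs$anion, cs$cation,
                                     dipole_vector(c(0, 0, 0)), 4.1), 0)
  # f = 0.05 on the only scoring atom without condensation
  expect_equal(drf_bruteforce_oracle(mol,
                 charge_set(c(0, 0), "neutral"),
                 charge_set(c(-0.05, -0.95), "anion"),
                 charge_set(c(0.05, 0.95), "cation"),
                 dipole_vector(c(10, 0, 0)), 4.1,
                 drf_control(condense = FALSE)), 2.05, tolerance = 1e-12)
})
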