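test_that("Fukui mode follows the screened receptor charge", {
  expect_equal(select_fukui_mode(4.1), "f_plus")
  expect_equal(select_fukui_mode(-4.1), "f_minus")
  expect_equal(select_fukui_mode(4.1, override = "f_minus"), "f_minus")
  expect_error(select_fukui_mode(0), "override")
  expect_error(select_fukui_mode(NaN), "finite")
})

test_that("site contributions multiply Fukui weight, dipole magnitude and cos(phi)", {
  mol <- toy_ch(c(1, 0, 0))
  sites <- find_terminal_sites(mol, perceive_bonds(mol))
  fv <- structure(list(mode = "f_plus", values = c(`1` = 0.05),
                       condensed = TRUE), class = "fukui_vector")
  par_d <- dipole_vector(c(10, 0, 0))
  ct <- site_contributions(sites, fv, par_d)
  expect_equal(ct$term, 0.5)       # 0.05 * 10 * 1
  expect_equal(ct$cos_phi, 1)

  zero <- site_contributions(sites, fv, dipole_vector(c(0, 0, 0)))
  expect_equal(zero$term, 0)
  expect_equal(zero$cos_phi, 0)

  bad_fv <- structure(list(mode = "f_plus", values = c(`9` = 0.05),
                           condensed = TRUE), class = "fukui_vector")
  expect_error(site_contributions(sites, bad_fv, par_d), "no Fukui value")

  # random fixture: terms equal a brute-force dot-product loop
  fx <- random_drf_fixture(41)
  bonds <- perceive_bonds(fx$mol)
  s <- find_terminal_sites(fx$mol, bonds)
  fvx <- hydrogen_condense(
    condensed_fukui(fx$charges$neutral, fx$charges$anion, fx$charges$cation),
    fx$mol, bonds)
  cts <- site_contributions(s, fvx, fx$dipole)
  dhat <- fx$dipole$vector / fx$dipole$magnitude
  for (k in seq_len(nrow(s))) {
    cp <- sum(c(s$dx[k], s$dy[k], s$dz[k]) * dhat)
    expect_equal(cts$cos_phi[k], cp, tolerance = 1e-12)
    expect_equal(cts$term[k],
                 unname(fvx$values[as.character(s$heavy[k])]) *
                   fx$dipole$magnitude * cp,
                 tolerance = 1e-12)
  }
})

test_that("the score assembles as c_lr * q_net * sum of terms", {
  ct <- data.frame(heavy = 1L, substituent = 2L, fukui = 0.05,
                   cos_phi = 1, term = 0.5)
  expect_equal(compute_drf(ct, 4.1), 2.05)
  expect_equal(compute_drf(ct, 4.1, drf_control(c_lr = 2)), 4.10)
  expect_error(compute_drf(ct[0, ], 4.1), "non-empty")
  ct$term <- NaN
  expect_error(compute_drf(ct, 4.1), "non-finite")
})

test_that("orientation classification thresholds on mean cos(phi)", {
  mk <- function(cos_phi, heavy = seq_along(cos_phi))
    data.frame(heavy = heavy, cos_phi = cos_phi)
  expect_equal(classify_orientation(1L, mk(1.0)), "F")
  expect_equal(classify_orientation(1L, mk(0.0)), "P")
  expect_equal(classify_orientation(1L, mk(-1.0)), "B")
  # ties are averaged: cos 1 and cos 0 -> mean 0.5 -> F at default tau
  expect_equal(classify_orientation(c(1L, 2L), mk(c(1, 0))), "F")
  # just inside the perpendicular band
  expect_equal(classify_orientation(1L, mk(0.25)), "P")
  expect_error(classify_orientation(integer(0), mk(1)), "at least one")
})

test_that("full pipeline matches single-site hand arithmetic", {
  mol <- toy_ch(c(1, 0, 0))
  cs <- list(neutral = charge_set(c(0, 0), "neutral"),
             anion = charge_set(c(-1, 0), "anion"),
             cation = charge_set(c(1, 0), "cation"))
  res <- drf(mol, cs$neutral, cs$anion, cs$cation, q_net = 4.1,
             dipole = dipole_vector(c(10, 0, 0)))
  # f+ condenses to 1 on the carbon; term = 1 * 10 * 1; DRF = 4.1 * 10
  expect_equal(res$drf, 41)
  expect_equal(res$fukui_mode, "f_plus")
  expect_equal(res$orientation_class, "F")
  expect_equal(res$max_fukui_atoms, 1L)
})

test_that("DRF is linear in c_lr, q_net and dipole magnitude", {
  fx <- random_drf_fixture(51)
  base_args <- list(fx$mol, fx$charges$neutral, fx$charges$anion,
                    fx$charges$cation)
  score <- function(q = fx$q_net, d = fx$dipole, p = drf_control())
    do.call(drf, c(base_args, list(q_net = q, dipole = d, params = p)))$drf
  s0 <- score()
  expect_equal(score(p = drf_control(c_lr = 2)), 2 * s0, tolerance = 1e-12)
  expect_equal(score(q = 2 * fx$q_net), 2 * s0, tolerance = 1e-12)
  expect_equal(score(d = dipole_vector(2 * fx$dipole$vector)), 2 * s0,
               tolerance = 1e-12)
})

test_that("ranking is descending with stable name tie-breaks", {
  ref <- load_reference_tables()
  ranked <- rank_by_drf(ref[, c("compound", "drf")])
  expect_equal(ranked$compound[1], "2-methylchrysene")
  expect_equal(ranked$drf[1], 27.97)
  # chrysene and dibenzo[b,def]chrysene tie at -0.02: name order
  tie <- ranked$compound[ranked$drf == -0.02]
  expect_equal(tie, sort(tie))

  set.seed(6)
  rnd <- data.frame(compound = paste0("c", 1:20), drf = rnorm(20))
  expect_equal(rank_by_drf(rnd)$drf, sort(rnd$drf, decreasing = TRUE))

  dup <- data.frame(compound = c("a", "a"), drf = c(1, 2))
  expect_error(rank_by_drf(dup), "duplicate")
})
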