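test_that("heinrich_eta matches the cubic fit and is monotone in Z", {
  # oracle: direct polynomial arithmetic
  expect_equal(heinrich_eta(6), eta_poly(6), tolerance = 1e-12)
  expect_equal(round(heinrich_eta(6), 3), 0.064)
  etas <- heinrich_eta(1:92)
  expect_true(all(etas > 0 & etas < 1))
  expect_true(all(diff(etas) > 0))
  expect_gt(heinrich_eta(20), heinrich_eta(8))
  expect_equal(heinrich_eta(1), min(etas))
  expect_error(heinrich_eta(0), "1..92")
  expect_error(heinrich_eta(93), "1..92")
})

test_that("eta_eff obeys the mixture rule, its bounds and linearity", {
  # single component reduces to the atomic coefficient
  carbon <- material("graphite", c(C = 1))
  expect_equal(eta_eff(carbon), heinrich_eta(6))
  # 50/50 mass mixture -> arithmetic mean
  mix <- material("CO-mix", c(C = 0.5, O = 0.5))
  expect_equal(eta_eff(mix), mean(heinrich_eta(c(6, 8))))
  # calcite: hand-computed weighted sum from formula mass fractions
  calcite <- material_from_formula("calcite", "CaCO3", density = 2.71)
  fr <- calcite$mass_fractions
  expect_equal(unname(fr["Ca"]), 0.4004, tolerance = 1e-3)
  oracle <- fr[["Ca"]] * eta_poly(20) + fr[["C"]] * eta_poly(6) +
    fr[["O"]] * eta_poly(8)
  expect_equal(eta_eff(calcite), oracle, tolerance = 1e-12)
  # bounded by the component coefficients
  expect_gt(eta_eff(calcite), heinrich_eta(6))
  expect_lt(eta_eff(calcite), heinrich_eta(20))
  # linear under mass-weighted blending
  a <- c(C = 0.3, O = 0.7)
  b <- c(Ca = 0.6, O = 0.4)
  blend <- material("blend", c(C = 0.25 * 0.3, Ca = 0.75 * 0.6,
                               O = 0.25 * 0.7 + 0.75 * 0.4))
  expect_equal(eta_eff(blend),
               0.25 * eta_eff(material("a", a)) +
                 0.75 * eta_eff(material("b", b)),
               tolerance = 1e-12)
  expect_error(material("bad", c(C = 0.5, O = 0.6)), "sum to 1")
  expect_error(eta_eff(c(Xx = 1)), "unknown element")
})

test_that("molarity_of_solution implements the density mixing rule", {
  # pure water, no solute
  w <- molarity_of_solution(c(H2O = 1), target_species = "H2O")
  expect_equal(attr(w, "rho_s"), 0.9982)
  # pure calcite as the "solution": 1000 * 2.71 / 100.09
  m <- molarity_of_solution(c(CaCO3 = 1), c(CaCO3 = 2.71), "CaCO3", "Ca")
  expect_equal(as.numeric(m), 1000 * 2.71 / formula_mass("CaCO3"),
               tolerance = 1e-12)
  expect_equal(round(as.numeric(m)), 27)
  # single-component solution reduces to 1000 rho / M
  s <- molarity_of_solution(c(NaCl = 1), c(NaCl = 2.165), "NaCl")
  expect_equal(as.numeric(s), 1000 * 2.165 / formula_mass("NaCl"))
  expect_error(molarity_of_solution(c(H2O = 0.9), target_species = "H2O"),
               "sum to 1")
})

test_that("electrolyte molarity matches a direct mass-balance oracle", {
  model <- electrolyte_model()
  c_ca <- 0.10
  # oracle: 1 kg of solution, V from summed component volumes
  avogadro <- 6.02214076e23
  rho_of <- function(formula, r_pm) {
    formula_mass(formula) / avogadro / (4 / 3 * pi * (r_pm * 1e-10)^3)
  }
  rho_ca <- rho_of("Ca", 100)
  rho_po3 <- rho_of("PO3", 210)
  c_po3 <- c_ca * 2 * formula_mass("PO3") / formula_mass("Ca")
  c_w <- 1 - c_ca - c_po3
  V_cm3 <- 1000 * (c_w / 0.9982 + c_ca / rho_ca + c_po3 / rho_po3)
  oracle_M <- (100 / formula_mass("Ca")) / (V_cm3 / 1000)
  expect_equal(as.numeric(electrolyte_molarity(c_ca, model)), oracle_M,
               tolerance = 1e-9)
  # monotone in the mass fraction
  ms <- vapply(seq(0, 0.2, by = 0.02),
               function(c) as.numeric(electrolyte_molarity(c, model)),
               numeric(1))
  expect_true(all(diff(ms) > 0))
  expect_equal(ms[1], 0)
})

test_that("build_electrolyte honours the configured Ca:P ratio", {
  model <- electrolyte_model()
  # zero calcium -> pure water
  w <- build_electrolyte(0, model)
  expect_equal(sort(names(w$mass_fractions[w$mass_fractions > 0])),
               c("H", "O"))
  # stoichiometric P fraction at 10% Ca
  m <- build_electrolyte(0.10, model)
  expect_equal(unname(m$mass_fractions["P"]),
               0.10 * (2 * 30.974 / 40.078), tolerance = 1e-4)
  expect_equal(sum(m$mass_fractions), 1, tolerance = 1e-12)
  # round trip: recompute the atomic ratio from the element fractions
  n_ca <- m$mass_fractions[["Ca"]] / formula_mass("Ca")
  n_p <- m$mass_fractions[["P"]] / formula_mass("P")
  expect_equal(n_p / n_ca, 2, tolerance = 1e-9)
  # over the consistency limit
  expect_error(build_electrolyte(0.5, model), "consistency limit")
  # alternative ratio flows through
  m2 <- build_electrolyte(0.05, electrolyte_model(ca_p_ratio = c(1, 1)))
  n_ca2 <- m2$mass_fractions[["Ca"]] / formula_mass("Ca")
  n_p2 <- m2$mass_fractions[["P"]] / formula_mass("P")
  expect_equal(n_p2 / n_ca2, 1, tolerance = 1e-9)
})

test_that("molarity inversion round-trips through the mass fraction", {
  model <- electrolyte_model()
  for (M in c(0.5, 1.5, 10, 13.4)) {
    cf <- ca_fraction_for_molarity(M, model)
    expect_equal(as.numeric(electrolyte_molarity(cf, model)), M,
                 tolerance = 1e-6)
  }
  expect_equal(ca_fraction_for_molarity(0, model), 0)
  expect_error(ca_fraction_for_molarity(50, model), "exceeds")
})
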