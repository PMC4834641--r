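test_that("calibration line fits standards exactly and matches closed form", {
  mk <- function(name, formula, grey) {
    calibration_standard(name, material_from_formula(name, formula), grey)
  }
  # two standards: line passes through both
  s2 <- list(mk("lipid", "CH2", 20), mk("calcite", "CaCO3", 80))
  cal <- fit_calibration(s2)
  expect_equal(predict(cal, s2[[1]]$eta_eff), 20, tolerance = 1e-9)
  expect_equal(predict(cal, s2[[2]]$eta_eff), 80, tolerance = 1e-9)
  expect_equal(cal$residual_norm, 0, tolerance = 1e-9)
  # three collinear standards: zero residual
  water <- material_from_formula("water", "H2O")
  eta_w <- eta_eff(water)
  s3 <- list(mk("lipid", "CH2", 0), mk("calcite", "CaCO3", 0),
             calibration_standard("water", water, 0))
  for (i in seq_along(s3)) s3[[i]]$mean_grey <- 100 * s3[[i]]$eta_eff + 5
  cal3 <- fit_calibration(s3)
  expect_equal(cal3$slope, 100, tolerance = 1e-9)
  expect_equal(cal3$intercept, 5, tolerance = 1e-9)
  expect_equal(cal3$residual_norm, 0, tolerance = 1e-6)
  # noisy standards: oracle = closed-form simple regression
  greys <- c(12.1, 25.3, 79.2)
  s3n <- Map(function(s, g) { s$mean_grey <- g; s }, s3, greys)
  caln <- fit_calibration(s3n)
  eta <- vapply(s3n, `[[`, numeric(1), "eta_eff")
  slope_or <- sum((eta - mean(eta)) * (greys - mean(greys))) /
    sum((eta - mean(eta))^2)
  int_or <- mean(greys) - slope_or * mean(eta)
  expect_equal(caln$slope, slope_or, tolerance = 1e-10)
  expect_equal(caln$intercept, int_or, tolerance = 1e-10)
  # degenerate spread
  expect_error(fit_calibration(list(mk("a", "CH2", 1), mk("b", "CH2", 2))),
               "degenerate")
})

test_that("grey_to_eta inverts the calibration line", {
  cal <- fit_calibration(list(
    calibration_standard("a", material_from_formula("a", "CH2"), 10),
    calibration_standard("b", material_from_formula("b", "CaCO3"), 110)))
  eta_a <- eta_eff(material_from_formula("a", "CH2"))
  eta_b <- eta_eff(material_from_formula("b", "CaCO3"))
  expect_equal(grey_to_eta(10, cal), eta_a, tolerance = 1e-10)
  expect_equal(grey_to_eta(110, cal), eta_b, tolerance = 1e-10)
  expect_equal(grey_to_eta(60, cal), (eta_a + eta_b) / 2, tolerance = 1e-10)
  for (eta in seq(0.05, 0.2, by = 0.05)) {
    expect_equal(grey_to_eta(predict(cal, eta), cal), eta, tolerance = 1e-10)
  }
})

test_that("eta inversion to molarity round-trips and is monotone", {
  model <- electrolyte_model()
  eta_w <- eta_eff(build_electrolyte(0, model))
  expect_equal(eta_to_ca_molarity(eta_w, model)$ca_molarity, 0,
               tolerance = 1e-5)
  # forward 10 M-equivalent electrolyte, invert: within 1%
  cf <- ca_fraction_for_molarity(10, model)
  eta10 <- eta_eff(build_electrolyte(cf, model))
  est <- eta_to_ca_molarity(eta10, model)
  expect_equal(est$ca_molarity, 10, tolerance = 0.01)
  # monotone: larger eta -> strictly larger molarity
  etas <- seq(eta_w + 1e-4, eta_eff(build_electrolyte(
    ca_mass_fraction_limit(model), model)) - 1e-4, length.out = 6)
  ms <- vapply(etas, function(e) eta_to_ca_molarity(e, model)$ca_molarity,
               numeric(1))
  expect_true(all(diff(ms) > 0))
  expect_warning(low <- eta_to_ca_molarity(eta_w - 0.01, model), "0 M")
  expect_equal(low$ca_molarity, 0)
  expect_error(eta_to_ca_molarity(0.9, model), "exceeds")
})

test_that("full chain recovers planted molarity from a noise-free phantom", {
  ph <- default_phantom()
  sb <- standard_bundle(ph)
  r <- render_bse(ph, gain = 180, offset = 12, noise_sd = 0)
  est <- quantify_body(r$esb, phantom_mask(ph, "body"),
                       sb$materials, sb$masks)
  expect_equal(est$ca_molarity, 10, tolerance = 1e-4)
  cal <- attr(est, "calibration")
  expect_equal(cal$slope, 180, tolerance = 1e-6)
  expect_equal(cal$intercept, 12, tolerance = 1e-6)
  # EsB modality is enforced
  expect_error(quantify_body(r$inlens, phantom_mask(ph, "body"),
                             sb$materials, sb$masks), "EsB")
})

test_that("recovery error scales roughly linearly with grey noise", {
  ph <- default_phantom()
  sb <- standard_bundle(ph)
  err_at <- function(noise_sd, seeds) {
    mean(vapply(seeds, function(s) {
      r <- render_bse(ph, gain = 200, offset = 10, noise_sd = noise_sd,
                      seed = s)
      abs(quantify_body(r$esb, phantom_mask(ph, "body"), sb$materials,
                        sb$masks)$ca_molarity - 10)
    }, numeric(1)))
  }
  e1 <- err_at(0.5, 1:6)
  e2 <- err_at(2.0, 1:6)
  expect_lt(e1, e2)            # error grows with noise
  expect_lt(e2, 4 * e1 * 3)    # and not faster than ~linearly (slack 3x)
})

test_that("a calcite region inverted against calcite composition gives ~27 M", {
  # sanity check: treat pure calcite as a single-species solution
  m <- molarity_of_solution(c(CaCO3 = 1), c(CaCO3 = 2.71), "CaCO3", "Ca")
  expect_equal(round(as.numeric(m)), 27)
  ph <- default_phantom()
  expect_equal(ph$molarity_M[["coccolith"]], as.numeric(m), tolerance = 1e-9)
})
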