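test_that("difference map isolates Ca and scales with thickness", {
  # delta-OD vanishes wherever no Ca phase lies in the beam path, even over
  # a zero-molarity body (its absorbance is energy-independent)
  ph0 <- default_phantom(body_molarity_M = 0)
  es0 <- render_xray(ph0, c(342, 353.2))
  dm0 <- ca_difference_map(es0)
  ca_free <- path_length_map(phantom_mask(ph0, "coccolith"), 1,
                             ph0$voxel_size_nm) == 0
  expect_lt(max(abs(dm0$pixels[ca_free])), 1e-10)
  # calcite-bearing phantom: positive inside the coccolith footprint
  ph <- default_phantom()
  es <- render_xray(ph, c(342, 353.2))
  dm <- ca_difference_map(es)
  fp <- path_length_map(phantom_mask(ph, "coccolith"), 1,
                        ph$voxel_size_nm) > 0
  bg <- path_length_map(phantom_mask(ph, "coccolith") |
                          phantom_mask(ph, "body"), 1, ph$voxel_size_nm) == 0
  expect_gt(min(dm$pixels[fp]), 0)
  expect_lt(max(abs(dm$pixels[bg])), 1e-10)
  # Beer-Lambert linearity: delta-OD proportional to the body chord length
  # (away from pixels whose path also crosses the coccolith)
  pl <- path_length_map(phantom_mask(ph, "body"), 1, ph$voxel_size_nm)
  plc <- path_length_map(phantom_mask(ph, "coccolith"), 1, ph$voxel_size_nm)
  bf <- pl > 0 & plc == 0
  ratio <- dm$pixels[bf] / pl[bf]
  expect_lt(stats::sd(ratio) / mean(ratio), 1e-9)
  expect_error(ca_difference_map(es, e_below = 300), "no frame within")
})

test_that("region spectra show crystal-field peaks only for calcite", {
  ph <- default_phantom(body_molarity_M = 13.4)
  en <- seq(346.5, 354.7, by = 0.15)
  es <- render_xray(ph, en)
  cocc_fp <- path_length_map(phantom_mask(ph, "coccolith"), 1,
                             ph$voxel_size_nm) > 0
  body_fp <- path_length_map(phantom_mask(ph, "body"), 1,
                             ph$voxel_size_nm) > 0
  sp_c <- extract_region_spectrum(es, cocc_fp)
  sp_b <- extract_region_spectrum(es, body_fp)
  expect_equal(sp_c$energies_eV, en)
  pk_c <- crystal_field_peaks(sp_c)
  pk_b <- crystal_field_peaks(sp_b)
  expect_true(pk_c$significant)
  expect_false(pk_b$significant)
  # single-pixel mask returns that pixel's series
  i <- which(body_fp, arr.ind = TRUE)[1, ]
  one <- matrix(FALSE, nrow(body_fp), ncol(body_fp))
  one[i[1], i[2]] <- TRUE
  sp1 <- extract_region_spectrum(es, one)
  ods <- vapply(seq_along(en), function(k) {
    -log(es$frames$voxels[k, i[1], i[2]] / es$flat_field[i[1], i[2]])
  }, numeric(1))
  expect_equal(sp1$intensity, ods, tolerance = 1e-12)
  expect_error(extract_region_spectrum(es, one & FALSE), "no pixels")
})

test_that("path length maps are brute-force verifiable", {
  m <- array(FALSE, c(10, 12, 14))
  m[3:7, 4:8, 5:9] <- TRUE  # solid 5-voxel cube
  pl <- path_length_map(m, 1, 20)
  expect_true(all(pl[4:8, 5:9] == 100))
  expect_true(all(pl[-(4:8), ] == 0))
  # axes 2 and 3
  expect_equal(max(path_length_map(m, 2, 20)), 100)
  expect_equal(max(path_length_map(m, 3, 20)), 100)
  # discretized sphere: central chord = diameter within one voxel
  d <- 21
  x <- seq_len(d) - (d + 1) / 2
  r2 <- outer(outer(x^2, x^2, `+`), x^2, `+`)
  sph <- r2 <= 8^2
  pls <- path_length_map(sph, 1, 1)
  expect_equal(max(pls), 2 * 8, tolerance = 1 / 8)
  # empty mask -> zeros
  expect_true(all(path_length_map(array(FALSE, c(4, 4, 4)), 1, 1) == 0))
})

test_that("concentration estimation is linear and self-calibrating", {
  # region identical to the calibration region
  expect_equal(estimate_concentration(0.4, 500, 0.4, 500)$ca_molarity, 27)
  # half the areal OD at equal path
  expect_equal(estimate_concentration(0.2, 500, 0.4, 500)$ca_molarity, 13.5)
  # inverse in path length
  expect_equal(estimate_concentration(0.4, 1000, 0.4, 500)$ca_molarity, 13.5)
  expect_error(estimate_concentration(0.4, 0, 0.4, 500), "positive")
})

test_that("the full X-ray chain recovers a planted 13.4 M body", {
  ph <- default_phantom(body_molarity_M = 13.4)
  body <- phantom_mask(ph, "body")
  cocc <- phantom_mask(ph, "coccolith")
  # noise-free, drift-free: exact
  c_cal <- ph$molarity_M[["coccolith"]]  # ground-truth calcite molarity
  es0 <- render_xray(ph, c(342, 353.2))
  est0 <- xray_quantify_body(es0, body, cocc, 1, ph$voxel_size_nm,
                             c_cal = c_cal, align = FALSE)
  expect_equal(est0$ca_molarity, 13.4, tolerance = 1e-6)
  # frame jitter without noise: sequential scan alignment restores exactness
  en <- c(342, seq(347.7, 353.2, by = 0.5))
  esj <- render_xray(ph, en, jitter_px = 2, seed = 11)
  estj <- xray_quantify_body(esj, body, cocc, 1, ph$voxel_size_nm,
                             c_cal = c_cal)
  expect_equal(estj$ca_molarity, 13.4, tolerance = 1e-6)
  # noise + frame jitter
  es <- render_xray(ph, en, noise = "gaussian", noise_sd = 0.01,
                    jitter_px = 2, seed = 5)
  est <- xray_quantify_body(es, body, cocc, 1, ph$voxel_size_nm)
  expect_equal(est$ca_molarity, 13.4, tolerance = 0.15)
  # chain linearity: doubled concentration doubles the estimate
  ph2 <- default_phantom(body_molarity_M = 6.7)
  es2 <- render_xray(ph2, c(342, 353.2))
  est2 <- xray_quantify_body(es2, body, cocc, 1, ph$voxel_size_nm,
                             c_cal = c_cal, align = FALSE)
  expect_equal(est0$ca_molarity / est2$ca_molarity, 2, tolerance = 1e-6)
  # invariance to flat-field scaling
  es3 <- es0
  es3$frames$voxels <- es3$frames$voxels * 7.5
  es3$flat_field <- es3$flat_field * 7.5
  est3 <- xray_quantify_body(es3, body, cocc, 1, ph$voxel_size_nm,
                             c_cal = c_cal, align = FALSE)
  expect_equal(est3$ca_molarity, est0$ca_molarity, tolerance = 1e-10)
  # invariance to the viewing axis (isotropic rendering model)
  for (ax in 2:3) {
    esx <- render_xray(ph, c(342, 353.2), axis = ax)
    estx <- xray_quantify_body(esx, body, cocc, ax, ph$voxel_size_nm,
                               c_cal = c_cal, align = FALSE)
    expect_equal(estx$ca_molarity, 13.4, tolerance = 1e-6)
  }
})

test_that("repeated-scan comparison flags spectral change", {
  e <- seq(346.5, 354.7, by = 0.15)
  s1 <- xas_spectrum(e, ca_ledge_mu(e, 10) * 500)
  s2 <- xas_spectrum(e, ca_ledge_mu(e, 10) * 500)
  cmp <- compare_scans(s1, s2, tol = 1e-6)
  expect_true(cmp$within_tol)
  s3 <- xas_spectrum(e, ca_ledge_mu(e, 12) * 500)
  expect_false(compare_scans(s1, s3, tol = 0.01)$within_tol)
})
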