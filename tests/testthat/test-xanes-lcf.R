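test_that("scan averaging reduces noise like 1/sqrt(n)", {
  refs <- kedge_references()
  base <- refs$calcite
  # single spectrum unchanged; offsets cancel
  expect_equal(average_scans(list(base))$intensity, base$intensity)
  up <- xas_spectrum(base$energies_eV, base$intensity + 0.2)
  dn <- xas_spectrum(base$energies_eV, base$intensity - 0.2)
  expect_equal(average_scans(list(up, dn))$intensity, base$intensity,
               tolerance = 1e-12)
  # residual sd shrinks ~1/sqrt(n) over seeds
  noisy_resid <- function(n, seed) {
    set.seed(seed)
    scans <- lapply(seq_len(n), function(i) {
      xas_spectrum(base$energies_eV,
                   base$intensity + rnorm(length(base$intensity), sd = 0.05))
    })
    stats::sd(average_scans(scans)$intensity - base$intensity)
  }
  r1 <- mean(vapply(1:8, function(s) noisy_resid(1, s), numeric(1)))
  r16 <- mean(vapply(1:8, function(s) noisy_resid(16, s + 100), numeric(1)))
  expect_equal(r1 / r16, 4, tolerance = 0.35)
  # incompatible grids need explicit interpolation
  other <- xas_spectrum(base$energies_eV + 0.1, base$intensity)
  expect_error(average_scans(list(base, other)), "different energy grids")
  expect_silent(average_scans(list(base, other), interpolate = TRUE))
})

test_that("edge finding takes the third derivative peak, with fallback", {
  e <- seq(4015, 4140, by = 0.25)
  arctan_edge <- 0.5 + atan((e - 4048) / 1.5) / pi
  # two pre-edge bumps + main edge: third derivative peak at the edge centre
  y <- 0.05 * exp(-(e - 4034)^2 / 2) + 0.06 * exp(-(e - 4041)^2 / 2) +
    arctan_edge
  expect_equal(find_edge(xas_spectrum(e, y)), 4048, tolerance = 0.5)
  # energy equivariance
  y2 <- 0.05 * exp(-(e - 4036)^2 / 2) + 0.06 * exp(-(e - 4043)^2 / 2) +
    0.5 + atan((e - 4050) / 1.5) / pi
  expect_equal(find_edge(xas_spectrum(e, y2)),
               find_edge(xas_spectrum(e, y)) + 2, tolerance = 0.3)
  # pure arctan: fewer than 3 peaks -> fallback to global derivative maximum
  expect_warning(E0 <- find_edge(xas_spectrum(e, arctan_edge)),
                 "fewer than 3")
  expect_equal(E0, 4048, tolerance = 0.5)
})

test_that("normalization is idempotent and affine-invariant", {
  e <- seq(4015, 4140, by = 0.25)
  step_fn <- 0.5 + atan((e - 4048) / 1.5) / pi
  raw <- xas_spectrum(e, 2.4 * step_fn)
  n0 <- normalize_spectrum(raw, E0 = 4048)
  expect_equal(n0$state, "normalized")
  # post-edge fluctuates about 1
  expect_equal(mean(n0$intensity[e > 4074 & e < 4138]), 1, tolerance = 0.01)
  # re-normalizing an ideal normalized spectrum changes nothing material
  n1 <- normalize_spectrum(n0, E0 = 4048)
  expect_equal(n1$intensity, n0$intensity, tolerance = 1e-8)
  # linear baseline invariance
  with_base <- xas_spectrum(e, 2.4 * step_fn + 0.003 * e - 7)
  nb <- normalize_spectrum(with_base, E0 = 4048)
  expect_equal(nb$intensity, n0$intensity, tolerance = 1e-9)
  # edge-step scale invariance
  ns <- normalize_spectrum(xas_spectrum(e, 4.8 * step_fn), E0 = 4048)
  expect_equal(ns$intensity, n0$intensity, tolerance = 1e-9)
  # insufficient span names the missing window
  short <- xas_spectrum(seq(4040, 4140, 0.25),
                        0.5 + atan((seq(4040, 4140, 0.25) - 4048) / 1.5) / pi)
  expect_error(normalize_spectrum(short, E0 = 4048), "pre-edge window")
})

test_that("LCF recovers weights exactly without noise", {
  refs <- kedge_references()
  # target equal to one reference
  f1 <- lcf(refs$acc, refs)
  expect_equal(unname(coef(f1)), c(0, 1, 0), tolerance = 1e-9)
  expect_lt(f1$residual, 1e-18)
  # exact convex mixture
  mx <- synth_kedge_mixture(c(0.5, 0.3, 0.2))
  f2 <- lcf(mx$target, refs)
  expect_equal(unname(coef(f2)), c(0.5, 0.3, 0.2), tolerance = 1e-6)
  expect_true(all(coef(f2) >= 0))
  expect_equal(sum(coef(f2)), 1, tolerance = 1e-6)
  # equal-weight mixture is the pointwise mean
  mx3 <- synth_kedge_mixture(rep(1, 3) / 3)
  mean_ref <- (refs$calcite$intensity + refs$acc$intensity +
                 refs$free_ion$intensity) / 3
  expect_equal(mx3$target$intensity, mean_ref, tolerance = 1e-12)
  # identical references warn but still return a valid simplex point
  expect_warning(f3 <- lcf(refs$calcite, list(a = refs$acc, b = refs$acc)),
                 "ill-conditioned")
  expect_equal(sum(coef(f3)), 1, tolerance = 1e-6)
})

test_that("noisy LCF matches a simplex grid-search oracle", {
  refs <- kedge_references()
  mx <- synth_kedge_mixture(c(0.5, 0.3, 0.2), noise_sd = 0.01, seed = 42)
  fit <- lcf(mx$target, refs)
  # oracle: grid search over the 2-simplex at 0.01 resolution
  e <- fit$energies_eV
  R <- vapply(refs, function(s) {
    stats::approx(s$energies_eV, s$intensity, e)$y
  }, numeric(length(e)))
  y <- stats::approx(mx$target$energies_eV, mx$target$intensity, e)$y
  best <- c(NA, NA, NA); best_r <- Inf
  for (w1 in seq(0, 1, by = 0.01)) {
    for (w2 in seq(0, 1 - w1, by = 0.01)) {
      w <- c(w1, w2, 1 - w1 - w2)
      r <- sum((y - R %*% w)^2)
      if (r < best_r) { best_r <- r; best <- w }
    }
  }
  expect_lt(max(abs(unname(coef(fit)) - best)), 0.011)
  expect_lte(fit$residual, best_r + 1e-12)
})

test_that("weight recovery bias vanishes as noise shrinks", {
  refs <- kedge_references()
  truth <- c(0.5, 0.3, 0.2)
  bias_at <- function(sd) {
    w <- rowMeans(vapply(1:10, function(s) {
      mx <- synth_kedge_mixture(truth, noise_sd = sd, seed = s)
      unname(coef(lcf(mx$target, refs)))
    }, numeric(3)))
    max(abs(w - truth))
  }
  b <- vapply(c(0.05, 0.01, 0.001), bias_at, numeric(1))
  expect_true(all(diff(b) < 0))
  expect_lt(b[3], 0.005)
})

test_that("reference-set comparison ranks the generating set first", {
  refs <- kedge_references()
  mx <- synth_kedge_mixture(c(0.4, 0.3, 0.3))
  rk <- compare_reference_sets(mx$target, list(
    with_acc = refs, no_acc = refs[c("calcite", "free_ion")]))
  expect_equal(rk$set[1], "with_acc")
  # nested sets with a zero-weight extra: tie broken toward the smaller set
  mx2 <- synth_kedge_mixture(c(calcite = 0.6, acc = 0, free_ion = 0.4))
  rk2 <- compare_reference_sets(mx2$target, list(
    full = refs, minimal = refs[c("calcite", "free_ion")]))
  expect_lt(abs(diff(rk2$residual)), 1e-9)
  expect_equal(rk2$set[1], "minimal")
})
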