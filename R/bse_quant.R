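# EsB grey-level quantification: calibrate grey against eta_eff of in-image
# standards, then invert a body's grey value to Ca molarity under the
# Ca:P 1:2 electrolyte model.

#' Define a calibration standard
#'
#' An internal standard: a region of known composition measured on the same
#' stack as the body of interest (lipid bodies as CH2 hydrocarbon, the
#' seawater culture medium, external coccolith calcite).
#'
#' @param name Standard name.
#' @param material A `"material"` of known composition.
#' @param mean_grey Measured mean grey value of the standard's region.
#' @param grey_sd Grey standard deviation (0 if unknown).
#' @return An object of class `"calibration_standard"`.
#' @export
calibration_standard <- function(name, material, mean_grey, grey_sd = 0) {
  stopifnot(inherits(material, "material"), is.finite(mean_grey),
            grey_sd >= 0)
  structure(list(name = name, material = material, mean_grey = mean_grey,
                 grey_sd = grey_sd, eta_eff = eta_eff(material)),
            class = "calibration_standard")
}

#' Fit the grey-level vs backscatter-coefficient calibration line
#'
#' Least-squares line `grey = slope * eta_eff + intercept` through the
#' internal standards; with exactly two standards the fit is exact. The
#' backscatter coefficients are computed from each standard's composition by
#' the mixture rule ([eta_eff()]).
#'
#' @param standards List of [calibration_standard()] objects (>= 2, with
#'   distinct eta_eff).
#' @return An object of class `"bse_calibration"` with components `slope`,
#'   `intercept`, `residual_norm`, `standards` (data.frame) and the
#'   underlying `lm` fit. Supports `coef()`, `predict()` (eta -> grey) and
#'   `print()`.
#' @export
fit_calibration <- function(standards) {
  stopifnot(is.list(standards), length(standards) >= 2,
            all(vapply(standards, inherits, logical(1),
                       "calibration_standard")))
  df <- data.frame(
    name = vapply(standards, `[[`, character(1), "name"),
    eta = vapply(standards, `[[`, numeric(1), "eta_eff"),
    grey = vapply(standards, `[[`, numeric(1), "mean_grey"),
    grey_sd = vapply(standards, `[[`, numeric(1), "grey_sd")
  )
  if (diff(range(df$eta)) < 1e-12) {
    stop("degenerate calibration: standards have indistinguishable eta_eff")
  }
  fit <- stats::lm(grey ~ eta, data = df)
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         residual_norm = sqrt(sum(stats::residuals(fit)^2)),
         standards = df, fit = fit),
    class = "bse_calibration"
  )
}

#' @export
print.bse_calibration <- function(x, ...) {
  cat("<bse_calibration> grey =", format(x$slope, digits = 6), "* eta +",
      format(x$intercept, digits = 6), "\n")
  cat("  standards:", paste(x$standards$name, collapse = ", "),
      " residual norm:", format(x$residual_norm, digits = 4), "\n")
  invisible(x)
}

#' @export
coef.bse_calibration <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.bse_calibration <- function(object, eta, ...) {
  object$slope * eta + object$intercept
}

#' Invert a grey value to a backscatter coefficient
#'
#' @param grey Grey value(s).
#' @param calibration A `"bse_calibration"`.
#' @return eta_eff value(s).
#' @export
grey_to_eta <- function(grey, calibration) {
  stopifnot(inherits(calibration, "bse_calibration"))
  (grey - calibration$intercept) / calibration$slope
}

#' Convert a backscatter coefficient to Ca molarity
#'
#' Solves for the Ca mass fraction whose Ca:P electrolyte reproduces the
#' given eta_eff (bisection on the mass fraction; eta_eff is strictly
#' increasing in concentration), then converts to mol/L by the density
#' mixing rule. Below the pure-water eta the estimate is clamped to 0 M with
#' a warning; above the most concentrated consistent solution it is an
#' error.
#'
#' @param eta Effective backscatter coefficient.
#' @param model An [electrolyte_model()].
#' @param label Region label for the returned estimate.
#' @param eta_sd Optional dispersion of eta; propagated to molarity by the
#'   first-order delta method on the numerically differentiated inverse map.
#' @param tol Bisection tolerance on the mass fraction.
#' @return An object of class `"ca_estimate"` with `ca_molarity` (mol/L),
#'   `dispersion`, `method = "bse"` and the solved mass fraction.
#' @export
eta_to_ca_molarity <- function(eta, model = electrolyte_model(),
                               label = "body", eta_sd = NULL, tol = 1e-9) {
  eta_w <- eta_eff(build_electrolyte(0, model))
  c_max <- ca_mass_fraction_limit(model)
  eta_max <- eta_eff(build_electrolyte(c_max, model))
  if (eta > eta_max) {
    stop("eta ", format(eta, digits = 5),
         " exceeds the most concentrated consistent electrolyte (eta ",
         format(eta_max, digits = 5), ")")
  }
  if (eta < eta_w) {
    warning("eta below pure-water value; reporting 0 M")
    cfrac <- 0
  } else {
    lo <- 0; hi <- c_max
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (eta_eff(build_electrolyte(mid, model)) < eta) lo <- mid else hi <- mid
    }
    cfrac <- (lo + hi) / 2
  }
  mol <- as.numeric(electrolyte_molarity(cfrac, model))
  disp <- NA_real_
  if (!is.null(eta_sd) && eta_sd > 0) {
    # delta method: dM/deta by central difference on the inverse map
    h <- max(1e-6, eta_sd / 10)
    lo_eta <- max(eta_w, eta - h)
    hi_eta <- min(eta_max, eta + h)
    m_lo <- as.numeric(electrolyte_molarity(
      .eta_to_cfrac(lo_eta, model, tol), model))
    m_hi <- as.numeric(electrolyte_molarity(
      .eta_to_cfrac(hi_eta, model, tol), model))
    disp <- abs((m_hi - m_lo) / (hi_eta - lo_eta)) * eta_sd
  }
  structure(list(label = label, ca_molarity = mol, dispersion = disp,
                 method = "bse", ca_mass_fraction = cfrac),
            class = "ca_estimate")
}

.eta_to_cfrac <- function(eta, model, tol = 1e-9) {
  eta_w <- eta_eff(build_electrolyte(0, model))
  if (eta <= eta_w) return(0)
  lo <- 0; hi <- ca_mass_fraction_limit(model)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (eta_eff(build_electrolyte(mid, model)) < eta) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' @export
print.ca_estimate <- function(x, ...) {
  cat(sprintf("<ca_estimate> %s: %.3g M Ca (%s)", x$label, x$ca_molarity,
              x$method))
  if (!is.na(x$dispersion)) cat(sprintf(" +/- %.2g M", x$dispersion))
  cat("\n")
  invisible(x)
}

#' Quantify a Ca-rich body from an EsB stack
#'
#' The full FIB-SEM chain: measure the mean grey of each in-image standard
#' and of the body ([region_stats()]), fit the calibration line
#' ([fit_calibration()]), invert the body grey to eta ([grey_to_eta()]) and
#' to molarity ([eta_to_ca_molarity()]). Grey dispersion of the body is
#' propagated through the local slope of the inverse map.
#'
#' @param stack EsB-modality `"image_stack"`.
#' @param body_mask Logical array congruent with the stack.
#' @param standards Named list of `"material"` objects, one per standard.
#' @param standard_masks Named list of logical arrays, same names.
#' @param model An [electrolyte_model()].
#' @param label Label for the estimate.
#' @return A `"ca_estimate"`; the fitted calibration and the per-standard
#'   (grey, eta) table are attached as attributes `"calibration"`.
#' @export
quantify_body <- function(stack, body_mask, standards, standard_masks,
                          model = electrolyte_model(), label = "body") {
  stopifnot(inherits(stack, "image_stack"))
  if (stack$modality != "bse-esb") {
    stop("grey-level quantification requires the EsB channel (modality 'bse-esb')")
  }
  stopifnot(identical(sort(names(standards)), sort(names(standard_masks))))
  std <- lapply(names(standards), function(nm) {
    rs <- region_stats(stack, standard_masks[[nm]])
    calibration_standard(nm, standards[[nm]], rs$mean, rs$sd)
  })
  cal <- fit_calibration(std)
  bs <- region_stats(stack, body_mask)
  eta <- grey_to_eta(bs$mean, cal)
  eta_sd <- bs$sd / abs(cal$slope)
  est <- eta_to_ca_molarity(eta, model, label = label, eta_sd = eta_sd)
  attr(est, "calibration") <- cal
  attr(est, "body_grey") <- bs
  est
}
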