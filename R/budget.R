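# Cellular Ca-budget arithmetic: 1 um^3 at 1 mol/L holds exactly 1 fmol.

#' Amount of calcium in a compartment
#'
#' `amount = volume * molarity` with the exact unit identity
#' 1 um^3 x 1 mol/L = 1 fmol (1 um^3 = 1e-15 L).
#'
#' @param volume_um3 Compartment volume (um^3), >= 0.
#' @param molarity_M Ca concentration (mol/L), >= 0.
#' @return Amount in fmol.
#' @export
#' @examples
#' ca_amount(1.5, 10)  # 15 fmol
ca_amount <- function(volume_um3, molarity_M) {
  if (any(volume_um3 < 0) || any(molarity_M < 0)) {
    stop("volume and molarity must be non-negative")
  }
  volume_um3 * molarity_M
}

#' Fraction of one coccolith's calcium demand
#'
#' An average coccolith requires about 22.5 fmol of Ca2+ to be transferred
#' into the coccolith vesicle; this reports a stored amount as a fraction
#' of that demand.
#'
#' @param amount_fmol Stored Ca (fmol), >= 0.
#' @param per_coccolith_fmol Ca demand per coccolith (fmol), > 0.
#' @return Dimensionless fraction.
#' @export
#' @examples
#' fraction_of_coccolith(15)  # ~2/3
fraction_of_coccolith <- function(amount_fmol, per_coccolith_fmol = 22.5) {
  if (per_coccolith_fmol <= 0) stop("per-coccolith demand must be positive")
  if (any(amount_fmol < 0)) stop("amount must be non-negative")
  amount_fmol / per_coccolith_fmol
}

#' Calcium budget of a compartment
#'
#' Convenience wrapper combining [ca_amount()] and
#' [fraction_of_coccolith()].
#'
#' @param volume_um3 Compartment volume (um^3).
#' @param molarity_M Ca concentration (mol/L).
#' @param per_coccolith_fmol Ca demand per coccolith (fmol).
#' @return An object of class `"ca_budget"` with fields `volume_um3`,
#'   `molarity_M`, `amount_fmol`, `per_coccolith_fmol`,
#'   `fraction_of_coccolith`.
#' @export
ca_budget <- function(volume_um3, molarity_M, per_coccolith_fmol = 22.5) {
  amount <- ca_amount(volume_um3, molarity_M)
  structure(
    list(volume_um3 = volume_um3, molarity_M = molarity_M,
         amount_fmol = amount, per_coccolith_fmol = per_coccolith_fmol,
         fraction_of_coccolith = fraction_of_coccolith(amount,
                                                       per_coccolith_fmol)),
    class = "ca_budget"
  )
}

#' @export
print.ca_budget <- function(x, ...) {
  cat(sprintf("<ca_budget> %.3g um^3 at %.3g M -> %.3g fmol Ca (%.1f%% of a %.3g fmol coccolith)\n",
              x$volume_um3, x$molarity_M, x$amount_fmol,
              100 * x$fraction_of_coccolith, x$per_coccolith_fmol))
  invisible(x)
}
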