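# Soft X-ray Ca L-edge quantification: difference maps across the edge,
# region spectra, mask chord lengths, and concentration from areal
# absorbance against the 27 M calcite internal standard.

#' XAS spectrum container
#'
#' A 1-D absorption spectrum: strictly increasing energies with one
#' intensity per energy and a preprocessing state flag.
#'
#' @param energies_eV Strictly increasing photon energies (eV).
#' @param intensity Intensities (or optical densities), same length.
#' @param state One of `"raw"`, `"averaged"`, `"normalized"`.
#' @param E0 Edge energy (eV) when determined.
#' @return An object of class `"xas_spectrum"`.
#' @export
xas_spectrum <- function(energies_eV, intensity,
                         state = c("raw", "averaged", "normalized"),
                         E0 = NULL) {
  state <- match.arg(state)
  stopifnot(length(energies_eV) == length(intensity),
            length(energies_eV) >= 2)
  if (any(diff(energies_eV) <= 0)) {
    stop("energies must be strictly increasing")
  }
  structure(list(energies_eV = as.numeric(energies_eV),
                 intensity = as.numeric(intensity),
                 state = state, E0 = E0),
            class = "xas_spectrum")
}

#' @export
print.xas_spectrum <- function(x, ...) {
  cat(sprintf("<xas_spectrum> %d points, %.4g..%.4g eV, state=%s",
              length(x$energies_eV), min(x$energies_eV), max(x$energies_eV),
              x$state))
  if (!is.null(x$E0)) cat(sprintf(", E0=%.4g eV", x$E0))
  cat("\n")
  invisible(x)
}

#' @export
plot.xas_spectrum <- function(x, ...) {
  graphics::plot(x$energies_eV, x$intensity, type = "l",
                 xlab = "energy (eV)", ylab = "intensity", ...)
}

.nearest_frame <- function(estack, energy_eV, tol = 0.5) {
  d <- abs(estack$energies_eV - energy_eV)
  i <- which.min(d)
  if (d[i] > tol) {
    stop("no frame within ", tol, " eV of ", energy_eV, " eV (closest: ",
         estack$energies_eV[i], " eV)")
  }
  i
}

.od_frame <- function(estack, i) {
  I <- estack$frames$voxels[i, , ]
  if (is.null(estack$flat_field)) {
    stop("energy stack has no flat field; cannot form optical density")
  }
  to_optical_density(I, estack$flat_field)
}

#' Align an energy scan by translation
#'
#' Registers all frames of an energy stack to a reference frame (default:
#' the middle frame) by phase correlation; see [align_translation()].
#'
#' @param estack An `"energy_stack"`.
#' @param ... Passed to [align_translation()].
#' @return The aligned `"energy_stack"`; the applied shifts are attached as
#'   attribute `"shifts"`.
#' @export
align_energy_stack <- function(estack, ...) {
  stopifnot(inherits(estack, "energy_stack"))
  res <- align_translation(estack$frames, ...)
  estack$frames <- res$aligned
  attr(estack, "shifts") <- res$shifts
  estack
}

#' Ca L-edge difference map
#'
#' Localizes calcium by subtracting the optical density of a frame below
#' the Ca L2,3-edge (default 342 eV, where Ca is virtually transparent)
#' from one at the peak of the second white line (default 353.2 eV). The
#' on-edge frame is registered to the below-edge frame by phase correlation
#' before subtraction; contrast in the result is dominated by Ca-bearing
#' pixels.
#'
#' @param estack An `"energy_stack"` with a flat field.
#' @param e_below,e_edge Energies (eV) of the below-edge and on-edge frames.
#' @param energy_tol Nearest-frame tolerance (eV).
#' @param align Register the on-edge frame before subtracting.
#' @return An object of class `"difference_map"`: `pixels` (delta-OD
#'   matrix), the energies used and the alignment shift applied.
#' @export
ca_difference_map <- function(estack, e_below = 342, e_edge = 353.2,
                              energy_tol = 0.5, align = TRUE) {
  stopifnot(inherits(estack, "energy_stack"))
  if (e_below >= e_edge) stop("e_below must be less than e_edge")
  ib <- .nearest_frame(estack, e_below, energy_tol)
  ie <- .nearest_frame(estack, e_edge, energy_tol)
  od_b <- .od_frame(estack, ib)
  od_e <- .od_frame(estack, ie)
  shift <- c(0L, 0L)
  if (align) {
    shift <- .phase_corr_shift(od_b, od_e)
    od_e <- .roll2(od_e, shift)
  }
  structure(list(pixels = od_e - od_b,
                 e_below = estack$energies_eV[ib],
                 e_edge = estack$energies_eV[ie],
                 shift = shift),
            class = "difference_map")
}

#' Extract a region-averaged spectrum from an energy stack
#'
#' Averages the pixels of a (2-D) region mask in every frame of an aligned
#' energy scan and returns the series as a spectrum: the averaged intensity
#' of the area as a function of the photon energy.
#'
#' @param estack An `"energy_stack"` (already aligned).
#' @param mask Logical matrix congruent with the frames; must select at
#'   least one pixel.
#' @param as_od Convert to optical density against the flat field (default);
#'   otherwise raw mean intensity.
#' @return An `"xas_spectrum"` (state `"raw"`).
#' @export
extract_region_spectrum <- function(estack, mask, as_od = TRUE) {
  stopifnot(inherits(estack, "energy_stack"), is.logical(mask))
  d <- dim(estack$frames$voxels)
  stopifnot(all(dim(mask) == d[2:3]))
  if (!any(mask)) stop("region mask selects no pixels")
  vals <- vapply(seq_len(d[1]), function(i) {
    f <- if (as_od) .od_frame(estack, i) else estack$frames$voxels[i, , ]
    mean(f[mask], na.rm = TRUE)
  }, numeric(1))
  xas_spectrum(estack$energies_eV, vals)
}

#' Per-pixel chord length of a 3-D mask
#'
#' Counts the `TRUE` voxels of a 3-D mask along the viewing axis and scales
#' by the voxel size: the length of the Ca-rich volume along the beam at
#' each pixel of the projection.
#'
#' @param volume_mask Logical 3-D array.
#' @param axis Projection axis (1, 2 or 3, in (slice, row, col) order).
#' @param voxel_size_nm Voxel edge length along `axis` (nm).
#' @return Matrix of chord lengths (nm) over the remaining two axes, with
#'   attributes `axis` and `voxel_size_nm`.
#' @export
path_length_map <- function(volume_mask, axis = 1, voxel_size_nm = 1) {
  stopifnot(is.logical(volume_mask), length(dim(volume_mask)) == 3,
            axis %in% 1:3, voxel_size_nm > 0)
  counts <- apply(volume_mask, setdiff(1:3, axis), sum)
  structure(counts * voxel_size_nm, axis = axis,
            voxel_size_nm = voxel_size_nm)
}

#' Concentration from areal absorbance with an internal standard
#'
#' The Ca-edge absorbance is proportional to the Ca content in the beam
#' path, so with a region mean delta-OD and a mean chord length L the
#' concentration follows from the calcite internal standard (27 M Ca):
#' `c = c_cal * (dOD / L) / (dOD_cal / L_cal)`.
#'
#' @param dod_region Mean delta-OD of the region of interest.
#' @param L_region Mean chord length of the region (nm).
#' @param dod_cal Mean delta-OD of the calibration (calcite) region.
#' @param L_cal Mean chord length of the calibration region (nm).
#' @param c_cal Calibration concentration (mol/L); 27 M for calcite.
#' @param label Region label.
#' @param dispersion Optional dispersion (mol/L) to attach, e.g. the s.d.
#'   across several calibration regions.
#' @return A `"ca_estimate"` with `method = "xray"`.
#' @export
estimate_concentration <- function(dod_region, L_region, dod_cal, L_cal,
                                   c_cal = 27, label = "body",
                                   dispersion = NA_real_) {
  if (L_region <= 0 || L_cal <= 0) stop("path lengths must be positive")
  if (dod_cal <= 0 || c_cal <= 0) {
    stop("calibration absorbance and concentration must be positive")
  }
  conc <- c_cal * (dod_region / L_region) / (dod_cal / L_cal)
  structure(list(label = label, ca_molarity = conc, dispersion = dispersion,
                 method = "xray", c_cal = c_cal),
            class = "ca_estimate")
}

#' Full soft X-ray quantification chain for one body
#'
#' Composes [ca_difference_map()], [path_length_map()] and
#' [estimate_concentration()]: region-mean areal absorbance of the body and
#' of the calcite internal standard, each divided by the corresponding mean
#' chord length from the 3-D masks at the chosen orientation.
#'
#' Pixels whose beam path crosses both regions are excluded from both
#' footprints, so each areal absorbance is attributed to a single region.
#' Scans with more than two frames are first aligned sequentially
#' (running reference, see [align_translation()]); a bare two-frame stack
#' falls back to pairwise registration inside [ca_difference_map()].
#'
#' @param estack An `"energy_stack"` with flat field.
#' @param body_mask,cal_mask Logical 3-D masks of the body and the calcite
#'   calibration region (same geometry as the rendered volume).
#' @param axis Viewing axis used for both the projection and the chords.
#' @param voxel_size_nm Voxel size along `axis` (nm).
#' @param c_cal Calibration molarity (27 M calcite).
#' @param align Register the frames before differencing.
#' @param ... Passed to [ca_difference_map()].
#' @return A `"ca_estimate"` with the difference map attached as attribute.
#' @export
xray_quantify_body <- function(estack, body_mask, cal_mask, axis = 1,
                               voxel_size_nm, c_cal = 27, align = TRUE,
                               ...) {
  if (align && dim(estack$frames$voxels)[1] > 2) {
    estack <- align_energy_stack(estack, reference = "previous")
    dm <- ca_difference_map(estack, align = FALSE, ...)
  } else {
    dm <- ca_difference_map(estack, align = align, ...)
  }
  pl_body <- path_length_map(body_mask, axis, voxel_size_nm)
  pl_cal <- path_length_map(cal_mask, axis, voxel_size_nm)
  fp_body <- pl_body > 0 & pl_cal == 0
  fp_cal <- pl_cal > 0 & pl_body == 0
  if (!any(fp_body) || !any(fp_cal)) stop("empty projection footprint")
  est <- estimate_concentration(
    mean(dm$pixels[fp_body], na.rm = TRUE), mean(pl_body[fp_body]),
    mean(dm$pixels[fp_cal], na.rm = TRUE), mean(pl_cal[fp_cal]),
    c_cal = c_cal
  )
  attr(est, "difference_map") <- dm
  est
}

#' Peak prominence at a given energy
#'
#' Height of the local maximum inside `at_energy +/- peak_halfwidth` above
#' the straight baseline interpolated between the flanking windows; used to
#' test for the calcite crystal-field peaks.
#'
#' @param spectrum An `"xas_spectrum"`.
#' @param at_energy Peak position to probe (eV).
#' @param peak_halfwidth Half-width of the peak window (eV).
#' @param baseline_halfwidth Outer half-width of the flanking baseline
#'   windows (eV).
#' @return Prominence in the spectrum's intensity units.
#' @export
peak_prominence <- function(spectrum, at_energy, peak_halfwidth = 0.4,
                            baseline_halfwidth = 1.0) {
  stopifnot(inherits(spectrum, "xas_spectrum"),
            baseline_halfwidth > peak_halfwidth)
  e <- spectrum$energies_eV
  y <- spectrum$intensity
  inside <- abs(e - at_energy) <= peak_halfwidth
  left <- e < at_energy - peak_halfwidth &
    e >= at_energy - baseline_halfwidth
  right <- e > at_energy + peak_halfwidth &
    e <= at_energy + baseline_halfwidth
  if (!any(inside) || !any(left) || !any(right)) {
    stop("spectrum does not cover the peak/baseline windows at ",
         at_energy, " eV")
  }
  bl <- stats::approx(x = c(mean(e[left]), mean(e[right])),
                      y = c(mean(y[left]), mean(y[right])),
                      xout = e[inside])$y
  max(y[inside] - bl)
}

#' Test for calcite crystal-field peaks
#'
#' Crystalline calcite shows small crystal-field peaks at 347.9 and
#' 351.3 eV that amorphous Ca phases lack. A peak counts as significant
#' when its prominence exceeds `threshold_frac` of the spectrum's overall
#' intensity range.
#'
#' @param spectrum An `"xas_spectrum"` across the Ca L-edge.
#' @param energies Peak positions (eV).
#' @param threshold_frac Significance threshold as a fraction of the
#'   intensity range.
#' @param ... Passed to [peak_prominence()].
#' @return List with `significant` (logical), per-peak `prominence` and the
#'   `threshold` used.
#' @export
crystal_field_peaks <- function(spectrum, energies = c(347.9, 351.3),
                                threshold_frac = 0.05, ...) {
  rng <- diff(range(spectrum$intensity))
  prom <- vapply(energies, function(e0)
    peak_prominence(spectrum, e0, ...), numeric(1))
  names(prom) <- format(energies)
  list(significant = all(prom > threshold_frac * rng),
       prominence = prom, threshold = threshold_frac * rng)
}

#' Compare two energy scans (radiation-damage check)
#'
#' Repeating an energy scan and comparing the extracted spectra checks that
#' irradiation did not alter the Ca local structure. Reports the maximum
#' absolute intensity difference on the common energy grid.
#'
#' @param scan1,scan2 `"xas_spectrum"` objects.
#' @param tol Tolerance on the maximum absolute difference.
#' @return List with `max_abs_diff` and `within_tol`.
#' @export
compare_scans <- function(scan1, scan2, tol = 0.05) {
  stopifnot(inherits(scan1, "xas_spectrum"), inherits(scan2, "xas_spectrum"))
  lo <- max(min(scan1$energies_eV), min(scan2$energies_eV))
  hi <- min(max(scan1$energies_eV), max(scan2$energies_eV))
  if (hi <= lo) stop("scans share no energy range")
  grid <- scan1$energies_eV[scan1$energies_eV >= lo & scan1$energies_eV <= hi]
  y1 <- stats::approx(scan1$energies_eV, scan1$intensity, grid)$y
  y2 <- stats::approx(scan2$energies_eV, scan2$intensity, grid)$y
  d <- max(abs(y1 - y2))
  list(max_abs_diff = d, within_tol = d <= tol)
}
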