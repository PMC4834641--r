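# Synthetic phantom generator: labelled 3-D cells with known materials and
# molarities, plus forward renderers for the EsB/in-lens FIB-SEM channels
# and for Beer-Lambert X-ray energy stacks, and Ca K-edge mixture spectra.
# Every render is deterministic under a fixed seed, so each analysis stage
# can be verified by closed-loop parameter recovery.

# Run `expr` with a seed without disturbing the caller's RNG stream.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Phantom configuration
#'
#' Geometry, composition and noise settings of the synthetic cell. The
#' defaults emulate the study conditions: a ~2.4 um coccolithophore cell
#' with nucleus, chloroplast, lipid bodies and an intracellular calcite
#' coccolith, a Ca-P body of 1.5 um^3 at 10 M Ca, and an optional dilute
#' cloud at 1.5 M.
#'
#' @param grid_dim Volume dimensions (slice, row, col) in voxels.
#' @param voxel_size_nm Isotropic voxel size (nm).
#' @param cell_semi_axes_nm Ellipsoid semi-axes of the cell (nm).
#' @param body_volume_um3 Volume of the Ca-rich body (um^3); the body is the
#'   set of voxels nearest its centre whose total volume matches this to
#'   within one voxel.
#' @param body_molarity_M Ca molarity of the body (mol/L).
#' @param cloud_molarity_M Ca molarity of the dilute cloud around the body;
#'   0 disables the cloud.
#' @param cloud_thickness_nm Shell thickness of the cloud (nm).
#' @param include_cloud Plant the dilute cloud shell.
#' @param seed Seed for any randomized placement (the default layout is
#'   deterministic).
#' @return A list of class `"phantom_config"`.
#' @export
phantom_config <- function(grid_dim = c(64, 64, 64), voxel_size_nm = 40,
                           cell_semi_axes_nm = c(1150, 1200, 1200),
                           body_volume_um3 = 1.5, body_molarity_M = 10,
                           cloud_molarity_M = 1.5, cloud_thickness_nm = 160,
                           include_cloud = FALSE, seed = 42) {
  stopifnot(all(grid_dim >= 8), voxel_size_nm > 0,
            all(cell_semi_axes_nm > 0), body_volume_um3 > 0,
            body_molarity_M >= 0, cloud_molarity_M >= 0)
  structure(list(grid_dim = grid_dim, voxel_size_nm = voxel_size_nm,
                 cell_semi_axes_nm = cell_semi_axes_nm,
                 body_volume_um3 = body_volume_um3,
                 body_molarity_M = body_molarity_M,
                 cloud_molarity_M = cloud_molarity_M,
                 cloud_thickness_nm = cloud_thickness_nm,
                 include_cloud = include_cloud, seed = seed),
            class = "phantom_config")
}

#' Default material inventory of the phantom
#'
#' Medium (artificial seawater with 10 mM CaCl2, from the shipped YAML
#' fixture), cytoplasm (dilute organic solution), nucleus and chloroplast
#' (denser organic solutions), lipid (CH2 linear hydrocarbon), coccolith
#' (pure calcite, 2.71 g/cm^3).
#'
#' @return Named list of `"material"` objects.
#' @export
phantom_materials <- function() {
  med_path <- system.file("extdata", "seawater_medium.yaml",
                          package = "calciq")
  med <- yaml::read_yaml(med_path)
  organic <- function(name, organic_frac) {
    # organic_frac of CH1.8O0.4N0.1 protein-like matter, rest water
    counts <- c(C = 1, H = 1.8, O = 0.4, N = 0.1)
    masses <- counts * .element_row(names(counts))$atomic_mass
    om <- organic_frac * masses / sum(masses)
    w <- 1 - organic_frac
    fr <- c(om, H = w * 2.016 / 18.015, O = w * 15.999 / 18.015)
    fr <- tapply(fr, names(fr), sum)
    material(name, fr / sum(fr))
  }
  list(
    medium = material(med$name, unlist(med$mass_fractions),
                      density = med$density),
    cytoplasm = organic("cytoplasm", 0.15),
    nucleus = organic("nucleus", 0.25),
    chloroplast = organic("chloroplast", 0.22),
    lipid = material_from_formula("lipid", "CH2", density = 0.86),
    coccolith = material_from_formula("coccolith_calcite", "CaCO3",
                                      density = 2.71)
  )
}

# Voxel-centre coordinates (nm) along each axis, origin at the volume centre.
.axis_coords <- function(n, voxel) (seq_len(n) - (n + 1) / 2) * voxel

.ellipsoid_mask <- function(dims, voxel, center_nm, semi_nm) {
  x <- .axis_coords(dims[1], voxel) - center_nm[1]
  y <- .axis_coords(dims[2], voxel) - center_nm[2]
  z <- .axis_coords(dims[3], voxel) - center_nm[3]
  q <- outer(outer((x / semi_nm[1])^2, (y / semi_nm[2])^2, `+`),
             (z / semi_nm[3])^2, `+`)
  q <= 1
}

.dist2_from <- function(dims, voxel, center_nm) {
  x <- .axis_coords(dims[1], voxel) - center_nm[1]
  y <- .axis_coords(dims[2], voxel) - center_nm[2]
  z <- .axis_coords(dims[3], voxel) - center_nm[3]
  outer(outer(x^2, y^2, `+`), z^2, `+`)
}

#' Generate the labelled cell phantom
#'
#' Builds the label volume and its ground truth: per-label materials and,
#' for the Ca-bearing labels, molarities. The Ca-P body's composition is the
#' Ca:P 1:2 electrolyte at the configured molarity (mass fraction obtained
#' by numerical inversion); the body occupies exactly the configured volume
#' to within one voxel. Deterministic for a fixed config.
#'
#' @param config A [phantom_config()].
#' @param electrolyte An [electrolyte_model()] for the body and cloud.
#' @return A list of class `"phantom"`: `labels` (integer 3-D array),
#'   `label_names`, `materials` (per label), `molarity_M` (per Ca label),
#'   `voxel_size_nm`, `config`.
#' @export
make_cell_phantom <- function(config = phantom_config(),
                              electrolyte = electrolyte_model()) {
  stopifnot(inherits(config, "phantom_config"))
  d <- config$grid_dim
  vox <- config$voxel_size_nm
  mats <- phantom_materials()
  ext <- d * vox

  labels <- array(1L, d)  # 1 = medium everywhere
  cell <- .ellipsoid_mask(d, vox, c(0, 0, 0), config$cell_semi_axes_nm)
  labels[cell] <- 2L      # cytoplasm

  place <- list(
    nucleus = list(center = c(0.45, 0.35, -0.45) * config$cell_semi_axes_nm,
                   semi = c(350, 350, 350)),
    chloroplast = list(center = c(0.45, -0.50, -0.45) * config$cell_semi_axes_nm,
                       semi = c(300, 350, 280)),
    lipid = list(center = c(-0.45, 0.45, 0.35) * config$cell_semi_axes_nm,
                 semi = c(200, 200, 200))
  )
  organelles <- list()
  for (nm in names(place)) {
    m <- .ellipsoid_mask(d, vox, place[[nm]]$center, place[[nm]]$semi) & cell
    organelles[[nm]] <- m
  }
  # coccolith: calcite annulus (forming coccolith) in the upper cell half
  cocc_center <- c(0.10, 0.55, 0.55) * config$cell_semi_axes_nm
  outer_m <- .ellipsoid_mask(d, vox, cocc_center, c(160, 380, 380))
  inner_m <- .ellipsoid_mask(d, vox, cocc_center, c(170, 230, 230))
  organelles$coccolith <- outer_m & !inner_m & cell
  # Ca-P body: exactly body_volume_um3 of voxels nearest its centre
  body_center <- c(-0.25, -0.30, 0.25) * config$cell_semi_axes_nm
  n_body <- round(config$body_volume_um3 * 1e9 / vox^3)
  d2 <- .dist2_from(d, vox, body_center)
  d2[!cell] <- Inf
  thr <- sort(d2[is.finite(d2)])[n_body]
  body <- d2 <= thr
  if (sum(body) > n_body) {  # ties at the boundary: trim deterministically
    extra <- which(body & d2 == thr)
    body[extra[seq_len(sum(body) - n_body)]] <- FALSE
  }
  organelles$body <- body

  mandatory <- c("nucleus", "chloroplast", "lipid", "coccolith", "body")
  for (i in seq_along(mandatory)) {
    for (j in seq_len(i - 1)) {
      if (any(organelles[[mandatory[i]]] & organelles[[mandatory[j]]])) {
        stop("phantom config error: organelles '", mandatory[j], "' and '",
             mandatory[i], "' overlap")
      }
    }
  }

  label_names <- c("medium", "cytoplasm", "nucleus", "chloroplast",
                   "lipid", "coccolith", "body")
  codes <- stats::setNames(seq_along(label_names), label_names)
  for (nm in mandatory) labels[organelles[[nm]]] <- codes[[nm]]

  calcite_M <- as.numeric(molarity_of_solution(
    c(CaCO3 = 1), c(CaCO3 = mats$coccolith$density), "CaCO3", "Ca"))
  molarity <- c(body = config$body_molarity_M, coccolith = calcite_M)
  if (config$include_cloud && config$cloud_molarity_M > 0) {
    r_body <- sqrt(thr)
    shell <- d2 > thr & d2 <= (r_body + config$cloud_thickness_nm)^2
    shell <- shell & labels == 2L  # only displaces cytoplasm
    label_names <- c(label_names, "cloud")
    codes["cloud"] <- length(label_names)
    labels[shell] <- codes[["cloud"]]
    molarity["cloud"] <- config$cloud_molarity_M
  }

  body_mat <- if (config$body_molarity_M > 0) {
    build_electrolyte(
      ca_fraction_for_molarity(config$body_molarity_M, electrolyte),
      electrolyte)
  } else {
    material_from_formula("water", "H2O", density = 0.9982)
  }
  materials <- list(
    medium = mats$medium, cytoplasm = mats$cytoplasm,
    nucleus = mats$nucleus, chloroplast = mats$chloroplast,
    lipid = mats$lipid, coccolith = mats$coccolith, body = body_mat
  )
  if ("cloud" %in% label_names) {
    materials$cloud <- if (config$cloud_molarity_M > 0) {
      build_electrolyte(
        ca_fraction_for_molarity(config$cloud_molarity_M, electrolyte),
        electrolyte)
    } else {
      material_from_formula("water", "H2O", density = 0.9982)
    }
  }
  structure(list(labels = labels, label_names = label_names,
                 materials = materials, molarity_M = molarity,
                 voxel_size_nm = vox, extent_nm = ext, config = config,
                 electrolyte = electrolyte),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<phantom> %dx%dx%d voxels @ %g nm\n", d[1], d[2], d[3],
              x$voxel_size_nm))
  tab <- table(factor(x$labels, seq_along(x$label_names), x$label_names))
  for (nm in names(tab)) {
    cat(sprintf("  %-12s %8d voxels (%.3g um^3)\n", nm, tab[[nm]],
                tab[[nm]] * x$voxel_size_nm^3 / 1e9))
  }
  invisible(x)
}

#' Mask of one phantom label
#'
#' @param phantom A `"phantom"`.
#' @param label Label name (e.g. `"body"`, `"coccolith"`).
#' @return Logical 3-D array.
#' @export
phantom_mask <- function(phantom, label) {
  i <- match(label, phantom$label_names)
  if (is.na(i)) stop("unknown phantom label: ", label)
  phantom$labels == i
}

#' Render the FIB-SEM channels of a phantom
#'
#' The EsB channel is affine in the effective backscatter coefficient:
#' `grey = gain * eta_eff(material) + offset + N(0, noise_sd)` per voxel.
#' The in-lens channel renders label boundaries as thin dark lines on a
#' bright cytosol (qualitative only).
#'
#' @param phantom A `"phantom"`.
#' @param gain,offset Affine detector response (grey per unit eta, grey
#'   offset).
#' @param noise_sd Gaussian grey noise s.d. (same units as grey).
#' @param seed RNG seed for the noise.
#' @return List with `esb` and `inlens` (`"image_stack"` objects, 5 nm-class
#'   geometry taken from the phantom voxel size).
#' @export
render_bse <- function(phantom, gain = 200, offset = 10, noise_sd = 0,
                       seed = NULL) {
  stopifnot(inherits(phantom, "phantom"), gain != 0)
  etas <- vapply(phantom$materials, eta_eff, numeric(1))
  grey_lut <- gain * etas[phantom$label_names] + offset
  v <- array(grey_lut[phantom$labels], dim(phantom$labels))
  if (noise_sd > 0) {
    v <- .with_seed(seed, v + stats::rnorm(length(v), sd = noise_sd))
  }
  esb <- image_stack(v, phantom$voxel_size_nm, phantom$voxel_size_nm,
                     modality = "bse-esb")
  # in-lens: bright interior, dark membrane outlines (boundary voxels)
  lab <- phantom$labels
  d <- dim(lab)
  boundary <- array(FALSE, d)
  boundary[-1, , ] <- boundary[-1, , ] | (lab[-1, , ] != lab[-d[1], , ])
  boundary[, -1, ] <- boundary[, -1, ] | (lab[, -1, ] != lab[, -d[2], ])
  boundary[, , -1] <- boundary[, , -1] | (lab[, , -1] != lab[, , -d[3]])
  il <- array(0.8, d)
  il[lab == 1L] <- 0.6
  il[boundary] <- 0.2
  if (noise_sd > 0) {
    il <- .with_seed(if (is.null(seed)) NULL else seed + 1L,
                     il + stats::rnorm(length(il), sd = noise_sd / gain))
  }
  inlens <- image_stack(il, phantom$voxel_size_nm, phantom$voxel_size_nm,
                        modality = "bse-inlens")
  list(esb = esb, inlens = inlens)
}

#' Ca L-edge linear attenuation model
#'
#' Phenomenological absorbance of a calcium phase across the L2,3-edge, per
#' nm of path and per mol/L of Ca: an arctan edge step plus Gaussian white
#' lines (L3 at 349.3 eV, second white line at 353.2 eV), with the
#' calcite crystal-field peaks (347.9 and 351.3 eV) present only for
#' crystalline phases. Valid over ~340-356 eV. Not a tabulated
#' cross-section database: the pipeline needs a self-consistent
#' forward/inverse pair, and the same linear Ca scaling holds for all
#' phases.
#'
#' @param energies_eV Energies (eV).
#' @param molarity_M Ca molarity of the phase (mol/L).
#' @param crystalline Include the crystal-field peaks.
#' @param kappa OD per (M nm) scale of the edge step.
#' @return Attenuation in OD/nm at each energy.
#' @export
ca_ledge_mu <- function(energies_eV, molarity_M, crystalline = FALSE,
                        kappa = 7e-5) {
  g <- function(e0, sd, amp) amp * exp(-(energies_eV - e0)^2 / (2 * sd^2))
  shape <- (0.5 + atan((energies_eV - 349.0) / 0.4) / pi) +
    g(349.3, 0.30, 1.5) + g(353.2, 0.35, 1.0)
  if (crystalline) shape <- shape + g(347.9, 0.25, 0.35) +
    g(351.3, 0.25, 0.35)
  kappa * molarity_M * shape
}

# Energy-independent (C/O dominated) background attenuation of a material,
# OD per nm, water-window scale: aqueous matrix ~1e-4/nm, carbon-rich
# matter much more absorbing. Cancels in across-edge difference maps.
.background_mu <- function(material) {
  fr <- material$mass_fractions
  c_frac <- if ("C" %in% names(fr)) fr[["C"]] else 0
  1e-4 + 1.5e-3 * c_frac
}

#' Render a Beer-Lambert X-ray energy stack of a phantom
#'
#' Projects the phantom along an axis at each energy:
#' `I(pixel, E) = I0 * exp(-sum_path mu(material, E) * voxel)`, with
#' `mu = ca_ledge_mu(E, molarity, crystalline) + background`. The coccolith
#' label is the only crystalline phase. Optional Gaussian (relative to I0)
#' or Poisson (photon flux) noise, and optional random integer per-frame
#' jitter to exercise the alignment step. Deterministic under a fixed seed.
#'
#' @param phantom A `"phantom"`.
#' @param energies_eV Photon energies (eV), within 340-356.
#' @param axis Projection (beam) axis, 1..3.
#' @param I0 Flat-field intensity.
#' @param noise `"none"`, `"gaussian"` or `"poisson"`.
#' @param noise_sd Gaussian noise s.d. as a fraction of I0.
#' @param flux Photons per pixel for Poisson noise.
#' @param jitter_px Maximum absolute per-frame jitter (pixels); frames are
#'   circularly shifted by uniform integer offsets.
#' @param seed RNG seed.
#' @return An `"energy_stack"` with flat field; the applied jitter shifts
#'   are attached as attribute `"true_shifts"`.
#' @export
render_xray <- function(phantom, energies_eV, axis = 1, I0 = 1,
                        noise = c("none", "gaussian", "poisson"),
                        noise_sd = 0.01, flux = 1e4, jitter_px = 0,
                        seed = NULL) {
  stopifnot(inherits(phantom, "phantom"))
  noise <- match.arg(noise)
  if (any(energies_eV < 340 | energies_eV > 356)) {
    stop("energies outside the L-edge model validity (340-356 eV)")
  }
  vox <- phantom$voxel_size_nm
  labs <- seq_along(phantom$label_names)
  counts <- lapply(labs, function(l) {
    apply(phantom$labels == l, setdiff(1:3, axis), sum)
  })
  mol <- function(nm) {
    if (nm %in% names(phantom$molarity_M)) phantom$molarity_M[[nm]] else 0
  }
  mu_tab <- vapply(labs, function(l) {
    nm <- phantom$label_names[l]
    ca_ledge_mu(energies_eV, mol(nm), crystalline = nm == "coccolith") +
      .background_mu(phantom$materials[[nm]])
  }, numeric(length(energies_eV)))
  mu_tab <- matrix(mu_tab, nrow = length(energies_eV))
  dims2 <- dim(counts[[1]])
  n_e <- length(energies_eV)
  frames <- array(0, c(n_e, dims2))
  .with_seed(seed, {
    shifts <- matrix(0L, n_e, 2)
    if (jitter_px > 0) {
      shifts <- matrix(sample(seq(-jitter_px, jitter_px),
                              2 * n_e, replace = TRUE), n_e, 2)
      shifts[1, ] <- 0L  # first frame is the drift reference
    }
    for (k in seq_len(n_e)) {
      od <- Reduce(`+`, Map(function(cnt, l) cnt * vox * mu_tab[k, l],
                            counts, labs))
      I <- I0 * exp(-od)
      if (noise == "gaussian") {
        I <- I + stats::rnorm(length(I), sd = noise_sd * I0)
      } else if (noise == "poisson") {
        I <- stats::rpois(length(I), lambda = pmax(I, 0) * flux) / flux
      }
      frames[k, , ] <- .roll2(matrix(I, dims2[1], dims2[2]), shifts[k, ])
    }
    es <- energy_stack(image_stack(frames, vox, vox, modality = "xray"),
                       energies_eV,
                       flat_field = matrix(I0, dims2[1], dims2[2]))
    attr(es, "true_shifts") <- shifts
    es
  })
}

#' Ca K-edge reference spectra (synthetic)
#'
#' Three parameterized, normalized-scale reference curves standing in for
#' the measured standards: calcite-like (sharp edge, strong white line,
#' pronounced post-edge oscillations), ACC-like (broader white line, damped
#' oscillations) and free-ion-like (10 mM CaCl2 solution: broad featureless
#' edge). Arctan edges near 4048 eV on a 0.25 eV grid.
#'
#' @param energies_eV Energy grid; default 4015-4140 eV.
#' @return Named list of `"xas_spectrum"` objects (state `"normalized"`).
#' @export
kedge_references <- function(energies_eV = seq(4015, 4140, by = 0.25)) {
  e <- energies_eV
  g <- function(e0, sd, amp) amp * exp(-(e - e0)^2 / (2 * sd^2))
  osc <- function(e0, amp, period, decay) {
    ifelse(e > e0,
           amp * sin(2 * pi * (e - e0) / period) * exp(-(e - e0) / decay), 0)
  }
  edge <- function(e0, w) 0.5 + atan((e - e0) / w) / pi
  calcite <- edge(4048.0, 1.2) + g(4051, 1.5, 0.60) + osc(4052, 0.12, 25, 60)
  acc <- edge(4047.5, 1.8) + g(4051, 2.8, 0.40) + osc(4053, 0.05, 32, 45)
  ion <- edge(4046.5, 2.4) + g(4050, 3.5, 0.30)
  list(calcite = xas_spectrum(e, calcite, state = "normalized", E0 = 4048.0),
       acc = xas_spectrum(e, acc, state = "normalized", E0 = 4047.5),
       free_ion = xas_spectrum(e, ion, state = "normalized", E0 = 4046.5))
}

#' Synthesize a Ca K-edge mixture spectrum
#'
#' Convex mixture of the three synthetic references plus optional Gaussian
#' noise; the ground-truth weights are the generator input for LCF
#' closed-loop tests.
#'
#' @param weights Numeric weights over (calcite, ACC, free ion); must be
#'   non-negative and sum to 1 within 1e-9. Named vectors are matched to
#'   the reference names.
#' @param noise_sd Gaussian noise s.d. (normalized intensity units).
#' @param seed RNG seed.
#' @param references Reference list (default [kedge_references()]).
#' @return List with `target` (`"xas_spectrum"`), `references` and
#'   `weights`.
#' @export
synth_kedge_mixture <- function(weights, noise_sd = 0, seed = NULL,
                                references = kedge_references()) {
  k <- length(references)
  stopifnot(length(weights) == k)
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
    stop("weights must be non-negative and sum to 1 (a point on the simplex)")
  }
  if (!is.null(names(weights))) {
    weights <- weights[names(references)]
  } else {
    names(weights) <- names(references)
  }
  e <- references[[1]]$energies_eV
  y <- Reduce(`+`, Map(function(w, s) w * s$intensity,
                       weights, references))
  if (noise_sd > 0) {
    y <- .with_seed(seed, y + stats::rnorm(length(y), sd = noise_sd))
  }
  list(target = xas_spectrum(e, y, state = "normalized",
                             E0 = references[[1]]$E0),
       references = references, weights = weights)
}
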