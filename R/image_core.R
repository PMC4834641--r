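# Shared conventions: stacks are numeric 3-D arrays indexed (slice, row, col),
# 0-based shifts in (row, col) order, voxel-centred coordinates. Grey values
# are held as doubles regardless of the on-disk type.

#' Construct an image stack
#'
#' @param voxels 3-D numeric array `(slice, row, col)`; a matrix is promoted
#'   to a single-slice stack.
#' @param pixel_size_nm Lateral pixel size (nm).
#' @param slice_thickness_nm Axial slice thickness (nm); defaults to the
#'   lateral pixel size.
#' @param modality One of `"bse-inlens"`, `"bse-esb"`, `"xray"`.
#' @return An object of class `"image_stack"`.
#' @export
image_stack <- function(voxels, pixel_size_nm,
                        slice_thickness_nm = pixel_size_nm,
                        modality = c("bse-esb", "bse-inlens", "xray")) {
  modality <- match.arg(modality)
  if (is.matrix(voxels)) {
    voxels <- array(voxels, dim = c(1L, dim(voxels)))
  }
  stopifnot(is.array(voxels), length(dim(voxels)) == 3,
            all(dim(voxels) >= 1), pixel_size_nm > 0, slice_thickness_nm > 0)
  if (!all(is.finite(voxels))) stop("voxel values must be finite")
  structure(
    list(voxels = voxels * 1.0, pixel_size_nm = pixel_size_nm,
         slice_thickness_nm = slice_thickness_nm, modality = modality),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack> %s  %d x %d x %d (slice,row,col)  %g nm px, %g nm slice\n",
              x$modality, d[1], d[2], d[3], x$pixel_size_nm,
              x$slice_thickness_nm))
  invisible(x)
}

#' Construct an energy-resolved stack
#'
#' @param frames An `"image_stack"` (slices are the energy frames) or 3-D
#'   array.
#' @param energies_eV One photon energy per frame, positive.
#' @param flat_field Optional flat-field reference frame (matrix).
#' @param ... Passed to [image_stack()] when `frames` is a bare array.
#' @return An object of class `"energy_stack"`.
#' @export
energy_stack <- function(frames, energies_eV, flat_field = NULL, ...) {
  if (!inherits(frames, "image_stack")) {
    frames <- image_stack(frames, ..., modality = "xray")
  }
  n <- dim(frames$voxels)[1]
  stopifnot(length(energies_eV) == n, all(energies_eV > 0))
  if (!is.null(flat_field)) {
    stopifnot(is.matrix(flat_field),
              all(dim(flat_field) == dim(frames$voxels)[2:3]))
  }
  structure(list(frames = frames, energies_eV = as.numeric(energies_eV),
                 flat_field = flat_field),
            class = "energy_stack")
}

.sidecar_path <- function(path) paste0(path, ".json")

.guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) return("tiff")
  if (ext %in% c("mrc", "rec", "st", "map")) return("mrc")
  stop("cannot guess stack format from extension: ", path)
}

#' Write an image stack to disk
#'
#' TIFF stacks go through the `tiff` package (32-bit float pages, affinely
#' rescaled to \[0,1\] with the transform recorded in the JSON sidecar); MRC
#' stacks are written as MRC2014 mode-2 (float32) with voxel size in the
#' header, a bit-exact round trip. Physical metadata is always echoed into
#' `<path>.json`.
#'
#' @param stack An `"image_stack"`.
#' @param path Output path.
#' @param format `"auto"` (from extension), `"tiff"` or `"mrc"`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, format = c("auto", "tiff", "mrc")) {
  stopifnot(inherits(stack, "image_stack"))
  format <- match.arg(format)
  if (format == "auto") format <- .guess_format(path)
  meta <- list(pixel_size_nm = stack$pixel_size_nm,
               slice_thickness_nm = stack$slice_thickness_nm,
               modality = stack$modality, format = format)
  if (format == "tiff") {
    v <- stack$voxels
    off <- min(v)
    sc <- max(v) - off
    scaled <- if (sc > 0) (v - off) / sc else array(0, dim(v))
    pages <- lapply(seq_len(dim(v)[1]), function(i) scaled[i, , ])
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
    meta$offset <- off
    meta$scale <- sc
  } else {
    .write_mrc(stack, path)
  }
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an image stack from disk
#'
#' Reads TIFF (via the `tiff` package) or MRC (MRC2014, modes 0/1/2/6).
#' Metadata comes from the JSON sidecar when present, otherwise from the MRC
#' header (voxel size) or the supplied defaults.
#'
#' @param path Input path.
#' @param format `"auto"`, `"tiff"` or `"mrc"`.
#' @param pixel_size_nm,modality Fallbacks when no sidecar exists.
#' @return An `"image_stack"`.
#' @export
read_stack <- function(path, format = c("auto", "tiff", "mrc"),
                       pixel_size_nm = 1, modality = "bse-esb") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- .guess_format(path)
  meta <- NULL
  if (file.exists(.sidecar_path(path))) {
    meta <- jsonlite::read_json(.sidecar_path(path), simplifyVector = TRUE)
  }
  if (format == "tiff") {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (is.matrix(pages)) pages <- list(pages)
    d <- dim(pages[[1]])
    v <- array(0, c(length(pages), d[1], d[2]))
    for (i in seq_along(pages)) {
      p <- pages[[i]]
      if (!is.matrix(p)) p <- p[, , 1]  # collapse accidental channels
      v[i, , ] <- p
    }
    if (!is.null(meta$scale)) v <- v * meta$scale + meta$offset
    px <- if (!is.null(meta$pixel_size_nm)) meta$pixel_size_nm else pixel_size_nm
    sl <- if (!is.null(meta$slice_thickness_nm)) meta$slice_thickness_nm else px
    mod <- if (!is.null(meta$modality)) meta$modality else modality
    image_stack(v, px, sl, modality = mod)
  } else {
    st <- .read_mrc(path)
    px <- if (!is.null(meta$pixel_size_nm)) meta$pixel_size_nm else st$pixel_size_nm
    sl <- if (!is.null(meta$slice_thickness_nm)) meta$slice_thickness_nm else st$slice_thickness_nm
    mod <- if (!is.null(meta$modality)) meta$modality else modality
    image_stack(st$voxels, px, sl, modality = mod)
  }
}

# Minimal MRC2014 writer, mode 2 (float32). Axis mapping: x = col (fastest),
# y = row, z = slice; cell dimensions carry the voxel size in Angstrom.
.write_mrc <- function(stack, path) {
  v <- stack$voxels
  d <- dim(v)  # (slice, row, col)
  nx <- d[3]; ny <- d[2]; nz <- d[1]
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(c(nx, ny, nz, 2L))                      # nx ny nz mode
  wi(c(0L, 0L, 0L))                          # nxstart nystart nzstart
  wi(c(nx, ny, nz))                          # mx my mz
  wf(c(nx * stack$pixel_size_nm * 10,
       ny * stack$pixel_size_nm * 10,
       nz * stack$slice_thickness_nm * 10))  # cella (Angstrom)
  wf(c(90, 90, 90))                          # cellb
  wi(c(1L, 2L, 3L))                          # mapc mapr maps
  wf(c(min(v), max(v), mean(v)))             # dmin dmax dmean
  wi(c(0L, 0L))                              # ispg nsymbt
  wi(rep(0L, 25))                            # extra
  wi(c(0L, 0L, 0L))                          # origin (as ints, zero)
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(v))                           # rms
  wi(0L)                                     # nlabl
  writeBin(raw(800), con)                    # empty labels
  writeBin(as.numeric(aperm(v, c(3, 2, 1))), con, size = 4,
           endian = "little")
  invisible(path)
}

.read_mrc <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 1024) stop("malformed MRC file (header truncated): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  h1 <- ri(4)  # nx ny nz mode
  nx <- h1[1]; ny <- h1[2]; nz <- h1[3]; mode <- h1[4]
  if (any(c(nx, ny, nz) < 1) || !(mode %in% c(0L, 1L, 2L, 6L))) {
    stop("malformed MRC file (bad dimensions or mode ", mode, "): ", path)
  }
  ri(3)               # nstart
  m <- ri(3)          # mx my mz
  cella <- rf(3)
  rf(3); ri(3); rf(3) # cellb, map order, dmin/max/mean
  ri(1)               # ispg
  nsymbt <- ri(1)
  bytes <- c(`0` = 1L, `1` = 2L, `2` = 4L, `6` = 2L)[[as.character(mode)]]
  need <- 1024 + nsymbt + as.numeric(nx) * ny * nz * bytes
  if (sz < need) {
    stop("malformed MRC file (expected ", need, " bytes, found ", sz, "): ",
         path)
  }
  seek(con, 1024 + nsymbt)
  n <- nx * ny * nz
  data <- switch(as.character(mode),
    `0` = readBin(con, "integer", n, size = 1, signed = TRUE),
    `1` = readBin(con, "integer", n, size = 2, signed = TRUE,
                  endian = "little"),
    `2` = readBin(con, "numeric", n, size = 4, endian = "little"),
    `6` = readBin(con, "integer", n, size = 2, signed = FALSE,
                  endian = "little"))
  v <- aperm(array(as.numeric(data), c(nx, ny, nz)), c(3, 2, 1))
  px <- if (m[1] > 0 && cella[1] > 0) cella[1] / m[1] / 10 else 1
  sl <- if (m[3] > 0 && cella[3] > 0) cella[3] / m[3] / 10 else px
  list(voxels = v, pixel_size_nm = px, slice_thickness_nm = sl)
}

#' Flat-field normalization to optical density
#'
#' Beer-Lambert optical density OD = -ln(I/I0) pixel-wise. Pixels where the
#' measured or reference intensity is non-positive are invalid and set to
#' `NA` (they are excluded from region statistics) rather than clamped.
#'
#' @param frame Measured intensity matrix I.
#' @param flat_field Reference intensity matrix I0, same shape.
#' @return Matrix of optical densities with `NA` at invalid pixels.
#' @export
to_optical_density <- function(frame, flat_field) {
  stopifnot(is.matrix(frame), is.matrix(flat_field))
  if (!all(dim(frame) == dim(flat_field))) {
    stop("frame and flat field shapes differ: ",
         paste(dim(frame), collapse = "x"), " vs ",
         paste(dim(flat_field), collapse = "x"))
  }
  od <- matrix(NA_real_, nrow(frame), ncol(frame))
  ok <- frame > 0 & flat_field > 0
  od[ok] <- -log(frame[ok] / flat_field[ok])
  od
}

# Circular shift of a matrix by (drow, dcol).
.roll2 <- function(m, shift) {
  n <- nrow(m); p <- ncol(m)
  i <- ((seq_len(n) - 1 - shift[1]) %% n) + 1
  j <- ((seq_len(p) - 1 - shift[2]) %% p) + 1
  m[i, j, drop = FALSE]
}

# Translation between two frames by phase correlation. Returns the (row, col)
# shift to apply to `b` (circularly) so that it matches `a`.
.phase_corr_shift <- function(a, b, eps = 1e-12) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("featureless (constant) frame; assuming zero shift")
    return(c(0L, 0L))
  }
  fa <- stats::fft(a)
  fb <- stats::fft(b)
  cp <- fa * Conj(fb)
  cp <- cp / pmax(Mod(cp), eps)
  r <- Re(stats::fft(cp, inverse = TRUE))
  k <- arrayInd(which.max(r), dim(r)) - 1L
  n <- dim(r)
  s <- ifelse(k > n / 2, k - n, k)
  as.integer(s)
}

#' Translation-only stack alignment by phase correlation
#'
#' Registers every frame to a reference frame (default: the middle frame)
#' using the phase-correlation peak, allowing integer-pixel translations
#' only, and applies the shifts circularly. Applying the reported shifts to
#' the input reproduces the output exactly, so the same shift list can be
#' transferred to a paired stack (e.g. in-lens shifts applied to the EsB
#' channel) with [apply_shifts()].
#'
#' @param stack An `"image_stack"` or 3-D array with at least 2 frames.
#' @param reference `"middle"` or `"first"` for a fixed reference frame;
#'   `"previous"` for a running reference (each frame is registered to its
#'   predecessor and the shifts are accumulated), which is the robust choice
#'   for energy scans whose contrast changes gradually across frames.
#' @param ref_index Optional explicit reference frame index.
#' @return List with `aligned` (same class as input) and `shifts`
#'   (n x 2 integer matrix of (row, col) shifts applied to each frame).
#' @export
align_translation <- function(stack,
                              reference = c("middle", "first", "previous"),
                              ref_index = NULL) {
  reference <- match.arg(reference)
  v <- if (inherits(stack, "image_stack")) stack$voxels else stack
  stopifnot(is.array(v), length(dim(v)) == 3)
  n <- dim(v)[1]
  if (n < 2) stop("alignment needs at least 2 frames")
  shifts <- matrix(0L, n, 2,
                   dimnames = list(NULL, c("row", "col")))
  out <- v
  if (reference == "previous" && is.null(ref_index)) {
    for (i in 2:n) {
      shifts[i, ] <- shifts[i - 1, ] +
        .phase_corr_shift(v[i - 1, , ], v[i, , ])
      out[i, , ] <- .roll2(v[i, , ], shifts[i, ])
    }
    aligned <- if (inherits(stack, "image_stack")) {
      s2 <- stack; s2$voxels <- out; s2
    } else out
    return(list(aligned = aligned, shifts = shifts))
  }
  ref <- if (!is.null(ref_index)) ref_index
         else if (reference == "middle") (n + 1L) %/% 2L else 1L
  for (i in seq_len(n)) {
    if (i == ref) next
    s <- .phase_corr_shift(v[ref, , ], v[i, , ])
    shifts[i, ] <- s
    out[i, , ] <- .roll2(v[i, , ], s)
  }
  aligned <- if (inherits(stack, "image_stack")) {
    s2 <- stack; s2$voxels <- out; s2
  } else out
  list(aligned = aligned, shifts = shifts)
}

#' Apply a shift list to a stack
#'
#' Circularly translates each frame by the given (row, col) shift; used to
#' transfer the alignment of one channel to a simultaneously acquired one.
#'
#' @param stack An `"image_stack"` or 3-D array.
#' @param shifts n x 2 integer matrix as returned by [align_translation()].
#' @return Same class as the input.
#' @export
apply_shifts <- function(stack, shifts) {
  v <- if (inherits(stack, "image_stack")) stack$voxels else stack
  stopifnot(is.array(v), length(dim(v)) == 3, nrow(shifts) == dim(v)[1])
  for (i in seq_len(dim(v)[1])) {
    v[i, , ] <- .roll2(v[i, , ], shifts[i, ])
  }
  if (inherits(stack, "image_stack")) { stack$voxels <- v; stack } else v
}

#' Remove vertical stripes by Fourier notch filtering
#'
#' Suppresses the FIB "waterfall" artefact: vertical stripes are constant
#' along the image rows, so their energy sits on the zero-vertical-frequency
#' line of the 2-D spectrum. All coefficients within `notch_halfwidth` of
#' that line (excluding the DC term, so the mean grey level is preserved
#' exactly) are zeroed.
#'
#' @param frame 2-D numeric matrix.
#' @param notch_halfwidth Half-width (in frequency samples) of the notch
#'   around the stripe line.
#' @return Filtered matrix of the same shape.
#' @export
destripe_vertical <- function(frame, notch_halfwidth = 2) {
  stopifnot(is.matrix(frame))
  n <- nrow(frame)
  f <- stats::fft(frame)
  hw <- min(notch_halfwidth, floor((n - 1) / 2))
  rows <- unique(c(1L, if (hw >= 1) c(2:(1 + hw), (n - hw + 1):n)))
  f[rows, 2:ncol(f)] <- 0  # keep column 1 (DC and pure-horizontal structure)
  Re(stats::fft(f, inverse = TRUE)) / length(frame)
}

#' Region statistics over a mask
#'
#' Exact arithmetic mean, standard deviation and voxel count of the stack
#' values under a boolean mask; `NA` voxels (e.g. invalid OD pixels) are
#' excluded.
#'
#' @param x An `"image_stack"`, 3-D array or matrix.
#' @param mask Logical array congruent with `x`.
#' @return List with `mean`, `sd` and `n`.
#' @export
region_stats <- function(x, mask) {
  v <- if (inherits(x, "image_stack")) x$voxels else x
  if (is.matrix(v) && is.matrix(mask)) {
    stopifnot(all(dim(v) == dim(mask)))
  } else {
    stopifnot(is.array(v), all(dim(v) == dim(mask)))
  }
  vals <- v[mask]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) stop("region mask selects no (valid) voxels")
  list(mean = mean(vals),
       sd = if (length(vals) > 1) stats::sd(vals) else 0,
       n = length(vals))
}
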