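# Resolution estimation by even/odd Fourier shell correlation, threshold
# 0.25, half-pitch reporting.

#' Construct an FSC curve
#'
#' @param shell_freqs Spatial frequencies of the shell centres (1/nm),
#'   increasing, at most Nyquist.
#' @param correlation Per-shell correlation values in \[-1, 1\].
#' @param voxel_size_nm Voxel size of the underlying volumes (nm).
#' @param n_voxels Optional number of Fourier voxels per shell.
#' @return An object of class `"fsc_curve"` (a data.frame with columns
#'   `freq`, `fsc`, `n`).
#' @export
fsc_curve <- function(shell_freqs, correlation, voxel_size_nm,
                      n_voxels = NA_integer_) {
  stopifnot(length(shell_freqs) == length(correlation),
            all(diff(shell_freqs) > 0), voxel_size_nm > 0)
  nyq <- 1 / (2 * voxel_size_nm)
  if (any(shell_freqs > nyq + 1e-12)) {
    stop("shell frequencies exceed Nyquist (", format(nyq), " /nm)")
  }
  df <- data.frame(freq = shell_freqs, fsc = correlation, n = n_voxels)
  structure(df, class = c("fsc_curve", "data.frame"),
            voxel_size_nm = voxel_size_nm)
}

#' @export
plot.fsc_curve <- function(x, threshold = 0.25, ...) {
  graphics::plot(x$freq, x$fsc, type = "l", ylim = c(min(0, min(x$fsc)), 1),
                 xlab = "spatial frequency (1/nm)", ylab = "FSC", ...)
  graphics::abline(h = threshold, lty = 2)
}

#' Fourier shell correlation of two volumes
#'
#' Shell-wise normalized cross-correlation of the Fourier coefficients,
#' `Re(sum(Fa * Conj(Fb))) / sqrt(sum(|Fa|^2) * sum(|Fb|^2))`, over
#' concentric spherical shells up to Nyquist. Non-cubic volumes are
#' zero-padded to the largest dimension.
#'
#' @param vol_a,vol_b 3-D numeric arrays of equal shape (e.g. the
#'   reconstructions from even and odd halves of a data set).
#' @param voxel_size_nm Isotropic voxel size (nm).
#' @param n_shells Number of shells; default half the (padded) edge length.
#' @return An `"fsc_curve"`.
#' @export
fsc <- function(vol_a, vol_b, voxel_size_nm = 1, n_shells = NULL) {
  stopifnot(is.array(vol_a), is.array(vol_b),
            length(dim(vol_a)) == 3, length(dim(vol_b)) == 3)
  if (!all(dim(vol_a) == dim(vol_b))) {
    stop("volume shapes differ: ", paste(dim(vol_a), collapse = "x"),
         " vs ", paste(dim(vol_b), collapse = "x"))
  }
  d <- dim(vol_a)
  n <- max(d)
  if (!all(d == n)) {  # zero-pad to cube
    pad <- function(v) {
      out <- array(0, c(n, n, n))
      out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- v
      out
    }
    vol_a <- pad(vol_a); vol_b <- pad(vol_b)
  }
  fa <- stats::fft(vol_a)
  fb <- stats::fft(vol_b)
  fr <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / (n * voxel_size_nm)
  r2 <- outer(outer(fr^2, fr^2, `+`), fr^2, `+`)
  r <- sqrt(r2)
  if (is.null(n_shells)) n_shells <- n %/% 2
  nyq <- 1 / (2 * voxel_size_nm)
  edges <- seq(0, nyq, length.out = n_shells + 1)
  shell <- findInterval(r, edges, rightmost.closed = TRUE)
  shell[shell < 1 | shell > n_shells] <- NA
  cross <- Re(fa * Conj(fb))
  pa <- Mod(fa)^2
  pb <- Mod(fb)^2
  num <- tapply(cross, shell, sum)
  da <- tapply(pa, shell, sum)
  db <- tapply(pb, shell, sum)
  cnt <- tapply(!is.na(shell), shell, sum)
  idx <- as.integer(names(num))
  corr <- as.numeric(num / sqrt(da * db))
  corr[!is.finite(corr)] <- 0
  centers <- (edges[idx] + edges[idx + 1]) / 2
  fsc_curve(centers, corr, voxel_size_nm, n_voxels = as.integer(cnt))
}

#' Resolution at an FSC threshold (half pitch)
#'
#' Finds the lowest frequency at which the FSC curve first drops below the
#' threshold (default 0.25), locating the crossing by linear interpolation
#' between the bracketing shells, and reports the half-pitch resolution
#' `1 / (2 * f_c)` in nm. When the curve never crosses, the Nyquist-limited
#' value `2 * voxel_size` is returned with `flagged = TRUE`.
#'
#' @param curve An `"fsc_curve"`.
#' @param threshold FSC threshold.
#' @return List with `resolution_nm`, `f_c` (crossing frequency, 1/nm),
#'   `threshold` and `flagged`.
#' @export
resolution_at_threshold <- function(curve, threshold = 0.25) {
  stopifnot(inherits(curve, "fsc_curve"))
  f <- curve$freq
  y <- curve$fsc
  vox <- attr(curve, "voxel_size_nm")
  below <- which(y < threshold)
  below <- below[below > 1]  # need a bracketing shell above threshold
  cross <- NULL
  for (i in below) {
    if (y[i - 1] >= threshold) { cross <- i; break }
  }
  if (is.null(cross)) {
    if (length(y) > 0 && y[1] < threshold) {
      # already below threshold at the first shell: resolution unsupported
      return(list(resolution_nm = 1 / (2 * f[1]), f_c = f[1],
                  threshold = threshold, flagged = TRUE))
    }
    # no crossing: resolution limited by sampling (two-voxel period);
    # f_c reported as Nyquist
    return(list(resolution_nm = 2 * vox, f_c = 1 / (2 * vox),
                threshold = threshold, flagged = TRUE))
  }
  i <- cross
  f_c <- f[i - 1] + (f[i] - f[i - 1]) *
    (y[i - 1] - threshold) / (y[i - 1] - y[i])
  list(resolution_nm = 1 / (2 * f_c), f_c = f_c, threshold = threshold,
       flagged = FALSE)
}
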