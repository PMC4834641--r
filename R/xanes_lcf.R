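# Ca K-edge XANES: scan averaging, edge finding from the first derivative,
# pre/post-edge normalization, and simplex-constrained linear combination
# fitting against reference standards.

#' Average repeated scans
#'
#' Pointwise mean of repeated scans of the same sample (typically three to
#' five), to improve the signal-to-noise ratio.
#'
#' @param spectra List of `"xas_spectrum"` objects.
#' @param interpolate Allow linear interpolation onto the first spectrum's
#'   grid when the grids differ; otherwise differing grids are an error.
#' @return An `"xas_spectrum"` with state `"averaged"`.
#' @export
average_scans <- function(spectra, interpolate = FALSE) {
  stopifnot(is.list(spectra), length(spectra) >= 1,
            all(vapply(spectra, inherits, logical(1), "xas_spectrum")))
  e0 <- spectra[[1]]$energies_eV
  same <- all(vapply(spectra, function(s) {
    length(s$energies_eV) == length(e0) &&
      max(abs(s$energies_eV - e0)) < 1e-9
  }, logical(1)))
  if (!same && !interpolate) {
    stop("scans are on different energy grids; set interpolate = TRUE")
  }
  ys <- vapply(spectra, function(s) {
    if (same) s$intensity
    else stats::approx(s$energies_eV, s$intensity, e0, rule = 2)$y
  }, numeric(length(e0)))
  xas_spectrum(e0, rowMeans(as.matrix(ys)), state = "averaged")
}

# Local maxima of a series with a simple prominence measure: height above
# the higher of the two valleys separating the peak from taller neighbours.
.find_peaks <- function(y) {
  n <- length(y)
  idx <- which(diff(sign(diff(y))) < 0) + 1L
  if (length(idx) == 0) return(data.frame(i = integer(), prominence = numeric()))
  prom <- vapply(idx, function(i) {
    lmin <- y[i]; j <- i
    while (j > 1 && y[j] <= y[i]) { lmin <- min(lmin, y[j]); j <- j - 1 }
    if (j == 1 && y[1] <= y[i]) lmin <- min(lmin, y[1])
    rmin <- y[i]; j <- i
    while (j < n && y[j] <= y[i]) { rmin <- min(rmin, y[j]); j <- j + 1 }
    if (j == n && y[n] <= y[i]) rmin <- min(rmin, y[n])
    y[i] - max(lmin, rmin)
  }, numeric(1))
  data.frame(i = idx, prominence = prom)
}

#' Locate the absorption edge energy E0
#'
#' E0 is the energy of the third peak of the first derivative of the
#' spectrum (the pre-edge features contribute the first two derivative
#' peaks; the main rising edge the third). The derivative is taken with a
#' Savitzky-Golay filter on a uniform resampling of the spectrum, and peaks
#' must have a prominence of at least `min_prominence_frac` of the
#' derivative's range. With fewer than three qualifying peaks the energy of
#' the global derivative maximum is returned with a warning.
#'
#' @param spectrum An `"xas_spectrum"` covering the edge.
#' @param smooth_eV Width (eV) of the local-polynomial derivative window.
#' @param min_prominence_frac Prominence threshold as a fraction of the
#'   derivative range.
#' @return E0 in eV.
#' @export
find_edge <- function(spectrum, smooth_eV = 1.0, min_prominence_frac = 0.05) {
  stopifnot(inherits(spectrum, "xas_spectrum"))
  e <- spectrum$energies_eV
  step <- min(diff(e))
  grid <- seq(min(e), max(e), by = step)
  y <- stats::approx(e, spectrum$intensity, grid)$y
  n_win <- max(5L, 2L * floor(smooth_eV / step / 2) + 1L)  # odd, >= 5
  if (n_win >= length(grid)) n_win <- 2L * floor((length(grid) - 1) / 2) - 1L
  dy <- signal::sgolayfilt(y, p = 2, n = n_win, m = 1, ts = step)
  pk <- .find_peaks(dy)
  pk <- pk[pk$prominence >= min_prominence_frac * diff(range(dy)), ,
           drop = FALSE]
  if (nrow(pk) < 3) {
    warning("fewer than 3 derivative peaks; falling back to the global ",
            "derivative maximum")
    return(grid[which.max(dy)])
  }
  grid[sort(pk$i)[3]]
}

.polyfit_eval <- function(e, y, degree, at) {
  fit <- stats::lm(y ~ stats::poly(e, degree, raw = TRUE))
  as.numeric(cbind(1, stats::poly(at, degree, raw = TRUE)) %*%
               stats::coef(fit))
}

#' Normalize a XANES spectrum
#'
#' Athena-style edge-step normalization: a linear pre-edge function is
#' fitted between `pre_window` eV relative to E0 (default 25 to 13 eV below
#' E0) and a quadratic polynomial for the post-edge between `post_window`
#' (default 26 to 90 eV above E0). The pre-edge line is subtracted, the
#' intensity divided by the edge step (post-edge minus pre-edge evaluated at
#' E0) and the post-edge flattened so it fluctuates about 1.
#'
#' @param spectrum An `"xas_spectrum"`.
#' @param E0 Edge energy (eV); found with [find_edge()] when `NULL`.
#' @param pre_window,post_window Fit windows in eV relative to E0
#'   (pre negative, post positive).
#' @param flatten Flatten the post-edge to 1 (default).
#' @return An `"xas_spectrum"` with state `"normalized"` and `E0` set; the
#'   edge step is attached as attribute `"edge_step"`.
#' @export
normalize_spectrum <- function(spectrum, E0 = NULL,
                               pre_window = c(-25, -13),
                               post_window = c(26, 90), flatten = TRUE) {
  stopifnot(inherits(spectrum, "xas_spectrum"))
  if (is.null(E0)) E0 <- find_edge(spectrum)
  e <- spectrum$energies_eV
  y <- spectrum$intensity
  pre_sel <- e >= E0 + pre_window[1] & e <= E0 + pre_window[2]
  post_sel <- e >= E0 + post_window[1] & e <= E0 + post_window[2]
  if (sum(pre_sel) < 2) {
    stop("spectrum does not span the pre-edge window [E0", pre_window[1],
         ", E0", pre_window[2], "] eV")
  }
  if (sum(post_sel) < 3) {
    stop("spectrum does not span the post-edge window [E0+", post_window[1],
         ", E0+", post_window[2], "] eV")
  }
  pre_fit <- stats::lm(y ~ e, data = data.frame(e = e[pre_sel],
                                                y = y[pre_sel]))
  pre_all <- as.numeric(stats::predict(pre_fit, data.frame(e = e)))
  pre_E0 <- as.numeric(stats::predict(pre_fit, data.frame(e = E0)))
  post_E0 <- .polyfit_eval(e[post_sel], y[post_sel], 2, E0)
  step <- post_E0 - pre_E0
  if (!is.finite(step) || step <= 0) {
    stop("non-positive edge step; is this an absorption edge?")
  }
  norm <- (y - pre_all) / step
  if (flatten) {
    post_all <- .polyfit_eval(e[post_sel], y[post_sel], 2, e)
    corr <- 1 - (post_all - pre_all) / step
    sel <- e >= E0
    norm[sel] <- norm[sel] + corr[sel]
  }
  out <- xas_spectrum(e, norm, state = "normalized", E0 = E0)
  attr(out, "edge_step") <- step
  out
}

# Equality-constrained least squares on a support set: minimize |y - R w|^2
# subject to sum(w) = 1, via the KKT system.
.ecls_sum1 <- function(R, y) {
  k <- ncol(R)
  A <- rbind(cbind(2 * crossprod(R), rep(1, k)), c(rep(1, k), 0))
  b <- c(2 * crossprod(R, y), 1)
  sol <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  sol[seq_len(k)]
}

#' Linear combination fit of XANES references
#'
#' Expresses a normalized spectrum as a weighted sum of normalized
#' reference spectra, minimizing the summed squared misfit over the fit
#' window subject to non-negative weights and (by default) weights summing
#' to one. The constrained optimum is found exactly by solving the
#' equality-constrained least-squares problem on every support set of the
#' references and keeping the feasible solution with the smallest residual
#' (ties go to the smaller support). Identical references trigger an
#' ill-conditioning warning but still return valid weights.
#'
#' @param target Normalized `"xas_spectrum"`.
#' @param references Named list of normalized `"xas_spectrum"` objects
#'   (>= 2).
#' @param window Fit window `c(lo, hi)` in eV; default `E0 - 20` to
#'   `E0 + 60` when the target has E0, otherwise the full common range.
#' @param sum_to_one Enforce the simplex constraint (default TRUE).
#' @return An object of class `"lcf_fit"`: `weights` (named, >= 0),
#'   `residual` (sum of squared misfit), `window`, `constraints`, plus
#'   `fitted`/`residuals` series. Supports `coef()`, `fitted()`,
#'   `residuals()` and `print()`.
#' @export
lcf <- function(target, references, window = NULL, sum_to_one = TRUE) {
  stopifnot(inherits(target, "xas_spectrum"), is.list(references),
            length(references) >= 2,
            all(vapply(references, inherits, logical(1), "xas_spectrum")))
  if (is.null(names(references))) {
    names(references) <- paste0("ref", seq_along(references))
  }
  if (is.null(window)) {
    window <- if (!is.null(target$E0)) target$E0 + c(-20, 60)
              else range(target$energies_eV)
  }
  lo <- max(window[1], min(target$energies_eV),
            vapply(references, function(s) min(s$energies_eV), numeric(1)))
  hi <- min(window[2], max(target$energies_eV),
            vapply(references, function(s) max(s$energies_eV), numeric(1)))
  if (hi <= lo) stop("empty fit window after intersecting energy ranges")
  sel <- target$energies_eV >= lo & target$energies_eV <= hi
  if (sum(sel) < length(references) + 1) {
    stop("too few energy points in the fit window")
  }
  e <- target$energies_eV[sel]
  y <- target$intensity[sel]
  R <- vapply(references, function(s) {
    stats::approx(s$energies_eV, s$intensity, e)$y
  }, numeric(length(e)))
  k <- ncol(R)
  if (qr(R)$rank < k) {
    warning("reference set is ill-conditioned (linearly dependent spectra)")
  }
  best <- NULL
  supports <- unlist(lapply(seq_len(k), function(m) {
    utils::combn(k, m, simplify = FALSE)
  }), recursive = FALSE)
  for (S in supports) {
    Rs <- R[, S, drop = FALSE]
    w_s <- if (sum_to_one) .ecls_sum1(Rs, y)
           else tryCatch(as.numeric(qr.solve(Rs, y)), error = function(e) NULL)
    if (is.null(w_s) || any(!is.finite(w_s)) || any(w_s < -1e-10)) next
    w <- numeric(k); w[S] <- pmax(w_s, 0)
    if (sum_to_one) w <- w / sum(w)
    res <- sum((y - R %*% w)^2)
    if (is.null(best) || res < best$residual - 1e-12 ||
        (abs(res - best$residual) <= 1e-12 && length(S) < best$support)) {
      best <- list(w = w, residual = res, support = length(S))
    }
  }
  if (is.null(best)) stop("no feasible LCF solution found")
  fit_series <- as.numeric(R %*% best$w)
  structure(
    list(weights = stats::setNames(best$w, names(references)),
         residual = best$residual,
         window = c(lo, hi),
         constraints = c(nonneg = TRUE, sum_to_one = sum_to_one),
         energies_eV = e, fitted = fit_series, residuals = y - fit_series),
    class = "lcf_fit"
  )
}

#' @export
print.lcf_fit <- function(x, ...) {
  cat("<lcf_fit> window", format(x$window[1], digits = 6), "-",
      format(x$window[2], digits = 6), "eV\n")
  for (nm in names(x$weights)) {
    cat(sprintf("  %-16s %.4f\n", nm, x$weights[[nm]]))
  }
  cat("  residual (SSQ):", format(x$residual, digits = 4), "\n")
  invisible(x)
}

#' @export
coef.lcf_fit <- function(object, ...) object$weights

#' @export
fitted.lcf_fit <- function(object, ...) object$fitted

#' @export
residuals.lcf_fit <- function(object, ...) object$residuals

#' Rank candidate reference sets by fit quality
#'
#' Fits the target against each candidate set and orders the sets by
#' residual (ascending); ties within `tie_tol` go to the set with fewer
#' references.
#'
#' @param target Normalized `"xas_spectrum"`.
#' @param sets Named list of reference lists (each a valid `references`
#'   argument for [lcf()]).
#' @param tie_tol Absolute residual tolerance for tie-breaking.
#' @param ... Passed to [lcf()].
#' @return A `data.frame` with `set`, `n_references`, `residual`, ordered
#'   best-first; the fits are attached as attribute `"fits"`.
#' @export
compare_reference_sets <- function(target, sets, tie_tol = 1e-9, ...) {
  stopifnot(is.list(sets), length(sets) >= 1)
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  fits <- lapply(sets, function(refs) lcf(target, refs, ...))
  df <- data.frame(
    set = names(sets),
    n_references = vapply(sets, length, integer(1)),
    residual = vapply(fits, `[[`, numeric(1), "residual")
  )
  ord <- order(round(df$residual / tie_tol), df$n_references)
  df <- df[ord, ]
  rownames(df) <- NULL
  attr(df, "fits") <- fits[df$set]
  df
}
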