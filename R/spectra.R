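#' Average replicate spectra
#'
#' Pointwise arithmetic mean of replicate scans. For an [OliveSet] the
#' replicate assays (`rep*`) are averaged into a new `"reflectance"` assay;
#' for a list of spectra matrices (wavelengths x olives, identical grids)
#' the mean matrix is returned.
#'
#' @param x an [OliveSet] or a list of numeric matrices/vectors.
#' @return same class as `x` (OliveSet gains the `"reflectance"` assay).
#' @export
averageReplicates <- function(x) {
    if (is(x, "OliveSet")) {
        nm <- grep("^rep", SummarizedExperiment::assayNames(x), value = TRUE)
        if (length(nm) == 0) stopf("no replicate assays (rep*) present")
        reps <- lapply(nm, function(a) SummarizedExperiment::assay(x, a))
        SummarizedExperiment::assay(x, "reflectance") <- Reduce(`+`, reps) /
            length(reps)
        return(x)
    }
    if (!is.list(x) || length(x) == 0)
        stopf("need an OliveSet or a non-empty list of replicates")
    dims <- lapply(x, dim)
    if (length(unique(vapply(x, length, 1L))) != 1 ||
        length(unique(vapply(dims, paste, "", collapse = "x"))) != 1)
        stopf("replicates must share one wavelength grid")
    Reduce(`+`, x) / length(x)
}

#' Standard normal variate (SNV) correction
#'
#' Centers and scales each spectrum to mean 0 and sample SD 1 across its
#' own points, removing additive offsets and multiplicative scatter:
#' invariant under a + b*x (b > 0), and idempotent.
#'
#' @param x numeric vector (one spectrum) or matrix with one spectrum per
#'   column.
#' @return same shape, each spectrum standardized.
#' @export
snv <- function(x) {
    one <- function(v) {
        s <- sd(v)
        if (!is.finite(s) || s == 0)
            stopf("constant spectrum: SNV is undefined")
        (v - mean(v)) / s
    }
    if (is.null(dim(x))) one(x) else apply(x, 2, one)
}

#' Smoothed second derivative (Savitzky-Golay)
#'
#' Savitzky-Golay second derivative with respect to wavelength: local
#' least-squares polynomial of order `polyorder` over a sliding window,
#' evaluated analytically (via \pkg{signal}) and scaled by the grid spacing
#' so units are reflectance per nm squared. The first and last
#' `floor(window/2)` points, where the centered window is undefined, are
#' returned as `NA`. Requires a uniform wavelength grid.
#'
#' @param x numeric vector or matrix (spectra in columns).
#' @param wavelengths ascending, uniformly spaced grid (nm).
#' @param window odd window length, `window > polyorder`.
#' @param polyorder polynomial order (>= 2 for a second derivative).
#' @return same shape as `x`, with `NA` at the excluded edges.
#' @export
secondDerivative <- function(x, wavelengths, window = 11, polyorder = 2) {
    if (window %% 2 != 1) stopf("window must be odd")
    if (polyorder < 2) stopf("polyorder must be >= 2 for a 2nd derivative")
    if (window <= polyorder) stopf("window must exceed polyorder")
    h <- diff(wavelengths)
    if (any(h <= 0)) stopf("wavelengths must be strictly increasing")
    if (diff(range(h)) > 1e-6 * mean(h))
        stopf("Savitzky-Golay differentiation needs a uniform grid")
    p <- length(wavelengths)
    if (p < window) stopf("spectrum shorter than the window")
    half <- (window - 1L) %/% 2L
    one <- function(v) {
        d <- signal::sgolayfilt(v, p = polyorder, n = window, m = 2,
                                ts = mean(h))
        d[c(seq_len(half), (p - half + 1L):p)] <- NA_real_
        d
    }
    if (is.null(dim(x))) {
        if (length(x) != p) stopf("spectrum and grid lengths differ")
        one(x)
    } else {
        if (nrow(x) != p) stopf("spectrum and grid lengths differ")
        apply(x, 2, one)
    }
}

#' Select the lipid absorption band on the acquisition grid
#'
#' Nominal wavelengths `start + k*step` for k = 0, 1, ... while they stay
#' within `stop + step/2`, each snapped to the nearest grid point. With the
#' default 512-point 900-2200 nm grid and the defaults 1710-1735 nm every
#' 2.53 nm this selects 11 points around the 1725 nm lipid absorption.
#' The step must exceed half the grid spacing so no two nominal wavelengths
#' snap to the same grid index.
#'
#' @param wavelengths ascending grid (nm).
#' @param start,stop band limits (nm); must lie within the grid range.
#' @param step nominal spacing (nm).
#' @return list of class `"BandSelection"`: `nominal` wavelengths,
#'   `index` into the grid, `grid` wavelengths actually used, `n` points.
#' @export
selectBand <- function(wavelengths, start = 1710, stop = 1735, step = 2.53) {
    if (start > stop) stopf("band start must be <= stop")
    if (step <= 0) stopf("step must be > 0")
    if (start < min(wavelengths) || stop > max(wavelengths))
        stopf("band [%g, %g] outside the grid range [%g, %g]", start, stop,
              min(wavelengths), max(wavelengths))
    nominal <- seq(start, stop + step / 2 + 1e-9, by = step)
    nominal <- nominal[nominal <= stop + step / 2 + 1e-9]
    idx <- vapply(nominal, function(w) which.min(abs(wavelengths - w)), 1L)
    if (anyDuplicated(idx))
        stopf("step %g nm too small for the grid spacing (%g nm)", step,
              mean(diff(wavelengths)))
    structure(list(nominal = nominal, index = idx,
                   grid = wavelengths[idx], n = length(idx)),
              class = "BandSelection")
}

#' @export
print.BandSelection <- function(x, ...) {
    cat(sprintf("BandSelection: %d points, nominal %.2f-%.2f nm\n",
                x$n, min(x$nominal), max(x$nominal)))
    invisible(x)
}

#' Extract band reflectances for a population of spectra
#'
#' @param x reflectance matrix (wavelengths x olives) or [OliveSet] (uses
#'   the averaged `"reflectance"` assay).
#' @param band a [selectBand()] result.
#' @return matrix olives x band points, columns `nir_1..nir_n` (ascending
#'   wavelength).
#' @export
bandValues <- function(x, band) {
    m <- if (is(x, "OliveSet")) reflectance(x) else x
    v <- t(m[band$index, , drop = FALSE])
    colnames(v) <- paste0("nir_", seq_len(band$n))
    v
}

#' Principal component analysis of a spectra population
#'
#' Column-centered (no scaling) PCA of spectra-as-observations, used to
#' compare seasons. Loadings are orthonormal, explained variances
#' non-increasing.
#'
#' @param X matrix with one spectrum per row (n x p), or an [OliveSet]
#'   (spectra transposed from the `"reflectance"` assay).
#' @param n_components number of components (<= min(n, p)).
#' @param preprocess optional function applied to each spectrum first (e.g.
#'   [snv()] expects wavelengths-in-rows, so it is applied to `t(X)`).
#' @return list: `scores` (n x k), `loadings` (p x k, orthonormal),
#'   `explained` (variance fractions), `center`.
#' @export
spectraPCA <- function(X, n_components = 3, preprocess = NULL) {
    if (is(X, "OliveSet")) X <- t(reflectance(X))
    if (!is.null(preprocess)) X <- t(preprocess(t(X)))
    n <- nrow(X); p <- ncol(X)
    if (n < 2) stopf("PCA needs at least two spectra")
    if (n_components > min(n, p))
        stopf("n_components exceeds min(n, p) = %d", min(n, p))
    pc <- prcomp(X, center = TRUE, scale. = FALSE, rank. = n_components)
    ev <- pc$sdev^2
    list(scores = pc$x[, seq_len(n_components), drop = FALSE],
         loadings = pc$rotation[, seq_len(n_components), drop = FALSE],
         explained = ev / sum(ev),
         center = pc$center)
}
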