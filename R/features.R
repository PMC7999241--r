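FEATURE_NAMES <- c("c1", "c2", "c3", paste0("nir_", 1:11))

#' Assemble the 14-dimensional olive descriptor
#'
#' Concatenates the three c1c2c3 color ratios with the 11 band
#' reflectances, in fixed order (c1, c2, c3, then ascending wavelength).
#'
#' @param color numeric length-3 (c1, c2, c3) or an n x 3 matrix.
#' @param band numeric length-11 (band reflectances) or an n x 11 matrix.
#' @return numeric vector of length 14, or an n x 14 matrix, with the
#'   canonical column names.
#' @export
buildDescriptor <- function(color, band) {
    cm <- rbind(color); bm <- rbind(band)
    if (ncol(cm) != 3) stopf("color part must have 3 values (c1, c2, c3)")
    if (ncol(bm) != 11)
        stopf("band part must have 11 values, got %d", ncol(bm))
    if (nrow(cm) != nrow(bm)) stopf("color and band row counts differ")
    if (!all(is.finite(cm)) || !all(is.finite(bm)))
        stopf("descriptor values must be finite")
    out <- cbind(cm, bm)
    colnames(out) <- FEATURE_NAMES
    if (is.null(dim(color)) && is.null(dim(band))) out[1, ] else out
}

#' Fit a column z-scoring model
#'
#' Stores per-column mean and standard deviation of the training
#' population, for the standardization Z = (x - mean)/sd. Sample SD
#' (n-1 denominator) is the default; population SD is available.
#'
#' @param X numeric matrix (n >= 2 rows); constant columns are an error.
#' @param type `"sample"` (n-1) or `"population"` (n).
#' @return a [ZScoreModel].
#' @export
zscoreFit <- function(X, type = c("sample", "population")) {
    type <- match.arg(type)
    X <- as.matrix(X)
    if (nrow(X) < 2) stopf("z-scoring needs at least 2 rows")
    ctr <- colMeans(X)
    s <- apply(X, 2, sd)
    if (type == "population") s <- s * sqrt((nrow(X) - 1) / nrow(X))
    nm <- colnames(X) %||% paste0("x", seq_len(ncol(X)))
    bad <- which(!is.finite(s) | s == 0)
    if (length(bad))
        stopf("constant column(s) cannot be z-scored: %s",
              paste(nm[bad], collapse = ", "))
    methods::new("ZScoreModel", center = unname(ctr), scale = unname(s),
                 featureNames = nm)
}

#' Apply (or invert) a fitted z-scoring model
#'
#' @param model a [ZScoreModel].
#' @param X numeric vector (length p) or matrix (n x p).
#' @return standardized values, same shape as `X`.
#' @export
zscoreApply <- function(model, X) {
    stopifnot(is(model, "ZScoreModel"))
    p <- length(model@center)
    vec <- is.null(dim(X))
    m <- rbind(X)
    if (ncol(m) != p)
        stopf("expected %d columns, got %d", p, ncol(m))
    out <- sweep(sweep(m, 2, model@center), 2, model@scale, "/")
    colnames(out) <- model@featureNames
    if (vec) out[1, ] else out
}

#' @rdname zscoreApply
#' @export
zscoreInvert <- function(model, X) {
    stopifnot(is(model, "ZScoreModel"))
    vec <- is.null(dim(X))
    m <- rbind(X)
    if (ncol(m) != length(model@center))
        stopf("expected %d columns, got %d", length(model@center), ncol(m))
    out <- sweep(sweep(m, 2, model@scale, "*"), 2, model@center, "+")
    colnames(out) <- model@featureNames
    if (vec) out[1, ] else out
}
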