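#' Convert RGB values to the illumination-invariant c1c2c3 color model
#'
#' c1 = R/max(G,B), c2 = G/max(R,B), c3 = B/max(R,G). The ratios are
#' invariant to a positive scaling of all three channels, i.e. to uniform
#' illumination changes. To guard against zero denominators on dark pixels,
#' every channel is offset by `eps` (1 on the 0-255 scale, below sensor
#' noise) before dividing. An `arctan` variant common in the color
#' literature (atan of the same ratios) is available via `variant`.
#'
#' @param r,g,b channel values (scalars or equal-length vectors, >= 0).
#' @param eps additive guard offset applied to each channel.
#' @param variant `"ratio"` (default, values may exceed 1) or `"atan"`.
#' @return named matrix with columns c1, c2, c3 (one row per input pixel).
#' @examples
#' rgbToC1c2c3(200, 100, 50)            # (2, 0.5, 0.25) up to the eps guard
#' rgbToC1c2c3(c(60, 120), c(120, 240), c(40, 80))  # scale-invariant rows
#' @export
rgbToC1c2c3 <- function(r, g, b, eps = 1, variant = c("ratio", "atan")) {
    variant <- match.arg(variant)
    if (any(c(r, g, b) < 0)) stopf("RGB channels must be >= 0")
    r <- r + eps; g <- g + eps; b <- b + eps
    out <- cbind(c1 = r / pmax(g, b), c2 = g / pmax(r, b),
                 c3 = b / pmax(r, g))
    if (variant == "atan") out <- atan(out)
    out
}

# c3 plane of an H x W x 3 image (0-255), used for tray/background
# separation: fruit has c3 <= ~1, the bluish tray background well above 1.
c3Channel <- function(img, eps = 1) {
    (img[, , 3] + eps) / (pmax(img[, , 1], img[, , 2]) + eps)
}

#' Binarize a grayscale image with Otsu's threshold
#'
#' The threshold maximizes the between-class variance of the gray-level
#' histogram (256 bins over the observed range; computed with
#' \pkg{EBImage}). Foreground is the class darker or brighter than the
#' threshold according to `polarity`.
#'
#' @param gray numeric matrix.
#' @param polarity `"dark"` (foreground below threshold; the default, since
#'   fruit is darker than the tray in the c3 channel) or `"bright"`.
#' @param levels number of histogram levels.
#' @return logical mask, same shape; the threshold (original gray units) is
#'   attached as attribute `"threshold"`.
#' @export
binarizeOtsu <- function(gray, polarity = c("dark", "bright"), levels = 256) {
    polarity <- match.arg(polarity)
    rng <- range(gray)
    if (diff(rng) == 0)
        stopf("constant image: Otsu threshold is undefined")
    scaled <- (gray - rng[1]) / diff(rng)
    thr01 <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1),
                           levels = levels)
    thr <- rng[1] + thr01 * diff(rng)
    mask <- if (polarity == "dark") gray <= thr else gray > thr
    attr(mask, "threshold") <- thr
    mask
}

#' Morphologically clean a binary mask
#'
#' Closing followed by opening with a disk structuring element of the given
#' radius; removes protrusions (stems) and closes pits thinner than the
#' disk without deforming the fruit outline. Idempotent on already-clean
#' convex blobs; an empty mask passes through.
#'
#' @param mask logical matrix.
#' @param radius disk radius in pixels (>= 1).
#' @return logical matrix.
#' @export
cleanMask <- function(mask, radius = 3) {
    if (radius < 1) stopf("disk radius must be >= 1")
    if (!any(mask)) return(mask)
    brush <- EBImage::makeBrush(2 * as.integer(radius) + 1, shape = "disc")
    m <- EBImage::opening(EBImage::closing(mask * 1, brush), brush)
    m > 0.5
}

#' Segment individual olives from a tray image
#'
#' Separates fruit from tray on the c3 channel (Otsu threshold, dark
#' polarity), cleans the mask morphologically, labels connected components
#' and assigns each blob to the nearest tray hole. Two blobs claiming one
#' hole is an ambiguity error.
#'
#' @param img RGB array `height x width x 3` (0-255).
#' @param layout a [trayLayout()].
#' @param radius disk radius for [cleanMask()].
#' @param min_area components below this pixel area are discarded as noise.
#' @param min_contrast minimum c3 gap between the background and foreground
#'   class means; below it the image is treated as fruit-free (an Otsu
#'   threshold always exists, even on an empty tray whose histogram is pure
#'   background noise).
#' @return list of olive regions; each is a list with `hole`, `area`,
#'   `centroid` (row, col), `bbox` (rmin, rmax, cmin, cmax), `mean_rgb`,
#'   and the logical pixel `mask` (full image size). An empty tray gives an
#'   empty list.
#' @export
segmentOlives <- function(img, layout = trayLayout(), radius = 3,
                          min_area = 40, min_contrast = 0.15) {
    c3 <- c3Channel(img)
    mask <- tryCatch(binarizeOtsu(c3, polarity = "dark"),
                     error = function(e) NULL)
    if (is.null(mask) || !any(mask) || all(mask)) return(list())
    if (mean(c3[!mask]) - mean(c3[mask]) < min_contrast) return(list())
    mask <- cleanMask(mask, radius)
    lab <- EBImage::bwlabel(mask * 1)
    nlab <- max(lab)
    if (nlab == 0) return(list())
    regions <- list()
    taken <- integer(0)
    for (l in seq_len(nlab)) {
        idx <- which(lab == l, arr.ind = TRUE)
        if (nrow(idx) < min_area) next
        ctr <- colMeans(idx)
        d2 <- (layout$centers[, 1] - ctr[1])^2 +
              (layout$centers[, 2] - ctr[2])^2
        hole <- which.min(d2)
        if (hole %in% taken)
            stopf("ambiguous segmentation: two blobs map to hole %d", hole)
        taken <- c(taken, hole)
        lin <- (idx[, 2] - 1L) * nrow(lab) + idx[, 1L]
        npix <- nrow(idx)
        mrgb <- vapply(1:3, function(ch)
            mean(img[, , ch][lin]), numeric(1))
        m <- matrix(FALSE, nrow(lab), ncol(lab))
        m[lin] <- TRUE
        regions[[length(regions) + 1L]] <- list(
            hole = hole, area = npix, centroid = ctr,
            bbox = c(rmin = min(idx[, 1]), rmax = max(idx[, 1]),
                     cmin = min(idx[, 2]), cmax = max(idx[, 2])),
            mean_rgb = stats::setNames(mrgb, c("r", "g", "b")), mask = m)
    }
    if (layout$n_holes < length(regions))
        stopf("more blobs than tray holes")
    regions[order(vapply(regions, `[[`, integer(1), "hole"))]
}

# Shape statistics of a region mask: pixel area, solidity (area over convex
# hull area, hull dilated half a pixel per side to stay commensurate with
# pixel counting), and ellipse-fit eccentricity from central moments.
regionShape <- function(mask) {
    idx <- which(mask, arr.ind = TRUE)
    n <- nrow(idx)
    if (n == 0) stopf("empty region mask")
    ecc <- 0
    if (n > 2) {
        cc <- scale(idx, scale = FALSE)
        S <- crossprod(cc) / n
        ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
        if (ev[1] > 0) ecc <- sqrt(max(0, 1 - ev[2] / ev[1]))
    }
    hull <- grDevices::chull(idx[, 2], idx[, 1])
    hx <- idx[hull, 2]; hy <- idx[hull, 1]
    harea <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
    hper <- sum(sqrt(diff(c(hx, hx[1]))^2 + diff(c(hy, hy[1]))^2))
    hull_pix <- harea + hper / 2 + 1          # Pick-style pixel-count hull area
    list(area = n, solidity = min(1, n / hull_pix), eccentricity = ecc)
}

#' Decide whether a segmented olive is defective
#'
#' Rejects regions whose shape departs from a clean convex fruit outline:
#' solidity (pixel area over convex-hull area) below `s_min`, or
#' ellipse-fit eccentricity above `e_max`. Deterministic.
#'
#' @param region a region from [segmentOlives()] (or any list with a
#'   logical `mask`).
#' @param s_min minimum solidity accepted.
#' @param e_max maximum eccentricity accepted.
#' @return `TRUE` when the olive should be rejected; shape statistics
#'   attached as attribute `"shape"`.
#' @export
rejectDefective <- function(region, s_min = 0.90, e_max = 0.85) {
    sh <- regionShape(region$mask)
    out <- sh$solidity < s_min || sh$eccentricity > e_max
    attr(out, "shape") <- sh
    out
}

#' Mean c1c2c3 descriptor of a segmented olive
#'
#' Per-pixel c1c2c3 values over the region mask, averaged arithmetically
#' into one descriptor per olive.
#'
#' @param img RGB array (0-255).
#' @param region a region from [segmentOlives()].
#' @param ... passed to [rgbToC1c2c3()].
#' @return named numeric vector (c1, c2, c3).
#' @export
oliveColorDescriptor <- function(img, region, ...) {
    lin <- which(region$mask)
    if (length(lin) == 0) stopf("empty region mask")
    px <- rgbToC1c2c3(img[, , 1][lin], img[, , 2][lin], img[, , 3][lin], ...)
    colMeans(px)
}
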