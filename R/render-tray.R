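#' Geometry of a 24-hole measurement tray
#'
#' Hole centers on a regular grid, row-major, 1-based (hole 1 is top-left).
#' The defaults give a compact tray image in which fruit blobs never touch.
#'
#' @param nrow,ncol grid shape (`nrow * ncol` holes, default 4 x 6 = 24).
#' @param cell cell edge in pixels.
#' @param margin outer margin in pixels.
#' @param radius nominal olive semi-major axis in pixels.
#' @return list with the grid parameters, image `width`/`height`, and an
#'   `n_holes x 2` matrix `centers` of (row, col) pixel centers.
#' @export
trayLayout <- function(nrow = 4L, ncol = 6L, cell = 46L, margin = 8L,
                       radius = 13) {
    holes <- nrow * ncol
    idx <- seq_len(holes) - 1L
    cy <- margin + cell * (idx %/% ncol + 0.5)
    cx <- margin + cell * (idx %% ncol + 0.5)
    list(nrow = nrow, ncol = ncol, cell = cell, margin = margin,
         radius = radius, n_holes = holes,
         height = 2L * margin + nrow * cell, width = 2L * margin + ncol * cell,
         centers = cbind(row = cy, col = cx))
}

# Default tray background: bluish, so the c3 = B/max(R,G) channel separates
# fruit (c3 <= ~1) from tray (c3 > 1.3) bimodally.
TRAY_BACKGROUND <- c(150, 160, 230)

#' Render a tray image from olive colors
#'
#' Draws one near-elliptical colored blob per occupied hole on the tray
#' background, with mild per-olive shape variation and per-pixel noise.
#' Defects emulating field artifacts can be injected: `"stem"` (thin
#' peduncle protruding from the fruit), `"notch"` (a bite-shaped concavity,
#' solidity well below 0.9) and `"elongated"` (an implausibly eccentric
#' blob). Deterministic under `seed`.
#'
#' @param colors numeric matrix `n x 3` of RGB skin colors (0-255 scale),
#'   one row per olive; `n <= layout$n_holes`.
#' @param layout a [trayLayout()].
#' @param holes integer vector assigning each olive to a hole (default
#'   `1..n`); duplicates are an error.
#' @param defects list of `list(hole =, type =)` entries with type one of
#'   `"stem"`, `"notch"`, `"elongated"`.
#' @param seed integer seed for shape jitter and pixel noise.
#' @param background background RGB (0-255).
#' @param noise_sd per-pixel Gaussian noise SD (0-255 scale).
#' @return array `height x width x 3` of RGB values in [0, 255].
#' @export
renderTray <- function(colors, layout = trayLayout(), holes = NULL,
                       defects = list(), seed = 1,
                       background = TRAY_BACKGROUND, noise_sd = 2) {
    colors <- rbind(colors)
    n <- nrow(colors)
    if (n > layout$n_holes)
        stopf("%d olives exceed the %d-hole tray", n, layout$n_holes)
    if (is.null(holes)) holes <- seq_len(n)
    if (anyDuplicated(holes))
        stopf("two olives assigned to the same hole")
    if (any(holes < 1 | holes > layout$n_holes))
        stopf("hole index outside the tray")
    deftype <- rep(NA_character_, layout$n_holes)
    for (d in defects) deftype[d$hole] <- match.arg(d$type,
        c("stem", "notch", "elongated"))

    H <- layout$height; W <- layout$width
    img <- withSeed(seed, {
        img <- array(rnorm(H * W * 3, 0, noise_sd), dim = c(H, W, 3))
        img <- sweep(img, 3, background, "+")
        for (i in seq_len(n)) {
            ctr <- layout$centers[holes[i], ]
            a <- layout$radius * runif(1, 0.9, 1.05)
            ratio <- runif(1, 0.75, 0.92)
            if (identical(deftype[holes[i]], "elongated")) ratio <- 0.32
            th <- runif(1, 0, pi)
            mask <- ellipseMask(H, W, ctr[1], ctr[2], a, a * ratio, th)
            if (identical(deftype[holes[i]], "notch")) {
                # deep slot from the rim toward the center, wide enough to
                # survive morphological closing
                y <- matrix(seq_len(H), H, W) - ctr[1]
                xg <- matrix(seq_len(W), H, W, byrow = TRUE) - ctr[2]
                xr <- xg * cos(th) + y * sin(th)
                yr <- -xg * sin(th) + y * cos(th)
                mask <- mask & !(xr > 0.05 * a & abs(yr) <= 0.38 * a)
            }
            if (identical(deftype[holes[i]], "stem")) {
                sx <- round(ctr[2] + (a * ratio) * 0.2)
                rows <- round(ctr[1] + a * 0.5 + seq(0, 7))
                rows <- rows[rows >= 1 & rows <= H]
                mask[rows, sx] <- TRUE
            }
            idx <- which(mask)
            for (ch in 1:3) {
                plane <- img[, , ch]
                plane[idx] <- clamp(colors[i, ch] +
                                    rnorm(length(idx), 0, 3), 0, 255)
                img[, , ch] <- plane
            }
        }
        img
    })
    clamp(img, 0, 255)
}

# Logical H x W mask of a rotated ellipse (center cy,cx; semi-axes a >= b).
ellipseMask <- function(H, W, cy, cx, a, b, theta) {
    y <- matrix(seq_len(H), H, W) - cy
    x <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
    xr <- x * cos(theta) + y * sin(theta)
    yr <- -x * sin(theta) + y * cos(theta)
    (xr / a)^2 + (yr / b)^2 <= 1
}

#' Render all tray images of a synthetic season
#'
#' One image per (week, tray) group of the season, drawn from the ground
#' truth skin colors, in tray order.
#'
#' @param x an [OliveSet] from [generateSeason()].
#' @param layout a [trayLayout()]; its hole count must match the config.
#' @param seed base seed (one stream per tray).
#' @return named list of RGB arrays, names `"w<week>_t<tray>"`.
#' @export
renderSeasonTrays <- function(x, layout = trayLayout(), seed = 1) {
    cd <- SummarizedExperiment::colData(x)
    if (max(cd$hole) > layout$n_holes)
        stopf("layout has %d holes but season uses %d", layout$n_holes,
              max(cd$hole))
    groups <- split(seq_len(ncol(x)), list(week = cd$week, tray = cd$tray),
                    drop = TRUE)
    out <- lapply(seq_along(groups), function(g) {
        i <- groups[[g]]
        renderTray(as.matrix(cd[i, c("r", "g", "b")]), layout = layout,
                   holes = cd$hole[i], seed = deriveSeed(seed, g))
    })
    key <- vapply(groups, function(i)
        sprintf("w%02d_t%03d", cd$week[i[1]], cd$tray[i[1]]), character(1))
    names(out) <- key
    out[order(key)]
}
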