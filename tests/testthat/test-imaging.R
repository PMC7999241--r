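test_that("c1c2c3 ratios follow the defining formula", {
    d <- rgbToC1c2c3(100, 100, 100)
    expect_equal(unname(d[1, ]), c(1, 1, 1))
    # eps guard: evaluate at the printed ratios with the +1 offset
    d <- rgbToC1c2c3(200, 100, 50, eps = 0)
    expect_equal(unname(d[1, ]), c(2, 0.5, 0.25))
    expect_error(rgbToC1c2c3(-1, 0, 0), ">= 0")
    # black pixel does not divide by zero thanks to the guard
    expect_true(all(is.finite(rgbToC1c2c3(0, 0, 0))))
})

test_that("c1c2c3 is invariant to uniform illumination scaling", {
    set.seed(42)
    for (i in 1:1000) {
        rgb <- runif(3, 1, 255)
        s <- runif(1, 0.2, 4)
        a <- rgbToC1c2c3(rgb[1], rgb[2], rgb[3], eps = 0)
        b <- rgbToC1c2c3(s * rgb[1], s * rgb[2], s * rgb[3], eps = 0)
        expect_equal(a, b, tolerance = 1e-12)
    }
    # the documented example pair: same olive under doubled illumination
    expect_equal(rgbToC1c2c3(60, 120, 40, eps = 0),
                 rgbToC1c2c3(120, 240, 80, eps = 0))
})

test_that("Otsu binarization matches the exhaustive threshold oracle", {
    # two-level image: background 10 on 60% of pixels, foreground 200 on 40%
    g <- matrix(10, 50, 50)
    g[1:50, 1:20] <- 200
    m <- binarizeOtsu(g, polarity = "bright")
    expect_identical(as.vector(m), as.vector(g == 200))
    # threshold agrees with exhaustive between-class-variance search
    set.seed(7)
    for (i in 1:5) {
        g <- matrix(c(rnorm(600, 30, 8), rnorm(400, 180, 20)), 25, 40)
        m <- binarizeOtsu(g, polarity = "bright")
        thr <- attr(m, "threshold")
        expect_equal(thr, otsuExhaustive(g), tolerance = diff(range(g)) / 128)
        expect_identical(as.vector(m), as.vector(g > thr))
    }
    expect_error(binarizeOtsu(matrix(5, 4, 4)), "constant")
})

test_that("mask cleaning removes stems and is idempotent", {
    disk <- oliveOC:::ellipseMask(60, 60, 30, 30, 20, 20, 0)
    # a clean disk is (essentially) unchanged: boundary shifts < 2% of area
    expect_lt(sum(xor(cleanMask(disk, 3), disk)) / sum(disk), 0.02)
    stem <- disk
    stem[5:10, 30] <- TRUE                               # 1-px-wide stem
    cleaned <- cleanMask(stem, 3)
    expect_lt(abs(sum(cleaned) - sum(disk)) / sum(disk), 0.05)
    expect_false(any(cleaned[5:8, 30]))   # stem gone (bar a nub at the body)
    expect_identical(cleanMask(cleaned, 3), cleaned)     # idempotent
    empty <- matrix(FALSE, 10, 10)
    expect_identical(cleanMask(empty, 3), empty)
    expect_error(cleanMask(disk, 0), "radius")
})

test_that("a rendered 24-olive tray segments into 24 uniquely-holed regions", {
    os <- generateSeason(tinyConfig(), seed = 9)
    cd <- groundTruth(os)
    i <- which(cd$tray == 1)
    img <- renderTray(as.matrix(cd[i, c("r", "g", "b")]), holes = cd$hole[i],
                      seed = 5)
    regions <- segmentOlives(img)
    expect_length(regions, 24L)
    expect_setequal(vapply(regions, `[[`, 1L, "hole"), 1:24)
    areas <- vapply(regions, `[[`, 1L, "area")
    expect_true(all(areas > 100))
    # recovered mean color close to the rendered color
    mrgb <- t(vapply(regions, `[[`, numeric(3), "mean_rgb"))
    expect_lt(max(abs(mrgb - as.matrix(cd[i, c("r", "g", "b")]))), 6)
})

test_that("empty trays and ambiguous blobs are handled", {
    empty <- renderTray(matrix(numeric(0), 0, 3), seed = 1)
    expect_length(segmentOlives(empty), 0L)
    # two separated blobs inside one hole's area -> ambiguity error
    lay <- trayLayout(radius = 8)
    img <- renderTray(matrix(c(60, 120, 40), 1), layout = lay, seed = 2)
    ctr <- lay$centers[1, ]
    extra <- oliveOC:::ellipseMask(lay$height, lay$width,
                                   ctr[1], ctr[2] + 20, 4, 4, 0)
    for (ch in 1:3) {
        plane <- img[, , ch]
        plane[extra] <- c(60, 120, 40)[ch]
        img[, , ch] <- plane
    }
    expect_error(segmentOlives(img, layout = lay, min_area = 30), "ambiguous")
    expect_error(renderTray(matrix(0, 2, 3), holes = c(3, 3)), "same hole")
})

test_that("defect rejection: clean accepted, notch and elongation rejected", {
    cols <- matrix(rep(c(70, 110, 50), each = 6), 6, 3)
    defects <- list(list(hole = 2, type = "notch"),
                    list(hole = 4, type = "elongated"),
                    list(hole = 6, type = "notch"))
    img <- renderTray(cols, defects = defects, seed = 31)
    regions <- segmentOlives(img)
    expect_length(regions, 6L)
    rej <- vapply(regions, rejectDefective, logical(1))
    holes <- vapply(regions, `[[`, 1L, "hole")
    expect_equal(sum(rej), 3L)                       # exactly the 3 injected
    expect_setequal(holes[rej], c(2L, 4L, 6L))
    sh <- attr(rejectDefective(regions[[which(holes == 2)]]), "shape")
    expect_lt(sh$solidity, 0.9)
    sh4 <- attr(rejectDefective(regions[[which(holes == 4)]]), "shape")
    expect_gt(sh4$eccentricity, 0.85)
})

test_that("per-olive color descriptor averages per-pixel c1c2c3", {
    img <- array(0, c(4, 4, 3))
    img[1, 1, ] <- c(100, 100, 100)
    img[1, 2, ] <- c(200, 100, 50)
    # single-pixel mask equals the pixel's own descriptor
    r1 <- list(mask = matrix(c(TRUE, rep(FALSE, 15)), 4, 4))
    expect_equal(oliveColorDescriptor(img, r1),
                 rgbToC1c2c3(100, 100, 100)[1, ])
    # two-pixel mask: arithmetic mean of the two descriptors
    m2 <- matrix(FALSE, 4, 4); m2[1, 1] <- TRUE; m2[1, 2] <- TRUE
    a <- rgbToC1c2c3(100, 100, 100)[1, ]
    b <- rgbToC1c2c3(200, 100, 50)[1, ]
    expect_equal(oliveColorDescriptor(img, list(mask = m2)), (a + b) / 2)
    expect_error(oliveColorDescriptor(img, list(mask = matrix(FALSE, 4, 4))),
                 "empty")
})
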