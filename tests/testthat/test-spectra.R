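grid512 <- seq(900, 2200, length.out = 512)

test_that("replicate averaging is the pointwise mean on a shared grid", {
    a <- matrix(0.1, 5, 2); b <- matrix(0.2, 5, 2); c <- matrix(0.3, 5, 2)
    expect_equal(averageReplicates(list(a, b, c)), matrix(0.2, 5, 2))
    expect_equal(averageReplicates(list(a, a, a)), a)
    expect_error(averageReplicates(list(a, matrix(0.2, 4, 2))), "grid")
    os <- generateSeason(tinyConfig(), seed = 1)
    os <- averageReplicates(os)
    expect_true("reflectance" %in% SummarizedExperiment::assayNames(os))
    expect_equal(reflectance(os),
                 (SummarizedExperiment::assay(os, "rep1") +
                  SummarizedExperiment::assay(os, "rep2") +
                  SummarizedExperiment::assay(os, "rep3")) / 3)
})

test_that("SNV standardizes each spectrum and is affine-invariant", {
    set.seed(3)
    x <- rnorm(512)
    s <- snv(x)
    expect_equal(mean(s), 0, tolerance = 1e-10)
    expect_equal(sd(s), 1, tolerance = 1e-10)
    expect_equal(snv(3 + 2 * x), s, tolerance = 1e-10)     # affine invariance
    expect_equal(snv(s), s, tolerance = 1e-10)             # idempotence
    m <- matrix(rnorm(512 * 4), 512, 4)
    sm <- snv(m)
    expect_equal(colMeans(sm), rep(0, 4), tolerance = 1e-10)
    expect_equal(apply(sm, 2, sd), rep(1, 4), tolerance = 1e-10)
    expect_error(snv(rep(1, 100)), "constant")
})

test_that("Savitzky-Golay second derivative is exact on polynomials", {
    wl <- grid512
    half <- 5L
    interior <- (half + 1):(512 - half)
    # quadratic 2 + 3*wl^2 -> second derivative 6 everywhere in the interior
    d <- secondDerivative(2 + 3 * wl^2, wl)
    expect_equal(d[interior], rep(6, length(interior)), tolerance = 1e-8)
    expect_true(all(is.na(d[c(1:half, (512 - half + 1):512)])))
    # linear -> 0
    d <- secondDerivative(5 - 0.01 * wl, wl)
    expect_equal(d[interior], rep(0, length(interior)), tolerance = 1e-10)
    # exactness up to the polynomial order (cubic with polyorder 3)
    d <- secondDerivative(wl^3 / 1e6, wl, window = 11, polyorder = 3)
    expect_equal(d[interior], 6 * wl[interior] / 1e6, tolerance = 1e-8)
})

test_that("second derivative localizes a Gaussian dip at the band center", {
    wl <- grid512
    spec <- 0.5 - 0.2 * exp(-(wl - 1725)^2 / (2 * 15^2))
    d <- secondDerivative(spec, wl)
    # dip curvature is maximal (positive 2nd derivative of -Gaussian) at center
    peak <- wl[which.max(d)]
    expect_lt(abs(peak - 1725), diff(wl)[1] + 1e-9)
    expect_error(secondDerivative(spec, wl, window = 10), "odd")
    expect_error(secondDerivative(spec, wl, window = 3, polyorder = 4),
                 "exceed")
    expect_error(secondDerivative(spec[1:5], wl[1:5], window = 11), "shorter")
})

test_that("band selection yields 11 points on the instrument grid", {
    band <- selectBand(grid512)
    expect_s3_class(band, "BandSelection")
    expect_equal(band$n, 11L)
    expect_equal(band$nominal, 1710 + 2.53 * (0:10))
    expect_equal(diff(band$nominal), rep(2.53, 10))
    expect_false(anyDuplicated(band$index) > 0)
    expect_lt(max(abs(band$grid - band$nominal)), diff(grid512)[1] / 2 + 1e-9)
    # degenerate and endpoint cases
    expect_equal(selectBand(grid512, 1710, 1710, 2.53)$n, 1L)
    expect_equal(selectBand(grid512, 1710, 1735, 25)$nominal, c(1710, 1735))
    expect_error(selectBand(grid512, 800, 1735), "outside")
    expect_error(selectBand(grid512, 1710, 1735, step = 0.5), "too small")
})

test_that("band count follows the nominal-spacing rule on dense grids", {
    dense <- seq(1000, 2000, by = 0.5)
    for (step in c(2, 3.7, 10)) {
        b <- selectBand(dense, 1500, 1550, step)
        expect_equal(b$n, floor(50 / step + 0.5) + 1)
    }
})

test_that("band values extract ascending-wavelength reflectances per olive", {
    os <- averageReplicates(generateSeason(tinyConfig(), seed = 2))
    band <- selectBand(wavelengths(os))
    v <- bandValues(os, band)
    expect_equal(dim(v), c(48L, 11L))
    expect_equal(colnames(v), paste0("nir_", 1:11))
    expect_equal(unname(v[3, ]), unname(reflectance(os)[band$index, 3]))
})

test_that("PCA: orthonormal loadings, ordered variance, exact reconstruction", {
    set.seed(9)
    X <- matrix(rnorm(40 * 12), 40, 12)
    pc <- spectraPCA(X, n_components = 12)
    expect_equal(crossprod(pc$loadings), diag(12), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_true(all(diff(pc$explained) <= 1e-12))
    Xc <- scale(X, center = TRUE, scale = FALSE)
    expect_equal(pc$scores %*% t(pc$loadings), Xc, tolerance = 1e-8,
                 ignore_attr = TRUE)
    # rank-1 matrix: first component carries all the variance
    r1 <- outer(rnorm(30), rnorm(12))
    p1 <- spectraPCA(r1, n_components = 2)
    expect_equal(p1$explained[1], 1, tolerance = 1e-8)
    expect_error(spectraPCA(X, n_components = 13), "exceeds")
    expect_error(spectraPCA(X[1, , drop = FALSE]), "two spectra")
})
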