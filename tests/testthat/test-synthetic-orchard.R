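test_that("default season accounting: weeks x trays x holes olives", {
    cfg <- syntheticConfig()
    expect_equal(cfg$olives_per_week, 600L)
    expect_equal(cfg$n_weeks * cfg$olives_per_week, 3000L)
    os <- generateSeason(tinyConfig(), seed = 3)
    expect_s4_class(os, "OliveSet")
    expect_equal(ncol(os), 48L)
    expect_equal(nrow(os), 512L)
    cd <- groundTruth(os)
    expect_equal(nrow(cd), 48L)
    expect_true(all(cd$true_oc >= 0))
    expect_true(all(cd$maturity >= 0 & cd$maturity <= 1))
    expect_true(all(cd[, c("r", "g", "b")] >= 0 & cd[, c("r", "g", "b")] <= 255))
    # one olive per (week, tray, hole)
    expect_false(anyDuplicated(cd[, c("week", "tray", "hole")]) > 0)
})

test_that("generation is bit-identical under a fixed config and seed", {
    cfg <- tinyConfig()
    a <- generateSeason(cfg, seed = 11)
    b <- generateSeason(cfg, seed = 11)
    expect_identical(SummarizedExperiment::assay(a, "rep2"),
                     SummarizedExperiment::assay(b, "rep2"))
    expect_identical(groundTruth(a), groundTruth(b))
    c <- generateSeason(cfg, seed = 12)
    expect_false(identical(SummarizedExperiment::assay(a, "rep1"),
                           SummarizedExperiment::assay(c, "rep1")))
})

test_that("config invariants are enforced", {
    expect_error(syntheticConfig(n_weeks = 0), "positive")
    expect_error(syntheticConfig(oc_noise_sd = -1), "noise")
    expect_error(syntheticConfig(maturity_range = c(0.5, 1.5)), "maturity")
    expect_error(syntheticConfig(season_shift = list(baseline_offset = Inf,
                                                     slope_delta = 0,
                                                     band_center_shift = 0)),
                 "finite")
})

noiseless <- function(...) {
    tinyConfig(oc_noise_sd = 0, replicate_noise_sd = 0, color_jitter_sd = 0,
               baseline = list(intercept = 0.55, slope = -0.08,
                               curvature = -0.05, offset_sd = 0,
                               slope_sd = 0), ...)
}

test_that("band-center reflectance is strictly decreasing in true OC (no noise)", {
    os <- generateSeason(noiseless(), seed = 5)
    cd <- groundTruth(os)
    wl <- wavelengths(os)
    i1725 <- which.min(abs(wl - 1725))
    refl <- SummarizedExperiment::assay(os, "rep1")[i1725, ]
    ord <- order(cd$true_oc)
    expect_true(all(diff(refl[ord]) < 0))
})

test_that("zero band depth makes equal-maturity olives spectrally identical", {
    cfg <- noiseless(band_depth_per_oc = 0)
    os <- generateSeason(cfg, seed = 5)
    m <- SummarizedExperiment::assay(os, "rep1")
    expect_lt(max(apply(m, 1, function(r) diff(range(r)))), 1e-12)
    # and all three replicates agree when replicate noise is off
    expect_identical(m, SummarizedExperiment::assay(os, "rep3"))
})

test_that("season shift: zero is identity, offset adds exactly", {
    os <- generateSeason(tinyConfig(), seed = 8)
    m <- SummarizedExperiment::assay(os, "rep1")
    wl <- wavelengths(os)
    expect_equal(applySeasonShift(m, wl, list(baseline_offset = 0,
                                              slope_delta = 0,
                                              band_center_shift = 0)), m)
    up <- applySeasonShift(m, wl, list(baseline_offset = 0.05))
    expect_equal(up, m + 0.05)
    # slope term is 0 at the first wavelength, full at the last
    sl <- applySeasonShift(m, wl, list(slope_delta = 0.1))
    expect_equal(sl[1, ], m[1, ])
    expect_equal(sl[nrow(m), ], m[nrow(m), ] + 0.1)
    expect_error(applySeasonShift(m, wl, list(baseline_offset = NaN)), "finite")
})

test_that("band-center displacement moves the absorption minimum", {
    cfg <- noiseless()
    os <- generateSeason(cfg, seed = 2)
    wl <- wavelengths(os)
    v <- SummarizedExperiment::assay(os, "rep1")[, 1]
    baselineless <- function(x) x - mean(x[wl < 1500])
    dipAt <- function(x) wl[which.min(baselineless(x))]
    shifted <- applySeasonShift(v, wl, list(band_center_shift = 40))
    expect_equal(dipAt(shifted), dipAt(v) + 40, tolerance = 0.01)
})

test_that("shifted vs unshifted season separate in PCA of SNV spectra", {
    cfg <- smallConfig()
    seas <- simulateSeasons(cfg, seed = 4)
    X <- cbind(reflectance(averageReplicates(seas[[1]])),
               reflectance(averageReplicates(seas[[2]])))
    lab <- rep(c(1, 2), each = 240)
    pc <- spectraPCA(t(X), n_components = 2, preprocess = snv)
    acc <- sapply(1:2, function(k) {
        s <- pc$scores[, k]
        thr <- sort(s)
        best <- max(sapply(thr, function(t)
            max(mean((s <= t) == (lab == 1)), mean((s <= t) == (lab == 2)))))
        best
    })
    expect_gt(max(acc), 0.95)
})
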