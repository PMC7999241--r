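test_that("rmsecv matches the closed form", {
    expect_equal(rmsecv(c(1, 2, 3), c(1, 2, 3)), 0)
    expect_equal(rmsecv(c(0, 0), c(3, 4)), sqrt(12.5))   # errors 3 and 4
    expect_equal(rmsecv(5, 7), 2)                        # single pair
    set.seed(1)
    a <- rnorm(50); b <- rnorm(50)
    expect_equal(rmsecv(a, b), sqrt(mean((a - b)^2)), tolerance = 1e-12)
    expect_error(rmsecv(1:3, 1:2), "mismatch")
    expect_error(rmsecv(numeric(0), numeric(0)), "empty")
})

test_that("percent deviation is RMSE over the mean reference value", {
    expect_equal(deviationPct(0, c(50, 50)), 0)
    expect_equal(deviationPct(3.0, rep(50, 10)), 6)
    expect_equal(deviationPct(7.0, rep(53.8, 4)), 13.01, tolerance = 1e-3)
    expect_error(deviationPct(1, c(-2, 1)), "> 0")
})

test_that("LOOCV matches manual unrolling and handles edge cases", {
    X <- matrix(c(0, 1, 2, 0, 2, 1), 3, 2)
    y <- c(10, 20, 30)
    p <- svrParams(C = 5, gamma = 0.5, epsilon = 0.05)
    got <- loocvRmse(X, y, p)
    pred <- sapply(1:3, function(i) {
        zs <- zscoreFit(X[-i, , drop = FALSE])
        m <- svrFit(X[-i, , drop = FALSE], y[-i], p, zscore = zs)
        predictOC(m, X[i, , drop = FALSE])
    })
    expect_equal(got, rmsecv(y, pred))
    expect_gte(got, 0)
    # constant labels: every fold predicts the constant
    expect_equal(loocvRmse(X, rep(7, 3), p), 0)
    expect_error(loocvRmse(X[1, , drop = FALSE], 1, p), "n >= 2")
})

test_that("the scheme set enumerates the evaluation matrix", {
    sch <- defaultSchemes(c("2016", "2017"))
    expect_length(sch, 7L)
    nm <- vapply(sch, `[[`, "", "name")
    expect_setequal(nm, c("cross_2016_to_2017", "cross_2017_to_2016",
                          "within_2016_70_30", "within_2017_70_30",
                          "mixed_50_50", "mixed_70_30", "mixed_80_20"))
    reps <- vapply(sch, `[[`, 1L, "n_repeats")
    expect_equal(sort(unique(reps)), c(1L, 10L))
    expect_equal(sum(reps == 1L), 2L)    # the two deterministic cross schemes
})

test_that("splits are disjoint, sized by the fractions, and seeded", {
    roles <- list(`2016` = list(train = 0.7, test = 0.3))
    sp <- oliveOC:::drawSplit(list(`2016` = 100L), roles, seed = 3)
    expect_length(sp$`2016`$train, 70L)
    expect_length(sp$`2016`$test, 30L)
    expect_length(intersect(sp$`2016`$train, sp$`2016`$test), 0L)
    expect_identical(sp, oliveOC:::drawSplit(list(`2016` = 100L), roles,
                                             seed = 3))
    # 80/20: train and test never overlap over many seeded draws
    roles80 <- list(s = list(train = 0.8, test = 0.2))
    for (s in 1:20) {
        d <- oliveOC:::drawSplit(list(s = 57L), roles80, seed = s)$s
        expect_length(intersect(d$train, d$test), 0L)
        expect_lte(length(d$train) + length(d$test), 57L)
    }
})

make_two_season_data <- function(seed = 31) {
    seas <- simulateSeasons(smallConfig(), seed = seed)
    ds <- lapply(seq_along(seas), function(i)
        buildSeasonDataset(seas[[i]], seed = seed + i))
    names(ds) <- names(seas)
    ds
}

test_that("runScheme: repeat bookkeeping, determinism, fixed params", {
    ds <- make_two_season_data(31)
    sch <- defaultSchemes(names(ds))
    p <- svrParams(C = 10, gamma = 0.1, epsilon = 0.5)
    mixed <- runScheme(ds, sch[[7]], params = p, seed = 2)    # 80+80/20+20
    expect_s3_class(mixed, "EvalResult")
    expect_length(mixed$rmsecv, 10L)
    expect_equal(mixed$mean_rmsecv, mean(mixed$rmsecv))
    expect_equal(mixed$sd_rmsecv, sd(mixed$rmsecv))
    expect_true(all(mixed$rmsecv >= 0))
    again <- runScheme(ds, sch[[7]], params = p, seed = 2)
    expect_identical(mixed$rmsecv, again$rmsecv)
    # deterministic cross scheme runs once with no SD
    cross <- runScheme(ds, sch[[1]], params = p, seed = 2)
    expect_length(cross$rmsecv, 1L)
    expect_true(is.na(cross$sd_rmsecv))
    expect_error(runScheme(ds["2016"], sch[[1]], params = p), "requires")
})

test_that("a self-train sanity bound holds with near-noiseless labels", {
    # train and test on the same season with zero label noise: RMSECV of the
    # 100/100 'scheme' stays near the training error of the model itself
    os <- generateSeason(smallConfig(), seed = 41)
    d <- buildSeasonDataset(os, seed = 41, soxhlet_noise_sd = 0)
    p <- svrParams(C = 100, gamma = 0.1, epsilon = 0.1)
    zs <- zscoreFit(d$X)
    m <- svrFit(d$X, d$y, p, zscore = zs)
    train_rmse <- rmsecv(d$y, predictOC(m, d$X))
    scheme <- list(name = "self", n_repeats = 1L,
                   roles = list(a = list(train = 1, test = 0),
                                b = list(train = 0, test = 1)))
    # register the same season twice so train and test see identical olives
    ds <- list(a = d, b = d)
    res <- runScheme(ds, scheme, params = p, seed = 1)
    expect_equal(res$mean_rmsecv, train_rmse, tolerance = 0.15)
})

test_that("the full evaluation matrix reports every scheme row", {
    ds <- make_two_season_data(51)
    p <- svrParams(C = 10, gamma = 0.1, epsilon = 0.5)
    sch <- defaultSchemes(names(ds), n_repeats = 3)
    tab <- runAllSchemes(ds, schemes = sch, params = p, seed = 4)
    expect_equal(nrow(tab), 7L)
    expect_true(all(tab$mean_rmsecv > 0))
    expect_equal(tab$n_repeats, vapply(sch, `[[`, 1L, "n_repeats"))
    tab2 <- runAllSchemes(ds, schemes = sch, params = p, seed = 4)
    expect_identical(tab$mean_rmsecv, tab2$mean_rmsecv)
})
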