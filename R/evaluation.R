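#' Root mean square error (of cross-validation)
#'
#' @param y_true,y_pred equal-length numeric vectors (length >= 1).
#' @return `sqrt(mean((y_true - y_pred)^2))`, in percent dry matter when
#'   the inputs are OC values.
#' @export
rmsecv <- function(y_true, y_pred) {
    if (length(y_true) == 0) stopf("empty input")
    if (length(y_true) != length(y_pred)) stopf("length mismatch")
    sqrt(mean((y_true - y_pred)^2))
}

#' Percent deviation of an RMSE from the real value
#'
#' The RMSE expressed as a percentage of the mean reference OC of the
#' evaluated set: `100 * rmse / mean(y_true)`.
#'
#' @param rmse RMSE in percent dry matter.
#' @param y_true reference OC values of the evaluated set (mean must be
#'   > 0).
#' @return deviation in percent.
#' @export
deviationPct <- function(rmse, y_true) {
    m <- mean(y_true)
    if (!is.finite(m) || m <= 0) stopf("mean reference OC must be > 0")
    100 * rmse / m
}

#' Leave-one-out cross-validated RMSE of the SVR
#'
#' Fits on n-1 olives (re-fitting the z-scoring each time), predicts the
#' held-out olive, aggregates with [rmsecv()].
#'
#' @param X descriptor matrix (n >= 2).
#' @param y labels.
#' @param params an [svrParams()].
#' @param zscore logical: refit a [ZScoreModel] per fold (default TRUE).
#' @return LOOCV RMSE (percent dry matter).
#' @export
loocvRmse <- function(X, y, params = svrParams(), zscore = TRUE) {
    X <- as.matrix(X)
    n <- nrow(X)
    if (n < 2) stopf("LOOCV needs n >= 2")
    pred <- vapply(seq_len(n), function(i) {
        Xi <- X[-i, , drop = FALSE]
        zs <- if (zscore) zscoreFit(Xi) else NULL
        m <- svrFit(Xi, y[-i], params, zscore = zs)
        predictOC(m, X[i, , drop = FALSE])
    }, numeric(1))
    rmsecv(y, pred)
}

#' The train/test split schemes of the evaluation matrix
#'
#' Seven schemes: within-season 70/30 for each season; the two cross-season
#' directions (train on the whole of one season, test on the whole of the
#' other); and the mixed two-season splits 50+50/50+50, 70+70/30+30 and
#' 80+80/20+20. Randomized schemes are repeated `n_repeats` times
#' (default 10); the deterministic cross-season schemes run once.
#'
#' @param seasons two season labels.
#' @param n_repeats repeats for randomized schemes.
#' @return list of scheme definitions (name, per-season train/test
#'   fractions, repeats).
#' @export
defaultSchemes <- function(seasons = c("2016", "2017"), n_repeats = 10) {
    s1 <- seasons[1]; s2 <- seasons[2]
    frac <- function(train, test) list(train = train, test = test)
    mk <- function(name, roles, rep) list(name = name, roles = roles,
                                          n_repeats = as.integer(rep))
    list(
        mk(sprintf("cross_%s_to_%s", s1, s2),
           stats::setNames(list(frac(1, 0), frac(0, 1)), c(s1, s2)), 1L),
        mk(sprintf("cross_%s_to_%s", s2, s1),
           stats::setNames(list(frac(0, 1), frac(1, 0)), c(s1, s2)), 1L),
        mk(sprintf("within_%s_70_30", s1),
           stats::setNames(list(frac(0.7, 0.3)), s1), n_repeats),
        mk(sprintf("within_%s_70_30", s2),
           stats::setNames(list(frac(0.7, 0.3)), s2), n_repeats),
        mk("mixed_50_50",
           stats::setNames(list(frac(0.5, 0.5), frac(0.5, 0.5)), c(s1, s2)),
           n_repeats),
        mk("mixed_70_30",
           stats::setNames(list(frac(0.7, 0.3), frac(0.7, 0.3)), c(s1, s2)),
           n_repeats),
        mk("mixed_80_20",
           stats::setNames(list(frac(0.8, 0.2), frac(0.8, 0.2)), c(s1, s2)),
           n_repeats))
}

# Draw one train/test split for a scheme repeat. Olives are sampled
# uniformly within each season; train and test sets are always disjoint.
drawSplit <- function(sizes, roles, seed) {
    withSeed(seed, {
        out <- lapply(names(roles), function(s) {
            n <- sizes[[s]]
            r <- roles[[s]]
            perm <- sample.int(n)
            ntr <- round(r$train * n)
            nte <- round(r$test * n)
            if (ntr + nte > n) nte <- n - ntr
            list(train = sort(perm[seq_len(ntr)]),
                 test = sort(perm[ntr + seq_len(nte)]))
        })
        stats::setNames(out, names(roles))
    })
}

#' Run one evaluation scheme
#'
#' For each repeat: draw the season-wise train/test split from a derived
#' seed, optionally tune hyperparameters by [saSearch()] on the training
#' split, z-score on the training split, fit the SVR, predict the test
#' olives, and record the RMSECV and the percent deviation from the mean
#' reference value of the test set. Deterministic under `seed`.
#'
#' @param datasets named list (one per season) of `list(X = n x 14 raw
#'   descriptor matrix, y = propagated labels)`.
#' @param scheme one element of [defaultSchemes()].
#' @param params fixed [svrParams()], or `NULL` to tune by simulated
#'   annealing on each repeat's training split.
#' @param sa_schedule an [saSchedule()] used when `params` is `NULL`.
#' @param seed integer seed (fans out per repeat).
#' @return list of class `"EvalResult"`: scheme name, per-repeat RMSECV,
#'   `mean_rmsecv`, `sd_rmsecv`, `deviation_pct`, and the tuned parameters
#'   of the last repeat.
#' @export
runScheme <- function(datasets, scheme, params = NULL,
                      sa_schedule = saSchedule(), seed = 1) {
    need <- names(scheme$roles)
    missing <- setdiff(need, names(datasets))
    if (length(missing))
        stopf("scheme '%s' requires season(s): %s", scheme$name,
              paste(missing, collapse = ", "))
    sizes <- lapply(datasets, function(d) nrow(d$X))
    rmse <- dev <- numeric(scheme$n_repeats)
    last_params <- params
    for (rep in seq_len(scheme$n_repeats)) {
        sp <- drawSplit(sizes[need], scheme$roles,
                        seed = deriveSeed(seed, 5000L + rep))
        Xtr <- do.call(rbind, lapply(need, function(s)
            datasets[[s]]$X[sp[[s]]$train, , drop = FALSE]))
        ytr <- unlist(lapply(need, function(s)
            datasets[[s]]$y[sp[[s]]$train]), use.names = FALSE)
        Xte <- do.call(rbind, lapply(need, function(s)
            datasets[[s]]$X[sp[[s]]$test, , drop = FALSE]))
        yte <- unlist(lapply(need, function(s)
            datasets[[s]]$y[sp[[s]]$test]), use.names = FALSE)
        p <- params
        if (is.null(p)) {
            sch <- sa_schedule
            sch$seed <- deriveSeed(seed, 9000L + rep)
            p <- saSearch(Xtr, ytr, schedule = sch)
        }
        zs <- zscoreFit(Xtr)
        model <- svrFit(Xtr, ytr, p, zscore = zs)
        pred <- predictOC(model, Xte)
        rmse[rep] <- rmsecv(yte, pred)
        dev[rep] <- deviationPct(rmse[rep], yte)
        last_params <- p
    }
    structure(list(scheme = scheme$name, rmsecv = rmse,
                   mean_rmsecv = mean(rmse),
                   sd_rmsecv = if (length(rmse) > 1) sd(rmse) else NA_real_,
                   deviation_pct = mean(dev), n_repeats = scheme$n_repeats,
                   params = last_params),
              class = "EvalResult")
}

#' @export
print.EvalResult <- function(x, ...) {
    cat(sprintf("%-22s RMSECV %.2f", x$scheme, x$mean_rmsecv))
    if (!is.na(x$sd_rmsecv)) cat(sprintf(" (SD %.2f, %d repeats)",
                                         x$sd_rmsecv, x$n_repeats))
    cat(sprintf(", deviation %.1f%%\n", x$deviation_pct))
    invisible(x)
}

#' Run the full evaluation matrix
#'
#' All schemes of [defaultSchemes()] on the per-season datasets, collected
#' into a table shaped like the study's evaluation matrix.
#'
#' @inheritParams runScheme
#' @param schemes list of scheme definitions.
#' @return data.frame: scheme, n_repeats, mean_rmsecv, sd_rmsecv,
#'   deviation_pct; per-scheme `EvalResult`s attached as attribute
#'   `"results"`.
#' @export
runAllSchemes <- function(datasets, schemes = defaultSchemes(names(datasets)),
                          params = NULL, sa_schedule = saSchedule(),
                          seed = 1) {
    res <- lapply(seq_along(schemes), function(i)
        runScheme(datasets, schemes[[i]], params = params,
                  sa_schedule = sa_schedule,
                  seed = deriveSeed(seed, 40L + i)))
    tab <- data.frame(
        scheme = vapply(res, `[[`, "", "scheme"),
        n_repeats = vapply(res, `[[`, 1L, "n_repeats"),
        mean_rmsecv = vapply(res, `[[`, 1, "mean_rmsecv"),
        sd_rmsecv = vapply(res, `[[`, 1, "sd_rmsecv"),
        deviation_pct = vapply(res, `[[`, 1, "deviation_pct"))
    attr(tab, "results") <- res
    tab
}
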