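#' SVR hyperparameters
#'
#' @param C penalty (> 0).
#' @param gamma RBF kernel width (> 0).
#' @param epsilon insensitive-tube half-width (>= 0).
#' @return validated list of class `"SvrParams"`.
#' @export
svrParams <- function(C = 1, gamma = 1 / 14, epsilon = 0.1) {
    if (C <= 0 || gamma <= 0 || epsilon < 0)
        stopf("require C > 0, gamma > 0, epsilon >= 0")
    structure(list(C = C, gamma = gamma, epsilon = epsilon),
              class = "SvrParams")
}

#' Simulated-annealing schedule
#'
#' Geometric cooling with Gaussian proposals in log-parameter space.
#'
#' @param initial_temperature starting temperature (in scorer units, i.e.
#'   percent dry matter of RMSE).
#' @param cooling_factor multiplicative temperature decay in (0, 1).
#' @param steps_per_temperature proposals between cooling steps.
#' @param total_iterations total proposals.
#' @param proposal_scale SD of the log-space Gaussian proposal.
#' @param seed integer seed.
#' @return validated list of class `"SaSchedule"`.
#' @export
saSchedule <- function(initial_temperature = 1.0, cooling_factor = 0.95,
                       steps_per_temperature = 5, total_iterations = 200,
                       proposal_scale = 0.3, seed = 1) {
    if (initial_temperature <= 0 || proposal_scale <= 0 ||
        steps_per_temperature < 1 || total_iterations < 0)
        stopf("schedule parameters must be positive")
    if (cooling_factor <= 0 || cooling_factor >= 1)
        stopf("cooling_factor must lie in (0, 1)")
    structure(list(initial_temperature = initial_temperature,
                   cooling_factor = cooling_factor,
                   steps_per_temperature = as.integer(steps_per_temperature),
                   total_iterations = as.integer(total_iterations),
                   proposal_scale = proposal_scale,
                   seed = as.integer(seed)),
              class = "SaSchedule")
}

#' Default log-space hyperparameter search box
#'
#' @return list of length-2 ranges for C, gamma and epsilon.
#' @export
svrBounds <- function() {
    list(C = c(1e-2, 1e4), gamma = c(1e-4, 1e1), epsilon = c(1e-3, 1e1))
}

#' Fit the epsilon-SVR oil-content model
#'
#' Epsilon-insensitive support vector regression with an RBF kernel
#' (`"linear"` and `"polynomial"` available), solved by the standard dual
#' (\pkg{libsvm} via \pkg{e1071}); deterministic for fixed inputs. When a
#' [ZScoreModel] is supplied, `X` is standardized before fitting and the
#' model is stored so [predictOC()] standardizes new descriptors
#' identically. A degenerate response (all labels equal) yields a
#' constant-predicting model rather than an error.
#'
#' @param X numeric matrix (n x p) of descriptors (raw if `zscore` given,
#'   already standardized otherwise).
#' @param y oil-content labels (percent dry matter).
#' @param params an [svrParams()].
#' @param zscore optional [ZScoreModel] fitted on the training population.
#' @param kernel kernel name.
#' @return an [OcModel].
#' @export
svrFit <- function(X, y, params = svrParams(), zscore = NULL,
                   kernel = c("radial", "linear", "polynomial")) {
    kernel <- match.arg(kernel)
    X <- as.matrix(X)
    if (nrow(X) < 2) stopf("need at least 2 training olives")
    if (length(y) != nrow(X)) stopf("X and y sizes differ")
    if (!all(is.finite(X)) || !all(is.finite(y)))
        stopf("training data must be finite")
    fn <- colnames(X) %||% paste0("x", seq_len(ncol(X)))
    if (!is.null(zscore)) X <- zscoreApply(zscore, X)
    if (diff(range(y)) == 0)
        return(methods::new("OcModel", fit = NULL, params = unclass(params),
                            zscore = zscore, constant = y[1],
                            featureNames = fn))
    fit <- e1071::svm(x = X, y = y, type = "eps-regression", kernel = kernel,
                      cost = params$C, gamma = params$gamma,
                      epsilon = params$epsilon, scale = FALSE,
                      fitted = FALSE)
    if (fit$tot.nSV == 0)      # epsilon tube swallowed every residual
        return(methods::new("OcModel", fit = NULL, params = unclass(params),
                            zscore = zscore, constant = mean(y),
                            featureNames = fn))
    methods::new("OcModel", fit = fit, params = unclass(params),
                 zscore = zscore, constant = NA_real_, featureNames = fn)
}

#' Predict oil content of olives
#'
#' Applies the model's stored z-scoring (if any) to the raw 14-feature
#' descriptors, then evaluates the fitted SVR.
#'
#' @param model an [OcModel].
#' @param X numeric matrix (n x 14) or vector of descriptors.
#' @return numeric OC estimates (percent dry matter), one per row.
#' @export
predictOC <- function(model, X) {
    stopifnot(is(model, "OcModel"))
    X <- rbind(X)
    if (ncol(X) != length(model@featureNames))
        stopf("expected %d descriptor columns, got %d",
              length(model@featureNames), ncol(X))
    if (is.null(model@fit)) return(rep(model@constant, nrow(X)))
    if (!is.null(model@zscore)) X <- zscoreApply(model@zscore, X)
    unname(predict(model@fit, X))
}

# k-fold cross-validated RMSE of an SVR at fixed hyperparameters; fold
# membership is drawn once from `seed` so all parameter sets are scored on
# identical folds. Each fold refits the z-scoring on its own training part.
cvRmse <- function(X, y, params, n_folds = 5, seed = 1) {
    n <- nrow(X)
    n_folds <- min(n_folds, n)
    folds <- withSeed(seed, sample(rep_len(seq_len(n_folds), n)))
    err2 <- 0
    for (f in seq_len(n_folds)) {
        tr <- folds != f
        zs <- zscoreFit(X[tr, , drop = FALSE])
        m <- svrFit(X[tr, , drop = FALSE], y[tr], params, zscore = zs)
        pred <- predictOC(m, X[!tr, , drop = FALSE])
        err2 <- err2 + sum((y[!tr] - pred)^2)
    }
    sqrt(err2 / n)
}

#' Simulated-annealing search for SVR hyperparameters
#'
#' Stochastic search over the log-space box `bounds`: Gaussian proposals,
#' Metropolis acceptance on scorer differences, geometric cooling every
#' `steps_per_temperature` proposals. The scorer defaults to 5-fold
#' cross-validated RMSE on the training set only. The best-ever visited
#' parameters are returned (never worse than the start), always inside the
#' bounds; with `total_iterations = 0` the center-of-box parameters are
#' returned. Deterministic under `schedule$seed`.
#'
#' @param X,y training descriptors and labels.
#' @param schedule an [saSchedule()].
#' @param bounds log-space box, see [svrBounds()].
#' @param scorer `function(params) -> numeric` to minimize; default
#'   `cvRmse` on `(X, y)`.
#' @param n_folds folds for the default scorer.
#' @return the best [svrParams()] found, with attributes `"score"` and
#'   `"trace"` (per-iteration best score).
#' @export
saSearch <- function(X, y, schedule = saSchedule(), bounds = svrBounds(),
                     scorer = NULL, n_folds = 5) {
    lo <- log(vapply(bounds, `[`, 1, 1))
    hi <- log(vapply(bounds, `[`, 1, 2))
    if (any(hi <= lo)) stopf("empty search box")
    if (is.null(scorer)) {
        fold_seed <- deriveSeed(schedule$seed, 7)
        scorer <- function(p) cvRmse(X, y, p, n_folds = n_folds,
                                     seed = fold_seed)
    }
    toParams <- function(th) svrParams(C = exp(th[[1]]), gamma = exp(th[[2]]),
                                       epsilon = exp(th[[3]]))
    theta <- (lo + hi) / 2
    if (schedule$total_iterations == 0) {
        p <- toParams(theta)
        attr(p, "score") <- NA_real_
        return(p)
    }
    cur_score <- scorer(toParams(theta))
    best <- theta; best_score <- cur_score
    trace <- numeric(schedule$total_iterations)
    temp <- schedule$initial_temperature
    withSeed(schedule$seed, {
        for (it in seq_len(schedule$total_iterations)) {
            prop <- clamp(theta + rnorm(3, 0, schedule$proposal_scale),
                          lo, hi)
            sc <- scorer(toParams(prop))
            if (sc <= cur_score ||
                runif(1) < exp(-(sc - cur_score) / temp)) {
                theta <- prop; cur_score <- sc
            }
            if (sc < best_score) { best <- prop; best_score <- sc }
            trace[it] <- best_score
            if (it %% schedule$steps_per_temperature == 0)
                temp <- temp * schedule$cooling_factor
        }
    })
    out <- toParams(best)
    attr(out, "score") <- best_score
    attr(out, "trace") <- trace
    out
}
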