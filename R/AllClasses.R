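#' @import methods
#' @importFrom stats rnorm runif sd prcomp predict quantile
#' @importFrom utils head
NULL

#' OliveSet: spectra and per-olive metadata for one season
#'
#' An `OliveSet` extends [SummarizedExperiment::SummarizedExperiment] with
#' rows = wavelengths and columns = olives. Assays hold reflectance matrices
#' (replicate scans `"rep1"`, `"rep2"`, `"rep3"` and, after
#' [averageReplicates()], the per-olive mean `"reflectance"`).
#' `rowData(x)$wavelength_nm` carries the strictly ascending acquisition grid
#' (512 points over 900-2200 nm by default); `colData(x)` carries olive
#' identity (season, week, tray, hole), mean skin RGB and — for synthetic
#' seasons — latent maturity and ground-truth oil content (`true_oc`,
#' percent of dry matter).
#'
#' @aliases OliveSet-class
#' @exportClass OliveSet
setClass("OliveSet", contains = "SummarizedExperiment")

setValidity("OliveSet", function(object) {
    wl <- SummarizedExperiment::rowData(object)$wavelength_nm
    if (is.null(wl))
        return("rowData must contain a 'wavelength_nm' column")
    if (anyNA(wl) || any(diff(wl) <= 0))
        return("wavelengths must be finite and strictly increasing")
    if (length(SummarizedExperiment::assayNames(object)) < 1L)
        return("at least one reflectance assay is required")
    TRUE
})

#' Column z-scoring model (per-feature mean and sample SD)
#'
#' Stores the per-column mean and sample standard deviation (n-1 denominator
#' by default) of a fitted feature population, so the same standardization
#' Z = (x - mean)/sd can be applied to new data and inverted.
#'
#' @slot center numeric, per-column means.
#' @slot scale numeric, per-column SDs (all > 0).
#' @slot featureNames character, column names.
#' @aliases ZScoreModel-class
#' @exportClass ZScoreModel
setClass("ZScoreModel", representation(
    center = "numeric", scale = "numeric", featureNames = "character"))

setValidity("ZScoreModel", function(object) {
    p <- length(object@center)
    if (length(object@scale) != p)
        return("center and scale must have equal length")
    if (length(object@featureNames) != p)
        return("featureNames must match the number of columns")
    if (anyNA(object@scale) || any(object@scale <= 0))
        return("all scales must be > 0 (constant columns cannot be z-scored)")
    TRUE
})

#' Clustering of olives by descriptor similarity
#'
#' Result of [kmeansLloyd()] or [constrainedCluster()]: a partition of the
#' olive set into `k` disjoint, exhaustive groups, the `k x p` centroid
#' matrix, cluster sizes and the within-cluster sum of squared distances
#' (inertia). `minSize` records the size constraint enforced by
#' [constrainedCluster()] (0 when unconstrained).
#'
#' @slot k integer, number of clusters.
#' @slot assignments integer vector, cluster index (1..k) per olive.
#' @slot centroids numeric matrix, k x p.
#' @slot sizes integer vector of cluster cardinalities.
#' @slot inertia numeric, total within-cluster SSE.
#' @slot minSize integer, enforced minimum cluster size (0 = none).
#' @slot iterations integer, Lloyd iterations run.
#' @aliases OliveClustering-class
#' @exportClass OliveClustering
setClass("OliveClustering", representation(
    k = "integer", assignments = "integer", centroids = "matrix",
    sizes = "integer", inertia = "numeric", minSize = "integer",
    iterations = "integer"))

setValidity("OliveClustering", function(object) {
    k <- object@k
    if (nrow(object@centroids) != k)
        return("centroids must have k rows")
    if (length(object@sizes) != k)
        return("sizes must have length k")
    a <- object@assignments
    if (any(a < 1L) || any(a > k))
        return("assignments must lie in 1..k")
    if (!identical(as.integer(tabulate(a, nbins = k)), object@sizes))
        return("sizes must tabulate the assignments")
    if (any(object@sizes < object@minSize))
        return("a cluster is smaller than the recorded minSize")
    if (is.na(object@inertia) || object@inertia < 0)
        return("inertia must be >= 0")
    TRUE
})

#' Fitted oil-content regression model
#'
#' Wraps a fitted epsilon-SVR (RBF kernel by default) together with the
#' hyperparameters used and the [ZScoreModel] applied to raw 14-feature
#' descriptors before training, so [predictOC()] can standardize new
#' descriptors identically. A degenerate training response (all labels
#' identical) yields a constant-predicting model.
#'
#' @slot fit the underlying \pkg{e1071} svm object (or NULL for a constant model).
#' @slot params list with C, gamma, epsilon.
#' @slot zscore the [ZScoreModel] applied before fitting (or NULL).
#' @slot constant numeric, the constant predicted when `fit` is NULL.
#' @slot featureNames character, expected descriptor column order.
#' @aliases OcModel-class
#' @exportClass OcModel
setClass("OcModel", representation(
    fit = "ANY", params = "list", zscore = "ANY",
    constant = "numeric", featureNames = "character"))

setValidity("OcModel", function(object) {
    p <- object@params
    if (!all(c("C", "gamma", "epsilon") %in% names(p)))
        return("params must contain C, gamma and epsilon")
    if (p$C <= 0 || p$gamma <= 0 || p$epsilon < 0)
        return("require C > 0, gamma > 0, epsilon >= 0")
    TRUE
})
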