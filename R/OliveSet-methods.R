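#' @describeIn OliveSet-class the acquisition wavelength grid (nm).
#' @param x an `OliveSet`.
#' @export
wavelengths <- function(x) {
    stopifnot(is(x, "OliveSet"))
    SummarizedExperiment::rowData(x)$wavelength_nm
}

#' @describeIn OliveSet-class a reflectance assay as a wavelengths x olives
#'   matrix; `assay` defaults to the averaged `"reflectance"` when present,
#'   else the first replicate.
#' @param assay assay name.
#' @export
reflectance <- function(x, assay = NULL) {
    stopifnot(is(x, "OliveSet"))
    nm <- SummarizedExperiment::assayNames(x)
    if (is.null(assay))
        assay <- if ("reflectance" %in% nm) "reflectance" else nm[1]
    if (!assay %in% nm)
        stopf("assay '%s' not present (have: %s)", assay,
              paste(nm, collapse = ", "))
    SummarizedExperiment::assay(x, assay)
}

setMethod("show", "OliveSet", function(object) {
    wl <- wavelengths(object)
    cat(sprintf("OliveSet: %d olives, %d wavelengths (%.0f-%.0f nm)\n",
                ncol(object), nrow(object), min(wl), max(wl)))
    cat("assays:", paste(SummarizedExperiment::assayNames(object),
                         collapse = ", "), "\n")
    cd <- SummarizedExperiment::colData(object)
    if ("season" %in% colnames(cd))
        cat("season(s):", paste(unique(cd$season), collapse = ", "), "\n")
    if ("true_oc" %in% colnames(cd))
        cat(sprintf("ground-truth OC: %.1f-%.1f %% dry matter\n",
                    min(cd$true_oc), max(cd$true_oc)))
})

setMethod("show", "OliveClustering", function(object) {
    cat(sprintf("OliveClustering: k = %d over %d olives (inertia %.3f)\n",
                object@k, length(object@assignments), object@inertia))
    cat("sizes:", paste(object@sizes, collapse = " "), "\n")
    if (object@minSize > 0)
        cat("minimum-size constraint:", object@minSize, "\n")
})

setMethod("show", "ZScoreModel", function(object) {
    cat(sprintf("ZScoreModel over %d features\n", length(object@center)))
    cat(" features:", paste(head(object@featureNames, 6), collapse = ", "),
        if (length(object@featureNames) > 6) "..." else "", "\n")
})

setMethod("show", "OcModel", function(object) {
    p <- object@params
    if (is.null(object@fit)) {
        cat(sprintf("OcModel: constant predictor (%.2f %% dry matter)\n",
                    object@constant))
    } else {
        cat(sprintf(
            "OcModel: epsilon-SVR (RBF), C = %.4g, gamma = %.4g, epsilon = %.4g\n",
            p$C, p$gamma, p$epsilon))
        cat(" support vectors:", object@fit$tot.nSV, "\n")
    }
})

#' @describeIn OliveClustering-class cluster index (1..k) per olive.
#' @param x an `OliveClustering`.
#' @export
clusterAssignments <- function(x) { stopifnot(is(x, "OliveClustering")); x@assignments }

#' @describeIn OliveClustering-class the k x p centroid matrix.
#' @export
clusterCentroids <- function(x) { stopifnot(is(x, "OliveClustering")); x@centroids }

#' @describeIn OliveClustering-class cluster cardinalities.
#' @export
clusterSizes <- function(x) { stopifnot(is(x, "OliveClustering")); x@sizes }

#' @describeIn OliveClustering-class number of clusters.
#' @export
nClusters <- function(x) { stopifnot(is(x, "OliveClustering")); x@k }

#' @describeIn OliveClustering-class total within-cluster sum of squares.
#' @export
clusterInertia <- function(x) { stopifnot(is(x, "OliveClustering")); x@inertia }
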