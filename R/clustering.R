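#' k-means++ centroid initialization
#'
#' The first centroid is drawn uniformly from the points; each subsequent
#' centroid is drawn with probability proportional to the squared Euclidean
#' distance to the nearest centroid chosen so far (D^2 weighting), which
#' spreads the seeds and makes the subsequent Lloyd iterations markedly
#' more stable than uniform seeding. Deterministic under `seed`.
#'
#' @param X numeric matrix (n x p).
#' @param k number of centroids (1 <= k <= n).
#' @param seed integer seed.
#' @return k x p matrix of initial centroids (rows of `X`).
#' @export
kmeansppInit <- function(X, k, seed = 1) {
    X <- as.matrix(X)
    n <- nrow(X)
    if (k < 1 || k > n) stopf("need 1 <= k <= n (k = %d, n = %d)", k, n)
    withSeed(seed, {
        idx <- integer(k)
        idx[1] <- sample.int(n, 1)
        if (k > 1) {
            d2 <- rowSums(sweep(X, 2, X[idx[1], ])^2)
            for (j in 2:k) {
                pr <- if (all(d2 == 0)) rep(1, n) else d2
                idx[j] <- sample.int(n, 1, prob = pr)
                d2 <- pmin(d2, rowSums(sweep(X, 2, X[idx[j], ])^2))
            }
        }
        X[idx, , drop = FALSE]
    })
}

# Squared Euclidean distances between rows of X (n x p) and C (k x p).
rowDist2 <- function(X, C) {
    d <- outer(rowSums(X^2), rep(1, nrow(C))) - 2 * tcrossprod(X, C)
    sweep(d, 2, rowSums(C^2), "+")
}

#' Lloyd's k-means from given initial centroids
#'
#' Alternates nearest-centroid assignment (ties broken toward the lowest
#' cluster index) and centroid mean updates until the largest centroid
#' displacement falls below `tol` or `max_iter` is reached. A cluster
#' emptied during iteration is re-seeded at the point farthest from its
#' current centroid. Inertia is non-increasing across iterations.
#'
#' @param X numeric matrix (n x p).
#' @param centers initial centroids (k x p), e.g. from [kmeansppInit()].
#' @param tol convergence tolerance on centroid displacement.
#' @param max_iter iteration cap.
#' @return an [OliveClustering] (with `minSize = 0`).
#' @export
kmeansLloyd <- function(X, centers, tol = 1e-6, max_iter = 300) {
    X <- as.matrix(X)
    C <- as.matrix(centers)
    k <- nrow(C)
    if (ncol(C) != ncol(X)) stopf("centers and X dimensions differ")
    n <- nrow(X)
    assign <- integer(n)
    it <- 0L
    repeat {
        it <- it + 1L
        D <- rowDist2(X, C)
        assign <- max.col(-D, ties.method = "first")
        sizes <- tabulate(assign, nbins = k)
        if (any(sizes == 0)) {
            dmin <- D[cbind(seq_len(n), assign)]
            for (j in which(sizes == 0)) {
                far <- which.max(dmin)
                assign[far] <- j
                dmin[far] <- 0
            }
            sizes <- tabulate(assign, nbins = k)
        }
        Cnew <- rowsum(X, assign) / sizes
        shift <- sqrt(max(rowSums((Cnew - C)^2)))
        C <- Cnew
        if (shift < tol || it >= max_iter) break
    }
    D <- rowDist2(X, C)
    assign <- max.col(-D, ties.method = "first")
    sizes <- tabulate(assign, nbins = k)
    inertia <- sum(D[cbind(seq_len(n), assign)])
    methods::new("OliveClustering", k = as.integer(k),
                 assignments = as.integer(assign), centroids = C,
                 sizes = as.integer(sizes), inertia = inertia,
                 minSize = 0L, iterations = it)
}

# Best-of-restarts k-means++ for one k; returns NULL if `feasible_only`
# and no restart satisfies the size constraint.
bestKmeans <- function(X, k, restarts, seed, min_size = 0, tol = 1e-6,
                       max_iter = 300) {
    best <- NULL
    for (r in seq_len(restarts)) {
        init <- kmeansppInit(X, k, seed = deriveSeed(seed, k * 1000L + r))
        sol <- kmeansLloyd(X, init, tol = tol, max_iter = max_iter)
        if (min_size > 0 && min(sol@sizes) < min_size) next
        if (is.null(best) || sol@inertia < best@inertia) best <- sol
    }
    best
}

#' Minimum-size constrained clustering (maximum number of groups)
#'
#' Searches for the maximum number of groups such that every group keeps at
#' least `min_size` members — the size needed for a duplicate Soxhlet
#' reference measurement per group. k is increased from 1; at each k the
#' best-inertia solution over `restarts` seeded k-means++ runs that
#' respects the constraint is kept, and the search stops at the first k for
#' which no restart is feasible, returning the last feasible solution.
#'
#' @param X numeric matrix (n x p) of (z-scored) descriptors; `n >= min_size`.
#' @param min_size minimum cluster cardinality (default 30).
#' @param restarts k-means++ restarts per k.
#' @param seed integer seed (fans out per k and restart).
#' @param max_k cap on the search (defaults to `floor(n / min_size)`, the
#'   combinatorial upper bound).
#' @param method `"incremental"` (default; increase k until infeasible) or
#'   `"bisect"` (recursively 2-means-split any cluster that can still yield
#'   two groups of `min_size`, keeping splits only while both halves stay
#'   feasible).
#' @param tol,max_iter passed to [kmeansLloyd()].
#' @return an [OliveClustering] with `minSize = min_size`; every cluster
#'   has `>= min_size` members and `k <= floor(n / min_size)`.
#' @export
constrainedCluster <- function(X, min_size = 30, restarts = 10, seed = 1,
                               max_k = NULL,
                               method = c("incremental", "bisect"),
                               tol = 1e-6, max_iter = 300) {
    method <- match.arg(method)
    X <- as.matrix(X)
    n <- nrow(X)
    if (n < min_size)
        stopf("n = %d olives is below the minimum group size %d", n, min_size)
    if (is.null(max_k)) max_k <- n %/% min_size
    if (method == "bisect")
        return(bisectCluster(X, min_size, restarts, seed, tol, max_iter))
    best <- NULL
    for (k in seq_len(max_k)) {
        sol <- bestKmeans(X, k, restarts = restarts, seed = seed,
                          min_size = min_size, tol = tol, max_iter = max_iter)
        if (is.null(sol)) break
        best <- sol
    }
    best@minSize <- as.integer(min_size)
    methods::validObject(best)
    best
}

# Recursive-bisection mode: repeatedly 2-means-split the cluster with the
# largest inertia whose split keeps both halves >= min_size.
bisectCluster <- function(X, min_size, restarts, seed, tol, max_iter) {
    n <- nrow(X)
    groups <- list(seq_len(n))
    splittable <- TRUE
    while (any(splittable)) {
        progressed <- FALSE
        for (g in which(splittable)) {
            idx <- groups[[g]]
            if (length(idx) < 2 * min_size) { splittable[g] <- FALSE; next }
            sub <- bestKmeans(X[idx, , drop = FALSE], 2, restarts = restarts,
                              seed = deriveSeed(seed, g * 131L),
                              min_size = min_size, tol = tol,
                              max_iter = max_iter)
            if (is.null(sub)) { splittable[g] <- FALSE; next }
            groups[[g]] <- idx[sub@assignments == 1L]
            groups[[length(groups) + 1L]] <- idx[sub@assignments == 2L]
            splittable[g] <- TRUE
            splittable <- c(splittable, TRUE)
            progressed <- TRUE
        }
        if (!progressed) break
    }
    k <- length(groups)
    assign <- integer(n)
    for (j in seq_len(k)) assign[groups[[j]]] <- j
    C <- rowsum(X, assign) / tabulate(assign, k)
    inertia <- sum((X - C[assign, , drop = FALSE])^2)
    methods::new("OliveClustering", k = as.integer(k),
                 assignments = assign, centroids = C,
                 sizes = as.integer(tabulate(assign, k)), inertia = inertia,
                 minSize = as.integer(min_size), iterations = NA_integer_)
}

#' Trim clusters to exactly the minimum size
#'
#' Optional post-step retaining, per cluster, the `min_size` members
#' nearest to the centroid (mirroring a bagging step in which exactly 30
#' olives per group go to the extraction). Off by default in the pipeline.
#'
#' @param clustering an [OliveClustering] with `minSize > 0`.
#' @param X the descriptor matrix the clustering was fitted on.
#' @return integer vector of retained row indices of `X`.
#' @export
trimToMinSize <- function(clustering, X) {
    stopifnot(is(clustering, "OliveClustering"), clustering@minSize > 0)
    X <- as.matrix(X)
    a <- clustering@assignments
    keep <- integer(0)
    for (j in seq_len(clustering@k)) {
        idx <- which(a == j)
        d2 <- rowSums(sweep(X[idx, , drop = FALSE], 2,
                            clustering@centroids[j, ])^2)
        keep <- c(keep, idx[order(d2)[seq_len(clustering@minSize)]])
    }
    sort(keep)
}
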