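#' Oil content on a dry-matter basis
#'
#' Gravimetric arithmetic of the Soxhlet worksheet: the extracted oil mass
#' as a percentage of the dry sample mass.
#'
#' @param oil_mass oil mass (g), `0 <= oil_mass <= dry_mass`.
#' @param dry_mass dry sample mass (g), > 0.
#' @return OC in percent of dry matter (vectorized).
#' @export
computeOcDryBasis <- function(oil_mass, dry_mass) {
    if (any(dry_mass <= 0)) stopf("dry_mass must be > 0")
    if (any(oil_mass < 0) || any(oil_mass > dry_mass))
        stopf("need 0 <= oil_mass <= dry_mass")
    100 * oil_mass / dry_mass
}

#' Reference OC of one cluster from duplicate measurements
#'
#' Arithmetic mean of the (usually two) replicate OC determinations of a
#' cluster. A single replicate is returned with a warning; replicates
#' disagreeing by more than `qc_gap` points are returned with a QC flag
#' (attribute `"qc_flag"`).
#'
#' @param oc_values numeric vector of replicate OC values (percent dry
#'   matter), length >= 1.
#' @param qc_gap allowed absolute disagreement between replicates.
#' @return the mean reference OC, with attribute `qc_flag` (logical).
#' @export
clusterReferenceOc <- function(oc_values, qc_gap = 5) {
    if (length(oc_values) < 1) stopf("no replicate OC measurements")
    if (any(oc_values < 0 | oc_values > 100))
        stopf("OC values must lie in [0, 100]")
    if (length(oc_values) == 1)
        warning("single Soxhlet replicate: reference OC has no duplicate",
                call. = FALSE)
    flag <- length(oc_values) > 1 &&
        diff(range(oc_values)) > qc_gap
    structure(mean(oc_values), qc_flag = flag)
}

#' Read (and validate) a Soxhlet worksheet
#'
#' Canonical CSV schema: `season, cluster_id, replicate, wet_mass_g,
#' dry_mass_g, oil_mass_g, oc_pct` with `oc_pct` optional. When both masses
#' and `oc_pct` are present they must agree within 0.1 points or a QC error
#' is raised; a missing `oc_pct` is recomputed from the masses. Wet mass is
#' carried but unused (OC is on a dry-matter basis).
#'
#' @param path CSV file path.
#' @return data.frame with a validated `oc_pct` column.
#' @export
readSoxhletWorksheet <- function(path) {
    ws <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("season", "cluster_id", "replicate")
    if (!all(need %in% names(ws)))
        stopf("worksheet must contain columns: %s", paste(need, collapse = ", "))
    has_mass <- all(c("dry_mass_g", "oil_mass_g") %in% names(ws)) &&
        !anyNA(ws$dry_mass_g) && !anyNA(ws$oil_mass_g)
    if (has_mass) {
        oc <- computeOcDryBasis(ws$oil_mass_g, ws$dry_mass_g)
        if (!is.null(ws$oc_pct) && !anyNA(ws$oc_pct)) {
            off <- abs(ws$oc_pct - oc) > 0.1
            if (any(off))
                stopf("oc_pct disagrees with masses by > 0.1 points in row(s) %s",
                      paste(which(off), collapse = ", "))
        }
        ws$oc_pct <- oc
    } else if (is.null(ws$oc_pct) || anyNA(ws$oc_pct)) {
        stopf("worksheet needs either masses or oc_pct for every row")
    }
    ws
}

#' Per-cluster reference OC table from a worksheet
#'
#' @param worksheet data.frame from [readSoxhletWorksheet()].
#' @param qc_gap passed to [clusterReferenceOc()].
#' @return data.frame: cluster_id, n_replicates, reference_oc, qc_flag.
#' @export
referenceTable <- function(worksheet, qc_gap = 5) {
    sp <- split(worksheet$oc_pct, worksheet$cluster_id)
    refs <- lapply(sp, clusterReferenceOc, qc_gap = qc_gap)
    data.frame(cluster_id = as.integer(names(sp)),
               n_replicates = lengths(sp),
               reference_oc = vapply(refs, as.numeric, 1),
               qc_flag = vapply(refs, function(r) attr(r, "qc_flag"), TRUE),
               row.names = NULL)
}

#' Propagate cluster reference OC to member olives
#'
#' Assigns every olive the reference OC of its cluster — the similarity
#' hypothesis that makes single-olive training labels out of batch Soxhlet
#' measurements. Every cluster must have a reference and every olive an
#' assignment.
#'
#' @param clustering an [OliveClustering].
#' @param references named numeric vector (names = cluster ids 1..k) or a
#'   [referenceTable()] data.frame.
#' @return numeric label vector (percent dry matter), one per olive.
#' @export
propagateLabels <- function(clustering, references) {
    stopifnot(is(clustering, "OliveClustering"))
    if (is.data.frame(references))
        references <- stats::setNames(references$reference_oc,
                                      references$cluster_id)
    ids <- as.character(seq_len(clustering@k))
    missing <- setdiff(ids, names(references))
    if (length(missing))
        stopf("cluster(s) without a Soxhlet reference: %s",
              paste(missing, collapse = ", "))
    unname(references[as.character(clustering@assignments)])
}

#' Simulate the Soxhlet campaign for a clustered synthetic season
#'
#' For each cluster, draws duplicate OC determinations around the mean true
#' OC of its members (measurement noise `noise_sd`), and lays them out as a
#' canonical worksheet with plausible gravimetric masses (the masses
#' reproduce each OC exactly).
#'
#' @param clustering an [OliveClustering].
#' @param true_oc per-olive ground-truth OC (percent dry matter).
#' @param noise_sd SD of one Soxhlet determination (percent dry matter).
#' @param n_replicates determinations per cluster (default 2: sample and
#'   counter-sample).
#' @param season season label.
#' @param seed integer seed.
#' @return worksheet data.frame (see [readSoxhletWorksheet()]).
#' @export
simulateSoxhlet <- function(clustering, true_oc, noise_sd = 0.5,
                            n_replicates = 2, season = "2016", seed = 1) {
    stopifnot(is(clustering, "OliveClustering"),
              length(true_oc) == length(clustering@assignments))
    k <- clustering@k
    withSeed(seed, {
        rows <- lapply(seq_len(k), function(j) {
            mu <- mean(true_oc[clustering@assignments == j])
            oc <- clamp(rnorm(n_replicates, mu, noise_sd), 0, 100)
            dry <- round(runif(n_replicates, 3, 5), 3)
            data.frame(season = season, cluster_id = j,
                       replicate = seq_len(n_replicates),
                       wet_mass_g = round(dry * runif(n_replicates, 2, 2.6), 3),
                       dry_mass_g = dry,
                       oil_mass_g = dry * oc / 100,
                       oc_pct = oc)
        })
        do.call(rbind, rows)
    })
}
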