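#' Build the labeled per-season dataset (descriptor -> cluster -> label)
#'
#' Runs the per-season half of the method on one [OliveSet]: obtain each
#' olive's c1c2c3 color (either from rendered tray images through
#' segmentation, or directly from the recorded mean skin RGB), average the
#' replicate spectra, select the 1710-1735 nm band, assemble the raw
#' 14-feature descriptors, z-score them over the season, cluster with the
#' minimum-size constraint, simulate (or accept) the per-cluster Soxhlet
#' references, and propagate each cluster's reference OC to its members.
#'
#' @param x an [OliveSet] season.
#' @param use_images render tray images and take each olive's color from
#'   segmentation (slower, exercises the imaging stage); otherwise use the
#'   ground-truth mean RGB in `colData`.
#' @param layout tray layout for rendering/segmentation.
#' @param band_start,band_stop,band_step band selection (nm).
#' @param min_size minimum cluster size.
#' @param restarts k-means++ restarts per k.
#' @param soxhlet_noise_sd SD of one simulated Soxhlet determination.
#' @param worksheet optional pre-existing Soxhlet worksheet data.frame
#'   (cluster ids must match the clustering); when `NULL` one is simulated
#'   from the ground truth.
#' @param trim retain only the `min_size` olives nearest each centroid
#'   (off by default).
#' @param seed integer seed.
#' @return list: `X` (raw n x 14 descriptors), `Z` (season-z-scored), `y`
#'   (propagated labels), `clustering`, `references`, `worksheet`, `band`,
#'   `true_oc` (when available), `olive_id`.
#' @export
buildSeasonDataset <- function(x, use_images = FALSE, layout = trayLayout(),
                               band_start = 1710, band_stop = 1735,
                               band_step = 2.53, min_size = 30,
                               restarts = 10, soxhlet_noise_sd = 0.5,
                               worksheet = NULL, trim = FALSE, seed = 1) {
    stopifnot(is(x, "OliveSet"))
    cd <- SummarizedExperiment::colData(x)
    if (use_images) {
        color <- seasonColorsFromImages(x, layout,
                                        seed = deriveSeed(seed, 11))
    } else {
        color <- rgbToC1c2c3(cd$r, cd$g, cd$b)
    }
    x <- averageReplicates(x)
    band <- selectBand(wavelengths(x), band_start, band_stop, band_step)
    X <- buildDescriptor(color, bandValues(x, band))
    rownames(X) <- cd$olive_id
    zs <- zscoreFit(X)
    Z <- zscoreApply(zs, X)
    clustering <- constrainedCluster(Z, min_size = min_size,
                                     restarts = restarts,
                                     seed = deriveSeed(seed, 21))
    keep <- seq_len(nrow(X))
    if (trim) {
        keep <- trimToMinSize(clustering, Z)
        X <- X[keep, , drop = FALSE]
        Z <- Z[keep, , drop = FALSE]
        clustering <- constrainedCluster(Z, min_size = min_size,
                                         restarts = restarts,
                                         seed = deriveSeed(seed, 22))
    }
    true_oc <- if ("true_oc" %in% colnames(cd)) cd$true_oc[keep] else NULL
    if (is.null(worksheet)) {
        if (is.null(true_oc))
            stopf("no Soxhlet worksheet given and no ground truth to simulate one")
        worksheet <- simulateSoxhlet(clustering, true_oc,
                                     noise_sd = soxhlet_noise_sd,
                                     season = cd$season[1],
                                     seed = deriveSeed(seed, 31))
    }
    refs <- referenceTable(worksheet)
    y <- propagateLabels(clustering, refs)
    list(X = X, Z = Z, y = y, clustering = clustering, references = refs,
         worksheet = worksheet, band = band, true_oc = true_oc,
         olive_id = cd$olive_id[keep])
}

# Per-olive c1c2c3 from rendered tray images: render each (week, tray)
# group, segment it, and read the mean color descriptor of the region in
# each olive's hole.
seasonColorsFromImages <- function(x, layout, seed = 1) {
    cd <- SummarizedExperiment::colData(x)
    trays <- renderSeasonTrays(x, layout, seed = seed)
    out <- matrix(NA_real_, ncol(x), 3,
                  dimnames = list(cd$olive_id, c("c1", "c2", "c3")))
    for (key in names(trays)) {
        w <- as.integer(sub("^w(\\d+)_t(\\d+)$", "\\1", key))
        t <- as.integer(sub("^w(\\d+)_t(\\d+)$", "\\2", key))
        img <- trays[[key]]
        regions <- segmentOlives(img, layout)
        for (rg in regions) {
            i <- which(cd$week == w & cd$tray == t & cd$hole == rg$hole)
            if (length(i) == 1)
                out[i, ] <- oliveColorDescriptor(img, rg)
        }
    }
    if (anyNA(out))
        stopf("segmentation failed to recover %d olive(s)",
              sum(is.na(out[, 1])))
    out
}

#' Run the end-to-end method on two seasons
#'
#' Generates (or accepts) two synthetic seasons, builds each season's
#' labeled dataset with [buildSeasonDataset()], and runs the evaluation
#' matrix with [runAllSchemes()]. Deterministic under `seed`.
#'
#' @param config a [syntheticConfig()]; ignored when `seasons` is given.
#' @param seasons optional named list of two [OliveSet]s.
#' @param params fixed [svrParams()] or `NULL` to tune by simulated
#'   annealing per repeat.
#' @param sa_schedule an [saSchedule()].
#' @param schemes scheme list (default [defaultSchemes()]).
#' @param seed global run seed.
#' @param ... passed to [buildSeasonDataset()].
#' @return list: `datasets` (per season), `report` (the evaluation table),
#'   `seasons` (the OliveSets).
#' @export
runPipeline <- function(config = syntheticConfig(), seasons = NULL,
                        params = NULL, sa_schedule = saSchedule(),
                        schemes = NULL, seed = 1, ...) {
    if (is.null(seasons))
        seasons <- simulateSeasons(config, seed = deriveSeed(seed, 1))
    datasets <- lapply(seq_along(seasons), function(i)
        buildSeasonDataset(seasons[[i]], seed = deriveSeed(seed, 100L + i),
                           ...))
    names(datasets) <- names(seasons)
    if (is.null(schemes)) schemes <- defaultSchemes(names(datasets))
    report <- runAllSchemes(datasets, schemes = schemes, params = params,
                            sa_schedule = sa_schedule,
                            seed = deriveSeed(seed, 777))
    list(datasets = datasets, report = report, seasons = seasons)
}

#' Write a synthetic season to disk
#'
#' Plain-text artifacts: long-format spectra CSV (`olive_id, replicate,
#' wavelength_nm, reflectance`), ground-truth CSV, the generator
#' configuration as YAML (the OC curve is stored by its defining
#' parameters, not as code), and optionally one PNG per tray.
#'
#' @param x an [OliveSet].
#' @param dir output directory (created if needed).
#' @param write_images render and write tray PNGs.
#' @param layout tray layout for rendering.
#' @param seed seed for tray rendering.
#' @return invisibly, the paths written.
#' @export
writeSeason <- function(x, dir, write_images = FALSE, layout = trayLayout(),
                        seed = 1) {
    stopifnot(is(x, "OliveSet"))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    cd <- SummarizedExperiment::colData(x)
    wl <- wavelengths(x)
    reps <- grep("^rep", SummarizedExperiment::assayNames(x), value = TRUE)
    long <- data.table::rbindlist(lapply(seq_along(reps), function(r) {
        m <- SummarizedExperiment::assay(x, reps[r])
        data.table::data.table(
            olive_id = rep(cd$olive_id, each = length(wl)),
            replicate = r,
            wavelength_nm = rep(wl, ncol(m)),
            reflectance = as.vector(m))
    }))
    paths <- c(spectra = file.path(dir, "spectra.csv"),
               truth = file.path(dir, "truth.csv"),
               config = file.path(dir, "config.yaml"))
    data.table::fwrite(long, paths["spectra"])
    data.table::fwrite(as.data.frame(cd), paths["truth"])
    cfg <- S4Vectors::metadata(x)$config
    if (!is.null(cfg)) {
        cfg$oc_curve <- NULL   # functions are not serialized
        yaml::write_yaml(cfg, paths["config"])
    }
    if (write_images) {
        trays <- renderSeasonTrays(x, layout, seed = seed)
        img_dir <- file.path(dir, "trays")
        dir.create(img_dir, showWarnings = FALSE)
        for (key in names(trays))
            png::writePNG(trays[[key]] / 255,
                          file.path(img_dir, paste0(key, ".png")))
        paths <- c(paths, trays = img_dir)
    }
    invisible(paths)
}

#' Read a season back from its on-disk form
#'
#' Inverse of [writeSeason()] for the spectra and truth CSVs.
#'
#' @param dir directory written by [writeSeason()].
#' @return an [OliveSet] with the replicate assays and ground-truth
#'   `colData`.
#' @export
readSeason <- function(dir) {
    long <- data.table::fread(file.path(dir, "spectra.csv"))
    truth <- data.table::fread(file.path(dir, "truth.csv"))
    wl <- sort(unique(long$wavelength_nm))
    ids <- truth$olive_id
    assays <- lapply(sort(unique(long$replicate)), function(r) {
        d <- long[long$replicate == r, ]
        m <- matrix(NA_real_, length(wl), length(ids),
                    dimnames = list(NULL, ids))
        m[cbind(match(d$wavelength_nm, wl), match(d$olive_id, ids))] <-
            d$reflectance
        m
    })
    names(assays) <- paste0("rep", seq_along(assays))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = assays,
        colData = S4Vectors::DataFrame(as.data.frame(truth),
                                       row.names = ids),
        rowData = S4Vectors::DataFrame(wavelength_nm = wl))
    methods::new("OliveSet", se)
}
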