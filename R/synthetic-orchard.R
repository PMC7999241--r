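#' Configuration of the synthetic orchard generator
#'
#' Defines one synthetic harvest season: its sampling structure (weeks,
#' 24-hole trays), the latent maturity -> oil-content (OC) curve, the
#' color model, the NIR spectral model (smooth baseline plus a Gaussian
#' lipid absorption band near 1725 nm whose depth scales with OC), the
#' measurement-noise levels, and the between-season shift. Olives per week
#' is always `trays_per_week * holes_per_tray`.
#'
#' Defaults mirror the study conditions the method targets: 5 weekly
#' harvests of 25 trays x 24 holes = 600 olives/week, 3000 olives/season;
#' 512-point spectra over 900-2200 nm with triplicate scans; OC rising
#' logistically from ~20 to ~55 percent of dry matter across maturity; skin
#' color running green -> purple -> black.
#'
#' @param n_weeks number of weekly harvests.
#' @param trays_per_week number of 24-hole trays measured per week.
#' @param holes_per_tray holes per tray.
#' @param maturity_range interval within [0,1] to which latent maturity is
#'   truncated.
#' @param oc_curve monotone function maturity -> OC (percent dry matter);
#'   default logistic from ~20 to ~55.
#' @param oc_noise_sd SD of biological OC noise around the curve (percent
#'   dry matter); OC is truncated at 0.
#' @param band_center center of the lipid absorption band (nm).
#' @param band_width Gaussian sigma of the band (nm).
#' @param band_depth_per_oc reflectance-units of band depth per percent OC.
#' @param baseline list: `intercept`, `slope`, `curvature` of the smooth
#'   quadratic baseline in normalized wavelength, plus per-olive jitter SDs
#'   `offset_sd` and `slope_sd`.
#' @param replicate_noise_sd SD of per-scan reflectance noise.
#' @param season_shift list: `baseline_offset`, `slope_delta` (per
#'   normalized wavelength) and `band_center_shift` (nm) applied to the
#'   second season by [simulateSeasons()].
#' @param n_wavelengths,wl_range acquisition grid size and span (nm).
#' @param color_jitter_sd SD of per-olive RGB jitter (0-255 scale).
#' @param seed integer generator seed.
#' @return a validated list of class `"SyntheticConfig"`.
#' @seealso [generateSeason()], [simulateSeasons()]
#' @export
syntheticConfig <- function(n_weeks = 5L, trays_per_week = 25L,
                            holes_per_tray = 24L,
                            maturity_range = c(0, 1),
                            oc_curve = NULL,
                            oc_noise_sd = 1.5,
                            band_center = 1725, band_width = 15,
                            band_depth_per_oc = 0.004,
                            baseline = list(intercept = 0.55, slope = -0.08,
                                            curvature = -0.05,
                                            offset_sd = 0.010,
                                            slope_sd = 0.006),
                            replicate_noise_sd = 0.003,
                            season_shift = list(baseline_offset = 0.006,
                                                slope_delta = 0.010,
                                                band_center_shift = 1.0),
                            n_wavelengths = 512L, wl_range = c(900, 2200),
                            color_jitter_sd = 6,
                            seed = 1L) {
    if (n_weeks < 1 || trays_per_week < 1 || holes_per_tray < 1)
        stopf("counts (n_weeks, trays_per_week, holes_per_tray) must be positive")
    if (length(maturity_range) != 2 || maturity_range[1] < 0 ||
        maturity_range[2] > 1 || maturity_range[1] >= maturity_range[2])
        stopf("maturity_range must be an interval within [0, 1]")
    if (oc_noise_sd < 0 || replicate_noise_sd < 0 ||
        baseline$offset_sd < 0 || baseline$slope_sd < 0 || color_jitter_sd < 0)
        stopf("all noise SDs must be >= 0")
    if (band_width <= 0 || band_depth_per_oc < 0)
        stopf("band_width must be > 0 and band_depth_per_oc >= 0")
    if (!all(is.finite(unlist(season_shift))))
        stopf("season_shift parameters must be finite")
    if (is.null(oc_curve))
        oc_curve <- function(m) 20 + 35 / (1 + exp(-8 * (m - 0.5)))
    cfg <- list(n_weeks = as.integer(n_weeks),
                trays_per_week = as.integer(trays_per_week),
                holes_per_tray = as.integer(holes_per_tray),
                olives_per_week = as.integer(trays_per_week * holes_per_tray),
                maturity_range = maturity_range, oc_curve = oc_curve,
                oc_noise_sd = oc_noise_sd,
                band_center = band_center, band_width = band_width,
                band_depth_per_oc = band_depth_per_oc,
                baseline = baseline, replicate_noise_sd = replicate_noise_sd,
                season_shift = season_shift,
                n_wavelengths = as.integer(n_wavelengths), wl_range = wl_range,
                color_jitter_sd = color_jitter_sd,
                seed = as.integer(seed))
    class(cfg) <- "SyntheticConfig"
    cfg
}

# Skin color along maturity: green -> purple -> black, linear in two legs.
maturityColor <- function(m) {
    green <- c(60, 120, 40); purple <- c(90, 40, 80); black <- c(25, 20, 25)
    out <- matrix(0, length(m), 3, dimnames = list(NULL, c("r", "g", "b")))
    lo <- m <= 0.5
    t1 <- m[lo] / 0.5
    out[lo, ] <- cbind((1 - t1)) %*% rbind(green) + cbind(t1) %*% rbind(purple)
    t2 <- (m[!lo] - 0.5) / 0.5
    out[!lo, ] <- cbind((1 - t2)) %*% rbind(purple) + cbind(t2) %*% rbind(black)
    out
}

#' Generate one synthetic season of olives
#'
#' Draws `n_weeks * olives_per_week` olives. Each olive has a latent
#' maturity (drifting upward week by week), a ground-truth oil content
#' `OC = oc_curve(maturity) + N(0, oc_noise_sd)` truncated at 0, a skin
#' color on the green->purple->black ramp with per-olive jitter, and three
#' replicate reflectance spectra on the shared 512-point grid: a smooth
#' per-olive baseline minus a Gaussian absorption dip at `band_center`
#' whose depth is `band_depth_per_oc * OC`, plus independent scan noise.
#' Identical `(config, seed)` give bit-identical output.
#'
#' @param config a [syntheticConfig()].
#' @param season season label stored in `colData` (e.g. `"2016"`).
#' @param seed generator seed; defaults to `config$seed`.
#' @param shift optional season-shift list applied to all replicate spectra
#'   (see [applySeasonShift()]).
#' @return an [OliveSet] with assays `rep1`, `rep2`, `rep3` and ground
#'   truth in `colData` (`maturity`, `true_oc`, `r`, `g`, `b`).
#' @examples
#' cfg <- syntheticConfig(n_weeks = 1, trays_per_week = 2)
#' os <- generateSeason(cfg)
#' ncol(os)  # 48 olives
#' @export
generateSeason <- function(config, season = "2016", seed = config$seed,
                           shift = NULL) {
    stopifnot(inherits(config, "SyntheticConfig"))
    n <- config$n_weeks * config$olives_per_week
    p <- config$n_wavelengths
    wl <- seq(config$wl_range[1], config$wl_range[2], length.out = p)
    u <- (wl - config$wl_range[1]) / diff(config$wl_range)

    dat <- withSeed(seed, {
        week <- rep(seq_len(config$n_weeks), each = config$olives_per_week)
        tray <- rep(rep(seq_len(config$trays_per_week),
                        each = config$holes_per_tray), config$n_weeks)
        hole <- rep(seq_len(config$holes_per_tray),
                    config$n_weeks * config$trays_per_week)
        maturity <- clamp(rnorm(n, (week - 0.5) / config$n_weeks, 0.18),
                          config$maturity_range[1], config$maturity_range[2])
        true_oc <- pmax(0, config$oc_curve(maturity) +
                           rnorm(n, 0, config$oc_noise_sd))
        rgb <- clamp(maturityColor(maturity) +
                     matrix(rnorm(3 * n, 0, config$color_jitter_sd), n, 3),
                     0, 255)
        bl <- config$baseline
        off <- rnorm(n, 0, bl$offset_sd)
        slp <- rnorm(n, 0, bl$slope_sd)
        poly <- bl$intercept + bl$slope * u + bl$curvature * u^2
        gauss <- exp(-(wl - config$band_center)^2 / (2 * config$band_width^2))
        depth <- config$band_depth_per_oc * true_oc
        base <- matrix(poly, p, n) +
            matrix(off, p, n, byrow = TRUE) +
            u %o% slp - gauss %o% depth
        reps <- lapply(1:3, function(r)
            base + matrix(rnorm(p * n, 0, config$replicate_noise_sd), p, n))
        list(week = week, tray = tray, hole = hole, maturity = maturity,
             true_oc = true_oc, rgb = rgb, reps = reps)
    })

    if (!is.null(shift))
        dat$reps <- lapply(dat$reps, applySeasonShift, wavelengths = wl,
                           shift = shift)

    ids <- sprintf("%s_w%02d_t%03d_h%02d", season, dat$week, dat$tray,
                   dat$hole)
    cd <- S4Vectors::DataFrame(
        olive_id = ids, season = season, week = dat$week, tray = dat$tray,
        hole = dat$hole, maturity = dat$maturity, true_oc = dat$true_oc,
        r = dat$rgb[, 1], g = dat$rgb[, 2], b = dat$rgb[, 3],
        row.names = ids)
    assays <- lapply(dat$reps, function(m) {
        dimnames(m) <- list(NULL, ids); m
    })
    names(assays) <- paste0("rep", 1:3)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = assays, colData = cd,
        rowData = S4Vectors::DataFrame(wavelength_nm = wl),
        metadata = list(config = config, season = season, seed = seed,
                        shift = shift))
    methods::new("OliveSet", se)
}

#' Generate a pair of synthetic seasons with a between-season shift
#'
#' The first season uses the configuration as-is; the second is drawn from
#' the same configuration (different stream) and then perturbed by
#' `config$season_shift` (baseline offset, wavelength-proportional slope,
#' band-center displacement), emulating the spectral domain difference
#' between consecutive harvest years.
#'
#' @param config a [syntheticConfig()].
#' @param seasons two season labels.
#' @param seed global seed; defaults to `config$seed`.
#' @return named list of two [OliveSet]s.
#' @export
simulateSeasons <- function(config, seasons = c("2016", "2017"),
                            seed = config$seed) {
    stopifnot(length(seasons) == 2)
    s1 <- generateSeason(config, season = seasons[1],
                         seed = deriveSeed(seed, 101))
    s2 <- generateSeason(config, season = seasons[2],
                         seed = deriveSeed(seed, 202),
                         shift = config$season_shift)
    stats::setNames(list(s1, s2), seasons)
}

#' Apply a season shift to reflectance spectra
#'
#' Adds a constant baseline offset and a slope proportional to normalized
#' wavelength, and optionally displaces the whole spectrum along the
#' wavelength axis (linear interpolation, edges held), which moves the
#' lipid band center. A zero shift is the identity.
#'
#' @param x reflectance matrix (wavelengths x olives) or vector.
#' @param wavelengths the ascending wavelength grid (nm).
#' @param shift list with `baseline_offset`, `slope_delta`,
#'   `band_center_shift` (nm); missing entries default to 0.
#' @return shifted reflectance, same shape as `x`.
#' @export
applySeasonShift <- function(x, wavelengths, shift) {
    off <- shift$baseline_offset %||% 0
    sl <- shift$slope_delta %||% 0
    dc <- shift$band_center_shift %||% 0
    if (!all(is.finite(c(off, sl, dc))))
        stopf("shift parameters must be finite")
    vec <- is.null(dim(x))
    m <- if (vec) matrix(x, ncol = 1) else x
    if (length(wavelengths) != nrow(m))
        stopf("wavelength grid does not match the spectra")
    if (dc != 0) {
        xout <- wavelengths - dc
        m <- apply(m, 2, function(col)
            stats::approx(wavelengths, col, xout = xout, rule = 2)$y)
    }
    u <- (wavelengths - wavelengths[1]) /
        (wavelengths[length(wavelengths)] - wavelengths[1])
    m <- m + off + sl * u
    if (vec) m[, 1] else m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ground-truth table of a synthetic season
#'
#' @param x an [OliveSet] produced by [generateSeason()].
#' @return data.frame with olive_id, season, week, tray, hole, maturity,
#'   true OC and mean skin RGB.
#' @export
groundTruth <- function(x) {
    stopifnot(is(x, "OliveSet"))
    as.data.frame(SummarizedExperiment::colData(x))
}
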