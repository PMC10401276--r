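#' Configuration of the synthetic split-plot experiment
#'
#' Describes the generative model used to emulate a multi-year cover-crop
#' field trial: a split-plot randomized-complete-block layout (4 cover-crop
#' treatments x 4 blocks = 16 subplots per year), a per-plot latent vigor
#' variable carrying treatment, block and plot effects, a seasonal canopy /
#' chlorophyll trajectory peaking in the early reproductive window, a
#' two-endmember (soil + leaf) linear mixture producing five-band
#' reflectance, and a linear vigor-to-yield link.
#'
#' @param seed Integer master seed; all randomness derives from it.
#' @param n_years Number of simulated seasons (default 3).
#' @param treatments Treatment labels (default the four cover-crop regimes:
#'   winter pea, radish-or-mix, cereal rye, no cover).
#' @param treatment_effects Additive treatment effects on vigor (sum ~ 0).
#' @param n_blocks Number of blocks (replicates).
#' @param block_sd,plot_sd SDs of block and plot-level vigor noise.
#' @param vigor_mean Baseline vigor (0-1 scale).
#' @param flights data.frame with `stage` and `dap` (days after planting),
#'   sorted by dap; default a 7-flight V5-R5 schedule.
#' @param band_noise_sd SD of plot-level reflectance noise per band.
#' @param pixel_noise_sd SD of per-pixel reflectance noise in scenes.
#' @param yield_intercept,yield_slope,yield_sd Vigor-to-yield link
#'   (Mg/ha): yield = intercept + year effect + slope * vigor + noise.
#' @param yield_year_effects Additive per-year yield shifts (Mg/ha),
#'   recycled to `n_years`; defaults emulate a good / wet / dry sequence.
#' @param canopy_max,canopy_mid,canopy_scale Logistic canopy-cover
#'   trajectory: cover rises to `canopy_max` with midpoint `canopy_mid` DAP.
#' @param chl_peak,chl_plateau_half,chl_width Chlorophyll trajectory:
#'   unimodal gain with a flat top of half-width `chl_plateau_half` centred
#'   at `chl_peak` DAP (covering the R1-R3 window) and Gaussian shoulders.
#' @param weed_fraction Share of scene pixels replaced by weed (default 2
#'   percent).
#' @param plot_px,margin_px Pixels per plot edge and margin width in scenes.
#' @param min_labels Labelled pixels sampled per class for classifier
#'   training (default 5000).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_years = 3L,
                       treatments = c("winter_pea", "radish_mix", "rye",
                                      "no_cover"),
                       treatment_effects = c(0.08, -0.12, -0.06, 0.10),
                       n_blocks = 4L, block_sd = 0.03, plot_sd = 0.04,
                       vigor_mean = 0.6,
                       flights = data.frame(
                         stage = c("V5", "V7", "V11", "Vn", "R1", "R3", "R5"),
                         dap = c(35, 48, 60, 67, 83, 95, 119)),
                       band_noise_sd = 0.004, pixel_noise_sd = 0.02,
                       yield_intercept = 2, yield_slope = 10,
                       yield_sd = 0.35,
                       yield_year_effects = c(2.7, -1.7, 1.2),
                       canopy_max = 0.95, canopy_mid = 45, canopy_scale = 8,
                       chl_peak = 89, chl_plateau_half = 6, chl_width = 30,
                       weed_fraction = 0.02, plot_px = 120L, margin_px = 10L,
                       min_labels = 5000L) {
  stopifnot(length(treatments) == length(treatment_effects),
            n_years >= 1L, n_blocks >= 2L,
            all(c(block_sd, plot_sd, band_noise_sd, pixel_noise_sd,
                  yield_sd) >= 0),
            all(c("stage", "dap") %in% names(flights)),
            weed_fraction >= 0, weed_fraction < 1,
            canopy_max > 0, canopy_max <= 1)
  if (is.unsorted(flights$dap)) stop("flights must be sorted by DAP")
  cfg <- list(seed = as.integer(seed), n_years = as.integer(n_years),
              years = 2020L + seq_len(n_years) - 1L,
              treatments = treatments,
              treatment_effects = treatment_effects,
              n_blocks = as.integer(n_blocks), block_sd = block_sd,
              plot_sd = plot_sd, vigor_mean = vigor_mean,
              flights = flights, band_noise_sd = band_noise_sd,
              pixel_noise_sd = pixel_noise_sd,
              yield_intercept = yield_intercept, yield_slope = yield_slope,
              yield_sd = yield_sd,
              yield_year_effects = rep_len(yield_year_effects, n_years),
              canopy_max = canopy_max, canopy_mid = canopy_mid,
              canopy_scale = canopy_scale, chl_peak = chl_peak,
              chl_plateau_half = chl_plateau_half, chl_width = chl_width,
              weed_fraction = weed_fraction, plot_px = as.integer(plot_px),
              margin_px = as.integer(margin_px),
              min_labels = as.integer(min_labels))
  class(cfg) <- "sim_config"
  cfg
}

#' Read and write simulation configurations as JSON
#'
#' @param config A [sim_config()].
#' @param path JSON file path.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  # JSON has one number type; restore double storage (the constructor
  # re-coerces its genuinely integer fields)
  raw <- lapply(raw, function(v) if (is.numeric(v)) as.numeric(v) else v)
  raw$flights <- as.data.frame(raw$flights)
  raw$flights$dap <- as.numeric(raw$flights$dap)
  raw$years <- NULL
  do.call(sim_config, raw[names(raw) %in% names(formals(sim_config))])
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<sim_config> seed=%d: %d year(s), %d treatments x %d blocks, ",
    "%d flights (%s)\n"),
    x$seed, x$n_years, length(x$treatments), x$n_blocks,
    nrow(x$flights), paste(x$flights$stage, collapse = " ")))
  invisible(x)
}

# ---- deterministic trajectory / spectral components -----------------------

#' Canopy-cover and chlorophyll trajectories
#'
#' `canopy_cover()` is a logistic rise to its plateau; `chl_gain()` is a
#' flat-topped unimodal gain (plateau over the early reproductive window,
#' Gaussian shoulders). The chlorophyll proxy of a plot is
#' vigor * chl_gain(dap).
#'
#' @param dap Days after planting.
#' @param config A [sim_config()].
#' @return Numeric in [0, 1].
#' @export
canopy_cover <- function(dap, config) {
  config$canopy_max / (1 + exp(-(dap - config$canopy_mid) /
                                 config$canopy_scale))
}

#' @rdname canopy_cover
#' @export
chl_gain <- function(dap, config) {
  d <- pmax(0, abs(dap - config$chl_peak) - config$chl_plateau_half)
  exp(-d^2 / (2 * config$chl_width^2))
}

#' Deterministic endmember spectra
#'
#' `leaf_reflectance()` maps a chlorophyll proxy and vigor to green-leaf
#' reflectance: visible bands decay exponentially with chlorophyll (strong
#' pigment absorption in blue/red, weaker in green), the red edge declines
#' mildly, and NIR increases with vigor (canopy structure).
#' `soil_reflectance()` is a fixed bright-soil spectrum rising with
#' wavelength.
#'
#' @param chl Chlorophyll proxy in [0, 1].
#' @param vigor Latent plot vigor in [0, 1].
#' @return Named numeric vector over [band_names()].
#' @export
leaf_reflectance <- function(chl, vigor) {
  c(blue = 0.02 + 0.08 * exp(-3.0 * chl),
    green = 0.05 + 0.13 * exp(-1.8 * chl),
    red = 0.04 + 0.14 * exp(-3.0 * chl),
    rededge = 0.16 + 0.14 * exp(-1.2 * chl),
    nir = 0.30 + 0.30 * vigor)
}

#' @rdname leaf_reflectance
#' @export
soil_reflectance <- function() {
  c(blue = 0.10, green = 0.14, red = 0.18, rededge = 0.22, nir = 0.26)
}

weed_reflectance <- function() {
  0.55 * soil_reflectance() + 0.45 * leaf_reflectance(0.25, 0.2)
}

# ---- experiment simulation ------------------------------------------------

#' Simulate the multi-year split-plot experiment
#'
#' Draws per-plot latent vigor v = mean + treatment + block + plot noise
#' (clipped to [0, 1]), links yield linearly to vigor, and generates
#' plot-mean five-band reflectance per flight as a canopy-weighted mixture
#' of the soil and leaf endmembers plus band noise. Fully reproducible
#' given the config seed; the caller's RNG state is untouched.
#'
#' @param config A [sim_config()].
#' @return Object of class `sim_experiment`: `yields` (year, plot_id,
#'   treatment, block, yield), `observations` (year, stage, dap, plot_id,
#'   five band columns), `truth` (list with `vigor` and noiseless per-flight
#'   `flights` ground truth) and `config`.
#' @export
simulate_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_experiment_impl(config))
}

simulate_experiment_impl <- function(config) {
  n_trt <- length(config$treatments)
  n_plots <- n_trt * config$n_blocks
  soil <- soil_reflectance()
  yields <- list(); obs <- list(); truth_flights <- list(); vig <- list()
  for (k in seq_len(config$n_years)) {
    yr <- config$years[k]
    design <- expand.grid(block = seq_len(config$n_blocks),
                          trt = seq_len(n_trt))
    plot_id <- sprintf("P%02d", seq_len(n_plots))
    beta <- stats::rnorm(config$n_blocks, 0, config$block_sd)
    eps <- stats::rnorm(n_plots, 0, config$plot_sd)
    v <- config$vigor_mean + config$treatment_effects[design$trt] +
      beta[design$block] + eps
    v <- pmin(pmax(v, 0), 1)
    yld <- config$yield_intercept + config$yield_year_effects[k] +
      config$yield_slope * v + stats::rnorm(n_plots, 0, config$yield_sd)
    yld <- pmax(yld, 0.01) # yields are strictly positive by definition
    yields[[k]] <- data.frame(
      year = yr, plot_id = plot_id,
      treatment = config$treatments[design$trt], block = design$block,
      yield = yld, stringsAsFactors = FALSE)
    vig[[k]] <- data.frame(
      year = yr, plot_id = plot_id,
      treatment = config$treatments[design$trt], block = design$block,
      vigor = v, stringsAsFactors = FALSE)
    for (f in seq_len(nrow(config$flights))) {
      dap <- config$flights$dap[f]
      stage <- config$flights$stage[f]
      cc <- canopy_cover(dap, config)
      chl <- v * chl_gain(dap, config)
      true_bands <- t(vapply(seq_len(n_plots), function(i) {
        (1 - cc) * soil + cc * leaf_reflectance(chl[i], v[i])
      }, numeric(5)))
      noisy <- true_bands + matrix(
        stats::rnorm(length(true_bands), 0, config$band_noise_sd),
        nrow = n_plots)
      noisy <- pmin(pmax(noisy, 0), 1)
      colnames(noisy) <- colnames(true_bands) <- band_names()
      obs[[length(obs) + 1L]] <- data.frame(
        year = yr, stage = stage, dap = dap, plot_id = plot_id, noisy,
        stringsAsFactors = FALSE)
      truth_flights[[length(truth_flights) + 1L]] <- data.frame(
        year = yr, stage = stage, dap = dap, plot_id = plot_id,
        canopy_fraction = cc, chl = chl, true_bands,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(
    yields = do.call(rbind, yields),
    observations = do.call(rbind, obs),
    truth = list(vigor = do.call(rbind, vig),
                 flights = do.call(rbind, truth_flights)),
    config = config
  ), class = "sim_experiment")
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat(sprintf(
    "<sim_experiment> %d year(s), %d plots/year, %d flights/year\n",
    x$config$n_years, length(unique(x$yields$plot_id)),
    nrow(x$config$flights)))
  invisible(x)
}

#' VI panels of a simulated (or observed) experiment
#'
#' Builds one `vi_matrix` per (year, flight) from the long observation
#' table.
#'
#' @param experiment A `sim_experiment` (or list with a compatible
#'   `observations` data.frame).
#' @param names VI names to compute (default: all registered).
#' @return List of `vi_matrix`.
#' @export
experiment_panels <- function(experiment, names = vi_names()) {
  ob <- experiment$observations
  keys <- unique(ob[c("year", "stage", "dap")])
  keys <- keys[order(keys$year, keys$dap), , drop = FALSE]
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- ob[ob$year == keys$year[i] & ob$dap == keys$dap[i], , drop = FALSE]
    bsets <- lapply(seq_len(nrow(sub)), function(j) {
      unlist(sub[j, band_names()])
    })
    base::names(bsets) <- sub$plot_id
    compute_panel(bsets, names,
                  flight = list(year = keys$year[i], date = NA,
                                dap = keys$dap[i], stage = keys$stage[i]))
  })
}

#' Null scenario: yields unlinked from vigor
#'
#' Returns the same experiment with the vigor-to-yield slope set to zero, a
#' negative control for estimating the screen's false-selection rate.
#'
#' @param config A [sim_config()].
#' @return A `sim_experiment` with `yield_slope = 0`.
#' @export
null_scenario <- function(config = sim_config()) {
  config$yield_slope <- 0
  simulate_experiment(config)
}

# ---- scene simulation -----------------------------------------------------

#' Simulate a pixel-level scene for one flight
#'
#' Lays the season's plots on a rectangular grid (blocks as rows,
#' treatments as columns), fills each plot with corn pixels at the flight's
#' canopy fraction (count = round(fraction * pixels), positions seeded),
#' soil elsewhere, and scatters weed pixels over the configured share of
#' the scene. Corn pixels are the plot's observed band set plus pixel
#' noise; soil and weed use their endmember spectra plus noise. Polygons
#' cover the harvested middle rows (the central half of each plot). Labels
#' are sampled from the true class map, `min_labels` per class where
#' available.
#'
#' @param experiment A `sim_experiment`.
#' @param year,stage Flight to render (defaults: first year, R1).
#' @param seed Seed for pixel-level randomness (default: config seed).
#' @return list with `scene`, `labels` (x, y, class), `polygons` (list of
#'   [plot_polygon()]) and `class_map` (character matrix).
#' @export
simulate_scene <- function(experiment, year = NULL, stage = "R1",
                           seed = NULL) {
  stopifnot(inherits(experiment, "sim_experiment"))
  cfg <- experiment$config
  if (is.null(year)) year <- cfg$years[1]
  if (is.null(seed)) seed <- cfg$seed
  ob <- experiment$observations
  fl <- ob[ob$year == year & ob$stage == stage, , drop = FALSE]
  tr <- experiment$truth$flights
  tr <- tr[tr$year == year & tr$stage == stage, , drop = FALSE]
  if (!nrow(fl)) stop("no flight ", stage, " in year ", year)
  if (any(tr$canopy_fraction < 0 | tr$canopy_fraction > 1)) {
    stop("canopy fraction outside [0, 1]")
  }
  design <- experiment$yields[experiment$yields$year == year, , drop = FALSE]
  n_trt <- length(cfg$treatments)
  pp <- cfg$plot_px; mg <- cfg$margin_px
  ncol_px <- n_trt * pp + (n_trt + 1) * mg
  nrow_px <- cfg$n_blocks * pp + (cfg$n_blocks + 1) * mg
  with_seed(seed, {
    soil <- soil_reflectance(); weed <- weed_reflectance()
    class_map <- matrix("soil", nrow_px, ncol_px)
    spectra <- matrix(rep(soil, each = nrow_px * ncol_px),
                      nrow = nrow_px * ncol_px)
    polygons <- vector("list", nrow(design))
    for (i in seq_len(nrow(design))) {
      bi <- design$block[i]
      ti <- match(design$treatment[i], cfg$treatments)
      row0 <- mg + (bi - 1) * (pp + mg) # top edge, px
      col0 <- mg + (ti - 1) * (pp + mg)
      rows <- (row0 + 1):(row0 + pp)
      cols <- (col0 + 1):(col0 + pp)
      cells <- as.vector(outer(rows, (cols - 1) * nrow_px, "+"))
      cf <- tr$canopy_fraction[tr$plot_id == design$plot_id[i]]
      n_corn <- round(cf * length(cells))
      corn_cells <- if (n_corn > 0) sample(cells, n_corn) else integer(0)
      class_map[corn_cells] <- "corn"
      pb <- unlist(fl[fl$plot_id == design$plot_id[i], band_names()])
      spectra[corn_cells, ] <- rep(pb, each = length(corn_cells))
      # harvested middle rows: central half of the plot, small end inset
      polygons[[i]] <- plot_polygon(design$plot_id[i], cbind(
        c(col0 + pp * 0.25, col0 + pp * 0.75, col0 + pp * 0.75,
          col0 + pp * 0.25),
        c(row0 + 2, row0 + 2, row0 + pp - 2, row0 + pp - 2)))
    }
    n_weed <- round(cfg$weed_fraction * length(class_map))
    weed_cells <- sample(which(class_map != "corn"), n_weed)
    class_map[weed_cells] <- "weed"
    spectra[weed_cells, ] <- rep(weed, each = length(weed_cells))
    noisy <- spectra + matrix(
      stats::rnorm(length(spectra), 0, cfg$pixel_noise_sd), ncol = 5)
    noisy <- pmin(pmax(noisy, 0), 1)
    a <- array(noisy, c(nrow_px, ncol_px, 5L))
    scn <- scene(a, pixel_size = 1, origin = c(0, 0), unit = "reflectance")
    labels <- do.call(rbind, lapply(c("corn", "soil", "weed"), function(cl) {
      cells <- which(class_map == cl)
      if (!length(cells)) return(NULL)
      take <- sample(cells, min(cfg$min_labels, length(cells)))
      row <- (take - 1) %% nrow_px + 1
      col <- (take - 1) %/% nrow_px + 1
      data.frame(x = col - 0.5, y = row - 0.5, class = cl,
                 stringsAsFactors = FALSE)
    }))
    list(scene = scn, labels = labels, polygons = polygons,
         class_map = class_map)
  })
}
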