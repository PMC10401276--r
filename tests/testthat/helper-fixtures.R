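# shared fixtures and cached heavy computations for the suite

# a uniform reflectance scene with all five bands equal to `value`
uniform_scene <- function(nrow = 8, ncol = 8, value = 0.4) {
  scene(array(value, c(nrow, ncol, 5)), pixel_size = 1, origin = c(0, 0))
}

# tiny labelled scene with three well-separated class spectra laid out in
# vertical thirds: corn | soil | weed
tiny_labelled_scene <- function(n = 30, noise = 0.01, seed = 42) {
  spectra <- list(
    corn = c(0.03, 0.08, 0.05, 0.22, 0.50),
    soil = c(0.10, 0.14, 0.18, 0.22, 0.26),
    weed = c(0.06, 0.12, 0.10, 0.22, 0.35)
  )
  set.seed(seed)
  a <- array(0, c(n, 3 * n, 5))
  cls <- matrix("", n, 3 * n)
  for (k in seq_along(spectra)) {
    cols <- ((k - 1) * n + 1):(k * n)
    for (b in 1:5) {
      a[, cols, b] <- pmin(pmax(
        spectra[[k]][b] + rnorm(n * n, 0, noise), 0), 1)
    }
    cls[, cols] <- names(spectra)[k]
  }
  labels <- data.frame(
    x = rep(seq_len(3 * n) - 0.5, each = n),
    y = rep(seq_len(n) - 0.5, times = 3 * n),
    class = as.vector(cls), stringsAsFactors = FALSE)
  list(scene = scene(a), labels = labels, class_map = cls)
}

# random band sets as a data.frame; upper bound keeps c=2 scaling in range
random_bandsets <- function(n, seed, max_val = 0.45) {
  set.seed(seed)
  data.frame(blue = runif(n, 0.01, max_val), green = runif(n, 0.01, max_val),
             red = runif(n, 0.01, max_val),
             rededge = runif(n, 0.01, max_val),
             nir = runif(n, 0.01, max_val))
}

# cache for replicate runs shared between acceptance blocks
.acc_cache <- new.env(parent = emptyenv())

# 100 default-config replicates: per year, are the planted chlorophyll
# indices stable? plus the R1 and V5 MTCI-yield correlations of year 1
acceptance_screen_reps <- function(n_reps = 100) {
  key <- paste0("screen_", n_reps)
  if (!is.null(.acc_cache[[key]])) return(.acc_cache[[key]])
  planted <- c("MTCI", "LCI", "mND705")
  res <- lapply(seq_len(n_reps), function(i) {
    ex <- simulate_experiment(sim_config(seed = 20000 + i))
    panels <- experiment_panels(ex, planted)
    records <- score_correlations(panels, ex$yields)
    stable_by_year <- vapply(split(records, records$year), function(rec) {
      s <- summarize_year(rec)
      all(planted %in% stable_set(s))
    }, logical(1))
    y1 <- ex$yields[ex$yields$year == ex$config$years[1], ]
    stages <- vapply(panels, attr, "", "stage")
    yrs <- vapply(panels, attr, 0, "year")
    r_at <- function(stg) {
      pm <- panels[[which(yrs == ex$config$years[1] & stages == stg)]]
      abs(cor(pm[y1$plot_id, "MTCI"], y1$yield))
    }
    list(all_stable = all(stable_by_year), r_r1 = r_at("R1"),
         r_v5 = r_at("V5"))
  })
  out <- list(
    all_stable = vapply(res, `[[`, logical(1), "all_stable"),
    r_r1 = vapply(res, `[[`, numeric(1), "r_r1"),
    r_v5 = vapply(res, `[[`, numeric(1), "r_v5"))
  .acc_cache[[key]] <- out
  out
}
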