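#' Multispectral scenes
#'
#' A scene is a stack of five co-registered raster planes (blue, green, red,
#' rededge, nir) on a regular pixel grid in scene-local metric coordinates:
#' origin at the top-left corner, x increasing with columns, y increasing
#' with rows (downwards), pixel centers at ((col - 0.5), (row - 0.5)) times
#' the pixel size. Values are either raw digital numbers (16-bit range) or
#' reflectance fractions; the `unit` flag records which.
#'
#' @param bands A nrow x ncol x 5 numeric array (third dimension in
#'   [band_names()] order), or a named list of five equal-size matrices.
#' @param pixel_size Pixel edge length in metres.
#' @param origin Numeric (x0, y0) of the top-left scene corner.
#' @param unit "reflectance" (values in [0, 1]) or "dn" (values in
#'   [0, 65535]).
#' @return An object of class `scene`.
#' @export
scene <- function(bands, pixel_size = 1, origin = c(0, 0),
                  unit = c("reflectance", "dn")) {
  unit <- match.arg(unit)
  if (is.list(bands)) {
    if (!all(band_names() %in% names(bands))) {
      stop("band list must contain: ", paste(band_names(), collapse = ", "))
    }
    dims <- dim(bands[[band_names()[1]]])
    a <- array(NA_real_, c(dims, 5L),
               dimnames = list(NULL, NULL, band_names()))
    for (bn in band_names()) {
      if (!identical(dim(bands[[bn]]), dims)) {
        stop("all band planes must share identical dimensions")
      }
      a[, , bn] <- bands[[bn]]
    }
    bands <- a
  }
  if (length(dim(bands)) != 3L || dim(bands)[3] != 5L) {
    stop("bands must be a nrow x ncol x 5 array")
  }
  dimnames(bands) <- list(NULL, NULL, band_names())
  rng <- range(bands, na.rm = TRUE)
  if (unit == "reflectance" && (rng[1] < 0 || rng[2] > 1)) {
    stop("reflectance scene has values outside [0, 1]")
  }
  if (unit == "dn" && (rng[1] < 0 || rng[2] > 65535)) {
    stop("DN scene has values outside [0, 65535]")
  }
  structure(list(bands = bands, pixel_size = pixel_size,
                 origin = as.numeric(origin), unit = unit),
            class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  d <- dim(x$bands)
  cat(sprintf("<scene> %d x %d px, 5 bands, pixel %.3g m, unit=%s\n",
              d[1], d[2], x$pixel_size, x$unit))
  invisible(x)
}

scene_dim <- function(scn) dim(scn$bands)[1:2]

# pixel-center coordinates of every pixel, in column-major plane order
pixel_centers <- function(scn) {
  d <- scene_dim(scn)
  px <- scn$pixel_size
  list(x = scn$origin[1] + (rep(seq_len(d[2]), each = d[1]) - 0.5) * px,
       y = scn$origin[2] + (rep(seq_len(d[1]), times = d[2]) - 0.5) * px)
}

# 5-column feature matrix of all pixels (column-major within each plane)
scene_features <- function(scn) {
  d <- scene_dim(scn)
  m <- matrix(scn$bands, nrow = d[1] * d[2], ncol = 5L)
  colnames(m) <- band_names()
  m
}

# map scene coordinates to linear pixel indices (column-major plane index)
coords_to_index <- function(scn, x, y) {
  d <- scene_dim(scn)
  col <- pmin(pmax(ceiling((x - scn$origin[1]) / scn$pixel_size), 1L), d[2])
  row <- pmin(pmax(ceiling((y - scn$origin[2]) / scn$pixel_size), 1L), d[1])
  (col - 1L) * d[1] + row
}

#' Radiometric calibration against a reference panel
#'
#' Converts digital numbers to reflectance using the calibration-panel
#' reading per band: reflectance = DN * (panel_reflectance / panel_dn),
#' clipped to [0, 1].
#'
#' @param scn A `scene` in digital numbers.
#' @param panel_dn Numeric length-5 (band order) panel digital numbers, > 0.
#' @param panel_reflectance Numeric length-5 known panel reflectance
#'   fractions.
#' @return A `scene` flagged as reflectance.
#' @export
calibrate <- function(scn, panel_dn, panel_reflectance) {
  stopifnot(inherits(scn, "scene"))
  if (scn$unit != "dn") stop("scene is already in reflectance units")
  panel_dn <- rep_len(panel_dn, 5L)
  panel_reflectance <- rep_len(panel_reflectance, 5L)
  if (any(panel_dn <= 0)) stop("calibration error: panel DN must be > 0")
  out <- scn$bands
  for (k in 1:5) {
    out[, , k] <- pmin(pmax(scn$bands[, , k] *
                              (panel_reflectance[k] / panel_dn[k]), 0), 1)
  }
  scene(out, pixel_size = scn$pixel_size, origin = scn$origin,
        unit = "reflectance")
}

# ---- per-pixel classification ---------------------------------------------

#' Train a per-pixel background classifier
#'
#' Fits a supervised per-pixel classifier over the five-band feature vector
#' to separate corn canopy from soil and weed background, reporting holdout
#' accuracy. The default learner is a maximum-margin linear classifier
#' (linear-kernel support vector machine).
#'
#' @param scn A reflectance `scene`.
#' @param labels data.frame with columns `x`, `y` (scene coordinates) and
#'   `class` (e.g. "corn", "soil", "weed"); at least two classes.
#' @param holdout_fraction Fraction of labelled pixels held out for accuracy
#'   estimation (default 0.2).
#' @param seed Integer seed; training and the holdout split are fully
#'   deterministic given it.
#' @param cost Soft-margin cost of the SVM.
#' @return A `pixel_classifier` with elements `model`, `accuracy` (holdout),
#'   `classes`, `n_train`, `n_holdout`.
#' @export
train_pixel_classifier <- function(scn, labels, holdout_fraction = 0.2,
                                   seed = 1L, cost = 1) {
  stopifnot(inherits(scn, "scene"))
  if (!all(c("x", "y", "class") %in% names(labels))) {
    stop("labels must have columns x, y, class")
  }
  cls <- factor(labels$class)
  if (nlevels(cls) < 2L) {
    stop("labels contain a single class; at least two are required")
  }
  feats <- scene_features(scn)[coords_to_index(scn, labels$x, labels$y), ,
                               drop = FALSE]
  n <- nrow(feats)
  idx_holdout <- with_seed(seed, sample.int(n, max(1L, round(
    holdout_fraction * n))))
  train <- setdiff(seq_len(n), idx_holdout)
  fit <- e1071::svm(x = feats[train, , drop = FALSE], y = cls[train],
                    kernel = "linear", cost = cost, scale = TRUE)
  pred <- stats::predict(fit, feats[idx_holdout, , drop = FALSE])
  acc <- mean(pred == cls[idx_holdout])
  structure(list(model = fit, accuracy = acc, classes = levels(cls),
                 n_train = length(train), n_holdout = length(idx_holdout)),
            class = "pixel_classifier")
}

#' @export
print.pixel_classifier <- function(x, ...) {
  cat(sprintf(
    "<pixel_classifier> classes: %s; holdout accuracy %.4f (n=%d)\n",
    paste(x$classes, collapse = "/"), x$accuracy, x$n_holdout))
  invisible(x)
}

#' Classify every pixel of a scene
#' @param classifier A `pixel_classifier`.
#' @param scn A reflectance `scene`.
#' @return Character matrix of class labels, same grid as the scene.
#' @export
classify_scene <- function(classifier, scn) {
  stopifnot(inherits(classifier, "pixel_classifier"), inherits(scn, "scene"))
  pred <- stats::predict(classifier$model, scene_features(scn))
  matrix(as.character(pred), nrow = scene_dim(scn)[1])
}

# ---- zonal statistics -----------------------------------------------------

#' Plot polygons
#'
#' A plot polygon is the digitized harvest region of one subplot (typically
#' its middle two rows): a simple polygon with positive area in scene
#' coordinates, carrying a `plot_id`.
#'
#' @param plot_id Plot identifier.
#' @param coords Two-column matrix of (x, y) vertices (closed or open ring).
#' @return An object of class `plot_polygon`.
#' @export
plot_polygon <- function(plot_id, coords) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2L, nrow(coords) >= 3L)
  # drop closing vertex if the ring is explicitly closed
  if (all(coords[1, ] == coords[nrow(coords), ]) && nrow(coords) > 3L) {
    coords <- coords[-nrow(coords), , drop = FALSE]
  }
  a <- polygon_area(coords)
  if (!is.finite(a) || a <= 0) {
    stop("polygon for plot ", plot_id, " must be simple with positive area")
  }
  structure(list(plot_id = as.character(plot_id), coords = coords),
            class = "plot_polygon")
}

polygon_area <- function(coords) {
  x <- coords[, 1]; y <- coords[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Masked zonal mean reflectance per plot
#'
#' For each plot polygon, classifies the pixels whose centers fall inside,
#' keeps those assigned to `keep_class` (corn canopy by default) and averages
#' their reflectance per band. The kept-pixel share is reported as the
#' canopy fraction (the complement is the soil/background cover).
#'
#' @param scn A reflectance `scene`.
#' @param classifier A `pixel_classifier`, or a character matrix of
#'   per-pixel classes on the scene grid (e.g. from [classify_scene()] or an
#'   external classification).
#' @param polygons List of `plot_polygon`s, all intersecting the scene.
#' @param keep_class Class retained for averaging (default "corn").
#' @return data.frame with one row per plot: `plot_id`, the five band means
#'   (`NA` if no pixel is kept), `canopy_fraction`, its complement
#'   `soil_fraction`, `n_pixels`, `n_kept`.
#' @export
mask_and_zonal_mean <- function(scn, classifier, polygons,
                                keep_class = "corn") {
  stopifnot(inherits(scn, "scene"))
  d <- scene_dim(scn)
  ext <- c(scn$origin[1], scn$origin[1] + d[2] * scn$pixel_size,
           scn$origin[2], scn$origin[2] + d[1] * scn$pixel_size)
  ctr <- pixel_centers(scn)
  pts <- cbind(ctr$x, ctr$y)
  feats <- scene_features(scn)
  precomputed <- is.matrix(classifier) && is.character(classifier)
  if (precomputed && !identical(dim(classifier), d)) {
    stop("class matrix dimensions do not match the scene grid")
  }
  out <- lapply(polygons, function(pg) {
    stopifnot(inherits(pg, "plot_polygon"))
    bb <- apply(pg$coords, 2, range)
    if (bb[2, 1] < ext[1] || bb[1, 1] > ext[2] ||
        bb[2, 2] < ext[3] || bb[1, 2] > ext[4]) {
      stop("polygon for plot ", pg$plot_id, " lies outside the scene")
    }
    cand <- which(pts[, 1] >= bb[1, 1] & pts[, 1] <= bb[2, 1] &
                    pts[, 2] >= bb[1, 2] & pts[, 2] <= bb[2, 2])
    inside <- cand[mgcv::in.out(
      rbind(pg$coords, pg$coords[1, ]), pts[cand, , drop = FALSE])]
    if (!length(inside)) {
      stop("polygon for plot ", pg$plot_id,
           " contains no pixel centers in the scene")
    }
    idx <- inside # pixel-center order matches the feature-matrix row order
    pred <- if (precomputed) {
      classifier[idx]
    } else {
      as.character(stats::predict(classifier$model,
                                  feats[idx, , drop = FALSE]))
    }
    kept <- idx[pred == keep_class]
    means <- if (length(kept)) {
      colMeans(feats[kept, , drop = FALSE])
    } else {
      stats::setNames(rep(NA_real_, 5L), band_names())
    }
    cf <- length(kept) / length(idx)
    data.frame(plot_id = pg$plot_id, t(means),
               canopy_fraction = cf, soil_fraction = 1 - cf,
               n_pixels = length(idx), n_kept = length(kept),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# ---- I/O ------------------------------------------------------------------

#' Read and write multispectral scenes as multi-page TIFF
#'
#' One TIFF directory (page) per band, in [band_names()] order. Reflectance
#' scenes are stored as 32-bit float; DN scenes as 16-bit integer samples.
#' Pixel size and origin are not stored in the file and are supplied on read.
#'
#' @param scn A `scene`.
#' @param path TIFF file path.
#' @export
write_scene <- function(scn, path) {
  stopifnot(inherits(scn, "scene"))
  pages <- lapply(band_names(), function(bn) {
    if (scn$unit == "dn") scn$bands[, , bn] / 65535 else scn$bands[, , bn]
  })
  if (scn$unit == "dn") {
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  } else {
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  }
  invisible(path)
}

#' @rdname write_scene
#' @param unit Unit flag of the stored scene.
#' @param pixel_size,origin Grid metadata to attach on read.
#' @export
read_scene <- function(path, unit = c("reflectance", "dn"),
                       pixel_size = 1, origin = c(0, 0)) {
  unit <- match.arg(unit)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != 5L) stop("expected a 5-page TIFF, got ", length(pages))
  a <- array(NA_real_, c(dim(pages[[1]]), 5L))
  for (k in 1:5) {
    a[, , k] <- if (unit == "dn") round(pages[[k]] * 65535) else pages[[k]]
  }
  scene(a, pixel_size = pixel_size, origin = origin, unit = unit)
}

#' Read and write plot polygons as GeoJSON
#'
#' FeatureCollection of Polygon features, each with a `plot_id` property;
#' coordinates are scene-local (x, y).
#'
#' @param polygons List of `plot_polygon`s.
#' @param path GeoJSON path.
#' @export
write_plot_polygons <- function(polygons, path) {
  feats <- lapply(polygons, function(pg) {
    ring <- rbind(pg$coords, pg$coords[1, ])
    list(type = "Feature",
         properties = list(plot_id = pg$plot_id),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) ring[i, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_plot_polygons
#' @export
read_plot_polygons <- function(path) {
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection")) {
    stop("expected a GeoJSON FeatureCollection")
  }
  lapply(gj$features, function(f) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(p) unlist(p)))
    plot_polygon(f$properties$plot_id, ring)
  })
}

#' Read and write pixel label sets as CSV (columns x, y, class)
#' @param labels data.frame with `x`, `y`, `class`.
#' @param path CSV path.
#' @export
write_pixel_labels <- function(labels, path) {
  utils::write.csv(labels[c("x", "y", "class")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pixel_labels
#' @export
read_pixel_labels <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# run code with a temporary RNG state; restores the caller's state after
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
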