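#' Simple linear yield model on one vegetation index
#'
#' Ordinary least squares of yield on a single index, reporting the
#' coefficient of determination, the mean absolute percentage error of the
#' in-sample predictions, and the two-sided slope test with the usual
#' significance stars.
#'
#' @param x Index values (predictor).
#' @param y Yields, Mg/ha (response); must be positive for MAPE.
#' @param vi_name,year,stage Optional labels carried on the fit.
#' @return Object of class `vi_lm` with elements `slope`, `intercept`, `n`,
#'   `r_squared`, `mape`, `p`, `stars`, `vi_name`, `year`, `stage` and the
#'   underlying `lm` fit.
#' @examples
#' f <- fit_simple_lm(1:5, 2 * (1:5) + 1)
#' coef(f)          # intercept 1, slope 2
#' f$r_squared      # 1
#' @export
fit_simple_lm <- function(x, y, vi_name = NA_character_, year = NA,
                          stage = NA_character_) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("fewer than 3 complete pairs (n = ", n, ")")
  if (stats::sd(x) == 0) stop("zero variance in predictor")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  p <- sm$coefficients["x", "Pr(>|t|)"]
  structure(list(
    vi_name = vi_name, year = year, stage = stage,
    slope = unname(stats::coef(fit)["x"]),
    intercept = unname(stats::coef(fit)["(Intercept)"]),
    n = n, r_squared = sm$r.squared,
    mape = if (all(y > 0)) mape(y, stats::fitted(fit)) else NA_real_,
    p = p, stars = p_stars(p), lm = fit
  ), class = "vi_lm")
}

#' @export
print.vi_lm <- function(x, ...) {
  cat(sprintf(
    "<vi_lm> %s%s%s: yield = %.4g + %.4g * VI  (n=%d, R2=%.3f, MAPE=%.2f%%, %s)\n",
    ifelse(is.na(x$vi_name), "", paste0(x$vi_name, " ")),
    ifelse(is.na(x$year), "", paste0(x$year, " ")),
    ifelse(is.na(x$stage), "", x$stage),
    x$intercept, x$slope, x$n, x$r_squared, x$mape, x$stars))
  invisible(x)
}

#' @export
coef.vi_lm <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.vi_lm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::fitted(object$lm))
  x <- if (is.data.frame(newdata)) newdata$x else newdata
  object$intercept + object$slope * x
}

#' @export
residuals.vi_lm <- function(object, ...) stats::residuals(object$lm)

#' Significance stars for a p-value
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, otherwise "ns".
#'
#' @param p Numeric p-value(s).
#' @return Character vector of star codes.
#' @export
p_stars <- function(p) {
  vapply(p, function(pi) {
    if (!is.finite(pi)) return(NA_character_)
    if (pi < 0.001) "***" else if (pi < 0.01) "**"
    else if (pi < 0.05) "*" else "ns"
  }, character(1))
}

#' Mean absolute percentage error
#'
#' 100 * mean(|y - yhat| / y); observed values must be strictly positive.
#'
#' @param y Observed values.
#' @param yhat Predicted values.
#' @return MAPE in percent.
#' @examples
#' mape(c(10, 10), c(9, 11)) # 10
#' @export
mape <- function(y, yhat) {
  stopifnot(length(y) == length(yhat))
  if (any(!is.finite(y)) || any(y <= 0)) {
    stop("MAPE requires strictly positive observed values")
  }
  100 * mean(abs(y - yhat) / y)
}

#' Select the best index per stage or year
#'
#' Within each group, fits are ranked by descending R-squared, ties broken
#' by lower MAPE, then alphabetically by index name. Win counts per index
#' across all groups are reported alongside (how often an index was the
#' season's best performer).
#'
#' @param fits data.frame with columns `vi_name`, `r_squared`, `mape` and
#'   the grouping columns, or a list of `vi_lm` objects.
#' @param per Grouping columns (default c("year", "stage")).
#' @return list with `winners` (one row per group) and `win_counts`
#'   (vi_name, wins, sorted by descending wins).
#' @export
select_best <- function(fits, per = c("year", "stage")) {
  if (!is.data.frame(fits)) fits <- fits_to_frame(fits)
  stopifnot(all(c("vi_name", "r_squared", "mape") %in% names(fits)),
            all(per %in% names(fits)))
  key <- interaction(fits[per], drop = TRUE, lex.order = TRUE)
  winners <- do.call(rbind, lapply(split(fits, key), function(g) {
    if (!nrow(g)) stop("empty group")
    g[order(-g$r_squared, g$mape, g$vi_name, method = "radix")[1], ,
      drop = FALSE]
  }))
  rownames(winners) <- NULL
  wc <- table(winners$vi_name)
  win_counts <- data.frame(vi_name = names(wc), wins = as.integer(wc),
                           stringsAsFactors = FALSE)
  win_counts <- win_counts[order(-win_counts$wins, win_counts$vi_name,
                                 method = "radix"), ]
  rownames(win_counts) <- NULL
  list(winners = winners, win_counts = win_counts)
}

fits_to_frame <- function(fits) {
  stopifnot(all(vapply(fits, inherits, logical(1), "vi_lm")))
  do.call(rbind, lapply(fits, function(f) {
    data.frame(vi_name = f$vi_name, year = f$year, stage = f$stage,
               slope = f$slope, intercept = f$intercept, n = f$n,
               r_squared = f$r_squared, mape = f$mape, p = f$p,
               stars = f$stars, stringsAsFactors = FALSE)
  }))
}

#' Treatment comparison with LSD letter grouping
#'
#' One-way randomized-complete-block ANOVA (treatment + block as fixed
#' effects) followed by Fisher's least significant difference,
#' LSD = t(1 - alpha/2, df_error) * sqrt(2 * MSE / r) with r replicates per
#' treatment. Letters are assigned by descending mean with the standard
#' agglomerative rule: treatments sharing a letter do not differ by more
#' than the LSD.
#'
#' @param data data.frame with columns `yield`, `treatment`, `block`.
#' @param alpha Significance level (default 0.05).
#' @return data.frame of class `lsd_grouping`: treatment, mean, sd, letters;
#'   attributes `lsd`, `mse`, `alpha`.
#' @export
lsd_letters <- function(data, alpha = 0.05) {
  stopifnot(all(c("yield", "treatment", "block") %in% names(data)))
  trt <- factor(data$treatment)
  blk <- factor(data$block)
  if (nlevels(trt) < 2L) stop("at least 2 treatments are required")
  reps <- table(trt)
  if (any(reps < 2L)) stop("at least 2 replicates per treatment are required")
  means <- tapply(data$yield, trt, mean)
  sds <- tapply(data$yield, trt, stats::sd)
  fit <- stats::aov(yield ~ treatment + block,
                    data = data.frame(yield = data$yield, treatment = trt,
                                      block = blk))
  ms <- stats::anova(fit)
  mse <- ms["Residuals", "Mean Sq"]
  dfe <- ms["Residuals", "Df"]
  r <- min(reps)
  ord <- order(-means)
  means <- means[ord]; sds <- sds[ord]
  if (!is.finite(mse) || mse == 0) {
    # degenerate: no residual variation; distinct means all differ
    lsd <- 0
    differs <- abs(outer(means, means, "-")) > 0
  } else {
    lsd <- stats::qt(1 - alpha / 2, dfe) * sqrt(2 * mse / r)
    differs <- abs(outer(means, means, "-")) > lsd
  }
  letters_vec <- assign_letters(!differs)
  out <- data.frame(treatment = names(means), mean = as.numeric(means),
                    sd = as.numeric(sds), letters = letters_vec,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "lsd") <- lsd
  attr(out, "mse") <- mse
  attr(out, "alpha") <- alpha
  class(out) <- c("lsd_grouping", "data.frame")
  out
}

# agglomerative letter assignment over a symmetric "not significantly
# different" matrix whose rows/cols are ordered by descending mean: find
# maximal runs of mutual non-significance, one letter per non-nested run
assign_letters <- function(nsd) {
  k <- nrow(nsd)
  runs <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && all(nsd[i:(j + 1), i:(j + 1)])) j <- j + 1
    runs[[length(runs) + 1L]] <- i:j
  }
  # drop runs nested inside another
  keep <- vapply(seq_along(runs), function(a) {
    !any(vapply(seq_along(runs), function(b) {
      b != a && all(runs[[a]] %in% runs[[b]])
    }, logical(1)))
  }, logical(1))
  runs <- unique(runs[keep])
  lab <- character(k)
  for (m in seq_along(runs)) {
    lab[runs[[m]]] <- paste0(lab[runs[[m]]], letters[m])
  }
  lab
}

#' Adjust wet yield to the 15.5 percent moisture standard
#'
#' Grain yields are conventionally reported at 15.5 percent water content:
#' adjusted = wet * (100 - measured) / (100 - 15.5).
#'
#' @param wet_yield Harvested yield, Mg/ha, at the measured moisture.
#' @param measured_moisture Grain moisture at harvest, percent, in [0, 100).
#' @return Yield at 15.5 percent moisture, Mg/ha.
#' @examples
#' moisture_adjust(10, 20) # 9.467
#' @export
moisture_adjust <- function(wet_yield, measured_moisture) {
  if (any(!is.finite(measured_moisture)) ||
      any(measured_moisture < 0 | measured_moisture >= 100)) {
    stop("measured_moisture must lie in [0, 100)")
  }
  wet_yield * (100 - measured_moisture) / (100 - 15.5)
}

#' Write per-stage regression results as a results-table CSV
#'
#' One row per (year, stage, index) with R-squared, stars, MAPE and a flag
#' marking the group winner.
#'
#' @param fits data.frame as produced by [fits_to_frame()] internals (or a
#'   list of `vi_lm`).
#' @param path Output CSV path.
#' @param per Grouping for the winner flag.
#' @export
write_regression_table <- function(fits, path, per = c("year", "stage")) {
  if (!is.data.frame(fits)) fits <- fits_to_frame(fits)
  sel <- select_best(fits, per = per)
  key <- function(d) do.call(paste, c(d[c(per, "vi_name")], sep = "\r"))
  fits$winner <- key(fits) %in% key(sel$winners)
  utils::write.csv(
    fits[c(per, "vi_name", "r_squared", "stars", "mape", "winner")],
    path, row.names = FALSE)
  invisible(path)
}
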