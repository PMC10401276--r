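#' Pearson correlation with pairwise missing handling
#'
#' Sample Pearson correlation between two paired vectors after removing
#' pairs with a missing member; the two-sided p-value comes from the t
#' transform with n - 2 degrees of freedom. A zero-variance input yields a
#' missing r with a warning instead of an error, so a degenerate flight can
#' flow through the screen.
#'
#' @param x,y Paired numeric vectors.
#' @return list(r, p, n) with n the number of complete pairs.
#' @examples
#' vi_pearson(c(1, 2, 3), c(1, 3, 2)) # r = 0.5
#' @export
vi_pearson <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("fewer than 3 complete pairs (n = ", n, ")")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance in input; correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = n))
  }
  r <- stats::cor(x, y)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  list(r = r, p = p, n = n)
}

#' Score VI-yield correlations per flight
#'
#' Correlates every index with plot yield, one record per index per flight,
#' and assigns a score of 1 whenever the absolute correlation reaches the
#' threshold (default 0.7, the conventional strong-correlation cut-off).
#' Selection uses only the threshold; p-values are reported for reference.
#'
#' @param panels A `vi_matrix` or list of them (one per flight).
#' @param yields data.frame with columns `year`, `plot_id`, `yield`
#'   (Mg/ha at 15.5 percent grain moisture).
#' @param threshold Absolute-correlation score threshold.
#' @return data.frame of class `correlation_records`: vi_name, year, date,
#'   dap, stage, r, p, n_pairs, score.
#' @export
score_correlations <- function(panels, yields, threshold = 0.7) {
  if (inherits(panels, "vi_matrix")) panels <- list(panels)
  stopifnot(all(c("plot_id", "yield") %in% names(yields)))
  recs <- lapply(panels, function(pm) {
    yr <- attr(pm, "year")
    ytab <- yields
    if ("year" %in% names(yields) && !is.na(yr)) {
      ytab <- yields[yields$year == yr, , drop = FALSE]
    }
    shared <- intersect(rownames(pm), as.character(ytab$plot_id))
    if (length(shared) < 3L) {
      stop("fewer than 3 plots shared between VI panel and yield table")
    }
    yv <- ytab$yield[match(shared, as.character(ytab$plot_id))]
    rows <- lapply(colnames(pm), function(vn) {
      ct <- vi_pearson(pm[shared, vn], yv)
      data.frame(vi_name = vn, year = yr, date = attr(pm, "date"),
                 dap = attr(pm, "dap"), stage = attr(pm, "stage"),
                 r = ct$r, p = ct$p, n_pairs = ct$n,
                 score = as.integer(is.finite(ct$r) &&
                                      abs(ct$r) >= threshold),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  class(out) <- c("correlation_records", "data.frame")
  out
}

#' Within-year stability summary of the correlation screen
#'
#' Sums the per-flight scores of each index over a season. An index is
#' stable when its cumulative score reaches `min_count` (default 2: strongly
#' correlated with yield on at least two flight dates). Indices with at
#' least one scoring flight are additionally ranked into tiers by descending
#' cumulative score (ties share a tier, alphabetical within); the top
#' `top_k` tiers identify the season's best-predictive-power indices.
#'
#' @param records `correlation_records` from a single year, covering at
#'   least two flights.
#' @param min_count Cumulative score needed to be called stable.
#' @param top_k Number of tiers reported as top tiers.
#' @return data.frame of class `stability_summary`: vi_name, year,
#'   cumulative_score, stable, tier (NA for indices that never scored).
#' @export
summarize_year <- function(records, min_count = 2L, top_k = 3L) {
  stopifnot(inherits(records, "data.frame"),
            all(c("vi_name", "score") %in% names(records)))
  yrs <- unique(records$year)
  if (length(yrs) != 1L) {
    stop("records must come from a single year; got: ",
         paste(yrs, collapse = ", "))
  }
  flights <- unique(records[c("date", "dap", "stage")])
  if (nrow(flights) < 2L) {
    stop("cumulative criterion needs records from at least 2 flights")
  }
  cum <- tapply(records$score, records$vi_name, sum)
  vi <- sort(names(cum), method = "radix")
  cum <- as.integer(cum[vi])
  pos <- sort(unique(cum[cum >= 1L]), decreasing = TRUE)
  tier <- ifelse(cum >= 1L, match(cum, pos), NA_integer_)
  out <- data.frame(vi_name = vi, year = yrs, cumulative_score = cum,
                    stable = cum >= min_count, tier = tier,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$cumulative_score, out$vi_name, method = "radix"), ]
  rownames(out) <- NULL
  attr(out, "min_count") <- min_count
  attr(out, "top_k") <- top_k
  class(out) <- c("stability_summary", "data.frame")
  out
}

#' Stable index set of a season
#' @param summary A `stability_summary`.
#' @return Sorted character vector of stable VI names.
#' @export
stable_set <- function(summary) {
  stopifnot(inherits(summary, "stability_summary"))
  sort(summary$vi_name[summary$stable], method = "radix")
}

#' Three-year set partition of stable indices
#'
#' Partitions the union of three seasons' stable-index sets into the seven
#' disjoint membership regions (each year alone, each pair, all three),
#' identifying indices unique to one season and those common across
#' seasons — the cross-year view of predictive power.
#'
#' @param stable_sets Named list of exactly three character vectors
#'   (year -> stable VI names).
#' @return Object of class `venn_partition` with `sets` (the input, sorted),
#'   `regions` (7 disjoint sorted vectors keyed e.g. "2020&2021"), `union`,
#'   and `counts`.
#' @export
venn_partition <- function(stable_sets) {
  if (length(stable_sets) != 3L || is.null(names(stable_sets))) {
    stop("exactly 3 named year-sets are required")
  }
  sets <- lapply(stable_sets, function(s) sort(unique(as.character(s)),
                                               method = "radix"))
  yrs <- names(sets)
  universe <- sort(unique(unlist(sets)), method = "radix")
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L)
  combos <- list(c(1), c(2), c(3), c(1, 2), c(1, 3), c(2, 3), c(1, 2, 3))
  regions <- lapply(combos, function(cb) {
    inside <- rowSums(member[, cb, drop = FALSE]) == length(cb) &
      rowSums(member[, -cb, drop = FALSE]) == 0
    universe[inside]
  })
  names(regions) <- vapply(combos, function(cb) paste(yrs[cb], collapse = "&"),
                           character(1))
  structure(list(sets = sets, regions = regions, union = universe,
                 counts = vapply(regions, length, integer(1))),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("<venn_partition> union:", length(x$union), "indices\n")
  for (nm in names(x$regions)) {
    cat(sprintf("  %-22s (%2d): %s\n", nm, length(x$regions[[nm]]),
                paste(x$regions[[nm]], collapse = ", ")))
  }
  invisible(x)
}

#' Number of indices present in at least k of the three year-sets
#' @param partition A `venn_partition`.
#' @param k Minimum number of years (1, 2 or 3).
#' @return Sorted character vector of VI names.
#' @export
venn_at_least <- function(partition, k) {
  stopifnot(inherits(partition, "venn_partition"), k %in% 1:3)
  deg <- lengths(regmatches(names(partition$regions),
                            gregexpr("&", names(partition$regions)))) + 1L
  sort(unlist(partition$regions[deg >= k], use.names = FALSE),
       method = "radix")
}

# ---- serialization --------------------------------------------------------

#' Write the correlation screen as a heatmap-shaped CSV
#'
#' Rows are indices, columns flights (stage labels); cells hold r, blanked
#' when |r| is below the score threshold, mirroring the usual
#' season-correlation heat map.
#'
#' @param records `correlation_records` for one year.
#' @param path Output CSV path.
#' @export
write_correlation_heatmap <- function(records, path) {
  thr <- attr(records, "threshold") %||% 0.7
  flights <- unique(records[order(records$dap), "stage"])
  vis <- sort(unique(records$vi_name), method = "radix")
  m <- matrix(NA_real_, length(vis), length(flights),
              dimnames = list(vis, flights))
  keep <- is.finite(records$r) & abs(records$r) >= thr
  m[cbind(match(records$vi_name[keep], vis),
          match(records$stage[keep], flights))] <- records$r[keep]
  df <- data.frame(vi_name = vis, round(m, 3), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a Venn partition to JSON
#' @param partition A `venn_partition`.
#' @param path Output JSON path.
#' @export
write_venn_json <- function(partition, path) {
  stopifnot(inherits(partition, "venn_partition"))
  jsonlite::write_json(
    list(sets = partition$sets, regions = partition$regions,
         union = partition$union,
         counts = as.list(partition$counts)),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
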