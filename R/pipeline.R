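#' Run the full correlation-stability screen
#'
#' Computes VI panels per flight, scores every index against yield per
#' flight, summarizes each season's cumulative scores into stable sets and
#' tiers, and (for three-year inputs) partitions the stable sets across
#' years.
#'
#' @param experiment A `sim_experiment`, or any list carrying compatible
#'   `observations` and `yields` data.frames.
#' @param names VI names to screen (default: all registered).
#' @param threshold Absolute-correlation score threshold (default 0.7).
#' @param min_count Cumulative score needed for stability (default 2).
#' @param top_k Tiers reported (default 3).
#' @return Object of class `vi_screen`: `records`, `summaries` (list per
#'   year), `stable_sets`, `venn` (a `venn_partition`, or NULL unless
#'   exactly 3 years), `panels`.
#' @export
run_screen <- function(experiment, names = vi_names(), threshold = 0.7,
                       min_count = 2L, top_k = 3L) {
  panels <- experiment_panels(experiment, names)
  records <- score_correlations(panels, experiment$yields,
                                threshold = threshold)
  years <- sort(unique(records$year))
  summaries <- lapply(years, function(yr) {
    summarize_year(records[records$year == yr, , drop = FALSE],
                   min_count = min_count, top_k = top_k)
  })
  base::names(summaries) <- as.character(years)
  sets <- lapply(summaries, stable_set)
  venn <- if (length(sets) == 3L) venn_partition(sets) else NULL
  structure(list(records = records, summaries = summaries,
                 stable_sets = sets, venn = venn, panels = panels),
            class = "vi_screen")
}

#' @export
print.vi_screen <- function(x, ...) {
  cat("<vi_screen>", length(unique(x$records$year)), "year(s),",
      length(unique(x$records$vi_name)), "indices\n")
  for (yr in names(x$stable_sets)) {
    cat(sprintf("  %s stable (%d): %s\n", yr, length(x$stable_sets[[yr]]),
                paste(x$stable_sets[[yr]], collapse = ", ")))
  }
  if (!is.null(x$venn)) {
    cat(sprintf("  union %d; >=2 years %d; all three years %d\n",
                length(x$venn$union), length(venn_at_least(x$venn, 2)),
                length(x$venn$regions[[7]])))
  }
  invisible(x)
}

#' Write the stability summaries as CSV
#' @param screen A `vi_screen`.
#' @param path Output CSV path.
#' @export
write_stability <- function(screen, path) {
  long <- do.call(rbind, lapply(screen$summaries, function(s) {
    as.data.frame(s)
  }))
  rownames(long) <- NULL
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Deterministic content hash of pipeline outputs
#'
#' Serializes the tabular content of an object (data.frames, at full
#' precision) to text and returns its MD5, for end-to-end reproducibility
#' checks: identical seeds must give identical hashes.
#'
#' @param x A `sim_experiment`, `vi_screen`, data.frame, or list of such.
#' @return MD5 hex string.
#' @export
pipeline_hash <- function(x) {
  tf <- tempfile(fileext = ".txt")
  on.exit(unlink(tf))
  con <- file(tf, open = "w")
  dump_obj <- function(obj, tag) {
    if (is.data.frame(obj)) {
      writeLines(tag, con)
      writeLines(names(obj), con)
      for (cl in names(obj)) {
        v <- obj[[cl]]
        writeLines(if (is.numeric(v)) sprintf("%.15g", v) else
          as.character(v), con)
      }
    } else if (is.list(obj)) {
      nms <- names(obj) %||% as.character(seq_along(obj))
      for (i in seq_along(obj)) {
        dump_obj(obj[[i]], paste0(tag, "/", nms[i]))
      }
    } else if (is.atomic(obj)) {
      writeLines(tag, con)
      writeLines(if (is.numeric(obj)) sprintf("%.15g", obj) else
        as.character(obj), con)
    }
  }
  content <- if (inherits(x, "sim_experiment")) {
    list(yields = x$yields, observations = x$observations,
         vigor = x$truth$vigor, flights = x$truth$flights)
  } else if (inherits(x, "vi_screen")) {
    list(records = x$records,
         summaries = lapply(x$summaries, as.data.frame),
         stable = x$stable_sets,
         venn = if (is.null(x$venn)) list() else x$venn$regions)
  } else {
    x
  }
  dump_obj(content, "root")
  close(con)
  unname(tools::md5sum(tf))
}
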