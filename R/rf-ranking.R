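#' Random-forest tuning specification
#'
#' Describes the randomized-search cross-validation protocol used to tune
#' the forest before ranking indices: by default 100 candidate
#' hyperparameter sets drawn uniformly from the declared space, scored by
#' five-fold cross-validated R-squared, with bootstrap resampling of tree
#' samples always on.
#'
#' @param n_candidates Number of sampled hyperparameter sets.
#' @param cv_folds Number of cross-validation folds.
#' @param trees Integer range (min, max) for the number of trees.
#' @param min_split Integer range for the minimum samples to split a node.
#' @param min_leaf Integer range for the minimum samples per leaf.
#' @param max_features Candidate feature subsampling rules: "all" and/or
#'   "sqrt" (square root of the number of features).
#' @param seed Integer seed driving candidate sampling, fold assignment and
#'   forest growth.
#' @return Object of class `rf_tuning_spec`.
#' @export
rf_tuning_spec <- function(n_candidates = 100L, cv_folds = 5L,
                           trees = c(100L, 1000L), min_split = c(2L, 10L),
                           min_leaf = c(1L, 5L),
                           max_features = c("all", "sqrt"), seed = 1L) {
  stopifnot(n_candidates >= 1L, cv_folds >= 2L,
            length(trees) == 2L, trees[1] >= 1L, trees[2] >= trees[1],
            length(min_split) == 2L, min_split[2] >= min_split[1],
            length(min_leaf) == 2L, min_leaf[2] >= min_leaf[1],
            all(max_features %in% c("all", "sqrt")))
  structure(list(n_candidates = as.integer(n_candidates),
                 cv_folds = as.integer(cv_folds),
                 trees = as.integer(trees), min_split = as.integer(min_split),
                 min_leaf = as.integer(min_leaf),
                 max_features = max_features, bootstrap = TRUE,
                 seed = as.integer(seed)),
            class = "rf_tuning_spec")
}

sample_candidates <- function(spec) {
  data.frame(
    num_trees = sample(spec$trees[1]:spec$trees[2], spec$n_candidates,
                       replace = TRUE),
    min_split = sample(spec$min_split[1]:spec$min_split[2],
                       spec$n_candidates, replace = TRUE),
    min_leaf = sample(spec$min_leaf[1]:spec$min_leaf[2], spec$n_candidates,
                      replace = TRUE),
    max_features = sample(spec$max_features, spec$n_candidates,
                          replace = TRUE),
    stringsAsFactors = FALSE
  )
}

fit_forest <- function(X, y, cand, seed) {
  mtry <- if (cand$max_features == "sqrt") {
    max(1L, floor(sqrt(ncol(X))))
  } else {
    ncol(X)
  }
  df <- data.frame(..y = y, X, check.names = FALSE)
  ranger::ranger(
    dependent.variable.name = "..y", data = df,
    num.trees = cand$num_trees, mtry = mtry,
    min.node.size = cand$min_split, min.bucket = cand$min_leaf,
    replace = TRUE, seed = seed, num.threads = 1
  )
}

rsq_score <- function(y, pred) {
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(NA_real_)
  1 - sum((y - pred)^2) / sst
}

#' Tune a random-forest yield regressor by randomized-search CV
#'
#' Samples `n_candidates` hyperparameter sets from the declared search
#' space, scores each by mean held-out R-squared over `cv_folds` folds,
#' picks the best and refits it on all rows. Fully reproducible given the
#' tuning seed.
#'
#' @param X Numeric matrix or data.frame, plots x indices, no missing cells.
#' @param y Yields, one per row of X.
#' @param spec An [rf_tuning_spec()].
#' @return list of class `tuned_forest`: `forest` (ranger fit), `best`
#'   (chosen hyperparameter row), `cv_score` (its mean CV R-squared),
#'   `candidates` (all candidates with their scores), `spec`.
#' @export
tune_forest <- function(X, y, spec = rf_tuning_spec()) {
  X <- as.matrix(X)
  stopifnot(is.numeric(X), length(y) == nrow(X))
  if (anyNA(X) || anyNA(y)) stop("X and y must have no missing values")
  if (nrow(X) < spec$cv_folds) {
    stop("need at least cv_folds (", spec$cv_folds, ") rows, got ", nrow(X))
  }
  with_seed(spec$seed, {
    cands <- sample_candidates(spec)
    folds <- sample(rep_len(seq_len(spec$cv_folds), nrow(X)))
  })
  scores <- vapply(seq_len(spec$n_candidates), function(i) {
    fold_scores <- vapply(seq_len(spec$cv_folds), function(f) {
      tr <- folds != f
      fit <- fit_forest(X[tr, , drop = FALSE], y[tr], cands[i, ],
                        seed = spec$seed + i)
      pred <- stats::predict(fit, data.frame(X[!tr, , drop = FALSE],
                                             check.names = FALSE),
                             num.threads = 1)$predictions
      rsq_score(y[!tr], pred)
    }, numeric(1))
    mean(fold_scores, na.rm = TRUE)
  }, numeric(1))
  best_i <- which.max(scores)
  forest <- fit_forest(X, y, cands[best_i, ], seed = spec$seed)
  cands$cv_score <- scores
  structure(list(forest = forest, best = cands[best_i, ],
                 cv_score = scores[best_i], candidates = cands, spec = spec),
            class = "tuned_forest")
}

#' @export
print.tuned_forest <- function(x, ...) {
  cat(sprintf(
    "<tuned_forest> trees=%d min_split=%d min_leaf=%d mtry=%s (CV R2=%.3f)\n",
    x$best$num_trees, x$best$min_split, x$best$min_leaf,
    x$best$max_features, x$cv_score))
  invisible(x)
}

#' Permutation-based index importance ranking
#'
#' Importance of an index is the mean drop in the forest's R-squared on the
#' training rows when that column is randomly permuted, averaged over
#' `n_repeats` permutations; the ranking is by descending mean importance
#' with alphabetical tie-breaking.
#'
#' @param tuned A `tuned_forest` (or any fitted model with a compatible
#'   `predict`), as returned by [tune_forest()].
#' @param X,y The data the forest was fitted on.
#' @param n_repeats Number of permutations per column.
#' @param seed Integer seed for the permutations.
#' @return Object of class `rf_ranking`: data.frame (rank, vi_name,
#'   importance_mean, importance_sd) with attribute `top_vi` and the
#'   baseline score.
#' @export
permutation_ranking <- function(tuned, X, y, n_repeats = 10L, seed = 1L) {
  if (!inherits(tuned, "tuned_forest")) {
    stop("tuned must be a tuned_forest (see tune_forest())")
  }
  X <- as.matrix(X)
  pred_fun <- function(M) {
    stats::predict(tuned$forest, data.frame(M, check.names = FALSE),
                   num.threads = 1)$predictions
  }
  baseline <- rsq_score(y, pred_fun(X))
  drops <- with_seed(seed, {
    vapply(colnames(X), function(cn) {
      vapply(seq_len(n_repeats), function(rep) {
        Xp <- X
        Xp[, cn] <- X[sample.int(nrow(X)), cn]
        baseline - rsq_score(y, pred_fun(Xp))
      }, numeric(1))
    }, numeric(n_repeats))
  })
  if (n_repeats == 1L) drops <- matrix(drops, nrow = 1L,
                                       dimnames = list(NULL, colnames(X)))
  imp_mean <- colMeans(drops)
  imp_sd <- apply(drops, 2, stats::sd)
  ord <- order(-imp_mean, colnames(X), method = "radix")
  out <- data.frame(rank = seq_along(ord), vi_name = colnames(X)[ord],
                    importance_mean = imp_mean[ord],
                    importance_sd = imp_sd[ord], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "top_vi") <- out$vi_name[1]
  attr(out, "baseline") <- baseline
  class(out) <- c("rf_ranking", "data.frame")
  out
}

#' Top-ranked index of a ranking
#' @param ranking An `rf_ranking`.
#' @return The top index name.
#' @export
top_vi <- function(ranking) attr(ranking, "top_vi")

#' Per-stage forest ranking with companion linear fits
#'
#' For every flight panel: drops plots with any missing index, tunes a
#' forest, ranks the indices by permutation importance, and fits the simple
#' linear yield model on the top-ranked index, reporting its R-squared and
#' MAPE. Flights with fewer complete plots than CV folds are skipped with a
#' warning.
#'
#' @param panels List of `vi_matrix` (one per flight).
#' @param yields Yield table (columns `year`, `plot_id`, `yield`).
#' @param spec An [rf_tuning_spec()].
#' @param n_repeats Permutation repeats for the importance.
#' @return list of per-flight results, each with `year`, `stage`, `dap`,
#'   `tuned`, `ranking`, `top_vi` and `fit` (the companion `vi_lm`).
#' @export
rank_per_stage <- function(panels, yields, spec = rf_tuning_spec(),
                           n_repeats = 10L) {
  if (inherits(panels, "vi_matrix")) panels <- list(panels)
  if (!length(panels)) stop("empty panel list")
  res <- lapply(panels, function(pm) {
    yr <- attr(pm, "year")
    ytab <- yields
    if ("year" %in% names(yields) && !is.na(yr)) {
      ytab <- yields[yields$year == yr, , drop = FALSE]
    }
    shared <- intersect(rownames(pm), as.character(ytab$plot_id))
    X <- unclass(pm)[shared, , drop = FALSE]
    complete <- stats::complete.cases(X)
    X <- X[complete, , drop = FALSE]
    yv <- ytab$yield[match(shared[complete], as.character(ytab$plot_id))]
    if (nrow(X) < spec$cv_folds) {
      warning("flight ", attr(pm, "stage"), " (", yr, ") skipped: ",
              nrow(X), " complete plots < ", spec$cv_folds, " folds")
      return(NULL)
    }
    tuned <- tune_forest(X, yv, spec)
    ranking <- permutation_ranking(tuned, X, yv, n_repeats = n_repeats,
                                   seed = spec$seed)
    best <- top_vi(ranking)
    fit <- fit_simple_lm(X[, best], yv, vi_name = best, year = yr,
                         stage = attr(pm, "stage"))
    list(year = yr, stage = attr(pm, "stage"), dap = attr(pm, "dap"),
         tuned = tuned, ranking = ranking, top_vi = best, fit = fit)
  })
  res[!vapply(res, is.null, logical(1))]
}

#' Write per-stage rankings and the top-index summary table
#'
#' @param results Output of [rank_per_stage()].
#' @param ranking_path CSV of (year, stage, rank, vi_name, importance_mean,
#'   importance_sd).
#' @param summary_path CSV of (year, stage, top_vi, r_squared, mape, stars).
#' @export
write_rf_tables <- function(results, ranking_path, summary_path) {
  rk <- do.call(rbind, lapply(results, function(r) {
    data.frame(year = r$year, stage = r$stage, r$ranking,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rk, ranking_path, row.names = FALSE)
  sm <- do.call(rbind, lapply(results, function(r) {
    data.frame(year = r$year, stage = r$stage, top_vi = r$top_vi,
               r_squared = r$fit$r_squared, mape = r$fit$mape,
               stars = r$fit$stars, stringsAsFactors = FALSE)
  }))
  utils::write.csv(sm, summary_path, row.names = FALSE)
  invisible(list(ranking = rk, summary = sm))
}
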