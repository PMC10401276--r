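# brute-force Pearson oracle from raw sums, independent of stats::cor
pearson_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

test_that("correlation matches hand values and the raw-sums oracle", {
  expect_equal(vi_pearson(c(1, 2, 3), c(2, 4, 6))$r, 1)
  expect_equal(vi_pearson(c(1, 2, 3), c(6, 4, 2))$r, -1)
  expect_equal(vi_pearson(c(1, 2, 3), c(1, 3, 2))$r, 0.5)

  set.seed(17)
  for (i in 1:1000) {
    n <- sample(3:30, 1)
    x <- rnorm(n); y <- rnorm(n)
    expect_equal(vi_pearson(x, y)$r, pearson_oracle(x, y),
                 tolerance = 1e-12)
  }
})

test_that("correlation is affine-invariant and antisymmetric under reflection", {
  set.seed(23)
  for (i in 1:50) {
    x <- rnorm(10); y <- rnorm(10)
    r0 <- vi_pearson(x, y)$r
    expect_equal(vi_pearson(2.5 * x + 3, y)$r, r0, tolerance = 1e-12)
    expect_equal(vi_pearson(x, 0.3 * y - 7)$r, r0, tolerance = 1e-12)
    expect_equal(vi_pearson(-1.5 * x + 2, y)$r, -r0, tolerance = 1e-12)
  }
})

test_that("correlation guards degenerate input", {
  expect_error(vi_pearson(c(1, 2), c(1, 2)), "fewer than 3")
  expect_error(vi_pearson(c(1, 2, NA), c(1, 2, 3)), "fewer than 3")
  expect_warning(out <- vi_pearson(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_true(is.na(out$r))
})

# build a one-flight panel whose single VI column is exactly `vals`
panel_of <- function(vals, yr = 2020, stage = "R1", dap = 83) {
  m <- matrix(vals, ncol = 1,
              dimnames = list(sprintf("P%02d", seq_along(vals)), "NDVI"))
  viscreen:::new_vi_matrix(m, list(year = yr, stage = stage, dap = dap))
}

yields_of <- function(y, yr = 2020) {
  data.frame(year = yr, plot_id = sprintf("P%02d", seq_along(y)), yield = y)
}

test_that("scores follow the absolute-correlation threshold rule", {
  y <- c(1, 2, 3, 4, 5, 6, 7, 8)
  # construct x with known r against y by mixing y with its orthogonal
  # complement: r(x, y) = target exactly
  make_x <- function(target) {
    e <- resid(lm(rnorm(length(y)) ~ y))
    target * scale(y)[, 1] + sqrt(1 - target^2) * scale(e)[, 1]
  }
  set.seed(9)
  for (target in c(0.71, -0.75, 0.69)) {
    rec <- score_correlations(panel_of(make_x(abs(target)) *
                                         sign(target)), yields_of(y))
    expect_equal(rec$r, target, tolerance = 1e-10)
    expect_identical(rec$score, as.integer(abs(target) >= 0.7))
  }
  expect_error(score_correlations(panel_of(1:8), yields_of(1:2)),
               "fewer than 3 plots shared")
})

test_that("yearly summaries accumulate scores into stable sets and tiers", {
  mk_rec <- function(vi, scores) {
    do.call(rbind, lapply(seq_along(scores), function(f) {
      data.frame(vi_name = vi, year = 2020, date = NA, dap = f * 10,
                 stage = paste0("F", f), r = 0.9 * scores[f], p = 0.01,
                 n_pairs = 16, score = scores[f])
    }))
  }
  rec <- rbind(mk_rec("A", c(1, 0, 1, 1)), mk_rec("B", c(1, 0, 0, 0)),
               mk_rec("C", c(1, 1, 1, 1)), mk_rec("D", c(1, 1, 1, 1)),
               mk_rec("E", c(1, 1, 1, 0)))
  class(rec) <- c("correlation_records", "data.frame")
  s <- summarize_year(rec)
  expect_equal(s$cumulative_score[s$vi_name == "A"], 3L)
  expect_true(s$stable[s$vi_name == "A"])
  expect_false(s$stable[s$vi_name == "B"])
  expect_setequal(stable_set(s), c("A", "C", "D", "E"))
  # C and D tie on 4 and share tier 1 (alphabetical order within the tier);
  # A and E tie on 3 in tier 2; B (score 1) falls to tier 3
  expect_equal(s$vi_name[s$tier == 1 & !is.na(s$tier)], c("C", "D"))
  expect_equal(s$tier[s$vi_name == "E"], 2L)
  expect_equal(s$tier[s$vi_name == "A"], 2L)
  expect_equal(s$tier[s$vi_name == "B"], 3L)

  one_flight <- rec[rec$stage == "F1", ]
  class(one_flight) <- c("correlation_records", "data.frame")
  expect_error(summarize_year(one_flight), "at least 2 flights")
})

test_that("raising the threshold or min_count never grows the selection", {
  ex <- simulate_experiment(sim_config(seed = 77, n_years = 1))
  panels <- experiment_panels(ex, c("MTCI", "NDVI", "SAVI", "CVI"))
  thresholds <- c(0.5, 0.7, 0.9)
  cums <- lapply(thresholds, function(th) {
    s <- summarize_year(score_correlations(panels, ex$yields,
                                           threshold = th))
    s$cumulative_score[order(s$vi_name)]
  })
  expect_true(all(cums[[2]] <= cums[[1]]))
  expect_true(all(cums[[3]] <= cums[[2]]))

  rec <- score_correlations(panels, ex$yields)
  s2 <- stable_set(summarize_year(rec, min_count = 2))
  s4 <- stable_set(summarize_year(rec, min_count = 4))
  expect_true(all(s4 %in% s2))
})

test_that("set partition matches brute-force enumeration", {
  vp1 <- venn_partition(list(A = "x", B = "x", C = "x"))
  expect_identical(vp1$regions[["A&B&C"]], "x")
  expect_equal(sum(vp1$counts), 1L)
  expect_identical(vp1$union, "x")

  vp2 <- venn_partition(list(A = c("a", "b"), B = c("b", "c"),
                             C = c("c", "a")))
  expect_identical(vp2$regions[["A&B"]], "b")
  expect_identical(vp2$regions[["B&C"]], "c")
  expect_identical(vp2$regions[["A&C"]], "a")
  expect_length(vp2$regions[["A&B&C"]], 0)
  expect_length(vp2$union, 3)

  expect_error(venn_partition(list(A = "x", B = "y")), "exactly 3")
})

test_that("partition regions are disjoint and reconstruct each input set", {
  set.seed(31)
  pool <- paste0("vi", 1:30)
  for (i in 1:25) {
    sets <- list(A = sample(pool, sample(0:20, 1)),
                 B = sample(pool, sample(0:20, 1)),
                 C = sample(pool, sample(0:20, 1)))
    vp <- venn_partition(sets)
    expect_equal(sum(vp$counts), length(vp$union))
    all_members <- unlist(vp$regions, use.names = FALSE)
    expect_identical(anyDuplicated(all_members), 0L)
    for (nm in names(sets)) {
      incident <- grepl(nm, names(vp$regions))
      rebuilt <- sort(unlist(vp$regions[incident], use.names = FALSE))
      expect_identical(rebuilt, sort(unique(sets[[nm]]), method = "radix"))
    }
  }
})

test_that("planted chlorophyll indices are recovered; noise columns are not", {
  set.seed(55)
  n_hits <- 0L
  n_reps <- 40
  noise_stable <- 0L
  for (i in seq_len(n_reps)) {
    ex <- simulate_experiment(sim_config(seed = 5000 + i, n_years = 1))
    panels <- experiment_panels(ex, c("MTCI", "LCI", "mND705"))
    # append a pure-noise VI column to every flight panel
    panels <- lapply(panels, function(pm) {
      m <- cbind(unclass(pm), NOISE = rnorm(nrow(pm)))
      viscreen:::new_vi_matrix(m, list(year = attr(pm, "year"),
                                       dap = attr(pm, "dap"),
                                       stage = attr(pm, "stage")))
    })
    s <- summarize_year(score_correlations(panels, ex$yields))
    st <- stable_set(s)
    if (all(c("MTCI", "LCI", "mND705") %in% st)) n_hits <- n_hits + 1L
    if ("NOISE" %in% st) noise_stable <- noise_stable + 1L
  }
  expect_gte(n_hits / n_reps, 0.9)
  expect_lte(noise_stable / n_reps, 0.1)
})

test_that("heatmap CSV blanks sub-threshold correlations", {
  rec <- data.frame(
    vi_name = c("A", "A", "B", "B"), year = 2020, date = NA,
    dap = c(40, 80, 40, 80), stage = rep(c("V5", "R1"), 2),
    r = c(0.9, 0.5, -0.8, 0.72), p = 0.01, n_pairs = 16,
    score = c(1L, 0L, 1L, 1L))
  attr(rec, "threshold") <- 0.7
  class(rec) <- c("correlation_records", "data.frame")
  path <- tempfile(fileext = ".csv")
  write_correlation_heatmap(rec, path)
  hm <- read.csv(path, check.names = FALSE)
  expect_equal(hm$V5[hm$vi_name == "A"], 0.9)
  expect_true(is.na(hm$R1[hm$vi_name == "A"]))
  expect_equal(hm$R1[hm$vi_name == "B"], 0.72)
})
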