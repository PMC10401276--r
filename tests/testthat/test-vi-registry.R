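# independently coded direct-arithmetic forms of every built-in index,
# kept deliberately separate from the registry's parsed formula strings
vi_oracles <- list(
  NDVI = function(b) (b$nir - b$red) / (b$nir + b$red),
  GNDVI = function(b) (b$nir - b$green) / (b$nir + b$green),
  reNDVI = function(b) (b$nir - b$rededge) / (b$nir + b$rededge),
  SR705 = function(b) b$nir / b$rededge,
  MTCI = function(b) (b$nir - b$rededge) / (b$rededge - b$red),
  LCI = function(b) (b$nir - b$rededge) / (b$nir + b$red),
  RIrededge = function(b) b$nir / b$rededge - 1,
  RIgreen = function(b) b$nir / b$green - 1,
  CIgreen = function(b) b$nir / b$green - 1,
  CVI = function(b) b$nir * b$red / b$green^2,
  mND705 = function(b) (b$nir - b$rededge) / (b$nir + b$rededge - 2 * b$blue),
  mSR705 = function(b) (b$nir - b$blue) / (b$rededge - b$blue),
  DATT = function(b) (b$nir - b$rededge) / (b$nir - b$red),
  SAVI = function(b) 1.5 * (b$nir - b$red) / (b$nir + b$red + 0.5),
  OSAVI = function(b) (b$nir - b$red) / (b$nir + b$red + 0.16),
  MSAVI = function(b) {
    0.5 * (2 * b$nir + 1 - sqrt((2 * b$nir + 1)^2 - 8 * (b$nir - b$red)))
  },
  RDVI = function(b) (b$nir - b$red) / sqrt(b$nir + b$red),
  EVI = function(b) {
    2.5 * (b$nir - b$red) / (b$nir + 6 * b$red - 7.5 * b$blue + 1)
  },
  WDRVI = function(b) (0.2 * b$nir - b$red) / (0.2 * b$nir + b$red),
  VARI = function(b) (b$green - b$red) / (b$green + b$red - b$blue),
  TGI = function(b) {
    -0.5 * (193 * (b$red - b$green) - 108 * (b$red - b$blue))
  },
  TVI = function(b) {
    0.5 * (120 * (b$nir - b$green) - 200 * (b$red - b$green))
  },
  MCARI2 = function(b) {
    1.5 * (2.5 * (b$nir - b$red) - 1.3 * (b$nir - b$green)) /
      sqrt((2 * b$nir + 1)^2 - (6 * b$nir - 5 * sqrt(b$red)) - 0.5)
  },
  TCARI_OSAVI = function(b) {
    tcari <- 3 * ((b$rededge - b$red) -
                    0.2 * (b$rededge - b$green) * (b$rededge / b$red))
    tcari / ((b$nir - b$red) / (b$nir + b$red + 0.16))
  },
  ARI = function(b) 1 / b$green - 1 / b$rededge,
  mARI = function(b) b$nir * (1 / b$green - 1 / b$rededge),
  CRIrededge = function(b) 1 / b$blue - 1 / b$rededge,
  RVI = function(b) b$nir / b$red,
  SR445 = function(b) b$nir / b$blue,
  PBI = function(b) b$nir / b$green,
  MCARI = function(b) {
    ((b$rededge - b$red) - 0.2 * (b$rededge - b$green)) *
      (b$rededge / b$red)
  }
)

test_that("narrowband wavelengths resolve to the configured sensor bands", {
  expect_identical(resolve_band(705), "rededge")
  expect_identical(resolve_band(445), "blue")
  expect_identical(resolve_band(750), "nir")
  expect_identical(resolve_band(560), "green")
  expect_error(resolve_band(1240), "outside sensor range")
  expect_error(resolve_band(623), "no sensor band")
})

test_that("hand-computed index values are reproduced", {
  expect_equal(compute_vi("NDVI", c(nir = 0.3, red = 0.3)), 0)
  expect_equal(compute_vi("NDVI", c(nir = 0.5, red = 0.1)), 0.4 / 0.6)
  expect_equal(compute_vi("MTCI", c(nir = 0.45, rededge = 0.30, red = 0.10)),
               0.15 / 0.20)
  expect_equal(compute_vi("LCI", c(nir = 0.45, rededge = 0.30, red = 0.10)),
               0.15 / 0.55)
  expect_equal(compute_vi("mND705", c(nir = 0.45, rededge = 0.30,
                                      blue = 0.05)), 0.15 / 0.65)
})

test_that("degenerate denominators yield missing, never an error", {
  expect_true(is.na(compute_vi("MTCI", c(nir = 0.45, rededge = 0.3,
                                         red = 0.3))))
  expect_true(is.na(compute_vi("SR705", c(nir = 0.45, rededge = 0))))
  expect_true(is.na(compute_vi("ARI", c(green = 0, rededge = 0.3))))
})

test_that("lookups are case-insensitive and unknown names list the registry", {
  expect_equal(compute_vi("ndvi", c(nir = 0.5, red = 0.1)),
               compute_vi("NDVI", c(nir = 0.5, red = 0.1)))
  expect_identical(vi_definition("TCARI/OSAVI")$name, "TCARI_OSAVI")
  expect_error(compute_vi("NOPE", c(nir = 0.5, red = 0.1)), "registered")
})

test_that("band validation rejects out-of-range and missing inputs", {
  expect_error(compute_vi("NDVI", c(nir = 1.2, red = 0.1)), "outside")
  expect_error(compute_vi("NDVI", c(nir = 0.5)), "missing band")
  expect_error(band_set(-0.1, 0.2, 0.2, 0.2, 0.2), "outside")
})

test_that("every registered formula matches the direct-arithmetic oracle", {
  bs <- random_bandsets(1000, seed = 101, max_val = 0.95)
  for (nm in names(vi_oracles)) {
    got <- vapply(seq_len(nrow(bs)), function(i) {
      compute_vi(nm, unlist(bs[i, ]))
    }, numeric(1))
    want <- vapply(seq_len(nrow(bs)), function(i) {
      v <- vi_oracles[[nm]](as.list(bs[i, ]))
      if (is.finite(v)) v else NA_real_
    }, numeric(1))
    expect_equal(got, want, tolerance = 1e-12, label = nm)
  }
})

test_that("ratio indices of equal degree are scale invariant", {
  ratio_vis <- c("NDVI", "MTCI", "LCI", "SR705", "reNDVI", "DATT",
                 "mSR705", "VARI", "mND705", "GNDVI", "WDRVI")
  bs <- random_bandsets(50, seed = 7)
  for (cc in c(0.5, 2)) {
    for (nm in ratio_vis) {
      base_v <- vapply(seq_len(nrow(bs)), function(i) {
        compute_vi(nm, unlist(bs[i, ]))
      }, numeric(1))
      scaled <- vapply(seq_len(nrow(bs)), function(i) {
        compute_vi(nm, unlist(bs[i, ]) * cc)
      }, numeric(1))
      expect_equal(scaled, base_v, tolerance = 1e-10,
                   label = paste(nm, "x", cc))
    }
  }
})

test_that("normalized-difference indices stay in [-1, 1]", {
  bs <- random_bandsets(500, seed = 13, max_val = 0.95)
  for (nm in c("NDVI", "GNDVI", "reNDVI")) {
    v <- vapply(seq_len(nrow(bs)), function(i) {
      compute_vi(nm, unlist(bs[i, ]))
    }, numeric(1))
    expect_true(all(abs(v[is.finite(v)]) <= 1), label = nm)
  }
  # mND705 is bounded whenever blue does not exceed the red-edge/NIR
  # reflectance, as holds for real surfaces
  bs$blue <- pmin(bs$blue, bs$rededge, bs$nir)
  v <- vapply(seq_len(nrow(bs)), function(i) {
    compute_vi("mND705", unlist(bs[i, ]))
  }, numeric(1))
  expect_true(all(abs(v[is.finite(v)]) <= 1 + 1e-12))
})

test_that("panels apply formulas cell-wise and propagate missingness", {
  plots <- list(P1 = c(nir = 0.3, red = 0.3, rededge = 0.2),
                P2 = c(nir = 0.5, red = 0.1, rededge = 0.2))
  pm <- compute_panel(plots, "NDVI",
                      flight = list(year = 2020, stage = "R1", dap = 83))
  expect_equal(dim(pm), c(2L, 1L))
  expect_equal(unname(pm[, "NDVI"]), c(0, 0.4 / 0.6), tolerance = 1e-12)
  expect_error(compute_panel(plots, character(0)), "no VI names")
  expect_error(compute_panel(list(), "NDVI"), "no plots")

  degenerate <- list(P1 = c(nir = 0.45, red = 0.3, rededge = 0.3))
  pm2 <- compute_panel(degenerate, c("MTCI", "NDVI"))
  expect_true(is.na(pm2[1, "MTCI"]))
  expect_false(is.na(pm2[1, "NDVI"]))
})

test_that("panels are permutation-equivariant in plot order", {
  bs <- random_bandsets(6, seed = 3)
  plots <- lapply(seq_len(6), function(i) unlist(bs[i, ]))
  names(plots) <- sprintf("P%d", 1:6)
  vis <- c("NDVI", "MTCI", "SAVI")
  pm <- compute_panel(plots, vis)
  perm <- c(4, 2, 6, 1, 3, 5)
  pm2 <- compute_panel(plots[perm], vis)
  expect_equal(unclass(pm2), unclass(pm)[perm, ], tolerance = 1e-15,
               ignore_attr = TRUE)
  expect_identical(rownames(pm2), rownames(pm)[perm])
})

test_that("custom indices register from formula strings and config files", {
  register_vi("testSR", "NIR / RE", overwrite = TRUE)
  expect_equal(compute_vi("testSR", c(rededge = 0.25, nir = 0.5)), 2)
  expect_setequal(vi_definition("testSR")$required_bands,
                  c("nir", "rededge"))
  expect_error(register_vi("bad1", "NIR + system('ls')"), "disallowed")
  expect_error(register_vi("bad2", "NIR + Z"), "disallowed symbol")

  cfg <- tempfile(fileext = ".csv")
  write.csv(data.frame(name = "testND", formula = "(NIR - G) / (NIR + G)",
                       reference = "demo"), cfg, row.names = FALSE)
  register_vi_config(cfg, overwrite = TRUE)
  expect_equal(compute_vi("testND", c(green = 0.1, nir = 0.3)), 0.5)
})

test_that("long CSV serialization round-trips a panel", {
  plots <- list(P1 = c(nir = 0.45, red = 0.3, rededge = 0.3),
                P2 = c(nir = 0.5, red = 0.1, rededge = 0.2))
  pm <- compute_panel(plots, c("MTCI", "NDVI"),
                      flight = list(year = 2021, date = "2021-07-01",
                                    dap = 83, stage = "R1"))
  path <- tempfile(fileext = ".csv")
  write_vi_matrix(pm, path)
  back <- read_vi_matrix(path)[[1]]
  expect_equal(unclass(back)[rownames(pm), colnames(pm)], unclass(pm),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(is.na(back["P1", "MTCI"]))
  expect_identical(attr(back, "stage"), "R1")
})
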