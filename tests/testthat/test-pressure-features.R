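test_that("midline region map splits seat into quadrants and back into halves", {
  m32 <- default_region_map(acquisition_config(32, 32))
  expect_equal(unname(lengths(m32$cells[c("BTL", "BTR", "THL", "THR")])),
               rep(256L, 4))
  expect_equal(unname(lengths(m32$cells[c("UB", "LB")])), rep(512L, 2))

  m4 <- default_region_map(acquisition_config(4, 4))
  expect_equal(unname(lengths(m4$cells[c("BTL", "BTR", "THL", "THR")])),
               rep(4L, 4))

  expect_error(default_region_map(acquisition_config(5, 4)), "grid_rows")
  expect_error(default_region_map(acquisition_config(4, 6 + 1)), "grid_cols")
})

test_that("region map rejects overlaps, wrong pads and empty regions", {
  cfg <- acquisition_config(4, 4)
  ok <- list(THL = list(pad = "seat", rows = 1:2, cols = 1:2),
             THR = list(pad = "seat", rows = 1:2, cols = 3:4),
             BTL = list(pad = "seat", rows = 3:4, cols = 1:2),
             BTR = list(pad = "seat", rows = 3:4, cols = 3:4),
             UB = list(pad = "back", rows = 1:2, cols = 1:4),
             LB = list(pad = "back", rows = 3:4, cols = 1:4))
  expect_s3_class(region_map(cfg, ok), "region_map")
  bad <- ok; bad$BTL$rows <- 2:3  # overlaps THL
  expect_error(region_map(cfg, bad), "overlap")
  bad <- ok; bad$UB$pad <- "seat"
  expect_error(region_map(cfg, bad), "back pad")
  bad <- ok; bad$LB$rows <- integer(0)
  expect_error(region_map(cfg, bad), "empty")
})

test_that("region map survives a JSON round trip", {
  m <- default_region_map(acquisition_config(8, 8))
  m2 <- region_map_from_json(region_map_to_json(m))
  expect_equal(m2$cells, m$cells)
  expect_equal(m2$config$sampling_hz, m$config$sampling_hz)
})

test_that("uniform field gives uniform averages, full areas and quadrant centroids", {
  cfg <- acquisition_config(4, 4)
  m <- default_region_map(cfg)
  f <- compute_frame_features(matrix(10, 4, 4), matrix(0, 4, 4), m)
  expect_length(f, 36)
  for (rg in c("BTL", "BTR", "THL", "THR")) {
    expect_equal(f[[paste0("avg", rg)]], 10)
    expect_equal(f[[paste0("a", rg)]], 4)
    expect_equal(f[[paste0("avg", rg, "/avgSUM")]], 0.25)
  }
  # THL occupies rows 1:2, cols 1:2 -> centroid (1.5, 1.5)
  expect_equal(f[["rCOPTHL"]], 1.5)
  expect_equal(f[["cCOPTHL"]], 1.5)
  expect_equal(f[["rCOPBTR"]], 3.5)
  expect_equal(f[["cCOPBTR"]], 3.5)
  # back pad empty: avg 0, area 0, COP undefined
  expect_equal(f[["avgUB"]], 0)
  expect_equal(f[["aLB"]], 0)
  expect_true(is.na(f[["rCOPUB"]]))
})

test_that("a point mass lands in exactly one region with its own coordinates", {
  cfg <- acquisition_config(4, 4)
  m <- default_region_map(cfg)
  seat <- matrix(0, 4, 4); seat[3, 3] <- 50  # rear half, right half -> BTR
  f <- compute_frame_features(seat, matrix(0, 4, 4), m)
  expect_equal(f[["aBTR"]], 1)
  expect_equal(f[["avgBTR"]], 50)
  expect_equal(f[["rCOPBTR"]], 3)
  expect_equal(f[["cCOPBTR"]], 3)
  expect_equal(f[["aBTR/aSUM"]], 1)
  other <- setdiff(c("BTL", "THL", "THR", "UB", "LB"), "BTR")
  expect_equal(unname(f[paste0("a", other)]), rep(0, 5))
})

test_that("frame features match the cell-loop oracle exactly on random grids", {
  cfg <- acquisition_config(8, 8)
  m <- default_region_map(cfg)
  set.seed(42)
  for (i in 1:120) {
    seat <- random_grid(8, 8, zero_frac = runif(1, 0.1, 0.9))
    back <- random_grid(8, 8, zero_frac = runif(1, 0.1, 0.9))
    got <- compute_frame_features(seat, back, m)
    want <- oracle_frame_features(seat, back, m)
    # equality at double precision: the oracle accumulates in a different
    # order, so the last bit can differ
    expect_equal(unname(got), unname(want), tolerance = 1e-12)
  }
})

test_that("ratio blocks sum to one whenever their denominator is positive", {
  cfg <- acquisition_config(6, 6)
  m <- default_region_map(cfg)
  set.seed(7)
  for (i in 1:25) {
    f <- compute_frame_features(random_grid(6, 6), random_grid(6, 6), m)
    expect_equal(sum(f[grep("/avgSUM", names(f))]), 1, tolerance = 1e-12)
    expect_equal(sum(f[grep("/aSUM", names(f))]), 1, tolerance = 1e-12)
  }
})

test_that("pressure scaling leaves areas, ratios and COPs invariant", {
  cfg <- acquisition_config(8, 8)
  m <- default_region_map(cfg)
  set.seed(11)
  seat <- random_grid(8, 8); back <- random_grid(8, 8)
  f1 <- compute_frame_features(seat, back, m)
  f2 <- compute_frame_features(3.7 * seat, 3.7 * back, m)
  avg_idx <- grep("^avg(BTL|BTR|THL|THR|UB|LB)$", names(f1))
  expect_equal(f2[avg_idx], 3.7 * f1[avg_idx])
  expect_equal(f2[-avg_idx], f1[-avg_idx])
})

test_that("shifting a point mass by one row shifts its COP row by one", {
  cfg <- acquisition_config(8, 8)
  m <- default_region_map(cfg)
  seat1 <- matrix(0, 8, 8); seat1[2, 2] <- 40  # THL interior
  seat2 <- matrix(0, 8, 8); seat2[3, 2] <- 40
  f1 <- compute_frame_features(seat1, matrix(0, 8, 8), m)
  f2 <- compute_frame_features(seat2, matrix(0, 8, 8), m)
  expect_equal(f2[["rCOPTHL"]], f1[["rCOPTHL"]] + 1)
  expect_equal(f2[["cCOPTHL"]], f1[["cCOPTHL"]])
})

test_that("frame feature extraction validates its inputs", {
  m <- default_region_map(acquisition_config(4, 4))
  expect_error(compute_frame_features(matrix(1, 5, 4), matrix(0, 4, 4), m),
               "4 x 4")
  expect_error(compute_frame_features(matrix(-1, 4, 4), matrix(0, 4, 4), m),
               "negative")
})

test_that("featurize_session preserves cardinality and flags no-contact frames", {
  s <- generate_static_session("S01", "calm", seed = 5, duration_s = 10)
  f <- featurize_session(s)
  expect_equal(nrow(f), 50)
  expect_equal(ncol(f), 38)  # timestamp + valid + 36 features
  expect_true(all(f$valid))

  s$seat[3, ] <- 0; s$back[3, ] <- 0
  f <- featurize_session(s)
  expect_false(f$valid[3])
  expect_equal(sum(!f$valid), 1)
})

test_that("featurized anxious/calm sessions recover the planted regional gain", {
  eff <- anxiety_effect_spec(pressure_gain_by_region = c(
    BTL = 1, BTR = 1, THL = 1.15, THR = 1, UB = 1, LB = 1))
  fa <- featurize_session(generate_static_session("S01", "anxious", eff,
                                                  duration_s = 120, seed = 7))
  fc <- featurize_session(generate_static_session("S01", "calm", eff,
                                                  duration_s = 120, seed = 8))
  expect_equal(mean(fa$avgTHL) / mean(fc$avgTHL), 1.15, tolerance = 0.03)
  expect_equal(mean(fa$avgBTR) / mean(fc$avgBTR), 1.00, tolerance = 0.03)
})

test_that("outlier cleaning replaces only planted spikes", {
  # smooth sinusoidal features: excursions stay well inside 4 robust z
  n <- 150
  f <- data.frame(timestamp = (seq_len(n) - 1) / 5, valid = TRUE,
                  check.names = FALSE)
  set.seed(9)
  for (nm in feature_names())
    f[[nm]] <- 20 + 3 * sin(seq_len(n) / 7 + runif(1, 0, 6)) + rnorm(n, 0, 0.3)
  clean <- clean_outliers(f)
  expect_equal(clean$features, f)
  expect_true(all(clean$report$n_replaced == 0))

  f2 <- f
  f2$avgBTL[70] <- 10 * median(f$avgBTL)
  clean2 <- clean_outliers(f2)
  expect_equal(clean2$report$n_replaced[clean2$report$feature == "avgBTL"], 1L)
  expect_equal(sum(clean2$report$n_replaced), 1L)
  # replacement interpolates the neighbours
  expect_equal(clean2$features$avgBTL[70],
               mean(f2$avgBTL[c(69, 71)]), tolerance = 1e-12)

  expect_equal(clean_outliers(f2, z_max = Inf)$features, f2)
})
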