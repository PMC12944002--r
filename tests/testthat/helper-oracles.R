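# Independent brute-force oracles, deliberately naive: they share no code
# with the package implementation.

# Cell-by-cell loop over every grid position, accumulating per-region sums.
oracle_frame_features <- function(seat, back, map) {
  regions <- c("BTL", "BTR", "THL", "THR", "UB", "LB")
  acc <- list()
  for (rg in regions)
    acc[[rg]] <- list(n = 0, tot = 0, wr = 0, wc = 0, area = 0)
  for (rg in regions) {
    def <- map$regions[[rg]]
    pad <- if (def$pad == "seat") seat else back
    for (r in def$rows) for (cl in def$cols) {
      p <- pad[r, cl]
      acc[[rg]]$tot <- acc[[rg]]$tot + p
      acc[[rg]]$wr <- acc[[rg]]$wr + p * r
      acc[[rg]]$wc <- acc[[rg]]$wc + p * cl
      if (p > 0) acc[[rg]]$area <- acc[[rg]]$area + 1
    }
  }
  avg <- area <- rcop <- ccop <- numeric(0)
  for (rg in regions) {
    a <- acc[[rg]]
    area[rg] <- a$area
    avg[rg] <- if (a$area > 0) a$tot / a$area else 0
    rcop[rg] <- if (a$tot > 0) a$wr / a$tot else NA_real_
    ccop[rg] <- if (a$tot > 0) a$wc / a$tot else NA_real_
  }
  avg_sum <- sum(avg); a_sum <- sum(area)
  c(avg,
    if (avg_sum > 0) avg / avg_sum else rep(NA_real_, 6),
    area,
    if (a_sum > 0) area / a_sum else rep(NA_real_, 6),
    rcop, ccop)
}

# Exact two-sided signed-rank p by enumerating all 2^n sign assignments of
# the non-zero differences (average ranks; doubled to stay in integers).
oracle_signed_rank_p <- function(d) {
  nz <- d[d != 0]
  n <- length(nz)
  if (n == 0) return(1)
  r2 <- as.integer(round(2 * rank(abs(nz))))
  w_obs <- sum(r2[nz > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0L, 1L)), n)))
  W <- as.vector(signs %*% r2)
  min(1, 2 * min(mean(W <= w_obs), mean(W >= w_obs)))
}

# Loop-based window statistics.
oracle_window_stats <- function(m) {
  out <- numeric(0)
  for (j in seq_len(ncol(m))) {
    x <- m[, j][is.finite(m[, j])]
    f <- colnames(m)[j]
    if (length(x) >= 2) {
      out[paste0(f, "_Mean")] <- sum(x) / length(x)
      mu <- sum(x) / length(x)
      out[paste0(f, "_Std")] <- sqrt(sum((x - mu)^2) / (length(x) - 1))
      out[paste0(f, "_Max")] <- max(x)
    } else {
      out[paste0(f, "_Mean")] <- NA_real_
      out[paste0(f, "_Std")] <- NA_real_
      out[paste0(f, "_Max")] <- NA_real_
    }
  }
  out
}

# Random non-negative pressure grids with a controlled share of zero cells.
random_grid <- function(nr, nc, zero_frac = 0.4) {
  g <- matrix(stats::rexp(nr * nc, rate = 1 / 30), nr, nc)
  g[stats::runif(nr * nc) < zero_frac] <- 0
  g
}

# Minimal featurized-session data frame for window tests: each feature column
# equals the frame index so window extraction is directly checkable.
make_feats <- function(n_frames, hz = 5) {
  df <- data.frame(timestamp = (seq_len(n_frames) - 1) / hz,
                   valid = TRUE, check.names = FALSE)
  for (f in feature_names()) df[[f]] <- seq_len(n_frames)
  df
}

# Minimal window_feature_set for pairing tests.
make_window <- function(subject, condition, scenario, value = 1) {
  structure(list(subject = subject, condition = condition,
                 scenario = scenario, kind = "instantaneous",
                 anchor_time = 0, timestamps = seq_len(50) / 5,
                 data = matrix(value, 50, 36,
                               dimnames = list(NULL, feature_names()))),
            class = "window_feature_set")
}
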