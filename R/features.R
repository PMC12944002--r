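# The 36-variable regional feature set: per region, average contact pressure
# over non-zero cells (mmHg), its share of the six-region total, contact area
# (count of non-zero cells), its share, and the pressure-weighted centre of
# pressure in (row, col) grid coordinates. Empty regions get avg = 0, area = 0
# and an undefined (NA) COP; zero-denominator shares are NA, never 0/0 -> 0.

#' Names of the 36 per-frame regional features
#'
#' Ordered in three blocks of twelve: contact pressure (six regional averages,
#' then their shares of `avgSUM`), contact area (six counts, then shares of
#' `aSUM`), and centre of pressure (six row coordinates, then six column
#' coordinates). Region order is BTL, BTR, THL, THR, UB, LB throughout.
#'
#' @return Character vector of length 36.
#' @export
feature_names <- function() {
  c(paste0("avg", PX_REGIONS),
    paste0("avg", PX_REGIONS, "/avgSUM"),
    paste0("a", PX_REGIONS),
    paste0("a", PX_REGIONS, "/aSUM"),
    paste0("rCOP", PX_REGIONS),
    paste0("cCOP", PX_REGIONS))
}

#' Map feature (or statistical feature) names to their region
#'
#' @param x Character vector of feature names, e.g. `"avgTHL/avgSUM"` or
#'   `"rCOPBTL_Std"`.
#' @return Character vector of region codes (`"BTL"` ... `"LB"`), `NA` where no
#'   region code is present.
#' @export
feature_region <- function(x) {
  m <- regmatches(x, regexpr("BTL|BTR|THL|THR|UB|LB", x))
  out <- rep(NA_character_, length(x))
  out[regexpr("BTL|BTR|THL|THR|UB|LB", x) > 0] <- m
  out
}

#' Compute the 36 regional features for one frame pair
#'
#' Per region: contact area = count of cells with pressure > 0; average
#' pressure = mean over those non-zero cells (0 if the region has no contact);
#' COP = pressure-weighted centroid of 1-based (row, col) cell coordinates
#' (NA if no contact). `avgSUM` / `aSUM` are the sums of the six averages /
#' areas; shares divide by them (NA when the denominator is 0).
#'
#' @param seat,back Numeric matrices (`grid_rows` x `grid_cols`), pressures in
#'   mmHg, all values finite and >= 0.
#' @param map A [region_map()].
#' @return Named numeric vector of length 36 in [feature_names()] order.
#' @export
#' @examples
#' cfg <- acquisition_config(4, 4)
#' m <- default_region_map(cfg)
#' seat <- matrix(10, 4, 4); back <- matrix(0, 4, 4)
#' compute_frame_features(seat, back, m)[["avgBTL/avgSUM"]]  # 0.25
compute_frame_features <- function(seat, back, map) {
  stopifnot(inherits(map, "region_map"))
  cfg <- map$config
  for (nm in c("seat", "back")) {
    g <- get(nm)
    if (!is.matrix(g) || nrow(g) != cfg$grid_rows || ncol(g) != cfg$grid_cols)
      stop(sprintf("%s pad must be a %d x %d matrix", nm, cfg$grid_rows, cfg$grid_cols))
    if (any(!is.finite(g))) stop(sprintf("%s pad contains non-finite values", nm))
    if (any(g < 0)) stop(sprintf("%s pad contains negative pressures", nm))
  }
  nr <- cfg$grid_rows
  rowcoord <- rep(seq_len(nr), cfg$grid_cols)        # row of cell index i
  colcoord <- rep(seq_len(cfg$grid_cols), each = nr) # col of cell index i
  avg <- area <- rcop <- ccop <- stats::setNames(numeric(6), PX_REGIONS)
  for (rg in PX_REGIONS) {
    pad <- if (rg %in% PX_SEAT_REGIONS) seat else back
    idx <- map$cells[[rg]]
    p <- pad[idx]
    a <- sum(p > 0)
    area[rg] <- a
    tot <- sum(p)
    avg[rg] <- if (a > 0) tot / a else 0
    if (tot > 0) {
      rcop[rg] <- sum(p * rowcoord[idx]) / tot
      ccop[rg] <- sum(p * colcoord[idx]) / tot
    } else {
      rcop[rg] <- NA_real_; ccop[rg] <- NA_real_
    }
  }
  avg_sum <- sum(avg); a_sum <- sum(area)
  avg_ratio <- if (avg_sum > 0) avg / avg_sum else rep(NA_real_, 6)
  a_ratio <- if (a_sum > 0) area / a_sum else rep(NA_real_, 6)
  stats::setNames(c(avg, avg_ratio, area, a_ratio, rcop, ccop), feature_names())
}

#' Featurize a whole session
#'
#' Applies the 36-variable extraction to every seat/back frame pair of a
#' session, vectorised over frames. Frame pairs with no contact on either pad
#' are flagged invalid (`valid = FALSE`) but kept, never silently dropped.
#'
#' @param session A `pressure_session` (see [generate_static_session()]), or
#'   any list with elements `seat` and `back` (each an `n_frames x n_cells`
#'   matrix, cells column-major within the pad grid), `timestamps`, and
#'   `config`.
#' @param map A [region_map()]; defaults to the midline split for the
#'   session's acquisition config.
#' @return A data frame with columns `timestamp`, `valid`, and the 36 features
#'   (names as in [feature_names()], `check.names = FALSE`).
#' @export
featurize_session <- function(session, map = default_region_map(session$config)) {
  stopifnot(inherits(map, "region_map"))
  cfg <- map$config
  ncell <- cfg$grid_rows * cfg$grid_cols
  seat <- session$seat; back <- session$back
  if (!is.matrix(seat) || !is.matrix(back) || ncol(seat) != ncell || ncol(back) != ncell)
    stop(sprintf("session pads must have %d cell columns", ncell))
  if (nrow(seat) != nrow(back)) {
    orphans <- setdiff(seq_len(max(nrow(seat), nrow(back))),
                       seq_len(min(nrow(seat), nrow(back))))
    stop("unpaired seat/back frames at indices: ",
         paste(utils::head(orphans, 10), collapse = ", "))
  }
  if (any(seat < 0) || any(back < 0)) stop("negative pressures in session")
  n <- nrow(seat)
  nr <- cfg$grid_rows
  rowcoord <- rep(seq_len(nr), cfg$grid_cols)
  colcoord <- rep(seq_len(cfg$grid_cols), each = nr)
  avg <- area <- rcop <- ccop <- matrix(NA_real_, n, 6,
                                        dimnames = list(NULL, PX_REGIONS))
  for (rg in PX_REGIONS) {
    pad <- if (rg %in% PX_SEAT_REGIONS) seat else back
    idx <- map$cells[[rg]]
    S <- pad[, idx, drop = FALSE]
    tot <- rowSums(S)
    a <- rowSums(S > 0)
    area[, rg] <- a
    avg[, rg] <- ifelse(a > 0, tot / a, 0)
    rc <- as.vector(S %*% rowcoord[idx]) / tot
    cc <- as.vector(S %*% colcoord[idx]) / tot
    rc[tot <= 0] <- NA_real_; cc[tot <= 0] <- NA_real_
    rcop[, rg] <- rc; ccop[, rg] <- cc
  }
  avg_sum <- rowSums(avg); a_sum <- rowSums(area)
  avg_ratio <- avg / avg_sum
  avg_ratio[avg_sum <= 0, ] <- NA_real_
  a_ratio <- area / a_sum
  a_ratio[a_sum <= 0, ] <- NA_real_
  out <- data.frame(
    timestamp = session$timestamps,
    valid = a_sum > 0,
    check.names = FALSE
  )
  feats <- cbind(avg, avg_ratio, area, a_ratio, rcop, ccop)
  colnames(feats) <- feature_names()
  cbind(out, as.data.frame(feats, check.names = FALSE))
}

#' Replace outlying feature values by neighbour interpolation
#'
#' Flags, per feature, values whose robust z-score (|x - median| / MAD, MAD
#' with the consistency constant 1.4826) exceeds `z_max`, and replaces them by
#' linear interpolation of the surrounding non-flagged values (nearest
#' non-flagged value at the sequence edges). Features with zero MAD are left
#' untouched. NA values (undefined COPs/shares) are not treated as outliers.
#'
#' @param features A featurized session as returned by [featurize_session()].
#' @param z_max Robust z-score bound (default 4); `Inf` is the identity.
#' @return List with `features` (cleaned data frame, same shape) and `report`
#'   (data frame `feature`, `n_replaced`).
#' @export
clean_outliers <- function(features, z_max = 4) {
  stopifnot(is.data.frame(features), nrow(features) >= 1, z_max > 0)
  fn <- intersect(feature_names(), names(features))
  n_rep <- stats::setNames(integer(length(fn)), fn)
  for (f in fn) {
    x <- features[[f]]
    ok <- is.finite(x)
    if (!any(ok)) stop(sprintf("feature %s has no finite values", f))
    med <- stats::median(x[ok])
    md <- stats::mad(x[ok])
    if (!is.finite(md) || md <= 0) next
    bad <- ok & abs(x - med) / md > z_max
    n_rep[f] <- sum(bad)
    if (any(bad)) {
      keep <- which(ok & !bad)
      features[[f]][bad] <- if (length(keep) == 1L) x[keep] else
        stats::approx(keep, x[keep], xout = which(bad), rule = 2)$y
    }
  }
  list(features = features,
       report = data.frame(feature = fn, n_replaced = as.integer(n_rep),
                           row.names = NULL))
}
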