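# Six anatomical regions of the two-pad seating layout.
# Seat pad: left/right buttock (BTL/BTR), left/right thigh (THL/THR).
# Back pad: upper/lower back (UB/LB).
# Coordinate convention (1-based, stated in all outputs): row 1 is the front
# edge of the seat pad / top of the backrest, so the row axis is
# anterior-posterior; the column axis is lateral (col 1 = sitter's left).

PX_REGIONS <- c("BTL", "BTR", "THL", "THR", "UB", "LB")
PX_SEAT_REGIONS <- c("BTL", "BTR", "THL", "THR")
PX_BACK_REGIONS <- c("UB", "LB")

#' Acquisition configuration of the pressure-mat system
#'
#' Describes the sensor geometry and sampling rate of the two Tactilus-style
#' pads (seat cushion and backrest): a square sensor array sampled at a fixed
#' frequency, pressures in mmHg.
#'
#' @param grid_rows Number of sensor rows per pad (default 32).
#' @param grid_cols Number of sensor columns per pad (default 32).
#' @param sampling_hz Sampling frequency in Hz (default 5).
#' @return An object of class `acquisition_config`.
#' @export
#' @examples
#' acquisition_config()
acquisition_config <- function(grid_rows = 32L, grid_cols = 32L, sampling_hz = 5) {
  grid_rows <- as.integer(grid_rows)
  grid_cols <- as.integer(grid_cols)
  if (is.na(grid_rows) || grid_rows < 2L) stop("grid_rows must be >= 2")
  if (is.na(grid_cols) || grid_cols < 2L) stop("grid_cols must be >= 2")
  if (!is.finite(sampling_hz) || sampling_hz <= 0) stop("sampling_hz must be > 0")
  structure(
    list(grid_rows = grid_rows, grid_cols = grid_cols, sampling_hz = sampling_hz,
         pads = c("seat", "back")),
    class = "acquisition_config"
  )
}

#' @export
print.acquisition_config <- function(x, ...) {
  cat(sprintf("<acquisition_config> %d x %d cells per pad (seat + back), %g Hz\n",
              x$grid_rows, x$grid_cols, x$sampling_hz))
  invisible(x)
}

#' Region map: assignment of pad cells to anatomical regions
#'
#' Builds a region map from explicit cell rectangles. Each region is a set of
#' cells on one pad; regions must be non-empty and mutually disjoint. Seat
#' regions (BTL, BTR, THL, THR) live on the seat pad, back regions (UB, LB) on
#' the back pad. Cells not covered by any region are unassigned and ignored by
#' feature extraction.
#'
#' @param config An [acquisition_config()].
#' @param regions Named list with one entry per region in
#'   `c("BTL","BTR","THL","THR","UB","LB")`, each a list with elements
#'   `pad` ("seat"/"back"), `rows` (integer vector) and `cols` (integer vector).
#' @return An object of class `region_map`.
#' @seealso [default_region_map()] for the midline-split default.
#' @export
region_map <- function(config, regions) {
  stopifnot(inherits(config, "acquisition_config"))
  if (!setequal(names(regions), PX_REGIONS))
    stop("regions must be named exactly: ", paste(PX_REGIONS, collapse = ", "))
  regions <- regions[PX_REGIONS]
  nr <- config$grid_rows; nc <- config$grid_cols
  cells <- vector("list", length(PX_REGIONS))
  names(cells) <- PX_REGIONS
  for (rg in PX_REGIONS) {
    def <- regions[[rg]]
    expected_pad <- if (rg %in% PX_SEAT_REGIONS) "seat" else "back"
    if (!identical(def$pad, expected_pad))
      stop(sprintf("region %s must be on the %s pad", rg, expected_pad))
    rows <- as.integer(def$rows); cols <- as.integer(def$cols)
    if (length(rows) == 0L || length(cols) == 0L)
      stop(sprintf("region %s is empty", rg))
    if (any(rows < 1L | rows > nr)) stop(sprintf("region %s rows outside grid", rg))
    if (any(cols < 1L | cols > nc)) stop(sprintf("region %s cols outside grid", rg))
    # cell index within a pad, column-major: (col - 1) * grid_rows + row
    cells[[rg]] <- as.vector(outer(rows, (cols - 1L) * nr, "+"))
  }
  for (pad in c("seat", "back")) {
    rg_pad <- if (pad == "seat") PX_SEAT_REGIONS else PX_BACK_REGIONS
    all_cells <- unlist(cells[rg_pad], use.names = FALSE)
    if (anyDuplicated(all_cells))
      stop(sprintf("regions overlap on the %s pad", pad))
  }
  structure(
    list(config = config, regions = regions, cells = cells),
    class = "region_map"
  )
}

#' Default midline-split region map
#'
#' Seat pad: split at the row midline into a thigh band (front half, rows
#' `1:(grid_rows/2)`) and a buttock band (rear half), and at the column midline
#' into left and right. Back pad: split at the row midline into upper back
#' (top half) and lower back. The boundaries are not anatomical measurements;
#' they are an explicit, overridable convention recorded with every output.
#'
#' @param config An [acquisition_config()]; both grid dimensions must be even
#'   so the midline split is exact.
#' @return A `region_map` with four seat quadrants and two back halves.
#' @export
#' @examples
#' m <- default_region_map(acquisition_config())
#' lengths(m$cells)  # 256 cells per seat quadrant, 512 per back half
default_region_map <- function(config = acquisition_config()) {
  nr <- config$grid_rows; nc <- config$grid_cols
  if (nr %% 2L != 0L)
    stop(sprintf("grid_rows = %d is odd: no exact row midline split", nr))
  if (nc %% 2L != 0L)
    stop(sprintf("grid_cols = %d is odd: no exact column midline split", nc))
  front <- seq_len(nr %/% 2L); rear <- (nr %/% 2L + 1L):nr
  left <- seq_len(nc %/% 2L); right <- (nc %/% 2L + 1L):nc
  region_map(config, list(
    THL = list(pad = "seat", rows = front, cols = left),
    THR = list(pad = "seat", rows = front, cols = right),
    BTL = list(pad = "seat", rows = rear, cols = left),
    BTR = list(pad = "seat", rows = rear, cols = right),
    UB  = list(pad = "back", rows = front, cols = seq_len(nc)),
    LB  = list(pad = "back", rows = rear, cols = seq_len(nc))
  ))
}

#' @export
print.region_map <- function(x, ...) {
  cat("<region_map>\n")
  for (rg in PX_REGIONS) {
    def <- x$regions[[rg]]
    cat(sprintf("  %-3s %s pad rows %d-%d cols %d-%d (%d cells)\n", rg, def$pad,
                min(def$rows), max(def$rows), min(def$cols), max(def$cols),
                length(x$cells[[rg]])))
  }
  invisible(x)
}

# Serialize / restore a region map as JSON (rectangles, not cell lists).
#' Serialize a region map to JSON
#' @param map A `region_map`.
#' @return A JSON string.
#' @export
region_map_to_json <- function(map) {
  stopifnot(inherits(map, "region_map"))
  obj <- list(
    grid_rows = map$config$grid_rows,
    grid_cols = map$config$grid_cols,
    sampling_hz = map$config$sampling_hz,
    regions = lapply(map$regions, function(d)
      list(pad = d$pad, rows = as.integer(d$rows), cols = as.integer(d$cols)))
  )
  jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
}

#' Restore a region map from JSON
#' @param json A JSON string produced by [region_map_to_json()].
#' @return A `region_map`.
#' @export
region_map_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  cfg <- acquisition_config(obj$grid_rows, obj$grid_cols, obj$sampling_hz)
  region_map(cfg, lapply(obj$regions, function(d)
    list(pad = d$pad, rows = d$rows, cols = d$cols)))
}
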