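# Event-anchored windows: every analysed epoch is exactly 10 s of features
# (sampling_hz * 10 frames; 50 at 5 Hz). Instantaneous events take the 5 s
# either side of the anchor (half-open [anchor - 5, anchor + 5), so the
# snapped anchor is frame 26 of 50 and 25 frames precede it); continuous
# events take the first 10 s from onset; entry/exit events yield two
# instantaneous-style windows labelled <scenario>_entry / <scenario>_exit.

#' Extract feature window(s) around an annotated event
#'
#' Anchors are snapped to the nearest frame timestamp (event marks are
#' asynchronous to the sampling clock).
#'
#' @param features Featurized session data frame ([featurize_session()]).
#' @param event One-row data frame or list with `scenario`, `kind`
#'   (`"instantaneous"`, `"continuous"` or `"entry_exit"`), `anchor_time`,
#'   and `exit_time` (entry_exit only).
#' @param config The [acquisition_config()] (for the sampling rate).
#' @param subject,condition Carried into the window metadata.
#' @return A list of one (`instantaneous`/`continuous`) or two (`entry_exit`)
#'   `window_feature_set` objects: each has `subject`, `condition`,
#'   `scenario`, `kind`, `anchor_time`, `timestamps` and `data` (a
#'   `n_frames x 36` feature matrix).
#' @export
extract_window <- function(features, event, config, subject = NA, condition = NA) {
  stopifnot(is.data.frame(features), nrow(features) >= 1)
  kind <- as.character(event$kind)
  if (!kind %in% c("instantaneous", "continuous", "entry_exit"))
    stop("unknown event kind: ", kind)
  n_win <- round(config$sampling_hz * 10)
  half <- n_win %/% 2
  ts <- features$timestamp

  one <- function(anchor, scenario, centred) {
    if (anchor < min(ts) || anchor > max(ts))
      stop(sprintf("anchor %.2f s outside session span [%.2f, %.2f]",
                   anchor, min(ts), max(ts)))
    a <- which.min(abs(ts - anchor))
    idx <- if (centred) (a - half):(a + half - 1) else a:(a + n_win - 1)
    if (min(idx) < 1 || max(idx) > nrow(features))
      stop(sprintf(
        "insufficient frames for %s window at %.2f s: %d available, %d required",
        scenario, anchor, sum(idx >= 1 & idx <= nrow(features)), n_win))
    structure(list(subject = subject, condition = condition,
                   scenario = scenario, kind = kind, anchor_time = ts[a],
                   timestamps = ts[idx],
                   data = as.matrix(features[idx, feature_names()])),
              class = "window_feature_set")
  }

  scenario <- as.character(event$scenario)
  if (kind == "instantaneous") {
    list(one(event$anchor_time, scenario, centred = TRUE))
  } else if (kind == "continuous") {
    list(one(event$anchor_time, scenario, centred = FALSE))
  } else {
    if (!is.finite(event$exit_time) || event$exit_time <= event$anchor_time)
      stop("entry_exit event requires exit_time > anchor_time")
    list(one(event$anchor_time, paste0(scenario, "_entry"), centred = TRUE),
         one(event$exit_time, paste0(scenario, "_exit"), centred = TRUE))
  }
}

#' Extract all event windows of a session
#'
#' @param session A `pressure_session`.
#' @param features Its featurized form; computed with the default region map
#'   if omitted.
#' @param map Optional [region_map()] used when featurizing.
#' @return List of `window_feature_set` objects, one per event window.
#' @export
session_windows <- function(session, features = NULL,
                            map = default_region_map(session$config)) {
  if (is.null(features)) features <- featurize_session(session, map)
  out <- list()
  for (i in seq_len(nrow(session$events))) {
    out <- c(out, extract_window(features, session$events[i, ], session$config,
                                 subject = session$subject_id,
                                 condition = session$condition))
  }
  out
}

#' Pair calm and anxious windows by subject and scenario
#'
#' Subjects missing one condition for a scenario are excluded (not imputed)
#' and listed in the report, mirroring complete-case analysis.
#'
#' @param windows List of `window_feature_set` objects from both conditions.
#' @return List with `pairs` (list of `list(subject, scenario, calm, anxious)`)
#'   and `excluded` (data frame `subject`, `scenario`, `reason`).
#' @export
pair_windows <- function(windows) {
  if (length(windows) == 0)
    return(list(pairs = list(),
                excluded = data.frame(subject = character(),
                                      scenario = character(),
                                      reason = character())))
  key <- vapply(windows, function(w) paste(w$subject, w$scenario, sep = "\r"),
                character(1))
  cond <- vapply(windows, function(w) as.character(w$condition), character(1))
  pairs <- list(); excl <- list()
  for (k in unique(key)) {
    ws <- windows[key == k]
    cs <- cond[key == k]
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    has_calm <- "calm" %in% cs; has_anx <- "anxious" %in% cs
    if (has_calm && has_anx) {
      pairs[[length(pairs) + 1]] <- list(
        subject = parts[1], scenario = parts[2],
        calm = ws[[which(cs == "calm")[1]]],
        anxious = ws[[which(cs == "anxious")[1]]])
    } else {
      excl[[length(excl) + 1]] <- data.frame(
        subject = parts[1], scenario = parts[2],
        reason = paste("missing", if (has_calm) "anxious" else "calm",
                       "condition"))
    }
  }
  list(pairs = pairs,
       excluded = if (length(excl)) do.call(rbind, excl) else
         data.frame(subject = character(), scenario = character(),
                    reason = character()))
}
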