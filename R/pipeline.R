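# End-to-end orchestration: session directories (or an in-memory study) ->
# featurized sessions -> static screening -> scenario similarity -> report
# tables. Sessions are stored one directory per session: one long-format CSV
# per pad (frame_index, row, col, pressure_mmHg; non-zero cells only) plus a
# JSON sidecar with subject, condition, sampling metadata, the event log and
# the generator ground truth.

#' Pipeline configuration
#'
#' @param acquisition An [acquisition_config()].
#' @param map Optional [region_map()] override (default midline split).
#' @param outlier_z Robust z bound of [clean_outliers()] (default 4).
#' @param screening A [screening_config()].
#' @param similarity_features Optional feature subset for the similarity
#'   stage (`NULL` = all 108, the default; `"significant"` = the screened
#'   set).
#' @param standardize Per-feature standardization before cosine (default
#'   FALSE).
#' @param min_support Minimum shared-support fraction for cosine (0.8).
#' @param seed Pipeline seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(acquisition = acquisition_config(), map = NULL,
                            outlier_z = 4, screening = screening_config(),
                            similarity_features = NULL, standardize = FALSE,
                            min_support = 0.8, seed = 1) {
  if (is.null(map)) map <- default_region_map(acquisition)
  structure(list(acquisition = acquisition, map = map, outlier_z = outlier_z,
                 screening = screening,
                 similarity_features = similarity_features,
                 standardize = standardize, min_support = min_support,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write a session to a directory
#'
#' @param session A `pressure_session`.
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- session$config
  nr <- cfg$grid_rows
  for (pad in c("seat", "back")) {
    X <- session[[pad]]
    nz <- which(X > 0, arr.ind = TRUE)
    df <- data.frame(frame_index = nz[, 1],
                     row = (nz[, 2] - 1L) %% nr + 1L,
                     col = (nz[, 2] - 1L) %/% nr + 1L,
                     pressure_mmHg = X[nz])
    df <- df[order(df$frame_index, df$col, df$row), ]
    utils::write.csv(df, file.path(dir, paste0(pad, ".csv")), row.names = FALSE)
  }
  meta <- list(subject = session$subject_id, condition = session$condition,
               grid_rows = cfg$grid_rows, grid_cols = cfg$grid_cols,
               sampling_hz = cfg$sampling_hz,
               n_frames = length(session$timestamps),
               events = session$events,
               ground_truth = .px_gt_to_list(session$ground_truth))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                              dataframe = "rows", null = "null"),
             file.path(dir, "session.json"))
  invisible(dir)
}

.px_gt_to_list <- function(gt) {
  if (is.null(gt)) return(NULL)
  list(kappa = as.list(gt$kappa),
       pressure_gain_by_region = as.list(gt$effect$pressure_gain_by_region),
       cop_row_sway_amplitude = gt$effect$cop_row_sway_amplitude,
       cop_col_sway_amplitude = gt$effect$cop_col_sway_amplitude,
       volatility_gain = gt$effect$volatility_gain,
       spike_rate = gt$effect$spike_rate,
       subject_scale = gt$subject_scale,
       base_levels = as.list(gt$base_levels))
}

#' Read a session directory
#'
#' @param dir Directory written by [write_session()].
#' @return A `pressure_session` (ground truth restored as a plain list).
#' @export
read_session <- function(dir) {
  meta_path <- file.path(dir, "session.json")
  if (!file.exists(meta_path)) stop("not a session directory: ", dir)
  meta <- jsonlite::fromJSON(readLines(meta_path), simplifyVector = TRUE)
  cfg <- acquisition_config(meta$grid_rows, meta$grid_cols, meta$sampling_hz)
  nr <- cfg$grid_rows
  ncell <- nr * cfg$grid_cols
  n <- meta$n_frames
  pads <- lapply(c("seat", "back"), function(pad) {
    df <- utils::read.csv(file.path(dir, paste0(pad, ".csv")))
    X <- matrix(0, n, ncell)
    X[cbind(df$frame_index, (df$col - 1L) * nr + df$row)] <- df$pressure_mmHg
    X
  })
  events <- as.data.frame(meta$events)
  if (is.null(events$exit_time)) events$exit_time <- NA_real_
  structure(list(subject_id = meta$subject, condition = meta$condition,
                 config = cfg, timestamps = (seq_len(n) - 1) / cfg$sampling_hz,
                 seat = pads[[1]], back = pads[[2]], events = events,
                 ground_truth = meta$ground_truth),
            class = "pressure_session")
}

#' Simulate a study and write it as a study directory
#'
#' @inheritParams simulate_study
#' @param out_dir Target study directory.
#' @return The `pressure_study`, invisibly.
#' @export
run_simulate <- function(out_dir, n_subjects = 18, seed = 1,
                         scenarios = default_scenarios(),
                         effect = anxiety_effect_spec(),
                         config = acquisition_config(),
                         noise = noise_spec(), static_duration_s = 60) {
  study <- simulate_study(n_subjects, seed, scenarios, effect, config, noise,
                          static_duration_s)
  dir.create(file.path(out_dir, "sessions"), recursive = TRUE,
             showWarnings = FALSE)
  for (nm in names(study$sessions))
    write_session(study$sessions[[nm]], file.path(out_dir, "sessions", nm))
  utils::write.csv(study$sam$calm, file.path(out_dir, "sam_calm.csv"),
                   row.names = FALSE)
  utils::write.csv(study$sam$anxious, file.path(out_dir, "sam_anxious.csv"),
                   row.names = FALSE)
  writeLines(jsonlite::toJSON(list(seed = seed, n_subjects = n_subjects),
                              auto_unbox = TRUE),
             file.path(out_dir, "study.json"))
  invisible(study)
}

#' Read a study directory back into memory
#'
#' @param study_dir Directory written by [run_simulate()].
#' @return A `pressure_study` (sessions and SAM tables only).
#' @export
read_study <- function(study_dir) {
  sdirs <- list.dirs(file.path(study_dir, "sessions"), recursive = FALSE)
  if (length(sdirs) == 0) stop("no session directories under ", study_dir)
  sessions <- list()
  for (d in sdirs) {
    s <- tryCatch(read_session(d), error = function(e) {
      warning("skipping malformed session ", basename(d), ": ",
              conditionMessage(e))
      NULL
    })
    if (!is.null(s)) sessions[[basename(d)]] <- s
  }
  if (length(sessions) == 0) stop("all sessions malformed under ", study_dir)
  sam <- list()
  for (cond in c("calm", "anxious")) {
    f <- file.path(study_dir, paste0("sam_", cond, ".csv"))
    if (file.exists(f)) sam[[cond]] <- utils::read.csv(f)
  }
  structure(list(sessions = sessions, sam = sam,
                 config = sessions[[1]]$config),
            class = "pressure_study")
}

# Split a study's sessions into static and driving sets by event content.
.px_session_type <- function(session) {
  if (nrow(session$events) == 1 && session$events$scenario[1] == "induction")
    "static" else "driving"
}

#' Analyze a study in memory
#'
#' The full pipeline over a `pressure_study`: featurize and outlier-clean
#' every session; reduce static-induction windows to 108 statistics and
#' screen the paired anxious-minus-calm differences; build per-subject static
#' and per-scenario difference vectors and score scenarios by cosine
#' similarity; validate SAM records if present. Subjects or pairs missing a
#' condition are excluded and reported, never imputed.
#'
#' @param study A `pressure_study` from [simulate_study()] or [read_study()].
#' @param config A [pipeline_config()].
#' @return List with `screening`, `region_summary`, `volcano`, `similarity`
#'   (result of [aggregate_similarity()]), `sam`, `exclusions`,
#'   `static_stats` (subject x 108 per condition), `n_subjects_screened`,
#'   and `config`.
#' @export
analyze_study <- function(study, config = pipeline_config()) {
  map <- config$map
  static_windows <- list()  # [[subject]][[condition]] -> window stats
  driving_windows <- list() # flat list of window_feature_set
  for (nm in names(study$sessions)) {
    sess <- study$sessions[[nm]]
    feats <- featurize_session(sess, map)
    feats <- clean_outliers(feats, config$outlier_z)$features
    wins <- session_windows(sess, feats, map)
    if (.px_session_type(sess) == "static") {
      static_windows[[as.character(sess$subject_id)]][[sess$condition]] <-
        window_stats(wins[[1]])
    } else {
      driving_windows <- c(driving_windows, wins)
    }
  }

  # paired static differences -> screening
  subjects <- names(static_windows)
  complete <- vapply(static_windows, function(w)
    all(c("calm", "anxious") %in% names(w)), logical(1))
  excl_static <- data.frame(subject = subjects[!complete],
                            stage = rep("static", sum(!complete)),
                            reason = rep("missing condition", sum(!complete)))
  subjects <- subjects[complete]
  static_diffs <- NULL; screening <- NULL; rs <- NULL; volc <- NULL
  D <- NULL
  if (length(subjects) > 0) {
    D <- t(vapply(subjects, function(s)
      static_windows[[s]]$anxious - static_windows[[s]]$calm,
      numeric(108)))
    colnames(D) <- stat_feature_names()
    if (nrow(D) >= 5) {
      screening <- paired_screen(D, config$screening)
      rs <- region_summary(screening)
      volc <- volcano_table(screening)
    }
    static_diffs <- lapply(subjects, function(s)
      feature_diff(static_windows[[s]]$anxious, static_windows[[s]]$calm))
    names(static_diffs) <- subjects
  }

  # paired scenario differences -> similarity
  paired <- pair_windows(driving_windows)
  scene_diffs <- list()
  for (p in paired$pairs) {
    if (!p$subject %in% subjects) next
    scene_diffs[[p$subject]][[p$scenario]] <-
      feature_diff(window_stats(p$anxious), window_stats(p$calm))
  }
  similarity <- NULL
  if (length(scene_diffs) > 0 && !is.null(static_diffs)) {
    feats_sel <- config$similarity_features
    if (identical(feats_sel, "significant")) {
      if (is.null(screening)) stop("significant feature set requested but screening unavailable")
      feats_sel <- screening$feature[screening$significant]
    }
    sim <- similarity_table(static_diffs, scene_diffs, features = feats_sel,
                            standardize = config$standardize,
                            min_support = config$min_support)
    similarity <- aggregate_similarity(sim)
  }

  sam <- if (!is.null(study$sam$calm) && !is.null(study$sam$anxious))
    sam_validation(study$sam$calm, study$sam$anxious) else NULL

  excl_pairs <- paired$excluded
  exclusions <- rbind(
    excl_static,
    if (nrow(excl_pairs))
      data.frame(subject = excl_pairs$subject, stage = "driving",
                 reason = paste(excl_pairs$scenario, excl_pairs$reason))
    else NULL)

  list(screening = screening, region_summary = rs, volcano = volc,
       similarity = similarity, sam = sam, exclusions = exclusions,
       paired_diffs = D, static_diffs = static_diffs,
       n_subjects_screened = length(subjects), config = config)
}

#' Run the analysis pipeline over a study directory and write reports
#'
#' Emits the screening table, region summary, volcano table, SAM summary,
#' similarity matrix, scenario ranking and stack-plot data as CSV, plus the
#' resolved configuration and an exclusion report. Rerunning on the same
#' inputs and seed reproduces the outputs.
#'
#' @param study A study directory path or a `pressure_study`.
#' @param out_dir Output directory for report files.
#' @param config A [pipeline_config()].
#' @return The [analyze_study()] result, invisibly.
#' @export
run_analyze <- function(study, out_dir, config = pipeline_config()) {
  if (is.character(study)) study <- read_study(study)
  res <- analyze_study(study, config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(x, f) if (!is.null(x))
    utils::write.csv(x, file.path(out_dir, f), row.names = FALSE)
  wcsv(res$screening, "screening.csv")
  wcsv(res$region_summary, "region_summary.csv")
  wcsv(res$volcano, "volcano.csv")
  wcsv(res$sam, "sam_summary.csv")
  if (!is.null(res$similarity)) {
    m <- res$similarity$matrix
    wcsv(data.frame(subject = rownames(m), m, check.names = FALSE),
         "similarity_matrix.csv")
    wcsv(res$similarity$scenario_summary, "scenario_summary.csv")
    wcsv(res$similarity$stack, "stack_data.csv")
  }
  wcsv(res$exclusions, "exclusions.csv")
  resolved <- list(
    outlier_z = config$outlier_z,
    normality_alpha = config$screening$normality_alpha,
    p_threshold = config$screening$p_threshold,
    lilliefors_mc_reps = config$screening$lilliefors_mc_reps,
    similarity_features = if (is.null(config$similarity_features)) "all"
      else config$similarity_features,
    standardize = config$standardize, min_support = config$min_support,
    seed = config$seed,
    region_map = jsonlite::fromJSON(region_map_to_json(config$map)))
  writeLines(jsonlite::toJSON(resolved, auto_unbox = TRUE, digits = NA),
             file.path(out_dir, "run_config.json"))
  message(sprintf(
    "analyze: %d sessions, %d subjects screened, %d significant features, %d exclusions",
    length(study$sessions), res$n_subjects_screened,
    if (is.null(res$screening)) 0L else sum(res$screening$significant),
    if (is.null(res$exclusions)) 0L else nrow(res$exclusions)))
  invisible(res)
}
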