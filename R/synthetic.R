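# Synthetic seated-pressure study generator.
#
# The pressure field of each region is a truncated Gaussian blob on the grid,
# rescaled each frame so that the mean over its non-zero cells equals a target
# level (mmHg) with multiplicative log-normal frame noise. The anxiety effect
# is planted as (i) multiplicative regional pressure gains (with contact area
# scaling in step, blob width ~ sqrt(gain)), (ii) an extra anterior-posterior
# COP sway component (slow sinusoid plus an AR(1) regression process,
# amplitude in grid units), (iii) a volatility multiplier on frame noise, and
# (iv) Poisson-timed 2-4-frame pressure spikes. Lateral COP sway is equal
# across conditions. Per-subject load scaling (a weight proxy) makes the
# amplitude-invariance of cosine similarity testable.

#' Anxiety effect specification
#'
#' Parameters of the planted anxiety pattern. Defaults follow the study
#' conditions: lower-body regional pressure (and contact area) elevated by
#' 10-20% with the upper back unaffected, an extra anterior-posterior COP sway
#' of 0.51 grid units, lateral sway equal across conditions, frame-to-frame
#' volatility increased 1.5x, and sporadic postural-adjustment spikes.
#'
#' @param pressure_gain_by_region Named multiplicative gains (unitless) for
#'   the six regions.
#' @param cop_row_sway_amplitude Extra anterior-posterior sway amplitude in
#'   grid units (anxious only; default 0.51).
#' @param cop_col_sway_amplitude Lateral sway amplitude in grid units, equal
#'   across conditions (default 0.3, within the 1-unit range).
#' @param volatility_gain Multiplier on frame-to-frame noise scale under
#'   anxiety (default 1.5).
#' @param spike_rate Poisson rate (events/s) of transient pressure
#'   redistributions under anxiety (default 0.03).
#' @return An object of class `anxiety_effect_spec`.
#' @export
anxiety_effect_spec <- function(pressure_gain_by_region = c(
                                  BTL = 1.12, BTR = 1.18, THL = 1.20,
                                  THR = 1.12, UB = 1.00, LB = 1.15),
                                cop_row_sway_amplitude = 0.51,
                                cop_col_sway_amplitude = 0.3,
                                volatility_gain = 1.5,
                                spike_rate = 0.03) {
  g <- pressure_gain_by_region
  if (!all(PX_REGIONS %in% names(g))) stop("gains must name all six regions")
  g <- g[PX_REGIONS]
  if (any(!is.finite(g)) || any(g <= 0)) stop("all gains must be > 0")
  if (cop_row_sway_amplitude < 0 || cop_col_sway_amplitude < 0)
    stop("sway amplitudes must be >= 0")
  if (volatility_gain <= 0) stop("volatility_gain must be > 0")
  if (spike_rate < 0) stop("spike_rate must be >= 0")
  structure(list(pressure_gain_by_region = g,
                 cop_row_sway_amplitude = cop_row_sway_amplitude,
                 cop_col_sway_amplitude = cop_col_sway_amplitude,
                 volatility_gain = volatility_gain,
                 spike_rate = spike_rate),
            class = "anxiety_effect_spec")
}

#' Measurement / physiological noise specification
#'
#' @param level_sd Log-scale sd of multiplicative frame noise on regional
#'   pressure levels (default 0.12, i.e. ~12% frame-to-frame variation).
#' @param width_sd Log-scale sd of blob-width jitter (default 0.02), the
#'   source of contact-area variability.
#' @param ar_scale Scale of the AR(1) component of COP sway relative to the
#'   sway amplitude (default 1; 0 disables it).
#' @param drift_rate Slow linear upward drift of pressure levels per second,
#'   equal across conditions (default 2e-4/s, the calm-state smooth tendency).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(level_sd = 0.12, width_sd = 0.02, ar_scale = 1,
                       drift_rate = 2e-4) {
  stopifnot(level_sd >= 0, width_sd >= 0, ar_scale >= 0, drift_rate >= 0)
  structure(list(level_sd = level_sd, width_sd = width_sd,
                 ar_scale = ar_scale, drift_rate = drift_rate),
            class = "noise_spec")
}

#' Noise-free generator settings
#'
#' Convenience for analytic checks: no level noise, no width jitter, no AR
#' sway component, no drift. With anxiety coupling 0 this makes calm and
#' anxious sessions bit-identical, so baseline-corrected differences vanish
#' exactly.
#' @return A `noise_spec` with all stochastic components off.
#' @export
noise_off <- function() noise_spec(level_sd = 0, width_sd = 0, ar_scale = 0,
                                   drift_rate = 0)

#' Driving scenario specification
#'
#' @param name Scenario name.
#' @param kind Event kind: `"instantaneous"` (horn-press style mark, window
#'   5 s either side), `"continuous"` (first 10 s from onset), or
#'   `"entry_exit"` (two instantaneous-style anchors, e.g. roundabout entry
#'   and exit, treated downstream as two scenarios `<name>_entry` /
#'   `<name>_exit`).
#' @param kappa Anxiety coupling in `[0, 1]`: how strongly the static anxiety
#'   pattern is expressed in this scenario (for `entry_exit`, at entry).
#' @param kappa_exit Coupling at exit (entry_exit only; defaults to `kappa`).
#' @param task_pressure Named additive regional pressure changes (mmHg)
#'   caused by the driving action itself, present in BOTH conditions.
#' @param task_cop_row Additive anterior-posterior COP shift (grid units) of
#'   the seat regions during the scenario, present in both conditions.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, kind = c("instantaneous", "continuous", "entry_exit"),
                          kappa = 0.5, kappa_exit = NULL,
                          task_pressure = NULL, task_cop_row = 0) {
  kind <- match.arg(kind)
  if (!is.finite(kappa) || kappa < 0 || kappa > 1)
    stop("kappa must be in [0, 1]")
  if (is.null(kappa_exit)) kappa_exit <- kappa
  if (!is.finite(kappa_exit) || kappa_exit < 0 || kappa_exit > 1)
    stop("kappa_exit must be in [0, 1]")
  tp <- stats::setNames(numeric(6), PX_REGIONS)
  if (!is.null(task_pressure)) {
    if (is.null(names(task_pressure)) || !all(names(task_pressure) %in% PX_REGIONS))
      stop("task_pressure must be named by region")
    if (any(!is.finite(task_pressure))) stop("task_pressure must be finite")
    tp[names(task_pressure)] <- task_pressure
  }
  structure(list(name = name, kind = kind, kappa = kappa,
                 kappa_exit = kappa_exit, task_pressure = tp,
                 task_cop_row = task_cop_row),
            class = "scenario_spec")
}

#' Default eight-scenario urban driving route
#'
#' Eight scenario labels (roundabout entry and exit are separate labels from
#' one entry/exit event) with plausible task components and a descending
#' anxiety-coupling profile: high-uncertainty, high-interaction scenarios
#' (roundabout entry, congestion) couple strongly; predictable, continuous
#' manoeuvres (consecutive turns, parking) couple weakly.
#'
#' @return List of [scenario_spec()] objects.
#' @export
default_scenarios <- function() {
  list(
    scenario_spec("congested_traffic", "continuous", kappa = 0.80,
                  task_pressure = c(BTL = 3, BTR = 3, LB = 2)),
    scenario_spec("lane_change", "instantaneous", kappa = 0.70,
                  task_pressure = c(BTL = 6, THR = 4)),
    scenario_spec("emergency_braking", "instantaneous", kappa = 0.60,
                  task_pressure = c(THL = 12, THR = 12, BTL = -5, BTR = -5),
                  task_cop_row = -0.8),
    scenario_spec("pedestrian_crossing", "instantaneous", kappa = 0.55,
                  task_pressure = c(THL = 6, THR = 6), task_cop_row = -0.4),
    scenario_spec("consecutive_turns", "continuous", kappa = 0.30,
                  task_pressure = c(BTL = 5, BTR = 5)),
    scenario_spec("roundabout", "entry_exit", kappa = 0.90, kappa_exit = 0.45,
                  task_pressure = c(THL = 8, THR = 8), task_cop_row = -0.5),
    scenario_spec("parking", "continuous", kappa = 0.15,
                  task_pressure = c(LB = 4, BTL = 3, BTR = 3))
  )
}

# Deterministic per-subject hash for phase offsets (condition-independent).
.px_hash <- function(subject_id) {
  sum(utf8ToInt(as.character(subject_id)) * seq_along(utf8ToInt(as.character(subject_id)))) %% 10007L
}

# Unit-variance stationary AR(1) series.
.px_ar1 <- function(n, phi = 0.9) {
  e <- stats::rnorm(n)
  x <- numeric(n)
  x[1] <- e[1]
  s <- sqrt(1 - phi^2)
  for (t in seq_len(n)[-1]) x[t] <- phi * x[t - 1] + s * e[t]
  x
}

# Build one pad's frame matrix (T x n_cells) from per-frame, per-region blob
# parameters. levels/sdr/sdc/cr/cc: T x k matrices, one column per region on
# this pad. The blob is truncated at `trunc` of its peak and rescaled so the
# mean over non-zero cells equals the level exactly.
.px_build_pad <- function(map, pad, levels, sdr, sdc, cr, cc, trunc = 0.1) {
  cfg <- map$config
  nr <- cfg$grid_rows
  n_frames <- nrow(levels)
  Xt <- matrix(0, nr * cfg$grid_cols, n_frames) # cells x frames, transposed once
  rg_pad <- if (pad == "seat") PX_SEAT_REGIONS else PX_BACK_REGIONS
  sq <- sqrt(trunc)
  for (rg in rg_pad) {
    def <- map$regions[[rg]]
    rows <- def$rows; cols <- def$cols
    a <- length(rows); b <- length(cols)
    # separable truncated-Gaussian factors, (a|b) x T; each factor truncated
    # at sqrt(trunc) of its peak so the product is zero outside the contact
    # patch; the scale making the non-zero mean equal the level is folded
    # into the row factor so only one full block product is formed
    E <- outer(rows, cr[, rg], "-")
    Rf <- exp(-E * E * rep(0.5 / sdr[, rg]^2, each = a))
    E <- outer(cols, cc[, rg], "-")
    Cf <- exp(-E * E * rep(0.5 / sdc[, rg]^2, each = b))
    Rf[Rf < sq] <- 0
    Cf[Cf < sq] <- 0
    cnt <- colSums(Rf > 0) * colSums(Cf > 0)
    tot <- colSums(Rf) * colSums(Cf)
    s <- ifelse(cnt > 0 & tot > 0, levels[, rg] * cnt / tot, 0)
    Rf <- Rf * rep(s, each = a)
    block <- Rf[rep.int(seq_len(a), b), , drop = FALSE] *
      Cf[rep(seq_len(b), each = a), , drop = FALSE]
    idx <- as.vector(outer(rows, (cols - 1L) * nr, "+"))
    Xt[idx, ] <- block
  }
  t(Xt)
}

# Shared frame engine. kappa_t: per-frame anxiety coupling in [0,1] (0 for
# calm frames); task_level: T x 6 additive mmHg; task_cop_row_t: length-T.
.px_generate_frames <- function(map, n_frames, hz, kappa_t, task_level,
                                task_cop_row_t, effect, noise, subject_scale,
                                base_levels, hash) {
  t_s <- (seq_len(n_frames) - 1) / hz
  gains <- effect$pressure_gain_by_region
  vol_t <- 1 + kappa_t * (effect$volatility_gain - 1)
  drift_t <- 1 + noise$drift_rate * t_s

  # COP sway offsets (grid units), shared across regions of a pad
  ph <- 2 * pi * ((hash * c(3, 7, 11)) %% 97) / 97
  calm_row_amp <- 0.10
  row_off <- calm_row_amp * sin(2 * pi * 0.08 * t_s + ph[1]) +
    kappa_t * effect$cop_row_sway_amplitude *
      (sin(2 * pi * 0.12 * t_s + ph[2]) + 0.3 * noise$ar_scale * .px_ar1(n_frames))
  col_off <- effect$cop_col_sway_amplitude * sin(2 * pi * 0.10 * t_s + ph[3])
  row_off_seat <- row_off + task_cop_row_t
  row_off_back <- 0.5 * row_off

  # spikes: transient pressure redistributions, rate scaled by coupling
  spike_mult <- matrix(1, n_frames, 6, dimnames = list(NULL, PX_REGIONS))
  lambda <- effect$spike_rate * sum(kappa_t) / hz
  if (lambda > 0) {
    n_sp <- stats::rpois(1, lambda)
    if (n_sp > 0) {
      cand <- which(kappa_t > 0)
      starts <- sample(cand, n_sp, replace = TRUE)
      for (s0 in starts) {
        len <- sample(2:4, 1)
        fr <- s0:min(s0 + len - 1, n_frames)
        fac <- stats::runif(6, 0.75, 1.35)
        fac[PX_REGIONS == "UB"] <- 1
        spike_mult[fr, ] <- spike_mult[fr, , drop = FALSE] *
          rep(fac, each = length(fr))
      }
    }
  }

  levels <- sdr <- sdc <- cr <- cc <-
    matrix(NA_real_, n_frames, 6, dimnames = list(NULL, PX_REGIONS))
  for (rg in PX_REGIONS) {
    def <- map$regions[[rg]]
    gain_t <- 1 + kappa_t * (gains[rg] - 1)
    lsd_t <- noise$level_sd * vol_t
    lnoise <- exp(stats::rnorm(n_frames) * lsd_t - lsd_t^2 / 2)
    levels[, rg] <- pmax(0.5, (base_levels[rg] * subject_scale * gain_t +
                                 task_level[, rg]) * drift_t) *
      lnoise * spike_mult[, rg]
    wsd_t <- noise$width_sd * vol_t
    wjit <- exp(stats::rnorm(n_frames) * wsd_t - wsd_t^2 / 2)
    sdr[, rg] <- (length(def$rows) / 4.5) * sqrt(gain_t) * wjit
    sdc[, rg] <- (length(def$cols) / 4.5) * sqrt(gain_t) * wjit
    off_r <- if (rg %in% PX_SEAT_REGIONS) row_off_seat else row_off_back
    cr[, rg] <- mean(def$rows) + off_r
    cc[, rg] <- mean(def$cols) + col_off
  }
  list(
    seat = .px_build_pad(map, "seat", levels, sdr, sdc, cr, cc),
    back = .px_build_pad(map, "back", levels, sdr, sdc, cr, cc),
    timestamps = t_s
  )
}

.px_session <- function(subject_id, condition, config, frames, events,
                        ground_truth) {
  structure(list(subject_id = subject_id, condition = condition,
                 config = config, timestamps = frames$timestamps,
                 seat = frames$seat, back = frames$back, events = events,
                 ground_truth = ground_truth),
            class = "pressure_session")
}

#' @export
print.pressure_session <- function(x, ...) {
  cat(sprintf("<pressure_session> subject %s, %s, %d frames @ %g Hz, %d events\n",
              x$subject_id, x$condition, length(x$timestamps),
              x$config$sampling_hz, nrow(x$events)))
  invisible(x)
}

#' Generate a static emotion-induction session
#'
#' Emulates the stationary induction recording: the subject sits still while
#' calm or anxious. Anxious sessions express the full anxiety pattern
#' (coupling 1) throughout; the buzzer press marking anxiety onset is logged
#' as an instantaneous event at mid-session.
#'
#' @param subject_id Subject identifier.
#' @param condition `"calm"` or `"anxious"`.
#' @param effect An [anxiety_effect_spec()].
#' @param duration_s Session length in seconds (>= 10).
#' @param seed Integer seed; identical seed and parameters give bit-identical
#'   sessions.
#' @param config An [acquisition_config()].
#' @param noise A [noise_spec()].
#' @param subject_scale Per-subject multiplicative load scale (weight proxy).
#' @param base_levels Named calm-state mean regional pressures (mmHg).
#' @return A `pressure_session`.
#' @export
generate_static_session <- function(subject_id, condition = c("calm", "anxious"),
                                    effect = anxiety_effect_spec(),
                                    duration_s = 120, seed = 1,
                                    config = acquisition_config(),
                                    noise = noise_spec(), subject_scale = 1,
                                    base_levels = c(BTL = 55, BTR = 55, THL = 35,
                                                    THR = 35, UB = 15, LB = 25)) {
  condition <- match.arg(condition)
  if (!is.finite(duration_s) || duration_s <= 0)
    stop("duration_s must be positive")
  if (duration_s < 10) stop("duration_s must be >= 10 (one full window)")
  stopifnot(inherits(effect, "anxiety_effect_spec"), inherits(noise, "noise_spec"))
  base_levels <- base_levels[PX_REGIONS]
  map <- default_region_map(config)
  n_frames <- floor(duration_s * config$sampling_hz)
  set.seed(as.integer(seed))
  kappa <- if (condition == "anxious") 1 else 0
  frames <- .px_generate_frames(
    map, n_frames, config$sampling_hz,
    kappa_t = rep(kappa, n_frames),
    task_level = matrix(0, n_frames, 6, dimnames = list(NULL, PX_REGIONS)),
    task_cop_row_t = rep(0, n_frames),
    effect = effect, noise = noise, subject_scale = subject_scale,
    base_levels = base_levels, hash = .px_hash(subject_id)
  )
  events <- data.frame(scenario = "induction", kind = "instantaneous",
                       anchor_time = duration_s / 2, exit_time = NA_real_)
  .px_session(subject_id, condition, config, frames, events,
              list(effect = effect, kappa = kappa, noise = noise,
                   subject_scale = subject_scale, base_levels = base_levels))
}

#' Generate a simulated driving session over a scenario sequence
#'
#' Scenarios are laid out along the session separated by 8 s of plain driving.
#' Within a scenario's active interval the task component (identical across
#' conditions) is applied, and — in anxious sessions — the anxiety pattern
#' scaled by the scenario's coupling `kappa`, so that per-feature
#' `anxious - calm` window differences equal `kappa` times the planted anxiety
#' pattern up to noise.
#'
#' @inheritParams generate_static_session
#' @param scenarios List of [scenario_spec()] objects (>= 1).
#' @return A `pressure_session` whose `events` hold one row per scenario with
#'   its kind and anchor time(s).
#' @export
generate_driving_session <- function(subject_id, condition = c("calm", "anxious"),
                                     scenarios = default_scenarios(),
                                     effect = anxiety_effect_spec(), seed = 1,
                                     config = acquisition_config(),
                                     noise = noise_spec(), subject_scale = 1,
                                     base_levels = c(BTL = 55, BTR = 55, THL = 35,
                                                     THR = 35, UB = 15, LB = 25)) {
  condition <- match.arg(condition)
  if (length(scenarios) < 1) stop("at least one scenario is required")
  for (sc in scenarios) {
    if (!inherits(sc, "scenario_spec")) stop("scenarios must be scenario_spec objects")
    if (!sc$kind %in% c("instantaneous", "continuous", "entry_exit"))
      stop("unknown event kind: ", sc$kind)
  }
  stopifnot(inherits(effect, "anxiety_effect_spec"), inherits(noise, "noise_spec"))
  base_levels <- base_levels[PX_REGIONS]
  map <- default_region_map(config)
  hz <- config$sampling_hz
  gap <- 4

  # schedule: active interval, anchors, per-label coupling
  cur <- gap
  ev <- list(); spans <- list()
  for (sc in scenarios) {
    if (sc$kind == "instantaneous") {
      spans[[length(spans) + 1]] <- list(sc = sc, from = cur, to = cur + 10,
                                         kappa = sc$kappa)
      ev[[length(ev) + 1]] <- data.frame(scenario = sc$name, kind = sc$kind,
                                         anchor_time = cur + 5, exit_time = NA_real_)
      cur <- cur + 10 + gap
    } else if (sc$kind == "continuous") {
      spans[[length(spans) + 1]] <- list(sc = sc, from = cur, to = cur + 10,
                                         kappa = sc$kappa)
      ev[[length(ev) + 1]] <- data.frame(scenario = sc$name, kind = sc$kind,
                                         anchor_time = cur, exit_time = NA_real_)
      cur <- cur + 10 + gap
    } else { # entry_exit: entry anchor, 12 s later the exit anchor
      entry <- cur + 5; exit <- entry + 12
      spans[[length(spans) + 1]] <- list(sc = sc, from = cur, to = cur + 10,
                                         kappa = sc$kappa)
      spans[[length(spans) + 1]] <- list(sc = sc, from = exit - 5, to = exit + 5,
                                         kappa = sc$kappa_exit)
      ev[[length(ev) + 1]] <- data.frame(scenario = sc$name, kind = sc$kind,
                                         anchor_time = entry, exit_time = exit)
      cur <- exit + 5 + gap
    }
  }
  duration_s <- cur
  n_frames <- floor(duration_s * hz)
  t_s <- (seq_len(n_frames) - 1) / hz

  kappa_t <- rep(0, n_frames)
  task_level <- matrix(0, n_frames, 6, dimnames = list(NULL, PX_REGIONS))
  task_cop_row_t <- rep(0, n_frames)
  anxious <- condition == "anxious"
  for (sp in spans) {
    sel <- t_s >= sp$from & t_s < sp$to
    if (anxious) kappa_t[sel] <- sp$kappa
    task_level[sel, ] <- rep(sp$sc$task_pressure, each = sum(sel))
    task_cop_row_t[sel] <- sp$sc$task_cop_row
  }

  set.seed(as.integer(seed))
  frames <- .px_generate_frames(
    map, n_frames, hz, kappa_t, task_level, task_cop_row_t,
    effect = effect, noise = noise, subject_scale = subject_scale,
    base_levels = base_levels, hash = .px_hash(subject_id)
  )
  events <- do.call(rbind, ev)
  kappa_by_label <- unlist(lapply(scenarios, function(sc) {
    if (sc$kind == "entry_exit")
      stats::setNames(c(sc$kappa, sc$kappa_exit),
                      paste0(sc$name, c("_entry", "_exit")))
    else stats::setNames(sc$kappa, sc$name)
  }))
  .px_session(subject_id, condition, config, frames, events,
              list(effect = effect, kappa = kappa_by_label, noise = noise,
                   subject_scale = subject_scale, base_levels = base_levels))
}

#' Generate SAM self-report records
#'
#' Integer valence/arousal/dominance scores in 1-9, centred on the study
#' conditions' medians: calm 5/2/8, anxious 2/8/2, with discrete spread
#' around the centre.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param condition `"calm"` or `"anxious"`.
#' @param seed Integer seed.
#' @param sd Spread of scores around the condition medians (default 0.8).
#' @return Data frame with columns `subject`, `valence`, `arousal`,
#'   `dominance`.
#' @export
generate_sam_records <- function(n_subjects, condition = c("calm", "anxious"),
                                 seed = 1, sd = 0.8) {
  condition <- match.arg(condition)
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  centers <- if (condition == "calm") c(5, 2, 8) else c(2, 8, 2)
  set.seed(as.integer(seed))
  draw <- function(center)
    pmin(9L, pmax(1L, as.integer(round(center + stats::rnorm(n_subjects, 0, sd)))))
  data.frame(subject = sprintf("S%02d", seq_len(n_subjects)),
             valence = draw(centers[1]), arousal = draw(centers[2]),
             dominance = draw(centers[3]))
}

#' Simulate a complete two-condition study
#'
#' For each subject: a calm and an anxious static induction session plus a
#' calm and an anxious driving session over the given scenarios, with a
#' per-subject load scale drawn once (log-normal, sd 0.15), and paired SAM
#' records for both conditions.
#'
#' @param n_subjects Number of subjects (default 18, the study's complete-case
#'   sample).
#' @param seed Integer study seed; drives all per-session seeds.
#' @param scenarios List of [scenario_spec()]s (default the eight-label route).
#' @param effect An [anxiety_effect_spec()].
#' @param config An [acquisition_config()].
#' @param noise A [noise_spec()].
#' @param static_duration_s Length of static induction sessions (default 60).
#' @return An object of class `pressure_study`: list with `sessions` (list of
#'   `pressure_session`), `sam` (list with `calm`/`anxious` data frames),
#'   `scenarios`, `effect`, `config`, `noise`, `seed`, `subject_scales`.
#' @export
simulate_study <- function(n_subjects = 18, seed = 1,
                           scenarios = default_scenarios(),
                           effect = anxiety_effect_spec(),
                           config = acquisition_config(),
                           noise = noise_spec(), static_duration_s = 60) {
  if (n_subjects < 1) stop("empty study: n_subjects must be >= 1")
  set.seed(as.integer(seed))
  subject_ids <- sprintf("S%02d", seq_len(n_subjects))
  subject_scales <- stats::setNames(stats::rlnorm(n_subjects, 0, 0.15), subject_ids)
  session_seeds <- matrix(sample.int(.Machine$integer.max - 1, n_subjects * 4),
                          n_subjects, 4)
  sessions <- list()
  for (i in seq_len(n_subjects)) {
    sid <- subject_ids[i]
    sessions[[paste0(sid, "_static_calm")]] <- generate_static_session(
      sid, "calm", effect, static_duration_s, session_seeds[i, 1], config,
      noise, subject_scales[i])
    sessions[[paste0(sid, "_static_anxious")]] <- generate_static_session(
      sid, "anxious", effect, static_duration_s, session_seeds[i, 2], config,
      noise, subject_scales[i])
    sessions[[paste0(sid, "_driving_calm")]] <- generate_driving_session(
      sid, "calm", scenarios, effect, session_seeds[i, 3], config, noise,
      subject_scales[i])
    sessions[[paste0(sid, "_driving_anxious")]] <- generate_driving_session(
      sid, "anxious", scenarios, effect, session_seeds[i, 4], config, noise,
      subject_scales[i])
  }
  sam_seeds <- sample.int(.Machine$integer.max - 1, 2)
  structure(list(sessions = sessions,
                 sam = list(calm = generate_sam_records(n_subjects, "calm", sam_seeds[1]),
                            anxious = generate_sam_records(n_subjects, "anxious", sam_seeds[2])),
                 scenarios = scenarios, effect = effect, config = config,
                 noise = noise, seed = seed, subject_scales = subject_scales),
            class = "pressure_study")
}

#' @export
print.pressure_study <- function(x, ...) {
  cat(sprintf("<pressure_study> %d subjects, %d sessions, %d scenario specs, seed %s\n",
              length(x$subject_scales), length(x$sessions),
              length(x$scenarios), format(x$seed)))
  invisible(x)
}
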