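# Scenario-anxiety similarity: the anxiety prototype is the per-subject
# anxious-minus-calm statistical feature vector from static induction
# (Delta_static); each scenario's anxious-minus-calm vector (Delta_scene) is
# dynamically baseline-corrected by construction (the calm-driving window of
# the same scenario removes the manoeuvre's own pressure changes); their
# cosine similarity scores how closely the scenario reproduces the static
# anxiety pattern, invariant to overall amplitude.

#' Difference of two condition feature vectors
#'
#' Elementwise anxious minus calm on the shared feature ordering, with
#' optional per-feature scaling. The all-zero result is flagged (attribute
#' `zero`), since a zero difference vector has no direction.
#'
#' @param anxious,calm Named numeric vectors with identical names (typically
#'   the 108 statistics from [window_stats()]).
#' @param scale Optional named per-feature scale (e.g. pooled standard
#'   deviations); the difference is divided by it elementwise.
#' @return Named numeric difference vector with attribute `zero`.
#' @export
feature_diff <- function(anxious, calm, scale = NULL) {
  stopifnot(identical(names(anxious), names(calm)))
  d <- anxious - calm
  if (!is.null(scale)) {
    stopifnot(identical(names(scale), names(d)))
    d <- d / ifelse(is.finite(scale) & scale > 0, scale, NA_real_)
  }
  fin <- is.finite(d)
  attr(d, "zero") <- !any(fin & d != 0)
  d
}

#' Cosine similarity of two difference vectors on their shared support
#'
#' `dot(a, b) / (||a|| ||b||)` over the pairwise non-missing components. The
#' result is undefined (NA) when the shared support covers less than
#' `min_support` of the vector, has fewer than two components, or either
#' vector is zero on it.
#'
#' @param a,b Numeric vectors of equal length.
#' @param min_support Minimum fraction of components that must be shared
#'   (default 0.8).
#' @return Similarity in `[-1, 1]`, or NA.
#' @export
cosine_similarity <- function(a, b, min_support = 0.8) {
  stopifnot(length(a) == length(b))
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 2 || sum(ok) < min_support * length(a)) return(NA_real_)
  a <- a[ok]; b <- b[ok]
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a * b) / (na * nb)
}

#' Per-subject scenario similarities against the anxiety prototype
#'
#' @param static_diffs Named list (by subject) of static difference vectors
#'   (Delta_static, from [feature_diff()] on static-induction window stats).
#' @param scene_diffs Data-frame-free structure: named list (by subject) of
#'   named lists (by scenario) of scenario difference vectors (Delta_scene).
#' @param features Optional character vector restricting the comparison to a
#'   feature subset (e.g. the screened significant set); default all.
#' @param standardize If TRUE, divide every difference component by the
#'   pooled across-subject standard deviation of that component of the
#'   scenario differences before the cosine (off by default; raw vectors are
#'   the faithful default, scaling is exposed and logged in outputs).
#' @param min_support Passed to [cosine_similarity()].
#' @return Long data frame `subject`, `scenario`, `similarity` (NA where
#'   undefined).
#' @export
similarity_table <- function(static_diffs, scene_diffs, features = NULL,
                             standardize = FALSE, min_support = 0.8) {
  subjects <- intersect(names(static_diffs), names(scene_diffs))
  if (length(subjects) == 0) stop("no subjects with both static and scenario differences")
  scale <- NULL
  if (standardize) {
    all_sc <- unlist(lapply(scene_diffs[subjects], names))
    mat <- do.call(rbind, lapply(subjects, function(s)
      do.call(rbind, lapply(scene_diffs[[s]], as.numeric))))
    scale <- apply(mat, 2, stats::sd, na.rm = TRUE)
    names(scale) <- names(scene_diffs[[subjects[1]]][[1]])
  }
  rows <- list()
  for (s in subjects) {
    ds <- as.numeric(static_diffs[[s]])
    nm <- names(static_diffs[[s]])
    for (sc in names(scene_diffs[[s]])) {
      dv <- as.numeric(scene_diffs[[s]][[sc]])
      keep <- if (is.null(features)) seq_along(nm) else which(nm %in% features)
      a <- ds[keep]; b <- dv[keep]
      if (!is.null(scale)) { a <- a / scale[keep]; b <- b / scale[keep] }
      rows[[length(rows) + 1]] <- data.frame(
        subject = s, scenario = sc,
        similarity = cosine_similarity(b, a, min_support = min_support))
    }
  }
  do.call(rbind, rows)
}

#' Aggregate similarities over subjects and rank scenarios
#'
#' Scenario means are taken over subjects with defined similarity only;
#' scenarios with no defined value are excluded and reported.
#'
#' @param sim Long data frame from [similarity_table()].
#' @return List with `matrix` (subjects x scenarios), `scenario_summary`
#'   (`scenario`, `mean_similarity`, `sd_similarity`, `n`, `rank`, descending
#'   mean), `stack` (the long table, for per-subject stacked displays) and
#'   `excluded` (scenarios with zero defined values).
#' @export
aggregate_similarity <- function(sim) {
  stopifnot(all(c("subject", "scenario", "similarity") %in% names(sim)))
  mat <- tapply(sim$similarity, list(sim$subject, sim$scenario), mean)
  def <- colSums(is.finite(mat)) > 0
  excluded <- colnames(mat)[!def]
  summ <- data.frame(
    scenario = colnames(mat)[def],
    mean_similarity = apply(mat[, def, drop = FALSE], 2, mean, na.rm = TRUE),
    sd_similarity = apply(mat[, def, drop = FALSE], 2, stats::sd, na.rm = TRUE),
    n = colSums(is.finite(mat[, def, drop = FALSE])), row.names = NULL)
  summ <- summ[order(-summ$mean_similarity), ]
  summ$rank <- seq_len(nrow(summ))
  list(matrix = mat, scenario_summary = summ, stack = sim,
       excluded = excluded)
}
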