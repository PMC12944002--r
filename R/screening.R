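# Paired anxious-vs-calm feature screening. Each 36-feature x 50-frame window
# is reduced to 108 statistical features (Mean/Std/Max per variable); paired
# differences D[j, i] = X_anx - X_calm are gated per feature by a Lilliefors
# normality test (Monte-Carlo null, alpha = 0.05): normal -> paired t-test
# with paired Cohen's d, non-normal -> Wilcoxon signed-rank with matched-pairs
# rank-biserial r. The hard significance gate is p < 0.005 with no further
# multiple-testing correction; surviving features are ranked by |effect size|.

#' Screening configuration
#'
#' @param normality_alpha Significance level of the Lilliefors gate (0.05).
#' @param p_threshold Hard significance threshold of the paired tests (0.005).
#' @param lilliefors_mc_reps Monte-Carlo replicates for the Lilliefors null
#'   distribution (default 10000).
#' @param seed Seed for the Monte-Carlo null.
#' @return An object of class `screening_config`.
#' @export
screening_config <- function(normality_alpha = 0.05, p_threshold = 0.005,
                             lilliefors_mc_reps = 10000, seed = 1) {
  stopifnot(normality_alpha > 0, normality_alpha < 1,
            p_threshold > 0, p_threshold < 1, lilliefors_mc_reps >= 100)
  structure(list(normality_alpha = normality_alpha, p_threshold = p_threshold,
                 lilliefors_mc_reps = lilliefors_mc_reps, seed = as.integer(seed)),
            class = "screening_config")
}

#' Names of the 108 window statistical features
#'
#' For each of the 36 regional variables, in [feature_names()] order:
#' `<var>_Mean`, `<var>_Std`, `<var>_Max`.
#' @return Character vector of length 108.
#' @export
stat_feature_names <- function() {
  as.vector(t(outer(feature_names(), c("_Mean", "_Std", "_Max"), paste0)))
}

#' Reduce a window to its 108 statistical features
#'
#' Mean, standard deviation (n - 1 denominator) and maximum of each of the 36
#' variables over the window's valid (non-missing) frames. Variables with
#' fewer than two valid frames get missing statistics.
#'
#' @param window A `window_feature_set` (see [extract_window()]), or a plain
#'   numeric matrix of frames x 36 features.
#' @return Named numeric vector of length 108 in [stat_feature_names()] order.
#' @export
window_stats <- function(window) {
  m <- if (inherits(window, "window_feature_set")) window$data else window
  stopifnot(is.matrix(m), ncol(m) == 36)
  out <- stats::setNames(rep(NA_real_, 108), stat_feature_names())
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    x <- x[is.finite(x)]
    f <- colnames(m)[j]
    if (length(x) >= 2) {
      out[paste0(f, "_Mean")] <- mean(x)
      out[paste0(f, "_Std")] <- stats::sd(x)
      out[paste0(f, "_Max")] <- max(x)
    }
  }
  out
}

# cache of Monte-Carlo Lilliefors null distributions, keyed by n/reps/seed
.px_lillie_cache <- new.env(parent = emptyenv())

.px_lillie_stat <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / stats::sd(x))
  p <- stats::pnorm(z)
  i <- seq_len(n)
  max(max(i / n - p), max(p - (i - 1) / n))
}

#' Lilliefors normality test with seeded Monte-Carlo p-value
#'
#' Kolmogorov-Smirnov statistic against a normal distribution with mean and
#' standard deviation estimated from the sample; the p-value is the fraction
#' of `lilliefors_mc_reps` seeded standard-normal samples of the same size
#' whose statistic is at least as large. A zero-variance sample is flagged
#' degenerate and treated as non-normal (`h = 1`).
#'
#' @param x Numeric sample (n >= 5 finite values).
#' @param config A [screening_config()].
#' @return List with `statistic`, `p_value`, `h` (1 = normality rejected at
#'   `normality_alpha`), `degenerate`.
#' @export
lilliefors_test <- function(x, config = screening_config()) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 5) stop("lilliefors_test requires n >= 5")
  if (stats::sd(x) == 0)
    return(list(statistic = NA_real_, p_value = 0, h = 1L, degenerate = TRUE))
  d <- .px_lillie_stat(x)
  key <- sprintf("n%d_r%d_s%d", n, config$lilliefors_mc_reps, config$seed)
  if (is.null(.px_lillie_cache[[key]])) {
    # isolate the cached null simulation from the caller's RNG stream
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(config$seed)
    null <- vapply(seq_len(config$lilliefors_mc_reps),
                   function(i) .px_lillie_stat(stats::rnorm(n)), numeric(1))
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, envir = globalenv())
    .px_lillie_cache[[key]] <- null
  }
  p <- mean(.px_lillie_cache[[key]] >= d)
  list(statistic = d, p_value = p,
       h = as.integer(p < config$normality_alpha), degenerate = FALSE)
}

# Exact null distribution of W+ given the (possibly tied, averaged) ranks:
# generating-function convolution over doubled ranks. Returns probabilities
# over W+ in half-rank units 0..sum(2r).
.px_signedrank_null <- function(ranks2) {
  tot <- sum(ranks2)
  pr <- c(1, rep(0, tot))
  for (r in ranks2) {
    shifted <- c(rep(0, r), pr[seq_len(tot + 1 - r)])
    pr <- 0.5 * (pr + shifted)
  }
  pr
}

#' Wilcoxon signed-rank test with tie-aware exact null
#'
#' Classic convention: zero differences are discarded before ranking; ties in
#' |d| receive average ranks. For n (non-zero differences) up to
#' `exact_limit` the two-sided p-value is computed from the exact conditional
#' null distribution of W+ given the observed ranks (which equals brute-force
#' enumeration over all 2^n sign assignments); beyond that, a normal
#' approximation with tie-corrected variance is used. Two-sided p =
#' min(1, 2 * min(P(W+ <= w), P(W+ >= w))). All differences zero gives the
#' degenerate convention p = 1.
#'
#' @param d Numeric vector of paired differences.
#' @param exact_limit Largest n for which the exact null is used (default 30).
#' @return List with `w_plus`, `w_minus`, `n_nonzero`, `p_value`, `exact`.
#' @export
signed_rank_test <- function(d, exact_limit = 30) {
  d <- d[is.finite(d)]
  nz <- d[d != 0]
  n <- length(nz)
  if (n == 0)
    return(list(w_plus = 0, w_minus = 0, n_nonzero = 0L, p_value = 1,
                exact = TRUE))
  r <- rank(abs(nz))
  w_plus <- sum(r[nz > 0])
  w_minus <- sum(r[nz < 0])
  if (n <= exact_limit) {
    ranks2 <- as.integer(round(2 * r))
    pr <- .px_signedrank_null(ranks2)
    w2 <- as.integer(round(2 * w_plus))
    p_le <- sum(pr[seq_len(w2 + 1)])
    p_ge <- sum(pr[(w2 + 1):length(pr)])
    p <- min(1, 2 * min(p_le, p_ge))
    list(w_plus = w_plus, w_minus = w_minus, n_nonzero = as.integer(n),
         p_value = p, exact = TRUE)
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (w_plus - mu) / sqrt(sigma2)
    list(w_plus = w_plus, w_minus = w_minus, n_nonzero = as.integer(n),
         p_value = min(1, 2 * stats::pnorm(-abs(z))), exact = FALSE)
  }
}

#' Paired Cohen's d
#'
#' `mean(d) / sd(d)` with the sample (n - 1) standard deviation; undefined
#' (NA) when the differences have zero spread.
#' @param d Numeric vector of paired differences (n >= 2).
#' @return Numeric scalar or NA.
#' @export
cohens_d_paired <- function(d) {
  d <- d[is.finite(d)]
  if (length(d) < 2) return(NA_real_)
  s <- stats::sd(d)
  if (s == 0) return(NA_real_)
  mean(d) / s
}

#' Matched-pairs rank-biserial correlation
#'
#' `(W+ - W-) / (W+ + W-)` over signed ranks of the non-zero differences
#' (average ranks under ties); undefined (NA) when all differences are zero.
#' @param d Numeric vector of paired differences.
#' @return Numeric scalar in `[-1, 1]` or NA.
#' @export
rank_biserial <- function(d) {
  d <- d[is.finite(d)]
  nz <- d[d != 0]
  if (length(nz) == 0) return(NA_real_)
  r <- rank(abs(nz))
  (sum(r[nz > 0]) - sum(r[nz < 0])) / sum(r)
}

#' Normality-gated paired screening of statistical features
#'
#' For each feature column of the paired-difference matrix: Lilliefors gate
#' on the differences (`h = 0` -> two-sided paired t-test + paired Cohen's d;
#' `h = 1` -> two-sided Wilcoxon signed-rank + rank-biserial r), significance
#' at `p < p_threshold`. Records for all features are returned; significant
#' features are ranked by |effect size| descending (ties: smaller p, then
#' feature name).
#'
#' @param D Numeric matrix, subjects x features, of paired differences
#'   (anxious minus calm), with feature column names.
#' @param config A [screening_config()].
#' @param min_n Minimum paired sample size per feature (default 5); features
#'   with fewer complete pairs get a missing p-value, never silently dropped.
#' @return Data frame with one row per feature: `feature`, `region`, `n`,
#'   `normality_h`, `test_used`, `p_value`, `effect_size`, `effect_type`,
#'   `significant`, `rank`.
#' @export
paired_screen <- function(D, config = screening_config(), min_n = 5) {
  stopifnot(is.matrix(D), !is.null(colnames(D)))
  nf <- ncol(D)
  rec <- data.frame(
    feature = colnames(D), region = feature_region(colnames(D)),
    n = NA_integer_, normality_h = NA_integer_, test_used = NA_character_,
    p_value = NA_real_, effect_size = NA_real_, effect_type = NA_character_,
    significant = FALSE, rank = NA_integer_, stringsAsFactors = FALSE)
  for (j in seq_len(nf)) {
    x <- D[, j]
    x <- x[is.finite(x)]
    rec$n[j] <- length(x)
    if (length(x) < min_n) next
    lt <- lilliefors_test(x, config)
    rec$normality_h[j] <- lt$h
    if (lt$h == 0) {
      rec$test_used[j] <- "paired_t"
      rec$p_value[j] <- stats::t.test(x)$p.value
      rec$effect_size[j] <- cohens_d_paired(x)
      rec$effect_type[j] <- "cohens_d"
    } else {
      rec$test_used[j] <- "wilcoxon_signed_rank"
      rec$p_value[j] <- signed_rank_test(x)$p_value
      rec$effect_size[j] <- rank_biserial(x)
      rec$effect_type[j] <- "rank_biserial_r"
    }
    rec$significant[j] <- is.finite(rec$p_value[j]) &&
      rec$p_value[j] < config$p_threshold
  }
  sig <- which(rec$significant)
  if (length(sig)) {
    o <- sig[order(-abs(rec$effect_size[sig]), rec$p_value[sig],
                   rec$feature[sig])]
    rec$rank[o] <- seq_along(o)
  }
  rec[order(is.na(rec$rank), rec$rank), , drop = FALSE]
}

#' Per-region counts and shares of significant features
#'
#' @param records Screening table from [paired_screen()].
#' @return Data frame `region`, `n_significant`, `share` (shares sum to 1
#'   over significant features); zero rows when nothing is significant.
#' @export
region_summary <- function(records) {
  sig <- records[records$significant & !is.na(records$region), ]
  if (nrow(sig) == 0)
    return(data.frame(region = character(), n_significant = integer(),
                      share = numeric()))
  tab <- table(factor(sig$region, levels = PX_REGIONS))
  out <- data.frame(region = names(tab), n_significant = as.integer(tab),
                    share = as.numeric(tab) / sum(tab), row.names = NULL)
  out[order(-out$n_significant), ]
}

#' Volcano table: effect size vs -log10 p per feature
#'
#' @param records Screening table from [paired_screen()].
#' @return Data frame `feature`, `region`, `effect_size`, `neg_log10_p`,
#'   `significant`, `missing` (TRUE where no p-value could be computed).
#' @export
volcano_table <- function(records) {
  data.frame(feature = records$feature, region = records$region,
             effect_size = records$effect_size,
             neg_log10_p = -log10(records$p_value),
             significant = records$significant,
             missing = !is.finite(records$p_value), row.names = NULL)
}

#' SAM manipulation check: paired Wilcoxon across the three dimensions
#'
#' Median and quartiles per condition plus the two-sided signed-rank p-value
#' of the paired calm-vs-anxious contrast, for valence, arousal and dominance.
#'
#' @param calm,anxious Data frames with columns `subject`, `valence`,
#'   `arousal`, `dominance`, paired by `subject`.
#' @return Data frame with one row per dimension.
#' @export
sam_validation <- function(calm, anxious) {
  m <- merge(calm, anxious, by = "subject", suffixes = c("_calm", "_anx"))
  if (nrow(m) == 0) stop("no subjects paired across conditions")
  dims <- c("valence", "arousal", "dominance")
  out <- lapply(dims, function(dm) {
    a <- m[[paste0(dm, "_calm")]]; b <- m[[paste0(dm, "_anx")]]
    qa <- stats::quantile(a, c(0.25, 0.5, 0.75), type = 1)
    qb <- stats::quantile(b, c(0.25, 0.5, 0.75), type = 1)
    data.frame(dimension = dm, n = nrow(m),
               median_calm = qa[2], q1_calm = qa[1], q3_calm = qa[3],
               median_anxious = qb[2], q1_anxious = qb[1], q3_anxious = qb[3],
               p_value = signed_rank_test(b - a)$p_value, row.names = NULL)
  })
  do.call(rbind, out)
}
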