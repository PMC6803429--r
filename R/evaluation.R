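#' Two-sample Kolmogorov-Smirnov statistic
#'
#' Exact `D = sup |F1 - F2|` between the empirical CDFs of two samples,
#' evaluated over the pooled support (ties handled exactly). Used as the
#' per-channel distance between replicate distributions.
#'
#' @param x,y Numeric vectors, non-empty.
#' @return `D` in \[0, 1\].
#' @export
ks_statistic <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  u <- sort(unique(c(x, y)))
  max(abs(stats::ecdf(x)(u) - stats::ecdf(y)(u)))
}

#' Mean pairwise KS consistency of replicates
#'
#' A single consistency score for one channel across an experiment: the
#' two-sample KS statistic is computed for every unordered pair of
#' replicate anchors and averaged. 0 means identical empirical
#' distributions, 1 maximal separation. Computed on raw intensities by
#' default — KS is invariant under strictly monotone transforms such as
#' arcsinh, so the exact value does not depend on the display space (it can
#' matter under subsampling, where the subsample is drawn before testing).
#'
#' @param replicate_values List of >= 2 numeric vectors (one per replicate).
#' @param subsample Optional integer: downsample each replicate to this many
#'   events without replacement before testing.
#' @param seed Seed for the subsampling draw (required when `subsample` is
#'   set).
#' @return Mean pairwise KS statistic in \[0, 1\].
#' @examples
#' ks_channel_consistency(list(c(0, 1), c(0, 1), c(10, 11)))  # 2/3
#' @export
ks_channel_consistency <- function(replicate_values, subsample = NULL, seed = NULL) {
  stopifnot(is.list(replicate_values))
  if (length(replicate_values) < 2L) {
    stop("at least two replicates are required", call. = FALSE)
  }
  stopifnot(all(lengths(replicate_values) >= 1))
  if (!is.null(subsample)) {
    if (is.null(seed)) stop("seed is required when subsampling", call. = FALSE)
    set.seed(seed)
    replicate_values <- lapply(replicate_values, function(v) {
      if (length(v) > subsample) sample(v, subsample) else v
    })
  }
  pairs <- utils::combn(length(replicate_values), 2)
  mean(apply(pairs, 2, function(ij) {
    ks_statistic(replicate_values[[ij[1]]], replicate_values[[ij[2]]])
  }))
}

as_feature_matrix <- function(x) {
  if (is.matrix(x)) {
    m <- x
  } else if (is.data.frame(x)) {
    num <- vapply(x, is.numeric, logical(1))
    m <- as.matrix(x[, num, drop = FALSE])
    ids <- x[[which(!num)[1]]]
    if (any(!num)) rownames(m) <- as.character(ids)
  } else {
    stop("expected a matrix or data frame of replicates x features", call. = FALSE)
  }
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("feature matrix must not contain missing values", call. = FALSE)
  m
}

#' Total variance of a replicate feature matrix
#'
#' The scalar dispersion measure used to compare replicate consistency pre-
#' and post-adjustment: the sum of the per-feature sample variances
#' (divisor n - 1) across replicates. This equals both the trace and the
#' eigenvalue sum of the features' covariance matrix, so it is invariant
#' under feature permutation and orthogonal rotation.
#'
#' @param x Replicates x features matrix, or a data frame whose numeric
#'   columns are the features (a non-numeric id column is used as row
#'   names).
#' @return Total variance (nonnegative scalar). Requires >= 2 replicates.
#' @examples
#' total_variance(rbind(c(1, 2), c(3, 4)))  # var(c(1,3)) + var(c(2,4)) = 4
#' @export
total_variance <- function(x) {
  m <- as_feature_matrix(x)
  if (nrow(m) < 2L) stop("total variance needs at least two replicates", call. = FALSE)
  sum(apply(m, 2, stats::var))
}

#' Permutation test for a change in total variance
#'
#' Tests whether adjustment reduced the total variance of a replicate
#' feature matrix (channel means or subpopulation fractions). The observed
#' statistic is `total_variance(post) - total_variance(pre)`. Under the
#' null of no systematic change, each replicate's pre/post labels are
#' exchangeable: for every subset of replicates, rows are swapped between
#' the two matrices and the change in total variance recomputed, giving the
#' null distribution. The p-value is the one-sided fraction of null changes
#' as small or smaller than the observed one (the "as or more extreme"
#' direction is a reduction). The identity assignment is included in the
#' null, so `p > 0` always; with `2^n` exact enumerations p is a multiple
#' of `2^-n`.
#'
#' All `2^n` sign assignments are enumerated when `n <= max_exact_n`;
#' otherwise `n_monte_carlo` seeded random assignments are drawn (always
#' including the identity). If the Monte-Carlo budget covers the full
#' assignment space it is enumerated exhaustively instead of sampled.
#'
#' @param pre,post Replicates x features matrices (or data frames), aligned
#'   row-by-row with identical shape.
#' @param max_exact_n Largest n for exact enumeration (default 20).
#' @param n_monte_carlo Number of random assignments beyond `max_exact_n`
#'   (default 10000).
#' @param seed Seed for the Monte-Carlo draw (required on that path).
#' @return An object of class `variance_perm_test`: `observed_delta`,
#'   `p_value`, `n_permutations`, `exact`, `null_deltas`, `n_replicates`.
#' @examples
#' pre <- rbind(c(0), c(10), c(20)); post <- rbind(c(10), c(10), c(10))
#' permutation_test_variance_change(pre, post)$p_value  # 0.25
#' @export
permutation_test_variance_change <- function(pre, post, max_exact_n = 20,
                                             n_monte_carlo = 10000, seed = NULL) {
  mpre <- as_feature_matrix(pre); mpost <- as_feature_matrix(post)
  if (!all(dim(mpre) == dim(mpost))) {
    stop("pre and post matrices must have identical shape", call. = FALSE)
  }
  if (!is.null(rownames(mpre)) && !is.null(rownames(mpost)) &&
      !identical(rownames(mpre), rownames(mpost))) {
    stop("pre and post replicate ids are not aligned", call. = FALSE)
  }
  n <- nrow(mpre)
  if (n < 2L) stop("at least two replicates are required", call. = FALSE)

  tv <- function(m) sum(apply(m, 2, stats::var))
  delta_for <- function(swap) {  # logical vector: rows whose labels are swapped
    p1 <- mpre; p2 <- mpost
    p1[swap, ] <- mpost[swap, , drop = FALSE]
    p2[swap, ] <- mpre[swap, , drop = FALSE]
    tv(p2) - tv(p1)
  }
  observed <- tv(mpost) - tv(mpre)

  exact <- n <= max_exact_n
  if (!exact && n <= 25 && n_monte_carlo >= 2^n) exact <- TRUE  # budget covers the space
  if (exact) {
    masks <- 0:(2^n - 1)
    null_deltas <- vapply(masks, function(m) {
      delta_for(as.logical(bitwAnd(m, 2^(0:(n - 1))) > 0))
    }, numeric(1))
  } else {
    if (is.null(seed)) stop("seed is required for the Monte-Carlo path", call. = FALSE)
    set.seed(seed)
    null_deltas <- c(observed,  # identity assignment always included
                     vapply(seq_len(n_monte_carlo - 1L), function(i) {
                       delta_for(stats::runif(n) < 0.5)
                     }, numeric(1)))
  }
  structure(list(observed_delta = observed,
                 p_value = mean(null_deltas <= observed),
                 n_permutations = length(null_deltas),
                 exact = exact, null_deltas = null_deltas,
                 n_replicates = n),
            class = "variance_perm_test")
}

#' @export
print.variance_perm_test <- function(x, ...) {
  cat(sprintf(paste0("Permutation test of change in total variance\n",
                     "  replicates: %d   permutations: %d (%s)\n",
                     "  observed delta: %.6g   one-sided p (reduction): %.6g\n"),
              x$n_replicates, x$n_permutations,
              if (x$exact) "exact" else "Monte Carlo",
              x$observed_delta, x$p_value))
  invisible(x)
}

#' @export
#' @importFrom generics tidy
#' @method tidy variance_perm_test
tidy.variance_perm_test <- function(x, ...) {
  tibble::tibble(observed_delta = x$observed_delta, p_value = x$p_value,
                 n_permutations = x$n_permutations, exact = x$exact,
                 n_replicates = x$n_replicates)
}

#' @export
#' @importFrom generics glance
#' @method glance variance_perm_test
glance.variance_perm_test <- function(x, ...) tidy(x)

#' @export
#' @importFrom ggplot2 autoplot
#' @method autoplot variance_perm_test
autoplot.variance_perm_test <- function(object, ...) {
  df <- tibble::tibble(delta = object$null_deltas)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta)) +
    ggplot2::geom_histogram(bins = min(60, max(10, object$n_permutations %/% 5)),
                            fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed_delta, colour = "red") +
    ggplot2::labs(x = "change in total variance (null permutations)", y = "count",
                  title = sprintf("Permutation null; observed delta = %.4g (p = %.4g)",
                                  object$observed_delta, object$p_value)) +
    ggplot2::theme_minimal()
}

#' Replicate x channel matrix of mean signal intensities
#'
#' Builds the feature matrix for the signal-intensity variance analysis:
#' one row per replicate (anchor), one column per channel, entries the mean
#' intensity over all cell events.
#'
#' @param tables List of [event_table()]s (the replicates).
#' @param channels Channel short names; every table must contain them all.
#' @return A tibble with `replicate_id` plus one numeric column per channel.
#' @export
channel_mean_matrix <- function(tables, channels) {
  stopifnot(length(tables) >= 1, all(vapply(tables, is_event_table, logical(1))))
  for (t in tables) {
    missing <- setdiff(channels, names(t))
    if (length(missing)) {
      stop("channels missing from '", et_sample_id(t), "': ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  purrr::map_dfr(tables, function(t) {
    means <- vapply(channels, function(ch) mean(t[[ch]]), numeric(1))
    tibble::as_tibble_row(c(list(replicate_id = et_sample_id(t)), as.list(means)))
  })
}

#' Replicate x channel matrix of positive-event fractions
#'
#' A fixed-threshold analog of applying reference-drawn gates unchanged to
#' every replicate: for each channel, the fraction of events above a fixed
#' intensity threshold. Thresholds are typically derived once from the
#' reference anchor (see `reference_thresholds()`) so that batch-driven
#' intensity shifts move events across the fixed cut — exactly the
#' mechanism by which batch effects distort gated population fractions.
#'
#' @param tables List of [event_table()]s.
#' @param thresholds Named numeric vector of per-channel thresholds.
#' @return A tibble with `replicate_id` plus one fraction column (in
#'   \[0, 1\]) per channel.
#' @export
positive_fraction_matrix <- function(tables, thresholds) {
  stopifnot(length(tables) >= 1, !is.null(names(thresholds)))
  channels <- names(thresholds)
  purrr::map_dfr(tables, function(t) {
    missing <- setdiff(channels, names(t))
    if (length(missing)) {
      stop("channels missing from '", et_sample_id(t), "': ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    fr <- vapply(channels, function(ch) mean(t[[ch]] > thresholds[[ch]]), numeric(1))
    tibble::as_tibble_row(c(list(replicate_id = et_sample_id(t)), as.list(fr)))
  })
}

#' Per-channel positivity thresholds from a reference anchor
#'
#' Convenience companion to [positive_fraction_matrix()]: the threshold for
#' each channel is a quantile of the reference anchor's intensities
#' (default the median), fixed once and applied to every replicate.
#'
#' @param reference_anchor An [event_table()].
#' @param channels Channel short names.
#' @param prob Quantile used as threshold (default 0.5).
#' @return Named numeric vector of thresholds.
#' @export
reference_thresholds <- function(reference_anchor, channels, prob = 0.5) {
  stopifnot(is_event_table(reference_anchor))
  vapply(stats::setNames(channels, channels), function(ch) {
    stats::quantile(reference_anchor[[ch]], prob, type = 7, names = FALSE)
  }, numeric(1))
}

#' Read or write a replicate feature matrix as CSV
#'
#' Fraction matrices produced by external gating (rows = replicates,
#' columns = populations, first column the replicate id) are accepted from
#' CSV; the gating itself is out of scope for this package.
#'
#' @param path CSV path.
#' @return A tibble with `replicate_id` plus numeric feature columns.
#' @export
read_feature_matrix <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  names(df)[1] <- "replicate_id"
  df$replicate_id <- as.character(df$replicate_id)
  tibble::as_tibble(df)
}

#' @rdname read_feature_matrix
#' @param x Feature matrix tibble.
#' @export
write_feature_matrix <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' Evaluation report for an adjustment run
#'
#' Bundles the package's validation statistics for a set of replicate
#' anchors pre- and post-adjustment: per-channel mean pairwise KS
#' consistency, pre/post total variance of channel means, and the
#' permutation test of the variance change. Written as CSV (per-channel
#' table) plus JSON (scalars) when `out_dir` is given.
#'
#' @param anchors_pre,anchors_post Lists of replicate [event_table()]s.
#' @param channels Channels to evaluate.
#' @param out_dir Optional output directory for `evaluation_channels.csv`
#'   and `evaluation_summary.json`.
#' @param max_exact_n,n_monte_carlo,seed Passed to
#'   [permutation_test_variance_change()].
#' @return A list: `per_channel` tibble (KS pre/post per channel),
#'   `total_variance_pre`, `total_variance_post`, `test`
#'   (`variance_perm_test`).
#' @export
evaluate_adjustment <- function(anchors_pre, anchors_post, channels,
                                out_dir = NULL, max_exact_n = 20,
                                n_monte_carlo = 10000, seed = NULL) {
  ks_of <- function(tabs, ch) ks_channel_consistency(lapply(tabs, `[[`, ch))
  per_channel <- tibble::tibble(
    channel = channels,
    ks_pre = vapply(channels, function(ch) ks_of(anchors_pre, ch), numeric(1)),
    ks_post = vapply(channels, function(ch) ks_of(anchors_post, ch), numeric(1)))
  pre_m <- channel_mean_matrix(anchors_pre, channels)
  post_m <- channel_mean_matrix(anchors_post, channels)
  test <- permutation_test_variance_change(pre_m, post_m, max_exact_n = max_exact_n,
                                           n_monte_carlo = n_monte_carlo, seed = seed)
  out <- list(per_channel = per_channel,
              total_variance_pre = total_variance(pre_m),
              total_variance_post = total_variance(post_m),
              test = test)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(per_channel, file.path(out_dir, "evaluation_channels.csv"))
    jsonlite::write_json(
      list(total_variance_pre = out$total_variance_pre,
           total_variance_post = out$total_variance_post,
           observed_delta = test$observed_delta, p_value = test$p_value,
           n_permutations = test$n_permutations, exact = test$exact,
           seed = seed),
      file.path(out_dir, "evaluation_summary.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}
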