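#' Adjustment configuration
#'
#' Bundles every knob of the anchor-based batch adjustment: the summary
#' statistic used to calibrate scale factors (or `"quantile_norm"` for a
#' full quantile map), the data space in which factors are computed and
#' applied, and the channel selection.
#'
#' @param method One of `"percentile"`, `"mean"`, `"median"`, `"sd"`,
#'   `"quantile_norm"`. Percentile scaling at the 95th (default) and 80th
#'   percentiles are the settings of primary practical interest: the high
#'   percentile avoids outliers, and the low one stays well-defined in
#'   channels where more than half of the events are zero.
#' @param percentile_p Percentile in (0, 100), used when
#'   `method = "percentile"`. Default 95.
#' @param space `"raw"` (untransformed ion counts; factors act linearly) or
#'   `"arcsinh"` (factors computed and applied on `asinh(x / cofactor)`,
#'   which is non-linear back in ion-count space).
#' @param cofactor Positive arcsinh cofactor; default 5, the mass-cytometry
#'   convention.
#' @param reference_batch Batch id of the designated reference batch; its
#'   samples are never modified.
#' @param channels Character vector of channel short names to adjust.
#' @param skip_on_zero_stat If `TRUE` (default), a channel whose anchor
#'   statistic is zero in either the batch or the reference anchor is left
#'   unadjusted and the reason is recorded, rather than dividing by zero.
#'   This is the `>50%` zero-event median pathology.
#' @param n_knots Number of quantile knots for `method = "quantile_norm"`
#'   (clamped to the smaller anchor's event count). Default 10001.
#' @param qn_zero_handling `"ecdf"` (default): plain empirical-quantile
#'   mapping over all events including zeros, which reproduces the known
#'   zero-inflation/squashing artifact when zero masses differ between
#'   anchors; `"preserve"`: zeros map to zeros and only positive values are
#'   quantile-mapped.
#'
#' @return A list of class `adjustment_config`.
#' @export
adjustment_config <- function(method = c("percentile", "mean", "median", "sd", "quantile_norm"),
                              percentile_p = 95, space = c("raw", "arcsinh"),
                              cofactor = 5, reference_batch, channels,
                              skip_on_zero_stat = TRUE, n_knots = 10001,
                              qn_zero_handling = c("ecdf", "preserve")) {
  method <- match.arg(method)
  space <- match.arg(space)
  qn_zero_handling <- match.arg(qn_zero_handling)
  stopifnot(is.numeric(percentile_p), length(percentile_p) == 1,
            percentile_p > 0, percentile_p < 100,
            is.numeric(cofactor), cofactor > 0,
            is.character(channels), length(channels) >= 1,
            n_knots >= 2)
  structure(list(method = method, percentile_p = percentile_p, space = space,
                 cofactor = cofactor, reference_batch = as.character(reference_batch),
                 channels = channels, skip_on_zero_stat = isTRUE(skip_on_zero_stat),
                 n_knots = as.integer(n_knots), qn_zero_handling = qn_zero_handling),
            class = "adjustment_config")
}

#' @export
print.adjustment_config <- function(x, ...) {
  m <- if (x$method == "percentile") sprintf("percentile(%g)", x$percentile_p) else x$method
  cat(sprintf("<adjustment_config> method=%s space=%s cofactor=%g reference=%s channels=%d\n",
              m, x$space, x$cofactor, x$reference_batch, length(x$channels)))
  invisible(x)
}

#' Per-channel summary statistic
#'
#' The descriptive statistic of one channel's event intensities used to
#' calibrate a scale factor. Computed over all events, including
#' zero-valued ones. Percentiles interpolate linearly between order
#' statistics at rank `1 + (n - 1) * p / 100`; the standard deviation uses
#' divisor `n - 1`. A constant vector has sd 0 (the caller decides whether
#' that means skipping the channel).
#'
#' @param values Nonnegative numeric vector, non-empty.
#' @param method `"percentile"`, `"mean"`, `"median"`, or `"sd"`.
#' @param percentile_p Percentile in (0, 100) when `method = "percentile"`.
#' @return A single number.
#' @examples
#' channel_statistic(c(0, 0, 0, 10), "median")   # 0: >50% zeros
#' channel_statistic(1:100, "percentile", 95)    # 95.05
#' @export
channel_statistic <- function(values, method = c("percentile", "mean", "median", "sd"),
                              percentile_p = 95) {
  method <- match.arg(method)
  if (length(values) == 0L) stop("cannot compute a statistic of an empty vector", call. = FALSE)
  switch(method,
         percentile = stats::quantile(values, percentile_p / 100, type = 7, names = FALSE),
         mean = mean(values),
         median = stats::median(values),
         sd = stats::sd(values))
}

# skip-signal: a channel deliberately left unadjusted, with the reason
skip_signal <- function(reason) structure(list(reason = reason), class = "anchornorm_skip")

#' Test for a skip signal
#'
#' [compute_scale_factor()] returns a skip signal instead of a factor when a
#' channel cannot be calibrated (zero anchor statistic) and
#' `skip_on_zero_stat` is set; the `reason` field says why.
#'
#' @param x Object.
#' @return Logical.
#' @export
is_skip_signal <- function(x) inherits(x, "anchornorm_skip")

#' Scale factor from an anchor pair
#'
#' The per-channel adjustment factor is the ratio of a summary statistic of
#' the reference anchor to the same statistic of the batch anchor:
#' `factor = stat(reference) / stat(batch)`. Multiplying the batch's events
#' by this factor aligns the batch anchor's statistic with the reference's.
#' In `space = "arcsinh"` both vectors are transformed with
#' `asinh(x / cofactor)` before the statistic is taken.
#'
#' @param ref_anchor_values Reference-anchor channel values.
#' @param batch_anchor_values Batch-anchor channel values.
#' @param config An [adjustment_config()] with a scale method (not
#'   `"quantile_norm"`).
#' @return A positive scale factor, or a skip-signal object (see
#'   [is_skip_signal()]) when either statistic is zero and
#'   `skip_on_zero_stat` is set. A zero statistic with
#'   `skip_on_zero_stat = FALSE` is an error.
#' @export
compute_scale_factor <- function(ref_anchor_values, batch_anchor_values, config) {
  stopifnot(inherits(config, "adjustment_config"))
  if (config$method == "quantile_norm") {
    stop("compute_scale_factor() is for scale methods; use build_quantile_map()", call. = FALSE)
  }
  r <- ref_anchor_values; b <- batch_anchor_values
  if (config$space == "arcsinh") {
    r <- asinh(r / config$cofactor)
    b <- asinh(b / config$cofactor)
  }
  sr <- channel_statistic(r, config$method, config$percentile_p)
  sb <- channel_statistic(b, config$method, config$percentile_p)
  if (sr == 0 || sb == 0) {
    reason <- sprintf("%s statistic is zero in %s anchor",
                      config$method, if (sb == 0) "batch" else "reference")
    if (config$skip_on_zero_stat) return(skip_signal(reason))
    stop(reason, call. = FALSE)
  }
  f <- sr / sb
  if (!is.finite(f) || f <= 0) stop("non-finite or non-positive scale factor", call. = FALSE)
  f
}

#' Apply a scale factor to event values
#'
#' In raw space the adjustment is elementwise multiplication. In arcsinh
#' space the factor multiplies the transformed values and the result is
#' mapped back: `cofactor * sinh(factor * asinh(v / cofactor))`, which is a
#' non-linear monotone adjustment in ion-count space. Both paths preserve
#' event rank order, keep zeros at zero, and keep nonnegative inputs
#' nonnegative.
#'
#' @param values Nonnegative numeric vector.
#' @param factor Positive finite scale factor.
#' @param space `"raw"` or `"arcsinh"`.
#' @param cofactor Positive arcsinh cofactor (used for `space = "arcsinh"`).
#' @return Adjusted numeric vector.
#' @export
apply_scale <- function(values, factor, space = c("raw", "arcsinh"), cofactor = 5) {
  space <- match.arg(space)
  stopifnot(is.numeric(factor), length(factor) == 1, is.finite(factor), factor > 0)
  if (space == "raw") values * factor
  else cofactor * sinh(factor * asinh(values / cofactor))
}

#' Build a quantile map between two anchors
#'
#' Constructs the monotone piecewise-linear map that carries the batch
#' anchor's empirical distribution onto the reference anchor's: both
#' distributions are summarized by quantiles on a common evenly spaced
#' probability grid, and values are mapped source-quantile to
#' target-quantile. Applying the map to the batch anchor itself makes its
#' empirical distribution match the reference's up to knot resolution.
#'
#' With `zero_handling = "ecdf"` (default) the map is built over all events
#' including zeros, so a surplus of zeros in the batch anchor is inflated to
#' positive reference values (or, conversely, the lowest nonzero batch
#' values are squashed to zero) — the documented artifact of per-channel
#' quantile normalization on zero-inflated ion counts. With `"preserve"`,
#' zeros map to zeros and only the positive parts are matched.
#'
#' @param ref_anchor_values Reference-anchor channel values (target).
#' @param batch_anchor_values Batch-anchor channel values (source).
#' @param n_knots Number of quantile knots (>= 2); clamped to the smaller
#'   anchor's event count.
#' @param zero_handling `"ecdf"` or `"preserve"`.
#' @return A `quantile_map` object with fields `source_knots`,
#'   `target_knots`, `zero_handling`.
#' @export
build_quantile_map <- function(ref_anchor_values, batch_anchor_values,
                               n_knots = 10001, zero_handling = c("ecdf", "preserve")) {
  zero_handling <- match.arg(zero_handling)
  stopifnot(length(ref_anchor_values) >= 1, length(batch_anchor_values) >= 1, n_knots >= 2)
  r <- ref_anchor_values; b <- batch_anchor_values
  if (zero_handling == "preserve") {
    r <- r[r > 0]; b <- b[b > 0]
    if (length(r) == 0L || length(b) == 0L) {
      # nothing positive to match; identity on the positive part
      r <- b <- c(0, 1)
    }
  }
  k <- max(2L, min(as.integer(n_knots), length(r), length(b)))
  probs <- seq(0, 1, length.out = k)
  source_knots <- cummax(stats::quantile(b, probs, type = 7, names = FALSE))
  target_knots <- cummax(stats::quantile(r, probs, type = 7, names = FALSE))
  structure(list(source_knots = source_knots, target_knots = target_knots,
                 zero_handling = zero_handling),
            class = "quantile_map")
}

#' @export
print.quantile_map <- function(x, ...) {
  cat(sprintf("<quantile_map> %d knots, source [%g, %g] -> target [%g, %g], zeros: %s\n",
              length(x$source_knots), min(x$source_knots), max(x$source_knots),
              min(x$target_knots), max(x$target_knots), x$zero_handling))
  invisible(x)
}

#' Apply a quantile map
#'
#' Piecewise-linear interpolation through the map's knots. Inputs below or
#' above the knot range clamp to the first or last target knot. Where
#' several source knots coincide (a probability mass, typically at zero),
#' the value maps to the highest corresponding target — the empirical-CDF
#' convention `Q_ref(F_batch(x))`. The map is monotone nondecreasing, so
#' event rank order is preserved (ties allowed).
#'
#' @param values Numeric vector.
#' @param map A `quantile_map` from [build_quantile_map()].
#' @return Mapped numeric vector, nonnegative whenever the target knots are.
#' @export
apply_quantile_map <- function(values, map) {
  stopifnot(inherits(map, "quantile_map"))
  src <- map$source_knots; tgt <- map$target_knots
  out <- numeric(length(values))
  pos <- rep(TRUE, length(values))
  if (map$zero_handling == "preserve") {
    pos <- values > 0
    out[!pos] <- 0
    if (!any(pos)) return(out)
  }
  if (length(unique(src)) < 2L) {
    out[pos] <- tgt[length(tgt)]
    return(out)
  }
  out[pos] <- stats::approx(src, tgt, xout = values[pos], method = "linear",
                            rule = 2, ties = max)$y
  out
}

#' Calibrate all channel adjustments for one batch
#'
#' Computes one adjustment per configured channel from the batch anchor /
#' reference anchor pair: a scale factor for the scale methods, a quantile
#' map for `method = "quantile_norm"`, or a skip record when a statistic is
#' zero. For the reference batch itself every factor is exactly 1 (identity
#' map for quantile normalization).
#'
#' @param ref_anchor Reference-batch anchor [event_table()].
#' @param batch_anchor Anchor of the batch being calibrated.
#' @param config [adjustment_config()].
#' @return A tibble of class `scale_factors` with one row per channel:
#'   `batch_id`, `channel`, `method`, `space`, `type`
#'   (`"factor"`/`"quantile_map"`/`"skipped"`), `factor`, `reason`, and a
#'   `qmap` list-column holding `quantile_map` objects.
#' @export
compute_batch_factors <- function(ref_anchor, batch_anchor, config) {
  stopifnot(is_event_table(ref_anchor), is_event_table(batch_anchor),
            inherits(config, "adjustment_config"))
  missing <- setdiff(config$channels, names(batch_anchor))
  if (length(missing)) {
    stop("channels missing from anchor '", et_sample_id(batch_anchor), "': ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  is_ref <- identical(et_batch_id(batch_anchor), config$reference_batch)
  rows <- purrr::map(config$channels, function(ch) {
    rv <- ref_anchor[[ch]]; bv <- batch_anchor[[ch]]
    if (config$method == "quantile_norm") {
      qm <- if (is_ref) {
        knots <- cummax(stats::quantile(rv, seq(0, 1, length.out = min(config$n_knots, length(rv))),
                                        type = 7, names = FALSE))
        structure(list(source_knots = knots, target_knots = knots,
                       zero_handling = config$qn_zero_handling), class = "quantile_map")
      } else {
        build_quantile_map(rv, bv, n_knots = config$n_knots,
                           zero_handling = config$qn_zero_handling)
      }
      tibble::tibble(channel = ch, type = "quantile_map", factor = NA_real_,
                     reason = NA_character_, qmap = list(qm))
    } else {
      f <- if (is_ref) 1 else compute_scale_factor(rv, bv, config)
      if (is_skip_signal(f)) {
        tibble::tibble(channel = ch, type = "skipped", factor = NA_real_,
                       reason = f$reason, qmap = list(NULL))
      } else {
        tibble::tibble(channel = ch, type = "factor", factor = f,
                       reason = NA_character_, qmap = list(NULL))
      }
    }
  })
  out <- dplyr::bind_rows(rows)
  out <- tibble::add_column(out,
                            batch_id = et_batch_id(batch_anchor),
                            method = config$method, space = config$space,
                            .before = 1)
  class(out) <- c("scale_factors", class(out))
  out
}

#' Adjust one sample with calibrated batch factors
#'
#' Applies a batch's calibrated per-channel adjustments (from
#' [compute_batch_factors()]) to an event table. Channels outside the
#' configured selection are untouched; skipped channels are left unadjusted
#' and flagged in the provenance keywords; samples from the reference batch
#' are returned with data identical to the input.
#'
#' @param table [event_table()] belonging to `record`'s batch.
#' @param record `scale_factors` tibble for that batch.
#' @param config [adjustment_config()].
#' @return The adjusted [event_table()], with `ANCHORNORM_ADJ_*` provenance
#'   keywords describing what was done per channel.
#' @export
adjust_sample <- function(table, record, config) {
  stopifnot(is_event_table(table), inherits(record, "scale_factors"),
            inherits(config, "adjustment_config"))
  if (!identical(unique(record$batch_id), et_batch_id(table))) {
    stop("record batch '", unique(record$batch_id), "' does not match sample batch '",
         et_batch_id(table), "' (", et_sample_id(table), ")", call. = FALSE)
  }
  missing <- setdiff(record$channel, names(table))
  if (length(missing)) {
    stop("channels missing from sample '", et_sample_id(table), "': ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  kw <- et_keywords(table)
  kw[["ANCHORNORM_ADJ_METHOD"]] <- config$method
  kw[["ANCHORNORM_ADJ_SPACE"]] <- config$space
  kw[["ANCHORNORM_ADJ_REFERENCE"]] <- config$reference_batch
  if (identical(et_batch_id(table), config$reference_batch)) {
    kw[["ANCHORNORM_ADJ_STATUS"]] <- "reference batch: unmodified"
    attr(table, "keywords") <- kw
    return(table)
  }
  data <- as.data.frame(table)
  for (i in seq_len(nrow(record))) {
    ch <- record$channel[i]
    key <- paste0("ANCHORNORM_ADJ_", ch)
    if (record$type[i] == "factor") {
      data[[ch]] <- apply_scale(data[[ch]], record$factor[i], config$space, config$cofactor)
      kw[[key]] <- sprintf("factor=%.10g", record$factor[i])
    } else if (record$type[i] == "quantile_map") {
      data[[ch]] <- apply_quantile_map(data[[ch]], record$qmap[[i]])
      kw[[key]] <- "quantile_map"
    } else {
      kw[[key]] <- paste0("skipped: ", record$reason[i])
    }
  }
  et_set_data(table, data, keywords = kw)
}
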