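#' Define a cell population for the synthetic generator
#'
#' One mixture component of the synthetic cell model. Each channel's
#' intensity is zero-inflated log-normal: an event is exactly zero with
#' probability `zero_prob` (the ion-count zero phenomenon), otherwise drawn
#' from `rlnorm(meanlog, sdlog)` — right-skewed, nonnegative, a qualitative
#' stand-in for CyTOF marginals.
#'
#' @param name Population name.
#' @param weight Mixture weight in (0, 1); weights across populations must
#'   sum to 1.
#' @param channels Tibble with columns `channel`, `zero_prob` (in \[0, 1)),
#'   `meanlog`, `sdlog`.
#' @return A list of class `population_spec`.
#' @export
population_spec <- function(name, weight, channels) {
  stopifnot(is.character(name), weight > 0, weight <= 1,
            all(c("channel", "zero_prob", "meanlog", "sdlog") %in% names(channels)),
            all(channels$zero_prob >= 0), all(channels$zero_prob < 1),
            all(channels$sdlog > 0))
  structure(list(name = name, weight = weight,
                 channels = tibble::as_tibble(channels)),
            class = "population_spec")
}

#' A deterministic example cell panel
#'
#' Builds a small set of populations over `n_channels` channels with
#' distinct per-population intensity profiles and channel-dependent zero
#' fractions, deterministic in its arguments (no randomness). Useful as a
#' realistic default input to [generate_experiment()].
#'
#' @param n_channels Number of channels (default 20).
#' @param n_populations Number of populations (default 3).
#' @param zero_prob_range Range of per-channel zero probabilities spread
#'   evenly across channels (default `c(0.05, 0.4)`).
#' @return List of [population_spec()]s with weights proportional to
#'   `n_populations:1`.
#' @export
example_populations <- function(n_channels = 20, n_populations = 3,
                                zero_prob_range = c(0.05, 0.4)) {
  channels <- sprintf("Ch%02d", seq_len(n_channels))
  zp <- seq(zero_prob_range[1], zero_prob_range[2], length.out = n_channels)
  w <- rev(seq_len(n_populations)); w <- w / sum(w)
  lapply(seq_len(n_populations), function(p) {
    population_spec(
      name = sprintf("pop%d", p), weight = w[p],
      channels = tibble::tibble(
        channel = channels,
        zero_prob = zp,
        # population-specific expression profile: phase-shifted across channels
        meanlog = 2 + 1.2 * sin(seq_len(n_channels) / 3 + p),
        sdlog = 0.5))
  })
}

#' Define per-batch, per-channel batch effects
#'
#' A batch effect is a multiplicative intensity distortion (`multiplier`)
#' plus an optional additive perturbation of the zero-event probability
#' (`zero_shift`, applied to every population's `zero_prob` and clipped to
#' \[0, 1)). The reference batch must be the identity (multiplier 1, shift
#' 0); [generate_experiment()] treats unlisted (batch, channel) pairs as
#' identity.
#'
#' @param effects Tibble with columns `batch_id`, `channel`, `multiplier`
#'   (> 0) and optionally `zero_shift`.
#' @return A tibble of class `batch_effect_spec`.
#' @export
batch_effect_spec <- function(effects) {
  stopifnot(all(c("batch_id", "channel", "multiplier") %in% names(effects)),
            all(effects$multiplier > 0))
  effects <- tibble::as_tibble(effects)
  if (!"zero_shift" %in% names(effects)) effects$zero_shift <- 0
  effects$batch_id <- as.character(effects$batch_id)
  class(effects) <- c("batch_effect_spec", class(effects))
  effects
}

#' Generate a synthetic multi-batch CyTOF-like experiment
#'
#' Emulates the structure of a barcoded multi-batch study: every batch
#' contains one anchor (a technical replicate drawn from the same
#' population mixture in every batch) plus study samples, all distorted by
#' the batch's injected effects. Study samples get mildly perturbed mixture
#' weights (biological variability); anchors never do. Optionally a second
#' replicate per batch is generated (`validation_anchors`) with `role =
#' "study"` and `condition = "validation"` — the analog of an unstimulated
#' anchor set that is adjusted with factors calibrated on the designated
#' anchors and then used to validate the adjustment.
#'
#' Fully reproducible: the same arguments and seed give byte-identical
#' event data.
#'
#' @param populations List of [population_spec()]s (weights summing to 1).
#' @param effects A [batch_effect_spec()] (or a tibble coercible to one).
#' @param n_batches Number of batches (>= 2); batch ids are `"B01"`,
#'   `"B02"`, ... and `"B01"` is the natural reference. Default 12, the
#'   scale of a typical barcoded study.
#' @param events_per_sample Events per file (>= 100). Default 10000.
#' @param samples_per_batch Study samples per batch in addition to the
#'   anchor (default 1).
#' @param seed Integer seed.
#' @param validation_anchors If `TRUE`, add one validation replicate per
#'   batch (see above).
#' @param study_weight_noise Log-normal sd of the study samples' mixture
#'   weight perturbation (default 0.1).
#' @return A list with `tables` (named list of [event_table()]s) and
#'   `truth` (a `synthetic_truth` object: the specs, seed, and per-file
#'   realized population fractions).
#' @export
generate_experiment <- function(populations, effects, n_batches = 12,
                                events_per_sample = 10000, samples_per_batch = 1,
                                seed = 1, validation_anchors = FALSE,
                                study_weight_noise = 0.1) {
  stopifnot(n_batches >= 2, events_per_sample >= 100, samples_per_batch >= 1)
  if (!inherits(effects, "batch_effect_spec")) effects <- batch_effect_spec(effects)
  w <- vapply(populations, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-8) stop("population weights must sum to 1", call. = FALSE)
  channels <- populations[[1]]$channels$channel
  for (p in populations) stopifnot(identical(p$channels$channel, channels))
  bad <- setdiff(effects$channel, channels)
  if (length(bad)) stop("batch effects name unknown channels: ",
                        paste(bad, collapse = ", "), call. = FALSE)

  batch_ids <- sprintf("B%02d", seq_len(n_batches))
  bad_b <- setdiff(effects$batch_id, batch_ids)
  if (length(bad_b)) stop("batch effects name unknown batches: ",
                          paste(bad_b, collapse = ", "), call. = FALSE)
  ref_fx <- effects[effects$batch_id == batch_ids[1], ]
  if (any(ref_fx$multiplier != 1 | ref_fx$zero_shift != 0)) {
    stop("the reference batch ", batch_ids[1], " must have identity effects", call. = FALSE)
  }

  effect_of <- function(b, ch) {
    row <- effects[effects$batch_id == b & effects$channel == ch, ]
    if (nrow(row) == 0) c(multiplier = 1, zero_shift = 0)
    else c(multiplier = row$multiplier[1], zero_shift = row$zero_shift[1])
  }

  set.seed(seed)
  pop_names <- vapply(populations, `[[`, character(1), "name")
  tables <- list()
  truth_rows <- list()

  draw_sample <- function(sample_id, batch_id, role, condition, weights) {
    assignment <- sample.int(length(populations), events_per_sample,
                             replace = TRUE, prob = weights)
    mat <- matrix(0, nrow = events_per_sample, ncol = length(channels),
                  dimnames = list(NULL, channels))
    for (ci in seq_along(channels)) {
      fx <- effect_of(batch_id, channels[ci])
      for (pi in seq_along(populations)) {
        idx <- which(assignment == pi)
        if (!length(idx)) next
        spec <- populations[[pi]]$channels[ci, ]
        zp <- min(max(spec$zero_prob + fx[["zero_shift"]], 0), 1 - 1e-9)
        nonzero <- stats::runif(length(idx)) >= zp
        vals <- numeric(length(idx))
        vals[nonzero] <- stats::rlnorm(sum(nonzero), spec$meanlog, spec$sdlog) *
          fx[["multiplier"]]
        mat[idx, ci] <- vals
      }
    }
    fractions <- as.numeric(tabulate(assignment, length(populations))) / events_per_sample
    truth_rows[[length(truth_rows) + 1L]] <<- tibble::tibble(
      sample_id = sample_id, batch_id = batch_id, role = role,
      condition = condition, n_events = events_per_sample,
      population = pop_names, fraction = fractions)
    event_table(mat, sample_id = sample_id, batch_id = batch_id,
                role = role, condition = condition)
  }

  for (b in batch_ids) {
    aid <- sprintf("%s_anchor", b)
    tables[[aid]] <- draw_sample(aid, b, "anchor", NA_character_, w)
    if (isTRUE(validation_anchors)) {
      vid <- sprintf("%s_validation", b)
      tables[[vid]] <- draw_sample(vid, b, "study", "validation", w)
    }
    for (s in seq_len(samples_per_batch)) {
      sid <- sprintf("%s_s%02d", b, s)
      ws <- w * stats::rlnorm(length(w), 0, study_weight_noise)
      ws <- ws / sum(ws)
      tables[[sid]] <- draw_sample(sid, b, "study", NA_character_, ws)
    }
  }

  truth <- structure(list(populations = populations, effects = effects,
                          seed = seed, n_batches = n_batches,
                          events_per_sample = events_per_sample,
                          batch_ids = batch_ids,
                          files = dplyr::bind_rows(truth_rows)),
                     class = "synthetic_truth")
  list(tables = tables, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %d batches, %d files, %d events/sample, seed=%d\n",
              x$n_batches, length(unique(x$files$sample_id)),
              x$events_per_sample, x$seed))
  invisible(x)
}

#' Realized population-fraction matrix from synthetic truth
#'
#' The ground-truth counterpart of a gated subpopulation fraction matrix:
#' rows are the selected files (replicates), columns the populations,
#' entries the realized (sampled) fractions recorded at generation time.
#'
#' @param truth A `synthetic_truth` from [generate_experiment()].
#' @param role_filter `"anchor"`, `"validation"`, `"study"` (study samples
#'   excluding validation replicates), or `"all"`.
#' @return A tibble with `replicate_id` plus one fraction column per
#'   population.
#' @export
true_fraction_matrix <- function(truth,
                                 role_filter = c("anchor", "validation", "study", "all")) {
  role_filter <- match.arg(role_filter)
  stopifnot(inherits(truth, "synthetic_truth"))
  df <- truth$files
  df <- switch(role_filter,
               anchor = df[df$role == "anchor", ],
               validation = df[!is.na(df$condition) & df$condition == "validation", ],
               study = df[df$role == "study" &
                            (is.na(df$condition) | df$condition != "validation"), ],
               all = df)
  out <- tidyr::pivot_wider(df[, c("sample_id", "population", "fraction")],
                            names_from = "population", values_from = "fraction")
  names(out)[1] <- "replicate_id"
  out
}

#' Write a generated experiment to FCS files
#'
#' Convenience wrapper: writes every generated table as
#' `<out_dir>/<sample_id>.fcs` plus the truth (specs, seed, realized
#' fractions) as JSON, and returns a [read_batch_manifest()]-compatible
#' manifest tibble.
#'
#' @param experiment Result of [generate_experiment()].
#' @param out_dir Output directory.
#' @return The `batch_manifest` tibble, invisibly.
#' @export
write_experiment_fcs <- function(experiment, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- purrr::map(names(experiment$tables), function(id) {
    t <- experiment$tables[[id]]
    p <- file.path(out_dir, paste0(id, ".fcs"))
    write_fcs(t, p)
    tibble::tibble(file_path = p, batch_id = et_batch_id(t),
                   role = et_role(t), condition = et_condition(t))
  })
  truth <- experiment$truth
  jsonlite::write_json(
    list(seed = truth$seed, n_batches = truth$n_batches,
         events_per_sample = truth$events_per_sample,
         effects = truth$effects, files = truth$files),
    file.path(out_dir, "synthetic_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(validate_manifest(dplyr::bind_rows(rows)))
}
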