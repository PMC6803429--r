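#' Write calibrated factors to disk
#'
#' Persists a `scale_factors` table (one or several batches bound together)
#' as a plain CSV of per-channel entries. Quantile maps cannot be expressed
#' as a single number, so their knots go to a sidecar CSV
#' (`<stem>_qn_knots.csv`, columns `batch_id`, `channel`, `knot`, `source`,
#' `target`); the main table marks those rows `"QN"`.
#'
#' @param record A `scale_factors` tibble (see [compute_batch_factors()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @seealso [read_scale_factors()]
#' @export
write_scale_factors <- function(record, path) {
  stopifnot(inherits(record, "scale_factors"))
  flat <- tibble::as_tibble(record[setdiff(names(record), "qmap")])
  flat$factor_or_qn <- ifelse(record$type == "quantile_map", "QN",
                              ifelse(record$type == "skipped", "skipped",
                                     format(record$factor, digits = 17)))
  flat$skipped <- record$type == "skipped"
  flat <- flat[, c("batch_id", "channel", "method", "space",
                   "factor_or_qn", "skipped", "reason")]
  readr::write_csv(flat, path, na = "")
  has_qn <- which(record$type == "quantile_map")
  if (length(has_qn)) {
    knots <- purrr::map_dfr(has_qn, function(i) {
      qm <- record$qmap[[i]]
      tibble::tibble(batch_id = record$batch_id[i], channel = record$channel[i],
                     zero_handling = qm$zero_handling,
                     knot = seq_along(qm$source_knots),
                     source = qm$source_knots, target = qm$target_knots)
    })
    readr::write_csv(knots, .qn_sidecar_path(path))
  }
  invisible(path)
}

.qn_sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), "_qn_knots.csv")
}

#' Read calibrated factors back from disk
#'
#' Inverse of [write_scale_factors()]: reconstructs the `scale_factors`
#' tibble, re-attaching quantile maps from the knot sidecar when present.
#'
#' @param path CSV path written by [write_scale_factors()].
#' @return A `scale_factors` tibble.
#' @export
read_scale_factors <- function(path) {
  flat <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            batch_id = readr::col_character(),
                            channel = readr::col_character(),
                            method = readr::col_character(),
                            space = readr::col_character(),
                            factor_or_qn = readr::col_character(),
                            skipped = readr::col_logical(),
                            reason = readr::col_character()))
  sidecar <- .qn_sidecar_path(path)
  knots <- if (file.exists(sidecar)) {
    readr::read_csv(sidecar, show_col_types = FALSE)
  } else NULL
  out <- tibble::tibble(
    batch_id = flat$batch_id, channel = flat$channel,
    method = flat$method, space = flat$space,
    type = ifelse(flat$skipped, "skipped",
                  ifelse(flat$factor_or_qn == "QN", "quantile_map", "factor")),
    factor = suppressWarnings(as.numeric(ifelse(flat$factor_or_qn %in% c("QN", "skipped"),
                                                NA, flat$factor_or_qn))),
    reason = flat$reason,
    qmap = purrr::map2(flat$batch_id, flat$channel, function(b, ch) {
      if (is.null(knots)) return(NULL)
      k <- knots[knots$batch_id == b & knots$channel == ch, ]
      if (nrow(k) == 0) return(NULL)
      structure(list(source_knots = k$source, target_knots = k$target,
                     zero_handling = k$zero_handling[1]), class = "quantile_map")
    }))
  class(out) <- c("scale_factors", class(out))
  out
}

#' @export
#' @importFrom generics tidy
#' @method tidy scale_factors
tidy.scale_factors <- function(x, ...) {
  tibble::as_tibble(x[, c("batch_id", "channel", "method", "space",
                          "type", "factor", "reason")])
}
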