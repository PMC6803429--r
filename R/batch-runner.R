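#' Build a batch manifest from filenames
#'
#' Scans a directory of FCS files and assembles the batch manifest that
#' [run_adjustment()] consumes. The batch id is taken from the first
#' capture group of `batch_pattern` applied to the file name; files whose
#' name contains `anchor_token` (case-insensitive) are the calibration
#' anchors. Every batch must contain exactly one anchor. Files not matching
#' `batch_pattern` are excluded with a warning. Ordering is lexicographic,
#' so discovery is deterministic.
#'
#' An explicit CSV manifest ([read_batch_manifest()]) is the primary,
#' unambiguous interface; filename discovery is a convenience for datasets
#' that follow a strict naming convention.
#'
#' @param directory Directory containing `.fcs` files.
#' @param anchor_token Substring marking anchor files (default `"anchor"`).
#' @param batch_pattern Regular expression with one capture group yielding
#'   the batch id (default `"Barcode(\\d+)"`).
#' @return A `batch_manifest` tibble with columns `file_path`, `batch_id`,
#'   `role`, `condition`.
#' @export
discover_batches <- function(directory, anchor_token = "anchor",
                             batch_pattern = "Barcode(\\d+)") {
  if (!dir.exists(directory)) stop("no such directory: '", directory, "'", call. = FALSE)
  files <- sort(list.files(directory, pattern = "\\.fcs$", ignore.case = TRUE,
                           full.names = TRUE))
  if (length(files) == 0L) stop("no batches found: no FCS files in '", directory, "'",
                                call. = FALSE)
  m <- stringr::str_match(basename(files), batch_pattern)
  if (ncol(m) < 2L) stop("batch_pattern must contain one capture group", call. = FALSE)
  unmatched <- is.na(m[, 2])
  if (any(unmatched)) {
    warning("excluding files not matching batch pattern: ",
            paste(basename(files)[unmatched], collapse = ", "), call. = FALSE)
    files <- files[!unmatched]; m <- m[!unmatched, , drop = FALSE]
  }
  if (length(files) == 0L) stop("no batches found in '", directory, "'", call. = FALSE)
  manifest <- tibble::tibble(
    file_path = files,
    batch_id = m[, 2],
    role = ifelse(stringr::str_detect(tolower(basename(files)), tolower(anchor_token)),
                  "anchor", "study"),
    condition = NA_character_)
  validate_manifest(manifest)
}

#' Read a batch manifest from CSV
#'
#' The manifest CSV must have columns `file_path`, `batch_id`, `role`
#' (`anchor`/`study`) and optionally `condition`. Exactly one anchor row is
#' required per batch; a second replicate set (e.g. unstimulated anchors
#' kept for validation) should be listed as study samples with a
#' `condition` tag.
#'
#' @param path Manifest CSV path.
#' @return A validated `batch_manifest` tibble.
#' @export
read_batch_manifest <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("file_path", "batch_id", "role")
  if (!all(need %in% names(df))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (!"condition" %in% names(df)) df$condition <- NA_character_
  df$batch_id <- as.character(df$batch_id)
  validate_manifest(tibble::as_tibble(df[, c("file_path", "batch_id", "role", "condition")]))
}

validate_manifest <- function(manifest) {
  if (!all(manifest$role %in% c("anchor", "study"))) {
    stop("manifest roles must be 'anchor' or 'study'", call. = FALSE)
  }
  if (anyDuplicated(manifest$file_path)) stop("duplicate file paths in manifest", call. = FALSE)
  missing <- manifest$file_path[!file.exists(manifest$file_path)]
  if (length(missing)) {
    stop("manifest files do not exist: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  counts <- table(manifest$batch_id[manifest$role == "anchor"])
  all_batches <- unique(manifest$batch_id)
  bad <- c(setdiff(all_batches, names(counts)), names(counts)[counts != 1L])
  if (length(bad)) {
    detail <- vapply(bad, function(b) {
      cand <- basename(manifest$file_path[manifest$batch_id == b & manifest$role == "anchor"])
      sprintf("batch %s: %d anchor(s)%s", b, length(cand),
              if (length(cand)) paste0(" [", paste(cand, collapse = ", "), "]") else "")
    }, character(1))
    stop("each batch needs exactly one anchor; ", paste(detail, collapse = "; "),
         call. = FALSE)
  }
  manifest <- manifest[order(manifest$batch_id, manifest$role != "anchor",
                             manifest$file_path), ]
  class(manifest) <- c("batch_manifest", class(manifest))
  manifest
}

#' Run anchor-based batch adjustment over a manifest
#'
#' The end-to-end driver: for every batch, reads its anchor, calibrates
#' per-channel adjustments against the reference batch's anchor
#' ([compute_batch_factors()]), applies them to every file of the batch
#' ([adjust_sample()]), and writes one adjusted FCS per input file plus the
#' calibrated factor tables and a processing log. Reference-batch files are
#' written with data identical to their input.
#'
#' Batches are processed independently: a batch's outputs depend only on
#' its own anchor, the reference anchor, and the configuration. Re-running
#' on a superset of batches therefore reproduces previously written outputs
#' byte-identically (rolling-basis processing).
#'
#' A per-file channel mismatch does not abort the run; the file is recorded
#' as failed and processing continues.
#'
#' @param manifest A `batch_manifest` (from [read_batch_manifest()] or
#'   [discover_batches()]).
#' @param config An [adjustment_config()]; its `reference_batch` must occur
#'   in the manifest.
#' @param out_dir Output directory (created if needed). Receives one
#'   adjusted FCS per input file (same basename), per-batch factor CSVs,
#'   a combined `scale_factors.csv`, `adjustment_log.txt` and
#'   `adjustment_summary.json`.
#' @param diagnostics If `TRUE`, also renders the graphical diagnostics via
#'   [emit_diagnostics()].
#' @return Invisibly, a list: `records` (named list of per-batch
#'   `scale_factors`), `log` (log file path), `files` (tibble of per-file
#'   outcomes and timings), `ok` (`TRUE` when every file was processed).
#' @export
run_adjustment <- function(manifest, config, out_dir, diagnostics = FALSE) {
  stopifnot(inherits(manifest, "batch_manifest"), inherits(config, "adjustment_config"))
  if (!config$reference_batch %in% manifest$batch_id) {
    stop("reference batch '", config$reference_batch, "' not present in manifest",
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "adjustment_log.txt")
  log_lines <- character(0)
  log_msg <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), sprintf(...))
    log_lines[[length(log_lines) + 1L]] <<- line
    invisible(line)
  }

  batches <- unique(manifest$batch_id)
  log_msg("run start: %d batches, %d files, method=%s space=%s reference=%s",
          length(batches), nrow(manifest), config$method, config$space,
          config$reference_batch)

  ref_row <- manifest[manifest$batch_id == config$reference_batch &
                        manifest$role == "anchor", ]
  ref_anchor <- read_fcs(ref_row$file_path[1])
  ref_anchor <- et_annotate(ref_anchor, batch_id = config$reference_batch, role = "anchor")

  records <- list()
  file_rows <- list()
  anchors_pre <- list(); anchors_post <- list()

  for (b in batches) {
    log_msg("batch found: %s", b)
    rows <- manifest[manifest$batch_id == b, ]
    anchor_path <- rows$file_path[rows$role == "anchor"][1]
    anchor <- read_fcs(anchor_path)
    anchor <- et_annotate(anchor, batch_id = b, role = "anchor")
    rec <- compute_batch_factors(ref_anchor, anchor, config)
    records[[b]] <- rec
    write_scale_factors(rec, file.path(out_dir, sprintf("scale_factors_batch_%s.csv", b)))
    for (i in seq_len(nrow(rec))) {
      if (rec$type[i] == "skipped") {
        log_msg("batch %s channel %s skipped: %s", b, rec$channel[i], rec$reason[i])
      }
    }
    anchors_pre[[b]] <- anchor

    for (j in seq_len(nrow(rows))) {
      path <- rows$file_path[j]
      t0 <- proc.time()[["elapsed"]]
      res <- tryCatch({
        tab <- if (rows$role[j] == "anchor") anchor else {
          et_annotate(read_fcs(path), batch_id = b,
                      role = rows$role[j], condition = rows$condition[j])
        }
        adj <- adjust_sample(tab, rec, config)
        out_path <- file.path(out_dir, basename(path))
        write_fcs(adj, out_path)
        if (rows$role[j] == "anchor") anchors_post[[b]] <- adj
        list(status = "ok", error = NA_character_, out = out_path)
      }, error = function(e) list(status = "failed", error = conditionMessage(e),
                                  out = NA_character_))
      dt <- proc.time()[["elapsed"]] - t0
      if (res$status == "ok") {
        log_msg("processed %s (batch %s, %s) in %.3f s", basename(path), b, rows$role[j], dt)
      } else {
        log_msg("FAILED %s (batch %s): %s", basename(path), b, res$error)
      }
      file_rows[[length(file_rows) + 1L]] <- tibble::tibble(
        file_path = path, batch_id = b, role = rows$role[j],
        status = res$status, seconds = dt, output = res$out, error = res$error)
    }
  }

  files <- dplyr::bind_rows(file_rows)
  combined <- dplyr::bind_rows(records)
  class(combined) <- c("scale_factors", class(combined))
  write_scale_factors(combined, file.path(out_dir, "scale_factors.csv"))

  ok <- all(files$status == "ok")
  log_msg("run end: %d/%d files processed", sum(files$status == "ok"), nrow(files))
  writeLines(log_lines, log_path)
  jsonlite::write_json(
    list(batches = batches, n_files = nrow(files),
         n_failed = sum(files$status != "ok"),
         method = config$method, space = config$space,
         reference_batch = config$reference_batch,
         files = files[, c("file_path", "batch_id", "role", "status", "seconds")]),
    file.path(out_dir, "adjustment_summary.json"),
    auto_unbox = TRUE, digits = NA)

  if (isTRUE(diagnostics)) {
    emit_diagnostics(records, anchors_pre, anchors_post, out_dir)
  }
  invisible(list(records = records, log = log_path, files = files, ok = ok))
}

#' Render graphical adjustment diagnostics
#'
#' Writes the run's diagnostic artifacts to `out_dir`: (a) one overview
#' figure of scale factors across channels and batches (skipped channels
#' annotated, never omitted); (b) one figure per adjusted channel
#' overlaying the signal-intensity densities of every batch anchor pre- and
#' post-adjustment; (c) the combined factor table CSV. Inspecting the
#' overview is how outlier batches or mislabeled channels are caught before
#' downstream analysis.
#'
#' @param records Named list of per-batch `scale_factors` tibbles.
#' @param anchors_pre,anchors_post Named lists of anchor [event_table()]s
#'   (same batch names), before and after adjustment.
#' @param out_dir Output directory.
#' @return Invisibly, the character vector of files written.
#' @export
emit_diagnostics <- function(records, anchors_pre, anchors_post, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  combined <- dplyr::bind_rows(records)
  class(combined) <- c("scale_factors", class(combined))
  written <- character(0)

  tab_path <- file.path(out_dir, "diagnostic_scale_factors.csv")
  write_scale_factors(combined, tab_path)
  written <- c(written, tab_path)

  p <- plot_scale_factors(combined)
  ov_path <- file.path(out_dir, "scale_factor_overview.pdf")
  ggplot2::ggsave(ov_path, p, width = 8,
                  height = max(3, 0.35 * length(unique(combined$channel))),
                  limitsize = FALSE)
  written <- c(written, ov_path)

  for (ch in unique(combined$channel)) {
    p <- plot_channel_density(anchors_pre, anchors_post, ch,
                              skipped = any(combined$channel == ch &
                                              combined$type == "skipped"))
    f <- file.path(out_dir, sprintf("channel_density_%s.pdf", gsub("[^A-Za-z0-9_.-]", "_", ch)))
    ggplot2::ggsave(f, p, width = 8, height = 4)
    written <- c(written, f)
  }
  invisible(written)
}
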