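write_batch_dir <- function(dir, batches = c("1", "2"), seed = 31) {
  set.seed(seed)
  for (b in batches) {
    for (f in c("anchor_stim", "s01")) {
      t <- lognorm_table(400, c("A", "B"), meanlog = 3 + 0.2 * as.numeric(b),
                         sample_id = sprintf("Barcode%s_%s", b, f),
                         batch_id = b, role = if (f == "anchor_stim") "anchor" else "study")
      write_fcs(t, file.path(dir, sprintf("Barcode%s_%s.fcs", b, f)))
    }
  }
  dir
}

test_that("discover_batches builds a manifest from filename conventions", {
  d <- withr::local_tempdir()
  write_batch_dir(d)
  m <- discover_batches(d, anchor_token = "anchor", batch_pattern = "Barcode(\\d+)")
  expect_identical(nrow(m), 4L)
  expect_identical(sort(unique(m$batch_id)), c("1", "2"))
  expect_identical(sum(m$role == "anchor"), 2L)
  expect_identical(sum(m$role == "study"), 2L)
  # two anchors in one batch
  t <- lognorm_table(100, c("A", "B"), sample_id = "x", batch_id = "1", role = "anchor")
  write_fcs(t, file.path(d, "Barcode1_anchor_unstim.fcs"))
  expect_error(discover_batches(d), "exactly one anchor")
  # files not matching the pattern: warning + exclusion
  file.remove(file.path(d, "Barcode1_anchor_unstim.fcs"))
  write_fcs(t, file.path(d, "README_notes.fcs"))
  expect_warning(m2 <- discover_batches(d), "not matching")
  expect_identical(nrow(m2), 4L)
  # empty directory
  d2 <- withr::local_tempdir()
  expect_error(discover_batches(d2), "no batches found")
})

test_that("CSV manifests are validated", {
  d <- withr::local_tempdir()
  write_batch_dir(d)
  files <- list.files(d, full.names = TRUE)
  mf <- tibble::tibble(file_path = files,
                       batch_id = sub(".*Barcode(\\d+).*", "\\1", files),
                       role = ifelse(grepl("anchor", files), "anchor", "study"))
  p <- file.path(d, "manifest.csv")
  readr::write_csv(mf, p)
  m <- read_batch_manifest(p)
  expect_s3_class(m, "batch_manifest")
  expect_identical(nrow(m), 4L)
  # missing anchor for a batch
  readr::write_csv(mf[mf$role != "anchor" | mf$batch_id != "2", ], p)
  expect_error(read_batch_manifest(p), "exactly one anchor")
  # nonexistent file
  mf2 <- mf; mf2$file_path[1] <- file.path(d, "ghost.fcs")
  readr::write_csv(mf2, p)
  expect_error(read_batch_manifest(p), "do not exist")
})

test_that("run_adjustment harmonizes anchors, logs everything, and never touches the reference", {
  d <- withr::local_tempdir()
  ex <- tiny_experiment(n_batches = 3, events = 1500, n_channels = 3)
  manifest <- write_experiment_fcs(ex, d)
  cfg <- adjustment_config(method = "percentile", percentile_p = 95,
                           reference_batch = "B01", channels = c("Ch01", "Ch02", "Ch03"))
  out <- withr::local_tempdir()
  res <- run_adjustment(manifest, cfg, out)
  expect_true(res$ok)
  expect_identical(sort(names(res$records)), c("B01", "B02", "B03"))
  # every input has an adjusted output
  expect_true(all(file.exists(file.path(out, basename(manifest$file_path)))))
  # reference-batch outputs value-identical to inputs
  for (f in manifest$file_path[manifest$batch_id == "B01"]) {
    expect_identical(et_matrix(read_fcs(file.path(out, basename(f)))),
                     et_matrix(read_fcs(f)))
  }
  # post-run anchors share the reference anchor's per-channel p95 (float32 storage)
  ref_anchor <- read_fcs(file.path(out, "B01_anchor.fcs"))
  for (b in c("B02", "B03")) {
    a <- read_fcs(file.path(out, sprintf("%s_anchor.fcs", b)))
    for (ch in c("Ch01", "Ch02", "Ch03")) {
      expect_equal(channel_statistic(a[[ch]], "percentile", 95),
                   channel_statistic(ref_anchor[[ch]], "percentile", 95),
                   tolerance = 1e-6)
    }
  }
  # artifacts: per-batch factor CSVs, combined table, log, JSON summary
  expect_true(file.exists(file.path(out, "scale_factors_batch_B02.csv")))
  expect_true(file.exists(file.path(out, "scale_factors.csv")))
  log <- readLines(res$log)
  expect_true(any(grepl("batch found: B03", log)))
  expect_true(any(grepl("processed B02_anchor.fcs", log)))
  expect_true(any(grepl(" in [0-9.]+ s", log)))
  summ <- jsonlite::read_json(file.path(out, "adjustment_summary.json"))
  expect_identical(summ$n_failed, 0L)
})

test_that("rolling basis: outputs for earlier batches are byte-identical on superset reruns", {
  d <- withr::local_tempdir()
  ex <- tiny_experiment(n_batches = 3, events = 800, n_channels = 3)
  manifest <- write_experiment_fcs(ex, d)
  cfg <- adjustment_config(method = "percentile", percentile_p = 95,
                           reference_batch = "B01", channels = c("Ch01", "Ch02"))
  out12 <- withr::local_tempdir(); out123 <- withr::local_tempdir()
  m12 <- manifest[manifest$batch_id %in% c("B01", "B02"), ]
  class(m12) <- class(manifest)
  run_adjustment(m12, cfg, out12)
  run_adjustment(manifest, cfg, out123)
  for (f in basename(m12$file_path)) {
    expect_identical(unname(tools::md5sum(file.path(out12, f))),
                     unname(tools::md5sum(file.path(out123, f))))
  }
})

test_that("a per-file channel mismatch fails that file only and the run reports it", {
  d <- withr::local_tempdir()
  ex <- tiny_experiment(n_batches = 2, events = 500, n_channels = 3)
  manifest <- write_experiment_fcs(ex, d)
  # corrupt one study file: drop an adjusted channel
  bad <- manifest$file_path[manifest$batch_id == "B02" & manifest$role == "study"][1]
  t <- read_fcs(bad)
  t2 <- event_table(as.data.frame(t)[, c("Ch01", "Ch03")], sample_id = et_sample_id(t),
                    batch_id = et_batch_id(t), role = et_role(t))
  write_fcs(t2, bad)
  cfg <- adjustment_config(method = "mean", reference_batch = "B01",
                           channels = c("Ch01", "Ch02"))
  out <- withr::local_tempdir()
  res <- run_adjustment(manifest, cfg, out)
  expect_false(res$ok)
  expect_identical(sum(res$files$status == "failed"), 1L)
  expect_match(res$files$error[res$files$status == "failed"], "Ch02")
  # all other files still processed
  expect_identical(sum(res$files$status == "ok"), nrow(manifest) - 1L)
  expect_true(any(grepl("FAILED", readLines(res$log))))
})

test_that("skipped channels are logged and diagnostics render one figure per channel", {
  d <- withr::local_tempdir()
  set.seed(33)
  chans <- c("A", "B", "C", "D", "E")
  mk <- function(b, zero_b = FALSE) {
    t <- lognorm_table(600, chans, batch_id = b, role = "anchor",
                       sample_id = paste0(b, "_anchor"))
    if (zero_b) {
      df <- as.data.frame(t); df$B <- 0 * df$B
      t <- event_table(df, sample_id = et_sample_id(t), batch_id = b, role = "anchor")
    }
    write_fcs(t, file.path(d, paste0(b, "_anchor.fcs")))
  }
  mk("B1"); mk("B2", zero_b = TRUE); mk("B3")
  p <- file.path(d, "m.csv")
  readr::write_csv(tibble::tibble(
    file_path = file.path(d, paste0(c("B1", "B2", "B3"), "_anchor.fcs")),
    batch_id = c("B1", "B2", "B3"), role = "anchor"), p)
  mf <- read_batch_manifest(p)
  cfg <- adjustment_config(method = "median", reference_batch = "B1", channels = chans)
  out <- withr::local_tempdir()
  res <- run_adjustment(mf, cfg, out, diagnostics = TRUE)
  expect_true(any(grepl("channel B skipped", readLines(res$log))))
  expect_identical(res$records$B2$type[res$records$B2$channel == "B"], "skipped")
  # 1 overview + 5 per-channel figures + factor table (+ per-batch CSVs)
  pdfs <- list.files(out, pattern = "\\.pdf$")
  expect_identical(sum(grepl("^scale_factor_overview", pdfs)), 1L)
  expect_identical(sum(grepl("^channel_density_", pdfs)), 5L)
  expect_true(file.exists(file.path(out, "diagnostic_scale_factors.csv")))
  # identical anchors across batches: all factors rendered at 1
  recs <- res$records
  expect_true(all(recs$B1$factor == 1))
  p <- plot_scale_factors(res$records$B3)
  expect_s3_class(p, "ggplot")
})
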