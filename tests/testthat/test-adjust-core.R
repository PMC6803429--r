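cfg95 <- function(channels = "A", ...) {
  adjustment_config(method = "percentile", percentile_p = 95,
                    reference_batch = "B1", channels = channels, ...)
}

test_that("channel_statistic matches its definitions", {
  expect_identical(channel_statistic(c(0, 0, 0, 10), "median"), 0)   # >50% zeros
  expect_equal(channel_statistic(1:100, "percentile", 95), 95.05)    # rank 1+99*0.95
  expect_equal(channel_statistic(c(5, 5, 5), "mean"), 5)
  expect_identical(channel_statistic(c(5, 5, 5), "sd"), 0)
  expect_equal(channel_statistic(c(1, 2, 3, 4), "sd"), sd(c(1, 2, 3, 4)))
  expect_error(channel_statistic(numeric(0), "mean"), "empty")
  # percentile agrees with brute-force sort + interpolation on random draws
  set.seed(3)
  for (p in c(20, 50, 80, 95)) {
    x <- rlnorm(57)
    s <- sort(x); h <- 1 + (length(x) - 1) * p / 100
    lo <- floor(h); hi <- ceiling(h)
    expect_equal(channel_statistic(x, "percentile", p),
                 s[lo] + (h - lo) * (s[hi] - s[lo]))
  }
})

test_that("compute_scale_factor is the reference/batch statistic ratio", {
  cfg <- adjustment_config(method = "mean", reference_batch = "B1", channels = "A")
  expect_equal(compute_scale_factor(c(0, 20), c(0, 10), cfg), 2.0)
  x <- rlnorm(100)
  expect_identical(compute_scale_factor(x, x, cfg), 1)  # identical anchors
  # >50% zeros breaks the median: skip-signal, or error when skipping is off
  cfgm <- adjustment_config(method = "median", reference_batch = "B1", channels = "A")
  s <- compute_scale_factor(c(1, 2, 3), c(0, 0, 0, 10), cfgm)
  expect_true(is_skip_signal(s))
  expect_match(s$reason, "zero")
  cfgm2 <- adjustment_config(method = "median", reference_batch = "B1",
                             channels = "A", skip_on_zero_stat = FALSE)
  expect_error(compute_scale_factor(c(1, 2, 3), c(0, 0, 0, 10), cfgm2), "zero")
  # arcsinh space: statistic taken on asinh(x / cofactor)
  cfga <- adjustment_config(method = "mean", space = "arcsinh", cofactor = 5,
                            reference_batch = "B1", channels = "A")
  r <- c(2, 8); b <- c(1, 4)
  expect_equal(compute_scale_factor(r, b, cfga),
               mean(asinh(r / 5)) / mean(asinh(b / 5)))
})

test_that("apply_scale is linear in raw space and sinh-warped in arcsinh space", {
  expect_equal(apply_scale(c(0, 2, 4), 1, "raw"), c(0, 2, 4))
  expect_equal(apply_scale(c(0, 2, 4), 1, "arcsinh"), c(0, 2, 4))
  expect_equal(apply_scale(c(0, 2, 4), 2, "raw"), c(0, 4, 8))
  # closed form 5*sinh(2*asinh(1)) = 5*2*sinh(asinh(1))*cosh(asinh(1)) = 10*sqrt(2)
  expect_equal(apply_scale(5, 2, "arcsinh", cofactor = 5), 14.1421356, tolerance = 1e-7)
  expect_identical(apply_scale(0, 3.7, "arcsinh", cofactor = 2), 0)  # zeros stay zero
  expect_error(apply_scale(1:3, -1, "raw"))
  expect_error(apply_scale(1:3, Inf, "raw"))
})

test_that("quantile maps match distributions and preserve rank order", {
  set.seed(5)
  x <- rlnorm(4000, 3, 0.5)
  # identity: batch anchor equals reference anchor
  qm <- build_quantile_map(x, x, n_knots = 101)
  expect_equal(qm$source_knots, qm$target_knots)
  expect_equal(apply_quantile_map(c(0, 7, 13), qm)[2:3], c(7, 13), tolerance = 1e-6)
  # batch = 2*ref: target ~ source/2 at interior knots
  qm2 <- build_quantile_map(x, 2 * x, n_knots = 101)
  expect_equal(qm2$target_knots[10:92], qm2$source_knots[10:92] / 2, tolerance = 1e-12)
  # simple linear interpolation and clamping
  qm3 <- structure(list(source_knots = c(0, 10), target_knots = c(0, 20),
                        zero_handling = "ecdf"), class = "quantile_map")
  expect_equal(apply_quantile_map(5, qm3), 10)
  expect_equal(apply_quantile_map(c(-1, 50), qm3), c(0, 20))  # clamp to end knots
  # property: rank order preserved (ties allowed) against brute-force sort
  for (i in 1:5) {
    src <- rlnorm(500); ref <- rlnorm(500, 1, 1)
    src[sample(500, 100)] <- 0
    qm4 <- build_quantile_map(ref, src, n_knots = 51)
    v <- sample(c(src, runif(100, 0, 30)))
    out <- apply_quantile_map(v, qm4)
    expect_true(all(diff(out[order(v)]) >= -1e-12))
    expect_true(all(out >= 0))
  }
})

test_that("quantile mapping of the batch anchor reproduces the reference distribution", {
  set.seed(6)
  ref <- rlnorm(20000, 3, 0.6)
  batch <- rlnorm(20000, 3.4, 0.4)
  qm <- build_quantile_map(ref, batch, n_knots = 2001)
  expect_lt(ks_statistic(apply_quantile_map(batch, qm), ref), 2 / 2001 + 0.02)
})

test_that("zero-mass handling: ecdf mapping shows the artifact, preserve mode does not", {
  set.seed(8)
  ref <- rlnorm(5000); ref[sample(5000, 500)] <- 0      # 10% zeros
  batch <- rlnorm(5000); batch[sample(5000, 2500)] <- 0 # 50% zeros
  qm <- build_quantile_map(ref, batch, n_knots = 1001, zero_handling = "ecdf")
  mapped <- apply_quantile_map(batch, qm)
  # surplus zeros are inflated to positive reference values
  expect_lt(mean(mapped == 0), 0.5)
  # squashing direction: reference has more zeros than the batch
  qm_rev <- build_quantile_map(batch, ref, n_knots = 1001, zero_handling = "ecdf")
  mapped_rev <- apply_quantile_map(ref, qm_rev)
  expect_gt(mean(mapped_rev == 0), mean(ref == 0))
  # preserve mode: zero fraction untouched
  qmp <- build_quantile_map(ref, batch, n_knots = 1001, zero_handling = "preserve")
  expect_equal(mean(apply_quantile_map(batch, qmp) == 0), mean(batch == 0))
})

test_that("adjust_sample: reference passthrough, identity factors, closure, skips", {
  set.seed(9)
  chans <- c("A", "B", "C")
  ref <- lognorm_table(3000, chans, batch_id = "B1", role = "anchor", sample_id = "a1")
  cfg <- cfg95(chans)
  # reference batch is a no-op on the data
  rec_ref <- compute_batch_factors(ref, ref, cfg)
  expect_true(all(rec_ref$factor == 1))
  out_ref <- adjust_sample(ref, rec_ref, cfg)
  expect_identical(et_matrix(out_ref), et_matrix(ref))
  # injected per-channel multipliers: post-adjustment p95 matches the reference's
  mults <- c(A = 0.4, B = 1, C = 3.2)
  b2 <- event_table(sweep(et_matrix(ref), 2, mults, `*`),
                    sample_id = "a2", batch_id = "B2", role = "anchor")
  rec <- compute_batch_factors(ref, b2, cfg)
  expect_equal(unname(rec$factor), unname(1 / mults), tolerance = 1e-12)
  adj <- adjust_sample(b2, rec, cfg)
  for (ch in chans) {
    expect_equal(channel_statistic(adj[[ch]], "percentile", 95),
                 channel_statistic(ref[[ch]], "percentile", 95), tolerance = 1e-9)
  }
  # channels outside the selection untouched
  cfgA <- cfg95("A")
  recA <- compute_batch_factors(ref, b2, cfgA)
  adjA <- adjust_sample(b2, recA, cfgA)
  expect_identical(adjA$B, b2$B)
  expect_identical(adjA$C, b2$C)
  # skipped channel left unadjusted and flagged in provenance keywords
  z <- b2; z$B <- rep(0, nrow(z))
  zt <- event_table(as.data.frame(z), sample_id = "a2z", batch_id = "B2", role = "anchor")
  cfgm <- adjustment_config(method = "median", reference_batch = "B1", channels = chans)
  recz <- compute_batch_factors(ref, zt, cfgm)
  expect_identical(recz$type[recz$channel == "B"], "skipped")
  adjz <- adjust_sample(zt, recz, cfgm)
  expect_identical(adjz$B, zt$B)
  expect_match(et_keywords(adjz)[["ANCHORNORM_ADJ_B"]], "skipped")
  # missing channel errors name the channel
  rec_bad <- recz
  rec_bad$channel[1] <- "Nope"
  expect_error(adjust_sample(zt, rec_bad, cfgm), "Nope")
})

test_that("statistic closure holds in arcsinh space and factors are idempotent", {
  set.seed(10)
  chans <- c("A", "B")
  ref <- lognorm_table(4000, chans, zero_prob = 0.2, batch_id = "B1",
                       role = "anchor", sample_id = "a1")
  b2 <- event_table(et_matrix(ref)[sample(4000), ] * 1.8,
                    sample_id = "a2", batch_id = "B2", role = "anchor")
  for (method in c("percentile", "mean", "sd")) {
    cfg <- adjustment_config(method = method, percentile_p = 80, space = "arcsinh",
                             cofactor = 5, reference_batch = "B1", channels = chans)
    rec <- compute_batch_factors(ref, b2, cfg)
    adj <- adjust_sample(b2, rec, cfg)
    for (ch in chans) {
      expect_equal(channel_statistic(asinh(adj[[ch]] / 5), method, 80),
                   channel_statistic(asinh(ref[[ch]] / 5), method, 80),
                   tolerance = 1e-6)
    }
    # recomputing factors on the adjusted anchor gives 1
    rec2 <- compute_batch_factors(ref, adj, cfg)
    expect_equal(rec2$factor, rep(1, length(chans)), tolerance = 1e-6)
  }
})

test_that("scale factors serialize to CSV and back, including quantile maps", {
  set.seed(12)
  ref <- lognorm_table(1000, c("A", "B"), batch_id = "B1", role = "anchor")
  b2 <- lognorm_table(1000, c("A", "B"), meanlog = 3.5, batch_id = "B2", role = "anchor")
  cfg <- adjustment_config(method = "quantile_norm", reference_batch = "B1",
                           channels = c("A", "B"), n_knots = 51)
  rec <- compute_batch_factors(ref, b2, cfg)
  p <- withr::local_tempfile(fileext = ".csv")
  write_scale_factors(rec, p)
  back <- read_scale_factors(p)
  expect_identical(back$type, rec$type)
  expect_equal(back$qmap[[1]]$source_knots, rec$qmap[[1]]$source_knots)
  expect_equal(back$qmap[[2]]$target_knots, rec$qmap[[2]]$target_knots)
  # scale-method round trip preserves factors at full precision
  cfg2 <- cfg95(c("A", "B"))
  rec2 <- compute_batch_factors(ref, b2, cfg2)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_scale_factors(rec2, p2)
  expect_identical(read_scale_factors(p2)$factor, rec2$factor)
  expect_s3_class(tidy(rec2), "tbl_df")
})
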