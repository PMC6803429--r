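# shared fixtures and independent oracles

# event table of zero-inflated lognormal channels
lognorm_table <- function(n, channels, meanlog = 3, sdlog = 0.5, zero_prob = 0,
                          sample_id = "s", batch_id = "B1", role = "study",
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mat <- sapply(seq_along(channels), function(i) {
    v <- rlnorm(n, meanlog, sdlog)
    v[runif(n) < zero_prob] <- 0
    v
  })
  colnames(mat) <- channels
  event_table(mat, sample_id = sample_id, batch_id = batch_id, role = role)
}

# independent minimal FCS 3.1 writer (float32 LE), used as an oracle for
# read_fcs: it shares no code with the package writer
oracle_write_fcs <- function(mat, names, path, extra_kw = character(0)) {
  d <- "/"
  kv <- c("$DATATYPE", "F", "$BYTEORD", "1,2,3,4", "$MODE", "L",
          "$TOT", as.character(nrow(mat)), "$PAR", as.character(ncol(mat)),
          "$NEXTDATA", "0")
  for (i in seq_len(ncol(mat))) {
    kv <- c(kv, sprintf("$P%dN", i), names[i], sprintf("$P%dB", i), "32",
            sprintf("$P%dE", i), "0,0", sprintf("$P%dR", i), "262144")
  }
  kv <- c(kv, extra_kw)
  txt <- paste0(d, paste0(kv, d, collapse = ""))
  text_beg <- 256L  # pad header region to a fixed TEXT start
  text_end <- text_beg + nchar(txt) - 1L
  data_beg <- text_end + 1L
  data_end <- data_beg + 4L * length(mat) - 1L
  header <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d",
                    text_beg, text_end, data_beg, data_end, 0L, 0L)
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(raw(text_beg - 58L), con)
  writeBin(charToRaw(txt), con)
  writeBin(as.vector(t(mat)), con, size = 4L, endian = "little")
  path
}

# brute-force enumeration oracle for the pre/post label-swap permutation
# test: deltas via trace of cov(), subsets via utils::combn
oracle_perm_deltas <- function(pre, post) {
  n <- nrow(pre)
  deltas <- numeric(0)
  for (k in 0:n) {
    subsets <- if (k == 0) list(integer(0)) else
      asplit(utils::combn(n, k), 2)
    for (s in subsets) {
      p1 <- pre; p2 <- post
      p1[s, ] <- post[s, , drop = FALSE]
      p2[s, ] <- pre[s, , drop = FALSE]
      deltas <- c(deltas, sum(diag(stats::cov(p2))) - sum(diag(stats::cov(p1))))
    }
  }
  deltas
}

# two-batch experiment with one multiplied channel; small and fast
tiny_experiment <- function(n_batches = 2, events = 1000, n_channels = 4,
                            multiplier = 2, seed = 11) {
  pops <- example_populations(n_channels = n_channels, n_populations = 2)
  fx <- batch_effect_spec(tibble::tibble(
    batch_id = sprintf("B%02d", seq_len(n_batches)[-1]),
    channel = "Ch01", multiplier = multiplier))
  generate_experiment(pops, fx, n_batches = n_batches,
                      events_per_sample = events, seed = seed)
}
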