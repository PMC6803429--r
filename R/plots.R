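#' Scale-factor overview plot
#'
#' One panel of adjustment factors for every (channel, batch) pair, the
#' quick visual check for outlier batches and suspect channels. Skipped
#' channels are drawn with an explicit marker rather than dropped; for the
#' reference batch all factors sit at 1.
#'
#' @param record A `scale_factors` tibble (one or many batches).
#' @return A ggplot object.
#' @export
plot_scale_factors <- function(record) {
  stopifnot(inherits(record, "scale_factors"))
  df <- tibble::as_tibble(record[, c("batch_id", "channel", "type", "factor")])
  df$status <- ifelse(df$type == "skipped", "skipped",
                      ifelse(df$type == "quantile_map", "quantile map", "factor"))
  df$plotted <- ifelse(df$type == "factor", df$factor, 1)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$plotted, y = .data$channel,
                                   colour = .data$batch_id, shape = .data$status)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_shape_manual(values = c(factor = 16, skipped = 4, `quantile map` = 1)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "scale factor (reference / batch statistic, log scale)",
                  y = NULL, colour = "batch", shape = NULL,
                  title = "Per-channel batch adjustment factors") +
    ggplot2::theme_minimal()
}

#' Pre/post anchor density plot for one channel
#'
#' Overlays the signal-intensity density of every batch anchor for a single
#' channel, before and after adjustment, on an arcsinh axis. Tight
#' post-adjustment overlap is what a successful harmonization looks like.
#'
#' @param anchors_pre,anchors_post Named lists of anchor [event_table()]s.
#' @param channel Channel short name.
#' @param cofactor arcsinh display cofactor (default 5).
#' @param skipped If `TRUE`, annotate the panel as a skipped channel.
#' @return A ggplot object.
#' @export
plot_channel_density <- function(anchors_pre, anchors_post, channel,
                                 cofactor = 5, skipped = FALSE) {
  gather <- function(lst, stage) {
    purrr::map_dfr(names(lst), function(b) {
      tibble::tibble(batch_id = b, stage = stage,
                     value = asinh(lst[[b]][[channel]] / cofactor))
    })
  }
  df <- dplyr::bind_rows(gather(anchors_pre, "pre-adjustment"),
                         gather(anchors_post, "post-adjustment"))
  df$stage <- factor(df$stage, levels = c("pre-adjustment", "post-adjustment"))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$value, colour = .data$batch_id)) +
    ggplot2::geom_density() +
    ggplot2::facet_wrap(~stage, nrow = 1) +
    ggplot2::labs(x = sprintf("asinh(%s / %g)", channel, cofactor), y = "density",
                  colour = "batch",
                  title = sprintf("Anchor signal distributions: %s%s", channel,
                                  if (skipped) "  [channel skipped: not adjusted]" else "")) +
    ggplot2::theme_minimal()
  p
}
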