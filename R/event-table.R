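#' Build an event table
#'
#' An event table is the in-memory form of one cytometry sample: a tibble
#' with one row per cell event and one numeric column per mass channel
#' (nonnegative ion counts), plus sample-level annotations carried as
#' attributes. It is the unit that [read_fcs()] returns, [adjust_sample()]
#' transforms, and [write_fcs()] serializes.
#'
#' @param data A data frame or numeric matrix of events x channels. All
#'   values must be finite and nonnegative; column names become channel
#'   short names and must be unique.
#' @param sample_id Sample identifier (defaults to `"sample"`).
#' @param batch_id Batch (barcode set) identifier; may be `NA` when unknown,
#'   e.g. for a file read outside any batch context.
#' @param role Either `"study"` or `"anchor"`. Anchors are the technical
#'   replicates used to calibrate batch adjustment.
#' @param condition Optional condition tag (e.g. `"stim"`/`"unstim"`) carried
#'   through but never interpreted by the adjustment itself.
#' @param channels Optional tibble with columns `short_name` and `antibody`
#'   describing the panel; defaults to the column names with no antibody
#'   labels.
#' @param keywords Named list of FCS TEXT-segment keywords to carry through
#'   on write.
#'
#' @return A tibble of class `event_table` with the annotations above stored
#'   as attributes (`sample_id`, `batch_id`, `role`, `condition`,
#'   `channels`, `keywords`).
#' @examples
#' et <- event_table(data.frame(CD3 = c(0, 4, 120), CD19 = c(2, 0, 7)),
#'                   sample_id = "s1", batch_id = "B1", role = "anchor")
#' et_sample_id(et)
#' @export
event_table <- function(data, sample_id = "sample", batch_id = NA_character_,
                        role = c("study", "anchor"), condition = NA_character_,
                        channels = NULL, keywords = list()) {
  role <- match.arg(role)
  if (is.matrix(data)) data <- as.data.frame(data)
  stopifnot(is.data.frame(data))
  data <- tibble::as_tibble(data)
  if (nrow(data) < 1L) stop("event table must contain at least one event", call. = FALSE)
  if (ncol(data) < 1L) stop("event table must contain at least one channel", call. = FALSE)
  if (anyDuplicated(names(data)) > 0L) {
    stop("duplicate channel short names: ",
         paste(unique(names(data)[duplicated(names(data))]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(vapply(data, is.numeric, logical(1)))) {
    stop("all channels must be numeric", call. = FALSE)
  }
  vals <- as.matrix(data)
  if (any(!is.finite(vals))) stop("intensities must be finite", call. = FALSE)
  if (any(vals < 0)) stop("intensities must be nonnegative (ion counts)", call. = FALSE)
  if (is.null(channels)) {
    channels <- tibble::tibble(short_name = names(data), antibody = NA_character_)
  }
  stopifnot(identical(channels$short_name, names(data)))
  structure(data,
            class = c("event_table", class(data)),
            sample_id = sample_id, batch_id = batch_id, role = role,
            condition = condition, channels = channels, keywords = keywords)
}

#' Test for an event table
#' @param x Object.
#' @return Logical.
#' @export
is_event_table <- function(x) inherits(x, "event_table")

#' Event table accessors
#'
#' Small helpers to read the annotations of an [event_table()]:
#' sample/batch identifiers, role, condition tag, panel metadata, carried
#' FCS keywords, and the raw events x channels numeric matrix.
#'
#' @param x An `event_table`.
#' @return `et_matrix()` returns a numeric matrix; `et_channels()` a tibble;
#'   `et_keywords()` a named list; the rest scalar character values.
#' @name event-table-accessors
NULL

#' @rdname event-table-accessors
#' @export
et_sample_id <- function(x) attr(x, "sample_id")

#' @rdname event-table-accessors
#' @export
et_batch_id <- function(x) attr(x, "batch_id")

#' @rdname event-table-accessors
#' @export
et_role <- function(x) attr(x, "role")

#' @rdname event-table-accessors
#' @export
et_condition <- function(x) attr(x, "condition")

#' @rdname event-table-accessors
#' @export
et_channels <- function(x) attr(x, "channels")

#' @rdname event-table-accessors
#' @export
et_keywords <- function(x) attr(x, "keywords")

#' @rdname event-table-accessors
#' @export
et_matrix <- function(x) {
  m <- as.matrix(as.data.frame(x))
  storage.mode(m) <- "double"
  m
}

# replace the event data, keeping all annotations
et_set_data <- function(x, data, keywords = et_keywords(x)) {
  event_table(data,
              sample_id = et_sample_id(x), batch_id = et_batch_id(x),
              role = et_role(x), condition = et_condition(x),
              channels = et_channels(x), keywords = keywords)
}

# set annotation fields on an existing table
et_annotate <- function(x, sample_id = et_sample_id(x), batch_id = et_batch_id(x),
                        role = et_role(x), condition = et_condition(x)) {
  attr(x, "sample_id") <- sample_id
  attr(x, "batch_id") <- batch_id
  attr(x, "role") <- role
  attr(x, "condition") <- condition
  x
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("<event_table> %s  batch=%s  role=%s%s  %d events x %d channels\n",
              et_sample_id(x), et_batch_id(x), et_role(x),
              if (!is.na(et_condition(x))) paste0("(", et_condition(x), ")") else "",
              nrow(x), ncol(x)))
  NextMethod()
}
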