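#' Read an FCS file into an event table
#'
#' Parses a Flow Cytometry Standard file (versions 2.0, 3.0, 3.1) and
#' returns its event data as an [event_table()]. Intensities are returned
#' exactly as stored — no compensation, transformation, or scaling is
#' applied. All TEXT-segment keywords are captured and carried through to
#' [write_fcs()]. Only the first dataset of a multi-dataset file is read
#' (CyTOF exports are single-dataset).
#'
#' @param path Path to an FCS file.
#' @return An [event_table()]. `sample_id` defaults to the file basename
#'   (without extension); batch/role/condition annotations are restored from
#'   `ANCHORNORM_*` keywords when the file was written by this package.
#' @seealso [write_fcs()]
#' @export
read_fcs <- function(path) {
  if (!file.exists(path)) stop("cannot read FCS file: no such file '", path, "'", call. = FALSE)
  size <- file.size(path)
  if (is.na(size) || size < 58) stop("malformed FCS file (too short): '", path, "'", call. = FALSE)
  raw <- readBin(path, what = "raw", n = size)

  version <- rawToChar(raw[1:6])
  if (!startsWith(version, "FCS")) {
    stop("not an FCS file (bad magic '", version, "'): '", path, "'", call. = FALSE)
  }
  hdr_int <- function(i) {
    s <- trimws(rawToChar(raw[(10 + 8 * (i - 1) + 1):(10 + 8 * i)]))
    if (s == "") 0 else suppressWarnings(as.numeric(s))
  }
  text_beg <- hdr_int(1); text_end <- hdr_int(2)
  data_beg <- hdr_int(3); data_end <- hdr_int(4)
  if (is.na(text_beg) || is.na(text_end) || text_end <= text_beg) {
    stop("malformed FCS header in '", path, "'", call. = FALSE)
  }

  txt <- rawToChar(raw[(text_beg + 1):(text_end + 1)])
  delim <- substr(txt, 1, 1)
  parts <- strsplit(substring(txt, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2L == 1L) parts <- parts[-length(parts)]
  keys <- parts[seq(1, length(parts), by = 2)]
  vals <- parts[seq(2, length(parts), by = 2)]
  keys <- ifelse(startsWith(keys, "$"), toupper(keys), keys)
  kw <- stats::setNames(as.list(vals), keys)

  need <- function(k) {
    v <- kw[[k]]
    if (is.null(v)) stop("FCS file missing required keyword ", k, ": '", path, "'", call. = FALSE)
    v
  }
  n_events <- as.integer(need("$TOT"))
  n_par <- as.integer(need("$PAR"))
  if (is.na(n_events) || n_events < 1L) {
    stop("malformed FCS file (zero events): '", path, "'", call. = FALSE)
  }
  datatype <- toupper(need("$DATATYPE"))
  byteord <- gsub("\\s", "", need("$BYTEORD"))
  endian <- switch(byteord,
                   "1,2,3,4" = "little", "1,2" = "little",
                   "4,3,2,1" = "big", "2,1" = "big",
                   stop("unsupported $BYTEORD '", byteord, "' in '", path, "'", call. = FALSE))

  if (data_beg == 0 || data_end == 0) {
    data_beg <- as.numeric(need("$BEGINDATA"))
    data_end <- as.numeric(need("$ENDDATA"))
  }
  count <- n_events * n_par
  data_raw <- raw[(data_beg + 1):(data_end + 1)]
  values <- switch(datatype,
    "F" = readBin(data_raw, "numeric", n = count, size = 4L, endian = endian),
    "D" = readBin(data_raw, "numeric", n = count, size = 8L, endian = endian),
    "I" = {
      bits <- unique(vapply(seq_len(n_par),
                            function(i) as.integer(need(sprintf("$P%dB", i))), integer(1)))
      if (length(bits) != 1L || !bits %in% c(8L, 16L, 32L)) {
        stop("unsupported integer layout ($PnB = ",
             paste(bits, collapse = ","), ") in '", path, "'", call. = FALSE)
      }
      if (bits == 32L) {
        readBin(data_raw, "integer", n = count, size = 4L, endian = endian)
      } else {
        readBin(data_raw, "integer", n = count, size = bits / 8L,
                signed = FALSE, endian = endian)
      }
    },
    stop("unsupported $DATATYPE '", datatype, "' in '", path, "'", call. = FALSE))
  if (length(values) < count) {
    stop("malformed FCS file (data segment truncated): '", path, "'", call. = FALSE)
  }

  short_names <- vapply(seq_len(n_par), function(i) need(sprintf("$P%dN", i)), character(1))
  if (anyDuplicated(short_names) > 0L) {
    stop("duplicate channel short names in '", path, "': ",
         paste(unique(short_names[duplicated(short_names)]), collapse = ", "),
         call. = FALSE)
  }
  antibodies <- vapply(seq_len(n_par), function(i) {
    v <- kw[[sprintf("$P%dS", i)]]
    if (is.null(v)) NA_character_ else v
  }, character(1))

  mat <- matrix(values, nrow = n_events, ncol = n_par, byrow = TRUE,
                dimnames = list(NULL, short_names))

  kw_get <- function(k, default) if (is.null(kw[[k]])) default else kw[[k]]
  role <- kw_get("ANCHORNORM_ROLE", "study")
  if (!role %in% c("anchor", "study")) role <- "study"
  cond <- kw_get("ANCHORNORM_CONDITION", NA_character_)
  if (identical(cond, "")) cond <- NA_character_

  event_table(mat,
              sample_id = kw_get("ANCHORNORM_SAMPLE_ID",
                                 tools::file_path_sans_ext(basename(path))),
              batch_id = kw_get("ANCHORNORM_BATCH_ID", NA_character_),
              role = role, condition = cond,
              channels = tibble::tibble(short_name = short_names, antibody = antibodies),
              keywords = kw)
}

# keywords regenerated on every write; carried copies are dropped first
.fcs_regenerated_keys <- function(n_par) {
  c("$BEGINANALYSIS", "$ENDANALYSIS", "$BEGINSTEXT", "$ENDSTEXT",
    "$BEGINDATA", "$ENDDATA", "$DATATYPE", "$BYTEORD", "$MODE",
    "$NEXTDATA", "$TOT", "$PAR", "$FIL",
    as.vector(outer(sprintf("$P%d", seq_len(max(n_par, 1))),
                    c("N", "S", "B", "E", "R"), paste0)),
    "ANCHORNORM_SAMPLE_ID", "ANCHORNORM_BATCH_ID",
    "ANCHORNORM_ROLE", "ANCHORNORM_CONDITION")
}

#' Write an event table to an FCS 3.1 file
#'
#' Serializes an [event_table()] as FCS 3.1 with list-mode float32
#' little-endian data (`$DATATYPE/F`, `$BYTEORD/1,2,3,4`), the storage
#' layout of contemporary CyTOF exports. Carried-through keywords are
#' re-emitted; structural keywords (`$TOT`, `$PnN`, offsets, ...) are
#' regenerated from the data so they always agree with the data block.
#' Sample annotations are written under the custom `ANCHORNORM_` keyword
#' prefix, which standard readers ignore. Output is deterministic: the same
#' table always produces byte-identical files.
#'
#' @param table An [event_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_fcs()]
#' @export
write_fcs <- function(table, path) {
  stopifnot(is_event_table(table))
  mat <- et_matrix(table)
  n_events <- nrow(mat); n_par <- ncol(mat)
  delim <- "\x0c"

  kw <- et_keywords(table)
  kw <- kw[!names(kw) %in% .fcs_regenerated_keys(max(n_par, length(kw)))]
  kw <- kw[!grepl("^\\$P\\d+[NSBER]$", names(kw))]

  chans <- et_channels(table)
  out <- list()
  out[["$BEGINANALYSIS"]] <- "0"; out[["$ENDANALYSIS"]] <- "0"
  out[["$BEGINSTEXT"]] <- "0"; out[["$ENDSTEXT"]] <- "0"
  out[["$BEGINDATA"]] <- sprintf("%012d", 0)   # placeholder, fixed width
  out[["$ENDDATA"]] <- sprintf("%012d", 0)
  out[["$NEXTDATA"]] <- "0"
  out[["$MODE"]] <- "L"
  out[["$DATATYPE"]] <- "F"
  out[["$BYTEORD"]] <- "1,2,3,4"
  out[["$TOT"]] <- as.character(n_events)
  out[["$PAR"]] <- as.character(n_par)
  out[["$FIL"]] <- et_sample_id(table)
  for (i in seq_len(n_par)) {
    out[[sprintf("$P%dN", i)]] <- chans$short_name[i]
    if (!is.na(chans$antibody[i])) out[[sprintf("$P%dS", i)]] <- chans$antibody[i]
    out[[sprintf("$P%dB", i)]] <- "32"
    out[[sprintf("$P%dE", i)]] <- "0,0"
    out[[sprintf("$P%dR", i)]] <- as.character(max(1, ceiling(max(mat[, i]) + 1)))
  }
  out[["ANCHORNORM_SAMPLE_ID"]] <- et_sample_id(table)
  if (!is.na(et_batch_id(table))) out[["ANCHORNORM_BATCH_ID"]] <- et_batch_id(table)
  out[["ANCHORNORM_ROLE"]] <- et_role(table)
  if (!is.na(et_condition(table))) out[["ANCHORNORM_CONDITION"]] <- et_condition(table)
  if (length(kw)) out <- c(out, kw[order(names(kw))])

  items <- c(rbind(names(out), vapply(out, as.character, character(1))))
  if (any(grepl(delim, items, fixed = TRUE))) {
    stop("keyword or channel name contains the TEXT delimiter byte", call. = FALSE)
  }
  render_text <- function(items) paste0(delim, paste0(items, delim, collapse = ""))

  text_beg <- 58L
  text_len <- nchar(render_text(items), type = "bytes")
  text_end <- text_beg + text_len - 1L
  data_beg <- text_beg + text_len
  data_end <- data_beg + 4 * n_events * n_par - 1

  out[["$BEGINDATA"]] <- sprintf("%012.0f", as.numeric(data_beg))
  out[["$ENDDATA"]] <- sprintf("%012.0f", as.numeric(data_end))
  items <- c(rbind(names(out), vapply(out, as.character, character(1))))
  txt <- render_text(items)
  stopifnot(nchar(txt, type = "bytes") == text_len)

  hdr_off <- function(x) if (x <= 99999999) sprintf("%8.0f", as.numeric(x)) else sprintf("%8d", 0L)
  header <- paste0("FCS3.1    ", hdr_off(text_beg), hdr_off(text_end),
                   hdr_off(data_beg), hdr_off(data_end),
                   sprintf("%8d", 0L), sprintf("%8d", 0L))

  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(txt), con)
  writeBin(as.vector(t(mat)), con, size = 4L, endian = "little")
  invisible(path)
}
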