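#' Construct a recording container
#'
#' A multi-channel sampled signal as a tibble (`time` plus one column per
#' channel, uV) carrying the sample rate, an annotation table (`label`,
#' `start`, `end` in seconds, `payload` character) and free-form metadata
#' as attributes. Times are seconds, sample indexing is 0-based and all
#' intervals are half-open `[start, end)`.
#'
#' @param channels Named list of equal-length numeric vectors.
#' @param sample_rate Hz.
#' @param annotations Tibble with columns `label`, `start`, `end`,
#'   `payload`; may be empty.
#' @param metadata Named list of scalar values (seed, config echo).
#' @return A `pac_recording`.
#' @export
new_recording <- function(channels, sample_rate,
                          annotations = empty_annotations(),
                          metadata = list()) {
  lens <- vapply(channels, length, integer(1))
  if (length(unique(lens)) != 1)
    stop("length mismatch: all channels must have equal length",
         call. = FALSE)
  if (sample_rate <= 0) stop("sample_rate must be > 0", call. = FALSE)
  dur <- lens[1] / sample_rate
  if (nrow(annotations) &&
      (any(annotations$start < 0) || any(annotations$end > dur + 1e-9)))
    stop("annotations outside recording bounds", call. = FALSE)
  rec <- tibble::as_tibble(
    c(list(time = (seq_len(lens[1]) - 1L) / sample_rate), channels))
  attr(rec, "sample_rate") <- sample_rate
  attr(rec, "annotations") <- annotations
  attr(rec, "metadata") <- metadata
  class(rec) <- c("pac_recording", class(rec))
  rec
}

#' @rdname new_recording
#' @export
empty_annotations <- function() {
  tibble::tibble(label = character(), start = numeric(), end = numeric(),
                 payload = character())
}

#' Accessors for recording attributes
#'
#' @param rec A `pac_recording`.
#' @return The annotation tibble / sample rate / metadata list.
#' @export
annotations <- function(rec) attr(rec, "annotations")

#' @rdname annotations
#' @export
sample_rate <- function(rec) attr(rec, "sample_rate")

#' @rdname annotations
#' @export
rec_metadata <- function(rec) attr(rec, "metadata")

#' @export
print.pac_recording <- function(x, ...) {
  cat(sprintf("<pac_recording> %d channels x %d samples @ %g Hz (%g s), %d annotations\n",
              ncol(x) - 1L, nrow(x), sample_rate(x),
              nrow(x) / sample_rate(x), nrow(annotations(x))))
  NextMethod()
}

#' Per-sample validity mask from stimulation-epoch annotations
#'
#' FALSE during every annotated epoch whose label matches, extended by a
#' guard margin on both sides — the digital recording/stimulation gate
#' leaves those samples artifact-dominated, so they must be excluded
#' from baselines, z-maps and coupling windows.
#'
#' @param rec A `pac_recording`.
#' @param labels Annotation labels treated as stimulation epochs.
#' @param guard Guard margin, s; default 1.
#' @return Logical vector, one entry per sample (TRUE = valid).
#' @export
epoch_mask <- function(rec, labels = "stim", guard = 1) {
  ann <- annotations(rec)
  mask <- rep(TRUE, nrow(rec))
  fs <- sample_rate(rec)
  times <- rec$time
  for (i in which(ann$label %in% labels)) {
    mask[times >= ann$start[i] - guard & times < ann$end[i] + guard] <- FALSE
  }
  mask
}

#' Write a recording to disk
#'
#' Two dialects, auto-detected from the extension. `.csv` / `.tsv`:
#' UTF-8 delimited text with `#`-prefixed header lines carrying the
#' sample rate, metadata and annotations, then one row per sample; values
#' are printed so they re-parse exactly. `.feather`: arrow binary
#' columnar file; attributes ride along bit-exactly (needs the `arrow`
#' package).
#'
#' @param rec A `pac_recording`.
#' @param path Output path ending in `.csv`, `.tsv` or `.feather`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "feather") {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("the arrow package is required for feather output", call. = FALSE)
    arrow::write_feather(rec, path)
    return(invisible(path))
  }
  if (!ext %in% c("csv", "tsv"))
    stop("unknown recording extension '.", ext,
         "' (use .csv, .tsv or .feather)", call. = FALSE)
  sep <- if (ext == "csv") "," else "\t"
  ann <- annotations(rec)
  md <- rec_metadata(rec)
  header <- c(
    "# pacstim recording v1",
    sprintf("# sample_rate: %s", format_num(sample_rate(rec))),
    vapply(names(md), function(k)
      sprintf("# meta %s: %s", k, as.character(md[[k]])), character(1)),
    vapply(seq_len(nrow(ann)), function(i)
      sprintf("# annotation: %s\t%s\t%s\t%s", ann$label[i],
              format_num(ann$start[i]), format_num(ann$end[i]),
              ann$payload[i]), character(1)))
  chans <- setdiff(names(rec), "time")
  body_cols <- lapply(rec[chans], format_num)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  writeLines(paste(chans, collapse = sep), con, sep = "\n")
  writeLines(do.call(paste, c(body_cols, sep = sep)), con, sep = "\n")
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path Path ending in `.csv`, `.tsv` or `.feather`.
#' @return A `pac_recording`.
#' @export
read_recording <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "feather") {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("the arrow package is required for feather input", call. = FALSE)
    rec <- tibble::as_tibble(arrow::read_feather(path))
    if (is.null(attr(rec, "sample_rate")))
      stop("malformed header: feather file lacks pacstim attributes",
           call. = FALSE)
    class(rec) <- c("pac_recording", class(rec))
    return(rec)
  }
  if (!ext %in% c("csv", "tsv"))
    stop("unknown recording extension '.", ext, "'", call. = FALSE)
  sep <- if (ext == "csv") "," else "\t"
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  hdr <- lines[is_hdr]
  if (!length(hdr) || !any(grepl("^# sample_rate: ", hdr)))
    stop("malformed header: missing sample_rate", call. = FALSE)
  fs <- as.numeric(sub("^# sample_rate: ", "",
                       grep("^# sample_rate: ", hdr, value = TRUE)[1]))
  md_lines <- grep("^# meta ", hdr, value = TRUE)
  md <- list()
  for (m in md_lines) {
    kv <- sub("^# meta ", "", m)
    k <- sub(":.*$", "", kv)
    md[[k]] <- sub("^[^:]*: ", "", kv)
  }
  ann_lines <- grep("^# annotation: ", hdr, value = TRUE)
  ann <- if (length(ann_lines)) {
    parts <- strsplit(sub("^# annotation: ", "", ann_lines), "\t",
                      fixed = TRUE)
    tibble::tibble(
      label = vapply(parts, `[`, character(1), 1),
      start = as.numeric(vapply(parts, `[`, character(1), 2)),
      end = as.numeric(vapply(parts, `[`, character(1), 3)),
      payload = vapply(parts, function(p)
        if (length(p) >= 4) p[4] else "", character(1)))
  } else empty_annotations()
  body <- lines[!is_hdr]
  chans <- strsplit(body[1], sep, fixed = TRUE)[[1]]
  rows <- strsplit(body[-1], sep, fixed = TRUE)
  if (any(lengths(rows) != length(chans)))
    stop("length mismatch: data rows do not match channel count",
         call. = FALSE)
  vals <- matrix(as.numeric(unlist(rows)), ncol = length(chans),
                 byrow = TRUE)
  if (anyNA(vals)) stop("malformed numeric data", call. = FALSE)
  channels <- stats::setNames(
    lapply(seq_along(chans), function(j) vals[, j]), chans)
  new_recording(channels, fs, ann, md)
}
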