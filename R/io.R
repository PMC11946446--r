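# CSV dialects: one row per sample with a timestamp column plus 14 channel
# columns (the layout of consumer-headset exports), and feature tables with
# label columns. Metadata travels in a JSON sidecar next to the data file.

.meta_path <- function(path) paste0(path, ".meta.json")

#' Write / read a recording in the CSV export dialect
#'
#' One row per sample: a `Timestamp` column (seconds from recording start)
#' plus one column per channel in microvolt. Subject, LED condition,
#' trajectory, repetition, seed, and sampling rate go to a JSON sidecar
#' (`<path>.meta.json`), so a write/read round trip is lossless.
#'
#' @param recording A `bci_recording`.
#' @param path CSV file path.
#' @return `write_recording_csv()`: the path, invisibly.
#' @export
write_recording_csv <- function(recording, path) {
  stopifnot(inherits(recording, "bci_recording"))
  n <- nrow(recording$samples)
  df <- data.frame(Timestamp = (seq_len(n) - 1) / recording$fs,
                   recording$samples, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  meta <- c(recording$meta, list(fs = recording$fs))
  jsonlite::write_json(meta, .meta_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_recording_csv
#' @param channels Channel columns required in the file.
#' @param fs Sampling rate, used when no sidecar is present.
#' @return `read_recording_csv()`: a `bci_recording`.
#' @export
read_recording_csv <- function(path, channels = EMOTIV_CHANNELS, fs = 256) {
  df <- read.csv(path, check.names = FALSE, colClasses = "character")
  missing <- setdiff(channels, names(df))
  if (length(missing))
    stop("missing channel column(s): ", paste(missing, collapse = ", "))
  samples <- vapply(channels, function(ch) {
    v <- suppressWarnings(as.numeric(df[[ch]]))
    bad <- which(is.na(v) & !is.na(df[[ch]]) & nzchar(df[[ch]]))
    if (length(bad))
      stop("non-numeric value in column ", ch, " at data row ", bad[1])
    if (anyNA(v))
      stop("missing value in column ", ch, " at data row ", which(is.na(v))[1])
    v
  }, numeric(nrow(df)))
  meta <- list(subject_id = NA_integer_, led_condition = NA_character_,
               trajectory = NA_character_, repetition = NA_integer_,
               seed = NULL)
  mp <- .meta_path(path)
  if (file.exists(mp)) {
    m <- jsonlite::read_json(mp, simplifyVector = TRUE)
    fs <- m$fs %||% fs
    for (f in intersect(names(meta), names(m))) meta[[f]] <- m[[f]]
  }
  structure(list(samples = samples, fs = fs, meta = meta),
            class = "bci_recording")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a feature table with labels
#'
#' Features as `feature_0001`, ... columns plus the per-segment metadata
#' columns; the feature-id map (channel, band, statistic per id) goes to a
#' JSON sidecar.
#'
#' @param features Feature matrix.
#' @param meta Per-segment metadata frame (as produced by the feature
#'   extractors).
#' @param path CSV file path.
#' @param id_map Optional [feature_id_map()] frame for the sidecar.
#' @return `write_feature_csv()`: the path, invisibly.
#' @export
write_feature_csv <- function(features, meta, path, id_map = NULL) {
  features <- as.matrix(features)
  colnames(features) <- sprintf("feature_%04d", seq_len(ncol(features)))
  write.csv(data.frame(meta, features, check.names = FALSE), path,
            row.names = FALSE)
  if (!is.null(id_map))
    jsonlite::write_json(id_map, .meta_path(path), digits = NA)
  invisible(path)
}

#' @rdname write_feature_csv
#' @return `read_feature_csv()`: list with `features`, `meta`, and (when a
#'   sidecar exists) `id_map`.
#' @export
read_feature_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  fcols <- grep("^feature_\\d+$", names(df))
  out <- list(features = as.matrix(df[, fcols, drop = FALSE]),
              meta = df[, -fcols, drop = FALSE])
  mp <- .meta_path(path)
  if (file.exists(mp))
    out$id_map <- as.data.frame(jsonlite::read_json(mp, simplifyVector = TRUE))
  out
}
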