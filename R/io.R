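# CSV with "# key: value" comment headers; all tabular outputs carry the
# run seed and a fingerprint of the configuration so runs are traceable.
writeCsvWithHeader <- function(df, file, meta = character()) {
  con <- file(file, "w")
  on.exit(close(con))
  for (nm in names(meta))
    writeLines(sprintf("# %s: %s", nm, meta[[nm]]), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(file)
}

readCsvWithHeader <- function(file) {
  lines <- readLines(file)
  hdr <- grep("^# ", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^# ", "", h)
    key <- sub(":.*$", "", kv)
    meta[[key]] <- sub("^[^:]*: ?", "", kv)
  }
  df <- utils::read.csv(text = paste(lines[!startsWith(lines, "# ")],
                                     collapse = "\n"))
  attr(df, "meta") <- meta
  df
}

#' Write a track to CSV
#'
#' Columns: `frame`, `time_s`, `arena`, `x_px`, `y_px`, `detected`,
#' `interpolated`.  The fps and frame window go into `# key: value` comment
#' headers so the track round-trips.
#'
#' @param track a [Track-class].
#' @param file output path.
#' @param meta extra named character metadata for the header.
#' @return `file`, invisibly.
#' @export
writeTrack <- function(track, file, meta = character()) {
  s <- track@samples
  df <- data.frame(frame = s$frame, time_s = s$frame / track@fps,
                   arena = track@arenaId, x_px = s$x, y_px = s$y,
                   detected = s$detected, interpolated = s$interpolated)
  writeCsvWithHeader(df, file, c(meta, fps = format(track@fps),
                                 startFrame = track@startFrame,
                                 endFrame = track@endFrame))
}

#' Read a track written by [writeTrack()]
#'
#' @param file CSV path.
#' @return a [Track-class].
#' @export
readTrack <- function(file) {
  df <- readCsvWithHeader(file)
  meta <- attr(df, "meta")
  new("Track", arenaId = as.character(df$arena[1L]),
      fps = as.numeric(meta$fps),
      samples = data.frame(frame = as.integer(df$frame), x = df$x_px,
                           y = df$y_px, detected = as.logical(df$detected),
                           interpolated = as.logical(df$interpolated)),
      startFrame = as.integer(meta$startFrame),
      endFrame = as.integer(meta$endFrame))
}

#' Write a dissimilarity matrix to CSV
#'
#' @param dmat a [DissimilarityMatrix-class].
#' @param file output path.
#' @param meta extra header metadata.
#' @return `file`, invisibly.
#' @export
writeDissimilarity <- function(dmat, file, meta = character()) {
  m <- as.matrix(dmat)
  df <- data.frame(subject = rownames(m), m, check.names = FALSE)
  writeCsvWithHeader(df, file, meta)
}
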