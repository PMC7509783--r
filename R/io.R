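# Plain-text readers/writers for the formats the pipeline exchanges:
# tachogram (one RR per line), beat annotations, protocol markers, VAS scores.

#' Read a tachogram file
#'
#' One RR interval per line; `#`-prefixed comment lines and blank lines are
#' ignored. Units may be ms (default) or seconds.
#'
#' @param path file path.
#' @param unit `"ms"` or `"s"`.
#' @return An [rr_series()].
#' @export
read_tachogram <- function(path, unit = c("ms", "s")) {
  unit <- match.arg(unit)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rr <- suppressWarnings(as.numeric(lines))
  if (anyNA(rr))
    stop(sprintf("read_tachogram: non-numeric value at data line %d of %s",
                 which(is.na(rr))[1], path))
  if (unit == "s") rr <- rr * 1000
  rr_series(rr)
}

#' Write a tachogram file (one RR interval in ms per line)
#' @param rr an [rr_series()].
#' @param path file path.
#' @export
write_tachogram <- function(rr, path) {
  stopifnot(inherits(rr, "rr_series"))
  writeLines(c("# RR intervals (ms), one per line",
               format(rr$rr, trim = TRUE, scientific = FALSE)), path)
  invisible(path)
}

#' Read beat annotations (CSV with columns `time_ms,label`)
#'
#' Labels are `N`, `V`, `S`, `A`. A validation failure reports the offending
#' file and line.
#'
#' @param path file path.
#' @param subject_id optional subject identifier to attach.
#' @return A [beat_series()].
#' @export
read_beats <- function(path, subject_id = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_ms", "label") %in% names(df)))
    stop("read_beats: expected columns time_ms,label in ", path)
  bad <- which(diff(df$time_ms) <= 0)
  if (length(bad) > 0L)
    stop(sprintf("read_beats: non-increasing beat time in %s at data line %d",
                 path, bad[1] + 2L))  # +1 for header, +1 for the later of the pair
  beat_series(df$time_ms, df$label, subject_id = subject_id)
}

#' Write beat annotations as CSV
#' @param beats a [beat_series()].
#' @param path file path.
#' @export
write_beats <- function(beats, path) {
  stopifnot(inherits(beats, "beat_series"))
  write.csv(data.frame(time_ms = beats$times, label = beats$labels),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read protocol markers (CSV with columns `label,time_ms`)
#' @param path file path.
#' @return data.frame with columns `label`, `time_ms`, ordered T1..T9.
#' @export
read_markers <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("label", "time_ms") %in% names(df)))
    stop("read_markers: expected columns label,time_ms in ", path)
  if (!all(df$label %in% paste0("T", 1:9)))
    stop("read_markers: marker labels must be T1..T9")
  df[order(match(df$label, paste0("T", 1:9))), c("label", "time_ms")]
}

#' Write protocol markers as CSV
#' @param markers data.frame with columns `label`, `time_ms`.
#' @param path file path.
#' @export
write_markers <- function(markers, path) {
  write.csv(markers[, c("label", "time_ms")], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Read a VAS score table (CSV with columns `subject,period,score`)
#'
#' Missing scores may be encoded as empty cells or `NA`.
#' @param path file path.
#' @return data.frame with columns `subject`, `period`, `score`.
#' @export
read_vas <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("subject", "period", "score") %in% names(df)))
    stop("read_vas: expected columns subject,period,score in ", path)
  df$score <- suppressWarnings(as.numeric(df$score))
  df
}

#' Write a VAS score table as CSV
#' @param vas data.frame with columns `subject`, `period`, `score`.
#' @param path file path.
#' @export
write_vas <- function(vas, path) {
  write.csv(vas[, c("subject", "period", "score")], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}
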