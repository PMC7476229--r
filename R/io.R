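## TSV persistence.  All analysis outputs are plain tab-separated text
## with a "." decimal point regardless of locale; numeric columns are
## written with 17 significant digits so that write/read round trips are
## lossless at double precision.

fmtNum <- function(x) {
  out <- vapply(x, function(v)
    if (is.na(v)) "NA" else sprintf("%.17g", v), character(1))
  out
}

writeTsv <- function(df, path, header = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  for (nm in names(df)) if (is.double(df[[nm]])) df[[nm]] <- fmtNum(df[[nm]])
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     dec = ".")
  invisible(path)
}

readTsv <- function(path) {
  utils::read.delim(path, comment.char = "#", sep = "\t",
                    stringsAsFactors = FALSE, dec = ".")
}

checkSchema <- function(df, required, what) {
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(errorCondition(
      sprintf("%s is missing required column(s): %s", what,
              paste(miss, collapse = ", ")),
      class = c("infantERP_schemaError", "error")))
  invisible(df)
}

#' Write / read a raw recording as TSV
#'
#' The trace is written as a wide samples-by-channels table (column
#' `sample` plus one column per electrode, uV) preceded by commented
#' metadata lines (`subject`, `visit`, `sample_rate`); events go to a
#' companion `*_events.tsv` with columns `onset`, `condition`, `block`,
#' `lookaway`.
#'
#' @param raw a [RawRecording-class].
#' @param dir output directory (created if needed).
#' @return (invisibly) the paths written.
#' @export
writeRecording <- function(raw, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stem <- file.path(dir, sprintf("%s_v%d", raw@subject, raw@visit))
  dataPath <- paste0(stem, "_eeg.tsv")
  con <- file(dataPath, open = "wt", encoding = "UTF-8")
  writeLines(c(sprintf("# subject=%s", raw@subject),
               sprintf("# visit=%d", raw@visit),
               sprintf("# sample_rate=%g", raw@sampleRate)), con)
  df <- cbind(data.frame(sample = seq_len(ncol(raw@data))),
              as.data.frame(t(raw@data)))
  names(df) <- c("sample", raw@channels)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  evPath <- paste0(stem, "_events.tsv")
  writeTsv(raw@events, evPath)
  invisible(c(dataPath, evPath))
}

#' @rdname writeRecording
#' @param subject,visit identify the recording to read back.
#' @export
readRecording <- function(dir, subject, visit) {
  stem <- file.path(dir, sprintf("%s_v%d", subject, as.integer(visit)))
  dataPath <- paste0(stem, "_eeg.tsv")
  meta <- readLines(dataPath, n = 10)
  meta <- meta[startsWith(meta, "# ")]
  kv <- strsplit(sub("^# ", "", meta), "=")
  vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  df <- readTsv(dataPath)
  checkSchema(df, "sample", "recording table")
  events <- readTsv(paste0(stem, "_events.tsv"))
  checkSchema(events, c("onset", "condition", "block", "lookaway"),
              "events table")
  events$lookaway <- as.logical(events$lookaway)
  channels <- setdiff(names(df), "sample")
  dat <- t(as.matrix(df[channels]))
  rownames(dat) <- channels
  new("RawRecording", subject = as.character(vals[["subject"]]),
      visit = as.integer(vals[["visit"]]),
      sampleRate = as.numeric(vals[["sample_rate"]]),
      channels = channels, data = dat, events = events)
}

#' Write / read the tidy component-scores table
#'
#' Schema: `subject`, `visit`, `component`, `condition`, `measure`,
#' `value`.  Reading validates the schema and raises a classed error
#' (`"infantERP_schemaError"`) naming any missing column.
#'
#' @param scores tidy scores data.frame from [scoreComponents()].
#' @param path TSV path.
#' @return `writeScores` the path (invisibly); `readScores` the table.
#' @export
writeScores <- function(scores, path) {
  checkSchema(scores, c("subject", "visit", "component", "condition",
                        "measure", "value"), "scores table")
  writeTsv(scores, path)
}

#' @rdname writeScores
#' @export
readScores <- function(path) {
  df <- readTsv(path)
  checkSchema(df, c("subject", "visit", "component", "condition",
                    "measure", "value"), "scores table")
  df$value <- as.numeric(df$value)
  df
}

#' Write transition tables as long-format TSV
#'
#' One row per component and cell: `component`, `from_state`, `to_state`,
#' `count`, `probability`, plus the summary percentages repeated per
#' component.
#'
#' @param tabs named list of [TransitionTable-class] objects.
#' @param path TSV path.
#' @return the path, invisibly.
#' @export
writeTransitionTables <- function(tabs, path) {
  rows <- list()
  for (tab in tabs) {
    s <- tab@summary
    for (i in 1:3) for (j in 1:3)
      rows[[length(rows) + 1L]] <- data.frame(
        component = tab@component,
        from_state = stateLevels()[i], to_state = stateLevels()[j],
        count = tab@counts[i, j], probability = tab@probabilities[i, j],
        dominant = s$dominant[1],
        dominant_share_v1 = s$dominantShareV1,
        dominant_share_v2 = s$dominantShareV2,
        persistence = s$persistence, mover_share = s$moverShare,
        both_visit_share = s$bothVisitShare,
        stringsAsFactors = FALSE)
  }
  writeTsv(do.call(rbind, rows), path)
}
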