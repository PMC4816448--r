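#' Read and write TRC marker files
#'
#' TRC is the tab-separated trajectory format used by Motion Analysis and
#' OpenSim: a `PathFileType` line, a header block with `DataRate`,
#' `NumFrames`, `NumMarkers` and `Units`, two label rows, then one row per
#' frame starting with the frame number and time stamp. Blank coordinate
#' fields are gaps. Units of `m` or `cm` are converted to millimetres.
#'
#' @param path file path.
#' @return `read_trc` returns a [marker_dataset()].
#' @export
read_trc <- function(path) {
  if (!file.exists(path)) mf_stop("io_error", "cannot read '%s'", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6L || !grepl("^PathFileType", lines[1]))
    mf_stop("format_error", "'%s' is not a TRC file", path)
  keys <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  vals <- strsplit(lines[3], "\t", fixed = TRUE)[[1]]
  hdr <- setNames(as.list(vals[seq_along(keys)]), keys)
  frame_rate <- as.numeric(hdr[["DataRate"]])
  n_mark <- as.integer(hdr[["NumMarkers"]])
  units <- tolower(trimws(hdr[["Units"]] %||% "mm"))
  if (is.na(frame_rate) || is.na(n_mark))
    mf_stop("format_error", "TRC header lacks DataRate/NumMarkers")
  labrow <- strsplit(lines[4], "\t", fixed = TRUE)[[1]]
  labels <- labrow[-(1:2)]
  labels <- labels[nzchar(trimws(labels))][seq_len(n_mark)]
  if (anyNA(labels))
    mf_stop("format_error", "TRC label row lists fewer than NumMarkers names")
  data_lines <- lines[-(1:5)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  nc <- 2L + 3L * n_mark
  rows <- lapply(seq_along(data_lines), function(i) {
    f <- strsplit(data_lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < nc) f <- c(f, rep("", nc - length(f)))
    f <- trimws(f[3:nc])
    f[f == "" | toupper(f) == "NAN"] <- NA_character_
    suppressWarnings(as.numeric(f))
  })
  vals <- do.call(rbind, rows)
  validate_dataset(marker_dataset(vals, labels, frame_rate, units))
}

#' @rdname read_trc
#' @param x a [marker_dataset()].
#' @export
write_trc <- function(x, path) {
  stopifnot(inherits(x, "marker_dataset"))
  con <- tryCatch(file(path, "w"), error = function(e)
    mf_stop("io_error", "cannot write '%s': %s", path, conditionMessage(e)))
  on.exit(close(con))
  n <- n_frames(x); m <- n_markers(x)
  writeLines(sprintf("PathFileType\t4\t(X/Y/Z)\t%s", basename(path)), con)
  writeLines(paste(c("DataRate", "CameraRate", "NumFrames", "NumMarkers",
                     "Units", "OrigDataRate", "OrigDataStartFrame",
                     "OrigNumFrames"), collapse = "\t"), con)
  writeLines(sprintf("%.10g\t%.10g\t%d\t%d\tmm\t%.10g\t1\t%d",
                     x$frame_rate, x$frame_rate, n, m, x$frame_rate, n), con)
  writeLines(paste(c("Frame#", "Time",
                     as.vector(rbind(x$labels, "", ""))), collapse = "\t"), con)
  writeLines(paste(c("", "", paste0(rep(c("X", "Y", "Z"), m),
                                    rep(seq_len(m), each = 3L))),
                   collapse = "\t"), con)
  t <- (seq_len(n) - 1L) / x$frame_rate
  body <- vapply(seq_len(n), function(i) {
    s <- sprintf("%.10g", x$data[i, ])
    s[is.na(x$data[i, ])] <- ""
    paste(c(sprintf("%d", i), sprintf("%.10g", t[i]), s), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
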