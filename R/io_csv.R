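#' Read and write marker trajectories as CSV
#'
#' The CSV dialect is a plain coordinate table: one row per frame, a header
#' of `<label>_X, <label>_Y, <label>_Z` column names, missing values as
#' empty cells or `NaN`, and an optional comment line `# frame_rate=<Hz>`
#' before the header. Coordinates are assumed to be in millimetres unless
#' `units` says otherwise.
#'
#' @param path file path.
#' @param units unit tag for the stored coordinates (`"mm"`, `"cm"`,
#'   `"m"`); values are converted to mm.
#' @return `read_mocap_csv` returns a [marker_dataset()].
#' @export
read_mocap_csv <- function(path, units = "mm") {
  if (!file.exists(path)) mf_stop("io_error", "cannot read '%s'", path)
  lines <- readLines(path, warn = FALSE)
  frame_rate <- 100
  comments <- grepl("^\\s*#", lines)
  for (cl in lines[comments]) {
    hit <- regmatches(cl, regexec("frame_rate\\s*=\\s*([0-9.eE+-]+)", cl))[[1]]
    if (length(hit) == 2L) frame_rate <- as.numeric(hit[2])
  }
  lines <- lines[!comments & nzchar(trimws(lines))]
  if (length(lines) < 2L) mf_stop("format_error", "no data rows in '%s'", path)
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  labels <- parse_coord_header(trimws(header))
  body_lines <- lines[-1]
  fields <- strsplit(body_lines, ",", fixed = TRUE)
  nc <- length(header)
  for (i in seq_along(fields)) {
    # strsplit drops a single trailing empty cell; restore it
    if (endsWith(body_lines[i], ","))
      fields[[i]] <- c(fields[[i]], "")
    if (length(fields[[i]]) != nc)
      mf_stop("format_error", "row %d has %d fields, expected %d",
              i, length(fields[[i]]), nc)
  }
  vals <- suppressWarnings(
    matrix(as.numeric(vapply(fields, function(f) {
      f <- trimws(f)
      f[f == "" | toupper(f) %in% c("NA", "NAN")] <- NA_character_
      f
    }, character(nc))), ncol = nc, byrow = TRUE))
  validate_dataset(marker_dataset(vals, labels, frame_rate, units))
}

# check <label>_X,<label>_Y,<label>_Z triples; return labels
parse_coord_header <- function(header) {
  if (length(header) %% 3L != 0L)
    mf_stop("format_error", "header has %d columns, not a multiple of 3",
            length(header))
  suf <- sub("^.*_", "", header)
  lab <- sub("_[XYZxyz]$", "", header)
  m <- length(header) %/% 3L
  for (j in seq_len(m)) {
    k <- (3L * j - 2L):(3L * j)
    if (!identical(toupper(suf[k]), c("X", "Y", "Z")) ||
        length(unique(lab[k])) != 1L)
      mf_stop("format_error",
              "columns %d-%d do not form an X,Y,Z triple for one label (near '%s')",
              k[1], k[3], paste(unique(lab[k]), collapse = "'/'"))
  }
  lab[seq(1L, length(header), by = 3L)]
}

#' @rdname read_mocap_csv
#' @param x a [marker_dataset()].
#' @export
write_mocap_csv <- function(x, path) {
  stopifnot(inherits(x, "marker_dataset"))
  con <- tryCatch(file(path, "w"), error = function(e)
    mf_stop("io_error", "cannot write '%s': %s", path, conditionMessage(e)))
  on.exit(close(con))
  writeLines(sprintf("# frame_rate=%.10g", x$frame_rate), con)
  writeLines(paste(colnames(x$data), collapse = ","), con)
  body <- apply(x$data, 1L, function(row) {
    s <- sprintf("%.10g", row)
    s[is.na(row)] <- ""
    paste(s, collapse = ",")
  })
  writeLines(body, con)
  invisible(path)
}
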