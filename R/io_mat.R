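#' Read a study-container dataset
#'
#' Reads a MATLAB v5 `.mat` file holding a numeric array named `Data`
#' with the `n x 3m` measurement matrix, the layout used by published
#' motion-capture supplements. Only uncompressed MAT v5 elements are
#' supported; a compressed element raises a format error. Marker labels
#' are not stored in this container, so `M1 ... Mm` are generated; the
#' frame rate must be supplied by the caller.
#'
#' @param path file path.
#' @param frame_rate capture rate in Hz (the container does not store it).
#' @param units unit tag of the stored coordinates; converted to mm.
#' @return A [marker_dataset()].
#' @export
read_study_dataset <- function(path, frame_rate, units = "mm") {
  if (missing(frame_rate))
    mf_stop("parameter_error", "frame_rate must be supplied for study containers")
  vars <- read_mat5(path)
  if (!"Data" %in% names(vars))
    mf_stop("format_error", "'%s' holds no array named 'Data'", path)
  d <- vars[["Data"]]
  validate_dataset(marker_dataset(d, NULL, frame_rate, units))
}

# minimal MAT v5 parser: numeric matrices, little-endian, uncompressed
read_mat5 <- function(path) {
  if (!file.exists(path)) mf_stop("io_error", "cannot read '%s'", path)
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 128L) mf_stop("format_error", "'%s': not a MAT file", path)
  endian <- rawToChar(raw[127:128])
  if (!endian %in% c("IM", "MI"))
    mf_stop("format_error", "'%s': missing MAT v5 endian indicator", path)
  if (endian == "MI")
    mf_stop("format_error", "big-endian MAT files are not supported")
  pos <- 129L
  vars <- list()
  while (pos + 8L <= length(raw) + 1L) {
    type <- readBin(raw[pos:(pos + 3L)], "integer", size = 4L, endian = "little")
    nb <- readBin(raw[(pos + 4L):(pos + 7L)], "integer", size = 4L,
                  endian = "little")
    if (type == 15L)
      mf_stop("format_error",
              "compressed MAT element found; re-save the file uncompressed")
    if (type == 14L) {
      v <- parse_mi_matrix(raw[(pos + 8L):(pos + 7L + nb)])
      if (!is.null(v)) vars[[v$name]] <- v$value
    }
    pos <- pos + 8L + nb + (-nb %% 8L)
  }
  vars
}

mat5_numeric <- function(bytes, type) {
  switch(as.character(type),
    `1` = readBin(bytes, "integer", length(bytes), size = 1L),
    `2` = as.integer(bytes),
    `3` = readBin(bytes, "integer", length(bytes) / 2L, size = 2L,
                  endian = "little"),
    `4` = readBin(bytes, "integer", length(bytes) / 2L, size = 2L,
                  endian = "little", signed = FALSE),
    `5` = readBin(bytes, "integer", length(bytes) / 4L, size = 4L,
                  endian = "little"),
    `6` = readBin(bytes, "integer", length(bytes) / 4L, size = 4L,
                  endian = "little"),
    `7` = readBin(bytes, "double", length(bytes) / 4L, size = 4L,
                  endian = "little"),
    `9` = readBin(bytes, "double", length(bytes) / 8L, size = 8L,
                  endian = "little"),
    mf_stop("format_error", "unsupported MAT data type %d", type))
}

parse_mi_matrix <- function(bytes) {
  pos <- 1L
  sub <- list()
  while (pos + 4L <= length(bytes) + 1L) {
    word <- readBin(bytes[pos:(pos + 3L)], "integer", size = 4L,
                    endian = "little")
    small_nb <- bitwShiftR(bitwAnd(word, -65536L), 16L) # high 16 bits
    if (small_nb != 0L) {                    # small element: 4 data bytes
      type <- bitwAnd(word, 65535L)
      nb <- small_nb
      dat <- bytes[(pos + 4L):(pos + 3L + nb)]
      pos <- pos + 8L
    } else {
      type <- word
      nb <- readBin(bytes[(pos + 4L):(pos + 7L)], "integer", size = 4L,
                    endian = "little")
      dat <- if (nb > 0L) bytes[(pos + 8L):(pos + 7L + nb)] else raw(0)
      pos <- pos + 8L + nb + (-nb %% 8L)
    }
    sub[[length(sub) + 1L]] <- list(type = type, bytes = dat)
  }
  if (length(sub) < 4L) return(NULL)
  flags <- sub[[1L]]
  cls <- as.integer(flags$bytes[1L])
  if (!cls %in% c(6L, 7L, 8L, 9L:15L)) return(NULL)  # keep numeric classes
  dims <- mat5_numeric(sub[[2L]]$bytes, sub[[2L]]$type)
  nm <- rawToChar(sub[[3L]]$bytes[sub[[3L]]$bytes != as.raw(0)])
  vals <- mat5_numeric(sub[[4L]]$bytes, sub[[4L]]$type)
  list(name = nm, value = matrix(as.numeric(vals), dims[1L], dims[2L]))
}

# companion writer (used for fixtures and round-trip checks)
write_mat5 <- function(vars, path) {
  con <- tryCatch(file(path, "wb"), error = function(e)
    mf_stop("io_error", "cannot write '%s': %s", path, conditionMessage(e)))
  on.exit(close(con))
  hdr <- charToRaw(sprintf("MATLAB 5.0 MAT-file, written by markerfill"))
  writeBin(c(hdr, raw(116L - length(hdr))), con)
  writeBin(raw(8L), con)                                   # subsys offset
  writeBin(as.raw(c(0x00, 0x01)), con)                     # version 0x0100
  writeBin(charToRaw("IM"), con)
  for (nm in names(vars)) {
    v <- as.matrix(vars[[nm]])
    name_b <- charToRaw(nm)
    name_pad <- -length(name_b) %% 8L
    nb <- 16L + 16L + 8L + length(name_b) + name_pad + 8L + 8L * length(v)
    writeBin(c(14L, nb), con, size = 4L, endian = "little")
    writeBin(c(6L, 8L), con, size = 4L, endian = "little")  # array flags
    writeBin(c(6L, 0L), con, size = 4L, endian = "little")  # class double
    writeBin(c(5L, 8L), con, size = 4L, endian = "little")  # dims
    writeBin(c(nrow(v), ncol(v)), con, size = 4L, endian = "little")
    writeBin(c(1L, length(name_b)), con, size = 4L, endian = "little")
    writeBin(c(name_b, raw(name_pad)), con)
    writeBin(c(9L, 8L * length(v)), con, size = 4L, endian = "little")
    writeBin(as.numeric(v), con, size = 8L, endian = "little")
  }
  invisible(path)
}
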