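#' Read and write C3D motion-capture files
#'
#' A self-contained reader and writer for the biomechanics-standard C3D
#' container, covering the subset the package needs: Intel
#' (little-endian) files, 3D point data in floating-point or scaled
#' integer form, marker labels and units from the `POINT` parameter
#' group. Analog channels are skipped. Points flagged invalid (negative
#' residual) or stored as all-zero are converted to gaps; `m`/`cm` units
#' are converted to millimetres. The writer emits floating-point Intel
#' files with a single parameter section.
#'
#' @param path file path.
#' @return `read_c3d` returns a [marker_dataset()].
#' @export
read_c3d <- function(path) {
  if (!file.exists(path)) mf_stop("io_error", "cannot read '%s'", path)
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 512L) mf_stop("format_error", "'%s': truncated C3D", path)
  i16 <- function(at, n = 1L)
    readBin(raw[at:(at + 2L * n - 1L)], "integer", n, size = 2L,
            endian = "little")
  f32 <- function(at, n = 1L)
    readBin(raw[at:(at + 4L * n - 1L)], "double", n, size = 4L,
            endian = "little")
  pb <- as.integer(raw[1])
  if (as.integer(raw[2]) != 0x50L)
    mf_stop("format_error", "'%s' is not a C3D file", path)
  np <- i16(3); nanalog <- i16(5)
  first <- i16(7); last <- i16(9)
  scale <- f32(13)
  data_start <- i16(17)
  frame_rate <- f32(21)
  if (np < 1L) mf_stop("format_error", "C3D declares no 3D points")

  # parameter section
  p0 <- (pb - 1L) * 512L
  proc <- as.integer(raw[p0 + 4L])
  if (proc != 84L)
    mf_stop("format_error",
            "unsupported C3D processor type %d (only Intel/84)", proc)
  groups <- list()   # id -> name
  params <- list()   # "<gid>:<name>" -> value
  pos <- p0 + 5L
  repeat {
    if (pos > length(raw)) break
    nname <- readBin(raw[pos], "integer", size = 1L)
    id <- readBin(raw[pos + 1L], "integer", size = 1L)
    if (nname == 0L || id == 0L) break
    name <- toupper(rawToChar(raw[(pos + 2L):(pos + 1L + abs(nname))]))
    off_at <- pos + 2L + abs(nname)
    offset <- i16(off_at)
    nxt <- off_at + 2L + offset
    if (id < 0L) {
      groups[[as.character(-id)]] <- name
    } else {
      elsize <- readBin(raw[off_at + 2L], "integer", size = 1L)
      ndims <- as.integer(raw[off_at + 3L])
      dims <- if (ndims > 0L)
        as.integer(raw[(off_at + 4L):(off_at + 3L + ndims)]) else integer()
      dat_at <- off_at + 4L + ndims
      count <- if (length(dims)) prod(dims) else 1L
      val <- switch(as.character(elsize),
        `-1` = rawToChar(raw[dat_at:(dat_at + count - 1L)]),
        `1`  = as.integer(raw[dat_at:(dat_at + count - 1L)]),
        `2`  = i16(dat_at, count),
        `4`  = f32(dat_at, count),
        NULL)
      if (elsize == -1L && length(dims) >= 2L)
        val <- apply(matrix(strsplit(val, "")[[1]], nrow = dims[1]), 2L,
                     function(ch) trimws(paste(ch, collapse = "")))
      params[[paste0(id, ":", name)]] <- val
    }
    if (offset == 0L) break
    pos <- nxt
  }
  point_gid <- names(groups)[vapply(groups, identical, logical(1), "POINT")]
  getp <- function(nm) if (length(point_gid))
    params[[paste0(point_gid[1], ":", nm)]] else NULL
  labels <- getp("LABELS")
  units <- tolower(trimws(getp("UNITS") %||% "mm"))
  if (!nzchar(units)) units <- "mm"

  # point data
  nf <- last - first + 1L
  vpf <- np * 4L + nanalog           # values per frame, analog interleaved
  d0 <- (data_start - 1L) * 512L
  if (scale < 0) {
    vals <- f32(d0 + 1L, nf * vpf)
  } else {
    vals <- as.numeric(i16(d0 + 1L, nf * vpf))
  }
  vals <- matrix(vals, nrow = nf, ncol = vpf, byrow = TRUE)
  pts <- matrix(NA_real_, nf, 3L * np)
  for (j in seq_len(np)) {
    xyz <- vals[, (4L * j - 3L):(4L * j - 1L), drop = FALSE]
    res <- vals[, 4L * j]
    if (scale > 0) xyz <- xyz * scale
    bad <- res < 0 | rowSums(xyz == 0) == 3L
    xyz[bad, ] <- NA_real_
    pts[, marker_columns(j)] <- xyz
  }
  if (is.null(labels) || length(labels) < np)
    labels <- paste0("M", seq_len(np))
  labels <- labels[seq_len(np)]
  if (anyDuplicated(labels) || any(!nzchar(labels)))
    labels <- paste0("M", seq_len(np))
  validate_dataset(marker_dataset(pts, labels, frame_rate, units))
}

#' @rdname read_c3d
#' @param x a [marker_dataset()].
#' @export
write_c3d <- function(x, path) {
  stopifnot(inherits(x, "marker_dataset"))
  n <- n_frames(x); m <- n_markers(x)
  if (n > 32767L)
    mf_stop("format_error", "C3D writer limited to 32767 frames, got %d", n)
  w_i16 <- function(v) writeBin(as.integer(v), con, size = 2L, endian = "little")
  w_f32 <- function(v) writeBin(as.numeric(v), con, size = 4L, endian = "little")
  w_i8 <- function(v) writeBin(as.integer(v), con, size = 1L)
  w_chr <- function(s) writeBin(charToRaw(s), con)

  # assemble parameter section in memory first to know its block count
  pcon <- rawConnection(raw(0), "wb")
  con <- pcon
  w_i8(c(1L, 0x50L, 0L, 84L))  # block count patched below
  # POINT group
  w_i8(c(5L, -1L)); w_chr("POINT"); w_i16(1L); w_i8(0L)
  wparam <- function(name, elsize, dims, write_data) {
    datb <- if (elsize == -1L) prod(dims)
            else prod(if (length(dims)) dims else 1L) * abs(elsize)
    w_i8(c(nchar(name), 1L)); w_chr(name)
    w_i16(1L + 1L + length(dims) + datb + 1L)
    w_i8(elsize); w_i8(length(dims)); if (length(dims)) w_i8(dims)
    write_data(); w_i8(0L)
  }
  wparam("USED", 2L, integer(), function() w_i16(m))
  wparam("FRAMES", 2L, integer(), function() w_i16(n))
  wparam("RATE", 4L, integer(), function() w_f32(x$frame_rate))
  wparam("SCALE", 4L, integer(), function() w_f32(-1))
  wparam("DATA_START", 2L, integer(), function() w_i16(0L))  # patched below
  wparam("UNITS", -1L, 2L, function() w_chr("mm"))
  width <- max(nchar(x$labels))
  wparam("LABELS", -1L, c(width, m), function()
    w_chr(paste(formatC(x$labels, width = -width), collapse = "")))
  w_i8(c(0L, 0L)); w_i16(0L)  # terminator
  pbytes <- rawConnectionValue(pcon); close(pcon)
  nblocks <- ceiling(length(pbytes) / 512)
  pbytes[3] <- as.raw(nblocks)
  pbytes <- c(pbytes, raw(nblocks * 512L - length(pbytes)))
  data_start <- 2L + nblocks
  # patch DATA_START parameter value (last 3 bytes before UNITS record are
  # value + desclen); simpler: locate by pattern of its name
  ds_at <- grepRaw("DATA_START", pbytes, fixed = TRUE)[1]
  pbytes[(ds_at + 14L):(ds_at + 15L)] <-
    as.raw(c(data_start %% 256L, data_start %/% 256L))

  con <- tryCatch(file(path, "wb"), error = function(e)
    mf_stop("io_error", "cannot write '%s': %s", path, conditionMessage(e)))
  on.exit(close(con))
  w_i8(c(2L, 0x50L))
  w_i16(c(m, 0L, 1L, n, 0L))
  w_f32(-1)                       # 3D scale: float data
  w_i16(c(data_start, 0L))
  w_f32(x$frame_rate)
  writeBin(raw(512L - 24L), con)  # pad header block
  writeBin(pbytes, con)
  for (i in seq_len(n)) {
    row <- x$data[i, ]
    for (j in seq_len(m)) {
      xyz <- row[marker_columns(j)]
      if (anyNA(xyz)) w_f32(c(0, 0, 0, -1)) else w_f32(c(xyz, 0))
    }
  }
  invisible(path)
}
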