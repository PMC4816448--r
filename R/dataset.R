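#' Marker trajectory dataset
#'
#' The in-memory container used throughout the package: an `n` frames by
#' `3 m` coordinates measurement matrix holding the X, Y, Z trajectory of
#' every marker, together with marker labels, the capture frame rate and a
#' unit tag. Columns `3j-2, 3j-1, 3j` belong to marker `j`, in X, Y, Z
#' order. The canonical unit is millimetres.
#'
#' A marker is missing at a frame when all three of its coordinates are
#' `NA` at that frame. Gaps are always whole-marker events: if an input has
#' only one or two coordinates of a marker missing at a frame, the whole
#' marker-frame is demoted to missing (with a warning), because an optical
#' system never loses a single axis of a reconstructed point.
#'
#' @param data numeric matrix, `n x 3m`, gaps encoded as `NA`/`NaN`.
#' @param labels character vector of `m` unique marker names. Defaults to
#'   `"M1" ... "Mm"`.
#' @param frame_rate capture rate in Hz (positive scalar).
#' @param units unit tag; `"mm"` is canonical. `"m"` and `"cm"` are
#'   converted to mm on construction.
#'
#' @return An object of class `marker_dataset` with elements `data`,
#'   `labels`, `frame_rate`, `units`.
#' @examples
#' d <- marker_dataset(matrix(rnorm(60), 10, 6), labels = c("LKNE", "LSHO"),
#'                     frame_rate = 120)
#' n_frames(d)
#' gap_mask(d)
#' @export
marker_dataset <- function(data, labels = NULL, frame_rate = 100, units = "mm") {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (nrow(data) < 1L)
    mf_stop("format_error", "dataset must contain at least one frame")
  if (ncol(data) %% 3L != 0L)
    mf_stop("format_error",
            "column count (%d) is not a multiple of 3", ncol(data))
  m <- ncol(data) %/% 3L
  if (m < 2L)
    mf_stop("format_error", "need at least 2 markers, got %d", m)
  if (is.null(labels)) labels <- paste0("M", seq_len(m))
  if (length(labels) != m || anyDuplicated(labels))
    mf_stop("format_error", "labels must be %d unique marker names", m)
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0)
    mf_stop("parameter_error", "frame_rate must be a positive scalar (Hz)")
  scale <- switch(units, mm = 1, cm = 10, m = 1000,
                  mf_stop("format_error", "unsupported units '%s'", units))
  if (scale != 1) data <- data * scale

  # demote partial per-axis missingness to whole-marker gaps
  for (j in seq_len(m)) {
    cols <- marker_columns(j)
    nmiss <- rowSums(is.na(data[, cols, drop = FALSE]))
    partial <- nmiss > 0L & nmiss < 3L
    if (any(partial)) {
      mf_warn("marker '%s': %d frame(s) with partially missing coordinates demoted to gaps",
              labels[j], sum(partial))
      data[partial, cols] <- NA_real_
    }
  }
  colnames(data) <- paste(rep(labels, each = 3L), c("X", "Y", "Z"), sep = "_")
  rownames(data) <- NULL
  structure(list(data = data, labels = labels,
                 frame_rate = as.numeric(frame_rate), units = "mm"),
            class = "marker_dataset")
}

#' @rdname marker_dataset
#' @param x a `marker_dataset`.
#' @export
n_frames <- function(x) nrow(x$data)

#' @rdname marker_dataset
#' @export
n_markers <- function(x) length(x$labels)

#' Coordinate columns of a marker
#'
#' @param j marker index (or vector of indices).
#' @return Integer vector of the X, Y, Z column positions for `j`.
#' @export
marker_columns <- function(j) as.vector(rbind(3L * j - 2L, 3L * j - 1L, 3L * j))

#' Missing-marker mask
#'
#' @param x a `marker_dataset`.
#' @return Logical `n x m` matrix; `TRUE` where the marker is absent at the
#'   frame. Column names are the marker labels.
#' @export
gap_mask <- function(x) {
  stopifnot(inherits(x, "marker_dataset"))
  m <- n_markers(x)
  out <- vapply(seq_len(m), function(j) is.na(x$data[, 3L * j - 2L]),
                logical(n_frames(x)))
  out <- matrix(out, nrow = n_frames(x), ncol = m)
  colnames(out) <- x$labels
  out
}

# index (integer) of a marker given index or label
marker_index <- function(x, marker) {
  if (is.character(marker)) {
    idx <- match(marker, x$labels)
    if (anyNA(idx))
      mf_stop("lookup_error", "unknown marker label '%s'",
              paste(marker[is.na(idx)], collapse = "', '"))
    return(idx)
  }
  marker <- as.integer(marker)
  if (any(marker < 1L | marker > n_markers(x)))
    mf_stop("lookup_error", "marker index out of range")
  marker
}

# markers that have at least one gap
corrupted_markers <- function(x) which(colSums(gap_mask(x)) > 0L)

# frames with no missing marker
complete_frame_idx <- function(x) which(rowSums(is.na(x$data)) == 0L)

#' @export
print.marker_dataset <- function(x, ...) {
  gm <- gap_mask(x)
  cat(sprintf("<marker_dataset> %d frames x %d markers @ %g Hz [%s]\n",
              n_frames(x), n_markers(x), x$frame_rate, x$units))
  ng <- sum(gm)
  if (ng > 0L)
    cat(sprintf("  %d missing marker-frames in %d marker(s)\n",
                ng, sum(colSums(gm) > 0L)))
  else cat("  gap-free\n")
  invisible(x)
}

# shared post-read validation used by every reader
validate_dataset <- function(x) {
  stopifnot(inherits(x, "marker_dataset"))
  d <- x$data
  if (ncol(d) != 3L * length(x$labels))
    mf_stop("format_error", "label/column mismatch")
  miss <- is.na(d)
  for (j in seq_along(x$labels)) {
    cols <- marker_columns(j)
    rs <- rowSums(miss[, cols, drop = FALSE])
    if (any(rs > 0L & rs < 3L))
      mf_stop("format_error", "per-axis missingness survived construction")
  }
  x
}
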