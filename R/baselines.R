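#' Interpolation baselines
#'
#' Conventional per-coordinate gap filling used as reference methods:
#' `fill_spline` fits a natural cubic spline through the observed samples
#' of each coordinate and evaluates it inside the gaps; `fill_linear`
#' interpolates linearly. Gaps before the first or after the last
#' observed sample are filled with the nearest observed value (constant
#' extrapolation). A coordinate with a single observed sample is filled
#' with that value, with a warning. Observed samples are never modified.
#'
#' @param x a [marker_dataset()].
#' @return A `marker_fill` result (report lists the filled count).
#' @export
fill_spline <- function(x) {
  fill_interpolate(x, "spline")
}

#' @rdname fill_spline
#' @export
fill_linear <- function(x) {
  fill_interpolate(x, "linear")
}

fill_interpolate <- function(x, kind) {
  stopifnot(inherits(x, "marker_dataset"))
  out <- x
  n <- n_frames(x)
  filled <- 0L
  for (cc in seq_len(ncol(x$data))) {
    y <- x$data[, cc]
    gap <- which(is.na(y))
    if (length(gap) == 0L) next
    obs <- which(!is.na(y))
    if (length(obs) == 0L)
      mf_stop("insufficient_support",
              "column %d has no observed samples", cc)
    if (length(obs) == 1L) {
      mf_warn("column %d has a single observed sample; constant fill", cc)
      out$data[gap, cc] <- y[obs]
      filled <- filled + length(gap)
      next
    }
    lo <- gap[gap < obs[1L]]
    hi <- gap[gap > obs[length(obs)]]
    mid <- setdiff(gap, c(lo, hi))
    if (length(mid)) {
      out$data[mid, cc] <- if (kind == "spline")
        spline(obs, y[obs], xout = mid, method = "natural")$y
      else
        approx(obs, y[obs], xout = mid)$y
    }
    if (length(lo)) out$data[lo, cc] <- y[obs[1L]]
    if (length(hi)) out$data[hi, cc] <- y[obs[length(obs)]]
    filled <- filled + length(gap)
  }
  structure(list(dataset = out,
                 report = list(strategy = kind,
                               corrupted = corrupted_markers(x),
                               gaps_filled = filled / 3L,
                               unfilled = integer())),
            class = "marker_fill")
}
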