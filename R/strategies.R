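#' Reconstruct a single corrupted marker
#'
#' Thin wrapper around [reconstruct_eq1()] with one target marker. With
#' exactly one corrupted marker in the dataset this coincides exactly
#' with both multi-gap strategies.
#'
#' @param x a [marker_dataset()].
#' @param marker index or label of the marker to fill.
#' @param params a [recon_params()].
#' @return As [reconstruct_eq1()].
#' @export
reconstruct_single_marker <- function(x, marker, params = recon_params()) {
  reconstruct_eq1(x, marker, params)
}

#' Strategy R1: simultaneous reconstruction of all gaps
#'
#' All corrupted trajectories are reconstructed in one application of the
#' dual-basis engine: the training frames are those without gaps in any
#' marker, every corrupted marker's columns are zeroed together, and each
#' complete marker receives the largest Gaussian weight over all
#' corrupted markers. Strengths: a single pass, no neighbour decisions.
#' Weaknesses: the weights serve all gaps at once, and frames that are
#' incomplete in any marker are discarded from training.
#'
#' @param x a [marker_dataset()] with gaps.
#' @param params a [recon_params()].
#' @return A list of class `marker_fill`: `dataset` (filled), `report`.
#' @export
reconstruct_r1 <- function(x, params = recon_params()) {
  stopifnot(inherits(x, "marker_dataset"))
  corrupted <- corrupted_markers(x)
  if (length(corrupted) == 0L) {
    return(structure(list(dataset = x,
                          report = list(strategy = "r1", corrupted = integer(),
                                        gaps_filled = 0L, unfilled = integer())),
                     class = "marker_fill"))
  }
  res <- reconstruct_eq1(x, corrupted, params)
  structure(list(dataset = res$dataset,
                 report = list(strategy = "r1",
                               corrupted = corrupted,
                               gaps_filled = res$info$filled,
                               unfilled = integer(),
                               k_full = res$info$k_full,
                               k_zeroed = res$info$k_zeroed,
                               n_complete = res$info$n_complete)),
            class = "marker_fill")
}

#' Neighbour decisions for strategy R2
#'
#' When reconstructing marker `i`, every *other corrupted* marker `h` is
#' either included (its own gap frames are dropped from training) or
#' omitted entirely. `h` is omitted when its mean distance to `i` exceeds
#' `theta_d * D_i` — `D_i` being the average of `i`'s mean distances to
#' all other markers — when its gaps overlap `i`'s gaps in time
#' (regardless of distance), or when the two markers share no frames.
#' Gap-free markers are always included.
#'
#' @param x the corrupted [marker_dataset()].
#' @param target index or label of the marker being reconstructed.
#' @param params a [recon_params()].
#' @return A list of class `neighbor_decision`: `included_markers`
#'   (corrupted markers kept), `dropped_frames`, `omitted_markers` (named
#'   character vector of reasons), `d_mean` (`D_i`).
#' @export
select_neighbors_r2 <- function(x, target, params = recon_params()) {
  target <- marker_index(x, target)
  mask <- gap_mask(x)
  if (!any(mask[, target]))
    mf_stop("parameter_error", "marker '%s' has no gaps", x$labels[target])
  m <- n_markers(x)
  others <- setdiff(seq_len(m), target)
  dbar <- vapply(others, function(j) {
    tryCatch(mean_marker_distance(x, target, j),
             markerfill_no_common_support = function(e) NA_real_)
  }, numeric(1))
  d_mean <- mean(dbar, na.rm = TRUE)
  corrupted <- corrupted_markers(x)
  gap_target <- which(mask[, target])
  included <- integer()
  dropped <- integer()
  omitted <- character()
  for (k in seq_along(others)) {
    h <- others[k]
    if (!h %in% corrupted) next
    gap_h <- which(mask[, h])
    if (is.na(dbar[k])) {
      omitted[x$labels[h]] <- "no-common-support"
    } else if (length(intersect(gap_h, gap_target)) > 0L) {
      omitted[x$labels[h]] <- "temporal-overlap"
    } else if (dbar[k] > params$theta_d * d_mean) {
      omitted[x$labels[h]] <- "beyond-theta-d"
    } else {
      included <- c(included, h)
      dropped <- union(dropped, gap_h)
    }
  }
  structure(list(included_markers = included,
                 dropped_frames = sort(dropped),
                 omitted_markers = omitted,
                 d_mean = d_mean),
            class = "neighbor_decision")
}

#' Strategy R2: consecutive per-marker reconstruction
#'
#' Each corrupted marker is reconstructed independently from the original
#' corrupted data. For marker `i`, [select_neighbors_r2()] decides which
#' other corrupted markers to keep; the omitted markers' columns and the
#' included markers' gap frames are removed, and the single-marker engine
#' runs on the reduced dataset. Because no reconstructed values are fed
#' back, the result does not depend on the processing order. A marker
#' whose reduced dataset lacks support is left unfilled and reported,
#' not treated as fatal.
#'
#' @param x a [marker_dataset()] with gaps.
#' @param params a [recon_params()].
#' @return A list of class `marker_fill`: `dataset`, `report` (per-marker
#'   decisions, unfilled markers with reasons).
#' @export
reconstruct_r2 <- function(x, params = recon_params()) {
  stopifnot(inherits(x, "marker_dataset"))
  corrupted <- corrupted_markers(x)
  out <- x
  per_marker <- list()
  unfilled <- integer()
  mask <- gap_mask(x)
  for (i in corrupted) {
    lab <- x$labels[i]
    status <- tryCatch({
      dec <- select_neighbors_r2(x, i, params)
      keep <- sort(c(i, dec$included_markers,
                     setdiff(seq_len(n_markers(x)), corrupted)))
      rows <- setdiff(seq_len(n_frames(x)), dec$dropped_frames)
      if (length(keep) < 2L)
        mf_stop("insufficient_support",
                "no markers available besides '%s'", lab)
      sub <- marker_dataset(x$data[rows, marker_columns(keep), drop = FALSE],
                            x$labels[keep], x$frame_rate)
      ti <- match(i, keep)
      res <- reconstruct_eq1(sub, ti, params)
      gap_i <- intersect(which(mask[, i]), rows)
      out$data[gap_i, marker_columns(i)] <-
        res$dataset$data[match(gap_i, rows), marker_columns(ti)]
      list(decision = dec, filled = length(gap_i),
           k_full = res$info$k_full, k_zeroed = res$info$k_zeroed,
           n_complete = res$info$n_complete, error = NULL)
    },
    markerfill_insufficient_support = function(e)
      list(decision = NULL, filled = 0L, error = conditionMessage(e)),
    markerfill_degenerate_basis = function(e)
      list(decision = NULL, filled = 0L, error = conditionMessage(e)))
    if (!is.null(status$error)) {
      unfilled <- c(unfilled, i)
      mf_warn("marker '%s' left unfilled: %s", lab, status$error)
    }
    per_marker[[lab]] <- status
  }
  structure(list(dataset = out,
                 report = list(strategy = "r2", corrupted = corrupted,
                               gaps_filled = sum(vapply(per_marker, `[[`,
                                                        numeric(1), "filled")),
                               unfilled = unfilled,
                               per_marker = per_marker)),
            class = "marker_fill")
}

#' @export
print.marker_fill <- function(x, ...) {
  r <- x$report
  cat(sprintf("<marker_fill> strategy %s: %d corrupted marker(s), %d marker-frames filled\n",
              toupper(r$strategy), length(r$corrupted), r$gaps_filled))
  if (length(r$unfilled))
    cat("  unfilled:", paste(x$dataset$labels[r$unfilled], collapse = ", "), "\n")
  invisible(x)
}

#' Fill gaps with a chosen method
#'
#' Uniform front end over the two subspace strategies and the two
#' interpolation baselines.
#'
#' @param x a [marker_dataset()].
#' @param method `"r2"` (default), `"r1"`, `"spline"` or `"linear"`.
#' @param params a [recon_params()] (ignored by the baselines).
#' @return A `marker_fill` result.
#' @export
fill_gaps <- function(x, method = c("r2", "r1", "spline", "linear"),
                      params = recon_params()) {
  method <- match.arg(method)
  switch(method,
         r1 = reconstruct_r1(x, params),
         r2 = reconstruct_r2(x, params),
         spline = fill_spline(x),
         linear = fill_linear(x))
}
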