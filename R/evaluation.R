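#' Score a reconstruction against the truth
#'
#' Reconstruction accuracy is the mean Euclidean distance between the
#' filled and true marker positions, pooled over every missing
#' marker-frame. Per-axis mean absolute errors and per-marker means are
#' reported alongside.
#'
#' @param truth the pristine [marker_dataset()].
#' @param filled the reconstructed dataset.
#' @param mask logical `n x m` missing-marker matrix (usually
#'   `gap_mask(corrupted)`).
#' @return A list of class `recon_error`: `mean_euclidean` (mm),
#'   `per_axis_mae` (named X/Y/Z, mm), `per_marker` (named, mm),
#'   `n_gap_frames`.
#' @export
score_reconstruction <- function(truth, filled, mask) {
  stopifnot(inherits(truth, "marker_dataset"), inherits(filled, "marker_dataset"))
  if (!all(dim(truth$data) == dim(filled$data)))
    mf_stop("parameter_error", "truth and filled datasets differ in shape")
  if (!is.matrix(mask) || nrow(mask) != n_frames(truth) ||
      ncol(mask) != n_markers(truth))
    mf_stop("parameter_error", "mask shape does not match the dataset")
  if (!any(mask)) mf_stop("parameter_error", "mask contains no gap samples")
  m <- n_markers(truth)
  dist_all <- numeric(0)
  abs_axis <- matrix(0, 0, 3L)
  per_marker <- setNames(rep(NA_real_, m), truth$labels)
  for (j in seq_len(m)) {
    rows <- which(mask[, j])
    if (length(rows) == 0L) next
    diff <- filled$data[rows, marker_columns(j), drop = FALSE] -
      truth$data[rows, marker_columns(j), drop = FALSE]
    d <- sqrt(rowSums(diff^2))
    per_marker[j] <- mean(d)
    dist_all <- c(dist_all, d)
    abs_axis <- rbind(abs_axis, abs(diff))
  }
  structure(list(mean_euclidean = mean(dist_all),
                 per_axis_mae = setNames(colMeans(abs_axis), c("X", "Y", "Z")),
                 per_marker = per_marker[!is.na(per_marker)],
                 n_gap_frames = length(dist_all)),
            class = "recon_error")
}

#' @export
print.recon_error <- function(x, ...) {
  cat(sprintf("<recon_error> mean Euclidean %.3f mm over %d gap frames (MAE X %.3f, Y %.3f, Z %.3f)\n",
              x$mean_euclidean, x$n_gap_frames,
              x$per_axis_mae[1], x$per_axis_mae[2], x$per_axis_mae[3]))
  invisible(x)
}

#' Replicated random-gap experiment
#'
#' Corrupts a gap-free dataset `n_replicates` times with the randomized
#' gap protocol, fills each copy with the requested method and scores it
#' against the truth. Replicate seeds are derived from the master seed,
#' so the whole experiment is reproducible bit for bit. A method failure
#' on a replicate is recorded as `NA` rather than aborting the run.
#'
#' @param x a gap-free [marker_dataset()].
#' @param method a method name accepted by [fill_gaps()], or a function
#'   `function(dataset, params)` returning a `marker_fill` result.
#' @param params a [recon_params()].
#' @param n_gaps,gap_len gap protocol, as in [corrupt_with_gaps()].
#' @param n_replicates number of corrupted copies (default 50).
#' @param seed master seed.
#' @return A list: `errors` (per-replicate mean Euclidean, mm), `median`.
#' @export
replicate_experiment <- function(x, method = "r2", params = recon_params(),
                                 n_gaps = c(5L, 15L), gap_len = c(20L, 480L),
                                 n_replicates = 50L, seed = 1L) {
  stopifnot(inherits(x, "marker_dataset"))
  fill_fun <- if (is.function(method)) method
  else function(d, p) fill_gaps(d, method, p)
  rep_seeds <- local_seed(seed, sample.int(2147483646L, n_replicates))
  errors <- vapply(seq_len(n_replicates), function(i) {
    cc <- corrupt_with_gaps(x, n_gaps, gap_len, seed = rep_seeds[i])
    tryCatch({
      res <- suppressWarnings(fill_fun(cc$dataset, params))
      score_reconstruction(x, res$dataset, gap_mask(cc$dataset))$mean_euclidean
    }, markerfill_error = function(e) NA_real_)
  }, numeric(1))
  list(errors = errors, median = median(errors, na.rm = TRUE))
}

#' Sensitivity analysis grids
#'
#' The one-at-a-time sweep grids: `w_mm` over 15 logarithmic steps from
#' 1e-5 to 1, `sigma` over 15 linear steps from 100 to 1500 mm,
#' `theta_lambda` over 15 linear steps from 0.86 to 1, and `theta_d`
#' over 11 linear steps from 0 to 2.
#'
#' @param parameter one of `"w_mm"`, `"sigma"`, `"theta_lambda"`,
#'   `"theta_d"`.
#' @return Numeric grid.
#' @export
sensitivity_grid <- function(parameter) {
  switch(parameter,
         w_mm = 10^seq(-5, 0, length.out = 15L),
         sigma = seq(100, 1500, length.out = 15L),
         theta_lambda = seq(0.86, 1, length.out = 15L),
         theta_d = seq(0, 2, length.out = 11L),
         mf_stop("parameter_error", "unknown parameter '%s'", parameter))
}

#' One-at-a-time parameter sensitivity sweep
#'
#' For each of `n_copies` random corruptions of each input dataset, the
#' gaps are filled with strategy R2 at every grid value of the swept
#' parameter (all other parameters held at their defaults), and the mean
#' Euclidean error is recorded. Each copy's error curve is centered by
#' subtracting its own across-grid mean, isolating the parameter effect
#' from the difficulty of the particular corruption; centered curves are
#' then averaged over all copies, with the standard error of the mean.
#'
#' @param datasets a gap-free [marker_dataset()] or a list of them.
#' @param parameter the parameter to sweep (see [sensitivity_grid()]).
#' @param grid grid of values (defaults to the standard grid).
#' @param params defaults for the parameters not being swept.
#' @param n_copies corrupted copies per dataset (default 20).
#' @param n_gaps,gap_len corruption protocol; may be a list with one
#'   entry per dataset.
#' @param seed master seed.
#' @return A data frame with `value`, `centered_error`, `sem`, and the
#'   swept parameter's name in the `parameter` column.
#' @export
sensitivity_sweep <- function(datasets, parameter,
                              grid = sensitivity_grid(parameter),
                              params = recon_params(), n_copies = 20L,
                              n_gaps = c(5L, 15L), gap_len = c(20L, 480L),
                              seed = 1L) {
  if (inherits(datasets, "marker_dataset")) datasets <- list(datasets)
  if (!is.list(n_gaps)) n_gaps <- rep(list(n_gaps), length(datasets))
  if (!is.list(gap_len)) gap_len <- rep(list(gap_len), length(datasets))
  if (any(grid < 0) ||
      (parameter %in% c("w_mm", "theta_lambda") && any(grid > 1)))
    mf_stop("parameter_error", "grid outside the domain of '%s'", parameter)
  seeds <- local_seed(seed, sample.int(2147483646L,
                                       length(datasets) * n_copies))
  curves <- matrix(NA_real_, 0L, length(grid))
  ctr <- 0L
  for (di in seq_along(datasets)) {
    for (cp in seq_len(n_copies)) {
      ctr <- ctr + 1L
      cc <- corrupt_with_gaps(datasets[[di]], n_gaps[[di]], gap_len[[di]],
                              seed = seeds[ctr])
      mask <- gap_mask(cc$dataset)
      errs <- vapply(grid, function(v) {
        p <- params
        if (v == 0 && parameter == "w_mm") return(NA_real_)
        p[[parameter]] <- v
        tryCatch({
          res <- suppressWarnings(reconstruct_r2(cc$dataset, p))
          score_reconstruction(datasets[[di]], res$dataset, mask)$mean_euclidean
        }, markerfill_error = function(e) NA_real_)
      }, numeric(1))
      curves <- rbind(curves, errs - mean(errs, na.rm = TRUE))
    }
  }
  data.frame(parameter = parameter, value = grid,
             centered_error = colMeans(curves, na.rm = TRUE),
             sem = apply(curves, 2L, function(v)
               sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v)))))
}
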