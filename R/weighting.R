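#' Reconstruction parameters
#'
#' Bundles the four tunable parameters of the reconstruction algorithm,
#' with the defaults used throughout: `w_mm = 0.02`, `sigma = 200` mm,
#' `theta_lambda = 0.99`, `theta_d = 0.5`.
#'
#' * `w_mm` - weight assigned to the available samples of the marker(s)
#'   being reconstructed. Must be strictly positive: with `w_mm = 0` the
#'   principal component bases with and without the corrupted columns
#'   coincide and the reconstruction degenerates to zeros, so a zero
#'   weight is rejected outright.
#' * `sigma` - length scale (mm) of the Gaussian distance weighting that
#'   emphasises markers near the gap.
#' * `theta_lambda` - threshold on the cumulative sum of normalized
#'   singular values that selects how many principal components to keep.
#' * `theta_d` - relative distance cutoff of strategy R2: a corrupted
#'   neighbour farther than `theta_d` times the target's mean inter-marker
#'   distance is omitted rather than frame-dropped.
#'
#' `transition` selects how the map between the two truncated score
#' spaces is computed: `"scores"` (default) solves the least-squares
#' problem between the score matrices of the gap-free frames, which makes
#' reconstruction exact for data lying in the complete-frame subspace;
#' `"basis"` uses the inner-product matrix of the two truncated bases,
#' which is more sensitive to the choice of `w_mm` (see the methods
#' vignette for the trade-off).
#'
#' @param w_mm weight on the missing marker's own columns, in (0, 1].
#' @param sigma Gaussian weighting scale in mm, > 0.
#' @param theta_lambda truncation threshold, in (0, 1].
#' @param theta_d neighbour-inclusion cutoff, >= 0.
#' @param transition `"scores"` or `"basis"`.
#' @param min_complete minimum number of gap-free frames required to fit
#'   the bases.
#' @return A list of class `recon_params`.
#' @export
recon_params <- function(w_mm = 0.02, sigma = 200, theta_lambda = 0.99,
                         theta_d = 0.5, transition = c("scores", "basis"),
                         min_complete = 10L) {
  transition <- match.arg(transition)
  if (!is.numeric(w_mm) || length(w_mm) != 1L || w_mm <= 0 || w_mm > 1)
    mf_stop("parameter_error",
            "w_mm must be in (0, 1]; w_mm = 0 would make the two PC bases identical")
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    mf_stop("parameter_error", "sigma must be a positive length in mm")
  if (!is.numeric(theta_lambda) || length(theta_lambda) != 1L ||
      theta_lambda <= 0 || theta_lambda > 1)
    mf_stop("parameter_error", "theta_lambda must be in (0, 1]")
  if (!is.numeric(theta_d) || length(theta_d) != 1L || theta_d < 0)
    mf_stop("parameter_error", "theta_d must be >= 0")
  structure(list(w_mm = w_mm, sigma = sigma, theta_lambda = theta_lambda,
                 theta_d = theta_d, transition = transition,
                 min_complete = max(10L, as.integer(min_complete))),
            class = "recon_params")
}

#' Mean inter-marker distance
#'
#' Time average of the Euclidean distance between two markers over exactly
#' the frames in which both are present.
#'
#' @param x a [marker_dataset()].
#' @param i,j marker indices or labels, `i != j`.
#' @return Mean distance in mm.
#' @export
mean_marker_distance <- function(x, i, j) {
  i <- marker_index(x, i); j <- marker_index(x, j)
  if (i == j)
    mf_stop("parameter_error", "distance of a marker to itself is undefined")
  pi_ <- x$data[, marker_columns(i), drop = FALSE]
  pj_ <- x$data[, marker_columns(j), drop = FALSE]
  ok <- !is.na(pi_[, 1L]) & !is.na(pj_[, 1L])
  if (!any(ok))
    mf_stop("no_common_support",
            "markers '%s' and '%s' share no frames", x$labels[i], x$labels[j])
  mean(sqrt(rowSums((pi_[ok, , drop = FALSE] - pj_[ok, , drop = FALSE])^2)))
}

#' Gaussian distance weight
#'
#' `exp(-d^2 / (2 sigma^2))`: 1 at distance zero, decaying with distance
#' on the scale `sigma`.
#'
#' @param d distance in mm, >= 0.
#' @param sigma scale in mm, > 0.
#' @return Weight in (0, 1].
#' @export
gaussian_weight <- function(d, sigma) {
  if (any(sigma <= 0)) mf_stop("parameter_error", "sigma must be > 0")
  if (any(d < 0)) mf_stop("parameter_error", "distance must be >= 0")
  exp(-d^2 / (2 * sigma^2))
}

# weight used for markers that share no frames with any target: effectively
# excluded but strictly positive so the weighted matrix stays well formed
.no_support_weight <- 1e-6

#' Build the coordinate weight vector
#'
#' Assigns `w_mm` to every target marker and, to every other marker `j`,
#' the largest Gaussian weight over the targets,
#' `max_i exp(-dbar(i,j)^2 / (2 sigma^2))`, where `dbar` is the mean
#' inter-marker distance over shared frames. Weights are broadcast to each
#' marker's three coordinate columns. Markers with no shared frames with
#' any target receive a vanishing positive weight and a warning.
#'
#' @param x a [marker_dataset()] (distances use its observed frames only).
#' @param targets marker indices or labels being reconstructed.
#' @param params a [recon_params()].
#' @return Numeric vector of length `3 m`, entries in (0, 1].
#' @export
build_weight_vector <- function(x, targets, params = recon_params()) {
  targets <- marker_index(x, targets)
  if (length(targets) == 0L)
    mf_stop("parameter_error", "targets must be non-empty")
  m <- n_markers(x)
  w <- numeric(m)
  w[targets] <- params$w_mm
  for (j in setdiff(seq_len(m), targets)) {
    ds <- vapply(targets, function(i) {
      tryCatch(mean_marker_distance(x, i, j),
               markerfill_no_common_support = function(e) NA_real_)
    }, numeric(1))
    if (all(is.na(ds))) {
      mf_warn("marker '%s' shares no frames with any target; weight set to %g",
              x$labels[j], .no_support_weight)
      w[j] <- .no_support_weight
    } else {
      w[j] <- max(gaussian_weight(ds[!is.na(ds)], params$sigma))
    }
  }
  rep(w, each = 3L)
}
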