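#' Extract the gap-free frames
#'
#' Returns the rows of the measurement matrix in which every marker is
#' present — the training set for the principal component bases.
#'
#' @param x a [marker_dataset()].
#' @param min_complete minimum acceptable number of complete frames
#'   (floored at 10).
#' @return A list with `matrix` (`k x 3m`) and `frames` (original row
#'   indices, in order).
#' @export
extract_complete_frames <- function(x, min_complete = 10L) {
  stopifnot(inherits(x, "marker_dataset"))
  idx <- complete_frame_idx(x)
  need <- max(10L, as.integer(min_complete))
  if (length(idx) < need)
    mf_stop("insufficient_support",
            "only %d complete frame(s) available, need at least %d",
            length(idx), need)
  list(matrix = x$data[idx, , drop = FALSE], frames = idx)
}

# smallest k whose cumulative normalized singular-value sum reaches theta
select_k <- function(d, theta_lambda) {
  tot <- sum(d)
  if (tot <= 0) mf_stop("degenerate_basis", "all singular values are zero")
  if (theta_lambda >= 1) return(sum(d > max(d) * 1e-12))
  frac <- cumsum(d) / tot
  which(frac >= theta_lambda - 1e-12)[1L]
}

#' Fit a weighted principal component basis
#'
#' Columns are mean-centered, scaled by the coordinate weights, and
#' decomposed by singular value decomposition. The basis keeps the full
#' set of right singular vectors together with the truncation index
#' `k_retained`: the smallest `k` at which the cumulative sum of
#' normalized singular values reaches `theta_lambda`. Normalization is by
#' the sum of the singular values themselves, not their squares.
#'
#' @param mat numeric matrix (`k x 3m`), complete frames, raw units.
#' @param weights coordinate weight vector of length `ncol(mat)`.
#' @param theta_lambda truncation threshold in (0, 1].
#' @return A list of class `principal_basis`: `vectors` (orthonormal
#'   columns), `singular_values`, `column_means`, `weights`, `k_retained`.
#' @export
fit_basis <- function(mat, weights, theta_lambda = 0.99) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L)
    mf_stop("insufficient_support", "need at least 2 rows to fit a basis")
  if (length(weights) != ncol(mat))
    mf_stop("parameter_error", "weight vector length %d != %d columns",
            length(weights), ncol(mat))
  mu <- colMeans(mat)
  xw <- sweep(sweep(mat, 2L, mu), 2L, weights, `*`)
  sv <- svd(xw, nu = 0L)
  k <- select_k(sv$d, theta_lambda)
  structure(list(vectors = sv$v, singular_values = sv$d, column_means = mu,
                 weights = weights, k_retained = k,
                 theta_lambda = theta_lambda),
            class = "principal_basis")
}

trunc_vectors <- function(basis) {
  basis$vectors[, seq_len(basis$k_retained), drop = FALSE]
}

# project raw rows onto a basis: center with the basis means, weight, project
basis_scores <- function(basis, mat, zero_fill = FALSE) {
  xw <- sweep(sweep(mat, 2L, basis$column_means), 2L, basis$weights, `*`)
  if (zero_fill) xw[is.na(xw)] <- 0
  xw %*% trunc_vectors(basis)
}

#' Transition matrix between the two truncated score spaces
#'
#' The least-squares map `T` taking the truncated scores of the zeroed
#' frames to the truncated scores of the same full frames. Solved through
#' the pseudoinverse; a rank-deficient score matrix triggers a
#' condition-number warning but still yields the minimum-norm solution.
#' With `transition = "basis"` the inner-product matrix of the truncated
#' bases is used instead.
#'
#' @param N complete-frame matrix (`k x 3m`).
#' @param N_zeros the same frames with the target columns zeroed.
#' @param basis_full,basis_zeroed the two fitted [fit_basis()] objects.
#' @param transition `"scores"` or `"basis"`.
#' @return A `k_zeroed x k_full` matrix.
#' @export
transition_matrix <- function(N, N_zeros, basis_full, basis_zeroed,
                              transition = "scores") {
  if (!all(dim(N) == dim(N_zeros)))
    mf_stop("parameter_error", "N and N_zeros must have identical shape")
  if (transition == "basis")
    return(t(trunc_vectors(basis_zeroed)) %*% trunc_vectors(basis_full))
  s_zero <- basis_scores(basis_zeroed, N_zeros)
  s_full <- basis_scores(basis_full, N)
  sv <- svd(s_zero)
  tol <- max(sv$d) * 1e-10
  keep <- sv$d > tol
  if (!all(keep) || max(sv$d) / max(min(sv$d), .Machine$double.xmin) > 1e10)
    mf_warn("zeroed score matrix is ill-conditioned (condition number %.3g); using pseudoinverse",
            max(sv$d) / max(min(sv$d), .Machine$double.xmin))
  sv$v[, keep, drop = FALSE] %*%
    ((t(sv$u[, keep, drop = FALSE]) %*% s_full) / sv$d[keep])
}

#' Fill gaps through the dual-basis reconstruction
#'
#' The single-pass engine: a principal component basis is fitted to the
#' weighted, centered complete frames `N`; a second basis to a copy
#' `N_zeros` with the target markers' columns zeroed; a transition matrix
#' links the two truncated score spaces. Every frame of the (centered,
#' weighted, zero-filled) measurement matrix is projected onto the zeroed
#' basis, mapped through the transition, and expanded through the
#' transpose of the truncated full basis — the pseudoinverse of an
#' orthonormal column block. After un-weighting and un-centering, the
#' reconstructed values replace the missing entries of the target
#' markers; observed samples are returned untouched.
#'
#' @param x a [marker_dataset()] with gaps.
#' @param targets indices or labels of the markers whose gaps to fill.
#' @param params a [recon_params()].
#' @param weights optional pre-built coordinate weight vector; built with
#'   [build_weight_vector()] when `NULL`.
#' @return A list: `dataset` (filled copy of `x`), `info` (list with
#'   `k_full`, `k_zeroed`, `n_complete`, `filled` count).
#' @export
reconstruct_eq1 <- function(x, targets, params = recon_params(),
                            weights = NULL) {
  stopifnot(inherits(x, "marker_dataset"))
  targets <- marker_index(x, targets)
  mask <- gap_mask(x)
  target_cols <- marker_columns(targets)
  if (!any(mask[, targets])) {
    return(list(dataset = x,
                info = list(k_full = NA_integer_, k_zeroed = NA_integer_,
                            n_complete = length(complete_frame_idx(x)),
                            filled = 0L)))
  }
  if (is.null(weights)) weights <- build_weight_vector(x, targets, params)
  cf <- extract_complete_frames(x, params$min_complete)
  N <- cf$matrix
  N_zeros <- N
  N_zeros[, target_cols] <- 0
  basis_full <- fit_basis(N, weights, params$theta_lambda)
  basis_zeroed <- fit_basis(N_zeros, weights, params$theta_lambda)
  # both bases center with the complete-frame means of the *unzeroed* data,
  # so that zero-filled gap entries sit at the centered origin
  basis_zeroed$column_means <- basis_full$column_means
  tr <- transition_matrix(N, N_zeros, basis_full, basis_zeroed,
                          params$transition)
  scores <- basis_scores(basis_zeroed, x$data, zero_fill = TRUE)
  recon_w <- scores %*% tr %*% t(trunc_vectors(basis_full))
  recon <- sweep(sweep(recon_w, 2L, weights, `/`), 2L,
                 basis_full$column_means, `+`)
  filled <- x
  fill_cells <- is.na(x$data)
  fill_cells[, -target_cols] <- FALSE
  filled$data[fill_cells] <- recon[fill_cells]
  list(dataset = filled,
       info = list(k_full = basis_full$k_retained,
                   k_zeroed = basis_zeroed$k_retained,
                   n_complete = nrow(N), filled = sum(fill_cells) / 3L))
}
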