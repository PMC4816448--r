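test_that("complete-frame extraction returns exactly the gap-free rows", {
  d <- generate_gait(gait_params(n_markers = 4, n_frames = 20, seed = 5))
  d2 <- make_single_marker_gap(d, 1, 5, 8)
  cf <- extract_complete_frames(d2)
  expect_equal(cf$frames, c(1:4, 9:20))
  expect_equal(nrow(cf$matrix), 16L)
  expect_equal(cf$matrix, d$data[c(1:4, 9:20), ], tolerance = 1e-12)

  expect_equal(extract_complete_frames(d)$frames, 1:20)

  d3 <- d
  d3$data[cbind(1:20, 3 * ((0:19 %% 4) + 1) - 2)] <- NA
  d3$data[cbind(1:20, 3 * ((0:19 %% 4) + 1) - 1)] <- NA
  d3$data[cbind(1:20, 3 * ((0:19 %% 4) + 1))] <- NA
  expect_error(extract_complete_frames(d3),
               class = "markerfill_insufficient_support")
})

test_that("truncation follows the cumulative normalized singular-value rule", {
  expect_equal(markerfill:::select_k(c(3, 1, 0, 0), 0.99), 2L)
  expect_equal(markerfill:::select_k(c(3, 1, 0, 0), 0.75), 1L)
  expect_equal(markerfill:::select_k(c(3, 1, 0, 0), 1), 2L)
  expect_equal(markerfill:::select_k(c(5, 3, 2, 1, 1), 1), 5L)
  expect_error(markerfill:::select_k(c(0, 0), 0.99),
               class = "markerfill_degenerate_basis")
})

test_that("a full basis reproduces its training matrix", {
  set.seed(8)
  x <- matrix(rnorm(200), 20, 10)
  w <- runif(10, 0.1, 1)
  b <- fit_basis(x, w, theta_lambda = 1)
  v <- markerfill:::trunc_vectors(b)
  xw <- sweep(sweep(x, 2, b$column_means), 2, w, `*`)
  expect_equal(xw %*% v %*% t(v), xw, tolerance = 1e-8)
  expect_equal(t(v) %*% v, diag(ncol(v)), tolerance = 1e-8)
  expect_true(all(diff(b$singular_values) <= 1e-12))
  expect_error(fit_basis(matrix(1, 5, 4), rep(1, 4)),
               class = "markerfill_degenerate_basis")
})

test_that("the transition matrix is identity when nothing is zeroed", {
  d <- exact_rank_dataset(n = 80, m = 5, r = 3, seed = 2)
  w <- rep(1, 15)
  b1 <- fit_basis(d$data, w, 0.99)
  b2 <- fit_basis(d$data, w, 0.99)
  tr <- transition_matrix(d$data, d$data, b1, b2)
  expect_equal(tr, diag(b1$k_retained), tolerance = 1e-8)
})

test_that("on exact rank-3 data the score mapping error vanishes", {
  d <- exact_rank_dataset(n = 150, m = 4, r = 3, seed = 6)
  w <- build_weight_vector(d, 2, recon_params())
  N <- d$data
  Nz <- N; Nz[, marker_columns(2)] <- 0
  bf <- fit_basis(N, w, 1)
  bz <- fit_basis(Nz, w, 1)
  bz$column_means <- bf$column_means
  tr <- transition_matrix(N, Nz, bf, bz)
  s_z <- markerfill:::basis_scores(bz, Nz)
  s_f <- markerfill:::basis_scores(bf, N)
  expect_lt(norm(s_z %*% tr - s_f, "F") / norm(s_f, "F"), 1e-6)

  # identical row permutation of both matrices leaves the map unchanged
  perm <- local({set.seed(1); sample(nrow(N))})
  tr2 <- transition_matrix(N[perm, ], Nz[perm, ], bf, bz)
  expect_equal(tr2, tr, tolerance = 1e-8)
})

test_that("gap-free input passes through the engine unmodified", {
  d <- exact_rank_dataset(n = 60, m = 5, r = 3, seed = 4)
  res <- reconstruct_eq1(d, 1, recon_params())
  expect_identical(res$dataset$data, d$data)
  expect_equal(res$info$filled, 0L)
})

test_that("data in the complete-frame subspace is recovered almost exactly", {
  truth <- exact_rank_dataset(n = 500, m = 40, r = 3, seed = 10)
  corrupted <- make_single_marker_gap(truth, 7, 201, 300)
  p <- recon_params(theta_lambda = 1)
  res <- reconstruct_eq1(corrupted, 7, p)
  expect_lt(mean_gap_error(truth, res$dataset, corrupted), 0.1)
  # cross-check against the independent least-squares completion oracle
  ora <- oracle_subspace_fill(corrupted)
  expect_lt(mean_gap_error(truth, ora, corrupted), 0.1)
  gap_cols <- marker_columns(7)
  expect_equal(res$dataset$data[201:300, gap_cols],
               ora$data[201:300, gap_cols], tolerance = 1e-4)
})

test_that("reconstruction is equivariant under global translation", {
  truth <- exact_rank_dataset(n = 200, m = 8, r = 3, seed = 12)
  corrupted <- make_single_marker_gap(truth, 3, 50, 90)
  p <- recon_params(theta_lambda = 1)
  base <- reconstruct_eq1(corrupted, 3, p)$dataset$data
  shift <- rep(c(500, -300, 250), times = 8)
  moved <- corrupted
  moved$data <- corrupted$data + shift[col(corrupted$data)]
  res <- reconstruct_eq1(moved, 3, p)$dataset$data
  expect_equal(res, base + shift[col(base)], tolerance = 1e-6)
})

test_that("a zero missing-marker weight is rejected", {
  expect_error(recon_params(w_mm = 0), class = "markerfill_parameter_error")
  expect_error(recon_params(w_mm = -0.1), class = "markerfill_parameter_error")
  expect_error(recon_params(sigma = 0), class = "markerfill_parameter_error")
  expect_error(recon_params(theta_lambda = 0), class = "markerfill_parameter_error")
  expect_error(recon_params(theta_d = -1), class = "markerfill_parameter_error")
})
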