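test_that("a perfect reconstruction scores zero", {
  d <- generate_gait(gait_params(n_markers = 5, n_frames = 50, seed = 1))
  mask <- matrix(FALSE, 50, 5)
  mask[10:20, 2] <- TRUE
  s <- score_reconstruction(d, d, mask)
  expect_equal(s$mean_euclidean, 0)
  expect_equal(unname(s$per_axis_mae), c(0, 0, 0))
  expect_equal(s$n_gap_frames, 11L)
})

test_that("a constant (1,2,2) mm offset scores mean Euclidean 3", {
  d <- generate_gait(gait_params(n_markers = 4, n_frames = 30, seed = 2))
  filled <- d
  mask <- matrix(FALSE, 30, 4)
  mask[5:14, 3] <- TRUE
  filled$data[5:14, marker_columns(3)] <-
    filled$data[5:14, marker_columns(3)] +
    matrix(c(1, 2, 2), 10, 3, byrow = TRUE)
  # perturb a non-gap sample of another marker: must not affect the score
  filled$data[1, 1] <- filled$data[1, 1] + 999
  s <- score_reconstruction(d, filled, mask)
  expect_equal(s$mean_euclidean, 3)
  expect_equal(unname(s$per_axis_mae), c(1, 2, 2))
  expect_equal(unname(s$per_marker["M3"]), 3)
  expect_error(score_reconstruction(d, filled, matrix(FALSE, 30, 4)),
               class = "markerfill_parameter_error")
})

test_that("scoring is symmetric under joint marker permutation", {
  d <- generate_gait(gait_params(n_markers = 6, n_frames = 80, seed = 3))
  cc <- corrupt_with_gaps(d, c(2, 3), c(10, 20), seed = 4)
  filled <- fill_linear(cc$dataset)$dataset
  s <- score_reconstruction(d, filled, gap_mask(cc$dataset))
  perm <- c(4, 1, 6, 2, 5, 3)
  pd <- function(x) marker_dataset(x$data[, marker_columns(perm)],
                                   x$labels[perm], x$frame_rate)
  s2 <- score_reconstruction(pd(d), pd(filled),
                             gap_mask(cc$dataset)[, perm, drop = FALSE])
  expect_equal(s2$mean_euclidean, s$mean_euclidean)
  expect_equal(s2$per_marker[names(s$per_marker)], s$per_marker)
})

test_that("replicated experiments are reproducible and exact for an oracle fill", {
  d <- generate_gait(gait_params(n_markers = 8, n_frames = 150, seed = 5))
  oracle <- function(corrupted, params) list(dataset = d)
  r <- replicate_experiment(d, oracle, n_gaps = c(1, 3), gap_len = c(5, 20),
                            n_replicates = 6, seed = 17)
  expect_equal(r$errors, rep(0, 6))
  r1 <- replicate_experiment(d, "linear", n_gaps = c(1, 3), gap_len = c(5, 20),
                             n_replicates = 6, seed = 17)
  r2 <- replicate_experiment(d, "linear", n_gaps = c(1, 3), gap_len = c(5, 20),
                             n_replicates = 6, seed = 17)
  expect_identical(r1$errors, r2$errors)
  expect_identical(r1$median, median(r1$errors))
})

test_that("sensitivity grids have the standard shapes and domains", {
  expect_length(sensitivity_grid("w_mm"), 15L)
  expect_length(sensitivity_grid("sigma"), 15L)
  expect_length(sensitivity_grid("theta_lambda"), 15L)
  expect_length(sensitivity_grid("theta_d"), 11L)
  expect_equal(range(sensitivity_grid("w_mm")), c(1e-5, 1))
  expect_equal(range(sensitivity_grid("sigma")), c(100, 1500))
  expect_equal(range(sensitivity_grid("theta_lambda")), c(0.86, 1))
  expect_equal(range(sensitivity_grid("theta_d")), c(0, 2))
  # logarithmic vs linear spacing
  expect_equal(diff(log10(sensitivity_grid("w_mm"))),
               rep(5 / 14, 14), tolerance = 1e-10)
  expect_equal(diff(sensitivity_grid("theta_d")), rep(0.2, 10))
  expect_error(sensitivity_grid("nope"), class = "markerfill_parameter_error")
})

test_that("sensitivity curves are centered per corrupted copy", {
  d <- generate_gait(gait_params(n_markers = 8, n_frames = 200, seed = 7))
  sw <- sensitivity_sweep(d, "theta_d", grid = c(0, 0.5, 1, 2),
                          n_copies = 3, n_gaps = c(2, 3),
                          gap_len = c(10, 30), seed = 23)
  expect_equal(nrow(sw), 4L)
  expect_equal(sum(sw$centered_error), 0, tolerance = 1e-9)
  expect_true(all(sw$sem >= 0, na.rm = TRUE))
})

test_that("the basis transition is strongly sensitive to the missing-marker weight", {
  # under the score-space least-squares transition the reconstruction is
  # close to optimal for any w_mm; the basis-overlap transition degrades
  # sharply as w_mm approaches 1 (see the methods vignette)
  truth <- generate_gait(gait_params(preset = "cp", seed = 71))
  cc <- corrupt_with_gaps(truth, c(2, 6), c(20, 120), seed = 72)
  err <- function(w, tr) {
    p <- recon_params(w_mm = w, transition = tr)
    mean_gap_error(truth, suppressWarnings(reconstruct_r2(cc$dataset, p))$dataset,
                   cc$dataset)
  }
  expect_gt(err(1, "basis") / err(0.02, "basis"), 3)
  expect_lt(err(0.02, "scores"), err(1, "basis"))
})
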