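# three markers at fixed mutual distances with gaps we control
three_marker_case <- function(gap_a = 11:20, gap_b = NULL, gap_c = NULL) {
  pos <- rbind(A = c(0, 0, 0), B = c(100, 0, 0), C = c(900, 0, 0))
  d <- constant_dataset(pos, n = 60)
  # wiggle so the bases are not degenerate
  set.seed(99)
  d$data <- d$data + matrix(rnorm(length(d$data), 0, 1), nrow = 60)
  if (length(gap_a)) d$data[gap_a, 1:3] <- NA
  if (length(gap_b)) d$data[gap_b, 4:6] <- NA
  if (length(gap_c)) d$data[gap_c, 7:9] <- NA
  d
}

test_that("the theta_d cutoff keeps near and omits far corrupted markers", {
  # D_A = (100 + 900) / 2 = 500, threshold 0.5 * 500 = 250 mm
  d <- three_marker_case(gap_a = 11:20, gap_b = 31:35, gap_c = 41:50)
  dec <- select_neighbors_r2(d, "A", recon_params())
  expect_equal(dec$included_markers, 2L)
  expect_equal(dec$dropped_frames, 31:35)
  expect_equal(dec$omitted_markers, c(C = "beyond-theta-d"))
  expect_equal(dec$d_mean, 500, tolerance = 0.05)
})

test_that("temporal overlap forces omission regardless of distance", {
  d <- three_marker_case(gap_a = 55:70 - 15, gap_b = 50:60 - 10)
  # target A gaps 40-55, B gaps 40-50: overlap, B at only 100 mm
  dec <- select_neighbors_r2(d, "A", recon_params())
  expect_equal(unname(dec$omitted_markers["B"]), "temporal-overlap")
  expect_false(2L %in% dec$included_markers)
})

test_that("a permissive theta_d includes all non-overlapping corrupted markers", {
  d <- three_marker_case(gap_a = 11:20, gap_b = 31:35, gap_c = 41:50)
  dec <- select_neighbors_r2(d, "A", recon_params(theta_d = 2))
  expect_equal(sort(dec$included_markers), c(2L, 3L))
  expect_equal(dec$dropped_frames, c(31:35, 41:50))
  expect_length(dec$omitted_markers, 0L)
})

test_that("with one corrupted marker R1, R2 and the single-marker engine coincide bitwise", {
  truth <- generate_gait(gait_params(n_markers = 10, n_frames = 150, seed = 21))
  corrupted <- make_single_marker_gap(truth, 4, 40, 80)
  p <- recon_params()
  f1 <- reconstruct_r1(corrupted, p)
  f2 <- reconstruct_r2(corrupted, p)
  fs <- reconstruct_single_marker(corrupted, 4, p)
  expect_identical(f1$dataset$data, f2$dataset$data)
  expect_identical(f1$dataset$data, fs$dataset$data)
})

test_that("disjoint multi-marker gaps on exact low-rank data are recovered", {
  truth <- exact_rank_dataset(n = 400, m = 12, r = 4, seed = 31)
  corrupted <- truth
  corrupted$data[51:130, marker_columns(2)] <- NA
  corrupted$data[151:230, marker_columns(7)] <- NA
  corrupted$data[251:330, marker_columns(11)] <- NA
  p <- recon_params(theta_lambda = 1)
  e1 <- mean_gap_error(truth, reconstruct_r1(corrupted, p)$dataset, corrupted)
  e2 <- mean_gap_error(truth, reconstruct_r2(corrupted, p)$dataset, corrupted)
  expect_lt(e1, 0.5)
  expect_lt(e2, 0.5)
  expect_lte(e2, e1 + 1e-6)
})

test_that("neither strategy modifies an observed sample", {
  truth <- generate_gait(gait_params(n_markers = 8, n_frames = 200, seed = 41))
  cc <- corrupt_with_gaps(truth, c(2, 4), c(10, 40), seed = 7)
  obs <- !is.na(cc$dataset$data)
  for (method in c("r1", "r2", "spline", "linear")) {
    res <- fill_gaps(cc$dataset, method)
    expect_identical(res$dataset$data[obs], cc$dataset$data[obs])
    expect_false(anyNA(res$dataset$data))
  }
})

test_that("gap-free input is returned unchanged with an empty report", {
  d <- generate_gait(gait_params(n_markers = 5, n_frames = 50, seed = 51))
  for (method in c("r1", "r2", "spline", "linear")) {
    res <- fill_gaps(d, method)
    expect_identical(res$dataset$data, d$data)
    expect_equal(res$report$gaps_filled, 0)
  }
})

test_that("a marker whose support collapses is reported unfilled, not fatal", {
  # two corrupted markers with overlapping gaps: each omits the other,
  # and no complete marker can rescue a 2-marker dataset
  pos <- rbind(A = c(0, 0, 0), B = c(100, 0, 0))
  d <- constant_dataset(pos, n = 40)
  set.seed(3)
  d$data <- d$data + matrix(rnorm(length(d$data), 0, 1), nrow = 40)
  d$data[11:20, 1:3] <- NA
  d$data[15:25, 4:6] <- NA
  w <- capture_warnings(res <- reconstruct_r2(d, recon_params()))
  expect_match(w, "unfilled", all = FALSE)
  expect_equal(sort(res$report$unfilled), c(1L, 2L))
  expect_true(anyNA(res$dataset$data))
})

test_that("R2 is independent of marker ordering", {
  truth <- generate_gait(gait_params(n_markers = 9, n_frames = 180, seed = 61))
  cc <- corrupt_with_gaps(truth, c(3, 3), c(15, 30), seed = 13)
  p <- recon_params()
  base <- reconstruct_r2(cc$dataset, p)$dataset$data
  perm <- local({set.seed(2); sample(9)})
  permuted <- marker_dataset(cc$dataset$data[, marker_columns(perm)],
                             cc$dataset$labels[perm], truth$frame_rate)
  res <- reconstruct_r2(permuted, p)$dataset$data
  expect_equal(res, base[, marker_columns(perm)], tolerance = 1e-6)
})
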