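# Shared fixtures: small datasets built in code, plus the independent
# least-squares subspace-completion oracle used to cross-check the
# dual-basis engine.

# dataset with every marker at a fixed position (optionally + per-frame drift)
constant_dataset <- function(positions, n = 10L, frame_rate = 100) {
  m <- nrow(positions)
  d <- matrix(rep(as.vector(t(positions)), each = n), nrow = n)
  marker_dataset(d, rownames(positions), frame_rate)
}

# exact rank-r gait-like data: latent sinusoids, no noise, no soft tissue
exact_rank_dataset <- function(n = 200L, m = 12L, r = 3L, seed = 1L) {
  generate_gait(gait_params(n_markers = m, n_frames = n, latent_rank = r,
                            noise_sd = 0, soft_tissue_segment = 0,
                            soft_tissue_marker = 0, seed = seed))
}

# brute-force completion: basis from the complete frames, per-frame least
# squares on the observed coordinates (no weighting, no dual basis)
oracle_subspace_fill <- function(corrupted) {
  M <- corrupted$data
  comp <- rowSums(is.na(M)) == 0L
  N <- M[comp, , drop = FALSE]
  mu <- colMeans(N)
  sv <- svd(sweep(N, 2L, mu))
  r <- sum(sv$d > sv$d[1L] * 1e-9)
  B <- sv$v[, seq_len(r), drop = FALSE]
  out <- M
  for (i in which(!comp)) {
    obs <- !is.na(M[i, ])
    coef <- qr.solve(B[obs, , drop = FALSE], M[i, obs] - mu[obs])
    out[i, !obs] <- B[!obs, , drop = FALSE] %*% coef + mu[!obs]
  }
  res <- corrupted
  res$data <- out
  res
}

mean_gap_error <- function(truth, filled, corrupted) {
  score_reconstruction(truth, filled, gap_mask(corrupted))$mean_euclidean
}
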