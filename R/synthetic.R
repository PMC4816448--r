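#' Parameters of the synthetic gait generator
#'
#' Describes a gait-like trial: a small set of latent periodic source
#' signals (harmonics of the stride frequency plus a slow drift), mixed
#' onto markers that sit in clusters on the segments of a connected,
#' body-sized kinematic chain. Mixing coefficients vary smoothly with a
#' segment's position in space, so nearby markers move similarly — the
#' property the distance-weighted reconstruction exploits. On top of the
#' shared low-rank motion, each segment carries a common low-frequency
#' "soft tissue" component, each marker a smaller idiosyncratic one, and
#' every sample white measurement noise.
#'
#' Presets mirror the three trial types used throughout the package's
#' experiments: `"walkl"` — long treadmill walking (4300 frames at
#' 240 Hz, 37 markers); `"cp"` — a short irregular over-ground trial
#' (600 frames at 200 Hz, 35 markers); `"walkrun"` — a short trial with
#' a walk-to-run regime switch halfway (400 frames at 120 Hz, 37
#' markers), where the mixing fields and stride frequency change at the
#' transition frame.
#'
#' @param n_markers number of markers.
#' @param n_frames number of time frames.
#' @param frame_rate capture rate in Hz.
#' @param stride_frequency stride rate in Hz.
#' @param amplitude_scale RMS amplitude of the shared motion, mm.
#' @param latent_rank number of latent source signals (must be below
#'   `3 * n_markers`).
#' @param noise_sd white measurement noise, mm.
#' @param soft_tissue_segment amplitude of the per-segment shared smooth
#'   artifact, mm.
#' @param soft_tissue_marker amplitude of the per-marker smooth artifact,
#'   mm.
#' @param transition_frame optional frame at which the movement regime
#'   switches (walk-to-run emulation); `NULL` for a single regime.
#' @param transition_scale relative size of the mixing-field change at
#'   the transition.
#' @param stride_ratio stride-frequency multiplier after the transition.
#' @param markers_per_segment cluster size on each chain segment.
#' @param segment_spread half-width of the marker cluster, mm.
#' @param chain_step distance between consecutive segments, mm.
#' @param field_scale smoothness length of the mixing fields, mm.
#' @param intra_segment_var relative within-segment mixing variation.
#' @param seed RNG seed; the generator is deterministic given the seed.
#' @param preset `"custom"`, `"walkl"`, `"cp"` or `"walkrun"`.
#' @return A list of class `gait_params`.
#' @export
gait_params <- function(n_markers = 37L, n_frames = 1200L, frame_rate = 120,
                        stride_frequency = 0.9, amplitude_scale = 300,
                        latent_rank = 8L, noise_sd = 0.5,
                        soft_tissue_segment = 4, soft_tissue_marker = 1.5,
                        transition_frame = NULL, transition_scale = 0.2,
                        stride_ratio = 1.3, markers_per_segment = 3L,
                        segment_spread = 70, chain_step = 300,
                        field_scale = 600, intra_segment_var = 0.15,
                        seed = 1L,
                        preset = c("custom", "walkl", "cp", "walkrun")) {
  preset <- match.arg(preset)
  p <- as.list(environment())
  p$preset <- NULL
  ov <- switch(preset,
               custom = list(),
               walkl = list(n_markers = 37L, n_frames = 4300L,
                            frame_rate = 240),
               cp = list(n_markers = 35L, n_frames = 600L, frame_rate = 200,
                         soft_tissue_segment = 6, soft_tissue_marker = 2.5),
               walkrun = list(n_markers = 37L, n_frames = 400L,
                              frame_rate = 120, transition_frame = 200L))
  p[names(ov)] <- ov
  with(p, {
    if (latent_rank >= 3L * n_markers)
      mf_stop("parameter_error", "latent_rank must be below 3 * n_markers")
    if (noise_sd < 0 || soft_tissue_segment < 0 || soft_tissue_marker < 0)
      mf_stop("parameter_error", "noise amplitudes must be >= 0")
    if (n_frames < 2L || n_markers < 2L)
      mf_stop("parameter_error", "need n_frames >= 2 and n_markers >= 2")
    if (!is.null(transition_frame) &&
        (transition_frame < 2L || transition_frame >= n_frames))
      mf_stop("parameter_error", "transition_frame outside the trial")
  })
  structure(p, class = "gait_params")
}

#' Generate a synthetic gait dataset
#'
#' @param params a [gait_params()] description.
#' @return A gap-free [marker_dataset()] in mm.
#' @seealso [corrupt_with_gaps()], [make_single_marker_gap()]
#' @export
generate_gait <- function(params = gait_params()) {
  stopifnot(inherits(params, "gait_params"))
  p <- params
  local_seed(p$seed, {
    m <- p$n_markers; n <- p$n_frames; r <- p$latent_rank
    n_seg <- ceiling(m / p$markers_per_segment)
    seg_of <- rep(seq_len(n_seg), each = p$markers_per_segment)[seq_len(m)]
    # random-walk chain of segments inside a standing-person volume
    seg_pos <- matrix(0, n_seg, 3L)
    seg_pos[1L, ] <- c(0, 0, 1000)
    if (n_seg > 1L) for (s in 2:n_seg) {
      repeat {
        dir <- rnorm(3L); dir <- dir / sqrt(sum(dir^2))
        cand <- seg_pos[s - 1L, ] + p$chain_step * dir
        if (abs(cand[1L]) < 400 && abs(cand[2L]) < 400 &&
            cand[3L] > 0 && cand[3L] < 1900) break
      }
      seg_pos[s, ] <- cand
    }
    pos <- seg_pos[seg_of, , drop = FALSE] +
      matrix(runif(3L * m, -p$segment_spread, p$segment_spread), m)

    latents <- function(n0, stride) {
      t0 <- (seq_len(n0) - 1L) / p$frame_rate
      vapply(seq_len(r), function(q) {
        f <- if (q == 1L) stride / 8 else stride * ceiling((q - 1L) / 2)
        sin(2 * pi * f * t0 + runif(1L, 0, 2 * pi))
      }, numeric(n0))
    }
    # mixing coefficients: smooth Gaussian random field over segment
    # positions, expanded to markers with a small within-segment deviation
    seg_field <- function() {
      cs <- array(0, c(r, n_seg, 3L)); nq <- 6L
      for (q in seq_len(r)) for (a in 1:3) {
        z <- cbind(runif(nq, -400, 400), runif(nq, -400, 400),
                   runif(nq, 0, 1900))
        b <- rnorm(nq)
        for (s in seq_len(n_seg)) {
          d2 <- rowSums((z - matrix(seg_pos[s, ], nq, 3L, byrow = TRUE))^2)
          cs[q, s, a] <- sum(b * exp(-d2 / (2 * p$field_scale^2)))
        }
      }
      cs
    }
    expand_field <- function(cs) {
      cmat <- matrix(0, r, 3L * m)
      for (j in seq_len(m)) for (a in 1:3)
        cmat[, 3L * (j - 1L) + a] <-
          cs[, seg_of[j], a] * (1 + p$intra_segment_var * rnorm(r))
      cmat
    }
    if (is.null(p$transition_frame)) {
      x <- latents(n, p$stride_frequency) %*% expand_field(seg_field())
    } else {
      cs1 <- seg_field()
      cs2 <- cs1 + p$transition_scale * seg_field()
      tf <- p$transition_frame
      x <- rbind(
        latents(tf, p$stride_frequency) %*% expand_field(cs1),
        latents(n - tf, p$stride_frequency * p$stride_ratio) %*%
          expand_field(cs2))
    }
    rms <- sqrt(mean(x^2))
    if (rms > 0) x <- x * (p$amplitude_scale / rms)

    t0 <- (seq_len(n) - 1L) / p$frame_rate
    smooth_artifact <- function(amp) {
      f1 <- runif(1L, 0.2, 1.4); f2 <- runif(1L, 0.2, 1.4)
      amp / sqrt(2) * (sin(2 * pi * f1 * t0 + runif(1L, 0, 2 * pi)) +
                       sin(2 * pi * f2 * t0 + runif(1L, 0, 2 * pi)))
    }
    if (p$soft_tissue_segment > 0) for (s in seq_len(n_seg)) for (a in 1:3) {
      w <- smooth_artifact(p$soft_tissue_segment)
      for (j in which(seg_of == s)) x[, 3L * (j - 1L) + a] <-
        x[, 3L * (j - 1L) + a] + w
    }
    if (p$soft_tissue_marker > 0) for (j in seq_len(m)) for (a in 1:3)
      x[, 3L * (j - 1L) + a] <-
        x[, 3L * (j - 1L) + a] + smooth_artifact(p$soft_tissue_marker)
    x <- sweep(x, 2L, as.vector(t(pos)), `+`)
    if (p$noise_sd > 0)
      x <- x + matrix(rnorm(n * 3L * m, 0, p$noise_sd), n)
    marker_dataset(x, frame_rate = p$frame_rate)
  })
}

#' Corrupt a dataset with randomly placed gaps
#'
#' Implements the randomized multi-gap protocol: the number of gaps is
#' drawn uniformly from `n_gaps`, and each gap hits a uniformly chosen
#' marker (with replacement) at a uniformly chosen start frame, with a
#' duration drawn uniformly from `gap_len`. Gaps on the same marker may
#' overlap; their union is removed. If fewer than `min_complete_frac` of
#' the frames remain complete, the whole configuration is redrawn so the
#' reconstruction always has a training set.
#'
#' @param x a gap-free [marker_dataset()].
#' @param n_gaps integer range `c(lo, hi)` for the number of gaps.
#' @param gap_len integer range `c(lo, hi)` for gap durations in frames.
#' @param seed RNG seed.
#' @param min_complete_frac minimum fraction of frames that must remain
#'   complete (default 5%).
#' @param max_tries redraw budget before giving up.
#' @return A list: `dataset` (corrupted copy), `gaps` (data frame with
#'   `marker`, `start`, `length` for every realized gap).
#' @export
corrupt_with_gaps <- function(x, n_gaps = c(5L, 15L), gap_len = c(20L, 480L),
                              seed = 1L, min_complete_frac = 0.05,
                              max_tries = 100L) {
  stopifnot(inherits(x, "marker_dataset"))
  if (any(gap_mask(x)))
    mf_stop("parameter_error", "input dataset must be gap-free")
  n <- n_frames(x); m <- n_markers(x)
  if (any(n_gaps < 1L) || any(gap_len < 1L) || max(gap_len) >= n)
    mf_stop("parameter_error",
            "infeasible gap specification for %d frames", n)
  local_seed(seed, {
    for (try in seq_len(max_tries)) {
      d <- x$data
      k <- n_gaps[1L] + sample.int(n_gaps[2L] - n_gaps[1L] + 1L, 1L) - 1L
      marker <- integer(k); start <- integer(k); len <- integer(k)
      for (g in seq_len(k)) {
        marker[g] <- sample.int(m, 1L)
        len[g] <- gap_len[1L] + sample.int(gap_len[2L] - gap_len[1L] + 1L, 1L) - 1L
        start[g] <- sample.int(n - len[g] + 1L, 1L)
        d[start[g]:(start[g] + len[g] - 1L), marker_columns(marker[g])] <-
          NA_real_
      }
      if (sum(rowSums(is.na(d)) == 0L) >= min_complete_frac * n) {
        out <- x; out$data <- d
        return(list(dataset = out,
                    gaps = data.frame(marker = x$labels[marker],
                                      start = start, length = len)))
      }
    }
    mf_stop("parameter_error",
            "could not place gaps leaving %.0f%% complete frames in %d tries",
            100 * min_complete_frac, max_tries)
  })
}

#' Remove one contiguous block of a single marker
#'
#' @param x a [marker_dataset()].
#' @param marker index or label.
#' @param start,end first and last frame of the gap (inclusive). An empty
#'   range (`start > end`) leaves the dataset unchanged.
#' @return The corrupted dataset.
#' @export
make_single_marker_gap <- function(x, marker, start, end) {
  stopifnot(inherits(x, "marker_dataset"))
  j <- marker_index(x, marker)
  if (start > end) return(x)
  if (start < 1L || end > n_frames(x))
    mf_stop("parameter_error", "frame range %d-%d outside 1-%d",
            start, end, n_frames(x))
  x$data[start:end, marker_columns(j)] <- NA_real_
  x
}
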