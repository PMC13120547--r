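# Independent oracles and shared fixtures, kept deliberately naive so they
# stay independent of the implementation paths they check.

with_seed <- function(seed, code) {
  set.seed(seed)
  force(code)
}

# brute-force backward finite difference, scalar loop
oracle_diff <- function(x, fps) {
  n <- length(x)
  out <- rep(NA_real_, n)
  for (t in 2:n) out[t] <- (x[t] - x[t - 1]) * fps
  out
}

# brute-force second derivative: two passes of the first-difference loop
oracle_diff2 <- function(x, fps) {
  v <- oracle_diff(x, fps)
  n <- length(x)
  out <- rep(NA_real_, n)
  for (t in 3:n) out[t] <- (v[t] - v[t - 1]) * fps
  out
}

# exact Mann-Whitney two-sided p by enumeration of all group-A position
# choices (tie-free inputs only); U counts pairs with a > b
oracle_mann_whitney <- function(a, b) {
  na <- length(a)
  pooled <- c(a, b)
  u_obs <- sum(outer(a, b, ">"))
  combos <- utils::combn(length(pooled), na)
  us <- apply(combos, 2L, function(idx) {
    sum(outer(pooled[idx], pooled[-idx], ">"))
  })
  mu <- na * length(b) / 2
  p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
  list(U = u_obs, p = p)
}

# hand BH step-up
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- rep(NA_real_, m)
  prev <- 1
  for (i in m:1) {
    v <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- v
    prev <- v
  }
  pmin(adj, 1)
}

# random but structurally valid pose sequence for round-trip/property tests
random_sequence <- function(seed, n_frames = 5L, fps = 60) {
  with_seed(seed, {
    kp <- array(stats::runif(n_frames * 17 * 3), c(n_frames, 17, 3))
    kp[, , 1] <- kp[, , 1] * 1920
    kp[, , 2] <- kp[, , 2] * 1080
    fall_sequence(
      subject_id = sprintf("R%05d", seed),
      track_id = sample(10, 1),
      fps = fps,
      keypoints = kp,
      frame_size = c(1920, 1080),
      visibility = matrix(stats::runif(n_frames * 17) > 0.1, n_frames, 17),
      cohort = sample(c("pre", "post", "unknown"), 1),
      quality_label = sample(c("safe", "hazardous", NA), 1),
      meta = list(note = "round-trip fixture"))
  })
}

# a sequence whose mid-hip follows a supplied (x, y) path, all other
# keypoints rigidly attached
path_sequence <- function(x, y, fps = 60, frame_size = c(1920, 1080)) {
  n <- length(x)
  kp <- array(0, c(n, 17, 3))
  kp[, , 3] <- 1
  offs_x <- seq(-40, 40, length.out = 17)
  offs_y <- seq(-160, 100, length.out = 17)
  for (k in 1:17) {
    kp[, k, 1] <- x + offs_x[k]
    kp[, k, 2] <- y + offs_y[k]
  }
  # hips straddle the path point symmetrically so mid_hip == (x, y)
  kp[, 12, 1] <- x - 40; kp[, 12, 2] <- y
  kp[, 13, 1] <- x + 40; kp[, 13, 2] <- y
  fall_sequence("path", fps = fps, keypoints = kp, frame_size = frame_size)
}

# noiseless profile defaults
clean_params <- function(profile, ...) {
  profile_params(profile, keypoint_noise_sd = 0, dropout_rate = 0, ...)
}

# Cohort metric tables are the expensive shared fixture: simulated lazily,
# cached for the whole test session, and reused by every test that needs a
# default-condition cohort.
.cohort_cache <- new.env(parent = emptyenv())

cached_cohort_table <- function(seed, n_pre = 285L, n_post = 130L,
                                null_mix = FALSE) {
  key <- sprintf("s%d_%d_%d_%d", seed, n_pre, n_post, null_mix)
  if (!is.null(.cohort_cache[[key]])) return(.cohort_cache[[key]])
  spec <- if (null_mix) {
    # global null: same mix and no training effect in either cohort
    mix <- c(chaotic = 0.10, controlled = 0.55, freezing = 0.35)
    cohort_spec(n_pre = n_pre, n_post = n_post, pre_mix = mix,
                post_mix = mix, post_descent_gain = 1, post_speed_gain = 1,
                seed = seed)
  } else {
    cohort_spec(n_pre = n_pre, n_post = n_post, seed = seed)
  }
  m <- cohort_metrics(simulate_cohort(spec))
  .cohort_cache[[key]] <- m
  m
}

# chance-corrected partition agreement (oracle: mclust)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
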