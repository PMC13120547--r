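# internal helpers shared across modules

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Centered moving average with a window that shrinks at the edges so the
# output has the same length as the input and no NA padding is introduced.
# NA values are ignored within each window.
moving_average <- function(x, width) {
  if (width <= 1L) return(x)
  n <- length(x)
  half <- floor(width / 2)
  ok <- !is.na(x)
  cs <- cumsum(c(0, ifelse(ok, x, 0)))
  cn <- cumsum(c(0, ok))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  s <- cs[hi + 1L] - cs[lo]
  m <- cn[hi + 1L] - cn[lo]
  out <- s / m
  out[m == 0] <- NA_real_
  out
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the global
# RNG state is restored afterwards so callers' streams are not perturbed.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a stream of independent child seeds from one master seed, kept
# below 2^31 so they are valid R integer seeds.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# cubic smoothstep on [0, 1]: C1-continuous ramp used for posture blends
smoothstep <- function(u) {
  u <- clamp(u, 0, 1)
  u * u * (3 - 2 * u)
}

# quintic smootherstep: C2-continuous, so its acceleration is continuous and
# the deceleration peak lies in the interior of the ramp (u ~ 0.79) — used
# for the hip descent so the template has a well-defined, smoothing-robust
# peak-deceleration frame
smootherstep <- function(u) {
  u <- clamp(u, 0, 1)
  u^3 * (10 - 15 * u + 6 * u^2)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
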