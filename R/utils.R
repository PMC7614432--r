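# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so simulation helpers never perturb user randomness.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv(), inherits = FALSE)
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Linear interpolation on a uniform grid (origin x0, spacing dx) with
# constant extrapolation beyond the ends. Fully vectorised in `q`; used on
# matrices of query times when shifting voxel timecourses.
lin_interp <- function(y, x0, dx, q) {
  n <- length(y)
  pos <- (q - x0) / dx
  pos <- pmin(pmax(pos, 0), n - 1)
  lo <- pmin(floor(pos), n - 2)
  frac <- pos - lo
  out <- y[lo + 1] * (1 - frac) + y[lo + 2] * frac
  if (!is.null(dim(q))) dim(out) <- dim(q)
  out
}

# Zero-mean, unit-variance stationary signal band-limited to `band` (Hz),
# built by top-hat filtering white noise in the frequency domain. Caller is
# responsible for seeding the RNG.
band_limited_signal <- function(n, dt, band = c(0.01, 0.1)) {
  stopifnot(n > 8, dt > 0, band[1] < band[2])
  w <- stats::rnorm(n)
  f <- stats::fft(w)
  freq <- (seq_len(n) - 1) / (n * dt)
  freq <- pmin(freq, 1 / dt - freq) # two-sided spectrum folded to [0, Nyquist]
  f[freq < band[1] | freq > band[2]] <- 0
  s <- Re(stats::fft(f, inverse = TRUE)) / n
  (s - mean(s)) / stats::sd(s)
}

gauss_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

# Separable Gaussian smoothing of a 3D array with edge replication; used to
# give synthetic parameter fields realistic spatial autocorrelation.
smooth3d <- function(arr, sigma_vox = 1.5) {
  k <- gauss_kernel_1d(sigma_vox)
  r <- (length(k) - 1L) / 2L
  smooth_vec <- function(v) {
    n <- length(v)
    vp <- c(rep(v[1], r), v, rep(v[n], r))
    as.numeric(stats::filter(vp, k, sides = 2))[(r + 1L):(r + n)]
  }
  d <- dim(arr)
  for (ax in 1:3) {
    arr <- apply(arr, setdiff(1:3, ax), smooth_vec)
    # apply collapses the processed axis to the first dimension; restore order
    arr <- aperm(array(arr, dim = c(d[ax], d[setdiff(1:3, ax)])),
                 order(c(ax, setdiff(1:3, ax))))
  }
  arr
}

# Coerce a mask argument to a logical 3D array, validating its grid.
as_mask <- function(mask, dims = NULL, arg = "mask") {
  if (is.null(mask)) return(NULL)
  m <- array(as.logical(mask), dim = dim(mask))
  if (length(dim(m)) != 3L) stop("`", arg, "` must be a 3D volume")
  if (!is.null(dims) && !all(dim(m) == dims)) {
    stop("`", arg, "` grid ", paste(dim(m), collapse = "x"),
         " does not match the expected grid ", paste(dims, collapse = "x"))
  }
  m
}

# Scatter a per-voxel vector back into a 3D volume over `mask`.
vec_to_vol <- function(values, mask, fill = NA_real_) {
  out <- array(fill, dim = dim(mask))
  out[mask] <- values
  out
}
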