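# Wavelet-threshold denoising of 1-D motion signals.
#
# The decimated discrete wavelet transform is implemented directly
# (Daubechies / Symlet orthogonal filter banks; symmetric or periodized
# boundary handling) since the thresholding pipeline needs full control over
# the coefficient layout. Conventions follow the usual pyramid algorithm:
# analysis by filtering the boundary-extended signal and downsampling by 2,
# synthesis by upsampling, filtering with the time-reversed filters and
# summing the two branches.

.wavelet_dec_lo <- list(
  db1 = c(0.70710678118654757, 0.70710678118654757),
  db2 = c(-0.12940952255126037, 0.22414386804201339,
          0.83651630373780794, 0.48296291314453416),
  db4 = c(-0.010597401785069032, 0.032883011666885197, 0.030841381835560764,
          -0.18703481171909309, -0.027983769416859854, 0.63088076792985892,
          0.71484657055291567, 0.23037781330889651),
  db8 = c(-0.00011747678412476953, 0.00067544940645056933,
          -0.00039174037337694705, -0.0048703529934515741,
          0.0087460940474057766, 0.013981027917398282,
          -0.044088253930794755, -0.017369301001807547,
          0.12874742662047847, 0.00047248457391328279,
          -0.28401554296154691, -0.015829105256349306,
          0.58535468365420673, 0.67563073629728976,
          0.31287159091429995, 0.054415842243104008),
  sym4 = c(-0.075765714789273325, -0.02963552764599851, 0.49761866763201545,
           0.80373875180591614, 0.29785779560527736, -0.099219543576847216,
           -0.012603967262037833, 0.032223100604042702),
  sym8 = c(-0.0033824159510061256, -0.00054213233179114812,
           0.031695087811492981, 0.0076074873249176054,
           -0.14329423835080971, -0.061273359067658524,
           0.48135965125837221, 0.77718575170052351,
           0.3644418948353314, -0.051945838107709037,
           -0.027219029917056003, 0.049137179673607506,
           0.0038087520138906151, -0.014952258337048231,
           -0.0003029205147213668, 0.0018899503327594609))

wavelet_filters <- function(wavelet) {
  dl <- .wavelet_dec_lo[[wavelet]]
  if (is.null(dl)) {
    stopf("unknown wavelet '%s' (available: %s)", wavelet,
          paste(names(.wavelet_dec_lo), collapse = ", "))
  }
  L <- length(dl)
  rec_hi <- dl * (-1)^(0:(L - 1))
  list(dec_lo = dl, dec_hi = rev(rec_hi), rec_lo = rev(dl), rec_hi = rec_hi,
       L = L)
}

conv_full <- function(x, f) {
  n <- length(x); L <- length(f)
  y <- numeric(n + L - 1)
  for (j in seq_len(L)) y[j:(j + n - 1)] <- y[j:(j + n - 1)] + f[j] * x
  y
}

dwt_step <- function(x, fb, mode) {
  L <- fb$L; n <- length(x)
  if (mode == "symmetric") {
    if (n < L - 1) stopf("signal too short for the filter length")
    ext <- c(x[(L - 1):1], x, x[n:(n - L + 2)])
    idx <- seq(L + 1, by = 2, length.out = floor((n + L - 1) / 2))
    z_lo <- conv_full(ext, fb$dec_lo); z_hi <- conv_full(ext, fb$dec_hi)
    list(cA = z_lo[idx], cD = z_hi[idx])
  } else { # periodic
    if (n %% 2 == 1) stopf("periodic boundary mode requires an even length")
    m <- n / 2
    cA <- numeric(m); cD <- numeric(m)
    pos0 <- 2 * seq_len(m) + L / 2 - 1          # window end per output sample
    for (j in seq_len(L)) {
      src <- ((pos0 - (j - 1) - 1) %% n) + 1
      cA <- cA + fb$dec_lo[j] * x[src]
      cD <- cD + fb$dec_hi[j] * x[src]
    }
    list(cA = cA, cD = cD)
  }
}

idwt_step <- function(cA, cD, fb, out_len, mode) {
  L <- fb$L
  if (mode == "symmetric") {
    up <- function(cc) {
      u <- numeric(2 * length(cc))
      u[seq(1, by = 2, length.out = length(cc))] <- cc
      u
    }
    y <- conv_full(up(cA), fb$rec_lo) + conv_full(up(cD), fb$rec_hi)
    if (L > 2) y <- y[-seq_len(L - 2)]
    y[seq_len(out_len)]
  } else {
    n <- out_len
    x <- numeric(n)
    pos0 <- 2 * seq_along(cA) + L / 2 - 1
    for (j in seq_len(L)) {
      dst <- ((pos0 - (j - 1) - 1) %% n) + 1
      contrib <- fb$dec_lo[j] * cA + fb$dec_hi[j] * cD
      # accumulate with possible repeated destinations
      acc <- tapply(contrib, dst, sum)
      x[as.integer(names(acc))] <- x[as.integer(names(acc))] + as.numeric(acc)
    }
    x
  }
}

#' Wavelet transform configuration
#'
#' @param wavelet filter-bank name: `"db1"`, `"db2"`, `"db4"`, `"db8"`,
#'   `"sym4"`, `"sym8"`.
#' @param levels decomposition depth (>= 1, <= log2 of the signal length).
#' @param mode boundary handling: `"symmetric"` (edge-reflecting) or
#'   `"periodic"`.
#' @param threshold_mode `"soft"` or `"hard"`.
#' @export
wavelet_config <- function(wavelet = "db4", levels = 5,
                           mode = c("symmetric", "periodic"),
                           threshold_mode = c("soft", "hard")) {
  mode <- match.arg(mode)
  threshold_mode <- match.arg(threshold_mode)
  wavelet_filters(wavelet)  # validates the name
  if (levels < 1) stopf("levels must be >= 1")
  structure(list(wavelet = wavelet, levels = as.integer(levels), mode = mode,
                 threshold_mode = threshold_mode), class = "wavelet_config")
}

#' Multi-level discrete wavelet decomposition
#'
#' Recursively splits the signal into a coarsest approximation and one
#' detail band per level.
#'
#' @param x numeric signal vector, length >= `2^levels`.
#' @param cfg a [wavelet_config()].
#' @return object of class `wavelet_decomposition`: list with `cA` (coarsest
#'   approximation), `details` (list, coarsest first), per-level input
#'   lengths, and the configuration.
#' @export
wavelet_decompose <- function(x, cfg = wavelet_config()) {
  n <- length(x)
  max_lev <- floor(log2(n))
  if (n < 2^cfg$levels) {
    stopf("signal of length %d supports at most %d levels (requested %d)",
          n, max_lev, cfg$levels)
  }
  if (!all(is.finite(x))) stopf("non-finite values in signal")
  fb <- wavelet_filters(cfg$wavelet)
  details <- vector("list", cfg$levels)
  lengths <- integer(cfg$levels)
  cur <- x
  for (lev in seq_len(cfg$levels)) {
    lengths[lev] <- length(cur)
    st <- dwt_step(cur, fb, cfg$mode)
    details[[lev]] <- st$cD
    cur <- st$cA
  }
  structure(list(cA = cur, details = rev(details), lengths = rev(lengths),
                 cfg = cfg, n = n), class = "wavelet_decomposition")
}

#' Universal denoising threshold
#'
#' `lambda = sigma * sqrt(2 * log(N))`: the threshold above which pure
#' Gaussian noise coefficients are unlikely to rise, for a signal of length
#' `N` with noise standard deviation `sigma`.
#'
#' @param sigma noise standard deviation (>= 0).
#' @param N signal length (>= 2).
#' @return the threshold, same units as `sigma`.
#' @export
universal_threshold <- function(sigma, N) {
  if (sigma < 0) stopf("sigma must be >= 0")
  if (N < 2) stopf("N must be >= 2")
  sigma * sqrt(2 * log(N))
}

#' Robust noise-level estimate from finest-scale detail coefficients
#'
#' Median absolute deviation of the finest detail band divided by 0.6745
#' (the MAD of a standard Gaussian), insensitive to sparse signal structure
#' leaking into the band.
#'
#' @param d numeric coefficient vector (typically `details[[levels]]` of a
#'   [wavelet_decompose()] result).
#' @return estimated noise standard deviation.
#' @export
estimate_sigma <- function(d) {
  if (length(d) == 0) stopf("empty coefficient vector")
  stats::median(abs(d)) / 0.6745
}

#' Threshold detail coefficients
#'
#' Soft thresholding shrinks every detail coefficient toward zero by
#' `lambda`, zeroing those below it; hard thresholding zeroes small
#' coefficients and leaves the rest untouched. Approximation coefficients are
#' never thresholded.
#'
#' @param dec a [wavelet_decompose()] result.
#' @param lambda threshold (>= 0); a scalar or one value per level.
#' @param mode `"soft"` or `"hard"` (defaults to the decomposition's
#'   configuration).
#' @return a `wavelet_decomposition` with thresholded detail bands.
#' @export
threshold_coeffs <- function(dec, lambda, mode = NULL) {
  mode <- mode %||% dec$cfg$threshold_mode
  if (any(lambda < 0)) stopf("lambda must be >= 0")
  lam <- rep_len(lambda, length(dec$details))
  dec$details <- lapply(seq_along(dec$details), function(i) {
    p <- dec$details[[i]]
    if (mode == "soft") sign(p) * pmax(abs(p) - lam[i], 0)
    else p * (abs(p) > lam[i])
  })
  dec
}

#' Reconstruct a signal from a wavelet decomposition
#'
#' @param dec a [wavelet_decompose()] (possibly thresholded) result.
#' @return numeric vector of the original signal length.
#' @export
wavelet_reconstruct <- function(dec) {
  fb <- wavelet_filters(dec$cfg$wavelet)
  cur <- dec$cA
  for (lev in seq_along(dec$details)) {
    cD <- dec$details[[lev]]
    if (length(cD) != length(cur)) {
      stopf("inconsistent coefficient shapes at level %d", lev)
    }
    cur <- idwt_step(cur, cD, fb, dec$lengths[lev], dec$cfg$mode)
  }
  cur
}

#' Wavelet universal-threshold denoising of a motion signal
#'
#' Decomposes the signal (default: Daubechies-4, 5 levels, symmetric
#' boundary), estimates the noise level from the finest detail band unless
#' supplied, applies the universal threshold to every detail band (soft by
#' default), and reconstructs. Signals shorter than `2^levels` after the
#' boundary requirements are symmetrically padded to the next working length
#' and trimmed after reconstruction.
#'
#' @param x numeric signal.
#' @param cfg a [wavelet_config()].
#' @param sigma optional known noise standard deviation; estimated by
#'   [estimate_sigma()] when `NULL`.
#' @param sigma_frac optional noise level as a fraction of the signal's
#'   standard deviation (overrides `sigma`), mirroring rigs where the noise
#'   floor is specified relative to signal power.
#' @param bandlimit_hz optional motion-bandwidth cutoff, Hz (requires
#'   `rate`): detail bands lying entirely above the cutoff are zeroed
#'   regardless of amplitude. This removes coherent high-frequency
#'   disturbances -- soft-tissue oscillation, resonances -- that sit far
#'   above the noise floor and therefore survive amplitude thresholding,
#'   while voluntary joint motion (below a few Hz) is untouched.
#' @param rate sampling rate, Hz; needed only with `bandlimit_hz`.
#' @return denoised signal, same length as `x`; the threshold used is
#'   attached as attribute `"lambda"`.
#' @export
wavelet_denoise <- function(x, cfg = wavelet_config(), sigma = NULL,
                            sigma_frac = NULL, bandlimit_hz = NULL,
                            rate = NULL) {
  n <- length(x)
  block <- 2^cfg$levels
  pad_to <- ceiling(n / block) * block
  if (cfg$mode == "periodic" && pad_to %% 2 == 1) pad_to <- pad_to + 1
  xp <- if (pad_to > n) c(x, x[n:(2 * n - pad_to + 1)]) else x
  dec <- wavelet_decompose(xp, cfg)
  if (!is.null(sigma_frac)) sigma <- sigma_frac * stats::sd(x)
  if (is.null(sigma)) sigma <- estimate_sigma(dec$details[[length(dec$details)]])
  lam <- universal_threshold(sigma, length(xp))
  dec <- threshold_coeffs(dec, lam)
  if (!is.null(bandlimit_hz)) {
    if (is.null(rate)) stopf("bandlimit_hz requires the sampling rate")
    L <- length(dec$details)
    for (i in seq_len(L)) {
      band_lo <- rate / 2^(L - i + 2)    # details[[i]]: coarsest first
      if (band_lo >= bandlimit_hz) dec$details[[i]][] <- 0
    }
  }
  y <- wavelet_reconstruct(dec)
  y <- y[seq_len(n)]
  attr(y, "lambda") <- lam
  y
}

#' Wavelet-denoise all six channels of an IMU stream
#'
#' Applies [wavelet_denoise()] column-wise to the accelerometer and gyro
#' channels, optionally band-limiting to the voluntary-motion bandwidth.
#'
#' @param series an [imu_series()].
#' @param cfg a [wavelet_config()].
#' @param bandlimit_hz optional cutoff, Hz (see [wavelet_denoise()]).
#' @return a denoised [imu_series()].
#' @export
denoise_imu <- function(series, cfg = wavelet_config(), bandlimit_hz = NULL) {
  rate <- 1 / series$dt
  dn <- function(M) apply(M, 2, function(x)
    as.numeric(wavelet_denoise(x, cfg, bandlimit_hz = bandlimit_hz,
                               rate = rate)))
  imu_series(series$t, dn(series$accel), dn(series$gyro))
}
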