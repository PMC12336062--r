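# Shared numeric helpers: peak picking, detrending, Legendre drift basis,
# Welch spectral estimation, interpolation onto uniform grids.

cfg_error <- function(msg) {
  stop(structure(class = c("physbold_config_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Locate local maxima with height and refractory-separation constraints
#'
#' Candidate peaks are strict local maxima of `x`; candidates below
#' `min_height` are dropped, then peaks closer than `min_sep_s` to an
#' already-accepted higher peak are suppressed (greedy, tallest first).
#'
#' @param x numeric waveform.
#' @param fs sampling rate (Hz).
#' @param min_height minimum peak amplitude; `NULL` disables the constraint.
#' @param min_sep_s minimum separation between accepted peaks (s).
#' @return integer vector of peak sample indices, in increasing order.
#' @keywords internal
find_peaks <- function(x, fs, min_height = NULL, min_sep_s = 0) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (!is.null(min_height)) cand <- cand[x[cand] >= min_height]
  if (length(cand) <= 1L || min_sep_s <= 0) return(cand)
  min_gap <- min_sep_s * fs
  ord <- cand[order(x[cand], decreasing = TRUE)]
  keep <- logical(length(ord))
  taken <- numeric(0)
  for (i in seq_along(ord)) {
    if (!length(taken) || all(abs(taken - ord[i]) >= min_gap)) {
      keep[i] <- TRUE
      taken <- c(taken, ord[i])
    }
  }
  sort(ord[keep])
}

# Remove a least-squares linear trend (and mean).
detrend_linear <- function(x) {
  t <- seq_along(x)
  stats::residuals(stats::lm.fit(cbind(1, t), x))
}

zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Legendre polynomial drift basis
#'
#' Columns are Legendre polynomials P0..Porder evaluated on `n` points
#' equally spaced in [-1, 1]; P0 is the intercept.
#'
#' @param n number of rows (volumes).
#' @param order highest polynomial order.
#' @return `n x (order + 1)` matrix.
#' @keywords internal
legendre_basis <- function(n, order) {
  x <- seq(-1, 1, length.out = n)
  P <- matrix(0, n, order + 1L)
  P[, 1] <- 1
  if (order >= 1L) P[, 2] <- x
  if (order >= 2L) {
    for (k in 2:order) {
      # Bonnet recursion
      P[, k + 1L] <- ((2 * k - 1) * x * P[, k] - (k - 1) * P[, k - 1L]) / k
    }
  }
  colnames(P) <- paste0("poly", 0:order)
  P
}

# Trapezoidal integral of y over x.
trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Welch power spectral density
#'
#' Mean-detrended, Hann-windowed periodograms of overlapping segments,
#' averaged; scaled so that the integral over frequency recovers the
#' signal variance (one-sided density).
#'
#' @param x uniformly sampled series.
#' @param fs sampling rate (Hz).
#' @param seg_len segment length in samples.
#' @param overlap fractional overlap between consecutive segments.
#' @return list with `freq` (Hz) and `psd` (power per Hz).
#' @keywords internal
welch_psd <- function(x, fs, seg_len = NULL, overlap = 0.5) {
  n <- length(x)
  if (is.null(seg_len)) seg_len <- min(n, round(120 * fs))
  seg_len <- min(seg_len, n)
  step <- max(1L, floor(seg_len * (1 - overlap)))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(seg_len) / (seg_len + 1)))  # Hann
  wnorm <- sum(w^2)
  nf <- floor(seg_len / 2)
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)]
    seg <- (seg - mean(seg)) * w
    ft <- stats::fft(seg)
    pxx <- (Mod(ft[2:(nf + 1L)])^2) / (wnorm * fs)
    pxx <- pxx * 2                      # one-sided
    acc <- acc + pxx
  }
  list(freq = (1:nf) * fs / seg_len, psd = acc / length(starts))
}

# Linear interpolation of (t, x) onto new times; constant extrapolation.
interp_to <- function(t, x, t_new) {
  stats::approx(t, x, xout = t_new, rule = 2)$y
}

# Deterministic 31-bit hash of a string, for per-subject seed derivation.
str_hash <- function(s) {
  h <- 0
  for (c in utf8ToInt(s)) h <- (h * 131 + c) %% 2147483629
  as.integer(h)
}

# Sub-seed derivation: keeps everything below 2^31.
derive_seed <- function(seed, ...) {
  h <- seed %% 2147483629
  for (part in list(...)) {
    p <- if (is.character(part)) str_hash(part) else as.numeric(part)
    h <- (h * 69069 + p + 7) %% 2147483629
  }
  as.integer(h)
}
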