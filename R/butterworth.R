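# Zero-phase low-pass Butterworth filtering.
#
# No DSP package is assumed: the digital filter is designed here from the
# analog Butterworth prototype via the bilinear transform, and the zero-phase
# (forward-backward) pass follows the usual convention of odd extension at
# both ends plus steady-state initial conditions, which suppresses edge
# transients.

#' Digital low-pass Butterworth coefficients
#'
#' Designs an order-`n` low-pass Butterworth filter by bilinear transform of
#' the analog prototype.
#'
#' @param n Filter order.
#' @param wn Cutoff as a fraction of the Nyquist frequency (0 < wn < 1).
#' @return List with numerator `b` and denominator `a` (length n+1 each,
#'   `a[1] == 1`).
#' @export
butter_lowpass <- function(n, wn) {
  if (wn <= 0 || wn >= 1) stop("wn must be in (0, 1)")
  warped <- tan(pi * wn / 2)          # pre-warped analog cutoff (fs = 2)
  k <- seq_len(n)
  # analog prototype poles on the unit circle's left half, scaled by cutoff
  p_a <- warped * exp(1i * pi * (2 * k + n - 1) / (2 * n))
  # bilinear transform z = (1 + s) / (1 - s); n zeros at z = -1
  p_z <- (1 + p_a) / (1 - p_a)
  gain <- Re(warped^n / prod(1 - p_a))
  a <- Re(poly_from_roots(p_z))
  b <- gain * Re(poly_from_roots(rep(-1 + 0i, n)))
  list(b = b, a = a)
}

poly_from_roots <- function(r) {
  coefs <- 1 + 0i
  for (root in r) coefs <- c(coefs, 0) - c(0, coefs * root)
  coefs
}

# Direct-form II transposed IIR filter with initial state zi.
iir_filter <- function(b, a, x, zi = NULL) {
  nfilt <- length(a)
  z <- if (is.null(zi)) numeric(nfilt - 1) else zi
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    for (j in seq_len(nfilt - 2))
      z[j] <- b[j + 1] * xi + z[j + 1] - a[j + 1] * yi
    z[nfilt - 1] <- b[nfilt] * xi - a[nfilt] * yi
    y[i] <- yi
  }
  y
}

# Steady-state initial filter state for a unit step input.
lfilter_zi <- function(b, a) {
  n <- length(a) - 1
  companion <- rbind(-a[-1], cbind(diag(1, n - 1), 0))
  iminusa <- diag(n) - t(companion)
  bb <- b[-1] - a[-1] * b[1]
  solve(iminusa, bb)
}

#' Zero-phase Butterworth low-pass of a grip-force series
#'
#' Applies a 3rd-order low-pass Butterworth filter forward and backward
#' (zero phase: symmetric features keep their peak positions), with odd
#' extension of 3x the filter length at both ends and steady-state initial
#' conditions. The cutoff is specified in physical Hz at the native sampling
#' rate.
#'
#' @param x Numeric series sampled at `fs` Hz.
#' @param fs Sampling rate in Hz (50 for the glove).
#' @param cutoff_hz Cutoff frequency, default 10.
#' @param order Filter order, default 3.
#' @return Filtered series of the same length.
#' @export
lowpass_gf <- function(x, fs = 50, cutoff_hz = 10, order = 3) {
  coefs <- butter_lowpass(order, cutoff_hz / (fs / 2))
  filtfilt_bw(coefs$b, coefs$a, x)
}

filtfilt_bw <- function(b, a, x) {
  padlen <- 3 * max(length(a), length(b))
  if (length(x) <= padlen)
    stop("series too short for zero-phase filtering: need > ", padlen,
         " samples, got ", length(x))
  # odd extension about both endpoints
  ext <- c(2 * x[1] - x[(padlen + 1):2],
           x,
           2 * x[length(x)] - x[(length(x) - 1):(length(x) - padlen)])
  zi <- lfilter_zi(b, a)
  y <- iir_filter(b, a, ext, zi * ext[1])
  y <- rev(iir_filter(b, a, rev(y), zi * y[length(y)]))
  y[(padlen + 1):(padlen + length(x))]
}
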