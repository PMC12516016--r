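# Orthonormal wavelet filter banks ------------------------------------------
#
# Families supported: haar and the minimal-phase Daubechies filters db4, db5
# and db8 (dbK = K vanishing moments, 2K taps).  The Daubechies taps are
# computed at construction time by spectral factorisation of the Daubechies
# half-band polynomial rather than hard-coded, and are validated numerically
# by the quadrature-mirror identities.

#' Wavelet filter specification
#'
#' Builds the analysis/synthesis filter pairs for one of the supported
#' orthonormal wavelet families.  The synthesis filters are the time-reversed
#' analysis filters, as is standard for orthonormal banks.
#'
#' @param family One of `"haar"`, `"db4"`, `"db5"`, `"db8"`.  `dbK` denotes
#'   the minimal-phase Daubechies filter with `K` vanishing moments
#'   (`2K` taps).
#' @param boundary Boundary extension mode.  Only `"periodic"`
#'   (periodization) is implemented: on even-sized inputs it yields exactly
#'   `M/2 x N/2` coefficient arrays per subband and exact perfect
#'   reconstruction.
#' @return An object of class `wavelet_spec`: a list with elements `family`,
#'   `boundary`, `analysis_lowpass`, `analysis_highpass`,
#'   `synthesis_lowpass`, `synthesis_highpass`.
#' @examples
#' ws <- wavelet_spec("haar")
#' ws$analysis_lowpass   # 1/sqrt(2), 1/sqrt(2)
#' @export
wavelet_spec <- function(family = c("haar", "db4", "db5", "db8"),
                         boundary = "periodic") {
  family <- match.arg(family)
  if (!identical(boundary, "periodic")) {
    stop("only the 'periodic' (periodization) boundary mode is supported")
  }
  h <- if (family == "haar") {
    c(1, 1) / sqrt(2)
  } else {
    daubechies_lowpass(as.integer(sub("^db", "", family)))
  }
  g <- qmf_highpass(h)
  spec <- structure(
    list(family = family, boundary = boundary,
         analysis_lowpass = h, analysis_highpass = g,
         synthesis_lowpass = rev(h), synthesis_highpass = rev(g)),
    class = "wavelet_spec")
  validate_filter_bank(spec)
  spec
}

#' @export
print.wavelet_spec <- function(x, ...) {
  cat(sprintf("<wavelet_spec> family=%s, taps=%d, boundary=%s\n",
              x$family, length(x$analysis_lowpass), x$boundary))
  invisible(x)
}

# Polynomial product (coefficient convolution), ascending powers.
poly_mult <- function(a, b) {
  out <- rep(0 + 0i, length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  }
  out
}

# Minimal-phase Daubechies lowpass filter with K vanishing moments.
#
# h(z) is proportional to (1 + z^-1)^K * Q(z^-1) where the roots of Q are
# the roots of the Daubechies polynomial P(y) = sum_k C(K-1+k, k) y^k mapped
# through y -> z via z + 1/z = 2 - 4y, retaining the root of each pair that
# lies inside the unit circle (minimal phase).  Normalised so sum(h) equals
# sqrt(2).
daubechies_lowpass <- function(K) {
  stopifnot(K >= 2)
  kk <- 0:(K - 1L)
  P <- choose(K - 1L + kk, kk)            # ascending powers of y
  yroots <- polyroot(P)                   # polyroot takes ascending coefs
  zroots <- vapply(yroots, function(y) {
    b <- 2 - 4 * y                        # z + 1/z = b
    disc <- sqrt(b^2 - 4 + 0i)
    z1 <- (b + disc) / 2
    z2 <- (b - disc) / 2
    if (Mod(z1) < 1) z1 else z2
  }, complex(1))
  coef <- c(1 + 0i)
  for (i in seq_len(K)) coef <- poly_mult(coef, c(1, 1) + 0i)
  for (z in zroots)     coef <- poly_mult(coef, c(1, -z))
  h <- Re(coef)
  h * sqrt(2) / sum(h)
}

# Quadrature-mirror highpass: g[k] = (-1)^k h[L-1-k] (0-based).
qmf_highpass <- function(h) {
  L <- length(h)
  rev(h) * (-1)^(seq_len(L) - 1L)
}

# Numerical check of the orthonormal quadrature-mirror identities:
# sum h = sqrt 2, <h, shift_2j h> = delta_j, same for g, h and g orthogonal
# at all even shifts.  Stops if violated beyond 1e-10.
validate_filter_bank <- function(spec, tol = 1e-10) {
  h <- spec$analysis_lowpass
  g <- spec$analysis_highpass
  L <- length(h)
  if (abs(sum(h) - sqrt(2)) > tol) stop("lowpass filter does not sum to sqrt(2)")
  shifts <- seq(0L, L - 2L, by = 2L)
  for (s in shifts) {
    hh <- sum(h[seq_len(L - s)] * h[seq_len(L - s) + s])
    gg <- sum(g[seq_len(L - s)] * g[seq_len(L - s) + s])
    hg <- sum(h[seq_len(L - s)] * g[seq_len(L - s) + s])
    gh <- sum(g[seq_len(L - s)] * h[seq_len(L - s) + s])
    want <- if (s == 0L) 1 else 0
    if (abs(hh - want) > tol || abs(gg - want) > tol ||
        abs(hg) > tol || (s > 0L && abs(gh) > tol)) {
      stop("filter bank is not orthonormal at even shifts")
    }
  }
  invisible(TRUE)
}
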