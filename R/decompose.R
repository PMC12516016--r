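# Multiband image decomposition ---------------------------------------------
#
# One-level 2D DWT with per-subband inverse reconstruction, the undecimated
# (stationary) variant, and SVD eigentriple grouping.  All three return four
# full-size "subband image tensors" whose sum reproduces the input.
#
# Implementation note: with periodization on even sizes, the analysis step
# (filter + dyadic downsample) along one axis is a linear operator that we
# materialise as an (n/2) x n matrix whose rows are the filter shifted by
# two samples (wrapped).  For orthonormal families the stacked low/high
# operator is an orthogonal n x n matrix, so synthesis is its transpose.
# Subband naming: first letter = vertical (column-direction) filter,
# second letter = horizontal (row-direction) filter.

SUBBAND_NAMES <- c("LL", "LH", "HL", "HH")

# (n/2) x n decimated analysis operator for filter taps `h`, periodic wrap.
analysis_operator <- function(h, n) {
  if (n %% 2L != 0L) stop("dyadic analysis requires an even size, got ", n)
  L <- length(h)
  A <- matrix(0, n / 2L, n)
  for (m in seq_len(n / 2L)) {
    for (k in seq_len(L)) {
      j <- ((2L * (m - 1L) + (k - 1L)) %% n) + 1L
      A[m, j] <- A[m, j] + h[k]
    }
  }
  A
}

# n x n undecimated (circulant) analysis operator.
circulant_operator <- function(h, n) {
  L <- length(h)
  S <- matrix(0, n, n)
  for (m in seq_len(n)) {
    for (k in seq_len(L)) {
      j <- (((m - 1L) + (k - 1L)) %% n) + 1L
      S[m, j] <- S[m, j] + h[k]
    }
  }
  S
}

check_channel <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) stop("channel must be a numeric matrix")
  if (any(!is.finite(x))) stop("channel contains non-finite values")
  if (nrow(x) %% 2L != 0L || ncol(x) %% 2L != 0L) {
    stop("channel dimensions must be even for one-level dyadic analysis, got ",
         nrow(x), "x", ncol(x))
  }
  invisible(x)
}

#' One-level 2D DWT analysis of a single channel
#'
#' Row-direction filtering + dyadic downsampling followed by
#' column-direction filtering + downsampling, under periodization.  Each of
#' the four coefficient arrays has size `M/2 x N/2`.
#'
#' @param x Numeric `M x N` matrix with `M`, `N` even.
#' @param spec A [wavelet_spec()].
#' @return A list of class `subband_coefficients` with elements
#'   `LL`, `LH`, `HL`, `HH` (first letter: vertical filter; second:
#'   horizontal filter), plus the `family` used.
#' @export
dwt2_analysis <- function(x, spec = wavelet_spec("haar")) {
  stopifnot(inherits(spec, "wavelet_spec"))
  check_channel(x)
  Rl <- analysis_operator(spec$analysis_lowpass, nrow(x))
  Rh <- analysis_operator(spec$analysis_highpass, nrow(x))
  Cl <- analysis_operator(spec$analysis_lowpass, ncol(x))
  Ch <- analysis_operator(spec$analysis_highpass, ncol(x))
  structure(list(LL = Rl %*% x %*% t(Cl), LH = Rl %*% x %*% t(Ch),
                 HL = Rh %*% x %*% t(Cl), HH = Rh %*% x %*% t(Ch),
                 family = spec$family),
            class = "subband_coefficients")
}

#' Per-subband inverse reconstruction of a single channel
#'
#' Applies the inverse transform to each subband with the other three
#' zeroed, yielding four full-size (`M x N`) images whose sum equals the
#' analysed channel (perfect reconstruction).
#'
#' @param coeffs A `subband_coefficients` object from [dwt2_analysis()].
#' @param spec The same [wavelet_spec()] used for analysis.
#' @return Named list `LL`, `LH`, `HL`, `HH` of `M x N` matrices.
#' @export
subband_reconstruct <- function(coeffs, spec = wavelet_spec(coeffs$family)) {
  stopifnot(inherits(coeffs, "subband_coefficients"))
  dims <- lapply(coeffs[SUBBAND_NAMES], dim)
  if (length(unique(dims)) != 1L) {
    stop("subband coefficient arrays must share one shape")
  }
  M <- 2L * nrow(coeffs$LL)
  N <- 2L * ncol(coeffs$LL)
  Rl <- analysis_operator(spec$analysis_lowpass, M)
  Rh <- analysis_operator(spec$analysis_highpass, M)
  Cl <- analysis_operator(spec$analysis_lowpass, N)
  Ch <- analysis_operator(spec$analysis_highpass, N)
  list(LL = t(Rl) %*% coeffs$LL %*% Cl,
       LH = t(Rl) %*% coeffs$LH %*% Ch,
       HL = t(Rh) %*% coeffs$HL %*% Cl,
       HH = t(Rh) %*% coeffs$HH %*% Ch)
}

# Undecimated one-level analysis + single-band inverse for one channel.
# For orthonormal taps the circulant operators satisfy
# t(S_L) S_L + t(S_H) S_H = 2 I, so dividing the separable synthesis by 4
# restores the input exactly.
swt2_subbands <- function(x, spec) {
  check_channel(x)
  Rl <- circulant_operator(spec$analysis_lowpass, nrow(x))
  Rh <- circulant_operator(spec$analysis_highpass, nrow(x))
  Cl <- circulant_operator(spec$analysis_lowpass, ncol(x))
  Ch <- circulant_operator(spec$analysis_highpass, ncol(x))
  list(LL = t(Rl) %*% (Rl %*% x %*% t(Cl)) %*% Cl / 4,
       LH = t(Rl) %*% (Rl %*% x %*% t(Ch)) %*% Ch / 4,
       HL = t(Rh) %*% (Rh %*% x %*% t(Cl)) %*% Cl / 4,
       HH = t(Rh) %*% (Rh %*% x %*% t(Ch)) %*% Ch / 4)
}

#' Eigentriple grouping for SVD decomposition
#'
#' Validates (and truncates to the available rank) the ordered, contiguous,
#' 1-based inclusive singular-triplet index intervals used to build the four
#' SVD "modes".  The default grouping is 1-5 / 6-15 / 16-40 / 41-128.
#'
#' @param ranges List of length-2 integer vectors `c(from, to)`.
#' @param rank Available rank, `min(M, N)` of the channel.
#' @return List of index vectors, one per subband (empty if the interval
#'   lies wholly above `rank`).
#' @export
eigentriple_grouping <- function(ranges = default_eigentriple_ranges(),
                                 rank) {
  froms <- vapply(ranges, `[`, numeric(1), 1L)
  tos <- vapply(ranges, `[`, numeric(1), 2L)
  if (any(froms > tos) || froms[1] != 1L ||
      any(froms[-1] != tos[-length(tos)] + 1L)) {
    stop("eigentriple ranges must be ascending, disjoint and contiguous from 1")
  }
  if (tos[length(tos)] < rank) {
    stop("eigentriple ranges must cover 1..", rank)
  }
  lapply(seq_along(ranges), function(i) {
    if (froms[i] > rank) integer(0) else seq.int(froms[i], min(tos[i], rank))
  })
}

#' @rdname eigentriple_grouping
#' @export
default_eigentriple_ranges <- function() {
  list(c(1L, 5L), c(6L, 15L), c(16L, 40L), c(41L, 128L))
}

svd_subbands <- function(x, ranges = default_eigentriple_ranges()) {
  if (any(!is.finite(x))) stop("channel contains non-finite values")
  r <- min(dim(x))
  groups <- eigentriple_grouping(ranges, rank = r)
  s <- svd(x)
  lapply(groups, function(idx) {
    if (length(idx) == 0L) {
      matrix(0, nrow(x), ncol(x))
    } else {
      s$u[, idx, drop = FALSE] %*%
        (s$d[idx] * t(s$v[, idx, drop = FALSE]))
    }
  })
}

#' Decompose an image into four full-size subband image tensors
#'
#' The workhorse of the multiband pipeline.  Channels are processed
#' independently and restacked.  For `method = "dwt2"` the result is
#' analysis ([dwt2_analysis()]) followed by per-subband inverse
#' reconstruction ([subband_reconstruct()]); `"swt2"` is the undecimated
#' analogue; `"svd"` groups singular triplets into four additive modes
#' (ordered subband1..4, stored in the LL..HH slots).
#'
#' @param image Numeric `M x N x C` array (or `M x N` matrix, treated as one
#'   channel); `M`, `N` even for the wavelet methods.
#' @param method `"dwt2"`, `"swt2"` or `"svd"`.
#' @param spec [wavelet_spec()] for the wavelet methods.
#' @param ranges Eigentriple index ranges for `"svd"`.
#' @return Object of class `subband_set`: list with `LL`, `LH`, `HL`, `HH`
#'   (`M x N x C` arrays, same shape as the input), plus `method` and
#'   `family` attributes fields.
#' @examples
#' img <- array(runif(16 * 16 * 3), c(16, 16, 3))
#' sb <- decompose(img, "dwt2", wavelet_spec("haar"))
#' max(abs(sb$LL + sb$LH + sb$HL + sb$HH - img))  # ~1e-15
#' @export
decompose <- function(image, method = c("dwt2", "swt2", "svd"),
                      spec = wavelet_spec("haar"),
                      ranges = default_eigentriple_ranges()) {
  method <- match.arg(method)
  if (is.matrix(image)) image <- array(image, c(dim(image), 1L))
  if (length(dim(image)) != 3L) stop("image must be an M x N x C array")
  C <- dim(image)[3]
  per_channel <- lapply(seq_len(C), function(c) {
    ch <- image[, , c]
    switch(method,
      dwt2 = subband_reconstruct(dwt2_analysis(ch, spec), spec),
      swt2 = swt2_subbands(ch, spec),
      svd = stats::setNames(svd_subbands(ch, ranges), SUBBAND_NAMES))
  })
  bands <- lapply(seq_along(SUBBAND_NAMES), function(b) {
    out <- array(0, dim(image))
    for (c in seq_len(C)) out[, , c] <- per_channel[[c]][[b]]
    out
  })
  names(bands) <- SUBBAND_NAMES
  structure(c(bands,
              list(method = method,
                   family = if (method == "svd") NA_character_ else spec$family)),
            class = "subband_set")
}

#' @export
print.subband_set <- function(x, ...) {
  cat(sprintf("<subband_set> method=%s family=%s, bands %s, shape %s\n",
              x$method, x$family, paste(SUBBAND_NAMES, collapse = "/"),
              paste(dim(x$LL), collapse = "x")))
  invisible(x)
}

#' Mean squared intensity of each subband image
#'
#' For an orthonormal wavelet decomposition the four energies sum to the
#' mean squared intensity of the source image (the subband images are
#' orthogonal projections).  Fracture-type crack discontinuities show up as
#' elevated detail-band (especially HH) energy.
#'
#' @param sub A `subband_set` from [decompose()].
#' @return Named numeric vector of four nonnegative energies.
#' @export
subband_energy <- function(sub) {
  stopifnot(inherits(sub, "subband_set"))
  vapply(SUBBAND_NAMES, function(b) mean(sub[[b]]^2), numeric(1))
}
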