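# Independent brute-force oracles, deliberately written as literal nested
# loops over the separable filter-downsample definition (periodic indexing)
# rather than via the package's matrix operators.

wrap1 <- function(i, n) ((i - 1L) %% n) + 1L

# One-level analysis: band (fv, fh) = (vertical filter, horizontal filter).
oracle_band_analysis <- function(x, fv, fh) {
  M <- nrow(x); N <- ncol(x)
  out <- matrix(0, M / 2L, N / 2L)
  for (m in seq_len(M / 2L)) {
    for (n in seq_len(N / 2L)) {
      acc <- 0
      for (k in seq_along(fv)) {
        for (l in seq_along(fh)) {
          acc <- acc + fv[k] * fh[l] *
            x[wrap1(2L * (m - 1L) + k, M), wrap1(2L * (n - 1L) + l, N)]
        }
      }
      out[m, n] <- acc
    }
  }
  out
}

oracle_dwt2 <- function(x, spec) {
  h <- spec$analysis_lowpass; g <- spec$analysis_highpass
  list(LL = oracle_band_analysis(x, h, h),
       LH = oracle_band_analysis(x, h, g),
       HL = oracle_band_analysis(x, g, h),
       HH = oracle_band_analysis(x, g, g))
}

# Single-band inverse: upsample-by-two + time-reversed filters, periodic.
oracle_band_reconstruct <- function(coef, fv, fh, M, N) {
  out <- matrix(0, M, N)
  for (m in seq_len(M / 2L)) {
    for (n in seq_len(N / 2L)) {
      for (k in seq_along(fv)) {
        for (l in seq_along(fh)) {
          i <- wrap1(2L * (m - 1L) + k, M)
          j <- wrap1(2L * (n - 1L) + l, N)
          out[i, j] <- out[i, j] + coef[m, n] * fv[k] * fh[l]
        }
      }
    }
  }
  out
}

oracle_subband_images <- function(x, spec) {
  h <- spec$analysis_lowpass; g <- spec$analysis_highpass
  cf <- oracle_dwt2(x, spec)
  M <- nrow(x); N <- ncol(x)
  list(LL = oracle_band_reconstruct(cf$LL, h, h, M, N),
       LH = oracle_band_reconstruct(cf$LH, h, g, M, N),
       HL = oracle_band_reconstruct(cf$HL, g, h, M, N),
       HH = oracle_band_reconstruct(cf$HH, g, g, M, N))
}

# Mann-Whitney correct-ranking probability (ties count half).
oracle_auroc <- function(y, p) {
  pos <- p[y == 1]; neg <- p[y == 0]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

sum_bands <- function(sb) sb$LL + sb$LH + sb$HL + sb$HH
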