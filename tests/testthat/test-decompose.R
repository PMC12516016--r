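haar <- wavelet_spec("haar")

test_that("dwt2 analysis matches hand-derived values on canonical inputs", {
  # constant image: details vanish, LL is 2c for orthonormal haar
  cimg <- matrix(3.5, 6, 6)
  cf <- dwt2_analysis(cimg, haar)
  expect_equal(cf$LL, matrix(7, 3, 3))
  expect_equal(cf$LH, matrix(0, 3, 3))
  expect_equal(cf$HL, matrix(0, 3, 3))
  expect_equal(cf$HH, matrix(0, 3, 3))

  # 2x2 block [[1,2],[3,4]] (frozen from the brute-force oracle)
  x <- matrix(c(1, 3, 2, 4), 2, 2)
  cf <- dwt2_analysis(x, haar)
  expect_equal(cf$LL[1, 1], 5)
  expect_equal(cf$LH[1, 1], -1)   # horizontal detail
  expect_equal(cf$HL[1, 1], -2)   # vertical detail
  expect_equal(cf$HH[1, 1], 0)

  # coefficient arrays are M/2 x N/2
  big <- matrix(stats::rnorm(128 * 128), 128, 128)
  cf <- dwt2_analysis(big, haar)
  for (b in c("LL", "LH", "HL", "HH")) expect_equal(dim(cf[[b]]), c(64L, 64L))
  # orthonormal transforms conserve energy
  expect_equal(sum(cf$LL^2) + sum(cf$LH^2) + sum(cf$HL^2) + sum(cf$HH^2),
               sum(big^2), tolerance = 1e-8)
})

test_that("analysis rejects odd sizes and reconstruct rejects ragged bands", {
  expect_error(dwt2_analysis(matrix(0, 5, 6), haar), "even")
  cf <- dwt2_analysis(matrix(stats::rnorm(16), 4, 4), haar)
  cf$HH <- matrix(0, 3, 3)
  expect_error(subband_reconstruct(cf, haar), "shape")
})

test_that("dwt2 path matches the brute-force separable oracle", {
  set.seed(101)
  for (f in c("haar", "db4", "db5", "db8")) {
    ws <- wavelet_spec(f)
    x <- matrix(stats::rnorm(8 * 8), 8, 8)
    got <- dwt2_analysis(x, ws)
    want <- oracle_dwt2(x, ws)
    for (b in c("LL", "LH", "HL", "HH")) {
      expect_equal(got[[b]], want[[b]], tolerance = 1e-8)
    }
    rec <- subband_reconstruct(got, ws)
    wrec <- oracle_subband_images(x, ws)
    for (b in c("LL", "LH", "HL", "HH")) {
      expect_equal(rec[[b]], wrec[[b]], tolerance = 1e-8)
    }
  }
  # and on a random 8x8x3 image through decompose()
  img <- array(stats::rnorm(8 * 8 * 3), c(8, 8, 3))
  sb <- decompose(img, "dwt2", wavelet_spec("db4"))
  for (c in 1:3) {
    want <- oracle_subband_images(img[, , c], wavelet_spec("db4"))
    expect_equal(sb$HH[, , c], want$HH, tolerance = 1e-8)
  }
})

test_that("perfect reconstruction holds for every family on random sizes", {
  set.seed(7)
  sizes <- list(c(8L, 8L), c(16L, 12L), c(32L, 20L))
  for (f in c("haar", "db4", "db5", "db8")) {
    ws <- wavelet_spec(f)
    for (sz in sizes) {
      img <- array(stats::runif(prod(sz) * 3), c(sz, 3L))
      for (method in c("dwt2", "swt2")) {
        sb <- decompose(img, method, ws)
        expect_lt(max(abs(sum_bands(sb) - img)), 1e-6)
        for (b in c("LL", "LH", "HL", "HH")) {
          expect_equal(dim(sb[[b]]), dim(img))
        }
      }
    }
  }
})

test_that("constant images put everything in LL", {
  img <- array(0.4, c(16, 16, 3))
  sb <- decompose(img, "dwt2", haar)
  expect_lt(max(abs(sb$LH)), 1e-12)
  expect_lt(max(abs(sb$HL)), 1e-12)
  expect_lt(max(abs(sb$HH)), 1e-12)
  expect_equal(sb$LL, img)
})

test_that("channels are processed independently", {
  set.seed(5)
  img <- array(stats::rnorm(16 * 16 * 3), c(16, 16, 3))
  whole <- decompose(img, "dwt2", wavelet_spec("db5"))
  for (c in 1:3) {
    single <- decompose(img[, , c, drop = FALSE], "dwt2", wavelet_spec("db5"))
    expect_equal(whole$LH[, , c], single$LH[, , 1])
  }
})

test_that("svd eigentriple grouping is complete and captures rank-1 input", {
  set.seed(9)
  # rank-1 channel: subband1 alone reconstructs it
  u <- stats::rnorm(32); v <- stats::rnorm(32)
  ch <- array(u %o% v, c(32, 32, 1))
  sb <- decompose(ch, "svd")
  expect_lt(max(abs(sb$LL - ch)), 1e-8)
  expect_lt(max(abs(sb$LH)), 1e-8)
  expect_lt(max(abs(sb$HH)), 1e-8)
  # completeness at full default grouping on a 128x128 channel
  ch <- array(stats::rnorm(128 * 128), c(128, 128, 1))
  sb <- decompose(ch, "svd")
  expect_lt(max(abs(sum_bands(sb) - ch)), 1e-8)
  # non-square channel: last interval truncates to min(M, N)
  ch <- array(stats::rnorm(64 * 128), c(64, 128, 1))
  expect_lt(max(abs(sum_bands(decompose(ch, "svd")) - ch)), 1e-8)
})

test_that("eigentriple grouping validation rejects bad ranges", {
  expect_error(eigentriple_grouping(list(c(2, 5), c(6, 128)), 128),
               "from 1")
  expect_error(eigentriple_grouping(list(c(1, 5), c(7, 128)), 128))
  expect_error(eigentriple_grouping(list(c(1, 5), c(6, 100)), 128), "cover")
  g <- eigentriple_grouping(rank = 64)
  expect_equal(g[[4]], 41:64)
  expect_equal(unlist(g), 1:64)
})

test_that("subband energies behave like orthogonal projections", {
  # constant image: detail energies vanish
  e <- subband_energy(decompose(array(1, c(8, 8, 1)), "dwt2", haar))
  expect_lt(max(e[c("LH", "HL", "HH")]), 1e-12)

  # 0/1 checkerboard: diagonal detail dominates both axis-aligned details;
  # its energy ties with LL, which carries the 0.5 mean (computed from the
  # definition: per 2x2 block LL = 1 and HH = -1, LH = HL = 0)
  cb <- outer(1:16, 1:16, function(i, j) (i + j) %% 2)
  e <- subband_energy(decompose(array(cb, c(16, 16, 1)), "dwt2", haar))
  expect_gt(e["HH"], e["LH"])
  expect_gt(e["HH"], e["HL"])
  expect_equal(unname(e["HH"]), unname(e["LL"]), tolerance = 1e-12)
  expect_equal(unname(e["HH"]), 0.25, tolerance = 1e-12)

  # Parseval: band energies sum to the mean squared intensity
  set.seed(3)
  img <- array(stats::runif(16 * 16 * 3), c(16, 16, 3))
  e <- subband_energy(decompose(img, "dwt2", haar))
  expect_equal(sum(e), mean(img^2), tolerance = 1e-8)
})
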