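test_that("centered transforms match the brute-force DFT oracle", {
  x <- rand_complex(8, 8, seed = 101)
  expect_lt(max(Mod(image_to_kspace(x) - brute_dft2(x))), 1e-10)
  expect_lt(max(Mod(kspace_to_image(x) - brute_dft2(x, inverse = TRUE))), 1e-10)

  # constant image: single nonzero bin at the centre, value c * N
  k <- image_to_kspace(matrix(2.5, 8, 8))
  expect_equal(Mod(k[5, 5]), 2.5 * 8, tolerance = 1e-10)
  k[5, 5] <- 0
  expect_lt(max(Mod(k)), 1e-10)

  # unit impulse at the centre pixel: flat spectrum of modulus 1/N
  d <- matrix(0, 8, 8); d[5, 5] <- 1
  expect_lt(max(abs(Mod(image_to_kspace(d)) - 1 / 8)), 1e-10)

  # single DC entry of value v -> constant image v / N
  k <- matrix(0 + 0i, 8, 8); k[5, 5] <- 3
  img <- kspace_to_image(k)
  expect_lt(max(Mod(img - 3 / 8)), 1e-12)
})

test_that("transform pair is unitary and mutually inverse", {
  x <- rand_complex(16, 16, seed = 7)
  expect_lt(max(Mod(kspace_to_image(image_to_kspace(x)) - x)), 1e-12)
  expect_lt(max(Mod(image_to_kspace(kspace_to_image(x)) - x)), 1e-12)
  # Parseval
  expect_equal(sum(Mod(image_to_kspace(x))^2), sum(Mod(x)^2),
               tolerance = 1e-10)
  # all-zero k-space -> all-zero image
  expect_true(all(kspace_to_image(matrix(0 + 0i, 4, 4)) == 0))
  # non-finite input rejected
  bad <- matrix(1, 4, 4); bad[2, 2] <- NaN
  expect_error(image_to_kspace(bad), "non-finite")
})

test_that("interleaved mask keeps 0-based even columns", {
  m <- make_interleaved_mask(4, 4, 2)
  expect_equal(unname(m[, 1]), rep(1, 4))
  expect_equal(unname(m[, 3]), rep(1, 4))
  expect_true(all(m[, c(2, 4)] == 0))

  expect_true(all(make_interleaved_mask(5, 7, 1) == 1))
  expect_equal(sum(make_interleaved_mask(8, 8, 2)), 32)
  # kept-column count is ceil(W/R) * H for assorted shapes
  for (w in c(5, 8, 9)) {
    for (r in c(2, 3)) {
      expect_equal(sum(make_interleaved_mask(6, w, r)), ceiling(w / r) * 6)
    }
  }
  expect_error(make_interleaved_mask(4, 4, 5), "exceeds")
})

test_that("apply_mask zeroes removed columns and keeps the rest bit-identical", {
  set.seed(3)
  k <- array(complex(real = rnorm(64 * 64 * 3), imaginary = rnorm(64 * 64 * 3)),
             dim = c(64, 64, 3))
  m <- make_interleaved_mask(64, 64, 2)
  mk <- apply_mask(k, m)
  expect_identical(mk[, seq(1, 63, 2), ], k[, seq(1, 63, 2), ])
  expect_true(all(mk[, seq(2, 64, 2), ] == 0))
  expect_equal(apply_mask(k, make_interleaved_mask(64, 64, 1)), k,
               ignore_attr = TRUE)
  expect_error(apply_mask(k, make_interleaved_mask(32, 64, 2)), "shapes")

  # retained energy fraction ~ 1/R for i.i.d. k-space
  fracs <- sapply(1:20, function(s) {
    set.seed(s)
    kk <- matrix(complex(real = rnorm(64^2), imaginary = rnorm(64^2)), 64, 64)
    sum(Mod(apply_mask(kk, m))^2) / sum(Mod(kk)^2)
  })
  expect_true(all(abs(fracs - 0.5) < 0.05))

  # masking is idempotent
  expect_identical(apply_mask(mk, m), mk)
})

test_that("sum-of-squares combination matches the per-pixel formula", {
  one <- rand_complex(6, 6, seed = 9)
  expect_equal(sos_combine(one), Mod(one))
  px <- array(c(3 + 0i, 0 + 4i), dim = c(1, 1, 2))
  expect_error(sos_combine(px), NA)
  expect_equal(sos_combine(array(c(3 + 0i, 4i), dim = c(1, 1, 2)))[1, 1], 5)
  set.seed(11)
  st <- array(complex(real = rnorm(8 * 8 * 4), imaginary = rnorm(8 * 8 * 4)),
              dim = c(8, 8, 4))
  oracle <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8) oracle[i, j] <- sqrt(sum(Mod(st[i, j, ])^2))
  expect_lt(max(abs(sos_combine(st) - oracle)), 1e-12)
})

test_that("R=2 masking creates two equal half-FOV ghosts along phase-encode", {
  # single-pixel phantom
  f <- matrix(0, 16, 16); f[6, 4] <- 1
  rec <- kspace_to_image(apply_mask(image_to_kspace(f),
                                    make_interleaved_mask(16, 16, 2)))
  mag <- Mod(rec)
  peaks <- which(mag > 1e-10, arr.ind = TRUE)
  expect_equal(nrow(peaks), 2)
  expect_equal(sort(peaks[, "col"]), c(4, 12))  # separated by W/2 columns
  expect_equal(unname(peaks[, "row"]), c(6, 6))
  expect_equal(mag[6, 4], mag[6, 12], tolerance = 1e-12)
  expect_equal(mag[6, 4], 0.5, tolerance = 1e-12)

  # random image: package result matches the brute-force oracle chain
  set.seed(21)
  x <- rand_complex(16, 16, seed = 21)
  m <- make_interleaved_mask(16, 16, 2)
  pkg <- kspace_to_image(apply_mask(image_to_kspace(x), m))
  ora <- brute_dft2(brute_dft2(x) * as.numeric(m), inverse = TRUE)
  expect_lt(max(Mod(pkg - ora)), 1e-10)
  # replica-sum closed form: with the DC column kept (W/2 even) the masked
  # reconstruction is the unsigned half-sum of the image and its half-FOV
  # translate along phase-encode
  x_shift <- x[, c(9:16, 1:8)]
  expect_lt(max(Mod(pkg - 0.5 * (x + x_shift))), 1e-10)
})
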