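test_that("repetition averaging is the elementwise mean", {
  k <- array(complex(real = 1:24), dim = c(2, 3, 2, 2))
  k[, , , 2] <- k[, , , 1]
  expect_equal(average_repetitions(k), k[, , , 1])

  two <- array(c(1 + 0i, 3 + 0i), dim = c(1, 1, 2))
  expect_equal(average_repetitions(two)[1, 1], 2 + 0i)

  set.seed(5)
  r4 <- array(complex(real = rnorm(4 * 4 * 4), imaginary = rnorm(4 * 4 * 4)),
              dim = c(4, 4, 4))
  oracle <- (r4[, , 1] + r4[, , 2] + r4[, , 3] + r4[, , 4]) / 4
  expect_lt(max(Mod(average_repetitions(r4) - oracle)), 1e-12)
})

test_that("complex resize is linear, identity-preserving and constant-preserving", {
  set.seed(8)
  a <- matrix(rnorm(64), 8, 8); b <- matrix(rnorm(64), 8, 8)
  z <- a + 1i * b
  expect_lt(max(Mod(complex_resize(z, c(8, 8)) - z)), 1e-12)
  cimg <- matrix(2 - 3i, 8, 8)
  expect_lt(max(Mod(complex_resize(cimg, c(13, 5)) - (2 - 3i))), 1e-12)
  # resize(a + ib) = resize(a) + i resize(b)
  expect_lt(max(Mod(complex_resize(z, c(12, 10)) -
                      (complex_resize(a, c(12, 10)) +
                         1i * complex_resize(b, c(12, 10))))), 1e-12)
  expect_error(complex_resize(z, c(1, 8)), ">= 2")
})

test_that("normalization maps onto [0, 255] and flags degenerate input", {
  img <- matrix(seq(0, 510, length.out = 16), 4, 4)
  out <- normalize_to_range(img)
  expect_equal(max(out), 255)
  expect_equal(out, img / 2)
  ident <- matrix(c(0, 100, 255, 30), 2, 2)
  expect_equal(normalize_to_range(ident), ident)
  expect_warning(z <- normalize_to_range(matrix(7, 3, 3)), "degenerate")
  expect_true(all(z == 0))
})

test_that("prepare_pair reproduces the retrospective under-sampling chain", {
  set.seed(31)
  k <- array(complex(real = rnorm(32 * 32 * 3), imaginary = rnorm(32 * 32 * 3)),
             dim = c(32, 32, 3))
  # accel 1: identity mask, aliased == truth
  p1 <- prepare_pair(k, c(32, 32), accel = 1, pair_id = "id")
  expect_lt(max(abs(p1$aliased - p1$truth)), 1e-10)

  # ground truth equals an independent recomposition of the coil chain
  p2 <- prepare_pair(k, c(48, 48), accel = 2)
  coil <- array(complex(real = 0), dim = dim(k))
  for (c in 1:3) coil[, , c] <- kspace_to_image(k[, , c])
  truth_raw <- sos_combine(complex_resize(coil, c(48, 48)))
  rng <- range(truth_raw)
  expect_lt(max(abs(p2$truth - (truth_raw - rng[1]) / diff(rng) * 255)), 1e-10)

  # values stay in [0, 255] and finite
  expect_true(all(is.finite(p2$aliased)) && all(is.finite(p2$truth)))
  expect_true(min(p2$aliased) >= 0 && max(p2$aliased) <= 255)
  expect_true(min(p2$truth) >= 0 && max(p2$truth) <= 255)

  # single-coil bright-pixel phantom at accel 2: two equal ghosts W'/2 apart
  ph <- matrix(0, 32, 32); ph[10, 7] <- 1
  kk <- image_to_kspace(ph)
  p3 <- prepare_pair(kk, c(32, 32), accel = 2)
  peaks <- which(p3$aliased > 100, arr.ind = TRUE)
  expect_equal(nrow(peaks), 2)
  expect_equal(abs(diff(peaks[, "col"])), 16)
  expect_equal(p3$aliased[peaks[1, 1], peaks[1, 2]],
               p3$aliased[peaks[2, 1], peaks[2, 2]], tolerance = 1e-8)

  # determinism of the full chain
  expect_identical(p2$truth, prepare_pair(k, c(48, 48), accel = 2)$truth)
})

test_that("split_dataset gives disjoint exhaustive deterministic splits", {
  s <- split_dataset(1:10, split_spec(0.7, 0.1, 0.2, seed = 4))
  expect_equal(lengths(s), c(train = 7L, val = 1L, test = 2L))
  expect_identical(s, split_dataset(1:10, split_spec(0.7, 0.1, 0.2, seed = 4)))

  set.seed(99)
  for (n in sample(11:97, 20, replace = TRUE)) {
    sp <- split_dataset(seq_len(n), split_spec(seed = n))
    all_ids <- c(sp$train, sp$val, sp$test)
    expect_equal(sort(all_ids), seq_len(n))
    expect_equal(length(all_ids), n)  # no duplicates across the three lists
  }
  expect_error(split_spec(0.7, 0.1, 0.3), "sum to 1")
  expect_error(split_dataset(integer(), split_spec()), "no items")
})

test_that("augmentation keeps the pair pixel-aligned", {
  p <- sim_pair(seed = 2, size = c(32, 32), n_coils = 4)
  expect_equal(augment_pair(p, character(), seed = 1)[c("aliased", "truth")],
               p[c("aliased", "truth")])
  # horizontal flip is an involution
  f2 <- augment_pair(augment_pair(p, "hflip", seed = 1), "hflip", seed = 1)
  expect_equal(f2$aliased, p$aliased, tolerance = 1e-12)
  expect_equal(f2$truth, p$truth, tolerance = 1e-12)
  expect_error(augment_pair(p, "shear", 1), "unknown transform")

  # impulse phantom: the truth peak moves exactly as the coordinates do
  ph <- matrix(0, 32, 32); ph[5, 9] <- 1
  ip <- prepare_pair(image_to_kspace(ph), c(32, 32), accel = 1)
  hf <- augment_pair(ip, "hflip", seed = 3)
  expect_equal(which(hf$truth == 255, arr.ind = TRUE)[1, ],
               c(row = 5, col = 32 - 9 + 1))
  vf <- augment_pair(ip, "vflip", seed = 3)
  expect_equal(which(vf$truth == 255, arr.ind = TRUE)[1, ],
               c(row = 32 - 5 + 1, col = 9))
  # and aliased/truth receive the identical sampled transform
  for (ops in list("rot90", "crop", c("rot90", "hflip", "crop"))) {
    g1 <- augment_pair(ip, ops, seed = 17)
    g2 <- augment_pair(ip, ops, seed = 17)
    expect_identical(g1$aliased, g2$aliased)
    expect_equal(dim(g1$aliased), dim(ip$aliased))
    expect_equal(g1$aliased, g1$truth, tolerance = 1e-8)  # pair was identical
  }
})
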