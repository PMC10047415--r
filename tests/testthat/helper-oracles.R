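# Independent oracles and small fixture factories shared across the suite.
# The oracles deliberately avoid the package's own code paths: the DFT
# oracle is the O(N^4) double sum, the SSIM oracle loops windows explicitly.

# Centered orthonormal 2-D DFT by direct summation:
#   X[j1, j2] = (1/sqrt(HW)) * sum_n x[n1, n2] *
#               exp(-+ 2 pi i ((j1' n1')/H + (j2' n2')/W))
# with n' = n - floor(N/2), j' = j - floor(N/2) (0-based centered indices).
brute_dft2 <- function(x, inverse = FALSE) {
  H <- nrow(x); W <- ncol(x)
  sgn <- if (inverse) 1 else -1
  out <- matrix(complex(real = 0), H, W)
  n1 <- (seq_len(H) - 1) - H %/% 2
  n2 <- (seq_len(W) - 1) - W %/% 2
  for (j1 in seq_len(H)) {
    for (j2 in seq_len(W)) {
      k1 <- (j1 - 1) - H %/% 2
      k2 <- (j2 - 1) - W %/% 2
      ph <- outer(n1 * k1 / H, n2 * k2 / W, `+`)
      out[j1, j2] <- sum(x * exp(sgn * 2i * pi * ph))
    }
  }
  out / sqrt(H * W)
}

# Per-window SSIM by explicit looping (uniform windows, population
# variance), averaged over all stride-1 window positions.
brute_ssim <- function(ref, tst, win = c(8, 8), L = 255) {
  c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  H <- nrow(ref); W <- ncol(ref)
  vals <- c()
  for (i in seq_len(H - win[1] + 1)) {
    for (j in seq_len(W - win[2] + 1)) {
      a <- ref[i:(i + win[1] - 1), j:(j + win[2] - 1)]
      b <- tst[i:(i + win[1] - 1), j:(j + win[2] - 1)]
      mu_a <- mean(a); mu_b <- mean(b)
      va <- mean((a - mu_a)^2); vb <- mean((b - mu_b)^2)
      cab <- mean((a - mu_a) * (b - mu_b))
      vals <- c(vals, ((2 * mu_a * mu_b + c1) * (2 * cab + c2)) /
                  ((mu_a^2 + mu_b^2 + c1) * (va + vb + c2)))
    }
  }
  mean(vals)
}

# Simulated aliased/ground-truth pair at desk scale.
sim_pair <- function(seed, size = c(64, 64), n_coils = 8, noise = 0.01,
                     accel = 2, n_ellipses = 5) {
  cfg <- phantom_config(size = size, n_ellipses = n_ellipses,
                        n_coils = n_coils, noise_sigma = noise, seed = seed)
  ph <- generate_phantom(cfg)
  maps <- generate_coil_maps(size, n_coils, seed = seed)
  k <- simulate_acquisition(ph, maps, noise, seed = seed)
  prepare_pair(k, size, accel, pair_id = paste0("sim", seed))
}

rand_complex <- function(n, m, seed = 1) {
  set.seed(seed)
  matrix(complex(real = rnorm(n * m), imaginary = rnorm(n * m)), n, m)
}
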