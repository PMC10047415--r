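# Classical parallel-imaging baseline: coil-sensitivity estimation from
# fully sampled data and Cartesian SENSE unfolding of interleaved
# under-sampled k-space.

# Circular Gaussian lowpass of a (complex) image via the centered transforms.
# `frac` is the kernel footprint as a fraction of the image size; the
# Gaussian SD is a quarter of that footprint (the usual +/- 2 SD truncation
# convention for discrete Gaussian kernels).
gaussian_lowpass <- function(img, frac = 1 / 8) {
  H <- nrow(img); W <- ncol(img)
  kx <- seq_len(W) - 1 - W %/% 2
  ky <- seq_len(H) - 1 - H %/% 2
  sy <- frac * H / 4; sx <- frac * W / 4
  gy <- exp(-2 * pi^2 * (sy * ky / H)^2)
  gx <- exp(-2 * pi^2 * (sx * kx / W)^2)
  env <- outer(gy, gx)
  kspace_to_image(image_to_kspace(img) * env)
}

#' Estimate coil sensitivity maps from fully sampled coil images
#'
#' Lowpass-normalized estimator: each coil image is smoothed with a broad
#' Gaussian (kernel footprint `kernel_frac` of the image size, SD a quarter
#' of the footprint) and divided by the
#' sum-of-squares of the smoothed stack, giving maps with unit per-pixel
#' sum of squares on the object support.  Pixels whose smoothed
#' sum-of-squares magnitude falls below `support_thresh` times its maximum
#' are outside the object and set to exactly 0.
#'
#' @param coil_images complex `H x W x C` fully sampled coil images, C >= 2.
#' @param kernel_frac Gaussian kernel footprint as a fraction of the image
#'   size (default 1/8).
#' @param support_thresh support threshold relative to the maximum smoothed
#'   intensity (default 0.1).
#' @return complex `H x W x C` sensitivity maps with attributes
#'   `normalized = TRUE` and `support` (logical matrix).
#' @export
estimate_sensitivities <- function(coil_images, kernel_frac = 1 / 8,
                                   support_thresh = 0.1) {
  d <- dim(coil_images)
  if (length(d) != 3 || d[3] < 2) stop("need an H x W x C stack with C >= 2")
  if (all(Mod(coil_images) == 0)) stop("all-zero coil images")
  low <- array(complex(real = 0), dim = d)
  for (c in seq_len(d[3])) {
    low[, , c] <- gaussian_lowpass(coil_images[, , c], kernel_frac)
  }
  norm <- sos_combine(low)
  support <- norm >= support_thresh * max(norm)
  maps <- array(complex(real = 0), dim = d)
  safe <- ifelse(support, norm, 1)
  for (c in seq_len(d[3])) {
    maps[, , c] <- ifelse(support, low[, , c] / safe, 0 + 0i)
  }
  attr(maps, "normalized") <- TRUE
  attr(maps, "support") <- support
  maps
}

# Replica weights of the zero-filled reconstruction: masking k-space with
# the interleaved pattern makes the image a weighted sum of R shifted copies
# y(c) = sum_m w_m * f(c + m*W/R).  The weights (which absorb the 1/R
# amplitude loss and any mask-offset phase) are read off numerically from
# the masked reconstruction of a delta image, which is exact because the
# masking operator is circularly shift-invariant.
replica_weights <- function(H, W, accel) {
  delta <- matrix(0, H, W); delta[1, 1] <- 1
  rec <- kspace_to_image(apply_mask(image_to_kspace(delta),
                                    make_interleaved_mask(H, W, accel)))
  shift <- W %/% accel
  vapply(seq_len(accel) - 1,
         function(m) rec[1, ((W - m * shift) %% W) + 1], complex(1))
}

#' SENSE reconstruction of interleaved under-sampled k-space
#'
#' Inverse-transforms the zero-filled under-sampled k-space per coil, then
#' unfolds each group of R aliased replicas along the phase-encode axis by
#' solving the per-pixel least-squares system built from the sensitivity
#' maps (all `C x R` coil equations at the R aliased positions are stacked).
#' The solve is Tikhonov-regularized with factor `1e-6 * ||A||`, and pixels
#' whose system has smallest singular value below `sv_tol` are flagged
#' ill-conditioned.  The replica weights absorb the 1/R amplitude scaling of
#' the zero-filled inverse transform, so the output is on the phantom scale.
#'
#' @param us_k complex `H x W x C` under-sampled k-space (interleaved mask,
#'   acceleration `accel`).
#' @param maps complex `H x W x C` sensitivity maps.
#' @param accel acceleration factor R; requires `C >= accel` and
#'   `W` divisible by `accel`.
#' @param sv_tol smallest-singular-value threshold for the
#'   ill-conditioning flag (default 1e-3).
#' @return a `sense_result`: list with `image` (real `H x W` magnitude
#'   reconstruction) and `condition_flags` (logical `H x W`).
#' @export
sense_reconstruct <- function(us_k, maps, accel, sv_tol = 1e-3) {
  d <- dim(us_k)
  if (length(d) != 3) stop("us_k must be H x W x C")
  if (!all(dim(maps) == d)) stop("maps and k-space shapes differ")
  C <- d[3]; H <- d[1]; W <- d[2]
  accel <- as.integer(accel)
  if (C < accel) stop("SENSE needs at least as many coils as the acceleration factor")
  if (W %% accel != 0) stop("inconsistent mask: width not divisible by accel")
  removed <- which((seq_len(W) - 1) %% accel != 0)
  if (length(removed)) {
    kept_energy <- sum(Mod(us_k[, -removed, , drop = FALSE])^2)
    bad_energy <- sum(Mod(us_k[, removed, , drop = FALSE])^2)
    if (bad_energy > 1e-8 * max(kept_energy, 1e-300)) {
      stop("inconsistent mask: energy present in removed phase-encode columns")
    }
  }

  aliased <- array(complex(real = 0), dim = d)
  for (c in seq_len(C)) aliased[, , c] <- kspace_to_image(us_k[, , c])

  w <- replica_weights(H, W, accel)
  shift <- W %/% accel
  rho <- matrix(complex(real = 0), H, W)
  flags <- matrix(FALSE, H, W)
  for (g in seq_len(shift)) {
    cols <- g + (seq_len(accel) - 1) * shift   # replica column group
    # rows of A: (coil i, base offset b); columns: group position m'
    A0 <- matrix(complex(real = 0), C * accel, accel)
    for (r in seq_len(H)) {
      S <- maps[r, cols, , drop = TRUE]          # accel x C (or vector if C==1)
      S <- matrix(S, nrow = accel, ncol = C)
      A <- A0
      for (b in seq_len(accel) - 1) {
        wr <- w[((seq_len(accel) - 1 - b) %% accel) + 1]
        A[(b * C) + seq_len(C), ] <- t(S * wr)   # C x accel rows for base b
      }
      # y ordering matches A's rows (base b outer, coil i inner):
      # base b uses the aliased value at column cols[b+1], all coils
      y <- as.vector(vapply(seq_len(accel), function(b) aliased[r, cols[b], ],
                            complex(C)))
      sv <- svd(A, nu = 0, nv = 0)$d
      if (max(sv) == 0) { rho[r, cols] <- 0; flags[r, cols] <- TRUE; next }
      if (min(sv) < sv_tol) flags[r, cols] <- TRUE
      tau <- 1e-6 * max(sv)
      AH <- Conj(t(A))
      rho[r, cols] <- solve(AH %*% A + diag(tau^2, accel), AH %*% y)
    }
  }
  structure(list(image = Mod(rho), condition_flags = flags),
            class = "sense_result")
}
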