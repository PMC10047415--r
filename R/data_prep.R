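# Dataset preparation: from fully sampled multi-coil k-space to paired
# (aliased, ground-truth) training images in [0, 255], plus the random
# split and the geometric augmentation used to enlarge the training set.

#' Average k-space acquisition repetitions
#'
#' Arithmetic mean over the trailing "averages" axis of a stacked k-space
#' array (`... x n_avg`).  A single repetition is returned unchanged.
#'
#' @param k complex array whose last axis indexes repetitions.
#' @return complex array with the averaging axis dropped.
#' @export
average_repetitions <- function(k) {
  d <- dim(k)
  if (is.null(d) || length(d) < 2) stop("k must be an array with an averaging axis")
  n_avg <- d[length(d)]
  if (n_avg < 1) stop("empty averaging axis")
  core <- d[-length(d)]
  out <- matrix(k, nrow = prod(core), ncol = n_avg)
  out <- rowMeans(out)
  if (length(core) > 1) dim(out) <- core else out <- as.vector(out)
  out
}

# 1-D linear-interpolation matrix mapping n source samples to m targets.
# Pixel centres follow the half-pixel convention: target i sits at source
# coordinate (i + 0.5) * n/m - 0.5 (0-based), clamped at the borders.
# Rows sum to one, so constants are reproduced exactly; m == n gives the
# identity matrix.
interp_matrix <- function(n, m) {
  A <- matrix(0, m, n)
  s <- (seq_len(m) - 0.5) * n / m - 0.5
  s <- pmin(pmax(s, 0), n - 1)
  lo <- floor(s)
  frac <- s - lo
  hi <- pmin(lo + 1, n - 1)
  for (i in seq_len(m)) {
    A[i, lo[i] + 1] <- A[i, lo[i] + 1] + (1 - frac[i])
    A[i, hi[i] + 1] <- A[i, hi[i] + 1] + frac[i]
  }
  A
}

#' Resize a complex image (or coil stack) bilinearly
#'
#' Real and imaginary channels are resized independently with the same
#' separable bilinear interpolator, so the operation is linear in the input
#' and reproduces constant images at any target size.
#'
#' @param img complex or real matrix `H x W`, or array `H x W x C`.
#' @param new_size integer pair `(H', W')`, both >= 2.
#' @return resized image/stack with the same number of coils.
#' @export
complex_resize <- function(img, new_size) {
  new_size <- as.integer(new_size)
  if (length(new_size) != 2 || any(new_size < 2)) {
    stop("new_size must be two integers >= 2")
  }
  d <- dim(img)
  if (is.null(d)) stop("img must be a matrix or 3-d array")
  A <- interp_matrix(d[1], new_size[1])
  B <- interp_matrix(d[2], new_size[2])
  resize_plane <- function(x) A %*% x %*% t(B)  # real coefficients: acts on
  # real and imaginary parts independently by linearity
  if (length(d) == 2) return(resize_plane(img))
  out <- array(if (is.complex(img)) complex(real = 0) else 0,
               dim = c(new_size, d[3]))
  for (c in seq_len(d[3])) out[, , c] <- resize_plane(img[, , c])
  out
}

#' Min-max normalize an image onto [0, 255]
#'
#' Affine map sending the input minimum to 0 and maximum to 255.  A constant
#' image has no range to stretch; it maps to all zeros with a warning.
#'
#' @param img finite real matrix.
#' @return real matrix with values in `[0, 255]`.
#' @export
normalize_to_range <- function(img) {
  stop_if_not_finite(img, "image")
  rng <- range(img)
  if (diff(rng) == 0) {
    warning("degenerate intensity range: constant image normalized to zeros")
    return(img * 0)
  }
  (img - rng[1]) / diff(rng) * 255
}

#' Build an aliased / ground-truth image pair from full k-space
#'
#' Runs the retrospective under-sampling chain on one fully sampled
#' multi-coil frame: inverse-transform each coil to image space, resize to
#' `target_size`, then (a) combine the resized coil images by sum-of-squares
#' for the ground truth and (b) re-transform to k-space, apply the
#' interleaved mask at acceleration `accel`, inverse-transform and combine
#' for the aliased image.  Both images are mapped to `[0, 255]` with a
#' *shared* scale taken from the ground truth, so the aliased image's energy
#' deficit stays visible; the aliased image is clipped into the range.
#'
#' @param full_k complex `H x W` matrix or `H x W x C` array of fully
#'   sampled k-space (DC centered).
#' @param target_size integer pair, default `c(256, 256)`.
#' @param accel acceleration factor R >= 1.
#' @param pair_id identifier stored with the pair.
#' @return an `image_pair`: list with elements `aliased`, `truth` (real
#'   `target_size` matrices in `[0, 255]`) and `pair_id`.
#' @export
prepare_pair <- function(full_k, target_size = c(256, 256), accel = 2,
                         pair_id = "pair") {
  d <- dim(full_k)
  if (is.null(d)) stop("full_k must be a matrix or 3-d array")
  if (length(d) == 2) {
    full_k <- array(full_k, dim = c(d, 1))
    d <- dim(full_k)
  }
  stop_if_not_finite(full_k, "k-space")
  if (accel < 1) stop("accel must be >= 1")

  coil_imgs <- array(complex(real = 0), dim = d)
  for (c in seq_len(d[3])) coil_imgs[, , c] <- kspace_to_image(full_k[, , c])
  resized <- complex_resize(coil_imgs, target_size)

  truth_raw <- sos_combine(resized)

  mask <- make_interleaved_mask(target_size[1], target_size[2], accel)
  us_imgs <- array(complex(real = 0), dim = dim(resized))
  for (c in seq_len(d[3])) {
    k_res <- image_to_kspace(resized[, , c])
    us_imgs[, , c] <- kspace_to_image(apply_mask(k_res, mask))
  }
  aliased_raw <- sos_combine(us_imgs)

  rng <- range(truth_raw)
  if (diff(rng) == 0) {
    warning("degenerate ground-truth intensity range")
    truth <- truth_raw * 0
    aliased <- aliased_raw * 0
  } else {
    scale <- 255 / diff(rng)
    truth <- (truth_raw - rng[1]) * scale
    aliased <- pmin(pmax((aliased_raw - rng[1]) * scale, 0), 255)
  }
  structure(list(aliased = aliased, truth = truth, pair_id = pair_id),
            class = "image_pair")
}

#' Split specification for train/validation/test partitioning
#'
#' @param train,val,test fractions in (0, 1) summing to 1
#'   (default 0.7 / 0.1 / 0.2).
#' @param seed integer controlling the shuffle.
#' @return a `split_spec` list.
#' @export
split_spec <- function(train = 0.7, val = 0.1, test = 0.2, seed = 1) {
  fr <- c(train = train, val = val, test = test)
  if (any(fr <= 0) || any(fr >= 1)) stop("each fraction must lie in (0, 1)")
  if (abs(sum(fr) - 1) > 1e-9) stop("split fractions must sum to 1")
  structure(list(train = train, val = val, test = test,
                 seed = as.integer(seed)), class = "split_spec")
}

#' Randomly split pair identifiers into train/validation/test sets
#'
#' Validation and test sizes are floors of their fractions; the remainder
#' goes to training.  The same seed always yields the same split; the three
#' lists are disjoint and jointly exhaustive.
#'
#' @param items vector of pair identifiers.
#' @param spec a [split_spec()].
#' @return list with elements `train`, `val`, `test`.
#' @export
split_dataset <- function(items, spec = split_spec()) {
  if (!inherits(spec, "split_spec")) stop("spec must be a split_spec")
  n <- length(items)
  if (n == 0) stop("no items to split")
  n_val <- floor(spec$val * n)
  n_test <- floor(spec$test * n)
  shuffled <- with_seed(spec$seed, sample(items, n))
  list(train = shuffled[seq_len(n - n_val - n_test)],
       val = if (n_val > 0) shuffled[n - n_val - n_test + seq_len(n_val)] else items[0],
       test = if (n_test > 0) shuffled[n - n_test + seq_len(n_test)] else items[0])
}

rot90k <- function(x, k) {
  k <- k %% 4
  if (k == 0) return(x)
  if (k == 1) return(t(x)[rev(seq_len(ncol(x))), , drop = FALSE])
  if (k == 2) return(x[rev(seq_len(nrow(x))), rev(seq_len(ncol(x))), drop = FALSE])
  t(x)[, rev(seq_len(nrow(x))), drop = FALSE]
}

#' Jointly augment an aliased/ground-truth pair
#'
#' Applies the listed geometric transforms, in order, identically to the
#' aliased and ground-truth images so they stay pixel-aligned.  Supported
#' transforms: `"rot90"` (a random multiple of 90 degrees; restricted to 0
#' or 180 for non-square images so the shape is preserved), `"hflip"` and
#' `"vflip"` (deterministic mirror flips), and `"crop"` (a random window of
#' 75-100% of the frame, resized back to the original shape).  Random
#' parameters are drawn from `seed` and shared by both images.
#'
#' @param p an `image_pair` from [prepare_pair()].
#' @param ops character vector of transform names (possibly empty).
#' @param seed integer seed for the sampled parameters.
#' @return augmented `image_pair` of the same shape.
#' @export
augment_pair <- function(p, ops = character(), seed = 1) {
  if (!inherits(p, "image_pair")) stop("p must be an image_pair")
  known <- c("rot90", "hflip", "vflip", "crop")
  bad <- setdiff(ops, known)
  if (length(bad)) stop("unknown transform: ", paste(bad, collapse = ", "))
  a <- p$aliased; t_ <- p$truth
  h <- nrow(a); w <- ncol(a)
  with_seed(seed, {
    for (op in ops) {
      if (op == "rot90") {
        k <- if (h == w) sample(0:3, 1) else sample(c(0L, 2L), 1)
        a <- rot90k(a, k); t_ <- rot90k(t_, k)
      } else if (op == "hflip") {
        a <- a[, rev(seq_len(w)), drop = FALSE]
        t_ <- t_[, rev(seq_len(w)), drop = FALSE]
      } else if (op == "vflip") {
        a <- a[rev(seq_len(h)), , drop = FALSE]
        t_ <- t_[rev(seq_len(h)), , drop = FALSE]
      } else if (op == "crop") {
        fr <- runif(1, 0.75, 1)
        ch <- max(2L, as.integer(round(fr * h)))
        cw <- max(2L, as.integer(round(fr * w)))
        r0 <- sample.int(h - ch + 1L, 1)
        c0 <- sample.int(w - cw + 1L, 1)
        a <- Re(complex_resize(a[r0:(r0 + ch - 1), c0:(c0 + cw - 1)], c(h, w)))
        t_ <- Re(complex_resize(t_[r0:(r0 + ch - 1), c0:(c0 + cw - 1)], c(h, w)))
      }
    }
  })
  structure(list(aliased = pmin(pmax(a, 0), 255),
                 truth = pmin(pmax(t_, 0), 255),
                 pair_id = paste0(p$pair_id, "_aug", seed)),
            class = "image_pair")
}
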