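# Numerical substrate: centered orthonormal 2-D Fourier transforms between
# image space and k-space, interleaved Cartesian sampling masks, masking, and
# sum-of-squares coil combination.
#
# Conventions (fixed package-wide):
#   * the zero spatial frequency (DC) sits at the grid centre,
#     row floor(H/2), column floor(W/2) in 0-based indexing;
#   * transforms carry 1/sqrt(HW) in each direction, so both are unitary and
#     Parseval's identity holds exactly;
#   * rows are the frequency-encode axis, columns the phase-encode axis
#     (the axis that is under-sampled).

fftshift2 <- function(x) {
  d <- dim(x)
  # fftshift moves index 1 (DC) to floor(d/2)+1: rotate left by ceil(d/2)
  s1 <- (seq_len(d[1]) - 1 + ceiling(d[1] / 2)) %% d[1] + 1
  s2 <- (seq_len(d[2]) - 1 + ceiling(d[2] / 2)) %% d[2] + 1
  x[s1, s2, drop = FALSE]
}

ifftshift2 <- function(x) {
  d <- dim(x)
  s1 <- (seq_len(d[1]) - 1 + d[1] %/% 2) %% d[1] + 1
  s2 <- (seq_len(d[2]) - 1 + d[2] %/% 2) %% d[2] + 1
  x[s1, s2, drop = FALSE]
}

#' Centered orthonormal 2-D Fourier transform (image to k-space)
#'
#' Transforms a complex-valued image into k-space with the DC component at
#' the grid centre (row `floor(H/2)`, column `floor(W/2)`, 0-based) and
#' orthonormal `1/sqrt(HW)` scaling, so the transform is unitary: the L2
#' norm of the input is preserved (Parseval).
#'
#' @param img complex (or real) matrix, at least 2 x 2, all entries finite.
#' @return complex matrix of the same size: the centered spectrum.
#' @seealso [kspace_to_image()] for the exact inverse.
#' @export
#' @examples
#' k <- image_to_kspace(matrix(1, 8, 8))
#' Mod(k[5, 5])  # constant image: all energy at the DC bin, value c * N
image_to_kspace <- function(img) {
  img <- as.matrix(img)
  if (nrow(img) < 2 || ncol(img) < 2) stop("image must be at least 2 x 2")
  stop_if_not_finite(img, "image")
  fftshift2(stats::fft(ifftshift2(img))) / sqrt(length(img))
}

#' Centered orthonormal 2-D inverse Fourier transform (k-space to image)
#'
#' Exact inverse of [image_to_kspace()]: same centering and orthonormal
#' scaling, so `kspace_to_image(image_to_kspace(x))` recovers `x` to
#' floating-point precision.
#'
#' @param k complex matrix: a centered k-space plane.
#' @return complex image matrix of the same size.
#' @export
kspace_to_image <- function(k) {
  k <- as.matrix(k)
  if (nrow(k) < 2 || ncol(k) < 2) stop("k-space plane must be at least 2 x 2")
  stop_if_not_finite(k, "k-space")
  fftshift2(stats::fft(ifftshift2(k), inverse = TRUE)) / sqrt(length(k))
}

#' Interleaved Cartesian sampling mask
#'
#' Builds the binary under-sampling mask that keeps every `accel`-th
#' phase-encode column (0-based columns `j` with `j %% accel == 0`) and
#' zeroes the rest; rows are untouched.  `accel = 2` reproduces the
#' "remove every second column" scheme, `accel = 1` is fully sampled.
#'
#' @param height,width mask size (rows x columns), both >= 1.
#' @param accel integer acceleration factor R >= 1; must not exceed `width`.
#' @return 0/1 matrix with attribute `accel`.
#' @export
#' @examples
#' make_interleaved_mask(4, 4, 2)  # columns 1 and 3 kept (0-based 0 and 2)
make_interleaved_mask <- function(height, width, accel) {
  height <- as.integer(height); width <- as.integer(width)
  accel <- as.integer(accel)
  if (height < 1 || width < 1) stop("mask dimensions must be >= 1")
  if (accel < 1) stop("acceleration factor must be >= 1")
  if (accel > width) stop("acceleration factor exceeds mask width")
  keep <- (seq_len(width) - 1) %% accel == 0
  m <- matrix(rep(as.numeric(keep), each = height), height, width)
  attr(m, "accel") <- accel
  m
}

#' Apply a sampling mask to (multi-coil) k-space
#'
#' Elementwise product of the mask with each coil plane; kept columns are
#' bit-identical to the input, removed columns are exactly zero.
#'
#' @param k complex matrix `H x W` or array `H x W x C`.
#' @param m mask from [make_interleaved_mask()] (or any 0/1 matrix of
#'   matching spatial size).
#' @return masked k-space of the same shape (attribute `accel` forwarded).
#' @export
apply_mask <- function(k, m) {
  dk <- dim(k)
  if (is.null(dk)) stop("k must be a matrix or 3-d array")
  if (dk[1] != nrow(m) || dk[2] != ncol(m)) {
    stop("mask and k-space spatial shapes differ")
  }
  out <- if (length(dk) == 2) {
    k * as.numeric(m)
  } else if (length(dk) == 3) {
    k * array(as.numeric(m), dim = dk)  # mask broadcast over coils
  } else {
    stop("k must be 2-d or 3-d")
  }
  attr(out, "accel") <- attr(m, "accel")
  out
}

#' Sum-of-squares coil combination
#'
#' Per-pixel root-sum-of-squared-magnitudes over the coil axis:
#' `sqrt(sum_c |img_c|^2)`.  With a single coil this is the pointwise
#' magnitude.
#'
#' @param imgs complex matrix `H x W` (one coil) or array `H x W x C`.
#' @return nonnegative real `H x W` matrix.
#' @export
sos_combine <- function(imgs) {
  d <- dim(imgs)
  if (is.null(d)) stop("imgs must be a matrix or 3-d array")
  if (length(d) == 2) return(Mod(imgs))
  if (length(d) != 3 || d[3] < 1) stop("imgs must be H x W x C with C >= 1")
  sq <- Mod(imgs)^2
  sqrt(matrix(rowSums(matrix(sq, nrow = d[1] * d[2])), d[1], d[2]))
}
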