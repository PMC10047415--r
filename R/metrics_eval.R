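# Image-quality evaluation: PSNR, local sliding-window SSIM, paired
# evaluation of several reconstruction methods on a test split, and the
# normality-screen + rank-sum significance protocol.

#' SSIM configuration
#'
#' @param window local window size (default `c(8, 8)`), slid with `stride`
#'   (default 1) using unweighted (uniform) window statistics.
#' @param stride window step in pixels.
#' @param dynamic_range dynamic range L of the images (default 255 for the
#'   `[0, 255]` normalization).
#' @param k1,k2 stabilization constants; `c1 = (k1 L)^2`, `c2 = (k2 L)^2`
#'   (standard 0.01 / 0.03).
#' @return an `ssim_config` list with fields `c1`, `c2` precomputed.
#' @export
ssim_config <- function(window = c(8, 8), stride = 1, dynamic_range = 255,
                        k1 = 0.01, k2 = 0.03) {
  window <- as.integer(window)
  if (any(window < 1)) stop("window must be positive")
  structure(list(window = window, stride = as.integer(stride),
                 L = dynamic_range,
                 c1 = (k1 * dynamic_range)^2, c2 = (k2 * dynamic_range)^2),
            class = "ssim_config")
}

#' Peak signal-to-noise ratio
#'
#' `20 * log10(max_val / sqrt(MSE))` in dB, with `max_val` the maximum
#' possible pixel value (255 under the package's normalization, not the
#' per-image maximum).  Identical images return `Inf` as a sentinel.
#'
#' @param reference,test real matrices of the same shape.
#' @param max_val maximum possible pixel value (default 255).
#' @return PSNR in dB (possibly `Inf`).
#' @export
psnr <- function(reference, test, max_val = 255) {
  if (!identical(dim(reference), dim(test))) stop("image shapes differ")
  if (max_val <= 0) stop("max_val must be > 0")
  mse <- mean((reference - test)^2)
  if (mse == 0) return(Inf)
  20 * log10(max_val / sqrt(mse))
}

# Summed-area table with a leading zero row/column, so rectangle sums are
# four lookups.
sat <- function(x) {
  s <- apply(x, 2, cumsum)
  s <- t(apply(s, 1, cumsum))
  rbind(0, cbind(0, s))
}

win_sums <- function(S, rows, cols, wh, ww) {
  S[rows + wh, cols + ww] - S[rows, cols + ww] - S[rows + wh, cols] +
    S[rows, cols]
}

#' Structural similarity index (local sliding window)
#'
#' Computes the local SSIM term
#' `((2 mu_I mu_K + c1)(2 sigma_IK + c2)) /
#'  ((mu_I^2 + mu_K^2 + c1)(sigma_I^2 + sigma_K^2 + c2))`
#' on every window position (unweighted window statistics, population
#' variance convention) and averages over the M windows.
#'
#' @param reference,test real matrices of the same shape, at least as large
#'   as the window.
#' @param cfg an [ssim_config()].
#' @return scalar in `[-1, 1]`; exactly 1 for identical images.
#' @export
ssim <- function(reference, test, cfg = ssim_config()) {
  if (!identical(dim(reference), dim(test))) stop("image shapes differ")
  wh <- cfg$window[1]; ww <- cfg$window[2]
  H <- nrow(reference); W <- ncol(reference)
  if (H < wh || W < ww) stop("image smaller than the SSIM window")
  rows <- seq(1, H - wh + 1, by = cfg$stride)
  cols <- seq(1, W - ww + 1, by = cfg$stride)
  n <- wh * ww
  Si <- sat(reference); Sk <- sat(test)
  Sii <- sat(reference^2); Skk <- sat(test^2); Sik <- sat(reference * test)
  rows_m <- matrix(rows, length(rows), length(cols))
  cols_m <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  lookup <- function(S) win_sums(S, rows_m, cols_m, wh, ww)
  mu_i <- lookup(Si) / n
  mu_k <- lookup(Sk) / n
  var_i <- lookup(Sii) / n - mu_i^2
  var_k <- lookup(Skk) / n - mu_k^2
  cov_ik <- lookup(Sik) / n - mu_i * mu_k
  num <- (2 * mu_i * mu_k + cfg$c1) * (2 * cov_ik + cfg$c2)
  den <- (mu_i^2 + mu_k^2 + cfg$c1) * (var_i + var_k + cfg$c2)
  mean(num / den)
}

#' Evaluate reconstruction methods on a test split
#'
#' Runs every method (a named function `aliased -> image`) on every test
#' pair, computes per-image SSIM and PSNR against the ground truth in the
#' same image order for every method (paired design), and summarizes each
#' method with mean, SD and median.  A method failure on an image is
#' recorded with a warning and that image is excluded for all methods, so
#' the arrays stay paired.  Infinite PSNR values are excluded from means
#' with a warning.
#'
#' @param testpairs nonempty list of `image_pair`s.
#' @param methods named list of reconstruction functions.
#' @param cfg an [ssim_config()].
#' @return a `metrics_report`: list with `per_image` (data frame: pair_id,
#'   method, ssim, psnr), `summary` (data frame: method, metric, mean, sd,
#'   median, n) and `n_images`.
#' @export
evaluate_models <- function(testpairs, methods, cfg = ssim_config()) {
  if (!length(testpairs)) stop("empty test set")
  if (is.null(names(methods)) || any(names(methods) == "")) {
    stop("methods must be a named list")
  }
  n <- length(testpairs)
  res <- list()
  failed <- logical(n)
  for (m in names(methods)) {
    sv <- numeric(n); pv <- numeric(n)
    for (i in seq_len(n)) {
      p <- testpairs[[i]]
      rec <- tryCatch(methods[[m]](p$aliased), error = function(e) {
        warning(sprintf("method '%s' failed on image %s: %s", m, p$pair_id,
                        conditionMessage(e)))
        NULL
      })
      if (is.null(rec)) { failed[i] <- TRUE; sv[i] <- NA; pv[i] <- NA; next }
      sv[i] <- ssim(p$truth, rec, cfg)
      pv[i] <- psnr(p$truth, rec, cfg$L)
    }
    res[[m]] <- list(ssim = sv, psnr = pv)
  }
  keep <- !failed
  if (any(failed)) {
    warning(sprintf("%d image(s) excluded pairwise after method failures",
                    sum(failed)))
  }
  ids <- vapply(testpairs, function(p) as.character(p$pair_id), character(1))
  per_image <- do.call(rbind, lapply(names(res), function(m) {
    data.frame(pair_id = ids[keep], method = rep(m, sum(keep)),
               ssim = res[[m]]$ssim[keep], psnr = res[[m]]$psnr[keep])
  }))
  summarize <- function(v, m, metric) {
    vv <- v
    if (metric == "psnr" && any(is.infinite(vv))) {
      warning(sprintf("infinite PSNR excluded from the mean for '%s'", m))
      vv <- vv[is.finite(vv)]
    }
    data.frame(method = m, metric = metric,
               mean = mean(vv), sd = sd(vv), median = median(v),
               n = length(v))
  }
  summary <- do.call(rbind, lapply(names(res), function(m) {
    rbind(summarize(res[[m]]$ssim[keep], m, "ssim"),
          summarize(res[[m]]$psnr[keep], m, "psnr"))
  }))
  structure(list(per_image = per_image, summary = summary,
                 n_images = sum(keep)), class = "metrics_report")
}

#' Normality screen and rank-sum comparison against a baseline method
#'
#' For every method other than `baseline_method` and each metric, reports
#' the Shapiro-Wilk normality p-value of the method's per-image scores and
#' the two-sample Mann-Whitney (Wilcoxon rank-sum) p-value against the
#' baseline (normal approximation without continuity correction, so
#' identical samples give p = 1), with a significance decision at 0.05.
#' Degenerate comparisons where every value is tied are flagged and
#' reported as p = 1.
#'
#' @param report a `metrics_report` from [evaluate_models()].
#' @param baseline_method name of the reference method.
#' @param alpha significance threshold (default 0.05).
#' @return data frame with columns method, metric, shapiro_p, baseline
#'   shapiro_p, ranksum_p, significant, degenerate.
#' @export
significance_compare <- function(report, baseline_method, alpha = 0.05) {
  stopifnot(inherits(report, "metrics_report"))
  per_img <- report$per_image
  methods <- unique(per_img$method)
  if (!(baseline_method %in% methods)) stop("unknown baseline method")
  if (length(methods) < 2) stop("need at least two methods to compare")
  safe_shapiro <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 3 || diff(range(x)) == 0) return(NA_real_)
    tryCatch(shapiro.test(x)$p.value, error = function(e) NA_real_)
  }
  rows <- list()
  for (m in setdiff(methods, baseline_method)) {
    for (metric in c("ssim", "psnr")) {
      a <- per_img[per_img$method == m, metric]
      b <- per_img[per_img$method == baseline_method, metric]
      if (length(a) < 3) stop("arrays must have length >= 3")
      degenerate <- diff(range(c(a, b))) == 0
      p <- if (degenerate) {
        1
      } else {
        wilcox.test(a, b, exact = FALSE, correct = FALSE)$p.value
      }
      rows[[length(rows) + 1]] <- data.frame(
        method = m, metric = metric,
        shapiro_p = safe_shapiro(a),
        baseline_shapiro_p = safe_shapiro(b),
        ranksum_p = p,
        significant = is.finite(p) && p < alpha,
        degenerate = degenerate)
    }
  }
  do.call(rbind, rows)
}
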