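#' @useDynLib rekonstruct, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd median shapiro.test wilcox.test
#' @importFrom utils write.csv modifyList
NULL

# Run `code` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(abs(seed) %% 2147483647))
  }
  force(code)
}

stop_if_not_finite <- function(x, what = "input") {
  if (!all(is.finite(Re(x))) || (is.complex(x) && !all(is.finite(Im(x))))) {
    stop(sprintf("non-finite values in %s", what), call. = FALSE)
  }
  invisible(x)
}

# Deterministic order-sensitive fingerprint of a numeric vector/array or a
# named list of them.  Used for parameter checksums and config hashes.
checksum <- function(x) {
  if (is.list(x)) {
    parts <- vapply(seq_along(x), function(i) checksum(x[[i]]), numeric(1))
    return(sum(parts * seq_along(parts)))
  }
  v <- as.numeric(x)
  sum(v * (seq_along(v) %% 97 + 1))
}

# Short hexadecimal FNV-1a hash of a character string (config provenance).
# 32-bit arithmetic is done on 16-bit limbs: R's bitwXor is integer-only and
# a direct 32-bit multiply loses precision in doubles.
fnv1a_hash <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    lo <- bitwXor(h %% 65536, b)
    hi <- h %/% 65536
    # (hi*2^16 + lo) * p mod 2^32
    h <- ((hi * p) %% 65536) * 65536 + lo * p
    h <- h %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
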