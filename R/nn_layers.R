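# Minimal neural-network layer set with hand-written backpropagation:
# convolution (compiled, im2col + BLAS), 2x2 max pooling, nearest-neighbour
# upsampling, channel concatenation, batch normalization, the activations
# used by the networks, and Adam.  Tensors are (H, W, C, N) arrays.

conv_init <- function(k, cin, cout, init_sd = 0.02) {
  list(W = array(rnorm(k * k * cin * cout, sd = init_sd),
                 dim = c(k, k, cin, cout)),
       b = numeric(cout))
}

conv_fwd <- function(x, W, b, stride = 1L, pad = 1L) {
  conv2d_fwd(x, W, b, as.integer(stride), as.integer(pad))
}

conv_bwd <- function(x, W, gy, stride = 1L, pad = 1L) {
  conv2d_bwd(x, W, gy, as.integer(stride), as.integer(pad))
}

leaky_relu_fwd <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)
leaky_relu_bwd <- function(x, gy, slope = 0.2) gy * ifelse(x > 0, 1, slope)
relu_fwd <- function(x) pmax(x, 0)
relu_bwd <- function(x, gy) gy * (x > 0)
tanh_bwd <- function(y, gy) gy * (1 - y^2)      # y = tanh(x)
sigmoid_fwd <- function(x) 1 / (1 + exp(-x))
sigmoid_bwd <- function(y, gy) gy * y * (1 - y)  # y = sigmoid(x)

# 2x2 max pooling, stride 2.  Returns the pooled tensor plus the four
# quadrant comparison masks needed for the backward routing (first maximal
# entry wins on exact ties).
maxpool2_fwd <- function(x) {
  d <- dim(x)
  i1 <- seq(1, d[1], by = 2); i2 <- i1 + 1
  j1 <- seq(1, d[2], by = 2); j2 <- j1 + 1
  a <- x[i1, j1, , , drop = FALSE]; b <- x[i2, j1, , , drop = FALSE]
  c_ <- x[i1, j2, , , drop = FALSE]; e <- x[i2, j2, , , drop = FALSE]
  m <- pmax(a, b, c_, e)
  ma <- a == m
  mb <- (b == m) & !ma
  mc <- (c_ == m) & !ma & !mb
  me <- !(ma | mb | mc)
  list(y = m, masks = list(ma, mb, mc, me), in_dim = d)
}

maxpool2_bwd <- function(cache, gy) {
  d <- cache$in_dim
  gx <- array(0, dim = d)
  i1 <- seq(1, d[1], by = 2); i2 <- i1 + 1
  j1 <- seq(1, d[2], by = 2); j2 <- j1 + 1
  m <- cache$masks
  gx[i1, j1, , ] <- gy * m[[1]]
  gx[i2, j1, , ] <- gx[i2, j1, , , drop = FALSE] + gy * m[[2]]
  gx[i1, j2, , ] <- gx[i1, j2, , , drop = FALSE] + gy * m[[3]]
  gx[i2, j2, , ] <- gx[i2, j2, , , drop = FALSE] + gy * m[[4]]
  gx
}

upsample2_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , ,
    drop = FALSE]
}

upsample2_bwd <- function(gy) {
  d <- dim(gy)
  i1 <- seq(1, d[1], by = 2); i2 <- i1 + 1
  j1 <- seq(1, d[2], by = 2); j2 <- j1 + 1
  gy[i1, j1, , , drop = FALSE] + gy[i2, j1, , , drop = FALSE] +
    gy[i1, j2, , , drop = FALSE] + gy[i2, j2, , , drop = FALSE]
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# Batch normalization over (H, W, N) per channel, batch statistics.
batchnorm_fwd <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x)
  C <- d[3]
  xp <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = C)   # columns = channels
  mu <- colMeans(xp)
  xc <- sweep(xp, 2, mu)
  v <- colMeans(xc^2)
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, istd, `*`)
  yp <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  y <- aperm(array(yp, dim = c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
  list(y = y, xhat = xhat, istd = istd, dims = d)
}

batchnorm_bwd <- function(cache, gamma, gy) {
  d <- cache$dims
  C <- d[3]
  gyp <- matrix(aperm(gy, c(1, 2, 4, 3)), ncol = C)
  M <- nrow(gyp)
  dgamma <- colSums(gyp * cache$xhat)
  dbeta <- colSums(gyp)
  dxhat <- sweep(gyp, 2, gamma, `*`)
  t1 <- sweep(dxhat, 2, colMeans(dxhat))
  t2 <- sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), `*`)
  dxp <- sweep(t1 - t2, 2, cache$istd, `*`)
  gx <- aperm(array(dxp, dim = c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
  list(gx = gx, dgamma = dgamma, dbeta = dbeta)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

# beta1 = 0.5: the conditional-GAN training convention adopted package-wide.
adam_step <- function(state, params, grads, lr = 2e-4, beta1 = 0.5,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(state = state, params = params)
}

params_sq_norm <- function(params) {
  sum(vapply(params, function(p) sum(p^2), numeric(1)))
}
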