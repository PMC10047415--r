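ns <- asNamespace("rekonstruct")

test_that("generator construction honours its shape and determinism contracts", {
  spec <- network_spec(depth = 3, base_channels = 4, input_size = c(32, 32))
  g1 <- build_generator(spec, seed = 5)
  g2 <- build_generator(spec, seed = 5)
  expect_equal(param_checksum(g1), param_checksum(g2))
  expect_false(param_checksum(g1) ==
                 param_checksum(build_generator(spec, seed = 6)))
  # forward pass preserves the input shape
  x <- array(runif(32 * 32 * 1 * 2, -1, 1), dim = c(32, 32, 1, 2))
  y <- ns$gen_forward(g1, x)$y
  expect_equal(dim(y), dim(x))
  expect_true(all(abs(y) <= 1))
  # one skip concatenation per down-sampling stage
  expect_equal(sum(grepl("^dec", names(g1$params))) / 2, spec$depth)
  expect_error(network_spec(depth = 4, input_size = c(24, 24)), "divisible")
})

test_that("every generator parameter receives gradient (no dead branches)", {
  spec <- network_spec(depth = 2, base_channels = 4, input_size = c(16, 16))
  gen <- build_generator(spec, seed = 2)
  set.seed(3)
  x <- array(runif(16 * 16 * 1 * 2, -1, 1), dim = c(16, 16, 1, 2))
  fwd <- ns$gen_forward(gen, x, keep_cache = TRUE)
  gy <- array(rnorm(length(fwd$y)), dim = dim(fwd$y))
  grads <- ns$gen_backward(gen, fwd$cache, gy)
  expect_setequal(names(grads), names(gen$params))
  for (nm in names(grads)) {
    expect_true(any(grads[[nm]] != 0), info = nm)
  }
})

test_that("discriminator has six stages, bounded outputs and is order-sensitive", {
  disc <- build_discriminator(c(32, 32), base_channels = 4, seed = 9)
  conv_layers <- grep("\\.W$", names(disc$params), value = TRUE)
  expect_equal(length(conv_layers), 6)
  bn_layers <- grep("\\.gamma$", names(disc$params), value = TRUE)
  expect_setequal(bn_layers, paste0("l", 2:5, ".gamma"))
  set.seed(4)
  x <- array(runif(32 * 32 * 2 * 3, -1, 1), dim = c(32, 32, 2, 3))
  d <- ns$disc_forward(disc, x)$d
  expect_true(all(d > 0 & d < 1))
  # conditioning is order-sensitive: swapping the pair changes the output
  xs <- x[, , c(2, 1), , drop = FALSE]
  expect_gt(max(abs(ns$disc_forward(disc, xs)$d - d)), 1e-8)
  expect_error(ns$disc_forward(disc, x[, , 1, , drop = FALSE]),
               "channel mismatch")
})

test_that("short training decreases the loss and records a full history", {
  pairs <- lapply(1:4, function(i) sim_pair(i, size = c(32, 32), n_coils = 4))
  cfg <- train_config(epochs = 30, batch_size = 4, seed = 2,
                      mode = "unet_hybrid")
  fit <- train_model(pairs, cfg)
  expect_equal(nrow(fit$history), 30)
  expect_lt(fit$history$train_total[30], fit$history$train_total[1])
  expect_null(fit$discriminator)
  # reconstruct_image: shape and range contracts
  rec <- reconstruct_image(fit$generator, pairs[[1]]$aliased)
  expect_equal(dim(rec), dim(pairs[[1]]$aliased))
  expect_true(min(rec) >= 0 && max(rec) <= 255)
  expect_error(reconstruct_image(fit$generator, matrix(0, 16, 16)),
               "does not match")
  expect_error(train_model(list(), cfg), "empty training set")
})

test_that("training histories are reproducible under a fixed seed", {
  pairs <- lapply(1:6, function(i) sim_pair(i, size = c(32, 32), n_coils = 4))
  cfg <- train_config(epochs = 2, batch_size = 2, seed = 7, mode = "unet_l1")
  f1 <- train_model(pairs, cfg, val_pairs = pairs[5:6])
  f2 <- train_model(pairs, cfg, val_pairs = pairs[5:6])
  expect_equal(f1$history$train_total, f2$history$train_total)
  expect_equal(f1$history$val_total, f2$history$val_total)
  expect_equal(param_checksum(f1$generator), param_checksum(f2$generator))
})

test_that("CGAN alternation freezes the discriminator during generator updates", {
  pairs <- lapply(1:4, function(i) sim_pair(i, size = c(32, 32), n_coils = 4))
  batch <- ns$stack_pairs(pairs)
  cfg <- train_config(epochs = 1, batch_size = 4, seed = 3, mode = "cgan_hybrid")
  gen <- build_generator(network_spec(depth = 3, base_channels = 4,
                                      input_size = c(32, 32)), seed = 3)
  disc <- build_discriminator(c(32, 32), base_channels = 4, seed = 4)
  opt_g <- ns$adam_init(gen$params)
  opt_d <- ns$adam_init(disc$params)
  ck_before <- param_checksum(disc)
  gu <- ns$generator_composite_update(gen, disc, opt_g, batch, cfg, 0.1)
  expect_identical(param_checksum(disc), ck_before)   # frozen discriminator
  expect_false(param_checksum(gu$gen) == param_checksum(gen))
  du <- ns$discriminator_update(gu$gen, disc, opt_d, batch, cfg)
  expect_false(param_checksum(du$disc) == ck_before)  # but it does train

  # full cgan training runs and logs both adversarial terms
  fit <- train_model(pairs, train_config(epochs = 2, batch_size = 4, seed = 5,
                                         mode = "cgan_l1", depth = 3,
                                         base_channels = 4, disc_base = 4))
  expect_s3_class(fit$discriminator, "discriminator")
  expect_true(all(is.finite(fit$history$train_adversarial)))
  expect_equal(nrow(fit$history), 2)
})
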