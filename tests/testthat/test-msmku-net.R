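# Architecture contracts of the U-shaped multi-scale multi-kernel network.

test_that("image pyramid halves each level and leaves level 1 untouched", {
  for (side in c(16L, 256L, 384L)) {
    X <- random_image(side)
    pyr <- build_image_pyramid(X)
    expect_identical(pyr[[1]], X)
    expect_equal(vapply(pyr, function(p) dim(p)[1], numeric(1)),
                 side / c(1, 2, 4, 8))
  }
  expect_error(build_image_pyramid(array(0, c(12, 12, 3))), "divisible")
})

test_that("multi-kernel module preserves spatial size, maps depth, and is
           residual at zero weights", {
  x <- array(runif(32 * 32 * 8), c(32, 32, 8))
  y <- multi_kernel_module(x, 8L)
  expect_equal(dim(y), c(32, 32, 8))
  # odd spatial sizes survive the asymmetric even-kernel padding
  xo <- array(runif(7 * 9 * 4), c(7, 9, 4))
  expect_equal(dim(multi_kernel_module(xo, 6L)), c(7, 9, 6))
  # zero input + identity short connection -> module reduces to its BN shift
  M <- fundusseg:::new_mk_module(4L, 4L)
  z <- list(array(0, c(8, 8, 4)))
  out <- fundusseg:::mk_forward(M, z, training = FALSE)[[1]]
  expect_equal(out, z[[1]] + out - z[[1]])  # finite
  M$fuse$W[] <- 0; M$fuse$b[] <- 0; M$bn$beta[] <- 0
  out0 <- fundusseg:::mk_forward(M, z, training = FALSE)[[1]]
  expect_equal(out0, z[[1]])               # pure short connection
})

test_that("bottleneck is side/16 and output matches input size in [0,1]", {
  for (side in c(32L, 64L)) {
    net <- build_msmku(msmku_config(side, 4L, seed = 3L))
    x <- random_image(side)
    P <- predict(net, x)
    expect_equal(dim(P), c(side, side))
    expect_true(all(P >= 0 & P <= 1))
    # bottleneck size observed through the deepest strided conv output
    B <- fundusseg:::conv_forward(net$layers$F3s,
      fundusseg:::mk_forward(net$layers$mk3,
        list(array(0, c(side / 8, side / 8, 4L * 4L))), FALSE), FALSE)[[1]]
    expect_equal(dim(B)[1:2], c(side / 16, side / 16))
  }
  expect_error(msmku_config(100L), "divisible")
})

test_that("initialisation is seed-deterministic and inference is stable", {
  net1 <- build_msmku(msmku_config(32L, 4L, seed = 9L))
  net2 <- build_msmku(msmku_config(32L, 4L, seed = 9L))
  x <- random_image(32L)
  expect_identical(predict(net1, x), predict(net2, x))
  expect_identical(predict(net1, x), predict(net1, x))
  net3 <- build_msmku(msmku_config(32L, 4L, seed = 10L))
  expect_false(identical(predict(net1, x), predict(net3, x)))
  expect_error(predict(net1, random_image(64L)), "must be")
})

test_that("every parameter tensor receives a finite nonzero gradient", {
  for (side in c(32L, 64L, 256L, 384L)) {
    net <- build_msmku(msmku_config(side, 4L, seed = 1L))
    set.seed(side)
    xs <- list(random_image(side))
    Gs <- list(random_mask(side, side))
    fundusseg:::zero_grads(net$param_refs)
    P <- fundusseg:::msmku_forward(net, xs, training = TRUE)
    fundusseg:::msmku_backward(
      net, Map(fundusseg:::dice_loss_grad, P, Gs))
    gnorm <- vapply(net$param_refs, function(r) {
      g <- r$layer[[paste0("d", r$name)]]
      expect_true(all(is.finite(g)))
      sum(abs(g))
    }, numeric(1))
    expect_true(all(gnorm > 0))
  }
})

test_that("analytic gradients match finite differences", {
  set.seed(5)
  net <- build_msmku(msmku_config(32L, 2L, seed = 5L))
  xs <- list(random_image(32L), random_image(32L))
  Gs <- list(random_mask(32, 32), random_mask(32, 32))
  loss <- function() sum(mapply(dice_loss,
                                fundusseg:::msmku_forward(net, xs, TRUE), Gs))
  fundusseg:::zero_grads(net$param_refs)
  P <- fundusseg:::msmku_forward(net, xs, TRUE)
  fundusseg:::msmku_backward(net, Map(fundusseg:::dice_loss_grad, P, Gs))
  eps <- 1e-5
  for (r in sample(net$param_refs, 8)) {
    k <- sample(length(r$layer[[r$name]]), 1)
    w0 <- r$layer[[r$name]][k]
    r$layer[[r$name]][k] <- w0 + eps; lp <- loss()
    r$layer[[r$name]][k] <- w0 - eps; lm <- loss()
    r$layer[[r$name]][k] <- w0
    num <- (lp - lm) / (2 * eps)
    ana <- r$layer[[paste0("d", r$name)]][k]
    expect_lt(abs(num - ana) / max(1e-8, abs(num) + abs(ana)), 1e-4)
  }
})

test_that("expanding-path skip connections contribute to the output", {
  net <- build_msmku(msmku_config(32L, 4L, seed = 2L))
  x <- random_image(32L)
  with_sk <- predict(net, x)
  net$no_skips <- TRUE
  without_sk <- predict(net, x)
  net$no_skips <- FALSE
  expect_false(identical(with_sk, without_sk))
})

test_that("a test-scale forward pass is fast enough for interactive use", {
  net <- build_msmku(msmku_config(64L, 4L, seed = 1L))
  x <- random_image(64L)
  predict(net, x)  # warm up
  el <- system.time(predict(net, x))[["elapsed"]]
  expect_lt(el, 1)
})
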