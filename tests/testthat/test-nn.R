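# Conv-net engine: analytic gradients against finite differences, shape
# contracts, schedule arithmetic, optimiser behaviour.

unet_tiny <- function(seed = 3, depth = 3L, base = 4L, c_in = 2L) {
  set.seed(seed)
  plexbridge:::.unet_init(c_in, base, depth)
}

test_that("backpropagated gradients match finite differences", {
  set.seed(3)
  net <- unet_tiny()
  H <- 8L; W <- 8L; N <- 2L
  x <- plexbridge:::.act_geom(matrix(rnorm(2 * H * W * N), nrow = 2), H, W, N)
  tg <- matrix(rnorm(H * W * N), nrow = 1)
  loss <- function(nt) {
    f <- plexbridge:::.unet_fwd(nt, x, training = TRUE)
    0.5 * sum((f$out$a - tg)^2)
  }
  f <- plexbridge:::.unet_fwd(net, x, training = TRUE)
  bw <- plexbridge:::.unet_bwd(net, f, f$out$a - tg)
  eps <- 1e-5
  check_leaf <- function(getp, setp, ana) {
    p0 <- getp(net)
    set.seed(11)
    for (i in sample(length(p0), min(6, length(p0)))) {
      n2 <- setp(net, `[<-`(p0, i, p0[i] + eps)); l1 <- loss(n2)
      n2 <- setp(net, `[<-`(p0, i, p0[i] - eps)); l2 <- loss(n2)
      expect_equal((l1 - l2) / (2 * eps), ana[i], tolerance = 1e-4)
    }
  }
  check_leaf(function(n) n$enc[[1]]$conv$W,
             function(n, p) { n$enc[[1]]$conv$W <- p; n }, bw$grads$enc[[1]]$conv$W)
  check_leaf(function(n) n$enc[[2]]$bn$gamma,
             function(n, p) { n$enc[[2]]$bn$gamma <- p; n }, bw$grads$enc[[2]]$bn$gamma)
  check_leaf(function(n) n$dec[[2]]$convt$W,
             function(n, p) { n$dec[[2]]$convt$W <- p; n }, bw$grads$dec[[2]]$convt$W)
  check_leaf(function(n) n$dec[[3]]$convt$b,
             function(n, p) { n$dec[[3]]$convt$b <- p; n }, bw$grads$dec[[3]]$convt$b)
})

test_that("U-Net shape contract and filter progression hold", {
  cfg <- model_config("DIC", "X", preset = "paper", seed = 1)
  m <- build_unet(cfg)
  expect_equal(m$net$widths, c(64L, 128L, 256L, 512L, 512L, 512L, 512L, 512L))
  expect_equal(m$net$depth, 8L)
  expect_null(m$net$enc[[1]]$bn)            # no BN on the first convolution
  expect_null(m$net$dec[[8]]$bn)            # nor on the final one
  expect_true(all(vapply(m$net$dec[1:3], `[[`, TRUE, "dropout")))
  expect_false(any(vapply(m$net$dec[4:7], `[[`, TRUE, "dropout")))

  # desk preset: 64 px input, depth 6 -> 1x1 bottleneck, output = input shape
  dcfg <- model_config(c("DIC", "DNA"), "X", preset = "desk", seed = 1)
  dm <- build_unet(dcfg)
  x <- plexbridge:::.act_geom(matrix(rnorm(2 * 64 * 64), nrow = 2), 64L, 64L, 1L)
  f <- plexbridge:::.unet_fwd(dm$net, x, training = FALSE)
  expect_equal(c(f$out$H, f$out$W, nrow(f$out$a)), c(64L, 64L, 1L))

  # zero-weight model emits tanh(0) = 0 everywhere
  zm <- dm$net
  for (i in seq_along(zm$enc)) zm$enc[[i]]$conv$W[] <- 0
  for (j in seq_along(zm$dec)) { zm$dec[[j]]$convt$W[] <- 0; zm$dec[[j]]$convt$b[] <- 0 }
  fz <- plexbridge:::.unet_fwd(zm, x, training = FALSE)
  expect_true(all(fz$out$a == 0))

  expect_error(model_config("DIC", "X", preset = "desk", patch_size = 96L),
               "divisible")
})

test_that("unet and cgan generators share the patch interface and output shapes", {
  tiles <- lapply(1:2, function(i) {
    a <- array(runif(64 * 64 * 2, 0, 255), c(64, 64, 2))
    dimnames(a) <- list(NULL, NULL, c("DIC", "X"))
    a
  })
  for (arch in c("unet", "cgan")) {
    cfg <- model_config("DIC", "X", arch = arch, preset = "desk", seed = 5)
    m <- if (arch == "cgan") build_cgan(cfg) else build_unet(cfg)
    pr <- predict_channel(m, tiles)
    expect_length(pr, 2L)
    expect_equal(dim(pr[[1]]), c(64L, 64L))
    expect_true(all(pr[[1]] == round(pr[[1]])) && all(pr[[1]] >= 0 & pr[[1]] <= 255))
  }
})

test_that("discriminator widths follow the doubling-to-cap recipe without first-layer BN", {
  cfg <- model_config("DIC", "X", arch = "cgan", preset = "desk", seed = 2)
  m <- build_cgan(cfg)
  widths <- vapply(m$disc$layers, function(l) length(l$conv$b), 0L)
  expect_equal(widths, c(16L, 32L, 64L, 128L, 128L, 1L))  # base 16: 16..128 cap, 128 stride-1, classifier
  strides <- vapply(m$disc$layers, `[[`, 0L, "stride")
  expect_equal(strides, c(2L, 2L, 2L, 2L, 1L, 1L))
  expect_null(m$disc$layers[[1]]$bn)
  expect_false(is.null(m$disc$layers[[2]]$bn))
  # LSGAN generator loss for an all-ones score map against the real label is zero
  expect_equal(mean((rep(1, 16) - 1)^2), 0)
})

test_that("learning-rate schedule is constant then linearly decaying", {
  lr <- 2e-4
  expect_equal(plexbridge:::.lr_at_epoch(0, lr, 50, 50), lr)
  expect_equal(plexbridge:::.lr_at_epoch(49, lr, 50, 50), lr)
  for (k in c(0, 10, 25, 49))
    expect_equal(plexbridge:::.lr_at_epoch(50 + k, lr, 50, 50), lr * (1 - k / 50))
  cfg <- model_config("DIC", "X", preset = "paper")
  expect_equal(cfg$epochs_const + cfg$epochs_decay, 100L)
})

test_that("a small U-Net memorises a single patch (training reduces L1 by >90%)", {
  set.seed(21)
  base <- matrix(runif(64 * 64, 0, 255), 64)
  smooth <- plexbridge:::.box_blur(base, 11L)  # structured target, as in staining
  a <- array(0, c(64, 64, 2))
  a[, , 1] <- smooth
  a[, , 2] <- 255 - smooth
  dimnames(a) <- list(NULL, NULL, c("DIC", "X"))
  cfg <- model_config("DIC", "X", preset = "desk", batch_size = 4L,
                      epochs_const = 100L, epochs_decay = 100L, seed = 9)
  m <- train_virtual_model(list(a), cfg, augment = TRUE)  # 1 step/epoch: 200 steps
  expect_equal(nrow(m$history), 200L)
  expect_lt(m$history$l1[200], 0.1 * m$history$l1[1])
  # eval-mode prediction is deterministic
  p1 <- predict_channel(m, list(a)); p2 <- predict_channel(m, list(a))
  expect_identical(p1, p2)
})

test_that("cgan training runs and records adversarial losses", {
  set.seed(22)
  a <- array(runif(64 * 64 * 2, 0, 255), c(64, 64, 2))
  dimnames(a) <- list(NULL, NULL, c("DIC", "X"))
  cfg <- model_config("DIC", "X", arch = "cgan", preset = "desk", batch_size = 4L,
                      epochs_const = 2L, epochs_decay = 2L, seed = 13)
  m <- train_virtual_model(list(a), cfg)
  expect_equal(nrow(m$history), 4L)
  expect_true(all(is.finite(m$history$gan_g)))
  expect_true(all(is.finite(m$history$gan_d)))
  expect_lt(m$history$l1[4], m$history$l1[1])
})

test_that("training a model rejects tiles lacking the target channel", {
  a <- array(runif(64 * 64, 0, 255), c(64, 64, 1))
  dimnames(a) <- list(NULL, NULL, "DIC")
  cfg <- model_config("DIC", "X", preset = "desk", seed = 1)
  expect_error(train_virtual_model(list(a), cfg), "target channel")
})
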