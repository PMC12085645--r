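## Virtual-labelling models: U-Net regression and conditional GAN (LSGAN +
## L1) built on the in-package conv-net engine, plus the training loop.
## Training runs 50 epochs at a constant learning rate then 50 epochs of
## linear decay to zero (ADAM, beta1 = 0.5, beta2 = 0.999) at defaults.

#' Virtual-labelling model configuration
#'
#' Architecture and schedule for one image-to-image model. Defaults follow
#' the paper-scale recipe (256-px patches, depth-8 U-Net, 64 base filters
#' capped at 512, 4x4 kernels, stride 2, leaky-ReLU 0.2 encoder, batch norm
#' eps 1e-5 / momentum 0.1, dropout 0.5 on the three deepest decoder blocks,
#' tanh output, lr 2e-4, 50 + 50 epochs). `preset = "desk"` selects a
#' CPU-scale variant exercising identical code paths: 64-px patches, depth
#' 6, 16 base filters, 5 + 5 epochs, batch 8.
#'
#' @param input_channels Character vector of input channel names.
#' @param target_channel Target channel name.
#' @param arch `"unet"` or `"cgan"`.
#' @param preset `"paper"` or `"desk"`.
#' @param patch_size,depth,base_filters,batch_size,epochs_const,epochs_decay,lr
#'   Overrides of the preset values.
#' @param lambda_l1,lambda_lsgan Loss weights for the cGAN objective
#'   (pix2pix convention 100:1).
#' @param seed Training RNG seed.
#' @return A `pb_model_config` list.
#' @export
model_config <- function(input_channels, target_channel,
                         arch = c("unet", "cgan"), preset = c("paper", "desk"),
                         patch_size = NULL, depth = NULL, base_filters = NULL,
                         batch_size = NULL, epochs_const = NULL, epochs_decay = NULL,
                         lr = 2e-4, lambda_l1 = 100, lambda_lsgan = 1, seed = 0L) {
  arch <- match.arg(arch); preset <- match.arg(preset)
  d <- if (preset == "desk")
    list(patch_size = 64L, depth = 6L, base_filters = 16L, batch_size = 8L,
         epochs_const = 5L, epochs_decay = 5L)
  else
    list(patch_size = 256L, depth = 8L, base_filters = 64L, batch_size = 1L,
         epochs_const = 50L, epochs_decay = 50L)
  cfg <- list(
    input_channels = input_channels, target_channel = target_channel,
    arch = arch, preset = preset,
    patch_size = as.integer(patch_size %||% d$patch_size),
    depth = as.integer(depth %||% d$depth),
    base_filters = as.integer(base_filters %||% d$base_filters),
    batch_size = as.integer(batch_size %||% d$batch_size),
    epochs_const = as.integer(epochs_const %||% d$epochs_const),
    epochs_decay = as.integer(epochs_decay %||% d$epochs_decay),
    lr = lr, lambda_l1 = lambda_l1, lambda_lsgan = lambda_lsgan,
    adam_beta1 = 0.5, adam_beta2 = 0.999, lrelu_slope = 0.2,
    bn_eps = 1e-5, bn_momentum = 0.1, seed = as.integer(seed)
  )
  if (cfg$patch_size %% 2L^cfg$depth != 0L)
    stop("patch_size must be divisible by 2^depth")
  if (cfg$base_filters < 1L || cfg$lr <= 0) stop("invalid rates/filters")
  structure(cfg, class = "pb_model_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build an untrained U-Net virtual-labelling model
#'
#' Encoder of `depth` 4x4/stride-2 down-convolutions with filter widths
#' doubling from `base_filters` and capped at `8 * base_filters`
#' (64..512 at defaults), mirrored decoder with skip concatenation, tanh
#' output of one channel; batch norm everywhere except the first and last
#' convolution; output spatial shape equals input shape.
#'
#' @param config A `pb_model_config`.
#' @return A `pb_unet` model object.
#' @export
build_unet <- function(config) {
  stopifnot(inherits(config, "pb_model_config"))
  set.seed(config$seed)
  net <- .unet_init(length(config$input_channels), config$base_filters, config$depth)
  structure(list(net = net, config = config, trained = FALSE, history = NULL),
            class = c("pb_unet", "pb_vlmodel"))
}

#' Build an untrained conditional GAN
#'
#' Uses [build_unet()] as the generator; the discriminator scores
#' (inputs, candidate target) stacks with 4x4 down-convolutions (widths
#' doubling from `base_filters` to the 8x cap, stride 2), a final
#' stride-1 down-convolution at the cap width, and a stride-1 one-channel
#' classification layer, emitting a patch score map. Batch norm on all but
#' the first discriminator layer. Objective:
#' `lambda_l1 * L1 + lambda_lsgan * LSGAN` where the LSGAN term is the mean
#' squared error of the discriminator's prediction.
#'
#' @param config A `pb_model_config`.
#' @return A `pb_cgan` model object with `generator` and `discriminator`.
#' @export
build_cgan <- function(config) {
  stopifnot(inherits(config, "pb_model_config"))
  gen <- build_unet(config)
  disc <- .disc_init(length(config$input_channels) + 1L, config$base_filters)
  structure(list(net = gen$net, disc = disc, config = config, trained = FALSE,
                 history = NULL), class = c("pb_cgan", "pb_vlmodel"))
}

#' @export
print.pb_vlmodel <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<%s> %s <- [%s], depth %d, base %d, patch %d, %strained\n",
              class(x)[1], cfg$target_channel, paste(cfg$input_channels, collapse = ", "),
              cfg$depth, cfg$base_filters, cfg$patch_size, if (x$trained) "" else "un"))
  if (x$trained) cat(sprintf("  %d epochs, final train L1 %.4f\n",
                             nrow(x$history), x$history$l1[nrow(x$history)]))
  invisible(x)
}

# tiles (list of HxWxC arrays with channel dimnames) -> model batch
.tiles_to_batch <- function(tiles, channels) {
  N <- length(tiles)
  H <- dim(tiles[[1]])[1]; W <- dim(tiles[[1]])[2]
  a <- matrix(0, length(channels), H * W * N)
  for (n in seq_len(N)) {
    tl <- tiles[[n]]
    chn <- dimnames(tl)[[3]]
    miss <- setdiff(channels, chn)
    if (length(miss)) stop("tile missing channel(s): ", paste(miss, collapse = ", "))
    cols <- (n - 1L) * H * W + seq_len(H * W)
    for (ci in seq_along(channels))
      a[ci, cols] <- as.numeric(tl[, , match(channels[ci], chn)])
  }
  .act_geom(a, H, W, N)
}

#' Train a virtual-labelling model
#'
#' Trains on model-range-normalised tiles with the constant-then-linear-decay
#' learning-rate schedule. Every training tile must carry all input channels
#' and the target channel. Seeded runs are reproducible on one device.
#' Augmentation ([augment_flips()]) is applied here when `augment = TRUE`.
#'
#' @param tiles List of `H x W x C` arrays on the 8-bit scale with channel
#'   dimnames (e.g. `pb_patchset$tiles` subset).
#' @param config A `pb_model_config`.
#' @param val_tiles Optional held-out tiles; per-epoch validation L1 is
#'   recorded.
#' @param augment Apply 4x flip augmentation to the training tiles.
#' @param model Optionally a prebuilt (e.g. partially trained) model.
#' @return A trained `pb_unet`/`pb_cgan` with `$history` (one row per epoch:
#'   epoch, lr, train l1, val l1, and GAN losses for cgan).
#' @export
train_virtual_model <- function(tiles, config, val_tiles = NULL, augment = TRUE,
                                model = NULL) {
  stopifnot(inherits(config, "pb_model_config"))
  if (!length(tiles)) stop("no training tiles")
  for (tl in tiles)
    if (!(config$target_channel %in% dimnames(tl)[[3]]))
      stop("training tile missing target channel ", config$target_channel)
  if (augment) tiles <- augment_flips(tiles)
  model <- model %||% (if (config$arch == "cgan") build_cgan(config) else build_unet(config))
  set.seed(config$seed + 1L)

  xb_all <- .tiles_to_batch(tiles, config$input_channels)
  yb_all <- .tiles_to_batch(tiles, config$target_channel)
  xb_all$a <- to_model_range(xb_all$a * 1)  # 8-bit -> [-0.5, 0.5]
  yb_all$a <- to_model_range(yb_all$a * 1)
  HW <- xb_all$H * xb_all$W
  ntile <- length(tiles)
  epochs <- config$epochs_const + config$epochs_decay

  gen_state <- .adam_init(model$net)
  disc_state <- if (config$arch == "cgan") .adam_init(model$disc) else NULL
  hist <- NULL
  tstep <- 0L
  val_x <- val_y <- NULL
  if (!is.null(val_tiles) && length(val_tiles)) {
    val_x <- .tiles_to_batch(val_tiles, config$input_channels)
    val_y <- .tiles_to_batch(val_tiles, config$target_channel)
    val_x$a <- to_model_range(val_x$a); val_y$a <- to_model_range(val_y$a)
  }

  take <- function(geom, idx) {
    cols <- as.integer(outer(seq_len(HW), (idx - 1L) * HW, `+`))
    .act_geom(geom$a[, cols, drop = FALSE], geom$H, geom$W, length(idx))
  }

  for (ep in seq_len(epochs)) {
    lr <- .lr_at_epoch(ep - 1L, config$lr, config$epochs_const, config$epochs_decay)
    ord <- sample(ntile)
    nb <- ceiling(ntile / config$batch_size)
    ep_l1 <- 0; ep_gan_g <- 0; ep_gan_d <- 0; npx <- 0
    for (b in seq_len(nb)) {
      idx <- ord[((b - 1L) * config$batch_size + 1L):min(b * config$batch_size, ntile)]
      x <- take(xb_all, idx); y <- take(yb_all, idx)
      tstep <- tstep + 1L
      f <- .unet_fwd(model$net, x, training = TRUE)
      model$net <- f$net
      resid <- f$out$a - y$a
      ep_l1 <- ep_l1 + sum(abs(resid)); npx <- npx + length(resid)
      dout <- sign(resid) / length(resid)

      if (config$arch == "cgan") {
        # discriminator step on (x, y_real) vs (x, G(x))
        fake <- f$out$a
        dreal <- .disc_fwd(model$disc, .act_geom(rbind(x$a, y$a), x$H, x$W, x$N), training = TRUE)
        model$disc <- dreal$disc
        dfake <- .disc_fwd(model$disc, .act_geom(rbind(x$a, fake), x$H, x$W, x$N), training = TRUE)
        model$disc <- dfake$disc
        nsc <- length(dreal$out$a)
        d_loss <- 0.5 * (mean((dreal$out$a - 1)^2) + mean(dfake$out$a^2))
        gr_real <- .disc_bwd(model$disc, dreal, (dreal$out$a - 1) / nsc)
        gr_fake <- .disc_bwd(model$disc, dfake, dfake$out$a / nsc)
        dgr <- .sum_grads(gr_real$grads, gr_fake$grads)
        rd <- .adam_step(model$disc, dgr, disc_state, lr, tstep,
                         config$adam_beta1, config$adam_beta2)
        model$disc <- rd$p; disc_state <- rd$s
        # generator adversarial gradient through the (updated) discriminator
        dfake2 <- .disc_fwd(model$disc, .act_geom(rbind(x$a, fake), x$H, x$W, x$N), training = FALSE)
        nsc2 <- length(dfake2$out$a)
        g_gan <- mean((dfake2$out$a - 1)^2)
        gb <- .disc_bwd(model$disc, dfake2, 2 * (dfake2$out$a - 1) / nsc2)
        d_on_fake <- gb$dx[(length(config$input_channels) + 1L):nrow(gb$dx), , drop = FALSE]
        dout <- config$lambda_l1 * dout + config$lambda_lsgan * d_on_fake
        ep_gan_d <- ep_gan_d + d_loss; ep_gan_g <- ep_gan_g + g_gan
      }

      bw <- .unet_bwd(model$net, f, dout)
      rg <- .adam_step(model$net, bw$grads, gen_state, lr, tstep,
                       config$adam_beta1, config$adam_beta2)
      model$net <- rg$p; gen_state <- rg$s
    }
    val_l1 <- NA_real_
    if (!is.null(val_x)) {
      pv <- .unet_fwd(model$net, val_x, training = FALSE)
      val_l1 <- mean(abs(pv$out$a - val_y$a))
    }
    hist <- rbind(hist, data.frame(epoch = ep, lr = lr, l1 = ep_l1 / npx,
                                   val_l1 = val_l1,
                                   gan_g = if (config$arch == "cgan") ep_gan_g / nb else NA_real_,
                                   gan_d = if (config$arch == "cgan") ep_gan_d / nb else NA_real_))
  }
  model$trained <- TRUE
  model$history <- hist
  model
}

.sum_grads <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.numeric(a)) return(a + b)
  for (nm in names(a)) a[[nm]] <- .sum_grads(a[[nm]], b[[nm]])
  a
}

#' Predict a virtual channel
#'
#' Runs the generator in inference mode (dropout off, batch-norm running
#' statistics), inverts the model-range normalisation and returns rounded
#' 8-bit images the same spatial shape as the input tiles. Deterministic.
#'
#' @param model A trained `pb_vlmodel`.
#' @param tiles List of `H x W x C` arrays (8-bit scale) carrying at least
#'   the model's input channels.
#' @return List of 8-bit matrices, one per tile.
#' @export
predict_channel <- function(model, tiles) {
  stopifnot(inherits(model, "pb_vlmodel"))
  cfg <- model$config
  x <- .tiles_to_batch(tiles, cfg$input_channels)
  x$a <- to_model_range(x$a)
  f <- .unet_fwd(model$net, x, training = FALSE)
  HW <- x$H * x$W
  lapply(seq_len(x$N), function(n) {
    v <- f$out$a[1, (n - 1L) * HW + seq_len(HW)]
    matrix(from_model_range(v), x$H, x$W)
  })
}

#' @export
predict.pb_vlmodel <- function(object, newdata, ...) predict_channel(object, newdata)

#' Ground-truth pass-through stub model
#'
#' A stand-in "oracle" model for testing the integration orchestrator
#' independently of learning quality: its predictions are the processed
#' ground-truth tiles of the target channel, so a perfect integration adds
#' no distortion.
#'
#' @param target_channel Marker name.
#' @param lookup Function `(well, field, row0, col0, P) -> matrix` returning
#'   the ground-truth tile.
#' @return A `pb_stub_model`.
#' @export
stub_oracle_model <- function(target_channel, lookup) {
  structure(list(target_channel = target_channel, lookup = lookup, trained = TRUE),
            class = c("pb_stub_model"))
}
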