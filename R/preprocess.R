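## Image preprocessing chain, fixed order:
## background subtraction (label-free only) -> contrast enhancement
## (label-free only) -> dataset-level 8-bit scaling (fluorescence, per
## channel) -> half-resize (bilinear) -> patching -> flip augmentation ->
## model-range normalisation.

#' Preprocessing configuration
#'
#' @param dic_background `"median_subtract"` (rolling median, default) or
#'   `"gaussian_subtract"`.
#' @param median_kernel_px Median filter window in pixels (default 40).
#' @param gaussian_sigma Gaussian blur sigma for the alternative mode
#'   (default 0.5).
#' @param dic_saturate_frac Fraction of label-free pixels allowed to
#'   saturate during contrast enhancement (default 0.35, split half per tail).
#' @param fluor_outlier_frac Fraction of pooled fluorescence pixels treated
#'   as outliers per channel for 8-bit scaling (default 0.10 per tail pair;
#'   i.e. bottom and top 10%).
#' @param resize_factor Bilinear resize factor (default 0.5).
#' @param patch_size Square patch side after resizing (default 256).
#' @param denoiser Optional plugin: `NULL` (default) or a
#'   `function(img) -> img` applied to resized 8-bit images.
#' @return A `pb_preprocess_config` list.
#' @export
preprocess_config <- function(dic_background = c("median_subtract", "gaussian_subtract"),
                              median_kernel_px = 40L, gaussian_sigma = 0.5,
                              dic_saturate_frac = 0.35, fluor_outlier_frac = 0.10,
                              resize_factor = 0.5, patch_size = 256L,
                              denoiser = NULL) {
  dic_background <- match.arg(dic_background)
  if (dic_saturate_frac < 0 || dic_saturate_frac >= 1) stop("dic_saturate_frac must be in [0, 1)")
  if (fluor_outlier_frac < 0 || fluor_outlier_frac >= 0.5) stop("fluor_outlier_frac must be in [0, 0.5)")
  structure(list(dic_background = dic_background, median_kernel_px = as.integer(median_kernel_px),
                 gaussian_sigma = gaussian_sigma, dic_saturate_frac = dic_saturate_frac,
                 fluor_outlier_frac = fluor_outlier_frac, resize_factor = resize_factor,
                 patch_size = as.integer(patch_size), denoiser = denoiser),
            class = "pb_preprocess_config")
}

#' Background subtraction for label-free images
#'
#' Subtracts a smoothed version of the image (rolling median over a square
#' window, or Gaussian blur) and clips at zero.
#'
#' @param img Numeric matrix.
#' @param config A `pb_preprocess_config`.
#' @return Matrix of the same shape.
#' @export
subtract_background_dic <- function(img, config = preprocess_config()) {
  if (config$dic_background == "median_subtract") {
    k <- config$median_kernel_px
    if (k > min(dim(img))) stop("median kernel larger than image")
    bg <- .median_filter_cpp(img, k, k)
  } else {
    bg <- .gaussian_blur(img, config$gaussian_sigma)
  }
  pmax(img - bg, 0)
}

.gaussian_blur <- function(img, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  conv1 <- function(m) {
    n <- nrow(m)
    mp <- rbind(m[rep(1L, r), , drop = FALSE], m, m[rep(n, r), , drop = FALSE])
    out <- matrix(0, n, ncol(m))
    for (i in seq_along(k)) out <- out + k[i] * mp[i:(i + n - 1L), , drop = FALSE]
    out
  }
  t(conv1(t(conv1(img))))
}

#' Linear contrast enhancement with tail saturation
#'
#' Rescales intensities linearly so that a fraction `saturate_frac` of the
#' pixels lies at or beyond the output extremes, split equally between the
#' two tails (the Fiji enhance-contrast convention). The output spans the
#' input's full range.
#'
#' @param img Numeric matrix.
#' @param saturate_frac Total saturated fraction in `[0, 1)`.
#' @return Matrix of the same shape, clipped to the original range.
#' @export
enhance_contrast <- function(img, saturate_frac = 0.35) {
  rng <- range(img)
  if (rng[1] == rng[2]) {
    warning("constant image: contrast enhancement is a no-op")
    return(img)
  }
  qs <- stats::quantile(img, c(saturate_frac / 2, 1 - saturate_frac / 2), names = FALSE)
  if (qs[1] == qs[2]) return(img)
  out <- (img - qs[1]) / (qs[2] - qs[1]) * (rng[2] - rng[1]) + rng[1]
  pmin(pmax(out, rng[1]), rng[2])
}

#' Dataset-level 8-bit conversion of fluorescence images
#'
#' Pools the pixels of all images of one channel, treats the bottom and top
#' `outlier_frac` as outliers, and maps the remaining range linearly to
#' 0..255, saturating the outliers. Applied per channel: different markers
#' have incommensurate dynamic ranges.
#'
#' @param images List of numeric matrices (one channel across the dataset).
#' @param outlier_frac Per-tail outlier fraction (default 0.10).
#' @param params Optional precomputed `c(lo, hi)` (e.g. to apply a training
#'   scaling to held-out ground-truth images).
#' @return List of 8-bit (integer 0..255) matrices, with attribute
#'   `"scale_params"` = `c(lo, hi)`.
#' @export
scale_dataset_8bit <- function(images, outlier_frac = 0.10, params = NULL) {
  if (length(images) == 0L) stop("no images")
  if (is.null(params)) {
    pool <- unlist(lapply(images, as.numeric), use.names = FALSE)
    params <- stats::quantile(pool, c(outlier_frac, 1 - outlier_frac), names = FALSE)
  }
  if (params[1] >= params[2]) stop("degenerate channel: scaling percentiles coincide")
  out <- lapply(images, function(im) {
    v <- round(255 * (im - params[1]) / (params[2] - params[1]))
    matrix(pmin(pmax(v, 0), 255), nrow(im), ncol(im))
  })
  attr(out, "scale_params") <- params
  out
}

#' Bilinear resize
#'
#' @param img Numeric matrix.
#' @param factor Scale factor (0.5 halves each side).
#' @return Resized matrix.
#' @export
resize_bilinear <- function(img, factor = 0.5) {
  ho <- max(1L, round(nrow(img) * factor)); wo <- max(1L, round(ncol(img) * factor))
  # align-corners-false convention: sample at pixel centres
  sx <- (seq_len(ho) - 0.5) / factor + 0.5 - 1
  sy <- (seq_len(wo) - 0.5) / factor + 0.5 - 1
  x0 <- pmin(pmax(floor(sx), 0), nrow(img) - 1); x1 <- pmin(x0 + 1, nrow(img) - 1)
  y0 <- pmin(pmax(floor(sy), 0), ncol(img) - 1); y1 <- pmin(y0 + 1, ncol(img) - 1)
  fx <- pmin(pmax(sx - x0, 0), 1); fy <- pmin(pmax(sy - y0, 0), 1)
  a <- img[x0 + 1, y0 + 1, drop = FALSE] * outer(1 - fx, 1 - fy)
  b <- img[x1 + 1, y0 + 1, drop = FALSE] * outer(fx, 1 - fy)
  cc <- img[x0 + 1, y1 + 1, drop = FALSE] * outer(1 - fx, fy)
  d <- img[x1 + 1, y1 + 1, drop = FALSE] * outer(fx, fy)
  a + b + cc + d
}

#' Resize all channels of a field and cut non-overlapping patches
#'
#' Applies the identical bilinear resize and tiling to every channel:
#' non-overlapping `patch_size` tiles from the origin, partial remainders
#' dropped, so tile count is `floor(H'/P) * floor(W'/P)`.
#'
#' @param field Named list of equally-shaped matrices (one per channel).
#' @param config A `pb_preprocess_config`.
#' @return List with `tiles` (list of `H x W x C` arrays, channels in input
#'   order) and `meta` (data.frame of 0-based tile origins `row0`, `col0`).
#' @export
resize_and_patch <- function(field, config = preprocess_config()) {
  shp <- vapply(field, function(x) paste(dim(x), collapse = "x"), "")
  if (length(unique(shp)) != 1L) stop("channels differ in shape")
  res <- lapply(field, resize_bilinear, factor = config$resize_factor)
  P <- config$patch_size
  H <- nrow(res[[1]]); W <- ncol(res[[1]])
  nr <- H %/% P; nc <- W %/% P
  if (nr == 0L || nc == 0L) {
    warning("resized field smaller than patch size: 0 tiles")
    return(list(tiles = list(), meta = data.frame(row0 = integer(), col0 = integer())))
  }
  tiles <- list(); row0 <- integer(); col0 <- integer()
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    r0 <- (i - 1L) * P; c0 <- (j - 1L) * P
    arr <- array(0, dim = c(P, P, length(res)), dimnames = list(NULL, NULL, names(field)))
    for (ci in seq_along(res)) arr[, , ci] <- res[[ci]][(r0 + 1L):(r0 + P), (c0 + 1L):(c0 + P)]
    tiles[[length(tiles) + 1L]] <- arr
    row0 <- c(row0, r0); col0 <- c(col0, c0)
  }
  list(tiles = tiles, meta = data.frame(row0 = row0, col0 = col0))
}

#' Four-fold flip augmentation
#'
#' Emits `{identity, horizontal flip, vertical flip, both}` of every tile
#' (all channels flipped jointly), exactly quadrupling the tile count; no
#' deduplication of symmetric tiles.
#'
#' @param tiles List of `H x W x C` arrays.
#' @return List of `4 * length(tiles)` arrays, input order preserved within
#'   each flip group.
#' @export
augment_flips <- function(tiles) {
  flip_h <- function(a) a[, rev(seq_len(dim(a)[2])), , drop = FALSE]
  flip_v <- function(a) a[rev(seq_len(dim(a)[1])), , , drop = FALSE]
  out <- vector("list", 4L * length(tiles))
  for (i in seq_along(tiles)) {
    a <- tiles[[i]]
    out[[(i - 1L) * 4L + 1L]] <- a
    out[[(i - 1L) * 4L + 2L]] <- flip_h(a)
    out[[(i - 1L) * 4L + 3L]] <- flip_v(a)
    out[[(i - 1L) * 4L + 4L]] <- flip_v(flip_h(a))
  }
  out
}

#' Model-domain normalisation
#'
#' Maps 8-bit intensities to the model range `[-0.5, 0.5]` via
#' `x/255 - 0.5`; the inverse clips to `[-0.5, 0.5]` first (the generator's
#' tanh can emit values in `[-1, 1]`) and maps back to rounded 8-bit.
#'
#' @param img Numeric matrix/array on the 0..255 scale.
#' @return Same shape on the model scale.
#' @export
to_model_range <- function(img) img / 255 - 0.5

#' @rdname to_model_range
#' @param x Numeric matrix/array on the model scale.
#' @export
from_model_range <- function(x) round((pmin(pmax(x, -0.5), 0.5) + 0.5) * 255)

#' Preprocess a whole dataset into a patch set
#'
#' Runs the full chain on every field of the manifest. Label-free images get
#' background subtraction, contrast enhancement and per-image min-max 8-bit
#' conversion; fluorescence channels get dataset-level per-channel 8-bit
#' scaling (percentiles pooled over the wells where the channel was
#' experimentally labelled). All channels are then half-resized and cut into
#' patches. When `gt_markers = TRUE` (synthetic datasets) the held-out
#' ground-truth variable channels are processed with the *same* per-channel
#' scale parameters, for evaluation only.
#'
#' @param manifest A `pb_manifest`.
#' @param config A `pb_preprocess_config`.
#' @param gt_markers Process held-out ground-truth marker images under
#'   `<root>/gt/` as well.
#' @return A `pb_patchset`: `tiles` (list of `P x P x C` arrays),
#'   `meta` (data.frame: well, field, condition, tile origins, fold),
#'   `fields` (processed full-size channel stacks per field),
#'   `gt_fields` (processed ground-truth marker stacks, if requested),
#'   `channels`, `scale_params`.
#' @export
preprocess_dataset <- function(manifest, config = preprocess_config(), gt_markers = FALSE) {
  ch <- manifest$channels
  lf <- ch$name[ch$role == "label_free"]
  fluor <- ch$name[ch$role != "label_free"]

  # read everything once
  fields <- list()
  for (w in manifest$wells) for (f in w$fields) {
    key <- paste(w$well_id, f$field_id, sep = "/")
    fields[[key]] <- list(well = w$well_id, field = f$field_id, condition = w$condition,
                          imgs = read_field(manifest, w$well_id, f$field_id))
  }

  # per-channel pooled scaling over the wells that carry the channel
  scale_params <- list()
  proc <- lapply(fields, function(fd) fd$imgs)
  for (cn in fluor) {
    keys <- names(fields)[vapply(fields, function(fd) cn %in% names(fd$imgs), TRUE)]
    if (!length(keys)) next
    scaled <- scale_dataset_8bit(lapply(keys, function(k) fields[[k]]$imgs[[cn]]),
                                 outlier_frac = config$fluor_outlier_frac)
    scale_params[[cn]] <- attr(scaled, "scale_params")
    for (i in seq_along(keys)) proc[[keys[i]]][[cn]] <- scaled[[i]]
  }
  for (key in names(proc)) {
    for (cn in lf) {
      x <- subtract_background_dic(proc[[key]][[cn]], config)
      x <- enhance_contrast(x, config$dic_saturate_frac)
      rng <- range(x)
      proc[[key]][[cn]] <- if (rng[1] == rng[2]) matrix(0, nrow(x), ncol(x))
                           else matrix(round(255 * (x - rng[1]) / (rng[2] - rng[1])), nrow(x), ncol(x))
    }
  }

  tiles <- list(); meta <- NULL
  proc_fields <- list()
  for (key in names(proc)) {
    fd <- fields[[key]]
    rp <- resize_and_patch(proc[[key]], config)
    rp$tiles <- lapply(rp$tiles, function(a) {
      if (!is.null(config$denoiser)) for (ci in seq_len(dim(a)[3])) a[, , ci] <- config$denoiser(a[, , ci])
      a
    })
    proc_fields[[key]] <- lapply(proc[[key]], function(m) round(resize_bilinear(m, config$resize_factor)))
    if (length(rp$tiles)) {
      md <- data.frame(key = key, well = fd$well, field = fd$field, condition = fd$condition,
                       row0 = rp$meta$row0, col0 = rp$meta$col0, fold = NA_integer_,
                       stringsAsFactors = FALSE)
      meta <- rbind(meta, md)
      tiles <- c(tiles, rp$tiles)
    }
  }

  gt_fields <- NULL
  if (gt_markers) {
    vars <- ch$name[ch$role == "variable"]
    gt_fields <- list()
    for (key in names(fields)) {
      fd <- fields[[key]]
      p <- file.path(manifest$root, sprintf("gt/%s_%s_markers.tif", fd$well, fd$field))
      if (!file.exists(p)) stop("missing ground-truth marker stack: ", p)
      gimgs <- read_field_tiff(p)
      names(gimgs) <- vars
      gproc <- list()
      for (cn in vars) {
        sp <- scale_params[[cn]]
        g8 <- scale_dataset_8bit(list(gimgs[[cn]]), params = sp)[[1]]
        gproc[[cn]] <- round(resize_bilinear(g8, config$resize_factor))
      }
      gt_fields[[key]] <- gproc
    }
  }

  structure(list(tiles = tiles, meta = meta, fields = proc_fields, gt_fields = gt_fields,
                 channels = ch, scale_params = scale_params, config = config),
            class = "pb_patchset")
}

#' @export
print.pb_patchset <- function(x, ...) {
  cat(sprintf("<pb_patchset> %d tiles (%dx%d) from %d fields, %d channels\n",
              length(x$tiles), x$config$patch_size, x$config$patch_size,
              length(x$fields), nrow(x$channels)))
  invisible(x)
}
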