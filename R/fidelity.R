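## Image- and feature-level fidelity metrics comparing virtual to real
## channels, plus the significance test used throughout (Welch's two-sided
## t-test, unequal variances).

#' Structural similarity index (SSIM)
#'
#' Mean local SSIM over sliding uniform windows (default 7x7), standard
#' luminance * contrast * structure form with stabilising constants
#' `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2` for dynamic range `L = 255`.
#'
#' @param a,b Equally-shaped matrices on the 8-bit scale.
#' @param window Odd window side, >= 3 (default 7).
#' @param dynamic_range Intensity range `L` (default 255).
#' @return SSIM score (<= 1; 1 iff identical).
#' @export
ssim <- function(a, b, window = 7L, dynamic_range = 255) {
  if (!all(dim(a) == dim(b))) stop("shape mismatch")
  if (window %% 2L != 1L || window < 3L) stop("window must be odd and >= 3")
  if (any(dim(a) < window)) stop("image smaller than SSIM window")
  C1 <- (0.01 * dynamic_range)^2
  C2 <- (0.03 * dynamic_range)^2
  box <- function(m) .box_valid(m, window)
  mu_a <- box(a); mu_b <- box(b)
  va <- box(a * a) - mu_a^2
  vb <- box(b * b) - mu_b^2
  cab <- box(a * b) - mu_a * mu_b
  s <- ((2 * mu_a * mu_b + C1) * (2 * cab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
  mean(s)
}

# running mean over valid k x k windows via integral image
.box_valid <- function(m, k) {
  H <- nrow(m); W <- ncol(m)
  ii <- matrix(0, H + 1, W + 1)
  ii[-1, -1] <- t(apply(apply(m, 2, cumsum), 1, cumsum))
  Ho <- H - k + 1L; Wo <- W - k + 1L
  r1 <- 1:Ho; c1 <- 1:Wo
  (ii[r1 + k, c1 + k, drop = FALSE] - ii[r1, c1 + k, drop = FALSE] -
      ii[r1 + k, c1, drop = FALSE] + ii[r1, c1, drop = FALSE]) / (k * k)
}

#' Pixel-level Pearson correlation
#'
#' @param a,b Equally-shaped matrices.
#' @return PCC over all pixel pairs; `NA` if either image is constant.
#' @export
pixel_pcc <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("shape mismatch")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(as.numeric(a), as.numeric(b))
}

#' Feature-level Pearson correlation
#'
#' Correlation across cells of one feature measured from experimentally and
#' virtually labelled channels; tables must be row-aligned on cell id.
#'
#' @param real,virtual Data frames with a `cell` column and the feature.
#' @param feature Feature column name.
#' @return PCC across cells.
#' @export
feature_pcc <- function(real, virtual, feature) {
  if (nrow(real) != nrow(virtual) || !all(real$cell == virtual$cell))
    stop("tables are not row-aligned on cell id")
  if (nrow(real) < 3) stop("need >= 3 cells")
  stats::cor(real[[feature]], virtual[[feature]])
}

#' Welch's two-sided t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom.
#'
#' @param x,y Numeric samples (length >= 2 each).
#' @return List with `t`, `df`, `p`.
#' @export
welch_ttest <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("need >= 2 observations per sample")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) stop("zero variance in both samples")
  ht <- stats::t.test(x, y, var.equal = FALSE, alternative = "two.sided")
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Real-vs-virtual intensity distribution report
#'
#' Density-normalised histograms of per-cell mean intensities and the
#' Kolmogorov-Smirnov distance between the real and virtual distributions,
#' per marker and condition.
#'
#' @param real,virtual Numeric vectors of per-cell mean intensities.
#' @param breaks Histogram breaks (default 30 bins over the joint range).
#' @return List with `breaks`, `density_real`, `density_virtual`, `ks`.
#' @export
intensity_distribution_report <- function(real, virtual, breaks = 30L) {
  rng <- range(c(real, virtual))
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  brk <- seq(rng[1], rng[2], length.out = breaks + 1L)
  hr <- graphics::hist(real, breaks = brk, plot = FALSE)
  hv <- graphics::hist(virtual, breaks = brk, plot = FALSE)
  ks <- suppressWarnings(stats::ks.test(real, virtual)$statistic)
  list(breaks = brk, density_real = hr$density, density_virtual = hv$density,
       ks = unname(ks))
}

#' Image-level fidelity of an integration run
#'
#' For every field and marker, compares the reassembled virtual channel with
#' the held-out processed ground-truth channel: SSIM and Pixel-PCC per
#' field, aggregated by median per marker x fold and per marker.
#'
#' @param integrated A `pb_integrated`.
#' @param patchset The `pb_patchset` with `gt_fields`.
#' @param window SSIM window.
#' @return List with `per_field` (data.frame) and `per_marker` (median
#'   over per-fold medians, mirroring median-across-folds reporting).
#' @export
evaluate_integration <- function(integrated, patchset, window = 7L) {
  gt <- patchset$gt_fields
  if (is.null(gt)) stop("patchset lacks ground-truth fields")
  rows <- NULL
  folds <- integrated$folds
  for (key in names(integrated$fields)) {
    fold <- folds$fold[folds$key == key]
    for (v in names(integrated$plan$markers)) {
      vc <- integrated$fields[[key]][[v]]
      gc <- gt[[key]][[v]]
      ok <- !is.na(vc)
      if (!any(ok)) next
      vv <- vc; vv[!ok] <- 0; gg <- gc; gg[!ok] <- 0
      rows <- rbind(rows, data.frame(
        key = key, marker = v, fold = fold,
        ssim = ssim(vv, gg, window = window),
        pcc = pixel_pcc(vc[ok], gc[ok]),
        stringsAsFactors = FALSE))
    }
  }
  fold_med <- stats::aggregate(cbind(ssim, pcc) ~ marker + fold, rows, stats::median)
  marker_med <- stats::aggregate(cbind(ssim, pcc) ~ marker, fold_med, stats::median)
  list(per_field = rows, per_fold = fold_med, per_marker = marker_med)
}
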