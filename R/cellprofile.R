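## Native single-cell segmentation and CellProfiler-convention features:
## 17 morphology/neighbourhood features, 142 per marker (15 intensity + 75
## radial distribution (3 statistics x 25 annuli) + 52 texture (13 Haralick
## statistics x 4 directions)), and pairwise per-cell colocalisation PCC.
## Convention-compatible with CellProfiler, not bit-compatible.

#' Segment cells from DNA and actin channels
#'
#' Nuclei by Otsu thresholding + connected-component labelling of the DNA
#' channel; cell bodies by seeded propagation on the actin channel
#' (marker-controlled watershed, CellProfiler's secondary-object
#' convention); objects in contact with the image border are excluded to
#' remove partial cells. Deterministic. External label masks can be
#' injected through `masks`.
#'
#' @param dna,actin 8-bit matrices (0..255).
#' @param min_nucleus_area Nuclei smaller than this are discarded.
#' @param masks Optional externally computed list(cells, nuclei) of label
#'   matrices (e.g. from another segmentation tool); border exclusion and
#'   relabelling are still applied.
#' @return A `pb_segmentation`: `cells`/`nuclei` label masks (1..K,
#'   border-excluded), `all_cells` pre-exclusion labels (for neighbourhood
#'   features), `n_cells`, `excluded` original ids dropped at the border.
#' @export
segment_cells <- function(dna, actin, min_nucleus_area = 5L, masks = NULL) {
  if (is.null(masks)) {
    d <- dna / 255
    thr <- tryCatch(EBImage::otsu(EBImage::Image(d)), error = function(e) 0.5)
    nm <- d > thr
    nlab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(nm)))
    if (max(nlab) > 0) {
      sizes <- tabulate(nlab[nlab > 0], nbins = max(nlab))
      drop <- which(sizes < min_nucleus_area)
      if (length(drop)) nlab[nlab %in% drop] <- 0L
    }
    if (max(nlab) == 0) {
      z <- matrix(0L, nrow(dna), ncol(dna))
      return(structure(list(cells = z, nuclei = z, all_cells = z, all_nuclei = z,
                            n_cells = 0L, excluded = integer()),
                       class = "pb_segmentation"))
    }
    a <- actin / 255
    athr <- tryCatch(EBImage::otsu(EBImage::Image(a)), error = function(e) 0.5)
    fg <- a > (0.5 * athr) | nlab > 0
    clab <- EBImage::imageData(EBImage::propagate(EBImage::Image(a), EBImage::Image(nlab),
                                                  mask = fg, lambda = 1e-4))
  } else {
    clab <- masks$cells; nlab <- masks$nuclei
  }
  clab <- matrix(as.integer(round(clab)), nrow(dna), ncol(dna))
  nlab <- matrix(as.integer(round(nlab)), nrow(dna), ncol(dna))
  H <- nrow(clab); W <- ncol(clab)
  border_ids <- unique(c(clab[1, ], clab[H, ], clab[, 1], clab[, W]))
  border_ids <- border_ids[border_ids > 0]
  keep <- setdiff(sort(unique(clab[clab > 0])), border_ids)
  remap <- integer(max(clab, 1L))
  remap[keep] <- seq_along(keep)
  cells <- matrix(0L, H, W); nuclei <- matrix(0L, H, W)
  pos <- clab > 0 & clab %in% keep
  cells[pos] <- remap[clab[pos]]
  npos <- nlab > 0 & nlab %in% keep
  nuclei[npos] <- remap[nlab[npos]]
  structure(list(cells = cells, nuclei = nuclei, all_cells = clab, all_nuclei = nlab,
                 n_cells = length(keep), excluded = border_ids),
            class = "pb_segmentation")
}

#' @export
print.pb_segmentation <- function(x, ...) {
  cat(sprintf("<pb_segmentation> %d cells retained (%d border-excluded)\n",
              x$n_cells, length(x$excluded)))
  invisible(x)
}

# exposed 4-connected boundary of a label mask, per pixel
.boundary_of <- function(lab) {
  H <- nrow(lab); W <- ncol(lab)
  up <- rbind(lab[1, ], lab[-H, ]); dn <- rbind(lab[-1, ], lab[H, ])
  lf <- cbind(lab[, 1], lab[, -W]); rt <- cbind(lab[, -1], lab[, W])
  lab > 0 & (up != lab | dn != lab | lf != lab | rt != lab |
               row(lab) == 1 | row(lab) == H | col(lab) == 1 | col(lab) == W)
}

.perimeter_of <- function(lab, id_px) {
  # number of exposed 4-edges of the pixel set (border edges count); callers
  # scale by pi/4, the isotropic city-block -> Euclidean boundary correction
  H <- attr(id_px, "H"); W <- attr(id_px, "W")
  inset <- logical(H * W); inset[id_px] <- TRUE
  r <- (id_px - 1L) %% H + 1L; cc <- (id_px - 1L) %/% H + 1L
  nb <- 0L
  nb <- nb + sum(r == 1 | !inset[pmax(id_px - 1L, 1L)])
  nb <- nb + sum(r == H | !inset[pmin(id_px + 1L, H * W)])
  nb <- nb + sum(cc == 1 | !inset[pmax(id_px - H, 1L)])
  nb <- nb + sum(cc == W | !inset[pmin(id_px + H, H * W)])
  nb
}

.haralick13 <- function(P) {
  tot <- sum(P)
  out <- numeric(13)
  if (tot <= 0) return(out)
  P <- P / tot
  N <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(seq_len(N) * px); muy <- sum(seq_len(N) * py)
  sx <- sqrt(sum((seq_len(N) - mux)^2 * px)); sy <- sqrt(sum((seq_len(N) - muy)^2 * py))
  plog <- function(p) ifelse(p > 0, log(p), 0)
  out[1] <- sum(P^2)                                   # angular second moment
  out[2] <- sum((i - j)^2 * P)                         # contrast
  out[3] <- if (sx > 0 && sy > 0) (sum(i * j * P) - mux * muy) / (sx * sy) else 0
  out[4] <- sum((i - mux)^2 * P)                       # variance
  out[5] <- sum(P / (1 + (i - j)^2))                   # inverse difference moment
  psum <- tapply(as.numeric(P), as.numeric(i + j), sum) # k = 2..2N
  ks <- as.numeric(names(psum))
  out[6] <- sum(ks * psum)                             # sum average
  out[7] <- sum((ks - out[6])^2 * psum)                # sum variance
  out[8] <- -sum(psum * plog(psum))                    # sum entropy
  out[9] <- -sum(P * plog(P))                          # entropy
  pdiff <- tapply(as.numeric(P), as.numeric(abs(i - j)), sum) # k = 0..N-1
  kd <- as.numeric(names(pdiff))
  mud <- sum(kd * pdiff)
  out[10] <- sum((kd - mud)^2 * pdiff)                 # difference variance
  out[11] <- -sum(pdiff * plog(pdiff))                 # difference entropy
  hx <- -sum(px * plog(px)); hy <- -sum(py * plog(py))
  pxy <- outer(px, py)
  hxy1 <- -sum(P * plog(pxy))
  hxy2 <- -sum(pxy * plog(pxy))
  out[12] <- if (max(hx, hy) > 0) (out[9] - hxy1) / max(hx, hy) else 0
  out[13] <- sqrt(pmax(1 - exp(-2 * (hxy2 - out[9])), 0))
  out
}

.tex_dirs <- list(d0 = c(0L, 1L), d45 = c(1L, 1L), d90 = c(1L, 0L), d135 = c(1L, -1L))

#' Per-cell colocalisation (Pearson over in-cell pixels)
#'
#' @param seg A `pb_segmentation`.
#' @param a,b Channel matrices.
#' @return Numeric vector, one PCC per retained cell; `NA` where a channel
#'   has zero variance inside the cell.
#' @export
cell_coloc_pcc <- function(seg, a, b) {
  K <- seg$n_cells
  out <- rep(NA_real_, K)
  if (K == 0) return(out)
  idx <- split(seq_along(seg$cells), factor(seg$cells, levels = 0:K))[-1]
  for (k in seq_len(K)) {
    va <- a[idx[[k]]]; vb <- b[idx[[k]]]
    if (stats::sd(va) > 0 && stats::sd(vb) > 0) out[k] <- stats::cor(va, vb)
  }
  out
}

#' The frozen feature schema
#'
#' Column names, in order, of the table produced by [extract_features()]
#' for a given marker set: identifiers, 17 morphology/neighbourhood
#' features, 142 features per marker, then pairwise colocalisation.
#'
#' @param markers Character vector of channel names measured per cell.
#' @return Character vector of column names.
#' @export
feature_schema <- function(markers) {
  morph <- c("Area", "Perimeter", "FormFactor", "Eccentricity", "Solidity",
             "Extent", "MajorAxisLength", "MinorAxisLength", "AspectRatio",
             "ConvexArea", "EquivalentDiameter", "Orientation",
             "NeighborCount", "PercentTouching", "NearestNeighborDistance",
             "MeanNeighborDistance", "NucleusAreaRatio")
  intens <- c("IntegratedIntensity", "MeanIntensity", "StdIntensity",
              "MinIntensity", "MaxIntensity", "IntegratedIntensityEdge",
              "MeanIntensityEdge", "StdIntensityEdge", "MinIntensityEdge",
              "MaxIntensityEdge", "MassDisplacement", "LowerQuartileIntensity",
              "MedianIntensity", "MADIntensity", "UpperQuartileIntensity")
  rad <- c(paste0("FracAtD_", sprintf("%02d", 1:25)),
           paste0("MeanFrac_", sprintf("%02d", 1:25)),
           paste0("RadialCV_", sprintf("%02d", 1:25)))
  tex <- as.vector(outer(sprintf("Haralick%02d", 1:13), names(.tex_dirs),
                         paste, sep = "_"))
  per_marker <- unlist(lapply(markers, function(m)
    paste(m, c(paste0("Int_", intens), paste0("Rad_", rad), paste0("Tex_", tex)),
          sep = "_")))
  coloc <- character()
  if (length(markers) > 1) {
    cmb <- utils::combn(markers, 2)
    coloc <- paste0("Coloc_", cmb[1, ], "_", cmb[2, ])
  }
  c("cell", "cx", "cy", paste0("Morph_", morph), per_marker, coloc)
}

#' Extract single-cell features
#'
#' Computes the full CellProfiler-convention feature block for every
#' retained cell: 17 morphology/neighbourhood features (neighbourhood
#' computed on the full field before border exclusion so border cells still
#' count as neighbours), per channel 15 intensity + 75 radial distribution
#' + 52 Haralick texture features (8-level global quantisation), and
#' pairwise colocalisation PCC. Intensities are measured on the 0..1 scale
#' (8-bit / 255). Cells smaller than `min_area` pixels are dropped.
#'
#' @param seg A `pb_segmentation`.
#' @param channels Named list of 8-bit matrices.
#' @param min_area Minimum cell area in pixels (default 9).
#' @return Data frame, one row per retained cell, columns per
#'   [feature_schema()].
#' @export
extract_features <- function(seg, channels, min_area = 9L) {
  K <- seg$n_cells
  markers <- names(channels)
  schema <- feature_schema(markers)
  if (K == 0) {
    out <- as.data.frame(matrix(numeric(0), 0, length(schema)))
    names(out) <- schema
    return(out)
  }
  H <- nrow(seg$cells); W <- ncol(seg$cells)
  idx_all <- split(seq_along(seg$cells), factor(seg$cells, levels = 0:K))[-1]
  areas <- lengths(idx_all)
  keep <- which(areas >= min_area)

  # --- neighbourhood on the pre-exclusion mask -------------------------
  lab0 <- seg$all_cells
  ids0 <- sort(unique(lab0[lab0 > 0]))
  cent0 <- t(vapply(split(seq_along(lab0), factor(lab0, levels = c(0, ids0)))[-1],
                    function(ii) c(mean((ii - 1) %% H + 1), mean((ii - 1) %/% H + 1)),
                    numeric(2)))
  shift_lab <- function(m, dr, dc) {
    out <- matrix(0L, H, W)
    rs <- max(1, 1 + dr):min(H, H + dr); cs <- max(1, 1 + dc):min(W, W + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  touch_neighbor <- matrix(FALSE, H, W)  # pixel has a different nonzero label within Chebyshev 2
  pairs <- NULL
  for (dr in -2:2) for (dc in -2:2) {
    if (dr == 0 && dc == 0) next
    sh <- shift_lab(lab0, dr, dc)
    hit <- lab0 > 0 & sh > 0 & sh != lab0
    touch_neighbor <- touch_neighbor | hit
    if (any(hit)) pairs <- rbind(pairs, unique(cbind(lab0[hit], sh[hit])))
  }
  nb_of <- function(id) if (is.null(pairs)) integer() else unique(pairs[pairs[, 1] == id, 2])
  bnd0 <- .boundary_of(lab0)
  # map retained ids back to original labels
  orig_of <- integer(K)
  for (id in ids0) {
    pick <- seg$cells[match(TRUE, lab0 == id & seg$cells > 0)]
    if (!is.na(pick) && pick > 0) orig_of[pick] <- id
  }

  rows <- vector("list", length(keep))
  bnd_retained <- .boundary_of(seg$cells)
  ri <- 0L
  for (k in keep) {
    ri <- ri + 1L
    ii <- idx_all[[k]]
    r <- (ii - 1) %% H + 1; cc <- (ii - 1) %/% H + 1
    A <- length(ii)
    cx <- mean(r); cy <- mean(cc)
    attr(ii, "H") <- H; attr(ii, "W") <- W
    perim <- .perimeter_of(seg$cells, ii) * pi / 4
    mu20 <- mean((r - cx)^2); mu02 <- mean((cc - cy)^2); mu11 <- mean((r - cx) * (cc - cy))
    tr2 <- (mu20 + mu02) / 2; det_rt <- sqrt(pmax(((mu20 - mu02) / 2)^2 + mu11^2, 0))
    l1 <- tr2 + det_rt; l2 <- pmax(tr2 - det_rt, 0)
    major <- 4 * sqrt(l1); minor <- 4 * sqrt(l2)
    ecc <- if (l1 > 0) sqrt(pmax(1 - l2 / l1, 0)) else 0
    orient <- 0.5 * atan2(2 * mu11, mu20 - mu02)
    hull <- grDevices::chull(r, cc)
    hx <- r[hull]; hy <- cc[hull]
    sh_area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
    hull_per <- sum(sqrt(diff(c(hx, hx[1]))^2 + diff(c(hy, hy[1]))^2))
    convex_area <- max(sh_area + hull_per / 2 + 1, A)  # lattice-polygon pixel count
    bbox_area <- (max(r) - min(r) + 1) * (max(cc) - min(cc) + 1)
    oid <- orig_of[k]
    nbs <- nb_of(oid)
    bpx <- ii[bnd_retained[ii]]
    pct_touch <- if (length(bpx)) 100 * sum(touch_neighbor[bpx]) / length(bpx) else 0
    dists <- if (nrow(cent0) > 1) sqrt((cent0[, 1] - cx)^2 + (cent0[, 2] - cy)^2) else numeric()
    dists <- dists[ids0 != oid]
    nnd <- if (length(dists)) min(dists) else sqrt(H^2 + W^2)
    mnd <- if (length(nbs)) {
      nb_rows <- match(nbs, ids0)
      mean(sqrt((cent0[nb_rows, 1] - cx)^2 + (cent0[nb_rows, 2] - cy)^2))
    } else nnd
    nuc_area <- sum(seg$nuclei[ii] == k)
    morph <- c(A, perim, 4 * pi * A / perim^2, ecc,
               min(A / convex_area, 1), A / bbox_area, major, minor,
               if (minor > 0) major / minor else 1,
               convex_area, sqrt(4 * A / pi), orient,
               length(nbs), pct_touch, nnd, mnd, nuc_area / A)

    # per-marker blocks
    d <- sqrt((r - cx)^2 + (cc - cy)^2)
    dmax <- max(d, 1e-9)
    ring <- pmin(pmax(ceiling(25 * d / dmax), 1L), 25L)
    wedge <- pmin(floor((atan2(cc - cy, r - cx) + pi) / (2 * pi) * 8), 7L) + 1L
    npix_ring <- tabulate(ring, 25)
    edge_ii <- bpx
    blocks <- numeric(0)
    vals <- lapply(channels, function(ch) ch[ii] / 255)
    for (m in markers) {
      v <- vals[[m]]
      ve <- channels[[m]][edge_ii] / 255
      tot <- sum(v)
      icx <- if (tot > 0) sum(r * v) / tot else cx
      icy <- if (tot > 0) sum(cc * v) / tot else cy
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      intens <- c(tot, mean(v), stats::sd(v), min(v), max(v),
                  sum(ve), if (length(ve)) mean(ve) else 0,
                  if (length(ve) > 1) stats::sd(ve) else 0,
                  if (length(ve)) min(ve) else 0, if (length(ve)) max(ve) else 0,
                  sqrt((icx - cx)^2 + (icy - cy)^2),
                  q[1], q[2], stats::mad(v, constant = 1), q[3])
      isum <- vapply(1:25, function(b) sum(v[ring == b]), 0)
      frac <- if (tot > 0) isum / tot else rep(0, 25)
      meanfrac <- ifelse(npix_ring > 0, frac / (npix_ring / A), 0)
      radcv <- vapply(1:25, function(b) {
        inb <- ring == b
        if (!any(inb)) return(0)
        wm <- tapply(v[inb], wedge[inb], mean)
        if (length(wm) < 2 || mean(wm) == 0) return(0)
        stats::sd(wm) / mean(wm)
      }, 0)
      qv <- pmin(channels[[m]][ii] %/% 32L, 7L) + 1L
      sub <- matrix(0L, max(r) - min(r) + 1, max(cc) - min(cc) + 1)
      sub[cbind(r - min(r) + 1, cc - min(cc) + 1)] <- qv
      # direction-major to match the schema (13 statistics per direction)
      tex <- unlist(lapply(.tex_dirs, function(dd)
        .haralick13(.glcm_cpp(sub, 8L, dd[1], dd[2]))), use.names = FALSE)
      blocks <- c(blocks, intens, frac, meanfrac, radcv, tex)
    }
    coloc <- numeric(0)
    if (length(markers) > 1) {
      cmb <- utils::combn(markers, 2)
      coloc <- vapply(seq_len(ncol(cmb)), function(p) {
        va <- vals[[cmb[1, p]]]; vb <- vals[[cmb[2, p]]]
        if (stats::sd(va) > 0 && stats::sd(vb) > 0) stats::cor(va, vb) else NA_real_
      }, 0)
    }
    rows[[ri]] <- c(k, cx, cy, morph, blocks, coloc)
  }
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- schema
  # degenerate cells (any non-finite morphology/marker value) are dropped
  core <- out[, !grepl("^Coloc_", names(out)), drop = FALSE]
  ok <- apply(core, 1, function(z) all(is.finite(z)))
  if (any(!ok))
    message(sum(!ok), " degenerate cell(s) dropped during feature extraction")
  out[ok, , drop = FALSE]
}
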