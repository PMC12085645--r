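## Synthetic multi-well dataset generator with known ground truth.
##
## Emulates an epithelial-mesenchymal (EM) plasticity screen imaged with an
## extensible panel design: every well carries a label-free relief channel
## (DIC), three anchoring fluorescence markers (DNA, F-actin, a junctional
## beta-catenin-like marker) and exactly one variable EM-state marker.
## Each cell has a latent EM state s in [0,1] drawn from a per-condition
## Beta distribution; anchors encode s through morphology (area, protrusions)
## and junctional relocalisation (membrane at s=0, diffuse at s=1); variable
## markers are monotone logistic functions of s with cell-level lognormal and
## pixel-level Gaussian + Poisson-like noise. Ground truth (latent states,
## label masks, every variable channel in every well) is emitted alongside,
## held out for evaluation only.

.default_marker_specs <- function() {
  data.frame(
    name = c("Ecad", "EpCAM", "CD44v9", "PTEN", "Ncad", "Vim", "CD44t", "CD44s"),
    direction = c(-1, -1, -1, -1, 1, 1, 1, 1),
    midpoint = c(0.45, 0.50, 0.55, 0.50, 0.55, 0.60, 0.50, 0.45),
    slope = c(8, 7, 7, 5, 8, 7, 5, 6),
    localisation = c("membrane", "membrane", "membrane", "cytoplasmic",
                     "membrane", "cytoplasmic", "membrane", "membrane"),
    lo = 0.10, hi = 0.85, sigma_cell = 0.12,
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Builds and validates the configuration for [simulate_dataset()]. The
#' defaults describe a three-condition EM-modulation experiment (control,
#' EGF-like weak induction, TGF-beta-like strong induction) with eight
#' variable-marker panels and one well per condition per panel (24 wells).
#'
#' @param seed Integer master seed; one RNG stream per well is derived from
#'   `(seed, well)` so wells are independently reproducible.
#' @param conditions Named list of Beta parameters `c(a, b)` for the latent
#'   state distribution of each condition, ordered by increasing mean state.
#' @param n_panels Number of variable markers (panels), taken from the head
#'   of `marker_specs`.
#' @param wells_per_condition_per_panel Wells replicating each
#'   condition x panel combination.
#' @param fields_per_well Imaging fields per well.
#' @param field_size Square field side in pixels (>= 64).
#' @param cells_per_field Integer range `c(min, max)` of cells placed per field.
#' @param nucleus_radius,cell_radius Baseline radii in pixels.
#' @param marker_specs Data frame of variable-marker response curves: `name`,
#'   `direction` (+1/-1), logistic `midpoint` and `slope`, `localisation`
#'   (`nuclear`/`cytoplasmic`/`membrane`), response range `lo`..`hi`
#'   (fraction of dynamic range) and cell-level lognormal `sigma_cell`.
#' @param junction_w0,junction_w1 Membrane weight of the junctional anchor at
#'   s=0 and s=1; the linear interpolation between them is the "anchor
#'   informativeness" control (how much latent state the anchors expose).
#' @param area_growth Relative cell-radius growth from s=0 to s=1.
#' @param protrusion_amp Amplitude of s-scaled protrusion lobes.
#' @param dic_state_gain How strongly the label-free relief amplitude and
#'   intracellular granularity scale with the latent state (0 disables;
#'   mesenchymal cells image with stronger relief texture).
#' @param marker_condition_shift Molecular condition regulation: each
#'   marker's effective sub-state is the shared state plus
#'   `(c - 2) * marker_condition_shift` for condition index c — inducers
#'   regulate the molecular EM program beyond the cell's shared
#'   morphological state (e.g. TGF-beta represses epithelial markers before
#'   morphology follows), so real labels carry condition information the
#'   anchors cannot reveal.
#' @param marker_state_sigma Cell-level sd of the marker-specific sub-state
#'   around the shared state (independent across markers).
#' @param noise Logical: enable cell-level and pixel-level noise.
#' @param pixel_gauss Pixel Gaussian noise sd (fraction of dynamic range).
#' @param pixel_poisson Poisson-like scaling: added variance is
#'   `intensity * pixel_poisson`.
#' @return A validated `pb_sim_config` list.
#' @export
sim_config <- function(seed = 0L,
                       conditions = list(control = c(2, 6), EGF = c(4, 4), TGFB1 = c(6, 2)),
                       n_panels = 8L,
                       wells_per_condition_per_panel = 1L,
                       fields_per_well = 4L,
                       field_size = 1024L,
                       cells_per_field = c(60L, 100L),
                       nucleus_radius = 18,
                       cell_radius = 45,
                       marker_specs = .default_marker_specs(),
                       junction_w0 = 0.75, junction_w1 = 0.35,
                       area_growth = 0.30, protrusion_amp = 0.25,
                       dic_state_gain = 0.9,
                       marker_condition_shift = 0.16,
                       marker_state_sigma = 0.05,
                       noise = TRUE,
                       pixel_gauss = 0.01, pixel_poisson = 0.002) {
  if (n_panels < 1L) stop("n_panels must be >= 1")
  if (n_panels > nrow(marker_specs)) stop("n_panels exceeds available marker_specs")
  if (field_size < 64L) stop("field_size must be >= 64")
  for (cn in names(conditions))
    if (any(conditions[[cn]] <= 0)) stop("Beta parameters must be > 0 (condition ", cn, ")")
  if (any(cells_per_field < 0) || cells_per_field[2] < cells_per_field[1])
    stop("invalid cells_per_field range")
  if (!all(marker_specs$slope > 0)) stop("logistic slopes must be > 0 (monotone response)")
  if (!all(marker_specs$localisation %in% c("nuclear", "cytoplasmic", "membrane")))
    stop("unknown marker localisation")
  structure(list(
    seed = as.integer(seed), conditions = conditions, n_panels = as.integer(n_panels),
    wells_per_condition_per_panel = as.integer(wells_per_condition_per_panel),
    fields_per_well = as.integer(fields_per_well), field_size = as.integer(field_size),
    cells_per_field = as.integer(cells_per_field),
    nucleus_radius = nucleus_radius, cell_radius = cell_radius,
    marker_specs = marker_specs[seq_len(n_panels), , drop = FALSE],
    junction_w0 = junction_w0, junction_w1 = junction_w1,
    area_growth = area_growth, protrusion_amp = protrusion_amp,
    dic_state_gain = dic_state_gain,
    marker_condition_shift = marker_condition_shift,
    marker_state_sigma = marker_state_sigma,
    noise = isTRUE(noise), pixel_gauss = pixel_gauss, pixel_poisson = pixel_poisson,
    anchors = c("DNA", "Actin", "Junction"), label_free = "DIC"
  ), class = "pb_sim_config")
}

# marker response curve: monotone logistic on [0,1], direction +/- 1
.marker_response <- function(spec, s) {
  z <- 1 / (1 + exp(-spec$slope * (s - spec$midpoint)))
  if (spec$direction < 0) z <- 1 - z
  spec$lo + (spec$hi - spec$lo) * z
}

.well_seed <- function(seed, well_index) {
  as.integer((as.numeric(seed) * 7919 + well_index * 104729) %% 2147483647)
}

#' Generate cell geometry for one field
#'
#' Places nuclei as random ellipses on a jittered grid and grows star-convex
#' cell bodies whose radius and protrusion lobes scale with the latent state;
#' pixels are assigned to the cell with the smallest normalised radial
#' coordinate, so neighbouring cells tile without overlap.
#'
#' @param n_cells Number of cells to place.
#' @param s Latent EM states, length `n_cells`.
#' @param config A `pb_sim_config`.
#' @return List with `labels` (cell label mask), `nuclei` (nucleus label
#'   mask), and per-cell `cells` data.frame (centroids, radii, state).
#' @export
generate_field_geometry <- function(n_cells, s, config) {
  fs <- config$field_size
  labels <- matrix(0L, fs, fs)
  nuclei <- matrix(0L, fs, fs)
  if (n_cells == 0L)
    return(list(labels = labels, nuclei = nuclei,
                cells = data.frame(cell = integer(), cx = numeric(), cy = numeric(),
                                   s = numeric(), r_cell = numeric(), r_nuc = numeric())))
  g <- ceiling(sqrt(n_cells))
  spacing <- fs / g
  slots <- sample(g * g, n_cells)
  sr <- (slots - 1L) %/% g
  sc <- (slots - 1L) %% g
  cx <- (sr + 0.5) * spacing + stats::runif(n_cells, -0.28, 0.28) * spacing
  cy <- (sc + 0.5) * spacing + stats::runif(n_cells, -0.28, 0.28) * spacing
  r_cell <- config$cell_radius * (1 + config$area_growth * s) * stats::runif(n_cells, 0.92, 1.08)
  r_nuc <- config$nucleus_radius * stats::runif(n_cells, 0.85, 1.15)
  n_lobes <- sample(2:5, n_cells, replace = TRUE)
  phase <- stats::runif(n_cells, 0, 2 * pi)
  amp <- config$protrusion_amp * s
  nuc_ecc <- stats::runif(n_cells, 0, 0.35)
  nuc_phi <- stats::runif(n_cells, 0, pi)

  score <- matrix(Inf, fs, fs)  # normalised radial coordinate of owning cell
  for (i in seq_len(n_cells)) {
    rmax <- r_cell[i] * (1 + abs(amp[i])) + 2
    r0 <- max(1L, floor(cx[i] - rmax)); r1 <- min(fs, ceiling(cx[i] + rmax))
    c0 <- max(1L, floor(cy[i] - rmax)); c1 <- min(fs, ceiling(cy[i] + rmax))
    if (r0 > r1 || c0 > c1) next
    xs <- r0:r1; ys <- c0:c1
    dx <- outer(xs - cx[i], rep(1, length(ys)))
    dy <- outer(rep(1, length(xs)), ys - cy[i])
    d <- sqrt(dx^2 + dy^2)
    th <- atan2(dy, dx)
    rb <- r_cell[i] * (1 + amp[i] * cos(n_lobes[i] * th + phase[i]))
    u <- d / pmax(rb, 1)
    upd <- u <= 1 & u < score[xs, ys]
    if (any(upd)) {
      sub_l <- labels[xs, ys]; sub_s <- score[xs, ys]
      sub_l[upd] <- i; sub_s[upd] <- u[upd]
      labels[xs, ys] <- sub_l; score[xs, ys] <- sub_s
    }
  }
  # nuclei: ellipses, clamped inside the minimum cell radius
  for (i in seq_len(n_cells)) {
    a <- min(r_nuc[i] * (1 + nuc_ecc[i]), 0.85 * r_cell[i] * (1 - abs(amp[i])))
    b <- min(r_nuc[i] * (1 - nuc_ecc[i]), a)
    rmax <- a + 1
    r0 <- max(1L, floor(cx[i] - rmax)); r1 <- min(fs, ceiling(cx[i] + rmax))
    c0 <- max(1L, floor(cy[i] - rmax)); c1 <- min(fs, ceiling(cy[i] + rmax))
    if (r0 > r1 || c0 > c1) next
    xs <- r0:r1; ys <- c0:c1
    dx <- outer(xs - cx[i], rep(1, length(ys)))
    dy <- outer(rep(1, length(xs)), ys - cy[i])
    xr <- dx * cos(nuc_phi[i]) + dy * sin(nuc_phi[i])
    yr <- -dx * sin(nuc_phi[i]) + dy * cos(nuc_phi[i])
    inside <- (xr / a)^2 + (yr / b)^2 <= 1
    # nuclei stay within their own cell and never overlap another nucleus
    sub_l <- labels[xs, ys]; sub_n <- nuclei[xs, ys]
    inside <- inside & sub_l == i & sub_n == 0L
    sub_n[inside] <- i
    nuclei[xs, ys] <- sub_n
  }
  list(labels = labels, nuclei = nuclei,
       cells = data.frame(cell = seq_len(n_cells), cx = cx, cy = cy, s = s,
                          r_cell = r_cell, r_nuc = r_nuc))
}

# membrane band: cell pixels within `width` px of the cell boundary
.boundary_band <- function(labels, width = 2L) {
  fs <- nrow(labels)
  interior <- labels
  pad <- function(m, dr, dc) {
    out <- matrix(-1L, fs, fs)
    rs <- max(1, 1 + dr):min(fs, fs + dr)
    cs <- max(1, 1 + dc):min(fs, fs + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  boundary <- matrix(FALSE, fs, fs)
  for (sh in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)))
    boundary <- boundary | (labels > 0L & pad(labels, sh[1], sh[2]) != labels)
  band <- boundary
  if (width > 1L) for (k in seq_len(width - 1L)) {
    grown <- band
    for (sh in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)))
      grown <- grown | pad(band * 1L, sh[1], sh[2]) == 1L
    band <- grown & labels > 0L
  }
  band
}

#' Render the channels of one field
#'
#' Draws all channels for a generated geometry on the `[0,1]` intensity
#' scale: nuclear DNA, cytoskeletal actin with a cortical rim, a junctional
#' marker that relocates from the membrane (s near 0) to diffuse cytoplasm
#' (s near 1), every variable marker (monotone logistic response in s with
#' its configured localisation), and a shaded-relief label-free channel
#' computed from the cell height map. With `noise = FALSE` the primary
#' compartment of marker m carries exactly its expected response `f_m(s)`.
#'
#' @param geom Output of [generate_field_geometry()].
#' @param config A `pb_sim_config`.
#' @param noise Override the config noise switch.
#' @param condition_index Index of the condition (1-based) driving the
#'   marker-specific condition shifts; 0 (default) disables them.
#' @return Named list of `[0,1]` matrices: `DIC`, `DNA`, `Actin`,
#'   `Junction`, then one per variable marker; plus attribute
#'   `expected` (per-cell noise-free mean response per marker).
#' @export
render_field_channels <- function(geom, config, noise = config$noise,
                                  condition_index = 0L) {
  fs <- config$field_size
  labels <- geom$labels; nuclei <- geom$nuclei
  cells <- geom$cells
  n <- nrow(cells)
  out <- list()
  band <- .boundary_band(labels, 2L)
  cyto <- labels > 0L & !band
  cell_px <- labels > 0L

  lut <- function(vals) { # per-cell value -> image
    v <- c(0, vals)
    matrix(v[labels + 1L], fs, fs)
  }
  cmul <- function(sigma) if (noise && n > 0) exp(stats::rnorm(n, 0, sigma)) else rep(1, n)

  # DNA: uniform nuclear signal, mild per-cell brightness variation
  dna_lvl <- if (n > 0) 0.75 * cmul(0.08) else numeric()
  dna <- matrix(0, fs, fs)
  if (n > 0) { v <- c(0, dna_lvl); dna <- matrix(v[nuclei + 1L], fs, fs) }

  # Actin: cytoplasmic with cortical rim, dimmer over the nucleus
  act_lvl <- if (n > 0) 0.55 * cmul(0.08) else numeric()
  actin <- matrix(0, fs, fs)
  if (n > 0) {
    actin[cell_px] <- lut(act_lvl)[cell_px]
    actin[nuclei > 0L] <- actin[nuclei > 0L] * 0.45
    actin[band] <- actin[band] * 1.35
  }

  # Junction: membrane weight w(s) interpolates junction_w0 -> junction_w1
  junction <- matrix(0, fs, fs)
  if (n > 0) {
    w <- config$junction_w0 + (config$junction_w1 - config$junction_w0) * cells$s
    lvl <- 0.7 * cmul(0.08)
    jb <- lut(lvl * w); jc <- lut(lvl * (1 - w) * 0.55 + 0.04)
    junction[band] <- jb[band]
    junction[cyto] <- jc[cyto]
  }

  expected <- matrix(NA_real_, n, config$n_panels,
                     dimnames = list(NULL, config$marker_specs$name))
  markers <- list()
  for (k in seq_len(config$n_panels)) {
    spec <- config$marker_specs[k, ]
    # marker-specific effective sub-state: shared state + condition
    # regulation on this marker's axis + independent cell-level variation
    s_eff <- cells$s
    if (n > 0 && condition_index > 0L)
      s_eff <- s_eff + (condition_index - 2L) * config$marker_condition_shift
    if (n > 0 && noise)
      s_eff <- s_eff + stats::rnorm(n, 0, config$marker_state_sigma)
    s_eff <- pmin(pmax(s_eff, 0), 1)
    f <- if (n > 0) .marker_response(spec, s_eff) else numeric()
    expected[, k] <- f
    lvl <- f * cmul(spec$sigma_cell)
    img <- matrix(0, fs, fs)
    if (n > 0) {
      li <- lut(lvl)
      if (spec$localisation == "nuclear") {
        img[nuclei > 0L] <- li[nuclei > 0L]
        img[cell_px & nuclei == 0L] <- 0.05 * li[cell_px & nuclei == 0L]
      } else if (spec$localisation == "cytoplasmic") {
        img[cell_px] <- li[cell_px]
        img[nuclei > 0L] <- 0.30 * li[nuclei > 0L]
      } else { # membrane
        img[band] <- li[band]
        img[cyto] <- 0.15 * li[cyto]
      }
    }
    markers[[spec$name]] <- img
  }

  # label-free relief channel from the cell height map; relief amplitude and
  # intracellular granularity scale with the latent state (mesenchymal cells
  # carry more dry mass / organelle texture), controlled by dic_state_gain
  height <- matrix(0, fs, fs)
  if (n > 0) {
    hfac <- 0.3 + 1.4 * config$dic_state_gain * cells$s
    hf <- lut(hfac)
    height[cell_px] <- 0.5 * hf[cell_px]
    height[nuclei > 0L] <- 1.0 * hf[nuclei > 0L]
    # coarse granularity so the texture cue survives half-resizing
    gran <- .box_blur(matrix(stats::rnorm(fs * fs), fs, fs), 5L)
    gamp <- lut(0.05 + 0.7 * config$dic_state_gain * cells$s)
    height[cell_px] <- height[cell_px] + gran[cell_px] * gamp[cell_px]
    height <- .box_blur(height, 3L)
  }
  gx <- rbind(height[-1, , drop = FALSE], height[fs, , drop = FALSE]) - height
  gy <- cbind(height[, -1, drop = FALSE], height[, fs, drop = FALSE]) - height
  dic <- 0.5 + 0.9 * (gx + gy)

  add_noise <- function(img, is_fluor = TRUE) {
    if (!noise) return(pmin(pmax(img, 0), 1))
    sd_px <- sqrt(config$pixel_gauss^2 + pmax(img, 0) * config$pixel_poisson)
    pmin(pmax(img + stats::rnorm(length(img), 0, 1) * sd_px, 0), 1)
  }
  out$DIC <- add_noise(dic, FALSE)
  out$DNA <- add_noise(dna)
  out$Actin <- add_noise(actin)
  out$Junction <- add_noise(junction)
  for (nm in names(markers)) out[[nm]] <- add_noise(markers[[nm]])
  attr(out, "expected") <- expected
  out
}

.box_blur <- function(m, k) {
  # small separable running-mean blur (k odd)
  h <- (k - 1L) %/% 2L
  pad_cum_mean <- function(x) {
    n2 <- nrow(x)
    xp <- rbind(x[rep(1L, h), , drop = FALSE], x, x[rep(n2, h), , drop = FALSE])
    cs <- apply(xp, 2, cumsum)
    (cs[(k):(n2 + k - 1L), , drop = FALSE] -
       rbind(0, cs[seq_len(n2 - 1L), , drop = FALSE])) / k
  }
  t(pad_cum_mean(t(pad_cum_mean(m))))
}

#' Generate a complete synthetic dataset
#'
#' Writes a multi-well dataset under `dir`: one multi-page 16-bit TIFF per
#' field (pages: DIC, DNA, Actin, Junction, the well's variable marker), a
#' YAML manifest, and ground truth held out for evaluation (all variable
#' channels for every field under `gt/`, label masks, and a per-cell CSV
#' with latent states and noise-free expected marker responses). Outputs are
#' byte-identical for identical `(config, seed)`.
#'
#' @param config A `pb_sim_config`.
#' @param dir Output directory (created if needed).
#' @return A list with the loaded `manifest`, the `ground_truth` data.frame
#'   and the dataset `dir`.
#' @export
simulate_dataset <- function(config, dir) {
  stopifnot(inherits(config, "pb_sim_config"))
  if (prod(config$cells_per_field) == 0 && all(config$cells_per_field == 0))
    stop("degenerate config: 0 cells per field")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "images"), showWarnings = FALSE)
  dir.create(file.path(dir, "gt"), showWarnings = FALSE)
  if (file.access(dir, 2) != 0) stop("output directory not writable: ", dir)

  specs <- config$marker_specs
  conds <- names(config$conditions)
  wells <- list()
  gt_rows <- list()
  widx <- 0L
  for (p in seq_len(config$n_panels)) {
    for (ci in seq_along(conds)) {
      for (rep_i in seq_len(config$wells_per_condition_per_panel)) {
        widx <- widx + 1L
        well_id <- sprintf("W%02d", widx)
        cond <- conds[ci]
        marker <- specs$name[p]
        set.seed(.well_seed(config$seed, widx))
        ab <- config$conditions[[cond]]
        fields <- list()
        for (fi in seq_len(config$fields_per_well)) {
          field_id <- sprintf("F%02d", fi)
          n_cells <- if (config$cells_per_field[1] == config$cells_per_field[2])
            config$cells_per_field[1] else
            sample(config$cells_per_field[1]:config$cells_per_field[2], 1L)
          s <- stats::rbeta(n_cells, ab[1], ab[2])
          geom <- generate_field_geometry(n_cells, s, config)
          chans <- render_field_channels(geom, config, condition_index = ci)
          to16 <- function(m) round(m * 65535)
          fn <- sprintf("images/%s_%s.tif", well_id, field_id)
          write_field_tiff(lapply(chans[c(config$label_free, config$anchors, marker)], to16),
                           file.path(dir, fn), bits = 16L)
          # ground truth: every variable channel + label masks
          write_field_tiff(lapply(chans[specs$name], to16),
                           file.path(dir, sprintf("gt/%s_%s_markers.tif", well_id, field_id)),
                           bits = 16L)
          write_field_tiff(list(cells = geom$labels, nuclei = geom$nuclei),
                           file.path(dir, sprintf("gt/%s_%s_labels.tif", well_id, field_id)),
                           bits = 16L)
          exp_mat <- attr(chans, "expected")
          if (n_cells > 0) {
            df <- data.frame(well = well_id, field = field_id, cell = geom$cells$cell,
                             condition = cond, panel = p, marker_assigned = marker,
                             s = geom$cells$s, cx = geom$cells$cx, cy = geom$cells$cy)
            for (nm in colnames(exp_mat)) df[[paste0("f_", nm)]] <- exp_mat[, nm]
            gt_rows[[length(gt_rows) + 1L]] <- df
          }
          fields[[fi]] <- list(field_id = field_id, path = fn)
        }
        wells[[widx]] <- list(well_id = well_id, condition = cond, panel_id = p,
                              channels = as.list(c(config$label_free, config$anchors, marker)),
                              fields = fields)
      }
    }
  }
  channels <- data.frame(
    name = c(config$label_free, config$anchors, specs$name),
    role = c("label_free", rep("anchor", length(config$anchors)),
             rep("variable", nrow(specs))),
    stringsAsFactors = FALSE
  )
  .write_manifest(channels, wells, file.path(dir, "manifest.yaml"))
  gt <- do.call(rbind, gt_rows)
  utils::write.csv(gt, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  list(manifest = load_manifest(file.path(dir, "manifest.yaml")),
       ground_truth = gt, dir = dir)
}
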