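# Segmentation and the CellProfiler-convention feature schema.

test_that("segmentation recovers the generated cells and excludes border objects", {
  cfg <- desk_sim_config(seed = 17, noise = FALSE, cells_per_field = c(15L, 15L))
  set.seed(99)
  geom <- generate_field_geometry(15L, rbeta(15, 2, 2), cfg)
  ch <- render_field_channels(geom, cfg, noise = FALSE)
  dna <- round(ch$DNA * 255); act <- round(ch$Actin * 255)
  seg <- segment_cells(dna, act)
  # ground truth: interior cells only
  gt_border <- unique(c(geom$labels[1, ], geom$labels[nrow(geom$labels), ],
                        geom$labels[, 1], geom$labels[, ncol(geom$labels)]))
  n_interior <- length(setdiff(unique(geom$labels[geom$labels > 0]),
                               gt_border[gt_border > 0]))
  expect_equal(seg$n_cells, n_interior)
  # each retained cell overlaps a distinct ground-truth cell at IoU >= 0.5
  ious <- vapply(seq_len(seg$n_cells), function(k) {
    m <- seg$cells == k
    gids <- table(geom$labels[m & geom$labels > 0])
    g <- as.integer(names(gids)[which.max(gids)])
    gm <- geom$labels == g
    sum(m & gm) / sum(m | gm)
  }, 0)
  expect_true(all(ious >= 0.5))
  # determinism
  expect_identical(seg$cells, segment_cells(dna, act)$cells)
})

test_that("blank fields segment to zero cells and border cells are dropped", {
  z <- matrix(0, 64, 64)
  expect_equal(segment_cells(z, z)$n_cells, 0L)
  # an injected mask with a cell spanning row 1 drops that cell
  cells <- matrix(0L, 32, 32)
  cells[1:6, 5:10] <- 1L      # touches the border
  cells[15:20, 15:20] <- 2L   # interior
  nuc <- matrix(0L, 32, 32); nuc[2:4, 6:8] <- 1L; nuc[16:18, 16:18] <- 2L
  seg <- segment_cells(matrix(0, 32, 32), matrix(0, 32, 32),
                       masks = list(cells = cells, nuclei = nuc))
  expect_equal(seg$n_cells, 1L)
  expect_equal(seg$excluded, 1L)
  expect_true(all(seg$cells[15:20, 15:20] == 1L))
})

test_that("the feature schema is frozen at 17 morphology + 142 per marker", {
  sch1 <- feature_schema("M")
  expect_equal(sum(grepl("^Morph_", sch1)), 17L)
  expect_equal(sum(grepl("^M_", sch1)), 142L)
  expect_equal(sum(grepl("^M_Int_", sch1)), 15L)
  expect_equal(sum(grepl("^M_Rad_", sch1)), 75L)
  expect_equal(sum(grepl("^M_Tex_", sch1)), 52L)
  sch3 <- feature_schema(c("A", "B", "C"))
  expect_equal(sum(grepl("^Coloc_", sch3)), 3L)  # C(C-1)/2
  # identical across calls (golden schema)
  expect_identical(sch3, feature_schema(c("A", "B", "C")))
})

disc_fixture <- function(intensity = 200) {
  cells <- matrix(0L, 40, 40)
  for (i in 1:40) for (j in 1:40)
    if ((i - 20)^2 + (j - 20)^2 <= 100) cells[i, j] <- 1L
  nuc <- matrix(0L, 40, 40)
  for (i in 1:40) for (j in 1:40)
    if ((i - 20)^2 + (j - 20)^2 <= 16) nuc[i, j] <- 1L
  seg <- segment_cells(matrix(0, 40, 40), matrix(0, 40, 40),
                       masks = list(cells = cells, nuclei = nuc))
  list(seg = seg, img = matrix(intensity, 40, 40))
}

test_that("a uniform disc yields the expected intensity and texture features", {
  fx <- disc_fixture(200)
  ft <- extract_features(fx$seg, list(M = fx$img))
  expect_equal(nrow(ft), 1L)
  expect_equal(ft$M_Int_MeanIntensity, 200 / 255, tolerance = 1e-12)
  expect_equal(ft$M_Int_StdIntensity, 0)
  expect_equal(ft$M_Int_MassDisplacement, 0, tolerance = 1e-9)
  expect_equal(ft$M_Int_MedianIntensity, 200 / 255)
  expect_equal(ft$M_Int_MADIntensity, 0)
  # constant region: single-entry co-occurrence matrix at every direction
  for (d in c("d0", "d45", "d90", "d135")) {
    expect_equal(ft[[paste0("M_Tex_Haralick01_", d)]], 1)   # angular 2nd moment
    expect_equal(ft[[paste0("M_Tex_Haralick02_", d)]], 0)   # contrast
  }
  # disc morphology sanity
  expect_equal(ft$Morph_FormFactor, 1, tolerance = 0.15)
  expect_equal(ft$Morph_Eccentricity, 0, tolerance = 0.1)
  expect_equal(ft$Morph_NucleusAreaRatio, sum(fx$seg$nuclei == 1) / sum(fx$seg$cells == 1))
})

test_that("radial distribution fractions sum to one for in-cell signal", {
  fx <- disc_fixture(100)
  set.seed(4)
  img <- matrix(runif(1600, 50, 250), 40, 40)
  ft <- extract_features(fx$seg, list(M = img))
  fr <- as.numeric(ft[, grepl("M_Rad_FracAtD", names(ft))])
  expect_equal(sum(fr), 1, tolerance = 1e-9)
  mf <- as.numeric(ft[, grepl("M_Rad_MeanFrac", names(ft))])
  expect_true(all(mf >= 0))
})

test_that("per-cell colocalisation matches hand-computed Pearson values", {
  cells <- matrix(0L, 10, 10); cells[3:8, 3:8] <- 1L
  nuc <- matrix(0L, 10, 10); nuc[5:6, 5:6] <- 1L
  seg <- segment_cells(matrix(0, 10, 10), matrix(0, 10, 10),
                       masks = list(cells = cells, nuclei = nuc))
  set.seed(6)
  a <- matrix(runif(100, 0, 255), 10)
  expect_equal(cell_coloc_pcc(seg, a, a), 1)
  expect_equal(cell_coloc_pcc(seg, a, 255 - a), -1)
  b <- matrix(runif(100, 0, 255), 10)
  idx <- which(seg$cells == 1)
  expect_equal(cell_coloc_pcc(seg, a, b), naive_pcc(a[idx], b[idx]), tolerance = 1e-12)
  # zero variance recorded as missing
  expect_true(is.na(cell_coloc_pcc(seg, matrix(7, 10, 10), a)))
})

test_that("tiny cells are dropped and degenerate features never reach the table", {
  cells <- matrix(0L, 20, 20)
  cells[2:3, 2:3] <- 1L        # 4 px, below the 9 px minimum
  cells[8:14, 8:14] <- 2L
  nuc <- matrix(0L, 20, 20); nuc[10:12, 10:12] <- 2L
  seg <- segment_cells(matrix(0, 20, 20), matrix(0, 20, 20),
                       masks = list(cells = cells, nuclei = nuc))
  set.seed(9)
  ft <- extract_features(seg, list(M = matrix(runif(400, 0, 255), 20)))
  expect_equal(nrow(ft), 1L)
  core <- ft[, !grepl("^Coloc_", names(ft))]
  expect_true(all(is.finite(as.numeric(core))))
})

test_that("noise-free per-cell mean intensity tracks the configured response", {
  cfg <- desk_sim_config(seed = 23, noise = FALSE, cells_per_field = c(16L, 16L))
  feats <- NULL; fvals <- NULL
  for (f in 1:4) {
    set.seed(300 + f)
    s <- rbeta(16, 2, 2)
    geom <- generate_field_geometry(16L, s, cfg)
    ch <- render_field_channels(geom, cfg, noise = FALSE)
    seg <- segment_cells(round(ch$DNA * 255), round(ch$Actin * 255))
    if (seg$n_cells == 0) next
    chans <- lapply(cfg$marker_specs$name, function(m) round(ch[[m]] * 255))
    names(chans) <- cfg$marker_specs$name
    ft <- extract_features(seg, chans)
    # map retained cells back to generator cells by centroid
    gmap <- vapply(seq_len(nrow(ft)), function(i) {
      d2 <- (geom$cells$cx - ft$cx[i])^2 + (geom$cells$cy - ft$cy[i])^2
      which.min(d2)
    }, 1L)
    feats <- rbind(feats, ft)
    ex <- attr(ch, "expected")[gmap, , drop = FALSE]
    fvals <- rbind(fvals, ex)
  }
  for (m in cfg$marker_specs$name) {
    r <- cor(feats[[paste0(m, "_Int_MeanIntensity")]], fvals[, m])
    expect_gte(r, 0.99)
  }
})
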