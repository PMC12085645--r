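# Synthetic dataset generator: panel structure, determinism, monotone
# responses, anchor localisation, condition ordering.

test_that("default design yields 3 conditions x 8 panels = 24 wells", {
  cfg <- sim_config(seed = 1)
  expect_equal(length(cfg$conditions) * cfg$n_panels * cfg$wells_per_condition_per_panel,
               24L)
  d <- pb_test_dataset()
  n_exp <- length(d$config$conditions) * d$config$n_panels *
    d$config$wells_per_condition_per_panel
  expect_length(d$ds$manifest$wells, n_exp)
})

test_that("invalid simulation configurations are rejected", {
  expect_error(sim_config(n_panels = 0), "n_panels")
  expect_error(sim_config(field_size = 32), "field_size")
  expect_error(sim_config(conditions = list(a = c(0, 1), b = c(1, 1), c = c(1, 1))),
               "Beta")
  expect_error(simulate_dataset(sim_config(cells_per_field = c(0L, 0L)),
                                tempfile()), "0 cells")
})

test_that("identical (config, seed) reproduces byte-identical files", {
  cfg <- desk_sim_config(seed = 11, n_panels = 2L, fields_per_well = 1L,
                         cells_per_field = c(6L, 8L))
  d1 <- simulate_dataset(cfg, file.path(tempdir(), "det1"))
  d2 <- simulate_dataset(cfg, file.path(tempdir(), "det2"))
  f1 <- list.files(d1$dir, recursive = TRUE, pattern = "tif$")
  expect_true(length(f1) > 0)
  for (f in f1)
    expect_identical(tools::md5sum(file.path(d1$dir, f))[[1]],
                     tools::md5sum(file.path(d2$dir, f))[[1]])
  # a different seed changes the images
  d3 <- simulate_dataset(desk_sim_config(seed = 12, n_panels = 2L,
                                         fields_per_well = 1L,
                                         cells_per_field = c(6L, 8L)),
                         file.path(tempdir(), "det3"))
  expect_false(tools::md5sum(file.path(d1$dir, f1[1]))[[1]] ==
                 tools::md5sum(file.path(d3$dir, f1[1]))[[1]])
})

test_that("noise-free responses are exactly monotone in the latent state", {
  cfg <- desk_sim_config(seed = 3, noise = FALSE)
  specs <- cfg$marker_specs
  s <- runif(200)
  for (i in seq_len(nrow(specs))) {
    f <- plexbridge:::.marker_response(specs[i, ], s)
    # monotone response: rank correlation with the state is exactly +-1
    r <- cor(f, s, method = "spearman")
    expect_equal(r, sign(specs$direction[i]), tolerance = 1e-12)
    ord <- order(s)
    d <- diff(f[ord]) * specs$direction[i]
    expect_true(all(d >= -1e-12))  # monotone
  }
})

test_that("noise-free compartment mean equals the marker response within quantisation", {
  cfg <- desk_sim_config(seed = 5, noise = FALSE, cells_per_field = c(10L, 10L))
  set.seed(31)
  s <- rbeta(10, 2, 2)
  geom <- generate_field_geometry(10L, s, cfg)
  ch <- render_field_channels(geom, cfg, noise = FALSE)
  expected <- attr(ch, "expected")
  band <- plexbridge:::.boundary_band(geom$labels, 2L)
  q16 <- function(m) round(m * 65535) / 65535  # emitted quantisation
  for (k in seq_len(cfg$n_panels)) {
    spec <- cfg$marker_specs[k, ]
    img <- q16(ch[[spec$name]])
    for (i in seq_len(10)) {
      px <- switch(spec$localisation,
                   membrane = band & geom$labels == i,
                   cytoplasmic = geom$labels == i & geom$nuclei == 0L,
                   nuclear = geom$nuclei == i)
      if (!any(px)) next
      expect_lt(abs(mean(img[px]) - expected[i, spec$name]), 1 / 255)
    }
  }
})

test_that("junctional anchor concentrates at the boundary for epithelial cells", {
  cfg <- desk_sim_config(seed = 6, noise = FALSE, cells_per_field = c(9L, 9L))
  set.seed(8)
  geom <- generate_field_geometry(9L, rep(0, 9), cfg)   # s = 0: epithelial
  ch <- render_field_channels(geom, cfg, noise = FALSE)
  band <- plexbridge:::.boundary_band(geom$labels, 2L)
  inside <- geom$labels > 0L
  frac <- sum(ch$Junction[band]) / sum(ch$Junction[inside])
  expect_gte(frac, 0.6)
  # and disperses for mesenchymal cells
  geom1 <- generate_field_geometry(9L, rep(1, 9), cfg)
  ch1 <- render_field_channels(geom1, cfg, noise = FALSE)
  band1 <- plexbridge:::.boundary_band(geom1$labels, 2L)
  frac1 <- sum(ch1$Junction[band1]) / sum(ch1$Junction[geom1$labels > 0L])
  expect_lt(frac1, frac)
})

test_that("cell area grows monotonically with the latent state in expectation", {
  cfg <- desk_sim_config(seed = 9, cells_per_field = c(9L, 9L))
  set.seed(123)
  g0 <- generate_field_geometry(9L, rep(0, 9), cfg)
  set.seed(123)
  g1 <- generate_field_geometry(9L, rep(1, 9), cfg)
  expect_gt(sum(g1$labels > 0), sum(g0$labels > 0))
})

test_that("an empty field renders all-zero fluorescence and a flat relief image", {
  cfg <- desk_sim_config(seed = 2, noise = FALSE)
  geom <- generate_field_geometry(0L, numeric(), cfg)
  ch <- render_field_channels(geom, cfg, noise = FALSE)
  for (nm in setdiff(names(ch), "DIC")) expect_true(all(ch[[nm]] == 0))
  expect_true(all(abs(ch$DIC - 0.5) < 1e-12))
})

test_that("nucleus channel is nonzero only inside nuclei", {
  cfg <- desk_sim_config(seed = 4, noise = FALSE, cells_per_field = c(8L, 8L))
  set.seed(14)
  geom <- generate_field_geometry(8L, rbeta(8, 2, 2), cfg)
  ch <- render_field_channels(geom, cfg, noise = FALSE)
  expect_true(all(ch$DNA[geom$nuclei == 0L] == 0))
  expect_true(all(ch$DNA[geom$nuclei > 0L] > 0))
})

test_that("latent states order conditions as control < EGF-like < TGF-beta-like", {
  d <- pb_test_dataset()
  gt <- d$ds$ground_truth
  expect_gte(nrow(gt), 500)
  s_ctrl <- gt$s[gt$condition == "control"]
  s_egf <- gt$s[gt$condition == "EGF"]
  s_tgf <- gt$s[gt$condition == "TGFB1"]
  w1 <- welch_ttest(s_egf, s_ctrl)
  w2 <- welch_ttest(s_tgf, s_egf)
  expect_gt(mean(s_egf), mean(s_ctrl))
  expect_gt(mean(s_tgf), mean(s_egf))
  expect_lt(w1$p, 0.01)
  expect_lt(w2$p, 0.01)
})

test_that("ground truth stores every variable channel for every well", {
  d <- pb_test_dataset()
  m <- d$ds$manifest
  vars <- m$channels$name[m$channels$role == "variable"]
  w <- m$wells[[1]]
  gtp <- file.path(m$root, sprintf("gt/%s_%s_markers.tif", w$well_id,
                                   w$fields[[1]]$field_id))
  expect_true(file.exists(gtp))
  expect_length(read_field_tiff(gtp), length(vars))
})
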