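# Bridging plan, stratified folds, and the integration orchestrator
# (stub-oracle identity and the leakage guard).

test_that("one model is planned per variable marker, applied to all wells", {
  d <- pb_test_dataset()
  plan <- plan_bridging(d$ds$manifest, "full")
  expect_length(plan$markers, 4L)
  all_wells <- vapply(d$ds$manifest$wells, `[[`, "", "well_id")
  for (mk in plan$markers) {
    expect_setequal(mk$apply_wells, all_wells)
    expect_length(mk$training_wells, 3L)   # one well per condition
    expect_setequal(mk$input_channels, c("DIC", "DNA", "Actin", "Junction"))
  }
  lf <- plan_bridging(d$ds$manifest, "label_free")
  expect_equal(lf$markers[[1]]$input_channels, "DIC")
  ao <- plan_bridging(d$ds$manifest, "anchors_only")
  expect_setequal(ao$markers[[1]]$input_channels, c("DNA", "Actin", "Junction"))
})

test_that("a single-panel manifest yields a degenerate single-model plan", {
  cfg <- desk_sim_config(seed = 31, n_panels = 1L, fields_per_well = 1L,
                         cells_per_field = c(6L, 8L))
  ds <- simulate_dataset(cfg, file.path(tempdir(), "one_panel"))
  plan <- plan_bridging(ds$manifest, "full")
  expect_length(plan$markers, 1L)
  expect_setequal(plan$markers[[1]]$training_wells, plan$markers[[1]]$apply_wells)
})

test_that("stratified folds preserve class proportions exactly where divisible", {
  y <- rep(c("a", "b", "c"), c(50, 30, 20))
  f <- stratified_kfold(y, k = 5, seed = 1)
  expect_setequal(unique(f), 1:5)
  for (k in 1:5) {
    expect_equal(sum(f == k & y == "a"), 10L)
    expect_equal(sum(f == k & y == "b"), 6L)
    expect_equal(sum(f == k & y == "c"), 4L)
  }
  # general case: within +-1 of the balanced count, a partition
  set.seed(2)
  y2 <- sample(c("a", "b", "c"), 83, TRUE, prob = c(0.5, 0.3, 0.2))
  f2 <- stratified_kfold(y2, k = 5, seed = 3)
  expect_length(f2, 83L)
  for (cl in unique(y2)) {
    cnt <- table(factor(f2[y2 == cl], levels = 1:5))
    expect_lte(max(cnt) - min(cnt), 1L)
  }
  expect_error(stratified_kfold(c("a", "a", "b"), k = 2), "smallest class")
})

test_that("stub-oracle integration reproduces the ground truth bit-exactly", {
  d <- pb_test_dataset()
  ps <- pb_test_patchset()
  plan <- plan_bridging(d$ds$manifest, "full")
  cfg <- model_config("DIC", "x", preset = "desk", seed = 0)
  integ <- run_integration(plan, ps, cfg, k = 2L, seed = 0L, stub = TRUE)
  vars <- names(plan$markers)
  for (key in names(integ$fields)) {
    for (v in vars) {
      expect_identical(integ$fields[[key]][[v]], ps$gt_fields[[key]][[v]] + 0)
    }
    # anchors stay real
    expect_identical(integ$fields[[key]][["DNA"]], ps$fields[[key]][["DNA"]])
    # post-integration plexity: label-free + anchors + all variable markers
    expect_setequal(names(integ$fields[[key]]),
                    c("DIC", "DNA", "Actin", "Junction", vars))
  }
})

test_that("the leakage guard holds: no field is predicted by a model trained on it", {
  d <- pb_test_dataset()
  ps <- pb_test_patchset()
  plan <- plan_bridging(d$ds$manifest, "full")
  cfg <- model_config("DIC", "x", preset = "desk", seed = 0)
  integ <- run_integration(plan, ps, cfg, k = 2L, seed = 0L, stub = TRUE)
  folds <- integ$folds
  for (key in names(integ$fields)) {
    ffold <- folds$fold[folds$key == key]
    for (v in names(plan$markers)) {
      pfold <- integ$provenance[[paste(key, v, sep = "|")]]
      # the model that produced this field's virtual channel is the one for
      # this field's fold ...
      expect_equal(pfold, ffold)
      # ... and that model's training set excludes every fold-f field
      train_keys <- folds$key[folds$fold != pfold &
                                folds$well %in% plan$markers[[v]]$training_wells]
      expect_false(key %in% train_keys && ffold == pfold)
    }
  }
  # training-well fields receive virtual values via their held-out fold
  tw <- plan$markers[[1]]$training_wells[1]
  twkeys <- folds$key[folds$well == tw]
  for (k2 in twkeys)
    expect_equal(integ$provenance[[paste(k2, names(plan$markers)[1], sep = "|")]],
                 folds$fold[folds$key == k2])
})

test_that("tile reassembly reproduces the original field tiling coordinates", {
  # multi-tile fields: 256-px fields -> 128 resized -> four 64-px tiles
  cfg <- desk_sim_config(seed = 41, n_panels = 1L, fields_per_well = 1L,
                         field_size = 256L, cells_per_field = c(30L, 30L),
                         wells_per_condition_per_panel = 2L)
  ds <- simulate_dataset(cfg, file.path(tempdir(), "reasm"))
  ps <- preprocess_dataset(ds$manifest, preprocess_config(patch_size = 64L),
                           gt_markers = TRUE)
  expect_equal(length(ps$tiles), 6L * 4L)
  plan <- plan_bridging(ds$manifest, "full")
  mcfg <- model_config("DIC", "x", preset = "desk", seed = 0)
  integ <- run_integration(plan, ps, mcfg, k = 2L, seed = 0L, stub = TRUE)
  v <- names(plan$markers)[1]
  for (key in names(integ$fields))
    expect_identical(integ$fields[[key]][[v]], ps$gt_fields[[key]][[v]] + 0)
})
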