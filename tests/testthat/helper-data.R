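# Shared fixtures, generated once per test session and memoised.

.pb_cache <- new.env(parent = emptyenv())

# small multi-panel dataset for structural tests (3 conditions x 4 panels,
# 3 fields/well, 128-px fields -> ~650 cells)
pb_test_dataset <- function() {
  if (is.null(.pb_cache$ds)) {
    cfg <- desk_sim_config(seed = 7, fields_per_well = 3L)
    .pb_cache$ds <- simulate_dataset(cfg, file.path(tempdir(), "pb_test_ds"))
    .pb_cache$ds_config <- cfg
  }
  list(ds = .pb_cache$ds, config = .pb_cache$ds_config)
}

pb_test_patchset <- function() {
  if (is.null(.pb_cache$ps)) {
    d <- pb_test_dataset()
    .pb_cache$ps <- preprocess_dataset(d$ds$manifest,
                                       preprocess_config(patch_size = 64L),
                                       gt_markers = TRUE)
  }
  .pb_cache$ps
}

# the seeded desk study shared by the acceptance properties (trains
# 4 markers x 2 folds x 2 input modes of the desk U-Net; minutes, one CPU)
pb_desk_run <- function() {
  if (is.null(.pb_cache$desk)) {
    .pb_cache$desk <- run_study(sim = desk_sim_config(seed = 0),
                                dir = file.path(tempdir(), "pb_desk_run"),
                                input_modes = c("full", "label_free"),
                                k = 2L, seed = 0L)
  }
  .pb_cache$desk
}
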