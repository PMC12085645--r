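## End-to-end study driver: simulate -> preprocess -> bridge-integrate ->
## profile -> evaluate -> classify -> pseudotime. The desk-scale
## configuration exercises every stage of the framework on one CPU in
## minutes; the paper-scale settings remain available through the
## constructors' defaults.

#' Desk-scale simulation configuration
#'
#' Three conditions x four variable-marker panels x one well, eight
#' 128-px fields per well; after half-resizing, fields match the desk
#' models' 64-px patches exactly.
#'
#' @param seed Master seed.
#' @param n_panels,fields_per_well,field_size,cells_per_field,... Overrides
#'   forwarded to [sim_config()].
#' @return A `pb_sim_config`.
#' @export
desk_sim_config <- function(seed = 0L, n_panels = 4L, fields_per_well = 12L,
                            field_size = 128L, cells_per_field = c(14L, 22L), ...) {
  # factorial marker subset: both response directions x both localisations
  specs <- .default_marker_specs()
  specs <- specs[specs$name %in% c("EpCAM", "Ncad", "PTEN", "Vim"), , drop = FALSE]
  sim_config(seed = seed, n_panels = n_panels, fields_per_well = fields_per_well,
             field_size = field_size, cells_per_field = cells_per_field,
             nucleus_radius = 4.5, cell_radius = 11,
             marker_specs = specs, ...)
}

# match segmented cells to ground-truth cells by nearest centroid (in the
# resized frame); returns the ground-truth row index or NA
.match_ground_truth <- function(feat, gt, well, field, resize_factor = 0.5) {
  g <- gt[gt$well == well & gt$field == field, , drop = FALSE]
  if (!nrow(g) || !nrow(feat)) return(rep(NA_integer_, nrow(feat)))
  gx <- g$cx * resize_factor; gy <- g$cy * resize_factor
  vapply(seq_len(nrow(feat)), function(i) {
    d2 <- (gx - feat$cx[i])^2 + (gy - feat$cy[i])^2
    j <- which.min(d2)
    if (d2[j] <= (6 / resize_factor)^2) as.integer(rownames(g)[j]) else NA_integer_
  }, 1L)
}

#' Build the integrated single-cell feature table
#'
#' Segments every field on the real DNA/actin channels and extracts the
#' full feature set for: real anchors (`real_<anchor>`), held-out real
#' variable markers (`real_<marker>`, from ground truth, evaluation only)
#' and the bridged virtual markers (`virt_<marker>`). Rows carry well,
#' field, condition, the matched ground-truth latent state `s`, and a
#' `labelled_marker` column naming the marker experimentally present in
#' that cell's well.
#'
#' @param integrated A `pb_integrated` (from [run_integration()]).
#' @param patchset The `pb_patchset` (with `gt_fields`).
#' @param ground_truth The generator's per-cell ground-truth data.frame.
#' @param manifest The dataset `pb_manifest`.
#' @return Data frame, one row per segmented cell.
#' @export
build_feature_table <- function(integrated, patchset, ground_truth, manifest) {
  plan <- integrated$plan
  anchors <- plan$anchors
  vars <- names(plan$markers)
  var_well <- list()
  for (w in manifest$wells)
    var_well[[w$well_id]] <- intersect(unlist(w$channels), vars)
  rows <- NULL
  for (key in names(integrated$fields)) {
    fd <- integrated$fields[[key]]
    parts <- strsplit(key, "/")[[1]]
    well <- parts[1]; field <- parts[2]
    seg <- segment_cells(fd[["DNA"]], fd[["Actin"]])
    if (seg$n_cells == 0) next
    channels <- list()
    for (a in anchors) channels[[paste0("real_", a)]] <- fd[[a]]
    for (v in vars) {
      channels[[paste0("real_", v)]] <- patchset$gt_fields[[key]][[v]]
      vc <- fd[[v]]
      vc[is.na(vc)] <- 0
      channels[[paste0("virt_", v)]] <- vc
    }
    feat <- extract_features(seg, channels)
    if (!nrow(feat)) next
    gi <- .match_ground_truth(feat, ground_truth, well, field)
    meta <- data.frame(well = well, field = field,
                       condition = integrated$folds$condition[integrated$folds$key == key],
                       labelled_marker = var_well[[well]][1],
                       s = ground_truth$s[gi],
                       stringsAsFactors = FALSE)
    rows <- rbind(rows, cbind(meta, feat))
  }
  rows
}

#' Run a complete bridging-integration study
#'
#' The full framework on a synthetic dataset: simulation, preprocessing,
#' per-marker model training under field-level stratified cross-validation
#' for each requested input mode, image-level fidelity evaluation,
#' single-cell profiling, recipe-based treatment classification,
#' manifold + principal-curve pseudotime, and marker-dynamics curves.
#'
#' @param sim A `pb_sim_config` (default [desk_sim_config()]).
#' @param dir Working directory for the dataset (default a tempdir).
#' @param input_modes Input modes to train (subset of `full`,
#'   `label_free`, `anchors_only`).
#' @param k Cross-validation folds over fields (desk default 2).
#' @param seed Orchestration seed (fold assignment + derived model seeds).
#' @param model_preset `"desk"` or `"paper"`.
#' @param arch `"unet"` or `"cgan"`.
#' @param classify,pseudotime Toggles for the downstream stages (need the
#'   `"full"` input mode).
#' @return A list with the dataset, patchset, per-mode integrations and
#'   evaluations, the feature table, classification results, pseudotime and
#'   dynamics.
#' @export
run_study <- function(sim = desk_sim_config(), dir = file.path(tempdir(), "pb_study"),
                      input_modes = c("full", "label_free"), k = 2L, seed = 0L,
                      model_preset = "desk", arch = "unet",
                      classify = TRUE, pseudotime = TRUE) {
  ds <- simulate_dataset(sim, dir)
  pcfg <- preprocess_config(patch_size = if (model_preset == "desk") 64L else 256L)
  ps <- preprocess_dataset(ds$manifest, pcfg, gt_markers = TRUE)
  mcfg <- model_config(input_channels = "DIC", target_channel = "x",
                       arch = arch, preset = model_preset, seed = seed)

  integrations <- list(); evaluations <- list()
  for (mode in input_modes) {
    plan <- plan_bridging(ds$manifest, mode)
    integ <- run_integration(plan, ps, mcfg, k = k, seed = seed)
    integrations[[mode]] <- integ
    evaluations[[mode]] <- evaluate_integration(integ, ps)
  }

  out <- list(dataset = ds, patchset = ps, integrations = integrations,
              evaluations = evaluations, k = k, seed = seed)
  if (!"full" %in% input_modes || !(classify || pseudotime)) return(out)

  integ <- integrations[["full"]]
  tab <- build_feature_table(integ, ps, ds$ground_truth, ds$manifest)
  out$features <- tab
  vars <- names(integ$plan$markers)
  anchors_real <- paste0("real_", integ$plan$anchors)

  if (classify) {
    recipes <- list(
      anchors_only = feature_recipe("anchors_only", anchors_real),
      full_exif = feature_recipe("full_exif", c(anchors_real, paste0("virt_", vars))),
      all_real = feature_recipe("all_real", c(anchors_real, paste0("real_", vars)))
    )
    out$classification <- lapply(recipes, function(rc)
      classify_treatments(tab, rc, k = 5L, seed = seed))
  }
  if (pseudotime) {
    man_recipe <- feature_recipe("manifold_full_exif",
                                 c(anchors_real, paste0("virt_", vars)),
                                 morphology = FALSE)
    coords <- embed_manifold(tab, man_recipe, method = "pca2")
    pt <- fit_pseudotime(coords, tab$condition, pseudotime_config(n_nodes = 25L))
    out$manifold <- coords
    out$pseudotime <- pt
    subset_real <- lapply(paste0("real_", vars), function(pm) {
      v <- sub("^real_", "", pm)
      tab$labelled_marker == v
    })
    names(subset_real) <- paste0("real_", vars)
    out$dynamics_virtual <- marker_dynamics(tab, pt, paste0("virt_", vars))
    out$dynamics_real <- marker_dynamics(tab, pt, paste0("real_", vars),
                                         subset = subset_real)
  }
  out
}

#' Feature-level fidelity of the integrated table
#'
#' Per marker: Pearson correlation across cells between the real (held-out
#' ground truth) and virtual versions of a feature.
#'
#' @param table Output of [build_feature_table()].
#' @param markers Marker names (unprefixed).
#' @param feature Feature suffix (default mean intensity).
#' @return Named numeric vector of Feature-PCC per marker.
#' @export
table_feature_pcc <- function(table, markers, feature = "Int_MeanIntensity") {
  vapply(markers, function(m) {
    real <- data.frame(cell = seq_len(nrow(table)),
                       f = table[[paste0("real_", m, "_", feature)]])
    virt <- data.frame(cell = seq_len(nrow(table)),
                       f = table[[paste0("virt_", m, "_", feature)]])
    names(real)[2] <- names(virt)[2] <- "f"
    feature_pcc(real, virt, "f")
  }, 0)
}
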