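## Bridging integration: one virtual-labelling model per variable marker,
## trained on the wells experimentally labelled for it and applied to all
## wells, assembling a unified dataset where every field carries every
## marker. Cross-validation folds are assigned at the field level
## (stratified by treatment condition); the model that produces a field's
## virtual value never saw that field as a training target.

#' Plan the bridging integration
#'
#' One model per distinct variable marker; its training wells are the wells
#' whose variable channel is that marker, and it is applied to all wells.
#'
#' @param manifest A `pb_manifest`.
#' @param input_mode `"full"` (label-free + anchors), `"label_free"`
#'   (label-free only) or `"anchors_only"`.
#' @return A `pb_plan`: list with `markers` (per-marker training/apply well
#'   sets and input channels) and `input_mode`.
#' @export
plan_bridging <- function(manifest, input_mode = c("full", "label_free", "anchors_only")) {
  input_mode <- match.arg(input_mode)
  ch <- manifest$channels
  lf <- ch$name[ch$role == "label_free"]
  anchors <- ch$name[ch$role == "anchor"]
  inputs <- switch(input_mode,
                   full = c(lf, anchors),
                   label_free = lf,
                   anchors_only = anchors)
  vars <- ch$name[ch$role == "variable"]
  all_wells <- vapply(manifest$wells, `[[`, "", "well_id")
  markers <- list()
  for (v in vars) {
    tw <- vapply(Filter(function(w) v %in% unlist(w$channels), manifest$wells), `[[`, "", "well_id")
    tc <- unique(vapply(Filter(function(w) v %in% unlist(w$channels), manifest$wells), `[[`, "", "condition"))
    miss <- setdiff(manifest$conditions, tc)
    if (length(miss))
      warning(sprintf("marker %s has no training well in condition(s): %s",
                      v, paste(miss, collapse = ", ")))
    markers[[v]] <- list(marker = v, training_wells = tw, apply_wells = all_wells,
                         input_channels = inputs)
  }
  structure(list(markers = markers, input_mode = input_mode,
                 anchors = anchors, label_free = lf), class = "pb_plan")
}

#' Stratified k-fold assignment
#'
#' Partitions items into `k` folds preserving class proportions within one
#' item per class per fold (per class: shuffle, then deal round-robin).
#'
#' @param labels Class label per item.
#' @param k Number of folds (default 5).
#' @param seed RNG seed.
#' @return Integer fold id (1..k) per item.
#' @export
stratified_kfold <- function(labels, k = 5L, seed = 0L) {
  labels <- as.character(labels)
  tab <- table(labels)
  if (k > min(tab)) stop("k exceeds the smallest class count")
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in names(tab)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Run the bridging integration
#'
#' For each marker and fold: train on the marker's training-well fields
#' outside the fold, then predict the virtual channel for every field inside
#' the fold (all wells) and reassemble tiles into field-sized images. Every
#' field therefore carries all variable markers exactly once, each produced
#' by a model that never saw it as a training target (held-out rule); anchors
#' stay real.
#'
#' @param plan A `pb_plan`.
#' @param patchset A `pb_patchset` from [preprocess_dataset()].
#' @param config A `pb_model_config` (input/target channels are overridden
#'   per marker from the plan).
#' @param k Folds (default 5; fold unit is the field, stratified by
#'   condition).
#' @param seed Seed for fold assignment and per-model training seeds.
#' @param stub If `TRUE`, use the ground-truth pass-through stub instead of
#'   training (requires `patchset$gt_fields`).
#' @param val_fraction Fraction of training tiles held out per model for the
#'   validation-loss curve (0 disables).
#' @return A `pb_integrated`: `fields` (per field: named list of real anchor
#'   / label-free channels + all virtual marker channels), `provenance`
#'   (per field x marker fold id), `models` (per marker x fold training
#'   histories), `folds` (field fold table), `plan`.
#' @export
run_integration <- function(plan, patchset, config, k = 5L, seed = 0L,
                            stub = FALSE, val_fraction = 0) {
  stopifnot(inherits(plan, "pb_plan"), inherits(patchset, "pb_patchset"))
  meta <- patchset$meta
  fields <- unique(meta[, c("key", "well", "field", "condition")])
  fields$fold <- stratified_kfold(fields$condition, k = k, seed = seed)
  meta$fold <- fields$fold[match(meta$key, fields$key)]
  P <- dim(patchset$tiles[[1]])[1]

  out_fields <- lapply(patchset$fields, function(fd) {
    fd[names(fd) %in% c(plan$label_free, plan$anchors)]
  })
  provenance <- list()
  models <- list()

  for (v in names(plan$markers)) {
    mk <- plan$markers[[v]]
    cfg <- config
    cfg$input_channels <- mk$input_channels
    cfg$target_channel <- v
    for (f in seq_len(k)) {
      train_idx <- which(meta$well %in% mk$training_wells & meta$fold != f)
      pred_idx <- which(meta$fold == f)
      if (!length(train_idx)) stop("no training tiles for marker ", v, " fold ", f)
      if (stub) {
        gt <- patchset$gt_fields
        if (is.null(gt)) stop("stub integration requires ground-truth fields")
        model <- stub_oracle_model(v, function(key, r0, c0)
          gt[[key]][[v]][(r0 + 1L):(r0 + P), (c0 + 1L):(c0 + P)])
        preds <- lapply(pred_idx, function(i)
          model$lookup(meta$key[i], meta$row0[i], meta$col0[i]))
      } else {
        cfg$seed <- as.integer((seed * 131071 + match(v, names(plan$markers)) * 8191 + f) %% 2147483647)
        vt <- NULL
        tr <- train_idx
        if (val_fraction > 0 && length(train_idx) >= 4) {
          set.seed(cfg$seed)
          nv <- max(1L, floor(val_fraction * length(train_idx)))
          vi <- sample(train_idx, nv)
          vt <- patchset$tiles[vi]
          tr <- setdiff(train_idx, vi)
        }
        model <- train_virtual_model(patchset$tiles[tr], cfg, val_tiles = vt)
        preds <- predict_channel(model, patchset$tiles[pred_idx])
        models[[paste(v, f, sep = "/")]] <- list(marker = v, fold = f,
                                                 history = model$history, config = cfg)
      }
      for (j in seq_along(pred_idx)) {
        i <- pred_idx[j]
        key <- meta$key[i]
        if (is.null(out_fields[[key]][[v]])) {
          fs <- dim(patchset$fields[[key]][[1]])
          out_fields[[key]][[v]] <- matrix(NA_real_, fs[1], fs[2])
        }
        out_fields[[key]][[v]][(meta$row0[i] + 1L):(meta$row0[i] + P),
                               (meta$col0[i] + 1L):(meta$col0[i] + P)] <- preds[[j]]
        provenance[[paste(key, v, sep = "|")]] <- f
      }
    }
  }
  structure(list(fields = out_fields, provenance = provenance, models = models,
                 folds = fields, plan = plan, patch_size = P),
            class = "pb_integrated")
}

#' @export
print.pb_integrated <- function(x, ...) {
  cat(sprintf("<pb_integrated> %d fields, %d virtual markers, %d-fold, input mode %s\n",
              length(x$fields), length(x$plan$markers),
              max(x$folds$fold), x$plan$input_mode))
  invisible(x)
}
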