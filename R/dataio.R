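## Dataset model: manifest validation and TIFF field I/O.
##
## A dataset is a directory with a YAML (or JSON) manifest describing wells,
## their treatment condition, panel, and per-field multi-page TIFF files.
## Channel identity is by name; the manifest records the page order of every
## well's TIFF stack. Every well carries the same label-free + anchoring
## channels and exactly one variable channel.

#' Load and validate a dataset manifest
#'
#' Reads a YAML or JSON manifest and validates its structural invariants:
#' every well lists the identical anchor set and exactly one variable
#' channel, every referenced image file exists, and every variable channel
#' is represented in at least one well per condition.
#'
#' @param path Path to a `manifest.yaml` / `manifest.json` file.
#' @return A `pb_manifest` object: list with `channels` (data.frame of
#'   `name`, `role`), `wells` (list of per-well records), `root` (dataset
#'   directory) and `conditions`.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = FALSE)
         else yaml::read_yaml(path)
  m <- structure(list(
    channels = data.frame(name = vapply(raw$channels, `[[`, "", "name"),
                          role = vapply(raw$channels, `[[`, "", "role"),
                          stringsAsFactors = FALSE),
    wells = raw$wells,
    root = dirname(normalizePath(path)),
    conditions = unique(vapply(raw$wells, `[[`, "", "condition"))
  ), class = "pb_manifest")
  validate_manifest(m)
  m
}

#' @rdname load_manifest
#' @param manifest A `pb_manifest` object.
#' @export
validate_manifest <- function(manifest) {
  ch <- manifest$channels
  if (!all(ch$role %in% c("label_free", "anchor", "variable")))
    stop("unknown channel role(s): ", paste(setdiff(ch$role, c("label_free", "anchor", "variable")), collapse = ", "))
  anchors <- ch$name[ch$role == "anchor"]
  vars <- ch$name[ch$role == "variable"]
  errs <- character()
  for (w in manifest$wells) {
    wc <- unlist(w$channels)
    miss <- setdiff(anchors, wc)
    if (length(miss))
      errs <- c(errs, sprintf("well %s missing anchor channel(s): %s", w$well_id, paste(miss, collapse = ", ")))
    nv <- intersect(wc, vars)
    if (length(nv) != 1L)
      errs <- c(errs, sprintf("well %s has %d variable channels (need exactly 1)", w$well_id, length(nv)))
    for (f in w$fields) {
      p <- file.path(manifest$root, f$path)
      if (!file.exists(p)) errs <- c(errs, sprintf("well %s field %s: missing file %s", w$well_id, f$field_id, f$path))
    }
  }
  # every variable channel present in >= 1 well per condition
  for (v in vars) {
    conds_with <- unique(vapply(Filter(function(w) v %in% unlist(w$channels), manifest$wells),
                                `[[`, "", "condition"))
    miss <- setdiff(manifest$conditions, conds_with)
    if (length(miss))
      errs <- c(errs, sprintf("variable channel %s absent from condition(s): %s", v, paste(miss, collapse = ", ")))
  }
  if (length(errs)) stop("invalid manifest:\n  ", paste(errs, collapse = "\n  "))
  invisible(manifest)
}

#' @export
print.pb_manifest <- function(x, ...) {
  cat(sprintf("<pb_manifest> %d wells, %d conditions, %d channels (%d anchor, %d variable)\n",
              length(x$wells), length(x$conditions), nrow(x$channels),
              sum(x$channels$role == "anchor"), sum(x$channels$role == "variable")))
  invisible(x)
}

.find_well <- function(manifest, well_id) {
  for (w in manifest$wells) if (w$well_id == well_id) return(w)
  stop("unknown well_id: ", well_id)
}

#' Read one imaging field
#'
#' Returns the channel images of one field of one well, in the well's
#' manifest channel order, as a named list of numeric matrices. 16-bit TIFF
#' input is returned on the integer scale 0..65535, 8-bit on 0..255.
#'
#' @param manifest A `pb_manifest`.
#' @param well_id,field_id Identifiers as listed in the manifest.
#' @return Named list of matrices, one per channel, all the same shape.
#' @export
read_field <- function(manifest, well_id, field_id) {
  w <- .find_well(manifest, well_id)
  f <- NULL
  for (fl in w$fields) if (fl$field_id == field_id) f <- fl
  if (is.null(f)) stop("unknown field_id: ", field_id, " in well ", well_id)
  imgs <- read_field_tiff(file.path(manifest$root, f$path))
  chn <- unlist(w$channels)
  if (length(imgs) != length(chn))
    stop(sprintf("field %s/%s: %d TIFF pages but %d channels in manifest",
                 well_id, field_id, length(imgs), length(chn)))
  names(imgs) <- chn
  shp <- vapply(imgs, function(x) paste(dim(x), collapse = "x"), "")
  if (length(unique(shp)) != 1L)
    stop("channel shape mismatch in ", well_id, "/", field_id, ": ", paste(unique(shp), collapse = " vs "))
  imgs
}

#' Write / read multi-page TIFF stacks
#'
#' `write_field_tiff()` writes a named list of matrices as one multi-page
#' TIFF (one page per channel); `read_field_tiff()` reads it back. Values
#' are integer grey levels; `bits` selects 8- or 16-bit storage and the
#' round trip is lossless for integral input within range.
#'
#' @param images Named list of numeric matrices (grey levels, 0..2^bits-1).
#' @param path Output path.
#' @param bits 8 or 16.
#' @export
write_field_tiff <- function(images, path, bits = 16L) {
  stopifnot(bits %in% c(8L, 16L))
  mx <- 2^bits - 1
  pages <- lapply(images, function(im) {
    im <- pmin(pmax(im, 0), mx)
    im / mx
  })
  tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "none")
  invisible(path)
}

#' @rdname write_field_tiff
#' @export
read_field_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(p) {
    bits <- attr(p, "bits.per.sample")
    if (is.null(bits)) bits <- 16L
    round(p * (2^bits - 1))
  })
}

.write_manifest <- function(channels, wells, path) {
  obj <- list(
    format = "plexbridge-manifest-v1",
    channels = lapply(seq_len(nrow(channels)), function(i)
      list(name = channels$name[i], role = channels$role[i])),
    wells = wells
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}
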