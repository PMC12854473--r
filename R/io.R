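# Readers and writers for every external representation the pipeline touches:
# nucleus annotation JSON (HoVer-Net dialect), binary tumor-mask rasters,
# flat feature-vector JSON, and cohort CSV tables.

#' Construct a slide annotation
#'
#' A slide annotation bundles the per-nucleus table of one whole-slide image
#' with its physical metadata. The nucleus table is an ordinary tibble so the
#' usual dplyr verbs apply to it directly.
#'
#' @param nuclei A tibble with columns `instance_id` (unique positive
#'   integers), `x`, `y` (centroid, pixels of the full-resolution nucleus
#'   frame, 0-based, x = column, y = row, origin top-left), `contour`
#'   (list-column of n x 2 matrices, n >= 3) and `class` (integer code, see
#'   [class_codes()]). A `tumor_region_id` column is added by
#'   [assign_nuclei_to_regions()].
#' @param mpp Microns per pixel of the nucleus coordinate frame (> 0).
#' @param image_size Integer vector `c(width, height)` in pixels.
#' @param sample_id Sample identifier string.
#'
#' @return An object of class `slide_annotation`.
#' @export
slide_annotation <- function(nuclei, mpp, image_size, sample_id = "sample") {
  nuclei <- as_tibble(nuclei)
  required <- c("instance_id", "x", "y", "contour", "class")
  missing_cols <- setdiff(required, names(nuclei))
  if (length(missing_cols) > 0) {
    abort(paste0("nuclei table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(nuclei$instance_id)) {
    abort("instance_id values must be unique")
  }
  if (!is.numeric(mpp) || length(mpp) != 1 || is.na(mpp) || mpp <= 0) {
    abort("mpp must be a single positive number")
  }
  if (length(image_size) != 2 || any(image_size <= 0)) {
    abort("image_size must be c(width, height), both positive")
  }
  if (nrow(nuclei) > 0) {
    oob <- nuclei$x < 0 | nuclei$x >= image_size[1] |
      nuclei$y < 0 | nuclei$y >= image_size[2]
    if (any(oob)) {
      abort(sprintf("%d nucleus centroid(s) fall outside the image bounds",
                    sum(oob)))
    }
  }
  structure(
    list(nuclei = nuclei, mpp = mpp,
         image_size = as.integer(image_size), sample_id = sample_id),
    class = "slide_annotation"
  )
}

#' @export
print.slide_annotation <- function(x, ...) {
  cat(sprintf("<slide_annotation> %s: %d nuclei, %d x %d px, %.3f um/px\n",
              x$sample_id, nrow(x$nuclei), x$image_size[1], x$image_size[2],
              x$mpp))
  counts <- table(class_name(x$nuclei$class))
  if (length(counts) > 0) {
    cat("  ", paste(sprintf("%s=%d", names(counts), counts), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Tidy a slide annotation into its nucleus table
#'
#' @param x A `slide_annotation`.
#' @param ... Unused.
#' @return The nucleus tibble with a `class_name` column added.
#' @export
tidy.slide_annotation <- function(x, ...) {
  mutate(x$nuclei, class_name = class_name(.data$class))
}

#' Read a nucleus annotation JSON file
#'
#' Parses the HoVer-Net style annotation dialect: a JSON object whose `nuc`
#' entry (or, failing that, the whole top level) maps instance ids to objects
#' with `centroid` (x, y), `contour` (list of (x, y) vertices) and `type`
#' (integer class code). Coordinates are taken verbatim; no scaling is
#' applied. Optional top-level `mpp`, `image_size` and `sample_id` entries are
#' honoured when present.
#'
#' @param path Path to the JSON file.
#' @param allowed_classes Integer class codes accepted in the file. Raw model
#'   output uses 1..5; files written after [reclassify_epithelial()] also
#'   contain 6, so pass `1:6` to re-read refined annotations.
#' @param mpp,image_size,sample_id Overrides used when the file carries no
#'   metadata block. `image_size` defaults to a tight bound on the centroids.
#'
#' @return A [slide_annotation()].
#' @export
read_nucleus_json <- function(path, allowed_classes = 1:5, mpp = NULL,
                              image_size = NULL, sample_id = NULL) {
  if (!file.exists(path)) abort(paste0("no such annotation file: ", path))
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  meta_keys <- c("mpp", "image_size", "sample_id", "mag")
  if (!is.null(raw$nuc)) {
    inst <- raw$nuc
    mpp <- mpp %||% raw$mpp
    image_size <- image_size %||% raw$image_size
    sample_id <- sample_id %||% raw$sample_id
  } else {
    inst <- raw[setdiff(names(raw), meta_keys)]
    mpp <- mpp %||% raw$mpp
    image_size <- image_size %||% raw$image_size
    sample_id <- sample_id %||% raw$sample_id
  }
  n <- length(inst)
  ids <- names(inst)
  parse_one <- function(obj, id) {
    cen <- suppressWarnings(as.numeric(unlist(obj$centroid)))
    if (length(cen) != 2 || anyNA(cen) || any(!is.finite(cen))) {
      abort(sprintf("instance %s: missing or non-finite centroid", id))
    }
    ctr <- obj$contour
    if (is.list(ctr)) ctr <- do.call(rbind, lapply(ctr, unlist))
    ctr <- matrix(as.numeric(ctr), ncol = 2)
    cls <- obj$type
    if (is.null(cls) || is.na(cls) || !(as.integer(cls) %in% allowed_classes)) {
      abort(sprintf(
        "instance %s: class code %s not among allowed codes {%s}",
        id, as.character(cls %||% "NULL"),
        paste(allowed_classes, collapse = ",")))
    }
    list(instance_id = as.integer(id), x = cen[1], y = cen[2],
         contour = ctr, class = as.integer(cls))
  }
  parsed <- imap(inst, parse_one)
  nuclei <- tibble(
    instance_id = unname(map_int(parsed, "instance_id")),
    x = unname(map_dbl(parsed, "x")),
    y = unname(map_dbl(parsed, "y")),
    contour = unname(map(parsed, "contour")),
    class = unname(map_int(parsed, "class"))
  )
  if (nrow(nuclei) != n) abort("parser dropped instances")  # never silent
  if (is.null(image_size)) {
    image_size <- if (n > 0) c(ceiling(max(nuclei$x)) + 1,
                               ceiling(max(nuclei$y)) + 1) else c(1, 1)
  }
  image_size <- as.numeric(unlist(image_size))
  slide_annotation(nuclei, mpp = mpp %||% 1.0, image_size = image_size,
                   sample_id = sample_id %||% basename_noext(path))
}

basename_noext <- function(path) sub("\\.[^.]*$", "", basename(path))

#' Write a nucleus annotation JSON file
#'
#' Inverse of [read_nucleus_json()]: writes the `nuc` mapping plus the
#' metadata block, so that a read of the written file reproduces the
#' annotation field for field.
#'
#' @param annotation A [slide_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_nucleus_json <- function(annotation, path) {
  stopifnot(inherits(annotation, "slide_annotation"))
  nuc <- annotation$nuclei
  inst <- vector("list", nrow(nuc))
  names(inst) <- as.character(nuc$instance_id)
  for (i in seq_len(nrow(nuc))) {
    inst[[i]] <- list(
      centroid = c(nuc$x[i], nuc$y[i]),
      contour = nuc$contour[[i]],
      type = nuc$class[i]
    )
  }
  out <- list(
    mpp = annotation$mpp,
    image_size = annotation$image_size,
    sample_id = annotation$sample_id,
    nuc = inst
  )
  json <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA)
  writeLines(json, path)
  invisible(path)
}

#' Construct a tumor mask
#'
#' @param raster Binary matrix (rows = y, cols = x) at mask resolution;
#'   any nonzero entry counts as tumor.
#' @param downsample Integer >= 1: one mask pixel spans `downsample` pixels of
#'   the nucleus coordinate frame. Point (x, y) in nucleus-frame pixels lies
#'   in mask pixel `[floor(y / downsample) + 1, floor(x / downsample) + 1]`.
#' @return An object of class `tumor_mask`.
#' @export
tumor_mask <- function(raster, downsample = 1L) {
  if (!is.matrix(raster)) abort("raster must be a matrix")
  if (length(downsample) != 1 || is.na(downsample) || downsample < 1) {
    abort("downsample must be a single integer >= 1")
  }
  raster <- matrix(as.integer(raster != 0), nrow(raster), ncol(raster))
  structure(list(raster = raster, downsample = as.integer(downsample)),
            class = "tumor_mask")
}

#' @export
print.tumor_mask <- function(x, ...) {
  cat(sprintf("<tumor_mask> %d x %d px (downsample %d), %d tumor px (%.1f%%)\n",
              ncol(x$raster), nrow(x$raster), x$downsample, sum(x$raster),
              100 * mean(x$raster)))
  invisible(x)
}

#' Read a binary tumor mask from a PNG or TIFF raster
#'
#' Any nonzero pixel counts as tumor. Multi-channel images are accepted only
#' when all channels agree on which pixels are nonzero.
#'
#' @param path PNG or single-page TIFF file.
#' @param downsample Integer >= 1 mapping mask pixels to nucleus-frame pixels.
#' @return A [tumor_mask()].
#' @export
read_tumor_mask <- function(path, downsample = 1L) {
  if (downsample < 1) abort("downsample must be >= 1")
  if (!file.exists(path)) abort(paste0("no such mask file: ", path))
  ext <- tolower(sub(".*\\.", "", path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    abort(paste0("unsupported mask format: .", ext, " (use PNG or TIFF)"))
  )
  if (length(dim(img)) == 3) {
    nch <- dim(img)[3]
    bin <- img[, , 1] != 0
    for (k in seq_len(nch)[-1]) {
      if (k == nch && nch %in% c(2, 4)) next  # alpha channel ignored
      if (!identical(bin, img[, , k] != 0)) {
        abort("multi-channel mask with conflicting channels")
      }
    }
    img <- img[, , 1]
  }
  tumor_mask(img != 0, downsample = downsample)
}

#' Write a tumor mask as PNG
#'
#' @param mask A [tumor_mask()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_tumor_mask <- function(mask, path) {
  stopifnot(inherits(mask, "tumor_mask"))
  png::writePNG(mask$raster * 1.0, path)
  invisible(path)
}

#' Write a feature vector as flat JSON
#'
#' Serializes one slide's feature vector as a flat JSON object in registry
#' order. Missing values (undefined features, e.g. a distance in a slide with
#' no tumor) are encoded as JSON `null` and round-trip back to `NA`.
#'
#' @param features A tibble with columns `feature` and `value`, as returned
#'   by [compute_features()].
#' @param path Output path.
#' @param registry Feature registry the vector must conform to (name set and
#'   order); defaults to [feature_registry()].
#' @return `path`, invisibly.
#' @export
write_feature_json <- function(features, path, registry = feature_registry()) {
  if (!all(c("feature", "value") %in% names(features))) {
    abort("features must have columns feature, value")
  }
  unknown <- setdiff(features$feature, registry$name)
  if (length(unknown) > 0) {
    abort(paste0("value(s) for unknown feature name(s): ",
                 paste(head(unknown, 3), collapse = ", ")))
  }
  if (!identical(features$feature, registry$name)) {
    abort("feature names/order do not match the registry")
  }
  vals <- as.list(features$value)
  names(vals) <- features$feature
  json <- jsonlite::toJSON(vals, auto_unbox = TRUE, digits = NA, na = "null")
  writeLines(json, path)
  invisible(path)
}

#' Read a feature-vector JSON file
#'
#' @param path Path written by [write_feature_json()].
#' @return A tibble with columns `feature`, `value` in file order; JSON nulls
#'   become `NA`.
#' @export
read_feature_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  tibble(
    feature = names(raw),
    value = unname(map_dbl(raw,
                           ~ if (is.null(.x)) NA_real_ else as.numeric(.x)))
  )
}

#' Read a cohort table
#'
#' @param path CSV with header `sample_id,label,annotation_path,mask_path`;
#'   labels must be `responder` / `non_responder`.
#' @return A tibble, one row per sample.
#' @export
read_cohort <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("sample_id", "label")
  if (!all(need %in% names(tab))) {
    abort("cohort CSV needs at least columns sample_id, label")
  }
  bad <- setdiff(unique(tab$label), c("responder", "non_responder"))
  if (length(bad) > 0) {
    abort(paste0("unknown label(s): ", paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(tab$sample_id)) abort("sample_id values must be unique")
  as_tibble(tab)
}
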