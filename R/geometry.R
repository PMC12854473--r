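# Tumor-region geometry: connected-component labeling of the mask, nucleus to
# region assignment, the epithelial refinement rule, and the 1 mm vicinity
# ring around the tumor.

#' Label connected tumor regions
#'
#' Connected-component labeling of the binary tumor mask with 8-connectivity
#' (diagonal contact joins regions). Bounding boxes are reported in
#' nucleus-frame pixels, i.e. mask coordinates scaled by the downsample
#' factor, so that the box side lengths feed directly into the
#' expanding-rectangle distance search.
#'
#' @param mask A [tumor_mask()].
#' @param mpp Microns per pixel of the nucleus frame, used to report region
#'   areas in mm^2. Optional; areas are `NA` when absent.
#' @param connectivity 8 (default) or 4.
#' @return An object of class `tumor_regions`: the integer label raster plus a
#'   tibble `regions` with columns `region_id`, `x_min`, `y_min`, `l` (box
#'   length along x), `w` (box width along y), `n_pixels`, `area_mm2`.
#' @export
label_tumor_regions <- function(mask, mpp = NULL, connectivity = 8) {
  stopifnot(inherits(mask, "tumor_mask"))
  if (!connectivity %in% c(4, 8)) abort("connectivity must be 4 or 8")
  lab <- label_components(mask$raster, connectivity)
  k <- max(lab)
  ds <- mask$downsample
  px_area_mm2 <- if (is.null(mpp)) NA_real_ else (mpp * ds / 1000)^2
  if (k == 0) {
    regions <- tibble(region_id = integer(), x_min = numeric(),
                      y_min = numeric(), l = numeric(), w = numeric(),
                      n_pixels = integer(), area_mm2 = numeric())
  } else {
    idx <- which(lab > 0, arr.ind = TRUE)
    ids <- lab[lab > 0]
    regions <- tibble(region_id = ids,
                      row = idx[, 1] - 1L, col = idx[, 2] - 1L) |>
      group_by(.data$region_id) |>
      summarise(
        x_min = min(.data$col) * ds,
        y_min = min(.data$row) * ds,
        l = (max(.data$col) - min(.data$col) + 1) * ds,
        w = (max(.data$row) - min(.data$row) + 1) * ds,
        n_pixels = n(),
        .groups = "drop"
      ) |>
      mutate(area_mm2 = .data$n_pixels * px_area_mm2) |>
      arrange(.data$region_id)
  }
  structure(list(label_raster = lab, regions = regions,
                 downsample = ds, mpp = mpp),
            class = "tumor_regions")
}

#' @export
print.tumor_regions <- function(x, ...) {
  cat(sprintf("<tumor_regions> %d region(s), downsample %d\n",
              nrow(x$regions), x$downsample))
  if (nrow(x$regions) > 0) print(x$regions)
  invisible(x)
}

# 8-connectivity labeling: EBImage::bwlabel is 4-connected, so labels that
# touch only diagonally are merged afterwards with a union-find pass.
label_components <- function(raster, connectivity = 8) {
  # EBImage images are indexed [x, y]; transpose so our [row, col] raster maps
  # correctly and back.
  lab <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(raster)))))
  lab <- matrix(as.integer(lab), nrow(raster), ncol(raster))
  k <- max(lab)
  if (connectivity == 4 || k < 2) return(relabel_contiguous(lab))
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  nr <- nrow(lab); nc <- ncol(lab)
  for (shift in list(c(1L, 1L), c(1L, -1L))) {
    a <- lab[seq_len(nr - 1), if (shift[2] == 1) seq_len(nc - 1) else 2:nc]
    b <- lab[2:nr, if (shift[2] == 1) 2:nc else seq_len(nc - 1)]
    touch <- which(a > 0 & b > 0 & a != b)
    if (length(touch) > 0) {
      pairs <- unique(cbind(a[touch], b[touch]))
      for (p in seq_len(nrow(pairs))) union_(pairs[p, 1], pairs[p, 2])
    }
  }
  roots <- vapply(seq_len(k), find, integer(1))
  lab[lab > 0] <- roots[lab[lab > 0]]
  relabel_contiguous(lab)
}

relabel_contiguous <- function(lab) {
  ids <- sort(unique(lab[lab > 0]))
  if (length(ids) == 0) return(lab)
  remap <- integer(max(ids))
  remap[ids] <- seq_along(ids)
  lab[lab > 0] <- remap[lab[lab > 0]]
  lab
}

# Region label (0 = background) at nucleus-frame points; points off the
# raster map to 0.
region_at <- function(label_raster, downsample, x, y) {
  row <- floor(y / downsample) + 1
  col <- floor(x / downsample) + 1
  ok <- row >= 1 & row <= nrow(label_raster) & col >= 1 & col <= ncol(label_raster)
  out <- integer(length(x))
  out[ok] <- label_raster[cbind(row[ok], col[ok])]
  out
}

#' Assign nuclei to tumor regions
#'
#' Each nucleus gets `tumor_region_id` = label of the mask pixel under its
#' centroid (0 when the centroid falls on background or off the mask raster).
#' Membership is decided at the centroid only; contours play no role.
#'
#' @param annotation A [slide_annotation()].
#' @param regions A [label_tumor_regions()] result from the same slide.
#' @return The annotation with a `tumor_region_id` column on its nucleus
#'   table. The number of centroids falling off the raster is reported via a
#'   message and stored in attribute `n_off_raster`.
#' @export
assign_nuclei_to_regions <- function(annotation, regions) {
  stopifnot(inherits(annotation, "slide_annotation"),
            inherits(regions, "tumor_regions"))
  nuc <- annotation$nuclei
  ds <- regions$downsample
  lab <- regions$label_raster
  row <- floor(nuc$y / ds) + 1
  col <- floor(nuc$x / ds) + 1
  off <- row < 1 | row > nrow(lab) | col < 1 | col > ncol(lab)
  ids <- integer(nrow(nuc))
  ids[!off] <- lab[cbind(row[!off], col[!off])]
  if (any(off)) {
    inform(sprintf("%d centroid(s) beyond the mask raster treated as background",
                   sum(off)))
  }
  annotation$nuclei$tumor_region_id <- ids
  attr(annotation, "n_off_raster") <- sum(off)
  annotation
}

#' Reclassify tumor-called nuclei outside tumor regions as epithelial
#'
#' Tumor and non-neoplastic epithelial nuclei are morphologically close, so a
#' nucleus-level classifier cannot separate them; the tissue-level tumor
#' segmentation can. Every nucleus carrying the tumor class (5) whose centroid
#' lies outside all segmented tumor regions (`tumor_region_id == 0`) is
#' relabeled as non-neoplastic epithelial (6). All other records are
#' untouched, so the rule is idempotent and conserves the counts of classes
#' 1-4.
#'
#' @param annotation A [slide_annotation()] that has been through
#'   [assign_nuclei_to_regions()].
#' @return The refined annotation; attribute `n_reclassified` holds the
#'   number of relabeled nuclei.
#' @export
reclassify_epithelial <- function(annotation) {
  stopifnot(inherits(annotation, "slide_annotation"))
  nuc <- annotation$nuclei
  if (!"tumor_region_id" %in% names(nuc)) {
    abort("run assign_nuclei_to_regions() before reclassify_epithelial()")
  }
  hit <- nuc$class == CLASS_CODES[["tumor"]] & nuc$tumor_region_id == 0L
  annotation$nuclei$class[hit] <- CLASS_CODES[["epithelial"]]
  attr(annotation, "n_reclassified") <- sum(hit)
  annotation
}

#' Compute the tumor-vicinity ring
#'
#' The vicinity of the tumor is a band of fixed physical width (default 1 mm)
#' around the union of all tumor regions: the Euclidean dilation of the tumor
#' by `width_mm`, minus the tumor itself. Computed at mask resolution with a
#' distance transform, so every ring pixel is within `width_mm` of some tumor
#' pixel.
#'
#' @param regions A [label_tumor_regions()] result.
#' @param mpp Microns per pixel of the nucleus frame (defaults to the value
#'   stored in `regions`).
#' @param width_mm Ring width in millimetres (> 0), default 1.
#' @return Binary matrix at mask resolution: 1 = vicinity ring.
#' @export
compute_vicinity <- function(regions, mpp = NULL, width_mm = 1) {
  stopifnot(inherits(regions, "tumor_regions"))
  mpp <- mpp %||% regions$mpp
  if (is.null(mpp)) abort("mpp must be supplied (not stored in regions)")
  if (width_mm <= 0) abort("width_mm must be > 0")
  px_um <- mpp * regions$downsample
  radius <- round(width_mm * 1000 / px_um)
  if (radius < 1) {
    abort("vicinity width is below one mask pixel; decrease the downsample")
  }
  tum <- regions$label_raster > 0
  if (!any(tum)) return(matrix(0L, nrow(tum), ncol(tum)))
  # distance of every background pixel to the nearest tumor pixel
  dist_bg <- t(EBImage::imageData(EBImage::distmap(EBImage::Image(t(1 - tum)))))
  ring <- !tum & dist_bg <= radius
  matrix(as.integer(ring), nrow(tum), ncol(tum))
}
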