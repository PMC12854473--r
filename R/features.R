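# The feature engine: computes one slide's 317-feature encoding from the
# refined annotation, the labeled tumor regions and the vicinity ring.

#' Smoothed log count ratio
#'
#' The ratio between two cell-class counts used throughout the feature
#' catalogue: `(log(n_a) + epsilon) / (log(n_b) + epsilon)` with a small
#' smoothness term `epsilon` to limit outliers. With equal counts the ratio
#' is exactly 1; it is undefined (`NA`) when either count is zero.
#'
#' @param n_a,n_b Non-negative counts (vectorized).
#' @param epsilon Smoothness parameter, default `1e-3`.
#' @param base Logarithm base, default natural.
#' @return Numeric vector; `NA` where either count is zero.
#' @export
#' @examples
#' smoothed_log_ratio(10, 10)    # 1
#' smoothed_log_ratio(100, 10)   # ~ 2
smoothed_log_ratio <- function(n_a, n_b, epsilon = 1e-3, base = exp(1)) {
  if (any(n_a < 0, na.rm = TRUE) || any(n_b < 0, na.rm = TRUE)) {
    abort("counts must be non-negative")
  }
  if (epsilon <= 0) abort("epsilon must be > 0")
  out <- (log(n_a, base = base) + epsilon) / (log(n_b, base = base) + epsilon)
  out[n_a == 0 | n_b == 0] <- NA_real_
  out
}

# Zone of each nucleus (tumor / vicinity / outside) plus zone areas in mm^2.
# Areas are measured on the mask grid so the three zones tile the raster.
zone_data <- function(annotation, regions, vicinity, mpp = NULL) {
  mpp <- mpp %||% annotation$mpp
  ds <- regions$downsample
  nuc <- annotation$nuclei
  if (!"tumor_region_id" %in% names(nuc)) {
    abort("run assign_nuclei_to_regions() first")
  }
  in_ring <- region_at(vicinity, ds, nuc$x, nuc$y) > 0
  zone <- ifelse(nuc$tumor_region_id > 0L, "tumor",
                 ifelse(in_ring, "vicinity", "outside"))
  px_mm2 <- (mpp * ds / 1000)^2
  n_tum <- sum(regions$label_raster > 0)
  n_ring <- sum(vicinity > 0)
  n_all <- length(regions$label_raster)
  areas <- c(whole = n_all, tumor = n_tum, vicinity = n_ring,
             outside = n_all - n_tum - n_ring) * px_mm2
  list(zone = zone, areas = areas)
}

zone_count <- function(nuc, zone, zname, classes) {
  in_zone <- if (zname == "whole") rep(TRUE, length(zone)) else zone == zname
  sum(in_zone & nuc$class %in% classes)
}

class_code_set <- function(cl) {
  switch(cl,
    immune = unname(CLASS_CODES[IMMUNE_CLASSES]),
    all = unname(CLASS_CODES),
    unname(CLASS_CODES[[cl]])
  )
}

#' Fraction of a cell class within a zone
#'
#' @param annotation A refined, region-assigned [slide_annotation()].
#' @param regions The matching [label_tumor_regions()] result.
#' @param class_label Class name (see [class_codes()]) or `"immune"`.
#' @param zone One of `"whole"`, `"tumor"`, `"vicinity"`, `"outside"`.
#' @param vicinity Ring raster from [compute_vicinity()].
#' @return Fraction in `[0, 1]`, or `NA` if the zone holds no cells.
#' @export
class_fraction <- function(annotation, regions, class_label, zone,
                           vicinity = compute_vicinity(regions,
                                                       annotation$mpp)) {
  if (!zone %in% ZONES) abort(paste0("unknown zone: ", zone))
  zd <- zone_data(annotation, regions, vicinity)
  n_tot <- zone_count(annotation$nuclei, zd$zone, zone, unname(CLASS_CODES))
  if (n_tot == 0) return(NA_real_)
  zone_count(annotation$nuclei, zd$zone, zone, class_code_set(class_label)) / n_tot
}

#' Cell density of a class within a zone
#'
#' @inheritParams class_fraction
#' @param mpp Microns per pixel (defaults to the annotation's).
#' @return Cells per mm^2, or `NA` if the zone has zero area.
#' @export
cell_density <- function(annotation, regions, class_label, zone,
                         vicinity = compute_vicinity(regions, annotation$mpp),
                         mpp = NULL) {
  if (!zone %in% ZONES) abort(paste0("unknown zone: ", zone))
  zd <- zone_data(annotation, regions, vicinity, mpp)
  if (zd$areas[[zone]] <= 0) return(NA_real_)
  zone_count(annotation$nuclei, zd$zone, zone, class_code_set(class_label)) /
    zd$areas[[zone]]
}

#' Compute the full feature vector of one slide
#'
#' Evaluates every registry entry on a refined, region-assigned slide:
#' per-zone class fractions and densities, zone repartitions of each class,
#' smoothed log and raw count ratios, and the expanding-rectangle average
#' closest-cell distances inside tumor regions. Values that are undefined on
#' the slide (an empty zone, a zero count in a ratio, a distance with no
#' eligible source) are `NA` and serialize as JSON `null`.
#'
#' @param annotation A [slide_annotation()] after [assign_nuclei_to_regions()]
#'   and [reclassify_epithelial()].
#' @param regions The matching [label_tumor_regions()] result.
#' @param vicinity Optional precomputed ring raster; computed at `width_mm`
#'   when absent.
#' @param registry Feature registry; defaults to [feature_registry()].
#' @param cfg [search_config()] for the distance family.
#' @param mpp Microns per pixel (defaults to the annotation's).
#' @param width_mm Vicinity ring width in mm, default 1.
#' @return A tibble with columns `feature`, `value` in registry order;
#'   attribute `sample_id` carries the slide id.
#' @export
compute_features <- function(annotation, regions, vicinity = NULL,
                             registry = feature_registry(),
                             cfg = search_config(), mpp = NULL,
                             width_mm = 1) {
  stopifnot(inherits(annotation, "slide_annotation"),
            inherits(regions, "tumor_regions"))
  mpp <- mpp %||% annotation$mpp
  nuc <- annotation$nuclei
  if (!"tumor_region_id" %in% names(nuc)) {
    abort("run assign_nuclei_to_regions() first")
  }
  if (any(nuc$class == CLASS_CODES[["tumor"]] & nuc$tumor_region_id == 0L)) {
    abort("run reclassify_epithelial() first")
  }
  if (is.null(vicinity)) {
    vicinity <- compute_vicinity(regions, mpp, width_mm = width_mm)
  }
  zd <- zone_data(annotation, regions, vicinity, mpp)

  # per-class, per-zone counts (rows: 6 classes; cols: 4 zones)
  counts <- sapply(ZONES, function(z) {
    vapply(CELL_CLASSES,
           function(cl) zone_count(nuc, zd$zone, z, CLASS_CODES[[cl]]),
           numeric(1))
  })
  totals <- colSums(counts)
  immune <- colSums(counts[IMMUNE_CLASSES, , drop = FALSE])

  # distances: all ordered pairs, computed once, both units read off
  dist_px <- matrix(NA_real_, 4, 4,
                    dimnames = list(DISTANCE_CLASSES, DISTANCE_CLASSES))
  for (a in DISTANCE_CLASSES) {
    for (b in DISTANCE_CLASSES) {
      res <- pair_min_distances(nuc, regions, CLASS_CODES[[a]],
                                CLASS_CODES[[b]], cfg)
      found <- res$dists[!is.na(res$dists)]
      if (length(found) > 0) dist_px[a, b] <- mean(found)
    }
  }

  eval_one <- function(i) {
    fam <- registry$family[i]
    z <- registry$zone[i]
    a <- registry$source_class[i]
    b <- registry$target_class[i]
    if (fam == "fraction") {
      if (totals[[z]] == 0) return(NA_real_)
      n <- if (a == "immune") immune[[z]] else counts[a, z]
      return(n / totals[[z]])
    }
    if (fam == "density") {
      if (zd$areas[[z]] <= 0) return(NA_real_)
      n <- switch(a, immune = immune[[z]], all = totals[[z]], counts[a, z])
      return(n / zd$areas[[z]])
    }
    if (fam == "repartition") {
      tot_cl <- counts[a, "whole"]
      if (tot_cl == 0) return(NA_real_)
      return(counts[a, z] / tot_cl)
    }
    if (fam == "ratio") {
      na <- counts[a, z]; nb <- counts[b, z]
      if (registry$variant[i] == "log") {
        return(smoothed_log_ratio(na, nb))
      }
      if (nb == 0) return(NA_real_)
      return(na / nb)
    }
    # distance
    if (registry$variant[i] == "um") dist_px[a, b] * mpp else dist_px[a, b]
  }

  values <- vapply(seq_len(nrow(registry)), eval_one, numeric(1))
  out <- tibble(feature = registry$name, value = values)
  attr(out, "sample_id") <- annotation$sample_id
  out
}
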