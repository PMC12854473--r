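# The feature registry: the ordered catalogue of the 317 named features that
# make up one slide's encoding. The 107 entries flagged `structure = TRUE`
# describe tissue architecture in size-independent units and form the default
# analysis subset used for response modelling; the remaining 210 are raw or
# unit-variant companions (counts enter only through ratios, never directly).
# The enumeration is deliberately explicit and versioned so a different
# catalogue can be swapped in verbatim.

REGISTRY_VERSION <- "1.0"

ZONES <- c("whole", "tumor", "vicinity", "outside")
CELL_CLASSES <- names(CLASS_CODES)
IMMUNE_CLASSES <- c("granulocyte", "lymphocyte", "plasma")
DISTANCE_CLASSES <- c("granulocyte", "lymphocyte", "plasma", "tumor")

#' The default feature registry
#'
#' Enumerates the 317 whole-slide features over five families:
#'
#' * `fraction` - share of a cell class among all cells of a zone (plus
#'   composite immune fractions);
#' * `density` - cells per mm^2 of a class in a zone (plus composite immune
#'   densities and overall cellularity);
#' * `repartition` - how one class's cells split across the tumor interior,
#'   the 1 mm vicinity ring, and the remaining tissue;
#' * `ratio` - smoothed log count ratios (variant `log`, the analysis form)
#'   and raw count ratios (variant `raw`) between class pairs in a zone;
#' * `distance` - expanding-rectangle average closest-cell distances inside
#'   tumor regions, in microns (analysis form) and pixels.
#'
#' Exactly 107 entries carry `structure = TRUE`: the size- and
#' unit-independent tissue-architecture subset used for feature selection.
#' Log-ratio structure entries cover unordered class pairs in the tumor and
#' vicinity zones; pairs involving the epithelial class are excluded in the
#' tumor zone because the refinement step makes epithelial cells inside tumor
#' regions impossible by construction. No nucleus-morphology features (area,
#' circularity) exist in the catalogue.
#'
#' @return A tibble with columns `name`, `family`, `zone`, `source_class`,
#'   `target_class`, `variant`, `structure`, in canonical order; attribute
#'   `version` carries the registry version string.
#' @export
#' @examples
#' reg <- feature_registry()
#' nrow(reg)              # 317
#' sum(reg$structure)     # 107
feature_registry <- function() {
  if (!is.null(.registry_cache$reg)) return(.registry_cache$reg)
  spec <- function(name, family, zone, source_class = NA_character_,
                   target_class = NA_character_, variant = NA_character_,
                   structure = FALSE) {
    list(name = name, family = family, zone = zone,
         source_class = source_class, target_class = target_class,
         variant = variant, structure = structure)
  }

  rows <- list()

  # -- fractions: 6 classes x 4 zones (structure) + immune composite x 4
  for (z in ZONES) {
    for (cl in CELL_CLASSES) {
      rows[[length(rows) + 1]] <- spec(
        paste0("fraction_", cl, "_", z), "fraction", z,
        source_class = cl, structure = TRUE)
    }
    rows[[length(rows) + 1]] <- spec(
      paste0("fraction_immune_", z), "fraction", z, source_class = "immune")
  }

  # -- densities: 6 classes x 4 zones (structure) + immune composite x 4
  #    + overall cellularity
  for (z in ZONES) {
    for (cl in CELL_CLASSES) {
      rows[[length(rows) + 1]] <- spec(
        paste0("density_", cl, "_", z, "_mm2"), "density", z,
        source_class = cl, structure = TRUE)
    }
    rows[[length(rows) + 1]] <- spec(
      paste0("density_immune_", z, "_mm2"), "density", z,
      source_class = "immune")
  }
  rows[[length(rows) + 1]] <- spec(
    "density_all_whole_mm2", "density", "whole", source_class = "all")

  # -- repartitions: 6 classes x {tumor, vicinity, outside}
  for (cl in CELL_CLASSES) {
    for (z in c("tumor", "vicinity", "outside")) {
      rows[[length(rows) + 1]] <- spec(
        paste0("repartition_", cl, "_", z), "repartition", z,
        source_class = cl, structure = TRUE)
    }
  }

  # -- log ratios: all ordered distinct pairs x 4 zones; structure subset =
  #    canonical (code-ordered) pairs in tumor & vicinity, minus epithelial
  #    pairs in the tumor zone
  for (z in ZONES) {
    for (a in CELL_CLASSES) {
      for (b in CELL_CLASSES) {
        if (a == b) next
        canonical <- CLASS_CODES[[a]] < CLASS_CODES[[b]]
        is_struct <- canonical &&
          ((z == "tumor" && a != "epithelial" && b != "epithelial") ||
             z == "vicinity")
        rows[[length(rows) + 1]] <- spec(
          paste0("ratio_log_", a, "_", b, "_", z), "ratio", z,
          source_class = a, target_class = b, variant = "log",
          structure = is_struct)
      }
    }
  }

  # -- raw count ratios: ordered distinct pairs x {whole, tumor, vicinity}
  for (z in c("whole", "tumor", "vicinity")) {
    for (a in CELL_CLASSES) {
      for (b in CELL_CLASSES) {
        if (a == b) next
        rows[[length(rows) + 1]] <- spec(
          paste0("ratio_raw_", a, "_", b, "_", z), "ratio", z,
          source_class = a, target_class = b, variant = "raw")
      }
    }
  }

  # -- distances: 4 x 4 ordered pairs (same-class allowed), tumor zone,
  #    microns (structure) and pixels
  for (unit in c("um", "px")) {
    for (a in DISTANCE_CLASSES) {
      for (b in DISTANCE_CLASSES) {
        rows[[length(rows) + 1]] <- spec(
          paste0("dist_", a, "_", b, "_", unit), "distance", "tumor",
          source_class = a, target_class = b, variant = unit,
          structure = unit == "um")
      }
    }
  }

  out <- tibble(
    name = map_chr(rows, "name"),
    family = map_chr(rows, "family"),
    zone = map_chr(rows, "zone"),
    source_class = map_chr(rows, "source_class"),
    target_class = map_chr(rows, "target_class"),
    variant = map_chr(rows, "variant"),
    structure = vapply(rows, `[[`, logical(1), "structure")
  )
  stopifnot(!anyDuplicated(out$name))
  attr(out, "version") <- REGISTRY_VERSION
  .registry_cache$reg <- out
  out
}

.registry_cache <- new.env(parent = emptyenv())
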