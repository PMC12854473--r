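# Synthetic slides and cohorts with known ground truth. The generator
# emulates the upstream models' outputs only: tumor blobs rasterized into a
# binary mask, and nuclei placed by independent Poisson sampling with
# class- and zone-specific intensities (expected cells per mm^2). Texture,
# stain and nucleus morphology are out of scope.

#' Slide-simulation configuration
#'
#' @param image_size `c(width, height)` of the nucleus frame in pixels.
#' @param mpp Microns per pixel of the nucleus frame.
#' @param downsample Mask downsample factor.
#' @param n_blobs Number of tumor blobs.
#' @param blob_radius_mm Mean blob radius in mm; each blob is a union of a
#'   few jittered disks, giving irregular but compact shapes.
#' @param n_lobes Disks per blob (shape irregularity).
#' @param intensities 5 x 3 matrix of expected cells per mm^2: rows
#'   granulocyte, lymphocyte, plasma, stromal, tumor; columns `tumor`,
#'   `vicinity`, `outside` zone. Raw (pre-refinement) classes only: tumor
#'   intensity outside the tumor regions models the epithelium the
#'   refinement step later relabels.
#' @param vicinity_mm Width of the vicinity ring used for zone-specific
#'   placement, default 1.
#' @param seed Integer seed; the whole slide is a deterministic function of
#'   the configuration.
#' @return A list of class `slide_sim_config`.
#' @export
slide_sim_config <- function(image_size = c(7200, 7200), mpp = 0.5,
                             downsample = 16, n_blobs = 1,
                             blob_radius_mm = 0.5, n_lobes = 4,
                             intensities = default_intensities(),
                             vicinity_mm = 1, seed = 1) {
  intensities <- as.matrix(intensities)
  stopifnot(nrow(intensities) == 5, ncol(intensities) == 3)
  if (any(intensities < 0)) abort("intensities must be >= 0")
  rownames(intensities) <- CELL_CLASSES[1:5]
  colnames(intensities) <- c("tumor", "vicinity", "outside")
  structure(list(image_size = image_size, mpp = mpp,
                 downsample = as.integer(downsample), n_blobs = n_blobs,
                 blob_radius_mm = blob_radius_mm, n_lobes = n_lobes,
                 intensities = intensities, vicinity_mm = vicinity_mm,
                 seed = seed),
            class = "slide_sim_config")
}

#' Default per-class, per-zone cell intensities
#'
#' Baseline expected densities (cells per mm^2) loosely typical of an H&E
#' skin-cancer section: tumor regions dominated by tumor cells with moderate
#' immune infiltrate, a stroma-rich vicinity, and sparse epithelium (raw
#' tumor-class calls) away from the tumor.
#'
#' @return A 5 x 3 numeric matrix (classes x zones).
#' @export
default_intensities <- function() {
  m <- rbind(
    granulocyte = c(40, 80, 30),
    lymphocyte  = c(100, 120, 60),
    plasma      = c(60, 80, 30),
    stromal     = c(60, 300, 250),
    tumor       = c(500, 50, 60)
  )
  colnames(m) <- c("tumor", "vicinity", "outside")
  m
}

# Rasterize irregular blobs: each blob is a union of n_lobes disks whose
# centers random-walk from the blob seed point.
rasterize_blobs <- function(mask_dim, n_blobs, radius_px, n_lobes) {
  raster <- matrix(0L, mask_dim[1], mask_dim[2])
  if (n_blobs == 0) return(raster)
  rows <- matrix(rep(seq_len(mask_dim[1]), mask_dim[2]), mask_dim[1])
  cols <- matrix(rep(seq_len(mask_dim[2]), each = mask_dim[1]), mask_dim[1])
  for (b in seq_len(n_blobs)) {
    cy <- runif(1, 0.3, 0.7) * mask_dim[1]
    cx <- runif(1, 0.3, 0.7) * mask_dim[2]
    for (k in seq_len(n_lobes)) {
      r <- radius_px * runif(1, 0.5, 1)
      raster[(rows - cy)^2 + (cols - cx)^2 <= r^2] <- 1L
      step <- radius_px * 0.6
      cy <- min(max(cy + runif(1, -step, step), 1), mask_dim[1])
      cx <- min(max(cx + runif(1, -step, step), 1), mask_dim[2])
    }
  }
  raster
}

hex_contour <- function(x, y, r = 3) {
  th <- seq(0, 2 * pi, length.out = 7)[1:6]
  cbind(x + r * cos(th), y + r * sin(th))
}

#' Simulate one synthetic slide
#'
#' Draws tumor blobs, rasterizes them into the mask, splits the mask grid
#' into tumor / vicinity / outside zones, and places nuclei of classes 1-5 by
#' independent Poisson sampling: in each zone the count of each class is
#' Poisson with mean intensity x zone area, and positions are uniform over
#' the zone's pixels. Small hexagonal contours are attached to each centroid.
#' The returned ground truth records the exact per-zone, per-class counts and
#' the mask geometry, so downstream bookkeeping can be verified against it.
#'
#' @param cfg A [slide_sim_config()].
#' @param sample_id Identifier for the generated slide.
#' @return A list with `annotation` ([slide_annotation()], raw classes 1-5),
#'   `mask` ([tumor_mask()]) and `truth` (per-zone class counts, tumor pixel
#'   count, zone areas in mm^2).
#' @export
simulate_slide <- function(cfg = slide_sim_config(), sample_id = "synthetic") {
  set.seed(cfg$seed)
  ds <- cfg$downsample
  mask_dim <- c(ceiling(cfg$image_size[2] / ds), ceiling(cfg$image_size[1] / ds))
  radius_px <- cfg$blob_radius_mm * 1000 / (cfg$mpp * ds)
  raster <- rasterize_blobs(mask_dim, cfg$n_blobs, radius_px, cfg$n_lobes)
  if (sum(raster) == 0 && any(cfg$intensities[, "tumor"] > 0)) {
    abort("zero-area tumor with positive tumor-zone intensities requested")
  }
  mask <- tumor_mask(raster, downsample = ds)
  regions <- label_tumor_regions(mask, mpp = cfg$mpp)
  ring <- if (sum(raster) > 0) {
    compute_vicinity(regions, cfg$mpp, width_mm = cfg$vicinity_mm)
  } else {
    matrix(0L, mask_dim[1], mask_dim[2])
  }
  zone_px <- list(
    tumor = which(regions$label_raster > 0),
    vicinity = which(ring > 0),
    outside = which(regions$label_raster == 0 & ring == 0)
  )
  px_mm2 <- (cfg$mpp * ds / 1000)^2
  areas <- vapply(zone_px, length, numeric(1)) * px_mm2

  xs <- numeric(0); ys <- numeric(0); cls <- integer(0)
  truth_counts <- matrix(0L, 5, 3,
                         dimnames = list(CELL_CLASSES[1:5], names(zone_px)))
  for (z in names(zone_px)) {
    px <- zone_px[[z]]
    if (length(px) == 0) next
    for (cl in seq_len(5)) {
      n <- rpois(1, cfg$intensities[cl, z] * areas[[z]])
      if (n == 0) next
      pick <- px[sample.int(length(px), n, replace = TRUE)]
      row <- (pick - 1) %% nrow(raster)       # 0-based mask row
      col <- (pick - 1) %/% nrow(raster)      # 0-based mask col
      x <- pmin((col + runif(n)) * ds, cfg$image_size[1] - 1e-6)
      y <- pmin((row + runif(n)) * ds, cfg$image_size[2] - 1e-6)
      xs <- c(xs, x); ys <- c(ys, y); cls <- c(cls, rep(cl, n))
      truth_counts[cl, z] <- truth_counts[cl, z] + n
    }
  }
  n_tot <- length(xs)
  nuclei <- tibble(
    instance_id = seq_len(n_tot),
    x = xs, y = ys,
    contour = map(seq_len(n_tot), ~ hex_contour(xs[.x], ys[.x])),
    class = cls
  )
  annotation <- slide_annotation(nuclei, mpp = cfg$mpp,
                                 image_size = cfg$image_size,
                                 sample_id = sample_id)
  truth <- list(counts = truth_counts, n_tumor_pixels = sum(raster),
                areas_mm2 = areas, n_blobs = cfg$n_blobs, seed = cfg$seed)
  list(annotation = annotation, mask = mask, truth = truth)
}

#' Cohort-simulation configuration
#'
#' Defines a two-group cohort (responders / non-responders) with planted
#' group effects expressed as class- and zone-specific cell intensities. The
#' defaults plant four effects chosen to mimic immune-contexture differences
#' reported for checkpoint-inhibition response in skin cancer: more
#' lymphocytes inside and around the tumor in responders, more granulocytes
#' in the tumor vicinity in non-responders, and fewer plasma cells inside the
#' tumor in non-responders (which also stretches the granulocyte-plasma
#' distance there).
#'
#' @param n_responders,n_non_responders Group sizes, defaults 28 and 17.
#' @param effects Tibble with columns `class`, `zone`, `responder`,
#'   `non_responder` (intensities, cells per mm^2) and `feature` (the
#'   registry feature the effect directly controls, recorded as ground
#'   truth).
#' @param jitter_sdlog Log-sd of the per-sample, per-(class, zone) lognormal
#'   intensity jitter modelling biological variability: a single value or one
#'   per class (granulocyte, lymphocyte, plasma, stromal, tumor). The default
#'   gives the stromal compartment a larger variability (0.30 versus 0.15),
#'   reflecting how strongly stromal content varies between sections.
#' @param seed Integer seed.
#' @return A list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_responders = 28, n_non_responders = 17,
                              effects = default_effects(),
                              jitter_sdlog = c(0.15, 0.15, 0.15, 0.30, 0.15),
                              seed = 1) {
  if (n_responders < 3 || n_non_responders < 3) {
    abort("each group needs at least 3 samples")
  }
  if (!length(jitter_sdlog) %in% c(1, 5)) {
    abort("jitter_sdlog must have length 1 or 5 (one per class)")
  }
  jitter_sdlog <- rep_len(jitter_sdlog, 5)
  reg <- feature_registry()
  bad <- setdiff(effects$feature, reg$name)
  if (length(bad) > 0) {
    abort(paste0("effect references unknown feature(s): ",
                 paste(bad, collapse = ", ")))
  }
  structure(list(n_responders = n_responders,
                 n_non_responders = n_non_responders,
                 effects = effects, jitter_sdlog = jitter_sdlog, seed = seed),
            class = "cohort_sim_config")
}

#' Default planted cohort effects
#'
#' @return The four-effect tibble used by [cohort_sim_config()].
#' @export
default_effects <- function() {
  tibble(
    class = c("lymphocyte", "plasma", "granulocyte", "tumor"),
    zone = c("vicinity", "vicinity", "outside", "outside"),
    responder = c(130, 72, 54, 75),
    non_responder = c(95, 52, 76, 50),
    feature = c("density_lymphocyte_vicinity_mm2",
                "density_plasma_vicinity_mm2",
                "density_granulocyte_outside_mm2",
                "density_epithelial_outside_mm2")
  )
}

#' Simulate a two-group cohort of synthetic slides
#'
#' Per sample, the base intensity matrix of `slide_cfg` is overridden at the
#' planted (class, zone) cells by the sample's group mean, every intensity is
#' jittered by an independent lognormal factor, and a slide is simulated with
#' a per-sample seed derived from the cohort seed. When `out_dir` is given,
#' annotation JSONs, mask PNGs, a cohort CSV and a ground-truth JSON naming
#' the planted features are written there; otherwise the slides are returned
#' in memory.
#'
#' @param cfg A [cohort_sim_config()].
#' @param slide_cfg Base [slide_sim_config()] shared by all samples.
#' @param out_dir Optional output directory.
#' @return A list with `cohort` (tibble `sample_id`, `label`, plus file paths
#'   when written), `slides` (in-memory list, `NULL` when written to disk)
#'   and `truth` (planted feature names and per-sample intensities).
#' @export
simulate_cohort <- function(cfg = cohort_sim_config(),
                            slide_cfg = slide_sim_config(),
                            out_dir = NULL) {
  labels <- c(rep("responder", cfg$n_responders),
              rep("non_responder", cfg$n_non_responders))
  n <- length(labels)
  sample_ids <- sprintf("S%03d", seq_len(n))
  set.seed(cfg$seed)
  slide_seeds <- sample.int(.Machine$integer.max - 1L, n)
  jitters <- lapply(seq_len(n), function(i) {
    matrix(pmax(1 + rnorm(15, 0, rep(cfg$jitter_sdlog, 3)), 0.2), 5, 3)
  })
  slides <- vector("list", n)
  intens_used <- vector("list", n)
  for (i in seq_len(n)) {
    intens <- slide_cfg$intensities
    for (e in seq_len(nrow(cfg$effects))) {
      intens[cfg$effects$class[e], cfg$effects$zone[e]] <-
        cfg$effects[[labels[i]]][e]
    }
    intens <- intens * jitters[[i]]
    s_cfg <- slide_cfg
    s_cfg$intensities <- intens
    s_cfg$seed <- slide_seeds[i]
    slides[[i]] <- simulate_slide(s_cfg, sample_id = sample_ids[i])
    intens_used[[i]] <- intens
  }
  cohort <- tibble(sample_id = sample_ids, label = labels)
  truth <- list(planted_features = cfg$effects$feature,
                effects = cfg$effects, seed = cfg$seed,
                intensities = intens_used)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    ann_paths <- file.path(out_dir, paste0(sample_ids, "_nuclei.json"))
    mask_paths <- file.path(out_dir, paste0(sample_ids, "_mask.png"))
    for (i in seq_len(n)) {
      write_nucleus_json(slides[[i]]$annotation, ann_paths[i])
      write_tumor_mask(slides[[i]]$mask, mask_paths[i])
    }
    cohort$annotation_path <- ann_paths
    cohort$mask_path <- mask_paths
    readr::write_csv(cohort, file.path(out_dir, "cohort.csv"))
    truth_json <- list(planted_features = cfg$effects$feature,
                       seed = cfg$seed)
    writeLines(jsonlite::toJSON(truth_json, auto_unbox = TRUE),
               file.path(out_dir, "ground_truth.json"))
    slides <- NULL
  }
  list(cohort = cohort, slides = slides, truth = truth)
}

#' Compute the feature table of a simulated or on-disk cohort
#'
#' Runs refinement, zone construction and [compute_features()] on every slide
#' of a cohort and binds the vectors into a samples-by-features tibble ready
#' for [sweep_n_features()] / [response_protocol()].
#'
#' @param cohort Result of [simulate_cohort()] (in-memory), or a cohort
#'   tibble with `annotation_path` / `mask_path` columns.
#' @param registry Feature registry, default [feature_registry()].
#' @param structure_only Keep only the structure-flagged analysis subset,
#'   default `TRUE`.
#' @param downsample Mask downsample when reading from disk.
#' @param cfg [search_config()] for distance features.
#' @return A tibble: `sample_id`, `label`, then one numeric column per
#'   feature.
#' @export
cohort_feature_table <- function(cohort, registry = feature_registry(),
                                 structure_only = TRUE, downsample = 16,
                                 cfg = search_config()) {
  if (is.list(cohort) && !is.data.frame(cohort) && !is.null(cohort$cohort)) {
    tab <- cohort$cohort
    slides <- cohort$slides
  } else {
    tab <- cohort
    slides <- NULL
  }
  rows <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    if (!is.null(slides)) {
      ann <- slides[[i]]$annotation
      mask <- slides[[i]]$mask
    } else {
      ann <- read_nucleus_json(tab$annotation_path[i])
      mask <- read_tumor_mask(tab$mask_path[i], downsample = downsample)
    }
    regions <- label_tumor_regions(mask, mpp = ann$mpp)
    ann <- reclassify_epithelial(assign_nuclei_to_regions(ann, regions))
    fv <- compute_features(ann, regions, registry = registry, cfg = cfg)
    rows[[i]] <- setNames(as.list(fv$value), fv$feature)
  }
  wide <- bind_rows(lapply(rows, as_tibble))
  if (structure_only) wide <- wide[, registry$name[registry$structure]]
  bind_cols(tibble(sample_id = tab$sample_id, label = tab$label), wide)
}

#' Default feature-level planted effects
#'
#' Group-conditional distributions for four structure features, mirroring the
#' immune-contexture families repeatedly reported as predictive of
#' checkpoint-inhibition response: lymphocyte fractions inside and around the
#' tumor (higher in responders), the granulocyte-to-lymphocyte log ratio in
#' the vicinity and the granulocyte-plasma distance in the tumor (higher in
#' non-responders).
#'
#' @return A tibble with columns `feature`, `mean_responder`, `sd_responder`,
#'   `mean_non_responder`, `sd_non_responder`.
#' @export
default_feature_effects <- function() {
  tibble(
    feature = c("fraction_lymphocyte_tumor",
                "fraction_lymphocyte_vicinity",
                "ratio_log_granulocyte_lymphocyte_vicinity",
                "dist_granulocyte_plasma_um"),
    mean_responder = c(0.19, 0.24, 0.78, 55),
    sd_responder = c(0.05, 0.06, 0.10, 18),
    mean_non_responder = c(0.085, 0.125, 1.02, 98),
    sd_non_responder = c(0.04, 0.05, 0.11, 22)
  )
}

#' Simulate a cohort directly in feature space
#'
#' Draws a samples-by-features table over the structure-feature subset of the
#' registry in which exactly the planted features carry a group effect: each
#' planted feature is Gaussian with its group-conditional mean and sd, and
#' every other feature is drawn from a single label-independent Gaussian
#' whose location and scale are family-typical. This is the sharp setting
#' for testing the selection-and-scoring protocol ("exactly k features carry
#' signal"); [simulate_cohort()] is the slide-level companion in which
#' derived features inevitably co-carry any planted intensity effect.
#'
#' @param n_responders,n_non_responders Group sizes, defaults 28 and 17.
#' @param effects Tibble as [default_feature_effects()].
#' @param registry Feature registry; the table covers its structure subset.
#' @param seed Integer seed.
#' @return A tibble: `sample_id`, `label`, then one column per structure
#'   feature; attribute `planted` names the effect-carrying features.
#' @export
simulate_feature_cohort <- function(n_responders = 28, n_non_responders = 17,
                                    effects = default_feature_effects(),
                                    registry = feature_registry(), seed = 1) {
  feats <- registry$name[registry$structure]
  bad <- setdiff(effects$feature, feats)
  if (length(bad) > 0) {
    abort(paste0("effect references unknown structure feature(s): ",
                 paste(bad, collapse = ", ")))
  }
  set.seed(seed)
  n <- n_responders + n_non_responders
  labels <- c(rep("responder", n_responders),
              rep("non_responder", n_non_responders))
  base_mean <- function(f) {
    if (startsWith(f, "fraction_")) return(0.15)
    if (startsWith(f, "density_")) return(120)
    if (startsWith(f, "repartition_")) return(0.33)
    if (startsWith(f, "ratio_")) return(1)
    80  # distance, um
  }
  base_sd <- function(f) {
    if (startsWith(f, "fraction_")) return(0.05)
    if (startsWith(f, "density_")) return(35)
    if (startsWith(f, "repartition_")) return(0.08)
    if (startsWith(f, "ratio_")) return(0.12)
    20
  }
  cols <- lapply(feats, function(f) {
    e <- effects[effects$feature == f, ]
    if (nrow(e) == 1) {
      mu <- ifelse(labels == "responder", e$mean_responder,
                   e$mean_non_responder)
      sdv <- ifelse(labels == "responder", e$sd_responder,
                    e$sd_non_responder)
      rnorm(n, mu, sdv)
    } else {
      rnorm(n, base_mean(f), base_sd(f))
    }
  })
  names(cols) <- feats
  out <- bind_cols(
    tibble(sample_id = sprintf("S%03d", seq_len(n)), label = labels),
    as_tibble(cols))
  attr(out, "planted") <- effects$feature
  out
}
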