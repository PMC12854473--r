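test_that("the default registry matches the documented catalogue shape", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 317)
  expect_equal(sum(reg$structure), 107)
  expect_false(any(duplicated(reg$name)))
  expect_true(all(reg$family %in%
                    c("fraction", "density", "ratio", "repartition",
                      "distance")))
  expect_true(all(reg$zone %in% c("whole", "tumor", "vicinity", "outside")))
  dist <- reg[reg$family == "distance", ]
  expect_true(all(dist$zone == "tumor"))
  expect_true(all(dist$source_class %in%
                    c("granulocyte", "lymphocyte", "plasma", "tumor")))
  # no nucleus-morphology features in the catalogue
  expect_false(any(grepl("area|circular|perimeter|eccentric", reg$name)))
  # refinement makes epithelial impossible inside tumor regions, so no
  # structure-flagged tumor-zone log ratio may involve the epithelial class
  struct_ratio_tumor <- reg[reg$structure & reg$family == "ratio" &
                              reg$zone == "tumor", ]
  expect_false(any(struct_ratio_tumor$source_class == "epithelial" |
                     struct_ratio_tumor$target_class == "epithelial"))
})

test_that("smoothed log ratio follows its closed form", {
  expect_identical(smoothed_log_ratio(10, 10), 1)
  # independent direct evaluation of the formula
  eps <- 1e-3
  expect_equal(smoothed_log_ratio(100, 10),
               (log(100) + eps) / (log(10) + eps))
  expect_equal(round(smoothed_log_ratio(100, 10), 5), 1.99957)
  expect_true(is.na(smoothed_log_ratio(5, 0)))
  expect_true(is.na(smoothed_log_ratio(0, 5)))
  expect_error(smoothed_log_ratio(-1, 5), "non-negative")
  # eta(n, n) = 1 for all n >= 2; near-reciprocity within epsilon
  for (n in c(2, 3, 17, 1000)) expect_equal(smoothed_log_ratio(n, n), 1)
  for (a in c(2, 5, 50)) {
    for (b in c(3, 20, 400)) {
      expect_lte(abs(smoothed_log_ratio(a, b) -
                       1 / smoothed_log_ratio(b, a)), 1e-3)
    }
  }
})

test_that("class fractions and densities follow counts and areas", {
  # 40 cells in the tumor zone, 10 of them lymphocytes -> 0.25
  m <- matrix(1L, 10, 10)   # all-tumor mask, downsample 10, frame 100x100
  regs <- label_tumor_regions(tumor_mask(m, 10), mpp = 5)
  set.seed(2)
  x <- runif(40, 0, 99); y <- runif(40, 0, 99)
  cls <- c(rep(2, 10), rep(5, 30))
  ann <- make_annotation(x, y, cls, image_size = c(100, 100), mpp = 5)
  ann <- assign_nuclei_to_regions(ann, regs)
  ring <- matrix(0L, 10, 10)
  expect_equal(class_fraction(ann, regs, "lymphocyte", "tumor",
                              vicinity = ring), 0.25)
  # empty zone is missing
  expect_true(is.na(class_fraction(ann, regs, "lymphocyte", "outside",
                                   vicinity = ring)))
  expect_error(class_fraction(ann, regs, "lymphocyte", "nowhere", ring),
               "zone")
  # whole slide covers 100 mask px x (5 um * 10)^2 = 0.25 mm^2
  expect_equal(cell_density(ann, regs, "lymphocyte", "whole",
                            vicinity = ring), 10 / 0.25)
  expect_equal(cell_density(ann, regs, "all", "tumor", vicinity = ring),
               40 / 0.25)
})

test_that("disk-region density agrees with the analytic area within 2%", {
  n <- 120
  rows <- matrix(rep(1:n, n), n); cols <- matrix(rep(1:n, each = n), n)
  disk <- matrix(as.integer((rows - 60.5)^2 + (cols - 60.5)^2 <= 40^2), n, n)
  regs <- label_tumor_regions(tumor_mask(disk, 8), mpp = 2.5)
  # 200 cells at fixed positions inside the disk
  set.seed(3)
  idx <- which(disk == 1)
  pick <- idx[sample.int(length(idx), 200, replace = TRUE)]
  r <- (pick - 1) %% n; cc <- (pick - 1) %/% n
  ann <- make_annotation((cc + 0.5) * 8, (r + 0.5) * 8, rep(2, 200),
                         image_size = c(960, 960), mpp = 2.5)
  ann <- assign_nuclei_to_regions(ann, regs)
  ring <- matrix(0L, n, n)
  analytic_area <- pi * 40^2 * (2.5 * 8 / 1000)^2
  got <- cell_density(ann, regs, "lymphocyte", "tumor", vicinity = ring)
  expect_lt(abs(got - 200 / analytic_area) / (200 / analytic_area), 0.02)
})

test_that("compute_features fills the registry deterministically", {
  s <- small_slide(seed = 4)
  regs <- label_tumor_regions(s$mask, mpp = s$annotation$mpp)
  ann <- reclassify_epithelial(assign_nuclei_to_regions(s$annotation, regs))
  reg <- feature_registry()
  fv <- compute_features(ann, regs)
  expect_identical(fv$feature, reg$name)
  expect_identical(compute_features(ann, regs)$value, fv$value)

  # unrefined input is refused
  expect_error(compute_features(assign_nuclei_to_regions(s$annotation, regs),
                                regs), "reclassify")

  # permuting the nucleus table changes nothing
  perm <- ann
  set.seed(1)
  perm$nuclei <- perm$nuclei[sample(nrow(perm$nuclei)), ]
  expect_equal(compute_features(perm, regs)$value, fv$value)

  # per-zone fractions over the six classes sum to 1 on non-empty zones
  for (z in c("whole", "tumor", "vicinity", "outside")) {
    fr <- fv$value[match(paste0("fraction_",
                                class_codes()$class, "_", z), fv$feature)]
    if (!anyNA(fr)) expect_equal(sum(fr), 1, tolerance = 1e-9)
  }
})

test_that("a slide without tumor yields missing tumor-zone features", {
  cfg <- slide_sim_config(image_size = c(800, 800), mpp = 1, downsample = 8,
                          n_blobs = 0,
                          intensities = cbind(tumor = rep(0, 5),
                                              vicinity = rep(0, 5),
                                              outside = c(50, 80, 40, 100, 60)),
                          seed = 6)
  s <- simulate_slide(cfg)
  regs <- label_tumor_regions(s$mask, mpp = 1)
  ann <- reclassify_epithelial(assign_nuclei_to_regions(s$annotation, regs))
  fv <- compute_features(ann, regs,
                         vicinity = matrix(0L, 100, 100))
  reg <- feature_registry()
  tum_zone <- (reg$zone == "tumor" & reg$family != "repartition") |
    reg$family == "distance"
  expect_true(all(is.na(fv$value[tum_zone])))
  # tumor-zone repartitions are a true zero, not undefined: the class exists
  # on the slide but none of its cells sit in a tumor region
  rep_tum <- reg$zone == "tumor" & reg$family == "repartition"
  expect_true(all(fv$value[rep_tum] == 0, na.rm = TRUE))
  whole_fr <- fv$value[fv$feature == "fraction_stromal_whole"]
  expect_false(is.na(whole_fr))
  expect_gt(whole_fr, 0)
})
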