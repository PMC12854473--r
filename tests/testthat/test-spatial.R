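test_that("expanding rectangle stops at the first capturing step", {
  cfg <- search_config(f = 0.05)
  # single target inside the first rectangle (half-extent 25)
  r <- expanding_min_distance(c(0, 0), rbind(c(3, 4)), 1000, 1000, cfg)
  expect_equal(r$distance, 5)
  expect_equal(r$lambda0, 1L)

  # first step empty, second captures (30, 0) only; (0, 60) never nearer
  r <- expanding_min_distance(c(0, 0), rbind(c(30, 0), c(0, 60)), 1000, 1000, cfg)
  expect_equal(r$distance, 30)
  expect_equal(r$lambda0, 2L)
  expect_equal(brute_force_min_distance(c(0, 0), rbind(c(30, 0), c(0, 60))), 30)

  # documented overestimation mode: (24, 24) is captured at step 1 while the
  # true nearest neighbour (0, 26) sits just outside the rectangle
  tg <- rbind(c(0, 26), c(24, 24))
  r <- expanding_min_distance(c(0, 0), tg, 1000, 1000, cfg)
  expect_equal(r$distance, sqrt(24^2 + 24^2))
  expect_equal(r$lambda0, 1L)
  expect_equal(brute_force_min_distance(c(0, 0), tg), 26)
  expect_gt(r$distance, 26)

  # no targets / unreachable targets
  expect_true(is.na(expanding_min_distance(c(0, 0),
                                           matrix(numeric(0), 0, 2),
                                           1000, 1000, cfg)$distance))
  capped <- search_config(f = 0.05, lambda_max = 1)
  expect_true(is.na(expanding_min_distance(c(0, 0), rbind(c(30, 0)),
                                           1000, 1000, capped)$distance))
  expect_error(expanding_min_distance(c(0, 0), rbind(c(1, 1)), 0, 10, cfg),
               "l_t")
})

test_that("rectangle search never undercuts brute force and is order-invariant", {
  set.seed(5)
  cfg <- search_config()
  for (rep in 1:20) {
    n <- sample(3:40, 1)
    tg <- cbind(runif(n, 0, 400), runif(n, 0, 300))
    src <- c(runif(1, 0, 400), runif(1, 0, 300))
    r <- expanding_min_distance(src, tg, 400, 300, cfg)
    bf <- brute_force_min_distance(src, tg)
    expect_gte(r$distance, bf)
    # permutation and duplication of non-minimal targets change nothing
    perm <- tg[sample(n), , drop = FALSE]
    expect_equal(expanding_min_distance(src, perm, 400, 300, cfg)$distance,
                 r$distance)
    dup <- rbind(tg, tg[which.max(sqrt(colSums((t(tg) - src)^2))), ])
    expect_equal(expanding_min_distance(src, dup, 400, 300, cfg)$distance,
                 r$distance)
    # a rectangle covering the whole extent at the first step is exact
    wide <- search_config(f = 1)
    expect_equal(expanding_min_distance(src, tg, 2 * 400, 2 * 300,
                                        wide)$distance, bf)
  }
})

test_that("vectorized region search equals the per-source reference", {
  set.seed(21)
  ns <- 60; nt <- 45
  sx <- runif(ns, 0, 500); sy <- runif(ns, 0, 350)
  tx <- runif(nt, 0, 500); ty <- runif(nt, 0, 350)
  fast <- histofeatr:::region_min_distances(sx, sy, tx, ty, NULL, 500, 350)
  ref <- vapply(seq_len(ns), function(i) {
    expanding_min_distance(c(sx[i], sy[i]), cbind(tx, ty), 500, 350)$distance
  }, numeric(1))
  expect_equal(fast, ref)
  # same-class: self exclusion per source
  fast2 <- histofeatr:::region_min_distances(sx, sy, sx, sy, seq_len(ns),
                                             500, 350)
  ref2 <- vapply(seq_len(ns), function(i) {
    expanding_min_distance(c(sx[i], sy[i]), cbind(sx[-i], sy[-i]),
                           500, 350)$distance
  }, numeric(1))
  expect_equal(fast2, ref2)
})

test_that("average closest distance confines the search to each region", {
  # one 10x10-mask-pixel region at downsample 10: box 100 x 100 px
  m <- matrix(1L, 10, 10)
  regs <- label_tumor_regions(tumor_mask(m, 10), mpp = 2)
  ann <- make_annotation(
    x = c(10, 80, 16, 62), y = c(10, 80, 18, 56),
    class = c(1, 1, 2, 2), image_size = c(100, 100), mpp = 2)
  ann <- assign_nuclei_to_regions(ann, regs)
  res <- average_closest_distance(ann, regs, "granulocyte", "lymphocyte")
  # per-source nearest distances are 10 and 30 -> mean 20 px, 40 um at 2 um/px
  expect_equal(res$mean_px, 20)
  expect_equal(res$mean_um, 40)
  expect_equal(res$n_sources, 2)

  # no targets in the region: sources skipped, result missing
  res0 <- average_closest_distance(ann, regs, "granulocyte", "plasma")
  expect_true(is.na(res0$mean_px))
  expect_equal(res0$n_skipped, 2)

  # same class excludes the source itself
  res_same <- average_closest_distance(ann, regs, "granulocyte", "granulocyte")
  expect_equal(res_same$mean_px, sqrt(70^2 + 70^2))

  expect_error(average_closest_distance(ann, regs, "stromal", "lymphocyte"),
               "limited")
})

test_that("searches never cross between tumor regions", {
  # two regions; the only lymphocyte in region 2 must not serve region 1
  m <- matrix(0L, 20, 20)
  m[1:8, 1:8] <- 1L
  m[13:20, 13:20] <- 1L
  regs <- label_tumor_regions(tumor_mask(m, 10), mpp = 1)
  ann <- make_annotation(
    x = c(40, 150), y = c(40, 150),
    class = c(1, 2), image_size = c(200, 200))
  ann <- assign_nuclei_to_regions(ann, regs)
  expect_equal(ann$nuclei$tumor_region_id, c(1L, 2L))
  res <- average_closest_distance(ann, regs, "granulocyte", "lymphocyte")
  expect_true(is.na(res$mean_px))
  expect_equal(res$n_skipped, 1)
})

test_that("on dense synthetic regions the rectangle search is mostly exact", {
  s <- small_slide(seed = 13)
  regs <- label_tumor_regions(s$mask, mpp = s$annotation$mpp)
  ann <- reclassify_epithelial(assign_nuclei_to_regions(s$annotation, regs))
  nuc <- ann$nuclei
  in_reg <- nuc[nuc$tumor_region_id > 0, ]
  src <- in_reg[in_reg$class == 5, ]
  tgt <- in_reg[in_reg$class == 2, ]
  expect_gt(nrow(tgt), 20)
  box <- regs$regions[1, ]
  fast <- histofeatr:::region_min_distances(src$x, src$y, tgt$x, tgt$y, NULL,
                                            box$l, box$w)
  bf <- vapply(seq_len(nrow(src)), function(i) {
    brute_force_min_distance(c(src$x[i], src$y[i]), cbind(tgt$x, tgt$y))
  }, numeric(1))
  expect_true(all(fast >= bf - 1e-12))
  expect_gt(mean(fast == bf), 0.95)
})
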