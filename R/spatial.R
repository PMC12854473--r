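# Closest-cell distances inside tumor regions via the expanding-rectangle
# search: a rectangle whose side lengths are a fraction f (default 0.05) of
# the tumor bounding box, centered on the source nucleus, grows in integer
# multiples lambda until it captures at least one target-class centroid; the
# minimum Euclidean distance over the captured set is returned. Because the
# capture set is rectangle- not disk-shaped, the result can exceed the true
# nearest-neighbour distance (a corner cell can be kept while a nearer cell
# just outside the rectangle is not); brute_force_min_distance() is the exact
# oracle and mc_overestimation_probability() quantifies how rare that is.

#' Search configuration for the expanding-rectangle distance
#'
#' @param f Fraction of the tumor bounding box added per growth step
#'   (0 < f <= 1), default 0.05: at step lambda the rectangle has full side
#'   lengths `f * lambda * l_t` by `f * lambda * w_t`.
#' @param lambda_max Cap on lambda guarding termination. `NULL` (default)
#'   means the smallest lambda whose rectangle spans the whole bounding box
#'   from any interior point, plus 1 (`ceiling(2 / f) + 1`).
#' @return A list of class `search_config`.
#' @export
search_config <- function(f = 0.05, lambda_max = NULL) {
  if (!is.numeric(f) || f <= 0 || f > 1) abort("f must be in (0, 1]")
  if (!is.null(lambda_max) && lambda_max < 1) abort("lambda_max must be >= 1")
  structure(list(f = f, lambda_max = lambda_max %||% (ceiling(2 / f) + 1)),
            class = "search_config")
}

#' Expanding-rectangle minimum distance from one source cell
#'
#' Grows a rectangle of full side lengths `f * lambda * l_t` (along x) by
#' `f * lambda * w_t` (along y), centered on the source centroid, over
#' lambda = 1, 2, ...; at the first lambda capturing at least one target
#' centroid (closed inequalities: the boundary counts as inside), returns the
#' minimum Euclidean distance over the captured targets.
#'
#' @param source Numeric `c(x, y)`: source-cell centroid.
#' @param targets Two-column matrix (or data frame) of target centroids in the
#'   same tumor region as the source.
#' @param l_t,w_t Length (x extent) and width (y extent) of the tumor region's
#'   bounding box, in the same pixel units as the centroids; both > 0.
#' @param cfg A [search_config()].
#' @return A list with `distance` (`NA` if no target was found before
#'   `lambda_max` or `targets` is empty) and `lambda0` (the capture step,
#'   `NA` when not found).
#' @export
expanding_min_distance <- function(source, targets, l_t, w_t,
                                   cfg = search_config()) {
  if (l_t <= 0 || w_t <= 0) abort("l_t and w_t must be > 0")
  targets <- as.matrix(targets)
  if (length(targets) == 0 || nrow(targets) == 0) {
    return(list(distance = NA_real_, lambda0 = NA_integer_))
  }
  dx <- abs(targets[, 1] - source[1])
  dy <- abs(targets[, 2] - source[2])
  for (lambda in seq_len(cfg$lambda_max)) {
    hx <- cfg$f * lambda * l_t / 2
    hy <- cfg$f * lambda * w_t / 2
    kept <- dx <= hx & dy <= hy
    if (any(kept)) {
      return(list(distance = sqrt(min(dx[kept]^2 + dy[kept]^2)),
                  lambda0 = lambda))
    }
  }
  list(distance = NA_real_, lambda0 = NA_integer_)
}

#' Exact minimum distance by full enumeration
#'
#' Test oracle for [expanding_min_distance()]: the global minimum Euclidean
#' distance from the source to any target, with no search-area restriction.
#'
#' @inheritParams expanding_min_distance
#' @return The minimum distance, or `NA` if `targets` is empty.
#' @export
brute_force_min_distance <- function(source, targets) {
  targets <- as.matrix(targets)
  if (length(targets) == 0 || nrow(targets) == 0) return(NA_real_)
  sqrt(min((targets[, 1] - source[1])^2 + (targets[, 2] - source[2])^2))
}

#' Average closest-cell distance between two classes inside tumor regions
#'
#' For every source-class nucleus inside a tumor region, runs the
#' expanding-rectangle search against the target-class nuclei of the same
#' region (the search never extends to other tumor regions) and averages the
#' distances over the sources that produced one. Sources in regions with no
#' target-class cell are skipped, as are the (logged) sources whose search
#' hits the lambda cap. When source and target class coincide, the source
#' nucleus itself is excluded from its own target set.
#'
#' @param annotation A refined, region-assigned [slide_annotation()].
#' @param regions The matching [label_tumor_regions()] result.
#' @param source_class,target_class Class names or integer codes; the
#'   distance features are defined for granulocyte, lymphocyte, plasma and
#'   tumor cells.
#' @param cfg A [search_config()].
#' @param mpp Microns per pixel for the micron-scale value (defaults to the
#'   annotation's).
#' @return A one-row tibble: `source_class`, `target_class`, `mean_px`,
#'   `mean_um`, `n_sources` (sources contributing to the mean), `n_skipped`
#'   (sources in regions without targets or hitting the lambda cap).
#'   `mean_px`/`mean_um` are `NA` when no source produced a distance.
#' @export
average_closest_distance <- function(annotation, regions, source_class,
                                     target_class, cfg = search_config(),
                                     mpp = NULL) {
  stopifnot(inherits(annotation, "slide_annotation"),
            inherits(regions, "tumor_regions"))
  mpp <- mpp %||% annotation$mpp
  src_code <- as_class_code(source_class)
  tgt_code <- as_class_code(target_class)
  allowed <- CLASS_CODES[c("granulocyte", "lymphocyte", "plasma", "tumor")]
  if (!src_code %in% allowed || !tgt_code %in% allowed) {
    abort("distance classes are limited to granulocyte, lymphocyte, plasma, tumor")
  }
  nuc <- annotation$nuclei
  if (!"tumor_region_id" %in% names(nuc)) {
    abort("run assign_nuclei_to_regions() first")
  }
  res <- pair_min_distances(nuc, regions, src_code, tgt_code, cfg)
  found <- res$dists[!is.na(res$dists)]
  mean_px <- if (length(found) > 0) mean(found) else NA_real_
  tibble(source_class = class_name(src_code),
         target_class = class_name(tgt_code),
         mean_px = mean_px,
         mean_um = mean_px * mpp,
         n_sources = length(found),
         n_skipped = res$n_skipped)
}

# Per-source expanding-rectangle distances for one (source, target) class
# pair over all tumor regions; base-R internals shared by
# average_closest_distance() and compute_features().
pair_min_distances <- function(nuc, regions, src_code, tgt_code,
                               cfg = search_config()) {
  in_reg <- nuc$tumor_region_id > 0L
  s_sel <- which(in_reg & nuc$class == src_code)
  t_sel <- which(in_reg & nuc$class == tgt_code)
  dists <- rep(NA_real_, length(s_sel))
  n_skipped <- 0L
  if (length(s_sel) > 0 && length(t_sel) > 0) {
    s_rid <- nuc$tumor_region_id[s_sel]
    t_rid <- nuc$tumor_region_id[t_sel]
    boxes <- regions$regions
    for (rid in unique(s_rid)) {
      si <- which(s_rid == rid)
      ti <- which(t_rid == rid)
      if (length(ti) == 0) {
        n_skipped <- n_skipped + length(si)
        next
      }
      self <- if (src_code == tgt_code) {
        match(nuc$instance_id[s_sel[si]], nuc$instance_id[t_sel[ti]])
      } else NULL
      bi <- match(rid, boxes$region_id)
      res <- region_min_distances(
        nuc$x[s_sel[si]], nuc$y[s_sel[si]],
        nuc$x[t_sel[ti]], nuc$y[t_sel[ti]], self = self,
        l_t = boxes$l[bi], w_t = boxes$w[bi], cfg = cfg)
      n_skipped <- n_skipped + sum(is.na(res))
      dists[si] <- res
    }
  } else {
    n_skipped <- length(s_sel)
  }
  list(dists = dists, n_skipped = n_skipped)
}

# Vectorized expanding-rectangle search for all sources of one region.
# For each (source, target) pair the smallest capture step is available in
# closed form: lambda_ij = max(ceil(2|dx| / (f l_t)), ceil(2|dy| / (f w_t)), 1),
# the step at which the growing rectangle first contains the target (closed
# inequalities: an exact boundary hit is captured). The search stops at
# lambda0_i = min_j lambda_ij, and the result is the minimum distance over
# the targets captured at that step - identical to stepping
# expanding_min_distance() through lambda = 1, 2, ... (property-tested).
# Sources are processed in blocks to bound the pairwise-matrix memory.
region_min_distances <- function(sx, sy, tx, ty, self, l_t, w_t,
                                 cfg = search_config(), block = 512L) {
  if (l_t <= 0 || w_t <= 0) abort("l_t and w_t must be > 0")
  ns <- length(sx)
  out <- rep(NA_real_, ns)
  for (start in seq(1L, ns, by = block)) {
    idx <- start:min(start + block - 1L, ns)
    dx <- abs(outer(sx[idx], tx, "-"))
    dy <- abs(outer(sy[idx], ty, "-"))
    lam <- pmax(ceiling(2 * dx / (cfg$f * l_t)),
                ceiling(2 * dy / (cfg$f * w_t)), 1)
    d2 <- dx^2 + dy^2
    if (!is.null(self)) {
      hit <- which(!is.na(self[idx]))
      if (length(hit) > 0) {
        lam[cbind(hit, self[idx][hit])] <- Inf
        d2[cbind(hit, self[idx][hit])] <- Inf
      }
    }
    lam0 <- apply(lam, 1, min)
    found <- lam0 <= cfg$lambda_max
    if (any(found)) {
      d2[lam > lam0] <- Inf  # only targets captured at the stopping step
      out[idx[found]] <- sqrt(apply(d2[found, , drop = FALSE], 1, min))
    }
  }
  out
}

as_class_code <- function(x) {
  if (is.character(x)) {
    code <- CLASS_CODES[x]
    if (anyNA(code)) abort(paste0("unknown class name: ", x))
    unname(code)
  } else {
    as.integer(x)
  }
}
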