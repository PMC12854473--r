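# Independent brute-force oracles and small fixture builders used across the
# suite. These re-derive results by enumeration or direct formula and never
# call the package internals they check.

# 8-connected flood-fill component count on a binary matrix (BFS).
flood_fill_components <- function(raster) {
  seen <- matrix(FALSE, nrow(raster), ncol(raster))
  k <- 0L
  shifts <- expand.grid(dr = -1:1, dc = -1:1)
  shifts <- shifts[!(shifts$dr == 0 & shifts$dc == 0), ]
  for (r0 in seq_len(nrow(raster))) {
    for (c0 in seq_len(ncol(raster))) {
      if (raster[r0, c0] == 0 || seen[r0, c0]) next
      k <- k + 1L
      queue <- list(c(r0, c0)); seen[r0, c0] <- TRUE
      while (length(queue) > 0) {
        p <- queue[[1]]; queue <- queue[-1]
        for (s in seq_len(nrow(shifts))) {
          r <- p[1] + shifts$dr[s]; cc <- p[2] + shifts$dc[s]
          if (r >= 1 && r <= nrow(raster) && cc >= 1 && cc <= ncol(raster) &&
              raster[r, cc] != 0 && !seen[r, cc]) {
            seen[r, cc] <- TRUE
            queue[[length(queue) + 1]] <- c(r, cc)
          }
        }
      }
    }
  }
  k
}

# Minimal annotation with nuclei at given positions/classes (tiny triangle
# contours), for hand-built geometry cases.
make_annotation <- function(x, y, class, image_size, mpp = 1,
                            sample_id = "fixture") {
  n <- length(x)
  nuclei <- tibble::tibble(
    instance_id = seq_len(n),
    x = x, y = y,
    contour = lapply(seq_len(n), function(i) {
      rbind(c(x[i] - 1, y[i] - 1), c(x[i] + 1, y[i] - 1), c(x[i], y[i] + 1))
    }),
    class = as.integer(class)
  )
  slide_annotation(nuclei, mpp = mpp, image_size = image_size,
                   sample_id = sample_id)
}

# A small, quick synthetic slide shared by several tests.
small_slide <- function(seed = 7, intensities = NULL) {
  cfg <- slide_sim_config(
    image_size = c(1600, 1600), mpp = 1, downsample = 8,
    blob_radius_mm = 0.3,
    intensities = intensities %||% default_intensities(),
    seed = seed)
  simulate_slide(cfg, sample_id = paste0("small", seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
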