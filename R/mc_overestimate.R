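# Monte-Carlo quantification of the rectangle-search overestimation: how
# often does a centered-square search area return a cell that is not the
# globally nearest one?

#' Monte-Carlo probability of rectangle-search distance overestimation
#'
#' Considers a square search area of full side `2 * r1` centered at the
#' origin and `n_points` cells drawn uniformly in the surrounding circle.
#' An overestimation event occurs when at least one cell lies inside the
#' square while the cell globally nearest to the origin lies outside it: the
#' square search then stops with a non-nearest cell. Draws with no cell in
#' the square are not events - the expanding search keeps growing and, once
#' the search area covers the disk, finds the true minimum. With a single
#' cell the probability is therefore exactly zero.
#'
#' @param n_points Cells per draw (`N >= 1`).
#' @param replicates Number of Monte-Carlo draws.
#' @param seed Optional integer seed.
#' @param r1 Half side length of the square, default 1 (scale-free).
#' @param geometry Sampling-disk radius convention: `"inscribed"` (default)
#'   draws points in the circle the square is inscribed in (radius
#'   `r1 * sqrt(2)`); `"radius_2r1"` uses a circle of radius `2 * r1`.
#' @param chunk Replicates per vectorized block (memory control).
#' @return A tibble: `n_points`, `replicates`, `events`, `p_hat` (event
#'   frequency) and `se` (binomial Monte-Carlo standard error
#'   `sqrt(p(1-p)/replicates)`).
#' @export
#' @examples
#' mc_overestimation_probability(2, 1e4, seed = 1)
mc_overestimation_probability <- function(n_points, replicates, seed = NULL,
                                          r1 = 1,
                                          geometry = c("inscribed",
                                                       "radius_2r1"),
                                          chunk = 5e5) {
  geometry <- match.arg(geometry)
  if (n_points < 1) abort("n_points must be >= 1")
  if (n_points >= 10 && replicates < 1e6) {
    warn(paste0("fewer than 1e6 replicates: the event is rare at n_points >= 10, ",
                "the estimate will be noisy"))
  }
  disk_r <- if (geometry == "inscribed") r1 * sqrt(2) else 2 * r1
  if (!is.null(seed)) set.seed(seed)
  events <- 0
  done <- 0
  while (done < replicates) {
    m <- min(chunk, replicates - done)
    r <- disk_r * sqrt(runif(m * n_points))
    th <- runif(m * n_points) * 2 * pi
    x <- matrix(r * cos(th), m, n_points)
    y <- matrix(r * sin(th), m, n_points)
    d <- matrix(r, m, n_points)          # distance to the origin
    in_sq <- abs(x) <= r1 & abs(y) <= r1
    any_in <- rowSums(in_sq) > 0
    nearest <- max.col(-d, ties.method = "first")
    err <- any_in & !in_sq[cbind(seq_len(m), nearest)]
    events <- events + sum(err)
    done <- done + m
  }
  p <- events / replicates
  tibble(n_points = n_points, replicates = replicates, events = events,
         p_hat = p, se = sqrt(p * (1 - p) / replicates))
}
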