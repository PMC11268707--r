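# Core island-algorithm stages: elimination count, sea-level range update,
# and new-plant generation. The "island" is a single per-dimension box
# [x_min, x_max] that contracts around the surviving population as the sea
# level rises; h tracks how much the box changed in the last update.

#' Island habitat range
#'
#' @param x_min,x_max Numeric vectors of per-dimension lower/upper bounds.
#' @param h Non-negative range-change scalar (initial value 1).
#' @return A list of class `"island_range"`.
#' @export
island_range <- function(x_min, x_max, h = 1) {
  x_min <- as.numeric(x_min); x_max <- as.numeric(x_max)
  if (length(x_min) != length(x_max)) stop("bound length mismatch")
  if (any(x_min > x_max)) stop("x_min must not exceed x_max")
  if (h < 0) stop("h must be non-negative")
  structure(list(x_min = x_min, x_max = x_max, h = h),
            class = "island_range")
}

#' @export
print.island_range <- function(x, ...) {
  cat(sprintf("<island_range D=%d, h=%.4g>\n", length(x$x_min), x$h))
  invisible(x)
}

#' Number of plants eliminated this iteration
#'
#' The elimination schedule is a decreasing exponential in the range change
#' h: `floor((a_max - a_min) * exp(-h)) + a_min`, clamped so that at least
#' two plants always remain to span the island.
#'
#' @param h Non-negative range change.
#' @param a_max,a_min Maximum/minimum elimination counts.
#' @param N Population size.
#' @return Integer count in `[a_min, min(a_max, N - 2)]`.
#' @export
eliminate_count <- function(h, a_max, a_min, N) {
  if (h < 0) stop("h must be non-negative")
  if (a_min > a_max) stop("a_min must not exceed a_max")
  if (a_min < 2 || N < a_min + 2) {
    stop("need 2 <= a_min <= N - 2 so two plants always span the island")
  }
  k <- floor((a_max - a_min) * exp(-h)) + a_min
  as.integer(min(max(k, a_min), a_max, N - 2))
}

#' Sea-level range update
#'
#' Contracts the island towards the surviving plants, then relaxes each new
#' endpoint a uniform-random fraction of the way back towards the old one
#' (so the new bound lies between the survivor extreme and the old bound).
#' The range change h is the Euclidean norm of the per-dimension difference
#' between old and new widths.
#'
#' @param survivors Numeric matrix of surviving positions (rows = plants).
#' @param old_range An [island_range()].
#' @param rand_max,rand_min Optional explicit uniform draws (length-D
#'   vectors in `[0, 1]`) used for the upper/lower relaxations; defaults to
#'   fresh `runif` draws. Exposed for deterministic testing.
#' @return The updated `"island_range"`.
#' @export
update_range <- function(survivors, old_range, rand_max = NULL,
                         rand_min = NULL) {
  survivors <- as.matrix(survivors)
  if (nrow(survivors) < 1) stop("survivors must be non-empty")
  D <- ncol(survivors)
  if (is.null(rand_max)) rand_max <- stats::runif(D)
  if (is.null(rand_min)) rand_min <- stats::runif(D)
  s_max <- apply(survivors, 2, max)
  s_min <- apply(survivors, 2, min)
  # survivors may have stepped outside the previous box (the regeneration
  # move is clipped to the objective domain, not the island); widen the
  # effective old bounds so the relaxation interval is always well formed
  old_max <- pmax(old_range$x_max, s_max)
  old_min <- pmin(old_range$x_min, s_min)
  new_max <- s_max + rand_max * (old_max - s_max)
  new_min <- s_min + rand_min * (old_min - s_min)
  new_min <- pmin(new_min, new_max)   # guard 1-ulp crossings at collapse
  h <- sqrt(sum(((old_range$x_max - old_range$x_min) -
                   (new_max - new_min))^2))
  island_range(new_min, new_max, h)
}

#' Generate new plants inside the island
#'
#' Each new plant starts at an independent uniform position inside the
#' current range and is then pulled towards the incumbent best position by
#' `x + 2 * r * (best - x)` with an independent per-dimension uniform draw
#' `r` (step factor in `[0, 2]`, so draws of 0.5 land exactly on the best
#' and draws of 1 reflect through it). Results are clipped to the range.
#'
#' @param count Number of plants to generate (>= 1).
#' @param range An [island_range()].
#' @param best Numeric vector, the incumbent best position (clipped into
#'   the range if outside).
#' @param init Optional explicit initial positions (count x D matrix);
#'   defaults to uniform draws. For deterministic testing.
#' @param rand5 Optional explicit step-factor draws in `[0, 1]` (count x D
#'   matrix). For deterministic testing.
#' @param clip_lower,clip_upper Bounds the moved plants are clipped to;
#'   default is the island range itself. The optimizer passes the
#'   objective's domain instead, so that reflections through the best may
#'   leave the contracted island (this overshoot is the algorithm's
#'   basin-escape mechanism).
#' @return A `count` x D matrix of clipped positions.
#' @export
spawn_plants <- function(count, range, best, init = NULL, rand5 = NULL,
                         clip_lower = NULL, clip_upper = NULL) {
  stopifnot(count >= 1)
  D <- length(range$x_min)
  width <- range$x_max - range$x_min
  best <- pmin(pmax(as.numeric(best), range$x_min), range$x_max)
  if (is.null(init)) {
    init <- matrix(range$x_min, count, D, byrow = TRUE) +
      matrix(stats::runif(count * D), count, D) *
        matrix(width, count, D, byrow = TRUE)
  }
  if (is.null(rand5)) {
    rand5 <- matrix(stats::runif(count * D), count, D)
  }
  bestm <- matrix(best, count, D, byrow = TRUE)
  out <- init + 2 * rand5 * (bestm - init)
  if (is.null(clip_lower)) clip_lower <- range$x_min
  if (is.null(clip_upper)) clip_upper <- range$x_max
  lo <- matrix(clip_lower, count, D, byrow = TRUE)
  hi <- matrix(clip_upper, count, D, byrow = TRUE)
  pmin(pmax(out, lo), hi)
}
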