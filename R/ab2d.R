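# Adaptive-bifurcation 2D Otsu. Two lines through the threshold point
# (s, t) open a small angle alpha (0-5 degrees) against the quadrant
# boundaries: l1 makes angle alpha with the vertical x = s (slope
# -cot(alpha)), l2 makes angle alpha with the horizontal y = t (slope
# -tan(alpha)). The four thin wedges they enclose inside quadrants B and D
# are reclaimed: the two adjacent to the background box A join the
# background class, the two adjacent to the target box C join the target
# class. alpha is selected adaptively so that the occupied-cell ratio of
# the wedges reaches 0.75; if no angle in (0, 5] qualifies the wedges are
# abandoned and the classical quadrant rule stands.

.check_alpha <- function(alpha_deg) {
  if (!is.numeric(alpha_deg) || length(alpha_deg) != 1 ||
      alpha_deg < 0 || alpha_deg > 5) {
    stop("alpha must lie in [0, 5] degrees")
  }
  alpha_deg
}

# Per-column j-intervals of the four wedges, 0-based, inclusive.
# Returns for each wedge a data frame (i, jlo, jhi) with only non-empty
# columns retained. Cells exactly on l1/l2 belong to the wedge; cells on
# the quadrant boundaries x = s, y = t do not, so alpha -> 0 empties all
# four sets.
.wedge_ranges <- function(s, t, alpha_deg, L) {
  .check_alpha(alpha_deg)
  .check_st(s, t, L)
  empty <- data.frame(i = integer(), jlo = integer(), jhi = integer())
  if (alpha_deg == 0) {
    return(list(bg_wedge_D = empty, tg_wedge_D = empty,
                bg_wedge_B = empty, tg_wedge_B = empty))
  }
  a <- alpha_deg * pi / 180
  tanA <- tan(a); cotA <- 1 / tanA
  clipdf <- function(i, jlo, jhi) {
    jlo <- pmax(jlo, 0); jhi <- pmin(jhi, L - 1)
    keep <- jlo <= jhi
    data.frame(i = i[keep], jlo = jlo[keep], jhi = jhi[keep])
  }
  # quadrant D (i > s, j <= t)
  iD <- if (s + 1 <= L - 1) (s + 1):(L - 1) else integer()
  l1D <- (s - iD) * cotA + t
  l2D <- (s - iD) * tanA + t
  bg_D <- clipdf(iD, rep(0L, length(iD)), pmin(floor(l1D), t))
  tg_D <- clipdf(iD, ceiling(l2D), rep(t - 1L, length(iD)))
  # quadrant B (i <= s, j > t)
  iB <- 0:s
  l2B <- (s - iB) * tanA + t
  bg_B <- clipdf(iB, rep(t + 1L, length(iB)), floor(l2B))
  iB1 <- if (s >= 1) 0:(s - 1) else integer()
  l1B <- (s - iB1) * cotA + t
  tg_B <- clipdf(iB1, pmax(ceiling(l1B), t + 1L),
                 rep(L - 1L, length(iB1)))
  list(bg_wedge_D = bg_D, tg_wedge_D = tg_D,
       bg_wedge_B = bg_B, tg_wedge_B = tg_B)
}

.ranges_to_cells <- function(rng) {
  if (nrow(rng) == 0) {
    return(matrix(integer(), 0, 2, dimnames = list(NULL, c("i", "j"))))
  }
  n <- rng$jhi - rng$jlo + 1L
  i <- rep(rng$i, n)
  j <- unlist(mapply(seq.int, rng$jlo, rng$jhi, SIMPLIFY = FALSE),
              use.names = FALSE)
  cbind(i = as.integer(i), j = as.integer(j))
}

#' Bifurcation wedge cell sets
#'
#' Enumerates the histogram cells of the four wedges enclosed between the
#' bifurcation lines and the quadrant boundaries, intersected with the
#' `[0, L-1]^2` grid. `bg_wedge_D`/`bg_wedge_B` are reclaimed into the
#' background class, `tg_wedge_B`/`tg_wedge_D` into the target class.
#' At `alpha = 0` all four sets are empty.
#'
#' @param s,t Threshold pair (0-based, in `[0, L-2]`).
#' @param alpha_deg Bifurcation angle in degrees, in `[0, 5]`.
#' @param L Number of levels.
#' @return List of four two-column integer matrices (columns `i`, `j`).
#' @export
wedges <- function(s, t, alpha_deg, L) {
  lapply(.wedge_ranges(s, t, alpha_deg, L), .ranges_to_cells)
}

#' Occupied-cell ratio of the bifurcation wedges
#'
#' The fraction of wedge cells that carry at least one count:
#' `N_alpha / (N_alpha + N_0)`.
#'
#' @param hist A `"histogram2d"`.
#' @inheritParams wedges
#' @return Ratio in `[0, 1]`.
#' @export
p_alpha <- function(hist, s, t, alpha_deg) {
  cells <- do.call(rbind, wedges(s, t, alpha_deg, hist$L))
  if (nrow(cells) == 0) {
    stop("wedge union is empty; the occupancy ratio is undefined")
  }
  occupied <- sum(hist$counts[cells + 1L] > 0)
  occupied / nrow(cells)
}

#' Adaptive selection of the bifurcation angle
#'
#' Scans angles `grid_step, 2*grid_step, ..., 5` degrees and returns the
#' smallest one whose wedge occupancy ratio reaches `p_target`; `NULL`
#' (wedges abandoned) when no grid angle qualifies.
#'
#' @param hist A `"histogram2d"`.
#' @param s,t Threshold pair.
#' @param grid_step_deg Angle grid step in degrees (default 0.25).
#' @param p_target Occupancy threshold (default 0.75).
#' @param largest If `TRUE`, return the largest qualifying angle instead of
#'   the smallest.
#' @return The selected angle in degrees, or `NULL`.
#' @export
select_alpha <- function(hist, s, t, grid_step_deg = 0.25,
                         p_target = 0.75, largest = FALSE) {
  grid <- seq(grid_step_deg, 5, by = grid_step_deg)
  if (largest) grid <- rev(grid)
  for (a in grid) {
    cells <- do.call(rbind, wedges(s, t, a, hist$L))
    if (nrow(cells) == 0) next
    if (sum(hist$counts[cells + 1L] > 0) / nrow(cells) >= p_target) {
      return(a)
    }
  }
  NULL
}

#' Bifurcated between-class variance
#'
#' With `alpha = NULL` this is exactly the classical [otsu_sigma()]. With
#' an angle, the background class is region A plus the two background
#' wedges and the target class is region C plus the two target wedges;
#' class masses and mean vectors are recomputed over the augmented cell
#' sets while the total mean is unchanged.
#'
#' @param hist A `"histogram2d"`.
#' @param s,t Threshold pair.
#' @param alpha_deg Angle in degrees in `[0, 5]`, or `NULL` for the
#'   classical statistic.
#' @return Non-negative scalar.
#' @export
sigma_ab <- function(hist, s, t, alpha_deg = NULL) {
  if (is.null(alpha_deg)) return(otsu_sigma(hist, s, t))
  L <- hist$L
  .check_st(s, t, L)
  w <- wedges(s, t, alpha_deg, L)
  P <- hist$probs
  iv <- 0:(L - 1)

  cell_sums <- function(cells) {
    if (nrow(cells) == 0) return(c(0, 0, 0))
    p <- P[cells + 1L]
    c(sum(p), sum(cells[, "i"] * p), sum(cells[, "j"] * p))
  }
  A <- P[1:(s + 1), 1:(t + 1), drop = FALSE]
  C <- P[(s + 2):L, (t + 2):L, drop = FALSE]
  sA <- c(sum(A), sum(iv[1:(s + 1)] * rowSums(A)),
          sum(iv[1:(t + 1)] * colSums(A)))
  sC <- c(sum(C), sum(iv[(s + 2):L] * rowSums(C)),
          sum(iv[(t + 2):L] * colSums(C)))
  s1 <- sA + cell_sums(w$bg_wedge_D) + cell_sums(w$bg_wedge_B)
  s2 <- sC + cell_sums(w$tg_wedge_B) + cell_sums(w$tg_wedge_D)
  muT <- c(sum(iv * rowSums(P)), sum(iv * colSums(P)))

  out <- 0
  if (s1[1] > 0) {
    out <- out + ((s1[2] - s1[1] * muT[1])^2 +
                    (s1[3] - s1[1] * muT[2])^2) / s1[1]
  }
  if (s2[1] > 0) {
    out <- out + ((s2[2] - s2[1] * muT[1])^2 +
                    (s2[3] - s2[1] * muT[2])^2) / s2[1]
  }
  out
}

#' Augmented class masses
#'
#' Masses of the background and target classes after wedge augmentation,
#' plus the probability mass left outside all six regions. Useful for
#' conservation checks.
#'
#' @inheritParams sigma_ab
#' @return List with `w1`, `w2`, `outside`.
#' @export
ab_class_masses <- function(hist, s, t, alpha_deg = NULL) {
  L <- hist$L
  st <- class_stats(hist, s, t)
  if (is.null(alpha_deg)) {
    return(list(w1 = st$w1, w2 = st$w2, outside = 1 - st$w1 - st$w2))
  }
  w <- wedges(s, t, alpha_deg, L)
  m <- function(cells) if (nrow(cells) == 0) 0 else sum(hist$probs[cells + 1L])
  w1 <- st$w1 + m(w$bg_wedge_D) + m(w$bg_wedge_B)
  w2 <- st$w2 + m(w$tg_wedge_B) + m(w$tg_wedge_D)
  list(w1 = w1, w2 = w2, outside = 1 - w1 - w2)
}
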