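# Independent brute-force oracles. These deliberately avoid the package's
# cumulative-sum / column-interval implementations: everything here is a
# plain double loop or a full-plane logical mask, so agreement is a real
# cross-check.

rand_hist <- function(L = 16, seed = 1, sparsity = 0.5) {
  set.seed(seed)
  counts <- matrix(stats::rpois(L * L, 3), L, L)
  counts[stats::runif(L * L) < sparsity] <- 0
  if (sum(counts) == 0) counts[1, 1] <- 1
  histogram2d(counts)
}

# Eq-by-eq class statistics and between-class variance, cell by cell.
naive_sigma <- function(hist, s, t) {
  P <- hist$probs
  L <- hist$L
  w1 <- w2 <- 0
  m1 <- m2 <- muT <- c(0, 0)
  for (i in 0:(L - 1)) {
    for (j in 0:(L - 1)) {
      p <- P[i + 1, j + 1]
      muT <- muT + c(i, j) * p
      if (i <= s && j <= t) {
        w1 <- w1 + p; m1 <- m1 + c(i, j) * p
      } else if (i > s && j > t) {
        w2 <- w2 + p; m2 <- m2 + c(i, j) * p
      }
    }
  }
  mu1 <- if (w1 > 0) m1 / w1 else c(0, 0)
  mu2 <- if (w2 > 0) m2 / w2 else c(0, 0)
  w1 * sum((mu1 - muT)^2) + w2 * sum((mu2 - muT)^2)
}

# Full-plane mask version of the wedge geometry.
naive_wedge_masks <- function(s, t, alpha_deg, L) {
  iM <- matrix(0:(L - 1), L, L)
  jM <- matrix(0:(L - 1), L, L, byrow = TRUE)
  f <- matrix(FALSE, L, L)
  if (alpha_deg == 0) {
    return(list(bg_wedge_D = f, tg_wedge_D = f,
                bg_wedge_B = f, tg_wedge_B = f))
  }
  a <- alpha_deg * pi / 180
  l1 <- (s - iM) / tan(a) + t
  l2 <- (s - iM) * tan(a) + t
  list(bg_wedge_D = iM > s & jM <= t & jM <= l1,
       tg_wedge_D = iM > s & jM < t & jM >= l2,
       bg_wedge_B = iM <= s & jM > t & jM <= l2,
       tg_wedge_B = iM < s & jM > t & jM >= l1)
}

# Bifurcated variance by explicit cell-set enumeration over the masks.
naive_sigma_ab <- function(hist, s, t, alpha_deg) {
  if (is.null(alpha_deg)) return(naive_sigma(hist, s, t))
  P <- hist$probs
  L <- hist$L
  m <- naive_wedge_masks(s, t, alpha_deg, L)
  iM <- matrix(0:(L - 1), L, L)
  jM <- matrix(0:(L - 1), L, L, byrow = TRUE)
  cls1 <- (iM <= s & jM <= t) | m$bg_wedge_D | m$bg_wedge_B
  cls2 <- (iM > s & jM > t) | m$tg_wedge_B | m$tg_wedge_D
  w1 <- sum(P[cls1]); w2 <- sum(P[cls2])
  muT <- c(sum(iM * P), sum(jM * P))
  mu1 <- if (w1 > 0) c(sum(iM[cls1] * P[cls1]), sum(jM[cls1] * P[cls1])) / w1
         else c(0, 0)
  mu2 <- if (w2 > 0) c(sum(iM[cls2] * P[cls2]), sum(jM[cls2] * P[cls2])) / w2
         else c(0, 0)
  w1 * sum((mu1 - muT)^2) + w2 * sum((mu2 - muT)^2)
}

# Independent exhaustive threshold scan: opposite loop nesting (t outer),
# naive statistics, same tie rule.
naive_exhaustive <- function(hist) {
  L <- hist$L
  best <- -1; bs <- bt <- 0     # sigma is non-negative
  for (t in 0:(L - 2)) {
    for (s in 0:(L - 2)) {
      v <- naive_sigma(hist, s, t)
      if (v > best + 1e-15 * max(1, abs(best))) {
        best <- v; bs <- s; bt <- t
      } else if (abs(v - best) <= 1e-15 * max(1, abs(best)) &&
                 (s < bs || (s == bs && t < bt))) {
        bs <- s; bt <- t
      }
    }
  }
  list(s = bs, t = bt, sigma = best)
}

# Exhaustive bifurcated search with the same adaptive angle rule used by
# find_threshold, for small-L oracle-equality tests.
exhaustive_ab <- function(hist, grid_step_deg = 0.25) {
  L <- hist$L
  best <- -Inf; bs <- bt <- 0; ba <- NULL
  for (s in 0:(L - 2)) {
    for (t in 0:(L - 2)) {
      a <- select_alpha(hist, s, t, grid_step_deg = grid_step_deg)
      v <- sigma_ab(hist, s, t, a)
      if (v > best) { best <- v; bs <- s; bt <- t; ba <- a }
    }
  }
  list(s = bs, t = bt, alpha = ba, sigma = best)
}

quantize_levels <- function(image, L) {
  m <- as.integer(floor(image / (256 / L)))
  matrix(pmin(pmax(m, 0L), L - 1L), nrow(image), ncol(image))
}
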