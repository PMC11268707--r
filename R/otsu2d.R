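# Classical two-dimensional Otsu machinery. The joint histogram pairs each
# pixel's gray level i with its neighbourhood-mean level j; a threshold
# pair (s, t) cuts the L x L plane into quadrants A (background,
# [0..s] x [0..t]), C (target, [s+1..L-1] x [t+1..L-1]) and the
# conventionally discarded off-diagonal quadrants B and D. All cell
# coordinates are 0-based; matrix storage is counts[i + 1, j + 1].

#' Validate a grayscale image
#'
#' @param pixels Integer-valued matrix with values in `[0, L - 1]`.
#' @param L Number of gray levels (default 256).
#' @return The matrix, invisibly, after validation.
#' @export
as_gray_image <- function(pixels, L = 256) {
  pixels <- as.matrix(pixels)
  if (nrow(pixels) < 2 || ncol(pixels) < 2) stop("image must be at least 2x2")
  if (any(pixels != round(pixels))) stop("pixel values must be integers")
  if (any(pixels < 0) || any(pixels > L - 1)) {
    stop("pixel values must lie in [0, L-1]")
  }
  storage.mode(pixels) <- "integer"
  invisible(pixels)
}

#' Neighbourhood-mean image
#'
#' Each output pixel is the arithmetic mean of the square window centred on
#' it (borders replicate-padded), rounded half-up to an integer level.
#'
#' @param image Integer matrix of gray levels.
#' @param window Odd window size, default 3.
#' @param L Number of gray levels.
#' @return Integer matrix of the same shape.
#' @export
neighborhood_mean <- function(image, window = 3, L = 256) {
  if (window %% 2 != 1 || window < 3) stop("window must be odd and >= 3")
  image <- as_gray_image(image, L)
  nr <- nrow(image); nc <- ncol(image)
  half <- (window - 1) %/% 2
  acc <- matrix(0, nr, nc)
  for (dr in -half:half) {
    ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
    for (dc in -half:half) {
      ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
      acc <- acc + image[ri, ci]
    }
  }
  out <- floor(acc / (window^2) + 0.5)   # round half-up
  out <- pmin(pmax(out, 0), L - 1)
  storage.mode(out) <- "integer"
  out
}

#' Build the 2D (gray, neighbourhood-mean) histogram
#'
#' @param image Gray-level image.
#' @param mean_image Its neighbourhood-mean image (same shape and L).
#' @param L Number of levels.
#' @return A list of class `"histogram2d"`: `counts` (L x L integer,
#'   `counts[i+1, j+1]` = number of pixels with gray i and mean j), `probs`
#'   (`counts / n_pixels`), `n_pixels`, `L`.
#' @export
build_histogram <- function(image, mean_image, L = 256) {
  image <- as_gray_image(image, L)
  mean_image <- as_gray_image(mean_image, L)
  if (!all(dim(image) == dim(mean_image))) stop("shape mismatch")
  idx <- as.integer(image) + as.integer(mean_image) * L + 1L
  counts <- matrix(tabulate(idx, nbins = L * L), L, L)
  n <- length(image)
  structure(list(counts = counts, probs = counts / n, n_pixels = n, L = L),
            class = "histogram2d")
}

#' Construct a histogram2d from a counts matrix
#'
#' @param counts Square non-negative count (or weight) matrix.
#' @return A `"histogram2d"`.
#' @export
histogram2d <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("counts must be square")
  if (any(counts < 0)) stop("counts must be non-negative")
  n <- sum(counts)
  if (n <= 0) stop("histogram must have positive total mass")
  structure(list(counts = counts, probs = counts / n, n_pixels = n,
                 L = nrow(counts)),
            class = "histogram2d")
}

#' @export
print.histogram2d <- function(x, ...) {
  cat(sprintf("<histogram2d L=%d, n=%g, occupied cells=%d>\n",
              x$L, x$n_pixels, sum(x$counts > 0)))
  invisible(x)
}

#' Class statistics at a threshold pair
#'
#' Background mass `w1` is taken over the closed box `[0..s] x [0..t]`,
#' target mass `w2` over `[s+1..L-1] x [t+1..L-1]`. Class mean vectors are
#' mass-weighted (i, j) means, defined as the zero vector for an empty
#' class; the total mean `muT` is taken over the full histogram.
#'
#' @param hist A `"histogram2d"`.
#' @param s,t Threshold pair, 0-based, each in `[0, L - 2]`.
#' @return List with `w1`, `w2`, `mu1`, `mu2`, `muT`.
#' @export
class_stats <- function(hist, s, t) {
  L <- hist$L
  .check_st(s, t, L)
  P <- hist$probs
  iv <- 0:(L - 1)
  A <- P[1:(s + 1), 1:(t + 1), drop = FALSE]
  C <- P[(s + 2):L, (t + 2):L, drop = FALSE]
  w1 <- sum(A); w2 <- sum(C)
  mu1 <- if (w1 > 0) {
    c(sum(iv[1:(s + 1)] * rowSums(A)), sum(iv[1:(t + 1)] * colSums(A))) / w1
  } else c(0, 0)
  mu2 <- if (w2 > 0) {
    c(sum(iv[(s + 2):L] * rowSums(C)), sum(iv[(t + 2):L] * colSums(C))) / w2
  } else c(0, 0)
  muT <- c(sum(iv * rowSums(P)), sum(iv * colSums(P)))
  list(w1 = w1, w2 = w2, mu1 = mu1, mu2 = mu2, muT = muT)
}

.check_st <- function(s, t, L) {
  if (s != round(s) || t != round(t) || s < 0 || t < 0 ||
      s > L - 2 || t > L - 2) {
    stop("thresholds s, t must be integers in [0, L-2]")
  }
}

#' Between-class variance of the 2D histogram
#'
#' `sigma = w1 * ||mu1 - muT||^2 + w2 * ||mu2 - muT||^2` with the class
#' statistics of [class_stats()].
#'
#' @inheritParams class_stats
#' @return Non-negative scalar.
#' @export
otsu_sigma <- function(hist, s, t) {
  st <- class_stats(hist, s, t)
  st$w1 * sum((st$mu1 - st$muT)^2) + st$w2 * sum((st$mu2 - st$muT)^2)
}

#' Exhaustive 2D Otsu threshold search
#'
#' Evaluates the between-class variance for every threshold pair
#' `(s, t)` in `[0, L-2]^2` (via cumulative-sum tables) and returns the
#' argmax; ties are broken by the smallest s, then the smallest t.
#'
#' @param hist A `"histogram2d"`.
#' @return List with `s`, `t`, `sigma`.
#' @export
exhaustive_threshold <- function(hist) {
  L <- hist$L
  P <- hist$probs
  iv <- 0:(L - 1)
  cum2 <- function(M) apply(apply(M, 2, cumsum), 1, cumsum) |> t()
  W <- cum2(P)
  Si <- cum2(P * iv)                     # i varies along rows, recycled
  Sj <- cum2(sweep(P, 2, iv, "*"))
  muT <- c(Si[L, L], Sj[L, L])

  ss <- 1:(L - 1)                        # matrix indices for s = 0..L-2
  w1 <- W[ss, ss, drop = FALSE]
  m1i <- Si[ss, ss, drop = FALSE]; m1j <- Sj[ss, ss, drop = FALSE]
  rw <- W[ss, L]; cw <- W[L, ss]
  w2 <- 1 - outer(rw, rep(1, L - 1)) - outer(rep(1, L - 1), cw) + w1
  m2i <- muT[1] - outer(Si[ss, L], rep(1, L - 1)) -
    outer(rep(1, L - 1), Si[L, ss]) + m1i
  m2j <- muT[2] - outer(Sj[ss, L], rep(1, L - 1)) -
    outer(rep(1, L - 1), Sj[L, ss]) + m1j

  sig <- matrix(0, L - 1, L - 1)
  pos1 <- w1 > 0
  sig[pos1] <- sig[pos1] +
    ((m1i[pos1] - w1[pos1] * muT[1])^2 +
       (m1j[pos1] - w1[pos1] * muT[2])^2) / w1[pos1]
  pos2 <- w2 > 0
  sig[pos2] <- sig[pos2] +
    ((m2i[pos2] - w2[pos2] * muT[1])^2 +
       (m2j[pos2] - w2[pos2] * muT[2])^2) / w2[pos2]

  best <- max(sig)
  hits <- which(sig == best, arr.ind = TRUE)
  s <- min(hits[, 1])
  t <- min(hits[hits[, 1] == s, 2])
  list(s = as.integer(s - 1), t = as.integer(t - 1), sigma = best)
}

#' Write / read a histogram as plain-text CSV
#'
#' Format: a first line `L,<levels>` followed by the L x L count matrix,
#' one row of gray level i per line.
#'
#' @param hist A `"histogram2d"`.
#' @param path File path.
#' @return `write_histogram_csv` returns `path` invisibly;
#'   `read_histogram_csv` returns a `"histogram2d"`.
#' @export
write_histogram_csv <- function(hist, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("L,", hist$L), con)
  utils::write.table(hist$counts, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_histogram_csv
#' @export
read_histogram_csv <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1], ",")[[1]]
  if (hdr[1] != "L") stop("not a histogram CSV (missing L header)")
  L <- as.integer(hdr[2])
  counts <- as.matrix(utils::read.table(text = lines[-1], sep = ","))
  dimnames(counts) <- NULL
  if (!all(dim(counts) == L)) stop("histogram CSV dimension mismatch")
  histogram2d(counts)
}
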