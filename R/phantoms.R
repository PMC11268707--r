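# Synthetic two-class phantom images and constructed histogram fixtures.
# Phantoms stand in for real grayscale scans: a geometric foreground shape
# on a flat background, with controllable class means, additive Gaussian
# noise, and salt-and-pepper corruption, plus an exact ground-truth mask.

#' Generate a two-class phantom image
#'
#' The foreground shape is drawn at `fg_mean` on a `bg_mean` background;
#' Gaussian noise is added, values are clipped to `[0, 255]` and rounded
#' (in that order), then a fraction of pixels is replaced by salt (255) or
#' pepper (0) with equal probability. Fully reproducible from `seed`.
#'
#' @param width,height Canvas size in pixels.
#' @param bg_mean,fg_mean Background/foreground levels in `[0, 255]`
#'   (must differ). Defaults 60 / 180.
#' @param noise_sd Gaussian noise standard deviation (>= 0), default 10.
#' @param salt_pepper_frac Fraction of corrupted pixels in `[0, 1)`.
#' @param shape `"disk"`, `"rectangle"`, or `"two_lobes"` (two disks,
#'   loosely emulating a pair of lungs).
#' @param radius Disk radius (or half the rectangle side); default
#'   `min(width, height) / 4` (`/ 6` per lobe for `"two_lobes"`).
#' @param seed Integer RNG seed.
#' @return List with `image` (integer matrix, levels 0-255) and `truth`
#'   (0/1 foreground mask).
#' @export
make_phantom <- function(width = 128, height = 128, bg_mean = 60,
                         fg_mean = 180, noise_sd = 10,
                         salt_pepper_frac = 0, shape = c("disk",
                         "rectangle", "two_lobes"), radius = NULL,
                         seed = 1) {
  shape <- match.arg(shape)
  stopifnot(bg_mean != fg_mean, bg_mean >= 0, bg_mean <= 255,
            fg_mean >= 0, fg_mean <= 255, noise_sd >= 0,
            salt_pepper_frac >= 0, salt_pepper_frac < 1)
  xs <- matrix(rep(seq_len(width), each = height), height, width)
  ys <- matrix(rep(seq_len(height), width), height, width)
  disk_mask <- function(cx, cy, r) (xs - cx)^2 + (ys - cy)^2 <= r^2
  truth <- switch(shape,
    disk = {
      r <- if (is.null(radius)) min(width, height) / 4 else radius
      if (2 * r > min(width, height)) stop("shape larger than canvas")
      disk_mask(ceiling(width / 2), ceiling(height / 2), r)
    },
    rectangle = {
      r <- if (is.null(radius)) min(width, height) / 4 else radius
      if (2 * r > min(width, height)) stop("shape larger than canvas")
      abs(xs - ceiling(width / 2)) <= r & abs(ys - ceiling(height / 2)) <= r
    },
    two_lobes = {
      r <- if (is.null(radius)) min(width, height) / 6 else radius
      if (2 * r > min(width, height)) stop("shape larger than canvas")
      disk_mask(round(width / 3), ceiling(height / 2), r) |
        disk_mask(round(2 * width / 3), ceiling(height / 2), r)
    })
  set.seed(seed)
  img <- ifelse(truth, fg_mean, bg_mean)
  if (noise_sd > 0) {
    img <- img + stats::rnorm(length(img), sd = noise_sd)
  }
  img <- round(pmin(pmax(img, 0), 255))
  if (salt_pepper_frac > 0) {
    n <- length(img)
    k <- round(salt_pepper_frac * n)
    idx <- sample.int(n, k)
    img[idx] <- 255 * stats::rbinom(k, 1, 0.5)
  }
  img <- matrix(as.integer(img), height, width)
  list(image = img, truth = matrix(as.integer(truth), height, width))
}

#' Construct a histogram fixture with planted wedge occupancy
#'
#' Builds a small joint histogram whose mass sits in the background box A
#' and target box C, plus exactly `ceiling(occupancy * |wedge|)` occupied
#' wedge cells for the given angle, enabling exact occupancy-ratio
#' targets. Wedge cells are occupied in a fixed enumeration order, so the
#' fixture is deterministic.
#'
#' @param L Number of levels (<= 64 keeps enumeration cheap).
#' @param s,t Threshold pair.
#' @param alpha_deg Wedge angle in `(0, 5]` degrees.
#' @param occupancy Fraction of wedge cells to occupy, in `[0, 1]`.
#' @param wedge_count Count placed in each occupied wedge cell (default 1).
#' @return A `"histogram2d"`.
#' @export
make_wedge_fixture <- function(L, s, t, alpha_deg, occupancy,
                               wedge_count = 1) {
  stopifnot(L <= 64)
  if (occupancy < 0 || occupancy > 1) stop("occupancy must be in [0, 1]")
  cells <- do.call(rbind, wedges(s, t, alpha_deg, L))
  if (nrow(cells) == 0) stop("wedge union is empty for this geometry")
  counts <- matrix(0, L, L)
  counts[ceiling((s + 1) / 2), ceiling((t + 1) / 2)] <- 100
  counts[s + 1 + ceiling((L - s - 1) / 2),
         t + 1 + ceiling((L - t - 1) / 2)] <- 100
  k <- ceiling(occupancy * nrow(cells))
  if (k > 0) {
    counts[cells[seq_len(k), , drop = FALSE] + 1L] <- wedge_count
  }
  histogram2d(counts)
}
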