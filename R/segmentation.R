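# End-to-end segmentation: metaheuristic search over the threshold pair
# (s, t) maximizing the (bifurcated) between-class variance, binarization
# of the image by histogram-cell membership, and PSNR/MSE quality metrics.

#' Search for the optimal threshold pair
#'
#' Runs the island optimizer over the continuous square `[0, L-2]^2`;
#' every candidate is rounded to an integer pair (s, t), the bifurcation
#' angle is re-selected for that pair, and the negated bifurcated variance
#' is minimized. Evaluations are memoized per integer cell, so repeated
#' visits cost nothing.
#'
#' @param image Gray-level image matrix.
#' @param config An [optimizer_config()]; the dimension is forced to 2 and
#'   defaults are scaled down for the small 2-D integer search space
#'   (`N = 50`, `T_max = 60`).
#' @param ab_enabled Use the adaptive bifurcation (`TRUE`) or the classical
#'   quadrant statistic (`FALSE`).
#' @param window Neighbourhood-mean window (odd, default 3).
#' @param L Number of gray levels.
#' @param grid_step_deg Angle grid step passed to [select_alpha()].
#' @return A list of class `"ab_threshold"`: integers `s`, `t`, the chosen
#'   `alpha_deg` (`NULL` when the wedges are abandoned or disabled),
#'   `sigma` (the attained variance), and the `optimizer` result.
#' @export
find_threshold <- function(image, config = NULL, ab_enabled = TRUE,
                           window = 3, L = 256, grid_step_deg = 0.25) {
  image <- as_gray_image(image, L)
  mimg <- neighborhood_mean(image, window, L)
  hist <- build_histogram(image, mimg, L)
  if (sum(hist$counts > 0) < 2) {
    warning("degenerate image with a single occupied histogram cell")
    return(structure(list(s = 0L, t = 0L, alpha_deg = NULL, sigma = 0,
                          optimizer = NULL, hist = hist),
                     class = "ab_threshold"))
  }
  if (is.null(config)) config <- optimizer_config(N = 50, T_max = 60)
  config$D <- 2L

  memo <- new.env(hash = TRUE, parent = emptyenv())
  eval_cell <- function(s, t) {
    key <- paste0(s, ",", t)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    alpha <- if (ab_enabled) {
      select_alpha(hist, s, t, grid_step_deg = grid_step_deg)
    } else NULL
    val <- list(sigma = sigma_ab(hist, s, t, alpha), alpha = alpha)
    memo[[key]] <- val
    val
  }
  obj <- island_objective(
    fn = function(X) {
      ss <- pmin(pmax(round(X[, 1]), 0), L - 2)
      tt <- pmin(pmax(round(X[, 2]), 0), L - 2)
      vapply(seq_len(nrow(X)),
             function(k) -eval_cell(ss[k], tt[k])$sigma, numeric(1))
    },
    lower = c(0, 0), upper = c(L - 2, L - 2),
    name = "ab2d-otsu"
  )
  res <- island_optimize(obj, config)
  s <- as.integer(min(max(round(res$best_position[1]), 0), L - 2))
  t <- as.integer(min(max(round(res$best_position[2]), 0), L - 2))
  cell <- eval_cell(s, t)
  structure(list(s = s, t = t, alpha_deg = cell$alpha,
                 sigma = cell$sigma, optimizer = res, hist = hist),
            class = "ab_threshold")
}

#' @export
print.ab_threshold <- function(x, ...) {
  cat(sprintf("<ab_threshold s=%d t=%d alpha=%s sigma=%.4f>\n",
              x$s, x$t,
              if (is.null(x$alpha_deg)) "none" else
                sprintf("%.2f deg", x$alpha_deg),
              x$sigma))
  invisible(x)
}

# 0/1 cell-classification lookup table for a threshold: 1 = target,
# 0 = background. Unassigned B/D cells follow bd_policy.
.cell_labels <- function(thr, L, bd_policy = c("background", "nearest")) {
  bd_policy <- match.arg(bd_policy)
  s <- thr$s; t <- thr$t
  lab <- matrix(NA_integer_, L, L)
  iM <- row(lab) - 1L; jM <- col(lab) - 1L
  lab[iM <= s & jM <= t] <- 0L
  lab[iM > s & jM > t] <- 1L
  if (!is.null(thr$alpha_deg)) {
    w <- wedges(s, t, thr$alpha_deg, L)
    lab[w$bg_wedge_D + 1L] <- 0L
    lab[w$bg_wedge_B + 1L] <- 0L
    lab[w$tg_wedge_B + 1L] <- 1L
    lab[w$tg_wedge_D + 1L] <- 1L
  }
  un <- is.na(lab)
  if (any(un)) {
    if (bd_policy == "background") {
      lab[un] <- 0L
    } else {
      dA <- pmax(iM - s, 0L) + pmax(jM - t, 0L)
      dC <- pmax(s + 1L - iM, 0L) + pmax(t + 1L - jM, 0L)
      lab[un] <- as.integer(dC[un] < dA[un])
    }
  }
  lab
}

#' Binarize an image at a threshold
#'
#' Each pixel is classified by the membership of its (gray, neighbourhood
#' mean) tuple: target for the closed upper quadrant and the target
#' wedges, background for the lower quadrant and the background wedges.
#' Remaining off-diagonal cells follow `bd_policy`: `"background"`
#' (conservative default) or `"nearest"` (Manhattan distance to the
#' background/target boxes).
#'
#' @param image Gray-level image.
#' @param mean_image Its neighbourhood-mean image.
#' @param thr An `"ab_threshold"` (or any list with `s`, `t`, `alpha_deg`).
#' @param L Number of levels.
#' @param bd_policy Assignment rule for unclaimed B/D cells.
#' @return Integer 0/1 mask of the image's shape.
#' @export
binarize <- function(image, mean_image, thr, L = 256,
                     bd_policy = c("background", "nearest")) {
  image <- as_gray_image(image, L)
  mean_image <- as_gray_image(mean_image, L)
  if (!all(dim(image) == dim(mean_image))) stop("shape mismatch")
  lab <- .cell_labels(thr, L, bd_policy)
  mask <- lab[cbind(as.integer(image) + 1L, as.integer(mean_image) + 1L)]
  matrix(mask, nrow(image), ncol(image))
}

#' Mean squared error between two images
#'
#' @param reference,segmented Numeric matrices of equal shape (a 0/1 mask
#'   should be rendered at levels 0/255 before comparison, see
#'   [render_mask()]).
#' @return Non-negative scalar.
#' @export
img_mse <- function(reference, segmented) {
  if (!all(dim(reference) == dim(segmented))) stop("shape mismatch")
  mean((as.numeric(reference) - as.numeric(segmented))^2)
}

#' Peak signal-to-noise ratio in dB
#'
#' `10 * log10(max_level^2 / MSE)`; `Inf` when the images are identical.
#'
#' @inheritParams img_mse
#' @param max_level Peak level (255 for 8-bit images).
#' @return PSNR in dB (possibly `Inf`).
#' @export
img_psnr <- function(reference, segmented, max_level = 255) {
  m <- img_mse(reference, segmented)
  if (m == 0) return(Inf)
  10 * log10(max_level^2 / m)
}

#' Render a 0/1 mask at display levels
#'
#' @param mask Integer 0/1 matrix.
#' @param high Level for the target class (default 255).
#' @return Matrix with values 0 / `high`.
#' @export
render_mask <- function(mask, high = 255) mask * high

#' Full segmentation pipeline
#'
#' Threshold search, binarization, and quality metrics (PSNR/MSE of the
#' 0/255-rendered mask against the original grayscale image).
#'
#' @inheritParams find_threshold
#' @inheritParams binarize
#' @return A list of class `"segmentation_result"`: `threshold`, `mask`
#'   (0/1), `mse`, `psnr_db`, `optimizer_trace`.
#' @export
segment_image <- function(image, config = NULL, ab_enabled = TRUE,
                          window = 3, L = 256, grid_step_deg = 0.25,
                          bd_policy = c("background", "nearest")) {
  image <- as_gray_image(image, L)
  thr <- find_threshold(image, config, ab_enabled, window, L,
                        grid_step_deg)
  mimg <- neighborhood_mean(image, window, L)
  mask <- binarize(image, mimg, thr, L, bd_policy)
  rendered <- render_mask(mask)
  structure(list(threshold = thr, mask = mask,
                 mse = img_mse(image, rendered),
                 psnr_db = img_psnr(image, rendered),
                 optimizer_trace = thr$optimizer),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf(
    "<segmentation s=%d t=%d alpha=%s sigma=%.2f psnr=%.4f dB mse=%.2f>\n",
    x$threshold$s, x$threshold$t,
    if (is.null(x$threshold$alpha_deg)) "none" else
      sprintf("%.2f", x$threshold$alpha_deg),
    x$threshold$sigma, x$psnr_db, x$mse))
  invisible(x)
}
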