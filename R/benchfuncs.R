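# Benchmark objective registry: seven classical test functions with their
# search domains and known global minima, used to exercise and accept the
# optimizer. All evaluators are vectorized over the rows of a matrix.

# Known minima for the non-trivial cases, frozen from a one-off numerical
# oracle (dense grid scan + L-BFGS-B refinement; see tests for the live
# cross-check):
#   Branin:  f(-pi, 12.275) = 0.3978873577297380
#   Salomon: global minimum 0 at the origin; first radial ring has
#            stationary value 0.09987334584681 at ||x|| = 0.99746686.
.BRANIN_MIN <- 0.3978873577297380

.bench_registry <- list(
  f1 = list(
    name = "Sphere", dims_rule = "any-D",
    lower = -5.12, upper = 5.12, known_optimum = 0,
    fn = function(X) rowSums(X^2)
  ),
  f2 = list(
    name = "Dixon-Price", dims_rule = "any-D",
    lower = -10, upper = 10, known_optimum = 0,
    fn = function(X) {
      D <- ncol(X)
      out <- (X[, 1] - 1)^2
      if (D >= 2) {
        for (i in 2:D) out <- out + i * (2 * X[, i]^2 - X[, i - 1])^2
      }
      out
    }
  ),
  f3 = list(
    name = "Rastrigin", dims_rule = "any-D",
    # domain implemented exactly as tabulated, lower bound -5.21
    lower = -5.21, upper = 5.12, known_optimum = 0,
    fn = function(X) 10 * ncol(X) + rowSums(X^2 - 10 * cos(2 * pi * X))
  ),
  f4 = list(
    name = "Griewank", dims_rule = "any-D",
    lower = -600, upper = 600, known_optimum = 0,
    fn = function(X) {
      D <- ncol(X)
      pr <- cos(sweep(X, 2, sqrt(seq_len(D)), "/"))
      rowSums(X^2) / 4000 - apply(pr, 1, prod) + 1
    }
  ),
  f5 = list(
    name = "Salomon", dims_rule = "any-D",
    lower = -10, upper = 10, known_optimum = 0,
    # as tabulated, the radial variable is u = sum(x^2) (no square root);
    # the 1-D profile -cos(2*pi*u) + 0.1*u + 1 has its first ring at
    # u = 0.99746686 with value 0.09987334584681.
    fn = function(X) {
      u <- rowSums(X^2)
      -cos(2 * pi * u) + 0.1 * u + 1
    }
  ),
  f6 = list(
    name = "Branin", dims_rule = "fixed-2D",
    lower = c(-5, 0), upper = c(10, 15),
    known_optimum = 0.3978873577297380,
    fn = function(X) {
      b <- 5.1 / (4 * pi^2); c0 <- 5 / pi
      (X[, 2] - b * X[, 1]^2 + c0 * X[, 1] - 6)^2 +
        10 * (1 - 1 / (8 * pi)) * cos(X[, 1]) + 10
    }
  ),
  f7 = list(
    name = "Eggcrate", dims_rule = "fixed-2D",
    # unusual asymmetric domain, implemented as tabulated
    lower = -10, upper = 40, known_optimum = 0,
    fn = function(X) {
      X[, 1]^2 + X[, 2]^2 + 25 * (sin(X[, 1])^2 + sin(X[, 2])^2)
    }
  )
)

#' List available benchmark function ids
#'
#' @return Character vector `"f1"`..`"f7"`.
#' @export
bench_ids <- function() names(.bench_registry)

.bench_get <- function(id) {
  id <- as.character(id)
  if (!id %in% names(.bench_registry)) {
    stop("unknown benchmark function id: ", id, call. = FALSE)
  }
  .bench_registry[[id]]
}

#' Benchmark function metadata
#'
#' Returns the registry entry for one benchmark objective: its name, whether
#' it is defined for any dimension or fixed at two, its per-dimension domain,
#' and the known value of the global minimum.
#'
#' @param id Function id, one of `"f1"`..`"f7"`.
#' @return A list of class `"bench_fun"` with elements `id`, `name`,
#'   `dims_rule`, `lower`, `upper`, `known_optimum` and the vectorized
#'   evaluator `fn` (matrix in, numeric vector out).
#' @export
bench_fun <- function(id) {
  f <- .bench_get(id)
  structure(c(list(id = id), f), class = "bench_fun")
}

#' @export
print.bench_fun <- function(x, ...) {
  cat(sprintf("<bench_fun %s: %s (%s), optimum %g>\n",
              x$id, x$name, x$dims_rule, x$known_optimum))
  invisible(x)
}

#' Per-dimension search bounds of a benchmark function
#'
#' @param id Function id (`"f1"`..`"f7"`).
#' @param D Requested dimensionality (coerced to 2 for the fixed-2D
#'   functions `f6` and `f7`).
#' @return A list with numeric vectors `lower` and `upper`, each of length
#'   `D` (or 2).
#' @export
bench_bounds <- function(id, D) {
  f <- .bench_get(id)
  stopifnot(is.numeric(D), length(D) == 1, D >= 1)
  D <- as.integer(D)
  if (f$dims_rule == "fixed-2D") D <- 2L
  list(lower = rep_len(f$lower, D), upper = rep_len(f$upper, D))
}

#' Evaluate a benchmark function
#'
#' @param id Function id (`"f1"`..`"f7"`).
#' @param x Numeric vector (one point) or matrix (one point per row).
#' @return Numeric vector of objective values, one per point. Out-of-bounds
#'   points are evaluated as-is (the optimizer clips before calling).
#' @export
bench_evaluate <- function(id, x) {
  f <- .bench_get(id)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (f$dims_rule == "fixed-2D" && ncol(x) != 2) {
    stop(f$name, " is a fixed two-variable function; got ", ncol(x),
         " coordinates", call. = FALSE)
  }
  if (ncol(x) < 1) stop("empty point", call. = FALSE)
  v <- f$fn(x)
  if (any(!is.finite(v))) stop("non-finite objective value", call. = FALSE)
  v
}

#' Benchmark function as an optimizer objective
#'
#' Packages a registry entry into the objective interface consumed by
#' [island_optimize()]: vectorized evaluator, bounds, and the known optimum
#' used by the early-stop rule.
#'
#' @inheritParams bench_bounds
#' @return An `"island_objective"` list.
#' @export
bench_objective <- function(id, D) {
  f <- .bench_get(id)
  b <- bench_bounds(id, D)
  island_objective(
    fn = function(X) bench_evaluate(id, X),
    lower = b$lower, upper = b$upper,
    known_optimum = f$known_optimum,
    name = paste0(id, ".", f$name)
  )
}
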