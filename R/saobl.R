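# The hybrid optimizer: island algorithm with opposition-based learning on
# the survivors and a simulated-annealing filter on the newly generated
# plants. The full loop lives in island_optimize().

#' Objective for the island optimizer
#'
#' @param fn Function taking an n x D matrix of positions and returning n
#'   objective values (minimized). Wrap a scalar function with
#'   `function(X) apply(X, 1, f)` if needed.
#' @param lower,upper Per-dimension search bounds.
#' @param known_optimum Optional theoretical minimum; enables the
#'   optimum-reached stopping rule.
#' @param name Optional label.
#' @return A list of class `"island_objective"`.
#' @export
island_objective <- function(fn, lower, upper, known_optimum = NULL,
                             name = NULL) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (length(lower) != length(upper) || any(lower >= upper)) {
    stop("bounds must satisfy lower < upper per dimension")
  }
  structure(list(fn = fn, lower = lower, upper = upper,
                 known_optimum = known_optimum,
                 name = if (is.null(name)) "objective" else name),
            class = "island_objective")
}

#' Optimizer configuration
#'
#' Defaults are the reference setting of the method: 100 plants, 1500
#' iterations, elimination counts between 2 and 50, initial temperature 100
#' cooled geometrically by 0.99 per iteration, and an early stop when the
#' best value is within `stop_tol` of a registered theoretical optimum.
#'
#' @param N Population size (>= 4).
#' @param D Dimensionality (may be `NULL` when implied by the objective).
#' @param T_max Maximum number of iterations.
#' @param E Maximum number of objective evaluations (`Inf` = unlimited).
#' @param a_max,a_min Elimination bounds; `a_max` defaults to
#'   `min(50, N - 2)` so the reference setting scales to small
#'   populations.
#' @param t0 Initial annealing temperature (> 0).
#' @param cooling Geometric cooling factor in (0, 1).
#' @param seed Integer RNG seed (`NULL` = leave the RNG state alone).
#' @param stop_tol Tolerance on |best - known optimum| for the
#'   optimum-reached stop.
#' @param init_pm100 If `TRUE`, initialize the island at `[-100, 100]^D`
#'   regardless of the objective's declared bounds (legacy initialization).
#' @return A list of class `"optimizer_config"`.
#' @export
optimizer_config <- function(N = 100, D = NULL, T_max = 1500, E = Inf,
                             a_max = NULL, a_min = 2, t0 = 100,
                             cooling = 0.99, seed = NULL,
                             stop_tol = 1e-12, init_pm100 = FALSE) {
  if (N < 4) stop("N must be at least 4")
  if (is.null(a_max)) a_max <- min(50L, N - 2L)
  if (a_min > a_max) stop("a_min must not exceed a_max")
  if (a_max > N - 2) stop("a_max must not exceed N - 2")
  if (t0 <= 0) stop("initial temperature must be positive")
  if (cooling <= 0 || cooling >= 1) stop("cooling must be in (0, 1)")
  structure(list(N = as.integer(N), D = D, T_max = as.integer(T_max),
                 E = E, a_max = as.integer(a_max),
                 a_min = as.integer(a_min), t0 = t0, cooling = cooling,
                 seed = seed, stop_tol = stop_tol,
                 init_pm100 = isTRUE(init_pm100)),
            class = "optimizer_config")
}

#' Opposition point within the island range
#'
#' Mirrors a position through the centre of the current island range:
#' per dimension, `x_min + x_max - x`. The mapping is an involution and
#' fixes the range midpoint.
#'
#' @param point Numeric vector (clipped into the range first) or matrix
#'   (one point per row).
#' @param range An [island_range()].
#' @return Object of the same shape as `point`.
#' @export
opposition <- function(point, range) {
  if (is.matrix(point)) {
    lo <- matrix(range$x_min, nrow(point), ncol(point), byrow = TRUE)
    hi <- matrix(range$x_max, nrow(point), ncol(point), byrow = TRUE)
    point <- pmin(pmax(point, lo), hi)
    return(pmin(pmax(lo + hi - point, lo), hi))   # FP-safe
  }
  point <- pmin(pmax(as.numeric(point), range$x_min), range$x_max)
  out <- range$x_min + range$x_max - point
  pmin(pmax(out, range$x_min), range$x_max)
}

#' Greedy opposition-based selection
#'
#' Evaluates the opposition point of each position and keeps whichever of
#' the pair has the smaller objective value; exact ties go to the
#' opposition point. Consumes exactly one objective evaluation per
#' position.
#'
#' @param position Numeric vector or matrix (one position per row).
#' @param fitness Objective value(s) of `position`.
#' @param range An [island_range()].
#' @param objective Vectorized objective function (matrix -> vector).
#' @return List with elements `position`, `fitness`, and `n_evaluations`.
#' @export
obl_select <- function(position, fitness, range, objective) {
  vec <- !is.matrix(position)
  X <- if (vec) matrix(position, nrow = 1) else position
  opp <- opposition(X, range)
  ofit <- objective(opp)
  if (any(!is.finite(ofit))) stop("objective returned a non-finite value")
  take <- ofit <= fitness
  X[take, ] <- opp[take, , drop = FALSE]
  fitness[take] <- ofit[take]
  list(position = if (vec) drop(X) else X, fitness = fitness,
       n_evaluations = nrow(X))
}

#' Metropolis acceptance probability
#'
#' Probability of accepting a candidate with energy `e_new` against the
#' reference energy `e_ref` at the given temperature: 1 when the candidate
#' is strictly better, `exp(-(e_new - e_ref) / temperature)` otherwise.
#'
#' @param e_new,e_ref Candidate and reference energies (vectorized).
#' @param temperature Positive annealing temperature.
#' @return Probabilities in (0, 1].
#' @export
sa_accept_prob <- function(e_new, e_ref, temperature) {
  if (temperature <= 0) stop("temperature must be positive")
  ifelse(e_new < e_ref, 1, exp(-(e_new - e_ref) / temperature))
}

#' Simulated-annealing filter for new plants
#'
#' The reference plant sits at the 90th-percentile index of the sorted
#' survivors, `floor((N - n_out) * 0.9 + 0.5)` (1-based). Each new plant
#' is kept if it beats the reference fitness, kept with Metropolis
#' probability otherwise, and replaced by a copy of the reference plant
#' (position and fitness) when rejected.
#'
#' @param new_positions Matrix of newly generated plants.
#' @param new_fitness Their objective values.
#' @param surv_positions,surv_fitness Sorted (ascending fitness) survivors.
#' @param temperature Current annealing temperature.
#' @param u Optional explicit uniform draws for the acceptance decisions
#'   (length `nrow(new_positions)`); for deterministic testing.
#' @return List with `positions`, `fitness`, `n_accepted_worse` (worse
#'   candidates kept by the Metropolis rule) and `n_rejected`.
#' @export
anneal_filter <- function(new_positions, new_fitness, surv_positions,
                          surv_fitness, temperature, u = NULL) {
  n_new <- nrow(new_positions)
  n_surv <- length(surv_fitness)
  mid <- floor(n_surv * 0.9 + 0.5)         # MATLAB-style round-half-up
  mid <- min(max(mid, 1L), n_surv)
  e_ref <- surv_fitness[mid]
  p <- sa_accept_prob(new_fitness, e_ref, temperature)
  if (is.null(u)) u <- stats::runif(n_new)
  accept <- new_fitness < e_ref | u < p
  worse_kept <- sum(accept & new_fitness >= e_ref)
  if (any(!accept)) {
    new_positions[!accept, ] <- matrix(surv_positions[mid, ],
                                       sum(!accept), ncol(new_positions),
                                       byrow = TRUE)
    new_fitness[!accept] <- e_ref
  }
  list(positions = new_positions, fitness = new_fitness,
       n_accepted_worse = worse_kept, n_rejected = sum(!accept))
}

#' Run the hybrid island optimizer
#'
#' One iteration: (i) compute the elimination count from the current range
#' change h; (ii) contract and relax the island range around the surviving
#' best plants; (iii) apply greedy opposition-based selection to every
#' survivor within the new range; (iv) generate replacements for the
#' eliminated plants, pulled towards the incumbent best; (v) pass the new
#' plants through the simulated-annealing filter; (vi) merge, stable-sort
#' by fitness, and cool the temperature. Terminates at `T_max` iterations,
#' when the evaluation budget would be exceeded, or when the best value is
#' within `stop_tol` of a known optimum.
#'
#' @param objective An [island_objective()] (or a benchmark id string, see
#'   [bench_objective()]; `config$D` then sets the dimension).
#' @param config An [optimizer_config()].
#' @return A list of class `"island_result"`: `best_position`,
#'   `best_fitness`, `history` (per-iteration best, non-increasing),
#'   `n_evaluations`, `n_iterations`, `terminated_by`, a per-iteration
#'   `trace` data frame (h, temperature, eliminations, worse acceptances,
#'   mean range width) and `range_widths` (iterations x D matrix).
#' @export
island_optimize <- function(objective, config = optimizer_config()) {
  if (is.character(objective)) {
    if (is.null(config$D)) stop("config$D required for a benchmark id")
    objective <- bench_objective(objective, config$D)
  }
  stopifnot(inherits(objective, "island_objective"))
  D <- length(objective$lower)
  N <- config$N
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.finite(config$E) && config$E < 2 * N) {
    stop("evaluation budget smaller than initialization plus one iteration")
  }

  lower <- objective$lower; upper <- objective$upper
  if (config$init_pm100) {
    range <- island_range(rep(-100, D), rep(100, D), h = 1)
  } else {
    range <- island_range(lower, upper, h = 1)
  }
  obj <- objective$fn
  opt <- objective$known_optimum

  X <- matrix(range$x_min, N, D, byrow = TRUE) +
    matrix(stats::runif(N * D), N, D) *
      matrix(range$x_max - range$x_min, N, D, byrow = TRUE)
  fit <- obj(X)
  evals <- N
  ord <- order(fit)
  X <- X[ord, , drop = FALSE]; fit <- fit[ord]

  temp <- config$t0
  history <- numeric(config$T_max)
  tr_h <- tr_temp <- tr_width <- numeric(config$T_max)
  tr_elim <- tr_worse <- integer(config$T_max)
  widths <- matrix(NA_real_, config$T_max, D)
  terminated_by <- "max_iter"
  iters <- 0L

  for (iter in seq_len(config$T_max)) {
    if (is.finite(config$E) && evals + N > config$E) {
      terminated_by <- "budget"
      break
    }
    tt <- eliminate_count(range$h, config$a_max, config$a_min, N)
    n_surv <- N - tt
    surv <- X[seq_len(n_surv), , drop = FALSE]
    sfit <- fit[seq_len(n_surv)]

    range <- update_range(surv, range)

    sel <- obl_select(surv, sfit, range, obj)
    surv <- sel$position; sfit <- sel$fitness
    evals <- evals + sel$n_evaluations
    o <- order(sfit)
    surv <- surv[o, , drop = FALSE]; sfit <- sfit[o]

    newX <- spawn_plants(tt, range, best = surv[1, ],
                         clip_lower = lower, clip_upper = upper)
    nfit <- obj(newX)
    evals <- evals + tt

    ann <- anneal_filter(newX, nfit, surv, sfit, temp)

    X <- rbind(surv, ann$positions)
    fit <- c(sfit, ann$fitness)
    ord <- order(fit)
    X <- X[ord, , drop = FALSE]; fit <- fit[ord]

    temp <- temp * config$cooling
    iters <- iter
    history[iter] <- fit[1]
    tr_h[iter] <- range$h; tr_temp[iter] <- temp
    tr_elim[iter] <- tt; tr_worse[iter] <- ann$n_accepted_worse
    widths[iter, ] <- range$x_max - range$x_min
    tr_width[iter] <- mean(widths[iter, ])

    if (!is.null(opt) && abs(fit[1] - opt) <= config$stop_tol) {
      terminated_by <- "optimum_reached"
      break
    }
  }

  keep <- seq_len(iters)
  structure(list(
    best_position = X[1, ], best_fitness = fit[1],
    history = history[keep], n_evaluations = evals,
    n_iterations = iters, terminated_by = terminated_by,
    trace = data.frame(iteration = keep, best = history[keep],
                       h = tr_h[keep], temperature = tr_temp[keep],
                       n_eliminated = tr_elim[keep],
                       n_accepted_worse = tr_worse[keep],
                       mean_width = tr_width[keep]),
    range_widths = widths[keep, , drop = FALSE],
    config = config, objective_name = objective$name
  ), class = "island_result")
}

#' @export
print.island_result <- function(x, ...) {
  cat(sprintf(
    "<island_result %s: best %.6g after %d iterations (%d evaluations, %s)>\n",
    x$objective_name, x$best_fitness, x$n_iterations, x$n_evaluations,
    x$terminated_by))
  invisible(x)
}

#' Serialize an optimizer result to JSON
#'
#' @param result An `"island_result"`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @param history Include the per-iteration best-fitness trace.
#' @return The JSON string, invisibly when written to a file.
#' @export
result_to_json <- function(result, path = NULL, history = TRUE) {
  cfg <- result$config
  rec <- list(
    objective = result$objective_name,
    best_position = result$best_position,
    best_fitness = result$best_fitness,
    n_evaluations = result$n_evaluations,
    n_iterations = result$n_iterations,
    terminated_by = result$terminated_by,
    seed = cfg$seed,
    config = cfg[c("N", "T_max", "a_max", "a_min", "t0", "cooling",
                   "stop_tol")]
  )
  if (history) rec$history <- result$history
  js <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
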