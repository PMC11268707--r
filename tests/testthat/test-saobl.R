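test_that("opposition mirrors through the island range", {
  rng <- island_range(0, 10)
  expect_identical(opposition(3, rng), 7)
  # midpoint is a fixed point; the mapping is an involution
  expect_equal(opposition(5, rng), 5)
  rng2 <- island_range(c(-2, 1), c(4, 9))
  x <- c(0.5, 2.25)
  expect_equal(opposition(opposition(x, rng2), rng2), x)
  # out-of-range points are clipped before mirroring
  expect_equal(opposition(-5, rng), 10)
})

test_that("opposition-based selection is greedy with ties to the mirror", {
  rng <- island_range(0, 10)
  shifted <- function(X) (X[, 1] - 7)^2          # mirror of 3 is better
  sel <- obl_select(3, shifted(matrix(3, 1, 1)), rng, shifted)
  expect_equal(sel$position, 7)
  expect_equal(sel$fitness, 0)
  expect_equal(sel$n_evaluations, 1)
  # symmetric objective: exact tie, the mirror is taken, fitness unchanged
  sym <- function(X) (X[, 1] - 5)^2
  sel2 <- obl_select(3, sym(matrix(3, 1, 1)), rng, sym)
  expect_equal(sel2$position, 7)
  expect_equal(sel2$fitness, 4)
  # worse mirror: original kept
  left <- function(X) X[, 1]^2
  sel3 <- obl_select(3, 9, rng, left)
  expect_equal(sel3$position, 3)
  # returned fitness never exceeds the input fitness (random matrix case)
  set.seed(3)
  X <- matrix(stats::runif(40, 0, 10), 20, 2)
  rngm <- island_range(c(0, 0), c(10, 10))
  f <- function(M) rowSums((M - 2)^2)
  sel4 <- obl_select(X, f(X), rngm, f)
  expect_true(all(sel4$fitness <= f(X) + 1e-15))
  expect_error(obl_select(3, 9, rng, function(X) NaN), "non-finite")
})

test_that("Metropolis acceptance probability has the standard form", {
  expect_equal(sa_accept_prob(1, 2, 10), 1)        # strictly better
  expect_equal(sa_accept_prob(2, 2, 10), 1)        # equal energy, exp(0)
  expect_equal(sa_accept_prob(3, 2, 1), exp(-1))   # gap equal to T
  expect_equal(sa_accept_prob(12, 2, 10), exp(-1))
  # monotone in the gap and in the temperature
  gaps <- seq(0, 5, by = 0.5)
  p <- sa_accept_prob(2 + gaps, 2, 1.7)
  expect_true(all(diff(p) <= 0))
  temps <- c(0.1, 1, 10, 100)
  pt <- vapply(temps, function(tm) sa_accept_prob(3, 2, tm), numeric(1))
  expect_true(all(diff(pt) >= 0))
  expect_error(sa_accept_prob(1, 2, 0), "positive")
})

test_that("annealing filter keeps, gambles on, or replaces new plants", {
  surv <- matrix(seq(0, 0.9, by = 0.1), 10, 1)
  sfit <- seq(1, 10)                       # reference index floor(9+0.5)=9
  newp <- matrix(c(5, 6), 2, 1)
  # enormous temperature: everything is retained
  hot <- anneal_filter(newp, c(100, 200), surv, sfit, temperature = 1e9,
                       u = c(0.5, 0.5))
  expect_equal(hot$positions, newp)
  expect_equal(hot$n_accepted_worse, 2)
  # vanishing temperature: worse candidates become copies of the
  # reference plant (position and fitness)
  cold <- anneal_filter(newp, c(100, 200), surv, sfit,
                        temperature = 1e-12, u = c(0.5, 0.5))
  expect_equal(cold$positions, matrix(surv[9, 1], 2, 1))
  expect_equal(cold$fitness, c(9, 9))
  expect_equal(cold$n_rejected, 2)
  # strictly better candidates survive any temperature without a draw
  best <- anneal_filter(newp, c(0.5, 0.1), surv, sfit,
                        temperature = 1e-12, u = c(0.99, 0.99))
  expect_equal(best$positions, newp)
  expect_equal(best$n_accepted_worse, 0)
})

test_that("the optimizer is elitist, deterministic, and counts evaluations", {
  cfg1 <- optimizer_config(N = 30, T_max = 40, a_max = 20, seed = 42)
  cfg2 <- optimizer_config(N = 30, T_max = 80, a_max = 20, seed = 42)
  counter <- local({
    n <- 0L
    function(X) { n <<- n + nrow(X); rowSums(X^2) }
  })
  obj <- island_objective(counter, rep(-5, 4), rep(5, 4))
  res <- island_optimize(obj, cfg1)
  expect_equal(res$n_evaluations, environment(counter)$n)
  expect_true(all(diff(res$history) <= 0))
  # the longer run can only improve on the shorter one at equal seed
  res2 <- island_optimize(obj, cfg2)
  expect_lte(res2$best_fitness, res$best_fitness)
  expect_equal(res2$history[seq_along(res$history)], res$history)
  # bit-identical reproducibility
  res3 <- island_optimize(island_objective(function(X) rowSums(X^2),
                                           rep(-5, 4), rep(5, 4)), cfg1)
  expect_identical(res3$history, res$history)
  expect_identical(res3$best_position, res$best_position)
})

test_that("the evaluation budget and the optimum stop both terminate runs", {
  cfg <- optimizer_config(N = 20, T_max = 1000, a_max = 10, seed = 1,
                          E = 200)
  res <- island_optimize(bench_objective("f3", 4), cfg)
  expect_equal(res$terminated_by, "budget")
  expect_lte(res$n_evaluations, 200)
  res2 <- island_optimize(bench_objective("f1", 3),
                          optimizer_config(N = 40, T_max = 1500, seed = 2,
                                           a_max = 30))
  expect_equal(res2$terminated_by, "optimum_reached")
  expect_lte(res2$best_fitness, 1e-12)
  expect_error(island_optimize(bench_objective("f1", 3),
                               optimizer_config(N = 40, a_max = 20,
                                                E = 50)),
               "budget")
})

test_that("worse-solution acceptances decay as the schedule cools", {
  frac_first <- frac_last <- numeric(3)
  for (seed in 1:3) {
    res <- island_optimize(bench_objective("f3", 10),
                           optimizer_config(N = 50, T_max = 300,
                                            a_max = 30, seed = seed))
    tr <- res$trace
    rate <- tr$n_accepted_worse / pmax(tr$n_eliminated, 1)
    n <- nrow(tr)
    head_idx <- seq_len(ceiling(n * 0.1))
    tail_idx <- seq(n - ceiling(n * 0.1) + 1, n)
    frac_first[seed] <- mean(rate[head_idx])
    frac_last[seed] <- mean(rate[tail_idx])
  }
  expect_lte(mean(frac_last), mean(frac_first))
})

test_that("optimizer results serialize to JSON with a config echo", {
  res <- island_optimize(bench_objective("f1", 2),
                         optimizer_config(N = 10, T_max = 5, a_max = 5,
                                          seed = 9))
  js <- jsonlite::fromJSON(result_to_json(res))
  expect_equal(js$seed, 9)
  expect_equal(js$config$N, 10)
  expect_equal(js$best_fitness, res$best_fitness)
  expect_equal(length(js$history), res$n_iterations)
})
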