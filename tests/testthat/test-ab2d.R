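test_that("wedge geometry matches the hand-computed l1 intercept", {
  # at s=100, t=50, alpha=5 deg: l1 meets j=0 at i = s + t*tan(5 deg)
  # ~ 104.37, so the background wedge in D spans columns 101..104
  w <- wedges(100, 50, 5, 256)
  expect_equal(sort(unique(w$bg_wedge_D[, "i"])), 101:104)
  # every wedge cell lies in the off-diagonal quadrants B or D
  all_cells <- do.call(rbind, w)
  inB <- all_cells[, "i"] <= 100 & all_cells[, "j"] > 50
  inD <- all_cells[, "i"] > 100 & all_cells[, "j"] <= 50
  expect_true(all(inB | inD))
  expect_error(wedges(100, 50, 7, 256), "alpha")
})

test_that("alpha = 0 gives four empty wedges and an undefined ratio", {
  w0 <- wedges(40, 60, 0, 128)
  expect_true(all(vapply(w0, nrow, integer(1)) == 0L))
  h <- rand_hist(16, seed = 2)
  expect_error(p_alpha(h, 5, 5, 0), "empty")
})

test_that("wedges agree with full-plane masks and are pairwise disjoint", {
  set.seed(41)
  for (rep in 1:40) {
    L <- sample(c(16, 32, 64), 1)
    s <- sample(0:(L - 2), 1); t <- sample(0:(L - 2), 1)
    a <- sample(seq(0.25, 5, by = 0.25), 1)
    w <- wedges(s, t, a, L)
    m <- naive_wedge_masks(s, t, a, L)
    seen <- matrix(FALSE, L, L)
    for (nm in names(w)) {
      mask <- matrix(FALSE, L, L)
      if (nrow(w[[nm]]) > 0) mask[w[[nm]] + 1L] <- TRUE
      expect_equal(mask, m[[nm]],
                   info = sprintf("%s L=%d s=%d t=%d a=%.2f",
                                  nm, L, s, t, a))
      expect_false(any(mask & seen))   # pairwise disjoint
      seen <- seen | mask
    }
    # disjoint from the background and target quadrants
    iM <- matrix(0:(L - 1), L, L); jM <- matrix(0:(L - 1), L, L,
                                                byrow = TRUE)
    expect_false(any(seen & iM <= s & jM <= t))
    expect_false(any(seen & iM > s & jM > t))
  }
})

test_that("occupancy ratio counts occupied wedge cells exactly", {
  # fixture with |wedge| divisible by 4 at the chosen geometry
  h <- make_wedge_fixture(32, 15, 15, 5, occupancy = 1)
  expect_equal(p_alpha(h, 15, 15, 5), 1)
  h0 <- make_wedge_fixture(32, 15, 15, 5, occupancy = 0)
  expect_equal(p_alpha(h0, 15, 15, 5), 0)
  n_wedge <- nrow(do.call(rbind, wedges(15, 15, 5, 32)))
  h75 <- make_wedge_fixture(32, 15, 15, 5, occupancy = 0.75)
  expect_equal(p_alpha(h75, 15, 15, 5),
               ceiling(0.75 * n_wedge) / n_wedge)
})

test_that("the adaptive angle rule returns the smallest qualifying angle", {
  # fully occupied histogram: the scan stops at the smallest grid angle
  # with a non-empty wedge union (very small angles produce no integer
  # cells at this resolution)
  dense <- histogram2d(matrix(1, 64, 64))
  grid <- seq(0.25, 5, by = 0.25)
  nonempty <- vapply(grid, function(a)
    nrow(do.call(rbind, wedges(31, 31, a, 64))) > 0, logical(1))
  expect_equal(select_alpha(dense, 31, 31), min(grid[nonempty]))
  # nothing near the boundary cross: no qualifying angle
  sparse <- matrix(0, 32, 32); sparse[2, 2] <- 10; sparse[30, 30] <- 10
  expect_null(select_alpha(histogram2d(sparse), 15, 15))
  # fixture fully occupied at the 2-degree wedge: smaller-angle wedges
  # nest inside it, so the scan stops at or before 2 degrees
  h2 <- make_wedge_fixture(64, 31, 31, 2, occupancy = 1)
  a <- select_alpha(h2, 31, 31)
  expect_false(is.null(a))
  expect_lte(a, 2)
  expect_gte(p_alpha(h2, 31, 31, a), 0.75)
  # largest-angle variant scans from the other end
  al <- select_alpha(dense, 31, 31, largest = TRUE)
  expect_equal(al, 5)
})

test_that("bifurcated variance reduces to the classical statistic", {
  h <- rand_hist(16, seed = 3)
  expect_identical(sigma_ab(h, 5, 6, NULL), otsu_sigma(h, 5, 6))
  # wedges carrying zero mass change nothing
  counts <- matrix(0, 32, 32); counts[5, 5] <- 7; counts[28, 28] <- 9
  hz <- histogram2d(counts)
  expect_equal(sigma_ab(hz, 15, 15, 5), otsu_sigma(hz, 15, 15),
               tolerance = 1e-12)
})

test_that("bifurcated variance matches the mask-based oracle", {
  set.seed(51)
  for (rep in 1:60) {
    h <- rand_hist(16, seed = 200 + rep)
    s <- sample(0:14, 1); t <- sample(0:14, 1)
    a <- sample(seq(0.25, 5, 0.25), 1)
    expect_equal(sigma_ab(h, s, t, a), naive_sigma_ab(h, s, t, a),
                 tolerance = 1e-9)
  }
  # planted wedge mass, including the halved-mass continuity check
  hw <- make_wedge_fixture(64, 31, 31, 3, occupancy = 1, wedge_count = 8)
  expect_equal(sigma_ab(hw, 31, 31, 3), naive_sigma_ab(hw, 31, 31, 3),
               tolerance = 1e-9)
  hw2 <- histogram2d({cc <- hw$counts; cc[cc == 8] <- 4; cc})
  expect_equal(sigma_ab(hw2, 31, 31, 3), naive_sigma_ab(hw2, 31, 31, 3),
               tolerance = 1e-9)
})

test_that("wedge augmentation conserves and never loses class mass", {
  set.seed(61)
  for (rep in 1:25) {
    h <- rand_hist(16, seed = 300 + rep)
    s <- sample(0:14, 1); t <- sample(0:14, 1)
    cs <- class_stats(h, s, t)
    for (a in c(0.5, 2, 5)) {
      m <- ab_class_masses(h, s, t, a)
      expect_gte(m$w1, cs$w1 - 1e-15)
      expect_gte(m$w2, cs$w2 - 1e-15)
      expect_equal(m$w1 + m$w2 + m$outside, 1, tolerance = 1e-12)
      expect_gte(m$outside, -1e-12)
    }
  }
})
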