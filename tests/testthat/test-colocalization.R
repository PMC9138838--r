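test_that("shadow matrix implements the at-least-one-bead occupancy rule", {
  fr <- toy_frame(c(0.1, 0.1, 0.5))
  g <- grid_spec2d(1, 1, 0.5)
  m <- shadow_matrix(fr, species_selector(residues = "C60"), g)
  expect_equal(unclass(m), matrix(c(1L, 0L, 0L, 0L), 2, 2),
               ignore_attr = TRUE)

  # two beads in the same cell: binarization makes it identical
  fr2 <- toy_frame(c(0.1, 0.1, 0.5, 0.2, 0.2, 0.5))
  m2 <- shadow_matrix(fr2, species_selector(residues = "C60"), g)
  expect_identical(unclass(m2), unclass(m))

  # bead beyond the box wraps into the first cell
  fr3 <- toy_frame(c(1.1, 0.1, 0.5))
  m3 <- shadow_matrix(fr3, species_selector(residues = "C60"), g)
  expect_identical(unclass(m3), unclass(m))
})

test_that("shadow matrix errors name an unmatched selector", {
  fr <- toy_frame(c(0.1, 0.1, 0.5))
  expect_error(shadow_matrix(fr, species_selector(residues = "DAPE",
                                                  label = "DAPE")),
               "DAPE")
})

test_that("mse equals the mismatch fraction with hand-counted cases", {
  a <- matrix(c(1, 0, 0, 1), 2, 2)
  b <- matrix(c(1, 0, 1, 0), 2, 2)
  expect_identical(mse(a, a), 0)
  expect_equal(mse(a, b), 0.5)
  expect_equal(mse(matrix(1, 3, 3), matrix(0, 3, 3)), 1.0)
  expect_error(mse(matrix(0, 2, 2), matrix(0, 3, 3)), "dimension")
})

test_that("mse matches a cell-by-cell oracle and is symmetric and bounded", {
  set.seed(11)
  for (rep in 1:50) {
    nx <- sample(1:10, 1); ny <- sample(1:10, 1)
    a <- matrix(rbinom(nx * ny, 1, runif(1)), nx, ny)
    b <- matrix(rbinom(nx * ny, 1, runif(1)), nx, ny)
    mm <- 0L
    for (i in seq_len(nx)) for (j in seq_len(ny))
      if (a[i, j] != b[i, j]) mm <- mm + 1L
    expect_identical(mse(a, b), mm / (nx * ny))
    expect_identical(mse(a, b), mse(b, a))
    expect_gte(mse(a, b), 0); expect_lte(mse(a, b), 1)
    expect_identical(mse(a, a), 0)
  }
})

test_that("adding occupied cells outside the reference support raises mse", {
  set.seed(3)
  ref <- matrix(rbinom(64, 1, 0.2), 8, 8)
  tgt <- ref  # covers the reference exactly
  free <- which(ref == 0)
  grow <- sample(free, 10)
  base <- mse(ref, tgt)
  for (k in seq_along(grow)) {
    tgt[grow[k]] <- 1
    expect_gt(mse(ref, tgt), base)
    base <- mse(ref, tgt)
  }
})

test_that("expected mse of independent random matrices is p(1-q)+q(1-p)", {
  set.seed(21)
  p <- 0.3; q <- 0.6; n <- 2000; cells <- 100
  vals <- replicate(n, mse(matrix(rbinom(cells, 1, p), 10, 10),
                           matrix(rbinom(cells, 1, q), 10, 10)))
  expected <- p * (1 - q) + q * (1 - p)
  se <- sd(vals) / sqrt(n)
  expect_lt(abs(mean(vals) - expected), 3 * se)
})

test_that("a species compared against itself has zero mean MSE", {
  sp <- membrane_spec(balanced_comp(), box = c(16, 16, 10), np_count = 40,
                      seed = 7)
  gen <- build_membrane(sp, n_frames = 3)
  npsel <- np_selector(balanced_comp())
  tab <- colocalization_table(gen$trajectory, npsel, list(NP = npsel))
  expect_identical(tab$mean_mse, 0)
  expect_identical(tab$se, 0)
})

test_that("planted co-localization ranks the target tail first", {
  wins <- 0L
  for (s in 1:5) {
    sp <- membrane_spec(balanced_comp(), box = c(16, 16, 10), np_count = 80,
                        np_colocal_target = "DA", np_colocal_strength = 0.9,
                        seed = s)
    gen <- build_membrane(sp)
    tab <- colocalization_table(gen$trajectory, np_selector(balanced_comp()),
                                balanced_tail_targets())
    wins <- wins + (tab$species[1] == "DA")
  }
  expect_gte(wins, 4L)
})

test_that("mean MSE to the target is non-increasing in planted strength", {
  comp <- balanced_comp()
  targets <- balanced_tail_targets(comp, tails = "DA", sterol = FALSE)
  mean_at <- function(strength) {
    mean(vapply(1:20, function(s) {
      sp <- membrane_spec(comp, box = c(16, 16, 10), np_count = 80,
                          np_colocal_target = "DA",
                          np_colocal_strength = strength, seed = s)
      gen <- build_membrane(sp)
      colocalization_table(gen$trajectory, np_selector(comp),
                           targets)$mean_mse[1]
    }, numeric(1)))
  }
  m <- vapply(c(0, 0.5, 1), mean_at, numeric(1))
  expect_true(all(diff(m) <= 0))
})

test_that("frame-range handling and time-average mode work", {
  sp <- membrane_spec(balanced_comp(), box = c(16, 16, 10), np_count = 40,
                      seed = 3)
  gen <- build_membrane(sp, n_frames = 3)
  comp <- balanced_comp()
  expect_error(colocalization_table(gen$trajectory, np_selector(comp),
                                    balanced_tail_targets(),
                                    frame_range = integer(0)), "empty")
  ta <- colocalization_table(gen$trajectory, np_selector(comp),
                             balanced_tail_targets(),
                             mode = "time_average")
  expect_true(all(ta$mean_mse >= 0 & ta$mean_mse <= 1))
  ex <- colocal_extremes(ta, k = 2)
  expect_equal(nrow(ex$smallest), 2L)
  expect_equal(ex$largest$mean_mse[1], max(ta$mean_mse))
})
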