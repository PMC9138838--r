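kt298 <- 0.00831446261815324 * 298

test_that("a single quasi-unbiased window reduces to Boltzmann inversion", {
  set.seed(1)
  s <- rnorm(5000, 1, 0.2)
  w <- list(umbrella_window(1, 1e-9, s))
  p <- wham_solve(w, bin_width = 0.05)
  h <- hist(s, breaks = attr(p, "bin_edges"), plot = FALSE)
  G0 <- -kt298 * log(h$counts)
  G0[!is.finite(G0)] <- NA
  sel <- !is.na(p$G) & !is.na(G0)
  d <- (p$G - G0)[sel]
  expect_lt(diff(range(d)), 1e-6)  # equal up to the reference constant
})

test_that("WHAM recovers a harmonic potential from sampled windows", {
  a <- 50
  U <- function(z) 0.5 * a * z^2
  centers <- seq(-1.5, 1.5, by = 0.1)
  w <- sample_umbrella_windows(U, centers, force_const = 1000,
                               n_samples = 3000, seed = 3)
  p <- wham_solve(w, bin_width = 0.05)
  expect_lt(attr(p, "residual"), 1e-7)
  sel <- !is.na(p$G) & abs(p$z) <= 1.2
  d <- p$G[sel] - U(p$z[sel])
  d <- d - mean(d)
  expect_lt(max(abs(d)), 1.5)
  mn <- pmf_minimum(p, refine = TRUE)
  expect_false(mn$boundary)
  expect_lt(abs(mn$position), 0.1)
})

test_that("free-energy error decreases with the number of samples", {
  a <- 50
  U <- function(z) 0.5 * a * z^2
  centers <- seq(-1, 1, by = 0.1)
  err <- vapply(c(1000, 10000), function(ns) {
    w <- sample_umbrella_windows(U, centers, force_const = 1000,
                                 n_samples = ns, seed = 17)
    p <- wham_solve(w, bin_width = 0.05)
    sel <- !is.na(p$G) & abs(p$z) <= 0.8
    d <- p$G[sel] - U(p$z[sel])
    max(abs(d - mean(d)))
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("an additive constant in the potential leaves the PMF unchanged", {
  U1 <- function(z) 0.5 * 50 * z^2
  U2 <- function(z) 0.5 * 50 * z^2 + 123.4
  centers <- seq(-0.5, 0.5, by = 0.1)
  w1 <- sample_umbrella_windows(U1, centers, 1000, 500, seed = 4)
  w2 <- sample_umbrella_windows(U2, centers, 1000, 500, seed = 4)
  p1 <- wham_solve(w1, bin_width = 0.05)
  p2 <- wham_solve(w2, bin_width = 0.05)
  expect_equal(p1$G, p2$G)
})

test_that("a double-well barrier height is recovered", {
  # U = 20 ((z^2 - 1))^2: minima at +/-1 (U=0), barrier 20 kJ/mol at z=0
  U <- function(z) 20 * (z^2 - 1)^2
  centers <- seq(-1.6, 1.6, by = 0.1)
  w <- sample_umbrella_windows(U, centers, force_const = 1000,
                               n_samples = 4000, seed = 6)
  p <- wham_solve(w, bin_width = 0.05)
  sel <- !is.na(p$G)
  zmin_l <- p$z[sel][which.min(p$G[sel] + 1e9 * (p$z[sel] > 0))]
  barrier <- min(p$G[sel & abs(p$z) < 0.2]) - min(p$G[sel])
  expect_equal(zmin_l, -1, tolerance = 0.1)
  expect_equal(barrier, 20, tolerance = 0.05 * 20)
})

test_that("non-overlapping windows trigger a coverage warning", {
  set.seed(9)
  w <- list(umbrella_window(0, 1000, rnorm(500, 0, 0.05)),
            umbrella_window(3, 1000, rnorm(500, 3, 0.05)))
  expect_warning(wham_solve(w, bin_width = 0.05), "no occupied bins")
})

test_that("bootstrap errors are deterministic, and zero for constant data", {
  w <- list(umbrella_window(0.0, 1000, rep(0.5, 200)),
            umbrella_window(0.5, 1000, rep(0.5, 200)))
  p <- suppressWarnings(bootstrap_pmf(w, n_boot = 25, seed = 2))
  expect_identical(unique(p$se[!is.na(p$se)]), 0)

  U <- function(z) 0.5 * 50 * z^2
  centers <- seq(-0.5, 0.5, by = 0.1)
  ws <- sample_umbrella_windows(U, centers, 1000, 500, seed = 5)
  b1 <- bootstrap_pmf(ws, n_boot = 25, seed = 7)
  b2 <- bootstrap_pmf(ws, n_boot = 25, seed = 7)
  expect_identical(b1$se, b2$se)
  expect_true(all(b1$se[!is.na(b1$se)] >= 0))
  b3 <- bootstrap_pmf(ws, n_boot = 25, seed = 8)
  expect_false(identical(b1$se, b3$se))
})

test_that("block bootstrap runs and keeps sample counts", {
  U <- function(z) 0.5 * 50 * z^2
  ws <- sample_umbrella_windows(U, c(-0.2, 0, 0.2), 1000, 400, seed = 5)
  pb <- bootstrap_pmf(ws, n_boot = 20, seed = 3, block_length = 20)
  expect_true(any(pb$se[!is.na(pb$se)] > 0))
})

test_that("pmf_minimum reports depth, position and boundary status", {
  z <- seq(-2, 2, by = 0.05)
  G <- 30 * ((z / 1.2)^2 - 1)^2 - 30   # minimum -30 at |z| = 1.2
  G <- G - G[length(G)]
  prof <- structure(data.frame(z = z, G = G - max(G[abs(z) > 1.9]) * 0,
                               se = NA_real_),
                    class = c("pmf_profile", "data.frame"))
  mn <- pmf_minimum(prof)
  expect_equal(mn$depth, min(G), tolerance = 1e-12)
  expect_equal(abs(mn$position), 1.2, tolerance = 0.051)
  expect_false(mn$boundary)

  mono <- structure(data.frame(z = z, G = 2 * z, se = NA_real_),
                    class = c("pmf_profile", "data.frame"))
  mn2 <- pmf_minimum(mono)
  expect_true(mn2$boundary)
  expect_equal(mn2$position, min(z))
})

test_that("window files round-trip through the manifest format", {
  dir <- withr::local_tempdir()
  w <- list(umbrella_window(0.5, 1000, c(0.4, 0.5, 0.6)),
            umbrella_window(1.0, 500, c(0.9, 1.0, 1.1)))
  mf <- write_umbrella_windows(w, dir)
  back <- read_umbrella_windows(mf)
  expect_length(back, 2L)
  expect_equal(back[[1]]$center, 0.5)
  expect_equal(back[[2]]$force_const, 500)
  expect_equal(back[[1]]$samples, w[[1]]$samples)
})

test_that("umbrella window objects enforce their invariants", {
  expect_error(umbrella_window(0, -1, c(1, 2)), "force_const")
  expect_error(umbrella_window(0, 100, numeric(0)), "samples")
  expect_error(umbrella_window(0, 100, c(1, NA)), "finite")
})
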