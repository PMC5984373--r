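test_that("nb_logpmf matches its closed forms and limits", {
  mu <- 3.7; phi <- 0.6; theta <- 1 / phi
  expect_equal(nb_logpmf(0, mu, phi), theta * log(theta / (theta + mu)))
  expect_equal(nb_logpmf(0:20, 4.2, 0), dpois(0:20, 4.2, log = TRUE))
  # continuity at the Poisson boundary
  expect_equal(nb_logpmf(0:50, 5, 1e-10), dpois(0:50, 5, log = TRUE),
               tolerance = 1e-8)
  # brute-force truncated normalization
  expect_equal(sum(exp(nb_logpmf(0:2000, 5, 0.5))), 1, tolerance = 1e-10)
  expect_error(nb_logpmf(-1, 5, 0.5), "non-negative")
})

test_that("zinb_logpmf is the stated mixture", {
  expect_equal(zinb_logpmf(0:30, 5, 0.5, 0), nb_logpmf(0:30, 5, 0.5))
  expect_lt(abs(zinb_logpmf(0, 5, 0.5, 1 - 1e-9)), 1e-8)
  expect_equal(sum(exp(zinb_logpmf(0:2000, 5, 0.5, 0.3))), 1,
               tolerance = 1e-10)
  # direct mixture identity at a few points
  y <- c(0, 1, 5)
  expect_equal(zinb_logpmf(y, 4, 0.8, 0.25),
               log(0.25 * (y == 0) + 0.75 * exp(nb_logpmf(y, 4, 0.8))))
})

test_that("fit_poisson returns the sample-mean MLE", {
  f <- fit_poisson(c(1, 2, 3))
  expect_equal(f$mean, 2)
  expect_equal(f$loglik, sum(dpois(c(1, 2, 3), 2, log = TRUE)))
  z <- fit_poisson(rep(0L, 10))
  expect_equal(z$loglik, 0)
  expect_true(z$degenerate)
})

test_that("fit_nb recovers simulated parameters and nests Poisson", {
  set.seed(401)
  y <- rnbinom(5000, mu = 5, size = 2)     # phi = 0.5
  f <- fit_nb(y)
  expect_true(f$converged)
  expect_lt(abs(f$mean - 5) / 5, 0.1)
  expect_lt(abs(f$dispersion - 0.5) / 0.5, 0.1)

  yp <- rpois(5000, 5)
  fp <- fit_nb(yp)
  expect_lt(fp$dispersion, 0.05)
  expect_lt(abs(fp$loglik - fit_poisson(yp)$loglik), 1)
})

test_that("likelihood ordering holds across random genes", {
  delta <- 0.5
  for (seed in 1:12) {
    set.seed(500 + seed)
    mu <- runif(1, 0.2, 20); phi <- runif(1, 0, 2)
    y <- rnbinom(200, mu = mu, size = 1 / max(phi, 1e-8))
    lp <- fit_poisson(y)$loglik
    ln <- fit_nb(y)$loglik
    lz <- fit_zinb(y)$loglik
    expect_lte(lp, ln + delta)
    expect_lte(ln, lz + delta)
  }
})

test_that("fit_nb matches a brute-force grid search on small vectors", {
  for (seed in 1:10) {
    set.seed(600 + seed)
    y <- rnbinom(sample(20:50, 1), mu = runif(1, 1, 8), size = 1 / runif(1, 0.2, 1.5))
    if (all(y == 0)) next
    f <- fit_nb(y)
    mu_grid <- seq(max(mean(y) * 0.5, 1e-3), mean(y) * 2, length.out = 201)
    th_grid <- 10^seq(-2, 6, length.out = 241)
    grid_ll <- max(vapply(th_grid, function(th) {
      max(vapply(mu_grid,
                 function(m) sum(dnbinom(y, size = th, mu = m, log = TRUE)),
                 numeric(1)))
    }, numeric(1)))
    expect_gte(f$loglik, grid_ll - 1e-6)
    expect_lt(f$loglik - grid_ll, 0.01 + 1e-6)
  }
})

test_that("fit_zinb recovers zero inflation and collapses to NB without it", {
  set.seed(402)
  y <- ifelse(runif(5000) < 0.3, 0L, rnbinom(5000, mu = 5, size = 2))
  f <- fit_zinb(y)
  expect_true(f$converged)
  expect_lt(abs(f$mean - 5) / 5, 0.1)
  expect_lt(abs(f$dispersion - 0.5) / 0.5, 0.1)
  expect_lt(abs(f$zero_mass - 0.3) / 0.3, 0.1)

  set.seed(403)
  ynb <- rnbinom(5000, mu = 5, size = 2)
  fnb <- fit_nb(ynb)
  fz <- fit_zinb(ynb)
  expect_lt(fz$zero_mass, 0.02)
  expect_gte(fz$loglik, fnb$loglik)          # by construction
  expect_lt(fz$loglik - fnb$loglik, 2)
})

test_that("downsample_cells equalizes totals by hypergeometric draws", {
  sim <- nb_gene_matrix(50, 40, c(0.5, 10), c(0.1, 1), seed = 404)
  m <- sim$matrix
  down <- downsample_cells(m, 0.10, seed = 7)
  target <- floor(quantile(colSums(unclass(m)), 0.10, names = FALSE))
  expect_true(all(colSums(unclass(down)) == target))
  # retained cells, never-increasing entries
  expect_true(all(colnames(down) %in% colnames(m)))
  expect_true(all(unclass(down) <= unclass(m)[, colnames(down)]))
  # determinism
  down2 <- downsample_cells(m, 0.10, seed = 7)
  expect_identical(unclass(down), unclass(down2))
  # a cell already at the target depth is retained unchanged
  at_target <- which(colSums(unclass(m)) == target)
  if (length(at_target) > 0)
    expect_identical(unclass(down)[, colnames(m)[at_target[1]]],
                     unclass(m)[, at_target[1]])
})

test_that("downsampled counts match the hypergeometric expectation", {
  counts <- c(g1 = 40L, g2 = 10L, g3 = 0L, g4 = 50L)
  m <- count_matrix(cbind(big = counts, pad1 = c(5L, 5L, 5L, 5L),
                          pad2 = c(5L, 5L, 5L, 5L)))
  # target = 10% quantile of totals (20, 20, 100) -> 20; "big" drawn to 20
  reps <- vapply(1:1000, function(s)
    unclass(downsample_cells(m, 0.10, seed = s))[, "big"],
    numeric(4))
  expected <- counts * 20 / 100
  se <- sqrt(counts * 0.2 * 0.8 * (100 - 20) / (100 - 1) / 1000)
  dev <- abs(rowMeans(reps) - expected)
  expect_true(all(dev[counts > 0] <= 3 * se[counts > 0] + 1e-9))
  expect_true(all(reps[3, ] == 0))
})
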