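test_that("the full fit recovers the group effect and both dispersions", {
  d <- two_group_gene(500, prop0 = 2e-3, log_fc = log(2), phi0 = 0.5,
                      phi1 = 0.5, seed = 901)
  f <- fit_nbid_full(d$y, d$group, offsets = d$offsets)
  expect_true(f$converged)
  # 3 SE of the effect from a crude variance bound
  se <- sqrt(sum(2 * (1 / (exp(d$offsets) * 2e-3) + 0.5)) / 1000^2 * 4)
  expect_lt(abs(f$beta1 - log(2)), 3 * max(se, 0.1))

  d2 <- two_group_gene(1000, prop0 = 5e-3, log_fc = 0, phi0 = 0.2,
                       phi1 = 1.0, seed = 902)
  f2 <- fit_nbid_full(d2$y, d2$group, offsets = d2$offsets)
  expect_lt(abs(f2$phi0 - 0.2) / 0.2, 0.25)
  expect_lt(abs(f2$phi1 - 1.0) / 1.0, 0.25)
})

test_that("relabeling the groups flips the effect and swaps dispersions", {
  d <- two_group_gene(200, prop0 = 3e-3, log_fc = log(3), phi0 = 0.3,
                      phi1 = 0.8, seed = 903)
  f <- fit_nbid_full(d$y, d$group, offsets = d$offsets)
  g <- fit_nbid_full(d$y, 1 - d$group, offsets = d$offsets)
  expect_equal(g$beta1, -f$beta1, tolerance = 1e-6)
  expect_equal(g$phi0, f$phi1, tolerance = 1e-6)
  expect_equal(g$phi1, f$phi0, tolerance = 1e-6)
  expect_equal(g$loglik, f$loglik, tolerance = 1e-8)
})

test_that("the null fit matches a one-dimensional likelihood grid", {
  for (seed in 1:5) {
    d <- two_group_gene(100, prop0 = 4e-3, log_fc = 0, phi0 = 0.4,
                        phi1 = 0.4, seed = 910 + seed)
    full <- fit_nbid_full(d$y, d$group, offsets = d$offsets)
    null <- fit_nbid_null(d$y, d$group, offsets = d$offsets,
                          phi_from_full = c(full$phi0, full$phi1))
    th <- ifelse(d$group == 0, 1 / full$phi0, 1 / full$phi1)
    llfun <- function(b0) sum(dnbinom(d$y, size = th,
                                      mu = exp(d$offsets + b0), log = TRUE))
    grid <- seq(null$beta0 - 0.5, null$beta0 + 0.5, length.out = 4001)
    grid_best <- max(vapply(grid, llfun, numeric(1)))
    expect_gte(null$loglik, grid_best - 1e-4)
    expect_lt(abs(null$loglik - grid_best), 1e-4)
    expect_lte(null$loglik, full$loglik + 1e-8)
  }
})

test_that("offsets act as exact multiplicative size factors", {
  d <- two_group_gene(150, prop0 = 3e-3, log_fc = log(2), phi0 = 0.5,
                      phi1 = 0.5, seed = 920)
  f1 <- fit_nbid_full(d$y, d$group, offsets = d$offsets)
  f2 <- fit_nbid_full(d$y, d$group, offsets = d$offsets + 3)
  expect_equal(f2$beta0, f1$beta0 - 3, tolerance = 1e-6)
  expect_equal(f2$loglik, f1$loglik, tolerance = 1e-6)
})

test_that("equal-dispersion constraint reproduces the standard NB GLM", {
  for (seed in 1:8) {
    d <- two_group_gene(150, prop0 = 5e-3, log_fc = log(1.5), phi0 = 0.5,
                        phi1 = 0.5, seed = 930 + seed)
    f <- fit_nbid_full(d$y, d$group, offsets = d$offsets,
                       common_dispersion = TRUE)
    ref <- suppressWarnings(
      MASS::glm.nb(d$y ~ d$group + offset(d$offsets)))
    expect_equal(f$beta1, unname(coef(ref)[2]), tolerance = 1e-3)
    expect_equal(f$loglik, as.numeric(logLik(ref)), tolerance = 1e-4)
    expect_equal(1 / f$phi0, ref$theta, tolerance = 0.01)
  }
})

test_that("the gene test is exchangeable within groups and powered at FC 4", {
  d <- two_group_gene(300, prop0 = 2e-3, log_fc = 0, phi0 = 0.5, phi1 = 0.5,
                      seed = 940)
  r1 <- nbid_gene_test(d$y, d$group, offsets = d$offsets)
  set.seed(1)
  perm <- c(sample(which(d$group == 0)), sample(which(d$group == 1)))
  r2 <- nbid_gene_test(d$y[perm], d$group[perm], offsets = d$offsets[perm])
  expect_equal(r1$p, r2$p, tolerance = 1e-8)

  dp <- two_group_gene(500, prop0 = 2e-3, log_fc = log(4), phi0 = 0.5,
                       phi1 = 0.5, seed = 941)
  rp <- nbid_gene_test(dp$y, dp$group, offsets = dp$offsets)
  expect_lt(rp$p, 1e-10)
  expect_equal(rp$log2_fold_change, 2, tolerance = 0.35)
})

test_that("type-I error is controlled with strongly unequal dispersions", {
  set.seed(950)
  n <- 500
  gi <- rep(0:1, each = n)
  depths <- rep(2000, 2 * n)
  phi <- ifelse(gi == 0, 0.2, 2.0)
  off <- log(depths)
  p <- vapply(1:800, function(g) {
    y <- rnbinom(2 * n, mu = depths * 3e-3, size = 1 / phi)
    nbid_gene_test(y, gi, offsets = off)$p
  }, numeric(1))
  frac <- mean(p < 0.05, na.rm = TRUE)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("run_nbid is invariant to rescaling size factors and flags zeros", {
  sim <- generate_nb_matrix(80, 120, seed = 960)
  grp <- rep(c("a", "b"), each = 60)
  sf <- colSums(unclass(sim$matrix))
  de1 <- run_nbid(sim$matrix, grp, size_factors = sf)
  de2 <- run_nbid(sim$matrix, grp, size_factors = sf * 10)
  expect_equal(de1$p, de2$p, tolerance = 1e-8)
  # default offsets are the totals themselves
  de3 <- run_nbid(sim$matrix, grp)
  expect_equal(de1$p, de3$p, tolerance = 1e-10)
  # an all-zero gene inside a tested matrix is filtered, a zero-total cell
  # dropped with a warning
  m <- unclass(sim$matrix)
  m[, 1] <- 0L
  expect_warning(run_nbid(count_matrix(m), grp), "zero total")
})
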