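#' @useDynLib nbid, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# bounds for theta = 1/phi on the optimization scale
.THETA_MIN <- 1e-8
.THETA_MAX <- 1e8

model_fit <- function(family, mean, dispersion, zero_mass = 0, loglik,
                      converged, degenerate = FALSE) {
  n_params <- switch(family, poisson = 1L, nb = 2L, zinb = 3L,
                     stop("unknown family"))
  structure(list(family = family, mean = mean, dispersion = dispersion,
                 zero_mass = zero_mass, loglik = loglik,
                 converged = converged, degenerate = degenerate,
                 n_params = n_params),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("%s fit: mean = %.4g, dispersion = %.4g%s, loglik = %.4f%s\n",
              toupper(x$family), x$mean, x$dispersion,
              if (x$family == "zinb") sprintf(", zero mass = %.4g", x$zero_mass)
              else "",
              x$loglik,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

check_counts <- function(y) {
  if (length(y) == 0L) stop("empty count vector")
  if (anyNA(y)) stop("counts contain missing values")
  if (any(y < 0)) stop("counts must be non-negative")
  if (any(abs(y - round(y)) > 1e-8)) stop("counts must be integral")
  as.numeric(round(y))
}

#' Negative binomial log-pmf in mean/dispersion parameterization
#'
#' Log of f(y | mu, phi) for the NB distribution with mean `mu` and variance
#' `mu + phi * mu^2`; `theta = 1/phi` is the size parameter. At `phi = 0` the
#' Poisson log-pmf (the analytic limit) is returned.
#'
#' @param y non-negative integer counts (vectorized).
#' @param mu positive mean.
#' @param phi non-negative dispersion.
#' @return log probability mass, same length as `y`.
#' @export
nb_logpmf <- function(y, mu, phi) {
  y <- check_counts(y)
  stopifnot(all(mu > 0), all(phi >= 0))
  n <- max(length(y), length(mu), length(phi))
  y <- rep_len(y, n); mu <- rep_len(mu, n); phi <- rep_len(phi, n)
  out <- numeric(n)
  pois <- phi == 0
  if (any(pois)) out[pois] <- stats::dpois(y[pois], mu[pois], log = TRUE)
  if (any(!pois))
    out[!pois] <- stats::dnbinom(y[!pois], size = 1 / phi[!pois],
                                 mu = mu[!pois], log = TRUE)
  out
}

#' Zero-inflated negative binomial log-pmf
#'
#' Log of `pi0 * 1{y = 0} + (1 - pi0) * f_NB(y | mu, phi)`.
#'
#' @inheritParams nb_logpmf
#' @param pi0 zero-inflation probability in `[0, 1)`.
#' @return log probability mass, same length as `y`.
#' @export
zinb_logpmf <- function(y, mu, phi, pi0) {
  stopifnot(all(pi0 >= 0), all(pi0 < 1))
  nb <- nb_logpmf(y, mu, phi)
  n <- length(nb)
  y <- rep_len(check_counts(y), n); pi0 <- rep_len(pi0, n)
  out <- log1p(-pi0) + nb
  z <- y == 0
  if (any(z)) out[z] <- log(pi0[z] + exp(log1p(-pi0[z]) + nb[z]))
  out
}

# collapse a count vector to unique values and multiplicities (fast repeated
# likelihood evaluation for intercept-only models)
collapse_counts <- function(y) {
  tab <- table(y)
  list(values = as.numeric(names(tab)), weights = as.numeric(tab))
}

nb_nll_collapsed <- function(par, vals, wts) {
  mu <- exp(par[1L]); theta <- exp(par[2L])
  -sum(wts * stats::dnbinom(vals, size = theta, mu = mu, log = TRUE))
}

nb_nll_grad_collapsed <- function(par, vals, wts) {
  mu <- exp(par[1L]); theta <- exp(par[2L])
  dmu <- sum(wts * (vals - mu * (vals + theta) / (theta + mu)))
  dth <- theta * sum(wts * (digamma(theta + vals) - digamma(theta) +
                              log(theta) + 1 - log(theta + mu) -
                              (theta + vals) / (theta + mu)))
  -c(dmu, dth)
}

#' Fit an intercept-only Poisson model to one gene
#'
#' The maximum-likelihood mean is the sample mean.
#'
#' @param y non-negative integer count vector (one value per cell).
#' @return a `model_fit` (`family = "poisson"`).
#' @export
fit_poisson <- function(y) {
  y <- check_counts(y)
  m <- mean(y)
  if (m == 0)
    return(model_fit("poisson", 0, 0, loglik = 0, converged = TRUE,
                     degenerate = TRUE))
  model_fit("poisson", m, 0,
            loglik = sum(stats::dpois(y, m, log = TRUE)), converged = TRUE)
}

#' Fit an intercept-only negative binomial model to one gene
#'
#' Two fitting strategies are run and the higher-likelihood result kept:
#' (a) joint optimization of (mu, theta) on the log scale started from each
#' theta in the grid 10^-8, 10^-7, ..., 10^4; (b) alternating profile
#' optimization (mean given dispersion, then dispersion given mean) until the
#' likelihood change falls below `tol` or `max_iter` iterations. theta is
#' box-bounded in [1e-8, 1e8]; a theta estimate at the upper bound is reported
#' as dispersion 0 (Poisson-like).
#'
#' @param y non-negative integer count vector, length >= 2.
#' @param tol convergence tolerance on the log-likelihood for the alternating
#'   strategy.
#' @param max_iter iteration cap for the alternating strategy.
#' @return a `model_fit` (`family = "nb"`).
#' @export
fit_nb <- function(y, tol = 1e-6, max_iter = 100L) {
  y <- check_counts(y)
  if (length(y) < 2L) stop("need at least two observations")
  if (all(y == 0))
    return(model_fit("nb", 0, 0, loglik = 0, converged = TRUE,
                     degenerate = TRUE))
  cc <- collapse_counts(y)
  vals <- cc$values; wts <- cc$weights
  lmu0 <- log(mean(y))
  lth_lo <- log(.THETA_MIN); lth_hi <- log(.THETA_MAX)

  best <- NULL
  # strategy (a): joint fits from a grid of theta starting values
  for (lth0 in log(10) * (-8:4)) {
    opt <- try(stats::optim(c(lmu0, lth0), nb_nll_collapsed,
                            gr = nb_nll_grad_collapsed,
                            vals = vals, wts = wts, method = "L-BFGS-B",
                            lower = c(lmu0 - 30, lth_lo),
                            upper = c(lmu0 + 30, lth_hi),
                            control = list(maxit = 200L)), silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value - 1e-12) {
      best <- opt
      best$ok <- opt$convergence == 0
    }
  }
  # strategy (b): alternate closed-form mean step and 1-d dispersion search
  lmu <- lmu0; lth <- log(1)
  prev <- Inf; ok_b <- FALSE
  for (it in seq_len(max_iter)) {
    lmu <- log(mean(y))  # intercept-only NB mean MLE is the sample mean
    o <- stats::optimize(function(l) nb_nll_collapsed(c(lmu, l), vals, wts),
                         lower = lth_lo, upper = lth_hi, tol = 1e-10)
    lth <- o$minimum
    if (abs(prev - o$objective) < tol) { ok_b <- TRUE; break }
    prev <- o$objective
  }
  alt <- list(par = c(lmu, lth), value = prev, ok = ok_b)
  if (is.null(best) || alt$value < best$value) best <- alt

  theta <- exp(best$par[2L])
  phi <- if (theta >= .THETA_MAX * 0.999) 0 else 1 / theta
  model_fit("nb", exp(best$par[1L]), phi, loglik = -best$value,
            converged = isTRUE(best$ok))
}

zinb_nll_collapsed <- function(par, vals, wts) {
  mu <- exp(par[1L]); theta <- exp(par[2L]); pi0 <- stats::plogis(par[3L])
  ll <- log1p(-pi0) + stats::dnbinom(vals, size = theta, mu = mu, log = TRUE)
  z <- vals == 0
  if (any(z)) ll[z] <- log(pi0 + exp(ll[z]))
  -sum(wts * ll)
}

#' Fit an intercept-only zero-inflated negative binomial model to one gene
#'
#' Three-parameter maximum likelihood, initialized from the NB fit (its mean
#' and dispersion, plus a small starting zero mass) and optimized with
#' Nelder-Mead on the (log mu, log theta, logit pi0) scale. If the optimizer
#' cannot improve on the NB likelihood the NB solution with zero mass 0 is
#' returned, so `loglik(zinb) >= loglik(nb)` always holds.
#'
#' @param y non-negative integer count vector, length >= 3.
#' @param pi0_init starting zero-inflation mass.
#' @return a `model_fit` (`family = "zinb"`).
#' @export
fit_zinb <- function(y, pi0_init = 0.01) {
  y <- check_counts(y)
  if (length(y) < 3L) stop("need at least three observations")
  nb <- fit_nb(y)
  if (nb$degenerate)
    return(model_fit("zinb", 0, 0, 0, loglik = 0, converged = TRUE,
                     degenerate = TRUE))
  as_nb <- function() model_fit("zinb", nb$mean, nb$dispersion, 0,
                                loglik = nb$loglik, converged = nb$converged)
  if (all(y > 0)) return(as_nb())  # zero mass MLE is 0 without zeros
  cc <- collapse_counts(y)
  theta_init <- if (nb$dispersion > 0) 1 / nb$dispersion else .THETA_MAX
  start <- c(log(nb$mean), log(theta_init), stats::qlogis(pi0_init))
  opt <- try(stats::optim(start, zinb_nll_collapsed,
                          vals = cc$values, wts = cc$weights,
                          method = "Nelder-Mead",
                          control = list(maxit = 2000L, reltol = 1e-12)),
             silent = TRUE)
  if (inherits(opt, "try-error") || -opt$value < nb$loglik) return(as_nb())
  theta <- min(exp(opt$par[2L]), .THETA_MAX)
  phi <- if (theta >= .THETA_MAX * 0.999) 0 else 1 / theta
  model_fit("zinb", exp(opt$par[1L]), phi, stats::plogis(opt$par[3L]),
            loglik = -opt$value, converged = opt$convergence == 0)
}

# draw `n_draw` molecules without replacement from a cell's gene-labeled pool
# (multivariate hypergeometric); `counts` is the cell's integer count vector
sample_molecules <- function(counts, n_draw) {
  total <- sum(counts)
  if (n_draw >= total) return(counts)
  nz <- which(counts > 0L)
  cum <- cumsum(counts[nz])
  picks <- sample.int(total, n_draw)
  hit <- findInterval(picks - 0.5, c(0, cum))
  out <- integer(length(counts))
  out[nz] <- tabulate(hit, nbins = length(nz))
  out
}

#' Down-sample every cell to a common sequencing depth
#'
#' Computes the `depth_quantile` quantile of the per-cell total UMI counts as
#' the target depth, drops the cells below it, and replaces each remaining
#' cell's counts with a draw of exactly the target number of molecules taken
#' without replacement from its gene-labeled molecule pool (multivariate
#' hypergeometric sampling). Used to make per-gene count values comparable
#' across cells before goodness-of-fit testing.
#'
#' @param matrix a [count_matrix()].
#' @param depth_quantile quantile of per-cell totals that defines the target
#'   depth (default 0.10).
#' @param seed integer seed; required for reproducibility.
#' @return a [count_matrix()] in which every cell has the same total.
#' @export
downsample_cells <- function(matrix, depth_quantile = 0.10, seed) {
  matrix <- count_matrix(matrix)
  if (missing(seed)) stop("seed is required")
  totals <- colSums(unclass(matrix))
  target <- floor(stats::quantile(totals, depth_quantile, names = FALSE))
  if (target < 1) stop("target depth is zero; cannot down-sample")
  keep <- which(totals >= target)  # cells exactly at the target are retained
  out <- unclass(matrix)[, keep, drop = FALSE]
  set.seed(seed)
  for (j in seq_along(keep)) {
    if (totals[keep[j]] > target)
      out[, j] <- sample_molecules(out[, j], target)
  }
  count_matrix(out)
}
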